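#' Chromatographic capacity factor
#'
#' \eqn{k' = (t_R - t_0) / t_0} from a retention time and the column dead
#' time.
#'
#' @param t_r retention time, minutes.
#' @param t0 dead time, minutes (per run, from the input table; the RP18
#'   protocol records it as the baseline disturbance, the IAM protocol uses
#'   citric acid).
#' @return numeric capacity factor, \eqn{\ge 0}.
#' @section Errors: \code{t0 <= 0} raises a dead-time error; \code{t_r < t0}
#'   raises a negative-retention error.
#' @examples
#' capacity_factor(2.0, 1.0) # 1
#' @export
capacity_factor <- function(t_r, t0) {
  if (any(!is.finite(t0)) || any(t0 <= 0)) {
    stop(structure(class = c("protacsol_dead_time_error", "error", "condition"),
                   list(message = "dead time t0 must be positive", call = NULL)))
  }
  if (any(t_r < t0)) {
    stop(structure(class = c("protacsol_negative_retention_error", "error", "condition"),
                   list(message = "t_R < t0: negative retention", call = NULL)))
  }
  (t_r - t0) / t0
}

#' BRlogD from log k'60
#'
#' Converts the log capacity factor measured on the RP18 system at 60%
#' acetonitrile into the BRlogD lipophilicity index via the calibration line
#' BRlogD = 3.31 log k'60 + 2.79.
#'
#' @param log_k60 log10 capacity factor at 60% ACN; must be finite
#'   (an unretained analyte with k' = 0 has no defined BRlogD).
#' @return numeric BRlogD.
#' @examples
#' brlogd_from_logk60(0)  # 2.79
#' brlogd_from_logk60(1)  # 6.10
#' @export
brlogd_from_logk60 <- function(log_k60) {
  if (any(!is.finite(log_k60))) {
    stop(structure(class = c("protacsol_undefined_log_error", "error", "condition"),
                   list(message = "log k'60 not finite (k' = 0 has no log)", call = NULL)))
  }
  3.31 * log_k60 + 2.79
}

#' Extrapolate log kw(IAM) to 100% aqueous mobile phase
#'
#' Fits an ordinary least-squares line of mean log k' versus the organic
#' modifier percentage and returns the intercept at 0% acetonitrile together
#' with the fit R-squared. Replicate injections at the same percentage are
#' averaged on the log k' scale before fitting.
#'
#' @param percent_organic \%v/v acetonitrile for each measurement.
#' @param log_k log10 capacity factor for each measurement.
#' @return list with \code{log_kw_iam} (intercept), \code{slope}, and
#'   \code{extrapolation_r2}.
#' @section Errors: fewer than 3 distinct percentages raises an
#'   insufficient-data error; non-finite log k' (k' = 0) raises an
#'   undefined-log error naming the offending points.
#' @examples
#' extrapolate_log_kw_iam(c(10, 20, 30), c(1.8, 1.4, 1.0)) # intercept 2.2
#' @export
extrapolate_log_kw_iam <- function(percent_organic, log_k) {
  stopifnot(length(percent_organic) == length(log_k))
  if (any(!is.finite(log_k))) {
    stop(structure(class = c("protacsol_undefined_log_error", "error", "condition"),
                   list(message = paste0("log k' not finite at %ACN = ",
                                         paste(percent_organic[!is.finite(log_k)], collapse = ", ")),
                        call = NULL)))
  }
  means <- tapply(log_k, percent_organic, mean)
  x <- as.numeric(names(means))
  y <- as.numeric(means)
  if (length(x) < 3) {
    stop(structure(class = c("protacsol_insufficient_data_error", "error", "condition"),
                   list(message = "need >= 3 distinct organic percentages for extrapolation",
                        call = NULL)))
  }
  fit <- fit_linear(x, y, x_name = "percent_acn", y_name = "log_k")
  list(log_kw_iam = fit$intercept, slope = fit$slope,
       extrapolation_r2 = fit$r2)
}

#' Expected log kw(IAM) of a PSA-free neutral analyte
#'
#' The reference line clog kw(IAM) = 0.92 BRlogD - 1.03 against which the
#' polarity excess is measured.
#'
#' @param brlogd numeric BRlogD.
#' @return numeric.
#' @export
clog_kw_iam <- function(brlogd) 0.92 * brlogd - 1.03

#' Polarity descriptor delta log kw(IAM)
#'
#' \eqn{\Delta \log k_w^{IAM} = \log k_w^{IAM} - (0.92\,BRlogD - 1.03)}: the
#' excess membrane affinity over the value expected for a polar-surface-free
#' neutral analyte of the same lipophilicity.
#'
#' @param log_kw_iam extrapolated log kw(IAM).
#' @param brlogd BRlogD of the same compound.
#' @return numeric.
#' @examples
#' delta_log_kw_iam(2.0, 2.0) # 1.19
#' @export
delta_log_kw_iam <- function(log_kw_iam, brlogd) {
  stopifnot(is.finite(log_kw_iam), is.finite(brlogd))
  log_kw_iam - clog_kw_iam(brlogd)
}

#' Chromatographic descriptor profiles from raw retention tables
#'
#' Computes, per compound: BRlogD from the RP18 isocratic run at 60\% ACN,
#' log kw(IAM) by linear extrapolation of the IAM gradient points to 0\% ACN,
#' the derived clog kw(IAM) and delta log kw(IAM), and (optionally) EPSA
#' ingested from a supercritical-fluid-chromatography result table.
#'
#' Replicates are averaged on the log k' scale. EPSA values are passed
#' through unchanged unless a user calibration line is supplied, in which
#' case EPSA = a * retention + b is applied to the raw retention column.
#'
#' @param retention data.frame with columns \code{compound_id}, \code{system}
#'   (\code{"RP18_isocratic_60ACN"} or \code{"IAM_gradient_points"}),
#'   \code{percent_organic}, \code{t_R_min}, \code{t0_min},
#'   \code{replicate}.
#' @param epsa optional data.frame with columns \code{compound_id} and either
#'   \code{epsa} (pass-through) or \code{retention} (transformed by
#'   \code{epsa_calibration}).
#' @param epsa_calibration optional list/vector with elements \code{a},
#'   \code{b} of a user-supplied calibration line.
#' @return data.frame with one row per compound: \code{compound_id},
#'   \code{brlogd}, \code{log_kw_iam}, \code{extrapolation_r2},
#'   \code{clog_kw_iam}, \code{delta_log_kw_iam}, \code{epsa}.
#' @export
chromatographic_descriptors <- function(retention, epsa = NULL,
                                        epsa_calibration = NULL) {
  req <- c("compound_id", "system", "percent_organic", "t_R_min", "t0_min",
           "replicate")
  miss <- setdiff(req, names(retention))
  if (length(miss) > 0) {
    stop(structure(class = c("protacsol_schema_error", "error", "condition"),
                   list(message = paste0("retention table missing column(s): ",
                                         paste(miss, collapse = ", ")), call = NULL)))
  }
  ids <- unique(retention$compound_id)
  rows <- lapply(ids, function(id) {
    sub <- retention[retention$compound_id == id, ]
    brlogd <- NA_real_
    rp <- sub[sub$system == "RP18_isocratic_60ACN", ]
    if (nrow(rp) > 0) {
      logk <- log10(capacity_factor(rp$t_R_min, rp$t0_min))
      brlogd <- brlogd_from_logk60(mean(logk))
    }
    log_kw <- r2 <- NA_real_
    iam <- sub[sub$system == "IAM_gradient_points", ]
    if (nrow(iam) > 0) {
      logk <- log10(capacity_factor(iam$t_R_min, iam$t0_min))
      ex <- extrapolate_log_kw_iam(iam$percent_organic, logk)
      log_kw <- ex$log_kw_iam
      r2 <- ex$extrapolation_r2
    }
    clog <- if (is.na(brlogd)) NA_real_ else clog_kw_iam(brlogd)
    delta <- if (is.na(brlogd) || is.na(log_kw)) NA_real_ else log_kw - clog
    data.frame(compound_id = id, brlogd = brlogd, log_kw_iam = log_kw,
               extrapolation_r2 = r2, clog_kw_iam = clog,
               delta_log_kw_iam = delta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$epsa <- NA_real_
  if (!is.null(epsa)) {
    if (!is.null(epsa_calibration)) {
      stopifnot(all(c("a", "b") %in% names(epsa_calibration)),
                "retention" %in% names(epsa))
      vals <- epsa_calibration[["a"]] * epsa$retention + epsa_calibration[["b"]]
    } else {
      stopifnot("epsa" %in% names(epsa))
      vals <- epsa$epsa
    }
    out$epsa <- vals[match(out$compound_id, epsa$compound_id)]
  }
  out
}
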