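#' Fit an HPLC-UV calibration curve
#'
#' Ordinary least-squares line AUC = slope * concentration + intercept over
#' the calibration points of one compound. The shake-flask protocol uses 5-10
#' point curves; fewer than 5 points returns the curve with an under-powered
#' warning.
#'
#' @param conc_mg_ml calibration concentrations, mg/mL.
#' @param auc peak areas, absorbance units (replicate injections may simply be
#'   repeated points; they are handled by the least-squares fit).
#' @return object of class \code{protacsol_calibration}: list with
#'   \code{slope}, \code{intercept}, \code{r2}, \code{n},
#'   \code{points}.
#' @section Errors: all concentrations equal raises a degenerate-design error.
#' @examples
#' fit_calibration(1:5, 100 * (1:5))
#' @export
fit_calibration <- function(conc_mg_ml, auc) {
  stopifnot(length(conc_mg_ml) == length(auc))
  if (length(unique(conc_mg_ml)) < 2) {
    stop(structure(class = c("protacsol_degenerate_design_error", "error", "condition"),
                   list(message = "calibration needs >= 2 distinct concentrations",
                        call = NULL)))
  }
  if (length(conc_mg_ml) < 5) {
    warning("calibration curve has fewer than 5 points; quantification may be under-powered")
  }
  fit <- fit_linear(conc_mg_ml, auc, x_name = "conc_mg_ml", y_name = "auc")
  structure(list(slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
                 n = length(auc),
                 points = data.frame(conc_mg_ml = conc_mg_ml, auc = auc)),
            class = "protacsol_calibration")
}

#' Quantify a sample concentration from its peak area
#'
#' Interpolates the sample AUC into the calibration line and applies the
#' dilution factor: conc = dilution * (auc - intercept) / slope. A
#' non-positive interpolated concentration is clamped to a censored
#' (below-LOQ) result rather than reported as a negative number.
#'
#' @param auc sample peak area.
#' @param curve a \code{protacsol_calibration} object.
#' @param dilution_factor dilution applied before injection (>= 1).
#' @return list with \code{conc_mg_ml} (NA when censored) and \code{censored}.
#' @examples
#' cal <- fit_calibration(1:5, 100 * (1:5))
#' quantify(500, cal, dilution_factor = 10) # 50 mg/mL
#' @export
quantify <- function(auc, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "protacsol_calibration"), dilution_factor >= 1)
  if (curve$slope == 0) {
    stop(structure(class = c("protacsol_unusable_curve_error", "error", "condition"),
                   list(message = "calibration slope is zero", call = NULL)))
  }
  conc <- dilution_factor * (auc - curve$intercept) / curve$slope
  if (!is.finite(conc) || conc <= 0) {
    return(list(conc_mg_ml = NA_real_, censored = TRUE))
  }
  list(conc_mg_ml = conc, censored = FALSE)
}

#' Convert a mass concentration to log S
#'
#' log10 of the molar saturation concentration: log10(conc / mw), with conc
#' in mg/mL (numerically equal to g/L) and mw in g/mol.
#'
#' @param conc_mg_ml concentration, mg/mL; must be positive.
#' @param mw molecular weight, g/mol; must be positive.
#' @return numeric log S (mol/L).
#' @examples
#' to_log_s(1, 1000) # -3
#' @export
to_log_s <- function(conc_mg_ml, mw) {
  if (any(conc_mg_ml <= 0) || any(mw <= 0)) {
    stop(structure(class = c("protacsol_domain_error", "error", "condition"),
                   list(message = "conc and mw must be positive", call = NULL)))
  }
  log10(conc_mg_ml / mw)
}

#' Micromolar solubility from log S
#'
#' @param log_s log10 molar solubility.
#' @return numeric, micromolar.
#' @export
log_s_to_micromolar <- function(log_s) 10^log_s * 1e6

#' GSK thermodynamic-solubility class
#'
#' Assigns the three-level GSK classification: low (< 30 uM), intermediate
#' (30-200 uM, boundaries included), high (> 200 uM). Censored (below-LOQ)
#' measurements carry no numeric value and are assigned to the low class.
#'
#' @param s_micromolar solubility in micromolar; may be NA for censored
#'   entries.
#' @param censored logical vector, same length (default all FALSE).
#' @return ordered factor with levels low < intermediate < high.
#' @examples
#' gsk_class(c(10, 100, 500))
#' gsk_class(NA, censored = TRUE) # low
#' @export
gsk_class <- function(s_micromolar, censored = FALSE) {
  n <- max(length(s_micromolar), length(censored))
  s <- rep_len(s_micromolar, n)
  cen <- rep_len(censored, n)
  if (any(!cen & (is.na(s) | s < 0))) {
    stop(structure(class = c("protacsol_domain_error", "error", "condition"),
                   list(message = "negative or missing concentration for a non-censored entry",
                        call = NULL)))
  }
  lab <- ifelse(cen, "low",
                ifelse(s < 30, "low", ifelse(s <= 200, "intermediate", "high")))
  factor(lab, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Keep only quantitative (non-censored) solubility records
#'
#' Censored measurements enter the classification (low class) but are
#' excluded from every regression; this helper applies that filter.
#'
#' @param measurements data.frame with a logical \code{censored} column.
#' @return the non-censored rows, original order preserved, with the retained
#'   count reported as attribute \code{n_quantitative}.
#' @export
filter_quantitative <- function(measurements) {
  stopifnot("censored" %in% names(measurements))
  out <- measurements[!measurements$censored, , drop = FALSE]
  attr(out, "n_quantitative") <- nrow(out)
  out
}

#' Replicate summary: mean, standard deviation, relative standard deviation
#'
#' Sample standard deviation (n - 1 denominator) and RSD = 100 * sd / mean.
#'
#' @param values numeric replicate values.
#' @return list with \code{mean}, \code{sd} (NA with a warning for a single
#'   value), \code{rsd} (\% of the mean).
#' @examples
#' summarize_replicates(c(4, 6)) # mean 5, sd 1.41, rsd 28.3
#' @export
summarize_replicates <- function(values) {
  m <- mean(values)
  if (length(values) < 2) {
    warning("single replicate: sd undefined")
    return(list(mean = m, sd = NA_real_, rsd = NA_real_))
  }
  s <- stats::sd(values)
  list(mean = m, sd = s, rsd = if (m != 0) 100 * s / m else NA_real_)
}

#' Shake-flask solubility quantification pipeline
#'
#' Per compound: fits the calibration curve, interpolates the replicate
#' sample peak areas with dilution correction, summarizes replicates, converts
#' to log S and micromolar units, applies censoring, and assigns the GSK
#' class.
#'
#' @param calibration data.frame with columns \code{compound_id},
#'   \code{conc_mg_ml}, \code{auc}.
#' @param samples data.frame with columns \code{compound_id}, \code{auc},
#'   \code{dilution_factor} (one row per replicate injection).
#' @param compounds data.frame with columns \code{id}, \code{mw}.
#' @return data.frame with one row per compound: \code{compound_id},
#'   \code{conc_mg_ml}, \code{sd}, \code{rsd}, \code{s_molar}, \code{log_s},
#'   \code{s_micromolar}, \code{censored}, \code{gsk_class}.
#' @export
quantify_solubility <- function(calibration, samples, compounds) {
  stopifnot(all(c("compound_id", "conc_mg_ml", "auc") %in% names(calibration)),
            all(c("compound_id", "auc", "dilution_factor") %in% names(samples)),
            all(c("id", "mw") %in% names(compounds)))
  ids <- unique(samples$compound_id)
  rows <- lapply(ids, function(id) {
    cal <- calibration[calibration$compound_id == id, ]
    smp <- samples[samples$compound_id == id, ]
    curve <- fit_calibration(cal$conc_mg_ml, cal$auc)
    reps <- vapply(seq_len(nrow(smp)), function(k) {
      q <- quantify(smp$auc[k], curve, smp$dilution_factor[k])
      if (q$censored) NA_real_ else q$conc_mg_ml
    }, numeric(1))
    censored <- all(is.na(reps))
    mw <- compounds$mw[match(id, compounds$id)]
    if (censored) {
      return(data.frame(compound_id = id, conc_mg_ml = NA_real_, sd = NA_real_,
                        rsd = NA_real_, s_molar = NA_real_, log_s = NA_real_,
                        s_micromolar = NA_real_, censored = TRUE,
                        gsk_class = "low", stringsAsFactors = FALSE))
    }
    st <- suppressWarnings(summarize_replicates(reps[!is.na(reps)]))
    log_s <- to_log_s(st$mean, mw)
    s_molar <- st$mean / mw
    s_um <- s_molar * 1e6
    data.frame(compound_id = id, conc_mg_ml = st$mean, sd = st$sd,
               rsd = st$rsd, s_molar = s_molar, log_s = log_s,
               s_micromolar = s_um, censored = FALSE,
               gsk_class = as.character(gsk_class(s_um)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gsk_class <- factor(out$gsk_class,
                          levels = c("low", "intermediate", "high"),
                          ordered = TRUE)
  out
}
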