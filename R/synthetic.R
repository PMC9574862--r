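#' Noise level for a target coefficient of determination
#'
#' Residual standard deviation sigma such that a simple linear model with
#' signal variance var(slope * x) attains the target R-squared in
#' expectation: sigma^2 = var(slope * x) (1 - R2) / R2.
#'
#' @param slope generating slope.
#' @param x_var variance of the regressor (for a uniform range \[a, b\]:
#'   (b - a)^2 / 12).
#' @param r2 target R-squared in (0, 1).
#' @return sigma.
#' @export
calibrate_noise_sd <- function(slope, x_var, r2) {
  stopifnot(r2 > 0, r2 < 1, x_var > 0)
  sqrt(slope^2 * x_var * (1 - r2) / r2)
}

#' Generator configuration for synthetic PROTAC studies
#'
#' Defaults emulate the measured study: 21 compounds spanning TPSA 166-335
#' A^2, nC 34-58 and Phi 9-27; solubility generated from
#' log S = -0.75 BRlogD - 3.29 with residual noise calibrated so the
#' regression attains R2 of about 0.67; log kw(IAM) generated as
#' 0.92 BRlogD - 1.03 plus a polarity offset ~ N(0, 0.4) so the
#' delta log kw(IAM) identity is exercised; censoring below the
#' quantification limit (default log S -6.5, just under the least soluble
#' quantified compound); GSK class thresholds 30 and 200 micromolar.
#'
#' @param n_compounds number of PROTACs.
#' @param seed RNG seed; every draw derives from it.
#' @param brlogd_range,tpsa_range,nc_range,phi_range uniform sampling ranges.
#' @param slope,intercept generating line for log S vs BRlogD.
#' @param target_r2 used to calibrate \code{noise_sd} when the latter is NULL.
#' @param noise_sd residual sd of log S; NULL = calibrate from
#'   \code{target_r2}.
#' @param delta_sd sd of the polarity offset added to clog kw(IAM).
#' @param loq_log_s censoring threshold on log S.
#' @param mw_range uniform range of assigned molecular weights, g/mol
#'   (synthetic compounds carry no structures).
#' @param class_thresholds GSK class bounds, micromolar.
#' @return list of class \code{protacsol_generator_config}.
#' @export
generator_config <- function(n_compounds = 21, seed = 1,
                             brlogd_range = c(0.5, 5.5),
                             tpsa_range = c(166, 335),
                             nc_range = c(34, 58),
                             phi_range = c(9, 27),
                             slope = -0.75, intercept = -3.29,
                             target_r2 = 0.67, noise_sd = NULL,
                             delta_sd = 0.4, loq_log_s = -6.5,
                             mw_range = c(700, 1100),
                             class_thresholds = c(30, 200)) {
  stopifnot(n_compounds >= 1, diff(brlogd_range) > 0, diff(tpsa_range) > 0,
            diff(nc_range) > 0, diff(phi_range) > 0, diff(mw_range) > 0)
  if (is.null(noise_sd)) {
    noise_sd <- calibrate_noise_sd(slope, diff(brlogd_range)^2 / 12, target_r2)
  }
  stopifnot(noise_sd >= 0)
  structure(list(n_compounds = n_compounds, seed = seed,
                 brlogd_range = brlogd_range, tpsa_range = tpsa_range,
                 nc_range = nc_range, phi_range = phi_range,
                 slope = slope, intercept = intercept,
                 target_r2 = target_r2, noise_sd = noise_sd,
                 delta_sd = delta_sd, loq_log_s = loq_log_s,
                 mw_range = mw_range, class_thresholds = class_thresholds),
            class = "protacsol_generator_config")
}

#' Generate a synthetic PROTAC dataset
#'
#' Draws descriptor vectors uniformly over the configured ranges
#' (independently; the weak BRlogD / computed-log P correlation of real data
#' is not emulated), builds log kw(IAM) from the clog kw(IAM) line plus a
#' polarity offset, generates log S from the configured linear model with
#' Gaussian noise, censors entries below the quantification limit, and
#' assigns GSK classes from the micromolar values. Fully reproducible from
#' the config seed.
#'
#' @param config a \code{protacsol_generator_config}.
#' @return a \code{protac_dataset} with compounds, descriptors and
#'   solubility filled in.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "protacsol_generator_config"))
  set.seed(config$seed)
  n <- config$n_compounds
  id <- sprintf("SYN-%03d", seq_len(n))
  brlogd <- runif(n, config$brlogd_range[1], config$brlogd_range[2])
  tpsa <- runif(n, config$tpsa_range[1], config$tpsa_range[2])
  nc <- round(runif(n, config$nc_range[1], config$nc_range[2]))
  phi <- runif(n, config$phi_range[1], config$phi_range[2])
  mw <- runif(n, config$mw_range[1], config$mw_range[2])
  delta <- rnorm(n, 0, config$delta_sd)
  log_kw_iam <- clog_kw_iam(brlogd) + delta
  log_s <- config$slope * brlogd + config$intercept +
    rnorm(n, 0, config$noise_sd)
  censored <- log_s < config$loq_log_s
  s_um <- ifelse(censored, NA_real_, 10^log_s * 1e6)
  cls <- gsk_class(s_um, censored)
  compounds <- data.frame(id = id, name = id, smiles = NA_character_,
                          mw = mw, role = "protac",
                          charge_note = "neutral at pH 7",
                          pair_tags = NA_character_, stringsAsFactors = FALSE)
  descriptors <- data.frame(id = id, nc = nc, tpsa = tpsa, phi = phi,
                            brlogd = brlogd, log_kw_iam = log_kw_iam,
                            clog_kw_iam = clog_kw_iam(brlogd),
                            delta_log_kw_iam = log_kw_iam - clog_kw_iam(brlogd),
                            stringsAsFactors = FALSE)
  solubility <- data.frame(compound_id = id,
                           log_s = ifelse(censored, NA_real_, log_s),
                           s_micromolar = s_um, censored = censored,
                           gsk_class = cls, stringsAsFactors = FALSE)
  ds <- protac_dataset(compounds, solubility = solubility,
                       descriptors = descriptors)
  ds$config <- config
  ds
}

#' Generate retention tables consistent with a dataset's descriptors
#'
#' Inverse of the chromatographic transforms: the RP18 record reproduces the
#' compound's BRlogD through t_R = t0 (1 + 10^((BRlogD - 2.79) / 3.31)), and
#' the IAM records lie on a line in \%ACN whose intercept at 0\% is the
#' compound's log kw(IAM) (slope \code{iam_slope} per \%). Replicate jitter
#' of sd \code{tau} is applied on the log k' scale; with \code{tau = 0} the
#' chromatography module recovers the descriptors exactly.
#'
#' @param dataset a \code{protac_dataset} whose descriptors contain
#'   \code{brlogd} and \code{log_kw_iam}.
#' @param tau replicate jitter sd on the log k' scale.
#' @param t0_rp18,t0_iam dead times, minutes.
#' @param iam_percents organic percentages of the IAM series.
#' @param iam_slope slope of the IAM log k' line per \%ACN.
#' @param replicates injections per condition.
#' @return retention data.frame (see
#'   \code{\link{chromatographic_descriptors}}).
#' @export
generate_retention_tables <- function(dataset, tau = 0, t0_rp18 = 1.0,
                                      t0_iam = 2.0,
                                      iam_percents = seq(10, 50, 10),
                                      iam_slope = -0.04, replicates = 2) {
  stopifnot(inherits(dataset, "protac_dataset"),
            all(c("brlogd", "log_kw_iam") %in% names(dataset$descriptors)))
  d <- dataset$descriptors
  rows <- list()
  for (i in seq_len(nrow(d))) {
    logk60 <- (d$brlogd[i] - 2.79) / 3.31
    for (r in seq_len(replicates)) {
      lk <- logk60 + if (tau > 0) rnorm(1, 0, tau) else 0
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = d$id[i], system = "RP18_isocratic_60ACN",
        percent_organic = 60, t_R_min = t0_rp18 * (1 + 10^lk),
        t0_min = t0_rp18, replicate = r, stringsAsFactors = FALSE)
    }
    for (p in iam_percents) {
      for (r in seq_len(replicates)) {
        lk <- d$log_kw_iam[i] + iam_slope * p +
          if (tau > 0) rnorm(1, 0, tau) else 0
        rows[[length(rows) + 1]] <- data.frame(
          compound_id = d$id[i], system = "IAM_gradient_points",
          percent_organic = p, t_R_min = t0_iam * (1 + 10^lk),
          t0_min = t0_iam, replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a toy conformer ensemble
#'
#' A small rigid polar fragment (an O-C-N triangle at roughly bonding
#' distances) with seeded per-conformer coordinate jitter; useful for
#' exercising the 3D-PSA machinery against known analytic bounds (each
#' conformer's PSA lies between one full polar-atom sphere and the sum of
#' the isolated O and N spheres).
#'
#' @param n_conformers number of conformers (>= 1).
#' @param seed RNG seed.
#' @param jitter sd of the coordinate jitter, angstroms (0 = identical
#'   conformers).
#' @return a \code{protacsol_ensemble}.
#' @export
generate_toy_ensemble <- function(n_conformers, seed = 1, jitter = 0.1) {
  stopifnot(n_conformers >= 1, jitter >= 0)
  set.seed(seed)
  base <- rbind(c(0.00, 0.00, 0), # C
                c(1.23, 0.00, 0), # O (carbonyl-like distance)
                c(-0.68, 1.18, 0)) # N (amide-like distance)
  elements <- c("C", "O", "N")
  conformers <- lapply(seq_len(n_conformers), function(i) {
    base + matrix(rnorm(9, 0, jitter), 3, 3)
  })
  conformer_ensemble(sprintf("TOY-%d", seed), elements, conformers,
                     source = "other")
}
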