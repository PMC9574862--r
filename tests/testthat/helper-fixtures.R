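# Shared fixtures: reference panels and small table builders.

tpsa_panel <- function() {
  read.csv(system.file("extdata", "tpsa_reference_panel.csv",
                       package = "protacsol"),
           stringsAsFactors = FALSE)
}

protac_set <- function() {
  read.csv(system.file("extdata", "protac_set_partly_synthetic.csv",
                       package = "protacsol"),
           stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

bb_pairs <- function() {
  read.csv(system.file("extdata", "building_block_pairs.csv",
                       package = "protacsol"),
           stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

# a minimal consistent retention table for one compound
make_iam_series <- function(id = "X", percents = c(10, 20, 30),
                            log_k = c(1.8, 1.4, 1.0), t0 = 2) {
  do.call(rbind, lapply(seq_along(percents), function(i) {
    data.frame(compound_id = id, system = "IAM_gradient_points",
               percent_organic = percents[i],
               t_R_min = t0 * (1 + 10^log_k[i]), t0_min = t0, replicate = 1L,
               stringsAsFactors = FALSE)
  }))
}

make_rp18_row <- function(id = "X", log_k60 = 0.5, t0 = 1, replicate = 1L) {
  data.frame(compound_id = id, system = "RP18_isocratic_60ACN",
             percent_organic = 60, t_R_min = t0 * (1 + 10^log_k60),
             t0_min = t0, replicate = replicate, stringsAsFactors = FALSE)
}

# closed-form OLS used as the independent oracle against fit_linear and the
# calibration / extrapolation fits
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r2 = r2)
}

# exposed area of sphere 1 (radius r1) partially occluded by sphere 2
# (radius r2) at centre distance d: spherical-cap closed form
two_sphere_exposed_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  2 * pi * r1 * (r1 + a)
}
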