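test_that("an unoccluded polar atom exposes its full sphere", {
  got <- compute_3d_psa("O", matrix(0, 1, 3))
  expect_equal(as.numeric(got), 4 * pi * 1.52^2, tolerance = 1e-12)
  # two O atoms far apart: additivity
  two <- compute_3d_psa(c("O", "O"), rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(as.numeric(two), 2 * 4 * pi * 1.52^2, tolerance = 1e-12)
})

test_that("apolar molecules have zero 3D-PSA", {
  coords <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
                  c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89))
  expect_equal(as.numeric(compute_3d_psa(c("C", rep("H", 4)), coords)), 0)
})

test_that("occluded areas match the spherical-cap oracle within 0.5%", {
  d <- 1.43 # C-O bonding distance
  coords <- rbind(c(0, 0, 0), c(d, 0, 0))
  got <- as.numeric(compute_3d_psa(c("O", "C"), coords, n_points = 960))
  oracle <- two_sphere_exposed_area(1.52, 1.70, d)
  expect_lt(abs(got - oracle) / oracle, 0.005)
  # polar pair: both spheres contribute their exposed caps
  got2 <- as.numeric(compute_3d_psa(c("O", "N"), coords, n_points = 960))
  oracle2 <- two_sphere_exposed_area(1.52, 1.55, d) +
    two_sphere_exposed_area(1.55, 1.52, d)
  expect_lt(abs(got2 - oracle2) / oracle2, 0.005)
})

test_that("PSA is rigid-motion invariant within sampling tolerance", {
  set.seed(42)
  base <- generate_toy_ensemble(1, seed = 5, jitter = 0.2)$conformers[[1]]
  els <- c("C", "O", "N")
  ref <- as.numeric(compute_3d_psa(els, base, n_points = 3840))
  for (k in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
                c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    moved <- base %*% Rx %*% Rz +
      matrix(runif(3, -5, 5), 3, 3, byrow = TRUE)
    got <- as.numeric(compute_3d_psa(els, moved, n_points = 3840))
    expect_lt(abs(got - ref) / ref, 0.005)
  }
})

test_that("PSA is bounded by the isolated-sphere sum and converges with points", {
  ens <- generate_toy_ensemble(1, seed = 3, jitter = 0)
  cf <- ens$conformers[[1]]
  isolated <- 4 * pi * (1.52^2 + 1.55^2)
  p960 <- as.numeric(compute_3d_psa(ens$elements, cf, n_points = 960))
  expect_lt(p960, isolated)
  p240 <- as.numeric(compute_3d_psa(ens$elements, cf, n_points = 240))
  p3840 <- as.numeric(compute_3d_psa(ens$elements, cf, n_points = 3840))
  p15360 <- as.numeric(compute_3d_psa(ens$elements, cf, n_points = 15360))
  expect_lt(abs(p3840 - p15360), abs(p240 - p960) + 1e-9)
})

test_that("unknown elements raise a parameterization error", {
  expect_error(compute_3d_psa("Xx", matrix(0, 1, 3)),
               class = "protacsol_parameterization_error")
})

test_that("ensemble summaries follow the interpolated-quantile/fence rules", {
  s <- summarize_ensemble(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q1, 25.75)
  expect_equal(s$q3, 75.25)
  # Tukey fences: {10,12,14,16,100} -> IQR on q1=12, q3=16; 100 outside
  s2 <- summarize_ensemble(c(10, 12, 14, 16, 100))
  expect_equal(s2$q1, 12)
  expect_equal(s2$q3, 16)
  expect_equal(s2$upper_adjacent, 16)
  expect_equal(s2$lower_adjacent, 10)
  s3 <- summarize_ensemble(7.5)
  expect_equal(unlist(s3[c("median", "q1", "q3", "lower_adjacent",
                           "upper_adjacent")]),
               rep(7.5, 5), ignore_attr = TRUE)
  expect_error(summarize_ensemble(numeric(0)),
               class = "protacsol_domain_error")
})

test_that("adjacent limits are data members and the summary is ordered", {
  set.seed(9)
  for (k in 1:20) {
    x <- rlnorm(sample(3:40, 1), 3, 0.5)
    s <- summarize_ensemble(x)
    # data members, except in the degenerate fall-back to the quartile itself
    expect_true(s$lower_adjacent %in% x || s$lower_adjacent == s$q1)
    expect_true(s$upper_adjacent %in% x || s$upper_adjacent == s$q3)
    expect_true(s$lower_adjacent <= s$q1 + 1e-12)
    expect_true(s$q1 <= s$median && s$median <= s$q3)
    expect_true(s$upper_adjacent >= s$q3 - 1e-12)
    # permutation invariance
    s2 <- summarize_ensemble(sample(x))
    expect_equal(s2[c("median", "q1", "q3")], s[c("median", "q1", "q3")])
  }
})

test_that("ensembles round-trip through SDF and PDB readers", {
  one <- protacsol::parse_smiles("CC(=O)N", ids = "acetamide")[[1]]
  sdf <- methods::new("SDFset", SDF = list(one, one),
                      ID = c("conf1", "conf2"))
  path <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, path, cid = TRUE)
  ens <- read_ensemble_sdf(path)
  expect_s3_class(ens, "protacsol_ensemble")
  expect_length(ens$conformers, 2)
  expect_equal(ens$elements, c("C", "C", "O", "N"))
  # tiny two-model PDB written inline: a C=O fragment
  pdb <- c(
    "MODEL        1",
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O1  LIG A   1       1.230   0.000   0.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O1  LIG A   1       1.250   0.000   0.000  1.00  0.00           O",
    "ENDMDL",
    "END")
  ppath <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, ppath)
  ens2 <- read_ensemble_pdb(ppath)
  expect_length(ens2$conformers, 2)
  expect_equal(ens2$elements, c("C", "O"))
  dist <- ensemble_psa_distribution(ens2)
  expect_length(dist$per_conformer_psa, 2)
})

test_that("representative-statistic regressions match the OLS oracle", {
  set.seed(21)
  dists <- lapply(1:6, function(i) {
    d <- summarize_ensemble(rnorm(30, 100 + 20 * i, 5))
    d$compound_id <- paste0("P", i)
    d
  })
  med <- vapply(dists, function(d) d$median, numeric(1))
  log_s <- setNames(-0.02 * med - 2, paste0("P", 1:6))
  tab <- representative_psa_regressions(dists, log_s)
  expect_equal(tab$statistic,
               c("lower_adjacent", "q1", "median", "q3", "upper_adjacent"))
  mrow <- tab[tab$statistic == "median", ]
  expect_equal(mrow$r2, 1, tolerance = 1e-9) # exactly linear in the median
  expect_equal(mrow$slope, -0.02, tolerance = 1e-9)
  q1row <- tab[tab$statistic == "q1", ]
  q1 <- vapply(dists, function(d) d$q1, numeric(1))
  oracle <- ols_oracle(q1, unname(log_s))
  expect_equal(q1row$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(q1row$r2, oracle$r2, tolerance = 1e-12)
  # permuting compounds leaves the table unchanged
  tab2 <- representative_psa_regressions(dists[sample(6)], log_s)
  expect_equal(tab2, tab)
})
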