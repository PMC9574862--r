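test_that("fit_linear matches the closed-form oracle and guards its domain", {
  f <- fit_linear(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  f0 <- fit_linear(1:5, rep(3, 5))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r2, 0)
  set.seed(4)
  x <- runif(30); y <- -1.4 * x + 0.3 + rnorm(30, 0, 0.2)
  f2 <- fit_linear(x, y)
  oracle <- ols_oracle(x, y)
  expect_equal(f2$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(f2$r2, oracle$r2, tolerance = 1e-10)
  expect_error(fit_linear(rep(2, 5), 1:5),
               class = "protacsol_degenerate_design_error")
  expect_error(fit_linear(1:2, 1:2),
               class = "protacsol_insufficient_data_error")
})

test_that("fit_linear is exchange-invariant and affine-equivariant in x", {
  set.seed(5)
  x <- c(1, 1, 2, 3, 5, 8); y <- 0.7 * x + rnorm(6, 0, 0.1)
  f <- fit_linear(x, y)
  perm <- c(2, 1, 4, 3, 6, 5)
  f2 <- fit_linear(x[perm], y[perm])
  expect_equal(f2$slope, f$slope, tolerance = 1e-12)
  # x -> a x + b: slope scales by 1/a, R2 unchanged
  fr <- fit_linear(10 * x + 3, y)
  expect_equal(fr$slope, f$slope / 10, tolerance = 1e-12)
  expect_equal(fr$r2, f$r2, tolerance = 1e-12)
})

test_that("the fixed TPSA/BRlogD rule classifies the three regions", {
  expect_equal(as.character(apply_paper_rule(300, 5)), "high")
  expect_equal(as.character(apply_paper_rule(200, 3.0)), "low")
  expect_equal(as.character(apply_paper_rule(200, 2.0)), "intermediate")
  # boundary: thresholds belong to the high / low branches
  expect_equal(as.character(apply_paper_rule(289.31, 0)), "high")
  expect_equal(as.character(apply_paper_rule(100, 2.58)), "low")
})

test_that("the fixed rule and its tree object agree on 10^4 random points", {
  set.seed(13)
  tpsa <- runif(1e4, 100, 400)
  brlogd <- runif(1e4, -1, 7)
  tree <- fixed_rule_tree()
  pred <- predict(tree, data.frame(tpsa = tpsa, brlogd = brlogd))
  expect_equal(as.character(pred),
               as.character(apply_paper_rule(tpsa, brlogd)))
})

test_that("tree learning finds the midpoint split by exhaustive search", {
  tr <- learn_tree(data.frame(x = c(1, 2, 3, 7, 8, 9)),
                   rep(c("A", "B"), each = 3))
  expect_equal(tr$root$threshold, 5.0)
  expect_equal(tr$root$feature, "x")
  # agreement with an independent recursive-partitioning implementation
  set.seed(8)
  x <- c(rnorm(20, 0), rnorm(20, 4))
  y <- rep(c("A", "B"), each = 20)
  tr2 <- learn_tree(data.frame(x = x), y, max_depth = 1)
  rp <- rpart::rpart(y ~ x, data.frame(x = x, y = factor(y)),
                     control = rpart::rpart.control(maxdepth = 1, minsplit = 2,
                                                    minbucket = 1, cp = 0))
  expect_equal(tr2$root$threshold, unname(rp$splits[1, "index"]),
               tolerance = 1e-9)
})

test_that("degenerate trees behave as specified", {
  expect_warning(tr <- learn_tree(data.frame(x = 1:4), rep("A", 4)),
                 "single-class")
  expect_true(tr$root$leaf)
  expect_equal(as.character(predict(tr, data.frame(x = 99))), "A")
  # XOR at depth 1: no single split beats 50%
  X <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  y <- c("A", "B", "B", "A")
  tr2 <- learn_tree(X, y, max_depth = 1)
  acc <- mean(as.character(predict(tr2, X)) == y)
  expect_equal(acc, 0.5)
})

test_that("training accuracy never drops below the majority baseline", {
  set.seed(17)
  for (k in 1:10) {
    n <- 40
    X <- data.frame(u = runif(n), v = runif(n))
    y <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
    tr <- learn_tree(X, factor(y, levels = c("low", "intermediate", "high")))
    acc <- mean(as.character(predict(tr, X)) == y)
    expect_gte(acc, max(table(y)) / n)
  }
})

test_that("cross-validation pools counts and scores separable data perfectly", {
  set.seed(3)
  n <- 60
  X <- data.frame(x = c(runif(n / 2, 0, 1), runif(n / 2, 5, 6)))
  y <- factor(rep(c("A", "B"), each = n / 2))
  cv <- cross_validate(X, y, k = 10, seed = 2)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(unname(rowSums(cv$confusion$table)), unname(table(y)),
               ignore_attr = TRUE)
  expect_error(cross_validate(X[1:5, , drop = FALSE], y[1:5], k = 10),
               class = "protacsol_fold_error")
})

test_that("cross-validated accuracy under label permutation is at chance", {
  set.seed(19)
  n <- 300
  X <- data.frame(x = runif(n), z = runif(n))
  y <- factor(rep(c("A", "B", "C"), each = n / 3)[sample(n)])
  cv <- cross_validate(X, y, k = 10, seed = 5, max_depth = 3)
  expect_lt(abs(cv$accuracy - 1 / 3), 0.12)
})

test_that("tree models survive a JSON round trip", {
  set.seed(23)
  X <- data.frame(tpsa = runif(30, 150, 350), brlogd = runif(30, 0, 6))
  y <- apply_paper_rule(X$tpsa, X$brlogd)
  tr <- learn_tree(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, path)
  tr2 <- read_tree(path)
  expect_equal(as.character(predict(tr2, X)), as.character(predict(tr, X)))
  expect_equal(tr2$provenance, "refit")
})

test_that("chemical-space export emits one complete row per compound", {
  ds <- generate_dataset(generator_config(n_compounds = 5, seed = 2))
  tab <- chemical_space_export(ds, axes = c("log_kw_iam", "brlogd", "tpsa"))
  expect_equal(nrow(tab), 5)
  expect_equal(attr(tab, "axes"), c("log_kw_iam", "brlogd", "tpsa"))
  expect_true(all(c("gsk_class", "censored") %in% names(tab)))
  ds$descriptors$tpsa[2] <- NA
  expect_warning(tab2 <- chemical_space_export(ds), "missing axis")
  expect_equal(nrow(tab2), 4)
})

test_that("pair comparison applies the interval concordance logic", {
  bb <- bb_pairs()
  sol <- unique(bb[, c("protac_id", "protac_log_s", "protac_censored")])
  names(sol) <- c("compound_id", "log_s", "censored")
  # warhead pair: PROTAC delta +1.87; censored-above warhead still decides
  w <- bb[bb$pair == "warhead_pair", ]
  bb_tab <- data.frame(protac_id = w$protac_id, bb_id = w$bb_id,
                       log_s = w$bb_log_s, censor = w$bb_censor)
  rep <- compare_pair(c("MZ1", "MZP-54"), "warhead", sol, bb_tab)
  expect_equal(rep$delta_log_s, 1.87, tolerance = 1e-9)
  expect_equal(rep$concordance, "concordant")
  # E3 pair: building-block ordering opposes the PROTAC ordering
  e <- bb[bb$pair == "e3_pair", ]
  bb_tab <- data.frame(protac_id = e$protac_id, bb_id = e$bb_id,
                       log_s = e$bb_log_s, censor = e$bb_censor)
  rep2 <- compare_pair(c("BI-3663", "BI-0319"), "e3_ligand", sol, bb_tab)
  expect_equal(rep2$delta_log_s, 0.42, tolerance = 1e-9)
  expect_equal(rep2$concordance, "discordant")
  expect_equal(unname(rep2$bb_delta["bb_delta_log_s"]), -1.76,
               tolerance = 1e-9)
  # missing building-block values: indeterminate
  l <- bb[bb$pair == "linker_pair", ]
  bb_tab <- data.frame(protac_id = l$protac_id, bb_id = l$bb_id,
                       log_s = l$bb_log_s, censor = l$bb_censor)
  rep3 <- compare_pair(c("dBET57", "ZXH-3-26"), "linker", sol, bb_tab)
  expect_equal(rep3$concordance, "indeterminate")
  # identical compound in both slots
  rep4 <- compare_pair(c("MZ1", "MZ1"), "warhead", sol,
                       data.frame(protac_id = "MZ1", bb_id = "JQ1",
                                  log_s = -2.6, censor = "above"))
  expect_equal(rep4$delta_log_s, 0)
  expect_equal(rep4$concordance, "indeterminate")
  expect_error(compare_pair(c("MZ1", "NOPE"), "warhead", sol, bb_tab),
               class = "protacsol_reference_error")
})

test_that("classification matrices honour exclusion lists and censoring", {
  ds <- generate_dataset(generator_config(n_compounds = 30, seed = 12))
  full <- classification_matrix(ds, quantitative_only = FALSE)
  expect_equal(nrow(full$X), 30)
  quant <- classification_matrix(ds)
  expect_equal(nrow(quant$X), sum(!ds$solubility$censored))
  drop1 <- classification_matrix(ds, exclude = quant$ids[1])
  expect_equal(nrow(drop1$X), nrow(quant$X) - 1)
  expect_false(quant$ids[1] %in% drop1$ids)
  expect_equal(names(drop1$X), c("tpsa", "brlogd", "log_kw_iam"))
})
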