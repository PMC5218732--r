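test_that("the published model carries the printed coefficients and the
           stated fold-change identities", {
  m <- published_model()
  expect_identical(unname(m$coefficients["FP1"]), 0.923)
  expect_identical(unname(m$coefficients["FP2"]), 2.209)
  expect_identical(unname(m$coefficients["FP3"]), 1.689)
  expect_identical(unname(m$coefficients["FP4"]), 1.487)
  expect_identical(unname(m$coefficients["FP5"]), 0.614)
  expect_identical(unname(m$coefficients["FP6"]), 3.861)
  expect_identical(m$intercept, -9.341)

  # fold-change readings of the coefficients
  expect_equal(round(10^m$coefficients[["FP2"]]), 162)
  expect_equal(signif(10^m$coefficients[["FP3"]], 1), 50)
  expect_equal(signif(10^m$coefficients[["FP4"]], 1), 30)
  expect_equal(round(10^m$coefficients[["FP1"]]), 8)
  expect_equal(round(10^m$coefficients[["FP5"]]), 4)
  expect_equal(m$coefficients[["FP2"]] - m$coefficients[["FP3"]], 0.52)
})

test_that("fingerprint assembly maps hits onto the frozen bit order", {
  # no hits, zero contact
  fp0 <- build_fingerprint(list(), 0)
  expect_identical(unname(fp0$fp), rep(0, 6))

  h_glu <- list(structure(list(feature = "hb_E353", partner = "GLU353",
                               measured = c(distance = 2.8),
                               atoms = c(O = 7L)),
                          class = "feature_hit"))
  fp2 <- build_fingerprint(h_glu, 0)
  expect_identical(unname(fp2$fp), c(0, 1, 0, 0, 0, 0))

  hits <- detect_features(make_toy_complex("amine_tail",
                                           c("salt_bridge", "HB_E353",
                                             "internal_hb"),
                                           "moved_back"))
  fp <- build_fingerprint(hits, 1.5)
  expect_identical(unname(fp$fp),
                   c(1, 1, 0, 0, 1, 1.5))
  expect_identical(unname(fp$candidate_bits["pistack_F404"]), 1)
  expect_identical(fp$provenance, hits)
})

test_that("prediction is the exact linear recomposition of Table-style
           coefficients", {
  m <- published_model()
  zero <- stats::setNames(numeric(6), fingerprint_bits())
  expect_identical(predict_log_rba(zero, m)$log_rba, -9.341)

  one2 <- zero; one2["FP2"] <- 1
  expect_equal(predict_log_rba(one2, m)$log_rba, -9.341 + 2.209)

  rich <- zero; rich["FP2"] <- 1; rich["FP6"] <- 2.44
  p <- predict_log_rba(rich, m)
  expect_equal(p$log_rba, -9.341 + 2.209 + 3.861 * 2.44)
  expect_equal(p$log_rba, 2.28884, tolerance = 1e-10)
  # breakdown sums exactly to the prediction
  expect_identical(p$log_rba,
                   unname(p$intercept + sum(p$per_feature_contribution)))

  # additivity: flipping any binary bit adds exactly its coefficient
  for (bit in c("FP1", "FP2", "FP3", "FP4")) {
    v <- zero; v[bit] <- 1
    expect_equal(predict_log_rba(v, m)$log_rba -
                   predict_log_rba(zero, m)$log_rba,
                 unname(m$coefficients[bit]))
  }

  expect_error(predict_log_rba(c(FP1 = 1), m), "lacks bits")
})

test_that("OLS fitting recovers noiseless truth and closed-form group
           means", {
  tab <- make_synthetic_table(n = 31, noise_sd = 0, seed = 11)
  fit <- fit_mlr(tab$X, tab$y)
  truth <- published_model()
  expect_lt(max(abs(fit$coefficients - truth$coefficients)), 1e-10)
  expect_lt(abs(fit$intercept - truth$intercept), 1e-10)
  expect_equal(fit$diagnostics$R2, 1, tolerance = 1e-12)

  # single binary feature: coefficient equals the group-mean difference
  x1 <- matrix(rep(c(0, 1), each = 8), ncol = 1,
               dimnames = list(NULL, "FP1"))
  y1 <- c(1.2, 0.8, 1.1, 0.9, 1.0, 1.3, 0.7, 1.0,
          3.2, 2.8, 3.1, 2.9, 3.0, 3.3, 2.7, 3.0)
  f1 <- fit_mlr(x1, y1)
  expect_equal(unname(f1$coefficients["FP1"]),
               mean(y1[x1 == 1]) - mean(y1[x1 == 0]))

  # rank-deficient design errors, naming the collinear bit
  xr <- cbind(FP1 = c(0, 1, 0, 1, 0, 1, 0, 1),
              FP2 = c(0, 1, 0, 1, 0, 1, 0, 1))
  expect_error(fit_mlr(xr, rnorm(8)), "collinear")
})

test_that("fitted coefficients stay within three standard errors of
           truth on noisy synthetic tables", {
  tab <- make_synthetic_table(n = 31, noise_sd = 0.3, seed = 21)
  fit <- fit_mlr(tab$X, tab$y)
  truth <- c(published_model()$coefficients,
             `(Intercept)` = published_model()$intercept)
  D <- cbind(`(Intercept)` = 1, tab$X)
  sigma2 <- sum(fit$diagnostics$residuals^2) / (nrow(D) - ncol(D))
  se <- sqrt(diag(solve(crossprod(D))) * sigma2)
  est <- c(fit$coefficients, `(Intercept)` = fit$intercept)
  z <- abs(est[names(truth)] - truth) / se[names(truth)]
  expect_true(all(z < 3))
})

test_that("coefficient recovery is unbiased and tightens as noise
           shrinks", {
  errs <- vapply(c(0.1, 0.3, 0.5), function(s) {
    bias <- rep(NA_real_, 250)
    for (r in seq_len(250)) {
      tab <- make_synthetic_table(n = 31, noise_sd = s, seed = 1000 + r)
      # rare draws leave a binary bit constant; those are not fittable
      fit <- tryCatch(fit_mlr(tab$X, tab$y), error = function(e) NULL)
      if (!is.null(fit)) bias[r] <- fit$coefficients[["FP6"]] - 3.861
    }
    c(mae = mean(abs(bias), na.rm = TRUE),
      bias = mean(bias, na.rm = TRUE))
  }, numeric(2))
  expect_true(all(diff(errs["mae", ]) > 0))          # grows with sigma
  expect_lt(abs(errs["bias", 2]), 0.05)              # unbiased at 0.3
})

test_that("leave-one-out Q2 equals the n-refit oracle and never exceeds
           R2", {
  tab <- make_synthetic_table(n = 31, noise_sd = 0.3, seed = 31)
  q2 <- loo_q2(tab$X, tab$y)
  # brute-force oracle: refit n models
  D <- cbind(1, tab$X)
  press <- 0
  for (i in seq_len(nrow(D))) {
    b <- qr.solve(D[-i, ], tab$y[-i])
    press <- press + (tab$y[i] - sum(D[i, ] * b))^2
  }
  q2_oracle <- 1 - press / sum((tab$y - mean(tab$y))^2)
  expect_equal(q2, q2_oracle, tolerance = 1e-12)

  # noiseless data validates perfectly
  tab0 <- make_synthetic_table(n = 31, noise_sd = 0, seed = 32)
  expect_equal(loo_q2(tab0$X, tab0$y), 1, tolerance = 1e-10)

  # pure noise has no predictive ability
  set.seed(33)
  Xn <- matrix(rbinom(200 * 3, 1, 0.5), ncol = 3,
               dimnames = list(NULL, c("FP1", "FP2", "FP3")))
  yn <- rnorm(200)
  expect_lt(loo_q2(Xn, yn), 0.05)

  # Q2 <= R2 across seeds
  for (s in 41:50) {
    t_s <- make_synthetic_table(n = 31, noise_sd = 0.4, seed = s)
    expect_lte(loo_q2(t_s$X, t_s$y),
               fit_mlr(t_s$X, t_s$y)$diagnostics$R2)
  }
})

test_that("GA selection equals exhaustive search on small candidate
           sets and is seed-deterministic", {
  tab <- make_synthetic_table(n = 25, noise_sd = 0.3, seed = 51)
  X3 <- tab$X[, c("FP1", "FP2", "FP6")]
  ex <- exhaustive_select(X3, tab$y)
  ga <- ga_select(X3, tab$y, ga_config(population_size = 20,
                                       generations = 30, seed = 5))
  expect_setequal(ga$mask, ex$mask)
  expect_equal(ga$model$coefficients, ex$model$coefficients)

  ga_again <- ga_select(X3, tab$y, ga_config(population_size = 20,
                                             generations = 30, seed = 5))
  expect_identical(ga$mask, ga_again$mask)

  # zero generations returns the best of the random initial population
  ga0 <- ga_select(X3, tab$y, ga_config(population_size = 30,
                                        generations = 0, seed = 5))
  expect_true(length(ga0$mask) >= 1)

  expect_error(ga_config(population_size = 1), "population")
})

test_that("GA recovers the true support over informative bits and
           excludes pure noise", {
  # y built from FP1, FP2, FP6 only; FP3/FP4/FP5 carry no signal
  truth <- c(FP1 = 0.9, FP2 = 2.2, FP3 = 0, FP4 = 0, FP5 = 0, FP6 = 3.9)
  hitrate <- 0
  n_runs <- 40
  for (r in seq_len(n_runs)) {
    tab <- make_synthetic_table(n = 31, true_coefficients = truth,
                                noise_sd = 0.25, seed = 7000 + r)
    ga <- ga_select(tab$X, tab$y,
                    ga_config(population_size = 24, generations = 25,
                              seed = r))
    ok <- all(c("FP1", "FP2", "FP6") %in% ga$mask)
    hitrate <- hitrate + ok
  }
  expect_gte(hitrate / n_runs, 0.95)
})

test_that("fingerprint tables round-trip through delimited text", {
  tab <- make_synthetic_table(n = 12, noise_sd = 0.2, seed = 61)
  df <- data.frame(tab$X, logRBA = tab$y, check.names = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_fingerprint_table(df, path)
  back <- read_fingerprint_table(path)
  for (b in c("FP1", "FP2", "FP3", "FP4", "FP5")) {
    expect_identical(as.integer(back[[b]]), as.integer(df[[b]]))
  }
  expect_equal(back$FP6, df$FP6, tolerance = 5e-4)
  expect_error(read_fingerprint_table(
    { p <- tempfile(); writeLines("a\tb\n1\t2", p); p }), "columns")
})
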