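# Unweighted two-group data for quick checks.
null_fit_fixture <- function(n_features = 60, n_per_group = 4, seed = 1,
                             sd = 0.5) {
  withr::with_seed(seed, {
    des <- two_group_design(n_per_group)
    x <- matrix(rnorm(n_features * 2 * n_per_group, 10, sd), n_features)
    colnames(x) <- des$sample_id
    list(data = long_from_matrix(x), design = des, x = x)
  })
}

test_that("unweighted fits reduce to group means and pooled variance", {
  fx <- null_fit_fixture(n_features = 20, seed = 2)
  fit <- fit_feature_models(fx$data, fx$design, include_batch = FALSE)
  tac <- fx$design$condition == "TAC"
  expect_equal(fit$log2fc, rowMeans(fx$x[, tac]) - rowMeans(fx$x[, !tac]),
               ignore_attr = TRUE)
  pooled <- apply(fx$x, 1, function(y) {
    (sum((y[tac] - mean(y[tac]))^2) + sum((y[!tac] - mean(y[!tac]))^2)) / 6
  })
  expect_equal(fit$sigma2, pooled, ignore_attr = TRUE)
  expect_equal(fit$stdev_unscaled, rep(sqrt(1 / 4 + 1 / 4), 20))
  expect_equal(fit$df_residual, rep(6, 20))
})

test_that("mixed-weight fits match a brute-force WLS solver", {
  withr::with_seed(4, {
    des <- two_group_design(4)
    X <- stats::model.matrix(~ condition + factor(replicate),
                             data = des[, c("condition", "replicate")])
    for (rep in 1:20) {
      y <- rnorm(8, 10)
      imputed <- sample(c(TRUE, FALSE), 8, replace = TRUE,
                        prob = c(0.3, 0.7))
      w <- ifelse(imputed, 0.05, 1)
      x <- matrix(y, 1, dimnames = list("F1", des$sample_id))
      status <- matrix(ifelse(imputed, "imputed", "observed"), 1,
                       dimnames = dimnames(x))
      long <- long_from_matrix(x, status = status)
      fit <- fit_feature_models(long, des, imputed_weight = 0.05)
      oracle <- oracle_wls(X, y, w)
      expect_equal(fit$log2fc, oracle$beta[["conditionTAC"]],
                   tolerance = 1e-10)
      expect_equal(fit$stdev_unscaled, oracle$su[[2]], tolerance = 1e-10)
      expect_equal(fit$sigma2, oracle$s2, tolerance = 1e-10)
      expect_equal(fit$df_residual, oracle$df)
    }
  })
})

test_that("features without residual degrees of freedom are untestable", {
  fx <- null_fit_fixture(n_features = 12, seed = 5)
  x <- fx$x
  x[1, 3:8] <- NA # observed in 2 samples, 2-coefficient model
  fit <- suppressMessages(
    fit_feature_models(long_from_matrix(x), fx$design, include_batch = FALSE)
  )
  expect_false(fit$testable[1])
  expect_true(all(fit$testable[-1]))
  mod <- moderate(fit)
  expect_true(is.na(mod$p[1]))
})

test_that("rank-deficient designs are rejected with the aliased column", {
  fx <- null_fit_fixture(n_features = 12, seed = 6)
  des <- fx$design
  des$replicate <- ifelse(des$condition == "TAC", 2L, 1L)
  expect_error(fit_feature_models(fx$data, des), "aliased")
})

test_that("prior_df = 0 reproduces the ordinary t-test exactly", {
  fx <- null_fit_fixture(seed = 7)
  fit <- fit_feature_models(fx$data, fx$design, include_batch = FALSE)
  mod <- moderate(fit, prior_df = 0)
  ordinary_t <- fit$log2fc / (fit$stdev_unscaled * sqrt(fit$sigma2))
  expect_equal(mod$t, ordinary_t)
  expect_equal(mod$p, 2 * pt(-abs(ordinary_t), fit$df_residual))
  # and agrees with t.test on a sampled feature
  tac <- fx$design$condition == "TAC"
  tt <- t.test(fx$x[3, tac], fx$x[3, !tac], var.equal = TRUE)
  expect_equal(mod$t[3], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(mod$p[3], tt$p.value, tolerance = 1e-12)
})

test_that("identical residual variances drive the common-variance limit", {
  des <- two_group_design(4)
  resid_pattern <- c(-1, 1, -0.5, 0.5, -1, 1, -0.5, 0.5)
  x <- t(vapply(1:15, function(i) i + resid_pattern, numeric(8)))
  colnames(x) <- des$sample_id
  fit <- fit_feature_models(long_from_matrix(x), des, include_batch = FALSE)
  expect_equal(stats::var(fit$sigma2), 0)
  mod <- moderate(fit)
  expect_true(is.infinite(attr(mod, "prior_df")))
  expect_equal(attr(mod, "prior_var"), fit$sigma2[1])
  expect_equal(unique(mod$sigma2_post), fit$sigma2[1])
  common_t <- fit$log2fc / (fit$stdev_unscaled * sqrt(fit$sigma2[1]))
  expect_equal(mod$t, common_t)
  expect_equal(mod$p, 2 * pnorm(-abs(common_t)))
})

test_that("moderated statistics agree with limma on unweighted data", {
  withr::with_seed(12, {
    des <- two_group_design(4)
    n <- 300
    sigma <- sqrt(0.05 * 4 / rchisq(n, 4))
    x <- matrix(rnorm(n * 8, 0, rep(sigma, 8)), n) +
      outer(rnorm(n, 10), rep(1, 8))
    colnames(x) <- des$sample_id
    fit <- fit_feature_models(long_from_matrix(x), des, include_batch = FALSE)
    mod <- moderate(fit)

    X <- stats::model.matrix(~condition, data = des)
    lfit <- limma::eBayes(limma::lmFit(x, X))
    expect_equal(attr(mod, "prior_df"), lfit$df.prior, tolerance = 1e-8)
    expect_equal(attr(mod, "prior_var"), lfit$s2.prior, tolerance = 1e-8)
    expect_equal(mod$t, unname(lfit$t[, 2]), tolerance = 1e-10)
    expect_equal(mod$p, unname(lfit$p.value[, 2]), tolerance = 1e-10)
  })
})

test_that("null moderated p-values are roughly uniform", {
  sim <- simulate_null_matrix(n_features = 2000, seed = 3)
  fit <- fit_feature_models(sim$data, sim$design, include_batch = FALSE)
  mod <- moderate(fit)
  expect_lt(abs(mean(mod$p < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(mod$p < 0.5) - 0.5), 0.05)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(13, {
    for (i in 1:5) {
      p <- runif(50)^2
      expect_equal(adjust_bh(p), oracle_bh(p))
      perm <- sample.int(50)
      expect_equal(adjust_bh(p[perm]), adjust_bh(p)[perm])
    }
    # monotone along sorted p
    p <- sort(runif(100))
    expect_true(all(diff(adjust_bh(p)) >= 0))
  })
})

test_that("two-tier classification applies the documented thresholds", {
  stats <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    log2fc = c(1.2, 0.7, 3.0, 0.2),
    p = c(0.001, 0.01, 0.1, 0.5),
    fdr = c(0.03, 0.10, 0.30, 0.8)
  )
  res <- classify_features(stats, preset = "phospho")
  expect_equal(res$class, c("hit", "candidate", "none", "none"))
  # boundary: phospho preset is inclusive at |log2FC| = 1
  edge <- tibble::tibble(feature_id = "e", log2fc = 1, p = 0.001, fdr = 0.01)
  expect_equal(classify_features(edge, "phospho")$class, "hit")
  # celltype preset is strict
  expect_equal(classify_features(edge, "celltype")$class, "candidate")

  bad <- list(hit = list(max_fdr = 0.3, min_abs_lfc = 0.5),
              candidate = list(max_fdr = 0.2, min_abs_lfc = 1),
              strict = FALSE)
  expect_error(classify_features(stats, thresholds = bad), "looser")
})

test_that("trigamma inversion solves trigamma(x) = y", {
  for (y in c(1e-5, 0.01, 0.5, 2, 50, 1e6)) {
    x <- phosphoflow:::trigamma_inverse(y)
    expect_equal(trigamma(x), y, tolerance = 1e-6)
  }
})
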