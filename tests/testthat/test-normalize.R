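make_phospho_input_pair <- function(P, I, feature_protein = NULL) {
  if (is.null(rownames(P))) rownames(P) <- sprintf("F%03d", seq_len(nrow(P)))
  if (is.null(colnames(P))) colnames(P) <- sprintf("S%02d", seq_len(ncol(P)))
  prot_of <- if (is.null(feature_protein)) paste0("PR_", rownames(P)) else
    feature_protein
  dimnames(I) <- list(unique(prot_of)[seq_len(nrow(I))], colnames(P))
  phospho <- tibble::tibble(
    feature_id = rep(rownames(P), times = ncol(P)),
    protein_id = rep(prot_of, times = ncol(P)),
    sample_id = rep(colnames(P), each = nrow(P)),
    intensity = as.vector(P)
  ) |> as_intensity_table("raw")
  input <- tibble::tibble(
    protein_id = rep(rownames(I), times = ncol(I)),
    sample_id = rep(colnames(I), each = nrow(I)),
    intensity = as.vector(I)
  )
  list(phospho = phospho, input = input)
}

test_that("input normalization reproduces the worked example", {
  pair <- make_phospho_input_pair(
    P = matrix(c(10, 20, 30, 40), 1),
    I = matrix(c(1, 2, 3, 4), 1)
  )
  out <- normalize_phospho_by_input(pair$phospho, pair$input)
  expect_equal(out$intensity, rep(25, 4)) # ratio 10; medians 25 / 2.5
  expect_equal(intensity_scale(out), "input_normalized")
})

test_that("input of ones leaves the phospho signal unchanged", {
  set.seed(1)
  P <- matrix(2^runif(40, 8, 14), 10)
  pair <- make_phospho_input_pair(P, matrix(1, 10, 4))
  out <- normalize_phospho_by_input(pair$phospho, pair$input)
  w <- matrix_from_long(out)
  expect_equal(w, P, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("features without an input protein are excluded and reported", {
  P <- matrix(c(10, 20, 30, 40, 1, 2, 3, 4), 2, byrow = TRUE)
  rownames(P) <- c("F001", "F002")
  pair <- make_phospho_input_pair(P, matrix(c(1, 2, 3, 4), 1),
                                  feature_protein = c("PA", "PB"))
  pair$input <- pair$input[pair$input$protein_id == "PA", ]
  out <- suppressMessages(normalize_phospho_by_input(pair$phospho, pair$input))
  expect_setequal(unique(out$feature_id), "F001")
  excl <- attr(out, "exclusions")
  expect_equal(excl$feature_id, "F002")
  expect_equal(excl$reason, "no_input_protein")
})

test_that("normalization is phospho-scale equivariant and input-scale invariant", {
  set.seed(42)
  P <- matrix(2^runif(60, 8, 14), 15)
  I <- matrix(2^runif(60, 9, 13), 15)
  pair <- make_phospho_input_pair(P, I)
  base <- matrix_from_long(normalize_phospho_by_input(pair$phospho, pair$input))

  pair_k <- make_phospho_input_pair(3 * P, I)
  scaled <- matrix_from_long(normalize_phospho_by_input(pair_k$phospho, pair_k$input))
  expect_equal(scaled, 3 * base, tolerance = 1e-12)

  pair_i <- make_phospho_input_pair(P, 7 * I)
  inv <- matrix_from_long(normalize_phospho_by_input(pair_i$phospho, pair_i$input))
  expect_equal(inv, base, tolerance = 1e-12)
})

test_that("cells missing in either operand are missing in the output", {
  P <- matrix(c(10, 20, 30, 40), 1)
  I <- matrix(c(1, NA, 3, 4), 1)
  pair <- make_phospho_input_pair(P, I)
  pair$phospho$intensity[1] <- NA
  pair$phospho$status[1] <- "missing"
  out <- normalize_phospho_by_input(pair$phospho, pair$input)
  expect_equal(out$status, c("missing", "missing", "observed", "observed"))
  expect_equal(sum(is.na(out$intensity)), 2)
})

test_that("glog calibration is exact on proportional samples", {
  set.seed(3)
  v <- 2^runif(120, 8, 14)
  x <- cbind(S1 = v, S2 = 3 * v)
  g <- glog_calibrate(long_from_matrix(x, scale = "raw"))
  w <- matrix_from_long(g)
  expect_lt(max(abs(w[, 1] - w[, 2]) / abs(w[, 1])), 1e-6)
  cal <- attr(g, "calibration")
  expect_equal(cal$b[2] / cal$b[1], 3, tolerance = 1e-6,
               ignore_attr = TRUE)

  # identical samples calibrate to a ~ 0, b ~ 1
  x2 <- cbind(S1 = v, S2 = v)
  g2 <- glog_calibrate(long_from_matrix(x2, scale = "raw"))
  cal2 <- attr(g2, "calibration")
  expect_equal(cal2$a, c(0, 0), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(cal2$b, c(1, 1), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("glog approaches log2 at high intensity and preserves ranks", {
  set.seed(4)
  v <- 2^runif(200, 4, 16)
  x <- cbind(S1 = v, S2 = v * 2^rnorm(200, 0, 0.1))
  g <- glog_calibrate(long_from_matrix(x, scale = "raw"))
  w <- matrix_from_long(g)
  c0 <- attr(g, "glog_c")
  cal <- attr(g, "calibration")
  xp <- (x[, 1] - cal$a[1]) / cal$b[1]
  hi <- xp / c0 > 1e3
  expect_gt(sum(hi), 0)
  expect_lt(max(abs(w[hi, 1] - log2(xp[hi]))), 1e-6)
  # strict monotonicity within each sample
  for (s in 1:2) {
    o <- order(x[, s])
    expect_true(all(diff(w[o, s]) > 0))
  }
})

test_that("glog calibration stabilizes variance across intensity strata", {
  set.seed(5)
  n <- 2000
  mu <- runif(n, 4, 16)
  base <- matrix(2^(mu + rnorm(n * 8, 0, 0.2)), n, 8)
  raw <- base + matrix(rnorm(n * 8, 0, 100), n, 8) # additive noise floor
  raw[raw <= 0] <- 0.1
  colnames(raw) <- sprintf("S%02d", 1:8)

  strata_slope <- function(x) {
    m <- rowMeans(x)
    s <- apply(x, 1, stats::sd)
    stratum <- cut(rank(m), 10, labels = FALSE)
    fit <- stats::lm(tapply(s, stratum, mean) ~ seq_len(10))
    abs(unname(stats::coef(fit)[2]))
  }
  slope_before <- strata_slope(log2(pmax(raw, 1)))
  g <- glog_calibrate(long_from_matrix(raw, scale = "raw"))
  slope_after <- strata_slope(matrix_from_long(g))
  expect_gt(slope_before, 0.2)
  expect_lt(slope_after, 0.05)
})

test_that("small samples are rejected by calibration", {
  x <- matrix(2^runif(10, 8, 12), 5, 2,
              dimnames = list(paste0("F", 1:5), c("A", "B")))
  expect_error(glog_calibrate(long_from_matrix(x, scale = "raw")),
               "< 10 observed")
})

test_that("known batch offsets are removed exactly on noiseless data", {
  des <- two_group_design(n_per_group = 4)
  n <- 50
  set.seed(6)
  signal <- outer(runif(n, 8, 14), rep(1, 8)) +
    outer(sample(c(0, 2), n, replace = TRUE), as.numeric(des$condition == "TAC"))
  offsets <- c(-0.5, 0.2, 0.4, -0.1)[des$replicate]
  x <- signal + matrix(offsets, n, 8, byrow = TRUE)
  colnames(x) <- des$sample_id
  out <- remove_batch_effects(long_from_matrix(x, scale = "glog2"), des)
  w <- matrix_from_long(out)
  # batch component gone; condition effect preserved
  expect_lt(max(abs(w - (signal - mean(offsets[1:4])))), 1e-9)
  tac <- des$condition == "TAC"
  expect_equal(rowMeans(w[, tac]) - rowMeans(w[, !tac]),
               rowMeans(signal[, tac]) - rowMeans(signal[, !tac]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(intensity_scale(out), "glog2_batch_corrected")
})

test_that("single-batch data passes through batch correction unchanged", {
  des <- two_group_design(n_per_group = 2)
  des$replicate <- 1L
  x <- matrix(rnorm(40, 10), 10, 4, dimnames = list(NULL, des$sample_id))
  out <- remove_batch_effects(long_from_matrix(x, scale = "glog2"), des)
  expect_equal(matrix_from_long(out), x, ignore_attr = TRUE)
})

test_that("batch confounded with condition raises a rank error", {
  des <- two_group_design(n_per_group = 2)
  des$replicate <- ifelse(des$condition == "TAC", 2L, 1L)
  x <- matrix(rnorm(40, 10), 10, 4, dimnames = list(NULL, des$sample_id))
  expect_error(remove_batch_effects(long_from_matrix(x, scale = "glog2"), des),
               "confounded")
})
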