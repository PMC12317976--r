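# Fixtures and independent oracles used across the suite.

# Long intensity table from a features x samples matrix.
long_from_matrix <- function(x, scale = "glog2", status = NULL) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("F%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("S%02d", seq_len(ncol(x)))
  d <- tibble::tibble(
    feature_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    intensity = as.vector(x),
    status = if (is.null(status)) ifelse(is.na(as.vector(x)), "missing", "observed")
             else as.vector(status)
  )
  as_intensity_table(d, scale = scale)
}

matrix_from_long <- function(data) {
  feats <- unique(data$feature_id)
  samps <- unique(data$sample_id)
  x <- matrix(NA_real_, length(feats), length(samps),
              dimnames = list(feats, samps))
  x[cbind(match(data$feature_id, feats), match(data$sample_id, samps))] <-
    data$intensity
  x
}

# Two-group design, first condition is the control.
two_group_design <- function(n_per_group = 4, conditions = c("Sham", "TAC")) {
  tibble::tibble(
    sample_id = paste0(rep(conditions, each = n_per_group), "_R",
                       rep(seq_len(n_per_group), 2)),
    channel = sprintf("ch%02d", seq_len(2 * n_per_group)),
    condition = rep(conditions, each = n_per_group),
    timepoint = "T1",
    replicate = rep(seq_len(n_per_group), 2)
  )
}

# Hand-built six-PSM table: two PSMs share a phosphopeptide ID, one peptide
# appears with 1 and 2 phosphosites, one PSM fails the localization filter,
# one protein has a single razor peptide.
six_psm_fixture <- function() {
  samples <- c("A", "B")
  psm_wide <- tibble::tibble(
    spectrum_id = sprintf("sp%02d", 1:6),
    protein_id = c("P01", "P01", "P01", "P01", "P02", "P03"),
    peptide = c("AASDEK", "AASDEK", "TAYK", "TAYK", "GGSEK", "LLSTK"),
    modified_peptide = c("AAS*DEK", "AAS*DEK", "T*AYK", "T*AY*K",
                         "GGS*EK", "LLS*TK"),
    n_phospho = c(1L, 1L, 1L, 2L, 1L, 1L),
    loc_prob = c(0.9, 0.8, 0.6, 0.95, 0.5, 0.7),
    intensity_A = c(100, 50, 200, 300, 400, 500),
    intensity_B = c(10, 0, 20, 30, 40, 50)
  )
  protein_wide <- tibble::tibble(
    protein_id = c("P01", "P02", "P03"),
    gene = c("GnA", "GnB", "GnC"),
    razor_peptides = c(3L, 2L, 1L),
    intensity_A = c(1000, 2000, 3000),
    intensity_B = c(1100, 2100, 3100)
  )
  list(psm_wide = psm_wide, protein_wide = protein_wide, samples = samples)
}

write_fixture_tsv <- function(df, name = "fixture.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

psm_long_fixture <- function() {
  fx <- six_psm_fixture()
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(fx$psm_wide, path, progress = FALSE)
  suppressMessages(read_psm_table(path))
}

protein_long_fixture <- function() {
  fx <- six_psm_fixture()
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(fx$protein_wide, path, progress = FALSE)
  suppressMessages(read_protein_table(path))
}

# ---- independent oracles ----------------------------------------------------

# Input-normalization formula evaluated entry by entry with plain loops.
oracle_input_norm <- function(P, I) {
  out <- matrix(NA_real_, nrow(P), ncol(P), dimnames = dimnames(P))
  for (g in seq_len(nrow(P))) {
    med_p <- stats::median(P[g, ], na.rm = TRUE)
    med_i <- stats::median(I[g, ], na.rm = TRUE)
    for (s in seq_len(ncol(P))) {
      if (!is.na(P[g, s]) && !is.na(I[g, s])) {
        out[g, s] <- ((P[g, s] / I[g, s]) / (med_p / med_i)) * med_p
      }
    }
  }
  out
}

# Brute-force weighted least squares via explicit normal equations.
oracle_wls <- function(X, y, w) {
  W <- diag(w)
  xtwx <- t(X) %*% W %*% X
  beta <- solve(xtwx, t(X) %*% W %*% y)
  res <- y - X %*% beta
  df <- length(y) - qr(X)$rank
  s2 <- sum(w * res^2) / df
  list(beta = drop(beta), su = sqrt(diag(solve(xtwx))), s2 = s2, df = df)
}

# BH step-up computed literally from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Hypergeometric upper tail by exhaustive summation of point masses.
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Adjusted Rand index from the contingency table.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
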