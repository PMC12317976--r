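test_that("control-median centering zeroes controls and preserves offsets", {
  des <- two_group_design(3)
  x <- matrix(c(1, 2, 3, 4, 5, 6,
                10, 20, 30, 40, 50, 60), 2, byrow = TRUE,
              dimnames = list(c("F1", "F2"), des$sample_id))
  out <- normalize_to_control_median(long_from_matrix(x), des)
  w <- matrix_from_long(out)
  # hand-computed: control medians are 2 and 20
  expect_equal(w, x - c(2, 20), ignore_attr = TRUE)

  ctrl_only <- des[des$condition == "Sham", ]
  out2 <- normalize_to_control_median(
    long_from_matrix(x[, ctrl_only$sample_id]), ctrl_only)
  expect_equal(apply(matrix_from_long(out2), 1, stats::median), c(F1 = 0, F2 = 0))

  shifted <- x
  shifted["F1", des$condition == "TAC"] <- x["F1", des$condition == "TAC"] + 5
  w3 <- matrix_from_long(normalize_to_control_median(long_from_matrix(shifted), des))
  expect_equal(w3["F1", des$condition == "TAC"],
               w["F1", des$condition == "TAC"] + 5)
  expect_equal(w3["F1", des$condition == "Sham"],
               w["F1", des$condition == "Sham"])
})

test_that("the elbow rule finds three well-separated blobs exactly", {
  withr::with_seed(31, {
    centers <- matrix(rnorm(3 * 8), 3) * 10
    truth <- rep(1:3, each = 20)
    x <- centers[truth, ] + matrix(rnorm(60 * 8, 0, 1), 60)
    rownames(x) <- sprintf("F%02d", 1:60)
    colnames(x) <- sprintf("S%02d", 1:8)
  })
  res <- choose_k_elbow(long_from_matrix(x), k_range = 1:6, seed = 5)
  expect_equal(res$k, 3)
  expect_equal(adjusted_rand(res$labels$cluster, truth), 1)
  expect_true(all(diff(res$wss$wss) <= 1e-8))
  res2 <- choose_k_elbow(long_from_matrix(x), k_range = 1:6, seed = 5)
  expect_identical(res$labels, res2$labels)
})

test_that("a single homogeneous blob falls back to the smallest k", {
  withr::with_seed(32, {
    x <- matrix(rnorm(400 * 20), 400, 20)
    rownames(x) <- sprintf("F%03d", 1:400)
    colnames(x) <- sprintf("S%02d", 1:20)
  })
  res <- choose_k_elbow(long_from_matrix(x), k_range = 1:5, seed = 2)
  expect_equal(res$k, 1)
  expect_error(choose_k_elbow(long_from_matrix(x), k_range = 1:400, seed = 1),
               "exceeds")
})

test_that("enrichment reproduces the worked odds-ratio instance", {
  background <- sprintf("g%04d", 1:1000)
  hits <- background[1:20]
  term_genes <- background[c(1:10, 101:190)] # 10 hits among 100 annotated
  ann <- tibble::tibble(term_id = "T1", term_name = "term one",
                        gene = term_genes)
  out <- enrich_terms(hits, background, ann)
  expect_equal(out$k, 10)
  expect_equal(out$gene_ratio, 0.5)
  expect_equal(out$bg_ratio, 0.1)
  expect_equal(out$odds_ratio, 5.0)
  expect_equal(out$p, oracle_hyper_upper(10, 100, 1000, 20), tolerance = 1e-12)
})

test_that("odds ratio is one when hit and background proportions agree", {
  background <- sprintf("g%03d", 1:100)
  hits <- background[1:20]
  ann <- tibble::tibble(term_id = "T1",
                        gene = background[c(1:4, 21:36)]) # 4/20 vs 20/100
  out <- enrich_terms(hits, background, ann)
  expect_equal(out$odds_ratio, 1.0)
})

test_that("hypergeometric p matches exhaustive summation on small instances", {
  withr::with_seed(33, {
    for (i in 1:30) {
      N <- sample(5:30, 1)
      background <- sprintf("g%02d", seq_len(N))
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      hits <- sample(background, n)
      ann <- tibble::tibble(term_id = "T", gene = sample(background, K))
      k <- length(intersect(hits, ann$gene))
      if (k == 0) next
      out <- enrich_terms(hits, background, ann)
      expect_equal(out$p, oracle_hyper_upper(k, K, N, n), tolerance = 1e-12)
      expect_equal(out$odds_ratio > 1, out$gene_ratio > out$bg_ratio)
    }
  })
  expect_error(enrich_terms(character(0), "g1",
                            tibble::tibble(term_id = "T", gene = "g1")),
               "empty hit set")
})

test_that("spearman clustering is rank-invariant and pairs duplicates", {
  withr::with_seed(34, {
    x <- matrix(rnorm(200, 10), 50, 4)
    x <- cbind(x, dup = x[, 1], mono = exp(x[, 2] / 3), neg = -x[, 3])
    colnames(x) <- c("a", "b", "c", "d", "dup", "mono", "neg")
  })
  sc <- spearman_sample_clustering(long_from_matrix(x))
  rho <- sc$correlation
  expect_equal(rho["a", "dup"], 1)
  expect_equal(rho["b", "mono"], 1)
  expect_equal(rho["c", "neg"], -1)
  expect_equal(abs(match("a", sc$order) - match("dup", sc$order)), 1)
})

test_that("cell-type specificity applies filters and recovers planted truth", {
  cfg <- sim_config(n_proteins = 400, frac_specific = 0.1,
                    celltype_log2fc = 2, noise_sd = 0.3, seed = 41)
  ct <- simulate_celltype_tables(cfg)
  calls <- suppressMessages(celltype_specificity(ct$runs, ct$design))
  truth <- ct$truth

  # qupm = 1 and single-run proteins never reach the calls
  expect_length(intersect(calls$protein_id,
                          truth$protein_id[truth$qupm1 | truth$single_run]), 0)
  log <- attr(calls, "filter_log")
  expect_equal(log$proteins_in, 400)
  expect_equal(log$proteins_out, dplyr::n_distinct(calls$protein_id))

  # recovery among quality-passing truly specific proteins
  eligible <- truth[!is.na(truth$specific_in) & !truth$qupm1 &
                      !truth$single_run, ]
  called <- calls[calls$specific, ]
  found <- dplyr::inner_join(eligible, called, by = "protein_id")
  expect_true(all(found$specific_in == found$celltype))
  expect_gte(nrow(found) / nrow(eligible), 0.9)

  # false specificity among null proteins is rare
  null_ids <- truth$protein_id[is.na(truth$specific_in)]
  fp <- sum(unique(called$protein_id) %in% null_ids)
  expect_lte(fp / max(length(unique(called$protein_id)), 1), 0.1)

  # always-detected set: quantified in all three cell types
  always <- attr(calls, "always_detected")
  expect_true(length(always) > 0)
  expect_true(all(!truth$single_run[match(always, truth$protein_id)]))
})

test_that("phospho overlap intersects specific and differential proteins", {
  calls <- tibble::tibble(
    protein_id = c("A", "B", "C", "D", "E"),
    celltype = c("CM", "CM", "EC", "FB", "CM"),
    log2fc = 2, p = 0.01,
    enriched = TRUE,
    specific = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  diff <- tibble::tibble(
    feature_id = paste0("f", 1:4),
    protein_id = c("B", "C", "D", "Z"),
    log2fc = c(1.5, -2, 1.2, 2),
    class = c("hit", "hit", "hit", "hit")
  )
  ov <- overlap_with_phospho(calls, diff)
  expect_setequal(ov$primary$proteins, "B")
  expect_setequal(ov$non_primary$proteins, c("C", "D"))
  expect_setequal(ov$non_primary$down, "C")
  expect_equal(ov$counts$n, c(1, 2))

  none <- overlap_with_phospho(calls, diff[diff$protein_id == "Z", ])
  expect_equal(none$counts$n, c(0, 0))

  all_same <- overlap_with_phospho(
    calls[calls$protein_id == "B", ],
    diff[diff$protein_id == "B", ]
  )
  expect_equal(all_same$primary$proteins, "B")
})
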