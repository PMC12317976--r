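#' Center features on the control-condition median
#'
#' Subtracts, per feature, the median over control samples (on the glog2
#' scale), so profiles read as deviations from the control state. Used to
#' prepare hit features for clustering.
#'
#' @param data Long intensity tibble on a glog2-type scale.
#' @param design Sample design with `sample_id`, `condition`.
#' @param control Control condition label.
#' @return The centered tibble (scale unchanged).
#' @export
normalize_to_control_median <- function(data, design, control = "Sham") {
  check_columns(design, c("sample_id", "condition"), "design")
  if (!control %in% design$condition) {
    rlang::abort(paste0("control condition '", control, "' not in design"))
  }
  w <- intensity_wide(data)
  ctrl <- w$samples %in% design$sample_id[design$condition == control]
  med <- apply(w$x[, ctrl, drop = FALSE], 1, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  intensity_long(w$x - med, w$status, w$features, scale = w$scale)
}

#' k-means clustering with elbow-based choice of k
#'
#' Runs k-means (Euclidean distance) for each candidate k, keeping the best
#' of `restarts` seeded starts plus a warm start grown from the previous
#' solution, which guarantees the within-cluster sum of squares (WSS) is
#' non-increasing in k. The number of clusters is chosen by the elbow rule:
#' the interior k with the largest second difference of the log-WSS curve
#' (the point where the curve stabilizes, detected scale-free), provided the
#' relative WSS drop at that k exceeds 5%; otherwise the smallest candidate
#' k is kept (a single homogeneous blob yields k = min(k_range)).
#'
#' @param data Long intensity tibble; features with missing cells are
#'   dropped with a message (cluster after imputation).
#' @param k_range Candidate numbers of clusters.
#' @param restarts Random restarts per k.
#' @param seed Integer seed making the whole scan reproducible.
#' @return A `cluster_result`: list with `k`, `labels` (tibble of
#'   `feature_id`, `cluster`), `wss` (tibble of `k`, `wss`), `restarts`,
#'   `seed`.
#' @export
choose_k_elbow <- function(data, k_range = 1:10, restarts = 25, seed = 1L) {
  w <- intensity_wide(data)
  complete <- rowSums(is.na(w$x)) == 0
  if (!all(complete)) {
    rlang::inform(paste0("choose_k_elbow: dropping ", sum(!complete),
                         " feature(s) with missing cells"))
  }
  x <- w$x[complete, , drop = FALSE]
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= nrow(x)) {
    rlang::abort("k_range exceeds the number of complete features")
  }
  if (min(k_range) < 1) rlang::abort("k_range must be >= 1")

  withr::with_seed(as.integer(seed), {
    fits <- vector("list", length(k_range))
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      fit <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 50)
      if (i > 1) {
        # warm start: previous centers plus the worst-fit point
        prev <- fits[[i - 1]]
        extra_needed <- k - nrow(prev$centers)
        if (extra_needed > 0) {
          d2 <- vapply(seq_len(nrow(x)), function(r) {
            min(colSums((t(prev$centers) - x[r, ])^2))
          }, numeric(1))
          extra <- x[order(-d2)[seq_len(extra_needed)], , drop = FALSE]
          centers <- rbind(prev$centers, extra)
          warm <- tryCatch(
            stats::kmeans(x, centers = centers, iter.max = 50),
            error = function(e) NULL
          )
          if (!is.null(warm) && warm$tot.withinss < fit$tot.withinss) fit <- warm
        }
      }
      fits[[i]] <- fit
    }
    wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
    k_chosen <- elbow_k(k_range, wss)
    chosen <- fits[[match(k_chosen, k_range)]]
    structure(
      list(
        k = k_chosen,
        labels = tibble::tibble(feature_id = rownames(x),
                                cluster = unname(chosen$cluster)),
        centers = chosen$centers,
        wss = tibble::tibble(k = k_range, wss = wss),
        restarts = restarts,
        seed = as.integer(seed)
      ),
      class = "cluster_result"
    )
  })
}

# Elbow rule: the WSS curve's kink is found as the maximum second difference
# of log(WSS) — the log makes the rule scale-free, so a later sharp kink is
# not masked by an earlier large absolute drop — guarded by a 5% minimum
# relative drop at the chosen k.
elbow_k <- function(k_range, wss, min_drop = 0.05) {
  if (length(k_range) < 3) return(min(k_range))
  lw <- log(pmax(wss, .Machine$double.eps))
  interior <- 2:(length(k_range) - 1)
  d2 <- lw[interior - 1] - 2 * lw[interior] + lw[interior + 1]
  drop <- (wss[interior - 1] - wss[interior]) / pmax(wss[interior - 1], .Machine$double.eps)
  eligible <- drop > min_drop
  if (!any(eligible)) return(min(k_range))
  k_range[interior[which.max(ifelse(eligible, d2, -Inf))]]
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k-means cluster result: k =", x$k, "over", nrow(x$labels),
      "features; WSS scanned for k =", paste(range(x$wss$k), collapse = ".."),
      "\n")
  invisible(x)
}

#' Term enrichment by odds ratio and hypergeometric test
#'
#' For every annotation term represented in the hit set, compares the
#' proportion of hits annotated to the term (gene ratio, k/n) with the
#' proportion in the background (background ratio, K/N). Their quotient is
#' the enrichment odds ratio; values above one indicate enrichment. The
#' p-value is the hypergeometric upper tail \eqn{P(X \ge k)} and is adjusted
#' across terms by Benjamini-Hochberg. The background defaults to what the
#' analysis actually quantified, not the genome.
#'
#' @param hit_genes Character vector of selected genes (must be a subset of
#'   the background).
#' @param background_genes Character vector of background genes.
#' @param annotation Tibble with `term_id`, `gene` and optionally
#'   `term_name`.
#' @return A tibble with one row per term carrying `k`, `n`, `K`, `N`,
#'   `gene_ratio`, `bg_ratio`, `odds_ratio`, `p`, `fdr`, sorted by p.
#' @export
enrich_terms <- function(hit_genes, background_genes, annotation) {
  hit_genes <- unique(hit_genes)
  background_genes <- unique(background_genes)
  if (length(hit_genes) == 0) rlang::abort("empty hit set")
  if (length(background_genes) == 0) rlang::abort("empty background set")
  extra <- setdiff(hit_genes, background_genes)
  if (length(extra) > 0) {
    rlang::abort(paste0("hit genes not in background: ",
                        paste(utils::head(extra, 5), collapse = ", ")))
  }
  check_columns(annotation, c("term_id", "gene"), "annotation")
  if (!"term_name" %in% names(annotation)) annotation$term_name <- annotation$term_id
  ann <- annotation[annotation$gene %in% background_genes, ]
  skipped <- setdiff(unique(annotation$term_id), unique(ann$term_id))
  if (length(skipped) > 0) {
    rlang::warn(paste0("skipping ", length(skipped),
                       " term(s) with no background genes"))
  }
  N <- length(background_genes)
  n <- length(hit_genes)
  out <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene),
      k = dplyr::n_distinct(.data$gene[.data$gene %in% hit_genes]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k >= 1) |>
    dplyr::mutate(
      n = n, N = N,
      gene_ratio = .data$k / .data$n,
      bg_ratio = .data$K / .data$N,
      odds_ratio = .data$gene_ratio / .data$bg_ratio,
      p = stats::phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                        lower.tail = FALSE),
      fdr = adjust_bh(.data$p)
    ) |>
    dplyr::arrange(.data$p)
  out
}

#' Spearman correlation clustering of samples
#'
#' Computes pairwise Spearman rank correlations between samples over
#' co-observed features and clusters samples hierarchically on 1 - rho with
#' average linkage.
#'
#' @param data Long intensity tibble with at least 2 samples.
#' @return A `sample_clustering` object: list with `correlation` (matrix),
#'   `hclust` and `order` (sample ids in dendrogram leaf order).
#' @export
spearman_sample_clustering <- function(data) {
  w <- intensity_wide(data)
  if (ncol(w$x) < 2) rlang::abort("need >= 2 samples")
  rho <- stats::cor(w$x, method = "spearman", use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  structure(list(correlation = rho, hclust = hc,
                 order = colnames(rho)[hc$order]),
            class = "sample_clustering")
}

#' Cell-type specificity calls across mass-spec runs
#'
#' Quality-filters the per-run protein tables (at least `min_qupm`
#' quantified unique peptides, presence in at least `min_runs` runs), builds
#' one intensity table across all runs, calibrates, removes the run batch
#' effect, imputes, and tests each cell type against the rest with the
#' imputation-weighted moderated test. A protein is *specific* to a cell
#' type when its one-vs-rest log2 fold change exceeds 1 with unadjusted
#' p < 0.05 in exactly one cell type.
#'
#' @param runs List of long protein tibbles (one per run) carrying `qupm`.
#' @param design Sample design with `sample_id`, `condition` (the cell
#'   type) and `replicate` (the run).
#' @param min_qupm Minimum quantified unique peptides per protein.
#' @param min_runs Minimum number of runs a protein must be quantified in.
#' @param imputed_weight Weight for imputed cells in the moderated test.
#' @param k Neighbours for imputation.
#' @param min_lfc,max_p Specificity thresholds (strict `>` resp. `<`).
#' @return A tibble with `protein_id`, `celltype`, `log2fc`, `p`,
#'   `enriched`, `specific`. The proteins quantified in every cell type are
#'   attached as the `"always_detected"` attribute and filter tallies as
#'   `"filter_log"`.
#' @export
celltype_specificity <- function(runs, design, min_qupm = 2, min_runs = 2,
                                 imputed_weight = 0.01, k = 10,
                                 min_lfc = 1, max_p = 0.05) {
  if (length(runs) < 2) rlang::abort("need at least 2 runs per cell type")
  check_columns(design, c("sample_id", "condition", "replicate"), "design")
  all_obs <- dplyr::bind_rows(runs, .id = "run")
  check_columns(all_obs, c("protein_id", "qupm", "sample_id", "intensity"),
                "runs")
  all_obs$run <- design$replicate[match(all_obs$sample_id, design$sample_id)]
  n_in <- dplyr::n_distinct(all_obs$protein_id)

  quant <- all_obs[!is.na(all_obs$intensity) & all_obs$qupm >= min_qupm, ]
  runs_per_protein <- quant |>
    dplyr::distinct(.data$protein_id, .data$run) |>
    dplyr::count(.data$protein_id, name = "n_runs")
  keep_ids <- runs_per_protein$protein_id[runs_per_protein$n_runs >= min_runs]
  dropped_qupm <- setdiff(unique(all_obs$protein_id), unique(quant$protein_id))
  filter_log <- tibble::tibble(
    proteins_in = n_in,
    removed_qupm = length(dropped_qupm),
    removed_few_runs = n_in - length(dropped_qupm) - length(keep_ids),
    proteins_out = length(keep_ids)
  )
  rlang::inform(paste0("celltype_specificity: ", filter_log$proteins_out,
                       " of ", n_in, " proteins pass qupm >= ", min_qupm,
                       " and >= ", min_runs, " runs"))
  quant <- quant[quant$protein_id %in% keep_ids, ]

  # full protein x sample grid; unquantified cells are missing
  grid <- tidyr::expand_grid(feature_id = sort(keep_ids),
                             sample_id = design$sample_id)
  quant$feature_id <- quant$protein_id
  long <- dplyr::left_join(
    grid,
    quant[, c("feature_id", "sample_id", "intensity")],
    by = c("feature_id", "sample_id")
  )
  long$protein_id <- long$feature_id
  long$status <- ifelse(is.na(long$intensity), "missing", "observed")
  long <- set_intensity_scale(long, "raw")

  glog <- glog_calibrate(long)
  corrected <- remove_batch_effects(glog, design)
  imputed <- knn_impute(corrected, k = min(k, length(keep_ids) - 2))

  cts <- unique(design$condition)
  calls <- purrr::map_dfr(cts, function(ct) {
    d <- design
    d$condition <- factor(ifelse(d$condition == ct, ct, "rest"),
                          levels = c("rest", ct))
    fit <- fit_feature_models(imputed, d, imputed_weight = imputed_weight,
                              coefficient = paste0("condition", ct))
    mod <- moderate(fit)
    tibble::tibble(protein_id = mod$feature_id, celltype = ct,
                   log2fc = mod$log2fc, p = mod$p)
  })
  calls <- calls |>
    dplyr::mutate(enriched = !is.na(.data$p) & .data$log2fc > min_lfc &
                    .data$p < max_p) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(specific = .data$enriched & sum(.data$enriched) == 1) |>
    dplyr::ungroup()

  detected_ct <- quant |>
    dplyr::left_join(design[, c("sample_id", "condition")], by = "sample_id") |>
    dplyr::distinct(.data$protein_id, .data$condition) |>
    dplyr::count(.data$protein_id, name = "n_ct")
  always <- detected_ct$protein_id[detected_ct$n_ct == length(cts)]

  attr(calls, "always_detected") <- always
  attr(calls, "filter_log") <- filter_log
  calls
}

#' Overlap cell-type-specific proteins with differential phosphoproteins
#'
#' Intersects the proteins called specific to the primary cell type (and,
#' separately, to the remaining cell types) with the proteins carrying
#' differential phosphopeptides, reporting counts and up/down splits by the
#' sign of the phosphopeptide log2 fold change.
#'
#' @param calls Cell-type call tibble from [celltype_specificity()].
#' @param diff Differential result tibble from [classify_features()]; must
#'   carry `protein_id` or be joinable via `features`.
#' @param features Optional tibble mapping `feature_id` to `protein_id`.
#' @param classes Differential classes counted as differential.
#' @param primary_celltype The cell type reported on its own (the rest are
#'   pooled as "non-primary").
#' @return A list with `primary` and `non_primary` elements (each a list of
#'   `proteins`, `up`, `down`) and a `counts` tibble.
#' @export
overlap_with_phospho <- function(calls, diff, features = NULL,
                                 classes = c("hit"),
                                 primary_celltype = "CM") {
  if (!"protein_id" %in% names(diff)) {
    if (is.null(features)) {
      rlang::abort("diff lacks protein_id; supply a features mapping")
    }
    diff <- dplyr::left_join(
      diff, dplyr::distinct(features, .data$feature_id, .data$protein_id),
      by = "feature_id"
    )
  }
  sig <- diff[diff$class %in% classes & !is.na(diff$protein_id), ]
  diff_up <- unique(sig$protein_id[sig$log2fc > 0])
  diff_down <- unique(sig$protein_id[sig$log2fc < 0])
  diff_all <- unique(sig$protein_id)

  spec <- calls[calls$specific, c("protein_id", "celltype")]
  one_set <- function(ids) {
    list(proteins = intersect(ids, diff_all),
         up = intersect(ids, diff_up),
         down = intersect(ids, diff_down))
  }
  primary <- one_set(unique(spec$protein_id[spec$celltype == primary_celltype]))
  non_primary <- one_set(unique(spec$protein_id[spec$celltype != primary_celltype]))
  counts <- tibble::tibble(
    set = c("primary", "non_primary"),
    celltypes = c(primary_celltype,
                  paste(setdiff(unique(calls$celltype), primary_celltype),
                        collapse = "+")),
    n = c(length(primary$proteins), length(non_primary$proteins)),
    up = c(length(primary$up), length(non_primary$up)),
    down = c(length(primary$down), length(non_primary$down))
  )
  list(primary = primary, non_primary = non_primary, counts = counts)
}
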