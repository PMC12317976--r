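#' Configuration for the synthetic TMT experiment generator
#'
#' Bundles and validates every knob of the simulation. Defaults emulate the
#' design the pipeline targets: a TMT16plex phosphoproteomics experiment with
#' four Sham and four TAC hearts per timepoint, replicate pairs labelled in
#' batches, serine-dominant phosphosites, and a mixture of random and
#' intensity-dependent (left-censored) missingness.
#'
#' @param n_proteins Number of proteins in the input proteome.
#' @param n_phosphopeptides Number of distinct phosphopeptides.
#' @param n_channels TMT plex width; must be at least the number of samples.
#' @param groups Named integer vector of replicate counts per condition; the
#'   first name is the control condition.
#' @param n_batches Number of batches; defaults to the largest replicate
#'   count, with replicate index = batch (one Sham/TAC pair per batch).
#' @param frac_differential Proportion of phosphopeptides with a true
#'   condition effect.
#' @param effect_log2fc Magnitude of the true log2 fold change (sign is
#'   random per feature).
#' @param noise_sd Additive SD of measurement noise on the log2 scale, at the
#'   phosphopeptide level.
#' @param batch_sd SD of per-batch offsets on the log2 scale.
#' @param missing_rate Expected proportion of missing feature-by-sample
#'   cells.
#' @param mnar_weight Share of missingness that is intensity-dependent
#'   (left-censoring); the remainder is missing completely at random.
#' @param residue_probs Probabilities of a phosphosite falling on S, T or Y.
#'   The default is serine-dominant, as in cardiac phosphoproteomes.
#' @param loc_prob_dist Function of `n` returning phosphosite localization
#'   probabilities in `[0, 1]`; the default `rbeta(n, 8, 1)` yields mostly
#'   confident localizations with a small tail below 0.5 to exercise the
#'   filter.
#' @param protein_match_prob Probability that a phosphopeptide's protein is
#'   present in the input protein table; the remainder test unmatched-feature
#'   handling.
#' @param frac_specific Cell-type arm: proportion of proteins enriched in
#'   exactly one cell type.
#' @param celltype_log2fc Cell-type arm: log2 fold change of specific
#'   proteins over the other cell types.
#' @param celltypes Cell-type labels (cardiomyocytes, endothelial cells,
#'   fibroblasts).
#' @param n_runs Cell-type arm: number of mass-spec runs (batches).
#' @param qupm1_frac Cell-type arm: fraction of proteins reported with a
#'   single quantified unique peptide (`qupm = 1`), which the quality filter
#'   must drop.
#' @param single_run_frac Cell-type arm: fraction of proteins detected in
#'   only one run, which the 2-of-3-runs filter must drop.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 500,
                       n_phosphopeptides = 1000,
                       n_channels = 16,
                       groups = c(Sham = 4L, TAC = 4L),
                       n_batches = NULL,
                       frac_differential = 0.1,
                       effect_log2fc = 2,
                       noise_sd = 0.3,
                       batch_sd = 0.3,
                       missing_rate = 0.1,
                       mnar_weight = 0.5,
                       residue_probs = c(S = 0.85, T = 0.13, Y = 0.02),
                       loc_prob_dist = function(n) stats::rbeta(n, 8, 1),
                       protein_match_prob = 0.95,
                       frac_specific = 0.1,
                       celltype_log2fc = 2,
                       celltypes = c("CM", "EC", "FB"),
                       n_runs = 3,
                       qupm1_frac = 0.05,
                       single_run_frac = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins, n_phosphopeptides = n_phosphopeptides,
    n_channels = n_channels, groups = groups,
    n_batches = n_batches %||% max(groups),
    frac_differential = frac_differential, effect_log2fc = effect_log2fc,
    noise_sd = noise_sd, batch_sd = batch_sd, missing_rate = missing_rate,
    mnar_weight = mnar_weight, residue_probs = residue_probs,
    loc_prob_dist = loc_prob_dist, protein_match_prob = protein_match_prob,
    frac_specific = frac_specific, celltype_log2fc = celltype_log2fc,
    celltypes = celltypes, n_runs = n_runs, qupm1_frac = qupm1_frac,
    single_run_frac = single_run_frac, seed = seed
  )
  bad_count <- function(x) !is.numeric(x) || length(x) != 1 || is.na(x) || x < 1
  for (f in c("n_proteins", "n_phosphopeptides", "n_channels", "n_batches", "n_runs")) {
    if (bad_count(cfg[[f]])) stop_config(f, "must be a positive count")
  }
  for (f in c("frac_differential", "missing_rate", "mnar_weight",
              "protein_match_prob", "frac_specific", "qupm1_frac",
              "single_run_frac")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_config(f, "must be a probability in [0, 1]")
    }
  }
  for (f in c("noise_sd", "batch_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) stop_config(f, "must be >= 0")
  }
  if (!is.numeric(cfg$effect_log2fc) || cfg$effect_log2fc < 0) {
    stop_config("effect_log2fc", "must be >= 0")
  }
  if (is.null(names(cfg$groups)) || any(!nzchar(names(cfg$groups)))) {
    stop_config("groups", "must be a named vector of replicate counts")
  }
  if (any(cfg$groups < 2)) stop_config("groups", "needs >= 2 replicates per condition")
  if (cfg$n_channels < sum(cfg$groups)) {
    stop_config("n_channels", "must be at least the total number of samples")
  }
  if (abs(sum(cfg$residue_probs) - 1) > 1e-8 || any(cfg$residue_probs < 0) ||
      !setequal(names(cfg$residue_probs), c("S", "T", "Y"))) {
    stop_config("residue_probs", "must be probabilities named S, T, Y summing to 1")
  }
  if (!is.function(cfg$loc_prob_dist)) {
    stop_config("loc_prob_dist", "must be a function of n")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop_config("seed", "must be a single integer")
  }
  structure(cfg, class = "sim_config")
}

stop_config <- function(field, msg) {
  rlang::abort(paste0("invalid sim_config field '", field, "': ", msg),
               class = "phosphoflow_config_error")
}

#' Simulate a TMT phosphoproteomics experiment with known ground truth
#'
#' Generates a PSM table, an input-proteome protein table, a sample design
#' and the simulation truth. Intensities are built on the log2 scale —
#' protein baseline + peptide offset + condition effect + batch offset +
#' noise — and exponentiated; each phosphopeptide is observed as
#' `1 + Poisson(2)` PSMs so that reporter-ion summation is exercised.
#' Missing cells follow a mixture of MCAR and left-censoring and affect all
#' PSMs of a feature in that channel. A small fraction of phosphopeptides
#' maps to proteins absent from the protein table to exercise
#' unmatched-feature handling.
#'
#' @param config A [sim_config()].
#' @return A list with elements `psm` (long PSM tibble), `proteins` (long
#'   input protein tibble), `design` (sample design tibble) and `truth`
#'   (list of `features`, `mask`, `batches` tibbles).
#' @examples
#' sim <- simulate_experiment(sim_config(n_proteins = 30, n_phosphopeptides = 50, seed = 7))
#' dplyr::count(sim$truth$features, differential)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(config$seed), simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(config) {
  design <- sim_design(config)
  n_s <- nrow(design)
  n_p <- config$n_proteins
  n_f <- config$n_phosphopeptides

  batch_off <- stats::rnorm(config$n_batches, 0, config$batch_sd)
  sample_off <- batch_off[design$replicate]
  treat <- as.numeric(design$condition != names(config$groups)[1])

  proteins <- tibble::tibble(
    protein_id = sprintf("PROT%04d", seq_len(n_p)),
    gene = sprintf("Gene%04d", seq_len(n_p)),
    razor_peptides = 1L + stats::rpois(n_p, 3),
    mu = stats::runif(n_p, 10, 16)
  )

  peps <- sim_peptides(n_f, config$residue_probs)
  prot_idx <- sample.int(n_p, n_f, replace = TRUE)
  matched <- stats::runif(n_f) < config$protein_match_prob
  feat_protein <- ifelse(matched, proteins$protein_id[prot_idx],
                         sprintf("NOVEL%04d", seq_len(n_f)))
  feat_mu <- ifelse(matched, proteins$mu[prot_idx], stats::runif(n_f, 10, 16))
  pep_off <- stats::rnorm(n_f, 0, 1.5)
  differential <- stats::runif(n_f) < config$frac_differential
  sgn <- sample(c(-1, 1), n_f, replace = TRUE)
  true_lfc <- ifelse(differential, sgn * config$effect_log2fc, 0)

  # feature x sample expected log2 intensity, with feature-level noise
  v <- outer(feat_mu + pep_off, rep(1, n_s)) +
    outer(true_lfc, treat) +
    matrix(sample_off, n_f, n_s, byrow = TRUE) +
    matrix(stats::rnorm(n_f * n_s, 0, config$noise_sd), n_f, n_s)

  miss <- sim_missing(v, config$missing_rate, config$mnar_weight)

  feature_id <- build_phosphopeptide_id(feat_protein, peps$modified_peptide)

  n_psm <- 1L + stats::rpois(n_f, 2)
  psm_feat <- rep(seq_len(n_f), n_psm)
  n_psm_tot <- length(psm_feat)
  psm_jitter <- stats::rnorm(n_psm_tot, 0, 0.25)
  loc_prob <- pmin(pmax(config$loc_prob_dist(n_psm_tot), 0), 1)

  intensity <- 2^(v[psm_feat, , drop = FALSE] + psm_jitter)
  intensity[miss[psm_feat, , drop = FALSE]] <- NA_real_

  psm <- tibble::tibble(
    spectrum_id = rep(sprintf("spec%06d", seq_len(n_psm_tot)), times = n_s),
    protein_id = rep(feat_protein[psm_feat], times = n_s),
    peptide = rep(peps$peptide[psm_feat], times = n_s),
    modified_peptide = rep(peps$modified_peptide[psm_feat], times = n_s),
    n_phospho = rep(peps$multiplicity[psm_feat], times = n_s),
    loc_prob = rep(loc_prob, times = n_s),
    sample_id = rep(design$sample_id, each = n_psm_tot),
    intensity = as.vector(intensity)
  )
  psm$status <- ifelse(is.na(psm$intensity), "missing", "observed")

  # input proteome: flat across conditions, light MCAR missingness
  pv <- outer(proteins$mu, rep(1, n_s)) +
    matrix(sample_off, n_p, n_s, byrow = TRUE) +
    matrix(stats::rnorm(n_p * n_s, 0, config$noise_sd), n_p, n_s)
  p_int <- 2^pv
  p_int[matrix(stats::runif(n_p * n_s) < config$missing_rate / 5, n_p, n_s)] <- NA_real_
  prot_long <- tibble::tibble(
    protein_id = rep(proteins$protein_id, times = n_s),
    gene = rep(proteins$gene, times = n_s),
    razor_peptides = rep(proteins$razor_peptides, times = n_s),
    sample_id = rep(design$sample_id, each = n_p),
    intensity = as.vector(p_int)
  )
  prot_long$status <- ifelse(is.na(prot_long$intensity), "missing", "observed")

  truth <- list(
    features = tibble::tibble(
      feature_id = feature_id, protein_id = feat_protein, matched = matched,
      differential = differential, true_log2fc = true_lfc
    ),
    mask = tibble::tibble(
      feature_id = rep(feature_id, times = n_s),
      sample_id = rep(design$sample_id, each = n_f),
      missing = as.vector(miss)
    ),
    batches = tibble::tibble(
      sample_id = design$sample_id, batch = design$replicate,
      offset = sample_off
    )
  )
  list(psm = psm, proteins = prot_long, design = design, truth = truth)
}

sim_design <- function(config) {
  conds <- names(config$groups)
  condition <- rep(conds, times = config$groups)
  replicate <- unlist(lapply(config$groups, seq_len), use.names = FALSE)
  tibble::tibble(
    sample_id = paste0(condition, "_R", replicate),
    channel = sprintf("ch%02d", seq_along(condition)),
    condition = condition,
    timepoint = "T1",
    replicate = as.integer(replicate)
  )
}

# Random tryptic-ish peptides with phosphosites marked "*" after the residue.
sim_peptides <- function(n, residue_probs,
                         multiplicity_probs = c(0.75, 0.2, 0.05)) {
  aa <- strsplit("ACDEFGHIKLMNPQRVW", "")[[1]] # no S/T/Y in the backbone
  one <- function(i) {
    len <- sample(8:18, 1)
    m <- sample(1:3, 1, prob = multiplicity_probs)
    chars <- sample(aa, len, replace = TRUE)
    n_extra <- sample(0:2, 1) # unphosphorylated S/T/Y residues
    pos <- sample(len, m + n_extra)
    chars[pos] <- sample(names(residue_probs), m + n_extra,
                         replace = TRUE, prob = residue_probs)
    starred <- chars
    starred[pos[seq_len(m)]] <- paste0(chars[pos[seq_len(m)]], "*")
    c(paste(chars, collapse = ""), paste(starred, collapse = ""), m)
  }
  out <- vapply(seq_len(n), one, character(3))
  mod <- out[2, ]
  # regenerate rare duplicate sequences so phosphopeptide IDs stay unique
  tries <- 0
  while (anyDuplicated(mod) && tries < 50) {
    dup <- which(duplicated(mod))
    redo <- vapply(dup, one, character(3))
    out[, dup] <- redo
    mod <- out[2, ]
    tries <- tries + 1
  }
  tibble::tibble(peptide = out[1, ], modified_peptide = out[2, ],
                 multiplicity = as.integer(out[3, ]))
}

# MCAR + left-censoring mixture with expected rate `missing_rate`.
sim_missing <- function(v, missing_rate, mnar_weight) {
  if (missing_rate == 0) {
    return(matrix(FALSE, nrow(v), ncol(v)))
  }
  q <- stats::quantile(v, 0.25)
  w <- 1 / (1 + exp(v - q)) # falls with intensity
  p <- missing_rate * ((1 - mnar_weight) + mnar_weight * w / mean(w))
  p <- pmin(p, 0.95)
  matrix(stats::runif(length(v)) < p, nrow(v), ncol(v))
}

#' Simulate cell-type proteome tables across mass-spec runs
#'
#' Emulates the cell-type arm: three cell types measured in three runs, an
#' IsobarQuant-style `qupm` column, a fraction of proteins enriched in
#' exactly one cell type, plus proteins present in only one run and proteins
#' with `qupm = 1` so the quality filters have something to reject.
#'
#' @param config A [sim_config()]; the cell-type fields (`celltypes`,
#'   `n_runs`, `frac_specific`, `celltype_log2fc`, `qupm1_frac`,
#'   `single_run_frac`) plus `n_proteins`, `noise_sd`, `batch_sd` and `seed`
#'   are used.
#' @return A list with `runs` (list of long protein tibbles, one per run),
#'   `design` and `truth` (per-protein specificity flags and filter-test
#'   labels).
#' @export
simulate_celltype_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$celltypes) < 2 || config$n_runs < 2) {
    stop_config("celltypes/n_runs", "cell-type arm needs >= 2 cell types and >= 2 runs")
  }
  withr::with_seed(as.integer(config$seed) + 1L, {
    cts <- config$celltypes
    n_p <- config$n_proteins
    n_r <- config$n_runs
    design <- tibble::tibble(
      sample_id = as.vector(outer(cts, seq_len(n_r), function(ct, r) paste0(ct, "_run", r))),
      channel = sprintf("ch%02d", seq_len(length(cts) * n_r)),
      condition = rep(cts, times = n_r),
      timepoint = "T1",
      replicate = rep(seq_len(n_r), each = length(cts))
    )
    protein_id <- sprintf("CTPROT%04d", seq_len(n_p))
    gene <- sprintf("CtGene%04d", seq_len(n_p))
    mu <- stats::runif(n_p, 10, 16)
    specific <- stats::runif(n_p) < config$frac_specific
    specific_in <- ifelse(specific, sample(cts, n_p, replace = TRUE), NA_character_)
    qupm1 <- stats::runif(n_p) < config$qupm1_frac
    single_run <- !qupm1 & stats::runif(n_p) < config$single_run_frac
    only_run <- ifelse(single_run, sample.int(n_r, n_p, replace = TRUE), NA_integer_)
    run_off <- stats::rnorm(n_r, 0, config$batch_sd)

    runs <- lapply(seq_len(n_r), function(r) {
      d <- design[design$replicate == r, ]
      eff <- outer(specific_in, d$condition, function(s, ct) {
        ifelse(!is.na(s) & s == ct, config$celltype_log2fc, 0)
      })
      y <- 2^(mu + eff + run_off[r] +
                matrix(stats::rnorm(n_p * nrow(d), 0, config$noise_sd), n_p))
      absent <- single_run & only_run != r
      y[absent, ] <- NA_real_
      qupm <- ifelse(qupm1, 1L, 2L + stats::rpois(n_p, 2))
      out <- tibble::tibble(
        protein_id = rep(protein_id, times = nrow(d)),
        gene = rep(gene, times = nrow(d)),
        qupm = rep(qupm, times = nrow(d)),
        sample_id = rep(d$sample_id, each = n_p),
        intensity = as.vector(y)
      )
      out$status <- ifelse(is.na(out$intensity), "missing", "observed")
      out[!is.na(out$intensity) | !rep(absent, times = nrow(d)), ]
    })

    truth <- tibble::tibble(
      protein_id = protein_id, gene = gene, specific_in = specific_in,
      true_log2fc = ifelse(specific, config$celltype_log2fc, 0),
      qupm1 = qupm1, single_run = single_run
    )
    list(runs = runs, design = design, truth = truth)
  })
}

#' Simulate a null feature-by-sample matrix under the moderated-t hierarchy
#'
#' Draws per-feature variances from a scaled inverse chi-square prior and
#' observations from centred normals, so that moderated t statistics are
#' exactly t-distributed under the null. Used to check type-I error
#' calibration of the testing machinery.
#'
#' @param n_features Number of features.
#' @param n_per_group Replicates per condition (two conditions).
#' @param prior_df,prior_var Hyperparameters of the variance prior.
#' @param seed Integer seed.
#' @return A list with a long intensity tibble (`data`, glog2 scale, fully
#'   observed) and a `design` tibble.
#' @export
simulate_null_matrix <- function(n_features = 10000, n_per_group = 4,
                                 prior_df = 4, prior_var = 0.05, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n_s <- 2L * n_per_group
    sigma2 <- prior_var * prior_df / stats::rchisq(n_features, prior_df)
    x <- matrix(stats::rnorm(n_features * n_s, 0, sqrt(sigma2)), n_features, n_s)
    rownames(x) <- sprintf("F%05d", seq_len(n_features))
    condition <- rep(c("Sham", "TAC"), each = n_per_group)
    colnames(x) <- paste0(condition, "_R", rep(seq_len(n_per_group), 2))
    design <- tibble::tibble(
      sample_id = colnames(x), channel = sprintf("ch%02d", seq_len(n_s)),
      condition = condition, timepoint = "T1",
      replicate = rep(seq_len(n_per_group), 2)
    )
    st <- matrix("observed", n_features, n_s, dimnames = dimnames(x))
    list(data = intensity_long(x, st, scale = "glog2"), design = design)
  })
}

#' Simulate a block-correlated matrix with masked cells
#'
#' Features come in blocks sharing a latent sample profile (correlation
#' `rho` within a block), and a fraction of observed cells is masked
#' completely at random. The masked truth is returned so imputation error
#' can be measured.
#'
#' @param n_blocks,block_size Number of feature blocks and features per block.
#' @param n_samples Number of samples.
#' @param rho Within-block correlation of features.
#' @param mask_rate Fraction of cells masked.
#' @param seed Integer seed.
#' @return A list with `data` (long tibble, glog2 scale, masked cells set to
#'   missing) and `masked` (tibble of `feature_id`, `sample_id`, `truth`).
#' @export
simulate_block_matrix <- function(n_blocks = 40, block_size = 10,
                                  n_samples = 12, rho = 0.9,
                                  mask_rate = 0.1, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n_f <- n_blocks * block_size
    latent <- matrix(stats::rnorm(n_blocks * n_samples, 0, 1), n_blocks)
    block <- rep(seq_len(n_blocks), each = block_size)
    shared <- sqrt(rho) * latent[block, , drop = FALSE]
    noise <- sqrt(1 - rho) * matrix(stats::rnorm(n_f * n_samples), n_f)
    x <- 12 + stats::rnorm(n_f, 0, 2) + shared + noise
    rownames(x) <- sprintf("B%02dF%02d", block, rep(seq_len(block_size), n_blocks))
    colnames(x) <- sprintf("S%02d", seq_len(n_samples))
    mask <- matrix(stats::runif(n_f * n_samples) < mask_rate, n_f, n_samples)
    truth <- x[mask]
    st <- matrix("observed", n_f, n_samples, dimnames = dimnames(x))
    st[mask] <- "missing"
    xm <- x
    xm[mask] <- NA_real_
    masked <- tibble::tibble(
      feature_id = rownames(x)[row(x)[mask]],
      sample_id = colnames(x)[col(x)[mask]],
      truth = truth
    )
    list(data = intensity_long(xm, st, scale = "glog2"), masked = masked)
  })
}

#' Write a simulated experiment to disk as fixture files
#'
#' Serializes the generator output as the simple-dialect `psm.tsv`,
#' `protein.tsv`, `design.tsv` and ground-truth TSVs, with missing cells
#' encoded as 0 in the raw tables (the dialect's missing value).
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  widen_zero <- function(long, id_cols) {
    wide <- tidyr::pivot_wider(long, id_cols = dplyr::all_of(id_cols),
                               names_from = "sample_id",
                               names_prefix = "intensity_",
                               values_from = "intensity")
    wide <- dplyr::mutate(wide, dplyr::across(
      dplyr::starts_with("intensity_"), ~ ifelse(is.na(.x), 0, .x)
    ))
    wide
  }
  psm_wide <- widen_zero(sim$psm, c("spectrum_id", "protein_id", "peptide",
                                    "modified_peptide", "n_phospho", "loc_prob"))
  prot_wide <- widen_zero(sim$proteins, c("protein_id", "gene", "razor_peptides"))
  paths <- c(
    psm = file.path(dir, "psm.tsv"),
    protein = file.path(dir, "protein.tsv"),
    design = file.path(dir, "design.tsv"),
    truth_features = file.path(dir, "ground_truth_features.tsv"),
    truth_mask = file.path(dir, "ground_truth_mask.tsv")
  )
  readr::write_tsv(psm_wide, paths["psm"], progress = FALSE)
  readr::write_tsv(prot_wide, paths["protein"], progress = FALSE)
  readr::write_tsv(sim$design, paths["design"], progress = FALSE)
  readr::write_tsv(sim$truth$features, paths["truth_features"], progress = FALSE)
  readr::write_tsv(sim$truth$mask, paths["truth_mask"], progress = FALSE)
  invisible(paths)
}
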