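#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis. Inputs come
#' either from files (`psm`, `protein`, `design` paths) or from the
#' synthetic generator (`sim`, a [sim_config()]), in which case the ground
#' truth is carried through to the result bundle.
#'
#' @param psm,protein,design Paths to the simple-dialect input tables
#'   (ignored when `sim` is given).
#' @param sim Optional [sim_config()] used to generate the inputs.
#' @param preset `"phospho"` (imputed weight 0.05) or `"celltype"` (0.01);
#'   also selects the hit/candidate thresholds of [classify_features()].
#' @param min_loc_prob,min_razor PSM filter thresholds.
#' @param input_normalize Also analyse the input-normalized phospho matrix.
#' @param trim Calibration trimming fraction for [glog_calibrate()].
#' @param batch_first Run batch correction before the variance-stabilizing
#'   transform (on a plain log2 scale) instead of after it. The default
#'   calibrates first: calibration needs raw-scale intensities and batch
#'   removal an additive scale.
#' @param k,max_missing_frac Imputation parameters.
#' @param imputed_weight Weight for imputed cells; defaults per preset.
#' @param thresholds Optional classification threshold override.
#' @param control Control condition; defaults to the design's first.
#' @param cluster_k_range Candidate k for hit clustering.
#' @param restarts k-means restarts.
#' @param seed Integer seed for every stochastic stage.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(psm = NULL, protein = NULL, design = NULL,
                            sim = NULL, preset = c("phospho", "celltype"),
                            min_loc_prob = 0.5, min_razor = 2,
                            input_normalize = TRUE, trim = 0.5,
                            batch_first = FALSE, k = 10,
                            max_missing_frac = 0.5, imputed_weight = NULL,
                            thresholds = NULL, control = NULL,
                            cluster_k_range = 1:8, restarts = 25, seed = 1L) {
  preset <- match.arg(preset)
  cfg <- list(
    psm = psm, protein = protein, design = design, sim = sim, preset = preset,
    min_loc_prob = min_loc_prob, min_razor = min_razor,
    input_normalize = input_normalize, trim = trim, batch_first = batch_first,
    k = k, max_missing_frac = max_missing_frac,
    imputed_weight = imputed_weight %||% switch(preset, phospho = 0.05,
                                                celltype = 0.01),
    thresholds = thresholds, control = control,
    cluster_k_range = cluster_k_range, restarts = restarts,
    seed = as.integer(seed)
  )
  if (is.null(cfg$sim)) {
    for (f in c("psm", "protein", "design")) {
      if (is.null(cfg[[f]])) {
        rlang::abort(paste0("pipeline_config: supply either 'sim' or a '", f,
                            "' path"), class = "phosphoflow_config_error")
      }
      if (!file.exists(cfg[[f]])) {
        rlang::abort(paste0("pipeline_config: file not found: ", cfg[[f]]),
                     class = "phosphoflow_config_error")
      }
    }
  } else if (!inherits(cfg$sim, "sim_config")) {
    rlang::abort("pipeline_config: 'sim' must be a sim_config",
                 class = "phosphoflow_config_error")
  }
  if (cfg$imputed_weight <= 0 || cfg$imputed_weight > 1) {
    rlang::abort("pipeline_config: imputed_weight must be in (0, 1]",
                 class = "phosphoflow_config_error")
  }
  # validate thresholds before any stage runs
  dummy <- tibble::tibble(feature_id = "f", log2fc = 0, p = 1)
  classify_features(dummy, preset = cfg$preset, thresholds = cfg$thresholds)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a `sim`
#' block is passed to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$groups)) y$sim$groups <- unlist(y$sim$groups)
    if (!is.null(y$sim$residue_probs)) {
      y$sim$residue_probs <- unlist(y$sim$residue_probs)
    }
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes aggregation, normalization, calibration, batch correction,
#' imputation, differential testing and classification for each analysis
#' arm — the phospho matrix, the input-normalized phospho matrix and the
#' input proteome — followed by hit clustering and Spearman sample
#' clustering, and writes per-stage outputs plus a provenance manifest. A
#' failing stage aborts with the stage name. With a fixed seed and config,
#' reruns are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return Invisibly, a list with per-arm `results`, the processed
#'   `matrices`, `cluster` and `sample_clustering` objects, the stage
#'   `counts` ledger, the simulation `truth` (if simulated) and output
#'   `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list()
  note <- function(stage, n) counts[[length(counts) + 1]] <<-
    tibble::tibble(stage = stage, n_features = as.integer(n))

  inputs <- run_stage("load_inputs", {
    if (!is.null(config$sim)) {
      sim <- simulate_experiment(config$sim)
      list(psm = sim$psm, proteins = sim$proteins, design = sim$design,
           truth = sim$truth)
    } else {
      list(psm = read_psm_table(config$psm),
           proteins = read_protein_table(config$protein),
           design = read_design(config$design),
           truth = NULL)
    }
  })
  design <- inputs$design
  control <- config$control %||% design$condition[1]
  note("psm_features", dplyr::n_distinct(
    build_phosphopeptide_id(inputs$psm$protein_id, inputs$psm$modified_peptide)
  ))

  phospho_raw <- run_stage("aggregate", {
    filtered <- filter_psms(inputs$psm, inputs$proteins,
                            min_loc_prob = config$min_loc_prob,
                            min_razor = config$min_razor)
    aggregate_psms(filtered)
  })
  note("phospho_aggregated", dplyr::n_distinct(phospho_raw$feature_id))

  input_raw <- run_stage("input_matrix", {
    p <- inputs$proteins
    p$feature_id <- p$protein_id
    set_intensity_scale(
      p[, c("feature_id", "protein_id", "sample_id", "intensity", "status")],
      "raw"
    )
  })

  arms <- list(phospho = phospho_raw, input = input_raw)
  if (config$input_normalize) {
    arms$normalized_phospho <- run_stage("input_normalization", {
      normalize_phospho_by_input(phospho_raw, inputs$proteins)
    })
    note("normalized_phospho", dplyr::n_distinct(arms$normalized_phospho$feature_id))
  }

  process_arm <- function(data, arm) {
    if (config$batch_first) {
      data <- run_stage(paste0(arm, ":batch_correction"), {
        remove_batch_on_log2(data, design)
      })
    }
    g <- run_stage(paste0(arm, ":glog_calibrate"),
                   glog_calibrate(data, trim = config$trim))
    if (!config$batch_first) {
      g <- run_stage(paste0(arm, ":batch_correction"),
                     remove_batch_effects(g, design))
    }
    imp <- run_stage(paste0(arm, ":impute"), {
      knn_impute(g, k = config$k, max_missing_frac = config$max_missing_frac)
    })
    res <- run_stage(paste0(arm, ":test"), {
      fit <- fit_feature_models(imp, design,
                                imputed_weight = config$imputed_weight)
      classify_features(moderate(fit), preset = config$preset,
                        thresholds = config$thresholds)
    })
    note(paste0(arm, "_tested"), sum(!is.na(res$p)))
    list(matrix = imp, result = res)
  }
  processed <- purrr::imap(arms, function(d, arm) process_arm(d, arm))
  results <- purrr::map(processed, "result")
  matrices <- purrr::map(processed, "matrix")

  cluster <- run_stage("cluster_hits", {
    hits <- results$phospho$feature_id[results$phospho$class == "hit"]
    if (length(hits) >= 4) {
      centered <- normalize_to_control_median(matrices$phospho, design,
                                              control = control)
      sub <- centered[centered$feature_id %in% hits, ]
      sub <- set_intensity_scale(sub, intensity_scale(centered))
      kr <- config$cluster_k_range
      kr <- kr[kr < length(hits)]
      choose_k_elbow(sub, k_range = kr, restarts = config$restarts,
                     seed = config$seed)
    } else {
      NULL
    }
  })
  spear <- run_stage("spearman_clustering",
                     spearman_sample_clustering(matrices$phospho))

  counts <- dplyr::bind_rows(counts)
  bundle <- list(results = results, matrices = matrices, cluster = cluster,
                 sample_clustering = spear, counts = counts,
                 truth = inputs$truth, design = design, config = config)

  if (!is.null(out_dir)) {
    bundle$paths <- run_stage("write_outputs", {
      tables <- purrr::imap(results, function(r, arm) r)
      names(tables) <- paste0("results_diff_", names(results))
      tables$stage_counts <- counts
      if (!is.null(cluster)) {
        tables$cluster_labels <- cluster$labels
        tables$cluster_wss <- cluster$wss
      }
      paths <- write_results(tables, out_dir, seed = config$seed,
                             config = unclass(config))
      manifest <- list(
        package = "phosphoflow",
        version = as.character(utils::packageVersion("phosphoflow")),
        seed = config$seed,
        config_hash = rlang::hash(unclass(config)),
        preset = config$preset
      )
      manifest_path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           pretty = TRUE)
      c(paths, manifest = manifest_path)
    })
  }
  invisible(bundle)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("pipeline stage '", stage, "' failed: ",
                        conditionMessage(e)),
                 class = "phosphoflow_stage_error")
  })
}

# Alternative stage order: batch correction on plain log2 intensities,
# before calibration. Returns a raw-scale table so glog_calibrate can follow.
remove_batch_on_log2 <- function(data, design) {
  w <- intensity_wide(data)
  lg <- intensity_long(log2(w$x), w$status, w$features, scale = "glog2")
  corrected <- remove_batch_effects(lg, design)
  cw <- intensity_wide(corrected)
  intensity_long(2^cw$x, cw$status, cw$features, scale = "raw")
}
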