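#' Long-format intensity tables
#'
#' Throughout phosphoflow, a quantified feature-by-sample matrix travels as a
#' long tibble with one row per (feature, sample) cell and the columns
#' `feature_id`, `sample_id`, `intensity` and `status`, plus any feature-level
#' metadata (`protein_id`, `residues`, `multiplicity`, ...). The `status`
#' column is the explicit missingness mask: `"observed"`, `"missing"` or
#' `"imputed"`. Missing cells carry `NA` intensity until imputation; sentinel
#' zeros are converted at ingestion and never reappear.
#'
#' The measurement scale of the table is tracked in the `"scale"` attribute
#' (one of `"raw"`, `"input_normalized"`, `"glog2"`,
#' `"glog2_batch_corrected"`) and is queried with [intensity_scale()].
#'
#' @param data A long intensity tibble.
#' @return `intensity_scale()` returns the scale tag as a string (`"raw"` if
#'   the table carries none).
#' @examples
#' sim <- simulate_experiment(sim_config(n_proteins = 20, n_phosphopeptides = 30, seed = 1))
#' mat <- aggregate_psms(sim$psm)
#' intensity_scale(mat)
#' @export
intensity_scale <- function(data) {
  attr(data, "scale") %||% "raw"
}

scale_order <- c("raw", "input_normalized", "glog2", "glog2_batch_corrected")

#' Construct a long intensity table
#'
#' Validates a long tibble as a phosphoflow intensity table, filling the
#' `status` mask from `NA` intensities when absent, and tags its measurement
#' scale.
#'
#' @param data A long tibble with `feature_id`, `sample_id`, `intensity` and
#'   optionally `status` plus feature metadata columns.
#' @param scale Measurement scale tag; one of `"raw"`,
#'   `"input_normalized"`, `"glog2"`, `"glog2_batch_corrected"`.
#' @return The validated tibble with the `"scale"` attribute set.
#' @export
as_intensity_table <- function(data, scale = "raw") {
  data <- tibble::as_tibble(data)
  if (!"status" %in% names(data)) {
    data$status <- ifelse(is.na(data$intensity), "missing", "observed")
  }
  check_intensity_tbl(data)
  if (anyDuplicated(data[, c("feature_id", "sample_id")])) {
    rlang::abort("duplicate (feature_id, sample_id) cells")
  }
  set_intensity_scale(data, scale)
}

set_intensity_scale <- function(data, scale) {
  scale <- match.arg(scale, scale_order)
  attr(data, "scale") <- scale
  data
}

#' @keywords internal
#' @noRd
check_intensity_tbl <- function(data, call = rlang::caller_env()) {
  needed <- c("feature_id", "sample_id", "intensity", "status")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) {
    rlang::abort(
      paste0("intensity table lacks column(s): ", paste(miss, collapse = ", ")),
      call = call
    )
  }
  bad <- !data$status %in% c("observed", "missing", "imputed")
  if (any(bad)) {
    rlang::abort("status must be one of 'observed', 'missing', 'imputed'", call = call)
  }
  invisible(data)
}

# Long tibble -> list(x = numeric matrix, status = character matrix,
# features = metadata tibble, samples = character). Feature and sample order
# follow first appearance so the round trip is stable.
intensity_wide <- function(data) {
  check_intensity_tbl(data)
  feats <- unique(data$feature_id)
  samps <- unique(data$sample_id)
  x <- matrix(NA_real_, length(feats), length(samps), dimnames = list(feats, samps))
  st <- matrix("missing", length(feats), length(samps), dimnames = list(feats, samps))
  idx <- cbind(match(data$feature_id, feats), match(data$sample_id, samps))
  x[idx] <- data$intensity
  st[idx] <- data$status
  meta_cols <- setdiff(names(data), c("sample_id", "intensity", "status"))
  features <- dplyr::distinct(data[, meta_cols, drop = FALSE], .data$feature_id, .keep_all = TRUE)
  features <- features[match(feats, features$feature_id), , drop = FALSE]
  list(x = x, status = st, features = features, samples = samps,
       scale = intensity_scale(data))
}

intensity_long <- function(x, status, features = NULL, scale = "raw") {
  stopifnot(all(dim(x) == dim(status)))
  out <- tibble::tibble(
    feature_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    intensity = as.vector(x),
    status = as.vector(status)
  )
  if (!is.null(features) && ncol(features) > 1) {
    out <- dplyr::left_join(out, features, by = "feature_id")
    out <- dplyr::relocate(out, "sample_id", "intensity", "status", .after = dplyr::last_col())
  }
  out <- dplyr::arrange(out, match(.data$feature_id, rownames(x)), match(.data$sample_id, colnames(x)))
  set_intensity_scale(out, scale)
}
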