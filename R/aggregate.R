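#' Filter PSMs by localization probability and razor-peptide support
#'
#' Retains peptide spectral matches with a phosphosite localization
#' probability strictly greater than `min_loc_prob` whose protein has at
#' least `min_razor` razor peptides in the protein table. PSMs whose protein
#' is absent from the protein table cannot demonstrate razor support and are
#' removed (conservative). The boundary at the localization threshold is
#' strict; pass `min_loc_prob = 0.5 - 1e-9` if an inclusive cut is wanted.
#'
#' @param psms Long PSM tibble from [read_psm_table()] or
#'   [simulate_experiment()].
#' @param proteins Protein tibble carrying `protein_id` and `razor_peptides`.
#' @param min_loc_prob Localization probability threshold (strict `>`).
#' @param min_razor Minimum razor peptides per protein (inclusive `>=`).
#' @return The filtered PSM tibble. Filter tallies (spectra in/out, removed
#'   per rule) are attached as the `"filter_log"` attribute and reported via
#'   a message.
#' @export
filter_psms <- function(psms, proteins, min_loc_prob = 0.5, min_razor = 2) {
  check_columns(psms, c("spectrum_id", "protein_id", "loc_prob"), "psms")
  check_columns(proteins, c("protein_id", "razor_peptides"), "proteins")
  razor <- dplyr::distinct(proteins, .data$protein_id, .data$razor_peptides)
  razor_of <- razor$razor_peptides[match(psms$protein_id, razor$protein_id)]
  pass_loc <- psms$loc_prob > min_loc_prob
  matched <- !is.na(razor_of)
  pass_razor <- matched & razor_of >= min_razor
  keep <- pass_loc & pass_razor

  n_spec <- function(i) length(unique(psms$spectrum_id[i]))
  log <- tibble::tibble(
    spectra_in = n_spec(TRUE),
    removed_loc_prob = n_spec(!pass_loc),
    removed_unmatched_protein = n_spec(pass_loc & !matched),
    removed_razor = n_spec(pass_loc & matched & !pass_razor),
    spectra_out = n_spec(keep)
  )
  rlang::inform(paste0(
    "filter_psms: ", log$spectra_in, " spectra in; removed ",
    log$removed_loc_prob, " (loc_prob <= ", min_loc_prob, "), ",
    log$removed_unmatched_protein, " (protein not in table), ",
    log$removed_razor, " (razor peptides < ", min_razor, "); ",
    log$spectra_out, " retained"
  ))
  if (log$spectra_out == 0) rlang::warn("filter_psms: no spectra retained")
  out <- psms[keep, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

#' Build the unique phosphopeptide identifier
#'
#' Concatenates the protein accession, the modified peptide sequence (with
#' `*` after each phosphorylated residue) and the number of phosphosites:
#' `P01` + `AAS*DEK` with one site becomes `"P01_AAS*DEK_1"`. The same
#' peptide carrying different numbers of phosphosites therefore yields
#' distinct identifiers.
#'
#' @param protein_id,modified_peptide Character vectors (recycled together).
#' @return Character vector of feature identifiers.
#' @examples
#' build_phosphopeptide_id("P01", "T*AY*K")
#' @export
build_phosphopeptide_id <- function(protein_id, modified_peptide) {
  n <- stringr::str_count(modified_peptide, stringr::fixed("*"))
  if (any(n == 0)) {
    rlang::abort("modified_peptide without any '*' is not a phosphopeptide")
  }
  paste0(protein_id, "_", modified_peptide, "_", n)
}

#' Aggregate PSMs into a phosphopeptide intensity table
#'
#' Sums raw reporter-ion intensities of all PSMs sharing a phosphopeptide
#' identifier, per channel. A cell with no observed contributing PSM stays
#' missing — an absence of evidence is not evidence of zero abundance.
#' Phosphosite residues and multiplicity are annotated from the modified
#' peptide.
#'
#' @param psms Filtered long PSM tibble.
#' @return A long intensity tibble (scale `"raw"`) with feature metadata
#'   columns `protein_id`, `modified_peptide`, `residues`, `multiplicity`.
#' @export
aggregate_psms <- function(psms) {
  check_columns(psms, c("protein_id", "modified_peptide", "sample_id",
                        "intensity"), "psms")
  psms$feature_id <- build_phosphopeptide_id(psms$protein_id, psms$modified_peptide)
  out <- psms |>
    dplyr::group_by(.data$feature_id, .data$protein_id,
                    .data$modified_peptide, .data$sample_id) |>
    dplyr::summarise(
      n_obs = sum(!is.na(.data$intensity)),
      intensity = if (any(!is.na(.data$intensity)))
        sum(.data$intensity, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      status = ifelse(.data$n_obs > 0, "observed", "missing"),
      residues = extract_residues(.data$modified_peptide),
      multiplicity = stringr::str_count(.data$modified_peptide,
                                        stringr::fixed("*"))
    ) |>
    dplyr::select("feature_id", "protein_id", "modified_peptide", "residues",
                  "multiplicity", "sample_id", "intensity", "status")
  set_intensity_scale(out, "raw")
}

# "AAS*DET*K" -> "ST" (residues preceding each '*', in sequence order)
extract_residues <- function(modified_peptide) {
  m <- stringr::str_match_all(modified_peptide, "([A-Z])\\*")
  vapply(m, function(x) paste(x[, 2], collapse = ""), character(1))
}

#' Count phosphosite residues in a feature selection
#'
#' Tallies phosphosites (not peptides) by residue type over a subset of
#' features; a doubly phosphorylated peptide contributes each of its sites.
#'
#' @param data Phosphopeptide tibble carrying `feature_id` and `residues`.
#' @param features Character vector of feature ids to tally; `NULL` means
#'   all features in `data`.
#' @return A tibble with columns `residue` (`S`, `T`, `Y`) and `n`.
#' @export
residue_breakdown <- function(data, features = NULL) {
  check_columns(data, c("feature_id", "residues"), "data")
  meta <- dplyr::distinct(data, .data$feature_id, .data$residues)
  if (!is.null(features)) meta <- meta[meta$feature_id %in% features, ]
  chars <- unlist(strsplit(meta$residues, ""), use.names = FALSE)
  tibble::tibble(
    residue = c("S", "T", "Y"),
    n = vapply(c("S", "T", "Y"), function(r) sum(chars == r), integer(1),
               USE.NAMES = FALSE)
  )
}
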