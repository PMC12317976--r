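#' Read a PSM table
#'
#' Reads a tab-separated table of peptide spectral matches (PSMs) into the
#' long format used throughout the package. Two dialects are understood:
#' `"simple"` (the package's canonical fixture format, with reporter channels
#' in `intensity_<sample>` columns) and `"fragpipe"`, which maps the column
#' aliases of FragPipe's `psm.tsv` onto the simple schema. Reporter
#' intensities of exactly zero encode non-quantified channels and are
#' converted to missing values at ingestion; after this point missingness is
#' carried only in the `status` mask.
#'
#' @param path Path to a TSV file.
#' @param dialect `"simple"` or `"fragpipe"`.
#' @param loc_prob_col For the fragpipe dialect, the column holding the
#'   phosphosite localization probability. FragPipe reports several
#'   probability-like columns and does not fix which one is "the"
#'   localization probability, so the choice is surfaced here.
#' @return A long tibble with columns `spectrum_id`, `protein_id`, `peptide`,
#'   `modified_peptide`, `n_phospho`, `loc_prob`, `sample_id`, `intensity`,
#'   `status`.
#' @export
read_psm_table <- function(path, dialect = c("simple", "fragpipe"),
                           loc_prob_col = "PTM Localization") {
  dialect <- match.arg(dialect)
  raw <- read_tsv_strict(path)
  if (dialect == "fragpipe") {
    alias <- c(
      "Spectrum" = "spectrum_id", "Protein ID" = "protein_id",
      "Peptide" = "peptide", "Modified Peptide" = "modified_peptide",
      "Number of Phospho (STY)" = "n_phospho"
    )
    alias[loc_prob_col] <- "loc_prob"
    raw <- rename_aliases(raw, alias, path)
  }
  required <- c("spectrum_id", "protein_id", "peptide", "modified_peptide",
                "loc_prob")
  check_columns(raw, required, path)
  if (!"n_phospho" %in% names(raw)) {
    raw$n_phospho <- stringr::str_count(raw$modified_peptide, stringr::fixed("*"))
  }
  validate_modified_peptides(raw)
  chan <- intensity_columns(raw, required = TRUE, path = path)
  out <- tidyr::pivot_longer(
    raw[, c(required[1:4], "n_phospho", "loc_prob", chan$cols)],
    cols = dplyr::all_of(chan$cols), names_to = "sample_id",
    values_to = "intensity"
  )
  out$sample_id <- chan$samples[match(out$sample_id, chan$cols)]
  zero_to_missing(out)
}

#' Read a protein table
#'
#' Reads a protein-level quantification table (FragPipe `protein.tsv` style
#' for the input proteome, or IsobarQuant style for the cell-type arm, which
#' carries a `qupm` column and `signal_sum_<channel>` intensities).
#' Contaminant and decoy entries are dropped by accession prefix and the
#' exclusions are reported via a message and the `"excluded"` attribute.
#'
#' @inheritParams read_psm_table
#' @param decoy_prefixes Accession prefixes identifying decoy/contaminant
#'   rows. Tools differ; `rev_` and `cont_` are common defaults.
#' @return A long tibble with columns `protein_id`, `gene`,
#'   `razor_peptides` and/or `qupm`, `sample_id`, `intensity`, `status`.
#' @export
read_protein_table <- function(path, dialect = c("simple", "fragpipe", "isobarquant"),
                               decoy_prefixes = c("rev_", "cont_")) {
  dialect <- match.arg(dialect)
  raw <- read_tsv_strict(path)
  if (dialect == "fragpipe") {
    raw <- rename_aliases(raw, c(
      "Protein ID" = "protein_id", "Gene" = "gene",
      "Razor Peptides" = "razor_peptides"
    ), path)
  }
  check_columns(raw, "protein_id", path)
  if (anyDuplicated(raw$protein_id)) {
    dups <- unique(raw$protein_id[duplicated(raw$protein_id)])
    rlang::abort(paste0("duplicate protein_id in ", path, ": ",
                        paste(utils::head(dups, 5), collapse = ", ")))
  }
  pat <- paste0("^(", paste(decoy_prefixes, collapse = "|"), ")")
  drop <- stringr::str_detect(raw$protein_id, pat)
  if (any(drop)) {
    rlang::inform(paste0("excluding ", sum(drop),
                         " decoy/contaminant protein(s) by prefix"))
  }
  excluded <- raw$protein_id[drop]
  raw <- raw[!drop, , drop = FALSE]
  meta <- intersect(c("protein_id", "gene", "razor_peptides", "qupm"), names(raw))
  chan <- intensity_columns(raw, required = FALSE, path = path)
  if (length(chan$cols) > 0) {
    out <- tidyr::pivot_longer(raw[, c(meta, chan$cols)],
                               cols = dplyr::all_of(chan$cols),
                               names_to = "sample_id", values_to = "intensity")
    out$sample_id <- chan$samples[match(out$sample_id, chan$cols)]
    out <- zero_to_missing(out)
  } else {
    out <- tibble::as_tibble(raw[, meta])
  }
  attr(out, "excluded") <- excluded
  out
}

#' Read a sample-design table
#'
#' The design maps samples to TMT channels, conditions, timepoints and
#' replicates. The replicate index doubles as the batch factor in batch
#' correction and in the design matrix of the differential tests.
#'
#' @inheritParams read_psm_table
#' @return A tibble with at least `sample_id`, `condition`, `replicate`.
#' @export
read_design <- function(path) {
  d <- read_tsv_strict(path)
  check_columns(d, c("sample_id", "condition", "replicate"), path)
  validate_design(d)
  d
}

#' @keywords internal
#' @noRd
validate_design <- function(d) {
  if (anyDuplicated(d$sample_id)) rlang::abort("duplicate sample_id in design")
  n_per <- table(d$condition)
  if (any(n_per < 2)) {
    rlang::abort(paste0("each condition needs >= 2 samples; offending: ",
                        paste(names(n_per)[n_per < 2], collapse = ", ")))
  }
  invisible(d)
}

#' Read a term-to-gene annotation table
#'
#' Two or three tab-separated columns: `term_id`, `gene` and optionally
#' `term_name`. The annotation database itself (e.g. GO) is a user input;
#' the package ships none.
#'
#' @inheritParams read_psm_table
#' @return A tibble with unique `(term_id, gene)` pairs.
#' @export
read_annotation <- function(path) {
  a <- read_tsv_strict(path)
  check_columns(a, c("term_id", "gene"), path)
  if (!"term_name" %in% names(a)) a$term_name <- a$term_id
  if (anyDuplicated(a[, c("term_id", "gene")])) {
    rlang::abort(paste0("duplicate (term_id, gene) pairs in ", path))
  }
  a
}

#' Write result tables as TSV
#'
#' Writes each table in a named list to `<out_dir>/<name>.tsv` with a fixed
#' column order and a run-metadata comment header (package version, seed,
#' config hash). Output is byte-deterministic for identical inputs: the
#' header carries no timestamps.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory, created if absent.
#' @param seed Integer seed recorded in the header.
#' @param config Configuration object hashed into the header.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_, config = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- c(
    paste0("# phosphoflow ", as.character(utils::packageVersion("phosphoflow"))),
    paste0("# seed: ", seed),
    paste0("# config_hash: ", rlang::hash(config))
  )
  paths <- purrr::imap_chr(tables, function(tab, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(p, open = "wb")
    on.exit(close(con))
    writeLines(header, con)
    body <- readr::format_tsv(tab)
    writeChar(body, con, eos = NULL)
    p
  })
  invisible(paths)
}

#' Read back a table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A tibble; the metadata header is exposed as the `"run_meta"`
#'   attribute.
#' @export
read_results <- function(path) {
  lines <- readLines(path, n = 50)
  meta <- lines[startsWith(lines, "#")]
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "run_meta") <- meta
  out
}

# ---- internal helpers -------------------------------------------------------

read_tsv_strict <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}

check_columns <- function(data, required, path) {
  miss <- setdiff(required, names(data))
  if (length(miss) > 0) {
    rlang::abort(paste0(path, ": missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  invisible(data)
}

rename_aliases <- function(data, alias, path) {
  hit <- intersect(names(alias), names(data))
  names(data)[match(hit, names(data))] <- alias[hit]
  data
}

# Intensity columns: `intensity_<sample>` or `signal_sum_<sample>` prefixes.
intensity_columns <- function(data, required, path) {
  cols <- grep("^(intensity|signal_sum)_", names(data), value = TRUE)
  if (required && length(cols) == 0) {
    rlang::abort(paste0(path, ": no reporter intensity columns ",
                        "(intensity_* / signal_sum_*) found"))
  }
  list(cols = cols, samples = sub("^(intensity|signal_sum)_", "", cols))
}

zero_to_missing <- function(out) {
  miss <- is.na(out$intensity) | out$intensity == 0
  out$intensity[miss] <- NA_real_
  out$status <- ifelse(miss, "missing", "observed")
  if (any(out$intensity < 0, na.rm = TRUE)) {
    rlang::abort("negative reporter intensities are not valid")
  }
  tibble::as_tibble(out)
}

validate_modified_peptides <- function(raw) {
  mp <- raw$modified_peptide
  stripped <- gsub("*", "", mp, fixed = TRUE)
  if (!all(stripped == raw$peptide)) {
    bad <- which(stripped != raw$peptide)
    rlang::abort(paste0("modified_peptide does not match peptide at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  # "*" must follow S, T or Y
  star_ok <- !stringr::str_detect(mp, "(^|[^STY])\\*")
  if (!all(star_ok)) {
    rlang::abort(paste0("phosphosite mark '*' after non-S/T/Y residue at row(s): ",
                        paste(utils::head(which(!star_ok), 5), collapse = ", ")))
  }
  n_star <- stringr::str_count(mp, stringr::fixed("*"))
  if (!all(n_star == raw$n_phospho)) {
    bad <- which(n_star != raw$n_phospho)
    rlang::abort(paste0("n_phospho disagrees with '*' count at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(raw)
}
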