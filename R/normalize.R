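#' Normalize phospho signal by input-proteome abundance
#'
#' For a phosphopeptide g measured in sample c, with matching input-proteome
#' protein abundance, the normalized intensity is
#'
#' \deqn{Norm_{g,c} = \frac{P_{g,c} / I_{g,c}}{\mathrm{median}_c(P_g) /
#'   \mathrm{median}_c(I_g)} \cdot \mathrm{median}_c(P_g)}
#'
#' where \eqn{P} is the summed phospho reporter intensity, \eqn{I} the input
#' protein reporter intensity and the medians run over the observed samples
#' of that feature or protein. This keeps the phospho signal on its own
#' intensity scale while dividing out protein-abundance changes. Features
#' whose protein is absent from the input table, or whose median denominator
#' is zero or undefined, are excluded and reported.
#'
#' @param phospho Long phosphopeptide intensity tibble (scale `"raw"`),
#'   carrying `protein_id`.
#' @param input Long input protein tibble sharing the sample set.
#' @return A long intensity tibble on scale `"input_normalized"`; cells
#'   missing in either operand are missing. Excluded features are reported
#'   in the `"exclusions"` attribute as a tibble of `feature_id`, `reason`.
#' @export
normalize_phospho_by_input <- function(phospho, input) {
  check_columns(phospho, c("feature_id", "protein_id", "sample_id",
                           "intensity", "status"), "phospho")
  check_columns(input, c("protein_id", "sample_id", "intensity"), "input")
  pw <- intensity_wide(phospho)
  inp <- input
  inp$feature_id <- inp$protein_id
  if (!"status" %in% names(inp)) {
    inp$status <- ifelse(is.na(inp$intensity), "missing", "observed")
  }
  iw <- intensity_wide(inp[, c("feature_id", "protein_id", "sample_id",
                               "intensity", "status")])
  missing_samples <- setdiff(pw$samples, iw$samples)
  if (length(missing_samples) > 0) {
    rlang::abort(paste0("input table lacks sample(s): ",
                        paste(missing_samples, collapse = ", ")))
  }
  I <- iw$x[, pw$samples, drop = FALSE]

  prot <- pw$features$protein_id
  row_in_input <- match(prot, rownames(I))
  med_p <- apply(pw$x, 1, stats::median, na.rm = TRUE)
  med_i_all <- apply(I, 1, stats::median, na.rm = TRUE)
  med_i <- med_i_all[row_in_input]

  reason <- rep(NA_character_, nrow(pw$x))
  reason[is.na(row_in_input)] <- "no_input_protein"
  reason[is.na(reason) & (!is.finite(med_p) | med_p == 0)] <- "no_phospho_median"
  reason[is.na(reason) & (!is.finite(med_i) | med_i == 0)] <- "no_input_median"
  keep <- is.na(reason)
  exclusions <- tibble::tibble(
    feature_id = rownames(pw$x)[!keep],
    reason = reason[!keep]
  )
  if (nrow(exclusions) > 0) {
    rlang::inform(paste0("normalize_phospho_by_input: excluded ",
                         nrow(exclusions), " feature(s); see attr 'exclusions'"))
  }

  P <- pw$x[keep, , drop = FALSE]
  Im <- I[row_in_input[keep], , drop = FALSE]
  norm <- (P / Im) / (med_p[keep] / med_i[keep]) * med_p[keep]
  st <- pw$status[keep, , drop = FALSE]
  st[is.na(norm) & st == "observed"] <- "missing"
  norm[st != "observed"] <- NA_real_
  rownames(norm) <- rownames(st) <- rownames(pw$x)[keep]

  out <- intensity_long(norm, st, pw$features[keep, , drop = FALSE],
                        scale = "input_normalized")
  attr(out, "exclusions") <- exclusions
  out
}

#' Calibrate samples and apply a generalized-log transform
#'
#' Variance stabilization in two steps, in the spirit of vsn-style
#' transforms. First, each sample is calibrated against a row-median
#' pseudo-reference by an affine fit \eqn{x \approx a_s + b_s \cdot ref}
#' estimated by iterated trimmed least squares (trimming fraction `trim`
#' keeps the best-fitting half of the features by default, making the fit
#' robust to a differential minority). Second, the calibrated intensities
#' \eqn{x' = (x - a_s)/b_s} pass through the generalized log
#' \deqn{glog_2(x) = \log_2\left(\frac{x' + \sqrt{x'^2 + c^2}}{2}\right)}
#' with \eqn{c} a robust additive-noise scale: candidate offsets spanning
#' the intensity range are scored by how evenly the transformed residual
#' spread (stratum-wise MAD) distributes across ten intensity strata, and
#' the flattest one is kept, so purely multiplicative noise yields an
#' effectively plain \eqn{\log_2} while an additive noise floor raises
#' \eqn{c} accordingly. The transform behaves like \eqn{\log_2} at high
#' intensity and is linear near zero, is strictly monotone per sample, and
#' so preserves within-sample rank order.
#'
#' @param data Long intensity tibble on scale `"raw"` or
#'   `"input_normalized"`, at least 2 samples.
#' @param trim Trimming fraction in `[0, 0.9]` for the calibration fit.
#' @return A long tibble on scale `"glog2"`. Per-sample calibration
#'   parameters are attached as the `"calibration"` attribute (tibble of
#'   `sample_id`, `a`, `b`) and the glog offset as `"glog_c"`.
#' @export
glog_calibrate <- function(data, trim = 0.5) {
  if (!intensity_scale(data) %in% c("raw", "input_normalized")) {
    rlang::abort("glog_calibrate expects a raw or input_normalized table")
  }
  stopifnot(trim >= 0, trim <= 0.9)
  w <- intensity_wide(data)
  x <- w$x
  if (ncol(x) < 2) rlang::abort("glog_calibrate needs >= 2 samples")
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 10)) {
    rlang::abort(paste0("sample(s) with < 10 observed values: ",
                        paste(colnames(x)[n_obs < 10], collapse = ", ")))
  }
  ref <- apply(x, 1, stats::median, na.rm = TRUE)

  fit_one <- function(xs) {
    ok <- !is.na(xs) & is.finite(ref)
    xx <- xs[ok]
    rr <- ref[ok]
    ab <- stats::coef(stats::lm.fit(cbind(1, rr), xx))
    for (i in seq_len(10)) {
      res <- abs(xx - ab[1] - ab[2] * rr)
      keep <- res <= stats::quantile(res, 1 - trim)
      if (sum(keep) < max(10, 2)) keep <- rank(res) <= max(10, 2)
      ab_new <- stats::coef(stats::lm.fit(cbind(1, rr[keep]), xx[keep]))
      if (max(abs(ab_new - ab)) < 1e-12 * max(1, abs(ab[2]))) {
        ab <- ab_new
        break
      }
      ab <- ab_new
    }
    if (!is.finite(ab[2]) || ab[2] <= 0) {
      rlang::abort("calibration failed: non-positive scale factor b_s")
    }
    ab
  }
  ab <- apply(x, 2, fit_one)
  xc <- sweep(sweep(x, 2, ab[1, ], "-"), 2, ab[2, ], "/")

  # glog offset c chosen to make the transformed residual spread flat across
  # the intensity range: candidate offsets spanning the calibrated intensity
  # range are scored by the dispersion of per-stratum residual MADs of the
  # transformed data, and the flattest candidate wins. Purely multiplicative
  # noise drives c to the lower end (plain log2); an additive noise floor
  # pushes c up to the intensity where that floor stops dominating.
  c_floor <- 1e-6 * max(stats::median(abs(xc), na.rm = TRUE), 1)
  c0 <- flattest_glog_offset(xc, c_floor)

  g <- log2((xc + sqrt(xc^2 + c0^2)) / 2)
  out <- intensity_long(g, w$status, w$features, scale = "glog2")
  attr(out, "calibration") <- tibble::tibble(
    sample_id = colnames(x), a = ab[1, ], b = ab[2, ]
  )
  attr(out, "glog_c") <- c0
  out
}

# Score candidate glog offsets by how evenly the transformed residuals
# spread across 10 intensity strata; return the flattest.
flattest_glog_offset <- function(xc, c_floor) {
  m <- apply(xc, 1, stats::median, na.rm = TRUE)
  stratum <- cut(rank(m, ties.method = "first"), 10, labels = FALSE)
  pos <- xc[!is.na(xc) & xc > 0]
  if (length(pos) < 20) return(c_floor)
  lo <- max(stats::quantile(pos, 0.001), c_floor)
  hi <- stats::quantile(pos, 0.999)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(c_floor)
  candidates <- c(c_floor, exp(seq(log(lo), log(hi), length.out = 25)))
  score <- vapply(candidates, function(cc) {
    g <- log2((xc + sqrt(xc^2 + cc^2)) / 2)
    gm <- apply(g, 1, stats::median, na.rm = TRUE)
    resid <- g - gm
    mads <- vapply(1:10, function(j) {
      rj <- resid[stratum == j, , drop = FALSE]
      stats::mad(rj[!is.na(rj)], center = 0)
    }, numeric(1))
    if (any(!is.finite(mads)) || all(mads < 1e-12)) return(NA_real_)
    stats::var(log(pmax(mads, 1e-12)))
  }, numeric(1))
  if (all(is.na(score))) return(c_floor)
  candidates[which.min(score)]
}

#' Remove batch effects from a transformed intensity table
#'
#' Per feature, fits condition and batch (the design's replicate factor,
#' sum-to-zero coded) by least squares and subtracts the fitted batch
#' component, leaving condition-associated variation untouched. This is the
#' standard removeBatchEffect contract and is computed by
#' \code{limma::removeBatchEffect} under the hood.
#'
#' @param data Long intensity tibble on scale `"glog2"`.
#' @param design Sample design with `sample_id`, `condition`, `replicate`.
#' @return A long tibble on scale `"glog2_batch_corrected"`.
#' @export
remove_batch_effects <- function(data, design) {
  if (intensity_scale(data) != "glog2") {
    rlang::abort("remove_batch_effects expects a glog2-scale table")
  }
  check_columns(design, c("sample_id", "condition", "replicate"), "design")
  w <- intensity_wide(data)
  d <- design[match(w$samples, design$sample_id), ]
  if (anyNA(d$sample_id)) {
    rlang::abort("design does not cover all samples in the table")
  }
  batch <- factor(d$replicate)
  if (nlevels(batch) < 2) {
    return(set_intensity_scale(
      intensity_long(w$x, w$status, w$features, scale = "glog2_batch_corrected"),
      "glog2_batch_corrected"
    ))
  }
  cond <- stats::model.matrix(~condition, data = d)
  contr <- stats::contr.sum(nlevels(batch))
  bmat <- contr[as.integer(batch), , drop = FALSE]
  full <- cbind(cond, bmat)
  if (qr(full)$rank < ncol(full)) {
    rlang::abort(paste0(
      "batch is confounded with condition: the combined design of condition (",
      paste(unique(d$condition), collapse = ", "), ") and batch (",
      paste(levels(batch), collapse = ", "), ") is rank deficient"
    ))
  }
  # features missing from an entire batch get no correction for that batch
  # (limma sets the inestimable coefficient to zero); silence its warning
  corrected <- withCallingHandlers(
    limma::removeBatchEffect(w$x, batch = batch, design = cond),
    warning = function(w2) {
      if (grepl("Partial NA coefficients", conditionMessage(w2))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  intensity_long(corrected, w$status, w$features,
                 scale = "glog2_batch_corrected")
}
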