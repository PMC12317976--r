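#' k-nearest-neighbour imputation with provenance tracking
#'
#' Fills missing cells of a transformed intensity table from the k most
#' similar features. Similarity is Euclidean distance over co-observed
#' samples, rescaled by \eqn{\sqrt{n_{samples}/n_{co\mbox{-}observed}}} so
#' that distances computed on few shared samples are not spuriously small.
#' Each missing cell becomes the inverse-distance-weighted mean of the
#' neighbours observed in that sample (zero distances floored at 1e-9).
#' Features missing more than `max_missing_frac` of their cells carry too
#' little profile information for neighbour matching and fall back to their
#' observed feature mean. Ties between equidistant neighbours are broken by
#' the lower feature index (input order), making the result deterministic
#' and invariant to feature shuffling up to that documented rule. Observed
#' entries are never altered.
#'
#' @param data Long intensity tibble on a transformed (glog2) scale.
#' @param k Number of neighbours, `>= 1`.
#' @param max_missing_frac Missingness cap above which a feature is imputed
#'   by its own mean instead of by neighbours.
#' @return The tibble with imputed cells filled and their `status` set to
#'   `"imputed"`; cells that cannot be imputed (feature never observed) stay
#'   `"missing"`. The `"imputation"` attribute records, per imputed cell,
#'   the number of neighbours used and the method (`"knn"` or
#'   `"feature_mean"`); the `"k"` attribute records `k`.
#' @export
knn_impute <- function(data, k = 10, max_missing_frac = 0.5) {
  stopifnot(k >= 1)
  if (!intensity_scale(data) %in% c("glog2", "glog2_batch_corrected")) {
    rlang::abort("knn_impute expects a glog2-scale table")
  }
  w <- intensity_wide(data)
  x <- w$x
  st <- w$status
  n_s <- ncol(x)
  empty_prov <- tibble::tibble(feature_id = character(),
                               sample_id = character(),
                               n_neighbours = integer(), method = character())
  miss_frac <- rowMeans(is.na(x))
  candidate <- miss_frac <= max_missing_frac
  targets <- which(miss_frac > 0)
  if (length(targets) == 0) {
    out <- intensity_long(x, st, w$features, scale = w$scale)
    attr(out, "imputation") <- empty_prov
    attr(out, "k") <- k
    return(out)
  }
  if (k > sum(candidate) - 1) {
    rlang::abort(paste0("k = ", k, " exceeds the number of usable neighbour ",
                        "features (", sum(candidate), " with missingness <= ",
                        max_missing_frac, ")"))
  }
  donors <- which(candidate)
  D <- x[donors, , drop = FALSE]
  prov <- list()

  for (f in targets) {
    miss_s <- which(is.na(x[f, ]))
    fmean <- mean(x[f, ], na.rm = TRUE)
    if (miss_frac[f] > max_missing_frac) {
      if (is.finite(fmean)) {
        x[f, miss_s] <- fmean
        st[f, miss_s] <- "imputed"
        prov[[length(prov) + 1]] <- tibble::tibble(
          feature_id = rownames(x)[f], sample_id = colnames(x)[miss_s],
          n_neighbours = 0L, method = "feature_mean"
        )
      }
      next
    }
    delta <- sweep(D, 2, x[f, ], "-")
    n_co <- rowSums(!is.na(delta))
    d <- sqrt(rowSums(delta^2, na.rm = TRUE) * n_s / pmax(n_co, 1))
    d[n_co == 0] <- Inf
    self <- match(f, donors)
    if (!is.na(self)) d[self] <- Inf
    ord <- order(d, seq_along(d))
    nb <- ord[seq_len(min(k, sum(is.finite(d))))]
    for (s in miss_s) {
      avail <- nb[!is.na(D[nb, s])]
      if (length(avail) == 0) {
        if (is.finite(fmean)) {
          x[f, s] <- fmean
          st[f, s] <- "imputed"
          prov[[length(prov) + 1]] <- tibble::tibble(
            feature_id = rownames(x)[f], sample_id = colnames(x)[s],
            n_neighbours = 0L, method = "feature_mean"
          )
        }
        next
      }
      wts <- 1 / pmax(d[avail], 1e-9)
      x[f, s] <- sum(wts * D[avail, s]) / sum(wts)
      st[f, s] <- "imputed"
      prov[[length(prov) + 1]] <- tibble::tibble(
        feature_id = rownames(x)[f], sample_id = colnames(x)[s],
        n_neighbours = length(avail), method = "knn"
      )
    }
  }
  out <- intensity_long(x, st, w$features, scale = w$scale)
  attr(out, "imputation") <- if (length(prov) > 0) dplyr::bind_rows(prov)
                             else empty_prov
  attr(out, "k") <- k
  out
}
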