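#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-feature model fits
#'
#' @param x A `feature_fits` object.
#' @param ... Unused.
#' @return A tibble with one row per feature.
#' @method tidy feature_fits
#' @export
tidy.feature_fits <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy moderated test results
#'
#' @param x A `moderated_tests` object.
#' @param ... Unused.
#' @return A tibble with one row per feature: estimate, statistic, p-value.
#' @method tidy moderated_tests
#' @export
tidy.moderated_tests <- function(x, ...) {
  tibble::tibble(
    feature_id = x$feature_id,
    estimate = x$log2fc,
    statistic = x$t,
    p.value = x$p,
    df = x$df_total
  )
}

#' One-row summary of a moderated fit
#'
#' @param x A `moderated_tests` object.
#' @param ... Unused.
#' @return A tibble with the estimated variance prior and feature counts.
#' @method glance moderated_tests
#' @export
glance.moderated_tests <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_testable = sum(!is.na(x$p)),
    prior_df = attr(x, "prior_df"),
    prior_var = attr(x, "prior_var")
  )
}

#' Tidy cluster assignments
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble of `feature_id`, `cluster`.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  x$labels
}

#' One-row summary of a cluster scan
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble with the chosen k and the WSS at that k.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    wss = x$wss$wss[match(x$k, x$wss$k)],
    n_features = nrow(x$labels),
    restarts = x$restarts,
    seed = x$seed
  )
}
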