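#' Fit per-feature weighted linear models
#'
#' Fits, for every feature, a least-squares model of transformed intensity
#' on condition plus the replicate (batch) factor, with per-entry weights:
#' observed cells weigh 1, imputed cells weigh `imputed_weight` (0.05 in the
#' phospho arm, 0.01 in the cell-type arm), and still-missing cells are
#' excluded. Features with no residual degrees of freedom, or whose
#' condition coefficient is not estimable from the cells present, are
#' flagged untestable.
#'
#' @param data Long intensity tibble on a glog2-type scale, with `status`
#'   distinguishing observed/imputed/missing cells.
#' @param design Sample design with `sample_id`, `condition`, `replicate`.
#'   The first-appearing condition is the reference (control).
#' @param imputed_weight Weight in `(0, 1]` given to imputed cells.
#' @param coefficient Name of the model coefficient to report as the log2
#'   fold change; defaults to the second condition level vs the first.
#' @param include_batch Add the replicate factor to the design matrix
#'   (skipped automatically when only one replicate level exists).
#' @return A `feature_fits` object: a tibble with `feature_id`, `log2fc`,
#'   `stdev_unscaled`, `sigma2`, `df_residual`, `n_used`, `testable`,
#'   carrying the contrast and weighting as attributes.
#' @export
fit_feature_models <- function(data, design, imputed_weight = 0.05,
                               coefficient = NULL, include_batch = TRUE) {
  if (!intensity_scale(data) %in% c("glog2", "glog2_batch_corrected")) {
    rlang::abort("fit_feature_models expects a glog2-scale table")
  }
  if (!is.numeric(imputed_weight) || imputed_weight <= 0 || imputed_weight > 1) {
    rlang::abort("imputed_weight must be in (0, 1]")
  }
  check_columns(design, c("sample_id", "condition", "replicate"), "design")
  w <- intensity_wide(data)
  d <- design[match(w$samples, design$sample_id), ]
  if (anyNA(d$sample_id)) rlang::abort("design does not cover all samples")

  cond <- if (is.factor(d$condition)) droplevels(d$condition) else
    factor(d$condition, levels = unique(d$condition))
  df_model <- data.frame(condition = cond)
  form <- ~condition
  if (include_batch && length(unique(d$replicate)) > 1) {
    df_model$replicate <- factor(d$replicate)
    form <- ~ condition + replicate
  }
  X <- stats::model.matrix(form, data = df_model)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    rlang::abort(paste0("design matrix is rank deficient; aliased column(s): ",
                        paste(aliased, collapse = ", ")))
  }
  coefficient <- coefficient %||% paste0("condition", levels(cond)[2])
  if (!coefficient %in% colnames(X)) {
    rlang::abort(paste0("coefficient '", coefficient, "' not in the design (",
                        paste(colnames(X), collapse = ", "), ")"))
  }
  j <- match(coefficient, colnames(X))

  wts_mat <- matrix(0, nrow(w$x), ncol(w$x))
  wts_mat[w$status == "observed"] <- 1
  wts_mat[w$status == "imputed"] <- imputed_weight

  fit_one <- function(y, wt) {
    use <- wt > 0 & !is.na(y)
    n_used <- sum(use)
    out <- list(coef = NA_real_, su = NA_real_, s2 = NA_real_,
                df = 0, n = n_used, ok = FALSE)
    if (n_used < 2) return(out)
    Xi <- X[use, , drop = FALSE]
    rank_i <- qr(Xi)$rank
    df <- n_used - rank_i
    fit <- stats::lm.wfit(Xi, y[use], wt[use])
    if (is.na(fit$coefficients[j]) || df <= 0) {
      out$df <- df
      return(out)
    }
    res <- y[use] - Xi %*% fit$coefficients
    s2 <- sum(wt[use] * res^2) / df
    xtwx <- crossprod(Xi * sqrt(wt[use]))
    cov_u <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (is.null(cov_u)) {
      out$df <- df
      return(out)
    }
    list(coef = unname(fit$coefficients[j]), su = sqrt(cov_u[j, j]),
         s2 = s2, df = df, n = n_used, ok = TRUE)
  }

  fits <- lapply(seq_len(nrow(w$x)), function(i) fit_one(w$x[i, ], wts_mat[i, ]))
  out <- tibble::tibble(
    feature_id = rownames(w$x),
    log2fc = vapply(fits, `[[`, numeric(1), "coef"),
    stdev_unscaled = vapply(fits, `[[`, numeric(1), "su"),
    sigma2 = vapply(fits, `[[`, numeric(1), "s2"),
    df_residual = vapply(fits, `[[`, numeric(1), "df"),
    n_used = vapply(fits, function(f) as.numeric(f$n), numeric(1)),
    testable = vapply(fits, `[[`, logical(1), "ok")
  )
  n_unt <- sum(!out$testable)
  if (n_unt > 0) {
    rlang::inform(paste0("fit_feature_models: ", n_unt,
                         " feature(s) untestable (insufficient residual df)"))
  }
  structure(out, class = c("feature_fits", class(out)),
            coefficient = coefficient, imputed_weight = imputed_weight,
            features = w$features)
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-feature residual variances toward a pooled prior estimated
#' across features, then forms moderated t statistics. The prior
#' \eqn{(d_0, s_0^2)} is estimated by matching the first two moments of
#' \eqn{\log s_g^2} to a scaled-F distribution; the trigamma equation is
#' inverted by Newton iteration. The posterior variance is
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, the moderated
#' statistic \eqn{t_g = \hat\beta_g /(u_g \tilde{s}_g)} with \eqn{u_g} the
#' unscaled coefficient SD, and two-sided p-values use \eqn{d_0 + d_g}
#' degrees of freedom. When the variance spread is no larger than expected
#' from chi-square sampling alone, \eqn{d_0 \to \infty} and every feature
#' receives the common variance. Features with \eqn{s_g^2 = 0} are excluded
#' from the moment match and assigned \eqn{s_0^2}.
#'
#' @param fits A `feature_fits` object from [fit_feature_models()].
#' @param prior_df Override for \eqn{d_0}: `0` reproduces the ordinary
#'   per-feature t-test, `Inf` forces the common-variance limit, `NULL`
#'   (default) estimates it from the data.
#' @param prior_var Override for \eqn{s_0^2}; estimated when `NULL`.
#' @return A `moderated_tests` object: a tibble with `feature_id`, `log2fc`,
#'   `t`, `p`, `df_total`, `sigma2_post`, plus `prior_df` and `prior_var`
#'   attributes.
#' @export
moderate <- function(fits, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(fits, "feature_fits"))
  ok <- fits$testable & fits$df_residual > 0
  pos <- ok & fits$sigma2 > 0
  if (sum(ok) < 10) {
    rlang::abort("moderation needs >= 10 testable features")
  }
  s2 <- fits$sigma2[pos]
  df <- fits$df_residual[pos]

  if (is.null(prior_df)) {
    mm <- fit_f_dist(s2, df)
    d0 <- mm$df_prior
    s02 <- prior_var %||% mm$var_prior
  } else {
    d0 <- prior_df
    s02 <- prior_var %||% (if (is.infinite(prior_df) || prior_df > 0)
      mean(s2) else NA_real_)
  }

  s2_all <- fits$sigma2
  s2_all[ok & fits$sigma2 == 0] <- s02 # degenerate features take the prior
  d_all <- fits$df_residual
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2_all))
    df_total <- rep(Inf, length(s2_all))
  } else if (d0 == 0) {
    s2_post <- s2_all
    df_total <- d_all
  } else {
    s2_post <- (d0 * s02 + d_all * s2_all) / (d0 + d_all)
    df_total <- pmin(d_all + d0, sum(d_all[ok]))
  }
  s2_post[!ok] <- NA_real_

  tstat <- fits$log2fc / (fits$stdev_unscaled * sqrt(s2_post))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- tibble::tibble(
    feature_id = fits$feature_id,
    log2fc = fits$log2fc,
    t = tstat,
    p = p,
    df_total = df_total,
    sigma2_post = s2_post,
    df_residual = fits$df_residual,
    n_used = fits$n_used
  )
  structure(out, class = c("moderated_tests", class(out)),
            prior_df = d0, prior_var = s02,
            coefficient = attr(fits, "coefficient"),
            features = attr(fits, "features"))
}

# Moment matching of log s^2 to a scaled F distribution.
fit_f_dist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(df_prior = d0, var_prior = s02)
}

# Newton inversion of the trigamma function.
trigamma_inverse <- function(y) {
  stopifnot(is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(100)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) return(x)
  }
  rlang::abort(paste0("trigamma inversion did not converge after 100 ",
                      "iterations (target ", signif(y, 6), ", last x ",
                      signif(x, 6), ")"))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment: with p-values sorted ascending, the i-th adjusted
#' value is \eqn{\min_{j \ge i} p_{(j)} n / j}, clipped at 1 and returned in
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted values (FDR).
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-tier hit/candidate classification
#'
#' Applies the two-tier significance scheme: a *hit* requires FDR < 5% and
#' at least a two-fold change (|log2FC| >= 1); a *candidate* requires
#' FDR < 20% and at least a 1.5-fold change. The cell-type preset uses the
#' same FDR cuts with strict fold-change inequalities (|log2FC| > 1, resp.
#' > log2 1.5). Each feature is assigned the highest tier it satisfies.
#'
#' @param stats A `moderated_tests` object or any data frame with `p` and
#'   `log2fc` columns.
#' @param preset `"phospho"` or `"celltype"`.
#' @param thresholds Optional override: a list with elements `hit` and
#'   `candidate`, each `list(max_fdr =, min_abs_lfc =)`, and logical
#'   `strict` for strict fold-change inequalities. The hit tier must not be
#'   looser than the candidate tier.
#' @param contrast Label stored in the result's `contrast` column.
#' @return A tibble with `feature_id`, `contrast`, `log2fc`, `t`, `p`,
#'   `fdr`, `class` (`"hit"`, `"candidate"` or `"none"`).
#' @export
classify_features <- function(stats, preset = c("phospho", "celltype"),
                              thresholds = NULL, contrast = NA_character_) {
  preset <- match.arg(preset)
  th <- thresholds %||% switch(preset,
    phospho = list(hit = list(max_fdr = 0.05, min_abs_lfc = 1),
                   candidate = list(max_fdr = 0.2, min_abs_lfc = log2(1.5)),
                   strict = FALSE),
    celltype = list(hit = list(max_fdr = 0.05, min_abs_lfc = 1),
                    candidate = list(max_fdr = 0.2, min_abs_lfc = log2(1.5)),
                    strict = TRUE)
  )
  if (th$hit$max_fdr > th$candidate$max_fdr ||
      th$hit$min_abs_lfc < th$candidate$min_abs_lfc) {
    rlang::abort("inconsistent thresholds: hit tier is looser than candidate tier",
                 class = "phosphoflow_config_error")
  }
  check_columns(stats, c("feature_id", "log2fc", "p"), "stats")
  fdr <- if ("fdr" %in% names(stats)) stats$fdr else adjust_bh(stats$p)
  fc_pass <- function(min_lfc) {
    if (isTRUE(th$strict)) abs(stats$log2fc) > min_lfc else abs(stats$log2fc) >= min_lfc
  }
  is_hit <- !is.na(stats$p) & fdr < th$hit$max_fdr & fc_pass(th$hit$min_abs_lfc)
  is_cand <- !is.na(stats$p) & fdr < th$candidate$max_fdr &
    fc_pass(th$candidate$min_abs_lfc)
  if (is.na(contrast)) {
    contrast <- attr(stats, "coefficient") %||% NA_character_
  }
  tibble::tibble(
    feature_id = stats$feature_id,
    contrast = contrast,
    log2fc = stats$log2fc,
    t = if ("t" %in% names(stats)) stats$t else NA_real_,
    p = stats$p,
    fdr = fdr,
    class = dplyr::case_when(is_hit ~ "hit", is_cand ~ "candidate",
                             .default = "none")
  )
}
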