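#' Welch's two-sample t-test
#'
#' Location test for two groups without assuming equal variances, with
#' Welch--Satterthwaite degrees of freedom and a two-sided p-value. The sign
#' of the statistic follows `mean(x) - mean(y)`. Degenerate inputs where
#' both groups have zero variance are handled by convention: equal means
#' give `t = 0, p = 1`; unequal means give an infinite statistic and
#' `p = 0`.
#'
#' @param x,y numeric samples (each of size at least 2).
#' @return object of class `welch_result`: list with `t_statistic`, `df`,
#'   `p_value`, `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @examples
#' welch_t(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
welch_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      res <- list(t_statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1)
    } else {
      res <- list(t_statistic = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p_value = 0)
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    res <- list(t_statistic = unname(ht$statistic),
                df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  structure(c(res, list(mean_x = mean(x), mean_y = mean(y),
                        n_x = length(x), n_y = length(y))),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4g, df = %.4g, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  cat(sprintf("  group means: %.4g (n = %d) vs %.4g (n = %d)\n",
              x$mean_x, x$n_x, x$mean_y, x$n_y))
  invisible(x)
}

#' Regression metrics for predicted versus chronological age
#'
#' Ordinary least squares of predicted age on chronological age with an
#' intercept: returns the coefficient of determination, the regression slope
#' and intercept, and the p-value of the regression F-test. The mean
#' absolute error is computed on the raw (predicted, chronological) pairs --
#' not on fitted values -- so a constant offset inflates MAE while leaving
#' R-squared untouched; this is exactly why delta-age is reported separately
#' from the regression fit.
#'
#' @param predicted predicted ages in years.
#' @param chronological chronological ages in years (must vary; at least 3
#'   pairs).
#' @return object of class `regression_metrics`: `r_squared`, `mae`,
#'   `slope`, `intercept`, `regression_p`, `n`.
#' @export
regression_metrics <- function(predicted, chronological) {
  stopifnot(is.numeric(predicted), is.numeric(chronological),
            length(predicted) == length(chronological))
  ok <- !is.na(predicted) & !is.na(chronological)
  predicted <- predicted[ok]
  chronological <- chronological[ok]
  if (length(predicted) < 3L) {
    stop("need at least 3 pairs", call. = FALSE)
  }
  if (stats::var(chronological) == 0) {
    stop("chronological age has zero variance", call. = FALSE)
  }
  fit <- stats::lm(predicted ~ chronological)
  # a perfect prediction is a legitimate input (R^2 = 1); suppress the
  # perfect-fit note from summary.lm
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    r_squared = sm$r.squared,
    mae = mean(abs(predicted - chronological)),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    regression_p = p,
    n = length(predicted)
  ), class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("R^2 = %.3f, MAE = %.2f years, slope = %.3f, p = %.3g (n = %d)\n",
              x$r_squared, x$mae, x$slope, x$regression_p, x$n))
  invisible(x)
}

#' Principal component analysis of a beta matrix
#'
#' Singular-value decomposition of the centered sample x CpG matrix
#' (samples as observations). Betas are centered but not scaled: all
#' features share the percent unit, so scaling would only inflate
#' low-variance CpGs.
#'
#' @param betas numeric matrix, CpGs x samples.
#' @param n_components number of components to return (at most
#'   `min(n_samples, n_cpgs)`).
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (CpGs x components, orthonormal), `variance_explained`
#'   (fraction per returned component), `variance_explained_all` (over all
#'   components, sums to 1).
#' @export
pca_betas <- function(betas, n_components = 2L) {
  check_beta_matrix(betas)
  if (ncol(betas) < 2L || nrow(betas) < 1L) {
    stop("need at least 2 samples and 1 CpG", call. = FALSE)
  }
  max_comp <- min(ncol(betas) - 1L, nrow(betas))
  if (n_components > min(ncol(betas), nrow(betas))) {
    stop("n_components exceeds matrix dimensions", call. = FALSE)
  }
  pc <- stats::prcomp(t(betas), center = TRUE, scale. = FALSE)
  ve_all <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  structure(list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    variance_explained = ve_all[seq_len(k)],
    variance_explained_all = ve_all
  ), class = "pca_result")
}

#' Compare delta-age between groups with Welch's t-test
#'
#' Convenience wrapper over [welch_t()] for annotated predictions: compares
#' `delta_age` between each non-reference group and the reference group,
#' optionally Bonferroni-correcting across comparisons.
#'
#' @param predictions data.frame from [delta_age()] (needs `delta_age` and
#'   `group`).
#' @param reference_group group compared against (default `"healthy"`).
#' @param bonferroni multiply p-values by the number of comparisons.
#' @return data.frame: `group`, `n`, `mean_delta`, `t_statistic`, `df`,
#'   `p_value` versus the reference group.
#' @export
compare_delta_age <- function(predictions, reference_group = "healthy",
                              bonferroni = FALSE) {
  stopifnot(is.data.frame(predictions),
            all(c("delta_age", "group") %in% names(predictions)))
  g <- as.character(predictions$group)
  if (!reference_group %in% g) {
    stop("reference group '", reference_group, "' not present",
         call. = FALSE)
  }
  ref <- predictions$delta_age[g == reference_group]
  others <- setdiff(unique(g[!is.na(g)]), reference_group)
  rows <- lapply(others, function(grp) {
    d <- predictions$delta_age[g == grp]
    w <- welch_t(d, ref)
    data.frame(group = grp, n = length(d), mean_delta = mean(d),
               t_statistic = w$t_statistic, df = w$df, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni && nrow(out) > 1) {
    out$p_value <- pmin(1, out$p_value * nrow(out))
  }
  attr(out, "reference_group") <- reference_group
  attr(out, "n_reference") <- length(ref)
  out
}
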