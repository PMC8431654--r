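# exact linear quantile regression (pinball loss). For the line model the
# optimum sits at a vertex determined by two data points, so for moderate n
# the global minimum is found by scoring every point pair; larger inputs are
# polished from the best subsampled candidate with Nelder-Mead.
.pinball_loss <- function(res, tau) sum(res * (tau - (res < 0)))

quantile_line <- function(x, y, tau, exact_max_n = 800L) {
  stopifnot(length(x) == length(y), length(x) >= 2L,
            tau > 0, tau < 1)
  if (diff(range(x)) == 0) {
    stop("cannot fit a quantile line: no spread in the predictor",
         call. = FALSE)
  }
  n <- length(x)
  score_pairs <- function(ii, jj) {
    keep <- x[ii] != x[jj]
    ii <- ii[keep]; jj <- jj[keep]
    b <- (y[jj] - y[ii]) / (x[jj] - x[ii])
    a <- y[ii] - b * x[ii]
    best <- c(Inf, NA, NA)
    chunk <- 4000L
    for (s in seq(1L, length(a), by = chunk)) {
      e <- min(s + chunk - 1L, length(a))
      res <- outer(y, rep(1, e - s + 1L)) -
        outer(rep(1, n), a[s:e]) - outer(x, b[s:e])
      loss <- colSums(res * (tau - (res < 0)))
      w <- which.min(loss)
      if (loss[w] < best[1]) best <- c(loss[w], a[s:e][w], b[s:e][w])
    }
    best
  }
  if (n <= exact_max_n) {
    cmb <- utils::combn(n, 2L)
    best <- score_pairs(cmb[1, ], cmb[2, ])
    list(intercept = best[2], slope = best[3], loss = best[1])
  } else {
    idx <- unique(round(seq(1L, n, length.out = 400L)))
    cmb <- utils::combn(idx, 2L)
    best <- score_pairs(cmb[1, ], cmb[2, ])
    opt <- stats::optim(best[2:3], function(p)
      .pinball_loss(y - p[1] - p[2] * x, tau), method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12))
    list(intercept = opt$par[1], slope = opt$par[2], loss = opt$value)
  }
}

ordinal_label <- function(p) {
  suffix <- if (p %% 100 %in% 11:13) "th" else
    switch(as.character(p %% 10), "1" = "st", "2" = "nd", "3" = "rd", "th")
  paste0(p, suffix)
}

#' Fit age-dependent telomere-length percentile curves
#'
#' Fits one straight line per requested percentile by linear quantile
#' regression (pinball-loss minimization), then enforces non-crossing within
#' the observed age range: curve values at the two ends of the range are
#' made non-decreasing across percentiles by pooled-adjacent-violators
#' averaging, and the lines are rebuilt from the adjusted endpoint values
#' (monotone at both ends of an interval implies monotone throughout it).
#' Linear curves are used deliberately: a few hundred reference donors do
#' not support stable nonlinear quantile fits, and lymphocyte telomere
#' attrition is approximately linear in adulthood.
#'
#' @param ages reference donor ages in years (at least 30 donors spanning at
#'   least 20 years).
#' @param kb telomere lengths in kilobases, same length as `ages`.
#' @param percentiles percentiles to fit, strictly between 0 and 100
#'   (default 1, 10, 50, 90, 99).
#' @return object of class `telomere_reference`: `percentiles`, `curves`
#'   (matrix percentile x c(intercept_kb, slope_kb_per_year)), `age_range`,
#'   `n_reference`.
#' @export
fit_percentile_curves <- function(ages, kb,
                                  percentiles = c(1, 10, 50, 90, 99)) {
  stopifnot(is.numeric(ages), is.numeric(kb), length(ages) == length(kb))
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100", call. = FALSE)
  }
  percentiles <- sort(unique(percentiles))
  if (length(ages) < 30L) {
    stop("need at least 30 reference samples (got ", length(ages), ")",
         call. = FALSE)
  }
  if (diff(range(ages)) < 20) {
    stop("reference ages must span at least 20 years", call. = FALSE)
  }
  fits <- lapply(percentiles / 100, function(tau)
    quantile_line(ages, kb, tau))
  curves <- cbind(
    intercept_kb = vapply(fits, `[[`, numeric(1), "intercept"),
    slope_kb_per_year = vapply(fits, `[[`, numeric(1), "slope")
  )
  rownames(curves) <- as.character(percentiles)
  # non-crossing adjustment at the ends of the observed age range
  rng <- range(ages)
  pava <- function(v) {  # non-decreasing pool-adjacent-violators
    f <- stats::isoreg(seq_along(v), v)$yf
    f + 1e-9 * seq_along(v)  # strictify ties
  }
  lo <- pava(curves[, 1] + curves[, 2] * rng[1])
  hi <- pava(curves[, 1] + curves[, 2] * rng[2])
  slope <- (hi - lo) / diff(rng)
  intercept <- lo - slope * rng[1]
  curves <- cbind(intercept_kb = intercept, slope_kb_per_year = slope)
  rownames(curves) <- as.character(percentiles)
  structure(list(percentiles = percentiles, curves = curves,
                 age_range = rng, n_reference = length(ages)),
            class = "telomere_reference")
}

#' Evaluate a fitted percentile curve at given ages
#'
#' @param reference a `telomere_reference`.
#' @param percentile one of the fitted percentiles.
#' @param age ages in years.
#' @return telomere length in kb along the requested curve.
#' @export
evaluate_percentile_curve <- function(reference, percentile, age) {
  stopifnot(inherits(reference, "telomere_reference"))
  key <- as.character(percentile)
  if (!key %in% rownames(reference$curves)) {
    stop("percentile ", percentile, " was not fitted", call. = FALSE)
  }
  reference$curves[key, 1] + reference$curves[key, 2] * age
}

#' Express telomere measurements as age-adjusted deltas
#'
#' For each measurement, `delta_kb` is the mean telomere length minus the
#' value of the 50th-percentile (median) reference curve at the donor's age.
#' The `band` labels attrition severity as the lowest fitted percentile
#' curve (among percentiles at or below the median) that the measurement
#' falls below -- e.g. `"<10th"` for the classical attrition criterion --
#' or `">=50th"` when the measurement is at or above the median curve.
#' Ages more than 5 years outside the fitted range trigger an extrapolation
#' warning and are flagged.
#'
#' @param measurements data.frame with `sample_id`, `age`, and either
#'   `mean_kb` or triplicate columns `rep1..repK` (averaged); optional
#'   `group` is carried through.
#' @param reference a `telomere_reference` fitted with the 50th percentile
#'   included.
#' @return data.frame with `sample_id`, `age`, `group` (if present),
#'   `mean_kb`, `expected_kb` (median curve), `delta_kb`, `band`,
#'   `below_10th` (if the 10th percentile was fitted), `extrapolated`.
#' @export
age_adjusted_delta <- function(measurements, reference) {
  stopifnot(inherits(reference, "telomere_reference"),
            is.data.frame(measurements),
            all(c("sample_id", "age") %in% names(measurements)))
  if (!"50" %in% rownames(reference$curves)) {
    stop("reference must include a fitted 50th percentile (median) curve",
         call. = FALSE)
  }
  m <- measurements
  if (!"mean_kb" %in% names(m)) {
    rep_cols <- grep("^rep[0-9]+$", names(m), value = TRUE)
    if (!length(rep_cols)) {
      stop("measurements need `mean_kb` or replicate columns rep1..repK",
           call. = FALSE)
    }
    m$mean_kb <- rowMeans(m[, rep_cols, drop = FALSE])
  }
  rng <- reference$age_range
  extrapolated <- m$age < rng[1] - 5 | m$age > rng[2] + 5
  if (any(extrapolated)) {
    warning(sum(extrapolated), " measurement(s) more than 5 years outside ",
            "the fitted age range [", round(rng[1], 1), ", ",
            round(rng[2], 1), "]; deltas are extrapolations")
  }
  expected <- evaluate_percentile_curve(reference, 50, m$age)
  lower_ps <- reference$percentiles[reference$percentiles <= 50]
  band <- vapply(seq_len(nrow(m)), function(i) {
    vals <- vapply(lower_ps, function(p)
      evaluate_percentile_curve(reference, p, m$age[i]), numeric(1))
    below <- lower_ps[m$mean_kb[i] < vals]
    if (length(below)) paste0("<", ordinal_label(min(below))) else ">=50th"
  }, character(1))
  out <- data.frame(sample_id = m$sample_id, age = m$age,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(m)) out$group <- m$group
  out$mean_kb <- m$mean_kb
  out$expected_kb <- expected
  out$delta_kb <- m$mean_kb - expected
  out$band <- band
  if (10 %in% reference$percentiles) {
    out$below_10th <- m$mean_kb <
      evaluate_percentile_curve(reference, 10, m$age)
  }
  out$extrapolated <- extrapolated
  out
}

#' Compare age-adjusted telomere deltas between two groups
#'
#' Welch's t-test on `delta_kb` between the two groups, plus a 2 x 2
#' Fisher's exact test on the counts of measurements below the 10th
#' percentile curve (the classical telomere-attrition criterion). Fisher's
#' exact test suits the small counts typical of this comparison; a zero row
#' (e.g. nobody below the 10th percentile) is handled without error.
#' Degenerate groupings (fewer than two groups, or fewer than two samples
#' in a group) return the descriptive summary only.
#'
#' @param deltas data.frame from [age_adjusted_delta()] (needs `delta_kb`;
#'   `below_10th` enables the contingency test).
#' @param groups group label per row (two distinct labels for testing);
#'   defaults to the `group` column of `deltas`.
#' @return list with `group_summary` (n, mean and sd of delta per group),
#'   `welch` ([welch_t()] result or NULL), `below_10th_table` (2 x 2 counts
#'   or NULL), `fisher_p` (or NA).
#' @export
compare_telomere_groups <- function(deltas, groups = deltas$group) {
  stopifnot(is.data.frame(deltas), "delta_kb" %in% names(deltas))
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(deltas))
  keep <- !is.na(groups)
  deltas <- deltas[keep, , drop = FALSE]
  groups <- groups[keep]
  lv <- unique(groups)
  summ <- do.call(rbind, lapply(lv, function(g) {
    d <- deltas$delta_kb[groups == g]
    data.frame(group = g, n = length(d), mean_delta_kb = mean(d),
               sd_delta_kb = stats::sd(d), stringsAsFactors = FALSE)
  }))
  testable <- length(lv) == 2 && all(table(groups) >= 2)
  welch <- NULL
  tab <- NULL
  fisher_p <- NA_real_
  if (testable) {
    welch <- welch_t(deltas$delta_kb[groups == lv[1]],
                     deltas$delta_kb[groups == lv[2]])
    if ("below_10th" %in% names(deltas)) {
      tab <- table(factor(groups, levels = lv),
                   factor(deltas$below_10th, levels = c(FALSE, TRUE)))
      fisher_p <- stats::fisher.test(tab)$p.value
    }
  }
  list(group_summary = summ, welch = welch, below_10th_table = tab,
       fisher_p = fisher_p)
}
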