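#' Leukocyte cell types used for deconvolution
#' @export
CELL_TYPES <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")

#' Synthetic leukocyte methylation reference
#'
#' A deterministic 12-CpG x 6-cell-type reference matrix (percent scale) for
#' testing and simulation: each cell type carries two CpGs highly methylated
#' in that type (90 percent) and low elsewhere (values 5--20), giving a
#' well-conditioned, full-column-rank design. This is a synthetic,
#' non-biological stand-in for a sorted-leukocyte reference; real references
#' are loaded with [read_cell_reference()].
#'
#' @return numeric matrix, 12 CpGs x 6 cell types, percent scale.
#' @export
synthetic_cell_reference <- function() {
  k <- length(CELL_TYPES)
  n <- 2 * k
  # deterministic low-level background varying over rows and columns so the
  # matrix is well conditioned, then two high CpGs planted per cell type
  ref <- outer(seq_len(n), seq_len(k),
               function(i, j) 5 + ((i * 7 + j * 13) %% 11))
  for (j in seq_len(k)) {
    ref[c(2 * j - 1, 2 * j), j] <- 90
  }
  rownames(ref) <- sprintf("cg_%s_%d", rep(CELL_TYPES, each = 2), 1:2)
  colnames(ref) <- CELL_TYPES
  stopifnot(qr(ref)$rank == k)
  ref
}

#' Read a cell-type methylation reference from TSV
#'
#' @param path TSV, rows = discriminating CpGs (first column id), columns =
#'   cell types, percent scale.
#' @return numeric matrix CpGs x cell types.
#' @export
read_cell_reference <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  ref <- as.matrix(tab)
  if (!is.numeric(ref)) stop("reference must be numeric", call. = FALSE)
  if (any(ref < 0 | ref > 100)) {
    stop("reference entries must lie in [0, 100] (percent)", call. = FALSE)
  }
  if (nrow(ref) < ncol(ref)) {
    stop("reference needs at least as many CpGs as cell types",
         call. = FALSE)
  }
  if (qr(ref)$rank < ncol(ref)) {
    stop("reference matrix is rank deficient", call. = FALSE)
  }
  ref
}

#' Write a cell-type reference to TSV
#' @param reference matrix CpGs x cell types.
#' @param path output path.
#' @export
write_cell_reference <- function(reference, path) {
  utils::write.table(cbind(cpg_id = rownames(reference),
                           as.data.frame(reference)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# solve min ||R f - b||^2 s.t. f >= 0, sum(f) <= 1 as a strictly convex
# quadratic program (dual active-set method); exact for full-rank references
.constrained_fractions <- function(R, b, tol = 1e-10) {
  k <- ncol(R)
  Dmat <- 2 * crossprod(R)
  dvec <- 2 * crossprod(R, b)
  Amat <- cbind(diag(k), -1)          # f >= 0 and -sum(f) >= -1
  bvec <- c(rep(0, k), -1)
  f <- quadprog::solve.QP(Dmat, dvec, Amat, bvec)$solution
  f[f < tol] <- 0
  f
}

#' Estimate leukocyte fractions from a methylation profile
#'
#' Reference-based deconvolution by constrained projection: minimizes
#' `||R f - b||^2` subject to `f >= 0` and `sum(f) <= 1`, where `R` is the
#' cell-type reference over its discriminating CpGs and `b` the sample's
#' betas at those CpGs. This is the constrained-least-squares estimator
#' underlying standard reference-based leukocyte estimation from blood
#' methylation profiles. With `normalize = TRUE` the solution is rescaled to
#' sum exactly to 1.
#'
#' @param betas a beta matrix (CpGs x samples) or a single named beta
#'   vector; must provide values for every reference CpG.
#' @param reference matrix CpGs x cell types, percent scale, full column
#'   rank.
#' @param normalize rescale fractions to sum to 1 (default FALSE).
#' @return data.frame of class `cell_fraction_estimate`: `sample_id`, one
#'   column per cell type, `residual_norm`.
#' @export
estimate_cell_fractions <- function(betas, reference, normalize = FALSE) {
  stopifnot(is.matrix(reference), !is.null(rownames(reference)),
            !is.null(colnames(reference)))
  if (qr(reference)$rank < ncol(reference)) {
    stop("reference matrix is rank deficient", call. = FALSE)
  }
  if (is.null(dim(betas))) {
    betas <- matrix(betas, ncol = 1,
                    dimnames = list(names(betas), "sample1"))
  }
  check_beta_matrix(betas)
  missing_cpgs <- setdiff(rownames(reference), rownames(betas))
  if (length(missing_cpgs)) {
    stop("sample lacks reference CpGs: ",
         paste(missing_cpgs, collapse = ", "), call. = FALSE)
  }
  B <- betas[rownames(reference), , drop = FALSE]
  res <- lapply(seq_len(ncol(B)), function(i) {
    f <- .constrained_fractions(reference, B[, i])
    if (normalize && sum(f) > 0) f <- f / sum(f)
    rn <- sqrt(sum((reference %*% f - B[, i])^2))
    c(f, residual_norm = rn)
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c(colnames(reference), "residual_norm")
  out <- cbind(data.frame(sample_id = colnames(B),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  class(out) <- c("cell_fraction_estimate", "data.frame")
  out
}

#' Compare leukocyte composition between two groups
#'
#' Per cell type: group means, mean difference, and Welch's t-test (no
#' multiple-testing correction by default, mirroring raw pairwise reporting;
#' `bonferroni = TRUE` multiplies p-values by the number of cell types).
#' With fewer than two groups containing at least two samples each, only the
#' descriptive summary is returned (no tests).
#'
#' @param estimates data.frame from [estimate_cell_fractions()].
#' @param groups group label per row of `estimates` (two distinct labels for
#'   testing).
#' @param bonferroni apply Bonferroni correction across cell types.
#' @return data.frame, one row per cell type: `cell_type`, `mean_<g1>`,
#'   `mean_<g2>`, `difference` (g1 - g2), `t_statistic`, `df`, `p_value`
#'   (test columns NA on the descriptive-only path).
#' @export
compare_composition <- function(estimates, groups, bonferroni = FALSE) {
  stopifnot(is.data.frame(estimates))
  cell_cols <- intersect(CELL_TYPES, names(estimates))
  if (!length(cell_cols)) {
    cell_cols <- setdiff(names(estimates),
                         c("sample_id", "residual_norm"))
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(estimates))
  keep <- !is.na(groups)
  estimates <- estimates[keep, , drop = FALSE]
  groups <- groups[keep]
  lv <- unique(groups)
  testable <- length(lv) == 2 && all(table(groups) >= 2)
  g1 <- lv[1]
  g2 <- if (length(lv) >= 2) lv[2] else NA_character_
  rows <- lapply(cell_cols, function(ct) {
    x <- estimates[[ct]][groups == g1]
    y <- if (!is.na(g2)) estimates[[ct]][groups == g2] else numeric(0)
    out <- data.frame(cell_type = ct,
                      mean_1 = mean(x),
                      mean_2 = if (length(y)) mean(y) else NA_real_,
                      difference = if (length(y)) mean(x) - mean(y) else
                        NA_real_,
                      t_statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    if (testable) {
      w <- welch_t(x, y)
      out$t_statistic <- w$t_statistic
      out$df <- w$df
      out$p_value <- w$p_value
    }
    out
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", g1)
  names(out)[names(out) == "mean_2"] <- paste0("mean_",
                                               if (is.na(g2)) "other" else g2)
  if (bonferroni && testable) {
    out$p_value <- pmin(1, out$p_value * nrow(out))
  }
  attr(out, "groups") <- c(g1, g2)
  attr(out, "tested") <- testable
  out
}
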