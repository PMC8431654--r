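#' Define a linear epigenetic clock
#'
#' A clock is a weighted sum of CpG methylation levels (percent scale) plus
#' an intercept, optionally passed through an age transform. With the
#' identity transform, predicted age in years is
#' `sum(weight_j * beta_j) + intercept`. The `log_linear` transform is the
#' piecewise log/linear age warp used by several published multi-tissue
#' clocks (logarithmic below an "adult age", linear above); it is provided
#' for applying such coefficient sets and is off by default.
#'
#' @param name clock name.
#' @param cpg_ids character vector of CpG identifiers (unique).
#' @param weights numeric weights, years per percent methylation.
#' @param intercept intercept in (transformed) years.
#' @param transform `"identity"` or `"log_linear"`.
#' @param adult_age pivot of the log_linear transform (default 20).
#' @return object of class `clock_definition`.
#' @export
clock_definition <- function(name, cpg_ids, weights, intercept,
                             transform = c("identity", "log_linear"),
                             adult_age = 20) {
  transform <- match.arg(transform)
  stopifnot(is.character(cpg_ids), length(cpg_ids) >= 1L,
            is.numeric(weights), length(weights) == length(cpg_ids))
  if (anyDuplicated(cpg_ids)) stop("duplicate cpg_id in clock", call. = FALSE)
  if (any(!is.finite(weights)) || !is.finite(intercept)) {
    stop("clock weights and intercept must be finite", call. = FALSE)
  }
  structure(list(name = name, cpg_ids = cpg_ids,
                 weights = stats::setNames(as.numeric(weights), cpg_ids),
                 intercept = as.numeric(intercept),
                 transform = transform, adult_age = adult_age),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("Epigenetic clock '%s' (%d CpGs, %s transform)\n",
              x$name, length(x$cpg_ids), x$transform))
  cat(sprintf("  intercept: %.4g years\n", x$intercept))
  for (id in x$cpg_ids) {
    cat(sprintf("  %-12s %+.4g years / %% methylation\n", id, x$weights[id]))
  }
  invisible(x)
}

#' The published three-CpG bisulfite-amplicon blood clock
#'
#' The refined targeted age predictor for human blood based on one signature
#' CpG in each of CCDC102B, FHL2 and PDE4C (a combination of hypo- and
#' hypermethylated sites), measured by bisulfite amplicon sequencing:
#'
#' `age (years) = -0.34 * CCDC102B + 0.83 * FHL2 + 1.18 * PDE4C + 3.86`
#'
#' with methylation levels in percent and no age transform.
#'
#' @return a [clock_definition()].
#' @examples
#' clock <- three_cpg_clock()
#' betas <- matrix(c(30, 40, 25), 3, 1,
#'                 dimnames = list(c("CCDC102B", "FHL2", "PDE4C"), "s1"))
#' predict_age(betas, clock)  # 56.46 years
#' @export
three_cpg_clock <- function() {
  clock_definition(
    name = "blood_3cpg",
    cpg_ids = c("CCDC102B", "FHL2", "PDE4C"),
    weights = c(-0.34, 0.83, 1.18),
    intercept = 3.86,
    transform = "identity"
  )
}

# piecewise log/linear age warp: log(age + 1) - log(adult + 1) below the
# pivot, (age - adult) / (adult + 1) above; its inverse maps a raw linear
# predictor back to years.
transform_age <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

inverse_transform_age <- function(raw, adult_age = 20) {
  ifelse(raw < 0,
         (adult_age + 1) * exp(raw) - 1,
         adult_age + raw * (adult_age + 1))
}

#' Predict epigenetic age from a beta matrix
#'
#' Computes `raw = sum(weight * beta) + intercept` per sample and applies the
#' clock's inverse age transform (identity clocks return `raw` unchanged).
#' Betas must be on the percent scale; see [read_beta_matrix()] for the
#' scale guard.
#'
#' Missing data handling (`missing_policy`):
#' \describe{
#'   \item{error}{any required CpG absent from the matrix, or NA for any
#'     sample, raises an error naming the CpGs (default -- silent imputation
#'     distorts clocks).}
#'   \item{drop_sample}{samples with NA at a required CpG are dropped.}
#'   \item{mean_impute}{NA entries are replaced by the CpG's mean across the
#'     samples that do have it; a CpG missing for all samples is still an
#'     error.}
#' }
#'
#' @param betas numeric matrix, CpGs x samples, percent scale.
#' @param clock a [clock_definition()].
#' @param missing_policy one of `"error"`, `"drop_sample"`, `"mean_impute"`.
#' @return data.frame with `sample_id`, `clock`, `predicted_age`.
#' @export
predict_age <- function(betas, clock,
                        missing_policy = c("error", "drop_sample",
                                           "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  check_beta_matrix(betas)
  stopifnot(inherits(clock, "clock_definition"))
  absent <- setdiff(clock$cpg_ids, rownames(betas))
  if (length(absent)) {
    stop("beta matrix lacks required CpGs: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  b <- betas[clock$cpg_ids, , drop = FALSE]
  if (anyNA(b)) {
    if (missing_policy == "error") {
      bad <- clock$cpg_ids[rowSums(is.na(b)) > 0]
      stop("missing beta values at required CpGs: ",
           paste(bad, collapse = ", "),
           " (use missing_policy = 'drop_sample' or 'mean_impute')",
           call. = FALSE)
    } else if (missing_policy == "drop_sample") {
      keep <- colSums(is.na(b)) == 0
      b <- b[, keep, drop = FALSE]
    } else {
      all_na <- rowSums(!is.na(b)) == 0
      if (any(all_na)) {
        stop("CpGs missing for every sample cannot be mean-imputed: ",
             paste(clock$cpg_ids[all_na], collapse = ", "), call. = FALSE)
      }
      rm_ <- rowMeans(b, na.rm = TRUE)
      idx <- which(is.na(b), arr.ind = TRUE)
      b[idx] <- rm_[idx[, 1]]
    }
  }
  raw <- drop(crossprod(b, clock$weights)) + clock$intercept
  pred <- if (clock$transform == "log_linear") {
    inverse_transform_age(raw, clock$adult_age)
  } else raw
  data.frame(sample_id = colnames(b), clock = clock$name,
             predicted_age = as.numeric(pred),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a linear epigenetic clock by ordinary least squares
#'
#' Regresses chronological age on the selected CpG betas (percent scale) with
#' an intercept, exactly the plain multivariable regression used for small
#' targeted clocks. No regularization is applied; for the three-CpG scale of
#' targeted assays OLS on a few dozen samples is the intended regime.
#'
#' @param betas numeric matrix, CpGs x samples, percent, no missing values.
#' @param ages chronological ages (years), one per sample (matched by the
#'   column order of `betas`, or by names if `ages` is named).
#' @param cpg_ids CpGs to include (default: all rows).
#' @param name clock name for the fitted object.
#' @return a [clock_definition()] with extra fields `fit` (list with
#'   `r_squared`, `mae`, `coef_table` including standard errors, `n`).
#' @export
fit_clock <- function(betas, ages, cpg_ids = rownames(betas),
                      name = "fitted") {
  check_beta_matrix(betas)
  missing_ids <- setdiff(cpg_ids, rownames(betas))
  if (length(missing_ids)) {
    stop("CpGs not in beta matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(names(ages))) ages <- ages[colnames(betas)]
  stopifnot(length(ages) == ncol(betas), !anyNA(ages))
  X <- t(betas[cpg_ids, , drop = FALSE])
  if (anyNA(X)) stop("beta matrix contains missing values", call. = FALSE)
  if (nrow(X) <= ncol(X) + 1L) {
    stop("need more samples than CpGs + 1 to fit", call. = FALSE)
  }
  df <- data.frame(age = as.numeric(ages), X, check.names = FALSE)
  fit <- stats::lm(age ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("collinear design; aliased CpGs: ",
         paste(gsub("`", "", bad), collapse = ", "), call. = FALSE)
  }
  # noise-free generators are a supported input; silence the benign
  # "essentially perfect fit" note summary.lm emits for them
  sm <- suppressWarnings(summary(fit))
  pred <- stats::fitted(fit)
  clock <- clock_definition(name, cpg_ids,
                            weights = unname(cf[-1]), intercept = cf[1])
  clock$fit <- list(
    r_squared = sm$r.squared,
    mae = mean(abs(pred - df$age)),
    coef_table = sm$coefficients,
    n = nrow(X)
  )
  clock
}

#' Annotate age predictions with delta-age
#'
#' Joins predictions with a sample sheet and computes
#' `delta_age = predicted_age - chronological_age`; positive values mean age
#' acceleration.
#'
#' @param predictions data.frame from [predict_age()].
#' @param sample_sheet data.frame with `sample_id`, `age`, optionally
#'   `group`; every predicted sample must be present.
#' @return the predictions with `chronological_age`, `delta_age` and (if
#'   available) `group` columns added.
#' @export
delta_age <- function(predictions, sample_sheet) {
  stopifnot(is.data.frame(predictions),
            all(c("sample_id", "predicted_age") %in% names(predictions)),
            is.data.frame(sample_sheet),
            all(c("sample_id", "age") %in% names(sample_sheet)))
  idx <- match(predictions$sample_id, sample_sheet$sample_id)
  if (anyNA(idx)) {
    stop("sample ids missing from sample sheet: ",
         paste(predictions$sample_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  predictions$chronological_age <- sample_sheet$age[idx]
  predictions$delta_age <- predictions$predicted_age -
    predictions$chronological_age
  if ("group" %in% names(sample_sheet)) {
    predictions$group <- sample_sheet$group[idx]
  }
  predictions
}

#' Write a clock coefficient table
#'
#' TSV with header `cpg_id<TAB>weight`, a reserved `(Intercept)` row, and a
#' leading `#transform=` comment line -- a format that accepts published
#' clock coefficient supplements with minimal editing.
#'
#' @param clock a [clock_definition()].
#' @param path output path.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_definition"))
  con <- file(path, "w")
  on.exit(close(con))
  tr <- if (clock$transform == "log_linear") {
    sprintf("log_linear(%g)", clock$adult_age)
  } else "identity"
  writeLines(sprintf("#transform=%s", tr), con)
  writeLines(sprintf("#name=%s", clock$name), con)
  writeLines("cpg_id\tweight", con)
  writeLines(sprintf("%s\t%.17g", clock$cpg_ids, clock$weights), con)
  writeLines(sprintf("(Intercept)\t%.17g", clock$intercept), con)
  invisible(path)
}

#' Read a clock coefficient table
#'
#' @param path TSV written by [write_clock()] or an edited published clock
#'   supplement in the same format.
#' @param name clock name override (default: `#name=` comment or file name).
#' @return a [clock_definition()].
#' @export
read_clock <- function(path, name = NULL) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("cpg_id", "weight") %in% names(tab)))
  transform <- "identity"
  adult_age <- 20
  tr_line <- grep("^#transform=", comments, value = TRUE)
  if (length(tr_line)) {
    spec <- sub("^#transform=", "", tr_line[1])
    if (grepl("^log_linear", spec)) {
      transform <- "log_linear"
      m <- regmatches(spec, regexec("log_linear\\(([0-9.]+)\\)", spec))[[1]]
      if (length(m) == 2) adult_age <- as.numeric(m[2])
    }
  }
  if (is.null(name)) {
    nm_line <- grep("^#name=", comments, value = TRUE)
    name <- if (length(nm_line)) sub("^#name=", "", nm_line[1]) else
      tools::file_path_sans_ext(basename(path))
  }
  is_int <- tab$cpg_id == "(Intercept)"
  if (sum(is_int) != 1L) {
    stop("clock table must contain exactly one (Intercept) row",
         call. = FALSE)
  }
  clock_definition(name, tab$cpg_id[!is_int], tab$weight[!is_int],
                   intercept = tab$weight[is_int], transform = transform,
                   adult_age = adult_age)
}

#' Write age predictions as TSV
#'
#' @param predictions data.frame from [predict_age()] / [delta_age()].
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
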