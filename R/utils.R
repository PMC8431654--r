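# internal helpers shared across modules

# run expr under a local RNG seeded with `seed`; NULL seed = use current RNG
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

clip01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# validate a beta matrix: numeric matrix, dimnames, percent scale
check_beta_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop("beta matrix must be a numeric matrix (CpGs x samples)", call. = FALSE)
  }
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop("beta matrix must carry CpG row names and sample column names",
         call. = FALSE)
  }
  invisible(betas)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
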