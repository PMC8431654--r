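#' Read a beta-value matrix from TSV
#'
#' Expects rows = CpG ids (first column), columns = sample ids (header row),
#' values on the percent scale (0--100). Matrices whose maximum value is at
#' most 1 look like fraction-scale data and are rejected unless
#' `fraction = TRUE`, in which case they are multiplied by 100. The percent
#' scale matters: linear clock coefficients calibrated on percent inputs
#' yield nonsense ages on fraction inputs.
#'
#' @param path TSV path (header row and id column mandatory).
#' @param fraction input is on the fraction scale \[0, 1\] and should be
#'   converted to percent.
#' @return numeric matrix, CpGs x samples, percent scale.
#' @export
read_beta_matrix <- function(path, fraction = FALSE) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  betas <- as.matrix(tab)
  if (!is.numeric(betas)) {
    stop("beta matrix must be numeric", call. = FALSE)
  }
  mx <- max(betas, na.rm = TRUE)
  if (fraction) {
    if (mx > 1) {
      stop("`fraction = TRUE` but values exceed 1; data already in percent?",
           call. = FALSE)
    }
    betas <- betas * 100
  } else if (mx <= 1) {
    stop("beta matrix looks fraction-scaled (max <= 1); pass ",
         "`fraction = TRUE` to convert to percent", call. = FALSE)
  }
  if (min(betas, na.rm = TRUE) < 0 || max(betas, na.rm = TRUE) > 100) {
    stop("beta values must lie in [0, 100] percent", call. = FALSE)
  }
  check_beta_matrix(betas)
}

#' Write a beta-value matrix as TSV
#' @param betas numeric matrix, CpGs x samples.
#' @param path output path.
#' @export
write_beta_matrix <- function(betas, path) {
  check_beta_matrix(betas)
  utils::write.table(cbind(cpg_id = rownames(betas), as.data.frame(betas)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with columns `sample_id`, `age`, optionally `group`
#'   (levels among [COHORT_GROUPS]).
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age") %in% names(tab))) {
    stop("sample sheet needs `sample_id` and `age` columns", call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample ids in sheet", call. = FALSE)
  }
  if ("group" %in% names(tab)) {
    bad <- setdiff(unique(tab$group), COHORT_GROUPS)
    if (length(bad)) {
      stop("unknown group labels: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    tab$group <- factor(tab$group, levels = COHORT_GROUPS)
  }
  tab
}

#' Write a sample sheet as TSV
#' @param samples data.frame with `sample_id`, `age`, optionally `group`.
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Sanger Phred+33 encoding; simulated reads carry the fixed quality 'I'
#' (Q40). Gzip output is selected by a `.gz` suffix.
#'
#' @param reads a `bisulfite_reads` object (or data.frame with `read_id`,
#'   `sequence`, optionally `quality`).
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(reads$sequence))
  Biostrings::writeXStringSet(
    seqs, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read a FASTQ file into a read data.frame
#'
#' Gzip-transparent. Qualities are read but the pipeline does not use them
#' (no quality trimming is applied).
#'
#' @param path FASTQ path (`.gz` allowed).
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  data.frame(
    read_id = names(seqs),
    sequence = as.character(seqs),
    quality = as.character(S4Vectors::mcols(seqs)$qualities),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write methylation calls as TSV
#' @param calls `methylation_calls` data.frame.
#' @param path output path.
#' @export
write_methylation_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read methylation calls from TSV
#' @param path path written by [write_methylation_calls()].
#' @return `methylation_calls` data.frame.
#' @export
read_methylation_calls <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("methylation_calls", "data.frame")
  out
}
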