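#' Construct an amplicon reference region
#'
#' One targeted bisulfite-amplicon region: the top-strand sequence and the
#' 0-based positions of the C of each interrogated CG dinucleotide.
#' Coordinates are 0-based, half-open throughout the package; a CpG is
#' identified by the position of its cytosine on the top strand.
#'
#' @param name region name (e.g. the associated gene: FHL2, CCDC102B, PDE4C).
#' @param sequence top-strand DNA sequence (A/C/G/T).
#' @param cpg_positions integer vector of 0-based offsets; each must point at
#'   a C immediately followed by a G, strictly increasing.
#' @param signature_cpg_index which CpG (1-based index into `cpg_positions`)
#'   feeds the epigenetic clock.
#' @return object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(name, sequence, cpg_positions,
                               signature_cpg_index = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence must contain only A/C/G/T", call. = FALSE)
  }
  cpg_positions <- as.integer(cpg_positions)
  if (length(cpg_positions) && any(diff(cpg_positions) <= 0)) {
    stop("`cpg_positions` must be strictly increasing", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  for (p in cpg_positions) {
    if (p < 0 || p + 2L > length(chars) ||
        chars[p + 1L] != "C" || chars[p + 2L] != "G") {
      stop(sprintf("position %d is not the C of a CG dinucleotide", p),
           call. = FALSE)
    }
  }
  if (length(cpg_positions)) {
    stopifnot(signature_cpg_index >= 1L,
              signature_cpg_index <= length(cpg_positions))
  }
  structure(list(name = name, sequence = sequence,
                 cpg_positions = cpg_positions,
                 signature_cpg_index = as.integer(signature_cpg_index)),
            class = "amplicon_reference")
}

#' Synthetic placeholder amplicon references
#'
#' Three deterministic 240 bp regions named after the clock loci (CCDC102B,
#' FHL2, PDE4C), each with three CpGs. These are synthetic test sequences --
#' NOT the genomic amplicons of the published assay (whose primers and
#' coordinates are defined in its original publication); real references are
#' loaded with [read_amplicon_references()].
#'
#' @return named list of [amplicon_reference()] objects (alphabetical order).
#' @export
synthetic_amplicon_references <- function() {
  make_ref <- function(name, seed, len = 240L,
                       cpg_at = c(60L, 120L, 180L), sig = 2L) {
    withr::with_seed(seed, {
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # scrub accidental CG dinucleotides so all CpGs are the planted ones
      repeat {
        s <- paste(chars, collapse = "")
        hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
        if (hits[1] == -1) break
        chars[hits + 1L] <- "A"
      }
      chars[cpg_at + 1L] <- "C"
      chars[cpg_at + 2L] <- "G"
      # planting may create a new upstream CG (x C C G); scrub it
      for (p in cpg_at) if (p >= 1L && chars[p] == "C") chars[p] <- "T"
      amplicon_reference(name, paste(chars, collapse = ""), cpg_at, sig)
    })
  }
  refs <- list(
    CCDC102B = make_ref("CCDC102B", 101L),
    FHL2     = make_ref("FHL2", 202L),
    PDE4C    = make_ref("PDE4C", 303L)
  )
  refs
}

check_references <- function(references) {
  if (inherits(references, "amplicon_reference")) {
    references <- list(references)
  }
  stopifnot(length(references) >= 1L,
            all(vapply(references, inherits, logical(1),
                       "amplicon_reference")))
  nms <- vapply(references, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate reference names", call. = FALSE)
  names(references) <- nms
  references[order(nms)]  # fixed alphabetical order for tie-breaking
}

#' Write amplicon references to FASTA plus a CpG-position table
#'
#' @param references list of [amplicon_reference()] objects.
#' @param fasta_path output FASTA path.
#' @param cpg_table_path output TSV path (columns `amplicon`, `position`
#'   (0-based), `signature` (0/1)).
#' @export
write_amplicon_references <- function(references, fasta_path,
                                      cpg_table_path) {
  references <- check_references(references)
  seqs <- Biostrings::DNAStringSet(
    vapply(references, `[[`, character(1), "sequence"))
  names(seqs) <- names(references)
  Biostrings::writeXStringSet(seqs, fasta_path)
  tab <- do.call(rbind, lapply(references, function(r) {
    data.frame(amplicon = r$name, position = r$cpg_positions,
               signature = as.integer(seq_along(r$cpg_positions) ==
                                        r$signature_cpg_index))
  }))
  utils::write.table(tab, cpg_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, cpgs = cpg_table_path))
}

#' Read amplicon references from FASTA plus a CpG-position table
#'
#' @param fasta_path FASTA of top-strand amplicon sequences.
#' @param cpg_table_path TSV with columns `amplicon`, `position` (0-based C
#'   of each CG), `signature` (0/1 flag of the clock-feeding CpG).
#' @return named list of [amplicon_reference()] objects.
#' @export
read_amplicon_references <- function(fasta_path, cpg_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tab <- utils::read.delim(cpg_table_path, stringsAsFactors = FALSE)
  stopifnot(all(c("amplicon", "position", "signature") %in% names(tab)))
  refs <- lapply(names(seqs), function(nm) {
    rows <- tab[tab$amplicon == nm, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    sig <- which(rows$signature == 1)
    amplicon_reference(nm, as.character(seqs[[nm]]), rows$position,
                       if (length(sig)) sig[1] else 1L)
  })
  check_references(refs)
}

# --- bisulfite-space alignment -------------------------------------------

# raw bytes of a string
.bytes <- function(s) charToRaw(s)

# matrix of all length-m windows of byte vector `ref` (m x noffsets)
.window_matrix <- function(refbytes, m) {
  L <- length(refbytes)
  noff <- L - m + 1L
  if (noff < 1L) return(NULL)
  idx <- outer(seq_len(m), 0L:(noff - 1L), `+`)
  matrix(refbytes[idx], nrow = m)
}

# alignment engine shared by bisulfite_align / align_reads.
# Collapsed spaces: original-top compares C->T read vs C->T reference;
# original-bottom compares G->A reverse-complemented read vs G->A reference,
# so methylation states never count as mismatches on either strand.
.align_engine <- function(seqs, references, max_mismatch_frac,
                          min_read_length) {
  references <- check_references(references)
  ref_ct <- lapply(references, function(r) .bytes(chartr("C", "T", r$sequence)))
  ref_ga <- lapply(references, function(r) .bytes(chartr("G", "A", r$sequence)))
  cache <- new.env(parent = emptyenv())
  get_windows <- function(key, refbytes, m) {
    id <- paste0(key, ":", m)
    w <- cache[[id]]
    if (is.null(w)) {
      w <- .window_matrix(refbytes, m)
      cache[[id]] <- w %||% FALSE
    }
    if (isFALSE(w)) NULL else w
  }
  n <- length(seqs)
  out <- data.frame(
    amplicon = rep(NA_character_, n), offset = rep(NA_integer_, n),
    strand = rep(NA_character_, n), mismatches = rep(NA_integer_, n),
    aligned = rep(FALSE, n), stringsAsFactors = FALSE
  )
  if (!n) return(out)
  rc <- reverse_complement(seqs)
  for (i in seq_len(n)) {
    m <- nchar(seqs[i])
    if (m < min_read_length) next
    read_ct <- .bytes(chartr("C", "T", seqs[i]))
    read_ga <- .bytes(chartr("G", "A", rc[i]))
    best <- NULL  # (mism, ref_rank, offset, strand_rank)
    for (k in seq_along(references)) {
      for (strand_rank in 1:2) {
        refbytes <- if (strand_rank == 1L) ref_ct[[k]] else ref_ga[[k]]
        rb <- if (strand_rank == 1L) read_ct else read_ga
        w <- get_windows(paste0(names(references)[k],
                                if (strand_rank == 1L) ":ct" else ":ga"),
                         refbytes, m)
        if (is.null(w)) next
        mism <- .colSums(w != rb, m, ncol(w))
        o <- which.min(mism)  # earliest offset at minimal mismatches
        cand <- c(mism[o], k, o - 1L, strand_rank)
        if (is.null(best) ||
            isTRUE(cand[1] < best[1]) ||
            (cand[1] == best[1] && (cand[2] < best[2] ||
              (cand[2] == best[2] && (cand[3] < best[3] ||
                (cand[3] == best[3] && cand[4] < best[4])))))) {
          best <- cand
        }
      }
    }
    if (!is.null(best) && best[1] / m <= max_mismatch_frac) {
      out$amplicon[i] <- names(references)[best[2]]
      out$offset[i] <- as.integer(best[3])
      out$strand[i] <- if (best[4] == 1L) "original_top" else "original_bottom"
      out$mismatches[i] <- as.integer(best[1])
      out$aligned[i] <- TRUE
    }
  }
  out
}

#' Align one bisulfite read to a set of amplicon references
#'
#' The read is compared against every reference, both bisulfite strands, at
#' every offset, in bisulfite-collapsed space: for an original-top placement
#' both read and reference are collapsed C to T; for original-bottom the
#' reverse complement of the read and the reference are collapsed G to A.
#' Collapsing makes methylation states (C vs T at CpGs) free of mismatch
#' cost, as in standard bisulfite aligners. The lowest-mismatch placement
#' wins if its mismatch fraction is at most `max_mismatch_frac`; ties are
#' broken by fewer mismatches, then fixed alphabetical reference order, then
#' smaller offset, then original-top strand.
#'
#' @param read a read sequence (character) or one-row read data.frame.
#' @param references list of [amplicon_reference()] objects.
#' @param max_mismatch_frac maximum allowed mismatches / read length
#'   (default 0.1).
#' @param min_read_length reads shorter than this are reported unaligned
#'   (default 30).
#' @return one-row data.frame with `read_id`, `amplicon`, `offset` (0-based),
#'   `strand`, `mismatches`, `aligned`. Unalignable reads have `aligned =
#'   FALSE` and NA placement, never an error.
#' @export
bisulfite_align <- function(read, references, max_mismatch_frac = 0.1,
                            min_read_length = 30L) {
  if (is.data.frame(read)) {
    stopifnot(nrow(read) == 1L)
    return(align_reads(read, references, max_mismatch_frac, min_read_length))
  }
  stopifnot(is.character(read), length(read) == 1L)
  res <- .align_engine(toupper(read), references, max_mismatch_frac,
                       min_read_length)
  cbind(data.frame(read_id = "read1", stringsAsFactors = FALSE), res)
}

#' Align a set of bisulfite reads to amplicon references
#'
#' Vectorized form of [bisulfite_align()]. Aligned and unaligned reads
#' together always account for every input read.
#'
#' @param reads a `bisulfite_reads` object, or any data.frame with `read_id`
#'   and `sequence` columns.
#' @param references list of [amplicon_reference()] objects.
#' @inheritParams bisulfite_align
#' @return data.frame, one row per input read, columns as in
#'   [bisulfite_align()].
#' @export
align_reads <- function(reads, references, max_mismatch_frac = 0.1,
                        min_read_length = 30L) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)))
  res <- .align_engine(toupper(reads$sequence), references,
                       max_mismatch_frac, min_read_length)
  cbind(data.frame(read_id = reads$read_id, stringsAsFactors = FALSE), res)
}

#' Call per-CpG methylation from aligned reads
#'
#' For every CpG of the reference, counts reads showing C (methylated)
#' versus T (unmethylated) at the CpG cytosine in reference coordinates. On
#' original-bottom alignments the evidence sits on the complementary strand:
#' the reverse-complemented read shows G (methylated) or A (unmethylated) at
#' the guanine position of the CpG. Any other base (sequencing error) is
#' ignored. CpGs with fewer than `min_coverage` informative reads are flagged
#' `low_coverage` and should be excluded from clock input.
#'
#' @param alignments data.frame from [align_reads()].
#' @param reads the read set the alignments refer to (`read_id`, `sequence`).
#' @param reference the [amplicon_reference()] to call.
#' @param min_coverage minimum informative reads per CpG (default 100, which
#'   keeps binomial sampling noise on the level below about 5 percent sd).
#' @return data.frame of class `methylation_calls`: `amplicon`,
#'   `cpg_position` (0-based), `methylated_count`, `unmethylated_count`,
#'   `total`, `level` (percent, NA when total is 0), `low_coverage`.
#'   With zero aligned reads an empty data.frame is returned with a warning.
#' @export
call_methylation <- function(alignments, reads, reference,
                             min_coverage = 100L) {
  stopifnot(inherits(reference, "amplicon_reference"),
            is.data.frame(alignments), is.data.frame(reads))
  al <- alignments[alignments$aligned %in% TRUE &
                     alignments$amplicon == reference$name, , drop = FALSE]
  template <- data.frame(
    amplicon = character(0), cpg_position = integer(0),
    methylated_count = integer(0), unmethylated_count = integer(0),
    total = integer(0), level = numeric(0), low_coverage = logical(0),
    stringsAsFactors = FALSE
  )
  if (!nrow(al)) {
    warning("no aligned reads for reference '", reference$name, "'")
    class(template) <- c("methylation_calls", "data.frame")
    return(template)
  }
  seqs <- toupper(reads$sequence[match(al$read_id, reads$read_id)])
  if (anyNA(seqs)) stop("alignments refer to read ids missing from `reads`",
                        call. = FALSE)
  is_top <- al$strand == "original_top"
  seqs[!is_top] <- reverse_complement(seqs[!is_top])
  lens <- nchar(seqs)
  calls <- lapply(reference$cpg_positions, function(p) {
    # column to inspect: the C for top reads, the G (p + 1) for bottom reads
    tpos <- ifelse(is_top, p, p + 1L)
    idx <- tpos - al$offset + 1L  # 1-based position within the read
    inside <- idx >= 1L & idx <= lens
    base <- rep(NA_character_, nrow(al))
    base[inside] <- substring(seqs[inside], idx[inside], idx[inside])
    meth <- sum(ifelse(is_top, base == "C", base == "G"), na.rm = TRUE)
    unmeth <- sum(ifelse(is_top, base == "T", base == "A"), na.rm = TRUE)
    total <- meth + unmeth
    data.frame(
      amplicon = reference$name, cpg_position = p,
      methylated_count = as.integer(meth),
      unmethylated_count = as.integer(unmeth),
      total = as.integer(total),
      level = if (total > 0) 100 * meth / total else NA_real_,
      low_coverage = total < min_coverage,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, calls)
  class(out) <- c("methylation_calls", "data.frame")
  out
}

#' Summarize coverage and alignment rate
#'
#' @param calls `methylation_calls` data.frame (possibly several amplicons
#'   row-bound together).
#' @param alignments optional alignment data.frame from [align_reads()]; if
#'   supplied, the aligned fraction is computed as aligned / total reads.
#' @return list with `per_amplicon` (mean/median CpG coverage per amplicon),
#'   `mean_coverage`, `median_coverage`, `n_reads`, `n_aligned`,
#'   `fraction_aligned`. Empty input gives NULL summaries and aligned
#'   fraction 0.
#' @export
coverage_report <- function(calls, alignments = NULL) {
  n_reads <- if (!is.null(alignments)) nrow(alignments) else NA_integer_
  n_aligned <- if (!is.null(alignments)) sum(alignments$aligned) else
    NA_integer_
  frac <- if (!is.null(alignments)) {
    if (n_reads > 0) n_aligned / n_reads else 0
  } else NA_real_
  if (is.null(calls) || !nrow(calls)) {
    return(list(per_amplicon = NULL, mean_coverage = NULL,
                median_coverage = NULL, n_reads = n_reads,
                n_aligned = n_aligned,
                fraction_aligned = if (is.null(alignments)) 0 else frac))
  }
  per <- do.call(rbind, lapply(split(calls, calls$amplicon), function(d) {
    data.frame(amplicon = d$amplicon[1],
               mean_coverage = mean(d$total),
               median_coverage = stats::median(d$total),
               n_cpgs = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_amplicon = per,
       mean_coverage = mean(calls$total),
       median_coverage = stats::median(calls$total),
       n_reads = n_reads, n_aligned = n_aligned,
       fraction_aligned = frac)
}

#' Assemble a beta matrix from methylation calls
#'
#' Turns per-amplicon methylation calls (one set per sample) into the
#' CpG x sample percent matrix consumed by [predict_age()]. CpG ids are
#' `amplicon` for signature CpGs (so they match clock coefficient tables
#' keyed by gene name) and `amplicon:position` otherwise. Low-coverage CpGs
#' become NA.
#'
#' @param call_list named list (by sample id) of `methylation_calls`.
#' @param references the reference list used for calling (identifies the
#'   signature CpG of each amplicon).
#' @return numeric matrix, CpGs x samples, percent scale.
#' @export
calls_to_beta_matrix <- function(call_list, references) {
  references <- check_references(references)
  stopifnot(is.list(call_list), !is.null(names(call_list)))
  sig <- lapply(references, function(r)
    r$cpg_positions[r$signature_cpg_index])
  cpg_name <- function(amp, pos) {
    ifelse(pos == sig[[amp]], amp, paste0(amp, ":", pos))
  }
  all_ids <- unlist(lapply(references, function(r)
    vapply(r$cpg_positions, function(p) cpg_name(r$name, p), character(1))),
    use.names = FALSE)
  out <- matrix(NA_real_, length(all_ids), length(call_list),
                dimnames = list(all_ids, names(call_list)))
  for (s in names(call_list)) {
    calls <- call_list[[s]]
    if (!nrow(calls)) next
    ids <- mapply(cpg_name, calls$amplicon, calls$cpg_position)
    lv <- ifelse(calls$low_coverage, NA_real_, calls$level)
    out[ids, s] <- lv
  }
  out
}
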