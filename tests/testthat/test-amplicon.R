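test_that("amplicon_reference validates CpG positions", {
  r <- amplicon_reference("A1", "AATCGATTCGAA", c(3, 8), 1)
  expect_s3_class(r, "amplicon_reference")
  expect_error(amplicon_reference("A1", "AATCGA", 1), "CG dinucleotide")
  expect_error(amplicon_reference("A1", "AACGACGA", c(5, 2)), "increasing")
  expect_error(amplicon_reference("A1", "AANGA", integer(0)), "A/C/G/T")
})

test_that("synthetic references have CpGs exactly where declared", {
  for (r in synthetic_amplicon_references()) {
    chars <- strsplit(r$sequence, "")[[1]]
    expect_true(all(chars[r$cpg_positions + 1L] == "C"))
    expect_true(all(chars[r$cpg_positions + 2L] == "G"))
    # no unlisted CG dinucleotides, so every read cytosine is accounted for
    hits <- gregexpr("CG", r$sequence, fixed = TRUE)[[1]]
    expect_setequal(as.integer(hits) - 1L, r$cpg_positions)
  }
})

test_that("an exactly converted read aligns perfectly; corrupt reads do not", {
  refs <- tiny_refs()
  # unmethylated fully converted top-strand copy of FHL2
  read <- gsub("C", "T", refs$FHL2$sequence)
  res <- bisulfite_align(read, refs)
  expect_true(res$aligned)
  expect_equal(res$amplicon, "FHL2")
  expect_equal(res$offset, 0)
  expect_equal(res$mismatches, 0)
  expect_equal(res$strand, "original_top")

  # 40% random substitutions exceed the 10% mismatch budget
  corrupt <- withr::with_seed(5, {
    chars <- strsplit(read, "")[[1]]
    idx <- sample(length(chars), round(0.4 * length(chars)))
    chars[idx] <- vapply(chars[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(chars, collapse = "")
  })
  expect_false(bisulfite_align(corrupt, refs, max_mismatch_frac = 0.1)$aligned)

  # reads below the minimum length are unaligned, not an error
  expect_false(bisulfite_align(substr(read, 1, 20), refs)$aligned)
})

test_that("bottom-strand reads align to the right amplicon and strand", {
  refs <- tiny_refs()
  rd <- simulate_reads(refs$CCDC102B, 50, coverage = 40,
                       conversion_rate = 1, error_rate = 0,
                       strand_fraction = 0, seed = 6)
  al <- align_reads(rd, refs)
  expect_true(all(al$aligned))
  expect_true(all(al$amplicon == "CCDC102B"))
  expect_true(all(al$strand == "original_bottom"))
  expect_true(all(al$mismatches == 0))
})

test_that("alignment matches the exhaustive brute-force oracle", {
  refs <- tiny_refs()
  set.seed(17)
  reads <- combine_reads(
    simulate_reads(refs$CCDC102B, 30, 60, seed = 101),
    simulate_reads(refs$FHL2, 50, 60, seed = 102),
    simulate_reads(refs$PDE4C, 80, 60, seed = 103)
  )
  al <- align_reads(reads, refs)
  expect_true(all(al$aligned))
  # assignment accuracy against ground-truth origin
  expect_gte(mean(al$amplicon == reads$amplicon), 0.999)
  # spot-check against the brute-force all-offset scorer
  idx <- seq(1, nrow(reads), by = 9)
  for (i in idx) {
    o <- oracle_align_one(reads$sequence[i], refs)
    expect_equal(al$mismatches[i], o$mism)
    expect_equal(al$amplicon[i], o$amplicon)
    expect_equal(al$offset[i], o$offset)
  }
})

test_that("alignment conserves reads: aligned + unaligned = total", {
  refs <- tiny_refs()
  rd <- simulate_reads(refs$FHL2, 42, 40, seed = 23)
  junk <- data.frame(read_id = c("junk1", "junk2"),
                     sequence = c(strrep("A", 240), strrep("ACGT", 60)),
                     quality = strrep("I", 240), strand = NA,
                     amplicon = NA)
  all_reads <- rbind(as.data.frame(rd)[names(junk)], junk)
  al <- align_reads(all_reads, refs)
  expect_equal(nrow(al), nrow(all_reads))
  expect_equal(sum(al$aligned) + sum(!al$aligned), nrow(all_reads))
  expect_false(any(al$aligned[al$read_id %in% junk$read_id]))
})

test_that("call_methylation counts C versus T in reference coordinates", {
  # hand-built reads: 7 methylated, 3 unmethylated at one CpG
  ref <- amplicon_reference("AMP", "AATTCGATTAATTAATTAATTAATTAATTAA", 4)
  n <- 10
  seqs <- ifelse(seq_len(n) <= 7,
                 gsub("C", "C", ref$sequence),           # methylated copy
                 sub("CG", "TG", ref$sequence))          # converted CpG
  reads <- data.frame(read_id = sprintf("r%d", 1:n), sequence = seqs)
  al <- align_reads(reads, list(ref), min_read_length = 10)
  calls <- call_methylation(al, reads, ref, min_coverage = 5)
  expect_equal(calls$methylated_count, 7L)
  expect_equal(calls$unmethylated_count, 3L)
  expect_equal(calls$level, 70)
  expect_false(calls$low_coverage)

  # low-coverage flagging
  calls2 <- call_methylation(al[1:2, ], reads[1:2, ], ref,
                             min_coverage = 100)
  expect_true(calls2$low_coverage)

  # zero aligned reads: empty result with a warning, not an error
  none <- al[0, ]
  expect_warning(empty <- call_methylation(none, reads, ref), "no aligned")
  expect_equal(nrow(empty), 0)
})

test_that("caller counts equal ground truth exactly on clean reads and are
           invariant to read order", {
  refs <- tiny_refs()
  rd <- simulate_reads(refs$PDE4C, 37, 400, conversion_rate = 1,
                       error_rate = 0, seed = 77)
  al <- align_reads(rd, refs)
  calls <- call_methylation(al, rd, refs$PDE4C, min_coverage = 10)
  tc <- attr(rd, "truth_counts")
  expect_equal(calls$methylated_count, tc$methylated)
  expect_equal(calls$total, tc$total)
  # per-read ground truth aggregated directly equals the caller's counts
  expect_equal(calls$methylated_count,
               unname(colSums(attr(rd, "truth"))))

  perm <- withr::with_seed(3, sample(nrow(rd)))
  al_p <- align_reads(rd[perm, ], refs)
  calls_p <- call_methylation(al_p, rd[perm, ], refs$PDE4C,
                              min_coverage = 10)
  expect_equal(calls_p$level, calls$level)
})

test_that("coverage_report summarizes counts and alignment rate", {
  calls <- data.frame(amplicon = "A", cpg_position = c(0, 5, 9),
                      methylated_count = c(50, 100, 150),
                      unmethylated_count = c(50, 100, 150),
                      total = c(100, 200, 300),
                      level = 50, low_coverage = FALSE)
  rep1 <- coverage_report(calls)
  expect_equal(rep1$mean_coverage, 200)
  expect_equal(rep1$per_amplicon$median_coverage, 200)

  empty <- coverage_report(calls[0, ], alignments = data.frame(aligned =
                                                                 logical(0)))
  expect_null(empty$per_amplicon)
  expect_equal(empty$fraction_aligned, 0)

  al <- data.frame(aligned = c(TRUE, TRUE, FALSE, TRUE))
  rep2 <- coverage_report(calls, al)
  expect_equal(rep2$fraction_aligned, 0.75)
})

test_that("calls_to_beta_matrix names signature CpGs by amplicon", {
  refs <- tiny_refs()
  rd <- simulate_reads(refs$FHL2, 42, 200, conversion_rate = 1,
                       error_rate = 0, seed = 55)
  al <- align_reads(rd, refs)
  calls <- call_methylation(al, rd, refs$FHL2, min_coverage = 10)
  bm <- calls_to_beta_matrix(list(s1 = calls), refs)
  expect_true("FHL2" %in% rownames(bm))
  sig_pos <- refs$FHL2$cpg_positions[refs$FHL2$signature_cpg_index]
  expect_equal(bm["FHL2", "s1"],
               calls$level[calls$cpg_position == sig_pos])
  expect_true(all(is.na(bm[grep("CCDC102B", rownames(bm)), "s1"])))
})
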