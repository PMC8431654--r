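# Independent oracles used by the tests. These are deliberately written as
# naive, self-contained computations (loops, closed forms, enumeration) so
# they never share code with the implementation they check.

# textbook Welch statistic, Satterthwaite df, two-sided p
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exact global solution of min ||R f - b||^2, f >= 0, sum(f) <= 1 by
# enumerating every support set, with and without the sum constraint active
oracle_constrained_ls <- function(R, b) {
  k <- ncol(R)
  best_f <- rep(0, k)
  best_obj <- sum(b^2)
  for (bits in 1:(2^k - 1)) {
    S <- which(bitwAnd(bits, 2^(0:(k - 1))) > 0)
    Rs <- R[, S, drop = FALSE]
    G <- crossprod(Rs)
    if (rcond(G) < 1e-12) next
    # sum constraint inactive
    f <- drop(solve(G, crossprod(Rs, b)))
    if (all(f >= -1e-9) && sum(f) <= 1 + 1e-9) {
      full <- rep(0, k); full[S] <- pmax(f, 0)
      obj <- sum((R %*% full - b)^2)
      if (obj < best_obj - 1e-12) { best_obj <- obj; best_f <- full }
    }
    # sum constraint active: KKT system with equality sum(f) = 1
    m <- length(S)
    K <- rbind(cbind(G, rep(1, m)), c(rep(1, m), 0))
    if (rcond(K) > 1e-12) {
      sol <- drop(solve(K, c(crossprod(Rs, b), 1)))
      f <- sol[seq_len(m)]
      if (all(f >= -1e-9)) {
        full <- rep(0, k); full[S] <- pmax(f, 0)
        full <- full / sum(full)  # exact feasibility
        obj <- sum((R %*% full - b)^2)
        if (obj < best_obj - 1e-12) { best_obj <- obj; best_f <- full }
      }
    }
  }
  best_f
}

# pinball loss of a candidate quantile line
oracle_pinball <- function(x, y, a, b, tau) {
  r <- y - a - b * x
  sum(r * (tau - (r < 0)))
}

# brute-force Nelder-Mead quantile line from an OLS start (independent of
# the implementation's pair-enumeration route)
oracle_quantile_line <- function(x, y, tau) {
  start <- coef(lm(y ~ x))
  start[1] <- start[1] + qnorm(tau, sd = sd(residuals(lm(y ~ x))))
  opt <- optim(start, function(p) oracle_pinball(x, y, p[1], p[2], tau),
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-13))
  opt
}

# exhaustive all-offset, all-strand, all-reference bisulfite alignment
# scorer built from character vectors and explicit loops
oracle_align_one <- function(seq, refs) {
  revcomp_chr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  best <- NULL
  ref_names <- sort(vapply(refs, `[[`, character(1), "name"))
  refs <- refs[ref_names]
  for (rn in ref_names) {
    rseq <- refs[[rn]]$sequence
    for (strand in c("original_top", "original_bottom")) {
      if (strand == "original_top") {
        rr <- strsplit(gsub("C", "T", rseq), "")[[1]]
        qq <- strsplit(gsub("C", "T", seq), "")[[1]]
      } else {
        rr <- strsplit(gsub("G", "A", rseq), "")[[1]]
        qq <- strsplit(gsub("G", "A", revcomp_chr(seq)), "")[[1]]
      }
      m <- length(qq)
      if (m > length(rr)) next
      for (off in 0:(length(rr) - m)) {
        mm <- sum(rr[(off + 1):(off + m)] != qq)
        cand <- list(mism = mm, amplicon = rn, offset = off,
                     strand = strand)
        if (is.null(best) || mm < best$mism) best <- cand
      }
    }
  }
  best
}

# small fast references for alignment unit tests
tiny_refs <- function() {
  synthetic_amplicon_references()
}

clock_cpg_ids <- function(models) {
  vapply(models, function(m) m$cpg_id, character(1))
}
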