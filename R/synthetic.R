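#' Valid cohort group labels
#'
#' Study groups: healthy controls, hospitalized COVID-19 patients without
#' acute respiratory distress syndrome, and patients with ARDS.
#' @export
COHORT_GROUPS <- c("healthy", "covid_no_ards", "covid_ards")

#' Generate a synthetic cohort sample sheet
#'
#' Draws `n` donors with chronological ages uniform on `age_range` and group
#' labels multinomial with the given proportions. The output is the sample
#' sheet consumed by every downstream simulator and by [delta_age()].
#'
#' @param n number of samples (>= 1).
#' @param age_range length-2 numeric, minimum and maximum age in years.
#' @param group_proportions named numeric vector over a subset of
#'   [COHORT_GROUPS], summing to 1.
#' @param seed integer seed; identical seed and arguments give an identical
#'   cohort.
#' @return data.frame with columns `sample_id`, `age`, `group`.
#' @examples
#' cohort <- generate_cohort(10, c(18, 74), seed = 1)
#' @export
generate_cohort <- function(n, age_range = c(18, 74),
                            group_proportions = c(healthy = 1),
                            seed = NULL) {
  stop_if_not_scalar_number(n, "n", min = 1)
  if (n != round(n)) stop("`n` must be a whole number", call. = FALSE)
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      any(!is.finite(age_range)) || age_range[2] < age_range[1] ||
      age_range[1] <= 0) {
    stop("`age_range` must be positive and non-empty (min <= max)",
         call. = FALSE)
  }
  if (is.null(names(group_proportions)) ||
      !all(names(group_proportions) %in% COHORT_GROUPS)) {
    stop("`group_proportions` must be named with labels among: ",
         paste(COHORT_GROUPS, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(group_proportions) - 1) > 1e-9) {
    stop("`group_proportions` must sum to 1", call. = FALSE)
  }
  n <- as.integer(n)
  with_seed_or_not(seed, {
    ages <- stats::runif(n, age_range[1], age_range[2])
    groups <- sample(names(group_proportions), n, replace = TRUE,
                     prob = group_proportions)
    data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      age = ages,
      group = factor(groups, levels = COHORT_GROUPS),
      stringsAsFactors = FALSE
    )
  })
}

#' Define a linear age--methylation model for one CpG
#'
#' Methylation at an age-associated CpG is modeled as
#' `beta = baseline + slope * age + N(0, noise_sd^2)`, clipped to the percent
#' scale \[0, 100\]. Negative slopes describe CpGs that lose methylation with
#' age (hypomethylating), positive slopes CpGs that gain it.
#'
#' @param cpg_id CpG identifier (e.g. the associated gene name).
#' @param baseline methylation in percent at age 0.
#' @param slope percent change per year (may be negative).
#' @param noise_sd Gaussian noise standard deviation in percent.
#' @return object of class `cpg_age_model`.
#' @export
cpg_age_model <- function(cpg_id, baseline, slope, noise_sd = 3) {
  stopifnot(is.character(cpg_id), length(cpg_id) == 1L)
  stop_if_not_scalar_number(baseline, "baseline")
  stop_if_not_scalar_number(slope, "slope")
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  structure(list(cpg_id = cpg_id, baseline = baseline, slope = slope,
                 noise_sd = noise_sd),
            class = "cpg_age_model")
}

#' Default three-CpG age models
#'
#' A hypomethylating CCDC102B-like CpG and two hypermethylating CpGs
#' (FHL2-like, PDE4C-like) with per-CpG noise sd 3 percent. Baselines and
#' slopes keep simulated betas well inside \[0, 100\] over ages 18--74, and
#' the noise level makes the mean absolute prediction error of the matched
#' exact clock (about 4 years) comparable to targeted bisulfite-amplicon
#' assays on adult blood.
#'
#' @return list of [cpg_age_model()] objects.
#' @export
default_cpg_models <- function() {
  list(
    cpg_age_model("CCDC102B", baseline = 80, slope = -0.45, noise_sd = 3),
    cpg_age_model("FHL2",     baseline = 10, slope =  0.50, noise_sd = 3),
    cpg_age_model("PDE4C",    baseline = 15, slope =  0.60, noise_sd = 3)
  )
}

check_cpg_models <- function(cpg_models) {
  if (inherits(cpg_models, "cpg_age_model")) cpg_models <- list(cpg_models)
  if (!length(cpg_models) ||
      !all(vapply(cpg_models, inherits, logical(1), "cpg_age_model"))) {
    stop("`cpg_models` must be a non-empty list of cpg_age_model objects",
         call. = FALSE)
  }
  ids <- vapply(cpg_models, `[[`, character(1), "cpg_id")
  if (anyDuplicated(ids)) stop("duplicate cpg_id in `cpg_models`", call. = FALSE)
  cpg_models
}

#' Simulate a beta-value matrix from per-CpG age models
#'
#' For every sample and CpG draws
#' `clip(baseline + slope * age + N(0, noise_sd^2), 0, 100)`.
#' Clipping introduces a small bias for CpGs whose linear trend approaches
#' the scale boundaries; the default models avoid this region.
#'
#' @param samples cohort data.frame from [generate_cohort()] (needs
#'   `sample_id` and `age`).
#' @param cpg_models list of [cpg_age_model()] objects.
#' @param seed integer seed.
#' @return numeric matrix, CpGs x samples, percent scale.
#' @export
simulate_betas <- function(samples, cpg_models = default_cpg_models(),
                           seed = NULL) {
  cpg_models <- check_cpg_models(cpg_models)
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "age") %in% names(samples)))
  ids <- vapply(cpg_models, `[[`, character(1), "cpg_id")
  with_seed_or_not(seed, {
    betas <- vapply(seq_along(cpg_models), function(j) {
      m <- cpg_models[[j]]
      clip01(m$baseline + m$slope * samples$age +
               stats::rnorm(nrow(samples), 0, m$noise_sd))
    }, numeric(nrow(samples)))
    betas <- t(matrix(betas, nrow = nrow(samples), ncol = length(cpg_models)))
    dimnames(betas) <- list(ids, samples$sample_id)
    betas
  })
}

#' Build the exact clock matched to a set of CpG age models
#'
#' Constructs a clock that inverts the generating model exactly: applied to
#' noise-free betas from [simulate_betas()], it returns the generating age.
#' The allocation rule puts all weight on the CpG with the largest absolute
#' slope `b*`: its weight is `1 / b*` and the intercept is `-baseline* / b*`,
#' so that the weighted slopes sum to 1 and the weighted baselines cancel.
#' This single-CpG allocation maximizes the signal per unit weight and gives
#' the prediction noise a closed form (`noise_sd / |b*|` per sample), which
#' parameter-recovery tests rely on.
#'
#' @param cpg_models list of [cpg_age_model()] objects; at least one slope
#'   must be non-zero.
#' @param name clock name.
#' @return a [clock_definition()] whose terms cover all supplied CpGs (zero
#'   weight off the carrier CpG).
#' @export
consistent_clock <- function(cpg_models, name = "consistent") {
  cpg_models <- check_cpg_models(cpg_models)
  slopes <- vapply(cpg_models, `[[`, numeric(1), "slope")
  if (all(slopes == 0)) {
    stop("no invertible signal: all CpG slopes are zero", call. = FALSE)
  }
  j <- which.max(abs(slopes))
  weights <- numeric(length(cpg_models))
  weights[j] <- 1 / slopes[j]
  intercept <- -cpg_models[[j]]$baseline / slopes[j]
  clock_definition(
    name = name,
    cpg_ids = vapply(cpg_models, `[[`, character(1), "cpg_id"),
    weights = weights,
    intercept = intercept
  )
}

#' Simulate bisulfite amplicon reads at set methylation levels
#'
#' Emulates targeted bisulfite amplicon sequencing of one reference region.
#' Per read: a strand is drawn (original-top with probability
#' `strand_fraction`); each CpG cytosine is methylated (kept as C) with
#' probability `level / 100`, independently per read; each non-CpG cytosine
#' is bisulfite-converted C to T with probability `conversion_rate`
#' (incomplete conversion leaves a C); finally every base suffers an
#' independent substitution to a uniformly chosen other base with probability
#' `error_rate`. Original-bottom reads are emitted as the converted bottom
#' strand 5' to 3' (the reverse complement of the reference, with its own
#' cytosines subject to the same chemistry). Reads span the full amplicon, as
#' in amplicon sequencing with read length exceeding the amplicon.
#'
#' @param amplicon an [amplicon_reference()].
#' @param cpg_levels methylation levels in percent: a single value recycled
#'   over the amplicon's CpGs, or one value per CpG (optionally named by
#'   position).
#' @param coverage number of reads; 0 gives an empty read set.
#' @param conversion_rate probability that an unmethylated cytosine is
#'   converted (default 0.995, typical bisulfite chemistry).
#' @param error_rate per-base substitution error probability (default 0.001).
#' @param strand_fraction fraction of reads from the original-top strand.
#' @param seed integer seed.
#' @return object of class `bisulfite_reads`: a data.frame with columns
#'   `read_id`, `sequence`, `quality`, `strand`, `amplicon`, and attributes
#'   `truth` (reads x CpGs logical matrix of per-read methylation states) and
#'   `truth_counts` (per-CpG methylated/total counts, the ground-truth
#'   sidecar for the methylation caller).
#' @export
simulate_reads <- function(amplicon, cpg_levels, coverage,
                           conversion_rate = 0.995, error_rate = 0.001,
                           strand_fraction = 0.5, seed = NULL) {
  stopifnot(inherits(amplicon, "amplicon_reference"))
  stop_if_not_scalar_number(coverage, "coverage", min = 0)
  stop_if_not_scalar_number(conversion_rate, "conversion_rate", 0, 1)
  stop_if_not_scalar_number(error_rate, "error_rate", 0, 1)
  stop_if_not_scalar_number(strand_fraction, "strand_fraction", 0, 1)
  pos <- amplicon$cpg_positions
  ncpg <- length(pos)
  if (length(cpg_levels) == 1L) cpg_levels <- rep(cpg_levels, ncpg)
  if (length(cpg_levels) != ncpg) {
    stop("`cpg_levels` must have one value per CpG (or a single value)",
         call. = FALSE)
  }
  if (any(cpg_levels < 0 | cpg_levels > 100)) {
    stop("`cpg_levels` must lie in [0, 100]", call. = FALSE)
  }
  coverage <- as.integer(coverage)

  top <- strsplit(amplicon$sequence, "")[[1]]
  L <- length(top)
  bottom <- strsplit(reverse_complement(amplicon$sequence), "")[[1]]
  # CpG cytosine index per strand (1-based); bottom-strand CpG C pairs with
  # the top-strand G at pos + 1 (0-based), i.e. bottom index L - 1 - pos
  top_cpg_i <- pos + 1L
  bot_cpg_i <- L - 1L - pos
  top_noncpg_c <- setdiff(which(top == "C"), top_cpg_i)
  bot_noncpg_c <- setdiff(which(bottom == "C"), bot_cpg_i)

  empty <- function() {
    out <- data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), strand = character(0),
                      amplicon = character(0), stringsAsFactors = FALSE)
    attr(out, "truth") <- matrix(logical(0), 0, ncpg,
                                 dimnames = list(NULL, as.character(pos)))
    attr(out, "truth_counts") <- data.frame(
      amplicon = character(0), cpg_position = integer(0),
      methylated = integer(0), total = integer(0))
    class(out) <- c("bisulfite_reads", "data.frame")
    out
  }
  if (coverage == 0L) return(empty())

  with_seed_or_not(seed, {
    is_top <- stats::runif(coverage) < strand_fraction
    meth <- matrix(stats::runif(coverage * ncpg) < rep(cpg_levels / 100,
                                                       each = coverage),
                   nrow = coverage, ncol = ncpg,
                   dimnames = list(NULL, as.character(pos)))
    bases <- c("A", "C", "G", "T")
    seqs <- character(coverage)
    for (r in seq_len(coverage)) {
      if (is_top[r]) {
        s <- top
        cpg_i <- top_cpg_i
        noncpg <- top_noncpg_c
        st <- meth[r, ]
      } else {
        s <- bottom
        cpg_i <- bot_cpg_i
        noncpg <- bot_noncpg_c
        st <- meth[r, ]  # per-molecule state, symmetric across strands
      }
      s[cpg_i[!st]] <- "T"
      if (length(noncpg)) {
        conv <- stats::runif(length(noncpg)) < conversion_rate
        s[noncpg[conv]] <- "T"
      }
      if (error_rate > 0) {
        err <- which(stats::runif(L) < error_rate)
        for (i in err) s[i] <- sample(setdiff(bases, s[i]), 1L)
      }
      seqs[r] <- paste(s, collapse = "")
    }
    out <- data.frame(
      read_id = sprintf("%s_read%05d", amplicon$name, seq_len(coverage)),
      sequence = seqs,
      quality = strrep("I", L),
      strand = ifelse(is_top, "original_top", "original_bottom"),
      amplicon = amplicon$name,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- meth
    attr(out, "truth_counts") <- data.frame(
      amplicon = amplicon$name,
      cpg_position = pos,
      methylated = as.integer(colSums(meth)),
      total = coverage
    )
    class(out) <- c("bisulfite_reads", "data.frame")
    out
  })
}

#' Combine read sets from several amplicons
#'
#' @param ... `bisulfite_reads` objects.
#' @return a single `bisulfite_reads` object; ground-truth attributes are
#'   concatenated.
#' @export
combine_reads <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "bisulfite_reads")))
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  out$read_id <- make.unique(out$read_id)
  attr(out, "truth_counts") <- do.call(rbind,
                                       lapply(parts, attr, "truth_counts"))
  class(out) <- c("bisulfite_reads", "data.frame")
  out
}

#' Reference leukocyte fractions for a healthy adult donor
#'
#' Approximate whole-blood leukocyte composition: granulocyte-dominated with
#' CD4 > CD8 T cells, and small NK, B and monocyte compartments.
#' @return named numeric vector over the six leukocyte types, summing to 1.
#' @export
healthy_cell_fractions <- function() {
  c(CD4T = 0.15, CD8T = 0.08, NK = 0.07, Bcell = 0.05,
    Mono = 0.05, Gran = 0.60)
}

#' Reference leukocyte fractions for a severe COVID-19 patient
#'
#' Emulates the leukocyte shift of severe COVID-19: lymphopenia (reduced
#' CD4, CD8, NK and B cells) with increased monocytes and granulocytes.
#' @return named numeric vector over the six leukocyte types, summing to 1.
#' @export
covid_cell_fractions <- function() {
  c(CD4T = 0.08, CD8T = 0.04, NK = 0.03, Bcell = 0.03,
    Mono = 0.08, Gran = 0.74)
}

#' Draw per-sample leukocyte fractions around a preset composition
#'
#' Dirichlet draws with concentration `concentration * preset`, so the
#' expectation equals the preset and larger `concentration` means less
#' inter-individual variation.
#'
#' @param n number of samples.
#' @param preset named fraction vector (e.g. [healthy_cell_fractions()]).
#' @param concentration Dirichlet concentration (default 200, giving
#'   realistic few-percent scatter on major populations).
#' @param seed integer seed.
#' @return matrix n x cell types, rows summing to 1.
#' @export
sample_cell_fractions <- function(n, preset = healthy_cell_fractions(),
                                  concentration = 200, seed = NULL) {
  stop_if_not_scalar_number(n, "n", min = 1)
  stopifnot(is.numeric(preset), !is.null(names(preset)),
            all(preset > 0), abs(sum(preset) - 1) < 1e-6)
  with_seed_or_not(seed, {
    g <- matrix(stats::rgamma(n * length(preset),
                              shape = rep(concentration * preset, each = n)),
                nrow = n)
    f <- g / rowSums(g)
    colnames(f) <- names(preset)
    f
  })
}

#' Simulate a methylation profile of a leukocyte mixture
#'
#' The profile is the fraction-weighted average of the cell-type reference
#' columns plus Gaussian noise, clipped to \[0, 100\].
#'
#' @param fractions non-negative named vector over the reference's cell
#'   types, summing to 1 (tolerance 1e-6).
#' @param reference cell-type reference matrix (CpGs x cell types, percent),
#'   e.g. [synthetic_cell_reference()].
#' @param noise_sd Gaussian noise sd in percent.
#' @param seed integer seed.
#' @return named numeric vector of betas over the reference CpGs.
#' @export
simulate_cell_mixture_betas <- function(fractions, reference, noise_sd = 0,
                                        seed = NULL) {
  stopifnot(is.matrix(reference), !is.null(colnames(reference)))
  if (length(fractions) != ncol(reference)) {
    stop("`fractions` length must equal the number of reference cell types",
         call. = FALSE)
  }
  if (!is.null(names(fractions))) {
    if (!setequal(names(fractions), colnames(reference))) {
      stop("`fractions` names must match the reference cell types",
           call. = FALSE)
    }
    fractions <- fractions[colnames(reference)]
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-6) {
    stop("`fractions` must be non-negative and sum to 1", call. = FALSE)
  }
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  with_seed_or_not(seed, {
    b <- drop(reference %*% fractions)
    clip01(b + stats::rnorm(length(b), 0, noise_sd))
  })
}

#' Simulate telomere-length measurements with age-dependent attrition
#'
#' Telomere length follows `intercept + slope * age + N(0, sd^2)` kilobases
#' per donor (floored at 0), and each donor is measured in triplicate with
#' small technical replicate noise around the donor value.
#'
#' @param samples cohort data.frame (`sample_id`, `age`, optionally `group`).
#' @param intercept_kb telomere length at age 0 (default 9.5 kb).
#' @param slope_kb_per_year attrition rate (default -0.05 kb/year, adult
#'   lymphocyte scale).
#' @param sd_kb inter-individual sd (default 0.7 kb).
#' @param replicate_sd_kb technical sd between triplicates (default 0.1 kb;
#'   0 gives identical replicates).
#' @param n_replicates measurements per donor (default 3).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `age`, `group`, replicate columns
#'   `rep1..repK`, and `mean_kb`.
#' @export
simulate_telomeres <- function(samples, intercept_kb = 9.5,
                               slope_kb_per_year = -0.05, sd_kb = 0.7,
                               replicate_sd_kb = 0.1, n_replicates = 3,
                               seed = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "age") %in% names(samples)))
  stop_if_not_scalar_number(sd_kb, "sd_kb", min = 0)
  stop_if_not_scalar_number(replicate_sd_kb, "replicate_sd_kb", min = 0)
  stop_if_not_scalar_number(n_replicates, "n_replicates", min = 1)
  n <- nrow(samples)
  with_seed_or_not(seed, {
    donor <- pmax(intercept_kb + slope_kb_per_year * samples$age +
                    stats::rnorm(n, 0, sd_kb), 0)
    reps <- vapply(seq_len(n_replicates), function(k) {
      pmax(donor + stats::rnorm(n, 0, replicate_sd_kb), 0)
    }, numeric(n))
    reps <- matrix(reps, nrow = n)
    colnames(reps) <- sprintf("rep%d", seq_len(n_replicates))
    out <- data.frame(sample_id = samples$sample_id, age = samples$age,
                      group = samples$group %||% rep(NA_character_, n),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(reps))
    out$mean_kb <- rowMeans(reps)
    out
  })
}

#' Simulate a complete study dataset with ground truth
#'
#' Generates a cohort at the study's sample sizes (95 healthy controls, 20
#' COVID-19 patients without ARDS, 27 with ARDS by default), clock-CpG betas
#' driven by age only, leukocyte mixtures with a composition shift in the
#' COVID groups (the clock CpGs are disjoint from the deconvolution CpGs, so
#' the shift does not touch epigenetic age), and telomere measurements.
#'
#' @param n_healthy,n_covid_no_ards,n_covid_ards group sizes.
#' @param age_range cohort age range in years.
#' @param cpg_models per-CpG age models for the clock betas.
#' @param cell_reference cell-type reference matrix.
#' @param mixture_noise_sd beta noise for mixture profiles (percent).
#' @param seed integer seed for the whole dataset.
#' @return list with `samples`, `betas` (clock CpGs), `clock` (the exact
#'   generating clock), `cell_fractions` (true per-sample fractions),
#'   `mixture_betas` (deconvolution CpGs), `telomeres`, and `seed`.
#' @export
simulate_study <- function(n_healthy = 95, n_covid_no_ards = 20,
                           n_covid_ards = 27, age_range = c(18, 74),
                           cpg_models = default_cpg_models(),
                           cell_reference = synthetic_cell_reference(),
                           mixture_noise_sd = 1, seed = NULL) {
  with_seed_or_not(seed, {
    counts <- c(healthy = n_healthy, covid_no_ards = n_covid_no_ards,
                covid_ards = n_covid_ards)
    counts <- counts[counts > 0]
    n <- sum(counts)
    samples <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      age = stats::runif(n, age_range[1], age_range[2]),
      group = factor(rep(names(counts), counts), levels = COHORT_GROUPS),
      stringsAsFactors = FALSE
    )
    betas <- simulate_betas(samples, cpg_models)
    is_covid <- samples$group != "healthy"
    fr <- matrix(NA_real_, n, ncol(cell_reference),
                 dimnames = list(samples$sample_id, colnames(cell_reference)))
    if (any(!is_covid)) {
      fr[!is_covid, ] <- sample_cell_fractions(sum(!is_covid),
                                               healthy_cell_fractions())
    }
    if (any(is_covid)) {
      fr[is_covid, ] <- sample_cell_fractions(sum(is_covid),
                                              covid_cell_fractions())
    }
    mix <- vapply(seq_len(n), function(i) {
      simulate_cell_mixture_betas(fr[i, ], cell_reference, mixture_noise_sd)
    }, numeric(nrow(cell_reference)))
    dimnames(mix) <- list(rownames(cell_reference), samples$sample_id)
    telo <- simulate_telomeres(samples)
    list(samples = samples, betas = betas,
         clock = consistent_clock(cpg_models),
         cell_fractions = fr, mixture_betas = mix,
         telomeres = telo, seed = seed)
  })
}

#' Write a ground-truth sidecar for a simulated dataset
#'
#' Serializes generator parameters and per-sample truths as JSON next to a
#' dataset so simulations are auditable and reproducible.
#'
#' @param truth a named list (any JSON-serializable ground truth).
#' @param path output path (`.json`).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth sidecar
#' @param path path written by [write_ground_truth()].
#' @return named list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
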