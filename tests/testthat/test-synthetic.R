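test_that("generate_cohort draws valid, deterministic cohorts", {
  co <- generate_cohort(95, c(18, 74), seed = 7)
  expect_equal(nrow(co), 95)
  expect_true(all(co$age >= 18 & co$age <= 74))
  expect_false(anyDuplicated(co$sample_id) > 0)
  expect_true(all(co$group == "healthy"))

  # degenerate range pins the age exactly
  one <- generate_cohort(1, c(30, 30), seed = 1)
  expect_equal(one$age, 30)

  # byte-identical under the same seed
  expect_identical(generate_cohort(20, seed = 42),
                   generate_cohort(20, seed = 42))
  expect_false(identical(generate_cohort(20, seed = 42),
                         generate_cohort(20, seed = 43)))
})

test_that("generate_cohort validates arguments", {
  expect_error(generate_cohort(0), "n")
  expect_error(generate_cohort(5, c(40, 30)), "age_range")
  expect_error(generate_cohort(5, c(-10, 30)), "age_range")
  expect_error(generate_cohort(5, group_proportions = c(healthy = 0.7)),
               "sum to 1")
  expect_error(generate_cohort(5, group_proportions = c(weird = 1)),
               "labels")
})

test_that("group sampling matches the binomial oracle at 3 sigma", {
  n <- 1000
  co <- generate_cohort(n, group_proportions = c(healthy = 0.5,
                                                 covid_ards = 0.5),
                        seed = 11)
  sd3 <- 3 * sqrt(n * 0.25)
  expect_lt(abs(sum(co$group == "healthy") - n / 2), sd3)
  # direct multinomial sampling lands in the same band
  direct <- withr::with_seed(11, rmultinom(1, n, c(0.5, 0.5)))
  expect_lt(abs(direct[1] - n / 2), sd3)
})

test_that("simulate_betas follows the linear model, clips, and has the
           right noise scale", {
  co <- data.frame(sample_id = "s1", age = 40)
  m <- cpg_age_model("cg1", baseline = 10, slope = 0.5, noise_sd = 0)
  expect_equal(unname(simulate_betas(co, list(m))[1, 1]), 30)

  m2 <- cpg_age_model("cg1", baseline = 99, slope = 1, noise_sd = 0)
  co2 <- data.frame(sample_id = "s1", age = 50)
  expect_equal(unname(simulate_betas(co2, list(m2))[1, 1]), 100)

  # empirical noise sd within the Monte-Carlo sampling band
  co3 <- data.frame(sample_id = sprintf("s%d", 1:500), age = rep(45, 500))
  m3 <- cpg_age_model("cg1", baseline = 30, slope = 0.2, noise_sd = 3)
  b <- simulate_betas(co3, list(m3), seed = 5)
  expect_gt(sd(b[1, ]), 2.6)
  expect_lt(sd(b[1, ]), 3.4)
})

test_that("consistent_clock inverts the generating model", {
  # single CpG, unit slope
  c1 <- consistent_clock(list(cpg_age_model("cg", 0, 1, 0)))
  expect_equal(unname(c1$weights), 1)
  expect_equal(c1$intercept, 0)

  # single CpG algebra: a = 10, b = 0.5 -> weight 2, intercept -20
  c2 <- consistent_clock(list(cpg_age_model("cg", 10, 0.5, 0)))
  expect_equal(unname(c2$weights), 2)
  expect_equal(c2$intercept, -20)
  beta40 <- matrix(10 + 0.5 * 40, 1, 1, dimnames = list("cg", "s"))
  expect_equal(predict_age(beta40, c2)$predicted_age, 40)

  # mixed-sign three-CpG model: noise-free identity to 1e-9
  models <- default_cpg_models()
  models <- lapply(models, function(m) { m$noise_sd <- 0; m })
  co <- withr::with_seed(9, data.frame(
    sample_id = sprintf("s%d", 1:100), age = runif(100, 18, 74)))
  betas <- simulate_betas(co, models)
  pred <- predict_age(betas, consistent_clock(models))
  expect_lt(max(abs(pred$predicted_age - co$age)), 1e-9)

  expect_error(consistent_clock(list(cpg_age_model("cg", 10, 0, 0))),
               "no invertible signal")
})

test_that("simulate_reads honors deterministic chemistry limits", {
  refs <- tiny_refs()
  amp <- refs$FHL2

  # fully methylated, complete conversion, no errors: CpGs read C,
  # every non-CpG cytosine reads T on both strands
  rd <- simulate_reads(amp, 100, coverage = 30, conversion_rate = 1,
                       error_rate = 0, seed = 2)
  chars <- strsplit(amp$sequence, "")[[1]]
  top_reads <- rd$sequence[rd$strand == "original_top"]
  for (s in top_reads) {
    rs <- strsplit(s, "")[[1]]
    expect_true(all(rs[amp$cpg_positions + 1L] == "C"))
    noncpg_c <- setdiff(which(chars == "C"), amp$cpg_positions + 1L)
    expect_true(all(rs[noncpg_c] == "T"))
  }

  # fully unmethylated: no cytosine survives on either strand
  rd0 <- simulate_reads(amp, 0, coverage = 30, conversion_rate = 1,
                        error_rate = 0, seed = 3)
  expect_false(any(grepl("C", rd0$sequence)))

  # zero coverage is an empty read set, not an error
  expect_equal(nrow(simulate_reads(amp, 50, coverage = 0)), 0)

  # determinism
  expect_identical(simulate_reads(amp, 42, 25, seed = 8),
                   simulate_reads(amp, 42, 25, seed = 8))
})

test_that("simulated methylated-read counts match the binomial oracle", {
  refs <- tiny_refs()
  rd <- simulate_reads(refs$PDE4C, 42, coverage = 3000,
                       conversion_rate = 1, error_rate = 0, seed = 13)
  tc <- attr(rd, "truth_counts")
  ci <- qbinom(c(0.005, 0.995), 3000, 0.42)
  expect_true(all(tc$methylated >= ci[1] & tc$methylated <= ci[2]))
})

test_that("cell mixture betas are exact fraction-weighted references", {
  ref <- synthetic_cell_reference()
  pure <- setNames(as.numeric(colnames(ref) == "CD4T"), colnames(ref))
  expect_equal(simulate_cell_mixture_betas(pure, ref, 0),
               ref[, "CD4T"])

  half <- setNames(c(0.5, 0.5, 0, 0, 0, 0), colnames(ref))
  expect_equal(simulate_cell_mixture_betas(half, ref, 0),
               (ref[, "CD4T"] + ref[, "CD8T"]) / 2)

  expect_error(simulate_cell_mixture_betas(c(0.5, 0.5), ref, 0), "length")

  # COVID preset shifts granulocyte-discriminating CpGs toward the
  # granulocyte reference, by direct mixture arithmetic
  hb <- simulate_cell_mixture_betas(healthy_cell_fractions(), ref, 0)
  cb <- simulate_cell_mixture_betas(covid_cell_fractions(), ref, 0)
  gran_cpgs <- c("cg_Gran_1", "cg_Gran_2")
  direct <- drop(ref %*% covid_cell_fractions()[colnames(ref)]) -
    drop(ref %*% healthy_cell_fractions()[colnames(ref)])
  expect_equal(unname((cb - hb)[gran_cpgs]), unname(direct[gran_cpgs]))
  expect_true(all((cb - hb)[gran_cpgs] > 0))
})

test_that("simulate_telomeres follows the attrition line and recovers the
           slope under noise", {
  s <- data.frame(sample_id = "p1", age = 40)
  t1 <- simulate_telomeres(s, intercept_kb = 10, slope_kb_per_year = -0.05,
                           sd_kb = 0, replicate_sd_kb = 0)
  expect_equal(t1$mean_kb, 8.0)

  s0 <- data.frame(sample_id = "p0", age = 0)
  t0 <- simulate_telomeres(s0, intercept_kb = 10, slope_kb_per_year = -0.05,
                           sd_kb = 0, replicate_sd_kb = 0)
  expect_equal(t0$mean_kb, 10)

  # regression oracle: OLS slope of 356 controls within 3 standard errors
  co <- withr::with_seed(21, data.frame(
    sample_id = sprintf("c%d", 1:356), age = runif(356, 18, 80)))
  tl <- simulate_telomeres(co, sd_kb = 0.7, seed = 22)
  fit <- summary(lm(mean_kb ~ age, data = tl))
  expect_lt(abs(fit$coefficients["age", "Estimate"] - (-0.05)),
            3 * fit$coefficients["age", "Std. Error"])
})

test_that("simulate_study ties the generators together with ground truth", {
  st <- simulate_study(n_healthy = 20, n_covid_no_ards = 5,
                       n_covid_ards = 5, seed = 31)
  expect_equal(ncol(st$betas), 30)
  expect_equal(dim(st$cell_fractions), c(30, 6))
  expect_equal(rowSums(st$cell_fractions), setNames(rep(1, 30),
               st$samples$sample_id), tolerance = 1e-9)
  # clock CpGs and deconvolution CpGs are disjoint by construction
  expect_length(intersect(rownames(st$betas), rownames(st$mixture_betas)), 0)
  expect_identical(simulate_study(n_healthy = 20, n_covid_no_ards = 5,
                                  n_covid_ards = 5, seed = 31)$betas,
                   st$betas)
})
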