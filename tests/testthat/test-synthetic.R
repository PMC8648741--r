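test_that("generators are seed-deterministic and honour empty classes", {
  cfg <- sim_config(n_samples = 3, n_elements = 20,
                    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6))
  set.seed(81); a <- simulate_genome_tracks(cfg)
  set.seed(81); b <- simulate_genome_tracks(cfg)
  expect_identical(lapply(a$tracks, as.data.frame),
                   lapply(b$tracks, as.data.frame))
  set.seed(82); ca <- simulate_cohort_breakpoints(cfg, a$genome, a$tracks)
  set.seed(82); cb <- simulate_cohort_breakpoints(cfg, a$genome, a$tracks)
  expect_identical(as.data.frame(ca), as.data.frame(cb))

  cfg0 <- sim_config(n_elements = 0, classes = "X")
  t0 <- simulate_genome_tracks(cfg0)$tracks$X
  expect_equal(nrow(t0), 0)
  expect_error(sim_config(enrichment = c(NOPE = 2)), "unknown")
  expect_error(simulate_genome_tracks(
    sim_config(n_elements = 50000, classes = "X",
               chrom_lengths = c(chr1 = 1e6))), "exceeds")
})

test_that("simulated track mass matches a bitmap union oracle", {
  set.seed(83)
  cfg <- sim_config(classes = "X", n_elements = 30,
                    element_len_meanlog = log(800),
                    chrom_lengths = c(chr1 = 1e6))
  tr <- simulate_genome_tracks(cfg)$tracks$X
  expect_true(is_merged(tr))
  expect_equal(cumulative_length(tr),
               oracle_union_length(list(tr), c(chr1 = 1e6)))
  expect_true(all(tr$end <= 1e6 & tr$start >= 0))
})

test_that("TBPc draws respect bounds, evenness and the log-normal scale", {
  set.seed(84)
  cfg <- sim_config(n_samples = 300, classes = "X", n_elements = 10,
                    chrom_lengths = c(chr1 = 1e7))
  gt <- simulate_genome_tracks(cfg)
  cat <- simulate_cohort_breakpoints(cfg, gt$genome, gt$tracks)
  counts <- tbpc(cat)
  expect_true(all(counts %% 2 == 0))
  expect_true(all(counts >= 26 & counts <= 1200))
  expect_gt(median(counts), 140)      # calibrated to median ~ 181
  expect_lt(median(counts), 230)
  expect_gt(mean(counts), 180)        # mean ~ 222, right-skewed
  expect_lt(mean(counts), 280)
})

test_that("SV pairing hits the configured intra-chromosomal fraction", {
  set.seed(85)
  cfg <- sim_config(n_samples = 20, classes = "X", n_elements = 10,
                    chrom_lengths = setNames(rep(1e6, 8), paste0("c", 1:8)),
                    intra_sv_fraction = 0.674)
  gt <- simulate_genome_tracks(cfg)
  cat <- simulate_cohort_breakpoints(cfg, gt$genome, gt$tracks)
  res <- classify_sv_sides(cat)
  frac <- res["n_bpsv_intra"] / sum(res)
  expect_gt(frac, 0.62)
  expect_lt(frac, 0.73)
  expect_equal(unname(sum(res)), sum(tbpc(cat)))
})

test_that("per-track counts under the null sit in their binomial bands", {
  set.seed(86)
  glen <- 1e7
  cfg <- sim_config(n_samples = 200, classes = "X", n_elements = 40,
                    element_len_meanlog = log(5000),
                    chrom_lengths = c(chr1 = glen),
                    tbpc_meanlog = log(300), tbpc_sdlog = 0)
  gt <- simulate_genome_tracks(cfg)
  cat <- simulate_cohort_breakpoints(cfg, gt$genome, gt$tracks)
  g <- gt$genome
  tr <- gt$tracks$X
  Li <- cumulative_length(tr)
  per_sample <- vapply(split_by_sample(cat), function(cs)
    count_breakpoints_in_track(cs, tr, g), numeric(1))
  counts <- tbpc(cat)[names(per_sample)]
  ## central 99% binomial band per sample
  lo <- qbinom(0.005, counts, Li / glen)
  hi <- qbinom(0.995, counts, Li / glen)
  cover <- mean(per_sample >= lo & per_sample <= hi)
  expect_gte(cover, 0.95)
})

test_that("enrichment factors bend the sampling density as configured", {
  set.seed(87)
  glen <- 1e8
  cfg <- sim_config(n_samples = 50, classes = "X", n_elements = 1,
                    chrom_lengths = c(chr1 = glen),
                    tbpc_meanlog = log(300), tbpc_sdlog = 0,
                    enrichment = c(X = 10))
  gt <- simulate_genome_tracks(cfg)
  ## force a known 5-Mb territory
  gt$tracks$X <- bp_track("chr1", 4e7, 4.5e7, element_class = "X",
                          merged = TRUE)
  cat <- simulate_cohort_breakpoints(cfg, gt$genome, gt$tracks)
  ni <- vapply(split_by_sample(cat), function(cs)
    count_breakpoints_in_track(cs, gt$tracks$X, gt$genome), numeric(1))
  ## density-integration oracle: 10 * 5 / (10 * 5 + 95) of 300 draws
  expected <- 300 * (10 * 5e6) / (10 * 5e6 + 9.5e7)
  expect_gt(mean(ni), expected * 0.9)
  expect_lt(mean(ni), expected * 1.1)

  ## factor 0 empties the territory
  cfg0 <- sim_config(n_samples = 5, classes = "X", n_elements = 5,
                     chrom_lengths = c(chr1 = 1e6), enrichment = c(X = 0))
  gt0 <- simulate_genome_tracks(cfg0)
  cat0 <- simulate_cohort_breakpoints(cfg0, gt0$genome, gt0$tracks)
  expect_equal(count_breakpoints_in_track(cat0, gt0$tracks$X, gt0$genome), 0)
})

test_that("survival simulation produces the lambda shape and obeys censoring", {
  set.seed(88)
  cfg <- sim_config()
  groups <- setNames(factor(rep(c("Low", "Medium", "High"), each = 80)),
                     sprintf("s%03d", 1:240))
  surv <- simulate_survival(groups, cfg)
  med <- group_km_medians(groups, surv)
  med[is.na(med)] <- Inf
  expect_equal(names(which.min(med)), "Medium")
  expect_true(all(surv$time_years <= cfg$max_follow_years))

  cfg_all_cens <- sim_config(censoring_rate = 1)
  surv0 <- simulate_survival(groups, cfg_all_cens)
  expect_true(all(surv0$event == 0))
  expect_error(simulate_survival(setNames("Huh", "s1"), cfg), "hazard")

  set.seed(89); s1 <- simulate_survival(groups, cfg)
  set.seed(89); s2 <- simulate_survival(groups, cfg)
  expect_identical(s1, s2)
})

test_that("the full synthetic pipeline recovers its own planted structure", {
  sim <- simulate_cohort(sim_config(n_samples = 60, seed = 90))
  expect_equal(nrow(sim$indexes), 60)
  fit <- ipart(sim$indexes[, c("sample_id", "itrac")], sim$clinical,
               p_cap = 0.3)
  ## recovered thresholds sit close to the planted ones, on the index scale
  expect_lt(max(abs(coef(fit) - sim$true_thresholds) /
                  pmax(sim$true_thresholds, 1)), 0.35)
  expect_lt(fit$logrank_p, 0.01)
  ## MAGIC High (medium instability) carries the excess risk
  fit_ir <- tryCatch(
    ipart(sim$indexes[, c("sample_id", "iracin")], sim$clinical,
          p_cap = 0.5),
    error = function(e) fit)
  m <- magic(fit, fit_ir)
  mg <- setNames(m$magic_risk, m$sample_id)
  cl <- sim$clinical
  rate <- tapply(cl$event, mg[cl$sample_id], mean)
  expect_gt(rate["High"], rate["Low"])
})
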