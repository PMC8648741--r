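test_that("log-rank p matches the hand-computed chi-square on a 12-record example", {
  time  <- c(1, 2, 3, 4.5, 5, 6, 2.5, 3.5, 7, 8, 9.5, 10)
  event <- c(1, 1, 0, 1,   1, 0, 1,   1,   0, 1, 1,   0)
  group <- rep(c("A", "B", "C"), each = 4)
  ## frozen from the counting-process formulas applied by hand:
  ## chisq = 7.3315287, df = 2
  expect_equal(logrank_p(time, event, group), 0.0255846087, tolerance = 1e-8)
  expect_equal(oracle_logrank(time, event, group)$chisq, 7.3315287,
               tolerance = 1e-6)
})

test_that("log-rank degenerate cases behave", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- c(1, 0, 1, 0, 1, 0, 1, 0)
  group <- rep(c("A", "B"), each = 4)
  expect_equal(logrank_p(time, event, group), 1)   # identical multisets
  expect_warning(p0 <- logrank_p(time, rep(0, 8), group), "no events")
  expect_equal(p0, 1)
  expect_error(logrank_p(time, event, rep("A", 8)), "2 non-empty")
})

test_that("analytic log-rank p agrees with a permutation oracle", {
  set.seed(17)
  time <- c(rexp(20, 0.1), rexp(20, 1.0))
  event <- rbinom(40, 1, 0.9)
  group <- rep(c("lo", "hi"), each = 20)
  p <- logrank_p(time, event, group)
  expect_lt(p, 1e-3)
  p_perm <- oracle_permutation_logrank_p(time, event, group, 2000)
  expect_lt(p_perm, 0.01)   # both routes call it highly significant
})

test_that("the scan's log-rank engine agrees with survdiff across random groupings", {
  set.seed(16)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    time <- round(rexp(n, 0.3), 2)          # rounding forces ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    k <- sample(2:4, 1)
    lab <- factor(sample(letters[1:k], n, replace = TRUE))
    if (nlevels(droplevels(lab)) < 2) next
    lab <- droplevels(lab)
    eng <- gibreak:::.logrank_engine(time, event)
    p_eng <- eng(gibreak:::.group_indicator(lab))
    expect_equal(p_eng, logrank_p(time, event, lab), tolerance = 1e-10)
  }
})

test_that("threshold candidates are midpoints and the scan is order-invariant", {
  vals <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  surv <- data.frame(sample_id = paste0("s", 1:4),
                     time_years = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  sc <- threshold_scan(vals, surv, min_group_size = 1)
  expect_equal(sc$threshold, c(1.5, 2.5, 3.5))
  perm <- sample(4)
  sc2 <- threshold_scan(vals[perm], surv[perm, ], min_group_size = 1)
  expect_equal(sc2, sc)
  expect_error(threshold_scan(vals, surv, min_group_size = 3),
               "min_group_size")
})

test_that("a perfectly separated cohort puts the argmin at the gap", {
  set.seed(18)
  n <- 40
  vals <- setNames(c(runif(20, 0, 1), runif(20, 2, 3)), sprintf("s%02d", 1:n))
  surv <- data.frame(sample_id = names(vals),
                     time_years = c(rexp(20, 2), rexp(20, 0.05)) + 0.01,
                     event = c(rep(1, 20), rbinom(20, 1, 0.3)))
  sc <- threshold_scan(vals, surv, min_group_size = 5)
  best <- sc$threshold[which.min(sc$p)]
  expect_gt(best, 1)
  expect_lt(best, 2)
})

test_that("local minima respect plateaus, boundaries and the cap", {
  mk_scan <- function(p) structure(
    data.frame(threshold = seq_along(p), p = p,
               n_low = seq_along(p), n_high = rev(seq_along(p))),
    class = c("threshold_scan", "data.frame"))
  expect_equal(local_minima(mk_scan(c(0.5, 0.05, 0.2, 0.08, 0.6)), 0.10),
               c(2, 4))
  ## monotone curve: at most one boundary minimum
  expect_equal(local_minima(mk_scan(c(0.02, 0.04, 0.2, 0.5)), 0.10), 1)
  expect_equal(local_minima(mk_scan(c(0.5, 0.2, 0.04)), 0.10), 3)
  ## plateau collapses to its midpoint
  expect_equal(local_minima(mk_scan(c(0.5, 0.03, 0.03, 0.03, 0.4)), 0.10), 3)
  ## cap filters
  expect_equal(local_minima(mk_scan(c(0.5, 0.2, 0.5)), 0.10), numeric(0))
  ## W shape against an exhaustive neighbour scan
  set.seed(19)
  p <- c(0.4, 0.01, 0.3, 0.05, 0.35, 0.02, 0.5)
  naive <- which(vapply(seq_along(p), function(i) {
    left <- if (i == 1) Inf else p[i - 1]
    right <- if (i == length(p)) Inf else p[i + 1]
    p[i] < left && p[i] < right && p[i] < 0.10
  }, logical(1)))
  expect_equal(local_minima(mk_scan(p), 0.10), as.numeric(naive))
})

test_that("k = 2 best partition equals the scan argmin", {
  set.seed(20)
  sim <- simulate_index_cohort(n = 80, thresholds = 1.5,
                               config = sim_config(
                                 hazards = c(Low = 0.05, High = 0.6)))
  sc <- threshold_scan(sim$values, sim$survival)
  fit <- ipart(sim$values, sim$survival, k = 2)
  expect_equal(coef(fit), sc$threshold[which.min(sc$p)])
  expect_equal(fit$logrank_p, min(sc$p))
})

test_that("the reported p is self-consistent with the returned labels", {
  set.seed(22)
  sim <- simulate_index_cohort(n = 100)
  fit <- ipart(sim$values, sim$survival)
  df <- fit$data
  expect_equal(fit$logrank_p,
               logrank_p(df$time, df$event, fit$labels[df$sample_id]))
  expect_equal(as.vector(table(fit$labels)), as.vector(fit$group_sizes))
})

test_that("labels are a monotone step function and rescale with the values", {
  set.seed(23)
  sim <- simulate_index_cohort(n = 100)
  fit <- ipart(sim$values, sim$survival)
  v <- sort(sim$values)
  lab <- as.integer(predict(fit, v))
  expect_true(all(diff(lab) >= 0))
  ## affine positive rescaling: thresholds rescale, labels unchanged
  fit2 <- ipart(2 * sim$values + 10, sim$survival)
  expect_equal(coef(fit2), 2 * coef(fit) + 10, tolerance = 1e-9)
  expect_equal(as.character(fit2$labels), as.character(fit$labels))
})

test_that("planted three-group cohorts are recovered with the lambda shape", {
  set.seed(24)
  ok <- logical(10)
  for (i in 1:10) {
    sim <- simulate_index_cohort(n = 200, thresholds = c(1, 2))
    fit <- ipart(sim$values, sim$survival)
    ok[i] <- all(abs(coef(fit) - c(1, 2)) <= 0.15) &&
      fit$logrank_p < 1e-4
    med <- group_km_medians(fit$labels, sim$survival)
    med[is.na(med)] <- Inf
    expect_equal(names(which.min(med)), "Medium")
    expect_gt(mean(predict(fit, sim$values) == sim$groups), 0.9)
  }
  ## recovery within +/- 0.15 is a distributional property, not a per-draw one
  expect_gte(sum(ok), 9)
})

test_that("hazard ratios are consistent and sane", {
  set.seed(25)
  ## identical groups: HR ~ 1, CI covers 1
  surv <- data.frame(sample_id = sprintf("s%03d", 1:200),
                     time_years = rexp(200, 0.3), event = rbinom(200, 1, 0.8))
  lab <- setNames(factor(rep(c("A", "B"), 100)), surv$sample_id)
  hr <- hazard_ratios(lab, surv)
  expect_lt(hr$ci_low, 1)
  expect_gt(hr$ci_high, 1)
  ## true HR 3 at n = 500 lands near 3
  n <- 500
  g <- rep(c("ref", "risk"), each = n / 2)
  time <- c(rexp(n / 2, 0.1), rexp(n / 2, 0.3))
  cens <- runif(n, 0, 15)
  surv2 <- data.frame(sample_id = sprintf("t%03d", 1:n),
                      time_years = pmin(time, cens),
                      event = as.numeric(time <= cens))
  hr2 <- hazard_ratios(setNames(factor(g), surv2$sample_id), surv2)
  expect_gt(hr2$hr, 2.4)
  expect_lt(hr2$hr, 3.75)
  expect_equal(attr(hr2, "reference"), "ref")
})

test_that("scanning k reports one row per group count", {
  set.seed(26)
  sim <- simulate_index_cohort(n = 150)
  ks <- ipart_scan_k(sim$values, sim$survival, k_max = 4, p_cap = 0.3)
  expect_equal(ks$k, 2:4)
  expect_true(all(ks$logrank_p[ks$feasible] <= 1))
  fits <- attr(ks, "fits")
  expect_s3_class(fits[[2]], "ipart")
})

test_that("the permutation p is honest about the search bias", {
  set.seed(27)
  ## null cohort: values carry no survival information
  n <- 60
  vals <- setNames(runif(n), sprintf("s%02d", 1:n))
  surv <- data.frame(sample_id = names(vals), time_years = rexp(n, 0.2),
                     event = rbinom(n, 1, 0.8))
  fit <- ipart(vals, surv, k = 2)
  pp <- ipart_permutation_p(fit, n_perm = 60)
  ## the scan-minimized p is far smaller than its permutation calibration
  expect_gt(pp$p_perm, pp$p_observed)
})

test_that("LOOCV is deterministic and stable under strong separation", {
  set.seed(28)
  sim <- simulate_index_cohort(n = 60, thresholds = c(1, 2))
  ## widen the gaps so every fold finds the same frontier
  v <- sim$values
  v[sim$groups == "Low"] <- v[sim$groups == "Low"] * 0.3
  v[sim$groups == "High"] <- v[sim$groups == "High"] + 2
  cv1 <- ipart_loocv(v, sim$survival, p_cap = 0.5)
  cv2 <- ipart_loocv(v, sim$survival, p_cap = 0.5)
  expect_identical(cv1, cv2)
  expect_gt(attr(cv1, "agreement"), 0.9)
})

test_that("ipart methods print, predict and plot", {
  set.seed(29)
  sim <- simulate_index_cohort(n = 80)
  fit <- ipart(sim$values, sim$survival)
  expect_output(print(fit), "iPART partition")
  expect_output(print(summary(fit)), "Hazard ratios")
  expect_equal(length(predict(fit)), 80)
  expect_equal(as.character(predict(fit, c(-1, 99))), c("Low", "High"))
  tmp <- tempfile(fileext = ".pdf")
  pdf(tmp); plot(fit); dev.off()
  expect_true(file.exists(tmp))
})
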