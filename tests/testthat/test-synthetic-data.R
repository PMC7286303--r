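# Synthetic-data generators: determinism, design invariants, planted
# effects, and the exchangeability/power properties the downstream
# analysis relies on.

test_that("atlas has the requested composition and is deterministic", {
  atl <- generate_atlas(76, 54, seed = 1)
  expect_equal(nrow(atl), 76)
  expect_equal(sum(atl$is_gray_matter), 54)
  expect_equal(atl$region_id, 1:76)
  expect_true(all(atl$volume > 0))
  expect_setequal(unique(atl$hemisphere), c("left", "right", "midline"))
  expect_identical(atl, generate_atlas(76, 54, seed = 1))
  expect_false(identical(atl$volume, generate_atlas(76, 54, seed = 2)$volume))

  one <- generate_atlas(1, 1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_error(generate_atlas(5, 6, seed = 1), "n_gm")
})

test_that("cohort honors dropout, increasing ages, and both groups", {
  full <- generate_cohort(9, c(6, 9, 12, 15, 18), 0, seed = 1)
  expect_equal(nrow(full), 18 * 5)
  expect_equal(sort(unique(full$group)), c("control", "tg"))

  drp <- generate_cohort(9, c(6, 9, 12, 15, 18), 0.25, seed = 2)
  n_tp <- table(drp$timepoint_index)
  expect_equal(unname(n_tp["1"]), 18)          # everyone observed at tp 1
  expect_true(all(n_tp[-1] <= 18))
  expect_lt(sum(n_tp[-1]), 4 * 18)             # some dropout realized
  for (s in split(drp, drp$subject_id))
    expect_true(all(diff(s$age[order(s$timepoint_index)]) > 0))

  expect_error(generate_cohort(9, numeric(0), 0, 1), "non-empty")
  expect_error(generate_cohort(9, c(9, 6), 0, 1), "increasing")
  expect_error(generate_cohort(9, c(6, 9), 1, 1), "dropout")
})

test_that("streamline tables are byte-identical under a fixed seed", {
  atl <- generate_atlas(12, 8, seed = 3)
  obs <- list(subject_id = "tg01", group = "tg", timepoint_index = 2,
              age = 9.1)
  s1 <- generate_streamline_table(atl, obs, effect_spec(), seed = 7)
  s2 <- generate_streamline_table(atl, obs, effect_spec(), seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_streamline_table(atl, obs, effect_spec(), seed = 8)
  expect_false(identical(s1, s3))
  expect_true(all(s1$length_mm > 0))
  expect_true(all(s1$mean_fa > 0 & s1$mean_fa < 1))
})

test_that("a planted FA group deficit shifts the mean edge FA by its size", {
  atl <- generate_atlas(10, 6, seed = 4)
  spec <- effect_spec(fa_group = -0.05,
                      total_streamlines = 400)
  mean_fa <- function(group, seeds) {
    vapply(seeds, function(sd) {
      obs <- list(subject_id = sprintf("%s%03d", group, sd), group = group,
                  timepoint_index = 1, age = 12)
      mean(generate_streamline_table(atl, obs, spec, seed = sd)$mean_fa)
    }, numeric(1))
  }
  diff_fa <- mean(mean_fa("control", 1:100)) - mean(mean_fa("tg", 1:100))
  expect_lt(abs(diff_fa - 0.05), 0.012)
})

test_that("expected binary density hits the target at the default scale", {
  atl <- generate_atlas(76, 54, seed = 5)
  dens <- vapply(1:5, function(sd) {
    obs <- list(subject_id = sprintf("c%02d", sd), group = "control",
                timepoint_index = 1, age = 12)
    st <- generate_streamline_table(atl, obs, effect_spec(), seed = sd)
    connectome_density(build_structural(st, atl)$struct_binary)
  }, numeric(1))
  expect_lt(abs(mean(dens) / 100 - 0.62), 0.05)
})

test_that("mean edge FA is linear in age with the specified slope", {
  atl <- generate_atlas(10, 6, seed = 6)
  spec <- effect_spec(fa_age = 0.004, total_streamlines = 400)
  ages <- rep(c(6, 9, 12, 15, 18), each = 24)
  y <- vapply(seq_along(ages), function(i) {
    obs <- list(subject_id = sprintf("s%03d", i), group = "control",
                timepoint_index = 1, age = ages[i])
    mean(generate_streamline_table(atl, obs, spec, seed = 1000 + i)$mean_fa)
  }, numeric(1))
  fit <- summary(lm(y ~ ages))
  slope <- fit$coefficients["ages", "Estimate"]
  se <- fit$coefficients["ages", "Std. Error"]
  expect_lt(abs(slope - 0.004), 2 * se)
})

test_that("null generator keeps the downstream type-I error at its level", {
  atl <- generate_atlas(8, 5, seed = 7)
  spec <- effect_spec(total_streamlines = 250)
  p <- vapply(1:500, function(rep) {
    vals <- vapply(1:10, function(k) {
      grp <- if (k <= 5) "control" else "tg"
      obs <- list(subject_id = sprintf("r%db%d", rep, k), group = grp,
                  timepoint_index = 1, age = 12)
      st <- generate_streamline_table(atl, obs, spec,
                                      seed = rep * 1000 + k)
      cs <- build_structural(st, atl)
      nodal_degree_strength(cs$fa_w)$network_strength
    }, numeric(1))
    kruskal_wallis(vals[1:5], vals[6:10])$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  # binomial 95% band around 0.05 over 500 replicates (KW at n = 5 + 5 is
  # discrete, so the achievable level sits just below 0.05)
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 500))
  expect_gt(rate, 0.05 - 2.5 * sqrt(0.05 * 0.95 / 500))
})

test_that("detection power rises monotonically with the group effect", {
  atl <- generate_atlas(8, 5, seed = 8)
  power_at <- function(eff) {
    spec <- effect_spec(fa_group = -eff, total_streamlines = 250)
    hits <- vapply(1:200, function(rep) {
      vals <- vapply(1:10, function(k) {
        grp <- if (k <= 5) "control" else "tg"
        obs <- list(subject_id = sprintf("p%dq%d", rep, k), group = grp,
                    timepoint_index = 1, age = 12)
        mean(generate_streamline_table(atl, obs, spec,
                                       seed = rep * 2000 + k)$mean_fa)
      }, numeric(1))
      kruskal_wallis(vals[1:5], vals[6:10])$p_value < 0.05
    }, logical(1))
    mean(hits)
  }
  pw <- c(power_at(0), power_at(0.02), power_at(0.05))
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[3], 0.8)
})

test_that("time series honor the precision structure and the band", {
  atl <- generate_atlas(16, 10, seed = 9)
  obs <- list(subject_id = "s1", group = "control", timepoint_index = 1,
              age = 12)
  spec0 <- effect_spec(func_background_pcor = 0, nuisance_sd = 0)
  sim <- generate_timeseries(atl, obs, spec0, n_volumes = 400, seed = 10)
  expect_equal(dim(sim$ts), c(10, 400))
  expect_equal(colnames(sim$nuisance),
               c(paste0("motion", 1:6), "wm_mean", "csf_mean"))
  # determinism
  sim2 <- generate_timeseries(atl, obs, spec0, n_volumes = 400, seed = 10)
  expect_identical(sim$ts, sim2$ts)

  # identity precision: estimated partial correlations stay small
  S <- cov(t(sim$ts))
  P <- solve(S)
  R <- -P / tcrossprod(sqrt(diag(P))); diag(R) <- 0
  expect_lt(max(abs(R)), 0.3)

  # spectral mass concentrated in the passband
  v <- sim$ts[1, ]
  spec_pow <- Mod(fft(v))^2
  freq <- (seq_along(v) - 1) / (length(v) * 2)   # tr = 2 s
  half <- freq <= 0.25
  inband <- freq >= 0.008 & freq <= 0.12
  expect_gt(sum(spec_pow[half & inband]), 0.9 * sum(spec_pow[half]))

  expect_error(generate_timeseries(atl, obs, spec0, n_volumes = 10,
                                   seed = 1), "n_volumes")
  # a large uniform *positive* partial correlation cannot come from any
  # positive-definite precision at 10 regions
  bad <- effect_spec(func_background_pcor = 0.3)
  expect_error(generate_timeseries(atl, obs, bad, n_volumes = 400,
                                   seed = 1), "positive definite")
})

test_that("a planted partial correlation is recovered from generated series", {
  atl <- generate_atlas(16, 12, seed = 11)
  spec <- effect_spec(func_background_pcor = 0,
                      func_planted_pairs = cbind(3, 7),
                      func_planted_pcor = 0.3)
  est <- vapply(1:50, function(rep) {
    obs <- list(subject_id = sprintf("s%03d", rep), group = "control",
                timepoint_index = 1, age = 12)
    sim <- generate_timeseries(atl, obs, spec, n_volumes = 600, seed = rep)
    proc <- preprocess_timeseries(sim$ts, sim$nuisance, tr = sim$tr)
    fc <- build_functional(proc)
    tanh(fc$func_w$weights[3, 7])
  }, numeric(1))
  expect_equal(mean(est), 0.3, tolerance = 0.1)
})

test_that("behavior generator respects the linear model and its bounds", {
  m <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                  group = rep(c("control", "tg"), each = 2),
                  timepoint_index = rep(1:2, 2),
                  value = c(1, 1.2, 0.8, 1.1))
  # constant model: betas (45, 0, 0, 0), no noise
  b <- generate_behavior(m, betas_trials = c(45, 0, 0, 0),
                         subject_sd = 0, noise_sd = 0, seed = 1)
  expect_true(all(b$trials == 45))
  expect_s3_class(b, "behavior_table")

  # ceiling: a huge intercept saturates at 90 trials / 100 percent
  b2 <- generate_behavior(m, betas_trials = c(500, 0, 0, 0),
                          betas_pct = c(500, 0, 0, 0),
                          subject_sd = 0, noise_sd = 30, seed = 2)
  expect_true(all(b2$trials <= 90 & b2$trials >= 0))
  expect_true(all(b2$pct_correct <= 100 & b2$pct_correct >= 0))

  # determinism + duplicate rejection
  expect_identical(generate_behavior(m, seed = 3),
                   generate_behavior(m, seed = 3))
  expect_error(generate_behavior(rbind(m, m[1, ]), seed = 1),
               "one value per")
})
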