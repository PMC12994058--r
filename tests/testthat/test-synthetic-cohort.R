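test_that("an all-empty cohort gives a table with headers only", {
  arch <- default_archetypes(c(NoFS = 0, Res = 0, Frz = 0, Esc = 0))
  tab <- simulate_cohort(cohort_config(arch, seed = 1))
  expect_equal(nrow(tab), 0L)
  expect_identical(names(tab), c("animal_id", "group", "test", "day",
                                 "variable", "value"))
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- cohort_config(seed = 77)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  arch <- default_archetypes()[[3]]
  h1 <- simulate_hypnogram(arch, "baseline", seed = 5, hours = 2)
  h2 <- simulate_hypnogram(arch, "baseline", seed = 5, hours = 2)
  expect_identical(h1$states, h2$states)
  expect_identical(simulate_epoch_features(h1, seed = 8),
                   simulate_epoch_features(h2, seed = 8))
  sp <- simulate_spot_field(10, 128, 128, seed = 3)
  expect_identical(simulate_cfos_image(128, 128, sp, seed = 4),
                   simulate_cfos_image(128, 128, sp, seed = 4))
})

test_that("cohort sample means agree with the configured distributions", {
  arch <- default_archetypes(c(NoFS = 200, Res = 200, Frz = 200, Esc = 200))
  tab <- simulate_cohort(cohort_config(arch, seed = 12))
  # independent expected means: numerical integration (truncated normal),
  # closed forms (log-normal mean, zero-inflated shifted Poisson)
  exp_mean <- function(p) {
    switch(p$family,
      truncnorm = {
        z <- integrate(function(x) dnorm(x, p$location, p$scale), 0, 100)$value
        integrate(function(x) x * dnorm(x, p$location, p$scale),
                  0, 100)$value / z
      },
      lognormal = p$location * exp(p$scale^2 / 2),
      zero_pois = (1 - p$p_zero) * (1 + p$lambda))
  }
  exp_var_bound <- function(p)      # crude SE via the sample itself
    NULL
  for (spec in arch) {
    for (v in c("nc_freezing", "epm_open_time", "epm_open_velocity",
                "startle_lat_ratio", "escape_attempts")) {
      x <- tab$value[tab$group == spec$name & tab$variable == v]
      mu <- exp_mean(spec$behavior[[v]])
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - mu), 3 * max(se, 1e-8),
                label = paste(spec$name, v, "mean deviation"))
    }
  }
})

test_that("percentages stay in [0,100] and escape counts are non-negative
           integers", {
  tab <- simulate_cohort(cohort_config(seed = 19))
  reg <- default_variable_registry()
  pct_vars <- c("nc_freezing", "nc_escaping", "no_freezing", "no_escaping",
                "epm_open_time", "cue_freezing", "cue_escaping",
                "ctx_freezing", "of_center_time")
  v <- tab$value[tab$variable %in% pct_vars]
  expect_true(all(v >= 0 & v <= 100))
  k <- tab$value[tab$variable == "escape_attempts"]
  expect_true(all(k >= 0 & k == round(k)))
})

test_that("per-group sample medians fall inside the central 95% interval of
           their configured distribution", {
  arch <- default_archetypes(c(NoFS = 100, Res = 100, Frz = 100, Esc = 100))
  tab <- simulate_cohort(cohort_config(arch, seed = 21))
  q_interval <- function(p) {
    switch(p$family,
      truncnorm = {
        lo <- pnorm(0, p$location, p$scale)
        hi <- pnorm(100, p$location, p$scale)
        qnorm(lo + c(0.025, 0.975) * (hi - lo), p$location, p$scale)
      },
      lognormal = exp(log(p$location) + qnorm(c(0.025, 0.975)) * p$scale),
      zero_pois = c(0, 1 + qpois(0.975, p$lambda)))
  }
  for (spec in arch) for (v in names(spec$behavior)) {
    x <- tab$value[tab$group == spec$name & tab$variable == v]
    ci <- q_interval(spec$behavior[[v]])
    expect_gte(median(x), ci[1])
    expect_lte(median(x), ci[2])
  }
})

test_that("hypnogram generation respects the sleep-stage grammar", {
  states <- c("WAKE", "SWS", "REM")
  absorbing <- matrix(c(1, 0, 0, 0.01, 0.98, 0.01, 0.05, 0.01, 0.94),
                      3, 3, byrow = TRUE, dimnames = list(states, states))
  h <- simulate_hypnogram(absorbing, seed = 1, hours = 1)
  expect_true(all(h$states == "WAKE"))
  bad <- absorbing
  bad["WAKE", ] <- c(0.9, 0.05, 0.05)
  expect_error(simulate_hypnogram(bad, seed = 1), "WAKE -> REM")
  # REM never directly follows WAKE in simulated data
  h2 <- simulate_hypnogram(default_archetypes()[[1]], "baseline",
                           seed = 2, hours = 24)
  i <- which(h2$states == "REM")
  i <- i[i > 1]
  expect_false(any(h2$states[i - 1] == "WAKE"))
})

test_that("long-run state fractions approach the stationary distribution", {
  P <- default_archetypes()[[1]]$sleep$baseline
  # independent oracle: stationary distribution by repeated squaring
  Pk <- P
  for (i in 1:14) Pk <- Pk %*% Pk      # P^(2^14)
  pow <- Pk[1, ]
  eig <- stationary_distribution(P)
  expect_equal(unname(eig), unname(pow), tolerance = 1e-9)
  h <- simulate_hypnogram(P, seed = 6, hours = 240)  # 10 simulated days
  emp <- table(factor(h$states, colnames(P))) / length(h$states)
  expect_lt(max(abs(emp - eig)), 0.02)
})

test_that("epoch features follow their state-conditional distributions", {
  # noise-free limit: features equal the state means exactly
  h <- hypnogram(c("WAKE", "SWS", "REM"))
  f0 <- simulate_epoch_features(h, default_feature_params(0), seed = 1)
  m <- default_feature_params(0)$means
  expect_equal(f0$emg, unname(m[h$states, "emg"]))
  expect_equal(f0$theta, unname(m[h$states, "theta"]))
  # single-state recording: the EMG sample mean matches the wake level
  hw <- hypnogram(rep("WAKE", 17280))
  fw <- simulate_epoch_features(hw, seed = 2)
  mu <- 10 * exp(0.3^2 / 2)            # log-normal mean
  se <- sd(fw$emg) / sqrt(nrow(fw))
  expect_lt(abs(mean(fw$emg) - mu), 3 * se)
  expect_error(default_feature_params(-1), ">= 0")
})

test_that("image synthesis validates its inputs", {
  sp <- data.frame(x = 200, y = 10, radius = 3, cfos = TRUE)
  expect_error(simulate_cfos_image(128, 128, sp), "bounds")
  sp2 <- data.frame(x = 10, y = 10, radius = 3, cfos = TRUE)
  expect_error(simulate_cfos_image(128, 128, sp2, noise_sd = -1), ">= 0")
  blank <- simulate_cfos_image(64, 64, sp2[0, ], noise_sd = 0)
  expect_true(all(blank$image[, , 1] == 0.1))  # background only
})

test_that("behavior table round-trips through delimited text", {
  tab <- simulate_cohort(cohort_config(seed = 30))
  p <- tempfile(fileext = ".tsv")
  write_behavior_table(tab, p)
  back <- read_behavior_table(p)
  expect_equal(back$value, tab$value, tolerance = 1e-9)
  expect_identical(back$animal_id, tab$animal_id)
  unlink(p)
})
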