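test_that("episodes are maximal runs in temporal order", {
  h <- hypnogram(c("WAKE", "WAKE", "SWS", "SWS", "SWS", "WAKE"))
  ep <- episodes(h, "SWS")
  expect_equal(ep$start_epoch, 3L)
  expect_equal(ep$length_epochs, 3L)
  expect_equal(nrow(episodes(hypnogram(rep("WAKE", 20)), "REM")), 0L)
})

test_that("episodes match a linear-scan run-length oracle", {
  set.seed(41)
  for (i in 1:60) {
    st <- sample(c("WAKE", "SWS", "REM"), 120, replace = TRUE)
    h <- hypnogram(st)
    for (s in c("WAKE", "SWS", "REM"))
      expect_equal(episodes(h, s), oracle_episodes(st, s))
  }
})

test_that("optional gap merging bridges brief interruptions only", {
  st <- c("SWS", "SWS", "WAKE", "SWS", "WAKE", "WAKE", "WAKE", "SWS")
  h <- hypnogram(st)
  expect_equal(nrow(episodes(h, "SWS")), 3L)            # default: off
  m <- episodes(h, "SWS", merge_gap_epochs = 1L)
  expect_equal(m$start_epoch, c(1L, 8L))                # 1-epoch gap bridged
  expect_equal(m$length_epochs[1], 4L)
})

test_that("state percentages tally epochs and sum to exactly 100", {
  h <- hypnogram(rep(c("WAKE", "SWS", "REM"), each = 40))
  expect_equal(percent_time(h, "WAKE"), 100 / 3)
  expect_equal(percent_time(hypnogram(rep("SWS", 7)), "SWS"), 100)
  expect_error(percent_time(hypnogram(character(0)), "SWS"), "empty")
  set.seed(43)
  for (i in 1:40) {
    st <- sample(c("WAKE", "SWS", "REM"), sample(10:300, 1), replace = TRUE)
    h <- hypnogram(st)
    pts <- sapply(c("WAKE", "SWS", "REM"), percent_time, hyp = h)
    expect_equal(sum(pts), 100, tolerance = 1e-12)
    expect_equal(unname(pts["REM"]), 100 * sum(st == "REM") / length(st))
  }
})

test_that("sleep onset latency requires a 25-second episode", {
  h <- hypnogram(c(rep("WAKE", 12), rep("SWS", 6)))
  expect_equal(sleep_onset_latency(h, "SWS"), 1.0)      # minutes
  h2 <- hypnogram(c(rep("WAKE", 3), rep("SWS", 4), rep("WAKE", 20)))
  expect_true(is.na(sleep_onset_latency(h2, "SWS")))    # 20 s < 25 s
  expect_error(sleep_onset_latency(h, "SWS", min_seconds = 13), "multiple")
})

test_that("latency matches the scan oracle and shifts exactly under
           prepended wake", {
  set.seed(47)
  for (i in 1:60) {
    st <- sample(c("WAKE", "SWS", "REM"), 200, replace = TRUE,
                 prob = c(0.5, 0.4, 0.1))
    h <- hypnogram(st)
    for (s in c("SWS", "REM"))
      expect_equal(sleep_onset_latency(h, s),
                   oracle_latency(st, 5, s, 5L))
    pre <- hypnogram(c(rep("WAKE", 24), st))     # +2 minutes of wake
    for (s in c("SWS", "REM")) {
      l0 <- sleep_onset_latency(h, s)
      l1 <- sleep_onset_latency(pre, s)
      if (is.na(l0)) expect_true(is.na(l1) ||
                                   l1 >= 0)     # new runs cannot pre-date
      else expect_equal(l1, l0 + 2)
    }
  }
})

test_that("metrics conserve time: episodes x mean duration equals total
           state time and percentages sum to 100", {
  set.seed(53)
  for (i in 1:25) {
    st <- sample(c("WAKE", "SWS", "REM"), 500, replace = TRUE)
    m <- sleep_metrics(hypnogram(st))
    expect_equal(sum(m$percent_time), 100, tolerance = 1e-12)
    for (k in seq_len(nrow(m))) {
      tot <- 5 * sum(st == m$state[k])
      if (m$episode_count[k] > 0)
        expect_equal(m$episode_count[k] * m$mean_episode_duration_s[k],
                     tot, tolerance = 1e-12)
      else expect_true(is.na(m$mean_episode_duration_s[k]))
    }
  }
})

test_that("hypnogram files round-trip with their header metadata", {
  h <- simulate_hypnogram(default_archetypes()[[2]], "d14", seed = 3,
                          hours = 0.5)
  p <- tempfile(fileext = ".tsv")
  write_hypnogram(h, p)
  back <- read_hypnogram(p)
  expect_identical(back$states, h$states)
  expect_equal(back$epoch_seconds, 5)
  expect_equal(back$origin, "cue_exposure")
  unlink(p)
})

test_that("the rule-based classifier follows the spectral signatures", {
  f <- data.frame(emg = c(10, 0.8, 0.4), delta = c(1, 8, 1.5),
                  theta = c(1.5, 2, 7))
  got <- classify_epochs(f)
  expect_identical(got$states, c("WAKE", "SWS", "REM"))
  expect_error(classify_epochs(f[, c("emg", "delta")]), "missing feature")
})

test_that("the classifier recovers at least 95% of ground-truth epochs on a
           well-separated recording", {
  h <- simulate_hypnogram(default_archetypes()[[1]], "baseline",
                          seed = 9, hours = 24)
  f <- simulate_epoch_features(h, seed = 10)
  pred <- classify_epochs(f)
  agree <- mean(pred$states == h$states)
  expect_gte(agree, 0.95)
  # metrics on classified states approach metrics on true states
  expect_lt(abs(percent_time(pred, "REM") - percent_time(h, "REM")), 2)
})

test_that("sleep radar scores are zero at the control medians and cap at 6", {
  mk <- function(id, pct, epi, dur, lat)
    data.frame(animal_id = id, state = "REM", percent_time = pct,
               episode_count = epi, mean_episode_duration_s = dur,
               onset_latency_min = lat)
  ctrl <- do.call(rbind, lapply(1:8, function(i)
    mk(paste0("c", i), 6 + i / 2, 100 + 2 * i, 80 + i, 20 + i)))
  med <- apply(ctrl[, 3:6], 2, median)
  probe <- mk("probe", med[1], med[2], med[3], med[4])
  sc <- sleep_radar_scores(rbind(ctrl, probe), paste0("c", 1:8),
                           states = "REM")
  pr <- sc[sc$animal_id == "probe", ]
  expect_equal(pr$entry, 0L)
  expect_equal(pr$continuity, 0L)
  # an animal far on the adverse side of every variable scores 3 + 3
  worst <- mk("worst", 0, 0, 1, NA)    # never entered REM at all
  sc2 <- sleep_radar_scores(rbind(ctrl, worst), paste0("c", 1:8),
                            states = "REM")
  wr <- sc2[sc2$animal_id == "worst", ]
  expect_equal(wr$entry, 6L)
  expect_equal(wr$continuity, 6L)
  expect_error(sleep_radar_scores(rbind(ctrl[1:3, ], probe),
                                  paste0("c", 1:3), states = "REM"),
               "undersampled")
})

test_that("sleep radar component scores replay through the generic
           bidirectional scorer", {
  set.seed(59)
  ids <- sprintf("a%02d", 1:24)
  met <- data.frame(animal_id = ids, state = "SWS",
                    percent_time = runif(24, 20, 60),
                    episode_count = rpois(24, 150),
                    mean_episode_duration_s = runif(24, 60, 240),
                    onset_latency_min = runif(24, 0, 40))
  ctrl_ids <- ids[1:10]
  sc <- sleep_radar_scores(met, ctrl_ids, states = "SWS")
  ctrl <- met[met$animal_id %in% ctrl_ids, ]
  ts_pct <- build_thresholds(make_registry_row("BIDIRECTIONAL",
                                               "lower_is_worse"),
                             ctrl$percent_time)
  expect_identical(sc$percent_score, assign_score(met$percent_time, ts_pct))
  ts_lat <- build_thresholds(make_registry_row("BIDIRECTIONAL",
                                               "higher_is_worse"),
                             ctrl$onset_latency_min)
  expect_identical(sc$latency_score,
                   assign_score(met$onset_latency_min, ts_lat))
  expect_identical(sc$entry, sc$latency_score + sc$episode_score)
})
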