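#' Hypnogram container
#'
#' A vigilance-state sequence in fixed-length epochs with a recorded time
#' origin. Baseline recordings start at lights-on; day-14 recordings start
#' at the cue-reminder exposure (the cue is placed at lights-on, so both
#' origins coincide with the start of the file).
#'
#' @param states character vector over `WAKE`, `SWS`, `REM`.
#' @param epoch_seconds epoch length in seconds (default 5).
#' @param origin `"lights_on"` or `"cue_exposure"`.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(states, epoch_seconds = 5,
                      origin = c("lights_on", "cue_exposure")) {
  origin <- match.arg(origin)
  states <- as.character(states)
  if (length(states) && !all(states %in% c("WAKE", "SWS", "REM")))
    stop("hypnogram(): states must be WAKE, SWS or REM")
  if (epoch_seconds <= 0) stop("hypnogram(): epoch_seconds must be > 0")
  structure(list(states = states, epoch_seconds = epoch_seconds,
                 origin = origin),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs (%.2f h), origin=%s\n",
              length(x$states), x$epoch_seconds,
              length(x$states) * x$epoch_seconds / 3600, x$origin))
  tab <- table(factor(x$states, c("WAKE", "SWS", "REM")))
  print(round(100 * tab / max(1L, length(x$states)), 2))
  invisible(x)
}

#' Read/write hypnogram files
#'
#' Tab-delimited text with columns `epoch_index`, `state`; header comment
#' lines record `epoch_seconds` and `origin`.
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @return `read_hypnogram` returns a [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# epoch_seconds: %g", hyp$epoch_seconds),
               sprintf("# origin: %s", hyp$origin),
               "epoch_index\tstate"), con)
  if (length(hyp$states))
    writeLines(paste(seq_along(hyp$states), hyp$states, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m)) trimws(sub(".*:", "", m[1])) else default
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  hypnogram(df$state[order(df$epoch_index)],
            epoch_seconds = as.numeric(get("epoch_seconds", "5")),
            origin = get("origin", "lights_on"))
}

#' State episodes
#'
#' Maximal runs of one state, in temporal order. An episode is a maximal
#' run of identical epochs; no smoothing is applied unless `merge_gap_epochs`
#' is set, in which case interruptions of at most that many epochs are
#' bridged before extracting runs.
#'
#' @param hyp a [hypnogram()].
#' @param state one of `WAKE`, `SWS`, `REM`.
#' @param merge_gap_epochs bridge interruptions up to this many epochs
#'   (default 0 = off).
#' @return data.frame with `start_epoch` (1-based) and `length_epochs`.
#' @export
episodes <- function(hyp, state, merge_gap_epochs = 0L) {
  stopifnot(inherits(hyp, "hypnogram"))
  flag <- hyp$states == state
  if (merge_gap_epochs > 0L && any(flag)) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    inner <- which(!r$values & r$lengths <= merge_gap_epochs &
                     seq_along(r$values) > 1L &
                     seq_along(r$values) < length(r$values))
    for (k in inner) flag[(ends[k] - r$lengths[k] + 1L):ends[k]] <- TRUE
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  keep <- which(r$values)
  data.frame(start_epoch = ends[keep] - r$lengths[keep] + 1L,
             length_epochs = r$lengths[keep])
}

#' Percentage of recording time in a state
#'
#' @param hyp a [hypnogram()].
#' @param state one of `WAKE`, `SWS`, `REM`.
#' @return percentage of epochs in `state` (0-100).
#' @export
percent_time <- function(hyp, state) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(hyp$states)
  if (n == 0L) stop("percent_time(): empty hypnogram")
  100 * sum(hyp$states == state) / n
}

#' Sleep onset latency
#'
#' Start time, in minutes from the recording origin, of the first maximal
#' episode of the state lasting at least `min_seconds` (default 25 s = 5
#' epochs of 5 s). Returns `NA` when no qualifying episode exists.
#'
#' @param hyp a [hypnogram()].
#' @param state one of `WAKE`, `SWS`, `REM`.
#' @param min_seconds minimum episode duration; must be a multiple of the
#'   epoch length.
#' @return latency in minutes, or `NA`.
#' @export
sleep_onset_latency <- function(hyp, state, min_seconds = 25) {
  stopifnot(inherits(hyp, "hypnogram"))
  k <- min_seconds / hyp$epoch_seconds
  if (abs(k - round(k)) > 1e-9)
    stop("sleep_onset_latency(): min_seconds must be a multiple of ",
         "epoch_seconds")
  ep <- episodes(hyp, state)
  ep <- ep[ep$length_epochs >= round(k), , drop = FALSE]
  if (nrow(ep) == 0L) return(NA_real_)
  (ep$start_epoch[1L] - 1L) * hyp$epoch_seconds / 60
}

#' Sleep architecture metrics
#'
#' Per-state percentage of recording time, episode count, mean episode
#' duration (seconds) and onset latency (minutes; `NA` when no episode of
#' at least `min_seconds` occurs). Percentages over the three states sum
#' to 100 exactly, and `episode_count * mean_episode_duration` equals the
#' total time in the state exactly.
#'
#' @param hyp a [hypnogram()].
#' @param min_seconds latency qualification threshold in seconds.
#' @return data.frame with one row per state.
#' @export
sleep_metrics <- function(hyp, min_seconds = 25) {
  stopifnot(inherits(hyp, "hypnogram"))
  states <- c("WAKE", "SWS", "REM")
  do.call(rbind, lapply(states, function(st) {
    ep <- episodes(hyp, st)
    n_ep <- nrow(ep)
    tot_s <- sum(ep$length_epochs) * hyp$epoch_seconds
    data.frame(state = st,
               percent_time = percent_time(hyp, st),
               episode_count = n_ep,
               mean_episode_duration_s = if (n_ep) tot_s / n_ep else NA_real_,
               onset_latency_min = sleep_onset_latency(hyp, st, min_seconds))
  }))
}

#' Sleep metrics for a set of hypnograms
#'
#' @param hyps named list of [hypnogram()] objects (names = animal ids).
#' @param min_seconds latency qualification threshold in seconds.
#' @return long data.frame with an `animal_id` column.
#' @export
sleep_metrics_table <- function(hyps, min_seconds = 25) {
  stopifnot(length(names(hyps)) == length(hyps))
  do.call(rbind, lapply(names(hyps), function(id)
    cbind(animal_id = id, sleep_metrics(hyps[[id]], min_seconds))))
}

#' Rule-based vigilance-state classifier configuration
#'
#' Decision rule: an epoch with EMG power above `emg_wake` is `WAKE`;
#' otherwise an epoch whose theta/delta power ratio exceeds
#' `rem_theta_delta` is `REM`; everything else is `SWS`. Defaults match
#' the documented feature scales of the epoch-feature generator (wake EMG
#' an order of magnitude above sleep EMG; REM theta several times delta).
#'
#' @param emg_wake EMG threshold separating wake from sleep.
#' @param rem_theta_delta theta/delta ratio threshold separating REM from
#'   SWS.
#' @return list of thresholds.
#' @export
epoch_classifier_config <- function(emg_wake = 3, rem_theta_delta = 2) {
  if (emg_wake <= 0 || rem_theta_delta <= 0)
    stop("epoch_classifier_config(): thresholds must be positive")
  list(emg_wake = emg_wake, rem_theta_delta = rem_theta_delta)
}

#' Classify epochs from spectral features
#'
#' @param features data.frame with columns `emg`, `delta`, `theta` (one row
#'   per epoch).
#' @param config an [epoch_classifier_config()].
#' @param epoch_seconds epoch length of the returned hypnogram.
#' @param origin recording origin of the returned hypnogram.
#' @return a [hypnogram()] of the inferred states.
#' @export
classify_epochs <- function(features, config = epoch_classifier_config(),
                            epoch_seconds = 5, origin = "lights_on") {
  need <- c("emg", "delta", "theta")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("classify_epochs(): missing feature column(s): ",
         paste(miss, collapse = ", "))
  st <- ifelse(features$emg > config$emg_wake, "WAKE",
               ifelse(features$theta / features$delta > config$rem_theta_delta,
                      "REM", "SWS"))
  hypnogram(st, epoch_seconds = epoch_seconds, origin = origin)
}

## Generic bidirectional 0-3 score against a control reference, shared by
## the sleep radar scores and usable for any continuous variable with an
## adverse direction.
bidirectional_score <- function(values, control_values, direction) {
  ts <- build_thresholds(list(variable = "generic", rule = "BIDIRECTIONAL",
                              direction = direction),
                         control_values)
  assign_score(values, ts)
}

#' Sleep entry and continuity radar scores
#'
#' Scores each animal's per-state sleep metrics 0-3 against the control
#' reference distribution with the bidirectional percentile rule, then sums
#' them into two 0-6 domain scores per state: entry (onset latency +
#' episode count) and continuity (percent time + mean episode duration).
#' The adverse direction is longer latency, fewer episodes, lower percent
#' time and shorter episodes; an animal with no qualifying episode (latency
#' `NA`) takes the maximal latency score of 3.
#'
#' @param metrics long metrics table as from [sleep_metrics_table()].
#' @param control_ids animal ids forming the control reference (at least
#'   4 with finite values per variable).
#' @param states states to score (default SWS and REM).
#' @return data.frame per animal x state with component scores, `entry`
#'   and `continuity`.
#' @export
sleep_radar_scores <- function(metrics, control_ids,
                               states = c("SWS", "REM")) {
  out <- list()
  for (st in states) {
    m <- metrics[metrics$state == st, , drop = FALSE]
    ctrl <- m[m$animal_id %in% control_ids, , drop = FALSE]
    if (sum(is.finite(ctrl$percent_time)) < 4L)
      stop("sleep_radar_scores(): undersampled control reference")
    sc_lat <- bidirectional_score(m$onset_latency_min,
                                  ctrl$onset_latency_min[
                                    is.finite(ctrl$onset_latency_min)],
                                  "higher_is_worse")
    sc_lat[!is.finite(m$onset_latency_min)] <- 3L  # never entered the state
    sc_epi <- bidirectional_score(m$episode_count, ctrl$episode_count,
                                  "lower_is_worse")
    sc_pct <- bidirectional_score(m$percent_time, ctrl$percent_time,
                                  "lower_is_worse")
    sc_dur <- bidirectional_score(m$mean_episode_duration_s,
                                  ctrl$mean_episode_duration_s[
                                    is.finite(ctrl$mean_episode_duration_s)],
                                  "lower_is_worse")
    out[[st]] <- data.frame(animal_id = m$animal_id, state = st,
                            latency_score = sc_lat,
                            episode_score = sc_epi,
                            percent_score = sc_pct,
                            duration_score = sc_dur,
                            entry = sc_lat + sc_epi,
                            continuity = sc_pct + sc_dur)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
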