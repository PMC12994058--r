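## Random draws for the behavioral distribution families. A zero scale
## degenerates to the location (noise-free limit), which keeps the
## generators testable against exact expectations.
draw_values <- function(n, params) {
  switch(params$family,
    truncnorm = {
      if (params$scale == 0) return(rep(params$location, n))
      lo <- stats::pnorm(0,   params$location, params$scale)
      hi <- stats::pnorm(100, params$location, params$scale)
      stats::qnorm(stats::runif(n, lo, hi), params$location, params$scale)
    },
    lognormal = {
      if (params$scale == 0) return(rep(params$location, n))
      exp(stats::rnorm(n, log(params$location), params$scale))
    },
    zero_pois = {
      zero <- stats::runif(n) < params$p_zero
      k <- 1 + stats::rpois(n, params$lambda)
      ifelse(zero, 0, k)
    },
    stop("unknown family: ", params$family))
}

## Closed-form mean of each family; used when checking that sample moments
## of a simulated cohort agree with the configured parameters.
family_mean <- function(params) {
  switch(params$family,
    truncnorm = {
      if (params$scale == 0) return(params$location)
      a <- (0   - params$location) / params$scale
      b <- (100 - params$location) / params$scale
      z <- stats::pnorm(b) - stats::pnorm(a)
      params$location +
        params$scale * (stats::dnorm(a) - stats::dnorm(b)) / z
    },
    lognormal = params$location * exp(params$scale^2 / 2),
    zero_pois = (1 - params$p_zero) * (1 + params$lambda))
}

#' Simulate a behavioral cohort
#'
#' Draws one value per animal for every variable in the registry, using the
#' per-archetype distribution parameters. Each animal consumes its own
#' random substream derived from the master seed (see [animal_seed()]), so
#' the table is byte-identical under a fixed configuration and any single
#' animal can be regenerated in isolation.
#'
#' @param config a [cohort_config()].
#' @return a long-format data.frame (`animal_id`, `group`, `test`, `day`,
#'   `variable`, `value`) — one row per animal x variable.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' head(cohort)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  registry <- default_variable_registry()
  rows <- list()
  idx <- 0L
  for (spec in config$archetypes) {
    if (spec$n == 0L) next
    miss <- setdiff(registry$variable, names(spec$behavior))
    if (length(miss))
      stop("simulate_cohort(): archetype '", spec$name,
           "' lacks parameters for: ", paste(miss, collapse = ", "))
    for (j in seq_len(spec$n)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", spec$name, j)
      set.seed(animal_seed(config$seed, idx, stream = 0L))
      vals <- vapply(registry$variable,
                     function(v) draw_values(1L, spec$behavior[[v]]),
                     numeric(1))
      rows[[idx]] <- data.frame(animal_id = id, group = spec$name,
                                test = registry$test, day = registry$day,
                                variable = registry$variable,
                                value = unname(vals))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(animal_id = character(), group = character(),
                      test = character(), day = integer(),
                      variable = character(), value = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write a behavioral table
#'
#' Tab-delimited UTF-8 text with columns
#' `animal_id, group, test, day, variable, value` and dot decimals.
#'
#' @param x behavioral table data.frame.
#' @param path file path.
#' @return `read_behavior_table` returns the data.frame.
#' @export
write_behavior_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_behavior_table
#' @export
read_behavior_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Simulate a hypnogram
#'
#' Generates a vigilance-state sequence from a first-order Markov chain
#' over `WAKE`, `SWS` and `REM` at fixed epoch resolution. REM can only be
#' entered from SWS (the usual rodent sleep-stage grammar); a transition
#' matrix with `WAKE -> REM` mass is rejected.
#'
#' @param spec an [archetype_spec()] or a 3x3 transition matrix with
#'   `WAKE`/`SWS`/`REM` dimnames.
#' @param condition which per-archetype matrix to use when `spec` is an
#'   archetype: `"baseline"` or `"d14"` (recording after the day-14 cue
#'   reminder).
#' @param seed integer seed.
#' @param hours recording length in hours.
#' @param epoch_seconds epoch length in seconds.
#' @param init initial state.
#' @param origin recorded time origin, `"lights_on"` (baseline) or
#'   `"cue_exposure"` (D14: the cue is placed at lights-on and recording
#'   starts immediately after).
#' @return a [hypnogram()] object.
#' @export
simulate_hypnogram <- function(spec, condition = c("baseline", "d14"),
                               seed = 1L, hours = 24, epoch_seconds = 5,
                               init = "WAKE",
                               origin = NULL) {
  condition <- match.arg(condition)
  P <- if (inherits(spec, "archetype_spec")) spec$sleep[[condition]] else spec
  check_transition_matrix(P)
  if (is.null(origin))
    origin <- if (condition == "d14") "cue_exposure" else "lights_on"
  n <- as.integer(round(hours * 3600 / epoch_seconds))
  states <- c("WAKE", "SWS", "REM")
  cum <- t(apply(P, 1L, cumsum))
  set.seed(seed)
  u <- stats::runif(n)
  s <- integer(n)
  cur <- match(init, states)
  for (i in seq_len(n)) {
    cur <- 1L + sum(u[i] > cum[cur, ]) # first column with cum >= u
    s[i] <- cur
  }
  hypnogram(states[s], epoch_seconds = epoch_seconds, origin = origin)
}

#' Stationary distribution of a vigilance-state chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised
#' to sum to one — the long-run fraction of time the simulated hypnogram
#' spends in each state.
#'
#' @param P 3x3 transition matrix.
#' @return named numeric vector over `WAKE`, `SWS`, `REM`.
#' @export
stationary_distribution <- function(P) {
  check_transition_matrix(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

#' Default per-state epoch-feature parameters
#'
#' State-conditional means of the four epoch features (EMG power, and the
#' delta 1-4 Hz, theta 5-9 Hz and spindle 10-14 Hz band powers, arbitrary
#' units) plus a multiplicative log-normal noise scale. Wakefulness has
#' high EMG; slow-wave sleep low EMG and dominant delta with spindles;
#' REM the lowest EMG with a theta-dominated spectrum.
#'
#' @param noise_sdlog sd of the log-scale multiplicative noise.
#' @return list with elements `means` (3x4 matrix) and `noise_sdlog`.
#' @export
default_feature_params <- function(noise_sdlog = 0.3) {
  m <- rbind(WAKE = c(emg = 10.0, delta = 1.0, theta = 1.5, spindle = 0.8),
             SWS  = c(emg =  1.0, delta = 8.0, theta = 2.0, spindle = 3.0),
             REM  = c(emg =  0.4, delta = 1.5, theta = 7.0, spindle = 1.0))
  if (noise_sdlog < 0) stop("noise_sdlog must be >= 0")
  list(means = m, noise_sdlog = noise_sdlog)
}

#' Simulate epoch features for a hypnogram
#'
#' Draws per-epoch EMG and band powers from state-conditional log-normal
#' distributions around the configured means; with a zero noise scale the
#' features equal the state means exactly. The true state is retained as
#' ground truth for evaluating the rule-based classifier.
#'
#' @param hyp a [hypnogram()].
#' @param params see [default_feature_params()].
#' @param seed integer seed.
#' @return data.frame: `epoch_index`, `state` (ground truth), `emg`,
#'   `delta`, `theta`, `spindle`.
#' @export
simulate_epoch_features <- function(hyp, params = default_feature_params(),
                                    seed = 1L) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(hyp$states)
  if (n == 0L) stop("simulate_epoch_features(): empty hypnogram")
  set.seed(seed)
  m <- params$means[hyp$states, , drop = FALSE]
  noise <- if (params$noise_sdlog == 0) matrix(0, n, 4L) else
    matrix(stats::rnorm(n * 4L, 0, params$noise_sdlog), n, 4L)
  feats <- m * exp(noise)
  data.frame(epoch_index = seq_len(n), state = hyp$states,
             emg = feats[, "emg"], delta = feats[, "delta"],
             theta = feats[, "theta"], spindle = feats[, "spindle"])
}

#' Simulate a two-channel c-Fos image
#'
#' Renders Gaussian-profile nuclei on a constant background with additive
#' Gaussian noise. Channel 1 (nuclear stain) contains every spot; channel 2
#' (c-Fos) only the spots flagged `cfos`. Overlapping spots are allowed —
#' they are the fixture for watershed splitting.
#'
#' @param width_px,height_px image size in pixels.
#' @param spots data.frame with columns `x`, `y`, `radius` and logical
#'   `cfos`; centers must lie inside the image.
#' @param background constant background level.
#' @param noise_sd sd of the additive noise (must be `>= 0`).
#' @param peak peak spot intensity above background.
#' @param seed integer seed.
#' @return list with `image` (`width_px` x `height_px` x 2 array, channels
#'   nuclear then c-Fos) and `truth` (the spot table).
#' @export
simulate_cfos_image <- function(width_px, height_px, spots,
                                background = 0.1, noise_sd = 0.02,
                                peak = 1, seed = 1L) {
  if (noise_sd < 0) stop("simulate_cfos_image(): noise_sd must be >= 0")
  if (nrow(spots) > 0) {
    stopifnot(all(c("x", "y", "radius") %in% names(spots)))
    if (is.null(spots$cfos)) spots$cfos <- TRUE
    if (any(spots$x < 1 | spots$x > width_px |
            spots$y < 1 | spots$y > height_px))
      stop("simulate_cfos_image(): spot centers outside image bounds")
  }
  ch1 <- matrix(0, width_px, height_px)
  ch2 <- matrix(0, width_px, height_px)
  for (k in seq_len(nrow(spots))) {
    x0 <- spots$x[k]; y0 <- spots$y[k]; r <- spots$radius[k]
    sd2 <- (r / 2)^2
    xs <- max(1L, floor(x0 - 3 * r)):min(width_px, ceiling(x0 + 3 * r))
    ys <- max(1L, floor(y0 - 3 * r)):min(height_px, ceiling(y0 + 3 * r))
    g <- peak * exp(-(outer((xs - x0)^2, (ys - y0)^2, "+")) / (2 * sd2))
    ch1[xs, ys] <- ch1[xs, ys] + g
    if (isTRUE(spots$cfos[k])) ch2[xs, ys] <- ch2[xs, ys] + g
  }
  set.seed(seed)
  npx <- width_px * height_px
  noise1 <- if (noise_sd == 0) 0 else
    matrix(stats::rnorm(npx, 0, noise_sd), width_px, height_px)
  noise2 <- if (noise_sd == 0) 0 else
    matrix(stats::rnorm(npx, 0, noise_sd), width_px, height_px)
  img <- array(0, dim = c(width_px, height_px, 2L))
  img[, , 1L] <- ch1 + background + noise1
  img[, , 2L] <- ch2 + background + noise2
  list(image = img, truth = spots)
}

#' Place random non-overlapping spots
#'
#' Rejection-samples `n` spot centers at least `min_distance` apart, with a
#' margin of `3 * radius` from the border. A configurable fraction is
#' flagged c-Fos positive.
#'
#' @param n number of spots.
#' @param width_px,height_px image size.
#' @param radius spot radius in pixels.
#' @param min_distance minimum center-to-center distance.
#' @param cfos_fraction fraction of spots flagged c-Fos positive.
#' @param seed integer seed.
#' @return spot data.frame (`x`, `y`, `radius`, `cfos`).
#' @export
simulate_spot_field <- function(n, width_px, height_px, radius = 4,
                                min_distance = 3 * radius,
                                cfos_fraction = 1, seed = 1L) {
  set.seed(seed)
  margin <- 3 * radius
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop("simulate_spot_field(): could not place spots; lower n or spacing")
    x <- stats::runif(1, margin, width_px - margin)
    y <- stats::runif(1, margin, height_px - margin)
    if (length(xs) == 0 ||
        min((xs - x)^2 + (ys - y)^2) >= min_distance^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cfos <- rep(FALSE, n)
  if (n > 0) cfos[seq_len(round(cfos_fraction * n))] <- TRUE
  data.frame(x = xs, y = ys, radius = radius, cfos = cfos)
}

#' Write/read a two-channel image as multi-page TIFF
#'
#' Page order: nuclear, c-Fos. Intensities are clipped to `[0, 1]` on
#' write (32-bit float storage).
#'
#' @param img `w x h x 2` array as returned by [simulate_cfos_image()].
#' @param path TIFF path.
#' @return `read_cfos_tiff` returns the `w x h x 2` array.
#' @export
write_cfos_tiff <- function(img, path) {
  pages <- lapply(1:2, function(k) {
    m <- t(img[, , k])          # TIFF rows are the y axis
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_cfos_tiff
#' @export
read_cfos_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) img[, , k] <- t(pages[[k]])
  img
}
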