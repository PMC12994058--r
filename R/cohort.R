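#' Archetype specification for the synthetic cohort
#'
#' An archetype bundles the distributional parameters of one planted
#' phenotype: per-variable behavioral distributions, per-condition sleep
#' state-transition matrices, and regional imaging densities. Four
#' archetypes make up the default cohort: unshocked controls (`NoFS`),
#' resilient (`Res`), susceptible freezers (`Frz`) and susceptible
#' escapers (`Esc`).
#'
#' Behavioral families:
#' \describe{
#'   \item{`truncnorm`}{normal with `location` (mean) and `scale` (sd),
#'     truncated to `[0, 100]` — used for percentage-of-session variables.}
#'   \item{`lognormal`}{`location` is the median on the natural scale,
#'     `scale` the sd of the log — used for velocities, distances and
#'     startle ratios.}
#'   \item{`zero_pois`}{point mass at 0 with probability `p_zero`, else
#'     `1 + Poisson(lambda)` — used for escape-attempt counts.}
#' }
#'
#' @param name phenotype label, one of `"NoFS"`, `"Res"`, `"Frz"`, `"Esc"`.
#' @param n number of animals (non-negative integer).
#' @param behavior named list of per-variable parameter lists, each with a
#'   `family` plus its parameters (see above).
#' @param sleep named list with elements `baseline` and `d14`, each a 3x3
#'   state-transition matrix over `WAKE`, `SWS`, `REM` at 5-s resolution.
#'   Direct `WAKE -> REM` transitions are forbidden.
#' @param imaging named list with `density` (spots per mm^2 per region),
#'   `cfos_fraction` (fraction of nuclei that are c-Fos positive per
#'   region), `spot_radius_px` and `noise_sd`.
#' @return an object of class `archetype_spec`.
#' @seealso [default_archetypes()], [cohort_config()], [simulate_cohort()]
#' @export
archetype_spec <- function(name, n, behavior, sleep, imaging) {
  name <- match.arg(name, c("NoFS", "Res", "Frz", "Esc"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("archetype_spec(): 'n' must be a non-negative integer")
  for (v in names(behavior)) {
    p <- behavior[[v]]
    if (is.null(p$family) ||
        !p$family %in% c("truncnorm", "lognormal", "zero_pois"))
      stop("archetype_spec(): unknown family for variable '", v, "'")
    if (p$family == "truncnorm" &&
        (p$location < 0 || p$location > 100))
      stop("archetype_spec(): truncnorm location for '", v,
           "' must lie in [0, 100]")
    if (!is.null(p$scale) && p$scale < 0)
      stop("archetype_spec(): negative scale for '", v, "'")
    if (p$family == "zero_pois" &&
        (p$p_zero < 0 || p$p_zero > 1 || p$lambda < 0))
      stop("archetype_spec(): invalid zero_pois parameters for '", v, "'")
  }
  for (cond in names(sleep)) check_transition_matrix(sleep[[cond]])
  if (!is.null(imaging$noise_sd) && imaging$noise_sd < 0)
    stop("archetype_spec(): negative imaging noise_sd")
  structure(list(name = name, n = as.integer(n), behavior = behavior,
                 sleep = sleep, imaging = imaging),
            class = "archetype_spec")
}

check_transition_matrix <- function(P) {
  states <- c("WAKE", "SWS", "REM")
  if (!is.matrix(P) || !identical(dim(P), c(3L, 3L)) ||
      !identical(rownames(P), states) || !identical(colnames(P), states))
    stop("transition matrix must be 3x3 with WAKE/SWS/REM dimnames")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix rows must be non-negative and sum to 1")
  if (P["WAKE", "REM"] > 0)
    stop("direct WAKE -> REM transitions are not allowed")
  invisible(P)
}

## Canonical variable registry: which test/day each variable belongs to, the
## threshold rule scoring it, its adverse direction, the radar domain it
## feeds, and whether it enters the 8-variable composite.
#' Default variable registry
#'
#' The canonical map from behavioral variables to tests, days, threshold
#' rules, severity directions and radar domains. Eight variables (two per
#' test: novel context, novel object, elevated-plus maze, startle) enter the
#' composite; the day-14 cue-reminder variables feed the intrusion radar
#' domain only; the day-28 full-context variables drive the second
#' classification step; the pre-stress open-field variables are carried for
#' baseline checks and are never scored.
#'
#' @return a data.frame with columns `variable`, `test`, `day`, `rule`,
#'   `direction`, `domain`, `in_composite`, `scored`.
#' @export
default_variable_registry <- function() {
  reg <- rbind(
    data.frame(variable = "nc_freezing",  test = "new_context", day = 16L,
               rule = "FS_TAIL", direction = "higher_is_worse",
               domain = "altered_reactivity", in_composite = TRUE),
    data.frame(variable = "nc_escaping",  test = "new_context", day = 16L,
               rule = "FS_TAIL", direction = "higher_is_worse",
               domain = "altered_reactivity", in_composite = TRUE),
    data.frame(variable = "no_freezing",  test = "new_object", day = 16L,
               rule = "FS_TAIL", direction = "higher_is_worse",
               domain = NA_character_, in_composite = TRUE),
    data.frame(variable = "no_escaping",  test = "new_object", day = 16L,
               rule = "FS_TAIL", direction = "higher_is_worse",
               domain = NA_character_, in_composite = TRUE),
    data.frame(variable = "epm_open_time", test = "epm", day = 18L,
               rule = "BIDIRECTIONAL", direction = "lower_is_worse",
               domain = "avoidance", in_composite = TRUE),
    data.frame(variable = "epm_open_velocity", test = "epm", day = 18L,
               rule = "BIDIRECTIONAL", direction = "lower_is_worse",
               domain = "avoidance", in_composite = TRUE),
    data.frame(variable = "startle_amp_ratio", test = "startle", day = 23L,
               rule = "STARTLE_RATIO", direction = "higher_is_worse",
               domain = "altered_arousal", in_composite = TRUE),
    data.frame(variable = "startle_lat_ratio", test = "startle", day = 23L,
               rule = "STARTLE_RATIO", direction = "lower_is_worse",
               domain = "altered_arousal", in_composite = TRUE),
    data.frame(variable = "cue_freezing", test = "cue_reminder", day = 14L,
               rule = "FS_TAIL", direction = "higher_is_worse",
               domain = "intrusion", in_composite = FALSE),
    data.frame(variable = "cue_escaping", test = "cue_reminder", day = 14L,
               rule = "FS_TAIL", direction = "higher_is_worse",
               domain = "intrusion", in_composite = FALSE),
    data.frame(variable = "ctx_freezing", test = "full_context", day = 28L,
               rule = NA_character_, direction = NA_character_,
               domain = NA_character_, in_composite = FALSE),
    data.frame(variable = "escape_attempts", test = "full_context", day = 28L,
               rule = NA_character_, direction = NA_character_,
               domain = NA_character_, in_composite = FALSE),
    data.frame(variable = "of_center_time", test = "open_field", day = -5L,
               rule = NA_character_, direction = NA_character_,
               domain = NA_character_, in_composite = FALSE),
    data.frame(variable = "of_distance", test = "open_field", day = -5L,
               rule = NA_character_, direction = NA_character_,
               domain = NA_character_, in_composite = FALSE))
  reg$scored <- !is.na(reg$rule)
  reg
}

#' Names of the eight composite variables
#'
#' @param registry a variable registry data.frame.
#' @return character vector of the variables entering the composite score.
#' @export
composite_variables <- function(registry = default_variable_registry()) {
  registry$variable[registry$in_composite]
}

## Behavioral parameter constants per archetype. These are package
## constants chosen to emulate a realistic post-stress cohort: freezers
## freeze heavily in novel settings and avoid the open arms, escapers climb
## and jump with no startle habituation, resilient animals look like
## controls on non-conditioned tests but freeze strongly to the conditioned
## cue, and all foot-shocked groups freeze to the day-14 cue.
default_behavior_params <- function(name) {
  tn <- function(location, scale)
    list(family = "truncnorm", location = location, scale = scale)
  ln <- function(location, scale)
    list(family = "lognormal", location = location, scale = scale)
  zp <- function(p_zero, lambda)
    list(family = "zero_pois", p_zero = p_zero, lambda = lambda)
  switch(name,
    NoFS = list(
      nc_freezing = tn(2, 2),    nc_escaping = tn(1, 1),
      no_freezing = tn(3, 2),    no_escaping = tn(1, 1),
      epm_open_time = tn(30, 8), epm_open_velocity = ln(4.0, 0.20),
      startle_amp_ratio = ln(0.75, 0.15), startle_lat_ratio = ln(1.10, 0.10),
      cue_freezing = tn(4, 3),   cue_escaping = tn(1, 1),
      ctx_freezing = tn(8, 5),   escape_attempts = zp(0.99, 0.5),
      of_center_time = tn(12, 4), of_distance = ln(20, 0.20)),
    Res = list(
      nc_freezing = tn(4, 3),    nc_escaping = tn(2, 2),
      no_freezing = tn(5, 3),    no_escaping = tn(2, 2),
      epm_open_time = tn(27, 8), epm_open_velocity = ln(3.9, 0.20),
      startle_amp_ratio = ln(0.80, 0.15), startle_lat_ratio = ln(1.35, 0.12),
      cue_freezing = tn(55, 15), cue_escaping = tn(2, 2),
      ctx_freezing = tn(55, 15), escape_attempts = zp(0.98, 0.5),
      of_center_time = tn(12, 4), of_distance = ln(20, 0.20)),
    Frz = list(
      nc_freezing = tn(45, 15),  nc_escaping = tn(3, 2),
      no_freezing = tn(50, 15),  no_escaping = tn(3, 2),
      epm_open_time = tn(8, 5),  epm_open_velocity = ln(2.0, 0.30),
      startle_amp_ratio = ln(0.80, 0.15), startle_lat_ratio = ln(0.85, 0.10),
      cue_freezing = tn(65, 15), cue_escaping = tn(3, 3),
      ctx_freezing = tn(70, 12), escape_attempts = zp(0.97, 0.5),
      of_center_time = tn(12, 4), of_distance = ln(20, 0.20)),
    Esc = list(
      nc_freezing = tn(8, 5),    nc_escaping = tn(30, 12),
      no_freezing = tn(8, 5),    no_escaping = tn(35, 12),
      epm_open_time = tn(28, 10), epm_open_velocity = ln(4.2, 0.25),
      startle_amp_ratio = ln(1.10, 0.15), startle_lat_ratio = ln(1.00, 0.10),
      cue_freezing = tn(45, 15), cue_escaping = tn(25, 10),
      ctx_freezing = tn(15, 8),  escape_attempts = zp(0.05, 2.0),
      of_center_time = tn(12, 4), of_distance = ln(20, 0.20)))
}

## Sleep transition matrices at 5-s resolution. REM is entered from SWS
## only. The D14 resilient variant raises SWS -> REM entry and REM
## maintenance, planting the post-stress REM increase specific to the
## resilient phenotype; the other groups keep their baseline dynamics.
default_sleep_params <- function(name) {
  tm <- function(w, s, r) {
    P <- rbind(w, s, r)
    dimnames(P) <- list(c("WAKE", "SWS", "REM"), c("WAKE", "SWS", "REM"))
    P
  }
  base <- tm(c(0.980, 0.020, 0.000),
             c(0.0125, 0.9785, 0.0090),
             c(0.050, 0.010, 0.940))
  d14_res <- tm(c(0.980, 0.020, 0.000),
                c(0.0125, 0.9715, 0.0160),
                c(0.040, 0.010, 0.950))
  list(baseline = base, d14 = if (name == "Res") d14_res else base)
}

## Regional planted spot densities (nuclei per mm^2) and the fraction of
## them that are c-Fos positive, encoding the group-specific activation
## directions: amygdala LA/CeL activation high in both susceptible groups,
## anterior dorsal PAG low in freezers, posterior dorsal PAG low in
## escapers, ventral PAG elevated in all foot-shocked groups.
default_imaging_params <- function(name) {
  cf <- switch(name,
    NoFS = c(BA = 0.30, LA = 0.25, CeL = 0.25, CeM = 0.30,
             dPAG_ant = 0.40, dPAG_post = 0.40,
             vPAG_ant = 0.30, vPAG_post = 0.30),
    Res  = c(BA = 0.30, LA = 0.25, CeL = 0.25, CeM = 0.35,
             dPAG_ant = 0.45, dPAG_post = 0.45,
             vPAG_ant = 0.55, vPAG_post = 0.55),
    Frz  = c(BA = 0.50, LA = 0.60, CeL = 0.60, CeM = 0.40,
             dPAG_ant = 0.15, dPAG_post = 0.40,
             vPAG_ant = 0.40, vPAG_post = 0.55),
    Esc  = c(BA = 0.50, LA = 0.60, CeL = 0.60, CeM = 0.40,
             dPAG_ant = 0.40, dPAG_post = 0.15,
             vPAG_ant = 0.40, vPAG_post = 0.55))
  list(density = c(BA = 600, LA = 600, CeL = 500, CeM = 500,
                   dPAG_ant = 500, dPAG_post = 500,
                   vPAG_ant = 450, vPAG_post = 450),
       cfos_fraction = cf, spot_radius_px = 4, noise_sd = 0.02)
}

#' Default cohort archetypes
#'
#' The packaged worked-example cohort: unshocked controls plus resilient,
#' freezer and escaper foot-shocked phenotypes, with group sizes matching a
#' 47-animal study (16/11/13/7) unless overridden.
#'
#' @param n named integer vector of group sizes.
#' @return list of [archetype_spec()] objects.
#' @export
default_archetypes <- function(n = c(NoFS = 16, Res = 11, Frz = 13, Esc = 7)) {
  lapply(c("NoFS", "Res", "Frz", "Esc"), function(a)
    archetype_spec(a, n = unname(n[[a]]),
                   behavior = default_behavior_params(a),
                   sleep = default_sleep_params(a),
                   imaging = default_imaging_params(a)))
}

#' Cohort simulation configuration
#'
#' @param archetypes list of [archetype_spec()] objects.
#' @param seed integer master seed. Every generator derives per-animal
#'   substreams from it (see [animal_seed()]), so a fixed seed gives
#'   byte-identical output and individual animals can be regenerated
#'   without rerunning the whole cohort.
#' @param epoch_seconds hypnogram epoch length in seconds.
#' @param recording_hours length of one polysomnographic recording.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(archetypes = default_archetypes(), seed = 1L,
                          epoch_seconds = 5, recording_hours = 24) {
  if (epoch_seconds <= 0 || recording_hours <= 0)
    stop("cohort_config(): durations must be positive")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("cohort_config(): 'seed' must be a single integer")
  stopifnot(all(vapply(archetypes, inherits, logical(1), "archetype_spec")))
  structure(list(archetypes = archetypes, seed = as.integer(seed),
                 epoch_seconds = epoch_seconds,
                 recording_hours = recording_hours),
            class = "cohort_config")
}

#' Per-animal substream seed
#'
#' Deterministic counter scheme: the substream for animal `i` (1-based
#' cohort index) and purpose `stream` (0 = behavior, 1 = baseline sleep,
#' 2 = D14 sleep, 3 = epoch features, 4 = imaging) is
#' `(seed + 104729 * i + 7919 * stream) mod (2^31 - 1)`.
#'
#' @param seed master seed.
#' @param i animal index (1-based).
#' @param stream purpose offset.
#' @return integer seed.
#' @export
animal_seed <- function(seed, i, stream = 0L) {
  as.integer((as.double(seed) + 104729 * i + 7919 * stream) %% 2147483647)
}
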