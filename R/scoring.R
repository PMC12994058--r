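#' Startle habituation ratios
#'
#' Ratio of the median of the last five valid trials to the median of the
#' first five valid trials of a startle session, for both the maximum
#' response amplitude and the latency-to-peak. Trials flagged for
#' pre-stimulus movement are excluded before the windows are taken; if
#' fewer than five valid trials remain per end the windows shrink
#' symmetrically down to a minimum of three, below which the ratios are
#' missing. A habituated animal has an amplitude ratio below 1 and a
#' latency ratio above 1.
#'
#' @param session data.frame with one row per trial and columns
#'   `amplitude`, `latency` and logical `flagged` (pre-stimulus movement);
#'   a standard session has 40 trials.
#' @return named numeric vector `c(amplitude_ratio, latency_ratio)`; `NA`
#'   components when a window cannot be formed or its baseline median is 0.
#' @export
startle_habituation_ratios <- function(session) {
  stopifnot(all(c("amplitude", "latency") %in% names(session)))
  flagged <- if (is.null(session$flagged)) rep(FALSE, nrow(session)) else
    session$flagged
  valid <- which(!flagged & is.finite(session$amplitude) &
                   is.finite(session$latency))
  k <- min(5L, floor(length(valid) / 2))
  if (k < 3L) {
    warning("startle_habituation_ratios(): fewer than 3 valid trials per ",
            "window; ratios are missing")
    return(c(amplitude_ratio = NA_real_, latency_ratio = NA_real_))
  }
  first <- valid[seq_len(k)]
  last <- valid[seq.int(length(valid) - k + 1L, length(valid))]
  ratio <- function(x) {
    num <- stats::median(x[last])
    den <- stats::median(x[first])
    if (den == 0) {
      warning("startle_habituation_ratios(): first-window median is 0")
      return(NA_real_)
    }
    num / den
  }
  c(amplitude_ratio = ratio(session$amplitude),
    latency_ratio = ratio(session$latency))
}

#' Composite behavioral severity score
#'
#' Sum of the eight per-variable 0-3 scores (two variables from each of
#' the four non-conditioned tests), range 0-24. A missing component makes
#' the composite missing: animals are analysed complete-case and the
#' exclusion is signalled via the `NA`.
#'
#' @param scores named integer vector (or one-row data.frame) of
#'   per-variable scores; must contain the eight composite variables.
#' @param variables names of the composite variables.
#' @return integer composite score, or `NA` if any component is missing.
#' @export
composite_score <- function(scores, variables = composite_variables()) {
  scores <- unlist(scores)
  miss <- setdiff(variables, names(scores))
  if (length(miss))
    stop("composite_score(): missing composite variable(s): ",
         paste(miss, collapse = ", "))
  comp <- scores[variables]
  if (anyNA(comp)) return(NA_integer_)
  if (any(comp < 0 | comp > 3))
    stop("composite_score(): component scores must be in 0..3")
  as.integer(sum(comp))
}

#' Radar domain scores
#'
#' Four 0-6 symptom-dimension scores, each the sum of two 0-3 component
#' scores: intrusion (day-14 cue-reminder freezing + escaping), avoidance
#' (open-arm time + open-arm velocity), altered reactivity (day-16 novel
#' context freezing + escaping) and altered arousal (the two startle
#' ratio scores). A missing component makes its domain missing.
#'
#' @param scores named integer vector of per-variable scores including the
#'   cue-reminder scores.
#' @return named integer vector of the four domain scores.
#' @export
radar_domain_scores <- function(scores) {
  scores <- unlist(scores)
  pair <- function(a, b) {
    if (!all(c(a, b) %in% names(scores))) return(NA_integer_)
    s <- scores[c(a, b)]
    if (anyNA(s)) NA_integer_ else as.integer(sum(s))
  }
  c(intrusion = pair("cue_freezing", "cue_escaping"),
    avoidance = pair("epm_open_time", "epm_open_velocity"),
    altered_reactivity = pair("nc_freezing", "nc_escaping"),
    altered_arousal = pair("startle_amp_ratio", "startle_lat_ratio"))
}

#' Rank variables by dispersion
#'
#' Orders behavioral variables by descending sample standard deviation in
#' the foot-shocked animals — the dispersion-ranking step of variable
#' selection. Constant variables (SD 0) rank last; ties break
#' alphabetically so the order is stable.
#'
#' @param behavior long behavioral table.
#' @param groups groups whose animals enter the SD (default: all
#'   non-control groups).
#' @param control_group the control group label.
#' @return data.frame `variable`, `sd`, ordered by decreasing SD.
#' @export
variable_dispersion_ranking <- function(behavior, groups = NULL,
                                        control_group = "NoFS") {
  if (is.null(groups)) groups <- setdiff(unique(behavior$group),
                                         control_group)
  b <- behavior[behavior$group %in% groups, , drop = FALSE]
  sds <- vapply(split(b$value, b$variable), function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      stop("variable_dispersion_ranking(): need >= 2 animals per variable")
    stats::sd(v)
  }, numeric(1))
  out <- data.frame(variable = names(sds), sd = unname(sds))
  out <- out[order(-out$sd, out$variable), ]
  rownames(out) <- NULL
  out
}
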