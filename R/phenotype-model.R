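#' Composite cut-off from control composites
#'
#' The susceptibility cut-off is defined as the maximal composite score
#' observed in the unshocked control group — it is always recomputed from
#' the supplied controls, never hard-coded.
#'
#' @param control_composites integer vector of control composite scores.
#' @return integer cut-off.
#' @export
derive_cutoff <- function(control_composites) {
  control_composites <- control_composites[!is.na(control_composites)]
  if (length(control_composites) == 0L)
    stop("derive_cutoff(): no control composite scores")
  as.integer(max(control_composites))
}

#' Step 1: resilient / susceptible split
#'
#' A foot-shocked animal is susceptible iff its composite score strictly
#' exceeds the cut-off; a composite equal to the cut-off is resilient,
#' since the cut-off is itself the maximal control composite and controls
#' must remain non-susceptible.
#'
#' @param composite integer composite score(s); `NA` gives `NA`
#'   (unclassified, excluded downstream).
#' @param cutoff integer cut-off from [derive_cutoff()].
#' @return character vector, `"Susceptible"` or `"Resilient"`.
#' @export
classify_step1 <- function(composite, cutoff) {
  ifelse(is.na(composite), NA_character_,
         ifelse(composite > cutoff, "Susceptible", "Resilient"))
}

#' Classification rule bundle
#'
#' @param composite_cutoff integer composite cut-off (the control maximum).
#' @param escape_rule minimum number of day-28 escape attempts defining an
#'   escaper (default 1).
#' @param freezing_reference control 95th percentile of day-28 freezing,
#'   kept as a QC annotation (it is not part of the decision rule).
#' @return an object of class `classification_rule`.
#' @export
classification_rule <- function(composite_cutoff, escape_rule = 1L,
                                freezing_reference = NA_real_) {
  if (escape_rule < 1) stop("classification_rule(): escape_rule must be >= 1")
  structure(list(composite_cutoff = as.integer(composite_cutoff),
                 escape_rule = as.integer(escape_rule),
                 freezing_reference = freezing_reference),
            class = "classification_rule")
}

#' Step 2: freezer / escaper split
#'
#' Among susceptible animals, an escaper is any animal with at least one
#' escape attempt (wall climb or jump) during the day-28 full-context
#' re-exposure, regardless of its freezing level; all other susceptible
#' animals are freezers. The day-28 freezing percentage is compared to the
#' control 95th percentile as a QC annotation only: a susceptible animal
#' with neither high freezing nor any escape attempt is labelled a freezer
#' with a QC flag.
#'
#' @param d28_freezing_pct day-28 freezing percentage(s).
#' @param escape_attempts day-28 escape attempt count(s); must be
#'   non-negative.
#' @param rule a [classification_rule()].
#' @return data.frame with `label` (`"Frz"`/`"Esc"`) and `qc` annotation.
#' @export
classify_step2 <- function(d28_freezing_pct, escape_attempts, rule) {
  stopifnot(inherits(rule, "classification_rule"))
  if (any(escape_attempts < 0, na.rm = TRUE))
    stop("classify_step2(): negative escape attempt counts")
  label <- ifelse(escape_attempts >= rule$escape_rule, "Esc", "Frz")
  high_freezing <- !is.na(rule$freezing_reference) &
    d28_freezing_pct > rule$freezing_reference
  qc <- ifelse(label == "Frz" & !high_freezing,
               "low_freezing_no_escape", "")
  data.frame(label = label, qc = qc)
}

#' Fit the two-step phenotype classification
#'
#' Fits the full scoring-and-classification procedure on a long behavioral
#' table: derives the per-variable threshold sets from the control (and,
#' for the tail rules, foot-shocked) distributions, assigns 0-3 scores,
#' sums the eight-variable composite, sets the susceptibility cut-off at
#' the maximal control composite, and splits susceptible animals into
#' freezers and escapers from their day-28 defensive behavior.
#'
#' @param behavior long behavioral table with columns `animal_id`, `group`,
#'   `test`, `day`, `variable`, `value` (see [simulate_cohort()] /
#'   [read_behavior_table()]).
#' @param control_group the unshocked control group label.
#' @param escape_rule minimum escape attempts defining an escaper.
#' @param registry variable registry (see [default_variable_registry()]).
#' @return an object of class `phenotype_model` with components
#'   `thresholds` (named list of threshold sets), `scores` (wide
#'   per-animal score table), `composite`, `cutoff`, `rule`, `labels`
#'   (per-animal step1/step2/final labels with QC), `radar` (per-animal
#'   domain scores) and `excluded` (animals with a missing composite).
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' fit <- phenotype_model(cohort)
#' fit
#' summary(fit)
#' @export
phenotype_model <- function(behavior, control_group = "NoFS",
                            escape_rule = 1L,
                            registry = default_variable_registry()) {
  need <- c("animal_id", "group", "variable", "value")
  miss <- setdiff(need, names(behavior))
  if (length(miss))
    stop("phenotype_model(): behavior table lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!control_group %in% behavior$group)
    stop("phenotype_model(): no animals in control group '",
         control_group, "'")

  animals <- unique(behavior[, c("animal_id", "group")])
  is_ctrl <- animals$group == control_group
  wide <- value_matrix(behavior, animals$animal_id)

  scored_vars <- registry$variable[registry$scored]
  thresholds <- lapply(scored_vars, function(v) {
    build_thresholds(v,
                     control_values = wide[is_ctrl, v],
                     fs_values = wide[!is_ctrl, v])
  })
  names(thresholds) <- scored_vars

  scores <- vapply(scored_vars, function(v)
    assign_score(wide[, v], thresholds[[v]]),
    integer(nrow(animals)))
  scores <- as.data.frame(scores)
  rownames(scores) <- animals$animal_id

  comp <- apply(scores[, composite_variables(registry), drop = FALSE], 1L,
                function(s) if (anyNA(s)) NA_integer_ else as.integer(sum(s)))
  cutoff <- derive_cutoff(comp[is_ctrl])
  rule <- classification_rule(
    cutoff, escape_rule = escape_rule,
    freezing_reference = pctl(wide[is_ctrl, "ctx_freezing"], 95))

  step1 <- rep(NA_character_, nrow(animals))
  step1[!is_ctrl] <- classify_step1(comp[!is_ctrl], cutoff)
  susceptible <- !is_ctrl & !is.na(step1) & step1 == "Susceptible"
  step2 <- rep(NA_character_, nrow(animals))
  qc <- rep("", nrow(animals))
  if (any(susceptible)) {
    s2 <- classify_step2(wide[susceptible, "ctx_freezing"],
                         wide[susceptible, "escape_attempts"], rule)
    step2[susceptible] <- s2$label
    qc[susceptible] <- s2$qc
  }
  final <- ifelse(is_ctrl, "NoFS",
                  ifelse(is.na(step1), NA_character_,
                         ifelse(step1 == "Resilient", "FS-Res",
                                paste0("FS-", step2))))
  labels <- data.frame(animal_id = animals$animal_id, group = animals$group,
                       composite = comp, step1 = step1, step2 = step2,
                       final = final, qc = qc)

  radar <- t(apply(scores, 1L, radar_domain_scores))
  radar <- data.frame(animal_id = animals$animal_id,
                      final = final, radar, row.names = NULL)

  structure(list(thresholds = thresholds, scores = scores,
                 composite = stats::setNames(comp, animals$animal_id),
                 cutoff = cutoff, rule = rule, labels = labels,
                 radar = radar, control_group = control_group,
                 registry = registry,
                 excluded = animals$animal_id[is.na(comp)],
                 call = match.call()),
            class = "phenotype_model")
}

## Long table -> animals x variables value matrix (last value wins if a
## variable is duplicated for an animal).
value_matrix <- function(behavior, animal_ids) {
  vars <- unique(behavior$variable)
  m <- matrix(NA_real_, length(animal_ids), length(vars),
              dimnames = list(animal_ids, vars))
  m[cbind(match(behavior$animal_id, animal_ids),
          match(behavior$variable, vars))] <- behavior$value
  m
}

#' Phenotype counts and percentages
#'
#' Counts per final label and percentages of the foot-shocked total,
#' rounded to the nearest 0.5 percentage point. Aggregate susceptible
#' (freezers + escapers) and resilient rows are included.
#'
#' @param x a `phenotype_model`, or a character vector of final labels
#'   (`NoFS`, `FS-Res`, `FS-Frz`, `FS-Esc`).
#' @return data.frame with columns `label`, `n`, `pct_of_fs`.
#' @examples
#' labs <- rep(c("NoFS", "FS-Res", "FS-Frz", "FS-Esc"), c(16, 11, 13, 7))
#' phenotype_summary(labs)
#' @export
phenotype_summary <- function(x) {
  final <- if (inherits(x, "phenotype_model")) x$labels$final else
    as.character(x)
  final <- final[!is.na(final)]
  n_fs <- sum(final != "NoFS")
  cnt <- function(lab) sum(final == lab)
  pct <- function(k) if (n_fs == 0) NA_real_ else round(200 * k / n_fs) / 2
  n_res <- cnt("FS-Res"); n_frz <- cnt("FS-Frz"); n_esc <- cnt("FS-Esc")
  data.frame(
    label = c("NoFS", "FS-Res", "FS-Frz", "FS-Esc",
              "Susceptible", "Resilient"),
    n = c(cnt("NoFS"), n_res, n_frz, n_esc, n_frz + n_esc, n_res),
    pct_of_fs = c(NA_real_, pct(n_res), pct(n_frz), pct(n_esc),
                  pct(n_frz + n_esc), pct(n_res)))
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("Two-step behavioral phenotype classification\n")
  cat(sprintf("  %d animals (%d control '%s'), composite cut-off = %d\n",
              nrow(x$labels), sum(x$labels$group == x$control_group),
              x$control_group, x$cutoff))
  s <- phenotype_summary(x)
  s <- s[s$label %in% c("FS-Res", "FS-Frz", "FS-Esc"), ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-7s n = %2d (%.1f%% of FS)\n",
                s$label[i], s$n[i], s$pct_of_fs[i]))
  if (length(x$excluded))
    cat("  excluded (missing composite):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.phenotype_model <- function(object, ...) {
  med_radar <- stats::aggregate(
    object$radar[, c("intrusion", "avoidance",
                     "altered_reactivity", "altered_arousal")],
    by = list(final = object$radar$final), FUN = stats::median,
    na.rm = TRUE)
  structure(list(counts = phenotype_summary(object),
                 cutoff = object$cutoff,
                 audit = threshold_audit(object$thresholds),
                 median_radar = med_radar),
            class = "summary.phenotype_model")
}

#' @export
print.summary.phenotype_model <- function(x, ...) {
  cat("Phenotype counts (percentages of the foot-shocked total):\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("\nComposite cut-off (max control composite): %d\n", x$cutoff))
  cat("\nMedian radar domain scores by phenotype:\n")
  print(x$median_radar, row.names = FALSE)
  cat("\nThreshold audit: use $audit for every cut and its provenance.\n")
  invisible(x)
}

#' Classify new animals with a fitted model
#'
#' Scores a new behavioral table with the threshold sets and cut-off frozen
#' at fit time (the reference distributions are not re-derived) and applies
#' both classification steps.
#'
#' @param object a fitted `phenotype_model`.
#' @param newdata long behavioral table.
#' @param ... unused.
#' @return per-animal label data.frame as in the fitted model.
#' @export
predict.phenotype_model <- function(object, newdata, ...) {
  animals <- unique(newdata[, c("animal_id", "group")])
  wide <- value_matrix(newdata, animals$animal_id)
  scored_vars <- names(object$thresholds)
  scores <- vapply(scored_vars, function(v)
    assign_score(wide[, v], object$thresholds[[v]]),
    integer(nrow(animals)))
  scores <- matrix(scores, nrow = nrow(animals),
                   dimnames = list(animals$animal_id, scored_vars))
  comp <- apply(scores[, composite_variables(object$registry),
                       drop = FALSE], 1L,
                function(s) if (anyNA(s)) NA_integer_ else as.integer(sum(s)))
  is_ctrl <- animals$group == object$control_group
  step1 <- rep(NA_character_, nrow(animals))
  step1[!is_ctrl] <- classify_step1(comp[!is_ctrl], object$cutoff)
  susceptible <- !is_ctrl & !is.na(step1) & step1 == "Susceptible"
  step2 <- rep(NA_character_, nrow(animals))
  qc <- rep("", nrow(animals))
  if (any(susceptible)) {
    s2 <- classify_step2(wide[susceptible, "ctx_freezing"],
                         wide[susceptible, "escape_attempts"], object$rule)
    step2[susceptible] <- s2$label
    qc[susceptible] <- s2$qc
  }
  final <- ifelse(is_ctrl, "NoFS",
                  ifelse(is.na(step1), NA_character_,
                         ifelse(step1 == "Resilient", "FS-Res",
                                paste0("FS-", step2))))
  data.frame(animal_id = animals$animal_id, group = animals$group,
             composite = comp, step1 = step1, step2 = step2,
             final = final, qc = qc)
}

#' Radar plot of median domain scores
#'
#' One star per phenotype over the four behavioral symptom domains
#' (intrusion, avoidance, altered reactivity, altered arousal), each on a
#' 0-6 scale.
#'
#' @param x a `phenotype_model`.
#' @param ... passed to [graphics::stars()].
#' @export
plot.phenotype_model <- function(x, ...) {
  med <- stats::aggregate(
    x$radar[, c("intrusion", "avoidance",
                "altered_reactivity", "altered_arousal")],
    by = list(final = x$radar$final), FUN = stats::median, na.rm = TRUE)
  m <- as.matrix(med[, -1L])
  rownames(m) <- med$final
  graphics::stars(m / 6, scale = FALSE, len = 1, key.loc = c(0.5, 0.5),
                  main = "Median behavioral domain scores (0-6)", ...)
  invisible(x)
}
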