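## Significance markers following the reporting conventions used
## throughout: significance at p < 0.05, a trend band in (0.05, 0.07].
marker <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p <= 0.07) "trend" else "ns"
}

new_test_result <- function(test, statistic, df = NA, n = NA, p_value,
                            posthoc = NULL, note = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), n = n, p_value = unname(p_value),
                 marker = marker(unname(p_value)),
                 posthoc = posthoc, note = note),
            class = "pheno_test")
}

#' @export
print.pheno_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g [%s]\n", x$test,
              x$statistic,
              if (!is.na(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value, x$marker))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Kruskal-Wallis omnibus test with Dunn post hoc
#'
#' Rank-based H test (tie-corrected) across groups; when the omnibus test
#' is significant at 0.05, pairwise Dunn rank comparisons are attached
#' (z statistics on mean ranks with the pooled tie-corrected variance),
#' unadjusted by default with an optional Holm correction.
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 groups, each n >= 2).
#' @param p_adjust `"none"` (default) or `"holm"` for the post hoc
#'   p-values.
#' @return a `pheno_test` result.
#' @export
kw_test <- function(values, groups, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("kw_test(): need >= 2 groups with >= 2 values each")
  if (length(unique(values)) == 1L) {
    res <- new_test_result("Kruskal-Wallis", 0, df = nlevels(groups) - 1L,
                           n = length(values), p_value = 1,
                           note = "all values identical")
    return(res)
  }
  kt <- stats::kruskal.test(values, groups)
  ph <- NULL
  if (kt$p.value < 0.05)
    ph <- dunn_posthoc(values, groups, p_adjust = p_adjust)
  new_test_result("Kruskal-Wallis", kt$statistic, df = kt$parameter,
                  n = length(values), p_value = kt$p.value, posthoc = ph)
}

#' Dunn pairwise rank comparisons
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @param p_adjust `"none"` or `"holm"`.
#' @return data.frame `comparison`, `z`, `p`, `marker`.
#' @export
dunn_posthoc <- function(values, groups, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- table(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[a] + 1 / n_g[b]))
    z[k] <- (mean_rank[a] - mean_rank[b]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  if (p_adjust == "holm") p <- stats::p.adjust(p, "holm")
  data.frame(comparison = paste(pairs[1L, ], pairs[2L, ], sep = " vs "),
             z = z, p = p, marker = vapply(p, marker, character(1)))
}

#' Friedman repeated-measures test
#'
#' Within-subject rank chi-square across timepoints on a complete
#' animals-by-timepoints matrix; when significant, pairwise Wilcoxon
#' signed-rank comparisons between timepoints are attached.
#'
#' @param mat numeric matrix, rows = animals, columns = timepoints;
#'   missing cells are an error (complete cases only).
#' @param p_adjust `"none"` or `"holm"` for the post hoc p-values.
#' @return a `pheno_test` result.
#' @export
friedman_rm <- function(mat, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("friedman_rm(): missing cells (complete cases only)")
  if (ncol(mat) < 2L) stop("friedman_rm(): need >= 2 timepoints")
  if (all(apply(mat, 1L, function(x) length(unique(x)) == 1L)))
    return(new_test_result("Friedman", 0, df = ncol(mat) - 1L,
                           n = nrow(mat), p_value = 1,
                           note = "no within-subject variation"))
  ft <- stats::friedman.test(mat)
  ph <- NULL
  if (ft$p.value < 0.05) {
    cols <- colnames(mat)
    if (is.null(cols)) cols <- paste0("t", seq_len(ncol(mat)))
    pairs <- utils::combn(seq_len(ncol(mat)), 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      w <- signed_rank_test(mat[, i] - mat[, j])
      data.frame(comparison = paste(cols[i], cols[j], sep = " vs "),
                 p = w$p_value)
    })
    ph <- do.call(rbind, rows)
    if (p_adjust == "holm") ph$p <- stats::p.adjust(ph$p, "holm")
    ph$marker <- vapply(ph$p, marker, character(1))
  }
  new_test_result("Friedman", ft$statistic, df = ft$parameter,
                  n = nrow(mat), p_value = ft$p.value, posthoc = ph)
}

## Two-sided Wilcoxon signed-rank on paired differences; exact for n <= 25
## without ties or zeros, corrected normal approximation otherwise.
signed_rank_test <- function(d) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (all(d == 0)) return(list(statistic = NA_real_, p_value = 1, n = n))
  exact <- n <= 25 && !any(d == 0) && !anyDuplicated(abs(d))
  w <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                           correct = TRUE))
  list(statistic = w$statistic, p_value = w$p.value, n = n)
}

#' One-sample comparison to a theoretical value
#'
#' Two-sided Wilcoxon signed-rank test of `values - theoretical` (used to
#' compare habituation ratios to 1). Exact distribution for n <= 25
#' without ties or zero differences; continuity-corrected normal
#' approximation otherwise.
#'
#' @param values numeric vector (n >= 4).
#' @param theoretical reference value (default 1).
#' @return a `pheno_test` result.
#' @export
one_sample_vs_theoretical <- function(values, theoretical = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stop("one_sample_vs_theoretical(): need n >= 4")
  w <- signed_rank_test(values - theoretical)
  new_test_result("Wilcoxon signed-rank vs theoretical",
                  if (is.na(w$statistic)) 0 else w$statistic,
                  n = w$n, p_value = w$p_value)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' from the t approximation.
#'
#' @param x,y paired numeric vectors (n >= 3 complete pairs).
#' @return an object of class `pheno_cor` with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_cor(): need >= 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("spearman_cor(): constant input; correlation undefined")
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          marker = NA_character_), class = "pheno_cor"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                 marker = marker(ct$p.value)),
            class = "pheno_cor")
}

#' @export
print.pheno_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g, n = %d [%s]\n",
              x$rho, x$p_value, x$n, x$marker))
  invisible(x)
}

#' Build a cohort analysis report
#'
#' Assembles the group summaries (median and IQR per variable), the
#' omnibus Kruskal-Wallis tests with post hoc comparisons, the radar-chart
#' medians, and the configured correlations (e.g. day-14 REM percentage
#' against the composite score) into one deterministic report object.
#' Sleep and imaging sections are included only when their tables are
#' supplied.
#'
#' @param model a fitted [phenotype_model()].
#' @param behavior the long behavioral table the model was fitted on.
#' @param sleep_metrics optional long sleep metrics table from
#'   [sleep_metrics_table()] restricted to one condition (e.g. D14).
#' @param cfos_combined optional combined activation score table from
#'   [activation_scores()].
#' @param seed seed recorded in the manifest.
#' @return an object of class `pheno_report`.
#' @export
build_report <- function(model, behavior, sleep_metrics = NULL,
                         cfos_combined = NULL, seed = NA_integer_) {
  stopifnot(inherits(model, "phenotype_model"))
  lab <- model$labels[, c("animal_id", "final")]
  b <- merge(behavior, lab, by = "animal_id")
  grp_sum <- do.call(rbind, lapply(split(b, list(b$variable, b$final),
                                         drop = TRUE), function(d) {
    q <- stats::quantile(d$value, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(variable = d$variable[1L], phenotype = d$final[1L],
               n = sum(is.finite(d$value)), median = q[[2L]],
               iqr_lo = q[[1L]], iqr_hi = q[[3L]])
  }))
  grp_sum <- grp_sum[order(grp_sum$variable, grp_sum$phenotype), ]
  rownames(grp_sum) <- NULL

  scored <- names(model$thresholds)
  tests <- lapply(scored, function(v) {
    d <- b[b$variable == v & !is.na(b$final), ]
    kw_test(d$value, d$final)
  })
  names(tests) <- scored

  radar <- stats::aggregate(
    model$radar[, c("intrusion", "avoidance",
                    "altered_reactivity", "altered_arousal")],
    by = list(phenotype = model$radar$final), FUN = stats::median,
    na.rm = TRUE)

  correlations <- list()
  sleep_section <- NULL
  if (!is.null(sleep_metrics)) {
    rem <- sleep_metrics[sleep_metrics$state == "REM", ]
    m <- merge(rem, data.frame(animal_id = names(model$composite),
                               composite = unname(model$composite)),
               by = "animal_id")
    correlations$rem_pct_vs_composite <-
      spearman_cor(m$percent_time, m$composite)
    sm <- merge(sleep_metrics, lab, by = "animal_id")
    sleep_section <- do.call(rbind, lapply(
      split(sm, list(sm$state, sm$final), drop = TRUE), function(d)
        data.frame(state = d$state[1L], phenotype = d$final[1L],
                   n = nrow(d),
                   median_percent = stats::median(d$percent_time),
                   median_episodes = stats::median(d$episode_count))))
    rownames(sleep_section) <- NULL
  }
  cfos_section <- NULL
  if (!is.null(cfos_combined)) {
    cm <- merge(cfos_combined, lab, by = "animal_id")
    num <- setdiff(names(cm), c("animal_id", "final"))
    cfos_section <- stats::aggregate(cm[num], by = list(phenotype = cm$final),
                                     FUN = stats::median, na.rm = TRUE)
  }

  structure(list(summary = phenotype_summary(model),
                 cutoff = model$cutoff,
                 group_summaries = grp_sum, tests = tests,
                 radar_medians = radar,
                 sleep = sleep_section, cfos = cfos_section,
                 correlations = correlations,
                 manifest = list(
                   package_version =
                     as.character(utils::packageVersion("stresspheno")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed)),
            class = "pheno_report")
}

#' @export
print.pheno_report <- function(x, ...) {
  cat("Cohort analysis report\n======================\n")
  cat(sprintf("Composite cut-off: %d\n", x$cutoff))
  print(x$summary, row.names = FALSE)
  cat("\nOmnibus tests per scored variable:\n")
  for (v in names(x$tests))
    cat(sprintf("  %-18s H = %7.3f, p = %.4g [%s]\n", v,
                x$tests[[v]]$statistic, x$tests[[v]]$p_value,
                x$tests[[v]]$marker))
  if (length(x$correlations)) {
    cat("\nCorrelations:\n")
    for (nm in names(x$correlations)) {
      cc <- x$correlations[[nm]]
      cat(sprintf("  %s: rho = %.4f, p = %.4g [%s]\n", nm, cc$rho,
                  cc$p_value, cc$marker))
    }
  }
  invisible(x)
}

#' Write a report to delimited text files
#'
#' Emits the report sections as tab-delimited files plus a run manifest;
#' regeneration from the same inputs is byte-identical.
#'
#' @param report a `pheno_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(wr(report$summary, "phenotype_summary.tsv"),
             wr(report$group_summaries, "group_summaries.tsv"),
             wr(report$radar_medians, "radar_medians.tsv"))
  tests <- do.call(rbind, lapply(names(report$tests), function(v) {
    t <- report$tests[[v]]
    data.frame(variable = v, statistic = t$statistic, df = t$df,
               p = t$p_value, marker = t$marker)
  }))
  paths <- c(paths, wr(tests, "omnibus_tests.tsv"))
  if (!is.null(report$sleep))
    paths <- c(paths, wr(report$sleep, "sleep_medians.tsv"))
  if (!is.null(report$cfos))
    paths <- c(paths, wr(report$cfos, "cfos_medians.tsv"))
  manifest <- data.frame(key = names(report$manifest),
                         value = vapply(report$manifest, as.character,
                                        character(1)))
  paths <- c(paths, wr(manifest, "manifest.tsv"))
  invisible(paths)
}
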