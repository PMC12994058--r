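#' Build a threshold set for one variable
#'
#' Derives the ordered cut values that map a raw behavioral (or sleep, or
#' imaging) value to a 0-3 severity score, from reference distributions.
#' Every cut records its provenance (which dataset and which percentile
#' produced it) so a threshold audit can replay the derivation.
#'
#' Rules:
#' \describe{
#'   \item{`FS_TAIL`}{for variables whose control values are near zero and
#'     unusable as a graded reference (novel context/object and cue-reminder
#'     freezing and escaping): score 0 up to the control 95th percentile,
#'     then cuts at the 75th and 95th percentiles of the foot-shocked
#'     dataset.}
#'   \item{`BIDIRECTIONAL`}{for variables with an adverse and a protective
#'     ("risk-taking") direction (elevated-plus-maze open-arm time and
#'     velocity): cuts at the control minimum and 5th/25th/75th/95th
#'     percentiles; deviations on the adverse side score 1-3, protective
#'     deviations beyond the 95th percentile are capped at 1.}
#'   \item{`STARTLE_RATIO`}{fixed hyperarousal gates (amplitude ratio
#'     `>= 0.95`, latency ratio `<= 1.05`, inclusive on the hyperarousal
#'     side as printed), with scores 2/3 cut at the control median and
#'     75th (amplitude) or 25th (latency) percentile beyond the gate. When
#'     a control statistic falls on the habituated side of the gate the
#'     corresponding cut is clamped onto the gate to keep the map monotone.}
#'   \item{`CONTROL_PERCENTILE`}{one-sided higher-is-more-severe cuts at
#'     the control median, 75th percentile and maximum (used for regional
#'     activation scores).}
#' }
#'
#' @param variable either a variable name (character) looked up in the
#'   default registry, or a list/one-row data.frame with elements
#'   `variable`, `rule`, `direction`.
#' @param control_values numeric vector of control (No-FS) reference
#'   values; at least 4 are required.
#' @param fs_values numeric vector of foot-shocked values; required for
#'   `FS_TAIL`.
#' @return an object of class `threshold_set` with elements `variable`,
#'   `rule`, `direction`, `cuts` (named numeric), and `provenance`
#'   (data.frame `cut`, `value`, `source`).
#' @seealso [assign_score()]
#' @export
build_thresholds <- function(variable, control_values, fs_values = NULL) {
  if (is.character(variable)) {
    reg <- default_variable_registry()
    row <- reg[reg$variable == variable, ]
    if (nrow(row) != 1L || !isTRUE(row$scored))
      stop("build_thresholds(): unknown or unscored variable '",
           variable, "'")
    variable <- as.list(row)
  }
  rule <- variable$rule
  direction <- variable$direction
  control_values <- control_values[is.finite(control_values)]
  if (length(control_values) < 4L)
    stop("build_thresholds(): need at least 4 finite control values ",
         "(undersampled reference)")
  prov <- function(cut, value, source)
    data.frame(cut = cut, value = value, source = source)

  if (rule == "FS_TAIL") {
    fs_values <- fs_values[is.finite(fs_values)]
    if (length(fs_values) == 0L)
      stop("build_thresholds(): FS_TAIL requires foot-shocked values")
    c0 <- pctl(control_values, 95)
    c1 <- max(c0, pctl(fs_values, 75))
    c2 <- max(c1, pctl(fs_values, 95))
    cuts <- c(cut0 = c0, cut1 = c1, cut2 = c2)
    provenance <- rbind(prov("cut0", c0, "No-FS p95"),
                        prov("cut1", c1, "FS p75"),
                        prov("cut2", c2, "FS p95"))
  } else if (rule == "BIDIRECTIONAL") {
    q <- pctl(control_values, c(0, 5, 25, 75, 95, 100))
    cuts <- c(min = q[1], p5 = q[2], p25 = q[3],
              p75 = q[4], p95 = q[5], max = q[6])
    provenance <- prov(names(cuts), unname(cuts),
                       paste0("No-FS ", c("min", "p5", "p25",
                                          "p75", "p95", "max")))
  } else if (rule == "STARTLE_RATIO") {
    if (direction == "higher_is_worse") {       # amplitude ratio
      gate <- 0.95
      med <- pctl(control_values, 50)
      p75 <- pctl(control_values, 75)
      c1 <- max(gate, med)
      c2 <- max(c1, p75)
      cuts <- c(gate = gate, cut1 = c1, cut2 = c2)
      provenance <- rbind(prov("gate", gate, "fixed amplitude-ratio gate"),
                          prov("cut1", c1, "No-FS median (clamped to gate)"),
                          prov("cut2", c2, "No-FS p75 (clamped to gate)"))
    } else {                                    # latency-to-peak ratio
      gate <- 1.05
      med <- pctl(control_values, 50)
      p25 <- pctl(control_values, 25)
      c1 <- min(gate, med)
      c2 <- min(c1, p25)
      cuts <- c(gate = gate, cut1 = c1, cut2 = c2)
      provenance <- rbind(prov("gate", gate, "fixed latency-ratio gate"),
                          prov("cut1", c1, "No-FS median (clamped to gate)"),
                          prov("cut2", c2, "No-FS p25 (clamped to gate)"))
    }
  } else if (rule == "CONTROL_PERCENTILE") {
    cuts <- c(cut0 = pctl(control_values, 50),
              cut1 = pctl(control_values, 75),
              cut2 = max(control_values))
    cuts["cut1"] <- max(cuts["cut0"], cuts["cut1"])
    cuts["cut2"] <- max(cuts["cut1"], cuts["cut2"])
    provenance <- prov(names(cuts), unname(cuts),
                       c("No-FS median", "No-FS p75", "No-FS max"))
  } else stop("build_thresholds(): unknown rule '", rule, "'")

  structure(list(variable = variable$variable, rule = rule,
                 direction = direction, cuts = cuts,
                 provenance = provenance),
            class = "threshold_set")
}

#' Assign a 0-3 severity score
#'
#' Maps raw values to severity scores under a [build_thresholds()] set.
#' Values exactly on a cut take the lower-severity score, except the
#' printed startle gates (`>= 0.95` amplitude, `<= 1.05` latency) which are
#' inclusive on the hyperarousal side. Non-finite values give `NA`, which
#' propagates into a missing composite.
#'
#' @param value numeric vector of raw values.
#' @param thresholds a `threshold_set`.
#' @return integer vector of scores in `0:3` (with `NA` for missing input).
#' @export
assign_score <- function(value, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  ct <- thresholds$cuts
  score <- rep(NA_integer_, length(value))
  ok <- is.finite(value)
  v <- value[ok]
  s <- integer(length(v))
  if (thresholds$rule == "FS_TAIL") {
    s[] <- 3L
    s[v <= ct["cut2"]] <- 2L
    s[v <= ct["cut1"]] <- 1L
    s[v <= ct["cut0"]] <- 0L
  } else if (thresholds$rule == "BIDIRECTIONAL") {
    if (thresholds$direction == "lower_is_worse") {
      s[] <- 0L
      s[v > ct["p95"]] <- 1L            # protective side, capped at 1
      s[v < ct["p25"]] <- 1L
      s[v <= ct["p5"]] <- 2L
      s[v < ct["min"]] <- 3L
    } else {
      s[] <- 0L
      s[v < ct["p5"]] <- 1L             # protective side, capped at 1
      s[v > ct["p75"]] <- 1L
      s[v >= ct["p95"]] <- 2L
      s[v > ct["max"]] <- 3L
    }
  } else if (thresholds$rule == "STARTLE_RATIO") {
    if (thresholds$direction == "higher_is_worse") {
      s[] <- 0L
      s[v >= ct["gate"]] <- 3L
      s[v <= ct["cut2"]] <- 2L
      s[v <= ct["cut1"]] <- 1L
      s[v < ct["gate"]] <- 0L
    } else {
      s[] <- 0L
      s[v <= ct["gate"]] <- 3L
      s[v >= ct["cut2"]] <- 2L
      s[v >= ct["cut1"]] <- 1L
      s[v > ct["gate"]] <- 0L
    }
  } else if (thresholds$rule == "CONTROL_PERCENTILE") {
    s[] <- 3L
    s[v <= ct["cut2"]] <- 2L
    s[v <= ct["cut1"]] <- 1L
    s[v <= ct["cut0"]] <- 0L
  }
  score[ok] <- s
  score
}

#' Threshold audit table
#'
#' Flattens a list of threshold sets into one data.frame recording every
#' cut and its provenance.
#'
#' @param thresholds named list of `threshold_set` objects.
#' @return data.frame with columns `variable`, `rule`, `cut`, `value`,
#'   `source`.
#' @export
threshold_audit <- function(thresholds) {
  do.call(rbind, lapply(thresholds, function(ts)
    cbind(variable = ts$variable, rule = ts$rule, ts$provenance)))
}
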