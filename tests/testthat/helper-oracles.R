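# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (sorting, scanning, enumeration) rather
# than calling the implementation under test.

# percentile by explicit sort + fractional-rank interpolation
oracle_pctl <- function(x, p) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  sapply(p, function(pp) {
    h <- 1 + (n - 1) * pp / 100
    i <- floor(h)
    if (i >= n) return(x[n])
    x[i] + (h - i) * (x[i + 1] - x[i])
  })
}

# brute-force bin scan over the interval system of a threshold set
oracle_assign <- function(v, ts) {
  if (!is.finite(v)) return(NA_integer_)
  ct <- ts$cuts
  if (ts$rule %in% c("FS_TAIL", "CONTROL_PERCENTILE")) {
    for (s in 0:2) if (v <= ct[[s + 1L]]) return(s)
    return(3L)
  }
  if (ts$rule == "BIDIRECTIONAL") {
    if (ts$direction == "lower_is_worse") {
      if (v < ct[["min"]]) return(3L)
      if (v <= ct[["p5"]]) return(2L)
      if (v < ct[["p25"]]) return(1L)
      if (v <= ct[["p95"]]) return(0L)
      return(1L)
    } else {
      if (v > ct[["max"]]) return(3L)
      if (v >= ct[["p95"]]) return(2L)
      if (v > ct[["p75"]]) return(1L)
      if (v >= ct[["p5"]]) return(0L)
      return(1L)
    }
  }
  if (ts$rule == "STARTLE_RATIO") {
    if (ts$direction == "higher_is_worse") {
      if (v < ct[["gate"]]) return(0L)
      if (v <= ct[["cut1"]]) return(1L)
      if (v <= ct[["cut2"]]) return(2L)
      return(3L)
    } else {
      if (v > ct[["gate"]]) return(0L)
      if (v >= ct[["cut1"]]) return(1L)
      if (v >= ct[["cut2"]]) return(2L)
      return(3L)
    }
  }
  stop("unknown rule")
}

# maximal runs of one state by explicit linear scan
oracle_episodes <- function(states, state) {
  starts <- integer(0); lens <- integer(0)
  inrun <- FALSE
  for (i in seq_along(states)) {
    if (states[i] == state) {
      if (!inrun) { starts <- c(starts, i); lens <- c(lens, 0L) }
      inrun <- TRUE
      lens[length(lens)] <- lens[length(lens)] + 1L
    } else inrun <- FALSE
  }
  data.frame(start_epoch = starts, length_epochs = lens)
}

oracle_latency <- function(states, epoch_seconds, state, min_epochs) {
  ep <- oracle_episodes(states, state)
  ep <- ep[ep$length_epochs >= min_epochs, , drop = FALSE]
  if (nrow(ep) == 0) return(NA_real_)
  (ep$start_epoch[1] - 1) * epoch_seconds / 60
}

# Kruskal-Wallis H with tie correction, from its rank-sum definition
oracle_kw_H <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, sum)^2 / tapply(r, groups, length)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Friedman chi-square from within-row ranks (tie-corrected)
oracle_friedman <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  colsum <- colSums(R)
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  (k - 1) * (sum((colsum - n * (k + 1) / 2)^2)) / (A - C)
}

# exact signed-rank tail probabilities by enumerating all sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  wdist <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    wdist <- c(wdist, sum(r[signs]))
  }
  wdist <- wdist[-1]
  p_le <- mean(wdist <= w_obs)
  p_ge <- mean(wdist >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Spearman rho as Pearson correlation of average ranks
oracle_spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# default worked-example group sizes and the planted -> final label map
planted_label_map <- c(NoFS = "NoFS", Res = "FS-Res",
                       Frz = "FS-Frz", Esc = "FS-Esc")

make_registry_row <- function(rule, direction) {
  list(variable = "v", rule = rule, direction = direction)
}
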