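#' Flag outliers in a measure table
#'
#' Single-pass rule applied per (block, measure): values more than
#' `k` standard deviations from that cell's mean are flagged. Flagged
#' rows are excluded from all group statistics; the flagging is not
#' re-iterated after exclusion.
#'
#' @param table data.frame with columns `subject`, `block`, `measure`,
#'   `value` (one row per subject x block x measure)
#' @param measure optional measure name to restrict flagging to
#' @param k SD multiplier (default 3)
#' @return the table with a logical `outlier` column
#' @export
flag_outliers <- function(table, measure = NULL, k = 3) {
  stopifnot(all(c("subject", "block", "measure", "value") %in%
                  names(table)))
  if (!"outlier" %in% names(table)) table$outlier <- FALSE
  sel_m <- if (is.null(measure)) unique(table$measure) else measure
  for (m in sel_m) {
    for (b in unique(table$block)) {
      i <- which(table$measure == m & table$block == b)
      if (length(i) == 0) next
      v <- table$value[i]
      if (sum(is.finite(v)) < 3) {
        warning("fewer than 3 values for ", m, "/", b, ": no flagging")
        next
      }
      mu <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) next
      table$outlier[i] <- is.finite(v) & abs(v - mu) > k * s
    }
  }
  table
}

#' Paired contrast between two blocks of a measure
#'
#' Two-tailed paired t test on complete subject pairs (subjects missing
#' either block, or outlier-flagged in it, are dropped pairwise), with
#' Cohen's d for paired data (mean difference / SD of differences) and
#' an optional Bonferroni correction for a caller-supplied family size.
#' A zero-variance nonzero difference is reported with `t = +-Inf`,
#' `p = 0` (documented convention).
#'
#' @param table measure table (see [flag_outliers()])
#' @param measure measure name
#' @param blockA,blockB block labels; the contrast is A - B
#' @param family Bonferroni family size (default 1 = no correction)
#' @return `list(t, df, p_raw, p_bonferroni, cohen_d, n_pairs)`
#' @export
paired_contrast <- function(table, measure, blockA, blockB, family = 1) {
  t0 <- table[table$measure == measure, , drop = FALSE]
  if ("outlier" %in% names(t0)) t0 <- t0[!t0$outlier, , drop = FALSE]
  a <- t0[t0$block == blockA, c("subject", "value")]
  b <- t0[t0$block == blockB, c("subject", "value")]
  m <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- m$value_a - m$value_b
  if (sd(d) <= 1e-10 * max(abs(d), 1)) {   # numerically constant diffs
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p_raw = 1, p_bonferroni = 1,
                  cohen_d = 0, n_pairs = n))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p_raw = 0,
                p_bonferroni = 0, cohen_d = sign(mean(d)) * Inf,
                n_pairs = n))
  }
  tt <- t.test(m$value_a, m$value_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value,
       p_bonferroni = min(1, tt$p.value * family),
       cohen_d = mean(d) / sd(d), n_pairs = n)
}

#' Condition-controlled Spearman correlation
#'
#' Rank-transforms `x` and `y`, residualizes both rank vectors on the
#' condition indicator, and correlates the residuals - a partial Spearman
#' correlation "controlling for the condition". The p-value uses the
#' t approximation with n - 3 degrees of freedom; a condition-stratified
#' permutation p-value is available.
#'
#' @param x,y numeric vectors (length >= 4)
#' @param condition factor-like vector (e.g. normal/enhanced)
#' @param method `"approx"` (t approximation) or `"permutation"`
#' @param n_perm permutations for `method = "permutation"`
#' @param seed RNG seed for the permutation draw
#' @return `list(rho, p)`
#' @export
partial_spearman <- function(x, y, condition, method = c("approx",
                                                         "permutation"),
                             n_perm = 5000, seed = 1L) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y) & !is.na(condition)
  x <- x[ok]; y <- y[ok]; condition <- factor(condition[ok])
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  rho_of <- function(xr, yr) {
    rx <- resid(lm(rank(xr) ~ condition))
    ry <- resid(lm(rank(yr) ~ condition))
    if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
    stats::cor(rx, ry)
  }
  rho <- rho_of(x, y)
  if (method == "approx") {
    df <- n - 3
    tv <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * pt(-abs(tv), df)
  } else {
    set.seed(seed)
    null <- replicate(n_perm, {
      yp <- y
      for (lev in levels(condition)) {
        i <- which(condition == lev)
        yp[i] <- y[sample(i)]
      }
      rho_of(x, yp)
    })
    p <- (1 + sum(abs(null) >= abs(rho), na.rm = TRUE)) / (1 + n_perm)
  }
  list(rho = rho, p = p)
}
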