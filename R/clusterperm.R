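#' Spatiotemporal cluster-based permutation test (paired design)
#'
#' Compares two within-subject conditions across a channels x time grid
#' while controlling the family-wise error rate: a paired t value is
#' computed per (channel, time) point; points exceeding the two-tailed
#' cluster-forming threshold are grouped into spatiotemporally connected
#' clusters (temporal contiguity plus spatial adjacency, separately by
#' sign); each cluster's mass is the sum of its member t values; and the
#' observed masses are referred to a Monte Carlo null distribution of the
#' maximum absolute cluster mass obtained by randomly exchanging the
#' condition labels within subjects (sign flips of the paired
#' differences). p-values carry the +1 correction, so the smallest
#' attainable p is `1/(n_perm + 1)`.
#'
#' @param condA,condB numeric arrays subjects x channels x time of
#'   subject-level condition means (same subjects, same order)
#' @param adjacency a [build_adjacency()] object covering the channels
#' @param labels channel labels for the second array dimension; defaults
#'   to `dimnames` or the adjacency labels
#' @param n_perm number of random label exchanges (default 5000), or the
#'   string `"all"` for exhaustive enumeration of all `2^n` sign patterns
#'   (exact test, feasible for small n)
#' @param alpha cluster significance level
#' @param cf_alpha two-tailed cluster-forming threshold (per-point paired
#'   t at this level)
#' @param seed RNG seed for the Monte Carlo draw
#' @return object of class `gw_cluster_result`: `clusters` (list of
#'   `members` (channel, time index pairs), `polarity`, `mass`, `p`),
#'   `tmap` (channels x time t values), `null_max` (the permutation
#'   distribution), `n_perm`, `t_crit`, `seed`, `sig_mask`
#' @export
cluster_test <- function(condA, condB, adjacency, labels = NULL,
                         n_perm = 5000, alpha = 0.05, cf_alpha = 0.05,
                         seed = 1L) {
  if (!identical(dim(condA), dim(condB)))
    stop("condition arrays must have identical dimensions")
  ns <- dim(condA)[1]; nc <- dim(condA)[2]; nt <- dim(condA)[3]
  if (ns < 2) stop("paired cluster test needs at least 2 subjects")
  if (is.null(labels)) labels <- dimnames(condA)[[2]]
  if (is.null(labels)) {
    if (nc != length(adjacency$labels))
      stop("cannot align channels with adjacency: provide labels")
    labels <- adjacency$labels
  }
  amat <- adjacency$matrix[labels, labels, drop = FALSE]

  D <- matrix(condA - condB, nrow = ns)        # subjects x (nc*nt)
  t_crit <- qt(1 - cf_alpha / 2, df = ns - 1)
  SS <- colSums(D^2)                            # sign-flip invariant

  v_floor <- max(1e-300, 1e-14 * mean(SS) / ns)
  t_from_signs <- function(sgn) {               # sgn: n_draws x ns
    m <- (sgn %*% D) / ns
    v <- (rep(1, nrow(sgn)) %o% SS - ns * m^2) / (ns - 1)
    v[v < v_floor] <- v_floor
    m / sqrt(v / ns)
  }

  tobs <- t_from_signs(matrix(1, 1, ns))[1, ]
  tmap <- matrix(tobs, nc, nt, dimnames = list(labels, NULL))
  obs <- find_clusters(tmap, t_crit, amat)

  if (identical(n_perm, "all")) {
    if (ns > 16) stop("exhaustive enumeration limited to <= 16 subjects")
    sgn <- as.matrix(expand.grid(rep(list(c(-1, 1)), ns)))
    exact <- TRUE
  } else {
    set.seed(seed)
    sgn <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE),
                  n_perm, ns)
    exact <- FALSE
  }
  null_max <- numeric(nrow(sgn))
  chunk <- max(1L, floor(2e6 / (nc * nt)))
  for (a in seq(1, nrow(sgn), by = chunk)) {
    b <- min(nrow(sgn), a + chunk - 1L)
    tp <- t_from_signs(sgn[a:b, , drop = FALSE])
    for (r in seq_len(b - a + 1L)) {
      tm <- matrix(tp[r, ], nc, nt)
      null_max[a + r - 1L] <- max_cluster_mass(tm, t_crit, amat)
    }
  }
  nperm_eff <- nrow(sgn)
  for (k in seq_along(obs)) {
    m <- abs(obs[[k]]$mass)
    obs[[k]]$p <- if (exact) mean(null_max >= m)
    else (1 + sum(null_max >= m)) / (1 + nperm_eff)
  }
  sig <- matrix(FALSE, nc, nt, dimnames = list(labels, NULL))
  for (cl in obs)
    if (cl$p < alpha) sig[cl$members] <- TRUE
  structure(list(clusters = obs, tmap = tmap, null_max = null_max,
                 n_perm = nperm_eff, t_crit = t_crit, alpha = alpha,
                 cf_alpha = cf_alpha, seed = seed, exact = exact,
                 labels = labels, sig_mask = sig),
            class = "gw_cluster_result")
}

#' @export
print.gw_cluster_result <- function(x, ...) {
  cat(sprintf("<gw_cluster_result> %d clusters, %d permutations%s\n",
              length(x$clusters), x$n_perm,
              if (x$exact) " (exhaustive)" else ""))
  for (cl in x$clusters)
    cat(sprintf("  %s mass %.1f over %d points, p = %.4g%s\n",
                cl$polarity, cl$mass, nrow(cl$members), cl$p,
                if (cl$p < x$alpha) " *" else ""))
  invisible(x)
}

# Connected components of suprathreshold points under temporal contiguity
# (same channel, adjacent time bins) and spatial adjacency (adjacent
# channels, same time bin), split by t-value sign. Implemented on
# per-channel runs of consecutive suprathreshold bins with union-find over
# runs, so cost scales with the suprathreshold count, not the grid.
find_clusters <- function(tmap, t_crit, amat) {
  out <- list()
  for (pol in c("positive", "negative")) {
    mask <- if (pol == "positive") tmap > t_crit else tmap < -t_crit
    runs <- mask_runs(mask)
    if (nrow(runs) == 0) next
    comp <- union_runs(runs, amat)
    for (cid in unique(comp)) {
      rs <- runs[comp == cid, , drop = FALSE]
      members <- do.call(rbind, lapply(seq_len(nrow(rs)), function(i)
        cbind(rs[i, "ch"], rs[i, "t0"]:rs[i, "t1"])))
      colnames(members) <- c("channel", "time")
      out[[length(out) + 1]] <- list(
        members = members, polarity = pol,
        mass = sum(tmap[members]))
    }
  }
  out
}

# fast path used inside the permutation loop
max_cluster_mass <- function(tmap, t_crit, amat) {
  best <- 0
  for (pol in 1:2) {
    mask <- if (pol == 1) tmap > t_crit else tmap < -t_crit
    if (!any(mask)) next
    runs <- mask_runs(mask)
    comp <- union_runs(runs, amat)
    sums <- vapply(seq_len(nrow(runs)), function(i)
      sum(tmap[runs[i, "ch"], runs[i, "t0"]:runs[i, "t1"]]), 0)
    mass <- abs(tapply(sums, comp, sum))
    best <- max(best, max(mass))
  }
  best
}

# runs of TRUE per row of a logical matrix -> matrix(ch, t0, t1)
mask_runs <- function(mask) {
  res <- NULL
  for (ch in which(rowSums(mask) > 0)) {
    r <- rle(mask[ch, ])
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    w <- which(r$values)
    if (length(w))
      res <- rbind(res, cbind(ch = ch, t0 = s[w], t1 = e[w]))
  }
  if (is.null(res))
    res <- matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("ch", "t0", "t1")))
  res
}

# union-find over runs: two runs connect iff their channels are spatially
# adjacent (or identical; same-channel runs are disjoint in time by
# construction so only cross-channel overlap matters) and their time
# spans overlap
union_runs <- function(runs, amat) {
  n <- nrow(runs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (runs[j, "t0"] > runs[i, "t1"] || runs[j, "t1"] < runs[i, "t0"])
        next
      if (!amat[runs[i, "ch"], runs[j, "ch"]]) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}
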