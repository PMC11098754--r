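#' Harmonize read thresholds of two samples before transport
#'
#' When two samples were quantified with different sample-specific read
#' thresholds, the higher threshold is applied to both (all counts below
#' it removed), after which both samples are renormalized to reads per
#' million. This makes the two lineage-size distributions comparable
#' before the optimal-transport mapping.
#'
#' @param x,y Data frames with a `count` column (and optionally
#'   `barcode`), or plain count vectors.
#' @param threshold_x,threshold_y The samples' read thresholds.
#' @return List with elements `x` and `y`: data frames with `count` and
#'   `rpm` columns; the applied threshold is stored in the `threshold`
#'   attribute.
#' @export
harmonize_thresholds <- function(x, y, threshold_x, threshold_y) {
  thr <- max(threshold_x, threshold_y)
  fix <- function(d) {
    if (!is.data.frame(d)) d <- data.frame(count = as.numeric(d))
    d <- d[d$count >= thr, , drop = FALSE]
    if (!nrow(d)) stop_user("threshold harmonization removed every lineage")
    d$rpm <- d$count * 1e6 / sum(d$count)
    rownames(d) <- NULL
    d
  }
  out <- list(x = fix(x), y = fix(y))
  attr(out, "threshold") <- thr
  out
}

#' lcm lineage weights for samples of unequal lineage number
#'
#' To compare a sample of `N` lineages with one of `M` lineages, each
#' lineage of the first is counted as `lcm(N, M) / N` lineage units and
#' each lineage of the second as `lcm(N, M) / M`, so both sides carry
#' exactly `lcm(N, M)` units.
#'
#' @param N,M Lineage counts (>= 1).
#' @return Named vector `c(w_x = , w_y = )` of integer-valued weights.
#' @export
lcm_weights <- function(N, M) {
  stopifnot(N >= 1, M >= 1)
  l <- lcm(N, M)
  c(w_x = l / N, w_y = l / M)
}

#' Rank-wise optimal transport between two lineage-size distributions
#'
#' Finds the transport map between two positive size distributions that
#' minimizes the summed absolute log2 fold change
#' `sum |log2 x_(i) - log2 T(x_(i))|` over all pairings of lineage units.
#' For this one-dimensional convex cost the optimum is attained by rank-
#' wise mapping: both samples are expanded to `lcm(N, M)` equal lineage
#' units ([lcm_weights()]), sorted by decreasing size, and paired unit
#' rank by unit rank. The expansion is virtual -- runs of units sharing
#' the same (source, target) lineage pair are stored once with a weight --
#' so arbitrarily large lcm values cost nothing.
#'
#' @param x,y Numeric vectors of positive lineage sizes (typically RPM),
#'   or data frames with an `rpm` column.
#' @return A `transport_result` data frame with one row per mapped pair:
#'   `x`, `y`, `weight` (lineage units), `log2fc` (`log2(y) - log2(x)`),
#'   `source_rank`, `target_rank`; attributes `N`, `M`, `w_x`, `w_y` and
#'   `cost` (total absolute cost in lineage units).
#' @export
rank_transport <- function(x, y) {
  x <- sizes_vec_(x); y <- sizes_vec_(y)
  if (min(x) <= 0 || min(y) <= 0)
    stop_user("sizes must be > 0 (apply thresholds first)")
  N <- length(x); M <- length(y)
  w <- lcm_weights(N, M)
  xs <- sort(x, decreasing = TRUE)
  ys <- sort(y, decreasing = TRUE)
  b <- sort(unique(c(seq_len(N) * w[["w_x"]], seq_len(M) * w[["w_y"]])))
  weight <- diff(c(0, b))
  src <- ceiling(b / w[["w_x"]])
  tgt <- ceiling(b / w[["w_y"]])
  out <- data.frame(x = xs[src], y = ys[tgt], weight = weight,
                    log2fc = log2(ys[tgt]) - log2(xs[src]),
                    source_rank = src, target_rank = tgt)
  structure(out, N = N, M = M, w_x = w[["w_x"]], w_y = w[["w_y"]],
            cost = sum(out$weight * abs(out$log2fc)),
            class = c("transport_result", "data.frame"))
}

#' Weighted mean log2 fold change of a transport result
#'
#' Equals the weighted mean log2 size of the target sample minus that of
#' the source sample.
#'
#' @param result A [rank_transport()] result.
#' @return A single number.
#' @export
mean_log2fc <- function(result) {
  sum(result$weight * result$log2fc) / sum(result$weight)
}

# All permutations of 1..n as an (n!) x n matrix.
permutations_ <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- permutations_(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[p], nrow(p), n - 1L))
  }))
}

#' Exhaustive-search transport oracle
#'
#' Materializes the lcm unit expansion of both samples and searches all
#' unit bijections for the minimum total absolute log2 fold-change cost.
#' Exponential in the unit count, so only usable for tiny instances; it
#' exists to certify the optimality of [rank_transport()].
#'
#' @inheritParams rank_transport
#' @param max_units Refuse instances whose lcm expansion exceeds this
#'   many units (default 9).
#' @return List with `cost` (minimal total cost, same units as the
#'   `cost` attribute of [rank_transport()]) and `mapping` (the optimal
#'   unit permutation).
#' @export
brute_force_transport <- function(x, y, max_units = 9) {
  x <- sizes_vec_(x); y <- sizes_vec_(y)
  w <- lcm_weights(length(x), length(y))
  units <- length(x) * w[["w_x"]]
  if (units > max_units)
    stop_user("instance too large for exhaustive search (", units, " units)")
  ux <- rep(sort(x, decreasing = TRUE), each = w[["w_x"]])
  uy <- rep(sort(y, decreasing = TRUE), each = w[["w_y"]])
  lx <- log2(ux); ly <- log2(uy)
  P <- permutations_(as.integer(units))
  M1 <- matrix(ly[P], nrow(P), units)
  costs <- rowSums(abs(sweep(M1, 2L, lx)))
  best <- which.min(costs)
  list(cost = costs[best], mapping = P[best, ])
}

#' Smoothed fold-change curve over lineage size, averaged over replicates
#'
#' For each replicate's transport result, the top 1% largest source
#' lineages are removed (they are few and highly variable), per-pair fold
#' changes are aggregated per source lineage, resampled by interpolation
#' onto a common log-spaced size grid, smoothed with LOWESS, and finally
#' averaged across replicates. A per-grid-point lineage density is
#' reported alongside (used as curve thickness in rank plots).
#'
#' @param results A `transport_result` or list of them (replicates).
#' @param lowess_frac LOWESS smoother span (default 0.3).
#' @param trim_top Fraction of largest source lineages removed
#'   (default 0.01, ceiling on the lineage count, source side).
#' @param n_grid Number of grid points (default 200).
#' @return A `fold_change_curve` data frame: `size`, `log2fc`,
#'   `n_lineages`; attribute `n_replicates`.
#' @export
fold_change_curve <- function(results, lowess_frac = 0.3, trim_top = 0.01,
                              n_grid = 200) {
  if (inherits(results, "transport_result")) results <- list(results)
  if (!length(results)) stop_user("no transport results given")
  per_rep <- lapply(results, function(r) {
    n_trim <- if (trim_top > 0) ceiling(trim_top * attr(r, "N")) else 0L
    r <- r[r$source_rank > n_trim, , drop = FALSE]
    if (!nrow(r)) stop_user("trim_top removed every source lineage")
    fc <- vapply(split(r, r$source_rank), function(d)
      sum(d$weight * d$log2fc) / sum(d$weight), numeric(1))
    xv <- vapply(split(r$x, r$source_rank), `[`, numeric(1), 1L)
    data.frame(x = xv, fc = fc)
  })
  lo <- max(vapply(per_rep, function(d) min(d$x), numeric(1)))
  hi <- min(vapply(per_rep, function(d) max(d$x), numeric(1)))
  if (lo >= hi) {
    lo <- min(vapply(per_rep, function(d) min(d$x), numeric(1)))
    hi <- max(vapply(per_rep, function(d) max(d$x), numeric(1)))
  }
  grid <- if (lo < hi) exp(seq(log(lo), log(hi), length.out = n_grid))
          else rep(lo, 1L)
  breaks <- exp(c(log(grid[1L]) - 1e-9,
                  (log(grid[-1L]) + log(grid[-length(grid)])) / 2,
                  log(grid[length(grid)]) + 1e-9))
  mats <- lapply(per_rep, function(d) {
    interp <- approx(log(d$x), d$fc, xout = log(grid), rule = 2,
                     ties = mean)$y
    smooth <- if (length(grid) > 2L)
      lowess(log(grid), interp, f = lowess_frac)$y else interp
    dens <- as.numeric(table(cut(d$x, breaks)))
    cbind(smooth, dens)
  })
  fc_avg <- rowMeans(vapply(mats, function(m) m[, 1L],
                            numeric(length(grid))))
  dn_avg <- rowMeans(vapply(mats, function(m) m[, 2L],
                            numeric(length(grid))))
  structure(data.frame(size = grid, log2fc = fc_avg, n_lineages = dn_avg),
            n_replicates = length(results),
            lowess_frac = lowess_frac, trim_top = trim_top,
            class = c("fold_change_curve", "data.frame"))
}

#' Lineage-density of transport fold changes
#'
#' Weighted kernel density of the per-pair log2 fold changes, each pair
#' weighted by its lineage units. A population responding uniformly shows
#' one mode; heterogeneous replenishment (a subset of lineages responding
#' strongly while others do not) shows up as multimodality.
#'
#' @param result A [rank_transport()] result.
#' @param bw Kernel bandwidth (default `"nrd0"`; a small fixed bandwidth
#'   is substituted for degenerate zero-spread inputs).
#' @param n Number of evaluation points.
#' @return Data frame with `log2fc` and `density`.
#' @export
fold_change_density <- function(result, bw = "nrd0", n = 512) {
  if (!NROW(result)) stop_user("empty transport result")
  w <- result$weight / sum(result$weight)
  fc <- result$log2fc
  if (identical(bw, "nrd0")) {
    # plug-in bandwidth from the unweighted fold changes; fixed fallback
    # for degenerate zero-spread inputs
    bw <- if (diff(range(fc)) < 1e-12) 0.01 else stats::bw.nrd0(fc)
  }
  d <- density(fc, weights = w, bw = bw, n = n)
  data.frame(log2fc = d$x, density = d$y)
}

#' Permutation null for the mean transport fold change
#'
#' Pools the two samples, reassigns sizes to the two groups at random
#' (preserving group sizes), and recomputes the mean log2 fold change of
#' the rank-wise transport for each permutation. The resulting interval
#' is the reference against which an observed mean fold change is judged:
#' replicate self-comparisons should fall inside it.
#'
#' @inheritParams rank_transport
#' @param n_perm Number of permutations.
#' @param probs Interval probabilities (default 2.5% and 97.5%).
#' @param seed Optional RNG seed.
#' @return List with `interval` (named quantiles) and `values`.
#' @export
transport_permutation_null <- function(x, y, n_perm = 200,
                                       probs = c(0.025, 0.975),
                                       seed = NULL) {
  x <- sizes_vec_(x); y <- sizes_vec_(y)
  pool <- c(x, y)
  vals <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), length(x))
    mean_log2fc(rank_transport(pool[idx], pool[-idx]))
  }, numeric(1)))
  list(interval = quantile(vals, probs), values = vals)
}
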