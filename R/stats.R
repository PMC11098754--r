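sizes_vec_ <- function(dist) {
  x <- if (is.data.frame(dist)) {
    if (!"rpm" %in% names(dist)) stop_user("expected an 'rpm' column")
    dist$rpm
  } else as.numeric(dist)
  if (!length(x)) stop_user("empty lineage-size distribution")
  if (any(!is.finite(x)) || any(x < 0)) stop_user("sizes must be finite, >= 0")
  x
}

#' Share of total output held by the largest p% of lineages
#'
#' Sums the sizes of the `ceiling(p% * N)` largest lineages and divides by
#' the total. Under equipotent growth the top 5% of lineages hold about 5%
#' of the progeny; clonal domination concentrates most of the tissue in a
#' small top percentile.
#'
#' @param dist Numeric vector of lineage sizes, or a `lineage_sizes` data
#'   frame for one sample (its `rpm` column is used).
#' @param p Percentile in (0, 100].
#' @return Fraction of total size in `[0, 1]`.
#' @export
top_percentile_share <- function(dist, p = 5) {
  x <- sizes_vec_(dist)
  if (p <= 0 || p > 100) stop_user("p must be in (0, 100]")
  k <- ceiling(p / 100 * length(x))
  sum(sort(x, decreasing = TRUE)[seq_len(k)]) / sum(x)
}

#' Orders of magnitude spanned by a size distribution
#'
#' @inheritParams top_percentile_share
#' @return `log10(max / min)` over the surviving lineages.
#' @export
size_range_orders <- function(dist) {
  x <- sizes_vec_(dist)
  if (min(x) <= 0) stop_user("all sizes must be > 0")
  log10(max(x) / min(x))
}

#' Lorenz-style cumulative lineage contribution curve
#'
#' Cumulative share of total size contributed by the largest lineages,
#' from rank 1 to rank N; the final point is (1, 1).
#'
#' @inheritParams top_percentile_share
#' @return Data frame with `rank_fraction` and `mass_fraction`.
#' @export
cumulative_contribution_curve <- function(dist) {
  x <- sort(sizes_vec_(dist), decreasing = TRUE)
  data.frame(rank_fraction = seq_along(x) / length(x),
             mass_fraction = cumsum(x) / sum(x))
}

#' Divergence summary of a lineage-size distribution
#'
#' Reports the median, mean, mean/median ratio and top-1% share -- the
#' quantities in which clonal heterogeneity manifests as the distribution
#' diverges from the equipotent regime (where the ratio is 1).
#'
#' @inheritParams top_percentile_share
#' @return A one-row data frame: `median`, `mean`, `mean_median_ratio`,
#'   `top1_share`.
#' @export
divergence_summary <- function(dist) {
  x <- sizes_vec_(dist)
  data.frame(median = median(x), mean = mean(x),
             mean_median_ratio = mean(x) / median(x),
             top1_share = top_percentile_share(x, 1))
}

#' Surviving lineage counts over time with replicate summaries
#'
#' @param sizes A `lineage_sizes` data frame (several samples).
#' @param sample_info Data frame mapping `sample` to `timepoint` (and
#'   anything else); one row per sample.
#' @return Data frame per timepoint: `timepoint`, `n_replicates`,
#'   `mean_count`, `sem` (NA when only one replicate), plus a
#'   `per_sample` attribute with the raw counts.
#' @export
lineage_count_over_time <- function(sizes, sample_info) {
  stopifnot(all(c("sample", "timepoint") %in% names(sample_info)))
  cnt <- table(sizes$sample)
  per <- data.frame(sample = names(cnt), count = as.integer(cnt))
  per$timepoint <- sample_info$timepoint[match(per$sample,
                                               sample_info$sample)]
  if (anyNA(per$timepoint))
    stop_user("sample_info lacks timepoints for some samples")
  agg <- lapply(split(per$count, per$timepoint), function(v) {
    data.frame(n_replicates = length(v), mean_count = mean(v),
               sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- cbind(timepoint = as.numeric(names(agg)), do.call(rbind, agg))
  rownames(out) <- NULL
  attr(out, "per_sample") <- per
  out
}

#' In-silico subsampling envelope of a distribution statistic
#'
#' Draws random subsets of lineages (without replacement) at a given
#' fraction, recomputes a statistic for every draw, and reports the median
#' with the 5th-95th percentile envelope. Used to ask how well a small
#' subset of starting cells recapitulates whole-tissue behaviour. The
#' statistic receives the subsampled sizes and the full vector, so both
#' internal statistics (e.g. top-percentile share) and relative ones
#' (e.g. share of total) are expressible. Read-wise binomial thinning is
#' available as an alternative to lineage-wise subsampling.
#'
#' @inheritParams top_percentile_share
#' @param fraction Fraction of lineages per draw, in (0, 1].
#' @param n_draws Number of random draws.
#' @param statistic `function(subsample, full)` returning one number;
#'   default: the subsample's share of total size.
#' @param mode `"lineages"` (default) subsamples lineages;
#'   `"reads"` thins each lineage's size binomially.
#' @param seed Optional RNG seed.
#' @return A `subsample_envelope`: list with `fraction`, `n_draws`,
#'   `median`, `lower`, `upper`, and the per-draw `values`.
#' @export
subsample_lineages <- function(dist, fraction, n_draws = 100,
                               statistic = function(sub, full)
                                 sum(sub) / sum(full),
                               mode = c("lineages", "reads"), seed = NULL) {
  x <- sizes_vec_(dist)
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction > 1) stop_user("fraction must be in (0, 1]")
  if (n_draws < 1) stop_user("n_draws must be >= 1")
  m <- floor(fraction * length(x))
  if (mode == "lineages" && m < 1)
    stop_user("fraction yields fewer than one lineage")
  vals <- with_seed(seed, vapply(seq_len(n_draws), function(i) {
    sub <- if (mode == "lineages") x[sample.int(length(x), m)]
           else rbinom(length(x), round(x), fraction)
    statistic(sub, x)
  }, numeric(1)))
  structure(list(fraction = fraction, n_draws = n_draws,
                 median = median(vals),
                 lower = unname(quantile(vals, 0.05)),
                 upper = unname(quantile(vals, 0.95)),
                 values = vals),
            class = "subsample_envelope")
}

#' @export
print.subsample_envelope <- function(x, ...) {
  cat(sprintf(
    "Subsample envelope (fraction %.3g, %d draws): %.4g [%.4g, %.4g]\n",
    x$fraction, x$n_draws, x$median, x$lower, x$upper))
  invisible(x)
}
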