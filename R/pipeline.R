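#' Count tables of barcode reads
#'
#' The central object of the quantification pipeline: a long data frame
#' with columns `sample`, `barcode`, `count` (non-negative integers), a
#' `flag` column recording why an entry was removed (`""` = alive,
#' `"cross20x"`, `"below_threshold"`, `"outlier_sample"`) and a `removed`
#' column holding the count an entry had when it was removed. Pipeline
#' stages only merge or remove mass, never create counts. Sample-specific
#' read thresholds and outlier flags live in the attributes `thresholds`
#' and `outlier_samples`.
#'
#' @param df Data frame with at least `sample`, `barcode`, `count`.
#' @return A `count_table`.
#' @export
count_table <- function(df) {
  need <- c("sample", "barcode", "count")
  if (!all(need %in% names(df)))
    stop_user("count table needs columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop_user("counts must be >= 0")
  if (any(df$count != round(df$count))) stop_user("counts must be integers")
  if (!"flag" %in% names(df)) df$flag <- ""
  if (!"removed" %in% names(df)) df$removed <- 0
  rownames(df) <- NULL
  class(df) <- unique(c("count_table", class(df)))
  df
}

alive_ <- function(tab) tab$count > 0 & tab$flag == ""

#' Error-correct observed sample indexes against the known inputs
#'
#' Assigns each observed index sequence to the unique known input index
#' within `max_distance` mismatches; observations matching no known index,
#' or not uniquely, are returned as `NA` (unassigned). The known set must
#' be unambiguous: every pair of known indexes must differ at more than
#' `2 * max_distance` positions.
#'
#' @param observed Character vector of observed index sequences.
#' @param known Character vector of known input index sequences.
#' @param max_distance Maximum Hamming distance for correction (default 1).
#' @return Character vector: for each observation the corrected known
#'   index, or `NA` if unassigned.
#' @export
correct_sample_barcodes <- function(observed, known, max_distance = 1) {
  if (length(unique(nchar(known))) != 1L)
    stop_user("known indexes must have equal length")
  if (length(known) > 1L) {
    dk <- hamming_matrix(known)
    if (min(dk[upper.tri(dk)]) <= 2 * max_distance)
      stop_user("ambiguous known index set: pairwise Hamming distance must ",
                "exceed ", 2 * max_distance)
  }
  u <- unique(observed)
  ok_len <- nchar(u) == nchar(known[1L])
  assign_u <- rep(NA_character_, length(u))
  exact <- match(u, known)
  assign_u[!is.na(exact)] <- known[exact[!is.na(exact)]]
  todo <- which(is.na(assign_u) & ok_len)
  if (length(todo)) {
    d <- hamming_matrix(u[todo], known)
    within <- d <= max_distance
    hits <- rowSums(within)
    one <- which(hits == 1L)
    assign_u[todo[one]] <- known[apply(within[one, , drop = FALSE], 1,
                                       which)]
  }
  assign_u[match(observed, u)]
}

#' Extract viral barcodes and demultiplex reads into raw counts
#'
#' Takes the first `barcode_length` bases of read 1 as the viral barcode
#' and assigns each read to a sample by error-correcting the concatenated
#' index pair against the sample sheet ([correct_sample_barcodes()]).
#' Reads whose indexes cannot be assigned are tallied in the `unassigned`
#' attribute, never silently dropped.
#'
#' @param reads A `read_set` (or data frame with `read1`, `index1`,
#'   `index2`).
#' @param sample_sheet Data frame with `sample`, `index1`, `index2`;
#'   defaults to the sheet attached to `reads`.
#' @param barcode_length Barcode length extracted from read 1 (default 50).
#' @param max_index_distance Mismatch tolerance for index correction.
#' @return A `count_table` of raw counts with attributes `unassigned`
#'   (number of unassignable reads) and `n_reads`.
#' @export
extract_barcodes <- function(reads, sample_sheet = attr(reads, "sample_sheet"),
                             barcode_length = 50, max_index_distance = 1) {
  if (is.null(sample_sheet))
    stop_user("a sample_sheet is required")
  if (any(nchar(reads$read1) < barcode_length))
    stop_user("read 1 shorter than barcode_length")
  key_obs <- paste0(reads$index1, reads$index2)
  key_known <- paste0(sample_sheet$index1, sample_sheet$index2)
  assigned_key <- correct_sample_barcodes(key_obs, key_known,
                                          max_index_distance)
  sample <- sample_sheet$sample[match(assigned_key, key_known)]
  bc <- substr(reads$read1, 1L, barcode_length)
  keep <- !is.na(sample)
  pair <- paste(sample[keep], bc[keep], sep = "\t")
  r <- rle(sort(pair))
  sp <- strsplit(r$values, "\t", fixed = TRUE)
  tab <- count_table(data.frame(
    sample = vapply(sp, `[`, "", 1L),
    barcode = vapply(sp, `[`, "", 2L),
    count = r$lengths))
  attr(tab, "unassigned") <- sum(!keep)
  attr(tab, "n_reads") <- length(keep)
  tab
}

# Split positions for the pigeonhole index: max_distance+1 contiguous
# segments; two strings within max_distance share at least one segment.
seg_bounds_ <- function(L, parts) {
  cuts <- floor(seq(0, L, length.out = parts + 1))
  list(start = cuts[-length(cuts)] + 1L, end = cuts[-1])
}

#' Cluster sequencing errors in viral barcodes
#'
#' Directional ratio-based Hamming clustering applied per sample: barcodes
#' are visited in descending count order (ties by barcode) and each
#' barcode is absorbed into an already-accepted seed if it lies within
#' `max_distance` mismatches of it and the seed's raw count is at least
#' `ratio` times its own; otherwise it becomes a seed itself. Absorbed
#' counts are added to their seed. Eligibility uses the raw
#' (pre-clustering) counts, so the result is independent of absorption
#' order. Candidate seeds are found with a pigeonhole segment index, which
#' keeps clustering near-linear in the number of distinct barcodes.
#'
#' @param tab A `count_table` of raw counts.
#' @param max_distance Maximum Hamming distance to a seed (default 2).
#' @param ratio Minimum seed/satellite count ratio for merging
#'   (default 10).
#' @return A `count_table` of clustered counts with attribute
#'   `n_merged` (named per sample).
#' @export
cluster_viral_barcodes <- function(tab, max_distance = 2, ratio = 10) {
  stopifnot(inherits(tab, "count_table"))
  out <- list(); merged <- integer()
  for (smp in unique(tab$sample)) {
    sub <- tab[tab$sample == smp & tab$count > 0, , drop = FALSE]
    bcs <- sub$barcode; cnt <- sub$count
    n <- length(bcs)
    if (n <= 1L) {
      out[[smp]] <- data.frame(sample = smp, barcode = bcs, count = cnt)
      merged[smp] <- 0L
      next
    }
    L <- nchar(bcs[1L])
    ord <- order(-cnt, bcs)
    sb <- seg_bounds_(L, max_distance + 1L)
    segs <- lapply(seq_along(sb$start), function(k)
      paste0(k, ":", substr(bcs, sb$start[k], sb$end[k])))
    m <- vapply(bcs, charToRaw, raw(L))
    env <- new.env(hash = TRUE, size = 4L * n)
    parent_of <- integer(n)  # 0 = seed
    for (i in ord) {
      cands <- integer()
      for (k in seq_along(segs))
        cands <- c(cands, get0(segs[[k]][i], envir = env,
                               ifnotfound = integer()))
      target <- 0L
      if (length(cands)) {
        cands <- unique(cands)
        d <- colSums(m[, cands, drop = FALSE] != m[, i])
        elig <- cands[d <= max_distance & cnt[cands] >= ratio * cnt[i]]
        if (length(elig)) {
          elig <- elig[order(-cnt[elig], bcs[elig])]
          target <- elig[1L]
        }
      }
      if (target > 0L) {
        parent_of[i] <- target
      } else {
        for (k in seq_along(segs)) {
          key <- segs[[k]][i]
          assign(key, c(get0(key, envir = env, ifnotfound = integer()), i),
                 envir = env)
        }
      }
    }
    newcnt <- cnt
    sat <- which(parent_of > 0L)
    if (length(sat)) {
      add <- tapply(cnt[sat], parent_of[sat], sum)
      idx <- as.integer(names(add))
      newcnt[idx] <- newcnt[idx] + as.integer(add)
      newcnt[sat] <- 0L
    }
    keep <- newcnt > 0L
    out[[smp]] <- data.frame(sample = smp, barcode = bcs[keep],
                             count = newcnt[keep])
    merged[smp] <- length(sat)
  }
  res <- count_table(do.call(rbind, out))
  attr(res, "n_merged") <- merged
  for (a in c("unassigned", "n_reads"))
    attr(res, a) <- attr(tab, a)
  res
}

#' Remove cross-sample contamination (the 20x rule)
#'
#' A barcode observed in several samples is removed from every sample in
#' which its count is 20-fold (or `factor`-fold) lower than its count in
#' some other sample: low-level occurrences of a barcode that dominates
#' elsewhere are treated as contamination. The comparison is inclusive
#' (`other >= factor * this` removes) and applied across all sample pairs.
#' Removed entries keep a `cross20x` flag and their count moves to the
#' `removed` column, so re-applying the filter is a no-op.
#'
#' @param tab A `count_table` (clustered counts).
#' @param factor Removal ratio (default 20).
#' @return The filtered `count_table`.
#' @export
filter_cross_sample <- function(tab, factor = 20) {
  stopifnot(inherits(tab, "count_table"))
  live <- which(alive_(tab))
  bc <- tab$barcode[live]
  dup <- bc %in% bc[duplicated(bc)]
  drop <- logical(length(live))
  if (any(dup)) {
    idx <- split(live[dup], bc[dup])
    for (rows in idx) {
      v <- tab$count[rows]
      for (j in seq_along(rows)) {
        if (max(v[-j]) >= factor * v[j])
          drop[match(rows[j], live)] <- TRUE
      }
    }
  }
  rows <- live[drop]
  tab$removed[rows] <- tab$count[rows]
  tab$count[rows] <- 0
  tab$flag[rows] <- "cross20x"
  tab
}

#' Sample-specific read threshold separating clones from noise counts
#'
#' True clones and residual noise barcodes (unmerged error reads,
#' leftover contamination) form distinct regimes of the per-sample count
#' distribution. The default `"valley"` method separates them on the
#' log10-count density: the lowest density mode is the noise floor, and
#' the threshold is placed at the density minimum between that mode and
#' the next one up. This locates the boundary reliably both when the
#' clone counts form a tight high plateau and when they span several
#' orders of magnitude down towards the noise floor. The `"chord"`
#' method instead returns the count just above the knee of the log-log
#' rank-count curve (the point of maximum distance below the chord
#' joining the first and last ranked points); it is adequate for
#' plateau-shaped clone regions but resolves the boundary poorly when
#' clone counts are log-spread. Either estimate is clamped to at least
#' `floor` and at most the largest count; degenerate inputs without two
#' modes (uniform counts, single barcode) fall back to the floor.
#'
#' @param counts Numeric vector of positive read counts of one sample.
#' @param floor Minimum threshold (default 2, removing singletons).
#' @param method `"valley"` (default) or `"chord"`.
#' @return The threshold: barcodes with `count < threshold` are removed.
#' @export
estimate_read_threshold <- function(counts, floor = 2,
                                    method = c("valley", "chord")) {
  method <- match.arg(method)
  counts <- counts[counts > 0]
  if (!length(counts)) stop_user("no nonzero counts in sample")
  cs <- sort(counts, decreasing = TRUE)
  n <- length(cs)
  knee_val <- -Inf
  if (n >= 3L && cs[1L] > cs[n]) {
    if (method == "valley") {
      lg <- log10(cs)
      # the bandwidth floor (0.3 decades) merges adjacent small integer
      # counts (1, 2, 3 ...) into a single noise mode
      bw <- max(stats::bw.nrd0(lg), 0.3)
      d <- density(lg, bw = bw, n = 512)
      peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
      if (length(peaks) >= 2L) {
        # upper edge of the noise mode: first grid point right of the
        # lowest-count mode where the density has decayed to 5% of that
        # mode's peak, provided another mode lies beyond it
        p1 <- peaks[1L]
        edge <- which(d$y < 0.05 * d$y[p1] & seq_along(d$y) > p1)
        if (length(edge) && any(peaks > edge[1L]))
          knee_val <- 10^d$x[edge[1L]]
      }
    } else {
      x <- log(seq_len(n)); y <- log(cs)
      chord <- y[1L] + (y[n] - y[1L]) * (x - x[1L]) / (x[n] - x[1L])
      below <- chord - y
      if (max(below) > 0) knee_val <- cs[max(which.max(below) - 1L, 1L)]
    }
  }
  min(max(knee_val, floor), cs[1L])
}

#' Apply sample-specific read thresholds
#'
#' Estimates (or reuses) per-sample thresholds and removes every barcode
#' whose count is below its sample's threshold. Thresholds already stored
#' on the table are reused, making re-application a no-op.
#'
#' @param tab A `count_table`.
#' @param thresholds Optional named vector of per-sample thresholds;
#'   default: stored thresholds, else [estimate_read_threshold()] per
#'   sample.
#' @param floor Passed to [estimate_read_threshold()].
#' @return The thresholded `count_table` with attribute `thresholds`.
#' @export
apply_read_threshold <- function(tab, thresholds = NULL, floor = 2) {
  stopifnot(inherits(tab, "count_table"))
  samples <- unique(tab$sample)
  if (is.null(thresholds)) thresholds <- attr(tab, "thresholds")
  if (is.null(thresholds)) {
    thresholds <- vapply(samples, function(smp)
      estimate_read_threshold(tab$count[tab$sample == smp & alive_(tab)],
                              floor = floor), numeric(1))
  }
  miss <- setdiff(samples, names(thresholds))
  if (length(miss))
    stop_user("no threshold for sample(s): ", paste(miss, collapse = ", "))
  rows <- which(alive_(tab) & tab$count < thresholds[tab$sample])
  tab$removed[rows] <- tab$count[rows]
  tab$count[rows] <- 0
  tab$flag[rows] <- "below_threshold"
  attr(tab, "thresholds") <- thresholds
  tab
}

#' Flag outlier samples by excess barcode overlap or low yield
#'
#' Under independent barcode draws from a library of complexity `B`, the
#' number of barcodes shared between two samples with `n_i` and `n_j`
#' surviving barcodes is approximately `Binomial(n_i, n_j / B)`. Samples
#' whose observed pairwise overlap has an upper binomial tail probability
#' below `alpha` for any partner (both partners are flagged), or whose
#' surviving lineage count or total read count falls below the floors,
#' are flagged as outliers. Flagged samples stay in the table (rows
#' flagged `outlier_sample`) but are excluded by [normalize_rpm()].
#'
#' @param tab A `count_table` with at least 3 samples.
#' @param library_size Barcode complexity `B` of the library; default: the
#'   number of distinct surviving barcodes in the table (a lower bound on
#'   `B`, hence conservative).
#' @param alpha Binomial tail level (default 1e-3).
#' @param min_lineages,min_reads Yield floors.
#' @return The `count_table` with attributes `outlier_samples` and
#'   `outlier_report`.
#' @export
detect_outlier_samples <- function(tab, library_size = NULL, alpha = 1e-3,
                                   min_lineages = 10, min_reads = 100) {
  stopifnot(inherits(tab, "count_table"))
  live <- tab[alive_(tab), , drop = FALSE]
  samples <- unique(tab$sample)
  if (length(samples) < 3L)
    stop_user("outlier detection needs at least 3 samples")
  sets <- split(live$barcode, factor(live$sample, levels = samples))
  reads <- vapply(split(live$count, factor(live$sample, levels = samples)),
                  sum, numeric(1))
  B <- if (is.null(library_size)) length(unique(live$barcode))
       else library_size
  flagged <- character(); reason <- character()
  add_flag <- function(smp, why) {
    flagged <<- c(flagged, smp); reason <<- c(reason, why)
  }
  for (smp in samples) {
    if (length(sets[[smp]]) < min_lineages)
      add_flag(smp, "low_lineage_count")
    else if (reads[[smp]] < min_reads) add_flag(smp, "low_read_count")
  }
  for (i in seq_along(samples)) for (j in seq_along(samples)) {
    if (i == j) next
    ni <- length(sets[[i]]); nj <- length(sets[[j]])
    if (ni == 0L || nj == 0L) next
    o <- length(intersect(sets[[i]], sets[[j]]))
    if (o == 0L) next
    p <- pbinom(o - 1L, ni, min(1, nj / B), lower.tail = FALSE)
    if (p < alpha) add_flag(samples[i], "excess_overlap")
  }
  report <- unique(data.frame(sample = flagged, reason = reason))
  rows <- which(tab$sample %in% report$sample & alive_(tab))
  tab$flag[rows] <- "outlier_sample"
  attr(tab, "outlier_samples") <- unique(report$sample)
  attr(tab, "outlier_report") <- report
  tab
}

#' Normalize surviving counts to reads per million and rank lineages
#'
#' Converts each sample's surviving counts to reads per million
#' (`count * 1e6 / sample total`) and assigns ranks by descending RPM,
#' ties broken by barcode so the ranking is a deterministic permutation.
#' Outlier samples and flagged entries are excluded.
#'
#' @param tab A filtered `count_table`.
#' @return A `lineage_sizes` data frame: `sample`, `barcode`, `count`,
#'   `rpm`, `rank`; carries the `thresholds` attribute along.
#' @export
normalize_rpm <- function(tab) {
  stopifnot(inherits(tab, "count_table"))
  keep <- alive_(tab) &
    !(tab$sample %in% attr(tab, "outlier_samples"))
  live <- tab[keep, c("sample", "barcode", "count")]
  if (!nrow(live)) stop_user("no surviving counts to normalize")
  parts <- lapply(split(live, live$sample), function(d) {
    tot <- sum(d$count)
    if (tot <= 0) stop_user("sample ", d$sample[1L], " has zero total")
    d$rpm <- d$count * 1e6 / tot
    ord <- order(-d$rpm, d$barcode)
    d <- d[ord, , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "thresholds") <- attr(tab, "thresholds")
  class(out) <- c("lineage_sizes", "data.frame")
  out
}
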