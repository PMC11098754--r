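# Independent oracles and fixture builders used across test files.

# Two-sample Kolmogorov-Smirnov statistic, written independently of the
# package internals (tie-safe; compared against the alpha = 0.01 critical
# value 1.628 * sqrt((n + m) / (n * m))).
ks2_oracle <- function(x, y) {
  g <- sort(unique(c(x, y)))
  Fx <- ecdf(x)(g)
  Fy <- ecdf(y)(g)
  max(abs(Fx - Fy))
}

ks2_crit <- function(n, m, alpha = 0.01) {
  stopifnot(alpha == 0.01)
  1.628 * sqrt((n + m) / (n * m))
}

# One-sample KS statistic against a discrete CDF given as a function.
ks1_oracle <- function(x, cdf) {
  g <- sort(unique(x))
  max(abs(ecdf(x)(g) - cdf(g)))
}

# Reference implementation of the directional clustering rule: full O(n^2)
# double loop over barcodes, merging b into the largest seed c with
# Hamming(b, c) <= max_distance and count(c) >= ratio * count(b), visiting
# barcodes in descending raw-count order. Used to certify the indexed
# implementation on small instances.
cluster_oracle <- function(barcodes, counts, max_distance = 2, ratio = 10) {
  hd <- function(a, b) sum(charToRaw(a) != charToRaw(b))
  ord <- order(-counts, barcodes)
  seeds <- integer()
  parent <- integer(length(barcodes))
  for (i in ord) {
    best <- 0L
    for (s in seeds) {
      if (hd(barcodes[i], barcodes[s]) <= max_distance &&
          counts[s] >= ratio * counts[i]) {
        if (best == 0L || counts[s] > counts[best] ||
            (counts[s] == counts[best] && barcodes[s] < barcodes[best]))
          best <- s
      }
    }
    if (best > 0L) parent[i] <- best else seeds <- c(seeds, i)
  }
  out <- counts
  for (i in which(parent > 0L)) {
    out[parent[i]] <- out[parent[i]] + counts[i]
    out[i] <- 0L
  }
  out
}

# Mutate exactly `k` bases of a barcode at chosen positions.
mutate_at <- function(barcode, positions) {
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    cur <- substr(barcode, p, p)
    substr(barcode, p, p) <- setdiff(bases, cur)[1L]
  }
  barcode
}

# Small standard sample sheet for read-generation tests.
toy_sheet <- function(n = 2) {
  data.frame(sample = paste0("s", seq_len(n)),
             index1 = c("ACGTACGT", "TTGGCCAA", "GACTGACT")[seq_len(n)],
             index2 = c("GGAATTCC", "CATGCATG", "TGCATGCA")[seq_len(n)])
}
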