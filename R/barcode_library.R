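#' Generate a semi-random viral barcode library
#'
#' Builds a library of fixed-length nucleotide barcodes. A short library
#' identifier sequence is embedded at a fixed position in every barcode so
#' that reads can be attributed to their library by an exact identifier
#' match; all remaining positions are independent uniform draws from
#' A/C/G/T. Alternatively an explicit design `pattern` may fix arbitrary
#' positions (non-`N` characters) and randomize the `N` positions.
#'
#' @param n Number of distinct barcodes to generate.
#' @param length Barcode length in bases (default 50).
#' @param library_id Character label of the library.
#' @param identifier Library identifier sequence embedded in every barcode.
#'   Give each co-used library a distinct identifier.
#' @param identifier_start 1-based position at which the identifier starts.
#' @param pattern Optional design string of length `length` over
#'   `A/C/G/T/N`; overrides `identifier`/`identifier_start`.
#' @param seed Optional RNG seed.
#' @return An object of class `barcode_library`: list with `library_id`,
#'   `identifier`, `identifier_start`, `pattern` and the character vector
#'   `barcodes`.
#' @examples
#' lib <- generate_barcode_library(5, length = 20, library_id = "L1",
#'                                 identifier = "ACGT", seed = 1)
#' lib$barcodes
#' @export
generate_barcode_library <- function(n, length = 50, library_id = "lib1",
                                     identifier = "GTCAGT",
                                     identifier_start = 1,
                                     pattern = NULL, seed = NULL) {
  if (n < 1) stop_user("n must be >= 1")
  if (is.null(pattern)) {
    if (nchar(identifier) > length)
      stop_user("identifier longer than barcode length")
    if (identifier_start + nchar(identifier) - 1 > length)
      stop_user("identifier does not fit at identifier_start")
    pattern <- strrep("N", length)
    substr(pattern, identifier_start,
           identifier_start + nchar(identifier) - 1) <- identifier
  } else {
    if (nchar(pattern) != length)
      stop_user("pattern length must equal barcode length")
    if (grepl("[^ACGTN]", pattern))
      stop_user("pattern may only contain A, C, G, T, N")
    id_match <- regexpr("[ACGT]+", pattern)
    identifier <- if (id_match > 0)
      substr(pattern, id_match, id_match + attr(id_match, "match.length") - 1)
      else ""
    identifier_start <- max(1L, as.integer(id_match))
  }
  pat <- strsplit(pattern, "")[[1]]
  rnd <- which(pat == "N")
  if (length(rnd) * log(4) < log(n))
    stop_user("n exceeds the design space of the random positions")

  bases <- c("A", "C", "G", "T")
  barcodes <- with_seed(seed, {
    draw <- function(m) {
      mat <- matrix(pat, nrow = length(pat), ncol = m)
      mat[rnd, ] <- sample(bases, length(rnd) * m, replace = TRUE)
      apply(mat, 2, paste, collapse = "")
    }
    out <- draw(n)
    # resample collisions until all barcodes are unique
    while (anyDuplicated(out)) {
      dup <- which(duplicated(out))
      out[dup] <- draw(length(dup))
    }
    out
  })
  structure(list(library_id = library_id, identifier = identifier,
                 identifier_start = as.integer(identifier_start),
                 pattern = pattern, barcodes = barcodes),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("Barcode library '%s': %d barcodes of length %d, identifier %s @%d\n",
              x$library_id, length(x$barcodes), nchar(x$barcodes[1]),
              x$identifier, x$identifier_start))
  invisible(x)
}

#' Pairwise Hamming-distance histogram of barcode sets
#'
#' Exact histogram of pairwise Hamming distances, either within one set of
#' equal-length barcodes (all unordered pairs) or between two sets (all
#' cross pairs). High, tightly distributed distances indicate a complex,
#' well-separated library; a mode near zero reveals duplicated or
#' error-derived barcodes.
#'
#' @param a Character vector of equal-length barcodes.
#' @param b Optional second set; if given, cross-set distances are counted.
#' @return Data frame with columns `distance` and `count` (exact pair
#'   counts; distances with zero count are omitted).
#' @export
hamming_distance_distribution <- function(a, b = NULL) {
  if (length(unique(nchar(c(a, b)))) != 1L)
    stop_user("all barcodes must have equal length")
  if (is.null(b)) {
    d <- hamming_matrix(a)
    vals <- d[upper.tri(d)]
  } else {
    vals <- as.vector(hamming_matrix(a, b))
  }
  tt <- table(vals)
  data.frame(distance = as.integer(names(tt)), count = as.integer(tt))
}
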