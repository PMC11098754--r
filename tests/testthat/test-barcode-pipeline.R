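test_that("sample-index correction assigns unique neighbors only", {
  known <- c("AAAAAA", "TTTTTT", "GGGGCC")
  expect_equal(correct_sample_barcodes("AAAAAA", known), "AAAAAA")
  expect_equal(correct_sample_barcodes("AAAAAC", known), "AAAAAA")
  expect_true(is.na(correct_sample_barcodes("AAATTT", known)))
  expect_equal(correct_sample_barcodes(c("TTTTTA", "GGGGCC", "CCCCCC"),
                                       known),
               c("TTTTTT", "GGGGCC", NA))
  # ambiguous known set (distance 2 apart with max_distance 1) is rejected
  expect_error(correct_sample_barcodes("AAAAAA", c("AAAAAA", "AAAACC")),
               "ambiguous")
})

test_that("barcode extraction demultiplexes and routes unassignables", {
  sheet <- toy_sheet(2)
  reads <- data.frame(
    read1 = c(strrep("A", 50), strrep("C", 50), strrep("G", 50)),
    index1 = c(sheet$index1[1], mutate_at(sheet$index1[2], 1),
               mutate_at(sheet$index1[1], 1:3)),
    index2 = c(sheet$index2[1], sheet$index2[2], sheet$index2[1]))
  tab <- extract_barcodes(reads, sheet)
  expect_s3_class(tab, "count_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$count[tab$sample == "s1"], 1)
  expect_equal(tab$count[tab$sample == "s2"], 1)
  expect_equal(attr(tab, "unassigned"), 1)
  expect_equal(attr(tab, "n_reads"), 3)
})

test_that("error-free extraction reproduces the multinomial draw exactly", {
  lib <- generate_barcode_library(20, length = 50, library_id = "L",
                                  identifier = "GTCAGT", seed = 11)
  clones <- data.frame(sample = rep(c("s1", "s2"), each = 10),
                       barcode = lib$barcodes,
                       cells = rep(c(5, 50, 500, 20, 200), 4))
  reads <- generate_reads(clones, toy_sheet(2), depth = 5e4, seed = 12)
  tab <- extract_barcodes(reads)
  truth <- attr(reads, "truth")
  want <- table(paste(truth$true_sample, truth$barcode))
  got <- setNames(tab$count, paste(tab$sample, tab$barcode))
  expect_equal(sort(names(got)), sort(names(want)))
  expect_equal(as.integer(got[names(want)]), as.integer(want))
  expect_equal(attr(tab, "unassigned"), 0)
})

test_that("directional clustering merges satellites into large seeds", {
  seed_bc <- strrep("A", 30)
  sat <- mutate_at(seed_bc, 7)
  far <- paste0(strrep("T", 10), strrep("A", 20))
  tab <- count_table(data.frame(sample = "s1",
                                barcode = c(seed_bc, sat, far),
                                count = c(1000, 5, 900)))
  cl <- cluster_viral_barcodes(tab)
  expect_equal(cl$count[cl$barcode == seed_bc], 1005)
  expect_false(sat %in% cl$barcode)
  # similar counts at distance 10: never merged
  expect_equal(cl$count[cl$barcode == far], 900)
  expect_equal(unname(attr(cl, "n_merged")["s1"]), 1L)

  one <- cluster_viral_barcodes(count_table(data.frame(
    sample = "s1", barcode = seed_bc, count = 7)))
  expect_equal(one$count, 7)
})

test_that("indexed clustering equals the exhaustive reference rule", {
  set.seed(13)
  base <- generate_barcode_library(12, length = 20, library_id = "L",
                                   identifier = "AC", seed = 14)$barcodes
  # satellites at distance 1-3 around seeds with assorted counts
  bcs <- base
  cnt <- sample(c(1000, 500, 80, 40), 12, replace = TRUE)
  for (i in 1:12) {
    k <- sample(1:3, 1)
    bcs <- c(bcs, mutate_at(base[i], sample(3:20, k)))
    cnt <- c(cnt, sample(c(1, 3, 9, 60), 1))
  }
  expected <- cluster_oracle(bcs, cnt)
  tab <- count_table(data.frame(sample = "s1", barcode = bcs, count = cnt))
  got <- cluster_viral_barcodes(tab)
  keep <- expected > 0
  expect_equal(setNames(got$count, got$barcode)[bcs[keep]],
               setNames(expected[keep], bcs[keep]))
})

test_that("the 20x cross-sample rule uses the inclusive boundary", {
  mk <- function(a, b) count_table(data.frame(
    sample = c("A", "B"), barcode = "X", count = c(a, b)))
  t1 <- filter_cross_sample(mk(5, 100))
  expect_equal(t1$count, c(0, 100))
  expect_equal(t1$flag, c("cross20x", ""))
  expect_equal(t1$removed, c(5, 0))
  t2 <- filter_cross_sample(mk(6, 100))
  expect_equal(t2$count, c(6, 100))
  solo <- filter_cross_sample(count_table(data.frame(
    sample = "A", barcode = "X", count = 3)))
  expect_equal(solo$count, 3)
  # idempotence
  expect_identical(filter_cross_sample(t1), t1)
})

test_that("knee thresholds separate clones from noise", {
  set.seed(15)
  cnts <- c(round(rnorm(100, 1e4, 300)), sample(1:10, 1e4, replace = TRUE))
  th <- estimate_read_threshold(cnts)
  expect_gt(th, 10)
  expect_lt(th, 1e4)
  expect_equal(sum(cnts >= th), 100)
  expect_equal(estimate_read_threshold(rep(50, 20)), 2)
  expect_lte(estimate_read_threshold(777), 777)
  expect_lte(estimate_read_threshold(1), 1)
  expect_error(estimate_read_threshold(numeric()), "nonzero")
})

test_that("threshold application removes sub-threshold counts once", {
  tab <- count_table(data.frame(
    sample = rep(c("A", "B"), each = 3),
    barcode = c("X", "Y", "Z", "X", "Y", "Z"),
    count = c(100, 40, 1, 9, 8, 200)))
  out <- apply_read_threshold(tab, thresholds = c(A = 10, B = 9))
  expect_equal(out$count, c(100, 40, 0, 9, 0, 200))
  expect_equal(out$flag[3], "below_threshold")
  expect_true(all(out$count[out$flag == ""] >=
                    attr(out, "thresholds")[out$sample[out$flag == ""]]))
  # stored thresholds make re-application a no-op
  expect_identical(apply_read_threshold(out), out)
})

test_that("outlier detection flags copies, not expected overlap", {
  bc <- sprintf("BC%04d", 1:400)
  disjoint <- count_table(data.frame(
    sample = rep(c("a", "b", "c"), each = 100),
    barcode = bc[1:300], count = 100))
  expect_length(attr(detect_outlier_samples(disjoint, library_size = 1e5),
                     "outlier_samples"), 0)

  copied <- count_table(data.frame(
    sample = rep(c("a", "b", "c"), each = 100),
    barcode = bc[c(1:100, 1:100, 201:300)], count = 100))
  out <- detect_outlier_samples(copied, library_size = 1e5)
  expect_setequal(attr(out, "outlier_samples"), c("a", "b"))
  expect_true(all(out$flag[out$sample %in% c("a", "b")] ==
                    "outlier_sample"))

  # overlap at the analytic expectation n_i * n_j / B is tolerated
  B <- 1000
  exp_overlap <- round(100 * 100 / B)  # 10 shared barcodes
  expected <- count_table(data.frame(
    sample = rep(c("a", "b", "c"), each = 100),
    barcode = bc[c(1:100, c(1:exp_overlap, 111:200), 211:310)],
    count = 100))
  out2 <- detect_outlier_samples(expected, library_size = B)
  expect_length(attr(out2, "outlier_samples"), 0)

  low <- count_table(data.frame(
    sample = c(rep("a", 100), rep("b", 100), "c"),
    barcode = bc[c(1:100, 101:200, 301)], count = 100))
  expect_equal(attr(detect_outlier_samples(low, library_size = 1e5),
                    "outlier_samples"), "c")
  expect_error(detect_outlier_samples(count_table(data.frame(
    sample = c("a", "b"), barcode = c("X", "Y"), count = 1))),
    "at least 3")
})

test_that("RPM normalization and ranking are exact and deterministic", {
  tab <- count_table(data.frame(sample = "s", barcode = c("B", "A"),
                                count = c(10, 30)))
  rpm <- normalize_rpm(tab)
  expect_equal(sort(rpm$rpm), c(250000, 750000))
  expect_equal(rpm$barcode[rpm$rank == 1], "A")
  expect_equal(sum(rpm$rpm), 1e6)
  # insertion order does not change ranks
  tab2 <- count_table(data.frame(sample = "s", barcode = c("A", "B"),
                                 count = c(30, 10)))
  rpm2 <- normalize_rpm(tab2)
  expect_equal(rpm[order(rpm$barcode), c("barcode", "rpm", "rank")],
               rpm2[order(rpm2$barcode), c("barcode", "rpm", "rank")],
               ignore_attr = TRUE)
  # ties broken lexicographically
  tie <- normalize_rpm(count_table(data.frame(
    sample = "s", barcode = c("Q", "C", "Z"), count = c(5, 5, 5))))
  expect_equal(tie$barcode, c("C", "Q", "Z"))
  expect_equal(tie$rank, 1:3)
})

test_that("Hamming histograms are exact at the edges", {
  expect_equal(hamming_distance_distribution(c("ACGT", "ACGT")),
               data.frame(distance = 0L, count = 1L))
  expect_equal(hamming_distance_distribution("ACGT", "TGCA"),
               data.frame(distance = 4L, count = 1L))
  expect_error(hamming_distance_distribution(c("ACGT", "ACGTA")),
               "equal length")
})

test_that("pipeline stages only remove or merge mass, never create it", {
  lib <- generate_barcode_library(40, length = 50, library_id = "L",
                                  identifier = "GTCAGT", seed = 16)
  clones <- data.frame(sample = rep(c("s1", "s2"), each = 20),
                       barcode = lib$barcodes,
                       cells = rep(round(10^seq(1, 3, length.out = 20)), 2))
  reads <- generate_reads(clones, toy_sheet(2), depth = 3e4,
                          substitution_rate = 0.01,
                          cross_sample_rate = 0.005, seed = 17)
  raw <- extract_barcodes(reads)
  expect_equal(sum(raw$count) + attr(raw, "unassigned"), nrow(reads))
  cl <- cluster_viral_barcodes(raw)
  expect_equal(sum(cl$count), sum(raw$count))
  expect_equal(nrow(raw), nrow(cl) + sum(attr(cl, "n_merged")))
  fc <- filter_cross_sample(cl)
  expect_lte(sum(fc$count), sum(cl$count))
  th <- apply_read_threshold(fc)
  expect_lte(sum(th$count), sum(fc$count))
  expect_equal(sum(th$count) + sum(th$removed), sum(cl$count))
})
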