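#' Read and write barcode sequencing reads as FASTQ triplets
#'
#' A `read_set` is stored as three FASTQ files following the Illumina
#' convention: read 1 (the viral barcode read) plus the two index reads,
#' with one record per read in identical order. Qualities are constant
#' placeholders ("I"): the quantification is count-based and never uses
#' base qualities. Gzip-compressed files are read transparently.
#'
#' @param reads A `read_set` data frame (`read1`, `index1`, `index2`).
#' @param prefix Output path prefix; files `<prefix>_R1.fastq`,
#'   `<prefix>_I1.fastq`, `<prefix>_I2.fastq` are written.
#' @return `write_fastq()` returns the three paths invisibly;
#'   `read_fastq()` returns a `read_set`.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, "_", c("R1", "I1", "I2"), ".fastq")
  cols <- c("read1", "index1", "index2")
  ids <- sprintf("read%d", seq_len(nrow(reads)))
  for (i in seq_along(cols)) {
    x <- Biostrings::DNAStringSet(reads[[cols[i]]])
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq",
                                qualities = q)
  }
  invisible(paths)
}

#' @rdname write_fastq
#' @param r1,i1,i2 Paths of the three FASTQ files.
#' @export
read_fastq <- function(r1, i1, i2) {
  rd <- function(p) {
    con <- gzfile(p, "r")
    n_lines <- 0L
    repeat {
      chunk <- readLines(con, n = 65536L)
      if (!length(chunk)) break
      n_lines <- n_lines + length(chunk)
    }
    close(con)
    if (n_lines %% 4L != 0L)
      stop_user("malformed FASTQ '", p, "': truncated record at line ",
                n_lines)
    x <- tryCatch(Biostrings::readDNAStringSet(p, format = "fastq"),
                  error = function(e)
                    stop_user("malformed FASTQ '", p, "': ",
                              conditionMessage(e)))
    as.character(x)
  }
  a <- rd(r1); b <- rd(i1); c_ <- rd(i2)
  if (length(unique(c(length(a), length(b), length(c_)))) != 1L)
    stop_user("FASTQ files carry different record counts")
  out <- data.frame(read1 = unname(a), index1 = unname(b),
                    index2 = unname(c_))
  class(out) <- c("read_set", "data.frame")
  out
}

#' Read and write count tables as TSV
#'
#' Tab-delimited UTF-8 with header `sample`, `barcode`, `count`, `flag`,
#' `removed`. Counts must be plain non-negative integers (scientific
#' notation and negative values are rejected). Thresholds travel in a
#' separate two-column TSV (`sample`, `threshold`).
#'
#' @param tab A `count_table`.
#' @param path Output/input TSV path.
#' @param thresholds_path Optional path of the thresholds TSV.
#' @return `read_counts_tsv()` returns a `count_table`;
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
write_counts_tsv <- function(tab, path, thresholds_path = NULL) {
  stopifnot(inherits(tab, "count_table"))
  utils::write.table(as.data.frame(tab)[c("sample", "barcode", "count",
                                          "flag", "removed")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  thr <- attr(tab, "thresholds")
  if (!is.null(thresholds_path) && !is.null(thr)) {
    utils::write.table(data.frame(sample = names(thr), threshold = thr),
                       thresholds_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, thresholds_path = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  for (col in c("sample", "barcode", "count"))
    if (!col %in% names(df))
      stop_user("counts TSV is missing required column '", col, "'")
  for (col in c("count", if ("removed" %in% names(df)) "removed"))
    if (any(!grepl("^[0-9]+$", df[[col]])))
      stop_user("column '", col,
                "' must contain plain non-negative integers")
  df$count <- as.numeric(df$count)
  if ("removed" %in% names(df)) df$removed <- as.numeric(df$removed)
  if ("flag" %in% names(df)) df$flag[is.na(df$flag)] <- ""
  tab <- count_table(df)
  if (!is.null(thresholds_path)) {
    thr <- utils::read.delim(thresholds_path)
    attr(tab, "thresholds") <- stats::setNames(thr$threshold, thr$sample)
  }
  tab
}

#' Write per-sample RPM lineage sizes as TSV
#'
#' RPM values are written with six decimal places.
#'
#' @param sizes A `lineage_sizes` data frame.
#' @param path Output path.
#' @export
write_rpm_tsv <- function(sizes, path) {
  out <- as.data.frame(sizes)
  out$rpm <- sprintf("%.6f", out$rpm)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

config_schema_ <- list(
  top = c("seed", "out_dir", "simulate", "generate", "count", "filter",
          "stats", "compare"),
  simulate = c("r_s", "r_a", "r_n", "r_dn", "k", "variant", "t_end",
               "n_lineages", "record_times"),
  generate = c("n_barcodes", "barcode_length", "library_id", "identifier",
               "identifier_start", "samples", "depth", "substitution_rate",
               "cross_sample_rate"),
  count = c("barcode_length", "max_index_distance"),
  filter = c("cluster_max_distance", "cluster_ratio", "cross_factor",
             "threshold_floor", "outlier_alpha", "outlier_min_lineages",
             "outlier_min_reads", "library_size"),
  stats = c("top_percentiles"),
  compare = c("pairs", "lowess_frac", "trim_top"))

#' Validate a pipeline run configuration
#'
#' Checks a configuration (a nested list, or a YAML file path) against the
#' documented schema before any computation: unknown keys are rejected,
#' stage parameters must lie in their documented ranges.
#'
#' @param config A nested list or path of a YAML file.
#' @return The validated configuration list, invisibly classed
#'   `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_user("config must be a list or a YAML path")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop_user("unknown config key(s) in ", where, ": ",
                paste(bad, collapse = ", "))
  }
  check_keys(config, config_schema_$top, "top level")
  for (sec in intersect(names(config), names(config_schema_)[-1]))
    check_keys(config[[sec]], config_schema_[[sec]], sec)
  if (!is.null(config$generate)) {
    g <- config$generate
    if (!is.null(g$substitution_rate) &&
        (g$substitution_rate < 0 || g$substitution_rate > 1))
      stop_user("generate$substitution_rate must be in [0, 1]")
    if (!is.null(g$cross_sample_rate) &&
        (g$cross_sample_rate < 0 || g$cross_sample_rate > 1))
      stop_user("generate$cross_sample_rate must be in [0, 1]")
    if (!is.null(g$depth) && g$depth < 1)
      stop_user("generate$depth must be >= 1")
  }
  class(config) <- c("run_config", class(config))
  invisible(config)
}

log_line_ <- function(con, stage, ...) {
  kv <- c(...)
  writeLines(paste0("stage=", stage, " ",
                    paste(names(kv), unname(kv), sep = "=",
                          collapse = " ")), con)
}

#' Run the full synthetic-data + quantification pipeline
#'
#' Executes the configured stages in fixed order -- simulate clonal
#' growth, generate barcode libraries and reads, count, filter (cluster,
#' cross-sample 20x rule, thresholds, outliers), summarize, compare --
#' writing TSV/FASTQ artifacts, a `key=value` log with per-stage removal
#' tallies, and a manifest of all parameters and seeds to `out_dir`.
#' Outputs are deterministic given the configured seed.
#'
#' @param config A configuration accepted by [read_run_config()].
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return Invisibly, a list with the main in-memory objects (`sim`,
#'   `reads`, `counts`, `filtered`, `rpm`, `stats`, `transports`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_run_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop_user("an out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  con <- file(logf, "w")
  on.exit(close(con))
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  res <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_user("stage '", name, "' failed: ", conditionMessage(e)))
  }

  if (!is.null(config$simulate)) {
    res$sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- seed
      p <- do.call(model_params, args)
      sim <- simulate_organoid(p)
      utils::write.table(sim$states, file.path(out_dir, "lineages.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_line_(con, "simulate", n_lineages = p$n_lineages,
                t_end = p$t_end)
      sim
    })
  }

  if (!is.null(config$generate)) {
    res$reads <- stage("generate", {
      g <- config$generate
      if (is.null(res$sim)) stop("generate requires a simulate stage")
      lib <- generate_barcode_library(
        n = if (is.null(g$n_barcodes)) res$sim$params$n_lineages
            else g$n_barcodes,
        length = if (is.null(g$barcode_length)) 50 else g$barcode_length,
        library_id = if (is.null(g$library_id)) "lib1" else g$library_id,
        identifier = if (is.null(g$identifier)) "GTCAGT" else g$identifier,
        seed = seed + 1L)
      sheet <- do.call(rbind, lapply(g$samples, as.data.frame))
      clones <- clones_from_simulation(res$sim, lib)
      reads <- generate_reads(
        clones, sheet, depth = g$depth,
        substitution_rate = if (is.null(g$substitution_rate)) 0
                            else g$substitution_rate,
        cross_sample_rate = if (is.null(g$cross_sample_rate)) 0
                            else g$cross_sample_rate,
        seed = seed + 2L)
      write_fastq(reads, file.path(out_dir, "reads"))
      utils::write.table(clones, file.path(out_dir, "clones_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_line_(con, "generate", n_reads = nrow(reads),
                n_samples = nrow(sheet))
      reads
    })
  }

  if (!is.null(config$count) && !is.null(res$reads)) {
    res$counts <- stage("count", {
      cc <- config$count
      tab <- extract_barcodes(
        res$reads,
        barcode_length = if (is.null(cc$barcode_length)) 50
                         else cc$barcode_length,
        max_index_distance = if (is.null(cc$max_index_distance)) 1
                             else cc$max_index_distance)
      write_counts_tsv(tab, file.path(out_dir, "counts_raw.tsv"))
      log_line_(con, "count", reads = attr(tab, "n_reads"),
                assigned = attr(tab, "n_reads") - attr(tab, "unassigned"),
                unassigned = attr(tab, "unassigned"))
      tab
    })
  }

  if (!is.null(config$filter) && !is.null(res$counts)) {
    out <- stage("filter", {
      ff <- config$filter
      gv <- function(key, def) if (is.null(ff[[key]])) def else ff[[key]]
      tab <- cluster_viral_barcodes(res$counts,
                                    max_distance = gv("cluster_max_distance", 2),
                                    ratio = gv("cluster_ratio", 10))
      merged <- sum(attr(tab, "n_merged"))
      tab <- filter_cross_sample(tab, factor = gv("cross_factor", 20))
      n_cross <- sum(tab$flag == "cross20x")
      tab <- apply_read_threshold(tab, floor = gv("threshold_floor", 2))
      n_thr <- sum(tab$flag == "below_threshold")
      if (length(unique(tab$sample)) >= 3L) {
        tab <- detect_outlier_samples(
          tab, library_size = ff$library_size,
          alpha = gv("outlier_alpha", 1e-3),
          min_lineages = gv("outlier_min_lineages", 10),
          min_reads = gv("outlier_min_reads", 100))
      }
      rpm <- normalize_rpm(tab)
      write_counts_tsv(tab, file.path(out_dir, "counts_filtered.tsv"),
                       file.path(out_dir, "thresholds.tsv"))
      write_rpm_tsv(rpm, file.path(out_dir, "rpm.tsv"))
      log_line_(con, "filter", cluster_merged = merged,
                cross20x_removed = n_cross, below_threshold = n_thr,
                outliers = length(attr(tab, "outlier_samples")),
                surviving = sum(alive_(tab)))
      list(filtered = tab, rpm = rpm)
    })
    res$filtered <- out$filtered
    res$rpm <- out$rpm
  }

  if (!is.null(config$stats) && !is.null(res$rpm)) {
    res$stats <- stage("stats", {
      ps <- config$stats$top_percentiles
      if (is.null(ps)) ps <- c(1, 5)
      st <- do.call(rbind, lapply(split(res$rpm, res$rpm$sample),
        function(d) {
          row <- divergence_summary(d$rpm)
          for (p in ps)
            row[[paste0("top", p, "_share")]] <-
              top_percentile_share(d$rpm, p)
          row$size_orders <- size_range_orders(d$rpm)
          cbind(sample = d$sample[1L], row)
        }))
      utils::write.table(st, file.path(out_dir, "stats.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log_line_(con, "stats", n_samples = nrow(st))
      st
    })
  }

  if (!is.null(config$compare) && !is.null(res$rpm)) {
    res$transports <- stage("compare", {
      cp <- config$compare
      thr <- attr(res$rpm, "thresholds")
      outs <- lapply(cp$pairs, function(pr) {
        pr <- unlist(pr)
        dx <- res$rpm[res$rpm$sample == pr[1L], ]
        dy <- res$rpm[res$rpm$sample == pr[2L], ]
        h <- harmonize_thresholds(dx, dy, thr[pr[1L]], thr[pr[2L]])
        tr <- rank_transport(h$x$rpm, h$y$rpm)
        base <- file.path(out_dir,
                          paste0("transport_", pr[1L], "_vs_", pr[2L]))
        utils::write.table(as.data.frame(tr), paste0(base, ".tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        crv <- fold_change_curve(
          tr,
          lowess_frac = if (is.null(cp$lowess_frac)) 0.3
                        else cp$lowess_frac,
          trim_top = if (is.null(cp$trim_top)) 0.01 else cp$trim_top)
        utils::write.table(as.data.frame(crv), paste0(base, "_curve.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        dns <- fold_change_density(tr)
        utils::write.table(dns, paste0(base, "_density.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        tr
      })
      log_line_(con, "compare", n_pairs = length(outs))
      outs
    })
  }

  manifest <- list(package = "clonetrace",
                   version = as.character(utils::packageVersion("clonetrace")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed,
                   config = unclass(config))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}
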