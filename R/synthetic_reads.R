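#' Attach library barcodes to simulated lineages
#'
#' Assigns one library barcode to every simulated lineage (a bijection in
#' lineage order) and tabulates the true clone size (cell count) of each
#' barcode at the requested record times.
#'
#' @param sim An `organoid_sim` from [simulate_organoid()].
#' @param library A [generate_barcode_library()] object with at least as
#'   many barcodes as lineages.
#' @param times Record times to tabulate; default all recorded times.
#' @return A `clone_table` data frame with columns `lineage`, `barcode`,
#'   `time`, `cells`.
#' @export
clones_from_simulation <- function(sim, library,
                                   times = unique(sim$states$time)) {
  stopifnot(inherits(sim, "organoid_sim"),
            inherits(library, "barcode_library"))
  L <- sim$params$n_lineages
  if (length(library$barcodes) < L)
    stop_user("library has fewer barcodes (", length(library$barcodes),
              ") than lineages (", L, ")")
  out <- do.call(rbind, lapply(times, function(tm) {
    st <- sim_states_at(sim, tm)
    data.frame(lineage = st$lineage,
               barcode = library$barcodes[st$lineage],
               time = tm,
               cells = st$s + st$a + st$n)
  }))
  class(out) <- c("clone_table", "data.frame")
  out
}

# Substitute bases at `rate` per base; every substitution changes the base
# (uniform over the three alternatives), so `rate` is the per-base error
# probability actually observed in the reads.
mutate_seqs <- function(x, rate) {
  if (rate <= 0 || !length(x)) return(x)
  L <- nchar(x[1L])
  n_err <- rbinom(length(x), L, rate)
  hit <- which(n_err > 0L)
  if (!length(hit)) return(x)
  one <- hit[n_err[hit] == 1L]
  multi <- hit[n_err[hit] > 1L]
  reads <- c(one, rep(multi, n_err[multi]))
  poss <- c(sample.int(L, length(one), replace = TRUE),
            unlist(lapply(n_err[multi], function(k) sample.int(L, k))))
  bases <- c("A", "C", "G", "T")
  for (p in sort(unique(poss))) {
    r <- reads[poss == p]
    orig <- substr(x[r], p, p)
    shift <- sample.int(3L, length(r), replace = TRUE)
    newb <- bases[(match(orig, bases) - 1L + shift) %% 4L + 1L]
    substr(x[r], p, p) <- newb
  }
  x
}

#' Generate synthetic barcode-sequencing reads
#'
#' Emulates PCR amplification and sequencing of barcoded samples. For each
#' sample, `depth` reads are drawn multinomially with probabilities
#' proportional to the clone cell counts; read 1 carries the clone's viral
#' barcode and the two index reads carry the sample's indexes. Per-base
#' substitution errors are applied independently to read 1 and both
#' indexes, and a `cross_sample_rate` fraction of reads is relabelled with
#' the indexes of a random other sample, emulating the cross-sample
#' contamination that the downstream 20x filter must remove.
#'
#' Clones are matched to samples either through a `sample` column in
#' `clones` or by matching `clones$time` against `sample_sheet$timepoint`.
#'
#' @param clones A `clone_table` (or data frame with `barcode`, `cells`
#'   and `sample` or `time`).
#' @param sample_sheet Data frame with columns `sample`, `index1`,
#'   `index2` and optionally `timepoint`.
#' @param depth Reads per sample.
#' @param substitution_rate Per-base substitution probability in `[0, 1]`.
#' @param cross_sample_rate Fraction of reads relabelled to another sample.
#' @param seed Optional RNG seed.
#' @return A `read_set`: data frame with columns `read1`, `index1`,
#'   `index2`; attributes `truth` (data frame `true_sample`,
#'   `dest_sample`, `barcode` per read) and `sample_sheet`.
#' @export
generate_reads <- function(clones, sample_sheet, depth,
                           substitution_rate = 0, cross_sample_rate = 0,
                           seed = NULL) {
  stopifnot(depth >= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            cross_sample_rate >= 0, cross_sample_rate <= 1)
  need <- c("sample", "index1", "index2")
  if (!all(need %in% names(sample_sheet)))
    stop_user("sample_sheet needs columns: ", paste(need, collapse = ", "))
  if (!NROW(clones)) stop_user("empty clone set")

  clones_for <- function(i) {
    if ("sample" %in% names(clones)) {
      clones[clones$sample == sample_sheet$sample[i], , drop = FALSE]
    } else if ("timepoint" %in% names(sample_sheet) &&
               "time" %in% names(clones)) {
      clones[abs(clones$time - sample_sheet$timepoint[i]) < 1e-9, ,
             drop = FALSE]
    } else {
      stop_user("clones need a 'sample' column, or clones$time plus ",
                "sample_sheet$timepoint")
    }
  }

  with_seed(seed, {
    parts <- lapply(seq_len(nrow(sample_sheet)), function(i) {
      cl <- clones_for(i)
      if (!nrow(cl)) stop_user("no clones for sample ",
                               sample_sheet$sample[i])
      cnt <- as.vector(rmultinom(1L, depth, cl$cells))
      data.frame(true_sample = sample_sheet$sample[i],
                 barcode = rep(cl$barcode, cnt))
    })
    truth <- do.call(rbind, parts)
    m <- nrow(truth)
    truth$dest_sample <- truth$true_sample
    if (cross_sample_rate > 0 && nrow(sample_sheet) > 1L) {
      bleed <- which(runif(m) < cross_sample_rate)
      if (length(bleed)) {
        others <- vapply(truth$true_sample[bleed], function(s) {
          pool <- setdiff(sample_sheet$sample, s)
          pool[sample.int(length(pool), 1L)]
        }, character(1))
        truth$dest_sample[bleed] <- others
      }
    }
    ii <- match(truth$dest_sample, sample_sheet$sample)
    reads <- data.frame(
      read1 = mutate_seqs(truth$barcode, substitution_rate),
      index1 = mutate_seqs(sample_sheet$index1[ii], substitution_rate),
      index2 = mutate_seqs(sample_sheet$index2[ii], substitution_rate))
    attr(reads, "truth") <- truth
    attr(reads, "sample_sheet") <- sample_sheet
    class(reads) <- c("read_set", "data.frame")
    reads
  })
}

#' Two-genotype chimeric organoid scenario with growth ablation
#'
#' Simulates an organoid grown from a mixture of two genotypes, each
#' barcoded with its own library. From `start_day` onwards the event rates
#' of genotype A are multiplied by `growth_penalty` (a value below 1
#' emulates chemical growth inhibition such as puromycin treatment of
#' non-resistant cells; the model has no death events, so ablation is
#' represented as growth arrest rather than cell loss). Genotype B is
#' unaffected.
#'
#' @param params_A,params_B [model_params()] for the two genotypes; both
#'   must share `record_times` and `t_end`. The total lineage number is
#'   `params_A$n_lineages`, split by `mix_fraction`.
#' @param mix_fraction Fraction of lineages belonging to genotype A,
#'   in (0, 1).
#' @param ablation List with `start_day` and `growth_penalty` (>= 0);
#'   `growth_penalty = 1` disables the perturbation.
#' @param libraries List of two `barcode_library` objects (A then B) with
#'   disjoint barcode sets.
#' @param seed Optional RNG seed for the whole scenario.
#' @return A `clone_table` with columns `genotype`, `lineage`, `barcode`,
#'   `time`, `cells`.
#' @export
generate_chimera_scenario <- function(params_A, params_B, mix_fraction,
                                      ablation = list(start_day = 11,
                                                      growth_penalty = 0),
                                      libraries, seed = NULL) {
  stopifnot(mix_fraction > 0, mix_fraction < 1,
            length(libraries) == 2L,
            inherits(libraries[[1]], "barcode_library"),
            inherits(libraries[[2]], "barcode_library"))
  if (length(intersect(libraries[[1]]$barcodes, libraries[[2]]$barcodes)))
    stop_user("genotype libraries share barcodes; they must be disjoint")
  if (!isTRUE(all.equal(params_A$record_times, params_B$record_times)))
    stop_user("params_A and params_B must share record_times")
  start_day <- ablation$start_day
  penalty <- ablation$growth_penalty
  stopifnot(penalty >= 0, start_day >= 0)

  total <- params_A$n_lineages
  n_A <- max(1L, round(mix_fraction * total))
  n_B <- max(1L, total - n_A)
  rec <- params_A$record_times

  scale_params <- function(p, fac, n, t_end, record_times) {
    model_params(r_s = p$r_s * fac, r_a = p$r_a * fac, r_n = p$r_n * fac,
                 k = p$k, variant = p$variant, r_dn = p$r_dn * fac,
                 t_end = t_end, n_lineages = n,
                 record_times = record_times, seed = NULL)
  }

  sim_states <- with_seed(seed, {
    # genotype A: unperturbed until start_day, penalized afterwards
    rec1 <- sort(unique(c(rec[rec <= start_day], min(start_day,
                                                     params_A$t_end))))
    pA1 <- scale_params(params_A, 1, n_A, min(start_day, params_A$t_end),
                        rec1)
    simA1 <- simulate_organoid(pA1)
    stA <- sim_states_at(simA1, min(start_day, params_A$t_end))
    statesA <- simA1$states[simA1$states$time %in% rec, , drop = FALSE]
    rec2 <- rec[rec > start_day]
    if (length(rec2)) {
      pA2 <- scale_params(params_A, penalty, n_A, params_A$t_end, rec2)
      simA2 <- simulate_organoid(
        pA2, init = list(s = stA$s, a = stA$a, n = stA$n),
        t_start = start_day)
      statesA <- rbind(statesA, simA2$states)
    }
    pB <- scale_params(params_B, 1, n_B, params_B$t_end, rec)
    simB <- simulate_organoid(pB)
    list(A = statesA, B = simB$states)
  })

  mk <- function(states, genotype, lib, offset) {
    if (length(lib$barcodes) < max(states$lineage))
      stop_user("library for genotype ", genotype, " is too small")
    data.frame(genotype = genotype,
               lineage = states$lineage + offset,
               barcode = lib$barcodes[states$lineage],
               time = states$time,
               cells = states$s + states$a + states$n)
  }
  out <- rbind(mk(sim_states$A, "A", libraries[[1]], 0L),
               mk(sim_states$B, "B", libraries[[2]], n_A))
  out <- out[order(out$time, out$lineage), ]
  rownames(out) <- NULL
  class(out) <- c("clone_table", "data.frame")
  out
}
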