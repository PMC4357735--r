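#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the statistical structure the method assumes: a
#' random genome with motif instances planted at known loci, ChIP-seq-style
#' peaks over a chosen fraction of them, and beta-binomial methylation
#' counts showing a hypomethylation dip across the window layout at bound
#' sites against a near-fully-methylated background.
#'
#' @param seed integer seed (mandatory; every draw derives from it).
#' @param genome_length chromosome length in bp.
#' @param n_chroms number of chromosomes.
#' @param motif_consensus consensus sequence planted at sites.
#' @param mutation_rate per-base probability of mutating a planted motif
#'   base away from consensus.
#' @param n_planted_sites total motif instances planted.
#' @param bound_fraction fraction of planted sites covered by a peak.
#' @param peak_pad bp added to each side of a bound motif to form its peak
#'   (>= 100 so containment labelling recovers the truth).
#' @param cpg_density expected cytosines per bp (per context).
#' @param coverage_mean mean reads per cytosine (Poisson).
#' @param profile per-window mean methylation at bound sites, length
#'   `2 * n_flank + 1`; default: linear dip 0.8 -> 0.2 -> 0.8.
#' @param background_mean background methylation level (close to fully
#'   methylated).
#' @param kappa beta concentration for methylation-level draws.
#' @param window_size,n_flank window geometry the profile refers to.
#' @param contexts methylation contexts to generate counts for.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 6e5,
                       n_chroms = 2,
                       motif_consensus = "TGACGCTAGTCCGAT",
                       mutation_rate = 0.05,
                       n_planted_sites = 500,
                       bound_fraction = 0.3,
                       peak_pad = 150,
                       cpg_density = 0.05,
                       coverage_mean = 20,
                       profile = NULL,
                       background_mean = 0.85,
                       kappa = 20,
                       window_size = 30,
                       n_flank = 10,
                       contexts = "CG") {
  if (missing(seed)) stop("sim_config requires an explicit seed",
                          call. = FALSE)
  if (is.null(profile)) {
    half <- seq(0.8, 0.2, length.out = n_flank + 1)
    profile <- c(half, rev(half)[-1])
  }
  stopifnot(length(profile) == 2 * n_flank + 1,
            all(profile > 0 & profile < 1),
            background_mean > 0, background_mean < 1,
            bound_fraction >= 0, bound_fraction <= 1,
            peak_pad >= 100, kappa > 0, coverage_mean > 0,
            mutation_rate >= 0, mutation_rate < 1)
  structure(list(seed = seed, genome_length = genome_length,
                 n_chroms = n_chroms, motif_consensus = motif_consensus,
                 mutation_rate = mutation_rate,
                 n_planted_sites = n_planted_sites,
                 bound_fraction = bound_fraction, peak_pad = peak_pad,
                 cpg_density = cpg_density, coverage_mean = coverage_mean,
                 profile = profile, background_mean = background_mean,
                 kappa = kappa, window_size = window_size,
                 n_flank = n_flank, contexts = contexts),
            class = "sim_config")
}

#' Generate a synthetic dataset bundle
#'
#' Produces, in memory, every input the pipeline consumes: genome, PFM,
#' per-context methylation count tables, peaks, annotation tracks, a
#' conservation track, and the planted-site truth table. Fully
#' reproducible from `config$seed`.
#'
#' The PFM handed to the scanner is the analytic frequency matrix implied
#' by the consensus and mutation rate (not re-estimated from the planted
#' instances).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle` with elements `genome`, `pfm`,
#'   `cpg` (named list per context), `peaks`, `annotations`, `track`,
#'   `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

#' Generate a null dataset (no methylation signal)
#'
#' Identical to [simulate_dataset()] except that bound sites draw their
#' methylation from the background distribution, so the methylation score
#' carries no information; used for type-I-error-style checks.
#'
#' @param config a [sim_config()].
#' @return a `sim_bundle`.
#' @export
make_null_dataset <- function(config) {
  config$profile <- rep(config$background_mean, 2 * config$n_flank + 1)
  simulate_dataset(config)
}

simulate_dataset_impl <- function(config) {
  L <- nchar(config$motif_consensus)
  span <- config$n_flank * config$window_size
  margin <- span + config$peak_pad + 50
  bases <- c("A", "C", "G", "T")
  consensus <- strsplit(config$motif_consensus, "")[[1]]
  if (!all(consensus %in% bases))
    stop("motif consensus must be ACGT only", call. = FALSE)

  # split planted sites across chromosomes as evenly as possible
  per_chrom <- diff(round(seq(0, config$n_planted_sites,
                              length.out = config$n_chroms + 1)))
  if (config$n_planted_sites < 1)
    stop("config yields zero planted sites", call. = FALSE)
  usable <- config$genome_length - 2 * margin
  if (any(per_chrom > 0 & usable / pmax(per_chrom, 1) < L + 1))
    stop("genome too short for the requested number of sites",
         call. = FALSE)

  genome <- character(config$n_chroms)
  names(genome) <- paste0("chr", seq_len(config$n_chroms))
  truth <- list()
  for (ci in seq_len(config$n_chroms)) {
    seq_v <- sample(bases, config$genome_length, replace = TRUE)
    n_sites <- per_chrom[ci]
    if (n_sites > 0) {
      # one site per equal-width slot keeps sites well separated so the
      # window layouts of different sites do not collide
      slot <- usable / n_sites
      offset <- floor(stats::runif(n_sites, 0, pmax(slot - L - 1, 1)))
      starts <- margin + floor((seq_len(n_sites) - 1) * slot) + offset
      for (k in seq_len(n_sites)) {
        inst <- consensus
        mut <- stats::runif(L) < config$mutation_rate
        if (any(mut))
          inst[mut] <- vapply(which(mut), function(i)
            sample(setdiff(bases, consensus[i]), 1), "")
        seq_v[(starts[k] + 1):(starts[k] + L)] <- inst
      }
      truth[[ci]] <- data.frame(chrom = names(genome)[ci],
                                start = starts, end = starts + L,
                                stringsAsFactors = FALSE)
    }
    genome[ci] <- paste(seq_v, collapse = "")
  }
  truth <- do.call(rbind, truth)
  truth$site_id <- sprintf("planted_%04d", seq_len(nrow(truth)))

  n_bound <- round(config$bound_fraction * nrow(truth))
  bound_idx <- sort(sample.int(nrow(truth), n_bound))
  truth$bound <- seq_len(nrow(truth)) %in% bound_idx

  peaks <- genomic_intervals(
    truth$chrom[bound_idx],
    pmax(truth$start[bound_idx] - config$peak_pad, 0),
    pmin(truth$end[bound_idx] + config$peak_pad, config$genome_length))
  peaks <- sort_intervals(peaks)

  # analytic PFM implied by consensus + mutation rate, at depth 100
  pfm_counts <- matrix(config$mutation_rate / 3 * 100, nrow = 4, ncol = L,
                       dimnames = list(bases, NULL))
  for (k in seq_len(L))
    pfm_counts[consensus[k], k] <- (1 - config$mutation_rate) * 100
  pfm <- list(counts = pfm_counts, name = "synthetic_motif")

  cpg <- lapply(stats::setNames(config$contexts, config$contexts),
                function(ctx) simulate_counts(config, genome, truth, ctx))

  annotations <- simulate_annotations(config, genome)
  track <- simulate_track(config, genome)

  structure(list(genome = genome, pfm = pfm, cpg = cpg, peaks = peaks,
                 annotations = annotations, track = track, truth = truth,
                 config = config),
            class = "sim_bundle")
}

# Beta-binomial methylation counts for one context. Cytosines inside the
# window span of a *bound* planted site draw their methylation level from
# the window's profile mean; all others from the background beta.
simulate_counts <- function(config, genome, truth, ctx = "CG") {
  out <- list()
  for (ch in names(genome)) {
    glen <- nchar(genome[[ch]])
    n_cpg <- stats::rpois(1, config$cpg_density * glen)
    pos <- sort(sample.int(glen, min(n_cpg, glen)) - 1L)
    mean_level <- rep(config$background_mean, length(pos))
    bound <- truth[truth$bound & truth$chrom == ch, , drop = FALSE]
    if (nrow(bound)) {
      layout <- build_windows_all(
        data.frame(site_id = bound$site_id, chrom = bound$chrom,
                   start = bound$start, end = bound$end,
                   stringsAsFactors = FALSE),
        config$window_size, config$n_flank,
        chrom_lengths = stats::setNames(glen, ch))
      hits <- IRanges::findOverlaps(
        as_iranges0(pos, pos + 1),
        as_iranges0(layout$start, layout$end))
      mean_level[S4Vectors::queryHits(hits)] <-
        config$profile[layout$index[S4Vectors::subjectHits(hits)]]
    }
    p <- stats::rbeta(length(pos), mean_level * config$kappa,
                      (1 - mean_level) * config$kappa)
    n <- stats::rpois(length(pos), config$coverage_mean)
    x <- stats::rbinom(length(pos), n, p)
    out[[ch]] <- data.frame(chrom = ch, pos = as.numeric(pos),
                            context = ctx, meth_count = as.numeric(x),
                            total_count = as.numeric(n),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Random annotation tracks with no relation to the planted sites: TSS/TES
# points, exon/intron/repeat intervals, and CpG islands as a few longer
# intervals.
simulate_annotations <- function(config, genome) {
  one <- function(n_per_chrom, width) {
    dfs <- lapply(names(genome), function(ch) {
      glen <- nchar(genome[[ch]])
      s <- sort(sample.int(glen - width, n_per_chrom))
      data.frame(chrom = ch, start = s, end = s + width,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, dfs)
    df$strand <- "."
    class(df) <- c("genomic_intervals", "data.frame")
    df
  }
  glen <- nchar(genome[[1]])
  list(tss = one(max(3, round(glen / 2e4)), 1),
       tes = one(max(3, round(glen / 2e4)), 1),
       exon = one(max(5, round(glen / 1e4)), 200),
       intron = one(max(5, round(glen / 1.5e4)), 1000),
       cpg_island = one(max(2, round(glen / 1e5)), 500),
       "repeat" = one(max(5, round(glen / 3e4)), 300))
}

# Sparse phastCons-like track: conserved patches covering a few percent of
# the genome with per-base scores in (0, 1]; unscored elsewhere.
simulate_track <- function(config, genome) {
  chroms <- character(0); poss <- numeric(0); scores <- numeric(0)
  for (ch in names(genome)) {
    glen <- nchar(genome[[ch]])
    n_patch <- max(3, round(glen / 2e4))
    width <- 100
    s <- sort(sample.int(glen - width, n_patch))
    pos <- unlist(lapply(s, function(a) seq.int(a, a + width - 1)))
    pos <- unique(pos)
    chroms <- c(chroms, rep(ch, length(pos)))
    poss <- c(poss, pos)
    scores <- c(scores, stats::runif(length(pos)))
  }
  conservation_track(chroms, poss, scores)
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_bundle: %d chromosome(s) x %g bp, %d planted sites (%d bound),\n",
    "  contexts: %s; seed %d\n"),
    x$config$n_chroms, x$config$genome_length, nrow(x$truth),
    sum(x$truth$bound), paste(names(x$cpg), collapse = ", "),
    x$config$seed))
  invisible(x)
}

#' Write a synthetic bundle to disk in the pipeline's file formats
#'
#' Emits `genome.fa`, `pfm.txt`, `cpg_<context>.tsv`, `peaks.bed`, one BED
#' per annotation class, `conservation.bedgraph` and `truth.tsv`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(bundle$genome)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  writeLines(c(paste0(">", bundle$pfm$name),
               vapply(rownames(bundle$pfm$counts), function(b)
                 sprintf("%s [ %s ]", b,
                         paste(format(bundle$pfm$counts[b, ]),
                               collapse = " ")), "")),
             file.path(dir, "pfm.txt"))
  for (ctx in names(bundle$cpg))
    write_cpg_table(bundle$cpg[[ctx]],
                    file.path(dir, paste0("cpg_", ctx, ".tsv")))
  write_bed(bundle$peaks, file.path(dir, "peaks.bed"))
  for (key in names(bundle$annotations))
    write_bed(bundle$annotations[[key]], file.path(dir, paste0(key, ".bed")))
  track_df <- do.call(rbind, lapply(names(bundle$track), function(ch) {
    d <- bundle$track[[ch]]
    data.frame(chrom = ch, start = d$pos, end = d$pos + 1, score = d$score)
  }))
  utils::write.table(track_df, file.path(dir, "conservation.bedgraph"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
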