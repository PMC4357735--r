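#' Convert a position frequency matrix to a log-odds PWM
#'
#' Column counts are converted to probabilities with a pseudocount shared
#' across bases in proportion to the background, then log2-scaled against
#' the background:
#' `entry(b, k) = log2(((count(b,k) + pc * bg_b) / (colsum_k + pc)) / bg_b)`.
#'
#' @param pfm list with `counts` (4 x L, rows A,C,G,T) and `name`, as
#'   returned by [read_pfm()].
#' @param background length-4 probability vector over A,C,G,T; default
#'   uniform.
#' @param pseudocount positive scalar spread over the column proportionally
#'   to the background.
#' @return list of class `pwm`: `log_odds` (4 x L), `background`,
#'   `pseudocount`, `name`, `max_score`, `min_score`.
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- pfm$counts
  stopifnot(is.matrix(counts), nrow(counts) == 4)
  if (pseudocount <= 0)
    stop("pseudocount must be > 0 (zero-count columns would give -Inf)",
         call. = FALSE)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 positive probabilities summing to 1",
         call. = FALSE)
  background <- as.numeric(background)
  colsum <- colSums(counts)
  prob <- sweep(counts + outer(background, rep(pseudocount, ncol(counts))),
                2, colsum + pseudocount, "/")
  lo <- log2(prob / background)
  dimnames(lo) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(log_odds = lo, background = background,
                 pseudocount = pseudocount,
                 name = if (is.null(pfm$name)) "pwm" else pfm$name,
                 max_score = sum(apply(lo, 2, max)),
                 min_score = sum(apply(lo, 2, min))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, score range [%.3f, %.3f]\n",
              x$name, ncol(x$log_odds), x$min_score, x$max_score))
  invisible(x)
}

# Base -> row-index encoding; anything outside ACGT becomes NA so windows
# containing ambiguity codes are skipped.
encode_seq <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  code
}

# Reverse-complement PWM: scanning the forward strand with it equals
# scanning the reverse complement of the sequence with the original.
revcomp_pwm <- function(log_odds) {
  log_odds[4:1, rev(seq_len(ncol(log_odds))), drop = FALSE]
}

# All window scores for one encoded sequence (NA where the window contains
# a non-ACGT base or runs off the end).
window_scores <- function(code, log_odds) {
  L <- ncol(log_odds)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (k in seq_len(L)) {
    s <- s + log_odds[, k][code[k:(k + n - 1L)]]
  }
  s
}

#' Scan a genome for PWM matches
#'
#' Both strands are scanned; reverse-strand hits are reported on forward
#' coordinates of the same window. Windows containing non-ACGT bases are
#' skipped. When the same window passes the threshold on both strands only
#' the higher-scoring strand is kept.
#'
#' @param genome named character vector of sequences (see [read_fasta()]).
#' @param pwm a [pfm_to_pwm()] object.
#' @param threshold absolute log-odds cutoff, or with
#'   `threshold_type = "fraction"` a fraction of the maximum attainable
#'   score.
#' @param threshold_type `"absolute"` or `"fraction"`.
#' @return A [genomic_intervals()] data.frame of candidate sites with
#'   columns `site_id`, `motif_score`, sorted by (chrom, start).
#' @export
scan_genome <- function(genome, pwm, threshold,
                        threshold_type = c("absolute", "fraction")) {
  threshold_type <- match.arg(threshold_type)
  if (threshold_type == "fraction") {
    if (threshold < 0 || threshold > 1)
      stop("fractional threshold must be in [0, 1]", call. = FALSE)
    threshold <- threshold * pwm$max_score
  }
  L <- ncol(pwm$log_odds)
  if (all(nchar(genome) < L)) {
    warning("PWM (length ", L, ") longer than every sequence; no hits")
    return(empty_candidates())
  }
  rc <- revcomp_pwm(pwm$log_odds)
  out <- list()
  for (ch in names(genome)) {
    code <- encode_seq(genome[[ch]])
    fwd <- window_scores(code, pwm$log_odds)
    rev <- window_scores(code, rc)
    if (!length(fwd)) next
    hit_f <- !is.na(fwd) & fwd >= threshold
    hit_r <- !is.na(rev) & rev >= threshold
    any_hit <- which(hit_f | hit_r)
    if (!length(any_hit)) next
    take_f <- hit_f[any_hit] & (!hit_r[any_hit] |
                                  fwd[any_hit] >= rev[any_hit])
    out[[ch]] <- data.frame(
      chrom = ch,
      start = any_hit - 1,
      end = any_hit - 1 + L,
      strand = ifelse(take_f, "+", "-"),
      motif_score = ifelse(take_f, fwd[any_hit], rev[any_hit]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_candidates())
  df <- do.call(rbind, out)
  df <- sort_intervals(df)
  df$site_id <- sprintf("site_%05d", seq_len(nrow(df)))
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

empty_candidates <- function() {
  genomic_intervals(character(), integer(), integer(),
                    motif_score = numeric(), site_id = character())
}

#' Choose a scan threshold targeting a candidate-site count range
#'
#' Evaluates hit counts on a grid of 100 thresholds between 50% and 100% of
#' the maximum attainable score and returns the smallest threshold whose
#' genome-wide count falls inside `target_range`. If no grid point attains
#' the range, the threshold with the nearest achievable count is returned
#' with a warning.
#'
#' @param genome named character vector of sequences.
#' @param pwm a [pfm_to_pwm()] object.
#' @param target_range length-2 numeric `c(lo, hi)` of acceptable site
#'   counts.
#' @param grid_size number of grid points.
#' @return list with `threshold` (absolute log-odds) and `n_sites` at that
#'   threshold.
#' @export
choose_threshold <- function(genome, pwm, target_range, grid_size = 100) {
  if (length(genome) == 0L || all(!nzchar(genome)))
    stop("empty genome", call. = FALSE)
  if (length(target_range) != 2L || any(target_range <= 0) ||
      target_range[1] > target_range[2])
    stop("target_range must be positive c(lo, hi)", call. = FALSE)
  scores <- numeric(0)
  rc <- revcomp_pwm(pwm$log_odds)
  for (ch in names(genome)) {
    code <- encode_seq(genome[[ch]])
    f <- window_scores(code, pwm$log_odds)
    r <- window_scores(code, rc)
    # count per locus once, using the better strand (matches scan_genome)
    s <- pmax(f, r, na.rm = TRUE)
    scores <- c(scores, s[!is.na(s)])
  }
  grid <- seq(0.5, 1, length.out = grid_size) * pwm$max_score
  counts <- vapply(grid, function(thr) sum(scores >= thr), 0L)
  ok <- counts >= target_range[1] & counts <= target_range[2]
  if (any(ok)) {
    i <- which(ok)[1]  # grid ascending: first ok point is the smallest
  } else {
    dist <- pmin(abs(counts - target_range[1]), abs(counts - target_range[2]))
    i <- which.min(dist)
    warning(sprintf(
      "no grid threshold attains %d..%d sites; nearest achievable count is %d",
      target_range[1], target_range[2], counts[i]))
  }
  list(threshold = grid[i], n_sites = counts[i])
}

#' Label candidate sites against gold-standard peaks
#'
#' A candidate is labelled `bound` when its motif interval is covered by a
#' peak. By default coverage means full containment; `min_overlap < 1`
#' relaxes this to requiring that fraction of the motif width to intersect
#' a single peak.
#'
#' @param sites candidate intervals (from [scan_genome()]).
#' @param peaks peak intervals (e.g. [read_bed()]).
#' @param min_overlap required overlap as a fraction of motif width;
#'   1 = containment.
#' @return `sites` with a `label` column, factor with levels
#'   `c("unbound", "bound")`.
#' @export
label_candidates <- function(sites, peaks, min_overlap = 1) {
  stopifnot(min_overlap > 0, min_overlap <= 1)
  n <- nrow(sites)
  bound <- logical(n)
  if (n && nrow(peaks)) {
    for (ch in unique(sites$chrom)) {
      qi <- which(sites$chrom == ch)
      si <- which(peaks$chrom == ch)
      if (!length(si)) next
      q <- as_iranges0(sites$start[qi], sites$end[qi])
      s <- as_iranges0(peaks$start[si], peaks$end[si])
      hits <- IRanges::findOverlaps(q, s)
      if (!length(hits)) next
      ov <- IRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]))
      need <- ceiling(min_overlap * IRanges::width(q[S4Vectors::queryHits(hits)]))
      good <- unique(S4Vectors::queryHits(hits)[ov >= need])
      bound[qi[good]] <- TRUE
    }
  }
  sites$label <- factor(ifelse(bound, "bound", "unbound"),
                        levels = c("unbound", "bound"))
  sites
}

#' Split candidate sites into equal-sized training and testing sets
#'
#' @param sites candidate table.
#' @param seed integer seed driving the permutation; the global RNG state is
#'   left untouched.
#' @return list with `train` and `test` data.frames (sizes differing by at
#'   most one row).
#' @export
split_train_test <- function(sites, seed) {
  n <- nrow(sites)
  if (n < 2L) stop("need at least 2 sites to split", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  n_train <- ceiling(n / 2)
  list(train = sites[sort(perm[seq_len(n_train)]), , drop = FALSE],
       test = sites[sort(perm[(n_train + 1L):n]), , drop = FALSE])
}
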