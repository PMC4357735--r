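# Shared fixtures and independent oracles used across test files.

# Small, fast bundle for most pipeline-level tests; the full "stated world"
# bundle (500 sites, 2 x 600 kb) is reserved for the acceptance suite.
small_bundle <- function(seed, ...) {
  simulate_dataset(sim_config(seed = seed, genome_length = 2e5,
                              n_chroms = 1, n_planted_sites = 120, ...))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force PWM scan: score every window on both strands independently
# of the vectorised scanner.
brute_scan <- function(genome, pwm, threshold) {
  L <- ncol(pwm$log_odds)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_kmer <- function(kmer) {
    b <- strsplit(kmer, "")[[1]]
    if (!all(b %in% names(comp))) return(NA_real_)
    sum(vapply(seq_len(L), function(k) pwm$log_odds[b[k], k], 0))
  }
  out <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    n <- nchar(s) - L + 1
    if (n < 1) next
    for (i in seq_len(n)) {
      kmer <- substr(s, i, i + L - 1)
      fs <- score_kmer(kmer)
      rb <- rev(strsplit(kmer, "")[[1]])
      rs <- if (all(rb %in% names(comp)))
        score_kmer(paste(comp[rb], collapse = "")) else NA_real_
      hit_f <- !is.na(fs) && fs >= threshold
      hit_r <- !is.na(rs) && rs >= threshold
      if (hit_f || hit_r) {
        use_f <- hit_f && (!hit_r || fs >= rs)
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = i - 1, end = i - 1 + L,
          strand = if (use_f) "+" else "-",
          motif_score = if (use_f) fs else rs,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      motif_score = numeric()))
  do.call(rbind, out)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_pwm <- function(L, seed) {
  set.seed(seed)
  counts <- matrix(sample(0:9, 4 * L, replace = TRUE), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[1, colSums(counts) == 0] <- 1
  pfm_to_pwm(list(counts = counts, name = "rand"))
}

# Mann-Whitney pair-counting AUC: concordant pairs plus half ties over all
# positive x negative pairs.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == "bound" | labels == TRUE | labels == 1]
  neg <- scores[!(labels == "bound" | labels == TRUE | labels == 1)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Quadrature beta-binomial pmf: numerically integrate the binomial
# likelihood against the beta density.
quadrature_betabinom <- function(x, n, alpha, beta) {
  stats::integrate(function(p) stats::dbinom(x, n, p) *
                     stats::dbeta(p, alpha, beta),
                   0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value
}
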