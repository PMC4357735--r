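test_that("pfm_to_pwm implements the log-odds construction", {
  pfm <- list(counts = matrix(c(1, 0, 0, 0), nrow = 4,
                              dimnames = list(c("A", "C", "G", "T"), NULL)),
              name = "x")
  pwm <- pfm_to_pwm(pfm, pseudocount = 1)
  expect_equal(unname(pwm$log_odds["A", 1]), log2(2.5), tolerance = 1e-12)

  # counts proportional to the background at large depth carry no
  # information: entries tend to 0
  deep <- list(counts = matrix(rep(25000, 8), nrow = 4,
                               dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm <- pfm_to_pwm(deep, pseudocount = 0.8)
  expect_lt(max(abs(pwm$log_odds)), 1e-4)

  expect_error(pfm_to_pwm(pfm, pseudocount = 0), "pseudocount")
  expect_error(pfm_to_pwm(pfm, background = c(0.5, 0.5, 0.2, 0.2)),
               "background")
})

test_that("max attainable score matches exhaustive k-mer enumeration", {
  pwm <- random_pwm(4, seed = 11)
  kmers <- do.call(expand.grid,
                   rep(list(c("A", "C", "G", "T")), 4))[, 4:1]
  best <- max(apply(kmers, 1, function(b)
    sum(vapply(1:4, function(k) pwm$log_odds[b[k], k], 0))))
  expect_equal(pwm$max_score, best, tolerance = 1e-12)
})

test_that("scan_genome finds consensus hits and skips ambiguous windows", {
  consensus <- list(counts = matrix(0, 4, 4,
                                    dimnames = list(c("A", "C", "G", "T"),
                                                    NULL)))
  consensus$counts["A", 1] <- 10; consensus$counts["C", 2] <- 10
  consensus$counts["G", 3] <- 10; consensus$counts["T", 4] <- 10
  pwm <- pfm_to_pwm(consensus)
  hits <- scan_genome(c(chr1 = "TTACGTTT"), pwm, 0.9, "fraction")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2)
  expect_equal(hits$end, 6)
  expect_equal(hits$strand, "+")

  expect_equal(nrow(scan_genome(c(chr1 = strrep("N", 50)), pwm, 0.5,
                                "fraction")), 0)
  expect_warning(scan_genome(c(chr1 = "ACG"), pwm, 0.5, "fraction"),
                 "longer")
})

test_that("scan_genome equals the brute-force all-window oracle", {
  set.seed(202)
  for (rep in 1:3) {
    genome <- c(chrA = random_seq(400), chrB = random_seq(250))
    pwm <- random_pwm(5, seed = rep)
    thr <- 0.6 * pwm$max_score
    got <- scan_genome(genome, pwm, thr, "absolute")
    want <- brute_scan(genome, pwm, thr)
    want <- want[order(want$chrom, want$start), ]
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$motif_score, want$motif_score, tolerance = 1e-12)
  }
})

test_that("reverse-strand scores equal forward scores of the reverse complement", {
  pwm <- random_pwm(4, seed = 5)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  kmers <- apply(do.call(expand.grid, rep(list(c("A", "C", "G", "T")), 4)),
                 1, paste, collapse = "")
  for (kmer in kmers) {
    rc <- paste(rev(comp[strsplit(kmer, "")[[1]]]), collapse = "")
    hit_k <- scan_genome(stats::setNames(kmer, "c"), pwm,
                         pwm$min_score - 1, "absolute")
    hit_rc <- scan_genome(stats::setNames(rc, "c"), pwm,
                          pwm$min_score - 1, "absolute")
    expect_equal(hit_k$motif_score, hit_rc$motif_score, tolerance = 1e-12)
  }
})

test_that("choose_threshold targets a site-count range on a grid", {
  set.seed(33)
  genome <- c(chr1 = random_seq(3000))
  pwm <- random_pwm(6, seed = 7)
  # oracle: hit counts over the same grid
  scores <- brute_scan(genome, pwm, pwm$min_score - 1)$motif_score
  grid <- seq(0.5, 1, length.out = 100) * pwm$max_score
  counts <- vapply(grid, function(t) sum(scores >= t), 0L)
  target <- c(5, 15)
  ok <- which(counts >= target[1] & counts <= target[2])
  if (length(ok)) {
    res <- choose_threshold(genome, pwm, target)
    expect_equal(res$threshold, grid[ok[1]])
    expect_true(res$n_sites >= 5 && res$n_sites <= 15)
  }

  # unattainably wide target saturates at the lowest grid point
  expect_warning(res <- choose_threshold(genome, pwm, c(1e6, 2e6)),
                 "nearest achievable")
  expect_equal(res$n_sites, counts[1])

  # exactly attainable point target
  k <- counts[50]
  if (k > 0) {
    res <- choose_threshold(genome, pwm, c(k, k))
    expect_equal(res$n_sites, k)
  }
  expect_error(choose_threshold(c(chr1 = ""), pwm, c(1, 2)), "empty")
})

test_that("label_candidates uses full containment and matches brute force", {
  sites <- genomic_intervals("chr1", c(100, 100), c(119, 119))
  sites$site_id <- c("a", "b")
  peak_in <- genomic_intervals("chr1", 50, 200)
  peak_part <- genomic_intervals("chr1", 110, 200)
  expect_equal(as.character(label_candidates(sites[1, ], peak_in)$label),
               "bound")
  expect_equal(as.character(label_candidates(sites[1, ], peak_part)$label),
               "unbound")
  # partial overlap counts under a relaxed min_overlap
  expect_equal(as.character(
    label_candidates(sites[1, ], peak_part, min_overlap = 0.4)$label),
    "bound")

  set.seed(9)
  s <- sort(sample(0:900, 10))
  sites <- genomic_intervals("chr1", s, s + 19)
  peaks <- genomic_intervals("chr1", c(0, 300, 700), c(150, 420, 800))
  got <- label_candidates(sites, peaks)$label == "bound"
  want <- vapply(seq_len(10), function(i)
    any(sites$start[i] >= peaks$start & sites$end[i] <= peaks$end), TRUE)
  expect_equal(got, want)

  # invariant to peak order and to padding with non-overlapping intervals
  perm <- peaks[c(2, 3, 1), ]
  pad <- rbind(as.data.frame(perm),
               data.frame(chrom = "chrZ", start = 0, end = 10, strand = "."))
  expect_equal(label_candidates(sites, perm)$label,
               label_candidates(sites, pad)$label)
})

test_that("split_train_test is a seeded, reproducible partition", {
  sites <- genomic_intervals("chr1", seq(0, 90, 10), seq(5, 95, 10))
  sites$site_id <- sprintf("s%02d", 1:10)
  a <- split_train_test(sites, seed = 4)
  b <- split_train_test(sites, seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a$train), 5)
  expect_equal(nrow(a$test), 5)
  expect_setequal(c(a$train$site_id, a$test$site_id), sites$site_id)
  expect_length(intersect(a$train$site_id, a$test$site_id), 0)

  odd <- split_train_test(sites[1:9, ], seed = 1)
  expect_true(abs(nrow(odd$train) - nrow(odd$test)) <= 1)
  expect_error(split_train_test(sites[1, ], seed = 1), "at least 2")
})
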