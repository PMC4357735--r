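test_that("default window construction gives the 21-window layout", {
  site <- data.frame(chrom = "chr1", start = 1000, end = 1019)
  w <- build_windows(site, chrom_length = 10000)
  expect_equal(nrow(w), 21)
  expect_equal(w$index, 1:21)
  expect_equal(w$start[1], 700)
  expect_equal(w$end[1], 730)
  expect_equal(w$start[10], 970)
  expect_equal(w$end[10], 1000)
  expect_equal(w$start[11], 1000)   # centre window = raw motif interval
  expect_equal(w$end[11], 1019)
  expect_equal(w$start[12], 1019)
  expect_equal(w$end[21], 1319)
  # windows tile without gaps or overlaps
  expect_true(all(w$start[-1] == w$end[-21]))

  expect_equal(nrow(build_windows(site, n_flank = 0)), 1)
  expect_error(build_windows(data.frame(chrom = "c", start = 500,
                                        end = 600), chrom_length = 550),
               "outside")
})

test_that("windows are clipped at chromosome ends with indices preserved", {
  site <- data.frame(chrom = "chr1", start = 10, end = 25)
  w <- build_windows(site, chrom_length = 10000)
  expect_lt(nrow(w), 21)
  expect_equal(min(w$start), 0)          # leftmost surviving window clipped
  expect_equal(w$index[1], 10)           # earlier flanks dropped, not renumbered
  expect_equal(w$index[w$start == 10], 11)
  expect_equal(max(w$index), 21)
})

test_that("multi-site layout agrees with per-site build_windows", {
  sites <- data.frame(site_id = c("a", "b"), chrom = "chr1",
                      start = c(50, 4000), end = c(69, 4019),
                      stringsAsFactors = FALSE)
  all_w <- methbind:::build_windows_all(sites, 30, 10, c(chr1 = 5000))
  for (i in 1:2) {
    single <- build_windows(sites[i, ], chrom_length = 5000)
    sub <- all_w[all_w$site_id == sites$site_id[i], ]
    expect_equal(sub$index, single$index)
    expect_equal(sub$start, single$start)
    expect_equal(sub$end, single$end)
  }
})

test_that("aggregate_counts sums covered cytosines per window", {
  layout <- data.frame(site_id = "s", index = 1, chrom = "chr1",
                       start = 0, end = 30)
  cpg <- data.frame(chrom = "chr1", pos = c(5, 20), context = "CG",
                    meth_count = c(3, 0), total_count = c(5, 4))
  got <- aggregate_counts(layout, cpg)
  expect_equal(got$x, 3)
  expect_equal(got$n, 9)
  expect_equal(got$cg, 2)

  # uncovered window and zero-coverage record
  cpg0 <- data.frame(chrom = "chr1", pos = 10, context = "CG",
                     meth_count = 0, total_count = 0)
  got <- aggregate_counts(layout, cpg0)
  expect_equal(c(got$x, got$n, got$cg), c(0, 0, 0))
})

test_that("window aggregation equals a per-position brute force", {
  set.seed(77)
  site <- data.frame(chrom = "chr1", start = 1000, end = 1019)
  layout <- build_windows(site, chrom_length = 5000)
  layout$site_id <- "s"
  pos <- sort(sample(600:1500, 50))
  tot <- rpois(50, 6)
  cpg <- data.frame(chrom = "chr1", pos = pos, context = "CG",
                    meth_count = rbinom(50, tot, 0.5), total_count = tot)
  got <- aggregate_counts(layout, cpg)
  for (j in seq_len(nrow(layout))) {
    inwin <- cpg$pos >= layout$start[j] & cpg$pos < layout$end[j] &
      cpg$total_count >= 1
    expect_equal(got$x[j], sum(cpg$meth_count[inwin]))
    expect_equal(got$n[j], sum(cpg$total_count[inwin]))
    expect_equal(got$cg[j], sum(inwin))
  }
})

test_that("training QC masks thin windows and drops island candidates", {
  sites <- genomic_intervals("chr1", c(0, 100), c(19, 119))
  sites$site_id <- c("a", "b")
  wc <- data.frame(site_id = rep(c("a", "b"), each = 3), index = rep(1:3, 2),
                   x = 1, n = c(4, 5, 12, 10, 2, 0), cg = 1)
  qc <- qc_filter_training(sites, wc, genomic_intervals(), min_reads = 5)
  expect_equal(qc$window_counts$masked,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))

  island <- genomic_intervals("chr1", 110, 300)
  qc <- qc_filter_training(sites, wc, island, min_reads = 5)
  expect_equal(qc$sites$site_id, "a")
  expect_false("b" %in% qc$window_counts$site_id)
  expect_equal(qc$n_dropped_island, 1)
})

test_that("QC on 20 synthetic candidates matches the brute-force rule oracle", {
  set.seed(41)
  starts <- seq(0, by = 500, length.out = 20)
  sites <- genomic_intervals("chr1", starts, starts + 19)
  sites$site_id <- sprintf("s%02d", 1:20)
  # islands over 6 of the candidates
  isl_idx <- sample(20, 6)
  islands <- genomic_intervals("chr1", starts[isl_idx] - 5,
                               starts[isl_idx] + 10)
  wc <- data.frame(site_id = rep(sites$site_id, each = 21),
                   index = rep(1:21, 20), x = 0,
                   n = rpois(20 * 21, 5), cg = 1)
  qc <- qc_filter_training(sites, wc, islands, min_reads = 5)
  keep_oracle <- !(seq_len(20) %in% isl_idx)
  expect_equal(qc$sites$site_id, sites$site_id[keep_oracle])
  surv <- qc$window_counts[!qc$window_counts$masked, c("site_id", "index")]
  oracle <- wc[wc$site_id %in% sites$site_id[keep_oracle] & wc$n >= 5,
               c("site_id", "index")]
  expect_equal(surv$site_id, oracle$site_id)
  expect_equal(surv$index, oracle$index)
})

test_that("fit_beta_mom matches closed-form MOM arithmetic", {
  # proportions 0.25 and 0.75 at depth 4: m = 1/2, S = 1/8, cbar = 1/4,
  # sigma2 = (1/8 - 1/16) / (3/4) = 1/12, kappa = (1/4)/(1/12) - 1 = 2
  fit <- fit_beta_mom(c(1, 3), c(4, 4))
  expect_equal(fit$alpha, 1, tolerance = 1e-12)
  expect_equal(fit$beta, 1, tolerance = 1e-12)

  # degenerate zero-variance slice: concentration clamped, mean preserved
  fit <- fit_beta_mom(c(2, 4, 6), c(10, 20, 30))
  expect_equal(fit$alpha + fit$beta, 1e4)
  expect_equal(fit$alpha / (fit$alpha + fit$beta), 0.2, tolerance = 1e-9)

  expect_error(fit_beta_mom(1, 10), "fewer than 2")
  expect_error(fit_beta_mom(c(1, 2), c(0, 0)), "fewer than 2")
})

test_that("MOM recovers beta parameters from seeded draws", {
  set.seed(123)
  p <- rbeta(10000, 2, 8)
  x <- rbinom(10000, 100, p)
  fit <- fit_beta_mom(x, rep(100, 10000))
  expect_lt(abs(fit$alpha - 2) / 2, 0.10)
  expect_lt(abs(fit$beta - 8) / 8, 0.10)
})

test_that("fit_methylation_model recovers a dip and pools the background", {
  set.seed(5)
  m <- 21
  dip <- c(seq(0.8, 0.2, length.out = 11), rev(seq(0.8, 0.2,
                                                   length.out = 11))[-1])
  sim_counts <- function(n_sites, means, kappa = 20, cov = 30) {
    do.call(rbind, lapply(seq_len(n_sites), function(i) {
      p <- rbeta(m, means * kappa, (1 - means) * kappa)
      n <- rpois(m, cov)
      data.frame(site_id = paste0("s", i), index = 1:m,
                 x = rbinom(m, n, p), n = n, cg = as.integer(n > 0))
    }))
  }
  bound <- sim_counts(300, dip)
  unbound <- sim_counts(300, rep(0.85, m))
  model <- fit_methylation_model(bound, unbound)
  mu <- model$binding$alpha / (model$binding$alpha + model$binding$beta)
  expect_lt(max(abs(mu - dip)), 0.05)
  bg <- model$background$alpha / (model$background$alpha +
                                    model$background$beta)
  expect_equal(bg, 0.85, tolerance = 0.05)

  # null: bound and unbound from the same beta -> means agree everywhere
  bound0 <- sim_counts(300, rep(0.85, m))
  model0 <- fit_methylation_model(bound0, unbound)
  mu0 <- model0$binding$alpha / (model0$binding$alpha + model0$binding$beta)
  expect_lt(max(abs(mu0 - bg)), 0.05)

  # windows without usable bound data inherit the background
  thin <- bound[bound$index != 3, ]
  expect_warning(model_thin <- fit_methylation_model(thin, unbound),
                 "window")
  expect_equal(model_thin$binding$alpha[3], model$background$alpha)
})

test_that("methylation model serialisation round-trips exactly", {
  set.seed(6)
  bound <- data.frame(site_id = rep(c("a", "b", "c"), each = 21),
                      index = rep(1:21, 3), x = rpois(63, 3),
                      n = rpois(63, 3) + 10, cg = 1)
  unbound <- transform(bound, site_id = paste0(site_id, "u"),
                       x = rpois(63, 8))
  model <- fit_methylation_model(bound, unbound)
  path <- tempfile(fileext = ".json")
  write_methylation_model(model, path)
  back <- read_methylation_model(path)
  expect_identical(back$binding$alpha, model$binding$alpha)
  expect_identical(back$binding$beta, model$binding$beta)
  expect_identical(back$background, model$background)
  expect_identical(back$context, model$context)
  expect_error(read_methylation_model(
    write_lines_tmp('{"format": "other"}', ".json")), "not a")
})

test_that("betabinom_logpmf matches known values and quadrature", {
  # uniform marginal when alpha = beta = 1
  expect_equal(betabinom_logpmf(0:5, 5, 1, 1), rep(log(1 / 6), 6),
               tolerance = 1e-12)
  # empty observation has probability one
  expect_equal(betabinom_logpmf(0, 0, 2, 3), 0)
  expect_error(betabinom_logpmf(3, 2, 1, 1), "0 <= x <= n")

  expect_equal(betabinom_logpmf(2, 7, 2, 5),
               log(quadrature_betabinom(2, 7, 2, 5)), tolerance = 1e-10)
})

test_that("betabinom pmf normalises over its support", {
  for (ab in list(c(1, 1), c(0.5, 0.5), c(2, 8), c(40, 3), c(10, 10))) {
    for (n in c(1, 7, 50)) {
      total <- sum(exp(betabinom_logpmf(0:n, n, ab[1], ab[2])))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("methylation score behaves as a log likelihood ratio", {
  model <- structure(list(
    binding = list(alpha = rep(1, 21), beta = rep(9, 21)),
    background = list(alpha = 9, beta = 1),
    window_size = 30, n_flank = 10, context = "CG"),
    class = "meth_model")

  # identical hypotheses give exactly zero
  null_model <- model
  null_model$binding <- list(alpha = rep(9, 21), beta = rep(1, 21))
  wc <- data.frame(index = 1:21, x = rbinom(21, 10, 0.5), n = 10, cg = 1)
  expect_identical(methylation_score(wc, null_model), 0)

  # no covered windows give zero
  wc0 <- transform(wc, cg = 0)
  expect_identical(methylation_score(wc0, model), 0)

  # closed form for constant counts, checked against quadrature
  wc1 <- data.frame(index = 1:21, x = 1, n = 10, cg = 1)
  lam <- methylation_score(wc1, model)
  expected <- 21 * (log(quadrature_betabinom(1, 10, 1, 9)) -
                    log(quadrature_betabinom(1, 10, 9, 1)))
  expect_equal(lam, expected, tolerance = 1e-8)
  expect_gt(lam, 0)

  # additive over windows and invariant to window order
  perm <- sample(21)
  expect_equal(methylation_score(wc1[perm, ], model), lam)
  half <- methylation_score(wc1[1:10, ], model) +
    methylation_score(wc1[11:21, ], model)
  expect_equal(half, lam)

  expect_error(methylation_score(data.frame(index = 25, x = 0, n = 1,
                                            cg = 1), model),
               "incompatible")
})

test_that("score is monotone in x when binding mean < background mean", {
  model <- structure(list(
    binding = list(alpha = rep(2, 21), beta = rep(8, 21)),
    background = list(alpha = 17, beta = 3),
    window_size = 30, n_flank = 10, context = "CG"),
    class = "meth_model")
  lam <- vapply(0:10, function(x)
    methylation_score(data.frame(index = 11, x = x, n = 10, cg = 1), model),
    0)
  expect_true(all(diff(lam) <= 1e-12))
})

test_that("a 20 bp window size yields a valid model and scores", {
  b <- small_bundle(31)
  fit <- run_train(b, seed = 2, window_size = 20, n_trees = 60)
  expect_equal(fit$model$meth_models$CG$window_size, 20)
  pred <- run_predict(fit$model, b, sites = fit$test_sites)
  expect_true(all(is.finite(pred$meth_score_cg)))
  expect_true(all(pred$prob_bound >= 0 & pred$prob_bound <= 1))
})
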