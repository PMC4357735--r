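#' Build the window layout around a candidate motif site
#'
#' The motif interval itself is the centre window; `n_flank` windows of
#' `window_size` bp are tiled immediately to each side, giving
#' `2 * n_flank + 1` windows (21 with the defaults of ten 30-bp flanks per
#' side). Windows running past a chromosome end are clipped; windows
#' falling entirely outside are dropped, but every surviving window keeps
#' its positional index (1 = leftmost flank, `n_flank + 1` = motif) so
#' window-specific model parameters stay aligned.
#'
#' @param site one-row candidate data.frame (needs `chrom`, `start`, `end`).
#' @param window_size flank window width in bp (default 30).
#' @param n_flank number of flank windows per side (default 10).
#' @param chrom_length length of the chromosome, used for clipping.
#' @return data.frame with columns `index`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' site <- data.frame(chrom = "chr1", start = 1000, end = 1019)
#' build_windows(site, chrom_length = 10000)
build_windows <- function(site, window_size = 30, n_flank = 10,
                          chrom_length = Inf) {
  stopifnot(window_size >= 1, n_flank >= 0)
  s <- site$start[1]; e <- site$end[1]
  if (s < 0 || e > chrom_length || s >= e)
    stop("motif interval [", s, ",", e, ") outside chromosome of length ",
         chrom_length, call. = FALSE)
  k <- seq_len(n_flank)
  starts <- c(s - rev(k) * window_size, s, e + (k - 1) * window_size)
  ends <- c(s - rev(k - 1) * window_size, e, e + k * window_size)
  df <- data.frame(index = seq_len(2 * n_flank + 1),
                   chrom = site$chrom[1],
                   start = pmax(starts, 0),
                   end = pmin(ends, chrom_length),
                   stringsAsFactors = FALSE)
  df[df$start < df$end, , drop = FALSE]
}

# Window layouts for many sites at once, as one long data.frame keyed by
# site_id; vectorised equivalent of lapply(build_windows).
build_windows_all <- function(sites, window_size = 30, n_flank = 10,
                              chrom_lengths = NULL) {
  n <- nrow(sites)
  m <- 2 * n_flank + 1
  k <- seq_len(n_flank)
  len <- if (is.null(chrom_lengths)) rep(Inf, n)
         else unname(chrom_lengths[sites$chrom])
  idx <- rep(seq_len(m), n)
  s_rep <- rep(sites$start, each = m)
  e_rep <- rep(sites$end, each = m)
  # left flanks anchor on the motif start, right flanks on the motif end
  starts <- s_rep + rep(c(-rev(k) * window_size, 0, rep(0, n_flank)), n)
  right <- idx > n_flank + 1
  starts[right] <- e_rep[right] + (idx[right] - n_flank - 2) * window_size
  ends <- starts + window_size
  centre <- idx == n_flank + 1
  starts[centre] <- s_rep[centre]
  ends[centre] <- e_rep[centre]
  df <- data.frame(site_id = rep(sites$site_id, each = m),
                   index = idx,
                   chrom = rep(sites$chrom, each = m),
                   start = pmax(starts, 0),
                   end = pmin(ends, rep(len, each = m)),
                   stringsAsFactors = FALSE)
  df[df$start < df$end, , drop = FALSE]
}

#' Aggregate methylation counts into windows
#'
#' For each window, sums methylated (`x`) and total (`n`) read counts over
#' the in-window cytosines that are covered by at least one read, and
#' counts those covered cytosines (`cg`). A window with no covered
#' cytosine gets `(0, 0, 0)`.
#'
#' @param layout window data.frame from [build_windows()] (or the
#'   multi-site variant used internally).
#' @param cpg data.frame of methylation records (see [read_cpg_table()]),
#'   already restricted to one context.
#' @return `layout` with columns `x`, `n`, `cg` appended.
#' @export
aggregate_counts <- function(layout, cpg) {
  layout$x <- 0; layout$n <- 0; layout$cg <- 0L
  covered <- cpg[cpg$total_count >= 1, , drop = FALSE]
  if (!nrow(covered) || !nrow(layout)) return(layout)
  for (ch in unique(layout$chrom)) {
    li <- which(layout$chrom == ch)
    ci <- which(covered$chrom == ch)
    if (!length(ci)) next
    hits <- IRanges::findOverlaps(
      as_iranges0(covered$pos[ci], covered$pos[ci] + 1),
      as_iranges0(layout$start[li], layout$end[li]))
    if (!length(hits)) next
    w <- li[S4Vectors::subjectHits(hits)]
    r <- ci[S4Vectors::queryHits(hits)]
    layout$x[li] <- layout$x[li] +
      rowsum_on(covered$meth_count[r], w, li)
    layout$n[li] <- layout$n[li] +
      rowsum_on(covered$total_count[r], w, li)
    layout$cg[li] <- layout$cg[li] + rowsum_on(rep(1L, length(r)), w, li)
  }
  layout
}

rowsum_on <- function(values, group, levels) {
  out <- numeric(length(levels))
  agg <- rowsum(values, group)
  out[match(as.numeric(rownames(agg)), levels)] <- agg[, 1]
  out
}

#' Training-set quality control
#'
#' Two filters applied before model fitting, and only to the training set:
#' windows with fewer than `min_reads` total reads are masked (excluded
#' from parameter estimation), and candidates whose motif interval
#' overlaps a CpG island are removed entirely.
#'
#' @param sites candidate table with `site_id`, `chrom`, `start`, `end`.
#' @param window_counts long window-count table (one row per site/window,
#'   as produced by [aggregate_counts()] on the multi-site layout).
#' @param cpg_islands CpG-island intervals; may be empty.
#' @param min_reads minimum total reads for a window to be usable
#'   (default 5).
#' @return list with `sites` (island-overlapping candidates dropped) and
#'   `window_counts` (rows for dropped candidates removed; a logical
#'   `masked` column marks low-coverage windows).
#' @export
qc_filter_training <- function(sites, window_counts, cpg_islands,
                               min_reads = 5) {
  stopifnot(min_reads >= 0)
  in_island <- overlaps_any0(sites, cpg_islands)
  kept <- sites[!in_island, , drop = FALSE]
  wc <- window_counts[window_counts$site_id %in% kept$site_id, ,
                      drop = FALSE]
  wc$masked <- wc$n < min_reads
  list(sites = kept, window_counts = wc,
       n_dropped_island = sum(in_island),
       n_masked_windows = sum(wc$masked))
}

#' Method-of-moments fit of a beta distribution to methylation proportions
#'
#' Observed proportions `p = x / n` are summarised by their mean `m` and
#' sample variance `S` (denominator `length - 1`). Because each `p` is a
#' binomial proportion, `S` mixes the between-site beta variance with
#' binomial counting noise; the counting component is removed by the
#' moment identity `E(S) = sigma2 (1 - cbar) + m (1 - m) cbar` with
#' `cbar = mean(1 / n)`, giving `sigma2 = (S - m (1 - m) cbar) /
#' (1 - cbar)`. The beta parameters follow from
#' `kappa = m (1 - m) / sigma2 - 1`, `alpha = m kappa`,
#' `beta = (1 - m) kappa`. Without this correction the concentration is
#' overestimated by a factor of roughly `1 + kappa / n`, a ~10% bias at
#' typical WGBS coverage.
#'
#' Degenerate slices are clamped: data at or below pure-binomial
#' dispersion (`sigma2 <= 0`, including zero sample variance) set `kappa`
#' to `kappa_max`; `sigma2` at or beyond the Bernoulli bound `m (1 - m)`
#' sets `kappa` to `kappa_min`; the mean is clipped away from 0 and 1.
#'
#' @param x,n methylated and total read counts (equal length); pairs with
#'   `n < 1` are ignored.
#' @param kappa_min,kappa_max concentration clamps.
#' @return list with `alpha`, `beta`.
#' @export
fit_beta_mom <- function(x, n, kappa_min = 0.01, kappa_max = 1e4) {
  ok <- n >= 1
  x <- x[ok]; n <- n[ok]
  if (length(x) < 2L)
    stop("fewer than 2 usable observations; fall back to the pooled ",
         "background fit", call. = FALSE)
  p <- x / n
  m <- mean(p)
  m <- min(max(m, 1e-6), 1 - 1e-6)
  S <- stats::var(p)
  cbar <- mean(1 / n)
  sigma2 <- if (cbar < 1) (S - m * (1 - m) * cbar) / (1 - cbar) else 0
  if (sigma2 <= 0) {
    kappa <- kappa_max
  } else if (sigma2 >= m * (1 - m)) {
    kappa <- kappa_min
  } else {
    kappa <- m * (1 - m) / sigma2 - 1
    kappa <- min(max(kappa, kappa_min), kappa_max)
  }
  list(alpha = m * kappa, beta = (1 - m) * kappa)
}

#' Fit the two-group beta-binomial methylation model
#'
#' Bound sites get a separate beta distribution of methylation level per
#' window, capturing the hypomethylation dip toward the motif; unbound
#' (background) sites share a single beta fitted from all their windows
#' pooled, reflecting the assumption that background methylation is
#' homogeneous and close to fully methylated. Windows with fewer than two
#' usable bound observations inherit the background parameters (with a
#' warning) so scoring stays defined everywhere.
#'
#' @param bound_counts,unbound_counts long window-count tables (site_id,
#'   index, x, n, cg, optional masked) for bound and unbound training
#'   candidates, after [qc_filter_training()].
#' @param window_size,n_flank window geometry the counts were built with.
#' @param context methylation context tag (`"CG"`, `"CH"`, `"hmC"`).
#' @return object of class `meth_model`: per-window `binding` alpha/beta
#'   vectors, single `background` pair, geometry, context and training
#'   sizes.
#' @export
fit_methylation_model <- function(bound_counts, unbound_counts,
                                  window_size = 30, n_flank = 10,
                                  context = "CG") {
  m <- 2 * n_flank + 1
  usable <- function(df) {
    if (!nrow(df)) return(df[0, , drop = FALSE])
    if (!is.null(df$masked)) df <- df[!df$masked, , drop = FALSE]
    df[df$n >= 1, , drop = FALSE]
  }
  ub <- usable(unbound_counts)
  if (nrow(ub) < 2L)
    stop("not enough unbound windows to fit the background model",
         call. = FALSE)
  background <- fit_beta_mom(ub$x, ub$n)
  bb <- usable(bound_counts)
  alpha <- numeric(m); beta <- numeric(m)
  inherited <- integer(0)
  for (j in seq_len(m)) {
    sl <- bb[bb$index == j, , drop = FALSE]
    if (nrow(sl) >= 2L) {
      fit <- fit_beta_mom(sl$x, sl$n)
    } else {
      fit <- background
      inherited <- c(inherited, j)
    }
    alpha[j] <- fit$alpha; beta[j] <- fit$beta
  }
  if (length(inherited))
    warning("window(s) ", paste(inherited, collapse = ", "),
            " had <2 usable bound observations; background parameters used")
  structure(list(
    binding = list(alpha = alpha, beta = beta),
    background = background,
    window_size = window_size,
    n_flank = n_flank,
    context = context,
    n_train_bound = length(unique(bound_counts$site_id)),
    n_train_unbound = length(unique(unbound_counts$site_id))),
    class = "meth_model")
}

#' @export
print.meth_model <- function(x, ...) {
  mu <- x$binding$alpha / (x$binding$alpha + x$binding$beta)
  bg <- x$background$alpha / (x$background$alpha + x$background$beta)
  cat(sprintf(paste0(
    "meth_model (%s): %d windows of %d bp, background mean %.3f\n",
    "  binding window means: %s\n"),
    x$context, 2 * x$n_flank + 1, x$window_size, bg,
    paste(sprintf("%.2f", mu), collapse = " ")))
  invisible(x)
}

#' Beta-binomial log probability mass
#'
#' `log P(x | n) = log C(n, x) + log B(x + alpha, n - x + beta) -
#' log B(alpha, beta)`, evaluated through log-gamma for stability. `n = 0`
#' gives log-probability 0. Vectorised over `x` and `n`.
#'
#' @param x methylated read count(s), `0 <= x <= n`.
#' @param n total read count(s).
#' @param alpha,beta beta parameters, both positive (recycled against `x`).
#' @return log probability, same length as `x`.
#' @export
betabinom_logpmf <- function(x, n, alpha, beta) {
  if (any(x < 0) || any(x > n))
    stop("need 0 <= x <= n", call. = FALSE)
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be positive", call. = FALSE)
  lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta)
}

#' Likelihood-ratio methylation score
#'
#' For one candidate, the score is the sum over windows that contain at
#' least one covered cytosine (`cg > 0`) of the log likelihood ratio
#' between the window's binding beta-binomial and the shared background
#' beta-binomial. Windows without data contribute 0. Larger scores mean
#' the observed methylation pattern looks more like a bound site
#' (typically: a hypomethylation dip).
#'
#' @param wc window-count data.frame for one site (`index`, `x`, `n`,
#'   `cg`), indices within `1 .. 2 n_flank + 1`.
#' @param model a [fit_methylation_model()] object.
#' @return scalar score.
#' @export
methylation_score <- function(wc, model) {
  m <- 2 * model$n_flank + 1
  if (any(wc$index < 1 | wc$index > m))
    stop("window indices incompatible with model layout (expected 1..",
         m, ")", call. = FALSE)
  use <- wc$cg > 0
  if (!any(use)) return(0)
  j <- wc$index[use]
  sum(betabinom_logpmf(wc$x[use], wc$n[use],
                       model$binding$alpha[j], model$binding$beta[j]) -
      betabinom_logpmf(wc$x[use], wc$n[use],
                       model$background$alpha, model$background$beta))
}

# Scores for all sites at once from a long window-count table.
methylation_score_all <- function(window_counts, model) {
  ids <- unique(window_counts$site_id)
  wc <- window_counts[window_counts$cg > 0, , drop = FALSE]
  out <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(wc)) {
    j <- wc$index
    ll <- betabinom_logpmf(wc$x, wc$n, model$binding$alpha[j],
                           model$binding$beta[j]) -
      betabinom_logpmf(wc$x, wc$n, model$background$alpha,
                       model$background$beta)
    agg <- rowsum(ll, wc$site_id)
    out[rownames(agg)] <- agg[, 1]
  }
  out
}

#' Serialize / restore a methylation model
#'
#' Versioned JSON text; numeric parameters are written with 17 significant
#' digits so the round-trip is bit-exact.
#'
#' @param model a `meth_model` object.
#' @param path file path.
#' @return `read_methylation_model` returns the restored `meth_model`.
#' @export
write_methylation_model <- function(model, path) {
  payload <- list(format = "methbind/meth_model", version = 1L,
                  model = unclass(model))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_methylation_model
#' @export
read_methylation_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format) || payload$format != "methbind/meth_model")
    stop("'", path, "' is not a methylation model file", call. = FALSE)
  if (payload$version != 1L)
    stop("unsupported methylation model version: ", payload$version,
         call. = FALSE)
  m <- payload$model
  m$binding <- list(alpha = as.numeric(m$binding$alpha),
                    beta = as.numeric(m$binding$beta))
  m$background <- list(alpha = as.numeric(m$background$alpha),
                       beta = as.numeric(m$background$beta))
  structure(m, class = "meth_model")
}
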