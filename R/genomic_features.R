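#' Mean conservation over a motif interval
#'
#' Positions without a score in the track count as 0, so sites in unscored
#' regions stay in the candidate set with a neutral value instead of being
#' dropped.
#'
#' @param sites candidate intervals.
#' @param track a [conservation_track()].
#' @return numeric vector, one mean per site.
#' @export
conservation_mean <- function(sites, track) {
  vapply(seq_len(nrow(sites)), function(i) {
    d <- track[[sites$chrom[i]]]
    if (is.null(d)) return(0)
    lo <- sites$start[i]; hi <- sites$end[i]
    j <- findInterval(c(lo - 0.5, hi - 0.5), d$pos)
    if (j[2] <= j[1]) return(0)
    sum(d$score[(j[1] + 1L):j[2]]) / (hi - lo)
  }, 0)
}

site_midpoints <- function(sites) {
  (sites$start + sites$end) / 2
}

#' Distance from motif midpoints to the nearest reference feature
#'
#' Point references (1-bp intervals, e.g. TSS) use their base position;
#' wider intervals use their closest edge, and a midpoint inside an
#' interval gets distance 0. Only same-chromosome references count; a site
#' on a chromosome with no reference gets `NA` (logged via `message`).
#'
#' @param sites candidate intervals.
#' @param reference reference intervals (e.g. TSS points).
#' @return numeric vector of distances in bp (`NA` where undefined).
#' @export
distance_to_nearest <- function(sites, reference) {
  if (nrow(reference) == 0L) {
    message("empty reference set; distances undefined (NA)")
    return(rep(NA_real_, nrow(sites)))
  }
  mid <- site_midpoints(sites)
  out <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    qi <- which(sites$chrom == ch)
    ri <- which(reference$chrom == ch)
    if (!length(ri)) next
    rs <- reference$start[ri]; re <- reference$end[ri]
    for (i in qi) {
      d <- ifelse(mid[i] < rs, rs - mid[i],
                  ifelse(mid[i] >= re, mid[i] - (re - 1), 0))
      out[i] <- min(d)
    }
  }
  if (anyNA(out)) message(sum(is.na(out)),
                          " site(s) on chromosomes without reference features")
  out
}

#' Binary overlap indicator against an annotation class
#'
#' 1 iff the motif interval shares at least one base with any annotation
#' interval (half-open semantics: abutting intervals do not overlap).
#'
#' @param sites candidate intervals.
#' @param annotation annotation intervals.
#' @return integer vector of 0/1.
#' @export
binary_overlap <- function(sites, annotation) {
  as.integer(overlaps_any0(sites, annotation))
}

#' Distance to the nearest other candidate site
#'
#' Midpoint-to-midpoint distance to the closest other candidate on the
#' same chromosome; a lone candidate on its chromosome gets `NA`.
#'
#' @param sites candidate intervals.
#' @return numeric vector of distances in bp.
#' @export
nearest_candidate_distance <- function(sites) {
  mid <- site_midpoints(sites)
  out <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    qi <- which(sites$chrom == ch)
    if (length(qi) < 2L) next
    m <- sort(mid[qi], index.return = TRUE)
    d <- diff(m$x)
    nn <- pmin(c(Inf, d), c(d, Inf))
    out[qi[m$ix]] <- nn
  }
  out
}

FEATURE_ORDER <- c("motif_score", "meth_score_cg", "meth_score_ch",
                   "meth_score_hmc", "conservation_mean", "dist_tss",
                   "dist_nearest_candidate", "overlap_tss", "overlap_tes",
                   "overlap_exon", "overlap_intron", "overlap_cpg_island",
                   "overlap_repeat")

ANNOTATION_KEYS <- c("tss", "tes", "exon", "intron", "cpg_island", "repeat")

# Sentinel for undefined distances (lone candidate / empty reference);
# finite so tree splits stay well-defined, large enough to sort beyond any
# real chromosome.
DIST_SENTINEL <- 1e9

#' Assemble the per-site feature table
#'
#' One row per candidate, columns in a fixed schema order: motif score,
#' methylation score per available context, mean conservation, distance to
#' TSS, distance to the nearest other candidate, and six binary overlap
#' indicators (TSS, TES, exon, intron, CpG island, repeat). Contexts
#' absent from `meth_scores` are left out of the schema rather than
#' imputed. Undefined distances are encoded by a large finite sentinel
#' (1e9) so downstream learners see a value meaning "nothing nearby".
#'
#' @param sites candidate table with `site_id` and `motif_score`.
#' @param meth_scores named list of per-context score vectors keyed by
#'   site_id; names among `CG`, `CH`, `hmC` (CG mandatory).
#' @param track a [conservation_track()].
#' @param annotations named list of interval data.frames with keys
#'   `tss`, `tes`, `exon`, `intron`, `cpg_island`, `repeat`.
#' @return data.frame keyed by `site_id` with the feature columns; the
#'   schema (ordered feature names) is attached as attribute `"schema"`.
#' @export
assemble_feature_table <- function(sites, meth_scores, track, annotations) {
  if (is.null(meth_scores$CG))
    stop("CG methylation scores are mandatory", call. = FALSE)
  missing_ann <- setdiff(ANNOTATION_KEYS, names(annotations))
  if (length(missing_ann))
    stop("missing annotation class(es): ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  sites <- sites[order(sites$site_id), , drop = FALSE]
  ids <- sites$site_id
  get_scores <- function(v, what) {
    if (is.null(names(v)))
      stop("methylation scores must be named by site_id", call. = FALSE)
    miss <- setdiff(ids, names(v))
    if (length(miss))
      stop("site ", miss[1], " missing mandatory feature ", what,
           call. = FALSE)
    as.numeric(v[ids])
  }
  df <- data.frame(site_id = ids,
                   motif_score = sites$motif_score,
                   meth_score_cg = get_scores(meth_scores$CG,
                                              "meth_score_cg"),
                   stringsAsFactors = FALSE)
  if (!is.null(meth_scores$CH))
    df$meth_score_ch <- get_scores(meth_scores$CH, "meth_score_ch")
  if (!is.null(meth_scores$hmC))
    df$meth_score_hmc <- get_scores(meth_scores$hmC, "meth_score_hmc")
  df$conservation_mean <- conservation_mean(sites, track)
  dist_tss <- suppressMessages(distance_to_nearest(sites, annotations$tss))
  df$dist_tss <- ifelse(is.na(dist_tss), DIST_SENTINEL, dist_tss)
  dnc <- nearest_candidate_distance(sites)
  df$dist_nearest_candidate <- ifelse(is.na(dnc), DIST_SENTINEL, dnc)
  df$overlap_tss <- binary_overlap(sites, annotations$tss)
  df$overlap_tes <- binary_overlap(sites, annotations$tes)
  df$overlap_exon <- binary_overlap(sites, annotations$exon)
  df$overlap_intron <- binary_overlap(sites, annotations$intron)
  df$overlap_cpg_island <- binary_overlap(sites, annotations$cpg_island)
  df$overlap_repeat <- binary_overlap(sites, annotations[["repeat"]])
  schema <- intersect(FEATURE_ORDER, names(df))
  df <- df[, c("site_id", schema), drop = FALSE]
  rownames(df) <- NULL
  attr(df, "schema") <- schema
  df
}
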