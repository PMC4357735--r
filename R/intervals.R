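#' Genomic interval container
#'
#' All coordinates in this package are 0-based, half-open: an interval
#' covers bases `start, start+1, ..., end-1`. This single convention is used
#' everywhere internally; the readers convert external dialects (1-based
#' fixedStep WIG, for instance) on the way in.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand character vector in `+`, `-`, `.`; defaults to `.`
#'   (unstranded).
#' @param ... further equal-length columns carried along (names, scores).
#'
#' @return A `data.frame` with class `genomic_intervals`, columns `chrom`,
#'   `start`, `end`, `strand` plus any extras.
#' @export
#' @examples
#' genomic_intervals("chr1", 10, 20)
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = NULL, ...) {
  n <- length(chrom)
  if (is.null(strand)) strand <- rep(".", n)
  if (length(strand) == 1L && n > 1L) strand <- rep(strand, n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    stop("interval chromosome names must be non-empty", call. = FALSE)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end", call. = FALSE)
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  invisible(df)
}

#' @export
print.genomic_intervals <- function(x, ...) {
  cat(sprintf("genomic_intervals with %d interval(s) (0-based, half-open)\n",
              nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# IRanges on the same chromosome; +1 shift localises the 0-based/1-based
# conversion to this one helper.
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# For each query interval, TRUE if it intersects (>= 1 bp) any subject
# interval on the same chromosome. Half-open semantics on both sides.
overlaps_any0 <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  out <- logical(nrow(query))
  if (nrow(subject) == 0L) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    hits <- IRanges::overlapsAny(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(subject$start[si], subject$end[si]))
    out[qi] <- hits
  }
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so library code never
# perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
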