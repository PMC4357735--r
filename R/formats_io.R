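#' Read a FASTA file into a named vector of sequences
#'
#' Sequences are upper-cased; IUPAC ambiguity codes are preserved.
#'
#' @param path path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA file '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (length(seqs) == 0L)
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate chromosome name(s) in FASTA: ",
         paste(dup, collapse = ", "), call. = FALSE)
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Read a per-cytosine methylation count table
#'
#' The expected on-disk format is a tab-delimited table with five columns:
#' `chrom`, `pos`, `context`, `meth_count`, `total_count`. Positions are
#' 0-based by this package's convention; pass `one_based = TRUE` for tables
#' using 1-based positions. Lines starting with `#` (and an optional header
#' line whose first field is `chrom`) are skipped.
#'
#' Rows with `total_count == 0` are retained: they carry no coverage and
#' never contribute to window counts, but dropping them would silently
#' change hand counts against the raw file.
#'
#' @param path path to the count table.
#' @param context_filter optional subset of `c("CG", "CH", "hmC")`; rows in
#'   other contexts are dropped.
#' @param one_based set `TRUE` if positions in the file are 1-based.
#' @return A `data.frame` with columns `chrom`, `pos`, `context`,
#'   `meth_count`, `total_count`, sorted by (chrom, pos).
#' @export
read_cpg_table <- function(path, context_filter = NULL, one_based = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) && grepl("^chrom\\b", lines[1])) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines))
    return(empty_cpg_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5))
    stop("CpG table '", path, "': line ", lineno[which(nf < 5)[1]],
         " has fewer than 5 tab-separated fields", call. = FALSE)
  m <- matrix(unlist(lapply(fields, `[`, 1:5)), ncol = 5, byrow = TRUE)
  df <- data.frame(chrom = m[, 1],
                   pos = suppressWarnings(as.numeric(m[, 2])),
                   context = m[, 3],
                   meth_count = suppressWarnings(as.numeric(m[, 4])),
                   total_count = suppressWarnings(as.numeric(m[, 5])),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$pos) | is.na(df$meth_count) | is.na(df$total_count))
  if (length(bad))
    stop("CpG table '", path, "': non-numeric field at line ", lineno[bad[1]],
         call. = FALSE)
  if (one_based) df$pos <- df$pos - 1
  bad <- which(df$meth_count < 0 | df$total_count < 0 |
                 df$meth_count > df$total_count)
  if (length(bad))
    stop("CpG table '", path, "': line ", lineno[bad[1]],
         ": meth_count must satisfy 0 <= meth_count <= total_count",
         call. = FALSE)
  bad <- which(df$pos < 0)
  if (length(bad))
    stop("CpG table '", path, "': line ", lineno[bad[1]],
         ": negative position", call. = FALSE)
  if (!is.null(context_filter)) df <- df[df$context %in% context_filter, ,
                                         drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_cpg_table <- function() {
  data.frame(chrom = character(), pos = numeric(), context = character(),
             meth_count = numeric(), total_count = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a methylation count table
#'
#' Inverse of [read_cpg_table()]; positions written 0-based.
#' @param records data.frame as returned by [read_cpg_table()].
#' @param path output path.
#' @export
write_cpg_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (BED3 or BED6)
#'
#' BED is 0-based, half-open, matching the internal convention, so
#' coordinates pass through unchanged. Intervals are returned sorted by
#' (chrom, start). Malformed lines (fewer than 3 fields, non-numeric or
#' inverted coordinates) raise an error naming the offending line.
#'
#' @param path path to a BED file. Track/browser/comment lines are skipped.
#' @return A [genomic_intervals()] data.frame; BED6 inputs carry `name`,
#'   `score` and `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(genomic_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED file '", path, "': line ", lineno[which(nf < 3)[1]],
         " has fewer than 3 fields", call. = FALSE)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED file '", path, "': line ", lineno[bad[1]],
         ": non-numeric coordinates", call. = FALSE)
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("BED file '", path, "': line ", lineno[bad[1]],
         ": need 0 <= start < end", call. = FALSE)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 6)) {
    df$name <- vapply(fields, `[`, "", 4L)
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    st <- vapply(fields, `[`, "", 6L)
    df$strand <- ifelse(st %in% c("+", "-"), st, ".")
  } else {
    df$strand <- "."
  }
  df <- sort_intervals(df)
  rownames(df) <- NULL
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Write intervals as BED
#'
#' @param intervals a [genomic_intervals()] data.frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- as.data.frame(intervals)
  cols <- c("chrom", "start", "end")
  if (!is.null(df$name) || !is.null(df$score) || any(df$strand != ".")) {
    df$name <- if (is.null(df$name)) "." else df$name
    df$score <- if (is.null(df$score)) 0 else df$score
    cols <- c(cols, "name", "score", "strand")
  }
  utils::write.table(format(df[, cols], scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a position frequency matrix in JASPAR text format
#'
#' Expects an optional `>` header line followed by four labelled rows, e.g.
#' `A [ 4 19 0 ]`. Brackets are optional; rows may appear in any order but
#' all of A, C, G, T must be present.
#'
#' @param path path to the PFM file.
#' @return list with `counts` (4 x L numeric matrix, rows A,C,G,T) and
#'   `name`.
#' @export
read_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- "pfm"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- trimws(sub("^>", "", lines[1]))
    name <- strsplit(name, "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  rows <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([ACGTacgt])\\s*[:\\[]?\\s*([-0-9. \\t]+)\\]?\\s*$", ln))[[1]]
    if (length(m) == 0L)
      stop("unrecognised PFM line: '", ln, "' (expected JASPAR text dialect)",
           call. = FALSE)
    base <- toupper(m[2])
    vals <- as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]])
    rows[[base]] <- vals
  }
  if (!setequal(names(rows), c("A", "C", "G", "T")))
    stop("PFM must contain exactly the four rows A, C, G, T", call. = FALSE)
  L <- unique(lengths(rows))
  if (length(L) != 1L)
    stop("PFM rows have unequal lengths", call. = FALSE)
  counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  if (any(counts < 0))
    stop("PFM counts must be non-negative", call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("PFM has an all-zero column", call. = FALSE)
  list(counts = counts, name = name)
}

#' Read a per-base conservation track
#'
#' Accepts fixedStep WIG (1-based; converted to the internal 0-based
#' convention on read) or 4-column bedGraph (0-based half-open). Scores are
#' expanded to single-base resolution. Dialect is auto-detected.
#'
#' @param path path to the track file.
#' @return A `conservation_track` object: per-chromosome sorted positions
#'   (0-based) with scores. Positions absent from the track are treated as
#'   missing (score 0) by consumers.
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*($|#|track\\b)", lines)]
  if (!length(body))
    stop("conservation track '", path, "' is empty", call. = FALSE)
  fmt <- if (any(grepl("^(fixedStep|variableStep)\\b", body))) "wig"
         else if (all(lengths(strsplit(body, "\\s+")) == 4)) "bedGraph"
         else stop("conservation track '", path,
                   "': expected fixedStep WIG or 4-column bedGraph",
                   call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("failed to parse '", path,
                                          "' as ", fmt, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L)
    stop("conservation track '", path, "' has no scored positions",
         call. = FALSE)
  w <- BiocGenerics::width(gr)
  # expand ranges to single bases; GRanges is 1-based so subtract 1
  pos0 <- unlist(mapply(function(a, n) seq.int(a, length.out = n),
                        BiocGenerics::start(gr) - 1L, w, SIMPLIFY = FALSE))
  conservation_track(rep(as.character(GenomeInfoDb::seqnames(gr)), w),
                     pos0, rep(gr$score, w))
}

#' Construct a conservation track from per-base scores
#'
#' @param chrom,pos,score equal-length vectors; `pos` 0-based.
#' @return `conservation_track` object.
#' @export
conservation_track <- function(chrom, pos, score) {
  if (length(chrom) == 1L && length(pos) > 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos), length(pos) == length(score))
  track <- split(data.frame(pos = pos, score = score), chrom)
  track <- lapply(track, function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    d <- d[!duplicated(d$pos), , drop = FALSE]  # last write does not win; first kept
    rownames(d) <- NULL
    d
  })
  structure(track, class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat(sprintf("conservation_track: %d chromosome(s), %d scored base(s)\n",
              length(x), sum(vapply(x, nrow, 0L))))
  invisible(x)
}

#' Write per-site predictions
#'
#' Output is BED6 plus extra numeric columns (methylation scores per
#' context and the class probability), with a single `#`-prefixed header
#' line naming every column so the file round-trips through
#' [read_predictions()].
#'
#' @param predictions data.frame with at least `chrom`, `start`, `end`,
#'   `site_id`, `motif_score`, `strand`, `prob_bound` and any
#'   `meth_score_*` columns.
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  extra <- setdiff(names(predictions),
                   c("chrom", "start", "end", "site_id", "motif_score",
                     "strand"))
  cols <- c("chrom", "start", "end", "site_id", "motif_score", "strand",
            extra)
  missing <- setdiff(c("chrom", "start", "end", "site_id", "motif_score",
                       "strand"), names(predictions))
  if (length(missing))
    stop("predictions table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- predictions[, cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a predictions file written by [write_predictions()]
#' @param path file path.
#' @return data.frame with the original columns.
#' @export
read_predictions <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("predictions file '", path, "' lacks the expected '#' header",
         call. = FALSE)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, header = FALSE, skip = 1L,
                          col.names = cols, stringsAsFactors = FALSE)
  df
}
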