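#' Build the analysis region set from a BED file
#'
#' Reproduces the region-preparation step used to stage the genotyping
#' template: every BED interval is widened by `extend_bp` on both sides
#' (clamped at the contig origin), overlapping or abutting intervals are
#' merged, an optional complex span (the CYP2D6-D7 complex) replaces
#' every interval it touches with one gap-free interval, and extra
#' regions (control genes) are appended with the same extension.
#'
#' @param bed_path Path to a BED file (0-based half-open; `track`,
#'   `browser` and `#` lines are ignored). A parse failure reports the
#'   offending line number.
#' @param extend_bp Non-negative extension in bp applied to each side.
#' @param complex_span Optional region, as a `"contig:start-end"` string
#'   (1-based, closed) or a `(contig, start, end)` vector; all intervals
#'   intersecting it are united with it into a single interval.
#' @param extra_regions Optional character vector of
#'   `"contig:start-end"` strings appended with the same extension.
#' @return A `GRanges` (1-based, closed; canonical contig names) with a
#'   `label` metadata column.
#' @export
prepare_regions <- function(bed_path, extend_bp = 0L, complex_span = NULL,
                            extra_regions = NULL) {
  stopifnot(length(extend_bp) == 1L, extend_bp >= 0)
  gr <- read_bed_regions(bed_path)
  gr <- extend_clamp(gr, extend_bp)
  gr <- GenomicRanges::reduce(gr, with.revmap = FALSE)
  S4Vectors::mcols(gr)$label <- rep("region", length(gr))

  if (!is.null(complex_span)) {
    cs <- as_region_gr(complex_span)
    if (!as.character(GenomicRanges::seqnames(cs)) %in%
        as.character(unique(GenomicRanges::seqnames(gr))))
      stop("complex span on unknown contig: ",
           as.character(GenomicRanges::seqnames(cs)))
    hit <- IRanges::overlapsAny(gr, cs)
    united <- range(concat_granges(gr[hit], cs), ignore.strand = TRUE)
    S4Vectors::mcols(united)$label <- "complex"
    gr <- sort(concat_granges(gr[!hit], united), ignore.strand = TRUE)
  }

  if (!is.null(extra_regions)) {
    ex <- do.call(concat_granges, lapply(extra_regions, as_region_gr))
    ex <- extend_clamp(ex, extend_bp)
    S4Vectors::mcols(ex)$label <- rep("extra", length(ex))
    gr <- sort(concat_granges(gr, ex), ignore.strand = TRUE)
  }
  gr
}

# c() on GRanges with disjoint seqlevels warns; rebuild instead.
concat_granges <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, length, 1L) > 0L]
  if (length(parts) == 1L) return(parts[[1L]])
  ctg <- unlist(lapply(parts, function(g) as.character(GenomicRanges::seqnames(g))))
  s <- unlist(lapply(parts, GenomicRanges::start))
  e <- unlist(lapply(parts, GenomicRanges::end))
  lab <- unlist(lapply(parts, function(g) {
    l <- S4Vectors::mcols(g)$label
    if (is.null(l)) rep(NA_character_, length(g)) else l
  }))
  out <- GenomicRanges::GRanges(ctg, IRanges::IRanges(s, e))
  if (!all(is.na(lab))) S4Vectors::mcols(out)$label <- lab
  out
}

read_bed_regions <- function(bed_path) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  lines <- readLines(bed_path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  recs <- lapply(which(keep), function(i) {
    f <- strsplit(lines[i], "\t")[[1L]]
    if (length(f) < 3L)
      stop("BED parse error at line ", i, ": fewer than 3 fields")
    start0 <- suppressWarnings(as.numeric(f[2L]))
    end0 <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start0) || is.na(end0))
      stop("BED parse error at line ", i, ": non-numeric coordinate")
    if (start0 < 0 || end0 <= start0)
      stop("BED parse error at line ", i, ": requires 0 <= start < end")
    data.frame(contig = f[1L], start0 = start0, end0 = end0,
               name = if (length(f) >= 4L) f[4L] else NA_character_)
  })
  if (!length(recs)) stop("BED file contains no intervals: ", bed_path)
  tab <- do.call(rbind, recs)
  GenomicRanges::GRanges(normalize_contig(tab$contig),
                         IRanges::IRanges(tab$start0 + 1, tab$end0),
                         name = tab$name)
}

extend_clamp <- function(gr, extend_bp) {
  s <- pmax(1, GenomicRanges::start(gr) - extend_bp)
  e <- GenomicRanges::end(gr) + extend_bp
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr), IRanges::IRanges(s, e))
}

as_region_gr <- function(x) {
  if (is.character(x) && length(x) == 1L && grepl(":", x)) {
    p <- parse_region_string(x)
    return(GenomicRanges::GRanges(p$contig, IRanges::IRanges(p$start, p$end)))
  }
  if (length(x) == 3L)
    return(GenomicRanges::GRanges(normalize_contig(as.character(x[[1L]])),
                                  IRanges::IRanges(as.numeric(x[[2L]]),
                                                   as.numeric(x[[3L]]))))
  stop("cannot interpret region specification")
}

#' Write a region set as BED
#'
#' @param regions `GRanges` as returned by [prepare_regions()].
#' @param path Output path; 0-based half-open coordinates are restored.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  lab <- S4Vectors::mcols(regions)$label
  if (is.null(lab)) lab <- rep(".", length(regions))
  writeLines(paste(as.character(GenomicRanges::seqnames(regions)),
                   GenomicRanges::start(regions) - 1L,
                   GenomicRanges::end(regions), lab, sep = "\t"), path)
  invisible(path)
}
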