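BASES <- c("A", "C", "G", "T")
EVENT_ROWS <- c(BASES, "del")

#' Build a per-position pileup over the analysis regions
#'
#' Accumulates base, deletion and insertion event counts per genomic
#' position from alignment records. Input may be the simulator's
#' truth-alignment TSV, a SAM/BAM file (read through Rsamtools), or an
#' in-memory data.frame with columns contig, pos, cigar, seq. Contig
#' names are normalized, so files using either chromosome naming
#' convention ("chr12" or "12") are accepted. Aligned bases outside the
#' regions, and unmapped records (contig `"*"`), are ignored; records on
#' contigs absent from the region set raise a lookup error naming the
#' offending contigs.
#'
#' @param alignments Path (truth TSV, `.sam` or `.bam`) or data.frame.
#' @param regions `GRanges` of analysis regions.
#' @return Object of class `pileup`: per-region 5 x width count
#'   matrices (rows A, C, G, T, del), an insertion count table, and the
#'   region set.
#' @export
build_pileup <- function(alignments, regions) {
  aln <- if (is.data.frame(alignments)) alignments
    else if (is.character(alignments) && length(alignments) == 1L) {
      if (grepl("\\.(sam|bam)$", alignments, ignore.case = TRUE))
        read_sam_alignments(alignments)
      else read_truth_alignments(alignments)
    } else stop("alignments must be a data.frame or a file path")

  regions <- normalize_region_contigs(regions)
  rcontig <- as.character(GenomicRanges::seqnames(regions))
  rstart <- GenomicRanges::start(regions)
  rend <- GenomicRanges::end(regions)
  widths <- rend - rstart + 1L
  counts <- lapply(widths, function(w)
    matrix(0L, nrow = 5L, ncol = w, dimnames = list(EVENT_ROWS, NULL)))

  ins_keys <- character(0)

  if (nrow(aln)) {
    mapped <- aln$contig != "*" & aln$cigar != "*"
    aln <- aln[mapped, , drop = FALSE]
  }
  if (nrow(aln)) {
    aln$contig <- normalize_contig(aln$contig)
    unknown <- setdiff(unique(aln$contig), unique(rcontig))
    if (length(unknown))
      stop("alignment contig(s) not present in the region set: ",
           paste(unknown, collapse = ", "))

    simple <- grepl("^[0-9]+M$", aln$cigar)
    ev <- alignment_events(aln, simple)
    # ev: list(pos_contig, pos, code) for base/del events; ins data.frame
    for (r in seq_along(widths)) {
      sel <- ev$contig == rcontig[r] & ev$pos >= rstart[r] & ev$pos <= rend[r]
      if (!any(sel)) next
      idx <- ev$pos[sel] - rstart[r]
      key <- idx * 5L + ev$code[sel]
      counts[[r]] <- counts[[r]] +
        matrix(tabulate(key, nbins = 5L * widths[r]), nrow = 5L,
               dimnames = list(EVENT_ROWS, NULL))
    }
    ins_keys <- ev$ins
  }
  ins <- if (length(ins_keys)) {
    t0 <- table(ins_keys)
    parts <- strsplit(names(t0), "\r")
    data.frame(contig = vapply(parts, `[`, "", 1L),
               pos = as.integer(vapply(parts, `[`, "", 2L)),
               seq = vapply(parts, `[`, "", 3L),
               count = as.integer(t0), stringsAsFactors = FALSE)
  } else data.frame(contig = character(), pos = integer(),
                    seq = character(), count = integer())

  structure(list(regions = regions, counts = counts, insertions = ins),
            class = "pileup")
}

# Expand alignment records into flat event vectors. Simple "<n>M"
# records take a vectorized path; others are walked op by op.
alignment_events <- function(aln, simple) {
  contig <- character(0); pos <- integer(0); code <- integer(0)
  ins <- character(0)

  if (any(simple)) {
    s <- aln[simple, , drop = FALSE]
    L <- nchar(s$seq)
    allpos <- sequence(L) - 1L + rep(s$pos, L)
    allctg <- rep(s$contig, L)
    ch <- strsplit(paste(s$seq, collapse = ""), "")[[1L]]
    allcode <- match(ch, BASES)  # N or other -> NA, dropped below
    keep <- !is.na(allcode)
    contig <- allctg[keep]; pos <- allpos[keep]; code <- allcode[keep]
  }
  for (i in which(!simple)) {
    ops <- parse_cigar(aln$cigar[i])
    rpos <- aln$pos[i]; qpos <- 1L
    for (j in seq_len(nrow(ops))) {
      l <- ops$len[j]
      switch(ops$op[j],
        M = {
          b <- match(strsplit(substr(aln$seq[i], qpos, qpos + l - 1L),
                              "")[[1L]], BASES)
          keep <- !is.na(b)
          contig <- c(contig, rep(aln$contig[i], sum(keep)))
          pos <- c(pos, (rpos:(rpos + l - 1L))[keep])
          code <- c(code, b[keep])
          rpos <- rpos + l; qpos <- qpos + l
        },
        D = {
          contig <- c(contig, rep(aln$contig[i], l))
          pos <- c(pos, rpos:(rpos + l - 1L))
          code <- c(code, rep(5L, l))
          rpos <- rpos + l
        },
        I = {
          ins <- c(ins, paste(aln$contig[i], rpos - 1L,
                              substr(aln$seq[i], qpos, qpos + l - 1L),
                              sep = "\r"))
          qpos <- qpos + l
        },
        S = { qpos <- qpos + l },
        H = { },
        stop("unsupported CIGAR op '", ops$op[j], "' in ", aln$cigar[i]))
    }
  }
  list(contig = contig, pos = pos, code = code, ins = ins)
}

parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(m) || paste(m, collapse = "") != cigar)
    stop("malformed CIGAR: ", cigar)
  data.frame(len = as.integer(sub("[A-Z=]$", "", m)),
             op = sub("^[0-9]+", "", m), stringsAsFactors = FALSE)
}

read_sam_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(qname = b$qname, mate = 1L,
             contig = as.character(b$rname), pos = b$pos,
             strand = as.character(b$strand), cigar = b$cigar,
             seq = as.character(b$seq), stringsAsFactors = FALSE)
}

#' @export
print.pileup <- function(x, ...) {
  tot <- vapply(x$counts, function(m) sum(as.numeric(m)), 0)
  cat("Pileup over", length(x$counts), "region(s);",
      format(sum(tot), big.mark = ","), "aligned base/del events;",
      nrow(x$insertions), "distinct insertion(s)\n")
  invisible(x)
}

# Rebuild a GRanges with canonical contig names (GRanges seqlevels
# cannot be renamed onto colliding levels in place).
normalize_region_contigs <- function(gr) {
  ctg <- normalize_contig(as.character(GenomicRanges::seqnames(gr)))
  out <- GenomicRanges::GRanges(ctg,
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

# Row index of the region containing (contig, pos), or NA.
region_index_of <- function(pileup, contig, pos) {
  rc <- as.character(GenomicRanges::seqnames(pileup$regions))
  rs <- GenomicRanges::start(pileup$regions)
  re <- GenomicRanges::end(pileup$regions)
  hit <- which(rc == contig & pos >= rs & pos <= re)
  if (length(hit)) hit[1L] else NA_integer_
}

# Event counts (A,C,G,T,del) at a single position.
counts_at <- function(pileup, contig, pos) {
  r <- region_index_of(pileup, contig, pos)
  if (is.na(r)) stop("position outside pileup regions: ", contig, ":", pos)
  pileup$counts[[r]][, pos - GenomicRanges::start(pileup$regions)[r] + 1L]
}

#' Mean read depth of a region
#'
#' Depth at a position counts aligned bases plus deletion events
#' (deleted positions are still spanned by their reads); the mean is
#' taken over every position of the region, including uncovered ones.
#'
#' @param pileup A `pileup`.
#' @param region `"contig:start-end"` string or `GRanges` of length 1;
#'   must be covered by the pileup's region set.
#' @return Mean depth (numeric).
#' @export
region_mean_depth <- function(pileup, region) {
  gr <- if (inherits(region, "GRanges")) normalize_region_contigs(region)
        else as_region_gr(region)
  ctg <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  r <- region_index_of(pileup, ctg, s)
  r2 <- region_index_of(pileup, ctg, e)
  if (is.na(r) || is.na(r2) || r != r2)
    stop("region not contained in a single pileup region: ", ctg, ":", s, "-", e)
  off <- GenomicRanges::start(pileup$regions)[r]
  m <- pileup$counts[[r]][, (s - off + 1L):(e - off + 1L), drop = FALSE]
  mean(colSums(m))
}

# Count of insertion events with the given inserted sequence anchored
# at (contig, pos), and the total insertion count at that anchor.
insertion_counts <- function(pileup, contig, pos, inserted) {
  i <- pileup$insertions
  at <- i$contig == contig & i$pos == pos
  c(match_count = sum(i$count[at & i$seq == inserted]),
    total = sum(i$count[at]))
}
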