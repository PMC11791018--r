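#' Build a simulation template from a reference genome
#'
#' Extracts one sequence per analysis region from the reference and
#' replaces the span of `placeholder_region` by a sentinel run of `N`,
#' into which a haplotype sequence is later inserted. Template sequences
#' are named `"contig:start-end"` (1-based, closed, canonical contig
#' names) so that every base maps back to a genomic coordinate.
#'
#' @param reference_fasta Path to the reference FASTA (indexed access is
#'   not required; the file is read whole).
#' @param regions `GRanges` of analysis regions (see [prepare_regions()]).
#' @param placeholder_region Region to blank out, as a
#'   `"contig:start-end"` string or `(contig, start, end)` vector; must
#'   fall entirely inside a single analysis region.
#' @return An object of class `genome_template`.
#' @export
build_template <- function(reference_fasta, regions, placeholder_region) {
  ref <- read_reference(reference_fasta)
  ctg <- as.character(GenomicRanges::seqnames(regions))
  miss <- setdiff(unique(ctg), names(ref))
  if (length(miss))
    stop("contig missing from reference: ", paste(miss, collapse = ", "))
  starts <- GenomicRanges::start(regions)
  ends <- GenomicRanges::end(regions)
  too_far <- ends > Biostrings::width(ref)[match(ctg, names(ref))]
  if (any(too_far))
    stop("region beyond contig end: ", ctg[too_far][1L], ":",
         starts[too_far][1L], "-", ends[too_far][1L])

  seqs <- Biostrings::DNAStringSet(lapply(seq_along(regions), function(i)
    Biostrings::subseq(ref[[ctg[i]]], starts[i], ends[i])))
  names(seqs) <- paste0(ctg, ":", starts, "-", ends)

  ph <- as_region_gr(placeholder_region)
  hit <- which(IRanges::overlapsAny(regions, ph))
  within <- which(IRanges::overlapsAny(ph, regions, type = "within"))
  if (length(hit) != 1L || length(within) != 1L)
    stop("placeholder must lie entirely within exactly one region")
  ph_ctg <- as.character(GenomicRanges::seqnames(ph))
  ph_s <- GenomicRanges::start(ph); ph_e <- GenomicRanges::end(ph)
  off_s <- ph_s - starts[hit] + 1L
  off_e <- ph_e - starts[hit] + 1L
  ph_seq <- seqs[[hit]]
  Biostrings::subseq(ph_seq, off_s, off_e) <-
    Biostrings::DNAString(strrep("N", off_e - off_s + 1L))
  seqs[[hit]] <- ph_seq

  structure(list(
    sequences = seqs,
    regions = regions,
    origin = data.frame(seq_name = names(seqs), contig = ctg,
                        gstart = starts, gend = ends,
                        stringsAsFactors = FALSE),
    placeholder = list(seq_name = names(seqs)[hit], offset_start = off_s,
                       offset_end = off_e, contig = ph_ctg,
                       gstart = ph_s, gend = ph_e)),
    class = "genome_template")
}

read_reference <- function(reference_fasta) {
  ref <- Biostrings::readDNAStringSet(reference_fasta)
  names(ref) <- normalize_contig(sub("\\s.*$", "", names(ref)))
  ref
}

#' @export
print.genome_template <- function(x, ...) {
  cat("Genome template:", length(x$sequences), "region sequence(s), total",
      sum(Biostrings::width(x$sequences)), "bp\n")
  cat("  placeholder:", x$placeholder$contig, ":", x$placeholder$gstart, "-",
      x$placeholder$gend, " (", x$placeholder$gend - x$placeholder$gstart + 1L,
      " bp)\n", sep = "")
  invisible(x)
}

#' Construct a haplotype sequence by applying variants to the reference
#'
#' Applies a VCF-style variant set (SNVs, anchored insertions and
#' deletions) to the reference bases of a region and returns both the
#' haplotype sequence and a per-base map back to genomic coordinates
#' (`NA` for inserted bases). Reference alleles are verified against the
#' reference sequence.
#'
#' @param reference_fasta Path to the reference FASTA, or a
#'   `DNAStringSet` already read with canonical names.
#' @param region `"contig:start-end"` string or `GRanges` of length 1.
#' @param variants data.frame with columns contig, pos, ref, alt.
#' @return list with `seq` (character), `refpos` (integer vector of
#'   genomic positions, `NA` at inserted bases).
#' @export
build_haplotype <- function(reference_fasta, region, variants) {
  ref <- if (inherits(reference_fasta, "DNAStringSet")) reference_fasta
         else read_reference(reference_fasta)
  gr <- if (inherits(region, "GRanges")) region else as_region_gr(region)
  stopifnot(length(gr) == 1L)
  ctg <- as.character(GenomicRanges::seqnames(gr))
  gs <- GenomicRanges::start(gr); ge <- GenomicRanges::end(gr)
  if (!ctg %in% names(ref)) stop("contig missing from reference: ", ctg)
  base <- strsplit(toupper(as.character(
    Biostrings::subseq(ref[[ctg]], gs, ge))), "")[[1L]]
  refpos <- seq.int(gs, ge)
  if (is.null(variants) || nrow(variants) == 0L)
    return(list(seq = paste(base, collapse = ""), refpos = refpos))

  v <- variants
  v$contig <- normalize_contig(v$contig)
  if (any(v$contig != ctg)) stop("variant on a different contig than the region")
  if (any(v$pos < gs | v$pos + nchar(v$ref) - 1L > ge))
    stop("variant outside the haplotype region")
  v <- v[order(-v$pos), , drop = FALSE]
  if (anyDuplicated(v$pos)) stop("overlapping variants at one position")
  for (i in seq_len(nrow(v))) {
    idx <- v$pos[i] - gs + 1L
    rl <- nchar(v$ref[i])
    seen <- paste(base[idx:(idx + rl - 1L)], collapse = "")
    if (seen != v$ref[i])
      stop("reference mismatch at ", ctg, ":", v$pos[i], " (expected ",
           v$ref[i], ", reference has ", seen, ")")
    altc <- strsplit(v$alt[i], "")[[1L]]
    pre <- if (idx > 1L) seq_len(idx - 1L) else integer(0)
    post <- if (idx + rl - 1L < length(base))
      seq.int(idx + rl, length(base)) else integer(0)
    newpos <- c(refpos[idx], rep(NA_integer_, length(altc) - 1L))
    if (nchar(v$ref[i]) > 1L && length(altc) == 1L)  # deletion keeps anchor
      newpos <- refpos[idx]
    base <- c(base[pre], altc, base[post])
    refpos <- c(refpos[pre], newpos, refpos[post])
  }
  list(seq = paste(base, collapse = ""), refpos = refpos)
}

#' Insert a haplotype sequence into a template
#'
#' Replaces the sentinel placeholder of a [build_template()] result by
#' the haplotype sequence, producing the per-region sample sequences a
#' read simulator draws from. Minus-orientation input is
#' reverse-complemented to the plus strand first. Every sequence keeps a
#' per-base map to genomic coordinates so that simulated reads carry
#' exact truth alignments.
#'
#' @param template A `genome_template`.
#' @param hap_seq Haplotype sequence (character or `DNAString`),
#'   alphabet ACGTN.
#' @param orientation `"plus"` or `"minus"`.
#' @param hap_refpos Optional integer map from haplotype base (plus
#'   orientation) to genomic position, as returned by
#'   [build_haplotype()]. Defaults to the identity map when the
#'   haplotype has the placeholder's length.
#' @return An object of class `hap_sample`: `sequences` (named character
#'   vector) and `refpos` (list of integer vectors).
#' @export
insert_haplotype <- function(template, hap_seq, orientation = c("plus", "minus"),
                             hap_refpos = NULL) {
  stopifnot(inherits(template, "genome_template"))
  orientation <- match.arg(orientation)
  hap <- toupper(as.character(hap_seq))
  if (!nzchar(hap)) stop("haplotype sequence is empty")
  if (grepl("[^ACGTN]", hap)) stop("haplotype sequence outside alphabet ACGTN")
  if (orientation == "minus") {
    hap <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hap)))
    if (!is.null(hap_refpos)) hap_refpos <- rev(hap_refpos)
  }
  ph <- template$placeholder
  seqs <- as.character(template$sequences)
  target <- seqs[[ph$seq_name]]
  span <- substr(target, ph$offset_start, ph$offset_end)
  if (grepl("[^N]", span))
    stop("placeholder sentinel absent: template span already holds sequence")

  if (is.null(hap_refpos)) {
    if (nchar(hap) == ph$gend - ph$gstart + 1L) {
      hap_refpos <- seq.int(ph$gstart, ph$gend)
    } else {
      warning("haplotype length differs from placeholder and no hap_refpos ",
              "given; bases inside the insert will carry no truth coordinates")
      hap_refpos <- rep(NA_integer_, nchar(hap))
    }
  }
  if (length(hap_refpos) != nchar(hap))
    stop("hap_refpos length does not match haplotype length")

  out_seqs <- seqs
  out_seqs[[ph$seq_name]] <- paste0(
    substr(target, 1L, ph$offset_start - 1L), hap,
    substr(target, ph$offset_end + 1L, nchar(target)))

  refpos <- lapply(seq_along(seqs), function(i) {
    o <- template$origin[i, ]
    seq.int(o$gstart, o$gend)
  })
  names(refpos) <- names(seqs)
  i <- match(ph$seq_name, names(seqs))
  o <- template$origin[i, ]
  refpos[[ph$seq_name]] <- c(
    if (ph$gstart > o$gstart) seq.int(o$gstart, ph$gstart - 1L) else integer(0),
    as.integer(hap_refpos),
    if (ph$gend < o$gend) seq.int(ph$gend + 1L, o$gend) else integer(0))

  structure(list(sequences = out_seqs, refpos = refpos,
                 contig = setNames(template$origin$contig,
                                   template$origin$seq_name),
                 placeholder_seq = ph$seq_name),
            class = "hap_sample")
}

#' Write template or sample sequences as FASTA
#' @param x A `genome_template` or `hap_sample`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_sample_fasta <- function(x, path) {
  s <- if (inherits(x, "genome_template")) x$sequences
       else Biostrings::DNAStringSet(x$sequences)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
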