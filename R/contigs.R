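#' Normalize contig names to the canonical bare form
#'
#' GRCh38-aligned files circulate with both chromosome naming conventions
#' ("chr1" and "1"). All contig names entering the package -- allele
#' definitions, region files, alignment records -- are mapped to one
#' canonical form (the bare form, "12" not "chr12", and "MT" for the
#' mitochondrion) so that downstream comparisons are convention-free.
#'
#' @param name Character vector of contig names.
#' @param warn Warn on contigs outside the standard human set
#'   (1-22, X, Y, MT)? Unknown contigs are passed through unchanged
#'   (minus any "chr" prefix).
#' @return Character vector of canonical contig names.
#' @examples
#' normalize_contig(c("chr12", "12", "chrMT", "chrM"))
#' @export
normalize_contig <- function(name, warn = FALSE) {
  if (length(name) == 0L) return(character(0))
  if (any(is.na(name)) || any(!nzchar(name)))
    stop("contig name must be non-empty")
  x <- sub("^chr", "", as.character(name))
  x[x == "M"] <- "MT"
  if (warn) {
    known <- c(as.character(1:22), "X", "Y", "MT")
    odd <- setdiff(unique(x), known)
    if (length(odd))
      warning("non-standard contig name(s) passed through: ",
              paste(odd, collapse = ", "))
  }
  x
}

# Parse "chr12:47841537-47905022" (1-based, closed) into a list
# (contig, start, end) with the contig normalized.
parse_region_string <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region string: ", x)
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (end < start) stop("region end precedes start: ", x)
  list(contig = normalize_contig(m[2]), start = start, end = end)
}
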