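#' Read-simulation configuration
#'
#' Paired-end read model: uniform fragment placement per sequence,
#' Gaussian insert size, constant base quality, substitution-only
#' sequencing errors. The seed is mandatory; identical configuration and
#' inputs reproduce byte-identical outputs.
#'
#' @param depth Target mean diploid coverage (e.g. 40).
#' @param read_len Read length in bases (>= 20).
#' @param insert_mean,insert_sd Fragment-size model (bp).
#' @param error_rate Per-base substitution probability, in [0, 0.1].
#' @param base_quality Constant Phred quality written to FASTQ.
#' @param seed Integer seed (required).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(depth = 40, read_len = 150L, insert_mean = 400,
                       insert_sd = 50, error_rate = 0.001,
                       base_quality = 30L, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(depth >= 0, read_len >= 20L, error_rate >= 0, error_rate <= 0.1,
            insert_mean >= 2 * read_len, insert_sd >= 0, base_quality >= 2L)
  structure(list(depth = depth, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, base_quality = as.integer(base_quality),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Project a read placed at [s, s+len-1] on a sample sequence onto
# genomic coordinates, via the sequence's per-base refpos map.
# Returns list(pos, cigar) or NULL when no base maps (read entirely
# inside an insertion).
project_read <- function(refpos, s, len) {
  rp <- refpos[s:(s + len - 1L)]
  nn <- which(!is.na(rp))
  if (!length(nn)) return(NULL)
  lead <- nn[1L] - 1L
  trail <- len - nn[length(nn)]
  seg <- rp[nn[1L]:nn[length(nn)]]
  ops <- character(0); lens <- integer(0)
  push <- function(op, l) {
    k <- length(ops)
    if (k && ops[k] == op) lens[k] <<- lens[k] + l
    else { ops[k + 1L] <<- op; lens[k + 1L] <<- l }
  }
  if (lead) push("S", lead)
  r <- rle(is.na(seg))
  at <- 1L
  last_ref <- NA_integer_
  for (j in seq_along(r$lengths)) {
    l <- r$lengths[j]
    if (r$values[j]) {
      push("I", l)
    } else {
      block <- seg[at:(at + l - 1L)]
      if (!is.na(last_ref) && block[1L] - last_ref > 1L)
        push("D", block[1L] - last_ref - 1L)
      # split on internal jumps (deletions)
      jumps <- which(diff(block) != 1L)
      prev <- 1L
      for (q in c(jumps, l)) {
        push("M", q - prev + 1L)
        if (q < l) push("D", block[q + 1L] - block[q] - 1L)
        prev <- q + 1L
      }
      last_ref <- block[l]
    }
    at <- at + l
  }
  if (trail) push("S", trail)
  list(pos = seg[1L], cigar = paste0(lens, ops, collapse = ""))
}

# Vectorized projection: reads whose window holds no insertion bases
# and no deletion gap take the fast "<len>M" path; the rest go through
# project_read().
project_many <- function(refpos, starts, rl) {
  n <- length(starts)
  ends <- starts + rl - 1L
  cumNA <- cumsum(is.na(refpos))
  noNA <- (cumNA[ends] - ifelse(starts > 1L, cumNA[starts - 1L], 0L)) == 0L
  simple <- noNA & (refpos[ends] - refpos[starts] == rl - 1L)
  simple[is.na(simple)] <- FALSE
  pos <- integer(n); cigar <- rep("*", n); ok <- logical(n)
  pos[simple] <- refpos[starts[simple]]
  cigar[simple] <- paste0(rl, "M")
  ok[simple] <- TRUE
  for (i in which(!simple)) {
    p <- project_read(refpos, starts[i], rl)
    if (!is.null(p)) { pos[i] <- p$pos; cigar[i] <- p$cigar; ok[i] <- TRUE }
  }
  list(pos = pos, cigar = cigar, ok = ok)
}

#' Simulate paired-end reads from a diploid sample
#'
#' Draws read pairs from the sequences of one or two chromosome copies
#' (one copy supplied twice is the homozygous mode). Fragment starts are
#' uniform along each sequence; each copy receives half the target
#' depth, so structural configurations (a copy lacking the gene
#' sequence, or carrying it twice) translate directly into depth ratios.
#' Truth alignments -- genomic position and CIGAR derived from the
#' haplotype coordinate map -- are recorded before error injection.
#'
#' @param copies list of one or two `hap_sample` objects (chromosome
#'   copies); a single element is used for both copies.
#' @param config A [sim_config()].
#' @param haplotype_ids Character vector naming the haplotypes, recorded
#'   in the manifest.
#' @param out_dir Optional directory; when given, paired FASTQ
#'   (Phred+33), a truth-alignment TSV and a JSON manifest are written.
#' @return Object of class `simulated_sample`: `reads` (data.frame with
#'   qname, mate, contig, pos, strand, cigar, seq -- aligned
#'   orientation), `fastq` (read sequences/quals as sequenced), and
#'   `manifest`.
#' @export
simulate_reads <- function(copies, config, haplotype_ids = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(copies, "hap_sample")) copies <- list(copies)
  stopifnot(length(copies) %in% c(1L, 2L))
  if (length(copies) == 1L) copies <- copies[c(1L, 1L)]
  set.seed(config$seed)

  instances <- list()
  for (ci in seq_along(copies)) {
    cp <- copies[[ci]]
    stopifnot(inherits(cp, "hap_sample"))
    for (sn in names(cp$sequences)) {
      instances[[length(instances) + 1L]] <- list(
        copy = ci, name = sn, seq = cp$sequences[[sn]],
        refpos = cp$refpos[[sn]], contig = cp$contig[[sn]])
    }
  }
  rl <- config$read_len
  recs <- vector("list", length(instances))
  fq <- vector("list", length(instances))
  for (k in seq_along(instances)) {
    ins <- instances[[k]]
    L <- nchar(ins$seq)
    n_pairs <- round(config$depth / 2 * L / (2 * rl))
    if (config$depth > 0 && L < config$insert_mean)
      stop("degenerate input: sequence ", ins$name, " (", L,
           " bp) shorter than the mean insert size")
    if (n_pairs < 1L) next
    frag <- pmin(pmax(round(rnorm(n_pairs, config$insert_mean,
                                  config$insert_sd)), 2L * rl), L)
    start <- floor(runif(n_pairs, 1, L - frag + 1 + 1))
    flip <- runif(n_pairs) < 0.5  # which physical strand the fragment is read from
    s1 <- start
    s2 <- start + frag - rl
    qn <- sprintf("sim:%d:%d:%d", config$seed, k, seq_len(n_pairs))

    fwd1 <- substring(ins$seq, s1, s1 + rl - 1L)
    fwd2 <- substring(ins$seq, s2, s2 + rl - 1L)
    # substitution errors on the aligned-orientation bases
    fwd1 <- inject_errors(fwd1, config$error_rate)
    fwd2 <- inject_errors(fwd2, config$error_rate)

    pc1 <- project_many(ins$refpos, s1, rl)
    pc2 <- project_many(ins$refpos, s2, rl)
    mk <- function(pc, seqv, mate, minus) {
      data.frame(
        qname = qn, mate = mate,
        contig = ifelse(pc$ok, ins$contig, "*"),
        pos = pc$pos,
        strand = ifelse(minus, "-", "+"),
        cigar = pc$cigar,
        seq = seqv, stringsAsFactors = FALSE)
    }
    # R1 reads the left end on the fragment strand: when flip, mate 1 is
    # the right end read on the minus strand
    recs[[k]] <- rbind(mk(pc1, fwd1, ifelse(flip, 2L, 1L), FALSE),
                       mk(pc2, fwd2, ifelse(flip, 1L, 2L), TRUE))
    fq[[k]] <- data.frame(qname = c(qn, qn),
                          mate = c(ifelse(flip, 2L, 1L), ifelse(flip, 1L, 2L)),
                          seq = c(fwd1, revcomp(fwd2)),
                          stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  fq <- fq[!vapply(fq, is.null, TRUE)]
  reads <- if (length(recs)) do.call(rbind, recs) else
    data.frame(qname = character(), mate = integer(), contig = character(),
               pos = integer(), strand = character(), cigar = character(),
               seq = character())
  fastq <- if (length(fq)) do.call(rbind, fq) else
    data.frame(qname = character(), mate = integer(), seq = character())

  manifest <- list(
    config = unclass(config),
    haplotype_ids = haplotype_ids,
    homozygous = length(unique(haplotype_ids)) <= 1L,
    instances = data.frame(
      copy = vapply(instances, `[[`, 0L, "copy"),
      name = vapply(instances, `[[`, "", "name"),
      length = vapply(instances, function(i) nchar(i$seq), 0L)),
    n_pairs = nrow(reads) / 2)
  sim <- structure(list(reads = reads, fastq = fastq, manifest = manifest),
                   class = "simulated_sample")
  if (!is.null(out_dir)) write_sim_outputs(sim, out_dir)
  sim
}

revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  rl <- nchar(seqs)
  n_err <- rbinom(length(seqs), rl, error_rate)
  for (i in which(n_err > 0L)) {
    at <- sample.int(rl[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1L]]
    for (p in at) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat("Simulated sample:", x$manifest$n_pairs, "read pairs")
  if (!is.null(x$manifest$haplotype_ids))
    cat(" from", paste(allele_label(x$manifest$haplotype_ids), collapse = "/"))
  cat("\n")
  invisible(x)
}

#' Write simulator outputs (FASTQ pair, truth TSV, manifest JSON)
#'
#' @param sim A `simulated_sample`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output paths.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  qual <- strrep(rawToChar(as.raw(33L + sim$manifest$config$base_quality)),
                 sim$manifest$config$read_len)
  paths <- file.path(dir, c("reads_R1.fastq", "reads_R2.fastq",
                            "truth.tsv", "manifest.json"))
  for (m in 1:2) {
    f <- sim$fastq[sim$fastq$mate == m, , drop = FALSE]
    f <- f[order(f$qname), , drop = FALSE]
    writeLines(as.vector(rbind(paste0("@", f$qname, "/", m),
                               f$seq, "+", qual)), paths[m])
  }
  tr <- sim$reads[order(sim$reads$qname, sim$reads$mate), , drop = FALSE]
  con <- file(paths[3L], "w")
  writeLines("#starcall-truth-1", con)
  write.table(tr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(sim$manifest, paths[4L], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(paths)
}

#' Write truth alignments as SAM
#'
#' Minimal single-end SAM rendering of the truth placements (mapped
#' records only), for interoperability with samtools/Rsamtools.
#'
#' @param sim A `simulated_sample`.
#' @param path Output SAM path.
#' @param reference_fasta Reference FASTA used for the header `@SQ`
#'   lines.
#' @return Invisibly, `path`.
#' @export
write_truth_sam <- function(sim, path, reference_fasta) {
  ref <- read_reference(reference_fasta)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref), "\tLN:", Biostrings::width(ref)))
  r <- sim$reads[sim$reads$contig != "*", , drop = FALSE]
  qual <- strrep(rawToChar(as.raw(33L + sim$manifest$config$base_quality)),
                 sim$manifest$config$read_len)
  flag <- ifelse(r$strand == "-", 16L, 0L)
  body <- paste(paste0(r$qname, "/", r$mate), flag, r$contig, r$pos, 60L,
                r$cigar, "*", 0L, 0L, r$seq, qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a truth-alignment TSV back into alignment records
#' @param path Truth TSV written by [write_sim_outputs()].
#' @return data.frame with qname, mate, contig, pos, strand, cigar, seq.
#' @export
read_truth_alignments <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "#starcall-truth-1")
    stop("not a truth-alignment file (missing #starcall-truth-1 header): ", path)
  read.delim(text = lines[-1L], header = TRUE, sep = "\t",
             colClasses = c(qname = "character", mate = "integer",
                            contig = "character", pos = "integer",
                            strand = "character", cigar = "character",
                            seq = "character"))
}
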