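#' Caller configuration
#'
#' Thresholds of the genotyping model. `delta` is the allelic-imbalance
#' tolerance: a site is homozygous-alternate at alternate fraction
#' >= 1 - delta and homozygous-reference at <= delta, so modest
#' imbalance (mismapping, sampling noise) does not block a homozygous
#' call. Heterozygotes live in the band 0.5 +/- `het_width`; fractions
#' between the bands are ambiguous and yield no-calls.
#'
#' @param min_site_depth Minimum informative depth at a definition site.
#' @param delta Allelic-imbalance tolerance, 0 < delta < 0.5.
#' @param het_width Half-width of the heterozygous band around 0.5.
#' @param control_region Copy-number control region (VDR gene by
#'   default), `"contig:start-end"` (1-based, closed).
#' @param cn_confidence_max Maximum |cn_raw - cn_called| before the CN
#'   estimate is flagged low-confidence.
#' @param cn_del_frac Gene/control depth ratio below which the sample
#'   is called a homozygous whole-gene deletion (*5/*5).
#' @param cn_trim Depth means for copy number stay this many bases away
#'   from the ends of the containing analysis region, where coverage of
#'   an extracted region tapers over roughly a fragment length.
#'   Clamping is skipped when fewer than 200 bp would remain.
#' @param max_depth_nocall_frac Fraction of definition sites allowed
#'   below `min_site_depth` before the whole sample is filtered
#'   `no_call_depth`.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(min_site_depth = 10L, delta = 0.15,
                          het_width = 0.15,
                          control_region = "chr12:47841537-47905022",
                          cn_confidence_max = 0.35, cn_del_frac = 0.05,
                          cn_trim = 500L, max_depth_nocall_frac = 0.25) {
  stopifnot(delta > 0, delta < 0.5, het_width > 0, het_width < 0.5,
            0.5 + het_width < 1 - delta,  # het and hom-alt bands must not touch
            min_site_depth >= 1, cn_del_frac > 0, cn_del_frac < 0.5)
  structure(list(min_site_depth = as.integer(min_site_depth), delta = delta,
                 het_width = het_width, control_region = control_region,
                 cn_confidence_max = cn_confidence_max,
                 cn_del_frac = cn_del_frac, cn_trim = as.integer(cn_trim),
                 max_depth_nocall_frac = max_depth_nocall_frac),
            class = "caller_config")
}

#' Classify one definition site from its allele counts
#'
#' @param ref_count,alt_count Reference/alternate read counts.
#' @param cfg A [caller_config()].
#' @return One of `"hom_ref"`, `"het"`, `"hom_alt"`, `"no_call"`.
#' @export
site_call <- function(ref_count, alt_count, cfg) {
  depth <- ref_count + alt_count
  af <- ifelse(depth > 0, alt_count / depth, NA_real_)
  out <- rep("no_call", length(depth))
  ok <- depth >= cfg$min_site_depth
  out[ok & af >= 1 - cfg$delta] <- "hom_alt"
  out[ok & af <= cfg$delta] <- "hom_ref"
  out[ok & af >= 0.5 - cfg$het_width & af <= 0.5 + cfg$het_width] <- "het"
  out
}

#' Genotype every allele-definition site from a pileup
#'
#' For each distinct variant in the database, extracts reference and
#' alternate evidence from the pileup (base counts for SNVs, spanning
#' deletion events for deletions, anchored insertion events for
#' insertions) and classifies the site under the imbalance-tolerant
#' model of [site_call()].
#'
#' @param pileup A [build_pileup()] result.
#' @param sites data.frame of variants (contig, pos, ref, alt, kind),
#'   typically `unique(db$variants[-1])`; contigs are normalized.
#' @param cfg A [caller_config()].
#' @return data.frame: one row per site with counts, `alt_fraction`,
#'   `depth`, `call` and `low_depth`.
#' @export
genotype_sites <- function(pileup, sites, cfg = caller_config()) {
  stopifnot(inherits(pileup, "pileup"))
  s <- unique(sites[, c("contig", "pos", "ref", "alt", "kind")])
  s$contig <- normalize_contig(s$contig)
  n <- nrow(s)
  rc <- ac <- integer(n)
  for (i in seq_len(n)) {
    kind <- s$kind[i]
    if (kind == "SNV") {
      cts <- counts_at(pileup, s$contig[i], s$pos[i])
      rc[i] <- cts[[s$ref[i]]]
      ac[i] <- cts[[s$alt[i]]]
    } else if (kind == "deletion") {
      cts <- counts_at(pileup, s$contig[i], s$pos[i] + 1L)
      rc[i] <- sum(cts[BASES])
      ac[i] <- cts[["del"]]
    } else {
      inserted <- substr(s$alt[i], 2L, nchar(s$alt[i]))
      ic <- insertion_counts(pileup, s$contig[i], s$pos[i], inserted)
      cts <- counts_at(pileup, s$contig[i], s$pos[i])
      rc[i] <- max(sum(cts[BASES]) - ic[["total"]], 0L)
      ac[i] <- ic[["match_count"]]
    }
  }
  depth <- rc + ac
  data.frame(s, ref_count = rc, alt_count = ac,
             alt_fraction = ifelse(depth > 0, ac / depth, NA_real_),
             depth = depth, call = site_call(rc, ac, cfg),
             low_depth = depth < cfg$min_site_depth,
             stringsAsFactors = FALSE)
}

#' Estimate gene copy number against the control region
#'
#' Copy number is twice the ratio of mean gene depth to mean control
#' depth (the control gene, VDR by default, is diploid and copy-number
#' stable), rounded to the nearest non-negative integer. The deviation
#' of the raw ratio from the rounded call is reported as a confidence
#' measure.
#'
#' @param pileup A `pileup` covering both regions.
#' @param gene_region,control_region `"contig:start-end"` strings or
#'   `GRanges`.
#' @param cfg A [caller_config()].
#' @return Object of class `cn_estimate`.
#' @export
estimate_copy_number <- function(pileup, gene_region,
                                 control_region = NULL,
                                 cfg = caller_config()) {
  if (is.null(control_region)) control_region <- cfg$control_region
  gene <- region_mean_depth(pileup, interior_clamp(pileup, gene_region,
                                                   cfg$cn_trim))
  ctrl <- region_mean_depth(pileup, interior_clamp(pileup, control_region,
                                                   cfg$cn_trim))
  if (ctrl <= 0) stop("control region has zero depth; cannot normalize")
  cn_raw <- 2 * gene / ctrl
  cn_called <- max(0L, as.integer(round(cn_raw)))
  structure(list(gene_mean_depth = gene, control_mean_depth = ctrl,
                 cn_raw = cn_raw, cn_called = cn_called,
                 confidence = abs(cn_raw - cn_called),
                 low_confidence = abs(cn_raw - cn_called) > cfg$cn_confidence_max,
                 deletion = gene / ctrl < cfg$cn_del_frac),
            class = "cn_estimate")
}

#' @export
print.cn_estimate <- function(x, ...) {
  cat(sprintf("Copy number %d (raw %.2f; gene %.1fx / control %.1fx%s)\n",
              x$cn_called, x$cn_raw, x$gene_mean_depth, x$control_mean_depth,
              if (x$low_confidence) "; LOW CONFIDENCE" else ""))
  invisible(x)
}

# Clamp a query region to the interior of its containing pileup region:
# coverage tapers within a fragment length of the ends of an extracted
# region, so depth means for CN stay `trim` bp away from those ends.
# Skipped when fewer than 200 bp would remain.
interior_clamp <- function(pileup, region, trim) {
  gr <- if (inherits(region, "GRanges")) normalize_region_contigs(region)
        else as_region_gr(region)
  ctg <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  r <- region_index_of(pileup, ctg, s)
  if (is.na(r)) return(gr)
  rs <- GenomicRanges::start(pileup$regions)[r] + trim
  re <- GenomicRanges::end(pileup$regions)[r] - trim
  s2 <- max(s, rs); e2 <- min(e, re)
  if (e2 - s2 + 1L < 200L) return(gr)
  GenomicRanges::GRanges(ctg, IRanges::IRanges(s2, e2))
}

# ---- diplotype resolution ------------------------------------------------

# Dosage matrix: canonical minors x unique sites (0/1).
dosage_matrix <- function(db, sites) {
  minors <- db$minors[db$minors$canonical, , drop = FALSE]
  skey <- paste(sites$contig, sites$pos, sites$ref, sites$alt, sep = ":")
  D <- matrix(0L, nrow = nrow(minors), ncol = nrow(sites),
              dimnames = list(minors$suballele_id, skey))
  v <- db$variants[db$variants$suballele_id %in% minors$suballele_id, ]
  if (nrow(v)) {
    vk <- paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
    D[cbind(match(v$suballele_id, minors$suballele_id), match(vk, skey))] <- 1L
  }
  D
}

# Expected site-call category for dosage d out of c copies:
# 0 copies carry the variant -> hom_ref(0); all -> hom_alt(2); else het(1).
expected_category <- function(d, copies) {
  ifelse(d == 0L, 0L, ifelse(d == copies, 2L, 1L))
}

#' Resolve the star-allele diplotype from site genotypes
#'
#' Enumerates candidate haplotype pairs over the canonical minor
#' alleles and keeps those whose expected per-site dosage matches every
#' informative site call. A copy-number call of 1 restricts candidates
#' to a single haplotype paired with the whole-gene deletion allele *5;
#' a call of 3 gives one haplotype a "x2" duplication multiplier.
#' Among consistent pairs the one with the fewest total defining
#' variants is preferred (so a variant-free sample resolves to the
#' reference diplotype); if distinct pairs remain tied the sample is
#' filtered `no_call_ambiguous`, with candidates ranked by lowest
#' canonical allele name. Alias-group members are collapsed to their
#' canonical representative and reported as aliases.
#'
#' @param site_gt [genotype_sites()] output covering all database
#'   sites.
#' @param cn A `cn_estimate` (or NULL to assume two copies).
#' @param db An `allele_db`.
#' @param cfg A [caller_config()].
#' @return Object of class `diplotype_call`.
#' @export
resolve_diplotype <- function(site_gt, cn, db, cfg = caller_config()) {
  stopifnot(inherits(db, "allele_db"))
  cn_called <- if (is.null(cn)) 2L else cn$cn_called
  if (!is.null(cn) && isTRUE(cn$deletion))
    return(new_diplotype_call("5", "5", db, cn, site_gt, "PASS"))

  if (mean(site_gt$low_depth) > cfg$max_depth_nocall_frac)
    return(new_diplotype_call(NA, NA, db, cn, site_gt, "no_call_depth"))

  calls <- c(hom_ref = 0L, het = 1L, hom_alt = 2L,
             no_call = NA_integer_)[site_gt$call]
  use <- !is.na(calls)
  D <- dosage_matrix(db, site_gt)
  minors <- db$minors[db$minors$canonical, , drop = FALSE]
  nv <- minors$n_variants
  m <- nrow(minors)
  tgt <- calls[use]
  Du <- D[, use, drop = FALSE]

  cand <- NULL
  if (cn_called >= 4L) cn_called <- 3L  # higher amplifications folded into x2
  if (cn_called == 2L) {
    rows <- list()
    for (i in seq_len(m)) {
      E <- sweep(Du, 2L, Du[i, ], "+")   # dosage of pair (i, j) per site
      okj <- which(rowSums(E != rep(tgt, each = m)) == 0L & seq_len(m) >= i)
      if (length(okj))
        rows[[length(rows) + 1L]] <- data.frame(
          a = i, b = okj, mult_a = 1L, mult_b = 1L,
          nvar = nv[i] + nv[okj])
    }
    cand <- if (length(rows)) do.call(rbind, rows) else NULL
  } else if (cn_called == 1L) {
    Ecat <- 2L * Du
    ok <- which(rowSums(Ecat != rep(tgt, each = m)) == 0L)
    if (length(ok))
      cand <- data.frame(a = ok, b = NA_integer_, mult_a = 1L, mult_b = 1L,
                         nvar = nv[ok])
  } else if (cn_called == 3L) {
    rows <- list()
    for (i in seq_len(m)) {
      d <- sweep(Du, 2L, 2L * Du[i, ], "+")
      Ecat <- ifelse(d == 0L, 0L, ifelse(d == 3L, 2L, 1L))
      okj <- which(rowSums(Ecat != rep(tgt, each = m)) == 0L)
      if (length(okj))
        rows[[length(rows) + 1L]] <- data.frame(
          a = i, b = okj, mult_a = 2L, mult_b = 1L,
          nvar = 2L * nv[i] + nv[okj])
    }
    cand <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(cand)) {  # (i x2, j) and (j x2, i) are distinct; drop exact dupes
      key <- paste(pmin(cand$a * 10L + 2L, cand$b * 10L + 1L),
                   pmax(cand$a * 10L + 2L, cand$b * 10L + 1L))
      cand <- cand[!duplicated(key), , drop = FALSE]
    }
  } else {  # cn_called == 0 without the explicit deletion flag
    return(new_diplotype_call("5", "5", db, cn, site_gt, "PASS"))
  }

  if (is.null(cand) || nrow(cand) == 0L)
    return(new_diplotype_call(NA, NA, db, cn, site_gt, "no_call_unmatched"))

  cand <- cand[cand$nvar == min(cand$nvar), , drop = FALSE]
  cand <- order_candidates(cand, minors)
  top <- cand[1L, ]
  a_id <- minors$suballele_id[top$a]
  b_id <- if (is.na(top$b)) "5" else minors$suballele_id[top$b]
  filter <- if (nrow(cand) > 1L) "no_call_ambiguous" else "PASS"
  new_diplotype_call(a_id, b_id, db, cn, site_gt, filter,
                     mult_a = top$mult_a, mult_b = top$mult_b,
                     candidates = cand, minors = minors)
}

# Order candidate pairs by the name-sorted (major, suffix) quadruple.
order_candidates <- function(cand, minors) {
  key <- t(vapply(seq_len(nrow(cand)), function(k) {
    ids <- c(cand$a[k], cand$b[k])
    mm <- minors$major_id[ids]; ss <- minors$suffix[ids]
    mm[is.na(ids)] <- 5L; ss[is.na(ids)] <- "000"
    o <- order(mm, ss)
    c(mm[o[1L]], as.integer(ss[o[1L]]), mm[o[2L]], as.integer(ss[o[2L]]))
  }, integer(4L)))
  cand[order(key[, 1L], key[, 2L], key[, 3L], key[, 4L]), , drop = FALSE]
}

new_diplotype_call <- function(a_id, b_id, db, cn, site_gt, filter,
                               mult_a = 1L, mult_b = 1L, candidates = NULL,
                               minors = NULL) {
  # order the pair so hap_a <= hap_b by (major, suffix, multiplier)
  if (!is.na(a_id) && !is.na(b_id)) {
    pa <- parse_allele_name(c(a_id, b_id))
    o <- order(pa$major_id, pa$suffix, c(mult_a, mult_b))
    ids <- c(a_id, b_id)[o]
    mults <- c(mult_a, mult_b)[o]
    a_id <- ids[1L]; b_id <- ids[2L]
    mult_a <- mults[1L]; mult_b <- mults[2L]
  }
  aliases_of <- function(id) {
    if (is.na(id) || !id %in% db$minors$suballele_id) return(character(0))
    grp <- db$minors$alias_group[db$minors$suballele_id == id]
    others <- db$minors$suballele_id[db$minors$alias_group == grp &
                                       db$minors$suballele_id != id]
    legacy <- db$minors$legacy_name[db$minors$suballele_id == id]
    c(allele_label(others), legacy[!is.na(legacy)])
  }
  cand_labels <- NULL
  if (!is.null(candidates) && nrow(candidates) > 1L) {
    cand_labels <- vapply(seq_len(nrow(candidates)), function(k) {
      a <- minors$suballele_id[candidates$a[k]]
      b <- if (is.na(candidates$b[k])) "5" else minors$suballele_id[candidates$b[k]]
      paste(allele_label(a, candidates$mult_a[k]),
            allele_label(b, candidates$mult_b[k]), sep = "/")
    }, "")
  }
  structure(list(hap_a = if (is.na(a_id)) NA_character_ else allele_label(a_id, mult_a),
                 hap_b = if (is.na(b_id)) NA_character_ else allele_label(b_id, mult_b),
                 hap_a_id = a_id, hap_b_id = b_id,
                 mult_a = mult_a, mult_b = mult_b,
                 aliases = list(hap_a = aliases_of(a_id),
                                hap_b = aliases_of(b_id)),
                 filter = filter, cn = cn, evidence = site_gt,
                 candidates = cand_labels),
            class = "diplotype_call")
}

#' @export
print.diplotype_call <- function(x, ...) {
  dip <- if (is.na(x$hap_a)) "./." else paste(x$hap_a, x$hap_b, sep = "/")
  cat("Diplotype:", dip, " [", x$filter, "]\n", sep = " ")
  if (length(x$aliases$hap_a) || length(x$aliases$hap_b)) {
    al <- c(x$aliases$hap_a, x$aliases$hap_b)
    cat("  aliases:", paste(unique(al), collapse = ", "), "\n")
  }
  if (!is.null(x$cn))
    cat(sprintf("  copy number: %d (raw %.2f)\n", x$cn$cn_called, x$cn$cn_raw))
  if (!is.null(x$candidates))
    cat("  tied candidates:", paste(x$candidates, collapse = "; "), "\n")
  invisible(x)
}

#' Genotype one sample end to end
#'
#' Composition of [build_pileup()], [genotype_sites()],
#' [estimate_copy_number()] and [resolve_diplotype()]; deterministic
#' for fixed inputs.
#'
#' @param alignments Truth TSV / SAM / BAM path or alignment
#'   data.frame.
#' @param db An `allele_db`.
#' @param regions `GRanges` of analysis regions (must cover the control
#'   region).
#' @param gene_region `"contig:start-end"` of the gene; defaults to the
#'   span of the database's definition sites.
#' @param cfg A [caller_config()].
#' @return A `diplotype_call`.
#' @export
call_sample <- function(alignments, db, regions, gene_region = NULL,
                        cfg = caller_config()) {
  pl <- build_pileup(alignments, regions)
  if (is.null(gene_region)) gene_region <- infer_gene_region(db, regions)
  cn <- estimate_copy_number(pl, gene_region, cfg$control_region, cfg)
  sg <- genotype_sites(pl, db$variants, cfg)
  resolve_diplotype(sg, cn, db, cfg)
}

# The analysis region containing the database's definition sites.
infer_gene_region <- function(db, regions) {
  if (nrow(db$variants) == 0L) stop("database defines no variants")
  gr <- GenomicRanges::GRanges(db$variants$contig,
                               IRanges::IRanges(db$variants$pos,
                                                db$variants$pos))
  hit <- IRanges::overlapsAny(regions, gr)
  if (!any(hit)) stop("no analysis region contains the definition sites")
  r <- regions[which(hit)[1L]]
  paste0(GenomicRanges::seqnames(r), ":", GenomicRanges::start(r), "-",
         GenomicRanges::end(r))
}
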