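#' Generate a self-contained toy fixture suite
#'
#' Emits, at desk scale, everything the genotyping pipeline consumes:
#' a two-contig toy reference FASTA (a gene-bearing contig and a
#' control-gene contig), a region BED, a synthetic star-allele
#' definition database in the native schema, and a JSON manifest of
#' every generated truth. The database contains `n_alleles` minor
#' alleles with mutually distinct variant sets, plus by construction:
#' one variant-free reference allele (`1.001`), exactly one alias pair
#' (two minors under different majors sharing one variant set), one
#' no-function allele, one decreased-function allele, one
#' unassigned-function allele (undefined activity), and at least one
#' insertion and one deletion variant. Major 5 (whole-gene deletion) is
#' annotated with no function but carries no variant rows.
#'
#' All randomness flows from `seed`; identical calls are byte-identical
#' on disk.
#'
#' @param n_alleles Number of minor alleles (>= 6 for the guaranteed
#'   features above; >= 2 accepted).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return list with `db` (the loaded `allele_db`), `regions`
#'   (`GRanges`), and the file `paths`, `gene_region`, `control_region`,
#'   `placeholder` strings.
#' @export
make_fixture_suite <- function(n_alleles = 20L, seed, dir = tempfile("fixture")) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_alleles >= 2L)
  set.seed(as.integer(seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  contig_gene <- "22"; len_gene <- 9000L
  contig_ctrl <- "12"; len_ctrl <- 6000L
  ref <- Biostrings::DNAStringSet(c(
    paste(sample(c("A", "C", "G", "T"), len_gene, replace = TRUE), collapse = ""),
    paste(sample(c("A", "C", "G", "T"), len_ctrl, replace = TRUE), collapse = "")))
  names(ref) <- c(contig_gene, contig_ctrl)
  ref_path <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(ref, ref_path)

  bed_path <- file.path(dir, "regions.bed")
  writeLines(paste(contig_gene, 4000L, 8000L, "gene_fixture", sep = "\t"),
             bed_path)
  control_region <- paste0(contig_ctrl, ":1201-4800")
  placeholder <- paste0(contig_gene, ":5001-7000")
  regions <- prepare_regions(bed_path, extend_bp = 1000L,
                             extra_regions = control_region)

  tab_annot <- synth_allele_table(n_alleles, ref, placeholder)
  def_path <- file.path(dir, "alleles.tsv")
  annot_path <- file.path(dir, "annotations.json")
  db0 <- build_allele_db(tab_annot$tab, tab_annot$annot,
                         regions = regions, source = "synthetic fixture")
  write_allele_db(db0, def_path, annot_path)
  db <- load_allele_db(def_path, annot_path, regions = regions)

  counts <- setNames(as.list(db$minors$n_variants), db$minors$suballele_id)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    generator = "make_fixture_suite", seed = as.integer(seed),
    n_alleles = n_alleles,
    gene_region = paste0(contig_gene, ":3001-9000"),
    control_region = control_region,
    placeholder = placeholder,
    alias_pair = tab_annot$alias_pair,
    unassigned_function_allele = tab_annot$unassigned,
    variant_counts = counts,
    files = list(reference = basename(ref_path), bed = basename(bed_path),
                 definitions = basename(def_path),
                 annotations = basename(annot_path))),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(db = db, regions = regions, dir = dir,
       paths = list(reference = ref_path, bed = bed_path,
                    definitions = def_path, annotations = annot_path,
                    manifest = manifest_path),
       gene_region = paste0(contig_gene, ":3001-9000"),
       control_region = control_region,
       placeholder = placeholder,
       alias_pair = tab_annot$alias_pair)
}

# Build the native-schema definition table + annotation list for a
# synthetic database whose variants are consistent with `ref` inside
# the placeholder span.
synth_allele_table <- function(n_alleles, ref, placeholder) {
  ph <- parse_region_string(placeholder)
  refseq <- strsplit(as.character(ref[[ph$contig]]), "")[[1L]]
  grid <- seq.int(ph$start + 20L, ph$end - 20L, by = 9L)
  grid <- sample(grid)  # shuffled; positions handed out disjointly

  n_payload <- n_alleles - 1L  # minus reference allele
  majors_avail <- setdiff(seq.int(2L, n_alleles + 100L), 5L)
  alias_pair <- NULL
  if (n_alleles >= 4L) {
    n_payload <- n_alleles - 3L
    am <- if (max(majors_avail[seq_len(n_payload)]) < 36L) c(36L, 57L)
          else majors_avail[n_payload + 1:2]
    alias_pair <- c(sprintf("%d.005", am[1L]), sprintf("%d.001", am[2L]))
  }
  payload_majors <- majors_avail[seq_len(max(n_payload, 0L))]

  need <- 4L * n_payload + 4L  # upper bound on positions consumed
  if (need > length(grid))
    stop("n_alleles exceeds placeholder capacity (", length(grid),
         " variant slots)")

  take <- local({
    i <- 0L
    function(k) { out <- grid[(i + 1L):(i + k)]; i <<- i + k; sort(out) }
  })
  snv_at <- function(p) {
    refb <- refseq[p - 0L]
    data.frame(contig = ph$contig, pos = p, ref = refb,
               alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1L))
  }
  ins_at <- function(p, len = 4L) {
    data.frame(contig = ph$contig, pos = p, ref = refseq[p],
               alt = paste0(refseq[p],
                            paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")))
  }
  del_at <- function(p, len = 3L) {
    data.frame(contig = ph$contig, pos = p,
               ref = paste(refseq[p:(p + len)], collapse = ""),
               alt = refseq[p])
  }

  rows <- list()
  add_allele <- function(id, major, legacy, v) {
    if (is.null(v) || nrow(v) == 0L)
      rows[[length(rows) + 1L]] <<- data.frame(
        suballele_id = id, major_id = as.character(major),
        legacy_name = legacy, contig = "", pos = "", ref = "", alt = "")
    else
      rows[[length(rows) + 1L]] <<- data.frame(
        suballele_id = id, major_id = as.character(major),
        legacy_name = legacy, contig = v$contig, pos = as.character(v$pos),
        ref = v$ref, alt = v$alt)
  }

  add_allele("1.001", 1L, "*1A", NULL)
  fun_cycle <- c("no", "decreased", "normal", "unassigned", "decreased",
                 "normal", "normal", "decreased")
  act_for <- c(no = 0, decreased = 0.5, normal = 1)
  funs <- character(0)
  for (j in seq_len(n_payload)) {
    m <- payload_majors[j]
    id <- sprintf("%d.001", m)
    k <- sample(1:3, 1L)
    v <- do.call(rbind, lapply(take(k), snv_at))
    if (j == 2L && n_payload >= 2L) v <- rbind(v, ins_at(take(1L)))
    if (j == 3L && n_payload >= 3L) v <- rbind(v, del_at(take(1L)))
    v <- v[order(v$pos), ]
    add_allele(id, m, if (j == 1L) sprintf("*%dA", m) else "", v)
    funs[as.character(m)] <- fun_cycle[(j - 1L) %% length(fun_cycle) + 1L]
  }
  if (!is.null(alias_pair)) {
    av <- do.call(rbind, lapply(take(2L), snv_at))
    am <- parse_suballele_id(alias_pair)$major_id
    add_allele(alias_pair[1L], am[1L], "", av)
    add_allele(alias_pair[2L], am[2L], sprintf("*%d", am[2L]), av)
    funs[as.character(am)] <- c("decreased", "decreased")
  }

  all_majors <- c(1L, 5L, payload_majors,
                  if (!is.null(alias_pair)) parse_suballele_id(alias_pair)$major_id)
  funs["1"] <- "normal"; funs["5"] <- "no"
  pops <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  majors <- lapply(all_majors, function(m) {
    f <- funs[[as.character(m)]]
    out <- list(`function` = f)
    if (f %in% names(act_for)) out$activity_value <- unname(act_for[[f]])
    out$evidence <- sample(c("Definitive", "Moderate", "Limited"), 1L)
    out$frequencies <- as.list(setNames(round(runif(length(pops), 0, 0.4), 4),
                                        pops))
    out
  })
  names(majors) <- as.character(all_majors)
  unassigned <- names(funs)[funs == "unassigned"]
  list(tab = do.call(rbind, rows),
       annot = list(schema_version = "starcall-annot-1",
                    source = "synthetic fixture", majors = majors),
       alias_pair = alias_pair,
       unassigned = if (length(unassigned))
         sprintf("%s.001", unassigned[1L]) else NULL)
}

#' Write a synthetic PharmVar-style download directory
#'
#' Renders an existing database in the file layout [import_pharmvar()]
#' consumes: a `CYP2D6.haplotypes.fasta` with one sequence per minor
#' allele (built by applying each allele's variants to the reference
#' placeholder span) and a tab-separated variant table with
#' PharmVar-style column headers. Indel rows are written in gap
#' notation (`-` alleles) to exercise re-anchoring on import. Synthetic
#' stand-in for a real PharmVar download; used by tests and importable
#' offline.
#'
#' @param fixture A [make_fixture_suite()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_pharmvar_fixture <- function(fixture, dir = file.path(fixture$dir, "pharmvar")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- fixture$db
  ref <- read_reference(fixture$paths$reference)
  seqs <- Biostrings::DNAStringSet(vapply(db$minors$suballele_id, function(id)
    build_haplotype(ref, fixture$placeholder, variants_of(db, id))$seq, ""))
  names(seqs) <- paste0("CYP2D6*", db$minors$suballele_id)
  Biostrings::writeXStringSet(seqs, file.path(dir, "CYP2D6.haplotypes.fasta"))

  rows <- lapply(db$minors$suballele_id, function(id) {
    v <- variants_of(db, id)
    hap <- paste0("CYP2D6*", id)
    if (nrow(v) == 0L) return(NULL)  # reference allele gets its own row below
    out <- data.frame(`Haplotype Name` = hap, Chromosome = v$contig,
                      `Variant Start` = as.character(v$pos),
                      `Reference Allele` = v$ref, `Variant Allele` = v$alt,
                      Type = v$kind, check.names = FALSE)
    ins <- v$kind == "insertion"
    del <- v$kind == "deletion"
    # gap notation: position of the anchor (ins) / first deleted base (del)
    out$`Reference Allele`[ins] <- "-"
    out$`Variant Allele`[ins] <- substr(v$alt[ins], 2L, nchar(v$alt[ins]))
    out$`Variant Start`[del] <- as.character(v$pos[del] + 1L)
    out$`Reference Allele`[del] <- substr(v$ref[del], 2L, nchar(v$ref[del]))
    out$`Variant Allele`[del] <- "-"
    out
  })
  tab <- do.call(rbind, rows)
  ref_rows <- data.frame(
    `Haplotype Name` = paste0("CYP2D6*",
      db$minors$suballele_id[db$minors$n_variants == 0L]),
    Chromosome = "", `Variant Start` = "", `Reference Allele` = "",
    `Variant Allele` = "", Type = "reference", check.names = FALSE)
  tab <- rbind(tab, ref_rows)
  write.table(tab, file.path(dir, "CYP2D6.variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate reads for a chosen diplotype on a fixture
#'
#' Convenience wrapper: builds both haplotype sequences from their
#' database variant sets, inserts them into the region template, and
#' simulates reads, optionally with an altered gene copy number.
#'
#' @param fixture A [make_fixture_suite()] result (or any list with
#'   `db`, `regions`, `placeholder` and `paths$reference`).
#' @param hap_a,hap_b Minor-allele ids (default homozygous for
#'   `hap_a`).
#' @param config A [sim_config()].
#' @param cn `"diploid"` (2 gene copies), `"hemi"` (1 copy; the other
#'   chromosome carries the whole-gene deletion *5), `"dup"` (3 copies;
#'   `hap_a` duplicated in tandem) or `"del_hom"` (0 copies, *5/*5).
#' @param template Optional pre-built [build_template()] result, to
#'   amortize template construction across a sweep.
#' @param out_dir Optional output directory (see [simulate_reads()]).
#' @return A `simulated_sample`; its manifest records the truth
#'   diplotype including copy-number qualifiers.
#' @export
simulate_diplotype <- function(fixture, hap_a, hap_b = hap_a, config,
                               cn = c("diploid", "hemi", "dup", "del_hom"),
                               template = NULL, out_dir = NULL) {
  cn <- match.arg(cn)
  db <- fixture$db
  if (is.null(template))
    template <- build_template(fixture$paths$reference, fixture$regions,
                               fixture$placeholder)
  ref <- read_reference(fixture$paths$reference)
  mk_copy <- function(id) {
    hp <- build_haplotype(ref, fixture$placeholder, variants_of(db, id))
    insert_haplotype(template, hp$seq, "plus", hap_refpos = hp$refpos)
  }
  ca <- mk_copy(hap_a)
  cb <- if (hap_b == hap_a) ca else mk_copy(hap_b)
  truth <- c(hap_a, hap_b)
  if (cn == "hemi") { cb <- drop_gene_copy(cb); truth <- c(hap_a, "5") }
  if (cn == "del_hom") {
    ca <- drop_gene_copy(ca); cb <- drop_gene_copy(cb); truth <- c("5", "5")
  }
  if (cn == "dup") {
    ca <- duplicate_gene_copy(ca)
    truth <- c(paste0(hap_a, "x2"), hap_b)
  }
  sim <- simulate_reads(list(ca, cb), config, haplotype_ids = truth,
                        out_dir = out_dir)
  sim$manifest$cn_mode <- cn
  sim
}

drop_gene_copy <- function(hs) {
  keep <- names(hs$sequences) != hs$placeholder_seq
  hs$sequences <- hs$sequences[keep]
  hs$refpos <- hs$refpos[keep]
  hs$contig <- hs$contig[keep]
  hs
}

duplicate_gene_copy <- function(hs) {
  g <- hs$placeholder_seq
  nm <- paste0(g, ".dup")
  hs$sequences[nm] <- hs$sequences[[g]]
  hs$refpos[[nm]] <- hs$refpos[[g]]
  hs$contig[nm] <- hs$contig[[g]]
  hs
}
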