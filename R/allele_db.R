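#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

ALLELE_FUNCTIONS <- c("normal", "decreased", "no",
                      "unknown", "uncertain", "unassigned")
DEF_SCHEMA <- "starcall-defs-1"
DEF_COLUMNS <- c("suballele_id", "major_id", "legacy_name",
                 "contig", "pos", "ref", "alt")

#' Classify a variant from its VCF-style ref/alt alleles
#'
#' Variants are held in 1-based, VCF-style minimal representation:
#' SNVs have one reference and one alternate base; indels are anchored
#' (deletion: alt is the single anchor base and a prefix of ref;
#' insertion: ref is the single anchor base and a prefix of alt).
#'
#' @param ref,alt Character vectors of reference/alternate alleles.
#' @return Character vector: "SNV", "insertion" or "deletion".
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  bad <- grepl("[^ACGTN]", ref) | grepl("[^ACGTN]", alt)
  if (any(bad))
    stop("non-ACGTN allele string: ", paste(ref[bad], alt[bad], collapse = " "))
  if (any(ref == alt)) stop("ref and alt must differ")
  kind <- rep(NA_character_, length(ref))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L
  del <- nchar(ref) > 1L & nchar(alt) == 1L & substr(ref, 1L, 1L) == alt
  ins <- nchar(alt) > 1L & nchar(ref) == 1L & substr(alt, 1L, 1L) == ref
  kind[snv] <- "SNV"; kind[del] <- "deletion"; kind[ins] <- "insertion"
  if (anyNA(kind))
    stop("variant not in minimal anchored representation: ",
         paste(ref[is.na(kind)], ">", alt[is.na(kind)], collapse = ", "))
  kind
}

# Canonical string key of a variant set, used for alias grouping and
# exact set matching. Empty set -> "".
variant_set_key <- function(v) {
  if (is.null(v) || nrow(v) == 0L) return("")
  paste(sort(paste(v$contig, v$pos, v$ref, v$alt, sep = ":")), collapse = ";")
}

parse_suballele_id <- function(id) {
  m <- regmatches(id, regexec("^([0-9]+)\\.([0-9]{3})$", id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed suballele id (expected <major>.<3-digit suffix>): ",
         paste(unique(id[bad]), collapse = ", "))
  data.frame(major_id = as.integer(vapply(m, `[`, "", 2L)),
             suffix = vapply(m, `[`, "", 3L))
}

#' Parse a star-allele name
#'
#' Accepts "*10.001", "10.001", "*1x2", "*5". Returns the bare id, the
#' major number, the suffix (NA for major-only names such as "*5") and
#' the copy multiplier.
#'
#' @param name Character vector of allele names.
#' @return data.frame with columns id, major_id, suffix, mult.
#' @export
parse_allele_name <- function(name) {
  x <- sub("^\\*", "", as.character(name))
  m <- regmatches(x, regexec("^([0-9]+)(\\.([0-9]{3}))?(x([0-9]+))?$", x))
  bad <- vapply(m, length, 1L) != 6L
  if (any(bad)) stop("cannot parse allele name: ",
                     paste(name[bad], collapse = ", "))
  mult <- vapply(m, `[`, "", 6L)
  suffix <- vapply(m, `[`, "", 4L)
  data.frame(id = sub("x[0-9]+$", "", x),
             major_id = as.integer(vapply(m, `[`, "", 2L)),
             suffix = ifelse(nzchar(suffix), suffix, NA_character_),
             mult = ifelse(nzchar(mult), as.integer(mult), 1L))
}

allele_label <- function(id, mult = 1L) {
  if (!length(id)) return(character(0))
  paste0("*", id, ifelse(mult > 1L, paste0("x", mult), ""))
}

#' Load a star-allele definition database
#'
#' Reads the native definition schema: a versioned TSV with one row per
#' allele-variant pair (the reference allele contributes a single row
#' with empty variant fields) and a JSON sidecar holding per-major
#' clinical annotation (function category, activity value, evidence,
#' population frequencies). All contig names are normalized on load and
#' alias groups -- sets of minor alleles sharing an identical variant
#' set -- are computed.
#'
#' @param def_path Path to the definition TSV. The first line must
#'   declare the schema (`#schema=starcall-defs-1`) and a header row is
#'   mandatory.
#' @param annot_path Path to the JSON annotation sidecar.
#' @param regions Optional `GRanges` of analysis regions; when supplied,
#'   every variant is checked to fall inside a region.
#' @return An object of class `allele_db` with components `minors`,
#'   `variants`, `majors`, `frequencies`, `schema_version`, `source`.
#' @export
load_allele_db <- function(def_path, annot_path, regions = NULL) {
  if (!file.exists(def_path)) stop("definition file not found: ", def_path)
  if (!file.exists(annot_path)) stop("annotation file not found: ", annot_path)
  lines <- readLines(def_path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#schema="))
    stop("definition file does not declare its schema (expected '#schema=...')")
  schema <- sub("^#schema=", "", lines[1L])
  if (schema != DEF_SCHEMA)
    stop("unsupported definition schema: ", schema)
  body <- lines[-1L]
  if (length(body) == 0L)
    stop("definition file has no header row")
  tab <- read.delim(text = body, header = TRUE, sep = "\t",
                    colClasses = "character", na.strings = NULL,
                    check.names = FALSE)
  missing_cols <- setdiff(DEF_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("definition file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  annot <- jsonlite::read_json(annot_path)
  build_allele_db(tab, annot, regions = regions, source = def_path)
}

# Shared constructor/validator behind load_allele_db and the importers.
build_allele_db <- function(tab, annot, regions = NULL, source = "in-memory") {
  if (nrow(tab) == 0L)
    stop("validation error: no alleles defined (missing reference allele)")
  rowno <- seq_len(nrow(tab)) + 2L  # +schema line +header line
  ids <- tab$suballele_id
  parsed <- parse_suballele_id(ids)
  major_decl <- suppressWarnings(as.integer(tab$major_id))
  bad_major <- is.na(major_decl) | major_decl != parsed$major_id
  if (any(bad_major))
    stop("record ", rowno[which(bad_major)[1L]],
         ": major_id does not match suballele_id")

  has_var <- nzchar(tab$pos) | nzchar(tab$ref) | nzchar(tab$alt)
  vt <- tab[has_var, , drop = FALSE]
  vrow <- rowno[has_var]
  pos <- suppressWarnings(as.integer(vt$pos))
  if (anyNA(pos) || any(pos < 1L))
    stop("record ", vrow[which(is.na(pos) | pos < 1L)[1L]],
         ": variant pos must be a positive integer")
  variants <- data.frame(suballele_id = vt$suballele_id,
                         contig = normalize_contig(vt$contig),
                         pos = pos,
                         ref = toupper(vt$ref),
                         alt = toupper(vt$alt),
                         stringsAsFactors = FALSE)
  variants$kind <- classify_variant(variants$ref, variants$alt)

  dupkey <- paste(variants$suballele_id, variants$contig, variants$pos,
                  variants$ref, variants$alt)
  if (anyDuplicated(dupkey))
    stop("record ", vrow[which(duplicated(dupkey))[1L]],
         ": duplicate variant row for ", variants$suballele_id[duplicated(dupkey)][1L])

  # declaration rows (no variant fields) are only legal once per allele,
  # and only for alleles with no variant rows at all
  decl_ids <- tab$suballele_id[!has_var]
  if (anyDuplicated(decl_ids))
    stop("duplicate suballele_id declaration: ",
         decl_ids[duplicated(decl_ids)][1L])
  clash <- intersect(decl_ids, variants$suballele_id)
  if (length(clash))
    stop("duplicate suballele_id (declared both empty and with variants): ",
         clash[1L])

  minor_ids <- unique(ids)
  pm <- parse_suballele_id(minor_ids)
  legacy <- tab$legacy_name[match(minor_ids, ids)]
  legacy[!nzchar(legacy)] <- NA_character_

  vsets <- split(variants, factor(variants$suballele_id, levels = minor_ids))
  keys <- vapply(vsets, variant_set_key, "")
  nvar <- vapply(vsets, nrow, 1L)
  refs <- minor_ids[nvar == 0L]
  if (length(refs) == 0L)
    stop("validation error: missing reference allele (no minor with an empty variant set)")
  if (length(refs) > 1L)
    stop("validation error: multiple variant-free alleles: ",
         paste(refs, collapse = ", "))

  ord <- order(pm$major_id, pm$suffix)
  # alias groups: equivalence classes of identical variant sets; the
  # canonical representative is the current name with the lowest major
  # number, then the lowest suffix
  gkey <- ifelse(keys == "", "<reference>", keys)  # "" cannot index by name
  canon_of_key <- tapply(seq_along(minor_ids)[ord], gkey[ord],
                         function(i) minor_ids[i][1L])
  alias_group <- unname(canon_of_key[gkey])
  canonical <- minor_ids == alias_group

  minors <- data.frame(suballele_id = minor_ids,
                       major_id = pm$major_id,
                       suffix = pm$suffix,
                       legacy_name = legacy,
                       n_variants = as.integer(nvar),
                       alias_group = alias_group,
                       canonical = canonical,
                       vkey = unname(keys),
                       stringsAsFactors = FALSE)
  minors <- minors[order(minors$major_id, minors$suffix), ]
  rownames(minors) <- NULL

  maj <- parse_annotations(annot)
  missing_major <- setdiff(minors$major_id, maj$majors$major_id)
  if (length(missing_major))
    stop("validation error: minor allele references unknown major *",
         missing_major[1L])

  if (!is.null(regions)) {
    inside <- variant_in_regions(variants, regions)
    if (any(!inside))
      stop("variant outside declared analysis regions: ",
           paste0(variants$contig[!inside][1L], ":", variants$pos[!inside][1L]))
  }

  structure(list(minors = minors,
                 variants = variants,
                 majors = maj$majors,
                 frequencies = maj$frequencies,
                 schema_version = maj$schema_version,
                 source = source),
            class = "allele_db")
}

parse_annotations <- function(annot) {
  if (is.null(annot$majors) || !length(annot$majors))
    stop("annotation file defines no major alleles")
  mj <- annot$majors
  major_id <- as.integer(names(mj))
  if (anyNA(major_id)) stop("non-integer major allele key in annotations")
  fun <- vapply(mj, function(m) as.character(m$`function`), "")
  bad <- !fun %in% ALLELE_FUNCTIONS
  if (any(bad))
    stop("invalid function category '", fun[bad][1L], "' for major *",
         major_id[bad][1L])
  act <- vapply(mj, function(m)
    if (is.null(m$activity_value)) NA_real_ else as.numeric(m$activity_value),
    0)
  defined <- !is.na(act)
  if (any(defined & !fun %in% c("normal", "decreased", "no")))
    stop("activity value defined for major *",
         major_id[defined & !fun %in% c("normal", "decreased", "no")][1L],
         " with function outside {normal, decreased, no}")
  if (any(defined & fun == "no" & act != 0))
    stop("no-function major *", major_id[defined & fun == "no" & act != 0][1L],
         " must have activity value 0")
  if (any(defined & act < 0)) stop("negative activity value")
  ev <- vapply(mj, function(m)
    if (is.null(m$evidence)) NA_character_ else as.character(m$evidence), "")
  freqs <- do.call(rbind, lapply(seq_along(mj), function(i) {
    f <- mj[[i]]$frequencies
    if (is.null(f) || !length(f)) return(NULL)
    data.frame(major_id = major_id[i], population = names(f),
               frequency = as.numeric(unlist(f)), stringsAsFactors = FALSE)
  }))
  if (is.null(freqs))
    freqs <- data.frame(major_id = integer(), population = character(),
                        frequency = numeric())
  if (any(freqs$frequency < 0 | freqs$frequency > 1))
    stop("population frequency outside [0,1]")
  majors <- data.frame(major_id = major_id, fun = unname(fun),
                       activity_value = unname(act), evidence = unname(ev),
                       stringsAsFactors = FALSE)
  majors <- majors[order(majors$major_id), ]
  rownames(majors) <- NULL
  list(majors = majors, frequencies = freqs,
       schema_version = if (is.null(annot$schema_version)) "unversioned"
                        else annot$schema_version)
}

variant_in_regions <- function(variants, regions) {
  if (nrow(variants) == 0L) return(logical(0))
  gr <- GenomicRanges::GRanges(variants$contig,
                               IRanges::IRanges(variants$pos,
                                                variants$pos + nchar(variants$ref) - 1L))
  IRanges::overlapsAny(gr, regions, type = "within")
}

#' Defining variant set of a minor allele
#'
#' @param db An `allele_db`.
#' @param suballele_id Minor allele name, e.g. `"10.001"` (a leading
#'   `"*"` is tolerated).
#' @return data.frame of variants (zero rows for the reference allele).
#' @export
variants_of <- function(db, suballele_id) {
  stopifnot(inherits(db, "allele_db"))
  id <- sub("^\\*", "", suballele_id)
  if (!id %in% db$minors$suballele_id)
    stop("unknown minor allele: ", suballele_id)
  v <- db$variants[db$variants$suballele_id == id, , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Minor alleles whose variant set matches an observed set exactly
#'
#' Exact set matching: every returned allele's defining variant set
#' equals `observed`. Members of one alias group are all returned with
#' the canonical representative flagged.
#'
#' @param db An `allele_db`.
#' @param observed data.frame with columns contig, pos, ref, alt
#'   (contigs are normalized before comparison).
#' @return Subset of `db$minors` (zero rows if nothing matches).
#' @export
alleles_matching <- function(db, observed) {
  stopifnot(inherits(db, "allele_db"))
  if (!is.null(observed) && nrow(observed))
    observed$contig <- normalize_contig(observed$contig)
  key <- variant_set_key(observed)
  hit <- db$minors[db$minors$vkey == key, , drop = FALSE]
  hit <- hit[order(!hit$canonical, hit$major_id, hit$suffix), ]
  rownames(hit) <- NULL
  hit
}

major_row <- function(db, major_id) {
  i <- match(as.integer(major_id), db$majors$major_id)
  if (anyNA(i)) stop("unknown major allele: *", major_id[is.na(i)][1L])
  db$majors[i, , drop = FALSE]
}

#' Clinical function category of a major star allele
#' @param db An `allele_db`.
#' @param major_id Integer major star number (e.g. 18 for *18).
#' @return One of normal, decreased, no, unknown, uncertain, unassigned.
#' @export
function_of <- function(db, major_id) major_row(db, major_id)$fun

#' Activity value of a major star allele
#' @inheritParams function_of
#' @return Non-negative quarter-step activity value, or NA when the
#'   function is unknown/uncertain/unassigned.
#' @export
activity_of <- function(db, major_id) major_row(db, major_id)$activity_value

#' Serialize an allele database in the native schema
#'
#' Writes the definition TSV (one row per allele-variant pair) and the
#' JSON annotation sidecar; `load_allele_db()` on the result reproduces
#' the database.
#'
#' @param db An `allele_db`.
#' @param def_path,annot_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_allele_db <- function(db, def_path, annot_path) {
  stopifnot(inherits(db, "allele_db"))
  m <- db$minors[order(db$minors$major_id, db$minors$suffix), ]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    v <- db$variants[db$variants$suballele_id == m$suballele_id[i], , drop = FALSE]
    lg <- if (is.na(m$legacy_name[i])) "" else m$legacy_name[i]
    if (nrow(v) == 0L)
      return(data.frame(suballele_id = m$suballele_id[i],
                        major_id = m$major_id[i], legacy_name = lg,
                        contig = "", pos = "", ref = "", alt = ""))
    v <- v[order(v$contig, v$pos, v$ref, v$alt), ]
    data.frame(suballele_id = m$suballele_id[i], major_id = m$major_id[i],
               legacy_name = lg, contig = v$contig, pos = as.character(v$pos),
               ref = v$ref, alt = v$alt)
  })
  tab <- do.call(rbind, rows)
  con <- file(def_path, "w")
  on.exit(close(con))
  writeLines(paste0("#schema=", DEF_SCHEMA), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)

  mj <- db$majors
  majors <- lapply(seq_len(nrow(mj)), function(i) {
    f <- db$frequencies[db$frequencies$major_id == mj$major_id[i], , drop = FALSE]
    out <- list(`function` = mj$fun[i])
    if (!is.na(mj$activity_value[i])) out$activity_value <- mj$activity_value[i]
    if (!is.na(mj$evidence[i])) out$evidence <- mj$evidence[i]
    if (nrow(f)) out$frequencies <- as.list(setNames(f$frequency, f$population))
    out
  })
  names(majors) <- as.character(mj$major_id)
  jsonlite::write_json(list(schema_version = db$schema_version,
                            source = db$source, majors = majors),
                       annot_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(def_path, annot_path))
}

#' @export
print.allele_db <- function(x, ...) {
  cat("Star-allele definition database (schema ", x$schema_version, ")\n",
      sep = "")
  cat("  minors: ", nrow(x$minors), " (", sum(x$minors$n_variants == 0L),
      " reference, ", sum(!x$minors$canonical), " alias)\n", sep = "")
  cat("  majors annotated: ", nrow(x$majors), "\n", sep = "")
  cat("  defining variants: ", nrow(x$variants), " (",
      sum(x$variants$kind == "SNV"), " SNV, ",
      sum(x$variants$kind == "insertion"), " ins, ",
      sum(x$variants$kind == "deletion"), " del)\n", sep = "")
  cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Import a PharmVar-style download directory
#'
#' Consumes the file-based layout of a PharmVar gene download: a
#' multi-record haplotype FASTA (`*.haplotypes.fasta`, one sequence per
#' minor allele, names like `CYP2D6*10.001`) and a tab-separated variant
#' table with columns `Haplotype Name`, `Variant Start`,
#' `Reference Allele`, `Variant Allele` (header matching is
#' case-insensitive; a `Chromosome` column is used when present,
#' otherwise `contig` applies to all rows). Gap-style indel rows
#' (reference or variant allele `"-"`) are re-anchored to VCF minimal
#' representation against `ref_fasta` when supplied. Clinical
#' annotations are not part of PharmVar downloads and come from
#' `annot_path` (same JSON schema as the native sidecar).
#'
#' The importer converts everything to the native schema so no other
#' part of the tool parses PharmVar formats.
#'
#' @param dir Directory containing the download.
#' @param annot_path JSON annotation sidecar.
#' @param contig Default contig for tables without a chromosome column.
#' @param ref_fasta Optional reference FASTA used to anchor gap-style
#'   indel rows.
#' @return list with components `db` (an `allele_db`) and `haplotypes`
#'   (a `DNAStringSet` of per-allele haplotype sequences, named by
#'   suballele id).
#' @export
import_pharmvar <- function(dir, annot_path, contig = "22", ref_fasta = NULL) {
  fa <- list.files(dir, pattern = "\\.haplotypes\\.fasta$", full.names = TRUE)
  if (length(fa) != 1L)
    stop("expected exactly one *.haplotypes.fasta in ", dir)
  tsv <- list.files(dir, pattern = "\\.(tsv|txt)$", full.names = TRUE)
  tab <- NULL
  for (f in tsv) {
    t0 <- tryCatch(read.delim(f, colClasses = "character", check.names = FALSE,
                              na.strings = NULL, comment.char = "#"),
                   error = function(e) NULL)
    if (!is.null(t0) && any(grepl("haplotype", names(t0), ignore.case = TRUE))) {
      tab <- t0; break
    }
  }
  if (is.null(tab))
    stop("no variant table with a 'Haplotype Name' column found in ", dir)
  getcol <- function(pattern) {
    i <- grep(pattern, names(tab), ignore.case = TRUE)
    if (!length(i)) stop("variant table lacks a column matching '", pattern, "'")
    tab[[i[1L]]]
  }
  hap <- getcol("haplotype")
  vstart <- getcol("variant.?start|^position|^start")
  refa <- getcol("reference.?allele")
  alta <- getcol("variant.?allele")
  ctg <- if (any(grepl("chrom|contig", names(tab), ignore.case = TRUE)))
    getcol("chrom|contig") else rep(contig, nrow(tab))

  id <- sub("^.*\\*", "", hap)
  is_ref_row <- !nzchar(refa) & !nzchar(alta) |
    toupper(refa) == "REFERENCE" | toupper(alta) == "REFERENCE"
  rows <- data.frame(suballele_id = id, contig = ctg, pos = vstart,
                     ref = toupper(refa), alt = toupper(alta),
                     stringsAsFactors = FALSE)[!is_ref_row, , drop = FALSE]
  gap <- rows$ref == "-" | rows$alt == "-"
  if (any(gap)) {
    if (is.null(ref_fasta))
      stop("gap-style indel rows present; supply ref_fasta to anchor them")
    rows[gap, ] <- anchor_gap_rows(rows[gap, , drop = FALSE], ref_fasta)
  }
  pm <- parse_suballele_id(unique(id))
  decl <- data.frame(suballele_id = unique(id),
                     major_id = as.character(pm$major_id),
                     legacy_name = "", contig = "", pos = "", ref = "", alt = "")
  have <- unique(rows$suballele_id)
  majors_of <- parse_suballele_id(rows$suballele_id)$major_id
  tab_native <- rbind(
    decl[!decl$suballele_id %in% have, , drop = FALSE],
    data.frame(suballele_id = rows$suballele_id,
               major_id = as.character(majors_of),
               legacy_name = "", contig = rows$contig,
               pos = rows$pos, ref = rows$ref, alt = rows$alt))
  annot <- jsonlite::read_json(annot_path)
  db <- build_allele_db(tab_native, annot, source = dir)

  haps <- Biostrings::readDNAStringSet(fa)
  names(haps) <- sub("\\s.*$", "", sub("^.*\\*", "", names(haps)))
  if (length(haps) != nrow(db$minors))
    stop("haplotype FASTA has ", length(haps), " sequences but ",
         nrow(db$minors), " minor alleles are defined")
  missing_seq <- setdiff(db$minors$suballele_id, names(haps))
  if (length(missing_seq))
    stop("no haplotype sequence for ", missing_seq[1L])
  list(db = db, haplotypes = haps)
}

# Re-anchor PharmVar gap-notation indels ("-" reference = insertion,
# "-" variant = deletion) to VCF minimal representation using the base
# preceding the event.
anchor_gap_rows <- function(rows, ref_fasta) {
  ref <- Biostrings::readDNAStringSet(ref_fasta)
  names(ref) <- normalize_contig(sub("\\s.*$", "", names(ref)))
  out <- rows
  for (i in seq_len(nrow(rows))) {
    ctg <- normalize_contig(rows$contig[i])
    if (!ctg %in% names(ref)) stop("contig missing from reference: ", ctg)
    pos <- as.integer(rows$pos[i])
    if (rows$ref[i] == "-") {        # insertion after pos
      anchor <- as.character(Biostrings::subseq(ref[[ctg]], pos, pos))
      out$pos[i] <- as.character(pos)
      out$ref[i] <- anchor
      out$alt[i] <- paste0(anchor, rows$alt[i])
    } else {                         # deletion starting at pos
      anchor <- as.character(Biostrings::subseq(ref[[ctg]], pos - 1L, pos - 1L))
      out$pos[i] <- as.character(pos - 1L)
      out$ref[i] <- paste0(anchor, rows$ref[i])
      out$alt[i] <- anchor
    }
    out$contig[i] <- ctg
  }
  out
}
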