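# Shared fixtures and independent oracles. Fixture suites are generated
# once per session and cached; everything is seeded and deterministic.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(n = 20L, seed = 11L) {
  key <- sprintf("fx_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture_suite(n, seed = seed)
  .fixture_cache[[key]]
}

fixture_caller_config <- function(fx, ...) {
  caller_config(control_region = fx$control_region, ...)
}

call_fixture_sample <- function(fx, sim, ...) {
  call_sample(sim$reads, fx$db, fx$regions, gene_region = fx$gene_region,
              cfg = fixture_caller_config(fx, ...))
}

# Write a minimal native-schema database to temp files and load it.
# `sets` is a named list: suballele id -> data.frame(contig,pos,ref,alt)
# (NULL for the reference allele). `majors` is a named list of
# list(function=, activity_value=, ...) entries keyed by major number.
write_toy_db <- function(sets, majors, dir = tempfile("toydb")) {
  dir.create(dir)
  rows <- lapply(names(sets), function(id) {
    major <- sub("\\..*$", "", id)
    v <- sets[[id]]
    if (is.null(v) || nrow(v) == 0L)
      data.frame(suballele_id = id, major_id = major, legacy_name = "",
                 contig = "", pos = "", ref = "", alt = "")
    else
      data.frame(suballele_id = id, major_id = major, legacy_name = "",
                 contig = v$contig, pos = as.character(v$pos), ref = v$ref,
                 alt = v$alt)
  })
  def <- file.path(dir, "defs.tsv")
  con <- file(def, "w")
  writeLines("#schema=starcall-defs-1", con)
  write.table(do.call(rbind, rows), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  annot <- file.path(dir, "annot.json")
  jsonlite::write_json(list(schema_version = "starcall-annot-1",
                            source = "test", majors = majors),
                       annot, auto_unbox = TRUE, digits = NA)
  list(def = def, annot = annot)
}

simple_major <- function(fun, act = NULL) {
  out <- list(`function` = fun)
  if (!is.null(act)) out$activity_value <- act
  out
}

# Independent exhaustive-enumeration oracle for diplotype resolution.
# Plain nested loops over canonical minors; mirrors the published
# decision rule (consistency on informative sites, minimum total
# variant count, ambiguity when distinct pairs remain tied).
oracle_resolve <- function(db, calls, cn_called = 2L) {
  minors <- db$minors[db$minors$canonical, , drop = FALSE]
  sites <- unique(db$variants[, c("contig", "pos", "ref", "alt")])
  skey <- paste(sites$contig, sites$pos, sites$ref, sites$alt)
  has <- function(id, s) {
    v <- db$variants[db$variants$suballele_id == id, , drop = FALSE]
    skey[s] %in% paste(v$contig, v$pos, v$ref, v$alt)
  }
  use <- which(!is.na(calls))
  pairs <- list()
  if (cn_called == 2L) {
    for (i in seq_len(nrow(minors))) for (j in i:nrow(minors)) {
      ok <- TRUE
      for (s in use) {
        d <- has(minors$suballele_id[i], s) + has(minors$suballele_id[j], s)
        if (d != calls[s]) { ok <- FALSE; break }
      }
      if (ok) pairs[[length(pairs) + 1L]] <- list(
        a = minors$suballele_id[i], b = minors$suballele_id[j],
        nvar = minors$n_variants[i] + minors$n_variants[j])
    }
  } else if (cn_called == 1L) {
    for (i in seq_len(nrow(minors))) {
      ok <- TRUE
      for (s in use) {
        d <- if (has(minors$suballele_id[i], s)) 2L else 0L
        if (d != calls[s]) { ok <- FALSE; break }
      }
      if (ok) pairs[[length(pairs) + 1L]] <- list(
        a = minors$suballele_id[i], b = "5", nvar = minors$n_variants[i])
    }
  }
  if (!length(pairs)) return(list(filter = "no_call_unmatched", pairs = list()))
  nv <- vapply(pairs, `[[`, 0, "nvar")
  pairs <- pairs[nv == min(nv)]
  list(filter = if (length(pairs) > 1L) "no_call_ambiguous" else "PASS",
       pairs = pairs)
}

allele_label_in <- function(aliases, id) any(grepl(id, aliases, fixed = TRUE))

# site-genotype data.frame for resolve_diplotype from a call-code
# vector (0 hom_ref, 1 het, 2 hom_alt, NA no-call) over db's sites.
site_gt_from_calls <- function(db, calls, low_depth = FALSE) {
  s <- unique(db$variants[, c("contig", "pos", "ref", "alt", "kind")])
  stopifnot(nrow(s) == length(calls))
  s$ref_count <- ifelse(is.na(calls), 0L, c(30L, 15L, 0L)[calls + 1L])
  s$alt_count <- ifelse(is.na(calls), 0L, c(0L, 15L, 30L)[calls + 1L])
  s$alt_fraction <- ifelse(is.na(calls), NA_real_, calls / 2)
  s$depth <- s$ref_count + s$alt_count
  s$call <- ifelse(is.na(calls), "no_call",
                   c("hom_ref", "het", "hom_alt")[calls + 1L])
  s$low_depth <- low_depth
  s
}
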