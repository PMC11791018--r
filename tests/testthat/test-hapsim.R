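# Toy single-contig reference for template tests.
toy_reference <- function(len = 10000L, seed = 3L, name = "22") {
  set.seed(seed)
  f <- tempfile(fileext = ".fasta")
  s <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), len,
                                             replace = TRUE), collapse = ""))
  names(s) <- name
  Biostrings::writeXStringSet(s, f)
  f
}

toy_regions <- function(contig = "22", start1 = 1L, end1 = 10000L) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start1, end1))
}

test_that("template extraction keeps reference bases outside a sentinel placeholder", {
  ref <- toy_reference(10000L)
  tpl <- build_template(ref, toy_regions(), "22:4001-6000")
  seq <- as.character(tpl$sequences[[1L]])
  expect_equal(nchar(seq), 10000L)
  expect_equal(substr(seq, 4001L, 6000L), strrep("N", 2000L))
  # round trip: non-placeholder bases equal the reference at the same
  # coordinates (direct coordinate-wise comparison)
  refseq <- as.character(Biostrings::readDNAStringSet(ref)[[1L]])
  expect_equal(substr(seq, 1L, 4000L), substr(refseq, 1L, 4000L))
  expect_equal(substr(seq, 6001L, 10000L), substr(refseq, 6001L, 10000L))
})

test_that("template construction rejects bad regions and placeholders", {
  ref <- toy_reference(10000L)
  expect_error(build_template(ref, toy_regions(end1 = 20000L), "22:4001-6000"),
               "beyond contig end")
  expect_error(build_template(ref, toy_regions("7"), "7:10-20"),
               "missing from reference")
  two <- GenomicRanges::GRanges("22", IRanges::IRanges(c(1L, 6001L),
                                                       c(5000L, 10000L)))
  expect_error(build_template(ref, two, "22:4000-7000"),
               "exactly one region")
})

test_that("haplotype insertion honors orientation, identity and length arithmetic", {
  ref <- toy_reference(10000L)
  tpl <- build_template(ref, toy_regions(), "22:4001-6000")
  refseq <- as.character(Biostrings::readDNAStringSet(ref)[[1L]])
  span <- substr(refseq, 4001L, 6000L)

  # identity: inserting the reference span restores the raw extraction
  hs <- insert_haplotype(tpl, span, "plus")
  expect_equal(unname(hs$sequences[[1L]]), refseq)
  expect_equal(hs$refpos[[1L]], 1:10000)

  # minus orientation reverse-complements before insertion
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(span)))
  hs2 <- insert_haplotype(tpl, rc, "minus")
  expect_equal(hs2$sequences[[1L]], hs$sequences[[1L]])

  # explicit small case
  tpl_small <- build_template(ref, toy_regions(), "22:4001-4005")
  hs3 <- insert_haplotype(tpl_small, "AACCT", "minus")
  expect_equal(substr(hs3$sequences[[1L]], 4001L, 4005L), "AGGTT")

  # length arithmetic over random insert lengths
  set.seed(42)
  for (L in sample(50:4000, 5L)) {
    hap <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    suppressWarnings(h <- insert_haplotype(tpl, hap))
    expect_equal(nchar(h$sequences[[1L]]), 10000L - 2000L + L)
  }

  # sentinel must still be present
  tpl2 <- tpl
  tpl2$sequences[[1L]] <- Biostrings::DNAString(refseq)  # placeholder overwritten
  expect_error(insert_haplotype(tpl2, span), "sentinel absent")
  expect_error(insert_haplotype(tpl, "ACGU"), "alphabet")
})

test_that("build_haplotype applies variants with a faithful coordinate map", {
  ref <- toy_reference(10000L)
  refseq <- as.character(Biostrings::readDNAStringSet(ref)[[1L]])
  base <- function(p) substr(refseq, p, p)
  v <- data.frame(
    contig = "22",
    pos = c(4100L, 4200L, 4300L),
    ref = c(base(4100L), base(4200L),
            substr(refseq, 4300L, 4303L)),
    alt = c(setdiff(c("A", "C", "G", "T"), base(4100L))[1L],
            paste0(base(4200L), "TTT"),       # insertion of TTT
            base(4300L)),                      # deletion of 3 bases
    stringsAsFactors = FALSE)
  h <- build_haplotype(ref, "22:4001-6000", v)
  expect_equal(nchar(h$seq), 2000L + 3L - 3L)
  # SNV applied in place
  expect_equal(substr(h$seq, 100L, 100L), v$alt[1L])
  expect_equal(h$refpos[100L], 4100L)
  # inserted bases carry NA coordinates
  ins_at <- which(is.na(h$refpos))
  expect_equal(length(ins_at), 3L)
  expect_equal(h$refpos[min(ins_at) - 1L], 4200L)
  # deletion removes coordinates 4301-4303 from the map
  expect_false(any(h$refpos %in% 4301:4303))
  # reference-mismatch detection
  v_bad <- data.frame(contig = "22", pos = 4100L,
                      ref = setdiff(c("A", "C", "G", "T"), base(4100L))[1L],
                      alt = base(4100L))
  expect_error(build_haplotype(ref, "22:4001-6000", v_bad),
               "reference mismatch")
})

test_that("simulated reads are exact substrings of the variant genome when error-free", {
  fx <- get_fixture(20)
  # pick an SNV-only allele
  db <- fx$db
  snv_only <- vapply(db$minors$suballele_id, function(id)
    nrow(variants_of(db, id)) > 0L && all(variants_of(db, id)$kind == "SNV"),
    TRUE)
  id <- db$minors$suballele_id[snv_only][1L]
  sim <- simulate_diplotype(fx, id, config = sim_config(
    depth = 15, error_rate = 0, seed = 21L))
  # independent expected genome: reference with SNVs substituted in
  ref <- Biostrings::readDNAStringSet(fx$paths$reference)
  genomes <- lapply(as.character(ref), identity)
  v <- variants_of(db, id)
  for (i in seq_len(nrow(v)))
    substr(genomes[[v$contig[i]]], v$pos[i], v$pos[i]) <- v$alt[i]
  r <- sim$reads[sim$reads$contig != "*", ]
  expect_true(all(grepl("^[0-9]+M$", r$cigar)))
  got <- substring(genomes[r$contig], r$pos, r$pos + nchar(r$seq) - 1L)
  expect_equal(got, r$seq)
})

test_that("simulation is seed-deterministic and respects depth accounting", {
  fx <- get_fixture(20)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_diplotype(fx, "1.001", config = sim_config(depth = 20, seed = 8L),
                     out_dir = d1)
  simulate_diplotype(fx, "1.001", config = sim_config(depth = 20, seed = 8L),
                     out_dir = d2)
  for (f in c("reads_R1.fastq", "reads_R2.fastq", "truth.tsv", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)

  # depth 0 -> no reads
  sim0 <- simulate_diplotype(fx, "1.001", config = sim_config(depth = 0, seed = 1L))
  expect_equal(nrow(sim0$reads), 0L)

  # coverage conservation: simulated bases / haploid length within 3%
  sim <- simulate_diplotype(fx, "1.001", config = sim_config(depth = 40, seed = 8L))
  total_len <- sum(sim$manifest$instances$length) / 2  # haploid
  bases <- sum(nchar(sim$reads$seq))
  expect_lt(abs(bases / total_len - 40) / 40, 0.03)

  # expected read-pair count
  expect_equal(sim$manifest$n_pairs, round(40 * total_len / (2 * 150)),
               tolerance = 0.01)
})

test_that("fragments longer than short sequences are rejected as degenerate", {
  ref <- toy_reference(300L)
  tpl <- build_template(ref, toy_regions(end1 = 300L), "22:100-200")
  hs <- insert_haplotype(tpl, strrep("A", 101L))
  expect_error(simulate_reads(list(hs), sim_config(depth = 10, seed = 1L)),
               "degenerate")
})

test_that("fixture generation is deterministic and carries its promised structure", {
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- make_fixture_suite(8L, seed = 99L, dir = d1)
  f2 <- make_fixture_suite(8L, seed = 99L, dir = d2)
  for (f in c("reference.fasta", "regions.bed", "alleles.tsv",
              "annotations.json", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  expect_equal(nrow(f1$db$minors), 8L)
  expect_equal(sum(!f1$db$minors$canonical), 1L)      # exactly one alias pair
  expect_equal(sum(f1$db$minors$n_variants == 0L), 1L)
  expect_error(make_fixture_suite(1000L, seed = 1L), "capacity")
})
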