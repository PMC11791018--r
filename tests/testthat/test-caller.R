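test_that("site classification applies the imbalance-tolerant threshold rule", {
  cfg <- caller_config()
  # hand-applied threshold oracle at delta = 0.15, het band 0.35-0.65
  expect_equal(site_call(0L, 30L, cfg), "hom_alt")    # af 1.00
  expect_equal(site_call(6L, 44L, cfg), "hom_alt")    # af 0.88
  expect_equal(site_call(45L, 55L, cfg), "het")       # af 0.55
  expect_equal(site_call(28L, 72L, cfg), "no_call")   # af 0.72, ambiguous
  expect_equal(site_call(90L, 10L, cfg), "hom_ref")   # af 0.10
  expect_equal(site_call(5L, 4L, cfg), "no_call")     # depth 9 < 10
  expect_equal(site_call(0L, 0L, cfg), "no_call")
  # band boundaries follow the configuration, not constants
  loose <- caller_config(delta = 0.25, het_width = 0.2)
  expect_equal(site_call(24L, 76L, loose), "hom_alt")
})

test_that("an all-reference sample genotypes hom_ref at every definition site", {
  fx <- get_fixture(20)
  sim <- simulate_diplotype(fx, "1.001", config = sim_config(
    depth = 40, error_rate = 0, seed = 31L))
  pl <- build_pileup(sim$reads, fx$regions)
  gt <- genotype_sites(pl, fx$db$variants, fixture_caller_config(fx))
  expect_true(all(gt$call == "hom_ref"))
})

test_that("homozygous and heterozygous variant sites are genotyped from pileups, indels included", {
  fx <- get_fixture(20)
  cfg <- fixture_caller_config(fx)
  # indel-bearing alleles in the fixture: majors 3 (ins) and 4 (del)
  hom <- simulate_diplotype(fx, "3.001", config = sim_config(
    depth = 40, error_rate = 0.001, seed = 37L))
  gt <- genotype_sites(build_pileup(hom$reads, fx$regions),
                       fx$db$variants, cfg)
  own <- variants_of(fx$db, "3.001")
  key <- paste(gt$contig, gt$pos, gt$ref, gt$alt)
  own_key <- paste(own$contig, own$pos, own$ref, own$alt)
  expect_true(all(gt$call[key %in% own_key] == "hom_alt"))
  expect_true(all(gt$call[!key %in% own_key] == "hom_ref"))

  het <- simulate_diplotype(fx, "4.001", "7.001", config = sim_config(
    depth = 40, error_rate = 0.001, seed = 37L))
  gt2 <- genotype_sites(build_pileup(het$reads, fx$regions),
                        fx$db$variants, cfg)
  both <- rbind(variants_of(fx$db, "4.001"), variants_of(fx$db, "7.001"))
  bkey <- paste(both$contig, both$pos, both$ref, both$alt)
  k2 <- paste(gt2$contig, gt2$pos, gt2$ref, gt2$alt)
  expect_true(all(gt2$call[k2 %in% bkey] == "het"))
  expect_true(all(gt2$call[!k2 %in% bkey] == "hom_ref"))
})

test_that("copy number is the rounded doubled depth ratio with a confidence margin", {
  mk_pileup <- function(gene_depth, ctrl_depth) {
    regions <- GenomicRanges::GRanges(c("22", "12"),
                                      IRanges::IRanges(c(1L, 1L),
                                                       c(1000L, 1000L)))
    counts <- list(
      matrix(c(gene_depth, 0L, 0L, 0L, 0L), nrow = 5L, ncol = 1000L,
             dimnames = list(c("A", "C", "G", "T", "del"), NULL)),
      matrix(c(ctrl_depth, 0L, 0L, 0L, 0L), nrow = 5L, ncol = 1000L,
             dimnames = list(c("A", "C", "G", "T", "del"), NULL)))
    structure(list(regions = regions, counts = counts,
                   insertions = data.frame()), class = "pileup")
  }
  cfg <- caller_config(cn_trim = 0L)
  cn <- estimate_copy_number(mk_pileup(30L, 30L), "22:1-1000", "12:1-1000", cfg)
  expect_equal(cn$cn_called, 2L)
  expect_equal(cn$cn_raw, 2)
  expect_equal(cn$confidence, 0)
  expect_false(cn$low_confidence)
  cn3 <- estimate_copy_number(mk_pileup(45L, 30L), "22:1-1000", "12:1-1000", cfg)
  expect_equal(cn3$cn_called, 3L)
  cn1 <- estimate_copy_number(mk_pileup(16L, 30L), "22:1-1000", "12:1-1000", cfg)
  expect_equal(cn1$cn_called, 1L)
  expect_true(estimate_copy_number(mk_pileup(1L, 30L), "22:1-1000",
                                   "12:1-1000", cfg)$deletion)
  expect_error(estimate_copy_number(mk_pileup(30L, 0L), "22:1-1000",
                                    "12:1-1000", cfg), "zero depth")
})

test_that("simulated copy-number states are recovered at depth 40", {
  fx <- get_fixture(20)
  cfg <- fixture_caller_config(fx)
  for (case in list(list(mode = "hemi", cn = 1L), list(mode = "diploid", cn = 2L),
                    list(mode = "dup", cn = 3L))) {
    sim <- simulate_diplotype(fx, "2.001", config = sim_config(
      depth = 40, seed = 41L), cn = case$mode)
    pl <- build_pileup(sim$reads, fx$regions)
    cn <- estimate_copy_number(pl, fx$gene_region, fx$control_region, cfg)
    expect_equal(cn$cn_called, case$cn, info = case$mode)
  }
  sim0 <- simulate_diplotype(fx, "2.001", config = sim_config(
    depth = 40, seed = 41L), cn = "del_hom")
  pl0 <- build_pileup(sim0$reads, fx$regions)
  cn0 <- estimate_copy_number(pl0, fx$gene_region, fx$control_region, cfg)
  expect_true(cn0$deletion)
  expect_lt(cn0$gene_mean_depth, 0.05 * cn0$control_mean_depth)
})

test_that("diplotype resolution matches the exhaustive-enumeration oracle on crafted cases", {
  db <- get_fixture(20)$db
  sites <- unique(db$variants[, c("contig", "pos", "ref", "alt", "kind")])
  skey <- paste(sites$contig, sites$pos, sites$ref, sites$alt)
  calls_for <- function(ids, dosage = NULL) {
    calls <- rep(0L, nrow(sites))
    tab <- table(unlist(lapply(ids, function(id) {
      v <- variants_of(db, id)
      match(paste(v$contig, v$pos, v$ref, v$alt), skey)
    })))
    calls[as.integer(names(tab))] <- as.integer(tab)
    calls
  }

  # homozygous no-function analog: all its sites hom_alt -> itself, not *1/*1
  calls <- calls_for(c("2.001", "2.001"))
  res <- resolve_diplotype(site_gt_from_calls(db, calls), NULL, db)
  expect_equal(res$filter, "PASS")
  expect_equal(c(res$hap_a_id, res$hap_b_id), c("2.001", "2.001"))

  # no variants observed -> reference/reference
  res0 <- resolve_diplotype(site_gt_from_calls(db, rep(0L, nrow(sites))),
                            NULL, db)
  expect_equal(c(res0$hap_a_id, res0$hap_b_id), c("1.001", "1.001"))

  # het union of two disjoint alleles -> that pair, matching the oracle
  calls2 <- calls_for(c("4.001", "7.001"))
  res2 <- resolve_diplotype(site_gt_from_calls(db, calls2), NULL, db)
  orc <- oracle_resolve(db, calls2)
  expect_equal(orc$filter, "PASS")
  expect_equal(sort(c(res2$hap_a_id, res2$hap_b_id)),
               sort(c(orc$pairs[[1L]]$a, orc$pairs[[1L]]$b)))

  # the alias pair resolves to its canonical representative
  fx <- get_fixture(20)
  calls3 <- calls_for(rep(fx$alias_pair[2L], 2L))
  res3 <- resolve_diplotype(site_gt_from_calls(db, calls3), NULL, db)
  expect_equal(res3$hap_a_id, fx$alias_pair[1L])
  expect_true(allele_label_in(res3$aliases$hap_a, fx$alias_pair[2L]))
})

test_that("resolution agrees with the oracle on random site-genotype vectors", {
  db <- get_fixture(10, seed = 23L)$db
  sites <- unique(db$variants[, c("contig", "pos", "ref", "alt", "kind")])
  set.seed(71)
  for (rep in 1:60) {
    calls <- sample(c(0L, 1L, 2L, NA_integer_), nrow(sites), replace = TRUE,
                    prob = c(0.6, 0.15, 0.15, 0.1))
    res <- resolve_diplotype(site_gt_from_calls(db, calls), NULL, db)
    orc <- oracle_resolve(db, calls)
    expect_equal(res$filter, orc$filter, info = paste(calls, collapse = ","))
    if (orc$filter == "PASS")
      expect_equal(sort(c(res$hap_a_id, res$hap_b_id)),
                   sort(c(orc$pairs[[1L]]$a, orc$pairs[[1L]]$b)))
  }
})

test_that("tied minimal-variant pairs are filtered as ambiguous", {
  files <- write_toy_db(
    sets = list("1.001" = NULL,
                "2.001" = data.frame(contig = "22", pos = 100L, ref = "A",
                                     alt = "T"),
                "3.001" = data.frame(contig = "22", pos = 200L, ref = "C",
                                     alt = "G"),
                "4.001" = data.frame(contig = "22", pos = c(100L, 200L),
                                     ref = c("A", "C"), alt = c("T", "G"))),
    majors = list(`1` = simple_major("normal", 1),
                  `2` = simple_major("decreased", 0.5),
                  `3` = simple_major("no", 0),
                  `4` = simple_major("normal", 1)))
  db <- load_allele_db(files$def, files$annot)
  # both sites het: *2/*3 and *1/*4 are both consistent with 2 variants total
  res <- resolve_diplotype(site_gt_from_calls(db, c(1L, 1L)), NULL, db)
  expect_equal(res$filter, "no_call_ambiguous")
  expect_equal(length(res$candidates), 2L)
  orc <- oracle_resolve(db, c(1L, 1L))
  expect_equal(orc$filter, "no_call_ambiguous")
  # an inconsistent pattern is unmatched: het at one site, hom_alt at a
  # site no allele pair can reach alone
  res2 <- resolve_diplotype(site_gt_from_calls(db, c(2L, 1L)), NULL, db)
  expect_equal(res2$filter, oracle_resolve(db, c(2L, 1L))$filter)
})

test_that("copy-number-one samples resolve against the deletion allele *5", {
  db <- get_fixture(20)$db
  sites <- unique(db$variants[, c("contig", "pos", "ref", "alt", "kind")])
  skey <- paste(sites$contig, sites$pos, sites$ref, sites$alt)
  v <- variants_of(db, "6.001")
  calls <- rep(0L, nrow(sites))
  calls[match(paste(v$contig, v$pos, v$ref, v$alt), skey)] <- 2L
  cn1 <- structure(list(cn_called = 1L, cn_raw = 1.02, deletion = FALSE),
                   class = "cn_estimate")
  res <- resolve_diplotype(site_gt_from_calls(db, calls), cn1, db)
  expect_equal(res$filter, "PASS")
  expect_setequal(c(res$hap_a_id, res$hap_b_id), c("5", "6.001"))
  orc <- oracle_resolve(db, calls, cn_called = 1L)
  expect_equal(orc$filter, "PASS")
  expect_equal(orc$pairs[[1L]]$a, "6.001")
})

test_that("end-to-end calls recover simulated truths and are order-invariant", {
  fx <- get_fixture(20)
  # homozygous indel allele
  sim <- simulate_diplotype(fx, "4.001", config = sim_config(depth = 40,
                                                             seed = 43L))
  call <- call_fixture_sample(fx, sim)
  expect_equal(call$filter, "PASS")
  expect_equal(c(call$hap_a_id, call$hap_b_id), c("4.001", "4.001"))
  # unordered: hap labels are sorted, so swapping truth order cannot matter
  sim2 <- simulate_diplotype(fx, "7.001", "4.001",
                             config = sim_config(depth = 40, seed = 43L))
  call2 <- call_fixture_sample(fx, sim2)
  expect_equal(c(call2$hap_a_id, call2$hap_b_id), c("4.001", "7.001"))
  cmp_ab <- compare_diplotypes(c("4.001", "7.001"), call2, fx$db)
  cmp_ba <- compare_diplotypes(c("7.001", "4.001"), call2, fx$db)
  expect_equal(cmp_ab$correct_minor, cmp_ba$correct_minor)
  expect_true(cmp_ab$correct_minor)
})

test_that("deeper resequencing of a correct call never degrades it to a depth no-call", {
  fx <- get_fixture(20)
  for (id in c("2.001", "9.001")) {
    call30 <- call_fixture_sample(fx, simulate_diplotype(
      fx, id, config = sim_config(depth = 30, seed = 47L)))
    expect_equal(call30$filter, "PASS")
    expect_equal(call30$hap_a_id, id)
    call60 <- call_fixture_sample(fx, simulate_diplotype(
      fx, id, config = sim_config(depth = 60, seed = 47L)))
    expect_equal(call60$filter, "PASS")
    expect_equal(call60$hap_a_id, id)
  }
})

test_that("shallow sequencing is filtered as a depth no-call", {
  fx <- get_fixture(20)
  call <- call_fixture_sample(fx, simulate_diplotype(
    fx, "2.001", config = sim_config(depth = 5, seed = 53L)))
  expect_equal(call$filter, "no_call_depth")
  expect_true(is.na(call$hap_a))
})
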