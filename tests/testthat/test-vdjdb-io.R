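test_that("frequency strings of all dialects parse to percent", {
  out <- parse_frequency(c("12/100", "3/400", "12.5%", "0.25", "2.5", NA, ""))
  expect_equal(out$frequency_pct,
               c(12, 0.75, 12.5, 25, 2.5, NA, NA))
  expect_equal(out$frequency_denominator,
               c("100", "400", NA, NA, NA, NA, NA))
})

test_that("MHC alleles normalize to locus plus 2-digit group", {
  expect_equal(as.character(normalize_mhc_group("HLA-A*02:01")), "HLA-A*02")
  expect_equal(as.character(normalize_mhc_group("HLA-B*08")), "HLA-B*08")
  expect_warning(g <- normalize_mhc_group("B2M"), "unparseable")
  expect_equal(as.character(g), "B2M")
  expect_true(attr(g, "unparseable"))
})

test_that("gene calls lose their allele suffix only", {
  expect_equal(normalize_gene_subgroup(c("TRBV19*01", "TRAJ42", "TRBV20-1*01")),
               c("TRBV19", "TRAJ42", "TRBV20-1"))
})

test_that("subject keys join five tokens with * and render missing as *", {
  expect_equal(build_subject_key("S1", "r1", "GILGFVFTL", "PMID:1", "100"),
               "S1*r1*GILGFVFTL*PMID:1*100")
  expect_equal(build_subject_key(NA, "r1", "GILGFVFTL", "PMID:1", "100"),
               "**r1*GILGFVFTL*PMID:1*100")
  k1 <- build_subject_key("S1", "r1", "E", "R", "100")
  k2 <- build_subject_key("S1", "r1", "E", "R", "100")
  expect_identical(k1, k2)
  expect_error(build_subject_key("S1", "r1", NA, "R", "100"), "epitope")
})

test_that("parsing tolerates malformed JSON and flags missing columns", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  meta <- rep('{"subject.id": "S1", "cell.subset": "CD8+"}', 5)
  meta[3] <- '{"subject.id": "S1", broken'
  write_fixture_tsv(tf, cdr3 = paste0("CASS", LETTERS[1:5], "EQYF"),
                    meta = meta)
  expect_warning(rec <- parse_vdjdb(tf), "malformed JSON")
  expect_equal(nrow(rec), 5)
  expect_true(is.na(rec$subject_id[3]))
  expect_false(anyNA(rec$subject_id[-3]))
  # subject key still built, missing parts rendered as *
  expect_match(rec$subject_key[3], "^\\*\\*\\*")

  # empty file with header only
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_tsv(tf2, cdr3 = character(0))
  expect_equal(nrow(parse_vdjdb(tf2)), 0)

  # missing mandatory column is a hard error naming the column
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = "TRB", cdr3 = "CASSF"), tf3)
  expect_error(parse_vdjdb(tf3), "antigen.epitope")
})

test_that("inclusion filters drop naive, frequency-less and CD4 records", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  meta <- c(rep('{"subject.id": "S1", "cell.subset": "CD8+"}', 6),
            rep('{"subject.id": "S1", "cell.subset": "Naive, CD45RA+CCR7+"}', 2),
            '{"subject.id": "S1", "cell.subset": "CD8+"}',
            '{"subject.id": "S1", "cell.subset": "CD4+"}')
  method <- rep('{"frequency": "10/100"}', 10)
  method[9] <- '{"identification": "sort"}'
  write_fixture_tsv(tf, cdr3 = paste0("CASS", LETTERS[1:10], "EQYF"),
                    meta = meta, method = method)
  rec <- parse_vdjdb(tf)
  flt <- filter_records(rec)
  expect_equal(nrow(flt$records), 6)
  expect_equal(flt$tally$n[flt$tally$reason == "naive"], 2)
  expect_equal(flt$tally$n[flt$tally$reason == "no_freq"], 1)
  expect_equal(flt$tally$n[flt$tally$reason == "not_cd8"], 1)
  # kept + rejected = input
  expect_equal(nrow(flt$records) + sum(flt$tally$n), nrow(rec))
  # idempotent
  again <- filter_records(flt$records)
  expect_identical(again$records, flt$records)
  expect_equal(sum(again$tally$n), 0)
  # order preserved
  expect_identical(flt$records$cdr3_aa,
                   rec$cdr3_aa[rec$cdr3_aa %in% flt$records$cdr3_aa])
})

test_that("all-naive input filters to nothing", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_tsv(tf, cdr3 = c("CASSAEQYF", "CASSWEQYF"),
                    meta = rep('{"cell.subset": "CD45RA+CCR7+ naive"}', 2))
  flt <- filter_records(parse_vdjdb(tf))
  expect_equal(nrow(flt$records), 0)
  expect_equal(flt$tally$n[flt$tally$reason == "naive"], 2)
})

test_that("parse -> write -> parse preserves record fields", {
  cfg <- synthetic_config(n_subjects = 6, clones_per_subject = 5, seed = 11)
  gen <- generate_repertoire(cfg)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_tsv(gen$table, tf)
  rec1 <- parse_vdjdb(tf)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_vdjdb(rec1, tf2)
  rec2 <- parse_vdjdb(tf2)
  for (col in c("chain", "cdr3_aa", "v_subgroup", "j_subgroup",
                "mhc_allele_group", "mhc_class", "epitope", "subject_id",
                "replica_id", "phenotype", "complex_id", "reference")) {
    expect_identical(rec2[[col]], rec1[[col]])
  }
  expect_equal(rec2$frequency_pct, rec1$frequency_pct, tolerance = 1e-9)
})

test_that("paired chains match on nonzero complex.id within epitope", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(
    "complex.id" = c(5L, 5L, 7L, 7L, 0L, 9L),
    gene = c("TRA", "TRB", "TRA", "TRB", "TRB", "TRA"),
    cdr3 = c("CAVNGSQGNLIF", "CASSLEQYF", "CAASYGQNFVF", "CASSWEQYF",
             "CASSPEQYF", "CAVNYGQNFVF"),
    "v.segm" = "TRAV12-2*01", "j.segm" = "TRAJ42*01",
    species = "HomoSapiens", "mhc.a" = "HLA-A*02:01", "mhc.class" = "MHCI",
    "antigen.epitope" = "GILGFVFTL", "antigen.species" = "InfluenzaA",
    "reference.id" = "PMID:1",
    meta = '{"subject.id": "S1", "cell.subset": "CD8+"}',
    method = '{"frequency": "1/100"}')
  write_clonotype_tsv(tab, tf)
  rec <- parse_vdjdb(tf)
  pairs <- match_paired_chains(rec)
  expect_equal(nrow(pairs), 2)       # complex 5 and 7; 0-sentinel and orphan 9 excluded
  expect_setequal(pairs$complex_id, c(5L, 7L))
  expect_equal(pairs$alpha_cdr3[pairs$complex_id == 5], "CAVNGSQGNLIF")
  expect_equal(pairs$beta_cdr3[pairs$complex_id == 5], "CASSLEQYF")

  # a duplicated chain under one complex.id skips the pair with a warning
  rec_dup <- dplyr::bind_rows(rec, rec[1, ])
  expect_warning(p2 <- match_paired_chains(rec_dup), "multiple records")
  expect_equal(nrow(p2), 1)
})
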