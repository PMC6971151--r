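test_that("V/J trimming follows the longest-match rule", {
  g <- toy_germline()
  r <- extract_nonvj_aa("CASSLGGEQYF", "TRBVX", "TRBJX", g)
  expect_equal(r$v_part, "CASS")
  expect_equal(r$nonvj_part, "LGG")
  expect_equal(r$j_part, "EQYF")

  # zero-insert case
  r2 <- extract_nonvj_aa("CASSEQYF", "TRBVX", "TRBJX", g)
  expect_equal(r2$nonvj_part, "")
  expect_equal(paste0(r2$v_part, r2$nonvj_part, r2$j_part), "CASSEQYF")

  # overlapping matches: V wins, J shortened
  expect_message(
    r3 <- extract_nonvj_aa("CASSEQYF", "TRBVY", "TRBJX", g),
    "overlap")
  expect_equal(r3$v_part, "CASSE")
  expect_equal(r3$j_part, "QYF")
  expect_equal(r3$nonvj_part, "")

  # unknown gene: skipped with a warning, not an error
  expect_warning(r4 <- extract_nonvj_aa("CASSLGGEQYF", "NOPE", "TRBJX", g),
                 "skipped")
  expect_true(r4$skipped)
  expect_error(extract_nonvj_aa("", "TRBVX", "TRBJX", g), "empty")
})

test_that("region concatenation reconstructs every synthetic CDR3", {
  cfg <- synthetic_config(n_subjects = 10, clones_per_subject = 10, seed = 5)
  gen <- generate_repertoire(cfg)
  r <- extract_nonvj_aa(gen$truth$cdr3_aa, gen$truth$v_gene,
                        gen$truth$j_gene, cfg$germline)
  expect_identical(paste0(r$v_part, r$nonvj_part, r$j_part),
                   gen$truth$cdr3_aa)
  # generated inserts are recovered exactly
  expect_identical(r$nonvj_part, gen$truth$insert)
})

test_that("nucleotide trimming recovers inserts and translates in-frame ones", {
  g <- toy_germline()
  # zero insert: CDR3 nt equals concatenated germline segments
  nt0 <- paste0("tgtgctagcagc", "gagcagtatttt")
  r0 <- extract_nonvj_nt(nt0, "TRBVX", "TRBJX", g)
  expect_equal(r0$nonvj_nt, "")
  expect_equal(r0$nonvj_aa, "")

  # known in-frame insert translates (V segment is 12 nt: codon boundary)
  nt1 <- paste0("tgtgctagcagc", "ggtggc", "gagcagtatttt")
  r1 <- extract_nonvj_nt(nt1, "TRBVX", "TRBJX", g)
  expect_equal(r1$nonvj_nt, "ggtggc")
  expect_equal(r1$nonvj_aa, "GG")
  # guanine composition of the insert: 4 of 6
  expect_equal(sum(strsplit(r1$nonvj_nt, "")[[1]] == "g") /
                 nchar(r1$nonvj_nt), 2 / 3, tolerance = 1e-12)

  # out-of-frame insert: translation omitted
  nt2 <- paste0("tgtgctagcagc", "ggtgg", "gagcagtatttt")
  r2 <- extract_nonvj_nt(nt2, "TRBVX", "TRBJX", g)
  expect_true(is.na(r2$nonvj_aa))
})

test_that("generated naive nucleotide inserts are recovered exactly", {
  cfg <- synthetic_config(naive_pool_size = 200, seed = 9)
  np <- generate_naive_pool(cfg)
  r <- extract_nonvj_nt(np$table$cdr3_nt, np$table$v_gene, np$table$j_gene,
                        cfg$germline)
  expect_equal(mean(r$nonvj_nt == np$truth$insert_nt), 1)
  expect_true(all(np$table$count >= 1))
  expect_true(is.integer(np$table$count))
})

test_that("feature panel matches hand-computed values", {
  f <- compute_features(c("FWYH", "AI", "GG", "AVIL", "KRH", "DE"))
  expect_equal(f$frac_aromatic[1], 1.0)
  expect_equal(f$hydropathy[2], 3.15)                       # mean of 1.8, 4.5
  kid_g <- aa_scales()$kidera["G", ]
  expect_equal(unlist(f[3, paste0("kidera_", 1:10)]),
               setNames(kid_g, paste0("kidera_", 1:10)))
  expect_equal(f$aliphatic_index[4],
               100 * (0.25 + 2.9 * 0.25 + 3.9 * 0.5))
  expect_equal(f$net_charge[5], 2.1)                        # K + R + 0.1 H
  expect_equal(f$net_charge[6], -2)
  expect_equal(f$frac_acidic[6], 1)
  expect_error(compute_features("CASZ"), "position 4")
})

test_that("feature vectors equal a brute-force loop over the scale tables", {
  set.seed(41)
  peps <- random_peptides(300)
  f <- compute_features(peps)
  sc <- aa_scales()
  for (i in seq_along(peps)) {
    cc <- strsplit(peps[i], "")[[1]]
    expect_equal(f$hydropathy[i], mean(sc$hydropathy[cc]), tolerance = 1e-9)
    expect_equal(f$polarity[i], mean(sc$polarity[cc]), tolerance = 1e-9)
    expect_equal(f$bulkiness[i], mean(sc$bulkiness[cc]), tolerance = 1e-9)
    expect_equal(f$boman[i], -mean(sc$boman_energy[cc]), tolerance = 1e-9)
    expect_equal(unname(unlist(f[i, paste0("kidera_", 1:10)])),
                 unname(colMeans(sc$kidera[cc, , drop = FALSE])),
                 tolerance = 1e-9)
    expect_equal(f$frac_basic[i], mean(cc %in% c("H", "K", "R")),
                 tolerance = 1e-12)
  }
  expect_true(all(f$frac_acidic >= 0 & f$frac_acidic <= 1))
  expect_true(all(f$frac_acidic + f$frac_basic <= 1 + 1e-12))
})

test_that("hydropathy classes partition the 20 residues", {
  cls <- hydropathy_classes()
  expect_length(unlist(cls), 20)
  expect_length(unique(unlist(cls)), 20)
  expect_equal(classify_hydropathy("G"), "neutral")
  expect_equal(classify_hydropathy("E"), "hydrophilic")
  expect_equal(classify_hydropathy("L"), "hydrophobic")
  all20 <- classify_hydropathy(unlist(cls))
  expect_equal(unname(table(all20)[c("hydrophobic", "neutral", "hydrophilic")]),
               c(8L, 6L, 6L), ignore_attr = TRUE)
  expect_error(classify_hydropathy("Z"), "non-standard")
})

test_that("pooled composition is a normalized frequency vector", {
  comp <- aa_composition(c("GG", "GS"))
  expect_equal(unname(comp["G"]), 0.75)
  expect_equal(unname(comp["S"]), 0.25)
  expect_equal(sum(comp), 1, tolerance = 1e-12)
  expect_equal(unname(aa_composition("W")["W"]), 1.0)
  expect_error(aa_composition(c("", NA)), "empty")

  set.seed(7)
  comp2 <- aa_composition(random_peptides(500))
  expect_equal(sum(comp2), 1, tolerance = 1e-12)
})

test_that("synthetic inserts hit the configured glycine enrichment", {
  cfg <- synthetic_config(n_subjects = 60, clones_per_subject = 20, seed = 13)
  gen <- generate_repertoire(cfg)
  ins <- gen$truth$insert[nzchar(gen$truth$insert)]
  comp <- aa_composition(ins)
  expect_gt(sum(nchar(ins)), 3000)
  expect_equal(unname(comp["G"]), 0.25, tolerance = 0.02)
})

test_that("composition log ratios follow the shared capping convention", {
  a <- c(G = 0.25, S = 0.5, W = 0.25)
  b <- c(G = 0.25, S = 0.25, L = 0.5)
  lr <- composition_log_ratio(a, b)
  expect_equal(unname(lr["G"]), 0)
  expect_equal(unname(lr["S"]), 1)       # log2(0.5/0.25)
  expect_equal(unname(lr["W"]), 5)       # present only in a
  expect_equal(unname(lr["L"]), -5)      # present only in b
  expect_false("A" %in% names(lr))       # absent from both: omitted
})

test_that("bundled scale tables keep their pinned fingerprints", {
  sc <- aa_scales()
  expect_equal(sum(sc$hydropathy), -9.8, tolerance = 1e-9)
  expect_equal(sum(sc$polarity), 166.5, tolerance = 1e-9)
  expect_equal(sum(sc$bulkiness), 307.35, tolerance = 1e-9)
  expect_equal(sum(sc$boman_energy), 33.1, tolerance = 1e-9)
  expect_equal(sum(sc$kidera), -0.09, tolerance = 1e-9)
  expect_equal(dim(sc$kidera), c(20L, 10L))
})
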