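test_that("two-sample comparisons report the named test faithfully", {
  x <- c(10, 11, 12, 13, 14, 15)
  r <- compare_lengths(x, x, test = "ks")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$n_a, 6)
  expect_equal(r$n_b, 6)

  r2 <- compare_lengths(1:100, 51:150, test = "mw")
  expect_lt(r2$p_value, 0.001)
  expect_true(r2$significant)

  r3 <- compare_lengths(rnorm(10), rnorm(12), test = "ks")
  expect_equal(c(r3$n_a, r3$n_b), c(10L, 12L))
  expect_error(compare_lengths(1, 1:5), "at least 2")
})

test_that("comparisons are invariant under within-sample permutation", {
  set.seed(19)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  for (tst in c("ks", "mw")) {
    r1 <- compare_lengths(a, b, test = tst)
    r2 <- compare_lengths(sample(a), sample(b), test = tst)
    expect_equal(r1$statistic, r2$statistic)
    expect_equal(r1$p_value, r2$p_value)
  }
  ad1 <- ad_ksample(list(a, b))
  ad2 <- ad_ksample(list(sample(a), sample(b)))
  expect_equal(ad1$statistic, ad2$statistic)
})

test_that("normality check flags clearly non-normal data and degenerate input", {
  set.seed(23)
  u <- runif(500)
  r <- normality_check(u)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$statistic, 0)
  expect_lte(r$statistic, 1)
  expect_error(normality_check(rep(5, 5)), "degenerate")
  expect_error(normality_check(c(1, 2)), "3 <= n")
})

test_that("epitope-length correlation handles monotone, degenerate and excluded input", {
  dec <- tibble::tibble(epitope_length = 8:12, cdr3_length = c(15, 14, 13, 12, 11))
  r <- epitope_length_correlation(dec)
  expect_equal(r$rho, -1)

  const <- tibble::tibble(epitope_length = rep(9, 5), cdr3_length = 11:15)
  expect_error(epitope_length_correlation(const), "degenerate")

  withA2 <- tibble::tibble(
    epitope_length = c(9, 9, 9, 8, 10, 11),
    cdr3_length = c(12, 13, 14, 15, 13, 12),
    mhc_allele_group = c("HLA-A*02", "HLA-A*02", "HLA-A*02",
                         "HLA-B*08", "HLA-B*07", "HLA-B*57"))
  r2 <- epitope_length_correlation(withA2, exclude_mhc_group = "HLA-A*02")
  expect_equal(r2$n, 3)
  expect_error(epitope_length_correlation(withA2[1:3, ],
                                          exclude_mhc_group = "HLA-A*02"),
               "fewer than 3")
})

test_that("a generator-coupled length correlation is recovered", {
  cfg <- synthetic_config(n_subjects = 160, clones_per_subject = 13,
                          length_correlation = -0.15, seed = 29)
  gen <- generate_repertoire(cfg)
  pairs <- tibble::tibble(epitope_length = nchar(gen$truth$epitope),
                          cdr3_length = nchar(gen$truth$cdr3_aa))
  r <- epitope_length_correlation(pairs)
  expect_lt(abs(r$rho - (-0.15)), 0.05)
  expect_lt(r$p_value, 0.001)
})

test_that("paired chain length table and alpha-longer fraction", {
  pairs <- tibble::tibble(alpha_cdr3 = c("CAVNGSQGNLIF", "CAVNYGQNFVF"),
                          beta_cdr3 = c("CASSLGGSEQYF", "CASSLGGSYEQYF"),
                          epitope = c("GILGFVFTL", "GILGFVFTL"))
  pl <- paired_chain_lengths(pairs)
  expect_equal(pl$table$combined_length, c(24, 24))
  expect_equal(pl$table$alpha_length[1], 12)
  expect_equal(pl$frac_alpha_longer, 0)  # 12 vs 12 tie and 11 vs 13
  expect_error(paired_chain_lengths(pairs[0, ]), "no pairs")

  # all-equal lengths give fraction 0
  eq <- tibble::tibble(alpha_cdr3 = c("CAVNGSQGNLIF", "CAVNGSQGNLIF"),
                       beta_cdr3 = c("CASSLGGSEQYF", "CASSLGGSEQYF"))
  expect_equal(paired_chain_lengths(eq)$frac_alpha_longer, 0)

  # generator plants the alpha-longer fraction
  cfg <- synthetic_config(n_subjects = 30, clones_per_subject = 8,
                          frac_paired = 0.6, frac_alpha_longer = 0.3,
                          seed = 37)
  gen <- generate_repertoire(cfg)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_tsv(gen$table, tf)
  got <- paired_chain_lengths(match_paired_chains(parse_vdjdb(tf)))
  expect_gt(nrow(gen$alpha_truth), 80)
  expect_equal(got$frac_alpha_longer, 0.3, tolerance = 0.1)
})

test_that("the k-sample Anderson-Darling test matches reference values", {
  # reference statistics and p-values computed independently with
  # scipy.stats.anderson_ksamp (midrank version) on these fixtures
  a <- c(1.1, 2.3, 3.1, 4.2, 5.5, 6.1, 7.9, 8.0)
  b <- c(2.0, 3.3, 4.1, 5.2, 6.6, 7.1, 9.9, 10.0, 11.2)
  cc <- c(0.5, 1.3, 2.1, 3.9, 4.4, 6.0, 7.7)
  r <- ad_ksample(list(a, b, cc))
  expect_equal(r$statistic, 0.15096255461222644, tolerance = 1e-10)
  expect_equal(r$p_value, 0.25)               # capped: similar samples
  expect_equal(r$k, 3)

  x <- c(10, 11, 11, 12, 12, 12, 13, 14, 14, 15)
  y <- c(11, 12, 12, 13, 13, 14, 14, 14, 15, 16, 16)
  r2 <- ad_ksample(list(x, y))
  expect_equal(r2$statistic, 1.1381036646738107, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.11061882453753637, tolerance = 1e-8)

  r3 <- ad_ksample(list(x, x + 5))
  expect_equal(r3$statistic, 10.505164471421857, tolerance = 1e-10)
  expect_equal(r3$p_value, 0.001)             # floored: disjoint samples
  expect_error(ad_ksample(list(a)), "at least 2 samples")
  expect_error(ad_ksample(list(a, 1)), "at least 2 observations")
})

test_that("composition similarity wraps the k-sample test", {
  set.seed(43)
  g1 <- rnorm(30); g2 <- rnorm(30); g3 <- rnorm(30)
  r <- composition_similarity(list(g1, g2, g3))
  expect_gt(r$p_value, 0.05)
  expect_equal(r$n_a, 3)                       # echoes group count
  r2 <- composition_similarity(list(g1, g2 + 10))
  expect_lt(r2$p_value, 0.01)
  expect_true(r2$significant)
  expect_error(composition_similarity(list(g1)), "at least 2")
})

test_that("display formatting suppresses non-significant p-values", {
  expect_equal(format_p_display(c(0.2, 0.01))[1], "ns")
  expect_false(format_p_display(c(0.2, 0.01))[2] == "ns")
})
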