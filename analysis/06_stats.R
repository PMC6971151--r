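#!/usr/bin/env Rscript
# Stage 6: distributional comparisons. Lengths and hydropathy between ID
# and SD, normality of the length distributions, epitope-length vs
# CDR3-length correlation with and without the A*02 stratum, paired
# alpha/beta chain lengths, and per-epitope composition similarity
# (k-sample Anderson-Darling).

suppressMessages(library(immunodominance))

feats <- readr::read_tsv("results/features.tsv", show_col_types = FALSE)
labels <- readr::read_tsv("results/labels.tsv", show_col_types = FALSE)
rows <- list()
add <- function(name, res) rows[[name]] <<- dplyr::mutate(res, comparison = name)

beta <- feats[feats$chain == "TRB", ]
len_id <- beta$length[beta$label == "ID"]
len_sd <- beta$length[beta$label == "SD"]
add("length_ID_vs_SD", compare_lengths(len_id, len_sd, test = "ks"))
add("length_ID_vs_SD_mw", compare_lengths(len_id, len_sd, test = "mw"))
add("hydropathy_ID_vs_SD",
    compare_lengths(beta$hydropathy[beta$label == "ID"],
                    beta$hydropathy[beta$label == "SD"], test = "mw"))
add("nonvj_length_ID_vs_SD",
    compare_lengths(beta$nonvj_length[beta$label == "ID"],
                    beta$nonvj_length[beta$label == "SD"], test = "ks"))
add("length_normality", normality_check(sample(beta$length, min(2000, nrow(beta)))))

if (any(feats$chain == "TRA")) {
  add("length_beta_vs_alpha",
      compare_lengths(beta$length, feats$length[feats$chain == "TRA"],
                      test = "ks"))
}

corr_all <- epitope_length_correlation(tibble::tibble(
  epitope_length = nchar(labels$epitope),
  cdr3_length = nchar(labels$cdr3_aa),
  mhc_allele_group = labels$mhc_allele_group))
corr_noA2 <- epitope_length_correlation(tibble::tibble(
  epitope_length = nchar(labels$epitope),
  cdr3_length = nchar(labels$cdr3_aa),
  mhc_allele_group = labels$mhc_allele_group),
  exclude_mhc_group = "HLA-A*02")
message(sprintf(
  "epitope vs CDR3 length: rho = %.3f (all, n=%d); rho = %.3f (non-A*02, n=%d, p=%.2g)",
  corr_all$rho, corr_all$n, corr_noA2$rho, corr_noA2$n, corr_noA2$p_value))

rec <- readr::read_tsv("results/records_filtered.tsv", show_col_types = FALSE)
pairs <- match_paired_chains(rec)
if (nrow(pairs) > 0) {
  pl <- paired_chain_lengths(pairs)
  message(sprintf("paired chains: %d pairs, alpha longer in %.1f%%",
                  nrow(pl$table), 100 * pl$frac_alpha_longer))
}

# composition similarity across the three best-covered epitopes: compare
# the per-sequence mean hydropathy of the non-VJ-bearing CDR3s
top3 <- names(sort(table(beta$epitope), decreasing = TRUE))[1:3]
groups <- lapply(top3, function(ep) beta$hydropathy[beta$epitope == ep])
ad <- composition_similarity(groups)
add("hydropathy_across_top3_epitopes", ad)
message(sprintf(
  "Anderson-Darling across %s: T = %.3f, p %s", paste(top3, collapse = "/"),
  ad$statistic, format_p_display(ad$p_value)))

stats_tab <- dplyr::bind_rows(rows)
stats_tab$p_display <- format_p_display(stats_tab$p_value)
readr::write_tsv(stats_tab, "results/stats.tsv", progress = FALSE)
message("wrote results/stats.tsv with ", nrow(stats_tab), " comparisons ",
        "(no multiple-testing correction applied)")
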