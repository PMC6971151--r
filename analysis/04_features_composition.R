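#!/usr/bin/env Rscript
# Stage 4: CDR3 region decomposition and physicochemical profiling.
# Trims each pooled sequence to its non-VJ core, computes the feature
# panel, compares ID vs SD hydropathy-class composition, contrasts the
# beta and alpha non-VJ residue usage, and profiles the naive nucleotide
# pool's guanine content.

suppressMessages(library(immunodominance))

id_set <- readr::read_tsv("results/id_set.tsv", show_col_types = FALSE)
sd_set <- readr::read_tsv("results/sd_set.tsv", show_col_types = FALSE)
labels <- readr::read_tsv("results/labels.tsv", show_col_types = FALSE)
germ <- synthetic_germline()

pools <- dplyr::bind_rows(
  dplyr::mutate(id_set, label = "ID"),
  dplyr::mutate(sd_set, label = "SD"))
genes <- labels |>
  dplyr::distinct(cdr3_aa, epitope, chain, .keep_all = TRUE) |>
  dplyr::select(cdr3_aa, epitope, chain, v_subgroup, j_subgroup)
pools <- dplyr::left_join(pools, genes,
                          by = c("cdr3_aa", "epitope", "chain"))

reg <- extract_nonvj_aa(pools$cdr3_aa, pools$v_subgroup, pools$j_subgroup,
                        germ)
feats <- compute_features(pools$cdr3_aa)
feats$nonvj_length <- nchar(reg$nonvj_part)
feats$nonvj_part <- reg$nonvj_part
feats$label <- pools$label
feats$chain <- pools$chain
feats$epitope <- pools$epitope
readr::write_tsv(feats[, names(feats) != "nonvj_part"],
                 "results/features.tsv", progress = FALSE)

comp_rows <- list()
for (lab in c("ID", "SD")) {
  nv <- feats$nonvj_part[feats$label == lab & nzchar(feats$nonvj_part)]
  comp <- aa_composition(nv)
  comp_rows[[lab]] <- tibble::tibble(group = lab, residue = names(comp),
                                     frequency = unname(comp),
                                     class = classify_hydropathy(names(comp)))
  message(sprintf("%s non-VJ: %d residues pooled, G fraction %.1f%%", lab,
                  sum(nchar(nv)), 100 * comp[["G"]]))
}
comp_tab <- dplyr::bind_rows(comp_rows)
readr::write_tsv(comp_tab, "results/nonvj_composition.tsv", progress = FALSE)

# beta vs alpha non-VJ usage (log2 ratio, shared capping convention)
by_chain <- lapply(c("TRB", "TRA"), function(ch) {
  nv <- feats$nonvj_part[feats$chain == ch & nzchar(feats$nonvj_part)]
  if (length(nv) == 0) NULL else aa_composition(nv)
})
names(by_chain) <- c("TRB", "TRA")
if (!is.null(by_chain$TRA)) {
  lr <- composition_log_ratio(by_chain$TRB, by_chain$TRA)
  readr::write_tsv(tibble::tibble(residue = names(lr), log2_beta_over_alpha = lr),
                   "results/composition_log_ratio_beta_alpha.tsv",
                   progress = FALSE)
  message(sprintf("glycine log2(beta/alpha): %+.3f", lr[["G"]]))
}

# naive nucleotide pool: insert recovery and guanine content
naive <- readr::read_tsv("results/synthetic/naive_pool.tsv",
                         show_col_types = FALSE)
nr <- extract_nonvj_nt(naive$cdr3_nt, naive$v_gene, naive$j_gene, germ)
ins <- nr$nonvj_nt[nzchar(nr$nonvj_nt)]
gf <- mean(unlist(strsplit(ins, "")) == "g")
message(sprintf("naive nucleotide inserts: %d with guanine fraction %.1f%%",
                length(ins), 100 * gf))
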