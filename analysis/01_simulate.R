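#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the default synthetic cohort: 60 subjects responding to the
# 8-epitope panel, 15 clones each with a geometric frequency spectrum, a
# built-in epitope-length/CDR3-length coupling of -0.15, 30% of clones
# alpha/beta paired, plus realistic nuisance rows (naive phenotypes,
# missing JSON fields, duplicated measurements). Also generates the naive
# nucleotide pool. Everything downstream reads the files written here.

suppressMessages(library(immunodominance))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(
  n_subjects = 60,
  clones_per_subject = 15,
  length_correlation = -0.15,
  frac_paired = 0.3,
  frac_alpha_longer = 0.3,
  frac_naive_phenotype = 0.05,
  frac_missing_fields = 0.03,
  frac_duplicated_measurements = 0.10,
  naive_pool_size = 2000,
  seed = 20191206L)

gen <- generate_repertoire(cfg)
write_clonotype_tsv(gen$table, file.path(out, "clonotypes.tsv"))
readr::write_tsv(gen$truth, file.path(out, "truth.tsv"), progress = FALSE)

naive <- generate_naive_pool(cfg)
readr::write_tsv(naive$table, file.path(out, "naive_pool.tsv"), progress = FALSE)
readr::write_tsv(naive$truth, file.path(out, "naive_truth.tsv"), progress = FALSE)

message("cohort: ", nrow(gen$table), " table rows over ", cfg$n_subjects,
        " subjects (", nrow(gen$truth), " true clones, ",
        sum(gen$truth$is_id), " intended ID)")
message("paired alpha records: ",
        if (is.null(gen$alpha_truth)) 0 else nrow(gen$alpha_truth))
message("naive pool: ", nrow(naive$table), " nucleotide clonotypes")
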