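#!/usr/bin/env Rscript
# Stage 5: positional enrichment. Anchors ID and SD sequences between
# C104 and F/W118 in a 17-column alignment, computes per-group positional
# probability matrices, the capped pLES, and the positive-logo matrix —
# per epitope and pooled across epitopes.

suppressMessages(library(immunodominance))

id_set <- readr::read_tsv("results/id_set.tsv", show_col_types = FALSE)
sd_set <- readr::read_tsv("results/sd_set.tsv", show_col_types = FALSE)
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

strata <- c(unique(id_set$epitope[id_set$chain == "TRB"]), "pooled")
n_done <- 0
for (ep in strata) {
  id_seq <- id_set$cdr3_aa[id_set$chain == "TRB" &
                             (ep == "pooled" | id_set$epitope == ep)]
  sd_seq <- sd_set$cdr3_aa[sd_set$chain == "TRB" &
                             (ep == "pooled" | sd_set$epitope == ep)]
  al_id <- align_cdr3(id_seq)
  al_sd <- align_cdr3(sd_seq)
  n_id <- sum(!is.na(al_id$aligned)); n_sd <- sum(!is.na(al_sd$aligned))
  if (n_id < 5 || n_sd < 5) {
    message(ep, ": skipped (", n_id, " ID / ", n_sd, " SD aligned)")
    next
  }
  ppm_id <- compute_ppm(al_id$aligned)
  ppm_sd <- compute_ppm(al_sd$aligned)
  ples <- compute_ples(ppm_id, ppm_sd, cap = 5, base = 2)
  tag <- gsub("[^A-Za-z0-9]+", "_", ep)
  write_matrix_tsv(ppm_id, file.path(out, paste0("ppm_id_", tag, ".tsv")))
  write_matrix_tsv(ppm_sd, file.path(out, paste0("ppm_sd_", tag, ".tsv")))
  write_matrix_tsv(ples, file.path(out, paste0("ples_", tag, ".tsv")))
  write_matrix_tsv(positive_logo_matrix(ples),
                   file.path(out, paste0("logo_", tag, ".tsv")))
  fin <- ples[is.finite(ples)]
  message(sprintf(
    "%s: %d ID / %d SD aligned; pLES range [%.2f, %.2f], %d capped, %d masked",
    ep, n_id, n_sd, min(fin), max(fin), sum(abs(fin) == 5),
    sum(is.na(ples))))
  n_done <- n_done + 1
}
message("enrichment matrices written for ", n_done, " strata (columns ",
        paste(range(imgt_position_labels(17)[c(1, 17)]), collapse = ".."),
        " in IMGT-style labels)")
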