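#!/usr/bin/env Rscript
# Stage 2: parse the clonotype table and apply the inclusion filters
# (drop naive CD45RA+CCR7+ rows, rows without a usable frequency, and
# CD4 rows). Writes the parsed records and the rejection tally.

suppressMessages(library(immunodominance))

rec <- parse_vdjdb("results/synthetic/clonotypes.tsv")
flt <- filter_records(rec)

dir.create("results", showWarnings = FALSE)
readr::write_tsv(flt$records, "results/records_filtered.tsv", progress = FALSE)
readr::write_tsv(flt$tally, "results/filter_tally.tsv", progress = FALSE)

message("parsed ", nrow(rec), " records; kept ", nrow(flt$records))
for (i in seq_len(nrow(flt$tally))) {
  message("  removed (", flt$tally$reason[i], "): ", flt$tally$n[i])
}
message("subjects (composite keys): ",
        length(unique(flt$records$subject_key)))
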