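# toy germline table matching the worked examples: V prefix "CASS"/"CASSE",
# J suffix "EQYF"
toy_germline <- function() {
  tibble::tibble(
    gene = c("TRBVX", "TRBVY", "TRBJX"),
    region = c("V", "V", "J"),
    chain = "TRB",
    aa_seq = c("CASS", "CASSE", "EQYF"),
    nt_seq = c("tgtgctagcagc", "tgtgctagcagcgag", "gagcagtatttt"))
}

# minimal VDJdb-dialect TSV from parallel field vectors
write_fixture_tsv <- function(path, cdr3, epitope = "GILGFVFTL",
                              meta = NULL, method = NULL, gene = "TRB",
                              v = "TRBV19*01", j = "TRBJ2-7*01",
                              mhc = "HLA-A*02:01", complex_id = 0,
                              reference = "PMID:1") {
  n <- length(cdr3)
  if (is.null(meta)) {
    meta <- rep('{"subject.id": "S1", "cell.subset": "CD8+"}', n)
  }
  if (is.null(method)) method <- rep('{"frequency": "10/100"}', n)
  tab <- tibble::tibble(
    "complex.id" = rep_len(complex_id, n),
    gene = rep_len(gene, n),
    cdr3 = cdr3,
    "v.segm" = rep_len(v, n),
    "j.segm" = rep_len(j, n),
    species = "HomoSapiens",
    "mhc.a" = rep_len(mhc, n),
    "mhc.class" = "MHCI",
    "antigen.epitope" = rep_len(epitope, n),
    "antigen.species" = "InfluenzaA",
    "reference.id" = rep_len(reference, n),
    meta = meta,
    method = method)
  write_clonotype_tsv(tab, path)
  path
}

# labeled-records tibble for dominance unit tests
make_labels <- function(cdr3, freq, subject = "S1", epitope = "GILGFVFTL",
                        mhc_group = "HLA-A*02", chain = "TRB") {
  n <- length(cdr3)
  tibble::tibble(
    subject_key = rep_len(subject, n),
    cdr3_aa = cdr3,
    epitope = rep_len(epitope, n),
    mhc_allele_group = rep_len(mhc_group, n),
    chain = rep_len(chain, n),
    frequency_pct = freq)
}

random_peptides <- function(n, min_len = 5, max_len = 18) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  vapply(sample(min_len:max_len, n, replace = TRUE), function(L) {
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
}
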