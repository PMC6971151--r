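# longest common prefix/suffix lengths of x against a fixed segment,
# vectorized over x (segments are short, so we scan lengths downward)
.lcp_len <- function(x, seg) {
  m <- pmin(nchar(x), nchar(seg))
  out <- integer(length(x))
  for (L in seq_len(nchar(seg))) {
    hit <- m >= L & substr(x, 1, L) == substr(seg, 1, L)
    out[hit] <- L
  }
  out
}
.lcs_len <- function(x, seg) {
  nx <- nchar(x)
  m <- pmin(nx, nchar(seg))
  out <- integer(length(x))
  ns <- nchar(seg)
  for (L in seq_len(ns)) {
    hit <- m >= L &
      substr(x, nx - L + 1, nx) == substr(seg, ns - L + 1, ns)
    out[hit] <- L
  }
  out
}

# shared worker for amino-acid and nucleotide trimming
.extract_regions <- function(seqs, v_genes, j_genes, germline, what) {
  vseg <- .germline_seq(germline, v_genes, "V", what)
  jseg <- .germline_seq(germline, j_genes, "J", what)
  n <- length(seqs)
  v_len <- integer(n); j_len <- integer(n)
  ok <- !is.na(vseg) & !is.na(jseg) & !is.na(seqs) & nzchar(seqs)
  for (vg in unique(vseg[ok])) {
    idx <- ok & vseg == vg
    v_len[idx] <- .lcp_len(seqs[idx], vg)
  }
  for (jg in unique(jseg[ok])) {
    idx <- ok & jseg == jg
    j_len[idx] <- .lcs_len(seqs[idx], jg)
  }
  # overlap: the V match wins, the J match is shortened
  over <- ok & (v_len + j_len > nchar(seqs))
  if (any(over)) {
    message(sum(over), " sequence(s) with overlapping V/J matches; J match shortened")
    j_len[over] <- nchar(seqs[over]) - v_len[over]
  }
  tibble::tibble(
    seq = seqs,
    v_part = ifelse(ok, substr(seqs, 1, v_len), NA_character_),
    nonvj_part = ifelse(ok, substr(seqs, v_len + 1, nchar(seqs) - j_len),
                        NA_character_),
    j_part = ifelse(ok, substr(seqs, nchar(seqs) - j_len + 1, nchar(seqs)),
                    NA_character_),
    v_len = ifelse(ok, v_len, NA_integer_),
    skipped = !ok)
}

#' Decompose CDR3 amino-acid sequences into V / non-VJ / J regions
#'
#' The germline-encoded V and J contributions are removed from the terminal
#' ends by exact longest prefix (against the V gene's CDR3-proximal
#' segment) and longest suffix (against the J gene segment) matching; the
#' remainder is the non-VJ region (D-segment remnants plus non-templated
#' insertions). If the two matches would overlap, the V match wins and the
#' J match is shortened. Concatenating the three parts always reconstructs
#' the input.
#'
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @param v_gene,j_gene Gene-level V and J calls (recycled if length 1).
#' @param germline Germline reference from [read_germline()].
#' @return A tibble with columns `cdr3_aa`, `v_part`, `nonvj_part`,
#'   `j_part` and `skipped` (gene missing from the reference).
#' @examples
#' g <- synthetic_germline()
#' extract_nonvj_aa("CASSLGGSYEQYF", "TRBV28", "TRBJ2-7", g)
#' @export
extract_nonvj_aa <- function(cdr3_aa, v_gene, j_gene, germline) {
  if (any(is.na(cdr3_aa) | !nzchar(cdr3_aa))) stop("empty CDR3 sequence")
  n <- length(cdr3_aa)
  v_gene <- rep_len(v_gene, n); j_gene <- rep_len(j_gene, n)
  out <- .extract_regions(cdr3_aa, v_gene, j_gene, germline, "aa_seq")
  n_skip <- sum(out$skipped)
  if (n_skip > 0) {
    warning(n_skip, " record(s) skipped: V or J gene absent from germline table")
  }
  tibble::tibble(cdr3_aa = cdr3_aa, v_part = out$v_part,
                 nonvj_part = out$nonvj_part, j_part = out$j_part,
                 skipped = out$skipped)
}

#' Decompose CDR3 nucleotide sequences into V / non-VJ / J regions
#'
#' Nucleotide-level analogue of [extract_nonvj_aa()] using the germline
#' `nt_seq` segments. The non-VJ insert is translated when it is in frame:
#' the V flank must end on a codon boundary and the insert length must be
#' divisible by three; otherwise the translation is omitted (`NA`).
#'
#' @param cdr3_nt Character vector of CDR3 nucleotide sequences
#'   (case-insensitive).
#' @param v_gene,j_gene Gene-level V and J calls.
#' @param germline Germline reference with an `nt_seq` column.
#' @return A tibble with columns `cdr3_nt`, `v_part`, `nonvj_nt`, `j_part`,
#'   `nonvj_aa` (translation or `NA`) and `skipped`.
#' @export
extract_nonvj_nt <- function(cdr3_nt, v_gene, j_gene, germline) {
  if (any(is.na(cdr3_nt) | !nzchar(cdr3_nt))) stop("empty CDR3 nucleotide sequence")
  n <- length(cdr3_nt)
  v_gene <- rep_len(v_gene, n); j_gene <- rep_len(j_gene, n)
  seqs <- tolower(cdr3_nt)
  out <- .extract_regions(seqs, v_gene, j_gene, germline, "nt_seq")
  n_skip <- sum(out$skipped)
  if (n_skip > 0) {
    warning(n_skip, " record(s) skipped: V or J gene absent from germline table")
  }
  ins <- out$nonvj_part
  in_frame <- !is.na(ins) & out$v_len %% 3 == 0 & nchar(ins) %% 3 == 0
  aa <- rep(NA_character_, n)
  aa[in_frame & nchar(ins) == 0] <- ""
  todo <- in_frame & nchar(ins) > 0
  if (any(todo)) aa[todo] <- vapply(ins[todo], translate_nt, character(1))
  tibble::tibble(cdr3_nt = seqs, v_part = out$v_part, nonvj_nt = ins,
                 j_part = out$j_part, nonvj_aa = aa, skipped = out$skipped)
}

#' Translate a nucleotide string (standard genetic code)
#'
#' @param nt A single in-frame nucleotide string (length divisible by 3).
#' @return The amino-acid translation; stop codons are rendered as `*`.
#' @export
translate_nt <- function(nt) {
  nt <- toupper(gsub("U", "T", nt, ignore.case = TRUE))
  if (nchar(nt) %% 3 != 0) stop("nucleotide string length not divisible by 3")
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- GENETIC_CODE_TABLE[codons]
  if (anyNA(aa)) stop("ambiguous or invalid codon: ",
                      paste(codons[is.na(aa)], collapse = ", "))
  paste(aa, collapse = "")
}

# standard genetic code, codon -> one-letter amino acid ('*' = stop)
GENETIC_CODE_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

# residue count matrix (n peptides x 20), errors on nonstandard residues
.residue_counts <- function(peptide) {
  chars <- strsplit(peptide, "")
  bad <- lapply(chars, function(cc) which(!cc %in% AA20))
  ibad <- which(lengths(bad) > 0)
  if (length(ibad) > 0) {
    i <- ibad[1]
    stop("non-standard residue '", chars[[i]][bad[[i]][1]], "' at position ",
         bad[[i]][1], " of peptide ", i)
  }
  counts <- t(vapply(chars,
                     function(cc) tabulate(match(cc, AA20), nbins = 20L),
                     integer(20)))
  colnames(counts) <- AA20
  counts
}

#' Compute the physicochemical feature panel of peptides
#'
#' For each peptide: length, mean Kyte-Doolittle hydropathy, mean Grantham
#' polarity, Ikai aliphatic index, mean Zimmerman bulkiness, net charge
#' (count of K/R minus count of D/E, plus `his_charge` per histidine),
#' fractions of acidic (D, E), basic (H, K, R) and aromatic (H, F, W, Y)
#' residues, Boman protein-binding index (negated mean transfer free
#' energy) and the ten Kidera factors as residue means.
#'
#' @param peptide Character vector of peptide sequences (standard residues
#'   only; non-standard residues raise an error naming the position).
#' @param his_charge Partial charge attributed to histidine (default 0.1).
#' @return A tibble with one row per peptide.
#' @examples
#' compute_features("CASSLGGSYEQYF")
#' @export
compute_features <- function(peptide, his_charge = 0.1) {
  if (any(is.na(peptide) | !nzchar(peptide))) stop("empty peptide")
  counts <- .residue_counts(peptide)
  len <- rowSums(counts)
  frac <- counts / len
  sc <- aa_scales()
  msum <- function(scale) as.numeric(counts %*% scale[AA20]) / len
  kid <- (counts %*% sc$kidera[AA20, , drop = FALSE]) / len
  colnames(kid) <- paste0("kidera_", 1:10)
  tibble::tibble(
    peptide = peptide,
    length = as.integer(len),
    hydropathy = msum(sc$hydropathy),
    polarity = msum(sc$polarity),
    aliphatic_index = 100 * (frac[, "A"] + 2.9 * frac[, "V"] +
                               3.9 * (frac[, "I"] + frac[, "L"])),
    bulkiness = msum(sc$bulkiness),
    net_charge = counts[, "K"] + counts[, "R"] - counts[, "D"] -
      counts[, "E"] + his_charge * counts[, "H"],
    frac_acidic = frac[, "D"] + frac[, "E"],
    frac_basic = frac[, "H"] + frac[, "K"] + frac[, "R"],
    frac_aromatic = frac[, "H"] + frac[, "F"] + frac[, "W"] + frac[, "Y"],
    boman = -msum(sc$boman_energy)) |>
    dplyr::bind_cols(tibble::as_tibble(kid))
}

#' Pooled amino-acid composition of a set of peptides
#'
#' Residue frequencies over all residues pooled from the given peptides;
#' empty strings contribute nothing. Frequencies sum to 1.
#'
#' @param peptides Character vector (e.g. whole CDR3s or non-VJ regions).
#' @return Named numeric vector of length 20 over the standard residues.
#' @export
aa_composition <- function(peptides) {
  peptides <- peptides[!is.na(peptides) & nzchar(peptides)]
  if (length(peptides) == 0) stop("no residues to pool: all peptides empty")
  counts <- colSums(.residue_counts(peptides))
  counts / sum(counts)
}

#' Log ratio of two residue compositions
#'
#' Per-residue `log(freq_a / freq_b)` in the given base. Residues with zero
#' frequency in both compositions are omitted; residues present in only
#' one composition receive the capped value (the same capping convention
#' as the positional log enrichment score).
#'
#' @param freq_a,freq_b Named numeric frequency vectors (normalized).
#' @param cap Positive bound substituted for infinite ratios (default 5).
#' @param base Logarithm base (default 2).
#' @return Named numeric vector over the residues present in either input.
#' @export
composition_log_ratio <- function(freq_a, freq_b, cap = 5, base = 2) {
  res <- union(names(freq_a)[freq_a > 0], names(freq_b)[freq_b > 0])
  res <- res[order(match(res, AA20))]
  fa <- ifelse(res %in% names(freq_a), freq_a[res], 0)
  fb <- ifelse(res %in% names(freq_b), freq_b[res], 0)
  out <- ifelse(fa > 0 & fb > 0, log(fa / fb, base = base),
                ifelse(fa > 0, cap, -cap))
  stats::setNames(out, res)
}
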