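#' Anchor-align CDR3 sequences to a fixed width
#'
#' CDR3s are anchored between the conserved C104 and F/W118 residues
#' (IMGT numbering). Sequences must start with `C` and end with `F` or `W`;
#' the interior (everything between the anchors) must have length within
#' `[interior_min, interior_max]`. The first `ceiling(n/2)` interior
#' residues are placed adjacent to the C anchor, the remaining
#' `floor(n/2)` adjacent to the F/W anchor, and `interior_max - n` gap
#' symbols (`-`) fill the middle — emulating IMGT junction numbering's
#' middle-of-loop gap creation. Total width is `interior_max + 2`
#' (17 with the defaults).
#'
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @param interior_min,interior_max Admissible interior lengths
#'   (defaults 10 and 15).
#' @return A list with `aligned` (character vector of fixed-width aligned
#'   strings, `NA` for excluded sequences), `status` (`"aligned"`,
#'   `"bad_anchor"` or `"length_out_of_range"` per sequence) and `tally`
#'   (named exclusion counts).
#' @examples
#' align_cdr3("CASSLGGSYEQYF")
#' @export
align_cdr3 <- function(cdr3_aa, interior_min = 10, interior_max = 15) {
  stopifnot(interior_min >= 1, interior_max >= interior_min)
  n_char <- nchar(cdr3_aa)
  first <- substr(cdr3_aa, 1, 1)
  last <- substr(cdr3_aa, n_char, n_char)
  anchored <- first == "C" & last %in% c("F", "W") & n_char >= 3
  interior_n <- n_char - 2L
  in_range <- interior_n >= interior_min & interior_n <= interior_max
  status <- ifelse(!anchored, "bad_anchor",
                   ifelse(!in_range, "length_out_of_range", "aligned"))
  ok <- status == "aligned"
  aligned <- rep(NA_character_, length(cdr3_aa))
  if (any(ok)) {
    n <- interior_n[ok]
    left <- ceiling(n / 2)
    interior <- substr(cdr3_aa[ok], 2, n_char[ok] - 1)
    aligned[ok] <- paste0(
      first[ok],
      substr(interior, 1, left),
      strrep("-", interior_max - n),
      substr(interior, left + 1, n),
      last[ok])
  }
  tally <- c(aligned = sum(ok),
             bad_anchor = sum(status == "bad_anchor"),
             length_out_of_range = sum(status == "length_out_of_range"))
  list(aligned = aligned, status = status, tally = tally,
       width = interior_max + 2L)
}

#' Strip gaps from aligned CDR3s
#'
#' Inverse of [align_cdr3()]: removes gap symbols, recovering the original
#' sequence (anchors included).
#'
#' @param aligned Character vector of aligned strings.
#' @return Character vector of ungapped sequences.
#' @export
ungap_cdr3 <- function(aligned) {
  gsub("-", "", aligned, fixed = TRUE)
}

#' Positional probability matrix of an aligned sequence set
#'
#' For `N` aligned sequences of common width `W`, entry `(k, j)` is the
#' fraction of sequences carrying symbol `k` at position `j`; the gap `-`
#' is the 21st symbol. Every column sums to 1.
#'
#' @param aligned Character vector of equal-width aligned strings
#'   (`NA` entries are dropped).
#' @return A 21 x W numeric matrix (rows: 20 residues then `-`), with
#'   attribute `n_sequences`.
#' @export
compute_ppm <- function(aligned) {
  aligned <- aligned[!is.na(aligned)]
  if (length(aligned) == 0) stop("no aligned sequences")
  w <- unique(nchar(aligned))
  if (length(w) != 1) stop("aligned sequences have differing widths")
  symbols <- c(AA20, "-")
  m <- matrix(unlist(strsplit(aligned, "")), nrow = length(aligned),
              ncol = w, byrow = TRUE)
  ppm <- vapply(seq_len(w), function(j) {
    tabulate(match(m[, j], symbols), nbins = 21L)
  }, integer(21)) / length(aligned)
  dimnames(ppm) <- list(symbols, paste0("p", seq_len(w)))
  attr(ppm, "n_sequences") <- length(aligned)
  ppm
}

#' Positional log enrichment score (pLES)
#'
#' The log ratio (default base 2) of the ID positional probability to the
#' SD positional probability at each symbol and position. A symbol present
#' in ID but absent in SD scores `+cap`; absent in ID but present in SD,
#' `-cap`; absent from both groups, the cell is masked (`NA`). No
#' pseudocounts are applied: zeros propagate to the caps exactly.
#'
#' @param ppm_id,ppm_sd Positional probability matrices of equal width
#'   from [compute_ppm()].
#' @param cap Positive bound replacing infinite ratios (default 5).
#' @param base Logarithm base (default 2).
#' @return A 21 x W matrix of scores with attributes `cap` and `log_base`;
#'   masked cells are `NA`.
#' @export
compute_ples <- function(ppm_id, ppm_sd, cap = 5, base = 2) {
  if (!identical(dim(ppm_id), dim(ppm_sd))) {
    stop("PPM width/shape mismatch between ID and SD")
  }
  stopifnot(cap > 0)
  out <- matrix(NA_real_, nrow = nrow(ppm_id), ncol = ncol(ppm_id),
                dimnames = dimnames(ppm_id))
  both <- ppm_id > 0 & ppm_sd > 0
  out[both] <- log(ppm_id[both] / ppm_sd[both], base = base)
  out[ppm_id > 0 & ppm_sd == 0] <- cap
  out[ppm_id == 0 & ppm_sd > 0] <- -cap
  attr(out, "cap") <- cap
  attr(out, "log_base") <- base
  out
}

#' Nonnegative logo matrix from a pLES matrix
#'
#' Keeps only positive enrichment: negative and masked cells become 0 and
#' the gap row is dropped, yielding a 20 x W matrix of stack heights for
#' sequence-logo rendering.
#'
#' @param ples Matrix from [compute_ples()].
#' @return A 20 x W nonnegative matrix.
#' @export
positive_logo_matrix <- function(ples) {
  m <- ples[rownames(ples) != "-", , drop = FALSE]
  m[is.na(m) | m < 0] <- 0
  attr(m, "cap") <- NULL
  attr(m, "log_base") <- NULL
  m
}

#' Map alignment columns to IMGT-style position labels
#'
#' Display labels 104..118 for the default 17-column alignment: anchors
#' C104 and F/W118, left block 105.., right block ..117, gaps in the
#' middle. Labels are for display only; no insertion codes (111.1, 112.1)
#' are assigned.
#'
#' @param width Alignment width (default 17).
#' @return Character vector of labels of length `width`.
#' @export
imgt_position_labels <- function(width = 17) {
  interior <- width - 2L
  left <- ceiling(interior / 2)
  right <- interior - left
  c("104", as.character(104 + seq_len(left)),
    as.character(118 - rev(seq_len(right))), "118")
}

#' Write a PPM/pLES-style matrix as TSV
#'
#' Rows are symbols, columns position labels; masked cells are written as
#' `NA`.
#'
#' @param mat Matrix with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(symbol = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Write aligned CDR3s as aligned FASTA
#'
#' @param aligned Character vector of aligned strings (`NA` dropped).
#' @param path Output path.
#' @param names Optional sequence names (default `seq1..seqN`).
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aligned, path, names = NULL) {
  aligned <- aligned[!is.na(aligned)]
  if (is.null(names)) names <- paste0("seq", seq_along(aligned))
  writeLines(paste0(">", names, "\n", aligned), path)
  invisible(path)
}
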