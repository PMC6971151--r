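#' Read a germline V/J reference table
#'
#' The reference lists, per gene, the CDR3-proximal amino-acid segment
#' (V genes: the conserved prefix starting at C104; J genes: the conserved
#' suffix ending at F/W118) and optionally the corresponding nucleotide
#' segment. Used for exact longest prefix/suffix trimming of CDR3s into
#' V / non-VJ / J regions.
#'
#' @param path Path to a tab-separated file with columns `gene`, `region`
#'   (`V` or `J`), `chain` (`TRA`/`TRB`), `aa_seq` and optionally `nt_seq`.
#' @return A tibble with one row per gene.
#' @export
read_germline <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("gene", "region", "aa_seq")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("germline table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$gene)) stop("germline table has duplicated gene names")
  tab
}

#' Bundled synthetic germline reference
#'
#' A small stand-in reference covering the genes emitted by the synthetic
#' repertoire generator. Gene names follow TRBV/TRBJ/TRAV/TRAJ nomenclature
#' but the segments are constructed examples, not database sequences; for
#' real data supply your own reference via [read_germline()].
#'
#' @return A tibble as returned by [read_germline()].
#' @export
synthetic_germline <- function() {
  read_germline(system.file("extdata", "germline_synthetic.tsv",
                            package = "immunodominance", mustWork = TRUE))
}

# gene -> segment lookup, errors listing the table's region if absent
.germline_seq <- function(germline, genes, region, what = c("aa_seq", "nt_seq")) {
  what <- match.arg(what)
  sub <- germline[germline$region == region, , drop = FALSE]
  idx <- match(genes, sub$gene)
  if (what == "nt_seq" && !"nt_seq" %in% names(sub)) {
    stop("germline table has no nt_seq column")
  }
  out <- sub[[what]][idx]
  out
}
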