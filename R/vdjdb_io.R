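#' @importFrom rlang .data
NULL

# Safe JSON object parse: returns a named list, or NULL on malformed input.
.parse_json_cell <- function(txt) {
  if (is.na(txt) || !nzchar(trimws(txt))) return(list())
  tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
           error = function(e) NULL)
}

.chr_or_na <- function(lst, key) {
  v <- lst[[key]]
  if (is.null(v) || length(v) == 0 || !nzchar(as.character(v)[1])) NA_character_
  else as.character(v)[1]
}

#' Parse a frequency string into percent
#'
#' Accepts the dialects seen across VDJdb-contributing studies:
#' `"x/y"` fractions (converted to `100 * x / y` percent), explicit percent
#' strings (`"12.5%"`), and bare decimals, interpreted as a fraction of 1
#' when `<= 1` and as percent otherwise.
#'
#' @param x Character vector of frequency strings (may contain `NA`).
#' @return A tibble with columns `frequency_pct` (numeric, `NA` if missing
#'   or unparseable) and `frequency_denominator` (character, the `y` of an
#'   `x/y` fraction, else `NA`).
#' @export
parse_frequency <- function(x) {
  n <- length(x)
  pct <- rep(NA_real_, n)
  den <- rep(NA_character_, n)
  x <- ifelse(is.na(x), NA_character_, trimws(x))
  ok <- !is.na(x) & nzchar(x)

  frac <- ok & grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", x)
  if (any(frac)) {
    parts <- stringr::str_split_fixed(x[frac], "/", 2)
    num <- suppressWarnings(as.numeric(trimws(parts[, 1])))
    dd <- suppressWarnings(as.numeric(trimws(parts[, 2])))
    pct[frac] <- 100 * num / dd
    den[frac] <- trimws(parts[, 2])
  }
  perc <- ok & !frac & grepl("%$", x)
  if (any(perc)) {
    pct[perc] <- suppressWarnings(as.numeric(sub("%$", "", x[perc])))
  }
  bare <- ok & !frac & !perc
  if (any(bare)) {
    v <- suppressWarnings(as.numeric(x[bare]))
    pct[bare] <- ifelse(!is.na(v) & v <= 1, 100 * v, v)
  }
  tibble::tibble(frequency_pct = pct, frequency_denominator = den)
}

#' Normalize an MHC allele to its allele group
#'
#' Truncates an allele string to locus plus first numeric field (e.g.
#' `"HLA-A*02:01"` to `"HLA-A*02"`), enabling comparison of differently
#' reported alleles across studies. Strings without a `*` field separator
#' are returned unchanged and flagged.
#'
#' @param allele Character vector of allele strings.
#' @return Character vector of allele groups, with a logical attribute
#'   `unparseable` marking entries returned unchanged.
#' @examples
#' normalize_mhc_group("HLA-A*02:01")
#' @export
normalize_mhc_group <- function(allele) {
  m <- regmatches(allele, regexec("^([^*]+)\\*([0-9]+)", allele))
  out <- vapply(seq_along(allele), function(i) {
    if (length(m[[i]]) == 3) paste0(m[[i]][2], "*", m[[i]][3]) else allele[i]
  }, character(1))
  bad <- vapply(m, function(g) length(g) != 3, logical(1)) & !is.na(allele)
  if (any(bad, na.rm = TRUE)) {
    warning("unparseable MHC allele(s) left unchanged: ",
            paste(unique(allele[bad]), collapse = ", "))
  }
  attr(out, "unparseable") <- bad
  out
}

#' Normalize a V/J gene call to its gene-level name
#'
#' Strips the allele designation (everything from `"*"` onward), e.g.
#' `"TRBV19*01"` to `"TRBV19"`.
#'
#' @param gene_call Character vector of gene calls.
#' @return Character vector of gene-level names.
#' @export
normalize_gene_subgroup <- function(gene_call) {
  sub("\\*.*$", "", gene_call)
}

#' Build the composite subject key
#'
#' Subject identifiers in public clonotype tables are often missing or too
#' coarse to delimit one individual's response, so responses are grouped by
#' the combination of subject id, replica id, epitope, publication reference
#' and the denominator of the reported frequency, joined with `"*"`. A
#' missing part is rendered as `"*"` (never dropped), so keys with missing
#' parts contain consecutive `"*"` characters. Keys are opaque grouping
#' labels and are never re-parsed.
#'
#' @param subject_id,replica_id,epitope,reference,denominator Character
#'   vectors (recycled); `NA` marks a missing part. `epitope` must be
#'   non-missing.
#' @return Character vector of keys.
#' @examples
#' build_subject_key("S1", "r1", "GILGFVFTL", "PMID:1", "100")
#' @export
build_subject_key <- function(subject_id, replica_id, epitope, reference,
                              denominator) {
  if (any(is.na(epitope))) stop("epitope must be non-missing in subject keys")
  tok <- function(x) ifelse(is.na(x) | !nzchar(x), "*", x)
  paste(tok(subject_id), tok(replica_id), tok(epitope), tok(reference),
        tok(denominator), sep = "*")
}

#' Parse a VDJdb-dialect clonotype table
#'
#' Reads a tab-separated export with columns `complex.id`, `gene`, `cdr3`,
#' `v.segm`, `j.segm`, `species`, `mhc.a`, `mhc.class`, `antigen.epitope`,
#' `antigen.species`, `reference.id`, `meta` and `method`, where `meta` and
#' `method` hold JSON object text (subject id, replica id, cell subset;
#' clonotype frequency). Produces one validated clonotype record per row:
#' gene calls are normalized to gene-level names, MHC alleles to allele
#' groups, frequencies to percent, and the composite subject key is built.
#' A malformed JSON cell yields a record with the affected fields missing
#' plus a warning, never an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble of clonotype records with columns `chain`, `cdr3_aa`,
#'   `cdr3_nt`, `v_gene`, `j_gene`, `v_subgroup`, `j_subgroup`,
#'   `mhc_allele`, `mhc_allele_group`, `mhc_class`, `epitope`,
#'   `epitope_species`, `subject_id`, `replica_id`, `subject_key`,
#'   `frequency_pct`, `frequency_denominator`, `phenotype`, `complex_id`,
#'   `reference`.
#' @export
parse_vdjdb <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c("gene", "cdr3", "antigen.epitope")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss) > 0) {
    stop("input table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  n <- nrow(tab)
  col <- function(nm) if (nm %in% names(tab)) tab[[nm]] else rep(NA_character_, n)

  meta_raw <- col("meta")
  method_raw <- col("method")
  # parse each distinct JSON text once
  parse_unique <- function(raw) {
    u <- unique(raw)
    parsed <- lapply(u, .parse_json_cell)
    bad <- vapply(parsed, is.null, logical(1))
    parsed[bad] <- list(list())
    n_bad <- sum(bad & !is.na(u) & nzchar(u))
    if (n_bad > 0) {
      warning(n_bad, " malformed JSON cell value(s); affected fields set to missing")
    }
    parsed[match(raw, u)]
  }
  meta <- parse_unique(meta_raw)
  method <- parse_unique(method_raw)

  subject_id <- vapply(meta, .chr_or_na, character(1), key = "subject.id")
  replica_id <- vapply(meta, .chr_or_na, character(1), key = "replica.id")
  phenotype <- vapply(meta, .chr_or_na, character(1), key = "cell.subset")
  freq_raw <- vapply(method, .chr_or_na, character(1), key = "frequency")
  freq <- parse_frequency(freq_raw)

  mhc_raw <- col("mhc.a")
  mhc_group <- suppressWarnings(normalize_mhc_group(mhc_raw))
  attr(mhc_group, "unparseable") <- NULL
  mhc_class <- toupper(ifelse(is.na(col("mhc.class")), "", col("mhc.class")))
  mhc_class <- dplyr::case_when(
    grepl("II", mhc_class) ~ "II",
    grepl("I", mhc_class) ~ "I",
    TRUE ~ NA_character_)

  complex_id <- suppressWarnings(as.integer(col("complex.id")))
  complex_id[is.na(complex_id)] <- 0L

  tibble::tibble(
    chain = tab$gene,
    cdr3_aa = toupper(tab$cdr3),
    cdr3_nt = col("cdr3.nt"),
    v_gene = col("v.segm"),
    j_gene = col("j.segm"),
    v_subgroup = normalize_gene_subgroup(col("v.segm")),
    j_subgroup = normalize_gene_subgroup(col("j.segm")),
    mhc_allele = mhc_raw,
    mhc_allele_group = as.character(mhc_group),
    mhc_class = mhc_class,
    epitope = tab$antigen.epitope,
    epitope_species = col("antigen.species"),
    subject_id = subject_id,
    replica_id = replica_id,
    subject_key = build_subject_key(subject_id, replica_id, tab$antigen.epitope,
                                    col("reference.id"), freq$frequency_denominator),
    frequency_pct = freq$frequency_pct,
    frequency_denominator = freq$frequency_denominator,
    phenotype = phenotype,
    complex_id = complex_id,
    reference = col("reference.id"))
}

#' Write clonotype records back to the VDJdb dialect
#'
#' Inverse of [parse_vdjdb()] for round-tripping: re-emits the tab-separated
#' dialect with JSON `meta`/`method` cells built from the record fields.
#' Frequencies are written as percent strings.
#'
#' @param records Tibble of clonotype records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vdjdb <- function(records, path) {
  jchr <- function(x) ifelse(is.na(x), NA_character_,
                             paste0('"', gsub('"', '\\\\"', x), '"'))
  obj <- function(...) {
    kv <- list(...)
    parts <- lapply(names(kv), function(k) {
      v <- kv[[k]]
      ifelse(is.na(v), NA_character_, paste0('"', k, '": ', v))
    })
    body <- do.call(function(...) {
      m <- cbind(...)
      apply(m, 1, function(r) paste(r[!is.na(r)], collapse = ", "))
    }, parts)
    paste0("{", body, "}")
  }
  meta <- obj("subject.id" = jchr(records$subject_id),
              "replica.id" = jchr(records$replica_id),
              "cell.subset" = jchr(records$phenotype))
  freq_str <- ifelse(is.na(records$frequency_pct), NA_character_,
                     paste0(format(records$frequency_pct, trim = TRUE,
                                   scientific = FALSE, digits = 12), "%"))
  method <- obj("frequency" = jchr(freq_str))
  out <- tibble::tibble(
    "complex.id" = records$complex_id,
    gene = records$chain,
    cdr3 = records$cdr3_aa,
    "v.segm" = records$v_gene,
    "j.segm" = records$j_gene,
    species = "HomoSapiens",
    "mhc.a" = records$mhc_allele,
    "mhc.class" = paste0("MHC", ifelse(is.na(records$mhc_class), "I", records$mhc_class)),
    "antigen.epitope" = records$epitope,
    "antigen.species" = records$epitope_species,
    "reference.id" = records$reference,
    meta = meta,
    method = method)
  if ("cdr3_nt" %in% names(records) && any(!is.na(records$cdr3_nt))) {
    out[["cdr3.nt"]] <- records$cdr3_nt
  }
  readr::write_tsv(out, path, escape = "none", progress = FALSE)
  invisible(path)
}

#' Apply the study inclusion filters
#'
#' Removes, in order of precedence: naive-phenotype records (cell subset
#' annotated with both `CD45RA+` and `CCR7+`, order-insensitive), records
#' with missing frequency (their dominance cannot be determined), and
#' non-CD8 records. A record is considered CD8 if its subset annotation
#' contains `"CD8"`; records with no subset annotation are kept by default
#' (the study removed CD4 records rather than requiring positive CD8
#' evidence) unless `strict_cd8 = TRUE`.
#'
#' @param records Tibble of clonotype records.
#' @param strict_cd8 Drop records with no subset annotation as well.
#' @return A list with `records` (kept rows, original order) and `tally`, a
#'   tibble of rejection counts per reason (`naive`, `no_freq`, `not_cd8`).
#' @export
filter_records <- function(records, strict_cd8 = FALSE) {
  ph <- ifelse(is.na(records$phenotype), "", records$phenotype)
  naive <- grepl("CD45RA\\+", ph) & grepl("CCR7\\+", ph)
  no_freq <- !naive & is.na(records$frequency_pct)
  has_cd8 <- grepl("CD8", ph)
  has_cd4 <- grepl("CD4(?!5)", ph, perl = TRUE)
  not_cd8 <- if (strict_cd8) !has_cd8 else (has_cd4 & !has_cd8)
  not_cd8 <- !naive & !no_freq & not_cd8
  keep <- !(naive | no_freq | not_cd8)
  tally <- tibble::tibble(
    reason = c("naive", "no_freq", "not_cd8"),
    n = c(sum(naive), sum(no_freq), sum(not_cd8)))
  list(records = records[keep, , drop = FALSE], tally = tally)
}

#' Match paired alpha/beta chains
#'
#' Pairs each TRA record with the TRB record sharing its nonzero
#' `complex_id` and epitope. Records with `complex_id` 0 (the unpaired
#' sentinel) are ignored; a pairing key carrying two records of the same
#' chain is skipped with a warning; each record appears in at most one pair.
#'
#' @param records Tibble of clonotype records.
#' @return A tibble with one row per pair, columns prefixed `alpha_` and
#'   `beta_`.
#' @export
match_paired_chains <- function(records) {
  cand <- records[records$complex_id != 0 & records$chain %in% c("TRA", "TRB"), ,
                  drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(alpha_cdr3 = character(), beta_cdr3 = character(),
                          epitope = character(), complex_id = integer()))
  }
  key <- paste(cand$complex_id, cand$epitope, sep = "\r")
  pairs <- lapply(split(seq_len(nrow(cand)), key), function(idx) {
    sub <- cand[idx, , drop = FALSE]
    a <- which(sub$chain == "TRA")
    b <- which(sub$chain == "TRB")
    if (length(a) > 1 || length(b) > 1) {
      warning("complex.id ", sub$complex_id[1],
              " has multiple records of one chain; pair skipped")
      return(NULL)
    }
    if (length(a) != 1 || length(b) != 1) return(NULL)
    tibble::tibble(
      complex_id = sub$complex_id[1],
      epitope = sub$epitope[1],
      mhc_allele_group = sub$mhc_allele_group[1],
      alpha_cdr3 = sub$cdr3_aa[a],
      beta_cdr3 = sub$cdr3_aa[b],
      alpha_v = sub$v_subgroup[a], alpha_j = sub$j_subgroup[a],
      beta_v = sub$v_subgroup[b], beta_j = sub$j_subgroup[b])
  })
  out <- dplyr::bind_rows(pairs)
  out[order(out$complex_id), , drop = FALSE]
}
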