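#' Collapse repeated measurements and rescale over-unity subjects
#'
#' Within each subject (composite subject key), repeated measurements of
#' the same CDR3 are collapsed to a single record so that every clonotype
#' is counted once per individual. If the collapsed frequencies still sum
#' to more than 100 percent the subject's frequencies are rescaled
#' proportionally to sum to 100; every rescale is reported via a message.
#'
#' @param records Tibble of clonotype records carrying `subject_key`,
#'   `cdr3_aa` and `frequency_pct`.
#' @param keep One of `"max"` (default) or `"mean"`: which frequency to
#'   retain when collapsing repeated measurements.
#' @return The deduplicated (and possibly rescaled) records.
#' @export
deduplicate_and_rescale <- function(records, keep = c("max", "mean")) {
  keep <- match.arg(keep)
  stopifnot(all(c("subject_key", "cdr3_aa", "frequency_pct") %in% names(records)))
  agg <- if (keep == "max") max else mean
  out <- records |>
    dplyr::group_by(.data$subject_key, .data$cdr3_aa) |>
    dplyr::mutate(.keep_freq = agg(.data$frequency_pct)) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(frequency_pct = .data$.keep_freq, .keep_freq = NULL)
  sums <- tapply(out$frequency_pct, out$subject_key, sum)
  over <- names(sums)[!is.na(sums) & sums > 100]
  if (length(over) > 0) {
    for (s in over) {
      message("rescaling frequencies for subject '", s, "' (sum ",
              format(sums[[s]], digits = 6), "% > 100%)")
    }
    idx <- out$subject_key %in% over
    out$frequency_pct[idx] <-
      out$frequency_pct[idx] * 100 / as.numeric(sums[out$subject_key[idx]])
  }
  out
}

#' Label the immunodominant clone per subject
#'
#' Within each subject the clone(s) with the maximal frequency are labeled
#' `ID` (immunodominant); all others `SD` (subdominant). Ties at the top
#' frequency are all labeled ID. Result is invariant under reordering of
#' the input records.
#'
#' @param records Deduplicated clonotype records.
#' @return The records with an added `label` column (`"ID"`/`"SD"`), sorted
#'   by subject key and decreasing frequency.
#' @export
label_dominance <- function(records) {
  if (nrow(records) == 0) {
    warning("no records to label")
    return(dplyr::mutate(records, label = character(0)))
  }
  out <- records |>
    dplyr::group_by(.data$subject_key) |>
    dplyr::mutate(label = ifelse(.data$frequency_pct >=
                                   max(.data$frequency_pct) - 1e-12,
                                 "ID", "SD")) |>
    dplyr::arrange(dplyr::desc(.data$frequency_pct), .data$cdr3_aa,
                   .by_group = TRUE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_key, dplyr::desc(.data$frequency_pct),
                   .data$cdr3_aa)
  out
}

#' Fraction of sequences observed in both dominance roles
#'
#' Counts, before any overlap removal, the unique CDR3 sequences (within
#' the same epitope and chain stratum) that appear as ID in at least one
#' subject and as SD in at least one subject.
#'
#' @param labels Labeled records from [label_dominance()].
#' @return A list with `count` and `fraction` (count over the number of
#'   unique sequences observed in either role).
#' @export
overlap_fraction <- function(labels) {
  key <- paste(labels$cdr3_aa, labels$epitope, labels$chain, sep = "\r")
  id_keys <- unique(key[labels$label == "ID"])
  sd_keys <- unique(key[labels$label == "SD"])
  both <- intersect(id_keys, sd_keys)
  total <- length(union(id_keys, sd_keys))
  list(count = length(both),
       fraction = if (total == 0) 0 else length(both) / total)
}

#' Finalize the non-overlapping ID and SD sequence pools
#'
#' Applies the rare-clonotype filter (strictly greater than
#' `min_frequency_pct`), removes from the SD pool every CDR3 sequence that
#' was found as an ID response in at least one subject (within the same
#' epitope and chain stratum), and deduplicates sequences within each pool.
#'
#' @param labels Labeled records from [label_dominance()].
#' @param min_frequency_pct Frequency threshold in percent; clones at or
#'   below it are dropped (default 0.01).
#' @return An object of class `dominance_set`: a list with `id_set` and
#'   `sd_set` (tibbles of unique sequences with epitope, MHC group and
#'   chain), `overlap_removed` (count of unique SD sequences deleted),
#'   `per_subject_labels` (the thresholded labeled records) and
#'   `min_frequency_pct`.
#' @export
finalize_sets <- function(labels, min_frequency_pct = 0.01) {
  kept <- labels[!is.na(labels$frequency_pct) &
                   labels$frequency_pct > min_frequency_pct, , drop = FALSE]
  strat_key <- function(d) paste(d$cdr3_aa, d$epitope, d$chain, sep = "\r")
  uniq_pool <- function(d) {
    d |>
      dplyr::distinct(.data$cdr3_aa, .data$epitope, .data$mhc_allele_group,
                      .data$chain)
  }
  id_pool <- uniq_pool(kept[kept$label == "ID", , drop = FALSE])
  sd_pool <- uniq_pool(kept[kept$label == "SD", , drop = FALSE])
  in_id <- strat_key(sd_pool) %in% strat_key(id_pool)
  structure(list(
    id_set = id_pool,
    sd_set = sd_pool[!in_id, , drop = FALSE],
    overlap_removed = sum(in_id),
    per_subject_labels = kept,
    min_frequency_pct = min_frequency_pct), class = "dominance_set")
}

#' @export
print.dominance_set <- function(x, ...) {
  cat("Dominance set (frequency > ", x$min_frequency_pct, "%)\n", sep = "")
  cat("  ID sequences: ", nrow(x$id_set), "\n", sep = "")
  cat("  SD sequences: ", nrow(x$sd_set),
      " (", x$overlap_removed, " removed for appearing as ID elsewhere)\n",
      sep = "")
  invisible(x)
}
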