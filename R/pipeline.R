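#' Run the full immunodominance analysis pipeline
#'
#' Orchestrates ingest, dominance labeling, non-VJ feature extraction,
#' anchored alignment with PPM/pLES enrichment, and the distributional
#' comparisons, per epitope-by-chain stratum plus a pooled stratum.
#' Identical inputs and parameters produce identical outputs.
#'
#' @param input Path to a VDJdb-dialect TSV, or an already-parsed records
#'   tibble from [parse_vdjdb()].
#' @param germline Germline reference tibble (default
#'   [synthetic_germline()]).
#' @param out_dir Optional output directory; when given, the ID/SD sets,
#'   feature table, per-stratum PPM/pLES/logo matrices, the stats table and
#'   a JSON run summary are written there.
#' @param min_frequency_pct Rare-clonotype threshold in percent
#'   (strictly-greater filter; default 0.01).
#' @param interior_min,interior_max Admissible CDR3 interior lengths for
#'   the anchored alignment (defaults 10 and 15).
#' @param cap pLES cap (default 5).
#' @param log_base pLES logarithm base (default 2).
#' @param strict_cd8 Passed to [filter_records()].
#' @param min_stratum_size Minimum ID and SD aligned sequences required to
#'   compute a stratum's enrichment matrices (default 5).
#' @return A list of class `immunodominance_run`: `summary` (counts per
#'   stage), `filter_tally`, `dominance` (the [finalize_sets()] result),
#'   `overlap`, `features`, `composition`, `enrichment` (per-stratum list
#'   of `ppm_id`, `ppm_sd`, `ples`, `logo`, `n_id`, `n_sd`), and `stats`
#'   (long-format comparison table).
#' @export
run_pipeline <- function(input,
                         germline = synthetic_germline(),
                         out_dir = NULL,
                         min_frequency_pct = 0.01,
                         interior_min = 10,
                         interior_max = 15,
                         cap = 5,
                         log_base = 2,
                         strict_cd8 = FALSE,
                         min_stratum_size = 5) {
  records <- if (is.character(input)) parse_vdjdb(input) else input

  flt <- filter_records(records, strict_cd8 = strict_cd8)
  if (nrow(flt$records) == 0) {
    stop("dominance stage: no records remain after filtering")
  }
  dedup <- deduplicate_and_rescale(flt$records)
  labels <- label_dominance(dedup)
  ov <- overlap_fraction(labels)
  dom <- finalize_sets(labels, min_frequency_pct = min_frequency_pct)
  if (nrow(dom$id_set) + nrow(dom$sd_set) == 0) {
    stop("dominance stage: all clones fell below the frequency threshold")
  }

  pools <- dplyr::bind_rows(
    dplyr::mutate(dom$id_set, label = "ID"),
    dplyr::mutate(dom$sd_set, label = "SD"))
  lookup <- dedup |>
    dplyr::distinct(.data$cdr3_aa, .data$epitope, .data$chain,
                    .keep_all = TRUE)
  pools <- dplyr::left_join(
    pools, lookup[, c("cdr3_aa", "epitope", "chain", "v_subgroup",
                      "j_subgroup")],
    by = c("cdr3_aa", "epitope", "chain"))

  regions <- suppressWarnings(
    extract_nonvj_aa(pools$cdr3_aa, pools$v_subgroup, pools$j_subgroup,
                     germline))
  feats <- compute_features(pools$cdr3_aa) |>
    dplyr::mutate(nonvj_length = nchar(regions$nonvj_part)) |>
    dplyr::bind_cols(pools[, c("epitope", "mhc_allele_group", "chain",
                               "label")]) |>
    dplyr::mutate(nonvj_part = regions$nonvj_part)

  composition <- list()
  for (lab in c("ID", "SD")) {
    nv <- feats$nonvj_part[feats$label == lab & !is.na(feats$nonvj_part)]
    if (sum(nchar(nv), na.rm = TRUE) > 0) {
      composition[[paste0("nonvj_", lab)]] <- aa_composition(nv)
    }
  }
  for (ch in unique(pools$chain)) {
    nv <- feats$nonvj_part[feats$chain == ch & !is.na(feats$nonvj_part)]
    if (sum(nchar(nv), na.rm = TRUE) > 0) {
      composition[[paste0("nonvj_", ch)]] <- aa_composition(nv)
    }
  }
  if (all(c("nonvj_TRB", "nonvj_TRA") %in% names(composition))) {
    composition$log_ratio_beta_alpha <- composition_log_ratio(
      composition$nonvj_TRB, composition$nonvj_TRA, cap = cap,
      base = log_base)
  }

  strata <- pools |>
    dplyr::count(.data$epitope, .data$chain) |>
    dplyr::select("epitope", "chain")
  strata <- dplyr::bind_rows(
    strata, tibble::tibble(epitope = "pooled", chain = unique(pools$chain)))
  enrichment <- list()
  for (i in seq_len(nrow(strata))) {
    ep <- strata$epitope[i]; ch <- strata$chain[i]
    sel <- pools$chain == ch & (ep == "pooled" | pools$epitope == ep)
    sub <- pools[sel, , drop = FALSE]
    al_id <- align_cdr3(sub$cdr3_aa[sub$label == "ID"], interior_min,
                        interior_max)
    al_sd <- align_cdr3(sub$cdr3_aa[sub$label == "SD"], interior_min,
                        interior_max)
    n_id <- sum(!is.na(al_id$aligned)); n_sd <- sum(!is.na(al_sd$aligned))
    if (n_id < min_stratum_size || n_sd < min_stratum_size) next
    ppm_id <- compute_ppm(al_id$aligned)
    ppm_sd <- compute_ppm(al_sd$aligned)
    ples <- compute_ples(ppm_id, ppm_sd, cap = cap, base = log_base)
    enrichment[[paste(ep, ch, sep = "|")]] <- list(
      epitope = ep, chain = ch, n_id = n_id, n_sd = n_sd,
      ppm_id = ppm_id, ppm_sd = ppm_sd, ples = ples,
      logo = positive_logo_matrix(ples),
      excluded = al_id$tally + al_sd$tally)
  }

  stats_rows <- list()
  for (ch in unique(pools$chain)) {
    len_id <- feats$length[feats$chain == ch & feats$label == "ID"]
    len_sd <- feats$length[feats$chain == ch & feats$label == "SD"]
    if (length(len_id) >= 2 && length(len_sd) >= 2) {
      for (tst in c("ks", "mw")) {
        stats_rows[[paste("len", ch, tst)]] <-
          dplyr::mutate(compare_lengths(len_id, len_sd, test = tst),
                        comparison = paste0("length_ID_vs_SD_", ch))
      }
      hyd <- compare_lengths(
        feats$hydropathy[feats$chain == ch & feats$label == "ID"],
        feats$hydropathy[feats$chain == ch & feats$label == "SD"],
        test = "mw")
      stats_rows[[paste("hyd", ch)]] <-
        dplyr::mutate(hyd, comparison = paste0("hydropathy_ID_vs_SD_", ch))
    }
  }
  corr <- tryCatch(
    epitope_length_correlation(
      tibble::tibble(epitope_length = nchar(pools$epitope),
                     cdr3_length = nchar(pools$cdr3_aa),
                     mhc_allele_group = pools$mhc_allele_group)),
    error = function(e) NULL)
  stats_tab <- dplyr::bind_rows(stats_rows)

  summary <- list(
    n_input = nrow(records),
    filter_tally = stats::setNames(as.list(flt$tally$n), flt$tally$reason),
    n_after_filter = nrow(flt$records),
    n_after_dedup = nrow(dedup),
    n_subjects = length(unique(dedup$subject_key)),
    n_id = nrow(dom$id_set),
    n_sd = nrow(dom$sd_set),
    overlap_removed = dom$overlap_removed,
    overlap_count = ov$count,
    overlap_fraction = ov$fraction,
    epitope_cdr3_length_rho = if (is.null(corr)) NA_real_ else corr$rho,
    min_frequency_pct = min_frequency_pct,
    interior_min = interior_min, interior_max = interior_max,
    cap = cap, log_base = log_base,
    n_strata_enriched = length(enrichment))

  run <- structure(list(summary = summary, filter_tally = flt$tally,
                        dominance = dom, overlap = ov, features = feats,
                        composition = composition, enrichment = enrichment,
                        stats = stats_tab),
                   class = "immunodominance_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write a pipeline run's outputs to a directory
#'
#' @param run An `immunodominance_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$dominance$id_set, file.path(out_dir, "id_set.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$dominance$sd_set, file.path(out_dir, "sd_set.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$features[, names(run$features) != "nonvj_part"],
                   file.path(out_dir, "features.tsv"), progress = FALSE)
  if (nrow(run$stats) > 0) {
    readr::write_tsv(run$stats, file.path(out_dir, "stats.tsv"),
                     progress = FALSE)
  }
  for (nm in names(run$enrichment)) {
    e <- run$enrichment[[nm]]
    tag <- gsub("[^A-Za-z0-9]+", "_", nm)
    write_matrix_tsv(e$ppm_id, file.path(out_dir, paste0("ppm_id_", tag, ".tsv")))
    write_matrix_tsv(e$ppm_sd, file.path(out_dir, paste0("ppm_sd_", tag, ".tsv")))
    write_matrix_tsv(e$ples, file.path(out_dir, paste0("ples_", tag, ".tsv")))
    write_matrix_tsv(e$logo, file.path(out_dir, paste0("logo_", tag, ".tsv")))
  }
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.immunodominance_run <- function(x, ...) {
  s <- x$summary
  cat("Immunodominance pipeline run\n")
  cat("  input records:     ", s$n_input, "\n")
  cat("  kept after filter: ", s$n_after_filter, "\n")
  cat("  subjects:          ", s$n_subjects, "\n")
  cat("  ID sequences:      ", s$n_id, "\n")
  cat("  SD sequences:      ", s$n_sd, "\n")
  cat("  ID/SD overlap:     ", s$overlap_count,
      sprintf(" (%.2f%%)", 100 * s$overlap_fraction), "\n")
  cat("  enriched strata:   ", s$n_strata_enriched, "\n")
  invisible(x)
}
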