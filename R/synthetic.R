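#' Default epitope panel of the synthetic generator
#'
#' Eight CD8 epitopes (8-11 residues) with their restricting MHC alleles
#' and source species, patterned on the viral epitopes that dominate
#' public epitope-specific TCR data.
#'
#' @return A tibble with columns `epitope`, `mhc`, `species`.
#' @export
default_epitopes <- function() {
  tibble::tribble(
    ~epitope,        ~mhc,           ~species,
    "GILGFVFTL",     "HLA-A*02:01",  "InfluenzaA",
    "NLVPMVATV",     "HLA-A*02:01",  "CMV",
    "GLCTLVAML",     "HLA-A*02:01",  "EBV",
    "RAKFKQLL",      "HLA-B*08:01",  "EBV",
    "FLKEKGGL",      "HLA-B*08:01",  "HIV-1",
    "IPSINVHHY",     "HLA-B*35:01",  "CMV",
    "TPRVTGGGAM",    "HLA-B*07:02",  "CMV",
    "KAFSPEVIPMF",   "HLA-B*57:01",  "HIV-1")
}

# glycine-enriched non-VJ residue distribution (~25% G), with the small
# neutral/polar residues over-represented as seen in junctional regions
.default_insert_probs <- c(
  A = 0.060, C = 0.015, D = 0.050, E = 0.040, F = 0.015,
  G = 0.250, H = 0.015, I = 0.015, K = 0.015, L = 0.070,
  M = 0.015, N = 0.015, P = 0.070, Q = 0.060, R = 0.080,
  S = 0.100, T = 0.070, V = 0.015, W = 0.015, Y = 0.015)

# amino-acid insert length distribution (lengths 0..8); bulk of non-VJ
# lengths falls at 3-6 residues
.default_insert_len_probs <- c(0.02, 0.05, 0.11, 0.22, 0.21, 0.17, 0.11,
                               0.07, 0.04)

#' Configuration of the synthetic repertoire generator
#'
#' Bundles every parameter of the generator: cohort size, epitope panel,
#' germline reference, clone-size law, non-VJ insert model, optional
#' planted positional motif, noise fractions and the seed. The generator
#' is fully deterministic given a config.
#'
#' @param n_subjects Number of subjects (one epitope response each).
#' @param epitopes Tibble of `epitope`, `mhc`, `species` rows; subjects are
#'   assigned epitopes round-robin.
#' @param clones_per_subject Clones per subject response.
#' @param germline Germline reference (default [synthetic_germline()]).
#' @param clone_size_law List: `law = "geometric"`, `ratio` in (0, 1) (the
#'   decay of ranked clone frequencies) and `total_range`, the range in
#'   percent from which each subject's total response frequency is drawn
#'   (sums never exceed 100).
#' @param insert_length_probs Probabilities over insert lengths 0..k-1.
#' @param insert_residue_probs Named residue distribution of inserts
#'   (default glycine-enriched, 25 percent G).
#' @param planted_motif `NULL`, or a list with `residue`, `column`
#'   (interior alignment column, 1..15), `prob_id` and `prob_sd`: the
#'   probability that an ID (resp. SD) clone carries `residue` at that
#'   aligned position. Planting overwrites the residue at the mapped CDR3
#'   position (anchors never touched) and is skipped when the column is a
#'   gap for the clone's length.
#' @param length_correlation Target Spearman correlation between epitope
#'   length and CDR3 length (0 disables the coupling).
#' @param frac_paired Fraction of eligible beta clones that receive a
#'   paired alpha record (shared `complex.id`).
#' @param frac_alpha_longer Among paired clones, probability that the
#'   alpha CDR3 is strictly longer than the beta CDR3.
#' @param frac_naive_phenotype Fraction of extra naive-phenotype
#'   (CD45RA+CCR7+) rows injected, relative to the clone rows.
#' @param frac_missing_fields Per-row probability that one of subject id,
#'   replica id or frequency is deleted from the JSON metadata.
#' @param frac_duplicated_measurements Per-row probability that a clone's
#'   measurement is duplicated (identical CDR3 and frequency).
#' @param naive_pool_size Rows in [generate_naive_pool()].
#' @param naive_insert_nt_probs Probabilities over nucleotide insert
#'   lengths 0..k-1 for the naive pool.
#' @param naive_g_fraction Guanine fraction of naive nucleotide inserts.
#' @param seed Integer seed.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_subjects = 30,
                             epitopes = default_epitopes(),
                             clones_per_subject = 15,
                             germline = synthetic_germline(),
                             clone_size_law = list(law = "geometric",
                                                   ratio = 0.65,
                                                   total_range = c(50, 95)),
                             insert_length_probs = .default_insert_len_probs,
                             insert_residue_probs = .default_insert_probs,
                             planted_motif = NULL,
                             length_correlation = 0,
                             frac_paired = 0,
                             frac_alpha_longer = 0.3,
                             frac_naive_phenotype = 0,
                             frac_missing_fields = 0,
                             frac_duplicated_measurements = 0,
                             naive_pool_size = 1000,
                             naive_insert_nt_probs = rep(1 / 13, 13),
                             naive_g_fraction = 0.4,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, clones_per_subject >= 1, nrow(epitopes) >= 1)
  if (nrow(germline) == 0) stop("germline table must be non-empty")
  if (!identical(clone_size_law$law, "geometric")) {
    stop("unsupported clone_size_law: ", clone_size_law$law)
  }
  if (!is.numeric(clone_size_law$ratio) || clone_size_law$ratio <= 0 ||
      clone_size_law$ratio >= 1) {
    stop("clone_size_law$ratio must lie in (0, 1), got ",
         clone_size_law$ratio)
  }
  tr <- clone_size_law$total_range
  if (length(tr) != 2 || any(tr <= 0) || any(tr > 100) || tr[1] > tr[2]) {
    stop("clone_size_law$total_range must be within (0, 100]")
  }
  for (f in c("frac_paired", "frac_alpha_longer", "frac_naive_phenotype",
              "frac_missing_fields", "frac_duplicated_measurements",
              "naive_g_fraction")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (abs(length_correlation) > 0.9) stop("length_correlation must be in [-0.9, 0.9]")
  if (!is.null(planted_motif)) {
    stopifnot(planted_motif$residue %in% AA20,
              planted_motif$column >= 1, planted_motif$column <= 15,
              planted_motif$prob_id >= 0, planted_motif$prob_id <= 1,
              planted_motif$prob_sd >= 0, planted_motif$prob_sd <= 1)
  }
  fields <- names(formals(synthetic_config))
  structure(mget(fields, envir = environment()), class = "synthetic_config")
}

# sample from a discrete length distribution via uniform quantiles
.q_discrete <- function(u, probs) {
  findInterval(u, cumsum(probs) / sum(probs), left.open = TRUE)
}

# map an interior alignment column (1..15) to the interior residue index
# of a sequence with interior length n; NA when the column is a gap
.column_to_interior_index <- function(column, n, interior_max = 15) {
  left <- ceiling(n / 2)
  idx <- rep(NA_integer_, length(n))
  lhs <- column <= left
  idx[lhs] <- column
  rhs <- !lhs & column > interior_max - (n - left)
  idx[rhs] <- n[rhs] - (interior_max - column)
  idx
}

#' Generate a synthetic epitope-specific clonotype table with ground truth
#'
#' Builds a VDJdb-dialect table of per-subject epitope responses: each
#' subject carries a geometric ranked frequency spectrum (the rank-1 clone
#' is the intended immunodominant response), CDR3s composed of germline V
#' prefix + random non-VJ insert + germline J suffix, JSON-embedded subject
#' metadata, and both frequency dialects (`"x/y"` fractions for
#' even-numbered subjects, percent strings for odd). Noise — naive
#' phenotype rows, missing JSON fields, duplicated measurements — is
#' injected at the configured fractions. The truth table records, per
#' clone, the intended region boundaries, frequency, dominance and
#' motif-planting status.
#'
#' @param config A [synthetic_config()].
#' @return A list with `table` (VDJdb-dialect tibble, ready to write with
#'   [write_clonotype_tsv()]) and `truth` (one row per generated clone).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  germ <- config$germline
  vb <- germ[germ$region == "V" & germ$chain == "TRB", ]
  jb <- germ[germ$region == "J" & germ$chain == "TRB", ]
  va <- germ[germ$region == "V" & germ$chain == "TRA", ]
  ja <- germ[germ$region == "J" & germ$chain == "TRA", ]
  if (nrow(vb) == 0 || nrow(jb) == 0) stop("germline table lacks TRB V or J genes")

  ns <- config$n_subjects
  m <- config$clones_per_subject
  epi <- config$epitopes[((seq_len(ns) - 1) %% nrow(config$epitopes)) + 1, ]
  refs <- paste0("PMID:10000", ((seq_len(ns) - 1) %% 3) + 1)
  dialect <- ifelse(seq_len(ns) %% 2 == 0, "frac", "pct")

  # ranked geometric frequencies per subject, total drawn <= 100%
  w <- config$clone_size_law$ratio^(seq_len(m) - 1)
  totals <- stats::runif(ns, config$clone_size_law$total_range[1],
                         config$clone_size_law$total_range[2])
  freq <- as.vector(outer(w / sum(w), totals))      # m x ns, column-major
  subj <- rep(seq_len(ns), each = m)
  rank <- rep(seq_len(m), times = ns)
  n_cl <- ns * m

  vi <- sample.int(nrow(vb), n_cl, replace = TRUE)
  ji <- sample.int(nrow(jb), n_cl, replace = TRUE)

  epi_len <- nchar(epi$epitope)[subj]
  base_len <- nchar(vb$aa_seq)[vi] + nchar(jb$aa_seq)[ji]
  if (config$length_correlation != 0) {
    # Gaussian copula between epitope length and total CDR3 length: the
    # insert length is conditioned on the clone's germline base length so
    # that V/J length variation does not dilute the coupling; residual
    # attenuation comes only from the discreteness (ties) of both lengths
    rho <- 2 * sin(pi * config$length_correlation / 6)
    ze <- (epi_len - mean(epi_len)) / max(stats::sd(epi_len), 1e-9)
    u <- stats::pnorm(rho * ze + sqrt(1 - rho^2) * stats::rnorm(n_cl))
    p_ins <- config$insert_length_probs / sum(config$insert_length_probs)
    k_max <- length(p_ins) - 1L
    tot_support <- (min(base_len)):(max(base_len) + k_max)
    tot_pmf <- vapply(tot_support, function(t) {
      k <- t - base_len
      ok <- k >= 0 & k <= k_max
      sum(p_ins[k[ok] + 1]) / length(base_len)
    }, numeric(1))
    tot_cdf <- cumsum(tot_pmf)
    target_tot <- tot_support[findInterval(u, tot_cdf, left.open = TRUE) + 1L]
    ins_len <- pmin(pmax(target_tot - base_len, 0L), k_max)
  } else {
    ins_len <- .q_discrete(stats::runif(n_cl), config$insert_length_probs)
  }

  draw_insert <- function(len) {
    res <- names(config$insert_residue_probs)
    vapply(len, function(L) {
      if (L == 0) "" else paste(sample(res, L, replace = TRUE,
                                       prob = config$insert_residue_probs),
                                collapse = "")
    }, character(1))
  }
  insert <- draw_insert(ins_len)
  v_part <- vb$aa_seq[vi]
  j_part <- jb$aa_seq[ji]
  cdr3 <- paste0(v_part, insert, j_part)

  # enforce CDR3 uniqueness within subject by redrawing colliding inserts
  for (try in 1:25) {
    dup <- duplicated(paste(subj, cdr3, sep = "\r"))
    if (!any(dup)) break
    ins_len[dup] <- .q_discrete(stats::runif(sum(dup)),
                                config$insert_length_probs) + 1L
    insert[dup] <- draw_insert(ins_len[dup])
    cdr3[dup] <- paste0(v_part[dup], insert[dup], j_part[dup])
  }

  planted <- rep(FALSE, n_cl)
  if (!is.null(config$planted_motif)) {
    pm <- config$planted_motif
    p_plant <- ifelse(rank == 1, pm$prob_id, pm$prob_sd)
    want <- stats::runif(n_cl) < p_plant
    idx <- .column_to_interior_index(pm$column, nchar(cdr3) - 2L)
    can <- want & !is.na(idx)
    if (any(can)) {
      pos <- idx[can] + 1L
      s <- cdr3[can]
      substr(s, pos, pos) <- pm$residue
      cdr3[can] <- s
      planted <- can
    }
  }

  truth <- tibble::tibble(
    subject_index = subj,
    subject_id = paste0("S", subj),
    replica_id = "r1",
    epitope = epi$epitope[subj],
    mhc = epi$mhc[subj],
    epitope_species = epi$species[subj],
    reference = refs[subj],
    chain = "TRB",
    rank = rank,
    cdr3_aa = cdr3,
    v_gene = vb$gene[vi],
    j_gene = jb$gene[ji],
    v_part = v_part,
    insert = insert,
    j_part = j_part,
    frequency_pct = freq,
    is_id = rank == 1,
    planted = planted,
    dialect = dialect[subj])
  truth$subject_key <- build_subject_key(
    truth$subject_id, truth$replica_id, truth$epitope, truth$reference,
    ifelse(truth$dialect == "frac", "1000000", NA_character_))

  # paired alpha records for a fraction of eligible beta clones
  alpha <- NULL
  complex_id <- rep(0L, n_cl)
  if (config$frac_paired > 0 && nrow(va) > 0 && nrow(ja) > 0) {
    base_grid <- expand.grid(v = seq_len(nrow(va)), j = seq_len(nrow(ja)))
    base_len <- nchar(va$aa_seq)[base_grid$v] + nchar(ja$aa_seq)[base_grid$j]
    min_base <- min(base_len)
    eligible <- which(nchar(cdr3) >= min_base + 1)
    take <- eligible[stats::runif(length(eligible)) < config$frac_paired]
    if (length(take) > 0) {
      complex_id[take] <- seq_along(take)
      beta_len <- nchar(cdr3[take])
      longer <- stats::runif(length(take)) < config$frac_alpha_longer
      a_len <- integer(length(take))
      a_len[longer] <- beta_len[longer] +
        sample(1:2, sum(longer), replace = TRUE)
      if (any(!longer)) {
        a_len[!longer] <- pmax(min_base,
                               beta_len[!longer] -
                                 sample(0:2, sum(!longer), replace = TRUE))
      }
      a_len <- pmax(a_len, min_base)
      combo <- vapply(a_len, function(L) {
        ok <- which(base_len <= L)
        ok[sample.int(length(ok), 1)]
      }, integer(1))
      a_ins_len <- a_len - base_len[combo]
      a_insert <- draw_insert(a_ins_len)
      alpha <- tibble::tibble(
        beta_row = take,
        complex_id = complex_id[take],
        cdr3_aa = paste0(va$aa_seq[base_grid$v[combo]], a_insert,
                         ja$aa_seq[base_grid$j[combo]]),
        v_gene = va$gene[base_grid$v[combo]],
        j_gene = ja$gene[base_grid$j[combo]],
        insert = a_insert,
        alpha_longer = nchar(cdr3_aa) > beta_len)
    }
  }
  truth$complex_id <- complex_id

  # render the VDJdb dialect -------------------------------------------------
  freq_str <- ifelse(
    truth$dialect == "frac",
    paste0(pmax(1, round(truth$frequency_pct / 100 * 1e6)), "/1000000"),
    paste0(sprintf("%.10g", truth$frequency_pct), "%"))
  render_rows <- function(chain, cdr3, v_gene, j_gene, subj_idx, complex_id,
                          freq_str, subset) {
    tibble::tibble(
      "complex.id" = complex_id,
      gene = chain,
      cdr3 = cdr3,
      "v.segm" = paste0(v_gene, "*01"),
      "j.segm" = paste0(j_gene, "*01"),
      species = "HomoSapiens",
      "mhc.a" = epi$mhc[subj_idx],
      "mhc.class" = "MHCI",
      "antigen.epitope" = epi$epitope[subj_idx],
      "antigen.species" = epi$species[subj_idx],
      "reference.id" = refs[subj_idx],
      subject_id = paste0("S", subj_idx),
      replica_id = "r1",
      subset = subset,
      freq_str = freq_str)
  }
  rows <- render_rows("TRB", truth$cdr3_aa, truth$v_gene, truth$j_gene,
                      subj, truth$complex_id, freq_str, "CD8+")
  if (!is.null(alpha)) {
    rows <- dplyr::bind_rows(
      rows,
      render_rows("TRA", alpha$cdr3_aa, alpha$v_gene, alpha$j_gene,
                  subj[alpha$beta_row], alpha$complex_id,
                  freq_str[alpha$beta_row], "CD8+"))
  }

  # duplicated measurements
  if (config$frac_duplicated_measurements > 0) {
    dup <- stats::runif(nrow(rows)) < config$frac_duplicated_measurements
    rows <- dplyr::bind_rows(rows, rows[dup, , drop = FALSE])
  }
  # extra naive-phenotype rows (filtered out downstream)
  n_naive <- round(config$frac_naive_phenotype * nrow(rows))
  if (n_naive > 0) {
    src <- rows[sample.int(nrow(rows), n_naive, replace = TRUE), , drop = FALSE]
    src$subset <- "Naive, CD45RA+CCR7+"
    src$`complex.id` <- 0L
    rows <- dplyr::bind_rows(rows, src)
  }
  # missing-field noise: delete a JSON key, not blank it
  drop_subject <- drop_replica <- drop_freq <- rep(FALSE, nrow(rows))
  if (config$frac_missing_fields > 0) {
    hit <- stats::runif(nrow(rows)) < config$frac_missing_fields
    which_field <- sample(1:3, nrow(rows), replace = TRUE)
    drop_subject <- hit & which_field == 1
    drop_replica <- hit & which_field == 2
    drop_freq <- hit & which_field == 3
  }
  meta_json <- paste0(
    "{",
    ifelse(drop_subject, "",
           paste0('"subject.id": "', rows$subject_id, '", ')),
    ifelse(drop_replica, "",
           paste0('"replica.id": "', rows$replica_id, '", ')),
    '"cell.subset": "', rows$subset, '"}')
  method_json <- ifelse(
    drop_freq, '{"identification": "tetramer-sort"}',
    paste0('{"frequency": "', rows$freq_str,
           '", "identification": "tetramer-sort"}'))
  table <- rows |>
    dplyr::mutate(meta = meta_json, method = method_json,
                  subject_id = NULL, replica_id = NULL, subset = NULL,
                  freq_str = NULL)
  list(table = table, truth = truth,
       alpha_truth = alpha)
}

#' Write a clonotype table in the raw TSV dialect
#'
#' Tab-separated with a header row and unescaped JSON cells (the dialect
#' of VDJdb exports); use this rather than `readr::write_tsv()`, which
#' would double the quotes inside the JSON columns.
#'
#' @param table A tibble such as the `table` from [generate_repertoire()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clonotype_tsv <- function(table, path) {
  readr::write_tsv(table, path, escape = "none", progress = FALSE)
  invisible(path)
}

#' Generate a naive T-cell nucleotide clonotype pool with ground truth
#'
#' Emits nucleotide-level CDR3s (germline V segment + random insert +
#' germline J segment) for both chains, with guanine-enriched inserts and
#' absolute read counts of at least 1, plus a truth table of the exact
#' insert boundaries.
#'
#' @param config A [synthetic_config()] whose germline table carries
#'   `nt_seq` for all genes.
#' @return A list with `table` (columns `chain`, `cdr3_nt`, `v_gene`,
#'   `j_gene`, `count`) and `truth` (insert boundaries per row).
#' @export
generate_naive_pool <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  germ <- config$germline
  if (!"nt_seq" %in% names(germ) || anyNA(germ$nt_seq)) {
    stop("germline table lacks nucleotide segments")
  }
  set.seed(config$seed + 1L)
  n <- config$naive_pool_size
  chain <- rep(c("TRB", "TRA"), length.out = n)
  out <- lapply(c("TRB", "TRA"), function(ch) {
    idx <- which(chain == ch)
    if (length(idx) == 0) return(NULL)
    vg <- germ[germ$region == "V" & germ$chain == ch, ]
    jg <- germ[germ$region == "J" & germ$chain == ch, ]
    vi <- sample.int(nrow(vg), length(idx), replace = TRUE)
    ji <- sample.int(nrow(jg), length(idx), replace = TRUE)
    len <- .q_discrete(stats::runif(length(idx)), config$naive_insert_nt_probs)
    gfrac <- config$naive_g_fraction
    probs <- c(a = (1 - gfrac) / 3, c = (1 - gfrac) / 3, g = gfrac,
               t = (1 - gfrac) / 3)
    ins <- vapply(len, function(L) {
      if (L == 0) "" else paste(sample(names(probs), L, replace = TRUE,
                                       prob = probs), collapse = "")
    }, character(1))
    tibble::tibble(
      chain = ch,
      cdr3_nt = paste0(vg$nt_seq[vi], ins, jg$nt_seq[ji]),
      v_gene = vg$gene[vi],
      j_gene = jg$gene[ji],
      count = 1L + stats::rpois(length(idx), 2),
      v_nt = vg$nt_seq[vi],
      insert_nt = ins,
      j_nt = jg$nt_seq[ji])
  })
  all <- dplyr::bind_rows(out)
  list(table = all[, c("chain", "cdr3_nt", "v_gene", "j_gene", "count")],
       truth = all[, c("chain", "cdr3_nt", "v_gene", "j_gene", "v_nt",
                       "insert_nt", "j_nt")])
}
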