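.comparison_result <- function(test, statistic, p_value, n_a, n_b,
                               alpha = 0.05, note = NA_character_) {
  tibble::tibble(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n_a = n_a, n_b = n_b,
                 alpha = alpha,
                 significant = !is.na(p_value) & p_value < alpha,
                 note = note)
}

#' Two-sample distribution comparison (KS or Mann-Whitney)
#'
#' Kolmogorov-Smirnov for distribution similarity; two-sided Mann-Whitney
#' (two-sample Wilcoxon) for quantitative shifts such as length or
#' hydropathy.
#'
#' @param group_a,group_b Numeric samples (each of size at least 2).
#' @param test `"ks"` or `"mw"`.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `n_a`, `n_b`,
#'   `alpha`, `significant`.
#' @export
compare_lengths <- function(group_a, group_b, test = c("ks", "mw"),
                            alpha = 0.05) {
  test <- match.arg(test)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each sample must have at least 2 observations")
  }
  res <- if (test == "ks") {
    suppressWarnings(stats::ks.test(group_a, group_b))
  } else {
    suppressWarnings(stats::wilcox.test(group_a, group_b,
                                        alternative = "two.sided"))
  }
  .comparison_result(test, res$statistic, res$p.value,
                     length(group_a), length(group_b), alpha)
}

#' Shapiro-Wilk normality check
#'
#' @param sample Numeric sample, 3 to 5000 observations, non-degenerate.
#' @param alpha Significance level.
#' @return A one-row tibble as in [compare_lengths()] (`n_b` is `NA`).
#' @export
normality_check <- function(sample, alpha = 0.05) {
  n <- length(sample)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (length(unique(sample)) == 1) stop("degenerate sample: all values identical")
  res <- stats::shapiro.test(sample)
  .comparison_result("shapiro_wilk", res$statistic, res$p.value, n, NA_integer_,
                     alpha)
}

#' Spearman correlation between epitope length and CDR3 length
#'
#' Optionally excludes records restricted by a given MHC allele group
#' before correlating (the A*02-restricted responses dominate public data
#' and their epitopes are all 9-mers, which would bias the estimate).
#'
#' @param pairs A data frame with columns `epitope_length`, `cdr3_length`
#'   and optionally `mhc_allele_group`.
#' @param exclude_mhc_group Optional allele group (e.g. `"HLA-A*02"`) whose
#'   records are dropped.
#' @return A list with `rho`, `p_value` and `n`.
#' @export
epitope_length_correlation <- function(pairs, exclude_mhc_group = NULL) {
  if (!is.null(exclude_mhc_group)) {
    pairs <- pairs[is.na(pairs$mhc_allele_group) |
                     pairs$mhc_allele_group != exclude_mhc_group, ,
                   drop = FALSE]
  }
  if (nrow(pairs) < 3) stop("fewer than 3 pairs after exclusion")
  if (length(unique(pairs$epitope_length)) < 2 ||
      length(unique(pairs$cdr3_length)) < 2) {
    stop("degenerate input: a variable is constant, correlation undefined")
  }
  res <- suppressWarnings(
    stats::cor.test(pairs$epitope_length, pairs$cdr3_length,
                    method = "spearman"))
  list(rho = unname(res$estimate), p_value = res$p.value, n = nrow(pairs))
}

#' Length table for paired alpha/beta chains
#'
#' @param pairs Tibble from [match_paired_chains()], optionally with an
#'   `epitope` column.
#' @return A list with `table` (per-pair alpha, beta and combined lengths
#'   plus epitope length) and `frac_alpha_longer`, the fraction of pairs
#'   whose alpha chain is strictly longer than the beta chain.
#' @export
paired_chain_lengths <- function(pairs) {
  if (nrow(pairs) < 1) stop("no pairs")
  tab <- tibble::tibble(
    alpha_length = nchar(pairs$alpha_cdr3),
    beta_length = nchar(pairs$beta_cdr3),
    combined_length = nchar(pairs$alpha_cdr3) + nchar(pairs$beta_cdr3),
    epitope_length = if ("epitope" %in% names(pairs)) nchar(pairs$epitope)
                     else NA_integer_)
  list(table = tab,
       frac_alpha_longer = mean(tab$alpha_length > tab$beta_length))
}

#' k-sample Anderson-Darling test
#'
#' The Scholz-Stephens (1987) rank test that k samples share one
#' (unspecified) continuous distribution, in the midrank version that
#' accommodates ties. The standardized statistic is referred to the
#' published critical-value interpolation to obtain an approximate p-value
#' (floored/capped at 0.001 and 0.25, beyond the tabulated range).
#'
#' @param samples List of 2 or more numeric samples (each of size >= 2).
#' @return A list with `statistic` (standardized), `a2kn` (raw statistic),
#'   `p_value`, `k` and `n` (total observations).
#' @export
ad_ksample <- function(samples) {
  k <- length(samples)
  if (k < 2) stop("need at least 2 samples")
  if (any(vapply(samples, length, 1L) < 2)) {
    stop("each sample must have at least 2 observations")
  }
  ni <- vapply(samples, length, 1L)
  pooled <- sort(unlist(samples, use.names = FALSE))
  n_tot <- length(pooled)
  zstar <- unique(pooled)
  if (length(zstar) < 2) stop("all pooled observations identical")
  # every pooled value is a member of zstar, so findInterval yields its
  # exact index; counting this way avoids any numeric -> character mapping
  lj <- tabulate(findInterval(pooled, zstar), nbins = length(zstar))
  bj <- cumsum(lj) - lj / 2
  a2akn <- 0
  for (i in seq_len(k)) {
    s <- sort(samples[[i]])
    eq <- tabulate(findInterval(s, zstar), nbins = length(zstar))
    mij <- findInterval(zstar, s) - 0.5 * eq
    inner <- lj / n_tot * (n_tot * mij - bj * ni[i])^2 /
      (bj * (n_tot - bj) - n_tot * lj / 4)
    a2akn <- a2akn + sum(inner) / ni[i]
  }
  a2akn <- a2akn * (n_tot - 1) / n_tot

  h_cap <- sum(1 / ni)
  h_small <- sum(1 / seq_len(n_tot - 1))
  # g = sum_{i=1}^{N-2} sum_{j=i+1}^{N-1} 1 / ((N-i) j)
  g <- 0
  for (i in seq_len(n_tot - 2)) {
    g <- g + sum(1 / ((n_tot - i) * seq(i + 1, n_tot - 1)))
  }
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * h_cap
  b <- (2 * g - 4) * k^2 + 8 * h_small * k +
    (2 * g - 14 * h_small - 4) * h_cap - 8 * h_small + 4 * g - 6
  cc <- (6 * h_small + 2 * g - 2) * k^2 +
    (4 * h_small - 4 * g + 6) * k + (2 * h_small - 6) * h_cap + 4 * h_small
  d <- (2 * h_small + 6) * k^2 - 4 * h_small * k
  sigmasq <- (a * n_tot^3 + b * n_tot^2 + cc * n_tot + d) /
    ((n_tot - 1) * (n_tot - 2) * (n_tot - 3))
  m <- k - 1
  tk <- (a2akn - m) / sqrt(sigmasq)

  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  sig <- c(0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001)
  tm <- b0 + b1 / sqrt(m) + b2 / m
  fit <- stats::lm.fit(cbind(1, tm, tm^2), log(sig))
  logp <- sum(fit$coefficients * c(1, tk, tk^2))
  p <- exp(logp)
  p <- min(max(p, 0.001), 0.25)
  if (tk < min(tm)) p <- 0.25
  if (tk > max(tm)) p <- 0.001
  list(statistic = tk, a2kn = a2akn, p_value = p, k = k, n = n_tot)
}

#' Composition similarity across groups (Anderson-Darling k-sample)
#'
#' Tests whether two or more samples (e.g. per-epitope residue-level
#' observations) share one distribution, via [ad_ksample()].
#'
#' @param groups List of 2 or more numeric samples.
#' @param alpha Significance level.
#' @return A one-row tibble as in [compare_lengths()], with `n_a` the
#'   number of groups and `n_b` the total observations.
#' @export
composition_similarity <- function(groups, alpha = 0.05) {
  res <- ad_ksample(groups)
  .comparison_result("anderson_darling_k", res$statistic, res$p_value,
                     res$k, res$n, alpha)
}

#' Render p-values with the non-significance suppression convention
#'
#' P-values above the threshold are rendered as `"ns"` in display output
#' (machine-readable tables always keep the numeric value).
#'
#' @param p Numeric vector of p-values.
#' @param threshold Suppression threshold (default 0.05).
#' @return Character vector.
#' @export
format_p_display <- function(p, threshold = 0.05) {
  ifelse(is.na(p), NA_character_,
         ifelse(p > threshold, "ns", format.pval(p, digits = 3)))
}
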