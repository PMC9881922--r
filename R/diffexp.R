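#' Per-cell size factors
#'
#' Ratio of each cell's total count to the geometric mean of all totals.
#'
#' @param counts Cells x genes count matrix (sparse or dense).
#' @return Positive numeric vector, one per cell.
#' @export
size_factors <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) stop_bad_arg("cells with zero totals have no size factor")
  totals / geometric_mean(totals)
}

#' Estimate shrunken negative-binomial dispersions
#'
#' Per-gene raw dispersions come from the method of moments on
#' size-factor-scaled counts (floored at zero): with `y = k / s`,
#' `E y = mu` and `Var y_i = mu / s_i + phi mu^2`, so
#' `phi_hat = (S^2 - mu_hat * mean(1/s)) / mu_hat^2`. The common dispersion
#' is the mean of the raw values and each gene's estimate is shrunk toward
#' it: `phi_tilde = delta * common + (1 - delta) * phi_hat`, with the
#' shrinkage weight `delta` from a mean-squared-error plug-in,
#' `delta = [sum (phi_hat - mean)^2 / (G-1)] / [sum (phi_hat - target)^2 /
#' (G-2)]` clipped to `[0, 1]`. With the target at the mean this shrinks
#' nearly fully toward the common value — the strong shrinkage regime that
#' suits shallow single-cell groups; with a single gene `delta = 1` and the
#' shrunken value equals the raw value.
#'
#' @param counts Cells x genes count matrix.
#' @param groups Two-level factor/character vector, one per cell.
#' @param sf Size factors (default recomputed from `counts`).
#' @return An object of class `dispersion_model`: list with tibble
#'   `dispersions` (`gene_id`, `raw`, `shrunken`), `common`, `delta`.
#' @export
estimate_dispersion <- function(counts, groups, sf = size_factors(counts)) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop_bad_arg("exactly two groups required")
  if (any(table(groups) < 2L)) stop_bad_arg("each group needs >= 2 cells")
  if (any(sf <= 0)) stop_bad_arg("size factors must be positive")
  y <- counts / sf
  mu <- Matrix::colMeans(y)
  s2 <- col_vars_any(y) * nrow(y) / (nrow(y) - 1)
  raw <- pmax((s2 - mu * mean(1 / sf)) / mu ^ 2, 0)
  raw[!is.finite(raw)] <- 0
  g <- length(raw)
  common <- mean(raw)
  delta <- if (g <= 2L) 1 else {
    num <- sum((raw - mean(raw)) ^ 2) / (g - 1)
    den <- sum((raw - common) ^ 2) / (g - 2)
    if (den == 0) 1 else min(1, max(0, num / den))
  }
  shrunken <- delta * common + (1 - delta) * raw
  structure(
    list(dispersions = tibble(
      gene_id = colnames(counts) %||% sprintf("gene_%05d", seq_len(g)),
      raw = unname(raw), shrunken = unname(shrunken)),
      common = common, delta = delta),
    class = "dispersion_model")
}

col_vars_any <- function(m) {
  if (inherits(m, "Matrix")) col_vars_sparse(m) else col_vars_dense(as.matrix(m))
}

#' @exportS3Method base::print
print.dispersion_model <- function(x, ...) {
  cat("<dispersion_model> ", nrow(x$dispersions), " genes; common = ",
      signif(x$common, 4), ", delta = ", signif(x$delta, 4), "\n", sep = "")
  invisible(x)
}

#' Negative-binomial test for differential expression between two groups
#'
#' Tests equal means per gene under a negative-binomial model with shrunken
#' dispersion. Genes whose total count across both groups is at most
#' `exact_threshold` use an exact conditional test: conditional on the
#' total, the group-A sum is compared against its distribution under the
#' null (group sums approximated as NB with summed means and sizes), summing
#' the probabilities of all outcomes no more likely than the observed one.
#' Above the threshold a Wald test on the log ratio of size-factor-scaled
#' group sums is used, with the null variance from the NB moments. The
#' reported fold-change is `log2(((1 + K_A) / (1 + K_B)) * (S_B / S_A))`
#' where `K` are group count sums and `S` group size-factor sums (the
#' droplet-toolchain convention; the pseudocount acts on group sums and is
#' negligible for expressed genes). Significance is called at
#' `|log2 FC| > 2` and `FDR < 0.05`; genes with zero counts in both groups
#' are flagged untestable (`p = 1`, excluded from the BH multiplicity
#' count).
#'
#' @param counts Cells x genes count matrix.
#' @param groups Two-level vector, one per cell; fold-changes are A vs. B
#'   with A the first level encountered (or factor level order).
#' @param dispersion A `dispersion_model` from [estimate_dispersion()].
#' @param sf Size factors.
#' @param exact_threshold Total-count cutoff for the exact conditional test.
#' @param lfc_threshold,fdr_threshold Call thresholds (defaults
#'   `|log2 FC| > 2`, FDR < 0.05).
#' @param contrast Optional contrast description string carried through.
#' @return A `de_result` tibble: `gene_id`, `log2_fc`, `p_value`, `fdr`,
#'   `significant`, `untestable`, `mean_a`, `mean_b`, `contrast`.
#' @export
nb_test <- function(counts, groups, dispersion = NULL,
                    sf = size_factors(counts), exact_threshold = 100L,
                    lfc_threshold = 2, fdr_threshold = 0.05,
                    contrast = NA_character_) {
  groups <- if (is.factor(groups)) groups else factor(groups,
                                                      levels = unique(groups))
  lv <- levels(groups)
  if (length(lv) != 2L) stop_bad_arg("exactly two groups required")
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, groups, sf)
  }
  phi <- dispersion$dispersions$shrunken
  a <- groups == lv[1]
  b <- !a
  ka <- Matrix::colSums(counts[a, , drop = FALSE])
  kb <- Matrix::colSums(counts[b, , drop = FALSE])
  s_a <- sum(sf[a]); s_b <- sum(sf[b])
  s2_a <- sum(sf[a] ^ 2); s2_b <- sum(sf[b] ^ 2)
  total <- ka + kb
  q0 <- total / (s_a + s_b)
  log2_fc <- log2(((1 + ka) / (1 + kb)) * (s_b / s_a))
  p <- rep(1, length(total))

  wald <- total > exact_threshold
  if (any(wald)) {
    qw <- q0[wald]; pw <- phi[wald]
    var_la <- (qw * s_a + pw * qw ^ 2 * s2_a) / (qw * s_a) ^ 2
    var_lb <- (qw * s_b + pw * qw ^ 2 * s2_b) / (qw * s_b) ^ 2
    z <- (log((ka[wald] + 0.5) / s_a) - log((kb[wald] + 0.5) / s_b)) /
      sqrt(var_la + var_lb)
    p[wald] <- 2 * pnorm(-abs(z))
  }
  exact <- which(!wald & total > 0)
  n_a <- sum(a); n_b <- sum(b)
  for (j in exact) {
    p[j] <- nb_exact_p(ka[j], total[j], q0[j], phi[j],
                       s_a, s_b, n_a, n_b)
  }
  untestable <- total == 0
  fdr <- rep(NA_real_, length(p))
  fdr[!untestable] <- bh_adjust(p[!untestable])
  fdr[untestable] <- 1
  res <- tibble(
    gene_id = colnames(counts) %||% sprintf("gene_%05d", seq_along(p)),
    log2_fc = unname(ifelse(untestable, 0, log2_fc)),
    p_value = unname(p), fdr = unname(fdr),
    significant = unname(!untestable & abs(log2_fc) > lfc_threshold &
                           fdr < fdr_threshold),
    untestable = unname(untestable),
    mean_a = unname(ka / s_a), mean_b = unname(kb / s_b),
    contrast = contrast)
  class(res) <- c("de_result", class(res))
  res
}

# Exact conditional two-sided NB test: group sums approximated as
# NB(mu = q*S_g, size = n_g / phi); p is the total probability of outcomes
# k (given the observed total) no more likely than the observed split.
nb_exact_p <- function(k_a, total, q, phi, s_a, s_b, n_a, n_b) {
  size_a <- if (phi > 0) n_a / phi else Inf
  size_b <- if (phi > 0) n_b / phi else Inf
  k <- 0:total
  lp <- if (is.finite(size_a)) {
    dnbinom(k, size = size_a, mu = q * s_a, log = TRUE) +
      dnbinom(total - k, size = size_b, mu = q * s_b, log = TRUE)
  } else {
    stats::dpois(k, lambda = q * s_a, log = TRUE) +
      stats::dpois(total - k, lambda = q * s_b, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  sum(pr[pr <= pr[k_a + 1] * (1 + 1e-8)]) / sum(pr)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control with monotonicity
#' enforcement; invariant under permutation of the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return FDR (q-)values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_bad_arg("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify condition responses across cell types
#'
#' Given per-cell-type differential-expression tables for the same
#' condition contrast, classifies each gene by where it responds:
#' `hepatocyte_only`, `npc_only`, `both` or `none`, with hepatocyte vs.
#' non-parenchymal (NPC) cell types supplied by the caller. Summary
#' fractions per biotype are attached as attribute `summary`.
#'
#' @param de_tables Named list of `de_result` tibbles, one per cell type.
#' @param hepatocyte_types Character vector naming which list entries are
#'   hepatocyte populations; the rest are NPCs.
#' @param biotypes Optional tibble `gene_id`, `biotype` to stratify the
#'   summary.
#' @return Tibble `gene_id`, `class`, `n_hep_sig`, `n_npc_sig` (+
#'   `biotype`), with attribute `summary`.
#' @export
classify_responses <- function(de_tables, hepatocyte_types, biotypes = NULL) {
  stopifnot(is.list(de_tables), !is.null(names(de_tables)))
  if (!all(hepatocyte_types %in% names(de_tables))) {
    stop_bad_arg("hepatocyte_types must name entries of de_tables")
  }
  long <- purrr::imap(de_tables, ~ mutate(.x, cell_type = .y)) |>
    dplyr::bind_rows() |>
    mutate(is_hep = .data$cell_type %in% hepatocyte_types)
  cls <- long |>
    group_by(.data$gene_id) |>
    summarise(n_hep_sig = sum(.data$significant & .data$is_hep),
              n_npc_sig = sum(.data$significant & !.data$is_hep),
              .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$n_hep_sig > 0 & .data$n_npc_sig == 0 ~ "hepatocyte_only",
      .data$n_hep_sig == 0 & .data$n_npc_sig > 0 ~ "npc_only",
      .data$n_hep_sig > 0 & .data$n_npc_sig > 0 ~ "both",
      TRUE ~ "none"))
  if (!is.null(biotypes)) {
    cls <- left_join(cls, biotypes, by = "gene_id")
    summ <- cls |>
      filter(.data$class != "none") |>
      dplyr::count(.data$biotype, .data$class) |>
      group_by(.data$biotype) |>
      mutate(fraction = .data$n / sum(.data$n)) |>
      ungroup()
  } else {
    summ <- cls |>
      filter(.data$class != "none") |>
      dplyr::count(.data$class) |>
      mutate(fraction = .data$n / sum(.data$n))
  }
  attr(cls, "summary") <- summ
  cls
}

#' Transcription-factor family enrichment among responders
#'
#' One-sided Fisher's exact test per family: differentially expressed
#' transcription factors against a background of non-responding factors
#' (the background excludes responders). Families with no members in either
#' set are skipped with a warning.
#'
#' @param de_tf_set Character vector of responding TF gene ids.
#' @param family_table Tibble `gene_id`, `family`.
#' @param background_tf_set Character vector of non-responding TF gene ids
#'   (disjoint from `de_tf_set`).
#' @param p_threshold Flagging threshold (default 0.05).
#' @return Tibble per family: counts, odds ratio, `p_value`, `enriched`.
#' @export
enrich_families <- function(de_tf_set, family_table, background_tf_set,
                            p_threshold = 0.05) {
  if (length(intersect(de_tf_set, background_tf_set)) > 0) {
    stop_bad_arg("background must exclude responding TFs")
  }
  fams <- unique(family_table$family)
  rows <- purrr::map(fams, function(fm) {
    members <- family_table$gene_id[family_table$family == fm]
    a <- sum(de_tf_set %in% members)
    b <- length(de_tf_set) - a
    c_ <- sum(background_tf_set %in% members)
    d <- length(background_tf_set) - c_
    if (a + c_ == 0) return(NULL)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = "greater")
    tibble(family = fm, de_in_family = a, de_other = b,
           bg_in_family = c_, bg_other = d,
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped)) {
    warn(paste0(sum(skipped), " famil(ies) with no members in either set skipped"))
  }
  dplyr::bind_rows(rows) |>
    mutate(enriched = .data$p_value < p_threshold) |>
    arrange(.data$p_value)
}
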