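#' Ligand-receptor communication probabilities between cell types
#'
#' For every (sender, receiver, ligand-receptor pair) triple the ligand
#' signal is the mean normalized ligand expression in the sender type and
#' the receptor signal the geometric mean of the subunit means in the
#' receiver type (a zero subunit silences the receptor complex). The
#' communication probability is the Hill form `(L * R) / (kh + L * R)`,
#' which is 0 when either side is absent, 0.5 when `L * R = kh`, strictly
#' increasing in each signal, and bounded in `[0, 1)`. This is an explicit
#' simplified stand-in for curated mass-action models; the downstream
#' information-flow definition (sum of significant probabilities) is
#' preserved exactly.
#'
#' @param x A [cell_matrix()] with a normalized layer.
#' @param labels Per-cell type labels (at least 2 types).
#' @param lr_pairs Tibble with columns `ligand`, `receptor` (subunits
#'   separated by `;`) and `pathway`. Pairs with genes absent from the
#'   matrix are skipped with a warning.
#' @param kh Hill half-saturation constant (default 0.5).
#' @param min_expr_frac Minimum fraction of expressing cells for a gene to
#'   contribute signal in a type (default 0.1; 0 disables the rule).
#' @param condition Label carried through.
#' @return A `comm_prob` tibble: `sender`, `receiver`, `ligand`, `receptor`,
#'   `pathway`, `prob`, `condition`.
#' @export
communication_probability <- function(x, labels, lr_pairs, kh = 0.5,
                                      min_expr_frac = 0.1,
                                      condition = NA_character_) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$norm)) stop_bad_arg("run normalize_log() first")
  types <- sort(unique(labels))
  if (length(types) < 2L) stop_bad_arg("need at least 2 cell types")
  genes_needed <- function(p) c(lr_pairs$ligand[p],
                                strsplit(lr_pairs$receptor[p], ";")[[1]])
  present <- vapply(seq_len(nrow(lr_pairs)), function(p)
    all(genes_needed(p) %in% colnames(x$norm)), logical(1))
  if (any(!present)) {
    warn(paste0(sum(!present), " ligand-receptor pair(s) with missing genes skipped"))
    lr_pairs <- lr_pairs[present, , drop = FALSE]
  }
  type_means <- type_mean_matrix(x$norm, labels, types)
  # A gene expressed in too few cells of a type contributes no signal there
  # (mirrors the trimmed-mean zeroing of curated communication models).
  if (min_expr_frac > 0) {
    frac <- type_mean_matrix(x$norm > 0, labels, types)
    type_means[frac < min_expr_frac] <- 0
  }
  rows <- purrr::map(seq_len(nrow(lr_pairs)), function(p) {
    lig <- lr_pairs$ligand[p]
    subs <- strsplit(lr_pairs$receptor[p], ";")[[1]]
    lsig <- type_means[, lig]
    rsig <- exp(rowMeans(log(pmax(type_means[, subs, drop = FALSE], 0))))
    rsig[apply(type_means[, subs, drop = FALSE] == 0, 1, any)] <- 0
    grid <- expand.grid(sender = types, receiver = types,
                        stringsAsFactors = FALSE)
    lr_prod <- lsig[grid$sender] * rsig[grid$receiver]
    tibble(sender = grid$sender, receiver = grid$receiver,
           ligand = lig, receptor = lr_pairs$receptor[p],
           pathway = lr_pairs$pathway[p],
           prob = unname(lr_prod / (kh + lr_prod)))
  })
  out <- dplyr::bind_rows(rows) |> mutate(condition = condition)
  class(out) <- c("comm_prob", class(out))
  out
}

type_mean_matrix <- function(norm, labels, types) {
  out <- vapply(types, function(tt)
    Matrix::colMeans(norm[labels == tt, , drop = FALSE]),
    numeric(ncol(norm)))
  t(out)  # types x genes
}

#' Permutation test for communication probabilities
#'
#' Cell-type labels are permuted `n_perm` times and each observed
#' probability is compared with its permutation distribution:
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)` (add-one correction, so the
#' smallest attainable p is `1 / (n_perm + 1)`). Interactions are retained
#' at `p < p_threshold`.
#'
#' @param x A [cell_matrix()] with normalized layer.
#' @param labels Per-cell type labels.
#' @param lr_pairs Ligand-receptor table (see
#'   [communication_probability()]).
#' @param n_perm Number of permutations (default 100, minimum 20).
#' @param kh Hill constant.
#' @param min_expr_frac Expressing-fraction floor passed through to
#'   [communication_probability()].
#' @param p_threshold Retention threshold (default 0.05).
#' @param seed RNG seed.
#' @param condition Label carried through.
#' @return The `comm_prob` tibble with `p_value` and `retained` columns.
#' @export
permutation_test <- function(x, labels, lr_pairs, n_perm = 100L, kh = 0.5,
                             min_expr_frac = 0.1, p_threshold = 0.05,
                             seed = 1L, condition = NA_character_) {
  if (n_perm < 20L) stop_bad_arg("n_perm must be at least 20")
  obs <- communication_probability(x, labels, lr_pairs, kh = kh,
                                   min_expr_frac = min_expr_frac,
                                   condition = condition)
  exceed <- numeric(nrow(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- suppressWarnings(
        communication_probability(x, sample(labels), lr_pairs, kh = kh,
                                  min_expr_frac = min_expr_frac))
      exceed <- exceed + (perm$prob >= obs$prob - 1e-12)
    }
  })
  obs$p_value <- (1 + exceed) / (1 + n_perm)
  obs$retained <- obs$p_value < p_threshold & obs$prob > 0
  obs
}

#' Pathway information flow
#'
#' The information flow of a signaling pathway is the sum of communication
#' probabilities over all retained (sender, receiver, pair) triples in that
#' pathway; relative flow divides by the condition's total flow. Flows are
#' additive: the pathway flows sum to the total retained probability.
#'
#' @param comm A `comm_prob` tibble, typically from [permutation_test()]
#'   (rows with `retained == FALSE` are dropped; if no `retained` column is
#'   present all rows count).
#' @return Tibble `pathway`, `flow`, `relative_flow`, `n_interactions`,
#'   `condition`.
#' @export
information_flow <- function(comm) {
  pathways <- sort(unique(comm$pathway))
  cond <- if (nrow(comm)) comm$condition[1] else NA_character_
  if ("retained" %in% names(comm)) comm <- comm[comm$retained, , drop = FALSE]
  flows <- comm |>
    group_by(.data$pathway) |>
    summarise(flow = sum(.data$prob), n_interactions = n(),
              .groups = "drop")
  # Pathways with no retained interaction are reported with zero flow.
  flows <- tibble(pathway = pathways) |>
    left_join(flows, by = "pathway") |>
    mutate(flow = ifelse(is.na(.data$flow), 0, .data$flow),
           n_interactions = ifelse(is.na(.data$n_interactions), 0L,
                                   .data$n_interactions))
  total <- sum(flows$flow)
  flows |>
    mutate(relative_flow = if (total > 0) .data$flow / total else 0,
           condition = cond) |>
    arrange(desc(.data$flow))
}

#' Compare pathway information flow between two conditions
#'
#' Joins the per-condition flow tables and classifies each pathway as
#' `shared`, or specific to one condition (specific = zero retained
#' interactions in the other condition). Pathways are reported with both
#' relative flows for bar-chart export; classification does not depend on
#' pathway order.
#'
#' @param flow_a,flow_b Flow tibbles from [information_flow()] computed
#'   with the same ligand-receptor table.
#' @return Tibble `pathway`, `flow_a`, `flow_b`, `relative_flow_a`,
#'   `relative_flow_b`, `class` (`shared` / `a_specific` / `b_specific`),
#'   plus condition names in attributes.
#' @export
compare_conditions <- function(flow_a, flow_b) {
  all_paths <- sort(union(flow_a$pathway, flow_b$pathway))
  a <- flow_a[match(all_paths, flow_a$pathway), ]
  b <- flow_b[match(all_paths, flow_b$pathway), ]
  fa <- ifelse(is.na(a$flow), 0, a$flow)
  fb <- ifelse(is.na(b$flow), 0, b$flow)
  na_i <- ifelse(is.na(a$n_interactions), 0L, a$n_interactions)
  nb_i <- ifelse(is.na(b$n_interactions), 0L, b$n_interactions)
  out <- tibble(
    pathway = all_paths, flow_a = fa, flow_b = fb,
    relative_flow_a = ifelse(is.na(a$relative_flow), 0, a$relative_flow),
    relative_flow_b = ifelse(is.na(b$relative_flow), 0, b$relative_flow),
    n_a = na_i, n_b = nb_i,
    class = dplyr::case_when(
      na_i > 0 & nb_i == 0 ~ "a_specific",
      na_i == 0 & nb_i > 0 ~ "b_specific",
      TRUE ~ "shared"))
  attr(out, "condition_a") <- flow_a$condition[1]
  attr(out, "condition_b") <- flow_b$condition[1]
  out
}
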