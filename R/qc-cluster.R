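#' Quality-control filter for nuclei
#'
#' Removes cells with fewer than `min_genes` detected genes, fewer than
#' `min_umi` total UMIs, or a mitochondrial UMI fraction above
#' `max_mito_frac` (defaults 200 genes / 400 UMIs / 5%). A cell failing
#' several criteria is attributed to each in the report. Filtering is
#' idempotent: applying it twice removes nothing the second time.
#'
#' @param x A [cell_matrix()] with raw counts and a logical `mito` column in
#'   `gene_meta`.
#' @param min_genes,min_umi,max_mito_frac QC thresholds.
#' @return The filtered [cell_matrix()], with attribute `qc_report`: a
#'   tibble of cells removed per criterion and in total.
#' @export
qc_filter <- function(x, min_genes = 200L, min_umi = 400L,
                      max_mito_frac = 0.05) {
  stopifnot(inherits(x, "cell_matrix"))
  if (min_genes <= 0 || min_umi <= 0 || max_mito_frac <= 0 ||
      max_mito_frac > 1) {
    stop_bad_arg("QC thresholds must be positive and max_mito_frac <= 1")
  }
  umi <- Matrix::rowSums(x$counts)
  detected <- Matrix::rowSums(x$counts > 0)
  mito_cols <- which(x$gene_meta$mito %||% rep(FALSE, ncol(x$counts)))
  if (length(mito_cols) == 0L) {
    warn("no mitochondrial genes flagged; mito criterion skipped")
    mito_frac <- rep(0, nrow(x$counts))
    fail_mito <- rep(FALSE, nrow(x$counts))
  } else {
    mito_frac <- Matrix::rowSums(x$counts[, mito_cols, drop = FALSE]) /
      pmax(umi, 1)
    fail_mito <- mito_frac > max_mito_frac
  }
  fail_genes <- detected < min_genes
  fail_umi <- umi < min_umi
  drop <- fail_genes | fail_umi | fail_mito
  report <- tibble(
    criterion = c("min_genes", "min_umi", "max_mito_frac", "any"),
    removed = c(sum(fail_genes), sum(fail_umi), sum(fail_mito), sum(drop)),
    threshold = c(min_genes, min_umi, max_mito_frac, NA))
  out <- subset_cells(x, !drop)
  attr(out, "qc_report") <- report
  out
}

#' Subset a cell_matrix by cells
#'
#' @param x A [cell_matrix()].
#' @param keep Logical or index vector over cells.
#' @return The subset [cell_matrix()] (normalized layer subset too).
#' @export
subset_cells <- function(x, keep) {
  cell_matrix(x$counts[keep, , drop = FALSE],
              cell_meta = x$cell_meta[keep, , drop = FALSE],
              gene_meta = x$gene_meta,
              norm = if (!is.null(x$norm)) x$norm[keep, , drop = FALSE])
}

#' Score and flag doublets with artificial doublets and k nearest neighbors
#'
#' Stand-in for dedicated doublet callers: artificial doublets are built by
#' summing the raw counts of random pairs of cells of distinct (cluster or
#' planted) types, real and artificial cells are embedded together in PCA
#' space, and each real cell is scored by the fraction of artificial
#' doublets among its `k` nearest neighbors. Scores above `threshold` are
#' flagged.
#'
#' @param x A [cell_matrix()] with raw counts.
#' @param types Per-cell type labels used to draw distinct-type pairs (e.g.
#'   cluster ids); at least two distinct values are required.
#' @param k Number of nearest neighbors (default 20).
#' @param threshold Score threshold for flagging (default 0.5).
#' @param n_artificial Number of artificial doublets (default: one per real
#'   cell).
#' @param n_pcs,n_hvg Embedding parameters.
#' @param seed RNG seed.
#' @return A tibble `barcode`, `doublet_score`, `doublet` (logical).
#' @export
detect_doublets <- function(x, types, k = 20L, threshold = 0.5,
                            n_artificial = NULL, n_pcs = 10L, n_hvg = 2000L,
                            seed = 1L) {
  stopifnot(inherits(x, "cell_matrix"))
  n <- nrow(x$counts)
  if (length(unique(types)) < 2L) {
    stop_bad_arg("doublet detection needs at least 2 cell types")
  }
  if (k >= n) stop_bad_arg("k must be smaller than the number of cells")
  n_art <- n_artificial %||% n
  with_seed(seed, {
    i <- sample(n, n_art, replace = TRUE)
    j <- vapply(i, function(a) {
      cand <- which(types != types[a])
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    art <- x$counts[i, , drop = FALSE] + x$counts[j, , drop = FALSE]
    rownames(art) <- sprintf("art_%05d", seq_len(n_art))
    combined <- rbind(x$counts, art)
    norm <- lognorm_values(combined, 1e4)
    emb <- pca_scores(norm, n_hvg = n_hvg, n_pcs = n_pcs)
    is_art <- c(rep(FALSE, n), rep(TRUE, n_art))
    score <- knn_fraction(emb, query = which(!is_art), flag = is_art, k = k)
    tibble(barcode = rownames(x$counts), doublet_score = score,
           doublet = score > threshold)
  })
}

# Fraction of flagged points among the k nearest neighbors of each query
# point (the query point itself excluded); computed in blocks to bound
# memory.
knn_fraction <- function(emb, query, flag, k) {
  n <- nrow(emb)
  score <- numeric(length(query))
  sq <- rowSums(emb ^ 2)
  block <- 512L
  for (s in seq(1, length(query), by = block)) {
    idx <- query[s:min(s + block - 1L, length(query))]
    d2 <- outer(sq[idx], sq, "+") - 2 * emb[idx, , drop = FALSE] %*% t(emb)
    for (r in seq_along(idx)) {
      ord <- order(d2[r, ])
      ord <- ord[ord != idx[r]][seq_len(k)]
      score[s + r - 1L] <- mean(flag[ord])
    }
  }
  score
}

#' Library-size log-normalization
#'
#' Divides each UMI count by the cell's total UMI count, multiplies by
#' `scale` and applies `log1p`: `value = log(1 + scale * count /
#' cell_total)`. The raw layer is preserved alongside. Zero counts stay
#' zero, so sparsity is preserved, and `sum(expm1(values)) / scale == 1`
#' per cell.
#'
#' @param x A [cell_matrix()] with raw counts and no all-zero cells.
#' @param scale Scale factor (default 10,000, the toolchain convention).
#' @return The [cell_matrix()] with a `norm` layer added.
#' @export
normalize_log <- function(x, scale = 1e4) {
  stopifnot(inherits(x, "cell_matrix"))
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0)) {
    stop_bad_arg(paste0("all-zero cell(s): ",
                        paste(head(rownames(x$counts)[totals == 0], 3L),
                              collapse = ", ")))
  }
  x$norm <- lognorm_values(x$counts, scale)
  x
}

# log1p-normalize a cells x genes CsparseMatrix by row (cell) totals; the
# i slot of dgCMatrix holds 0-based row indices of the nonzero entries.
lognorm_values <- function(counts, scale) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  totals <- Matrix::rowSums(counts)
  norm <- counts
  norm@x <- log1p(scale * counts@x / totals[counts@i + 1L])
  norm
}

#' Principal-component embedding of highly variable genes
#'
#' Selects the `n_hvg` genes with the highest standardized variance of the
#' normalized values, centers and unit-scales them per gene, and returns the
#' top `n_pcs` principal-component scores. The sign of each component is
#' fixed so that its largest-magnitude gene loading is positive.
#'
#' @param x A [cell_matrix()] with a normalized layer, or a dense/sparse
#'   cells x genes matrix of normalized values.
#' @param n_hvg Number of highly variable genes (default 2,000).
#' @param n_pcs Number of components (default 10).
#' @param batch Optional per-cell batch labels; if given, each batch's PC
#'   scores are mean-centered in PC space (a simple stand-in for iterative
#'   batch integration, sufficient for additive batch shifts).
#' @return A cells x n_pcs score matrix with barcode rownames and attribute
#'   `var_explained`.
#' @export
embed_pca <- function(x, n_hvg = 2000L, n_pcs = 10L, batch = NULL) {
  norm <- if (inherits(x, "cell_matrix")) {
    if (is.null(x$norm)) stop_bad_arg("run normalize_log() first")
    x$norm
  } else x
  emb <- pca_scores(norm, n_hvg = n_hvg, n_pcs = n_pcs)
  if (!is.null(batch)) {
    for (b in unique(batch)) {
      sel <- batch == b
      emb[sel, ] <- sweep(emb[sel, , drop = FALSE], 2,
                          colMeans(emb[sel, , drop = FALSE]))
    }
  }
  emb
}

pca_scores <- function(norm, n_hvg, n_pcs) {
  if (n_pcs > min(dim(norm))) stop_bad_arg("n_pcs exceeds matrix dimensions")
  v <- col_vars_sparse(norm)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, ncol(norm)))]
  m <- as.matrix(norm[, hvg, drop = FALSE])
  sdv <- pmax(sqrt(col_vars_dense(m)), 1e-8)
  m <- sweep(sweep(m, 2, colMeans(m)), 2, sdv, `/`)
  sv <- svd(m, nu = n_pcs, nv = n_pcs)
  # Sign convention: largest-|loading| entry of each component positive.
  for (cmp in seq_len(n_pcs)) {
    pivot <- which.max(abs(sv$v[, cmp]))
    if (sv$v[pivot, cmp] < 0) {
      sv$v[, cmp] <- -sv$v[, cmp]
      sv$u[, cmp] <- -sv$u[, cmp]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(scores) <- rownames(norm)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  attr(scores, "var_explained") <- sv$d[seq_len(n_pcs)] ^ 2 /
    sum(sv$d ^ 2)
  scores
}

col_vars_sparse <- function(m) {
  mu <- Matrix::colMeans(m)
  Matrix::colMeans(m ^ 2) - mu ^ 2
}

col_vars_dense <- function(m) {
  mu <- colMeans(m)
  colMeans(m ^ 2) - mu ^ 2
}

#' Graph-based clustering of an embedding
#'
#' Builds a k-nearest-neighbor graph in PC space and maximizes modularity
#' (Louvain) at the given resolution. Deterministic under `seed`.
#'
#' @param embedding Cells x PCs score matrix from [embed_pca()].
#' @param resolution Modularity resolution (default 0.2).
#' @param k Neighbors per cell (default 20; reduced with a warning if fewer
#'   cells are available).
#' @param seed RNG seed.
#' @return Integer cluster ids (1-based), named by barcode.
#' @export
cluster_cells <- function(embedding, resolution = 0.2, k = 20L, seed = 1L) {
  n <- nrow(embedding)
  if (!all(is.finite(embedding))) stop_bad_arg("embedding must be finite")
  if (k >= n) {
    warn("fewer cells than k; k reduced")
    k <- n - 1L
  }
  nn <- knn_index(embedding, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- with_seed(seed,
                  igraph::cluster_louvain(g, resolution = resolution))
  ids <- igraph::membership(cl)
  stats::setNames(as.integer(ids), rownames(embedding))
}

knn_index <- function(emb, k) {
  n <- nrow(emb)
  sq <- rowSums(emb ^ 2)
  out <- matrix(0L, n, k)
  block <- 512L
  for (s in seq(1, n, by = block)) {
    idx <- s:min(s + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * emb[idx, , drop = FALSE] %*% t(emb)
    for (r in seq_along(idx)) {
      ord <- order(d2[r, ])
      out[idx[r], ] <- ord[ord != idx[r]][seq_len(k)]
    }
  }
  out
}

#' Label clusters by marker-gene expression
#'
#' Each cluster receives the cell-type label whose marker set has the
#' highest mean scaled (z-scored across cells) normalized expression in the
#' cluster. Marker genes absent from the matrix are dropped with a warning;
#' a type with no present markers is an error. Exact score ties produce the
#' label `"unresolved:<t1>|<t2>"` with types in lexicographic order.
#'
#' @param x A [cell_matrix()] with a normalized layer.
#' @param clusters Per-cell cluster ids (named by barcode or aligned).
#' @param marker_table Tibble with columns `type` and `gene_id`.
#' @return A tibble `cluster`, `label`, `score`, `margin` (top score minus
#'   runner-up), plus per-cell labels in attribute `cell_labels`.
#' @export
annotate_clusters <- function(x, clusters, marker_table) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$norm)) stop_bad_arg("run normalize_log() first")
  types_requested <- sort(unique(marker_table$type))
  present <- marker_table$gene_id %in% colnames(x$norm)
  if (any(!present)) {
    warn(paste0(sum(!present), " marker gene(s) absent from matrix; dropped"))
    marker_table <- marker_table[present, , drop = FALSE]
  }
  types <- sort(unique(marker_table$type))
  if (length(setdiff(types_requested, types)) > 0 || nrow(marker_table) == 0) {
    stop_bad_arg("cell type without any marker present in the matrix")
  }
  # z-score each marker gene across cells, then average per cluster & type.
  mm <- as.matrix(x$norm[, unique(marker_table$gene_id), drop = FALSE])
  mm <- scale(mm)
  mm[is.na(mm)] <- 0
  cl_ids <- sort(unique(clusters))
  score_mat <- matrix(0, length(cl_ids), length(types),
                      dimnames = list(as.character(cl_ids), types))
  for (tt in types) {
    mg <- marker_table$gene_id[marker_table$type == tt]
    type_score <- rowMeans(mm[, mg, drop = FALSE])
    score_mat[, tt] <- vapply(cl_ids, function(cc)
      mean(type_score[clusters == cc]), numeric(1))
  }
  rows <- purrr::map(seq_along(cl_ids), function(r) {
    sc <- score_mat[r, ]
    ord <- order(-sc, names(sc))
    top <- sc[ord[1]]; second <- if (length(sc) > 1) sc[ord[2]] else -Inf
    label <- if (is.finite(second) && top == second) {
      tied <- sort(names(sc)[sc == top])
      paste0("unresolved:", paste(tied, collapse = "|"))
    } else names(sc)[ord[1]]
    tibble(cluster = cl_ids[r], label = label, score = unname(top),
           margin = unname(top - second))
  })
  out <- dplyr::bind_rows(rows)
  cell_labels <- out$label[match(clusters, out$cluster)]
  names(cell_labels) <- names(clusters)
  attr(out, "cell_labels") <- cell_labels
  out
}

#' Cell-type composition per condition with two-proportion z-tests
#'
#' For each cell type, compares its proportion between the two conditions
#' with a pooled two-proportion z-test.
#'
#' @param labels Per-cell type labels.
#' @param condition Per-cell condition labels (exactly two levels).
#' @return A tibble per type: counts and proportions per condition,
#'   difference, z statistic and p-value.
#' @export
composition_table <- function(labels, condition) {
  conds <- sort(unique(condition))
  if (length(conds) != 2L) stop_bad_arg("exactly two conditions required")
  n1 <- sum(condition == conds[1]); n2 <- sum(condition == conds[2])
  purrr::map(sort(unique(labels)), function(tt) {
    x1 <- sum(labels == tt & condition == conds[1])
    x2 <- sum(labels == tt & condition == conds[2])
    p1 <- x1 / n1; p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p2 - p1) / se
    tibble(cell_type = tt, n_1 = x1, n_2 = x2, prop_1 = p1, prop_2 = p2,
           diff = p2 - p1, z = z, p_value = 2 * pnorm(-abs(z)))
  }) |>
    dplyr::bind_rows() |>
    mutate(condition_1 = conds[1], condition_2 = conds[2])
}
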