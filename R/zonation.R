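#' Order hepatocytes along a 1-D lobule trajectory
#'
#' Stand-in for tree-based pseudotime tools: hepatocytes are embedded by PCA
#' of the normalized expression and ordered by the first nontrivial
#' component of a diffusion map (Gaussian kernel, symmetrically normalized
#' random-walk operator) over that embedding. Positions are min-max rescaled
#' to `[0, 1]` and oriented so that the mean expression of the periportal
#' anchor markers decreases with position (periportal end at 0, pericentral
#' at 1).
#'
#' @param x A [cell_matrix()] with a normalized layer, already subset to
#'   hepatocytes (see [subset_cells()]).
#' @param anchor_markers Gene ids expressed highest at the periportal end.
#' @param n_pcs,n_hvg Embedding parameters.
#' @param min_cells Minimum number of hepatocytes (default 50).
#' @return A `trajectory` object: tibble `barcode`, `position`, with
#'   attributes `anchors`, `spline` (degree, n_knots) and `axis_correlation`
#'   (largest |correlation| between position and a PC; a warning is raised
#'   when it falls below 0.3, i.e. no dominant gradient).
#' @export
order_cells_1d <- function(x, anchor_markers, n_pcs = 10L, n_hvg = 2000L,
                           min_cells = 50L) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$norm)) stop_bad_arg("run normalize_log() first")
  n <- nrow(x$counts)
  if (n < min_cells) stop_bad_arg("too few hepatocytes for trajectory inference")
  anchor_markers <- intersect(anchor_markers, colnames(x$norm))
  if (length(anchor_markers) == 0L) {
    stop_bad_arg("no anchor marker present in the matrix")
  }
  emb <- embed_pca(x, n_hvg = n_hvg, n_pcs = min(n_pcs, n - 1L))
  # Several expression programs (cell state, regulons) can compete with the
  # lobule axis for the leading components; the anchor markers identify
  # which diffusion component is the zonation axis.
  comps <- diffusion_components(emb, n_comp = 5L)
  anchor_score <- module_score(x$norm, anchor_markers)
  ac <- abs(suppressWarnings(cor(anchor_score, comps)))
  pos <- comps[, which.max(ac)]
  pos <- (pos - min(pos)) / (max(pos) - min(pos))
  if (cor(anchor_score, pos) > 0) pos <- 1 - pos
  axis_cor <- max(ac, na.rm = TRUE)
  # Genuine lobule gradients put the anchor-axis correlation well above 0.4;
  # a structureless blob stays below ~0.3 even with the anchors' own noise
  # feeding the embedding.
  if (axis_cor < 0.3) {
    warn(paste0("anchor markers show no gradient along any leading ",
                "component; the ordering explains little variance"))
  }
  out <- tibble(barcode = rownames(x$counts), position = pos)
  attr(out, "anchors") <- anchor_markers
  attr(out, "spline") <- list(degree = 3L, n_knots = 3L)
  attr(out, "axis_correlation") <- axis_cor
  class(out) <- c("trajectory", class(out))
  out
}

# Background-corrected per-cell score of a gene set: mean normalized
# expression of the set minus the mean of an expression-matched background
# (100 nearest genes by overall mean per set gene), which cancels
# compositional library effects that would otherwise couple the score to
# unrelated high-variance programs.
module_score <- function(norm, genes) {
  gm <- Matrix::colMeans(norm)
  bg <- unique(unlist(lapply(genes, function(a) {
    names(sort(abs(gm - gm[[a]]))[2:min(101, length(gm))])
  })))
  bg <- setdiff(bg, genes)
  Matrix::rowMeans(norm[, genes, drop = FALSE]) -
    Matrix::rowMeans(norm[, bg, drop = FALSE])
}

# Leading nontrivial eigenvectors of the symmetrically normalized Gaussian
# affinity operator, mapped back to the random-walk eigenvectors.
diffusion_components <- function(emb, n_comp = 5L) {
  d2 <- as.matrix(stats::dist(emb)) ^ 2
  sigma2 <- stats::median(d2[d2 > 0])
  a <- exp(-d2 / sigma2)
  diag(a) <- 0
  dg <- pmax(rowSums(a), 1e-12)
  m <- a / sqrt(dg) / rep(sqrt(dg), each = nrow(a))
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  ev$vectors[, 1L + seq_len(min(n_comp, ncol(ev$vectors) - 1L)),
             drop = FALSE] / sqrt(dg)
}

#' Test genes for zonated expression along a trajectory
#'
#' Per gene, a likelihood-ratio test (Gaussian working model on
#' log-normalized values) of a cubic B-spline in lobule position against an
#' intercept-only model, with Benjamini-Hochberg q-values. Significant genes
#' receive a zone label (`periportal` / `mid` / `pericentral`) by the argmax
#' of the fitted profile over the position tertile midpoints.
#'
#' @param x A [cell_matrix()] with a normalized layer, same cells as the
#'   trajectory.
#' @param trajectory A `trajectory` from [order_cells_1d()].
#' @param n_knots Internal spline knots (default 3).
#' @param q_threshold Significance threshold (default 0.001).
#' @param genes Optional subset of gene ids to test.
#' @param min_cells Genes expressed in fewer cells are not testable along
#'   the trajectory (the Gaussian working model is unreliable for
#'   near-all-zero genes); they are reported with `NA` statistics and
#'   excluded from the multiplicity correction. Default: 5% of cells.
#' @return A `zonation_result` tibble: `gene_id`, `statistic`, `df`,
#'   `p_value`, `q_value`, `zonated`, `zone`.
#' @export
zonation_test <- function(x, trajectory, n_knots = 3L, q_threshold = 0.001,
                          genes = NULL, min_cells = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$norm)) stop_bad_arg("run normalize_log() first")
  if (!identical(trajectory$barcode, rownames(x$norm))) {
    stop_bad_arg("trajectory cells do not match the matrix")
  }
  pos <- trajectory$position
  y <- as.matrix(x$norm[, genes %||% colnames(x$norm), drop = FALSE])
  testable <- zonation_testable(y, min_cells)
  basis <- spline_basis(pos, n_knots)
  fit <- fit_lrt(y, cbind(1, basis), intercept_only = TRUE)
  fit$stat[!testable] <- NA_real_
  fit$p[!testable] <- NA_real_
  q <- rep(NA_real_, length(fit$p))
  q[testable] <- bh_adjust(fit$p[testable])
  # Zone by argmax of the fitted spline profile at tertile midpoints.
  grid <- c(1 / 6, 3 / 6, 5 / 6)
  gb <- cbind(1, eval_basis(basis, grid))
  prof <- gb %*% fit$coef
  zone <- c("periportal", "mid", "pericentral")[apply(prof, 2, which.max)]
  res <- tibble(
    gene_id = colnames(y), statistic = unname(fit$stat), df = fit$df,
    p_value = unname(fit$p), q_value = unname(q),
    zonated = !is.na(q) & q < q_threshold,
    zone = ifelse(!is.na(q) & q < q_threshold, zone, NA_character_))
  class(res) <- c("zonation_result", class(res))
  res
}

#' Test for differential zonation between conditions
#'
#' Both conditions are mapped onto one common trajectory (fit on the pooled
#' cells); per gene the null hypothesis of identical expression patterns in
#' each condition along the trajectory (one shared spline) is tested against
#' separate per-condition splines by a Gaussian working-model F-test, with
#' Benjamini-Hochberg adjustment and a default call at FDR < 0.001. The test
#' is symmetric in the condition labels.
#'
#' @param x A [cell_matrix()] (normalized layer) covering both conditions.
#' @param trajectory Common trajectory over the same cells.
#' @param condition Two-level vector, one per cell.
#' @param n_knots Internal spline knots (default 3).
#' @param fdr_threshold Call threshold (default 0.001).
#' @param genes Optional subset of gene ids.
#' @param min_cells Expression filter as in [zonation_test()].
#' @return A `zonation_result` tibble: `gene_id`, `statistic`, `df`,
#'   `p_value`, `fdr`, `differential`.
#' @export
differential_zonation <- function(x, trajectory, condition, n_knots = 3L,
                                  fdr_threshold = 0.001, genes = NULL,
                                  min_cells = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$norm)) stop_bad_arg("run normalize_log() first")
  if (length(unique(condition)) != 2L) {
    stop_bad_arg("exactly two conditions required")
  }
  pos <- trajectory$position
  y <- as.matrix(x$norm[, genes %||% colnames(x$norm), drop = FALSE])
  testable <- zonation_testable(y, min_cells)
  basis <- spline_basis(pos, n_knots)
  cond <- as.integer(factor(condition)) - 1L
  x_null <- cbind(1, basis)
  x_full <- cbind(x_null, cond, basis * cond)
  fit <- fit_lrt(y, x_full, x_null = x_null)
  fit$stat[!testable] <- NA_real_
  fit$p[!testable] <- NA_real_
  fdr <- rep(NA_real_, length(fit$p))
  fdr[testable] <- bh_adjust(fit$p[testable])
  res <- tibble(
    gene_id = colnames(y), statistic = unname(fit$stat), df = fit$df,
    p_value = unname(fit$p), fdr = unname(fdr),
    differential = !is.na(fdr) & fdr < fdr_threshold)
  class(res) <- c("zonation_result", class(res))
  res
}

# Cubic B-spline basis with equal-count internal knots; n_knots = 0 falls
# back to a plain linear trend, so the test reduces to the OLS linear-trend
# F-test.
spline_basis <- function(pos, n_knots) {
  if (n_knots == 0L) {
    b <- matrix(pos, ncol = 1L)
    colnames(b) <- "pos"
    return(b)
  }
  knots <- stats::quantile(pos, probs = seq_len(n_knots) / (n_knots + 1))
  splines::bs(pos, knots = knots, degree = 3L, Boundary.knots = c(0, 1))
}

# Genes expressed in too few cells cannot be tested along the trajectory.
zonation_testable <- function(y, min_cells) {
  min_cells <- min_cells %||% ceiling(0.05 * nrow(y))
  colSums(y > 0) >= min_cells
}

eval_basis <- function(basis, at) {
  if (inherits(basis, "bs")) stats::predict(basis, at) else
    matrix(at, ncol = 1L)
}

# Gaussian working-model F-test of x_full against x_null (default:
# intercept-only) for every column of y at once; identical to the OLS anova
# F-test per gene.
fit_lrt <- function(y, x_full, x_null = NULL, intercept_only = FALSE) {
  n <- nrow(y)
  q_full <- qr(x_full)
  res_full <- qr.resid(q_full, y)
  rss1 <- colSums(res_full ^ 2)
  if (intercept_only) {
    rss0 <- colSums(sweep(y, 2, colMeans(y)) ^ 2)
    df <- q_full$rank - 1L
  } else {
    q_null <- qr(x_null)
    rss0 <- colSums(qr.resid(q_null, y) ^ 2)
    df <- q_full$rank - q_null$rank
  }
  df2 <- n - q_full$rank
  stat <- ((rss0 - rss1) / df) / (rss1 / df2)
  stat[rss1 <= 1e-300 | !is.finite(stat)] <- 0
  stat[rss0 <= 1e-300] <- 0
  p <- stats::pf(stat, df1 = df, df2 = df2, lower.tail = FALSE)
  list(stat = stat, df = df, p = p, coef = qr.coef(q_full, y))
}

#' Binned expression profiles along the trajectory
#'
#' Cells are cut into `n_bins` equal-count bins of lobule position; each
#' gene's binned mean expression is z-scored across bins (constant genes
#' give all-zero rows). Bin boundaries are position quantiles, so bin counts
#' sum to the number of cells.
#'
#' @param x A [cell_matrix()] with normalized layer.
#' @param trajectory Trajectory over the same cells.
#' @param n_bins Number of bins (default 10, minimum 3).
#' @param genes Optional gene subset.
#' @return genes x bins matrix with attribute `bin_counts`.
#' @export
zone_profile_matrix <- function(x, trajectory, n_bins = 10L, genes = NULL) {
  if (n_bins < 3L) stop_bad_arg("n_bins must be at least 3")
  pos <- trajectory$position
  breaks <- stats::quantile(pos, probs = seq(0, 1, length.out = n_bins + 1L))
  breaks[1] <- -Inf; breaks[n_bins + 1L] <- Inf
  bin <- cut(pos, breaks = breaks, labels = FALSE)
  y <- as.matrix(x$norm[, genes %||% colnames(x$norm), drop = FALSE])
  prof <- t(vapply(seq_len(n_bins),
                   function(b) colMeans(y[bin == b, , drop = FALSE]),
                   numeric(ncol(y))))
  prof <- t(prof)  # genes x bins
  rownames(prof) <- colnames(y)
  mu <- rowMeans(prof)
  sdv <- apply(prof, 1, sd)
  out <- (prof - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  colnames(out) <- paste0("bin", seq_len(n_bins))
  attr(out, "bin_counts") <- as.integer(table(bin))
  out
}
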