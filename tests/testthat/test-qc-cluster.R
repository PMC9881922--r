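toy_matrix <- function(counts, mito = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  mito <- mito %||% rep(FALSE, ncol(counts))
  cell_matrix(counts,
              cell_meta = tibble::tibble(barcode = rownames(counts)),
              gene_meta = tibble::tibble(
                gene_id = colnames(counts),
                biotype = ifelse(mito, "mitochondrial", "protein_coding"),
                mito = mito))
}

test_that("qc_filter applies the gene, UMI and mito thresholds and is idempotent", {
  # cell 1: 150 detected genes (fails min_genes); cell 2: 401 UMI over 300
  # genes, no mito (boundary, retained); cell 3: 10% mito (fails)
  m <- matrix(0L, 3, 500)
  m[1, 1:150] <- 3L                       # 450 UMI but only 150 genes
  m[2, 1:300] <- 1L; m[2, 1:101] <- 2L    # 401 UMI, 300 genes
  m[3, 1:400] <- 1L; m[3, 500] <- 45L     # 445 UMI, 45/445 = 10% mito
  x <- toy_matrix(m, mito = c(rep(FALSE, 499), TRUE))
  out <- qc_filter(x)
  rep <- attr(out, "qc_report")
  expect_equal(rownames(out$counts), "c002")
  expect_equal(rep$removed[rep$criterion == "min_genes"], 1)
  expect_equal(rep$removed[rep$criterion == "max_mito_frac"], 1)

  again <- qc_filter(out)
  expect_equal(dim(again), dim(out))
  expect_equal(attr(again, "qc_report")$removed[4], 0)
})

test_that("qc_filter removals equal a brute-force recount on random data", {
  withr::local_seed(8)
  m <- matrix(rpois(200 * 300, 1.2), 200, 300)
  mito <- c(rep(TRUE, 10), rep(FALSE, 290))
  x <- toy_matrix(m, mito = mito)
  out <- qc_filter(x, min_genes = 100, min_umi = 300, max_mito_frac = 0.05)
  keep_oracle <- vapply(seq_len(nrow(m)), function(i) {
    sum(m[i, ] > 0) >= 100 && sum(m[i, ]) >= 300 &&
      sum(m[i, mito]) / sum(m[i, ]) <= 0.05
  }, logical(1))
  expect_identical(rownames(out$counts), rownames(x$counts)[keep_oracle])

  no_mito <- toy_matrix(m)
  expect_warning(qc_filter(no_mito, min_genes = 10, min_umi = 10),
                 "mito")
})

test_that("log-normalization matches its closed form and algebraic identities", {
  m <- matrix(0L, 2, 4)
  m[1, ] <- c(10L, 490L, 500L, 0L)   # total 1000
  m[2, ] <- c(1L, 1L, 1L, 1L)
  x <- toy_matrix(m)
  xn <- normalize_log(x, scale = 1e4)
  expect_equal(xn$norm[1, 1], log(1 + 100))
  expect_equal(xn$norm[1, 4], 0)
  # zero pattern preserved; expm1(values)/scale sums to 1 per cell
  expect_identical(as.matrix(xn$norm == 0), as.matrix(x$counts == 0))
  expect_equal(unname(Matrix::rowSums(expm1(xn$norm)) / 1e4), c(1, 1))

  z <- toy_matrix(matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_error(normalize_log(z), "all-zero")
})

test_that("PCA embedding honors its variance and symmetry properties", {
  withr::local_seed(42)
  base <- matrix(rnorm(60 * 30), 60, 30)
  rownames(base) <- sprintf("c%03d", 1:60)
  dup <- rbind(base, base)
  rownames(dup) <- sprintf("c%03d", 1:120)
  emb <- embed_pca(dup, n_hvg = 30, n_pcs = 5)
  expect_equal(emb[1:60, ], emb[61:120, ], ignore_attr = TRUE)
  ve <- attr(emb, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))

  # reconstruction error decreases with more components
  recon_err <- function(k) {
    e <- embed_pca(base, n_hvg = 30, n_pcs = k)
    s <- scale(base)
    fit <- e %*% (t(e) %*% s) / nrow(s)  # projection onto PC scores
    # compare via residual variance of regression of s on scores
    sum(qr.resid(qr(e), s) ^ 2)
  }
  expect_lte(recon_err(10), recon_err(5))
  expect_error(embed_pca(base, n_pcs = 100), "n_pcs")
})

test_that("graph clustering separates Gaussian blobs deterministically", {
  withr::local_seed(1)
  blob <- rbind(matrix(rnorm(100 * 5), 100, 5),
                matrix(rnorm(100 * 5, mean = 8), 100, 5))
  rownames(blob) <- sprintf("c%03d", 1:200)
  cl <- cluster_cells(blob, resolution = 0.2, seed = 4)
  expect_equal(length(unique(cl)), 2)
  expect_equal(lobulex:::adjusted_rand_index(cl, rep(1:2, each = 100)), 1)
  expect_identical(cl, cluster_cells(blob, resolution = 0.2, seed = 4))
  expect_warning(cluster_cells(blob[1:10, ], k = 20), "k reduced")
})

test_that("marker annotation labels clusters, reports ties and recovers planted types", {
  sim <- simulate_counts(small_config())
  m <- normalize_log(sim$matrix)
  truth <- sim$truth$cells
  # use the planted types as "clusters": every type must be recalled
  clusters <- as.integer(factor(truth$cell_type))
  singlet <- !truth$doublet
  ann <- annotate_clusters(subset_cells(m, singlet), clusters[singlet],
                           sim$truth$markers)
  lab <- ann$label[match(sort(unique(clusters[singlet])), ann$cluster)]
  expect_setequal(lab, unique(truth$cell_type[singlet]))
  expect_true(all(ann$margin > 0))

  # tie rule: two types with identical marker sets
  mk <- tibble::tibble(type = c("t1", "t2"),
                       gene_id = sim$truth$markers$gene_id[1])
  ann2 <- annotate_clusters(subset_cells(m, singlet), clusters[singlet], mk)
  expect_true(all(ann2$label == "unresolved:t1|t2"))

  # absent markers are dropped with a warning
  mk_extra <- dplyr::bind_rows(
    sim$truth$markers,
    tibble::tibble(type = sim$truth$markers$type[1], gene_id = "nope"))
  expect_warning(
    annotate_clusters(subset_cells(m, singlet), clusters[singlet], mk_extra),
    "absent")
  # a type with no present marker at all is an error
  mk3 <- dplyr::bind_rows(sim$truth$markers,
                          tibble::tibble(type = "ghost", gene_id = "nope"))
  expect_error(suppressWarnings(
    annotate_clusters(subset_cells(m, singlet), clusters[singlet], mk3)),
    "without any marker")
})

test_that("composition comparison finds planted shifts and respects identities", {
  labels <- rep(c("A", "B", "C"), times = c(100, 100, 100))
  cond <- rep(c("x", "y"), 150)
  tab <- composition_table(labels, cond)
  expect_true(all(abs(tab$diff) < 1e-9))
  expect_equal(sum(tab$prop_1), 1)
  expect_equal(sum(tab$prop_2), 1)

  # planted 2x Kupffer expansion at 500 cells per condition
  withr::local_seed(3)
  p1 <- c(Kupffer = 0.1, Hep = 0.7, Other = 0.2)
  p2 <- c(Kupffer = 0.2, Hep = 0.6, Other = 0.2)
  l1 <- sample(names(p1), 500, replace = TRUE, prob = p1)
  l2 <- sample(names(p2), 500, replace = TRUE, prob = p2)
  tab2 <- composition_table(c(l1, l2), rep(c("control", "exposed"), each = 500))
  expect_lt(tab2$p_value[tab2$cell_type == "Kupffer"], 0.05)
})

test_that("doublet detection needs two types and flags summed profiles", {
  sim <- simulate_counts(small_config(seed = 6, doublet_rate = 0.1))
  m <- sim$matrix
  truth <- sim$truth$cells
  expect_error(detect_doublets(subset_cells(m, truth$cell_type == "B"),
                               types = rep("B", sum(truth$cell_type == "B"))),
               "2 cell types")
  res <- detect_doublets(m, types = truth$cell_type, seed = 5)
  expect_true(all(res$doublet_score >= 0 & res$doublet_score <= 1))
  expect_gte(mean(res$doublet[truth$doublet]), 0.6)   # sensitivity

  # doublet-free data (after QC, as in the pipeline): false-positive rate
  # at most 5%. The kNN scorer assumes droplet-scale cell numbers, so the
  # null world uses ~1,600 cells.
  sim0 <- simulate_counts(small_config(
    seed = 7, doublet_rate = 0,
    cells_per_type_per_condition = list(
      "Hep-PC" = c(210L, 210L), "Hep-PP" = c(180L, 180L),
      "Endothelial" = c(90L, 90L), "Kupffer" = c(90L, 90L),
      "Stellate" = c(60L, 60L), "Cholangiocyte" = c(60L, 60L),
      "B" = c(60L, 60L), "T" = c(60L, 60L))))
  m0 <- qc_filter(sim0$matrix)
  res0 <- detect_doublets(m0, types = m0$cell_meta$cell_type, seed = 5)
  expect_lte(mean(res0$doublet), 0.05)
})
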