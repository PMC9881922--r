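sim_nb_counts <- function(n_per_group, mu, size, seed = 1,
                          lfc_idx = integer(), lfc = 0) {
  withr::local_seed(seed, .local_envir = parent.frame(2))
  g <- length(mu)
  sf <- rlnorm(2 * n_per_group, 0, 0.3)
  groups <- rep(c("A", "B"), each = n_per_group)
  counts <- vapply(seq_len(g), function(j) {
    m <- rep(mu[j], 2 * n_per_group)
    if (j %in% lfc_idx) m[groups == "A"] <- m[groups == "A"] * 2 ^ lfc
    if (is.finite(size)) rnbinom(2 * n_per_group, size = size, mu = m * sf)
    else rpois(2 * n_per_group, lambda = m * sf)
  }, numeric(2 * n_per_group))
  rownames(counts) <- sprintf("c%04d", seq_len(2 * n_per_group))
  colnames(counts) <- sprintf("g%04d", seq_len(g))
  list(counts = counts, groups = groups)
}

test_that("dispersion estimation recovers Poisson and NB truths", {
  d <- sim_nb_counts(100, mu = rep(2, 500), size = Inf, seed = 2)
  # Poisson data: dispersion zero
  disp <- estimate_dispersion(d$counts, d$groups)
  expect_lte(median(disp$dispersions$shrunken), 0.05)

  d2 <- sim_nb_counts(100, mu = exp(runif(2000, log(0.5), log(4))),
                      size = 2, seed = 3)
  disp2 <- estimate_dispersion(d2$counts, d2$groups)
  expect_equal(mean(disp2$dispersions$shrunken), 0.5, tolerance = 0.2)

  # single gene: full weight on the (identical) common value
  one <- estimate_dispersion(d2$counts[, 1, drop = FALSE], d2$groups,
                             sf = size_factors(d2$counts))
  expect_equal(one$delta, 1)
  expect_equal(one$dispersions$shrunken, one$dispersions$raw)

  expect_error(estimate_dispersion(d2$counts[c(1, 2, 101), ],
                                   d2$groups[c(1, 2, 101)]),
               ">= 2 cells")
  expect_equal(names(glance(disp2)),
               c("n_genes", "common", "delta", "median_raw",
                 "median_shrunken"))
})

test_that("the NB test is a null identity on copied groups and symmetric in groups", {
  withr::local_seed(4)
  half <- matrix(rnbinom(50 * 100, size = 2, mu = 1), 50, 100)
  counts <- rbind(half, half)  # group B is an exact copy of group A
  rownames(counts) <- sprintf("c%03d", 1:100)
  colnames(counts) <- sprintf("g%03d", 1:100)
  groups <- rep(c("A", "B"), each = 50)
  res <- nb_test(counts, groups)
  ok <- !res$untestable
  expect_true(all(res$log2_fc[ok] == 0))
  expect_true(all(res$p_value[ok] >= 0.99))

  d <- sim_nb_counts(60, mu = exp(runif(200, log(0.2), log(3))), size = 2,
                     seed = 5, lfc_idx = 1:20, lfc = 3)
  ra <- nb_test(d$counts, d$groups)
  rb <- nb_test(d$counts, factor(d$groups, levels = c("B", "A")))
  expect_equal(ra$log2_fc, -rb$log2_fc, tolerance = 1e-12)
  expect_equal(ra$p_value, rb$p_value, tolerance = 1e-12)

  # gene zero in both groups: untestable, p = 1, log2 fc 0
  d$counts[, 7] <- 0
  rz <- nb_test(d$counts, d$groups)
  expect_true(rz$untestable[7])
  expect_equal(rz$p_value[7], 1)
  expect_equal(rz$log2_fc[7], 0)
})

test_that("power never decreases with the planted effect size", {
  power_at <- function(lfc) {
    d <- sim_nb_counts(100, mu = rep(1.5, 300), size = 2, seed = 11,
                       lfc_idx = 1:50, lfc = lfc)
    res <- nb_test(d$counts, d$groups)
    mean(res$fdr[1:50] < 0.05)
  }
  p <- vapply(c(1, 2, 3), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::local_seed(6)
  for (rep in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # invariant under input permutation
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("response classes follow the significance pattern across cell types", {
  de_tab <- function(sig) {
    tibble::tibble(gene_id = sprintf("g%02d", seq_along(sig)),
                   log2_fc = 3, p_value = 0.001, fdr = 0.001,
                   significant = sig, untestable = FALSE,
                   mean_a = 1, mean_b = 1, contrast = NA_character_)
  }
  tables <- list(
    "Hep-PC" = de_tab(c(TRUE, FALSE, TRUE, FALSE)),
    "Hep-PP" = de_tab(c(FALSE, FALSE, TRUE, FALSE)),
    "Kupffer" = de_tab(c(FALSE, TRUE, TRUE, FALSE)),
    "Endothelial" = de_tab(c(FALSE, TRUE, FALSE, FALSE)))
  cls <- classify_responses(tables, hepatocyte_types = c("Hep-PC", "Hep-PP"))
  expect_equal(cls$class[match(sprintf("g%02d", 1:4), cls$gene_id)],
               c("hepatocyte_only", "npc_only", "both", "none"))

  bt <- tibble::tibble(gene_id = sprintf("g%02d", 1:4),
                       biotype = c("lncRNA", "protein_coding",
                                   "protein_coding", "lncRNA"))
  cls2 <- classify_responses(tables, c("Hep-PC", "Hep-PP"), biotypes = bt)
  summ <- attr(cls2, "summary")
  expect_equal(summ$fraction[summ$biotype == "lncRNA" &
                               summ$class == "hepatocyte_only"], 1)
})

test_that("planted response classes are recovered from simulated counts", {
  # two hepatocyte and two NPC populations; genes respond in planted subsets
  withr::local_seed(12)
  n <- 150
  types <- rep(c("HepA", "HepB", "NpcA", "NpcB"), each = 2 * n)
  cond <- rep(rep(c("control", "exposed"), each = n), 4)
  g <- 300
  mu <- exp(runif(g, log(0.8), log(4)))
  class_plan <- rep(c("none", "hepatocyte_only", "npc_only", "both"),
                    length.out = 60)
  sf <- rlnorm(length(types), 0, 0.3)
  counts <- vapply(seq_len(g), function(j) {
    m <- rep(mu[j], length(types))
    if (j <= 60) {
      up_hep <- class_plan[j] %in% c("hepatocyte_only", "both")
      up_npc <- class_plan[j] %in% c("npc_only", "both")
      sel <- (cond == "exposed") &
        ((up_hep & types %in% c("HepA", "HepB")) |
           (up_npc & types %in% c("NpcA", "NpcB")))
      m[sel] <- m[sel] * 8
    }
    rnbinom(length(types), size = 2, mu = m * sf)
  }, numeric(length(types)))
  rownames(counts) <- sprintf("c%05d", seq_along(types))
  colnames(counts) <- sprintf("g%04d", seq_len(g))
  tables <- lapply(split(seq_along(types), types), function(idx) {
    nb_test(counts[idx, ], cond[idx])
  })
  cls <- classify_responses(tables, hepatocyte_types = c("HepA", "HepB"))
  got <- cls$class[match(sprintf("g%04d", 1:60), cls$gene_id)]
  expect_gte(mean(got == class_plan), 0.9)
})

test_that("TF-family enrichment matches the hypergeometric oracle and calibrates", {
  # 2x2 table (10, 5, 90, 895): one-sided Fisher equals the hypergeometric
  # tail of drawing >= 10 in-family among the 15 responders
  fam <- tibble::tibble(
    gene_id = sprintf("tf%04d", 1:1000),
    family = c(rep("F1", 100), rep("other", 900)))
  de <- c(sprintf("tf%04d", 1:10), sprintf("tf%04d", 101:105))
  bg <- setdiff(fam$gene_id, de)
  res <- enrich_families(de, fam, bg)
  p_oracle <- oracle_hyper_tail(10, 100, 1000, 15)
  expect_equal(res$p_value[res$family == "F1"], p_oracle, tolerance = 1e-10)

  # family with no members in either set is skipped with a warning
  fam2 <- dplyr::bind_rows(fam, tibble::tibble(gene_id = "zzz",
                                               family = "EMPTY"))
  expect_warning(enrich_families(de, fam2, bg), "skipped")
  expect_error(enrich_families(de, fam, c(de[1], bg)), "exclude")

  # permuted response labels: ~5% of families flagged at p < 0.05
  withr::local_seed(13)
  fam3 <- tibble::tibble(gene_id = sprintf("t%04d", 1:800),
                         family = rep(sprintf("f%02d", 1:40), each = 20))
  hits <- unlist(lapply(1:25, function(b) {
    de_b <- sample(fam3$gene_id, 80)
    r <- enrich_families(de_b, fam3, setdiff(fam3$gene_id, de_b))
    r$enriched
  }))
  expect_lt(mean(hits), 0.09)
})
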