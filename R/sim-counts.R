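# Synthetic two-condition liver snRNA-seq counts with planted ground truth.

#' Simulate a feature-barcode count matrix with planted ground truth
#'
#' Draws negative-binomial counts for the configured cell types in two
#' conditions (`control`, `exposed`). On a log2 mean scale the generator
#' superimposes, per gene: cell-type marker elevation; a log-linear lobule
#' zonation gradient for hepatocyte genes (flattened or sign-flipped in the
#' exposed condition for the planted disrupted set); planted condition
#' fold-changes in one cell type each; shared latent factors tying regulator
#' hubs to their target modules (the super-hub's factor also feeds the other
#' hubs); and ligand/receptor elevation in planted sender/receiver types.
#' Per-cell library-size factors are log-normal(0, 0.3); a small fraction of
#' cells is made shallow (tiny size factor) or damaged (high mitochondrial
#' fraction) so the QC filters have true positives, and doublets are sums of
#' the counts of two random cells of distinct types from the same condition.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (a [cell_matrix()]) and `truth`
#'   (class `sim_truth`: tibbles `cells`, `genes`, `hubs`, `markers`,
#'   `anchors`, `lr` recording everything planted).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_table(config)
  cells <- sim_cell_table(config)
  with_seed(config$seed + 303L, {
    cells$size_factor <- rlnorm(nrow(cells), 0, 0.3)
    cells$size_factor[cells$shallow] <- cells$size_factor[cells$shallow] * 0.05

    base_mu <- exp(runif(nrow(genes), log(config$nb_mean_range[1]),
                         log(config$nb_mean_range[2])))
    # Planted-signal genes are drawn from the well-expressed range: real
    # zonation markers and called responders are abundant transcripts.
    sig <- !genes$role %in% c("filler", "mito", "lr")
    base_mu[sig] <- exp(runif(sum(sig), log(config$signal_mean_range[1]),
                              log(config$signal_mean_range[2])))
    # Ligands/receptors are near-silent outside their planted context, as
    # real signaling genes are cell-type restricted.
    is_lr <- genes$role == "lr"
    base_mu[is_lr] <- exp(runif(sum(is_lr), log(0.02), log(0.08)))
    # Mitochondrial means set so the expected mito UMI share is mito_frac
    # (10x that in damaged cells).
    is_mt <- genes$biotype == "mitochondrial"
    if (any(is_mt)) {
      t_nuc <- sum(base_mu[!is_mt])
      base_mu[is_mt] <- config$mito_frac / (1 - config$mito_frac) *
        t_nuc / sum(is_mt)
    }
    genes$base_log2_mu <- log2(base_mu)

    lfc <- sim_log2fc_matrix(config, genes, cells)
    mu <- sweep(2 ^ (matrix(genes$base_log2_mu, nrow(cells), nrow(genes),
                            byrow = TRUE) + lfc),
                1, cells$size_factor, `*`)
    counts <- matrix(rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
                     nrow(cells), nrow(genes))

    # Doublets: sums of two random singlets of distinct types, same condition.
    n_doub <- round(config$doublet_rate * nrow(cells))
    if (n_doub > 0) {
      pairs <- sim_doublet_pairs(cells, n_doub)
      dcounts <- counts[pairs$i, , drop = FALSE] +
        counts[pairs$j, , drop = FALSE]
      dcells <- tibble(
        barcode = sprintf("doublet_%04d", seq_len(nrow(pairs))),
        cell_type = "doublet", condition = cells$condition[pairs$i],
        lobule_position = NA_real_, doublet = TRUE,
        shallow = FALSE, damaged = FALSE,
        size_factor = cells$size_factor[pairs$i] +
          cells$size_factor[pairs$j],
        member_type_1 = cells$cell_type[pairs$i],
        member_type_2 = cells$cell_type[pairs$j]
      )
      cells$member_type_1 <- NA_character_
      cells$member_type_2 <- NA_character_
      counts <- rbind(counts, dcounts)
      cells <- dplyr::bind_rows(cells, dcells)
    } else {
      cells$member_type_1 <- NA_character_
      cells$member_type_2 <- NA_character_
    }
    rownames(counts) <- cells$barcode
    colnames(counts) <- genes$gene_id

    mat <- cell_matrix(
      counts,
      cell_meta = cells[, c("barcode", "cell_type", "condition",
                            "lobule_position", "doublet")],
      gene_meta = tibble(gene_id = genes$gene_id, biotype = genes$biotype,
                         mito = genes$biotype == "mitochondrial")
    )
    truth <- structure(
      list(
        cells = cells, genes = genes,
        hubs = sim_hub_targets(genes),
        markers = genes |> filter(.data$role == "marker") |>
          select(type = "role_param", gene_id = "gene_id"),
        anchors = genes$gene_id[genes$role == "zonated" & genes$anchor],
        lr = config$lr_spec
      ),
      class = "sim_truth")
    list(matrix = mat, truth = truth)
  })
}

# Gene table with planted roles. Special genes carry descriptive ids; the
# remaining budget is filled with plain pc_/lnc_ filler genes.
sim_gene_table <- function(config) {
  ct <- config$cell_types
  rows <- list()
  add <- function(gene_id, biotype, role, role_param = NA_character_,
                  zon_dir = NA_real_, disrupted = NA_character_,
                  de_sign = NA_real_, anchor = FALSE) {
    tibble(gene_id = gene_id, biotype = biotype, role = role,
           role_param = role_param, zon_dir = zon_dir, disrupted = disrupted,
           de_sign = de_sign, anchor = anchor)
  }
  # Markers: n_markers_per_type per cell type, protein-coding.
  for (t in ct) {
    safe <- gsub("[^A-Za-z]", "", t)
    rows[[length(rows) + 1L]] <- add(
      sprintf("mk_%s_%02d", safe, seq_len(config$n_markers_per_type)),
      "protein_coding", "marker", t)
  }
  # Zonated genes: 2/3 protein-coding, 1/3 lncRNA; alternating direction;
  # the first `zonation_disrupted_count` are disrupted in the exposed
  # condition (half flattened, half reversed); the first 5 periportal-high
  # protein-coding genes double as trajectory-orientation anchors.
  nz <- config$zonated_gene_count
  nz_pc <- ceiling(2 * nz / 3)
  zon_ids <- c(sprintf("zon_pc_%03d", seq_len(nz_pc)),
               sprintf("zon_lnc_%03d", seq_len(nz - nz_pc)))
  zon_bt <- c(rep("protein_coding", nz_pc), rep("lncRNA", nz - nz_pc))
  zon_dir <- rep(c(-1, 1), length.out = nz)
  nd <- min(config$zonation_disrupted_count, nz)
  disrupted <- rep(NA_character_, nz)
  if (nd > 0) disrupted[seq_len(nd)] <- rep(c("flattened", "reversed"),
                                            length.out = nd)
  anchor <- zon_dir == -1 & zon_bt == "protein_coding" & is.na(disrupted)
  anchor[setdiff(seq_len(nz), head(which(anchor), 5L))] <- FALSE
  rows[[length(rows) + 1L]] <- add(zon_ids, zon_bt, "zonated",
                                   zon_dir = zon_dir, disrupted = disrupted,
                                   anchor = anchor)
  # Condition-response genes: one home cell type each, alternating sign,
  # half protein-coding, half lncRNA.
  nde <- config$de_gene_count
  nde_pc <- ceiling(nde / 2)
  de_ids <- c(sprintf("de_pc_%03d", seq_len(nde_pc)),
              sprintf("de_lnc_%03d", seq_len(nde - nde_pc)))
  de_bt <- c(rep("protein_coding", nde_pc), rep("lncRNA", nde - nde_pc))
  rows[[length(rows) + 1L]] <- add(
    de_ids, de_bt, "de", role_param = rep(ct, length.out = nde),
    de_sign = rep(c(1, -1), length.out = nde))
  # Regulator hubs and their target modules.
  hs <- config$hub_spec
  for (h in seq_len(nrow(hs))) {
    rows[[length(rows) + 1L]] <- add(hs$regulator[h], hs$biotype[h], "hub",
                                     role_param = hs$regulator[h])
    rows[[length(rows) + 1L]] <- add(
      sprintf("tgt_%s_%02d", hs$regulator[h], seq_len(hs$n_targets[h])),
      "protein_coding", "target", role_param = hs$regulator[h])
  }
  # Ligand / receptor genes.
  lr <- config$lr_spec
  lr_genes <- unique(c(lr$ligand, unlist(strsplit(lr$receptor, ";"))))
  if (length(lr_genes) > 0) {
    rows[[length(rows) + 1L]] <- add(lr_genes, "protein_coding", "lr")
  }
  special <- dplyr::bind_rows(rows)
  if (anyDuplicated(special$gene_id)) {
    stop_bad_arg("planted gene ids collide; check hub_spec/lr_spec names")
  }
  n_pc_special <- sum(special$biotype == "protein_coding")
  n_lnc_special <- sum(special$biotype == "lncRNA")
  if (n_pc_special > config$n_genes_pc || n_lnc_special > config$n_genes_lnc) {
    stop_bad_arg("gene budget too small for the planted structure")
  }
  filler <- dplyr::bind_rows(
    add(sprintf("pc_%04d", seq_len(config$n_genes_pc - n_pc_special)),
        "protein_coding", "filler"),
    add(sprintf("lnc_%04d", seq_len(config$n_genes_lnc - n_lnc_special)),
        "lncRNA", "filler"),
    if (config$n_mito > 0)
      add(sprintf("mt_%02d", seq_len(config$n_mito)), "mitochondrial",
          "mito")
  )
  dplyr::bind_rows(special, filler)
}

sim_cell_table <- function(config) {
  rows <- list()
  for (t in config$cell_types) {
    nn <- config$cells_per_type_per_condition[[t]]
    for (k in 1:2) {
      cond <- c("control", "exposed")[k]
      n <- nn[k]
      if (n == 0) next
      rows[[length(rows) + 1L]] <- tibble(
        cell_type = t, condition = cond, n = n)
    }
  }
  plan <- dplyr::bind_rows(rows)
  cells <- plan[rep(seq_len(nrow(plan)), plan$n), c("cell_type", "condition")]
  n <- nrow(cells)
  cells$barcode <- sprintf("cell_%05d", seq_len(n))
  with_seed(config$seed + 404L, {
    # Lobule coordinate: periportal subtype occupies [0, 0.55], pericentral
    # [0.45, 1]; other types carry no position.
    pos <- rep(NA_real_, n)
    is_pc <- cells$cell_type == config$hepatocyte_types[1]
    is_pp <- cells$cell_type == config$hepatocyte_types[2]
    pos[is_pc] <- runif(sum(is_pc), 0.45, 1)
    pos[is_pp] <- runif(sum(is_pp), 0, 0.55)
    cells$lobule_position <- pos
    cells$doublet <- FALSE
    cells$shallow <- runif(n) < config$shallow_rate
    cells$damaged <- !cells$shallow & runif(n) < config$damaged_rate
  })
  cells[, c("barcode", "cell_type", "condition", "lobule_position",
            "doublet", "shallow", "damaged")]
}

# Dense cells x genes matrix of planted log2 fold-change offsets.
sim_log2fc_matrix <- function(config, genes, cells) {
  n <- nrow(cells); g <- nrow(genes)
  lfc <- matrix(0, n, g)
  gidx <- stats::setNames(seq_len(g), genes$gene_id)
  exposed <- cells$condition == "exposed"
  hep <- !is.na(cells$lobule_position)

  mk <- which(genes$role == "marker")
  for (j in mk) {
    lfc[cells$cell_type == genes$role_param[j], j] <- config$marker_log2fc
  }

  zon <- which(genes$role == "zonated")
  x_centered <- cells$lobule_position - 0.5
  for (j in zon) {
    d <- genes$zon_dir[j] * config$zonation_amplitude
    slope <- rep(d, n)
    if (!is.na(genes$disrupted[j])) {
      slope[exposed] <- if (genes$disrupted[j] == "flattened") 0 else -d
    }
    lfc[hep, j] <- lfc[hep, j] + slope[hep] * x_centered[hep]
  }

  de <- which(genes$role == "de")
  for (j in de) {
    sel <- exposed & cells$cell_type == genes$role_param[j]
    lfc[sel, j] <- lfc[sel, j] + genes$de_sign[j] * config$de_log2fc
  }

  # Hub latent factors: one standard-normal factor per hub per cell; the
  # super-hub's factor is mixed into every other hub's factor so that hubs
  # correlate with the super-hub (a hub of hubs). A hub contributes to its
  # own gene and its targets only in its active condition(s).
  hs <- config$hub_spec
  if (nrow(hs) > 0) {
    z <- matrix(rnorm(n * nrow(hs)), n, nrow(hs))
    super <- which(hs$super)
    if (length(super) == 1L) {
      # Strong coupling keeps hub-to-super-hub correlations above the
      # adaptive edge cutoff, so the super-hub bridges the hub stars.
      mix <- 0.85
      for (h in setdiff(seq_len(nrow(hs)), super)) {
        z[, h] <- mix * z[, super] + sqrt(1 - mix^2) * z[, h]
      }
    }
    for (h in seq_len(nrow(hs))) {
      active <- switch(hs$condition[h],
                       both = rep(TRUE, n),
                       control = !exposed,
                       exposed = exposed)
      # Loading calibrated so the realized hub-target Spearman correlation
      # (after NB sampling, normalization and zero inflation) tracks the
      # nominal strength; saturation caps it near ~0.5-0.6 at strength 0.8.
      lambda <- 2.5 * hs$strength[h]
      hub_col <- gidx[[hs$regulator[h]]]
      tgt_cols <- gidx[genes$role == "target" &
                         genes$role_param == hs$regulator[h]]
      lfc[active, hub_col] <- lfc[active, hub_col] + lambda * z[active, h]
      # Hub-centric module: each target mixes the hub factor with private
      # noise (mixing b), so hub-target correlation (prop. to b) exceeds
      # target-target correlation (prop. to b^2) and the adaptive edge
      # cutoff keeps the star around the hub rather than a target clique.
      b <- 0.7
      e <- matrix(rnorm(n * length(tgt_cols)), n)
      w <- b * z[, h] + sqrt(1 - b ^ 2) * e
      lfc[active, tgt_cols] <- lfc[active, tgt_cols] +
        lambda * w[active, , drop = FALSE]
    }
  }

  # Planted ligand-receptor activity: ligand up in sender cells, receptor
  # subunits up in receiver cells, in the active condition(s).
  lr <- config$lr_spec
  for (p in seq_len(nrow(lr))) {
    active <- switch(lr$condition[p],
                     both = rep(TRUE, n),
                     control = !exposed,
                     exposed = exposed)
    send <- active & cells$cell_type == lr$sender[p]
    recv <- active & cells$cell_type == lr$receiver[p]
    lfc[send, gidx[[lr$ligand[p]]]] <- lfc[send, gidx[[lr$ligand[p]]]] + 4
    for (sub in strsplit(lr$receptor[p], ";")[[1]]) {
      lfc[recv, gidx[[sub]]] <- lfc[recv, gidx[[sub]]] + 4
    }
  }

  # Damaged cells: mitochondrial means x10.
  mt <- which(genes$biotype == "mitochondrial")
  if (length(mt) > 0 && any(cells$damaged)) {
    lfc[cells$damaged, mt] <- lfc[cells$damaged, mt] + log2(10)
  }
  lfc
}

sim_doublet_pairs <- function(cells, n_doub) {
  i <- sample(nrow(cells), n_doub, replace = TRUE)
  j <- vapply(i, function(a) {
    cand <- which(cells$condition == cells$condition[a] &
                    cells$cell_type != cells$cell_type[a])
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
  tibble(i = i, j = j)
}

sim_hub_targets <- function(genes) {
  genes |>
    filter(.data$role == "target") |>
    select(hub = "role_param", target = "gene_id")
}

#' @exportS3Method base::print
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$cells), " cells (",
      sum(x$cells$doublet), " doublets), ", nrow(x$genes), " genes, ",
      nrow(x$hubs), " hub-target links\n", sep = "")
  invisible(x)
}

#' Write planted ground truth as TSV tables
#'
#' Emits `truth_cells.tsv`, `truth_genes.tsv`, `truth_hubs.tsv`,
#' `truth_markers.tsv`, `truth_anchors.tsv` and `truth_lr.tsv` into `dir`,
#' losslessly (read back with `readr::read_tsv`).
#'
#' @param truth A `sim_truth` from [simulate_counts()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(truth$cells, file.path(dir, "truth_cells.tsv"))
  readr::write_tsv(truth$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(truth$hubs, file.path(dir, "truth_hubs.tsv"))
  readr::write_tsv(truth$markers, file.path(dir, "truth_markers.tsv"))
  readr::write_tsv(tibble(gene_id = truth$anchors),
                   file.path(dir, "truth_anchors.tsv"))
  readr::write_tsv(truth$lr, file.path(dir, "truth_lr.tsv"))
  invisible(dir)
}
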