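#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic liver snRNA-seq
#' world used by [simulate_annotation()], [simulate_reads()] and
#' [simulate_counts()]. Defaults describe a two-condition (control vs.
#' exposed) liver with 8 cell types, negative-binomial counts, a latent 1-D
#' lobule coordinate driving zonated hepatocyte genes, planted condition
#' fold-changes (including zonation disruption), planted regulator hubs with
#' correlated target modules, planted ligand-receptor activity, doublets and
#' mitochondrial contamination.
#'
#' @param seed Integer RNG seed; every simulated artefact is deterministic
#'   given the full configuration including the seed.
#' @param cell_types Character vector of cell-type names. The first two are
#'   treated as hepatocyte subtypes (pericentral, periportal) carrying the
#'   lobule coordinate.
#' @param cells_per_type_per_condition Named list or single integer: number
#'   of cells per type in each of the two conditions. The default mirrors a
#'   liver nucleus suspension, where the two hepatocyte subtypes dominate
#'   and non-parenchymal populations are smaller (~4,500 singlets total).
#' @param n_genes_pc,n_genes_lnc,n_mito Gene counts by biotype
#'   (protein-coding, lncRNA, mitochondrial).
#' @param nb_mean_range Range of per-gene baseline negative-binomial means;
#'   baseline means are drawn log-uniformly from this interval.
#' @param signal_mean_range Baseline mean range for genes carrying planted
#'   signal (markers, zonated, condition-response, hubs and targets,
#'   ligands/receptors): such genes are well expressed in real liver data
#'   (zonated metabolic genes and called responders are abundant), so their
#'   baselines are drawn from this higher log-uniform range.
#' @param nb_dispersion Negative-binomial size parameter (size = 1 /
#'   dispersion in the mean-dispersion parameterization); 2 corresponds to
#'   the overdispersion typical of droplet snRNA-seq counts.
#' @param doublet_rate Fraction of additional barcodes that are doublets
#'   (sums of two random cells of distinct types); must be < 0.5.
#' @param shallow_rate Fraction of cells given a very small library-size
#'   factor so that the QC UMI/gene filters have true positives.
#' @param damaged_rate Fraction of cells with elevated mitochondrial UMI
#'   fraction (above the 5% QC threshold).
#' @param mito_frac Baseline expected mitochondrial UMI fraction.
#' @param zonated_gene_count Number of hepatocyte genes following a
#'   log-linear gradient along the lobule coordinate.
#' @param zonation_amplitude Log2-fold expression span of zonated genes
#'   across the whole lobule axis.
#' @param zonation_disrupted_count Number of zonated genes whose gradient is
#'   flattened (half) or sign-flipped (half) in the exposed condition.
#' @param de_gene_count Number of genes with a planted condition response in
#'   one cell type each.
#' @param de_log2fc Planted absolute log2 fold-change of condition-response
#'   genes (default 3, i.e. 8-fold, clearing the |FC| > 4 call threshold).
#' @param n_markers_per_type Number of marker genes elevated in each type.
#' @param marker_log2fc Marker elevation (log2) in the home type.
#' @param hub_spec Tibble with columns `regulator`, `biotype`
#'   (`protein_coding` or `lncRNA`), `n_targets`, `strength` (latent
#'   correlation strength in (0,1)), `condition` (`both`, `control` or
#'   `exposed`) and `super` (logical; the super-hub's latent factor also
#'   drives the other hubs, making it a hub of hubs).
#' @param lr_spec Tibble with columns `ligand`, `receptor`
#'   (`;`-separated subunits for complexes), `sender`, `receiver`, `pathway`,
#'   `condition` describing planted ligand-receptor activity.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       cell_types = c("Hep-PC", "Hep-PP", "Endothelial",
                                      "Kupffer", "Stellate", "Cholangiocyte",
                                      "B", "T"),
                       cells_per_type_per_condition = list(
                         "Hep-PC" = c(700L, 700L), "Hep-PP" = c(600L, 600L),
                         "Endothelial" = c(200L, 200L),
                         "Kupffer" = c(200L, 200L),
                         "Stellate" = c(150L, 150L),
                         "Cholangiocyte" = c(100L, 100L),
                         "B" = c(150L, 150L), "T" = c(150L, 150L)),
                       n_genes_pc = 2000L,
                       n_genes_lnc = 987L,
                       n_mito = 13L,
                       nb_mean_range = c(0.02, 2),
                       signal_mean_range = c(0.5, 4),
                       nb_dispersion = 2,
                       doublet_rate = 0.05,
                       shallow_rate = 0.02,
                       damaged_rate = 0.03,
                       mito_frac = 0.02,
                       zonated_gene_count = 150L,
                       zonation_amplitude = 3,
                       zonation_disrupted_count = 40L,
                       de_gene_count = 200L,
                       de_log2fc = 3,
                       n_markers_per_type = 40L,
                       marker_log2fc = 3,
                       hub_spec = default_hub_spec(),
                       lr_spec = default_lr_spec()) {
  if (length(cell_types) < 2L) stop_bad_arg("need at least 2 cell types")
  if (n_genes_pc <= 0L || n_genes_lnc <= 0L) {
    stop_bad_arg("gene counts must be positive")
  }
  if (n_mito < 0L) stop_bad_arg("n_mito must be non-negative")
  if (doublet_rate < 0 || doublet_rate >= 0.5) {
    stop_bad_arg("doublet_rate must lie in [0, 0.5)")
  }
  if (any(nb_mean_range <= 0) || diff(nb_mean_range) < 0) {
    stop_bad_arg("nb_mean_range must be positive and increasing")
  }
  if (nb_dispersion <= 0) stop_bad_arg("nb_dispersion must be positive")
  if (is.numeric(cells_per_type_per_condition) &&
      length(cells_per_type_per_condition) == 1L) {
    cells_per_type_per_condition <- stats::setNames(
      rep(list(c(cells_per_type_per_condition, cells_per_type_per_condition)),
          length(cell_types)),
      cell_types)
  }
  if (!all(cell_types %in% names(cells_per_type_per_condition))) {
    stop_bad_arg("cells_per_type_per_condition must name every cell type")
  }
  totals <- vapply(cells_per_type_per_condition, sum, numeric(1))
  if (any(totals <= 0)) stop_bad_arg("each cell type needs > 0 cells")
  hub_spec <- as_tibble(hub_spec)
  if (nrow(hub_spec) > 0) {
    stopifnot(all(c("regulator", "biotype", "n_targets", "strength",
                    "condition", "super") %in% names(hub_spec)))
    if (any(hub_spec$strength < 0 | hub_spec$strength >= 1)) {
      stop_bad_arg("hub strength must lie in [0, 1)")
    }
  }
  cfg <- list(
    seed = as.integer(seed), cell_types = cell_types,
    hepatocyte_types = cell_types[1:2],
    cells_per_type_per_condition = cells_per_type_per_condition,
    n_genes_pc = as.integer(n_genes_pc),
    n_genes_lnc = as.integer(n_genes_lnc),
    n_mito = as.integer(n_mito),
    nb_mean_range = nb_mean_range, signal_mean_range = signal_mean_range,
    nb_dispersion = nb_dispersion,
    doublet_rate = doublet_rate, shallow_rate = shallow_rate,
    damaged_rate = damaged_rate, mito_frac = mito_frac,
    zonated_gene_count = as.integer(zonated_gene_count),
    zonation_amplitude = zonation_amplitude,
    zonation_disrupted_count = as.integer(zonation_disrupted_count),
    de_gene_count = as.integer(de_gene_count), de_log2fc = de_log2fc,
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_log2fc = marker_log2fc,
    hub_spec = hub_spec, lr_spec = as_tibble(lr_spec)
  )
  structure(cfg, class = "sim_config")
}

#' Default planted regulator hubs
#'
#' Three protein-coding and two lncRNA hubs; `hub_pc_super` is the super-hub
#' whose latent factor also feeds the other hubs, and `hub_pc_exposed` /
#' `hub_lnc_exposed` are active only in the exposed condition so that the
#' per-condition networks differ.
#'
#' @return A tibble, one row per hub.
#' @export
default_hub_spec <- function() {
  tibble(
    regulator = c("hub_pc_super", "hub_pc_1", "hub_pc_exposed",
                  "hub_lnc_1", "hub_lnc_exposed"),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lncRNA", "lncRNA"),
    n_targets = c(120L, 100L, 100L, 80L, 80L),
    strength = c(0.9, 0.8, 0.8, 0.8, 0.8),
    condition = c("both", "control", "exposed", "both", "exposed"),
    super = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Default planted ligand-receptor activity
#'
#' One fibrosis-like pathway active only in the exposed condition
#' (stellate -> pericentral hepatocyte, two-subunit receptor complex), one
#' pathway active in both conditions, and one control-only pathway.
#'
#' @return A tibble, one row per planted interaction.
#' @export
default_lr_spec <- function() {
  tibble(
    ligand = c("lig_fib", "lig_base", "lig_ctrl"),
    receptor = c("rec_fib_a;rec_fib_b", "rec_base", "rec_ctrl"),
    sender = c("Stellate", "Endothelial", "Kupffer"),
    receiver = c("Hep-PC", "Kupffer", "B"),
    pathway = c("FIBROSIS", "BASELINE", "CTRLONLY"),
    condition = c("exposed", "both", "control")
  )
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  n_cells <- sum(vapply(x$cells_per_type_per_condition, sum, numeric(1)))
  cat("<sim_config> ", length(x$cell_types), " cell types, ",
      n_cells, " singlet cells, ",
      x$n_genes_pc + x$n_genes_lnc + x$n_mito, " genes, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
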