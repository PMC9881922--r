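#' Build a correlation network over genes
#'
#' Computes pairwise Spearman correlation of normalized expression over the
#' selected cells for genes expressed in at least `min_cells_expressed`
#' cells, and keeps an edge between two genes iff `|r|` reaches the given
#' quantile of the `|r|` distribution over all retained gene pairs (the
#' default 0.999 keeps the top 0.1% of pairs). Edge weights carry the
#' signed correlation. All retained genes stay as nodes, connected or not.
#'
#' @param x A [cell_matrix()] with a normalized layer.
#' @param cells Optional logical/index vector selecting cells (e.g. one
#'   condition).
#' @param quantile Edge-cutoff quantile of `|r|` (default 0.999; 0 keeps
#'   every pair).
#' @param min_cells_expressed Minimum cells with nonzero expression for a
#'   gene to enter (default 5% of the selected cells).
#' @param condition Label stored on the network.
#' @return A `gene_network`: list with `graph` (igraph, weight = signed r),
#'   `nodes` tibble (`gene_id`, `biotype`), `condition`, `cutoff`.
#' @export
build_network <- function(x, cells = NULL, quantile = 0.999,
                          min_cells_expressed = NULL,
                          condition = NA_character_) {
  stopifnot(inherits(x, "cell_matrix"))
  if (is.null(x$norm)) stop_bad_arg("run normalize_log() first")
  norm <- if (is.null(cells)) x$norm else x$norm[cells, , drop = FALSE]
  if (nrow(norm) < 50L) stop_bad_arg("need at least 50 cells")
  min_cells_expressed <- min_cells_expressed %||% ceiling(0.05 * nrow(norm))
  keep <- Matrix::colSums(norm > 0) >= min_cells_expressed
  if (sum(keep) < 2L) stop_bad_arg("fewer than 2 genes pass the expression filter")
  norm <- norm[, keep, drop = FALSE]
  biotype <- x$gene_meta$biotype[keep]
  r <- stats::cor(apply(as.matrix(norm), 2, rank))
  absr <- abs(r[upper.tri(r)])
  cutoff <- if (quantile <= 0) 0 else
    stats::quantile(absr, probs = quantile, names = FALSE)
  adj <- abs(r) >= cutoff
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = colnames(norm)[idx[, 1]],
               to = colnames(norm)[idx[, 2]],
               weight = r[idx]),
    directed = FALSE,
    vertices = data.frame(name = colnames(norm), biotype = biotype))
  structure(list(graph = g,
                 nodes = tibble(gene_id = colnames(norm), biotype = biotype),
                 condition = condition, cutoff = cutoff),
            class = "gene_network")
}

gene_network_from_graph <- function(g, condition = NA_character_,
                                    cutoff = NA_real_) {
  structure(list(
    graph = g,
    nodes = tibble(gene_id = igraph::V(g)$name,
                   biotype = igraph::V(g)$biotype %||%
                     rep("unknown", igraph::vcount(g))),
    condition = condition, cutoff = cutoff),
    class = "gene_network")
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges",
      if (!is.na(x$condition)) paste0(" (", x$condition, ")"), "\n", sep = "")
  invisible(x)
}

#' Network summary
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return One-row tibble: node/edge counts by biotype, mean degree
#'   (density as average connections per node), condition.
#' @export
glance.gene_network <- function(x, ...) {
  deg <- igraph::degree(x$graph)
  tibble(n_nodes = igraph::vcount(x$graph),
         n_edges = igraph::ecount(x$graph),
         n_protein_coding = sum(x$nodes$biotype == "protein_coding"),
         n_lncrna = sum(x$nodes$biotype == "lncRNA"),
         mean_degree = mean(deg),
         condition = x$condition)
}

#' Keep regulators and their direct neighbors
#'
#' Retains a node iff it is a supplied regulator or has at least one edge to
#' one (edges induced). Never adds nodes or edges, and is idempotent.
#'
#' @param network A `gene_network`.
#' @param regulator_ids Character vector of regulator gene ids (e.g. GO
#'   transcription-regulator terms plus the lncRNA list).
#' @return The subset `gene_network`; node tibble gains a `regulator` flag.
#' @export
regulator_subset <- function(network, regulator_ids) {
  if (length(regulator_ids) == 0L) stop_bad_arg("regulator_ids is empty")
  g <- network$graph
  is_reg <- igraph::V(g)$name %in% regulator_ids
  if (!any(is_reg)) {
    warn("no regulator present in the network; result is empty")
    keep <- rep(FALSE, igraph::vcount(g))
  } else {
    nb <- igraph::ego(g, order = 1, nodes = which(is_reg))
    keep_idx <- unique(unlist(lapply(nb, as.integer)))
    keep <- seq_len(igraph::vcount(g)) %in% keep_idx
  }
  sub <- igraph::induced_subgraph(g, which(keep))
  out <- gene_network_from_graph(sub, network$condition, network$cutoff)
  out$nodes$regulator <- out$nodes$gene_id %in% regulator_ids
  out
}

#' Detect gene modules by modularity communities
#'
#' Louvain modularity maximization (on absolute edge weights) respecting
#' connected components; modules smaller than `min_size` are merged into
#' module 0 ("unassigned"). Deterministic under `seed`.
#'
#' @param network A `gene_network`.
#' @param seed RNG seed.
#' @param min_size Minimum module size (default 3).
#' @return Tibble `gene_id`, `module` (integer; 0 = unassigned).
#' @export
detect_modules <- function(network, seed = 1L, min_size = 3L) {
  g <- network$graph
  if (igraph::vcount(g) == 0L) stop_bad_arg("empty network")
  w <- abs(igraph::E(g)$weight %||% rep(1, igraph::ecount(g)))
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, weights = w)))
  memb <- as.integer(memb)
  sizes <- table(memb)
  small <- as.integer(names(sizes)[sizes < min_size])
  memb[memb %in% small] <- 0L
  relabel <- stats::setNames(seq_along(setdiff(sort(unique(memb)), 0L)),
                             setdiff(sort(unique(memb)), 0L))
  memb <- ifelse(memb == 0L, 0L, relabel[as.character(memb)])
  tibble(gene_id = igraph::V(g)$name, module = as.integer(memb))
}

#' Node centrality metrics
#'
#' Computes, per node: unweighted degree; betweenness and stress from
#' all-pairs shortest paths on the unweighted graph (unnormalized pair
#' counts; stress counts the shortest paths passing through the node);
#' harmonic closeness (sum of reciprocal distances, the deterministic
#' convention for disconnected graphs); PageRank with damping 0.85 on
#' absolute edge weights (sums to 1); and neighborhood connectivity (mean
#' degree of the node's neighbors; 0 for isolated nodes).
#'
#' @param network A `gene_network`.
#' @return Tibble `gene_id`, `biotype`, `degree`, `betweenness`, `stress`,
#'   `closeness`, `pagerank`, `neighborhood_connectivity`.
#' @export
compute_metrics <- function(network) {
  g <- network$graph
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(tibble(gene_id = character(), biotype = character(),
                  degree = numeric(), betweenness = numeric(),
                  stress = numeric(), closeness = numeric(),
                  pagerank = numeric(),
                  neighborhood_connectivity = numeric()))
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  cls <- igraph::harmonic_centrality(g, weights = NA, normalized = FALSE)
  w <- abs(igraph::E(g)$weight %||% rep(1, igraph::ecount(g)))
  pr <- igraph::page_rank(g, damping = 0.85,
                          weights = if (length(w)) w else NULL)$vector
  adj <- igraph::as_adj_list(g, mode = "all")
  nc <- vapply(seq_len(n), function(i) {
    nb <- as.integer(adj[[i]])
    if (length(nb) == 0L) 0 else mean(deg[nb])
  }, numeric(1))
  tibble(gene_id = igraph::V(g)$name, biotype = network$nodes$biotype,
         degree = unname(deg), betweenness = unname(btw),
         stress = stress_centrality(g), closeness = unname(cls),
         pagerank = unname(pr), neighborhood_connectivity = nc)
}

# Stress centrality: number of shortest paths (over unordered node pairs)
# passing through each node, by Brandes-style BFS accumulation. For source
# s, sigma(s, v) counts shortest s-v paths and zeta_s(v) counts the DAG
# paths from v to all downstream targets; stress(v) = sum_s sigma(s, v) *
# zeta_s(v) / 2.
stress_centrality <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  stress <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); sigma <- numeric(n); order_v <- integer(0)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_v <- c(order_v, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    zeta <- numeric(n)
    for (v in rev(order_v)) {
      for (w in adj[[v]]) {
        if (dist[w] == dist[v] + 1L) zeta[v] <- zeta[v] + 1 + zeta[w]
      }
    }
    contrib <- sigma * zeta
    contrib[s] <- 0
    stress <- stress + contrib
  }
  stress / 2
}

#' Select network-essential genes
#'
#' Within each biotype stratum, nodes are ranked (descending) by each of
#' four centrality metrics — degree, betweenness, closeness, PageRank — and
#' the essential set is the union of the top `top_pc` protein-coding and
#' top `top_lnc` lncRNA nodes per metric. Ties at the rank boundary are
#' broken by the mean rank across the other metrics, then lexicographic
#' gene id; the metrics that selected each gene are recorded as provenance.
#'
#' @param network A `gene_network`.
#' @param metrics Metric tibble from [compute_metrics()] (recomputed if
#'   omitted).
#' @param top_pc,top_lnc Per-metric cutoffs (defaults 100 and 50).
#' @return An `essential_selection`: tibble `gene_id`, `biotype`,
#'   `selected_by` (comma-joined metric names), `essential = TRUE`.
#' @export
select_essential <- function(network, metrics = NULL, top_pc = 100L,
                             top_lnc = 50L) {
  metrics <- metrics %||% compute_metrics(network)
  four <- c("degree", "betweenness", "closeness", "pagerank")
  strata <- list(protein_coding = top_pc, lncRNA = top_lnc)
  picks <- list()
  for (bt in names(strata)) {
    sub <- metrics[metrics$biotype == bt, , drop = FALSE]
    if (nrow(sub) == 0L) next
    k <- min(strata[[bt]], nrow(sub))
    for (m in four) {
      sel <- top_k_ids(sub, m, four, k)
      picks[[length(picks) + 1L]] <- tibble(gene_id = sel, biotype = bt,
                                            metric = m)
    }
  }
  picks <- dplyr::bind_rows(picks)
  out <- picks |>
    group_by(.data$gene_id, .data$biotype) |>
    summarise(selected_by = paste(sort(unique(.data$metric)),
                                  collapse = ","), .groups = "drop") |>
    mutate(essential = TRUE) |>
    arrange(.data$biotype, .data$gene_id)
  structure(out, class = c("essential_selection", class(out)),
            top_pc = top_pc, top_lnc = top_lnc)
}

# Rank descending by `metric`; ties broken by mean rank over the other
# metrics, then lexicographic id.
top_k_ids <- function(tab, metric, all_metrics, k) {
  others <- setdiff(all_metrics, metric)
  other_rank <- rowMeans(vapply(others,
                                function(m) rank(-tab[[m]], ties.method = "average"),
                                numeric(nrow(tab))))
  ord <- order(-tab[[metric]], other_rank, tab$gene_id)
  tab$gene_id[ord[seq_len(k)]]
}

#' Identify master regulators on the essential-gene subnetwork
#'
#' Extracts the induced subgraph on the essential genes, recomputes five
#' metrics on it (stress, degree, betweenness, closeness, neighborhood
#' connectivity) and takes the union of the top `top_k` nodes per metric
#' (same tie rule as [select_essential()]) as master regulators — nodes
#' regulating the regulators. The result can contain at most `5 * top_k`
#' genes.
#'
#' @param network The full `gene_network`.
#' @param essential An `essential_selection` from [select_essential()].
#' @param top_k Per-metric cutoff (default 5).
#' @return The completed `essential_selection` with columns `master`
#'   (logical) and `master_selected_by`; the subnetwork metric table is
#'   attached as attribute `subnetwork_metrics`.
#' @export
master_regulators <- function(network, essential, top_k = 5L) {
  if (nrow(essential) == 0L) stop_bad_arg("essential set is empty")
  g <- network$graph
  idx <- which(igraph::V(g)$name %in% essential$gene_id)
  sub <- gene_network_from_graph(igraph::induced_subgraph(g, idx),
                                 network$condition, network$cutoff)
  met <- compute_metrics(sub)
  five <- c("stress", "degree", "betweenness", "closeness",
            "neighborhood_connectivity")
  k <- min(top_k, nrow(met))
  picks <- purrr::map(five, function(m)
    tibble(gene_id = top_k_ids(met, m, five, k), metric = m)) |>
    dplyr::bind_rows()
  prov <- picks |>
    group_by(.data$gene_id) |>
    summarise(master_selected_by = paste(sort(unique(.data$metric)),
                                         collapse = ","), .groups = "drop")
  out <- essential |>
    left_join(prov, by = "gene_id") |>
    mutate(master = !is.na(.data$master_selected_by))
  structure(out, class = class(essential),
            top_pc = attr(essential, "top_pc"),
            top_lnc = attr(essential, "top_lnc"),
            subnetwork_metrics = met)
}

#' Protein-coding targets of a lncRNA
#'
#' Direct network neighbors of the given lncRNA with biotype
#' `protein_coding`, with the connecting edge weights.
#'
#' @param network A `gene_network`.
#' @param lnc_id A lncRNA gene id present in the network.
#' @return Tibble `gene_id`, `weight`, sorted by `|weight|` descending.
#' @export
lncrna_targets <- function(network, lnc_id) {
  g <- network$graph
  v <- which(igraph::V(g)$name == lnc_id)
  if (length(v) == 0L) stop_bad_arg(paste0(lnc_id, " not in network"))
  inc <- igraph::incident(g, v)
  if (length(inc) == 0L) {
    return(tibble(gene_id = character(), weight = numeric()))
  }
  ends <- igraph::ends(g, inc)
  nb <- ifelse(ends[, 1] == lnc_id, ends[, 2], ends[, 1])
  bt <- network$nodes$biotype[match(nb, network$nodes$gene_id)]
  out <- tibble(gene_id = nb, weight = igraph::E(g)$weight[as.integer(inc)])
  out[bt == "protein_coding", ] |> arrange(desc(abs(.data$weight)))
}

#' Over-representation of a gene list in gene sets
#'
#' One-sided hypergeometric test per gene set against the universe, BH
#' adjusted across sets; fold enrichment is the observed/expected overlap
#' ratio. An empty overlap gives p = 1.
#'
#' @param gene_list Character vector (must be a subset of `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all eligible genes.
#' @return Tibble per set: overlap counts, `fold_enrichment`, `p_value`,
#'   `fdr`.
#' @export
enrich_targets <- function(gene_list, gene_sets, universe) {
  if (!all(gene_list %in% universe)) {
    stop_bad_arg("gene_list must be contained in the universe")
  }
  n_u <- length(unique(universe))
  n_l <- length(unique(gene_list))
  rows <- purrr::imap(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(gene_list, set))
    expected <- n_l * length(set) / n_u
    tibble(gene_set = nm, set_size = length(set), overlap = k,
           fold_enrichment = if (expected > 0) k / expected else NA_real_,
           p_value = phyper(k - 1, length(set), n_u - length(set), n_l,
                            lower.tail = FALSE))
  })
  dplyr::bind_rows(rows) |>
    mutate(fdr = bh_adjust(.data$p_value)) |>
    arrange(.data$p_value)
}

#' -log10 enrichment matrix across multiple gene lists
#'
#' Runs [enrich_targets()] for each list (e.g. the targets of each
#' regulatory lncRNA) and assembles the `-log10(p)` matrix used for
#' two-way-clustered enrichment heatmaps.
#'
#' @param gene_lists Named list of character vectors.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector.
#' @return Matrix gene sets x lists of `-log10(p)`.
#' @export
enrichment_matrix <- function(gene_lists, gene_sets, universe) {
  cols <- purrr::map(gene_lists, function(gl) {
    e <- enrich_targets(intersect(gl, universe), gene_sets, universe)
    stats::setNames(-log10(pmax(e$p_value, 1e-300)), e$gene_set)
  })
  sets <- names(gene_sets)
  out <- matrix(unlist(lapply(cols, function(cc) cc[sets])),
                nrow = length(sets),
                dimnames = list(sets, names(gene_lists)))
  out
}

#' Export a network as Cytoscape.js JSON
#'
#' Nodes carry biotype, module and metric attributes plus
#' `essential`/`master` flags from the selection; edges carry signed
#' weights. The file round-trips through [import_cytoscape_json()] exactly.
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @param selection Optional `essential_selection`.
#' @param metrics Optional metric tibble to embed.
#' @param modules Optional module tibble from [detect_modules()].
#' @return `path`, invisibly.
#' @export
export_cytoscape_json <- function(network, path, selection = NULL,
                                  metrics = NULL, modules = NULL) {
  nodes <- network$nodes
  if (!is.null(metrics)) nodes <- left_join(nodes, metrics,
                                            by = c("gene_id", "biotype"))
  if (!is.null(modules)) nodes <- left_join(nodes, modules, by = "gene_id")
  if (!is.null(selection)) {
    sel <- selection |>
      select("gene_id", "essential",
             dplyr::any_of(c("master", "selected_by", "master_selected_by")))
    nodes <- left_join(nodes, sel, by = "gene_id") |>
      mutate(essential = !is.na(.data$essential) & .data$essential)
    if ("master" %in% names(nodes)) {
      nodes$master <- !is.na(nodes$master) & nodes$master
    }
  }
  node_elems <- purrr::pmap(nodes, function(gene_id, ...) {
    list(data = c(list(id = gene_id), purrr::discard(list(...), is.na)))
  })
  g <- network$graph
  ee <- igraph::as_data_frame(g, what = "edges")
  edge_elems <- purrr::pmap(ee, function(from, to, weight, ...) {
    list(data = list(id = paste0(from, "|", to), source = from,
                     target = to, weight = weight))
  })
  jsonlite::write_json(
    list(elements = list(nodes = node_elems, edges = edge_elems),
         data = list(condition = network$condition,
                     cutoff = network$cutoff)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Import a network from Cytoscape.js JSON
#'
#' @param path JSON file written by [export_cytoscape_json()].
#' @return A `gene_network` (node attributes restored onto the tibble).
#' @export
import_cytoscape_json <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- purrr::map(obj$elements$nodes, function(nd) {
    as_tibble(nd$data[!vapply(nd$data, is.null, logical(1))]) |>
      dplyr::rename(gene_id = "id")
  }) |> dplyr::bind_rows()
  edges <- purrr::map(obj$elements$edges, function(ed) {
    tibble(from = ed$data$source, to = ed$data$target,
           weight = ed$data$weight)
  }) |> dplyr::bind_rows()
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(from = character(),
                                           to = character(),
                                           weight = numeric()),
    directed = FALSE,
    vertices = data.frame(
      name = nodes$gene_id,
      biotype = nodes$biotype %||% rep("unknown", nrow(nodes))))
  out <- gene_network_from_graph(g, obj$data$condition %||% NA_character_,
                                 obj$data$cutoff %||% NA_real_)
  out$nodes <- nodes
  out
}
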