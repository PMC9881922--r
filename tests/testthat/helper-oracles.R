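# Independent brute-force oracles and random fixture generators. These are
# deliberately naive re-derivations (per-base scans, all-pairs path counting,
# direct enumeration) kept free of the package's interval/graph code paths.

# ---- random toy genomes ----------------------------------------------------

# Random gene models on one chromosome, overlaps allowed, <= 50 kb.
random_toy_genome <- function(n_genes = 20L, len = 20000L) {
  rows <- lapply(seq_len(n_genes), function(i) {
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(0:(len - 400L), n_ex))
    widths <- sample(50:300, n_ex, replace = TRUE)
    ex <- data.frame(start = starts, end = pmin(starts + widths, len))
    # merge overlapping exons the dumb way
    ex <- ex[order(ex$start), ]
    merged <- ex[1, ]
    for (r in seq_len(nrow(ex))[-1]) {
      if (ex$start[r] <= merged$end[nrow(merged)]) {
        merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], ex$end[r])
      } else merged <- rbind(merged, ex[r, ])
    }
    tibble::tibble(
      gene_id = sprintf("g%03d", i), chrom = "chr1",
      strand = sample(c("+", "-"), 1),
      biotype = sample(c("protein_coding", "lncRNA"), 1),
      span_start = min(merged$start), span_end = max(merged$end),
      exons = list(tibble::as_tibble(merged)))
  })
  dplyr::bind_rows(rows)
}

# Per-base territory assignment by scanning every base against the rules:
# a base belongs to the unique gene with an exon there, else to the unique
# gene whose span covers it, else to no gene. Returns an integer vector per
# strand (0 = unassigned/ambiguous, i = gene row index).
oracle_base_assignment <- function(genes, len) {
  out <- list()
  for (st in c("+", "-")) {
    idx <- which(genes$strand == st)
    exon_count <- integer(len); exon_owner <- integer(len)
    span_count <- integer(len); span_owner <- integer(len)
    for (i in idx) {
      sp <- (genes$span_start[i] + 1L):genes$span_end[i]
      span_count[sp] <- span_count[sp] + 1L
      span_owner[sp] <- i
      ex <- genes$exons[[i]]
      for (r in seq_len(nrow(ex))) {
        b <- (ex$start[r] + 1L):ex$end[r]
        exon_count[b] <- exon_count[b] + 1L
        exon_owner[b] <- i
      }
    }
    assign <- integer(len)
    one_ex <- exon_count == 1L
    assign[one_ex] <- exon_owner[one_ex]
    intronic <- exon_count == 0L & span_count == 1L
    assign[intronic] <- span_owner[intronic]
    out[[st]] <- assign
  }
  out
}

# Per-base vector implied by remodel_full_gene_body() territories.
territories_to_bases <- function(territories, genes, len) {
  out <- list()
  for (st in c("+", "-")) {
    assign <- integer(len)
    idx <- which(territories$strand == st)
    for (i in idx) {
      row <- match(territories$gene_id[i], genes$gene_id)
      terr <- territories$territory[[i]]
      for (r in seq_len(nrow(terr))) {
        b <- (terr$start[r] + 1L):terr$end[r]
        assign[b] <- row
      }
    }
    out[[st]] <- assign
  }
  out
}

# ---- graph centrality oracles ----------------------------------------------

random_graph_adj <- function(n, p = 0.15) {
  a <- matrix(runif(n * n) < p, n, n)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  a <- a | t(a)
  a
}

# All-pairs shortest-path distances and path counts by plain dynamic
# programming on the adjacency matrix.
oracle_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- d[i, k] + d[k, ]
    upd <- nd < d[i, ]
    d[i, upd] <- nd[upd]
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  list(d = d, sigma = sigma)
}

oracle_centralities <- function(adj) {
  n <- nrow(adj)
  o <- oracle_paths(adj)
  btw <- numeric(n); stress <- numeric(n); closeness <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(o$d[s, t])) next
      if (o$d[s, v] + o$d[v, t] == o$d[s, t]) {
        paths_thru <- o$sigma[s, v] * o$sigma[v, t]
        stress[v] <- stress[v] + paths_thru
        btw[v] <- btw[v] + paths_thru / o$sigma[s, t]
      }
    }
    reach <- is.finite(o$d[v, ]) & o$d[v, ] > 0
    closeness[v] <- sum(1 / o$d[v, reach])
  }
  list(betweenness = btw, stress = stress, closeness = closeness,
       degree = rowSums(adj))
}

adj_to_network <- function(adj, biotype = NULL) {
  n <- nrow(adj)
  ids <- sprintf("n%02d", seq_len(n))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- if (nrow(idx) > 0) {
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]], weight = 1)
  } else {
    data.frame(from = character(), to = character(), weight = numeric())
  }
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(
      name = ids,
      biotype = biotype %||% rep("protein_coding", n)))
  lobulex:::gene_network_from_graph(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- small statistical oracles ---------------------------------------------

# Step-up BH from first principles: q_i = min_{j: p_j >= p_i} m * p_j / rank_j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (r in rev(seq_len(m))) {
    running <- min(running, m * p[ord[r]] / r)
    q[ord[r]] <- running
  }
  pmin(q, 1)
}

# Upper hypergeometric tail by direct summation of choose() terms.
oracle_hyper_tail <- function(k, set_size, universe, draw) {
  j <- k:min(set_size, draw)
  sum(choose(set_size, j) * choose(universe - set_size, draw - j)) /
    choose(universe, draw)
}

# ---- shared fixtures ---------------------------------------------------------

# The default synthetic world is expensive (~1 min); build it once per test
# run and memoize.
default_sim_env <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(default_sim_env$sim)) {
    default_sim_env$sim <- simulate_counts(sim_config(seed = 20260918 %% 1000))
  }
  default_sim_env$sim
}

# A small, fast world for unit tests.
small_config <- function(seed = 5, ...) {
  defaults <- list(
    seed = seed,
    cells_per_type_per_condition = list(
      "Hep-PC" = c(70L, 70L), "Hep-PP" = c(60L, 60L),
      "Endothelial" = c(30L, 30L), "Kupffer" = c(30L, 30L),
      "Stellate" = c(20L, 20L), "Cholangiocyte" = c(20L, 20L),
      "B" = c(20L, 20L), "T" = c(20L, 20L)),
    n_genes_pc = 600L, n_genes_lnc = 320L,
    zonated_gene_count = 40L, zonation_disrupted_count = 10L,
    de_gene_count = 40L, n_markers_per_type = 10L,
    hub_spec = tibble::tibble(
      regulator = c("hub_pc_super", "hub_lnc_1"),
      biotype = c("protein_coding", "lncRNA"),
      n_targets = c(30L, 25L), strength = c(0.8, 0.8),
      condition = c("both", "both"), super = c(TRUE, FALSE)))
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  do.call(sim_config, defaults)
}

# Minimal single-gene model row used across test files.
gene_row <- function(id, strand, exons, chrom = "chr1",
                     biotype = "protein_coding") {
  ex <- tibble::tibble(start = sapply(exons, `[`, 1),
                       end = sapply(exons, `[`, 2))
  tibble::tibble(gene_id = id, chrom = chrom, strand = strand,
                 biotype = biotype, span_start = min(ex$start),
                 span_end = max(ex$end), exons = list(ex))
}
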