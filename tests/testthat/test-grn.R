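norm_matrix_from <- function(values, biotype = NULL) {
  rownames(values) <- sprintf("c%03d", seq_len(nrow(values)))
  colnames(values) <- colnames(values) %||%
    sprintf("g%03d", seq_len(ncol(values)))
  bt <- biotype %||% rep("protein_coding", ncol(values))
  x <- cell_matrix(matrix(1L, nrow(values), ncol(values),
                          dimnames = dimnames(values)),
                   tibble::tibble(barcode = rownames(values)),
                   tibble::tibble(gene_id = colnames(values), biotype = bt,
                                  mito = FALSE))
  x$norm <- methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  x
}

test_that("the edge cutoff keeps the top quantile of |correlation|", {
  withr::local_seed(21)
  # quantile 0: complete graph
  v <- matrix(rnorm(60 * 10), 60, 10) + 2
  x <- norm_matrix_from(v)
  net0 <- build_network(x, quantile = 0, min_cells_expressed = 1)
  expect_equal(igraph::ecount(net0$graph), choose(10, 2))

  # 1,000 independent genes at quantile 0.999: ~0.1% of 499,500 pairs
  v2 <- matrix(rnorm(120 * 1000), 120, 1000) + 3
  net <- build_network(norm_matrix_from(v2), quantile = 0.999,
                       min_cells_expressed = 1)
  expect_gte(igraph::ecount(net$graph), 400)
  expect_lte(igraph::ecount(net$graph), 600)
  expect_error(build_network(norm_matrix_from(v2[1:10, ])), "50 cells")
})

test_that("a planted hub with strength 0.8 keeps most hub-target edges", {
  withr::local_seed(22)
  n <- 500
  z <- rnorm(n)
  g_bg <- 550
  vals <- matrix(rnorm(n * g_bg), n, g_bg)
  # hub-centric module: hub correlates 0.8 with each target, targets 0.64
  # with each other, so the adaptive cutoff keeps the star edges
  targets <- vapply(1:50, function(j) 0.8 * z + sqrt(1 - 0.8 ^ 2) * rnorm(n),
                    numeric(n))
  v <- cbind(z, targets, vals) + 4
  colnames(v) <- c("hub", sprintf("t%02d", 1:50), sprintf("bg%03d", 1:g_bg))
  bt <- c("lncRNA", rep("protein_coding", 50 + g_bg))
  net <- build_network(norm_matrix_from(v, biotype = bt), quantile = 0.999,
                       min_cells_expressed = 1)
  tg <- lncrna_targets(net, "hub")
  expect_gte(sum(sprintf("t%02d", 1:50) %in% tg$gene_id), 45)
  # symmetry of the neighbor relation
  other_end <- igraph::neighbors(net$graph, tg$gene_id[1])$name
  expect_true("hub" %in% other_end)
})

test_that("regulator subsetting keeps regulators and their neighbors only", {
  # star: regulator hub with 6 leaves, plus an isolated pair elsewhere
  edges <- data.frame(from = c(rep("R", 6), "x1"),
                      to = c(sprintf("l%d", 1:6), "x2"),
                      weight = 0.9)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c("R", sprintf("l%d", 1:6), "x1", "x2"),
                          biotype = "protein_coding"))
  net <- lobulex:::gene_network_from_graph(g)
  sub <- regulator_subset(net, "R")
  expect_setequal(sub$nodes$gene_id, c("R", sprintf("l%d", 1:6)))
  # idempotent and never growing
  sub2 <- regulator_subset(sub, "R")
  expect_setequal(sub2$nodes$gene_id, sub$nodes$gene_id)
  expect_warning(empty <- regulator_subset(net, "absent"), "no regulator")
  expect_equal(nrow(empty$nodes), 0)

  # oracle: retained set equals a brute-force adjacency scan
  withr::local_seed(23)
  for (rep in 1:10) {
    adj <- random_graph_adj(15, 0.2)
    net_r <- adj_to_network(adj)
    regs <- sample(net_r$nodes$gene_id, 3)
    keep <- vapply(seq_len(15), function(i) {
      id <- net_r$nodes$gene_id[i]
      id %in% regs || any(adj[i, net_r$nodes$gene_id %in% regs])
    }, logical(1))
    sub_r <- regulator_subset(net_r, regs)
    expect_setequal(sub_r$nodes$gene_id, net_r$nodes$gene_id[keep])
  }
})

test_that("module detection matches planted communities and is deterministic", {
  # two disjoint cliques
  blocks <- function(sizes, p_in = 1, p_out = 0) {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (lab[i] == lab[j]) p_in else p_out
      adj[i, j] <- adj[j, i] <- runif(1) < p
    }
    list(adj = adj, lab = lab)
  }
  withr::local_seed(24)
  two <- blocks(c(6, 6))
  net <- adj_to_network(two$adj)
  mods <- detect_modules(net, seed = 2)
  expect_equal(lobulex:::adjusted_rand_index(mods$module, two$lab), 1)
  expect_identical(mods, detect_modules(net, seed = 2))

  five <- blocks(c(8, 8, 8, 8, 8), p_in = 0.9, p_out = 0.02)
  net5 <- adj_to_network(five$adj)
  mods5 <- detect_modules(net5, seed = 3)
  expect_gte(lobulex:::adjusted_rand_index(mods5$module, five$lab), 0.9)
})

test_that("centrality metrics match closed forms and the brute-force oracle", {
  # path a-b-c
  path <- adj_to_network(matrix(c(FALSE, TRUE, FALSE,
                                  TRUE, FALSE, TRUE,
                                  FALSE, TRUE, FALSE), 3, 3))
  met <- compute_metrics(path)
  expect_equal(met$betweenness, c(0, 1, 0))
  expect_equal(met$stress, c(0, 1, 0))
  expect_equal(met$closeness, c(1.5, 2, 1.5))

  # star with 6 leaves: hub degree 6, leaf neighborhood connectivity 6
  n <- 7
  adj <- matrix(FALSE, n, n); adj[1, 2:n] <- adj[2:n, 1] <- TRUE
  star <- adj_to_network(adj)
  ms <- compute_metrics(star)
  expect_equal(ms$degree[1], 6)
  expect_equal(ms$neighborhood_connectivity[2:n], rep(6, 6))
  expect_equal(ms$pagerank |> sum(), 1, tolerance = 1e-9)

  withr::local_seed(25)
  for (rep in 1:10) {
    adj <- random_graph_adj(sample(8:20, 1), 0.2)
    net <- adj_to_network(adj)
    met <- compute_metrics(net)
    oracle <- oracle_centralities(adj)
    expect_equal(met$degree, oracle$degree)
    expect_equal(met$betweenness, oracle$betweenness, tolerance = 1e-9)
    expect_equal(met$stress, oracle$stress)
    expect_equal(met$closeness, oracle$closeness, tolerance = 1e-9)
  }
})

test_that("essential selection unions the per-metric top lists with the tie rule", {
  fake_metrics <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:12),
    biotype = "protein_coding",
    degree = c(12:1), betweenness = c(1:12),
    closeness = runif(12), pagerank = runif(12))
  # k larger than n: everything is essential
  all_in <- select_essential(NULL, fake_metrics, top_pc = 100)
  expect_equal(nrow(all_in), 12)

  # disjoint winners: 4 metrics, top-1 each, all different genes
  dm <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"), biotype = "protein_coding",
    degree = c(10, 1, 1, 1), betweenness = c(1, 10, 1, 1),
    closeness = c(1, 1, 10, 1), pagerank = c(1, 1, 1, 10))
  sel <- select_essential(NULL, dm, top_pc = 1)
  expect_equal(nrow(sel), 4)
  expect_equal(sel$selected_by[sel$gene_id == "a"], "degree")

  # ties at the boundary resolve by mean other-metric rank then id
  tie <- tibble::tibble(
    gene_id = c("z", "y", "x"), biotype = "protein_coding",
    degree = c(5, 5, 5), betweenness = c(3, 2, 1),
    closeness = c(3, 2, 1), pagerank = c(3, 2, 1))
  sel2 <- select_essential(NULL, tie, top_pc = 1)
  expect_true("z" %in% sel2$gene_id[grepl("degree", sel2$selected_by)])
})

test_that("master regulators are the top-5 union on the essential subnetwork", {
  # a single star: hub wins every recomputed metric except neighborhood
  # connectivity
  n <- 9
  adj <- matrix(FALSE, n, n); adj[1, 2:n] <- adj[2:n, 1] <- TRUE
  star <- adj_to_network(adj)
  ess <- select_essential(star, compute_metrics(star), top_pc = 100)
  ms <- master_regulators(star, ess)
  hub <- ms[ms$gene_id == "n01", ]
  expect_true(hub$master)
  sel <- strsplit(hub$master_selected_by, ",")[[1]]
  expect_setequal(setdiff(c("stress", "degree", "betweenness", "closeness"),
                          sel), character(0))
  expect_lte(sum(ms$master), 25)
})

test_that("over-representation matches the hypergeometric oracle and calibrates", {
  universe <- sprintf("u%04d", 1:1000)
  set <- universe[1:20]
  res <- enrich_targets(set, list(S = set), universe)
  expect_equal(res$p_value, oracle_hyper_tail(20, 20, 1000, 20),
               tolerance = 1e-12)
  # empty overlap: p = 1 under the one-sided convention
  res0 <- enrich_targets(universe[900:950], list(S = set), universe)
  expect_equal(res0$p_value, 1)
  expect_error(enrich_targets("nope", list(S = set), universe), "universe")

  withr::local_seed(26)
  sets <- lapply(1:40, function(i) sample(universe, 50))
  names(sets) <- sprintf("s%02d", 1:40)
  hits <- unlist(lapply(1:10, function(b) {
    gl <- sample(universe, 60)
    enrich_targets(gl, sets, universe)$p_value < 0.05
  }))
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.09)

  em <- enrichment_matrix(list(a = set, b = universe[21:40]),
                          gene_sets = list(S = set), universe = universe)
  expect_equal(dim(em), c(1L, 2L))
  expect_gt(em["S", "a"], em["S", "b"])
})

test_that("Cytoscape JSON export round-trips the network with its flags", {
  withr::local_seed(27)
  adj <- random_graph_adj(12, 0.3)
  net <- adj_to_network(adj, biotype = sample(c("protein_coding", "lncRNA"),
                                              12, replace = TRUE))
  igraph::E(net$graph)$weight <- runif(igraph::ecount(net$graph), -1, 1)
  met <- compute_metrics(net)
  ess <- select_essential(net, met, top_pc = 3, top_lnc = 2)
  ms <- master_regulators(net, ess, top_k = 2)
  mods <- detect_modules(net, seed = 1, min_size = 1)
  f <- withr::local_tempfile(fileext = ".json")
  export_cytoscape_json(net, f, selection = ms, metrics = met,
                        modules = mods)
  back <- import_cytoscape_json(f)
  expect_setequal(back$nodes$gene_id, net$nodes$gene_id)
  e_orig <- igraph::as_data_frame(net$graph)
  e_back <- igraph::as_data_frame(back$graph)
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_setequal(key(e_back), key(e_orig))
  expect_equal(sort(e_back$weight), sort(e_orig$weight), tolerance = 1e-12)
  # every master node carries master = TRUE in the file
  masters <- ms$gene_id[ms$master]
  expect_true(all(back$nodes$master[back$nodes$gene_id %in% masters]))

  empty <- lobulex:::gene_network_from_graph(
    igraph::make_empty_graph(0, directed = FALSE))
  f2 <- withr::local_tempfile(fileext = ".json")
  export_cytoscape_json(empty, f2)
  expect_silent(jsonlite::read_json(f2))

  # isolated lncRNA has no targets
  iso <- adj_to_network(matrix(FALSE, 2, 2), biotype = c("lncRNA", "lncRNA"))
  expect_equal(nrow(lncrna_targets(iso, "n01")), 0)
})
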