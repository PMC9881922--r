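#' Simulate a toy genome annotation with overlapping genes
#'
#' Generates gene models on a small number of chromosomes with
#' protein-coding, lncRNA and mitochondrial biotypes, including same-strand
#' overlapping gene pairs (a partner gene nested in a host gene's intron, the
#' configuration the full-gene-body remodeling must resolve) and
#' opposite-strand overlapping pairs (which remodeling must leave alone).
#' Output is deterministic given `config$seed`.
#'
#' The overlapping pairs are drawn from the configured gene budget, so the
#' total number of genes equals `n_genes_pc + n_genes_lnc + n_mito`.
#'
#' @param config A [sim_config()].
#' @param n_same_strand_overlaps Number of same-strand overlapping pairs.
#' @param n_opposite_overlaps Number of opposite-strand overlapping pairs.
#' @param chromosomes Chromosome names for nuclear genes; mitochondrial genes
#'   go on `"chrM"`.
#' @return A gene-model tibble (see [load_gtf()]).
#' @export
simulate_annotation <- function(config,
                                n_same_strand_overlaps = 5L,
                                n_opposite_overlaps = 2L,
                                chromosomes = c("chr1", "chr2", "chr3")) {
  stopifnot(inherits(config, "sim_config"))
  n_pc <- config$n_genes_pc
  n_lnc <- config$n_genes_lnc
  n_mito <- config$n_mito
  n_nuclear <- n_pc + n_lnc
  n_pairs <- n_same_strand_overlaps + n_opposite_overlaps
  if (2L * n_pairs > n_nuclear) {
    stop_bad_arg("not enough nuclear genes to host the requested overlaps")
  }
  with_seed(config$seed + 101L, {
    ids <- c(sprintf("pc_%04d", seq_len(n_pc)),
             sprintf("lnc_%04d", seq_len(n_lnc)))
    biotypes <- c(rep("protein_coding", n_pc), rep("lncRNA", n_lnc))
    ord <- sample.int(n_nuclear)
    ids <- ids[ord]
    biotypes <- biotypes[ord]

    rows <- vector("list", n_nuclear + n_mito)
    cursor <- stats::setNames(rep(0L, length(chromosomes)), chromosomes)
    chrom_of <- function(i) chromosomes[((i - 1L) %% length(chromosomes)) + 1L]
    gi <- 1L
    ri <- 1L
    # Overlapping pairs first: host gene with two exons and a long intron,
    # partner nested fully inside the intron.
    for (p in seq_len(n_pairs)) {
      chrom <- chrom_of(p)
      host_strand <- sample(c("+", "-"), 1L)
      same <- p <= n_same_strand_overlaps
      partner_strand <- if (same) host_strand else setdiff(c("+", "-"), host_strand)
      start <- cursor[chrom] + sample(200:800, 1L)
      e1 <- sample(150:400, 1L)
      intron <- sample(1500:3000, 1L)
      e2 <- sample(150:400, 1L)
      ex_start <- c(start, start + e1 + intron)
      ex_end <- c(start + e1, start + e1 + intron + e2)
      host_ex <- tibble(start = ex_start, end = ex_end)
      rows[[ri]] <- tibble(
        gene_id = ids[gi], chrom = chrom, strand = host_strand,
        biotype = biotypes[gi],
        span_start = min(host_ex$start), span_end = max(host_ex$end),
        exons = list(host_ex))
      gi <- gi + 1L; ri <- ri + 1L
      p_len <- sample(300:800, 1L)
      p_start <- start + e1 + sample(100:300, 1L)
      p_ex <- tibble(start = p_start, end = p_start + p_len)
      rows[[ri]] <- tibble(
        gene_id = ids[gi], chrom = chrom, strand = partner_strand,
        biotype = biotypes[gi],
        span_start = p_start, span_end = p_start + p_len,
        exons = list(p_ex))
      gi <- gi + 1L; ri <- ri + 1L
      cursor[chrom] <- max(host_ex$end)
    }
    # Remaining nuclear genes: disjoint placement (coordinates never overlap,
    # on either strand), 1-4 exons each.
    k <- 0L
    while (gi <= n_nuclear) {
      k <- k + 1L
      chrom <- chrom_of(n_pairs + k)
      n_ex <- sample(1:4, 1L)
      ex_len <- sample(100:400, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1L) sample(200:900, n_ex - 1L, replace = TRUE) else integer()
      start <- cursor[chrom] + sample(200:800, 1L)
      starts <- start + cumsum(c(0L, head(ex_len, -1L) + gaps))
      ex <- tibble(start = starts, end = starts + ex_len)
      rows[[ri]] <- tibble(
        gene_id = ids[gi], chrom = chrom,
        strand = sample(c("+", "-"), 1L), biotype = biotypes[gi],
        span_start = min(ex$start), span_end = max(ex$end),
        exons = list(ex))
      cursor[chrom] <- max(ex$end)
      gi <- gi + 1L; ri <- ri + 1L
    }
    # Mitochondrial genes: single-exon, tandem on chrM.
    mt_cursor <- 0L
    for (m in seq_len(n_mito)) {
      len <- sample(300:1200, 1L)
      start <- mt_cursor + sample(50:200, 1L)
      rows[[ri]] <- tibble(
        gene_id = sprintf("mt_%02d", m), chrom = "chrM", strand = "+",
        biotype = "mitochondrial",
        span_start = start, span_end = start + len,
        exons = list(tibble(start = start, end = start + len)))
      mt_cursor <- start + len
      ri <- ri + 1L
    }
    dplyr::bind_rows(rows) |>
      arrange(.data$chrom, .data$span_start, .data$gene_id)
  })
}

#' Simulate stranded reads from gene territories
#'
#' Samples single-end reads from the exonic and intronic regions of source
#' genes in a configurable proportion, emulating the large intronic
#' (pre-mRNA) read fraction of single-nucleus RNA-seq. Each read records its
#' true source gene so that downstream read-assignment can be scored against
#' ground truth. Reads lie entirely inside one region interval of their
#' source gene and carry its strand.
#'
#' For each read the exonic/intronic status is drawn first
#' (`Bernoulli(intron_fraction)`), then a source gene is drawn uniformly
#' among genes possessing a region of that type, so the marginal intronic
#' share equals `intron_fraction`. Genes whose territory cannot host a read
#' (no intron when an intronic read is requested) are never chosen; a gene
#' with an empty span is skipped with a warning.
#'
#' @param genes Gene-model tibble.
#' @param config A [sim_config()]; supplies the RNG seed.
#' @param n_reads Number of reads.
#' @param intron_fraction Fraction of reads drawn from intronic sequence.
#' @param read_length Read length in bases (truncated to the host interval).
#' @param barcodes Character vector of cell barcodes to assign uniformly.
#' @return A tibble `chrom`, `start`, `end`, `strand`, `barcode`,
#'   `true_gene`, `intronic`.
#' @export
simulate_reads <- function(genes, config, n_reads = 10000L,
                           intron_fraction = 0.3, read_length = 90L,
                           barcodes = sprintf("BC%03d", 1:24)) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(genes) == 0L) stop_bad_arg("no genes to simulate reads from")
  empty <- vapply(genes$exons, nrow, integer(1)) == 0L
  if (any(empty)) {
    warn(paste0("skipping ", sum(empty), " gene(s) with empty territory"))
    genes <- genes[!empty, ]
  }
  introns <- purrr::pmap(genes, function(span_start, span_end, exons, ...) {
    from_iranges(BiocGenerics::setdiff(to_iranges(span_start, span_end),
                                       to_iranges(exons$start, exons$end)))
  })
  has_intron <- vapply(introns, nrow, integer(1)) > 0L
  with_seed(config$seed + 202L, {
    intronic <- runif(n_reads) < intron_fraction
    if (any(intronic) && !any(has_intron)) {
      stop_bad_arg("intronic reads requested but no gene has an intron")
    }
    src <- integer(n_reads)
    src[!intronic] <- sample(nrow(genes), sum(!intronic), replace = TRUE)
    src[intronic] <- sample(which(has_intron), sum(intronic), replace = TRUE)
    regions <- purrr::map(seq_len(n_reads), function(i) {
      if (intronic[i]) introns[[src[i]]] else genes$exons[[src[i]]]
    })
    picked <- purrr::map(regions, function(reg) {
      w <- reg$end - reg$start
      j <- sample.int(nrow(reg), 1L, prob = w)
      len <- min(read_length, w[j])
      s <- reg$start[j] + sample.int(w[j] - len + 1L, 1L) - 1L
      c(s, s + len)
    })
    picked <- do.call(rbind, picked)
    tibble(
      chrom = genes$chrom[src],
      start = as.integer(picked[, 1]),
      end = as.integer(picked[, 2]),
      strand = genes$strand[src],
      barcode = sample(barcodes, n_reads, replace = TRUE),
      true_gene = genes$gene_id[src],
      intronic = intronic
    )
  })
}

#' Write a read table as BED-like TSV
#'
#' Six columns without header: chrom, start, end, barcode, true source gene,
#' strand (0-based half-open coordinates, as in BED).
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  readr::write_tsv(reads[, c("chrom", "start", "end", "barcode",
                             "true_gene", "strand")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a BED-like read table written by [write_reads_bed()]
#'
#' @param path Input path.
#' @return Read tibble with columns `chrom`, `start`, `end`, `barcode`,
#'   `true_gene`, `strand`.
#' @export
read_reads_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "barcode",
                                "true_gene", "strand"),
                  col_types = "ciiccc", progress = FALSE)
}
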