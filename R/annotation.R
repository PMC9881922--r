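#' Load gene models from a GTF file
#'
#' Parses a GTF annotation into a tibble of gene models, one row per
#' `gene_id`. GTF coordinates (1-based, inclusive) are converted to the
#' package-internal convention (0-based, half-open). Exons of each gene are
#' sorted and merged so that overlapping or abutting exons collapse into
#' maximal disjoint intervals; the gene span is the interval from the first
#' exon start to the last exon end.
#'
#' Only `exon` feature rows contribute intervals; `gene` rows, if present,
#' are ignored (the span is always recomputed from exons). The attribute
#' column must carry `gene_id` and may carry `gene_biotype`.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `biotype`,
#'   `span_start`, `span_end` and a list-column `exons` of tibbles with
#'   0-based half-open `start`/`end`.
#' @export
load_gtf <- function(path) {
  if (!file.exists(path)) stop_bad_arg(paste0("GTF file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_gene_models())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad) > 0L) {
    stop_bad_arg(paste0("malformed GTF record (fewer than 9 fields) at line ",
                        line_no[bad[1]]))
  }
  feat <- vapply(fields, `[[`, "", 3L)
  is_exon <- feat == "exon"
  if (!any(is_exon)) return(empty_gene_models())
  fields <- fields[is_exon]
  line_no <- line_no[is_exon]
  attrs <- vapply(fields, `[[`, "", 9L)
  gene_id <- gtf_attr(attrs, "gene_id")
  if (anyNA(gene_id)) {
    stop_bad_arg(paste0("exon record without gene_id attribute at line ",
                        line_no[which(is.na(gene_id))[1]]))
  }
  biotype <- gtf_attr(attrs, "gene_biotype")
  biotype[is.na(biotype)] <- "unknown"
  ex <- tibble(
    gene_id = gene_id,
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,
    end = as.integer(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    biotype = biotype
  )
  if (any(ex$end <= ex$start)) {
    stop_bad_arg(paste0("exon with non-positive width at line ",
                        line_no[which(ex$end <= ex$start)[1]]))
  }
  per_gene <- split(ex, ex$gene_id)
  rows <- purrr::map(per_gene, function(g) {
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L) {
      stop_bad_arg(paste0(
        "gene ", g$gene_id[1],
        " has exons on multiple chromosomes or strands; not supported"))
    }
    merged <- from_iranges(IRanges::reduce(to_iranges(g$start, g$end)))
    tibble(
      gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
      biotype = g$biotype[1],
      span_start = min(merged$start), span_end = max(merged$end),
      exons = list(merged)
    )
  })
  dplyr::bind_rows(rows) |> arrange(.data$chrom, .data$span_start, .data$gene_id)
}

empty_gene_models <- function() {
  tibble(
    gene_id = character(), chrom = character(), strand = character(),
    biotype = character(), span_start = integer(), span_end = integer(),
    exons = list()
  )
}

gtf_attr <- function(attrs, key) {
  pat <- paste0(key, " \"([^\"]*)\"")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

#' Write gene models to a GTF file
#'
#' Emits one `gene` row and one `exon` row per exon interval for each gene,
#' converting internal 0-based half-open coordinates back to the GTF
#' convention. `load_gtf(write_gtf(x))` reproduces `x`.
#'
#' @param genes A gene-model tibble as returned by [load_gtf()] or
#'   [simulate_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- purrr::pmap(genes, function(gene_id, chrom, strand, biotype,
                                       span_start, span_end, exons, ...) {
    attr_str <- sprintf('gene_id "%s"; gene_biotype "%s";', gene_id, biotype)
    gene_line <- paste(chrom, "lobulex", "gene", span_start + 1L, span_end,
                       ".", strand, ".", attr_str, sep = "\t")
    exon_lines <- paste(chrom, "lobulex", "exon", exons$start + 1L, exons$end,
                        ".", strand, ".", attr_str, sep = "\t")
    c(gene_line, exon_lines)
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Remodel genes to full-gene-body counting territories
#'
#' Single-nucleus RNA-seq libraries carry abundant intronic (pre-mRNA)
#' signal, so reads are counted over the full gene body rather than exons
#' only. When two genes on the same strand overlap, the shared region must be
#' divided: each gene keeps its own exons plus the non-exonic (intronic or
#' flanking) parts of its span that no same-strand partner claims, so that a
#' read mapping to an exon of one gene inside an intron of the other is
#' counted for the exon's gene. Bases exonic in two same-strand genes, or
#' intronic in two same-strand genes, stay ambiguous and belong to no
#' territory. Opposite-strand overlap never modifies a territory, and a gene
#' with no same-strand overlap keeps its whole span.
#'
#' Equivalently, per strand each genomic base is assigned to: the unique gene
#' with an exon there; otherwise the unique gene whose span covers it;
#' otherwise no gene. Chains of more than two overlapping genes are resolved
#' by this base-level rule over all partners simultaneously.
#'
#' @param genes Gene-model tibble (see [load_gtf()]).
#' @return A tibble with `gene_id`, `chrom`, `strand`, `biotype` and a
#'   list-column `territory` of disjoint sorted 0-based half-open intervals.
#' @export
remodel_full_gene_body <- function(genes) {
  if (nrow(genes) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), biotype = character(),
                  territory = list()))
  }
  groups <- split(genes, paste(genes$chrom, genes$strand))
  out <- purrr::map(groups, remodel_group)
  dplyr::bind_rows(out) |> arrange(.data$chrom, .data$gene_id)
}

remodel_group <- function(g) {
  n <- nrow(g)
  ex_list <- purrr::map(g$exons, ~ to_iranges(.x$start, .x$end))
  sp_list <- purrr::map2(g$span_start, g$span_end, to_iranges)
  terr <- vector("list", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (length(others) == 0L) {
      terr[[i]] <- from_iranges(sp_list[[i]])
      next
    }
    others_ex <- IRanges::reduce(do.call(c, ex_list[others]))
    others_sp <- IRanges::reduce(do.call(c, sp_list[others]))
    own_ex <- BiocGenerics::setdiff(ex_list[[i]], others_ex)
    own_intronic <- BiocGenerics::setdiff(sp_list[[i]], others_sp)
    terr[[i]] <- from_iranges(IRanges::reduce(c(own_ex, own_intronic)))
  }
  tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
         biotype = g$biotype, territory = terr)
}

#' Write remodeled territories as a counting-ready GTF
#'
#' Each territory interval becomes one `exon` row so that any
#' exon-interval-based counter will count over the full (overlap-resolved)
#' gene body.
#'
#' @param territories Output of [remodel_full_gene_body()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_remodeled_gtf <- function(territories, path) {
  lines <- purrr::pmap(territories, function(gene_id, chrom, strand, biotype,
                                             territory, ...) {
    if (nrow(territory) == 0L) return(character())
    attr_str <- sprintf('gene_id "%s"; gene_biotype "%s";', gene_id, biotype)
    paste(chrom, "lobulex", "exon", territory$start + 1L, territory$end,
          ".", strand, ".", attr_str, sep = "\t")
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Validate an annotation manifest
#'
#' Checks per-biotype gene counts against an expected manifest and checks the
#' manifest's own arithmetic: a category may be given as a vector of parts
#' (their sum is the expected category count) and the expected total is the
#' sum over categories, optionally compared with a stated grand total.
#'
#' Mismatches are report rows, never errors.
#'
#' @param genes Gene-model tibble, or `NULL` to check only the manifest
#'   arithmetic.
#' @param expected Named list or vector: category -> expected count, or
#'   category -> vector of part counts summed to the expected count.
#' @param expected_total Optional stated grand total to compare against the
#'   sum of category expectations.
#' @return A tibble with columns `category`, `expected`, `observed`, `match`,
#'   including a `total` row, and attribute `pass` (also returned by
#'   `attr(x, "pass")`): `TRUE` iff all comparisons that could be made agree.
#' @export
validate_manifest <- function(genes, expected, expected_total = NULL) {
  cats <- names(expected)
  exp_counts <- vapply(expected, function(x) sum(as.numeric(x)), numeric(1))
  if (!is.null(genes)) {
    obs_tab <- table(genes$biotype)
    obs <- as.numeric(obs_tab[cats])
    obs[is.na(obs)] <- 0
    obs_total <- nrow(genes)
  } else {
    obs <- rep(NA_real_, length(cats))
    obs_total <- NA_real_
  }
  exp_total <- if (!is.null(expected_total)) expected_total else sum(exp_counts)
  report <- tibble(
    category = c(cats, "total"),
    expected = unname(c(exp_counts, sum(exp_counts))),
    observed = unname(c(obs, obs_total)),
    match = unname(c(
      ifelse(is.na(obs), NA, obs == exp_counts),
      if (is.na(obs_total)) sum(exp_counts) == exp_total else
        obs_total == exp_total && sum(exp_counts) == exp_total
    ))
  )
  pass <- all(report$match[!is.na(report$match)]) &&
    sum(exp_counts) == exp_total
  attr(report, "pass") <- pass
  report
}
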