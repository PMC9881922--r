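#' Assign reads to gene territories
#'
#' A read is assigned to gene G iff it overlaps (by at least one base) the
#' territory of G on the matching strand and overlaps no other same-strand
#' territory; a read overlapping two or more territories is `ambiguous`
#' (multi-gene reads are discarded by droplet counters) and a read
#' overlapping none is `unassigned`.
#'
#' @param reads Tibble with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open) and any further columns (carried through).
#' @param territories Output of [remodel_full_gene_body()].
#' @return `reads` with columns `gene_id` (NA unless assigned) and `status`
#'   (`assigned`/`ambiguous`/`unassigned`).
#' @export
assign_reads <- function(reads, territories) {
  if (any(reads$end <= reads$start)) {
    bad <- which(reads$end <= reads$start)[1]
    stop_bad_arg(paste0("malformed read (end <= start) at row ", bad))
  }
  terr_flat <- territories |>
    mutate(.gene_row = dplyr::row_number()) |>
    tidyr::unnest("territory")
  reads$gene_id <- NA_character_
  reads$n_hit <- 0L
  for (key in unique(paste(terr_flat$chrom, terr_flat$strand))) {
    tf <- terr_flat[paste(terr_flat$chrom, terr_flat$strand) == key, ]
    sel <- which(paste(reads$chrom, reads$strand) == key)
    if (length(sel) == 0L) next
    hits <- IRanges::findOverlaps(
      to_iranges(reads$start[sel], reads$end[sel]),
      to_iranges(tf$start, tf$end))
    if (length(hits) == 0L) next
    hit_gene <- territories$gene_id[tf$.gene_row[S4Vectors::subjectHits(hits)]]
    by_read <- split(hit_gene, S4Vectors::queryHits(hits))
    uq <- lapply(by_read, unique)
    ridx <- sel[as.integer(names(by_read))]
    reads$n_hit[ridx] <- lengths(uq)
    one <- lengths(uq) == 1L
    reads$gene_id[ridx[one]] <- unlist(uq[one])
  }
  reads$status <- dplyr::case_when(
    reads$n_hit == 1L ~ "assigned",
    reads$n_hit >= 2L ~ "ambiguous",
    TRUE ~ "unassigned")
  reads$gene_id[reads$status != "assigned"] <- NA_character_
  reads$n_hit <- NULL
  reads
}

#' Build a feature-barcode count matrix from assigned reads
#'
#' Entry (cell, gene) is the number of reads assigned to the gene carrying
#' that barcode. Reads whose barcode is not on the whitelist are counted as
#' `filtered`; the remainder partition exactly into assigned / ambiguous /
#' unassigned (the QC sidecar), so that matrix sum + ambiguous + unassigned
#' + filtered equals the number of input reads. Synthetic reads are treated
#' as deduplicated molecules (no UMI collapsing).
#'
#' @param reads Read tibble with a `barcode` column.
#' @param territories Output of [remodel_full_gene_body()].
#' @param barcodes Barcode whitelist defining matrix rows.
#' @return A [cell_matrix()] with attribute `qc` (tibble of read-fate
#'   counts: assigned, ambiguous, unassigned, filtered).
#' @export
build_matrix <- function(reads, territories, barcodes) {
  on_list <- reads$barcode %in% barcodes
  asn <- if (sum(on_list) > 0) {
    assign_reads(reads[on_list, , drop = FALSE], territories)
  } else {
    reads[on_list, , drop = FALSE] |>
      mutate(gene_id = character(), status = character())
  }
  gene_ids <- territories$gene_id
  ok <- asn$status == "assigned"
  counts <- Matrix::sparseMatrix(
    i = match(asn$barcode[ok], barcodes),
    j = match(asn$gene_id[ok], gene_ids),
    x = rep(1, sum(ok)),
    dims = c(length(barcodes), length(gene_ids)),
    dimnames = list(barcodes, gene_ids))
  qc <- tibble(
    assigned = sum(ok),
    ambiguous = sum(asn$status == "ambiguous"),
    unassigned = sum(asn$status == "unassigned"),
    filtered = sum(!on_list))
  out <- cell_matrix(
    counts,
    cell_meta = tibble(barcode = barcodes),
    gene_meta = tibble(gene_id = gene_ids,
                       biotype = territories$biotype,
                       mito = territories$biotype == "mitochondrial"))
  attr(out, "qc") <- qc
  out
}
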