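# Chromosomal organisation of a gene family: tandem gene-array calling
# from a coordinate table, and subgenome / ortholog copy-number
# accounting from a synteny table (gene id, optional ortholog anchor,
# subgenome LF/MF1/MF2, ancestral block label).

SUBGENOMES <- c("LF", "MF1", "MF2")

#' Call tandem gene arrays from a gene coordinate table
#'
#' An array is a maximal run of family genes on one chromosome in which
#' consecutive members are separated by at most `max_gap_kb` kilobases
#' (intergenic distance, end of the upstream gene to start of the
#' downstream gene) and by at most `max_intervening` non-family genes.
#' Arrays have at least two members. Scaffold entries participate like
#' chromosomes; the caller decides what to exclude.
#'
#' @param genes data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, base pairs), `gene_id`, `in_family` (logical); extra
#'   columns ignored. Unsorted input is sorted with a notice.
#' @param max_gap_kb Maximum intergenic distance between consecutive
#'   array members, in kb (default 100).
#' @param max_intervening Maximum number of non-family genes allowed
#'   between consecutive members (default 1).
#' @return data.frame with columns `array_id`, `chrom`, `gene_id`, one
#'   row per member gene; zero rows when no array is found.
#' @export
call_tandem_arrays <- function(genes, max_gap_kb = 100, max_intervening = 1L) {
  stopifnot(all(c("chrom", "start", "end", "gene_id", "in_family")
                %in% names(genes)))
  if (any(genes$start >= genes$end)) {
    stop("gene intervals must satisfy start < end", call. = FALSE)
  }
  ord <- order(genes$chrom, genes$start)
  if (!identical(ord, seq_len(nrow(genes)))) {
    message("call_tandem_arrays: input not sorted by (chrom, start); sorting")
    genes <- genes[ord, , drop = FALSE]
  }
  max_gap <- max_gap_kb * 1000
  arrays <- list()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    fam <- which(g$in_family)
    if (length(fam) < 2L) next
    current <- fam[1L]
    for (i in fam[-1L]) {
      prev <- current[length(current)]
      gap <- g$start[i] - g$end[prev]
      n_between <- sum(!g$in_family[seq_len(nrow(g)) > prev &
                                      seq_len(nrow(g)) < i])
      if (gap <= max_gap && n_between <= max_intervening) {
        current <- c(current, i)
      } else {
        if (length(current) >= 2L) arrays[[length(arrays) + 1L]] <-
            list(chrom = chr, ids = g$gene_id[current])
        current <- i
      }
    }
    if (length(current) >= 2L) arrays[[length(arrays) + 1L]] <-
        list(chrom = chr, ids = g$gene_id[current])
  }
  if (length(arrays) == 0L) {
    return(data.frame(array_id = integer(0), chrom = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_along(arrays), function(k) {
    data.frame(array_id = k, chrom = arrays[[k]]$chrom,
               gene_id = arrays[[k]]$ids, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarise subgenome occupancy and ortholog copy numbers
#'
#' For a whole-genome-triplicated genome carrying three subgenomes (LF,
#' MF1, MF2), counts family genes per subgenome and, for every ortholog
#' anchor (e.g. an *A. thaliana* gene id), how many distinct subgenome
#' copies survive (1, 2 or 3). Genes without an anchor are counted
#' separately. Duplicate (gene, subgenome) rows are collapsed with a
#' warning.
#'
#' @param records data.frame with columns `gene_id`, `anchor_id` (NA
#'   allowed), `subgenome` (one of LF/MF1/MF2), and optionally `block`.
#' @return list with `subgenome_counts` (named integer vector over
#'   LF/MF1/MF2), `copy_number` (named vector `singlet`/`duplet`/
#'   `triplet`), `n_anchors`, `n_no_anchor`, `n_genes`.
#' @export
subgenome_summary <- function(records) {
  stopifnot(all(c("gene_id", "anchor_id", "subgenome") %in% names(records)))
  bad <- !(records$subgenome %in% SUBGENOMES)
  if (any(bad)) {
    stop(sprintf("unknown subgenome label '%s'",
                 records$subgenome[which(bad)[1L]]), call. = FALSE)
  }
  key <- paste(records$gene_id, records$subgenome)
  if (anyDuplicated(key)) {
    warning("duplicate (gene, subgenome) rows collapsed", call. = FALSE)
    records <- records[!duplicated(key), , drop = FALSE]
  }
  sg <- table(factor(records$subgenome, levels = SUBGENOMES))
  subgenome_counts <- stats::setNames(as.integer(sg), SUBGENOMES)
  anchored <- records[!is.na(records$anchor_id), , drop = FALSE]
  copies <- tapply(anchored$subgenome, anchored$anchor_id,
                   function(x) length(unique(x)))
  copy_number <- c(singlet = sum(copies == 1L),
                   duplet = sum(copies == 2L),
                   triplet = sum(copies == 3L))
  list(subgenome_counts = subgenome_counts,
       copy_number = copy_number,
       n_anchors = length(copies),
       n_no_anchor = sum(is.na(records$anchor_id)),
       n_genes = nrow(records))
}

#' Segmental duplicate pairs from synteny block labels
#'
#' Two family genes are reported as a segmental pair when they share the
#' same ancestral block label but sit on different subgenomes. This reads
#' segmental duplication off the synteny table rather than re-deriving it
#' from sequence.
#'
#' @param records As for [subgenome_summary()], with a `block` column.
#' @return data.frame with columns `gene_a`, `gene_b`, `block`.
#' @export
segmental_pairs <- function(records) {
  stopifnot("block" %in% names(records))
  rows <- list()
  for (blk in unique(stats::na.omit(records$block))) {
    g <- records[!is.na(records$block) & records$block == blk, , drop = FALSE]
    if (nrow(g) < 2L) next
    idx <- utils::combn(nrow(g), 2L)
    for (j in seq_len(ncol(idx))) {
      a <- idx[1L, j]; b <- idx[2L, j]
      if (g$subgenome[a] != g$subgenome[b]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = g$gene_id[a], gene_b = g$gene_id[b], block = blk,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      block = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
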