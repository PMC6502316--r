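# Rule-based detection of candidate C2H2 zinc-finger domains.
#
# A candidate is a Cys/Cys/His/His ligand quadruple (or a His-less
# Cys/Cys/His triple, the "D" geometry) whose inter-ligand spacings fall
# inside the union of the spacing envelopes of the plant C2H2-ZF taxonomy:
#   C -X(1..4)- C -X(1..max_ch)- H -X(1..8)- H
# All coordinates are 0-based; spans are half-open [start, end).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate a protein sequence string
#'
#' Accepts the 20 standard one-letter amino-acid codes plus `X` (unknown),
#' case-insensitively. Any other character is an error naming the offending
#' 0-based position.
#'
#' @param sequence Single protein sequence string.
#' @return The upper-cased sequence.
#' @keywords internal
validate_protein <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% c(AA20, "X")))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d (0-based)",
                 chars[bad[1L]], bad[1L] - 1L), call. = FALSE)
  }
  s
}

empty_matches <- function() {
  data.frame(c1 = integer(0), c2 = integer(0), h1 = integer(0),
             h2 = integer(0), c2_spacing = integer(0),
             ch_spacing = integer(0), hh_spacing = integer(0),
             span_start = integer(0), span_end = integer(0),
             motif6 = character(0), stringsAsFactors = FALSE)
}

motif6_at <- function(chars, h1) {
  # residues [h1-5 .. h1] inclusive, 0-based; clipped at the N-terminus
  from <- max(0L, h1 - 5L)
  paste(chars[(from + 1L):(h1 + 1L)], collapse = "")
}

#' Enumerate all candidate C2H2-ZF ligand arrangements in a protein
#'
#' Exhaustively lists every index quadruple `(c1, c2, h1, h2)` with
#' `C` at `c1`, `c2` and `H` at `h1`, `h2` satisfying
#' `c2_spacing` in 1..4, `ch_spacing` in 1..`max_ch`, `hh_spacing` in 1..8
#' (spacings are counts of residues strictly between the two ligands).
#' His-less triples (`h2 = NA`) are emitted when `ch_spacing` is 12 or 13
#' and no His completes the quadruple within the 1..8 envelope after `h1`.
#' This enumeration is the brute-force surface on which overlap resolution
#' operates; it is deliberately unfiltered.
#'
#' @param sequence Protein sequence (20 amino-acid letters plus `X`;
#'   case-insensitive). `X` never counts as a ligand.
#' @param max_ch Upper bound on the Cys2-His1 spacing (default 35, chosen
#'   so the whole domain stays near its canonical ~30-residue size).
#' @return A data.frame with 0-based columns `c1, c2, h1, h2` (NA `h2` for
#'   D-candidates), the three spacings (`hh_spacing` NA for D), the
#'   half-open residue span `span_start, span_end`, and `motif6`, the six
#'   residues ending at the first His. Rows are sorted by `(c1, span
#'   length)`.
#' @examples
#' enumerate_candidates("MACKTCFSRSGKAQALGGHRRTH")
#' @export
enumerate_candidates <- function(sequence, max_ch = 35L) {
  s <- validate_protein(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cpos <- which(chars == "C") - 1L   # 0-based
  hpos <- which(chars == "H") - 1L
  rows <- list()
  for (c1 in cpos) {
    for (c2 in cpos[cpos > c1]) {
      c2sp <- c2 - c1 - 1L
      if (c2sp < 1L) next
      if (c2sp > 4L) break
      for (h1 in hpos[hpos > c2]) {
        chsp <- h1 - c2 - 1L
        if (chsp < 1L) next
        if (chsp > max_ch) break
        h2s <- hpos[hpos > h1 & (hpos - h1 - 1L) >= 1L & (hpos - h1 - 1L) <= 8L]
        for (h2 in h2s) {
          rows[[length(rows) + 1L]] <- data.frame(
            c1 = c1, c2 = c2, h1 = h1, h2 = h2,
            c2_spacing = c2sp, ch_spacing = chsp,
            hh_spacing = h2 - h1 - 1L,
            span_start = max(0L, c1 - 2L), span_end = h2 + 1L,
            motif6 = motif6_at(chars, h1), stringsAsFactors = FALSE)
        }
        # D geometry: canonical-ish Cys2-His spacing but no completing His
        if (length(h2s) == 0L && chsp %in% c(12L, 13L)) {
          rows[[length(rows) + 1L]] <- data.frame(
            c1 = c1, c2 = c2, h1 = h1, h2 = NA_integer_,
            c2_spacing = c2sp, ch_spacing = chsp,
            hh_spacing = NA_integer_,
            span_start = max(0L, c1 - 2L),
            span_end = min(n, h1 + 3L),
            motif6 = motif6_at(chars, h1), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_matches())
  out <- do.call(rbind, rows)
  out <- out[order(out$c1, out$span_end - out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ligand_sets <- function(m) {
  lapply(seq_len(nrow(m)), function(i) {
    v <- c(m$c1[i], m$c2[i], m$h1[i], m$h2[i])
    v[!is.na(v)]
  })
}

#' Resolve overlapping domain candidates
#'
#' Greedy selection of a pairwise ligand-disjoint candidate set. Priority
#' order: (1) canonical Cys2-His1 spacing of 12, (2) full quadruples over
#' His-less D triples, (3) smaller span, (4) smaller `c1`. Two candidates
#' overlap when they share any ligand residue index. Deterministic and
#' stable.
#'
#' @param candidates data.frame as returned by [enumerate_candidates()],
#'   from a single protein.
#' @return Subset of `candidates`, sorted by `c1`.
#' @export
resolve_overlaps <- function(candidates) {
  if (nrow(candidates) <= 1L) return(candidates)
  span <- candidates$span_end - candidates$span_start
  pri <- order(candidates$ch_spacing != 12L,   # canonical geometry first
               is.na(candidates$h2),           # quadruples before D triples
               span,
               candidates$c1)
  lig <- ligand_sets(candidates)
  used <- integer(0)
  keep <- logical(nrow(candidates))
  for (i in pri) {
    if (!any(lig[[i]] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, lig[[i]])
    }
  }
  out <- candidates[keep, , drop = FALSE]
  out <- out[order(out$c1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan one protein for C2H2-ZF domains
#'
#' Composition of [enumerate_candidates()] and [resolve_overlaps()]: the
#' exhaustive candidate list is reduced to a non-overlapping set of domain
#' matches sorted along the sequence.
#'
#' @inheritParams enumerate_candidates
#' @return data.frame of non-overlapping matches sorted by `c1`.
#' @examples
#' scan_protein("MACKTCFSRSGKAQALGGHRRTH")
#' @export
scan_protein <- function(sequence, max_ch = 35L) {
  resolve_overlaps(enumerate_candidates(sequence, max_ch = max_ch))
}

#' Scan a set of proteins (or a protein FASTA file)
#'
#' @param x Named character vector of protein sequences, a
#'   `Biostrings::AAStringSet`, or the path to a protein FASTA file.
#' @param max_ch Upper bound on the Cys2-His1 spacing.
#' @return data.frame of matches with a leading `protein_id` column.
#' @export
scan_proteome <- function(x, max_ch = 35L) {
  seqs <- as_protein_set(x)
  res <- lapply(names(seqs), function(id) {
    m <- scan_protein(seqs[[id]], max_ch = max_ch)
    if (nrow(m) == 0L) return(NULL)
    cbind(data.frame(protein_id = id, stringsAsFactors = FALSE), m)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(cbind(data.frame(protein_id = character(0),
                            stringsAsFactors = FALSE), empty_matches()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Coerce FASTA path / AAStringSet / named character to named character.
as_protein_set <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    aa <- Biostrings::readAAStringSet(x)
    seqs <- as.character(aa)
    names(seqs) <- sub("\\s.*$", "", names(aa))
    return(seqs)
  }
  if (methods::is(x, "AAStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    return(seqs)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
    return(x)
  }
  stop("cannot interpret 'x' as a protein set", call. = FALSE)
}

#' Write a domain-match table to TSV
#'
#' Columns are emitted in a fixed order:
#' `protein_id, c1, c2, h1, h2, span_start, span_end, motif6`.
#'
#' @param matches data.frame from [scan_proteome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_domain_tsv <- function(matches, path) {
  cols <- c("protein_id", "c1", "c2", "h1", "h2",
            "span_start", "span_end", "motif6")
  utils::write.table(matches[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
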