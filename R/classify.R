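# Typing of detected C2H2-ZF domains and protein-level subfamily labels.
#
# Domain types follow the plant taxonomy: Q has the intact QALGGH hexamer
# at canonical Cys2-His1 spacing 12; M1-M5 have 1-5 degraded residues in
# QALGG at the same spacing; Z1/Z2 have spacing >12 / <12; D lacks the
# second His. Proteins are then binned into tandem (Br-t1-SF, Br-t2-SF)
# and dispersed (Br-1i-*, Br-2i-*, Br-3i-SF, Br-4i-SF) subsets by the
# linker lengths between consecutive fingers.

#' Subset labels recognised by the classifier, in fixed output order.
#' @export
SUBSET_LEVELS <- c("Br-t1-SF", "Br-t2-SF",
                   "Br-1i-Q-SF", "Br-1i-M-SF", "Br-1i-Z-SF", "Br-1i-D-SF",
                   "Br-2i-Q-SF", "Br-2i-M-SF", "Br-2i-Z-SF", "Br-2i-Mix-SF",
                   "Br-3i-SF", "Br-4i-SF", "Unclassified")

#' Domain type labels, in fixed output order.
#' @export
TYPE_LEVELS <- c("Q", paste0("M", 1:5), "Z1", "Z2", "D")

#' Count degraded residues in a QALGGH-context hexamer
#'
#' Hamming mismatches of the first five residues of `motif6` against
#' `QALGG`. The sixth position is the His ligand itself and is never
#' counted; `X` counts as a mismatch.
#'
#' @param motif6 Character vector of 6-mers, each ending in `H`.
#' @return Integer vector of mismatch counts in 0..5.
#' @examples
#' count_degraded("QALGGH")  # 0
#' count_degraded("QSLGAH")  # 2
#' @export
count_degraded <- function(motif6) {
  stopifnot(is.character(motif6))
  if (any(nchar(motif6) != 6L)) {
    stop("motif6 must have length 6", call. = FALSE)
  }
  if (any(substr(motif6, 6L, 6L) != "H")) {
    stop("motif6 must end in the His ligand 'H'", call. = FALSE)
  }
  ref <- c("Q", "A", "L", "G", "G")
  vapply(motif6, function(m) {
    sum(strsplit(substr(m, 1L, 5L), "", fixed = TRUE)[[1]] != ref)
  }, integer(1), USE.NAMES = FALSE)
}

#' Assign a type label to each detected domain
#'
#' Total, exclusive decision tree: missing second His -> `D`; Cys2-His1
#' spacing > 12 -> `Z1`; < 12 -> `Z2`; spacing exactly 12 with an intact
#' QALGGH -> `Q`, otherwise `Mk` where k is the degraded-residue count.
#'
#' @param matches data.frame from [scan_protein()] / [scan_proteome()].
#' @return `matches` with added `type_label` and `degraded_count` columns
#'   (`degraded_count` is NA when the motif window is truncated at the
#'   N-terminus).
#' @export
classify_domains <- function(matches) {
  n <- nrow(matches)
  deg <- rep(NA_integer_, n)
  full <- nchar(matches$motif6) == 6L
  if (any(full)) deg[full] <- count_degraded(matches$motif6[full])
  type <- character(n)
  for (i in seq_len(n)) {
    type[i] <- if (is.na(matches$h2[i])) "D"
    else if (matches$ch_spacing[i] > 12L) "Z1"
    else if (matches$ch_spacing[i] < 12L) "Z2"
    else if (isTRUE(deg[i] == 0L)) "Q"
    else paste0("M", deg[i])
  }
  matches$type_label <- type
  matches$degraded_count <- deg
  matches
}

collapse_type <- function(type_label) {
  out <- substr(type_label, 1L, 1L)  # Q, M, Z, D
  out
}

#' Classify a protein into a subfamily subset from its typed domains
#'
#' The linker between consecutive fingers is the number of residues
#' strictly between the last His ligand of the upstream finger and the
#' first Cys of the downstream finger. Proteins whose fingers are all
#' linked by <= 11 residues are tandem (`Br-t1-SF` for 2-5 fingers,
#' `Br-t2-SF` for 6 or more); single-finger proteins are `Br-1i-{Q,M,Z,D}-SF`
#' by collapsed type; two dispersed fingers give `Br-2i-{Q,M,Z}-SF` when
#' both share a collapsed type and `Br-2i-Mix-SF` otherwise; three or four
#' dispersed fingers give `Br-3i-SF` / `Br-4i-SF`. Five or more dispersed
#' fingers have no defined subset and return `Unclassified` with a warning.
#' Mixed linker patterns (some <= 11, some >= 12) are assigned by linker
#' majority, ties favouring tandem, and flagged.
#'
#' @param domains data.frame of typed domains for one protein (output of
#'   [classify_domains()]), non-overlapping.
#' @return list with `subset` (character label), `mixed_linker` (logical)
#'   and `linkers` (integer vector).
#' @export
classify_protein <- function(domains) {
  n <- nrow(domains)
  if (n == 0L) {
    return(list(subset = "Unclassified", mixed_linker = FALSE,
                linkers = integer(0)))
  }
  domains <- domains[order(domains$c1), , drop = FALSE]
  last_lig <- ifelse(is.na(domains$h2), domains$h1, domains$h2)
  if (n > 1L && any(domains$c1[-1L] <= last_lig[-n])) {
    stop("overlapping domains passed to classify_protein", call. = FALSE)
  }
  linkers <- if (n > 1L) domains$c1[-1L] - last_lig[-n] - 1L else integer(0)
  ctype <- collapse_type(domains$type_label)
  mixed <- FALSE
  if (n == 1L) {
    subset <- sprintf("Br-1i-%s-SF", ctype[1L])
  } else {
    short <- sum(linkers <= 11L)
    long <- sum(linkers >= 12L)
    if (long == 0L) {
      tandem <- TRUE
    } else if (short == 0L) {
      tandem <- FALSE
    } else {
      mixed <- TRUE
      tandem <- short >= long  # majority, ties -> tandem
    }
    if (tandem) {
      subset <- if (n <= 5L) "Br-t1-SF" else "Br-t2-SF"
    } else if (n == 2L) {
      subset <- if (ctype[1L] == ctype[2L] && ctype[1L] %in% c("Q", "M", "Z"))
        sprintf("Br-2i-%s-SF", ctype[1L]) else "Br-2i-Mix-SF"
    } else if (n == 3L) {
      subset <- "Br-3i-SF"
    } else if (n == 4L) {
      subset <- "Br-4i-SF"
    } else {
      warning(sprintf("%d dispersed domains have no defined subset; %s",
                      n, "labelling Unclassified"), call. = FALSE)
      subset <- "Unclassified"
    }
  }
  list(subset = subset, mixed_linker = mixed, linkers = linkers)
}

#' Classify every protein in a scanned proteome
#'
#' @param matches data.frame from [scan_proteome()] (typed or untyped;
#'   types are added when absent).
#' @param proteins Optional character vector of all protein ids, so that
#'   proteins without any detected domain appear as `Unclassified`.
#' @return data.frame with one row per protein: `protein_id`, `n_domains`,
#'   `types` (comma string), `subset`, `mixed_linker`.
#' @export
classify_proteome <- function(matches, proteins = NULL) {
  if (!"type_label" %in% names(matches)) matches <- classify_domains(matches)
  ids <- unique(matches$protein_id)
  if (!is.null(proteins)) ids <- unique(c(ids, proteins))
  rows <- lapply(ids, function(id) {
    d <- matches[matches$protein_id == id, , drop = FALSE]
    cl <- classify_protein(d)
    data.frame(protein_id = id, n_domains = nrow(d),
               types = paste(d$type_label[order(d$c1)], collapse = ","),
               subset = cl$subset, mixed_linker = cl$mixed_linker,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-tabulate subset labels against domain counts
#'
#' @param subsets Character vector of subset labels.
#' @param n_domains Integer vector of per-protein domain counts, parallel
#'   to `subsets`.
#' @return Integer matrix, rows = the fixed subset order, columns = the
#'   observed domain counts (ascending). Row totals equal the number of
#'   proteins carrying that label.
#' @export
crosstab_subsets <- function(subsets, n_domains) {
  stopifnot(length(subsets) == length(n_domains))
  if (length(subsets) == 0L) {
    m <- matrix(0L, nrow = length(SUBSET_LEVELS), ncol = 0L,
                dimnames = list(SUBSET_LEVELS, character(0)))
    return(m)
  }
  tab <- table(factor(subsets, levels = SUBSET_LEVELS),
               factor(n_domains, levels = sort(unique(n_domains))))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  m
}
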