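# Nei-Gojobori (1986) counting estimator of synonymous (Ks) and
# non-synonymous (Ka) substitution rates for a pair of in-frame,
# pre-aligned coding sequences, with Jukes-Cantor multiple-hit
# correction, plus Ks-based divergence dating.
#
# Conventions: per codon position the synonymous fraction is the number
# of synonymous single-nucleotide changes divided by 3; changes creating
# a stop codon count as non-synonymous, so synonymous + non-synonymous
# site counts always sum to 3 per codon. Multi-difference codon pairs are
# resolved by averaging over all mutational pathways that avoid stop
# codon intermediates (falling back to all pathways if none avoids one).

NUCS <- c("A", "C", "G", "T")

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  gc <- genetic_code()
  aa <- gc[codon]
  ifelse(is.na(aa), NA_character_, aa)
}

is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# Synonymous site count of one sense codon (stops as non-synonymous).
codon_syn_sites <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (!is_stop(alt) && gc[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Lazily built lookup of synonymous sites for the 61 sense codons.
syn_sites_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codons <- names(genetic_code())
      codons <- codons[!is_stop(codons)]
      tab <<- vapply(codons, codon_syn_sites, numeric(1))
    }
    tab
  }
})

split_codons <- function(cds) {
  s <- toupper(gsub("U", "T", cds))
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

# All orderings of the differing positions between two codons; per
# ordering, count synonymous / non-synonymous steps, skipping orderings
# that pass through a stop codon (unless all do).
codon_path_diffs <- function(ca, cb) {
  gc <- genetic_code()
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  orderings <- all_permutations(pos)
  res <- lapply(orderings, function(ord) {
    cur <- ca
    sd <- 0; nd <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (is_stop(nxt)) hit_stop <- TRUE
      aa1 <- if (is_stop(cur)) "*" else gc[[cur]]
      aa2 <- if (is_stop(nxt)) "*" else gc[[nxt]]
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, hit_stop = hit_stop)
  })
  ok <- !vapply(res, `[[`, logical(1), "hit_stop")
  if (any(ok)) res <- res[ok]  # documented fallback: keep all if none ok
  c(syn = mean(vapply(res, `[[`, numeric(1), "sd")),
    nonsyn = mean(vapply(res, `[[`, numeric(1), "nd")))
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`. Monotone increasing in `p` and
#' asymptotically equal to `p` as `p -> 0`. Proportions at or above 3/4
#' are saturated and return `Inf`.
#'
#' @param p Observed proportion of differing sites.
#' @return Corrected distance (possibly `Inf`).
#' @export
jukes_cantor <- function(p) {
  stopifnot(all(p >= 0))
  ifelse(p >= 3 / 4, Inf, -3 / 4 * log(1 - 4 * p / 3))
}

#' NG86 Ka/Ks for a pair of aligned coding sequences
#'
#' Sequences must be equal length, in frame (length a multiple of 3) and
#' free of internal stop codons; a shared terminal stop is dropped.
#' Codons containing gaps or ambiguity characters in either sequence are
#' skipped pairwise. Synonymous/non-synonymous site counts are averaged
#' over the two sequences; differences are counted by averaging over
#' minimal mutational pathways; proportions are Jukes-Cantor corrected.
#'
#' @param cds_a,cds_b Nucleotide sequence strings (T or U).
#' @return list with `ka`, `ks`, `omega` (`NA` when Ks = 0, see
#'   `omega_defined`), `omega_defined`, site counts `syn_sites`,
#'   `nonsyn_sites`, difference counts `syn_diffs`, `nonsyn_diffs`,
#'   proportions `ps`, `pn`, and `n_codons` used.
#' @examples
#' p <- simulate_cds_pair(40, n_syn = 2, n_nonsyn = 1, seed = 1)
#' ng86_kaks(p$cds_a, p$cds_b)[c("ka", "ks")]
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  if (nchar(cds_a) %% 3 != 0) {
    stop("sequence length must be a multiple of 3", call. = FALSE)
  }
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  nc <- length(ca)
  # drop a shared terminal stop codon, if present
  if (nc > 0L && (is_stop(ca[nc]) || is_stop(cb[nc]))) {
    if (!(is_stop(ca[nc]) && is_stop(cb[nc]))) {
      stop("terminal stop codon present in only one sequence", call. = FALSE)
    }
    ca <- ca[-nc]; cb <- cb[-nc]; nc <- nc - 1L
  }
  valid <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  if (any(is_stop(ca[valid])) || any(is_stop(cb[valid]))) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  ca <- ca[valid]; cb <- cb[valid]
  stab <- syn_sites_table()
  S <- (sum(stab[ca]) + sum(stab[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) codon_path_diffs(ca[i], cb[i]),
                  numeric(2))
  Sd <- if (length(ca)) sum(diffs["syn", ]) else 0
  Nd <- if (length(ca)) sum(diffs["nonsyn", ]) else 0
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  omega_defined <- is.finite(ks) && ks > 0 && is.finite(ka)
  list(ka = ka, ks = ks,
       omega = if (omega_defined) ka / ks else NA_real_,
       omega_defined = omega_defined,
       syn_sites = S, nonsyn_sites = N,
       syn_diffs = Sd, nonsyn_diffs = Nd,
       ps = ps, pn = pn, n_codons = length(ca),
       estimator = "NG86")
}

#' Divergence time from a synonymous distance
#'
#' `T = Ks / (2 R)`, reported in million years (MY). The default clock
#' rate `R = 1.5e-8` synonymous substitutions per site per year is the
#' standard value for nuclear genes of dicotyledonous plants.
#'
#' @param ks Synonymous distance(s), substitutions per synonymous site.
#' @param rate Clock rate R in substitutions/site/year.
#' @return Divergence time(s) in MY.
#' @examples
#' divergence_time(0.3)  # 10 MY
#' @export
divergence_time <- function(ks, rate = 1.5e-8) {
  stopifnot(rate > 0)
  if (any(ks < 0, na.rm = TRUE)) stop("Ks must be >= 0", call. = FALSE)
  ks / (2 * rate) / 1e6
}

#' Summarise selection pressure over a set of Ka/Ks ratios
#'
#' @param omega Numeric vector of Ka/Ks ratios; `NA` (undefined) and
#'   non-finite values are excluded with a warning.
#' @return list with `n_gt1` (positive selection), `n_lt1` (purifying),
#'   `n_eq1`, and `mean`, `min`, `max` over the included ratios.
#' @export
selection_summary <- function(omega) {
  drop <- is.na(omega) | !is.finite(omega)
  if (any(drop)) {
    warning(sprintf("%d undefined/non-finite Ka/Ks values excluded",
                    sum(drop)), call. = FALSE)
  }
  om <- omega[!drop]
  list(n_gt1 = sum(om > 1), n_lt1 = sum(om < 1), n_eq1 = sum(om == 1),
       mean = if (length(om)) mean(om) else NA_real_,
       min = if (length(om)) min(om) else NA_real_,
       max = if (length(om)) max(om) else NA_real_)
}

#' Ka/Ks and divergence times for a table of CDS pairs
#'
#' @param pairs data.frame with columns `id_a`, `id_b`.
#' @param cds Named character vector (or list) of CDS sequences.
#' @param rate Clock rate passed to [divergence_time()].
#' @return data.frame with one row per pair: ids, `ka`, `ks`, `omega`,
#'   `t_my`.
#' @export
kaks_table <- function(pairs, cds, rate = 1.5e-8) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$id_a[i]; b <- pairs$id_b[i]
    r <- ng86_kaks(cds[[a]], cds[[b]])
    data.frame(id_a = a, id_b = b, ka = r$ka, ks = r$ks,
               omega = r$omega,
               t_my = if (is.finite(r$ks)) divergence_time(r$ks, rate)
                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
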