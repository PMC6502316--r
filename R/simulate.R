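# Simulators with planted ground truth: proteomes carrying zinc-finger
# domains of known type and position, coding-sequence pairs with a
# controlled synonymous/non-synonymous mutation budget, gene maps with
# planted tandem arrays, synteny tables with known copy numbers, and
# expression matrices with tissue-preferential groups.
#
# Background and linker residues are drawn from an alphabet excluding C
# and H by default, so rule-based scanning recovers exactly the planted
# domains; a decoy mode re-enables isolated C/H residues to exercise
# overlap resolution.

BACKGROUND18 <- setdiff(AA20, c("C", "H"))
MOTIF_ALPHABET <- setdiff(BACKGROUND18, "Q")  # degraded picks never restore Q

# Spacing envelopes of the nine domain types. `hh = NA` marks the
# His-less D geometry.
TYPE_ENVELOPE <- list(
  Q  = list(c2 = 2L,           ch = 12L,     hh = 3L),
  M1 = list(c2 = 2L,           ch = 12L,     hh = c(3L, 4L)),
  M2 = list(c2 = 2L,           ch = 12L,     hh = c(3L, 4L)),
  M3 = list(c2 = c(2L, 4L),    ch = 12L,     hh = c(3L, 4L, 5L)),
  M4 = list(c2 = c(1L, 2L, 4L), ch = 12L,    hh = c(1L, 3L, 4L, 5L, 7L)),
  M5 = list(c2 = c(2L, 4L),    ch = 12L,     hh = c(3L, 4L, 5L, 8L)),
  Z1 = list(c2 = 2:4,          ch = 13:35,   hh = 2:5),
  Z2 = list(c2 = 2L,           ch = 1:11,    hh = c(3L, 4L)),
  D  = list(c2 = c(2L, 4L),    ch = c(12L, 13L), hh = NA_integer_)
)

#' Specify a zinc-finger domain to plant in a simulated protein
#'
#' Validates spacings against the spacing envelope of the requested type
#' and, for Q/M types, the degradation count of the motif. Unspecified
#' fields take the first (most canonical) value of the type's envelope;
#' an unspecified motif is drawn at render time.
#'
#' @param type One of `Q`, `M1`..`M5`, `Z1`, `Z2`, `D`.
#' @param c2_spacing Residues between the two Cys ligands.
#' @param ch_spacing Residues between the second Cys and the first His.
#' @param hh_spacing Residues between the two His ligands (ignored for D).
#' @param motif6 Optional 6-mer ending in `H` occupying the six positions
#'   up to and including the first His.
#' @return An object of class `zf_spec`.
#' @export
zf_spec <- function(type, c2_spacing = NULL, ch_spacing = NULL,
                    hh_spacing = NULL, motif6 = NULL) {
  if (!type %in% names(TYPE_ENVELOPE)) {
    stop(sprintf("unknown domain type '%s'", type), call. = FALSE)
  }
  env <- TYPE_ENVELOPE[[type]]
  if (is.null(c2_spacing)) c2_spacing <- env$c2[1L]
  if (is.null(ch_spacing)) ch_spacing <- env$ch[1L]
  if (type == "D") {
    hh_spacing <- NA_integer_
  } else if (is.null(hh_spacing)) {
    hh_spacing <- env$hh[1L]
  }
  reject <- function(field) {
    stop(sprintf("%s inconsistent with the %s row of the domain taxonomy",
                 field, type), call. = FALSE)
  }
  if (!c2_spacing %in% env$c2) reject("c2_spacing")
  if (!ch_spacing %in% env$ch) reject("ch_spacing")
  if (type != "D" && !hh_spacing %in% env$hh) reject("hh_spacing")
  if (!is.null(motif6)) {
    if (nchar(motif6) != 6L || substr(motif6, 6L, 6L) != "H") {
      stop("motif6 must be a 6-mer ending in 'H'", call. = FALSE)
    }
    deg <- count_degraded(motif6)
    if (type == "Q" && deg != 0L) reject("motif6")
    if (grepl("^M", type) && deg != as.integer(substr(type, 2L, 2L))) {
      reject("motif6")
    }
  } else if (type == "Q") {
    motif6 <- "QALGGH"
  }
  structure(list(type = type, c2_spacing = c2_spacing,
                 ch_spacing = ch_spacing, hh_spacing = hh_spacing,
                 motif6 = motif6),
            class = "zf_spec")
}

rand_bg <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BACKGROUND18, n, replace = TRUE), collapse = "")
}

# Random 6-mer ending in H with exactly `deg` mismatches vs QALGG,
# drawn from an alphabet excluding C, H and Q (so degradations never
# recreate the reference residue or a ligand letter).
rand_motif6 <- function(deg) {
  ref <- c("Q", "A", "L", "G", "G")
  pos <- if (deg > 0L) sample(5L, deg) else integer(0)
  out <- ref
  for (p in pos) {
    out[p] <- sample(setdiff(MOTIF_ALPHABET, ref[p]), 1L)
  }
  paste(c(out, "H"), collapse = "")
}

# Render one spec into residues from c1 to the last ligand, inclusive.
render_domain <- function(spec) {
  motif <- spec$motif6
  if (is.null(motif)) {
    deg <- if (grepl("^M", spec$type)) {
      as.integer(substr(spec$type, 2L, 2L))
    } else {
      sample(0:5, 1L)  # Z and D types are unconstrained in the motif
    }
    motif <- rand_motif6(deg)
  }
  ch <- spec$ch_spacing
  # the motif occupies the last 6 positions before-and-including h1;
  # for short Cys2-His1 spacings only its tail fits
  if (ch >= 5L) {
    mid <- paste0(rand_bg(ch - 5L), substr(motif, 1L, 5L))
  } else {
    mid <- substr(motif, 6L - ch, 5L)
  }
  core <- paste0("C", rand_bg(spec$c2_spacing), "C", mid, "H")
  if (spec$type != "D") {
    core <- paste0(core, rand_bg(spec$hh_spacing), "H")
  }
  list(residues = core, motif6 = motif)
}

domain_len <- function(spec) {
  base <- 1L + spec$c2_spacing + 1L + spec$ch_spacing + 1L
  if (spec$type == "D") base else base + spec$hh_spacing + 1L
}

#' Simulate a proteome with planted zinc-finger domains
#'
#' Each protein is built as
#' `flank | domain_1 | linker_1 | domain_2 | ... | flank`, with
#' background drawn from the 18-letter alphabet excluding C and H (so
#' the planted domains are the only candidates the scanner can find).
#' `decoys = TRUE` additionally sprinkles isolated C/H residues into the
#' flanks to exercise overlap resolution.
#'
#' @param domain_plan List over proteins; each element a list of
#'   [zf_spec()] objects (possibly empty).
#' @param linker_lengths List over proteins of integer vectors, one
#'   linker per adjacent domain pair (length = domains - 1). Linkers
#'   count residues strictly between the last ligand of one domain and
#'   the first Cys of the next.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param flank Two integers: background residues before the first and
#'   after the last domain (default `c(5, 5)`; the leading flank must be
#'   >= 0, no minimum is enforced).
#' @param decoys Insert isolated C/H decoy residues into flanks.
#' @return list with `sequences` (named character vector), `truth`
#'   (data.frame `protein_id`, `c1`, `last_ligand`, `span_start`,
#'   `span_end`, `type_label`, `motif6`, 0-based), and `subsets`
#'   (data.frame `protein_id`, `subset`, `n_domains`) — the expected
#'   subset labels derived from the planted types and linkers.
#' @export
simulate_proteome <- function(domain_plan, linker_lengths = NULL, seed = 1L,
                              flank = c(5L, 5L), decoys = FALSE) {
  set.seed(seed)
  n <- length(domain_plan)
  if (is.null(linker_lengths)) {
    linker_lengths <- lapply(domain_plan, function(p) {
      if (length(p) >= 2L) rep(20L, length(p) - 1L) else integer(0)
    })
  }
  stopifnot(length(linker_lengths) == n)
  seqs <- character(n)
  ids <- sprintf("prot%03d", seq_len(n))
  truth <- list()
  subsets <- list()
  for (i in seq_len(n)) {
    plan <- domain_plan[[i]]
    linkers <- as.integer(linker_lengths[[i]])
    if (length(plan) >= 1L && length(linkers) != length(plan) - 1L) {
      stop("need one linker per adjacent domain pair", call. = FALSE)
    }
    parts <- rand_bg(flank[1L])
    pos <- nchar(parts)  # 0-based index of the next residue
    for (j in seq_along(plan)) {
      spec <- plan[[j]]
      rd <- render_domain(spec)
      c1 <- pos
      last <- pos + nchar(rd$residues) - 1L
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = ids[i], c1 = c1, last_ligand = last,
        span_start = max(0L, c1 - 2L),
        span_end = if (spec$type == "D") last + 3L else last + 1L,
        type_label = spec$type, motif6 = rd$motif6,
        stringsAsFactors = FALSE)
      parts <- paste0(parts, rd$residues)
      pos <- last + 1L
      if (j < length(plan)) {
        parts <- paste0(parts, rand_bg(linkers[j]))
        pos <- pos + linkers[j]
      }
    }
    parts <- paste0(parts, rand_bg(flank[2L]))
    if (decoys && nchar(parts) > 2L) {
      chars <- strsplit(parts, "", fixed = TRUE)[[1]]
      planted <- truth[vapply(truth, function(t) t$protein_id == ids[i],
                              logical(1))]
      occupied <- unlist(lapply(planted, function(t) t$c1:t$last_ligand))
      free <- setdiff(seq_along(chars) - 1L, occupied)
      if (length(free) > 0L) {
        k <- max(1L, length(free) %/% 10L)
        at <- sample(free, min(k, length(free)))
        chars[at + 1L] <- sample(c("C", "H"), length(at), replace = TRUE)
        parts <- paste(chars, collapse = "")
      }
    }
    seqs[i] <- parts
    # expected subset from the planted plan
    types <- vapply(plan, `[[`, character(1), "type")
    subsets[[i]] <- data.frame(
      protein_id = ids[i],
      subset = planted_subset(types, linkers),
      n_domains = length(plan), stringsAsFactors = FALSE)
  }
  names(seqs) <- ids
  list(sequences = seqs,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       subsets = do.call(rbind, subsets),
       seed = seed)
}

# Subset label implied by planted types and linkers (ground truth side;
# mirrors the published classification rules, applied to the plan rather
# than to a scanned sequence).
planted_subset <- function(types, linkers) {
  n <- length(types)
  if (n == 0L) return("Unclassified")
  ctype <- substr(types, 1L, 1L)
  if (n == 1L) return(sprintf("Br-1i-%s-SF", ctype))
  if (all(linkers <= 11L)) return(if (n <= 5L) "Br-t1-SF" else "Br-t2-SF")
  if (all(linkers >= 12L)) {
    if (n == 2L) {
      if (ctype[1L] == ctype[2L] && ctype[1L] %in% c("Q", "M", "Z")) {
        return(sprintf("Br-2i-%s-SF", ctype[1L]))
      }
      return("Br-2i-Mix-SF")
    }
    if (n == 3L) return("Br-3i-SF")
    if (n == 4L) return("Br-4i-SF")
    return("Unclassified")
  }
  # mixed linkers: majority rule, ties tandem
  if (sum(linkers <= 11L) >= sum(linkers >= 12L)) {
    if (n <= 5L) "Br-t1-SF" else "Br-t2-SF"
  } else if (n == 3L) "Br-3i-SF" else if (n == 4L) "Br-4i-SF"
  else "Unclassified"
}

#' Write simulated protein sequences to a FASTA file
#'
#' The generator seed is recorded in each header.
#'
#' @param sim Result of [simulate_proteome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(sim, path) {
  aa <- Biostrings::AAStringSet(sim$sequences)
  names(aa) <- sprintf("%s seed=%d", names(sim$sequences), sim$seed)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Simulate a pair of coding sequences with a known mutation budget
#'
#' Builds a random stop-free CDS and derives a partner carrying exactly
#' `n_syn` synonymous and `n_nonsyn` non-synonymous single-nucleotide
#' substitutions, each in a distinct codon, never creating a stop codon.
#'
#' @param n_codons Number of codons.
#' @param n_syn,n_nonsyn Numbers of synonymous / non-synonymous changes.
#' @param seed Integer seed.
#' @return list with `cds_a`, `cds_b` and `ledger`, a data.frame
#'   recording each substitution (`codon` index 1-based, `pos` in codon,
#'   `from`, `to` codons, `type`).
#' @export
simulate_cds_pair <- function(n_codons, n_syn, n_nonsyn, seed = 1L) {
  stopifnot(n_codons >= 1L, n_syn >= 0L, n_nonsyn >= 0L)
  if (n_syn + n_nonsyn > n_codons) {
    stop("mutation budget exceeds the number of codons", call. = FALSE)
  }
  set.seed(seed)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  codons_a <- sample(sense, n_codons, replace = TRUE)
  codons_b <- codons_a
  # candidate (pos, alt) changes of the requested status for one codon
  options_for <- function(codon, want_syn) {
    res <- list()
    for (pos in 1:3) {
      for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- nt
        if (is_stop(alt)) next
        syn <- gc[[alt]] == gc[[codon]]
        if (syn == want_syn) res[[length(res) + 1L]] <- list(pos = pos,
                                                            alt = alt)
      }
    }
    res
  }
  ledger <- list()
  available <- seq_len(n_codons)
  plant <- function(n_changes, want_syn, label) {
    placed <- 0L
    while (placed < n_changes) {
      usable <- available[vapply(available, function(i) {
        length(options_for(codons_a[i], want_syn)) > 0L
      }, logical(1))]
      if (length(usable) == 0L) {
        stop(sprintf("cannot place %d %s change(s) in the generated CDS",
                     n_changes - placed, label), call. = FALSE)
      }
      i <- if (length(usable) == 1L) usable else sample(usable, 1L)
      opt <- options_for(codons_a[i], want_syn)
      ch <- opt[[if (length(opt) == 1L) 1L else sample(length(opt), 1L)]]
      ledger[[length(ledger) + 1L]] <<- data.frame(
        codon = i, pos = ch$pos, from = codons_a[i], to = ch$alt,
        type = label, stringsAsFactors = FALSE)
      codons_b[i] <<- ch$alt
      available <<- setdiff(available, i)
      placed <- placed + 1L
    }
  }
  plant(n_syn, TRUE, "synonymous")
  plant(n_nonsyn, FALSE, "nonsynonymous")
  list(cds_a = paste(codons_a, collapse = ""),
       cds_b = paste(codons_b, collapse = ""),
       ledger = if (length(ledger)) do.call(rbind, ledger)
                else data.frame(codon = integer(0), pos = integer(0),
                                from = character(0), to = character(0),
                                type = character(0),
                                stringsAsFactors = FALSE))
}

#' Simulate an FPKM expression matrix with tissue-preferential groups
#'
#' Genes in a group draw log-normal FPKM with a high mean in the group's
#' listed tissues and a low mean elsewhere; FPKM is therefore always
#' non-negative and right-skewed, as in RNA-seq practice. Groups with an
#' empty tissue set yield all-zero genes (for exercising the all-zero
#' exclusion filter).
#'
#' @param groups List of groups, each `list(size =, high = <tissues>)`;
#'   `high = character(0)` plants all-zero genes.
#' @param tissues Tissue labels (default the six-organ panel callus,
#'   root, stem, leaf, flower, silique).
#' @param seed Integer seed.
#' @param meanlog_high,meanlog_low,sdlog Log-normal parameters for high
#'   and low tissues (defaults: median FPKM 50 vs 0.5, sdlog 0.5).
#' @return list with `fpkm` (matrix genes x tissues) and `truth`, a
#'   named integer vector of group ids per gene.
#' @export
simulate_expression <- function(groups,
                                tissues = c("callus", "root", "stem",
                                            "leaf", "flower", "silique"),
                                seed = 1L, meanlog_high = log(50),
                                meanlog_low = log(0.5), sdlog = 0.5) {
  set.seed(seed)
  n_genes <- sum(vapply(groups, `[[`, numeric(1), "size"))
  ids <- sprintf("gene%03d", seq_len(n_genes))
  mat <- matrix(0, nrow = n_genes, ncol = length(tissues),
                dimnames = list(ids, tissues))
  truth <- integer(n_genes)
  row <- 1L
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    stopifnot(all(grp$high %in% tissues))
    for (k in seq_len(grp$size)) {
      if (length(grp$high) > 0L) {
        hi <- tissues %in% grp$high
        mat[row, hi] <- stats::rlnorm(sum(hi), meanlog_high, sdlog)
        mat[row, !hi] <- stats::rlnorm(sum(!hi), meanlog_low, sdlog)
      }  # else: all-zero gene
      truth[row] <- g
      row <- row + 1L
    }
  }
  list(fpkm = mat, truth = stats::setNames(truth, ids))
}

#' Simulate a gene coordinate map with planted tandem arrays
#'
#' Plants family-gene arrays (members ~10 kb apart with no intervening
#' genes), isolated family singletons (>= 500 kb from anything) and
#' scattered non-family genes on a set of chromosomes.
#'
#' @param arrays Integer vector of planted array sizes (each >= 2).
#' @param n_singletons Number of isolated family genes.
#' @param n_nonfamily Number of scattered non-family genes.
#' @param n_chromosomes Number of chromosomes (labelled `A01`, ...).
#' @param seed Integer seed.
#' @return list with `genes` (data.frame `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `in_family`) and `truth`, a list of gene-id
#'   vectors, one per planted array.
#' @export
simulate_gene_map <- function(arrays = c(2L, 2L, 3L), n_singletons = 20L,
                              n_nonfamily = 30L, n_chromosomes = 10L,
                              seed = 1L) {
  set.seed(seed)
  chroms <- sprintf("A%02d", seq_len(n_chromosomes))
  rows <- list()
  truth <- list()
  gid <- 0L
  next_id <- function(fam) {
    gid <<- gid + 1L
    sprintf("%s%03d", if (fam) "Fam" else "Bg", gid)
  }
  cursor <- stats::setNames(rep(1e6, n_chromosomes), chroms)
  place <- function(chrom, fam, width = 2000) {
    start <- cursor[[chrom]]
    cursor[[chrom]] <<- start + width + 10e3  # ~10 kb to the next gene
    id <- next_id(fam)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = start + width,
      strand = sample(c("+", "-"), 1L), gene_id = id, in_family = fam,
      stringsAsFactors = FALSE)
    id
  }
  skip <- function(chrom) cursor[[chrom]] <<- cursor[[chrom]] + 5e5
  for (a in seq_along(arrays)) {
    chrom <- chroms[(a - 1L) %% n_chromosomes + 1L]
    skip(chrom)
    truth[[a]] <- vapply(seq_len(arrays[a]), function(k) place(chrom, TRUE),
                         character(1))
    skip(chrom)
  }
  for (k in seq_len(n_singletons)) {
    chrom <- sample(chroms, 1L)
    skip(chrom); place(chrom, FALSE); skip(chrom)
    place(chrom, TRUE)
    skip(chrom)
  }
  for (k in seq_len(n_nonfamily)) {
    chrom <- sample(chroms, 1L)
    skip(chrom); place(chrom, FALSE)
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, truth = truth)
}

#' Simulate a synteny table with known subgenome copy numbers
#'
#' @param n_triplet,n_duplet,n_singlet Numbers of ortholog anchors with
#'   3, 2 and 1 surviving subgenome copies.
#' @param n_orphans Family genes with no ortholog anchor.
#' @param seed Integer seed.
#' @return data.frame `gene_id`, `anchor_id`, `subgenome`, `block`.
#' @export
simulate_synteny <- function(n_triplet = 5L, n_duplet = 10L,
                             n_singlet = 20L, n_orphans = 3L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  gid <- 0L
  add <- function(anchor, sgs, block) {
    for (sg in sgs) {
      gid <<- gid + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = sprintf("Bra%05d", gid), anchor_id = anchor,
        subgenome = sg, block = block, stringsAsFactors = FALSE)
    }
  }
  anchor_no <- 0L
  blocks <- sprintf("%s", LETTERS[1:23])
  new_anchor <- function() {
    anchor_no <<- anchor_no + 1L
    sprintf("AT%05d", anchor_no)
  }
  for (k in seq_len(n_triplet)) add(new_anchor(), SUBGENOMES,
                                    sample(blocks, 1L))
  for (k in seq_len(n_duplet)) add(new_anchor(), sample(SUBGENOMES, 2L),
                                   sample(blocks, 1L))
  for (k in seq_len(n_singlet)) add(new_anchor(), sample(SUBGENOMES, 1L),
                                    sample(blocks, 1L))
  for (k in seq_len(n_orphans)) add(NA_character_, sample(SUBGENOMES, 1L),
                                    sample(blocks, 1L))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
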