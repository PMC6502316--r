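# Independent oracles, deliberately written as plain brute force so they
# share no code path with the package implementation.

# Exhaustive candidate enumeration by four nested index loops.
oracle_enumerate <- function(sequence, max_ch = 35L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  rows <- list()
  for (c1 in 0:(n - 1L)) {
    if (chars[c1 + 1L] != "C") next
    for (c2 in 0:(n - 1L)) {
      if (chars[c2 + 1L] != "C") next
      c2sp <- c2 - c1 - 1L
      if (c2sp < 1L || c2sp > 4L) next
      for (h1 in 0:(n - 1L)) {
        if (chars[h1 + 1L] != "H") next
        chsp <- h1 - c2 - 1L
        if (chsp < 1L || chsp > max_ch) next
        found <- FALSE
        for (h2 in 0:(n - 1L)) {
          if (chars[h2 + 1L] != "H") next
          hhsp <- h2 - h1 - 1L
          if (hhsp < 1L || hhsp > 8L) next
          found <- TRUE
          rows[[length(rows) + 1L]] <- c(c1, c2, h1, h2)
        }
        if (!found && chsp %in% c(12L, 13L)) {
          rows[[length(rows) + 1L]] <- c(c1, c2, h1, NA_integer_)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(matrix(integer(0), ncol = 4L,
                  dimnames = list(NULL, c("c1", "c2", "h1", "h2"))))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("c1", "c2", "h1", "h2")
  m[order(m[, "c1"], m[, "c2"], m[, "h1"], m[, "h2"],
          na.last = TRUE), , drop = FALSE]
}

# Canonical key for comparing candidate sets regardless of row order.
candidate_key <- function(df) {
  sort(paste(df[["c1"]], df[["c2"]], df[["h1"]], df[["h2"]], sep = ":"))
}

# --- NG86 oracle: explicit pathway enumeration by recursion ------------

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

oracle_aa <- function(codon) {
  if (codon %in% ORACLE_STOPS) "*" else Biostrings::GENETIC_CODE[[codon]]
}

oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (nt == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (!(alt %in% ORACLE_STOPS) &&
          oracle_aa(alt) == oracle_aa(codon)) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# All mutational pathways from one codon to another, as lists of
# (syn steps, nonsyn steps, passed through a stop).
oracle_paths <- function(from, to) {
  pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (length(pos) == 0L) {
    return(list(list(s = 0, n = 0, stop = FALSE)))
  }
  out <- list()
  for (p in pos) {
    mid <- from
    substr(mid, p, p) <- substr(to, p, p)
    step_syn <- oracle_aa(from) == oracle_aa(mid)
    step_stop <- mid %in% ORACLE_STOPS
    for (rest in oracle_paths(mid, to)) {
      out[[length(out) + 1L]] <- list(
        s = rest$s + as.integer(step_syn),
        n = rest$n + as.integer(!step_syn),
        stop = rest$stop || step_stop)
    }
  }
  out
}

oracle_codon_diffs <- function(from, to) {
  paths <- oracle_paths(from, to)
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  if (any(ok)) paths <- paths[ok]
  c(s = mean(vapply(paths, `[[`, numeric(1), "s")),
    n = mean(vapply(paths, `[[`, numeric(1), "n")))
}

oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca),
              function(i) oracle_codon_diffs(ca[i], cb[i]), numeric(2))
  Sd <- sum(d["s", ])
  Nd <- sum(d["n", ])
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p >= 3 / 4) Inf else -3 / 4 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       ks = jc(ps), ka = jc(pn))
}

random_sense_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# --- pI oracle: charge-curve grid search -------------------------------

oracle_pi <- function(sequence) {
  coarse <- seq(0, 14, by = 0.01)
  q <- peptide_charge(sequence, coarse)
  i <- which(diff(sign(q)) < 0)[1]  # charge is decreasing in pH
  fine <- seq(coarse[i], coarse[i + 1L], by = 1e-5)
  qf <- peptide_charge(sequence, fine)
  fine[which.min(abs(qf))]
}

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Random protein over the full alphabet with C/H enriched so candidate
# geometries actually occur.
random_protein <- function(len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  w <- rep(1, length(aa))
  w[aa == "C"] <- 6
  w[aa == "H"] <- 6
  w[aa == "X"] <- 0.3
  paste(sample(aa, len, replace = TRUE, prob = w), collapse = "")
}
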