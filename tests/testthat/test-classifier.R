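make_match <- function(c2_spacing = 2L, ch_spacing = 12L, hh_spacing = 3L,
                       motif6 = "QALGGH", d_type = FALSE, c1 = 10L) {
  c2 <- c1 + c2_spacing + 1L
  h1 <- c2 + ch_spacing + 1L
  h2 <- if (d_type) NA_integer_ else h1 + hh_spacing + 1L
  data.frame(c1 = c1, c2 = c2, h1 = h1, h2 = h2,
             c2_spacing = c2_spacing, ch_spacing = ch_spacing,
             hh_spacing = if (d_type) NA_integer_ else hh_spacing,
             span_start = c1 - 2L,
             span_end = if (d_type) h1 + 3L else h2 + 1L,
             motif6 = motif6, stringsAsFactors = FALSE)
}

test_that("count_degraded counts mismatches over the first five positions", {
  expect_equal(count_degraded("QALGGH"), 0L)
  expect_equal(count_degraded("QSLGAH"), 2L)
  expect_equal(count_degraded("STVKRH"), 5L)
  expect_equal(count_degraded(c("QALGGH", "XALGGH")), c(0L, 1L))  # X mismatch
  expect_error(count_degraded("QALGG"), "length 6")
  expect_error(count_degraded("QALGGG"), "end in")
})

test_that("classify_domains implements the full decision tree", {
  expect_equal(classify_domains(make_match())$type_label, "Q")
  expect_equal(classify_domains(make_match(motif6 = "QSLGAH"))$type_label,
               "M2")
  expect_equal(classify_domains(make_match(ch_spacing = 14L,
                                           motif6 = "QALGGH"))$type_label,
               "Z1")
  expect_equal(classify_domains(make_match(ch_spacing = 9L))$type_label,
               "Z2")
  expect_equal(classify_domains(make_match(d_type = TRUE))$type_label, "D")
})

test_that("the type partition is total and exclusive", {
  set.seed(21)
  for (i in 1:200) {
    d_type <- runif(1) < 0.15
    m <- make_match(c2_spacing = sample(1:4, 1L),
                    ch_spacing = sample(1:35, 1L),
                    hh_spacing = sample(1:8, 1L),
                    motif6 = paste0(random_peptide(5L), "H"),
                    d_type = d_type)
    cl <- classify_domains(m)
    expect_true(cl$type_label %in% TYPE_LEVELS)
    # label consistency with its defining property
    if (cl$type_label == "D") expect_true(is.na(m$h2))
    if (cl$type_label == "Z1") expect_gt(m$ch_spacing, 12L)
    if (cl$type_label == "Z2") expect_lt(m$ch_spacing, 12L)
    if (cl$type_label == "Q") {
      expect_equal(m$ch_spacing, 12L)
      expect_equal(cl$degraded_count, 0L)
    }
    if (grepl("^M", cl$type_label)) {
      expect_equal(m$ch_spacing, 12L)
      expect_equal(cl$degraded_count,
                   as.integer(substr(cl$type_label, 2L, 2L)))
    }
  }
})

test_that("classify_protein assigns tandem and dispersed subsets", {
  place <- function(specs, linkers) {
    # lay typed domains along a virtual sequence with given linkers
    out <- list(); pos <- 10L
    for (j in seq_along(specs)) {
      m <- classify_domains(do.call(make_match, c(specs[[j]],
                                                  list(c1 = pos))))
      out[[j]] <- m
      last <- if (is.na(m$h2)) m$h1 else m$h2
      if (j < length(specs)) pos <- last + linkers[j] + 1L
    }
    do.call(rbind, out)
  }
  q <- list()
  expect_equal(classify_protein(place(list(q, q, q), c(5L, 8L)))$subset,
               "Br-t1-SF")
  expect_equal(classify_protein(place(list(list(motif6 = "QSLGSH")),
                                      integer(0)))$subset, "Br-1i-M-SF")
  expect_equal(classify_protein(place(list(q, list(motif6 = "QSLGAH")),
                                      20L))$subset, "Br-2i-Mix-SF")
  nine <- place(rep(list(q), 9L), rep(5L, 8L))
  expect_equal(classify_protein(nine)$subset, "Br-t2-SF")
  expect_equal(classify_protein(place(list(q, q), 20L))$subset,
               "Br-2i-Q-SF")
  expect_equal(classify_protein(place(list(list(ch_spacing = 14L),
                                           list(ch_spacing = 9L)),
                                      30L))$subset, "Br-2i-Z-SF")
  expect_equal(classify_protein(place(rep(list(q), 3L),
                                      c(15L, 20L)))$subset, "Br-3i-SF")
  expect_equal(classify_protein(place(rep(list(q), 4L),
                                      c(15L, 20L, 12L)))$subset, "Br-4i-SF")
  expect_equal(classify_protein(place(list(list(d_type = TRUE)),
                                      integer(0)))$subset, "Br-1i-D-SF")
})

test_that("edge subsets: >= 5 dispersed, mixed linkers, overlap error", {
  place2 <- function(n, linkers) {
    out <- list(); pos <- 10L
    for (j in seq_len(n)) {
      m <- classify_domains(make_match(c1 = pos))
      out[[j]] <- m
      if (j < n) pos <- m$h2 + linkers[j] + 1L
    }
    do.call(rbind, out)
  }
  expect_warning(cl <- classify_protein(place2(5L, rep(20L, 4L))),
                 "no defined subset")
  expect_equal(cl$subset, "Unclassified")

  mixed <- classify_protein(place2(3L, c(5L, 20L)))
  expect_true(mixed$mixed_linker)
  expect_equal(mixed$subset, "Br-t1-SF")  # 1 vs 1, tie goes to tandem

  mixed2 <- classify_protein(place2(4L, c(20L, 20L, 5L)))
  expect_true(mixed2$mixed_linker)
  expect_equal(mixed2$subset, "Br-4i-SF")  # dispersed majority

  overlapping <- rbind(classify_domains(make_match(c1 = 10L)),
                       classify_domains(make_match(c1 = 12L)))
  expect_error(classify_protein(overlapping), "overlapping")
})

test_that("classification ignores sequence content outside domains", {
  tpl <- subset_templates()
  for (seed in c(2, 3)) {
    sim <- simulate_proteome(list(tpl$i2_mix$specs), list(tpl$i2_mix$linkers),
                             seed = seed, flank = c(8L, 30L))
    cls <- classify_proteome(scan_proteome(sim$sequences))
    expect_equal(cls$subset, "Br-2i-Mix-SF")
  }
})

test_that("protein_stats computes length, MW and pI", {
  g <- protein_stats("G")
  expect_equal(g$length, 1L)
  expect_equal(g$mw_kda * 1000, 75.07, tolerance = 1e-4)

  polyd <- protein_stats(strrep("D", 10L))
  expect_lt(polyd$pi, 7)
  polyk <- protein_stats(strrep("K", 10L))
  expect_gt(polyk$pi, 7)

  all20 <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(protein_stats(all20)$pi, oracle_pi(all20), tolerance = 1e-3)

  withx <- protein_stats("GXG")
  expect_true(withx$has_unknown)
  expect_gt(withx$mw_kda, 0)
})

test_that("crosstab_subsets tallies subsets by domain count", {
  m <- crosstab_subsets(c("Br-1i-Q-SF", "Br-1i-Q-SF"), c(1L, 1L))
  expect_equal(m["Br-1i-Q-SF", "1"], 2L)
  expect_equal(sum(m), 2L)
  expect_equal(ncol(crosstab_subsets(character(0), integer(0))), 0L)

  sim <- full_coverage_proteome(30L, seed = 4)
  cls <- classify_proteome(scan_proteome(sim$sequences),
                           proteins = names(sim$sequences))
  xt <- crosstab_subsets(cls$subset, cls$n_domains)
  truth_tab <- table(factor(sim$subsets$subset, levels = SUBSET_LEVELS),
                     factor(sim$subsets$n_domains))
  expect_equal(sum(xt), 30L)
  expect_equal(unname(rowSums(xt)), unname(as.integer(rowSums(truth_tab))))
})
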