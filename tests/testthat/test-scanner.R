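test_that("enumerate_candidates matches hand-enumerated examples", {
  m <- enumerate_candidates("MACKTCFSRSGKAQALGGHRRTH")
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1L, c("c1", "c2", "h1", "h2")]),
               c(c1 = 2L, c2 = 5L, h1 = 18L, h2 = 22L))
  expect_equal(m$motif6, "QALGGH")
  expect_equal(m$span_start, 0L)  # leading X2 clamped at the start
  expect_equal(m$span_end, 23L)

  # final His removed: the quadruple degrades to a D-candidate triple
  d <- enumerate_candidates("MACKTCFSRSGKAQALGGHRT")
  expect_equal(nrow(d), 1L)
  expect_true(is.na(d$h2))
  expect_equal(d$ch_spacing, 12L)

  expect_equal(nrow(enumerate_candidates("MKLVAAHTWHAA")), 0L)  # no Cys
})

test_that("invalid residues are rejected with the offending position", {
  expect_error(enumerate_candidates("MAB"), "position 2")
  expect_error(enumerate_candidates("MAC*TC"), "position 3")
  # X is tolerated but never a ligand
  expect_equal(nrow(enumerate_candidates("MAXKTXFSRSGKAQALGGXRRTX")), 0L)
})

test_that("enumeration equals the four-nested-loop oracle", {
  set.seed(42)
  for (i in 1:60) {
    s <- random_protein(sample(10:60, 1L))
    expect_identical(candidate_key(enumerate_candidates(s)),
                     candidate_key(as.data.frame(oracle_enumerate(s))),
                     info = s)
  }
})

test_that("resolve_overlaps keeps disjoint candidates and applies priority", {
  one <- enumerate_candidates("MACKTCFSRSGKAQALGGHRRTH")
  expect_identical(resolve_overlaps(one), one)

  # two quadruples sharing c1; ch_spacing 12 beats ch_spacing 14
  s <- "AACTTCAAAAAAAAAAAAHTHTTTH"
  cand <- enumerate_candidates(s)
  expect_true(any(cand$ch_spacing == 12L) && any(cand$ch_spacing == 14L))
  res <- resolve_overlaps(cand)
  expect_true(all(res$ch_spacing == 12L))

  # two disjoint fingers: both survive, sorted by c1
  sim <- simulate_proteome(list(list(zf_spec("Q"), zf_spec("Q"))),
                           list(20L), seed = 3)
  res2 <- scan_protein(sim$sequences[[1L]])
  expect_equal(nrow(res2), 2L)
  expect_true(!is.unsorted(res2$c1))
})

test_that("scan output is non-overlapping, sorted, a candidate subset", {
  set.seed(7)
  for (i in 1:25) {
    s <- random_protein(sample(20:60, 1L))
    cand <- enumerate_candidates(s)
    res <- scan_protein(s)
    expect_true(all(candidate_key(res) %in% candidate_key(cand)))
    expect_true(!is.unsorted(res$c1))
    lig <- unlist(lapply(seq_len(nrow(res)), function(j) {
      v <- c(res$c1[j], res$c2[j], res$h1[j], res$h2[j])
      v[!is.na(v)]
    }))
    expect_false(anyDuplicated(lig) > 0)
  }
})

test_that("appending residues never removes a fully-contained match", {
  # "fully contained": quadruples, and D-triples whose His-completion
  # window [h1+2, h1+9] already lies inside the original sequence (a
  # D-candidate with an open window is by definition provisional).
  set.seed(11)
  for (i in 1:20) {
    s <- random_protein(sample(20:50, 1L))
    n <- nchar(s)
    before <- enumerate_candidates(s)
    closed <- before[!is.na(before$h2) |
                       (before$h1 + 9L) < n, , drop = FALSE]
    longer <- paste0(s, random_protein(sample(5:20, 1L)))
    after <- enumerate_candidates(longer)
    expect_true(all(candidate_key(closed) %in% candidate_key(after)))
  }
})

test_that("scan of a planted proteome recovers exactly the truth", {
  sim <- simulate_proteome(
    list(list(zf_spec("Q"), zf_spec("M2"), zf_spec("Z1", ch_spacing = 18L))),
    list(c(20L, 25L)), seed = 5)
  res <- scan_protein(sim$sequences[[1L]])
  expect_equal(nrow(res), 3L)
  expect_equal(res$c1, sim$truth$c1)
  expect_equal(ifelse(is.na(res$h2), res$h1, res$h2), sim$truth$last_ligand)
})

test_that("decoy-mode scan equals the optimal selection's ligand count", {
  # on short decoy sequences, greedy output must be maximal: no candidate
  # outside the selection is ligand-disjoint from all selected ones
  set.seed(13)
  for (i in 1:15) {
    s <- random_protein(sample(20:55, 1L))
    cand <- enumerate_candidates(s)
    res <- scan_protein(s)
    if (nrow(cand) == 0L) next
    used <- unlist(lapply(seq_len(nrow(res)), function(j) {
      v <- c(res$c1[j], res$c2[j], res$h1[j], res$h2[j]); v[!is.na(v)]
    }))
    key_res <- candidate_key(res)
    for (j in seq_len(nrow(cand))) {
      v <- c(cand$c1[j], cand$c2[j], cand$h1[j], cand$h2[j])
      v <- v[!is.na(v)]
      k <- paste(cand$c1[j], cand$c2[j], cand$h1[j], cand$h2[j], sep = ":")
      if (!k %in% key_res) expect_true(any(v %in% used), info = s)
    }
  }
})

test_that("scan_proteome handles FASTA round trips", {
  sim <- full_coverage_proteome(6L, seed = 9)
  fa <- tempfile(fileext = ".faa")
  write_proteome_fasta(sim, fa)
  res <- scan_proteome(fa)
  expect_equal(sort(unique(res$protein_id)), sort(names(sim$sequences)))
  expect_equal(nrow(res), nrow(sim$truth))
  tsv <- tempfile(fileext = ".tsv")
  write_domain_tsv(res, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(res))
  expect_equal(names(back)[1:3], c("protein_id", "c1", "c2"))
})
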