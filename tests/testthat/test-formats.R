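# alignment containers, formats, weights, consensus, column statistics

test_that("mFASTA parsing infers match columns and keeps insert states", {
  m <- read_mfasta(c(">a", "AC-D", ">b", "AGGD"))
  expect_equal(m$L, 4L)
  expect_equal(nrow(m$rows), 2L)
  expect_equal(m$rows$states, c("AC-D", "AGGD"))

  m2 <- read_mfasta(c(">a", "AC-D", ">b", "ACxxGD"))
  expect_equal(m2$L, 4L)
  expect_equal(m2$rows$states[2], "ACxxGD")
  expect_equal(ungap_states(m2$rows$states[2]), "ACXXGD")

  expect_error(read_mfasta(c(">a", "ACD", ">b", "ACDE")), "match columns")
})

test_that("mFASTA and cma writers invert their readers", {
  m <- read_mfasta(c(">a desc here", "AC-Dxx", ">b", "AGG-a"))
  expect_equal(read_mfasta(write_mfasta(m))$rows, m$rows)

  # cma keeps flanks and the protected flag
  m$rows$flank_left <- c(3L, 0L)
  m$rows$flank_right <- c(0L, 7L)
  m$rows$protected <- c(TRUE, FALSE)
  back <- read_cma(write_cma(m))
  expect_equal(back$rows, m$rows)
  expect_equal(back$L, m$L)
  expect_equal(back$name, m$name)
})

test_that("format round-trips are lossless on seeded random alignments", {
  for (seed in 1:25) {
    m <- random_msa(seed, L_range = c(5, 60), rows_range = c(1, 20),
                    flanks = TRUE)
    expect_equal(read_cma(write_cma(m))$rows, m$rows, info = paste("seed", seed))
    m0 <- m
    m0$rows$flank_left <- 0L
    m0$rows$flank_right <- 0L
    via_cma <- read_cma(write_cma(read_mfasta(write_mfasta(m0))))
    expect_equal(read_mfasta(write_mfasta(via_cma))$rows$states, m0$rows$states,
                 info = paste("seed", seed))
  }
})

test_that("cma parse errors carry line numbers", {
  lines <- write_cma(mk_msa(c("ACD", "AC-")))
  expect_error(read_cma_bundle(lines[-length(lines)]), "line")
  bad <- lines
  bad[2] <- sub("^>", "", bad[2])
  expect_error(read_cma_bundle(bad), "line 2")
})

test_that("split_fasta chunks preserve record order and sizes", {
  db <- data.frame(seq_id = sprintf("s%d", 1:7), desc = "",
                   seq = rep("ACDEF", 7), stringsAsFactors = FALSE)
  ch <- split_fasta(db, 3)
  expect_equal(vapply(ch, nrow, 0L), c(3L, 3L, 1L))
  expect_equal(do.call(rbind, c(ch, list(make.row.names = FALSE))), db)
  expect_equal(split_fasta(db[0, ], 3), list())
  big <- data.frame(seq_id = sprintf("s%d", 1:250000), desc = "", seq = "A",
                    stringsAsFactors = FALSE)
  expect_length(split_fasta(big, 250000), 1L)
})

test_that("position weights are Henikoff position-based, mean 1", {
  expect_equal(position_weights(mk_msa("ACD")), 1)
  m <- mk_msa(c("A", "A", "C"))
  w <- position_weights(m)
  expect_equal(mean(w), 1)
  # unnormalized masses 1/4, 1/4, 1/2
  expect_equal(w / sum(w), c(0.25, 0.25, 0.5))
  # duplicating a row strictly reduces its weight share
  m2 <- mk_msa(c("AC", "GT"))
  m3 <- mk_msa(c("AC", "GT", "GT"))
  w2 <- position_weights(m2) / sum(position_weights(m2))
  w3 <- position_weights(m3) / sum(position_weights(m3))
  expect_lt(w3[2], w2[2])
  expect_equal(w3[2], w3[3])
})

test_that("consensus follows weighted majority with alphabetical ties", {
  expect_equal(consensus(mk_msa(c("A", "A", "C"))), "A")
  expect_equal(consensus(mk_msa(c("A", "C")), weights = c(1, 1)), "A")
  expect_equal(consensus(mk_msa(c("A", "A", "C")),
                         weights = c(0.2, 0.2, 1.0)), "C")
  expect_error(consensus(mk_msa(c("A-", "A-"))), "all-gap|no residues")
  # invariant under row duplication once weights are recomputed
  m <- mk_msa(c("ACDE", "ACDG", "TCDG"))
  m2 <- mk_msa(c("ACDE", "ACDG", "TCDG", "TCDG"))
  expect_equal(consensus(m2), consensus(m))
})

test_that("column relative entropy matches closed forms and is nonnegative", {
  uni <- column_stats(mk_msa(aa20))
  expect_equal(uni$relative_entropy, 0, tolerance = 1e-12)
  single <- column_stats(mk_msa(c("A", "A", "A")))
  expect_equal(single$relative_entropy, log(20), tolerance = 1e-9)
  half <- column_stats(mk_msa(c("A", "C")))
  expect_equal(half$relative_entropy, log(10), tolerance = 1e-9)
  expect_equal(half$average_re, log(10), tolerance = 1e-9)
  for (seed in 1:5) {
    m <- random_msa(seed, L_range = c(5, 30), rows_range = c(2, 20))
    expect_true(all(column_stats(m)$relative_entropy >= -1e-12))
  }
})

test_that("percent identity uses the min-residue-count denominator", {
  expect_equal(percent_identity("AAAA", "AAAA"), 1)
  expect_equal(percent_identity("AAAA", "AAAC"), 0.75)
  expect_equal(percent_identity("AA--", "AACC"), 1)
  expect_equal(percent_identity("A---", "-CCC"), 0)
  expect_error(percent_identity("AAA", "AAAA"), "match-column counts")
  # symmetry on random rows
  for (seed in 1:10) {
    m <- random_msa(seed, L_range = c(5, 40), rows_range = c(2, 6))
    a <- m$rows$states[1]; b <- m$rows$states[2]
    expect_equal(percent_identity(a, b), percent_identity(b, a))
  }
})

test_that("match fraction counts residues over match columns", {
  expect_equal(match_fraction("ACDE"), 1)
  expect_equal(match_fraction("A-C-"), 0.5)
  expect_equal(match_fraction(strrep("A", 74), L = 100), 0.74)
})
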