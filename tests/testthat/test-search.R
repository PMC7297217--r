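# profiles, alignment, E-values, pruned search, split-hit merging

test_that("profile scores are half-bit log-odds with pseudocounts", {
  # near-zero pseudocount mass: a single-row profile favors its residue
  m <- mk_msa("A")
  p <- build_profile(m, beta = 1e-9)
  expect_gt(p$scores[1, "A"], 0)
  expect_true(all(p$scores[1, setdiff(aa20, "A")] < p$scores[1, "A"]))

  # frequencies equal to the background give score 0 as beta -> 0
  q <- hialign:::robinson_background()
  mq <- mk_msa(aa20)  # one residue per row, L = 1
  pq <- build_profile(mq, weights = 20 * q / sum(q), beta = 1e-9,
                      background = q)
  expect_true(all(pq$scores == 0))

  expect_true(p$gap_extend <= p$gap_open)
})

test_that("profile construction matches an independent reference", {
  # straight-line reimplementation of the same formula, no shared code paths
  ref_scores <- function(m, weights, beta) {
    q <- hialign:::robinson_background()
    B <- hialign:::get_blosum62()[aa20, aa20]
    P <- sapply(aa20, function(b) {
      v <- q * 2^(B[, b] / 2); v / sum(v)
    })
    t(sapply(seq_len(m$L), function(j) {
      counts <- setNames(numeric(20), aa20)
      for (i in seq_len(nrow(m$rows))) {
        ch <- strsplit(m$rows$states[i], "")[[1]]
        mc <- ch[ch == "-" | ch %in% LETTERS][j]
        if (mc %in% aa20) counts[mc] <- counts[mc] + weights[i]
      }
      mj <- sum(counts)
      f <- counts / mj
      g <- as.numeric(P %*% f)
      round(2 * log2(((mj * f + beta * g) / (mj + beta)) / q))
    }))
  }
  m <- random_msa(5, L_range = c(4, 8), rows_range = c(3, 8))
  w <- position_weights(m)
  p <- build_profile(m, weights = w, beta = 10)
  expect_equal(unname(p$scores), unname(ref_scores(m, w, 10)))
})

test_that("local alignment handles perfect matches and hopeless queries", {
  m <- mk_msa("ACDE")
  p <- build_profile(m, beta = 1e-9)
  al <- local_align(p, "ACDE")
  expect_equal(al$col_of_res, 1:4)
  expect_equal(al$score, sum(p$scores[cbind(1:4, match(c("A", "C", "D", "E"), aa20))]))
  expect_equal(c(al$qstart, al$qend, al$cstart, al$cend), c(1, 4, 1, 4))

  pw <- build_profile(mk_msa("WWWW"), beta = 1e-9)
  al0 <- local_align(pw, "AAAA")
  expect_equal(al0$score, 0)
  expect_length(al0$col_of_res, 0)
})

test_that("local alignment equals the brute-force oracle on random cases", {
  for (case in 1:40) {
    p <- rand_profile(case)
    s <- rand_seq(1000 + case, sample(2:8, 1))
    got <- local_align(p, s)
    want <- oracle_local_score(p$scores, encode20(s), p$gap_open, p$gap_extend)
    expect_equal(got$score, want, info = paste("case", case))
  }
})

test_that("local alignment score ignores flanks that cannot score", {
  p <- build_profile(mk_msa(c("ACDEFG", "ACDEFG")), beta = 1e-9)
  base <- local_align(p, "ACDEFG")$score
  expect_equal(local_align(p, "XXXACDEFGXXX")$score, base)
})

test_that("glocal paths consume every profile column", {
  p <- build_profile(mk_msa(c("ACDEFG", "ACDEFG")), beta = 1e-9)
  g <- glocal_align(p, "WWACDEFGWW")
  expect_equal(c(g$cstart, g$cend), c(1, 6))
  expect_equal(g$col_of_res, 1:6)
  expect_equal(c(g$qstart, g$qend), c(3, 8))
  # a truly missing terminal column becomes a deletion, not a misalignment
  g2 <- glocal_align(p, "CDEFG")
  expect_equal(g2$col_of_res, 2:6)
})

test_that("expectation values follow the Karlin-Altschul form", {
  p <- rand_profile(3, L = 5)
  expect_equal(evalue(0, p, 1000), p$K * p$L * 1000)
  expect_equal(evalue(10, p, 2000), 2 * evalue(10, p, 1000))
  s <- seq(0, 100, by = 5)
  e <- vapply(s, evalue, 0, profile = p, db_residues = 1e6)
  expect_true(all(diff(e) < 0))
  expect_equal(score_for_evalue(p, evalue(37, p, 1e6), 1e6), 37)
})

test_that("calibration recovers sane Gumbel parameters", {
  m <- random_msa(21, L_range = c(30, 30), rows_range = c(10, 10))
  p <- build_profile(m)
  pc <- calibrate_evalue(p, n_seqs = 100, seq_len = 100, seed = 5)
  expect_gt(pc$lambda, 0.05)
  expect_lt(pc$lambda, 1.5)
  expect_gt(pc$K, 0)
})

sim_small <- simulate_superfamily(sf_params(n_nodes = 6, seqs_per_node = 10,
                                            n_decoys = 15, seed = 3))
profs_small <- build_himsa_profiles(sim_small$himsa)

test_that("a leaf consensus is assigned to that leaf", {
  h <- sim_small$himsa
  depths <- as.integer(h$tree)
  children <- hialign:::dft_parents(depths)
  leaves <- setdiff(seq_along(h$order), children)
  leaf <- h$order[leaves[which.max(depths[leaves])]]
  seq <- h$nodes[[leaf]]$consensus
  hits <- hierarchical_search(h, seq, search_params(), profs_small,
                              db_residues = 1e5)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$accession, leaf)
})

test_that("two concatenated domain copies give two disjoint hits", {
  h <- sim_small$himsa
  cons <- h$nodes[[1]]$consensus
  seq <- paste0(cons, rand_seq(99, 30), cons)
  hits <- hierarchical_search(h, seq, search_params(), profs_small,
                              db_residues = 1e5)
  expect_length(hits, 2L)
  r <- hits_table(hits)
  expect_true(r$end[1] < r$start[2])
})

test_that("unrelated sequences yield no significant hits", {
  h <- sim_small$himsa
  for (seed in 1:10) {
    hits <- hierarchical_search(h, rand_seq(seed, 150),
                                search_params(max_evalue = 0.001),
                                profs_small, db_residues = 2e5)
    expect_length(hits, 0L)
  }
})

test_that("pruned search with disabled triggers equals exhaustive argmax", {
  h <- sim_small$himsa
  neg <- setNames(rep(-Inf, length(h$order)), h$order)
  pars <- search_params(triggers = neg)
  dbres <- sum(nchar(sim_small$db$seq))
  for (i in seq_len(30)) {
    s <- sim_small$db$seq[i]
    ex <- exhaustive_assign(h, s, profs_small)
    hits <- hierarchical_search(h, s, pars, profs_small, dbres)
    if (length(hits) > 0) {
      expect_equal(hits[[1]]$accession, ex$accession,
                   info = sim_small$db$seq_id[i])
    }
  }
})

test_that("split sub-matches merge only when colinear and near", {
  mk_hit <- function(start, end, cstart, cend) {
    list(seq_id = "s", accession = "n", start = start, end = end,
         cstart = cstart, cend = cend,
         col_of_res = seq(cstart, length.out = end - start + 1L),
         residues = strrep("A", end - start + 1L),
         score = 50, evalue = 1e-6, seq_len = 200L)
  }
  h1 <- mk_hit(1, 40, 1, 40)
  h2 <- mk_hit(46, 85, 61, 100)
  merged <- merge_split_hits(list(h1, h2), max_internal_gap = 50)
  expect_length(merged, 1L)
  expect_equal(c(merged[[1]]$start, merged[[1]]$end), c(1, 85))
  expect_equal(c(merged[[1]]$cstart, merged[[1]]$cend), c(1, 100))
  expect_equal(sum(merged[[1]]$col_of_res == 0), 5L)  # bridged inserts
  expect_length(merge_split_hits(list(h1)), 1L)
  # overlapping column ranges are not colinear
  h3 <- mk_hit(46, 85, 30, 69)
  expect_length(merge_split_hits(list(h1, h3), 50), 2L)
  # too-long sequence gap stays split
  h4 <- mk_hit(120, 159, 61, 100)
  expect_length(merge_split_hits(list(h1, h4), 50), 2L)
})

test_that("repeated-domain masking terminates with disjoint regions", {
  h <- sim_small$himsa
  cons <- h$nodes[[1]]$consensus
  seq <- paste0(cons, rand_seq(7, 25), cons, rand_seq(8, 25), cons)
  hits <- hierarchical_search(h, seq, search_params(), profs_small, 1e5)
  expect_length(hits, 3L)
  r <- hits_table(hits)
  r <- r[order(r$start), ]
  expect_true(all(r$start[-1] > r$end[-nrow(r)]))
})
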