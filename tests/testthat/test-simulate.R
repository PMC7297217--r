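# synthetic superfamily generator and ground truth

test_that("identical seeds give byte-identical fixtures", {
  a <- simulate_superfamily(sf_params(n_nodes = 5, seqs_per_node = 6,
                                      n_decoys = 10, seed = 17))
  b <- simulate_superfamily(sf_params(n_nodes = 5, seqs_per_node = 6,
                                      n_decoys = 10, seed = 17))
  expect_identical(a$db, b$db)
  expect_identical(a$truth, b$truth)
  expect_identical(write_cma(a$himsa$template), write_cma(b$himsa$template))
  c_ <- simulate_superfamily(sf_params(n_nodes = 5, seqs_per_node = 6,
                                       n_decoys = 10, seed = 18))
  expect_false(identical(a$db$seq, c_$db$seq))
})

test_that("degenerate single-node hierarchies simulate cleanly", {
  sim <- simulate_superfamily(sf_params(n_nodes = 1, seqs_per_node = 5,
                                        n_decoys = 3, seed = 2))
  expect_length(sim$himsa$nodes, 1L)
  expect_equal(nrow(sim$db), 8L)
  expect_equal(nrow(validate_himsa(sim$himsa)), 0L)
})

test_that("the truth table covers exactly the embedded domain residues", {
  sim <- simulate_superfamily(sf_params(n_nodes = 6, seqs_per_node = 8,
                                        n_decoys = 5, seed = 19))
  members <- sim$db[!grepl("^decoy", sim$db$seq_id), ]
  # every member's domain residues appear, flanks and decoys do not
  per_seq <- split(sim$truth, sim$truth$seq_id)
  for (id in members$seq_id) {
    tt <- per_seq[[id]]
    expect_false(is.null(tt))
    expect_true(all(tt$pos >= 1 & tt$pos <= nchar(members$seq[members$seq_id == id])))
    expect_true(all(diff(tt$pos) == 1))  # contiguous embedded domain
  }
  expect_false(any(grepl("^decoy", sim$truth$seq_id)))
  # truth root columns respect the template maps
  expect_true(all(sim$truth$root_col[!sim$truth$insert] >= 1))
  expect_true(all(sim$truth$root_col[!sim$truth$insert] <= sim$himsa$root_L))
})

test_that("truth-derived placements score a perfect recovery", {
  sim <- simulate_superfamily(sf_params(n_nodes = 5, seqs_per_node = 6,
                                        n_decoys = 0, seed = 23))
  h <- sim$himsa
  rows <- lapply(split(sim$truth, sim$truth$seq_id), function(tt) {
    acc <- tt$node[1]
    nd <- h$nodes[[acc]]
    st <- nd$msa$rows$states[nd$msa$rows$seq_id == tt$seq_id[1]]
    data.frame(seq_id = paste0(tt$seq_id[1], "/r"), desc = "",
               states = project_curated_row(h, acc, st),
               flank_left = min(tt$pos) - 1L, flank_right = 0L,
               protected = FALSE, source_node = acc, orig_id = tt$seq_id[1],
               region_start = min(tt$pos), region_end = max(tt$pos),
               stringsAsFactors = FALSE)
  })
  g <- hialign:::new_global_msa(do.call(rbind, rows), h$root_L)
  expect_equal(score_recovery(g, sim$truth), 1)
  empty <- build_global_msa(list(), h)
  expect_equal(score_recovery(empty, sim$truth), 0)
})

test_that("covariation fixtures are seeded and carry their planted pairs", {
  a <- simulate_covariation(L = 10, n = 50, planted_pairs = 2, seed = 3)
  b <- simulate_covariation(L = 10, n = 50, planted_pairs = 2, seed = 3)
  expect_identical(a$rows$states, b$rows$states)
  pp <- attr(a, "planted_pairs")
  expect_equal(dim(pp), c(2L, 2L))
  expect_true(all(pp[, 2] - pp[, 1] >= 5))
  # explicit pair matrix is honored
  m <- simulate_covariation(L = 10, n = 20, planted_pairs = cbind(1, 8),
                            seed = 1)
  expect_equal(attr(m, "planted_pairs"), cbind(1, 8))
})

test_that("column-shuffle corruption preserves column compositions", {
  m <- simulate_covariation(L = 8, n = 100, planted_pairs = 1, seed = 6)
  mb <- corrupt_msa_rows(m, 0.5, seed = 7)
  comp <- function(x) apply(
    t(vapply(x$rows$states, function(s) strsplit(s, "")[[1]], character(8))),
    2, function(col) sort(table(col)))
  expect_equal(comp(mb), comp(m))
  expect_false(identical(m$rows$states, mb$rows$states))
})
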