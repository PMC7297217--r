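# hierarchy ingestion, tree arrays, template column maps

test_that("dft arrays parse, reject bad depth structure, and round-trip", {
  d <- parse_dft("0 1 2 2 1")
  expect_equal(as.integer(d), c(0L, 1L, 2L, 2L, 1L))
  expect_equal(emit_dft(d), "0 1 2 2 1")
  expect_equal(as.integer(parse_dft(emit_dft(d))), as.integer(d))
  expect_error(parse_dft("0 2"), "depth jump")
  expect_error(parse_dft("0 1 x"), "malformed")
  expect_error(parse_dft("1 2"), "root")
  expect_error(parse_dft("0 1 0"), "one root")
})

test_that("cdd2mgs assembles and validates hierarchies", {
  # degenerate single-node hierarchy
  root <- mk_msa(rep("ACDEFGHI", 2), c("a", "b"), accession = "cd01")
  tpl <- msa(data.frame(seq_id = "cd01", states = "ACDEFGHI",
                        stringsAsFactors = FALSE))
  h1 <- cdd2mgs(list(cd01 = root), tpl, parse_dft("0"))
  expect_s3_class(h1, "himsa")
  expect_length(h1$nodes, 1L)
  expect_equal(h1$root_L, 8L)

  h <- tiny_himsa()
  expect_length(h$nodes, 3L)
  expect_equal(h$nodes[["cd02"]]$parent, "cd01")
  expect_equal(nrow(validate_himsa(h)), 0L)

  # consensus mismatch is reported with the accession
  bad_tpl <- h$template
  bad_tpl$rows$states[2] <- "ACD--FGwyL"
  expect_error(
    cdd2mgs(list(cd01 = h$nodes[["cd01"]]$msa, cd02 = h$nodes[["cd02"]]$msa,
                 cd03 = h$nodes[["cd03"]]$msa), bad_tpl, parse_dft("0 1 1")),
    "cd02")

  # missing node file
  expect_error(
    cdd2mgs(list(cd01 = h$nodes[["cd01"]]$msa), h$template, parse_dft("0 1 1")),
    "cd02")
})

test_that("node-to-root maps follow template co-occupancy", {
  h <- tiny_himsa()
  expect_equal(unname(node_to_root_map(h, "cd01")), 1:8)
  # child cd02: planted deletion of root columns 4-5, insert of 2 residues
  mp <- node_to_root_map(h, "cd02")
  expect_equal(unname(mp[as.character(c(1, 2, 3, 4, 5, 8))]),
               c(1L, 2L, 3L, 6L, 7L, 8L))
  expect_false("6" %in% names(mp))  # insert-state columns map nowhere
  expect_false("7" %in% names(mp))
  skipped_roots <- setdiff(c(4L, 5L), unname(mp))
  expect_equal(skipped_roots, c(4L, 5L))  # deleted root columns have no image
  expect_true(all(diff(unname(mp)) > 0))
  expect_error(node_to_root_map(h, "nope"), "unknown accession")
})

test_that("validation reports planted defects as findings", {
  h <- tiny_himsa()
  h$template$rows$states[3] <- "AC-EFGHL"  # breaks consensus agreement
  f <- validate_himsa(h)
  expect_gt(nrow(f), 0L)
  expect_true(any(f$node == "cd03"))

  h2 <- tiny_himsa()
  h2$tree <- structure(c(0L, 2L, 1L), class = "dft")
  f2 <- validate_himsa(h2)
  expect_true(any(grepl("depth jump", f2$message)))
})

test_that("hierarchy distribution layout round-trips through disk", {
  sim <- simulate_superfamily(sf_params(n_nodes = 5, seqs_per_node = 6,
                                        n_decoys = 0, seed = 11))
  dir <- tempfile("himsa")
  write_himsa_dir(sim$himsa, dir)
  h2 <- read_himsa_dir(dir)
  expect_equal(h2$order, sim$himsa$order)
  expect_equal(h2$root_L, sim$himsa$root_L)
  expect_equal(lapply(h2$nodes, function(n) n$consensus),
               lapply(sim$himsa$nodes, function(n) n$consensus))
  expect_equal(nrow(validate_himsa(h2)), 0L)
  unlink(dir, recursive = TRUE)
})

test_that("node-to-root maps compose through parents (functoriality)", {
  sim <- simulate_superfamily(sf_params(n_nodes = 10, seqs_per_node = 5,
                                        n_decoys = 0, seed = 12))
  h <- sim$himsa
  for (acc in h$order[-1]) {
    par <- h$nodes[[acc]]$parent
    via <- hialign:::node_to_node_map(h, acc, par)
    p2r <- node_to_root_map(h, par)
    direct <- node_to_root_map(h, acc)
    composed <- p2r[as.character(unname(via))]
    names(composed) <- names(via)
    composed <- composed[!is.na(composed)]
    expect_equal(composed, direct[names(composed)], info = acc)
    expect_equal(sort(names(composed)), sort(names(direct)), info = acc)
  }
})

test_that("curated rows project to exactly root_L match states", {
  sim <- simulate_superfamily(sf_params(n_nodes = 6, seqs_per_node = 5,
                                        n_decoys = 0, seed = 13))
  h <- sim$himsa
  for (acc in h$order) {
    for (st in h$nodes[[acc]]$msa$rows$states) {
      proj <- project_curated_row(h, acc, st)
      expect_equal(hialign:::n_match_cols(proj), h$root_L)
      expect_equal(ungap_states(proj), ungap_states(st))
    }
  }
})
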