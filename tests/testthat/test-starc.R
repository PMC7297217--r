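# harmonization, direct couplings, contact maps, S-scores

test_that("harmonize trims, filters deletions, and equalizes sizes", {
  set.seed(31)
  mk_rand <- function(n, L, prefix) mk_msa(
    vapply(seq_len(n), function(i)
      paste(sample(aa20, L, replace = TRUE), collapse = ""), ""),
    sprintf("%s%03d", prefix, seq_len(n)))
  a <- mk_rand(50, 20, "a")
  out <- harmonize(a, a)
  expect_equal(out$a$rows$states, a$rows$states)

  expect_error(harmonize(a, a, cols_a = 1:5, cols_b = 1:6), "unequal")

  # a row with deletions in 30% of columns is removed
  b <- a
  b$rows$states[1] <- paste0(strrep("-", 6), substr(b$rows$states[1], 7, 20))
  out2 <- harmonize(b, a)
  expect_false("a001" %in% out2$a$rows$seq_id)

  # size equalization with protected rows retained
  big <- mk_rand(500, 15, "x")
  small <- mk_rand(300, 15, "y")
  res <- harmonize(big, small, structures = c("x001", "x002"), seed = 7)
  expect_equal(nrow(res$a$rows), 302L)  # 300 unprotected + 2 structures
  expect_equal(nrow(res$b$rows), 300L)
  expect_true(all(c("x001", "x002") %in% res$a$rows$seq_id))
  # seeded: reproducible
  res2 <- harmonize(big, small, structures = c("x001", "x002"), seed = 7)
  expect_equal(res$a$rows, res2$a$rows)
})

test_that("couplings are symmetric, row-order invariant, and signal-bearing", {
  m <- simulate_covariation(L = 12, n = 400, planted_pairs = 2, seed = 41)
  cp <- dca_couplings(m)
  ut <- upper.tri(cp)
  expect_equal(cp[ut], t(cp)[ut])
  expect_true(all(cp[ut] >= 0))
  perm <- m
  set.seed(1)
  perm$rows <- perm$rows[sample.int(nrow(perm$rows)), ]
  expect_equal(unclass(dca_couplings(perm)), unclass(cp))
  pp <- attr(m, "planted_pairs")
  noise <- cp
  noise[pp] <- NA; noise[pp[, c(2, 1)]] <- NA
  expect_gt(min(cp[pp]), max(noise[ut], na.rm = TRUE))
})

test_that("planted covarying pairs dominate independent-column noise", {
  m <- simulate_covariation(L = 30, n = 2000, planted_pairs = 5, seed = 8)
  pp <- attr(m, "planted_pairs")
  cp <- dca_couplings(m)
  ut <- which(upper.tri(cp), arr.ind = TRUE)
  key <- function(x) paste(pmin(x[, 1], x[, 2]), pmax(x[, 1], x[, 2]))
  noise_max <- max(cp[ut][!(key(ut) %in% key(pp))])
  expect_gte(min(cp[pp]), 3 * noise_max)
})

test_that("contact maps apply distance cutoff and separation rules", {
  coords <- data.frame(col = c(1, 10), x = c(0, 7.9), y = 0, z = 0)
  cm <- contact_map(coords, cutoff = 8, min_separation = 5)
  expect_equal(cm$M, 1L)
  expect_equal(cm$contacts, data.frame(i = 1L, j = 10L))

  near <- data.frame(col = c(1, 3), x = c(0, 1), y = 0, z = 0)
  expect_equal(contact_map(near, 8, 5)$M, 0L)

  chain <- data.frame(col = 1:30, x = 3.8 * (0:29), y = 0, z = 0)
  cm3 <- contact_map(chain, cutoff = 8, min_separation = 5)
  expect_equal(cm3$M, 0L)
  expect_equal(cm3$N, sum(outer(1:30, 1:30, function(i, j) j - i >= 5)))
})

test_that("S-scores match hypergeometric closed forms", {
  # k = 1, contact density 0.1, top pair is a contact -> P = 0.1, S = 1
  L <- 5L
  cp <- matrix(0, L, L)
  cp[1, 2] <- cp[2, 1] <- 5  # top pair
  cm <- contact_map_from_pairs(data.frame(i = 1, j = 2), L, min_separation = 1)
  expect_equal(cm$N, 10L)
  s1 <- s_score(structure(cp, class = c("coupling_matrix", "matrix")), cm, k = 1)
  expect_equal(s1$s_value, 1, tolerance = 1e-12)

  # all eligible pairs are contacts -> P = 1, S = 0
  allp <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  cm_all <- contact_map_from_pairs(data.frame(i = allp[, 1], j = allp[, 2]),
                                   L, min_separation = 1)
  s0 <- s_score(structure(cp, class = c("coupling_matrix", "matrix")), cm_all,
                k = 3)
  expect_equal(s0$s_value, 0)

  # perfect recovery of 5 planted contacts among 325 pairs
  m <- simulate_covariation(L = 30, n = 2000, planted_pairs = 5, seed = 8)
  pp <- attr(m, "planted_pairs")
  cmp <- contact_map_from_pairs(data.frame(i = pp[, 1], j = pp[, 2]), 30)
  sp <- s_score(dca_couplings(m), cmp, k = 5)
  expect_equal(sp$overlap, 5L)
  expect_equal(sp$s_value, log10(choose(325, 5)), tolerance = 1e-9)

  expect_error(s_score(dca_couplings(m), cmp, k = 0), "positive")
})

test_that("S is monotone in overlap at fixed k, M, N", {
  p <- vapply(0:5, function(x) phyper(x - 1, 5, 320, 5, lower.tail = FALSE), 0)
  s <- -log10(p)
  expect_true(all(diff(s) > 0))
})

test_that("quality report includes diversity alongside the S-score", {
  m <- simulate_covariation(L = 12, n = 200, planted_pairs = 2, seed = 5)
  pp <- attr(m, "planted_pairs")
  cm <- contact_map_from_pairs(data.frame(i = pp[, 1], j = pp[, 2]), 12)
  f <- tempfile(fileext = ".json")
  r <- starc_report(m, dca_couplings(m), cm, k = 2, file = f)
  expect_true(file.exists(f))
  back <- jsonlite::read_json(f)
  expect_equal(back$S, r$S, tolerance = 1e-9)
  expect_true(is.finite(r$avg_column_RE))
  unlink(f)
})
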