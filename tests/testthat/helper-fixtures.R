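# shared fixture builders and independent oracles

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mk_msa <- function(states, ids = sprintf("s%02d", seq_along(states)), ...) {
  msa(data.frame(seq_id = ids, states = states, stringsAsFactors = FALSE), ...)
}

# hand-built 3-node hierarchy: root (L = 8), one child with a planted
# 2-column deletion (root columns 4-5) plus a 2-residue insertion, one child
# with a single-column deletion (root column 3)
tiny_himsa <- function() {
  root <- mk_msa(rep("ACDEFGHI", 3), sprintf("r%02d", 1:3),
                 name = "cd01", accession = "cd01")
  kid1 <- mk_msa(rep("ACDFGWYI", 3), sprintf("k%02d", 1:3),
                 name = "cd02", accession = "cd02")
  kid2 <- mk_msa(rep("ACEFGHI", 3), sprintf("q%02d", 1:3),
                 name = "cd03", accession = "cd03")
  tpl <- msa(data.frame(seq_id = c("cd01", "cd02", "cd03"),
                        states = c("ACDEFGHI", "ACD--FGwyI", "AC-EFGHI"),
                        stringsAsFactors = FALSE),
             name = "template", accession = "cd01")
  cdd2mgs(list(cd01 = root, cd02 = kid1, cd03 = kid2), tpl, parse_dft("0 1 1"))
}

# random alignment with inserts, deletions and (optionally) flanks
random_msa <- function(seed, L_range = c(5, 200), rows_range = c(1, 50),
                       flanks = FALSE) {
  set.seed(seed)
  L <- sample(L_range[1]:L_range[2], 1)
  n <- sample(rows_range[1]:rows_range[2], 1)
  states <- vapply(seq_len(n), function(i) {
    ch <- ifelse(runif(L) < 0.9, sample(aa20, L, replace = TRUE), "-")
    # guarantee at least one residue so consensus-style ops stay defined
    if (all(ch == "-")) ch[sample.int(L, 1)] <- sample(aa20, 1)
    if (L > 1 && runif(1) < 0.5) {
      k <- sample.int(L - 1, 1)
      ch[k] <- paste0(ch[k], paste(tolower(sample(aa20, sample.int(3, 1),
                                                  replace = TRUE)),
                                   collapse = ""))
    }
    paste(ch, collapse = "")
  }, character(1))
  rows <- data.frame(seq_id = sprintf("r%03d", seq_len(n)),
                     desc = ifelse(runif(n) < 0.5, "some description", ""),
                     states = states,
                     flank_left = if (flanks) sample(0:9, n, TRUE) else 0L,
                     flank_right = if (flanks) sample(0:9, n, TRUE) else 0L,
                     protected = runif(n) < 0.2,
                     stringsAsFactors = FALSE)
  msa(rows, name = "fixture", accession = sprintf("fx%04d", seed))
}

# brute-force local alignment score: enumerate every set of matched residue/
# column pairs (equal-size increasing subsequences); gaps between
# consecutive pairs cost open + extend * length per run. Equivalent to the
# affine-gap local alignment optimum, computed without any dynamic program.
oracle_local_score <- function(scores, codes, go, ge) {
  n <- length(codes)
  L <- nrow(scores)
  sc <- function(i, j) {
    if (codes[i] >= 1 && codes[i] <= 20) scores[j, codes[i]] else 0
  }
  best <- 0
  for (k in seq_len(min(n, L))) {
    qs <- utils::combn(n, k, simplify = FALSE)
    cs <- utils::combn(L, k, simplify = FALSE)
    for (qi in qs) {
      for (cj in cs) {
        s <- 0
        for (t in seq_len(k)) s <- s + sc(qi[t], cj[t])
        if (k > 1) {
          di <- diff(qi) - 1L
          dj <- diff(cj) - 1L
          s <- s - sum((go + ge * di)[di > 0]) - sum((go + ge * dj)[dj > 0])
        }
        if (s > best) best <- s
      }
    }
  }
  unname(best)
}

# random small profile with integer half-bit scores
rand_profile <- function(seed, L = NULL) {
  set.seed(seed)
  if (is.null(L)) L <- sample(2:6, 1)
  structure(list(accession = "rnd", L = L,
                 scores = matrix(sample(-6:8, L * 20, replace = TRUE), L, 20,
                                 dimnames = list(NULL, aa20)),
                 gap_open = sample(4:12, 1), gap_extend = sample(1:3, 1),
                 trigger = NA_real_, lambda = 0.267, K = 0.041),
            class = "profile")
}

rand_seq <- function(seed, len) {
  set.seed(seed)
  paste(sample(aa20, len, replace = TRUE), collapse = "")
}

encode20 <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], aa20)
  idx[is.na(idx)] <- 0L
  idx
}

# the purge-count fixture: 100 rows over 100 match columns; by construction
#   20 fragments below 75% coverage (incl. 2 duplicate pairs among them),
#    2 boundary rows at exactly 75% coverage (retained),
#   62 distinct full-coverage rows,
#   16 rows forming 8 full-coverage duplicate pairs,
# so purging leaves 100 - 20 - 8 = 72 rows.
build_purge_fixture <- function(seed = 42) {
  set.seed(seed)
  L <- 100L
  rand_row <- function() paste(sample(aa20, L, replace = TRUE), collapse = "")
  frag <- function(st, ncov) {
    ch <- strsplit(st, "")[[1]]
    ch[(ncov + 1):L] <- "-"
    paste(ch, collapse = "")
  }
  states <- character(0); ids <- character(0)
  for (i in 1:16) { states <- c(states, frag(rand_row(), 74)); ids <- c(ids, sprintf("frag%02d", i)) }
  for (p in 1:2) {
    st <- frag(rand_row(), 70)
    states <- c(states, st, st)
    ids <- c(ids, sprintf("fragdup%02d", 2 * p - 1), sprintf("fragdup%02d", 2 * p))
  }
  for (i in 1:2) { states <- c(states, frag(rand_row(), 75)); ids <- c(ids, sprintf("bound%02d", i)) }
  for (i in 1:62) { states <- c(states, rand_row()); ids <- c(ids, sprintf("full%02d", i)) }
  for (p in 1:8) {
    st <- rand_row()
    states <- c(states, st, st)
    ids <- c(ids, sprintf("dup%02da", p), sprintf("dup%02db", p))
  }
  mk_msa(states, ids, name = "purge_fixture")
}
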