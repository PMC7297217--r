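# ---- synthetic superfamilies with ground truth ----------------------------

#' Simulation parameters for a synthetic superfamily
#'
#' The defaults define the package's standard benchmark conditions: a
#' 20-node hierarchy of depth up to 3 over a 120-column root domain, 50
#' member sequences per node, and 500 unrelated decoy sequences. Subgroup
#' consensus sequences diverge along each tree edge by conditional
#' (BLOSUM-like) substitutions plus subgroup-specific insertions/deletions;
#' member sequences diverge from their node consensus the same way at lower
#' rates. Four 5-column anchor motifs are never mutated or deleted,
#' mimicking the conserved motifs that hold a real superfamily alignment
#' together.
#'
#' @param n_nodes number of hierarchy nodes (root included).
#' @param depth maximum tree depth.
#' @param root_L root match-column count.
#' @param seqs_per_node curated members per node.
#' @param substitution_rate per-column substitution probability along a tree
#'   edge (consensus divergence).
#' @param indel_rate probability that a non-root node carries a
#'   subgroup-specific insertion (and, independently, a deletion).
#' @param max_indel_len longest subgroup indel (columns).
#' @param member_substitution_rate per-column substitution probability from
#'   node consensus to member.
#' @param member_indel_rate probability a member carries a small insertion
#'   (and, independently, a deletion).
#' @param member_max_indel longest member indel.
#' @param n_decoys number of unrelated background sequences.
#' @param decoy_len_range decoy length range.
#' @param flank_len_range unaligned flank length range around each embedded
#'   domain.
#' @param linker_len_range linker length range between copies in two-copy
#'   sequences.
#' @param n_two_copy sequences carrying two domain copies (default 0).
#' @param n_anchors,anchor_len conserved anchor motifs (count, width).
#' @param seed RNG seed (mandatory; the whole fixture is a pure function of
#'   the parameters and seed).
#' @return list of class `sf_params`.
#' @export
sf_params <- function(n_nodes = 20L, depth = 3L, root_L = 120L,
                      seqs_per_node = 50L, substitution_rate = 0.15,
                      indel_rate = 0.6, max_indel_len = 6L,
                      member_substitution_rate = 0.10,
                      member_indel_rate = 0.08, member_max_indel = 3L,
                      n_decoys = 500L, decoy_len_range = c(80L, 250L),
                      flank_len_range = c(5L, 30L),
                      linker_len_range = c(20L, 40L), n_two_copy = 0L,
                      n_anchors = 4L, anchor_len = 5L, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_nodes >= 1L, p$depth >= 0L, p$root_L >= 20L,
            p$seqs_per_node >= 1L, p$seed == as.integer(p$seed))
  structure(p, class = "sf_params")
}

# substitution that always changes the residue, drawn from the
# BLOSUM62-conditional model renormalized off the original residue
substitute_res <- function(res) {
  P <- blosum62_conditional()
  vapply(res, function(b) {
    pr <- P[, b]
    pr[b] <- 0
    sample(AA, 1L, prob = pr / sum(pr))
  }, character(1), USE.NAMES = FALSE)
}

sample_bg <- function(n) {
  q <- robinson_background()
  paste(sample(AA, n, replace = TRUE, prob = q), collapse = "")
}

# choose a deletion run of length len among positions `allowed` (logical);
# returns indices or NULL if no window fits
pick_run <- function(allowed, len) {
  n <- length(allowed)
  if (n < len) return(NULL)
  ok <- which(vapply(seq_len(n - len + 1L),
                     function(s) all(allowed[s:(s + len - 1L)]), logical(1)))
  if (length(ok) == 0L) return(NULL)
  s <- ok[sample.int(length(ok), 1L)]
  s:(s + len - 1L)
}

#' Simulate a superfamily: hierarchy, database and ground truth
#'
#' Generates a complete synthetic benchmark: a validated hierarchical MSA
#' (node alignments, template of consensus sequences, depth-first tree
#' array), a FASTA database embedding every curated member between random
#' flanks plus unrelated decoys, and a residue-level truth table recording,
#' for every embedded domain residue, its true root column (or insert
#' status) and node. Fully reproducible from the seed.
#'
#' @param params an [sf_params()] list.
#' @return list of class `sf_sim`: `himsa`, `db` (data.frame as
#'   [read_fasta()]), `truth` (data.frame `seq_id`, `pos`, `root_col`,
#'   `insert`, `node`), `params`.
#' @export
simulate_superfamily <- function(params = sf_params()) {
  p <- params
  with_seed(p$seed, {
    accs <- sprintf("cd%04d", seq_len(p$n_nodes))
    # tree depths in depth-first order
    d <- integer(p$n_nodes)
    for (k in seq_len(p$n_nodes)[-1L]) {
      d[k] <- sample.int(min(d[k - 1L] + 1L, p$depth), 1L)
    }
    tree <- structure(d, class = "dft")
    parents <- dft_parents(d)

    # anchors: evenly spaced conserved 5-column motifs (root coordinates)
    astarts <- round(seq(10L, p$root_L - 10L - p$anchor_len,
                         length.out = p$n_anchors))
    anchor_cols <- unlist(lapply(astarts, function(s) s:(s + p$anchor_len - 1L)))

    # node consensus sequences + their root-column maps
    nodes_gen <- vector("list", p$n_nodes)
    root_res <- strsplit(sample_bg(p$root_L), "")[[1]]
    nodes_gen[[1L]] <- list(res = root_res, root_col = seq_len(p$root_L))
    for (k in seq_len(p$n_nodes)[-1L]) {
      par <- nodes_gen[[parents[k]]]
      res <- par$res
      rc <- par$root_col
      mutable <- !(rc %in% anchor_cols)
      sub <- mutable & stats::runif(length(res)) < p$substitution_rate
      if (any(sub)) res[sub] <- substitute_res(res[sub])
      if (stats::runif(1) < p$indel_rate && length(res) > 30L) {
        len <- sample.int(p$max_indel_len, 1L)
        run <- pick_run(mutable, len)
        if (!is.null(run)) { res <- res[-run]; rc <- rc[-run] }
      }
      if (stats::runif(1) < p$indel_rate) {
        len <- sample.int(p$max_indel_len, 1L)
        # boundary after position b, not splitting an anchor
        bs <- 0:length(res)
        okb <- vapply(bs, function(b) {
          l <- if (b >= 1L) rc[b] else NA_integer_
          r <- if (b < length(res)) rc[b + 1L] else NA_integer_
          !(!is.na(l) && !is.na(r) && l %in% anchor_cols &&
              r %in% anchor_cols && r == l + 1L)
        }, logical(1))
        b <- sample(bs[okb], 1L)
        ins <- strsplit(sample_bg(len), "")[[1]]
        res <- append(res, ins, after = b)
        rc <- append(rc, rep(NA_integer_, len), after = b)
      }
      nodes_gen[[k]] <- list(res = res, root_col = rc)
    }

    # template: node consensus rows projected onto root columns
    tpl_rows <- data.frame(
      seq_id = accs,
      desc = "",
      states = vapply(nodes_gen, function(g) {
        assemble_row_states(p$root_L, paste(g$res, collapse = ""), g$root_col)
      }, character(1)),
      stringsAsFactors = FALSE)
    template <- msa(tpl_rows, name = "template", accession = accs[1L])

    # members, node MSAs, database, truth
    db_id <- character(0); db_seq <- character(0)
    truth <- list()
    node_msas <- vector("list", p$n_nodes)
    member_states <- list()  # curated states per member id
    for (k in seq_len(p$n_nodes)) {
      g <- nodes_gen[[k]]
      Ln <- length(g$res)
      anchor_pos <- which(g$root_col %in% anchor_cols)
      ids <- sprintf("%s_m%02d", accs[k], seq_len(p$seqs_per_node))
      states <- character(p$seqs_per_node)
      for (s in seq_len(p$seqs_per_node)) {
        res <- g$res
        deleted <- rep(FALSE, Ln)
        mutable <- !(seq_len(Ln) %in% anchor_pos)
        sub <- mutable & stats::runif(Ln) < p$member_substitution_rate
        if (any(sub)) res[sub] <- substitute_res(res[sub])
        if (stats::runif(1) < p$member_indel_rate) {
          run <- pick_run(mutable, sample.int(p$member_max_indel, 1L))
          if (!is.null(run)) deleted[run] <- TRUE
        }
        ins_after <- integer(0); ins_res <- character(0)
        if (stats::runif(1) < p$member_indel_rate) {
          len <- sample.int(p$member_max_indel, 1L)
          # insertion boundary must not split an anchor motif
          cand <- seq_len(Ln - 1L)
          okb <- cand[!(cand %in% anchor_pos & (cand + 1L) %in% anchor_pos)]
          ins_after <- okb[sample.int(length(okb), 1L)]
          ins_res <- sample_bg(len)
        }
        chunks <- character(Ln)
        chunks[!deleted] <- res[!deleted]
        chunks[deleted] <- "-"
        if (length(ins_after)) {
          chunks[ins_after] <- paste0(chunks[ins_after], tolower(ins_res))
        }
        states[s] <- paste(chunks, collapse = "")
      }
      node_msas[[k]] <- msa(data.frame(seq_id = ids, desc = "",
                                       states = states,
                                       stringsAsFactors = FALSE),
                            name = accs[k], accession = accs[k])
      member_states[ids] <- as.list(states)
      # database embedding + truth
      for (s in seq_len(p$seqs_per_node)) {
        st <- states[s]
        dom <- ungap_states(st)
        fl <- sample(p$flank_len_range[1]:p$flank_len_range[2], 2L,
                     replace = TRUE)
        db_id <- c(db_id, ids[s])
        db_seq <- c(db_seq, paste0(sample_bg(fl[1]), dom, sample_bg(fl[2])))
        tr <- residue_truth(st, g$root_col)
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = ids[s], pos = fl[1] + seq_len(nrow(tr)),
          root_col = tr$root_col, insert = tr$insert, node = accs[k],
          stringsAsFactors = FALSE)
      }
    }

    # optional two-copy sequences built from fresh members of the root node
    if (p$n_two_copy > 0L) {
      g <- nodes_gen[[1L]]
      for (t in seq_len(p$n_two_copy)) {
        id <- sprintf("twocopy%02d", t)
        doms <- character(2L); trs <- vector("list", 2L)
        for (cpy in 1:2) {
          res <- g$res
          sub <- stats::runif(length(res)) < p$member_substitution_rate
          if (any(sub)) res[sub] <- substitute_res(res[sub])
          st <- paste(res, collapse = "")
          doms[cpy] <- st
          trs[[cpy]] <- residue_truth(st, g$root_col)
        }
        linker <- sample(p$linker_len_range[1]:p$linker_len_range[2], 1L)
        fl <- sample(p$flank_len_range[1]:p$flank_len_range[2], 2L,
                     replace = TRUE)
        db_id <- c(db_id, id)
        db_seq <- c(db_seq, paste0(sample_bg(fl[1]), doms[1],
                                   sample_bg(linker), doms[2],
                                   sample_bg(fl[2])))
        off1 <- fl[1]; off2 <- fl[1] + nchar(doms[1]) + linker
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = id,
          pos = c(off1 + seq_len(nrow(trs[[1]])), off2 + seq_len(nrow(trs[[2]]))),
          root_col = c(trs[[1]]$root_col, trs[[2]]$root_col),
          insert = c(trs[[1]]$insert, trs[[2]]$insert),
          node = accs[1L], stringsAsFactors = FALSE)
      }
    }

    # decoys
    for (dd in seq_len(p$n_decoys)) {
      db_id <- c(db_id, sprintf("decoy%04d", dd))
      db_seq <- c(db_seq,
                  sample_bg(sample(p$decoy_len_range[1]:p$decoy_len_range[2], 1L)))
    }

    nodes <- vector("list", p$n_nodes)
    names(nodes) <- accs
    for (k in seq_len(p$n_nodes)) {
      nodes[[k]] <- list(accession = accs[k], msa = node_msas[[k]],
                         consensus = paste(nodes_gen[[k]]$res, collapse = ""),
                         parent = if (parents[k] == 0L) NA_character_ else
                           accs[parents[k]],
                         depth = d[k], trigger = NA_real_)
    }
    h <- structure(list(nodes = nodes, order = accs, template = template,
                        tree = tree, root_L = p$root_L),
                   class = "himsa")
    db <- data.frame(seq_id = db_id, desc = "", seq = db_seq,
                     stringsAsFactors = FALSE)
    structure(list(himsa = h, db = db, truth = do.call(rbind, truth),
                   params = p),
              class = "sf_sim")
  })
}

# residue-level truth of a curated state string: for each emitted residue in
# order, its root column (NA + insert flag for insert-state residues and
# residues on columns the node does not share with the root)
residue_truth <- function(states, root_col_of_node_col) {
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  ncol_ <- cumsum(ch == "-" | ch %in% LETTERS)
  sel <- ch %in% c(LETTERS, letters)
  nc <- ifelse(ch[sel] %in% LETTERS, ncol_[sel], NA_integer_)
  rc <- rep(NA_integer_, length(nc))
  ok <- !is.na(nc)
  rc[ok] <- root_col_of_node_col[nc[ok]]
  data.frame(root_col = rc, insert = is.na(rc))
}

#' @export
print.sf_sim <- function(x, ...) {
  cat("sf_sim:", length(x$himsa$nodes), "nodes,", nrow(x$db),
      "database sequences,", nrow(x$truth), "truth residues (seed",
      x$params$seed, ")\n")
  invisible(x)
}

#' Simulate an alignment with planted covarying column pairs
#'
#' Columns are independent uniform draws over the 20 residues except at the
#' planted pairs, which follow a two-state paired model: each sequence picks
#' one of two modes per pair, emitting that mode's residue pair, and each
#' side independently reverts to a random residue with probability
#' `1 - coupling_strength`. This produces the compensating-substitution
#' signal direct coupling analysis is designed to detect.
#'
#' @param L columns.
#' @param n sequences.
#' @param planted_pairs how many pairs to plant, or a 2-column matrix of
#'   column pairs.
#' @param coupling_strength probability a side follows its mode (default
#'   0.9); a vector gives each planted pair its own strength, which yields
#'   a graded band of couplings from near-noise to strong.
#' @param min_separation minimum column separation of random planted pairs
#'   (default 5, matching the default contact-map universe).
#' @param seed RNG seed.
#' @return an [msa]; attribute `planted_pairs` holds the pairs (matrix,
#'   i < j rows).
#' @export
simulate_covariation <- function(L = 30L, n = 2000L, planted_pairs = 5L,
                                 coupling_strength = 0.9,
                                 min_separation = 5L, seed = 1L) {
  with_seed(seed, {
    if (is.matrix(planted_pairs)) {
      pairs <- cbind(pmin(planted_pairs[, 1L], planted_pairs[, 2L]),
                     pmax(planted_pairs[, 1L], planted_pairs[, 2L]))
    } else {
      k <- as.integer(planted_pairs)
      pairs <- matrix(0L, k, 2L)
      used <- integer(0)
      for (t in seq_len(k)) {
        repeat {
          pr <- sort(sample.int(L, 2L))
          if (pr[2L] - pr[1L] >= min_separation && !any(pr %in% used)) break
        }
        pairs[t, ] <- pr
        used <- c(used, pr)
      }
    }
    cs <- rep_len(coupling_strength, nrow(pairs))
    M <- matrix(sample(AA, n * L, replace = TRUE), n, L)
    for (t in seq_len(nrow(pairs))) {
      modes <- matrix(sample(AA, 4L), 2L, 2L)  # rows: mode; cols: (i, j) side
      while (modes[1L, 1L] == modes[2L, 1L] || modes[1L, 2L] == modes[2L, 2L]) {
        modes <- matrix(sample(AA, 4L), 2L, 2L)
      }
      mode <- sample.int(2L, n, replace = TRUE)
      for (side in 1:2) {
        res <- modes[mode, side]
        revert <- stats::runif(n) >= cs[t]
        res[revert] <- sample(AA, sum(revert), replace = TRUE)
        M[, pairs[t, side]] <- res
      }
    }
    states <- apply(M, 1L, paste, collapse = "")
    out <- msa(data.frame(seq_id = sprintf("s%05d", seq_len(n)), desc = "",
                          states = states, stringsAsFactors = FALSE),
               name = "covariation")
    attr(out, "planted_pairs") <- pairs
    out
  })
}

#' Corrupt an alignment by shuffling rows within a column window
#'
#' For a random fraction of rows, each match column in the window is
#' independently permuted among the selected rows. Column compositions are
#' preserved exactly, but the inter-column covariation carried by those
#' rows is destroyed — the canonical degradation for checking that
#' better-aligned inputs earn higher coupling-vs-contact scores.
#'
#' @param m an [msa] whose rows have no insert states in the window.
#' @param fraction fraction of rows to corrupt (default 0.2).
#' @param window integer vector of match columns (default: all).
#' @param seed RNG seed.
#' @return the corrupted [msa].
#' @export
corrupt_msa_rows <- function(m, fraction = 0.2, window = seq_len(m$L),
                             seed = 1L) {
  with_seed(seed, {
    n <- nrow(m$rows)
    pick <- sample.int(n, round(fraction * n))
    if (length(pick) < 2L) return(m)
    chs <- strsplit(m$rows$states[pick], "", fixed = TRUE)
    # per-column positions within each selected row's state string
    mpos <- lapply(chs, function(ch) which(ch == "-" | ch %in% LETTERS))
    for (j in window) {
      perm <- sample(seq_along(pick))
      vals <- vapply(seq_along(pick), function(r) chs[[r]][mpos[[r]][j]], "")
      for (r in seq_along(pick)) chs[[r]][mpos[[r]][j]] <- vals[perm[r]]
    }
    m$rows$states[pick] <- vapply(chs, paste, "", collapse = "")
    m
  })
}

#' Fraction of embedded residues placed at their true root column
#'
#' For every residue in the truth table, the global alignment's placement
#' (root match column, or insert status) is compared with the truth; the
#' returned fraction counts exact agreements over all truth residues.
#' Residues of sequences absent from the global alignment count as wrong,
#' so an empty alignment scores 0.
#'
#' @param gmsa a `global_msa`.
#' @param truth truth table from [simulate_superfamily()].
#' @return fraction in \[0, 1\].
#' @export
score_recovery <- function(gmsa, truth) {
  if (nrow(truth) == 0L) return(NaN)
  # assignment lookup: (orig_id, pos) -> root col (NA = insert)
  assign_id <- character(0); assign_pos <- integer(0); assign_rc <- integer(0)
  for (i in seq_len(nrow(gmsa$rows))) {
    ch <- strsplit(gmsa$rows$states[i], "", fixed = TRUE)[[1]]
    col <- cumsum(ch == "-" | ch %in% LETTERS)
    sel <- ch %in% c(LETTERS, letters)
    rc <- ifelse(ch[sel] %in% LETTERS, col[sel], NA_integer_)
    pos <- gmsa$rows$region_start[i] - 1L + seq_along(rc)
    assign_id <- c(assign_id, rep(gmsa$rows$orig_id[i], length(rc)))
    assign_pos <- c(assign_pos, pos)
    assign_rc <- c(assign_rc, rc)
  }
  key <- paste(assign_id, assign_pos)
  first <- !duplicated(key)
  lut <- setNames(assign_rc[first], key[first])
  covered <- setNames(rep(TRUE, sum(first)), key[first])
  tkey <- paste(truth$seq_id, truth$pos)
  got <- tkey %in% names(covered)
  arc <- lut[tkey]
  correct <- got & ((is.na(arc) & truth$insert) |
                      (!is.na(arc) & !truth$insert & arc == truth$root_col))
  mean(correct)
}
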