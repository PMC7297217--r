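# ---- MSA quality via direct couplings vs 3D contacts ----------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

# keep only the given match columns of every row; insert-state residues are
# dropped (harmonized MSAs are pure match-column matrices)
msa_select_columns <- function(m, cols) {
  cols <- as.integer(cols)
  stopifnot(all(cols >= 1L), all(cols <= m$L), !is.unsorted(cols, strictly = TRUE))
  for (i in seq_len(nrow(m$rows))) {
    ch <- match_column_chars(m$rows$states[i])[cols]
    ch[is.na(ch)] <- "-"
    m$rows$states[i] <- paste(ch, collapse = "")
  }
  m$rows$flank_left <- 0L
  m$rows$flank_right <- 0L
  m$L <- length(cols)
  m
}

#' Harmonize two alignments for a like-for-like quality comparison
#'
#' Equalizes what the two alignments are allowed to differ in before their
#' coupling quality is compared: (i) both are restricted to a user-supplied
#' column correspondence (terminal trimming and removal of insertion
#' columns), which must leave equal column counts; (ii) rows with deletions
#' in more than `max_deletion_fraction` of the columns are removed; (iii)
#' among unprotected rows, all but one of each group sharing at least
#' `max_identity` identity are removed; (iv) the larger alignment's
#' unprotected rows are randomly subsampled (seeded) to the smaller's
#' count, and protected (structure-bearing) rows are always retained.
#'
#' @param a,b [msa] objects.
#' @param cols_a,cols_b strictly increasing match-column selections of equal
#'   length (default: all columns).
#' @param structures ids of protected structure-bearing rows.
#' @param max_deletion_fraction rows above this deletion fraction are
#'   dropped (default 0.25, strict).
#' @param max_identity redundancy threshold (default 0.98).
#' @param seed RNG seed for the subsampling step.
#' @return list with harmonized `a` and `b`.
#' @export
harmonize <- function(a, b, cols_a = seq_len(a$L), cols_b = seq_len(b$L),
                      structures = character(0),
                      max_deletion_fraction = 0.25, max_identity = 0.98,
                      seed = 1) {
  if (length(cols_a) != length(cols_b)) {
    stop("harmonize: column selections have unequal lengths (",
         length(cols_a), " vs ", length(cols_b), ")")
  }
  a <- msa_select_columns(a, cols_a)
  b <- msa_select_columns(b, cols_b)
  prep <- function(m) {
    m$rows$protected <- m$rows$protected | m$rows$seq_id %in% structures
    keep <- (1 - match_fraction(m)) <= max_deletion_fraction
    m <- subset_rows(m, keep)
    redundancy_filter(m, max_identity)
  }
  a <- prep(a); b <- prep(b)
  na <- sum(!a$rows$protected); nb <- sum(!b$rows$protected)
  target <- min(na, nb)
  shrink <- function(m, n_unprot) {
    if (n_unprot <= target) return(m)
    up <- which(!m$rows$protected)
    drop <- with_seed(seed, sample(up, n_unprot - target))
    subset_rows(m, !seq_len(nrow(m$rows)) %in% drop)
  }
  list(a = shrink(a, na), b = shrink(b, nb))
}

# ---- mean-field direct coupling analysis ----------------------------------

# integer state matrix for coupling analysis: residues 1..20, everything
# else (deletions, X) = state 21
msa_dca_matrix <- function(m) {
  sm <- msa_state_matrix(m)
  sm[sm == 0L] <- 21L
  sm
}

#' Mean-field direct couplings of an alignment
#'
#' Mean-field DCA: sequences are reweighted at `reweight_identity` (a
#' sequence's weight is one over the number of sequences at least that
#' similar to it, itself included); single and pair frequencies over 21
#' states (20 residues + gap) are mixed with a uniform pseudocount of
#' fraction `pseudocount_weight`; the couplings are minus the inverse of
#' the resulting covariance matrix over the 20 residue states. Per column
#' pair the 20 x 20 coupling block is put in the zero-sum gauge, its
#' Frobenius norm taken, and the average-product correction applied;
#' negative corrected values are clipped to 0 so the matrix is a
#' nonnegative coupling strength.
#'
#' @param m an [msa] with at least 2 rows and 2 columns.
#' @param pseudocount_weight pseudocount fraction in (0, 1) (default 0.5).
#' @param reweight_identity identity threshold for reweighting (default 0.8).
#' @return symmetric L x L matrix of class `coupling_matrix`; diagonal `NA`.
#' @export
dca_couplings <- function(m, pseudocount_weight = 0.5,
                          reweight_identity = 0.8) {
  L <- m$L
  stopifnot(L >= 2L, nrow(m$rows) >= 2L)
  q <- 21L
  X <- msa_dca_matrix(m)
  w <- dca_weights_cpp(X, reweight_identity)
  W <- sum(w)
  # one-hot over the 20 residue states (gap contributes no indicator)
  n <- nrow(X)
  A <- matrix(0, n, L * 20L)
  res <- X <= 20L
  idx <- which(res)
  rows_i <- ((idx - 1L) %% n) + 1L
  cols_j <- ((idx - 1L) %/% n) + 1L
  A[cbind(rows_i, (cols_j - 1L) * 20L + X[idx])] <- 1
  f1 <- colSums(w * A) / W
  f2 <- crossprod(A, w * A) / W
  lam <- pseudocount_weight
  f1p <- (1 - lam) * f1 + lam / q
  f2p <- (1 - lam) * f2 + lam / q^2
  # same-column blocks: pair frequency is diagonal in the states
  for (i in seq_len(L)) {
    blk <- (i - 1L) * 20L + seq_len(20L)
    f2p[blk, blk] <- (1 - lam) * f2[blk, blk] + diag(lam / q, 20L)
  }
  C <- f2p - tcrossprod(f1p)
  J <- tryCatch(-solve(C), error = function(e) {
    stop("dca_couplings: covariance matrix is singular; ",
         "increase pseudocount_weight")
  })
  FN <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1L)) {
    bi <- (i - 1L) * 20L + seq_len(20L)
    for (j in (i + 1L):L) {
      bj <- (j - 1L) * 20L + seq_len(20L)
      K <- J[bi, bj]
      K <- K - outer(rowMeans(K), rep(1, 20L)) -
        outer(rep(1, 20L), colMeans(K)) + mean(K)
      FN[i, j] <- FN[j, i] <- sqrt(sum(K^2))
    }
  }
  rm_ <- rowMeans(FN, na.rm = TRUE)
  gm <- mean(FN[upper.tri(FN)])
  apc <- FN - outer(rm_, rm_) / gm
  apc[apc < 0] <- 0
  diag(apc) <- NA_real_
  structure(apc, class = c("coupling_matrix", "matrix"))
}

# ---- contacts and the hypergeometric S-score ------------------------------

#' Contact map from per-column coordinates
#'
#' A column pair (i, j) is a contact iff the representative-atom distance is
#' at most `cutoff` and the separation `j - i` at least `min_separation`.
#' Columns without coordinates are excluded from the eligible-pair universe.
#'
#' @param coords data.frame with columns `col`, `x`, `y`, `z` (one row per
#'   column with a representative atom, conventionally C-beta).
#' @param cutoff distance cutoff in Angstrom (default 8).
#' @param min_separation minimum column separation (default 5).
#' @return list of class `contact_map`: `contacts` and `eligible`
#'   (data.frames `i`, `j` with i < j), `M` (contact count), `N` (eligible
#'   count), `cutoff`, `min_separation`.
#' @export
contact_map <- function(coords, cutoff = 8, min_separation = 5) {
  stopifnot(nrow(coords) >= 2L, all(c("col", "x", "y", "z") %in% names(coords)))
  coords <- coords[order(coords$col), , drop = FALSE]
  cc <- as.integer(coords$col)
  P <- as.matrix(coords[, c("x", "y", "z")])
  pr <- which(upper.tri(matrix(0, length(cc), length(cc))), arr.ind = TRUE)
  i <- pr[, 1L]; j <- pr[, 2L]
  sep_ok <- (cc[j] - cc[i]) >= min_separation
  d <- sqrt(rowSums((P[i, , drop = FALSE] - P[j, , drop = FALSE])^2))
  elig <- data.frame(i = cc[i][sep_ok], j = cc[j][sep_ok])
  cont <- data.frame(i = cc[i][sep_ok & d <= cutoff],
                     j = cc[j][sep_ok & d <= cutoff])
  structure(list(contacts = cont, eligible = elig,
                 M = nrow(cont), N = nrow(elig),
                 cutoff = cutoff, min_separation = min_separation),
            class = "contact_map")
}

#' Contact map from a tabulated pair list
#'
#' @param pairs data.frame (or TSV path) with columns `i`, `j` of contacting
#'   columns.
#' @param L number of alignment columns (defines the eligible universe).
#' @param min_separation minimum column separation (default 5).
#' @return a `contact_map` (see [contact_map()]).
#' @export
contact_map_from_pairs <- function(pairs, L, min_separation = 5) {
  if (is.character(pairs)) {
    pairs <- utils::read.table(pairs, header = FALSE, col.names = c("i", "j"))
  }
  ii <- pmin(pairs$i, pairs$j); jj <- pmax(pairs$i, pairs$j)
  pr <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  sep_ok <- (pr[, 2L] - pr[, 1L]) >= min_separation
  elig <- data.frame(i = pr[sep_ok, 1L], j = pr[sep_ok, 2L])
  keep <- (jj - ii) >= min_separation
  cont <- unique(data.frame(i = ii[keep], j = jj[keep]))
  structure(list(contacts = cont, eligible = elig,
                 M = nrow(cont), N = nrow(elig),
                 cutoff = NA_real_, min_separation = min_separation),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", x$M, "contacts among", x$N, "eligible pairs",
      "(separation >=", x$min_separation, ")\n")
  invisible(x)
}

#' Hypergeometric S-score of coupling/contact correspondence
#'
#' Takes the `k` most strongly coupled eligible column pairs, counts how
#' many are contacts, and computes the upper-tail hypergeometric probability
#' of at least that overlap when drawing `k` pairs at random from the
#' eligible universe containing `M` contacts. `S = -log10(P)`: higher means
#' the alignment's strongest couplings coincide with structure, i.e. a
#' better alignment.
#'
#' @param couplings a [dca_couplings()] matrix.
#' @param contacts a `contact_map`.
#' @param k number of top pairs (default: the column count, capped at the
#'   eligible-pair count).
#' @return list of class `s_score`: `s_value`, `k`, `overlap`, `M`, `N`,
#'   `p_value`.
#' @export
s_score <- function(couplings, contacts, k = NULL) {
  L <- nrow(couplings)
  elig <- contacts$eligible
  elig <- elig[elig$i >= 1 & elig$j <= L, , drop = FALSE]
  N <- nrow(elig)
  if (is.null(k)) k <- min(L, N)
  if (k <= 0) stop("s_score: k must be positive")
  if (k > N) stop("s_score: k exceeds the eligible-pair universe (", N, ")")
  cp <- couplings[cbind(elig$i, elig$j)]
  ord <- order(-cp, elig$i, elig$j)
  top <- elig[ord[seq_len(k)], , drop = FALSE]
  ckey <- paste(contacts$contacts$i, contacts$contacts$j)
  overlap <- sum(paste(top$i, top$j) %in% ckey)
  M <- contacts$M
  p <- stats::phyper(overlap - 1, M, N - M, k, lower.tail = FALSE)
  structure(list(s_value = -log10(p), k = k, overlap = overlap,
                 M = M, N = N, p_value = p),
            class = "s_score")
}

#' @export
print.s_score <- function(x, ...) {
  cat(sprintf("S = %.3f  (overlap %d of top %d; %d contacts among %d pairs)\n",
              x$s_value, x$overlap, x$k, x$M, x$N))
  invisible(x)
}

#' JSON quality report for one alignment
#'
#' @param m the evaluated [msa].
#' @param couplings its coupling matrix.
#' @param contacts the contact map.
#' @param k top-pair count (see [s_score()]).
#' @param file optional output path.
#' @return list with `S`, `k`, `overlap`, `M`, `N`, `avg_column_RE`.
#' @export
starc_report <- function(m, couplings, contacts, k = NULL, file = NULL) {
  s <- s_score(couplings, contacts, k)
  rep_ <- list(S = s$s_value, k = s$k, overlap = s$overlap, M = s$M, N = s$N,
               avg_column_RE = column_stats(m)$average_re)
  if (!is.null(file)) {
    jsonlite::write_json(rep_, file, auto_unbox = TRUE, digits = NA)
  }
  rep_
}
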