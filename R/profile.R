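# ---- position-specific scoring profiles and E-value statistics ------------

# Robinson & Robinson amino acid background frequencies, reordered to the
# package alphabet ACDEFGHIKLMNPQRSTVWY (the standard protein-search
# background; renormalized to sum exactly to 1).
robinson_background <- function() {
  q <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
         G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
         M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
         S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
  q / sum(q)
}

# 20 x 20 conditional substitution probabilities P(a | b) reconstructed from
# the BLOSUM62 score matrix (half-bit log-odds): P(a|b) proportional to
# q_a * 2^(s_ab / 2), normalized over a. Used as the pseudocount model.
blosum62_conditional <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    B <- get_blosum62()[AA, AA]
    q <- robinson_background()
    P <- matrix(0, 20, 20, dimnames = list(AA, AA))
    for (b in seq_len(20)) {
      v <- q * 2^(B[, b] / 2)
      P[, b] <- v / sum(v)
    }
    cache <<- P
    P
  }
})

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Build a position-specific scoring profile from an alignment
#'
#' Per match column, redundancy-weighted residue frequencies are mixed with
#' substitution-matrix pseudocounts (BLOSUM62-derived conditional
#' probabilities, pseudocount mass `beta` against the observed weighted
#' mass) and converted to half-bit log-odds against the background:
#' `score(a, j) = 2 * log2(p_aj / q_a)`, rounded to integer half-bits as is
#' conventional for search profiles.
#'
#' @param m an [msa] with at least one row.
#' @param weights per-row weights, default [position_weights()].
#' @param beta pseudocount mass (default 10).
#' @param gap_open,gap_extend affine gap penalties in half-bits; a gap of
#'   length k costs `gap_open + gap_extend * k`.
#' @param background length-20 background distribution; default
#'   Robinson-Robinson.
#' @return object of class `profile`: `accession`, `L`, `scores` (L x 20),
#'   `gap_open`, `gap_extend`, `trigger`, `lambda`, `K`.
#' @export
build_profile <- function(m, weights = position_weights(m), beta = 10,
                          gap_open = 22, gap_extend = 2,
                          background = robinson_background()) {
  stopifnot(nrow(m$rows) >= 1L, m$L >= 1L)
  P <- blosum62_conditional()
  cm <- msa_char_matrix(m)
  scores <- matrix(0, m$L, 20, dimnames = list(NULL, AA))
  for (j in seq_len(m$L)) {
    col <- cm[, j]
    occ <- !is.na(col) & col %in% AA
    if (!any(occ)) stop("build_profile: column ", j, " has no residues")
    wmass <- tapply(weights[occ], factor(col[occ], levels = AA), sum)
    wmass[is.na(wmass)] <- 0
    mj <- sum(wmass)
    f <- wmass / mj
    g <- as.numeric(P %*% f)          # pseudocount distribution
    p <- (mj * f + beta * g) / (mj + beta)
    scores[j, ] <- round(2 * log2(p / background))
  }
  structure(list(accession = m$accession, L = m$L, scores = scores,
                 gap_open = gap_open, gap_extend = gap_extend,
                 trigger = NA_real_, lambda = 0.267, K = 0.041),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat("profile", x$accession, ":", x$L, "columns, gap",
      x$gap_open, "/", x$gap_extend, "half-bits\n")
  invisible(x)
}

encode_seq <- function(seq) {
  idx <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], AA)
  idx[is.na(idx)] <- 0L
  idx
}

#' Local alignment of a sequence against a profile
#'
#' Maximal-scoring affine-gap local (Smith-Waterman/Gotoh) alignment of a
#' residue string against the profile's columns. Unknown residues (X and any
#' non-standard letter) score 0 at every column. The empty alignment scores
#' 0, so the score is never negative.
#'
#' @param profile a [build_profile()] object.
#' @param seq residue string.
#' @return list: `score` (half-bits), `qstart`/`qend` (residue interval,
#'   1-based closed; `qstart > qend` for an empty alignment), `cstart`/`cend`
#'   (profile column interval) and `col_of_res` (for each residue in the
#'   interval, its profile column or 0 for an insertion).
#' @export
local_align <- function(profile, seq) {
  stopifnot(nchar(seq) >= 1L)
  align_local_cpp(profile$scores, encode_seq(seq),
                  profile$gap_open, profile$gap_extend)
}

#' Glocal alignment of a sequence against a profile
#'
#' Global across the profile (every match column is consumed by a residue
#' or a deletion), local in the sequence (unaligned flanks are free). This
#' is the alignment the search reports for an assigned domain: detection
#' and significance use the local score, but the reported path covers the
#' whole domain model so that weakly conserved terminal columns are aligned
#' rather than trimmed.
#'
#' @param profile a `profile`.
#' @param seq residue string.
#' @return list as [local_align()]; `cstart`/`cend` always span `1..L` and
#'   the score may be negative.
#' @export
glocal_align <- function(profile, seq) {
  stopifnot(nchar(seq) >= 1L)
  align_glocal_cpp(profile$scores, encode_seq(seq),
                   profile$gap_open, profile$gap_extend)
}

#' Karlin-Altschul expectation value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the profile length, `n` the
#' number of database residues and `S` the raw half-bit score; `lambda` and
#' `K` are the profile's stored gapped parameters (defaults 0.267 and 0.041,
#' the standard values for BLOSUM62 with 11/1-convention gaps).
#'
#' @param score raw alignment score in half-bits (>= 0).
#' @param profile a `profile`.
#' @param db_residues total residue count of the searched database.
#' @return expectation value.
#' @export
evalue <- function(score, profile, db_residues) {
  stopifnot(score >= 0, db_residues > 0)
  profile$K * profile$L * db_residues * exp(-profile$lambda * score)
}

#' Score threshold attaining a target E-value
#'
#' Inverse of [evalue()]; used to turn an E-value-style trigger into a raw
#' score threshold for the pruned descent.
#'
#' @param profile a `profile`.
#' @param e target E-value.
#' @param db_residues database residue count.
#' @return raw half-bit score.
#' @export
score_for_evalue <- function(profile, e, db_residues) {
  log(profile$K * profile$L * db_residues / e) / profile$lambda
}

#' Refit E-value parameters from shuffled-sequence scores
#'
#' Aligns random background sequences against the profile and fits the
#' Gumbel law by the method of moments (`lambda = pi / sqrt(6 * var)`,
#' `K = exp(lambda * mu) / (m * n)`), giving empirical `lambda`/`K` that can
#' replace the fixed defaults.
#'
#' @param profile a `profile`.
#' @param n_seqs number of random sequences.
#' @param seq_len their length.
#' @param seed RNG seed.
#' @return the profile with `lambda`, `K` replaced.
#' @export
calibrate_evalue <- function(profile, n_seqs = 200, seq_len = 200, seed = 1) {
  set.seed(seed)
  q <- robinson_background()
  sc <- vapply(seq_len(n_seqs), function(i) {
    s <- paste(sample(AA, seq_len, replace = TRUE, prob = q), collapse = "")
    local_align(profile, s)$score
  }, numeric(1))
  v <- stats::var(sc)
  lambda <- pi / sqrt(6 * v)
  mu <- mean(sc) - 0.5772156649 / lambda
  K <- exp(lambda * mu) / (profile$L * seq_len)
  profile$lambda <- lambda
  profile$K <- K
  profile
}
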