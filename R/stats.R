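# ---- redundancy weighting, consensus, column diversity --------------------

#' Position-based sequence weights
#'
#' Henikoff & Henikoff position-based weights: at each match column a row
#' holding residue `a` receives 1/(k * n_a), where `k` is the number of
#' distinct residues in the column and `n_a` the number of rows holding `a`;
#' deletions contribute nothing. Row weights are the column sums, normalized
#' to mean 1, so duplicated rows share the mass a unique row would get alone.
#'
#' @param m an [msa] with at least one row.
#' @return numeric vector of positive weights, mean 1.
#' @export
position_weights <- function(m) {
  n <- nrow(m$rows)
  if (n < 1L) stop("position_weights: empty alignment")
  if (m$L == 0L || n == 1L) return(rep(1, n))
  cm <- msa_char_matrix(m)
  w <- numeric(n)
  for (j in seq_len(m$L)) {
    col <- cm[, j]
    occ <- !is.na(col)
    if (!any(occ)) next
    tab <- table(col[occ])
    k <- length(tab)
    w[occ] <- w[occ] + 1 / (k * as.numeric(tab[col[occ]]))
  }
  if (all(w == 0)) w[] <- 1
  w / mean(w)
}

#' Weighted consensus sequence
#'
#' The most frequent residue per match column after redundancy weighting;
#' ties broken alphabetically for determinism.
#'
#' @param m an [msa].
#' @param weights per-row weights (default: [position_weights()]).
#' @return residue string of length `m$L`.
#' @export
consensus <- function(m, weights = position_weights(m)) {
  stopifnot(length(weights) == nrow(m$rows))
  if (m$L == 0L) return("")
  cm <- msa_char_matrix(m)
  out <- character(m$L)
  for (j in seq_len(m$L)) {
    col <- cm[, j]
    occ <- !is.na(col)
    if (!any(occ)) {
      stop("consensus: column ", j, " has no residues (all-gap match column)")
    }
    mass <- tapply(weights[occ], col[occ], sum)
    mass <- mass[order(names(mass))]  # alphabetical tie-break
    out[j] <- names(mass)[which.max(mass)]
  }
  paste(out, collapse = "")
}

#' Per-column residue frequencies and relative entropy
#'
#' For each match column, residue frequencies `f` are computed over the 20
#' standard amino acids with gaps excluded from the normalization, and the
#' relative entropy (Kullback-Leibler divergence from the background) is
#' `RE_j = sum_a f_aj * ln(f_aj / q_a)` in nats. Conserved columns score
#' high (up to ln 20 for an invariant column against a uniform background);
#' columns matching the background score 0.
#'
#' @param m an [msa].
#' @param background length-20 strictly positive probability vector over
#'   residues in the order `ACDEFGHIKLMNPQRSTVWY`; default uniform.
#' @return list of class `column_stats`: `frequencies` (L x 20 matrix),
#'   `relative_entropy` (length L, nats), `average_re` (mean, nats).
#' @export
column_stats <- function(m, background = rep(1 / 20, 20)) {
  stopifnot(length(background) == 20, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  if (m$L == 0L || nrow(m$rows) == 0L) {
    return(structure(list(frequencies = matrix(0, 0, 20),
                          relative_entropy = numeric(0), average_re = NaN),
                     class = "column_stats"))
  }
  cm <- msa_char_matrix(m)
  freq <- matrix(0, m$L, 20, dimnames = list(NULL, AA))
  re <- numeric(m$L)
  for (j in seq_len(m$L)) {
    col <- cm[, j]
    col <- col[!is.na(col) & col %in% AA]
    if (length(col) == 0L) {
      stop("column_stats: column ", j, " has no residues")
    }
    f <- tabulate(match(col, AA), 20) / length(col)
    freq[j, ] <- f
    nz <- f > 0
    re[j] <- sum(f[nz] * log(f[nz] / background[nz]))
  }
  structure(list(frequencies = freq, relative_entropy = re,
                 average_re = mean(re)),
            class = "column_stats")
}

#' @export
print.column_stats <- function(x, ...) {
  cat("column_stats:", length(x$relative_entropy), "columns, average RE",
      format(x$average_re, digits = 4), "nats\n")
  invisible(x)
}
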