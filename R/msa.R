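#' @useDynLib hialign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames phyper median
#' @importFrom utils head tail
NULL

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an alignment object
#'
#' An `msa` holds an ordered set of aligned rows sharing the same number of
#' match columns `L`. Each row's `states` string uses the conserved-domain
#' convention: uppercase letters are residues occupying match columns,
#' lowercase letters are inserted residues between match columns, and `-`
#' marks a deletion at a match column. Residues outside the aligned region
#' (flanks) are stored as counts, not characters.
#'
#' @param rows data.frame with columns `seq_id`, `desc`, `states`,
#'   `flank_left`, `flank_right`, `protected`. Missing optional columns are
#'   filled with defaults (`desc = ""`, flanks 0, `protected = FALSE`).
#' @param name alignment name.
#' @param accession accession string (e.g. a cd-style identifier).
#' @return an object of class `msa` with fields `name`, `accession`, `L`,
#'   `rows`.
#' @export
msa <- function(rows, name = "", accession = "") {
  stopifnot(is.data.frame(rows), "seq_id" %in% names(rows), "states" %in% names(rows))
  if (is.null(rows$desc)) rows$desc <- ""
  if (is.null(rows$flank_left)) rows$flank_left <- 0L
  if (is.null(rows$flank_right)) rows$flank_right <- 0L
  if (is.null(rows$protected)) rows$protected <- FALSE
  rows <- rows[, c("seq_id", "desc", "states", "flank_left", "flank_right", "protected")]
  rows$seq_id <- as.character(rows$seq_id)
  rows$desc <- as.character(rows$desc)
  rows$states <- as.character(rows$states)
  rows$flank_left <- as.integer(rows$flank_left)
  rows$flank_right <- as.integer(rows$flank_right)
  rows$protected <- as.logical(rows$protected)
  rownames(rows) <- NULL
  Ls <- vapply(rows$states, n_match_cols, integer(1), USE.NAMES = FALSE)
  L <- if (nrow(rows) == 0L) 0L else Ls[1L]
  if (nrow(rows) > 0L && any(Ls != L)) {
    bad <- rows$seq_id[which(Ls != L)[1L]]
    stop("malformed alignment: record '", bad, "' has ", Ls[which(Ls != L)[1L]],
         " match columns, expected ", L)
  }
  if (anyDuplicated(rows$seq_id)) {
    stop("duplicate seq_id in alignment: ",
         rows$seq_id[anyDuplicated(rows$seq_id)])
  }
  structure(list(name = name, accession = accession, L = L, rows = rows),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa", if (nzchar(x$accession)) paste0("[", x$accession, "]") else "",
      if (nzchar(x$name)) x$name else "", "\n")
  cat("  match columns:", x$L, "  rows:", nrow(x$rows), "\n")
  n <- min(5L, nrow(x$rows))
  if (n > 0L) {
    for (i in seq_len(n)) {
      s <- x$rows$states[i]
      if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
      cat(sprintf("  %-15s %s\n", x$rows$seq_id[i], s))
    }
    if (nrow(x$rows) > n) cat("  ...", nrow(x$rows) - n, "more rows\n")
  }
  invisible(x)
}

n_match_cols <- function(states) {
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  sum(ch == "-" | (ch %in% LETTERS))
}

# per-match-column content of a row: residue letter at occupied columns, NA at
# deletions; inserts and flanks do not appear
match_column_chars <- function(states) {
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  keep <- ch == "-" | (ch %in% LETTERS)
  out <- ch[keep]
  out[out == "-"] <- NA_character_
  out
}

#' Residue sequence of an aligned row
#'
#' Strips deletion characters and case, returning the residues the row
#' actually contains (inserts included, flanks excluded since they are stored
#' as counts only).
#'
#' @param states a state string.
#' @return uppercase residue string.
#' @export
ungap_states <- function(states) {
  toupper(gsub("-", "", states, fixed = TRUE))
}

#' Fraction of match columns occupied by a row
#'
#' The number of match-state residues (uppercase) divided by the alignment's
#' match-column count. Fragments score low; full-coverage rows score 1.
#'
#' @param states state string, or an `msa` (returns a vector over rows).
#' @param L match-column count; inferred from the string when missing.
#' @return fraction in \[0, 1\].
#' @export
match_fraction <- function(states, L = NULL) {
  if (inherits(states, "msa")) {
    m <- states
    return(vapply(m$rows$states, match_fraction, numeric(1), L = m$L,
                  USE.NAMES = FALSE))
  }
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  if (is.null(L)) L <- sum(ch == "-" | ch %in% LETTERS)
  if (L == 0L) return(0)
  sum(ch %in% LETTERS) / L
}

#' Percent identity between two aligned rows
#'
#' Identities are counted over match columns where both rows carry a residue;
#' the denominator is the smaller of the two rows' match-residue counts, so a
#' fragment identical to a full-length row scores 1. Returns 0 when no column
#' is occupied in both rows.
#'
#' @param a,b state strings with the same number of match columns.
#' @return fraction in \[0, 1\].
#' @export
percent_identity <- function(a, b) {
  ca <- match_column_chars(a)
  cb <- match_column_chars(b)
  if (length(ca) != length(cb)) {
    stop("percent_identity: rows have different match-column counts (",
         length(ca), " vs ", length(cb), ")")
  }
  both <- !is.na(ca) & !is.na(cb)
  denom <- min(sum(!is.na(ca)), sum(!is.na(cb)))
  if (denom == 0L || !any(both)) return(0)
  sum(ca[both] == cb[both]) / denom
}

# n x L character matrix of match-column content (NA = deletion); the L = 1
# case needs explicit shaping because vapply returns a bare vector there
msa_char_matrix <- function(m) {
  cm <- vapply(m$rows$states, match_column_chars, character(m$L),
               USE.NAMES = FALSE)
  if (m$L == 1L) matrix(cm, ncol = 1L) else t(cm)
}

# integer-coded match-column matrix (n x L): 1..20 residue index, 0 deletion
msa_state_matrix <- function(m) {
  n <- nrow(m$rows)
  out <- matrix(0L, n, m$L)
  for (i in seq_len(n)) {
    ch <- match_column_chars(m$rows$states[i])
    idx <- match(ch, AA)
    idx[is.na(idx) & !is.na(ch)] <- 21L  # non-standard residue (X etc.)
    idx[is.na(idx)] <- 0L                # deletion
    out[i, ] <- idx
  }
  out
}
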