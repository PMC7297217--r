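# ---- fragment and redundancy purging --------------------------------------

#' Purge parameter set
#'
#' @param min_match_fraction rows matching fewer than this fraction of the
#'   aligned columns are removed (default 0.75; strictly-below removes, the
#'   boundary is retained).
#' @param max_identity among unprotected rows sharing at least this
#'   identity, all but one representative are removed (default 0.98).
#' @param max_deletion_fraction optional evaluation-preprocessing filter;
#'   `NULL` disables it.
#' @return list of class `purge_params`.
#' @export
purge_params <- function(min_match_fraction = 0.75, max_identity = 0.98,
                         max_deletion_fraction = NULL) {
  stopifnot(min_match_fraction > 0, min_match_fraction <= 1,
            max_identity > 0, max_identity <= 1)
  structure(list(min_match_fraction = min_match_fraction,
                 max_identity = max_identity,
                 max_deletion_fraction = max_deletion_fraction),
            class = "purge_params")
}

#' Merge per-chunk global alignments
#'
#' Concatenates chunk outputs in order and collapses duplicate
#' (sequence, region) pairs, so re-running over overlapping chunks cannot
#' inflate the alignment.
#'
#' @param chunks list of `global_msa` objects sharing the same root length.
#' @return one `global_msa`.
#' @export
merge_outputs <- function(chunks) {
  stopifnot(length(chunks) >= 1L)
  Ls <- vapply(chunks, `[[`, 0L, "L")
  if (length(unique(Ls)) != 1L) {
    stop("merge_outputs: mismatched root match-column counts: ",
         paste(unique(Ls), collapse = ", "))
  }
  rows <- do.call(rbind, lapply(chunks, function(m) m$rows))
  key <- paste(rows$orig_id, rows$region_start, rows$region_end, sep = "\r")
  rows <- rows[!duplicated(key), , drop = FALSE]
  rows <- rows[!duplicated(rows$seq_id), , drop = FALSE]
  rownames(rows) <- NULL
  new_global_msa(rows, Ls[1L], chunks[[1L]]$accession)
}

#' Remove short fragments
#'
#' Retains rows occupying at least `min_match_fraction` of the match
#' columns; a row exactly at the threshold is retained.
#'
#' @param m a `global_msa` (any [msa] works).
#' @param min_match_fraction coverage threshold.
#' @return the filtered alignment.
#' @export
fragment_filter <- function(m, min_match_fraction = 0.75) {
  keep <- match_fraction(m) >= min_match_fraction
  subset_rows(m, keep)
}

subset_rows <- function(m, keep) {
  m$rows <- m$rows[keep, , drop = FALSE]
  rownames(m$rows) <- NULL
  m
}

#' Remove redundant rows
#'
#' Greedy representative selection: rows are visited protected-first, then
#' by decreasing match-residue count, then by id; a row is kept iff it is
#' protected or its identity ([percent_identity()] semantics) to every
#' already-kept row is below `max_identity`. After filtering, no unprotected
#' pair of kept rows reaches the threshold.
#'
#' @param m a `global_msa` or [msa].
#' @param max_identity identity threshold (default 0.98).
#' @param protected_ids ids (row `seq_id` or original sequence id) exempt
#'   from removal, in addition to rows flagged `protected`.
#' @return the filtered alignment.
#' @export
redundancy_filter <- function(m, max_identity = 0.98,
                              protected_ids = character(0)) {
  n <- nrow(m$rows)
  if (n <= 1L) return(m)
  prot <- m$rows$protected | m$rows$seq_id %in% protected_ids
  if (!is.null(m$rows$orig_id)) prot <- prot | m$rows$orig_id %in% protected_ids
  sm <- msa_state_matrix(m)
  nres <- rowSums(sm > 0L)
  ord <- order(!prot, -nres, m$rows$seq_id)
  idm <- identity_matrix_cpp(sm)
  kept <- integer(0)
  keep <- logical(n)
  for (i in ord) {
    if (prot[i] || length(kept) == 0L || all(idm[i, kept] < max_identity)) {
      keep[i] <- TRUE
      kept <- c(kept, i)
    }
  }
  subset_rows(m, keep)
}

#' Purge a merged global alignment
#'
#' [fragment_filter()] followed by [redundancy_filter()]; idempotent.
#'
#' @param m a `global_msa`.
#' @param params a [purge_params()] list.
#' @param protected_ids ids exempt from redundancy removal.
#' @return the purged alignment.
#' @export
purge <- function(m, params = purge_params(), protected_ids = character(0)) {
  m <- fragment_filter(m, params$min_match_fraction)
  if (!is.null(params$max_deletion_fraction)) {
    keep <- (1 - match_fraction(m)) <= params$max_deletion_fraction
    m <- subset_rows(m, keep)
  }
  redundancy_filter(m, params$max_identity, protected_ids)
}
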