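# ---- projection of hits into root match columns ---------------------------

# Build a state string with exactly root_L (uppercase + '-') states from a
# residue string and, per residue, its root column (NA = insert). Inserts
# are attached after the nearest preceding mapped root column (left-anchored);
# residues before the first mapped column become leading inserts.
assemble_row_states <- function(root_L, residues, root_cols) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  stopifnot(length(ch) == length(root_cols))
  match_char <- rep("-", root_L)
  ins <- vector("list", root_L + 1L)  # ins[[rc + 1]] = inserts after column rc
  last <- 0L
  for (r in seq_along(ch)) {
    rc <- root_cols[r]
    if (!is.na(rc)) {
      match_char[rc] <- toupper(ch[r])
      last <- rc
    } else {
      ins[[last + 1L]] <- c(ins[[last + 1L]], tolower(ch[r]))
    }
  }
  parts <- character(0)
  if (length(ins[[1L]])) parts <- paste(ins[[1L]], collapse = "")
  for (rc in seq_len(root_L)) {
    parts <- c(parts, match_char[rc],
               if (length(ins[[rc + 1L]])) paste(ins[[rc + 1L]], collapse = ""))
  }
  paste(parts, collapse = "")
}

#' Project one domain hit into root coordinates
#'
#' A residue aligned to node column `i` becomes a match residue at root
#' column `node_to_root_map(i)`; residues on unmapped node columns (subgroup
#' insertions) and insert-state residues of the hit path become lowercase
#' inserts attached after the nearest preceding mapped root column; root
#' columns with no image are deletions.
#'
#' @param hit a domain hit from [hierarchical_search()].
#' @param h the `himsa` it was found with.
#' @return one-row data.frame in global-row layout (`seq_id`, `desc`,
#'   `states`, flanks, `protected`, `source_node`, `orig_id`,
#'   `region_start`, `region_end`).
#' @export
map_hit_to_root <- function(hit, h) {
  mp <- node_to_root_map(h, hit$accession)
  root_cols <- rep(NA_integer_, length(hit$col_of_res))
  pos <- hit$col_of_res > 0L
  root_cols[pos] <- unname(mp[as.character(hit$col_of_res[pos])])
  states <- assemble_row_states(h$root_L, hit$residues, root_cols)
  data.frame(
    seq_id = sprintf("%s/%d-%d", hit$seq_id, hit$start, hit$end),
    desc = "",
    states = states,
    flank_left = hit$start - 1L,
    flank_right = hit$seq_len - hit$end,
    protected = FALSE,
    source_node = hit$accession,
    orig_id = hit$seq_id,
    region_start = hit$start,
    region_end = hit$end,
    stringsAsFactors = FALSE)
}

#' Assemble the global alignment from a hit set
#'
#' One global row per hit (a sequence carrying two domain copies contributes
#' two rows), ordered deterministically by source node (depth-first order),
#' then sequence id, then region start.
#'
#' @param hits list of domain hits.
#' @param h the `himsa`.
#' @return a `global_msa` (also an [msa]) whose `L` is the root
#'   match-column count; rows carry `source_node`, `orig_id`,
#'   `region_start`, `region_end`.
#' @export
build_global_msa <- function(hits, h) {
  if (length(hits) == 0L) {
    rows <- cbind(empty_rows(),
                  data.frame(source_node = character(0), orig_id = character(0),
                             region_start = integer(0), region_end = integer(0),
                             stringsAsFactors = FALSE))
    return(new_global_msa(rows, h$root_L, h$order[1L]))
  }
  rows <- do.call(rbind, lapply(hits, map_hit_to_root, h = h))
  node_rank <- match(rows$source_node, h$order)
  rows <- rows[order(node_rank, rows$orig_id, rows$region_start), , drop = FALSE]
  rownames(rows) <- NULL
  new_global_msa(rows, h$root_L, h$order[1L])
}

new_global_msa <- function(rows, root_L, root_acc = "") {
  base <- msa(rows[, c("seq_id", "desc", "states", "flank_left", "flank_right",
                       "protected")], name = "global", accession = root_acc)
  if (nrow(rows) > 0L && base$L != root_L) {
    stop("global rows have ", base$L, " match columns, expected root_L = ", root_L)
  }
  base$L <- root_L
  base$rows$source_node <- rows$source_node
  base$rows$orig_id <- rows$orig_id
  base$rows$region_start <- as.integer(rows$region_start)
  base$rows$region_end <- as.integer(rows$region_end)
  class(base) <- c("global_msa", "msa")
  base
}

#' Project a curated node row directly into root coordinates
#'
#' The template-defined projection of a curated alignment row (no search
#' involved): each match residue goes to its mapped root column, residues at
#' unmapped columns and insert-state residues become inserts. Used as the
#' ground-truth placement when checking self-recovery.
#'
#' @param h a `himsa`.
#' @param accession node accession.
#' @param states the curated row's state string.
#' @return state string with `root_L` match states.
#' @export
project_curated_row <- function(h, accession, states) {
  mp <- node_to_root_map(h, accession)
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  col <- cumsum(ch == "-" | ch %in% LETTERS)
  res_sel <- ch %in% c(LETTERS, letters)
  res <- ch[res_sel]
  # node column of each residue (NA for lowercase inserts)
  nc <- ifelse(ch[res_sel] %in% LETTERS, col[res_sel], NA_integer_)
  rc <- rep(NA_integer_, length(nc))
  ok <- !is.na(nc)
  rc[ok] <- unname(mp[as.character(nc[ok])])
  assemble_row_states(h$root_L, paste(res, collapse = ""), rc)
}
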