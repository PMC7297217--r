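# ---- tree-pruned profile search -------------------------------------------

#' Build one scoring profile per hierarchy node
#'
#' @param h a `himsa`.
#' @param ... passed to [build_profile()] (pseudocount mass, gap penalties).
#' @return named list of `profile` objects in depth-first order.
#' @export
build_himsa_profiles <- function(h, ...) {
  out <- lapply(h$nodes, function(nd) {
    p <- build_profile(nd$msa, ...)
    p$accession <- nd$accession
    p$trigger <- nd$trigger
    p
  })
  names(out) <- h$order
  out
}

#' Search parameter set
#'
#' @param max_evalue report hits at or below this expectation value.
#' @param trigger_evalue nodes whose score reaches the score equivalent of
#'   this E-value admit their children into the search (the "trigger").
#' @param triggers optional named numeric vector of per-node raw-score
#'   triggers overriding the E-value-derived default (`-Inf` disables
#'   pruning entirely).
#' @param max_copies cap on domain copies detected per sequence.
#' @param max_internal_gap largest unaligned stretch bridged when merging
#'   split matches of one domain copy.
#' @return list of class `search_params`.
#' @export
search_params <- function(max_evalue = 0.001, trigger_evalue = 10,
                          triggers = NULL, max_copies = 10L,
                          max_internal_gap = 50L) {
  structure(list(max_evalue = max_evalue, trigger_evalue = trigger_evalue,
                 triggers = triggers, max_copies = as.integer(max_copies),
                 max_internal_gap = as.integer(max_internal_gap)),
            class = "search_params")
}

node_triggers <- function(h, profiles, params, db_residues) {
  tr <- vapply(h$order, function(acc) {
    if (!is.null(params$triggers) && acc %in% names(params$triggers)) {
      return(unname(params$triggers[acc]))
    }
    nd <- h$nodes[[acc]]
    if (!is.na(nd$trigger)) return(nd$trigger)
    score_for_evalue(profiles[[acc]], params$trigger_evalue, db_residues)
  }, numeric(1))
  names(tr) <- h$order
  tr
}

new_hit <- function(seq_id, accession, aln, seq, evalue) {
  list(seq_id = seq_id, accession = accession,
       start = aln$qstart, end = aln$qend,
       cstart = aln$cstart, cend = aln$cend,
       col_of_res = aln$col_of_res,
       residues = substr(seq, aln$qstart, aln$qend),
       score = aln$score, evalue = evalue, seq_len = nchar(seq))
}

#' Tree-pruned search of one sequence against a hierarchy
#'
#' The root profile is scored first; a node's children are evaluated only
#' when the node's score reaches its trigger. Among all evaluated nodes the
#' match is assigned to the highest-scoring profile (ties: deeper node, then
#' depth-first order). The matched region is then masked with X and the
#' search repeats, so each copy of a repeated domain is reported separately;
#' finally, colinear same-node matches separated by at most
#' `max_internal_gap` unaligned residues are merged into one hit. Only hits
#' with E-value at or below `max_evalue` are returned.
#'
#' @param h a `himsa`.
#' @param seq residue string.
#' @param params a [search_params()] list.
#' @param profiles profiles from [build_himsa_profiles()] (rebuilt when
#'   omitted).
#' @param db_residues database size used for E-values and triggers.
#' @param seq_id identifier recorded in hits.
#' @return list of domain hits (possibly empty); each hit has `seq_id`,
#'   `accession`, `start`/`end`, `cstart`/`cend`, `col_of_res`, `residues`,
#'   `score`, `evalue`, `seq_len`.
#' @export
hierarchical_search <- function(h, seq, params = search_params(),
                                profiles = build_himsa_profiles(h),
                                db_residues = nchar(seq), seq_id = "query") {
  triggers <- node_triggers(h, profiles, params, db_residues)
  parents <- dft_parents(as.integer(h$tree))
  depths <- as.integer(h$tree)
  masked <- seq
  hits <- list()
  for (iter in seq_len(params$max_copies)) {
    if (!grepl("[A-WYZ]", masked)) break
    scores <- rep(NA_real_, length(h$order))
    alns <- vector("list", length(h$order))
    for (k in seq_along(h$order)) {
      if (k > 1L) {
        p <- parents[k]
        if (is.na(scores[p]) || scores[p] < triggers[p]) next
      }
      alns[[k]] <- local_align(profiles[[k]], masked)
      scores[k] <- alns[[k]]$score
    }
    ev <- which(!is.na(scores))
    if (length(ev) == 0L) break
    # highest score; ties to the deeper node, then depth-first order
    ord <- ev[order(-scores[ev], -depths[ev], ev)]
    best <- ord[1L]
    aln <- alns[[best]]
    if (aln$qend < aln$qstart) break
    e <- evalue(scores[best], profiles[[best]], db_residues)
    if (e > params$max_evalue) break
    # the reported path is glocal in the chosen profile: the projection then
    # covers the full domain model instead of trimming weak terminal columns
    gal <- glocal_align(profiles[[best]], masked)
    if (gal$qend < gal$qstart) break
    gal$score <- aln$score  # significance is the local detection score
    hits[[length(hits) + 1L]] <- new_hit(seq_id, h$order[best], gal, seq, e)
    # mask the matched region for further copy detection
    substr(masked, gal$qstart, gal$qend) <-
      strrep("X", gal$qend - gal$qstart + 1L)
  }
  if (length(hits) > 1L) {
    hits <- merge_hits_by_node(hits, params$max_internal_gap,
                               profiles, db_residues, seq)
  }
  hits
}

merge_hits_by_node <- function(hits, max_internal_gap, profiles = NULL,
                               db_residues = NULL, seq = NULL) {
  accs <- vapply(hits, `[[`, "", "accession")
  out <- list()
  for (acc in unique(accs)) {
    grp <- hits[accs == acc]
    prof <- if (!is.null(profiles)) profiles[[acc]] else NULL
    out <- c(out, merge_split_hits(grp, max_internal_gap, prof, db_residues,
                                   seq))
  }
  out[order(vapply(out, `[[`, 0, "start"))]
}

#' Merge split sub-matches of one domain copy
#'
#' A domain with a long low-similarity insertion may surface as two or more
#' short matches. Colinear sub-matches (increasing in both sequence and
#' column coordinates, non-overlapping column ranges) separated by at most
#' `max_internal_gap` unaligned residues are combined into one hit whose
#' path bridges the gap with insert and deletion runs. Anything non-colinear
#' is returned unmerged.
#'
#' @param hits list of hits for one sequence and one node.
#' @param max_internal_gap largest bridgeable unaligned stretch (residues).
#' @param profile,db_residues when supplied, the merged hit's E-value is
#'   recomputed from the summed score; otherwise the smaller input E-value
#'   is kept.
#' @param seq the source sequence; when supplied the bridged residues are
#'   taken from it, otherwise the bridge is X-padded.
#' @return list of hits (length 1 if everything merged).
#' @export
merge_split_hits <- function(hits, max_internal_gap = 50L, profile = NULL,
                             db_residues = NULL, seq = NULL) {
  if (length(hits) <= 1L) return(hits)
  hits <- hits[order(vapply(hits, `[[`, 0, "start"))]
  out <- list(hits[[1L]])
  for (k in 2L:length(hits)) {
    cur <- out[[length(out)]]
    nxt <- hits[[k]]
    gap <- nxt$start - cur$end - 1L
    colinear <- nxt$start > cur$end && nxt$cstart > cur$cend
    if (colinear && gap >= 0L && gap <= max_internal_gap) {
      merged <- cur
      merged$end <- nxt$end
      merged$cend <- nxt$cend
      merged$col_of_res <- c(cur$col_of_res, rep(0L, gap), nxt$col_of_res)
      bridge <- if (gap == 0L) "" else if (!is.null(seq)) {
        substr(seq, cur$end + 1L, nxt$start - 1L)
      } else strrep("X", gap)
      merged$residues <- paste0(cur$residues, bridge, nxt$residues)
      merged$score <- cur$score + nxt$score
      merged$evalue <- if (!is.null(profile) && !is.null(db_residues)) {
        evalue(merged$score, profile, db_residues)
      } else min(cur$evalue, nxt$evalue)
      out[[length(out)]] <- merged
    } else {
      out[[length(out) + 1L]] <- nxt
    }
  }
  out
}

#' Assign a sequence by exhaustive scoring of every node profile
#'
#' The unpruned reference: scores all profiles and applies the same
#' assignment rule as the pruned search (highest score, deeper node, then
#' depth-first order). Used to check pruning soundness.
#'
#' @param h a `himsa`.
#' @param seq residue string.
#' @param profiles node profiles.
#' @return list: `accession`, `score`, per-node `scores`.
#' @export
exhaustive_assign <- function(h, seq, profiles = build_himsa_profiles(h)) {
  depths <- as.integer(h$tree)
  scores <- vapply(seq_along(h$order), function(k) {
    local_align(profiles[[k]], seq)$score
  }, numeric(1))
  ord <- order(-scores, -depths, seq_along(scores))
  list(accession = h$order[ord[1L]], score = scores[ord[1L]],
       scores = setNames(scores, h$order))
}

#' Search a whole database against a hierarchy
#'
#' @param h a `himsa`.
#' @param db data.frame from [read_fasta()].
#' @param params a [search_params()].
#' @param profiles node profiles (rebuilt when omitted).
#' @param db_residues database residue count for the E-value statistics;
#'   defaults to the total residues of `db` (pass the full-database count
#'   when searching a chunk so chunking does not change E-values).
#' @return list of domain hits across all sequences.
#' @export
search_db <- function(h, db, params = search_params(),
                      profiles = build_himsa_profiles(h),
                      db_residues = sum(nchar(db$seq))) {
  out <- list()
  for (i in seq_len(nrow(db))) {
    out <- c(out, hierarchical_search(h, db$seq[i], params, profiles,
                                      db_residues, seq_id = db$seq_id[i]))
  }
  out
}

#' Tabulate domain hits
#'
#' @param hits list of hits from [search_db()].
#' @return data.frame: `seq_id`, `node`, `start`, `end`, `score`, `evalue`.
#' @export
hits_table <- function(hits) {
  data.frame(
    seq_id = vapply(hits, `[[`, "", "seq_id"),
    node = vapply(hits, `[[`, "", "accession"),
    start = vapply(hits, `[[`, 0, "start"),
    end = vapply(hits, `[[`, 0, "end"),
    score = vapply(hits, `[[`, 0, "score"),
    evalue = vapply(hits, `[[`, 0, "evalue"),
    stringsAsFactors = FALSE)
}
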