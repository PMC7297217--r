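# ---- hierarchical MSA: tree, template, column maps ------------------------

#' Parse a depth-first-traversal tree array
#'
#' The hierarchy is encoded as the depths of the nodes in depth-first order:
#' entry k is the depth of node k, the root (depth 0) comes first, and a
#' node's parent is the nearest preceding node one level up. `"0 1 2 2 1"`
#' is a root with two children, the first of which has two children.
#'
#' @param x file path, string, or lines of whitespace-separated integers.
#' @return integer vector of depths (class `dft`).
#' @export
parse_dft <- function(x) {
  txt <- paste(as_lines(x), collapse = " ")
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  d <- suppressWarnings(as.integer(toks))
  if (length(d) == 0L) stop("dft parse error: no entries")
  if (anyNA(d)) stop("dft parse error: malformed integer '", toks[which(is.na(d))[1]], "'")
  if (d[1L] != 0L) stop("dft parse error: first entry must be the root (depth 0)")
  if (length(d) > 1L && any(d[-1L] == 0L)) {
    stop("dft parse error: more than one root (depth 0 after position 1)")
  }
  if (length(d) > 1L && any(diff(d) > 1L)) {
    k <- which(diff(d) > 1L)[1L]
    stop("dft parse error: depth jump >1 between entries ", k, " and ", k + 1L)
  }
  structure(d, class = "dft")
}

#' Serialize a tree array
#' @param d integer depths as from [parse_dft()].
#' @return single text line.
#' @export
emit_dft <- function(d) paste(as.integer(d), collapse = " ")

# parent index per node from the depth array (0 for the root)
dft_parents <- function(d) {
  n <- length(d)
  par <- integer(n)
  for (k in seq_len(n)) {
    if (d[k] == 0L) { par[k] <- 0L; next }
    p <- max(which(d[seq_len(k - 1L)] == d[k] - 1L))
    par[k] <- p
  }
  par
}

#' Assemble and validate a hierarchical MSA
#'
#' Converts an mFASTA-distributed hierarchy (one alignment file per node, a
#' template alignment of node consensus sequences, and a depth-first tree
#' array) into the package's search-ready form. The consensus of every node
#' alignment is recomputed (weighted most-frequent residue per column) and
#' checked against the ungapped residues of the node's template row.
#'
#' @param node_msas named list of [msa] objects (names = accessions), or a
#'   character vector of mFASTA file paths named by accession.
#' @param template an [msa] whose rows are the node consensus sequences in
#'   tree order, first row the root; or an mFASTA file path.
#' @param tree a `dft` object or file/text accepted by [parse_dft()].
#' @return object of class `himsa` with fields `nodes` (named list:
#'   `accession`, `msa`, `consensus`, `parent`, `depth`, `trigger`), `order`
#'   (accessions in depth-first order), `template`, `tree`, `root_L`.
#' @export
cdd2mgs <- function(node_msas, template, tree) {
  if (is.character(template)) template <- read_mfasta(template)
  if (!inherits(tree, "dft")) tree <- parse_dft(tree)
  if (is.character(node_msas)) {
    paths <- node_msas
    node_msas <- lapply(paths, read_mfasta)
    names(node_msas) <- if (!is.null(names(paths)) && all(nzchar(names(paths))))
      names(paths) else sub("\\.[^.]*$", "", basename(paths))
  }
  accs <- template$rows$seq_id
  if (length(tree) != length(accs)) {
    stop("cdd2mgs: tree has ", length(tree), " nodes but template has ",
         length(accs), " rows")
  }
  missing <- setdiff(accs, names(node_msas))
  if (length(missing)) {
    stop("cdd2mgs: no node alignment for accession(s): ",
         paste(missing, collapse = ", "))
  }
  orphan <- setdiff(names(node_msas), accs)
  if (length(orphan)) {
    stop("cdd2mgs: orphan node(s) not present in template: ",
         paste(orphan, collapse = ", "))
  }
  par <- dft_parents(tree)
  nodes <- vector("list", length(accs))
  names(nodes) <- accs
  for (k in seq_along(accs)) {
    acc <- accs[k]
    m <- node_msas[[acc]]
    m$accession <- acc
    cons <- consensus(m)
    trow <- ungap_states(template$rows$states[k])
    if (cons != trow) {
      stop("cdd2mgs: consensus mismatch for node ", acc,
           ": recomputed '", abbrev(cons), "' vs template '", abbrev(trow), "'")
    }
    nodes[[k]] <- list(accession = acc, msa = m, consensus = cons,
                       parent = if (par[k] == 0L) NA_character_ else accs[par[k]],
                       depth = as.integer(tree[k]), trigger = NA_real_)
  }
  h <- structure(list(nodes = nodes, order = accs, template = template,
                      tree = tree, root_L = nodes[[1L]]$msa$L),
                 class = "himsa")
  f <- validate_himsa(h)
  if (nrow(f) > 0L) {
    stop("cdd2mgs: hierarchy validation failed: ",
         paste(sprintf("[%s] %s", f$node, f$message), collapse = "; "))
  }
  h
}

abbrev <- function(s, n = 24L) if (nchar(s) > n) paste0(substr(s, 1, n), "...") else s

#' @export
print.himsa <- function(x, ...) {
  cat("himsa:", length(x$nodes), "nodes, root", x$order[1L],
      "with", x$root_L, "match columns\n")
  for (k in seq_along(x$order)) {
    nd <- x$nodes[[k]]
    cat(strrep("  ", nd$depth + 1L), nd$accession, " (L=", nd$msa$L,
        ", n=", nrow(nd$msa$rows), ")\n", sep = "")
    if (k >= 12L && length(x$order) > 13L) {
      cat("  ...", length(x$order) - k, "more nodes\n"); break
    }
  }
  invisible(x)
}

# residue index -> template match column (NA for lowercase inserts)
template_res_cols <- function(states) {
  ch <- strsplit(states, "", fixed = TRUE)[[1]]
  col <- cumsum(ch == "-" | ch %in% LETTERS)
  ifelse(ch %in% LETTERS, col, NA_integer_)[ch %in% c(LETTERS, letters)]
}

#' Column map from a node onto the root
#'
#' A node's match column maps onto a root match column exactly when the
#' node's template row has a (match-state) residue in a template column that
#' the root's template row also occupies; insert-state residues of the
#' template row map nowhere. The map is strictly increasing and partial.
#'
#' @param h a `himsa`.
#' @param accession node accession.
#' @return named integer vector: names are node columns (as character),
#'   values the corresponding root columns.
#' @export
node_to_root_map <- function(h, accession) {
  k <- match(accession, h$order)
  if (is.na(k)) stop("unknown accession: ", accession)
  node_rc <- template_res_cols(h$template$rows$states[k])
  root_rc <- template_res_cols(h$template$rows$states[1L])
  # inverse on the root side: template column -> root column index
  inv <- rep(NA_integer_, max(c(0L, node_rc, root_rc), na.rm = TRUE))
  ok <- !is.na(root_rc)
  inv[root_rc[ok]] <- seq_along(root_rc)[ok]
  out <- integer(0)
  for (i in seq_along(node_rc)) {
    tc <- node_rc[i]
    if (!is.na(tc) && tc <= length(inv) && !is.na(inv[tc])) {
      out[as.character(i)] <- inv[tc]
    }
  }
  out
}

# map between two arbitrary nodes via template co-occupancy (used for the
# functoriality checks): node column -> other node's column
node_to_node_map <- function(h, from, to) {
  kf <- match(from, h$order); kt <- match(to, h$order)
  if (is.na(kf) || is.na(kt)) stop("unknown accession")
  f_rc <- template_res_cols(h$template$rows$states[kf])
  t_rc <- template_res_cols(h$template$rows$states[kt])
  inv <- rep(NA_integer_, max(c(0L, f_rc, t_rc), na.rm = TRUE))
  ok <- !is.na(t_rc)
  inv[t_rc[ok]] <- seq_along(t_rc)[ok]
  out <- integer(0)
  for (i in seq_along(f_rc)) {
    tc <- f_rc[i]
    if (!is.na(tc) && tc <= length(inv) && !is.na(inv[tc])) out[as.character(i)] <- inv[tc]
  }
  out
}

#' Validate a hierarchical MSA
#'
#' Checks the structural invariants: single root, legal depth steps,
#' template/node correspondence, consensus agreement, and strict
#' monotonicity of every node-to-root column map. Findings are returned as
#' data, not raised.
#'
#' @param h a `himsa`.
#' @return data.frame with columns `node`, `message`; zero rows when valid.
#' @export
validate_himsa <- function(h) {
  f <- list()
  add <- function(node, msg) f[[length(f) + 1L]] <<- data.frame(
    node = node, message = msg, stringsAsFactors = FALSE)
  d <- as.integer(h$tree)
  if (d[1L] != 0L) add(h$order[1L], "root depth is not 0")
  if (length(d) > 1L && any(diff(d) > 1L)) add("*", "depth jump >1 in tree array")
  if (sum(d == 0L) != 1L) add("*", "hierarchy must have exactly one root")
  if (length(h$nodes) != nrow(h$template$rows)) {
    add("*", "template row count differs from node count")
  }
  for (k in seq_along(h$order)) {
    acc <- h$order[k]
    nd <- h$nodes[[k]]
    if (nchar(nd$consensus) != nd$msa$L) {
      add(acc, "consensus length differs from match-column count")
    }
    if (k <= nrow(h$template$rows)) {
      trow <- ungap_states(h$template$rows$states[k])
      if (trow != nd$consensus) add(acc, "template row does not match node consensus")
    }
    mp <- tryCatch(node_to_root_map(h, acc), error = function(e) NULL)
    if (is.null(mp)) {
      add(acc, "node-to-root map could not be computed")
    } else if (length(mp) > 1L && any(diff(mp) <= 0L)) {
      add(acc, "node-to-root map is not strictly increasing")
    }
  }
  if (length(f) == 0L) {
    return(data.frame(node = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, f)
}

# ---- on-disk layout -------------------------------------------------------

#' Write a hierarchy in its distribution layout
#'
#' One mFASTA file per node (`<accession>.mfa`), the template alignment
#' (`<prefix>.tpl`, mFASTA) and the tree array (`<prefix>.dft`) — the layout
#' [cdd2mgs()] and [read_himsa_dir()] consume.
#'
#' @param h a `himsa`.
#' @param dir output directory (created if needed).
#' @param prefix file prefix for the template and tree files.
#' @return `dir`, invisibly.
#' @export
write_himsa_dir <- function(h, dir, prefix = "himsa") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nd in h$nodes) {
    write_mfasta(nd$msa, file.path(dir, paste0(nd$accession, ".mfa")))
  }
  write_mfasta(h$template, file.path(dir, paste0(prefix, ".tpl")))
  writeLines(emit_dft(h$tree), file.path(dir, paste0(prefix, ".dft")))
  invisible(dir)
}

#' Read a hierarchy from its distribution layout
#'
#' @param dir directory holding `<accession>.mfa` files plus `<prefix>.tpl`
#'   and `<prefix>.dft`.
#' @param prefix file prefix; auto-detected when exactly one `.tpl` exists.
#' @return a validated `himsa` (via [cdd2mgs()]).
#' @export
read_himsa_dir <- function(dir, prefix = NULL) {
  if (is.null(prefix)) {
    tpl <- list.files(dir, "\\.tpl$")
    if (length(tpl) != 1L) stop("read_himsa_dir: expected exactly one .tpl in ", dir)
    prefix <- sub("\\.tpl$", "", tpl)
  }
  tpl_path <- file.path(dir, paste0(prefix, ".tpl"))
  dft_path <- file.path(dir, paste0(prefix, ".dft"))
  if (!file.exists(tpl_path)) stop("read_himsa_dir: missing template file ", tpl_path)
  if (!file.exists(dft_path)) stop("read_himsa_dir: missing tree file ", dft_path)
  node_paths <- list.files(dir, "\\.mfa$", full.names = TRUE)
  names(node_paths) <- sub("\\.mfa$", "", basename(node_paths))
  cdd2mgs(node_paths, tpl_path, dft_path)
}
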