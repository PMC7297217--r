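# ---- shared line handling -------------------------------------------------

as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

# split FASTA-like lines into records: list of (header, body)
split_fasta_records <- function(lines) {
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) > 0L && !hdr[1L]) {
    stop("malformed FASTA: first non-empty line is not a header")
  }
  idx <- cumsum(hdr)
  recs <- split(lines, idx)
  lapply(recs, function(r) {
    list(header = sub("^>", "", r[1L]),
         body = paste(r[-1L], collapse = ""))
  })
}

parse_header <- function(h) {
  h <- trimws(h)
  sp <- regexpr("\\s", h)
  if (sp < 0) list(id = h, desc = "") else
    list(id = substr(h, 1L, sp - 1L), desc = trimws(substr(h, sp + 1L, nchar(h))))
}

wrap_seq <- function(s, width = 70L) {
  if (nchar(s) == 0L) return(character(0))
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

# ---- mFASTA ---------------------------------------------------------------

#' Read an alignment in mFASTA format
#'
#' mFASTA is standard FASTA carrying alignment state: uppercase letters are
#' residues at match columns, `-` is a deletion at a match column and
#' lowercase letters are inserted residues between match columns. Every
#' record must have the same number of match columns (uppercase plus `-`).
#' Flank counts are not represented in mFASTA and read as 0; the cma dialect
#' stores them explicitly.
#'
#' @param x file path, single string with newlines, or character vector of
#'   lines.
#' @param name,accession metadata attached to the returned alignment.
#' @return an [msa].
#' @export
read_mfasta <- function(x, name = "", accession = "") {
  recs <- split_fasta_records(as_lines(x))
  if (length(recs) == 0L) return(msa(empty_rows(), name, accession))
  ids <- character(length(recs)); descs <- character(length(recs))
  states <- character(length(recs))
  for (i in seq_along(recs)) {
    h <- parse_header(recs[[i]]$header)
    ids[i] <- h$id; descs[i] <- h$desc
    s <- recs[[i]]$body
    if (grepl("[^A-Za-z-]", s)) {
      stop("malformed alignment: record '", h$id,
           "' contains characters outside [A-Za-z-]")
    }
    states[i] <- s
  }
  msa(data.frame(seq_id = ids, desc = descs, states = states,
                 stringsAsFactors = FALSE), name, accession)
}

empty_rows <- function() {
  data.frame(seq_id = character(0), desc = character(0), states = character(0),
             flank_left = integer(0), flank_right = integer(0),
             protected = logical(0), stringsAsFactors = FALSE)
}

#' Write an alignment in mFASTA format
#'
#' Inverse of [read_mfasta()] up to flank counts, which mFASTA cannot
#' represent and which are dropped.
#'
#' @param m an [msa].
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return character vector of lines, invisibly when writing to a file.
#' @export
write_mfasta <- function(m, file = NULL) {
  out <- character(0)
  for (i in seq_len(nrow(m$rows))) {
    h <- paste0(">", m$rows$seq_id[i],
                if (nzchar(m$rows$desc[i])) paste0(" ", m$rows$desc[i]) else "")
    out <- c(out, h, wrap_seq(m$rows$states[i]))
  }
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

# ---- cma dialect ----------------------------------------------------------
# Line-oriented, lossless for (name, accession, L, per-row id/desc/flanks/
# protected/states):
#   [cma]<TAB>name<TAB>accession<TAB>L<TAB>nrows
#   ><TAB>seq_id<TAB>flank_left<TAB>flank_right<TAB>0|1<TAB>desc
#   <states on one line>
#   ... (nrows record pairs)
#   [end]
# Multiple blocks may be concatenated into one bundle file.

#' Write an alignment in the cma dialect
#'
#' A compact line-oriented alignment format that, unlike mFASTA, stores flank
#' counts (unaligned residues before/after the aligned region) and the
#' protected flag per row. See the package vignette for the grammar.
#'
#' @param m an [msa].
#' @param file optional output path.
#' @return character vector of lines.
#' @export
write_cma <- function(m, file = NULL) {
  out <- sprintf("[cma]\t%s\t%s\t%d\t%d", m$name, m$accession, m$L, nrow(m$rows))
  for (i in seq_len(nrow(m$rows))) {
    out <- c(out,
             sprintf(">\t%s\t%d\t%d\t%d\t%s", m$rows$seq_id[i],
                     m$rows$flank_left[i], m$rows$flank_right[i],
                     as.integer(m$rows$protected[i]), m$rows$desc[i]),
             m$rows$states[i])
  }
  out <- c(out, "[end]")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Read an alignment in the cma dialect
#'
#' @param x file path, string, or lines (see [read_mfasta()]).
#' @return an [msa] (the first block; use [read_cma_bundle()] for multi-block
#'   files).
#' @export
read_cma <- function(x) {
  read_cma_bundle(x)[[1L]]
}

#' Read all alignment blocks from a cma bundle
#'
#' @param x file path, string, or lines.
#' @return named list of [msa] objects (names = accessions where set).
#' @export
read_cma_bundle <- function(x) {
  lines <- as_lines(x)
  lines <- lines[!grepl("^\\s*$", lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "[cma]")) {
      stop("cma parse error at line ", i, ": expected [cma] header")
    }
    hf <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(hf) != 5L) {
      stop("cma parse error at line ", i, ": header needs 5 tab-separated fields")
    }
    L <- suppressWarnings(as.integer(hf[4]))
    n <- suppressWarnings(as.integer(hf[5]))
    if (is.na(L) || is.na(n)) {
      stop("cma parse error at line ", i, ": non-integer L or row count")
    }
    ids <- character(n); descs <- character(n); sts <- character(n)
    fls <- integer(n); frs <- integer(n); prot <- logical(n)
    j <- i + 1L
    for (k in seq_len(n)) {
      if (j + 1L > length(lines) || !startsWith(lines[j], ">")) {
        stop("cma parse error at line ", j, ": expected row header")
      }
      rf <- strsplit(lines[j], "\t", fixed = TRUE)[[1]]
      if (length(rf) < 5L) {
        stop("cma parse error at line ", j, ": row header needs >=5 fields")
      }
      fl <- suppressWarnings(as.integer(rf[3])); fr <- suppressWarnings(as.integer(rf[4]))
      if (is.na(fl) || is.na(fr)) {
        stop("cma parse error at line ", j, ": non-integer flank count")
      }
      ids[k] <- rf[2]
      descs[k] <- if (length(rf) >= 6L) paste(rf[-(1:5)], collapse = "\t") else ""
      sts[k] <- lines[j + 1L]; fls[k] <- fl; frs[k] <- fr; prot[k] <- rf[5] == "1"
      j <- j + 2L
    }
    rows <- data.frame(seq_id = ids, desc = descs, states = sts,
                       flank_left = fls, flank_right = frs, protected = prot,
                       stringsAsFactors = FALSE)
    if (j > length(lines) || lines[j] != "[end]") {
      stop("cma parse error at line ", j, ": expected [end]")
    }
    m <- msa(rows, name = hf[2], accession = hf[3])
    if (m$L != L && n > 0L) {
      stop("cma parse error at line ", i, ": header L=", L,
           " but rows have ", m$L, " match columns")
    }
    m$L <- L
    out[[length(out) + 1L]] <- m
    if (nzchar(hf[3])) names(out)[length(out)] <- hf[3]
    i <- j + 1L
  }
  if (length(out) == 0L) stop("cma parse error: no [cma] block found")
  out
}

# ---- plain FASTA databases ------------------------------------------------

#' Read a protein FASTA database
#'
#' @param x file path (read via Biostrings) or text/lines.
#' @return data.frame with columns `seq_id`, `desc`, `seq`.
#' @export
read_fasta <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    ss <- Biostrings::readAAStringSet(x)
    hd <- lapply(names(ss), parse_header)
    return(data.frame(seq_id = vapply(hd, `[[`, "", "id"),
                      desc = vapply(hd, `[[`, "", "desc"),
                      seq = as.character(ss), stringsAsFactors = FALSE,
                      row.names = NULL))
  }
  recs <- split_fasta_records(as_lines(x))
  hd <- lapply(recs, function(r) parse_header(r$header))
  data.frame(seq_id = vapply(hd, `[[`, "", "id"),
             desc = vapply(hd, `[[`, "", "desc"),
             seq = toupper(vapply(recs, `[[`, "", "body")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a protein FASTA database
#'
#' @param db data.frame with `seq_id`, `desc`, `seq`.
#' @param file output path.
#' @export
write_fasta <- function(db, file) {
  nm <- ifelse(nzchar(db$desc), paste(db$seq_id, db$desc), db$seq_id)
  ss <- Biostrings::AAStringSet(setNames(db$seq, nm))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Split a sequence database into fixed-size chunks
#'
#' Large searches are run per chunk and the outputs merged afterwards; the
#' final alignment is invariant to the chunking.
#'
#' @param db data.frame as returned by [read_fasta()].
#' @param chunk_size records per chunk (>= 1).
#' @return list of data.frames; concatenating them restores `db` in order.
#' @export
split_fasta <- function(db, chunk_size) {
  stopifnot(chunk_size >= 1)
  n <- nrow(db)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = as.integer(chunk_size))
  lapply(starts, function(s) db[s:min(s + chunk_size - 1L, n), , drop = FALSE])
}
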