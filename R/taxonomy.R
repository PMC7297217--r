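# ---- phylum / kingdom annotation ------------------------------------------

#' Read a taxonomy mapping table
#'
#' Tab-separated with columns `key`, `phylum`, `kingdom`; `key` is either an
#' organism name (matched against the bracketed `[Genus species]` suffix of
#' FASTA descriptions) or an explicit sequence id. Kingdom is a one-letter
#' code: E (eukaryote), B (bacterium), A (archaeon), V (virus), U (unknown).
#'
#' @param x file path, string, or lines.
#' @return data.frame `key`, `phylum`, `kingdom`; malformed rows are dropped
#'   with a warning, not fatal.
#' @export
read_taxmap <- function(x) {
  lines <- as_lines(x)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 3L
  if (any(!ok)) {
    warning("read_taxmap: dropping ", sum(!ok), " malformed row(s)")
  }
  parts <- parts[ok]
  data.frame(key = vapply(parts, `[[`, "", 1L),
             phylum = vapply(parts, `[[`, "", 2L),
             kingdom = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

tax_tag_re <- " ?\\{<[^>]*>\\}"

#' Annotate sequences with phylum and kingdom labels
#'
#' Appends a `{<Phylum(K)>}` tag to each record's description, resolving the
#' organism from the bracketed `[Genus species]` suffix or, failing that,
#' the sequence id against the mapping table. Unmapped records are tagged
#' `{<unknown(U)>}`. Re-annotation replaces an existing tag (idempotent);
#' sequence residues are never altered.
#'
#' @param db data.frame from [read_fasta()].
#' @param taxmap data.frame from [read_taxmap()].
#' @param quiet suppress the tagged/unknown count message.
#' @return the annotated `db`, with attribute `annotation_counts`
#'   (`tagged`, `unknown`).
#' @export
annotate_phylum <- function(db, taxmap, quiet = FALSE) {
  desc <- gsub(tax_tag_re, "", db$desc)
  org <- rep(NA_character_, nrow(db))
  mm <- regmatches(desc, gregexpr("\\[([^][]+)\\]", desc))
  has <- lengths(mm) > 0L
  org[has] <- gsub("^\\[|\\]$", "", vapply(mm[has], function(x) x[[length(x)]], ""))
  i <- match(org, taxmap$key)
  miss <- is.na(i)
  i[miss] <- match(db$seq_id[miss], taxmap$key)
  tag <- ifelse(is.na(i), "{<unknown(U)>}",
                sprintf("{<%s(%s)>}", taxmap$phylum[i], taxmap$kingdom[i]))
  db$desc <- trimws(paste(desc, tag))
  n_unknown <- sum(is.na(i))
  if (!quiet) {
    message("annotate_phylum: tagged ", nrow(db) - n_unknown,
            " record(s), ", n_unknown, " unknown")
  }
  attr(db, "annotation_counts") <- c(tagged = nrow(db) - n_unknown,
                                     unknown = n_unknown)
  db
}
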