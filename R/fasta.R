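#' Construct a sequence database tibble
#'
#' A sequence database is an ordered tibble with one row per record and columns
#' `id`, `sequence`, `provenance` and `source_tag`. Provenance records where a
#' sequence came from: the reference proteome, a simulated-novel copy, a
#' six-frame translation, or a decoy.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of sequences (upper-cased on construction).
#' @param provenance One of `"reference"`, `"simulated_novel"`, `"six_frame"`,
#'   `"decoy"`; recycled to the number of records.
#' @param source_tag Free-text tag (e.g. which shuffled copy); recycled.
#' @param type `"protein"` (20 amino acids plus X) or `"nucleotide"` (ACGTN).
#' @return A tibble with columns `id`, `sequence`, `provenance`, `source_tag`.
#' @export
#' @examples
#' seq_db(c("p1", "p2"), c("MAKR", "GGKPLR"))
seq_db <- function(id, sequence,
                   provenance = "reference",
                   source_tag = NA_character_,
                   type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (length(id) != length(sequence)) {
    abort("`id` and `sequence` must have the same length")
  }
  sequence <- toupper(sequence)
  db <- tibble(
    id = as.character(id),
    sequence = sequence,
    provenance = rep_len(as.character(provenance), length(id)),
    source_tag = rep_len(as.character(source_tag), length(id))
  )
  validate_seq_db(db, type = type)
  db
}

validate_seq_db <- function(db, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  stopifnot(all(c("id", "sequence") %in% names(db)))
  if (nrow(db) == 0L) return(invisible(db))
  if (anyDuplicated(db$id)) {
    dup <- unique(db$id[duplicated(db$id)])
    abort(sprintf("duplicate record identifiers: %s",
                  paste(head(dup, 5L), collapse = ", ")))
  }
  if (any(!nzchar(db$sequence))) {
    abort(sprintf("empty sequence for record(s): %s",
                  paste(head(db$id[!nzchar(db$sequence)], 5L), collapse = ", ")))
  }
  allowed <- if (type == "protein") AA_ALLOWED else NT_ALLOWED
  pat <- sprintf("[^%s]", paste(allowed, collapse = ""))
  bad <- grepl(pat, db$sequence)
  if (any(bad)) {
    abort(sprintf(
      "record %s contains symbols outside the %s alphabet (%s)",
      db$id[bad][1L], type, paste(allowed, collapse = "")
    ))
  }
  bad_prov <- !db$provenance %in%
    c("reference", "simulated_novel", "six_frame", "decoy")
  if (!is.null(db$provenance) && any(bad_prov)) {
    abort(sprintf("unknown provenance: %s", db$provenance[bad_prov][1L]))
  }
  invisible(db)
}

#' Read a FASTA file into a sequence database
#'
#' Reads protein or nucleotide FASTA via Biostrings, after light structural
#' checks so malformed input is reported with a line number. Sequences are
#' upper-cased; `*` characters (stop/translation artefacts) are stripped with a
#' warning. Header lines may carry `provenance=` and `source_tag=` key=value
#' tags (as written by [write_fasta()]); the identifier is the first
#' whitespace-delimited token.
#'
#' @param path Path to a FASTA file.
#' @inheritParams seq_db
#' @return A sequence-database tibble (see [seq_db()]).
#' @export
read_fasta <- function(path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    abort(sprintf("empty FASTA file: %s", path))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf("malformed FASTA: line %d of %s is not a header line ('>')",
                  first, path))
  }
  headers <- sub("^>", "", trimws(lines[startsWith(trimws(lines), ">")]))
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate FASTA identifiers in %s: %s",
                  path, paste(head(dup, 5L), collapse = ", ")))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warn(sprintf("stripping '*' characters from %d record(s) in %s",
                 sum(grepl("*", seqs, fixed = TRUE)), path))
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  tag_of <- function(key) {
    m <- regmatches(headers, regexpr(sprintf("%s=\\S+", key), headers))
    out <- rep(NA_character_, length(headers))
    hit <- grepl(sprintf("%s=", key), headers)
    out[hit] <- sub(sprintf("^.*%s=(\\S+).*$", key), "\\1", headers[hit])
    out
  }
  prov <- tag_of("provenance")
  prov[is.na(prov)] <- "reference"
  seq_db(ids, unname(seqs), provenance = prov, source_tag = tag_of("source_tag"),
         type = type)
}

#' Write a sequence database to FASTA
#'
#' Sequences are wrapped at 60 columns; each header is the identifier followed
#' by `provenance=` and (when present) `source_tag=` tags, so a round trip
#' through [read_fasta()] preserves the database.
#'
#' @param db A sequence-database tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  validate_seq_db(db)
  set <- Biostrings::BStringSet(db$sequence)
  tags <- paste0(db$id, " provenance=", db$provenance,
                 ifelse(is.na(db$source_tag), "",
                        paste0(" source_tag=", db$source_tag)))
  names(set) <- tags
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Total amino-acid (or nucleotide) length of a database
#'
#' @param db A sequence-database tibble.
#' @return Total number of residues across all records.
#' @export
#' @examples
#' total_aa(seq_db("p1", "MAKR"))
total_aa <- function(db) {
  sum(nchar(db$sequence))
}
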