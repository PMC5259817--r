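# Codon table (standard genetic code); codons containing N translate to X.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_codons <- function(codons, table) {
  aa <- unname(table[codons])
  aa[is.na(aa)] <- "X"   # any codon containing N (or short trailing codon)
  aa
}

# ORFs in one frame of one strand: within each stop-delimited region, from the
# first ATG to the residue before the stop. A trailing region with no in-frame
# stop is emitted too, flagged partial.
frame_orfs <- function(seq_fwd, contig, strand, frame, min_orf_aa, table) {
  s <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
  L <- nchar(s)
  n_codons <- (L - frame + 1L) %/% 3L
  if (n_codons < 1L) return(NULL)
  starts_nt <- frame + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(s, starts_nt, starts_nt + 2L)
  aa <- translate_codons(codons, table)
  stops <- which(aa == "*")
  region_start <- c(1L, stops + 1L)
  region_end <- c(stops - 1L, n_codons)
  keep <- region_end >= region_start
  region_start <- region_start[keep]
  region_end <- region_end[keep]
  partial <- c(rep(FALSE, length(stops)), TRUE)[keep]
  out <- list()
  is_atg <- codons == "ATG"
  for (r in seq_along(region_start)) {
    rs <- region_start[r]; re <- region_end[r]
    atg <- which(is_atg[rs:re])
    if (!length(atg)) next
    c0 <- rs + atg[1L] - 1L
    len <- re - c0 + 1L
    if (len < min_orf_aa) next
    nt_s <- frame + 3L * (c0 - 1L)
    nt_e <- frame + 3L * re - 1L
    # map to forward-strand coordinates (1-based, inclusive)
    if (strand == "+") {
      fs <- nt_s; fe <- nt_e
    } else {
      fs <- L - nt_e + 1L; fe <- L - nt_s + 1L
    }
    out[[length(out) + 1L]] <- tibble(
      id = sprintf("%s|%s|frame%d|%d-%d%s", contig, strand, frame, fs, fe,
                   if (partial[r]) "|partial" else ""),
      sequence = paste(aa[c0:re], collapse = ""),
      contig = contig, strand = strand, frame = frame,
      start = fs, end = fe, partial = partial[r]
    )
  }
  if (length(out)) bind_rows(out) else NULL
}

#' Six-frame translation of a genome
#'
#' Translates every maximal region starting at an ATG codon and ending at the
#' first in-frame stop codon (stop excluded), in all three frames of both
#' strands, ignoring splicing. Regions reaching the contig end without an
#' in-frame stop are emitted and flagged `partial` in the identifier. Codons
#' containing N translate to X. Coordinates in identifiers are 1-based,
#' inclusive, on the forward strand.
#'
#' @param genome A nucleotide sequence-database tibble (A/C/G/T/N only).
#' @param min_orf_aa Minimum ORF length in amino acids (default 8, matching
#'   the minimum peptide length used in digestion).
#' @return A protein sequence-database tibble with `provenance = "six_frame"`;
#'   identifiers encode contig, strand, frame and coordinates.
#' @export
#' @examples
#' six_frame_translate(seq_db("c1", "ATGAAATAA", type = "nucleotide"),
#'                     min_orf_aa = 1)
six_frame_translate <- function(genome, min_orf_aa = 8L) {
  assert_count(min_orf_aa, "min_orf_aa", min = 1L)
  validate_seq_db(genome, type = "nucleotide")
  table <- codon_table()
  res <- purrr::map2(genome$id, genome$sequence, function(contig, s) {
    frames <- expand.grid(strand = c("+", "-"), frame = 1:3,
                          stringsAsFactors = FALSE)
    bind_rows(purrr::pmap(frames, function(strand, frame) {
      frame_orfs(s, contig, strand, frame, min_orf_aa, table)
    }))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(seq_db(character(), character(), provenance = character(),
                  source_tag = character()))
  }
  seq_db(out$id, out$sequence, provenance = "six_frame",
         source_tag = paste0(out$strand, out$frame))
}
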