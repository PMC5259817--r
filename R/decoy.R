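#' Pseudo-reverse a peptide
#'
#' Reverses all residues except the last, which stays fixed so that a tryptic
#' peptide remains tryptic. Length and amino-acid composition are preserved.
#'
#' @param peptide Character vector of peptide sequences.
#' @return Character vector of pseudo-reversed peptides.
#' @export
#' @examples
#' pseudo_reverse("ACDEFK") # "FEDCAK"
pseudo_reverse <- function(peptide) {
  vapply(peptide, function(p) {
    ch <- split_chars(p)
    n <- length(ch)
    if (n <= 2L) return(p)
    paste0(paste(rev(ch[-n]), collapse = ""), ch[n])
  }, character(1), USE.NAMES = FALSE)
}

#' Pseudo-shuffle a peptide
#'
#' Uniformly permutes all residues except the last, which stays fixed. Length
#' and amino-acid composition are preserved. Consumes the current RNG stream;
#' wrap in [withr::with_seed()] (or set a seed) for reproducibility.
#'
#' @inheritParams pseudo_reverse
#' @return Character vector of pseudo-shuffled peptides.
#' @export
#' @examples
#' withr::with_seed(1, pseudo_shuffle("ACDEFK"))
pseudo_shuffle <- function(peptide) {
  vapply(peptide, function(p) {
    ch <- split_chars(p)
    n <- length(ch)
    if (n <= 2L) return(p)
    paste0(paste(sample(ch[-n]), collapse = ""), ch[n])
  }, character(1), USE.NAMES = FALSE)
}

# Transform one protein: cut into mc=0 tryptic segments, apply the peptide
# transform to each segment with its terminal residue fixed, reconcatenate.
# Vectorised over positions so whole proteomes stay fast.
transform_protein <- function(sequence, method = c("pseudo_reverse", "pseudo_shuffle")) {
  method <- match.arg(method)
  ch <- split_chars(sequence)
  n <- length(ch)
  if (n <= 1L) return(sequence)
  cuts <- cleavage_positions(ch)
  seg_end <- c(cuts, n)
  seg_start <- c(1L, cuts + 1L)
  seg_id <- rep(seq_along(seg_start), seg_end - seg_start + 1L)
  is_last <- logical(n)
  is_last[seg_end] <- TRUE
  idx <- which(!is_last)
  if (length(idx) > 1L) {
    if (method == "pseudo_reverse") {
      # position p in segment [s, e] maps to s + (e - 1) - p within [s, e-1]
      src <- seg_start[seg_id[idx]] + (seg_end[seg_id[idx]] - 1L) - idx
      ch[idx] <- ch[src]
    } else {
      # idx is sorted by segment; ordering by (segment, U) permutes uniformly
      # within each segment
      perm <- idx[order(seg_id[idx], runif(length(idx)))]
      ch[idx] <- ch[perm]
    }
  }
  paste(ch, collapse = "")
}

transform_db <- function(db, method, provenance, source_tag, id_suffix,
                         label_seed = NULL) {
  run <- function() {
    tibble(
      id = paste0(db$id, id_suffix),
      sequence = vapply(db$sequence, transform_protein, character(1),
                        method = method, USE.NAMES = FALSE),
      provenance = provenance,
      source_tag = source_tag
    )
  }
  if (is.null(label_seed)) run() else withr::with_seed(label_seed, run())
}

#' Build a peptide-level decoy database
#'
#' Each target protein is segmented at every tryptic cleavage point and each
#' segment is pseudo-reversed or pseudo-shuffled with its C-terminal residue
#' fixed, then the segments are reconcatenated in order. Each decoy record
#' therefore has the same length and residue composition as its target.
#'
#' @param db A sequence-database tibble.
#' @param method `"pseudo_reverse"` or `"pseudo_shuffle"`.
#' @param seed Integer seed used for pseudo-shuffling (ignored for reversal).
#' @return A sequence-database tibble with `provenance = "decoy"`.
#' @export
#' @examples
#' make_decoy_db(seq_db("p1", "MAKGGR"), "pseudo_reverse")
make_decoy_db <- function(db, method = c("pseudo_reverse", "pseudo_shuffle"),
                          seed = 1L) {
  method <- match.arg(method)
  validate_seq_db(db)
  transform_db(
    db, method,
    provenance = "decoy",
    source_tag = paste0("decoy_", sub("pseudo_", "", method)),
    id_suffix = "_decoy",
    label_seed = if (method == "pseudo_shuffle") {
      substream_seed(seed, "decoy", 0L)
    }
  )
}

#' Build a simulated proteogenomic target database (1TnD)
#'
#' Emulates database inflation by appending `n` reference-sized blocks of
#' simulated-novel sequence to the reference database: one pseudo-reversed copy
#' and `n - 1` independently pseudo-shuffled copies, so the result has total
#' length `(n + 1)` times the base. The added blocks play the role of the
#' spurious sequence that six-frame translation or splice-graph construction
#' adds in a real proteogenomic database.
#'
#' @param db The reference sequence-database tibble.
#' @param n Inflation factor (integer >= 0); `n = 0` returns `db` unchanged.
#' @param seed Master seed; each shuffled copy uses its own sub-stream.
#' @return A sequence-database tibble; the added records carry
#'   `provenance = "simulated_novel"` and a `source_tag` naming the copy.
#' @export
#' @examples
#' build_simulated_target(seq_db("p1", "MAKGGR"), n = 2)
build_simulated_target <- function(db, n, seed = 1L) {
  assert_count(n, "n")
  validate_seq_db(db)
  out <- list(db)
  if (n >= 1L) {
    out[[2L]] <- transform_db(db, "pseudo_reverse", "simulated_novel",
                              "sim_rev1", "_simrev1")
    for (k in seq_len(n - 1L)) {
      out[[k + 2L]] <- transform_db(
        db, "pseudo_shuffle", "simulated_novel",
        paste0("sim_shuf", k), paste0("_simshuf", k),
        label_seed = substream_seed(seed, "target_shuffle", k)
      )
    }
  }
  bind_rows(out)
}

#' Build the decoy database for a simulated proteogenomic target
#'
#' The decoy for an inflation-`n` target is `(n + 1)` independently
#' pseudo-shuffled copies of the base database, matching the target's total
#' length. The shuffle streams are disjoint from those used by
#' [build_simulated_target()].
#'
#' @inheritParams build_simulated_target
#' @return A sequence-database tibble with `provenance = "decoy"`.
#' @export
build_simulated_decoy <- function(db, n, seed = 1L) {
  assert_count(n, "n")
  validate_seq_db(db)
  out <- lapply(seq_len(n + 1L), function(k) {
    transform_db(
      db, "pseudo_shuffle", "decoy",
      paste0("decoy_shuf", k), paste0("_decshuf", k),
      label_seed = substream_seed(seed, "decoy_shuffle", k)
    )
  })
  bind_rows(out)
}
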