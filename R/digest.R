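#' Digestion parameters
#'
#' Trypsin cleaves C-terminal to lysine (K) or arginine (R) except when the
#' next residue is proline. Protein termini count as tryptic termini.
#'
#' @param max_missed_cleavages Maximum number of internal (missed) cleavage
#'   sites allowed within a peptide. Default 2.
#' @param min_length Minimum peptide length in residues. Default 8.
#' @param specificity `"full"` (both termini tryptic) or `"semi"` (at least one
#'   terminus tryptic).
#' @return A list of class `digest_params`.
#' @export
#' @examples
#' digest_params(max_missed_cleavages = 2, min_length = 8)
digest_params <- function(max_missed_cleavages = 2L, min_length = 8L,
                          specificity = c("full", "semi")) {
  specificity <- match.arg(specificity)
  assert_count(max_missed_cleavages, "max_missed_cleavages")
  if (max_missed_cleavages > 10L) abort("`max_missed_cleavages` must be <= 10")
  assert_count(min_length, "min_length", min = 1L)
  structure(
    list(
      enzyme = "trypsin",
      max_missed_cleavages = as.integer(max_missed_cleavages),
      min_length = as.integer(min_length),
      specificity = specificity
    ),
    class = "digest_params"
  )
}

# Positions i such that trypsin cleaves between i and i+1 (K/R not before P).
cleavage_positions <- function(chars) {
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% c("K", "R"))
  idx[chars[idx + 1L] != "P"]
}

digest_one <- function(sequence, params) {
  ch <- split_chars(sequence)
  n <- length(ch)
  cuts <- cleavage_positions(ch)
  bounds <- c(0L, cuts, n)            # segment boundaries (positions after which a cut occurs)
  k <- length(bounds) - 1L            # number of mc=0 segments
  mc_max <- params$max_missed_cleavages

  # fully tryptic: spans of 1..(mc_max+1) consecutive segments
  starts <- integer(0); ends <- integer(0); mcs <- integer(0)
  for (span in seq_len(min(mc_max + 1L, k))) {
    i <- seq_len(k - span + 1L)
    starts <- c(starts, bounds[i] + 1L)
    ends <- c(ends, bounds[i + span])
    mcs <- c(mcs, rep(span - 1L, length(i)))
  }
  full <- tibble(
    start = starts, end = ends, missed_cleavages = mcs,
    n_term_tryptic = TRUE, c_term_tryptic = TRUE
  )
  out <- full
  if (params$specificity == "semi") {
    boundary_set <- bounds
    semi_rows <- list()
    # N-terminally tryptic, non-tryptic C terminus
    for (i in seq_len(k)) {
      s <- bounds[i] + 1L
      emax <- bounds[min(i + mc_max + 1L, k + 1L)]
      e <- setdiff(seq.int(s, emax), boundary_set)
      if (length(e)) {
        mc <- vapply(e, function(ee) sum(cuts >= s & cuts < ee), integer(1))
        semi_rows[[length(semi_rows) + 1L]] <- tibble(
          start = s, end = e, missed_cleavages = mc,
          n_term_tryptic = TRUE, c_term_tryptic = FALSE
        )
      }
    }
    # C-terminally tryptic, non-tryptic N terminus
    for (j in seq_len(k)) {
      e <- bounds[j + 1L]
      smin <- bounds[max(j - mc_max, 1L)] + 1L
      s <- setdiff(seq.int(smin, e), boundary_set + 1L)
      if (length(s)) {
        mc <- vapply(s, function(ss) sum(cuts >= ss & cuts < e), integer(1))
        semi_rows[[length(semi_rows) + 1L]] <- tibble(
          start = s, end = e, missed_cleavages = mc,
          n_term_tryptic = FALSE, c_term_tryptic = TRUE
        )
      }
    }
    out <- bind_rows(full, semi_rows)
  }
  out <- out[out$end - out$start + 1L >= params$min_length, , drop = FALSE]
  out$sequence <- if (nrow(out)) {
    substring(sequence, out$start, out$end)
  } else {
    character(0)
  }
  out
}

#' Digest proteins into tryptic peptides
#'
#' Enumerates the tryptic peptides of each record: in `"full"` mode every
#' substring delimited by tryptic cleavage points (protein termini included)
#' spanning at most `max_missed_cleavages` internal cleavage points; in
#' `"semi"` mode additionally every substring with exactly one tryptic
#' terminus. K/R followed by P is never a cleavage point.
#'
#' @param db A sequence-database tibble (or any tibble with `id`, `sequence`).
#' @param params A [digest_params()] object.
#' @return A tibble with columns `parent_id`, `sequence`, `start`, `end`,
#'   `missed_cleavages`, `n_term_tryptic`, `c_term_tryptic`.
#' @export
#' @examples
#' digest(seq_db("p1", "MAKRGGKPLR"), digest_params(min_length = 1))
digest <- function(db, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  validate_seq_db(db)
  res <- purrr::map2(db$id, db$sequence, function(id, s) {
    d <- digest_one(s, params)
    if (nrow(d)) d$parent_id <- id
    d
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(
      parent_id = character(), sequence = character(), start = integer(),
      end = integer(), missed_cleavages = integer(),
      n_term_tryptic = logical(), c_term_tryptic = logical()
    ))
  }
  select(out, "parent_id", "sequence", "start", "end", "missed_cleavages",
         "n_term_tryptic", "c_term_tryptic")
}

#' Database size and redundancy statistics
#'
#' Reports the number of proteins, total residue length, total and unique
#' digested peptide counts under `params`, and the redundancy proportion
#' `1 - unique/total`. Peptides containing `X` (indeterminate residues) are
#' excluded from the peptide counts.
#'
#' @inheritParams digest
#' @param label Optional database label carried into the output.
#' @return A one-row tibble with columns `label`, `n_proteins`, `total_aa`,
#'   `n_total_peptides`, `n_unique_peptides`, `redundancy_proportion`.
#' @export
db_stats <- function(db, params = digest_params(), label = "db") {
  peps <- digest(db, params)
  peps <- peps[!grepl("X", peps$sequence, fixed = TRUE), , drop = FALSE]
  n_total <- nrow(peps)
  n_unique <- length(unique(peps$sequence))
  tibble(
    label = label,
    n_proteins = nrow(db),
    total_aa = total_aa(db),
    n_total_peptides = n_total,
    n_unique_peptides = n_unique,
    redundancy_proportion = if (n_total > 0L) 1 - n_unique / n_total else 0
  )
}
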