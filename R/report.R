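#' Percent change between two counts
#'
#' `(after - before) / before * 100`, rounded to two decimals. Used to report
#' e.g. how many more known peptides separate filtering accepts than pooled
#' filtering on the same search result.
#'
#' @param before Baseline count (> 0).
#' @param after New count.
#' @return Signed percent change, two decimals.
#' @export
#' @examples
#' percent_change(4115, 6336) # +53.97
percent_change <- function(before, after) {
  if (any(before <= 0)) abort("`before` must be > 0: percent change undefined")
  round((after - before) / before * 100, 2)
}

#' Decrease rate between a small-n and a large-n count
#'
#' `(count_small_n - count_large_n) / count_small_n * 100`, rounded to two
#' decimals: the relative loss of identified peptides as the database grows.
#'
#' @param count_small_n Count at the smaller inflation factor (> 0).
#' @param count_large_n Count at the larger inflation factor.
#' @return Percent decrease, two decimals.
#' @export
#' @examples
#' decrease_rate(3759, 3434) # 8.65
decrease_rate <- function(count_small_n, count_large_n) {
  if (any(count_small_n <= 0)) abort("zero baseline: decrease rate undefined")
  round((count_small_n - count_large_n) / count_small_n * 100, 2)
}

#' Relative size difference between simulated and real databases
#'
#' `|real - sim| / real * 100`, rounded to two decimals; the denominator is the
#' real proteogenomic database size.
#'
#' @param sim_total_aa Simulated proteogenomic database size (AA).
#' @param real_total_aa Real proteogenomic database size (AA, > 0).
#' @return Percent size difference, two decimals.
#' @export
#' @examples
#' size_difference(9186837, 9654965) # 4.85
size_difference <- function(sim_total_aa, real_total_aa) {
  if (any(real_total_aa <= 0)) abort("`real_total_aa` must be > 0")
  round(abs(real_total_aa - sim_total_aa) / real_total_aa * 100, 2)
}

#' Overlap of accepted peptide sets across methods
#'
#' Computes every Venn region for the peptide sets accepted by different
#' validation methods (typically the novel peptides of SepTD, SepBP, SepMB),
#' plus pairwise intersection counts and the proportion of the union that all
#' methods identify in common.
#'
#' @param accepted_sets Named list of character vectors of peptide sequences.
#' @return A list with `regions` (one row per membership pattern with its
#'   count), `pairwise` (intersection size per method pair), `n_common`,
#'   `n_union`, and `prop_common_pct` (percentage of the union identified by
#'   all methods).
#' @export
#' @examples
#' overlap_report(list(a = c("P1", "P2"), b = c("P2", "P3"), c = "P2"))
overlap_report <- function(accepted_sets) {
  stopifnot(is.list(accepted_sets), length(accepted_sets) >= 1L)
  if (is.null(names(accepted_sets)) || any(!nzchar(names(accepted_sets)))) {
    abort("`accepted_sets` must be a named list")
  }
  sets <- lapply(accepted_sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 0L) {
    memb <- matrix(logical(0), 0, length(sets),
                   dimnames = list(NULL, names(sets)))
  }
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe))
  colnames(memb) <- names(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                   drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(memb, 1L, function(row) all(row == as.logical(p))))
  })
  regions <- as_tibble(patterns)
  regions$count <- as.integer(counts)
  pairs <- if (length(sets) >= 2L) utils::combn(names(sets), 2L) else NULL
  pairwise <- if (!is.null(pairs)) {
    tibble(
      set1 = pairs[1L, ], set2 = pairs[2L, ],
      n_intersect = apply(pairs, 2L, function(p) {
        length(intersect(sets[[p[1L]]], sets[[p[2L]]]))
      })
    )
  } else {
    tibble(set1 = character(), set2 = character(), n_intersect = integer())
  }
  n_common <- length(Reduce(intersect, sets))
  n_union <- length(universe)
  list(
    regions = regions,
    pairwise = pairwise,
    n_common = n_common,
    n_union = n_union,
    prop_common_pct = if (n_union > 0L) round(n_common / n_union * 100, 2) else 0
  )
}
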