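#' Target-decoy FDR estimate
#'
#' The number of decoy hits over the number of target hits above a score
#' threshold, `N_D / N_T`; defined as 0 when there are no target hits.
#'
#' @param n_decoy,n_target Non-negative counts (vectorised).
#' @return Numeric vector of FDR estimates.
#' @export
#' @examples
#' td_fdr(1, 100)
td_fdr <- function(n_decoy, n_target) {
  if (any(n_decoy < 0) || any(n_target < 0)) {
    abort("counts must be non-negative")
  }
  ifelse(n_target == 0, 0, n_decoy / n_target)
}

#' Collapse PSMs to peptide level
#'
#' Keeps, for each distinct peptide, the single record maximising the ranking
#' field; ties are broken by lexicographic spectrum identifier. Peptide-level
#' FDR is then computed on the collapsed records.
#'
#' @param psms A tibble of PSM records with `peptide_id` and `spectrum_id`.
#' @param key Name of the ranking column (default `"score"`).
#' @return A tibble with one row per distinct peptide.
#' @export
peptide_collapse <- function(psms, key = "score") {
  if (!key %in% names(psms)) abort(sprintf("ranking field `%s` missing", key))
  psms |>
    arrange(desc(.data[[key]]), .data$spectrum_id) |>
    distinct(.data$peptide_id, .keep_all = TRUE)
}

#' Filter records at a target FDR by the target-decoy estimator
#'
#' Scans every observed value of the ranking field as a threshold `t` (accept
#' if value >= t), estimates FDR as `N_D / N_T`, converts the estimates to
#' q-values by taking the cumulative minimum from the most permissive to the
#' strictest threshold, and accepts all target records with q-value <= `alpha`.
#'
#' @param records A tibble with an `is_decoy` column and the ranking field.
#' @param alpha Target FDR level in (0, 1).
#' @param key Name of the ranking column (default `"score"`).
#' @param method,group Labels stored on the outcome (bookkeeping only).
#' @return A `filter_outcome`: a list with the selected `threshold`, counts
#'   `n_target` and `n_decoy` at the threshold, the q-value at the threshold
#'   (`fdr_est`), the `accepted` target records (decoys excluded), and — when
#'   the records carry ground truth — the empirical FDR `fdr_emp`.
#' @export
#' @examples
#' rec <- tibble::tibble(score = c(10, 9, 8, 7, 6),
#'                       is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE))
#' filter_at_fdr(rec, alpha = 0.01)
filter_at_fdr <- function(records, alpha, key = "score",
                          method = "TD", group = "pooled") {
  assert_fraction(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (nrow(records) == 0L) {
    return(new_filter_outcome(method, group, alpha, threshold = Inf,
                              n_target = 0L, n_decoy = 0L, fdr_est = 0,
                              accepted = records, fdr_emp = NA_real_))
  }
  if (!"is_decoy" %in% names(records)) abort("`is_decoy` column required")
  v <- records[[key]]
  ord <- order(v, decreasing = TRUE)
  vs <- v[ord]
  dec <- records$is_decoy[ord]
  # cumulative counts at each distinct threshold (accept iff value >= t)
  last_of_t <- !duplicated(vs, fromLast = TRUE)   # last row of each tie block
  n_t <- cumsum(!dec)[last_of_t]
  n_d <- cumsum(dec)[last_of_t]
  thresholds <- vs[last_of_t]
  fdr <- td_fdr(n_d, n_t)
  q <- rev(cummin(rev(fdr)))
  ok <- which(q <= alpha)
  if (length(ok) == 0L) {
    return(new_filter_outcome(method, group, alpha, threshold = Inf,
                              n_target = 0L, n_decoy = 0L, fdr_est = 0,
                              accepted = records[0, , drop = FALSE],
                              fdr_emp = NA_real_))
  }
  sel <- max(ok)                       # most permissive threshold with q <= alpha
  t_star <- thresholds[sel]
  accepted <- records[!records$is_decoy & v >= t_star, , drop = FALSE]
  fdr_emp <- if ("is_correct" %in% names(records)) {
    empirical_fdr(accepted)
  } else NA_real_
  new_filter_outcome(method, group, alpha, threshold = t_star,
                     n_target = n_t[sel], n_decoy = n_d[sel],
                     fdr_est = q[sel], accepted = accepted, fdr_emp = fdr_emp)
}

new_filter_outcome <- function(method, group, alpha, threshold, n_target,
                               n_decoy, fdr_est, accepted, fdr_emp) {
  structure(list(
    method = method, group = group, alpha = alpha,
    threshold = threshold,
    n_target = as.integer(n_target), n_decoy = as.integer(n_decoy),
    fdr_est = fdr_est, fdr_emp = fdr_emp,
    n_accepted = nrow(accepted),
    accepted = accepted
  ), class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat(sprintf(
    "<filter_outcome> %s/%s: %d accepted at alpha=%g (t=%.4g, N_T=%d, N_D=%d, est FDR=%.4g%s)\n",
    x$method, x$group, x$n_accepted, x$alpha, x$threshold, x$n_target,
    x$n_decoy, x$fdr_est,
    if (!is.na(x$fdr_emp)) sprintf(", emp FDR=%.4g", x$fdr_emp) else ""
  ))
  invisible(x)
}

#' @rdname filter_at_fdr
#' @param x A `filter_outcome`.
#' @param ... Unused.
#' @export
glance.filter_outcome <- function(x, ...) {
  tibble(
    method = x$method, group = x$group, alpha = x$alpha,
    threshold = x$threshold, n_target = x$n_target, n_decoy = x$n_decoy,
    fdr_est = x$fdr_est, fdr_emp = x$fdr_emp, n_accepted = x$n_accepted
  )
}

#' Mixture-model FDR above a threshold
#'
#' The mean posterior error probability of the records above the threshold:
#' `sum(PEP_i) / #\{S_i >= t\}`.
#'
#' @param peps Posterior error probabilities (in `[0, 1]`) of the records with
#'   score at or above the threshold.
#' @return The estimated FDR.
#' @export
#' @examples
#' mb_fdr(c(0.2, 0.0))
mb_fdr <- function(peps) {
  if (length(peps) == 0L) abort("no records above threshold: FDR undefined")
  if (any(peps < 0 | peps > 1)) abort("PEPs must lie in [0, 1]")
  mean(peps)
}
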