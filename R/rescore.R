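#' Configuration for the boosted rescorer
#'
#' @param n_boost_rounds Number of boosting rounds (re-drawn positive
#'   labelings). Default 5.
#' @param n_folds Cross-validation folds (>= 2). Default 3.
#' @param init_fdr FDR level used to pick positive training examples.
#' @param positive_frac Fraction of the positive set re-drawn each round after
#'   the first (the perturbed labeling that reduces sensitivity to the initial
#'   ranking).
#' @param seed Integer seed.
#' @return A list of class `bp_config`.
#' @export
bp_config <- function(n_boost_rounds = 5L, n_folds = 3L, init_fdr = 0.01,
                      positive_frac = 0.8, seed = 1L) {
  assert_count(n_boost_rounds, "n_boost_rounds", min = 1L)
  assert_count(n_folds, "n_folds", min = 2L)
  assert_fraction(init_fdr, "init_fdr")
  if (init_fdr <= 0 || init_fdr >= 1) abort("`init_fdr` must be in (0, 1)")
  assert_fraction(positive_frac, "positive_frac")
  structure(list(n_boost_rounds = as.integer(n_boost_rounds),
                 n_folds = as.integer(n_folds), init_fdr = init_fdr,
                 positive_frac = positive_frac, seed = as.integer(seed)),
            class = "bp_config")
}

bp_features <- c("score", "delta_next", "mass_error_like")

# Fisher linear discriminant: w = pooled-Sigma^{-1} (mu1 - mu0), oriented so
# positives score higher. Stable under class separation, unlike unregularised
# logistic regression. Returns held-out projections (or `fallback` if the
# training matrix is degenerate).
train_linear_discriminant <- function(Xtr, y, Xte, fallback) {
  keep <- apply(Xtr, 2L, function(col) stats::sd(col) > 1e-8)
  if (!any(keep)) return(fallback)
  Xtr <- Xtr[, keep, drop = FALSE]
  Xte <- Xte[, keep, drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(MASS::lda(x = Xtr, grouping = factor(y))),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fallback)
  w <- fit$scaling[, 1L]
  proj_tr <- drop(Xtr %*% w)
  if (mean(proj_tr[y == 1]) < mean(proj_tr[y == 0])) w <- -w
  drop(Xte %*% w)
}

#' Semi-supervised boosted rescoring of PSMs (BP)
#'
#' A Percolator-style rescorer: per boosting round and cross-validation fold, a
#' linear discriminant is trained on positives (target PSMs accepted at
#' `init_fdr` under the current ranking — the raw score in round one, a
#' perturbed re-drawn positive labeling in later rounds) versus negatives
#' (decoy PSMs), using the features `score`, `delta_next` and
#' `mass_error_like` (plus `|mass_error_like|`, since the informative signal is
#' the error magnitude). Each PSM's rescored value is the average of its
#' held-out discriminant score across rounds. Deterministic under `cfg$seed`.
#'
#' If there are no decoys or no positives at `init_fdr`, the raw score is
#' returned unchanged with a warning.
#'
#' @param psms A tibble of PSM records carrying the feature columns,
#'   `is_decoy` and `spectrum_id`.
#' @param cfg A [bp_config()].
#' @return `psms` with an added `rescored` column (rows in original order).
#' @export
boosted_rescore <- function(psms, cfg = bp_config()) {
  stopifnot(inherits(cfg, "bp_config"))
  missing_f <- setdiff(bp_features, names(psms))
  if (length(missing_f)) {
    abort(sprintf("missing feature column(s): %s",
                  paste(missing_f, collapse = ", ")))
  }
  n <- nrow(psms)
  fallback <- function(msg) {
    warn(paste0("boosted_rescore: ", msg, "; falling back to raw score"))
    out <- psms
    out$rescored <- psms$score
    out
  }
  if (!any(psms$is_decoy)) return(fallback("no decoy PSMs"))
  init_pos <- filter_at_fdr(psms, cfg$init_fdr, key = "score")
  if (init_pos$n_accepted == 0L) {
    return(fallback(sprintf("no positives at init_fdr=%g", cfg$init_fdr)))
  }

  X <- cbind(
    scale(psms$score),
    scale(psms$delta_next),
    scale(psms$mass_error_like),
    scale(abs(psms$mass_error_like))
  )
  X[is.nan(X)] <- 0   # constant feature columns
  colnames(X) <- c("f_score", "f_delta", "f_merr", "f_amerr")
  df <- as.data.frame(X)

  pos_key <- function(ranking) {
    tmp <- psms
    tmp$.rank <- ranking
    out <- filter_at_fdr(tmp, cfg$init_fdr, key = ".rank")
    psms$spectrum_id %in% out$accepted$spectrum_id
  }

  rescored <- withr::with_seed(substream_seed(cfg$seed, "bp"), {
    folds <- sample(rep_len(seq_len(cfg$n_folds), n))
    total <- numeric(n)
    n_rounds_used <- 0L
    current_ranking <- psms$score
    for (r in seq_len(cfg$n_boost_rounds)) {
      positive <- pos_key(current_ranking)
      if (r > 1L) {
        # perturbed labeling: keep a random subset of the current positives
        pos_idx <- which(positive)
        keep <- sample(pos_idx, max(1L, round(cfg$positive_frac *
                                                length(pos_idx))))
        positive <- logical(n)
        positive[keep] <- TRUE
      }
      if (!any(positive)) next
      round_score <- rep(NA_real_, n)
      for (k in seq_len(cfg$n_folds)) {
        test <- folds == k
        train <- !test & (positive | psms$is_decoy)
        if (sum(positive[!test]) == 0L || sum(psms$is_decoy[!test]) == 0L) {
          round_score[test] <- psms$score[test]
          next
        }
        y <- as.integer(positive[train])
        round_score[test] <- train_linear_discriminant(
          X[train, , drop = FALSE], y, X[test, , drop = FALSE],
          fallback = psms$score[test]
        )
      }
      total <- total + round_score
      n_rounds_used <- n_rounds_used + 1L
      current_ranking <- total / n_rounds_used
    }
    if (n_rounds_used == 0L) NULL else total / n_rounds_used
  })
  if (is.null(rescored)) return(fallback("no usable boosting round"))
  out <- psms
  out$rescored <- rescored
  out
}
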