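#' Separate (class-specific) filtering of known and novel peptides
#'
#' Implements the SepTD / SepBP / SepMB procedures: any learning step (boosted
#' rescoring, mixture fitting) runs once on the pooled PSMs — a separate model
#' cannot be trained on the novel class alone — then the records are
#' partitioned by group (known vs novel; decoy PSMs carry the group of the
#' decoy block they were drawn from) and each group is filtered independently
#' with the target-decoy estimator `N_D / N_T` on the method's ranking field:
#' the raw score (SepTD), the rescored value (SepBP), or `1 - PEP` (SepMB).
#'
#' PSMs are collapsed to peptide level on the ranking field before filtering.
#'
#' @param psms A tibble of PSM records with `group` (`"known"`/`"novel"`),
#'   `is_decoy`, `score`, `peptide_id`, `spectrum_id`.
#' @param alpha Target FDR level per group.
#' @param method `"TD"`, `"BP"` or `"MB"`.
#' @param bp_cfg A [bp_config()] (BP only).
#' @param fit_on Scores used for the mixture fit (MB only); see [mb_filter()].
#' @param collapse Collapse to peptide level before filtering? Default `TRUE`.
#' @return A list with elements `known` and `novel`, each a `filter_outcome`.
#' @export
separate_filter <- function(psms, alpha, method = c("TD", "BP", "MB"),
                            bp_cfg = bp_config(),
                            fit_on = c("targets", "pooled"),
                            collapse = TRUE) {
  method <- match.arg(method)
  fit_on <- match.arg(fit_on)
  stopifnot(all(c("group", "is_decoy") %in% names(psms)))
  bad <- !psms$group %in% c("known", "novel")
  if (any(bad)) abort("every PSM must carry group 'known' or 'novel'")

  key <- switch(method, TD = "score", BP = "rescored", MB = "one_minus_pep")
  scored <- switch(
    method,
    TD = psms,
    BP = boosted_rescore(psms, bp_cfg),
    MB = {
      train <- if (fit_on == "targets") psms$score[!psms$is_decoy] else psms$score
      fit <- fit_mixture_em(train)
      mutate(psms, one_minus_pep = 1 - compute_pep(fit, .data$score))
    }
  )
  if (collapse) scored <- peptide_collapse(scored, key = key)

  out <- lapply(c("known", "novel"), function(g) {
    grp <- scored[scored$group == g, , drop = FALSE]
    if (nrow(grp) > 0L && !any(grp$is_decoy)) {
      inform(sprintf(
        "separate_filter: group '%s' has no decoy records; N_D = 0 at every threshold",
        g))
    }
    filter_at_fdr(grp, alpha, key = key,
                  method = paste0("Sep", method), group = g)
  })
  names(out) <- c("known", "novel")
  out
}

#' Two-stage FDR filtering
#'
#' Stage 1 filters the reference-only search at `alpha`; spectra not accepted
#' at stage 1 are re-searched against the full proteogenomic database (the
#' `stage2_provider` callable supplies their PSMs) and the stage-2 result is
#' filtered at `alpha` by `N_D / N_T`. Stage 1 reports known peptides, stage 2
#' novel ones. Spectra accepted at stage 1 never appear in stage 2 (any such
#' PSM returned by the provider is dropped with a warning).
#'
#' @param stage1_psms PSMs from the reference-only search.
#' @param stage2_provider Function taking a character vector of residual
#'   spectrum identifiers and returning their PSMs against the proteogenomic
#'   database.
#' @param alpha Target FDR level per stage.
#' @param key Ranking column (default `"score"`).
#' @param collapse Collapse to peptide level before filtering? Default `TRUE`.
#' @return A list with elements `stage1` and `stage2`, each a `filter_outcome`.
#' @export
two_stage_filter <- function(stage1_psms, stage2_provider, alpha,
                             key = "score", collapse = TRUE) {
  stopifnot(is.function(stage2_provider))
  s1 <- stage1_psms
  if (collapse) s1 <- peptide_collapse(s1, key = key)
  out1 <- filter_at_fdr(s1, alpha, key = key,
                        method = "TwoStage", group = "stage1")
  accepted_spectra <- unique(out1$accepted$spectrum_id)
  # a spectrum is consumed if its best target match scored at or above the
  # stage-1 threshold and mapped to an accepted peptide
  residual <- setdiff(unique(stage1_psms$spectrum_id), accepted_spectra)
  if (length(residual) == 0L) {
    empty <- stage1_psms[0, , drop = FALSE]
    return(list(stage1 = out1,
                stage2 = filter_at_fdr(empty, alpha, key = key,
                                       method = "TwoStage", group = "stage2")))
  }
  s2 <- stage2_provider(residual)
  leak <- s2$spectrum_id %in% accepted_spectra
  if (any(leak)) {
    warn(sprintf("two_stage_filter: dropping %d stage-2 PSM(s) for spectra already accepted at stage 1",
                 sum(leak)))
    s2 <- s2[!leak, , drop = FALSE]
  }
  if (collapse && nrow(s2) > 0L) s2 <- peptide_collapse(s2, key = key)
  out2 <- filter_at_fdr(s2, alpha, key = key,
                        method = "TwoStage", group = "stage2")
  list(stage1 = out1, stage2 = out2)
}
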