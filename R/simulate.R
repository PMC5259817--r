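#' The Gumbel (extreme-value, maximum) distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the Gumbel distribution with location `mu` and scale `beta`, the
#' extreme-value law used to model the best random match score in a database
#' search: `F(x) = exp(-exp(-(x - mu)/beta))`.
#'
#' @param x,q,p Numeric vectors.
#' @param n Number of draws.
#' @param mu Location parameter.
#' @param beta Scale parameter (> 0).
#' @param log Return log density?
#' @return Numeric vector.
#' @name gumbel
NULL

#' @rdname gumbel
#' @export
dgumbel <- function(x, mu = 0, beta = 1, log = FALSE) {
  stopifnot(all(beta > 0))
  z <- (x - mu) / beta
  ld <- -z - exp(-z) - base::log(beta)
  if (log) ld else exp(ld)
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, mu = 0, beta = 1) {
  stopifnot(all(beta > 0))
  exp(-exp(-(q - mu) / beta))
}

#' @rdname gumbel
#' @export
qgumbel <- function(p, mu = 0, beta = 1) {
  stopifnot(all(beta > 0), all(p >= 0 & p <= 1))
  mu - beta * base::log(-base::log(p))
}

#' @rdname gumbel
#' @export
rgumbel <- function(n, mu = 0, beta = 1) {
  qgumbel(runif(n), mu, beta)
}

#' Distribution of the maximum of m Gumbel scores
#'
#' If each of `m` independent candidate scores is Gumbel(`mu0`, `beta`), their
#' maximum is Gumbel(`mu0 + beta * log(m)`, `beta`). This is the mechanism by
#' which a larger search space raises the best random-match score: location
#' grows logarithmically with the number of candidates.
#'
#' @param mu0 Per-candidate location.
#' @param beta Per-candidate (and maximum) scale, > 0.
#' @param m Number of candidates, integer >= 1.
#' @return A list with elements `mu` and `beta`.
#' @export
#' @examples
#' max_gumbel_params(0, 1, 50)
max_gumbel_params <- function(mu0, beta, m) {
  stopifnot(is.numeric(beta), all(beta > 0))
  if (!is.numeric(m) || any(m < 1)) abort("`m` must be an integer >= 1")
  list(mu = mu0 + beta * base::log(m), beta = beta)
}

#' Simulation configuration
#'
#' Describes a simulated database search: per spectrum, a correct candidate
#' (when the spectrum's true peptide is in the database) scores
#' Normal(`gaussian_mu`, `gaussian_sigma`); each database partition (known
#' targets, novel targets, decoys) contributes its best random score, the
#' maximum of `m_*` Gumbel(`gumbel_mu0`, `gumbel_beta`) draws. The reported PSM
#' is the overall maximum.
#'
#' Defaults emulate a yeast-scale search: `m_known = 688452` unique
#' fully-tryptic reference peptides, 20,000 spectra per charge stratum, 40% of
#' spectra identifiable, 1% of correct identifications novel, and score
#' parameters placing correct matches well above, but overlapping, the random
#' background (see the package vignette).
#'
#' @param n_spectra Spectra per charge stratum.
#' @param p_correct Fraction of spectra whose true peptide is in the database.
#' @param p_novel_true Fraction of correct identifications whose peptide lies
#'   in the novel partition.
#' @param gaussian_mu,gaussian_sigma Correct-score parameters (per stratum;
#'   scalars are recycled across strata).
#' @param gumbel_mu0,gumbel_beta Per-candidate incorrect-score parameters.
#' @param m_known,m_novel,m_decoy Searchable candidate counts per partition.
#' @param decoy_known_frac Probability that a winning decoy PSM is attributed
#'   to the known group (by default `m_known / m_decoy`, i.e. one decoy copy
#'   per reference block).
#' @param peptide_pool_frac Distinct true peptides as a fraction of expected
#'   correct spectra (peptide-level collapse granularity).
#' @param charge_strata Labels of independently simulated charge strata.
#' @param seed Master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_spectra = 20000L,
                       p_correct = 0.4,
                       p_novel_true = 0.01,
                       gaussian_mu = 25,
                       gaussian_sigma = 3,
                       gumbel_mu0 = 0,
                       gumbel_beta = 1,
                       m_known = 688452L,
                       m_novel = 0L,
                       m_decoy = 688452L,
                       decoy_known_frac = NULL,
                       peptide_pool_frac = 0.6,
                       charge_strata = c("2+", "3+"),
                       seed = 1L) {
  assert_count(n_spectra, "n_spectra", min = 1L)
  assert_fraction(p_correct, "p_correct")
  assert_fraction(p_novel_true, "p_novel_true")
  stopifnot(all(gaussian_sigma > 0), all(gumbel_beta > 0))
  assert_count(m_known, "m_known", min = 1L)
  assert_count(m_novel, "m_novel")
  assert_count(m_decoy, "m_decoy")
  if (m_known + m_novel + m_decoy == 0L) abort("all partitions empty")
  if (is.null(decoy_known_frac)) {
    decoy_known_frac <- if (m_decoy > 0L) min(1, m_known / m_decoy) else 1
  }
  assert_fraction(decoy_known_frac, "decoy_known_frac")
  ns <- length(charge_strata)
  structure(list(
    n_spectra = as.integer(n_spectra),
    p_correct = p_correct,
    p_novel_true = p_novel_true,
    gaussian_mu = rep_len(gaussian_mu, ns),
    gaussian_sigma = rep_len(gaussian_sigma, ns),
    gumbel_mu0 = rep_len(gumbel_mu0, ns),
    gumbel_beta = rep_len(gumbel_beta, ns),
    m_known = as.integer(m_known),
    m_novel = as.integer(m_novel),
    m_decoy = as.integer(m_decoy),
    decoy_known_frac = decoy_known_frac,
    peptide_pool_frac = peptide_pool_frac,
    charge_strata = as.character(charge_strata),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Ground truth for one stratum: which spectra have their true peptide in the
# database, in which partition, and what its (spectrum-specific) correct score
# is. Fixed once per replicate so staged searches see consistent truth.
sim_truth <- function(config, stratum_index = 1L) {
  n <- config$n_spectra
  stratum <- config$charge_strata[stratum_index]
  is_correct <- runif(n) < config$p_correct
  group_true <- ifelse(is_correct & runif(n) < config$p_novel_true,
                       "novel", "known")
  pool_known <- max(1L, round(config$peptide_pool_frac * n * config$p_correct))
  pool_novel <- max(1L, round(config$peptide_pool_frac * n * config$p_correct *
                                config$p_novel_true))
  pep <- ifelse(
    group_true == "novel",
    sprintf("novel_pep_%s_%d", stratum, sample.int(pool_novel, n, replace = TRUE)),
    sprintf("known_pep_%s_%d", stratum, sample.int(pool_known, n, replace = TRUE))
  )
  tibble(
    spectrum_id = sprintf("sp_%s_%06d", stratum, seq_len(n)),
    charge = stratum,
    is_correct_avail = is_correct,
    group_true = group_true,
    correct_peptide = pep,
    correct_score = rnorm(n, config$gaussian_mu[stratum_index],
                          config$gaussian_sigma[stratum_index])
  )
}

# Competition stage: draw each partition's best random score and report the
# overall best match per spectrum. `m_*` may differ from the config (staged
# searches); a correct novel candidate is only available when the novel
# partition is searched.
sim_compete <- function(truth, config, stratum_index = 1L,
                        m_known = config$m_known,
                        m_novel = config$m_novel,
                        m_decoy = config$m_decoy,
                        decoy_known_frac = NULL) {
  n <- nrow(truth)
  if (m_known + m_novel + m_decoy == 0L) abort("all partitions empty")
  if (is.null(decoy_known_frac)) {
    decoy_known_frac <- if (m_decoy > 0) min(1, m_known / m_decoy) else 1
  }
  mu0 <- config$gumbel_mu0[stratum_index]
  beta <- config$gumbel_beta[stratum_index]
  stratum <- truth$charge[1L]

  correct_avail <- truth$is_correct_avail &
    (truth$group_true == "known" | m_novel > 0L)
  cand <- cbind(
    correct = ifelse(correct_avail, truth$correct_score, -Inf),
    known = if (m_known > 0L) {
      rgumbel(n, max_gumbel_params(mu0, beta, m_known)$mu, beta)
    } else rep(-Inf, n),
    novel = if (m_novel > 0L) {
      rgumbel(n, max_gumbel_params(mu0, beta, m_novel)$mu, beta)
    } else rep(-Inf, n),
    decoy = if (m_decoy > 0L) {
      rgumbel(n, max_gumbel_params(mu0, beta, m_decoy)$mu, beta)
    } else rep(-Inf, n)
  )
  winner <- max.col(cand, ties.method = "first")
  score <- cand[cbind(seq_len(n), winner)]
  runner <- apply(cand, 1L, function(r) sort(r, decreasing = TRUE)[2L])
  delta_next <- ifelse(is.finite(runner), score - runner, 0)

  kind <- colnames(cand)[winner]
  is_correct <- kind == "correct"
  is_decoy <- kind == "decoy"
  group <- character(n)
  group[is_correct] <- truth$group_true[is_correct]
  group[kind == "known"] <- "known"
  group[kind == "novel"] <- "novel"
  if (any(is_decoy)) {
    group[is_decoy] <- ifelse(runif(sum(is_decoy)) < decoy_known_frac,
                              "known", "novel")
  }
  peptide_id <- character(n)
  peptide_id[is_correct] <- truth$correct_peptide[is_correct]
  for (part in c("known", "novel", "decoy")) {
    sel <- kind == part
    if (any(sel)) {
      m <- switch(part, known = m_known, novel = m_novel, decoy = m_decoy)
      peptide_id[sel] <- sprintf("%s_rand_%s_%d", part, stratum,
                                 sample.int(m, sum(sel), replace = TRUE))
    }
  }
  mass_error_like <- ifelse(is_correct, rnorm(n, 0, 0.05), runif(n, -2.5, 2.5))
  tibble(
    spectrum_id = truth$spectrum_id,
    peptide_id = peptide_id,
    score = score,
    delta_next = delta_next,
    mass_error_like = mass_error_like,
    group = group,
    is_decoy = is_decoy,
    is_correct = is_correct,
    charge = truth$charge
  )
}

#' Simulate a database search
#'
#' Generates one best-match PSM per spectrum with known ground truth, per
#' charge stratum, under the generative model described in [sim_config()]. The
#' winning provenance (known target, novel target, or decoy), the correctness
#' flag, and three features (score, margin over the runner-up, and a
#' mass-error-like feature that is tight for correct and diffuse for incorrect
#' matches) are recorded. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_result`: `psms` (tibble of PSM records, one row
#'   per spectrum), `config`, and `partition_sizes`.
#' @export
#' @examples
#' res <- simulate_search(sim_config(n_spectra = 500, charge_strata = "2+"))
#' head(res$psms)
simulate_search <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  psms <- bind_rows(lapply(seq_along(config$charge_strata), function(si) {
    withr::with_seed(
      substream_seed(config$seed, "simulate", si),
      sim_compete(sim_truth(config, si), config, si,
                  decoy_known_frac = config$decoy_known_frac)
    )
  }))
  structure(list(
    psms = psms,
    config = config,
    partition_sizes = c(m_known = config$m_known, m_novel = config$m_novel,
                        m_decoy = config$m_decoy)
  ), class = "sim_result")
}

#' Empirical FDR of an accepted set
#'
#' The ground-truth counterpart of an estimated FDR: the fraction of accepted
#' target records that are incorrect. Decoy records are excluded from both
#' numerator and denominator; returns 0 when no targets are accepted.
#'
#' @param accepted A tibble of PSM or peptide records with `is_decoy` and
#'   `is_correct` columns.
#' @return A fraction in `[0, 1]`.
#' @export
empirical_fdr <- function(accepted) {
  stopifnot(all(c("is_decoy", "is_correct") %in% names(accepted)))
  tgt <- accepted[!accepted$is_decoy, , drop = FALSE]
  if (nrow(tgt) == 0L) return(0)
  mean(!tgt$is_correct)
}
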