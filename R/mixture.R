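# Weighted Gumbel maximum-likelihood M-step. Given weights w and data x, the
# MLE satisfies  beta = wmean(x) - S1(beta)/S0(beta)  with
# S_k(beta) = sum(w * x^k * exp(-x/beta)); computed on shifted x for stability.
gumbel_mle_weighted <- function(x, w, beta_init = 1) {
  xmin <- min(x)
  xs <- x - xmin
  wsum <- sum(w)
  wmean <- sum(w * x) / wsum
  g <- function(beta) {
    u <- exp(-xs / beta)
    s0 <- sum(w * u)
    if (!is.finite(s0) || s0 <= 0) return(beta - wmean + xmin)
    val <- beta - wmean + sum(w * x * u) / s0
    if (!is.finite(val)) beta else val
  }
  # bracket the root: g(beta) -> beta - wmean + max-weighted mean < 0 for small
  # beta only if data spread; expand until sign change
  lo <- 1e-3
  hi <- max(1, 2 * beta_init)
  span <- diff(range(x))
  hi <- max(hi, span)
  glo <- g(lo)
  ghi <- g(hi)
  tries <- 0L
  while (glo * ghi > 0 && tries < 30L) {
    if (ghi < 0) hi <- hi * 2 else lo <- lo / 2
    glo <- g(lo)
    ghi <- g(hi)
    tries <- tries + 1L
  }
  if (glo * ghi > 0) {
    return(list(mu = NA_real_, beta = NA_real_, ok = FALSE))
  }
  beta <- uniroot(g, c(lo, hi), tol = 1e-8)$root
  u <- exp(-xs / beta)
  mu <- xmin - beta * base::log(sum(w * u) / wsum)
  list(mu = mu, beta = beta, ok = TRUE)
}

#' Fit a two-component Gumbel + Gaussian score mixture by EM
#'
#' Models the distribution of best-match scores as
#' `pi0 * Gumbel(gumbel_mu, gumbel_beta) + pi1 * Normal(normal_mu,
#' normal_sigma)`: the Gumbel component captures incorrect matches (the maximum
#' of many random candidate scores) and the Gaussian component correct matches.
#' The E-step computes responsibilities; the M-step uses closed-form weighted
#' Gaussian moments and weighted Gumbel maximum likelihood (one-dimensional
#' root finding for the scale). The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param scores Numeric vector of at least 50 scores.
#' @param init Optional `mixture_fit` (or list with the same parameter names)
#'   used as the starting point.
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the log-likelihood improves by less than `tol`.
#' @return A `mixture_fit` object: mixing weights `pi0`/`pi1`, component
#'   parameters, `loglik`, the per-iteration `loglik_trace`, `n_iter` and a
#'   `converged` flag (degenerate fits are flagged non-converged).
#' @export
#' @examples
#' s <- c(rgumbel(500, 0, 1), rnorm(300, 5, 1))
#' fit <- fit_mixture_em(s)
#' glance(fit)
fit_mixture_em <- function(scores, init = NULL, max_iter = 200L, tol = 1e-6) {
  if (length(scores) < 50L) abort("need at least 50 scores to fit the mixture")
  if (tol <= 0) abort("`tol` must be > 0")
  x <- as.numeric(scores)
  n <- length(x)

  if (is.null(init)) {
    med <- stats::median(x)
    lo <- x[x <= med]
    hi <- x[x > med]
    beta0 <- max(sd(lo) * sqrt(6) / pi, 1e-2)
    par <- list(
      pi1 = 0.5,
      gumbel_mu = mean(lo) - 0.5772156649 * beta0,
      gumbel_beta = beta0,
      normal_mu = mean(hi),
      normal_sigma = max(sd(hi), 1e-2)
    )
  } else {
    par <- list(pi1 = init$pi1, gumbel_mu = init$gumbel_mu,
                gumbel_beta = init$gumbel_beta, normal_mu = init$normal_mu,
                normal_sigma = init$normal_sigma)
  }

  loglik_trace <- numeric(0)
  converged <- FALSE
  degenerate <- FALSE
  ll_old <- -Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    f0 <- dgumbel(x, par$gumbel_mu, par$gumbel_beta)
    f1 <- dnorm(x, par$normal_mu, par$normal_sigma)
    mix <- (1 - par$pi1) * f0 + par$pi1 * f1
    mix <- pmax(mix, .Machine$double.xmin)
    ll <- sum(base::log(mix))
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r1 <- par$pi1 * f1 / mix
    r0 <- 1 - r1
    pi1 <- mean(r1)
    if (pi1 < 1e-8 || pi1 > 1 - 1e-8 || sum(r0) < 1e-6 || sum(r1) < 1e-6) {
      degenerate <- TRUE
      break
    }
    normal_mu <- sum(r1 * x) / sum(r1)
    normal_sigma <- sqrt(sum(r1 * (x - normal_mu)^2) / sum(r1))
    gfit <- gumbel_mle_weighted(x, r0, par$gumbel_beta)
    if (!gfit$ok || normal_sigma < 1e-6 || gfit$beta < 1e-6) {
      degenerate <- TRUE
      break
    }
    par <- list(pi1 = pi1, gumbel_mu = gfit$mu, gumbel_beta = gfit$beta,
                normal_mu = normal_mu, normal_sigma = normal_sigma)
  }
  structure(list(
    pi0 = 1 - par$pi1, pi1 = par$pi1,
    gumbel_mu = par$gumbel_mu, gumbel_beta = par$gumbel_beta,
    normal_mu = par$normal_mu, normal_sigma = par$normal_sigma,
    loglik = loglik_trace[length(loglik_trace)],
    loglik_trace = loglik_trace,
    n_iter = iter,
    converged = converged && !degenerate,
    degenerate = degenerate,
    n = n
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<mixture_fit> pi1=%.3f, incorrect ~ Gumbel(%.3f, %.3f), ",
           "correct ~ Normal(%.3f, %.3f)\n  loglik=%.2f after %d iter (%s)\n"),
    x$pi1, x$gumbel_mu, x$gumbel_beta, x$normal_mu, x$normal_sigma,
    x$loglik, x$n_iter,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' @rdname fit_mixture_em
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(
    term = c("pi0", "pi1", "gumbel_mu", "gumbel_beta", "normal_mu",
             "normal_sigma"),
    estimate = c(x$pi0, x$pi1, x$gumbel_mu, x$gumbel_beta, x$normal_mu,
                 x$normal_sigma)
  )
}

#' @rdname fit_mixture_em
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(pi1 = x$pi1, gumbel_mu = x$gumbel_mu, gumbel_beta = x$gumbel_beta,
         normal_mu = x$normal_mu, normal_sigma = x$normal_sigma,
         loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         nobs = x$n)
}

#' @rdname fit_mixture_em
#' @param object A `mixture_fit`.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  lim <- c(
    min(object$gumbel_mu - 5 * object$gumbel_beta,
        object$normal_mu - 4 * object$normal_sigma),
    max(object$gumbel_mu + 10 * object$gumbel_beta,
        object$normal_mu + 4 * object$normal_sigma)
  )
  grid <- tibble(score = seq(lim[1], lim[2], length.out = 400))
  grid <- mutate(
    grid,
    incorrect = object$pi0 * dgumbel(.data$score, object$gumbel_mu,
                                     object$gumbel_beta),
    correct = object$pi1 * dnorm(.data$score, object$normal_mu,
                                 object$normal_sigma)
  )
  long <- tidyr::pivot_longer(grid, c("incorrect", "correct"),
                              names_to = "component", values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(.data$score, .data$density,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "score", y = "weighted density",
                  title = "Fitted score mixture") +
    ggplot2::theme_minimal()
}

#' Posterior error probability from a fitted mixture
#'
#' The probability that a PSM with the given score is incorrect:
#' `pi0 * f0(S) / (pi0 * f0(S) + pi1 * f1(S))` with `f0` the Gumbel and `f1`
#' the Gaussian density; clamped to `[0, 1]`.
#'
#' @param fit A `mixture_fit`.
#' @param score Numeric vector of scores.
#' @return Vector of PEPs in `[0, 1]`.
#' @export
compute_pep <- function(fit, score) {
  stopifnot(inherits(fit, "mixture_fit"))
  a <- fit$pi0 * dgumbel(score, fit$gumbel_mu, fit$gumbel_beta)
  b <- fit$pi1 * dnorm(score, fit$normal_mu, fit$normal_sigma)
  pep <- ifelse(a + b <= 0, 1, a / (a + b))
  pmin(pmax(pep, 0), 1)
}

#' Mixture-model filtering (MB)
#'
#' Fits the Gumbel + Gaussian mixture to target PSM scores (by default decoys
#' are excluded from the fit and from thresholding; the mixture-model method
#' does not use decoy counts), assigns each record a posterior error
#' probability, and selects the most permissive score threshold whose mean PEP
#' ([mb_fdr()]) — monotonised by cumulative minimum as in [filter_at_fdr()] —
#' is at most `alpha`.
#'
#' @param psms A tibble of PSM records with `score` and `is_decoy`.
#' @param alpha Target FDR level in (0, 1).
#' @param fit_on `"targets"` (default) or `"pooled"`: which scores the mixture
#'   is fitted to.
#' @param group Label stored on the outcome.
#' @param fit Optional pre-fitted `mixture_fit` to reuse.
#' @return A `filter_outcome` (see [filter_at_fdr()]); the accepted records
#'   gain a `pep` column.
#' @export
mb_filter <- function(psms, alpha, fit_on = c("targets", "pooled"),
                      group = "pooled", fit = NULL) {
  fit_on <- match.arg(fit_on)
  assert_fraction(alpha, "alpha")
  if (is.null(fit)) {
    train <- if (fit_on == "targets") psms$score[!psms$is_decoy] else psms$score
    fit <- fit_mixture_em(train)
  }
  targets <- psms[!psms$is_decoy, , drop = FALSE]
  targets$pep <- compute_pep(fit, targets$score)
  ord <- order(targets$score, decreasing = TRUE)
  pep_sorted <- targets$pep[ord]
  score_sorted <- targets$score[ord]
  fdr <- cumsum(pep_sorted) / seq_along(pep_sorted)
  last_of_t <- !duplicated(score_sorted, fromLast = TRUE)
  fdr <- fdr[last_of_t]
  thresholds <- score_sorted[last_of_t]
  q <- rev(cummin(rev(fdr)))
  ok <- which(q <= alpha)
  if (length(ok) == 0L) {
    out <- new_filter_outcome("MB", group, alpha, threshold = Inf,
                              n_target = 0L, n_decoy = 0L, fdr_est = 0,
                              accepted = targets[0, , drop = FALSE],
                              fdr_emp = NA_real_)
    out$fit <- fit
    return(out)
  }
  sel <- max(ok)
  t_star <- thresholds[sel]
  accepted <- targets[targets$score >= t_star, , drop = FALSE]
  fdr_emp <- if ("is_correct" %in% names(accepted)) {
    empirical_fdr(accepted)
  } else NA_real_
  n_d <- sum(psms$is_decoy & psms$score >= t_star)
  out <- new_filter_outcome("MB", group, alpha, threshold = t_star,
                            n_target = nrow(accepted), n_decoy = n_d,
                            fdr_est = q[sel], accepted = accepted,
                            fdr_emp = fdr_emp)
  out$fit <- fit
  out
}
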