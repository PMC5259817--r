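test_that("max-of-m Gumbel parameters follow the closed form", {
  expect_equal(max_gumbel_params(0, 1, 1), list(mu = 0, beta = 1))
  expect_equal(max_gumbel_params(0, 2, exp(1))$mu, 2, tolerance = 1e-12)
  expect_error(max_gumbel_params(0, 1, 0), "m")
})

test_that("empirical maximum of m Gumbel draws matches the shifted closed form", {
  m <- 50
  withr::local_seed(314)
  maxima <- vapply(1:10000, function(i) max(rgumbel(m, 0, 1)), numeric(1))
  p <- max_gumbel_params(0, 1, m)
  # one-sample KS distance against the closed form, 1% critical value
  ks <- suppressWarnings(
    stats::ks.test(maxima, function(q) pgumbel(q, p$mu, p$beta))
  )
  expect_lt(unname(ks$statistic), 1.63 / sqrt(10000))
})

test_that("gumbel density, distribution and quantiles are mutually consistent", {
  x <- seq(-3, 10, length.out = 50)
  expect_equal(pgumbel(qgumbel(seq(0.01, 0.99, 0.07), 2, 1.5), 2, 1.5),
               seq(0.01, 0.99, 0.07), tolerance = 1e-10)
  num <- vapply(x, function(q) {
    stats::integrate(dgumbel, -Inf, q, mu = 1, beta = 2)$value
  }, numeric(1))
  expect_equal(num, pgumbel(x, 1, 2), tolerance = 1e-6)
})

test_that("well-separated correct scores dominate: no decoys, all correct", {
  cfg <- sim_config(n_spectra = 2000, p_correct = 1, p_novel_true = 0,
                    gaussian_mu = 200, gaussian_sigma = 1, m_known = 1000,
                    m_decoy = 1000, charge_strata = "2+", seed = 5)
  res <- simulate_search(cfg)
  expect_true(all(res$psms$is_correct))
  expect_equal(sum(res$psms$is_decoy), 0L)
})

test_that("identically sized target and decoy partitions split wins evenly", {
  n <- 20000
  cfg <- sim_config(n_spectra = n, p_correct = 0, m_known = 5000,
                    m_novel = 0, m_decoy = 5000, charge_strata = "2+",
                    seed = 17)
  res <- simulate_search(cfg)
  expect_true(all(!res$psms$is_correct))
  frac_decoy <- mean(res$psms$is_decoy)
  expect_lt(abs(frac_decoy - 0.5), 3 * sqrt(0.25 / n))
})

test_that("winning-partition probabilities are proportional to partition sizes", {
  # for competing Gumbel maxima with common beta, P(partition j wins) = m_j / sum(m)
  n <- 30000
  cfg <- sim_config(n_spectra = n, p_correct = 0, m_known = 1000,
                    m_novel = 3000, m_decoy = 4000, charge_strata = "2+",
                    seed = 23)
  res <- simulate_search(cfg)
  probs <- c(known = 1000, novel = 3000, decoy = 4000) / 8000
  obs <- c(
    known = mean(!res$psms$is_decoy & res$psms$group == "known"),
    novel = mean(!res$psms$is_decoy & res$psms$group == "novel"),
    decoy = mean(res$psms$is_decoy)
  )
  for (k in names(probs)) {
    expect_lt(abs(obs[[k]] - probs[[k]]),
              4 * sqrt(probs[[k]] * (1 - probs[[k]]) / n))
  }
})

test_that("incorrect winner scores shift by beta * log of database growth", {
  base <- sim_config(n_spectra = 30000, p_correct = 0, m_known = 1000,
                     m_novel = 0, m_decoy = 0, decoy_known_frac = 1,
                     charge_strata = "2+", seed = 31)
  grown <- sim_config(n_spectra = 30000, p_correct = 0, m_known = 8000,
                      m_novel = 0, m_decoy = 0, decoy_known_frac = 1,
                      charge_strata = "2+", seed = 32)
  m1 <- mean(simulate_search(base)$psms$score)
  m2 <- mean(simulate_search(grown)$psms$score)
  expect_equal(m2 - m1, log(8000 / 1000), tolerance = 0.05)
})

test_that("simulation is byte-identical under the same config", {
  cfg <- sim_config(n_spectra = 1000, seed = 12)
  expect_identical(simulate_search(cfg)$psms, simulate_search(cfg)$psms)
  cfg2 <- sim_config(n_spectra = 1000, seed = 13)
  expect_false(identical(simulate_search(cfg)$psms,
                         simulate_search(cfg2)$psms))
})

test_that("features separate correct from incorrect matches", {
  res <- simulate_search(sim_config(n_spectra = 10000, charge_strata = "2+",
                                    seed = 3))
  p <- res$psms
  expect_lt(sd(p$mass_error_like[p$is_correct]),
            sd(p$mass_error_like[!p$is_correct]) / 5)
})

test_that("empirical FDR counts incorrect accepted targets only", {
  acc <- tibble::tibble(
    is_decoy = c(FALSE, FALSE, TRUE, FALSE),
    is_correct = c(TRUE, FALSE, FALSE, TRUE)
  )
  expect_equal(empirical_fdr(acc), 1 / 3)
  expect_equal(empirical_fdr(acc[acc$is_correct, ]), 0)
  expect_equal(empirical_fdr(acc[acc$is_decoy, ]), 0)
  # matches a hand count on a random labelled fixture
  withr::local_seed(4)
  fix <- tibble::tibble(is_decoy = runif(200) < 0.3,
                        is_correct = runif(200) < 0.5)
  fix$is_correct[fix$is_decoy] <- FALSE
  take <- runif(200) < 0.4
  hand <- sum(take & !fix$is_decoy & !fix$is_correct) /
    sum(take & !fix$is_decoy)
  expect_equal(empirical_fdr(fix[take, ]), hand)
})

test_that("simulator config validation rejects degenerate setups", {
  expect_error(sim_config(p_correct = 1.5), "p_correct")
  expect_error(sim_config(m_known = 0), "m_known")
  expect_error(sim_config(n_spectra = 0), "n_spectra")
})

test_that("a spectrum count mismatch between strata never occurs", {
  cfg <- sim_config(n_spectra = 500, charge_strata = c("2+", "3+"), seed = 9)
  res <- simulate_search(cfg)
  expect_equal(nrow(res$psms), 1000L)
  expect_equal(unname(table(res$psms$charge)), c(500L, 500L),
               ignore_attr = TRUE)
  expect_equal(anyDuplicated(res$psms$spectrum_id), 0L)
})
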