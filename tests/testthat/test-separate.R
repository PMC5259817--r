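# m_* sizes mirroring an inflation-n proteogenomic search at reduced scale
inflated_cfg <- function(seed, n_infl = 5L, n_spectra = 10000L,
                         p_novel_true = 0.01, m = 100000L) {
  sim_config(
    n_spectra = n_spectra, p_novel_true = p_novel_true,
    m_known = m, m_novel = n_infl * m, m_decoy = (n_infl + 1L) * m,
    charge_strata = "2+", seed = seed
  )
}

test_that("separate filtering partitions records and filters within groups", {
  psms <- simulate_search(inflated_cfg(800))$psms
  sep <- suppressMessages(separate_filter(psms, 0.01, method = "TD"))
  expect_named(sep, c("known", "novel"))
  expect_true(all(sep$known$accepted$group == "known"))
  expect_true(all(sep$novel$accepted$group == "novel"))
  expect_false(any(sep$known$accepted$is_decoy))
  expect_lte(sep$known$fdr_est, 0.01)
  expect_lte(sep$novel$fdr_est, 0.01)
  # the group partition is a set partition of the PSMs
  expect_setequal(unique(psms$group), c("known", "novel"))
})

test_that("novel targets scoring below all decoys are never accepted", {
  psms <- tibble::tibble(
    spectrum_id = sprintf("s%02d", 1:8),
    peptide_id = sprintf("p%02d", 1:8),
    score = c(10, 9, 8, 7, 3, 2, 5, 4),
    group = c(rep("known", 4), "novel", "novel", "novel", "novel"),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  )
  # novel targets (5,4) sit below novel decoys? no: decoys at 3,2; make them above
  psms$score[psms$is_decoy] <- c(6, 6.5)
  sep <- suppressMessages(separate_filter(psms, 0.01, method = "TD"))
  expect_equal(sep$novel$n_accepted, 0L)
})

test_that("separate filtering beats pooled filtering on a two-population fixture", {
  # known targets well separated from their decoys; a large spurious novel
  # block floods the pooled decoy count
  withr::local_seed(42)
  known_t <- tibble::tibble(score = rnorm(300, 12, 1), group = "known",
                            is_decoy = FALSE)
  known_d <- tibble::tibble(score = rnorm(300, 5, 1), group = "known",
                            is_decoy = TRUE)
  novel_t <- tibble::tibble(score = rnorm(2000, 8.2, 1), group = "novel",
                            is_decoy = FALSE)
  novel_d <- tibble::tibble(score = rnorm(2000, 8, 1), group = "novel",
                            is_decoy = TRUE)
  fix <- dplyr::bind_rows(known_t, known_d, novel_t, novel_d)
  fix$spectrum_id <- sprintf("s%05d", seq_len(nrow(fix)))
  fix$peptide_id <- sprintf("p%05d", seq_len(nrow(fix)))
  pooled <- filter_at_fdr(fix, 0.01)
  sep <- suppressMessages(separate_filter(fix, 0.01, method = "TD"))
  pooled_known <- sum(pooled$accepted$group == "known")
  expect_gte(sep$known$n_accepted, pooled_known)
  # and the brute-force oracle agrees with the known-group outcome
  grp <- fix[fix$group == "known", ]
  want <- oracle_filter(grp$score, grp$is_decoy, 0.01)
  expect_equal(sep$known$n_accepted, length(want$accepted_idx))
})

test_that("SepBP and SepMB learn pooled and filter per group by N_D/N_T", {
  psms <- simulate_search(inflated_cfg(801, n_spectra = 6000))$psms
  for (m in c("BP", "MB")) {
    sep <- suppressMessages(separate_filter(psms, 0.01, method = m,
                                            bp_cfg = bp_config(seed = 2)))
    expect_lte(sep$known$fdr_est, 0.01)
    expect_false(any(sep$known$accepted$is_decoy))
    expect_true(all(sep$novel$accepted$group == "novel"))
    # separate filtering keeps essentially all the correct known peptides
    expect_gt(sep$known$n_accepted, 0L)
  }
})

test_that("two-stage filtering: stage-1 acceptances never re-enter stage 2", {
  cfg <- inflated_cfg(900)
  truth <- withr::with_seed(1, sepfdr:::sim_truth(cfg, 1L))
  stage1 <- withr::with_seed(2, sepfdr:::sim_compete(truth, cfg, 1L,
                                                     cfg$m_known, 0L,
                                                     cfg$m_known, 1))
  provider <- function(ids) {
    withr::with_seed(3, sepfdr:::sim_compete(
      truth[truth$spectrum_id %in% ids, ], cfg, 1L,
      cfg$m_known, cfg$m_novel, cfg$m_decoy, 1 / 6))
  }
  ts <- two_stage_filter(stage1, provider, 0.01)
  expect_equal(
    length(intersect(ts$stage1$accepted$spectrum_id,
                     ts$stage2$accepted$spectrum_id)), 0L)
  expect_lte(ts$stage1$fdr_est, 0.01)
  expect_lte(ts$stage2$fdr_est, 0.01)
})

test_that("two-stage filtering with nothing residual leaves stage 2 empty", {
  psms <- tibble::tibble(
    spectrum_id = c("s1", "s2"), peptide_id = c("p1", "p2"),
    score = c(100, 90), group = "known", is_decoy = FALSE
  )
  called <- FALSE
  ts <- two_stage_filter(psms, function(ids) stop("should not be called"),
                         0.999)
  expect_equal(ts$stage2$n_accepted, 0L)
  expect_equal(ts$stage1$n_accepted, 2L)
})

test_that("two-stage and SepTD identify comparable novel-peptide counts", {
  # soft property over seeds: the two approaches agree within a factor of two
  counts <- vapply(1:20, function(s) {
    cfg <- inflated_cfg(1000 + s, n_spectra = 8000L)
    truth <- withr::with_seed(substream_seed(s, "t"),
                              sepfdr:::sim_truth(cfg, 1L))
    full <- withr::with_seed(substream_seed(s, "full"),
                             sepfdr:::sim_compete(truth, cfg, 1L))
    sep <- suppressMessages(separate_filter(full, 0.01, method = "TD"))
    stage1 <- withr::with_seed(substream_seed(s, "s1"),
                               sepfdr:::sim_compete(truth, cfg, 1L,
                                                    cfg$m_known, 0L,
                                                    cfg$m_known, 1))
    provider <- function(ids) {
      withr::with_seed(substream_seed(s, "s2"), sepfdr:::sim_compete(
        truth[truth$spectrum_id %in% ids, ], cfg, 1L))
    }
    ts <- two_stage_filter(stage1, provider, 0.01)
    c(sep = sum(sep$novel$accepted$group == "novel"),
      two = sum(ts$stage2$accepted$group == "novel"))
  }, numeric(2))
  m_sep <- mean(counts["sep", ])
  m_two <- mean(counts["two", ])
  expect_gt(m_two, 0)
  expect_lte(m_two, 2 * m_sep)
  expect_gte(m_two, m_sep / 2)
})

test_that("group labels are validated", {
  psms <- tibble::tibble(spectrum_id = "s", peptide_id = "p", score = 1,
                         group = "mystery", is_decoy = FALSE)
  expect_error(separate_filter(psms, 0.01), "group")
})
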