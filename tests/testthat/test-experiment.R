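small_exp_cfg <- function(n_values = c(0L, 2L), n_replicates = 2L,
                          methods = c("TD", "SepTD"), seed = 1L,
                          n_spectra = 3000L) {
  experiment_config(
    n_values = n_values, n_replicates = n_replicates, methods = methods,
    sim = sim_config(n_spectra = n_spectra, m_known = 50000L,
                     charge_strata = "2+"),
    master_seed = seed
  )
}

test_that("the experiment table is reproducible under the master seed", {
  cfg <- small_exp_cfg()
  a <- suppressMessages(run_inflation_experiment(cfg))
  b <- suppressMessages(run_inflation_experiment(cfg))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- suppressMessages(run_inflation_experiment(small_exp_cfg(seed = 2L)))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("every row respects the estimated-FDR contract", {
  tab <- suppressMessages(run_inflation_experiment(small_exp_cfg()))
  expect_true(all(tab$fdr_est <= 0.01 + 1e-12))
  expect_true(all(tab$accepted_known >= 0 & tab$accepted_novel >= 0))
})

test_that("no novel peptides exist at n = 0 without novel truth", {
  cfg <- experiment_config(
    n_values = 0L, n_replicates = 2L, methods = c("TD", "SepTD", "TwoStage"),
    sim = sim_config(n_spectra = 3000L, m_known = 50000L, p_novel_true = 0,
                     charge_strata = "2+"),
    master_seed = 4L
  )
  tab <- suppressMessages(run_inflation_experiment(cfg))
  expect_true(all(tab$accepted_novel == 0L))
})

test_that("all seven methods produce rows keyed by (n, method, group)", {
  cfg <- experiment_config(
    n_values = 1L, n_replicates = 1L,
    sim = sim_config(n_spectra = 2500L, m_known = 30000L,
                     charge_strata = "2+"),
    master_seed = 9L
  )
  tab <- suppressMessages(run_inflation_experiment(cfg))
  expect_setequal(unique(tab$method),
                  c("TD", "BP", "MB", "SepTD", "SepBP", "SepMB", "TwoStage"))
  expect_setequal(tab$group[tab$method == "SepTD"], c("known", "novel"))
  expect_setequal(tab$group[tab$method == "TwoStage"], c("stage1", "stage2"))
  expect_equal(sum(tab$method == "TD"), 1L)
})

test_that("report files round-trip and aggregate correctly", {
  tab <- suppressMessages(run_inflation_experiment(small_exp_cfg()))
  dir <- withr::local_tempdir()
  paths <- write_report(tab, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(paths[1])
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$accepted_known, tab$accepted_known)
  summ <- utils::read.delim(paths[2])
  # aggregation equals brute-force group means
  one <- summ[summ$method == "TD" & summ$n == 0, ]
  want <- mean(tab$accepted_known[tab$method == "TD" & tab$n == 0])
  expect_equal(one$mean_known, want)
  expect_match(readLines(paths[3]), "master_seed", all = FALSE)
})

test_that("autoplot produces a faceted ggplot", {
  tab <- suppressMessages(run_inflation_experiment(small_exp_cfg(
    n_replicates = 1L)))
  expect_s3_class(autoplot(tab), "ggplot")
})

test_that("percent change, decrease rate and size difference follow their formulas", {
  expect_equal(percent_change(4115, 6336), 53.97)
  expect_equal(percent_change(62, 11), -82.26)
  expect_equal(percent_change(100, 100), 0)
  expect_error(percent_change(0, 5), "undefined")

  expect_equal(decrease_rate(3759, 3434), 8.65)
  expect_equal(decrease_rate(100, 100), 0)
  expect_error(decrease_rate(0, 5), "baseline")

  expect_equal(size_difference(9186837, 9654965), 4.85)
  expect_equal(size_difference(107568099, 123364545), 12.80)
  expect_equal(size_difference(5, 5), 0)
  expect_error(size_difference(1, 0), "real_total_aa")

  withr::local_seed(77)
  for (i in 1:50) {
    b <- sample(1:5000, 1); a <- sample(0:5000, 1)
    expect_equal(percent_change(b, a), round((a - b) / b * 100, 2))
    expect_equal(decrease_rate(b, a), round((b - a) / b * 100, 2))
  }
})

test_that("overlap report reproduces brute-force set algebra", {
  identical_sets <- list(a = c("x", "y"), b = c("x", "y"), c = c("y", "x"))
  rep1 <- overlap_report(identical_sets)
  expect_equal(rep1$n_common, 2L)
  expect_equal(rep1$prop_common_pct, 100)
  all_on <- rep1$regions[rep1$regions$a & rep1$regions$b & rep1$regions$c, ]
  expect_equal(all_on$count, 2L)

  disjoint <- list(a = "x", b = "y", c = "z")
  rep2 <- overlap_report(disjoint)
  expect_equal(rep2$n_common, 0L)
  expect_true(all(rep2$pairwise$n_intersect == 0L))

  withr::local_seed(303)
  for (i in 1:100) {
    universe <- sprintf("pep%02d", 1:20)
    sets <- list(a = sample(universe, sample(0:15, 1)),
                 b = sample(universe, sample(0:15, 1)),
                 c = sample(universe, sample(0:15, 1)))
    got <- overlap_report(sets)
    expect_equal(got$n_common,
                 length(intersect(intersect(sets$a, sets$b), sets$c)))
    expect_equal(got$n_union, length(union(union(sets$a, sets$b), sets$c)))
    ab <- got$pairwise$n_intersect[got$pairwise$set1 == "a" &
                                     got$pairwise$set2 == "b"]
    expect_equal(ab, length(intersect(sets$a, sets$b)))
    only_a <- got$regions[got$regions$a & !got$regions$b & !got$regions$c, ]
    expect_equal(only_a$count,
                 length(setdiff(setdiff(sets$a, sets$b), sets$c)))
  }
})

test_that("experiment configuration is validated", {
  expect_error(experiment_config(n_values = integer()), "n_values")
  expect_error(experiment_config(alpha = 1.2), "alpha")
  expect_error(experiment_config(methods = "nope"), "arg")
})
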