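#' Configuration of an inflation-sweep experiment
#'
#' @param n_values Inflation factors to sweep (integers >= 0).
#' @param alpha Target FDR level. Default 0.01.
#' @param n_replicates Seeded replicates per inflation factor.
#' @param sim A [sim_config()] template; `m_novel`, `m_decoy` and
#'   `decoy_known_frac` are derived per inflation factor as
#'   `m_novel = n * m_known`, `m_decoy = (n + 1) * m_known`,
#'   `decoy_known_frac = 1 / (n + 1)`.
#' @param methods Validation methods to run, a subset of
#'   `c("TD", "BP", "MB", "SepTD", "SepBP", "SepMB", "TwoStage")`.
#' @param bp A [bp_config()] template for the boosted rescorer.
#' @param master_seed Master seed; every replicate and stage derives named
#'   sub-streams from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_values = c(0L, 1L, 2L, 5L),
                              alpha = 0.01,
                              n_replicates = 3L,
                              sim = sim_config(),
                              methods = c("TD", "BP", "MB", "SepTD", "SepBP",
                                          "SepMB", "TwoStage"),
                              bp = bp_config(),
                              master_seed = 1L) {
  if (length(n_values) == 0L || any(n_values < 0) ||
      any(n_values != floor(n_values))) {
    abort("`n_values` must be non-empty non-negative integers")
  }
  assert_fraction(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  assert_count(n_replicates, "n_replicates", min = 1L)
  stopifnot(inherits(sim, "sim_config"), inherits(bp, "bp_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(
    n_values = as.integer(n_values), alpha = alpha,
    n_replicates = as.integer(n_replicates), sim = sim, methods = methods,
    bp = bp, master_seed = as.integer(master_seed)
  ), class = "experiment_config")
}

outcome_row <- function(out, n, charge, replicate, seed) {
  acc <- out$accepted
  tibble(
    n = n, method = out$method, charge = charge, group = out$group,
    replicate = replicate,
    accepted_known = sum(acc$group == "known"),
    accepted_novel = sum(acc$group == "novel"),
    n_accepted = out$n_accepted,
    n_decoy_at_t = out$n_decoy,
    threshold = out$threshold,
    fdr_est = out$fdr_est,
    fdr_emp = out$fdr_emp,
    seed = seed
  )
}

run_one_condition <- function(cfg, n, replicate) {
  sim <- cfg$sim
  m_known <- sim$m_known
  m_novel <- n * m_known
  m_decoy <- (n + 1L) * m_known
  dkf <- 1 / (n + 1)
  alpha <- cfg$alpha

  rows <- list()
  for (si in seq_along(sim$charge_strata)) {
    tag <- sprintf("r%d_n%d_s%d", replicate, n, si)
    base_seed <- substream_seed(cfg$master_seed, tag)
    truth <- withr::with_seed(substream_seed(base_seed, "truth"),
                              sim_truth(sim, si))
    psms <- withr::with_seed(
      substream_seed(base_seed, "search"),
      sim_compete(truth, sim, si, m_known, m_novel, m_decoy, dkf)
    )
    charge <- sim$charge_strata[si]
    add <- function(out) {
      rows[[length(rows) + 1L]] <<- outcome_row(out, n, charge, replicate,
                                                base_seed)
    }
    for (method in cfg$methods) {
      if (method == "TD") {
        add(filter_at_fdr(peptide_collapse(psms, "score"), alpha,
                          key = "score", method = "TD"))
      } else if (method == "BP") {
        bp <- cfg$bp
        bp$seed <- substream_seed(base_seed, "bp")
        rescored <- boosted_rescore(psms, bp)
        out <- filter_at_fdr(peptide_collapse(rescored, "rescored"), alpha,
                             key = "rescored", method = "BP")
        add(out)
      } else if (method == "MB") {
        add(mb_filter(peptide_collapse(psms, "score"), alpha))
      } else if (method %in% c("SepTD", "SepBP", "SepMB")) {
        bp <- cfg$bp
        bp$seed <- substream_seed(base_seed, paste0("sep_bp"))
        sep <- separate_filter(psms, alpha,
                               method = sub("Sep", "", method), bp_cfg = bp)
        add(sep$known)
        add(sep$novel)
      } else if (method == "TwoStage") {
        stage1 <- withr::with_seed(
          substream_seed(base_seed, "stage1"),
          sim_compete(truth, sim, si, m_known, 0L, m_known, 1)
        )
        provider <- function(ids) {
          withr::with_seed(
            substream_seed(base_seed, "stage2"),
            sim_compete(truth[truth$spectrum_id %in% ids, , drop = FALSE],
                        sim, si, m_known, m_novel, m_decoy, dkf)
          )
        }
        ts <- two_stage_filter(stage1, provider, alpha)
        add(ts$stage1)
        add(ts$stage2)
      }
    }
  }
  bind_rows(rows)
}

#' Run an inflation-sweep experiment
#'
#' For each replicate and each inflation factor `n`, derives the partition
#' sizes (`m_novel = n * m_known`, `m_decoy = (n + 1) * m_known`, mirroring a
#' 1TnD target plus an (n+1)-sized decoy), simulates the search, applies the
#' requested validation methods after peptide-level collapse, and records
#' accepted known/novel peptide counts, thresholds, and estimated and
#' empirical FDR. Deterministic under `config$master_seed`.
#'
#' @param config An [experiment_config()].
#' @return A tibble of class `inflation_experiment`, one row per
#'   (replicate, n, charge stratum, method, group), with the configuration in
#'   `attr(, "config")`.
#' @export
#' @examples
#' \donttest{
#' cfg <- experiment_config(
#'   n_values = c(0L, 2L), n_replicates = 2L, methods = c("TD", "SepTD"),
#'   sim = sim_config(n_spectra = 2000L, charge_strata = "2+")
#' )
#' run_inflation_experiment(cfg)
#' }
run_inflation_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      n = config$n_values)
  out <- bind_rows(purrr::map2(grid$replicate, grid$n, function(r, n) {
    run_one_condition(config, n, r)
  }))
  structure(out, class = c("inflation_experiment", class(out)),
            config = config)
}

#' Summarise an inflation experiment over replicates
#'
#' Mean and standard deviation of the accepted known/novel counts and the
#' empirical FDR per (n, method, charge stratum, group).
#'
#' @param table An `inflation_experiment` tibble.
#' @return A summary tibble.
#' @export
summarise_experiment <- function(table) {
  table |>
    group_by(.data$n, .data$method, .data$charge, .data$group) |>
    summarise(
      n_replicates = dplyr::n(),
      mean_known = mean(.data$accepted_known),
      sd_known = sd(.data$accepted_known),
      mean_novel = mean(.data$accepted_novel),
      sd_novel = sd(.data$accepted_novel),
      mean_fdr_emp = mean(.data$fdr_emp),
      .groups = "drop"
    )
}

#' Write experiment results, summary and manifest
#'
#' Writes `results.tsv` (all rows), `summary.tsv` (mean and SD over replicates
#' per condition) and `manifest.txt` (configuration, seeds, package version)
#' into `dir`.
#'
#' @param table An `inflation_experiment` tibble.
#' @param dir Output directory (created if missing).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_report <- function(table, dir) {
  if (nrow(table) == 0L) abort("empty experiment table")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("results.tsv", "summary.tsv", "manifest.txt"))
  utils::write.table(as.data.frame(table), paths[1L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(summarise_experiment(table)), paths[2L],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- attr(table, "config")
  manifest <- c(
    sprintf("package: sepfdr %s",
            as.character(utils::packageVersion("sepfdr"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    if (!is.null(cfg)) c(
      sprintf("master_seed: %d", cfg$master_seed),
      sprintf("alpha: %g", cfg$alpha),
      sprintf("n_values: %s", paste(cfg$n_values, collapse = ",")),
      sprintf("n_replicates: %d", cfg$n_replicates),
      sprintf("methods: %s", paste(cfg$methods, collapse = ",")),
      sprintf("n_spectra: %d", cfg$sim$n_spectra),
      sprintf("m_known: %d", cfg$sim$m_known),
      sprintf("charge_strata: %s", paste(cfg$sim$charge_strata, collapse = ","))
    )
  )
  writeLines(manifest, paths[3L])
  invisible(paths)
}

#' Plot accepted peptide counts against the inflation factor
#'
#' Bar chart of mean accepted known and novel peptide counts per inflation
#' factor, faceted by method (and charge stratum when several are present).
#'
#' @param object An `inflation_experiment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inflation_experiment <- function(object, ...) {
  summ <- summarise_experiment(object) |>
    tidyr::pivot_longer(c("mean_known", "mean_novel"),
                        names_to = "class", values_to = "count") |>
    mutate(class = sub("mean_", "", .data$class))
  p <- ggplot2::ggplot(
    summ,
    ggplot2::aes(x = factor(.data$n), y = .data$count, fill = .data$class)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "inflation factor n", y = "accepted peptides at 1% FDR",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(summ$charge)) > 1L) {
    p + ggplot2::facet_grid(charge ~ method)
  } else {
    p + ggplot2::facet_wrap(~method)
  }
}
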