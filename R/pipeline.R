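# End-to-end orchestration: cohort -> SCN per group -> Louvain ensembles ->
# modularity comparison -> trajectory report, with persisted intermediates.

#' Build a run configuration
#'
#' @param input path to a cohort file, or `NULL` to simulate one.
#' @param generator generator configuration used when `input` is `NULL`.
#' @param gamma resolution parameter (default 1, the value used for the
#'   headline community structure).
#' @param n_runs Louvain runs per group (default 50).
#' @param seed master seed; all randomness (generator, per-run Louvain
#'   seeds) derives from it through named substreams.
#' @param scheme composite-layer scheme.
#' @param var_equal pooled-variance t-tests instead of Welch.
#' @param family trajectory-report family.
#' @param out_dir output directory for persisted artifacts, or `NULL` to
#'   keep everything in memory.
#' @return A list of class `scn_run_config`.
#' @export
run_config <- function(input = NULL,
                       generator = default_generator_config(),
                       gamma = 1, n_runs = 50L, seed = 1L,
                       scheme = default_composite_scheme(),
                       var_equal = FALSE,
                       family = default_trajectory_family(),
                       out_dir = NULL) {
  stopifnot(gamma > 0, n_runs >= 1L)
  structure(list(input = input, generator = generator, gamma = gamma,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 scheme = scheme, var_equal = var_equal, family = family,
                 out_dir = out_dir),
            class = "scn_run_config")
}

# Internal: derive named substream seeds (< 2^31) from the master seed.
derive_seeds <- function(master, names) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(master)
  stats::setNames(sample.int(.Machine$integer.max, length(names)), names)
}

#' Run the full covariance-network pipeline
#'
#' Loads or simulates a cohort, builds the age-adjusted structural
#' covariance network of each group, runs a Louvain ensemble with consensus
#' on each, compares run-level modularity between groups (Welch t-test by
#' default), and computes the age-trajectory report. All artifacts are
#' written to `config$out_dir` when given (cohort CSV, truth JSON when
#' simulated, SCN TSVs with JSON sidecars, consensus and per-run partition
#' tables, Q-run TSV, comparison JSON, trajectory TSV, report JSON). The
#' run is deterministic given the master seed.
#'
#' @param config an `scn_run_config`.
#' @return A report list: per-group `mean_Q`, `n_communities`,
#'   `negative_fraction`, the `comparison` (t, p), trajectory summary
#'   counts, the configuration echo and seeds.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "scn_run_config"))
  seeds <- derive_seeds(config$seed,
                        c("generator", "ensemble_HC", "ensemble_DWOR"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  persist <- function(fun, ...) if (!is.null(out)) fun(...)

  truth <- NULL
  if (is.null(config$input)) {
    sim <- generate_cohort(config$generator,
                           seed = unname(seeds[["generator"]]))
    cohort <- sim$cohort
    truth <- sim$truth
    persist(save_cohort, cohort, file.path(out, "cohort.csv"))
    persist(function(...) jsonlite::write_json(...),
            truth, file.path(out, "truth.json"),
            auto_unbox = TRUE, digits = NA)
  } else {
    cohort <- load_cohort(config$input)
  }

  scns <- list()
  ensembles <- list()
  for (g in cohort_groups()) {
    scn <- build_scn(cohort, g)
    model <- modularity_model(scn, gamma = config$gamma)
    ens <- run_ensemble(model, n_runs = config$n_runs,
                        seed = unname(seeds[[paste0("ensemble_", g)]]),
                        group = g)
    scns[[g]] <- scn
    ensembles[[g]] <- ens
    persist(save_scn, scn, file.path(out, paste0("scn_", g, ".tsv")))
    persist(save_partition, ens$consensus,
            file.path(out, paste0("consensus_", g, ".tsv")))
    persist(function(...) utils::write.table(...),
            data.frame(run = seq_len(ens$n_runs), Q = ens$Q_values),
            file.path(out, paste0("q_runs_", g, ".tsv")),
            sep = "\t", row.names = FALSE, quote = FALSE)
  }

  comparison <- compare_modularity(ensembles$HC, ensembles$DWOR,
                                   var_equal = config$var_equal)
  trajectories <- trajectory_report(cohort, family = config$family,
                                    scheme = config$scheme)
  persist(function(...) utils::write.table(...),
          trajectories, file.path(out, "trajectories.tsv"),
          sep = "\t", row.names = FALSE, quote = FALSE)
  persist(function(...) jsonlite::write_json(...),
          list(t = comparison$t_statistic, p = comparison$p_value,
               meanQ_hc = comparison$mean_Q[["HC"]],
               meanQ_dwor = comparison$mean_Q[["DWOR"]],
               n_runs = config$n_runs, seed = config$seed,
               gamma = config$gamma),
          file.path(out, "comparison.json"), auto_unbox = TRUE, digits = NA)

  report <- list(
    version = as.character(utils::packageVersion("retscn")),
    seed = config$seed,
    substream_seeds = as.list(seeds),
    gamma = config$gamma,
    n_runs = config$n_runs,
    n_eyes = as.list(table(cohort$group)),
    composite_scheme = config$scheme,
    simulated = is.null(config$input),
    mean_Q = lapply(ensembles, `[[`, "mean_Q"),
    n_communities = lapply(ensembles, `[[`, "n_communities"),
    negative_fraction = lapply(scns, `[[`, "negative_fraction"),
    comparison = list(t = comparison$t_statistic,
                      p = comparison$p_value, df = comparison$df),
    trajectories = list(
      n_tests = nrow(trajectories),
      n_q_below_0.05 = sum(trajectories$q < 0.05),
      min_q = min(trajectories$q))
  )
  persist(function(...) jsonlite::write_json(...),
          report, file.path(out, "report.json"),
          auto_unbox = TRUE, digits = NA)

  invisible(structure(list(report = report, cohort = cohort, truth = truth,
                           scns = scns, ensembles = ensembles,
                           comparison = comparison,
                           trajectories = trajectories),
                      class = "scn_run_result"))
}

#' @export
print.scn_run_result <- function(x, ...) {
  r <- x$report
  cat("Retinal covariance-network pipeline run\n")
  cat(sprintf("  seed %d, gamma %.2f, %d Louvain runs per group\n",
              r$seed, r$gamma, r$n_runs))
  for (g in names(r$mean_Q)) {
    cat(sprintf("  %s: mean Q %.4f, %d consensus communities, negative fraction %.3f\n",
                g, r$mean_Q[[g]], r$n_communities[[g]],
                r$negative_fraction[[g]]))
  }
  cat(sprintf("  modularity comparison: t = %.3f, p = %.3g\n",
              r$comparison$t, r$comparison$p))
  cat(sprintf("  trajectories: %d tests, %d with q < 0.05\n",
              r$trajectories$n_tests, r$trajectories$n_q_below_0.05))
  invisible(x)
}
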