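# End-to-end runs: a single config drives synthetic-data generation and the
# analysis stages in dependency order, writing per-stage CSV outputs, a
# machine-readable JSON summary, and a log with the package version, seed and
# config hash. Re-running an identical config reproduces identical summaries.

#' Default pipeline configuration
#'
#' A complete, runnable configuration exercising every stage on synthetic
#' data. Override fields as needed; `run_pipeline()` validates the result.
#'
#' @param outdir Output directory.
#' @param seed Random seed used by all stochastic stages.
#' @return Named list understood by [run_pipeline()].
#' @export
default_config <- function(outdir = tempfile("calgevo_run_"), seed = 1) {
  list(
    seed = seed,
    outdir = outdir,
    stages = c("topologies", "asr", "parsimony", "gel", "decay",
               "two_state", "growth", "reporter"),
    topologies = list(clades = c("A8", "A9", "A12", "MRP126")),
    asr = list(tree = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);",
               L = 100, threshold = 0.20),
    parsimony = list(tree = "(((A8,A9),A12),MRP126);",
                     traits = c(A8 = "susceptible", A9 = "susceptible",
                                A12 = "resistant", MRP126 = "resistant")),
    gel = list(k = 0.1, times = c(0, 5, 10, 20, 40, 80), noise_sd = 0.03),
    decay = list(k = DECAY_PRESETS[["hA9-like"]],
                 times = seq(0, 30, length.out = 10), n_replicates = 3,
                 noise_sd = 0.05),
    two_state = list(dG = 8, m = 1.6, noise_sd = 0),
    growth = list(t_eval_hr = 7),
    reporter = list(true_inductions = c(mock = 0.05, "S100+PB" = 0.6))
  )
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON path")
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$outdir)) stop("config must set an outdir")
  if (length(config$stages) == 0) stop("empty stage selection")
  known <- c("topologies", "asr", "parsimony", "gel", "decay", "two_state",
             "growth", "reporter")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(config$asr$threshold) &&
      (config$asr$threshold <= 0 || config$asr$threshold >= 1))
    stop("altAll threshold must lie in (0, 1)")
  config
}

read_tree_spec <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (file.exists(x)) return(ape::read.tree(x))
  ape::read.tree(text = x)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the selected stages in order on synthetic inputs generated from
#' the config's seed, writes per-stage CSVs plus `summary.json`,
#' `config.json` and `log.txt` under the output directory, and returns the
#' summary. Any stage error aborts the run with the failing stage named;
#' outputs of earlier stages are retained.
#'
#' @param config Named list (see [default_config()]) or path to a JSON
#'   config.
#' @return The summary list, invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$outdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  summary <- list(seed = config$seed)
  warnings_log <- character(0)
  run_stage <- function(name, fn) {
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(name, ": ",
                                                conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    summary[[name]] <<- res
  }

  for (stage in config$stages) {
    switch(stage,
      topologies = run_stage("topologies", function() {
        tp <- enumerate_clade_topologies(config$topologies$clades)
        writeLines(tp, file.path(config$outdir, "topologies.nwk"))
        list(n_clades = length(config$topologies$clades),
             n_topologies = length(tp))
      }),
      asr = run_stage("asr", function() {
        p <- config$asr
        tree <- read_tree_spec(p$tree)
        sim <- simulate_msa(tree, p$L, seed = config$seed)
        rec <- marginal_asr(tree, sim$alignment)
        write_posterior_csv(rec, file.path(config$outdir, "posteriors.csv"))
        root_lab <- names(rec$ml)[1]
        aa <- build_altall(rec$posteriors[[root_lab]],
                           ml_sequence = rec$ml[[root_lab]],
                           threshold = p$threshold %||% 0.20)
        write_fasta(c(ml = aa$ml_sequence, altall = aa$altall_sequence),
                    file.path(config$outdir, "ancestors.fasta"))
        truth <- sim$ancestors[[root_lab]]
        list(root_node = root_lab,
             average_pp = aa$average_pp,
             n_altall_substitutions = length(aa$substituted_sites),
             ml_vs_altall_differences =
               count_differences(aa$ml_sequence, aa$altall_sequence),
             ml_vs_truth_identity =
               1 - count_differences(aa$ml_sequence, truth) /
                 nchar(truth))
      }),
      parsimony = run_stage("parsimony", function() {
        p <- config$parsimony
        fp <- fitch_parsimony(read_tree_spec(p$tree), unlist(p$traits))
        list(root_states = paste(fp$root_set, collapse = "|"),
             changes = fp$changes)
      }),
      gel = run_stage("gel", function() {
        p <- config$gel
        g <- simulate_gel_timecourse(p$k, p$times, seed = config$seed,
                                     noise_sd = p$noise_sd %||% 0.03)
        tc <- quantify_gel_timecourse(g$image, g$times,
                                      window = g$truth$band_window)
        write.csv(tc, file.path(config$outdir, "gel_timecourse.csv"),
                  row.names = FALSE)
        fit <- fit_exponential_decay(tc)
        list(true_k = p$k, fitted_k = fit$k, sd_k = fit$sd_k)
      }),
      decay = run_stage("decay", function() {
        p <- config$decay
        d <- simulate_decay_data(p$k, p$times, seed = config$seed,
                                 n_replicates = p$n_replicates %||% 3,
                                 noise_sd = p$noise_sd %||% 0.05)
        write.csv(d, file.path(config$outdir, "decay_data.csv"),
                  row.names = FALSE)
        fit <- fit_exponential_decay(d)
        list(true_k = p$k, fitted_k = fit$k, sd_k = fit$sd_k,
             A0 = fit$A0)
      }),
      two_state = run_stage("two_state", function() {
        p <- config$two_state
        d <- simulate_denaturation(p$dG, p$m, seed = config$seed,
                                   noise_sd = p$noise_sd %||% 0)
        write.csv(d, file.path(config$outdir, "denaturation.csv"),
                  row.names = FALSE)
        fit <- fit_two_state(d$x_molar, d$signal_mdeg)
        list(true_dG = p$dG, fitted_dG = fit$dG, fitted_m = fit$m,
             Cm = fit$Cm, sd_Cm = fit$sd_Cm)
      }),
      growth = run_stage("growth", function() {
        trts <- list(untreated = list(K = 0.8, r = 0.02, t_lag = 240),
                     "hA8/A9 5uM" = list(K = 0.4, r = 0.02, t_lag = 240,
                                         concentration_uM = 5))
        gc <- simulate_growth(trts, seed = config$seed)
        res <- growth_inhibition(gc,
                                 t_eval_hr = config$growth$t_eval_hr %||% 7)
        write.csv(res, file.path(config$outdir, "growth_inhibition.csv"),
                  row.names = FALSE)
        as.list(setNames(res$percent_of_untreated, res$treatment))
      }),
      reporter = run_stage("reporter", function() {
        plate <- simulate_reporter_plate(
          unlist(config$reporter$true_inductions), seed = config$seed)
        res <- nfkb_induction(plate)
        write.csv(res, file.path(config$outdir, "nfkb_induction.csv"),
                  row.names = FALSE)
        as.list(setNames(res$induction, res$treatment))
      })
    )
  }

  summary$warnings <- warnings_log
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- c(paste("calgevo version:",
                 as.character(utils::packageVersion("calgevo"))),
           paste("seed:", config$seed),
           paste("config md5:", unname(tools::md5sum(cfg_path))),
           paste("stages:", paste(config$stages, collapse = ", ")),
           if (length(warnings_log)) paste("warning:", warnings_log))
  writeLines(log, file.path(config$outdir, "log.txt"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate input files against their declared formats
#'
#' Report-only checker: each file is parsed according to its format and the
#' first offending record (illegal FASTA character, non-normalized posterior
#' row, negative time, unreadable tree) is reported. Supported formats:
#' `fasta`, `newick`, `posterior_csv`, `decay_csv`, `gel_csv`.
#'
#' @param paths Character vector of file paths.
#' @param formats Character vector of formats, one per path.
#' @return Data frame (`path`, `format`, `pass`, `issue`).
#' @export
validate_inputs <- function(paths, formats) {
  if (length(paths) != length(formats))
    stop("paths and formats must have equal length")
  check_one <- function(path, format) {
    if (!file.exists(path)) return(paste0("file not found: ", path))
    tryCatch({
      switch(format,
        fasta = validate_alignment(read_fasta(path)),
        newick = check_tree(ape::read.tree(path)),
        posterior_csv = lapply(read_posterior_csv(path), validate_posterior),
        decay_csv = {
          d <- read.csv(path)
          if (!all(c("time_min", "fraction_intact") %in% names(d)))
            stop("missing time_min/fraction_intact columns")
          if (any(d$time_min < 0))
            stop("negative time at row ", which(d$time_min < 0)[1])
        },
        gel_csv = {
          m <- as.matrix(read.csv(path, header = FALSE))
          if (!all(is.finite(m))) stop("non-finite intensity values")
        },
        stop("unknown format '", format, "'"))
      NA_character_
    }, error = function(e) conditionMessage(e))
  }
  issues <- mapply(check_one, paths, formats)
  data.frame(path = paths, format = formats,
             pass = is.na(issues), issue = unname(issues),
             row.names = NULL)
}
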