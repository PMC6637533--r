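# Config-driven orchestration of the analysis stages with per-stage
# sub-seeds, plain-text logging and a machine-readable run report.

default_pipeline_config <- function() {
  list(
    scenario = "feno_threshold",
    n_total = 1207,
    seed = 1,
    arm = "q2w",
    sides = list(L = 1, M = 5, N_min = 60, min_prevalence = 0.30,
                 n_splits = 50, criterion = 1, gamma = 1.0,
                 selection_threshold = 0),
    bootstrap_B = 50,   # reduced profile; production uses 500
    permutation_P = 50, # reduced profile; production uses 500
    scan_span = 5,      # cut-offs either side of the chosen one
    endpoints = ENDPOINTS,
    outlier_rules = list(list(biomarker = "eos_cells_ul", threshold = 4000))
  )
}

#' Run the full biomarker analysis pipeline
#'
#' Executes the stages in order: data (simulate a named scenario or load
#' CSVs) -> prepare -> descriptives -> interaction screening -> SIDES
#' search -> bootstrap + permutation null -> cut-off scan -> secondary
#' endpoint models -> decision summary. Every artifact is written under
#' `out_dir` with stage provenance and seeds, and a single JSON run report
#' indexes all outputs. Adverse-event tabulations are out of scope and the
#' report says so. Stage failures abort with the stage name; artifacts
#' already written are preserved.
#'
#' @param config list or path to a YAML file; see
#'   `nbsides:::default_pipeline_config()` for the recognised fields.
#'   Supply `participants_csv`/`visits_csv` instead of `scenario` to run on
#'   existing data.
#' @param out_dir output directory (created if needed).
#' @param seed master seed override; per-stage sub-seeds are derived
#'   deterministically from it.
#' @param dry_run validate the config and print the stage plan without
#'   executing anything.
#' @return invisibly, the run report list.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("nbsides_run_"),
                         seed = NULL, dry_run = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  stages <- c("data", "prepare", "descriptives", "screening", "sides",
              "bootstrap", "permutation", "scan", "secondary", "decision")
  if (dry_run) {
    message("pipeline plan (dry run): ", paste(stages, collapse = " -> "))
    message("scenario: ", cfg$scenario %||% "(from files)",
            "; seed: ", cfg$seed)
    return(invisible(list(dry_run = TRUE, stages = stages, config = cfg)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, length(stages))
  names(seeds) <- stages
  report <- list(config = cfg[setdiff(names(cfg), "endpoint_params")],
                 seeds = as.list(seeds), stages = list(), files = character(),
                 questions = list(
                   q1 = "descriptives + screening",
                   q2 = "sides + bootstrap + permutation + scan",
                   q3 = "secondary endpoints + decision summary",
                   q4 = "out of scope: safety tabulations are descriptive and reported elsewhere"))
  t_all <- Sys.time()
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    if (is.data.frame(obj)) write.csv(obj, path, row.names = FALSE, na = "")
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE)
    report$files <<- c(report$files, file)
    path
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] start", name))
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    el <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    report$stages[[name]] <<- list(status = "ok", seconds = el)
    message(sprintf("[%s] done (%.1fs)", name, el))
    out
  }

  raw <- stage("data", {
    if (!is.null(cfg$participants_csv)) {
      load_trial(cfg$participants_csv, cfg$visits_csv)
    } else {
      sc <- scenario_library(n_total = cfg$n_total)[[cfg$scenario]]
      if (is.null(sc)) stop("unknown scenario: ", cfg$scenario)
      simulate_trial(sc, seed = seeds[["data"]])
    }
  })
  prepared <- stage("prepare", {
    d <- prepare_analysis_set(raw, outlier_rules = cfg$outlier_rules)
    emit(d$metadata$exclusions, "exclusions.csv")
    d
  })
  stage("descriptives", {
    emit(summarize_baseline(prepared), "baseline_summary.csv")
    emit(covariate_associations(prepared), "covariate_associations.csv")
  })
  screen <- stage("screening", {
    it <- interaction_tests(prepared)
    emit(it, "interaction_tests.csv")
    for (bmn in c("feno_ppb", "periostin_ng_ml")) {
      emit(subgroup_forest(prepared, bmn, "quartile"),
           paste0("forest_quartile_", bmn, ".csv"))
      emit(subgroup_forest(prepared, bmn, "cumulative"),
           paste0("forest_cumulative_", bmn, ".csv"))
      emit(effect_curves(prepared, bmn, "linear"),
           paste0("curve_linear_", bmn, ".csv"))
    }
    it
  })
  pars <- do.call(sides_params, cfg$sides)
  sres <- stage("sides", {
    r <- sides_run(prepared, pars, cfg$arm)
    emit(r$subgroups, "sides_subgroups.csv")
    emit(r$trace, "sides_trace.csv")
    r
  })
  best <- best_subgroup(sres)
  stage("bootstrap", {
    bc <- bootstrap_cutoffs(prepared, pars, B = cfg$bootstrap_B,
                            seed = seeds[["bootstrap"]], arm = cfg$arm)
    summ <- lapply(bc$biomarkers, function(b)
      list(grid = b$grid, bins_above = b$bins_above,
           bins_below = b$bins_below, n_selected = b$n_selected,
           main_cutoff = b$main_cutoff))
    emit(list(B = bc$B, n_failed = bc$n_failed, biomarkers = summ),
         "bootstrap_cutoffs.json")
    if (!is.null(bc$draws)) emit(bc$draws, "bootstrap_draws.csv")
  })
  perm <- stage("permutation", {
    pn <- permutation_null(prepared, pars, P = cfg$permutation_P,
                           seed = seeds[["permutation"]], arm = cfg$arm)
    emit(data.frame(draw = seq_len(pn$P),
                    best_reduction = pn$null_reductions),
         "permutation_draws.csv")
    emit(list(P = pn$P, observed = pn$observed,
              observed_percentile = pn$observed_percentile,
              null_median = pn$null_median, n_fallback = pn$n_fallback,
              n_failed = pn$n_failed), "permutation_summary.json")
    pn
  })
  scan <- stage("scan", {
    if (is.null(best)) return(NULL)
    cc <- best$conditions$cutoff
    bmn <- best$conditions$biomarker
    step <- max(abs(cc) * 0.03, 0.5)
    grid <- round(cc + step * seq(-cfg$scan_span, cfg$scan_span), 2)
    tab <- cutoff_scan(prepared, bmn, grid, arm = cfg$arm)
    emit(tab, "cutoff_scan.csv")
    tab
  })
  secondary <- stage("secondary", {
    if (is.null(best)) return(NULL)
    res <- lapply(cfg$endpoints, function(e)
      mmrm_endpoint(prepared, e, best, arm = cfg$arm))
    names(res) <- cfg$endpoints
    tab <- do.call(rbind, lapply(res, function(mm) do.call(rbind, lapply(
      list(mm$inside, mm$outside), function(s) data.frame(
        endpoint = s$endpoint, side = s$side, n_treated = s$n_treated,
        n_control = s$n_control, effect = s$effect, ci_low = s$ci_low,
        ci_high = s$ci_high, p_value = s$p_value,
        covariance = s$covariance_structure, stringsAsFactors = FALSE)))))
    emit(tab, "secondary_endpoints.csv")
    res
  })
  stage("decision", {
    if (is.null(best)) return(NULL)
    dfp <- arm_frame(prepared, cfg$arm)
    memb <- in_subgroup(dfp, best)
    ev <- evaluate_subgroup(prepared, best, cfg$arm)
    bmn <- best$conditions$biomarker
    it_row <- screen[screen$biomarker == bmn, , drop = FALSE]
    cands <- list(list(subgroup = best, n_in = sum(memb, na.rm = TRUE),
                       N = sum(!is.na(memb)), effect = ev$subgroup,
                       interaction_p = it_row[[paste0(cfg$arm, "_p")]],
                       secondary = secondary))
    names(cands) <- bmn
    emit(decision_summary(cands), "decision_summary.csv")
  })
  report$elapsed_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 2)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report$files <- c(report$files, "run_report.json")
  invisible(report)
}
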