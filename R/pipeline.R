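#' Experiment specification
#'
#' The end-to-end protocol: build a phantom "patient" (baseline anatomy plus
#' progression/regression training augmentations and a distinct replan
#' anatomy standing in for the re-imaged patient), train patient-specific
#' DQN and PPO agents round-robin over the three training anatomies, then
#' evaluate each agent on the replan anatomy against the default-priority
#' initial plan.
#'
#' @param phantom a [phantom_config()].
#' @param beams a [beam_config()].
#' @param progression_margin,regression_margin training-augmentation margins
#'   in mm (defaults +2 / -3).
#' @param replan_margin_mm per-axis anisotropic CTV expansion (mm) of the
#'   replan anatomy; combined with `replan_shift` it must differ from both
#'   training augmentations.
#' @param replan_shift list(structure, shift_mm): a rigid OAR shift applied
#'   to the replan anatomy.
#' @param dqn,ppo agent configurations (`NULL` skips that agent).
#' @param episodes training episodes per agent (default 100).
#' @param eval_horizon priority-adjustment steps at evaluation (default 15).
#' @param rx_boost planning-margin factor passed to the environments.
#' @param horizon training-episode horizon.
#' @param settings [optimizer_settings()] for all plan optimizations.
#' @param seed experiment seed; agent seeds are derived from it.
#' @return Object of class `experiment_spec`.
#' @export
experiment_spec <- function(phantom = phantom_config(),
                            beams = beam_config(),
                            progression_margin = 2,
                            regression_margin = 3,
                            replan_margin_mm = c(3, 1, 0),
                            replan_shift = list(structure = "PARL",
                                                shift_mm = c(4, 0, 0)),
                            dqn = dqn_config(),
                            ppo = ppo_config(),
                            episodes = 100L,
                            eval_horizon = 15L,
                            rx_boost = 1.08,
                            horizon = 15L,
                            settings = optimizer_settings(),
                            seed = 1L) {
  out <- list(phantom = phantom, beams = beams,
              progression_margin = progression_margin,
              regression_margin = regression_margin,
              replan_margin_mm = replan_margin_mm,
              replan_shift = replan_shift,
              dqn = dqn, ppo = ppo,
              episodes = as.integer(episodes),
              eval_horizon = as.integer(eval_horizon),
              rx_boost = rx_boost, horizon = as.integer(horizon),
              settings = settings, seed = as.integer(seed))
  class(out) <- "experiment_spec"
  out
}

masks_equal <- function(a, b) {
  all(vapply(names(a$masks),
             function(nm) identical(a$masks[[nm]], b$masks[[nm]]), logical(1)))
}

#' Build the anatomies of an experiment
#'
#' @param spec an [experiment_spec()].
#' @return list with `original`, `progression`, `regression`, `replan`
#'   phantoms. Errors if the replan anatomy coincides with any training
#'   anatomy.
#' @export
build_patient <- function(spec) {
  geom <- generate_phantom(spec$phantom, seed = spec$seed)
  prog <- augment_anatomy(geom, "progression", spec$progression_margin)
  regr <- augment_anatomy(geom, "regression", spec$regression_margin)
  replan <- augment_anatomy(geom, "progression", margin_mm = spec$replan_margin_mm)
  if (!is.null(spec$replan_shift))
    replan <- shift_structure(replan, spec$replan_shift$structure,
                              spec$replan_shift$shift_mm)
  for (tr in list(geom, prog, regr))
    if (masks_equal(replan, tr))
      stop("replan anatomy coincides with a training anatomy; ",
           "choose a different replan_margin_mm / replan_shift")
  list(original = geom, progression = prog, regression = regr, replan = replan)
}

make_env <- function(geom, spec) {
  dinf <- compute_dose_influence(geom, spec$beams)
  planning_env(geom, dinf, horizon = spec$horizon,
               settings = spec$settings, rx_boost = spec$rx_boost)
}

#' Run a full replanning experiment
#'
#' Builds the patient anatomies, precomputes their dose-influence matrices,
#' trains the configured agents patient-specifically (episodes cycling over
#' original / progression / regression), and evaluates each greedily on the
#' held-out replan anatomy. Deterministic per seed. With `episodes = 0` only
#' the default-priority initial plan is evaluated.
#'
#' @param spec an [experiment_spec()].
#' @param outdir optional directory; when given, the report, per-goal
#'   dosimetric table, training logs and episode traces are written there
#'   (CSV/JSON).
#' @param verbose print stage progress.
#' @return Object of class `evaluation_report`: `initial_score`,
#'   `initial_plan` (plan_score of the default-priority plan on the replan
#'   anatomy), `agents` (per-agent evaluation: best/final scores, actions,
#'   score trajectory, training log), `dosimetric_table` (metric rows x plan
#'   columns), `anatomies`, `spec`.
#' @export
run_experiment <- function(spec, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage %-12s %6.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  pat <- stage("anatomy", build_patient(spec))
  train_envs <- stage("dose", lapply(pat[c("original", "progression", "regression")],
                                     make_env, spec = spec))
  eval_env <- stage("replan-dose", make_env(pat$replan, spec))

  env_reset(eval_env)
  initial_plan <- eval_env$score
  initial_dose <- eval_env$dose
  initial_score <- initial_plan$total
  say("initial plan score on replan anatomy: %.2f", initial_score)

  agents <- list()
  agent_cfgs <- Filter(Negate(is.null), list(dqn = spec$dqn, ppo = spec$ppo))
  if (spec$episodes > 0) {
    for (nm in names(agent_cfgs)) {
      cfg <- agent_cfgs[[nm]]
      cfg$seed <- spec$seed + cfg$seed
      ag <- stage(paste0("train-", nm),
                  train_agent(cfg, train_envs, episodes = spec$episodes))
      ev <- stage(paste0("eval-", nm),
                  evaluate_agent(ag, eval_env, horizon = spec$eval_horizon))
      # rescore the best intermediate plan to get its per-goal table
      best_dose <- compute_dose(eval_env$dinf, eval_env$best$x)
      agents[[nm]] <- list(agent = ag, evaluation = ev,
                           best_dose = best_dose,
                           best_plan = score_plan(best_dose, pat$replan,
                                                  eval_env$goals))
    }
  }

  tab <- dosimetric_table(initial_plan, agents)
  out <- list(initial_score = initial_score, initial_plan = initial_plan,
              initial_dose = initial_dose,
              agents = agents, dosimetric_table = tab,
              anatomies = pat, spec = spec)
  class(out) <- "evaluation_report"
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Metric rows x plan columns table (initial / per-agent best plans).
dosimetric_table <- function(initial_plan, agents) {
  tab <- initial_plan$per_goal[, c("structure", "label")]
  tab$initial_value <- initial_plan$per_goal$value
  tab$initial_points <- initial_plan$per_goal$points
  for (nm in names(agents)) {
    pg <- agents[[nm]]$best_plan$per_goal
    tab[[paste0(nm, "_value")]] <- pg$value
    tab[[paste0(nm, "_points")]] <- pg$points
  }
  tab
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Replanning experiment report\n")
  cat(sprintf("  initial plan score (default priorities): %.2f\n", x$initial_score))
  for (nm in names(x$agents)) {
    ev <- x$agents[[nm]]$evaluation
    cat(sprintf("  %-4s best %.2f (step %d), final %.2f\n",
                toupper(nm), ev$best_score, ev$best_step, ev$final_score))
  }
  invisible(x)
}

#' Summarize evaluation reports across seeds or phantoms
#'
#' Mean and standard deviation of each agent's best plan score over a
#' collection of reports (no inferential statistics).
#'
#' @param reports list of `evaluation_report` objects (or a single one).
#' @return data.frame with one row per plan (initial and each agent):
#'   `plan`, `mean`, `sd`, `n`.
#' @export
compare_agents <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "evaluation_report")))
  plans <- c("initial", unique(unlist(lapply(reports, function(r) names(r$agents)))))
  rows <- lapply(plans, function(p) {
    v <- vapply(reports, function(r) {
      if (p == "initial") r$initial_score
      else if (p %in% names(r$agents)) r$agents[[p]]$evaluation$best_score
      else NA_real_
    }, numeric(1))
    v <- v[!is.na(v)]
    data.frame(plan = p, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  })
  do.call(rbind, rows)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$dosimetric_table,
                   file.path(outdir, "dosimetric_table.csv"), row.names = FALSE)
  summ <- list(initial_score = report$initial_score,
               agents = lapply(report$agents, function(a) {
                 ev <- a$evaluation
                 list(best_score = ev$best_score, best_step = ev$best_step,
                      final_score = ev$final_score, actions = ev$actions,
                      scores = ev$scores)
               }))
  jsonlite::write_json(summ, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$agents)) {
    utils::write.csv(report$agents[[nm]]$agent$log,
                     file.path(outdir, paste0("training_log_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(report$agents[[nm]]$evaluation$trace,
                     file.path(outdir, paste0("eval_trace_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(outdir)
}
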