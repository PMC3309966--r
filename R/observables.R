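#' Summary observables of a converged cycle
#'
#' Cycle-averaged quantities used to compare the model with population
#' measurements: the mean *dnaA* expression rate per cell
#' `(1/tau) * integral of Q`, the same rate per gene copy, the mean RNAP
#' count `(1/tau) * integral of P`, the mean DnaA-ATP count, the
#' initiation potential at initiation `r(X)`, and the peak-to-trough
#' amplitude of `r` over the cycle.  Integrals are trapezoidal on the
#' solution grid; `r(X)` is read exactly at the grid node `t = X`.
#'
#' @param trajectory A converged [solve_cyclic_steady_state] result.
#' @return One-row data frame with columns `tau`, `mean_expression`,
#'   `mean_expression_per_gene`, `mean_P`, `mean_A_minus`, `r_X`,
#'   `r_amplitude`.
#' @examples
#' \donttest{
#' traj <- solve_cyclic_steady_state(build_schedule(cell_cycle_periods(21)),
#'                                   model_parameters(), step = 21 / 2000)
#' summarize_trajectory(traj)
#' }
#' @export
summarize_trajectory <- function(trajectory) {
  if (!inherits(trajectory, "dnaa_trajectory"))
    stop("summaries are computed only from converged cyclic ",
         "steady-state trajectories", call. = FALSE)
  conv <- attr(trajectory, "convergence")
  if (is.null(conv))
    stop("trajectory carries no convergence record", call. = FALSE)
  tau <- attr(trajectory, "schedule")$periods$tau
  out <- data.frame(
    tau = tau,
    mean_expression = trapz(trajectory$t, trajectory$Q) / tau,
    mean_expression_per_gene =
      trapz(trajectory$t, trajectory$Q / trajectory$Theta) / tau,
    mean_P = trapz(trajectory$t, trajectory$P) / tau,
    mean_A_minus = trapz(trajectory$t, trajectory$A_minus) / tau,
    r_X = attr(trajectory, "r_X"),
    r_amplitude = max(trajectory$r) - min(trajectory$r))
  stopifnot(all(is.finite(unlist(out))))
  out
}

# Trapezoidal quadrature on an (ordered, possibly non-uniform) grid.
trapz <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n])) / 2
}

#' Sensitivity of the initiation threshold to origin-affinity co-variation
#'
#' Scenario 1 keeps the threshold constant by letting the DnaA-ATP
#' binding affinity at the *dnaA* promoter vary with growth rate while
#' assuming the affinity at the origin does not.  If instead the origin
#' affinity co-varied by the same factor, the DnaA-ATP level required
#' for a fixed origin-site occupancy would scale inversely with the
#' binding weight: in the thermodynamic occupancy model the occupancy
#' depends on `w_ori * r`, so the required threshold is
#' `r_required(tau) = r* / f(tau)` with
#' `f(tau) = w_ad'(tau) / w_ad'(21)` the promoter-affinity factor of
#' the scenario-1 trend.  The maximum relative change of `r_required`
#' across the grid measures how robust the constant-threshold picture
#' is to this assumption.
#'
#' @param trends A [scan_trends] table for scenario 1a or 1b.
#' @param affinity_factor Optional explicit factor vector `f(tau)`
#'   (same length as `trends$tau`), overriding the `w_ad` column.
#' @return List with `max_rel_change` (dimensionless), `percent`
#'   (the same as a percentage) and the per-tau table.
#' @export
origin_affinity_sensitivity <- function(trends, affinity_factor = NULL) {
  stopifnot(inherits(trends, "dnaa_trend") || is.data.frame(trends))
  if (is.null(affinity_factor)) {
    if (!attr(trends, "scenario") %in% c("1a", "1b"))
      stop("origin-affinity co-variation is defined for scenario 1 ",
           "trends (the promoter affinity floats there)", call. = FALSE)
    affinity_factor <- trends$w_ad / trends$w_ad[1]
  }
  stopifnot(length(affinity_factor) == nrow(trends),
            all(affinity_factor > 0))
  r_star <- attr(trends, "r_star")
  r_required <- r_star / affinity_factor
  rel <- abs(r_required / r_required[1] - 1)
  list(max_rel_change = max(rel), percent = 100 * max(rel),
       table = data.frame(tau = trends$tau,
                          affinity_factor = affinity_factor,
                          r_required = r_required, rel_change = rel))
}

#' Scan the fixed-parameter model over doubling times
#'
#' Solves the baseline cyclic steady state at each doubling time with
#' one fixed parameter set and records the threshold `r(X)` together
#' with the cycle-averaged observables.  With fixed parameters the
#' threshold varies across growth rates — the failure that motivates
#' the constant-threshold transformation.
#'
#' @param tau_grid Doubling times, minutes.
#' @param params Baseline [model_parameters].
#' @param step_frac RK4 target step as a fraction of tau.
#' @param variant Optional [variant_config].
#' @param ... Passed to [solve_cyclic_steady_state].
#' @return Data frame: one [summarize_trajectory] row per tau.
#' @export
fixed_params_scan <- function(tau_grid = 21:60,
                              params = model_parameters(),
                              step_frac = 1 / 5000, variant = NULL, ...) {
  rows <- lapply(tau_grid, function(tau) {
    sched <- build_schedule(cell_cycle_periods(tau),
                            k_lambda = params$k_lambda)
    traj <- solve_cyclic_steady_state(sched, params,
                                      step = tau * step_frac,
                                      variant = variant, ...)
    summarize_trajectory(traj)
  })
  do.call(rbind, rows)
}

#' Observable trends along a constant-threshold scenario
#'
#' Re-solves the cyclic steady state with each transformed parameter
#' set of a [scan_trends] table and summarizes the observables, giving
#' the model's predicted growth-rate trends of mean RNAP and mean
#' *dnaA* expression per cell.
#'
#' @param trends A [scan_trends] result.
#' @param step_frac RK4 target step as a fraction of tau.
#' @param ... Passed to [solve_cyclic_steady_state].
#' @return Data frame: one [summarize_trajectory] row per tau.
#' @export
observable_trends <- function(trends, step_frac = 1 / 5000, ...) {
  base_params <- attr(trends, "base_params")
  rows <- lapply(seq_len(nrow(trends)), function(i) {
    tau <- trends$tau[i]
    sched <- build_schedule(cell_cycle_periods(tau),
                            k_lambda = base_params$k_lambda)
    p <- modify_parameters(base_params, k_A = trends$k_A[i],
                           c1 = trends$c1[i], c2 = trends$c2[i],
                           P0 = trends$P0[i], k_R = trends$k_R[i])
    traj <- solve_cyclic_steady_state(sched, p, step = tau * step_frac,
                                      ...)
    summarize_trajectory(traj)
  })
  do.call(rbind, rows)
}

#' In-silico Hda perturbation of the RIDA rate
#'
#' Starting from a constant-threshold parameter set (a [scan_trends]
#' table), multiplies the RIDA rate by `fold` at every doubling time
#' while leaving all other parameters at their transformed values, and
#' records the resulting threshold `r(X; tau)`.  The perturbation makes
#' the threshold growth-rate-dependent again, most strongly at slow
#' growth: a faster RIDA rate raises the threshold at slow growth and a
#' slower rate lowers it.
#'
#' @param trends A [scan_trends] result.
#' @param fold Multiplicative change of `k_R` (e.g. 10 or 0.1).
#' @param step_frac RK4 target step as a fraction of tau.
#' @param ... Passed to [solve_cyclic_steady_state].
#' @return Data frame with columns `tau`, `fold`, `r_X`, `r_star`,
#'   `rel_deviation`.
#' @export
hda_perturbation <- function(trends, fold, step_frac = 1 / 5000, ...) {
  stopifnot(fold > 0)
  base_params <- attr(trends, "base_params")
  r_star <- attr(trends, "r_star")
  rows <- lapply(seq_len(nrow(trends)), function(i) {
    tau <- trends$tau[i]
    sched <- build_schedule(cell_cycle_periods(tau),
                            k_lambda = base_params$k_lambda)
    p <- modify_parameters(base_params, k_A = trends$k_A[i],
                           c1 = trends$c1[i], c2 = trends$c2[i],
                           P0 = trends$P0[i],
                           k_R = fold * trends$k_R[i])
    traj <- solve_cyclic_steady_state(sched, p, step = tau * step_frac,
                                      ...)
    rX <- attr(traj, "r_X")
    data.frame(tau = tau, fold = fold, r_X = rX, r_star = r_star,
               rel_deviation = (rX - r_star) / r_star)
  })
  do.call(rbind, rows)
}

#' Run a named experiment and export its tables
#'
#' Drives the full tau-scan experiments behind one entry point.  All
#' experiments are deterministic given the configuration (the model has
#' no random component).  Results are returned and, when `out_dir` is
#' given, written as CSV plus a JSON copy embedding the resolved
#' configuration.
#'
#' Available experiments: `"fixed-params-scan"` (fixed parameters, the
#' threshold drifts with tau), `"threshold-scan"` (constant-threshold
#' transformation for one scenario), `"observable-trends"` (mean RNAP
#' and mean expression along a scenario), `"amplitude-grid"`
#' (oscillation amplitude across autorepression and RIDA strength),
#' `"hda-perturbation"` (RIDA rate scaled 10-fold up and down on
#' transformed parameters), `"origin-affinity-sensitivity"` (threshold
#' robustness under origin-affinity co-variation, scenario 1).
#'
#' @param experiment Experiment name (see above).
#' @param scenario Scenario id for the experiments that need one.
#' @param tau_grid Doubling times, minutes.
#' @param params Baseline [model_parameters].
#' @param step_frac RK4 target step as a fraction of tau.
#' @param out_dir Optional output directory.
#' @param ... Experiment-specific extras: `folds` (hda-perturbation),
#'   `c2_values`, `k_R_values`, `taus` (amplitude-grid).
#' @return A list with the experiment's table(s) and the resolved
#'   configuration, invisibly when writing to disk.
#' @export
run_experiment <- function(experiment = c("fixed-params-scan",
                                          "threshold-scan",
                                          "observable-trends",
                                          "amplitude-grid",
                                          "hda-perturbation",
                                          "origin-affinity-sensitivity"),
                           scenario = "1b", tau_grid = 21:60,
                           params = model_parameters(),
                           step_frac = 1 / 5000, out_dir = NULL, ...) {
  experiment <- match.arg(experiment)
  extras <- list(...)
  config <- list(experiment = experiment, scenario = scenario,
                 tau_grid = tau_grid, step_frac = step_frac,
                 params = unclass(params), extras = extras)
  result <- switch(experiment,
    "fixed-params-scan" = list(
      scan = fixed_params_scan(tau_grid, params, step_frac)),
    "threshold-scan" = list(
      trends = scan_trends(scenario_spec(scenario), tau_grid, params,
                           step_frac)),
    "observable-trends" = {
      tr <- scan_trends(scenario_spec(scenario), tau_grid, params,
                        step_frac, verify = FALSE)
      list(trends = tr, observables = observable_trends(tr, step_frac))
    },
    "amplitude-grid" = {
      taus <- extras$taus %||% c(21, 50)
      c2v <- extras$c2_values %||% c(6, 12, 24)
      kRv <- extras$k_R_values %||% c(5, 10, 20)
      list(grid = do.call(rbind, lapply(taus, function(tt)
        amplitude_grid(tt, c2v, kRv, params, step = tt * step_frac))))
    },
    "hda-perturbation" = {
      folds <- extras$folds %||% c(0.1, 10)
      tr <- scan_trends(scenario_spec(scenario), tau_grid, params,
                        step_frac, verify = FALSE)
      runs <- lapply(folds, function(f)
        tryCatch(hda_perturbation(tr, f, step_frac),
                 error = function(e) {
                   warning("RIDA fold ", f, " infeasible: ",
                           conditionMessage(e), call. = FALSE)
                   data.frame(tau = NA_real_, fold = f, r_X = NA_real_,
                              r_star = attr(tr, "r_star"),
                              rel_deviation = NA_real_,
                              error = conditionMessage(e))
                 }))
      ok <- vapply(runs, function(x) is.null(x$error), logical(1))
      list(trends = tr,
           perturbation = do.call(rbind, runs[ok]),
           infeasible = if (any(!ok)) do.call(rbind, runs[!ok]))
    },
    "origin-affinity-sensitivity" = {
      sc <- if (scenario %in% c("1a", "1b")) scenario else "1b"
      tr <- scan_trends(scenario_spec(sc), tau_grid, params, step_frac,
                        verify = FALSE)
      sens <- origin_affinity_sensitivity(tr)
      list(trends = tr, sensitivity = sens$table,
           max_rel_change = sens$max_rel_change,
           percent = sens$percent)
    })
  result$config <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(result)) {
      if (is.data.frame(result[[nm]]))
        utils::write.csv(format(as.data.frame(result[[nm]]),
                                digits = 12, trim = TRUE),
                         file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(result, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    return(invisible(result))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
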