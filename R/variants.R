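#' Configuration of the model variants
#'
#' Switches for the published extensions of the core circuit, each a
#' decorator on the core dynamics.  At the neutral defaults
#' (`delay_td = 0`, `coop = NULL`, `datA_capacity = 0`,
#' `distributed_sites = 0`, `rho = 0`, `rida_fold = 1`) every variant
#' reduces exactly to the core model.
#'
#' * `delay_td` — translation delay (min): DnaA appearing at time `t`
#'   was transcribed at `t - delay_td`.
#' * `coop` — cooperative autorepression, `list(omega, k1, k2)`:
#'   `omega` is the cooperativity factor and `k1`, `k2` the binding
#'   affinities of the two operator sites in units of the initiation
#'   potential `r` (affinity constants multiplied by the
#'   genome-length/non-specific-site proportionality).  The published
#'   promoter form is
#'   `Q = k_A * Theta / (1 + (c1*Lambda/P) * (1 + r/k1 + r^2*omega/(k1*k2)) / (1 + r/k1))`.
#' * `datA_capacity` — DnaA-ATP molecules sequestered per datA copy
#'   (the published estimate is 300); datA sits near the origin, so its
#'   copy number doubles at initiation.  Sequestration is instantaneous
#'   and capacity-limited; only the unsequestered pool feeds the
#'   initiation potential and promoter repression.
#' * `distributed_sites` — high-affinity DnaA boxes per genome
#'   equivalent (published estimate about 300).  New sites appear at
#'   rate `distributed_sites * k_lambda` per fork pair and each absorbs
#'   one DnaA-ATP, which acts as an additive rescaling of the RIDA rate:
#'   `k_R -> k_R + distributed_sites * k_lambda`.
#' * `rho` — recycling rate of DnaA-ADP back to DnaA-ATP at genomic
#'   recycling regions, molecules/min per genome equivalent; enters as
#'   `k_R -> max(0, k_R - rho * Lambda / F)` inside the fork-coupled
#'   sink.
#' * `rida_fold` — multiplicative perturbation of `k_R` (the in-silico
#'   Hda over/under-expression experiment).
#'
#' @param delay_td Translation delay, minutes (>= 0, < tau).
#' @param coop `NULL` or `list(omega, k1, k2)`.
#' @param datA_capacity Molecules per datA copy (>= 0).
#' @param distributed_sites Sites per genome equivalent (>= 0).
#' @param rho Recycling rate, molecules/min per genome equivalent.
#' @param rida_fold Multiplier on `k_R` (> 0).
#' @return An object of class `variant_config`.
#' @examples
#' variant_config(datA_capacity = 300)
#' @export
variant_config <- function(delay_td = 0, coop = NULL, datA_capacity = 0,
                           distributed_sites = 0, rho = 0, rida_fold = 1) {
  stopifnot(delay_td >= 0, datA_capacity >= 0, distributed_sites >= 0,
            rho >= 0, rida_fold > 0)
  if (!is.null(coop)) {
    stopifnot(is.list(coop), all(c("omega", "k1", "k2") %in% names(coop)))
    if (coop$k1 <= 0 || coop$k2 <= 0)
      stop("cooperative promoter affinities k1, k2 must be positive",
           call. = FALSE)
    if (coop$omega < 0)
      stop("cooperativity omega must be non-negative", call. = FALSE)
  }
  structure(list(delay_td = delay_td, coop = coop,
                 datA_capacity = datA_capacity,
                 distributed_sites = distributed_sites, rho = rho,
                 rida_fold = rida_fold),
            class = "variant_config")
}

#' @export
print.variant_config <- function(x, ...) {
  cat("Model variant configuration\n")
  cat("  delay_td =", x$delay_td, "min; datA capacity =", x$datA_capacity,
      "; distributed sites =", x$distributed_sites,
      "/geq; rho =", x$rho, "; rida_fold =", x$rida_fold, "\n")
  if (!is.null(x$coop))
    cat("  cooperative promoter: omega =", x$coop$omega, ", k1 =",
        x$coop$k1, ", k2 =", x$coop$k2, "\n")
  invisible(x)
}

#' Free (unsequestered) DnaA-ATP under datA titration
#'
#' Each datA copy instantaneously sequesters up to `datA_capacity`
#' DnaA-ATP molecules; datA copies track origin number (`Theta`,
#' doubling at initiation).  With no datA variant the pool is untouched.
#'
#' @param params A [model_parameters] object.
#' @param variant `NULL` or a [variant_config].
#' @param A_minus Total DnaA-ATP (vectorized).
#' @param Theta datA/origin copy number (vectorized).
#' @param ctx Internal integration context (unused here; kept for a
#'   uniform decorator signature).
#' @return Free DnaA-ATP available for origin binding and repression.
#' @export
variant_free_A <- function(params, variant, A_minus, Theta, ctx = NULL) {
  if (is.null(variant) || variant$datA_capacity == 0) return(A_minus)
  pmax(0, A_minus - variant$datA_capacity * Theta)
}

#' Promoter rate under the active variant
#'
#' Dispatches between the core non-cooperative promoter and the
#' cooperative two-site form, applying datA sequestration to the
#' repressing pool first.  With `variant = NULL` this is exactly
#' [promoter_rate].
#'
#' @inheritParams variant_free_A
#' @param Theta,Lambda,P,A_minus Promoter-state quantities (vectorized).
#' @param free_A Optional precomputed free pool.
#' @return Synthesis rate `Q`, molecules/min.
#' @export
variant_Q <- function(params, variant, Theta, Lambda, P, A_minus,
                      ctx = NULL, free_A = NULL) {
  if (is.null(free_A))
    free_A <- variant_free_A(params, variant, A_minus, Theta, ctx)
  if (!is.null(variant) && !is.null(variant$coop)) {
    co <- variant$coop
    r <- free_A / Lambda
    occ <- (1 + r / co$k1 + r^2 * co$omega / (co$k1 * co$k2)) /
      (1 + r / co$k1)
    params$k_A * Theta / (1 + params$c1 * Lambda / P * occ)
  } else {
    params$k_A * Theta / (1 + params$c1 * Lambda / P +
                            params$c2 * free_A / P)
  }
}

#' Effective RIDA rate under the active variant
#'
#' Applies, in order: the Hda perturbation (`k_R * rida_fold`), the
#' distributed high-affinity sites (additive `distributed_sites *
#' k_lambda`, the rate at which replication creates new absorbing
#' sites per fork pair), and the recycling correction
#' `max(0, k_R - rho * Lambda / F)`.  Intervals with `F = 0` have no
#' fork-coupled sink regardless.
#'
#' @inheritParams variant_free_A
#' @param Lambda Genome length(s) at which the rate is evaluated.
#' @param F Fork-pair count(s).
#' @return Effective per-fork-pair RIDA rate(s), molecules/min.
#' @export
effective_kR <- function(params, variant, Lambda, F) {
  kR <- params$k_R
  if (!is.null(variant)) {
    kR <- kR * variant$rida_fold +
      variant$distributed_sites * params$k_lambda
    if (variant$rho > 0) {
      kR <- rep_len(kR, length(F))
      pos <- F > 0
      kR[pos] <- pmax(0, kR[pos] - variant$rho * Lambda[pos] / F[pos])
    }
  }
  rep_len(kR, length(F))
}

# Delayed-source solver: the promoter output seen at time t was decided
# at t - delay_td on the periodic orbit.  History for t < delay_td wraps
# into the mother cell's end-of-cycle output, halved at division (each
# daughter receives half the mother's production).  The history is
# seeded from the converged no-delay orbit and the (history -> orbit)
# map is iterated to a fixed point; with the source frozen, the cyclic
# birth value is reached in a single closed-form step per iteration.
solve_delayed <- function(ctx, step, tol, max_cycles, A0_init) {
  td <- ctx$variant$delay_td
  tau <- ctx$tau
  if (td >= tau)
    stop("translation delay must be smaller than the doubling time",
         call. = FALSE)
  # seed: no-delay converged orbit
  base_variant <- ctx$variant
  base_variant$delay_td <- 0
  base <- solve_cyclic_steady_state(ctx$schedule, ctx$params, step = step,
                                    tol = tol, max_cycles = max_cycles,
                                    A0_init = A0_init,
                                    variant = base_variant)
  g <- ctx$grid
  N <- ctx$N
  Q_of <- function(A) {       # promoter output at nodes and midpoints
    A_mid <- (A[-(N + 1)] + A[-1]) / 2
    list(node = variant_Q(ctx$params, ctx$variant,
                          c(g$Theta, g$Theta[N]), ctx$Lambda,
                          ctx$P_node, pmax(A, 0), ctx),
         mid = variant_Q(ctx$params, ctx$variant, g$Theta,
                         ctx$Lambda_mid, ctx$P_mid, pmax(A_mid, 0), ctx))
  }
  lag_lookup <- function(tq) {
    s <- tq - td
    wrap <- s < 0
    s[wrap] <- s[wrap] + tau
    list(s = s, wrap = wrap)
  }
  # piecewise-linear history on the combined node + midpoint grid
  t_hist <- c(g$t, ctx$t_mid)
  ord <- order(t_hist)
  t_hist <- t_hist[ord]
  interp <- function(Q, s) {
    stats::approx(t_hist, c(Q$node, Q$mid)[ord], xout = s, rule = 2)$y
  }
  A <- base$A_minus
  cycles <- 0L
  repeat {
    Q <- Q_of(A)
    ln <- lag_lookup(g$t)
    lm <- lag_lookup(g$t[-(N + 1)] + g$h / 2)
    src <- list(node = interp(Q, ln$s) * ifelse(ln$wrap, 0.5, 1),
                mid = interp(Q, lm$s) * ifelse(lm$wrap, 0.5, 1))
    ctx$source_override <- src
    # with a frozen source the cyclic birth value is G = net cycle gain
    gain <- rk4_cycle(ctx, 0)[N + 1]
    A_new <- rk4_cycle(ctx, gain)
    cycles <- cycles + 1L
    residual <- max(abs(A_new - A)) / max(1, max(abs(A_new)))
    A <- A_new
    if (residual <= max(tol, 1e-12) || cycles >= max_cycles) break
  }
  if (residual > max(tol, 1e-12))
    stop("delayed-source iteration did not converge (residual ",
         format(residual), ")", call. = FALSE)
  finish_trajectory(ctx, A, cycles, residual)
}

#' Peak-to-trough amplitude of the initiation-potential oscillation
#'
#' Convenience scan over an autorepression-strength (`c2`) by RIDA-rate
#' (`k_R`) grid: for each pair the cyclic steady state is solved and the
#' amplitude `max(r) - min(r)` over the cycle recorded.  Both stronger
#' autorepression and faster RIDA damp the oscillation of the
#' DnaA-ATP:genome ratio.
#'
#' @param tau Doubling time, minutes.
#' @param c2_values,k_R_values Grids of parameter values.
#' @param base_params Baseline [model_parameters].
#' @param step RK4 target step.
#' @param ... Passed to [solve_cyclic_steady_state].
#' @return Data frame with columns `tau`, `c2`, `k_R`, `r_min`, `r_max`,
#'   `amplitude`.
#' @export
amplitude_grid <- function(tau, c2_values, k_R_values,
                           base_params = model_parameters(),
                           step = tau / 5000, ...) {
  sched <- build_schedule(cell_cycle_periods(tau),
                          k_lambda = base_params$k_lambda)
  out <- expand.grid(tau = tau, c2 = c2_values, k_R = k_R_values,
                     KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    p <- modify_parameters(base_params, c2 = out$c2[i], k_R = out$k_R[i])
    traj <- solve_cyclic_steady_state(sched, p, step = step, ...)
    c(r_min = min(traj$r), r_max = max(traj$r))
  })
  res <- do.call(rbind, res)
  out$r_min <- res[, "r_min"]
  out$r_max <- res[, "r_max"]
  out$amplitude <- out$r_max - out$r_min
  out
}

# Rebuild a dnaa_parameters object with some fields replaced, keeping
# the weight convention consistent (c1/c2 re-derive w_pd/w_ad).
modify_parameters <- function(params, ...) {
  repl <- list(...)
  stopifnot(all(names(repl) %in%
                  c("k_A", "P0", "k_R", "k_lambda", "c1", "c2")))
  args <- list(k_A = params$k_A, N_NS = params$N_NS, P0 = params$P0,
               k_R = params$k_R, k_lambda = params$k_lambda,
               c1 = params$c1, c2 = params$c2, w_pd = params$w_pd,
               w_ad = params$w_ad,
               rnap_growth = params$rnap_growth,
               P0_convention = params$P0_convention)
  args[names(repl)] <- repl
  do.call(model_parameters, args)
}
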