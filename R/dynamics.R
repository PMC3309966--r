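#' Kinetic and thermodynamic parameters of the DnaA circuit
#'
#' Parameter set of the minimal DnaA-ATP model.  The promoter source term
#' uses the thermodynamic (Shea-Ackers) occupancy of the *dnaA* promoter
#' by RNA polymerase, with all DNA-binding proteins partitioned between
#' specific sites and the non-specific genomic background.  Two derived
#' constants enter the rate law: `c1 = w_pd * N_NS`, the RNAP
#' specific-to-non-specific weight times the number of non-specific sites
#' per genome equivalent (so `c1 * Lambda / P` is the RNAP partition
#' factor when `Lambda` is in genome equivalents), and `c2 = w_pd / w_ad`,
#' the relative weight of DnaA-ATP at its repressor sites.  `c2 = 0`
#' switches autorepression off; `k_R = 0` switches RIDA off.
#'
#' `c1` and `c2` may be supplied directly (e.g. for transformed parameter
#' sets); the Boltzmann weights are then recovered through the same
#' `N_NS` convention, keeping affinity trends comparable across runs.
#'
#' @param k_A Basal transcription rate, molecules/min per gene copy.
#' @param w_pd RNAP specific/non-specific Boltzmann weight
#'   `exp(d_eps_pd / kBT)`, dimensionless.
#' @param w_ad DnaA-ATP specific/non-specific weight
#'   `exp(d_eps_ad / kBT)`, dimensionless.
#' @param N_NS Non-specific binding sites per genome equivalent.
#' @param P0 RNA polymerase molecules at cell birth.
#' @param k_R RIDA rate per fork pair, molecules/min.
#' @param k_lambda Replication rate per fork pair, genome equivalents/min.
#' @param c1,c2 Optional direct values for the derived constants,
#'   overriding the weight-based construction.
#' @param rnap_growth RNAP growth law over the cycle: `"exponential"`
#'   (default, constant concentration in an exponentially growing cell)
#'   or `"linear"`.
#' @param P0_convention Whether `P0` is the birth value (`"birth"`,
#'   default) or the cycle average (`"cycle_average"`, in which case the
#'   birth value is `P0 * log(2)` under exponential RNAP growth).
#' @return An object of class `dnaa_parameters`.
#' @examples
#' p <- model_parameters()
#' c(c1 = p$c1, c2 = p$c2)
#' @export
model_parameters <- function(k_A = 75, w_pd = 12 / 10000, w_ad = 1 / 10000,
                             N_NS = 5e6, P0 = 5050, k_R = 10,
                             k_lambda = 1 / 40, c1 = NULL, c2 = NULL,
                             rnap_growth = c("exponential", "linear"),
                             P0_convention = c("birth", "cycle_average")) {
  rnap_growth <- match.arg(rnap_growth)
  P0_convention <- match.arg(P0_convention)
  if (is.null(c1)) c1 <- w_pd * N_NS else w_pd <- c1 / N_NS
  if (is.null(c2)) {
    c2 <- if (w_ad > 0) w_pd / w_ad else 0
  } else {
    w_ad <- if (c2 > 0) w_pd / c2 else 0
  }
  vals <- c(k_A = k_A, w_pd = w_pd, w_ad = w_ad, N_NS = N_NS, P0 = P0,
            k_R = k_R, k_lambda = k_lambda, c1 = c1, c2 = c2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all parameters must be finite and non-negative", call. = FALSE)
  if (k_lambda <= 0) stop("k_lambda must be positive", call. = FALSE)
  if (P0 <= 0) stop("P0 must be positive", call. = FALSE)
  structure(list(k_A = k_A, w_pd = w_pd, w_ad = w_ad, N_NS = N_NS,
                 P0 = P0, k_R = k_R, k_lambda = k_lambda, c1 = c1,
                 c2 = c2, rnap_growth = rnap_growth,
                 P0_convention = P0_convention),
            class = "dnaa_parameters")
}

#' @export
print.dnaa_parameters <- function(x, ...) {
  cat("DnaA circuit parameters\n")
  cat(sprintf("  k_A = %g molecules/min/gene, k_R = %g molecules/min/fork pair\n",
              x$k_A, x$k_R))
  cat(sprintf("  w_pd = %g, w_ad = %g, N_NS = %g per genome equivalent\n",
              x$w_pd, x$w_ad, x$N_NS))
  cat(sprintf("  derived: c1 = %g, c2 = %g\n", x$c1, x$c2))
  cat(sprintf("  P0 = %g molecules (%s, %s growth), k_lambda = %g geq/min\n",
              x$P0, x$P0_convention, x$rnap_growth, x$k_lambda))
  invisible(x)
}

# Birth-time RNAP count under the chosen P0 convention.
rnap_birth <- function(params) {
  if (params$P0_convention == "cycle_average") {
    if (params$rnap_growth == "exponential") params$P0 * log(2)
    else params$P0 / 1.5
  } else {
    params$P0
  }
}

#' RNA polymerase profile over the cell cycle
#'
#' RNAP numbers grow from birth to division and halve at division.  The
#' default law is exponential, `P(t) = P0 * 2^(t / tau)`, corresponding
#' to constant RNAP concentration in an exponentially growing cell; a
#' linear alternative `P(t) = P0 * (1 + t / tau)` is available and gives
#' nearly indistinguishable dynamics.
#'
#' @param P0 RNAP molecules at birth.
#' @param tau Doubling time, minutes.
#' @param t Time(s) within the cycle, minutes, in `[0, tau]`.
#' @param growth `"exponential"` or `"linear"`.
#' @return RNAP molecule count(s) at `t`.
#' @examples
#' rnap_profile(5050, 21, c(0, 10.5, 21))
#' @export
rnap_profile <- function(P0, tau, t, growth = c("exponential", "linear")) {
  growth <- match.arg(growth)
  stopifnot(all(t >= 0 & t <= tau))
  if (growth == "exponential") P0 * 2^(t / tau) else P0 * (1 + t / tau)
}

#' Promoter activity of the dnaA gene
#'
#' Rate of DnaA synthesis (molecules/min, all newly made DnaA being
#' ATP-bound): `Q = k_A * Theta / (1 + c1 * Lambda / P + c2 * A_minus / P)`.
#' The denominator is the inverse equilibrium probability that RNAP
#' occupies the promoter: `c1 * Lambda / P` is titration of RNAP by the
#' non-specific genomic background and `c2 * A_minus / P` is repression
#' by DnaA-ATP bound at its operator sites.  `Q` is linear in gene dosage
#' `Theta`, bounded by `k_A * Theta`, and decreasing in both `Lambda`
#' and `A_minus`.
#'
#' @param params A [model_parameters] object.
#' @param Theta Gene (promoter) copies.
#' @param Lambda Genome length, genome equivalents.
#' @param P RNAP molecules (> 0).
#' @param A_minus DnaA-ATP molecules.
#' @return Synthesis rate `Q` in molecules/min.
#' @examples
#' promoter_rate(model_parameters(), Theta = 4, Lambda = 2.875,
#'               P = 5050, A_minus = 0)
#' @export
promoter_rate <- function(params, Theta, Lambda, P, A_minus) {
  stopifnot(inherits(params, "dnaa_parameters"))
  if (any(P <= 0))
    stop("promoter occupancy is undefined for P <= 0", call. = FALSE)
  if (any(Theta < 0 | Lambda < 0 | A_minus < 0))
    stop("Theta, Lambda and A_minus must be non-negative", call. = FALSE)
  params$k_A * Theta / (1 + params$c1 * Lambda / P + params$c2 * A_minus / P)
}

#' Time derivatives of the DnaA circuit state
#'
#' The coupled balance equations for one average cell:
#' `dA_minus/dt = Q - k_R * F` (promoter source minus RIDA conversion at
#' the fork pairs), `dA_plus/dt = k_R * F` (DnaA-ADP created only by
#' RIDA), and `dLambda/dt = k_lambda * F` (each fork pair replicates DNA
#' at a constant rate).  `F` and `Theta` are read from the schedule at
#' the state's time; `P` follows the RNAP profile.
#'
#' @param state List (or [cell_state]) with `t`, `A_minus`, `A_plus`,
#'   `Lambda`.
#' @param schedule A [build_schedule] result.
#' @param params A [model_parameters] object.
#' @return Named numeric vector of derivatives
#'   `c(A_minus = , A_plus = , Lambda = )` in units per minute.
#' @export
dnaa_rhs <- function(state, schedule, params) {
  stopifnot(inherits(schedule, "cell_cycle_schedule"),
            inherits(params, "dnaa_parameters"))
  if (state$A_minus < 0 || state$A_plus < 0 || state$Lambda <= 0)
    stop("invalid state: molecule counts must be non-negative and ",
         "Lambda positive", call. = FALSE)
  prof <- profiles_at(schedule, state$t)
  P <- rnap_profile(rnap_birth(params), schedule$periods$tau, state$t,
                    params$rnap_growth)
  Q <- promoter_rate(params, prof$Theta, state$Lambda, P, state$A_minus)
  sink <- params$k_R * prof$F
  c(A_minus = Q - sink, A_plus = sink, Lambda = params$k_lambda * prof$F)
}

#' Cell state constructor
#'
#' @param t Time within the cycle, minutes.
#' @param A_minus DnaA-ATP molecules.
#' @param A_plus DnaA-ADP molecules.
#' @param Lambda Genome length, genome equivalents.
#' @return A `cell_state` list.
#' @export
cell_state <- function(t = 0, A_minus = 0, A_plus = 0, Lambda = 1) {
  structure(list(t = t, A_minus = A_minus, A_plus = A_plus,
                 Lambda = Lambda), class = "cell_state")
}

# ---------------------------------------------------------------------
# Internal integration machinery.
#
# The integration grid is the union of the schedule's breakpoint
# intervals, each subdivided so that no Runge-Kutta step straddles a
# discontinuity of F or Theta and so that the initiation age X is always
# a grid node (r(X) is read exactly, never interpolated).
# ---------------------------------------------------------------------

# Build the aligned grid: returns list with nodes t (length N+1), and
# per-step vectors h, F, Theta (constant within each step).
aligned_grid <- function(schedule, step) {
  bp <- schedule$breakpoints
  t <- 0
  Fv <- integer(0); Th <- integer(0)
  for (i in seq_len(nrow(bp))) {
    len <- bp$t_end[i] - bp$t_start[i]
    nsub <- max(1L, as.integer(ceiling(len / step - 1e-9)))
    t <- c(t, bp$t_start[i] + len * seq_len(nsub) / nsub)
    Fv <- c(Fv, rep.int(bp$F[i], nsub))
    Th <- c(Th, rep.int(bp$Theta[i], nsub))
  }
  list(t = t, h = diff(t), F = Fv, Theta = Th)
}

# Precompute everything that does not depend on the unknown A_minus:
# Lambda (exact piecewise-linear), P at nodes/midpoints, Theta/F per
# step, and the RIDA sink rate per step (possibly variant-adjusted).
# `variant` is NULL or a dnaa_variant object (see variants.R).
cycle_context <- function(schedule, params, step, variant = NULL) {
  g <- aligned_grid(schedule, step)
  tau <- schedule$periods$tau
  N <- length(g$h)
  Lam <- schedule$Lambda0 +
    schedule$k_lambda * c(0, cumsum(g$F * g$h))        # at nodes
  Lam_mid <- (Lam[-(N + 1)] + Lam[-1]) / 2             # exact: F const
  Pb <- rnap_birth(params)
  P_node <- rnap_profile(Pb, tau, g$t, params$rnap_growth)
  t_mid <- g$t[-(N + 1)] + g$h / 2
  P_mid <- rnap_profile(Pb, tau, t_mid, params$rnap_growth)
  kR_step <- effective_kR(params, variant, Lam_mid, g$F)
  sink <- kR_step * g$F                                # molecules/min
  ctx <- list(grid = g, N = N, tau = tau, Lambda = Lam,
              Lambda_mid = Lam_mid, P_node = P_node, P_mid = P_mid,
              t_mid = t_mid, sink = sink, schedule = schedule,
              params = params, variant = variant)
  ctx$fast <- is.null(variant) ||
    (is.null(variant$coop) && variant$datA_capacity == 0)
  if (ctx$fast) ctx <- precompute_promoter(ctx)
  ctx
}

# Precompute the promoter rate law Q(A) = qa / (den + cc * A) at the
# nodes and midpoints (fast path: non-cooperative promoter, no datA).
precompute_promoter <- function(ctx) {
  p <- ctx$params
  g <- ctx$grid
  ctx$qa <- p$k_A * g$Theta                       # per step
  ctx$den_node <- 1 + p$c1 * ctx$Lambda / ctx$P_node
  ctx$den_mid <- 1 + p$c1 * ctx$Lambda_mid / ctx$P_mid
  ctx$cc_node <- p$c2 / ctx$P_node
  ctx$cc_mid <- p$c2 / ctx$P_mid
  ctx
}

# Q at one RK stage.  A_minus may be any real during iteration; the
# repression term uses max(A_free, 0) so intermediate stages stay
# well-defined, while the converged solution is checked for negativity.
stage_Q <- function(ctx, i, at_mid, at_end, A_minus) {
  g <- ctx$grid
  if (at_mid) {
    Lam <- ctx$Lambda_mid[i]; P <- ctx$P_mid[i]
  } else if (at_end) {
    Lam <- ctx$Lambda[i + 1]; P <- ctx$P_node[i + 1]
  } else {
    Lam <- ctx$Lambda[i]; P <- ctx$P_node[i]
  }
  variant_Q(ctx$params, ctx$variant, g$Theta[i], Lam, P,
            max(A_minus, 0), ctx)
}

# One cycle of classical RK4 for A_minus on the aligned grid, with the
# delayed-source option handled by substituting a fixed source history.
# Returns the A_minus values at all nodes.
rk4_cycle <- function(ctx, A0) {
  N <- ctx$N
  g <- ctx$grid
  h <- g$h
  sink <- ctx$sink
  A <- numeric(N + 1)
  A[1] <- A0
  src <- ctx$source_override  # NULL, or list(node=, mid=) fixed rates
  if (!is.null(src)) {
    for (i in seq_len(N)) {
      k1 <- src$node[i] - sink[i]
      k23 <- src$mid[i] - sink[i]
      k4 <- src$node[i + 1] - sink[i]
      A[i + 1] <- A[i] + h[i] / 6 * (k1 + 4 * k23 + k4)
    }
    return(A)
  }
  if (ctx$fast) {
    qa <- ctx$qa
    dn <- ctx$den_node; dm <- ctx$den_mid
    cn <- ctx$cc_node; cm <- ctx$cc_mid
    a <- A0
    for (i in seq_len(N)) {
      hh <- h[i]; s <- sink[i]; q <- qa[i]
      k1 <- q / (dn[i] + cn[i] * max(a, 0)) - s
      k2 <- q / (dm[i] + cm[i] * max(a + hh / 2 * k1, 0)) - s
      k3 <- q / (dm[i] + cm[i] * max(a + hh / 2 * k2, 0)) - s
      k4 <- q / (dn[i + 1] + cn[i + 1] * max(a + hh * k3, 0)) - s
      a <- a + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      A[i + 1] <- a
    }
    return(A)
  }
  for (i in seq_len(N)) {
    hh <- h[i]
    s <- sink[i]
    a <- A[i]
    k1 <- stage_Q(ctx, i, FALSE, FALSE, a) - s
    k2 <- stage_Q(ctx, i, TRUE, FALSE, a + hh / 2 * k1) - s
    k3 <- stage_Q(ctx, i, TRUE, FALSE, a + hh / 2 * k2) - s
    k4 <- stage_Q(ctx, i, FALSE, TRUE, a + hh * k3) - s
    A[i + 1] <- a + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  A
}

#' Integrate one cell cycle of the DnaA dynamics
#'
#' Fourth-order Runge-Kutta integration of the DnaA-ATP / DnaA-ADP /
#' genome-length system over a single cycle `[0, tau]`, without applying
#' the division map.  The grid is aligned to the schedule breakpoints so
#' that the piecewise-constant fork count `F` and gene dosage `Theta`
#' are uniform within every step, and the initiation age `X` is a node.
#' `Lambda` and `A_plus` have piecewise-constant derivatives in time and
#' are recovered exactly (to rounding) by the same scheme.
#'
#' @param initial A [cell_state] at `t = 0`.
#' @param schedule A [build_schedule] result.
#' @param params A [model_parameters] object.
#' @param step Target step size, minutes; steps are shrunk per interval
#'   to land exactly on breakpoints.  Default `tau / 5000`.
#' @return A data frame with columns `t`, `A_minus`, `A_plus`, `Lambda`,
#'   `r`, `Q`, `P`, `F`, `Theta` at the grid nodes (`F`, `Theta`, `Q`
#'   take right-limit values; the last row holds the pre-division state).
#' @export
integrate_cycle <- function(initial, schedule, params,
                            step = schedule$periods$tau / 5000) {
  stopifnot(inherits(schedule, "cell_cycle_schedule"),
            inherits(params, "dnaa_parameters"))
  if (step <= 0) stop("step must be positive", call. = FALSE)
  ctx <- cycle_context(schedule, params, step)
  ctx$source_override <- NULL
  if (abs(initial$Lambda - schedule$Lambda0) > 1e-9 * schedule$Lambda0)
    ctx <- shift_lambda(ctx, initial$Lambda - schedule$Lambda0)
  A <- rk4_cycle(ctx, initial$A_minus)
  assemble_trajectory(ctx, A, A_plus0 = initial$A_plus)
}

# Offset the precomputed Lambda arrays (used when an initial state with
# Lambda != Lambda0 is integrated; the growth law itself is unchanged).
shift_lambda <- function(ctx, delta) {
  ctx$Lambda <- ctx$Lambda + delta
  ctx$Lambda_mid <- ctx$Lambda_mid + delta
  if (isTRUE(ctx$fast)) ctx <- precompute_promoter(ctx)
  ctx
}

# Build the exported trajectory table from node values.
assemble_trajectory <- function(ctx, A, A_plus0 = 0) {
  g <- ctx$grid
  N <- ctx$N
  # A_plus and the node-value source/sink bookkeeping
  Aplus <- A_plus0 + c(0, cumsum(ctx$sink * g$h))
  Fnode <- c(g$F, g$F[N])        # right-limit; last node keeps last value
  Thnode <- c(g$Theta, g$Theta[N])
  Afree <- variant_free_A(ctx$params, ctx$variant, pmax(A, 0), Thnode, ctx)
  Qnode <- variant_Q(ctx$params, ctx$variant, Thnode, ctx$Lambda,
                     ctx$P_node, pmax(A, 0), ctx, free_A = Afree)
  data.frame(t = g$t, A_minus = A, A_plus = Aplus, Lambda = ctx$Lambda,
             r = Afree / ctx$Lambda, Q = Qnode, P = ctx$P_node,
             F = Fnode, Theta = Thnode)
}

#' Solve for the cyclic steady state of one average cell cycle
#'
#' Under balanced exponential growth the cell cycle repeats itself
#' identically: integrating one cycle and halving all molecule counts
#' and the genome at division must reproduce the birth state.  The
#' genome trivially satisfies this when started from the schedule's
#' `Lambda0`, and DnaA-ADP has the closed-form birth value equal to the
#' cycle integral of the RIDA flux, so the only genuinely unknown birth
#' value is DnaA-ATP.  The map `A_minus(0) -> A_minus(tau)/2` is a
#' contraction (autorepression makes the promoter output decrease in
#' `A_minus`); it is iterated with secant acceleration until the
#' relative change is below `tol`.
#'
#' @param schedule A [build_schedule] result.
#' @param params A [model_parameters] object.
#' @param step RK4 target step, minutes.  Default `tau / 5000`.
#' @param tol Relative cyclicity tolerance on the birth DnaA-ATP value.
#' @param max_cycles Iteration cap; exceeding it is an error.
#' @param A0_init Starting guess for DnaA-ATP at birth.
#' @param variant Optional [variant_config] modifying the dynamics.
#' @return An object of class `dnaa_trajectory`: the converged cycle as
#'   in [integrate_cycle] plus attributes `schedule`, `params`,
#'   `variant`, `r_X` (the initiation potential at `t = X`),
#'   `convergence` (cycles, residual).
#' @examples
#' \donttest{
#' traj <- solve_cyclic_steady_state(build_schedule(cell_cycle_periods(21)),
#'                                   model_parameters(), step = 21 / 2000)
#' attr(traj, "r_X")
#' }
#' @export
solve_cyclic_steady_state <- function(schedule, params,
                                      step = schedule$periods$tau / 5000,
                                      tol = 1e-10, max_cycles = 10000,
                                      A0_init = 0, variant = NULL) {
  stopifnot(inherits(schedule, "cell_cycle_schedule"),
            inherits(params, "dnaa_parameters"))
  ctx <- cycle_context(schedule, params, step, variant)
  ctx$source_override <- NULL
  if (!is.null(variant) && variant$delay_td > 0)
    return(solve_delayed(ctx, step, tol, max_cycles, A0_init))

  endmap <- function(a0) rk4_cycle(ctx, a0)[ctx$N + 1] / 2
  a_prev <- A0_init
  f_prev <- endmap(a_prev)
  a <- f_prev
  cycles <- 1L
  residual <- abs(a - a_prev) / max(1, abs(a))
  while (residual > tol && cycles < max_cycles) {
    f_a <- endmap(a)
    # secant step on g(x) = endmap(x) - x; fall back to plain iteration
    denom <- (f_a - a) - (f_prev - a_prev)
    a_new <- if (abs(denom) > .Machine$double.eps * max(1, abs(a)))
      a - (f_a - a) * (a - a_prev) / denom else f_a
    if (!is.finite(a_new)) a_new <- f_a
    a_prev <- a; f_prev <- f_a
    residual <- abs(a_new - a) / max(1, abs(a_new))
    a <- a_new
    cycles <- cycles + 1L
  }
  if (residual > tol)
    stop("cyclic steady state not reached in ", max_cycles,
         " cycles (last relative residual ", format(residual), ")",
         call. = FALSE)
  A <- rk4_cycle(ctx, a)
  if (min(A) < -1e-9 * max(1, max(A)))
    stop("model-regime error: DnaA-ATP becomes negative during the ",
         "cycle (min ", format(min(A)), "); the parameter set does not ",
         "support a non-negative cyclic solution", call. = FALSE)
  finish_trajectory(ctx, A, cycles, residual)
}

finish_trajectory <- function(ctx, A, cycles, residual) {
  sched <- ctx$schedule
  gain <- sum(ctx$sink * ctx$grid$h)   # A_plus made per cycle
  traj <- assemble_trajectory(ctx, A, A_plus0 = gain)
  iX <- which.min(abs(traj$t - sched$X))
  structure(traj, class = c("dnaa_trajectory", "data.frame"),
            schedule = sched, params = ctx$params, variant = ctx$variant,
            r_X = traj$r[iX], i_X = iX,
            convergence = list(cycles = cycles, residual = residual))
}

#' @export
print.dnaa_trajectory <- function(x, ...) {
  sched <- attr(x, "schedule")
  conv <- attr(x, "convergence")
  cat("Cyclic steady-state DnaA trajectory (tau =", sched$periods$tau,
      "min)\n")
  cat("  birth: A- =", format(x$A_minus[1]), ", A+ =",
      format(x$A_plus[1]), ", Lambda =", format(x$Lambda[1]), "\n")
  cat("  initiation potential r(X) =", format(attr(x, "r_X")),
      "molecules per genome equivalent at X =", format(sched$X), "min\n")
  cat("  converged in", conv$cycles, "cycles; residual",
      format(conv$residual), "\n")
  invisible(x)
}

#' Export a trajectory as CSV or JSON
#'
#' CSV holds the per-node columns; JSON adds a metadata block with the
#' parameter set, schedule and convergence record.
#'
#' @param trajectory A [solve_cyclic_steady_state] result.
#' @param file Output path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, file, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(trajectory)
  if (format == "csv") {
    utils::write.csv(format(df, digits = 12, trim = TRUE), file,
                     row.names = FALSE, quote = FALSE)
  } else {
    sched <- attr(trajectory, "schedule")
    out <- list(metadata = list(
      params = unclass(attr(trajectory, "params")),
      schedule = list(tau = sched$periods$tau, C = sched$periods$C,
                      D = sched$periods$D, n = sched$n, X = sched$X,
                      Y = sched$Y, Lambda0 = sched$Lambda0),
      convergence = attr(trajectory, "convergence"),
      r_X = attr(trajectory, "r_X")),
      trajectory = df)
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
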