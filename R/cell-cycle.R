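#' Cell-cycle periods of the Cooper-Helmstetter model
#'
#' Bundle the three time periods that determine the deterministic timing
#' skeleton of an *E. coli* cell cycle under balanced exponential growth:
#' the doubling time `tau`, the chromosome replication time `C` (origin to
#' terminus for one fork pair) and the post-replication division delay `D`.
#' `C` and `D` are treated as constants of the growth regime; outside the
#' doubling-time window 20-60 min, where that approximation is known to
#' hold, a warning is raised.
#'
#' @param tau Doubling time in minutes (> 0).
#' @param C Chromosome replication (C) period in minutes (> 0). Default 40.
#' @param D Division delay (D) period in minutes (>= 0). Default 20.
#' @return An object of class `cell_cycle_periods`.
#' @examples
#' cell_cycle_periods(21)
#' @export
cell_cycle_periods <- function(tau, C = 40, D = 20) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  stopifnot(is.numeric(C), length(C) == 1L, is.finite(C))
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D))
  if (tau <= 0) stop("doubling time 'tau' must be positive", call. = FALSE)
  if (C <= 0) stop("C period must be positive", call. = FALSE)
  if (D < 0) stop("D period must be non-negative", call. = FALSE)
  if (tau < 20 || tau > 60)
    warning("tau = ", tau, " min is outside the 20-60 min regime of ",
            "constant C and D periods; results extrapolate the model",
            call. = FALSE)
  structure(list(tau = tau, C = C, D = D), class = "cell_cycle_periods")
}

#' @export
print.cell_cycle_periods <- function(x, ...) {
  cat("Cell-cycle periods: tau =", x$tau, "min, C =", x$C,
      "min, D =", x$D, "min\n")
  invisible(x)
}

#' Number of overlapping replication rounds
#'
#' The number `n` of rounds of replication initiated in earlier generations
#' that are still running at cell birth.  It is the smallest non-negative
#' integer for which `(n + 1) * tau >= C + D`, so that the initiation age
#' `X = (n + 1) * tau - (C + D)` falls inside the cycle, in `[0, tau)`.
#' `2^n` origins are present at birth.
#'
#' @param periods A [cell_cycle_periods] object.
#' @return Integer count of overlapping rounds.
#' @examples
#' overlap_rounds(cell_cycle_periods(21))  # 2
#' overlap_rounds(cell_cycle_periods(60))  # 0
#' @export
overlap_rounds <- function(periods) {
  stopifnot(inherits(periods, "cell_cycle_periods"))
  n <- ceiling((periods$C + periods$D) / periods$tau) - 1
  as.integer(max(0, n))
}

#' Build the Cooper-Helmstetter schedule for one cell cycle
#'
#' Computes the initiation age `X` (from `X + C + D = (n + 1) * tau`), the
#' replication-completion age `Y = tau - D`, and the piecewise-constant
#' profiles over the cycle `[0, tau)` of the number of replication fork
#' pairs `F(t)` and of origin-proximal gene copies `Theta(t)` (the *dnaA*
#' gene sits next to the origin, so its dosage doubles at initiation).
#' The genome length at birth, `Lambda0`, is fixed by cyclic consistency:
#' the genome must exactly double over one cycle, so
#' `Lambda0 = k_lambda * integral of F over the cycle`.
#'
#' Fork counts follow the two published orderings of the within-cycle
#' events.  With `m = 2^n`: if `X < Y` the fork-pair counts are
#' `m - 1, 2 m - 1, 2 (m - 1)` on `(0, X), (X, Y), (Y, tau)`; if `X > Y`
#' they are `m - 1, m - 2, 2 (m - 1)` on `(0, Y), (Y, X), (X, tau)`.
#' Empty intervals (`X = 0`, or `X = Y`) are dropped; values at
#' breakpoints are the right-limit (post-event) values.
#'
#' @param periods A [cell_cycle_periods] object.
#' @param k_lambda Replication rate per fork pair, genome equivalents per
#'   minute.  Defaults to `1 / C` so that one fork pair copies one genome
#'   in exactly the C period.
#' @return An object of class `cell_cycle_schedule` with elements
#'   `periods`, `n`, `X`, `Y`, `k_lambda`, `Lambda0` and `breakpoints`
#'   (a data frame with columns `t_start`, `t_end`, `F`, `Theta`).
#' @examples
#' sched <- build_schedule(cell_cycle_periods(21))
#' sched$breakpoints
#' @export
build_schedule <- function(periods, k_lambda = 1 / periods$C) {
  stopifnot(inherits(periods, "cell_cycle_periods"))
  stopifnot(is.numeric(k_lambda), length(k_lambda) == 1L, k_lambda > 0)
  tau <- periods$tau
  n <- overlap_rounds(periods)
  X <- (n + 1) * tau - (periods$C + periods$D)
  Y <- tau - periods$D
  if (Y < 0)
    stop("D period exceeds the doubling time; no completion age within ",
         "the cycle", call. = FALSE)
  m <- 2^n
  if (X <= Y) {
    edges <- c(0, X, Y, tau)
    Fv <- c(m - 1, 2 * m - 1, 2 * (m - 1))
  } else {
    edges <- c(0, Y, X, tau)
    Fv <- c(m - 1, m - 2, 2 * (m - 1))
  }
  Th <- ifelse(edges[-length(edges)] >= X, 2 * m, m)
  keep <- diff(edges) > 0
  bp <- data.frame(t_start = edges[-length(edges)][keep],
                   t_end = edges[-1][keep],
                   F = as.integer(Fv[keep]),
                   Theta = as.integer(Th[keep]))
  Lambda0 <- k_lambda * sum(bp$F * (bp$t_end - bp$t_start))
  structure(list(periods = periods, n = n, X = X, Y = Y,
                 k_lambda = k_lambda, Lambda0 = Lambda0,
                 breakpoints = bp),
            class = "cell_cycle_schedule")
}

#' @export
print.cell_cycle_schedule <- function(x, ...) {
  cat("Cooper-Helmstetter schedule (tau =", x$periods$tau, "min)\n")
  cat("  overlapping rounds n =", x$n, " origins at birth =", 2^x$n, "\n")
  cat("  initiation age X =", format(x$X), "min; completion age Y =",
      format(x$Y), "min\n")
  cat("  genome at birth Lambda0 =", format(x$Lambda0),
      "genome equivalents\n")
  print(x$breakpoints, row.names = FALSE)
  invisible(x)
}

#' Evaluate the schedule profiles at given cycle times
#'
#' Returns the fork-pair count `F(t)`, gene-copy number `Theta(t)` and
#' genome length `Lambda(t)` at times within one cycle.  `F` and `Theta`
#' take their right-limit value at interior breakpoints; `Lambda` is the
#' continuous piecewise-linear integral
#' `Lambda(t) = Lambda0 + k_lambda * integral of F from 0 to t`, so that
#' `Lambda(tau) = 2 * Lambda0` by construction.
#'
#' @param schedule A [build_schedule] result.
#' @param t Numeric vector of times in minutes, each in `[0, tau]`.
#' @return A data frame with columns `t`, `F`, `Theta`, `Lambda`.
#' @examples
#' profiles_at(build_schedule(cell_cycle_periods(21)), c(0, 2, 21))
#' @export
profiles_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "cell_cycle_schedule"))
  tau <- schedule$periods$tau
  if (any(t < 0 | t > tau))
    stop("times must lie within [0, tau]", call. = FALSE)
  bp <- schedule$breakpoints
  # right-limit convention; t == tau falls in the last interval
  idx <- findInterval(t, bp$t_start, rightmost.closed = FALSE)
  idx[idx > nrow(bp)] <- nrow(bp)
  cumF <- c(0, cumsum(bp$F * (bp$t_end - bp$t_start)))
  Lambda <- schedule$Lambda0 +
    schedule$k_lambda * (cumF[idx] + bp$F[idx] * (t - bp$t_start[idx]))
  data.frame(t = t, F = bp$F[idx], Theta = bp$Theta[idx], Lambda = Lambda)
}

#' Export a schedule as a plain-text table
#'
#' Writes the piecewise-constant profile table (`t_start`, `t_end`, `F`,
#' `Theta`) as CSV, or the full schedule (periods, `n`, `X`, `Y`,
#' `Lambda0` and the table) as JSON.
#'
#' @param schedule A [build_schedule] result.
#' @param file Output path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_schedule <- function(schedule, file, format = c("csv", "json")) {
  stopifnot(inherits(schedule, "cell_cycle_schedule"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(schedule$breakpoints, file, row.names = FALSE)
  } else {
    out <- list(tau = schedule$periods$tau, C = schedule$periods$C,
                D = schedule$periods$D, n = schedule$n, X = schedule$X,
                Y = schedule$Y, k_lambda = schedule$k_lambda,
                Lambda0 = schedule$Lambda0,
                breakpoints = schedule$breakpoints)
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
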