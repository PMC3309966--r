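# Independent event-driven lineage simulator, used as the oracle for the
# analytic Cooper-Helmstetter schedule.  One cell lineage is followed in
# absolute time: every initiation event spawns one fork pair per origin
# present and doubles the origins; each replication round terminates C
# minutes after its initiation; the cell divides D minutes after each
# termination, halving origins and all fork counts.  After a burn-in the
# lineage is periodic and one inter-division interval is sampled.
#
# Returns a function of cycle age t (right-limit convention) giving
# c(F = total fork pairs, Theta = origin/gene copies).
lineage_oracle <- function(tau, C = 40, D = 20, generations = 30) {
  init_times <- (0:(generations - 1)) * tau
  events <- rbind(
    data.frame(time = init_times, type = "init", id = seq_along(init_times)),
    data.frame(time = init_times + C, type = "complete",
               id = seq_along(init_times)),
    data.frame(time = init_times + C + D, type = "divide",
               id = seq_along(init_times)))
  # at equal times: divide first (birth state), then completion, then
  # initiation, so sampled values are right-limits
  ord <- order(events$time, match(events$type, c("divide", "complete",
                                                 "init")))
  events <- events[ord, ]
  # sample a late (periodic) cycle whose full event window, including
  # the following initiation, is still covered by the generated events
  last_div <- (generations - 6) * tau + C + D
  state_at <- function(t_abs) {
    origins <- 1
    forks <- numeric(length(init_times))
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      if (ev$time > t_abs + 1e-9) break
      if (ev$type == "init") {
        forks[ev$id] <- origins
        origins <- origins * 2
      } else if (ev$type == "complete") {
        forks[ev$id] <- 0
      } else {
        origins <- origins / 2
        forks <- forks / 2
      }
    }
    c(F = sum(forks), Theta = origins)
  }
  function(t) state_at(last_div + t)
}

# Small-step defaults shared by the integration tests: coarse enough to
# keep the suite fast, fine enough that every assertion tolerance holds
# with two orders of magnitude to spare.
test_step <- function(tau) tau / 5000
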