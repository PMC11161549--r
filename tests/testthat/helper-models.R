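# Shared fixture models, built in code.

# Two-type communicating model, type-independent p0 = 0.35, exponential(1)
# lifespans.  Row-stochastic pair kernel => alpha = (2 * 0.65 - 1) * 1 = 0.3.
twoTypeModel <- function(p0 = 0.35, rate = 1) {
  q1 <- matrix(c(0.6, 0.3, 0, 0.1), 2, 2, byrow = TRUE)
  q2 <- matrix(c(0.1, 0.3, 0, 0.6), 2, 2, byrow = TRUE)
  branchingModel(list(offspringLaw(p0, q1), offspringLaw(p0, q2)),
                 expLifespan(rate), K = 2)
}

# Simulate one clone of `model` conditioned on carrying at least `minCells`
# at the horizon; returns the first qualifying trajectory.
surviveClone <- function(model, horizon, minCells = 200, cap = 3e5,
                         maxTries = 60, firstSeed = 1) {
  for (s in firstSeed:(firstSeed + maxTries - 1)) {
    tr <- simulateClone(model, 1, horizon, seed = s, cap = cap)
    if (!tr@truncated && sum(countsAt(tr, horizon)) >= minCells) return(tr)
  }
  stop("no surviving clone found")
}

# Replay a clone's event log and return the total live-cell path at `times`
# (independent of countsAt's bookkeeping): +1 at each birth, -1 at each
# death/division event.
replayTotal <- function(traj, times) {
  ev <- rbind(data.frame(t = traj@cells$birth, d = 1),
              data.frame(t = traj@cells$end[traj@cells$fate != "alive"],
                         d = -1))
  vapply(times, function(x) sum(ev$d[ev$t <= x]), 0) -
    # births at exactly x count, ends at exactly x count (post-event state);
    # both use <= so nothing to adjust
    0
}
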