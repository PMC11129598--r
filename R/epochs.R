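# Internal epoch machinery: piecewise-constant pairwise coalescence rates for
# the three sampled lineages (a, b, c) under each scenario and each path of
# the recipient lineage ("stay" = speciation history, "jump" = introgressed
# history). Populations only ever merge going back in time, so two lineages
# that share a population at time t share it at every later time; all pairwise
# and joint coalescent-time densities reduce to step-function hazards on a
# common break grid.

# population label of a lineage at time t (t strictly inside an interval)
.pop_of <- function(lineage, t, model, path) {
  s <- model$scenario
  top_R <- if (s == "GHOST") model$tau_G else model$tau_O  # when R merges upward
  jump <- identical(path, "jump")
  if (lineage == "a") {
    if (jump && s == "GHOST") {
      if (t < model$tau_H) return("A")
      if (t < model$tau_G) return("G")
      return("anc")
    }
    if (t < model$tau_T) return("A")
    if (t < model$tau_R) return("T")
    if (t < top_R) return("R")
    return("anc")
  }
  if (lineage == "b") {
    if (jump && s == "INFLOW") {
      if (t < model$tau_H) return("B")
      if (t < model$tau_R) return("C")
      if (t < top_R) return("R")
      return("anc")
    }
    if (t < model$tau_T) return("B")
    if (t < model$tau_R) return("T")
    if (t < top_R) return("R")
    return("anc")
  }
  if (lineage == "c") {
    if (jump && s == "OUTFLOW") {
      if (t < model$tau_H) return("C")
      if (t < model$tau_T) return("B")
      if (t < model$tau_R) return("T")
      if (t < top_R) return("R")
      return("anc")
    }
    if (t < model$tau_R) return("C")
    if (t < top_R) return("R")
    return("anc")
  }
  if (lineage == "o") {
    if (t < model$tau_O) return("O")
    return("anc")
  }
  stop("unknown lineage ", lineage)
}

.pair_names <- c("ab", "bc", "ac")

# shared-population label per pair per interval, cached per (scenario, path);
# intervals are delimited by the ordered times tau_H < tau_T < tau_R
# (< tau_G) < tau_O, which the model invariants guarantee
.pair_pop_cache <- new.env(parent = emptyenv())

.pair_pops <- function(scenario, path, ghost_break) {
  key <- paste(scenario, path, ghost_break)
  hit <- .pair_pop_cache[[key]]
  if (!is.null(hit)) return(hit)
  K <- if (ghost_break) 5L else 4L    # tau_H, tau_T, tau_R, (tau_G), tau_O
  model_like <- list(scenario = scenario,
                     tau_H = 1, tau_T = 2, tau_R = 3,
                     tau_G = if (ghost_break) 4 else NA, tau_O = K)
  mids <- c(0.5, seq_len(K) + 0.5)    # representative point per interval
  pops <- matrix("", nrow = 3L, ncol = K + 1L,
                 dimnames = list(.pair_names, NULL))
  lin <- list(ab = c("a", "b"), bc = c("b", "c"), ac = c("a", "c"))
  for (p in .pair_names) {
    for (k in seq_len(K + 1L)) {
      p1 <- .pop_of(lin[[p]][1], mids[k], model_like, path)
      p2 <- .pop_of(lin[[p]][2], mids[k], model_like, path)
      if (identical(p1, p2)) pops[p, k] <- p1
    }
  }
  .pair_pop_cache[[key]] <- pops
  pops
}

# breaks (sorted event times) and a 3 x (K+1) matrix of pairwise rates per
# interval [0,b1), [b1,b2), ..., [bK, Inf); rows ab, bc, ac
.pair_rates <- function(model, path) {
  ghost <- model$scenario == "GHOST"
  breaks <- if (ghost)
    c(model$tau_H, model$tau_T, model$tau_R, model$tau_G, model$tau_O)
  else c(model$tau_H, model$tau_T, model$tau_R, model$tau_O)
  pops <- .pair_pops(model$scenario, path, ghost)
  rates <- array(0, dim(pops), dimnames = dimnames(pops))
  on <- pops != ""
  rates[on] <- 2 / model$theta[pops[on]]
  list(breaks = breaks, rates = rates)
}

# step-function evaluation and cumulative hazard, vectorized over t
.step_eval <- function(breaks, rates, t) {
  rates[findInterval(t, breaks) + 1L]
}

.step_cumhaz <- function(breaks, rates, t) {
  K <- length(breaks)
  H <- c(0, cumsum(rates[seq_len(K)] * diff(c(0, breaks))))  # cum hazard at 0, b1..bK
  i <- findInterval(t, breaks)
  H[i + 1L] + rates[i + 1L] * (t - c(0, breaks)[i + 1L])
}

# weights of the two paths; zero-weight paths dropped
.path_weights <- function(model) {
  w <- c(stay = 1 - model$gamma, jump = model$gamma)
  w[w > 0]
}
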