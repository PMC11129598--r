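# shared fixtures and independent oracles, built in code

ghost_grid_model <- function(gamma = 0.3, c1 = 0.3, c2 = 1.5, theta = 0.036,
                             stem = 1.5)
  msci_from_grid("GHOST", c1, c2, gamma, theta = theta, ghost_stem_cu = stem)

# numeric marginalization of the joint gene-tree density over (t1, t2),
# splitting the integrals at the model's break points (independent quadrature
# oracle for the closed-form topology probabilities)
quad_topology_prob <- function(model, topology) {
  brk <- sort(unique(c(model$tau_H, model$tau_T, model$tau_R, model$tau_G,
                       model$tau_O)))
  brk <- brk[is.finite(brk)]
  hi <- max(brk) + 60 * max(model$theta)
  jd <- joint_density(model)
  inner <- function(u) {
    cuts <- sort(unique(pmax(u, c(u, brk, hi))))
    s <- 0
    for (j in seq_len(length(cuts) - 1L))
      s <- s + stats::integrate(function(v)
        exp(jd$logpdf(topology, rep(u, length(v)), v)),
        cuts[j], cuts[j + 1L], rel.tol = 1e-10, stop.on.error = FALSE)$value
    s
  }
  cuts <- c(0, brk, hi)
  tot <- 0
  for (i in seq_len(length(cuts) - 1L))
    tot <- tot + stats::integrate(Vectorize(inner), cuts[i], cuts[i + 1L],
                                  rel.tol = 1e-8, stop.on.error = FALSE)$value
  tot
}

# quadrature of a pexp_mixture density over its support
quad_mixture_mass <- function(mix, upto = NULL) {
  brk <- sort(unique(unlist(lapply(mix$components, function(cm)
    c(cm$start, cm$ends[is.finite(cm$ends)])))))
  hi <- if (is.null(upto)) max(brk) + 60 * max(mix$model$theta) else upto
  cuts <- sort(unique(c(0, brk, hi)))
  s <- 0
  for (j in seq_len(length(cuts) - 1L))
    s <- s + stats::integrate(function(t) mixture_pdf(mix, t),
                              cuts[j], cuts[j + 1L], rel.tol = 1e-10)$value
  s
}

# brute-force maximizer of the topology-count multinomial likelihood over a
# (gamma, exp(-C_T), exp(-C_S)) grid — oracle for triple_profile()
brute_force_topology_loglik <- function(n, ngrid = 120) {
  g <- seq(0.002, 0.998, length.out = ngrid)
  q <- seq(1e-6, 1, length.out = ngrid)
  best <- -Inf
  for (gamma in g) {
    eT <- matrix(q, ngrid, ngrid)          # rows: q1, cols: q2
    eS <- matrix(q, ngrid, ngrid, byrow = TRUE)
    p3 <- ((1 - gamma) * eT + gamma * eS) / 3
    p1 <- (1 - gamma) * (1 - eT) + p3
    p2 <- gamma * (1 - eS) + p3
    ll <- n[1] * log(p1) + n[2] * log(p2) + n[3] * log(p3)
    ll[!is.finite(ll)] <- -Inf
    best <- max(best, max(ll))
  }
  best
}

# closed-form 3-taxon MSC joint density (no introgression, common theta):
# independent oracle for the gamma = 0 limit of the joint density
msc_logpdf <- function(topology, t1, t2, tau_T, tau_R, theta) {
  lam <- 2 / theta
  if (topology == "ab|c") {
    if (t1 < tau_T || t2 < max(t1, tau_R)) return(-Inf)
    log(lam^2) - lam * (t1 - tau_T) - 2 * lam * max(0, t1 - tau_R) -
      lam * (t2 - max(t1, tau_R))
  } else {
    if (t1 < tau_R || t2 < t1) return(-Inf)
    # the first coalescence must happen after tau_R with all three present
    log(lam^2) - lam * (t1 - tau_T) - 2 * lam * (t1 - tau_R) - lam * (t2 - t1)
  }
}
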