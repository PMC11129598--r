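#' Rooted-triple gene-tree topology probabilities under introgression
#'
#' Closed-form probabilities of the three rooted gene-tree topologies
#' `G1 = ab|c`, `G2 = a|bc`, `G3 = ac|b` for a species trio with one
#' introgression edge, as a function of the introgression probability `gamma`
#' and the internal branch lengths `C_T` (speciation history) and `C_S`
#' (introgressed history) in coalescent units:
#' \deqn{P(G_3) = \tfrac13 (1-\gamma) e^{-C_T} + \tfrac13 \gamma e^{-C_S},}
#' \deqn{P(G_1) = (1-\gamma)(1 - e^{-C_T}) + P(G_3),}
#' \deqn{P(G_2) = \gamma (1 - e^{-C_S}) + P(G_3).}
#'
#' The expressions depend on the scenario only through `(gamma, C_T, C_S)`:
#' ghost introgression, inflow and outflow with matched values produce
#' identical topology distributions, which is why topology-count methods
#' cannot tell the scenarios apart.
#'
#' @param gamma introgression probability in `[0, 1]`.
#' @param C_T,C_S internal branch lengths in coalescent units (`>= 0`, may be
#'   `Inf`). Arguments are recycled to a common length.
#' @return for scalar input, a named vector `c(p1 =, p2 =, p3 =)`; for vector
#'   input a matrix with one row per parameter combination.
#' @examples
#' topology_probs(0.3, 1.5, 1.5)
#' topology_probs(0, 1.5, 7)   # pure MSC limit
#' @export
topology_probs <- function(gamma, C_T, C_S) {
  n <- max(length(gamma), length(C_T), length(C_S))
  gamma <- rep_len(gamma, n); C_T <- rep_len(C_T, n); C_S <- rep_len(C_S, n)
  if (any(gamma < 0 | gamma > 1)) stop("'gamma' must lie in [0, 1]", call. = FALSE)
  if (any(C_T < 0) || any(C_S < 0)) stop("'C_T' and 'C_S' must be >= 0", call. = FALSE)
  eT <- exp(-C_T); eS <- exp(-C_S)
  p3 <- (1 - gamma) * eT / 3 + gamma * eS / 3
  p1 <- (1 - gamma) * (1 - eT) + p3
  p2 <- gamma * (1 - eS) + p3
  out <- cbind(p1 = p1, p2 = p2, p3 = p3)
  if (n == 1L) out[1L, ] else out
}

#' Unidentifiability interval for topology-based estimates of gamma
#'
#' A topology-count (pseudo-likelihood) method observes only
#' `P(G1) - P(G3) = (1-gamma)(1 - exp(-C_T))` and
#' `P(G2) - P(G3) = gamma (1 - exp(-C_S))`: two equations in three unknowns.
#' Any reported estimate of the introgression probability can fall anywhere in
#' \deqn{\gamma - \gamma e^{-C_S} < \hat\gamma < \gamma + (1-\gamma) e^{-C_T}.}
#'
#' @inheritParams topology_probs
#' @return named vector `c(low =, high =)` (or matrix for vector input).
#' @examples
#' gamma_bounds_mpl(0.3, 1.5, 1.5)
#' @export
gamma_bounds_mpl <- function(gamma, C_T, C_S) {
  n <- max(length(gamma), length(C_T), length(C_S))
  gamma <- rep_len(gamma, n); C_T <- rep_len(C_T, n); C_S <- rep_len(C_S, n)
  out <- cbind(low = gamma - gamma * exp(-C_S),
               high = gamma + (1 - gamma) * exp(-C_T))
  if (n == 1L) out[1L, ] else out
}

#' Expected per-site frequencies of the parsimony-informative site patterns
#'
#' Under an infinite-sites mutation model the biallelic patterns BBAA, ABBA
#' and BABA (taxon order A, B, C with the outgroup carrying the ancestral
#' state) arise from mutations on the internal branches of gene trees
#' `ab|c`, `a|bc` and `ac|b` respectively. With a constant population size
#' `theta` their expected per-site frequencies are
#' \deqn{f(BABA) = \tfrac{\theta}{6}(1-\gamma) e^{-2 l_T/\theta}
#'               + \tfrac{\theta}{6}\gamma e^{-2 l_S/\theta},}
#' \deqn{f(BBAA) = (1-\gamma) l_T + f(BABA), \quad
#'       f(ABBA) = \gamma l_S + f(BABA),}
#' so `BABA` is always the rarest pattern in all three scenarios — the
#' signature a HyDe-style test interprets as species B being the hybrid.
#'
#' @param model an [msci_model()] with a common `theta` across populations.
#' @return named vector `c(BBAA =, ABBA =, BABA =)` of per-site frequencies.
#' @examples
#' m <- msci_from_grid("GHOST", C1 = 0.3, C2 = 1.5, gamma = 0.3)
#' site_pattern_freqs(m)
#' @export
site_pattern_freqs <- function(model) {
  stopifnot(inherits(model, "msci_model"))
  if (length(unique(model$theta)) != 1L)
    stop("site_pattern_freqs() assumes a constant population size; ",
         "'model' has population-specific theta values", call. = FALSE)
  th <- model$theta[[1L]]
  l <- internal_branch_lengths(model)
  g <- model$gamma
  fBABA <- th / 6 * ((1 - g) * exp(-2 * l[["l_T"]] / th) +
                     g * exp(-2 * l[["l_S"]] / th))
  c(BBAA = (1 - g) * l[["l_T"]] + fBABA,
    ABBA = g * l[["l_S"]] + fBABA,
    BABA = fBABA)
}

#' Expected value of the HyDe introgression-probability estimator
#'
#' The HyDe estimator `(f(ABBA) - f(BABA)) / (f(ABBA) + f(BBAA) - 2 f(BABA))`
#' has expectation
#' \deqn{\hat\gamma_{HyDe} = \frac{1}{1 + (1/\gamma - 1)\, C_T/C_S},}
#' so it is unbiased only when `C_T = C_S` and is otherwise pulled towards 0
#' (when `C_T > C_S`) or towards 1 (when `C_T < C_S`), identically in all
#' three introgression scenarios.
#'
#' @param gamma true introgression probability in `[0, 1]`.
#' @param ratio_CT_over_CS the ratio `C_T / C_S` (equivalently `l_T / l_S`
#'   under a constant population size); must be `> 0`.
#' @return the expected estimate, recycled over the longer argument.
#' @examples
#' gamma_hyde_expected(0.3, c(1 / 3, 1, 3))
#' @export
gamma_hyde_expected <- function(gamma, ratio_CT_over_CS) {
  if (any(ratio_CT_over_CS <= 0)) stop("'ratio_CT_over_CS' must be > 0", call. = FALSE)
  if (any(gamma < 0 | gamma > 1)) stop("'gamma' must lie in [0, 1]", call. = FALSE)
  ifelse(gamma <= 0, 0,
         ifelse(gamma >= 1, 1, 1 / (1 + (1 / gamma - 1) * ratio_CT_over_CS)))
}

#' Detectability of introgression by a site-pattern test
#'
#' The power of the site-pattern test is governed by the margin between the
#' rarest pattern and its rival: `min{f(BBAA), f(ABBA)} - f(BABA) =
#' min{(1-gamma) l_T, gamma l_S}` (per site, constant population size).
#'
#' @inheritParams site_pattern_freqs
#' @return a single number; 0 means introgression is undetectable from pooled
#'   site patterns.
#' @export
hyde_detectability <- function(model) {
  stopifnot(inherits(model, "msci_model"))
  if (length(unique(model$theta)) != 1L)
    stop("hyde_detectability() assumes a constant population size", call. = FALSE)
  l <- internal_branch_lengths(model)
  min((1 - model$gamma) * l[["l_T"]], model$gamma * l[["l_S"]])
}
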