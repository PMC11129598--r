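#' Analytic density of the coalescent time of one sequence pair
#'
#' Enumerates the itineraries of the two lineages (whether the recipient
#' lineage follows the speciation or the introgressed history) and composes,
#' for each itinerary, the piecewise-exponential density of their first
#' coalescence: within a population of size `theta` a pair coalesces at rate
#' `2/theta`, and the rate changes at every population merge. The result is a
#' mixture of piecewise-exponential components; identical components arising
#' from both histories (a pair that does not involve the recipient) are pooled,
#' so such pairs always have a single smooth component.
#'
#' The minimum support points of the three pair densities order differently in
#' the three scenarios — `min(t_ab) < min(t_ac) = min(t_bc)` (GHOST),
#' `min(t_bc) < min(t_ab) < min(t_ac)` (INFLOW),
#' `min(t_bc) < min(t_ab) = min(t_ac)` (OUTFLOW) — which is the branch-length
#' signal that full-likelihood methods exploit and topology-only methods
#' discard.
#'
#' @param model an [msci_model()].
#' @param pair one of `"ab"`, `"bc"`, `"ac"`.
#' @return an object of class `"pexp_mixture"`: a list of components, each
#'   with a `weight`, a support `start`, segment `ends` (last is `Inf`) and
#'   per-segment `rates` (per mutation-unit time).
#' @examples
#' m <- msci_from_grid("INFLOW", C1 = 0.3, C2 = 0.5, gamma = 0.3)
#' d <- pairwise_density(m, "bc")
#' support_min(d)            # equals tau_H: introgressed copies coalesce early
#' mixture_cdf(d, m$tau_R)
#' @export
pairwise_density <- function(model, pair = c("ab", "bc", "ac")) {
  stopifnot(inherits(model, "msci_model"))
  pair <- match.arg(pair)
  comps <- list()
  w <- .path_weights(model)
  for (path in names(w)) {
    pr <- .pair_rates(model, path)
    r <- pr$rates[pair, ]
    pos <- which(r > 0)
    if (!length(pos)) stop("pair never shares a population")  # cannot happen
    i0 <- pos[1L]                       # rates stay positive once merged
    start <- if (i0 == 1L) 0 else pr$breaks[i0 - 1L]
    ends <- c(pr$breaks, Inf)[i0:(length(pr$breaks) + 1L)]
    comps[[length(comps) + 1L]] <- list(weight = unname(w[[path]]), start = start,
                                        ends = ends, rates = r[i0:length(r)])
  }
  # pool identical components (pair untouched by the introgression edge)
  if (length(comps) == 2L &&
      isTRUE(all.equal(comps[[1L]][c("start", "ends", "rates")],
                       comps[[2L]][c("start", "ends", "rates")]))) {
    comps[[1L]]$weight <- comps[[1L]]$weight + comps[[2L]]$weight
    comps <- comps[1L]
  }
  structure(list(components = comps, pair = pair, model = model),
            class = "pexp_mixture")
}

#' @export
print.pexp_mixture <- function(x, ...) {
  cat("Piecewise-exponential mixture for pair", x$pair,
      sprintf("(%s)\n", x$model$scenario))
  for (cm in x$components)
    cat(sprintf("  weight %.4g, support from %.6g, rates %s on ends %s\n",
                cm$weight, cm$start,
                paste(signif(cm$rates, 4), collapse = "/"),
                paste(signif(cm$ends, 4), collapse = "/")))
  invisible(x)
}

# density/survival of one component, vectorized over t
.comp_pdf <- function(cm, t) {
  out <- numeric(length(t))
  ok <- t >= cm$start & is.finite(t)
  if (any(ok)) {
    tt <- t[ok]
    i <- findInterval(tt, cm$ends, left.open = FALSE) + 1L  # segment index
    seg_start <- c(cm$start, cm$ends[-length(cm$ends)])
    lens <- diff(c(cm$start, cm$ends))
    H0 <- c(0, cumsum((cm$rates * lens)[-length(lens)]))  # cum hazard at segment starts
    H <- H0[i] + cm$rates[i] * (tt - seg_start[i])
    out[ok] <- cm$rates[i] * exp(-H)
  }
  out
}

.comp_cdf <- function(cm, t) {
  out <- numeric(length(t))
  out[is.infinite(t) & t > 0] <- 1
  ok <- t >= cm$start & is.finite(t)
  if (any(ok)) {
    tt <- t[ok]
    i <- findInterval(tt, cm$ends, left.open = FALSE) + 1L
    seg_start <- c(cm$start, cm$ends[-length(cm$ends)])
    lens <- diff(c(cm$start, cm$ends))
    H0 <- c(0, cumsum((cm$rates * lens)[-length(lens)]))
    H <- H0[i] + cm$rates[i] * (tt - seg_start[i])
    out[ok] <- 1 - exp(-H)
  }
  out
}

#' Evaluate a piecewise-exponential mixture
#'
#' @param mix a `"pexp_mixture"` from [pairwise_density()].
#' @param t vector of times (mutation units), `t >= 0`.
#' @return `mixture_pdf()` the density, `mixture_cdf()` the distribution
#'   function (`mixture_cdf(mix, Inf)` is 1), `support_min()` the smallest
#'   support point of any positive-weight component.
#' @export
mixture_pdf <- function(mix, t) {
  stopifnot(inherits(mix, "pexp_mixture"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  Reduce(`+`, lapply(mix$components, function(cm) cm$weight * .comp_pdf(cm, t)))
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(mix, t) {
  stopifnot(inherits(mix, "pexp_mixture"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  Reduce(`+`, lapply(mix$components, function(cm) cm$weight * .comp_cdf(cm, t)))
}

#' @rdname mixture_pdf
#' @export
support_min <- function(mix) {
  stopifnot(inherits(mix, "pexp_mixture"))
  min(vapply(mix$components, `[[`, 0, "start"))
}

#' @export
plot.pexp_mixture <- function(x, from = 0, to = NULL, n = 512, ...) {
  if (is.null(to)) to <- support_min(x) + 4 * max(x$model$theta)
  tt <- seq(from, to, length.out = n)
  graphics::plot(tt, mixture_pdf(x, tt), type = "l",
                 xlab = "coalescent time (mutation units)", ylab = "density",
                 main = paste0("t_", x$pair, " (", x$model$scenario, ")"), ...)
  invisible(x)
}

# --- joint density of (topology, t1, t2) ------------------------------------

.topo_levels <- c("ab|c", "a|bc", "ac|b")
# pair that coalesces first for each topology, and the cross pair used for the
# second coalescence (any pair spanning the merged clade and the third tip;
# both choices share a population from t1 onward)
.first_pair <- c("ab|c" = "ab", "a|bc" = "bc", "ac|b" = "ac")
.cross_pair <- c("ab|c" = "ac", "a|bc" = "ab", "ac|b" = "ab")

# log joint density, vectorized over loci; topo is an index into .topo_levels
.joint_logpdf <- function(model, topo, t1, t2) {
  w <- .path_weights(model)
  path_lp <- vector("list", length(w))
  for (j in seq_along(w)) {
    pr <- .pair_rates(model, names(w)[j])
    brk <- pr$breaks
    # cumulative hazards at the break points, per pair
    i1 <- findInterval(t1, brk); i2 <- findInterval(t2, brk)
    b0 <- c(0, brk)
    lp <- rep(log(w[[j]]), length(t1))
    for (p in 1:3) {
      r <- pr$rates[p, ]
      H <- c(0, cumsum(r[seq_along(brk)] * diff(b0)))
      lp <- lp - (H[i1 + 1L] + r[i1 + 1L] * (t1 - b0[i1 + 1L]))
      sel <- which(topo == p)   # topology k's first-coalescing pair is pair k
      if (length(sel)) lp[sel] <- lp[sel] + log(r[i1[sel] + 1L])
      csel <- which(topo %in% which(.cross_idx == p))
      if (length(csel)) {
        h2 <- (H[i2[csel] + 1L] + r[i2[csel] + 1L] * (t2[csel] - b0[i2[csel] + 1L])) -
              (H[i1[csel] + 1L] + r[i1[csel] + 1L] * (t1[csel] - b0[i1[csel] + 1L]))
        lp[csel] <- lp[csel] + log(r[i2[csel] + 1L]) - h2
      }
    }
    path_lp[[j]] <- lp
  }
  if (length(path_lp) == 1L) return(path_lp[[1L]])
  a <- path_lp[[1L]]; b <- path_lp[[2L]]
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

#' Joint gene-tree density under an MSci model
#'
#' The joint probability density of a 3-tip gene tree — its rooted topology,
#' first coalescence age `t1` and root age `t2` — obtained by enumerating the
#' recipient lineage's path (introgressed with probability `gamma`), the epoch
#' structure of the populations, and which pair coalesces first. This is the
#' object a full-likelihood method integrates over, and unlike the topology
#' probabilities it differs among the three scenarios at matched
#' `(gamma, C_T, C_S)`.
#'
#' @param model an [msci_model()].
#' @return an object of class `"msci_density"` with a vectorized `$logpdf`
#'   evaluator, `logpdf(topology, t1, t2)`, where `topology` takes values in
#'   `"ab|c"`, `"a|bc"`, `"ac|b"` and `0 <= t1 <= t2`.
#' @seealso [msci_loglik()] to evaluate a whole set of gene trees.
#' @export
joint_density <- function(model) {
  stopifnot(inherits(model, "msci_model"))
  force(model)
  structure(list(
    model = model,
    logpdf = function(topology, t1, t2) {
      topo <- .as_topo_index(topology)
      n <- max(length(topo), length(t1), length(t2))
      topo <- rep_len(topo, n); t1 <- rep_len(t1, n); t2 <- rep_len(t2, n)
      if (any(t1 < 0)) stop("'t1' must be >= 0", call. = FALSE)
      if (any(t2 < t1)) stop("'t2' must be >= 't1'", call. = FALSE)
      .joint_logpdf(model, topo, t1, t2)
    }), class = "msci_density")
}

#' @export
print.msci_density <- function(x, ...) {
  cat("Joint gene-tree density for a", x$model$scenario, "MSci model\n")
  invisible(x)
}

.as_topo_index <- function(topology) {
  if (is.numeric(topology)) {
    topo <- as.integer(topology)
  } else {
    topo <- match(as.character(topology), .topo_levels)
  }
  if (anyNA(topo) || any(topo < 1L | topo > 3L))
    stop("'topology' must be one of ", paste(.topo_levels, collapse = ", "),
         call. = FALSE)
  topo
}

#' Gene-tree log-likelihood of an MSci model
#'
#' Sum over loci of the log joint density of each observed 3-tip gene tree
#' (rooted topology plus its two coalescence ages, outgroup removed). Trees
#' whose ages fall outside the support of the model (for instance an a-b
#' coalescence younger than `tau_T`) contribute `-Inf`, which is returned
#' rather than raised as an error.
#'
#' @param model an [msci_model()].
#' @param data either a data frame with columns `topology`, `t1`, `t2` (as
#'   produced by [simulate_triples()] or [as_triples()]) or a `multiPhylo` of
#'   gene trees containing tips `a`, `b`, `c` and an outgroup.
#' @param outgroup outgroup tip label, used when `data` is a set of trees.
#' @return the total log-likelihood (a single number, possibly `-Inf`).
#' @export
msci_loglik <- function(model, data, outgroup = "o") {
  tr <- .as_triples_df(data, outgroup)
  if (any(tr$t1 > tr$t2)) stop("found a locus with t1 > t2", call. = FALSE)
  sum(.joint_logpdf(model, .as_topo_index(tr$topology), tr$t1, tr$t2))
}

.as_triples_df <- function(data, outgroup = "o") {
  if (is.data.frame(data)) {
    if (!all(c("topology", "t1", "t2") %in% names(data)))
      stop("'data' must have columns topology, t1, t2", call. = FALSE)
    return(data)
  }
  if (inherits(data, "multiPhylo") || inherits(data, "phylo"))
    return(as_triples(data, outgroup = outgroup))
  stop("'data' must be a triples data frame or gene trees", call. = FALSE)
}
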