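#' Count rooted-triple topologies in a set of gene trees
#'
#' Each gene tree is rerooted on the outgroup, the outgroup is pruned, and the
#' remaining rooted triple over `a`, `b`, `c` is classified as `ab|c`,
#' `a|bc` or `ac|b`. A zero-length internal branch is classified by the given
#' topology (node ages break the tie in the simulated trees).
#'
#' @param trees a `multiPhylo` (or single `phylo`); every tree must contain
#'   tips `a`, `b`, `c` and the outgroup.
#' @param outgroup outgroup tip label.
#' @return an object of class `"topology_counts"` with fields `n1` (`ab|c`),
#'   `n2` (`a|bc`), `n3` (`ac|b`) and `n_total`.
#' @export
count_topologies <- function(trees, outgroup = "o") {
  tr <- .as_triples_df(trees, outgroup)
  tab <- table(factor(tr$topology, levels = .topo_levels))
  topology_counts(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' @rdname count_topologies
#' @param n1,n2,n3 counts of `ab|c`, `a|bc`, `ac|b`.
#' @export
topology_counts <- function(n1, n2, n3) {
  stopifnot(n1 >= 0, n2 >= 0, n3 >= 0, n1 + n2 + n3 >= 1)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), n3 = as.integer(n3),
                 n_total = as.integer(n1 + n2 + n3)),
            class = "topology_counts")
}

#' @export
print.topology_counts <- function(x, ...) {
  cat(sprintf("Rooted-triple counts: ab|c %d, a|bc %d, ac|b %d (total %d)\n",
              x$n1, x$n2, x$n3, x$n_total))
  invisible(x)
}

#' Extract rooted-triple summaries from gene trees
#'
#' Reroots each gene tree on the outgroup, prunes it, and returns the rooted
#' topology together with the two coalescence ages (tips are at age 0; the
#' trees must be ultrametric, as coalescent gene trees under a clock are).
#'
#' @inheritParams count_topologies
#' @return a data frame with columns `topology`, `t1`, `t2`.
#' @export
as_triples <- function(trees, outgroup = "o") {
  if (inherits(trees, "phylo")) trees <- c(trees)
  out <- data.frame(topology = factor(character(length(trees)),
                                      levels = .topo_levels),
                    t1 = numeric(length(trees)), t2 = numeric(length(trees)))
  for (i in seq_along(trees)) {
    r <- .classify_triple(trees[[i]], outgroup, i)
    out$topology[i] <- r$topology; out$t1[i] <- r$t1; out$t2[i] <- r$t2
  }
  out
}

.classify_triple <- function(tr, outgroup, locus = NA) {
  need <- c("a", "b", "c", outgroup)
  if (!all(need %in% tr$tip.label))
    stop("tree ", locus, " is missing taxa: ",
         paste(setdiff(need, tr$tip.label), collapse = ", "), call. = FALSE)
  tr <- ape::drop.tip(ape::root(ape::unroot(tr), outgroup, resolve.root = TRUE),
                      outgroup)
  # ages from root-to-node path lengths (clock trees: tips at age 0)
  depth <- ape::node.depth.edgelength(tr)
  age <- max(depth[seq_along(tr$tip.label)]) - depth
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  inner <- setdiff(unique(tr$edge[, 1L]), root)
  cherry <- sort(tr$tip.label[tr$edge[tr$edge[, 1L] == inner, 2L]])
  topo <- if (identical(cherry, c("a", "b"))) "ab|c"
          else if (identical(cherry, c("b", "c"))) "a|bc"
          else "ac|b"
  list(topology = topo, t1 = age[inner], t2 = age[root])
}

#' Profile likelihood of the introgression probability from topology counts
#'
#' The multinomial likelihood of rooted-triple counts under the topology
#' probabilities [topology_probs()] has only two degrees of freedom, so the
#' three parameters `(gamma, C_T, C_S)` sit on a one-dimensional ridge: for
#' every `gamma` inside the plug-in interval
#' `(p2_hat - p3_hat, 1 - (p1_hat - p3_hat))` there exist `C_T`, `C_S`
#' reproducing the observed frequencies exactly, and the profile
#' log-likelihood is perfectly flat there. This function computes the profile
#' over a `gamma` grid (maximizing over `C_T`, `C_S` capped at `cap`
#' coalescent units), locates the flat region by bisection, and draws the
#' kind of arbitrary point estimate a pseudo-likelihood network method
#' reports (uniform over the flat region).
#'
#' The maximized log-likelihood does not depend on which scenario label is
#' attached: ghost introgression, inflow and outflow fit topology counts
#' exactly equally well.
#'
#' @param counts a [topology_counts()] object.
#' @param gamma_grid grid of `gamma` values for the reported profile.
#' @param cap upper bound for `C_T`, `C_S` in coalescent units (effectively
#'   infinity).
#' @param scenario optional scenario label carried through (never used in the
#'   fit).
#' @return an object of class `"triple_profile"`: the grid, profile
#'   log-likelihood, `max_loglik`, `flat_region` (length-2 vector),
#'   `gamma_point` (uniform draw from the flat region; respects
#'   [set.seed()]), and the plug-in interval `plugin_interval`.
#' @export
triple_profile <- function(counts, gamma_grid = seq(0.001, 0.999, length.out = 201),
                           cap = 50, scenario = NULL) {
  stopifnot(inherits(counts, "topology_counts"))
  n <- c(counts$n1, counts$n2, counts$n3)
  prof <- vapply(gamma_grid, .profile_at_gamma, 0, n = n, cap = cap)
  Lmax <- max(prof)
  flat <- .flat_region(n, cap, Lmax, range(gamma_grid))
  p_hat <- n / sum(n)
  plugin <- c(low = max(0, p_hat[2L] - p_hat[3L]),
              high = min(1, 1 - (p_hat[1L] - p_hat[3L])))
  gamma_point <- if (flat[2L] > flat[1L])
    stats::runif(1, flat[1L], flat[2L]) else mean(flat)
  structure(list(gamma_grid = gamma_grid, profile = prof, max_loglik = Lmax,
                 flat_region = flat, plugin_interval = plugin,
                 gamma_point = gamma_point, counts = counts,
                 scenario = scenario, degenerate = any(p_hat[3L] > p_hat[-3L])),
            class = "triple_profile")
}

# maximized multinomial log-likelihood at fixed gamma
.profile_at_gamma <- function(gamma, n, cap = 50) {
  p_hat <- n / sum(n)
  qmin <- exp(-cap)
  D1 <- p_hat[1L] - p_hat[3L]; D2 <- p_hat[2L] - p_hat[3L]
  q1 <- 1 - D1 / (1 - gamma); q2 <- 1 - D2 / gamma
  if (q1 >= qmin && q1 <= 1 && q2 >= qmin && q2 <= 1)
    return(sum(n[n > 0] * log(p_hat[n > 0])))        # saturated fit
  negll <- function(u) {
    q1 <- qmin + (1 - qmin) * stats::plogis(u[1L])
    q2 <- qmin + (1 - qmin) * stats::plogis(u[2L])
    p <- topology_probs(gamma, -log(q1), -log(q2))
    -sum(n[n > 0] * log(p[n > 0]))
  }
  best <- Inf
  for (st in list(c(0, 0), c(4, -4), c(-4, 4)))
    best <- min(best, stats::optim(st, negll, method = "Nelder-Mead",
                                   control = list(maxit = 250,
                                                  reltol = 1e-10))$value)
  -best
}

# endpoints of the flat region by bisection on the profile itself
.flat_region <- function(n, cap, Lmax, bounds, tol = 1e-7) {
  flat_at <- function(g) .profile_at_gamma(g, n, cap) >= Lmax - 1e-8
  gg <- seq(bounds[1L], bounds[2L], length.out = 201)
  inside <- vapply(gg, flat_at, TRUE)
  if (!any(inside)) {
    i <- which.max(vapply(gg, .profile_at_gamma, 0, n = n, cap = cap))
    return(c(gg[i], gg[i]))
  }
  lo <- gg[which(inside)[1L]]; hi <- gg[rev(which(inside))[1L]]
  bis <- function(out, ins) {     # out: not flat, ins: flat
    for (i in 1:40) {
      mid <- (out + ins) / 2
      if (flat_at(mid)) ins <- mid else out <- mid
      if (abs(out - ins) < tol) break
    }
    ins
  }
  left <- if (lo > bounds[1L]) bis(max(bounds[1L], lo - diff(gg[1:2])), lo) else lo
  right <- if (hi < bounds[2L]) bis(min(bounds[2L], hi + diff(gg[1:2])), hi) else hi
  c(left, right)
}

#' @export
print.triple_profile <- function(x, ...) {
  cat("Topology-count profile likelihood\n")
  print(x$counts)
  cat(sprintf("  max log-likelihood: %.4f%s\n", x$max_loglik,
              if (!is.null(x$scenario)) paste0(" (label: ", x$scenario, ")") else ""))
  cat(sprintf("  flat region for gamma: [%.4f, %.4f]", x$flat_region[1L],
              x$flat_region[2L]))
  if (x$degenerate) cat("  (degenerate counts: boundary solution)")
  cat(sprintf("\n  arbitrary point estimate: %.4f\n", x$gamma_point))
  invisible(x)
}

#' @export
plot.triple_profile <- function(x, ...) {
  graphics::plot(x$gamma_grid, x$profile, type = "l", xlab = expression(gamma),
                 ylab = "profile log-likelihood", ...)
  graphics::abline(v = x$flat_region, lty = 2, col = "grey40")
  invisible(x)
}
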