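#' Multispecies-coalescent-with-introgression (MSci) model for a species trio
#'
#' Defines one of three introgression scenarios on the species tree `AB|C`
#' with a distant outgroup `O`:
#'
#' * `"GHOST"`  — introgression from an unsampled lineage that diverged from
#'   the stem lineage above the ingroup root into species A;
#' * `"INFLOW"` — introgression from C into B (into the sister pair);
#' * `"OUTFLOW"` — introgression from B into C (out of the sister pair).
#'
#' All times are measured backwards from the present in expected substitutions
#' per site (`tau = T * mu`); population sizes are `theta = 4 N mu` on the same
#' mutation scale, so a pair of lineages in a population of size `theta`
#' coalesces at rate `2/theta` and the within-population pairwise coalescent
#' time has mean `theta/2`.
#'
#' @param scenario one of `"GHOST"`, `"INFLOW"`, `"OUTFLOW"`.
#' @param tau_T divergence time of the sister species A and B (node T).
#' @param tau_R root of the sampled ingroup: divergence of (AB) and C (node R).
#' @param tau_H time of the introgression event. The recipient lineage (A for
#'   GHOST, B for INFLOW, C for OUTFLOW) switches to the donor population with
#'   probability `gamma` at this time; must predate `tau_T` so the recipient
#'   branch exists.
#' @param tau_G GHOST only: time at which the ghost lineage diverged from the
#'   stem above the ingroup root (`tau_R < tau_G < tau_O`). Ignored otherwise.
#' @param tau_O divergence of the distant outgroup O from the ancestral lineage.
#' @param theta population size parameter(s): either a single value applied to
#'   every population, or a named vector over population labels
#'   `A, B, C, T, R, G, O, anc` (`G` is the ghost branch, `anc` the population
#'   ancestral to everything sampled, `O` the outgroup stem).
#' @param gamma introgression probability in `[0, 1]`: the probability that a
#'   lineage sampled from the recipient species traces the introgressed
#'   history.
#'
#' @return An object of class `"msci_model"`.
#' @examples
#' m <- msci_model("GHOST", tau_T = 0.027, tau_R = 0.054, tau_H = 0.01,
#'                 tau_G = 0.081, tau_O = 0.144, theta = 0.036, gamma = 0.3)
#' internal_branch_lengths(m)
#' coalescent_units(m)
#' @seealso [msci_from_grid()] for the coalescent-unit parameterization used in
#'   the simulation grids, [topology_probs()] for the induced rooted-triple
#'   probabilities.
#' @export
msci_model <- function(scenario = c("GHOST", "INFLOW", "OUTFLOW"),
                       tau_T, tau_R, tau_H, tau_G = NA_real_, tau_O,
                       theta = 0.036, gamma = 0) {
  scenario <- match.arg(toupper(scenario), c("GHOST", "INFLOW", "OUTFLOW"))
  for (nm in c("tau_T", "tau_R", "tau_H", "tau_O", "gamma"))
    if (!is.numeric(get(nm)) || length(get(nm)) != 1L || !is.finite(get(nm)))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  theta <- .expand_theta(theta)
  if (any(theta <= 0)) stop("all population sizes 'theta' must be > 0", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]", call. = FALSE)
  if (tau_H <= 0) stop("'tau_H' must be > 0", call. = FALSE)
  if (!(tau_H < tau_T && tau_T < tau_R))
    stop("times must satisfy tau_H < tau_T < tau_R (the recipient branch must ",
         "exist at the time of introgression)", call. = FALSE)
  if (scenario == "GHOST") {
    if (!is.finite(tau_G))
      stop("GHOST models require 'tau_G' (ghost divergence above the root)", call. = FALSE)
    if (!(tau_R < tau_G && tau_G < tau_O))
      stop("GHOST models require tau_R < tau_G < tau_O", call. = FALSE)
  } else {
    if (!(tau_R < tau_O)) stop("times must satisfy tau_R < tau_O", call. = FALSE)
    tau_G <- NA_real_
  }
  structure(
    list(scenario = scenario, tau_T = tau_T, tau_R = tau_R, tau_H = tau_H,
         tau_G = tau_G, tau_O = tau_O, theta = theta, gamma = gamma),
    class = "msci_model")
}

.pop_labels <- c("A", "B", "C", "T", "R", "G", "O", "anc")

.expand_theta <- function(theta) {
  if (is.null(names(theta)) && length(theta) == 1L) {
    theta <- rep(theta, length(.pop_labels))
    names(theta) <- .pop_labels
    return(theta)
  }
  if (is.null(names(theta)) || !all(names(theta) %in% .pop_labels))
    stop("named 'theta' must use population labels ",
         paste(.pop_labels, collapse = ", "), call. = FALSE)
  out <- rep(NA_real_, length(.pop_labels)); names(out) <- .pop_labels
  out[names(theta)] <- theta
  if (anyNA(out)) stop("named 'theta' must cover all populations", call. = FALSE)
  out
}

#' @export
print.msci_model <- function(x, ...) {
  cat("MSci model (", x$scenario, ")\n", sep = "")
  cat(sprintf("  tau_H = %.6g  tau_T = %.6g  tau_R = %.6g", x$tau_H, x$tau_T, x$tau_R))
  if (x$scenario == "GHOST") cat(sprintf("  tau_G = %.6g", x$tau_G))
  cat(sprintf("  tau_O = %.6g\n", x$tau_O))
  cat(sprintf("  gamma = %.4g\n", x$gamma))
  if (length(unique(x$theta)) == 1L) {
    cat(sprintf("  theta = %.6g (all populations)\n", x$theta[[1L]]))
  } else {
    cat("  theta:", paste(names(x$theta), signif(x$theta, 4), sep = "=",
                          collapse = " "), "\n")
  }
  cu <- coalescent_units(x)
  cat(sprintf("  internal branches: C_T = %.4g, C_S = %.4g coalescent units\n",
              cu[["C_T"]], cu[["C_S"]]))
  invisible(x)
}

#' Internal branch lengths of the speciation and introgressed histories
#'
#' `l_T` is the interval during which only sequences a and b can coalesce when
#' the recipient lineage follows the speciation history; `l_S` is the interval
#' during which only b and c can coalesce along the introgressed history:
#' `l_T = tau_R - tau_T` in every scenario, and `l_S` equals
#' `tau_G - tau_R` (GHOST), `tau_R - tau_H` (INFLOW) or `tau_T - tau_H`
#' (OUTFLOW; above `tau_T` all three lineages share population T, so later
#' coalescences are symmetric and contribute no exclusive signal).
#'
#' @param model an [msci_model()].
#' @return named numeric vector `c(l_T =, l_S =)` in expected substitutions
#'   per site.
#' @export
internal_branch_lengths <- function(model) {
  stopifnot(inherits(model, "msci_model"))
  l_T <- model$tau_R - model$tau_T
  l_S <- switch(model$scenario,
    GHOST   = model$tau_G - model$tau_R,
    INFLOW  = model$tau_R - model$tau_H,
    OUTFLOW = model$tau_T - model$tau_H)
  c(l_T = l_T, l_S = l_S)
}

#' Internal branch lengths in coalescent units
#'
#' `C_T = 2 l_T / theta_T` and `C_S = 2 l_S / theta_S`, where `theta_S` is the
#' size of the population hosting the exclusive b-c coalescence window: the
#' stem segment between the ingroup root and the ghost divergence (GHOST),
#' population C (INFLOW) or population B (OUTFLOW). `exp(-C)` is the
#' probability that the focal pair fails to coalesce within the window.
#'
#' @inheritParams internal_branch_lengths
#' @return named numeric vector `c(C_T =, C_S =)` (dimensionless).
#' @export
coalescent_units <- function(model) {
  l <- internal_branch_lengths(model)
  th_S <- switch(model$scenario,
    GHOST   = model$theta[["R"]],
    INFLOW  = model$theta[["C"]],
    OUTFLOW = model$theta[["B"]])
  c(C_T = 2 * l[["l_T"]] / model$theta[["T"]],
    C_S = 2 * l[["l_S"]] / th_S)
}

#' Time of the introgression-history ancestor node S
#'
#' The node called S sits at the upper end of the introgressed history's
#' exclusive coalescence window: the ghost divergence `tau_G` for GHOST models
#' and the introgression time `tau_H` for INFLOW and OUTFLOW models (where the
#' introgression edge is horizontal and S and H are contemporaneous).
#'
#' @inheritParams internal_branch_lengths
#' @return a single time in expected substitutions per site.
#' @export
tau_S <- function(model) {
  stopifnot(inherits(model, "msci_model"))
  if (model$scenario == "GHOST") model$tau_G else model$tau_H
}

#' Build an MSci model from the coalescent-unit simulation grid
#'
#' The simulation grids are indexed by `(C1, C2, gamma)` under a constant
#' `theta`: `C2` is the length of the speciation-history internal branch T in
#' coalescent units (`C_T = C2`), and `C1` is the time of the introgression
#' event, measured from the present in coalescent units. The depth of the
#' sister divergence is fixed at `tip_cu` (1.5 CU), the ghost lineage diverges
#' `ghost_stem_cu` (1.5 CU) above the ingroup root, and the outgroup attaches
#' `outgroup_cu` (5 CU) above the root. One coalescent unit equals `theta/2`
#' mutation units.
#'
#' Under this construction `C_S` equals `ghost_stem_cu` (GHOST),
#' `C2 + tip_cu - C1` (INFLOW) or `tip_cu - C1` (OUTFLOW).
#'
#' @param scenario one of `"GHOST"`, `"INFLOW"`, `"OUTFLOW"`.
#' @param C1 introgression time from the present, coalescent units
#'   (`0 < C1 < tip_cu`).
#' @param C2 speciation-history internal branch length, coalescent units.
#' @param gamma introgression probability.
#' @param theta common population size (mutation units).
#' @param outgroup_cu outgroup divergence above the ingroup root, coalescent
#'   units.
#' @param ghost_stem_cu GHOST only: stem length between the ingroup root and
#'   the ghost divergence, coalescent units.
#' @param tip_cu depth of the sister divergence `tau_T`, coalescent units.
#' @return an [msci_model()] with constant `theta`.
#' @examples
#' msci_from_grid("GHOST", C1 = 0.3, C2 = 1.5, gamma = 0.3)
#' @export
msci_from_grid <- function(scenario, C1, C2, gamma, theta = 0.036,
                           outgroup_cu = 5, ghost_stem_cu = 1.5, tip_cu = 1.5) {
  if (any(c(C1, C2, theta, outgroup_cu, ghost_stem_cu, tip_cu) <= 0))
    stop("grid quantities must be positive", call. = FALSE)
  if (C1 >= tip_cu)
    stop("C1 must be below tip_cu: the introgression event must predate the ",
         "sister divergence", call. = FALSE)
  cu <- theta / 2
  tau_T <- tip_cu * cu
  tau_R <- tau_T + C2 * cu
  scenario <- match.arg(toupper(scenario), c("GHOST", "INFLOW", "OUTFLOW"))
  msci_model(scenario,
             tau_T = tau_T, tau_R = tau_R, tau_H = C1 * cu,
             tau_G = if (scenario == "GHOST") tau_R + ghost_stem_cu * cu else NA_real_,
             tau_O = tau_R + outgroup_cu * cu,
             theta = theta, gamma = gamma)
}

#' Read or write an MSci model as a flat key-value config file
#'
#' Plain-text serialization, one `key = value` per line. Population sizes are
#' stored as `theta.A`, `theta.B`, ... entries.
#'
#' @param model an [msci_model()].
#' @param path file path.
#' @return `write_msci_config()` returns `path` invisibly;
#'   `read_msci_config()` returns an [msci_model()].
#' @export
write_msci_config <- function(model, path) {
  stopifnot(inherits(model, "msci_model"))
  kv <- c(scenario = model$scenario,
          tau_T = format(model$tau_T, digits = 17),
          tau_R = format(model$tau_R, digits = 17),
          tau_H = format(model$tau_H, digits = 17),
          tau_G = format(model$tau_G, digits = 17),
          tau_O = format(model$tau_O, digits = 17),
          gamma = format(model$gamma, digits = 17))
  th <- vapply(model$theta, format, "", digits = 17)
  names(th) <- paste0("theta.", names(model$theta))
  writeLines(paste(names(c(kv, th)), "=", c(kv, th)), path)
  invisible(path)
}

#' @rdname write_msci_config
#' @export
read_msci_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  kv <- stats::setNames(vals, keys)
  th_keys <- grep("^theta\\.", keys, value = TRUE)
  theta <- stats::setNames(as.numeric(kv[th_keys]), sub("^theta\\.", "", th_keys))
  msci_model(kv[["scenario"]],
             tau_T = as.numeric(kv[["tau_T"]]), tau_R = as.numeric(kv[["tau_R"]]),
             tau_H = as.numeric(kv[["tau_H"]]),
             tau_G = as.numeric(kv[["tau_G"]]), tau_O = as.numeric(kv[["tau_O"]]),
             theta = theta, gamma = as.numeric(kv[["gamma"]]))
}
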