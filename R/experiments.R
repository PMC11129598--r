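#' Specification of a simulation grid
#'
#' A cartesian grid over scenarios, introgression times (`C1`, coalescent
#' units from the present), speciation-history branch lengths (`C2`) and
#' introgression probabilities, each cell replicated; see [msci_from_grid()]
#' for the induced model. Enumeration order is deterministic
#' (scenario-major, then `C1`, `C2`, `gamma`).
#'
#' @param scenarios character vector of scenario names.
#' @param c1,c2,gamma numeric vectors of grid values.
#' @param replicates replicates per cell.
#' @param n_loci,sites loci and sites per locus for each replicate.
#' @param theta common population size.
#' @param seed base seed; every (cell, replicate) derives its own seed from it.
#' @param methods subset of `"hyde"`, `"topology"`, `"likelihood"` (empty for
#'   simulation-only runs).
#' @param n_restarts restarts passed to [msci_select()] when `"likelihood"`
#'   is requested.
#' @return an object of class `"grid_spec"`.
#' @export
grid_spec <- function(scenarios = c("GHOST", "INFLOW", "OUTFLOW"),
                      c1 = 0.3, c2 = c(0.5, 1.5), gamma = 0.3,
                      replicates = 20, n_loci = 1000, sites = 1000,
                      theta = 0.036, seed = 1,
                      methods = c("hyde", "topology", "likelihood"),
                      n_restarts = 8) {
  if (length(methods)) methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(replicates >= 1, n_loci >= 1, sites >= 1, all(gamma >= 0 & gamma <= 1))
  cells <- expand.grid(gamma = gamma, c2 = c2, c1 = c1, scenario = scenarios,
                       stringsAsFactors = FALSE)[, c("scenario", "c1", "c2", "gamma")]
  structure(list(cells = cells, replicates = as.integer(replicates),
                 n_loci = as.integer(n_loci), sites = as.integer(sites),
                 theta = theta, seed = as.integer(seed), methods = methods,
                 n_restarts = n_restarts),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("Simulation grid:", nrow(x$cells), "cells x", x$replicates, "replicates,",
      x$n_loci, "loci x", x$sites, "bp; methods:",
      if (length(x$methods)) paste(x$methods, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Read or write a grid specification as a key-value config file
#'
#' Plain text, one `key = value` per line; vector values are comma-separated.
#'
#' @param spec a [grid_spec()].
#' @param path file path.
#' @export
write_grid_config <- function(spec, path) {
  kv <- c(scenarios = paste(unique(spec$cells$scenario), collapse = ","),
          c1 = paste(unique(spec$cells$c1), collapse = ","),
          c2 = paste(unique(spec$cells$c2), collapse = ","),
          gamma = paste(unique(spec$cells$gamma), collapse = ","),
          replicates = spec$replicates, n_loci = spec$n_loci,
          sites = spec$sites, theta = spec$theta, seed = spec$seed,
          methods = paste(spec$methods, collapse = ","),
          n_restarts = spec$n_restarts)
  writeLines(paste(names(kv), "=", kv), path)
  invisible(path)
}

#' @rdname write_grid_config
#' @export
read_grid_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- stats::setNames(trimws(sub("^[^=]*=", "", lines)),
                        trimws(sub("=.*", "", lines)))
  splitnum <- function(s) as.numeric(strsplit(s, ",")[[1L]])
  grid_spec(scenarios = strsplit(kv[["scenarios"]], ",")[[1L]],
            c1 = splitnum(kv[["c1"]]), c2 = splitnum(kv[["c2"]]),
            gamma = splitnum(kv[["gamma"]]),
            replicates = as.integer(kv[["replicates"]]),
            n_loci = as.integer(kv[["n_loci"]]), sites = as.integer(kv[["sites"]]),
            theta = as.numeric(kv[["theta"]]), seed = as.integer(kv[["seed"]]),
            methods = if (nzchar(kv[["methods"]]))
              strsplit(kv[["methods"]], ",")[[1L]] else character(),
            n_restarts = as.integer(kv[["n_restarts"]]))
}

#' Run a simulation grid
#'
#' For every cell and replicate: simulate gene trees (and sequences when the
#' HyDe-style test is requested), run the requested analyses, and aggregate
#' one row per replicate. Fully deterministic given the spec's seed; when
#' `out_dir` is given each cell is cached as a tab-separated file and
#' `resume = TRUE` skips finished cells. Failures inside a cell are logged
#' and skipped, never abort the grid. Within each cell the HyDe-style p
#' values are Benjamini-Hochberg adjusted across replicates.
#'
#' @param spec a [grid_spec()].
#' @param out_dir optional directory for per-cell caching.
#' @param resume reuse cached cell files if present.
#' @param alpha significance level for the adjusted HyDe-style calls.
#' @return an object of class `"grid_report"`: `$results` (one row per
#'   replicate), `$summary` (one row per cell) and the spec.
#' @export
run_grid <- function(spec, out_dir = NULL, resume = FALSE, alpha = 0.05) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- vector("list", nrow(spec$cells))
  for (ci in seq_len(nrow(spec$cells))) {
    cache <- if (!is.null(out_dir)) file.path(out_dir, sprintf("cell_%03d.tsv", ci))
    if (resume && !is.null(cache) && file.exists(cache)) {
      res[[ci]] <- utils::read.delim(cache, stringsAsFactors = FALSE)
      next
    }
    cell <- spec$cells[ci, ]
    rows <- tryCatch(.run_cell(spec, cell, ci, alpha),
                     error = function(e) {
                       message("cell ", ci, " failed: ", conditionMessage(e))
                       NULL
                     })
    if (!is.null(rows) && !is.null(cache))
      utils::write.table(rows, cache, sep = "\t", quote = FALSE, row.names = FALSE)
    res[[ci]] <- rows
  }
  done <- !vapply(res, is.null, TRUE)
  results <- do.call(rbind, res[done])
  structure(list(results = results, summary = .summarize_grid(spec, res, alpha),
                 spec = spec), class = "grid_report")
}

.run_cell <- function(spec, cell, ci, alpha) {
  model <- msci_from_grid(cell$scenario, cell$c1, cell$c2, cell$gamma,
                          theta = spec$theta)
  rows <- vector("list", spec$replicates)
  hyde_tests <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    seed_r <- as.integer((spec$seed + 104729 * ci + r) %% 2147483647)
    row <- data.frame(cell = ci, scenario = cell$scenario, c1 = cell$c1,
                      c2 = cell$c2, gamma = cell$gamma, replicate = r)
    need_trees4 <- "hyde" %in% spec$methods
    if (need_trees4) {
      cfg <- sim_config(n_loci = spec$n_loci, sites = spec$sites, seed = seed_r)
      trees <- simulate_gene_trees(model, cfg)
      aln <- simulate_alignments(trees, cfg)
      cnt <- count_site_patterns(aln)
      ht <- hyde_jackknife(cnt, alpha = alpha)
      hyde_tests[[r]] <- ht
      row$hyde_p <- ht$p.value
      row$hyde_hybrid <- ht$hybrid
      row$hyde_gamma <- ht$gamma_hat
      triples <- as_triples(trees)
    } else {
      triples <- simulate_triples(model, spec$n_loci, seed = seed_r)
    }
    if ("topology" %in% spec$methods) {
      prof <- triple_profile(count_topologies_from(triples))
      row$topo_flat_low <- prof$flat_region[1L]
      row$topo_flat_high <- prof$flat_region[2L]
      row$topo_gamma <- prof$gamma_point
    }
    if ("likelihood" %in% spec$methods) {
      sel <- msci_select(triples, n_restarts = spec$n_restarts, seed = seed_r)
      row$lik_selected <- sel$best
      row$lik_gamma <- sel$fits[[sel$best]]$model$gamma
      row$lik_delta2nd <- sort(sel$delta)[2L]
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  if ("hyde" %in% spec$methods) {
    adj <- bh_adjust(hyde_tests, alpha = alpha)
    out$hyde_p_adj <- vapply(adj, `[[`, 0, "p.adjusted")
    out$hyde_significant <- vapply(adj, `[[`, TRUE, "significant")
  }
  out
}

#' @rdname count_topologies
#' @param triples a triples data frame.
#' @export
count_topologies_from <- function(triples) {
  tab <- table(factor(triples$topology, levels = .topo_levels))
  topology_counts(tab[[1L]], tab[[2L]], tab[[3L]])
}

.summarize_grid <- function(spec, res, alpha) {
  out <- lapply(seq_len(nrow(spec$cells)), function(ci) {
    cell <- spec$cells[ci, ]
    s <- data.frame(cell = ci, cell, completed = !is.null(res[[ci]]))
    rows <- res[[ci]]
    if (is.null(rows)) return(s)
    s$replicates <- nrow(rows)
    if ("hyde_significant" %in% names(rows)) {
      s$hyde_n_sig <- sum(rows$hyde_significant)
      s$hyde_n_hybrid_B <- sum(rows$hyde_significant & rows$hyde_hybrid == "B")
      s$hyde_gamma_mean <- mean(rows$hyde_gamma, na.rm = TRUE)
    }
    if ("topo_gamma" %in% names(rows)) {
      s$topo_flat_low_mean <- mean(rows$topo_flat_low)
      s$topo_flat_high_mean <- mean(rows$topo_flat_high)
    }
    if ("lik_selected" %in% names(rows)) {
      s$lik_n_true <- sum(rows$lik_selected == cell$scenario)
      s$lik_gamma_mean <- mean(rows$lik_gamma)
    }
    s
  })
  nm <- unique(unlist(lapply(out, names)))
  do.call(rbind, lapply(out, function(s) { s[setdiff(nm, names(s))] <- NA; s[nm] }))
}

#' Write the tables of a grid report
#'
#' Writes `results.tsv` (one row per replicate) and `summary.tsv` (one row
#' per cell, incomplete cells marked, never dropped). Byte-identical on
#' rerun with the same report.
#'
#' @param report a `"grid_report"` from [run_grid()].
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
report_tables <- function(report, outdir) {
  stopifnot(inherits(report, "grid_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("results.tsv", "summary.tsv"))
  tryCatch({
    utils::write.table(report$results, paths[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(report$summary, paths[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, error = function(e)
    stop("failed writing report under '", outdir, "': ", conditionMessage(e),
         call. = FALSE))
  invisible(paths)
}

#' Illustration presets for the pairwise coalescent-time densities
#'
#' Three models (one per scenario) used to draw the pairwise densities whose
#' support minima and discontinuities distinguish the scenarios. The inflow
#' and outflow presets use `tau_H = 0.15 theta`, `tau_T = 0.75 theta`,
#' `tau_R = theta`; the ghost preset uses `tau_T = 0.75 theta`,
#' `tau_R = 1.75 theta` with the ghost divergence 1.5 coalescent units
#' (`0.75 theta`) above the root.
#'
#' @param theta common population size.
#' @param gamma introgression probability.
#' @return named list of three [msci_model()] objects.
#' @export
scenario_presets <- function(theta = 0.036, gamma = 0.3) {
  list(
    GHOST = msci_model("GHOST", tau_T = 0.75 * theta, tau_R = 1.75 * theta,
                       tau_H = 0.375 * theta, tau_G = 2.5 * theta,
                       tau_O = 4.25 * theta, theta = theta, gamma = gamma),
    INFLOW = msci_model("INFLOW", tau_T = 0.75 * theta, tau_R = theta,
                        tau_H = 0.15 * theta, tau_O = 3.5 * theta,
                        theta = theta, gamma = gamma),
    OUTFLOW = msci_model("OUTFLOW", tau_T = 0.75 * theta, tau_R = theta,
                         tau_H = 0.15 * theta, tau_O = 3.5 * theta,
                         theta = theta, gamma = gamma))
}

#' Plot the pairwise coalescent-time densities of a set of models
#'
#' One panel per model overlaying the analytic densities of `t_ab`, `t_bc`
#' and `t_ac`, with dashed guides at the model's divergence times; optionally
#' overlays histograms of simulated pairwise coalescent ages.
#'
#' @param models list of [msci_model()] objects (default [scenario_presets()]).
#' @param file optional PDF path; when `NULL`, plots on the active device.
#' @param n_sim if positive, number of simulated loci per model for the
#'   histogram overlay.
#' @param seed seed for the overlay simulation.
#' @return invisibly, `file` (or `NULL`).
#' @export
plot_scenario_densities <- function(models = scenario_presets(), file = NULL,
                                n_sim = 0, seed = NULL) {
  if (!is.null(file)) grDevices::pdf(file, width = 9, height = 3.2 * length(models))
  op <- graphics::par(mfrow = c(length(models), 1), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  for (nm in names(models)) {
    m <- models[[nm]]
    to <- (if (m$scenario == "GHOST") m$tau_G else m$tau_R) + 2.5 * max(m$theta)
    tt <- seq(0, to, length.out = 600)
    dens <- lapply(c("ab", "bc", "ac"), function(p)
      mixture_pdf(pairwise_density(m, p), tt))
    sims <- NULL
    if (n_sim > 0) {
      tr <- simulate_triples(m, n_sim, seed = seed)
      sims <- lapply(c("ab", "bc", "ac"), function(p) .pair_age(tr, p))
    }
    ylim <- c(0, max(unlist(dens)))
    graphics::plot(NA, xlim = c(0, to), ylim = ylim, xlab = "coalescent time",
                   ylab = "density", main = nm)
    if (!is.null(sims))
      for (j in 1:3)
        graphics::hist(sims[[j]], breaks = 60, freq = FALSE, add = TRUE,
                       border = grDevices::adjustcolor(j + 1, 0.3), lty = 0,
                       col = grDevices::adjustcolor(j + 1, 0.15))
    for (j in 1:3) graphics::lines(tt, dens[[j]], col = j + 1, lwd = 2)
    guides <- c(m$tau_H, m$tau_T, m$tau_R, if (m$scenario == "GHOST") m$tau_G)
    graphics::abline(v = guides, lty = 3, col = "grey50")
    graphics::legend("topright", legend = c("t_ab", "t_bc", "t_ac"),
                     col = 2:4, lwd = 2, bty = "n")
  }
  invisible(file)
}
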