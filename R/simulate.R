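#' Simulation settings for multilocus data
#'
#' @param n_loci number of independent loci.
#' @param sites alignment length per locus (bp).
#' @param seqs_per_species number of sequences sampled per ingroup species
#'   (the outgroup always contributes one sequence).
#' @param model substitution model, `"HKY"` or `"JC69"`.
#' @param kappa HKY transition/transversion rate ratio. The default `kappa = 1`
#'   gives a transition:transversion ratio of 0.5 under equal base
#'   frequencies.
#' @param base_freqs stationary base frequencies (A, C, G, T).
#' @param seed integer seed fixing the whole simulation stream; per-locus
#'   substreams are derived from it so any locus is reproducible in isolation.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_loci = 1000, sites = 1000, seqs_per_species = 1,
                       model = c("HKY", "JC69"), kappa = 1,
                       base_freqs = rep(0.25, 4), seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_loci >= 1, sites >= 1, seqs_per_species >= 1, kappa > 0,
            length(base_freqs) == 4, all(base_freqs > 0))
  base_freqs <- base_freqs / sum(base_freqs)
  structure(list(n_loci = as.integer(n_loci), sites = as.integer(sites),
                 seqs_per_species = as.integer(seqs_per_species),
                 model = model, kappa = kappa, base_freqs = base_freqs,
                 seed = seed),
            class = "sim_config")
}

.locus_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate gene trees under an MSci model
#'
#' Event-driven coalescent simulation on the species network: each lineage of
#' the recipient species still present at `tau_H` independently switches to
#' the donor population with probability `gamma`; within every population a
#' pair of lineages coalesces at rate `2/theta`, and populations merge at the
#' divergence times of the scenario. Node ages are exact and branch lengths
#' are in expected substitutions per site.
#'
#' Tip labels are `a`, `b`, `c`, `o` for one sequence per species, and
#' `a1, a2, ..., o` when `seqs_per_species > 1`.
#'
#' @param model an [msci_model()].
#' @param config a [sim_config()]; `n_loci`, `seqs_per_species` and `seed` are
#'   used here.
#' @return a `multiPhylo` of rooted gene trees.
#' @seealso [simulate_triples()] for a fast sampler of
#'   `(topology, t1, t2)` summaries with one sequence per species and no
#'   outgroup.
#' @export
simulate_gene_trees <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "msci_model"), inherits(config, "sim_config"))
  seeds <- .locus_seeds(config$seed, config$n_loci)
  trees <- vector("list", config$n_loci)
  for (i in seq_len(config$n_loci)) {
    set.seed(seeds[i])
    trees[[i]] <- .sim_one_locus(model, config$seqs_per_species)
  }
  class(trees) <- "multiPhylo"
  trees
}

# one locus -> phylo; n sequences per ingroup species, 1 outgroup seq
.sim_one_locus <- function(model, n_per_sp = 1L) {
  s <- model$scenario
  recipient <- switch(s, GHOST = "A", INFLOW = "B", OUTFLOW = "C")
  target <- switch(s, GHOST = "G", INFLOW = "C", OUTFLOW = "B")
  labs <- if (n_per_sp == 1L) c("a", "b", "c") else
    as.vector(t(outer(c("a", "b", "c"), seq_len(n_per_sp), paste0)))
  pop <- c(rep(c("A", "B", "C"), each = n_per_sp), "O")
  ntip <- length(pop)
  node <- seq_len(ntip)         # node id per active lineage
  age <- rep(0, ntip)           # age of each lineage's node
  merges <- matrix(0, nrow = ntip - 1L, ncol = 3L)  # child1, child2, age
  nm <- 0L
  # merge events: time, populations merged, label afterwards
  ev <- list(list(t = model$tau_H, what = "jump"),
             list(t = model$tau_T, from = c("A", "B"), to = "T"),
             list(t = model$tau_R, from = c("T", "C"), to = "R"))
  if (s == "GHOST")
    ev <- c(ev, list(list(t = model$tau_G, from = c("G", "R"), to = "anc")))
  ev <- c(ev, list(list(t = model$tau_O, from = c("R", "anc", "O"), to = "anc"),
                   list(t = Inf)))
  ev <- ev[order(vapply(ev, `[[`, 0, "t"))]
  t0 <- 0
  for (e in ev) {
    # coalesce until the next demographic event
    repeat {
      if (length(pop) == 1L) break
      tab <- table(pop)
      rates <- tab * (tab - 1) / model$theta[names(tab)]
      tot <- sum(rates)
      if (tot == 0) break
      t1 <- t0 + stats::rexp(1, tot)
      if (t1 >= e$t) break
      p <- sample(names(rates), 1L, prob = rates)
      idx <- which(pop == p)
      pick <- sample(idx, 2L)
      nm <- nm + 1L
      merges[nm, ] <- c(node[pick], t1)
      node[pick[1L]] <- ntip + nm
      age[pick[1L]] <- t1
      pop <- pop[-pick[2L]]; node <- node[-pick[2L]]; age <- age[-pick[2L]]
      t0 <- t1
    }
    if (length(pop) == 1L) break
    t0 <- e$t
    if (is.infinite(e$t)) break
    if (identical(e$what, "jump")) {
      r <- which(pop == recipient)
      if (length(r)) {
        move <- r[stats::runif(length(r)) < model$gamma]
        pop[move] <- target
      }
    } else {
      pop[pop %in% e$from] <- e$to
    }
  }
  .merges_to_phylo(merges, c(labs, "o"))
}

# build an ape phylo from the merge record; internal ids were assigned in
# merge order (ntip+1, ntip+2, ...), so renumber to put the root at ntip+1
.merges_to_phylo <- function(merges, tip_label) {
  ntip <- length(tip_label)
  K <- ntip - 1L
  node_age <- merges[, 3L]
  new_id <- function(id) ifelse(id <= ntip, id, ntip + (K - (id - ntip) + 1L))
  parent <- rep(seq_len(K) + ntip, each = 2L)           # merge ids
  child <- as.vector(t(merges[, 1:2, drop = FALSE]))
  child_age <- ifelse(child <= ntip, 0, node_age[pmax(child - ntip, 1L)])
  edge_len <- node_age[rep(seq_len(K), each = 2L)] - child_age
  tree <- structure(list(edge = cbind(new_id(parent), new_id(child)),
                         edge.length = edge_len,
                         tip.label = tip_label, Nnode = K),
                    class = "phylo")
  storage.mode(tree$edge) <- "integer"
  ape::reorder.phylo(tree, "cladewise")
}

#' Fast sampler of rooted-triple summaries
#'
#' Vectorized coalescent sampler for one sequence per ingroup species (no
#' outgroup): draws, for each locus, the recipient path (introgressed with
#' probability `gamma`), then races the pairwise coalescences through the
#' piecewise-constant epoch rates. Distributionally identical to extracting
#' `(topology, t1, t2)` from [simulate_gene_trees()], but orders of magnitude
#' faster for large locus counts.
#'
#' @param model an [msci_model()].
#' @param n_loci number of loci.
#' @param seed optional integer seed.
#' @return a data frame with columns `topology` (factor with levels
#'   `"ab|c"`, `"a|bc"`, `"ac|b"`), `t1` and `t2` (ages in mutation units).
#' @export
simulate_triples <- function(model, n_loci, seed = NULL) {
  stopifnot(inherits(model, "msci_model"), n_loci >= 1)
  if (!is.null(seed)) set.seed(seed)
  jump <- stats::runif(n_loci) < model$gamma
  out_topo <- integer(n_loci); out_t1 <- numeric(n_loci); out_t2 <- numeric(n_loci)
  for (path in c("stay", "jump")) {
    sel <- if (path == "stay") which(!jump) else which(jump)
    if (!length(sel)) next
    pr <- .pair_rates(model, path)
    res <- .race_triples(pr$breaks, pr$rates, length(sel))
    out_topo[sel] <- res$topo; out_t1[sel] <- res$t1; out_t2[sel] <- res$t2
  }
  data.frame(topology = factor(.topo_levels[out_topo], levels = .topo_levels),
             t1 = out_t1, t2 = out_t2)
}

# race n triples through interval structure; rates is the 3 x (K+1) pair-rate
# matrix on intervals delimited by breaks
.race_triples <- function(breaks, rates, n) {
  bounds <- c(0, breaks, Inf)
  topo <- integer(n); t1 <- rep(NA_real_, n); t2 <- rep(NA_real_, n)
  lower2 <- rep(NA_real_, n)  # entry time into 2-lineage state per locus
  for (k in seq_len(ncol(rates))) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    # second coalescence for loci already in the 2-lineage state
    act2 <- which(!is.na(t1) & is.na(t2))
    if (length(act2)) {
      q <- rates[cbind(.cross_idx[topo[act2]], k)]
      pos <- q > 0
      if (any(pos)) {
        cand <- pmax(lo, lower2[act2[pos]]) + stats::rexp(sum(pos), q[pos])
        hit <- cand < hi
        t2[act2[pos][hit]] <- cand[hit]
      }
    }
    # first coalescence for loci still holding 3 lineages
    act3 <- which(is.na(t1))
    if (length(act3)) {
      rk <- rates[, k]; tot <- sum(rk)
      if (tot > 0) {
        cand <- lo + stats::rexp(length(act3), tot)
        hit <- which(cand < hi)
        if (length(hit)) {
          ii <- act3[hit]
          pairs <- sample.int(3L, length(hit), replace = TRUE, prob = rk / tot)
          topo[ii] <- pairs           # pair index == topology index
          t1[ii] <- cand[hit]
          lower2[ii] <- cand[hit]
          # try the second coalescence within the remainder of this interval
          q <- rates[cbind(.cross_idx[pairs], k)]
          pos <- q > 0
          if (any(pos)) {
            cand2 <- t1[ii][pos] + stats::rexp(sum(pos), q[pos])
            hit2 <- cand2 < hi
            t2[ii[pos][hit2]] <- cand2[hit2]
          }
        }
      }
    }
    if (!anyNA(t2)) break
  }
  list(topo = topo, t1 = t1, t2 = t2)
}

# cross-pair row index per topology (see .cross_pair)
.cross_idx <- c(3L, 1L, 1L)

#' Evolve sequences along gene trees
#'
#' Sites evolve i.i.d. under a reversible continuous-time Markov substitution
#' model (JC69, or HKY with configurable `kappa` and base frequencies) with
#' the root state drawn from the stationary distribution. Branch lengths are
#' taken as expected substitutions per site. Simulation is delegated to
#' [phangorn::simSeq()].
#'
#' @param trees a `multiPhylo` (or single `phylo`) with non-negative branch
#'   lengths.
#' @param config a [sim_config()]; `sites`, `model`, `kappa`, `base_freqs` and
#'   `seed` are used here.
#' @return a list of character matrices (one per locus; rows = taxa, columns =
#'   sites, entries `"a"/"c"/"g"/"t"`) of class `"locus_alignments"`.
#' @export
simulate_alignments <- function(trees, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  for (tr in trees)
    if (any(tr$edge.length < 0))
      stop("trees must have non-negative branch lengths", call. = FALSE)
  Q <- if (config$model == "JC69") rep(1, 6) else
    c(1, config$kappa, 1, 1, config$kappa, 1)
  bf <- if (config$model == "JC69") rep(0.25, 4) else config$base_freqs
  seeds <- .locus_seeds(config$seed, length(trees))
  out <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    set.seed(seeds[i])
    out[[i]] <- as.character(phangorn::simSeq(trees[[i]], l = config$sites,
                                              Q = Q, bf = bf))
  }
  class(out) <- "locus_alignments"
  out
}

#' Write or read a simulated multilocus dataset
#'
#' Writes the gene trees (one Newick per line), one alignment file per locus
#' (FASTA or relaxed sequential PHYLIP) and a plain-text manifest recording
#' the model and simulation settings; `read_dataset()` round-trips the lot.
#'
#' @param trees a `multiPhylo` of gene trees (may be `NULL`).
#' @param alignments a `"locus_alignments"` list (may be `NULL`).
#' @param outdir output directory, created if needed.
#' @param model,config optional [msci_model()] / [sim_config()] recorded in
#'   the manifest.
#' @param format `"fasta"` or `"phylip"`.
#' @return `write_dataset()` returns `outdir` invisibly; `read_dataset()`
#'   returns `list(trees, alignments, manifest)`.
#' @export
write_dataset <- function(trees, alignments, outdir, model = NULL,
                          config = NULL, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wrap <- function(expr, what) tryCatch(expr, error = function(e)
    stop("failed writing ", what, " under '", outdir, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(trees) && length(trees))
    wrap(ape::write.tree(trees, file.path(outdir, "trees.nwk"), digits = 15),
         "trees.nwk")
  ext <- if (format == "fasta") "fa" else "phy"
  for (i in seq_along(alignments)) {
    f <- file.path(outdir, sprintf("locus_%05d.%s", i, ext))
    m <- alignments[[i]]
    if (format == "fasta") {
      wrap(writeLines(rbind(paste0(">", rownames(m)),
                            apply(m, 1L, paste0, collapse = "")), f), basename(f))
    } else {
      wrap(writeLines(c(paste(nrow(m), ncol(m)),
                        paste(formatC(rownames(m), width = 10, flag = "-"),
                              apply(m, 1L, paste0, collapse = ""))), f), basename(f))
    }
  }
  man <- c(n_loci = if (is.null(alignments)) length(trees) else length(alignments),
           format = format)
  if (!is.null(config))
    man <- c(man, sites = config$sites, seqs_per_species = config$seqs_per_species,
             subst_model = config$model, kappa = config$kappa,
             base_freqs = paste(config$base_freqs, collapse = ","),
             seed = if (is.null(config$seed)) "NA" else config$seed)
  if (!is.null(model)) {
    tmp <- tempfile(); write_msci_config(model, tmp)
    man <- c(man, stats::setNames(sub("^[^=]*= ", "", readLines(tmp)),
                                  paste0("model.", trimws(sub("=.*", "", readLines(tmp))))))
    unlink(tmp)
  }
  writeLines(paste(names(man), "=", man), file.path(outdir, "manifest.txt"))
  invisible(outdir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(outdir) {
  manifest_path <- file.path(outdir, "manifest.txt")
  if (!file.exists(manifest_path))
    stop("no manifest.txt under '", outdir, "'", call. = FALSE)
  lines <- readLines(manifest_path)
  manifest <- stats::setNames(trimws(sub("^[^=]*=", "", lines)),
                              trimws(sub("=.*", "", lines)))
  trees <- NULL
  if (file.exists(file.path(outdir, "trees.nwk")))
    trees <- ape::read.tree(file.path(outdir, "trees.nwk"))
  if (inherits(trees, "phylo")) { trees <- c(trees); class(trees) <- "multiPhylo" }
  files <- sort(list.files(outdir, pattern = "^locus_\\d+\\.(fa|phy)$",
                           full.names = TRUE))
  alignments <- lapply(files, .read_locus)
  class(alignments) <- "locus_alignments"
  list(trees = trees, alignments = alignments, manifest = manifest)
}

.read_locus <- function(f) {
  if (grepl("\\.fa$", f)) {
    m <- tolower(as.character(as.matrix(ape::read.FASTA(f))))
  } else {
    lines <- readLines(f)[-1L]
    nm <- trimws(substr(lines, 1, 10))
    m <- do.call(rbind, strsplit(tolower(substring(lines, 12)), ""))
    rownames(m) <- nm
  }
  m
}

#' @export
simulate.msci_model <- function(object, nsim = 1000, seed = NULL, ...) {
  simulate_triples(object, n_loci = nsim, seed = seed)
}
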