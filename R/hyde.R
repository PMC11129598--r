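#' Count parsimony-informative site patterns across loci
#'
#' Classifies every alignment column of each locus against the taxon roles
#' (A, B, C, outgroup last): a site is counted only if it is biallelic and the
#' outgroup carries one of the two states (taken as ancestral, "A"), with the
#' derived state ("B") shared by exactly two ingroup taxa. `BBAA` sites group
#' A with B, `ABBA` groups B with C, `BABA` groups A with C; sites with three
#' or more alleles, a singleton derived state, or the derived state in all
#' three ingroup taxa are excluded.
#'
#' @param alignments a `"locus_alignments"` list (see [simulate_alignments()]),
#'   or a single character matrix.
#' @param taxon_map named character vector mapping roles to tip labels,
#'   default `c(A = "a", B = "b", C = "c", O = "o")`; alternatively the path
#'   of a plain-text file with one `role = label` line per taxon.
#' @return an object of class `"site_pattern_counts"`: per-locus counts
#'   (`$per_locus`, one row per locus), pooled counts (`$pooled`), the total
#'   number of sites scanned and the number of blocks (loci).
#' @export
count_site_patterns <- function(alignments,
                                taxon_map = c(A = "a", B = "b", C = "c", O = "o")) {
  if (is.matrix(alignments)) alignments <- list(alignments)
  if (is.null(names(taxon_map)) && length(taxon_map) == 1L &&
      file.exists(taxon_map)) {
    lines <- grep("=", readLines(taxon_map), fixed = TRUE, value = TRUE)
    taxon_map <- stats::setNames(trimws(sub("^[^=]*=", "", lines)),
                                 toupper(trimws(sub("=.*", "", lines))))
  }
  if (!all(c("A", "B", "C", "O") %in% names(taxon_map)))
    stop("'taxon_map' must name A, B, C and O", call. = FALSE)
  n_loci <- length(alignments)
  rows <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    m <- alignments[[i]]
    if (!is.matrix(m)) {               # list of per-taxon sequences
      if (length(unique(lengths(m))) != 1L)
        stop("locus ", i, ": sequences have unequal lengths", call. = FALSE)
      m <- do.call(rbind, m)
    }
    miss <- setdiff(taxon_map, rownames(m))
    if (length(miss))
      stop("locus ", i, " is missing taxa: ", paste(miss, collapse = ", "),
           call. = FALSE)
    rows[[i]] <- m[taxon_map, , drop = FALSE]
  }
  per <- matrix(0L, nrow = n_loci, ncol = 3L,
                dimnames = list(NULL, c("BBAA", "ABBA", "BABA")))
  total <- 0L
  for (i in seq_len(n_loci)) {
    m <- rows[[i]]
    a <- m[1L, ]; b <- m[2L, ]; cc <- m[3L, ]; o <- m[4L, ]
    bad <- !(a %in% .dna_states & b %in% .dna_states &
             cc %in% .dna_states & o %in% .dna_states)
    if (any(bad)) {
      lowered <- FALSE
      if (any(grepl("[ACGT]", m))) { m <- tolower(m); lowered <- TRUE }
      if (lowered) {
        a <- m[1L, ]; b <- m[2L, ]; cc <- m[3L, ]; o <- m[4L, ]
        bad <- !(a %in% .dna_states & b %in% .dna_states &
                 cc %in% .dna_states & o %in% .dna_states)
      }
      if (any(bad))
        stop("locus ", i, ": unknown characters at ", sum(bad), " site(s)",
             call. = FALSE)
    }
    da <- a != o; db <- b != o; dc <- cc != o
    nder <- da + db + dc
    per[i, 1L] <- sum(nder == 2L & da & db & a == b)
    per[i, 2L] <- sum(nder == 2L & db & dc & b == cc)
    per[i, 3L] <- sum(nder == 2L & da & dc & a == cc)
    total <- total + length(a)
  }
  structure(list(per_locus = per, pooled = colSums(per), total_sites = total,
                 n_blocks = length(alignments)),
            class = "site_pattern_counts")
}

.dna_states <- c("a", "c", "g", "t")

#' @export
print.site_pattern_counts <- function(x, ...) {
  cat("Site-pattern counts over", x$n_blocks, "loci (", x$total_sites, "sites )\n")
  print(x$pooled)
  invisible(x)
}

#' Block-jackknife site-pattern test for introgression
#'
#' Tests the multispecies-coalescent null hypothesis that the two least
#' frequent site patterns are equally frequent. The statistic is the pooled
#' difference between the second-smallest and smallest pattern counts,
#' normalized by a delete-one-block (one block = one locus) jackknife standard
#' error; the jackknife accounts for the non-independence of sites within a
#' locus that share one genealogy, which otherwise makes pooled-count tests
#' wildly anticonservative. Because the identity of the two rival patterns is
#' chosen from the data, the one-sided normal tail is doubled, which keeps the
#' test calibrated at its nominal level under the null.
#'
#' A significant result is interpreted the way HyDe's hybrid-speciation model
#' dictates: the two taxa sharing the derived state in the rarest pattern are
#' the putative parents and the remaining taxon is the hybrid, with the
#' introgression fraction estimated by the empirical ratio
#' `(mid - small) / (mid + large - 2 small)` (patterns oriented so the
#' numerator pairs the hybrid with its non-sister parent). Since `BABA` is the
#' rarest pattern under ghost introgression, inflow and outflow alike, the
#' call is "B is the hybrid" — correct only for inflow.
#'
#' @param counts a `"site_pattern_counts"` object (at least 2 blocks).
#' @param alpha significance level applied to the (adjusted) p value.
#' @return an object of class `"hyde_test"` with fields `z`, `p.value`,
#'   `p.adjusted` (equal to `p.value` until adjusted across tests, see
#'   [bh_adjust()]), `significant`, `hybrid`, `parents`, `gamma_hat` and the
#'   pooled counts.
#' @export
hyde_jackknife <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "site_pattern_counts"))
  if (counts$n_blocks < 2L)
    stop("need at least 2 blocks (loci) for the jackknife", call. = FALSE)
  pooled <- counts$pooled
  ord <- order(pooled)                 # smallest, middle, largest
  small <- names(pooled)[ord[1L]]; mid <- names(pooled)[ord[2L]]
  nb <- counts$n_blocks
  d_full <- pooled[[mid]] - pooled[[small]]
  d_loo <- (pooled[[mid]] - counts$per_locus[, mid]) -
           (pooled[[small]] - counts$per_locus[, small])
  se <- sqrt((nb - 1) / nb * sum((d_loo - mean(d_loo))^2))
  if (sum(pooled > 0) < 2L || d_full == 0) {
    z <- 0; p <- 1
  } else if (se == 0) {
    warning("zero jackknife variance; returning p = 1")
    z <- NA_real_; p <- 1
  } else {
    z <- d_full / se
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  hy <- .hybrid_call(small)
  gam <- .gamma_from_counts(pooled, small)
  structure(list(z = z, p.value = p, p.adjusted = p,
                 significant = p < alpha, alpha = alpha,
                 hybrid = hy$hybrid, parents = hy$parents,
                 gamma_hat = gam, counts = pooled, n_blocks = nb),
            class = "hyde_test")
}

# the taxa sharing the derived state in the rarest pattern are the parents
.hybrid_call <- function(smallest) {
  switch(smallest,
         BABA = list(hybrid = "B", parents = c("A", "C")),
         ABBA = list(hybrid = "A", parents = c("B", "C")),
         BBAA = list(hybrid = "C", parents = c("A", "B")))
}

# empirical analogue of the HyDe gamma formula, oriented so the numerator
# pairs the hybrid with the later-listed parent (C for hybrid B, matching
# gamma = share inherited from the introgressed history)
.gamma_from_counts <- function(pooled, smallest) {
  num_pat <- switch(smallest, BABA = "ABBA", ABBA = "BABA", BBAA = "ABBA")
  oth_pat <- setdiff(names(pooled), c(smallest, num_pat))
  den <- (pooled[[num_pat]] - pooled[[smallest]]) +
         (pooled[[oth_pat]] - pooled[[smallest]])
  if (den <= 0) return(NA_real_)
  min(1, max(0, (pooled[[num_pat]] - pooled[[smallest]]) / den))
}

#' @export
print.hyde_test <- function(x, ...) {
  cat("Block-jackknife site-pattern test (", x$n_blocks, "blocks )\n")
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = "  "), "\n")
  cat(sprintf("  z = %.3f, p = %.4g, adjusted p = %.4g -> %s\n", x$z, x$p.value,
              x$p.adjusted, if (x$significant) "significant" else "not significant"))
  if (x$significant)
    cat(sprintf("  inferred hybrid %s (parents %s), gamma_hat = %.4f\n",
                x$hybrid, paste(x$parents, collapse = ","), x$gamma_hat))
  invisible(x)
}

#' Benjamini-Hochberg adjustment of p values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' wraps [stats::p.adjust()] with `method = "BH"`. When given a list of
#' `"hyde_test"` objects it returns them with `p.adjusted` and `significant`
#' updated.
#'
#' @param p numeric vector of p values in `[0, 1]`, or a list of
#'   `"hyde_test"` results.
#' @param alpha significance level used when re-flagging test objects.
#' @return adjusted p values (or the updated list of tests).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (is.list(p) && all(vapply(p, inherits, TRUE, "hyde_test"))) {
    adj <- stats::p.adjust(vapply(p, `[[`, 0, "p.value"), method = "BH")
    return(Map(function(t, a) { t$p.adjusted <- a; t$significant <- a < alpha; t },
               p, adj))
  }
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
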