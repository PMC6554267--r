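# Evaluation statistics: automorphism-corrected RMSD, success curves,
# RMSD95, Kolmogorov-Smirnov critical differences and paired t-tests.

#' Automorphism-corrected RMSD of an ensemble against a reference
#'
#' For every conformer and every heavy-atom graph automorphism, the optimal
#' rigid superposition (Kabsch) is applied and the heavy-atom RMSD computed;
#' the minimum is reported. For macrocyclic molecules the ring RMSD
#' (macrocyclic-system atoms) is evaluated under the same search.
#'
#' @param mol a [mol_graph()]
#' @param ensemble a `conformer_ensemble` or list of conformers
#' @param reference reference conformer (or coordinate matrix)
#' @param cap automorphism cap (see [mol_automorphisms()])
#' @return list with `rmsd`, `ring_rmsd` (NA when non-macrocyclic),
#'   `best_conformer`
#' @export
automorph_rmsd <- function(mol, ensemble, reference, cap = 10000) {
  confs <- if (inherits(ensemble, "conformer_ensemble")) ensemble$conformers
           else ensemble
  ref_xyz <- if (is.matrix(reference)) reference else reference$xyz
  maps <- mol_automorphisms(mol, cap = cap)
  hv <- heavy_atoms(mol)
  macros <- perceive_macrocycles(mol)
  ring_atoms <- sort(unique(unlist(lapply(macros, function(m) m$atoms))))
  best <- Inf; best_k <- NA_integer_
  best_ring <- Inf
  for (k in seq_along(confs)) {
    r <- min_map_rmsd_cpp(ref_xyz, confs[[k]]$xyz, maps, hv)
    if (r < best) { best <- r; best_k <- k }
    if (length(ring_atoms)) {
      rr <- min_map_rmsd_cpp(ref_xyz, confs[[k]]$xyz, maps, ring_atoms)
      if (rr < best_ring) best_ring <- rr
    }
  }
  list(rmsd = best,
       ring_rmsd = if (length(ring_atoms)) best_ring else NA_real_,
       best_conformer = best_k)
}

# all permutations of 1..n (exhaustive-oracle helper; keep n small)
permn_all <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permn_all(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

#' Success fractions and RMSD95
#'
#' Fraction of values at or below each threshold, plus the 95th percentile
#' (linear interpolation, type 7).
#'
#' @param rmsds numeric vector of per-molecule best RMSDs
#' @param thresholds Angstrom thresholds
#' @return list with `success` (named fractions) and `rmsd95`
#' @export
success_curve <- function(rmsds, thresholds = c(0.5, 1.0, 1.5, 2.0)) {
  stopifnot(length(rmsds) >= 1)
  succ <- vapply(thresholds, function(t) mean(rmsds <= t), numeric(1))
  list(success = setNames(succ, sprintf("%.2f", thresholds)),
       rmsd95 = as.numeric(quantile(rmsds, 0.95, type = 7)))
}

#' Two-sample Kolmogorov-Smirnov critical difference
#'
#' The maximal cumulative-distribution difference needed for significance at
#' level `alpha` with samples of size `n` and `m`, using the asymptotic form
#' `c(alpha) * sqrt((n + m) / (n * m))` with
#' `c(alpha) = sqrt(-log(alpha / 2) / 2)`.
#'
#' @param n,m sample sizes
#' @param alpha significance level
#' @return critical difference in cumulative probability
#' @export
ks_critical_difference <- function(n, m, alpha = 0.05) {
  stopifnot(n >= 1, m >= 1, alpha > 0, alpha < 1)
  sqrt(-log(alpha / 2) / 2) * sqrt((n + m) / (n * m))
}

#' Paired t-test on performance pairs
#'
#' Standard two-sided paired t-test; with zero variance of the differences
#' the degenerate limit is returned with a warning (p = 1 for identical
#' columns, p -> 0 for a constant nonzero difference).
#'
#' @param a,b paired numeric vectors
#' @return list with `t`, `p`, `mean_difference`, `n`
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (isTRUE(all.equal(var(d), 0)) || var(d) == 0) {
    if (all(d == 0)) {
      warning("zero variance and zero mean difference; p = 1")
      return(list(t = 0, p = 1, mean_difference = 0, n = length(d)))
    }
    warning("zero variance with nonzero difference; degenerate p -> 0")
    return(list(t = sign(mean(d)) * Inf, p = 0,
                mean_difference = mean(d), n = length(d)))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_difference = unname(tt$estimate), n = length(d))
}
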