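# Search orchestration: memory-free starts, iterative ring search over all
# movements, hydrogen-bond-network exploration, exocyclic torsional
# elaboration and energy-windowed capped ensemble assembly.

#' Search configuration
#'
#' Seven user-selectable accuracy/speed modes. Caps follow the mode
#' definitions (50 for the fast/screen family, with `pscreen` switching to
#' 120 above the flexibility threshold; 250 for the geometric modes; 1000
#' for the thorough modes). Deeper modes enable sub-cycle flips and, on
#' macrocycles, hydrogen-bond network exploration.
#'
#' @param mode one of `pfastf`, `pscreen`, `pfast`, `pgeomf`, `pgeom`,
#'   `pquantf`, `pquant`
#' @param ... overrides for any config field (e.g. `max_conformers`,
#'   `max_rounds`, `twist_angles`, `redundancy_ring`, `redundancy_heavy`,
#'   `search_window`, `final_window_macro`, `hbond_exploration`, `use_flips`,
#'   `threads`, `seed`, `minimize_maxit`)
#' @return a `search_config` list
#' @export
search_config <- function(mode = c("pgeom", "pfastf", "pscreen", "pfast",
                                   "pgeomf", "pquantf", "pquant"), ...) {
  mode <- match.arg(mode)
  base <- list(
    mode = mode,
    max_conformers = switch(mode, pfastf = 50, pscreen = 50, pfast = 50,
                            pgeomf = 250, pgeom = 250, pquantf = 1000,
                            pquant = 1000),
    pscreen_flex_threshold = 8,      # rotatable bonds above which cap is 120
    search_window = 10,              # kcal/mol during search
    final_window_macro = 20,         # kcal/mol, final window for macrocycles
    max_rounds = switch(mode, pfastf = 2, pscreen = 2, pfast = 3,
                        pgeomf = 4, pgeom = 8, pquantf = 8, pquant = 12),
    twist_angles = if (mode %in% c("pfastf", "pscreen", "pfast"))
      c(-60, 60, 180) else c(-120, -60, 60, 120, 180),
    redundancy_ring = 0.3,           # Angstrom, ring-atom RMSD duplicate gate
    redundancy_heavy = 0.5,          # Angstrom, heavy-atom RMSD at assembly
    use_flips = mode %in% c("pgeom", "pquantf", "pquant"),
    hbond_exploration = mode %in% c("pgeom", "pquant"),
    hbond_keep = 8,
    minimize_maxit = 1200,
    energy_match_tol = 0.25,         # kcal/mol band for redundancy compares
    threads = 1,
    seed = 1)
  over <- list(...)
  base[names(over)] <- over
  structure(base, class = "search_config")
}

effective_cap <- function(config, mol) {
  cap <- config$max_conformers
  if (config$mode == "pscreen" &&
      total_flexibility(mol) > config$pscreen_flex_threshold) cap <- 120
  cap
}

#' Memory-free starting conformer
#'
#' Generates a 3D structure from topology and recorded stereochemistry only:
#' input coordinates are never read. Chirality is verified against the
#' records; on mismatch the embedding is retried with a perturbed seed, and
#' a persistent failure is surfaced as an error.
#'
#' @param mol a [mol_graph()]
#' @param seed integer seed
#' @param restraints restraints active during generation (NMR constraints)
#' @param max_retries retry budget for chirality-failed embeddings
#' @param n_valid number of valid embeddings to compare; the lowest-energy
#'   one becomes the start
#' @return a `conformer`
#' @export
memory_free_start <- function(mol, seed = 1,
                              restraints = empty_restraints(),
                              max_retries = 60, n_valid = 10) {
  mol <- with_ff_cache(mol)
  chir <- chirality_impropers(mol$stereo)
  chir_strong <- chirality_impropers(mol$stereo, k = 400, margin = 0.45)
  best <- NULL
  n_ok <- 0L
  for (att in seq_len(max_retries)) {
    x0 <- embed_coordinates(mol, seed = seed + 7919 * (att - 1))
    # relax into a good fold first, then repair any inverted centers locally
    # and re-minimize under enforcement
    m <- relax_embedding(mol, x0, restraints = restraints, enforce = FALSE)
    if (!is.finite(m$total)) next
    if (length(mol$stereo) && !check_chirality(mol, m$xyz)$pass) {
      xr <- repair_chirality(mol, m$xyz)
      m <- ff_minimize_cpp(xr, get_terms(mol),
                           merge_restraints(restraints, chir_strong),
                           tol = 1e-4, maxit = 2000)
      if (!is.finite(m$total)) next
    }
    if (!check_chirality(mol, m$xyz)$pass) next
    # reject folds where the impropers hold the configuration under tension
    # against the force field (residual enforcement energy)
    chir_resid <- ff_eval(m$xyz, get_terms(mol), chir)$violation
    if (chir_resid > 0.5) next
    n_ok <- n_ok + 1L
    if (is.null(best) || m$total < best$total) best <- m
    # a reasonable starting conformer: lowest energy over a few valid
    # embeddings, discarding pathological high-energy folds
    if (n_ok >= n_valid) break
  }
  if (!is.null(best))
    return(conformer(best$xyz, best$energy, best$violation,
                     "memory_free_start"))
  stop("memory-free start failed: chirality could not be reproduced after ",
       max_retries, " attempts")
}

# redundancy: is candidate a duplicate of any pool member (ring-atom RMSD
# under automorphisms, restricted to an energy band)?
is_duplicate <- function(cand, pool, maps, subset, thr, etol) {
  for (p in pool) {
    if (abs(p$energy - cand$energy) > etol) next
    if (min_map_rmsd_cpp(cand$xyz, p$xyz, maps, subset) < thr) return(TRUE)
  }
  FALSE
}

#' Iterative ring conformational search
#'
#' Fixed-point iteration: every conformer in the growing pool is expanded
#' once by all eligible bends, twists, and (in deeper modes) flips and
#' bridge flips; candidates failing chirality, the energy window, or the
#' ring-RMSD redundancy gate are dropped. Restraints stay active in every
#' minimization. Terminates when no new ring conformers appear, the round cap
#' is reached, or the pool hits the mode cap.
#'
#' @param mol a [mol_graph()]
#' @param start starting `conformer`
#' @param config a [search_config()]
#' @param restraints restraint set active throughout
#' @return list of ring conformers, energies ascending
#' @export
ring_search <- function(mol, start, config = search_config("pgeom"),
                        restraints = empty_restraints()) {
  mol <- with_ff_cache(mol)
  # recorded configurations are enforced (not merely checked) in every
  # minimization; the improper terms are inactive once the margin is met
  restraints <- merge_restraints(restraints, chirality_impropers(mol$stereo))
  rsys <- perceive_ring_systems(mol)
  macros <- perceive_macrocycles(mol)
  bends <- list()
  for (s in rsys) bends <- c(bends, enumerate_bends(mol, s))
  twists <- list()
  for (m in macros) twists <- c(twists, enumerate_twists(mol, m))
  maps <- matrix(seq_len(n_atoms(mol)), 1)  # redundancy is label-fixed
  ring_atoms <- sort(unique(unlist(c(lapply(rsys, function(s) s$atoms),
                                     lapply(macros, function(m) m$atoms)))))
  if (!length(ring_atoms)) ring_atoms <- heavy_atoms(mol)
  is_macro_mol <- length(macros) > 0
  window <- if (is_macro_mol) config$final_window_macro else
    config$search_window
  cap <- effective_cap(config, mol)

  s0 <- minimize_conformer(mol, start$xyz, restraints,
                           maxit = config$minimize_maxit)
  first <- conformer(s0$xyz, s0$energy, s0$violation, start$provenance)
  first$expanded <- FALSE
  pool <- list(first)
  emin <- s0$energy
  rounds <- 0L
  consider <- function(cand) {
    if (is.null(cand) || !is.finite(cand$energy)) return(FALSE)
    if (cand$energy > emin + window) return(FALSE)
    if (!check_chirality(mol, cand$xyz)$pass) return(FALSE)
    if (is_duplicate(cand, pool, maps, ring_atoms,
                     config$redundancy_ring, config$energy_match_tol))
      return(FALSE)
    cand$expanded <- FALSE
    pool[[length(pool) + 1]] <<- cand
    if (cand$energy < emin) {
      emin <<- cand$energy
      keep <- vapply(pool, function(p) p$energy <= emin + window, logical(1))
      pool <<- pool[keep]
    }
    TRUE
  }
  # fixed-point iteration: every pool member is expanded exactly once; a
  # round is one pass over the currently unexpanded members
  repeat {
    todo <- which(!vapply(pool, function(p) p$expanded, logical(1)))
    if (!length(todo) || rounds >= config$max_rounds ||
        length(pool) >= cap) break
    rounds <- rounds + 1L
    for (fi in todo) {
      if (fi > length(pool)) break   # pool shrank past this round's slice
      cf <- pool[[fi]]
      if (cf$expanded) next
      pool[[fi]]$expanded <- TRUE
      for (bd in bends) {
        if (length(pool) >= cap) break
        consider(apply_bend(mol, cf, bd, restraints,
                            maxit = config$minimize_maxit))
      }
      for (tw in twists) {
        if (length(pool) >= cap) break
        for (cand in apply_twist(mol, cf, tw, angles = config$twist_angles,
                                 restraints = restraints,
                                 maxit = config$minimize_maxit)) {
          if (length(pool) >= cap) break
          consider(cand)
        }
      }
      if (config$use_flips && is_macro_mol) {
        for (m in macros) {
          for (fl in enumerate_flips(mol, cf, m)) {
            if (length(pool) >= cap) break
            consider(apply_flip(mol, cf, fl, restraints,
                                maxit = config$minimize_maxit))
          }
          for (br in m$bridges) {
            if (length(pool) >= cap) break
            consider(apply_bridge_flip(mol, cf, m, br, restraints,
                                       maxit = config$minimize_maxit))
          }
        }
      }
    }
  }
  pool <- lapply(pool, function(p) { p$expanded <- NULL; p })
  pool[order(vapply(pool, function(p) p$energy, numeric(1)))]
}

#' Hydrogen-bond network exploration
#'
#' Enumerates topologically compatible trans-annular hydrogen-bond triplets,
#' builds constrained starting structures (plus the agnostic one), runs the
#' ring search from each (triplet wells active for constrained starts), and
#' merges the pools by energy.
#'
#' @inheritParams ring_search
#' @return list of ring conformers, energies ascending
#' @export
hbond_network_search <- function(mol, start, config = search_config("pgeom"),
                                 restraints = empty_restraints()) {
  mol <- with_ff_cache(mol)
  macros <- perceive_macrocycles(mol)
  triplets <- list()
  for (m in macros) {
    pairs <- enumerate_hbond_pairs(mol, m)
    triplets <- c(triplets, enumerate_hbond_triplets(pairs, m))
  }
  if (!length(triplets))
    return(ring_search(mol, start, config, restraints))
  starts <- build_constrained_starts(mol, triplets, start,
                                     keep = config$hbond_keep,
                                     seed = config$seed)
  merged <- list()
  for (st in starts) {
    rs <- merge_restraints(restraints, st$restraints)
    branch <- ring_search(mol, st$conf, config, rs)
    merged <- c(merged, branch)
  }
  # retain best ring alternatives by energy under the shared redundancy gate
  maps <- matrix(seq_len(n_atoms(mol)), 1)
  ring_atoms <- sort(unique(unlist(lapply(macros, function(m) m$atoms))))
  merged <- merged[order(vapply(merged, function(p) p$energy, numeric(1)))]
  out <- list()
  emin <- if (length(merged)) merged[[1]]$energy else 0
  cap <- effective_cap(config, mol)
  for (cand in merged) {
    if (length(out) >= cap) break
    if (cand$energy > emin + config$final_window_macro) break
    if (!is_duplicate(cand, out, maps, ring_atoms, config$redundancy_ring,
                      config$energy_match_tol))
      out[[length(out) + 1]] <- cand
  }
  out
}

# exocyclic rotatable torsions as 4-atom windows
exocyclic_torsions <- function(mol) {
  b <- mol$bonds
  el <- mol$atoms$element
  rs <- mol$rings$bond_ring_size
  amide <- amide_bond_ids(mol)
  hdeg <- integer(n_atoms(mol))
  for (e in seq_len(nrow(b))) {
    if (el[b$i[e]] != "H" && el[b$j[e]] != "H") {
      hdeg[b$i[e]] <- hdeg[b$i[e]] + 1L
      hdeg[b$j[e]] <- hdeg[b$j[e]] + 1L
    }
  }
  planar <- atom_planar(mol)
  out <- list()
  for (e in which(rs == 0 & b$order == 1)) {
    j <- b$i[e]; k <- b$j[e]
    if (el[j] == "H" || el[k] == "H") next
    if (hdeg[j] < 2 || hdeg[k] < 2) next
    if (e %in% amide) next
    ni <- setdiff(neighbors_of(mol, j), k); ni <- ni[el[ni] != "H"]
    nl <- setdiff(neighbors_of(mol, k), j); nl <- nl[el[nl] != "H"]
    if (!length(ni)) ni <- setdiff(neighbors_of(mol, j), k)
    if (!length(nl)) nl <- setdiff(neighbors_of(mol, k), j)
    if (!length(ni) || !length(nl)) next
    vals <- if (planar[j] || planar[k]) c(0, 180) else c(-60, 60, 180)
    out[[length(out) + 1]] <- list(window = c(min(ni), j, k, min(nl)),
                                   bond = c(j, k), values = vals)
  }
  out
}

# rotate the side of bond (j,k) containing k to set torsion to value
set_torsion <- function(mol, xyz, window, value_deg) {
  j <- window[2]; k <- window[3]
  cur <- torsion_angle_cpp(xyz, window[1], j, k, window[4]) * 180 / pi
  delta <- (value_deg - cur) * pi / 180
  side <- pendants_of(mol, k, j)   # everything reachable from k avoiding j
  side <- setdiff(side, k)
  mv <- c(side)
  if (!length(mv)) return(xyz)
  xyz[mv, ] <- rotate_about_axis_cpp(xyz[mv, , drop = FALSE], xyz[j, ],
                                     xyz[k, ] - xyz[j, ], delta)
  xyz
}

#' Exocyclic torsional elaboration
#'
#' Greedy systematic sampling: for each exocyclic rotatable torsion,
#' staggered (sp3) or planar (conjugated) target values are applied to every
#' current conformer, minimized, deduplicated by heavy-atom RMSD and
#' windowed. With no exocyclic rotatables the input is returned unchanged.
#'
#' @param mol a [mol_graph()]
#' @param ring_conformers list of conformers from the ring phase
#' @param config a [search_config()]
#' @param restraints restraints active in minimization
#' @return list of conformers
#' @export
exocyclic_elaboration <- function(mol, ring_conformers,
                                  config = search_config("pgeom"),
                                  restraints = empty_restraints()) {
  tors <- exocyclic_torsions(mol)
  if (!length(tors) || !length(ring_conformers)) return(ring_conformers)
  mol <- with_ff_cache(mol)
  restraints <- merge_restraints(restraints, chirality_impropers(mol$stereo))
  maps <- matrix(seq_len(n_atoms(mol)), 1)
  hv <- heavy_atoms(mol)
  cap <- effective_cap(config, mol)
  pool <- ring_conformers
  emin <- min(vapply(pool, function(p) p$energy, numeric(1)))
  macros <- perceive_macrocycles(mol)
  window <- if (length(macros)) config$final_window_macro else
    config$search_window
  for (tq in tors) {
    adds <- list()
    for (cf in pool) {
      if (length(pool) + length(adds) >= cap) break
      for (v in tq$values) {
        xyz2 <- set_torsion(mol, cf$xyz, tq$window, v)
        m <- minimize_conformer(mol, xyz2, restraints,
                                maxit = config$minimize_maxit)
        if (!is.finite(m$energy)) next
        cand <- conformer(m$xyz, m$energy, m$violation,
                          c(cf$provenance,
                            sprintf("exo[%d-%d;%d]", tq$bond[1], tq$bond[2],
                                    v)))
        if (cand$energy > emin + window) next
        if (!check_chirality(mol, cand$xyz)$pass) next
        if (!is_duplicate(cand, c(pool, adds), maps, hv,
                          config$redundancy_heavy, config$energy_match_tol))
          adds[[length(adds) + 1]] <- cand
        if (length(pool) + length(adds) >= cap) break
      }
    }
    pool <- c(pool, adds)
    emin <- min(emin, vapply(pool, function(p) p$energy, numeric(1)))
  }
  pool[order(vapply(pool, function(p) p$energy, numeric(1)))]
}

#' Assemble the final conformer ensemble
#'
#' Sorts by energy, applies the final window (20 kcal/mol for macrocycles,
#' 10 otherwise), prunes redundant conformers greedily by automorphism-
#' corrected heavy-atom RMSD (preferring distinct conformations over minor
#' variants), and truncates to the mode cap. The lowest-energy conformer is
#' always retained.
#'
#' @param mol a [mol_graph()]
#' @param conformers list of conformers
#' @param config a [search_config()]
#' @return a `conformer_ensemble`
#' @export
assemble_ensemble <- function(mol, conformers, config = search_config("pgeom")) {
  stopifnot(length(conformers) >= 1)
  macros <- perceive_macrocycles(mol)
  window <- if (length(macros)) config$final_window_macro else
    config$search_window
  ord <- order(vapply(conformers, function(p) p$energy, numeric(1)))
  conformers <- conformers[ord]
  emin <- conformers[[1]]$energy
  maps <- matrix(seq_len(n_atoms(mol)), 1)
  hv <- heavy_atoms(mol)
  cap <- effective_cap(config, mol)
  out <- list()
  for (cand in conformers) {
    if (length(out) >= cap) break
    if (cand$energy > emin + window) break
    if (!is_duplicate(cand, out, maps, hv, config$redundancy_heavy,
                      config$energy_match_tol))
      out[[length(out) + 1]] <- cand
  }
  energies <- vapply(out, function(p) p$energy, numeric(1))
  structure(list(conformers = out, energies = energies,
                 rel_energies = energies - emin, global_min = emin,
                 metadata = list(mode = config$mode, n = length(out),
                                 macrocyclic = length(macros) > 0)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d conformers (%s), E = %.2f .. %.2f kcal/mol\n",
              length(x$conformers), x$metadata$mode, x$global_min,
              max(x$energies)))
  invisible(x)
}

#' Generate a conformer ensemble (full pipeline)
#'
#' Memory-free start, ring search (with hydrogen-bond network exploration on
#' macrocycles in the deeper modes), exocyclic torsional elaboration, and
#' energy-windowed capped ensemble assembly. NMR constraints, when given,
#' are active from initial structure generation through the entire search.
#'
#' @param mol a [mol_graph()]
#' @param config a [search_config()]
#' @param constraints optional constraint set from [parse_constraint_file()]
#'   or [make_synthetic_constraints()]
#' @return a `conformer_ensemble`
#' @export
generate_conformers <- function(mol, config = search_config("pgeom"),
                                constraints = NULL) {
  mol <- with_ff_cache(mol)
  restraints <- if (is.null(constraints)) empty_restraints() else
    constraints_to_restraints(constraints)
  start <- memory_free_start(mol, seed = config$seed, restraints = restraints)
  macros <- perceive_macrocycles(mol)
  ring_pool <- if (config$hbond_exploration && length(macros))
    hbond_network_search(mol, start, config, restraints)
  else
    ring_search(mol, start, config, restraints)
  full <- exocyclic_elaboration(mol, ring_pool, config, restraints)
  assemble_ensemble(mol, full, config)
}
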