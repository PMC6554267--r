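# Force-field adapter: a compact valence force field (harmonic bonds and
# angles, cosine torsions, out-of-plane terms for trigonal centers, 12-6
# Lennard-Jones plus screened Coulomb from electronegativity-increment
# charges), square-well restraints and FIRE minimization. All energies in
# kcal/mol.

#' Build force-field terms for a molecule
#'
#' Assigns parameters from element, bond order and hybridization. The result
#' is cached on the molecule by [energy()] and [minimize_conformer()].
#'
#' @param mol a [mol_graph()]
#' @return an opaque term list consumed by the minimizer
#' @export
ff_terms <- function(mol) {
  el <- mol$atoms$element
  bad <- setdiff(unique(el), FF_ELEMENTS)
  if (length(bad))
    stop(structure(class = c("ringconf_parameterization_error",
                             "error", "condition"),
                   list(message = sprintf(
                     "atoms not parameterizable: %s",
                     paste(bad, collapse = ", ")), call = NULL)))
  ed <- ELEMENT_DATA[match(el, ELEMENT_DATA$element), ]
  n <- n_atoms(mol)
  b <- mol$bonds
  planar <- atom_planar(mol)
  nbrs <- lapply(seq_len(n), function(a) neighbors_of(mol, a))
  # hybridization-ish: sp if triple bond or 2 double bonds; sp2 if planar
  ndouble <- integer(n); ntriple <- integer(n)
  for (e in seq_len(nrow(b))) {
    if (b$order[e] == 2) {
      ndouble[b$i[e]] <- ndouble[b$i[e]] + 1L
      ndouble[b$j[e]] <- ndouble[b$j[e]] + 1L
    } else if (b$order[e] == 3) {
      ntriple[b$i[e]] <- ntriple[b$i[e]] + 1L
      ntriple[b$j[e]] <- ntriple[b$j[e]] + 1L
    }
  }
  hyb <- ifelse(ntriple > 0 | ndouble >= 2, 1L, ifelse(planar, 2L, 3L))

  # bonds
  r0 <- ed$rcov[b$i] + ed$rcov[b$j]
  r0[b$order == 2] <- r0[b$order == 2] * 0.87
  r0[b$order == 3] <- r0[b$order == 3] * 0.78
  kb <- c(350, 550, 750)[b$order]
  bonds <- cbind(b$i, b$j, r0, kb)

  # angles: one per bonded path i-j-k
  ang <- list()
  ring_small <- function(i, j) {
    e <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))
    if (!length(e)) return(0L)
    mol$rings$bond_ring_size[e[1]]
  }
  for (j in seq_len(n)) {
    nb <- nbrs[[j]]
    if (length(nb) < 2) next
    for (p in seq_len(length(nb) - 1)) for (q in seq((p + 1), length(nb))) {
      i <- nb[p]; k <- nb[q]
      th0 <- switch(hyb[j], 180, 120, 109.471) * pi / 180
      # strained small rings: ideal interior angle when i-j-k lie in one
      s1 <- ring_small(i, j); s2 <- ring_small(j, k)
      if (s1 > 0 && s1 == s2 && s1 <= 5) th0 <- (s1 - 2) * pi / s1
      kth <- if (el[i] == "H" || el[k] == "H") 35 else 60
      ang[[length(ang) + 1]] <- c(i, j, k, th0, kth)
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else NULL

  # torsions: one term per (i, j, k, l) path; parameters by central bond
  amide <- amide_bond_ids(mol)
  tor <- list()
  for (e in seq_len(nrow(b))) {
    j <- b$i[e]; k <- b$j[e]
    ni <- setdiff(nbrs[[j]], k); nl <- setdiff(nbrs[[k]], j)
    if (!length(ni) || !length(nl)) next
    if (b$order[e] >= 3) next
    if (e %in% amide) { V <- 14; nn <- 2; p0 <- pi }
    else if (b$order[e] == 2) { V <- 30; nn <- 2; p0 <- pi }
    else if (hyb[j] == 2 && hyb[k] == 2) { V <- 4; nn <- 2; p0 <- pi }
    else { V <- 2.9; nn <- 3; p0 <- 0 }   # ethane-like threefold barrier
    npair <- length(ni) * length(nl)
    for (i in ni) for (l in nl)
      tor[[length(tor) + 1]] <- c(i, j, k, l, V / npair, nn, p0)
  }
  torsions <- if (length(tor)) do.call(rbind, tor) else NULL

  # out-of-plane for trigonal sp2 centers
  oop <- list()
  for (a in which(hyb == 2)) {
    nb <- nbrs[[a]]
    if (length(nb) == 3)
      oop[[length(oop) + 1]] <- c(a, nb[1], nb[2], nb[3], 40)
  }
  oops <- if (length(oop)) do.call(rbind, oop) else NULL

  # charges: electronegativity increments over bonds
  q <- numeric(n)
  for (e in seq_len(nrow(b))) {
    dq <- 0.28 * (ed$en[b$i[e]] - ed$en[b$j[e]])   # more EN end goes negative
    q[b$i[e]] <- q[b$i[e]] - dq
    q[b$j[e]] <- q[b$j[e]] + dq
  }
  q <- q + mol$atoms$charge * 0.5

  # nonbonded pairs: exclude 1-2, 1-3; scale 1-4 by 0.5
  g <- mol_igraph(mol)
  d <- igraph::distances(g)
  pr <- which(upper.tri(d) & d >= 3, arr.ind = TRUE)
  if (nrow(pr)) {
    sc <- ifelse(d[pr] == 3, 0.5, 1.0)
    eps <- sqrt(ed$eps[pr[, 1]] * ed$eps[pr[, 2]]) * sc
    rmin <- ed$rvdw[pr[, 1]] + ed$rvdw[pr[, 2]]
    qq <- 332.0636 * q[pr[, 1]] * q[pr[, 2]] * sc
    nbm <- cbind(pr[, 1], pr[, 2], eps, rmin, qq)
  } else nbm <- NULL

  list(bonds = bonds, angles = angles, torsions = torsions, oops = oops,
       nb = nbm)
}

get_terms <- function(mol) {
  if (is.null(attr(mol, "ff_terms_cache"))) ff_terms(mol) else
    attr(mol, "ff_terms_cache")
}

#' Attach cached force-field terms to a molecule
#'
#' Avoids re-deriving parameters inside tight search loops.
#' @param mol a [mol_graph()]
#' @return the molecule with terms cached in an attribute
#' @export
with_ff_cache <- function(mol) {
  attr(mol, "ff_terms_cache") <- ff_terms(mol)
  mol
}

empty_restraints <- function() {
  list(pins = NULL, dwells = list(), twells = NULL, chir = NULL)
}

merge_restraints <- function(a, b) {
  list(pins = rbind(a$pins, b$pins),
       dwells = c(a$dwells, b$dwells),
       twells = rbind(a$twells, b$twells),
       chir = rbind(a$chir, b$chir))
}

#' Positional pin restraints
#' @param idx atom indices to pin
#' @param xyz target coordinates (full molecule matrix)
#' @param k force constant, kcal/mol/A^2
#' @export
pin_restraints <- function(idx, xyz, k = 100) {
  r <- empty_restraints()
  if (length(idx))
    r$pins <- cbind(idx, xyz[idx, 1], xyz[idx, 2], xyz[idx, 3], k)
  r
}

#' Square-well distance restraint between two point sets
#'
#' Distances are measured between the centroids of sets `a` and `b`. Zero
#' inside `dist +/- wiggle`, quadratic outside.
#' @param a,b atom index vectors
#' @param dist target distance, Angstrom
#' @param wiggle half-width of the flat well, Angstrom
#' @param penalty force constant, kcal/mol/A^2
#' @export
distance_well <- function(a, b, dist, wiggle = 0.5, penalty = 10) {
  stopifnot(wiggle >= 0, penalty >= 0, length(a) >= 1, length(b) >= 1)
  r <- empty_restraints()
  r$dwells <- list(list(a = as.integer(a), b = as.integer(b),
                        dist = dist, wiggle = wiggle, penalty = penalty))
  r
}

#' Square-well torsion restraint
#' @param atoms 4 atom indices
#' @param lo,hi well bounds in degrees, in (-180, 180]
#' @param penalty force constant, kcal/mol/deg^2
#' @export
torsion_well <- function(atoms, lo, hi, penalty = 0.05) {
  stopifnot(length(atoms) == 4, penalty >= 0, lo <= hi)
  r <- empty_restraints()
  r$twells <- matrix(c(atoms, lo, hi, penalty), 1)
  r
}

#' Chirality-enforcing improper restraints from stereo records
#' @param stereo list from [record_stereo()]
#' @param k force constant
#' @param margin normalized-volume margin below which the penalty engages
#' @export
chirality_impropers <- function(stereo, k = 200, margin = 0.25) {
  r <- empty_restraints()
  tet <- Filter(function(s) s$kind == "tetrahedral", stereo)
  if (length(tet))
    r$chir <- do.call(rbind, lapply(tet, function(s)
      c(s$atoms, s$config, k, margin)))
  dbl <- Filter(function(s) s$kind == "double_bond", stereo)
  for (s in dbl) {
    if (s$config == "E") r <- merge_restraints(r, torsion_well(s$atoms, 150, 180, 0.05))
    else r <- merge_restraints(r, torsion_well(s$atoms, -30, 30, 0.05))
  }
  r
}

#' Square-well distance penalty (closed form)
#'
#' `penalty * max(0, |d - dist| - wiggle)^2`; continuous and once
#' differentiable everywhere, flat inside the well.
#' @param d observed distance, Angstrom
#' @param dist well center; `wiggle` free half-width; `penalty` kcal/mol/A^2
#' @param wiggle,penalty see above
#' @export
square_well_distance_penalty <- function(d, dist, wiggle, penalty) {
  exc <- pmax(0, abs(d - dist) - wiggle)
  penalty * exc^2
}

#' Square-well torsion penalty (closed form)
#'
#' Zero inside `[lo, hi]`; outside, `penalty` times the squared periodic
#' angular distance (degrees) to the nearest bound.
#' @param angle observed torsion, degrees in (-180, 180]
#' @param lo,hi bounds in degrees
#' @param penalty kcal/mol/deg^2
#' @export
square_well_torsion_penalty <- function(angle, lo, hi, penalty) {
  vapply(angle, function(a) {
    devs <- vapply(c(-1, 0, 1), function(w) {
      p <- a + 360 * w
      if (p >= lo && p <= hi) 0 else min(abs(p - lo), abs(p - hi))
    }, numeric(1))
    penalty * min(devs)^2
  }, numeric(1))
}

#' Force-field energy of a coordinate set
#'
#' Restraint terms are excluded; see [minimize_conformer()] for the combined
#' objective.
#' @param mol a [mol_graph()]
#' @param xyz N x 3 coordinates; defaults to the molecule's own
#' @return energy in kcal/mol
#' @export
energy <- function(mol, xyz = mol$xyz) {
  stopifnot(!is.null(xyz))
  ff_eval(xyz, get_terms(mol), empty_restraints())$ff
}

#' Restrained minimization
#'
#' Minimizes force-field energy plus restraint energy (pins, square wells,
#' chirality impropers) with a FIRE descent, deterministic for fixed input.
#'
#' @param mol a [mol_graph()]
#' @param xyz starting coordinates
#' @param restraints restraint set (see [pin_restraints()] and friends)
#' @param tol gradient RMS tolerance, kcal/mol/A
#' @param maxit iteration cap
#' @return list with `xyz`, `energy` (force field), `violation` (restraint),
#'   `total`, `converged`, `iterations`, `grad_norm`
#' @export
minimize_conformer <- function(mol, xyz = mol$xyz,
                               restraints = empty_restraints(),
                               tol = 1e-4, maxit = 2000) {
  stopifnot(!is.null(xyz))
  ff_minimize_cpp(xyz, get_terms(mol), restraints, tol = tol, maxit = maxit)
}

#' Verify recorded stereochemistry against coordinates
#'
#' Re-perceives tetrahedral configurations (signed volume) and double-bond
#' configurations (torsion) and compares with the records.
#'
#' @param mol a [mol_graph()]
#' @param xyz coordinates to check
#' @param stereo records; defaults to the molecule's own
#' @return list with `pass` (logical) and `violations` (list of failed records)
#' @export
check_chirality <- function(mol, xyz, stereo = mol$stereo) {
  viol <- list()
  for (s in stereo) {
    if (s$kind == "tetrahedral") {
      v <- chir_volume_cpp(xyz, s$atoms[1], s$atoms[2], s$atoms[3], s$atoms[4])
      if (sign(v) != s$config) viol[[length(viol) + 1]] <- s
    } else if (s$kind == "double_bond") {
      phi <- torsion_angle_cpp(xyz, s$atoms[1], s$atoms[2], s$atoms[3],
                               s$atoms[4])
      lab <- if (abs(phi) > pi / 2) "E" else "Z"
      if (lab != s$config) viol[[length(viol) + 1]] <- s
    }
  }
  list(pass = length(viol) == 0, violations = viol)
}
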