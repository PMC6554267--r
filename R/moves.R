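# Physical ring movements: bends (negate a cross-ring torsion about a
# non-bonded atom-pair axis), twists (force one macrocycle atom around a ring
# bond), flips (180-degree rotation of a macrocycle arc about the axis
# between two near-colinear bonds), bridge flips, and topological
# trans-annular hydrogen-bond pair/triplet enumeration.

#' Construct a conformer
#'
#' One coordinate set with its force-field energy, restraint-violation
#' energy, and the labels of the moves that produced it.
#'
#' @param xyz N x 3 coordinate matrix, Angstrom
#' @param energy force-field energy, kcal/mol
#' @param violation restraint-violation energy, kcal/mol
#' @param provenance character vector of move labels
#' @return object of class `conformer`
#' @export
conformer <- function(xyz, energy = NA_real_, violation = 0,
                      provenance = character(0)) {
  structure(list(xyz = xyz, energy = energy, violation_energy = violation,
                 provenance = provenance), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d atoms, E = %.3f kcal/mol (violation %.3f)\n",
              nrow(x$xyz), x$energy, x$violation_energy))
  invisible(x)
}

# pendant substituent trees hanging off `side` atoms of a ring system,
# excluding paths through other system atoms
pendants_of <- function(mol, side, system_atoms) {
  block <- setdiff(system_atoms, side)
  seen <- side
  queue <- side
  out <- integer(0)
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (nb in neighbors_of(mol, a)) {
      if (nb %in% seen || nb %in% block) next
      seen <- c(seen, nb); out <- c(out, nb); queue <- c(queue, nb)
    }
  }
  out
}

#' Enumerate ring bends for a small-ring system
#'
#' A pair of system atoms is a bend axis when (1) the atoms are not directly
#' bonded, (2) at least one is part of a non-planar ring, and (3) the axis
#' does not cross a ring fusion or bridgehead: removing the pair must split
#' the system into exactly two sides (pairs spanning a fusion leave it
#' connected and are excluded; a fusion-atom pair itself gives the butterfly
#' bend). The smaller side is the moving right-hand side.
#'
#' @param mol a [mol_graph()]
#' @param system a `ring_system` from [perceive_ring_systems()]
#' @return list of bend descriptors (`axis`, `lhs`, `rhs`)
#' @export
enumerate_bends <- function(mol, system) {
  atoms <- system$atoms
  if (length(atoms) < 4) return(list())
  # atom is part of a non-planar ring if any incident ring bond's smallest
  # ring contains a non-planar atom
  planar <- atom_planar(mol)
  ring_atoms_by_bond <- mol$rings$bond_ring_atoms[system$bonds]
  in_nonplanar_ring <- setNames(rep(FALSE, length(atoms)), atoms)
  for (ra in ring_atoms_by_bond) {
    if (any(!planar[ra]))
      in_nonplanar_ring[as.character(intersect(ra, atoms))] <- TRUE
  }
  sub <- mol$bonds[system$bonds, , drop = FALSE]
  out <- list()
  cmb <- if (length(atoms) >= 2) utils::combn(sort(atoms), 2) else
    matrix(integer(0), 2, 0)
  for (cix in seq_len(ncol(cmb))) {
    p <- cmb[1, cix]; q <- cmb[2, cix]
    if (bond_order_between(mol, p, q) > 0) next
    if (!in_nonplanar_ring[as.character(p)] &&
        !in_nonplanar_ring[as.character(q)]) next
    # axes crossing a fusion or bridgehead fail to split the system in two
    # (e.g. decalin pairs spanning the fusion); fusion atoms themselves can
    # serve as the axis, giving the butterfly bend of fused bicyclics
    rest <- setdiff(atoms, c(p, q))
    keep <- sub$i %in% rest & sub$j %in% rest
    g <- igraph::make_empty_graph(n = length(rest), directed = FALSE)
    idx <- match(seq_len(n_atoms(mol)), rest)
    g <- igraph::add_edges(g, rbind(idx[sub$i[keep]], idx[sub$j[keep]]))
    cm <- igraph::components(g)
    if (cm$no != 2) next
    s1 <- rest[cm$membership == 1]; s2 <- rest[cm$membership == 2]
    if (length(s2) > length(s1)) { tmp <- s1; s1 <- s2; s2 <- tmp }
    out[[length(out) + 1]] <- list(axis = c(p, q), lhs = s1, rhs = s2,
                                   system_atoms = atoms)
  }
  out
}

#' Apply a ring bend
#'
#' Rotates the right-hand-side atoms and their pendants about the axis so the
#' cross-ring torsion (RHS centroid, axis, LHS centroid) is negated, then
#' relaxes under ring pins and finally freely.
#'
#' @param mol a [mol_graph()]
#' @param conf a conformer (list with `xyz`)
#' @param bend a descriptor from [enumerate_bends()]
#' @param restraints restraints kept active in every minimization
#' @param pin_k pin force constant; `maxit` minimizer cap
#' @param maxit iteration cap per minimization stage
#' @return candidate `conformer`, or `NULL` on minimization failure
#' @export
apply_bend <- function(mol, conf, bend, restraints = empty_restraints(),
                       pin_k = 100, maxit = 1200) {
  xyz <- conf$xyz
  p <- bend$axis[1]; q <- bend$axis[2]
  rhs_all <- c(bend$rhs, pendants_of(mol, bend$rhs, bend$system_atoms))
  cl <- colMeans(xyz[bend$lhs, , drop = FALSE])
  cr <- colMeans(xyz[bend$rhs, , drop = FALSE])
  tau <- torsion_angle_cpp(rbind(cr, xyz[p, ], xyz[q, ], cl), 1, 2, 3, 4)
  axis <- xyz[q, ] - xyz[p, ]
  if (sqrt(sum(axis^2)) < 1e-6 || !is.finite(tau)) return(NULL)
  # rotating the RHS by +2*tau about p->q negates the cross-ring torsion
  xyz[rhs_all, ] <- rotate_about_axis_cpp(xyz[rhs_all, , drop = FALSE],
                                          xyz[p, ], axis, 2 * tau)
  pins <- pin_restraints(bend$system_atoms, xyz, pin_k)
  s1 <- minimize_conformer(mol, xyz, merge_restraints(pins, restraints),
                           tol = 5e-4, maxit = maxit)
  s2 <- minimize_conformer(mol, s1$xyz, restraints, tol = 5e-4, maxit = maxit)
  if (!is.finite(s2$energy)) return(NULL)
  conformer(s2$xyz, s2$energy, s2$violation,
            c(conf$provenance, sprintf("bend[%d-%d]", p, q)))
}

#' Enumerate macrocycle twists
#'
#' One twist per rotatable macrocyclic bond and moving end: the bond's
#' smallest enclosing ring has nine or more atoms, the bond is a single bond,
#' and amide C-N bonds are excluded. The four-atom window follows the main
#' cycle.
#'
#' @param mol a [mol_graph()]
#' @param macro a `macrocycle` from [perceive_macrocycles()]
#' @return list of twist descriptors (`window` = a1,a2,a3,a4; `moving` = 1 or 4)
#' @export
enumerate_twists <- function(mol, macro) {
  cyc <- macro$cycle
  nn <- length(cyc)
  amide <- amide_bond_ids(mol)
  rs <- mol$rings$bond_ring_size
  out <- list()
  for (k in seq_len(nn)) {
    a2 <- cyc[k]; a3 <- cyc[k %% nn + 1]
    e <- which((mol$bonds$i == a2 & mol$bonds$j == a3) |
               (mol$bonds$i == a3 & mol$bonds$j == a2))
    if (!length(e)) next
    e <- e[1]
    if (mol$bonds$order[e] != 1 || rs[e] < 9 || e %in% amide) next
    a1 <- cyc[(k - 2) %% nn + 1]
    a4 <- cyc[(k + 1) %% nn + 1]
    out[[length(out) + 1]] <- list(window = c(a1, a2, a3, a4), moving = 4L)
    out[[length(out) + 1]] <- list(window = c(a1, a2, a3, a4), moving = 1L)
  }
  out
}

#' Apply a macrocycle twist
#'
#' The three non-moving window atoms are pinned; the moving atom is pulled to
#' positions rotated about the central bond by each angle in `angles`
#' (degrees, relative to the current torsion), each followed by pinned then
#' free minimization.
#'
#' @param mol,conf,restraints as in [apply_bend()]
#' @param twist descriptor from [enumerate_twists()]
#' @param angles target rotations in degrees
#' @param pin_k,maxit as in [apply_bend()]
#' @return list of candidate conformers (may be empty)
#' @export
apply_twist <- function(mol, conf, twist, angles = c(-120, -60, 60, 120, 180),
                        restraints = empty_restraints(), pin_k = 100,
                        maxit = 1200) {
  w <- twist$window
  mov <- w[twist$moving]
  fixed <- setdiff(w, mov)
  xyz <- conf$xyz
  axis_from <- xyz[w[2], ]; axis_to <- xyz[w[3], ]
  if (twist$moving == 1L) { axis_from <- xyz[w[3], ]; axis_to <- xyz[w[2], ] }
  out <- list()
  for (ang in angles) {
    tgt <- rotate_about_axis_cpp(matrix(xyz[mov, ], 1), axis_from,
                                 axis_to - axis_from, ang * pi / 180)
    xyz2 <- xyz
    pins <- pin_restraints(fixed, xyz, pin_k)
    tp <- empty_restraints()
    tp$pins <- rbind(pins$pins, c(mov, tgt[1, ], pin_k))
    s1 <- minimize_conformer(mol, xyz2, merge_restraints(tp, restraints),
                             tol = 5e-4, maxit = maxit)
    s2 <- minimize_conformer(mol, s1$xyz, restraints, tol = 5e-4, maxit = maxit)
    if (!is.finite(s2$energy)) next
    out[[length(out) + 1]] <- conformer(
      s2$xyz, s2$energy, s2$violation,
      c(conf$provenance, sprintf("twist[%d-%d;%+d]", w[2], w[3], ang)))
  }
  out
}

#' Enumerate sub-cycle flips
#'
#' Pairs of main-cycle bonds whose midpoints are at least 4.0 Angstrom apart
#' and whose bond vectors and midpoint vector are mutually directionally
#' compatible (`min` pairwise dot product > 0.3, i.e. deviations from
#' co-linearity up to about 70 degrees). Both arcs between the bonds are
#' emitted as independent candidates; arcs crossing a bridge attachment are
#' skipped.
#'
#' @param mol a [mol_graph()]
#' @param conf conformer providing the geometry
#' @param macro a `macrocycle`
#' @param min_dist midpoint distance gate (Angstrom)
#' @param min_dot directional gate (strict)
#' @return list of flip descriptors
#' @export
enumerate_flips <- function(mol, conf, macro, min_dist = 4.0, min_dot = 0.3) {
  cyc <- macro$cycle
  nn <- length(cyc)
  xyz <- conf$xyz
  anchors <- unlist(lapply(macro$bridges, function(p) p[c(1, length(p))]))
  out <- list()
  for (k1 in seq_len(nn - 1)) for (k2 in seq((k1 + 1), nn)) {
    b1 <- c(cyc[k1], cyc[k1 %% nn + 1])
    b2 <- c(cyc[k2], cyc[k2 %% nn + 1])
    if (length(intersect(b1, b2))) next
    m1 <- (xyz[b1[1], ] + xyz[b1[2], ]) / 2
    m2 <- (xyz[b2[1], ] + xyz[b2[2], ]) / 2
    if (!flip_gate(m1, m2, xyz[b1[2], ] - xyz[b1[1], ],
                   xyz[b2[2], ] - xyz[b2[1], ], min_dist, min_dot)) next
    # two arcs between the inner bond ends (exclusive of the bond atoms)
    arc1 <- arc_between(cyc, k1 %% nn + 1, k2)
    arc2 <- arc_between(cyc, k2 %% nn + 1, k1)
    for (arc in list(arc1, arc2)) {
      if (!length(arc)) next
      if (any(arc %in% anchors)) next
      out[[length(out) + 1]] <- list(bond1 = b1, bond2 = b2, arc = arc,
                                     mid1 = m1, mid2 = m2)
    }
  }
  out
}

#' Flip eligibility gate
#'
#' A bond pair qualifies for a sub-cycle flip when the bond midpoints are at
#' least `min_dist` apart and the two bond vectors and the midpoint vector
#' are pairwise directionally compatible: `min` of the three pairwise dot
#' products of the unit vectors strictly greater than `min_dot`. The default
#' 0.3 admits deviations from co-linearity up to about 70 degrees
#' (`acos(0.3)` = 72.5).
#'
#' @param mid1,mid2 bond midpoints
#' @param v1,v2 bond vectors (need not be normalized)
#' @param min_dist midpoint distance gate, Angstrom
#' @param min_dot directional gate (strict inequality)
#' @return logical
#' @export
flip_gate <- function(mid1, mid2, v1, v2, min_dist = 4.0, min_dot = 0.3) {
  d <- sqrt(sum((mid1 - mid2)^2))
  if (d < min_dist) return(FALSE)
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- (mid2 - mid1) / d
  min(sum(v1 * v2), sum(v1 * v3), sum(v2 * v3)) > min_dot
}

# main-cycle atoms strictly between positions i..j walking forward (exclusive
# of the bond end atoms at positions i and j themselves)
arc_between <- function(cyc, i, j) {
  nn <- length(cyc)
  ks <- integer(0)
  k <- i %% nn + 1
  while (k != j) { ks <- c(ks, k); k <- k %% nn + 1 }
  cyc[ks]
}

#' Apply a sub-cycle flip
#'
#' The arc atoms and their pendants are rotated exactly 180 degrees about the
#' axis through the two bond midpoints (an isometry and involution before
#' minimization), then the four bond-end atoms are pinned, minimized, and
#' released for free minimization.
#'
#' @param mol,conf,restraints,pin_k,maxit as in [apply_bend()]
#' @param flip a descriptor from [enumerate_flips()]
#' @param minimize set `FALSE` to return the raw rotated geometry
#' @export
apply_flip <- function(mol, conf, flip, restraints = empty_restraints(),
                       pin_k = 100, maxit = 1200, minimize = TRUE) {
  xyz <- conf$xyz
  macro_atoms <- unique(c(flip$bond1, flip$bond2, flip$arc))
  moving <- c(flip$arc, pendants_of(mol, flip$arc,
                                    setdiff(macro_atoms, flip$arc)))
  axis <- flip$mid2 - flip$mid1
  xyz[moving, ] <- rotate_about_axis_cpp(xyz[moving, , drop = FALSE],
                                         flip$mid1, axis, pi)
  if (!minimize)
    return(conformer(xyz, NA_real_, 0,
                     c(conf$provenance, "flip[raw]")))
  ends <- c(flip$bond1, flip$bond2)
  pins <- pin_restraints(ends, xyz, pin_k)
  s1 <- minimize_conformer(mol, xyz, merge_restraints(pins, restraints),
                           tol = 5e-4, maxit = maxit)
  s2 <- minimize_conformer(mol, s1$xyz, restraints, tol = 5e-4, maxit = maxit)
  if (!is.finite(s2$energy)) return(NULL)
  conformer(s2$xyz, s2$energy, s2$violation,
            c(conf$provenance,
              sprintf("flip[%d-%d|%d-%d]", flip$bond1[1], flip$bond1[2],
                      flip$bond2[1], flip$bond2[2])))
}

#' Apply a bridge flip
#'
#' Mirrors the bridge interior across the local plane through the two
#' attachment atoms and the macrocycle centroid, then minimizes with
#' chirality-enforcing impropers active and finally without them.
#'
#' @param mol,conf,restraints,maxit as in [apply_bend()]
#' @param macro the `macrocycle`
#' @param bridge one element of `macro$bridges`
#' @export
apply_bridge_flip <- function(mol, conf, macro, bridge,
                              restraints = empty_restraints(), maxit = 1200) {
  if (length(bridge) < 3) return(NULL)
  xyz <- conf$xyz
  interior <- bridge[-c(1, length(bridge))]
  moving <- c(interior, pendants_of(mol, interior, macro$atoms))
  p <- xyz[bridge[1], ]; q <- xyz[bridge[length(bridge)], ]
  c0 <- colMeans(xyz[macro$cycle, , drop = FALSE])
  nrm <- vcross(q - p, c0 - p)
  if (sqrt(sum(nrm^2)) < 1e-8) return(NULL)
  nrm <- nrm / sqrt(sum(nrm^2))
  for (a in moving) {
    d <- sum((xyz[a, ] - p) * nrm)
    xyz[a, ] <- xyz[a, ] - 2 * d * nrm
  }
  chir <- chirality_impropers(mol$stereo)
  s1 <- minimize_conformer(mol, xyz, merge_restraints(chir, restraints),
                           tol = 5e-4, maxit = maxit)
  s2 <- minimize_conformer(mol, s1$xyz, restraints, tol = 5e-4, maxit = maxit)
  if (!is.finite(s2$energy)) return(NULL)
  conformer(s2$xyz, s2$energy, s2$violation,
            c(conf$provenance, sprintf("bridgeflip[%d..%d]", bridge[1],
                                       bridge[length(bridge)])))
}

vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Enumerate trans-annular hydrogen-bond pairs
#'
#' Donor/acceptor pairs within one macrocyclic system whose anchors (the
#' main-cycle atom carrying or nearest to the donor/acceptor) are joined by a
#' non-bridging arc of at least eight atoms inclusive. Arcs through bridge
#' attachment atoms are not used; pairs with no admissible arc are dropped.
#'
#' @param mol a [mol_graph()]
#' @param macro a `macrocycle`
#' @param min_path minimum inclusive path length (default 8)
#' @return list of pairs (`donor_h`, `donor_heavy`, `acceptor`, `pos_d`,
#'   `pos_a` ring positions, `path_len`)
#' @export
enumerate_hbond_pairs <- function(mol, macro, min_path = 8) {
  da <- find_donors_acceptors(mol)
  cyc <- macro$cycle
  nn <- length(cyc)
  anchors <- unlist(lapply(macro$bridges,
                           function(p) p[c(1, length(p))]))
  g_full <- mol_igraph(mol)
  anchor_pos <- function(atom) {
    # nearest main-cycle atom by graph distance
    if (atom %in% cyc) return(match(atom, cyc))
    d <- igraph::distances(g_full, v = atom, to = cyc)
    match(cyc[which.min(d)], cyc)
  }
  out <- list()
  for (di in seq_along(da$donor_h)) {
    dh <- da$donor_h[di]; dheavy <- da$donor_heavy[di]
    pd <- anchor_pos(dheavy)
    if (is.na(pd)) next
    for (acc in da$acceptors) {
      if (acc == dheavy) next
      pa <- anchor_pos(acc)
      if (is.na(pa) || pa == pd) next
      # two arcs between ring positions pd, pa (inclusive lengths)
      fw <- (pa - pd) %% nn + 1          # atoms walking forward
      bw <- (pd - pa) %% nn + 1
      arc_ok <- function(from, to) {
        ks <- from
        k <- from
        while (k != to) { k <- k %% nn + 1; ks <- c(ks, k) }
        !any(cyc[ks] %in% anchors)
      }
      lens <- c()
      if (arc_ok(pd, pa)) lens <- c(lens, fw)
      if (arc_ok(pa, pd)) lens <- c(lens, bw)
      if (!length(lens)) next
      if (min(lens) < min_path) next
      out[[length(out) + 1]] <- list(donor_h = dh, donor_heavy = dheavy,
                                     acceptor = acc, pos_d = pd, pos_a = pa,
                                     path_len = min(lens))
    }
  }
  out
}

# signed wrap of an index difference into (-n/2, n/2]
wrap_delta <- function(x, n) {
  y <- x %% n
  ifelse(y > n / 2, y - n, y)
}

hbond_triplet_compatible <- function(p1, p2, p3, n) {
  prm <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ps <- list(p1, p2, p3)
  for (o in prm) {
    a <- ps[[o[1]]]; b <- ps[[o[2]]]; cc <- ps[[o[3]]]
    dd1 <- wrap_delta(b$pos_d - a$pos_d, n)
    dd2 <- wrap_delta(cc$pos_d - b$pos_d, n)
    da1 <- wrap_delta(b$pos_a - a$pos_a, n)
    da2 <- wrap_delta(cc$pos_a - b$pos_a, n)
    if (dd1 == 0 || dd2 == 0 || da1 == 0 || da2 == 0) next
    if (dd1 == -da1 && dd2 == -da2) return(TRUE)
  }
  FALSE
}

#' Enumerate topologically compatible hydrogen-bond triplets
#'
#' Scans all three-subsets of pairs; a triplet is compatible when, for some
#' ordering, the ring-index steps on the donor side are exactly the negated
#' steps on the acceptor side (indices move in opposite directions around the
#' ring, as required for simultaneous trans-annular bonds). Triplets must use
#' three distinct donors and three distinct acceptors.
#'
#' @param pairs from [enumerate_hbond_pairs()]
#' @param macro the `macrocycle` the pairs live on
#' @return list of triplets (index triples into `pairs` plus the pairs)
#' @export
enumerate_hbond_triplets <- function(pairs, macro) {
  if (length(pairs) < 3) return(list())
  n <- macro$ring_size
  out <- list()
  cmb <- utils::combn(length(pairs), 3)
  for (cix in seq_len(ncol(cmb))) {
    k <- cmb[, cix]
    p1 <- pairs[[k[1]]]; p2 <- pairs[[k[2]]]; p3 <- pairs[[k[3]]]
    if (length(unique(c(p1$donor_h, p2$donor_h, p3$donor_h))) < 3) next
    if (length(unique(c(p1$acceptor, p2$acceptor, p3$acceptor))) < 3) next
    if (hbond_triplet_compatible(p1, p2, p3, n))
      out[[length(out) + 1]] <- list(idx = k, pairs = list(p1, p2, p3))
  }
  out
}

triplet_restraints <- function(triplet, max_dist = 2.0, penalty = 20) {
  # free below max_dist, quadratic beyond: well centered at max_dist/2 with
  # wiggle max_dist/2
  r <- empty_restraints()
  for (p in triplet$pairs) {
    r <- merge_restraints(r, distance_well(p$donor_h, p$acceptor,
                                           dist = max_dist / 2,
                                           wiggle = max_dist / 2,
                                           penalty = penalty))
  }
  r
}

mean_triplet_distance <- function(xyz, triplet) {
  mean(vapply(triplet$pairs, function(p)
    sqrt(sum((xyz[p$donor_h, ] - xyz[p$acceptor, ])^2)), numeric(1)))
}

#' Build constrained starting structures for hydrogen-bond triplets
#'
#' Each triplet is minimized under 2.0-Angstrom-or-less distance wells from a
#' common start; candidates are ranked by mean minimized H-bond distance and
#' the best `keep` retained. For each retained triplet a fresh structure is
#' generated from zeroed coordinates under the triplet restraints. The
#' restraint-free agnostic start is always appended last.
#'
#' @param mol a [mol_graph()]
#' @param triplets from [enumerate_hbond_triplets()]
#' @param base_conf common starting conformer (typically the agnostic
#'   memory-free start)
#' @param keep number of triplet starts retained (default 8)
#' @param seed seed for the fresh embeddings
#' @return list of `list(conf, restraints, label)`
#' @export
build_constrained_starts <- function(mol, triplets, base_conf, keep = 8,
                                     seed = 1) {
  scored <- list()
  chir <- chirality_impropers(mol$stereo)
  for (t in seq_along(triplets)) {
    tr <- triplets[[t]]
    rs <- merge_restraints(triplet_restraints(tr), chir)
    m <- minimize_conformer(mol, base_conf$xyz, rs, maxit = 1500)
    if (!is.finite(m$total)) next
    scored[[length(scored) + 1]] <-
      list(triplet = tr, score = mean_triplet_distance(m$xyz, tr))
  }
  ord <- order(vapply(scored, function(s) s$score, numeric(1)))
  kept <- scored[head(ord, keep)]
  out <- list()
  for (s in seq_along(kept)) {
    tr <- kept[[s]]$triplet
    rs <- triplet_restraints(tr)
    x0 <- embed_coordinates(mol, seed = seed + 1000 * s)
    m <- relax_embedding(mol, x0, restraints = rs)
    if (!is.finite(m$total)) next
    out[[length(out) + 1]] <- list(
      conf = conformer(m$xyz, m$energy, m$violation,
                       sprintf("hb_triplet_start_%d", s)),
      restraints = rs,
      label = sprintf("triplet_%d", s))
  }
  out[[length(out) + 1]] <- list(conf = base_conf,
                                 restraints = empty_restraints(),
                                 label = "agnostic")
  out
}
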