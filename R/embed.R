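# Memory-free 3D embedding: coordinates are generated from topology and
# recorded stereochemistry only. Macrocycle main cycles start on a circle;
# remaining atoms are attached breadth-first with seeded jitter; staged FIRE
# minimization (valence terms first, then full force field with chirality
# impropers) relaxes to a chemically sensible conformer.

embed_coordinates <- function(mol, seed = 1) {
  n <- n_atoms(mol)
  set.seed(seed %% .Machine$integer.max)
  xyz <- matrix(NA_real_, n, 3)
  mcs <- perceive_macrocycles(mol)
  if (length(mcs)) {
    # largest macrocycle on a circle in the xy plane
    sizes <- vapply(mcs, function(m) m$ring_size, integer(1))
    cyc <- mcs[[which.max(sizes)]]$cycle
    r <- 1.5 / (2 * sin(pi / length(cyc)))
    th <- 2 * pi * (seq_along(cyc) - 1) / length(cyc)
    xyz[cyc, ] <- cbind(r * cos(th), r * sin(th),
                        0.3 * sin(3 * th) + runif(length(cyc), -0.05, 0.05))
  } else {
    rsys <- perceive_ring_systems(mol)
    if (length(rsys)) {
      # largest small-ring system: 2D spring layout, jittered in z
      sz <- vapply(rsys, function(s) length(s$atoms), integer(1))
      sys <- rsys[[which.max(sz)]]
      sub <- mol$bonds[sys$bonds, , drop = FALSE]
      g <- igraph::make_empty_graph(n = length(sys$atoms), directed = FALSE)
      idx <- match(seq_len(n), sys$atoms)
      g <- igraph::add_edges(g, rbind(idx[sub$i], idx[sub$j]))
      ly <- igraph::layout_with_fr(g, dim = 2, niter = 500)
      bl <- sqrt(rowSums((ly[idx[sub$i], , drop = FALSE] -
                          ly[idx[sub$j], , drop = FALSE])^2))
      ly <- ly * 1.5 / max(1e-9, mean(bl))
      xyz[sys$atoms, ] <- cbind(ly, runif(length(sys$atoms), -1, 1))
    } else {
      xyz[1, ] <- c(0, 0, 0)
    }
  }
  # BFS attachment of the remaining atoms
  placed <- which(!is.na(xyz[, 1]))
  if (!length(placed)) { xyz[1, ] <- 0; placed <- 1L }
  queue <- placed
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (nb in neighbors_of(mol, a)) {
      if (!is.na(xyz[nb, 1])) next
      dir <- rnorm(3)
      # bias away from already-placed neighbors of a
      pn <- Filter(function(x) !is.na(xyz[x, 1]), neighbors_of(mol, a))
      if (length(pn)) {
        away <- xyz[a, ] - colMeans(xyz[pn, , drop = FALSE])
        if (sum(away^2) > 1e-8) dir <- dir + 2 * away / sqrt(sum(away^2))
      }
      dir <- dir / sqrt(sum(dir^2))
      xyz[nb, ] <- xyz[a, ] + 1.45 * dir
      queue <- c(queue, nb)
    }
  }
  # disconnected safety net
  miss <- which(is.na(xyz[, 1]))
  if (length(miss)) xyz[miss, ] <- matrix(rnorm(3 * length(miss), sd = 3),
                                          ncol = 3)
  xyz
}

# staged relaxation used by memory_free_start and fixture references
relax_embedding <- function(mol, xyz, restraints = empty_restraints(),
                            maxit = 2000, enforce = TRUE) {
  terms <- get_terms(mol)
  # strong enforcement with a healthy volume margin, so that the
  # configuration survives the final unrestrained relaxation
  chir <- if (enforce) chirality_impropers(mol$stereo, k = 400, margin = 0.45)
          else empty_restraints()
  r1 <- merge_restraints(restraints, chir)
  # stage 1: valence only (no nonbonded), untangles without clash traps
  t1 <- terms; t1$nb <- NULL
  s1 <- ff_minimize_cpp(xyz, t1, r1, tol = 1e-3, maxit = maxit)
  # stages 2-3: full force field, enforcement kept active (it is zero-cost
  # once satisfied; search keeps the impropers too, so configurations are
  # maintained rather than merely checked)
  s2 <- ff_minimize_cpp(s1$xyz, terms, r1, tol = 1e-4, maxit = maxit)
  ff_minimize_cpp(s2$xyz, terms, r1, tol = 1e-4, maxit = maxit)
}

# Local repair of inverted tetrahedral centers on an otherwise relaxed fold:
# a whole-molecule mirror first if most centers are inverted (free), then,
# per remaining center, either swap the two smallest pendant substituents
# (bisector-plane reflection) or umbrella-flip a lone pendant plus the
# center across the plane of the other three neighbors.
repair_chirality <- function(mol, xyz, stereo = mol$stereo) {
  tet <- Filter(function(s) s$kind == "tetrahedral", stereo)
  if (!length(tet)) return(xyz)
  bad_centers <- function(x) {
    Filter(function(s) {
      v <- chir_volume_cpp(x, s$atoms[1], s$atoms[2], s$atoms[3], s$atoms[4])
      sign(v) != s$config
    }, tet)
  }
  bad <- bad_centers(xyz)
  if (length(bad) > length(tet) / 2) {
    xyz[, 1] <- -xyz[, 1]   # mirror image: flips every center at no cost
    bad <- bad_centers(xyz)
  }
  for (s in bad) {
    cc <- s$atoms[1]
    nbs <- neighbors_of(mol, cc)
    if (length(nbs) != 4) next
    branches <- lapply(nbs, function(nb) {
      br <- c(nb, pendants_of(mol, nb, cc))
      if (cc %in% br) NULL else br          # ring branch loops back: skip
    })
    acyclic <- which(!vapply(branches, is.null, logical(1)) &
                     !vapply(seq_along(nbs), function(k) {
                       # a branch that reaches another neighbor is cyclic
                       any(setdiff(nbs, nbs[k]) %in% branches[[k]])
                     }, logical(1)))
    if (length(acyclic) >= 2) {
      sz <- vapply(branches[acyclic], length, integer(1))
      pick <- acyclic[order(sz)][1:2]
      a <- nbs[pick[1]]; b <- nbs[pick[2]]
      ua <- xyz[a, ] - xyz[cc, ]; ua <- ua / sqrt(sum(ua^2))
      ub <- xyz[b, ] - xyz[cc, ]; ub <- ub / sqrt(sum(ub^2))
      nrm <- ua - ub
      if (sqrt(sum(nrm^2)) < 1e-8) next
      nrm <- nrm / sqrt(sum(nrm^2))
      mv <- unique(c(branches[[pick[1]]], branches[[pick[2]]]))
      for (at in mv) {
        d <- sum((xyz[at, ] - xyz[cc, ]) * nrm)
        xyz[at, ] <- xyz[at, ] - 2 * d * nrm
      }
    } else if (length(acyclic) == 1) {
      others <- nbs[-match(nbs[acyclic], nbs)]
      p1 <- xyz[others[1], ]
      nrm <- vcross(xyz[others[2], ] - p1, xyz[others[3], ] - p1)
      if (sqrt(sum(nrm^2)) < 1e-8) next
      nrm <- nrm / sqrt(sum(nrm^2))
      mv <- c(cc, branches[[acyclic]])
      for (at in mv) {
        d <- sum((xyz[at, ] - p1) * nrm)
        xyz[at, ] <- xyz[at, ] - 2 * d * nrm
      }
    }
  }
  xyz
}
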