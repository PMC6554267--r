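test_that("square-well distance penalty matches its closed form and boundaries", {
  expect_equal(square_well_distance_penalty(2.6, 2.4, 0.5, 10), 0)
  k <- 7.3
  expect_equal(square_well_distance_penalty(3.4, 2.4, 0.5, k), 0.25 * k)
  # boundary: exactly dist +/- wiggle is zero with zero one-sided slope
  for (d in c(2.4 - 0.5, 2.4 + 0.5)) {
    expect_equal(square_well_distance_penalty(d, 2.4, 0.5, k), 0)
    eps <- 1e-7
    slope_out <- (square_well_distance_penalty(d + sign(d - 2.4) * eps,
                                               2.4, 0.5, k)) / eps
    expect_lt(abs(slope_out), 1e-5)
  }
  # symmetric on both sides of the well
  expect_equal(square_well_distance_penalty(1.4, 2.4, 0.5, k),
               square_well_distance_penalty(3.4, 2.4, 0.5, k))
})

test_that("square-well torsion penalty is periodic and quadratic beyond bounds", {
  expect_equal(square_well_torsion_penalty(-120, -150, -90, 0.05), 0)
  k <- 0.05
  expect_equal(square_well_torsion_penalty(-80, -150, -90, k), 100 * k)
  # wrap case: 175 deg is 10 deg from lo = -175 through the periodic boundary
  # (oracle: brute force over wrap candidates)
  brute <- function(angle, lo, hi, k) {
    devs <- sapply(seq(lo, hi, by = 0.01), function(t)
      min(abs(angle - t), abs(angle - t + 360), abs(angle - t - 360)))
    k * min(devs)^2
  }
  expect_equal(square_well_torsion_penalty(175, -175, -165, k),
               k * 10^2, tolerance = 1e-8)
  expect_equal(square_well_torsion_penalty(175, -175, -165, k),
               brute(175, -175, -165, k), tolerance = 1e-3)
})

test_that("restraint penalties in the minimizer match the closed forms", {
  mol <- fix_cyclohexane()
  st <- cached("cyclohexane_start", memory_free_start(mol, seed = 1))
  d <- sqrt(sum((st$xyz[1, ] - st$xyz[4, ])^2))
  w <- distance_well(1, 4, dist = d + 1.5, wiggle = 0.5, penalty = 10)
  ev <- ringconf:::ff_eval(st$xyz, ff_terms(mol), w)
  expect_equal(ev$violation,
               square_well_distance_penalty(d, d + 1.5, 0.5, 10),
               tolerance = 1e-9)
  phi <- ringconf:::torsion_angle_cpp(st$xyz, 1, 2, 3, 4) * 180 / pi
  tw <- torsion_well(c(1, 2, 3, 4), phi + 20, phi + 40, 0.05)
  ev2 <- ringconf:::ff_eval(st$xyz, ff_terms(mol), tw)
  expect_equal(ev2$violation,
               square_well_torsion_penalty(phi, phi + 20, phi + 40, 0.05),
               tolerance = 1e-6)
})

test_that("energy is deterministic and restraint-free", {
  mol <- fix_cyclohexane()
  st <- cached("cyclohexane_start", memory_free_start(mol, seed = 1))
  expect_identical(energy(mol, st$xyz), energy(mol, st$xyz))
  w <- distance_well(1, 4, 20, 0.1, 100)  # wildly violated well
  ev <- ringconf:::ff_eval(st$xyz, ff_terms(mol), w)
  expect_equal(ev$ff, energy(mol, st$xyz))
  expect_gt(ev$violation, 0)
})

test_that("unparameterizable elements raise a typed error naming the atom", {
  mol <- suppressWarnings(read_mol("C[Si](C)C"))
  expect_error(ff_terms(mol), class = "ringconf_parameterization_error")
  expect_error(ff_terms(mol), "Si")
})

test_that("analytic gradient matches numeric differentiation", {
  mol <- fix_hexapeptide()  # exercises oop, amide torsions, polar charges
  st <- cached("hexapeptide_start", memory_free_start(mol, seed = 2))
  set.seed(4)
  x <- st$xyz + matrix(rnorm(3 * nrow(st$xyz), 0, 0.05), ncol = 3)
  terms <- ff_terms(mol)
  rest <- merge_restraints(
    distance_well(1, 7, 3.0, 0.1, 10),
    torsion_well(c(1, 2, 3, 4), -30, 30, 0.05))
  rest <- merge_restraints(rest, chirality_impropers(list(
    list(kind = "tetrahedral", atoms = c(2, 1, 3, 5), config = 1))))
  ev <- ringconf:::ff_eval(x, terms, rest, gradient = TRUE)
  g <- ev$gradient
  h <- 1e-5
  set.seed(9)
  for (probe in sample(length(x), 25)) {
    xp <- x; xp[probe] <- xp[probe] + h
    xm <- x; xm[probe] <- xm[probe] - h
    num <- (ringconf:::ff_eval(xp, terms, rest)$total -
            ringconf:::ff_eval(xm, terms, rest)$total) / (2 * h)
    expect_equal(g[probe], num, tolerance = 1e-4)
  }
})

test_that("minimization is a fixed point on a minimized conformer", {
  mol <- fix_cyclohexane()
  st <- cached("cyclohexane_start", memory_free_start(mol, seed = 1))
  m <- minimize_conformer(mol, st$xyz)
  expect_lt(abs(m$energy - st$energy), 1e-3)
  expect_lt(max(abs(m$xyz - st$xyz)), 0.05)
})

test_that("strong pins dominate: all-atom pinning freezes coordinates", {
  mol <- fix_cyclohexane()
  st <- cached("cyclohexane_start", memory_free_start(mol, seed = 1))
  x0 <- st$xyz + matrix(0.2, nrow(st$xyz), 3)  # translate, then perturb one atom
  x0[1, ] <- x0[1, ] + 0.3
  pins <- pin_restraints(seq_len(nrow(x0)), x0, k = 1e4)
  m <- minimize_conformer(mol, x0, pins)
  expect_lt(max(abs(m$xyz - x0)), 0.05)
})

test_that("a distance well pulls a distant donor-acceptor pair closer", {
  mol <- fix_hexapeptide()
  st <- cached("hexapeptide_start", memory_free_start(mol, seed = 2))
  da <- find_donors_acceptors(mol)
  # pick the farthest donor-H/acceptor pair
  best <- NULL
  for (dh in da$donor_h) for (acc in da$acceptors) {
    d <- sqrt(sum((st$xyz[dh, ] - st$xyz[acc, ])^2))
    if (is.null(best) || d > best$d) best <- list(dh = dh, acc = acc, d = d)
  }
  expect_gt(best$d, 3.5)
  w <- distance_well(best$dh, best$acc, dist = 1.0, wiggle = 1.0, penalty = 20)
  m <- minimize_conformer(mol, st$xyz, w)
  d_after <- sqrt(sum((m$xyz[best$dh, ] - m$xyz[best$acc, ])^2))
  expect_lt(d_after, best$d)
})

test_that("chirality check detects mirror inversion and matches signed volume", {
  mol <- fix_ala_hexapeptide()  # methyl side chains give real stereocenters
  st <- cached("ala_hexapeptide_start", memory_free_start(mol, seed = 2))
  stereo <- record_stereo(
    mol_graph(mol$atoms, mol$bonds, xyz = st$xyz))
  expect_gt(length(stereo), 0)
  expect_true(check_chirality(mol, st$xyz, stereo)$pass)
  mirrored <- st$xyz
  mirrored[, 1] <- -mirrored[, 1]
  chk <- check_chirality(mol, mirrored, stereo)
  tet <- Filter(function(s) s$kind == "tetrahedral", stereo)
  if (length(tet)) {
    expect_false(chk$pass)
    # every tetrahedral violation agrees with an independent signed-volume
    # computation (determinant oracle)
    vol <- function(xyz, s) {
      m <- rbind(xyz[s$atoms[2], ] - xyz[s$atoms[1], ],
                 xyz[s$atoms[3], ] - xyz[s$atoms[1], ],
                 xyz[s$atoms[4], ] - xyz[s$atoms[1], ])
      det(m)
    }
    for (s in tet) {
      expect_equal(sign(vol(mirrored, s)), -s$config)
    }
  }
})
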