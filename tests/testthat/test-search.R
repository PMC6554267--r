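test_that("memory-free starts never read input coordinates", {
  mol <- fix_cyclohexane()
  # give the molecule nonsense coordinates; the start must be unaffected
  fake1 <- mol; fake1$xyz <- matrix(99, n_atoms(mol), 3)
  fake2 <- mol; fake2$xyz <- matrix(-7, n_atoms(mol), 3)
  s1 <- memory_free_start(fake1, seed = 5)
  s2 <- memory_free_start(fake2, seed = 5)
  expect_identical(s1$xyz, s2$xyz)
  expect_true(is.finite(s1$energy))
})

test_that("memory-free starts reproduce recorded chirality", {
  k <- fix_ala_hexapeptide()  # six genuine alpha-carbon stereocenters
  ref <- cached("ala_hexapeptide_start", memory_free_start(k, seed = 2))
  stereo <- record_stereo(mol_graph(k$atoms, k$bonds, xyz = ref$xyz))
  expect_gte(length(Filter(function(s) s$kind == "tetrahedral", stereo)), 6)
  k2 <- k; k2$stereo <- stereo
  st <- memory_free_start(k2, seed = 77)
  expect_true(check_chirality(k2, st$xyz, stereo)$pass)
})

test_that("rigid molecules give exactly one conformer", {
  bz <- fix_benzene()
  st <- memory_free_start(bz, seed = 1)
  pool <- ring_search(bz, st, search_config("pgeom"))
  expect_length(pool, 1)
  ens <- generate_conformers(bz, search_config("pfastf", seed = 1))
  expect_length(ens$conformers, 1)
})

test_that("cyclohexane ring search recovers chair and twist-boat families", {
  ch <- fix_cyclohexane()
  st <- cached("cyclohexane_start", memory_free_start(ch, seed = 1))
  pool <- cached("cyclohexane_pool", ring_search(ch, st, search_config("pgeom")))
  expect_gte(length(pool), 2)
  es <- vapply(pool, function(p) p$energy, numeric(1))
  expect_true(all(diff(es) >= -1e-9))  # ascending
  ring_tors <- function(xyz) sapply(1:6, function(k) {
    idx <- ((k - 1):(k + 2)) %% 6 + 1
    ringconf:::torsion_angle_cpp(xyz, idx[1], idx[2], idx[3], idx[4]) * 180 / pi
  })
  classes <- vapply(pool, function(p) {
    t <- abs(ring_tors(p$xyz))
    if (all(abs(t - 60) < 10)) "chair" else "boat_family"
  }, character(1))
  expect_true("chair" %in% classes)
  expect_true("boat_family" %in% classes)
  # the chair is the global minimum
  expect_equal(classes[[1]], "chair")
})

test_that("ensemble assembly enforces window, redundancy and cap", {
  ch <- fix_cyclohexane()
  st <- cached("cyclohexane_start", memory_free_start(ch, seed = 1))
  mk <- function(e, shift = 0) {
    x <- st$xyz; x[, 1] <- x[, 1] + shift
    conformer(x, e)
  }
  cfg <- search_config("pgeom")
  # duplicates collapse to one survivor
  ens <- assemble_ensemble(ch, list(mk(1), mk(1), mk(1)), cfg)
  expect_length(ens$conformers, 1)
  # all conformers above the window vanish except the minimum
  ens2 <- assemble_ensemble(ch, list(mk(0), mk(30, 5), mk(35, 9)), cfg)
  expect_length(ens2$conformers, 1)
  # cap: more windowed distinct conformers than the cap allows
  many <- lapply(seq_len(30), function(i) {
    set.seed(i)
    conformer(st$xyz + matrix(rnorm(length(st$xyz), 0, 2), ncol = 3),
              i * 0.01)
  })
  cfg_small <- search_config("pgeom", max_conformers = 10)
  ens3 <- assemble_ensemble(ch, many, cfg_small)
  expect_lte(length(ens3$conformers), 10)
  expect_equal(ens3$conformers[[1]]$energy, 0.01)  # lowest always kept
})

test_that("output ensembles satisfy window, cap, redundancy and chirality", {
  hx <- fix_hexapeptide()
  cfg <- shallow_config(seed = 2)
  ens <- cached("hexapeptide_ensemble", generate_conformers(hx, cfg))
  n <- length(ens$conformers)
  expect_lte(n, cfg$max_conformers)
  expect_true(all(ens$rel_energies <= cfg$final_window_macro + 1e-9))
  expect_true(all(diff(ens$energies) >= -1e-9))
  id <- matrix(seq_len(n_atoms(hx)), 1)
  hv <- which(hx$atoms$element != "H")
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (abs(ens$energies[i] - ens$energies[j]) > cfg$energy_match_tol) next
      r <- ringconf:::min_map_rmsd_cpp(ens$conformers[[i]]$xyz,
                                       ens$conformers[[j]]$xyz, id, hv)
      expect_gte(r, cfg$redundancy_heavy)
    }
  }
  for (cf in ens$conformers)
    expect_true(check_chirality(hx, cf$xyz)$pass)
})

test_that("search is deterministic and independent of the thread knob", {
  ch <- fix_cyclohexane()
  e1 <- generate_conformers(ch, search_config("pfastf", seed = 4, threads = 1))
  e2 <- generate_conformers(ch, search_config("pfastf", seed = 4, threads = 4))
  expect_identical(lapply(e1$conformers, function(p) p$xyz),
                   lapply(e2$conformers, function(p) p$xyz))
  expect_identical(e1$energies, e2$energies)
})

test_that("hydrogen-bond network search falls back without donors", {
  cd <- fix_cyclodecane()
  st <- cached("cyclodecane_start", memory_free_start(cd, seed = 1))
  cfg <- search_config("pgeom", max_rounds = 1)
  p1 <- ring_search(cd, st, cfg)
  p2 <- hbond_network_search(cd, st, cfg)
  expect_identical(lapply(p1, function(p) p$xyz), lapply(p2, function(p) p$xyz))
})

test_that("exocyclic elaboration finds side-chain rotamers and respects caps", {
  eb <- cached("ethylbenzene", read_mol(fixture_smiles$ethylbenzene))
  st <- memory_free_start(eb, seed = 1)
  cfg <- search_config("pgeomf", seed = 1)
  ring_pool <- ring_search(eb, st, cfg)
  expect_length(ring_pool, 1)  # aromatic ring is rigid
  out <- exocyclic_elaboration(eb, ring_pool, cfg)
  expect_gte(length(out), 2)   # distinct ethyl rotamers
  expect_lte(length(out), cfg$max_conformers)
  # no exocyclic rotatables: identity
  cd <- fix_cyclodecane()
  stc <- cached("cyclodecane_start", memory_free_start(cd, seed = 1))
  pool <- list(stc)
  expect_identical(exocyclic_elaboration(cd, pool, cfg), pool)
})

test_that("pscreen cap switches with ligand flexibility", {
  cfg <- search_config("pscreen")
  expect_equal(ringconf:::effective_cap(cfg, fix_benzene()), 50)
  expect_equal(ringconf:::effective_cap(cfg, fix_hexapeptide()), 120)
})
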