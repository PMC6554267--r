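test_that("bend enumeration follows the three eligibility rules", {
  bz <- fix_benzene()
  expect_length(enumerate_bends(bz, perceive_ring_systems(bz)[[1]]), 0)

  ch <- fix_cyclohexane()
  bends <- enumerate_bends(ch, perceive_ring_systems(ch)[[1]])
  # brute-force oracle over the 15 atom pairs: non-adjacent ring pairs
  adj <- with(ch$bonds, cbind(i, j))
  is_adj <- function(p, q) any((adj[, 1] == p & adj[, 2] == q) |
                               (adj[, 1] == q & adj[, 2] == p))
  oracle <- sum(apply(utils::combn(1:6, 2), 2,
                      function(pq) !is_adj(pq[1], pq[2])))
  expect_equal(length(bends), oracle)
  expect_equal(length(bends), 9)
  # smaller side is the RHS
  for (b in bends) expect_lte(length(b$rhs), length(b$lhs))

  dec <- fix_decalin()
  bd <- enumerate_bends(dec, perceive_ring_systems(dec)[[1]])
  fus <- perceive_ring_systems(dec)[[1]]$fusion_atoms
  # pairs spanning the fusion (one atom in each ring) are excluded: removing
  # them leaves the system connected through the fusion bond
  sysat <- perceive_ring_systems(dec)[[1]]$atoms
  ring_a <- setdiff(dec$rings$bond_ring_atoms[[1]], fus)
  for (b in bd) {
    in_a <- b$axis %in% ring_a
    not_fus <- !(b$axis %in% fus)
    expect_false(sum(in_a & not_fus) == 1 && sum(!in_a & not_fus) == 1)
  }
})

test_that("bends on the cyclohexane chair reach the twist-boat family", {
  ch <- fix_cyclohexane()
  st <- cached("cyclohexane_start", memory_free_start(ch, seed = 1))
  chm <- ringconf:::with_ff_cache(ch)
  ring_tors <- function(xyz) sapply(1:6, function(k) {
    idx <- ((k - 1):(k + 2)) %% 6 + 1
    ringconf:::torsion_angle_cpp(xyz, idx[1], idx[2], idx[3], idx[4]) * 180 / pi
  })
  # the start is a chair (alternating +/- 60 ring torsions)
  expect_true(all(abs(abs(ring_tors(st$xyz)) - 60) < 5))
  bends <- enumerate_bends(ch, perceive_ring_systems(ch)[[1]])
  cands <- Filter(Negate(is.null),
                  lapply(bends, function(b) apply_bend(chm, st, b)))
  es <- vapply(cands, function(p) p$energy, numeric(1))
  # at least one bend leaves the chair basin, at strictly higher energy
  expect_gt(max(es) - st$energy, 1)
  nonchair <- cands[[which.max(es)]]
  expect_true(any(abs(ring_tors(nonchair$xyz)) < 40))  # boat-family torsions
  expect_gt(st$energy + 1e-9, min(c(es, st$energy)))   # chair is the minimum
})

test_that("twist enumeration counts rotatable macrocyclic bonds times two ends", {
  cd <- fix_cyclodecane()
  expect_length(enumerate_twists(cd, perceive_macrocycles(cd)[[1]]), 20)
  ch <- fix_cyclohexane()
  expect_length(perceive_macrocycles(ch), 0)
  hx <- fix_hexapeptide()
  tw <- enumerate_twists(hx, perceive_macrocycles(hx)[[1]])
  expect_length(tw, 24)  # 18 ring bonds - 6 amides = 12, times 2 ends
})

test_that("twist application honors the pin contract and rejects identity", {
  cd <- ringconf:::with_ff_cache(fix_cyclodecane())
  st <- cached("cyclodecane_start", memory_free_start(cd, seed = 1))
  tw <- enumerate_twists(cd, perceive_macrocycles(cd)[[1]])[[1]]
  fixed <- tw$window[-tw$moving]
  # pinned phase: reproduce it manually and check pinned atoms barely move
  pins <- pin_restraints(fixed, st$xyz, 100)
  m <- minimize_conformer(cd, st$xyz, pins, maxit = 800)
  expect_lt(max(abs(m$xyz[fixed, ] - st$xyz[fixed, ])), 0.1)
  # a 0-degree twist relaxes back to the parent (duplicate by ring RMSD)
  cand0 <- apply_twist(cd, st, tw, angles = 0)
  id <- matrix(seq_len(nrow(st$xyz)), 1)
  r <- ringconf:::min_map_rmsd_cpp(cand0[[1]]$xyz, st$xyz, id, 1:10)
  expect_lt(r, 0.3)
})

test_that("flip gate applies distance and directional thresholds", {
  ex <- c(1, 0, 0)
  # parallel bonds 5 A apart with the midpoint vector parallel: included
  expect_true(flip_gate(c(0, 0, 0), c(5, 0, 0), ex, ex))
  # midpoints at 3.9 A: excluded by the distance gate
  expect_false(flip_gate(c(0, 0, 0), c(3.9, 0, 0), ex, ex))
  # min dot product exactly at the threshold: excluded (strict inequality)
  th <- acos(0.3)
  v2 <- c(cos(th), sin(th), 0)
  expect_false(flip_gate(c(0, 0, 0), c(5, 0, 0), ex, v2))
  # just inside the cone: included
  v2in <- c(cos(th - 1e-3), sin(th - 1e-3), 0)
  expect_true(flip_gate(c(0, 0, 0), c(5, 0, 0), ex, v2in))
})

test_that("pre-minimization flips are exact involutive isometries", {
  cd <- fix_cyclodecane()
  st <- cached("cyclodecane_start", memory_free_start(cd, seed = 1))
  mc <- perceive_macrocycles(cd)[[1]]
  # construct a flip descriptor directly (eligibility is tested separately)
  cyc <- mc$cycle
  b1 <- cyc[1:2]; b2 <- cyc[6:7]
  fl <- list(bond1 = b1, bond2 = b2,
             arc = cyc[3:5],
             mid1 = (st$xyz[b1[1], ] + st$xyz[b1[2], ]) / 2,
             mid2 = (st$xyz[b2[1], ] + st$xyz[b2[2], ]) / 2)
  raw <- apply_flip(cd, st, fl, minimize = FALSE)
  moved <- c(fl$arc)
  # isometry: distance to the flip axis is preserved for each flipped atom
  axis <- fl$mid2 - fl$mid1
  axis <- axis / sqrt(sum(axis^2))
  dist_axis <- function(xyz, a) {
    d <- xyz[a, ] - fl$mid1
    sqrt(sum(d^2) - sum(d * axis)^2)
  }
  for (a in moved)
    expect_equal(dist_axis(raw$xyz, a), dist_axis(st$xyz, a),
                 tolerance = 1e-10)
  # involution: applying the same flip twice restores coordinates exactly
  raw2 <- apply_flip(cd, raw, fl, minimize = FALSE)
  expect_lt(max(abs(raw2$xyz - st$xyz)), 1e-9)
})

test_that("bridge flips move the bridge and preserve chirality", {
  k <- ringconf:::with_ff_cache(fix_kel_like())
  st <- cached("kel_start", memory_free_start(k, seed = 3))
  mc <- perceive_macrocycles(k)[[1]]
  expect_length(mc$bridges, 1)
  stereo <- record_stereo(mol_graph(k$atoms, k$bonds, xyz = st$xyz))
  k2 <- k; k2$stereo <- stereo
  cand <- apply_bridge_flip(k2, st, mc, mc$bridges[[1]], maxit = 800)
  if (!is.null(cand)) {
    expect_true(check_chirality(k2, cand$xyz, stereo)$pass)
    interior <- mc$bridges[[1]][-c(1, length(mc$bridges[[1]]))]
    moved <- max(abs(cand$xyz[interior, ] - st$xyz[interior, ]))
    expect_gt(moved, 0.5)
  }
  # bridge-free macrocycle: nothing to flip
  cd <- fix_cyclodecane()
  expect_length(perceive_macrocycles(cd)[[1]]$bridges, 0)
})

test_that("hydrogen-bond pairs respect path-length and bridge rules", {
  cd <- fix_cyclodecane()
  expect_length(enumerate_hbond_pairs(cd, perceive_macrocycles(cd)[[1]]), 0)

  hx <- fix_hexapeptide()
  mc <- perceive_macrocycles(hx)[[1]]
  pairs <- enumerate_hbond_pairs(hx, mc)
  for (p in pairs) expect_gte(p$path_len, 8)

  # bridged peptide: no shortest arc may pass a bridge attachment atom
  k <- fix_kel_like()
  mk <- perceive_macrocycles(k)[[1]]
  anchors <- unlist(lapply(mk$bridges, function(b) b[c(1, length(b))]))
  pk <- enumerate_hbond_pairs(k, mk)
  expect_gt(length(pk), 0)
  cyc <- mk$cycle
  nn <- length(cyc)
  for (p in pk) {
    # reconstruct the admissible arcs and check none contain an anchor
    walk <- function(from, to) {
      ks <- from; cur <- from
      while (cur != to) { cur <- cur %% nn + 1; ks <- c(ks, cur) }
      cyc[ks]
    }
    arcs <- list(walk(p$pos_d, p$pos_a), walk(p$pos_a, p$pos_d))
    ok <- vapply(arcs, function(a) !any(a %in% anchors), logical(1))
    lens <- vapply(arcs, length, integer(1))
    expect_true(any(ok & lens >= 8))
    expect_equal(min(lens[ok]), p$path_len)
  }
})

test_that("triplet compatibility requires negated index deltas", {
  mkpair <- function(d, a) list(donor_h = d * 100L, donor_heavy = d,
                                acceptor = a, pos_d = d, pos_a = a,
                                path_len = 10L)
  macro <- list(ring_size = 30L)
  # deltas +2, +4 on the donor side; -2, -4 on the acceptor side
  good <- list(mkpair(3, 25), mkpair(5, 23), mkpair(9, 19))
  out <- enumerate_hbond_triplets(good, macro)
  expect_length(out, 1)
  # indices increasing on both sides: incompatible
  bad <- list(mkpair(3, 15), mkpair(5, 17), mkpair(9, 21))
  expect_length(enumerate_hbond_triplets(bad, macro), 0)
  # fewer than three pairs
  expect_length(enumerate_hbond_triplets(good[1:2], macro), 0)
})

test_that("triplet enumeration equals brute-force C(n,3) scanning", {
  k <- fix_kel_like()
  mk <- perceive_macrocycles(k)[[1]]
  pairs <- enumerate_hbond_pairs(k, mk)
  tris <- enumerate_hbond_triplets(pairs, mk)
  # independent brute force with a re-derived predicate
  wrap <- function(x, n) { y <- x %% n; ifelse(y > n / 2, y - n, y) }
  compat <- function(ps, n) {
    for (o in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))) {
      a <- ps[[o[1]]]; b <- ps[[o[2]]]; cc <- ps[[o[3]]]
      dd <- c(wrap(b$pos_d - a$pos_d, n), wrap(cc$pos_d - b$pos_d, n))
      da <- c(wrap(b$pos_a - a$pos_a, n), wrap(cc$pos_a - b$pos_a, n))
      if (all(dd != 0) && all(da != 0) && all(dd == -da)) return(TRUE)
    }
    FALSE
  }
  n_brute <- 0
  cmb <- utils::combn(length(pairs), 3)
  for (cix in seq_len(ncol(cmb))) {
    ps <- pairs[cmb[, cix]]
    if (length(unique(vapply(ps, function(p) p$donor_h, numeric(1)))) < 3) next
    if (length(unique(vapply(ps, function(p) p$acceptor, numeric(1)))) < 3) next
    if (compat(ps, mk$ring_size)) n_brute <- n_brute + 1
  }
  expect_equal(length(tris), n_brute)
})

test_that("constrained start generation caps at eight plus the agnostic start", {
  hx <- ringconf:::with_ff_cache(fix_hexapeptide())
  st <- cached("hexapeptide_start", memory_free_start(hx, seed = 2))
  # synthetic triplets: three donors/acceptors with compatible topology
  da <- find_donors_acceptors(hx)
  mkp <- function(dh, dheavy, acc, pd, pa)
    list(donor_h = dh, donor_heavy = dheavy, acceptor = acc,
         pos_d = pd, pos_a = pa, path_len = 9L)
  dh <- da$donor_h[1:3]; dv <- da$donor_heavy[1:3]; ac <- da$acceptors[1:3]
  trip <- list(idx = 1:3,
               pairs = list(mkp(dh[1], dv[1], ac[1], 1, 10),
                            mkp(dh[2], dv[2], ac[2], 3, 8),
                            mkp(dh[3], dv[3], ac[3], 5, 6)))
  many <- rep(list(trip), 12)
  starts <- build_constrained_starts(hx, many, st, keep = 8, seed = 1)
  expect_equal(length(starts), 9)  # 8 constrained + agnostic
  expect_equal(starts[[9]]$label, "agnostic")
  few <- build_constrained_starts(hx, many[1:3], st, keep = 8, seed = 1)
  expect_equal(length(few), 4)
  none <- build_constrained_starts(hx, list(), st, keep = 8, seed = 1)
  expect_equal(length(none), 1)
  expect_equal(none[[1]]$label, "agnostic")
})

test_that("moves preserve molecular topology and are deterministic", {
  cd <- ringconf:::with_ff_cache(fix_cyclodecane())
  st <- cached("cyclodecane_start", memory_free_start(cd, seed = 1))
  tw <- enumerate_twists(cd, perceive_macrocycles(cd)[[1]])
  tw2 <- enumerate_twists(cd, perceive_macrocycles(cd)[[1]])
  expect_identical(tw, tw2)
  c1 <- apply_twist(cd, st, tw[[3]], angles = c(60, 180))
  c2 <- apply_twist(cd, st, tw[[3]], angles = c(60, 180))
  expect_identical(lapply(c1, function(p) p$xyz), lapply(c2, function(p) p$xyz))
  # bond lengths remain chemically sensible after the move (topology intact)
  bl <- sqrt(rowSums((c1[[1]]$xyz[cd$bonds$i, ] - c1[[1]]$xyz[cd$bonds$j, ])^2))
  expect_true(all(bl > 0.8 & bl < 2.0))
})
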