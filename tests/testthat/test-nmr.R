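test_that("constraint files parse per the dialect with validation", {
  tf <- withr::local_tempfile(fileext = ".cons")
  writeLines(c(
    "# toy constraint set",
    "nmr 12 47 dist=2.8 wiggle=0.5 penalty=10",
    "qnmr 21,22,23 35 dist=3.5 wiggle=0.5 penalty=10",
    "torsion 1 2 3 4 lo=-150 hi=-90 penalty=0.05"), tf)
  cs <- parse_constraint_file(tf)
  expect_length(cs, 3)
  expect_equal(cs[[1]]$kind, "nmr")
  expect_equal(cs[[1]]$dist, 2.8)
  expect_equal(cs[[2]]$kind, "qnmr")
  expect_equal(cs[[2]]$a, c(21L, 22L, 23L))
  expect_equal(cs[[3]]$lo, -150)

  # errors carry line numbers
  tf2 <- withr::local_tempfile(fileext = ".cons")
  writeLines(c("nmr 1 2 dist=2.0", "bogus 1 2 dist=2.0"), tf2)
  expect_error(parse_constraint_file(tf2), "line 2")
  tf3 <- withr::local_tempfile(fileext = ".cons")
  writeLines("nmr 1 2 dist=2.0 wiggle=-0.3", tf3)
  expect_error(parse_constraint_file(tf3), "wiggle")
  tf4 <- withr::local_tempfile(fileext = ".cons")
  writeLines("nmr 1 999 dist=2.0", tf4)
  expect_error(parse_constraint_file(tf4, mol = fix_cyclohexane()),
               "exceeds")
})

test_that("a study-scale file of 20 distance and 3 torsion records parses", {
  tf <- withr::local_tempfile(fileext = ".cons")
  set.seed(1)
  lines <- c(sprintf("nmr %d %d dist=%.1f wiggle=0.5 penalty=10",
                     1:20, 21:40, runif(20, 2, 5)),
             sprintf("torsion %d %d %d %d lo=-120 hi=-60 penalty=0.05",
                     1:3, 4:6, 7:9, 10:12))
  writeLines(lines, tf)
  cs <- parse_constraint_file(tf)
  expect_length(cs, 23)
  expect_equal(sum(vapply(cs, function(x) x$kind == "torsion", logical(1))), 3)
})

test_that("profiling reports violation energies identical to the minimizer", {
  hx <- fix_hexapeptide()
  ens <- cached("hexapeptide_ensemble",
                generate_conformers(hx, shallow_config(seed = 2)))
  ref <- cached("hexapeptide_ref", fixture_reference_conformer(hx, seed = 5))
  cons <- make_synthetic_constraints(hx, ref, k = 6, noise = 0, seed = 1)
  prof <- profile_ensemble(hx, ens, cons, reference = ref)
  expect_equal(nrow(prof$conformers), length(ens$conformers))
  rest <- ringconf:::constraints_to_restraints(cons)
  terms <- ff_terms(hx)
  for (i in seq_along(ens$conformers)) {
    ev <- ringconf:::ff_eval(ens$conformers[[i]]$xyz, terms, rest)
    expect_equal(prof$conformers$violation_energy[i], ev$violation,
                 tolerance = 1e-6)
  }
  # frequencies two ways agree: per-constraint column vs direct recount
  mags <- sapply(cons, function(cst) vapply(ens$conformers, function(cf)
    ringconf:::constraint_violation(cf$xyz, cst)$magnitude, numeric(1)))
  expect_equal(prof$constraints$freq_violated,
               unname(colMeans(mags > 1e-9)))
  expect_true(all(prof$constraints$freq_violated >= 0 &
                  prof$constraints$freq_violated <= 1))
})

test_that("profiling the reference against its own constraints gives zeros", {
  hx <- fix_hexapeptide()
  ref <- cached("hexapeptide_ref", fixture_reference_conformer(hx, seed = 5))
  cons <- make_synthetic_constraints(hx, ref, k = 6, noise = 0, seed = 1)
  prof <- profile_ensemble(hx, list(ref), cons, reference = ref)
  expect_equal(prof$conformers$violation_energy, 0)
  expect_equal(prof$conformers$n_viol_minor, 0L)
  expect_equal(prof$conformers$rmsd_to_ref, 0, tolerance = 1e-8)
})

test_that("a 1 A violation beyond the wiggle at penalty 10 scores 10", {
  ch <- fix_cyclohexane()
  st <- cached("cyclohexane_start", memory_free_start(ch, seed = 1))
  d <- sqrt(sum((st$xyz[1, ] - st$xyz[4, ])^2))
  cons <- structure(list(list(kind = "nmr", a = 1L, b = 4L,
                              dist = d - 1.5, wiggle = 0.5, penalty = 10,
                              label = "nmr_1")), class = "constraint_set")
  prof <- profile_ensemble(ch, list(st), cons)
  expect_equal(prof$conformers$violation_energy, 10, tolerance = 1e-9)
})

test_that("profile tables serialize to tab-delimited files", {
  hx <- fix_hexapeptide()
  ref <- cached("hexapeptide_ref", fixture_reference_conformer(hx, seed = 5))
  cons <- make_synthetic_constraints(hx, ref, k = 4, noise = 0, seed = 2)
  prof <- profile_ensemble(hx, list(ref), cons)
  pre <- withr::local_tempfile()
  write_profile(prof, pre)
  ct <- read.table(paste0(pre, "_conformers.tsv"), header = TRUE, sep = "\t")
  kt <- read.table(paste0(pre, "_constraints.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(ct), 1)
  expect_equal(nrow(kt), 4)
})

test_that("alignment tensor is recovered exactly from noise-free couplings", {
  hx <- fix_hexapeptide()
  ref <- cached("hexapeptide_ref", fixture_reference_conformer(hx, seed = 5))
  sa <- c(1e-4, -2e-4, 5e-5, 8e-5, -6e-5)
  rdc <- make_synthetic_rdcs(hx, ref, sa, noise = 0)
  fit <- fit_alignment_tensor(ref, rdc)
  expect_equal(unname(fit$saupe), sa, tolerance = 1e-10)
  expect_lt(fit$q_factor, 1e-10)
  # tensor is symmetric traceless
  expect_equal(fit$tensor, t(fit$tensor))
  expect_lt(abs(sum(diag(fit$tensor))), 1e-18)
})

test_that("Q-factor is invariant under rigid rotation of the conformer", {
  hx <- fix_hexapeptide()
  ref <- cached("hexapeptide_ref", fixture_reference_conformer(hx, seed = 5))
  sa <- c(1e-4, -2e-4, 5e-5, 8e-5, -6e-5)
  rdc <- make_synthetic_rdcs(hx, ref, sa, noise = 0.05, seed = 3)
  q0 <- fit_alignment_tensor(ref, rdc)$q_factor
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  q1 <- fit_alignment_tensor(ref$xyz %*% R, rdc)$q_factor
  expect_equal(q0, q1, tolerance = 1e-10)
  expect_gt(q0, 0)
})

test_that("noisy couplings give Q on the scale of the noise", {
  hx <- fix_hexapeptide()
  ref <- cached("hexapeptide_ref", fixture_reference_conformer(hx, seed = 5))
  sa <- c(1e-4, -2e-4, 5e-5, 8e-5, -6e-5)
  qs <- vapply(1:30, function(s) {
    rdc <- make_synthetic_rdcs(hx, ref, sa, noise = 0.05, seed = s)
    fit_alignment_tensor(ref, rdc)$q_factor
  }, numeric(1))
  expect_gt(mean(qs), 0.02)
  expect_lt(mean(qs), 0.10)
})

test_that("degenerate RDC input is rejected with guidance", {
  hx <- fix_hexapeptide()
  ref <- cached("hexapeptide_ref", fixture_reference_conformer(hx, seed = 5))
  rdc <- make_synthetic_rdcs(hx, ref, c(1e-4, 0, 0, 0, 0), noise = 0)
  rdc5 <- rdc[rep(1, 6), ]  # six copies of one bond direction
  expect_error(fit_alignment_tensor(ref, rdc5), "rank")
})
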