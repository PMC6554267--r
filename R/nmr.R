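# NMR constraint files, ensemble/constraint profiling, and RDC
# alignment-tensor / Q-factor validation.

#' Parse an NMR constraint file
#'
#' Whitespace-separated records, `#` comments, 1-based atom indices in
#' input-file order:
#' \preformatted{
#' nmr     i j         dist=2.8 wiggle=0.5 penalty=10
#' qnmr    i1,i2,..  j1,j2,..  dist=3.5 wiggle=0.5 penalty=10
#' torsion a b c d     lo=-150 hi=-90 penalty=0.05
#' }
#' `nmr` restrains two specific protons; `qnmr` restrains symmetry-related
#' proton groups, measured from the group centroids; `torsion` is a
#' square-well on a dihedral in degrees.
#'
#' @param path file to read
#' @param mol optional [mol_graph()] to validate indices against
#' @return a `constraint_set` (list of constraints)
#' @export
parse_constraint_file <- function(path, mol = NULL) {
  lines <- readLines(path)
  out <- list()
  for (li in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[li])
    ln <- trimws(ln)
    if (!nchar(ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    kind <- f[1]
    kv <- f[grepl("=", f)]
    pos <- f[!grepl("=", f)][-1]
    getv <- function(name, default = NULL) {
      hit <- grep(paste0("^", name, "="), kv, value = TRUE)
      if (!length(hit)) {
        if (is.null(default))
          stop(sprintf("line %d: missing %s=", li, name))
        return(default)
      }
      as.numeric(sub(paste0("^", name, "="), "", hit[1]))
    }
    parse_idx <- function(s) as.integer(strsplit(s, ",")[[1]])
    cst <- switch(kind,
      nmr = {
        if (length(pos) != 2) stop(sprintf("line %d: nmr needs 2 atoms", li))
        list(kind = "nmr", a = parse_idx(pos[1]), b = parse_idx(pos[2]),
             dist = getv("dist"), wiggle = getv("wiggle", 0.5),
             penalty = getv("penalty", 10))
      },
      qnmr = {
        if (length(pos) != 2) stop(sprintf("line %d: qnmr needs 2 groups", li))
        list(kind = "qnmr", a = parse_idx(pos[1]), b = parse_idx(pos[2]),
             dist = getv("dist"), wiggle = getv("wiggle", 0.5),
             penalty = getv("penalty", 10))
      },
      torsion = {
        if (length(pos) != 4)
          stop(sprintf("line %d: torsion needs 4 atoms", li))
        list(kind = "torsion", atoms = as.integer(pos),
             lo = getv("lo"), hi = getv("hi"),
             penalty = getv("penalty", 0.05))
      },
      stop(sprintf("line %d: unknown record kind '%s'", li, kind)))
    if (cst$kind %in% c("nmr", "qnmr")) {
      if (cst$wiggle < 0) stop(sprintf("line %d: negative wiggle", li))
      if (any(is.na(c(cst$a, cst$b))) || any(c(cst$a, cst$b) < 1))
        stop(sprintf("line %d: bad atom index", li))
      if (!is.null(mol) && max(c(cst$a, cst$b)) > n_atoms(mol))
        stop(sprintf("line %d: atom index exceeds molecule size", li))
    } else if (!is.null(mol) && max(cst$atoms) > n_atoms(mol)) {
      stop(sprintf("line %d: atom index exceeds molecule size", li))
    }
    cst$label <- sprintf("%s_%d", kind, length(out) + 1)
    out[[length(out) + 1]] <- cst
  }
  structure(out, class = "constraint_set")
}

#' Serialize a constraint set to the file dialect
#' @param constraints a `constraint_set`
#' @param path output file
#' @export
write_constraint_file <- function(constraints, path) {
  lines <- vapply(constraints, function(cst) {
    switch(cst$kind,
      nmr = sprintf("nmr %s %s dist=%g wiggle=%g penalty=%g",
                    paste(cst$a, collapse = ","),
                    paste(cst$b, collapse = ","),
                    cst$dist, cst$wiggle, cst$penalty),
      qnmr = sprintf("qnmr %s %s dist=%g wiggle=%g penalty=%g",
                     paste(cst$a, collapse = ","),
                     paste(cst$b, collapse = ","),
                     cst$dist, cst$wiggle, cst$penalty),
      torsion = sprintf("torsion %s lo=%g hi=%g penalty=%g",
                        paste(cst$atoms, collapse = " "),
                        cst$lo, cst$hi, cst$penalty))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# constraint set -> minimizer restraints (single source of the penalty form)
constraints_to_restraints <- function(constraints) {
  r <- empty_restraints()
  for (cst in constraints) {
    if (cst$kind %in% c("nmr", "qnmr"))
      r <- merge_restraints(r, distance_well(cst$a, cst$b, cst$dist,
                                             cst$wiggle, cst$penalty))
    else
      r <- merge_restraints(r, torsion_well(cst$atoms, cst$lo, cst$hi,
                                            cst$penalty))
  }
  r
}

constraint_violation <- function(xyz, cst) {
  if (cst$kind %in% c("nmr", "qnmr")) {
    ca <- colMeans(xyz[cst$a, , drop = FALSE])
    cb <- colMeans(xyz[cst$b, , drop = FALSE])
    d <- sqrt(sum((ca - cb)^2))
    list(energy = square_well_distance_penalty(d, cst$dist, cst$wiggle,
                                               cst$penalty),
         magnitude = max(0, abs(d - cst$dist) - cst$wiggle))
  } else {
    phi <- torsion_angle_cpp(xyz, cst$atoms[1], cst$atoms[2], cst$atoms[3],
                             cst$atoms[4]) * 180 / pi
    e <- square_well_torsion_penalty(phi, cst$lo, cst$hi, cst$penalty)
    list(energy = e, magnitude = if (cst$penalty > 0) sqrt(e / cst$penalty)
         else 0)
  }
}

#' Profile an ensemble against a constraint set
#'
#' Per conformer: force-field energy, violation energy (sum of square-well
#' penalties, identical to what the minimizer uses), discrete violation
#' counts at thresholds, and optionally automorphism-corrected RMSD to a
#' reference. Per constraint: violation frequency over the ensemble and the
#' mean and maximum violation magnitude.
#'
#' @param mol a [mol_graph()]
#' @param ensemble a `conformer_ensemble` or list of conformers
#' @param constraints a `constraint_set`
#' @param reference optional reference conformer (or coordinate matrix)
#' @param dist_thresholds,tors_thresholds discrete violation thresholds
#'   (Angstrom / degrees)
#' @return list with data.frames `conformers` and `constraints`
#' @export
profile_ensemble <- function(mol, ensemble, constraints, reference = NULL,
                             dist_thresholds = c(0.2, 0.5),
                             tors_thresholds = c(5, 15)) {
  confs <- if (inherits(ensemble, "conformer_ensemble")) ensemble$conformers
           else ensemble
  nc <- length(confs); nk <- length(constraints)
  emat <- matrix(0, nc, nk)     # violation energies
  vmag <- matrix(0, nc, nk)     # magnitudes
  for (ci in seq_len(nc)) for (ki in seq_len(nk)) {
    v <- constraint_violation(confs[[ci]]$xyz, constraints[[ki]])
    emat[ci, ki] <- v$energy
    vmag[ci, ki] <- v$magnitude
  }
  is_dist <- vapply(constraints, function(cst)
    cst$kind %in% c("nmr", "qnmr"), logical(1))
  cdf <- data.frame(
    conformer = seq_len(nc),
    energy = vapply(confs, function(cf) cf$energy, numeric(1)),
    violation_energy = rowSums(emat))
  thr1 <- ifelse(is_dist, dist_thresholds[1], tors_thresholds[1])
  thr2 <- ifelse(is_dist, dist_thresholds[2], tors_thresholds[2])
  cdf$n_viol_minor <- as.integer(rowSums(sweep(vmag, 2, thr1, ">")))
  cdf$n_viol_major <- as.integer(rowSums(sweep(vmag, 2, thr2, ">")))
  if (!is.null(reference)) {
    ref_xyz <- if (is.matrix(reference)) reference else reference$xyz
    cdf$rmsd_to_ref <- vapply(confs, function(cf)
      automorph_rmsd(mol, list(cf), conformer(ref_xyz))$rmsd, numeric(1))
  }
  kdf <- data.frame(
    label = vapply(constraints, function(cst) cst$label, character(1)),
    kind = vapply(constraints, function(cst) cst$kind, character(1)),
    freq_violated = colMeans(vmag > 1e-9),
    mean_magnitude = colMeans(vmag),
    max_magnitude = apply(vmag, 2, max))
  list(conformers = cdf, constraints = kdf)
}

#' Write profile tables as tab-delimited text
#' @param profile result of [profile_ensemble()]
#' @param prefix output path prefix; writes `<prefix>_conformers.tsv` and
#'   `<prefix>_constraints.tsv`
#' @export
write_profile <- function(profile, prefix) {
  write.table(profile$conformers, paste0(prefix, "_conformers.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(profile$constraints, paste0(prefix, "_constraints.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Fit an RDC alignment tensor by SVD
#'
#' Least-squares Saupe tensor from the 5-column direction-cosine design
#' matrix; back-calculated couplings and the quality factor
#' `Q = rms(D_obs - D_calc) / rms(D_obs)`.
#'
#' @param conformer a conformer (or coordinate matrix)
#' @param rdcs data.frame with columns `i`, `j` (atom indices) and `d_obs`
#'   (observed coupling, Hz)
#' @return list with `saupe` (named 5-vector), `tensor` (3x3 symmetric
#'   traceless), `d_calc`, `q_factor`
#' @export
fit_alignment_tensor <- function(conformer, rdcs) {
  xyz <- if (is.matrix(conformer)) conformer else conformer$xyz
  stopifnot(nrow(rdcs) >= 5)
  u <- xyz[rdcs$i, , drop = FALSE] - xyz[rdcs$j, , drop = FALSE]
  u <- u / sqrt(rowSums(u^2))
  A <- cbind(u[, 1]^2 - u[, 3]^2, u[, 2]^2 - u[, 3]^2,
             2 * u[, 1] * u[, 2], 2 * u[, 1] * u[, 3], 2 * u[, 2] * u[, 3])
  sv <- svd(A)
  if (min(sv$d) < 1e-8 * max(sv$d))
    stop("rank-deficient RDC design matrix: add RDCs with more diverse bond directions")
  s <- sv$v %*% (crossprod(sv$u, rdcs$d_obs) / sv$d)
  d_calc <- as.numeric(A %*% s)
  q <- sqrt(mean((rdcs$d_obs - d_calc)^2)) / sqrt(mean(rdcs$d_obs^2))
  S <- matrix(c(s[1], s[3], s[4],
                s[3], s[2], s[5],
                s[4], s[5], -s[1] - s[2]), 3, 3)
  list(saupe = setNames(as.numeric(s), c("Sxx", "Syy", "Sxy", "Sxz", "Syz")),
       tensor = S, d_calc = d_calc, q_factor = q)
}
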