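# Synthetic molecules and data so every stage is testable without downloads:
# cycloalkanes, classic fused-ring systems from canonical SMILES, toy cyclic
# peptides with controllable N-methylation / proline / ester / disulfide
# patterns, and synthetic NOE-like constraint and RDC sets.

#' Canonical SMILES for reference fixture molecules
#' @export
fixture_smiles <- list(
  benzene = "c1ccccc1",
  cyclohexane = "C1CCCCC1",
  decalin = "C1CCC2CCCCC2C1",
  tetracycline = paste0("C[C@]1([C@H]2C[C@H]3[C@@H](C(=O)C(=C([C@]3(C(=O)",
                        "C2=C(C4=C1C=CC=C4O)O)O)O)C(=O)N)N(C)C)O"),
  ethylbenzene = "CCc1ccccc1"
)

#' Build a cycloalkane
#' @param n ring size, 3 to 60
#' @return a [mol_graph()] with explicit hydrogens (no coordinates)
#' @export
make_cycloalkane <- function(n) {
  stopifnot(n >= 3, n <= 60)
  atoms <- data.frame(element = rep("C", n), charge = 0L)
  bonds <- data.frame(i = seq_len(n), j = c(seq_len(n)[-1], 1L),
                      order = 1L)
  add_hydrogens(mol_graph(atoms, bonds))
}

#' Specification for a toy cyclic peptide
#'
#' @param n_residues number of residues (>= 3)
#' @param sidechains character vector recycled over residues: `"H"`
#'   (glycine-like), `"methyl"`, `"hydroxyl"`, `"aromatic"`
#' @param n_methyl residue indices whose amide nitrogen is methylated
#' @param proline residue indices built as prolines (ring N, no H)
#' @param ester residue indices whose backbone nitrogen is replaced by an
#'   ester oxygen (depsipeptide linkage)
#' @param disulfide optional pair of residue indices joined CB-S-S-CB
#' @return a `peptide_spec` list
#' @export
peptide_spec <- function(n_residues, sidechains = "H", n_methyl = integer(0),
                         proline = integer(0), ester = integer(0),
                         disulfide = NULL) {
  stopifnot(n_residues >= 3)
  if (!is.null(disulfide)) {
    stopifnot(length(disulfide) == 2, disulfide[1] != disulfide[2])
  }
  structure(list(n_residues = n_residues,
                 sidechains = rep_len(sidechains, n_residues),
                 n_methyl = n_methyl, proline = proline, ester = ester,
                 disulfide = disulfide), class = "peptide_spec")
}

#' Build a toy head-to-tail cyclic peptide
#'
#' Backbone N-CA-C(=O) per residue closed head to tail; the main macrocycle
#' has three atoms per residue. N-methylation removes the amide H;
#' prolines close a five-membered ring onto the backbone nitrogen; ester
#' positions give depsipeptide linkages; a disulfide pair adds a CB-S-S-CB
#' bridge across the ring.
#'
#' @param spec a [peptide_spec()]
#' @return a [mol_graph()] with explicit hydrogens (no coordinates)
#' @export
make_cyclic_peptide <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  atoms <- data.frame(element = character(0), charge = integer(0))
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  add_atom <- function(el) {
    atoms <<- rbind(atoms, data.frame(element = el, charge = 0L))
    nrow(atoms)
  }
  add_bond <- function(i, j, order = 1L) {
    bonds <<- rbind(bonds, data.frame(i = i, j = j, order = as.integer(order)))
  }
  nres <- spec$n_residues
  N <- CA <- C <- integer(nres)
  for (r in seq_len(nres)) {
    if (r %in% spec$ester) {
      if (r %in% spec$proline || r %in% spec$n_methyl)
        stop("ester position cannot also be proline or N-methylated")
      N[r] <- add_atom("O")
    } else {
      N[r] <- add_atom("N")
    }
    CA[r] <- add_atom("C")
    C[r] <- add_atom("C")
    O <- add_atom("O")
    add_bond(N[r], CA[r]); add_bond(CA[r], C[r]); add_bond(C[r], O, 2L)
    if (r %in% spec$n_methyl) add_bond(N[r], add_atom("C"))
    if (r %in% spec$proline) {
      if (r %in% spec$n_methyl) stop("proline cannot be N-methylated")
      cb <- add_atom("C"); cg <- add_atom("C"); cd <- add_atom("C")
      add_bond(CA[r], cb); add_bond(cb, cg); add_bond(cg, cd)
      add_bond(cd, N[r])
    } else {
      sc <- spec$sidechains[r]
      if (!is.null(spec$disulfide) && r %in% spec$disulfide) sc <- "thiol"
      if (sc == "methyl") add_bond(CA[r], add_atom("C"))
      if (sc == "hydroxyl") {
        cb <- add_atom("C"); add_bond(CA[r], cb)
        add_bond(cb, add_atom("O"))
      }
      if (sc == "aromatic") {
        cb <- add_atom("C"); add_bond(CA[r], cb)
        ring <- vapply(1:6, function(s) add_atom("C"), integer(1))
        add_bond(cb, ring[1])
        for (s in 1:6) add_bond(ring[s], ring[s %% 6 + 1],
                                if (s %% 2 == 1) 2L else 1L)
      }
      if (sc == "thiol") {
        cb <- add_atom("C"); add_bond(CA[r], cb)
        sg <- add_atom("S"); add_bond(cb, sg)
        if (r == spec$disulfide[1]) sg1 <- sg
        if (r == spec$disulfide[2]) sg2 <- sg
      }
    }
  }
  for (r in seq_len(nres)) add_bond(C[r], N[r %% nres + 1])
  if (!is.null(spec$disulfide)) add_bond(sg1, sg2)
  add_hydrogens(mol_graph(atoms, bonds))
}

#' Tetracycline fixture with noted stereochemistry
#'
#' Connection table and stereo descriptors come from the isomeric SMILES;
#' configurations are noted from a throwaway 3D build, whose coordinates are
#' then discarded, so conformational search starts memory-free with only
#' topology and the noted configurations.
#'
#' @return a [mol_graph()] with recorded stereo and no coordinates
#' @export
make_tetracycline <- function() {
  mol <- suppressWarnings(read_mol(fixture_smiles$tetracycline, gen3d = TRUE))
  mol$xyz <- NULL
  mol
}

#' Reference conformer for a fixture molecule
#'
#' A deterministic embedded-and-minimized conformer used as the "known"
#' structure in parameter-recovery tests (labelled synthetic: it is not an
#' experimental geometry).
#'
#' @param mol a [mol_graph()]
#' @param seed seed for the embedding
#' @return a `conformer`
#' @export
fixture_reference_conformer <- function(mol, seed = 42) {
  memory_free_start(mol, seed = seed)
}

#' Synthetic NOE-like distance constraints from a reference conformer
#'
#' Samples `k` polar-hydrogen / acceptor (falling back to heavy-atom)
#' distances from the reference, perturbs them by Gaussian noise, and emits
#' square-well constraints with the conventional 0.5 Angstrom allowance.
#' By construction the reference itself has zero violation energy at zero
#' noise, enabling parameter-recovery tests.
#'
#' @param mol a [mol_graph()]
#' @param reference a `conformer`
#' @param k number of constraints
#' @param noise distance noise sd, Angstrom
#' @param seed RNG seed
#' @param wiggle well half-width (default 0.5)
#' @param penalty well force constant
#' @return a `constraint_set`
#' @export
make_synthetic_constraints <- function(mol, reference, k = 10, noise = 0,
                                       seed = 1, wiggle = 0.5, penalty = 10) {
  set.seed(seed)
  da <- find_donors_acceptors(mol)
  xyz <- reference$xyz
  cand <- list()
  for (dh in da$donor_h) for (acc in da$acceptors) {
    if (acc %in% neighbors_of(mol, dh)) next
    d <- sqrt(sum((xyz[dh, ] - xyz[acc, ]) ^ 2))
    if (d > 1.8 && d < 6.0)
      cand[[length(cand) + 1]] <- list(a = dh, b = acc, d = d)
  }
  if (length(cand) < k) {
    hv <- heavy_atoms(mol)
    g <- mol_igraph(mol)
    gd <- igraph::distances(g)
    for (p in seq_along(hv)) for (q in seq_along(hv)) {
      if (q <= p) next
      i <- hv[p]; j <- hv[q]
      if (gd[i, j] < 4) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ]) ^ 2))
      if (d < 7.0) cand[[length(cand) + 1]] <- list(a = i, b = j, d = d)
    }
  }
  if (!length(cand)) stop("no constraint candidates on this fixture")
  if (length(cand) > k) {
    # deterministic spread: order by observed distance, take evenly spaced
    ord <- order(vapply(cand, function(x) x$d, numeric(1)))
    cand <- cand[ord[round(seq(1, length(cand), length.out = k))]]
  } else if (length(cand) < k) {
    warning("only ", length(cand), " candidate pairs available; capping k")
  }
  out <- lapply(seq_along(cand), function(s) {
    cc <- cand[[s]]
    list(kind = "nmr", a = cc$a, b = cc$b,
         dist = cc$d + rnorm(1, 0, noise), wiggle = wiggle,
         penalty = penalty, label = sprintf("nmr_%d", s))
  })
  structure(out, class = "constraint_set")
}

#' Synthetic residual dipolar couplings from a known alignment tensor
#'
#' Forward-calculates couplings for polar and CH bond vectors of a conformer
#' under the given Saupe elements, with optional multiplicative noise;
#' exercises the alignment-tensor fit without experimental data.
#'
#' @param mol a [mol_graph()]
#' @param conformer a `conformer`
#' @param saupe 5 Saupe elements (Sxx, Syy, Sxy, Sxz, Syz)
#' @param noise multiplicative noise fraction
#' @param seed RNG seed
#' @param max_bonds cap on the number of bond vectors used
#' @return data.frame with `i`, `j`, `d_obs`
#' @export
make_synthetic_rdcs <- function(mol, conformer, saupe, noise = 0, seed = 1,
                                max_bonds = 30) {
  set.seed(seed)
  stopifnot(length(saupe) == 5)
  el <- mol$atoms$element
  b <- mol$bonds
  sel <- which((el[b$i] == "H") != (el[b$j] == "H"))  # X-H bonds
  if (length(sel) < 5) sel <- seq_len(nrow(b))
  sel <- head(sel, max_bonds)
  xyz <- conformer$xyz
  u <- xyz[b$i[sel], , drop = FALSE] - xyz[b$j[sel], , drop = FALSE]
  u <- u / sqrt(rowSums(u^2))
  A <- cbind(u[, 1]^2 - u[, 3]^2, u[, 2]^2 - u[, 3]^2,
             2 * u[, 1] * u[, 2], 2 * u[, 1] * u[, 3], 2 * u[, 2] * u[, 3])
  d <- as.numeric(A %*% saupe)
  if (noise > 0) d <- d * (1 + rnorm(length(d), 0, noise))
  data.frame(i = b$i[sel], j = b$j[sel], d_obs = d)
}
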