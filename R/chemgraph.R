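#' @useDynLib ringconf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif t.test setNames
#' @importFrom utils head read.table write.table
NULL

# Elements the force field can parameterize.
FF_ELEMENTS <- c("H", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

ELEMENT_DATA <- data.frame(
  element = FF_ELEMENTS,
  rcov = c(0.32, 0.77, 0.70, 0.66, 1.10, 1.04, 0.64, 0.99, 1.14, 1.33),
  rvdw = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98),
  eps  = c(0.02, 0.07, 0.12, 0.12, 0.20, 0.20, 0.15, 0.20, 0.25, 0.30),
  en   = c(2.20, 2.55, 3.04, 3.44, 2.19, 2.58, 3.98, 3.16, 2.96, 2.66),
  valence = c(1, 4, 3, 2, 3, 2, 1, 1, 1, 1),
  stringsAsFactors = FALSE
)

#' Construct a molecular graph
#'
#' The central container: an atom table, a bond table and recorded
#' stereochemistry, plus cached ring perception. Hydrogens are explicit atoms.
#'
#' @param atoms data.frame with columns `element` (symbol) and optionally
#'   `charge` (formal charge, default 0).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2 or 3; aromatic input bonds should be kekulized upstream).
#' @param xyz optional N x 3 coordinate matrix (Angstrom); may be `NULL` for
#'   purely topological graphs.
#' @param stereo optional list of stereo records (see [record_stereo()]).
#' @param source_format one of `"smiles"`, `"sdf"`, `"mol2"`, `"built"`.
#' @return object of class `mol_graph`
#' @export
mol_graph <- function(atoms, bonds, xyz = NULL, stereo = list(),
                      source_format = "built") {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      stringsAsFactors = FALSE)
  n <- nrow(atoms)
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.integer(bonds$order))
  if (nrow(bonds) && (max(bonds$i, bonds$j) > n || min(bonds$i, bonds$j) < 1))
    stop("bond references an invalid atom index")
  if (any(bonds$i == bonds$j)) stop("self-bond not allowed")
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    stopifnot(nrow(xyz) == n, ncol(xyz) == 3)
    dimnames(xyz) <- NULL
  }
  m <- structure(list(atoms = atoms, bonds = bonds, xyz = xyz,
                      stereo = stereo, source_format = source_format),
                 class = "mol_graph")
  m$rings <- perceive_rings_internal(m)
  m
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms (%d heavy), %d bonds, %s coordinates\n",
              nrow(x$atoms), sum(x$atoms$element != "H"), nrow(x$bonds),
              if (is.null(x$xyz)) "no" else "with"))
  rs <- x$rings
  cat(sprintf("  ring bonds: %d; macrocyclic bonds: %d\n",
              sum(rs$bond_ring_size > 0), sum(rs$bond_ring_size >= 9)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

heavy_atoms <- function(mol) which(mol$atoms$element != "H")

#' Adjacency helpers
#' @noRd
neighbors_of <- function(mol, i) {
  b <- mol$bonds
  c(b$j[b$i == i], b$i[b$j == i])
}

bond_order_between <- function(mol, i, j) {
  b <- mol$bonds
  k <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))
  if (!length(k)) return(0L)
  b$order[k[1]]
}

mol_igraph <- function(mol, heavy_only = FALSE) {
  b <- mol$bonds
  if (heavy_only) {
    hv <- heavy_atoms(mol)
    keep <- b$i %in% hv & b$j %in% hv
    b <- b[keep, , drop = FALSE]
    idx <- match(seq_len(n_atoms(mol)), hv)
    g <- igraph::make_empty_graph(n = length(hv), directed = FALSE)
    if (nrow(b))
      g <- igraph::add_edges(g, rbind(idx[b$i], idx[b$j]))
    igraph::V(g)$orig <- hv
    g
  } else {
    g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
    if (nrow(b)) g <- igraph::add_edges(g, rbind(b$i, b$j))
    g
  }
}

# Ring perception: for every bond, the size and atom set of its smallest
# enclosing ring (0 / empty when acyclic). The smallest ring through bond
# (i, j) is the shortest i--j path in the graph with that edge deleted.
perceive_rings_internal <- function(mol) {
  g <- mol_igraph(mol)
  nb <- nrow(mol$bonds)
  ring_size <- integer(nb)
  ring_atoms <- vector("list", nb)
  for (e in seq_len(nb)) {
    i <- mol$bonds$i[e]; j <- mol$bonds$j[e]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j))
    p <- as.integer(sp$vpath[[1]])
    if (length(p) >= 2) {
      ring_size[e] <- length(p)
      ring_atoms[[e]] <- p
    }
  }
  list(bond_ring_size = ring_size, bond_ring_atoms = ring_atoms)
}

ring_bond_ids <- function(mol) which(mol$rings$bond_ring_size > 0)

macro_bond_ids <- function(mol) which(mol$rings$bond_ring_size >= 9)

small_ring_bond_ids <- function(mol) {
  rs <- mol$rings$bond_ring_size
  which(rs >= 3 & rs <= 8)
}

# Is atom sp2/aromatic-like (planar)?  True when the atom carries a double or
# triple bond, or is an amide/ester-conjugated nitrogen.
atom_planar <- function(mol) {
  n <- n_atoms(mol)
  planar <- logical(n)
  b <- mol$bonds
  multi <- b$order >= 2
  planar[unique(c(b$i[multi], b$j[multi]))] <- TRUE
  # amide N: N single-bonded to a carbonyl carbon
  for (a in which(mol$atoms$element == "N")) {
    for (c in neighbors_of(mol, a)) {
      if (mol$atoms$element[c] == "C" && bond_order_between(mol, a, c) == 1) {
        for (o in neighbors_of(mol, c)) {
          if (mol$atoms$element[o] %in% c("O", "S") &&
              bond_order_between(mol, c, o) == 2) planar[a] <- TRUE
        }
      }
    }
  }
  planar
}

# amide C-N bonds (N single-bonded to C which is double bonded to O/S)
amide_bond_ids <- function(mol) {
  b <- mol$bonds
  el <- mol$atoms$element
  out <- integer(0)
  for (e in seq_len(nrow(b))) {
    if (b$order[e] != 1) next
    ij <- c(b$i[e], b$j[e])
    cn <- el[ij]
    if (setequal(cn, c("C", "N"))) {
      cc <- ij[which(cn == "C")[1]]
      is_amide <- any(vapply(neighbors_of(mol, cc), function(o) {
        el[o] %in% c("O", "S") && bond_order_between(mol, cc, o) == 2
      }, logical(1)))
      if (is_amide) out <- c(out, e)
    }
  }
  out
}

#' Perceive small-ring systems
#'
#' Ring systems in which every internal bond belongs to a ring of size three
#' to eight. Connected components are taken over such bonds; macrocyclic
#' components (any bond with smallest enclosing ring of nine or more) are
#' excluded here and handled by [perceive_macrocycles()].
#'
#' @param mol a [mol_graph()]
#' @return list of `ring_system` objects with fields `atoms`, `bonds`,
#'   `planar` (per-atom flag), `fusion_atoms`, `bridge_atoms`,
#'   `is_macrocyclic`
#' @export
perceive_ring_systems <- function(mol) {
  comps <- ring_components(mol, bond_ids = small_ring_bond_ids(mol))
  out <- list()
  planar <- atom_planar(mol)
  for (cp in comps) {
    deg <- table(factor(c(mol$bonds$i[cp$bonds], mol$bonds$j[cp$bonds]),
                        levels = cp$atoms))
    # atoms in >= 2 distinct smallest rings
    ratoms <- mol$rings$bond_ring_atoms[cp$bonds]
    keys <- vapply(ratoms, function(a) paste(sort(a), collapse = ","),
                   character(1))
    uniq <- !duplicated(keys)
    cnt <- table(unlist(lapply(ratoms[uniq], unique)))
    fusion <- as.integer(names(cnt)[cnt >= 2])
    bridgeheads <- cp$atoms[deg >= 3]
    out[[length(out) + 1]] <- structure(list(
      atoms = cp$atoms, bonds = cp$bonds,
      planar = planar[cp$atoms],
      fusion_atoms = intersect(fusion, cp$atoms),
      bridge_atoms = setdiff(bridgeheads, fusion),
      is_macrocyclic = FALSE), class = "ring_system")
  }
  out
}

# connected components over the given ring bonds
ring_components <- function(mol, bond_ids = ring_bond_ids(mol)) {
  rb <- bond_ids
  if (!length(rb)) return(list())
  ratoms <- sort(unique(c(mol$bonds$i[rb], mol$bonds$j[rb])))
  g <- igraph::make_empty_graph(n = length(ratoms), directed = FALSE)
  idx <- match(seq_len(n_atoms(mol)), ratoms)
  g <- igraph::add_edges(g, rbind(idx[mol$bonds$i[rb]], idx[mol$bonds$j[rb]]))
  cm <- igraph::components(g)$membership
  lapply(seq_len(max(cm)), function(k) {
    atoms <- ratoms[cm == k]
    bonds <- rb[mol$bonds$i[rb] %in% atoms]
    list(atoms = atoms, bonds = bonds,
         is_macro = any(mol$rings$bond_ring_size[bonds] >= 9))
  })
}

#' Perceive macrocyclic systems
#'
#' A ring system is macrocyclic when it contains a bond whose smallest
#' enclosing ring has nine or more atoms. For each such system the main cycle
#' (the bridge-free cycle with the largest atom count), its ordered atom
#' sequence, its ring size, and any bridges (shortest paths shortcutting the
#' main cycle, e.g. a disulfide) are reported.
#'
#' @param mol a [mol_graph()]
#' @return list of `macrocycle` objects with fields `atoms`, `bonds`,
#'   `cycle` (ordered main-cycle atoms), `ring_size`, `bridges` (list of
#'   integer paths including both attachment atoms)
#' @export
perceive_macrocycles <- function(mol) {
  comps <- ring_components(mol)
  out <- list()
  for (cp in comps) {
    if (!cp$is_macro) next
    dec <- main_cycle_and_bridges(mol, cp)
    out[[length(out) + 1]] <- structure(list(
      atoms = cp$atoms, bonds = cp$bonds,
      cycle = dec$cycle, ring_size = length(dec$cycle),
      bridges = dec$bridges), class = "macrocycle")
  }
  out
}

#' @export
print.macrocycle <- function(x, ...) {
  cat(sprintf("<macrocycle> ring size %d, %d bridge(s), %d system atoms\n",
              x$ring_size, length(x$bridges), length(x$atoms)))
  invisible(x)
}

# Decompose a macrocyclic ring-bond subgraph into its main cycle and bridges.
# Chains between branch vertices (ring-bond degree >= 3) are enumerated; the
# cycle through chains maximizing total atom count is the main cycle, and all
# remaining chains are bridges (spec'd as the shortest shortcutting paths).
main_cycle_and_bridges <- function(mol, cp) {
  atoms <- cp$atoms
  bnd <- mol$bonds[cp$bonds, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(atoms), directed = FALSE)
  idx <- match(seq_len(n_atoms(mol)), atoms)
  g <- igraph::add_edges(g, rbind(idx[bnd$i], idx[bnd$j]))
  deg <- igraph::degree(g)
  branch <- which(deg >= 3)
  if (!length(branch)) {
    # simple cycle: order by walking
    ord <- walk_cycle(g)
    return(list(cycle = atoms[ord], bridges = list()))
  }
  # chain decomposition: maximal paths whose interior vertices have degree 2
  chains <- chain_decompose(g, branch)
  # macro-bond count along each chain (in original indexing)
  rsz <- mol$rings$bond_ring_size
  chain_macro <- vapply(chains, function(ch) {
    p <- atoms[ch$path]
    sum(vapply(seq_len(length(p) - 1), function(s) {
      e <- which((mol$bonds$i == p[s] & mol$bonds$j == p[s + 1]) |
                 (mol$bonds$i == p[s + 1] & mol$bonds$j == p[s]))
      length(e) > 0 && rsz[e[1]] >= 9
    }, logical(1)))
  }, numeric(1))
  # enumerate simple cycles in the chain graph (few chains expected); the
  # main cycle maximizes macrocyclic-bond count, then minimizes atom count
  # (so fused small rings do not divert it while bridges are excluded)
  best <- NULL
  ncand <- cycles_over_chains(chains, branch)
  for (cyc in ncand) {
    natoms <- length(unique(unlist(lapply(chains[cyc], function(ch) ch$path))))
    nmacro <- sum(chain_macro[cyc])
    score <- c(nmacro, -natoms)
    if (is.null(best) || nmacro > best$score[1] ||
        (nmacro == best$score[1] && -natoms > best$score[2]))
      best <- list(chains = cyc, n = natoms, score = score)
  }
  if (is.null(best)) {
    ord <- walk_cycle(g)
    return(list(cycle = atoms[ord], bridges = list()))
  }
  # stitch main cycle atom order from its chains
  cyc_atoms <- stitch_chains(chains[best$chains])
  bridges <- lapply(setdiff(seq_along(chains), best$chains),
                    function(k) atoms[chains[[k]]$path])
  # drop bridge chains fully inside the main cycle (possible in odd topologies)
  bridges <- Filter(function(p) !all(p %in% atoms[cyc_atoms]), bridges)
  list(cycle = atoms[cyc_atoms], bridges = bridges)
}

walk_cycle <- function(g) {
  n <- igraph::vcount(g)
  start <- 1L
  ord <- integer(0)
  prev <- -1L; cur <- start
  repeat {
    ord <- c(ord, cur)
    nxt <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
    if (!length(nxt)) break
    prev <- cur; cur <- min(nxt)
    if (cur == start) break
  }
  ord
}

chain_decompose <- function(g, branch) {
  used <- matrix(FALSE, igraph::ecount(g), 1)
  chains <- list()
  el <- igraph::as_edgelist(g, names = FALSE)
  for (b in branch) {
    for (nb in as.integer(igraph::neighbors(g, b))) {
      eid <- igraph::get_edge_ids(g, c(b, nb))
      if (used[eid]) next
      path <- c(b, nb); used[eid] <- TRUE
      prev <- b; cur <- nb
      while (!(cur %in% branch)) {
        nxt <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (!length(nxt)) break
        nxt <- nxt[1]
        eid2 <- igraph::get_edge_ids(g, c(cur, nxt))
        if (used[eid2]) break
        used[eid2] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      chains[[length(chains) + 1]] <- list(path = path,
                                           ends = c(path[1], path[length(path)]))
    }
  }
  # deduplicate reversed copies
  keys <- vapply(chains, function(ch) {
    p <- ch$path
    if (p[1] > p[length(p)] ||
        (p[1] == p[length(p)] && length(p) > 2 && p[2] > p[length(p) - 1]))
      p <- rev(p)
    paste(p, collapse = "-")
  }, character(1))
  chains[!duplicated(keys)]
}

# all chain index sets that form a simple cycle over branch vertices
cycles_over_chains <- function(chains, branch) {
  res <- list()
  nch <- length(chains)
  # self-loop chains (both ends equal) are cycles by themselves
  for (k in seq_len(nch))
    if (chains[[k]]$ends[1] == chains[[k]]$ends[2])
      res[[length(res) + 1]] <- k
  # DFS over chain graph
  recurse <- function(cur, start, usedch, visited, path) {
    for (k in seq_len(nch)) {
      if (usedch[k]) next
      e <- chains[[k]]$ends
      if (e[1] == e[2]) next
      if (e[1] == cur) nxt <- e[2]
      else if (e[2] == cur) nxt <- e[1]
      else next
      if (nxt == start && length(path) >= 1) {
        res[[length(res) + 1]] <<- sort(c(path, k))
      } else if (!(nxt %in% visited)) {
        usedch2 <- usedch; usedch2[k] <- TRUE
        recurse(nxt, start, usedch2, c(visited, nxt), c(path, k))
      }
    }
  }
  for (s in branch) recurse(s, s, rep(FALSE, nch), s, integer(0))
  res[!duplicated(res)]
}

stitch_chains <- function(chs) {
  ord <- chs[[1]]$path
  used <- c(TRUE, rep(FALSE, length(chs) - 1))
  while (any(!used)) {
    tail_v <- ord[length(ord)]
    found <- FALSE
    for (k in which(!used)) {
      p <- chs[[k]]$path
      if (p[1] == tail_v) { ord <- c(ord, p[-1]); used[k] <- TRUE; found <- TRUE; break }
      if (p[length(p)] == tail_v) { ord <- c(ord, rev(p)[-1]); used[k] <- TRUE; found <- TRUE; break }
    }
    if (!found) break
  }
  if (ord[1] == ord[length(ord)]) ord <- ord[-length(ord)]
  ord
}

#' Molecule-level macrocycle ring size
#'
#' Largest main-cycle size over all macrocyclic systems (0 when none).
#' @param mol a [mol_graph()]
#' @export
macrocycle_size <- function(mol) {
  mcs <- perceive_macrocycles(mol)
  if (!length(mcs)) return(0L)
  max(vapply(mcs, function(m) m$ring_size, integer(1)))
}

#' Total flexibility
#'
#' Exocyclic freely rotatable bonds plus single bonds within macrocyclic
#' rings that are not amide C-N bonds.
#'
#' @param mol a [mol_graph()]
#' @return integer count
#' @export
total_flexibility <- function(mol) {
  b <- mol$bonds
  el <- mol$atoms$element
  amide <- amide_bond_ids(mol)
  rs <- mol$rings$bond_ring_size
  # macrocyclic single bonds, excluding amides
  macro <- which(rs >= 9 & b$order == 1)
  macro <- setdiff(macro, amide)
  # exocyclic rotatable: non-ring single bond between heavy atoms with
  # heavy-degree > 1 on both sides, excluding amides
  hdeg <- integer(n_atoms(mol))
  for (e in seq_len(nrow(b))) {
    if (el[b$i[e]] != "H" && el[b$j[e]] != "H") {
      hdeg[b$i[e]] <- hdeg[b$i[e]] + 1L
      hdeg[b$j[e]] <- hdeg[b$j[e]] + 1L
    }
  }
  exo <- which(rs == 0 & b$order == 1 &
               el[b$i] != "H" & el[b$j] != "H" &
               hdeg[b$i] > 1 & hdeg[b$j] > 1)
  exo <- setdiff(exo, amide)
  length(macro) + length(exo)
}

#' Hydrogen-bond donors and acceptors
#'
#' Donors are polar hydrogens (attached to N, O or S); acceptors are oxygens
#' and non-amide, non-cationic nitrogens with an available lone pair.
#' N-methylated ring nitrogens contribute no donor because they carry no H.
#'
#' @param mol a [mol_graph()]
#' @return list with `donor_h` (H atom indices), `donor_heavy` (their parent
#'   atoms) and `acceptors` (heavy-atom indices)
#' @export
find_donors_acceptors <- function(mol) {
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  donor_h <- integer(0); donor_heavy <- integer(0)
  for (h in which(el == "H")) {
    nb <- neighbors_of(mol, h)
    if (length(nb) == 1 && el[nb] %in% c("N", "O", "S")) {
      donor_h <- c(donor_h, h); donor_heavy <- c(donor_heavy, nb)
    }
  }
  amide_n <- integer(0)
  for (e in amide_bond_ids(mol)) {
    ij <- c(mol$bonds$i[e], mol$bonds$j[e])
    amide_n <- c(amide_n, ij[el[ij] == "N"])
  }
  acc <- which(el == "O" & chg <= 0)
  for (a in which(el == "N" & chg <= 0)) {
    if (a %in% amide_n) next
    tot <- sum(vapply(neighbors_of(mol, a),
                      function(x) bond_order_between(mol, a, x), integer(1)))
    if (tot <= 3) acc <- c(acc, a)
  }
  list(donor_h = donor_h, donor_heavy = donor_heavy, acceptors = sort(acc))
}

#' Add missing hydrogens by standard valence
#'
#' Fills each heavy atom to its standard valence (adjusted for formal
#' charge). Added hydrogens have no coordinates; generate them with
#' [memory_free_start()] or place them before minimization.
#'
#' @param mol a [mol_graph()]
#' @return a new `mol_graph` with explicit hydrogens
#' @export
add_hydrogens <- function(mol) {
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  val <- ELEMENT_DATA$valence[match(el, ELEMENT_DATA$element)]
  need <- integer(n_atoms(mol))
  for (a in seq_len(n_atoms(mol))) {
    if (el[a] == "H" || is.na(val[a])) next  # unknown elements left as-is
    v <- val[a]
    if (el[a] == "N" && chg[a] > 0) v <- 4
    if (el[a] == "N" && chg[a] < 0) v <- 2
    if (el[a] == "O" && chg[a] < 0) v <- 1
    if (el[a] == "O" && chg[a] > 0) v <- 3
    if (el[a] %in% c("S", "P")) {
      # hypervalent S/P keep their explicit bonds only
      bsum <- sum(vapply(neighbors_of(mol, a),
                         function(x) bond_order_between(mol, a, x), integer(1)))
      v <- max(v, bsum)
    }
    bsum <- sum(vapply(neighbors_of(mol, a),
                       function(x) bond_order_between(mol, a, x), integer(1)))
    need[a] <- max(0L, as.integer(v - bsum))
  }
  if (!sum(need)) return(mol)
  atoms <- mol$atoms; bonds <- mol$bonds
  xyz <- mol$xyz
  for (a in which(need > 0)) {
    for (k in seq_len(need[a])) {
      atoms <- rbind(atoms, data.frame(element = "H", charge = 0L))
      hid <- nrow(atoms)
      bonds <- rbind(bonds, data.frame(i = a, j = hid, order = 1L))
      if (!is.null(xyz)) {
        # deterministic placement near parent; refined by minimization
        dir <- c(cos(2.399 * hid), sin(2.399 * hid), cos(1.3 * hid + 0.5))
        dir <- dir / sqrt(sum(dir^2))
        xyz <- rbind(xyz, xyz[a, ] + dir)
      }
    }
  }
  mol_graph(atoms, bonds, xyz = xyz, stereo = mol$stereo,
            source_format = mol$source_format)
}

#' Graph automorphisms of the heavy-atom skeleton
#'
#' Enumerates automorphisms of the heavy-atom bond graph colored by element,
#' extended to full-molecule index maps (hydrogens map by parent, first
#' available assignment). Used for symmetry-corrected RMSD.
#'
#' @param mol a [mol_graph()]
#' @param cap maximum number of automorphisms to enumerate
#' @return integer matrix, one row per automorphism, column a = image of atom a
#' @export
mol_automorphisms <- function(mol, cap = 10000) {
  hv <- heavy_atoms(mol)
  g <- mol_igraph(mol, heavy_only = TRUE)
  col <- as.integer(factor(paste(mol$atoms$element[hv], mol$atoms$charge[hv])))
  iso <- igraph::isomorphisms(g, g, method = "vf2", vertex.color1 = col,
                              vertex.color2 = col)
  if (length(iso) > cap) iso <- iso[seq_len(cap)]
  n <- n_atoms(mol)
  # parent of each hydrogen
  hpar <- integer(n)
  for (h in which(mol$atoms$element == "H")) {
    nb <- neighbors_of(mol, h)
    hpar[h] <- if (length(nb)) nb[1] else 0L
  }
  hyd_by_parent <- split(which(hpar > 0), hpar[hpar > 0])
  maps <- matrix(0L, length(iso), n)
  for (k in seq_along(iso)) {
    perm <- seq_len(n)
    img <- as.integer(iso[[k]])
    perm[hv] <- hv[img]
    # hydrogens follow their parents; within a parent, keep listed order
    for (p in names(hyd_by_parent)) {
      hs <- hyd_by_parent[[p]]
      tgt_parent <- perm[as.integer(p)]
      tg <- hyd_by_parent[[as.character(tgt_parent)]]
      if (!is.null(tg) && length(tg) == length(hs)) perm[hs] <- tg
    }
    maps[k, ] <- perm
  }
  maps[!duplicated(maps), , drop = FALSE]
}

# iterative neighborhood-refinement codes (Morgan-like); two atoms share a
# code only if their environments are indistinguishable at the given depth
atom_env_codes <- function(mol, iters = 6) {
  code <- as.integer(factor(paste(mol$atoms$element, mol$atoms$charge)))
  for (it in seq_len(iters)) {
    sig <- vapply(seq_len(n_atoms(mol)), function(a) {
      nb <- sort(code[neighbors_of(mol, a)])
      paste(code[a], paste(nb, collapse = ","), sep = "|")
    }, character(1))
    code <- as.integer(factor(sig))
  }
  code
}

#' Record stereochemistry from 3D coordinates
#'
#' Notes tetrahedral configurations (signed volume over the first three
#' neighbors) and double-bond configurations (torsion sign) so they can be
#' enforced and verified during search. Records are taken before any
#' coordinate zeroing and are immutable during search.
#'
#' @param mol a [mol_graph()] with coordinates
#' @return list of stereo records, each `list(kind, atoms, config)`
#' @export
record_stereo <- function(mol) {
  if (is.null(mol$xyz)) return(list())
  el <- mol$atoms$element
  out <- list()
  codes <- atom_env_codes(mol)
  for (a in which(el != "H")) {
    nb <- neighbors_of(mol, a)
    if (length(nb) != 4) next
    # genuine stereocenter: all four substituents topologically distinct
    # (equivalent substituents, e.g. two hydrogens, make the signed volume
    # arbitrary and unenforceable)
    if (length(unique(codes[nb])) < 4) next
    nb <- sort(nb)
    v <- chir_volume_cpp(mol$xyz, a, nb[1], nb[2], nb[3])
    if (abs(v) > 0.05)
      out[[length(out) + 1]] <- list(kind = "tetrahedral",
                                     atoms = c(a, nb[1:3]),
                                     config = sign(v))
  }
  for (e in which(mol$bonds$order == 2)) {
    i <- mol$bonds$i[e]; j <- mol$bonds$j[e]
    if (mol$rings$bond_ring_size[e] > 0 && mol$rings$bond_ring_size[e] <= 8) next
    ni <- setdiff(neighbors_of(mol, i), j)
    nj <- setdiff(neighbors_of(mol, j), i)
    ni <- ni[el[ni] != "H"]; nj <- nj[el[nj] != "H"]
    if (!length(ni) || !length(nj)) next
    phi <- torsion_angle_cpp(mol$xyz, min(ni), i, j, min(nj))
    out[[length(out) + 1]] <- list(kind = "double_bond",
                                   atoms = c(min(ni), i, j, min(nj)),
                                   config = if (abs(phi) > pi / 2) "E" else "Z")
  }
  out
}
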