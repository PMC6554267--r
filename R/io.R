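#' Read a molecule into a molecular graph
#'
#' SMILES strings are parsed through Open Babel (kekulized, 2D-free); SDF
#' (V2000) files through ChemmineR; mol2 files through bio3d. Hydrogens are
#' added by standard-valence protonation when absent, and stereochemistry is
#' recorded from 3D coordinates when present.
#'
#' @param x a SMILES string, or a path to an `.sdf`/`.mol`/`.mol2` file
#' @param format one of `"auto"`, `"smiles"`, `"sdf"`, `"mol2"`
#' @param protonate add missing hydrogens (default `TRUE`)
#' @param gen3d for SMILES input, build a 3D structure (Open Babel) so that
#'   stereochemistry can be noted; conformational search itself never reads
#'   these coordinates (starts are memory-free)
#' @return a [mol_graph()]
#' @export
read_mol <- function(x, format = c("auto", "smiles", "sdf", "mol2"),
                     protonate = TRUE, gen3d = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(x)) {
      if (grepl("\\.mol2$", x, ignore.case = TRUE)) "mol2" else "sdf"
    } else "smiles"
  }
  mol <- switch(format,
                smiles = read_smiles(x, gen3d = gen3d),
                sdf = read_sdf_file(x),
                mol2 = read_mol2_file(x))
  bad <- setdiff(unique(mol$atoms$element), FF_ELEMENTS)
  if (length(bad))
    warning(sprintf("elements outside force-field coverage: %s",
                    paste(bad, collapse = ", ")))
  if (protonate) mol <- add_hydrogens(mol)
  if (!is.null(mol$xyz) && !any(is.na(mol$xyz)) && sum(abs(mol$xyz)) > 0)
    mol$stereo <- record_stereo(mol)
  mol
}

read_smiles <- function(smi, gen3d = FALSE) {
  txt <- if (gen3d)
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"),
                              options = data.frame(names = "gen3D", args = ""))
  else
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))
  parse_sdf_text(strsplit(txt, "\n")[[1]], source_format = "smiles")
}

read_sdf_file <- function(path) {
  parse_sdf_text(readLines(path), source_format = "sdf")
}

# Structural fields come from ChemmineR's reader; formal charges additionally
# from M CHG lines (ChemmineR folds them into the atom block numerically).
parse_sdf_text <- function(lines, source_format = "sdf") {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sdfs <- ChemmineR::read.SDFset(tf)
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  xyz <- ab[, 1:3, drop = FALSE]
  charges <- integer(length(el))
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (s in seq_len(k)) charges[f[2 * s]] <- f[2 * s + 1]
  }
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  # 2D depictions (flat z) carry no conformational information: drop them so
  # stereo is never recorded from them and starts stay memory-free
  has_3d <- nrow(xyz) > 0 && diff(range(xyz[, 3])) > 1e-6
  mol_graph(data.frame(element = el, charge = charges),
            bonds, xyz = if (has_3d) xyz else NULL,
            source_format = source_format)
}

read_mol2_file <- function(path) {
  m2 <- bio3d::read.mol2(path)
  at <- m2$atom
  el <- sub("\\..*$", "", at$elety)
  el <- paste0(toupper(substring(el, 1, 1)), tolower(substring(el, 2)))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  bd <- m2$bond
  ord <- bd$type
  ord[ord %in% c("ar", "am")] <- "1"   # kekulization not attempted; aromatic
  ord <- as.integer(ord)               # rings read as single + planar flags
  bonds <- data.frame(i = as.integer(bd$origin), j = as.integer(bd$target),
                      order = ord)
  mol_graph(data.frame(element = el, charge = 0L), bonds, xyz = xyz,
            source_format = "mol2")
}

#' Write a conformer ensemble to an SDF (V2000) file
#'
#' One record per conformer with energy, relative energy, violation energy
#' and move provenance as data fields.
#'
#' @param ensemble a `conformer_ensemble` (see [assemble_ensemble()]) or a
#'   list of conformers
#' @param mol the [mol_graph()] the conformers belong to
#' @param path output file
#' @param name molecule title
#' @export
write_ensemble_sdf <- function(ensemble, mol, path, name = "ringconf") {
  confs <- if (inherits(ensemble, "conformer_ensemble")) ensemble$conformers
           else ensemble
  emin <- if (length(confs)) min(vapply(confs, function(cf) cf$energy,
                                        numeric(1))) else 0
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(confs)) {
    cf <- confs[[k]]
    writeLines(sdf_record(mol, cf$xyz, sprintf("%s_%d", name, k)), con)
    writeLines(sprintf(">  <energy_kcal_mol>\n%.4f\n", cf$energy), con)
    writeLines(sprintf(">  <relative_energy_kcal_mol>\n%.4f\n",
                       cf$energy - emin), con)
    writeLines(sprintf(">  <violation_energy_kcal_mol>\n%.4f\n",
                       if (is.null(cf$violation_energy)) 0
                       else cf$violation_energy), con)
    writeLines(sprintf(">  <provenance>\n%s\n",
                       paste(cf$provenance, collapse = ";")), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

sdf_record <- function(mol, xyz, title) {
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  out <- c(title, "  ringconf", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n)) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          xyz[a, 1], xyz[a, 2], xyz[a, 3], mol$atoms$element[a]))
  }
  for (e in seq_len(nb)) {
    out <- c(out, sprintf("%3d%3d%3d  0", mol$bonds$i[e], mol$bonds$j[e],
                          mol$bonds$order[e]))
  }
  chg <- which(mol$atoms$charge != 0)
  if (length(chg))
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(chg)),
                         paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]),
                                collapse = "")))
  c(out, "M  END")
}
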