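# Shared fixtures and a session cache so expensive searches run once per
# test session and are reused across test files.

.ringconf_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .ringconf_cache)) {
    assign(name, force(expr), envir = .ringconf_cache)
  }
  get(name, envir = .ringconf_cache)
}

fix_cyclohexane <- function() cached("cyclohexane", make_cycloalkane(6))
fix_cyclodecane <- function() cached("cyclodecane", make_cycloalkane(10))
fix_benzene <- function() cached("benzene", read_mol(fixture_smiles$benzene))
fix_decalin <- function() cached("decalin", read_mol(fixture_smiles$decalin))
fix_tetracycline <- function()
  cached("tetracycline", make_tetracycline())

# toy cyclic peptides
fix_hexapeptide <- function()
  cached("hexapeptide", make_cyclic_peptide(peptide_spec(6)))
fix_ala_hexapeptide <- function()
  cached("ala_hexapeptide",
         make_cyclic_peptide(peptide_spec(6, sidechains = "methyl")))
fix_aba_like <- function()
  cached("aba_like", make_cyclic_peptide(peptide_spec(
    9, sidechains = "methyl", n_methyl = c(2, 4, 6, 8), proline = 5,
    ester = 1)))
fix_kel_like <- function()
  cached("kel_like", make_cyclic_peptide(peptide_spec(
    14, sidechains = "H", disulfide = c(3, 12))))

# full ring searches shared between acceptance and property tests
cyclodecane_pool <- function() cached("cyclodecane_pool", {
  mol <- fix_cyclodecane()
  st <- memory_free_start(mol, seed = 1)
  ring_search(mol, st, search_config("pgeom", seed = 1, max_rounds = 30))
})

tetracycline_pool <- function() cached("tetracycline_pool", {
  mol <- fix_tetracycline()
  st <- memory_free_start(mol, seed = 1)
  # run to convergence: the bend search terminates well before this cap
  ring_search(mol, st, search_config("pgeom", seed = 1, max_rounds = 30))
})

# small shallow config for peptide-scale tests
shallow_config <- function(...) {
  search_config("pfast", max_conformers = 25, max_rounds = 2,
                minimize_maxit = 700, ...)
}
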