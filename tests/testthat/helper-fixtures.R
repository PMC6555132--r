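# Shared fixtures: tiny molecules and models built in code.

mol_benzene <- function() parse_smiles("c1ccccc1", id = "benzene")
mol_toluene <- function() parse_smiles("Cc1ccccc1", id = "toluene")
mol_methylammonium <- function() parse_smiles("C[NH3+]", id = "mma")
mol_acetamidine <- function() parse_smiles("CC(=N)N", id = "acetamidine")

# give a 2D-less molecule a flat deterministic conformer (chain layout);
# good enough for feature-geometry tests that only need *some* coordinates
with_chain_conformer <- function(mol) {
  n <- nrow(mol$atoms)
  mol$confs <- list(cbind(1.5 * seq_len(n), rep(0, n), rep(0, n)))
  mol
}

# minimal two-feature model: PI at origin, HYD at distance d on x
model_pi_hyd <- function(d = 3.7, tol = 1.6) {
  pharmacophore("pi-hyd", tibble::tibble(
    kind = c("PI", "HYD"), x = c(0, d), y = 0, z = 0, tol = tol, weight = 1))
}

# a molecule whose conformer carries a PI (charged N) and one C2 hydrophobe
# with feature positions exactly at the given points
mol_pi_hyd_ligand <- function(pi_pos = c(0, 0, 0), hyd_pos = c(3.7, 0, 0),
                              id = "lig") {
  u <- c(0, 1, 0)
  b <- hyd_pos + 0.75 * u
  cc <- hyd_pos - 0.75 * u
  new_molecule(
    id,
    atoms = tibble::tibble(element = c("N", "C", "C"),
                           charge = c(1L, 0L, 0L), nH = NA_integer_),
    bonds = tibble::tibble(a1 = 2L, a2 = 3L, order = 1L),
    confs = list(rbind(pi_pos, b, cc)))
}

expect_feature_counts <- function(feats, ...) {
  want <- list(...)
  for (k in names(want)) {
    testthat::expect_equal(sum(feats$kind == k), want[[k]],
                           info = paste("feature kind", k))
  }
}
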