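#' Interaction rules for structure-derived model generation
#'
#' Standard literature cutoffs, all overridable: an ionic contact keeps a
#' PI feature when a deprotonated acidic receptor atom lies within
#' `ionic_max` of it; a hydrophobe survives when at least `n_apolar`
#' apolar receptor heavy atoms lie within `hydrophobic_max`; hydrogen
#' bonds require donor-acceptor distance within `hbond_max` and an
#' approach angle of at least `hbond_min_angle` degrees at the ligand
#' atom; aromatic stacking requires a receptor ring centroid within
#' `stacking_max`. Excluded volumes of radius `exclusion_radius` are
#' placed on receptor heavy atoms within `pocket_shell` of any ligand
#' atom that are not part of a kept interaction.
#'
#' @param ionic_max,hydrophobic_max,hbond_max,stacking_max distance
#'   cutoffs (Angstrom).
#' @param n_apolar minimum apolar receptor atoms for a hydrophobic
#'   contact.
#' @param hbond_min_angle minimum hydrogen-bond angle (degrees).
#' @param pocket_shell receptor shell around the ligand considered for
#'   excluded volumes (Angstrom).
#' @param exclusion_radius radius of placed excluded volumes (Angstrom).
#' @param feature_tol,projection_tol tolerances given to the derived
#'   features and their projections.
#' @return a list of rule parameters.
#' @export
interaction_rules <- function(ionic_max = 4.0, hydrophobic_max = 4.5,
                              n_apolar = 3, hbond_max = 3.5,
                              hbond_min_angle = 120, stacking_max = 5.0,
                              pocket_shell = 5.0, exclusion_radius = 1.2,
                              feature_tol = 1.6, projection_tol = 2.2) {
  as.list(environment())
}

.ACIDIC_O_NAMES <- c("OE1", "OE2", "OD1", "OD2")
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

.receptor_ring_centroids <- function(protein) {
  out <- list()
  for (rn in names(.RING_ATOMS)) {
    sub <- protein[protein$resname == rn, ]
    if (nrow(sub) == 0) next
    for (rid in unique(sub$resid)) {
      ring <- sub[sub$resid == rid & sub$atom_name %in% .RING_ATOMS[[rn]], ]
      if (nrow(ring) >= 5)
        out[[length(out) + 1]] <- colMeans(as.matrix(ring[, c("x", "y", "z")]))
    }
  }
  out
}

#' Derive a pharmacophore from a protein-ligand complex
#'
#' Implements receptor-ligand pharmacophore generation: (1) all ligand
#' features are perceived on the bound conformer; (2) a feature is kept
#' only when an interaction rule fires against the receptor (ionic for
#' PI, apolar-contact count for HYD, distance-plus-angle hydrogen bonds
#' for HBA/HBD, ring-centroid stacking for AR); (3) excluded volumes are
#' placed on receptor heavy atoms lining the pocket that do not belong
#' to a kept interaction. Both structures must be in one coordinate
#' frame. The output is equivariant under rigid motion of the whole
#' complex.
#'
#' @param protein receptor atom tibble (`element`, `x`, `y`, `z`,
#'   `resname`, `resid`, `atom_name`, `charge`), e.g. from
#'   [read_pdb_atoms()] or [generate_toy_complex()].
#' @param ligand a `phmol` with the bound conformer.
#' @param rules an [interaction_rules()] list.
#' @param conf ligand conformer index.
#' @param name name of the derived model.
#' @return a `pharmacophore`.
#' @export
derive_pharmacophore <- function(protein, ligand, rules = interaction_rules(),
                                 conf = 1, name = "derived") {
  res <- derive_interaction_features(protein, ligand, rules, conf)
  if (nrow(res$features) < 2)
    abort(paste("only one interaction detected; a pharmacophore needs at",
                "least two features"))
  pharmacophore(name, res$features, res$exclusions, max_omitted = 0,
                provenance = "derived from a receptor-ligand complex")
}

#' @rdname derive_pharmacophore
#' @return `derive_interaction_features` returns the pruning result
#'   before model assembly: a list with `features` (kept feature tibble)
#'   and `exclusions`.
#' @export
derive_interaction_features <- function(protein, ligand,
                                        rules = interaction_rules(),
                                        conf = 1) {
  protein <- as_tibble(protein)
  if (is.null(protein$charge)) protein$charge <- 0L
  feats <- perceive_features(ligand, conf)
  if (nrow(feats) == 0) abort("no interactions detected")
  pxyz <- as.matrix(protein[, c("x", "y", "z")])
  lig_xyz <- ligand$confs[[conf]]
  nb <- neighbors_of(ligand)
  apolar_rec <- protein$element %in% c("C", "S")
  acidic_rec <- protein$charge < 0 |
    (protein$element == "O" & protein$resname %in% c("GLU", "ASP") &
       protein$atom_name %in% .ACIDIC_O_NAMES)
  donor_rec <- protein$element == "N"
  acceptor_rec <- protein$element %in% c("O", "N")
  ring_cents <- .receptor_ring_centroids(protein)
  partner_atoms <- integer(0)
  kept <- list()
  dist_to <- function(pos) sqrt(colSums((t(pxyz) - pos)^2))
  angle_ok <- function(fi, partner_pos) {
    atoms <- feats$source_atoms[[fi]]
    a <- atoms[1]
    nbrs <- nb[[a]]
    if (length(nbrs) == 0) return(TRUE)
    ncen <- colMeans(lig_xyz[nbrs, , drop = FALSE])
    v1 <- ncen - lig_xyz[a, ]
    v2 <- partner_pos - lig_xyz[a, ]
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ang >= rules$hbond_min_angle
  }
  for (i in seq_len(nrow(feats))) {
    pos <- c(feats$x[i], feats$y[i], feats$z[i])
    d <- dist_to(pos)
    keep <- FALSE; partners <- integer(0); proj_target <- NULL
    if (feats$kind[i] == "PI") {
      hit <- which(acidic_rec & d <= rules$ionic_max)
      if (length(hit) > 0) { keep <- TRUE; partners <- hit }
    } else if (feats$kind[i] == "HYD") {
      hit <- which(apolar_rec & d <= rules$hydrophobic_max)
      if (length(hit) >= rules$n_apolar) { keep <- TRUE; partners <- hit }
    } else if (feats$kind[i] == "HBA") {
      hit <- which(donor_rec & d <= rules$hbond_max)
      hit <- hit[vapply(hit, function(h) angle_ok(i, pxyz[h, ]), logical(1))]
      if (length(hit) > 0) {
        keep <- TRUE; partners <- hit[which.min(d[hit])]
        proj_target <- pxyz[partners[1], ]
      }
    } else if (feats$kind[i] == "HBD") {
      hit <- which(acceptor_rec & d <= rules$hbond_max)
      hit <- hit[vapply(hit, function(h) angle_ok(i, pxyz[h, ]), logical(1))]
      if (length(hit) > 0) {
        keep <- TRUE; partners <- hit[which.min(d[hit])]
        proj_target <- pxyz[partners[1], ]
      }
    } else if (feats$kind[i] == "AR") {
      for (rc in ring_cents) {
        if (sqrt(sum((rc - pos)^2)) <= rules$stacking_max) {
          keep <- TRUE
          proj_target <- rc
          break
        }
      }
    }
    if (keep) {
      row <- tibble(kind = feats$kind[i], x = pos[1], y = pos[2], z = pos[3],
                    tol = rules$feature_tol, weight = 1,
                    px = NA_real_, py = NA_real_, pz = NA_real_,
                    ptol = NA_real_, pconstrained = NA)
      if (!is.null(proj_target)) {
        row$px <- proj_target[1]; row$py <- proj_target[2]
        row$pz <- proj_target[3]
        row$ptol <- rules$projection_tol; row$pconstrained <- TRUE
      }
      kept[[length(kept) + 1]] <- row
      partner_atoms <- c(partner_atoms, partners)
    }
  }
  if (length(kept) == 0) abort("no interactions detected")
  features <- bind_rows(kept)
  # pocket shell: receptor heavy atoms near any ligand atom, minus the
  # partners of kept interactions
  min_d_lig <- apply(pxyz, 1, function(p)
    min(sqrt(rowSums(sweep(lig_xyz, 2, p)^2))))
  shell <- which(protein$element != "H" & min_d_lig <= rules$pocket_shell)
  shell <- setdiff(shell, unique(partner_atoms))
  exclusions <- if (length(shell) > 0) {
    tibble(x = pxyz[shell, 1], y = pxyz[shell, 2], z = pxyz[shell, 3],
           radius = rules$exclusion_radius)
  } else {
    tibble(x = double(), y = double(), z = double(), radius = double())
  }
  list(features = features, exclusions = exclusions)
}

#' Read protein atoms from a PDB file
#'
#' Thin wrapper around `bio3d::read.pdb` producing the atom tibble
#' consumed by [derive_pharmacophore()].
#'
#' @param path PDB file.
#' @return tibble with columns `element`, `x`, `y`, `z`, `resname`,
#'   `resid`, `atom_name`, `charge`.
#' @export
read_pdb_atoms <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(el)))
    el <- substr(trimws(at$elety), 1, 1)
  tibble(element = trimws(el), x = at$x, y = at$y, z = at$z,
         resname = trimws(at$resid), resid = at$resno,
         atom_name = trimws(at$elety), charge = 0L)
}
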