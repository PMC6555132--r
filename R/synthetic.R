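#' Seeded synthetic ligand library built on a pharmacophore
#'
#' Constructs a benchmark library with known ground truth, standing in
#' for a proprietary screening collection. Actives are built
#' fragment-on-scaffold: a feature-bearing fragment is posed at each
#' model feature center (protonated amine for PI, short alkyl group for
#' HYD, benzene ring for AR/HYD_AR, imine nitrogen or ether oxygen for
#' HBA, amine N-H for HBD), jittered by an isotropic Gaussian of
#' `jitter_sd`, and fragments are joined through ether-oxygen bridge
#' atoms so hydrophobe perception keeps the groups distinct. The
#' resulting geometries are idealized poses, not force-field minima:
#' they guarantee ground truth for matcher benchmarking, not
#' synthesizability.
#'
#' Decoys violate the model per `decoy_mode`: `missing_feature` drops
#' one fragment per decoy (cycling over features), `shuffled_geometry`
#' rescales the feature distances so no assignment survives pairwise
#' pruning, `clashing` adds a detached carbon atom inside an excluded
#' volume. Every decoy is verified against the model after construction;
#' actives at the default jitter keep each feature well inside its
#' tolerance sphere.
#'
#' @param model a `pharmacophore`.
#' @param n_actives,n_decoys library composition.
#' @param jitter_sd Gaussian placement noise for actives, Angstrom
#'   (default 0.4).
#' @param decoy_mode decoy construction mode.
#' @param seed integer seed; the library is bit-reproducible given the
#'   seed.
#' @return library tibble with columns `id`, `mol`, `n_conformers`,
#'   `label` (`active`/`inactive`), `ki_nM` and `inhib_pct_1uM`
#'   (synthetic annotations consistent with the label).
#' @export
generate_ligand_library <- function(model, n_actives, n_decoys,
                                    jitter_sd = 0.4,
                                    decoy_mode = c("missing_feature",
                                                   "shuffled_geometry",
                                                   "clashing"),
                                    seed = 1) {
  decoy_mode <- match.arg(decoy_mode)
  mf <- model$features
  if (!any(mf$kind %in% c("PI", "HYD", "HYD_AR", "AR")))
    abort("no fragment vocabulary for this model (no PI/HYD/AR features)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_actives)) {
    m <- .build_posed_molecule(model, jitter_sd, drop_feature = NA,
                               id = sprintf("ACT%04d", i))
    rows[[length(rows) + 1]] <- tibble(
      id = m$id, mol = list(m), n_conformers = 1L, label = "active",
      ki_nM = round(stats::runif(1, 5, 900), 1), inhib_pct_1uM = NA_real_)
  }
  defs <- model_feature_definitions(model)
  for (i in seq_len(n_decoys)) {
    id <- sprintf("DEC%04d", i)
    ok <- FALSE
    for (try in 1:25) {
      m <- switch(decoy_mode,
        missing_feature = .build_posed_molecule(
          model, jitter_sd, drop_feature = (i + try - 2) %% nrow(mf) + 1,
          id = id),
        shuffled_geometry = .build_scaled_molecule(model, jitter_sd, id),
        clashing = .build_clashing_molecule(model, jitter_sd, id))
      sr <- screen_library(tibble(id = id, mol = list(m)), model,
                           mode = "rigid", defs = defs)
      if (!sr$qualifies[1]) { ok <- TRUE; break }
    }
    if (!ok) abort(sprintf("could not construct a non-matching decoy (%s)",
                           decoy_mode))
    rows[[length(rows) + 1]] <- tibble(
      id = id, mol = list(m), n_conformers = 1L, label = "inactive",
      ki_nM = NA_real_, inhib_pct_1uM = round(stats::runif(1, 0, 45), 1))
  }
  bind_rows(rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# unit vector orthogonal-ish to v, deterministic
.perp_unit <- function(v) {
  b <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- c(v[2] * b[3] - v[3] * b[2],
         v[3] * b[1] - v[1] * b[3],
         v[1] * b[2] - v[2] * b[1])
  n <- sqrt(sum(p^2))
  if (n < 1e-9) return(c(0, 0, 1))
  p / n
}

# one fragment posed at a target point; returns atoms/bonds/coords local
# to the fragment plus the index (within the fragment) of the linker
# connection atom and of the feature anchor
.make_fragment <- function(kind, target, next_dir, model_row) {
  if (kind == "PI") {
    return(list(atoms = tibble(element = "N", charge = 1L, nH = NA_integer_),
                bonds = tibble(a1 = integer(), a2 = integer(),
                               order = integer()),
                coords = rbind(target), connect = 1L))
  }
  if (kind == "HYD") {
    u <- .perp_unit(next_dir)
    b <- target + 0.75 * u
    cc <- target - 0.75 * u
    a <- b + 1.45 * next_dir
    return(list(atoms = tibble(element = c("C", "C", "C"), charge = 0L,
                               nH = NA_integer_),
                bonds = tibble(a1 = c(1L, 2L), a2 = c(2L, 3L),
                               order = c(1L, 1L)),
                coords = rbind(a, b, cc), connect = 1L))
  }
  if (kind %in% c("AR", "HYD_AR")) {
    # benzene; ring normal toward the model projection point when present
    nrm <- if (!is.na(model_row$px)) {
      v <- c(model_row$px - target[1], model_row$py - target[2],
             model_row$pz - target[3])
      v / sqrt(sum(v^2))
    } else .perp_unit(next_dir)
    e1 <- .perp_unit(nrm)
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    ang <- 2 * pi * (0:5) / 6
    coords <- t(vapply(ang, function(a)
      target + 1.39 * (cos(a) * e1 + sin(a) * e2), numeric(3)))
    return(list(atoms = tibble(element = rep("C", 6), charge = 0L,
                               nH = NA_integer_),
                bonds = tibble(a1 = 1:6, a2 = c(2:6, 1L),
                               order = c(2L, 1L, 2L, 1L, 2L, 1L)),
                coords = coords, connect = 1L))
  }
  if (kind == "HBA") {
    # imine C=N when the acceptor must be a nitrogen, ether O otherwise
    accept <- model_row$accept_elements[[1]]
    proj_dir <- if (!is.na(model_row$px)) {
      v <- c(model_row$px - target[1], model_row$py - target[2],
             model_row$pz - target[3])
      v / sqrt(sum(v^2))
    } else .perp_unit(next_dir)
    partner <- target - 1.43 * proj_dir  # neighbor opposite the lone pair
    if (!is.null(accept) && "N" %in% accept) {
      return(list(atoms = tibble(element = c("N", "C"), charge = 0L,
                                 nH = NA_integer_),
                  bonds = tibble(a1 = 1L, a2 = 2L, order = 2L),
                  coords = rbind(target, partner), connect = 2L))
    }
    return(list(atoms = tibble(element = c("O", "C"), charge = 0L,
                               nH = NA_integer_),
                bonds = tibble(a1 = 1L, a2 = 2L, order = 1L),
                coords = rbind(target, partner), connect = 2L))
  }
  if (kind == "HBD") {
    proj_dir <- if (!is.na(model_row$px)) {
      v <- c(model_row$px - target[1], model_row$py - target[2],
             model_row$pz - target[3])
      v / sqrt(sum(v^2))
    } else .perp_unit(next_dir)
    partner <- target - 1.45 * proj_dir
    return(list(atoms = tibble(element = c("N", "C"), charge = 0L,
                               nH = NA_integer_),
                bonds = tibble(a1 = 1L, a2 = 2L, order = 1L),
                coords = rbind(target, partner), connect = 2L))
  }
  abort(sprintf("no fragment vocabulary for feature kind %s", kind))
}

.assemble_molecule <- function(frags, id, extra_atoms = NULL) {
  atoms <- tibble(element = character(), charge = integer(), nH = integer())
  bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  coords <- NULL
  offsets <- integer(length(frags))
  for (k in seq_along(frags)) {
    offsets[k] <- nrow(atoms)
    fr <- frags[[k]]
    bonds <- bind_rows(bonds, mutate(fr$bonds, a1 = .data$a1 + offsets[k],
                                     a2 = .data$a2 + offsets[k]))
    atoms <- bind_rows(atoms, fr$atoms)
    coords <- rbind(coords, fr$coords)
  }
  # ether-oxygen bridges between consecutive fragments keep the molecule
  # connected without merging apolar groups
  for (k in seq_len(length(frags) - 1)) {
    c1 <- offsets[k] + frags[[k]]$connect
    c2 <- offsets[k + 1] + frags[[k + 1]]$connect
    op <- (coords[c1, ] + coords[c2, ]) / 2
    atoms <- bind_rows(atoms, tibble(element = "O", charge = 0L,
                                     nH = 0L))
    coords <- rbind(coords, op)
    oi <- nrow(atoms)
    bonds <- bind_rows(bonds, tibble(a1 = c(c1, oi), a2 = c(oi, c2),
                                     order = 1L))
  }
  if (!is.null(extra_atoms)) {
    atoms <- bind_rows(atoms, extra_atoms$atoms)
    coords <- rbind(coords, extra_atoms$coords)
  }
  rownames(coords) <- NULL
  new_molecule(id, atoms, bonds, confs = list(unname(as.matrix(coords))))
}

.build_posed_molecule <- function(model, jitter_sd, drop_feature, id) {
  mf <- model$features
  keep <- seq_len(nrow(mf))
  if (!is.na(drop_feature)) keep <- setdiff(keep, drop_feature)
  centers <- as.matrix(mf[, c("x", "y", "z")])
  frags <- list()
  for (k in keep) {
    target <- centers[k, ] + stats::rnorm(3, 0, jitter_sd)
    nxt <- if (k < nrow(mf)) centers[min(k + 1, nrow(mf)), ] else
      centers[max(k - 1, 1), ]
    dirv <- nxt - centers[k, ]
    nd <- sqrt(sum(dirv^2))
    dirv <- if (nd > 1e-9) dirv / nd else c(1, 0, 0)
    frags[[length(frags) + 1]] <- .make_fragment(mf$kind[k], target, dirv,
                                                 mf[k, ])
  }
  .assemble_molecule(frags, id)
}

.build_scaled_molecule <- function(model, jitter_sd, id) {
  mf <- model$features
  d <- feature_distances(mf)
  dmin <- min(d[upper.tri(d)])
  max_tolsum <- max(outer(mf$tol, mf$tol, `+`))
  s <- 1 + (max_tolsum + 1.5) / dmin  # every pair off by > the prune bound
  scaled <- model
  cen <- colMeans(as.matrix(mf[, c("x", "y", "z")]))
  scaled$features$x <- cen[1] + s * (mf$x - cen[1])
  scaled$features$y <- cen[2] + s * (mf$y - cen[2])
  scaled$features$z <- cen[3] + s * (mf$z - cen[3])
  if (any(!is.na(mf$px))) {
    keep <- !is.na(mf$px)
    scaled$features$px[keep] <- scaled$features$x[keep] +
      (mf$px[keep] - mf$x[keep])
    scaled$features$py[keep] <- scaled$features$y[keep] +
      (mf$py[keep] - mf$y[keep])
    scaled$features$pz[keep] <- scaled$features$z[keep] +
      (mf$pz[keep] - mf$z[keep])
  }
  m <- .build_posed_molecule(scaled, jitter_sd, NA, id)
  # random rigid reorientation so decoys are not axis-aligned
  rot <- random_rotation()
  m$confs[[1]] <- apply_rigid(m$confs[[1]], rot,
                              stats::rnorm(3, 0, 2))
  m
}

.build_clashing_molecule <- function(model, jitter_sd, id) {
  if (nrow(model$exclusions) == 0)
    abort("clashing decoys need a model with exclusion volumes")
  k <- sample.int(nrow(model$exclusions), 1)
  ex <- model$exclusions[k, ]
  extra <- list(atoms = tibble(element = "C", charge = 0L, nH = 4L),
                coords = rbind(c(ex$x, ex$y, ex$z) +
                                 stats::rnorm(3, 0, 0.2 * ex$radius)))
  mf <- model$features
  centers <- as.matrix(mf[, c("x", "y", "z")])
  frags <- list()
  for (k2 in seq_len(nrow(mf))) {
    target <- centers[k2, ] + stats::rnorm(3, 0, jitter_sd)
    nxt <- centers[min(k2 + 1, nrow(mf)), ]
    dirv <- nxt - centers[k2, ]
    nd <- sqrt(sum(dirv^2))
    dirv <- if (nd > 1e-9) dirv / nd else c(1, 0, 0)
    frags[[length(frags) + 1]] <- .make_fragment(mf$kind[k2], target, dirv,
                                                 mf[k2, ])
  }
  .assemble_molecule(frags, id, extra_atoms = extra)
}

#' Synthetic labelled ranking with controllable AUC
#'
#' Scores are drawn from two unit-variance Gaussians whose mean
#' separation is solved from the binormal relation
#' `AUC = Phi(delta / sqrt(2))`, so the expected tie-aware ROC-AUC of
#' the ranking equals `target_auc`. `target_auc = 1` produces disjoint
#' score supports.
#'
#' @param n_total ranking size.
#' @param active_fraction fraction of actives (default 0.186, the
#'   composition of the reference sigma-1 screening dataset: 18.6
#'   percent actives).
#' @param target_auc expected AUC, in (0.5, 1].
#' @param seed integer seed.
#' @return ranking tibble: `compound_id`, `score`, `qualifies`, `label`.
#' @export
generate_ranking <- function(n_total, active_fraction = 0.186,
                             target_auc = 0.85, seed = 1) {
  if (target_auc <= 0.5 || target_auc > 1)
    abort("target_auc must be in (0.5, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_a <- round(n_total * active_fraction)
  n_i <- n_total - n_a
  if (target_auc == 1) {
    sa <- stats::runif(n_a, 10, 11)
    si <- stats::runif(n_i, 0, 1)
  } else {
    delta <- sqrt(2) * stats::qnorm(target_auc)
    sa <- stats::rnorm(n_a, delta, 1)
    si <- stats::rnorm(n_i, 0, 1)
  }
  out <- tibble(
    compound_id = sprintf("cmp%05d", seq_len(n_total)),
    score = c(sa, si),
    qualifies = TRUE,
    label = c(rep("active", n_a), rep("inactive", n_i)))
  out[sample.int(n_total), ]
}

#' Toy protein-ligand complexes with known interactions
#'
#' Minimal fixtures for structure-derived model generation: `ionic`
#' places a glutamate-like carboxylate 3.0 A from a ligand ammonium
#' nitrogen; `hydrophobic` rings a ligand ethyl group with three apolar
#' receptor carbons; `full_site` combines both and adds a
#' non-interacting polar receptor atom inside the pocket shell (an
#' excluded-volume candidate).
#'
#' @param kind fixture kind.
#' @param seed seed for the small random displacements of the
#'   non-interacting atoms.
#' @return list with `protein` (atom tibble: `element`, `x`, `y`, `z`,
#'   `resname`, `resid`, `atom_name`, `charge`) and `ligand` (`phmol`
#'   with one conformer).
#' @export
generate_toy_complex <- function(kind = c("ionic", "hydrophobic", "full_site"),
                                 seed = 1) {
  kind <- match.arg(kind)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  carboxylate <- function(near, dist = 3.0) {
    dirv <- c(0, 1, 0)
    o1 <- near + dist * dirv
    cd <- o1 + c(0.4, 1.2, 0)
    o2 <- cd + c(1.1, 0.5, 0)
    tibble(element = c("O", "C", "O"),
           x = c(o1[1], cd[1], o2[1]), y = c(o1[2], cd[2], o2[2]),
           z = c(o1[3], cd[3], o2[3]),
           resname = "GLU", resid = 172L,
           atom_name = c("OE1", "CD", "OE2"), charge = c(-1L, 0L, 0L))
  }
  apolar_cage <- function(center, r = 4.0) {
    ang <- c(0, 2 * pi / 3, 4 * pi / 3)
    tibble(element = "C",
           x = center[1] + r * cos(ang), y = center[2] + r * sin(ang),
           z = center[3] + stats::rnorm(3, 0, 0.2),
           resname = "LEU", resid = 105L,
           atom_name = c("CD1", "CD2", "CG"), charge = 0L)
  }
  if (kind == "ionic") {
    lig <- new_molecule("lig_ionic",
                        atoms = tibble(element = c("N", "C"),
                                       charge = c(1L, 0L), nH = NA_integer_),
                        bonds = tibble(a1 = 1L, a2 = 2L, order = 1L),
                        confs = list(rbind(c(0, 0, 0), c(1.5, 0, 0))))
    return(list(protein = carboxylate(c(0, 0, 0)), ligand = lig))
  }
  if (kind == "hydrophobic") {
    lig <- new_molecule("lig_hyd",
                        atoms = tibble(element = c("C", "C"), charge = 0L,
                                       nH = NA_integer_),
                        bonds = tibble(a1 = 1L, a2 = 2L, order = 1L),
                        confs = list(rbind(c(0, 0, 0), c(1.5, 0, 0))))
    return(list(protein = apolar_cage(c(0.75, 0, 0)), ligand = lig))
  }
  lig <- new_molecule("lig_full",
                      atoms = tibble(element = c("N", "C", "C", "C"),
                                     charge = c(1L, 0L, 0L, 0L),
                                     nH = NA_integer_),
                      bonds = tibble(a1 = c(1L, 2L, 3L), a2 = c(2L, 3L, 4L),
                                     order = 1L),
                      confs = list(rbind(c(0, 0, 0), c(1.5, 0, 0),
                                         c(3.0, 0, 0), c(4.5, 0, 0))))
  bystander <- tibble(element = "N", x = 2.0, y = -3.6, z = 0.3,
                      resname = "HIS", resid = 154L, atom_name = "ND1",
                      charge = 0L)
  list(protein = bind_rows(carboxylate(c(0, 0, 0)),
                           apolar_cage(c(3.75, 0, 0)), bystander),
       ligand = lig)
}
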