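#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `src` onto `dst`. With a single point the transform is a pure
#' translation; for collinear point sets the SVD-based minimizer with
#' proper-rotation (determinant) correction is returned, which is the
#' package's documented axis convention for degenerate hypotheses.
#'
#' @param src,dst n x 3 matrices of paired points.
#' @return list with `rot` (3 x 3), `trans` (length 3): the transform
#'   maps `x` to `x %*% t(rot) + trans`.
#' @export
kabsch <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  cs <- colMeans(src); cd <- colMeans(dst)
  if (nrow(src) == 1) {
    return(list(rot = diag(3), trans = as.numeric(cd - cs)))
  }
  s <- sweep(src, 2, cs); d <- sweep(dst, 2, cd)
  h <- t(s) %*% d
  sv <- svd(h)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, sgn)) %*% t(sv$u)
  trans <- as.numeric(cd - cs %*% t(rot))
  list(rot = rot, trans = trans)
}

.kind_compatible <- function(model_kind, lig_kind) {
  if (model_kind == "HYD_AR") return(lig_kind %in% c("HYD", "AR"))
  model_kind == lig_kind
}

.feat_points <- function(feats) as.matrix(feats[, c("x", "y", "z")])

#' Enumerate mapping hypotheses between a model and ligand features
#'
#' All injective, kind-compatible assignments of model features to ligand
#' features that survive pairwise-distance pruning: a pair of mapped
#' features is kept only when the model and ligand inter-feature
#' distances agree within the sum of the two tolerance radii. Feature
#' omission subsets up to `max_omitted` are enumerated smallest-first;
#' output order is deterministic.
#'
#' @param model a `pharmacophore`.
#' @param feats a perceived-feature tibble (see [perceive_features()]).
#' @param max_omitted maximum omitted model features (default: the
#'   model's own setting).
#' @return list of hypotheses, each a list with `assignment` (integer
#'   vector over model features, `NA` for omitted) and `omitted`.
#' @export
enumerate_hypotheses <- function(model, feats,
                                 max_omitted = model$max_omitted) {
  nf <- nrow(model$features)
  nl <- nrow(feats)
  if (nl == 0) return(list())
  dm <- feature_distances(model$features)
  dl <- as.matrix(stats::dist(.feat_points(feats)))
  tol <- model$features$tol
  cand <- lapply(seq_len(nf), function(i) {
    ok <- vapply(seq_len(nl), function(j) {
      if (!.kind_compatible(model$features$kind[i], feats$kind[j]))
        return(FALSE)
      acc <- model$features$accept_elements[[i]]
      if (!is.null(acc)) {
        els <- feats$elements[[j]]
        if (is.null(els) || !any(els %in% acc)) return(FALSE)
      }
      TRUE
    }, logical(1))
    which(ok)
  })
  out <- list()
  omit_sets <- list(integer(0))
  if (max_omitted > 0) {
    for (k in seq_len(min(max_omitted, nf - 1))) {
      cmb <- utils::combn(nf, k)
      for (ci in seq_len(ncol(cmb))) omit_sets[[length(omit_sets) + 1]] <- cmb[, ci]
    }
  }
  for (omit in omit_sets) {
    mapped <- setdiff(seq_len(nf), omit)
    if (length(mapped) == 0) next
    assign_vec <- rep(NA_integer_, nf)
    used <- logical(nl)
    bt <- function(pos) {
      if (pos > length(mapped)) {
        hyp <- list(assignment = assign_vec, omitted = omit)
        out[[length(out) + 1]] <<- hyp
        return(invisible(NULL))
      }
      i <- mapped[pos]
      for (j in cand[[i]]) {
        if (used[j]) next
        ok <- TRUE
        if (pos > 1) {
          for (q in mapped[seq_len(pos - 1)]) {
            if (abs(dm[i, q] - dl[j, assign_vec[q]]) > tol[i] + tol[q]) {
              ok <- FALSE; break
            }
          }
        }
        if (!ok) next
        assign_vec[i] <<- j
        used[j] <<- TRUE
        bt(pos + 1)
        assign_vec[i] <<- NA_integer_
        used[j] <<- FALSE
      }
      invisible(NULL)
    }
    bt(1)
  }
  out
}

#' Test ligand atoms against excluded volumes
#'
#' @param coords transformed heavy-atom coordinates (n x 3).
#' @param exclusions exclusion tibble (`x`, `y`, `z`, `radius`).
#' @return `TRUE` when any atom center lies strictly inside any sphere.
#' @export
check_exclusion <- function(coords, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(FALSE)
  for (k in seq_len(nrow(exclusions))) {
    d2 <- (coords[, 1] - exclusions$x[k])^2 +
      (coords[, 2] - exclusions$y[k])^2 + (coords[, 3] - exclusions$z[k])^2
    if (any(d2 < exclusions$radius[k]^2 - 1e-12)) return(TRUE)
  }
  FALSE
}

# fit value: sum over mapped features of weight * max(0, 1 - (d/tol)^2)
.fit_value <- function(disp, tol, weight) {
  sum(weight * pmax(0, 1 - (disp / tol)^2))
}

#' Align a conformer onto a pharmacophore under one hypothesis and score it
#'
#' The mapped ligand-feature points (plus constrained projection points)
#' are superposed onto the model feature centers by least squares; the
#' result qualifies when every mapped displacement is within its
#' tolerance sphere, every constrained projection lands inside its
#' projection sphere, and no ligand heavy atom falls inside an excluded
#' volume. The fit value is `sum w * max(0, 1 - (d/tol)^2)` over mapped
#' feature centers; omitted features contribute zero.
#'
#' For aromatic-ring ligand features the ring normal is direction-free:
#' both projection orientations are tried and the better one kept.
#'
#' @param model a `pharmacophore`.
#' @param feats perceived features of the conformer.
#' @param coords heavy-atom coordinates of the conformer.
#' @param hyp one hypothesis from [enumerate_hypotheses()].
#' @return a `fit_result` list: `hypothesis`, `rot`, `trans`,
#'   `displacements`, `proj_displacements`, `clash`, `qualifies`,
#'   `fit_value`, `mode`.
#' @export
align_and_score <- function(model, feats, coords, hyp) {
  mf <- model$features
  mapped <- which(!is.na(hyp$assignment))
  li <- hyp$assignment[mapped]
  lig_pts <- .feat_points(feats)[li, , drop = FALSE]
  mod_pts <- as.matrix(mf[mapped, c("x", "y", "z")])
  # constrained projections participate in the alignment as extra points
  proj_rows <- which(!is.na(mf$px[mapped]) & mf$pconstrained[mapped] %in% TRUE)
  sign_opts <- rep(list(1), length(proj_rows))
  has_lig_proj <- logical(length(proj_rows))
  if (length(proj_rows) > 0) {
    for (k in seq_along(proj_rows)) {
      lf <- li[proj_rows[k]]
      has_lig_proj[k] <- !is.na(feats$px[lf])
      if (has_lig_proj[k] && feats$kind[lf] == "AR") sign_opts[[k]] <- c(1, -1)
    }
  }
  combos <- if (length(proj_rows) == 0) list(integer(0)) else
    do.call(expand.grid, sign_opts)
  best <- NULL
  n_combo <- if (is.data.frame(combos)) nrow(combos) else 1L
  for (ci in seq_len(n_combo)) {
    src <- lig_pts; dst <- mod_pts
    pk <- 0
    lig_proj_pts <- NULL; mod_proj_pts <- NULL
    missing_proj <- FALSE
    for (k in seq_along(proj_rows)) {
      r <- proj_rows[k]; lf <- li[r]; mi <- mapped[r]
      if (!has_lig_proj[k]) { missing_proj <- TRUE; next }
      sgn <- if (is.data.frame(combos)) combos[ci, k] else 1
      base <- as.numeric(lig_pts[r, ])
      pp <- c(feats$px[lf], feats$py[lf], feats$pz[lf])
      if (sgn < 0) pp <- 2 * base - pp
      lig_proj_pts <- rbind(lig_proj_pts, pp)
      mod_proj_pts <- rbind(mod_proj_pts, c(mf$px[mi], mf$py[mi], mf$pz[mi]))
    }
    tf <- kabsch(rbind(src, lig_proj_pts), rbind(dst, mod_proj_pts))
    new_pts <- apply_rigid(lig_pts, tf$rot, tf$trans)
    disp <- sqrt(rowSums((new_pts - mod_pts)^2))
    pdisp <- if (is.null(lig_proj_pts)) numeric(0) else {
      tp <- apply_rigid(lig_proj_pts, tf$rot, tf$trans)
      sqrt(rowSums((tp - mod_proj_pts)^2))
    }
    new_coords <- apply_rigid(coords, tf$rot, tf$trans)
    clash <- check_exclusion(new_coords, model$exclusions)
    ptol_mapped <- mf$ptol[mapped][proj_rows[has_lig_proj]]
    qualifies <- all(disp <= mf$tol[mapped] + 1e-9) &&
      (length(pdisp) == 0 || all(pdisp <= ptol_mapped + 1e-9)) &&
      !missing_proj && !clash
    fv <- .fit_value(disp, mf$tol[mapped], mf$weight[mapped])
    excess <- sum(pmax(0, disp - mf$tol[mapped])) +
      (if (length(pdisp)) sum(pmax(0, pdisp - ptol_mapped)) else 0) +
      (if (clash) 1 else 0) + (if (missing_proj) 1 else 0)
    fr <- structure(list(hypothesis = hyp, rot = tf$rot, trans = tf$trans,
                         displacements = disp, proj_displacements = pdisp,
                         clash = clash, qualifies = qualifies,
                         fit_value = fv, excess = excess, mode = "rigid"),
                    class = "fit_result")
    if (is.null(best) || .fit_key(fr) > .fit_key(best)) best <- fr
  }
  best
}

# comparable scalarized key: qualification dominates, then fit value, then
# smaller maximum displacement
.fit_key <- function(fr) {
  maxd <- if (length(fr$displacements)) max(fr$displacements) else 0
  (if (fr$qualifies) 1e6 else 0) + fr$fit_value - 1e-7 * maxd
}

.better_fit <- function(a, b) {
  # TRUE when a beats b; tie-break: qualifies, fit value, smaller max
  # displacement, lexicographically smallest assignment
  if (is.null(b)) return(TRUE)
  if (a$qualifies != b$qualifies) return(a$qualifies)
  if (abs(a$fit_value - b$fit_value) > 1e-12)
    return(a$fit_value > b$fit_value)
  ma <- if (length(a$displacements)) max(a$displacements) else 0
  mb <- if (length(b$displacements)) max(b$displacements) else 0
  if (abs(ma - mb) > 1e-12) return(ma < mb)
  ka <- paste(ifelse(is.na(a$hypothesis$assignment), 0,
                     a$hypothesis$assignment), collapse = ",")
  kb <- paste(ifelse(is.na(b$hypothesis$assignment), 0,
                     b$hypothesis$assignment), collapse = ",")
  ka < kb
}

## ---- flexible fit ----

rotatable_bonds <- function(mol) {
  bd <- mol$bonds
  if (nrow(bd) == 0) return(bd[0, ])
  in_ring_bond <- logical(nrow(bd))
  for (r in mol$rings) {
    rs <- sort(r)
    for (k in seq_len(nrow(bd))) {
      if (bd$a1[k] %in% r && bd$a2[k] %in% r) {
        # both endpoints in same ring: check consecutive
        in_ring_bond[k] <- TRUE
      }
    }
  }
  env <- atom_env(mol)
  keep <- bd$order == 1 & !mol$bond_aromatic & !in_ring_bond &
    env$degree[bd$a1] > 1 & env$degree[bd$a2] > 1
  bd[keep, , drop = FALSE]
}

# atoms on the a2 side of bond a1-a2 (the side that rotates)
.bond_side <- function(mol, a1, a2) {
  g <- mol_graph(mol)
  eid <- igraph::get_edge_ids(g, c(as.character(a1), as.character(a2)))
  g2 <- igraph::delete_edges(g, eid)
  comp <- igraph::components(g2)
  side <- which(comp$membership == comp$membership[a2])
  as.integer(igraph::V(g)$name[side])
}

rotate_about_bond <- function(coords, axis_from, axis_to, side_atoms, angle_deg) {
  p0 <- coords[axis_from, ]
  ax <- coords[axis_to, ] - p0
  ax <- ax / sqrt(sum(ax^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + st * K + (1 - ct) * (K %*% K)
  out <- coords
  rel <- sweep(coords[side_atoms, , drop = FALSE], 2, p0)
  out[side_atoms, ] <- sweep(rel %*% t(R), 2, p0, `+`)
  out
}

#' Flexible fit of a conformer to a pharmacophore
#'
#' Starting from the rigid solution for one hypothesis, torsion-space
#' coordinate descent perturbs rotatable bonds (re-aligning rigidly after
#' each move) to reduce the weighted squared feature displacements,
#' subject to a heavy-atom RMSD cap of 0.5 A from the input conformer
#' ("slight conformational modification"). Qualification rules are those
#' of the rigid fit; the returned result is never worse than the rigid
#' start.
#'
#' @inheritParams align_and_score
#' @param mol the molecule owning the conformer (topology for torsions).
#' @param conf conformer index.
#' @param defs feature definitions used to re-perceive features on
#'   perturbed geometries.
#' @param rmsd_cap maximum heavy-atom RMSD from the input conformer.
#' @return a `fit_result` with `mode = "flexible"`.
#' @export
flexible_fit <- function(model, mol, conf, hyp,
                         defs = default_feature_definitions(),
                         rmsd_cap = 0.5) {
  coords0 <- mol$confs[[conf]]
  feats0 <- perceive_features(mol, conf, defs)
  rigid <- align_and_score(model, feats0, coords0, hyp)
  best <- rigid; best$mode <- "flexible"
  rb <- rotatable_bonds(mol)
  if (nrow(rb) == 0) return(best)
  sides <- lapply(seq_len(nrow(rb)), function(k)
    .bond_side(mol, rb$a1[k], rb$a2[k]))
  cur <- coords0
  cur_key <- .flex_key(rigid)
  eval_coords <- function(coords) {
    m2 <- mol; m2$confs[[conf]] <- coords
    f2 <- perceive_features(m2, conf, defs)
    if (nrow(f2) != nrow(feats0) ||
        !identical(f2$kind, feats0$kind)) return(NULL)
    align_and_score(model, f2, coords, hyp)
  }
  deltas <- c(-20, -10, -5, -2, 2, 5, 10, 20)
  for (sweep_i in 1:2) {
    improved <- FALSE
    for (k in seq_len(nrow(rb))) {
      for (dl in deltas) {
        trial <- rotate_about_bond(cur, rb$a1[k], rb$a2[k], sides[[k]], dl)
        rmsd <- sqrt(mean(rowSums((trial - coords0)^2)))
        if (rmsd > rmsd_cap) next
        fr <- eval_coords(trial)
        if (is.null(fr)) next
        key <- .flex_key(fr)
        if (key > cur_key + 1e-9) {
          cur <- trial; cur_key <- key; improved <- TRUE
          fr$mode <- "flexible"
          if (.better_fit(fr, best)) best <- fr
          break
        }
      }
    }
    if (!improved) break
  }
  # never worse than the rigid start
  if (!.better_fit(best, rigid) && !identical(best, rigid)) {
    best <- rigid; best$mode <- "flexible"
  }
  if (best$mode != "flexible") best$mode <- "flexible"
  best
}

# continuous descent objective: qualification excess dominates, fit value
# refines
.flex_key <- function(fr) -10 * fr$excess + fr$fit_value

#' Screen a ligand library with a pharmacophore model
#'
#' Every conformer of every compound is mapped separately; only the best
#' mapping per conformer and then the best-scoring qualifying conformer
#' per compound is kept. Compounds with no qualifying fit are recorded as
#' non-hits (score `NA`). With `mode = "flexible"`, each rigid solution
#' is refined by [flexible_fit()].
#'
#' @param library library tibble with columns `id` and `mol`
#'   (list-column of `phmol`).
#' @param model a `pharmacophore`.
#' @param mode `"rigid"` or `"flexible"`.
#' @param max_omitted maximum omitted features (default: the model's
#'   setting; the conventional virtual-screening setting is 0, no
#'   omission allowed).
#' @param defs feature definitions; when the model carries a PI
#'   customization it is applied automatically.
#' @param detailed attach the winning `fit_result` objects as a
#'   list-column `fit`.
#' @param progress print one line per 50 compounds.
#' @return a ranking tibble: `compound_id`, `score`, `qualifies`,
#'   `n_features_mapped`, `conformer_index`.
#' @export
screen_library <- function(library, model, mode = c("rigid", "flexible"),
                           max_omitted = model$max_omitted,
                           defs = NULL, detailed = FALSE, progress = FALSE) {
  mode <- match.arg(mode)
  if (nrow(library) == 0) abort("library is empty")
  if (is.null(defs)) defs <- model_feature_definitions(model)
  rows <- vector("list", nrow(library))
  fits <- vector("list", nrow(library))
  for (i in seq_len(nrow(library))) {
    mol <- library$mol[[i]]
    best <- NULL
    if (length(mol$confs) == 0) {
      warn(sprintf("compound %s has no conformers; recorded as non-hit", mol$id))
    }
    for (cf in seq_along(mol$confs)) {
      feats <- perceive_features(mol, cf, defs)
      if (nrow(feats) == 0) next
      hyps <- enumerate_hypotheses(model, feats, max_omitted)
      for (hyp in hyps) {
        fr <- if (mode == "rigid")
          align_and_score(model, feats, mol$confs[[cf]], hyp)
        else flexible_fit(model, mol, cf, hyp, defs)
        fr$conformer <- cf
        if (.better_fit(fr, best)) best <- fr
      }
    }
    hit <- !is.null(best) && best$qualifies
    rows[[i]] <- tibble(
      compound_id = library$id[i],
      score = if (hit) best$fit_value else NA_real_,
      qualifies = hit,
      n_features_mapped = if (hit)
        sum(!is.na(best$hypothesis$assignment)) else 0L,
      conformer_index = if (hit) best$conformer else NA_integer_)
    fits[i] <- list(if (hit) best else NULL)
    if (progress && i %% 50 == 0)
      message(sprintf("screened %d/%d compounds", i, nrow(library)))
  }
  out <- bind_rows(rows)
  if (detailed) out$fit <- fits
  out
}

#' Feature definitions implied by a model's PI customization
#' @param model a `pharmacophore`.
#' @return a feature definition set.
#' @export
model_feature_definitions <- function(model) {
  defs <- default_feature_definitions()
  if (!is.null(model$pi_exclude) && model$pi_exclude == "nonbasic_amidine")
    defs <- customize_pi_definition(defs, nonbasic_amidine_patterns())
  defs
}

#' Dual-direction aromatic screening protocol
#'
#' Screens with the "up" model, then re-tests every passing pose in
#' place (without re-fitting) against the "down" model, which must be
#' identical except for the aromatic-ring projection point. Final hits
#' pass both directions; scores are those of the first stage.
#'
#' @param up_model,down_model `pharmacophore` objects differing only in
#'   the AR projection point.
#' @param library library tibble.
#' @param mode `"rigid"` or `"flexible"`.
#' @return ranking tibble as in [screen_library()].
#' @export
gund_dual_direction_screen <- function(up_model, down_model, library,
                                       mode = "rigid") {
  fu <- up_model$features; fd <- down_model$features
  strip_ar_proj <- function(f) {
    f$px[f$kind == "AR"] <- NA; f$py[f$kind == "AR"] <- NA
    f$pz[f$kind == "AR"] <- NA
    f[, c("kind", "x", "y", "z", "tol", "weight", "px", "py", "pz", "ptol")]
  }
  if (!isTRUE(all.equal(as.data.frame(strip_ar_proj(fu)),
                        as.data.frame(strip_ar_proj(fd)),
                        tolerance = 1e-9)) ||
      nrow(up_model$exclusions) != nrow(down_model$exclusions))
    abort("models must differ only in the AR projection point")
  defs <- model_feature_definitions(up_model)
  stage1 <- screen_library(library, up_model, mode = mode, defs = defs,
                           detailed = TRUE)
  for (i in seq_len(nrow(stage1))) {
    if (!stage1$qualifies[i]) next
    fr <- stage1$fit[[i]]
    mol <- library$mol[[match(stage1$compound_id[i], library$id)]]
    feats <- perceive_features(mol, fr$conformer, defs)
    ok <- .in_place_qualifies(down_model, feats, mol$confs[[fr$conformer]], fr)
    if (!ok) {
      stage1$qualifies[i] <- FALSE
      stage1$score[i] <- NA_real_
      stage1$n_features_mapped[i] <- 0L
      stage1$conformer_index[i] <- NA_integer_
    }
  }
  stage1$fit <- NULL
  stage1
}

# re-test a fitted pose against another model without re-alignment
.in_place_qualifies <- function(model, feats, coords, fr) {
  hyp <- fr$hypothesis
  mf <- model$features
  mapped <- which(!is.na(hyp$assignment))
  li <- hyp$assignment[mapped]
  pts <- apply_rigid(.feat_points(feats)[li, , drop = FALSE], fr$rot, fr$trans)
  mod_pts <- as.matrix(mf[mapped, c("x", "y", "z")])
  disp <- sqrt(rowSums((pts - mod_pts)^2))
  if (any(disp > mf$tol[mapped] + 1e-9)) return(FALSE)
  for (k in seq_along(mapped)) {
    mi <- mapped[k]; lf <- li[k]
    if (is.na(mf$px[mi]) || !isTRUE(mf$pconstrained[mi])) next
    if (is.na(feats$px[lf])) return(FALSE)
    base <- .feat_points(feats)[lf, ]
    pp1 <- c(feats$px[lf], feats$py[lf], feats$pz[lf])
    opts <- if (feats$kind[lf] == "AR") list(pp1, 2 * base - pp1) else list(pp1)
    target <- c(mf$px[mi], mf$py[mi], mf$pz[mi])
    ok <- FALSE
    for (pp in opts) {
      tp <- apply_rigid(rbind(pp), fr$rot, fr$trans)
      if (sqrt(sum((tp - target)^2)) <= mf$ptol[mi] + 1e-9) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  !check_exclusion(apply_rigid(coords, fr$rot, fr$trans), model$exclusions)
}

#' Affinity-prediction screening (weighted, any omission)
#'
#' Screens with the maximum number of omitted features set to "any"
#' (all but one), so every compound mapping at least one model feature
#' receives a weighted score; the output is a ranking, not an affinity
#' estimate.
#'
#' @param model a `pharmacophore` carrying per-feature weights.
#' @param library library tibble.
#' @param mode `"rigid"` or `"flexible"`.
#' @return ranking tibble as in [screen_library()].
#' @export
langer_affinity_mode <- function(model, library, mode = "rigid") {
  screen_library(library, model, mode = mode,
                 max_omitted = nrow(model$features) - 1L)
}

#' Test ligand features against a distance-only model
#'
#' @param dm a `distance_model`.
#' @param feats perceived-feature tibble.
#' @return `TRUE` when some injective assignment of ligand features to
#'   the model's slots satisfies every pairwise distance range.
#' @export
check_distance_model <- function(dm, feats) {
  slots <- dm$slots
  nl <- nrow(feats)
  if (nl == 0) return(FALSE)
  dl <- as.matrix(stats::dist(.feat_points(feats)))
  cand <- lapply(slots$kind, function(k) which(feats$kind == k))
  if (any(lengths(cand) == 0)) return(FALSE)
  cons <- dm$constraints
  ca <- match(cons$a, slots$slot); cb <- match(cons$b, slots$slot)
  assign_vec <- integer(nrow(slots))
  found <- FALSE
  bt <- function(si) {
    if (found) return(invisible(NULL))
    if (si > nrow(slots)) { found <<- TRUE; return(invisible(NULL)) }
    for (j in cand[[si]]) {
      if (j %in% assign_vec[seq_len(si - 1)]) next
      ok <- TRUE
      for (q in which((ca == si & cb < si) | (cb == si & ca < si))) {
        other <- if (ca[q] == si) assign_vec[cb[q]] else assign_vec[ca[q]]
        d <- dl[j, other]
        if (d < cons$dmin[q] || d > cons$dmax[q]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[si] <<- j
      bt(si + 1)
      if (found) return(invisible(NULL))
      assign_vec[si] <<- 0L
    }
    invisible(NULL)
  }
  bt(1)
  found
}
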