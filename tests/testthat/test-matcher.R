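test_that("hypothesis enumeration respects kinds, injectivity and distance pruning", {
  model <- model_pi_hyd(d = 3.7, tol = 1.6)
  lig <- perceive_features(mol_pi_hyd_ligand(hyd_pos = c(3.7, 0, 0)))
  hyps <- enumerate_hypotheses(model, lig)
  expect_equal(length(hyps), 1)
  expect_equal(hyps[[1]]$assignment[1], which(lig$kind == "PI"))
  # pair 10 A apart: |10 - 3.7| = 6.3 > 1.6 + 1.6, pruned entirely
  far <- perceive_features(mol_pi_hyd_ligand(hyd_pos = c(10, 0, 0)))
  expect_equal(length(enumerate_hypotheses(model, far)), 0)
})

test_that("two equivalent hydrophobe candidates give two hypotheses", {
  model <- model_pi_hyd(d = 3.7, tol = 1.6)
  # ligand with one PI and two C2 hydrophobes symmetric about it
  m <- new_molecule("twin",
    atoms = tibble::tibble(element = c("N", "C", "C", "C", "C"),
                           charge = c(1L, 0L, 0L, 0L, 0L), nH = NA_integer_),
    bonds = tibble::tibble(a1 = c(2L, 4L), a2 = c(3L, 5L), order = 1L),
    confs = list(rbind(c(0, 0, 0),
                       c(3.7, 0.75, 0), c(3.7, -0.75, 0),
                       c(-3.7, 0.75, 0), c(-3.7, -0.75, 0))))
  feats <- perceive_features(m)
  hyps <- enumerate_hypotheses(model, feats)
  expect_equal(length(hyps), 2)
})

test_that("perfect fits score the weight sum; boundary displacement scores zero", {
  model <- pharmacophore("sq", tibble::tibble(
    kind = "HYD", x = c(0, 4, 4, 0), y = c(0, 0, 4, 4), z = 0,
    tol = 1.6, weight = 1))
  feats <- tibble::tibble(
    kind = "HYD", x = c(0, 4, 4, 0), y = c(0, 0, 4, 4), z = 0,
    px = NA_real_, py = NA_real_, pz = NA_real_,
    source_atoms = list(1L, 2L, 3L, 4L),
    elements = list("C", "C", "C", "C"))
  coords <- as.matrix(feats[, c("x", "y", "z")])
  hyp <- list(assignment = 1:4, omitted = integer(0))
  fr <- align_and_score(model, feats, coords, hyp)
  expect_true(fr$qualifies)
  expect_equal(fr$fit_value, 4.0, tolerance = 1e-9)
  expect_lt(max(fr$displacements), 1e-9)
  # a segment 2 A longer than the model pair leaves each feature exactly on
  # its 1.0 A sphere boundary after least-squares alignment: contribution 0,
  # but still qualifying
  seg_model <- pharmacophore("seg", tibble::tibble(
    kind = "HYD", x = c(0, 4), y = 0, z = 0, tol = 1.0, weight = 1))
  seg_feats <- tibble::tibble(
    kind = "HYD", x = c(0, 6), y = 0, z = 0,
    px = NA_real_, py = NA_real_, pz = NA_real_,
    source_atoms = list(1L, 2L), elements = list("C", "C"))
  fr2 <- align_and_score(seg_model, seg_feats,
                         as.matrix(seg_feats[, c("x", "y", "z")]),
                         list(assignment = 1:2, omitted = integer(0)))
  expect_equal(fr2$displacements, c(1, 1), tolerance = 1e-9)
  expect_equal(fr2$fit_value, 0, tolerance = 1e-9)
  expect_true(fr2$qualifies)
  # displacement of tol/2 contributes 0.75
  expect_equal(sigmaphore:::.fit_value(0.8, 1.6, 1), 0.75)
})

test_that("excluded volumes reject atoms strictly inside", {
  ex <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.2)
  expect_true(check_exclusion(rbind(c(0, 0, 0)), ex))
  expect_false(check_exclusion(rbind(c(1.3, 0, 0)), ex))
  expect_false(check_exclusion(rbind(c(1.2, 0, 0)), ex))  # boundary is outside
  expect_false(check_exclusion(rbind(c(0, 0, 0)),
                               tibble::tibble(x = double(), y = double(),
                                              z = double(), radius = double())))
})

test_that("screening returns the best qualifying conformer per compound", {
  model <- model_pi_hyd(d = 3.7, tol = 1.6)
  good <- mol_pi_hyd_ligand(hyd_pos = c(3.7, 0, 0), id = "two-conf")
  off <- mol_pi_hyd_ligand(hyd_pos = c(4.6, 0, 0), id = "two-conf")
  good$confs <- c(good$confs, off$confs)
  r <- screen_library(tibble::tibble(id = "two-conf", mol = list(good)), model)
  expect_true(r$qualifies)
  expect_equal(r$conformer_index, 1L)
  expect_equal(r$score, 2.0, tolerance = 1e-6)
})

test_that("a ligand missing one feature is a non-hit when omission is not allowed", {
  model <- builtin_models()[["5HK1-Ph.B"]]
  m <- sigmaphore:::.build_posed_molecule(model, 0.1, drop_feature = 2,
                                          id = "partial")
  r <- screen_library(tibble::tibble(id = "partial", mol = list(m)), model,
                      max_omitted = 0)
  expect_false(r$qualifies)
  expect_true(is.na(r$score))
})

test_that("screen matches the brute-force oracle on random small instances", {
  n_match <- 0
  for (seed in 1:40) {
    inst <- random_small_instance(seed)
    r <- screen_library(tibble::tibble(id = inst$mol$id,
                                       mol = list(inst$mol)), inst$model)
    o <- oracle_best_fit(inst$model, inst$mol)
    o_hit <- !is.null(o) && o$qualifies
    expect_equal(r$qualifies, o_hit, info = paste("seed", seed))
    if (o_hit) {
      expect_equal(r$score, o$fit_value, tolerance = 1e-9,
                   info = paste("seed", seed))
      expect_equal(r$conformer_index, o$conformer,
                   info = paste("seed", seed))
      n_match <- n_match + 1
    }
  }
  expect_gt(n_match, 5)  # the suite exercises both hits and misses
})

test_that("fit values are rigid-motion invariant and bounded by the weight sum", {
  set.seed(99)
  model <- builtin_models()[["5HK1-Ph.B"]]
  m <- sigmaphore:::.build_posed_molecule(model, 0.4, NA, "inv")
  lib <- tibble::tibble(id = "inv", mol = list(m))
  r0 <- screen_library(lib, model)
  for (k in 1:4) {
    m2 <- m
    m2$confs[[1]] <- sigmaphore:::apply_rigid(
      m$confs[[1]], sigmaphore:::random_rotation(), rnorm(3, 0, 8))
    r1 <- screen_library(tibble::tibble(id = "inv", mol = list(m2)), model)
    expect_equal(r1$score, r0$score, tolerance = 1e-6)
  }
  expect_lte(r0$score, sum(model$features$weight) + 1e-12)
})

test_that("shrinking tolerances never improves a fit or converts a non-hit", {
  set.seed(7)
  model <- builtin_models()[["5HK1-Ph.B"]]
  for (seed in 1:6) {
    m <- sigmaphore:::.build_posed_molecule(model, 0.6, NA,
                                            sprintf("shr%d", seed))
    lib <- tibble::tibble(id = m$id, mol = list(m))
    r0 <- screen_library(lib, model)
    shrunk <- model
    shrunk$features$tol <- model$features$tol * 0.6
    r1 <- screen_library(lib, shrunk)
    if (r1$qualifies) expect_true(r0$qualifies)
    if (r0$qualifies && r1$qualifies) expect_lte(r1$score, r0$score + 1e-9)
  }
})

test_that("flexible fit never scores below rigid and can rescue near misses", {
  model <- model_pi_hyd(d = 3.7, tol = 1.0)
  # hydrophobe 0.4 A beyond the sphere, reachable by one torsion
  m <- new_molecule("flex",
    atoms = tibble::tibble(element = c("N", "C", "C", "C"),
                           charge = c(1L, 0L, 0L, 0L), nH = NA_integer_),
    bonds = tibble::tibble(a1 = c(1L, 2L, 3L), a2 = c(2L, 3L, 4L), order = 1L),
    confs = list(rbind(c(0, 0, 0), c(1.8, 0, 0), c(3.2, 0.9, 0),
                       c(4.4, 1.7, 0))))
  feats <- perceive_features(m)
  hyps <- enumerate_hypotheses(model, feats, max_omitted = 0)
  expect_gte(length(hyps), 1)
  rigid <- align_and_score(model, feats, m$confs[[1]], hyps[[1]])
  flex <- flexible_fit(model, m, 1, hyps[[1]])
  expect_gte(flex$fit_value, rigid$fit_value - 1e-9)
  # an already-perfect fit is left unchanged
  perf <- mol_pi_hyd_ligand(hyd_pos = c(3.7, 0, 0), id = "perf")
  pf <- perceive_features(perf)
  ph <- enumerate_hypotheses(model_pi_hyd(), pf)[[1]]
  r1 <- align_and_score(model_pi_hyd(), pf, perf$confs[[1]], ph)
  f1 <- flexible_fit(model_pi_hyd(), perf, 1, ph)
  expect_equal(f1$fit_value, r1$fit_value, tolerance = 1e-9)
  # a feature far out of reach stays non-qualifying under the RMSD cap
  far <- mol_pi_hyd_ligand(hyd_pos = c(8.7, 0, 0), id = "far")
  ff <- perceive_features(far)
  fh <- list(assignment = c(which(ff$kind == "PI"), which(ff$kind == "HYD")),
             omitted = integer(0))
  expect_false(flexible_fit(model_pi_hyd(), far, 1, fh)$qualifies)
})

test_that("the dual-direction protocol filters poses in place", {
  up <- builtin_models()[["Gund-up-Ph"]]
  down <- builtin_models()[["Gund-down-Ph"]]
  lib <- generate_ligand_library(up, 4, 4, seed = 5)
  both <- gund_dual_direction_screen(up, down, lib)
  single <- screen_library(lib, up)
  # a planar ring's normal is double-sided, so compliant actives pass both
  expect_equal(both$qualifies, single$qualifies)
  expect_equal(sum(both$qualifies), 4)
  # models differing beyond the AR projection are rejected
  expect_error(gund_dual_direction_screen(up, builtin_models()[["Langer-Ph"]],
                                          lib), "AR projection")
  # empty stage-1 hit list propagates
  miss <- generate_ligand_library(up, 0, 3, seed = 6)
  expect_equal(sum(gund_dual_direction_screen(up, down, miss)$qualifies), 0)
})

test_that("affinity-prediction mode scores partial mappers and is weight-linear", {
  L <- builtin_models()[["Langer-Ph"]]
  m <- sigmaphore:::.build_posed_molecule(L, 0.1, NA, "full")
  partial <- sigmaphore:::.build_posed_molecule(
    merge_features(L, 3, 4, 1.6), 0.1, NA, "partial")  # only 4 fragments
  lib <- tibble::tibble(id = c("full", "partial"),
                        mol = list(m, partial))
  r <- langer_affinity_mode(L, lib)
  expect_true(all(!is.na(r$score)))
  expect_lt(r$n_features_mapped[2], nrow(L$features))
  L2 <- L; L2$features$weight <- L$features$weight * 2
  r2 <- langer_affinity_mode(L2, lib)
  expect_equal(r2$score, 2 * r$score, tolerance = 1e-9)
  expect_equal(order(r2$score), order(r$score))
})

test_that("distance-only models accept and reject by pairwise ranges", {
  gl <- builtin_models()[["Glennon-Ph"]]
  lig_ok <- perceive_features(new_molecule(
    "ok", atoms = tibble::tibble(element = c("N", "C", "C", "C", "C"),
                                 charge = c(1L, 0L, 0L, 0L, 0L),
                                 nH = NA_integer_),
    bonds = tibble::tibble(a1 = c(2L, 4L), a2 = c(3L, 5L), order = 1L),
    confs = list(rbind(c(0, 0, 0), c(3.0, 0.75, 0), c(3.0, -0.75, 0),
                       c(-8, 0.75, 0), c(-8, -0.75, 0)))))
  expect_true(check_distance_model(gl, lig_ok))
  lig_single <- perceive_features(mol_pi_hyd_ligand(hyd_pos = c(3, 0, 0)))
  expect_false(check_distance_model(gl, lig_single))
  lig_bad <- perceive_features(new_molecule(
    "bad", atoms = tibble::tibble(element = c("N", "C", "C", "C", "C"),
                                  charge = c(1L, 0L, 0L, 0L, 0L),
                                  nH = NA_integer_),
    bonds = tibble::tibble(a1 = c(2L, 4L), a2 = c(3L, 5L), order = 1L),
    confs = list(rbind(c(0, 0, 0), c(5.0, 0.75, 0), c(5.0, -0.75, 0),
                       c(-5.5, 0.75, 0), c(-5.5, -0.75, 0)))))
  expect_false(check_distance_model(gl, lig_bad))
})

test_that("merged models keep matching ligands that matched both originals", {
  set.seed(21)
  a <- builtin_models()[["5HK1-Ph.A"]]
  d34 <- feature_distances(a$features)[3, 4]
  new_tol <- d34 / 2 + max(a$features$tol[3:4]) + 0.05
  b <- merge_features(a, 3, 4, new_tolerance = new_tol)
  for (seed in 1:5) {
    m <- sigmaphore:::.build_posed_molecule(a, 0.15, NA, sprintf("mg%d", seed))
    lib <- tibble::tibble(id = m$id, mol = list(m))
    ra <- screen_library(lib, a)
    if (ra$qualifies) {
      rb <- screen_library(lib, b)
      expect_true(rb$qualifies, info = paste("seed", seed))
    }
  }
})
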