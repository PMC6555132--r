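#' Construct a pharmacophore model
#'
#' A pharmacophore is a named set of typed features (location sphere,
#' optional projected point) plus excluded-volume spheres. Feature kinds:
#' PI, HBA, HBD, HYD, HYD_AR (accepts hydrophobic or aromatic ligand
#' features) and AR.
#'
#' @param name model name.
#' @param features data frame with columns `kind`, `x`, `y`, `z`, `tol`
#'   (tolerance radius, Angstrom, > 0) and optionally `weight` (default
#'   1), `px`, `py`, `pz`, `ptol`, `pconstrained` (projection point), and
#'   `accept_elements` (list-column restricting the elements a mapped
#'   ligand feature may be anchored on, `NA` for no restriction).
#' @param exclusions data frame with columns `x`, `y`, `z`, `radius`.
#' @param max_omitted maximum number of model features a hit may leave
#'   unmapped (default 0: no omission allowed).
#' @param provenance free-text provenance note.
#' @param pi_exclude optional name of a PI customization
#'   (`"nonbasic_amidine"`) applied to feature perception when screening
#'   with this model.
#' @return an object of class `pharmacophore`.
#' @export
pharmacophore <- function(name, features, exclusions = NULL, max_omitted = 0L,
                          provenance = "", pi_exclude = NULL) {
  features <- as_tibble(features)
  valid_kinds <- c("PI", "HBA", "HBD", "HYD", "HYD_AR", "AR")
  if (!all(features$kind %in% valid_kinds))
    abort(sprintf("unknown feature kind: %s",
                  paste(setdiff(features$kind, valid_kinds), collapse = ", ")))
  if (nrow(features) < 2) abort("a pharmacophore needs at least 2 features")
  if (any(features$tol <= 0)) abort("feature tolerance must be > 0")
  if (is.null(features[["weight"]])) features$weight <- 1
  if (any(features$weight < 0)) abort("feature weights must be non-negative")
  for (col in c("px", "py", "pz", "ptol")) {
    if (is.null(features[[col]])) features[[col]] <- NA_real_
  }
  if (is.null(features[["pconstrained"]])) features$pconstrained <- NA
  features$pconstrained <- ifelse(is.na(features$px), NA,
                                  ifelse(is.na(features$pconstrained), TRUE,
                                         features$pconstrained))
  if (is.null(features[["accept_elements"]]))
    features$accept_elements <- rep(list(NULL), nrow(features))
  if (is.null(exclusions))
    exclusions <- tibble(x = double(), y = double(), z = double(),
                         radius = double())
  exclusions <- as_tibble(exclusions)
  if (nrow(exclusions) > 0 && any(exclusions$radius <= 0))
    abort("exclusion radius must be > 0")
  if (max_omitted >= nrow(features))
    abort("max_omitted must be smaller than the number of features")
  d <- feature_distances(features)
  if (any(!is.finite(d))) abort("feature pairwise distances must be finite")
  structure(list(name = name, features = features, exclusions = exclusions,
                 max_omitted = as.integer(max_omitted),
                 provenance = provenance, pi_exclude = pi_exclude),
            class = "pharmacophore")
}

feature_distances <- function(features) {
  as.matrix(stats::dist(as.matrix(features[, c("x", "y", "z")])))
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat(sprintf("<pharmacophore %s: %d features, %d exclusion volumes, max_omitted=%d>\n",
              x$name, nrow(x$features), nrow(x$exclusions), x$max_omitted))
  ft <- x$features
  for (i in seq_len(nrow(ft))) {
    cat(sprintf("  [%d] %-6s (%6.2f,%6.2f,%6.2f) tol %.2f wt %.2f%s\n",
                i, ft$kind[i], ft$x[i], ft$y[i], ft$z[i], ft$tol[i],
                ft$weight[i],
                if (!is.na(ft$px[i]))
                  sprintf("  proj (%.2f,%.2f,%.2f) ptol %.2f%s", ft$px[i],
                          ft$py[i], ft$pz[i], ft$ptol[i],
                          if (isTRUE(ft$pconstrained[i])) "" else " [unconstrained]")
                else ""))
  }
  if (!is.null(x$pi_exclude))
    cat(sprintf("  PI customization: %s\n", x$pi_exclude))
  invisible(x)
}

#' Construct a distance-only pharmacophore model
#'
#' Distance models (such as the classic two-hydrophobe sigma-1 ligand
#' rule) constrain pairwise distances between typed feature slots without
#' fixing coordinates or angles.
#'
#' @param name model name.
#' @param slots data frame with columns `slot` (label) and `kind`.
#' @param constraints data frame with columns `a`, `b` (slot labels),
#'   `dmin`, `dmax` (Angstrom).
#' @return an object of class `distance_model`.
#' @export
distance_model <- function(name, slots, constraints) {
  slots <- as_tibble(slots); constraints <- as_tibble(constraints)
  if (any(constraints$dmin > constraints$dmax)) abort("dmin must be <= dmax")
  if (!all(c(constraints$a, constraints$b) %in% slots$slot))
    abort("constraint references an unknown slot")
  structure(list(name = name, slots = slots, constraints = constraints),
            class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("<distance model %s>\n", x$name))
  for (i in seq_len(nrow(x$constraints))) {
    cn <- x$constraints[i, ]
    cat(sprintf("  %s - %s: %.1f-%.1f A\n", cn$a, cn$b, cn$dmin, cn$dmax))
  }
  invisible(x)
}

## ---- pharmjson/1 serialization ----

#' Read and write pharmacophore models (pharmjson/1)
#'
#' Models are stored in a small versioned JSON dialect. `save_model`
#' followed by `load_model` is the identity to 1e-6 Angstrom.
#'
#' @param model a `pharmacophore` or `distance_model`.
#' @param path file path.
#' @return `load_model` returns the model object.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "pharmacophore")) {
    ft <- model$features
    feats <- lapply(seq_len(nrow(ft)), function(i) {
      f <- list(kind = ft$kind[i],
                center = c(ft$x[i], ft$y[i], ft$z[i]),
                tolerance = ft$tol[i],
                weight = ft$weight[i])
      if (!is.na(ft$px[i])) {
        f$projection <- list(point = c(ft$px[i], ft$py[i], ft$pz[i]),
                             tolerance = ft$ptol[i],
                             constrained = isTRUE(ft$pconstrained[i]))
      }
      if (!is.null(ft$accept_elements[[i]]))
        f$accept_elements <- ft$accept_elements[[i]]
      f
    })
    obj <- list(format = "pharmjson/1", kind = "pharmacophore",
                name = model$name, features = feats,
                exclusions = lapply(seq_len(nrow(model$exclusions)), function(i)
                  list(center = unlist(model$exclusions[i, c("x", "y", "z")],
                                       use.names = FALSE),
                       radius = model$exclusions$radius[i])),
                max_omitted = model$max_omitted,
                provenance = model$provenance)
    if (!is.null(model$pi_exclude)) obj$pi_exclude <- model$pi_exclude
  } else if (inherits(model, "distance_model")) {
    obj <- list(format = "pharmjson/1", kind = "distance_model",
                name = model$name,
                slots = model$slots, constraints = model$constraints)
  } else abort("not a pharmacophore or distance model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

.schema_err <- function(field, msg) {
  abort(sprintf("pharmjson schema violation in field '%s': %s", field, msg))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "pharmjson/1")
    .schema_err("format", "expected \"pharmjson/1\"")
  if (is.null(obj$name)) .schema_err("name", "missing")
  kind <- obj$kind %||% "pharmacophore"
  if (kind == "distance_model") {
    slots <- bind_rows(lapply(obj$slots, as_tibble))
    constraints <- bind_rows(lapply(obj$constraints, as_tibble))
    return(distance_model(obj$name, slots, constraints))
  }
  if (is.null(obj$features)) .schema_err("features", "missing")
  valid_kinds <- c("PI", "HBA", "HBD", "HYD", "HYD_AR", "AR")
  rows <- lapply(seq_along(obj$features), function(i) {
    f <- obj$features[[i]]
    if (is.null(f$kind) || !(f$kind %in% valid_kinds))
      .schema_err(sprintf("features[%d].kind", i),
                  paste("unknown feature kind", f$kind %||% "(missing)"))
    if (is.null(f$center) || length(f$center) != 3)
      .schema_err(sprintf("features[%d].center", i), "need 3 coordinates")
    if (is.null(f$tolerance))
      .schema_err(sprintf("features[%d].tolerance", i), "missing")
    cen <- as.numeric(f$center)
    row <- tibble(kind = f$kind, x = cen[1], y = cen[2], z = cen[3],
                  tol = as.numeric(f$tolerance),
                  weight = as.numeric(f$weight %||% 1),
                  px = NA_real_, py = NA_real_, pz = NA_real_,
                  ptol = NA_real_, pconstrained = NA)
    if (!is.null(f$projection)) {
      pp <- f$projection
      if (is.null(pp$point) || length(pp$point) != 3)
        .schema_err(sprintf("features[%d].projection.point", i),
                    "need 3 coordinates")
      pt <- as.numeric(pp$point)
      row$px <- pt[1]; row$py <- pt[2]; row$pz <- pt[3]
      row$ptol <- as.numeric(pp$tolerance %||% 2.2)
      row$pconstrained <- isTRUE(pp$constrained %||% TRUE)
    }
    row$accept_elements <- list(
      if (is.null(f$accept_elements)) NULL else unlist(f$accept_elements))
    row
  })
  features <- bind_rows(rows)
  excl <- if (length(obj$exclusions %||% list()) == 0) NULL else
    bind_rows(lapply(seq_along(obj$exclusions), function(i) {
      e <- obj$exclusions[[i]]
      if (is.null(e$center) || length(e$center) != 3)
        .schema_err(sprintf("exclusions[%d].center", i), "need 3 coordinates")
      if (is.null(e$radius))
        .schema_err(sprintf("exclusions[%d].radius", i), "missing")
      cen <- as.numeric(e$center)
      tibble(x = cen[1], y = cen[2], z = cen[3], radius = as.numeric(e$radius))
    }))
  pharmacophore(obj$name, features, excl,
                max_omitted = as.integer(obj$max_omitted %||% 0),
                provenance = obj$provenance %||% "",
                pi_exclude = obj$pi_exclude)
}

## ---- editing operations ----

#' Merge two features of the same kind
#'
#' Replaces features `f1` and `f2` by a single feature of the same kind
#' placed at the midpoint of their centers, with the given tolerance and
#' the mean of their weights. Exclusion volumes are left unchanged.
#'
#' @param model a `pharmacophore`.
#' @param f1,f2 feature indices (1-based, as printed).
#' @param new_tolerance tolerance radius of the merged feature (Angstrom).
#' @return the edited `pharmacophore`.
#' @export
merge_features <- function(model, f1, f2, new_tolerance) {
  ft <- model$features
  if (f1 == f2) abort("f1 and f2 must differ")
  if (ft$kind[f1] != ft$kind[f2]) abort("cannot merge features of different kinds")
  merged <- ft[f1, ]
  merged$x <- (ft$x[f1] + ft$x[f2]) / 2
  merged$y <- (ft$y[f1] + ft$y[f2]) / 2
  merged$z <- (ft$z[f1] + ft$z[f2]) / 2
  merged$tol <- new_tolerance
  merged$weight <- (ft$weight[f1] + ft$weight[f2]) / 2
  merged$px <- NA_real_; merged$py <- NA_real_; merged$pz <- NA_real_
  merged$ptol <- NA_real_; merged$pconstrained <- NA
  keep_idx <- setdiff(seq_len(nrow(ft)), c(f1, f2))
  before <- keep_idx[keep_idx < min(f1, f2)]
  after <- keep_idx[keep_idx >= min(f1, f2)]
  newft <- bind_rows(ft[before, ], merged, ft[after, ])
  pharmacophore(model$name, newft, model$exclusions, model$max_omitted,
                provenance = paste0(model$provenance,
                                    sprintf(" | merged features %d,%d (tol %.2f)",
                                            f1, f2, new_tolerance)),
                pi_exclude = model$pi_exclude)
}

#' Set the tolerance of one feature
#'
#' @param model a `pharmacophore`.
#' @param feature feature index.
#' @param tol new tolerance radius (Angstrom, > 0).
#' @return the edited `pharmacophore`.
#' @export
set_tolerance <- function(model, feature, tol) {
  if (tol <= 0) abort("tolerance must be > 0")
  model$features$tol[feature] <- tol
  model
}

## ---- the encoded model library ----

# Coordinates of all built-in models are constructed in a model-local,
# right-handed Angstrom frame to satisfy the distances, feature counts and
# tolerances reported for each model; no original coordinate sets are
# reused. Matching is frame-independent (ligands are aligned into the
# model frame), so any consistent embedding of the printed geometry is
# equivalent for screening.

.ring_points <- function(x0, radius, n, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  tibble(x = rep(x0, n), y = radius * cos(ang), z = radius * sin(ang),
         radius = 1.2)
}

.model_5hk1_a <- function() {
  feats <- tibble(
    kind = c("PI", "HYD", "HYD", "HYD"),
    x = c(0, -3.7, 7.8, 10.6),
    y = c(0, 0, 1.4, -0.9),
    z = c(0, 0, 0, 0.5),
    tol = c(1.6, 0.8, 1.6, 1.6),
    weight = 1)
  excl <- bind_rows(
    .ring_points(-3.7, 4.5, 8),
    .ring_points(2.5, 5.0, 4, phase = pi / 4),
    .ring_points(9.2, 5.0, 8, phase = pi / 8),
    tibble(x = -7.5, y = 0, z = 0, radius = 1.2))
  pharmacophore(
    "5HK1-Ph.A", feats, excl, max_omitted = 0,
    provenance = paste(
      "Structure-derived sigma-1 model: one positive-ionizable feature",
      "(ionic contact with Glu172/Asp126), one proximal hydrophobe at",
      "3.7 A (tolerance 0.8 A) and two distal hydrophobes at 7-13 A on",
      "the opposite side, with 21 excluded volumes for the pocket wall.",
      "Coordinates constructed to satisfy the published distances."))
}

.model_5hk1_b <- function() {
  a <- .model_5hk1_a()
  b <- merge_features(a, 3, 4, new_tolerance = 3.0)
  b <- set_tolerance(b, 2, 2.2)
  b$name <- "5HK1-Ph.B"
  b$pi_exclude <- "nonbasic_amidine"
  b$provenance <- paste(
    "Curated sigma-1 model: the two distal hydrophobes of 5HK1-Ph.A",
    "averaged into one feature at their center (tolerance 3.0 A), the",
    "proximal hydrophobe widened to 2.2 A, excluded volumes unchanged,",
    "and non-basic amidine/guanidine substructures removed from the",
    "positive-ionizable mapping.")
  b
}

.model_langer <- function() {
  feats <- tibble(
    kind = c("PI", "HYD", "HYD", "HYD", "HYD"),
    x = c(0, -3.4, 7.6, 10.4, 6.8),
    y = c(0, 0.8, 1.6, -1.0, 4.2),
    z = c(0, 0, 0.3, 0.4, -0.8),
    tol = 1.6, weight = 1)
  pharmacophore(
    "Langer-Ph", feats, NULL, max_omitted = 0,
    provenance = paste(
      "Ligand-based HypoGen-style sigma-1 model: one positive-ionizable",
      "and four hydrophobic features. Constructed coordinates; per-feature",
      "weights are user-replaceable for affinity-prediction screening."))
}

.gund_base <- function(up = TRUE) {
  zproj <- if (up) 3.0 else -3.0
  hba_dir <- c(-0.6, 0.55, 0.58)
  hba_dir <- hba_dir / sqrt(sum(hba_dir^2))
  feats <- tibble(
    kind = c("AR", "HBA"),
    x = c(8.0, 0), y = c(0.6, 0), z = c(0, 0),
    tol = 1.6, weight = 1,
    px = c(8.0, 3 * hba_dir[1]), py = c(0.6, 3 * hba_dir[2]),
    pz = c(zproj, 3 * hba_dir[3]),
    ptol = 2.2, pconstrained = TRUE)
  feats$accept_elements <- list(NULL, "N")
  pharmacophore(
    sprintf("Gund-%s-Ph", if (up) "up" else "down"), feats, NULL,
    max_omitted = 0,
    provenance = paste(
      "Reproduction of the aromatic-plus-nitrogen-acceptor sigma-1 model",
      "with a single-sided ring-normal projection",
      if (up) "(toward Tyr103)." else "(inverted).",
      "The acceptor is restricted to nitrogen atoms."))
}

.model_zampieri <- function() {
  feats <- tibble(
    kind = c("PI", "HYD", "HYD_AR", "HYD_AR", "HBA"),
    x = c(0, -3.3, 6.9, 9.6, 3.1),
    y = c(0, 0.9, 1.9, -1.2, 3.2),
    z = c(0, 0.4, 0.2, -0.3, 0.1),
    tol = 1.6, weight = 1,
    px = c(NA, NA, NA, NA, 3.1), py = c(NA, NA, NA, NA, 3.2),
    pz = c(NA, NA, NA, NA, 3.1),
    ptol = c(NA, NA, NA, NA, 2.2),
    pconstrained = c(NA, NA, NA, NA, FALSE))
  pharmacophore(
    "Zampieri-Ph", feats, NULL, max_omitted = 0,
    provenance = paste(
      "Reproduction of a benzoxazolone-series sigma-1 model: one",
      "positive-ionizable, one hydrophobe, two aromatic/hydrophobic",
      "features and a hydrogen-bond acceptor whose projection direction",
      "was not published and is therefore left unconstrained."))
}

.model_banister <- function() {
  feats <- tibble(
    kind = c("PI", "HYD", "HYD", "AR", "HBA"),
    x = c(0, 1.6, 9.8, 7.2, -2.4),
    y = c(0, -3.1, -0.8, 1.5, 2.2),
    z = c(0, 0.2, 0.3, -0.2, 0.3),
    tol = 1.6, weight = 1,
    px = c(NA, NA, NA, 7.2, -2.4), py = c(NA, NA, NA, 1.5, 2.2),
    pz = c(NA, NA, NA, 2.8, 3.3),
    ptol = c(NA, NA, NA, 2.2, 2.2),
    pconstrained = c(NA, NA, NA, FALSE, FALSE))
  pharmacophore(
    "Banister-Ph", feats, NULL, max_omitted = 0,
    provenance = paste(
      "Reproduction of an azahexacyclododecanol-series sigma-1 model;",
      "no directionality was published for the acceptor and aromatic",
      "projections, so both are serialized unconstrained."))
}

.model_glennon <- function() {
  distance_model(
    "Glennon-Ph",
    slots = tibble(slot = c("PI", "HYD_A", "HYD_B"),
                   kind = c("PI", "HYD", "HYD")),
    constraints = tibble(a = c("PI", "PI"), b = c("HYD_A", "HYD_B"),
                         dmin = c(2.5, 6), dmax = c(3.9, 10)))
}

#' Built-in sigma-1 pharmacophore model library
#'
#' Returns the encoded model collection: the structure-derived
#' `5HK1-Ph.A`, its curated derivative `5HK1-Ph.B` (distal hydrophobes
#' merged at tolerance 3.0 A, proximal hydrophobe at 2.2 A, customized
#' positive-ionizable mapping), the reproduced literature models
#' (`Langer-Ph`, `Gund-up-Ph`, `Gund-down-Ph`, `Zampieri-Ph`,
#' `Banister-Ph`) and the distance-only `Glennon-Ph`. Coordinates are
#' constructed embeddings of the published distances; each model carries
#' a provenance note.
#'
#' @return named list of `pharmacophore` / `distance_model` objects.
#' @export
builtin_models <- function() {
  list(
    `5HK1-Ph.A` = .model_5hk1_a(),
    `5HK1-Ph.B` = .model_5hk1_b(),
    `Langer-Ph` = .model_langer(),
    `Gund-up-Ph` = .gund_base(TRUE),
    `Gund-down-Ph` = .gund_base(FALSE),
    `Zampieri-Ph` = .model_zampieri(),
    `Banister-Ph` = .model_banister(),
    `Glennon-Ph` = .model_glennon())
}
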