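#' Default pharmacophoric feature definitions
#'
#' Feature kinds follow common pharmacophore practice: PI (positive
#' ionizable), HBA / HBD (hydrogen-bond acceptor / donor, each with a 3 A
#' projected point along the idealized partner direction), HYD
#' (hydrophobe, one centroid per contiguous apolar heavy-atom group) and
#' AR (aromatic ring with a 3 A normal projection). Each kind carries
#' include patterns and exclude patterns in the package's substructure
#' dialect (see [parse_smarts()]); exclusions only narrow match sets.
#'
#' The PI definition covers protonated/protonatable amines plus amidines
#' and guanidines; amides, sulfonamides and anilines are excluded by
#' default. HYD grouping is procedural (connected apolar components of at
#' least two heavy atoms) rather than pattern based.
#'
#' @return a named list, one entry per feature kind, with elements
#'   `include`, `exclude` and `rule`.
#' @export
default_feature_definitions <- function() {
  list(
    PI = list(
      include = c("[N+]",
                  "[NX3;H2]", "[NX3;H1]", "[NX3;H0]",
                  "[NX2]=[CX3]-[NX3]",               # amidine
                  "[NX2]=[CX3](-[NX3])-[NX3]"),      # guanidine
      exclude = c("[NX3]-[CX3]=[OX1]",               # amide
                  "[NX3]-[SX4]=[OX1]",               # sulfonamide
                  "[NX3]-a"),                        # aniline (weak base)
      rule = "atom_point"),
    HBA = list(
      include = c("[OX2]", "[OX1]", "[O-]", "[nX2]", "[NX2]", "[NX1]"),
      exclude = c("[N+]", "[n+]"),
      rule = "acceptor_with_lone_pair_projection"),
    HBD = list(
      include = c("[NX3;H1]", "[NX3;H2]", "[NX4+;H1]", "[NX4+;H2]",
                  "[NX4+;H3]", "[OX2;H1]", "[SX2;H1]"),
      exclude = character(0),
      rule = "acceptor_with_lone_pair_projection"),
    HYD = list(include = character(0), exclude = character(0),
               rule = "group_centroid"),
    AR = list(include = character(0), exclude = character(0),
              rule = "ring_centroid_with_normal")
  )
}

#' Restrict the positive-ionizable definition
#'
#' Adds exclusion patterns to the PI feature definition, used to drop
#' amidine/guanidine substructures that are not basic (for example
#' aryl-conjugated amidines). The returned definition set matches a
#' subset of the PI sites matched by the input set on any molecule.
#'
#' @param defs a feature definition set from
#'   [default_feature_definitions()].
#' @param excluded_substructures character vector of patterns to exclude.
#' @return the modified definition set.
#' @export
customize_pi_definition <- function(defs, excluded_substructures) {
  for (p in excluded_substructures) parse_smarts(p)  # validate early
  defs$PI$exclude <- unique(c(defs$PI$exclude, excluded_substructures))
  defs
}

#' Exclusion patterns for non-basic amidine/guanidine groups
#'
#' Named pattern set used by the curated 5HK1-Ph.B model: amidines and
#' guanidines conjugated to an aromatic ring or flanked by a carbonyl are
#' poor proton acceptors and are removed from the PI mapping.
#'
#' @return character vector of patterns.
#' @export
nonbasic_amidine_patterns <- function() {
  # each pattern covers every atom of the amidine/guanidine group so that
  # no alternative include pattern can re-claim one of its nitrogens
  c("a-[CX3](=[NX2])-[NX3]",               # aryl-conjugated amidine
    "a-[NX2]=[CX3]-[NX3]",                 # N-aryl amidine
    "[OX1]=[CX3]-[NX3]-[CX3](=[NX2])-[NX3]", # acyl guanidine
    "[OX1]=[CX3]-[NX3]-[CX3]=[NX2]",       # acyl amidine
    "[OX2]-[CX3](=[NX2])-[NX3]")           # O-substituted (isourea-like)
}

.apolar_atom_set <- function(mol) {
  env <- atom_env(mol)
  nb <- neighbors_of(mol)
  el <- mol$atoms$element
  polar <- el %in% c("N", "O", "P")
  apolar <- logical(nrow(env))
  for (i in seq_len(nrow(env))) {
    if (el[i] == "C" && mol$atoms$charge[i] == 0) {
      nbrs <- nb[[i]]
      apolar[i] <- length(nbrs) == 0 || !any(polar[nbrs])
    } else if (el[i] == "S" && mol$atoms$charge[i] == 0) {
      nbrs <- nb[[i]]
      apolar[i] <- length(nbrs) > 0 && all(el[nbrs] == "C")
    } else if (el[i] %in% c("F", "Cl", "Br", "I")) {
      nbrs <- nb[[i]]
      apolar[i] <- length(nbrs) == 1 && mol$atoms$aromatic[nbrs]
    }
  }
  apolar
}

.ring_normal <- function(coords) {
  c0 <- colMeans(coords)
  cc <- sweep(coords, 2, c0)
  sv <- svd(cc)
  nrm <- sv$v[, 3]
  nrm / sqrt(sum(nrm^2))
}

# lone-pair / donor-H direction: opposite the mean of neighbor directions;
# for an isolated atom no projection is produced
.projection_from_neighbors <- function(xyz, atom, nbrs, length_A = 3.0) {
  if (length(nbrs) == 0) return(NULL)
  p <- xyz[atom, ]
  dirs <- sweep(xyz[nbrs, , drop = FALSE], 2, p)
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs / pmax(nrm, 1e-9)
  v <- -colSums(dirs)
  nv <- sqrt(sum(v^2))
  # a (near-)linear environment has no preferred lone-pair direction;
  # such features carry no projection point (keeps perception equivariant)
  if (nv < 1e-4) return(NULL)
  p + v / nv * length_A
}

#' Perceive pharmacophoric features on a conformer
#'
#' Detects PI, HBA, HBD, HYD and AR feature points on one conformer.
#' Output order is deterministic: by kind (PI, HBA, HBD, HYD, AR), then
#' by lowest source-atom index. AR features always carry a ring-normal
#' projection point (3 A above the centroid; the mirrored point is implied
#' during matching). HYD and PI features never carry projections.
#'
#' @param mol a `phmol` with at least one conformer.
#' @param conf conformer index.
#' @param defs feature definitions (default
#'   [default_feature_definitions()]).
#' @return tibble with columns `kind`, `x`, `y`, `z`, `px`, `py`, `pz`
#'   (projection point, `NA` when absent) and `source_atoms`
#'   (list-column of atom indices).
#' @export
perceive_features <- function(mol, conf = 1, defs = default_feature_definitions()) {
  if (length(mol$confs) < conf) abort("conformer coordinates not present")
  xyz <- mol$confs[[conf]]
  nb <- neighbors_of(mol)
  rows <- list()
  add_row <- function(kind, pos, proj, atoms) {
    atoms <- sort(unique(atoms))
    rows[[length(rows) + 1]] <<- tibble(
      kind = kind, x = pos[1], y = pos[2], z = pos[3],
      px = if (is.null(proj)) NA_real_ else proj[1],
      py = if (is.null(proj)) NA_real_ else proj[2],
      pz = if (is.null(proj)) NA_real_ else proj[3],
      source_atoms = list(atoms),
      elements = list(mol$atoms$element[atoms]))
  }

  matched_sites <- function(def) {
    sites <- list()
    for (p in def$include) {
      for (mt in smarts_match(mol, p, unique_sets = TRUE)) {
        sites[[length(sites) + 1]] <- mt
      }
    }
    if (length(sites) == 0) return(sites)
    excluded_atoms <- integer(0)
    for (p in def$exclude) {
      for (mt in smarts_match(mol, p, unique_sets = TRUE)) {
        excluded_atoms <- c(excluded_atoms, mt)
      }
    }
    if (length(excluded_atoms) > 0) {
      sites <- keep(sites, function(s) !(s[1] %in% excluded_atoms))
    }
    sites
  }

  # PI: anchor is the first query atom; overlapping sites (e.g. an amidine
  # nitrogen also matching the plain amine pattern) collapse to one feature
  # per connected charged group, preferring the most specific (largest) match
  pi_sites <- matched_sites(defs$PI)
  if (length(pi_sites) > 0) {
    pi_sites <- pi_sites[order(-lengths(pi_sites),
                               vapply(pi_sites, min, integer(1)))]
    taken <- integer(0)
    for (s in pi_sites) {
      if (any(s %in% taken)) next
      taken <- c(taken, s)
      pos <- if (length(s) > 2) colMeans(xyz[s, , drop = FALSE]) else xyz[s[1], ]
      add_row("PI", pos, NULL, s)
    }
  }

  for (kind in c("HBA", "HBD")) {
    sites <- matched_sites(defs[[kind]])
    anchors <- sort(unique(vapply(sites, function(s) s[1], integer(1))))
    for (a in anchors) {
      proj <- .projection_from_neighbors(xyz, a, nb[[a]])
      add_row(kind, xyz[a, ], proj, a)
    }
  }

  apolar <- .apolar_atom_set(mol)
  if (any(apolar)) {
    sub <- igraph::induced_subgraph(mol_graph(mol), which(apolar))
    comp <- igraph::components(sub)
    vnames <- as.integer(igraph::V(sub)$name)
    for (ci in seq_len(comp$no)) {
      grp <- sort(vnames[comp$membership == ci])
      if (length(grp) < 2) next
      add_row("HYD", colMeans(xyz[grp, , drop = FALSE]), NULL, grp)
    }
  }

  for (ring in mol$aromatic_rings) {
    ring <- sort(ring)
    cen <- colMeans(xyz[ring, , drop = FALSE])
    nrm <- .ring_normal(xyz[ring, , drop = FALSE])
    add_row("AR", cen, cen + 3.0 * nrm, ring)
  }

  if (length(rows) == 0) {
    return(tibble(kind = character(), x = double(), y = double(),
                  z = double(), px = double(), py = double(), pz = double(),
                  source_atoms = list(), elements = list()))
  }
  out <- bind_rows(rows)
  kind_order <- c(PI = 1, HBA = 2, HBD = 3, HYD = 4, AR = 5)
  out <- out[order(kind_order[out$kind],
                   vapply(out$source_atoms, min, integer(1))), ]
  out
}

#' Perceive features for every conformer of a library
#'
#' @param library a library tibble from [read_library()] or
#'   [generate_ligand_library()].
#' @param defs feature definitions.
#' @return the library with a `features` list-column (one tibble per
#'   conformer of each molecule).
#' @export
perceive_library_features <- function(library, defs = default_feature_definitions()) {
  library$features <- map(library$mol, function(m)
    map(seq_along(m$confs), function(i) perceive_features(m, i, defs)))
  library
}
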