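#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter arrange select bind_rows left_join group_by summarise ungroup n row_number
#' @importFrom purrr map keep
#' @importFrom rlang abort warn .data
NULL

# Standard valences used to infer implicit hydrogen counts on heavy atoms.
.STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                  I = 1, B = 3, Si = 4, Se = 2, H = 1)

#' Construct a molecule object
#'
#' A molecule is a heavy-atom connection table (elements, bonds, formal
#' charges), zero or more 3D conformers in Angstrom, and optional
#' stereo-centre markers. Explicit hydrogens are folded into the per-atom
#' implicit hydrogen count `nH`. Aromaticity and small rings (size 5-7)
#' are perceived on construction from Kekule bond orders.
#'
#' @param id compound identifier, unique within a library.
#' @param atoms data frame with columns `element` (symbol), `charge`
#'   (integral formal charge) and optionally `nH` (total attached
#'   hydrogens; inferred from standard valences when missing).
#' @param bonds data frame with columns `a1`, `a2` (1-based atom indices)
#'   and `order` (1, 2, 3; 4 is accepted as an aromatic bond).
#' @param confs list of numeric n x 3 coordinate matrices (Angstrom).
#' @param stereo optional data frame with columns `atom` and `mark`
#'   (`"definite"`, `"racemic"` or `"grouped"`).
#' @param provenance conformer provenance: `"embedded"`,
#'   `"systematic_torsion"` or `"external_file"`.
#' @return an object of class `phmol`.
#' @export
new_molecule <- function(id, atoms, bonds, confs = list(), stereo = NULL,
                         provenance = "external_file") {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  if (nrow(atoms) == 0) abort("molecule must contain at least one atom")
  if (!all(atoms$charge == round(atoms$charge)))
    abort("formal charges must be integral")
  if (nrow(bonds) > 0 &&
      (any(bonds$a1 < 1) || any(bonds$a2 < 1) ||
       any(bonds$a1 > nrow(atoms)) || any(bonds$a2 > nrow(atoms))))
    abort("bond endpoint outside atom table")
  if (is.null(stereo)) stereo <- tibble(atom = integer(), mark = character())
  stereo <- as_tibble(stereo)
  if (nrow(stereo) > 0 && any(stereo$atom > nrow(atoms)))
    abort("stereo marker references a nonexistent atom")
  atoms$charge <- as.integer(atoms$charge)
  if (is.null(atoms$nH))
    atoms$nH <- NA_integer_
  for (cf in confs) {
    if (!is.matrix(cf) || nrow(cf) != nrow(atoms) || ncol(cf) != 3)
      abort("each conformer needs one coordinate triple per atom")
    if (!all(is.finite(cf))) abort("conformer coordinates must be finite")
  }
  mol <- structure(list(id = id, atoms = atoms, bonds = bonds,
                        confs = confs, stereo = stereo,
                        provenance = provenance),
                   class = "phmol")
  mol <- .finalize_mol(mol)
  mol
}

# fill nH, perceive rings and aromaticity
.finalize_mol <- function(mol) {
  at <- mol$atoms; bd <- mol$bonds
  bosum <- numeric(nrow(at))
  if (nrow(bd) > 0) {
    ord <- ifelse(bd$order == 4, 1.5, bd$order)
    for (k in seq_len(nrow(bd))) {
      bosum[bd$a1[k]] <- bosum[bd$a1[k]] + ord[k]
      bosum[bd$a2[k]] <- bosum[bd$a2[k]] + ord[k]
    }
  }
  need <- is.na(at$nH)
  if (any(need)) {
    val <- .STD_VALENCE[at$element]
    val[is.na(val)] <- 0
    # charge raises N valence (ammonium) and lowers O/S (alkoxide)
    adj <- ifelse(at$element %in% c("N", "P"), at$charge,
                  ifelse(at$element %in% c("O", "S"), at$charge, 0))
    nh <- pmax(0, round(val + adj - bosum))
    at$nH[need] <- as.integer(nh[need])
  }
  mol$atoms <- at
  mol$rings <- .find_rings(at, bd)
  arom <- .perceive_aromaticity(at, bd, mol$rings)
  mol$atoms$aromatic <- arom$atom
  mol$aromatic_rings <- arom$rings
  mol$bond_aromatic <- arom$bond
  mol
}

#' @export
print.phmol <- function(x, ...) {
  cat(sprintf("<molecule %s: %d heavy atoms, %d bonds, %d conformer(s)>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$confs)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

# small rings (size 3-7): for every bond, shortest alternative path between
# its endpoints; dedupe by atom set
.find_rings <- function(atoms, bonds) {
  if (nrow(bonds) < 3) return(list())
  g <- igraph::graph_from_data_frame(
    bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(atoms))))
  rings <- list()
  for (k in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, k)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(bonds$a1[k]), to = as.character(bonds$a2[k]),
      output = "vpath"))
    vp <- sp$vpath[[1]]
    if (length(vp) >= 3 && length(vp) <= 7) {
      ring <- as.integer(names(vp))
      key <- paste(sort(ring), collapse = ",")
      rings[[key]] <- ring
    }
  }
  unname(rings)
}

# Hueckel-style aromaticity on Kekule structures for 5-7 membered rings of
# C/N/O/S. Pi contributions: atom in a ring double bond -> 1; N/O/S with no
# double bond -> 2 (lone pair); sp3 carbon -> not aromatic.
.perceive_aromaticity <- function(atoms, bonds, rings) {
  n <- nrow(atoms)
  atom_arom <- rep(FALSE, n)
  bond_arom <- rep(FALSE, nrow(bonds))
  arings <- list()
  if (length(rings) == 0 || nrow(bonds) == 0)
    return(list(atom = atom_arom, bond = bond_arom, rings = arings))
  dbl_partner <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] == 2) {
      dbl_partner[[bonds$a1[k]]] <- c(dbl_partner[[bonds$a1[k]]], bonds$a2[k])
      dbl_partner[[bonds$a2[k]]] <- c(dbl_partner[[bonds$a2[k]]], bonds$a1[k])
    }
  }
  bond_key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  for (ring in rings) {
    if (length(ring) < 5 || length(ring) > 7) next
    els <- atoms$element[ring]
    if (!all(els %in% c("C", "N", "O", "S"))) next
    explicit_aromatic <- TRUE
    pi_e <- 0L; ok <- TRUE
    for (i in seq_along(ring)) {
      a <- ring[i]
      nxt <- ring[if (i == length(ring)) 1 else i + 1]
      kidx <- match(paste(min(a, nxt), max(a, nxt)), bond_key)
      if (is.na(kidx)) { ok <- FALSE; break }
      if (bonds$order[kidx] != 4) explicit_aromatic <- FALSE
      dp <- dbl_partner[[a]]
      if (length(dp) > 0 && any(dp %in% ring)) {
        pi_e <- pi_e + 1L
      } else if (atoms$element[a] %in% c("N", "O", "S") && length(dp) == 0) {
        pi_e <- pi_e + 2L
      } else if (atoms$element[a] == "C") {
        ok <- FALSE; break  # sp3 carbon (or exocyclic-only double bond)
      }
    }
    if (explicit_aromatic || (ok && pi_e == 6L)) {
      arings[[length(arings) + 1]] <- ring
      atom_arom[ring] <- TRUE
      for (i in seq_along(ring)) {
        a <- ring[i]
        nxt <- ring[if (i == length(ring)) 1 else i + 1]
        kidx <- match(paste(min(a, nxt), max(a, nxt)), bond_key)
        bond_arom[kidx] <- TRUE
      }
    }
  }
  list(atom = atom_arom, bond = bond_arom, rings = arings)
}

# heavy-atom degree and total connectivity, used by the pattern matcher
atom_env <- function(mol) {
  n <- n_atoms(mol)
  deg <- integer(n)
  if (nrow(mol$bonds) > 0) {
    tb <- table(factor(c(mol$bonds$a1, mol$bonds$a2), levels = seq_len(n)))
    deg <- as.integer(tb)
  }
  in_ring <- rep(FALSE, n)
  for (r in mol$rings) in_ring[r] <- TRUE
  tibble(idx = seq_len(n),
         element = mol$atoms$element,
         charge = mol$atoms$charge,
         nH = mol$atoms$nH,
         aromatic = mol$atoms$aromatic,
         degree = deg,
         X = deg + mol$atoms$nH,
         in_ring = in_ring)
}

neighbors_of <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  bd <- mol$bonds
  for (k in seq_len(nrow(bd))) {
    nb[[bd$a1[k]]] <- c(nb[[bd$a1[k]]], bd$a2[k])
    nb[[bd$a2[k]]] <- c(nb[[bd$a2[k]]], bd$a1[k])
  }
  nb
}

bond_order_lookup <- function(mol) {
  bd <- mol$bonds
  key <- paste(pmin(bd$a1, bd$a2), pmax(bd$a1, bd$a2))
  ord <- bd$order
  arom <- mol$bond_aromatic
  list(key = key, order = ord, aromatic = arom,
       get = function(a, b) {
         i <- match(paste(min(a, b), max(a, b)), key)
         if (is.na(i)) NULL else list(order = ord[i], aromatic = arom[i])
       })
}

## ---- conversion from/to ChemmineR SDF objects ----

.OLD_CHARGE_CODE <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)

sdf_charge_from_code <- function(code) {
  out <- integer(length(code))
  out[code == 1] <- 3L; out[code == 2] <- 2L; out[code == 3] <- 1L
  out[code == 5] <- -1L; out[code == 6] <- -2L; out[code == 7] <- -3L
  out
}

# one ChemmineR SDF record (+ raw lines for M CHG) -> phmol with 1 conformer
phmol_from_sdf <- function(sdf, id = NULL, raw_lines = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(id)) id <- ChemmineR::sdfid(sdf)
  el <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:3, drop = FALSE]
  # charge code is the 5th field of a V2000 atom line (x, y, z, mass, charge)
  charge <- if (ncol(ab) >= 5) sdf_charge_from_code(ab[, 5]) else
    integer(nrow(ab))
  if (!is.null(raw_lines)) {
    chg_lines <- grep("^M  CHG", raw_lines, value = TRUE)
    for (ln in chg_lines) {
      toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      npair <- toks[1]
      for (j in seq_len(npair)) {
        charge[toks[2 * j]] <- toks[2 * j + 1]
      }
    }
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }
  heavy <- el != "H"
  nH_explicit <- integer(sum(heavy))
  if (!all(heavy)) {
    hidx <- which(!heavy)
    keep_map <- cumsum(heavy)
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]
      if (!heavy[a] && heavy[b]) nH_explicit[keep_map[b]] <- nH_explicit[keep_map[b]] + 1L
      if (heavy[a] && !heavy[b]) nH_explicit[keep_map[a]] <- nH_explicit[keep_map[a]] + 1L
    }
    bonds <- bonds[heavy[bonds$a1] & heavy[bonds$a2], , drop = FALSE]
    bonds$a1 <- keep_map[bonds$a1]; bonds$a2 <- keep_map[bonds$a2]
    coords <- coords[heavy, , drop = FALSE]
    el <- el[heavy]; charge <- charge[heavy]
  }
  atoms <- tibble(element = el, charge = as.integer(charge), nH = NA_integer_)
  confs <- list()
  if (any(coords != 0) || nrow(coords) == 1) {
    cm <- unname(as.matrix(coords)); dimnames(cm) <- NULL
    confs <- list(cm)
  }
  m <- new_molecule(id = id, atoms = atoms, bonds = bonds, confs = confs)
  # explicit hydrogens stripped above take precedence over valence inference
  if (!all(heavy)) {
    m$atoms$nH <- pmax(m$atoms$nH, nH_explicit)
  }
  m
}

#' Parse a SMILES string into a molecule
#'
#' Uses OpenBabel (through ChemmineR) for the SMILES grammar; the result is
#' converted to the package's heavy-atom connection table. No 3D
#' coordinates are attached.
#'
#' @param smiles a single SMILES string.
#' @param id compound identifier (default: the SMILES string itself).
#' @return a `phmol`.
#' @export
parse_smiles <- function(smiles, id = smiles) {
  sdfset <- ChemmineR::smiles2sdf(smiles)
  m <- phmol_from_sdf(sdfset[[1]], id = id)
  m$confs <- list()  # 2D layout from the SMILES converter is not a conformer
  m
}

# V2000 SDF text for one conformer of a molecule (heavy atoms only)
mol_to_sdf_text <- function(mol, conf = 1) {
  n <- n_atoms(mol)
  if (length(mol$confs) >= conf) {
    xyz <- mol$confs[[conf]]
  } else {
    xyz <- matrix(0, n, 3)
  }
  hdr <- c(mol$id, "  sigmaphore", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    n, nrow(mol$bonds))
  atoms <- vapply(seq_len(n), function(i) {
    code <- 0L
    ch <- mol$atoms$charge[i]
    if (ch >= 1 && ch <= 3) code <- 4L - ch
    if (ch <= -1 && ch >= -3) code <- 4L - ch
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            xyz[i, 1], xyz[i, 2], xyz[i, 3], mol$atoms$element[i], code)
  }, character(1))
  bonds <- vapply(seq_len(nrow(mol$bonds)), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1[k], mol$bonds$a2[k],
            mol$bonds$order[k])
  }, character(1))
  chg <- which(mol$atoms$charge != 0)
  mlines <- character(0)
  if (length(chg) > 0) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      mlines <- c(mlines, paste0(
        "M  CHG", sprintf("%3d", length(grp)),
        paste0(vapply(grp, function(i)
          sprintf("%4d%4d", i, mol$atoms$charge[i]), character(1)),
          collapse = "")))
    }
  }
  c(hdr, counts, atoms, bonds, mlines, "M  END", "$$$$")
}

# character lines -> SDFstr; the coercion is registered when the
# ChemmineR namespace loads, which plain methods::as does not guarantee
as_sdfstr <- function(lines) {
  loadNamespace("ChemmineR")
  methods::as(lines, "SDFstr")
}

# molecule (all conformers) -> ChemmineR SDFset
mol_to_sdfset <- function(mol) {
  nconf <- max(1L, length(mol$confs))
  txt <- unlist(lapply(seq_len(nconf), function(i) mol_to_sdf_text(mol, i)))
  ChemmineR::read.SDFset(as_sdfstr(txt))
}

apply_rigid <- function(coords, rot, trans) {
  sweep(coords %*% t(rot), 2, trans, `+`)
}

random_rotation <- function() {
  # QR-based uniform random rotation
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
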