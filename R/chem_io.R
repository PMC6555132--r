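#' Read a ligand library from SMILES or SDF
#'
#' SMILES files hold one record per line (`SMILES[ id]`); SD files may
#' hold several records per compound identifier (multi-conformer
#' libraries), which are merged into one molecule with a conformer per
#' record. Unparseable records are skipped with a warning; an empty file
#' is an error.
#'
#' @param path input file.
#' @param format `"smiles"` or `"sdf"` (default: guessed from the file
#'   extension).
#' @return a library tibble with columns `id`, `mol` (list-column of
#'   `phmol`), `n_conformers` and `provenance`.
#' @export
read_library <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- if (grepl("\\.(smi|smiles|txt)$", path, ignore.case = TRUE))
      "smiles" else "sdf"
  }
  format <- match.arg(format, c("smiles", "sdf"))
  mols <- list()
  n_bad <- 0L
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) abort("empty library file")
    for (k in seq_along(lines)) {
      toks <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      smi <- toks[1]
      id <- if (length(toks) >= 2) toks[2] else sprintf("mol%04d", k)
      m <- tryCatch(parse_smiles(smi, id = id), error = function(e) NULL)
      if (is.null(m)) {
        warn(sprintf("skipping unparseable record %d ('%s')", k, smi))
        n_bad <- n_bad + 1L
        next
      }
      mols[[length(mols) + 1]] <- m
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    if (length(txt) == 0 || !any(grepl("\\$\\$\\$\\$", txt)))
      abort("empty library file")
    # split records on $$$$ and parse each independently so one corrupt
    # record does not abort the read
    ends <- grep("^\\$\\$\\$\\$", txt)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    for (k in seq_along(ends)) {
      rec <- txt[starts[k]:ends[k]]
      if (all(!nzchar(trimws(rec)))) next
      m <- tryCatch({
        sdfstr <- as_sdfstr(c(rec))
        sdfset <- suppressWarnings(ChemmineR::read.SDFset(sdfstr))
        ChemmineR::validSDF(sdfset)
        sdf <- sdfset[[1]]
        id <- trimws(ChemmineR::header(sdf)[[1]])
        if (!nzchar(id)) id <- sprintf("mol%04d", k)
        phmol_from_sdf(sdf, id = id, raw_lines = rec)
      }, error = function(e) NULL)
      if (is.null(m) || n_atoms(m) == 0) {
        warn(sprintf("skipping unparseable SDF record %d", k))
        n_bad <- n_bad + 1L
        next
      }
      mols[[length(mols) + 1]] <- m
    }
  }
  if (length(mols) == 0)
    abort(sprintf("no valid records in %s (%d skipped)", path, n_bad))
  if (n_bad > 0)
    message(sprintf("read %d records, skipped %d unparseable", length(mols), n_bad))
  # merge records sharing an id into one molecule with several conformers
  ids <- vapply(mols, function(m) m$id, character(1))
  merged <- list()
  for (uid in unique(ids)) {
    grp <- mols[ids == uid]
    base <- grp[[1]]
    if (length(grp) > 1) {
      for (m2 in grp[-1]) {
        if (n_atoms(m2) != n_atoms(base) ||
            !identical(m2$atoms$element, base$atoms$element)) {
          warn(sprintf(
            "records with id %s differ in structure; keeping separate conformers of the first",
            uid))
          next
        }
        base$confs <- c(base$confs, m2$confs)
      }
    }
    merged[[length(merged) + 1]] <- base
  }
  tibble(id = vapply(merged, function(m) m$id, character(1)),
         mol = merged,
         n_conformers = vapply(merged, function(m) length(m$confs), integer(1)),
         provenance = "external_file")
}

#' Write a library to an SD file
#'
#' Each conformer of each molecule becomes one record, repeated records
#' sharing the compound id (the multi-conformer convention read back by
#' [read_library()]). Coordinates are written at 1e-4 Angstrom precision.
#'
#' @param library library tibble.
#' @param path output path.
#' @export
write_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in library$mol) {
    nconf <- max(1L, length(m$confs))
    for (cf in seq_len(nconf)) {
      writeLines(mol_to_sdf_text(m, cf), con)
    }
  }
  invisible(path)
}

#' Classify experimental sigma-1 activity annotations
#'
#' A compound is active when its Ki is at or below 1000 nM (1 uM);
#' inactive when Ki exceeds 1000 nM, or when Ki was not determined
#' because the percentage inhibition at 1 uM was below 50; unknown
#' otherwise. Vectorized; classification is a pure function of the two
#' annotations.
#'
#' @param ki_nM Ki in nM (`NA` when not determined); negative values are
#'   an error.
#' @param inhibition_pct percent inhibition at 1 uM (`NA` allowed when
#'   `ki_nM` is present).
#' @return character vector: `"active"`, `"inactive"` or `"unknown"`.
#' @export
classify_activity <- function(ki_nM = NULL, inhibition_pct = NULL) {
  if (is.null(ki_nM) && is.null(inhibition_pct))
    abort("at least one of ki_nM and inhibition_pct must be given")
  n <- max(length(ki_nM), length(inhibition_pct))
  if (is.null(ki_nM)) ki_nM <- rep(NA_real_, n)
  if (is.null(inhibition_pct)) inhibition_pct <- rep(NA_real_, n)
  ki_nM <- rep_len(ki_nM, n); inhibition_pct <- rep_len(inhibition_pct, n)
  if (any(is.na(ki_nM) & is.na(inhibition_pct)))
    abort("record with neither Ki nor inhibition annotation")
  if (any(!is.na(ki_nM) & ki_nM < 0)) abort("negative Ki")
  if (any(!is.na(inhibition_pct) & inhibition_pct > 100))
    abort("inhibition percentage above 100")
  dplyr::case_when(
    !is.na(ki_nM) & ki_nM <= 1000 ~ "active",
    !is.na(ki_nM) & ki_nM > 1000 ~ "inactive",
    is.na(ki_nM) & inhibition_pct < 50 ~ "inactive",
    TRUE ~ "unknown")
}

#' Label a library's activity records
#'
#' @param activity data frame with columns `compound_id` and `ki_nM`
#'   and/or `inhib_pct_1uM`.
#' @return the input with a `label` column appended.
#' @export
label_activities <- function(activity) {
  ki <- activity$ki_nM
  inh <- activity$inhib_pct_1uM %||% activity$inhibition_pct_1uM
  activity$label <- classify_activity(ki, inh)
  as_tibble(activity)
}

## ---- ionization-state enumeration ----

#' Built-in pKa assignment rules
#'
#' A small substructure-rule table standing in for a full pKa predictor:
#' aliphatic amines (~10.5), amidines (~11.1), anilines (~4.6),
#' carboxylic acids (~4.2), phenols (~10.0) and tetrazoles (~4.9). Each
#' rule names the query-atom index that is the ionizable site and
#' patterns that veto a match (amides are not basic amines). Users may
#' override per-atom via the `pka_table` argument of
#' [enumerate_ionization_states()].
#'
#' @return tibble with columns `name`, `pattern`, `not` (list-column),
#'   `anchor`, `type` (`basic`/`acidic`), `pka`.
#' @export
default_pka_rules <- function() {
  tibble(
    name = c("amidine", "tetrazole", "carboxylic_acid", "phenol",
             "aniline", "aliphatic_amine"),
    pattern = c("[NX2]=[CX3]-[NX3]", "[nX3;H1]1[nX2][nX2][nX2]c1",
                "[CX3](=[OX1])-[OX2;H1]", "a-[OX2;H1]",
                "[NX3]-a", "[NX3]"),
    not = list(character(0), character(0), character(0), character(0),
               character(0),
               c("[NX3]-[CX3]=[OX1]", "[NX3]-[SX4]=[OX1]", "[NX3]-a",
                 "[NX3]-[CX3]=[NX2]")),
    anchor = c(1L, 1L, 3L, 2L, 1L, 1L),
    type = c("basic", "acidic", "acidic", "acidic", "basic", "basic"),
    pka = c(11.1, 4.9, 4.2, 10.0, 4.6, 10.5))
}

#' Find ionizable sites on a molecule
#'
#' @param mol a `phmol`.
#' @param rules rule table (see [default_pka_rules()]).
#' @return tibble with columns `atom`, `rule`, `type`, `pka`; each atom
#'   is claimed by at most one rule (rule-table order decides).
#' @export
find_ionizable_sites <- function(mol, rules = default_pka_rules()) {
  out <- list()
  claimed <- integer(0)
  for (i in seq_len(nrow(rules))) {
    matches <- smarts_match(mol, rules$pattern[i], unique_sets = TRUE)
    if (length(matches) == 0) next
    veto <- integer(0)
    for (p in rules$not[[i]]) {
      for (mt in smarts_match(mol, p, unique_sets = TRUE)) veto <- c(veto, mt[1])
    }
    for (mt in matches) {
      a <- mt[rules$anchor[i]]
      if (a %in% claimed || a %in% veto) next
      claimed <- c(claimed, a)
      out[[length(out) + 1]] <- tibble(atom = a, rule = rules$name[i],
                                       type = rules$type[i], pka = rules$pka[i])
    }
  }
  if (length(out) == 0)
    return(tibble(atom = integer(), rule = character(), type = character(),
                  pka = double()))
  arrange(bind_rows(out), .data$atom)
}

#' Enumerate ionization states at pH threshold 5
#'
#' Starting from the neutral input, basic sites with pKa above 5 are
#' protonated and acidic sites with pKa below 5 deprotonated,
#' successively (each new state built on the previous one); every
#' intermediate joins the pool, the neutral input is always retained and
#' duplicate states are removed. Re-running on any output state adds no
#' new states.
#'
#' @param mol a `phmol` (neutral input).
#' @param pka_table optional per-atom override: data frame with columns
#'   `atom`, `type` (`basic`/`acidic`) and `pka`. Sites referencing
#'   nonexistent atoms are an error.
#' @param ph_threshold pKa cutoff (default 5).
#' @return list of `phmol` states; each carries an `applied_rules`
#'   data frame field (`atom`, `action`, `pka`).
#' @export
enumerate_ionization_states <- function(mol, pka_table = NULL,
                                        ph_threshold = 5) {
  sites <- if (is.null(pka_table)) find_ionizable_sites(mol) else {
    pk <- as_tibble(pka_table)
    if (any(pk$atom > n_atoms(mol)))
      abort("pKa table references a nonexistent atom")
    pk$rule <- pk[["rule"]] %||% "user"
    pk[, c("atom", "rule", "type", "pka")]
  }
  act <- sites[(sites$type == "basic" & sites$pka > ph_threshold) |
                 (sites$type == "acidic" & sites$pka < ph_threshold), ]
  neutral <- mol
  neutral$applied_rules <- tibble(atom = integer(), action = character(),
                                  pka = double())
  pool <- list(neutral)
  state_key <- function(m) paste(m$atoms$charge, collapse = ",")
  seen <- state_key(neutral)
  cur <- neutral
  if (nrow(act) > 0) {
    for (i in seq_len(nrow(act))) {
      a <- act$atom[i]
      nxt <- cur
      if (act$type[i] == "basic") {
        if (nxt$atoms$charge[a] > 0) next  # already protonated
        nxt$atoms$charge[a] <- nxt$atoms$charge[a] + 1L
        nxt$atoms$nH[a] <- nxt$atoms$nH[a] + 1L
        action <- "protonate"
      } else {
        if (nxt$atoms$nH[a] < 1 || nxt$atoms$charge[a] < 0) next
        nxt$atoms$charge[a] <- nxt$atoms$charge[a] - 1L
        nxt$atoms$nH[a] <- nxt$atoms$nH[a] - 1L
        action <- "deprotonate"
      }
      nxt$applied_rules <- bind_rows(cur$applied_rules,
                                     tibble(atom = a, action = action,
                                            pka = act$pka[i]))
      key <- state_key(nxt)
      if (!(key %in% seen)) {
        pool[[length(pool) + 1]] <- nxt
        seen <- c(seen, key)
      }
      cur <- nxt
    }
  }
  pool
}

## ---- conformer generation ----

.hybridization <- function(mol) {
  n <- n_atoms(mol)
  hyb <- rep("sp3", n)
  bd <- mol$bonds
  for (k in seq_len(nrow(bd))) {
    if (bd$order[k] == 2 || mol$bond_aromatic[k]) {
      hyb[bd$a1[k]] <- "sp2"; hyb[bd$a2[k]] <- "sp2"
    }
    if (bd$order[k] == 3) {
      hyb[bd$a1[k]] <- "sp"; hyb[bd$a2[k]] <- "sp"
    }
  }
  hyb
}

best_fit_rmsd <- function(a, b) {
  tf <- kabsch(a, b)
  sqrt(mean(rowSums((apply_rigid(a, tf$rot, tf$trans) - b)^2)))
}

.embed_3d <- function(mol) {
  sdfset <- mol_to_sdfset(mol)
  out <- tryCatch(ChemmineR::generate3DCoords(sdfset[1]),
                  error = function(e) NULL)
  if (is.null(out)) return(NULL)
  m2 <- tryCatch(phmol_from_sdf(out[[1]], id = mol$id), error = function(e) NULL)
  if (is.null(m2) || length(m2$confs) == 0) return(NULL)
  if (n_atoms(m2) != n_atoms(mol)) return(NULL)
  m2$confs[[1]]
}

#' Generate a conformer ensemble
#'
#' `mode = "systematic"` drives every rotatable bond on the conventional
#' torsion grid - 60 degree increments for sp3-sp3 and sp3-sp2 bonds,
#' 180 degrees for sp2-sp2 - starting from an embedded geometry, then
#' removes near-duplicates (heavy-atom best-fit RMSD below 0.3 A).
#' `mode = "embed"` uses distance-geometry embedding (OpenBabel) for the
#' base geometry plus torsion sampling for additional conformers. For
#' molecules with racemic or grouped stereo markers both mirror-image
#' forms are generated and pooled under the one compound id. Energies
#' are never attached: downstream matching consumes geometries only.
#'
#' @param mol a `phmol`.
#' @param max_confs maximum conformers returned (>= 1).
#' @param mode `"embed"` or `"systematic"`.
#' @return the molecule with `confs` replaced by the ensemble and
#'   `provenance` set.
#' @export
generate_conformers <- function(mol, max_confs = 10,
                                mode = c("embed", "systematic")) {
  mode <- match.arg(mode)
  if (max_confs < 1) abort("max_confs must be >= 1")
  base <- if (length(mol$confs) > 0) mol$confs[[1]] else .embed_3d(mol)
  if (is.null(base)) abort(sprintf("could not embed molecule %s", mol$id))
  rb <- rotatable_bonds(mol)
  hyb <- .hybridization(mol)
  torsion_grid <- function(k) {
    h1 <- hyb[rb$a1[k]]; h2 <- hyb[rb$a2[k]]
    if (h1 == "sp2" && h2 == "sp2") c(0, 180) else c(0, 60, 120, 180, 240, 300)
  }
  confs <- list(base)
  if (nrow(rb) > 0) {
    sides <- lapply(seq_len(nrow(rb)), function(k)
      .bond_side(mol, rb$a1[k], rb$a2[k]))
    grids <- lapply(seq_len(nrow(rb)), torsion_grid)
    combos <- do.call(expand.grid, grids)
    cap <- if (mode == "systematic") 4096L else 256L
    if (nrow(combos) > cap) combos <- combos[seq_len(cap), , drop = FALSE]
    for (ci in seq_len(nrow(combos))) {
      if (length(confs) >= max_confs) break
      cc <- base
      for (k in seq_len(nrow(rb))) {
        ang <- combos[ci, k]
        if (ang == 0) next
        cc <- rotate_about_bond(cc, rb$a1[k], rb$a2[k], sides[[k]], ang)
      }
      dup <- any(vapply(confs, function(old)
        best_fit_rmsd(cc, old) < 0.3, logical(1)))
      if (!dup) confs[[length(confs) + 1]] <- cc
    }
  }
  # racemic / grouped stereo: pool both mirror-image forms under one id
  if (nrow(mol$stereo) > 0 && any(mol$stereo$mark %in% c("racemic", "grouped"))) {
    mirrored <- lapply(confs, function(cc) {
      cc[, 3] <- -cc[, 3]
      cc
    })
    confs <- c(confs, mirrored)
    if (length(confs) > max_confs) {
      # keep an even split of the two enantiomers
      half <- ceiling(max_confs / 2)
      confs <- c(confs[seq_len(min(half, length(mirrored)))],
                 mirrored[seq_len(max_confs - min(half, length(mirrored)))])
    }
  }
  if (length(confs) > max_confs) confs <- confs[seq_len(max_confs)]
  if (length(confs) == 0) abort(sprintf("no conformers for %s", mol$id))
  mol$confs <- confs
  mol$provenance <- if (mode == "systematic") "systematic_torsion" else "embedded"
  mol
}
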