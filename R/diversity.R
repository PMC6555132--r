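#' Fingerprint specification
#'
#' Three descriptor families are available: `circular_atom_type`
#' (extended-connectivity style environments keyed on element, degree,
#' hydrogen count, charge, aromaticity and ring membership),
#' `circular_functional_class` (the same environments keyed on
#' pharmacophoric classes: donor, acceptor, positively/negatively
#' ionizable, aromatic, halogen) and `structural_keys` (the public
#' MACCS-type key set, computed through OpenBabel). `diameter` is the
#' maximal environment width in bonds for the circular families (4 or 6,
#' i.e. radius 2 or 3).
#'
#' @param family fingerprint family.
#' @param diameter even integer, 4 or 6 (circular families only).
#' @return a `fingerprint_spec`.
#' @export
fingerprint_spec <- function(family = c("circular_atom_type",
                                        "circular_functional_class",
                                        "structural_keys"),
                             diameter = 4) {
  family <- match.arg(family)
  if (family != "structural_keys" && !(diameter %in% c(4, 6)))
    abort("diameter must be 4 or 6 for circular fingerprints")
  structure(list(family = family, diameter = as.integer(diameter)),
            class = "fingerprint_spec")
}

.atom_invariants <- function(mol, functional_class = FALSE) {
  env <- atom_env(mol)
  if (!functional_class) {
    sprintf("%s|%d|%d|%d|%d|%d", env$element, env$degree, env$nH, env$charge,
            as.integer(env$aromatic), as.integer(env$in_ring))
  } else {
    defs <- default_feature_definitions()
    mark <- function(patterns) {
      hit <- logical(nrow(env))
      for (p in patterns) {
        for (mt in smarts_match(mol, p, unique_sets = TRUE)) hit[mt[1]] <- TRUE
      }
      hit
    }
    don <- mark(defs$HBD$include)
    acc <- mark(defs$HBA$include)
    pos <- mark(defs$PI$include)
    neg <- env$charge < 0 | mark(c("[CX3](=[OX1])-[OX2;H1]"))
    halo <- env$element %in% c("F", "Cl", "Br", "I")
    sprintf("%d%d%d%d%d%d", as.integer(don), as.integer(acc), as.integer(pos),
            as.integer(neg), as.integer(env$aromatic), as.integer(halo))
  }
}

.circular_fp <- function(mol, diameter, functional_class) {
  ids <- .atom_invariants(mol, functional_class)
  nb <- neighbors_of(mol)
  bl <- bond_order_lookup(mol)
  n <- n_atoms(mol)
  feats <- paste0("r0:", unique(ids))
  if (n > 1) {
    for (r in seq_len(diameter / 2)) {
      new_ids <- character(n)
      for (i in seq_len(n)) {
        nbrs <- nb[[i]]
        if (length(nbrs) == 0) {
          new_ids[i] <- paste0(r, "(", ids[i], ")")
          next
        }
        parts <- vapply(nbrs, function(j) {
          b <- bl$get(i, j)
          bt <- if (isTRUE(b$aromatic)) "a" else as.character(b$order)
          paste0(bt, ":", ids[j])
        }, character(1))
        new_ids[i] <- paste0(r, "(", ids[i], "|", paste(sort(parts),
                                                        collapse = ","), ")")
      }
      ids <- new_ids
      feats <- c(feats, paste0("r", r, ":", unique(ids)))
    }
  }
  sort(unique(feats))
}

.maccs_fp <- function(mol) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    abort("structural_keys fingerprints require the ChemmineOB package")
  sdfset <- ChemmineR::read.SDFset(as_sdfstr(mol_to_sdf_text(mol, 1)))
  ChemmineR::cid(sdfset) <- mol$id
  fp <- ChemmineR::fingerprintOB(sdfset, "MACCS")
  bits <- which(methods::slot(fp, "fpma")[1, ] == 1)
  paste0("key", bits)
}

#' Compute a molecular fingerprint
#'
#' @param mol a `phmol`.
#' @param spec a [fingerprint_spec()].
#' @return character vector: the set of hashed environment identifiers
#'   (circular families) or set key names (structural keys). Tanimoto
#'   arithmetic treats fingerprints as sets.
#' @export
fingerprint <- function(mol, spec = fingerprint_spec()) {
  if (is.null(mol) || n_atoms(mol) == 0) abort("empty molecule")
  switch(spec$family,
         circular_atom_type = .circular_fp(mol, spec$diameter, FALSE),
         circular_functional_class = .circular_fp(mol, spec$diameter, TRUE),
         structural_keys = .maccs_fp(mol))
}

#' Tanimoto distance between two fingerprints
#'
#' `1 - |A intersect B| / |A union B|`; zero iff the fingerprints are
#' identical sets, at most one.
#'
#' @param a,b fingerprints (character sets).
#' @return numeric in [0, 1].
#' @export
tanimoto_distance <- function(a, b) {
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - i / u
}

#' Pairwise Tanimoto diversity of a compound set
#'
#' Computes all pairwise Tanimoto distances of the library under the
#' given fingerprint, and their mean, median and mode. The mode is taken
#' on a 0.01-wide histogram and reported at the bin center; ties between
#' bins break toward the lower bin.
#'
#' @param library library tibble (columns `id`, `mol`), at least 2
#'   compounds.
#' @param spec a [fingerprint_spec()].
#' @return a `diversity_report`: n_compounds, n_pairs, mean, median,
#'   mode, the histogram and the distance vector.
#' @export
pairwise_diversity <- function(library, spec = fingerprint_spec()) {
  if (nrow(library) < 2) abort("need at least 2 molecules")
  fps <- lapply(library$mol, fingerprint, spec = spec)
  n <- length(fps)
  d <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      k <- k + 1L
      d[k] <- tanimoto_distance(fps[[i]], fps[[j]])
    }
  }
  edges <- seq(0, 1, by = 0.01)
  # right-closed bins, distance 0 in the first bin; 1.0 in the last
  bin <- pmin(pmax(ceiling(d / 0.01), 1L), 100L)
  counts <- tabulate(bin, nbins = 100L)
  mode_bin <- which.max(counts)  # which.max takes the first (lower) tie
  structure(list(
    n_compounds = n,
    n_pairs = length(d),
    mean = mean(d),
    median = stats::median(d),
    mode = edges[mode_bin] + 0.005,
    histogram = tibble(bin_low = edges[seq_len(100)],
                       bin_high = edges[seq_len(100) + 1],
                       mid = edges[seq_len(100)] + 0.005,
                       count = counts),
    distances = d,
    spec = spec), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    "<diversity: %d compounds, %d pairs (%s%s)>\n  mean %.3f  median %.3f  mode %.3f\n",
    x$n_compounds, x$n_pairs, x$spec$family,
    if (x$spec$family == "structural_keys") "" else
      sprintf(", diameter %d", x$spec$diameter),
    x$mean, x$median, x$mode))
  invisible(x)
}

#' Tidy a diversity report
#' @param x a `diversity_report`.
#' @param ... unused.
#' @return one-row tibble of the summary statistics.
#' @export
tidy.diversity_report <- function(x, ...) {
  tibble(family = x$spec$family,
         diameter = if (x$spec$family == "structural_keys") NA_integer_ else
           x$spec$diameter,
         n_compounds = x$n_compounds, n_pairs = x$n_pairs,
         mean = x$mean, median = x$median, mode = x$mode)
}

#' Histogram of pairwise Tanimoto distances
#'
#' @param object a `diversity_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.diversity_report <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 0.01, fill = "#4393c3") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(x = "Pairwise Tanimoto distance", y = "Pair count",
                  title = sprintf("Diversity (mean %.2f, median %.2f, mode %.2f)",
                                  object$mean, object$median, object$mode)) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
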