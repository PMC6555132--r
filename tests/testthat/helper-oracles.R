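# Independent brute-force oracle for the matcher: enumerate EVERY injective
# kind-compatible assignment of model features to ligand features (no
# distance pruning, no shared code with enumerate_hypotheses), score each
# with align_and_score and keep the best by (qualifies, fit value, smaller
# max displacement, lexicographically smallest assignment).

oracle_all_assignments <- function(model_kinds, lig_kinds) {
  nf <- length(model_kinds); nl <- length(lig_kinds)
  compat <- function(mk, lk) if (mk == "HYD_AR") lk %in% c("HYD", "AR") else mk == lk
  res <- list()
  rec <- function(i, cur) {
    if (i > nf) { res[[length(res) + 1]] <<- cur; return(invisible(NULL)) }
    for (j in seq_len(nl)) {
      if (j %in% cur) next
      if (!compat(model_kinds[i], lig_kinds[j])) next
      rec(i + 1, c(cur, j))
    }
    invisible(NULL)
  }
  rec(1, integer(0))
  res
}

oracle_best_fit <- function(model, mol) {
  best <- NULL
  best_key <- NULL
  for (cf in seq_along(mol$confs)) {
    feats <- perceive_features(mol, cf)
    if (nrow(feats) == 0) next
    assigns <- oracle_all_assignments(model$features$kind, feats$kind)
    for (as_ in assigns) {
      hyp <- list(assignment = as_, omitted = integer(0))
      fr <- align_and_score(model, feats, mol$confs[[cf]], hyp)
      maxd <- if (length(fr$displacements)) max(fr$displacements) else 0
      key <- list(q = fr$qualifies, fv = fr$fit_value, md = maxd,
                  lex = paste(as_, collapse = ","), conf = cf)
      better <- is.null(best_key) ||
        (key$q && !best_key$q) ||
        (key$q == best_key$q && key$fv > best_key$fv + 1e-12) ||
        (key$q == best_key$q && abs(key$fv - best_key$fv) <= 1e-12 &&
           key$md < best_key$md - 1e-12) ||
        (key$q == best_key$q && abs(key$fv - best_key$fv) <= 1e-12 &&
           abs(key$md - best_key$md) <= 1e-12 && key$lex < best_key$lex)
      if (better) { best <- fr; best$conformer <- cf; best_key <- key }
    }
  }
  best
}

# random small instance: a 2-4 feature model of PI/HYD/AR kinds plus one
# posed molecule (an active with generous jitter, so hypotheses are
# plentiful but not always qualifying)
random_small_instance <- function(seed) {
  set.seed(seed)
  nf <- sample(2:4, 1)
  kinds <- c("PI", sample(c("HYD", "HYD", "AR"), nf - 1, replace = TRUE))
  repeat {
    pos <- matrix(stats::runif(nf * 3, -6, 6), nf, 3)
    if (nf < 2 || min(stats::dist(pos)) > 3.5) break
  }
  feats <- tibble::tibble(kind = kinds, x = pos[, 1], y = pos[, 2],
                          z = pos[, 3],
                          tol = stats::runif(nf, 1.0, 2.0), weight = 1)
  model <- pharmacophore(sprintf("rnd%03d", seed), feats)
  jitter <- stats::runif(1, 0.2, 1.2)
  mol <- sigmaphore:::.build_posed_molecule(model, jitter, NA,
                                            sprintf("m%03d", seed))
  # occasionally add a second, more distorted conformer
  if (stats::runif(1) < 0.5) {
    m2 <- sigmaphore:::.build_posed_molecule(model, jitter + 0.8, NA, mol$id)
    if (nrow(m2$atoms) == nrow(mol$atoms))
      mol$confs <- c(mol$confs, m2$confs)
  }
  list(model = model, mol = mol)
}
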