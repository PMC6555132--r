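#' Attach activity labels to a screening ranking
#'
#' @param ranking ranking tibble from [screen_library()].
#' @param activity data frame with `compound_id` and either a `label`
#'   column or `ki_nM` / `inhib_pct_1uM` annotations.
#' @return the ranking with a `label` column.
#' @export
join_activity <- function(ranking, activity) {
  if (is.null(activity$label)) activity <- label_activities(activity)
  out <- left_join(ranking, activity[, c("compound_id", "label")],
                   by = "compound_id")
  if (any(is.na(out$label)))
    abort("activity annotation missing for some compounds")
  out
}

.check_ranking <- function(ranking) {
  if (!all(c("score", "label") %in% names(ranking)))
    abort("ranking needs 'score' and 'label' columns")
  if (!all(ranking$label %in% c("active", "inactive")))
    abort("labels must be 'active' or 'inactive' (drop unknowns first)")
  if (any(is.infinite(ranking$score), na.rm = TRUE))
    abort("scores must be finite (use NA for non-hits)")
  invisible(ranking)
}

# round half away from zero, floor 1
.n_selected <- function(n_total, x_pct) {
  max(1L, as.integer(floor(n_total * x_pct / 100 + 0.5)))
}

# expected active/selected counts at a cut of n_sel, with tie groups
# (including the NA non-hit mass) split by expectation
.selection_counts <- function(ranking, n_sel) {
  sc <- ifelse(is.na(ranking$score), -Inf, ranking$score)
  act <- ranking$label == "active"
  grp <- split(seq_along(sc), factor(-sc))  # descending score groups
  taken <- 0; a_sel <- 0
  for (g in grp) {
    if (taken >= n_sel) break
    gs <- length(g); ga <- sum(act[g])
    if (taken + gs <= n_sel) {
      a_sel <- a_sel + ga
      taken <- taken + gs
    } else {
      frac <- (n_sel - taken) / gs
      a_sel <- a_sel + ga * frac
      taken <- n_sel
    }
  }
  list(n_sel = n_sel, actives_sel = a_sel)
}

#' Enrichment factor at a database fraction
#'
#' The density of active compounds in the top x percent of the ranking,
#' relative to the active density of the whole database:
#' `EF = (Actives_sel / N_sel) / (Actives_total / N_total)`. The
#' selection size is x percent of the database rounded half away from
#' zero (minimum 1). Tie groups straddling the cut (including the tied
#' non-hit mass) contribute their expected active count, so the result
#' does not depend on an arbitrary ordering of tied compounds.
#'
#' @param ranking tibble with `score` (`NA` for non-hits) and `label`.
#' @param x_pct selection fraction in percent, in (0, 100].
#' @return the enrichment factor (>= 0).
#' @export
enrichment_factor <- function(ranking, x_pct) {
  .check_ranking(ranking)
  if (x_pct <= 0 || x_pct > 100) abort("x_pct must be in (0, 100]")
  n <- nrow(ranking)
  a_tot <- sum(ranking$label == "active")
  if (a_tot == 0) abort("enrichment undefined: no actives in the database")
  cnt <- .selection_counts(ranking, .n_selected(n, x_pct))
  (cnt$actives_sel / cnt$n_sel) / (a_tot / n)
}

#' Ideal enrichment factor of a database composition
#'
#' The enrichment factor obtained when the top selection is filled with
#' actives first: `min(Actives_total, N_sel)/N_sel / (Actives_total/N_total)`.
#'
#' @param n_total database size.
#' @param actives_total number of actives.
#' @param x_pct selection fraction in percent.
#' @return the ideal enrichment factor.
#' @export
ideal_enrichment_factor <- function(n_total, actives_total, x_pct) {
  n_sel <- .n_selected(n_total, x_pct)
  (min(actives_total, n_sel) / n_sel) / (actives_total / n_total)
}

#' Hit rate at a database fraction
#'
#' The quotient of the real and the ideal enrichment factor, as a
#' percentage: `HR = 100 * EF / EF_ideal`.
#'
#' @inheritParams enrichment_factor
#' @return hit rate in percent, in [0, 100].
#' @export
hit_rate <- function(ranking, x_pct) {
  ef <- enrichment_factor(ranking, x_pct)
  a_tot <- sum(ranking$label == "active")
  100 * ef / ideal_enrichment_factor(nrow(ranking), a_tot, x_pct)
}

#' @rdname ideal_enrichment_factor
#' @param ef a real enrichment factor at `x_pct`.
#' @return `hit_rate_from_ef`: the hit rate in percent implied by a
#'   composition and an enrichment factor.
#' @export
hit_rate_from_ef <- function(ef, n_total, actives_total, x_pct) {
  100 * ef / ideal_enrichment_factor(n_total, actives_total, x_pct)
}

#' Sensitivity and specificity of a top-fraction selection
#'
#' Sensitivity (TPR) is the fraction of all actives recovered in the top
#' x percent; specificity (TNR) the fraction of inactives not selected.
#'
#' @inheritParams enrichment_factor
#' @return tibble with columns `tpr` and `tnr`.
#' @export
sensitivity_specificity <- function(ranking, x_pct) {
  .check_ranking(ranking)
  n <- nrow(ranking)
  a_tot <- sum(ranking$label == "active")
  i_tot <- n - a_tot
  cnt <- .selection_counts(ranking, .n_selected(n, x_pct))
  i_sel <- cnt$n_sel - cnt$actives_sel
  tibble(tpr = if (a_tot > 0) cnt$actives_sel / a_tot else NA_real_,
         tnr = if (i_tot > 0) (i_tot - i_sel) / i_tot else NA_real_)
}

#' Area under the ROC curve of a labelled ranking
#'
#' Rank-based (Mann-Whitney) AUC with average ranks for tied scores;
#' non-hits (score `NA`) share one tied group at the bottom of the
#' ranking. Requires at least one active and one inactive.
#'
#' @inheritParams enrichment_factor
#' @return the AUC in [0, 1].
#' @export
roc_auc <- function(ranking) {
  .check_ranking(ranking)
  act <- ranking$label == "active"
  n_a <- sum(act); n_i <- sum(!act)
  if (n_a == 0 || n_i == 0)
    abort("ROC undefined: need both actives and inactives")
  sc <- ifelse(is.na(ranking$score), -Inf, ranking$score)
  r <- rank(sc, ties.method = "average")
  (sum(r[act]) - n_a * (n_a + 1) / 2) / (n_a * n_i)
}

#' ROC curve points over all score thresholds
#'
#' @inheritParams enrichment_factor
#' @return tibble of `(fpr, tpr)` points, one per distinct score
#'   threshold (descending), starting at (0, 0) and ending at (1, 1);
#'   tied groups contribute one diagonal segment.
#' @export
roc_curve <- function(ranking) {
  .check_ranking(ranking)
  act <- ranking$label == "active"
  n_a <- sum(act); n_i <- sum(!act)
  sc <- ifelse(is.na(ranking$score), -Inf, ranking$score)
  o <- order(-sc)
  sc <- sc[o]; act <- act[o]
  brk <- !duplicated(sc)
  grp <- cumsum(brk)
  ca <- as.numeric(rowsum(as.numeric(act), grp))
  cn <- as.numeric(rowsum(as.numeric(!act), grp))
  tibble(threshold = c(Inf, sc[brk]),
         tpr = c(0, cumsum(ca) / max(n_a, 1)),
         fpr = c(0, cumsum(cn) / max(n_i, 1)))
}

#' Full screening-performance report
#'
#' Computes the enrichment factor, hit rate, sensitivity and specificity
#' at the requested database fractions, the ROC-AUC and the curves
#' needed for enrichment plotting.
#'
#' @inheritParams enrichment_factor
#' @param fractions selection fractions in percent (default 1, 5, 10).
#' @return an `enrichment_report` object; see [tidy()], [glance()] and
#'   `autoplot()` methods.
#' @export
enrichment_report <- function(ranking, fractions = c(1, 5, 10)) {
  .check_ranking(ranking)
  metrics <- bind_rows(lapply(fractions, function(x) {
    ss <- sensitivity_specificity(ranking, x)
    tibble(fraction_pct = x,
           ef = enrichment_factor(ranking, x),
           hr = hit_rate(ranking, x),
           tpr = ss$tpr, tnr = ss$tnr)
  }))
  n <- nrow(ranking)
  a_tot <- sum(ranking$label == "active")
  pts <- sort(unique(c(seq(0.2, 10, by = 0.2))))
  enr_curve <- bind_rows(lapply(pts, function(x) {
    cnt <- .selection_counts(ranking, .n_selected(n, x))
    tibble(pct_screened = x,
           pct_actives_found = 100 * cnt$actives_sel / a_tot)
  }))
  structure(list(metrics = metrics, roc_auc = roc_auc(ranking),
                 curve = roc_curve(ranking), enrichment_curve = enr_curve,
                 n_total = n, actives_total = a_tot),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<screening performance: N=%d, actives=%d (%.1f%%), ROC-AUC=%.3f>\n",
              x$n_total, x$actives_total,
              100 * x$actives_total / x$n_total, x$roc_auc))
  df <- x$metrics
  for (i in seq_len(nrow(df)))
    cat(sprintf("  top %4.1f%%: EF %.2f  HR %.1f%%  TPR %.2f  TNR %.2f\n",
                df$fraction_pct[i], df$ef[i], df$hr[i], df$tpr[i], df$tnr[i]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a screening-performance report
#'
#' @param x an `enrichment_report`.
#' @param ... unused.
#' @return tibble with one row per evaluated fraction.
#' @export
tidy.enrichment_report <- function(x, ...) x$metrics

#' One-row summary of a screening-performance report
#'
#' @param x an `enrichment_report`.
#' @param ... unused.
#' @return tibble with `n_total`, `actives_total` and `roc_auc`.
#' @export
glance.enrichment_report <- function(x, ...) {
  tibble(n_total = x$n_total, actives_total = x$actives_total,
         roc_auc = x$roc_auc)
}

#' Plot a screening-performance report
#'
#' Draws the early-enrichment curve (percent of actives recovered versus
#' percent of database screened, first 10 percent) with the random
#' baseline, or the ROC curve.
#'
#' @param object an `enrichment_report`.
#' @param type `"enrichment"` or `"roc"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.enrichment_report <- function(object, type = c("enrichment", "roc"),
                                       ...) {
  type <- match.arg(type)
  if (type == "enrichment") {
    ggplot2::ggplot(object$enrichment_curve,
                    ggplot2::aes(x = .data$pct_screened,
                                 y = .data$pct_actives_found)) +
      ggplot2::geom_line(colour = "#2166ac") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "% of database screened", y = "% of actives found",
                    title = "Early enrichment") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$curve,
                    ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_line(colour = "#b2182b") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (AUC = %.3f)", object$roc_auc)) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Reference sigma-1 screening-database composition
#'
#' The affinity-range distribution of the large annotated sigma-1
#' binding dataset used to benchmark the encoded models: twenty Ki bins
#' up to 1000 nM (the actives) and one bin above 1000 nM (the
#' inactives).
#'
#' @return tibble with columns `ki_low_nM`, `ki_high_nM`, `n_compounds`
#'   and `label`.
#' @export
sigma1_affinity_distribution <- function() {
  lows <- c(0, 50, seq(100, 950, by = 50))
  highs <- c(50, seq(100, 1000, by = 50))
  counts <- c(1620, 707, 430, 298, 235, 165, 110, 114, 127, 99, 91, 96, 93,
              120, 135, 107, 84, 50, 54, 31)
  bins <- tibble(ki_low_nM = lows, ki_high_nM = highs, n_compounds = counts)
  bind_rows(bins, tibble(ki_low_nM = 1000, ki_high_nM = Inf,
                         n_compounds = 20910)) %>%
    mutate(label = classify_activity(ki_nM = ifelse(
      is.finite(.data$ki_high_nM), .data$ki_high_nM, 2000)))
}
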