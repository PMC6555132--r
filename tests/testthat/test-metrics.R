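rank_tbl <- function(score, label) {
  tibble::tibble(compound_id = sprintf("c%03d", seq_along(score)),
                 score = score, label = label)
}

test_that("enrichment factors reproduce hand-computed cases", {
  # N = 1000, 100 actives, top-10 all active: EF = (10/10)/(100/1000) = 10
  r <- rank_tbl(score = c(seq(1000, 991), runif(990, 0, 900)),
                label = c(rep("active", 10),
                          rep(c("active", "inactive"), c(90, 900))))
  expect_equal(enrichment_factor(r, 1), 10.0)
  # selection with the global active fraction: EF = 1
  r2 <- rank_tbl(score = 100:1,
                 label = rep(c("active", "inactive", "inactive", "inactive"),
                             25))
  expect_equal(enrichment_factor(r2, 20), 1.0)
  # the reference composition, ideal top 1%
  n <- 25676; a <- 4766
  expect_equal(ideal_enrichment_factor(n, a, 1), 5.39, tolerance = 5e-3)
  expect_error(enrichment_factor(rank_tbl(1:4, rep("inactive", 4)), 5),
               "no actives")
  expect_error(enrichment_factor(r2, 0), "x_pct")
})

test_that("EF at 100 percent is exactly 1 and ignores order below the cut", {
  set.seed(3)
  r <- rank_tbl(score = rnorm(200), label = sample(c("active", "inactive"),
                                                   200, TRUE))
  expect_equal(enrichment_factor(r, 100), 1.0)
  # permuting entries below the selection cut leaves EF unchanged
  n_sel <- sigmaphore:::.n_selected(200, 10)
  o <- order(-r$score)
  below <- o[(n_sel + 1):200]
  r2 <- r
  r2[below, ] <- r2[sample(below), ]
  expect_equal(enrichment_factor(r2, 10), enrichment_factor(r, 10))
})

test_that("hit rate is the EF over the ideal EF, matching the published identity", {
  n <- 25676; a <- 4766
  expect_equal(hit_rate_from_ef(3.44, n, a, 1), 63.8, tolerance = 0.1)
  expect_equal(hit_rate_from_ef(3.17, n, a, 5), 58.8, tolerance = 0.1)
  expect_equal(hit_rate_from_ef(1.66, n, a, 1), 30.8, tolerance = 0.1)
  # degenerate endpoints
  r <- rank_tbl(score = c(10, 9, 1, 2, 3, 4, 5, 1, 2, 3),
                label = rep(c("active", "inactive"), c(2, 8)))
  expect_equal(hit_rate(r, 20), 100)
  r0 <- rank_tbl(score = 10:1, label = rep(c("inactive", "active"), c(5, 5)))
  expect_equal(hit_rate(r0, 10), 0)
})

test_that("hit rate identity holds exactly on random rankings", {
  set.seed(14)
  for (i in 1:300) {
    n <- sample(20:200, 1)
    na <- sample(1:(n - 1), 1)
    r <- rank_tbl(score = ifelse(runif(n) < 0.2, NA, rnorm(n)),
                  label = sample(rep(c("active", "inactive"), c(na, n - na))))
    x <- runif(1, 0.5, 100)
    expect_equal(hit_rate(r, x),
                 100 * enrichment_factor(r, x) /
                   ideal_enrichment_factor(n, na, x),
                 tolerance = 1e-12)
  }
})

test_that("sensitivity and specificity count the selection correctly", {
  # N = 10 (4 actives), top-5 holds 3 actives: TPR 0.75, TNR 4/6
  r <- rank_tbl(score = 10:1,
                label = c("active", "active", "inactive", "active",
                          "inactive", "inactive", "active", "inactive",
                          "inactive", "inactive"))
  ss <- sensitivity_specificity(r, 50)
  expect_equal(ss$tpr, 0.75)
  expect_equal(ss$tnr, 4 / 6)
  ss_all <- sensitivity_specificity(r, 100)
  expect_equal(ss_all$tpr, 1)
  expect_equal(ss_all$tnr, 0)
})

test_that("ROC-AUC handles perfect, tied and mixed rankings", {
  perfect <- rank_tbl(score = c(5, 4, 1, 2), label = c("active", "active",
                                                       "inactive", "inactive"))
  expect_equal(roc_auc(perfect), 1.0)
  tied <- rank_tbl(score = rep(1, 6), label = rep(c("active", "inactive"), 3))
  expect_equal(roc_auc(tied), 0.5)
  mixed <- rank_tbl(score = c(3, 2, 1),
                    label = c("active", "inactive", "active"))
  expect_equal(roc_auc(mixed), 0.5)
  # non-hits share the bottom tied rank
  nh <- rank_tbl(score = c(3, NA, NA, NA),
                 label = c("active", "inactive", "inactive", "active"))
  # top active beats both inactives (2 wins); bottom active ties both
  # inactives (2 half-wins): AUC = (2 + 1) / 4
  expect_equal(roc_auc(nh), 0.75)
  expect_error(roc_auc(rank_tbl(1:3, rep("active", 3))), "ROC")
})

test_that("the ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(5)
  r <- rank_tbl(score = ifelse(runif(120) < 0.3, NA, rnorm(120)),
                label = sample(c("active", "inactive"), 120, TRUE,
                               prob = c(0.3, 0.7)))
  cv <- roc_curve(r)
  expect_equal(cv$tpr[1], 0); expect_equal(cv$fpr[1], 0)
  expect_equal(cv$tpr[nrow(cv)], 1); expect_equal(cv$fpr[nrow(cv)], 1)
  expect_true(all(diff(cv$tpr) >= -1e-12))
  expect_true(all(diff(cv$fpr) >= -1e-12))
})

test_that("label-permuted rankings average AUC 0.5 and EF 1", {
  set.seed(8)
  score <- rnorm(400)
  label <- rep(c("active", "inactive"), c(80, 320))
  aucs <- vapply(1:200, function(i)
    roc_auc(rank_tbl(score, sample(label))), numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  efs <- vapply(1:200, function(i)
    enrichment_factor(rank_tbl(score, sample(label)), 10), numeric(1))
  expect_lt(abs(mean(efs) - 1), 0.05)
})

test_that("tied score groups straddling the cut contribute expected counts", {
  # 4 tied at the top over a cut of 2: expect half of the group's actives
  r <- rank_tbl(score = c(rep(5, 4), 1, 0),
                label = c("active", "active", "inactive", "inactive",
                          "active", "inactive"))
  cnt <- sigmaphore:::.selection_counts(r, 2)
  expect_equal(cnt$actives_sel, 1.0)  # 2/4 of 2 actives
  expect_equal(enrichment_factor(r, 33.4),
               (1 / 2) / (3 / 6))
})

test_that("reports carry consistent tidy, glance and plot output", {
  set.seed(2)
  r <- generate_ranking(400, active_fraction = 0.25, target_auc = 0.9,
                        seed = 4)
  rep <- enrichment_report(r, fractions = c(1, 5, 10))
  td <- tidy(rep)
  expect_equal(nrow(td), 3)
  expect_true(all(td$hr >= 0 & td$hr <= 100 + 1e-9))
  expect_true(all(td$tpr >= 0 & td$tpr <= 1))
  expect_equal(glance(rep)$roc_auc, roc_auc(r))
  expect_equal(td$hr, 100 * td$ef /
                 vapply(td$fraction_pct, function(x)
                   ideal_enrichment_factor(rep$n_total, rep$actives_total, x),
                   numeric(1)),
               tolerance = 1e-12)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
  p2 <- ggplot2::autoplot(rep, type = "roc")
  expect_s3_class(p2, "ggplot")
})
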