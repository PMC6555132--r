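test_that("pharmjson round-trip is the identity", {
  for (nm in c("5HK1-Ph.B", "Zampieri-Ph", "Banister-Ph", "Glennon-Ph")) {
    m <- builtin_models()[[nm]]
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    back <- load_model(path)
    if (inherits(m, "pharmacophore")) {
      expect_equal(back$features$kind, m$features$kind)
      expect_lt(max(abs(as.matrix(back$features[, c("x", "y", "z")]) -
                          as.matrix(m$features[, c("x", "y", "z")]))), 1e-6)
      expect_equal(back$features$tol, m$features$tol)
      expect_equal(back$features$pconstrained, m$features$pconstrained)
      expect_equal(nrow(back$exclusions), nrow(m$exclusions))
      expect_equal(back$max_omitted, m$max_omitted)
      expect_equal(back$pi_exclude, m$pi_exclude)
      # second serialization is byte-identical
      path2 <- withr::local_tempfile(fileext = ".json")
      save_model(back, path2)
      expect_identical(readLines(path), readLines(path2))
    } else {
      expect_equal(back$constraints, m$constraints)
    }
  }
})

test_that("schema violations name the offending field", {
  path <- withr::local_tempfile(fileext = ".json")
  good <- jsonlite::read_json(
    {save_model(builtin_models()[["5HK1-Ph.B"]], path); path},
    simplifyVector = FALSE)
  bad <- good
  bad$features[[1]]$tolerance <- NULL
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_model(path), "tolerance")
  bad2 <- good
  bad2$features[[1]]$kind <- "XYZ"
  jsonlite::write_json(bad2, path, auto_unbox = TRUE)
  expect_error(load_model(path), "kind")
  bad3 <- good
  bad3$format <- "something/9"
  jsonlite::write_json(bad3, path, auto_unbox = TRUE)
  expect_error(load_model(path), "format")
})

test_that("merging places the new feature at the midpoint with averaged weight", {
  m <- pharmacophore("toy", tibble::tibble(
    kind = c("PI", "HYD", "HYD"), x = c(-4, 0, 2), y = 0, z = 0,
    tol = 1.6, weight = c(1, 1, 1)))
  merged <- merge_features(m, 2, 3, new_tolerance = 3.0)
  expect_equal(nrow(merged$features), 2)
  hyd <- merged$features[merged$features$kind == "HYD", ]
  expect_equal(c(hyd$x, hyd$y, hyd$z), c(1, 0, 0))
  expect_equal(hyd$tol, 3.0)
  expect_equal(hyd$weight, 1)
  expect_error(merge_features(m, 1, 2, 3.0), "kind")
  # coincident features merge in place; exclusions are untouched
  a <- builtin_models()[["5HK1-Ph.A"]]
  m2 <- merge_features(a, 3, 4, 3.0)
  expect_equal(nrow(m2$features), nrow(a$features) - 1)
  expect_equal(m2$exclusions, a$exclusions)
})

test_that("set_tolerance changes exactly one tolerance and rejects non-positive values", {
  a <- builtin_models()[["5HK1-Ph.A"]]
  b <- set_tolerance(a, 2, 2.2)
  expect_equal(b$features$tol[2], 2.2)
  expect_equal(b$features$tol[-2], a$features$tol[-2])
  expect_equal(set_tolerance(a, 2, a$features$tol[2])$features, a$features)
  expect_error(set_tolerance(a, 2, 0), "> 0")
})

test_that("the structure-derived model satisfies its printed geometry", {
  a <- builtin_models()[["5HK1-Ph.A"]]
  expect_equal(a$features$kind, c("PI", "HYD", "HYD", "HYD"))
  d <- feature_distances(a$features)
  expect_equal(d[1, 2], 3.7, tolerance = 1e-12)
  expect_equal(a$features$tol[2], 0.8)
  expect_true(all(d[1, 3:4] >= 7 & d[1, 3:4] <= 13))
  expect_equal(nrow(a$exclusions), 21)
})

test_that("the curated model is exactly the recorded edit of the derived one", {
  a <- builtin_models()[["5HK1-Ph.A"]]
  b <- builtin_models()[["5HK1-Ph.B"]]
  edited <- set_tolerance(merge_features(a, 3, 4, new_tolerance = 3.0), 2, 2.2)
  expect_equal(edited$features[, c("kind", "x", "y", "z", "tol", "weight")],
               b$features[, c("kind", "x", "y", "z", "tol", "weight")])
  expect_equal(b$features$tol, c(1.6, 2.2, 3.0))
  expect_equal(b$pi_exclude, "nonbasic_amidine")
  expect_equal(nrow(b$exclusions), 21)
})

test_that("the reproduced literature models have their published shapes", {
  m <- builtin_models()
  expect_gte(length(m), 8)
  langer <- m[["Langer-Ph"]]
  expect_equal(sum(langer$features$kind == "PI"), 1)
  expect_equal(sum(langer$features$kind == "HYD"), 4)
  gu <- m[["Gund-up-Ph"]]; gd <- m[["Gund-down-Ph"]]
  expect_equal(gu$features$kind, gd$features$kind)
  ar_u <- gu$features[gu$features$kind == "AR", ]
  ar_d <- gd$features[gd$features$kind == "AR", ]
  expect_equal(c(ar_u$x, ar_u$y), c(ar_d$x, ar_d$y))
  expect_equal(ar_u$pz, -ar_d$pz)  # inverted projection point
  hba_u <- gu$features[gu$features$kind == "HBA", ]
  expect_equal(hba_u$accept_elements[[1]], "N")  # nitrogen-only acceptor
  expect_equal(hba_u$ptol, 2.2)
  za <- m[["Zampieri-Ph"]]
  expect_setequal(za$features$kind, c("PI", "HYD", "HYD_AR", "HBA"))
  expect_equal(sum(za$features$kind == "HYD_AR"), 2)
  expect_false(za$features$pconstrained[za$features$kind == "HBA"])
  ba <- m[["Banister-Ph"]]
  expect_false(any(ba$features$pconstrained[!is.na(ba$features$px)]))
  gl <- m[["Glennon-Ph"]]
  expect_s3_class(gl, "distance_model")
  expect_equal(sort(gl$constraints$dmin), c(2.5, 6))
  expect_equal(sort(gl$constraints$dmax), c(3.9, 10))
})

test_that("model construction enforces its invariants", {
  expect_error(pharmacophore("x", tibble::tibble(
    kind = "PI", x = 0, y = 0, z = 0, tol = 1.6)), "at least 2")
  expect_error(pharmacophore("x", tibble::tibble(
    kind = c("PI", "HYD"), x = c(0, 3), y = 0, z = 0, tol = c(1.6, 0))),
    "> 0")
  expect_error(pharmacophore("x", tibble::tibble(
    kind = c("PI", "ZZZ"), x = c(0, 3), y = 0, z = 0, tol = 1.6)),
    "kind")
  expect_error(pharmacophore("x", tibble::tibble(
    kind = c("PI", "HYD"), x = c(0, 3), y = 0, z = 0, tol = 1.6),
    max_omitted = 2), "max_omitted")
})
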