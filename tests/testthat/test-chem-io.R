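test_that("SDF records sharing an id merge into one multi-conformer molecule", {
  m <- mol_pi_hyd_ligand(id = "cmp1")
  m2 <- m; m2$confs[[1]] <- m$confs[[1]] + 1.0
  m3 <- m; m3$confs[[1]] <- m$confs[[1]] + 2.0
  path <- withr::local_tempfile(fileext = ".sdf")
  write_library(tibble::tibble(id = rep("cmp1", 3), mol = list(m, m2, m3)),
                path)
  lib <- read_library(path, format = "sdf")
  expect_equal(nrow(lib), 1)
  expect_equal(lib$id, "cmp1")
  expect_equal(lib$n_conformers, 3L)
})

test_that("SMILES libraries parse with ids and skip corrupt records", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benz", "this_is_not_smiles((( bad", "CCO ethanol"),
             path)
  expect_warning(lib <- read_library(path, format = "smiles"),
                 "unparseable")
  expect_equal(nrow(lib), 2)
  benz <- lib$mol[[which(lib$id == "benz")]]
  expect_equal(sum(benz$atoms$element == "C" & benz$atoms$aromatic), 6)
})

test_that("empty library files are an error", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), path)
  expect_error(read_library(path, format = "smiles"), "empty")
})

test_that("SDF round-trip preserves elements, charges and coordinates to 1e-4 A", {
  m <- mol_pi_hyd_ligand(pi_pos = c(0.12345, -2.5, 1.0),
                         hyd_pos = c(3.71234, 0.5, -0.25), id = "rt")
  path <- withr::local_tempfile(fileext = ".sdf")
  write_library(tibble::tibble(id = "rt", mol = list(m)), path)
  back <- read_library(path, format = "sdf")$mol[[1]]
  expect_identical(back$atoms$element, m$atoms$element)
  expect_identical(back$atoms$charge, m$atoms$charge)
  expect_lt(max(abs(back$confs[[1]] - m$confs[[1]])), 1e-4)
})

test_that("activity classification follows the 1 uM / 50 percent rule", {
  expect_equal(classify_activity(ki_nM = 1000), "active")
  expect_equal(classify_activity(ki_nM = 999.9), "active")
  expect_equal(classify_activity(ki_nM = 1500), "inactive")
  expect_equal(classify_activity(ki_nM = NA, inhibition_pct = 40), "inactive")
  expect_equal(classify_activity(ki_nM = NA, inhibition_pct = 75), "unknown")
  expect_error(classify_activity(ki_nM = -5), "negative")
  expect_error(classify_activity(), "at least one")
  expect_error(classify_activity(ki_nM = NA_real_, inhibition_pct = NA_real_),
               "neither")
})

test_that("classification partitions any annotated library", {
  set.seed(42)
  n <- 500
  ki <- ifelse(runif(n) < 0.5, NA, rlnorm(n, log(800), 1.5))
  inh <- ifelse(is.na(ki), runif(n, 0, 100), NA)
  lab <- classify_activity(ki, inh)
  expect_equal(sum(lab == "active") + sum(lab == "inactive") +
                 sum(lab == "unknown"), n)
})

test_that("ionization enumeration protonates bases above pKa 5 and keeps the neutral state", {
  amine <- parse_smiles("CCN", id = "ethylamine")
  states <- enumerate_ionization_states(amine)
  expect_equal(length(states), 2)
  expect_equal(states[[1]]$atoms$charge, c(0L, 0L, 0L))
  expect_equal(sum(states[[2]]$atoms$charge), 1L)
  expect_equal(states[[2]]$applied_rules$action, "protonate")
})

test_that("acids below pKa 5 are deprotonated; weak acids and bases are left alone", {
  acid <- parse_smiles("CC(=O)O", id = "acetic")
  states <- enumerate_ionization_states(acid)
  expect_equal(length(states), 2)
  expect_equal(sum(states[[2]]$atoms$charge), -1L)
  expect_equal(states[[2]]$applied_rules$action, "deprotonate")
  phenol <- parse_smiles("Oc1ccccc1", id = "phenol")     # pKa ~10: stays
  expect_equal(length(enumerate_ionization_states(phenol)), 1)
  aniline <- parse_smiles("Nc1ccccc1", id = "aniline")   # pKa ~4.6: stays
  expect_equal(length(enumerate_ionization_states(aniline)), 1)
})

test_that("molecules without ionizable sites give exactly the neutral state", {
  states <- enumerate_ionization_states(mol_benzene())
  expect_equal(length(states), 1)
})

test_that("ionization enumeration is idempotent on its own output", {
  m <- parse_smiles("NCCCC(=O)O", id = "gaba")
  states <- enumerate_ionization_states(m)
  expect_gt(length(states), 1)
  for (s in states) {
    again <- enumerate_ionization_states(s)
    keys <- vapply(again, function(x) paste(x$atoms$charge, collapse = ","),
                   character(1))
    base <- vapply(states, function(x) paste(x$atoms$charge, collapse = ","),
                   character(1))
    expect_true(all(keys %in% base) || length(again) <= length(states))
  }
})

test_that("user pKa tables override the rules and must reference real atoms", {
  amine <- parse_smiles("CCN", id = "ea")
  st <- enumerate_ionization_states(
    amine, pka_table = data.frame(atom = 3, type = "basic", pka = 9.5))
  expect_equal(length(st), 2)
  st2 <- enumerate_ionization_states(
    amine, pka_table = data.frame(atom = 3, type = "basic", pka = 4.0))
  expect_equal(length(st2), 1)  # below threshold: never protonated
  expect_error(enumerate_ionization_states(
    amine, pka_table = data.frame(atom = 99, type = "basic", pka = 9)),
    "nonexistent")
})

test_that("rigid ring systems give a single conformer; torsions expand acyclics", {
  benz <- generate_conformers(mol_benzene(), max_confs = 10,
                              mode = "systematic")
  expect_equal(length(benz$confs), 1)
  but <- generate_conformers(parse_smiles("CCCC", id = "butane"),
                             max_confs = 10, mode = "systematic")
  expect_gt(length(but$confs), 1)
  expect_lte(length(but$confs), 6)  # 60-degree grid on one rotatable bond
  # deduplication: all conformers at least 0.3 A apart (best-fit RMSD)
  if (length(but$confs) > 1) {
    for (i in seq_along(but$confs)[-1]) {
      expect_gte(sigmaphore:::best_fit_rmsd(but$confs[[i]], but$confs[[1]]),
                 0.3)
    }
  }
})

test_that("racemic stereo markers produce both mirror-image conformers under one id", {
  m <- parse_smiles("CC(N)C(=O)O", id = "ala")
  m$stereo <- tibble::tibble(atom = 2L, mark = "racemic")
  out <- generate_conformers(m, max_confs = 20, mode = "embed")
  expect_equal(out$id, "ala")
  expect_gt(length(out$confs), 1)
  # some pair must be mirror images: reflection beats proper rotation
  c1 <- out$confs[[1]]
  mir <- out$confs[[length(out$confs)]]
  reflected <- mir; reflected[, 3] <- -reflected[, 3]
  expect_lt(sigmaphore:::best_fit_rmsd(reflected, c1),
            sigmaphore:::best_fit_rmsd(mir, c1) + 1e-6)
})
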