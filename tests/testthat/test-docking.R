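# Docking adapter: ligand preparation, mock scoring, matrix assembly.

test_that("ligand preparation counts heavy atoms and rejects bad SMILES", {
  eth <- prepare_ligand("CCO", "ethanol")
  expect_s3_class(eth, "ligand_record")
  expect_equal(eth$n_heavy_atoms, 3)
  benz <- prepare_ligand("c1ccccc1", "benzene")
  expect_equal(benz$n_heavy_atoms, 6)
  expect_equal(sort(unique(benz$elements)), "C")
  expect_error(prepare_ligand("C((", "broken"), "broken")
})

test_that("the mock scorer is deterministic with an exact planted boost", {
  planted <- list(cpd_a = c("s1", "s3"))
  e1 <- mock_scorer("cpd_a", "s1", planted, seed = 5)
  e2 <- mock_scorer("cpd_a", "s1", planted, seed = 5)
  expect_identical(e1, e2)
  un <- mock_scorer("cpd_a", "s1", NULL, seed = 5)
  expect_equal(un - e1, 3)              # default delta
  expect_equal(mock_scorer("cpd_a", "s2", planted, seed = 5),
               mock_scorer("cpd_a", "s2", NULL, seed = 5))
  expect_false(mock_scorer("cpd_a", "s1", seed = 5) ==
                 mock_scorer("cpd_a", "s1", seed = 6))
})

test_that("docking keeps the lowest of the requested poses", {
  r <- dock("cpd_x", "site_1", list(engine = "mock", seed = 2))
  expect_equal(r$n_poses, 5)
  expect_equal(r$best_energy, min(r$pose_energies))
  expect_equal(r$pose_energies[1], r$best_energy)
  expect_warning(
    r1 <- dock("cpd_x", "site_1",
               list(engine = "mock", seed = 2, n_poses = 1)),
    "pose")
  expect_error(dock("c", "s", list(engine = "warp")), "unknown")
  expect_error(dock(prepare_ligand("CCO"), "s", list(engine = "vina")),
               "obabel|not found")
})

test_that("planted binders occupy the low tail of the mock matrix", {
  ids <- sprintf("c%03d", 1:100)
  sites <- sprintf("s%02d", 1:10)
  planted <- stats::setNames(
    lapply(1:5, function(i) sites), ids[1:5])
  m <- ensdock:::mock_energy_matrix(ids, sites, planted, seed = 9,
                                    delta = 5)
  for (s in sites) {
    low5 <- rownames(m)[order(m[, s])][1:5]
    expect_setequal(low5, ids[1:5])
  }
})

test_that("energy-matrix assembly is order-invariant and flags problems", {
  res <- expand.grid(compound_id = c("a", "b"),
                     site_id = c("s1", "s2", "s3"),
                     stringsAsFactors = FALSE)
  res$best_energy <- as.numeric(1:6)
  m <- assemble_energy_matrix(res)
  expect_equal(dim(m), c(2, 3))
  expect_equal(sum(is.na(m)), 0)
  expect_equal(m["b", "s2"], res$best_energy[res$compound_id == "b" &
                                               res$site_id == "s2"])
  shuffled <- assemble_energy_matrix(res[sample(nrow(res)), ])
  expect_equal(unclass(shuffled)[rownames(m), colnames(m)], unclass(m))
  # a failed docking becomes one marked-missing cell
  res_na <- res; res_na$best_energy[4] <- NA
  expect_equal(sum(is.na(assemble_energy_matrix(res_na))), 1)
  expect_error(assemble_energy_matrix(rbind(res, res[1, ])),
               "duplicate")
})

test_that("the mock library pipeline is reproducible end to end", {
  lib <- c(l1 = "CCO", l2 = "CCC", l3 = "CCN")
  cfg <- list(engine = "mock", seed = 4,
              planted_binders = list(l2 = "sB"), delta = 2)
  r1 <- dock_library(lib, c("sA", "sB"), cfg)
  r2 <- dock_library(lib, c("sA", "sB"), cfg)
  expect_identical(r1, r2)
  m <- assemble_energy_matrix(r1)
  expect_equal(dim(m), c(3, 2))
  expect_equal(m["l2", "sB"],
               mock_scorer("l2", "sB", list(l2 = "sB"), seed = 4,
                           delta = 2))
  csv <- tempfile(fileext = ".csv")
  write_energy_csv(m, csv)
  expect_equal(unclass(read_energy_csv(csv))[rownames(m), colnames(m)],
               unclass(m))
})
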