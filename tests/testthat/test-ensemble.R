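# Ensemble containers, reweighting and structural analytics.

kbt <- 0.008314462618 * 298

test_that("Torrie-Valleau weights normalise, shift-invariantly", {
  expect_equal(torrie_valleau_weights(bias_trace(c(5, 5, 5))),
               rep(1 / 3, 3))
  expect_equal(torrie_valleau_weights(bias_trace(0)), 1)
  w <- torrie_valleau_weights(bias_trace(c(0, kbt * log(2)), 298))
  expect_equal(w, c(1 / 3, 2 / 3))
  # adding a constant changes nothing; monotone in bias
  b <- c(1.2, 8.4, 3.3, 6.1)
  expect_equal(torrie_valleau_weights(bias_trace(b)),
               torrie_valleau_weights(bias_trace(b + 57.3)))
  expect_equal(order(torrie_valleau_weights(bias_trace(b))), order(b))
})

test_that("bias traces are validated and reject length mismatch", {
  expect_error(bias_trace(c(1, NA)), "finite")
  expect_error(bias_trace(1, temperature = 0), "positive")
  expect_error(torrie_valleau_weights(bias_trace(1:3), n_frames = 5),
               "5")
  ens <- structural_ensemble(list(ca_conf(diag(3)), ca_conf(diag(3) + 1)))
  expect_error(reweight_ensemble(ens, bias_trace(1:5)), "frames")
})

test_that("ensemble construction enforces invariants", {
  expect_error(structural_ensemble(list()), "at least one")
  expect_error(conformation(matrix(c(0, 0, Inf), 1), 1), "finite")
  expect_error(conformation(diag(3), c(2, 1, 3)), "non-decreasing")
  a <- ca_conf(diag(3))
  b <- conformation(diag(3), 1:3, atom_name = "CB")
  expect_error(structural_ensemble(list(a, b)), "atom naming")
  ens <- structural_ensemble(list(a, a), weights = c(3, 1))
  expect_equal(sum(ens$weights), 1)
  expect_equal(ens$weights, c(0.75, 0.25))
})

test_that("RMSF is zero for identical frames and matches hand values", {
  conf <- ca_conf(matrix(rnorm(30), 10))
  ens <- structural_ensemble(list(conf, conf, conf))
  expect_equal(unname(residue_rmsf(ens)), rep(0, 10))

  # two equally weighted frames, residue 2 displaced by 6 A -> 3 A
  xyz <- matrix(0, 3, 3); xyz[, 1] <- c(0, 10, 20)
  xyz2 <- xyz; xyz2[2, 2] <- 6
  ens2 <- structural_ensemble(list(ca_conf(xyz), ca_conf(xyz2)))
  r <- residue_rmsf(ens2, superpose = FALSE)
  expect_equal(unname(r), c(0, 0.3, 0), tolerance = 1e-12)  # nm

  expect_error(residue_rmsf(ens2, selection = integer(0)), "empty")
  expect_error(residue_rmsf(structural_ensemble(list(conf))), "two frames")
})

test_that("RMSF is invariant to frame order and weight rescaling", {
  set.seed(11)
  frames <- lapply(1:6, function(i) ca_conf(matrix(rnorm(24, sd = 3), 8)))
  w <- runif(6)
  e1 <- structural_ensemble(frames, weights = w)
  e2 <- structural_ensemble(frames[c(4, 2, 6, 1, 3, 5)],
                            weights = w[c(4, 2, 6, 1, 3, 5)])
  e3 <- structural_ensemble(frames, weights = 2 * w)
  expect_equal(residue_rmsf(e1), residue_rmsf(e2))
  expect_equal(residue_rmsf(e1), residue_rmsf(e3))
  # against the independent per-residue weighted variance
  r <- residue_rmsf(e1)
  w_n <- w / sum(w)
  for (res in c(1L, 5L)) {
    coords <- lapply(frames, function(f) f$xyz[res, ])
    expect_equal(unname(r[res]) / 0.1, brute_rmsf(coords, w_n))
  }
})

test_that("superposed RMSF removes rigid-body motion", {
  set.seed(3)
  base <- matrix(rnorm(30, sd = 4), 10)
  rot <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  frames <- lapply(c(0, 0.7, 2.1), function(a) {
    ca_conf(base %*% rot(a) + 5 * a)
  })
  ens <- structural_ensemble(frames)
  expect_gt(max(residue_rmsf(ens, superpose = FALSE)), 0.5)
  expect_lt(max(residue_rmsf(ens, superpose = TRUE)), 1e-6)
})

test_that("radius of gyration matches closed forms and a brute oracle", {
  expect_equal(radius_of_gyration(ca_conf(matrix(c(1, 2, 3), 1))), 0)
  two <- ca_conf(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(radius_of_gyration(two), 0.5)    # d/2 in nm for d = 1 nm
  three <- ca_conf(rbind(c(-6, 0, 0), c(0, 0, 0), c(6, 0, 0)))
  expect_equal(radius_of_gyration(three), 0.6 * sqrt(2 / 3))
  set.seed(5)
  xyz <- matrix(rnorm(90, sd = 7), 30)
  conf <- conformation(xyz, 1:30, element = rep(c("C", "N", "O"), 10))
  m <- rep(c(12.011, 14.007, 15.999), 10)
  expect_equal(radius_of_gyration(conf), 0.1 * brute_rg(xyz, m))
  expect_error(radius_of_gyration(conf, selection = integer(0)), "empty")
})

test_that("minimum ligand distance equals the exhaustive scan", {
  coincident <- ca_conf(rbind(c(1, 2, 3)),
                        ligand = list(xyz = rbind(c(1, 2, 3)),
                                      element = "C"))
  expect_equal(min_ligand_distance(coincident), 0)
  simple <- ca_conf(rbind(c(0, 0, 0)),
                    ligand = list(xyz = rbind(c(5, 0, 0)), element = "C"))
  expect_equal(min_ligand_distance(simple), 0.5)
  set.seed(9)
  prot <- matrix(rnorm(120, sd = 8), 40)
  lig <- matrix(rnorm(30, sd = 8), 10)
  conf <- ca_conf(prot, ligand = list(xyz = lig, element = "C"))
  expect_equal(min_ligand_distance(conf),
               0.1 * brute_min_distance(prot, lig))
  expect_error(min_ligand_distance(ca_conf(prot)), "ligand")
})

test_that("region sets validate their intervals", {
  rs <- region_set(list(a = rbind(c(1, 5), c(8, 9)), b = c(3, 7)),
                   n_residues = 10)
  expect_equal(ensdock:::region_residues(rs, "a"), c(1:5, 8:9))
  expect_error(region_set(list(a = c(0, 4)), 10), "1 <= start")
  expect_error(region_set(list(c(1, 2)), 10), "named")
})

test_that("multi-model PDB round-trips through read/write", {
  set.seed(21)
  frames <- lapply(1:3, function(i) {
    ca_conf(matrix(round(rnorm(36, sd = 5), 3), 12),
            ligand = if (i == 1) NULL else
              list(xyz = matrix(round(rnorm(6, sd = 5), 3), 2),
                   element = c("C", "O")))
  })
  # uniform frames: keep ligand on all or none for a consistent model
  frames <- lapply(frames, function(f) { f$ligand <- NULL; f })
  ens <- structural_ensemble(frames)
  path <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble_pdb(path)
  expect_length(back$frames, 3)
  expect_equal(back$frames[[2]]$xyz, frames[[2]]$xyz, tolerance = 1e-6)
  expect_equal(back$frames[[1]]$resid, frames[[1]]$resid)
})

test_that("bias traces parse from two-column text", {
  path <- tempfile()
  writeLines(c("# frame bias", "2 4.0", "1 3.0", "3 5.0"), path)
  bt <- read_bias_trace(path, temperature = 310)
  expect_equal(bt$bias, c(3, 4, 5))   # reordered by frame index
  expect_equal(bt$temperature, 310)
})
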