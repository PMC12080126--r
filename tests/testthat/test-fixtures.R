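# Synthetic-fixture generators: validity, planted structure, determinism.

test_that("toy ensembles satisfy the container invariants", {
  spec <- small_spec()
  toy <- gen_toy_ensemble(spec)
  ens <- toy$ensemble
  expect_s3_class(ens, "structural_ensemble")
  expect_length(ens$frames, spec$n_frames)
  expect_equal(sum(ens$weights), 1)
  expect_length(toy$bias$bias, spec$n_frames)
  # virtual bond length is fixed at 3.8 A outside the rigid block
  xyz <- ens$frames[[1]]$xyz
  d <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
  flexible <- setdiff(seq_len(spec$n_residues - 1),
                      (spec$rigid_block[1] - 1):spec$rigid_block[2])
  expect_equal(d[flexible], rep(3.8, length(flexible)), tolerance = 1e-9)
})

test_that("rigid-block residues fluctuate less than the tails", {
  spec <- small_spec()
  ens <- gen_toy_ensemble(spec)$ensemble
  r <- residue_rmsf(ens)
  block <- spec$rigid_block[1]:spec$rigid_block[2]
  expect_lt(mean(r[block]), mean(r[-block]))
  expect_lt(mean(r[block]), 0.1)
})

test_that("fixture generation is bit-reproducible under its seed", {
  spec <- small_spec(seed = 31L)
  e1 <- gen_toy_ensemble(spec)
  e2 <- gen_toy_ensemble(spec)
  expect_identical(e1$ensemble$frames[[3]]$xyz,
                   e2$ensemble$frames[[3]]$xyz)
  expect_identical(e1$bias$bias, e2$bias$bias)
  m1 <- gen_energy_matrix(spec)
  m2 <- gen_energy_matrix(spec)
  expect_identical(unclass(m1$energy), unclass(m2$energy))
  expect_identical(m1$planted, m2$planted)
  l1 <- gen_smiles_library(50, seed = 8)
  l2 <- gen_smiles_library(50, seed = 8)
  expect_identical(l1, l2)
})

test_that("prediction bundles reproduce the designated restraints", {
  spec <- small_spec()
  ref <- gen_toy_ensemble(spec)$ensemble$frames[[1]]
  # all pairs confident, no structured exclusion, zero noise
  b <- gen_prediction_bundle(spec, ref, plddt_high = 0.3)
  rs <- select_restraints(b, structured = NULL, pae_cutoff = 4,
                          min_separation = 3)
  n <- spec$n_residues
  expected <- sum(vapply(seq_len(n - 1), function(i) {
    sum((i + 1):n - i >= 3)
  }, numeric(1)))
  expect_equal(nrow(rs), expected)
  # the forward model on the reference gives a zero data term
  em <- error_model(0.5, 0.5)
  expect_equal(metainference_energy(ref, rs, em)$data_term, 0,
               tolerance = 1e-9)
  # all PAE above the cutoff: nothing selected
  b_high <- gen_prediction_bundle(spec, ref,
                                  confident_pairs = cbind(1L, 2L),
                                  pae_low = 9, pae_high = 9)
  expect_equal(nrow(select_restraints(b_high, pae_cutoff = 4)), 0)
})

test_that("planted multibinders dominate the low tail when boosted", {
  spec <- fixture_spec(n_compounds = 500L, n_sites = 20L,
                       n_planted = 20L, delta = 5,
                       planted_site_fraction = 0.8, seed = 37L)
  gem <- gen_energy_matrix(spec)
  lm <- build_labels(gem$energy, 5)
  frac <- rowMeans(lm$labels[names(gem$planted), ] == 1L)
  expect_true(all(frac > 0.7))
  # delta = 0: planted set is statistically indistinguishable
  spec0 <- spec; spec0$delta <- 0
  gem0 <- gen_energy_matrix(spec0)
  planted_e <- as.vector(unclass(gem0$energy)[names(gem0$planted), ])
  other_e <- as.vector(unclass(gem0$energy)[
    setdiff(rownames(gem0$energy), names(gem0$planted)), ])
  expect_gt(stats::t.test(planted_e, other_e)$p.value, 0.05)
})

test_that("SMILES libraries are unique, parseable and capacity-bounded", {
  lib <- gen_smiles_library(100, seed = 5, kind = "mixed")
  expect_length(lib, 100)
  canon <- ensdock:::canonical_smiles(lib)
  expect_equal(anyDuplicated(canon), 0)
  fp <- featurize(lib)
  expect_length(attr(fp, "rejected"), 0)
  expect_error(gen_smiles_library(10^6, seed = 1), "capacity")
})

test_that("fixture cavities split into known pass/fail groups", {
  spec <- small_spec()
  ens <- gen_toy_ensemble(spec)$ensemble
  rmsf <- residue_rmsf(ens)
  cavs <- gen_fixture_cavities(spec, n_pass = 6L, n_fail = 10L)
  sites <- filter_cavities(cavs, rmsf)
  expect_length(sites, 6)
})
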