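# AlphaFold-derived restraint selection and the metainference score.

kbt <- 0.008314462618 * 298

test_that("structured regions are maximal high-confidence runs", {
  sr <- structured_regions(c(0.9, 0.9, 0.2, 0.8), threshold = 0.75)
  expect_equal(unclass(sr)[, ], cbind(start = c(1L, 4L), end = c(2L, 4L))[, ])
  expect_equal(nrow(structured_regions(rep(0.5, 6), 0.75)), 0)
  # threshold is strict: a value exactly at it is unstructured
  expect_equal(nrow(structured_regions(c(0.75, 0.75), 0.75)), 0)
  expect_error(structured_regions(numeric(0)), "non-empty")
  expect_error(structured_regions(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_bundle <- function(n, pae, d = NULL, plddt = rep(0.3, n)) {
  if (is.null(d)) {
    d <- abs(outer(seq_len(n), seq_len(n), "-")) * 3.8
  }
  prediction_bundle(plddt, pae, d)
}

test_that("restraint selection matches an exhaustive double loop", {
  set.seed(17)
  n <- 10
  pae <- matrix(runif(n * n, 0, 8), n)
  diag(pae) <- 0
  plddt <- rep(0.3, n); plddt[4:6] <- 0.9
  bundle <- make_bundle(n, pae, plddt = plddt)
  sr <- structured_regions(plddt, 0.75)
  rs <- select_restraints(bundle, sr, pae_cutoff = 4, min_separation = 3)

  ps <- pmin(pae, t(pae))
  mask <- rep(FALSE, n); mask[4:6] <- TRUE
  expected <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ps[i, j] < 4 && (j - i) >= 3 && !(mask[i] && mask[j])) {
        expected[[length(expected) + 1]] <- c(i, j)
      }
    }
  }
  expect_equal(nrow(rs), length(expected))
  expect_equal(unname(as.matrix(rs[, c("i", "j")])),
               do.call(rbind, expected))
  expect_equal(rs$d_af, bundle$d_af[as.matrix(rs[, c("i", "j")])])
  # symmetric in the inputs: transposing the PAE changes nothing
  rs_t <- select_restraints(make_bundle(n, t(pae), plddt = plddt), sr,
                            pae_cutoff = 4, min_separation = 3)
  expect_equal(as.data.frame(rs), as.data.frame(rs_t))
})

test_that("restraint count is monotone in the PAE cutoff", {
  set.seed(23)
  n <- 12
  pae <- matrix(runif(n * n, 0, 10), n)
  bundle <- make_bundle(n, pae)
  counts <- vapply(c(1, 2, 4, 6, 10),
                   function(ct) nrow(select_restraints(bundle,
                     pae_cutoff = ct)), integer(1))
  expect_true(all(diff(counts) >= 0))
  all_high <- select_restraints(make_bundle(n, matrix(9, n, n)),
                                pae_cutoff = 4)
  expect_equal(nrow(all_high), 0)
  expect_error(select_restraints(bundle, pae_cutoff = 0), "positive")
})

test_that("forward-model distances are plain CA Euclidean distances", {
  conf <- ca_conf(rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 3.8)))
  rs <- data.frame(i = c(1L, 1L), j = c(2L, 3L), d_af = c(5, 3.8),
                   pae = c(1, 1))
  d <- forward_model_distances(conf, rs)
  expect_equal(d, c(5, 3.8))
  rs_bad <- data.frame(i = 1L, j = 9L, d_af = 1, pae = 1)
  expect_error(forward_model_distances(conf, rs_bad), "9")
  # 20-pair toy set equals the direct per-pair norm
  set.seed(31)
  xyz <- matrix(rnorm(60, sd = 6), 20)
  conf2 <- ca_conf(xyz)
  pairs <- cbind(sample(1:10), sample(11:20))
  rs2 <- data.frame(i = pairs[, 1], j = pairs[, 2], d_af = 1, pae = 1)
  expect_equal(forward_model_distances(conf2, rs2),
               sqrt(rowSums((xyz[pairs[, 1], ] - xyz[pairs[, 2], ])^2)))
})

test_that("metainference data term obeys its closed forms", {
  conf <- ca_conf(rbind(c(0, 0, 0), c(0, 0, 5)))
  rs <- data.frame(i = 1L, j = 2L, d_af = 5, pae = 1)
  em <- error_model(sigma_sem = 0.3, sigma_b = 0.4)
  perfect <- metainference_energy(conf, rs, em)
  expect_equal(perfect$data_term, 0)
  expect_equal(perfect$total, perfect$data_term + perfect$error_term)

  # single pair, deviation delta, combined sigma: kB T delta^2 / (2 s2)
  rs$d_af <- 4
  one <- metainference_energy(conf, rs, em, temperature = 298)
  expect_equal(one$data_term, kbt * 1^2 / (2 * (0.3^2 + 0.4^2)))

  # doubling every sigma divides the data term by exactly 4
  em2 <- error_model(sigma_sem = 0.6, sigma_b = 0.8)
  four <- metainference_energy(conf, rs, em2, temperature = 298)
  expect_equal(one$data_term / four$data_term, 4)
})

test_that("metainference energy sums replicas and validates sigmas", {
  confs <- list(ca_conf(rbind(c(0, 0, 0), c(0, 0, 5))),
                ca_conf(rbind(c(0, 0, 0), c(0, 0, 6))))
  rs <- data.frame(i = 1L, j = 2L, d_af = 5.5, pae = 1)
  em <- error_model(sigma_sem = 0.5, sigma_b = 0.5)
  sc <- metainference_energy(confs, rs, em, temperature = 298)
  expect_equal(sc$data_term, sum(sc$per_replica_data))
  expect_equal(sc$per_replica_data,
               rep(kbt * 0.25 / (2 * 0.5), 2))
  expect_error(error_model(sigma_sem = 0, sigma_b = 1), "within")
  expect_error(error_model(sigma_sem = 1, sigma_b = 11), "within")
  # convex in the replica distance, minimised at the predicted value
  devs <- seq(-2, 2, by = 0.5)
  e <- vapply(devs, function(dv) {
    conf <- ca_conf(rbind(c(0, 0, 0), c(0, 0, 5.5 + dv)))
    metainference_energy(conf, rs, em)$data_term
  }, numeric(1))
  expect_equal(which.min(e), which(devs == 0))
  expect_true(all(diff(e[devs >= 0]) > 0) && all(diff(e[devs <= 0]) < 0))
})

test_that("prediction bundles validate and round-trip through JSON", {
  expect_error(prediction_bundle(c(0.5, 1.3), diag(2), diag(2)),
               "\\[0, 1\\]")
  expect_error(prediction_bundle(c(0.5, 0.5), diag(3), diag(2)), "n x n")
  b <- make_bundle(5, matrix(2, 5, 5))
  path <- tempfile(fileext = ".json")
  write_prediction_bundle(b, path)
  b2 <- read_prediction_bundle(path)
  expect_equal(b2$plddt, b$plddt)
  expect_equal(b2$pae, b$pae, ignore_attr = TRUE)
  expect_equal(b2$d_af, b$d_af, ignore_attr = TRUE)
})

test_that("restraint sets export to CSV and PLUMED blocks", {
  rs <- structure(data.frame(i = c(1L, 2L), j = c(5L, 9L),
                             d_af = c(7.5, 12.25), pae = c(1, 2)),
                  class = c("restraint_set", "data.frame"))
  csv <- tempfile(fileext = ".csv")
  write_restraints_csv(rs, csv)
  expect_equal(utils::read.csv(csv)$d_af, c(7.5, 12.25))
  plumed <- tempfile()
  write_restraints_plumed(rs, plumed)
  lines <- readLines(plumed)
  expect_match(lines[1], "DISTANCE ATOMS=@CA-1,@CA-5")
  expect_match(lines[3], "RESTRAINT .*AT=0.750,1.225")
})
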