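# Cavity filtering, site clustering and docking boxes.

test_that("Eisenberg-Weiss hydropathy averages the scale constants", {
  expect_equal(eisenberg_weiss_hydropathy("ILE"), 1.38)
  expect_equal(eisenberg_weiss_hydropathy(c("LEU", "LYS")),
               (1.06 - 1.50) / 2)
  set.seed(2)
  res <- sample(c("ALA", "TRP", "ASP", "GLY", "TYR"), 12, replace = TRUE)
  expect_equal(eisenberg_weiss_hydropathy(res),
               eisenberg_weiss_hydropathy(rev(res)))
  expect_error(eisenberg_weiss_hydropathy("XYZ"), "XYZ")
  expect_error(eisenberg_weiss_hydropathy(character(0)), "non-empty")
})

# six cavities, each violating exactly one filter, plus one passing all
filter_fixture <- function() {
  ok <- function(...) cavity(frame_id = 1L, residues = 1:8,
                             volume = 300, area = 500,
                             avg_hydropathy = -0.5, ...)
  cavs <- list(
    pass = ok(),
    few = cavity(1L, 1:5, 300, 500, -0.5),            # not > 5 residues
    philic = cavity(1L, 1:8, 300, 500, 0.3),          # hydropathy > 0
    small_a = cavity(1L, 1:8, 300, 60, -0.5),         # area < 80
    big_a = cavity(1L, 1:8, 300, 2600, -0.5),         # area > 2480
    small_v = cavity(1L, 1:8, 100, 500, -0.5),        # volume < 120
    floppy = cavity(1L, 9:16, 300, 500, -0.5))        # high RMSF below
  rmsf <- stats::setNames(c(rep(1, 8), rep(6, 8)), 1:16)
  list(cavs = cavs, rmsf = rmsf)
}

test_that("cavity filters are conjunctive and match a condition oracle", {
  fx <- filter_fixture()
  sites <- filter_cavities(fx$cavs, fx$rmsf)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$cavity$residues, 1:8)
  expect_equal(sites[[1]]$site_id, 0L)
  # brute re-check of every condition over every cavity
  cfg <- filter_config()
  oracle <- vapply(fx$cavs, function(cv) {
    length(cv$residues) > cfg$min_residues &&
      cv$avg_hydropathy <= cfg$max_hydropathy &&
      cv$area >= cfg$area_bounds[1] && cv$area <= cfg$area_bounds[2] &&
      cv$volume >= cfg$min_volume &&
      mean(fx$rmsf[as.character(cv$residues)]) < cfg$max_mean_rmsf
  }, logical(1))
  expect_equal(sum(oracle), length(sites))
  expect_true(oracle[["pass"]])
})

test_that("filtering is idempotent, order-independent, and validates rmsf", {
  fx <- filter_fixture()
  sites <- filter_cavities(fx$cavs, fx$rmsf)
  again <- filter_cavities(lapply(sites, `[[`, "cavity"), fx$rmsf)
  expect_equal(lapply(again, `[[`, "cavity"),
               lapply(sites, `[[`, "cavity"))
  shuffled <- filter_cavities(fx$cavs[c(3, 1, 7, 2, 4, 6, 5)], fx$rmsf)
  expect_equal(lapply(shuffled, `[[`, "cavity"),
               lapply(sites, `[[`, "cavity"))
  expect_equal(filter_cavities(list(), fx$rmsf), list())
  expect_error(filter_cavities(fx$cavs, fx$rmsf[1:4]), "residues")
})

toy_sites <- function(res_sets) {
  lapply(seq_along(res_sets), function(k) {
    structure(list(site_id = k - 1L,
                   cavity = cavity(1L, res_sets[[k]], 300, 500, -0.5)),
              class = "binding_site")
  })
}

test_that("site clustering equals brute-force connected components", {
  sets <- list(1:10, 5:14, 30:40, 33:38, 50:55)
  sites <- toy_sites(sets)
  cl <- cluster_sites(sites, 0.5)
  # brute force: overlap coefficient graph + component search
  n <- length(sets)
  adj <- matrix(FALSE, n, n)
  for (a in 1:n) for (b in 1:n) {
    if (a == b) next
    ov <- length(intersect(sets[[a]], sets[[b]])) /
      min(length(sets[[a]]), length(sets[[b]]))
    adj[a, b] <- ov > 0.5
  }
  groups <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, "undirected"))$membership
  expect_equal(length(cl$clusters), length(unique(groups)))
  expect_equal(sort(lengths(cl$clusters), decreasing = TRUE),
               sort(as.integer(table(groups)), decreasing = TRUE))
  # pairwise-disjoint sites are all singletons
  cl2 <- cluster_sites(toy_sites(list(1:5, 10:15, 20:25)), 0.6)
  expect_length(cl2$clusters, 3)
  expect_true(all(lengths(cl2$clusters) == 1))
})

test_that("cluster count is monotone as the threshold tightens", {
  set.seed(41)
  sets <- lapply(1:12, function(i) sort(sample(1:60, sample(6:15, 1))))
  sites <- toy_sites(sets)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(th) {
    length(cluster_sites(sites, th)$clusters)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(cluster_sites(sites, 0), "\\(0, 1\\]")
  expect_error(cluster_sites(list(), 0.5), "at least one")
})

test_that("docking boxes bound the site residues plus padding", {
  conf <- ca_conf(rbind(c(0, 0, 0), c(10, 0, 0)))
  single <- structure(list(site_id = 0L,
                           cavity = cavity(1L, 1L, 200, 300, -0.5)),
                      class = "binding_site")
  b1 <- site_to_box(single, conf, padding = 5)
  expect_equal(b1$center, c(0, 0, 0))
  expect_equal(b1$size, c(10, 10, 10))
  pair <- structure(list(site_id = 1L,
                         cavity = cavity(1L, 1:2, 200, 300, -0.5)),
                    class = "binding_site")
  b2 <- site_to_box(pair, conf, padding = 5)
  expect_equal(b2$center, c(5, 0, 0))
  expect_equal(b2$size, c(20, 10, 10))
  expect_warning(site_to_box(single, conf, padding = 0), "degenerate")
})

test_that("cavity records validate and round-trip through CSV", {
  expect_error(cavity(1L, integer(0), 100, 100, 0), "non-empty")
  expect_error(cavity(1L, 1:6, -5, 100, 0), ">= 0")
  cv <- cavity(2L, c(4, 9, 11), 210.5, 330.25, resnames = c("LEU",
               "ILE", "VAL"), max_depth = 7.5, avg_depth = 3.25)
  expect_equal(cv$avg_hydropathy, mean(c(1.06, 1.38, 1.08)))
  path <- tempfile(fileext = ".csv")
  write_cavities_csv(list(cv), path)
  back <- read_cavities_csv(path)
  expect_equal(back[[1]]$residues, cv$residues)
  expect_equal(back[[1]]$avg_hydropathy, cv$avg_hydropathy)
  expect_equal(back[[1]]$volume, cv$volume)
})

test_that("the detector adapter passes fixtures through and fails loud", {
  cavs <- filter_fixture()$cavs[1:3]
  got <- detect_cavities(NULL, list(backend = "fixture",
                                    cavities = cavs), frame_id = 1L)
  expect_equal(got, cavs)
  expect_equal(detect_cavities(NULL, list(backend = "fixture")), list())
  expect_error(detect_cavities(NULL, list(backend = "kvfinder")),
               "fixture")
})
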