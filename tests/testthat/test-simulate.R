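test_that("simulation is deterministic given the master seed", {
  sc <- im_scenario(0.005, 0.5, 1, n_loci = 5L)
  d1 <- simulate_im_pair(sc, 77)
  d2 <- simulate_im_pair(sc, 77)
  expect_identical(d1, d2)
  d3 <- simulate_im_pair(sc, 78)
  expect_false(identical(d1$loci, d3$loci))
  gc_ <- genus_config(n_loci = 4L)
  expect_identical(simulate_reference_genus(gc_, 5),
                   simulate_reference_genus(gc_, 5))
})

test_that("simulated datasets have the configured dimensions and labels", {
  sc <- im_scenario(0.01, 0, 2, n_loci = 3L, locus_length = 120L,
                    haplotypes_per_pop = 3L)
  ds <- simulate_im_pair(sc, 9)
  expect_length(ds$loci, 3L)
  expect_true(all(vapply(ds$loci, dim, integer(2))[1, ] == 6L))
  expect_true(all(vapply(ds$loci, dim, integer(2))[2, ] == 120L))
  expect_setequal(populations(ds), c("pop1", "pop2"))
  g <- simulate_reference_genus(genus_config(n_species = 3L,
                                             pops_per_species = 2L,
                                             n_loci = 2L), 3)
  expect_length(populations(g), 6L)
  sp <- table(g$sample_map$species[!duplicated(g$sample_map$population)])
  expect_equal(unname(as.integer(sp)), c(2L, 2L, 2L))
})

test_that("genus output passes complete-matrix filtering unchanged and respects co-location", {
  g <- simulate_reference_genus(genus_config(n_loci = 3L), 21)
  expect_identical(filter_complete_matrix(g)$loci, g$loci)
  g0 <- simulate_reference_genus(genus_config(n_loci = 2L,
                                              co_location_rate = 0), 21)
  sm <- g0$sample_map[!duplicated(g0$sample_map$population), ]
  expect_equal(length(unique(sm$locality)), nrow(sm))
  # co-located populations are always conspecific
  g1 <- simulate_reference_genus(genus_config(n_loci = 2L,
                                              co_location_rate = 1), 22)
  sm1 <- g1$sample_map[!duplicated(g1$sample_map$population), ]
  for (loc in unique(sm1$locality))
    expect_length(unique(sm1$species[sm1$locality == loc]), 1L)
})

test_that("segregating sites grow with theta", {
  seg_count <- function(theta) {
    ds <- simulate_im_pair(im_scenario(theta, 0, 1, n_loci = 25L), 99)
    tot <- 0
    for (sq in ds$loci) tot <- tot + sum(apply(sq, 2, function(col)
      length(unique(col[col %in% c("A", "C", "G", "T")])) > 1))
    tot
  }
  s <- vapply(c(0.001, 0.005, 0.01), seg_count, numeric(1))
  expect_true(s[1] < s[2] && s[2] < s[3])
})

test_that("a split at time zero leaves the two populations exchangeable", {
  fst_tau0 <- vapply(1:20, function(r) {
    ds <- simulate_im_pair(im_scenario(0.005, 0, 0, n_loci = 25L), 1000 + r)
    div <- diversity_stats(ds, "pop1", "pop2")
    compute_fst(div[["pi_A"]], div[["pi_B"]], div[["d_xy"]])
  }, numeric(1))
  expect_lt(abs(mean(fst_tau0)), 0.05)
  # deep no-migration split: strong differentiation
  ds_deep <- simulate_im_pair(im_scenario(0.005, 0, 5, n_loci = 50L), 4242)
  div <- diversity_stats(ds_deep, "pop1", "pop2")
  expect_gt(compute_fst(div[["pi_A"]], div[["pi_B"]], div[["d_xy"]]), 0.8)
})

test_that("differentiation statistics rise monotonically with divergence time", {
  cell_means <- sapply(c(0.5, 2, 5), function(tau) {
    reps <- sapply(1:5, function(r) {
      ds <- simulate_im_pair(im_scenario(0.005, 0, tau, n_loci = 20L), 500 + r)
      div <- diversity_stats(ds, "pop1", "pop2")
      c(fst = compute_fst(div[["pi_A"]], div[["pi_B"]], div[["d_xy"]]),
        private = private_positions(ds, "pop1", "pop2"))
    })
    rowMeans(reps)
  })
  expect_true(all(diff(cell_means["fst", ]) > 0))
  expect_true(all(diff(cell_means["private", ]) >= 0))
  expect_gt(cell_means["private", 3], 0.9)
  # at the stated deep-split condition (theta 0.005, 200 loci) FST is high
  deep <- vapply(1:3, function(r) {
    ds <- simulate_im_pair(im_scenario(0.005, 0, 5, n_loci = 200L), 600 + r)
    div <- diversity_stats(ds, "pop1", "pop2")
    compute_fst(div[["pi_A"]], div[["pi_B"]], div[["d_xy"]])
  }, numeric(1))
  expect_gt(mean(deep), 0.8)
})

test_that("the default general grid is labeled by the documented rule", {
  grid <- default_general_grid()
  expect_length(grid, 3L * 4L * 5L)
  labs <- vapply(grid, function(s) s$label, integer(1))
  expect_true(any(labs == -1L, na.rm = TRUE) && any(labs == 1L, na.rm = TRUE))
  for (s in grid) {
    if (s$tau == 0) expect_identical(s$label, -1L)
    else if (s$mig >= 10) expect_identical(s$label, -1L)
    else if (s$tau >= 1 && s$mig <= 0.1) expect_identical(s$label, 1L)
    else expect_true(is.na(s$label))
  }
})

test_that("scenario and genus configs round-trip through YAML", {
  gc_ <- genus_config(n_species = 4L, tau_species = 2.5, co_location_rate = 0.3)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(gc_), path)
  back <- do.call(genus_config, yaml::read_yaml(path))
  expect_equal(back, gc_)
  sc <- im_scenario(0.005, 1, 2, label = -1L)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(sc), path2)
  expect_equal(do.call(im_scenario, yaml::read_yaml(path2)), sc)
})
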