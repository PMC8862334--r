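# small grid used throughout: extremes only, cheap but unambiguous
small_grid <- function(n_loci = 15L) {
  list(im_scenario(0.005, 0, 0, n_loci = n_loci, label = -1L),
       im_scenario(0.005, 0, 5, n_loci = n_loci, label = 1L))
}

test_that("general training sets have the promised size, balance and determinism", {
  ts <- build_general_training_set(small_grid(), 10L, seed = 3)
  expect_s3_class(ts, "training_set")
  expect_length(ts$labels, 20L)
  expect_equal(sum(ts$labels == -1L), 10L)
  ts2 <- build_general_training_set(small_grid(), 10L, seed = 3)
  expect_identical(ts, ts2)
  # one-class grid is rejected
  expect_error(build_general_training_set(small_grid()[1], 5L, seed = 3),
               "both classes")
})

test_that("unlabeled grid cells are excluded from training", {
  grid <- c(small_grid(), list(im_scenario(0.005, 1, 0.5, n_loci = 15L)))
  expect_true(is.na(grid[[3]]$label))
  ts <- build_general_training_set(grid, 4L, seed = 8)
  expect_length(ts$labels, 8L)
})

test_that("custom training labels follow the known species map", {
  g <- simulate_reference_genus(genus_config(n_loci = 15L), 31)
  ts <- build_custom_training_set(g)
  expect_equal(ts$provenance, "custom")
  expect_length(ts$labels, choose(6, 2))
  # conspecific pairs -1, heterospecific +1, straight from the generator map
  tb <- feature_table(g)
  sp <- setNames(g$sample_map$species, g$sample_map$population)
  expect_equal(ts$labels,
               ifelse(sp[tb$popA] == sp[tb$popB], -1L, 1L),
               ignore_attr = TRUE)
  expect_equal(sum(ts$labels == -1L), 3L)
  # all-conspecific reference is rejected (single class)
  sm1 <- g$sample_map; sm1$species <- "spX"
  g1 <- multilocus_dataset(g$loci, sm1)
  expect_error(build_custom_training_set(g1), "conspecific")
  # unlabeled reference is rejected
  g2 <- multilocus_dataset(g$loci, g$sample_map[, 1:3])
  expect_error(build_custom_training_set(g2), "species")
})

test_that("the classifier separates a separable toy problem and calibrates sanely", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, -2, 0.4), ncol = 2),
             matrix(rnorm(60, 2, 0.4), ncol = 2))
  colnames(x) <- c("f1", "f2")
  labs <- rep(c(-1L, 1L), each = 30)
  cfg <- feature_config(2)
  # bypass feature assembly: training_set checks shapes only
  ts <- structure(list(features = cbind(x, matrix(0, 60, 4)), labels = labs,
                       provenance = "general", cfg = cfg,
                       scaling = fit_scaling(cbind(x, matrix(0, 60, 4)))),
                  class = "training_set")
  colnames(ts$features) <- feature_names(cfg)
  model <- train_classifier(ts, seed = 1)
  pred <- predict_pairs(model, ts$features)
  expect_equal(pred$label, labs)
  expect_true(all(pred$p_same[labs == -1L] > 0.5))
  expect_true(all(pred$p_same[labs == 1L] < 0.5))
  expect_true(all(pred$p_same >= 0 & pred$p_same <= 1))
})

test_that("swapping the labels swaps the calibrated probabilities", {
  set.seed(6)
  x <- rbind(matrix(rnorm(80, -1.5, 0.5), ncol = 2),
             matrix(rnorm(80, 1.5, 0.5), ncol = 2))
  pad <- function(m) { m <- cbind(m, matrix(0, nrow(m), 4)); m }
  cfg <- feature_config(2)
  mk_ts <- function(labels) {
    f <- pad(x); colnames(f) <- feature_names(cfg)
    structure(list(features = f, labels = labels, provenance = "general",
                   cfg = cfg, scaling = fit_scaling(f)),
              class = "training_set")
  }
  labs <- rep(c(-1L, 1L), each = 40)
  m1 <- train_classifier(mk_ts(labs), seed = 2)
  m2 <- train_classifier(mk_ts(-labs), seed = 2)
  p1 <- predict_pairs(m1, pad(x))$p_same
  p2 <- predict_pairs(m2, pad(x))$p_same
  expect_true(all(abs(p1 - (1 - p2)) < 0.05))
})

test_that("reference training beats general training on deeply structured conspecific pairs", {
  # Conspecific populations in the motivating taxa are anciently diverged
  # lineages; at tau_pop = 1.5 (2N units) with 4Nm = 0.1 they sit beyond the
  # general grid's same-species manifold, so a grid-trained model splits
  # them, while a reference-trained model learns they are conspecific.
  gm <- acc_general_model()
  deep <- function(colo) genus_config(tau_pop = 1.5, within_species_mig = 0.1,
                                      co_location_rate = colo)
  ref <- simulate_reference_genus(deep(0.5), seed = 5002)
  focal <- simulate_reference_genus(deep(1), seed = 5003)
  custom <- train_classifier(build_custom_training_set(ref), seed = 1)
  cls_c <- classify_pairs(custom, focal)
  cls_g <- classify_pairs(gm, focal)
  sp <- setNames(focal$sample_map$species, focal$sample_map$population)
  consp <- sp[cls_c$popA] == sp[cls_c$popB]
  expect_gt(mean(cls_c$p_same[consp]), mean(cls_g$p_same[consp]))
  expect_gt(same_locality_consistency(cls_c, focal)$mean_p_same_colocated,
            same_locality_consistency(cls_g, focal)$mean_p_same_colocated)
  # custom recovers the true species count; general over-splits
  expect_equal(aggregate_partition(cls_c)$k, 3L)
  expect_gte(aggregate_partition(cls_g)$k, 3L)
})

test_that("training is deterministic: same seed and set give identical serialized models", {
  ts <- build_general_training_set(small_grid(), 5L, seed = 13)
  m1 <- train_classifier(ts, seed = 4)
  m2 <- train_classifier(ts, seed = 4)
  f1 <- withr::local_tempfile(fileext = ".rds")
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_model(m1, f1); save_model(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_s3_class(load_model(f1), "delim_model")
})

test_that("degenerate training sets are rejected with a helpful error", {
  ts <- build_general_training_set(small_grid(), 5L, seed = 13)
  ts$labels[ts$labels == 1L][-1] <- -1L   # leave one +1 example
  ts$labels <- head(c(ts$labels[ts$labels == -1L], 1L), length(ts$labels))
  expect_error(train_classifier(ts, seed = 1), "2 examples per class")
})
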