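test_that("reference normalization gives mean 0 / sd 1 and matches hand arithmetic", {
  ref <- c(1, 2, 3)
  expect_equal(normalize_scores(2, ref), 0)
  expect_equal(normalize_scores(3, ref), 1 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(normalize_scores(3, ref), 1.2247, tolerance = 1e-4)
  set.seed(2)
  r <- rnorm(50)
  z <- normalize_scores(r, r)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  expect_error(normalize_scores(1, c(2, 2, 2)), "zero")
})

test_that("ensemble score is the mean of normalized member scores", {
  expect_equal(ensemble_score(c(0.5, -0.5)), 0)
  expect_equal(ensemble_score(matrix(c(1, 1, 3, 3), 2)), c(2, 2))
  expect_equal(ensemble_score(matrix(0.7, 1, 5)), 0.7)
})

test_that("relative uncertainty divides the member spread by the shifted score", {
  # scores {1, 3}, reference min -1: sigma = 1 (population), yhat = 3
  out <- relative_uncertainty(matrix(c(1, 3), 1), reference_min = -1)
  expect_equal(out$sigma, 1)
  expect_equal(out$yhat, 3)
  expect_equal(out$u_rel, 1 / 3)
  # identical member scores give zero uncertainty
  expect_equal(relative_uncertainty(matrix(c(2, 2, 2), 1), 0)$u_rel, 0)
  # non-positive shifted scores are dropped, not scored
  out2 <- relative_uncertainty(matrix(c(-2, -1, 0.5, 1.5), 2), 0)
  expect_true(out2$dropped[1])
  expect_false(out2$dropped[2])
  expect_true(is.na(out2$u_rel[1]))
})

test_that("top-fraction and uncertainty-half selection use floor semantics with stable ties", {
  s <- seq_len(1000) / 1000
  expect_length(select_top_fraction(s, 0.1), 100)
  expect_length(select_top_fraction(s, 1), 1000)
  # the screening-scale arithmetic: floor(0.001 * 27,354,600) and half of it
  expect_equal(floor(0.001 * 27354600), 27354)
  expect_length(drop_uncertain_half(runif(27354)), 13677)
  expect_length(drop_uncertain_half(1), 0)
  # ties broken by enumeration order
  expect_equal(select_top_fraction(rep(1, 10), 0.3), 1:3)
  expect_equal(drop_uncertain_half(rep(0.2, 5)), 1:2)
})

test_that("scaled screening run exercises the same selection path as the full library", {
  set.seed(10)
  n <- 1e5
  scores <- rnorm(n)
  u <- runif(n)
  top <- select_top_fraction(scores, 0.001)
  expect_length(top, 100)
  expect_true(all(scores[top] >= sort(scores, decreasing = TRUE)[100]))
  kept <- drop_uncertain_half(u[top])
  expect_length(kept, 50)
  expect_lte(max(u[top][kept]), min(u[top][-kept]))
})

test_that("ensemble selection is invariant to per-model affine rescaling", {
  set.seed(5)
  n <- 200; k <- 4
  raw <- matrix(rnorm(n * k), n, k)
  ref <- matrix(rnorm(300 * k), 300, k)
  norm1 <- vapply(1:k, function(i) normalize_scores(raw[, i], ref[, i]),
                  numeric(n))
  # affine-rescale each model's raw outputs (and its reference scores)
  a <- runif(k, 0.5, 3); b <- rnorm(k)
  norm2 <- vapply(1:k, function(i)
    normalize_scores(a[i] * raw[, i] + b[i], a[i] * ref[, i] + b[i]),
    numeric(n))
  expect_equal(norm1, norm2, tolerance = 1e-9)
  e1 <- ensemble_score(norm1); e2 <- ensemble_score(norm2)
  expect_equal(select_top_fraction(e1, 0.05), select_top_fraction(e2, 0.05))
})

test_that("diverse hits picks the best candidate per well-separated cluster", {
  set.seed(3)
  blob1 <- matrix(rnorm(40, mean = 0, sd = 0.5), 20, 2)
  blob2 <- matrix(rnorm(40, mean = 20, sd = 0.5), 20, 2)
  X <- rbind(blob1, blob2)
  scores <- c(seq(0, 1, length.out = 20), seq(0, 1, length.out = 20))
  picks <- diverse_hits(X, scores, k = 2, n_restarts = 25, seed = 1)
  expect_length(picks, 2)
  expect_setequal(picks, c(20L, 40L)) # the top scorer of each blob
  # k = N returns everything
  expect_setequal(diverse_hits(X[1:4, ], scores[1:4], k = 4), 1:4)
  expect_error(diverse_hits(X[1:3, ], scores[1:3], k = 5), "exceeds")
})

test_that("fivefold ensembling partitions the data into disjoint validation folds", {
  catl <- tiny_catalogue()
  ds <- tiny_labelled_data(n = 100, noise_sd = 0, seed = 12)
  cfg <- tiny_cfg(seed = 6)
  dat <- comet_data(ds$formulations, catl, cfg)
  tc <- train_config(max_epochs = 2, patience = 2, seed = 3, batch_size = 32)
  ens <- comet_ensemble(dat, cfg, tc, n_models = 5, mode = "folds", seed = 2)
  folds <- lapply(ens$models, function(m) m$split$val)
  expect_equal(sort(unlist(folds)), 1:100)          # union = dataset
  expect_equal(sum(lengths(folds)), 100)            # disjoint
  for (i in 1:5)
    expect_setequal(c(ens$models[[i]]$split$train, folds[[i]]), 1:100)
  # after normalization the reference set has mean 0, sd 1 per model
  ref_norm <- vapply(seq_along(ens$models), function(i)
    normalize_scores(
      forward_batch(ens$models[[i]], dat$tokens, task = "t1"),
      ens$reference$t1$stats[[i]]), numeric(100))
  expect_equal(colMeans(ref_norm), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(ref_norm, 2, function(x) sqrt(mean(x^2))), rep(1, 5),
               tolerance = 1e-9)
  pred <- predict(ens, dat$tokens)
  expect_true(all(c("ensemble", "u_rel", "dropped") %in% names(pred)))
  # seeds mode: shared split, different initializations
  ens2 <- comet_ensemble(dat, cfg, tc, n_models = 2, mode = "seeds", seed = 2)
  expect_identical(ens2$models[[1]]$split, ens2$models[[2]]$split)
  expect_false(identical(ens2$models[[1]]$theta, ens2$models[[2]]$theta))
})

test_that("the screening funnel has monotone nonincreasing stage counts", {
  catl <- tiny_catalogue()
  ds <- tiny_labelled_data(n = 90, noise_sd = 0, seed = 13)
  cfg <- tiny_cfg(seed = 8)
  dat <- comet_data(ds$formulations, catl, cfg)
  tc <- train_config(max_epochs = 2, patience = 2, seed = 1, batch_size = 32)
  ens <- comet_ensemble(dat, cfg, tc, n_models = 2, mode = "folds", seed = 4)
  lib <- virtual_library(tiny_grid(dual = FALSE))
  hits <- ds$formulations[order(-ds$formulations$`label:t1`)[1:5], ]
  rep <- screen_library(ens, lib, catl, hits = hits, exclude_radius = 10,
                        top_fraction = 0.5, k = 3, n_restarts = 20,
                        chunk_size = 17, seed = 2)
  cts <- rep$counts
  expect_equal(cts[["enumerated"]], lib$count)
  expect_lte(cts[["scored"]], cts[["enumerated"]])
  expect_lte(cts[["top_fraction"]], cts[["scored"]])
  expect_lte(cts[["uncertainty_retained"]], cts[["top_fraction"]])
  expect_lte(cts[["selected"]], cts[["uncertainty_retained"]])
  expect_equal(nrow(rep$selected), cts[["selected"]])
  expect_equal(cts[["top_fraction"]], floor(0.5 * cts[["scored"]]))
  # deterministic rerun
  rep2 <- screen_library(ens, lib, catl, hits = hits, exclude_radius = 10,
                         top_fraction = 0.5, k = 3, n_restarts = 20,
                         chunk_size = 17, seed = 2)
  expect_identical(rep$selected$formulation_id, rep2$selected$formulation_id)
})

test_that("lead optimization returns the zone optima found by exhaustive scoring", {
  catl <- tiny_catalogue()
  ds <- tiny_labelled_data(n = 80, noise_sd = 0, seed = 14)
  cfg <- tiny_cfg(seed = 9)
  dat <- comet_data(ds$formulations, catl, cfg)
  tc <- train_config(max_epochs = 2, patience = 2, seed = 1, batch_size = 32)
  ens <- comet_ensemble(dat, cfg, tc, n_models = 2, mode = "folds", seed = 5)
  grid <- tiny_grid()
  lead <- enumerate_single_il(grid)[1, ]
  lead$np_ratio <- 6
  out <- lead_optimization_segments(lead, grid, ens, catl, radius = 40)
  expect_true(all(out$zone %in% c("composition", "substitution", "parameter")))
  expect_false(any(out$component_ids == lead$component_ids &
                     out$molar_percents == lead$molar_percents &
                     out$np_ratio == lead$np_ratio))
  # zones are disjoint by construction: composition zone keeps the lipid
  # set, substitution changes it, parameter keeps set+composition
  comp <- out[out$zone == "composition", ]
  if (nrow(comp)) expect_identical(comp$component_ids, lead$component_ids)
  sub <- out[out$zone == "substitution", ]
  if (nrow(sub)) expect_false(identical(sub$component_ids,
                                        lead$component_ids))
  # brute force: the composition-zone pick is the best-scoring candidate
  lib <- virtual_library(grid)
  cand <- lib$slice(1, lib$count)
  pred <- predict(ens, cand, catalogue = catl)
  Ml <- molar_slot_matrix(lead, catl)
  Mc <- molar_slot_matrix(cand, catl)
  d <- l1_molar_distance(Mc, Ml[1, ])
  zone1 <- which(cand$component_ids == lead$component_ids & d > 1e-9 &
                   d <= 40 & abs(cand$np_ratio - lead$np_ratio) < 1e-9)
  if (nrow(comp) && length(zone1)) {
    best <- zone1[which.max(pred$ensemble[zone1])]
    expect_equal(comp$ensemble, max(pred$ensemble[zone1]), tolerance = 1e-9)
    expect_identical(comp$molar_percents, cand$molar_percents[best])
  }
})
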