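test_that("scores are invariant to component-token order and reproducible", {
  catl <- tiny_catalogue()
  cfg <- tiny_cfg(tasks = c("t1", "t2"), seed = 3)
  model <- comet_init(cfg)
  tbl <- formulation_table(
    list(c("ION-A", "ION-B", "HEL-A", "STE-A", "PEG-A")),
    list(c(30, 20, 16, 31.5, 2.5)), np_ratio = 6)
  s <- forward_score(model, tbl, task = "t1", catalogue = catl)
  set.seed(9)
  for (i in 1:5) {
    perm <- sample(5)
    pc <- parse_components(tbl)
    tp <- tbl
    tp$component_ids <- paste(pc$ids[[1]][perm], collapse = ";")
    tp$molar_percents <- paste(pc$molar[[1]][perm], collapse = ";")
    sp <- forward_score(model, tp, task = "t1", catalogue = catl)
    expect_equal(unname(sp), unname(s), tolerance = 1e-5)
  }
  # repeated calls are bit-identical
  expect_identical(s, forward_score(model, tbl, task = "t1", catalogue = catl))
  # two models from the same seed agree exactly; different seeds differ
  m2 <- comet_init(cfg)
  expect_identical(forward_score(m2, tbl, task = "t1", catalogue = catl), s)
  cfg2 <- cfg; cfg2$seed <- 99L
  m3 <- comet_init(cfg2)
  expect_false(isTRUE(all.equal(
    forward_score(m3, tbl, task = "t1", catalogue = catl), s)))
})

test_that("per-task CLS tokens give independent scores and heads read the CLS state", {
  catl <- tiny_catalogue()
  cfg <- tiny_cfg(tasks = c("t1", "t2"), seed = 5)
  model <- comet_init(cfg)
  tbl <- formulation_table(list(c("ION-A", "HEL-A", "STE-A", "PEG-A")),
                           list(c(35, 16, 46.5, 2.5)), np_ratio = 6)
  s1 <- forward_score(model, tbl, task = "t1", catalogue = catl)
  s2 <- forward_score(model, tbl, task = "t2", catalogue = catl)
  expect_false(isTRUE(all.equal(unname(s1), unname(s2))))
  expect_error(forward_score(model, tbl, task = "t9", catalogue = catl),
               "unknown task")
  # head(cls) == forward score: recompute the two-layer head by hand
  cls <- extract_cls_representation(model, tbl, task = "t1",
                                    catalogue = catl)
  expect_equal(ncol(cls), cfg$d_token)
  lay <- model$layout$tasks[[1]]
  th <- model$theta
  hW1 <- matrix(th[lay$hW1 + seq_len(cfg$d_token * cfg$head_hidden)],
                cfg$d_token, cfg$head_hidden)
  hb1 <- th[lay$hb1 + seq_len(cfg$head_hidden)]
  hW2 <- th[lay$hW2 + seq_len(cfg$head_hidden)]
  hb2 <- th[lay$hb2 + 1]
  u <- pmax(0, drop(cls %*% hW1) + hb1)
  expect_equal(unname(sum(u * hW2) + hb2), unname(s1), tolerance = 1e-6)
})

test_that("batched scoring equals single-formulation scoring despite mixed sizes", {
  catl <- tiny_catalogue()
  cfg <- tiny_cfg(seed = 2)
  model <- comet_init(cfg)
  tbl <- formulation_table(
    list(c("ION-A", "HEL-A", "STE-A", "PEG-A"),
         c("ION-A", "ION-C", "HEL-B", "STE-A", "PEG-B"),
         c("ION-B", "HEL-A", "STE-B", "PEG-A")),
    list(c(35, 16, 46.5, 2.5), c(30, 20, 16, 31.5, 2.5),
         c(50, 10, 37.5, 2.5)),
    np_ratio = c(6, 9, 12), aq_org_ratio = c("3:1", "1:1", "3:1"))
  sb <- forward_batch(model, tbl, catalogue = catl)
  for (i in 1:3) {
    si <- forward_score(model, tbl[i, , drop = FALSE], catalogue = catl)
    expect_equal(unname(sb[i]), unname(si), tolerance = 1e-5)
  }
  expect_error(forward_batch(model, tbl[0, , drop = FALSE],
                             catalogue = catl), "empty|fewer")
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- comet_config(tasks = c("a", "b"), d_token = 16, n_blocks = 2,
                      n_heads = 2, mlp_hidden = 12, head_hidden = 5,
                      d_mol = 8, d_comp = 4, d_type = 4,
                      np_range = c(0, 20), seed = 3)
  model <- comet_init(cfg)
  lay <- model$layout
  ccfg <- formucomet:::cfg_for_cpp(cfg)
  set.seed(42)
  ncomp <- c(4L, 5L, 4L)
  ntot <- sum(ncomp)
  FP <- matrix(rbinom(8 * ntot, 1, 0.3), 8, ntot)
  molar <- runif(ntot, 0, 60)
  type <- as.integer(sample(0:3, ntot, TRUE))
  np <- runif(3, 1, 15)
  phase <- as.integer(c(0, 1, 0))
  y <- c(0.2, 0.9, 0.5)
  pr <- make_pairs(y)
  loss_at <- function(theta) {
    g <- numeric(lay$n_par)
    formucomet:::cpp_comet_rank_grad(theta, g, ccfg, lay, FP, molar, type,
                                     ncomp, np, phase, 1L, pr$h - 1L,
                                     pr$l - 1L, pr$dy, 0.01)$loss
  }
  grad <- numeric(lay$n_par)
  formucomet:::cpp_comet_rank_grad(model$theta, grad, ccfg, lay, FP, molar,
                                   type, ncomp, np, phase, 1L, pr$h - 1L,
                                   pr$l - 1L, pr$dy, 0.01)
  set.seed(7)
  idx <- sample(lay$n_par, 200)
  eps <- 1e-6
  num <- vapply(idx, function(j) {
    tp <- model$theta; tp[j] <- tp[j] + eps
    tm <- model$theta; tm[j] <- tm[j] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, 0)
  rel <- abs(num - grad[idx]) / pmax(1e-6, abs(num) + abs(grad[idx]))
  # allow a handful of coordinates near ReLU kinks where central
  # differences are unreliable
  expect_gt(mean(rel < 1e-3), 0.97)
  expect_lt(stats::median(rel), 1e-5)
})

test_that("gradients do not flow into the frozen molecular embedding", {
  # the fingerprint enters as data, not parameters: the gradient vector has
  # entries only at layout offsets, and perturbing a fingerprint changes
  # the score while leaving the parameter count fixed
  cfg <- comet_config(tasks = "a", d_token = 16, n_blocks = 1, n_heads = 2,
                      mlp_hidden = 12, head_hidden = 5, d_mol = 8,
                      d_comp = 4, d_type = 4, np_range = c(0, 20), seed = 1)
  model <- comet_init(cfg)
  lay <- model$layout
  ccfg <- formucomet:::cfg_for_cpp(cfg)
  set.seed(1)
  FP <- matrix(rbinom(16, 1, 0.5), 8, 2)
  grad <- numeric(lay$n_par)
  res <- formucomet:::cpp_comet_rank_grad(
    model$theta, grad, ccfg, lay, FP, c(60, 40), c(0L, 1L), 2L, 6, 0L, 0L,
    integer(0), integer(0), numeric(0), 0.01)
  expect_length(grad, lay$n_par)
  # every trainable parameter group receives gradient under a real pair
  tok2 <- list(FP = cbind(FP, FP), molar = c(60, 40, 55, 45),
               type = c(0L, 1L, 0L, 1L), ncomp = c(2L, 2L),
               np = c(6, 12), phase = c(0L, 1L))
  grad2 <- numeric(lay$n_par)
  formucomet:::cpp_comet_rank_grad(
    model$theta, grad2, ccfg, lay, tok2$FP, tok2$molar, tok2$type,
    tok2$ncomp, tok2$np, tok2$phase, 0L, 0L, 1L, 0.5, 0.01)
  blocks <- lay$blocks[[1]]
  sizes <- c(Wq = 256, Wk = 256, Wv = 256, Wo = 256, Wm1 = 16 * 12,
             Wm2 = 12 * 16)
  for (nm in names(sizes))
    expect_gt(sum(abs(grad2[blocks[[nm]] + seq_len(sizes[[nm]])])), 0)
  expect_gt(sum(abs(grad2[lay$gc_mu + 1:4])), 0)
  expect_gt(sum(abs(grad2[lay$tasks[[1]]$cls + 1:16])), 0)
})
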