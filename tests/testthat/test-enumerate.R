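test_that("single-ionizable enumeration covers the full lipid x ratio grid", {
  grid <- tiny_grid() # 3 x 2 x 2 x 2 lipids, 2 ratios
  tbl <- enumerate_single_il(grid)
  expect_equal(nrow(tbl), 3 * 2 * 2 * 2 * 2)
  expect_equal(anyDuplicated(paste(tbl$component_ids, tbl$molar_percents)), 0)
  # one of each with a single ratio enumerates exactly one formulation
  g1 <- design_grid("ION-A", "HEL-A", "STE-A", "PEG-A", np_ratios = 6)
  expect_equal(nrow(enumerate_single_il(g1)), 1)
})

test_that("dual-ionizable enumeration yields |I|^2 x |R| ordered pairs", {
  grid <- tiny_grid(dual = TRUE) # 3 ionizable, 2 ratios
  tbl <- enumerate_dual_il(grid)
  expect_equal(nrow(tbl), 9 * 2)
  pc <- parse_components(tbl)
  n_comp <- lengths(pc$ids)
  # self-pairs collapse to four components, true pairs have five
  expect_equal(sum(n_comp == 4), 3 * 2)
  expect_equal(sum(n_comp == 5), 6 * 2)
  # 60:40 split of the ionizable allocation
  five <- which(n_comp == 5)[1]
  m <- pc$molar[[five]]
  expect_equal(m[1] / m[2], 60 / 40, tolerance = 1e-9)
  expect_equal(sum(m), 100, tolerance = 1e-9)
  g1 <- design_grid("ION-A", "HEL-A", "STE-A", "PEG-A", np_ratios = 6,
                    dual_ionizable = list(enabled = TRUE, split = c(60, 40)))
  expect_equal(nrow(enumerate_dual_il(g1)), 1)
})

test_that("molar sweeps are evenly spaced and rescale the other classes", {
  sw <- enumerate_sweeps(base_molar_ratio(), "ionizable", 10, 80, 24)
  expect_length(sw, 24)
  vals <- unname(vapply(sw, `[[`, 0, "ionizable"))
  expect_equal(vals[1], 10)
  expect_equal(vals[24], 80)
  expect_equal(diff(vals), rep(70 / 23, 23), tolerance = 1e-9)
  for (v in sw) expect_equal(sum(v), 100, tolerance = 1e-9)
  # non-swept classes keep their base proportions
  b <- base_molar_ratio()
  expect_equal(sw[[1]][["helper"]] / sw[[1]][["sterol"]],
               b[["helper"]] / b[["sterol"]], tolerance = 1e-9)
  expect_error(enumerate_sweeps(b, "ionizable", 80, 10, 5), "lo must be")
  expect_error(enumerate_sweeps(b, "ionizable", 10, 80, 1), "n_points")
})

test_that("the reference design reproduces its published counts", {
  ratios <- reference_molar_ratios()
  expect_length(ratios, 13)
  for (r in ratios) expect_equal(sum(r), 100, tolerance = 1e-9)
  expect_length(reference_molar_compositions(), 85)

  catl <- sample_catalogue()
  grid <- reference_grid(catl)
  expect_equal(length(grid$ionizable) * length(grid$sterol) *
                 length(grid$helper) * length(grid$peg), 84)
  expect_equal(nrow(enumerate_single_il(grid)), 1092)
  expect_equal(nrow(enumerate_dual_il(grid)), 637)
  man <- reference_manifest()
  expect_equal(man$part1_unique, 975)
  expect_equal(man$total, 3028)
})

test_that("virtual library count matches brute-force materialization on random grids", {
  catl <- tiny_catalogue()
  by <- split(catl$id, catl$component_class)
  set.seed(11)
  for (i in 1:15) {
    nI <- sample(1:3, 1); nH <- sample(1:2, 1)
    nS <- sample(1:2, 1); nP <- sample(1:2, 1)
    nR <- sample(1:3, 1); nV <- sample(1:2, 1); nA <- sample(1:2, 1)
    dual <- runif(1) < 0.4
    ratios <- lapply(seq_len(nR), function(k)
      rescale_composition(base_molar_ratio(), "ionizable", 20 + 5 * k))
    names(ratios) <- sprintf("R%d", seq_len(nR))
    g <- design_grid(by$ionizable[seq_len(nI)], by$helper[seq_len(nH)],
                     by$sterol[seq_len(nS)], by$peg[seq_len(nP)],
                     molar_ratios = ratios, np_ratios = seq_len(nV) * 6,
                     aq_org_ratios = c("3:1", "1:1")[seq_len(nA)],
                     dual_ionizable = list(enabled = dual, split = c(60, 40)))
    lib <- virtual_library(g)
    closed_form <- (nI + if (dual) nI^2 else 0) * nH * nS * nP * nR * nV * nA
    expect_equal(lib$count, closed_form)
    tbl <- lib$slice(1, lib$count)
    expect_equal(nrow(tbl), closed_form)
    key <- paste(tbl$component_ids, tbl$molar_percents, tbl$np_ratio,
                 tbl$aq_org_ratio)
    # dual self-pairs duplicate their single-ionizable counterparts (that is
    # what makes the dual count |I|^2); everything else is unique
    n_self_dup <- if (dual) nI * nH * nS * nP * nR * nV * nA else 0
    expect_equal(sum(duplicated(key)), n_self_dup)
  }
})

test_that("virtual library streaming is reproducible and consistent with slicing", {
  grid <- tiny_grid(dual = TRUE)
  lib <- virtual_library(grid)
  expect_equal(lib$count, (3 + 9) * 2 * 2 * 2 * 2 * 2 * 2)
  whole <- lib$slice(1, lib$count)
  seen <- list()
  lib$chunks(37, function(tbl, from) seen[[length(seen) + 1L]] <<- tbl)
  streamed <- do.call(rbind, seen)
  rownames(streamed) <- NULL
  expect_identical(streamed, whole)
  expect_identical(lib$pick(c(5, 50)),
                   rbind(lib$slice(5, 5), lib$slice(50, 50)))
})

test_that("near-hit exclusion is inclusive and lipid-set aware", {
  catl <- tiny_catalogue()
  hits <- formulation_table(list(c("ION-A", "HEL-A", "STE-A", "PEG-A")),
                            list(c(35, 16, 46.5, 2.5)), np_ratio = 6)
  cand <- formulation_table(
    list(c("ION-A", "HEL-A", "STE-A", "PEG-A"),   # at distance 10 (boundary)
         c("ION-A", "HEL-A", "STE-A", "PEG-A"),   # exact duplicate
         c("ION-A", "HEL-A", "STE-A", "PEG-A"),   # far away
         c("ION-B", "HEL-A", "STE-A", "PEG-A")),  # same composition, other lipid
    list(c(40, 16, 41.5, 2.5), c(35, 16, 46.5, 2.5), c(60, 16, 21.5, 2.5),
         c(35, 16, 46.5, 2.5)), np_ratio = 6)
  out <- exclude_near_hits(cand, hits, radius = 10, catalogue = catl)
  expect_identical(out$formulation_id, cand$formulation_id[c(3, 4)])
  # radius 0 removes only exact-composition duplicates
  out0 <- exclude_near_hits(cand, hits, radius = 0, catalogue = catl)
  expect_identical(out0$formulation_id, cand$formulation_id[c(1, 3, 4)])
  # radius below the minimal distance leaves the library unchanged
  out_small <- exclude_near_hits(cand[c(1, 3), ], hits, radius = 5,
                                 catalogue = catl)
  expect_equal(nrow(out_small), 2)
})
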