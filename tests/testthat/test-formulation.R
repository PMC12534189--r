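test_that("formulation validation enforces the composition invariants", {
  catl <- tiny_catalogue()
  ok <- formulation_table(list(c("ION-A", "HEL-A", "STE-A", "PEG-A")),
                          list(c(35, 16, 46.5, 2.5)), np_ratio = 6)
  expect_identical(validate_formulations(ok, catl)$molar_percents,
                   ok$molar_percents)

  # five-component dual-ionizable summing to 100 is valid
  dual <- formulation_table(
    list(c("ION-A", "ION-B", "HEL-A", "STE-A", "PEG-A")),
    list(c(30, 20, 16, 31.5, 2.5)), np_ratio = 6)
  expect_silent(validate_formulations(dual, catl))

  bad_sum <- formulation_table(list(c("ION-A", "HEL-A", "STE-A", "PEG-A")),
                               list(c(35, 16, 46.5, 3.5)), np_ratio = 6)
  expect_error(validate_formulations(bad_sum, catl), "molar sum 101")

  unknown <- formulation_table(list(c("NOPE", "HEL-A")), list(c(50, 50)),
                               np_ratio = 6)
  expect_error(validate_formulations(unknown, catl), "unknown molecule")

  no_ratio <- formulation_table(list(c("ION-A", "HEL-A")), list(c(50, 50)))
  expect_error(validate_formulations(no_ratio, catl), "missing both")

  # slightly-off sums are renormalized with a warning
  near <- formulation_table(list(c("ION-A", "HEL-A")), list(c(50, 50.005)),
                            np_ratio = 6)
  expect_warning(fixed <- validate_formulations(near, catl), "renormalizing")
  expect_equal(sum(parse_components(fixed)$molar[[1]]), 100, tolerance = 1e-9)
})

test_that("label normalization divides by plate standard, averages, logs and min-max scales", {
  raw <- data.frame(formulation_id = c("a", "b", "c"), plate_id = "P1",
                    raw_value = c(10, 100, 1000))
  expect_equal(normalize_labels(raw, c(P1 = 1)),
               c(a = 0, b = 0.5, c = 1))

  # replicate averaging happens on the ratio scale, before the log
  raw4 <- data.frame(formulation_id = rep(c("a", "b", "c"), each = 2),
                     plate_id = "P1",
                     raw_value = c(5, 15, 100, 100, 900, 1100))
  expect_equal(normalize_labels(raw4, c(P1 = 1)), c(a = 0, b = 0.5, c = 1))

  # plate standards cancel plate effects
  raw2 <- data.frame(formulation_id = c("a", "b", "c", "d"),
                     plate_id = c("P1", "P1", "P2", "P2"),
                     raw_value = c(10, 1000, 50, 5000))
  lab <- normalize_labels(raw2, c(P1 = 10, P2 = 50))
  expect_equal(unname(lab[c("a", "c")]), c(0, 0))
  expect_equal(unname(lab[c("b", "d")]), c(1, 1))

  expect_error(normalize_labels(
    data.frame(formulation_id = "a", plate_id = "P1", raw_value = 5),
    c(P1 = 1)), "degenerate")
  expect_error(normalize_labels(
    data.frame(formulation_id = c("a", "b"), plate_id = "P1",
               raw_value = c(3, 3)), c(P1 = 3)), "degenerate")
  expect_error(normalize_labels(
    data.frame(formulation_id = "a", plate_id = "P1", raw_value = -1),
    c(P1 = 1)), "nonpositive")

  # output always spans [0, 1] exactly for >= 2 distinct inputs
  set.seed(1)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    raw_r <- data.frame(formulation_id = sprintf("f%02d", seq_len(n)),
                        plate_id = "P1",
                        raw_value = exp(rnorm(n, 5, 2)))
    lab <- normalize_labels(raw_r, c(P1 = 100))
    expect_equal(range(lab), c(0, 1))
  }
})

test_that("weight-ratio to N/P conversion follows amine and phosphate stoichiometry", {
  catl <- tiny_catalogue()
  tbl <- formulation_table(list(c("ION-A", "HEL-A", "STE-A", "PEG-A")),
                           list(c(35, 16, 46.5, 2.5)), weight_ratio = 10)
  catl$molar_mass[catl$id == "ION-A"] <- 710
  catl$amine_count[catl$id == "ION-A"] <- 1L
  out <- weight_ratio_to_np(tbl, catl, per_nt_mass = 330)
  expect_equal(out$np_ratio, 10 * 330 / 710, tolerance = 1e-12)

  # doubling the weight ratio doubles N/P (linearity)
  tbl2 <- tbl; tbl2$weight_ratio <- 20
  expect_equal(weight_ratio_to_np(tbl2, catl)$np_ratio,
               2 * out$np_ratio, tolerance = 1e-12)

  # masses chosen so amine moles equal phosphate moles give N/P = 1
  catl$molar_mass[catl$id == "ION-A"] <- 330
  expect_equal(weight_ratio_to_np({
    t3 <- tbl; t3$weight_ratio <- 1; t3
  }, catl)$np_ratio, 1, tolerance = 1e-12)

  # missing amine count is an error
  catl$amine_count[catl$id == "ION-A"] <- NA_integer_
  expect_error(weight_ratio_to_np(tbl, catl), "amine_count")
})

test_that("dual-ionizable N/P conversion splits mass by molar proportion", {
  catl <- tiny_catalogue()
  catl$molar_mass[catl$id %in% c("ION-A", "ION-B")] <- c(500, 1000)
  catl$amine_count[catl$id %in% c("ION-A", "ION-B")] <- c(1L, 4L)
  tbl <- formulation_table(
    list(c("ION-A", "ION-B", "HEL-A", "STE-A", "PEG-A")),
    list(c(30, 20, 16, 31.5, 2.5)), weight_ratio = 10)
  out <- weight_ratio_to_np(tbl, catl, per_nt_mass = 330)
  # moles split 30:20 -> amines = .6*1 + .4*4 per (.6*500 + .4*1000) g
  expect_equal(out$np_ratio, 10 * 330 * (0.6 * 1 + 0.4 * 4) /
                 (0.6 * 500 + 0.4 * 1000), tolerance = 1e-12)
})

test_that("L1 molar distance is a metric on slot vectors", {
  catl <- tiny_catalogue()
  tbl <- formulation_table(
    list(c("ION-A", "HEL-A", "STE-A", "PEG-A"),
         c("ION-A", "HEL-A", "STE-A", "PEG-A"),
         c("ION-B", "HEL-A", "STE-A", "PEG-A")),
    list(c(35, 16, 46.5, 2.5), c(40, 16, 41.5, 2.5), c(35, 16, 46.5, 2.5)),
    np_ratio = 6)
  M <- molar_slot_matrix(tbl, catl)
  expect_equal(l1_molar_distance(M[1, ], M[1, ]), 0)
  expect_equal(l1_molar_distance(M[1, ], M[2, ]), 10)
  # a different lipid at the same percentage costs twice the share
  expect_equal(l1_molar_distance(M[1, ], M[3, ]), 70)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(ncol(M)); b <- runif(ncol(M)); cc <- runif(ncol(M))
    expect_equal(l1_molar_distance(a, b), l1_molar_distance(b, a))
    expect_gte(l1_molar_distance(a, cc) + l1_molar_distance(cc, b),
               l1_molar_distance(a, b) - 1e-12)
  }
})

test_that("degradation label is the signed pre/post difference", {
  expect_equal(degradation_label(0.8, 0.8), 0)
  expect_equal(degradation_label(0.9, 0.2), 0.7)
  expect_equal(degradation_label(0.2, 0.9), -0.7)
})

test_that("formulation tables round-trip through CSV", {
  tbl <- formulation_table(
    list(c("ION-A", "HEL-A", "STE-A", "PEG-A"), c("ION-B", "HEL-B")),
    list(c(35.123456, 16, 46.376544, 2.5), c(60.5, 39.5)),
    np_ratio = c(6, NA), weight_ratio = c(NA, 10.25),
    aq_org_ratio = c("3:1", "1:1"),
    labels = list(t1 = c(0.25, 0.875)))
  f <- tempfile(fileext = ".csv")
  write_formulations(tbl, f)
  back <- read_formulations(f)
  expect_identical(back$component_ids, tbl$component_ids)
  expect_identical(back$molar_percents, tbl$molar_percents)
  expect_equal(back$np_ratio, tbl$np_ratio)
  expect_equal(back$weight_ratio, tbl$weight_ratio)
  expect_equal(back[["label:t1"]], tbl[["label:t1"]])
})
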