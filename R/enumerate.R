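# Design grids and library enumeration: reference four-part training-set
# structure and streaming virtual libraries for in silico screening.

#' Declarative design grid
#'
#' A design grid describes a formulation space as the product of lipid
#' choices (one molecule per canonical class), named molar compositions,
#' N/P or weight ratios, and aqueous/organic phase ratios, optionally
#' augmented with dual-ionizable variants.
#'
#' @param ionizable,helper,sterol,peg Character vectors of molecule ids per
#'   class (all non-empty).
#' @param molar_ratios Named list of compositions, each a numeric vector
#'   `c(ionizable=, helper=, sterol=, peg=)` summing to 100.
#' @param np_ratios Numeric N/P ratios (optional if `weight_ratios` given).
#' @param weight_ratios Ionizable/RNA weight ratios (optional).
#' @param aq_org_ratios Character vector of phase ratios.
#' @param dual_ionizable List `list(enabled=, split=)`; `split` is the
#'   major:minor molar split of the ionizable allocation (default 60:40).
#' @return A `design_grid` object.
#' @export
design_grid <- function(ionizable, helper, sterol, peg,
                        molar_ratios = list(BASE = base_molar_ratio()),
                        np_ratios = 6, weight_ratios = NULL,
                        aq_org_ratios = "3:1",
                        dual_ionizable = list(enabled = FALSE,
                                              split = c(60, 40))) {
  for (nm in c("ionizable", "helper", "sterol", "peg"))
    if (!length(get(nm))) stop_fc("empty class list: %s", nm)
  if (is.null(names(molar_ratios)))
    names(molar_ratios) <- sprintf("R%02d", seq_along(molar_ratios))
  for (nm in names(molar_ratios)) {
    r <- molar_ratios[[nm]]
    if (length(r) != 4 || abs(sum(r) - 100) > 1e-6)
      stop_fc("molar ratio %s must have 4 entries summing to 100", nm)
    if (is.null(names(r)))
      names(molar_ratios[[nm]]) <- c("ionizable", "helper", "sterol", "peg")
  }
  if (is.null(np_ratios) && is.null(weight_ratios))
    stop_fc("one of np_ratios / weight_ratios is required")
  g <- list(ionizable = ionizable, helper = helper, sterol = sterol,
            peg = peg, molar_ratios = molar_ratios, np_ratios = np_ratios,
            weight_ratios = weight_ratios, aq_org_ratios = aq_org_ratios,
            dual_ionizable = dual_ionizable)
  class(g) <- "design_grid"
  g
}

#' @export
print.design_grid <- function(x, ...) {
  cat("Design grid:",
      sprintf("%d x %d x %d x %d lipids, %d molar ratios, %d ratio values, %d phases",
              length(x$ionizable), length(x$sterol), length(x$helper),
              length(x$peg), length(x$molar_ratios),
              length(x$np_ratios %||% x$weight_ratios),
              length(x$aq_org_ratios)),
      if (isTRUE(x$dual_ionizable$enabled)) "(+ dual-ionizable)" else "", "\n")
  invisible(x)
}

#' Reference base composition
#'
#' The BASE lipid molar composition from which single-class variations are
#' generated: 35% ionizable, 16% helper, 46.5% sterol, 2.5% PEG.
#'
#' @return Named numeric vector summing to 100.
#' @export
base_molar_ratio <- function() {
  c(ionizable = 35, helper = 16, sterol = 46.5, peg = 2.5)
}

#' Rescale a composition after fixing one class
#'
#' Sets `class` to `value` percent and rescales the remaining classes
#' proportionally from `base` so the composition still sums to 100.
#'
#' @param base Named composition vector summing to 100.
#' @param class One of the names of `base`.
#' @param value New percentage for `class`.
#' @return Rescaled composition.
#' @export
rescale_composition <- function(base, class, value) {
  if (!class %in% names(base)) stop_fc("unknown class %s", class)
  if (value < 0 || value > 100) stop_fc("value out of [0, 100]")
  rest <- setdiff(names(base), class)
  out <- base
  out[class] <- value
  total_rest <- sum(base[rest])
  if (total_rest <= 0 && value < 100)
    stop_fc("cannot rescale: remaining classes have zero share")
  out[rest] <- base[rest] * (100 - value) / total_rest
  if (any(out < 0)) stop_fc("rescaling leaves a negative share")
  out
}

#' The 13 reference molar compositions
#'
#' Thirteen named lipid compositions used by the bulk of the reference
#' training design: the BASE ratio, four ionizable-lipid variations
#' (I1-I4, other classes rescaled proportionally), three sterol variations
#' compensated by the helper lipid (C1-C3), three PEG variations (P1-P3)
#' and two multi-class variations (M1-M2).
#'
#' @return Named list of 13 compositions, each summing to 100.
#' @export
reference_molar_ratios <- function() {
  b <- base_molar_ratio()
  r <- list(BASE = b)
  il <- c(I1 = 20, I2 = 27.5, I3 = 42.5, I4 = 50)
  for (nm in names(il)) r[[nm]] <- rescale_composition(b, "ionizable", il[nm])
  for (nm in names(c(C1 = 30, C2 = 40, C3 = 55))) {
    v <- c(C1 = 30, C2 = 40, C3 = 55)[nm]
    x <- b
    x["sterol"] <- v
    x["helper"] <- 100 - x["ionizable"] - x["sterol"] - x["peg"]
    if (x["helper"] < 0) stop_fc("infeasible sterol variation")
    r[[nm]] <- x
  }
  pg <- c(P1 = 1, P2 = 4, P3 = 5.5)
  for (nm in names(pg)) r[[nm]] <- rescale_composition(b, "peg", pg[nm])
  r$M1 <- c(ionizable = 25, helper = 30, sterol = 42.5, peg = 2.5)
  r$M2 <- c(ionizable = 45, helper = 25, sterol = 27.5, peg = 2.5)
  lapply(r, function(x) setNames(as.numeric(x), names(b)))
}

grid_ratio_values <- function(grid) {
  if (!is.null(grid$np_ratios)) list(kind = "np", values = grid$np_ratios)
  else list(kind = "weight", values = grid$weight_ratios)
}

make_formulation_rows <- function(ids_list, molar_list, ratio_kind,
                                  ratio_value, aq, id_prefix, start_idx) {
  n <- length(ids_list)
  formulation_table(
    component_ids = ids_list, molar_percents = molar_list,
    np_ratio = if (ratio_kind == "np") ratio_value else NA_real_,
    weight_ratio = if (ratio_kind == "weight") ratio_value else NA_real_,
    aq_org_ratio = aq,
    id = sprintf("%s%06d", id_prefix, seq.int(start_idx, length.out = n)))
}

#' Enumerate single-ionizable-lipid formulations
#'
#' Every (ionizable x sterol x helper x PEG) lipid combination crossed with
#' every molar composition of the grid, at the grid's first ratio value and
#' phase ratio. Deterministic odometer order over the declared axes (last
#' axis fastest). Count = |I| * |S| * |H| * |P| * |ratios|.
#'
#' @param grid A [design_grid()].
#' @return Formulation table.
#' @export
enumerate_single_il <- function(grid) {
  rv <- grid_ratio_values(grid)
  # expand.grid varies the first factor fastest, so list axes in reverse of
  # the declared ionizable > sterol > helper > peg > ratio odometer order
  combos <- expand.grid(ratio = names(grid$molar_ratios),
                        peg = grid$peg, helper = grid$helper,
                        sterol = grid$sterol, ionizable = grid$ionizable,
                        stringsAsFactors = FALSE)
  ids <- Map(function(i, h, s, p) c(i, h, s, p),
             combos$ionizable, combos$helper, combos$sterol, combos$peg)
  molar <- lapply(combos$ratio, function(r)
    as.numeric(grid$molar_ratios[[r]]))
  make_formulation_rows(unname(ids), molar, rv$kind, rv$values[1],
                        grid$aq_org_ratios[1], "S", 1L)
}

#' Enumerate dual-ionizable-lipid formulations
#'
#' Every ordered (major, minor) pair of ionizable lipids -- self-pairs
#' included, collapsing to a single ionizable entry -- with the ionizable
#' molar allocation split `split[1]:split[2]`, over every molar
#' composition. Uses the grid's first helper/sterol/PEG choice. Count =
#' |I|^2 * |ratios|.
#'
#' @param grid A [design_grid()] with `dual_ionizable$enabled`.
#' @return Formulation table.
#' @export
enumerate_dual_il <- function(grid) {
  if (!isTRUE(grid$dual_ionizable$enabled))
    stop_fc("dual_ionizable not enabled in grid")
  split <- grid$dual_ionizable$split / sum(grid$dual_ionizable$split)
  rv <- grid_ratio_values(grid)
  ids <- list(); molar <- list(); n <- 0L
  for (major in grid$ionizable) for (minor in grid$ionizable)
    for (r in names(grid$molar_ratios)) {
      comp <- grid$molar_ratios[[r]]
      rest <- c(grid$helper[1], grid$sterol[1], grid$peg[1])
      restm <- as.numeric(comp[c("helper", "sterol", "peg")])
      n <- n + 1L
      if (major == minor) {
        ids[[n]] <- c(major, rest)
        molar[[n]] <- c(comp[["ionizable"]], restm)
      } else {
        ids[[n]] <- c(major, minor, rest)
        molar[[n]] <- c(comp[["ionizable"]] * split, restm)
      }
    }
  make_formulation_rows(ids, molar, rv$kind, rv$values[1],
                        grid$aq_org_ratios[1], "D", 1L)
}

#' Evenly spaced molar-percentage sweeps for one class
#'
#' Generates `n_points` compositions with the swept class at evenly spaced
#' values in `[lo, hi]` and the remaining classes rescaled proportionally
#' from `base`.
#'
#' @param base Named base composition summing to 100.
#' @param class Class to sweep.
#' @param lo,hi Sweep range in percent (`lo < hi`).
#' @param n_points Number of sweep points (>= 2).
#' @return List of compositions.
#' @export
enumerate_sweeps <- function(base, class, lo, hi, n_points) {
  if (!(lo < hi)) stop_fc("lo must be < hi")
  if (n_points < 2) stop_fc("n_points must be >= 2")
  vals <- seq(lo, hi, length.out = n_points)
  out <- lapply(vals, function(v) rescale_composition(base, class, v))
  names(out) <- sprintf("%s_%s", class, format(vals, trim = TRUE))
  out
}

#' All distinct molar compositions of the reference design
#'
#' The 13 named ratios plus 24-point sweeps (10% to 80%) of the ionizable,
#' sterol and helper classes from the BASE ratio, deduplicated.
#'
#' @param ratios Named list of base compositions
#'   (default [reference_molar_ratios()]).
#' @param sweep_classes Classes swept.
#' @param lo,hi,n_points Sweep parameters.
#' @return List of distinct compositions.
#' @export
reference_molar_compositions <- function(ratios = reference_molar_ratios(),
                                     sweep_classes = c("ionizable", "sterol",
                                                       "helper"),
                                     lo = 10, hi = 80, n_points = 24) {
  out <- ratios
  for (cl in sweep_classes)
    out <- c(out, enumerate_sweeps(ratios[[1]], cl, lo, hi, n_points))
  key <- vapply(out, function(x) paste(round(x, 9), collapse = "|"), "")
  out[!duplicated(key)]
}

#' Reference-style design grid
#'
#' A grid shaped like the reference training design: 7 ionizable x 3 sterol
#' x 2 helper x 2 PEG lipids, 13 molar ratios, weight ratios 10/15/20,
#' phase ratios 3:1 and 1:1, dual-ionizable 60:40.
#'
#' @param catalogue A catalogue holding at least 7/2/3/2 molecules of the
#'   four classes (e.g. from [sample_catalogue()]).
#' @return A `design_grid`.
#' @export
reference_grid <- function(catalogue) {
  by_cls <- split(catalogue$id, catalogue$component_class)
  need <- c(ionizable = 7, helper = 2, sterol = 3, peg = 2)
  for (nm in names(need))
    if (length(by_cls[[nm]] %||% character()) < need[nm])
      stop_fc("catalogue needs >= %d %s molecules", need[nm], nm)
  design_grid(ionizable = by_cls$ionizable[1:7], helper = by_cls$helper[1:2],
              sterol = by_cls$sterol[1:3], peg = by_cls$peg[1:2],
              molar_ratios = reference_molar_ratios(),
              np_ratios = NULL, weight_ratios = c(10, 15, 20),
              aq_org_ratios = c("3:1", "1:1"),
              dual_ionizable = list(enabled = TRUE, split = c(60, 40)))
}

#' Dataset part manifest and totals
#'
#' Bookkeeping for a four-part screened dataset: possible part-1 grid size,
#' tested counts, the part-1/part-2 overlap, and derived unique/total
#' counts. Defaults describe the reference study design.
#'
#' @param part1_tested Number of part-1 formulations actually screened.
#' @param part1_overlap Part-1 formulations overlapping part 2.
#' @param part2,part3,part4 Screened counts for the other parts.
#' @return List with the inputs plus `part1_unique` and `total`.
#' @export
reference_manifest <- function(part1_tested = 1066, part1_overlap = 91,
                           part2 = 637, part3 = 924, part4 = 492) {
  part1_unique <- part1_tested - part1_overlap
  list(part1_tested = part1_tested, part1_overlap = part1_overlap,
       part2 = part2, part3 = part3, part4 = part4,
       part1_unique = part1_unique,
       total = part1_unique + part2 + part3 + part4)
}

# --- streaming virtual library ----------------------------------------------

#' Streaming virtual formulation library
#'
#' The Cartesian product of the grid's lipid choices (single-ionizable
#' quadruples, plus ordered dual-ionizable pairs when enabled), molar
#' compositions, N/P (or weight) ratio values and phase ratios. The library
#' is never materialized: its exact `count` is the product of axis
#' cardinalities, and formulations are decoded on demand from their index.
#' Axis order (slowest to fastest): lipid choice, molar ratio, ratio value,
#' phase ratio; dual-ionizable choices follow all single choices.
#'
#' @param grid A [design_grid()].
#' @return A `virtual_library` object with fields `count` and functions
#'   `slice(from, to)` (1-based inclusive index range -> formulation table)
#'   and `chunks(chunk_size, fun)` (apply `fun(tbl, from)` over the whole
#'   stream).
#' @export
virtual_library <- function(grid) {
  rv <- grid_ratio_values(grid)
  nI <- length(grid$ionizable); nH <- length(grid$helper)
  nS <- length(grid$sterol); nP <- length(grid$peg)
  nR <- length(grid$molar_ratios); nV <- length(rv$values)
  nA <- length(grid$aq_org_ratios)
  n_single <- nI * nH * nS * nP
  n_dual <- if (isTRUE(grid$dual_ionizable$enabled)) nI * nI * nH * nS * nP else 0
  n_choice <- n_single + n_dual
  count <- n_choice * nR * nV * nA
  if (count > 2^53) stop_fc("library too large for exact double counting")
  split <- grid$dual_ionizable$split
  split <- split / sum(split)
  rat_names <- names(grid$molar_ratios)

  decode <- function(idx) { # 1-based
    i0 <- idx - 1
    a <- i0 %% nA; i0 <- i0 %/% nA
    v <- i0 %% nV; i0 <- i0 %/% nV
    r <- i0 %% nR; ch <- i0 %/% nR
    comp <- grid$molar_ratios[[rat_names[r + 1]]]
    if (ch < n_single) {
      p <- ch %% nP; ch <- ch %/% nP
      h <- ch %% nH; ch <- ch %/% nH
      s <- ch %% nS; i <- ch %/% nS
      ids <- c(grid$ionizable[i + 1], grid$helper[h + 1],
               grid$sterol[s + 1], grid$peg[p + 1])
      molar <- as.numeric(comp[c("ionizable", "helper", "sterol", "peg")])
    } else {
      ch <- ch - n_single
      p <- ch %% nP; ch <- ch %/% nP
      h <- ch %% nH; ch <- ch %/% nH
      s <- ch %% nS; ch <- ch %/% nS
      i2 <- ch %% nI; i1 <- ch %/% nI
      maj <- grid$ionizable[i1 + 1]; min_ <- grid$ionizable[i2 + 1]
      if (maj == min_) {
        ids <- c(maj, grid$helper[h + 1], grid$sterol[s + 1], grid$peg[p + 1])
        molar <- c(comp[["ionizable"]],
                   as.numeric(comp[c("helper", "sterol", "peg")]))
      } else {
        ids <- c(maj, min_, grid$helper[h + 1], grid$sterol[s + 1],
                 grid$peg[p + 1])
        molar <- c(comp[["ionizable"]] * split,
                   as.numeric(comp[c("helper", "sterol", "peg")]))
      }
    }
    list(ids = ids, molar = molar, ratio_value = rv$values[v + 1],
         aq = grid$aq_org_ratios[a + 1])
  }

  build <- function(indices) {
    items <- lapply(indices, decode)
    tbl <- make_formulation_rows(lapply(items, `[[`, "ids"),
                                 lapply(items, `[[`, "molar"),
                                 rv$kind,
                                 vapply(items, `[[`, 0, "ratio_value"),
                                 vapply(items, `[[`, "", "aq"),
                                 "V", 1L)
    tbl$formulation_id <- sprintf("V%09d", indices)
    tbl
  }
  slice <- function(from, to) {
    stopifnot(from >= 1, to <= count, from <= to)
    build(seq.int(from, to))
  }
  pick <- function(indices) {
    stopifnot(all(indices >= 1), all(indices <= count))
    build(indices)
  }
  chunks <- function(chunk_size, fun) {
    from <- 1
    while (from <= count) {
      to <- min(from + chunk_size - 1, count)
      fun(slice(from, to), from)
      from <- to + 1
    }
    invisible(NULL)
  }
  structure(list(count = count, slice = slice, pick = pick, chunks = chunks,
                 grid = grid),
            class = "virtual_library")
}

#' @export
print.virtual_library <- function(x, ...) {
  cat(sprintf("Virtual formulation library: %s candidates\n",
              format(x$count, big.mark = ",")))
  invisible(x)
}

#' Exclude candidates near known hits
#'
#' Drops candidates whose lipid set matches a hit and whose composition is
#' within `radius` L1 molar-percentage distance (inclusive) of that hit.
#' Candidates with a different lipid set are never considered near.
#'
#' @param candidates,hits Formulation tables.
#' @param radius L1 radius in percentage points.
#' @param catalogue A `comet_catalogue` (defines the slot vector).
#' @return The filtered candidate table.
#' @export
exclude_near_hits <- function(candidates, hits, radius, catalogue) {
  if (radius < 0) stop_fc("radius must be >= 0")
  if (!nrow(hits)) return(candidates)
  Mc <- molar_slot_matrix(candidates, catalogue)
  Mh <- molar_slot_matrix(hits, catalogue)
  key_c <- vapply(parse_components(candidates)$ids,
                  function(x) paste(sort(x), collapse = "|"), "")
  key_h <- vapply(parse_components(hits)$ids,
                  function(x) paste(sort(x), collapse = "|"), "")
  drop <- rep(FALSE, nrow(candidates))
  for (j in seq_len(nrow(hits))) {
    same <- which(key_c == key_h[j] & !drop)
    if (!length(same)) next
    d <- l1_molar_distance(Mc[same, , drop = FALSE], Mh[j, ])
    drop[same[d <= radius]] <- TRUE
  }
  candidates[!drop, , drop = FALSE]
}
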