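# Synthetic formulation datasets with a known ground-truth oracle, so the
# whole pipeline -- labelling, training, screening, attribution -- can be
# validated end to end without any external data.
#
# The bundled molecule pool holds representative structures of widely used
# ionizable lipids, helper phospholipids, sterols and PEG lipids. PEG-lipid
# structures are truncated to a short PEG segment and some multi-amine
# lipidoid structures are simplified; the pool is a synthetic stand-in for
# a measured catalogue, not reference data.

#' Sample a molecule catalogue from the bundled pool
#'
#' Takes the first `n` molecules per class from the bundled pool
#' (deterministically), padding with chain-elongated structural variants of
#' the class's first molecule when more are requested than the pool holds.
#'
#' @param n_ionizable,n_helper,n_sterol,n_peg Molecules per class. The
#'   defaults mirror the reference screening design (7/2/3/2).
#' @param max_variants Cap on generated variants per class.
#' @return A `comet_catalogue`.
#' @export
sample_catalogue <- function(n_ionizable = 7, n_helper = 2, n_sterol = 3,
                             n_peg = 2, max_variants = 16) {
  pool <- read_catalogue(system.file("extdata", "lipid_catalogue.csv",
                                     package = "formucomet"))
  want <- c(ionizable = n_ionizable, helper = n_helper, sterol = n_sterol,
            peg = n_peg)
  if (any(want < 1)) stop_fc("need at least one molecule per class")
  out <- list()
  for (cl in names(want)) {
    rows <- pool[pool$component_class == cl, , drop = FALSE]
    n <- want[[cl]]
    if (n > nrow(rows) + max_variants)
      stop_fc("requested %d %s molecules; pool holds %d (+%d variants)",
              n, cl, nrow(rows), max_variants)
    extra <- n - nrow(rows)
    if (extra > 0) {
      # chain-elongated homologues of the first pool entry
      var_rows <- rows[rep(1, extra), , drop = FALSE]
      var_rows$id <- sprintf("%s-V%d", rows$id[1], seq_len(extra))
      var_rows$smiles <- vapply(seq_len(extra), function(k)
        paste0(strrep("C", k), rows$smiles[1]), "")
      var_rows$molar_mass <- rows$molar_mass[1] + 14.03 * seq_len(extra)
      rows <- rbind(rows, var_rows)
    }
    out[[cl]] <- rows[seq_len(n), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("comet_catalogue", "data.frame")
  res
}

#' Ground-truth oracle configuration
#'
#' Defines a latent efficacy surface over formulations, emulating the
#' effect structure seen in real screens: additive per-molecule potencies
#' (largest spread for ionizable lipids), a quadratic penalty for moving
#' each class away from its optimal molar percentage, a pairwise synergy
#' term for dual-ionizable formulations, a smooth N/P response bump, and a
#' phase-ratio x helper-content interaction. Effects are drawn reproducibly
#' per task from `seed`.
#'
#' @param catalogue A `comet_catalogue`.
#' @param tasks Task ids (independent effect draws per task).
#' @param seed Seed for the effect draws.
#' @param potency_sd Named per-class sd of molecule potencies.
#' @param molar_opt,molar_width Named per-class optima and quadratic
#'   penalty widths (percent).
#' @param synergy_sd Sd of dual-ionizable synergy effects.
#' @param np_opt,np_width,np_amp N/P response bump parameters.
#' @param phase_sd Sd of the phase-interaction coefficients.
#' @param phase_levels Phase vocabulary.
#' @return An `oracle_config`.
#' @export
oracle_config <- function(catalogue, tasks = "dc24", seed = 1L,
                          potency_sd = c(ionizable = 1.0, helper = 0.5,
                                         sterol = 0.4, peg = 0.3,
                                         pbae_repeat = 0.8,
                                         pbae_branch = 0.2),
                          molar_opt = c(ionizable = 40, helper = 20,
                                        sterol = 40, peg = 2.5),
                          molar_width = c(ionizable = 25, helper = 20,
                                          sterol = 25, peg = 3),
                          synergy_sd = 0.4, np_opt = 10, np_width = 8,
                          np_amp = 0.5, phase_sd = 0.5,
                          phase_levels = c("3:1", "1:1")) {
  set.seed(seed)
  il <- catalogue$id[catalogue$component_class == "ionizable"]
  per_task <- lapply(setNames(tasks, tasks), function(t) {
    pot <- rnorm(nrow(catalogue)) *
      potency_sd[catalogue$component_class]
    syn <- matrix(rnorm(length(il)^2, sd = synergy_sd), length(il),
                  dimnames = list(il, il))
    ph <- setNames(rnorm(length(phase_levels), sd = phase_sd), phase_levels)
    list(potency = setNames(pot, catalogue$id), synergy = syn, phase = ph)
  })
  structure(list(tasks = tasks, per_task = per_task,
                 molar_opt = molar_opt, molar_width = molar_width,
                 np_opt = np_opt, np_width = np_width, np_amp = np_amp,
                 phase_levels = phase_levels, seed = seed),
            class = "oracle_config")
}

#' Latent oracle efficacy of formulations
#'
#' Deterministic ground-truth efficacy under an [oracle_config()]:
#' the molar-percentage-weighted mean molecule potency, minus quadratic
#' molar penalties per class, plus dual-ionizable synergy, the N/P bump and
#' the phase x helper interaction.
#'
#' @param tbl Formulation table.
#' @param oc An `oracle_config`.
#' @param catalogue A `comet_catalogue`.
#' @param task Task id.
#' @return Numeric latent efficacy per formulation (arbitrary scale).
#' @export
oracle_efficacy <- function(tbl, oc, catalogue, task = oc$tasks[1]) {
  pt <- oc$per_task[[task]]
  if (is.null(pt)) stop_fc("unknown oracle task: %s", task)
  tbl <- weight_ratio_to_np(tbl, catalogue)
  pc <- parse_components(tbl)
  cls <- setNames(catalogue$component_class, catalogue$id)
  vapply(seq_len(nrow(tbl)), function(i) {
    ids <- pc$ids[[i]]; m <- pc$molar[[i]]
    v <- sum(pt$potency[ids] * m) / 100
    for (cl in names(oc$molar_opt)) {
      mc <- sum(m[cls[ids] == cl])
      v <- v - ((mc - oc$molar_opt[[cl]]) / oc$molar_width[[cl]])^2
    }
    il <- which(cls[ids] == "ionizable")
    if (length(il) >= 2) {
      ord <- il[order(-m[il])]
      v <- v + pt$synergy[ids[ord[1]], ids[ord[2]]]
    }
    v <- v + oc$np_amp * exp(-(tbl$np_ratio[i] - oc$np_opt)^2 /
                               (2 * oc$np_width^2))
    hel <- sum(m[cls[ids] == "helper"])
    v + pt$phase[[tbl$aq_org_ratio[i]]] * hel / 100
  }, 0)
}

#' Generate a labelled synthetic dataset
#'
#' Samples `n` distinct formulations from a design grid, computes their
#' latent oracle efficacies, and emulates a plate-based assay: formulations
#' are assigned to plates with a per-plate standard, each of
#' `n_replicates` raw readouts is the standard times 10^(standardized
#' oracle) times multiplicative lognormal handling noise (log-domain
#' additive, emulating bioluminescence assays), and [normalize_labels()]
#' turns the readouts into \[0, 1\] labels. The hidden oracle values are
#' returned separately from the labelled table so they cannot leak into
#' model inputs.
#'
#' @param grid A [design_grid()].
#' @param oc An [oracle_config()].
#' @param n Number of formulations (<= grid size).
#' @param plate_size Formulations per plate.
#' @param n_replicates Replicates per formulation.
#' @param noise_sd Standard deviation of the lognormal handling noise on
#'   the natural-log scale.
#' @param seed Seed (sampling, plate standards, noise).
#' @param catalogue Catalogue (for weight-ratio conversion in the oracle).
#' @return List: `formulations` (labelled table), `oracle` (hidden truth
#'   per task), `plates` (assignment).
#' @export
generate_dataset <- function(grid, oc, n, plate_size = 94L,
                             n_replicates = 4L, noise_sd = 0.1, seed = 0L,
                             catalogue) {
  lib <- virtual_library(grid)
  if (n > lib$count) stop_fc("n exceeds grid size (%d)", lib$count)
  set.seed(seed)
  idx <- sort(sample.int(lib$count, n))
  tbl <- lib$pick(idx)
  tbl$formulation_id <- sprintf("SYN%05d", seq_len(n))
  tbl <- weight_ratio_to_np(tbl, catalogue)
  plate <- rep(seq_len(ceiling(n / plate_size)), each = plate_size)[seq_len(n)]
  plate_ids <- sprintf("P%03d", plate)
  standards <- setNames(exp(rnorm(max(plate), log(1e4), 0.2)),
                        sprintf("P%03d", seq_len(max(plate))))
  oracle <- data.frame(formulation_id = tbl$formulation_id)
  for (task in oc$tasks) {
    z <- oracle_efficacy(tbl, oc, catalogue, task)
    zc <- (z - mean(z)) / pop_sd(z)
    raw <- data.frame(
      formulation_id = rep(tbl$formulation_id, each = n_replicates),
      plate_id = rep(plate_ids, each = n_replicates),
      raw_value = rep(standards[plate_ids] * 10^zc, each = n_replicates) *
        exp(rnorm(n * n_replicates, sd = noise_sd)))
    lab <- normalize_labels(raw, standards)
    tbl[[paste0("label:", task)]] <- as.numeric(lab[tbl$formulation_id])
    oracle[[task]] <- z
  }
  list(formulations = tbl,
       oracle = oracle,
       plates = data.frame(formulation_id = tbl$formulation_id,
                           plate_id = plate_ids))
}
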