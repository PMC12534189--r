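# Branched poly(beta-amino ester) support: polymers enter the model as two
# extra component tokens -- the diacrylate-amine repeat unit (carrying the
# polymer's molar percentage) and the branching agent (identity only, 0%).

#' Catalogue rows for a branched polymer
#'
#' Represents a branched poly(beta-amino ester) by its diacrylate-amine
#' repeat unit and its branching agent, each with its own component class
#' (`pbae_repeat`, `pbae_branch`). Returns the two catalogue rows to append
#' to a lipid catalogue.
#'
#' @param id Polymer identifier (rows become `<id>_repeat`, `<id>_branch`).
#' @param repeat_smiles SMILES of the diacrylate-amine repeat unit.
#' @param branch_smiles SMILES of the branching agent.
#' @param repeat_mw Repeat-unit molar mass, g/mol.
#' @return A `comet_catalogue` with two rows.
#' @export
pbae_record <- function(id, repeat_smiles, branch_smiles, repeat_mw) {
  if (repeat_mw <= 0) stop_fc("repeat_mw must be > 0")
  molecule_catalogue(
    id = paste0(id, c("_repeat", "_branch")),
    smiles = c(repeat_smiles, branch_smiles),
    component_class = c("pbae_repeat", "pbae_branch"),
    molar_mass = c(repeat_mw, NA_real_))
}

#' Read a polymer catalogue CSV
#'
#' Columns: `pbae_id`, `repeat_unit_smiles`, `branch_smiles`,
#' `repeat_unit_mw`.
#'
#' @param path CSV path.
#' @return A `comet_catalogue` with two rows per polymer.
#' @export
read_pbae_catalogue <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  rows <- Map(pbae_record, df$pbae_id, df$repeat_unit_smiles,
              df$branch_smiles, df$repeat_unit_mw)
  out <- do.call(rbind, rows)
  class(out) <- c("comet_catalogue", "data.frame")
  out
}

#' Polymer molar percentage from mass
#'
#' The polymer's molar contribution is estimated from its weight and the
#' repeat-unit molecular weight: `moles = mass / repeat_mw`. Its molar
#' percentage is taken over polymer plus lipid moles, so that lipid and
#' polymer molar percentages sum to 100.
#'
#' @param polymer_mass Polymer mass in mg.
#' @param repeat_mw Repeat-unit molar mass, g/mol.
#' @param lipid_moles Total lipid amount in micromoles.
#' @return Molar percentage of the polymer in \[0, 100\].
#' @export
pbae_molar_percent <- function(polymer_mass, repeat_mw, lipid_moles) {
  if (repeat_mw <= 0) stop_fc("repeat_mw must be > 0")
  if (polymer_mass < 0 || lipid_moles < 0) stop_fc("negative mass or moles")
  pbae_umol <- 1000 * polymer_mass / repeat_mw # mg / (g/mol) = mmol/1000
  100 * pbae_umol / (pbae_umol + lipid_moles)
}

#' Add a polymer to a lipid formulation
#'
#' Rescales the lipid molar percentages to `100 - pbae_percent` and appends
#' the repeat-unit token at `pbae_percent` plus the branching-agent token
#' at 0% (the branching agent contributes identity information only).
#'
#' @param tbl Single- or multi-row lipid formulation table.
#' @param pbae_id Polymer identifier (as given to [pbae_record()]).
#' @param pbae_percent Polymer molar percentage (see
#'   [pbae_molar_percent()]).
#' @return The polymer-containing formulation table.
#' @export
add_pbae <- function(tbl, pbae_id, pbae_percent) {
  if (pbae_percent < 0 || pbae_percent >= 100)
    stop_fc("pbae_percent must be in [0, 100)")
  pc <- parse_components(tbl)
  ids <- lapply(pc$ids, function(x) c(x, paste0(pbae_id, "_repeat"),
                                      paste0(pbae_id, "_branch")))
  molar <- lapply(pc$molar, function(m)
    c(m * (100 - pbae_percent) / sum(m), pbae_percent, 0))
  out <- tbl
  out$component_ids <- vapply(ids, paste, "", collapse = ";")
  out$molar_percents <- vapply(molar, function(m)
    paste(format(m, trim = TRUE, scientific = FALSE, digits = 15), collapse = ";"), "")
  out
}
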