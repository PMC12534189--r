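# Domain types and shared operations: molecule catalogues, formulation
# tables, label normalization, weight-ratio -> N/P conversion, composition
# distance.

#' Build a molecule catalogue
#'
#' A catalogue is a data frame with one row per molecule: its identifier,
#' SMILES structure, component class (see [component_classes()]), and the
#' optional amine count and molar mass needed for weight-ratio to N/P
#' conversion.
#'
#' @param id Character vector of unique molecule identifiers.
#' @param smiles SMILES strings, one per molecule.
#' @param component_class One of [component_classes()] per molecule.
#' @param amine_count Integer count of ionizable amines per molecule
#'   (optional, `NA` if unknown).
#' @param molar_mass Molar mass in g/mol (optional, `NA` if unknown).
#' @param check_smiles Verify that every SMILES parses (via the molecular
#'   encoder). Slower, but catches data errors early.
#' @return A `comet_catalogue` data frame.
#' @export
molecule_catalogue <- function(id, smiles, component_class,
                               amine_count = NA_integer_,
                               molar_mass = NA_real_,
                               check_smiles = FALSE) {
  if (anyDuplicated(id)) stop_fc("duplicate molecule id(s): %s",
                                 paste(unique(id[duplicated(id)]), collapse = ", "))
  bad <- setdiff(unique(component_class), COMPONENT_CLASSES)
  if (length(bad)) stop_fc("unknown component class(es): %s",
                           paste(bad, collapse = ", "))
  if (any(!is.na(amine_count) & amine_count < 0))
    stop_fc("amine_count must be >= 0")
  if (any(!is.na(molar_mass) & molar_mass <= 0))
    stop_fc("molar_mass must be > 0")
  cat_df <- data.frame(id = as.character(id), smiles = as.character(smiles),
                       component_class = as.character(component_class),
                       amine_count = as.integer(rep_len(amine_count, length(id))),
                       molar_mass = as.numeric(rep_len(molar_mass, length(id))),
                       stringsAsFactors = FALSE)
  if (check_smiles) for (s in unique(cat_df$smiles)) default_molecular_encoder(s)
  class(cat_df) <- c("comet_catalogue", "data.frame")
  cat_df
}

#' Read / write a molecule catalogue CSV
#'
#' Columns: `id`, `smiles`, `component_class`, optional `amine_count`,
#' `molar_mass`.
#'
#' @param path CSV file path.
#' @param ... Passed to [molecule_catalogue()].
#' @return A `comet_catalogue`.
#' @export
read_catalogue <- function(path, ...) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  molecule_catalogue(df$id, df$smiles, df$component_class,
                     df$amine_count %||% NA_integer_,
                     df$molar_mass %||% NA_real_, ...)
}

#' @rdname read_catalogue
#' @param catalogue A `comet_catalogue`.
#' @export
write_catalogue <- function(catalogue, path) {
  write.csv(as.data.frame(catalogue), path, row.names = FALSE)
  invisible(path)
}

#' Build a formulation table
#'
#' Formulations are stored one per row. Component identities and molar
#' percentages are semicolon-joined strings (the on-disk CSV format), and
#' exactly one of `np_ratio` / `weight_ratio` may be missing per row.
#' Efficacy labels, if present, live in `label:<task>` columns on the
#' \[0, 1\] scale produced by [normalize_labels()].
#'
#' @param component_ids List of character vectors (one per formulation).
#' @param molar_percents List of numeric vectors matching `component_ids`;
#'   each must sum to 100.
#' @param np_ratio Numeric N/P ratio (`NA` if `weight_ratio` is given).
#' @param weight_ratio Ionizable-lipid/RNA weight ratio (`NA` if `np_ratio`
#'   is given).
#' @param aq_org_ratio Aqueous/organic volumetric ratio, categorical (e.g.
#'   `"3:1"`).
#' @param labels Optional named list `task -> numeric vector` of labels.
#' @param id Formulation identifiers; autogenerated when `NULL`.
#' @return A data frame with one row per formulation.
#' @export
formulation_table <- function(component_ids, molar_percents,
                              np_ratio = NA_real_, weight_ratio = NA_real_,
                              aq_org_ratio = "3:1", labels = NULL, id = NULL) {
  n <- length(component_ids)
  stopifnot(length(molar_percents) == n)
  id <- id %||% sprintf("F%05d", seq_len(n))
  tbl <- data.frame(
    formulation_id = as.character(id),
    component_ids = vapply(component_ids, paste, "", collapse = ";"),
    molar_percents = vapply(molar_percents, function(m)
      paste(format(m, trim = TRUE, scientific = FALSE, digits = 15), collapse = ";"), ""),
    np_ratio = as.numeric(rep_len(np_ratio, n)),
    weight_ratio = as.numeric(rep_len(weight_ratio, n)),
    aq_org_ratio = as.character(rep_len(aq_org_ratio, n)),
    stringsAsFactors = FALSE, check.names = FALSE)
  for (task in names(labels)) tbl[[paste0("label:", task)]] <- labels[[task]]
  tbl
}

split_semi <- function(x) strsplit(x, ";", fixed = TRUE)

#' Parse the component columns of a formulation table
#'
#' @param tbl A formulation table.
#' @return A list with `ids` (list of character vectors) and `molar`
#'   (list of numeric vectors).
#' @export
parse_components <- function(tbl) {
  list(ids = split_semi(tbl$component_ids),
       molar = lapply(split_semi(tbl$molar_percents), as.numeric))
}

label_columns <- function(tbl) {
  cols <- grep("^label:", names(tbl), value = TRUE)
  setNames(cols, sub("^label:", "", cols))
}

#' Task labels stored in a formulation table
#'
#' @param tbl A formulation table.
#' @return Named list `task -> numeric vector` (with `NA` where unlabeled).
#' @export
formulation_labels <- function(tbl) {
  cols <- label_columns(tbl)
  lapply(setNames(as.list(cols), names(cols)), function(cl) tbl[[cl]])
}

#' Validate formulations against a catalogue
#'
#' Checks that every component id exists in the catalogue, that molar
#' percentages sum to 100 (within `tol`; sums off by at most `renorm_tol`
#' are renormalized with a warning), that each formulation has at least two
#' components, at most one entry per molecule, and that at least one of
#' N/P ratio or weight ratio is present.
#'
#' @param tbl Formulation table.
#' @param catalogue A `comet_catalogue`.
#' @param tol Tolerance on the molar sum, in percentage points.
#' @param renorm_tol Sums within `renorm_tol` of 100 are rescaled rather
#'   than rejected.
#' @return The validated (possibly renormalized) table.
#' @export
validate_formulations <- function(tbl, catalogue, tol = 1e-6,
                                  renorm_tol = 0.01) {
  pc <- parse_components(tbl)
  unknown <- setdiff(unique(unlist(pc$ids)), catalogue$id)
  if (length(unknown)) stop_fc("unknown molecule id(s): %s",
                               paste(unknown, collapse = ", "))
  n_comp <- lengths(pc$ids)
  if (any(n_comp < 2)) stop_fc("formulation(s) with fewer than 2 components: %s",
                               paste(tbl$formulation_id[n_comp < 2], collapse = ", "))
  dup <- vapply(pc$ids, anyDuplicated, 0L) > 0L
  if (any(dup)) stop_fc("duplicate component within formulation(s): %s",
                        paste(tbl$formulation_id[dup], collapse = ", "))
  sums <- vapply(pc$molar, sum, 0)
  off <- abs(sums - 100)
  if (any(off > renorm_tol))
    stop_fc("molar sum %s for formulation %s",
            format(sums[which.max(off)]),
            tbl$formulation_id[which.max(off)])
  fix <- which(off > tol)
  if (length(fix)) {
    warn_fc("renormalizing %d formulation(s) whose molar sums were off by <= %g",
            length(fix), renorm_tol)
    for (i in fix) {
      m <- pc$molar[[i]] * 100 / sums[i]
      tbl$molar_percents[i] <- paste(format(m, trim = TRUE, scientific = FALSE, digits = 15),
                                     collapse = ";")
    }
  }
  no_ratio <- is.na(tbl$np_ratio) & is.na(tbl$weight_ratio)
  if (any(no_ratio))
    stop_fc("missing both N/P and weight ratio: %s",
            paste(tbl$formulation_id[no_ratio], collapse = ", "))
  tbl
}

#' Read / write formulation tables
#'
#' Plain CSV round-trip of the formulation table format. Numbers written
#' with up to six fractional decimal digits survive the round trip exactly.
#'
#' @param path CSV file path.
#' @return `read_formulations()` returns the table; `write_formulations()`
#'   returns `path` invisibly.
#' @export
read_formulations <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_formulations
#' @param tbl Formulation table.
#' @export
write_formulations <- function(tbl, path) {
  write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Normalize plate-based efficacy readouts to \[0, 1\] labels
#'
#' Raw per-replicate readouts (for example luminescence) are divided by
#' their plate's standard value, averaged across replicates per
#' formulation, log-transformed, and min-max normalized so the weakest
#' formulation maps to 0 and the strongest to 1.
#'
#' @param raw Data frame with columns `formulation_id`, `plate_id`,
#'   `raw_value` (one row per replicate).
#' @param standards Named numeric vector mapping `plate_id` to the plate's
#'   standard readout (> 0).
#' @param log_base Base of the log transform. The choice is irrelevant
#'   after min-max scaling; base 10 is the default for readability.
#' @return Named numeric vector of labels in \[0, 1\], one per formulation.
#' @export
normalize_labels <- function(raw, standards, log_base = 10) {
  req <- c("formulation_id", "plate_id", "raw_value")
  if (!all(req %in% names(raw))) stop_fc("raw must have columns %s",
                                         paste(req, collapse = ", "))
  if (any(raw$raw_value <= 0)) stop_fc("nonpositive raw value")
  miss <- setdiff(unique(raw$plate_id), names(standards))
  if (length(miss)) stop_fc("plate(s) without a standard: %s",
                            paste(miss, collapse = ", "))
  if (any(standards <= 0)) stop_fc("nonpositive plate standard")
  ratio <- raw$raw_value / standards[raw$plate_id]
  m <- tapply(ratio, raw$formulation_id, mean)
  lg <- log(m, base = log_base)
  rng <- range(lg)
  if (diff(rng) == 0) stop_fc("degenerate range: all normalized values equal")
  out <- (lg - rng[1]) / diff(rng)
  setNames(as.numeric(out), names(m))
}

#' Convert ionizable-lipid/RNA weight ratio to N/P ratio
#'
#' N/P is the molar ratio of ionizable amine nitrogens to RNA backbone
#' phosphates. Given the weight ratio of total ionizable lipid to RNA, the
#' ionizable lipids' amine counts and molar masses, and the RNA
#' per-nucleotide molar mass, N/P = weight_ratio * per_nt_mass *
#' (sum_i p_i * amine_i) / (sum_i p_i * mw_i), where p_i are the ionizable
#' components' molar proportions (so dual-ionizable mass is split according
#' to the formulation's stated molar composition).
#'
#' @param tbl Formulation table; rows with `NA` `np_ratio` and a
#'   `weight_ratio` are converted, others pass through.
#' @param catalogue A `comet_catalogue` with `amine_count` and `molar_mass`
#'   for every ionizable molecule used.
#' @param per_nt_mass RNA per-nucleotide molar mass, g/mol.
#' @return The table with `np_ratio` filled in.
#' @export
weight_ratio_to_np <- function(tbl, catalogue, per_nt_mass = 330) {
  todo <- which(is.na(tbl$np_ratio) & !is.na(tbl$weight_ratio))
  if (!length(todo)) return(tbl)
  pc <- parse_components(tbl)
  cls <- setNames(catalogue$component_class, catalogue$id)
  amine <- setNames(catalogue$amine_count, catalogue$id)
  mw <- setNames(catalogue$molar_mass, catalogue$id)
  for (i in todo) {
    ids <- pc$ids[[i]]
    il <- ids[cls[ids] == "ionizable"]
    if (!length(il)) stop_fc("no ionizable component in %s", tbl$formulation_id[i])
    if (any(is.na(amine[il])) || any(is.na(mw[il])))
      stop_fc("missing amine_count/molar_mass for ionizable lipid(s) in %s",
              tbl$formulation_id[i])
    p <- pc$molar[[i]][match(il, ids)]
    tbl$np_ratio[i] <- tbl$weight_ratio[i] * per_nt_mass *
      sum(p * amine[il]) / sum(p * mw[il])
  }
  tbl
}

#' Composition slot matrix
#'
#' Expands formulations onto a shared component-slot vector: one column per
#' catalogue molecule (catalogue-sorted ids, deterministic across runs),
#' entries are molar percentages, zero where a molecule is absent.
#'
#' @param tbl Formulation table.
#' @param catalogue A `comet_catalogue`.
#' @return Numeric matrix, `nrow(tbl)` x `nrow(catalogue)`.
#' @export
molar_slot_matrix <- function(tbl, catalogue) {
  slots <- sort(catalogue$id)
  pc <- parse_components(tbl)
  M <- matrix(0, nrow(tbl), length(slots),
              dimnames = list(tbl$formulation_id, slots))
  for (i in seq_len(nrow(tbl))) {
    j <- match(pc$ids[[i]], slots)
    if (anyNA(j)) stop_fc("unknown molecule id in row %d", i)
    M[i, j] <- M[i, j] + pc$molar[[i]]
  }
  M
}

#' L1 distance between compositions
#'
#' Sum of absolute molar-percentage differences over a shared component
#' slot vector (absent components count as 0%). Symmetric, zero iff the
#' compositions are identical.
#'
#' @param a,b Numeric slot vectors (from [molar_slot_matrix()]) or matrices
#'   with matching columns (rowwise distances of `a` to a single-row `b`).
#' @return Numeric distance(s) in percentage points.
#' @export
l1_molar_distance <- function(a, b) {
  if (is.matrix(a)) return(rowSums(abs(sweep(a, 2, as.numeric(b)))))
  sum(abs(a - b))
}

#' Lyophilization degradation label
#'
#' The stability label is the drop in normalized efficacy caused by
#' freeze-drying: pre-lyophilization minus post-lyophilization label.
#' Negative values (improvement) keep their sign.
#'
#' @param pre,post Normalized efficacy labels in \[0, 1\].
#' @return `pre - post`.
#' @export
degradation_label <- function(pre, post) pre - post
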