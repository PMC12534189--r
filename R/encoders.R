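# Molecular and scalar encoders: turn a formulation into the token inputs
# the scoring network consumes.

.encoder_registry <- new.env(parent = emptyenv())
.fp_cache <- new.env(parent = emptyenv())

#' Default molecular encoder: folded circular fingerprint plus descriptors
#'
#' Encodes a molecule as a deterministic 512-dimensional real vector: a
#' circular substructure fingerprint of radius 2 (ECFP4, computed with
#' OpenBabel via ChemmineOB) folded from 4096 to 504 bits by OR-ing eight
#' segments, concatenated with eight scaled physicochemical descriptors
#' (molecular weight, logP, topological polar surface area, molar
#' refractivity, H-bond acceptor/donor counts, fluorine count). The
#' descriptor block is needed because a binary substructure fingerprint
#' cannot separate chain-length homologues (for example C14- versus
#' C18-tail PEG lipids), which are ubiquitous among lipids. Parameter-free
#' and frozen by construction: the same SMILES always yields the same
#' vector and no gradient flows into it.
#'
#' @param smiles A single SMILES string.
#' @return Numeric vector of length 512 (504 bits in \{0, 1\}, then 8
#'   scaled descriptors).
#' @export
default_molecular_encoder <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  hit <- .fp_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  mol <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tmol"), identity),
    error = function(e) NULL)
  fp <- if (is.null(mol)) NULL else tryCatch(
    ChemmineOB::fingerprint_OB(mol, "ECFP4"), error = function(e) NULL)
  if (is.null(fp) || !length(fp) || sum(fp) == 0)
    stop_fc("unparseable SMILES: %s", smiles)
  folded <- as.numeric(rowSums(matrix(fp[seq_len(4032)], nrow = 504)) > 0)
  pr <- ChemmineOB::prop_OB(mol)
  desc <- c(pr$MW / 1000, pr$logP / 10, pr$TPSA / 100, pr$MR / 100,
            pr$HBA1 / 10, pr$HBA2 / 10, pr$HBD / 10, pr$nF / 10)
  out <- c(folded, desc)
  assign(smiles, out, envir = .fp_cache)
  out
}

#' Molecular encoder registry
#'
#' Encoders are pluggable: any function mapping a SMILES string to a fixed
#' length numeric vector can be registered under a name and selected in
#' [comet_config()]. The default `"ecfp512"` encoder is registered at load.
#'
#' @param name Encoder name.
#' @param fn Function `smiles -> numeric vector`.
#' @param dim Output dimension.
#' @export
register_molecular_encoder <- function(name, fn, dim) {
  assign(name, list(fn = fn, dim = as.integer(dim)),
         envir = .encoder_registry)
  invisible(name)
}

#' @rdname register_molecular_encoder
#' @return `molecular_encoder()` returns the registered
#'   `list(fn=, dim=)`.
#' @export
molecular_encoder <- function(name = "ecfp512") {
  enc <- .encoder_registry[[name]]
  if (is.null(enc)) stop_fc("unknown molecular encoder: %s", name)
  enc
}

.onLoad <- function(libname, pkgname) {
  register_molecular_encoder("ecfp512", default_molecular_encoder, 512L)
}

#' Gaussian basis encoding of a scalar
#'
#' Encodes a scalar feature as its response under a bank of Gaussian basis
#' functions: `e_j = exp(-(v - mu_j)^2 / (2 sigma_j^2))`. All entries lie in
#' (0, 1] and the encoding varies smoothly with `v`. Inside the network the
#' means and widths are learnable; this function exposes the same map for a
#' given parameter set.
#'
#' @param v Finite scalar (vectorized over `v`).
#' @param mu Numeric vector of basis means.
#' @param sigma Numeric vector of basis widths (> 0).
#' @return Matrix `length(v)` x `length(mu)` of basis responses.
#' @export
encode_scalar <- function(v, mu, sigma) {
  if (any(!is.finite(v))) stop_fc("non-finite scalar input")
  if (any(sigma <= 0)) stop_fc("sigma must be > 0")
  t(vapply(v, function(x) exp(-(x - mu)^2 / (2 * sigma^2)),
           numeric(length(mu))))
}

#' Tokenize formulations for the scoring network
#'
#' Converts formulation rows into the flat token-feature batch consumed by
#' the transformer core: stacked molecular fingerprints, molar percentages
#' and component-class indices per component, plus the formulation-wide N/P
#' value (converting from weight ratio when necessary) and phase category
#' index. Supports any component count per formulation (dual-ionizable
#' formulations contribute five component tokens; polymer formulations add
#' repeat-unit and branching-agent tokens).
#'
#' @param tbl Formulation table (validated).
#' @param catalogue A `comet_catalogue`.
#' @param phase_levels Closed vocabulary of aqueous/organic categories;
#'   unseen categories are an error.
#' @param encoder Molecular encoder name (see [molecular_encoder()]).
#' @param class_levels Component classes the model knows; defaults to all
#'   of [component_classes()]. A class outside this vocabulary is an error.
#' @param per_nt_mass RNA per-nucleotide molar mass for weight-ratio
#'   conversion.
#' @return A `comet_tokens` list: `FP` (d_mol x total components), `molar`,
#'   `type` (0-based), `ncomp`, `np`, `phase` (0-based), `ids`, `labels`.
#' @export
tokenize_formulations <- function(tbl, catalogue,
                                  phase_levels = c("3:1", "1:1"),
                                  encoder = "ecfp512",
                                  class_levels = component_classes(),
                                  per_nt_mass = 330) {
  tbl <- weight_ratio_to_np(tbl, catalogue, per_nt_mass)
  if (anyNA(tbl$np_ratio)) stop_fc("N/P unavailable for some formulations")
  ph <- match(tbl$aq_org_ratio, phase_levels)
  if (anyNA(ph))
    stop_fc("unknown phase category: %s",
            paste(unique(tbl$aq_org_ratio[is.na(ph)]), collapse = ", "))
  pc <- parse_components(tbl)
  cls <- setNames(catalogue$component_class, catalogue$id)
  smi <- setNames(catalogue$smiles, catalogue$id)
  all_ids <- unlist(pc$ids)
  type <- match(cls[all_ids], class_levels)
  if (anyNA(type))
    stop_fc("component class outside model vocabulary: %s",
            paste(unique(cls[all_ids][is.na(type)]), collapse = ", "))
  enc <- molecular_encoder(encoder)
  uniq <- unique(smi[all_ids])
  fps <- vapply(uniq, enc$fn, numeric(enc$dim))
  FP <- fps[, match(smi[all_ids], uniq), drop = FALSE]
  out <- list(FP = unname(FP),
              molar = as.numeric(unlist(pc$molar)),
              type = as.integer(type - 1L),
              ncomp = as.integer(lengths(pc$ids)),
              np = as.numeric(tbl$np_ratio),
              phase = as.integer(ph - 1L),
              ids = tbl$formulation_id,
              labels = formulation_labels(tbl),
              encoder = encoder, phase_levels = phase_levels,
              class_levels = class_levels)
  class(out) <- "comet_tokens"
  out
}

#' @export
print.comet_tokens <- function(x, ...) {
  cat(sprintf("Tokenized batch: %d formulations, %d component tokens, %d labelled task(s)\n",
              length(x$ncomp), length(x$molar),
              sum(vapply(x$labels, function(l) any(!is.na(l)), TRUE))))
  invisible(x)
}

# subset a comet_tokens batch by formulation index
subset_tokens <- function(tokens, idx) {
  ends <- cumsum(tokens$ncomp)
  starts <- ends - tokens$ncomp + 1L
  comp_idx <- unlist(lapply(idx, function(i) starts[i]:ends[i]))
  out <- tokens
  out$FP <- tokens$FP[, comp_idx, drop = FALSE]
  out$molar <- tokens$molar[comp_idx]
  out$type <- tokens$type[comp_idx]
  out$ncomp <- tokens$ncomp[idx]
  out$np <- tokens$np[idx]
  out$phase <- tokens$phase[idx]
  out$ids <- tokens$ids[idx]
  out$labels <- lapply(tokens$labels, `[`, idx)
  out
}

n_tokens <- function(tokens) length(tokens$ncomp)
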