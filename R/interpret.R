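# Integrated-gradients attribution over the model's multimodal embeddings,
# grouped per feature, plus CLS-representation export for visualization.

# embedding-level inputs for one formulation: component embedding matrix
# (n_comp x d_in), the N/P gaussian token and the phase token
formulation_embeddings <- function(model, tok, i) {
  cfg <- model$config; lay <- model$layout
  th <- model$theta
  gc_mu <- th[lay$gc_mu + seq_len(cfg$d_comp)]
  gc_sg <- exp(th[lay$gc_ls + seq_len(cfg$d_comp)])
  gn_mu <- th[lay$gn_mu + seq_len(cfg$d_token)]
  gn_sg <- exp(th[lay$gn_ls + seq_len(cfg$d_token)])
  type_emb <- matrix(th[lay$type_emb + seq_len(cfg$d_type * cfg$n_types)],
                     cfg$d_type, cfg$n_types)
  phase_emb <- matrix(th[lay$phase_emb + seq_len(cfg$d_token * cfg$n_phases)],
                      cfg$d_token, cfg$n_phases)
  bt <- subset_tokens(tok, i)
  E <- cbind(t(bt$FP),
             encode_scalar(bt$molar, gc_mu, gc_sg),
             t(type_emb[, bt$type + 1L, drop = FALSE]))
  list(E = E,
       enp = as.numeric(encode_scalar(bt$np, gn_mu, gn_sg)),
       ephase = phase_emb[, bt$phase + 1L],
       type = bt$type)
}

# class-conditional mean embeddings over a reference token set
reference_baseline <- function(model, ref_tok) {
  cfg <- model$config
  n <- n_tokens(ref_tok)
  emb <- formulation_embeddings(model, ref_tok, seq_len(n))
  E_by_class <- lapply(seq_len(cfg$n_types) - 1L, function(cl) {
    rows <- emb$type == cl
    if (!any(rows)) return(NULL)
    colMeans(emb$E[rows, , drop = FALSE])
  })
  # np / phase tokens: mean over reference formulations
  gn_mu <- model$theta[model$layout$gn_mu + seq_len(cfg$d_token)]
  gn_sg <- exp(model$theta[model$layout$gn_ls + seq_len(cfg$d_token)])
  enp <- colMeans(encode_scalar(ref_tok$np, gn_mu, gn_sg))
  phase_emb <- matrix(model$theta[model$layout$phase_emb +
                                    seq_len(cfg$d_token * cfg$n_phases)],
                      cfg$d_token, cfg$n_phases)
  ephase <- rowMeans(phase_emb[, ref_tok$phase + 1L, drop = FALSE])
  list(E_by_class = E_by_class, enp = enp, ephase = ephase)
}

#' Integrated-gradients attribution for one formulation
#'
#' Computes path-integrated gradients of the task score with respect to the
#' model's input embeddings, from a reference baseline to the formulation.
#' The baseline is the class-conditional mean embedding of a reference
#' dataset (for each component, the mean embedding of reference components
#' of the same class; for the N/P and phase tokens, the reference mean
#' token). Attributions are summed into feature groups: molecule choice and
#' molar percentage per component class, N/P ratio, and phase ratio. The
#' completeness property holds: grouped attributions sum to
#' `score(x) - score(baseline)` up to quadrature error.
#'
#' When several models are supplied, per-model grouped attributions are
#' normalized to maximum absolute value 1 and averaged across models.
#'
#' @param models A `comet_model`, list of models, or `comet_ensemble`.
#' @param x Single formulation (table row or 1-formulation `comet_tokens`).
#' @param reference Reference dataset (`comet_data`, `comet_tokens`, or
#'   table with `catalogue`): defines the baseline. Typically the non-polymer
#'   training formulations.
#' @param task Task id.
#' @param n_steps Path quadrature steps (midpoint rule; >= 16).
#' @param catalogue Catalogue when tables are supplied.
#' @return An `attribution_report`: normalized group attributions
#'   (`groups`), per-model raw group attributions, scores and completeness
#'   residuals.
#' @export
integrated_gradients <- function(models, x, reference, task, n_steps = 128L,
                                 catalogue = NULL) {
  if (inherits(models, "comet_ensemble")) models <- models$models
  if (inherits(models, "comet_model")) models <- list(models)
  if (n_steps < 16) stop_fc("n_steps must be >= 16")
  m1 <- models[[1]]
  tok <- as_tokens(x, m1, catalogue)
  if (n_tokens(tok) != 1) stop_fc("attribution is per formulation")
  ref_tok <- if (inherits(reference, "comet_data")) reference$tokens
             else as_tokens(reference, m1, catalogue)
  ti <- task_index(m1, task)
  cfg <- m1$config
  d_mol <- cfg$d_mol; d_comp <- cfg$d_comp
  cls_names <- cfg$class_levels
  per_model <- lapply(models, function(model) {
    emb <- formulation_embeddings(model, tok, 1L)
    base <- reference_baseline(model, ref_tok)
    Eb <- t(vapply(emb$type + 1L, function(cl) {
      bc <- base$E_by_class[[cl]]
      if (is.null(bc)) stop_fc("no reference components of class %s",
                               cls_names[cl])
      bc
    }, numeric(ncol(emb$E))))
    dE <- emb$E - Eb
    dnp <- emb$enp - base$enp
    dph <- emb$ephase - base$ephase
    gE <- matrix(0, nrow(emb$E), ncol(emb$E))
    gnp <- numeric(cfg$d_token); gph <- numeric(cfg$d_token)
    ccfg <- cfg_for_cpp(cfg)
    for (s in (seq_len(n_steps) - 0.5) / n_steps) {
      out <- cpp_comet_embed_score(model$theta, ccfg, model$layout,
                                   Eb + s * dE, base$enp + s * dnp,
                                   base$ephase + s * dph, ti, TRUE)
      gE <- gE + out$dEcomp; gnp <- gnp + out$dEnp; gph <- gph + out$dEphase
    }
    attr_E <- dE * gE / n_steps
    attr_np <- sum(dnp * gnp) / n_steps
    attr_ph <- sum(dph * gph) / n_steps
    groups <- c(setNames(numeric(2 * length(cls_names)),
                         c(paste0("choice_", cls_names),
                           paste0("molar_", cls_names))),
                np = attr_np, phase = attr_ph)
    for (kk in seq_len(nrow(attr_E))) {
      cl <- cls_names[emb$type[kk] + 1L]
      # molecule identity: fingerprint + class-embedding coordinates
      groups[paste0("choice_", cl)] <- groups[paste0("choice_", cl)] +
        sum(attr_E[kk, c(seq_len(d_mol), (d_mol + d_comp + 1):ncol(attr_E))])
      groups[paste0("molar_", cl)] <- groups[paste0("molar_", cl)] +
        sum(attr_E[kk, d_mol + seq_len(d_comp)])
    }
    sx <- cpp_comet_embed_score(model$theta, ccfg, model$layout, emb$E,
                                emb$enp, emb$ephase, ti, FALSE)$score
    sb <- cpp_comet_embed_score(model$theta, ccfg, model$layout, Eb,
                                base$enp, base$ephase, ti, FALSE)$score
    list(groups = groups, score_x = sx, score_base = sb,
         residual = sum(groups) - (sx - sb))
  })
  norm_groups <- lapply(per_model, function(pm) {
    mx <- max(abs(pm$groups))
    if (mx == 0) pm$groups else pm$groups / mx
  })
  structure(list(
    groups = Reduce(`+`, norm_groups) / length(norm_groups),
    per_model = per_model, task = task, n_steps = n_steps,
    formulation_id = tok$ids),
    class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("Integrated-gradients attribution for %s (task %s):\n",
              x$formulation_id, x$task))
  g <- sort(abs(x$groups), decreasing = TRUE)
  print(round(x$groups[names(g)], 4))
  invisible(x)
}

#' Rank feature groups by attribution magnitude
#'
#' Aggregates attribution reports over a dataset: the mean absolute
#' normalized attribution per feature group, ranked.
#'
#' @param reports List of [integrated_gradients()] reports (one task).
#' @return Data frame `group`, `mean_abs_attribution`, sorted decreasing.
#' @export
feature_importance_summary <- function(reports) {
  if (!length(reports)) stop_fc("no attribution reports")
  M <- vapply(reports, function(r) abs(r$groups),
              numeric(length(reports[[1]]$groups)))
  if (!is.matrix(M)) M <- matrix(M, ncol = length(reports))
  mean_abs <- rowMeans(M)
  if (all(mean_abs == 0)) warn_fc("all attributions are zero; ranks are uniform")
  out <- data.frame(group = names(reports[[1]]$groups),
                    mean_abs_attribution = mean_abs, row.names = NULL)
  out[order(-out$mean_abs_attribution, out$group), ]
}

#' Export CLS representations for embedding visualization
#'
#' Scores a probe set with every ensemble member, selects the member whose
#' scores correlate best (Spearman) with the ensemble scores, and returns
#' that member's CLS vectors -- optionally subsampled to a fixed number of
#' formulations per ionizable-lipid class, with dual-ionizable formulations
#' treated as their own class.
#'
#' @param ensemble A `comet_ensemble` (or list of models).
#' @param x Probe formulations (table or `comet_tokens`).
#' @param task Task id.
#' @param catalogue Catalogue (needed for tables / class labels).
#' @param per_class Optional per-class subsample size.
#' @param seed Subsampling seed.
#' @return List: `representation` (matrix n x d_token), `class` (labels),
#'   `model_index` (selected member), `scores` (ensemble scores of the
#'   returned rows).
#' @export
export_representations <- function(ensemble, x, task, catalogue = NULL,
                                   per_class = NULL, seed = 1L) {
  models <- if (inherits(ensemble, "comet_ensemble")) ensemble$models
            else ensemble
  tok <- as_tokens(x, models[[1]], catalogue)
  n <- n_tokens(tok)
  if (!n) stop_fc("empty probe set")
  raw <- vapply(models, function(m) forward_batch(m, tok, task = task),
                numeric(n))
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = n)
  ens <- rowMeans(scale(raw))
  pick <- if (ncol(raw) == 1) 1L else
    which.max(vapply(seq_len(ncol(raw)), function(i)
      suppressWarnings(cor(raw[, i], ens, method = "spearman")), 0))
  # ionizable-lipid class label per formulation: the ionizable molecule id
  # when the input was a table, with dual-ionizable as its own class
  cls_lab <- if (is.data.frame(x) && !is.null(catalogue)) {
    pc <- parse_components(x)
    cls <- setNames(catalogue$component_class, catalogue$id)
    vapply(pc$ids, function(ids) {
      il <- ids[cls[ids] == "ionizable"]
      if (length(il) > 1) "dual" else il[1]
    }, "")
  } else {
    # tokenized input: count ionizable component tokens per formulation
    ends <- cumsum(tok$ncomp); starts <- ends - tok$ncomp + 1L
    il_idx <- which(tok$class_levels[tok$type + 1L] == "ionizable")
    vapply(seq_len(n), function(i) {
      k <- length(intersect(starts[i]:ends[i], il_idx))
      if (k > 1) "dual" else "single"
    }, "")
  }
  keep <- seq_len(n)
  if (!is.null(per_class)) {
    set.seed(seed)
    keep <- unlist(lapply(split(seq_len(n), cls_lab), function(ix)
      if (length(ix) <= per_class) ix else sample(ix, per_class)))
    keep <- sort(keep)
  }
  rep_mat <- extract_cls_representation(models[[pick]],
                                        subset_tokens(tok, keep), task = task)
  list(representation = rep_mat, class = cls_lab[keep],
       model_index = pick, scores = ens[keep])
}
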