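# Evaluation protocol: split construction, ranking metrics, classical
# baselines, and adversarial identity-shuffling robustness probes.

#' Split specification
#'
#' @param kind `"random"` (70/10/20 train/valid/test), `"hits_test"` (the
#'   top 10% of labels withheld as hits plus a random 10% of non-hits), or
#'   `"leave_chemistry_out"` (every formulation containing a named molecule
#'   goes to test).
#' @param seed Seed for the random draws.
#' @param task Task whose labels define hits (hits_test).
#' @param molecules Molecule ids to hold out (leave_chemistry_out).
#' @param fractions Train/valid/test fractions for `"random"`.
#' @return A `split_spec`.
#' @export
split_spec <- function(kind = c("random", "hits_test", "leave_chemistry_out"),
                       seed = 1L, task = NULL, molecules = NULL,
                       fractions = c(train = 0.7, valid = 0.1, test = 0.2)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), task = task,
                 molecules = molecules, fractions = fractions),
            class = "split_spec")
}

#' Construct train/valid/test index sets
#'
#' Deterministic under the spec's seed. For `hits_test`, the test set is
#' the top `ceil(0.1 N)` formulations by label (label ties at the threshold
#' included) plus a random `floor(0.1 (N - n_hits))` non-hits; the
#' remaining formulations are split train/valid. For
#' `leave_chemistry_out`, all formulations containing a named molecule form
#' the test set.
#'
#' @param tbl Formulation table (labelled for the hit task if needed).
#' @param spec A [split_spec()].
#' @return List of integer index vectors `train`, `valid`, `test`.
#' @export
make_split <- function(tbl, spec) {
  n <- nrow(tbl)
  if (n < 10) stop_fc("dataset too small to split")
  set.seed(spec$seed)
  if (spec$kind == "random") {
    f <- spec$fractions
    idx <- sample.int(n)
    n_test <- round(f[["test"]] * n)
    n_valid <- round(f[["valid"]] * n)
    list(train = sort(idx[seq_len(n - n_test - n_valid)]),
         valid = sort(idx[n - n_test - n_valid + seq_len(n_valid)]),
         test = sort(idx[n - n_test + seq_len(n_test)]))
  } else if (spec$kind == "hits_test") {
    task <- spec$task %||% names(label_columns(tbl))[1]
    y <- tbl[[paste0("label:", task)]]
    if (anyNA(y)) stop_fc("hits_test requires labels for every formulation")
    n_hits <- ceiling(0.1 * n)
    ord <- order(-y, seq_len(n))
    thresh <- y[ord[n_hits]]
    hits <- which(y >= thresh) # ties at the threshold count as hits
    non_hits <- setdiff(seq_len(n), hits)
    extra <- sort(sample(non_hits, floor(0.1 * length(non_hits))))
    test <- sort(c(hits, extra))
    rest <- setdiff(seq_len(n), test)
    n_valid <- max(1, round(length(rest) / 8))
    valid <- sort(sample(rest, n_valid))
    list(train = setdiff(rest, valid), valid = valid, test = test)
  } else {
    pc <- parse_components(tbl)
    has <- vapply(pc$ids, function(ids)
      any(spec$molecules %in% ids), TRUE)
    test <- which(has)
    rest <- which(!has)
    if (!length(rest)) stop_fc("exclusion empties the training set")
    n_valid <- max(1, round(length(rest) / 8))
    valid <- sort(sample(rest, n_valid))
    list(train = setdiff(rest, valid), valid = valid, test = test)
  }
}

#' Ranking metrics
#'
#' Spearman and Pearson correlation between predictions and labels (ties
#' mid-ranked). With fewer than 3 points or zero variance the result is
#' `NaN` with a warning rather than an error, matching how degenerate
#' baseline fits are reported.
#'
#' @param pred Predicted scores.
#' @param truth Labels.
#' @return Named vector `c(spearman=, pearson=)`.
#' @export
rank_metrics <- function(pred, truth) {
  if (length(pred) < 3) stop_fc("need >= 3 observations")
  if (pop_sd(pred) == 0 || pop_sd(truth) == 0) {
    warn_fc("zero variance: correlation undefined, reporting NaN")
    return(c(spearman = NaN, pearson = NaN))
  }
  c(spearman = cor(pred, truth, method = "spearman"),
    pearson = cor(pred, truth, method = "pearson"))
}

#' Top-half hit classification accuracy
#'
#' Fraction of true hits whose predicted rank falls within the top
#' `ceil(N/2)` of the ranked predictions.
#'
#' @param pred Predicted scores.
#' @param hit_mask Logical vector marking true hits (>= 1 hit).
#' @return Fraction in \[0, 1\].
#' @export
top_half_hit_accuracy <- function(pred, hit_mask) {
  if (!any(hit_mask)) stop_fc("no hits in mask")
  top <- order(-pred, seq_along(pred))[seq_len(ceiling(length(pred) / 2))]
  mean(which(hit_mask) %in% top)
}

# flattened feature matrix for classical baselines: molecule presence
# one-hots, molar % per slot, N/P, phase one-hot
baseline_features <- function(tbl, catalogue,
                              phase_levels = c("3:1", "1:1")) {
  M <- molar_slot_matrix(tbl, catalogue)
  tbl <- weight_ratio_to_np(tbl, catalogue)
  ph <- outer(tbl$aq_org_ratio, phase_levels, `==`) * 1
  colnames(ph) <- paste0("phase_", phase_levels)
  cbind(M > 0, M, np = tbl$np_ratio, ph)
}

#' Classical baselines: k-NN and random forest
#'
#' Fits k-nearest-neighbours regression (k = 5) and a random forest
#' (100 trees) on flattened formulation features (molecule one-hots, molar
#' percentages, N/P, phase one-hot) and evaluates them with the same
#' metrics as the transformer.
#'
#' @param tbl Labelled formulation table.
#' @param catalogue A `comet_catalogue`.
#' @param split List with `train` and `test` indices.
#' @param task Task id.
#' @param hit_quantile Quantile defining hits for the accuracy metric.
#' @param phase_levels Phase vocabulary.
#' @return Data frame of metrics per baseline model.
#' @export
baseline_models <- function(tbl, catalogue, split, task,
                            hit_quantile = 0.9,
                            phase_levels = c("3:1", "1:1")) {
  y <- tbl[[paste0("label:", task)]]
  X <- baseline_features(tbl, catalogue, phase_levels)
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xte <- X[split$test, , drop = FALSE]; yte <- y[split$test]
  knn_fit <- caret::knnreg(Xtr, ytr, k = 5)
  rf_fit <- randomForest::randomForest(Xtr, ytr, ntree = 100)
  preds <- list(knn = predict(knn_fit, Xte),
                random_forest = predict(rf_fit, Xte))
  hit_thresh <- quantile(y, hit_quantile, names = FALSE)
  do.call(rbind, lapply(names(preds), function(nm) {
    m <- suppressWarnings(rank_metrics(preds[[nm]], yte))
    data.frame(model = nm, spearman = m[["spearman"]],
               pearson = m[["pearson"]],
               top_half_accuracy = top_half_hit_accuracy(
                 preds[[nm]], yte >= hit_thresh))
  }))
}

#' Adversarial identity shuffling
#'
#' Corrupts a fraction of formulations by replacing their component
#' molecules: `"within_class"` substitutes each component with a random
#' catalogue molecule of the same class; `"cross_class"` substitutes
#' across classes (each corrupted formulation is guaranteed to lose its
#' original lipid set); `"plus_parameters"` additionally permutes N/P,
#' molar compositions and phase ratios among the corrupted rows. Labels are
#' untouched, so increasing `p` severs the structure-activity link.
#'
#' @param tbl Formulation table.
#' @param catalogue A `comet_catalogue`.
#' @param p Fraction of rows corrupted, in \[0, 1\].
#' @param mode Corruption mode.
#' @param seed Seed.
#' @return The corrupted table.
#' @export
corrupt_identities <- function(tbl, catalogue, p,
                               mode = c("within_class", "cross_class",
                                        "plus_parameters"),
                               seed = 1L) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) stop_fc("p must be in [0, 1]")
  if (p == 0) return(tbl)
  set.seed(seed)
  n <- nrow(tbl)
  rows <- sort(sample.int(n, round(p * n)))
  pc <- parse_components(tbl)
  cls <- setNames(catalogue$component_class, catalogue$id)
  by_class <- split(catalogue$id, catalogue$component_class)
  lipids <- catalogue$id[catalogue$component_class %in%
                           c("ionizable", "helper", "sterol", "peg")]
  for (i in rows) {
    ids <- pc$ids[[i]]
    for (try in 1:100) {
      new_ids <- if (mode == "within_class") {
        vapply(ids, function(id) {
          pool <- by_class[[cls[id]]]
          if (length(pool) == 1) id else sample(setdiff(pool, id), 1)
        }, "")
      } else {
        sample(lipids, length(ids))
      }
      if (anyDuplicated(new_ids) == 0 && !setequal(new_ids, ids)) break
    }
    pc$ids[[i]] <- unname(new_ids)
  }
  tbl$component_ids[rows] <- vapply(pc$ids[rows], paste, "", collapse = ";")
  if (mode == "plus_parameters" && length(rows) > 1) {
    perm <- sample(rows)
    tbl$np_ratio[rows] <- tbl$np_ratio[perm]
    tbl$weight_ratio[rows] <- tbl$weight_ratio[perm]
    tbl$aq_org_ratio[rows] <- tbl$aq_org_ratio[perm]
    # compositions are permuted within equal component counts so every row
    # keeps one percentage per component
    for (grp in split(rows, lengths(pc$ids[rows]))) {
      if (length(grp) > 1)
        tbl$molar_percents[grp] <- tbl$molar_percents[sample(grp)]
    }
  }
  tbl
}
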