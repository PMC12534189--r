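# Ensembling, score normalization, relative uncertainty, and the in silico
# screening funnel: exclusion -> top fraction -> uncertainty filter ->
# diversity clustering -> lead optimization.

#' Train a model ensemble
#'
#' Either five-fold (`"folds"`): the labelled data are partitioned into
#' `n_models` disjoint validation folds and each member trains on the
#' complement of its fold; or same-split (`"seeds"`): every member uses the
#' same train/validation split but a different weight-initialization seed.
#' After training, each member's scores on the full training-role dataset
#' (the reference set) are summarized so later predictions can be
#' normalized to reference mean 0 / sd 1 per model.
#'
#' @param data A [comet_data()].
#' @param config A [comet_config()].
#' @param train A [train_config()].
#' @param n_models Ensemble size.
#' @param mode `"folds"` or `"seeds"`.
#' @param seed Master seed (fold assignment and per-member seed stream).
#' @return A `comet_ensemble` with members, per-model reference statistics
#'   and the reference minimum ensemble score.
#' @export
comet_ensemble <- function(data, config, train = train_config(),
                           n_models = 5L, mode = c("folds", "seeds"),
                           seed = 1L) {
  mode <- match.arg(mode)
  n <- n_tokens(data$tokens)
  if (n < n_models) stop_fc("need at least %d formulations", n_models)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(n_models), n))
  shared_val <- sort(sample.int(n, max(1, round(train$val_fraction * n))))
  models <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    split <- if (mode == "folds") {
      list(train = which(fold_of != i), val = which(fold_of == i))
    } else {
      list(train = setdiff(seq_len(n), shared_val), val = shared_val)
    }
    cfg_i <- config
    cfg_i$seed <- as.integer(seed + 1000L * i)
    tr_i <- train
    tr_i$seed <- as.integer(seed + 1000L * i + 1L)
    models[[i]] <- comet(data, cfg_i, tr_i, split = split)
  }
  ens <- structure(list(models = models, config = config, mode = mode,
                        tasks = config$tasks, seed = seed),
                   class = "comet_ensemble")
  ens$reference <- lapply(setNames(config$tasks, config$tasks), function(t) {
    raw <- vapply(models, function(m) forward_batch(m, data$tokens, task = t),
                  numeric(n))
    stats <- lapply(seq_len(n_models), function(i)
      list(mean = mean(raw[, i]), sd = pop_sd(raw[, i])))
    norm <- vapply(seq_len(n_models),
                   function(i) (raw[, i] - stats[[i]]$mean) / stats[[i]]$sd,
                   numeric(n))
    list(stats = stats, min_ensemble = min(rowMeans(norm)))
  })
  ens
}

#' @export
print.comet_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d formulation scorers (%s mode), tasks: %s\n",
              length(x$models), x$mode, paste(x$tasks, collapse = ", ")))
  invisible(x)
}

#' Normalize raw model scores against a reference set
#'
#' Each model's scores are centred and scaled by the mean and population
#' standard deviation of its scores on the reference (training-role)
#' dataset, so ensemble averaging is not biased towards high-variance
#' members. After normalization the reference scores have mean 0 and sd 1.
#'
#' @param raw Numeric vector of raw scores from one model.
#' @param reference That model's raw scores on the reference set (>= 2
#'   distinct values), or a `list(mean=, sd=)` of precomputed statistics.
#' @return Normalized scores.
#' @export
normalize_scores <- function(raw, reference) {
  st <- if (is.list(reference)) reference
        else list(mean = mean(reference), sd = pop_sd(reference))
  if (!is.finite(st$sd) || st$sd <= 0) stop_fc("zero reference score spread")
  (raw - st$mean) / st$sd
}

#' Ensemble score
#'
#' The arithmetic mean of the models' normalized scores.
#'
#' @param norm_scores Matrix (formulations x models) of normalized scores,
#'   or a vector for a single formulation.
#' @return Numeric ensemble score(s).
#' @export
ensemble_score <- function(norm_scores) {
  if (is.matrix(norm_scores)) rowMeans(norm_scores) else mean(norm_scores)
}

#' Relative prediction uncertainty
#'
#' The population standard deviation of the models' normalized scores,
#' divided by the shifted non-negative ensemble score
#' `yhat = ensemble - reference_min` (the reference minimum makes the
#' denominator non-negative on reference-like inputs). Candidates whose
#' shifted score is not positive are flagged `dropped` rather than given an
#' uncertainty value.
#'
#' @param norm_scores Matrix (formulations x models), >= 2 models.
#' @param reference_min Minimum ensemble score over the reference set.
#' @return Data frame with `ensemble`, `yhat`, `sigma`, `u_rel`, `dropped`.
#' @export
relative_uncertainty <- function(norm_scores, reference_min) {
  if (!is.matrix(norm_scores) || ncol(norm_scores) < 2)
    stop_fc("need scores from >= 2 models")
  ens <- rowMeans(norm_scores)
  sigma <- apply(norm_scores, 1, pop_sd)
  yhat <- ens - reference_min
  dropped <- yhat <= 0
  u <- ifelse(dropped, NA_real_, sigma / yhat)
  data.frame(ensemble = ens, yhat = yhat, sigma = sigma, u_rel = u,
             dropped = dropped)
}

#' Per-model and ensemble predictions
#'
#' @param object A `comet_ensemble`.
#' @param newdata Formulation table or `comet_tokens`.
#' @param task Task id.
#' @param catalogue Catalogue when `newdata` is a table.
#' @param ... Unused.
#' @return Data frame with per-model normalized scores (`m1..mk`),
#'   `ensemble`, `yhat`, `sigma`, `u_rel`, `dropped`.
#' @export
predict.comet_ensemble <- function(object, newdata,
                                   task = object$tasks[1],
                                   catalogue = NULL, ...) {
  tok <- as_tokens(newdata, object$models[[1]], catalogue)
  ref <- object$reference[[task]]
  if (is.null(ref)) stop_fc("unknown task: %s", task)
  norm <- vapply(seq_along(object$models), function(i)
    normalize_scores(forward_batch(object$models[[i]], tok, task = task),
                     ref$stats[[i]]),
    numeric(n_tokens(tok)))
  if (!is.matrix(norm)) norm <- matrix(norm, nrow = 1)
  out <- relative_uncertainty(norm, ref$min_ensemble)
  colnames(norm) <- paste0("m", seq_len(ncol(norm)))
  cbind(data.frame(formulation_id = tok$ids), norm, out)
}

#' Select the top fraction of scored candidates
#'
#' Keeps the `floor(fraction * N)` highest-scoring candidates; ties are
#' broken by original (enumeration) order, so results are reproducible for
#' a fixed grid.
#'
#' @param scores Numeric scores.
#' @param fraction Fraction in (0, 1].
#' @return Integer indices of the selected candidates, highest first.
#' @export
select_top_fraction <- function(scores, fraction) {
  if (!length(scores)) stop_fc("empty score vector")
  if (fraction <= 0 || fraction > 1) stop_fc("fraction must be in (0, 1]")
  k <- floor(fraction * length(scores))
  head(order(-scores, seq_along(scores)), k)
}

#' Drop the most uncertain half
#'
#' Retains the `floor(N/2)` candidates with the lowest relative
#' uncertainty (ties by original order). Candidates flagged dropped must be
#' removed beforehand.
#'
#' @param u_rel Numeric relative uncertainties.
#' @return Integer indices of the retained candidates.
#' @export
drop_uncertain_half <- function(u_rel) {
  k <- floor(length(u_rel) / 2)
  sort(head(order(u_rel, seq_along(u_rel)), k))
}

#' Diversity selection by stabilized K-means
#'
#' Clusters candidate compositions (molar-percentage slot vectors) into `k`
#' groups with K-means, keeping the lowest-inertia solution over
#' `n_restarts` seeded restarts, and returns the highest-scoring candidate
#' of each cluster.
#'
#' @param molar_mat Numeric matrix of candidate composition vectors.
#' @param scores Candidate scores (same length as rows).
#' @param k Number of clusters / picks.
#' @param n_restarts K-means restarts (best of, by total within-cluster
#'   sum of squares).
#' @param seed Seed for the restarts.
#' @return Integer indices of the `k` selected candidates (score-descending).
#' @export
diverse_hits <- function(molar_mat, scores, k = 10L, n_restarts = 1000L,
                         seed = 1L) {
  n <- nrow(molar_mat)
  if (k > n) stop_fc("k exceeds the number of candidates")
  if (k == n) return(order(-scores, seq_len(n)))
  set.seed(seed)
  km <- suppressWarnings(
    kmeans(molar_mat, centers = k, nstart = n_restarts, iter.max = 100))
  picks <- vapply(seq_len(k), function(cl) {
    members <- which(km$cluster == cl)
    members[order(-scores[members], members)[1]]
  }, 0L)
  picks[order(-scores[picks])]
}

#' Run the full in silico screening funnel
#'
#' Streams a virtual library through: (1) exclusion of candidates within an
#' L1 composition radius of known hits (same lipid set only); (2) ensemble
#' scoring with per-model reference normalization; (3) top-fraction
#' selection; (4) removal of non-positive shifted scores and of the most
#' uncertain half; (5) K-means diversity selection of `k` final hits.
#'
#' @param ensemble A `comet_ensemble`.
#' @param library A [virtual_library()] (or formulation table).
#' @param catalogue A `comet_catalogue`.
#' @param task Task to screen for.
#' @param hits Formulation table of known hits to exclude around (may be
#'   empty).
#' @param exclude_radius L1 exclusion radius in percentage points.
#' @param top_fraction Fraction kept after scoring.
#' @param k Number of diverse hits returned.
#' @param n_restarts K-means restarts.
#' @param chunk_size Streaming chunk size.
#' @param seed Seed (clustering).
#' @return A `funnel_report`: stage counts, selected formulation table with
#'   ensemble scores and uncertainties.
#' @export
screen_library <- function(ensemble, library, catalogue,
                           task = ensemble$tasks[1],
                           hits = NULL, exclude_radius = 10,
                           top_fraction = 0.001, k = 10L,
                           n_restarts = 1000L, chunk_size = 2000L,
                           seed = 1L) {
  if (is.data.frame(library)) {
    count <- nrow(library)
    slices <- function(fun) fun(library, 1)
  } else {
    count <- library$count
    slices <- function(fun) library$chunks(chunk_size, fun)
  }
  kept_tbl <- list(); kept_pred <- list()
  slices(function(tbl, from) {
    if (!is.null(hits) && nrow(hits))
      tbl <- exclude_near_hits(tbl, hits, exclude_radius, catalogue)
    if (!nrow(tbl)) return(invisible(NULL))
    pred <- predict(ensemble, tbl, task = task, catalogue = catalogue)
    kept_tbl[[length(kept_tbl) + 1L]] <<- tbl
    kept_pred[[length(kept_pred) + 1L]] <<- pred
    invisible(NULL)
  })
  tbl <- do.call(rbind, kept_tbl)
  pred <- do.call(rbind, kept_pred)
  n_scored <- nrow(tbl)
  top <- select_top_fraction(pred$ensemble, top_fraction)
  tbl_top <- tbl[top, , drop = FALSE]; pred_top <- pred[top, , drop = FALSE]
  ok <- !pred_top$dropped
  n_dropped_nonpos <- sum(!ok)
  tbl_top <- tbl_top[ok, , drop = FALSE]
  pred_top <- pred_top[ok, , drop = FALSE]
  retained <- drop_uncertain_half(pred_top$u_rel)
  tbl_ret <- tbl_top[retained, , drop = FALSE]
  pred_ret <- pred_top[retained, , drop = FALSE]
  k_eff <- min(k, nrow(tbl_ret))
  sel <- diverse_hits(molar_slot_matrix(tbl_ret, catalogue),
                      pred_ret$ensemble, k = k_eff,
                      n_restarts = n_restarts, seed = seed)
  selected <- cbind(tbl_ret[sel, , drop = FALSE],
                    pred_ret[sel, c("ensemble", "u_rel"), drop = FALSE])
  structure(list(
    counts = c(enumerated = count, scored = n_scored,
               excluded = count - n_scored,
               top_fraction = length(top),
               nonpositive_dropped = n_dropped_nonpos,
               uncertainty_retained = length(retained),
               selected = k_eff),
    task = task, selected = selected),
    class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("Screening funnel (%s):\n", x$task))
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %s\n", nm, format(x$counts[[nm]], big.mark = ",")))
  invisible(x)
}

#' Lead-optimization candidates around a hit
#'
#' Segments the neighbourhood of a lead formulation into three disjoint
#' zones and returns the ensemble-best candidate from each: (1) composition
#' zone -- identical lipids, composition within `radius` L1 but not equal
#' to the lead; (2) substitution zone -- at least one different lipid,
#' composition within `radius` L1; (3) for lipid leads, an N/P zone --
#' identical lipids and composition, different N/P; for polymer leads, a
#' dual-ionizable zone -- the lead's ionizable lipid paired 60:40 with each
#' alternative. The lead itself belongs to no zone.
#'
#' @param lead Single-row formulation table.
#' @param grid A [design_grid()] defining the candidate space.
#' @param ensemble A `comet_ensemble`.
#' @param catalogue A `comet_catalogue`.
#' @param task Task to optimize.
#' @param mode `"lipid"` or `"pbae"` (selects zone 3).
#' @param radius L1 neighbourhood radius in percentage points.
#' @return Formulation table of up to three candidates with a `zone`
#'   column; zones with no candidates are reported with a warning.
#' @export
lead_optimization_segments <- function(lead, grid, ensemble, catalogue,
                                       task = ensemble$tasks[1],
                                       mode = c("lipid", "pbae"),
                                       radius = 20) {
  mode <- match.arg(mode)
  stopifnot(nrow(lead) == 1)
  lib <- virtual_library(grid)
  cand <- lib$slice(1, lib$count)
  lead_slot <- molar_slot_matrix(lead, catalogue)[1, ]
  cand_slot <- molar_slot_matrix(cand, catalogue)
  d <- l1_molar_distance(cand_slot, lead_slot)
  lead_set <- paste(sort(parse_components(lead)$ids[[1]]), collapse = "|")
  cand_set <- vapply(parse_components(cand)$ids,
                     function(x) paste(sort(x), collapse = "|"), "")
  same_lipids <- cand_set == lead_set
  lead_np <- lead$np_ratio
  same_np <- if (!is.na(lead_np)) abs(cand$np_ratio - lead_np) < 1e-9
             else is.na(cand$np_ratio) |
                  abs(cand$weight_ratio - lead$weight_ratio) < 1e-9
  is_lead <- same_lipids & d < 1e-9 & same_np
  zones <- list(
    composition = same_lipids & d > 1e-9 & d <= radius & same_np,
    substitution = !same_lipids & d <= radius & same_np)
  zones$parameter <- if (mode == "lipid") {
    same_lipids & d < 1e-9 & !same_np
  } else {
    lead_il <- parse_components(lead)$ids[[1]][
      catalogue$component_class[match(parse_components(lead)$ids[[1]],
                                      catalogue$id)] == "ionizable"]
    n_il <- vapply(parse_components(cand)$ids, function(ids)
      sum(catalogue$component_class[match(ids, catalogue$id)] == "ionizable"),
      0L)
    n_il >= 2 & vapply(parse_components(cand)$ids, function(ids)
      lead_il[1] %in% ids, TRUE) & !is_lead
  }
  out <- list()
  for (z in names(zones)) {
    idx <- which(zones[[z]] & !is_lead)
    if (!length(idx)) {
      warn_fc("lead-optimization zone '%s' is empty", z)
      next
    }
    pred <- predict(ensemble, cand[idx, , drop = FALSE], task = task,
                    catalogue = catalogue)
    best <- idx[order(-pred$ensemble, idx)[1]]
    row <- cand[best, , drop = FALSE]
    row$zone <- z
    row$ensemble <- max(pred$ensemble)
    out[[z]] <- row
  }
  do.call(rbind, out)
}
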