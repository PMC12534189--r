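# The scoring network: configuration, parameter layout, initialization and
# the forward pass. Training lives in train.R.

#' Scoring-network configuration
#'
#' Architecture of the set-transformer scoring function. Each formulation
#' is a set of tokens -- one 256-d token per component (molecular embedding
#' + Gaussian molar-percentage embedding + class embedding, projected by a
#' two-layer MLP), an N/P token from a 256-d Gaussian basis layer, a phase
#' token from a categorical embedding, and one learned CLS token per task.
#' Pre-LayerNorm transformer blocks aggregate the set; a per-task two-layer
#' MLP head reads the task's CLS state out to a scalar score. There is no
#' positional encoding, making the score invariant to component order.
#'
#' @param tasks Character vector of task identifiers (one CLS token and
#'   prediction head each).
#' @param d_token Token width (divisible by `n_heads`).
#' @param n_blocks Number of transformer blocks. The default (2) is sized
#'   for CPU-scale training; see the methods vignette.
#' @param n_heads Attention heads.
#' @param mlp_hidden Width of each block's feed-forward hidden layer.
#' @param head_hidden Hidden width of the prediction heads.
#' @param d_mol Molecular embedding dimension (must match the encoder).
#' @param d_comp Gaussian basis size for molar percentages.
#' @param d_type Component-class embedding dimension.
#' @param phase_levels Closed vocabulary of aqueous/organic categories.
#' @param class_levels Component classes the model accepts.
#' @param molar_range Range over which the molar-percentage Gaussian means
#'   are initialized (percent scale).
#' @param np_range Range over which the N/P Gaussian means are initialized.
#' @param encoder Molecular encoder name.
#' @param seed Seed for weight initialization.
#' @return A `comet_config` list.
#' @export
comet_config <- function(tasks, d_token = 256L, n_blocks = 2L, n_heads = 8L,
                         mlp_hidden = 512L, head_hidden = 128L,
                         d_mol = 512L, d_comp = 128L, d_type = 128L,
                         phase_levels = c("3:1", "1:1"),
                         class_levels = component_classes(),
                         molar_range = c(0, 100), np_range = c(0, 60),
                         encoder = "ecfp512", seed = 1L) {
  stopifnot(length(tasks) >= 1, d_token %% n_heads == 0)
  cfg <- list(tasks = as.character(tasks), d_token = as.integer(d_token),
              n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
              mlp_hidden = as.integer(mlp_hidden),
              head_hidden = as.integer(head_hidden),
              d_mol = as.integer(d_mol), d_comp = as.integer(d_comp),
              d_type = as.integer(d_type),
              n_types = length(class_levels),
              n_phases = length(phase_levels),
              n_tasks = length(tasks),
              phase_levels = phase_levels, class_levels = class_levels,
              molar_range = molar_range, np_range = np_range,
              encoder = encoder, seed = as.integer(seed))
  class(cfg) <- "comet_config"
  cfg
}

#' Flat parameter layout
#'
#' All network weights live in one flat numeric vector. This function
#' computes the 0-based offset of every weight tensor, shared between the R
#' initializer and the compiled core.
#'
#' @param cfg A [comet_config()].
#' @return List of offsets, with `n_par` giving the total parameter count.
#' @export
comet_param_layout <- function(cfg) {
  off <- 0L
  take <- function(n) { o <- off; off <<- off + as.integer(n); o }
  d <- cfg$d_token
  lay <- list(
    gc_mu = take(cfg$d_comp), gc_ls = take(cfg$d_comp),
    gn_mu = take(d), gn_ls = take(d),
    type_emb = take(cfg$d_type * cfg$n_types),
    phase_emb = take(d * cfg$n_phases),
    c_W1 = take((cfg$d_mol + cfg$d_comp + cfg$d_type) * d),
    c_b1 = take(d), c_W2 = take(d * d), c_b2 = take(d))
  lay$blocks <- lapply(seq_len(cfg$n_blocks), function(b) list(
    ln1_g = take(d), ln1_b = take(d),
    Wq = take(d * d), bq = take(d), Wk = take(d * d), bk = take(d),
    Wv = take(d * d), bv = take(d), Wo = take(d * d), bo = take(d),
    ln2_g = take(d), ln2_b = take(d),
    Wm1 = take(d * cfg$mlp_hidden), bm1 = take(cfg$mlp_hidden),
    Wm2 = take(cfg$mlp_hidden * d), bm2 = take(d)))
  lay$lnf_g <- take(d); lay$lnf_b <- take(d)
  lay$tasks <- lapply(seq_len(cfg$n_tasks), function(t) list(
    cls = take(d), hW1 = take(d * cfg$head_hidden),
    hb1 = take(cfg$head_hidden), hW2 = take(cfg$head_hidden),
    hb2 = take(1)))
  lay$n_par <- off
  lay
}

# fill a (rows x cols) weight block with scaled gaussian init
fill_mat <- function(theta, off, rows, cols, scale = sqrt(2 / (rows + cols))) {
  theta[off + seq_len(rows * cols)] <- rnorm(rows * cols, sd = scale)
  theta
}

#' Initialize an untrained scoring model
#'
#' Weights are drawn reproducibly from `cfg$seed`: Gaussian-basis means
#' evenly spaced over their feature range with widths equal to the grid
#' spacing (both learnable thereafter), variance-scaled random projection
#' weights, unit layer-norm gains, zero biases.
#'
#' @param cfg A [comet_config()].
#' @return A `comet_model` (untrained).
#' @export
comet_init <- function(cfg) {
  lay <- comet_param_layout(cfg)
  set.seed(cfg$seed)
  th <- numeric(lay$n_par)
  d <- cfg$d_token
  seq_range <- function(r, n) seq(r[1], r[2], length.out = n)
  # gaussian banks: means on an even grid, widths = grid spacing
  th[lay$gc_mu + seq_len(cfg$d_comp)] <- seq_range(cfg$molar_range, cfg$d_comp)
  th[lay$gc_ls + seq_len(cfg$d_comp)] <- log(diff(cfg$molar_range) / (cfg$d_comp - 1))
  th[lay$gn_mu + seq_len(d)] <- seq_range(cfg$np_range, d)
  th[lay$gn_ls + seq_len(d)] <- log(diff(cfg$np_range) / (d - 1))
  th <- fill_mat(th, lay$type_emb, cfg$d_type, cfg$n_types, 0.02)
  th <- fill_mat(th, lay$phase_emb, d, cfg$n_phases, 0.02)
  d_in <- cfg$d_mol + cfg$d_comp + cfg$d_type
  th <- fill_mat(th, lay$c_W1, d_in, d)
  th <- fill_mat(th, lay$c_W2, d, d)
  for (b in lay$blocks) {
    th[b$ln1_g + seq_len(d)] <- 1; th[b$ln2_g + seq_len(d)] <- 1
    for (w in c("Wq", "Wk", "Wv", "Wo")) th <- fill_mat(th, b[[w]], d, d)
    th <- fill_mat(th, b$Wm1, d, cfg$mlp_hidden)
    th <- fill_mat(th, b$Wm2, cfg$mlp_hidden, d)
  }
  th[lay$lnf_g + seq_len(d)] <- 1
  for (t in lay$tasks) {
    th[t$cls + seq_len(d)] <- rnorm(d, sd = 0.02)
    th <- fill_mat(th, t$hW1, d, cfg$head_hidden)
    th <- fill_mat(th, t$hW2, cfg$head_hidden, 1)
  }
  structure(list(theta = th, config = cfg, layout = lay,
                 trained = FALSE, history = NULL),
            class = "comet_model")
}

task_index <- function(model, task) {
  i <- match(task, model$config$tasks)
  if (is.na(i)) stop_fc("unknown task: %s (model tasks: %s)", task,
                        paste(model$config$tasks, collapse = ", "))
  as.integer(i - 1L)
}

as_tokens <- function(x, model, catalogue = NULL) {
  if (inherits(x, "comet_tokens")) return(x)
  if (is.null(catalogue)) stop_fc("catalogue required to tokenize formulations")
  tokenize_formulations(x, catalogue,
                        phase_levels = model$config$phase_levels,
                        encoder = model$config$encoder,
                        class_levels = model$config$class_levels)
}

cfg_for_cpp <- function(cfg) {
  cfg[c("d_mol", "d_comp", "d_type", "d_token", "n_types", "n_phases",
        "n_tasks", "n_blocks", "n_heads", "mlp_hidden", "head_hidden")]
}

#' Score formulations
#'
#' Runs the forward pass and returns one scalar score per formulation for
#' the requested task. Scores are relative efficacy scores (trained by
#' ranking): higher means predicted-better. `forward_batch()` is the
#' batched identity of `forward_score()`; both accept a formulation table
#' (plus catalogue) or a pre-tokenized `comet_tokens` batch.
#'
#' @param model A `comet_model`.
#' @param x Formulation table or `comet_tokens`.
#' @param task Task identifier; defaults to the model's first task.
#' @param catalogue Catalogue, required when `x` is a table.
#' @return Numeric score vector.
#' @export
forward_batch <- function(model, x, task = model$config$tasks[1],
                          catalogue = NULL) {
  tok <- as_tokens(x, model, catalogue)
  if (!n_tokens(tok)) stop_fc("empty formulation batch")
  out <- cpp_comet_scores(model$theta, cfg_for_cpp(model$config),
                          model$layout, tok$FP, tok$molar, tok$type,
                          tok$ncomp, tok$np, tok$phase,
                          task_index(model, task), FALSE)
  setNames(out$scores, tok$ids)
}

#' @rdname forward_batch
#' @export
forward_score <- forward_batch

#' Extract CLS representations
#'
#' Returns the task's CLS token state after the final layer norm -- the
#' vector the prediction head reads -- for each formulation. Useful for
#' embedding visualization (e.g. t-SNE).
#'
#' @inheritParams forward_batch
#' @return Matrix `n x d_token` with formulation ids as row names.
#' @export
extract_cls_representation <- function(model, x,
                                       task = model$config$tasks[1],
                                       catalogue = NULL) {
  tok <- as_tokens(x, model, catalogue)
  out <- cpp_comet_scores(model$theta, cfg_for_cpp(model$config),
                          model$layout, tok$FP, tok$molar, tok$type,
                          tok$ncomp, tok$np, tok$phase,
                          task_index(model, task), TRUE)
  rownames(out$cls) <- tok$ids
  out$cls
}

#' @export
predict.comet_model <- function(object, newdata,
                                task = object$config$tasks[1],
                                catalogue = NULL, ...) {
  forward_batch(object, newdata, task = task, catalogue = catalogue)
}

#' @export
print.comet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Set-transformer formulation scorer (%s)\n",
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  tasks: %s\n", paste(cfg$tasks, collapse = ", ")))
  cat(sprintf("  %d blocks x %d heads, d_token %d, %s parameters\n",
              cfg$n_blocks, cfg$n_heads, cfg$d_token,
              format(x$layout$n_par, big.mark = ",")))
  if (!is.null(x$history)) {
    best <- max(x$history$val_spearman, na.rm = TRUE)
    cat(sprintf("  %d epochs trained, best validation Spearman %.3f\n",
                nrow(x$history), best))
  }
  invisible(x)
}

#' @export
summary.comet_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}
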