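# Training: pairwise ranking objective with label margin, molar-noise
# augmentation, conflict-averse multitask gradient combination, Adam.

#' Training configuration
#'
#' @param batch_size Formulations per batch (all pairs within a batch are
#'   ranked: a batch of 64 yields 2,016 pairwise comparisons).
#' @param lambda_margin Label-margin coefficient of the ranking loss.
#' @param noise_sd_fraction Molar-noise augmentation: each molar percentage
#'   m is perturbed by Gaussian noise with standard deviation
#'   `noise_sd_fraction * m` during training.
#' @param cagrad_c Conflict-averse gradient coefficient (trust-ball radius
#'   as a fraction of the average-gradient norm).
#' @param objective `"ranking"` (default) or `"regression"` (ablation arm:
#'   squared error on the label).
#' @param lr,beta1,beta2,adam_eps Adam optimizer parameters.
#' @param max_epochs,patience Early stopping on validation Spearman.
#' @param val_fraction Fraction held out for validation when no explicit
#'   split is given.
#' @param seed Seed for batching, noise and the validation split.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64L, lambda_margin = 0.01,
                         noise_sd_fraction = 0.10, cagrad_c = 0.2,
                         objective = c("ranking", "regression"),
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, max_epochs = 40L, patience = 8L,
                         val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 2, lr > 0, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 lambda_margin = lambda_margin,
                 noise_sd_fraction = noise_sd_fraction,
                 cagrad_c = cagrad_c, objective = match.arg(objective),
                 lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' All ranked pairs within a labelled batch
#'
#' Every unordered pair of batch members is ordered by label into a
#' (higher, lower) pair; exact label ties are excluded. A batch of 64
#' distinct labels yields choose(64, 2) = 2,016 pairs.
#'
#' @param y Numeric label vector (length >= 2).
#' @return List with integer vectors `h`, `l` (indices into `y`) and the
#'   label gaps `dy = y[h] - y[l] > 0`.
#' @export
make_pairs <- function(y) {
  n <- length(y)
  if (n < 2) stop_fc("need at least 2 labelled formulations")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  keep <- y[a] != y[b]
  a <- a[keep]; b <- b[keep]
  swap <- y[a] < y[b]
  h <- ifelse(swap, b, a); l <- ifelse(swap, a, b)
  list(h = as.integer(h), l = as.integer(l), dy = y[h] - y[l])
}

#' Pairwise ranking loss with label margin
#'
#' `-log sigmoid(s_h - s_l - lambda_margin * (y_h - y_l))`: the model is
#' pushed to score the empirically better formulation higher, by a margin
#' proportional to the label gap. With `lambda_margin = 0` this reduces to
#' the plain binary ranking objective. Numerically stabilized; at zero
#' score gap and zero margin the loss is `log(2)`.
#'
#' @param s_h,s_l Scores of the higher- and lower-labelled formulation.
#' @param y_h,y_l Their labels.
#' @param lambda_margin Margin coefficient.
#' @return Mean loss over the supplied pairs (non-negative for correct
#'   orderings).
#' @export
ranking_loss <- function(s_h, s_l, y_h = 1, y_l = 0, lambda_margin = 0.01) {
  m <- s_h - s_l - lambda_margin * (y_h - y_l)
  mean(pmax(-m, 0) + log1p(exp(-abs(m))))
}

#' Squared-error regression loss
#'
#' The regression ablation objective: mean squared difference between the
#' score and the label.
#'
#' @param s Scores.
#' @param y Labels.
#' @return Mean squared error.
#' @export
regression_loss <- function(s, y) mean((s - y)^2)

#' Molar-percentage noise augmentation
#'
#' Perturbs each molar percentage m with Gaussian noise of standard
#' deviation `fraction * m`, clipped at zero. The composition is
#' deliberately not renormalized and labels are untouched; this emulates
#' fluid-handling noise during training. A component at 0% stays at 0.
#'
#' @param molar Numeric vector of molar percentages.
#' @param fraction Noise standard deviation as a fraction of each value.
#' @return Perturbed vector.
#' @export
augment_molar_noise <- function(molar, fraction = 0.10) {
  if (fraction == 0) return(molar)
  pmax(0, molar + rnorm(length(molar), sd = fraction * molar))
}

#' Conflict-averse combination of task gradients
#'
#' Combines per-task gradients into a single update direction that
#' maximizes the worst-case task improvement within a ball of radius
#' `c * ||g0||` around the average gradient `g0`. The inner problem is
#' solved in its dual form: minimize `g_w' g0 + sqrt(phi) ||g_w||` over
#' convex weights w (phi = c^2 ||g0||^2), giving the direction
#' `d = g0 + sqrt(phi) / ||g_w*|| * g_w*`, rescaled by 1/(1+c) so that
#' identical task gradients return that gradient unchanged. With `c = 0`
#' or a single task the average gradient is returned.
#'
#' @param G Matrix with one column per task gradient (equal lengths).
#' @param c Trust-ball coefficient (>= 0).
#' @return The combined update direction (numeric vector).
#' @export
cagrad_combine <- function(G, c = 0.2) {
  if (is.list(G)) G <- do.call(cbind, G)
  K <- ncol(G)
  g0 <- rowMeans(G)
  if (K == 1 || c == 0) return(g0)
  GtG <- crossprod(G)            # K x K; everything below is O(K^2)
  Gg0 <- as.numeric(crossprod(G, g0))
  phi <- c^2 * sum(g0^2)
  obj <- function(z) {           # softmax-parameterized simplex weights
    w <- exp(z - max(z)); w <- w / sum(w)
    gw_norm <- sqrt(max(as.numeric(t(w) %*% GtG %*% w), 0))
    sum(w * Gg0) + sqrt(phi) * gw_norm
  }
  fit <- optim(rep(0, K), obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  w <- exp(fit$par - max(fit$par)); w <- w / sum(w)
  gw <- as.numeric(G %*% w)
  gw_norm <- sqrt(sum(gw^2))
  d <- if (gw_norm < 1e-12) g0 else g0 + sqrt(phi) / gw_norm * gw
  d / (1 + c)
}

#' Assemble a training dataset
#'
#' Validates and tokenizes a labelled formulation table once, so training
#' and scoring reuse cached molecular fingerprints.
#'
#' @param formulations Formulation table with `label:<task>` columns.
#' @param catalogue A `comet_catalogue`.
#' @param config A [comet_config()] (controls phase vocabulary and encoder).
#' @return A `comet_data` list with `tokens`, `labels`, `catalogue`.
#' @export
comet_data <- function(formulations, catalogue, config) {
  formulations <- validate_formulations(formulations, catalogue)
  tokens <- tokenize_formulations(formulations, catalogue,
                                  phase_levels = config$phase_levels,
                                  encoder = config$encoder,
                                  class_levels = config$class_levels)
  structure(list(tokens = tokens, labels = tokens$labels,
                 catalogue = catalogue, formulations = formulations),
            class = "comet_data")
}

#' @export
print.comet_data <- function(x, ...) {
  cat(sprintf("Training data: %d formulations, tasks: %s\n",
              n_tokens(x$tokens),
              paste(names(x$labels), collapse = ", ")))
  invisible(x)
}

rank_grad_batch <- function(model, tok, idx, y, tc, task_i) {
  bt <- subset_tokens(tok, idx)
  if (tc$noise_sd_fraction > 0)
    bt$molar <- augment_molar_noise(bt$molar, tc$noise_sd_fraction)
  grad <- numeric(model$layout$n_par)
  res <- if (tc$objective == "ranking") {
    pr <- make_pairs(y[idx])
    if (!length(pr$h)) return(NULL) # all ties
    cpp_comet_rank_grad(model$theta, grad, cfg_for_cpp(model$config),
                        model$layout, bt$FP, bt$molar, bt$type, bt$ncomp,
                        bt$np, bt$phase, task_i,
                        pr$h - 1L, pr$l - 1L, pr$dy, tc$lambda_margin)
  } else {
    cpp_comet_reg_grad(model$theta, grad, cfg_for_cpp(model$config),
                       model$layout, bt$FP, bt$molar, bt$type, bt$ncomp,
                       bt$np, bt$phase, task_i, y[idx])
  }
  list(loss = res$loss, grad = grad)
}

#' Fit the scoring model
#'
#' Trains the set-transformer by stochastic gradient steps: per step, one
#' batch per task is sampled from that task's labelled formulations, molar
#' noise is applied, the all-pairs ranking loss (or the regression
#' ablation) and its gradient are computed, per-task gradients are
#' combined conflict-aversely, and an Adam update is taken. Early stopping
#' restores the weights with the best mean validation Spearman.
#'
#' @param data A [comet_data()] (or a formulation table, with `catalogue`).
#' @param config A [comet_config()]; its `tasks` must be labelled in the
#'   data.
#' @param train A [train_config()].
#' @param catalogue Catalogue when `data` is a table.
#' @param split Optional list with integer vectors `train` and `val`
#'   (indices into the data); defaults to a seeded random split.
#' @return A trained `comet_model` with a `history` data frame
#'   (epoch, per-task loss, validation Spearman).
#' @export
comet <- function(data, config, train = train_config(), catalogue = NULL,
                  split = NULL) {
  if (!inherits(data, "comet_data")) {
    data <- comet_data(data, catalogue, config)
  }
  tok <- data$tokens
  tasks <- config$tasks
  missing_tasks <- setdiff(tasks, names(data$labels))
  if (length(missing_tasks))
    stop_fc("no labels for task(s): %s", paste(missing_tasks, collapse = ", "))
  n <- n_tokens(tok)
  set.seed(train$seed)
  if (is.null(split)) {
    val <- sort(sample.int(n, max(1, round(train$val_fraction * n))))
    split <- list(train = setdiff(seq_len(n), val), val = val)
  }
  lab_idx <- lapply(tasks, function(t) {
    idx <- intersect(split$train, which(!is.na(data$labels[[t]])))
    if (length(unique(data$labels[[t]][idx])) < 2)
      stop_fc("task %s needs >= 2 distinct labels in the training split", t)
    idx
  })
  val_idx <- lapply(tasks, function(t)
    intersect(split$val, which(!is.na(data$labels[[t]]))))

  model <- comet_init(config)
  theta <- model$theta
  m1 <- numeric(length(theta)); m2 <- numeric(length(theta)); step <- 0L
  n_steps <- max(vapply(lab_idx, function(ix)
    ceiling(length(ix) / train$batch_size), 0))
  best <- -Inf; best_theta <- theta; best_epoch <- 0L; wait <- 0L
  hist <- vector("list", train$max_epochs)

  for (epoch in seq_len(train$max_epochs)) {
    order_t <- lapply(lab_idx, sample) # fresh shuffle per task per epoch
    losses <- setNames(numeric(length(tasks)), tasks)
    counts <- numeric(length(tasks))
    for (s in seq_len(n_steps)) {
      grads <- list(); ls <- c()
      for (ti in seq_along(tasks)) {
        ord <- order_t[[ti]]
        pos <- ((s - 1) * train$batch_size) %% length(ord)
        idx <- ord[(pos + seq_len(min(train$batch_size, length(ord))) - 1L) %%
                     length(ord) + 1L]
        model$theta <- theta
        g <- rank_grad_batch(model, tok, idx, data$labels[[tasks[ti]]],
                             train, ti - 1L)
        if (is.null(g)) next
        if (!is.finite(g$loss)) stop_fc("non-finite loss at epoch %d", epoch)
        grads[[length(grads) + 1L]] <- g$grad
        losses[ti] <- losses[ti] + g$loss; counts[ti] <- counts[ti] + 1
      }
      if (!length(grads)) next
      dvec <- if (length(grads) == 1) grads[[1]]
              else cagrad_combine(do.call(cbind, grads), train$cagrad_c)
      step <- step + 1L
      m1 <- train$beta1 * m1 + (1 - train$beta1) * dvec
      m2 <- train$beta2 * m2 + (1 - train$beta2) * dvec^2
      mh <- m1 / (1 - train$beta1^step)
      vh <- m2 / (1 - train$beta2^step)
      theta <- theta - train$lr * mh / (sqrt(vh) + train$adam_eps)
    }
    model$theta <- theta
    val_sp <- vapply(seq_along(tasks), function(ti) {
      vi <- val_idx[[ti]]
      if (length(vi) < 3) return(NA_real_)
      pred <- forward_batch(model, subset_tokens(tok, vi), task = tasks[ti])
      suppressWarnings(cor(pred, data$labels[[tasks[ti]]][vi],
                           method = "spearman"))
    }, 0)
    mean_sp <- mean(val_sp, na.rm = TRUE)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                t(losses / pmax(counts, 1)),
                                val_spearman = mean_sp)
    if (train$verbose)
      message(sprintf("epoch %d: loss %s, val spearman %.3f", epoch,
                      paste(sprintf("%.4f", losses / pmax(counts, 1)),
                            collapse = "/"), mean_sp))
    if (is.finite(mean_sp) && mean_sp > best) {
      best <- mean_sp; best_theta <- theta; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train$patience) break
    }
  }
  model$theta <- best_theta
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$best_epoch <- best_epoch
  model$split <- split
  model$train_config <- train
  model
}
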