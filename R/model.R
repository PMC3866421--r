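#' Configure a dual-memory model
#'
#' The model comprises two three-layer auto-encoders sharing the same input:
#' a fast-learning hippocampal component and a slow-learning cortical
#' component. Their hidden layers are joined by trainable cross-connections
#' through which activation flows until it settles; optional label (task)
#' units read out from the cortical hidden layer. Each hidden layer must be
#' narrower than the input so that the auto-encoders are forced through a
#' bottleneck.
#'
#' @param n_input Input (and output) dimensionality; must match the stimulus
#'   feature count (default 18).
#' @param n_hidden_hip,n_hidden_cor Hidden-layer sizes (default 15 each);
#'   each must be smaller than `n_input`.
#' @param lr_hip,lr_cor Learning rates of the two components (defaults 0.02
#'   and 0.01). The hippocampal rate must be at least the cortical rate;
#'   the asymmetry is the model's core assumption. Task weights learn at
#'   the cortical rate; cross-connections follow `cross_lr`.
#' @param n_task Number of label units (0 = no task layer; 26 for
#'   basic-level labels, 4 for global-level labels).
#' @param init_range Weights are initialized uniformly in
#'   `[-init_range, init_range]` (default 0.5).
#' @param settle_tol Settling stops when the largest absolute change of any
#'   hidden activation falls below this tolerance (default 1e-4).
#' @param settle_max_iter Maximum settling iterations (default 50).
#' @param settle_damping Damping factor in `[0, 1)` mixed into each settling
#'   update (0 = plain synchronous iteration, the default).
#' @param cross_lr How the two cross-connection blocks learn:
#'   `"recipient"` (default) updates each block at the learning rate of the
#'   component whose hidden layer it feeds, so the fast hippocampal system
#'   also binds quickly to the cortical representations it receives;
#'   `"cortical"` updates both blocks at the slow cortical rate.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_input = 18,
                         n_hidden_hip = 15,
                         n_hidden_cor = 15,
                         lr_hip = 0.02,
                         lr_cor = 0.01,
                         n_task = 0,
                         init_range = 0.5,
                         settle_tol = 1e-4,
                         settle_max_iter = 50,
                         settle_damping = 0,
                         cross_lr = c("recipient", "cortical")) {
  cross_lr <- match.arg(cross_lr)
  cfg <- list(
    n_input = check_count(n_input, "n_input", min = 2L),
    n_hidden_hip = check_count(n_hidden_hip, "n_hidden_hip"),
    n_hidden_cor = check_count(n_hidden_cor, "n_hidden_cor"),
    lr_hip = check_number(lr_hip, "lr_hip", min = 0),
    lr_cor = check_number(lr_cor, "lr_cor", min = 0),
    n_task = check_count(n_task, "n_task", min = 0L),
    init_range = check_number(init_range, "init_range", min = 0),
    settle_tol = check_number(settle_tol, "settle_tol", min = 0),
    settle_max_iter = check_count(settle_max_iter, "settle_max_iter"),
    settle_damping = check_number(settle_damping, "settle_damping", min = 0, max = 1 - 1e-12),
    cross_lr = cross_lr
  )
  if (cfg$n_hidden_hip >= cfg$n_input || cfg$n_hidden_cor >= cfg$n_input)
    stop_config("hidden layers must be smaller than the input layer (auto-encoder bottleneck)")
  if (cfg$lr_hip < cfg$lr_cor)
    stop_config("the hippocampal learning rate must not be below the cortical rate")
  structure(cfg, class = "model_config")
}

#' Initialize a dual-memory model
#'
#' All weights and biases are drawn uniformly in
#' `[-init_range, init_range]`, reproducibly per seed. Weight blocks are
#' drawn in a fixed order with the task block last, so two models that
#' differ only in `n_task` share identical auto-encoder and cross-connection
#' weights for the same seed — the basis of the paired experimental designs.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `dual_memory_model`.
#' @export
#' @examples
#' m <- init_model(model_config(), seed = 1)
#' dim(m$cortical$W_in)  # 15 x 18
init_model <- function(config = model_config(), seed = 1L) {
  if (!inherits(config, "model_config"))
    stop_config("config must be created with model_config()")
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  r <- config$init_range
  ni <- config$n_input; nh <- config$n_hidden_hip; nc <- config$n_hidden_cor
  draw <- function(nr, ncol) matrix(stats::runif(nr * ncol, -r, r), nr, ncol)
  model <- with_local_seed(seed, {
    hip <- list(W_in = draw(nh, ni), b_h = stats::runif(nh, -r, r),
                W_out = draw(ni, nh), b_o = stats::runif(ni, -r, r),
                n_hidden = nh, learning_rate = config$lr_hip)
    cor <- list(W_in = draw(nc, ni), b_h = stats::runif(nc, -r, r),
                W_out = draw(ni, nc), b_o = stats::runif(ni, -r, r),
                n_hidden = nc, learning_rate = config$lr_cor)
    W_hc <- draw(nc, nh)  # hippocampal hidden -> cortical hidden
    W_ch <- draw(nh, nc)  # cortical hidden -> hippocampal hidden
    if (config$n_task > 0L) {
      W_task <- draw(config$n_task, nc)
      b_task <- stats::runif(config$n_task, -r, r)
    } else {
      W_task <- NULL; b_task <- NULL
    }
    list(hippocampal = hip, cortical = cor, W_hc = W_hc, W_ch = W_ch,
         W_task = W_task, b_task = b_task)
  })
  model$n_task <- config$n_task
  model$settle_tol <- config$settle_tol
  model$settle_max_iter <- config$settle_max_iter
  model$settle_damping <- config$settle_damping
  model$config <- config
  model$seed <- seed
  class(model) <- "dual_memory_model"
  model
}

#' @export
print.dual_memory_model <- function(x, ...) {
  cat(sprintf(
    "Dual-memory model: input %d | hippocampal hidden %d (lr %g) | cortical hidden %d (lr %g) | task units %d\n",
    x$config$n_input, x$hippocampal$n_hidden, x$hippocampal$learning_rate,
    x$cortical$n_hidden, x$cortical$learning_rate, x$n_task))
  invisible(x)
}

# ---------------------------------------------------------------------------
# fast internal core: the model's weights in an environment, so that training
# loops avoid repeated list copying

model_env <- function(model) {
  e <- new.env(parent = emptyenv())
  e$W1h <- model$hippocampal$W_in;  e$b1h <- model$hippocampal$b_h
  e$W2h <- model$hippocampal$W_out; e$b2h <- model$hippocampal$b_o
  e$W1c <- model$cortical$W_in;     e$b1c <- model$cortical$b_h
  e$W2c <- model$cortical$W_out;    e$b2c <- model$cortical$b_o
  e$Whc <- model$W_hc; e$Wch <- model$W_ch
  e$Wt <- model$W_task; e$bt <- model$b_task
  e$lrh <- model$hippocampal$learning_rate
  e$lrc <- model$cortical$learning_rate
  if (identical(model$config$cross_lr, "recipient")) {
    e$lr_ch <- e$lrh; e$lr_hc <- e$lrc
  } else {
    e$lr_ch <- e$lrc; e$lr_hc <- e$lrc
  }
  e$n_task <- model$n_task
  e$tol <- model$settle_tol
  e$max_iter <- model$settle_max_iter
  e$damp <- model$settle_damping
  e
}

env_to_model <- function(e, model) {
  model$hippocampal$W_in <- e$W1h;  model$hippocampal$b_h <- e$b1h
  model$hippocampal$W_out <- e$W2h; model$hippocampal$b_o <- e$b2h
  model$cortical$W_in <- e$W1c;     model$cortical$b_h <- e$b1c
  model$cortical$W_out <- e$W2c;    model$cortical$b_o <- e$b2c
  model$W_hc <- e$Whc; model$W_ch <- e$Wch
  # assignment via [ keeps the slot present when the task block is NULL
  model["W_task"] <- list(e$Wt); model["b_task"] <- list(e$bt)
  model
}

# Settle the two hidden layers: input drive held fixed, cross input from the
# other component's current hidden state, synchronous logistic updates until
# the largest absolute change drops below tol.
settle_env <- function(e, x) {
  ah <- drop(e$W1h %*% x) + e$b1h
  ac <- drop(e$W1c %*% x) + e$b1c
  hh <- logistic(ah); hc <- logistic(ac)
  converged <- FALSE; iters <- 0L
  d <- e$damp
  for (i in seq_len(e$max_iter)) {
    nh <- logistic(ah + drop(e$Wch %*% hc))
    nc <- logistic(ac + drop(e$Whc %*% hh))
    if (d > 0) { nh <- (1 - d) * nh + d * hh; nc <- (1 - d) * nc + d * hc }
    delta <- max(max(abs(nh - hh)), max(abs(nc - hc)))
    hh <- nh; hc <- nc; iters <- i
    if (delta < e$tol) { converged <- TRUE; break }
  }
  list(h_hip = hh, h_cor = hc, settle_iters = iters, converged = converged)
}

forward_env <- function(e, x) {
  s <- settle_env(e, x)
  o_hip <- logistic(drop(e$W2h %*% s$h_hip) + e$b2h)
  o_cor <- logistic(drop(e$W2c %*% s$h_cor) + e$b2c)
  o_task <- if (e$n_task > 0L) logistic(drop(e$Wt %*% s$h_cor) + e$bt) else NULL
  list(h_hip = s$h_hip, h_cor = s$h_cor, o_hip = o_hip, o_cor = o_cor,
       o_task = o_task, settle_iters = s$settle_iters, converged = s$converged)
}

# Gradients of the summed squared error at the settled state. The settled
# hidden activations are treated as an ordinary feed-forward hidden layer
# (the last settling step is the linearization point; no backpropagation
# through the settling iterations).
grads_env <- function(e, x, label_index, acts) {
  hh <- acts$h_hip; hc <- acts$h_cor
  d_oh <- 2 * (acts$o_hip - x) * acts$o_hip * (1 - acts$o_hip)
  d_oc <- 2 * (acts$o_cor - x) * acts$o_cor * (1 - acts$o_cor)
  d_hh_in <- drop(crossprod(e$W2h, d_oh))
  d_hc_in <- drop(crossprod(e$W2c, d_oc))
  g <- list()
  if (!is.null(label_index)) {
    target <- numeric(e$n_task); target[label_index] <- 1
    d_ot <- 2 * (acts$o_task - target) * acts$o_task * (1 - acts$o_task)
    d_hc_in <- d_hc_in + drop(crossprod(e$Wt, d_ot))
    g$W_task <- tcrossprod(d_ot, hc); g$b_task <- d_ot
  }
  d_hh <- d_hh_in * hh * (1 - hh)
  d_hc <- d_hc_in * hc * (1 - hc)
  g$hip_W_out <- tcrossprod(d_oh, hh); g$hip_b_o <- d_oh
  g$cor_W_out <- tcrossprod(d_oc, hc); g$cor_b_o <- d_oc
  g$hip_W_in <- tcrossprod(d_hh, x);   g$hip_b_h <- d_hh
  g$cor_W_in <- tcrossprod(d_hc, x);   g$cor_b_h <- d_hc
  g$W_ch <- tcrossprod(d_hh, hc)       # into hippocampal hidden
  g$W_hc <- tcrossprod(d_hc, hh)       # into cortical hidden
  g
}

step_env <- function(e, x, label_index = NULL) {
  acts <- forward_env(e, x)
  g <- grads_env(e, x, label_index, acts)
  lrh <- e$lrh; lrc <- e$lrc
  e$W2h <- e$W2h - lrh * g$hip_W_out; e$b2h <- e$b2h - lrh * g$hip_b_o
  e$W1h <- e$W1h - lrh * g$hip_W_in;  e$b1h <- e$b1h - lrh * g$hip_b_h
  e$W2c <- e$W2c - lrc * g$cor_W_out; e$b2c <- e$b2c - lrc * g$cor_b_o
  e$W1c <- e$W1c - lrc * g$cor_W_in;  e$b1c <- e$b1c - lrc * g$cor_b_h
  e$Wch <- e$Wch - e$lr_ch * g$W_ch;  e$Whc <- e$Whc - e$lr_hc * g$W_hc
  if (!is.null(label_index)) {
    e$Wt <- e$Wt - lrc * g$W_task; e$bt <- e$bt - lrc * g$b_task
  }
  list(hip_error = sum((acts$o_hip - x)^2),
       cor_error = sum((acts$o_cor - x)^2),
       settle_iters = acts$settle_iters,
       converged = acts$converged)
}

check_features <- function(model, features) {
  if (!is.numeric(features) || length(features) != model$config$n_input)
    stop_config("features must be a numeric vector of length %d", model$config$n_input)
  as.numeric(features)
}

# ---------------------------------------------------------------------------
# public operations

#' Run a stimulus through the model to a settled state
#'
#' The input drives both components' hidden layers; the hidden layers then
#' exchange activation through the cross-connections, with the input drive
#' held fixed, until no activation changes by more than `settle_tol` (or
#' `settle_max_iter` is reached, in which case the result is flagged
#' unconverged rather than raising an error). Outputs and task activations
#' are computed once from the settled hidden states. No weights change.
#'
#' @param model A `dual_memory_model`.
#' @param features Numeric input vector of length `n_input`.
#' @return A list of class `dualmem_activations`: `h_hip`, `h_cor` (settled
#'   hidden states), `o_hip`, `o_cor` (reconstructions), `o_task` (label
#'   activations or `NULL`), `settle_iters`, `converged`.
#' @export
forward_settle <- function(model, features) {
  x <- check_features(model, features)
  acts <- forward_env(model_env(model), x)
  class(acts) <- "dualmem_activations"
  acts
}

#' Model looking time for a stimulus
#'
#' The model's linking hypothesis to infant looking times: the hippocampal
#' component's reconstruction error — the sum over output units of the
#' squared difference between output and input. The worse the
#' reconstruction, the more novel the stimulus and the longer the simulated
#' look.
#'
#' @inheritParams forward_settle
#' @return Non-negative scalar.
#' @export
looking_time <- function(model, features) {
  x <- check_features(model, features)
  acts <- forward_env(model_env(model), x)
  sum((acts$o_hip - x)^2)
}

#' One online training step
#'
#' Runs [forward_settle()], compares outputs with their targets (the input
#' for both reconstruction layers; a one-hot vector at `label_index` for the
#' task layer when a label is shown), and applies one backpropagation update
#' of the summed squared error. Each component's weights move at its own
#' learning rate; each cross-connection block moves at the rate set by the
#' config's `cross_lr` rule, and task weights move at the cortical rate.
#' When no label is shown, the task weights are left untouched.
#'
#' @inheritParams forward_settle
#' @param label_index 1-based index of the label unit to clamp as target, or
#'   `NULL` for an unlabeled presentation.
#' @return A list with `model` (the updated model) and `record` (hippocampal
#'   and cortical reconstruction errors measured before the update, settling
#'   iteration count, convergence flag, and the label shown).
#' @export
train_step <- function(model, features, label_index = NULL) {
  x <- check_features(model, features)
  if (!is.null(label_index)) {
    if (model$n_task == 0L)
      stop_config("label_index given but the model has no task units")
    label_index <- check_count(label_index, "label_index")
    if (label_index > model$n_task)
      stop_config("label_index %d exceeds n_task = %d", label_index, model$n_task)
  }
  e <- model_env(model)
  rec <- step_env(e, x, label_index)
  rec$label_index <- label_index
  list(model = env_to_model(e, model), record = rec)
}

#' Gradients of the summed squared error at the settled state
#'
#' Exposes the exact gradients that [train_step()] applies, for inspection
#' and verification. The settled hidden activations are treated as a
#' feed-forward hidden layer: each cross-connection block receives the
#' gradient of the final settling step only, with the other component's
#' settled state held fixed (no backpropagation through the settling
#' iterations).
#'
#' @inheritParams train_step
#' @return A list with `gradients` (one entry per weight block) and
#'   `activations` (the settled forward pass).
#' @export
model_gradients <- function(model, features, label_index = NULL) {
  x <- check_features(model, features)
  if (!is.null(label_index) && model$n_task == 0L)
    stop_config("label_index given but the model has no task units")
  e <- model_env(model)
  acts <- forward_env(e, x)
  list(gradients = grads_env(e, x, label_index, acts), activations = acts)
}
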