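# Independent oracle implementations used to verify the package's numerics.
# These are written from the definitions and deliberately share no code with
# the package internals.

sigmoid_ref <- function(z) 1 / (1 + exp(-z))

# Objective of one training step's computational graph: each hidden layer is
# driven by the input plus cross input from the *other* component's settled
# state, which is held fixed (the linearization point that backpropagation
# differentiates).
oracle_objective <- function(model, x, h_pre_hip, h_pre_cor, label_index = NULL) {
  hh <- sigmoid_ref(as.vector(model$hippocampal$W_in %*% x) +
                    model$hippocampal$b_h + as.vector(model$W_ch %*% h_pre_cor))
  hc <- sigmoid_ref(as.vector(model$cortical$W_in %*% x) +
                    model$cortical$b_h + as.vector(model$W_hc %*% h_pre_hip))
  oh <- sigmoid_ref(as.vector(model$hippocampal$W_out %*% hh) +
                    model$hippocampal$b_o)
  oc <- sigmoid_ref(as.vector(model$cortical$W_out %*% hc) +
                    model$cortical$b_o)
  err <- sum((oh - x)^2) + sum((oc - x)^2)
  if (!is.null(label_index)) {
    ot <- sigmoid_ref(as.vector(model$W_task %*% hc) + model$b_task)
    tt <- numeric(model$n_task); tt[label_index] <- 1
    err <- err + sum((ot - tt)^2)
  }
  err
}

# weight-block accessors keyed by the names model_gradients() uses
block_get <- function(model, name) {
  switch(name,
    hip_W_in = model$hippocampal$W_in, hip_b_h = model$hippocampal$b_h,
    hip_W_out = model$hippocampal$W_out, hip_b_o = model$hippocampal$b_o,
    cor_W_in = model$cortical$W_in, cor_b_h = model$cortical$b_h,
    cor_W_out = model$cortical$W_out, cor_b_o = model$cortical$b_o,
    W_hc = model$W_hc, W_ch = model$W_ch,
    W_task = model$W_task, b_task = model$b_task)
}

block_set <- function(model, name, value) {
  switch(name,
    hip_W_in = model$hippocampal$W_in <- value,
    hip_b_h = model$hippocampal$b_h <- value,
    hip_W_out = model$hippocampal$W_out <- value,
    hip_b_o = model$hippocampal$b_o <- value,
    cor_W_in = model$cortical$W_in <- value,
    cor_b_h = model$cortical$b_h <- value,
    cor_W_out = model$cortical$W_out <- value,
    cor_b_o = model$cortical$b_o <- value,
    W_hc = model$W_hc <- value, W_ch = model$W_ch <- value,
    W_task = model$W_task <- value, b_task = model$b_task <- value)
  model
}

# Central-difference gradient of oracle_objective for one weight block, with
# the linearization point (the unperturbed model's settled states) fixed.
numeric_block_gradient <- function(model, x, block, h_pre_hip, h_pre_cor,
                                   label_index = NULL, h = 1e-5) {
  w <- block_get(model, block)
  g <- w
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    fp <- oracle_objective(block_set(model, block, wp), x,
                           h_pre_hip, h_pre_cor, label_index)
    fm <- oracle_objective(block_set(model, block, wm), x,
                           h_pre_hip, h_pre_cor, label_index)
    g[i] <- (fp - fm) / (2 * h)
  }
  g
}

max_rel_gradient_error <- function(model, x, label_index = NULL) {
  out <- model_gradients(model, x, label_index)
  acts <- out$activations
  worst <- 0
  for (block in names(out$gradients)) {
    fd <- numeric_block_gradient(model, x, block, acts$h_hip, acts$h_cor,
                                 label_index)
    rel <- abs(out$gradients[[block]] - fd) / pmax(abs(fd), 1e-4)
    worst <- max(worst, max(rel))
  }
  worst
}

# silhouette width per the definitional formula (Euclidean); singleton
# clusters get width 0
silhouette_ref <- function(vectors, groups) {
  d <- as.matrix(stats::dist(vectors))
  groups <- as.character(groups)
  n <- nrow(vectors)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(groups == groups[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small random dual-memory model for gradient sweeps
random_small_model <- function(seed, with_task = TRUE) {
  set.seed(seed)
  n_in <- sample(3:5, 1)
  nh <- sample(1:min(3, n_in - 1), 1)
  nc <- sample(1:min(3, n_in - 1), 1)
  n_task <- if (with_task) sample(1:3, 1) else 0
  cfg <- model_config(n_input = n_in, n_hidden_hip = nh, n_hidden_cor = nc,
                      n_task = n_task, settle_tol = 1e-10,
                      settle_max_iter = 500)
  list(model = init_model(cfg, seed = seed),
       x = runif(n_in),
       label = if (n_task > 0) sample.int(n_task, 1) else NULL)
}

default_set_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_stimulus_set(stimulus_design(seed = 1))
    cache
  }
})
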