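test_that("initialization is reproducible and respects the bottleneck", {
  m1 <- init_model(model_config(), seed = 4)
  m2 <- init_model(model_config(), seed = 4)
  expect_identical(m1, m2)
  expect_equal(nrow(m1$cortical$W_in), 15)
  expect_equal(ncol(m1$cortical$W_in), 18)
  expect_error(model_config(n_hidden_cor = 18), "bottleneck")
  expect_error(model_config(lr_hip = 0.005, lr_cor = 0.01), "rate")
  # task block is drawn last: models differing only in n_task share weights
  mt <- init_model(model_config(n_task = 4), seed = 4)
  expect_identical(m1$hippocampal, mt$hippocampal)
  expect_identical(m1$W_hc, mt$W_hc)
  expect_equal(dim(mt$W_task), c(4, 15))
})

test_that("zero cross-weights settle to the plain feed-forward pass in one step", {
  m <- init_model(model_config(), seed = 2)
  m$W_hc[] <- 0; m$W_ch[] <- 0
  x <- runif(18)
  a <- forward_settle(m, x)
  expect_true(a$converged)
  expect_equal(a$settle_iters, 1L)
  ff_h <- 1 / (1 + exp(-(as.vector(m$hippocampal$W_in %*% x) + m$hippocampal$b_h)))
  expect_equal(a$h_hip, ff_h)
})

test_that("settling matches an independent damped-iteration oracle on a toy net", {
  cfg <- model_config(n_input = 3, n_hidden_hip = 2, n_hidden_cor = 2,
                      settle_tol = 1e-12, settle_max_iter = 10000)
  m <- init_model(cfg, seed = 9)
  m$W_ch <- matrix(c(0.4, -0.3, 0.2, 0.5), 2)
  m$W_hc <- matrix(c(-0.2, 0.6, 0.1, -0.4), 2)
  x <- c(0.2, 0.9, 0.5)
  a <- forward_settle(m, x)
  expect_true(a$converged)
  # independent oracle: heavily damped iteration to tolerance 1e-10
  ah <- as.vector(m$hippocampal$W_in %*% x) + m$hippocampal$b_h
  ac <- as.vector(m$cortical$W_in %*% x) + m$cortical$b_h
  hh <- sigmoid_ref(ah); hc <- sigmoid_ref(ac)
  for (i in 1:100000) {
    nh <- 0.7 * hh + 0.3 * sigmoid_ref(ah + as.vector(m$W_ch %*% hc))
    nc <- 0.7 * hc + 0.3 * sigmoid_ref(ac + as.vector(m$W_hc %*% hh))
    if (max(abs(nh - hh), abs(nc - hc)) < 1e-10) { hh <- nh; hc <- nc; break }
    hh <- nh; hc <- nc
  }
  expect_equal(a$h_hip, hh, tolerance = 1e-8)
  expect_equal(a$h_cor, hc, tolerance = 1e-8)
})

test_that("settling converges for the whole default corpus at default init", {
  set <- default_set_cached()
  m <- init_model(model_config(), seed = 1)
  fm <- feature_matrix(set)
  acts <- apply(fm, 1, function(x) forward_settle(m, x))
  expect_true(all(vapply(acts, `[[`, logical(1), "converged")))
  expect_true(all(vapply(acts, `[[`, integer(1), "settle_iters") <= 50))
})

test_that("looking time is the hippocampal summed squared error", {
  m <- init_model(model_config(n_input = 2, n_hidden_hip = 1,
                               n_hidden_cor = 1), seed = 1)
  x <- c(1, 0)
  a <- forward_settle(m, x)
  expect_equal(looking_time(m, x), sum((a$o_hip - x)^2))
  # hand case: output (0.5, 0.5) against input (1, 0) gives 0.5
  expect_equal(sum((c(0.5, 0.5) - x)^2), 0.5)
  # monotone in any one output unit's deviation
  devs <- seq(0, 0.4, by = 0.1)
  vals <- vapply(devs, function(d) sum((c(0.5 + d, 0.5) - c(1, 0))^2), numeric(1))
  expect_true(all(diff(vals) < 0))  # moving 0.5 -> 0.9 toward input 1 reduces error
})

test_that("zero learning rates leave the model bit-identical", {
  cfg <- model_config(lr_hip = 0, lr_cor = 0, n_task = 4)
  m <- init_model(cfg, seed = 6)
  out <- train_step(m, runif(18), label_index = 2)
  expect_identical(out$model, m)
})

test_that("analytic gradients match central differences on random small nets", {
  for (s in 1:10) {
    case <- random_small_model(seed = 100 + s, with_task = s %% 2 == 0)
    err <- max_rel_gradient_error(case$model, case$x, case$label)
    expect_lt(err, 1e-5)
  }
})

test_that("gradient check is exact on the decoupled 3-2-3 toy", {
  cfg <- model_config(n_input = 3, n_hidden_hip = 2, n_hidden_cor = 2,
                      settle_tol = 1e-12, settle_max_iter = 1000)
  m <- init_model(cfg, seed = 21)
  m$W_hc[] <- 0; m$W_ch[] <- 0
  expect_lt(max_rel_gradient_error(m, c(0.1, 0.8, 0.4)), 1e-6)
})

test_that("unlabeled presentations never touch the task weights", {
  m <- init_model(model_config(n_task = 4), seed = 3)
  w0 <- m$W_task; b0 <- m$b_task
  for (i in 1:20) m <- train_step(m, runif(18))$model
  expect_identical(m$W_task, w0)
  expect_identical(m$b_task, b0)
  # labelled presentation does move them
  m2 <- train_step(m, runif(18), label_index = 1)$model
  expect_false(identical(m2$W_task, w0))
  # labels require task units
  m3 <- init_model(model_config(), seed = 3)
  expect_error(train_step(m3, runif(18), label_index = 1), "task units")
  expect_error(train_step(m, runif(18), label_index = 9), "n_task")
})

test_that("repeated training on one stimulus drives its error down", {
  cfg <- model_config(lr_hip = 0.01, lr_cor = 0.01)
  m <- init_model(cfg, seed = 8)
  m$W_hc[] <- 0; m$W_ch[] <- 0
  x <- runif(18)
  errs <- numeric(101)
  errs[1] <- looking_time(m, x)
  for (i in 1:100) {
    out <- train_step(m, x)
    m <- out$model
    errs[i + 1] <- looking_time(m, x)
  }
  expect_lt(errs[101], errs[1])
  expect_true(all(diff(errs) < 1e-9))
})

test_that("the fast component fits a just-trained item better than the slow one", {
  wins <- 0L
  for (s in 1:20) {
    m <- init_model(model_config(), seed = s)
    x <- withr::with_seed(s, runif(18))
    for (i in 1:50) m <- train_step(m, x)$model
    a <- forward_settle(m, x)
    hip <- sum((a$o_hip - x)^2); cor <- sum((a$o_cor - x)^2)
    if (hip < cor) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("models serialize to JSON and back exactly", {
  m <- init_model(model_config(n_task = 26), seed = 13)
  m <- train_step(m, runif(18), label_index = 5)$model
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$hippocampal, m2$hippocampal)
  expect_identical(m$cortical, m2$cortical)
  expect_identical(m$W_hc, m2$W_hc)
  expect_identical(m$W_ch, m2$W_ch)
  expect_identical(m$W_task, m2$W_task)
  expect_identical(m$b_task, m2$b_task)
  expect_identical(m$config, m2$config)
})
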