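test_that("a zero-step budget returns the model unchanged with an empty log", {
  set <- default_set_cached()
  m <- init_model(model_config(), seed = 1)
  out <- background_train(m, set, background_config(total_presentations = 0))
  expect_identical(out$model, m)
  expect_equal(nrow(out$log), 0)
})

test_that("background training is reproducible and fully logged", {
  set <- default_set_cached()
  cfg <- background_config(total_presentations = 300, label_scheme = "global",
                           seed = 42)
  m <- init_model(model_config(n_task = 4), seed = 1)
  a <- background_train(m, set, cfg)
  b <- background_train(m, set, cfg)
  expect_identical(a$model, b$model)
  expect_identical(a$log, b$log)
  expect_identical(a$log$step, seq_len(300))
  expect_true(all(a$log$stimulus_id %in% set$exemplars$id))
  # labels, when shown, are the object's own global label
  lab <- a$log[!is.na(a$log$label), ]
  glob <- set$exemplars$global_category[match(lab$stimulus_id, set$exemplars$id)]
  expect_identical(lab$label, glob)
})

test_that("the labelling coin respects label_probability across encounters", {
  set <- default_set_cached()
  m <- init_model(model_config(n_task = 26), seed = 1)
  cfg <- background_config(total_presentations = 4000, exposure_min = 1,
                           exposure_max = 1, label_scheme = "basic", seed = 5)
  out <- background_train(m, set, cfg)
  frac <- mean(!is.na(out$log$label))
  ci <- stats::qbinom(c(0.005, 0.995), 4000, 0.5) / 4000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("background training reduces mean reconstruction error on the corpus", {
  set <- default_set_cached()
  fm <- feature_matrix(set)
  m <- init_model(model_config(), seed = 2)
  probe <- fm[seq(1, 208, by = 4), ]
  before <- mean(apply(probe, 1, function(x) looking_time(m, x)))
  out <- background_train(m, set, background_config(seed = 3))
  after <- mean(apply(probe, 1, function(x) looking_time(out$model, x)))
  expect_lt(after, before)
})

test_that("exclusions are honoured and validated", {
  set <- default_set_cached()
  m <- init_model(model_config(), seed = 1)
  held <- set$exemplars$id[set$exemplars$basic_category == "rabbit"][1:6]
  out <- background_train(m, set, background_config(
    total_presentations = 500, exposure_min = 1, exposure_max = 1,
    excluded_items = held, seed = 1))
  expect_false(any(out$log$stimulus_id %in% held))
  expect_error(background_train(m, set, background_config(
    excluded_items = "no_such_id")), "no_such_id")
  expect_error(background_train(m, set, background_config(
    excluded_items = set$exemplars$id)), "excluded")
})

test_that("scheme/model task mismatches are rejected", {
  set <- default_set_cached()
  m <- init_model(model_config(n_task = 4), seed = 1)
  expect_error(background_train(m, set, background_config(label_scheme = "basic")),
               "26")
})

test_that("familiarization stops at zero for a pre-satisfied criterion", {
  set <- default_set_cached()
  items <- set$exemplars[set$exemplars$basic_category == "rabbit", ][1:6, ]
  m <- init_model(model_config(), seed = 1)
  res <- familiarize(m, items, familiarization_config(criterion = 1000))
  expect_equal(res$presentations, 0L)
  expect_true(res$converged)
  expect_identical(res$model$hippocampal, m$hippocampal)
})

test_that("an easily learnable item reaches criterion with a decreasing tail", {
  m <- init_model(model_config(), seed = 4)
  x <- matrix(withr::with_seed(4, runif(18)), nrow = 1)
  res <- familiarize(m, x, familiarization_config(criterion = 0.05))
  expect_true(res$converged)
  expect_gt(res$presentations, 0)
  tail_err <- utils::tail(res$trace$mean_hip_error, 5)
  expect_true(all(diff(tail_err) < 0))
})

test_that("familiarization never touches task weights and is frozen at lr 0", {
  set <- default_set_cached()
  items <- set$exemplars[set$exemplars$basic_category == "rabbit", ][1:6, ]
  m <- init_model(model_config(n_task = 26), seed = 2)
  res <- familiarize(m, items, familiarization_config(max_presentations = 60))
  expect_identical(res$model$W_task, m$W_task)
  expect_identical(res$model$b_task, m$b_task)

  frozen <- init_model(model_config(lr_hip = 0, lr_cor = 0), seed = 2)
  res0 <- familiarize(frozen, items,
                      familiarization_config(criterion = 0.001,
                                             max_presentations = 120))
  expect_false(res0$converged)
  expect_equal(res0$presentations, 120L)
})

test_that("presentations-to-criterion is non-increasing in the criterion", {
  set <- default_set_cached()
  items <- set$exemplars[set$exemplars$basic_category == "rabbit", ][1:6, ]
  m <- init_model(model_config(), seed = 5)
  m <- background_train(m, set, background_config(
    total_presentations = 1000, exposure_min = 1, exposure_max = 1,
    seed = 5))$model
  pres <- vapply(c(0.02, 0.05, 0.1), function(cr) {
    familiarize(m, items, familiarization_config(criterion = cr,
                                                 max_presentations = 20000))$presentations
  }, numeric(1))
  expect_true(all(diff(pres) <= 0))
})

test_that("background experience with related items speeds familiarization", {
  set <- default_set_cached()
  rid <- set$exemplars$id[set$exemplars$basic_category == "rabbit"]
  held <- rid[3:8]
  items <- set$exemplars[set$exemplars$id %in% held, ]
  signs <- vapply(1:10, function(s) {
    fresh <- init_model(model_config(), seed = s)
    trained <- background_train(fresh, set, background_config(
      total_presentations = 2000, exposure_min = 1, exposure_max = 1,
      excluded_items = held, seed = s))$model
    familiarize(fresh, items)$presentations -
      familiarize(trained, items)$presentations
  }, numeric(1))
  k <- sum(signs > 0)
  p <- stats::binom.test(k, sum(signs != 0), alternative = "greater")$p.value
  expect_lt(p, 0.05)
})
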