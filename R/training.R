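#' Configure background training
#'
#' Background training simulates everyday experience with objects: objects
#' are drawn at random and attended for random exposure lengths, and on each
#' encounter the object has a fixed chance of being labelled. One "epoch" of
#' exposure is one online weight update on that object, so an encounter of
#' length d contributes d consecutive training steps.
#'
#' @param total_presentations Total weight-update budget (default 4000); the
#'   final encounter is truncated to fit.
#' @param exposure_min,exposure_max Encounter length range in update steps
#'   (defaults 1 and 1000); lengths are drawn uniformly.
#' @param label_scheme `"none"`, `"basic"` or `"global"`: which label tier
#'   (if any) is taught.
#' @param label_probability Chance that an encounter is labelled (default
#'   0.5). The labelling coin is tossed once per encounter, and it is tossed
#'   even under `label_scheme = "none"` so that runs differing only in the
#'   scheme see identical object streams (paired designs).
#' @param excluded_items Character vector of stimulus ids never presented.
#' @param seed Integer seed; the full presentation stream is reproducible.
#' @return An object of class `background_config`.
#' @export
background_config <- function(total_presentations = 4000,
                              exposure_min = 1,
                              exposure_max = 1000,
                              label_scheme = c("none", "basic", "global"),
                              label_probability = 0.5,
                              excluded_items = character(),
                              seed = 1L) {
  label_scheme <- match.arg(label_scheme)
  cfg <- list(
    total_presentations = check_count(total_presentations, "total_presentations", min = 0L),
    exposure_min = check_count(exposure_min, "exposure_min"),
    exposure_max = check_count(exposure_max, "exposure_max"),
    label_scheme = label_scheme,
    label_probability = check_number(label_probability, "label_probability", 0, 1),
    excluded_items = as.character(excluded_items),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (cfg$exposure_min > cfg$exposure_max)
    stop_config("exposure_min must not exceed exposure_max")
  structure(cfg, class = "background_config")
}

#' Configure familiarization training
#'
#' @param criterion Hippocampal summed-squared-error threshold (default
#'   0.05). By default the criterion applies to the mean error over the
#'   familiarization set; with `per_item = TRUE` every item must
#'   individually fall below it.
#' @param max_presentations Safety cap on training steps (default 10000); a
#'   run that hits the cap is flagged unconverged.
#' @param per_item Apply the criterion to each item instead of the mean.
#' @param seed Kept for interface symmetry with the other configs; the
#'   familiarization procedure itself is deterministic (fixed cyclic order,
#'   no labels).
#' @return An object of class `familiarization_config`.
#' @export
familiarization_config <- function(criterion = 0.05,
                                   max_presentations = 10000,
                                   per_item = FALSE,
                                   seed = 1L) {
  if (!is.numeric(criterion) || length(criterion) != 1L || !(criterion > 0))
    stop_config("criterion must be a single number > 0")
  structure(list(
    criterion = as.numeric(criterion),
    max_presentations = check_count(max_presentations, "max_presentations"),
    per_item = isTRUE(per_item),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "familiarization_config")
}

label_indices_for <- function(set, scheme) {
  switch(scheme,
    none = rep(NA_integer_, nrow(set$exemplars)),
    basic = match(set$exemplars$basic_category, set$label_vocab_basic),
    global = match(set$exemplars$global_category, set$label_vocab_global)
  )
}

label_names_for <- function(set, scheme) {
  switch(scheme,
    none = NULL,
    basic = set$label_vocab_basic,
    global = set$label_vocab_global
  )
}

#' Background training on a stimulus set
#'
#' Repeatedly draws a non-excluded object uniformly at random, draws an
#' encounter length uniformly in `[exposure_min, exposure_max]`, decides
#' labelling once per encounter with probability `label_probability`, and
#' applies one online training step per step of the encounter, until the
#' total step budget is exhausted.
#'
#' @param model A `dual_memory_model`. Under `label_scheme = "basic"` or
#'   `"global"` its `n_task` must equal the corresponding label vocabulary
#'   size.
#' @param set A `stimulus_set`.
#' @param cfg A [background_config()].
#' @return A list with `model` (trained) and `log`, a data frame with one
#'   row per training step: `step`, `stimulus_id`, `label` (shown label or
#'   `NA`), `hip_error`, `cor_error` (reconstruction errors before that
#'   step's update).
#' @export
background_train <- function(model, set, cfg = background_config()) {
  if (!inherits(set, "stimulus_set")) stop_config("set must be a stimulus_set")
  if (!inherits(cfg, "background_config"))
    stop_config("cfg must be created with background_config()")
  ids <- set$exemplars$id
  unknown <- setdiff(cfg$excluded_items, ids)
  if (length(unknown))
    stop_config("excluded_items not in the stimulus set: %s",
                paste(unknown, collapse = ", "))
  keep <- !(ids %in% cfg$excluded_items)
  if (!any(keep)) stop_config("all stimuli are excluded")

  if (cfg$label_scheme != "none") {
    vocab <- label_names_for(set, cfg$label_scheme)
    if (model$n_task != length(vocab))
      stop_config("model has %d task units but label scheme '%s' needs %d",
                  model$n_task, cfg$label_scheme, length(vocab))
  }

  feats <- feature_matrix(set)[keep, , drop = FALSE]
  pool_ids <- ids[keep]
  lab_idx <- label_indices_for(set, cfg$label_scheme)[keep]
  vocab <- label_names_for(set, cfg$label_scheme)

  total <- cfg$total_presentations
  log_id <- character(total); log_lab <- rep(NA_character_, total)
  log_hip <- numeric(total); log_cor <- numeric(total)

  e <- model_env(model)
  span <- cfg$exposure_max - cfg$exposure_min + 1L
  with_local_seed(cfg$seed, {
    step <- 0L
    while (step < total) {
      obj <- sample.int(length(pool_ids), 1L)
      dur <- cfg$exposure_min - 1L + sample.int(span, 1L)
      coin <- stats::runif(1L)
      labelled <- cfg$label_scheme != "none" && coin < cfg$label_probability
      lab <- if (labelled) lab_idx[[obj]] else NULL
      x <- feats[obj, ]
      for (k in seq_len(min(dur, total - step))) {
        rec <- step_env(e, x, lab)
        step <- step + 1L
        log_id[[step]] <- pool_ids[[obj]]
        if (labelled) log_lab[[step]] <- vocab[[lab]]
        log_hip[[step]] <- rec$hip_error
        log_cor[[step]] <- rec$cor_error
      }
    }
  })

  log <- data.frame(step = seq_len(total), stimulus_id = log_id,
                    label = log_lab, hip_error = log_hip,
                    cor_error = log_cor, stringsAsFactors = FALSE)
  list(model = env_to_model(e, model), log = log)
}

items_feature_matrix <- function(items) {
  if (is.matrix(items)) {
    m <- items
    if (is.null(rownames(m))) rownames(m) <- paste0("item_", seq_len(nrow(m)))
    return(m)
  }
  if (is.data.frame(items)) {
    fcols <- grep("^f[0-9]+$", names(items), value = TRUE)
    if (!length(fcols)) stop_config("items data frame has no feature columns f1..fn")
    m <- as.matrix(items[fcols])
    rownames(m) <- if ("id" %in% names(items)) items$id else paste0("item_", seq_len(nrow(m)))
    return(m)
  }
  stop_config("items must be a feature matrix or a data frame of exemplar rows")
}

#' Familiarize a model to criterion
#'
#' The laboratory looking-time paradigm: the items are presented cyclically
#' in the given order, one unlabeled online training step per presentation.
#' After each full cycle the mean hippocampal reconstruction error over all
#' items is evaluated without updating weights; training stops as soon as it
#' falls below `criterion`. The number of training steps executed at that
#' point models familiarization time. Task weights are never touched (no
#' labels are shown in the test situation); both components keep learning at
#' their own rates.
#'
#' @param model A `dual_memory_model`.
#' @param items Feature matrix (rows = items) or a data frame of exemplar
#'   rows (as in `stimulus_set$exemplars`); must be nonempty.
#' @param cfg A [familiarization_config()].
#' @return An object of class `familiarization_result`: `presentations`
#'   (training steps to criterion; 0 if already below before any step),
#'   `converged` (`FALSE` if `max_presentations` was hit first), `trace`
#'   (data frame of per-cycle mean errors, starting at cycle 0), `model`
#'   (final state), and `criterion`.
#' @export
familiarize <- function(model, items, cfg = familiarization_config()) {
  if (!inherits(cfg, "familiarization_config"))
    stop_config("cfg must be created with familiarization_config()")
  feats <- items_feature_matrix(items)
  if (nrow(feats) == 0L) stop_config("familiarization item list is empty")
  if (ncol(feats) != model$config$n_input)
    stop_config("items have %d features but the model expects %d",
                ncol(feats), model$config$n_input)

  e <- model_env(model)
  n <- nrow(feats)
  eval_errors <- function() {
    vapply(seq_len(n), function(i) {
      a <- forward_env(e, feats[i, ])
      sum((a$o_hip - feats[i, ])^2)
    }, numeric(1))
  }
  below <- function(err) {
    if (cfg$per_item) all(err < cfg$criterion) else mean(err) < cfg$criterion
  }

  err <- eval_errors()
  trace_cycles <- 0L; trace_pres <- 0L; trace_err <- mean(err)
  presentations <- 0L; converged <- TRUE
  if (!below(err)) {
    converged <- FALSE
    cycle <- 0L
    while (presentations < cfg$max_presentations) {
      todo <- min(n, cfg$max_presentations - presentations)
      for (i in seq_len(todo)) step_env(e, feats[i, ])
      presentations <- presentations + todo
      cycle <- cycle + 1L
      err <- eval_errors()
      trace_cycles <- c(trace_cycles, cycle)
      trace_pres <- c(trace_pres, presentations)
      trace_err <- c(trace_err, mean(err))
      if (below(err)) { converged <- TRUE; break }
    }
  }

  structure(list(
    presentations = presentations,
    converged = converged,
    trace = data.frame(cycle = trace_cycles, presentations = trace_pres,
                       mean_hip_error = trace_err),
    final_errors = stats::setNames(err, rownames(feats)),
    criterion = cfg$criterion,
    model = env_to_model(e, model)
  ), class = "familiarization_result")
}

#' @export
print.familiarization_result <- function(x, ...) {
  cat(sprintf(
    "Familiarization: %d presentations (%s), criterion %g, final mean error %g\n",
    x$presentations, if (x$converged) "reached criterion" else "NOT converged",
    x$criterion, utils::tail(x$trace$mean_hip_error, 1)))
  invisible(x)
}

#' Write a training log to CSV
#'
#' Columns `step,stimulus_id,label,hip_error,cor_error`; errors are printed
#' with 17 significant digits for exact replay comparison.
#'
#' @param log Data frame as returned by [background_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(log, path) {
  lines <- c("step,stimulus_id,label,hip_error,cor_error",
             paste(log$step, log$stimulus_id,
                   ifelse(is.na(log$label), "", log$label),
                   sprintf("%.17g", log$hip_error),
                   sprintf("%.17g", log$cor_error), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
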