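#' Save a dual-memory model to a JSON file
#'
#' All weight matrices are written row-major with shape metadata, together
#' with the model configuration and seed, at full floating-point precision;
#' [load_model()] restores the model exactly.
#'
#' @param model A `dual_memory_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  mat <- function(m) {
    if (is.null(m)) return(NULL)
    list(shape = dim(m), data = as.vector(t(m)))
  }
  payload <- list(
    format = "dualmem-model",
    version = 1L,
    config = unclass(model$config),
    seed = model$seed,
    n_task = model$n_task,
    weights = list(
      hip_W_in = mat(model$hippocampal$W_in), hip_b_h = model$hippocampal$b_h,
      hip_W_out = mat(model$hippocampal$W_out), hip_b_o = model$hippocampal$b_o,
      cor_W_in = mat(model$cortical$W_in), cor_b_h = model$cortical$b_h,
      cor_W_out = mat(model$cortical$W_out), cor_b_o = model$cortical$b_o,
      W_hc = mat(model$W_hc), W_ch = mat(model$W_ch),
      W_task = mat(model$W_task), b_task = model$b_task
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a dual-memory model saved with [save_model()]
#'
#' @param path Path to a model JSON file.
#' @return A `dual_memory_model`, bit-identical to the saved one.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dualmem-model"))
    stop_config("%s is not a dualmem model file", path)
  unmat <- function(m) {
    if (is.null(m) || length(m$data) == 0L) return(NULL)
    matrix(m$data, nrow = m$shape[[1]], ncol = m$shape[[2]], byrow = TRUE)
  }
  cfg <- do.call(model_config, p$config)
  model <- init_model(cfg, seed = p$seed)
  model$hippocampal$W_in <- unmat(p$weights$hip_W_in)
  model$hippocampal$b_h <- p$weights$hip_b_h
  model$hippocampal$W_out <- unmat(p$weights$hip_W_out)
  model$hippocampal$b_o <- p$weights$hip_b_o
  model$cortical$W_in <- unmat(p$weights$cor_W_in)
  model$cortical$b_h <- p$weights$cor_b_h
  model$cortical$W_out <- unmat(p$weights$cor_W_out)
  model$cortical$b_o <- p$weights$cor_b_o
  model$W_hc <- unmat(p$weights$W_hc)
  model$W_ch <- unmat(p$weights$W_ch)
  model$W_task <- unmat(p$weights$W_task)
  model$b_task <- p$weights$b_task
  model
}
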