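# Model checkpoints: a single JSON file holding config, basis and all
# parameter arrays at full double precision.

#' Write a model checkpoint
#'
#' @param model a [schnorb_model()] (or the `model` field of a trained
#'   [train_model()] fit).
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  if (inherits(model, "slite_fit")) model <- model$model
  cfg <- model$config
  payload <- list(
    format = "schnorblite-checkpoint", version = 1L,
    config = list(B = cfg$B, D = cfg$D, T = cfg$T, L = cfg$L, r_c = cfg$r_c,
                  delta_mu = cfg$delta_mu, gamma = cfg$gamma,
                  n_hidden = cfg$n_hidden, share_w_dir = cfg$share_w_dir,
                  elements = cfg$elements),
    basis = list(name = model$basis$name,
                 elements = lapply(model$basis$shells, function(el) {
                   lapply(el, function(s) {
                     list(l = s$l, exp = s$exponents, coef = s$coefficients)
                   })
                 })),
    params = unclass(model$params)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# jsonlite reads matrices back as matrices but drops dimnames and turns
# length-1 leaves into scalars; restore what the model relies on.
restore_params <- function(p, config) {
  p$embed <- as.matrix(p$embed)
  rownames(p$embed) <- as.character(config$elements)
  names(p$heads$s_on) <- as.character(config$elements)
  p$heads$s_on <- lapply(p$heads$s_on, as.matrix)
  structure(p, class = "slite_params")
}

#' Read a model checkpoint
#' @param path a path written by [write_checkpoint()].
#' @return a [schnorb_model()].
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(raw$format) || raw$format != "schnorblite-checkpoint") {
    stop("not a schnorblite checkpoint: ", path)
  }
  shells <- lapply(raw$basis$elements, function(el) {
    lapply(el, function(s) gaussian_shell(s$l, unlist(s$exp), unlist(s$coef)))
  })
  basis <- basis_set(shells, name = raw$basis$name)
  cfg <- model_config(basis, elements = raw$config$elements,
                      B = raw$config$B, D = raw$config$D,
                      T_interactions = raw$config$T, L = raw$config$L,
                      r_c = raw$config$r_c, delta_mu = raw$config$delta_mu,
                      gamma = raw$config$gamma,
                      n_hidden = raw$config$n_hidden,
                      share_w_dir = raw$config$share_w_dir)
  schnorb_model(cfg, restore_params(raw$params, cfg), basis)
}
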