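.state_schema_version <- "1.0"

#' Save / load an MGSM state
#'
#' States are written as JSON with numbers at 17 significant digits,
#' which round-trips IEEE doubles exactly, so `load_state(save_state(s))`
#' reproduces every array bit-identically on any platform.  Files carry a
#' schema version; loading a file with a different schema version is an
#' error rather than a silent misread.
#'
#' @param state an [mgsm_state()].
#' @param path file path to write to / read from.
#' @return `save_state` returns `path` invisibly; `load_state` returns
#'   the `mgsm_state`.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "mgsm_state"))
  ser_comp <- function(comp) {
    list(d = comp$d, scale = comp$scale,
         Sigma = as.numeric(comp$Sigma))
  }
  obj <- list(
    schema_version = .state_schema_version,
    priors = as.list(state$priors),
    Sigma_C = ser_comp(state$Sigma_C),
    Sigma_CN = lapply(state$Sigma_CN, ser_comp),
    Sigma_N = lapply(state$Sigma_N, ser_comp),
    meta = state$meta
  )
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  if (!file.exists(path)) stop("state file not found: ", path)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) stop("corrupt state file ", path, ": ",
                             conditionMessage(e))
  )
  if (!identical(obj$schema_version, .state_schema_version)) {
    stop("state file ", path, " has schema version ",
         obj$schema_version %||% "<missing>", ", expected ",
         .state_schema_version)
  }
  de_comp <- function(x) {
    gsm_component(matrix(x$Sigma, x$d, x$d), scale = x$scale,
                  normalize = FALSE)
  }
  mgsm_state(
    priors = unlist(obj$priors),
    Sigma_C = de_comp(obj$Sigma_C),
    Sigma_CN = lapply(obj$Sigma_CN, de_comp),
    Sigma_N = lapply(obj$Sigma_N, de_comp),
    meta = as.list(obj$meta)
  )
}
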