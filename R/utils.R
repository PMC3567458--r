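#' @keywords internal
"_PACKAGE"

#' @importFrom utils read.csv modifyList head tail
#' @importFrom stats runif setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("raasim_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_domain <- function(...) {
  stop(structure(class = c("raasim_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop_domain(what, " must be finite and >= 0")
  invisible(x)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "raasim")
  if (!nzchar(path)) stop_config("packaged data file not found: ", file)
  path
}

#' Get or set a parameter by dotted path
#'
#' Parameter sets are nested named lists (e.g. the output of [raas_params()]).
#' A dotted path such as `"renin.kcat"` addresses one leaf.
#'
#' @param params nested parameter list
#' @param path dotted path string
#' @param value replacement value (for `set_param`)
#' @return `get_param` returns the leaf value; `set_param` the modified list.
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]]))
      stop_config("unknown parameter path: ", path,
                  suggest_key(k, names(node)))
    node <- node[[k]]
  }
  node
}

#' @rdname get_param
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]]))
      stop_config("unknown parameter path: ", path,
                  suggest_key(k, names(node)))
    node <- node[[k]]
  }
  params[[keys]] <- value
  params
}

suggest_key <- function(key, candidates) {
  if (is.null(candidates) || !length(candidates)) return("")
  d <- utils::adist(key, candidates, ignore.case = TRUE)
  best <- candidates[which.min(d)]
  paste0(" (did you mean '", best, "'?)")
}

## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Stable fingerprint of an R object (used for trajectory metadata).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
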