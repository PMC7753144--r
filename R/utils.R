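# Internal helpers: classed conditions, seeded evaluation, tiny hash.

qp_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "qpalmspt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

qp_param_error <- function(fmt, ...) qp_stop("qp_parameter_error", fmt, ...)
qp_data_error  <- function(fmt, ...) qp_stop("qp_data_error", fmt, ...)

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards, so seeded helpers do not
#' perturb the surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Polynomial rolling hash over the serialized object; used to fingerprint
# configs in run manifests (no cryptographic strength needed, just replay
# identity).
qp_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # drop the serialization header (R version stamps) so equal values hash
  # equal across sessions
  bytes <- bytes[-seq_len(14)]
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)
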