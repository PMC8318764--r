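#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. Keeps all package randomness reproducible per
# call without clobbering the session RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named RNG substream seed
#'
#' Every module draws its seed from the single global seed plus a stream
#' label, so independent pipeline stages (phantom geometry, mask draw,
#' noise, cohort) never share a random stream. The result stays below
#' 2^31 - 1 (R integers are 32-bit).
#'
#' @param global_seed integer global seed.
#' @param name stream label, e.g. `"mask"`, `"noise"`, `"cohort"`.
#' @return a deterministic integer seed.
#' @export
substream_seed <- function(global_seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483629L)
}

stop_dim <- function(msg) stop(structure(class = c("csmri_dimension_error", "error", "condition"),
                                         list(message = msg, call = sys.call(-1))))
stop_param <- function(msg) stop(structure(class = c("csmri_parameter_error", "error", "condition"),
                                           list(message = msg, call = sys.call(-1))))
stop_resource <- function(msg) stop(structure(class = c("csmri_resource_error", "error", "condition"),
                                              list(message = msg, call = sys.call(-1))))
stop_input <- function(msg) stop(structure(class = c("csmri_input_error", "error", "condition"),
                                           list(message = msg, call = sys.call(-1))))

`%||%` <- function(a, b) if (is.null(a)) b else a
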