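# Deterministic seed derivation and scoped RNG use.
#
# Every stochastic component (scatterer fields, measurement noise, ROI
# placement) draws from its own stream, derived by hashing a master seed
# together with string labels. Adding samples or temperatures therefore
# never shifts the draws of existing ones.

#' Derive a child seed from a master seed and string labels
#'
#' Hashes the master seed and any number of labels into an integer seed in
#' `[0, 2^31 - 2]`, suitable for [set.seed()]. The same inputs always yield
#' the same child seed; distinct label tuples yield (with overwhelming
#' probability) distinct streams.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the stream
#'   (e.g. sample id, temperature, role).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "s01", "scatterers")
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483563
  as.integer(h)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' library internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old_seed <- .GlobalEnv$.Random.seed
  on.exit({
    if (is.null(old_seed)) {
      if (!is.null(.GlobalEnv$.Random.seed))
        rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}
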