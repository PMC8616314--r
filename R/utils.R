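`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a namespaced random seed
#'
#' Expands one user-facing seed into per-component seeds so that fold
#' shuffling, simulations, and stochastic learners are jointly reproducible
#' without sharing a single RNG stream. The derivation is a fixed integer
#' hash of the tag folded into the base seed modulo 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param tag Character tag naming the consumer (e.g. `"cv_folds"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "cv_folds")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer(((seed %% 2147483647) + h * 48271) %% 2147483647)
}

# stop() with a consistent condition class so the CLI can map validation
# failures onto exit codes
rf_stop <- function(msg, class = "radfusion_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

rf_validation_error <- function(msg) rf_stop(msg, class = c("radfusion_validation_error", "radfusion_error"))

is_binary01 <- function(x) {
  !anyNA(x) && all(x %in% c(0, 1))
}
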