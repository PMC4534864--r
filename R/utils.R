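#' @keywords internal
"_PACKAGE"

#' @importFrom stats dbinom dnbinom dpois median optimize p.adjust pbinom
#'   pnbinom ppois qnbinom qpois quantile rbinom rlnorm rnbinom rpois runif
#'   rgamma sd setNames splinefun cmdscale dist var
#' @importFrom utils combn read.csv read.delim write.csv head
NULL

# polynomial rolling hash over the serialized object; stable fingerprint
# for run headers (31-bit arithmetic keeps everything in exact doubles)
config_hash <- function(x) {
  raw <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}

# deterministic child seed, kept below 2^31
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483629
}
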