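#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Derive a deterministic sub-stream seed from a master seed and a tag
#'
#' All stochastic operations in the package draw their seed through this
#' helper so that a single master seed reproduces every intermediate result
#' while distinct pipeline stages use distinct, documented sub-streams.
#'
#' @param seed Integer master seed.
#' @param tag Character label of the sub-stream (e.g. `"tracts"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 65521L
  as.integer((as.numeric(seed) %% 2147483647 + 10007 * h) %% 2147483629)
}

# Lightweight leveled logging: controlled by options(admixqtl.log_level =
# "debug"|"info"|"warn"|"quiet"). Default "warn" keeps tests quiet.
aq_log <- function(level = c("info", "debug", "warn"), ...) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  opt <- getOption("admixqtl.log_level", "warn")
  if (ranks[[level]] >= ranks[[opt]]) {
    message(sprintf("[admixqtl %s] %s", level, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
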