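#' Raise a classed error
#'
#' All input-contract violations in the package raise conditions that carry a
#' distinct class (prefixed `segmap_error_`) so callers can branch on them.
#'
#' @param class character scalar, error subclass.
#' @param msg message.
#' @noRd
segmap_abort <- function(class, msg) {
  cond <- structure(
    class = c(class, "segmap_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

#' Derive a child seed from a master seed and a stage name
#'
#' A single pipeline seed fans out deterministically to per-stage seeds so
#' that stages are individually reproducible. The derived seed always lies in
#' `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed, or `NULL` (returns `NULL`).
#' @param stage character stage label.
#' @return integer seed or `NULL`.
#' @export
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  x <- (abs(as.numeric(seed)) %% 2147483646) + 1
  as.integer(((x * 48271 + h * 7919) %% 2147483646) + 1)
}

# Set the RNG if a seed is supplied; no-op otherwise.
use_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Collapse a logical run-length encoding into (start, end) index pairs of TRUE runs.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
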