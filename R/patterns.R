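#' Define a four-track/three-loop G-quadruplex search pattern
#'
#' A pattern is four G-tracks of at least `min_track_len` guanines separated
#' by three loops, each loop constrained to a `(min, max)` length range. The
#' built-in patterns (see [g4_pattern_builtin()]) are
#' \describe{
#'   \item{PLL1}{loops 1-40 / 1-7 / 1-7 (oversized first loop)}
#'   \item{PLL3}{loops 1-7 / 1-7 / 1-40 (oversized third loop)}
#'   \item{CANONICAL}{loops 1-7 / 1-7 / 1-7}
#' }
#'
#' @param name Pattern label carried into hits.
#' @param loop_bounds List of three integer pairs `c(min, max)`, one per loop.
#' @param min_track_len Minimum G-track length, at least 3.
#' @return An object of class `g4_pattern`.
#' @export
g4_pattern <- function(name, loop_bounds, min_track_len = 3L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  min_track_len <- as.integer(min_track_len)
  if (is.na(min_track_len) || min_track_len < 3L) {
    stop("'min_track_len' must be an integer >= 3")
  }
  if (!is.list(loop_bounds) || length(loop_bounds) != 3L) {
    stop("'loop_bounds' must be a list of three (min, max) pairs")
  }
  lb <- do.call(rbind, lapply(loop_bounds, function(b) {
    b <- as.integer(b)
    if (length(b) != 2L || anyNA(b) || b[1] < 1L || b[1] > b[2]) {
      stop("each loop bound must satisfy 1 <= min <= max")
    }
    b
  }))
  dimnames(lb) <- list(c("loop1", "loop2", "loop3"), c("min", "max"))
  structure(list(name = name, min_track_len = min_track_len, loop_bounds = lb),
            class = "g4_pattern")
}

#' @export
print.g4_pattern <- function(x, ...) {
  lb <- x$loop_bounds
  cat(sprintf("<g4_pattern> %s: G{%d,} N%d-%d G{%d,} N%d-%d G{%d,} N%d-%d G{%d,}\n",
              x$name, x$min_track_len,
              lb[1, 1], lb[1, 2], x$min_track_len,
              lb[2, 1], lb[2, 2], x$min_track_len,
              lb[3, 1], lb[3, 2], x$min_track_len))
  invisible(x)
}

#' Built-in search patterns
#'
#' @param name One of `"PLL1"`, `"PLL3"`, `"CANONICAL"` (case-insensitive), or
#'   an existing `g4_pattern`, which is returned unchanged.
#' @return A [g4_pattern()].
#' @export
g4_pattern_builtin <- function(name) {
  if (inherits(name, "g4_pattern")) return(name)
  switch(toupper(name),
    PLL1 = g4_pattern("PLL1", list(c(1L, 40L), c(1L, 7L), c(1L, 7L))),
    PLL3 = g4_pattern("PLL3", list(c(1L, 7L), c(1L, 7L), c(1L, 40L))),
    CANONICAL = g4_pattern("CANONICAL", list(c(1L, 7L), c(1L, 7L), c(1L, 7L))),
    stop(sprintf("unknown built-in pattern '%s'", name)))
}
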