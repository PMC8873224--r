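# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Sets the random seed, runs `expr`, and restores the previous global RNG
#' state so that seeded package functions never perturb the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed; always < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483629)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(as.double(x))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

# Coerce a point (length-2 numeric) or an n x 2 matrix / data.frame of
# points to an n x 2 double matrix.
as_points <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.numeric(p) && is.null(dim(p))) {
    if (length(p) != 2L) stop("a point must have exactly 2 coordinates",
                              call. = FALSE)
    p <- matrix(p, nrow = 1L)
  }
  if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p)) {
    stop("points must be a length-2 vector or an n x 2 numeric matrix",
         call. = FALSE)
  }
  storage.mode(p) <- "double"
  if (any(!is.finite(p))) stop("points must be finite", call. = FALSE)
  p
}

# Stable 6-significant-digit formatting used by all CSV/JSON writers so
# repeated runs are byte-identical.
format_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 6L, format = "g"))
}
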