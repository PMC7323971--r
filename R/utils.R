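# Internal helpers shared across modules.

# Tissue label codes used by the phantom volume.
.labels <- c(
  background = 0L, epithelium = 1L, stroma = 2L,
  vessel_wall = 3L, vessel_lumen = 4L, extravasation = 5L
)

#' Tissue label codes
#'
#' Integer codes used in the `labels` array of a [tissue_volume].
#'
#' @return Named integer vector mapping tissue class names to label codes.
#' @export
tissue_labels <- function() .labels

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Separable 2D median smoothing (row-wise then column-wise running median).
# `window` must be odd; window <= 1 disables smoothing.  NA entries are
# carried through untouched.
median_smooth_2d <- function(m, window) {
  if (is.null(window) || window <= 1L) return(m)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  pass <- function(x) {
    ok <- which(is.finite(x))
    if (length(ok) < 3L) return(x)
    v <- x[ok]
    k <- min(window, if (length(v) %% 2L == 0L) length(v) - 1L else length(v))
    if (k < 3L) return(x)
    x[ok] <- stats::runmed(v, k, endrule = "median")
    x
  }
  m1 <- t(apply(m, 1L, pass))
  if (nrow(m) == 1L) m1 <- matrix(m1, nrow = 1L)
  m2 <- apply(m1, 2L, pass)
  matrix(m2, nrow = nrow(m), ncol = ncol(m))
}

# Linear index -> (i, j) for the first two axes of a 3D array.
index3_to_ij <- function(idx, dims) {
  i <- (idx - 1L) %% dims[1L] + 1L
  j <- ((idx - 1L) %/% dims[1L]) %% dims[2L] + 1L
  cbind(i = i, j = j)
}

index3_to_k <- function(idx, dims) {
  (idx - 1L) %/% (dims[1L] * dims[2L]) + 1L
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_min && x <= min)
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  invisible(x)
}
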