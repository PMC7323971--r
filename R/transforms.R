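#' Rigid 2D transform
#'
#' A rigid in-plane transform applied to slice images: a rotation by `theta`
#' degrees about the image centre followed by a translation of `(dx, dy)`
#' pixels along the first and second image axes.  Transforms compose
#' (`compose_transforms()`) and invert (`invert_transform()`) exactly; the
#' identity has all fields zero.
#'
#' @param dx,dy Translation in pixels along the first / second image axis.
#' @param theta Rotation in degrees, counter-clockwise about the image centre.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0) {
  stop_if_not_scalar_number(dx, "dx")
  stop_if_not_scalar_number(dy, "dy")
  stop_if_not_scalar_number(theta, "theta")
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 theta = as.numeric(theta)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: dx=%.3f px, dy=%.3f px, theta=%.3f deg\n",
              x$dx, x$dy, x$theta))
  invisible(x)
}

is_identity_transform <- function(t, tol = 1e-12) {
  abs(t$dx) < tol && abs(t$dy) < tol && abs(t$theta) < tol
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform equivalent to applying `t1`
#' first and then `t2` (function-composition order).
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  th2 <- t2$theta * pi / 180
  c2 <- cos(th2); s2 <- sin(th2)
  rigid_transform(
    dx = c2 * t1$dx - s2 * t1$dy + t2$dx,
    dy = s2 * t1$dx + c2 * t1$dy + t2$dy,
    theta = t1$theta + t2$theta
  )
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  th <- -t$theta * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  rigid_transform(
    dx = -(c1 * t$dx - s1 * t$dy),
    dy = -(s1 * t$dx + c1 * t$dy),
    theta = -t$theta
  )
}

#' Resample an image under a rigid transform
#'
#' Applies `t` to the image content: the output at position `p` samples the
#' input at `T^-1(p)`, where `T` rotates by `theta` about the image centre and
#' then translates by `(dx, dy)`.  Regions mapped from outside the input are
#' filled with `background`.  Binary masks should use nearest-neighbour
#' interpolation so membership is preserved.
#'
#' @param image Numeric or logical matrix.
#' @param t A [rigid_transform].
#' @param interpolation `"linear"` (default for intensity images) or
#'   `"nearest"` (exact pixel relocation for masks and integer shifts).
#' @param background Fill value for out-of-frame regions (default 0).
#' @return A matrix of the same dimensions and storage mode as `image`.
#' @export
apply_transform <- function(image, t,
                            interpolation = c("linear", "nearest"),
                            background = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.matrix(image), inherits(t, "rigid_transform"))
  if (is_identity_transform(t)) return(image)
  logical_in <- is.logical(image)
  x <- if (logical_in) image * 1 else image

  n1 <- nrow(x); n2 <- ncol(x)
  ci <- (n1 + 1) / 2; cj <- (n2 + 1) / 2
  th <- t$theta * pi / 180
  cth <- cos(th); sth <- sin(th)

  pi_ <- rep.int(seq_len(n1), n2) - ci - t$dx
  pj_ <- rep(seq_len(n2), each = n1) - cj - t$dy
  # inverse rotation (by -theta)
  src_i <- cth * pi_ + sth * pj_ + ci
  src_j <- -sth * pi_ + cth * pj_ + cj

  out <- rep.int(as.numeric(background), n1 * n2)
  if (interpolation == "nearest") {
    ii <- round(src_i); jj <- round(src_j)
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    out[ok] <- x[cbind(ii[ok], jj[ok])]
  } else {
    i0 <- floor(src_i); j0 <- floor(src_j)
    fi <- src_i - i0; fj <- src_j - j0
    gather <- function(ia, ja) {
      ok <- ia >= 1 & ia <= n1 & ja >= 1 & ja <= n2
      v <- rep.int(as.numeric(background), length(ia))
      v[ok] <- x[cbind(ia[ok], ja[ok])]
      v
    }
    v00 <- gather(i0, j0); v10 <- gather(i0 + 1, j0)
    v01 <- gather(i0, j0 + 1); v11 <- gather(i0 + 1, j0 + 1)
    out <- (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
      (1 - fi) * fj * v01 + fi * fj * v11
    # fully out-of-frame pixels keep the background value
    off <- src_i < 0.5 | src_i > n1 + 0.5 | src_j < 0.5 | src_j > n2 + 0.5
    out[off] <- as.numeric(background)
  }
  res <- matrix(out, n1, n2)
  if (logical_in) res > 0.5 else res
}
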