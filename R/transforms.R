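#' Rigid-body transforms
#'
#' A `rigid_transform` is a proper rotation plus a translation, the carrier
#' for every superposition and placement step in the package.  The screw
#' motion relating successive base pairs of a regular helix is one of these
#' (see [helical_step()]).
#'
#' @param rotation 3x3 proper rotation matrix (determinant +1, orthonormal).
#' @param translation length-3 numeric translation (Angstrom).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' tf <- rigid_transform(diag(3), c(1, 0, 0))
#' compose_transform(tf, invert_transform(tf))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    stop("rigid_transform: non-finite rotation or translation", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rigid_transform: rotation must be proper (det = +1)", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rigid_transform: rotation must be orthonormal", call. = FALSE)
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
tf_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @rdname rigid_transform
#' @param tf,tf1,tf2 `rigid_transform` objects.
#' @details `compose_transform(tf1, tf2)` applies `tf2` first, then `tf1`,
#'   matching function composition.
#' @export
compose_transform <- function(tf1, tf2) {
  stopifnot(inherits(tf1, "rigid_transform"), inherits(tf2, "rigid_transform"))
  R <- tf1$R %*% tf2$R
  # re-orthonormalise to keep long compositions inside the group
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  rigid_transform(R, as.numeric(tf1$R %*% tf2$t) + tf1$t)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$R, 6))
  cat("translation:", paste(round(x$t, 6), collapse = " "), "\n")
  invisible(x)
}

#' Rotation about an arbitrary axis
#'
#' @param axis length-3 direction (normalised internally).
#' @param angle rotation angle in degrees.
#' @param point a point on the axis (default origin).
#' @return A `rigid_transform`.
#' @export
axis_rotation <- function(axis, angle, point = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  rigid_transform(R, as.numeric(point - R %*% point))
}

coords_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    return(unname(x))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    return(unname(cbind(x$x, x$y, x$z)))
  }
  stop("expected an n x 3 matrix or a data frame with x/y/z columns",
       call. = FALSE)
}

#' Apply a rigid transform to coordinates
#'
#' @param s a structure tibble (with `x`, `y`, `z` columns) or an n x 3
#'   coordinate matrix.
#' @param tf a `rigid_transform`.
#' @return The same kind of object with transformed coordinates.  All
#'   pairwise interatomic distances are preserved.
#' @export
apply_transform <- function(s, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  m <- coords_matrix(s)
  out <- m %*% t(tf$R)
  out <- sweep(out, 2, tf$t, "+")
  if (is.data.frame(s)) {
    s$x <- out[, 1]; s$y <- out[, 2]; s$z <- out[, 3]
    return(s)
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD between
#' paired point sets, with a reflection guard: the returned rotation always
#' has determinant +1, even for mirror-image inputs.
#'
#' @param mobile,reference paired coordinates: n x 3 matrices or data frames
#'   with `x`,`y`,`z` columns; n >= 3, not all collinear.
#' @return A list with `transform` (a [rigid_transform()] mapping mobile
#'   onto reference) and `rmsd` (residual, Angstrom).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' fit <- superpose(a, apply_transform(a, axis_rotation(c(0, 0, 1), 40)))
#' fit$rmsd
#' @export
superpose <- function(mobile, reference) {
  A <- coords_matrix(mobile)
  B <- coords_matrix(reference)
  if (nrow(A) != nrow(B)) stop("superpose: point sets differ in length", call. = FALSE)
  n <- nrow(A)
  if (n < 3) stop("superpose: need at least 3 points", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity / degeneracy guard: covariance rank must be >= 2
  if (sum(svd(A0)$d > 1e-8 * max(1, max(abs(A0)))) < 2) {
    stop("superpose: degenerate (collinear) point set", call. = FALSE)
  }
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tfin <- rigid_transform(R, as.numeric(cb - R %*% ca))
  fitted <- apply_transform(A, tfin)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(transform = tfin, rmsd = rmsd)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' @param a,b paired coordinates (matrix or data frame), no fitting applied.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  A <- coords_matrix(a); B <- coords_matrix(b)
  stopifnot(nrow(A) == nrow(B))
  sqrt(mean(rowSums((A - B)^2)))
}
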