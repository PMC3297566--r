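#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, via the SVD of the covariance matrix with
#' reflection correction. The returned transform maps `mobile` onto
#' `reference`: `fitted = mobile_centred %*% t(rotation) + centre(reference)`.
#'
#' @param mobile `N x 3` coordinate matrix to be moved.
#' @param reference `N x 3` coordinate matrix to fit onto.
#' @return An object of class `"superposition"`: list with `rotation`
#'   (3x3, determinant +1), `translation` (length 3) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be N x 3 matrices of equal size",
         call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points", call. = FALSE)
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  # Degenerate (collinear) sets leave the rotation about the common axis
  # undetermined.
  if (svd(p)$d[2] < 1e-10 * max(1, svd(p)$d[1])) {
    stop("degenerate (collinear) coordinates: rotation is not determined",
         call. = FALSE)
  }
  h <- crossprod(p, q)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
         rmsd = rmsd),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param sp A [superpose()] result.
#' @param coords `N x 3` matrix.
#' @return Transformed `N x 3` matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Superposed RMSD between two coordinate sets
#' @inheritParams superpose
#' @param fit If `FALSE`, skip the fit and compute the raw coordinate RMSD.
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(mobile, reference, fit = TRUE) {
  if (!fit) {
    return(sqrt(mean(rowSums((as.matrix(mobile) - as.matrix(reference))^2))))
  }
  superpose(mobile, reference)$rmsd
}
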