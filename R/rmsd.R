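# Root-mean-square deviation, optionally after optimal rigid
# superposition (Kabsch).

#' Optimal rotation superposing one coordinate set onto another
#'
#' Kabsch algorithm via SVD; both sets are centred first. Reflections are
#' corrected so the returned matrix is a proper rotation (det = +1).
#'
#' @param x,ref N x 3 coordinate matrices.
#' @return 3 x 3 rotation matrix R such that `(x - centroid) %*% t(R)`
#'   best matches `ref - centroid(ref)`.
#' @export
kabsch_rotation <- function(x, ref) {
  xc <- sweep(x, 2, colMeans(x))
  rc <- sweep(ref, 2, colMeans(ref))
  s <- svd(crossprod(xc, rc))          # X^T R
  d <- sign(det(tcrossprod(s$v, s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # maps x-frame onto ref-frame
}

#' Root-mean-square deviation between two coordinate sets
#'
#' \eqn{RMSD = \sqrt{(1/N)\sum_i |x_i - x_i^{ref}|^2}}. With `fit = TRUE`
#' the deviation is computed after optimal rigid superposition
#' (translation + Kabsch rotation), as trajectory-RMSD tools do; with
#' `fit = FALSE` the raw formula is evaluated on the coordinates as given.
#'
#' @param x,ref N x 3 coordinate matrices (same N >= 1), nm.
#' @param fit superpose before measuring.
#' @return RMSD in the input length unit.
#' @export
rmsd <- function(x, ref, fit = FALSE) {
  x <- as.matrix(x); ref <- as.matrix(ref)
  if (!all(dim(x) == dim(ref)) || ncol(x) != 3)
    stop("coordinate sets must both be N x 3 with equal N")
  if (nrow(x) < 1) stop("empty coordinate set")
  if (fit) {
    R <- kabsch_rotation(x, ref)
    x <- sweep(x, 2, colMeans(x)) %*% t(R)
    x <- sweep(x, 2, colMeans(ref), "+")
  }
  sqrt(mean(rowSums((x - ref)^2)))
}
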