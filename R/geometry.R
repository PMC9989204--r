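#' Minimum-image displacement under orthorhombic periodic boundaries
#'
#' Returns the displacement `b - a` with each component wrapped into
#' `(-L/2, L/2]` for the corresponding box edge L. Both arguments may be
#' matrices (N x 3), in which case rows are paired (with recycling of a
#' single row).
#'
#' @param a,b points (length-3 vectors or N x 3 matrices), nm.
#' @param box orthorhombic box edge lengths (length-3), nm; all > 0.
#' @return displacement vector(s), same shape as the larger input.
#' @export
minimum_image_vector <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must have three strictly positive edges")
  a <- if (is.matrix(a)) a else matrix(a, 1, 3)
  b <- if (is.matrix(b)) b else matrix(b, 1, 3)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  d <- b - a
  for (k in 1:3) {
    L <- box[k]
    # wrap into (-L/2, L/2]: subtract L * round(d/L), then push -L/2 -> +L/2
    d[, k] <- d[, k] - L * round(d[, k] / L)
    at_edge <- d[, k] == -L / 2
    d[, k][at_edge] <- L / 2
  }
  if (n == 1L) drop(d) else d
}

#' Wrap coordinates into the primary box [0, L)
#' @param coords N x 3 matrix, nm.
#' @param box length-3 box edges, nm.
#' @return wrapped N x 3 matrix.
#' @export
wrap_coords <- function(coords, box) {
  coords <- as.matrix(coords)
  for (k in 1:3) coords[, k] <- coords[, k] %% box[k]
  coords
}

# N x 3 matrix slice of a coordinate array at frame f (robust to N = 1)
coord_slice <- function(coords, rows, f) {
  matrix(coords[rows, , f], ncol = 3)
}

# pairwise minimum-image distances between two coordinate sets (small groups)
min_image_dists <- function(A, B, box) {
  nA <- nrow(A); nB <- nrow(B)
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}
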