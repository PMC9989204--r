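#' Frame and trajectory containers
#'
#' A `md_frame` is a snapshot: an N x 3 coordinate matrix in nm, a
#' 3-vector of orthorhombic box edge lengths in nm, and a time stamp in
#' ps. A `md_trajectory` stacks frames into an N x 3 x F array with
#' per-frame box edges and strictly increasing times; all frames share one
#' `site_table`. Coordinates are stored as read (unwrapped); analyses wrap
#' on demand.
#'
#' @param coords numeric N x 3 matrix, nm.
#' @param box numeric length-3 vector of strictly positive edge lengths, nm.
#' @param time time stamp, ps.
#' @param title optional title string carried from file headers.
#' @return `md_frame()` returns an object of class `md_frame`.
#' @export
md_frame <- function(coords, box, time = 0, title = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three strictly positive orthorhombic edge lengths")
  structure(list(coords = coords, box = box, time = as.numeric(time),
                 title = title),
            class = "md_frame")
}

#' @rdname md_frame
#' @param sites the shared `site_table`.
#' @param coords_array numeric N x 3 x F array of coordinates, nm.
#' @param times numeric length-F vector of frame times, ps, strictly
#'   increasing.
#' @param boxes F x 3 matrix of box edges (or a single length-3 vector,
#'   recycled).
#' @param dt nominal frame spacing, ps; defaults to the median time step.
#' @export
md_trajectory <- function(sites, coords_array, times, boxes, dt = NULL) {
  validate_site_table(sites)
  dm <- dim(coords_array)
  if (length(dm) != 3L || dm[2] != 3L)
    stop("coords_array must be an N x 3 x F array")
  if (dm[1] != nrow(sites))
    stop("coordinate count (", dm[1], ") does not match site_table length (",
         nrow(sites), ")")
  nf <- dm[3]
  times <- as.numeric(times)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dim(boxes))) boxes <- matrix(boxes, nf, 3, byrow = TRUE)
  boxes <- as.matrix(boxes)
  if (nrow(boxes) != nf || ncol(boxes) != 3L)
    stop("boxes must be an F x 3 matrix")
  if (any(boxes <= 0)) stop("box edges must be strictly positive")
  if (is.null(dt)) dt <- if (nf > 1L) stats::median(diff(times)) else NA_real_
  structure(list(sites = sites, coords = coords_array, times = times,
                 boxes = boxes, dt = dt),
            class = "md_trajectory")
}

#' Number of frames / sites in a trajectory
#' @param traj a `md_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_sites <- function(traj) dim(traj$coords)[1]

#' Extract one frame from a trajectory
#' @param traj a `md_trajectory`.
#' @param i frame index (1-based).
#' @return a `md_frame`.
#' @export
get_frame <- function(traj, i) {
  md_frame(traj$coords[, , i, drop = TRUE], traj$boxes[i, ], traj$times[i])
}

#' Promote a single frame to a one-frame trajectory
#' @param sites a `site_table`.
#' @param frame a `md_frame`.
#' @return a `md_trajectory` with one frame.
#' @export
as_trajectory <- function(sites, frame) {
  md_trajectory(sites, array(frame$coords, c(nrow(frame$coords), 3, 1)),
                frame$time, matrix(frame$box, 1, 3), dt = NA_real_)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_sites(x), "sites x", n_frames(x), "frames, t =",
      x$times[1], "..", x$times[n_frames(x)], "ps\n")
  invisible(x)
}

#' @export
print.md_frame <- function(x, ...) {
  cat("md_frame:", nrow(x$coords), "sites, t =", x$time, "ps, box =",
      paste(format(x$box), collapse = " x "), "nm\n")
  invisible(x)
}
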