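#' Radial distribution function g(r)
#'
#' Standard pair-distance histogram under the minimum-image convention,
#' normalised per frame by the ideal-gas expectation: the expected pair
#' count in a shell `[r, r+dr)` is `n_pairs * V_shell / V`. Self-pairs
#' (identical sites) are always excluded; when the two selections are
#' identical, unordered pairs are counted once.
#'
#' @param traj a `md_trajectory`.
#' @param selA,selB selection expressions (or 0-based site_id vectors).
#' @param r_max histogram range, nm; must not exceed half the smallest
#'   box edge (minimum-image bound).
#' @param dr bin width, nm.
#' @return data.frame `r_nm` (bin centres), `g`, with attributes
#'   `n_frames`, `n_pairs`.
#' @export
radial_distribution <- function(traj, selA, selB, r_max, dr = 0.01) {
  ia <- resolve_selection(traj$sites, selA)
  ib <- resolve_selection(traj$sites, selB)
  if (!length(ia)) stop("selA matches no sites")
  if (!length(ib)) stop("selB matches no sites")
  if (r_max <= 0 || dr <= 0) stop("r_max and dr must be > 0")
  if (any(r_max > apply(traj$boxes, 1, min) / 2))
    stop("r_max (", r_max, " nm) exceeds half the smallest box edge; ",
         "minimum-image distances are undefined beyond that")
  same <- identical(sort(ia), sort(ib))
  n_pairs <- if (same) length(ia) * (length(ia) - 1) / 2
             else length(ia) * length(ib) - length(intersect(ia, ib))
  if (n_pairs == 0) stop("no distinct pairs between the selections")
  nb <- ceiling(r_max / dr)
  edges <- (0:nb) * dr
  g <- numeric(nb)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    box <- traj$boxes[f, ]
    xyz <- wrap_coords(matrix(traj$coords[, , f], ncol = 3), box)
    hist <- if (same)
      pair_hist_self(xyz, ia + 1L, box, r_max, dr)
    else
      pair_hist_cross(xyz, ia + 1L, ib + 1L, box, r_max, dr)
    V <- prod(box)
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
    g <- g + hist / (n_pairs * shell / V)
  }
  out <- data.frame(r_nm = (edges[-1] + edges[-(nb + 1)]) / 2, g = g / nf)
  attr(out, "n_frames") <- nf
  attr(out, "n_pairs") <- n_pairs
  out
}

resolve_selection <- function(sites, sel) {
  if (is.character(sel) && length(sel) == 1L) select_sites(sites, sel)
  else sort(as.integer(sel))
}

#' Contact-recurrence matrix between guest groups and lipid atom classes
#'
#' For each (guest group, lipid class) pair and frame, a contact is
#' scored when the minimum over site pairs of the minimum-image distance
#' falls below `cutoff`; the matrix entry is the fraction of frames in
#' contact. This binary per-frame convention is robust to group size and
#' reads directly as a recurrence fingerprint of hydrogen bonds / salt
#' bridges (polar groups, default cutoff 0.35 nm heavy-atom criterion)
#' or van der Waals adhesion (apolar groups, conventionally 0.50 nm).
#' A pair where either group is absent from the system scores 0.
#'
#' @param traj a `md_trajectory`.
#' @param guest_groups named list of selections (rows of the matrix).
#' @param lipid_classes named list of selections (columns).
#' @param cutoff contact distance cutoff, nm (> 0).
#' @return a `contact_recurrence` matrix (rows = guest groups, columns =
#'   lipid classes, values in [0,1]) with attributes `cutoff_nm`,
#'   `n_frames`.
#' @export
contact_recurrence <- function(traj, guest_groups, lipid_classes,
                               cutoff = 0.35) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(names(guest_groups)) || is.null(names(lipid_classes)))
    stop("guest_groups and lipid_classes must be named lists")
  gi <- lapply(guest_groups, resolve_selection, sites = traj$sites)
  li <- lapply(lipid_classes, resolve_selection, sites = traj$sites)
  check_disjoint(gi, "guest_groups")
  check_disjoint(li, "lipid_classes")
  nf <- n_frames(traj)
  hits <- matrix(0L, length(gi), length(li),
                 dimnames = list(names(gi), names(li)))
  for (f in seq_len(nf)) {
    xyz <- wrap_coords(matrix(traj$coords[, , f], ncol = 3),
                       traj$boxes[f, ])
    for (a in seq_along(gi)) {
      for (b in seq_along(li)) {
        if (!length(gi[[a]]) || !length(li[[b]])) next  # absent -> 0
        d <- min_pair_dist(xyz, gi[[a]] + 1L, li[[b]] + 1L,
                           traj$boxes[f, ])
        if (d < cutoff) hits[a, b] <- hits[a, b] + 1L
      }
    }
  }
  M <- hits / nf
  attr(M, "cutoff_nm") <- cutoff
  attr(M, "n_frames") <- nf
  class(M) <- c("contact_recurrence", class(M))
  M
}

check_disjoint <- function(groups, what) {
  all_idx <- unlist(groups)
  if (anyDuplicated(all_idx))
    stop(what, " must be pairwise non-overlapping (site_id ",
         all_idx[duplicated(all_idx)][1], " appears twice)")
}

#' Write a contact-recurrence matrix as TSV
#'
#' Named rows/columns; the cutoff, frame count and the per-frame binary
#' convention are recorded in `#` header lines.
#'
#' @param m a `contact_recurrence` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recurrence_tsv <- function(m, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# cutoff_nm: %s", num_txt(attr(m, "cutoff_nm"))),
               sprintf("# n_frames: %d", attr(m, "n_frames")),
               "# convention: binary per-frame minimum-distance contact"),
             con)
  writeLines(paste(c("group", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], num_txt(m[i, ])), collapse = "\t"),
               con)
  invisible(path)
}
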