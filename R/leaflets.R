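#' Assign lipids to leaflets frame by frame
#'
#' Under the planar (global z-normal) bilayer model, each molecule with a
#' reference site (typically the phosphate) is labelled `upper` or
#' `lower` by the sign of `z_ref - z_mid`, where `z_mid` is the mean z of
#' all reference sites in that frame; molecules within `transit_band` of
#' the midplane are labelled `transiting`. The molecule set is defined by
#' the reference selection: every molecule with at least one matching
#' site is assigned, and a molecule with more than one matching site is
#' an error.
#'
#' @param traj a `md_trajectory`.
#' @param ref selection expression picking exactly one reference site per
#'   lipid, e.g. `"polarity_class == phosphate"`.
#' @param transit_band half-width of the transiting band around the
#'   midplane, nm. Default 0.3 nm: smaller than half a headgroup, large
#'   enough to catch mid-plane crossers.
#' @param midplane_ref selection defining the sites whose mean z is the
#'   midplane; defaults to `ref`. Useful when assigning molecules that
#'   all sit in one leaflet (e.g. guests), where the lipid phosphates,
#'   not the guests themselves, define the midplane.
#' @return a `leaflet_assignment`: list with `times` (ps),
#'   `molecule_id`, `labels` (frames x molecules character matrix with
#'   values `upper`/`lower`/`transiting`), `ref`, `transit_band`.
#' @export
assign_leaflets <- function(traj, ref = "polarity_class == phosphate",
                            transit_band = 0.3, midplane_ref = ref) {
  idx0 <- select_sites(traj$sites, ref)
  if (!length(idx0))
    stop("reference selection matches no sites")
  rows <- idx0 + 1L
  mols <- traj$sites$molecule_id[rows]
  dup <- unique(mols[duplicated(mols)])
  if (length(dup))
    stop("reference selection picks more than one site for lipid ",
         paste(head(dup, 5), collapse = ", "))
  nf <- n_frames(traj)
  z <- traj$coords[rows, 3, , drop = FALSE]
  dim(z) <- c(length(rows), nf)
  mid_rows <- if (identical(midplane_ref, ref)) rows else
    select_sites(traj$sites, midplane_ref) + 1L
  zm <- traj$coords[mid_rows, 3, , drop = FALSE]
  dim(zm) <- c(length(mid_rows), nf)
  zmid <- colMeans(zm)
  dz <- sweep(z, 2, zmid)
  lab <- matrix("lower", nf, length(rows))
  lab[t(dz) > 0] <- "upper"
  lab[abs(t(dz)) < transit_band] <- "transiting"
  structure(list(times = traj$times, molecule_id = mols, labels = lab,
                 ref = ref, transit_band = transit_band),
            class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  n <- table(factor(x$labels[nrow(x$labels), ],
                    c("upper", "lower", "transiting")))
  cat("leaflet_assignment:", length(x$molecule_id), "lipids x",
      nrow(x$labels), "frames; last frame:", n["upper"], "upper,",
      n["lower"], "lower,", n["transiting"], "transiting\n")
  invisible(x)
}

#' Membrane thickness time series
#'
#' Per frame, the thickness is the mean z of the upper-leaflet reference
#' sites minus the mean z of the lower-leaflet reference sites;
#' transiting lipids are excluded. Frames where a leaflet is empty after
#' exclusion get `NA` and are flagged in the `undefined_frames`
#' attribute.
#'
#' @inheritParams assign_leaflets
#' @return data.frame `time_ps`, `thickness_nm`.
#' @export
membrane_thickness <- function(traj, ref = "polarity_class == phosphate",
                               transit_band = 0.3) {
  asg <- assign_leaflets(traj, ref, transit_band)
  ridx <- select_sites(traj$sites, ref) + 1L
  nf <- n_frames(traj)
  z <- traj$coords[ridx, 3, , drop = FALSE]
  dim(z) <- c(length(ridx), nf)
  th <- vapply(seq_len(nf), function(f) {
    up <- asg$labels[f, ] == "upper"
    lo <- asg$labels[f, ] == "lower"
    if (!any(up) || !any(lo)) return(NA_real_)
    mean(z[up, f]) - mean(z[lo, f])
  }, numeric(1))
  out <- data.frame(time_ps = traj$times, thickness_nm = th)
  attr(out, "undefined_frames") <- which(is.na(th))
  out
}

#' Area per lipid time series
#'
#' Per frame, `APL = box_x * box_y / mean(n_upper, n_lower)` where the
#' counts come from a leaflet assignment (transiting lipids count toward
#' neither leaflet). The mean-count denominator treats asymmetric
#' bilayers symmetrically; per-leaflet areas are also reported. Guests
#' are excluded from the lipid count unless a `guest_assignment` (an
#' assignment built from a guest reference selection) is supplied, in
#' which case an `apl_with_guests_nm2` column reports the alternative
#' convention.
#'
#' @param traj a `md_trajectory`.
#' @param assignment a `leaflet_assignment` of the lipids.
#' @param guest_assignment optional `leaflet_assignment` of guest
#'   molecules.
#' @return data.frame `time_ps`, `apl_nm2`, `apl_upper_nm2`,
#'   `apl_lower_nm2` and, with guests, `apl_with_guests_nm2`.
#' @export
area_per_lipid <- function(traj, assignment, guest_assignment = NULL) {
  stopifnot(inherits(assignment, "leaflet_assignment"))
  nf <- n_frames(traj)
  if (nrow(assignment$labels) != nf)
    stop("assignment frame count does not match trajectory")
  area <- traj$boxes[, 1] * traj$boxes[, 2]
  n_up <- rowSums(assignment$labels == "upper")
  n_lo <- rowSums(assignment$labels == "lower")
  if (any(n_up + n_lo == 0))
    stop("zero lipid count in frame ", which(n_up + n_lo == 0)[1])
  out <- data.frame(
    time_ps = traj$times,
    apl_nm2 = area / ((n_up + n_lo) / 2),
    apl_upper_nm2 = ifelse(n_up > 0, area / n_up, NA_real_),
    apl_lower_nm2 = ifelse(n_lo > 0, area / n_lo, NA_real_))
  if (!is.null(guest_assignment)) {
    g_up <- rowSums(guest_assignment$labels == "upper")
    g_lo <- rowSums(guest_assignment$labels == "lower")
    out$apl_with_guests_nm2 <- area / ((n_up + n_lo + g_up + g_lo) / 2)
  }
  out
}
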