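#' Lateral mean-squared displacement
#'
#' Computes MSD over x and y only, averaged over molecules and over all
#' time origins (FFT autocorrelation algorithm), for lags up to 50% of
#' the trajectory length. Molecule positions are the mass-weighted
#' centres of the selected sites, on unwrapped coordinates; wrapped
#' input (detected by inter-frame jumps larger than half a box edge) is
#' rejected. The per-frame centre-of-mass motion of each leaflet is
#' subtracted before accumulation, and molecules that change leaflet
#' during the trajectory are excluded and reported in the `excluded`
#' attribute.
#'
#' @param traj a `md_trajectory` with unwrapped coordinates.
#' @param sel selection defining the tracked sites (grouped by
#'   molecule), e.g. `"polarity_class == phosphate"`.
#' @param assignment a `leaflet_assignment` covering the selected
#'   molecules.
#' @return data.frame `lag_ps`, `msd_nm2`, with attributes
#'   `n_molecules`, `excluded`.
#' @export
lateral_msd <- function(traj, sel, assignment) {
  stopifnot(inherits(assignment, "leaflet_assignment"))
  idx <- select_sites(traj$sites, sel) + 1L
  if (!length(idx)) stop("selection matches no sites")
  mols <- traj$sites$molecule_id[idx]
  umol <- unique(mols)
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least two frames")
  # molecule lateral track: mass-weighted centre of selected sites
  xs <- matrix(0, nf, length(umol))
  ys <- matrix(0, nf, length(umol))
  for (j in seq_along(umol)) {
    rows <- idx[mols == umol[j]]
    w <- traj$sites$mass[rows]
    w <- w / sum(w)
    if (length(rows) == 1L) {
      xs[, j] <- traj$coords[rows, 1, ]
      ys[, j] <- traj$coords[rows, 2, ]
    } else {
      xs[, j] <- colSums(traj$coords[rows, 1, , drop = TRUE] * w)
      ys[, j] <- colSums(traj$coords[rows, 2, , drop = TRUE] * w)
    }
  }
  jump_x <- max(abs(diff(xs)))
  jump_y <- max(abs(diff(ys)))
  if (jump_x > min(traj$boxes[, 1]) / 2 || jump_y > min(traj$boxes[, 2]) / 2)
    stop("coordinates appear wrapped (inter-frame jump exceeds half a box ",
         "edge); lateral_msd requires unwrapped coordinates")
  am <- match(umol, assignment$molecule_id)
  if (any(is.na(am)))
    stop("assignment does not cover molecule ", umol[is.na(am)][1])
  lab <- assignment$labels[, am, drop = FALSE]
  leaflet_of <- vapply(seq_along(umol), function(j) {
    l <- unique(lab[, j][lab[, j] != "transiting"])
    if (length(l) == 1L) l else NA_character_
  }, character(1))
  excluded <- umol[is.na(leaflet_of)]
  keep <- which(!is.na(leaflet_of))
  if (!length(keep)) stop("no molecules remain after leaflet exclusion")
  # subtract per-frame leaflet centre-of-mass motion
  for (lf in unique(leaflet_of[keep])) {
    cols <- keep[leaflet_of[keep] == lf]
    cx <- rowMeans(xs[, cols, drop = FALSE])
    cy <- rowMeans(ys[, cols, drop = FALSE])
    xs[, cols] <- xs[, cols] - cx
    ys[, cols] <- ys[, cols] - cy
  }
  max_lag <- floor((nf - 1) / 2)
  acc <- numeric(max_lag + 1L)
  for (j in keep)
    acc <- acc + msd_fft(xs[, j], max_lag) + msd_fft(ys[, j], max_lag)
  dt_grid <- traj$times[seq_len(max_lag + 1L)] - traj$times[1]
  out <- data.frame(lag_ps = dt_grid, msd_nm2 = acc / length(keep))
  attr(out, "n_molecules") <- length(keep)
  attr(out, "excluded") <- excluded
  out
}

# all-time-origin 1-D MSD by the FFT autocorrelation algorithm:
# MSD(m) = S1(m) - 2*S2(m), S2 computed as an autocorrelation.
msd_fft <- function(x, max_lag) {
  N <- length(x)
  Fx <- stats::fft(c(x, numeric(N)))
  S2 <- Re(stats::fft(Fx * Conj(Fx), inverse = TRUE))[seq_len(N)] / (2 * N)
  S2 <- S2 / (N - 0:(N - 1))
  D <- x * x
  S <- sum(D)
  sub <- c(0, cumsum(D)[-N] + cumsum(rev(D))[-N])
  S1 <- (2 * S - sub) / (N - 0:(N - 1))
  (S1 - 2 * S2)[seq_len(max_lag + 1L)]
}

#' Fit a lateral diffusion coefficient from an MSD curve
#'
#' Least-squares straight line through MSD versus lag over a fractional
#' lag window; under the two-dimensional Einstein relation
#' `MSD(t) = 4 D t`, so `D = slope / 4`. The default 10-50% window
#' avoids both the short-lag ballistic/noise regime and the poorly
#' averaged long lags.
#'
#' @param msd data.frame from [lateral_msd()] (`lag_ps`, `msd_nm2`).
#' @param window fraction pair `(lower, upper)` of the maximum lag.
#' @return list `D_nm2_per_ps`, `slope`, `intercept`, `n_points`.
#' @export
fit_diffusion <- function(msd, window = c(0.1, 0.5)) {
  if (length(window) != 2L || window[1] <= 0 || window[2] <= window[1] ||
      window[2] > 1)
    stop("window must be a fraction pair with 0 < lower < upper <= 1")
  lmax <- max(msd$lag_ps)
  inwin <- msd$lag_ps >= window[1] * lmax & msd$lag_ps <= window[2] * lmax &
    msd$lag_ps > 0
  if (sum(inwin) < 5)
    stop("fewer than 5 MSD points in the fit window")
  fit <- lm(msd_nm2 ~ lag_ps, data = msd[inwin, ])
  co <- coef(fit)
  list(D_nm2_per_ps = unname(co[2]) / 4, slope = unname(co[2]),
       intercept = unname(co[1]), n_points = sum(inwin))
}

#' Detect leaflet translocation (flip-flop) events
#'
#' Scans each molecule's leaflet-label time series. A crossing is the
#' first frame carrying the opposite leaflet label after frames carrying
#' the resident label; transiting frames bridge (they neither trigger
#' nor reset). The residency achieved is the time from the crossing to
#' the first return to the departure leaflet (or to the trajectory end).
#' An event is accepted when the destination leaflet is held for at
#' least `min_residency` (default 10 ns, i.e. 10000 ps); a crossing
#' whose residency window runs past the trajectory end without reaching
#' the threshold is reported as censored, not accepted. A return
#' crossing closes its excursion and is not counted as a separate event.
#'
#' @param assignment a `leaflet_assignment` over contiguous time.
#' @param min_residency required post-crossing residency, ps.
#' @return data.frame `molecule_id`, `departure`, `t_cross_ps`,
#'   `residency_ps`, `accepted`, `censored` (zero rows if no events).
#' @export
detect_flipflops <- function(assignment, min_residency = 10000) {
  stopifnot(inherits(assignment, "leaflet_assignment"))
  lab <- assignment$labels
  times <- assignment$times
  if (nrow(lab) < 2)
    stop("flip-flop detection needs more than one frame")
  t_end <- times[length(times)]
  ev <- list()
  for (j in seq_along(assignment$molecule_id)) {
    l <- lab[, j]
    nt <- which(l != "transiting")
    if (length(nt) < 2) next
    current <- l[nt[1]]
    i <- 2L
    while (i <= length(nt)) {
      f <- nt[i]
      if (l[f] != current) {
        dest <- l[f]
        t_cross <- times[f]
        later <- nt[nt > f]
        back <- later[l[later] == current]
        if (length(back)) {
          res <- times[back[1]] - t_cross
          accepted <- res >= min_residency
          censored <- FALSE
          i <- which(nt == back[1])  # resume after the return
        } else {
          res <- t_end - t_cross
          accepted <- res >= min_residency
          censored <- !accepted
          i <- length(nt)  # nothing left to scan
        }
        ev[[length(ev) + 1L]] <- data.frame(
          molecule_id = assignment$molecule_id[j], departure = current,
          t_cross_ps = t_cross, residency_ps = res, accepted = accepted,
          censored = censored, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (!length(ev))
    return(data.frame(molecule_id = integer(), departure = character(),
                      t_cross_ps = numeric(), residency_ps = numeric(),
                      accepted = logical(), censored = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, ev)
}
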