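# fixture builders used across test files; everything is generated in code

# trajectory holding explicit per-frame coordinate matrices
point_traj <- function(coord_list, box, times = NULL, sites = NULL) {
  if (is.matrix(coord_list)) coord_list <- list(coord_list)
  n <- nrow(coord_list[[1]])
  if (is.null(sites))
    sites <- site_table(paste0("X", seq_len(n)), "TST", seq_len(n))
  if (is.null(times)) times <- (seq_along(coord_list) - 1) * 10
  arr <- array(0, c(n, 3, length(coord_list)))
  for (f in seq_along(coord_list)) arr[, , f] <- coord_list[[f]]
  md_trajectory(sites, arr, times, box)
}

# single two-site bond with displacement d (3-vector), one frame
bond_traj <- function(d, box = c(10, 10, 10)) {
  st <- site_table(c("A", "B"), "BND", 1)
  point_traj(rbind(c(1, 1, 1), c(1, 1, 1) + d), box, sites = st)
}

# hand-built leaflet assignment from a frames x molecules label matrix
manual_assignment <- function(labels, times = NULL, molecule_id = NULL) {
  if (is.null(times)) times <- (seq_len(nrow(labels)) - 1) * 100
  if (is.null(molecule_id)) molecule_id <- seq_len(ncol(labels))
  structure(list(times = times, molecule_id = molecule_id,
                 labels = labels, ref = "manual", transit_band = 0.3),
            class = "leaflet_assignment")
}

# atomistic-style all-trans chain along direction u with two explicit
# hydrogens per carbon, rotated about the chain axis by `phase` (radians)
aa_chain_traj <- function(n_carbons = 6, u = c(0, 0, 1), phases = 0,
                          box = c(20, 20, 20), cc = 0.15, ch = 0.11) {
  u <- u / sqrt(sum(u^2))
  # orthonormal frame around the chain axis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - u * sum(ref * u)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  names <- c(rbind(paste0("C", seq_len(n_carbons)),
                   paste0("HA", seq_len(n_carbons)),
                   paste0("HB", seq_len(n_carbons))))
  kpos <- rep(seq_len(n_carbons), each = 3)
  st <- site_table(names, "CHN", 1, mass = rep(c(12, 1, 1), n_carbons),
                   polarity_class = "apolar", chain_label = "sn1",
                   chain_position = kpos)
  origin <- box / 2
  frames <- lapply(phases, function(ph) {
    h1 <- cos(ph) * e1 + sin(ph) * e2
    h2 <- cos(ph + pi) * e1 + sin(ph + pi) * e2
    xyz <- matrix(0, n_carbons * 3, 3)
    for (k in seq_len(n_carbons)) {
      C <- origin + (k - 1) * cc * u
      xyz[(k - 1) * 3 + 1, ] <- C
      xyz[(k - 1) * 3 + 2, ] <- C + ch * h1
      xyz[(k - 1) * 3 + 3, ] <- C + ch * h2
    }
    xyz
  })
  point_traj(frames, box, sites = st)
}

# naive all-time-origin lateral MSD oracle, O(F^2), on an F x 2 track
naive_msd_track <- function(xy, max_lag) {
  vapply(0:max_lag, function(m) {
    if (m == 0) return(0)
    d <- xy[(1 + m):nrow(xy), , drop = FALSE] -
      xy[1:(nrow(xy) - m), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}
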