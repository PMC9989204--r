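#' Coarse-grained P2 order parameter of bead-bead bonds
#'
#' For each bond, P2 = <(3 cos^2(theta) - 1)/2> over frames (and over
#' bonds sharing a label), where theta is the angle between the
#' minimum-image bond vector and the membrane normal (+z). Values of 1,
#' -0.5 and 0 correspond to perfect alignment, anti-alignment (in-plane)
#' and random orientation with respect to the normal.
#'
#' Zero-length bond vectors are skipped and counted; if more than 1% of
#' samples are skipped a warning is raised. Error bars are standard
#' deviations over contiguous block means (`n_blocks` blocks).
#'
#' @param traj a `md_trajectory`.
#' @param bond_list 2-column matrix/data.frame of ordered site pairs
#'   (0-based `site_id`s), e.g. from [chain_bond_list()].
#' @param bond_labels optional character vector (one per bond); bonds
#'   sharing a label are averaged together. Defaults to one label per
#'   row.
#' @param n_blocks block count for the block-averaged standard
#'   deviation.
#' @return an `order_parameter_result` data.frame: `label`, `p2`, `sd`,
#'   `n_samples`, with attributes `block_length_ps`, `n_skipped`.
#' @export
cg_order_p2 <- function(traj, bond_list, bond_labels = NULL, n_blocks = 5) {
  bond_list <- as.matrix(bond_list)
  if (ncol(bond_list) != 2L) stop("bond_list must have two columns")
  nb <- nrow(bond_list)
  if (is.null(bond_labels))
    bond_labels <- paste0("bond", seq_len(nb))
  if (length(bond_labels) != nb)
    stop("bond_labels length must match bond_list rows")
  nmax <- n_sites(traj)
  if (any(bond_list < 0) || any(bond_list >= nmax))
    stop("bond_list site_ids out of range")
  nf <- n_frames(traj)
  ia <- bond_list[, 1] + 1L
  ib <- bond_list[, 2] + 1L
  # cos2[bond, frame]
  cos2 <- matrix(NA_real_, nb, nf)
  for (f in seq_len(nf)) {
    d <- minimum_image_vector(coord_slice(traj$coords, ia, f),
                              coord_slice(traj$coords, ib, f),
                              traj$boxes[f, ])
    if (!is.matrix(d)) d <- matrix(d, 1, 3)
    r2 <- rowSums(d * d)
    ok <- r2 > 0
    cos2[ok, f] <- d[ok, 3]^2 / r2[ok]
  }
  n_skip <- sum(is.na(cos2))
  if (n_skip > 0.01 * length(cos2))
    warning(sprintf("%d of %d bond samples had zero length and were skipped",
                    n_skip, length(cos2)))
  p2 <- (3 * cos2 - 1) / 2
  out <- aggregate_order(p2, bond_labels, traj$times, n_blocks)
  attr(out, "n_skipped") <- n_skip
  class(out) <- c("order_parameter_result", "data.frame")
  out
}

# average a per-unit x per-frame order matrix into labelled means with
# block-averaged standard deviations
aggregate_order <- function(vals, labels, times, n_blocks) {
  nf <- ncol(vals)
  ulab <- unique(labels)
  blocks <- if (nf >= n_blocks)
    split(seq_len(nf), cut(seq_len(nf), n_blocks, labels = FALSE))
  else list(seq_len(nf))
  res <- lapply(ulab, function(l) {
    v <- vals[labels == l, , drop = FALSE]
    bm <- vapply(blocks, function(b) mean(v[, b], na.rm = TRUE), numeric(1))
    data.frame(label = l, p2 = mean(v, na.rm = TRUE),
               sd = if (length(bm) > 1) sd(bm) else NA_real_,
               n_samples = sum(!is.na(v)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "block_length_ps") <- if (nf > 1)
    diff(range(times)) / length(blocks) else NA_real_
  out
}

#' Enumerate consecutive chain-bead bonds of a chain
#'
#' Builds the ordered (site_id, site_id) pairs linking chain positions
#' k -> k+1 within each molecule for one chain label, labelled
#' `"k-k+1"` so [cg_order_p2()] returns the per-bond profile along the
#' chain.
#'
#' @param sites a `site_table`.
#' @param chain chain label (`sn1`, `sn2`, ...).
#' @return list with `bonds` (matrix of 0-based pairs) and `labels`.
#' @export
chain_bond_list <- function(sites, chain = "sn1") {
  sel <- !is.na(sites$chain_label) & sites$chain_label == chain
  if (!any(sel)) stop("no sites with chain_label '", chain, "'")
  d <- sites[sel, c("site_id", "molecule_id", "chain_position")]
  d <- d[order(d$molecule_id, d$chain_position), ]
  bonds <- NULL; labels <- NULL
  for (mol in unique(d$molecule_id)) {
    dm <- d[d$molecule_id == mol, ]
    if (nrow(dm) < 2) next
    consec <- dm$chain_position[-1] == dm$chain_position[-nrow(dm)] + 1L
    from <- dm$site_id[-nrow(dm)][consec]
    to <- dm$site_id[-1][consec]
    bonds <- rbind(bonds, cbind(from, to))
    labels <- c(labels, paste0(dm$chain_position[-nrow(dm)][consec], "-",
                               dm$chain_position[-1][consec]))
  }
  list(bonds = unname(bonds), labels = labels)
}

#' Deuterium order parameter profile along an acyl chain
#'
#' Per carbon position k, `S_CD(k) = |<(3 cos^2(theta_CH) - 1)/2>|`,
#' averaged over frames, molecules and the hydrogens of that carbon
#' (absolute-value convention: profiles are reported on a positive
#' axis). Carbons are identified as chain sites whose name starts with
#' `C`; in `explicit_H` mode hydrogens are chain sites starting with `H`
#' that share the carbon's `chain_label` and `chain_position`.
#'
#' In `reconstructed` mode no hydrogens are needed: for each inner
#' carbon k the two ideal tetrahedral C-H unit vectors are built in the
#' plane perpendicular to the C(k-1) -> C(k+1) axis, symmetric about the
#' in-plane bisector of the two C-C bonds (H-C-H angle 109.4712
#' degrees). Terminal carbons are omitted from the profile. When the
#' three carbons are exactly collinear (idealised straight chains) the
#' bisector is undefined and the analytic uniform average over the
#' circle of perpendicular directions, `-P2(cos theta_axis)/2`, is used
#' instead.
#'
#' @param traj a `md_trajectory`.
#' @param chain chain label to profile.
#' @param h_mode `explicit_H` or `reconstructed`.
#' @param n_blocks block count for error bars.
#' @return an `order_parameter_result` data.frame: `carbon_index`,
#'   `scd`, `sd`, `n_samples`.
#' @export
deuterium_order_scd <- function(traj, chain = "sn1",
                                h_mode = c("reconstructed", "explicit_H"),
                                n_blocks = 5) {
  h_mode <- match.arg(h_mode)
  sites <- traj$sites
  onchain <- !is.na(sites$chain_label) & sites$chain_label == chain
  if (!any(onchain)) stop("no sites with chain_label '", chain, "'")
  isC <- onchain & grepl("^C", sites$site_name)
  isH <- onchain & grepl("^H", sites$site_name)
  nf <- n_frames(traj)
  if (h_mode == "explicit_H") {
    if (!any(isH))
      stop("explicit_H mode requires hydrogen sites on chain '", chain, "'")
    hrows <- which(isH)
    crows <- which(isC)
    key <- paste(sites$molecule_id, sites$chain_position)
    crow_of_h <- crows[match(key[hrows], key[crows])]
    if (any(is.na(crow_of_h)))
      stop("hydrogen site without a matching chain carbon (same ",
           "molecule_id and chain_position required)")
    kpos <- sites$chain_position[hrows]
    p2 <- matrix(NA_real_, length(hrows), nf)
    for (f in seq_len(nf)) {
      d <- minimum_image_vector(coord_slice(traj$coords, crow_of_h, f),
                                coord_slice(traj$coords, hrows, f),
                                traj$boxes[f, ])
      if (!is.matrix(d)) d <- matrix(d, 1, 3)
      r2 <- rowSums(d * d)
      ok <- r2 > 0
      p2[ok, f] <- (3 * d[ok, 3]^2 / r2[ok] - 1) / 2
    }
    labels <- kpos
  } else {
    # reconstructed: inner carbons only
    d <- sites[isC, c("site_id", "molecule_id", "chain_position")]
    d <- d[order(d$molecule_id, d$chain_position), ]
    trips <- NULL
    for (mol in unique(d$molecule_id)) {
      dm <- d[d$molecule_id == mol, ]
      if (nrow(dm) < 3) next
      for (j in 2:(nrow(dm) - 1)) {
        if (dm$chain_position[j - 1] + 1L == dm$chain_position[j] &&
            dm$chain_position[j] + 1L == dm$chain_position[j + 1])
          trips <- rbind(trips, c(dm$site_id[j - 1] + 1L,
                                  dm$site_id[j] + 1L,
                                  dm$site_id[j + 1] + 1L,
                                  dm$chain_position[j]))
      }
    }
    if (is.null(trips))
      stop("reconstructed mode needs at least three consecutive carbons")
    p2 <- matrix(NA_real_, nrow(trips), nf)
    half_hch <- 109.4712206 / 2 * pi / 180
    for (f in seq_len(nf)) {
      box <- traj$boxes[f, ]
      prev <- coord_slice(traj$coords, trips[, 1], f)
      cent <- coord_slice(traj$coords, trips[, 2], f)
      nxt <- coord_slice(traj$coords, trips[, 3], f)
      axis <- minimum_image_vector(prev, nxt, box)
      if (!is.matrix(axis)) axis <- matrix(axis, 1, 3)
      b1 <- minimum_image_vector(prev, cent, box)
      b2 <- minimum_image_vector(nxt, cent, box)
      if (!is.matrix(b1)) b1 <- matrix(b1, 1, 3)
      if (!is.matrix(b2)) b2 <- matrix(b2, 1, 3)
      a_hat <- axis / sqrt(rowSums(axis^2))
      bis <- b1 + b2
      # project bisector onto plane perpendicular to the chain axis
      bis <- bis - a_hat * rowSums(bis * a_hat)
      bn <- sqrt(rowSums(bis^2))
      degen <- bn < 1e-9
      czA <- rep(NA_real_, nrow(trips))
      if (any(!degen)) {
        b_hat <- bis[!degen, , drop = FALSE] / bn[!degen]
        ah <- a_hat[!degen, , drop = FALSE]
        c_hat <- cbind(ah[, 2] * b_hat[, 3] - ah[, 3] * b_hat[, 2],
                       ah[, 3] * b_hat[, 1] - ah[, 1] * b_hat[, 3],
                       ah[, 1] * b_hat[, 2] - ah[, 2] * b_hat[, 1])
        h1z <- cos(half_hch) * b_hat[, 3] + sin(half_hch) * c_hat[, 3]
        h2z <- cos(half_hch) * b_hat[, 3] - sin(half_hch) * c_hat[, 3]
        p2[!degen, f] <- ((3 * h1z^2 - 1) / 2 + (3 * h2z^2 - 1) / 2) / 2
      }
      if (any(degen)) {
        # straight chain: average P2 over the circle of directions
        # perpendicular to the axis = -P2(cos theta_axis)/2
        az <- a_hat[degen, 3]
        p2[degen, f] <- -((3 * az^2 - 1) / 2) / 2
      }
    }
    labels <- trips[, 4]
  }
  agg <- aggregate_order(p2, labels, traj$times, n_blocks)
  out <- data.frame(carbon_index = as.integer(agg$label),
                    scd = abs(agg$p2), sd = agg$sd,
                    n_samples = agg$n_samples)
  out <- out[order(out$carbon_index), ]
  rownames(out) <- NULL
  attr(out, "block_length_ps") <- attr(agg, "block_length_ps")
  attr(out, "h_mode") <- h_mode
  class(out) <- c("order_parameter_result", "data.frame")
  out
}
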