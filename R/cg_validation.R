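#' Coarse-grained mapping specification
#'
#' A mapping names the beads of one residue as lists of atom (site)
#' names, plus the bonded terms (bond pairs, angle triples, dihedral
#' quadruples) over bead names. Used to project an atomistic trajectory
#' onto pseudo-beads at the centre of mass of each bead's atoms and to
#' compare bonded-term distributions between the mapped atomistic and
#' the coarse-grained trajectories.
#'
#' @param beads named list: bead name -> character vector of atom site
#'   names (each atom may belong to at most one bead).
#' @param bonds list of length-2 character vectors of bead names.
#' @param angles list of length-3 character vectors.
#' @param dihedrals list of length-4 character vectors.
#' @return a validated `mapping_spec`.
#' @export
mapping_spec <- function(beads, bonds = list(), angles = list(),
                         dihedrals = list()) {
  if (is.null(names(beads)) || any(!nzchar(names(beads))))
    stop("beads must be a named list")
  atoms <- unlist(beads)
  if (anyDuplicated(atoms))
    stop("atom '", atoms[duplicated(atoms)][1],
         "' is assigned to more than one bead")
  check_terms <- function(terms, len, what) {
    for (tm in terms) {
      if (length(tm) != len)
        stop(what, " terms must have ", len, " bead names")
      unknown <- setdiff(tm, names(beads))
      if (length(unknown))
        stop(what, " term references undeclared bead '", unknown[1], "'")
    }
  }
  check_terms(bonds, 2L, "bond")
  check_terms(angles, 3L, "angle")
  check_terms(dihedrals, 4L, "dihedral")
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 dihedrals = dihedrals),
            class = "mapping_spec")
}

#' Read a mapping specification from a YAML config
#'
#' Layout: `beads:` mapping bead names to atom-name lists; `bonds:` /
#' `angles:` / `dihedrals:` as lists of bead-name tuples.
#'
#' @param path YAML file path.
#' @return a `mapping_spec`.
#' @export
read_mapping_spec <- function(path) {
  y <- yaml::read_yaml(path)
  mapping_spec(beads = lapply(y$beads, as.character),
               bonds = lapply(y$bonds, as.character),
               angles = lapply(y$angles, as.character),
               dihedrals = lapply(y$dihedrals, as.character))
}

#' Map an atomistic trajectory onto pseudo-CG beads by centre of mass
#'
#' For every molecule and bead, places one pseudo-site at the
#' mass-weighted mean position of the bead's atoms, after making the
#' bead whole across periodic boundaries (minimum-image reconstruction
#' of each atom around the bead's first atom). A bead whose
#' reconstructed atoms still span more than half a box edge is rejected
#' (its centre of mass is ill-defined under periodicity).
#'
#' @param traj an atomistic `md_trajectory`.
#' @param mapping a `mapping_spec`.
#' @return a `md_trajectory` of pseudo-beads; bead sites inherit the
#'   molecule id and residue name, mass/charge/electrons are sums over
#'   the constituent atoms.
#' @export
map_aa_to_cg <- function(traj, mapping) {
  stopifnot(inherits(mapping, "mapping_spec"))
  sites <- traj$sites
  mol_ids <- unique(sites$molecule_id)
  bead_rows <- list()
  bead_name <- character()
  bead_mol <- integer()
  bead_res <- character()
  for (mol in mol_ids) {
    in_mol <- which(sites$molecule_id == mol)
    for (bn in names(mapping$beads)) {
      rows <- in_mol[match(mapping$beads[[bn]],
                           sites$site_name[in_mol])]
      if (any(is.na(rows)))
        stop("molecule ", mol, ": atom '",
             mapping$beads[[bn]][is.na(rows)][1],
             "' of bead '", bn, "' not found")
      bead_rows[[length(bead_rows) + 1L]] <- rows
      bead_name <- c(bead_name, bn)
      bead_mol <- c(bead_mol, mol)
      bead_res <- c(bead_res, sites$residue_name[rows[1]])
    }
  }
  nb <- length(bead_rows)
  nf <- n_frames(traj)
  arr <- array(0, c(nb, 3, nf))
  for (f in seq_len(nf)) {
    box <- traj$boxes[f, ]
    xyz <- traj$coords[, , f, drop = TRUE]
    for (i in seq_len(nb)) {
      rows <- bead_rows[[i]]
      m <- sites$mass[rows]
      ref <- xyz[rows[1], ]
      rel <- minimum_image_vector(matrix(ref, length(rows), 3,
                                         byrow = TRUE),
                                  xyz[rows, , drop = FALSE], box)
      if (!is.matrix(rel)) rel <- matrix(rel, 1, 3)
      spread <- apply(rel, 2, function(v) diff(range(v)))
      if (any(spread > box / 2))
        stop("bead '", bead_name[i], "' of molecule ", bead_mol[i],
             " spans more than half a box edge after periodic ",
             "reconstruction; centre of mass is ill-defined")
      com <- ref + colSums(rel * m) / sum(m)
      w <- com %% box  # wrap the pseudo-site into the box
      w[box - w < 1e-9] <- 0  # a hair below 0 wraps to the box edge
      arr[i, , f] <- w
    }
  }
  bead_tab <- site_table(
    site_name = bead_name, residue_name = bead_res, molecule_id = bead_mol,
    mass = vapply(bead_rows, function(r) sum(sites$mass[r]), numeric(1)),
    charge = vapply(bead_rows, function(r) sum(sites$charge[r]),
                    numeric(1)),
    electrons = vapply(bead_rows, function(r) sum(sites$electrons[r]),
                       numeric(1)))
  md_trajectory(bead_tab, arr, traj$times, traj$boxes, dt = traj$dt)
}

#' Bonded-term distributions of a (pseudo-)CG trajectory
#'
#' Measures every bond length (minimum image, nm), angle (degrees in
#' [0, 180]) and dihedral (degrees in (-180, 180], IUPAC sign
#' convention: cis = 0) declared in the mapping, across all molecules
#' and frames, and normalises each histogram to sum 1. Degenerate
#' (zero-length) vectors in an angle or dihedral skip the sample and
#' are counted.
#'
#' Default bin widths: 0.005 nm (bonds), 2 deg (angles), 5 deg
#' (dihedrals) over data-driven ranges padded by 5% (angles/dihedrals
#' use their natural full ranges). To compare two trajectories pass the
#' `breaks` of the first result when computing the second, so both use
#' identical binning.
#'
#' @param traj a bead trajectory (from [map_aa_to_cg()] or native CG).
#' @param mapping the `mapping_spec` declaring the bonded terms.
#' @param breaks optional named list of break vectors (from a previous
#'   result's `breaks` field) forcing identical binning.
#' @return a `bonded_distributions` object: list with `terms` (per-term
#'   list of `type`, `prob`, `mids`, `breaks`, `n`, `n_skipped`).
#' @export
bonded_distributions <- function(traj, mapping, breaks = NULL) {
  stopifnot(inherits(mapping, "mapping_spec"))
  sites <- traj$sites
  term_defs <- c(
    lapply(mapping$bonds, function(tm) list(type = "bond", beads = tm)),
    lapply(mapping$angles, function(tm) list(type = "angle", beads = tm)),
    lapply(mapping$dihedrals,
           function(tm) list(type = "dihedral", beads = tm)))
  names(term_defs) <- vapply(term_defs, function(d)
    paste(d$beads, collapse = "-"), character(1))
  nf <- n_frames(traj)
  mol_ids <- unique(sites$molecule_id)
  out <- list()
  for (nm in names(term_defs)) {
    def <- term_defs[[nm]]
    rows <- lapply(mol_ids, function(mol) {
      in_mol <- which(sites$molecule_id == mol)
      r <- in_mol[match(def$beads, sites$site_name[in_mol])]
      if (any(is.na(r))) NULL else r
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
      stop("term '", nm, "' is not resolvable in any molecule")
    samples <- numeric(0)
    n_skipped <- 0L
    for (f in seq_len(nf)) {
      box <- traj$boxes[f, ]
      xyz <- traj$coords[, , f, drop = TRUE]
      for (r in rows) {
        v <- measure_term(xyz, r, box, def$type)
        if (is.na(v)) n_skipped <- n_skipped + 1L
        else samples <- c(samples, v)
      }
    }
    brk <- if (!is.null(breaks)) {
      if (is.null(breaks[[nm]]))
        stop("supplied breaks are missing term '", nm, "'")
      breaks[[nm]]
    } else default_breaks(samples, def$type)
    if (any(samples < brk[1] | samples > brk[length(brk)]))
      stop("term '", nm, "': samples fall outside the supplied breaks")
    h <- hist(samples, breaks = brk, plot = FALSE)
    out[[nm]] <- list(type = def$type, prob = h$counts / sum(h$counts),
                      mids = h$mids, breaks = brk, n = length(samples),
                      n_skipped = n_skipped)
  }
  structure(list(terms = out), class = "bonded_distributions")
}

measure_term <- function(xyz, r, box, type) {
  if (type == "bond") {
    d <- minimum_image_vector(xyz[r[1], ], xyz[r[2], ], box)
    return(sqrt(sum(d * d)))
  }
  if (type == "angle") {
    v1 <- minimum_image_vector(xyz[r[2], ], xyz[r[1], ], box)
    v2 <- minimum_image_vector(xyz[r[2], ], xyz[r[3], ], box)
    n1 <- sqrt(sum(v1 * v1)); n2 <- sqrt(sum(v2 * v2))
    if (n1 == 0 || n2 == 0) return(NA_real_)
    cosa <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
    return(acos(cosa) * 180 / pi)
  }
  # dihedral: IUPAC convention, cis (eclipsed) = 0
  b1 <- minimum_image_vector(xyz[r[1], ], xyz[r[2], ], box)
  b2 <- minimum_image_vector(xyz[r[2], ], xyz[r[3], ], box)
  b3 <- minimum_image_vector(xyz[r[3], ], xyz[r[4], ], box)
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1 * n1) == 0 || sum(n2 * n2) == 0 || sum(b2 * b2) == 0)
    return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2 * b2))
  ang <- atan2(sum(m1 * n2) / b2n, sum(n1 * n2)) * 180 / pi
  # convention: trans = 180, cis = 0; map -180 -> 180 for half-open range
  if (ang <= -180) ang <- ang + 360
  ang
}

default_breaks <- function(samples, type) {
  width <- switch(type, bond = 0.005, angle = 2, dihedral = 5)
  if (type == "angle") return(seq(0, 180, by = width))
  if (type == "dihedral") return(seq(-180, 180, by = width))
  rng <- range(samples)
  pad <- max(diff(rng) * 0.05, width)
  lo <- max(0, rng[1] - pad)
  hi <- rng[2] + pad
  seq(lo, hi + width, by = width)
}

#' Distance between two bonded-term histograms
#'
#' Headline metric: Jensen-Shannon divergence in bits (base 2), which is
#' symmetric, zero iff the histograms are identical, and bounded by 1
#' bit (disjoint distributions). The overlap coefficient
#' `sum(min(p_i, q_i))` is reported alongside for interpretability.
#' Histograms must share identical binning; mismatched breaks are an
#' error (no silent rebinning).
#'
#' @param p,q per-term histogram entries (from a `bonded_distributions`
#'   object) or plain probability vectors of equal length.
#' @return list `jsd_bits`, `overlap`.
#' @export
distribution_distance <- function(p, q) {
  if (is.list(p) && !is.null(p$breaks)) {
    if (!is.list(q) || is.null(q$breaks) ||
        length(p$breaks) != length(q$breaks) ||
        max(abs(p$breaks - q$breaks)) > 1e-12)
      stop("histograms have mismatched binning; recompute with shared ",
           "breaks (no silent rebinning)")
    pv <- p$prob; qv <- q$prob
  } else {
    pv <- as.numeric(p); qv <- as.numeric(q)
    if (length(pv) != length(qv))
      stop("histograms have mismatched binning; recompute with shared ",
           "breaks (no silent rebinning)")
  }
  pv <- pv / sum(pv); qv <- qv / sum(qv)
  m <- (pv + qv) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  list(jsd_bits = (kl(pv, m) + kl(qv, m)) / 2,
       overlap = sum(pmin(pv, qv)))
}

#' Per-term agreement report between atomistic-mapped and CG distributions
#'
#' For every bonded term present in both inputs, reports the
#' Jensen-Shannon divergence and overlap coefficient; a term passes when
#' `JSD <= jsd_threshold` and the overall validation passes iff all
#' terms pass. A term present in only one input is reported untestable
#' and fails the overall validation.
#'
#' @param aa_dists `bonded_distributions` of the mapped atomistic
#'   trajectory.
#' @param cg_dists `bonded_distributions` of the CG trajectory (computed
#'   with the atomistic result's breaks).
#' @param jsd_threshold pass threshold, bits. The default 0.05 bits is a
#'   strict numerical reading of "good reproduction"; configurable.
#' @return a `validation_report` data.frame `term`, `type`, `jsd_bits`,
#'   `overlap`, `pass`, with attribute `overall_pass`.
#' @export
validation_report <- function(aa_dists, cg_dists, jsd_threshold = 0.05) {
  stopifnot(inherits(aa_dists, "bonded_distributions"),
            inherits(cg_dists, "bonded_distributions"))
  terms <- union(names(aa_dists$terms), names(cg_dists$terms))
  rows <- lapply(terms, function(nm) {
    pa <- aa_dists$terms[[nm]]
    pc <- cg_dists$terms[[nm]]
    if (is.null(pa) || is.null(pc))
      return(data.frame(term = nm,
                        type = (if (is.null(pa)) pc else pa)$type,
                        jsd_bits = NA_real_, overlap = NA_real_,
                        pass = FALSE, stringsAsFactors = FALSE))
    dd <- distribution_distance(pa, pc)
    data.frame(term = nm, type = pa$type, jsd_bits = dd$jsd_bits,
               overlap = dd$overlap, pass = dd$jsd_bits <= jsd_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_pass") <- all(out$pass)
  attr(out, "jsd_threshold") <- jsd_threshold
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("CG bonded-distribution validation (JSD threshold",
      attr(x, "jsd_threshold"), "bits):",
      if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  NextMethod()
}
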