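two_bead_mapping <- function() {
  mapping_spec(beads = list(B1 = c("CA", "CB"), B2 = c("CC", "CD")),
               bonds = list(c("B1", "B2")))
}

test_that("centre-of-mass mapping does mass-weighted averages", {
  st <- site_table(c("CA", "CB"), "MOL", 1, mass = c(1, 1))
  tr <- point_traj(rbind(c(1, 1, 0), c(1, 1, 1)), c(10, 10, 10),
                   sites = st)
  cg <- map_aa_to_cg(tr, mapping_spec(beads = list(B = c("CA", "CB"))))
  expect_equal(cg$coords[1, , 1], c(1, 1, 0.5))
  st2 <- site_table(c("CA", "CB"), "MOL", 1, mass = c(1, 3))
  tr2 <- point_traj(rbind(c(0, 2, 2), c(1, 2, 2)), c(10, 10, 10),
                    sites = st2)
  cg2 <- map_aa_to_cg(tr2, mapping_spec(beads = list(B = c("CA", "CB"))))
  expect_equal(cg2$coords[1, 1, 1], 0.75)
  expect_equal(cg2$sites$mass, 4)
})

test_that("beads split across the boundary are reconstructed, not averaged
           naively", {
  st <- site_table(c("CA", "CB"), "MOL", 1, mass = c(1, 1))
  tr <- point_traj(rbind(c(0.05, 1, 1), c(9.95, 1, 1)), c(10, 10, 10),
                   sites = st)
  cg <- map_aa_to_cg(tr, mapping_spec(beads = list(B = c("CA", "CB"))))
  expect_equal(cg$coords[1, 1, 1], 0)
})

test_that("mapping commutes with rigid translation", {
  set.seed(36)
  st <- site_table(c("CA", "CB", "CC", "CD"), "MOL", 1,
                   mass = c(12, 1, 14, 16))
  xyz <- matrix(runif(12, 2, 4), 4, 3)
  tr <- point_traj(xyz, c(10, 10, 10), sites = st)
  trs <- point_traj(sweep(xyz, 2, c(0.7, -0.3, 1.1), "+"), c(10, 10, 10),
                    sites = st)
  cg <- map_aa_to_cg(tr, two_bead_mapping())
  cgs <- map_aa_to_cg(trs, two_bead_mapping())
  expect_equal(cgs$coords[, , 1], cg$coords[, , 1] +
                 matrix(c(0.7, -0.3, 1.1), 2, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("beads spanning more than half the box are rejected", {
  st <- site_table(c("CA", "CB", "CC"), "MOL", 1, mass = 1)
  tr <- point_traj(rbind(c(0, 1, 1), c(3.3, 1, 1), c(6.6, 1, 1)),
                   c(10, 10, 10), sites = st)
  expect_error(map_aa_to_cg(tr, mapping_spec(
    beads = list(B = c("CA", "CB", "CC")))), "half a box edge")
})

test_that("mapping specs validate bead and term declarations", {
  expect_error(mapping_spec(beads = list(B1 = c("CA"), B2 = c("CA"))),
               "more than one bead")
  expect_error(mapping_spec(beads = list(B1 = "CA"),
                            bonds = list(c("B1", "BX"))), "undeclared")
  expect_error(mapping_spec(beads = list(B1 = "CA"),
                            angles = list(c("B1", "B1"))), "3 bead")
})

test_that("geometry measurements: collinear angle, cis/trans dihedral", {
  st <- site_table(c("CA", "CB", "CC", "CD"), "MOL", 1, mass = 1)
  ms <- mapping_spec(beads = as.list(setNames(c("CA", "CB", "CC", "CD"),
                                              c("B1", "B2", "B3", "B4"))),
                     bonds = list(c("B1", "B2")),
                     angles = list(c("B1", "B2", "B3")),
                     dihedrals = list(c("B1", "B2", "B3", "B4")))
  # collinear chain with a cis fourth site
  cis <- rbind(c(1, 2, 1), c(1, 1, 1), c(2, 1, 1), c(2, 2, 1))
  tr <- point_traj(cis, c(10, 10, 10), sites = st)
  d <- bonded_distributions(map_aa_to_cg(tr, ms), ms)
  expect_equal(sum(d$terms[["B1-B2"]]$prob), 1)
  ang_mode <- d$terms[["B1-B2-B3"]]$mids[which.max(
    d$terms[["B1-B2-B3"]]$prob)]
  expect_equal(ang_mode, 89, tolerance = 0.02)  # right angle fixture
  dih <- d$terms[["B1-B2-B3-B4"]]
  cis_bin <- dih$mids[which.max(dih$prob)]
  expect_lt(abs(cis_bin), 2.6)  # cis = 0 degrees
  # trans arrangement
  trans <- rbind(c(1, 2, 1), c(1, 1, 1), c(2, 1, 1), c(2, 0, 1))
  dtr <- bonded_distributions(map_aa_to_cg(
    point_traj(trans, c(10, 10, 10), sites = st), ms), ms)
  tbin <- dtr$terms[["B1-B2-B3-B4"]]$mids[which.max(
    dtr$terms[["B1-B2-B3-B4"]]$prob)]
  expect_gt(abs(tbin), 177)
  # collinear triple -> 180 degree angle
  col <- rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1), c(3, 2, 1))
  dcol <- bonded_distributions(map_aa_to_cg(
    point_traj(col, c(10, 10, 10), sites = st), ms), ms)
  amode <- dcol$terms[["B1-B2-B3"]]$mids[which.max(
    dcol$terms[["B1-B2-B3"]]$prob)]
  expect_equal(amode, 179)
})

test_that("a fixed bond length yields a delta distribution", {
  spec <- bilayer_spec(n_per_leaflet = 4, tilt_mode = "fixed_angle",
                       tilt_param = 0, d_lat = 0, seed = 37)
  tr <- generate_bilayer_trajectory(spec, 5, 100)
  ms <- mapping_spec(beads = list(P = "PO4", C1 = "C1", C2 = "C2"),
                     bonds = list(c("P", "C1"), c("C1", "C2")),
                     angles = list(c("P", "C1", "C2")))
  d <- bonded_distributions(map_aa_to_cg(tr$trajectory, ms), ms)
  for (term in c("P-C1", "C1-C2")) {
    h <- d$terms[[term]]
    expect_equal(sum(h$prob > 0), 1)
    peak <- h$mids[h$prob > 0]
    expect_lt(abs(peak - 0.3), 0.005)  # within the bin containing d
  }
  # straight chains: the P-C1-C2 angle is exactly 180
  a <- d$terms[["P-C1-C2"]]
  expect_equal(a$mids[a$prob > 0], 179)
})

test_that("Jensen-Shannon divergence matches hand and oracle values", {
  expect_equal(distribution_distance(c(0.3, 0.7), c(0.3, 0.7)),
               list(jsd_bits = 0, overlap = 1))
  d <- distribution_distance(c(1, 0), c(0, 1))
  expect_equal(d$jsd_bits, 1)
  expect_equal(d$overlap, 0)
  # frozen hand computation for p = (1/2, 1/2), q = (1, 0)
  expect_equal(distribution_distance(c(0.5, 0.5), c(1, 0))$jsd_bits,
               0.311278124459133, tolerance = 1e-12)
})

test_that("JSD is symmetric, bounded and matches an entropy-identity oracle", {
  set.seed(38)
  H <- function(p) {
    nz <- p > 0
    -sum(p[nz] * log2(p[nz]))
  }
  for (i in 1:25) {
    k <- sample(2:12, 1)
    p <- runif(k); p <- p / sum(p)
    q <- runif(k); q <- q / sum(q)
    d1 <- distribution_distance(p, q)
    d2 <- distribution_distance(q, p)
    expect_equal(d1$jsd_bits, d2$jsd_bits, tolerance = 1e-12)
    expect_gte(d1$jsd_bits, 0)
    expect_lte(d1$jsd_bits, 1 + 1e-12)
    expect_true(d1$overlap >= 0 && d1$overlap <= 1)
    # independent identity: JSD = H(m) - (H(p) + H(q))/2
    expect_equal(d1$jsd_bits,
                 H((p + q) / 2) - (H(p) + H(q)) / 2, tolerance = 1e-10)
  }
})

test_that("mismatched binning is an error, not a silent rebin", {
  h1 <- list(prob = c(0.5, 0.5), breaks = c(0, 1, 2), mids = c(0.5, 1.5))
  h2 <- list(prob = c(0.5, 0.5), breaks = c(0, 2, 4), mids = c(1, 3))
  expect_error(distribution_distance(h1, h2), "mismatched binning")
  expect_error(distribution_distance(c(0.5, 0.5), c(1, 0, 0)),
               "mismatched binning")
})

test_that("validation reports pass/fail per term and overall", {
  spec <- bilayer_spec(n_per_leaflet = 4, tilt_mode = "fixed_angle",
                       tilt_param = 0, d_lat = 0, seed = 39)
  tr <- generate_bilayer_trajectory(spec, 5, 100)
  ms <- mapping_spec(beads = list(P = "PO4", C1 = "C1", C2 = "C2"),
                     bonds = list(c("P", "C1"), c("C1", "C2")))
  d <- bonded_distributions(map_aa_to_cg(tr$trajectory, ms), ms)
  rep1 <- validation_report(d, d)
  expect_true(all(rep1$pass))
  expect_true(attr(rep1, "overall_pass"))
  expect_true(attr(validation_report(d, d, jsd_threshold = 0),
                   "overall_pass"))  # JSD is exactly 0 for identical input
  # a disjoint term fails and is named
  d2 <- d
  d2$terms[["P-C1"]]$prob <- rev(d2$terms[["P-C1"]]$prob)
  rep2 <- validation_report(d, d2)
  expect_false(rep2$pass[rep2$term == "P-C1"])
  expect_false(attr(rep2, "overall_pass"))
  expect_true(rep2$pass[rep2$term == "C1-C2"])
  # a term missing on one side is untestable and fails overall
  d3 <- d
  d3$terms[["P-C1"]] <- NULL
  rep3 <- validation_report(d, d3)
  expect_false(attr(rep3, "overall_pass"))
  expect_true(is.na(rep3$jsd_bits[rep3$term == "P-C1"]))
})

test_that("YAML mapping specs round-trip through the reader", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("beads:",
               "  P: [PO4]",
               "  C1: [C1]",
               "bonds:",
               "  - [P, C1]",
               "angles: []",
               "dihedrals: []"), path)
  ms <- read_mapping_spec(path)
  expect_identical(names(ms$beads), c("P", "C1"))
  expect_identical(ms$bonds[[1]], c("P", "C1"))
})
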