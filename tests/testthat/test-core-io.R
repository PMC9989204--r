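test_that("GRO write/read roundtrips coordinates to 3 decimals", {
  set.seed(42)
  st <- site_table(sprintf("A%d", 1:7), c(rep("PL", 4), rep("RL", 3)),
                   c(1, 1, 1, 1, 2, 2, 2))
  coords <- matrix(runif(21, 0, 5), 7, 3)
  fr <- md_frame(coords, c(5, 5, 5), time = 120)
  path <- tempfile(fileext = ".gro")
  write_gro(st, fr, path)
  back <- read_gro(path)
  expect_lt(max(abs(back$frame$coords - fr$coords)), 5.001e-4)
  expect_equal(back$frame$box, c(5, 5, 5))
  expect_equal(back$frame$time, 120)
  expect_equal(back$sites$site_name, st$site_name)
  expect_equal(back$sites$residue_name, st$residue_name)
})

test_that("GRO formatting uses fixed 3-decimal columns", {
  st <- site_table("P", "PL", 1)
  fr <- md_frame(rbind(c(0.05, 0.05, 0.05)), c(1, 1, 1))
  path <- tempfile(fileext = ".gro")
  write_gro(st, fr, path)
  expect_true(any(grepl("0.050   0.050   0.050", readLines(path),
                        fixed = TRUE)))
})

test_that("multi-frame GRO roundtrips as a trajectory", {
  st <- site_table(c("A", "B"), "PL", 1)
  arr <- array(runif(2 * 3 * 4), c(2, 3, 4))
  arr <- round(arr, 3)
  traj <- md_trajectory(st, arr, c(0, 10, 20, 30), c(3, 3, 3))
  path <- tempfile(fileext = ".gro")
  write_gro_trajectory(traj, path)
  back <- read_gro(path)
  expect_false(is.null(back$trajectory))
  expect_equal(n_frames(back$trajectory), 4)
  expect_equal(back$trajectory$coords, traj$coords, tolerance = 1e-12)
  expect_equal(back$trajectory$times, traj$times)
})

test_that("GRO parse errors name the offending line", {
  path <- tempfile(fileext = ".gro")
  writeLines(c("title", "3",
               "    1PL       A    1   0.000   0.000   0.000",
               "    1PL       B    2   0.100   0.200   0.300",
               "   1.0 1.0 1.0"), path)
  expect_error(read_gro(path), "line")
  writeLines(c("title", "x",
               "    1PL       A    1   0.000   0.000   0.000",
               "   1.0"), path)
  expect_error(read_gro(path), "atom count.*line 2")
})

test_that("triclinic box lines are rejected, orthorhombic 9-field accepted", {
  base <- c("title", "1", "    1PL       A    1   0.100   0.200   0.300")
  path <- tempfile(fileext = ".gro")
  writeLines(c(base, "  2.0 2.0 2.0 0.0 0.0 0.0 0.0 0.5 0.0"), path)
  expect_error(read_gro(path), "off-diagonal|triclinic")
  writeLines(c(base, "  2.0 2.0 2.0 0.0 0.0 0.0 0.0 0.0 0.0"), path)
  expect_equal(read_gro(path)$frame$box, c(2, 2, 2))
})

test_that("GRO refuses site counts beyond its fixed field width", {
  n <- 100001L
  st <- site_table(rep("W", n), "SOL", seq_len(n))
  fr <- md_frame(matrix(0.5, n, 3), c(50, 50, 50))
  expect_error(write_gro(st, fr, tempfile()), "99,999")
})

test_that("site tables validate their invariants", {
  expect_error(site_table(character(0), "PL", integer(0)), "at least one")
  expect_error(site_table("A", "PL", 1, mass = 0), "mass")
  expect_error(site_table("A", "PL", 1, electrons = -1), "electron")
  expect_error(site_table("A", "PL", 1, polarity_class = "greasy"),
               "polarity_class")
  expect_error(site_table("A", "PL", 1, chain_position = 2),
               "chain_label")
  tab <- site_table(c("A", "B"), "PL", 1)
  tab$site_id <- c(5L, 6L)
  expect_error(validate_site_table(tab), "contiguous")
})

test_that("site table TSV roundtrips including NA chain fields", {
  st <- site_table(c("PO4", "C1", "W"), c("PL", "PL", "SOL"), c(1, 1, 2),
                   mass = c(94, 56, 18), charge = c(-1, 0, 0),
                   electrons = c(47, 32, 10),
                   polarity_class = c("phosphate", "apolar", "water"),
                   chain_label = c(NA, "sn1", NA),
                   chain_position = c(NA, 1, NA))
  path <- tempfile(fileext = ".tsv")
  write_site_table(st, path)
  expect_identical(strsplit(readLines(path, n = 1), "\t")[[1]],
                   c("site_id", "site_name", "residue_name", "molecule_id",
                     "mass", "charge", "electrons", "polarity_class",
                     "chain_label", "chain_position"))
  back <- read_site_table(path)
  expect_equal(as.data.frame(back), as.data.frame(st))
})

test_that("TRJTXT roundtrips bit-exactly", {
  st <- site_table(c("A", "B", "C"), "PL", 1)
  arr <- array(rnorm(3 * 3 * 5), c(3, 3, 5))
  traj <- md_trajectory(st, arr, c(0, 7, 14, 21, 28), c(4, 4, 9), dt = 7)
  path <- tempfile(fileext = ".trjtxt")
  write_trjtxt(traj, path)
  back <- read_trjtxt(path, st)
  expect_identical(back$coords, traj$coords)
  expect_identical(back$times, traj$times)
  expect_identical(back$boxes, traj$boxes)
  expect_error(read_trjtxt(path, site_table(c("A", "B"), "PL", 1)),
               "site")
})

test_that("minimum image wraps components into (-L/2, L/2]", {
  expect_equal(minimum_image_vector(c(0, 0, 0), c(0.95, 0, 0), c(1, 1, 1)),
               c(-0.05, 0, 0))
  expect_equal(sqrt(sum(minimum_image_vector(c(0, 0, 0), c(0.95, 0, 0),
                                             c(1, 1, 1))^2)), 0.05)
  expect_equal(minimum_image_vector(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3),
                                    c(1, 1, 1)), c(0, 0, 0))
  d <- minimum_image_vector(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2),
                            c(10, 10, 10))
  expect_equal(sqrt(sum(d^2)), sqrt(0.03), tolerance = 1e-12)
  expect_error(minimum_image_vector(c(0, 0, 0), c(1, 1, 1), c(1, 0, 1)),
               "box")
})

test_that("minimum image norm is symmetric and bounded by half diagonal", {
  set.seed(7)
  box <- c(3, 5, 8)
  for (i in 1:50) {
    a <- runif(3, -10, 10)
    b <- runif(3, -10, 10)
    dab <- minimum_image_vector(a, b, box)
    dba <- minimum_image_vector(b, a, box)
    expect_equal(sqrt(sum(dab^2)), sqrt(sum(dba^2)), tolerance = 1e-12)
    expect_lte(sqrt(sum(dab^2)), sqrt(sum((box / 2)^2)) + 1e-12)
    expect_true(all(dab > -box / 2 - 1e-12 & dab <= box / 2 + 1e-12))
  }
})

test_that("selection language matches classes, names and ids", {
  spec <- bilayer_spec(n_per_leaflet = 64, seed = 3)
  b <- build_bilayer(spec)
  expect_length(select_sites(b$sites, "polarity_class == phosphate"), 128)
  expect_length(select_sites(b$sites, "residue_name == XYZ"), 0)
  expect_identical(select_sites(b$sites, "all"), b$sites$site_id)
  expect_length(select_sites(b$sites, "none"), 0)
  expect_length(select_sites(b$sites, "site_name == PO4 & molecule_id <= 2"),
                2)
  expect_length(select_sites(b$sites,
                             "chain_label == sn1 & chain_position in (1, 2)"),
                256)
  expect_length(select_sites(b$sites,
                             'site_name in ("NH3", "PO4") | site_name == C1'),
                384)
  expect_length(select_sites(b$sites, "not polarity_class == apolar"), 256)
  # results are ascending site_id regardless of construction
  got <- select_sites(b$sites, "polarity_class == phosphate")
  expect_identical(got, sort(got))
})

test_that("selection syntax errors carry a character position", {
  tab <- site_table("A", "PL", 1)
  expect_error(select_sites(tab, "polarity_class =="), "position")
  expect_error(select_sites(tab, "bogus_field == 1"), "position 1")
  expect_error(select_sites(tab, "site_name < A"), "ordering")
  expect_error(select_sites(tab, "(site_name == A"), "position")
  expect_error(select_sites(tab, "molecule_id == abc"), "numeric")
})

test_that("trajectory containers enforce their invariants", {
  st <- site_table(c("A", "B"), "PL", 1)
  arr <- array(0, c(2, 3, 3))
  expect_error(md_trajectory(st, arr, c(0, 10, 10), c(1, 1, 1)),
               "strictly increasing")
  expect_error(md_trajectory(st, array(0, c(3, 3, 3)), c(0, 1, 2),
                             c(1, 1, 1)), "does not match")
  expect_error(md_frame(matrix(0, 2, 3), c(1, -1, 1)), "positive")
  tr <- md_trajectory(st, arr, c(0, 10, 20), c(1, 2, 3))
  expect_equal(get_frame(tr, 2)$time, 10)
  expect_equal(n_sites(tr), 2)
})
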