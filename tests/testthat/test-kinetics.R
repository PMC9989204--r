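ballistic_traj <- function(v = 0.01, nf = 40, dt = 10) {
  # two molecules per leaflet moving at +/- v: leaflet COM stays put
  st <- site_table(rep("PO4", 4), "PL", 1:4, polarity_class = "phosphate")
  frames <- lapply(seq_len(nf) - 1, function(f) {
    t <- f * dt
    cbind(c(10 + v * t, 10 - v * t, 10 + v * t, 10 - v * t),
          rep(10, 4), c(12, 12, 8, 8))
  })
  point_traj(frames, c(1000, 1000, 20),
             times = (seq_len(nf) - 1) * dt, sites = st)
}

test_that("ballistic motion gives MSD = v^2 t^2 exactly", {
  v <- 0.01
  tr <- ballistic_traj(v)
  asg <- assign_leaflets(tr)
  msd <- lateral_msd(tr, "all", asg)
  expect_equal(msd$msd_nm2, v^2 * msd$lag_ps^2, tolerance = 1e-10)
})

test_that("a static system has zero MSD and zero fitted D", {
  st <- site_table(rep("PO4", 4), "PL", 1:4, polarity_class = "phosphate")
  xyz <- cbind(runif(4, 0, 5), runif(4, 0, 5), c(6, 6, 2, 2))
  tr <- point_traj(replicate(30, xyz, simplify = FALSE), c(5, 5, 8),
                   sites = st)
  asg <- assign_leaflets(tr)
  msd <- lateral_msd(tr, "all", asg)
  expect_equal(msd$msd_nm2, rep(0, nrow(msd)), tolerance = 1e-12)
  expect_equal(fit_diffusion(msd)$D_nm2_per_ps, 0, tolerance = 1e-12)
})

test_that("FFT MSD matches the naive all-origin oracle", {
  set.seed(33)
  nf <- 64
  st <- site_table(rep("PO4", 6), "PL", 1:6, polarity_class = "phosphate")
  steps_x <- matrix(rnorm(nf * 6, 0, 0.05), nf, 6)
  steps_y <- matrix(rnorm(nf * 6, 0, 0.05), nf, 6)
  xs <- apply(steps_x, 2, cumsum)
  ys <- apply(steps_y, 2, cumsum)
  frames <- lapply(seq_len(nf), function(f)
    cbind(xs[f, ] + 50, ys[f, ] + 50, c(12, 12, 12, 8, 8, 8)))
  tr <- point_traj(frames, c(100, 100, 20), sites = st)
  asg <- assign_leaflets(tr)
  msd <- lateral_msd(tr, "all", asg)
  # oracle: subtract the leaflet centre then naive O(F^2) averaging
  max_lag <- floor((nf - 1) / 2)
  acc <- numeric(max_lag + 1)
  for (leaf in list(1:3, 4:6)) {
    cx <- rowMeans(xs[, leaf]); cy <- rowMeans(ys[, leaf])
    for (j in leaf)
      acc <- acc + naive_msd_track(cbind(xs[, j] - cx, ys[, j] - cy),
                                   max_lag)
  }
  expect_equal(msd$msd_nm2, acc / 6, tolerance = 1e-10)
})

test_that("wrapped coordinates are rejected", {
  st <- site_table(rep("PO4", 2), "PL", 1:2, polarity_class = "phosphate")
  frames <- list(rbind(c(0.1, 1, 3), c(1, 1, 1)),
                 rbind(c(3.9, 1, 3), c(1, 1, 1)))  # jump of 3.8 in box 4
  tr <- point_traj(frames, c(4, 4, 4), sites = st)
  asg <- assign_leaflets(tr)
  expect_error(lateral_msd(tr, "all", asg), "unwrapped")
})

test_that("molecules that change leaflet are excluded from the MSD", {
  st <- site_table(rep("PO4", 3), "PL", 1:3, polarity_class = "phosphate")
  frames <- lapply(0:19, function(f) {
    z3 <- if (f < 10) 6 else 2  # molecule 3 flips midway
    cbind(c(1, 2, 3), c(1, 2, 3), c(6, 2, z3))
  })
  tr <- point_traj(frames, c(50, 50, 8), sites = st)
  asg <- assign_leaflets(tr)
  msd <- lateral_msd(tr, "all", asg)
  expect_equal(attr(msd, "excluded"), 3)
  expect_equal(attr(msd, "n_molecules"), 2)
})

test_that("fit_diffusion recovers exact lines and rejects bad windows", {
  lag <- seq(0, 1000, by = 10)
  msd <- data.frame(lag_ps = lag, msd_nm2 = 4 * 0.002 * lag)
  expect_equal(fit_diffusion(msd)$D_nm2_per_ps, 0.002, tolerance = 1e-12)
  expect_error(fit_diffusion(msd, window = c(0.5, 0.1)), "window")
  expect_error(fit_diffusion(msd[1:6, ], window = c(0.9, 1)), "fewer than 5")
})

test_that("flip-flop residency rule accepts 12 ns and rejects 8 ns", {
  # labels sampled every 500 ps over 40 ns
  times <- seq(0, 40000, by = 500)
  mk <- function(start, res) {
    lab <- rep("lower", length(times))
    lab[times >= start & times < start + res] <- "upper"
    lab
  }
  labels <- cbind(mk(5000, 12000), mk(5000, 8000))
  asg <- manual_assignment(labels, times = times)
  ev <- detect_flipflops(asg, min_residency = 10000)
  expect_equal(nrow(ev), 2)
  expect_true(ev$accepted[ev$molecule_id == 1])
  expect_false(ev$accepted[ev$molecule_id == 2])
  expect_false(any(ev$censored))
  expect_equal(ev$residency_ps, c(12000, 8000))
  expect_identical(ev$departure, c("lower", "lower"))
})

test_that("rapid midplane oscillation yields no accepted events", {
  times <- seq(0, 40000, by = 500)
  lab <- rep(c("lower", "upper"), length.out = length(times))
  asg <- manual_assignment(cbind(lab), times = times)
  ev <- detect_flipflops(asg, min_residency = 10000)
  expect_equal(sum(ev$accepted), 0)
})

test_that("accepted count is monotone non-increasing in the threshold", {
  set.seed(34)
  times <- seq(0, 60000, by = 250)
  labels <- replicate(6, {
    lab <- rep("lower", length(times))
    for (k in 1:3) {
      start <- runif(1, 0, 50000)
      res <- runif(1, 500, 25000)
      lab[times >= start & times < start + res] <- "upper"
    }
    lab
  })
  asg <- manual_assignment(labels, times = times)
  counts <- vapply(c(1000, 5000, 10000, 20000), function(thr)
    sum(detect_flipflops(asg, min_residency = thr)$accepted), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("transiting frames bridge a crossing without resetting residency", {
  times <- seq(0, 30000, by = 1000)
  lab <- rep("lower", length(times))
  lab[times >= 5000 & times < 8000] <- "transiting"
  lab[times >= 8000 & times < 21000] <- "upper"
  lab[times >= 12000 & times < 13000] <- "transiting"  # mid-excursion dip
  asg <- manual_assignment(cbind(lab), times = times)
  ev <- detect_flipflops(asg, min_residency = 10000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_cross_ps, 8000)
  expect_equal(ev$residency_ps, 13000)
  expect_true(ev$accepted)
})

test_that("a crossing running past the end is censored unless already long
           enough", {
  times <- seq(0, 30000, by = 1000)
  lab <- rep("lower", length(times))
  lab[times >= 25000] <- "upper"  # 5 ns observed, never returns
  asg <- manual_assignment(cbind(lab), times = times)
  ev <- detect_flipflops(asg, min_residency = 10000)
  expect_false(ev$accepted)
  expect_true(ev$censored)
  # same geometry but threshold below the observed residency: accepted
  ev2 <- detect_flipflops(asg, min_residency = 4000)
  expect_true(ev2$accepted)
  expect_false(ev2$censored)
  expect_error(detect_flipflops(manual_assignment(cbind("upper"),
                                                  times = 0)),
               "more than one frame")
})
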