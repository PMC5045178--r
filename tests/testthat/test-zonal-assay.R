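filled_disc <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  yy <- matrix(seq_len(n) - cy, n, n)
  xx <- matrix(rep(seq_len(n) - cx, each = n), n, n)
  yy^2 + xx^2 <= r^2
}

filled_ellipse <- function(ny, nx, a, b, theta = 0,
                           cy = (ny + 1) / 2, cx = (nx + 1) / 2) {
  yy <- matrix(seq_len(ny) - cy, ny, nx)
  xx <- matrix(rep(seq_len(nx) - cx, each = ny), ny, nx)
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

test_that("mid-plane selection maximizes signal with the stated tie rules", {
  m <- array(FALSE, dim = c(9, 5, 5))
  m[4, 2:4, 2:4] <- TRUE
  expect_equal(select_midplane(m, z_window = 1), 4L)
  # per-plane counts 0,2,7,7,1: tie between planes 3 and 4, centre is 3
  m2 <- array(FALSE, dim = c(5, 4, 4))
  set_plane <- function(m, z, k) {
    pl <- m[z, , ]; pl[seq_len(k)] <- TRUE; m[z, , ] <- pl; m
  }
  m2 <- set_plane(m2, 2, 2)
  m2 <- set_plane(m2, 3, 7)
  m2 <- set_plane(m2, 4, 7)
  m2 <- set_plane(m2, 5, 1)
  counts <- rowSums(matrix(m2, nrow = 5))
  expect_equal(counts, c(0, 2, 7, 7, 1))
  expect_equal(select_midplane(m2, z_window = 1), 3L)
  # lower index wins when ties are equidistant from the centre
  m3 <- array(FALSE, dim = c(5, 3, 3))
  m3[2, 1, 1] <- TRUE; m3[4, 1, 1] <- TRUE
  expect_equal(select_midplane(m3, z_window = 1), 2L)
  expect_error(select_midplane(array(FALSE, c(5, 3, 3))), "no-signal")
})

test_that("shape eligibility accepts discs and rejects elongated masks", {
  disc <- filled_disc(101, 40)
  e1 <- check_eligibility(disc)
  expect_true(e1$eligible)
  expect_equal(unname(e1$metrics["axis_ratio"]), 1, tolerance = 0.02)
  expect_gt(e1$metrics["solidity"], 0.95)
  rect <- matrix(FALSE, 120, 120); rect[50:59, 11:110] <- TRUE
  e2 <- check_eligibility(rect)
  expect_false(e2$eligible)
  expect_lt(e2$metrics["axis_ratio"], 0.15)
  expect_error(check_eligibility(matrix(FALSE, 5, 5)), "empty")
})

test_that("a cohort of 10 round and 10 elongated masks is 50 percent eligible", {
  masks <- c(lapply(30:39, function(r) filled_disc(101, r)),
             lapply(1:10, function(i) {
               m <- matrix(FALSE, 120, 120); m[55:(55 + i), 6:115] <- TRUE; m
             }))
  elig <- vapply(masks, function(m) check_eligibility(m)$eligible, logical(1))
  expect_equal(100 * mean(elig), 50)
})

test_that("equivalent ellipse recovers circles, ellipses, and rotations", {
  disc <- filled_disc(121, 50)
  f1 <- fit_equivalent_ellipse(disc)
  expect_equal(f1$a, 50, tolerance = 0.02)
  expect_equal(f1$b, 50, tolerance = 0.02)
  ell <- filled_ellipse(101, 101, a = 40, b = 20)
  f2 <- fit_equivalent_ellipse(ell)
  expect_equal(f2$a, 40, tolerance = 0.02)
  expect_equal(f2$b, 20, tolerance = 0.02)
  expect_equal(abs(f2$orientation), 0, tolerance = 0.05)
  rot <- filled_ellipse(121, 121, a = 40, b = 20, theta = pi / 6)
  f3 <- fit_equivalent_ellipse(rot)
  expect_equal(f3$orientation, pi / 6, tolerance = 2 * pi / 180)
  expect_error(fit_equivalent_ellipse(matrix(c(TRUE, rep(FALSE, 24)), 5, 5)),
               "underdetermined")
})

test_that("zone boundaries sit at the closed-form equal-area radii", {
  # circle r = 300: boundaries at 300*sqrt(1/3) = 173.205, 300*sqrt(2/3) = 244.949
  ell <- structure(list(center = c(y = 350, x = 350), a = 300, b = 300,
                        orientation = 0), class = "ellipse_params")
  z <- build_equal_area_zones(ell, c(700, 700))
  rad <- function(m) {
    pts <- which(m, arr.ind = TRUE)
    sqrt((pts[, 1] - 350)^2 + (pts[, 2] - 350)^2)
  }
  expect_lt(max(rad(z$central)), 300 * sqrt(1 / 3) + 1e-9)
  expect_gt(min(rad(z$intermediate)), 300 * sqrt(1 / 3) - 1e-9)
  expect_lt(max(rad(z$intermediate)), 300 * sqrt(2 / 3) + 1e-9)
  expect_gt(min(rad(z$peripheral)), 300 * sqrt(2 / 3) - 1e-9)
  expect_lt(max(rad(z$peripheral)), 300 + 1e-9)
  expect_false(z$clipped)
})

test_that("zone pixel areas are equal within 1 percent for random ellipses", {
  set.seed(77)
  for (i in 1:5) {
    a <- runif(1, 100, 300)
    b <- a * runif(1, 0.5, 1)
    th <- runif(1, -pi / 2, pi / 2)
    ell <- structure(list(center = c(y = 330, x = 330), a = a, b = b,
                          orientation = th), class = "ellipse_params")
    z <- build_equal_area_zones(ell, c(660, 660))
    areas <- c(sum(z$peripheral), sum(z$intermediate), sum(z$central))
    expect_lt((max(areas) - min(areas)) / mean(areas), 0.01)
  }
  expect_error(build_equal_area_zones(
    structure(list(center = c(y = 10, x = 10), a = 5, b = 0, orientation = 0),
              class = "ellipse_params"), c(20, 20)), "degenerate")
})

test_that("uniform probe signal over the nucleus yields thirds; central signal yields (0,0,1)", {
  sp <- small_spec(noise_sd = 2)
  out <- generate_nucleus_stack(sp, 9)
  uniform <- out$stack
  uniform$channels$probe <- uniform$channels$dapi
  # explicit threshold: the within-nucleus histogram of a uniformly bright
  # probe is unimodal, which is not a use case for the automatic threshold
  zp <- run_zonal_assay(uniform, config = list(probe_threshold = 55))
  expect_true(zp$eligible)
  expect_equal(sum(zp$fractions), 1, tolerance = 1e-9)
  expect_true(all(abs(zp$fractions - 1 / 3) < 0.02))
  central <- generate_nucleus_stack(small_spec(radial_bias = 0,
                                               territory_fraction = 0.03,
                                               n_territories = 1L,
                                               noise_sd = 0), 9)
  zc <- run_zonal_assay(central$stack)
  expect_equal(unname(zc$fractions["central"]), 1, tolerance = 1e-6)
  expect_equal(unname(zc$fractions["peripheral"]), 0)
})

test_that("zone fractions are invariant to a 90-degree rotation of the plane", {
  out <- generate_nucleus_stack(small_spec(), 25)
  zp <- run_zonal_assay(out$stack)
  rot <- out$stack
  rot$channels$dapi <- aperm(out$stack$channels$dapi, c(1, 3, 2))[, , dim(out$stack$channels$dapi)[2]:1]
  rot$channels$probe <- aperm(out$stack$channels$probe, c(1, 3, 2))[, , dim(out$stack$channels$probe)[2]:1]
  zr <- run_zonal_assay(rot)
  expect_true(zr$eligible)
  expect_true(all(abs(zp$fractions - zr$fractions) < 0.02))
})

test_that("anisotropic xy voxel sizes raise a config error", {
  out <- generate_nucleus_stack(small_spec(), 2)
  bad <- out$stack
  bad$voxel_size <- c(0.25, 0.15, 0.2)
  expect_error(run_zonal_assay(bad), "isotropic")
})

test_that("mean recovered central fraction tracks calibrated truth within 3 points", {
  for (target in c(0.17, 0.20, 0.33, 0.50)) {
    sp <- small_spec(territory_fraction = 0.10)
    seeds <- vapply(1:10, function(i) xterritory:::derive_seed(round(100 * target), i),
                    integer(1))
    recovered <- truth <- numeric(10)
    for (i in 1:10) {
      rb <- calibrate_radial_bias(sp, target, seed = seeds[i])
      sp_i <- sp; sp_i$radial_bias <- as.numeric(rb)
      out <- generate_nucleus_stack(sp_i, seeds[i])
      zp <- run_zonal_assay(out$stack)
      expect_true(zp$eligible)
      recovered[i] <- zp$fractions["central"]
      truth[i] <- out$truth$true_zone_masses["central"]
    }
    expect_lt(abs(mean(recovered) - mean(truth)), 0.03)
    expect_lt(abs(mean(truth) - target), 0.02)
  }
})
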