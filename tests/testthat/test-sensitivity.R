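test_that("fluence is absorption divided by the local mua", {
  # 2x2x1 toy volume: two tissues plus air
  labs <- array(c(1L, 2L, 0L, 1L), dim = c(2, 2, 1))
  vol <- labeled_volume(labs, 1,
                        label_names = c(air = 0L, a = 1L, b = 2L))
  tab <- as_tissue_table(data.frame(label = 1:2, tissue = c("a", "b"),
                                    n = 1, mua = c(2.0, 0.5),
                                    mus = c(10, 10), g = 0))
  A <- array(c(0.5, 0.2, 0.7, 0.0), dim = c(2, 2, 1))
  f <- fluence_from_absorption(A, vol, tab, launched = 1)
  expect_equal(f[1, 1, 1], 0.25)    # 0.5 / 2.0
  expect_equal(f[2, 1, 1], 0.4)     # 0.2 / 0.5
  expect_equal(f[1, 2, 1], 0)       # air voxel: zero regardless of A
  expect_equal(f[2, 2, 1], 0)
  # zero map in, zero map out
  expect_true(all(fluence_from_absorption(array(0, dim(A)), vol, tab,
                                          launched = 1) == 0))
  expect_error(fluence_from_absorption(array(-1, dim(A)), vol, tab,
                                       launched = 1), "negative")
})

test_that("absorption-derived fluence agrees with the pathlength tally", {
  med <- tiny_medium(mua = 0.5, mus = 20, g = 0.8)
  src <- source_config(15, 15)
  det <- detector_config(15, 15)
  diffs <- vapply(1:6, function(s) {
    res <- propagate(med$volume, med$table, src, det,
                     quick_run(4000, seed = 100 + s, tally_fluence = TRUE))
    f_abs <- fluence_from_absorption(res, med$volume, med$table)
    sum(f_abs) - sum(res$tally) / res$launched
  }, numeric(1))
  # the two estimators target the same total fluence: the mean
  # difference over independent runs is zero within 3 standard errors
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
  expect_lt(abs(mean(diffs)) / 2, 0.05)  # and they are close in scale
})

test_that("ssd_map is the commutative voxelwise product", {
  f1 <- array(c(0.2, 0.1), dim = c(2, 1, 1))
  f2 <- array(c(0.3, 0.4), dim = c(2, 1, 1))
  s <- ssd_map(f1, f2)
  expect_equal(as.numeric(s), c(0.06, 0.04))
  expect_equal(as.numeric(ssd_map(f2, f1)), as.numeric(s))
  expect_true(all(ssd_map(f1, array(0, dim(f1))) == 0))
  expect_error(ssd_map(f1, array(1, c(3, 1, 1))), "mismatch")
})

test_that("SSD proportions are normalized percentages per tissue", {
  labs <- array(1L, dim = c(3, 3, 1))
  vol <- labeled_volume(labs, 1, label_names = c(air = 0L, only = 1L))
  ssd <- array(runif(9), dim = dim(labs))
  tab <- tissue_ssd_proportions(ssd, vol)
  expect_equal(tab$proportion_pct[tab$tissue == "only"], 100)

  st <- small_thorax()
  ssd2 <- array(abs(rnorm(length(st$volume$labels))),
                dim = dim(st$volume$labels))
  t2 <- tissue_ssd_proportions(ssd2, st$volume)
  expect_equal(sum(t2$proportion_pct), 100, tolerance = 1e-9)
  expect_true(all(t2$proportion_pct >= 0))
  # canonical reporting order
  expect_equal(t2$tissue[1:3], c("fat", "skin", "lung"))
  # proportions are invariant to global rescaling
  t3 <- tissue_ssd_proportions(ssd2 * 17.3, st$volume)
  expect_equal(t3$proportion_pct, t2$proportion_pct, tolerance = 1e-12)
  expect_error(tissue_ssd_proportions(array(0, dim(ssd2)), st$volume),
               "zero")
})

test_that("Eq-style pipeline is quadratic under scaling of absorption", {
  med <- tiny_medium()
  src <- source_config(15, 15)
  res <- propagate(med$volume, med$table, src, detector_config(15, 15),
                   quick_run(3000, seed = 44))
  f <- fluence_from_absorption(res, med$volume, med$table)
  c_ <- 2.5
  f_scaled <- fluence_from_absorption(res$absorption * c_, med$volume,
                                      med$table, launched = res$launched)
  s1 <- ssd_map(f, f)
  s2 <- ssd_map(f_scaled, f_scaled)
  expect_equal(sum(s2), c_^2 * sum(s1), tolerance = 1e-12)
})

test_that("adjoint fluence mirrors the forward map in a symmetric medium", {
  med <- tiny_medium(mua = 0.3, mus = 25, g = 0.8, nx = 80, nz = 80,
                     thickness_mm = 12, voxel_mm = 0.5)
  pa <- c(14, 20); pb <- c(26, 20)
  run <- quick_run(2e4, seed = 55)
  f_fwd <- fluence_from_absorption(
    propagate(med$volume, med$table, source_config(pa[1], pa[2]),
              detector_config(pb[1], pb[2]), run),
    med$volume, med$table)
  f_adj <- adjoint_fluence(med$volume, med$table,
                           detector_config(pb[1], pb[2]), run)
  # mirror the adjoint map about the midplane between the two sites
  f_mirror <- f_adj[rev(seq_len(dim(f_adj)[1])), , ]
  # compare depth profiles under the two sites (coarse, stochastic)
  ix_a <- floor(pa[1] / 0.5) + 1
  pf <- f_fwd[ix_a, , 40]
  pm <- f_mirror[ix_a, , 40]
  sel <- pf > 0 & pm > 0
  expect_gt(cor(log(pf[sel]), log(pm[sel])), 0.97)
})

test_that("penetration depth is read off the fluence floor", {
  labs <- array(1L, dim = c(5, 30, 5))
  vol <- labeled_volume(labs, 1, label_names = c(air = 0L, t = 1L))
  # synthetic monotone profile crossing the floor (1 per 1e6) at voxel 11
  prof <- 10^seq(2, -8, length.out = 30)
  k <- which(prof * 1e6 < 1)[1]
  F <- array(rep(prof, each = 5), dim = c(5, 30, 5))
  pp <- penetration_profile(F, vol, entry = c(2.5, 2.5))
  expect_equal(pp$penetration_depth_mm, (k - 1) * vol$voxel_mm)
  expect_equal(nrow(pp$profile), 30)
  # all-zero map: zero depth
  p0 <- penetration_profile(array(0, dim(F)), vol, entry = c(2.5, 2.5))
  expect_equal(p0$penetration_depth_mm, 0)
  expect_error(penetration_profile(F, vol, entry = c(99, 2.5)), "outside")
})

test_that("fluence decays monotonically with depth in a homogeneous
           medium beyond the source zone", {
  med <- tiny_medium(mua = 0.5, mus = 30, g = 0.8, nx = 60, nz = 60,
                     thickness_mm = 15, voxel_mm = 0.5)
  res <- propagate(med$volume, med$table, source_config(15, 15),
                   detector_config(15, 15), quick_run(2e4, seed = 8))
  f <- fluence_from_absorption(res, med$volume, med$table)
  pp <- penetration_profile(f, med$volume, entry = c(15, 15))
  prof <- pp$profile
  sm <- stats::filter(prof$intensity, rep(1 / 3, 3), sides = 2)
  sel <- which(prof$depth_mm > 2 & prof$depth_mm < 12)
  expect_true(all(diff(sm[sel]) < 0))
})
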