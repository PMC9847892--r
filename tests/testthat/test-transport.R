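test_that("non-scattering matched slab reproduces Beer-Lambert decay", {
  sl <- build_slab_phantom(data.frame(thickness_mm = 10, n = 1, mua = 1,
                                      mus = 1e-9, g = 0),
                           nx = 40, nz = 40, voxel_mm = 0.5)
  src <- source_config(10, 10)
  res <- propagate(sl$volume, sl$table, src, detector_config(10, 10),
                   quick_run(2e4, seed = 7, roulette = FALSE))
  t <- res$totals
  T_hat <- unname(t["exit_bottom"] / t["launched"])
  p <- exp(-1)                    # transmit probability, full weight
  se <- sqrt(p * (1 - p) / t[["launched"]])
  expect_lt(abs(T_hat - p), 3 * se)
  # absorbed fraction is the complement
  expect_lt(abs(t[["absorbed"]] / t[["launched"]] - (1 - p)), 3 * se)
})

test_that("energy is conserved exactly with roulette off and in
           expectation with roulette on", {
  med <- tiny_medium()
  src <- source_config(15, 15)
  det <- detector_config(20, 15)
  bal <- function(t) {
    (t[["launched"]] - t[["absorbed"]] - t[["specular"]] -
       t[["exit_top"]] - t[["exit_bottom"]] - t[["exit_side"]] -
       t[["roulette_killed"]] + t[["roulette_injected"]]) / t[["launched"]]
  }
  off <- propagate(med$volume, med$table, src, det,
                   quick_run(2e4, seed = 3, roulette = FALSE))
  expect_lt(abs(bal(off$totals)), 1e-12)
  expect_equal(unname(off$totals[["roulette_killed"]]), 0)
  # map total equals the absorbed tally
  expect_equal(sum(off$absorption), unname(off$totals[["absorbed"]]),
               tolerance = 1e-12)

  on <- propagate(med$volume, med$table, src, det,
                  quick_run(1e5, seed = 3, roulette = TRUE))
  t <- on$totals
  drift <- (t[["launched"]] - t[["absorbed"]] - t[["specular"]] -
              t[["exit_top"]] - t[["exit_bottom"]] -
              t[["exit_side"]]) / t[["launched"]]
  expect_lt(abs(drift), 5e-3)
  # and the roulette ledger itself balances exactly
  expect_lt(abs(bal(t)), 1e-12)
})

test_that("absorption map is empty where absorption vanishes", {
  sl <- build_slab_phantom(data.frame(thickness_mm = 8, n = 1, mua = 0,
                                      mus = 15, g = 0.5),
                           nx = 30, nz = 30, voxel_mm = 0.5)
  res <- propagate(sl$volume, sl$table, source_config(7.5, 7.5),
                   detector_config(7.5, 7.5),
                   quick_run(5000, seed = 9, roulette = FALSE))
  expect_true(all(res$absorption == 0))
  t <- res$totals
  expect_equal(t[["launched"]],
               t[["specular"]] + t[["exit_top"]] + t[["exit_bottom"]] +
                 t[["exit_side"]])
})

test_that("per-record partial path lengths sum to the total", {
  st <- small_thorax()
  tab <- default_tissue_table()
  src <- source_config(st$cfg$source_x_mm, st$cfg$source_z_mm)
  det <- detector_config(st$cfg$source_x_mm + 10, st$cfg$source_z_mm, 8)
  res <- propagate(st$volume, tab, src, det,
                   quick_run(2e4, seed = 21, record_all_exits = TRUE))
  expect_gt(nrow(res$records), 50)
  pcols <- grep("^path_.*_cm$", names(res$records), value = TRUE)
  pcols <- setdiff(pcols, "path_region_cm")
  sums <- rowSums(res$records[, pcols])
  expect_lt(max(abs(sums - res$records$total_cm) /
                  pmax(res$records$total_cm, 1e-12)), 1e-9)
  # weights lie in (0, 1]
  expect_true(all(res$records$weight > 0 & res$records$weight <= 1))
})

test_that("identical seeds give bit-identical results, new seeds differ", {
  med <- tiny_medium()
  src <- source_config(15, 15); det <- detector_config(19, 15, 4)
  a <- propagate(med$volume, med$table, src, det, quick_run(4000, seed = 5))
  b <- propagate(med$volume, med$table, src, det, quick_run(4000, seed = 5))
  expect_identical(a$absorption, b$absorption)
  expect_identical(a$records, b$records)
  expect_identical(a$totals, b$totals)
  c <- propagate(med$volume, med$table, src, det, quick_run(4000, seed = 6))
  expect_false(identical(a$totals, c$totals))
})

test_that("source placement off the tissue surface is rejected", {
  st <- small_thorax()
  tab <- default_tissue_table()
  expect_error(propagate(st$volume, tab, source_config(-5, 10),
                         detector_config(10, 10), quick_run(10)),
               "outside")
  # a volume whose entry voxel is air
  labs <- st$volume$labels
  labs[, , ] <- tissue_labels()[["air"]]
  allair <- labeled_volume(labs, st$volume$voxel_mm,
                           tissue_surface_mm = st$volume$tissue_surface_mm)
  expect_error(propagate(allair, tab,
                         source_config(st$cfg$source_x_mm,
                                       st$cfg$source_z_mm),
                         detector_config(10, 10), quick_run(10)),
               "air")
})

test_that("unmapped tissue labels abort the run", {
  med <- tiny_medium()
  tab2 <- med$table[med$table$label == 1, ]
  vol <- med$volume
  vol$labels[30, 10, 30] <- 2L
  vol$label_names <- c(vol$label_names, layer2 = 2L)
  expect_error(propagate(vol, tab2, source_config(15, 15),
                         detector_config(15, 15), quick_run(100)),
               "without optical properties")
})

test_that("averaging results is the voxelwise mean with concatenated
           records", {
  med <- tiny_medium()
  src <- source_config(15, 15); det <- detector_config(18, 15, 6)
  r1 <- propagate(med$volume, med$table, src, det, quick_run(3000, seed = 1))
  r2 <- propagate(med$volume, med$table, src, det, quick_run(3000, seed = 2))
  avg <- average_results(list(r1, r2))
  expect_equal(avg$absorption, (r1$absorption + r2$absorption) / 2)
  expect_equal(nrow(avg$records), nrow(r1$records) + nrow(r2$records))
  expect_equal(avg$totals, (r1$totals + r2$totals) / 2)
  # averaging identical inputs is the identity
  same <- average_results(list(r1, r1))
  expect_equal(same$absorption, r1$absorption)
  # mean of 4 seeded runs equals the brute-force sum / 4
  rs <- lapply(1:4, function(s)
    propagate(med$volume, med$table, src, det, quick_run(1000, seed = s)))
  m4 <- average_results(rs)
  expect_equal(m4$absorption,
               Reduce(`+`, lapply(rs, `[[`, "absorption")) / 4)
  # dimension mismatch is an error
  other <- tiny_medium(nx = 20, nz = 20)
  r3 <- propagate(other$volume, other$table, source_config(5, 5),
                  detector_config(5, 5), quick_run(500))
  expect_error(average_results(list(r1, r3)), "mismatch")
})

test_that("source-detector reciprocity holds in a homogeneous medium", {
  med <- tiny_medium(mua = 0.2, mus = 15, g = 0.8, nx = 80, nz = 80,
                     thickness_mm = 15)
  a <- source_config(12, 20); b <- source_config(28, 20)
  run <- quick_run(4e4, seed = 31)
  f <- propagate(med$volume, med$table, a,
                 detector_config(b$x_mm, b$z_mm, 6), run)
  r <- propagate(med$volume, med$table, b,
                 detector_config(a$x_mm, a$z_mm, 6), run)
  wf <- f$records$weight; wr <- r$records$weight
  se <- sqrt(sum(wf^2) + sum(wr^2))
  expect_lt(abs(sum(wf) - sum(wr)), 3 * se)
})

test_that("detected mean path length grows with separation", {
  med <- tiny_medium(mua = 0.05, mus = 50, g = 0.8, nx = 120, nz = 80,
                     thickness_mm = 40, voxel_mm = 0.5)
  src <- source_config(10, 20)
  sw <- sweep_separations(med$volume, med$table, src, c(1, 2, 3),
                          quick_run(8e4, seed = 13),
                          detector_side_mm = 10)
  expect_gt(min(sw$n_records), 30)
  expect_true(all(diff(sw$dpf) > 0))
})
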