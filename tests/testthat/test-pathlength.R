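fake_records <- function(w, L, Lregion = NULL, tissue = "lung") {
  df <- data.frame(weight = w, total_cm = L)
  df[[paste0("path_", tissue, "_cm")]] <- if (is.null(Lregion)) L
  else Lregion
  df
}

test_that("DPF is the weighted mean path over the separation", {
  expect_equal(compute_dpf(fake_records(1, 5.8), 2.9), 2)
  # ballistic surface paths: L = d gives DPF 1
  expect_equal(compute_dpf(fake_records(c(0.3, 0.7), c(2, 2)), 2), 1)
  expect_error(compute_dpf(fake_records(1, 1)[0, ], 2), "no detected")
  expect_error(compute_dpf(fake_records(1, 1), 0), "separation")
})

test_that("PPF uses per-tissue partial paths and caps at DPF", {
  rec <- fake_records(c(0.5, 0.25), c(3, 6), Lregion = c(1.0, 4.0))
  expect_equal(compute_ppf(rec, 2, region = "lung"),
               ((0.5 * 1.0 + 0.25 * 4.0) / 0.75) / 2)
  expect_equal(compute_ppf(rec, 2, region = "lung"), 1.0)
  # region never traversed
  rec$path_lung_cm <- 0
  expect_equal(compute_ppf(rec, 2, region = "lung"), 0)
  expect_error(compute_ppf(rec, 2, region = "bone"), "lack")
})

test_that("PPF over all tissues partitions DPF exactly", {
  st <- small_thorax()
  tab <- default_tissue_table()
  src <- source_config(st$cfg$source_x_mm, st$cfg$source_z_mm)
  det <- detector_config(st$cfg$source_x_mm + 12, st$cfg$source_z_mm, 8)
  res <- propagate(st$volume, tab, src, det,
                   quick_run(3e4, seed = 77, record_all_exits = TRUE))
  d <- 1.2
  dpf <- compute_dpf(res$records, d)
  ppf_sum <- sum(vapply(tab$tissue, function(t)
    compute_ppf(res$records, d, region = t), numeric(1)))
  expect_equal(ppf_sum, dpf, tolerance = 1e-9)
  # DPF from records equals an independently accumulated tally
  tally <- sum(res$records$weight * res$records$total_cm) /
    sum(res$records$weight) / d
  expect_equal(dpf, tally, tolerance = 1e-12)
})

test_that("absorbed fractions respect conservation and empty regions", {
  med <- tiny_medium()
  res <- propagate(med$volume, med$table, source_config(15, 15),
                   detector_config(15, 15),
                   quick_run(2e4, seed = 12, roulette = FALSE))
  whole <- absorbed_fraction(res, med$volume, "layer1")
  t <- res$totals
  exited <- (t[["specular"]] + t[["exit_top"]] + t[["exit_bottom"]] +
               t[["exit_side"]]) / t[["launched"]]
  expect_equal(whole + exited, 1, tolerance = 1e-12)
  expect_warning(f0 <- absorbed_fraction(res, med$volume,
                                         array(FALSE, dim(res$absorption))),
                 "empty region")
  expect_equal(f0, 0)

  # Beer-Lambert absorbed fraction in a non-scattering matched slab
  sl <- build_slab_phantom(data.frame(thickness_mm = 10, n = 1, mua = 1,
                                      mus = 1e-9, g = 0),
                           nx = 40, nz = 40, voxel_mm = 0.5)
  res2 <- propagate(sl$volume, sl$table, source_config(10, 10),
                    detector_config(10, 10),
                    quick_run(2e4, seed = 13, roulette = FALSE))
  fr <- absorbed_fraction(res2, sl$volume, "layer1")
  p <- 1 - exp(-1)
  se <- sqrt(p * (1 - p) / res2$launched)
  expect_lt(abs(fr - p), 3 * se)
})

test_that("separation sweeps post-filter a shared photon ensemble", {
  med <- tiny_medium(mua = 0.3, mus = 30, g = 0.8, nx = 100, nz = 50,
                     thickness_mm = 15, voxel_mm = 0.5)
  src <- source_config(10, 12.5)
  sw1 <- sweep_separations(med$volume, med$table, src, 2,
                           quick_run(2e4, seed = 19),
                           detector_side_mm = 6)
  expect_equal(nrow(sw1), 1)
  expect_error(sweep_separations(med$volume, med$table, src, c(2, 1),
                                 quick_run(100)), "increasing")
  expect_error(sweep_separations(med$volume, med$table, src, 20,
                                 quick_run(100)), "outside")

  sw <- sweep_separations(med$volume, med$table, src, c(1, 2, 3),
                          quick_run(2e4, seed = 19), detector_side_mm = 6)
  expect_equal(sw$d_cm, c(1, 2, 3))
  # matching a manual post-filter of a record_all run
  res <- propagate(med$volume, med$table, src, detector_config(20, 12.5, 6),
                   quick_run(2e4, seed = 19, record_all_exits = TRUE))
  sel <- abs(res$records$exit_x_mm - (10 + 10)) <= 3 &
    abs(res$records$exit_z_mm - 12.5) <= 3
  expect_equal(sw$detected_per_packet[sw$d_cm == 1],
               sum(res$records$weight[sel]) / res$launched)
  expect_equal(sw$dpf[sw$d_cm == 1],
               compute_dpf(res$records[sel, ], 1))
})

test_that("per-tissue absorbed fractions and exited weight sum to one in
           the sweep bookkeeping", {
  st <- small_thorax()
  tab <- default_tissue_table()
  src <- source_config(st$cfg$source_x_mm, st$cfg$source_z_mm)
  sw <- sweep_separations(st$volume, tab, src, c(1, 1.5),
                          quick_run(5000, seed = 4, roulette = FALSE),
                          detector_side_mm = 8,
                          region_mask = pa_region_mask(st$volume, st$cfg))
  af <- attr(sw, "absorbed_fractions")
  expect_true(all(af >= 0))
  expect_equal(sum(af) + attr(sw, "exited_fraction"), 1,
               tolerance = 1e-12)
  # single-separation sweep: the argmax markers are that separation
  sw1 <- sweep_separations(st$volume, tab, src, 1.2,
                           quick_run(4000, seed = 4),
                           detector_side_mm = 8,
                           region_mask = pa_region_mask(st$volume, st$cfg))
  expect_equal(attr(sw1, "argmax_ppf_over_dpf"), 1.2)
  expect_equal(attr(sw1, "argmax_pa_absorption"), 1.2)
})
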