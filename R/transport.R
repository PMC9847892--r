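#' Source, detector, and run configuration
#'
#' The source is a pencil beam entering the tissue along the inward surface
#' normal (+y) at lateral position `(x_mm, z_mm)` on the outer surface. The
#' detector is a square aperture on the same surface, centered at its own
#' `(x_mm, z_mm)`, collecting photons at all exit angles. Run settings
#' follow the convention of averaging several independent repeats of a
#' fixed photon budget.
#'
#' @param x_mm,z_mm Lateral position on the outer surface (mm).
#' @return A `source_config` / `detector_config` / `run_config` list.
#' @export
source_config <- function(x_mm, z_mm) {
  structure(list(x_mm = x_mm, z_mm = z_mm), class = "source_config")
}

#' @rdname source_config
#' @param side_mm Square aperture side (mm); the default matches a common
#'   monolithic photodiode die (2.29 mm).
#' @export
detector_config <- function(x_mm, z_mm, side_mm = 2.29) {
  if (side_mm <= 0) stop("detector side must be > 0")
  structure(list(x_mm = x_mm, z_mm = z_mm, side_mm = side_mm),
            class = "detector_config")
}

#' @rdname source_config
#' @param n_photons Photon packets per repeat (default 1e6).
#' @param n_repeats Independent repeats averaged together (default 10).
#' @param base_seed Base RNG seed; repeat `i` uses
#'   `derive_seed(base_seed, "repeat", i - 1)`.
#' @param roulette Enable Russian roulette termination of low-weight
#'   packets.
#' @param roulette_threshold Weight below which roulette triggers.
#' @param roulette_p Survival probability; survivors' weight is divided by
#'   it (unbiased).
#' @param record_all_exits Record every photon exiting the top surface,
#'   not only those inside the detector aperture (used by separation
#'   sweeps, where apertures are applied as post-filters).
#' @param tally_fluence Also accumulate a per-voxel pathlength fluence
#'   tally (weight x path), an independent estimator of fluence.
#' @param ambient_n Refractive index of the surrounding medium.
#' @export
run_config <- function(n_photons = 1e6, n_repeats = 10, base_seed = 1L,
                       roulette = TRUE, roulette_threshold = 1e-4,
                       roulette_p = 0.1, record_all_exits = FALSE,
                       tally_fluence = FALSE, ambient_n = 1.0) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (roulette_p <= 0 || roulette_p > 1)
    stop("roulette_p must be in (0, 1]")
  structure(list(n_photons = as.integer(n_photons),
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 roulette = isTRUE(roulette),
                 roulette_threshold = roulette_threshold,
                 roulette_p = roulette_p,
                 record_all_exits = isTRUE(record_all_exits),
                 tally_fluence = isTRUE(tally_fluence),
                 ambient_n = ambient_n),
            class = "run_config")
}

# per-label property arrays (index = code + 1); air / unmapped invalid
.prop_arrays <- function(volume, props) {
  ncode <- max(volume$label_names) + 1L
  pn <- rep(1.0, ncode); pa <- rep(0.0, ncode)
  ps <- rep(0.0, ncode); pg <- rep(0.0, ncode)
  ok <- rep(FALSE, ncode)
  idx <- props$label + 1L
  pn[idx] <- props$n; pa[idx] <- props$mua
  ps[idx] <- props$mus; pg[idx] <- props$g
  ok[idx] <- TRUE
  # any non-air label present in the volume must be mapped
  present <- sort(unique(as.integer(volume$labels)))
  air_code <- if ("air" %in% names(volume$label_names))
    volume$label_names[["air"]] else -1L
  bad <- setdiff(present, c(props$label, air_code))
  if (length(bad) > 0)
    stop("volume contains labels without optical properties: ",
         paste(bad, collapse = ", "))
  list(n = pn, mua = pa, mus = ps, g = pg, valid = ok)
}

#' Run the voxel Monte Carlo transport simulation
#'
#' Launches `n_photons` photon packets per repeat from the source, walks
#' them voxel-by-voxel (the sampled optical depth is spent across voxels of
#' differing attenuation), deposits the fraction mua/mut of the packet
#' weight at each interaction, scatters by the Henyey-Greenstein phase
#' function, applies Fresnel reflection/refraction wherever the refractive
#' index changes (including tissue-air exits), and terminates low-weight
#' packets by Russian roulette. Photons exiting the top surface inside the
#' detector aperture are recorded with their total and per-tissue path
#' lengths.
#'
#' @param volume A [labeled_volume].
#' @param props A `tissue_table` covering every non-air label in `volume`.
#' @param source A [source_config()].
#' @param detector A [detector_config()].
#' @param run A [run_config()].
#' @param region_mask Optional logical/integer array matching the volume:
#'   voxels of a focal region (e.g. the pulmonary artery) whose partial
#'   path length is recorded per photon in a dedicated column.
#' @return An `mc_result`: list with `absorption` (3D array of accumulated
#'   absorbed weight over all repeats), optional `tally` fluence array,
#'   `records` (data frame of detected/recorded exits, one row per photon,
#'   with per-tissue partial path lengths in cm), `totals` (summed energy
#'   bookkeeping), `per_repeat` (per-repeat totals and seeds), and the
#'   configurations used.
#' @export
propagate <- function(volume, props, source, detector,
                      run = run_config(), region_mask = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  d <- dim(volume$labels)
  v <- volume$voxel_mm
  pr <- .prop_arrays(volume, props)
  rmask <- if (is.null(region_mask)) integer(0) else {
    if (!all(dim(region_mask) == d))
      stop("region mask does not match the volume dimensions")
    as.integer(region_mask != 0)
  }

  surface_iy <- as.integer(round(volume$tissue_surface_mm / v))
  eix <- as.integer(floor(source$x_mm / v)) + 1L
  eiz <- as.integer(floor(source$z_mm / v)) + 1L
  if (eix < 1 || eix > d[1] || eiz < 1 || eiz > d[3])
    stop("source position lies outside the volume surface")
  entry_lab <- volume$labels[eix, surface_iy + 1L, eiz]
  if (!pr$valid[entry_lab + 1L])
    stop("source does not sit on a tissue surface (entry voxel is air)")
  if (surface_iy > 0) {
    above <- volume$labels[eix, surface_iy, eiz]
    if (pr$valid[above + 1L])
      stop("source entry voxel has no air above it (not on the surface)")
  }

  thr <- if (run$roulette) run$roulette_threshold else 0.0
  maps <- NULL; tly <- NULL; recs <- list(); seeds <- integer(run$n_repeats)
  tot_names <- c("launched", "specular", "absorbed", "exit_top",
                 "exit_bottom", "exit_side", "detected", "roulette_killed",
                 "roulette_injected")
  per_rep <- matrix(0, run$n_repeats, length(tot_names),
                    dimnames = list(NULL, tot_names))
  for (r in seq_len(run$n_repeats)) {
    seeds[r] <- derive_seed(run$base_seed, "repeat", r - 1L)
    out <- mc_kernel(volume$labels, d, v,
                     pr$n, pr$mua, pr$mus, pr$g, pr$valid, run$ambient_n,
                     source$x_mm, source$z_mm, surface_iy,
                     detector$x_mm, detector$z_mm, detector$side_mm / 2,
                     run$n_photons, thr, run$roulette_p,
                     run$record_all_exits, run$tally_fluence, rmask,
                     seeds[r])
    maps <- if (is.null(maps)) out$absorption else maps + out$absorption
    if (run$tally_fluence)
      tly <- if (is.null(tly)) out$tally else tly + out$tally
    per_rep[r, ] <- out$totals[tot_names]
    if (nrow(out$records) > 0) {
      df <- as.data.frame(out$records)
      names(df) <- .record_names(props)
      df$run <- r
      recs[[length(recs) + 1L]] <- df
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else {
    df <- as.data.frame(matrix(numeric(0), 0, length(.record_names(props))))
    names(df) <- .record_names(props); df$run <- integer(0); df
  }
  totals <- colSums(per_rep)
  structure(list(absorption = maps, tally = tly, records = records,
                 totals = totals,
                 per_repeat = cbind(per_rep, seed = seeds),
                 launched = unname(totals["launched"]),
                 volume_dims = d, voxel_mm = v,
                 source = source, detector = detector, run = run,
                 props = props),
            class = "mc_result")
}

.record_names <- function(props) {
  # kernel partial-path columns come out in label-code order 0..max
  ncode <- max(props$label) + 1L
  pnames <- rep(NA_character_, ncode)
  pnames[props$label + 1L] <- props$tissue
  pnames[is.na(pnames)] <- paste0("code", which(is.na(pnames)) - 1L)
  c("exit_x_mm", "exit_y_mm", "exit_z_mm", "dir_x", "dir_y", "dir_z",
    "weight", "total_cm", paste0("path_", pnames, "_cm"), "path_region_cm", "photon")
}

#' @export
print.mc_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Monte Carlo transport result: %s photons in %d repeat(s)\n",
              format(x$launched, big.mark = ","),
              nrow(x$per_repeat)))
  cat(sprintf("  absorbed %.4f | exited %.4f | detected %.3e (per packet)\n",
              t["absorbed"] / t["launched"],
              (t["specular"] + t["exit_top"] + t["exit_bottom"] +
                 t["exit_side"]) / t["launched"],
              t["detected"] / t["launched"]))
  cat(sprintf("  detector records: %d\n", nrow(x$records)))
  invisible(x)
}

#' @export
summary.mc_result <- function(object, ...) {
  print(object)
  cat("Per-repeat detected weight per packet:\n")
  print(object$per_repeat[, "detected"] / object$per_repeat[, "launched"])
  invisible(object)
}

#' Detected intensity of a transport result
#'
#' Sum of detected residual photon weights per launched packet, with the
#' between-repeat standard error.
#'
#' @param result An `mc_result`.
#' @return List with `intensity`, `se`, and the per-repeat values.
#' @export
detected_intensity <- function(result) {
  per <- result$per_repeat[, "detected"] / result$per_repeat[, "launched"]
  list(intensity = mean(per),
       se = if (length(per) > 1) stats::sd(per) / sqrt(length(per)) else NA_real_,
       per_repeat = per)
}

#' Average a list of simulation results
#'
#' Voxelwise mean of the absorption maps, concatenated detector records
#' with per-result provenance, and averaged totals.
#'
#' @param results List of `mc_result` objects sharing dimensions.
#' @return An `mc_result` representing the average.
#' @export
average_results <- function(results) {
  if (length(results) < 1) stop("need at least one result")
  d <- results[[1]]$volume_dims
  for (r in results)
    if (!all(r$volume_dims == d)) stop("results have mismatched dimensions")
  map <- Reduce(`+`, lapply(results, `[[`, "absorption")) / length(results)
  recs <- do.call(rbind, lapply(seq_along(results), function(i) {
    df <- results[[i]]$records
    if (nrow(df)) df$result <- i
    df
  }))
  totals <- Reduce(`+`, lapply(results, `[[`, "totals")) / length(results)
  out <- results[[1]]
  out$absorption <- map
  out$records <- recs
  out$totals <- totals
  out$launched <- unname(totals["launched"])
  out$per_repeat <- do.call(rbind, lapply(results, `[[`, "per_repeat"))
  out
}

#' Elementary transport kernels
#'
#' Single-step building blocks of the Monte Carlo walk, exposed for
#' validation: exponential step sampling, Henyey-Greenstein scattering, and
#' unpolarized Fresnel reflectance.
#'
#' @param xi,xi1,xi2 Uniform deviates in (0, 1].
#' @param mut Total attenuation coefficient (cm^-1), > 0.
#' @return `sample_step`: step length in cm.
#' @export
#' @examples
#' sample_step(exp(-1), 1)  # 1 cm
sample_step <- function(xi, mut) {
  if (any(mut <= 0)) stop("mut must be > 0")
  if (any(xi <= 0 | xi > 1)) stop("xi must lie in (0, 1]")
  -log(xi) / mut
}

#' @rdname sample_step
#' @param g Henyey-Greenstein anisotropy factor, |g| < 1.
#' @return `hg_cos_theta`: the sampled deflection cosine.
#' @export
hg_cos_theta <- function(g, xi) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  vapply(xi, function(x) cpp_hg_cos(g, x), numeric(1))
}

#' @rdname sample_step
#' @param direction Incoming unit direction (length-3).
#' @return `hg_scatter`: the new unit direction after deflection by the
#'   sampled polar angle and azimuth `2 * pi * xi2`.
#' @export
hg_scatter <- function(g, xi1, xi2, direction = c(0, 0, 1)) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) stop("direction must be unit-norm")
  cpp_hg_direction(direction, g, xi1, xi2)
}

#' @rdname sample_step
#' @param n1,n2 Refractive indices on the incident / transmitted side.
#' @param cos_incident Cosine of the incidence angle, in [0, 1].
#' @return `fresnel_reflectance`: reflectance in [0, 1] (1 beyond the
#'   critical angle).
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  if (n1 < 1 || n2 < 1) stop("refractive indices must be >= 1")
  if (cos_incident < 0 || cos_incident > 1)
    stop("cos_incident must lie in [0, 1]")
  cpp_fresnel(n1, n2, cos_incident)
}
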