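#' Fluence from the absorption map
#'
#' Converts per-voxel absorbed weight into fluence by dividing each voxel
#' by the absorption coefficient of its tissue, F = A / mua, after
#' normalizing per launched packet. Air voxels (and any tissue with
#' mua = 0) get zero fluence.
#'
#' @param A An `mc_result` or a 3D absorption array.
#' @param volume The [labeled_volume] the map was computed on.
#' @param props The `tissue_table` used for transport.
#' @param launched Total launched weight (taken from the `mc_result` if
#'   `A` is one).
#' @param source_tag Tag stored with the map (`"forward"` or `"adjoint"`).
#' @return 3D fluence array (cm per voxel per launched packet) with
#'   attribute `source_tag`.
#' @export
fluence_from_absorption <- function(A, volume, props, launched = NULL,
                                    source_tag = "forward") {
  if (inherits(A, "mc_result")) {
    launched <- A$launched
    A <- A$absorption
  }
  if (is.null(launched)) launched <- 1
  if (!all(dim(A) == dim(volume$labels)))
    stop("absorption map and volume have mismatched dimensions")
  if (any(A < 0)) stop("absorption map has negative entries")
  mua_lookup <- rep(0, max(volume$label_names) + 1L)
  mua_lookup[props$label + 1L] <- props$mua
  mua_arr <- mua_lookup[as.integer(volume$labels) + 1L]
  f <- as.numeric(A) / launched
  f <- ifelse(mua_arr > 0, f / mua_arr, 0)
  out <- array(f, dim = dim(A))
  attr(out, "source_tag") <- source_tag
  attr(out, "voxel_mm") <- volume$voxel_mm
  out
}

#' Detector-side (adjoint) fluence
#'
#' The detector-side Green's function is obtained by an explicit adjoint
#' simulation: a source is placed at the detector position and its fluence
#' map returned, normalized per launched packet.
#'
#' @param volume,props As in [propagate()].
#' @param detector A [detector_config()]; its center becomes the adjoint
#'   source site.
#' @param run A [run_config()].
#' @return 3D fluence array tagged `"adjoint"`.
#' @export
adjoint_fluence <- function(volume, props, detector, run = run_config()) {
  src <- source_config(detector$x_mm, detector$z_mm)
  det <- detector_config(detector$x_mm, detector$z_mm, detector$side_mm)
  res <- propagate(volume, props, src, det, run)
  fluence_from_absorption(res, volume, props, source_tag = "adjoint")
}

#' Spatial sensitivity distribution (three-point Green's function)
#'
#' Voxelwise product of the source-side and detector-side fluence maps,
#' SSD(rS, rD, rm) = F(rS, rm) * F(rD, rm): how strongly an absorption
#' change in each voxel influences the detected signal.
#'
#' @param F_src,F_det Fluence arrays of identical dimensions.
#' @return 3D SSD array.
#' @export
ssd_map <- function(F_src, F_det) {
  if (!all(dim(F_src) == dim(F_det)))
    stop("fluence maps have mismatched dimensions")
  out <- F_src * F_det
  attributes(out) <- list(dim = dim(F_src),
                          voxel_mm = attr(F_src, "voxel_mm"))
  out
}

#' Per-tissue SSD sums and proportions
#'
#' Sums the SSD over the voxels of each tissue and expresses each sum as a
#' percentage of the whole-model SSD (air excluded from the denominator;
#' its fluence is zero by construction).
#'
#' @param ssd SSD array from [ssd_map()].
#' @param volume The matching [labeled_volume].
#' @return Data frame with columns `tissue`, `ssd_sum`, `proportion_pct`;
#'   proportions sum to 100.
#' @export
tissue_ssd_proportions <- function(ssd, volume) {
  if (!all(dim(ssd) == dim(volume$labels)))
    stop("SSD map and volume have mismatched dimensions")
  labs <- volume$label_names[names(volume$label_names) != "air"]
  sums <- vapply(labs, function(code)
    sum(ssd[volume$labels == code]), numeric(1))
  total <- sum(sums)
  if (total <= 0) stop("total SSD is zero: proportions undefined")
  ord <- if (all(.tissue_report_order %in% names(labs)))
    .tissue_report_order else names(labs)
  data.frame(tissue = ord,
             ssd_sum = unname(sums[ord]),
             proportion_pct = unname(100 * sums[ord] / total),
             stringsAsFactors = FALSE)
}

#' Fluence profile along the depth axis and penetration depth
#'
#' Samples the fluence along the depth line through the entry point and
#' reports the penetration depth: the distance from the tissue surface to
#' the first voxel whose intensity falls below the floor. Intensity is
#' expressed per `floor_scale` launched packets (default 1e6, so the
#' default floor of 1 means "one weight unit per voxel per million
#' packets").
#'
#' @param F Fluence array (per launched packet).
#' @param volume The matching [labeled_volume].
#' @param entry `c(x_mm, z_mm)` entry point on the surface.
#' @param floor Intensity floor defining the end of penetration.
#' @param floor_scale Packet count the floor refers to.
#' @return List with `profile` (data frame: `depth_mm`, `intensity`) and
#'   `penetration_depth_mm`.
#' @export
penetration_profile <- function(F, volume, entry = volume$source_hint,
                                floor = 1, floor_scale = 1e6) {
  d <- dim(F)
  v <- volume$voxel_mm
  ix <- as.integer(base::floor(entry[[1]] / v)) + 1L
  iz <- as.integer(base::floor(entry[[2]] / v)) + 1L
  if (ix < 1 || ix > d[1] || iz < 1 || iz > d[3])
    stop("entry point lies outside the volume")
  iy0 <- as.integer(round(volume$tissue_surface_mm / v)) + 1L
  vals <- F[ix, iy0:d[2], iz] * floor_scale
  depth_mm <- (seq_along(vals) - 0.5) * v
  below <- which(vals < floor)
  pen <- if (length(below) == 0) length(vals) * v else (below[1] - 1) * v
  list(profile = data.frame(depth_mm = depth_mm, intensity = vals),
       penetration_depth_mm = pen)
}
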