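#' Labeled voxel volume
#'
#' Container for a 3D integer array of tissue labels plus its voxel size.
#' Axis convention: the first dimension (x) is lateral, the second (y) is
#' depth below the outer surface, the third (z) indexes slices. Physical
#' position of voxel index `i` along an axis is `(i - 0.5) * voxel_mm`.
#'
#' @param labels 3D integer array of label codes (see [tissue_labels()]).
#' @param voxel_mm Isotropic voxel edge length in mm.
#' @param label_names Named integer vector mapping tissue name to code.
#' @param tissue_surface_mm Depth (mm, along y) at which tissue begins; air
#'   padding occupies `y < tissue_surface_mm`.
#' @param source_hint Optional `c(x_mm, z_mm)` recommended source site.
#' @return A `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_mm,
                           label_names = tissue_labels(),
                           tissue_surface_mm = 0,
                           source_hint = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || !all(labels %in% label_names))
    stop("every voxel must carry a valid label code")
  if (voxel_mm <= 0) stop("voxel_mm must be > 0")
  structure(
    list(labels = labels, voxel_mm = voxel_mm, label_names = label_names,
         tissue_surface_mm = tissue_surface_mm, source_hint = source_hint),
    class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Labeled volume: %d x %d x %d voxels at %.3g mm (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], x$voxel_mm,
              d[1] * x$voxel_mm, d[2] * x$voxel_mm, d[3] * x$voxel_mm))
  tab <- label_histogram(x)
  print(tab)
  invisible(x)
}

#' @export
summary.labeled_volume <- function(object, ...) print(object, ...)

#' Per-label voxel counts of a labeled volume
#'
#' @param volume A `labeled_volume`.
#' @return Named integer vector of voxel counts, one entry per known label
#'   (zero where absent). Counts sum to the total voxel number.
#' @export
label_histogram <- function(volume) {
  counts <- tabulate(volume$labels + 1L, nbins = max(volume$label_names) + 1L)
  names(counts) <- names(sort(volume$label_names))
  counts
}

#' Configuration of the synthetic thoracic phantom
#'
#' Parametric stand-in for a photographic thoracic voxel model: flat
#' skin/fat/bone/muscle layers over lung, an inter-rib gap in the bone
#' plate at the source site, a pulmonary-artery cylinder (vessel wall
#' around a venous-blood lumen) running along z with its anterior wall at a
#' prescribed depth, and small embedded arterial/venous vessels in the
#' intercostal muscle and lung so that all blood pools intersect the
#' sampled region.
#'
#' @param dims Voxel counts `c(nx, ny, nz)`.
#' @param voxel_mm Isotropic voxel size (mm).
#' @param air_mm Air padding above the skin (mm).
#' @param skin_mm,fat_mm,bone_mm,muscle_mm Layer thicknesses (mm).
#' @param rib_gap_mm Width (along z) of the inter-rib gap in the bone
#'   plate, centered on the source slice; filled with intercostal muscle.
#' @param mediastinum_halfwidth_mm Half-width (along x, centered on the
#'   source) of the mediastinal fat column behind the chest wall. The
#'   pulmonary artery is embedded in mediastinal fat, with lung parenchyma
#'   lateral to it, mirroring the anatomy of the anterior mediastinum; a
#'   lung-filled prepulmonary space would over-attenuate the light by
#'   orders of magnitude relative to the depth attenuation thoracic
#'   photon-migration studies report.
#' @param pa_depth_mm Depth of the anterior pulmonary-artery wall below the
#'   tissue surface (mm).
#' @param pa_wall_mm Vessel wall thickness (mm); must be > 0.
#' @param pa_lumen_radius_mm Lumen radius (mm).
#' @param source_x_mm,source_z_mm Recommended source site (mm); the PA
#'   cylinder and rib gap are centered here.
#' @param vessels Include embedded arterial/venous vessel inclusions.
#' @param vessel_radius_mm,vessel_spacing_mm Radius / x-spacing of muscle
#'   vessels (mm).
#' @param lung_vessel_radius_mm,lung_vessel_spacing_mm Radius / x-spacing
#'   of lung vessels (mm).
#' @param seed Reserved; phantom construction is fully deterministic.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(dims = c(220L, 180L, 60L), voxel_mm = 0.4,
                           air_mm = 0.8,
                           skin_mm = 2, fat_mm = 6, bone_mm = 8,
                           muscle_mm = 4, rib_gap_mm = 15,
                           mediastinum_halfwidth_mm = 22,
                           pa_depth_mm = 33, pa_wall_mm = 2,
                           pa_lumen_radius_mm = 13,
                           source_x_mm = 24,
                           source_z_mm = dims[3] * voxel_mm / 2,
                           vessels = TRUE,
                           vessel_radius_mm = 1.0, vessel_spacing_mm = 6,
                           lung_vessel_radius_mm = 1.2,
                           lung_vessel_spacing_mm = 8,
                           seed = 1L) {
  cfg <- list(dims = as.integer(dims), voxel_mm = voxel_mm, air_mm = air_mm,
              skin_mm = skin_mm, fat_mm = fat_mm, bone_mm = bone_mm,
              muscle_mm = muscle_mm, rib_gap_mm = rib_gap_mm,
              mediastinum_halfwidth_mm = mediastinum_halfwidth_mm,
              pa_depth_mm = pa_depth_mm, pa_wall_mm = pa_wall_mm,
              pa_lumen_radius_mm = pa_lumen_radius_mm,
              source_x_mm = source_x_mm, source_z_mm = source_z_mm,
              vessels = vessels,
              vessel_radius_mm = vessel_radius_mm,
              vessel_spacing_mm = vessel_spacing_mm,
              lung_vessel_radius_mm = lung_vessel_radius_mm,
              lung_vessel_spacing_mm = lung_vessel_spacing_mm,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  th <- c(skin = cfg$skin_mm, fat = cfg$fat_mm, bone = cfg$bone_mm,
          muscle = cfg$muscle_mm)
  if (any(th <= 0))
    stop("layer thicknesses must be > 0 (offending: ",
         paste(names(th)[th <= 0], collapse = ", "), ")")
  if (cfg$pa_wall_mm <= 0) stop("pa_wall_mm must be > 0")
  if (cfg$pa_lumen_radius_mm <= 0) stop("pa_lumen_radius_mm must be > 0")
  depth_mm <- cfg$dims[2] * cfg$voxel_mm
  need <- cfg$air_mm + cfg$pa_depth_mm + cfg$pa_wall_mm +
    2 * cfg$pa_lumen_radius_mm + cfg$pa_wall_mm
  if (need > depth_mm)
    stop(sprintf(paste0("pulmonary artery overflows the domain: wall depth",
                        " + lumen diameter needs %.1f mm, domain depth is",
                        " %.1f mm"), need, depth_mm))
  if (cfg$pa_depth_mm <= cfg$air_mm + cfg$skin_mm + cfg$fat_mm +
      cfg$bone_mm + cfg$muscle_mm - cfg$air_mm)
    stop("pa_depth_mm must lie below the layered wall (inside lung)")
  invisible(cfg)
}

# mask helper: cylinder along z -> (nx x ny) logical expanded to 3D later
.cyl_xy <- function(xs, ys, xc, yc, r) {
  outer((xs - xc)^2, (ys - yc)^2, "+") <= r^2
}

#' Build the synthetic thoracic phantom
#'
#' Deterministically paints a [labeled_volume] from a [phantom_config]:
#' air pad, skin, fat, bone plate with an inter-rib (intercostal muscle)
#' gap, a muscle sheet, a central mediastinal fat column flanked by lung
#' parenchyma, embedded arterial/venous vessels, and the pulmonary artery
#' (wall + venous lumen) embedded in the mediastinum with its anterior
#' wall at `pa_depth_mm` directly beneath the source site.
#'
#' @param cfg A [phantom_config()].
#' @return A `labeled_volume` whose `source_hint` carries the recommended
#'   source position.
#' @export
#' @examples
#' vol <- build_thoracic_phantom(phantom_config(dims = c(80, 120, 40)))
#' label_histogram(vol)
build_thoracic_phantom <- function(cfg = phantom_config()) {
  validate_phantom_config(cfg)
  labs <- tissue_labels()
  nx <- cfg$dims[1]; ny <- cfg$dims[2]; nz <- cfg$dims[3]
  v <- cfg$voxel_mm
  xs <- (seq_len(nx) - 0.5) * v
  ys <- (seq_len(ny) - 0.5) * v          # physical y, 0 at outer face
  zs <- (seq_len(nz) - 0.5) * v
  depth <- ys - cfg$air_mm               # depth below tissue surface

  arr <- array(labs[["air"]], dim = c(nx, ny, nz))

  # flat layers as depth bands (same for every x, z)
  b_skin <- cfg$skin_mm
  b_fat <- b_skin + cfg$fat_mm
  b_bone <- b_fat + cfg$bone_mm
  b_muscle <- b_bone + cfg$muscle_mm
  band <- rep(labs[["air"]], ny)
  band[depth >= 0 & depth < b_skin] <- labs[["skin"]]
  band[depth >= b_skin & depth < b_fat] <- labs[["fat"]]
  band[depth >= b_fat & depth < b_bone] <- labs[["bone"]]
  band[depth >= b_bone & depth < b_muscle] <- labs[["muscle"]]
  band[depth >= b_muscle] <- labs[["lung"]]
  arr[] <- rep(rep(band, each = nx), times = nz)

  # mediastinal fat column around the pulmonary artery; lung stays lateral
  in_med_x <- abs(xs - cfg$source_x_mm) < cfg$mediastinum_halfwidth_mm
  in_lung_y <- depth >= b_muscle
  if (any(in_med_x) && any(in_lung_y)) {
    m <- array(FALSE, dim = c(nx, ny, nz))
    m[in_med_x, in_lung_y, ] <- TRUE
    arr[m] <- labs[["fat"]]
  }

  # inter-rib gap: bone replaced by intercostal muscle in a z band
  in_gap_z <- abs(zs - cfg$source_z_mm) < cfg$rib_gap_mm / 2
  in_bone_y <- depth >= b_fat & depth < b_bone
  if (any(in_gap_z) && any(in_bone_y)) {
    m <- array(FALSE, dim = c(nx, ny, nz))
    m[, in_bone_y, in_gap_z] <- TRUE
    arr[m] <- labs[["muscle"]]
  }

  if (isTRUE(cfg$vessels)) {
    # intercostal vessels: cylinders along x at the gap mid-depth,
    # alternating arterial / venous around the source slice
    yv <- cfg$air_mm + (b_fat + b_bone) / 2
    dz_off <- c(-4.8, -1.6, 1.6, 4.8)
    kinds <- c("arterial_blood", "venous_blood", "arterial_blood",
               "venous_blood")
    for (k in seq_along(dz_off)) {
      zc <- cfg$source_z_mm + dz_off[k]
      myz <- outer((ys - yv)^2, (zs - zc)^2, "+") <= cfg$vessel_radius_mm^2
      m <- aperm(array(myz, dim = c(ny, nz, nx)), c(3, 1, 2))
      sel <- m & arr == labs[["muscle"]]
      arr[sel] <- labs[[kinds[k]]]
    }
    # muscle-sheet vessels: cylinders along z, alternating along x
    yv2 <- cfg$air_mm + (b_bone + b_muscle) / 2
    xcs <- seq(cfg$vessel_spacing_mm / 2, nx * v, by = cfg$vessel_spacing_mm)
    for (k in seq_along(xcs)) {
      mxy <- .cyl_xy(xs, ys, xcs[k], yv2, cfg$vessel_radius_mm)
      m <- array(mxy, dim = c(nx, ny, nz))
      sel <- m & arr == labs[["muscle"]]
      arr[sel] <- labs[[if (k %% 2 == 1) "arterial_blood" else "venous_blood"]]
    }
    # mediastinal great-vessel stand-ins flanking the pulmonary artery
    for (k in 1:2) {
      xc <- cfg$source_x_mm + c(-8, 8)[k]
      mxy <- .cyl_xy(xs, ys, xc, cfg$air_mm + b_muscle + 6, 2)
      m <- array(mxy, dim = c(nx, ny, nz))
      sel <- m & arr == labs[["fat"]]
      arr[sel] <- labs[[c("arterial_blood", "venous_blood")[k]]]
    }
    # lung vessels: two depth rows of z-cylinders
    for (row in 1:2) {
      yv3 <- cfg$air_mm + b_muscle + c(5, 11)[row]
      xcs <- seq(cfg$lung_vessel_spacing_mm / (1 + row %% 2), nx * v,
                 by = cfg$lung_vessel_spacing_mm)
      for (k in seq_along(xcs)) {
        mxy <- .cyl_xy(xs, ys, xcs[k], yv3, cfg$lung_vessel_radius_mm)
        m <- array(mxy, dim = c(nx, ny, nz))
        sel <- m & arr == labs[["lung"]]
        arr[sel] <- labs[[if ((k + row) %% 2 == 0) "arterial_blood"
                          else "venous_blood"]]
      }
    }
  }

  # pulmonary artery: z-cylinder, anterior outer wall at pa_depth_mm
  r_out <- cfg$pa_wall_mm + cfg$pa_lumen_radius_mm
  yc <- cfg$air_mm + cfg$pa_depth_mm + r_out
  m_out <- .cyl_xy(xs, ys, cfg$source_x_mm, yc, r_out)
  m_in <- .cyl_xy(xs, ys, cfg$source_x_mm, yc, cfg$pa_lumen_radius_mm)
  m3 <- array(m_out, dim = c(nx, ny, nz))
  sel <- m3 & arr != labs[["air"]]
  arr[sel] <- labs[["pa_vessel_wall"]]
  m3 <- array(m_in, dim = c(nx, ny, nz))
  sel <- m3 & arr != labs[["air"]]
  arr[sel] <- labs[["venous_blood"]]

  labeled_volume(arr, v, labs, tissue_surface_mm = cfg$air_mm,
                 source_hint = c(x_mm = cfg$source_x_mm,
                                 z_mm = cfg$source_z_mm))
}

#' Pulmonary-artery region mask of a thoracic phantom
#'
#' Logical array marking the pulmonary artery proper: vessel wall plus the
#' venous blood inside the lumen (venous vessels elsewhere are excluded).
#' Used as the focal region for partial pathlength factors (PPFpa).
#'
#' @param volume The `labeled_volume` built from `cfg`.
#' @param cfg The [phantom_config()] that produced `volume`.
#' @return Logical array with the volume's dimensions.
#' @export
pa_region_mask <- function(volume, cfg = phantom_config()) {
  labs <- volume$label_names
  nx <- dim(volume$labels)[1]; ny <- dim(volume$labels)[2]
  v <- volume$voxel_mm
  xs <- (seq_len(nx) - 0.5) * v
  ys <- (seq_len(ny) - 0.5) * v
  r_out <- cfg$pa_wall_mm + cfg$pa_lumen_radius_mm
  yc <- cfg$air_mm + cfg$pa_depth_mm + r_out
  m_out <- .cyl_xy(xs, ys, cfg$source_x_mm, yc, r_out)
  m3 <- array(m_out, dim = dim(volume$labels))
  m3 & (volume$labels == labs[["pa_vessel_wall"]] |
          volume$labels == labs[["venous_blood"]])
}

#' Build a laterally uniform layered slab phantom
#'
#' Validation geometry: a stack of homogeneous layers, uniform in x and z,
#' with no air padding (ambient air bounds the slab). Each layer gets its
#' own label (1, 2, ...) and the supplied optical properties, so the result
#' can be compared against layered-medium reference simulations.
#'
#' @param layers Data frame with one row per layer and columns
#'   `thickness_mm`, `n`, `mua`, `mus`, `g`.
#' @param nx,nz Lateral voxel counts.
#' @param voxel_mm Voxel size (mm).
#' @return List with elements `volume` (a `labeled_volume`) and `table`
#'   (the matching `tissue_table` with labels `layer1`, `layer2`, ...).
#' @export
#' @examples
#' sl <- build_slab_phantom(data.frame(thickness_mm = 10, n = 1,
#'                                     mua = 1, mus = 0.001, g = 0))
build_slab_phantom <- function(layers, nx = 100L, nz = 100L, voxel_mm = 0.4) {
  layers <- as.data.frame(layers)
  if (nrow(layers) < 1) stop("need at least one layer")
  if (any(layers$thickness_mm <= 0)) stop("layer thicknesses must be > 0")
  bounds <- cumsum(layers$thickness_mm)
  ny <- as.integer(ceiling(bounds[length(bounds)] / voxel_mm))
  ys <- (seq_len(ny) - 0.5) * voxel_mm
  band <- findInterval(ys, c(0, bounds), rightmost.closed = TRUE)
  band[band > nrow(layers)] <- nrow(layers)
  arr <- array(0L, dim = c(nx, ny, nz))
  arr[] <- rep(rep(as.integer(band), each = nx), times = nz)
  label_names <- c(air = 0L,
                   stats::setNames(seq_len(nrow(layers)),
                                   paste0("layer", seq_len(nrow(layers)))))
  tab <- as_tissue_table(data.frame(
    label = seq_len(nrow(layers)),
    tissue = paste0("layer", seq_len(nrow(layers))),
    n = layers$n, mua = layers$mua, mus = layers$mus, g = layers$g,
    stringsAsFactors = FALSE))
  vol <- labeled_volume(arr, voxel_mm, label_names, tissue_surface_mm = 0,
                        source_hint = c(x_mm = nx * voxel_mm / 2,
                                        z_mm = nz * voxel_mm / 2))
  list(volume = vol, table = tab)
}

#' Read / write labeled volumes
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) stores the label array with its voxel size;
#' a JSON sidecar (same path + `.json`) carries the label map and surface
#' depth. The raw format (`.raw`) stores one byte per voxel (x fastest)
#' with the same JSON sidecar.
#'
#' @param volume A `labeled_volume`.
#' @param path Output path ending in `.nii`, `.nii.gz`, or `.raw`.
#' @return `write_volume` returns `path` invisibly; `read_volume` the
#'   `labeled_volume`.
#' @export
write_volume <- function(volume, path) {
  side <- list(dims = dim(volume$labels), voxel_mm = volume$voxel_mm,
               tissue_surface_mm = volume$tissue_surface_mm,
               source_hint = as.list(volume$source_hint),
               labels = as.list(volume$label_names))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(volume$labels,
                           pixdim = rep(volume$voxel_mm, 3),
                           datatype = "int16")
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.raw$", path, ignore.case = TRUE)) {
    writeBin(as.raw(volume$labels), path)
  } else stop("unsupported volume format: ", path)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  label_names <- stats::setNames(as.integer(unlist(side$labels)),
                                 names(side$labels))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- array(as.integer(RNifti::readNifti(path)),
                 dim = as.integer(side$dims))
  } else {
    n <- prod(side$dims)
    arr <- array(as.integer(readBin(path, "raw", n = n)),
                 dim = as.integer(side$dims))
  }
  src <- if (!is.null(side$source_hint))
    unlist(side$source_hint) else NULL
  labeled_volume(arr, side$voxel_mm, label_names,
                 tissue_surface_mm = side$tissue_surface_mm,
                 source_hint = src)
}
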