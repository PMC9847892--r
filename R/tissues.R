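#' Tissue labels used by the thoracic transport model
#'
#' The voxel phantoms use nine integer labels: `air` (code 0) plus eight
#' thoracic tissue classes. Air takes part in no transport physics; a photon
#' crossing into an air voxel has left the tissue.
#'
#' @return A named integer vector mapping tissue name to label code.
#' @export
#' @examples
#' tissue_labels()
tissue_labels <- function() {
  c(air = 0L, skin = 1L, fat = 2L, muscle = 3L, bone = 4L, lung = 5L,
    pa_vessel_wall = 6L, arterial_blood = 7L, venous_blood = 8L)
}

# Row order used when writing per-tissue tables (matches the conventional
# reporting order: fat, skin, lung, bone, muscle, wall, arterial, venous).
.tissue_report_order <- c("fat", "skin", "lung", "bone", "muscle",
                          "pa_vessel_wall", "arterial_blood", "venous_blood")

#' Optical properties of thoracic tissue at 800 nm
#'
#' Returns the default per-tissue optical property table: refractive index
#' `n`, absorption coefficient `mua` (cm^-1), scattering coefficient `mus`
#' (cm^-1), Henyey-Greenstein anisotropy `g`, and the derived total
#' attenuation `mut = mua + mus`. Air has no entry: it is a non-transport
#' label.
#'
#' @param wavelength_nm Wavelength tag stored with the table (default 800).
#' @return A `tissue_table`: a data frame with one row per non-air tissue
#'   and columns `label`, `tissue`, `n`, `mua`, `mus`, `g`, `mut`.
#' @export
#' @examples
#' tab <- default_tissue_table()
#' tab[tab$tissue == "lung", ]
default_tissue_table <- function(wavelength_nm = 800) {
  labs <- tissue_labels()
  df <- data.frame(
    tissue = c("skin", "fat", "muscle", "bone", "lung",
               "pa_vessel_wall", "arterial_blood", "venous_blood"),
    n   = c(1.37, 1.33, 1.40, 1.43, 1.40, 1.40, 1.40, 1.40),
    mua = c(0.20, 0.083, 0.54, 0.11, 1.0, 0.92, 2.33, 2.38),
    mus = c(73.7, 134, 66.7, 291, 95.0, 103, 522, 440),
    g   = c(0.715, 0.910, 0.930, 0.936, 0.910, 0.930, 0.990, 0.990),
    stringsAsFactors = FALSE
  )
  df$label <- unname(labs[df$tissue])
  df$mut <- df$mua + df$mus
  df <- df[, c("label", "tissue", "n", "mua", "mus", "g", "mut")]
  as_tissue_table(df, wavelength_nm)
}

#' Construct / validate a tissue_table
#'
#' @param df Data frame with columns `label`, `tissue`, `n`, `mua`, `mus`,
#'   `g` (`mut` recomputed).
#' @param wavelength_nm Wavelength tag (nm).
#' @return The validated `tissue_table`.
#' @export
as_tissue_table <- function(df, wavelength_nm = 800) {
  req <- c("label", "tissue", "n", "mua", "mus", "g")
  if (!all(req %in% names(df)))
    stop("tissue table needs columns: ", paste(req, collapse = ", "))
  if (any(df$mua < 0)) stop("mua must be >= 0")
  if (any(df$mus < 0)) stop("mus must be >= 0")
  if (any(abs(df$g) >= 1)) stop("anisotropy g must satisfy |g| < 1")
  if (any(df$n < 1)) stop("refractive index n must be >= 1")
  df$mut <- df$mua + df$mus
  if (any(df$mut <= 0)) stop("mut = mua + mus must be > 0 for every tissue")
  if (any(df$tissue == "air"))
    stop("air is a non-transport label and has no optical properties")
  if (anyDuplicated(df$label)) stop("duplicate tissue labels in table")
  rownames(df) <- NULL
  structure(df, class = c("tissue_table", "data.frame"),
            wavelength_nm = wavelength_nm)
}

#' Look up optical properties of one tissue
#'
#' @param table A `tissue_table`.
#' @param tissue Tissue name or integer label code.
#' @return One-row data frame of properties.
#' @export
tissue_properties <- function(table, tissue) {
  if (is.character(tissue)) {
    if (tissue == "air") stop("air is a non-transport label (no properties)")
    i <- match(tissue, table$tissue)
  } else {
    if (tissue == tissue_labels()[["air"]])
      stop("air is a non-transport label (no properties)")
    i <- match(as.integer(tissue), table$label)
  }
  if (is.na(i)) stop("tissue not present in table: ", tissue)
  table[i, , drop = FALSE]
}

#' @export
print.tissue_table <- function(x, ...) {
  cat(sprintf("Tissue optical properties at %g nm (%d tissues)\n",
              attr(x, "wavelength_nm"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Blood absorption coefficient as a function of oxygen saturation
#'
#' Maps hemoglobin oxygen saturation (percent) to a blood absorption
#' coefficient at 800 nm by the straight line through two anchor points.
#' The default anchors are normally saturated arterial blood (95%,
#' 2.33 cm^-1) and normally saturated venous blood (75%, 2.38 cm^-1), so
#' desaturation raises absorption.
#'
#' @param saturation Oxygen saturation in percent, in [0, 100]. Vectorized.
#' @param anchors 2x2 matrix-like of `(saturation, mua)` anchor pairs.
#' @return Absorption coefficient(s) in cm^-1.
#' @export
#' @examples
#' blood_mua(95)  # 2.33
#' blood_mua(63)  # 2.41
blood_mua <- function(saturation,
                      anchors = rbind(c(95, 2.33), c(75, 2.38))) {
  anchors <- as.matrix(anchors)
  if (!all(dim(anchors) == c(2L, 2L))) stop("anchors must be two (s, mua) pairs")
  if (anchors[1, 1] == anchors[2, 1])
    stop("degenerate calibration: anchor saturations are identical")
  if (any(saturation < 0 | saturation > 100))
    stop("saturation must lie in [0, 100]")
  slope <- (anchors[2, 2] - anchors[1, 2]) / (anchors[2, 1] - anchors[1, 1])
  anchors[1, 2] + slope * (saturation - anchors[1, 1])
}

#' Oxygenation conditions for the pulmonary-embolism severity groups
#'
#' The four study groups: a normal control and three disease severities
#' (Level I mild, Level II medium, Level III serious), each defined by an
#' arterial (SaO2) and venous (SvO2) hemoglobin oxygen saturation.
#'
#' @return Data frame with columns `condition`, `level` (0 = Normal ... 3 =
#'   LevelIII), `sao2`, `svo2` (percent).
#' @export
#' @examples
#' oxygenation_conditions()
oxygenation_conditions <- function() {
  data.frame(
    condition = c("Normal", "LevelI", "LevelII", "LevelIII"),
    level = 0:3,
    sao2 = c(95, 93, 91, 89),
    svo2 = c(75, 71, 67, 63),
    stringsAsFactors = FALSE
  )
}

#' Apply an oxygenation condition to a tissue table
#'
#' Returns a copy of `table` in which the arterial and venous blood
#' absorption coefficients are replaced by [blood_mua()] evaluated at the
#' condition's SaO2 and SvO2. All other properties are unchanged.
#'
#' @param table A `tissue_table` containing `arterial_blood` and
#'   `venous_blood` rows.
#' @param condition One row of [oxygenation_conditions()] (or any list with
#'   `sao2` and `svo2`), or a condition name such as `"LevelII"`.
#' @param anchors Saturation-to-mua anchors passed to [blood_mua()].
#' @return The perturbed `tissue_table`.
#' @export
#' @examples
#' apply_condition(default_tissue_table(), "LevelIII")
apply_condition <- function(table, condition,
                            anchors = rbind(c(95, 2.33), c(75, 2.38))) {
  if (is.character(condition)) {
    conds <- oxygenation_conditions()
    i <- match(condition, conds$condition)
    if (is.na(i)) stop("unknown oxygenation condition: ", condition)
    condition <- conds[i, ]
  }
  if (condition$svo2 >= condition$sao2)
    stop("invalid condition: require svo2 < sao2")
  ia <- match("arterial_blood", table$tissue)
  iv <- match("venous_blood", table$tissue)
  if (is.na(ia) || is.na(iv))
    stop("table must contain arterial_blood and venous_blood entries")
  table$mua[ia] <- blood_mua(condition$sao2, anchors)
  table$mua[iv] <- blood_mua(condition$svo2, anchors)
  table$mut <- table$mua + table$mus
  table
}

#' Read / write tissue tables
#'
#' Tables round-trip through CSV (one row per tissue) or JSON (records plus
#' the wavelength tag).
#'
#' @param table A `tissue_table`.
#' @param path Output/input file path; format chosen by extension
#'   (`.csv` or `.json`).
#' @return `write_tissue_table` returns `path` invisibly;
#'   `read_tissue_table` returns the `tissue_table`.
#' @export
write_tissue_table <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(wavelength_nm = attr(table, "wavelength_nm"),
           tissues = as.data.frame(table)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_tissue_table
#' @param wavelength_nm Wavelength tag used when reading CSV (JSON stores
#'   its own).
#' @export
read_tissue_table <- function(path, wavelength_nm = 800) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    as_tissue_table(obj$tissues, obj$wavelength_nm)
  } else {
    as_tissue_table(utils::read.csv(path, stringsAsFactors = FALSE),
                    wavelength_nm)
  }
}
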