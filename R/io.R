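#' Derive a reproducible RNG seed from a base seed and a stream label
#'
#' Deterministic, collision-resistant mapping from `(base, label, index)`
#' to a 31-bit integer seed, so that every randomized stage of a pipeline
#' draws from its own reproducible stream. Distinct indices under the same
#' base and label always map to distinct seeds (the final mixing step is a
#' bijection modulo a prime).
#'
#' @param base Integer base seed.
#' @param label Character stream label (e.g. `"repeat"`, `"adjoint"`).
#' @param index Non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "repeat", 0)
#' derive_seed(1, "repeat", 1)
derive_seed <- function(base, label = "run", index = 0L) {
  m <- 2147483647  # 2^31 - 1, prime; intermediates stay below 2^53
  h <- (abs(as.numeric(base)) + 1) %% m
  h <- (h * 69069 + 1) %% m
  for (ch in utf8ToInt(as.character(label)))
    h <- (h * 69069 + ch + 1) %% m
  h <- (h * 69069 + (as.numeric(index) %% m) + 1) %% m
  h <- (h * 69069 + 1) %% m
  as.integer(h)
}

.known_config_keys <- c("phantom", "tissues", "conditions", "run",
                        "separation_cm", "detector_side_mm", "anchors")

#' Load / save a pipeline configuration
#'
#' Configurations are JSON or YAML (chosen by extension) with optional
#' sections `phantom` (arguments of [phantom_config()]), `tissues` (rows of
#' a tissue table), `conditions` (oxygenation groups), `run` (arguments of
#' [run_config()]), plus scalars `separation_cm`, `detector_side_mm` and
#' the blood-saturation `anchors`. Missing sections are filled with the
#' package defaults (the 800 nm property table, the four oxygenation
#' groups, 1e6 photons x 10 repeats, 2.9 cm separation); unknown keys and
#' invalid values raise validation errors naming the offending field.
#'
#' @param path Configuration file (`.json`, `.yaml`, or `.yml`).
#' @return A validated config bundle: list with elements `phantom`
#'   (`phantom_config`), `tissues` (`tissue_table`), `conditions`,
#'   `run` (`run_config`), `separation_cm`, `detector_side_mm`, `anchors`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .known_config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  validate_config_bundle(raw)
}

#' @rdname load_config
#' @param config A config bundle (as returned by [load_config()]) or a
#'   plain list of overrides.
#' @export
save_config <- function(config, path) {
  out <- list(
    phantom = unclass(config$phantom),
    tissues = as.data.frame(config$tissues),
    conditions = as.data.frame(config$conditions),
    run = unclass(config$run),
    separation_cm = config$separation_cm,
    detector_side_mm = config$detector_side_mm,
    anchors = config$anchors)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(rapply(out, unclass, how = "replace"), path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

validate_config_bundle <- function(raw) {
  phantom <- do.call(phantom_config, as.list(raw$phantom %||% list()))
  tissues <- if (is.null(raw$tissues)) default_tissue_table()
  else as_tissue_table(as.data.frame(raw$tissues))
  conditions <- if (is.null(raw$conditions)) oxygenation_conditions()
  else {
    cd <- as.data.frame(raw$conditions)
    if (!all(c("condition", "sao2", "svo2") %in% names(cd)))
      stop("conditions need columns condition, sao2, svo2")
    if (any(cd$svo2 >= cd$sao2))
      stop("conditions: require svo2 < sao2 in every group")
    if (is.null(cd$level)) cd$level <- seq_len(nrow(cd)) - 1L
    cd
  }
  run <- do.call(run_config, as.list(raw$run %||% list()))
  sep <- raw$separation_cm %||% 2.9
  if (sep <= 0) stop("separation_cm must be > 0")
  side <- raw$detector_side_mm %||% 2.29
  if (side <= 0) stop("detector_side_mm must be > 0")
  anchors <- if (is.null(raw$anchors)) rbind(c(95, 2.33), c(75, 2.38))
  else matrix(unlist(raw$anchors), 2, 2, byrow = TRUE)
  list(phantom = phantom, tissues = tissues, conditions = conditions,
       run = run, separation_cm = sep, detector_side_mm = side,
       anchors = anchors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records everything needed to re-run a stage bit-identically: the config
#' snapshot, the derived per-run seeds, package and R versions, digests of
#' the listed files, and wall-clock metadata.
#'
#' @param path Output JSON path.
#' @param config Config bundle or any serializable configuration snapshot.
#' @param seeds Integer vector of seeds actually used.
#' @param files Character vector of produced files to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seeds = integer(0),
                           files = character(0)) {
  digest <- if (length(files))
    as.list(tools::md5sum(files[file.exists(files)])) else list()
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  obj <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = as.character(utils::packageVersion("thoraxmc")),
    r_version = R.version.string,
    seeds = seeds,
    files = digest,
    config = if (is.null(config)) list() else strip(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read detector records
#'
#' Columnar CSV: exit position and direction, residual weight, total path
#' length, and one partial-path column per tissue.
#'
#' @param records Data frame of detector records (from an `mc_result`).
#' @param path CSV path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) utils::read.csv(path)
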