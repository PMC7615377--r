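# File formats: localisation and track CSV, float-TIFF maps with JSON
# sidecars, YAML run configuration.

#' Read a localisation table
#'
#' Expects a CSV with header `frame,x_um,y_um[,intensity][,truth_id]`;
#' coordinates must carry the `_um` suffix (micrometre units are part of
#' the contract).  Rows are validated and returned frame-sorted.
#'
#' @param path CSV file path.
#' @return data.frame of detections.
#' @export
read_localisations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  det <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad_unit <- grep("^(x|y)_(mm|m|px|pixel)", names(det), value = TRUE)
  if (length(bad_unit))
    stop("unit mismatch: columns ", paste(bad_unit, collapse = ", "),
         " -- coordinates must be in micrometres (x_um, y_um)")
  need <- c("frame", "x_um", "y_um")
  miss <- setdiff(need, names(det))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  for (cn in need) {
    bad <- which(!is.finite(det[[cn]]))
    if (length(bad))
      stop("non-finite ", cn, " at data line ", bad[1L], " of ", path)
  }
  det <- validate_detections(det)
  det[order(det$frame), , drop = FALSE]
}

#' Write a localisation table
#'
#' @param det detections data.frame (`frame`, `x_um`, `y_um`, optional
#'   extras).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localisations <- function(det, path) {
  det <- validate_detections(det)
  utils::write.csv(det, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a track table
#'
#' Columns: `track_id,frame,x_um,y_um,vx_mm_s,vy_mm_s,ax_mm_s2,ay_mm_s2`.
#'
#' @param fit an `ulm_tracks` object or a compatible data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(fit, path) {
  tr <- if (inherits(fit, "ulm_tracks")) fit$tracks else as.data.frame(fit)
  cols <- c("track_id", "frame", "x_um", "y_um", "vx_mm_s", "vy_mm_s",
            "ax_mm_s2", "ay_mm_s2")
  miss <- setdiff(cols, names(tr))
  if (length(miss)) stop("track table missing: ", paste(miss, collapse = ", "))
  utils::write.csv(tr[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track table into a renderable object
#'
#' Rebuilds a minimal `ulm_tracks` object (no pairing log) from a track CSV
#' written by [write_tracks()], for map rendering.
#'
#' @param path track CSV path.
#' @param frame_rate acquisition frame rate in Hz.
#' @return an `ulm_tracks` object.
#' @export
read_tracks <- function(path, frame_rate) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("track_id", "frame", "x_um", "y_um", "vx_mm_s", "vy_mm_s",
            "ax_mm_s2", "ay_mm_s2")
  miss <- setdiff(cols, names(tr))
  if (length(miss)) stop("track table missing: ", paste(miss, collapse = ", "))
  if (!"det_index" %in% names(tr)) tr$det_index <- NA_integer_
  structure(list(tracks = tr,
                 pairs = data.frame(frame_k = integer(), frame_k1 = integer(),
                                    det_k = integer(), det_k1 = integer(),
                                    track_id = integer()),
                 n_detections = nrow(tr),
                 config = kalman_config(frame_rate),
                 detections = NULL),
            class = "ulm_tracks")
}

#' Write a rendered map as float TIFF plus JSON sidecar
#'
#' The TIFF has two 32-bit float pages: page 1 the map values affinely
#' rescaled to \[0, 1\] (the scaling recorded in the sidecar as `value_min`
#' and `value_max`), page 2 a validity mask (1 = sampled pixel).  The
#' sidecar (`<path>.json`) records pixel size, origin, kind, frame rate and
#' scaling so [read_map()] can restore the map exactly (to float32
#' precision).
#'
#' @param map an `ulm_map`.
#' @param path output TIFF path.
#' @param extra optional named list merged into the sidecar (e.g. seed,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, extra = NULL) {
  stopifnot(inherits(map, "ulm_map"))
  g <- map$grid
  mask <- ifelse(is.finite(g) & map$counts > 0, 1, 0)
  v <- g[is.finite(g)]
  vmin <- if (length(v)) min(v) else 0
  vmax <- if (length(v)) max(v) else 0
  norm <- if (vmax > vmin) (g - vmin) / (vmax - vmin) else g * 0
  norm[!is.finite(norm)] <- 0
  tiff::writeTIFF(list(norm, mask), path, bits.per.sample = 32L,
                  reduce = FALSE)
  side <- c(list(kind = map$kind, pixel_size_um = map$pixel_size,
                 origin_um = map$origin, frame_rate = map$frame_rate,
                 value_min = vmin, value_max = vmax,
                 nrow = nrow(g), ncol = ncol(g)), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a map written by [write_map()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return an `ulm_map` (unsampled pixels restored to `NA`; counts reduced
#'   to the 0/1 validity mask).
#' @export
read_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- pages[[1L]] * (side$value_max - side$value_min) + side$value_min
  mask <- pages[[2L]] > 0.5
  g[!mask] <- NA_real_
  if (side$kind == "density") g[!mask] <- 0
  structure(list(grid = g, counts = mask * 1, pixel_size = side$pixel_size_um,
                 origin = as.numeric(side$origin_um), kind = side$kind,
                 frame_rate = side$frame_rate),
            class = "ulm_map")
}

#' Read a YAML/JSON run configuration
#'
#' Validates keys against the documented schema and returns a
#' [kalman_config()] plus rendering parameters.  Unknown keys are
#' rejected.
#'
#' @param path YAML (or JSON) file with a `schema_version` field.
#' @return list with `config` (a `kalman_config`) and `render` (pixel size,
#'   spacing).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("schema_version", "frame_rate", "model", "sigma_a", "sigma_obs",
             "gate_chi2", "v_max", "cost_cap", "max_misses",
             "min_track_length", "pixel_size", "spacing", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$schema_version))
    stop("configuration must declare 'schema_version'")
  if (is.null(cfg$frame_rate)) stop("configuration must set 'frame_rate'")
  pick <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  kc <- kalman_config(
    frame_rate = cfg$frame_rate,
    model = pick("model", "accel"),
    sigma_a = pick("sigma_a", 25),
    sigma_obs = pick("sigma_obs", 10),
    gate_chi2 = pick("gate_chi2", stats::qchisq(0.99, 2)),
    v_max = pick("v_max", 50),
    cost_cap = pick("cost_cap", 0.5),
    max_misses = pick("max_misses", 0L),
    min_track_length = pick("min_track_length", 3L))
  list(config = kc,
       render = list(pixel_size = pick("pixel_size", 10),
                     spacing = pick("spacing", pick("pixel_size", 10) / 2)),
       seed = pick("seed", 1L))
}
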