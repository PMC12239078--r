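#' Read a trajectory table
#'
#' Reads a comma-separated trajectory export with header columns
#' `particle,frame,x_um,y_um` (any order; extra columns ignored), or
#' pixel-unit columns `x_px,y_px` converted with `pixel_size`. Frames
#' are 0-based and may be gapped; duplicated (particle, frame) rows and
#' non-finite positions are rejected with row numbers.
#'
#' @param path CSV file path.
#' @param pixel_size micrometers per pixel; required when the file
#'   carries `x_px,y_px` columns.
#' @return trajectory data.frame `particle,frame,x_um,y_um`.
#' @export
read_trajectories <- function(path, pixel_size = NULL) {
  d <- read.csv(path, check.names = TRUE)
  if (all(c("x_px", "y_px") %in% names(d)) && !("x_um" %in% names(d))) {
    if (is.null(pixel_size)) {
      stop("pixel-unit file: supply `pixel_size` to convert to micrometers", call. = FALSE)
    }
    d$x_um <- d$x_px * pixel_size
    d$y_um <- d$y_px * pixel_size
  }
  need <- c("particle", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  bad <- which(!is.finite(d$x_um) | !is.finite(d$y_um) | !is.finite(d$frame))
  if (length(bad)) {
    stop(sprintf(
      "%s: non-finite values at data row(s) %s", path,
      paste(head(bad, 5), collapse = ", ")
    ), call. = FALSE)
  }
  dup <- which(duplicated(d[c("particle", "frame")]))
  if (length(dup)) {
    stop(sprintf(
      "%s: duplicated (particle, frame) at data row(s) %s", path,
      paste(head(dup, 5), collapse = ", ")
    ), call. = FALSE)
  }
  d <- d[order(d$particle, d$frame), need]
  rownames(d) <- NULL
  d
}

#' Write a trajectory table
#'
#' @param traj trajectory data.frame.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  assert_trajectories(traj)
  write.csv(traj[c("particle", "frame", "x_um", "y_um")], path, row.names = FALSE)
  invisible(path)
}

#' Read an oscillation sweep CSV (`omega_rad_s,g_prime_pa,g_loss_pa`)
#' @param path CSV path.
#' @return an [oscillation_sweep()].
#' @export
read_sweep <- function(path) {
  d <- read.csv(path)
  need <- c("omega_rad_s", "g_prime_pa", "g_loss_pa")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ",")), call. = FALSE)
  }
  oscillation_sweep(d$omega_rad_s, d$g_prime_pa, d$g_loss_pa)
}

#' Write an oscillation sweep CSV
#' @param sweep an [oscillation_sweep()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Read a flow curve CSV (`shear_rate_1_s,viscosity_pa_s`)
#' @param path CSV path.
#' @return a [flow_curve()].
#' @export
read_flow_curve <- function(path) {
  d <- read.csv(path)
  need <- c("shear_rate_1_s", "viscosity_pa_s")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ",")), call. = FALSE)
  }
  flow_curve(d$shear_rate_1_s, d$viscosity_pa_s)
}

#' Write a flow curve CSV
#' @param curve a [flow_curve()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_flow_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read a FRAP trace CSV plus metadata JSON
#'
#' The CSV carries `time_s,i_frap,i_ref,i_back`; the JSON sidecar
#' supplies `t_bleach_s` and optionally `w_um`, `i_frap_pre`,
#' `i_ref_pre`.
#'
#' @param path trace CSV.
#' @param meta_path metadata JSON (default: `path` with a `.json`
#'   extension).
#' @return a [frap_trace()] with attribute `w_um` when present.
#' @export
read_frap_trace <- function(path, meta_path = sub("\\.csv$", ".json", path)) {
  d <- read.csv(path)
  need <- c("time_s", "i_frap", "i_ref", "i_back")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ",")), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$t_bleach_s)) stop(meta_path, ": `t_bleach_s` missing", call. = FALSE)
  tr <- frap_trace(d$time_s, d$i_frap, d$i_ref, d$i_back,
    t_bleach = meta$t_bleach_s,
    i_frap_pre = meta$i_frap_pre, i_ref_pre = meta$i_ref_pre
  )
  attr(tr, "w_um") <- meta$w_um
  tr
}

#' Write a FRAP trace CSV plus metadata JSON
#' @param trace a [frap_trace()].
#' @param path destination CSV; the JSON sidecar takes a `.json`
#'   extension.
#' @param w_um bleach radius recorded in the metadata (optional).
#' @return `path`, invisibly.
#' @export
write_frap_trace <- function(trace, path, w_um = NULL) {
  stopifnot(inherits(trace, "frap_trace"))
  write.csv(trace$data, path, row.names = FALSE)
  meta <- list(
    t_bleach_s = trace$t_bleach,
    i_frap_pre = trace$i_frap_pre, i_ref_pre = trace$i_ref_pre
  )
  if (!is.null(w_um)) meta$w_um <- w_um
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a binding series CSV (`target_conc_mg_ml,response`)
#' @param path CSV path.
#' @param meta_path optional JSON with `ligand_conc`; defaults to the
#'   CSV path with a `.json` extension when that file exists.
#' @return a [binding_series()].
#' @export
read_binding_series <- function(path, meta_path = NULL) {
  d <- read.csv(path)
  need <- c("target_conc_mg_ml", "response")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ",")), call. = FALSE)
  }
  ligand <- 0
  if (is.null(meta_path)) {
    cand <- sub("\\.csv$", ".json", path)
    if (file.exists(cand)) meta_path <- cand
  }
  if (!is.null(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$ligand_conc)) ligand <- meta$ligand_conc
  }
  binding_series(d$target_conc_mg_ml, d$response, ligand_conc = ligand)
}

#' Write a binding series CSV
#' @param series a [binding_series()].
#' @param path destination CSV; ligand concentration goes to a `.json`
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_binding_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  jsonlite::write_json(list(ligand_conc = attr(series, "ligand_conc") %||% 0),
    sub("\\.csv$", ".json", path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an 8-bit grayscale micrograph (TIFF + JSON sidecar)
#'
#' @param path TIFF path (single-channel grayscale).
#' @param meta_path JSON sidecar with `scale_nm_per_px` (default: `path`
#'   with `.json`); alternatively pass `scale` directly.
#' @param scale nanometers per pixel, overriding the sidecar.
#' @param rescale allow rescaling 16-bit input to 8-bit (otherwise
#'   rejected, because the fixed pore threshold presumes 8-bit gray
#'   levels).
#' @return a [micrograph()].
#' @export
read_micrograph <- function(path, meta_path = sub("\\.tiff?$", ".json", path),
                            scale = NULL, rescale = FALSE) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) stop(path, ": RGB/multichannel input not supported", call. = FALSE)
    img <- img[, , 1]
  }
  if (max(img) > 255) {
    if (!rescale) {
      stop(path, ": not 8-bit; pass `rescale = TRUE` to rescale explicitly", call. = FALSE)
    }
    img <- round(img / max(img) * 255)
  }
  if (is.null(scale)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    scale <- meta$scale_nm_per_px
    if (is.null(scale)) stop(meta_path, ": `scale_nm_per_px` missing", call. = FALSE)
  }
  micrograph(img, scale)
}

#' Write a micrograph as 8-bit TIFF + JSON sidecar
#' @param image a [micrograph()].
#' @param path destination TIFF.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  stopifnot(inherits(image, "micrograph"))
  tiff::writeTIFF(image$pixels / 255, path, bits.per.sample = 8)
  jsonlite::write_json(list(scale_nm_per_px = image$scale_nm_per_px),
    sub("\\.tiff?$", ".json", path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write pore records CSV
#' @param records a `pore_records` table.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_pore_records <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Provenance record for an output artifact
#'
#' Captures what is needed to reproduce an artifact: package version,
#' the configuration (including every seed), and digests of the inputs.
#' Wall-clock timestamps are off by default so that identical runs
#' produce byte-identical artifacts; enable them when auditing live
#' runs.
#'
#' @param config named list of the parameters used (seeds included).
#' @param inputs character vector of input file paths to digest (size
#'   is recorded; content digest via `tools::md5sum`).
#' @param timestamp record wall-clock time (breaks byte-identical
#'   reruns)?
#' @return list of class `provenance_record`.
#' @export
provenance_record <- function(config = list(), inputs = character(0),
                              timestamp = FALSE) {
  digests <- if (length(inputs)) {
    data.frame(
      path = inputs,
      md5 = unname(tools::md5sum(inputs)),
      bytes = unname(file.size(inputs))
    )
  } else {
    NULL
  }
  rec <- list(
    tool = "mucodiff",
    version = as.character(packageVersion("mucodiff")),
    config = config,
    inputs = digests
  )
  if (timestamp) rec$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  class(rec) <- c("provenance_record", "list")
  rec
}

#' Write a provenance record alongside an artifact
#' @param record a [provenance_record()].
#' @param artifact_path path of the artifact the record describes; the
#'   record is written next to it with suffix `.provenance.json`.
#' @return the provenance path, invisibly.
#' @export
write_provenance <- function(record, artifact_path) {
  stopifnot(inherits(record, "provenance_record"))
  out <- paste0(artifact_path, ".provenance.json")
  jsonlite::write_json(unclass(record), out,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out)
}
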