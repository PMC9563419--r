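#' High-speed videolaryngoscopy recording
#'
#' Container for an ordered stack of RGB frames with a frame rate. Frames are
#' `H x W x 3` arrays with integer intensities in `[0, 255]`; all frames share
#' the same dimensions and at least two frames are required (spectral analysis
#' is meaningless on a single image).
#'
#' @param frames list of `H x W x 3` numeric arrays, intensities in 0..255.
#' @param fps frames per second (positive; clinical systems use 2400 or 3200).
#' @param source_id free-text provenance label.
#' @return An object of class `hsv_recording` with elements `frames`, `fps`,
#'   `source_id` and `dim` (`c(H, W)`).
#' @export
hsv_recording <- function(frames, fps, source_id = "unknown") {
  if (!is.list(frames) || length(frames) < 2L)
    ltg_input_error("a recording needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    ltg_config_error("fps must be a positive number")
  d <- dim(frames[[1]])
  if (length(d) != 3L || d[3] != 3L)
    ltg_input_error("frames must be H x W x 3 RGB arrays")
  for (f in frames) {
    if (!identical(dim(f), d))
      ltg_input_error("all frames must share identical dimensions")
  }
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255)
    ltg_input_error("frame intensities must lie in [0, 255]")
  structure(list(frames = frames, fps = fps, source_id = source_id,
                 dim = d[1:2]),
            class = "hsv_recording")
}

#' @export
print.hsv_recording <- function(x, ...) {
  cat(sprintf("<hsv_recording> %d frames, %d x %d px, %.0f fps (%s)\n",
              length(x$frames), x$dim[1], x$dim[2], x$fps, x$source_id))
  invisible(x)
}

n_frames <- function(rec) length(rec$frames)

#' Read a recording from a directory of frame images
#'
#' Frames are read from lexicographically sorted files matching `pattern`
#' (zero-padded numbering is therefore required, e.g. `frame_00042.png`).
#' PNG and TIFF frames are supported; lossy video containers are not decoded
#' -- extract frames to a lossless directory first, since lossy compression
#' perturbs per-pixel spectra. The frame rate is taken from a `meta.json`
#' file in the directory (written by [write_recording()]) or from
#' `fps_override`, which wins when both are present.
#'
#' @param path directory containing frame images.
#' @param fps_override frame rate to use (required when no `meta.json`).
#' @param pattern filename glob selecting the frames.
#' @return An [hsv_recording()].
#' @export
read_recording <- function(path, fps_override = NULL, pattern = "*.png") {
  if (!dir.exists(path)) {
    if (file.exists(path))
      ltg_format_error(paste0(
        "'", path, "' is a file; only frame directories are readable. ",
        "Decode video containers to a PNG/TIFF frame directory first."))
    ltg_io_error(paste0("no such directory: ", path))
  }
  files <- sort(list.files(path, pattern = utils::glob2rx(pattern),
                           full.names = TRUE))
  if (length(files) < 2L)
    ltg_input_error(paste0("fewer than 2 frames match '", pattern, "' in ", path))

  fps <- fps_override
  meta_file <- file.path(path, "meta.json")
  meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file) else NULL
  if (is.null(fps)) fps <- meta$fps
  if (is.null(fps))
    ltg_config_error("frame rate unavailable: no meta.json and no fps_override")

  read_one <- function(f) {
    img <- if (grepl("\\.tiff?$", f, ignore.case = TRUE)) tiff::readTIFF(f)
           else png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    round(img * 255)
  }
  frames <- lapply(files, read_one)
  d <- dim(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), d))
      ltg_input_error("frames in directory differ in size")
  hsv_recording(frames, fps = fps,
                source_id = meta$source_id %||% basename(path))
}

#' Write a recording as a PNG frame directory
#'
#' Writes zero-padded `frame_#####.png` files plus a `meta.json` holding the
#' frame rate and provenance label, so [read_recording()] round-trips the
#' recording bit-exactly.
#'
#' @param rec an [hsv_recording()].
#' @param path output directory (created if missing).
#' @return Invisibly, the vector of written frame paths.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "hsv_recording"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    ltg_io_error(paste0("cannot create directory: ", path))
  files <- character(n_frames(rec))
  for (i in seq_along(rec$frames)) {
    files[i] <- file.path(path, sprintf("frame_%05d.png", i))
    png::writePNG(rec$frames[[i]] / 255, files[i])
  }
  jsonlite::write_json(list(fps = rec$fps, source_id = rec$source_id),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(files)
}

# Full-precision headerless CSV grid writer/reader: row-major, origin
# top-left, phase in radians; %.17g guarantees double round-trip.
write_grid_csv <- function(m, file) {
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, file)
}

read_grid_csv <- function(file) {
  as.matrix(utils::read.table(file, sep = ",", header = FALSE,
                              na.strings = c("NA", "nan")))
}

# Pseudocolor PNG rendering of a numeric grid (NA -> black).
write_map_png <- function(m, file, palette = grDevices::hcl.colors(256, "viridis")) {
  rng <- range(m, na.rm = TRUE)
  if (!is.finite(rng[1]) || diff(rng) == 0) rng <- c(0, 1)
  idx <- matrix(NA_integer_, nrow(m), ncol(m))
  ok <- is.finite(m)
  idx[ok] <- pmin(255L, pmax(0L, as.integer(round(
    (m[ok] - rng[1]) / (rng[2] - rng[1]) * 255)))) + 1L
  rgb <- grDevices::col2rgb(palette)
  img <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(m), ncol(m))
    plane[ok] <- rgb[ch, idx[ok]] / 255
    img[, , ch] <- plane
  }
  png::writePNG(img, file)
}

#' Export laryngotopographic maps
#'
#' Writes the F0, normalized-amplitude and phase maps plus the vibrating
#' mask in the requested formats and returns a manifest of everything
#' written. CSV grids are headerless, row-major with origin top-left, full
#' double precision, phase in radians; PNGs are pseudocolor renderings.
#' A `manifest.json` is written alongside the files.
#'
#' @param maps an `ltg_maps` object from [build_ltg_maps()].
#' @param out_dir output directory (created if missing).
#' @param formats subset of `c("csv", "png", "rds")`; empty writes nothing.
#'   `rds` stores the full map stack as one compressed array container.
#' @return Named list of written file paths (the manifest), invisibly the
#'   same list.
#' @export
write_maps <- function(maps, out_dir, formats = c("csv", "png")) {
  stopifnot(inherits(maps, "ltg_maps"))
  if (length(formats) == 0) return(list())
  formats <- match.arg(formats, c("csv", "png", "rds"), several.ok = TRUE)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    ltg_io_error(paste0("cannot create directory: ", out_dir))
  grids <- list(f0 = maps$f0_map, amplitude = maps$amp_map,
                phase = maps$phase_map,
                vibrating_mask = maps$vibrating_mask * 1)
  manifest <- list()
  for (nm in names(grids)) {
    if ("csv" %in% formats) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write_grid_csv(grids[[nm]], f)
      manifest[[paste0(nm, "_csv")]] <- f
    }
    if ("png" %in% formats) {
      f <- file.path(out_dir, paste0(nm, ".png"))
      write_map_png(grids[[nm]], f)
      manifest[[paste0(nm, "_png")]] <- f
    }
  }
  if ("rds" %in% formats) {
    f <- file.path(out_dir, "maps.rds")
    saveRDS(maps, f)
    manifest$maps_rds <- f
  }
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  manifest$manifest_json <- mf
  invisible(manifest)
}
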