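csvNote <- paste("# All coordinates are 0-based voxel indices in (z,y,x);",
                 "all physical quantities are in micrometres (um).")

writeCsvWithNote <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csvNote, con)
  utils::write.csv(df, con, row.names = FALSE)
}

readCsvWithNote <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# One 3D array <-> multi-page TIFF (one page per z slice), with a JSON sidecar
# recording the intensity scale so float data round-trips.
writeArrayTIFF <- function(arr, path, bitsPerSample = 32L) {
  maxI <- max(arr, 1e-12)
  if (bitsPerSample == 16L && all(arr == round(arr)) && max(arr) <= 65535) {
    scale <- 65535
  } else scale <- maxI
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / scale)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF at '", path, "': ", attr(ok, "condition")$message)
  scale
}

readArrayTIFF <- function(path, scale = 1) {
  pages <- try(tiff::readTIFF(path, all = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop("failed to read TIFF at '", path, "': ",
         attr(pages, "condition")$message)
  dims <- unique(t(vapply(pages, dim, integer(2))))
  if (nrow(dims) != 1L)
    stop("inconsistent page shapes in '", path, "'")
  arr <- array(0, c(length(pages), dims[1, 1], dims[1, 2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr * scale
}

#' Write a simulated environment to disk
#'
#' The composite volume and auxiliary channels go to multi-page TIFF (one
#' page per z slice), the per-voxel attribution labels to a 16-bit TIFF, the
#' ground-truth object table to CSV (columns object_id, class, cz, cy, cx,
#' orientation_deg, clipped, params_json; 0-based voxel coordinates), and the
#' intensity scales/spacing/noise rate to a JSON sidecar, so a write-read
#' round trip reproduces the arrays and the object table.
#'
#' @param env a \linkS4class{SimulatedEnvironment}.
#' @param dir output directory (created if needed).
#' @param bitsPerSample TIFF bit depth for intensity channels (16 or 32).
#' @return invisibly, the directory.
#' @export
writeEnvironment <- function(env, dir, bitsPerSample = 32L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- list(volume = writeArrayTIFF(voxelData(envVolume(env)),
                                         file.path(dir, "volume.tif"),
                                         bitsPerSample))
  for (nm in names(env@channels))
    scales[[nm]] <- writeArrayTIFF(voxelData(env@channels[[nm]]),
                                   file.path(dir, paste0(nm, ".tif")),
                                   bitsPerSample)
  labScale <- max(1L, max(env@labels))
  tiff::writeTIFF(lapply(seq_len(dim(env@labels)[1]),
                         function(z) env@labels[z, , ] / labScale),
                  file.path(dir, "labels.tif"), bits.per.sample = 16L)
  writeCsvWithNote(gtObjects(envTruth(env)), file.path(dir, "truth.csv"))
  meta <- list(spacing = voxelSpacing(envVolume(env)),
               scales = scales, labelScale = labScale,
               noiseRate = noiseRate(envTruth(env)), seed = env@seed,
               bitsPerSample = bitsPerSample,
               axisOrder = "zyx", coordinateOrigin = "0-based")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back an environment written by \code{\link{writeEnvironment}}
#'
#' @param dir the environment directory.
#' @return A \linkS4class{SimulatedEnvironment} (tail centerlines are not
#'   persisted and come back empty).
#' @export
readEnvironment <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  spacing <- as.numeric(meta$spacing)
  vol <- readArrayTIFF(file.path(dir, "volume.tif"), meta$scales$volume)
  chNames <- setdiff(names(meta$scales), "volume")
  channels <- lapply(chNames, function(nm)
    VoxelGrid(readArrayTIFF(file.path(dir, paste0(nm, ".tif")),
                            meta$scales[[nm]]), spacing, nm))
  names(channels) <- chNames
  labRaw <- readArrayTIFF(file.path(dir, "labels.tif"), meta$labelScale)
  labels <- array(as.integer(round(labRaw)), dim(labRaw))
  objects <- readCsvWithNote(file.path(dir, "truth.csv"))
  if (nrow(objects) == 0L)
    objects <- data.frame(object_id = integer(), class = character(),
                          cz = numeric(), cy = numeric(), cx = numeric(),
                          orientation_deg = numeric(), clipped = logical(),
                          params_json = character())
  new("SimulatedEnvironment",
      volume = VoxelGrid(vol, spacing, "composite"),
      channels = channels, labels = labels,
      truth = new("GroundTruth", objects = objects,
                  noiseRate = as.numeric(meta$noiseRate)),
      centerlines = list(), seed = as.numeric(meta$seed))
}

#' Read a multi-page TIFF z-stack as a VoxelGrid
#'
#' Axis order is normalized to (z, y, x). Voxel spacing is taken from (in
#' order of precedence) the \code{spacing} override, a JSON sidecar written
#' by this package, or OME-XML PhysicalSize attributes in the TIFF
#' description; an error is raised when none is available.
#'
#' @param path TIFF/OME-TIFF file.
#' @param spacing optional numeric(3) (z,y,x) um override.
#' @return A \linkS4class{VoxelGrid}.
#' @export
readStack <- function(path, spacing = NULL) {
  pages <- try(tiff::readTIFF(path, all = TRUE, info = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop("failed to read TIFF at '", path, "': ",
         attr(pages, "condition")$message)
  dims <- unique(t(vapply(pages, dim, integer(2))))
  if (nrow(dims) != 1L) stop("inconsistent page shapes in '", path, "'")
  scale <- 1
  sidecar <- file.path(dirname(path), "meta.json")
  if (is.null(spacing)) {
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      spacing <- as.numeric(meta$spacing)
      nm <- sub("\\.tif{1,2}$", "", basename(path))
      if (!is.null(meta$scales[[nm]])) scale <- as.numeric(meta$scales[[nm]])
    } else {
      desc <- attr(pages[[1]], "description")
      if (!is.null(desc)) {
        getPS <- function(axis) {
          m <- regmatches(desc, regexpr(
            paste0("PhysicalSize", axis, "=\"[0-9.eE+-]+\""), desc))
          if (length(m)) as.numeric(gsub("[^0-9.eE+-]", "", sub(
            paste0("PhysicalSize", axis, "="), "", m))) else NA_real_
        }
        ps <- c(getPS("Z"), getPS("Y"), getPS("X"))
        if (all(is.finite(ps))) spacing <- ps
      }
    }
  }
  if (is.null(spacing))
    stop("no voxel spacing found for '", path,
         "': supply spacing= or provide a meta.json sidecar / OME metadata")
  arr <- array(0, c(length(pages), dims[1, 1], dims[1, 2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  VoxelGrid(arr * scale, spacing, "composite")
}
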