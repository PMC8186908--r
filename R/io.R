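#' Read an imaging stack from a multi-page TIFF
#'
#' Grayscale multi-page TIFFs (uint8/16 or float32) are read losslessly:
#' integer encodings are rescaled back to raw counts using the file's bit
#' depth, float encodings are taken verbatim.
#'
#' @param path Path to a multi-page TIFF with >= 2 frames of constant shape.
#' @param frame_rate_hz Acquisition frame rate (4 Hz FA, 10 Hz calcium).
#' @param channel `"FA"` or `"calcium"`.
#' @param t0_s Time of the first frame relative to trial start.
#' @return An [imaging_stack()].
#' @export
read_stack <- function(path, frame_rate_hz, channel = c("FA", "calcium"),
                       t0_s = 0) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  scale_file <- paste0(path, ".scale.json")
  scale <- if (file.exists(scale_file))
    jsonlite::read_json(scale_file)$scale else NULL
  pages <- tiff::readTIFF(path, all = TRUE, as.is = is.null(scale))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("stack TIFF must contain at least 2 frames")
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("inconsistent frame shapes in TIFF stack")
  d <- dims[[1L]]
  frames <- array(0, c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  if (!is.null(scale)) frames <- frames * scale
  imaging_stack(frames, frame_rate_hz, channel, t0_s)
}

#' Write an imaging stack to a multi-page TIFF
#'
#' Integer-valued stacks with a maximum below 2^16 are written as uint16
#' (bit-exact round trip). Anything else is written as 32-bit float after
#' division by the stack maximum; the scale factor is stored in a JSON
#' sidecar (`<path>.scale.json`) that [read_stack()] applies transparently,
#' so float round trips are lossless to single precision.
#'
#' @param stack An [imaging_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "imaging_stack"))
  tdim <- dim(stack$frames)[1L]
  pages <- lapply(seq_len(tdim), function(i) stack$frames[i, , ])
  int_ok <- all(stack$frames == round(stack$frames)) &&
    max(stack$frames) < 65536
  scale_file <- paste0(path, ".scale.json")
  if (int_ok) {
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    if (file.exists(scale_file)) unlink(scale_file)
  } else {
    scale <- max(stack$frames)
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = 32L)
    jsonlite::write_json(list(scale = scale), scale_file,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trace set from CSV
#'
#' Expects an RFC 4180 CSV whose first column `time_s` gives uniformly spaced
#' sample times and whose remaining columns hold one trace per trial/cell.
#' Sampling is inferred from the time column; jitter beyond 1e-6 of the
#' sampling interval is an error.
#'
#' @param path CSV path.
#' @param unit Unit of the traces; if absent, a `# unit:` comment on the
#'   file's first line is honoured, otherwise an error is raised.
#' @return A [trace_set()] (traces as rows).
#' @export
read_traces <- function(path, unit = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("#\\s*unit:\\s*(\\S+)", first))[[1L]]
    if (is.null(unit) && length(m) == 2L) unit <- m[2L]
  }
  if (is.null(unit)) stop("unit missing: pass `unit` or annotate the CSV")
  df <- utils::read.csv(path, check.names = FALSE, skip = skip)
  if (names(df)[1L] != "time_s") stop("first column must be `time_s`")
  tm <- df[[1L]]
  if (length(tm) < 2L) stop("need at least 2 samples")
  dt <- diff(tm)
  if (any(dt <= 0)) stop("non-monotone time column")
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L]) stop("non-uniform sampling")
  tr <- t(as.matrix(df[, -1L, drop = FALSE]))
  if (anyNA(tr)) stop("ragged or missing trace values")
  trace_set(tr, sampling_rate_hz = 1 / dt[1L], unit = unit, t0_s = tm[1L],
            ids = names(df)[-1L])
}

#' Write a trace set to CSV
#'
#' Emits `time_s` plus one column per trace, with a `# unit:` comment line so
#' the file is self-describing. Values are written at full double precision.
#'
#' @param x A [trace_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path) {
  stopifnot(inherits(x, "trace_set"))
  df <- data.frame(time_s = trace_times(x), t(x$traces),
                   check.names = FALSE)
  names(df) <- c("time_s", rownames(x$traces))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", x$unit), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

roi_to_list <- function(r) {
  out <- list(id = r$id, kind = r$kind)
  if (!is.null(r$mask)) {
    idx <- which(r$mask, arr.ind = TRUE) - 1L
    out$mask <- list(dim = dim(r$mask), rows = idx[, 1L], cols = idx[, 2L])
  }
  if (!is.null(r$center)) {
    out$center <- r$center
    out$radii <- r$radii
  }
  out
}

roi_from_list <- function(l) {
  mask <- NULL
  if (!is.null(l$mask)) {
    mask <- matrix(FALSE, l$mask$dim[1L], l$mask$dim[2L])
    mask[cbind(l$mask$rows + 1L, l$mask$cols + 1L)] <- TRUE
  }
  roi(l$id, l$kind, mask = mask, center = unlist(l$center),
      radii = unlist(l$radii))
}

#' Read / write ROI sets as JSON
#'
#' Masks are stored as sparse 0-based `(row, col)` index lists; ellipses as
#' center + radii.
#'
#' @param path JSON path.
#' @return `read_rois`: a list of [roi()] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lapply(jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE),
         roi_from_list)
}

#' @rdname read_rois
#' @param rois List of [roi()] objects.
#' @return `write_rois`: `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, roi_to_list), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write trial protocols as JSON
#' @param path JSON path.
#' @return `read_protocols`: a [trial_protocol()] data frame.
#' @export
read_protocols <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(trial_protocol, as.list(df))
}

#' @rdname read_protocols
#' @param protocols A [trial_protocol()] data frame.
#' @return `write_protocols`: `path`, invisibly.
#' @export
write_protocols <- function(protocols, path) {
  jsonlite::write_json(protocols, path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

BUNDLE_SCHEMA <- "popgate-bundle/1"

#' Write a dataset bundle
#'
#' Persists a full experiment (stacks, trace sets, ROIs, protocols,
#' classification tables) as a directory bundle: TIFF for stacks, annotated
#' CSV for traces and tables, JSON for ROIs/protocols, plus a
#' `manifest.json` carrying the schema version and the index of members.
#' Trial cross-references are validated before anything is written.
#'
#' @param bundle Named list with any of `stacks` (named list of
#'   [imaging_stack()]), `traces` (named list of [trace_set()]), `rois`
#'   (list of [roi()]), `protocols` ([trial_protocol()]), `classification`
#'   (data frame with a `trial_id` column).
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(bundle, path) {
  stopifnot(is.list(bundle))
  validate_bundle(bundle)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema = BUNDLE_SCHEMA, members = list())
  for (nm in names(bundle$stacks)) {
    f <- sprintf("stack-%s.tif", nm)
    write_stack(bundle$stacks[[nm]], file.path(path, f))
    s <- bundle$stacks[[nm]]
    manifest$members$stacks[[nm]] <-
      list(file = f, frame_rate_hz = s$frame_rate_hz, channel = s$channel,
           t0_s = s$t0_s)
  }
  for (nm in names(bundle$traces)) {
    f <- sprintf("traces-%s.csv", nm)
    write_traces(bundle$traces[[nm]], file.path(path, f))
    manifest$members$traces[[nm]] <- list(file = f)
  }
  if (!is.null(bundle$rois)) {
    write_rois(bundle$rois, file.path(path, "rois.json"))
    manifest$members$rois <- "rois.json"
  }
  if (!is.null(bundle$protocols)) {
    write_protocols(bundle$protocols, file.path(path, "protocols.json"))
    manifest$members$protocols <- "protocols.json"
  }
  if (!is.null(bundle$classification)) {
    utils::write.csv(bundle$classification,
                     file.path(path, "classification.csv"), row.names = FALSE)
    manifest$members$classification <- "classification.csv"
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset bundle
#' @param path Bundle directory written by [write_dataset()].
#' @return The reconstructed bundle list.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("not a bundle (no manifest): %s", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (!identical(manifest$schema, BUNDLE_SCHEMA))
    stop(sprintf("unsupported bundle schema: %s", manifest$schema))
  bundle <- list()
  for (nm in names(manifest$members$stacks)) {
    m <- manifest$members$stacks[[nm]]
    bundle$stacks[[nm]] <- read_stack(file.path(path, m$file),
                                      m$frame_rate_hz, m$channel, m$t0_s)
  }
  for (nm in names(manifest$members$traces)) {
    bundle$traces[[nm]] <-
      read_traces(file.path(path, manifest$members$traces[[nm]]$file))
  }
  if (!is.null(manifest$members$rois))
    bundle$rois <- read_rois(file.path(path, manifest$members$rois))
  if (!is.null(manifest$members$protocols))
    bundle$protocols <-
      read_protocols(file.path(path, manifest$members$protocols))
  if (!is.null(manifest$members$classification))
    bundle$classification <-
      utils::read.csv(file.path(path, manifest$members$classification))
  validate_bundle(bundle)
  bundle
}

validate_bundle <- function(bundle) {
  if (!is.null(bundle$classification)) {
    if (is.null(bundle$protocols))
      stop("classification present without protocols to cross-reference")
    dangling <- setdiff(bundle$classification$trial_id,
                        bundle$protocols$trial_id)
    if (length(dangling))
      stop(sprintf("classification references unknown trial id(s): %s",
                   paste(dangling, collapse = ", ")))
  }
  invisible(TRUE)
}
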