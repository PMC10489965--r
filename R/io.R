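# Volume, model and config I/O. Slice index is 0-based in filenames,
# pixel order row-major with origin top-left.

.naturalOrder <- function(x) {
  key <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(v)
      sprintf("%020.0f", as.numeric(v)))
    s
  }, character(1))
  order(key, x)
}

.RAW_MAGIC <- "OCTVOL1"

.sliceToGray <- function(px, file) {
  if (length(dim(px)) == 3L) {
    # colour or grey+alpha input: collapse by luminance, drop alpha
    warning(sprintf("'%s' is not single-channel greyscale; converting by luminance",
                    file))
    if (dim(px)[3] >= 3L) {
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px <- px[, , 1]
    }
  }
  m <- round(px * 255)
  storage.mode(m) <- "integer"
  m
}

.readSliceFile <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    .sliceToGray(png::readPNG(file), file)
  } else if (ext %in% c("tif", "tiff")) {
    .sliceToGray(tiff::readTIFF(file), file)
  } else {
    stop(sprintf("unsupported slice file type '%s' (%s)", ext, file))
  }
}

#' Read an OCT volume from disk
#'
#' Supported layouts: a directory of per-slice PNG/TIFF images (ordered
#' by natural sort of the filename, so zero padding is optional), a
#' multi-page TIFF, or the package's headered raw binary (magic
#' "OCTVOL1", little-endian int32 S, H, W, then 8-bit pixels row-major
#' per slice). Non-greyscale images are converted by luminance with a
#' warning.
#'
#' @param path directory or file path
#' @param layout "auto" (default, inferred from the path), "slices",
#'   "tiff" or "raw"
#' @param id volume identifier (default: basename of the path)
#' @param classLabel optional "normal"/"amd" ground truth
#' @return an [OCTVolume-class]
#' @export
readVolume <- function(path, layout = c("auto", "slices", "tiff", "raw"),
                       id = basename(path), classLabel = NA_character_) {
  layout <- match.arg(layout)
  if (layout == "auto") {
    layout <- if (dir.exists(path)) "slices"
      else if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) "tiff"
      else "raw"
  }
  slices <- switch(layout,
    slices = {
      if (!dir.exists(path)) stop(sprintf("'%s' is not a directory", path))
      files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE)
      if (length(files) == 0L)
        stop(sprintf("no slice images found in '%s'", path))
      files <- files[.naturalOrder(basename(files))]
      lapply(files, .readSliceFile)
    },
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(seq_along(pages), function(i)
        .sliceToGray(pages[[i]], sprintf("%s[page %d]", path, i)))
    },
    raw = {
      con <- file(path, "rb")
      on.exit(close(con))
      magic <- rawToChar(readBin(con, "raw", n = nchar(.RAW_MAGIC)))
      if (!identical(magic, .RAW_MAGIC))
        stop(sprintf("'%s' is not a raw volume (bad magic)", path))
      dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
      S <- dims[1]; H <- dims[2]; W <- dims[3]
      lapply(seq_len(S), function(s) {
        px <- as.integer(readBin(con, "raw", n = H * W))
        matrix(px, H, W, byrow = TRUE)   # stored row-major
      })
    })
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stop(sprintf("slice %d has dimensions %d x %d, expected %d x %d",
                 bad, dims[1, bad], dims[2, bad], dims[1, 1], dims[2, 1]))
  }
  new("OCTVolume", slices = slices, id = id,
      classLabel = as.character(classLabel))
}

#' Write an OCT volume to disk
#'
#' @param volume an [OCTVolume-class]
#' @param path output directory (layout "slices") or file path
#' @param layout "slices" (8-bit PNG per slice, zero-padded 0-based
#'   index), "tiff" (multi-page 8-bit TIFF) or "raw" (headered binary)
#' @return `path`, invisibly
#' @export
writeVolume <- function(volume, path, layout = c("slices", "tiff", "raw")) {
  stopifnot(is(volume, "OCTVolume"))
  layout <- match.arg(layout)
  slices <- volume@slices
  if (layout == "slices") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(slices))
      png::writePNG(slices[[i]] / 255,
                    file.path(path, sprintf("slice_%04d.png", i - 1L)))
  } else if (layout == "tiff") {
    tiff::writeTIFF(lapply(slices, function(m) m / 255), path,
                    bits.per.sample = 8L)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(.RAW_MAGIC), con)
    d <- dim(slices[[1]])
    writeBin(as.integer(c(length(slices), d[1], d[2])), con, size = 4L,
             endian = "little")
    for (m in slices) writeBin(as.raw(as.vector(t(m))), con)
  }
  invisible(path)
}

.fmtNum <- function(x) sprintf("%.17g", x)

.fmtFormat <- function(fmt) {
  sprintf("%s %d %d %s", ifelse(fmt@signed, "signed", "unsigned"),
          fmt@integerBits, fmt@fractionBits, fmt@overflow)
}

.parseFormat <- function(s) {
  p <- strsplit(trimws(s), "\\s+")[[1]]
  fixedPointFormat(signed = p[1] == "signed",
                   integerBits = as.integer(p[2]),
                   fractionBits = as.integer(p[3]), overflow = p[4])
}

#' Write a model-parameter file
#'
#' Plain-text key/value document holding the format version, variant and
#' connection-method provenance, feature length, label convention, bias
#' and weights as decimal numbers, plus optional fixed-point formats.
#' Numbers are printed with 17 significant digits so the
#' write/read/write round trip is byte-identical.
#'
#' @param model a [LinearSVMModel-class]
#' @param path output file
#' @param formats optional named list of [FixedPointFormat-class]
#'   (entries among feature, weights, bias, accumulator)
#' @return `path`, invisibly
#' @export
writeModelFile <- function(model, path, formats = NULL) {
  stopifnot(is(model, "LinearSVMModel"))
  lines <- c(
    "format_version: 1",
    sprintf("variant: %s", model@variant),
    sprintf("method: %s", model@method),
    sprintf("feature_length: %d", length(model@weights)),
    sprintf("label_positive: %s", model@labelMap[["positive"]]),
    sprintf("label_negative: %s", model@labelMap[["negative"]]),
    sprintf("bias: %s", .fmtNum(model@bias)),
    sprintf("weights: %s", paste(.fmtNum(model@weights), collapse = " ")))
  for (nm in names(formats))
    lines <- c(lines, sprintf("fp_%s: %s", nm, .fmtFormat(formats[[nm]])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model-parameter file
#'
#' @param path file written by [writeModelFile()]
#' @return a [LinearSVMModel-class]; any fixed-point formats in the file
#'   are attached as the "formats" attribute
#' @export
readModelFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file '%s' not found", path))
  kv <- .readKeyValues(path)
  if (!identical(kv[["format_version"]], "1"))
    stop("unsupported model file format version")
  n <- as.integer(kv[["feature_length"]])
  w <- as.numeric(strsplit(trimws(kv[["weights"]]), "\\s+")[[1]])
  if (length(w) != n)
    stop(sprintf("model file declares %d weights but lists %d", n, length(w)))
  model <- linearSVMModel(
    w, as.numeric(kv[["bias"]]),
    labelMap = c(positive = kv[["label_positive"]],
                 negative = kv[["label_negative"]]),
    variant = kv[["variant"]], method = kv[["method"]])
  fpKeys <- grep("^fp_", names(kv), value = TRUE)
  if (length(fpKeys) > 0L) {
    formats <- lapply(kv[fpKeys], .parseFormat)
    names(formats) <- sub("^fp_", "", fpKeys)
    attr(model, "formats") <- formats
  }
  model
}

.readKeyValues <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(as.list(vals), trimws(keys))
}

#' Read a flat key/value pipeline config file
#'
#' Lines of the form `key: value`; blank lines and `#` comments are
#' ignored. Values are returned as character; callers coerce as needed.
#'
#' @param path config file
#' @return named list of character values
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  .readKeyValues(path)
}
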