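#' Read a color carcass image
#'
#' PNG or TIFF, returned as an H x W x 3 array with values 0-255.
#'
#' @param path image file path.
#' @return numeric array H x W x 3.
#' @export
readSteakImage <- function(path) {
  a <- .readRaster(path)
  if (length(dim(a)) == 2) stop("expected a color image: ", path,
                                call. = FALSE)
  a[, , 1:3, drop = FALSE] * 255
}

#' Read a grayscale ultrasound frame
#'
#' PNG or TIFF; color inputs are converted by channel averaging.
#'
#' @param path image file path.
#' @return numeric matrix with values 0-255.
#' @export
readUSImage <- function(path) {
  a <- .readRaster(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
  a * 255
}

.readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: ", ext, call. = FALSE)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask binary matrix.
#' @param path output path (.png).
#' @export
writeMask <- function(mask, path) {
  .assertMask(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' Read a binary mask written by \code{\link{writeMask}}
#'
#' @param path PNG path.
#' @return binary matrix.
#' @export
readMask <- function(path) {
  a <- .readRaster(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  (a > 0.5) * 1
}

#' Write a grayscale or color image (values 0-255) as PNG
#'
#' @param img matrix or H x W x 3 array, values 0-255.
#' @param path output path (.png).
#' @export
writeImage <- function(img, path) {
  png::writePNG(.clamp(img) / 255, path)
  invisible(path)
}

# known configuration keys per section; unknown keys are rejected
.configSchema <- list(
  global = c("seed", "outDir", "verbosity"),
  preproc = c("votingRule", "diffusionIterations", "diffusionK",
              "diffusionStep"),
  ribeye = c("sigma", "alpha1", "alpha2", "maxIter1", "maxIter2",
             "checkEvery1", "checkEvery2", "areaGrowthStop",
             "refineIterations"),
  backfat = c("step", "spacing", "maxIterations", "minBand"),
  usroi = c("nmsWindow", "minCorrelation", "minSeparation",
            "templateWidth", "templateHeight"),
  imf = c("cvFolds", "cost", "components"))

#' Read and validate a run configuration file
#'
#' YAML with per-module sections; unknown sections or keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in names(cfg)) {
    if (!sec %in% names(.configSchema))
      stop("unknown config section: ", sec, call. = FALSE)
    bad <- setdiff(names(cfg[[sec]]), .configSchema[[sec]])
    if (length(bad) > 0)
      stop("unknown config key(s) in [", sec, "]: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}
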