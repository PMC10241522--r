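#' Generate a synthetic in situ hybridization image
#'
#' A uniform background with disk-shaped labeled cells, optional Gaussian
#' pixel noise, on the 0-256 intensity scale used for optical densitometry.
#' The image is signal-positive (labeled cells brighter than background);
#' chromogenic dark-on-light micrographs should be inverted before
#' quantification (see `invert` in [count_labeled_cells()]).
#'
#' @param width,height image size (px)
#' @param background background intensity (0-256)
#' @param cells data.frame with `x`, `y` (px, centers), `radius` (px),
#'   `intensity` (0-256); may have zero rows
#' @param noise_sd Gaussian pixel noise SD (0 disables)
#' @param pixel_size um per pixel (metadata)
#' @param seed integer seed
#' @return an `ish_image`: list with `pixels` (width x height matrix),
#'   `pixel_size`, `background`, `cells`
#' @export
generate_ish_image <- function(width = 400, height = 400, background = 40,
                               cells = NULL, noise_sd = 0,
                               pixel_size = 1.0, seed = 1L) {
  stopifnot(background >= 0, background <= 256)
  if (is.null(cells))
    cells <- data.frame(x = numeric(), y = numeric(), radius = numeric(),
                        intensity = numeric())
  stopifnot(all(cells$intensity >= 0), all(cells$intensity <= 256),
            all(cells$radius > 0))
  img <- matrix(background, width, height)
  xs <- row(img); ys <- col(img)
  for (i in seq_len(nrow(cells))) {
    mask <- (xs - cells$x[i])^2 + (ys - cells$y[i])^2 <= cells$radius[i]^2
    img[mask] <- cells$intensity[i]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
    img[] <- pmin(256, pmax(0, img))  # keep the matrix dim
  }
  structure(list(pixels = img, pixel_size = pixel_size,
                 background = background, cells = cells),
            class = "ish_image")
}

#' Write / read an ISH image as 8-bit grayscale TIFF
#'
#' Intensities are mapped 0-256 to 0-1 for storage; the pixel size is kept
#' in a JSON sidecar.
#'
#' @param image an `ish_image`
#' @param path file path
#' @return `path` invisibly (`write_ish_tiff`); an `ish_image`
#'   (`read_ish_tiff`)
#' @export
write_ish_tiff <- function(image, path) {
  tiff::writeTIFF(t(image$pixels) / 256, path, bits.per.sample = 8L)
  jsonlite::write_json(list(pixel_size = image$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ish_tiff
#' @export
read_ish_tiff <- function(path) {
  px <- t(tiff::readTIFF(path)) * 256
  side <- paste0(path, ".json")
  ps <- if (file.exists(side))
    jsonlite::read_json(side)$pixel_size else 1.0
  structure(list(pixels = px, pixel_size = ps, background = NA,
                 cells = NULL), class = "ish_image")
}

window_indices <- function(image, window) {
  ps <- image$pixel_size
  x0 <- round(window$x / ps) + 1
  y0 <- round(window$y / ps) + 1
  w <- round(window$width / ps)
  h <- round(window$height / ps)
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > nrow(image$pixels) ||
      y0 + h - 1 > ncol(image$pixels))
    stop("window out of image bounds")
  list(x = x0:(x0 + w - 1), y = y0:(y0 + h - 1))
}

#' Windowed optical density with background subtraction
#'
#' Mean pixel intensity (0-256 scale) over a measurement window minus the
#' mean over an adjacent control (background) window, the standard
#' background-subtracted OD for chromogenic in situ material. A negative
#' net OD is legal and flagged.
#'
#' @param image an `ish_image`
#' @param window,background_window lists with `x`, `y` (um, lower corner),
#'   `width`, `height` (um); the classical choice is a 200 x 200 um window
#' @return one-row data.frame: `region_od`, `background_od`, `net_od`,
#'   `negative_net` flag
#' @export
window_od <- function(image,
                      window = list(x = 0, y = 0, width = 200, height = 200),
                      background_window) {
  wi <- window_indices(image, window)
  bi <- window_indices(image, background_window)
  region <- mean(image$pixels[wi$x, wi$y])
  bg <- mean(image$pixels[bi$x, bi$y])
  data.frame(region_od = region, background_od = bg, net_od = region - bg,
             negative_net = region < bg)
}

#' Regional expression ratio
#'
#' Ratio of two background-subtracted ODs; values above 1 mean stronger
#' expression in region a.
#'
#' @param od_a,od_b net ODs
#' @return `od_a / od_b`
#' @export
expression_ratio <- function(od_a, od_b) {
  if (any(od_b == 0)) stop("zero denominator OD")
  od_a / od_b
}

#' Count labeled cells above an expression threshold
#'
#' Binarizes at `threshold_factor` times the background level (the 2.5x
#' criterion), applies one binary opening then one closing with a 3x3
#' structuring element, labels connected components, and counts those whose
#' area lies within `area_bounds` (px^2) and whose centroid falls inside the
#' counting window.
#'
#' @param image an `ish_image`
#' @param background_od background level (must be > 0)
#' @param window counting window as in [window_od()]; `NULL` = whole image
#' @param threshold_factor multiple of background defining expression
#' @param area_bounds admissible component area (px)
#' @param invert treat the image as dark-on-light and invert (256 - I)
#'   before thresholding
#' @return integer count; the labeled component table is attached as
#'   attribute `components`
#' @export
count_labeled_cells <- function(image, background_od, window = NULL,
                                threshold_factor = 2.5,
                                area_bounds = c(10, 500), invert = FALSE) {
  if (background_od <= 0) stop("background level must be positive")
  px <- image$pixels
  if (invert) {
    px <- 256 - px
    background_od <- 256 - background_od
  }
  bin <- px >= threshold_factor * background_od
  kern <- EBImage::makeBrush(3, shape = "box")
  bin <- EBImage::closing(EBImage::opening(bin, kern), kern)
  lab <- EBImage::bwlabel(bin)
  if (max(lab) == 0) return(structure(0L, components = data.frame()))
  areas <- tabulate(lab[lab > 0])
  cx <- tapply(row(lab)[lab > 0], lab[lab > 0], mean)
  cy <- tapply(col(lab)[lab > 0], lab[lab > 0], mean)
  comp <- data.frame(label = seq_along(areas), area = areas,
                     cx = as.numeric(cx), cy = as.numeric(cy))
  keep <- comp$area >= area_bounds[1] & comp$area <= area_bounds[2]
  if (!is.null(window)) {
    wi <- window_indices(image, window)
    keep <- keep & comp$cx >= min(wi$x) & comp$cx <= max(wi$x) &
      comp$cy >= min(wi$y) & comp$cy <= max(wi$y)
  }
  structure(sum(keep), components = comp[keep, , drop = FALSE])
}
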