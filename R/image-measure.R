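#' Belt annotation constructor
#'
#' Axial (0-based, sub-pixel) coordinates of the larval body ends and of the
#' anterior/posterior borders of each denticle belt, in image columns.
#'
#' @param body_anterior_px,body_posterior_px axial coordinates of the body ends.
#' @param belts n x 2 matrix, columns `anterior`/`posterior`, rows ordered
#'   anterior to posterior.
#' @param pixel_size_um micrometres per pixel.
#' @return a `segmorph_belt_annotation`.
#' @export
belt_annotation <- function(body_anterior_px, body_posterior_px, belts,
                            pixel_size_um = 1) {
  belts <- matrix(as.numeric(belts), ncol = 2,
                  dimnames = list(NULL, c("anterior", "posterior")))
  ord <- c(body_anterior_px, t(belts), body_posterior_px)
  if (any(diff(ord) <= 0))
    abort("annotation violates ordering: body anterior < belt borders < body posterior",
          class = "segmorph_invalid_annotation")
  structure(list(body_anterior_px = body_anterior_px,
                 body_posterior_px = body_posterior_px,
                 belts = belts, pixel_size_um = pixel_size_um),
            class = "segmorph_belt_annotation")
}

# body half-width profile (px) at axial position u in [0, L]: tapered anterior
# ("head") end, blunt elliptical posterior end
body_halfwidth <- function(u, L, H) {
  a_len <- 0.22 * L
  p_len <- 0.10 * L
  h <- rep(H, length(u))
  a <- u < a_len
  h[a] <- H * pmax(0, u[a] / a_len)^0.6
  p <- u > L - p_len
  h[p] <- H * sqrt(pmax(0, 1 - ((u[p] - (L - p_len)) / p_len)^2))
  h[u < 0 | u > L] <- 0
  h
}

#' Render a synthetic dark-field larva image with ground truth
#'
#' Draws a bright, horizontally elongated body (tapered anterior end) on a
#' dark background with one bright transverse band per denticle belt, at the
#' axial positions of the supplied measurement; optionally rotates the whole
#' scene and adds Gaussian pixel noise. The returned ground truth is in the
#' body frame (axial pixel coordinates of the un-rotated, cropped body), so
#' it is unchanged by rotation.
#'
#' @param measurement tidy measurement rows for one larva (`segment`,
#'   `x_anterior_um`, `x_posterior_um`, `body_length_um`).
#' @param width_px canvas width before rotation (>= 200); the body spans 90%.
#' @param rotation_deg rotation of the body axis, degrees counter-clockwise.
#' @param noise_sd additive Gaussian noise sd on the 0..1 intensity scale.
#' @param seed integer seed for the noise.
#' @return list with `image` (matrix, rows = y, columns = x, intensities in
#'   0..1), `pixel_size_um`, and `annotation` (ground-truth
#'   [belt_annotation()]).
#' @export
render_larva_image <- function(measurement, width_px = 600, rotation_deg = 0,
                               noise_sd = 0.03, seed = 1) {
  if (width_px < 200)
    abort("`width_px` must be >= 200", class = "segmorph_invalid_argument")
  assert_measurements(measurement)
  stopifnot(length(unique(measurement$larva_id)) == 1)
  L_um <- measurement$body_length_um[1]
  Lpx <- 0.9 * width_px
  scale <- Lpx / L_um                      # px per um
  ant <- measurement$x_anterior_um * scale
  post <- measurement$x_posterior_um * scale
  if (any(post - ant < 1))
    abort("a belt would occupy less than one pixel at this resolution",
          class = "segmorph_render_resolution_error")
  H <- max(25, round(0.12 * Lpx))
  mar <- ceiling(0.05 * width_px)
  # body-frame canvas extents
  bw <- Lpx + 2 * mar
  bh <- 2 * H + 2 * mar
  th <- rotation_deg * pi / 180
  # rotated canvas large enough for the rotated body box
  W <- ceiling(abs(bw * cos(th)) + abs(bh * sin(th))) + 2
  Hc <- ceiling(abs(bw * sin(th)) + abs(bh * cos(th))) + 2
  xs <- seq_len(W) - 1 - (W - 1) / 2
  ys <- seq_len(Hc) - 1 - (Hc - 1) / 2
  # inverse-rotate output pixel centres into the body frame
  u <- outer(ys * sin(th), xs * cos(th), `+`) + bw / 2 - mar   # axial coord
  v <- outer(ys * cos(th), -xs * sin(th), `+`)                 # lateral coord
  bg <- 0.05; body <- 0.45; band <- 0.95
  img <- matrix(bg, Hc, W)
  inside <- abs(v) <= body_halfwidth(as.vector(u), Lpx, H)
  img[inside] <- body
  # belt bands with ~1 px linear ramp at the edges (sub-pixel localisation)
  cov <- matrix(0, Hc, W)
  for (i in seq_along(ant)) {
    cov <- pmax(cov, pmin(1, pmax(0, u - ant[i] + 0.5)) * pmin(1, pmax(0, post[i] - u + 0.5)))
  }
  img[inside] <- img[inside] + (band - body) * cov[inside]
  if (noise_sd > 0) {
    img <- img + withr::with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd), Hc, W))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  list(image = img,
       pixel_size_um = 1 / scale,
       annotation = belt_annotation(0, Lpx, cbind(ant, post), pixel_size_um = 1 / scale))
}

# largest connected foreground component mask; errors per spec
segment_body <- function(img) {
  if (diff(range(img)) < 1e-6)
    abort("no foreground region found", class = "segmorph_segmentation_error")
  th <- EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1))
  # dark-field scenes are tri-modal (background, body, bands); Otsu may land
  # between body and bands, so cap the threshold just above the background
  bg <- stats::quantile(img, 0.01)
  th <- min(th, bg + 0.3 * (max(img) - bg))
  mask <- img > th
  if (!any(mask))
    abort("no foreground region found", class = "segmorph_segmentation_error")
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sum(sizes[-big] > 0.2 * sizes[big]) > 0)
    abort("more than one large foreground region", class = "segmorph_segmentation_error")
  lab == big
}

#' Standardise larva orientation
#'
#' Rotates the image so the body's principal axis is horizontal, flips it so
#' the anterior (tapered) end is at low column indices, and crops to the
#' body's bounding box. Anterior is taken as the end with the thinner width
#' profile; if the two ends are indistinguishable, the end farther from the
#' nearest bright band is used.
#'
#' @param image intensity matrix (rows = y) or a list with an `image` field
#'   as returned by [render_larva_image()].
#' @return list with `image` (standardised matrix) and `pixel_size_um`.
#' @export
orient_larva <- function(image) {
  px <- 1
  if (is.list(image)) { px <- image$pixel_size_um %||% 1; image <- image$image }
  if (nrow(image) < 50 || ncol(image) < 50)
    abort("image too small", class = "segmorph_invalid_argument")
  mask <- segment_body(image)
  idx <- which(mask, arr.ind = TRUE)
  cxy <- cov(cbind(idx[, 2], idx[, 1]))
  ang <- 0.5 * atan2(2 * cxy[1, 2], cxy[1, 1] - cxy[2, 2]) * 180 / pi
  if (abs(ang) > 0.1) {
    rot <- t(EBImage::imageData(EBImage::rotate(EBImage::Image(t(image)), -ang,
                                                bg.col = stats::median(image[!mask]))))
    img2 <- rot
    mask <- segment_body(img2)
  } else img2 <- image
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  img2 <- img2[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  mask <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  # anterior = thinner end
  nc <- ncol(mask)
  wseg <- floor(0.18 * nc)
  wL <- mean(colSums(mask)[seq_len(wseg)])
  wR <- mean(colSums(mask)[(nc - wseg + 1):nc])
  flip <- wL > wR
  if (abs(wL - wR) < 0.03 * max(wL, wR)) {
    # fallback: anterior end is farther from the first bright band
    prof <- axial_profile(img2, mask)
    bandish <- which(prof > stats::median(prof, na.rm = TRUE) +
                       0.5 * (max(prof, na.rm = TRUE) - stats::median(prof, na.rm = TRUE)))
    if (length(bandish))
      flip <- (min(bandish) - 1) < (nc - max(bandish))
  }
  if (flip) img2 <- img2[, rev(seq_len(nc)), drop = FALSE]
  list(image = img2, pixel_size_um = px)
}

# column-wise mean intensity over the central body rows
axial_profile <- function(img, mask = NULL) {
  if (is.null(mask)) mask <- segment_body(img)
  heights <- rowSums(mask)
  central <- which(heights > 0.6 * max(heights))
  colMeans(img[central, , drop = FALSE])
}

# half-maximum crossing positions (0-based, interpolated) around peak ip
half_max_edges <- function(prof, ip, half) {
  j <- ip
  while (j > 1 && prof[j - 1] > half) j <- j - 1
  a <- if (j == 1) 0 else (j - 1) + (half - prof[j - 1]) / (prof[j] - prof[j - 1]) - 1
  k <- ip
  n <- length(prof)
  while (k < n && prof[k + 1] > half) k <- k + 1
  b <- if (k == n) n - 1 else (k - 1) + (prof[k] - half) / (prof[k] - prof[k + 1])
  c(a, b)
}

#' Detect denticle-belt borders on a standardised image
#'
#' Computes the axial intensity profile (column means over the central body
#' rows), smooths it, keeps the `expected_n` highest bright bands, and places
#' each band's anterior/posterior edge at the interpolated half-maximum
#' crossing of its peak.
#'
#' @param image standardised image (from [orient_larva()]) or a bare matrix.
#' @param expected_n number of belts expected (default 8).
#' @param smooth_px running-mean window width (odd; default 5).
#' @return a [belt_annotation()] with body ends at the image borders.
#' @export
detect_belts <- function(image, expected_n = 8, smooth_px = 5) {
  px <- 1
  if (is.list(image)) { px <- image$pixel_size_um %||% 1; image <- image$image }
  prof <- axial_profile(image)
  w <- max(3, smooth_px %/% 2 * 2 + 1)
  sm <- stats::filter(prof, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  sm <- as.numeric(sm)
  base <- stats::median(sm)
  minh <- base + 0.3 * (max(sm) - base)
  # plateau-tolerant peak pattern: bands have flat tops
  pk <- pracma::findpeaks(sm, minpeakheight = minh, peakpat = "[+]{1,}[0]{0,}[-]{1,}")
  if (is.null(pk))
    abort(sprintf("found 0 band(s), expected %d", expected_n),
          class = "segmorph_detection_error")
  iv <- t(vapply(seq_len(nrow(pk)), function(i)
    half_max_edges(sm, pk[i, 2], (pk[i, 1] + base) / 2), numeric(2)))
  # merge peaks whose half-maximum intervals overlap into one band
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]; hh <- pk[o, 1]
  bands <- list(c(iv[1, ], hh[1]))
  for (i in seq_len(nrow(iv))[-1]) {
    last <- bands[[length(bands)]]
    if (iv[i, 1] <= last[2]) {
      bands[[length(bands)]] <- c(last[1], max(last[2], iv[i, 2]), max(last[3], hh[i]))
    } else bands[[length(bands) + 1L]] <- c(iv[i, ], hh[i])
  }
  bands <- do.call(rbind, bands)
  if (nrow(bands) < expected_n) {
    widths <- bands[, 2] - bands[, 1]
    if (nrow(pk) >= expected_n && max(widths) > 3 * stats::median(widths))
      abort("overlapping bands: belt edges are ambiguous", class = "segmorph_ambiguity_error")
    abort(sprintf("found %d band(s), expected %d", nrow(bands), expected_n),
          class = "segmorph_detection_error")
  }
  if (nrow(bands) > expected_n)
    bands <- bands[order(bands[, 3], decreasing = TRUE)[seq_len(expected_n)], , drop = FALSE]
  bands <- bands[order(bands[, 1]), , drop = FALSE]
  belt_annotation(0, ncol(image) - 1, bands[, 1:2], pixel_size_um = px)
}

#' Convert a belt annotation to physical measurements
#'
#' Distances are measured from the body's anterior end: `x_anterior_um` of
#' belt i is `(belt_anterior_px - body_anterior_px) * pixel_size_um`, and the
#' body length is the anterior-to-posterior pixel span times the pixel size.
#'
#' @param annotation a [belt_annotation()].
#' @param pixel_size_um micrometres per pixel (defaults to the annotation's).
#' @param species,larva_id labels for the output rows.
#' @return tidy measurement tibble (one row per belt).
#' @export
measure_positions <- function(annotation, pixel_size_um = NULL,
                              species = "unknown", larva_id = "larva") {
  stopifnot(inherits(annotation, "segmorph_belt_annotation"))
  ps <- pixel_size_um %||% annotation$pixel_size_um
  nb <- nrow(annotation$belts)
  tibble(
    species = species, larva_id = larva_id,
    segment = SEGMENTS[seq_len(nb)],
    x_anterior_um = (annotation$belts[, "anterior"] - annotation$body_anterior_px) * ps,
    x_posterior_um = (annotation$belts[, "posterior"] - annotation$body_anterior_px) * ps,
    body_length_um = (annotation$body_posterior_px - annotation$body_anterior_px) * ps)
}

#' Measure one larva image end to end
#'
#' [orient_larva()] then [detect_belts()] then [measure_positions()].
#'
#' @inheritParams orient_larva
#' @inheritParams measure_positions
#' @param expected_n number of belts expected.
#' @export
measure_image <- function(image, pixel_size_um = NULL, expected_n = 8,
                          species = "unknown", larva_id = "larva") {
  std <- orient_larva(image)
  ann <- detect_belts(std, expected_n = expected_n)
  measure_positions(ann, pixel_size_um = pixel_size_um,
                    species = species, larva_id = larva_id)
}

#' Write an image (16-bit PNG or TIFF) and, optionally, its annotation JSON
#' @param image intensity matrix in 0..1 or a [render_larva_image()] result.
#' @param path output path ending in .png or .tif/.tiff.
#' @export
write_larva_image <- function(image, path) {
  ann <- NULL
  if (is.list(image)) { ann <- image$annotation; image <- image$image }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      abort("the 'png' package is required to write PNG")
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("the 'tiff' package is required to write TIFF")
    tiff::writeTIFF(image, path, bits.per.sample = 16L)
  } else abort("unsupported image format: use .png or .tif")
  if (!is.null(ann)) {
    jsonlite::write_json(
      list(body_anterior_px = ann$body_anterior_px,
           body_posterior_px = ann$body_posterior_px,
           belts = as.data.frame(ann$belts),
           pixel_size_um = ann$pixel_size_um),
      paste0(tools::file_path_sans_ext(path), ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a larva image from PNG or TIFF
#' @param path image file.
#' @return intensity matrix (rows = y), values in 0..1.
#' @export
read_larva_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else abort("unsupported image format: use .png or .tif")
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
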