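#' Parameters for the synthetic valve-opening frame generator
#'
#' Emulates a top-down high-speed camera frame of an open tri-leaflet valve
#' at peak systole: a bright holder rim (a circle of known physical
#' diameter, 26 mm, used for pixel calibration), a mid-gray leaflet field
#' inside it, and a brighter lobed orifice of configured physical area.
#' The orifice boundary is a cosine-lobed star
#' `r(theta) = r0 * (1 + a * cos(n_lobes * theta))`, reducing to a circle
#' for `n_lobes = 1`.
#'
#' @param image_size Image side length, pixels (square frames).
#' @param holder_diameter_px Holder rim diameter in pixels; the rim maps to
#'   `holder_diameter_mm`, fixing the scale `mm_per_px`.
#' @param holder_diameter_mm Physical rim diameter, mm (default 26).
#' @param target_goa Target orifice area, cm^2. Default 3.24 cm^2, a
#'   typical fully-open bioprosthetic orifice at this holder size.
#' @param n_lobes Number of orifice lobes (3 for a tri-leaflet valve; 1
#'   gives a plain disk).
#' @param lobe_depth Relative lobe modulation amplitude (ignored when
#'   `n_lobes < 2`).
#' @param contrast Orifice-to-leaflet contrast in `[0, 1]`.
#' @param blur_sigma Gaussian blur applied to the rendered frame, pixels.
#' @param noise_sd Additive Gaussian pixel noise, gray levels (0-255).
#' @param timestamp Frame timestamp, s.
#' @param seed Integer seed.
#' @return A list of class `orifice_image_params`.
#' @export
orifice_image_params <- function(image_size = 256L,
                                 holder_diameter_px = 230,
                                 holder_diameter_mm = 26,
                                 target_goa = 3.24,
                                 n_lobes = 3L,
                                 lobe_depth = 0.2,
                                 contrast = 0.8,
                                 blur_sigma = 1.5,
                                 noise_sd = 4,
                                 timestamp = 0,
                                 seed = 1L) {
  check_positive(image_size, "image_size")
  check_positive(holder_diameter_px, "holder_diameter_px")
  check_positive(holder_diameter_mm, "holder_diameter_mm")
  check_positive(target_goa, "target_goa")
  if (n_lobes < 1L) stop_param("`n_lobes` must be >= 1", field = "n_lobes")
  check_nonneg(lobe_depth, "lobe_depth")
  if (contrast < 0 || contrast > 1) {
    stop_param("`contrast` must lie in [0, 1]", field = "contrast")
  }
  check_nonneg(blur_sigma, "blur_sigma")
  check_nonneg(noise_sd, "noise_sd")
  if (holder_diameter_px >= image_size) {
    stop_param("holder rim must fit inside the image",
               field = "holder_diameter_px")
  }
  mm_per_px <- holder_diameter_mm / holder_diameter_px
  holder_area_cm2 <- pi * (holder_diameter_mm / 2 / 10)^2
  if (target_goa >= holder_area_cm2) {
    stop_param("`target_goa` exceeds the holder disk area",
               field = "target_goa")
  }
  a <- if (n_lobes >= 2L) lobe_depth else 0
  r0_px <- sqrt(target_goa * 100 / mm_per_px^2 / (pi * (1 + a^2 / 2)))
  if (r0_px * (1 + a) >= 0.95 * holder_diameter_px / 2) {
    stop_param("`target_goa` too large for the holder at this lobe depth",
               field = "target_goa")
  }
  structure(
    list(image_size = as.integer(image_size),
         holder_diameter_px = holder_diameter_px,
         holder_diameter_mm = holder_diameter_mm,
         target_goa = target_goa, n_lobes = as.integer(n_lobes),
         lobe_depth = a, contrast = contrast, blur_sigma = blur_sigma,
         noise_sd = noise_sd, timestamp = timestamp, seed = as.integer(seed),
         mm_per_px = mm_per_px, r0_px = r0_px),
    class = "orifice_image_params")
}

new_orifice_frame <- function(pixels, mm_per_px, timestamp = 0) {
  structure(list(pixels = pixels, mm_per_px = mm_per_px,
                 timestamp = timestamp),
            class = "orifice_frame")
}

#' Construct an orifice frame from a pixel matrix
#'
#' @param pixels Numeric matrix of 8-bit gray levels (0-255).
#' @param mm_per_px Pixel calibration, mm/pixel.
#' @param timestamp Acquisition time, s.
#' @return Object of class `orifice_frame`.
#' @export
orifice_frame <- function(pixels, mm_per_px, timestamp = 0) {
  if (!is.matrix(pixels) || !length(pixels)) {
    stop_data("`pixels` must be a nonempty matrix")
  }
  check_positive(mm_per_px, "mm_per_px")
  new_orifice_frame(pixels, mm_per_px, timestamp)
}

#' @export
print.orifice_frame <- function(x, ...) {
  cat(sprintf("orifice_frame: %d x %d px, %.4f mm/px, t = %.4g s\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_px, x$timestamp))
  invisible(x)
}

#' Generate a synthetic valve-opening frame with ground truth
#'
#' @param params An [orifice_image_params()] object.
#' @return A list with `frame` (an `orifice_frame`), `truth_mask` (logical
#'   matrix of orifice pixels at pixel centres) and `truth` (list:
#'   `area_cm2` from the mask pixel count, `mm_per_px`, `center_px`,
#'   `r0_px`). With a fixed seed the frame is bit-identical across calls.
#' @export
#' @examples
#' g <- gen_orifice_image(orifice_image_params(image_size = 128,
#'                                             holder_diameter_px = 110))
#' g$truth$area_cm2
gen_orifice_image <- function(params = orifice_image_params()) {
  if (!inherits(params, "orifice_image_params")) {
    stop_param("`params` must be built with orifice_image_params()")
  }
  p <- params
  n <- p$image_size
  cx <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), nrow = n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), nrow = n)  # row index
  dx <- xs - cx; dy <- ys - cx
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  r_holder <- p$holder_diameter_px / 2

  boundary <- p$r0_px * (1 + p$lobe_depth * cos(p$n_lobes * theta))
  truth_mask <- r <= boundary
  bg <- 30; leaflet <- 60
  orifice_val <- leaflet + p$contrast * (230 - leaflet)
  img <- matrix(bg, n, n)
  img[r < r_holder] <- leaflet
  img[truth_mask] <- orifice_val
  img[abs(r - r_holder) <= 2] <- 245

  if (p$blur_sigma > 0) {
    img <- EBImage::gblur(img / 255, sigma = p$blur_sigma) * 255
  }
  if (p$noise_sd > 0) {
    img <- with_seed(p$seed, img + matrix(rnorm(n * n, 0, p$noise_sd), n, n))
  }
  img <- round(pmin(pmax(img, 0), 255))

  area_cm2 <- sum(truth_mask) * p$mm_per_px^2 / 100
  list(frame = new_orifice_frame(img, p$mm_per_px, p$timestamp),
       truth_mask = truth_mask,
       truth = list(area_cm2 = area_cm2, target_goa = p$target_goa,
                    mm_per_px = p$mm_per_px, center_px = c(cx, cx),
                    r0_px = p$r0_px))
}
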