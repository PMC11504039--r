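#' Select the frame nearest to peak flow
#'
#' Matches timestamped valve frames with a concurrently recorded flow
#' waveform and returns the index of the frame closest in time to the flow
#' maximum (ties broken towards the earlier frame).
#'
#' @param frames List of [orifice_frame()] objects with timestamps, or a
#'   tibble with a `timestamp` column.
#' @param w A `pf_waveform`.
#' @return Integer frame index.
#' @export
select_peak_frame <- function(frames, w) {
  ts <- if (is.data.frame(frames)) frames$timestamp else {
    vapply(frames, function(f) f$timestamp, numeric(1))
  }
  if (!length(ts)) stop_data("no frames supplied")
  t_peak <- w$time_s[which.max(w$q_mls)]
  which.min(abs(ts - t_peak))   # which.min takes the first (earlier) tie
}

#' Enhance a valve frame for segmentation
#'
#' Contrast-limited adaptive histogram equalisation (CLAHE) followed by
#' Gaussian blurring, the standard pre-segmentation chain for uneven
#' bench-camera illumination. Output has the input's shape with gray
#' levels in `[0, 255]`.
#'
#' @param frame An [orifice_frame()].
#' @param clahe_tiles CLAHE tile grid per axis.
#' @param clahe_limit CLAHE clip limit (0 disables equalisation).
#' @param blur_sigma Gaussian blur standard deviation, pixels.
#' @return Numeric matrix of enhanced gray levels.
#' @export
preprocess_frame <- function(frame, clahe_tiles = 8L, clahe_limit = 2,
                             blur_sigma = 2) {
  img <- frame$pixels / 255
  if (clahe_limit > 0 && diff(range(img)) > 0) {
    img <- EBImage::clahe(EBImage::Image(img), nx = clahe_tiles,
                          ny = clahe_tiles, limit = clahe_limit)
    img <- EBImage::imageData(img)
  }
  if (blur_sigma > 0) {
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = blur_sigma))
  }
  pmin(pmax(img * 255, 0), 255)
}

# star-shaped (radial) edge-based active contour about a fixed centre:
# each radial node moves towards the strongest edge response within a
# small search window along its ray, then the radius profile is smoothed
# (curvature regularisation); iterate to convergence or the cap.
refine_contour_radial <- function(img, center, r_init, n_angles = 120L,
                                  search = 4, smooth_k = 5L, max_iter = 50L,
                                  tol = 0.05) {
  grad_row <- img[c(2:nrow(img), nrow(img)), ] - img[c(1, 1:(nrow(img) - 1)), ]
  grad_col <- img[, c(2:ncol(img), ncol(img))] - img[, c(1, 1:(ncol(img) - 1))]
  gmag <- sqrt(grad_row^2 + grad_col^2)
  angles <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  r <- r_init
  offs <- seq(-search, search, by = 0.5)
  ksm <- rep(1 / smooth_k, smooth_k)
  for (it in seq_len(max_iter)) {
    cand <- outer(r, offs, `+`)          # n_angles x n_off
    cand[cand < 2] <- 2
    rows <- round(center[2] + cand * sin(angles))
    cols <- round(center[1] + cand * cos(angles))
    ok <- rows >= 1 & rows <= nrow(img) & cols >= 1 & cols <= ncol(img)
    score <- matrix(-Inf, nrow(cand), ncol(cand))
    score[ok] <- gmag[cbind(rows[ok], cols[ok])]
    pick <- max.col(score, ties.method = "first")
    target <- cand[cbind(seq_along(r), pick)]
    r_new <- 0.5 * r + 0.5 * target
    # periodic moving-average smoothing of the radius profile
    ext <- c(tail(r_new, (smooth_k - 1) %/% 2), r_new,
             head(r_new, smooth_k %/% 2))
    r_new <- as.numeric(stats::filter(ext, ksm, sides = 2))
    r_new <- r_new[((smooth_k - 1) %/% 2 + 1):(length(r_new) - smooth_k %/% 2)]
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }
  list(angles = angles, r = r, center = center, iterations = it)
}

# rasterise a star-shaped contour to a mask: pixel is inside when its
# radius is below the (linearly interpolated) contour radius at its angle
star_mask <- function(dim_img, center, angles, r) {
  n <- dim_img
  xs <- matrix(rep(seq_len(n[2]), each = n[1]), nrow = n[1])
  ys <- matrix(rep(seq_len(n[1]), times = n[2]), nrow = n[1])
  dx <- xs - center[1]; dy <- ys - center[2]
  th <- atan2(dy, dx) %% (2 * pi)
  rr <- sqrt(dx^2 + dy^2)
  r_at <- approx(c(angles, 2 * pi), c(r, r[1]), xout = th)$y
  rr <= r_at
}

#' Segment the open orifice from an enhanced frame
#'
#' Foreground extraction restricted to a region of interest — Otsu
#' thresholding followed by largest-connected-component selection and hole
#' filling — then refinement of the boundary by an edge-based active
#' contour (a star-shaped radial snake attracted to the strongest local
#' image gradient, with curvature smoothing) run to convergence or an
#' iteration cap.
#'
#' @param enhanced Numeric matrix from [preprocess_frame()] (gray levels).
#' @param roi_hint Region of interest as `c(row_min, row_max, col_min,
#'   col_max)`; default is the central 60% box.
#' @param refine Run the active-contour refinement (default TRUE).
#' @param max_iter Iteration cap for the refinement.
#' @return Logical mask matrix (TRUE = orifice).
#' @export
segment_orifice <- function(enhanced, roi_hint = NULL, refine = TRUE,
                            max_iter = 50L) {
  d <- dim(enhanced)
  if (is.null(roi_hint)) {
    roi_hint <- round(c(d[1] * 0.2, d[1] * 0.8, d[2] * 0.2, d[2] * 0.8))
  }
  roi_hint <- round(roi_hint)
  if (roi_hint[1] < 1 || roi_hint[3] < 1 || roi_hint[2] > d[1] ||
      roi_hint[4] > d[2] || roi_hint[1] >= roi_hint[2] ||
      roi_hint[3] >= roi_hint[4]) {
    stop_param("`roi_hint` must be a valid rectangle inside the image",
               field = "roi_hint")
  }
  rows <- roi_hint[1]:roi_hint[2]
  cols <- roi_hint[3]:roi_hint[4]
  sub <- enhanced[rows, cols] / 255
  if (diff(range(sub)) < 1e-6) {
    stop_segmentation("region of interest has no contrast")
  }
  # threshold from the ROI statistics, applied to the full frame so the
  # foreground is not clipped at the ROI border; the ROI centre seeds the
  # component choice
  thr <- EBImage::otsu(EBImage::Image(sub), range = c(0, 1))
  fg <- enhanced / 255 > thr
  if (!any(fg[rows, cols])) {
    stop_segmentation("empty segmentation: no foreground in ROI")
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
  cen <- c(round(mean(roi_hint[1:2])), round(mean(roi_hint[3:4])))
  keep <- lab[cen[1], cen[2]]
  if (keep == 0) {   # centre off the blob: take the largest component in ROI
    in_roi <- lab[rows, cols]
    sizes <- tabulate(in_roi[in_roi > 0])
    if (!length(sizes)) stop_segmentation("no foreground component in ROI")
    keep <- which.max(sizes)
  }
  comp <- lab == keep
  comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp))) > 0
  mask <- comp
  if (!refine) return(mask)

  # initial star contour from the component: per-angle outermost radius
  cen_r <- mean(which(mask, arr.ind = TRUE)[, 1])
  cen_c <- mean(which(mask, arr.ind = TRUE)[, 2])
  idx <- which(mask, arr.ind = TRUE)
  dy <- idx[, 1] - cen_r; dx <- idx[, 2] - cen_c
  th <- atan2(dy, dx) %% (2 * pi)
  rr <- sqrt(dx^2 + dy^2)
  n_angles <- 120L
  bins <- pmin(floor(th / (2 * pi) * n_angles) + 1L, n_angles)
  r_init <- rep(NA_real_, n_angles)
  agg <- tapply(rr, bins, max)
  r_init[as.integer(names(agg))] <- agg
  if (anyNA(r_init)) {   # fill empty bins by interpolation
    good <- which(!is.na(r_init))
    r_init <- approx(good, r_init[good], xout = seq_len(n_angles),
                     rule = 2)$y
  }
  rc <- refine_contour_radial(enhanced / 255, c(cen_c, cen_r), r_init,
                              n_angles = n_angles, max_iter = max_iter)
  refined <- star_mask(d, rc$center, rc$angles, rc$r)
  if (!any(refined)) stop_segmentation("refined contour collapsed")
  refined
}

#' Geometric orifice area from a segmentation mask
#'
#' Planimetric area: the mask pixel count times the pixel area, reported
#' in cm^2 (`count * mm_per_px^2 / 100` exactly). The boundary polygon is
#' returned as derived output.
#'
#' @param mask Logical matrix (TRUE = orifice).
#' @param mm_per_px Pixel calibration, mm/pixel.
#' @return List of class `goa_result`: `area_cm2`, `contour` (tibble of
#'   ordered boundary pixel coordinates `row`, `col`), `mask`.
#' @export
#' @examples
#' m <- matrix(FALSE, 64, 64); m[20:40, 20:40] <- TRUE
#' compute_goa(m, mm_per_px = 0.1)$area_cm2
compute_goa <- function(mask, mm_per_px) {
  if (!is.matrix(mask)) stop_data("`mask` must be a matrix")
  mask <- mask > 0
  if (!any(mask)) stop_data("empty mask")
  check_positive(mm_per_px, "mm_per_px")
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  contour <- if (length(oc)) {
    tibble::tibble(row = oc[[1]][, 1], col = oc[[1]][, 2])
  } else tibble::tibble(row = integer(), col = integer())
  structure(list(area_cm2 = sum(mask) * mm_per_px^2 / 100,
                 contour = contour, mask = mask),
            class = "goa_result")
}

#' @export
print.goa_result <- function(x, ...) {
  cat(sprintf("GOA: %.3f cm^2 (%d px)\n", x$area_cm2, sum(x$mask)))
  invisible(x)
}

#' Pixel calibration from the valve-holder rim
#'
#' The valve holder has a known physical diameter and its bright rim is
#' the calibration reference: the radial intensity profile about the frame
#' centre is scanned for the outermost bright ring, and the scale follows
#' as `mm_per_px = holder_diameter_mm / rim_diameter_px`. Frames are
#' assumed centred on the holder (as bench recordings are framed).
#'
#' @param frame An [orifice_frame()] (its `mm_per_px` is ignored).
#' @param holder_diameter_mm Physical rim diameter, mm (default 26).
#' @return Estimated `mm_per_px`.
#' @export
calibrate_from_holder <- function(frame, holder_diameter_mm = 26) {
  img <- frame$pixels
  d <- dim(img)
  cx <- (d[2] + 1) / 2; cy <- (d[1] + 1) / 2
  xs <- matrix(rep(seq_len(d[2]), each = d[1]), nrow = d[1])
  ys <- matrix(rep(seq_len(d[1]), times = d[2]), nrow = d[1])
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  rmax <- min(d) / 2 - 1
  bin <- floor(rr) + 1L
  ok <- rr <= rmax
  prof_tab <- tapply(img[ok], bin[ok], mean)
  prof <- as.numeric(prof_tab)
  radius <- as.integer(names(prof_tab)) - 0.5
  bg <- median(prof)
  peak <- max(prof)
  thr <- bg + 0.6 * (peak - bg)
  bright <- prof > thr
  if (!any(bright)) stop_calibration("no rim-like bright ring found")
  # outermost contiguous bright group = the rim
  r <- rle(bright)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  grp <- which(r$values)
  rim <- grp[length(grp)]
  sel <- starts[rim]:ends[rim]
  if (radius[max(sel)] < 0.4 * rmax) {
    stop_calibration("bright ring too close to centre to be the holder rim")
  }
  wts <- prof[sel] - bg
  rim_radius <- sum(radius[sel] * wts) / sum(wts)
  holder_diameter_mm / (2 * rim_radius)
}

#' Full planimetric pipeline on a frame sequence
#'
#' Selects the peak-flow frame, enhances it, segments the orifice and
#' returns the geometric orifice area.
#'
#' @param frames List of [orifice_frame()] objects.
#' @param w A `pf_waveform` recorded concurrently.
#' @param mm_per_px Calibration; `NULL` (default) uses the selected
#'   frame's own value, `"holder"` calibrates from the rim.
#' @param ... Passed to [segment_orifice()].
#' @return A `goa_result` with an extra `frame_index` element.
#' @export
measure_goa <- function(frames, w, mm_per_px = NULL, ...) {
  i <- select_peak_frame(frames, w)
  frame <- if (is.data.frame(frames)) frames$frame[[i]] else frames[[i]]
  scale <- if (is.null(mm_per_px)) frame$mm_per_px
           else if (identical(mm_per_px, "holder")) calibrate_from_holder(frame)
           else mm_per_px
  enhanced <- preprocess_frame(frame)
  mask <- segment_orifice(enhanced, ...)
  out <- compute_goa(mask, scale)
  out$frame_index <- i
  out
}
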