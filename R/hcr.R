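#' HCR signal quantification
#'
#' Hybridization chain reaction (HCR) produces countable fluorescent
#' puncta per transcript. Three readouts: puncta density inside a traced
#' neuron mask (count / mask area, the dcc readout), background-corrected
#' mean grey value of a traced dorsal region (the netrin1b readout), and
#' the mean grey value of a 200-um^2 floor-plate box. Images are plain
#' numeric matrices with a `pixel_size_um` attribute; regions are simple
#' polygons in um. Pixels belong to a polygon when their centers fall
#' inside (centers on an edge count as inside).
#'
#' @name regenquant-hcr
NULL

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' @param x,y point coordinates (vectorized).
#' @param polygon 2-column matrix of vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, polygon) {
  p <- as.matrix(polygon)
  nv <- nrow(p)
  stopifnot(ncol(p) == 2, nv >= 3)
  px <- p[, 1]; py <- p[, 2]
  jx <- px[c(nv, seq_len(nv - 1))]; jy <- py[c(nv, seq_len(nv - 1))]
  vapply(seq_along(x), function(k) {
    xi <- x[k]; yi <- y[k]
    # boundary check: point on any edge segment
    on_edge <- any(vapply(seq_len(nv), function(e) {
      x1 <- px[e]; y1 <- py[e]; x2 <- jx[e]; y2 <- jy[e]
      cr <- (x2 - x1) * (yi - y1) - (y2 - y1) * (xi - x1)
      if (abs(cr) > 1e-9 * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
      xi >= min(x1, x2) - 1e-12 && xi <= max(x1, x2) + 1e-12 &&
        yi >= min(y1, y2) - 1e-12 && yi <= max(y1, y2) + 1e-12
    }, TRUE))
    if (on_edge) return(TRUE)
    crossings <- (py > yi) != (jy > yi) &
      xi < (jx - px) * (yi - py) / (jy - py) + px
    sum(crossings) %% 2 == 1
  }, TRUE)
}

#' Polygon area by the shoelace formula
#'
#' @param polygon 2-column vertex matrix, um.
#' @return area, um^2.
#' @export
polygon_area <- function(polygon) {
  p <- as.matrix(polygon)
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# logical pixel mask for a polygon; rows = y, cols = x, centers at
# (i - 0.5) * pixel size
polygon_pixel_mask <- function(image, polygon, pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(image, "pixel_size_um")
  if (is.null(ps)) stop("pixel size unknown: supply pixel_size_um")
  xs <- (seq_len(ncol(image)) - 0.5) * ps
  ys <- (seq_len(nrow(image)) - 0.5) * ps
  poly <- as.matrix(polygon)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  mask <- matrix(FALSE, nrow(image), ncol(image))
  ci <- which(xs >= xr[1] - ps & xs <= xr[2] + ps)
  ri <- which(ys >= yr[1] - ps & ys <= yr[2] + ps)
  if (!length(ci) || !length(ri)) return(mask)
  grid <- expand.grid(y = ys[ri], x = xs[ci])
  inside <- point_in_polygon(grid$x, grid$y, poly)
  mask[cbind(rep(ri, times = length(ci))[inside],
             rep(ci, each = length(ri))[inside])] <- TRUE
  mask
}

# separable Gaussian smoothing with reflected edges
gaussian_smooth <- function(image, sigma_px) {
  if (sigma_px <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma_px)
  k <- k / sum(k)
  smooth_1d <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(r)]), v, rev(v[seq.int(n - r + 1, n)]))
    stats::filter(vp, k, sides = 2)[seq.int(r + 1, r + n)]
  }
  tmp <- apply(image, 2, smooth_1d)
  t(apply(tmp, 1, smooth_1d))
}

#' Detect HCR puncta inside a region mask
#'
#' Gaussian-smooths the image, finds local maxima inside the mask whose
#' smoothed intensity exceeds the masked median plus `k_sd` robust
#' standard deviations (1.4826 x MAD — robust so bright puncta cannot
#' inflate their own baseline), merges maxima closer than `2 * sigma`
#' (keeping the brighter), and reports count and count / mask-area
#' density. The count is monotone non-increasing in `k_sd`.
#'
#' @param image numeric matrix with `pixel_size_um` attribute (or supply
#'   `pixel_size_um`).
#' @param mask polygon vertex matrix, um.
#' @param smooth_sigma_um Gaussian smoothing sd, um.
#' @param k_sd detection threshold in robust SDs above the masked median.
#' @param pixel_size_um pixel pitch override, um.
#' @return list of class `puncta_result`: `n_puncta`, `density_per_um2`
#'   (count / polygon area in um^2), `density_per_pixel` (count / masked
#'   pixel count, the pixel-count variant), `centers` (data.frame, um).
#' @export
detect_puncta <- function(image, mask, smooth_sigma_um = 0.15, k_sd = 3,
                          pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(image, "pixel_size_um")
  if (is.null(ps)) stop("pixel size unknown: supply pixel_size_um")
  pm <- polygon_pixel_mask(image, mask, ps)
  if (!any(pm)) stop("empty mask")
  sm <- gaussian_smooth(unclass(image), smooth_sigma_um / ps)
  vals <- sm[pm]
  thr <- stats::median(vals) + k_sd * stats::mad(vals, constant = 1.4826)
  nr <- nrow(sm); nc <- ncol(sm)
  cand <- which(pm & sm > thr, arr.ind = TRUE)
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, c - 1):min(nc, c + 1)
    nb <- sm[rs, cs]
    is_max[i] <- sm[r, c] == max(nb)
  }
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand)) {
    cx <- (cand[, 2] - 0.5) * ps
    cy <- (cand[, 1] - 0.5) * ps
    inten <- sm[cand]
    o <- order(inten, decreasing = TRUE)
    cx <- cx[o]; cy <- cy[o]; inten <- inten[o]
    keep <- logical(length(cx))
    min_sep <- 2 * smooth_sigma_um
    for (i in seq_along(cx)) {
      if (!any(keep) ||
          all(sqrt((cx[keep] - cx[i])^2 + (cy[keep] - cy[i])^2) >= min_sep)) {
        keep[i] <- TRUE
      }
    }
    centers <- data.frame(x_um = cx[keep], y_um = cy[keep],
                          intensity = inten[keep])
  } else {
    centers <- data.frame(x_um = numeric(0), y_um = numeric(0),
                          intensity = numeric(0))
  }
  area <- polygon_area(mask)
  structure(list(n_puncta = nrow(centers),
                 density_per_um2 = nrow(centers) / area,
                 density_per_pixel = nrow(centers) / sum(pm),
                 centers = centers, area_um2 = area),
            class = "puncta_result")
}

#' Puncta density from a pre-counted puncta table
#'
#' Maps the manual-count workflow directly: counts supplied puncta centers
#' falling inside the mask and divides by the polygon area.
#'
#' @param puncta_xy data.frame/matrix with x, y columns, um.
#' @param mask polygon vertex matrix, um.
#' @return `puncta_result` (without intensities).
#' @export
puncta_density <- function(puncta_xy, mask) {
  m <- as.matrix(puncta_xy)
  area <- polygon_area(mask)
  if (nrow(m) == 0) {
    inside <- logical(0)
  } else {
    inside <- point_in_polygon(m[, 1], m[, 2], mask)
  }
  centers <- data.frame(x_um = m[inside, 1], y_um = m[inside, 2])
  structure(list(n_puncta = sum(inside), density_per_um2 = sum(inside) / area,
                 density_per_pixel = NA_real_, centers = centers,
                 area_um2 = area),
            class = "puncta_result")
}

#' Background-corrected mean grey value of a region
#'
#' Mean pixel intensity of the traced region minus that of a disjoint
#' adjacent background region; negative results are preserved. Invariant
#' under adding a constant to the whole image.
#'
#' @param image numeric matrix with `pixel_size_um` attribute.
#' @param region,background polygon vertex matrices, um; must not share
#'   pixels.
#' @param pixel_size_um pixel pitch override, um.
#' @return corrected mean grey value, a.u.
#' @export
corrected_mean_grey <- function(image, region, background,
                                pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(image, "pixel_size_um")
  rm_ <- polygon_pixel_mask(image, region, ps)
  bm <- polygon_pixel_mask(image, background, ps)
  if (!any(rm_) || !any(bm)) stop("empty region or background")
  if (any(rm_ & bm)) stop("region and background overlap")
  mean(image[rm_]) - mean(image[bm])
}

#' Mean grey value inside a floor-plate box
#'
#' Axis-aligned square of the stated area (side = sqrt(area); 200 um^2 by
#' default) centered on the given point.
#'
#' @param image numeric matrix with `pixel_size_um` attribute.
#' @param box_center length-2 numeric center, um.
#' @param box_area_um2 box area, um^2.
#' @param pixel_size_um pixel pitch override, um.
#' @return mean grey value, a.u.
#' @export
floorplate_mean <- function(image, box_center, box_area_um2 = 200,
                            pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(image, "pixel_size_um")
  if (is.null(ps)) stop("pixel size unknown: supply pixel_size_um")
  side <- sqrt(box_area_um2)
  x0 <- box_center[1] - side / 2; x1 <- box_center[1] + side / 2
  y0 <- box_center[2] - side / 2; y1 <- box_center[2] + side / 2
  if (x0 < 0 || y0 < 0 || x1 > ncol(image) * ps || y1 > nrow(image) * ps) {
    stop("floor-plate box exceeds the image")
  }
  box <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  mask <- polygon_pixel_mask(image, box, ps)
  mean(image[mask])
}
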