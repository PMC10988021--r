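# Colocalization (per-cell Pearson correlation) and GUV analysis: ring
# fitting, membrane-centred radial profiles (-50..+50 px, each normalized to
# its own maximum), and diameter comparisons.

#' Per-cell Pearson colocalization coefficient
#'
#' Pearson correlation of the two channels over each cell's mask pixels.
#' Cells with zero variance in either channel are excluded and reported.
#'
#' @param imgA,imgB registered channel images (same size).
#' @param mask integer label matrix.
#' @return data.frame (id, pcc); excluded cell ids in
#'   `attr(, "excluded")`.
#' @export
pcc_per_cell <- function(imgA, imgB, mask) {
  if (!all(dim(imgA) == dim(imgB)) || !all(dim(imgA) == dim(mask)))
    stop("channel/mask shape mismatch")
  ids <- setdiff(sort(unique(as.vector(mask))), 0)
  excluded <- integer(0)
  rows <- list()
  for (i in ids) {
    a <- imgA[mask == i]; b <- imgB[mask == i]
    if (sd(a) == 0 || sd(b) == 0) { excluded <- c(excluded, i); next }
    rows[[length(rows) + 1L]] <- data.frame(id = i, pcc = cor(a, b))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), pcc = numeric())
  attr(out, "excluded") <- excluded
  out
}

# bilinear interpolation at (x, y) in pixel units (pixel centres at i - 0.5)
.bilinear <- function(img, x, y) {
  gx <- x + 0.5; gy <- y + 0.5 # to 1-based grid coordinates
  x0 <- pmin(pmax(floor(gx), 1L), nrow(img) - 1L)
  y0 <- pmin(pmax(floor(gy), 1L), ncol(img) - 1L)
  fx <- pmin(pmax(gx - x0, 0), 1)
  fy <- pmin(pmax(gy - y0, 0), 1)
  i00 <- img[cbind(x0, y0)]; i10 <- img[cbind(x0 + 1L, y0)]
  i01 <- img[cbind(x0, y0 + 1L)]; i11 <- img[cbind(x0 + 1L, y0 + 1L)]
  i00 * (1 - fx) * (1 - fy) + i10 * fx * (1 - fy) +
    i01 * (1 - fx) * fy + i11 * fx * fy
}

#' Fit the centre and radius of a GUV membrane ring
#'
#' Edge pixels (Otsu-thresholded gradient magnitude) seed an algebraic
#' least-squares circle fit, refined deterministically by maximizing the mean
#' interpolated intensity on the fitted circle.
#'
#' @param img single-channel image.
#' @param smooth_sigma Gaussian sigma (px) before the gradient.
#' @param n_rays points on the circle used during refinement.
#' @return list with `cx`, `cy`, `radius` (px).
#' @export
fit_guv <- function(img, smooth_sigma = 1, n_rays = 360L) {
  if (max(img) <= min(img)) stop("no ring found: blank image")
  sm <- .gblur((img - min(img)) / (max(img) - min(img)), smooth_sigma)
  gx <- sm[c(2:nrow(sm), nrow(sm)), ] - sm[c(1, 1:(nrow(sm) - 1)), ]
  gy <- sm[, c(2:ncol(sm), ncol(sm))] - sm[, c(1, 1:(ncol(sm) - 1))]
  gm <- sqrt(gx^2 + gy^2)
  thr <- EBImage::otsu(EBImage::Image(gm / max(gm)), range = c(0, 1)) * max(gm)
  pts <- which(gm > thr, arr.ind = TRUE)
  if (nrow(pts) < 10) stop("no ring found: too few edge pixels")
  x <- pts[, 1] - 0.5; y <- pts[, 2] - 0.5
  # Kasa algebraic fit: x^2 + y^2 = a x + b y + c
  A <- cbind(x, y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r <- sqrt(sol[3] + cx^2 + cy^2)
  ang <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  ring_mean <- function(p) {
    xs <- p[1] + p[3] * cos(ang); ys <- p[2] + p[3] * sin(ang)
    ok <- xs > 0 & xs < nrow(img) - 1 & ys > 0 & ys < ncol(img) - 1
    if (mean(ok) < 0.75) return(Inf)
    -mean(.bilinear(sm, xs[ok], ys[ok]))
  }
  opt <- optim(c(cx, cy, r), ring_mean, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  list(cx = opt$par[1], cy = opt$par[2], radius = opt$par[3])
}

#' Membrane-centred radial intensity profile
#'
#' For each offset -50..+50 px from the fitted radius (negative = interior),
#' the mean bilinear-interpolated intensity over `n_rays` equally spaced rays
#' from the centre; the profile is normalized to its own maximum. Offsets
#' that would fall at negative radius are clipped to the centre and flagged.
#'
#' @param img image.
#' @param center `c(cx, cy)` in px.
#' @param radius fitted radius in px.
#' @param n_rays number of rays (default 720).
#' @param half_width profile half-width in px (default 50).
#' @return list with `offsets` (-50..50), `profile` (normalized), `raw`,
#'   `clipped` (number of clipped offsets).
#' @export
radial_profile <- function(img, center, radius, n_rays = 720L, half_width = 50L) {
  offsets <- seq(-half_width, half_width)
  ang <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  ca <- cos(ang); sa <- sin(ang)
  clipped <- sum(radius + offsets < 0)
  raw <- vapply(offsets, function(d) {
    r <- max(radius + d, 0)
    xs <- center[1] + r * ca; ys <- center[2] + r * sa
    ok <- xs > 0 & xs < nrow(img) - 1 & ys > 0 & ys < ncol(img) - 1
    mean(.bilinear(img, xs[ok], ys[ok]))
  }, numeric(1))
  list(offsets = offsets, profile = raw / max(raw), raw = raw,
       clipped = clipped)
}

#' GUV diameters and group comparison
#'
#' @param radii_px numeric vector of fitted radii in px (one group) or a list
#'   of two named groups for comparison.
#' @param pixel_size micrometres per pixel.
#' @return for one group: data.frame of diameters (um). For two groups:
#'   additionally a [ttest_groups()] result under `$test`.
#' @export
guv_diameters <- function(radii_px, pixel_size = 0.1) {
  if (is.list(radii_px)) {
    stopifnot(length(radii_px) == 2L)
    gs <- names(radii_px) %||% c("treated", "control")
    d1 <- 2 * radii_px[[1]] * pixel_size
    d2 <- 2 * radii_px[[2]] * pixel_size
    out <- data.frame(group = rep(gs, c(length(d1), length(d2))),
                      diameter = c(d1, d2))
    list(diameters = out, test = ttest_groups(d1, d2))
  } else {
    data.frame(diameter = 2 * radii_px * pixel_size)
  }
}
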