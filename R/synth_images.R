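# Synthetic microscopy scene rendering with planted ground truth.
#
# Images are numeric matrices indexed [x, y] (EBImage convention), pixel
# units; physical coordinates are in micrometres with pixel centres at
# (i - 0.5) * pixel_size. Cells are spherocylinders (rods): the set of points
# within W/2 of the central axis segment of length L - W. Rendering order:
# rasterize intensities -> Gaussian PSF blur -> noise (Gaussian and/or
# Poisson). The clean (pre-noise) image is kept in the truth so downstream
# measurements can be checked against planted values exactly.

#' Describe a synthetic cell
#'
#' @param x,y centre in micrometres.
#' @param angle orientation of the major axis in radians.
#' @param length,width cell length and width in micrometres (`length > width`).
#' @param cyto cytoplasmic intensity.
#' @param membrane membrane intensity (0 = no membrane signal); rendered as a
#'   band of `membrane_thickness` um at the cell boundary.
#' @param spots list of spots, each `c(dlong, dtrans, amplitude, sigma)`:
#'   signed offsets (um) from the centroid along/across the axis, peak
#'   amplitude, and Gaussian sigma (um).
#' @param membrane_thickness thickness of the membrane band (um).
#' @return a `synth_cell` list.
#' @export
synth_cell <- function(x, y, angle = 0, length = 2.5, width = 0.8,
                       cyto = 100, membrane = 0, spots = list(),
                       membrane_thickness = 0.1) {
  if (!(length > width) || width <= 0) stop("need length > width > 0")
  for (s in spots) {
    if (abs(s[1]) > length / 2 || abs(s[2]) > width / 2)
      stop("spot outside its cell")
  }
  list(x = x, y = y, angle = angle, length = length, width = width,
       cyto = cyto, membrane = membrane, spots = spots,
       membrane_thickness = membrane_thickness)
}

#' Describe a cell scene
#'
#' @param cells list of [synth_cell()]s (must not overlap).
#' @param nx,ny image size in pixels.
#' @param pixel_size micrometres per pixel (Airyscan-like default 0.05).
#' @param background background intensity level.
#' @param psf_sigma PSF Gaussian sigma in micrometres.
#' @param gaussian_sd additive Gaussian read-noise sd (0 = off).
#' @param poisson apply Poisson (photon) noise.
#' @param seed integer seed for the noise.
#' @return a `cell_scene` list.
#' @export
cell_scene <- function(cells, nx = 256L, ny = 256L, pixel_size = 0.05,
                       background = 5, psf_sigma = 0.08, gaussian_sd = 0,
                       poisson = FALSE, seed = 1L) {
  list(cells = cells, nx = as.integer(nx), ny = as.integer(ny),
       pixel_size = pixel_size, background = background,
       psf_sigma = psf_sigma, gaussian_sd = gaussian_sd,
       poisson = isTRUE(poisson), seed = as.integer(seed))
}

# distance from pixel-centre grid to a cell's axis segment; returns matrix
.cell_distance <- function(scene, cell) {
  px <- scene$pixel_size
  xs <- (seq_len(scene$nx) - 0.5) * px
  ys <- (seq_len(scene$ny) - 0.5) * px
  u <- c(cos(cell$angle), sin(cell$angle))
  half <- max(cell$length / 2 - cell$width / 2, 0)
  X <- matrix(xs - cell$x, scene$nx, scene$ny)
  Y <- matrix(rep(ys - cell$y, each = scene$nx), scene$nx, scene$ny)
  t_ <- X * u[1] + Y * u[2]
  t_ <- pmin(pmax(t_, -half), half)
  sqrt((X - t_ * u[1])^2 + (Y - t_ * u[2])^2)
}

.gblur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  EBImage::gblur(img, sigma = sigma_px)
}

#' Render a cell scene
#'
#' @param scene a [cell_scene()].
#' @return list with `image` (noisy), `clean` (pre-noise, post-blur), and
#'   `truth`: `mask` (label matrix, cells numbered in scene order), `cells`
#'   data.frame (id, centroid px, angle, length/width um, true in-mask mean
#'   of the clean image, spot count) and `spots` data.frame (cell, x, y in
#'   px, dlong, dtrans um, amplitude, sigma).
#' @export
render_cells <- function(scene) {
  px <- scene$pixel_size
  img <- matrix(scene$background, scene$nx, scene$ny)
  mask <- matrix(0L, scene$nx, scene$ny)
  spot_rows <- list()
  for (ci in seq_along(scene$cells)) {
    cell <- scene$cells[[ci]]
    d <- .cell_distance(scene, cell)
    inside <- d <= cell$width / 2
    if (any(mask[inside] != 0L)) stop("overlapping cells in scene")
    mask[inside] <- ci
    img[inside] <- cell$cyto
    if (cell$membrane > 0) {
      band <- inside & d > cell$width / 2 - cell$membrane_thickness
      img[band] <- cell$membrane
    }
    if (length(cell$spots)) {
      u <- c(cos(cell$angle), sin(cell$angle))
      v <- c(-u[2], u[1])
      xs <- (seq_len(scene$nx) - 0.5) * px
      ys <- (seq_len(scene$ny) - 0.5) * px
      for (si in seq_along(cell$spots)) {
        s <- cell$spots[[si]]
        sx <- cell$x + s[1] * u[1] + s[2] * v[1]
        sy <- cell$y + s[1] * u[2] + s[2] * v[2]
        G <- outer(xs - sx, ys - sy, function(a, b) exp(-(a^2 + b^2) / (2 * s[4]^2)))
        img <- img + s[3] * G
        spot_rows[[length(spot_rows) + 1L]] <- data.frame(
          cell = ci, x = sx / px + 0.5, y = sy / px + 0.5,
          dlong = s[1], dtrans = s[2], amplitude = s[3], sigma = s[4])
      }
    }
  }
  clean <- .gblur(img, scene$psf_sigma / px)
  noisy <- with_seed(scene$seed, {
    out <- clean
    if (scene$poisson) out <- matrix(rpois(length(out), pmax(out, 0)),
                                     nrow(out), ncol(out))
    if (scene$gaussian_sd > 0) out <- out + rnorm(length(out), 0, scene$gaussian_sd)
    out
  })
  cells_df <- do.call(rbind, lapply(seq_along(scene$cells), function(ci) {
    cell <- scene$cells[[ci]]
    data.frame(id = ci, x = cell$x / px + 0.5, y = cell$y / px + 0.5,
               angle = cell$angle, length = cell$length, width = cell$width,
               cyto = cell$cyto,
               true_mean = mean(clean[mask == ci]),
               n_spots = length(cell$spots))
  }))
  spots_df <- if (length(spot_rows)) do.call(rbind, spot_rows) else
    data.frame(cell = integer(), x = numeric(), y = numeric(),
               dlong = numeric(), dtrans = numeric(), amplitude = numeric(),
               sigma = numeric())
  list(image = noisy, clean = clean,
       truth = list(mask = mask, cells = cells_df, spots = spots_df,
                    pixel_size = px, psf_sigma = scene$psf_sigma))
}

#' Render a two-channel colocalization scene
#'
#' Channel A carries a smooth random structure inside the cell masks; channel
#' B carries `coloc` times the same structure plus an orthogonal independent
#' structure weighted `sqrt(1 - coloc^2)`, so the planted (pre-noise) in-mask
#' Pearson correlation equals `coloc` up to sampling of the random fields.
#' The truth records the exact correlation of the clean channels.
#'
#' @param scene a [cell_scene()].
#' @param coloc planted colocalization fraction in `[0, 1]`.
#' @param structure_amp amplitude (sd) of the structured signal.
#' @return list with `imageA`, `imageB`, `cleanA`, `cleanB`, `truth`
#'   (as [render_cells()] plus `coloc`, `expected_pcc` — the in-mask Pearson
#'   correlation of the clean channels — and `expected_pcc_per_cell`, the
#'   same computed within each cell's mask).
#' @export
render_two_channel <- function(scene, coloc, structure_amp = 30) {
  if (coloc < 0 || coloc > 1) stop("coloc must be in [0, 1]")
  base <- render_cells(scene)
  mask <- base$truth$mask
  fields <- with_seed(scene$seed + 104729L, {
    f <- function() {
      F0 <- matrix(rnorm(scene$nx * scene$ny), scene$nx, scene$ny)
      F0 <- .gblur(F0, 3)
      (F0 - mean(F0)) / sd(F0)
    }
    list(f(), f())
  })
  F1 <- fields[[1]]; F2 <- fields[[2]]
  inmask <- mask > 0
  structA <- structB <- matrix(0, scene$nx, scene$ny)
  structA[inmask] <- structure_amp * F1[inmask]
  structB[inmask] <- structure_amp * (coloc * F1[inmask] +
                                        sqrt(1 - coloc^2) * F2[inmask])
  cleanA <- base$clean + structA
  cleanB <- base$clean + structB
  addnoise <- function(img, seed) with_seed(seed, {
    out <- img
    if (scene$poisson) out <- matrix(rpois(length(out), pmax(out, 0)),
                                     nrow(out), ncol(out))
    if (scene$gaussian_sd > 0) out <- out + rnorm(length(out), 0, scene$gaussian_sd)
    out
  })
  truth <- base$truth
  truth$coloc <- coloc
  truth$expected_pcc <- cor(cleanA[inmask], cleanB[inmask])
  truth$expected_pcc_per_cell <- vapply(seq_along(scene$cells), function(ci)
    cor(cleanA[mask == ci], cleanB[mask == ci]), numeric(1))
  list(imageA = addnoise(cleanA, scene$seed + 1L),
       imageB = addnoise(cleanB, scene$seed + 2L),
       cleanA = cleanA, cleanB = cleanB, truth = truth)
}

#' Describe and render a GUV (giant unilamellar vesicle) scene
#'
#' A single vesicle: a bright membrane annulus of the given thickness at the
#' given radius, an interior plateau and an exterior plateau, blurred by the
#' PSF, with optional noise. The truth records the centre, radius and the
#' ideal membrane-centred radial profile (-50..+50 px) measured on the clean
#' image.
#'
#' @param cx,cy centre in pixels.
#' @param radius radius in pixels.
#' @param membrane,interior,exterior intensity levels.
#' @param thickness membrane annulus thickness in pixels.
#' @param nx,ny image size; pixel_size um/px; psf_sigma in px here.
#' @param gaussian_sd,poisson,seed noise model.
#' @return list with `image`, `clean`, `truth` (centre, radius_px,
#'   radius_um, profile of 101 values).
#' @export
render_guv <- function(cx, cy, radius, membrane = 200, interior = 10,
                       exterior = 10, thickness = 4, nx = 300L, ny = 300L,
                       pixel_size = 0.1, psf_sigma = 0, gaussian_sd = 0,
                       poisson = FALSE, seed = 1L) {
  if (!(radius > thickness) || thickness <= 0) stop("need radius > thickness > 0")
  xs <- seq_len(nx) - 0.5
  ys <- seq_len(ny) - 0.5
  R <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
  img <- matrix(exterior, nx, ny)
  img[R < radius] <- interior
  img[abs(R - radius) <= thickness / 2] <- membrane
  clean <- .gblur(img, psf_sigma)
  noisy <- with_seed(seed, {
    out <- clean
    if (poisson) out <- matrix(rpois(length(out), pmax(out, 0)), nx, ny)
    if (gaussian_sd > 0) out <- out + rnorm(length(out), 0, gaussian_sd)
    out
  })
  prof <- radial_profile(clean, c(cx, cy), radius)
  list(image = noisy, clean = clean,
       truth = list(cx = cx, cy = cy, radius_px = radius,
                    radius_um = radius * pixel_size,
                    pixel_size = pixel_size, profile = prof$profile))
}

#' Write an image (or multi-channel list of images) to TIFF
#'
#' @param img numeric matrix or list of matrices (pages).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) img <- list(img)
  pages <- lapply(img, function(m) {
    m <- m / max(m, 1e-12)
    t(m) # tiff expects row = image row (y)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a (multi-page) TIFF as a list of [x, y] matrices
#'
#' @param path TIFF path.
#' @return list of numeric matrices.
#' @export
read_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, t)
}
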