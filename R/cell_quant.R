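# Single-cell quantification: segmentation, per-cell background-subtracted
# intensity, accumulation-spot (intensity maxima) detection, and mapping of
# spots into a normalized per-cell coordinate frame.
#
# Segmentation parameters are exposed with documented defaults: Otsu
# threshold on a lightly smoothed image, hole filling, distance-transform
# watershed to split touching cells, and a minimum-area filter. Labels are
# deterministic, ordered by centroid row-major (y, then x).

#' Segment cells in a single-channel image
#'
#' A global Otsu threshold biases boundaries on scenes that mix bright and
#' dim cells (the threshold sits too high for dim cells, eroding them), so
#' after the initial watershed labelling each cell's boundary is refined at
#' its own half-maximum: pixels above halfway between the background level
#' and the cell's plateau (median) are claimed, with contested pixels
#' resolved by intensity-guided propagation from the initial labels.
#'
#' @param img numeric matrix `[x, y]`.
#' @param pixel_size micrometres per pixel.
#' @param smooth_sigma pre-threshold Gaussian sigma in px.
#' @param min_area minimum object area in px.
#' @param watershed_tolerance tolerance of the distance-map watershed.
#' @param refine apply the per-cell half-maximum boundary refinement.
#' @return list with `mask` (integer label matrix) and `cells` data.frame
#'   (id, x, y centroid px, angle, length, width in um, area px).
#' @export
segment_cells <- function(img, pixel_size = 0.05, smooth_sigma = 1,
                          min_area = 50L, watershed_tolerance = 2,
                          refine = TRUE) {
  if (max(img) <= min(img)) {
    return(list(mask = matrix(0L, nrow(img), ncol(img)),
                cells = .empty_cells_df()))
  }
  norm <- (img - min(img)) / (max(img) - min(img))
  sm <- .gblur(norm, smooth_sigma)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- sm > thr
  bin <- EBImage::fillHull(EBImage::Image(bin, colormode = "Grayscale")) > 0
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- EBImage::imageData(lab)
  lab[!bin] <- 0
  # area filter + deterministic relabel by centroid (row-major: y then x)
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  keep <- ids[vapply(ids, function(i) sum(lab == i), numeric(1)) >= min_area]
  if (!length(keep))
    return(list(mask = matrix(0L, nrow(img), ncol(img)),
                cells = .empty_cells_df()))
  if (refine) {
    bg <- median(sm[lab == 0])
    thr_cell <- vapply(keep, function(i)
      bg + 0.5 * (median(sm[lab == i]) - bg), numeric(1))
    # permissive binary at the lowest per-cell threshold; contested pixels
    # are split by propagation from the initial labels
    seeds <- matrix(0L, nrow(img), ncol(img))
    for (i in keep) seeds[lab == i] <- i
    bin_lo <- sm > min(thr_cell)
    prop <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(sm), EBImage::Image(seeds), mask = bin_lo))
    lab2 <- matrix(0L, nrow(img), ncol(img))
    for (k in seq_along(keep)) {
      i <- keep[k]
      lab2[prop == i & sm > thr_cell[k]] <- i
    }
    lab <- lab2
    keep <- keep[vapply(keep, function(i) sum(lab == i), numeric(1)) >= min_area]
    if (!length(keep))
      return(list(mask = matrix(0L, nrow(img), ncol(img)),
                  cells = .empty_cells_df()))
  }
  cent <- t(vapply(keep, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    c(x = mean(w[, 1]), y = mean(w[, 2]))
  }, numeric(2)))
  ord <- order(cent[, 2], cent[, 1])
  mask <- matrix(0L, nrow(img), ncol(img))
  rows <- list()
  for (k in seq_along(ord)) {
    i <- keep[ord[k]]
    sel <- lab == i
    mask[sel] <- k
    w <- which(sel, arr.ind = TRUE)
    geom <- .axis_geometry(w, pixel_size)
    rows[[k]] <- data.frame(id = k, x = mean(w[, 1]), y = mean(w[, 2]),
                            angle = geom$angle, length = geom$length,
                            width = geom$width, area = nrow(w))
  }
  list(mask = mask, cells = do.call(rbind, rows))
}

.empty_cells_df <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(), angle = numeric(),
             length = numeric(), width = numeric(), area = integer())
}

# principal-axis geometry from mask pixel coordinates (second moments);
# length/width are max-min extents of the projections, in micrometres
.axis_geometry <- function(w, pixel_size) {
  xy <- sweep(w, 2, colMeans(w))
  cv <- crossprod(xy) / nrow(xy)
  e <- eigen(cv, symmetric = TRUE)
  u <- e$vectors[, 1]
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u # deterministic sign
  v <- c(-u[2], u[1])
  pl <- xy %*% u
  pt <- xy %*% v
  list(angle = atan2(u[2], u[1]),
       length = (max(pl) - min(pl) + 1) * pixel_size,
       width = (max(pt) - min(pt) + 1) * pixel_size,
       u = u)
}

#' Background-subtracted mean intensity per cell
#'
#' Background is the median of out-of-mask pixels; per-cell means are clamped
#' at zero.
#'
#' @param mask integer label matrix from [segment_cells()].
#' @param img fluorescence image.
#' @return data.frame (id, mean_intensity).
#' @export
per_cell_intensity <- function(mask, img) {
  stopifnot(all(dim(mask) == dim(img)))
  ids <- setdiff(sort(unique(as.vector(mask))), 0)
  bg <- if (any(mask == 0)) median(img[mask == 0]) else 0
  data.frame(id = ids,
             mean_intensity = vapply(ids, function(i)
               max(mean(img[mask == i]) - bg, 0), numeric(1)))
}

#' Detect intensity maxima ("spots") inside cells
#'
#' Local maxima of the Gaussian-smoothed image within the mask; a maximum is
#' kept if its prominence (smoothed value minus the owning cell's median
#' smoothed intensity) is at least `min_prominence` times that median. Maxima
#' closer than `merge_dist` px are merged (brightest kept).
#'
#' @param img fluorescence image.
#' @param mask label matrix.
#' @param min_prominence prominence multiplier (> 0).
#' @param smooth_sigma Gaussian sigma (px) before peak finding.
#' @param merge_dist minimum separation (px), typically the PSF sigma.
#' @return data.frame (cell, x, y, intensity, prominence).
#' @export
detect_maxima <- function(img, mask, min_prominence = 1.5, smooth_sigma = 1,
                          merge_dist = 2) {
  if (min_prominence <= 0) stop("min_prominence must be > 0")
  sm <- .gblur(img, smooth_sigma)
  nx <- nrow(sm); ny <- ncol(sm)
  # strict local maxima on the 8-neighborhood (plateaus excluded)
  inner_x <- 2:(nx - 1); inner_y <- 2:(ny - 1)
  C <- sm[inner_x, inner_y]
  is_max <- matrix(TRUE, length(inner_x), length(inner_y))
  strict <- matrix(FALSE, length(inner_x), length(inner_y))
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    Nb <- sm[inner_x + dx, inner_y + dy]
    is_max <- is_max & (C >= Nb)
    strict <- strict | (C > Nb)
  }
  cand <- which(is_max & strict, arr.ind = TRUE)
  if (nrow(cand)) {
    cand[, 1] <- cand[, 1] + 1L
    cand[, 2] <- cand[, 2] + 1L
  }
  rows <- list()
  med <- local({
    ids <- setdiff(sort(unique(as.vector(mask))), 0)
    setNames(vapply(ids, function(i) median(sm[mask == i]), numeric(1)),
             as.character(ids))
  })
  for (k in seq_len(nrow(cand))) {
    cx <- cand[k, 1]; cy <- cand[k, 2]
    owner <- mask[cx, cy]
    if (owner == 0) next
    m <- med[[as.character(owner)]]
    prom <- sm[cx, cy] - m
    if (prom >= min_prominence * m) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = owner, x = cx, y = cy, intensity = sm[cx, cy], prominence = prom)
    }
  }
  if (!length(rows))
    return(data.frame(cell = integer(), x = numeric(), y = numeric(),
                      intensity = numeric(), prominence = numeric()))
  sp <- do.call(rbind, rows)
  sp <- sp[order(-sp$intensity), , drop = FALSE]
  keep <- rep(TRUE, nrow(sp))
  for (i in seq_len(nrow(sp))) {
    if (!keep[i]) next
    if (i < nrow(sp)) {
      for (j in (i + 1):nrow(sp)) {
        if (keep[j] && sp$cell[j] == sp$cell[i] &&
            sqrt((sp$x[j] - sp$x[i])^2 + (sp$y[j] - sp$y[i])^2) < merge_dist)
          keep[j] <- FALSE
      }
    }
  }
  sp <- sp[keep, , drop = FALSE]
  sp <- sp[order(sp$cell, sp$x, sp$y), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

#' Map spots into per-cell coordinates
#'
#' Projects each spot's displacement from its cell centroid onto the cell's
#' major/minor axes. `dlong`/`dtrans` are signed offsets in micrometres;
#' `fold_long`/`fold_trans` are |offsets| normalized by the half-length and
#' half-width (0 = centroid, 1 = pole/boundary).
#'
#' @param spots data.frame from [detect_maxima()].
#' @param cells data.frame from [segment_cells()].
#' @param pixel_size micrometres per pixel.
#' @return `spots` with added columns dlong, dtrans, fold_long, fold_trans.
#' @export
map_to_cell_frame <- function(spots, cells, pixel_size = 0.05) {
  if (!nrow(spots)) {
    spots$dlong <- spots$dtrans <- spots$fold_long <- spots$fold_trans <- numeric(0)
    return(spots)
  }
  idx <- match(spots$cell, cells$id)
  a <- cells$angle[idx]
  dx <- (spots$x - cells$x[idx]) * pixel_size
  dy <- (spots$y - cells$y[idx]) * pixel_size
  spots$dlong <- dx * cos(a) + dy * sin(a)
  spots$dtrans <- -dx * sin(a) + dy * cos(a)
  spots$fold_long <- abs(spots$dlong) / (cells$length[idx] / 2)
  spots$fold_trans <- abs(spots$dtrans) / (cells$width[idx] / 2)
  spots
}

#' Spots per cell
#'
#' @param spots data.frame from [detect_maxima()].
#' @param cells data.frame from [segment_cells()].
#' @return list with `mean_spots_per_cell` and `per_cell` (id, n_spots).
#' @export
spots_per_cell <- function(spots, cells) {
  counts <- vapply(cells$id, function(i) sum(spots$cell == i), numeric(1))
  list(mean_spots_per_cell = if (nrow(cells)) mean(counts) else 0,
       per_cell = data.frame(id = cells$id, n_spots = counts))
}
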