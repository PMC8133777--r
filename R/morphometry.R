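#' Triangle state tensor and its decomposition
#'
#' The state of each triangle of the centroid triangulation is the linear map
#' `s` taking an equilateral reference triangle (area `ref_area`) to the
#' observed triangle. It factors uniquely as
#' `s = (a/a0)^(1/2) * exp(q) * R(theta)` where `a/a0` is the area ratio,
#' `q` the triangle elongation nematic and `R(theta)` a rotation. The
#' decomposition is exact: recomposing the factors reproduces `s` to
#' numerical precision.
#'
#' @param vertices 3 x 2 numeric matrix of triangle vertices (um), in
#'   counter-clockwise order (clockwise input is reordered).
#' @param ref_area area of the equilateral reference triangle (um^2). Only
#'   the area ratio depends on it; elongation and angle do not.
#' @return list with `area_ratio`, `elong` (nematic `c(xx, xy)`), `theta`
#'   (rotation, radians), `area` (um^2) and the raw 2x2 matrix `s`.
#' @export
triangle_state <- function(vertices, ref_area = 1) {
  stopifnot(is.matrix(vertices), nrow(vertices) == 3, ncol(vertices) == 2,
            ref_area > 0)
  e1 <- vertices[2, ] - vertices[1, ]
  e2 <- vertices[3, ] - vertices[1, ]
  a2 <- e1[1] * e2[2] - e1[2] * e2[1] # twice signed area
  if (abs(a2) < 1e-12 * max(1, sum(abs(vertices))))
    stop("degenerate triangle: collinear vertices", call. = FALSE)
  if (a2 < 0) { # reorder to counter-clockwise
    vertices <- vertices[c(1, 3, 2), ]
    e1 <- vertices[2, ] - vertices[1, ]
    e2 <- vertices[3, ] - vertices[1, ]
    a2 <- -a2
  }
  # reference equilateral triangle of area ref_area, counter-clockwise
  L <- sqrt(4 * ref_area / sqrt(3))
  r1 <- c(0, L / sqrt(3))
  r2 <- c(-L / 2, -L / (2 * sqrt(3)))
  r3 <- c(L / 2, -L / (2 * sqrt(3)))
  Eref <- cbind(r2 - r1, r3 - r1)
  Eobs <- cbind(e1, e2)
  s <- Eobs %*% solve(Eref)
  dec <- decompose_map(s)
  list(area_ratio = dec$det, elong = dec$elong, theta = dec$theta,
       area = a2 / 2, s = s)
}

# factor a 2x2 map with positive determinant as sqrt(det) * exp(q) * R(theta)
decompose_map <- function(s) {
  d <- s[1, 1] * s[2, 2] - s[1, 2] * s[2, 1]
  if (d <= 0) stop("map must have positive determinant", call. = FALSE)
  M <- s / sqrt(d)
  theta <- atan2(M[2, 1] - M[1, 2], M[1, 1] + M[2, 2])
  E <- M %*% rot2(-theta) # symmetric positive definite, det 1
  tt <- (E[1, 1] + E[2, 2]) / 2
  n <- acosh(max(1, tt))
  f <- if (n < 1e-12) 1 else n / sinh(n)
  q <- c(xx = f * (E[1, 1] - E[2, 2]) / 2, xy = f * (E[1, 2] + E[2, 1]) / 2)
  list(det = d, elong = q, theta = theta)
}

#' Triangle states for a whole frame
#'
#' Computes the state decomposition for every triangle of one frame of an
#' [epithelium()]. The reference triangle area is the frame's mean triangle
#' area (only area ratios enter downstream results).
#'
#' @param tissue an [epithelium()].
#' @param frame frame index (default: first frame).
#' @return data.frame with one row per triangle: `tri_id`, cell ids, the
#'   triangle centroid `x`, `y`, `area`, `area_ratio`, elongation components
#'   `q_xx`, `q_xy` and rotation `theta`.
#' @export
frame_triangle_states <- function(tissue, frame = tissue_frames(tissue)[1]) {
  fr <- get_frame(tissue, frame)
  triangle_states_impl(fr$cells, fr$triangles)
}

triangle_states_impl <- function(cells, triangles) {
  if (nrow(triangles) == 0)
    stop("no triangles in frame", call. = FALSE)
  idx <- match(c(triangles$cell_a, triangles$cell_b, triangles$cell_c),
               cells$cell_id)
  n <- nrow(triangles)
  px <- matrix(cells$x[idx], n, 3)
  py <- matrix(cells$y[idx], n, 3)
  # vectorized edge vectors
  e1x <- px[, 2] - px[, 1]; e1y <- py[, 2] - py[, 1]
  e2x <- px[, 3] - px[, 1]; e2y <- py[, 3] - py[, 1]
  a2 <- e1x * e2y - e1y * e2x
  flip <- a2 < 0
  if (any(flip)) { # enforce counter-clockwise
    tmp <- e1x[flip]; e1x[flip] <- e2x[flip]; e2x[flip] <- tmp
    tmp <- e1y[flip]; e1y[flip] <- e2y[flip]; e2y[flip] <- tmp
    a2 <- abs(a2)
  }
  area <- a2 / 2
  if (any(area < 1e-12))
    stop("degenerate triangle(s) in frame", call. = FALSE)
  ref_area <- mean(area)
  L <- sqrt(4 * ref_area / sqrt(3))
  r1 <- c(0, L / sqrt(3)); r2 <- c(-L / 2, -L / (2 * sqrt(3)))
  r3 <- c(L / 2, -L / (2 * sqrt(3)))
  Eref_inv <- solve(cbind(r2 - r1, r3 - r1))
  # s = [e1 e2] %*% Eref_inv, elementwise over triangles
  s11 <- e1x * Eref_inv[1, 1] + e2x * Eref_inv[2, 1]
  s12 <- e1x * Eref_inv[1, 2] + e2x * Eref_inv[2, 2]
  s21 <- e1y * Eref_inv[1, 1] + e2y * Eref_inv[2, 1]
  s22 <- e1y * Eref_inv[1, 2] + e2y * Eref_inv[2, 2]
  dec <- decompose_map_vec(s11, s12, s21, s22)
  data.frame(tri_id = triangles$tri_id,
             cell_a = triangles$cell_a, cell_b = triangles$cell_b,
             cell_c = triangles$cell_c,
             x = rowMeans(px), y = rowMeans(py), area = area,
             area_ratio = dec$det, q_xx = dec$q_xx, q_xy = dec$q_xy,
             theta = dec$theta)
}

# vectorized version of decompose_map for many 2x2 maps
decompose_map_vec <- function(s11, s12, s21, s22) {
  d <- s11 * s22 - s12 * s21
  sq <- sqrt(d)
  m11 <- s11 / sq; m12 <- s12 / sq; m21 <- s21 / sq; m22 <- s22 / sq
  theta <- atan2(m21 - m12, m11 + m22)
  ct <- cos(theta); st <- sin(theta)
  # E = M %*% R(-theta); R(-theta) = [[ct, st], [-st, ct]]
  E11 <- m11 * ct - m12 * st
  E12 <- m11 * st + m12 * ct
  E21 <- m21 * ct - m22 * st
  E22 <- m21 * st + m22 * ct
  tt <- pmax(1, (E11 + E22) / 2)
  n <- acosh(tt)
  f <- ifelse(n < 1e-12, 1, n / sinh(pmax(n, 1e-300)))
  list(det = d, theta = theta,
       q_xx = f * (E11 - E22) / 2, q_xy = f * (E12 + E21) / 2)
}

#' Area-weighted patch elongation
#'
#' Cell elongation of a tissue region is the area-weighted average of
#' triangle elongation. Averaging is linear: the elongation of a union of
#' patches is the area-weighted combination of the sub-patch results.
#'
#' @param states data.frame from [frame_triangle_states()] (columns `q_xx`,
#'   `q_xy`, `area`), possibly subset to a patch.
#' @param weights optional weights; default the triangle areas.
#' @return nematic `c(xx, xy)`.
#' @export
patch_elongation <- function(states, weights = states$area) {
  if (is.null(states) || nrow(states) == 0)
    stop("empty patch: no triangles to average", call. = FALSE)
  w <- weights / sum(weights)
  nematic(sum(w * states$q_xx), sum(w * states$q_xy))
}

# separable Gaussian convolution with replicate padding; sigma in pixels
gauss_smooth <- function(m, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  pad <- function(mat, n) {
    rbind(mat[rep(1, n), , drop = FALSE], mat,
          mat[rep(nrow(mat), n), , drop = FALSE])
  }
  conv_cols <- function(mat) { # convolve along rows dimension
    p <- pad(mat, r)
    out <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq_along(k)) out <- out + k[j] * p[j:(j + nrow(mat) - 1), ,
                                                  drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Smoothed height-gradient field
#'
#' Smooths the height map with a Gaussian filter of width `sigma` (um),
#' takes the centered finite-difference gradient, then smooths the result
#' again with the same filter. The returned object evaluates `(dh/dx,
#' dh/dy)` at arbitrary um positions by bilinear interpolation.
#'
#' @param h a [height_field()].
#' @param sigma Gaussian width in um (default 2).
#' @return object of class `"height_gradient"`: call
#'   [eval_gradient()] to sample it.
#' @export
height_gradient <- function(h, sigma = 2) {
  stopifnot(inherits(h, "height_field"))
  sp <- sigma / h$pixel_size
  if (min(dim(h$values)) < 6 * sp + 3)
    stop("height field too small for a sigma=", sigma, " um kernel",
         call. = FALSE)
  hs <- gauss_smooth(h$values, sp)
  # centered differences; rows are y, columns x
  nx <- ncol(hs); ny <- nrow(hs)
  dx <- (hs[, c(2:nx, nx)] - hs[, c(1, 1:(nx - 1))]) /
    (h$pixel_size * rep(c(1, rep(2, nx - 2), 1), each = ny))
  dy <- (hs[c(2:ny, ny), ] - hs[c(1, 1:(ny - 1)), ]) /
    (h$pixel_size * rep(c(1, rep(2, ny - 2), 1), times = nx))
  structure(list(dx = gauss_smooth(dx, sp), dy = gauss_smooth(dy, sp),
                 pixel_size = h$pixel_size, origin = h$origin),
            class = "height_gradient")
}

#' Sample a gradient field at um positions
#'
#' @param g a `"height_gradient"` from [height_gradient()].
#' @param x,y um coordinates (vectors).
#' @return two-column matrix `(dhdx, dhdy)`.
#' @export
eval_gradient <- function(g, x, y) {
  bil <- function(m, px, py) {
    # px, py: 0-based pixel coordinates of query (pixel centers at i+0.5)
    nx <- ncol(m); ny <- nrow(m)
    fx <- pmin(pmax(px - 0.5, 0), nx - 1)
    fy <- pmin(pmax(py - 0.5, 0), ny - 1)
    i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
    tx <- fx - i0; ty <- fy - j0
    m[cbind(j0 + 1, i0 + 1)] * (1 - tx) * (1 - ty) +
      m[cbind(j0 + 1, i0 + 2)] * tx * (1 - ty) +
      m[cbind(j0 + 2, i0 + 1)] * (1 - tx) * ty +
      m[cbind(j0 + 2, i0 + 2)] * tx * ty
  }
  px <- (x - g$origin[1]) / g$pixel_size
  py <- (y - g$origin[2]) / g$pixel_size
  cbind(dhdx = bil(g$dx, px, py), dhdy = bil(g$dy, px, py))
}

#' Deproject shapes and areas measured on a curved surface
#'
#' A domed epithelium imaged in 2D projection distorts apparent shapes. With
#' height gradient `grad = (dh/dx, dh/dy)` at the element center, the tilt
#' factor is `lambda = sqrt(1 + |grad|^2)` and the tilt transformation
#' `N = R(alpha) diag(lambda, 1) R(-alpha)` with `alpha` the steepest-ascent
#' angle. The deprojected state tensor is `N %*% s` and the deprojected area
#' `a * lambda`. For a flat field the operation is the identity; on an
#' analytic tilted plane it recovers in-plane shapes exactly.
#'
#' @param states data.frame of triangle states (from
#'   [frame_triangle_states()]) with positions `x`, `y`, or a cell table for
#'   area-only deprojection.
#' @param grad either a `"height_gradient"` or an n x 2 matrix of gradient
#'   values at the element centers.
#' @return the input data.frame with `area`, `q_xx`, `q_xy`, `theta`,
#'   `area_ratio` replaced by deprojected values (for cell tables, `area`
#'   only).
#' @export
deproject <- function(states, grad) {
  if (inherits(grad, "height_gradient"))
    grad <- eval_gradient(grad, states$x, states$y)
  grad <- matrix(grad, ncol = 2)
  stopifnot(nrow(grad) == nrow(states), all(is.finite(grad)))
  lam <- sqrt(1 + grad[, 1]^2 + grad[, 2]^2)
  out <- states
  out$area <- states$area * lam
  if (!all(c("q_xx", "q_xy", "theta", "area_ratio") %in% names(states)))
    return(out) # area-only (cell table)
  alpha <- atan2(grad[, 2], grad[, 1])
  ca <- cos(alpha); sa <- sin(alpha)
  # N = R(alpha) diag(lam, 1) R(-alpha)
  N11 <- lam * ca^2 + sa^2
  N12 <- (lam - 1) * ca * sa
  N22 <- lam * sa^2 + ca^2
  # s from the stored decomposition, s = sqrt(ar) expq R(theta)
  n <- nrow(states)
  q_xx <- numeric(n); q_xy <- numeric(n); theta <- numeric(n)
  ar <- numeric(n)
  for (i in seq_len(n)) {
    E <- nematic_expm(states$q_xx[i], states$q_xy[i])
    s <- sqrt(states$area_ratio[i]) * E %*% rot2(states$theta[i])
    Nm <- matrix(c(N11[i], N12[i], N12[i], N22[i]), 2, 2)
    dec <- decompose_map(Nm %*% s)
    ar[i] <- dec$det; q_xx[i] <- dec$elong[1]; q_xy[i] <- dec$elong[2]
    theta[i] <- dec$theta
  }
  out$area_ratio <- ar; out$q_xx <- q_xx; out$q_xy <- q_xy
  out$theta <- theta
  out
}

#' Center of the radial elongation pattern
#'
#' The pouch center is assumed to lie on the DV boundary (the x axis after
#' alignment). For each candidate x the tissue is split into four quadrants
#' by the DV axis and the perpendicular through x, and
#' `F(x) = A_I <Q_xy>_I - A_II <Q_xy>_II + A_III <Q_xy>_III - A_IV <Q_xy>_IV`
#' is formed from quadrant areas and area-weighted mean `Q_xy`, with
#' quadrants numbered counter-clockwise from the top-right. For a
#' tangentially (or radially) patterned tissue the off-diagonal component
#' `Q_xy` integrated per quadrant makes `F` a signed well whose minimum
#' sits where the vertical line passes through the pattern center (there
#' `Q_xy` vanishes along the line, so `F` is stationary); the estimate is
#' the scanned x minimizing `F` (ties broken toward smallest `|x|`). For
#' spatially uniform elongation `F` carries no center information (it
#' reduces to a quadrant-area imbalance); this is flagged `degenerate`.
#'
#' @param states triangle states with positions and elongation (columns `x`,
#'   `y`, `area`, `q_xy`).
#' @param scan x positions to scan (um); default a 1-um grid spanning the
#'   tissue interior.
#' @return list with `xc` (um), `F_values` (data.frame `x`, `F`),
#'   `scan_step`, and a `degenerate` flag.
#' @export
find_center <- function(states, scan = NULL) {
  if (all(states$y >= 0) || all(states$y <= 0))
    stop("geometry error: tissue must span both sides of the DV axis",
         call. = FALSE)
  if (is.null(scan)) {
    rng <- stats::quantile(states$x, c(0.1, 0.9))
    scan <- seq(floor(rng[1]), ceiling(rng[2]), by = 1)
  }
  aq <- states$area * states$q_xy
  up <- states$y >= 0
  Fv <- vapply(scan, function(x0) {
    right <- states$x >= x0
    sum(aq[right & up]) - sum(aq[!right & up]) +
      sum(aq[!right & !up]) - sum(aq[right & !up])
  }, numeric(1))
  best <- which(Fv <= min(Fv) + 1e-15)
  xc <- scan[best[which.min(abs(scan[best]))]]
  # if F never dips below a small fraction of the available elongation
  # scale, the pattern carries no center information along x
  f_scale <- sum(states$area * sqrt(states$q_xy^2 + states$q_xx^2))
  degenerate <- (max(Fv) - min(Fv)) < 0.02 * f_scale + 1e-12
  list(xc = xc, F_values = data.frame(x = scan, F = Fv),
       scan_step = if (length(scan) > 1) diff(scan[1:2]) else NA_real_,
       degenerate = degenerate)
}

#' Label cells inside the DV-boundary band
#'
#' Cells within the horizontal stripe of total width `band_width` centered
#' on the DV boundary (|y - y_dv| < band_width/2) are labeled `"DV_band"`;
#' radial-profile operations exclude them by default.
#'
#' @param cells cell table (columns `y`, `region`).
#' @param band_width stripe width in um (default 22).
#' @param y_dv y position of the DV boundary (default 0).
#' @return the cell table with updated `region`.
#' @export
filter_dv_band <- function(cells, band_width = 22, y_dv = 0) {
  stopifnot(band_width >= 0)
  inband <- abs(cells$y - y_dv) < band_width / 2
  cells$region[inband & cells$region != "excluded"] <- "DV_band"
  cells
}

#' Radial profiles of cell area and elongation
#'
#' Bins elements by radius (rounding to the nearest `bin` um around
#' `center`) and reports per bin the mean cell area, the area-weighted
#' radial elongation component `Q_rr` (projection of triangle elongation on
#' the local radial axis; negative = tangential), dispersion and counts.
#' Cells labeled `DV_band` or `excluded` are dropped by default.
#'
#' @param cells cell table of one frame.
#' @param states matching triangle states (same frame); if `NULL` only
#'   areas are profiled.
#' @param center length-2 um position of the pattern center.
#' @param bin bin width, um (default 10; bin centers at 0, 10, 20, ...).
#' @param exclude region labels to drop (applies to cells; triangles are
#'   dropped when any of their cells is excluded).
#' @return data.frame with `bin_r`, `mean_area`, `sd_area`, `n_cells`,
#'   `Qrr`, `sd_Qrr`, `n_tri`. Empty bins are absent, not zero.
#' @export
radial_profile <- function(cells, states = NULL, center = c(0, 0), bin = 10,
                           exclude = c("DV_band", "excluded")) {
  keep <- !(cells$region %in% exclude)
  cl <- cells[keep, , drop = FALSE]
  if (nrow(cl) == 0) stop("no cells left after exclusions", call. = FALSE)
  r <- sqrt((cl$x - center[1])^2 + (cl$y - center[2])^2)
  br <- round(r / bin) * bin
  prof <- do.call(rbind, lapply(split(seq_along(br), br), function(ix) {
    data.frame(bin_r = br[ix[1]], mean_area = mean(cl$area[ix]),
               sd_area = stats::sd(cl$area[ix]), n_cells = length(ix))
  }))
  if (!is.null(states)) {
    excl_cells <- cells$cell_id[cells$region %in% exclude]
    tkeep <- !(states$cell_a %in% excl_cells |
                 states$cell_b %in% excl_cells |
                 states$cell_c %in% excl_cells)
    st <- states[tkeep, , drop = FALSE]
    rt <- sqrt((st$x - center[1])^2 + (st$y - center[2])^2)
    phi <- atan2(st$y - center[2], st$x - center[1])
    qrr <- st$q_xx * cos(2 * phi) + st$q_xy * sin(2 * phi)
    bt <- round(rt / bin) * bin
    el <- do.call(rbind, lapply(split(seq_along(bt), bt), function(ix) {
      w <- st$area[ix] / sum(st$area[ix])
      m <- sum(w * qrr[ix])
      data.frame(bin_r = bt[ix[1]], Qrr = m,
                 sd_Qrr = sqrt(sum(w * (qrr[ix] - m)^2)),
                 n_tri = length(ix))
    }))
    prof <- merge(prof, el, by = "bin_r", all = TRUE)
  }
  rownames(prof) <- NULL
  prof[order(prof$bin_r), , drop = FALSE]
}

#' Grid-averaged spatial maps of area and elongation
#'
#' Divides aligned coordinates into square boxes and reports per box the
#' mean cell area and the area-weighted elongation nematic. Boxes whose
#' cell-area coverage is below `min_fill` of the box area are discarded
#' (border noise).
#'
#' @param cells cell table of one frame.
#' @param states matching triangle states; `NULL` for area-only maps.
#' @param grid box size, um.
#' @param min_fill minimum filled fraction (default 0.33).
#' @return data.frame with box centers `gx`, `gy`, `mean_area`, `n_cells`,
#'   and when states are given `Q_xx`, `Q_xy`.
#' @export
grid_average <- function(cells, states = NULL, grid = 8, min_fill = 0.33) {
  bx <- floor(cells$x / grid); by <- floor(cells$y / grid)
  key <- paste(bx, by)
  boxes <- do.call(rbind, lapply(split(seq_along(key), key), function(ix) {
    data.frame(gx = (bx[ix[1]] + 0.5) * grid, gy = (by[ix[1]] + 0.5) * grid,
               mean_area = mean(cells$area[ix]),
               fill = sum(cells$area[ix]) / grid^2, n_cells = length(ix))
  }))
  boxes <- boxes[boxes$fill >= min_fill, , drop = FALSE]
  if (!is.null(states)) {
    tx <- floor(states$x / grid); ty <- floor(states$y / grid)
    tkey <- paste(tx, ty)
    el <- do.call(rbind, lapply(split(seq_along(tkey), tkey), function(ix) {
      w <- states$area[ix] / sum(states$area[ix])
      data.frame(gx = (tx[ix[1]] + 0.5) * grid,
                 gy = (ty[ix[1]] + 0.5) * grid,
                 Q_xx = sum(w * states$q_xx[ix]),
                 Q_xy = sum(w * states$q_xy[ix]))
    }))
    boxes <- merge(boxes, el, by = c("gx", "gy"), all.x = TRUE)
  }
  rownames(boxes) <- NULL
  boxes[order(boxes$gx, boxes$gy), , drop = FALSE]
}
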