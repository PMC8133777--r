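#' Specification for synthetic wing-pouch tissues
#'
#' Defines the study conditions emulated by the generator: a roughly
#' circular pouch with an imposed radial gradient of tangential elongation
#' (Q_rr ~ 0 at r = 10 um falling to ~ -0.1 at r = 40 um), a cell-area
#' gradient (~3 um^2 centrally to ~7 um^2 peripherally), a domed height
#' field, T1 rearrangements at ~1 per cell per hour with a radial bias of
#' the new bond, and uniform divisions.
#'
#' @param pouch_radius pouch radius, um.
#' @param elong_profile function r -> target radial elongation Q_rr
#'   (dimensionless; negative = tangential). The default interpolates 0 at
#'   10 um to -0.1 at 40 um and saturates beyond.
#' @param area_profile function r -> target mean cell area, um^2 (default a
#'   linear 3 -> 7 um^2 gradient over the pouch).
#' @param t1_rate T1 rate per cell, hr^-1.
#' @param t1_radial_bias bias of the new T1 bond toward the radial axis, in
#'   [0, 1]: 0 = unbiased, 1 = deterministically the most radial candidate.
#' @param division_rate division rate per cell, hr^-1.
#' @param dome_height apex height of the domed apical surface, um.
#' @param noise positional jitter, as a fraction of the local lattice
#'   spacing.
#' @param center pouch center, um.
#' @param seed integer seed recorded in the output metadata.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(pouch_radius = 50,
                           elong_profile = default_elong_profile,
                           area_profile = default_area_profile(pouch_radius),
                           t1_rate = 1.0, t1_radial_bias = 0.6,
                           division_rate = 0.0, dome_height = 15,
                           noise = 0.05, center = c(0, 0), seed = 1L) {
  stopifnot(pouch_radius > 0, t1_rate >= 0, division_rate >= 0,
            t1_radial_bias >= 0, t1_radial_bias <= 1, dome_height >= 0,
            noise >= 0)
  rr <- seq(0, pouch_radius, length.out = 200)
  q <- elong_profile(rr); a <- area_profile(rr)
  if (any(!is.finite(q)) || any(!is.finite(a)) || any(a <= 0))
    stop("profiles must be finite (and areas positive) on [0, pouch_radius]",
         call. = FALSE)
  if (any(abs(q) >= 0.5))
    stop("|Q_rr| >= 0.5 requested: outside the small-elongation regime",
         call. = FALSE)
  structure(list(pouch_radius = pouch_radius, elong_profile = elong_profile,
                 area_profile = area_profile, t1_rate = t1_rate,
                 t1_radial_bias = t1_radial_bias,
                 division_rate = division_rate, dome_height = dome_height,
                 noise = noise, center = center, seed = as.integer(seed),
                 twist_profile = function(r) rep(0, length(r))),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param r radius, um.
#' @export
default_elong_profile <- function(r) {
  -0.1 * pmin(1, pmax(0, (r - 10) / 30))
}

#' @rdname synthetic_spec
#' @export
default_area_profile <- function(pouch_radius) {
  force(pouch_radius)
  function(r) 3 + 4 * pmin(1, r / pouch_radius)
}

#' Generate a single-frame synthetic epithelium
#'
#' Builds a polygonal tissue on concentric staggered rings. Ring spacing and
#' in-ring spacing are set locally so that cell area matches
#' `area_profile(r)` and the triangle elongation of the lattice matches
#' `elong_profile(r)`: for an equilateral-derived lattice stretched by
#' `exp(+Q)` radially and `exp(-Q)` tangentially the triangle elongation
#' nematic has radial component `Q`. The triangulation between adjacent
#' rings is constructed by an angular merge walk, so connectivity is exact
#' ground truth rather than inferred. Cell areas are assigned as one third
#' of the incident triangle areas (the triangle-method identity); the
#' outermost ring is labeled `"excluded"` as tissue border.
#'
#' Generator targets are verified by the independent morphometry module in
#' the test-suite, not by the generator's own bookkeeping.
#'
#' @param spec a [synthetic_spec()].
#' @param calibrate number of closed-loop calibration passes in which the
#'   built tissue is re-measured with the morphometry module and the
#'   residual against the target profiles is folded back into the
#'   construction (default 5; 0 disables).
#' @return an [epithelium()] with one frame (frame 0).
#' @export
generate_tissue <- function(spec, calibrate = 5L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  qf_t <- spec$elong_profile
  af_t <- spec$area_profile
  build <- function(s) withr_seed(s$seed, {
    lat <- ring_lattice(s)
    build_epithelium_from_lattice(lat, s, frame = 0L)
  })
  tis <- build(spec)
  # closed-loop calibration: the construction has small systematic biases
  # (ring-count mismatch shear, boundary pinning), so re-measure with the
  # independent morphometry and fold the residual back into the profiles
  # used for construction. Deterministic given the seed.
  for (it in seq_len(calibrate)) {
    st <- frame_triangle_states(tis)
    prof <- radial_profile(tis$cells, st, center = spec$center,
                           exclude = "excluded")
    ok <- !is.na(prof$n_tri) & prof$n_tri >= 30
    if (sum(ok) < 2) break
    dq <- stats::approxfun(prof$bin_r[ok], prof$Qrr[ok] - qf_t(prof$bin_r[ok]),
                           rule = 2)
    da <- stats::approxfun(prof$bin_r[ok],
                           prof$mean_area[ok] / af_t(prof$bin_r[ok]),
                           rule = 2)
    # residual spiral shear: counter-twist the rings. A map
    # theta -> theta + psi(r) shears by q_rt = r psi'(r) / 2, so
    # psi'(r) = -2 q_rt(r) / r undoes the measured q_rt.
    phi <- atan2(st$y - spec$center[2], st$x - spec$center[1])
    rr <- sqrt((st$x - spec$center[1])^2 + (st$y - spec$center[2])^2)
    qrt <- -st$q_xx * sin(2 * phi) + st$q_xy * cos(2 * phi)
    brt <- round(rr / 10) * 10
    mrt <- tapply(qrt * st$area, brt, sum) / tapply(st$area, brt, sum)
    rbin <- as.numeric(names(mrt))
    usebin <- rbin %in% prof$bin_r[ok]
    if (sum(usebin) >= 2) {
      rb <- rbin[usebin]; qb <- mrt[usebin]
      dpsi <- -2 * qb / pmax(rb, 5)
      psi <- cumsum(c(0, (dpsi[-1] + dpsi[-length(dpsi)]) / 2 * diff(rb)))
      addtw <- stats::approxfun(rb, psi, rule = 2)
      prev_t <- spec$twist_profile
      spec$twist_profile <- local({
        pt <- prev_t; at <- addtw
        function(r) pt(r) + at(r)
      })
    }
    prev_q <- spec$elong_profile; prev_a <- spec$area_profile
    spec$elong_profile <- local({
      pq <- prev_q; d <- dq
      function(r) pmax(-0.49, pmin(0.49, pq(r) - d(r)))
    })
    spec$area_profile <- local({
      pa <- prev_a; d <- da
      function(r) pmax(0.2, pa(r) / d(r))
    })
    tis <- build(spec)
  }
  tis$meta$spec <- spec
  tis
}

# evaluate-with-seed helper that restores RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# local equilateral spacing for target area a: area per lattice point
# d^2 sqrt(3)/2 = a
lat_spacing <- function(a) sqrt(2 * a / sqrt(3))

# Concentric-ring lattice. Returns points (id, r0, th0 ideal; x, y jittered),
# ring index, and triangles (ids) from the ring-merge walk.
ring_lattice <- function(spec) {
  af <- spec$area_profile; qf <- spec$elong_profile
  Rp <- spec$pouch_radius
  drow <- function(r) sqrt(3) / 2 * lat_spacing(af(r)) * exp(qf(r))
  sarc <- function(r) lat_spacing(af(r)) * exp(-qf(r))
  # ring radii by midpoint stepping
  radii <- c()
  r <- drow(0)
  while (r <= Rp) {
    radii <- c(radii, r)
    step <- drow(r + drow(r) / 2)
    r <- r + step
  }
  nring <- length(radii)
  pts <- list(data.frame(id = 1L, ring = 0L, r0 = 0, th0 = 0))
  nid <- 1L
  for (k in seq_len(nring)) {
    rk <- radii[k]
    nk <- max(4L, round(2 * pi * rk / sarc(rk)))
    # random ring phase: de-correlates the angular drift between ring
    # pairs that would otherwise imprint a systematic spiral shear; the
    # twist profile is the calibration's counter-rotation for what remains
    off <- stats::runif(1)
    th <- 2 * pi * (seq_len(nk) - 1 + off) / nk + spec$twist_profile(rk)
    pts[[k + 1]] <- data.frame(id = nid + seq_len(nk), ring = k,
                               r0 = rk, th0 = th)
    nid <- nid + nk
  }
  pts <- do.call(rbind, pts)
  # triangles: center fan + ring-merge strips
  # (ring-count mismatch between adjacent rings shears strip triangles; a
  # damped neighbor-centroid relaxation below irons this out — a perfect
  # anisotropic triangular lattice is a fixed point of that relaxation, so
  # the imposed elongation/area profiles survive)
  tris <- list()
  first <- pts[pts$ring == 1, ]
  n1 <- nrow(first)
  tris[[1]] <- cbind(1L, first$id, first$id[c(2:n1, 1)])
  for (k in seq_len(nring - 1)) {
    A <- pts[pts$ring == k, ]
    B <- pts[pts$ring == k + 1, ]
    tris[[k + 1]] <- merge_rings(A$id, A$th0, B$id, B$th0)
  }
  tris <- do.call(rbind, tris)
  x0 <- pts$r0 * cos(pts$th0)
  y0 <- pts$r0 * sin(pts$th0)
  rel <- relax_lattice(x0, y0, tris, fixed = pts$ring >= nring - 1)
  # jitter in the local frame, sd = noise * local spacing
  sd_r <- spec$noise * drow(pts$r0)
  sd_t <- spec$noise * sarc(pts$r0)
  jr <- stats::rnorm(nrow(pts), 0, sd_r)
  jt <- stats::rnorm(nrow(pts), 0, sd_t)
  jr[1] <- 0; jt[1] <- 0
  ct <- cos(pts$th0); stn <- sin(pts$th0)
  x <- rel$x + jr * ct - jt * stn + spec$center[1]
  y <- rel$y + jr * stn + jt * ct + spec$center[2]
  list(points = data.frame(id = pts$id, ring = pts$ring, x = x, y = y),
       triangles = tris, nring = nring)
}

# triangulate the annulus between two rings by an angular merge walk:
# advance around both rings in increasing angle; each advance on the inner
# ring emits (A_i, A_i+1, B_j), each on the outer emits (A_i, B_j, B_j+1).
# Produces exactly nA + nB planar triangles for convex rings.
merge_rings <- function(idA, thA, idB, thB) {
  nA <- length(idA); nB <- length(idB)
  # start at A point 1; B starts at the last point at or below thA[1]
  difb <- (thA[1] - thB) %% (2 * pi)
  jb <- which.min(difb)
  ordB <- ((jb + seq_len(nB) - 2) %% nB) + 1
  bId <- idB[ordB]
  bAng <- thB[ordB]
  # unwrap outer angles and anchor just below the inner start
  for (j in seq_len(nB - 1))
    if (bAng[j + 1] < bAng[j]) bAng[j + 1] <- bAng[j + 1] + 2 * pi
  if (bAng[1] > thA[1]) bAng <- bAng - 2 * pi
  aAngN <- c(thA, thA[1] + 2 * pi)
  bAngN <- c(bAng, bAng[1] + 2 * pi)
  aIdx <- function(i) idA[(i - 1) %% nA + 1]
  bIdx <- function(j) bId[(j - 1) %% nB + 1]
  tris <- matrix(0L, nA + nB, 3)
  ia <- 1L; ib <- 1L; rowi <- 0L
  while (ia <= nA || ib <= nB) {
    nexta <- if (ia <= nA) aAngN[ia + 1] else Inf
    nextb <- if (ib <= nB) bAngN[ib + 1] else Inf
    rowi <- rowi + 1L
    if (nexta <= nextb) {
      tris[rowi, ] <- c(aIdx(ia), aIdx(ia + 1), bIdx(ib))
      ia <- ia + 1L
    } else {
      tris[rowi, ] <- c(aIdx(ia), bIdx(ib), bIdx(ib + 1))
      ib <- ib + 1L
    }
  }
  tris[seq_len(rowi), , drop = FALSE]
}

build_epithelium_from_lattice <- function(lat, spec, frame = 0L) {
  tris <- lat$triangles
  p <- lat$points
  tri_df <- data.frame(frame = frame, tri_id = seq_len(nrow(tris)),
                       cell_a = tris[, 1], cell_b = tris[, 2],
                       cell_c = tris[, 3])
  bonds <- tri_edges(tris)
  bonds_df <- data.frame(frame = frame, cell_a = bonds[, 1],
                         cell_b = bonds[, 2])
  area <- cell_areas_from_triangles(p, tris)
  region <- ifelse(p$ring >= lat$nring, "excluded", "blade")
  cells <- data.frame(frame = frame, cell_id = p$id, track_id = p$id,
                      x = p$x, y = p$y, area = area, region = region)
  epithelium(cells, bonds_df, tri_df,
             meta = list(spec = spec, seed = spec$seed))
}

# damped neighbor-centroid relaxation over the bond graph; boundary
# (fixed) points do not move. ids are assumed to be 1..n row indices.
relax_lattice <- function(x, y, tris, fixed, iters = 20, w = 0.5) {
  e <- tri_edges(tris)
  src <- c(e[, 1], e[, 2]); dst <- c(e[, 2], e[, 1])
  deg <- tabulate(src, nbins = length(x))
  mov <- which(!fixed & deg > 0)
  for (it in seq_len(iters)) {
    sx <- unname(rowsum(x[dst], src, reorder = TRUE))
    sy <- unname(rowsum(y[dst], src, reorder = TRUE))
    ids <- sort(unique(src))
    mx <- x; my <- y
    mx[ids] <- sx[, 1] / deg[ids]
    my[ids] <- sy[, 1] / deg[ids]
    x[mov] <- (1 - w) * x[mov] + w * mx[mov]
    y[mov] <- (1 - w) * y[mov] + w * my[mov]
  }
  list(x = x, y = y)
}

tri_edges <- function(tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

cell_areas_from_triangles <- function(p, tris) {
  ix <- match(tris[, 1], p$id); iy <- match(tris[, 2], p$id)
  iz <- match(tris[, 3], p$id)
  a2 <- abs((p$x[iy] - p$x[ix]) * (p$y[iz] - p$y[ix]) -
              (p$y[iy] - p$y[ix]) * (p$x[iz] - p$x[ix]))
  ta <- a2 / 2
  acc <- numeric(nrow(p))
  for (col in 1:3) {
    idx <- match(tris[, col], p$id)
    tab <- tapply(ta, idx, sum)
    acc[as.integer(names(tab))] <- acc[as.integer(names(tab))] + tab
  }
  pmax(acc / 3, 1e-9)
}

#' Generate a domed height field
#'
#' A smooth radially symmetric paraboloid dome,
#' `h(r) = h0 * max(0, 1 - r^2 / R^2)`, sampled on a raster covering the
#' pouch. Deterministic given the spec.
#'
#' @param spec a [synthetic_spec()].
#' @param pixel_size raster pixel size, um (default 0.5).
#' @param pad extra margin around the pouch, um.
#' @return a [height_field()] with metadata recording the maximum slope.
#' @export
generate_height_dome <- function(spec, pixel_size = 0.5, pad = 10) {
  R <- spec$pouch_radius + pad
  n <- ceiling(2 * R / pixel_size)
  ctr <- spec$center
  xs <- ((seq_len(n)) - 0.5) * pixel_size - R + ctr[1]
  ys <- ((seq_len(n)) - 0.5) * pixel_size - R + ctr[2]
  rr2 <- outer(ys - ctr[2], xs - ctr[1],
               function(y, x) x^2 + y^2)
  h0 <- spec$dome_height
  Rp <- spec$pouch_radius
  v <- h0 * pmax(1 - rr2 / Rp^2, 0) # pmax keeps the matrix attributes
  hf <- height_field(v, pixel_size, origin = c(ctr[1] - R, ctr[2] - R))
  hf$max_slope <- 2 * h0 / Rp
  hf
}
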