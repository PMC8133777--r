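#' ESCA: stress inference from circular laser ablation
#'
#' After a circular cut of radius `r_cut`, the released inner piece and the
#' retracted outer rim relax to ellipses whose sizes and anisotropies encode
#' the pre-cut tissue stress, normalized by the elastic constants: the
#' anisotropic stress `s_tilde = sigma~/(2K)`, the area pressure
#' `p = P/K_bar`, and (at the ensemble level) the elastic-constant ratio
#' `rho = 2K/K_bar`.
#'
#' Forward model conventions (see the methods vignette): tension positive;
#' `p > 0` means compression so the freed inner piece expands. The inner
#' piece completely releases its elastic deformation: semi-axes
#' `r_eff * exp(p/2 -+ s_tilde)` with the contracted axis along the tension
#' axis. The outer rim follows the classical traction-free circular hole in
#' an infinite 2D elastic sheet (Kolosov constant `kappa = 1 + rho`),
#' rim displacement measured from the unstressed reference:
#' `u_r(theta) = r_cut * (c0 * p + c2 * s_tilde * cos 2(theta - axis))`
#' with `c0 = -(1/2 + 1/rho)` and `c2 = 2 + rho`, i.e. outer semi-axes
#' `r_cut * (1 + c0 p +- c2 s_tilde)`, major axis along the tension axis.
#'
#' @name esca
NULL

#' Effective initial radius of the inner piece
#'
#' Cells directly hit by the laser die and do not contribute to the
#' relaxation, so half a mean cell diameter is removed from the initial
#' inner radius: `r_eff = r_cut - d/2` with `d = 2 sqrt(a/pi)`.
#'
#' @param r_cut cut radius, um (default 7).
#' @param hit_cell_mean_area mean area of the hit cells, um^2.
#' @return `r_eff` in um; error if non-positive.
#' @export
effective_radius <- function(r_cut = 7, hit_cell_mean_area) {
  stopifnot(r_cut > 0, hit_cell_mean_area >= 0)
  r_eff <- r_cut - sqrt(hit_cell_mean_area / pi)
  if (r_eff <= 0)
    stop("dead-cell correction exceeds the cut radius (r_eff <= 0)",
         call. = FALSE)
  r_eff
}

#' Least-squares ellipse fit
#'
#' Direct algebraic (Fitzgibbon) least-squares conic fit constrained to an
#' ellipse, followed by geometric refinement minimizing the RMS
#' point-to-ellipse distance.
#'
#' @param points n x 2 matrix (n >= 6) of contour points, um.
#' @param refine run the geometric refinement (default TRUE).
#' @return list with `center`, `semi_major`, `semi_minor`, `angle` (radians
#'   in (-pi/2, pi/2]) and `residual` (RMS point distance, um).
#' @export
fit_ellipse <- function(points, refine = TRUE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 6)
    stop("need at least 6 points to fit an ellipse", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  mx <- mean(x); my <- mean(y); sc <- max(stats::sd(x), stats::sd(y))
  if (sc == 0) stop("degenerate point set", call. = FALSE)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("non-elliptical conic: degenerate (collinear?) point set",
         call. = FALSE))
  M <- S1 + S2 %*% Tm
  Minv_c <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(Minv_c)
  # eigenvector with 4ac - b^2 > 0
  cond <- 4 * ev$vectors[1, ] * ev$vectors[3, ] - ev$vectors[2, ]^2
  ok <- which(Re(cond) > 0 & abs(Im(cond)) < 1e-9)
  if (!length(ok))
    stop("non-elliptical conic: points do not determine an ellipse",
         call. = FALSE)
  a1 <- Re(ev$vectors[, ok[1]])
  par <- c(a1, Tm %*% a1) # A B C D E F in scaled frame
  ell <- conic_to_ellipse(par)
  # un-scale
  ell$center <- ell$center * sc + c(mx, my)
  ell$semi_major <- ell$semi_major * sc
  ell$semi_minor <- ell$semi_minor * sc
  ell$residual <- ellipse_rms(points, ell)
  if (refine) {
    obj <- function(p) {
      e <- list(center = p[1:2], semi_major = exp(p[3]),
                semi_minor = exp(p[4]), angle = p[5])
      ellipse_rms(points, e)
    }
    p0 <- c(ell$center, log(ell$semi_major), log(ell$semi_minor), ell$angle)
    op <- stats::optim(p0, obj, control = list(reltol = 1e-12,
                                               maxit = 500))
    if (op$value < ell$residual) {
      ell <- list(center = op$par[1:2], semi_major = exp(op$par[3]),
                  semi_minor = exp(op$par[4]), angle = op$par[5],
                  residual = op$value)
    }
  }
  if (ell$semi_major < ell$semi_minor) {
    tmp <- ell$semi_major; ell$semi_major <- ell$semi_minor
    ell$semi_minor <- tmp
    ell$angle <- ell$angle + pi / 2
  }
  ell$angle <- ((ell$angle + pi / 2) %% pi) - pi / 2
  if (ell$angle <= -pi / 2 + 1e-15) ell$angle <- ell$angle + pi
  ell
}

conic_to_ellipse <- function(par) {
  A <- par[1]; B <- par[2]; C <- par[3]; D <- par[4]; E <- par[5]
  Fc <- par[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("non-elliptical conic", call. = FALSE)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  th <- 0.5 * atan2(B, A - C)
  Fc2 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + Fc
  ca <- cos(th); sa <- sin(th)
  Ap <- A * ca^2 + B * ca * sa + C * sa^2
  Cp <- A * sa^2 - B * ca * sa + C * ca^2
  a2 <- -Fc2 / Ap; b2 <- -Fc2 / Cp
  if (a2 <= 0 || b2 <= 0) stop("non-elliptical conic", call. = FALSE)
  list(center = c(cx, cy), semi_major = sqrt(a2), semi_minor = sqrt(b2),
       angle = th)
}

# RMS exact point-to-ellipse distance (per-point Newton on the support
# angle)
ellipse_rms <- function(points, ell) {
  ca <- cos(ell$angle); sa <- sin(ell$angle)
  xr <- (points[, 1] - ell$center[1]) * ca +
    (points[, 2] - ell$center[2]) * sa
  yr <- -(points[, 1] - ell$center[1]) * sa +
    (points[, 2] - ell$center[2]) * ca
  a <- ell$semi_major; b <- ell$semi_minor
  d2 <- vapply(seq_along(xr), function(i) {
    px <- abs(xr[i]); py <- abs(yr[i])
    t <- atan2(py * a, px * b)
    for (it in 1:30) {
      ct <- cos(t); st <- sin(t)
      ex <- a * ct; ey <- b * st
      rx <- ex - px; ry <- ey - py
      g <- -a * st * rx + b * ct * ry
      h <- -a * ct * rx + a^2 * st^2 - b * st * ry + b^2 * ct^2
      step <- g / h
      t <- t - step
      if (abs(step) < 1e-14) break
    }
    (a * cos(t) - px)^2 + (b * sin(t) - py)^2
  }, numeric(1))
  sqrt(mean(d2))
}

#' Forward model of a circular cut
#'
#' Maps normalized stresses to the relaxed inner and outer contours (see
#' [esca]).
#'
#' @param p normalized area pressure `P/K_bar` (|p| < 1; > 0 compression).
#' @param s_tilde normalized anisotropic stress magnitude `sigma~/(2K)`
#'   (|s_tilde| < 0.5), tension positive along `axis`.
#' @param axis tension axis, radians.
#' @param rho elastic-constant ratio `2K/K_bar` (> 0).
#' @param r_eff initial radius of the inner piece, um.
#' @param r_cut cut radius, um.
#' @return list of two ellipses `inner`, `outer` (center at origin).
#' @export
forward_cut <- function(p, s_tilde, axis, rho, r_eff, r_cut = 7) {
  if (abs(s_tilde) >= 0.5 || abs(p) >= 1)
    stop("stress parameters outside the admissible regime", call. = FALSE)
  stopifnot(rho > 0, r_eff > 0, r_eff <= r_cut)
  if (s_tilde < 0) { # fold sign into the axis
    s_tilde <- -s_tilde; axis <- axis + pi / 2
  }
  axis <- ((axis + pi / 2) %% pi) - pi / 2
  inner <- list(center = c(0, 0),
                semi_major = r_eff * exp(p / 2 + s_tilde),
                semi_minor = r_eff * exp(p / 2 - s_tilde),
                angle = norm_angle(axis + pi / 2))
  c0 <- -(0.5 + 1 / rho)
  c2 <- 2 + rho
  outer <- list(center = c(0, 0),
                semi_major = r_cut * (1 + c0 * p + c2 * s_tilde),
                semi_minor = r_cut * (1 + c0 * p - c2 * s_tilde),
                angle = norm_angle(axis))
  if (outer$semi_minor <= 0)
    stop("parameters outside the linear-response regime (outer contour ",
         "collapses)", call. = FALSE)
  list(inner = inner, outer = outer)
}

norm_angle <- function(a) {
  a <- ((a + pi / 2) %% pi) - pi / 2
  if (a <= -pi / 2 + 1e-15) a + pi else a
}

# size/anisotropy observables of an ellipse relative to a reference radius
ellipse_nematic <- function(ell) {
  e <- ((ell$semi_major - ell$semi_minor) / 2)
  c(e * cos(2 * ell$angle), e * sin(2 * ell$angle))
}

#' Invert one cut at fixed elastic-constant ratio
#'
#' Linear least squares of the forward model against the observed inner and
#' outer ellipses over `(p, s_tilde, axis)` with `rho` fixed. Inner
#' observables enter on log scale (exact release), outer on linear scale
#' (linear elastic response); both are weighted equally.
#'
#' @param inner,outer ellipses (lists with `semi_major`, `semi_minor`,
#'   `angle`), e.g. from [fit_ellipse()].
#' @param r_eff,r_cut radii as in [forward_cut()].
#' @param rho fixed elastic-constant ratio.
#' @return list: `p`, `s_tilde` (>= 0), `axis` (0 by convention for an
#'   isotropic cut), `rho`, and `residual` (RMS misfit of the six
#'   observables).
#' @export
invert_cut <- function(inner, outer, r_eff, r_cut = 7, rho) {
  stopifnot(rho > 0)
  # observables: inner log-size, minus inner log-anisotropy nematic (the
  # inner piece contracts along the tension axis), outer mean-size change,
  # outer anisotropy nematic
  ei <- 0.5 * log(inner$semi_major / inner$semi_minor)
  y <- c(log(sqrt(inner$semi_major * inner$semi_minor) / r_eff),
         -ei * c(cos(2 * inner$angle), sin(2 * inner$angle)),
         (outer$semi_major + outer$semi_minor) / (2 * r_cut) - 1,
         ellipse_nematic(outer) / r_cut)
  c0 <- -(0.5 + 1 / rho); c2 <- 2 + rho
  # model: y = M %*% c(p/2... ) in unknowns (p, sxx, sxy)
  M <- rbind(c(0.5, 0, 0),
             c(0, 1, 0),
             c(0, 0, 1),
             c(c0, 0, 0),
             c(0, c2, 0),
             c(0, 0, c2))
  fit <- stats::lsfit(M, y, intercept = FALSE)
  co <- unname(fit$coefficients)
  res <- sqrt(mean(fit$residuals^2))
  s_mag <- sqrt(co[2]^2 + co[3]^2)
  axis <- if (s_mag < 1e-12) 0 else 0.5 * atan2(co[3], co[2])
  list(p = co[1], s_tilde = s_mag, axis = norm_angle(axis), rho = rho,
       residual = res)
}

#' Classify a cut by its position in the pouch
#'
#' Distances measured on fixed tissue shrink by ~15% and are rescaled by
#' `1/(1 - shrinkage)`. Cuts within `ap_margin` of the AP boundary are
#' excluded; otherwise a cut is `DV_band` if it extends no more than
#' `tolerance` outside the `band_width` stripe around the DV boundary,
#' `outside` if it extends no more than `tolerance` into the stripe, and
#' `border_excluded` when it straddles.
#'
#' @param cut_center `(x, y)` um relative to the AP/DV boundaries (ventral/
#'   posterior negative), as measured on the fixed tissue.
#' @param r_cut cut radius, um.
#' @param band_width DV stripe width, um (default 22).
#' @param tolerance allowed protrusion, um (default 1.4 = 20% of 7 um).
#' @param ap_margin AP-boundary exclusion margin, um (default 7).
#' @param shrinkage fixation shrinkage fraction (default 0.15); set 0 for
#'   live measurements.
#' @return one of `"DV_band"`, `"outside"`, `"border_excluded"`,
#'   `"AP_excluded"`.
#' @export
classify_cut_region <- function(cut_center, r_cut = 7, band_width = 22,
                                tolerance = 1.4, ap_margin = 7,
                                shrinkage = 0.15) {
  xy <- as.numeric(cut_center) / (1 - shrinkage)
  if (abs(xy[1]) < ap_margin) return("AP_excluded")
  half <- band_width / 2
  hi <- abs(xy[2]) + r_cut # outermost extent of the cut
  lo <- abs(xy[2]) - r_cut # innermost extent
  if (hi <= half + tolerance) return("DV_band")
  if (lo >= half - tolerance) return("outside")
  "border_excluded"
}

#' Ensemble estimation of the elastic-constant ratio
#'
#' Inverts every cut of a region over a grid of fixed `rho = 2K/K_bar`
#' values; the estimate is the grid value minimizing the summed per-cut
#' residuals after excluding cuts whose best residual exceeds
#' `residual_threshold` (default 3x the ensemble median; eliminates cuts
#' with non-elliptical outlines). Uncertainty by bootstrap: subsets of
#' `subset` cuts, `reps` times; the SD of the per-subset optima is
#' reported.
#'
#' @param cuts list of cut records, each with `inner`, `outer`, `r_eff`,
#'   `r_cut` (e.g. from [generate_ablation_set()] after ellipse fitting).
#' @param rho_grid candidate ratios (default `seq(1, 8, by = 0.1)`).
#' @param residual_threshold absolute threshold; `NULL` for the 3x-median
#'   default.
#' @param subset,reps bootstrap design (defaults 7 and 100).
#' @param seed integer seed for the bootstrap resampling.
#' @return list: `rho` (optimum), `sd` (bootstrap SD), `residuals` (grid
#'   curve), `estimates` (per-cut stresses at the optimum), `excluded`
#'   (indices dropped by the residual threshold).
#' @export
ensemble_ratio_fit <- function(cuts, rho_grid = seq(1, 8, by = 0.1),
                               residual_threshold = NULL, subset = 7,
                               reps = 100, seed = 1L) {
  if (length(cuts) < 2)
    stop("need at least 2 cuts in the region", call. = FALSE)
  res_mat <- vapply(cuts, function(cut) {
    vapply(rho_grid, function(r)
      invert_cut(cut$inner, cut$outer, cut$r_eff, cut$r_cut, r)$residual,
      numeric(1))
  }, numeric(length(rho_grid)))
  best_per_cut <- apply(res_mat, 2, min)
  if (is.null(residual_threshold))
    residual_threshold <- 3 * stats::median(best_per_cut) + 1e-12
  excluded <- which(best_per_cut > residual_threshold)
  keep <- setdiff(seq_along(cuts), excluded)
  if (!length(keep))
    stop("all cuts excluded by the residual threshold", call. = FALSE)
  total <- rowSums(res_mat[, keep, drop = FALSE])
  rho_star <- rho_grid[which.min(total)]
  ests <- lapply(keep, function(i)
    invert_cut(cuts[[i]]$inner, cuts[[i]]$outer, cuts[[i]]$r_eff,
               cuts[[i]]$r_cut, rho_star))
  boots <- withr_seed(seed, {
    vapply(seq_len(reps), function(b) {
      ix <- sample(keep, min(subset, length(keep)))
      rho_grid[which.min(rowSums(res_mat[, ix, drop = FALSE]))]
    }, numeric(1))
  })
  list(rho = rho_star, sd = stats::sd(boots),
       residuals = data.frame(rho = rho_grid, residual = total),
       estimates = ests, excluded = excluded,
       residual_threshold = residual_threshold)
}

#' Area pressure versus distance to the center
#'
#' @param cuts list of cut records with `cut_center`.
#' @param estimates per-cut stress estimates (matching order) with `p`.
#' @param center tissue center, um.
#' @return list with `table` (data.frame `r`, `p`) and `correlation`
#'   (Pearson; `NA` with a flag when `p` is constant).
#' @export
pressure_vs_radius <- function(cuts, estimates, center = c(0, 0)) {
  if (length(cuts) < 3)
    stop("need at least 3 cuts with estimates", call. = FALSE)
  r <- vapply(cuts, function(cut)
    sqrt(sum((as.numeric(cut$cut_center) - center)^2)), numeric(1))
  p <- vapply(estimates, `[[`, numeric(1), "p")
  if (stats::sd(p) < 1e-14)
    return(list(table = data.frame(r = r, p = p), correlation = NA_real_,
                degenerate = TRUE))
  list(table = data.frame(r = r, p = p),
       correlation = stats::cor(r, p), degenerate = FALSE)
}
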