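#' Generate synthetic circular-ablation records
#'
#' Applies the ESCA forward model ([forward_cut()]) at sampled cut
#' positions under a prescribed stress field and emits noisy contour point
#' clouds for the relaxed inner and outer outlines, with the ground truth
#' stored per cut. Used to exercise the whole inversion chain (ellipse
#' fitting, per-cut inversion, ensemble ratio estimation) against known
#' truth.
#'
#' @param stress_field function `r -> list(p, s_tilde, axis)` giving the
#'   normalized stresses at distance `r` from the center; `axis = NA` means
#'   the local radial axis (tension radial for `s_tilde > 0`).
#' @param rho true elastic-constant ratio `2K/K_bar`.
#' @param n_cuts number of cuts.
#' @param positions optional n x 2 matrix of cut centers (um); default:
#'   uniform angles, radii uniform in `[10, 45]` um.
#' @param r_cut cut radius, um (default 7).
#' @param hit_area mean area of cells hit by the laser, um^2 (sets
#'   `r_eff`; default 5).
#' @param noise isotropic contour-point noise SD, um.
#' @param n_points points sampled per contour (default 60).
#' @param seed integer seed.
#' @return list of cut records: `cut_center`, `r_cut`, `r_eff`,
#'   `inner_points`, `outer_points` (matrices, absolute um), `truth`
#'   (list `p`, `s_tilde`, `axis`).
#' @export
generate_ablation_set <- function(stress_field, rho, n_cuts,
                                  positions = NULL, r_cut = 7,
                                  hit_area = 5, noise = 0.05,
                                  n_points = 60, seed = 1L) {
  stopifnot(rho > 0, n_cuts >= 1)
  withr_seed(seed, {
    if (is.null(positions)) {
      rr <- stats::runif(n_cuts, 10, 45)
      th <- stats::runif(n_cuts, 0, 2 * pi)
      positions <- cbind(rr * cos(th), rr * sin(th))
    }
    r_eff <- effective_radius(r_cut, hit_area)
    lapply(seq_len(n_cuts), function(i) {
      ctr <- positions[i, ]
      r <- sqrt(sum(ctr^2))
      sf <- stress_field(r)
      axis <- if (is.na(sf$axis)) atan2(ctr[2], ctr[1]) else sf$axis
      if (abs(sf$s_tilde) >= 0.5)
        stop("|s_tilde| >= 0.5: outside the forward-model regime",
             call. = FALSE)
      fw <- forward_cut(sf$p, sf$s_tilde, axis, rho, r_eff, r_cut)
      list(cut_center = ctr, r_cut = r_cut, r_eff = r_eff,
           inner_points = sample_ellipse(fw$inner, n_points, noise, ctr),
           outer_points = sample_ellipse(fw$outer, n_points, noise, ctr),
           truth = list(p = sf$p, s_tilde = sf$s_tilde, axis = axis,
                        rho = rho))
    })
  })
}

sample_ellipse <- function(ell, n, noise, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ca <- cos(ell$angle); sa <- sin(ell$angle)
  ex <- ell$semi_major * cos(t); ey <- ell$semi_minor * sin(t)
  x <- ex * ca - ey * sa + ell$center[1] + center[1]
  y <- ex * sa + ey * ca + ell$center[2] + center[2]
  cbind(x = x + stats::rnorm(n, 0, noise),
        y = y + stats::rnorm(n, 0, noise))
}

#' Fit ellipses to the contours of generated cuts
#'
#' Convenience wrapper running [fit_ellipse()] on the stored inner/outer
#' point clouds (centered on the cut) so the records can be fed to
#' [invert_cut()] / [ensemble_ratio_fit()].
#'
#' @param cuts output of [generate_ablation_set()] (or records with the
#'   same fields).
#' @return the records with `inner` and `outer` ellipse fits added.
#' @export
fit_cut_contours <- function(cuts) {
  lapply(cuts, function(cut) {
    ctr <- cut$cut_center
    cut$inner <- fit_ellipse(sweep(cut$inner_points, 2, ctr))
    cut$outer <- fit_ellipse(sweep(cut$outer_points, 2, ctr))
    cut
  })
}
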