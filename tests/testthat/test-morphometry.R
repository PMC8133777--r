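equilateral <- function(area = 1, rot = 0, shift = c(0, 0)) {
  L <- sqrt(4 * area / sqrt(3))
  v <- rbind(c(0, L / sqrt(3)),
             c(-L / 2, -L / (2 * sqrt(3))),
             c(L / 2, -L / (2 * sqrt(3))))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  sweep(v %*% t(R), 2, shift, `+`)
}

test_that("triangle state decomposes identity, pure stretch and rotations", {
  ts <- triangle_state(equilateral(2), ref_area = 2)
  expect_equal(ts$area_ratio, 1, tolerance = 1e-10)
  expect_lt(nematic_norm(ts$elong), 1e-10)
  # reference triangle mapped by diag(e^0.3, e^-0.3)
  v <- equilateral(1) %*% diag(c(exp(0.3), exp(-0.3)))
  ts2 <- triangle_state(v, ref_area = 1)
  expect_equal(unname(ts2$elong), c(0.3, 0), tolerance = 1e-10)
  expect_equal(ts2$area_ratio, 1, tolerance = 1e-10)
  # recomposition reproduces s
  E <- epimech:::nematic_expm(ts2$elong[1], ts2$elong[2])
  s_re <- sqrt(ts2$area_ratio) * E %*% epimech:::rot2(ts2$theta)
  expect_equal(s_re, ts2$s, tolerance = 1e-10)
})

test_that("triangle elongation is nematically covariant under rotation", {
  set.seed(5)
  for (i in 1:10) {
    v <- matrix(rnorm(6, sd = 2), 3, 2)
    if (abs(det(cbind(v[2, ] - v[1, ], v[3, ] - v[1, ]))) < 0.1) next
    q0 <- triangle_state(v, 1)$elong
    th <- runif(1, 0, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    q1 <- triangle_state(v %*% t(R), 1)$elong
    expect_equal(unname(q1), unname(nematic_rotate(q0, th)),
                 tolerance = 1e-8)
  }
})

test_that("collinear vertices raise a degenerate-triangle error", {
  expect_error(triangle_state(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("patch elongation is the area-weighted mean and is linear", {
  st <- data.frame(q_xx = c(0.2, 0), q_xy = c(0, 0), area = c(3, 1))
  expect_equal(unname(patch_elongation(st)), c(0.15, 0), tolerance = 1e-12)
  # opposite elongations of equal area cancel
  st2 <- data.frame(q_xx = c(0.1, -0.1), q_xy = c(0.05, -0.05),
                    area = c(2, 2))
  expect_lt(nematic_norm(patch_elongation(st2)), 1e-14)
  # union equals area-weighted combination of sub-patches
  set.seed(2)
  st3 <- data.frame(q_xx = rnorm(20, sd = 0.1), q_xy = rnorm(20, sd = 0.1),
                    area = runif(20, 1, 5))
  whole <- patch_elongation(st3)
  pa <- patch_elongation(st3[1:8, ]); pb <- patch_elongation(st3[9:20, ])
  wa <- sum(st3$area[1:8]); wb <- sum(st3$area[9:20])
  expect_equal(unname(whole), unname((wa * pa + wb * pb) / (wa + wb)),
               tolerance = 1e-12)
  expect_error(patch_elongation(st3[0, ]), "empty patch")
})

test_that("height gradient recovers constants, planes and domes", {
  flat <- height_field(matrix(3, 40, 40), pixel_size = 1)
  g <- height_gradient(flat, sigma = 2)
  gv <- eval_gradient(g, c(10, 25), c(12, 30))
  expect_lt(max(abs(gv)), 1e-12)
  # plane h = x (column index)
  plane <- height_field(outer(rep(1, 60), seq(0.5, 59.5)), pixel_size = 1)
  gp <- height_gradient(plane, sigma = 2)
  gvp <- eval_gradient(gp, seq(20, 40, 5), rep(30, 5))
  expect_equal(unname(gvp[, 1]), rep(1, 5), tolerance = 1e-8)
  expect_lt(max(abs(gvp[, 2])), 1e-8)
  # paraboloid dome: grad h = -2 h0 / R^2 * (x - xc, y - yc) inside
  spec <- synthetic_spec(pouch_radius = 30, dome_height = 10, seed = 1)
  dome <- generate_height_dome(spec, pixel_size = 0.5)
  gd <- height_gradient(dome, sigma = 2)
  xs <- c(5, -8, 12); ys <- c(-3, 6, 4)
  gvd <- eval_gradient(gd, xs, ys)
  expect_equal(unname(gvd[, 1]), -2 * 10 / 30^2 * xs, tolerance = 0.02)
  expect_equal(unname(gvd[, 2]), -2 * 10 / 30^2 * ys, tolerance = 0.02)
  expect_error(height_gradient(height_field(matrix(0, 5, 5), 1), sigma = 2),
               "too small")
})

test_that("deprojection is the identity on flat fields and exact on planes", {
  tis <- small_flat_tissue()
  st <- frame_triangle_states(tis)
  flat <- deproject(st, matrix(0, nrow(st), 2))
  expect_equal(flat$q_xx, st$q_xx, tolerance = 1e-12)
  expect_equal(flat$area, st$area, tolerance = 1e-12)
  # plane h = x: a circle maps to an ellipse with ratio sqrt(2) along x;
  # areas scale by sqrt(2)
  grad <- matrix(rep(c(1, 0), each = nrow(st)), ncol = 2)
  dep <- deproject(st, grad)
  expect_equal(dep$area, st$area * sqrt(2), tolerance = 1e-12)
})

test_that("projection of shapes on a tilted plane is undone exactly", {
  # place triangles on the 3D plane z = x tan(phi); orthographic projection
  # onto xy compresses x by cos(phi) -- deprojection must recover the
  # in-plane shapes
  set.seed(7)
  phi <- 35 * pi / 180
  for (i in 1:10) {
    v3 <- matrix(rnorm(6, sd = 3), 3, 2) # in-plane coordinates (u, y)
    if (abs(det(cbind(v3[2, ] - v3[1, ], v3[3, ] - v3[1, ]))) < 0.5) next
    truth <- triangle_state(v3, 1)
    proj <- v3 %*% diag(c(cos(phi), 1)) # u -> x = u cos(phi)
    obs <- triangle_state(proj, 1)
    st <- data.frame(tri_id = 1, cell_a = 1, cell_b = 2, cell_c = 3,
                     x = mean(proj[, 1]), y = mean(proj[, 2]),
                     area = obs$area, area_ratio = obs$area_ratio,
                     q_xx = obs$elong[1], q_xy = obs$elong[2],
                     theta = obs$theta)
    dep <- deproject(st, matrix(c(tan(phi), 0), 1, 2))
    expect_equal(dep$q_xx, unname(truth$elong[1]), tolerance = 1e-6)
    expect_equal(dep$q_xy, unname(truth$elong[2]), tolerance = 1e-6)
    expect_equal(dep$area, unname(truth$area), tolerance = 1e-6)
  }
})

# impose an exact tangential elongation field on the triangle positions
exact_tangential <- function(st, center) {
  r <- sqrt((st$x - center[1])^2 + (st$y - center[2])^2)
  phi <- atan2(st$y - center[2], st$x - center[1])
  mag <- -default_elong_profile(r) # tangential, |Q| from the profile
  st$q_xx <- -mag * cos(2 * phi)
  st$q_xy <- -mag * sin(2 * phi)
  st
}

test_that("center finding recovers an exact pattern center within one scan
           step", {
  tis <- generate_tissue(synthetic_spec(pouch_radius = 35,
                                        center = c(12, 0), seed = 13))
  st <- exact_tangential(frame_triangle_states(tis), c(12, 0))
  cen <- find_center(st, scan = seq(-5, 25, by = 1))
  expect_lte(abs(cen$xc - 12), 1)
  expect_false(cen$degenerate)
})

test_that("center finding on measured elongation lands near the center and
           degenerates gracefully", {
  tis <- paper_like_tissue()
  st <- frame_triangle_states(tis)
  cen <- find_center(st, scan = seq(-20, 20, 1))
  # the signed well is shallow; measured lattice elongation localizes the
  # center to a few micrometres
  expect_lte(abs(cen$xc), 6)
  # uniform elongation: F carries no center information
  stu <- st
  stu$q_xx <- 0.1; stu$q_xy <- 0.1
  cenu <- find_center(stu, scan = seq(-10, 10, 5))
  expect_true(cenu$degenerate)
  expect_error(find_center(st[st$y > 0, ]), "both sides")
})

test_that("DV-band filtering follows the 22-um stripe rule", {
  cells <- data.frame(y = c(5, -30, 10.9, 11.1), region = "blade")
  lab <- filter_dv_band(cells, band_width = 22)
  expect_equal(lab$region, c("DV_band", "blade", "DV_band", "blade"))
  none <- filter_dv_band(cells, band_width = 0)
  expect_true(all(none$region == "blade"))
})

test_that("radial profiles are flat for isotropic tissue and recover the
           imposed gradient", {
  flat <- small_flat_tissue()
  pf <- radial_profile(flat$cells, frame_triangle_states(flat),
                       exclude = "excluded")
  expect_true(all(abs(pf$Qrr) < 0.015))
  tis <- paper_like_tissue()
  prof <- radial_profile(tis$cells, frame_triangle_states(tis))
  tgt <- default_elong_profile(prof$bin_r)
  inner <- prof$bin_r <= 40
  expect_true(all(abs(prof$Qrr[inner] - tgt[inner]) < 0.01))
  # areas track the 3..7 um^2 gradient
  atgt <- default_area_profile(50)(prof$bin_r)
  expect_true(all(abs(prof$mean_area[inner] / atgt[inner] - 1) < 0.1))
})

test_that("rotating a tangential pattern to radial flips the sign of Qrr", {
  tis <- paper_like_tissue()
  st <- frame_triangle_states(tis)
  st_rot <- st
  # rotate each triangle's elongation by 90 degrees: tangential <-> radial
  rot <- nematic_rotate(cbind(st$q_xx, st$q_xy), pi / 2)
  st_rot$q_xx <- rot[, 1]; st_rot$q_xy <- rot[, 2]
  p1 <- radial_profile(tis$cells, st)
  p2 <- radial_profile(tis$cells, st_rot)
  expect_equal(p2$Qrr, -p1$Qrr, tolerance = 1e-10)
})

test_that("grid averaging drops under-filled boxes and keeps the pattern", {
  tis <- paper_like_tissue()
  st <- frame_triangle_states(tis)
  cl <- tis$cells[tis$cells$region != "excluded", ]
  g <- grid_average(cl, st, grid = 8)
  expect_true(all(g$fill >= 0.33))
  # boxes fully outside the pouch are absent
  expect_true(all(sqrt(g$gx^2 + g$gy^2) < 50 + 8 * sqrt(2)))
  # the imposed pattern: outer boxes tangential (Q_rr < 0)
  phi <- atan2(g$gy, g$gx)
  qrr <- g$Q_xx * cos(2 * phi) + g$Q_xy * sin(2 * phi)
  far <- sqrt(g$gx^2 + g$gy^2) > 35 & is.finite(qrr)
  expect_gt(mean(qrr[far] < 0), 0.9)
})
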