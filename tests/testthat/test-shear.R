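# an 8-cell fixture with one interior quad for scripting exact T1 events.
# Cells 1-2 are the bonded pair whose junction is shrinking: at frame 0
# the opposite pair 3-4 has already approached (T1 caught mid-flight), so
# the triangles on edge 1-2 are flattened along x. The flip rebonds 3-4
# and the quartet relaxes; the new junction axis is x (perpendicular to
# the 3-4 centroid line).
quad_fixture <- function(flip = FALSE, relax = TRUE) {
  pts <- rbind(c(-0.6, 0), c(0.6, 0), c(0, 0.55), c(0, -0.55),
               c(-2.2, 1.4), c(2.2, 1.4), c(-2.2, -1.4), c(2.2, -1.4))
  cells <- data.frame(frame = 0L, cell_id = 1:8, track_id = 1:8,
                      x = pts[, 1], y = pts[, 2], area = 1,
                      region = "blade")
  tris0 <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 5), c(2, 3, 6),
                 c(1, 4, 7), c(2, 4, 8))
  tris1 <- tris0
  pts1 <- pts
  if (flip) {
    tris1[1, ] <- c(3, 4, 1)
    tris1[2, ] <- c(3, 4, 2)
    if (relax) { # post-exchange relaxed quartet
      pts1[1, ] <- c(-0.78, 0)
      pts1[2, ] <- c(0.78, 0)
      pts1[3, ] <- c(0, 0.5)
      pts1[4, ] <- c(0, -0.5)
    }
  }
  mk <- function(frame, p, tr) {
    cl <- cells
    cl$frame <- frame; cl$x <- p[, 1]; cl$y <- p[, 2]
    list(cells = cl,
         tris = data.frame(frame = frame, tri_id = seq_len(nrow(tr)),
                           cell_a = tr[, 1], cell_b = tr[, 2],
                           cell_c = tr[, 3]))
  }
  f0 <- mk(0L, pts, tris0); f1 <- mk(1L, pts1, tris1)
  bonds <- function(frame, tr) {
    e <- epimech:::tri_edges(as.matrix(tr[, c("cell_a", "cell_b", "cell_c")]))
    data.frame(frame = frame, cell_a = e[, 1], cell_b = e[, 2])
  }
  epithelium(rbind(f0$cells, f1$cells),
             rbind(bonds(0L, f0$tris), bonds(1L, f1$tris)),
             rbind(f0$tris, f1$tris))
}

test_that("a static tissue matches all triangles with no events", {
  tis <- quad_fixture(flip = FALSE)
  mt <- match_triangles(tis, 0)
  expect_equal(nrow(mt$matched), 6)
  expect_equal(nrow(mt$destroyed), 0)
  expect_equal(nrow(mt$created), 0)
})

test_that("a scripted T1 labels exactly the flipped-edge triangles", {
  tis <- quad_fixture(flip = TRUE)
  mt <- match_triangles(tis, 0)
  expect_equal(nrow(mt$destroyed), 2)
  expect_equal(nrow(mt$created), 2)
  expect_true(all(mt$destroyed$fate == "T1"))
  expect_true(all(mt$created$fate == "T1"))
  expect_equal(nrow(mt$matched), 4)
})

test_that("a scripted division labels the daughters' triangles as division", {
  tis <- quad_fixture(flip = FALSE)
  # divide cell 3 into 9, 10 in frame 1
  cl <- tis$cells
  f1 <- cl$frame == 1
  par_row <- which(f1 & cl$cell_id == 3)
  d <- cl[par_row, ]
  cl <- cl[-par_row, ]
  d1 <- d; d1$cell_id <- 9L; d1$track_id <- 3L; d1$y <- d$y + 0.2
  d2 <- d; d2$cell_id <- 10L; d2$track_id <- 3L; d2$y <- d$y - 0.2
  cl <- rbind(cl, d1, d2)
  tr <- tis$triangles
  # triangles touching 3 in frame 1 get rewired to a daughter; new twin
  # triangle closes the fan
  sel <- tr$frame == 1 & (tr$cell_a == 3 | tr$cell_b == 3 | tr$cell_c == 3)
  tr[tr$frame == 1 & tr$cell_a == 1 & tr$cell_b == 2 & tr$cell_c == 3,
     "cell_c"] <- 10L
  tr[tr$frame == 1 & tr$cell_a == 1 & tr$cell_b == 3, "cell_b"] <- 9L
  tr[tr$frame == 1 & tr$cell_a == 2 & tr$cell_b == 3, "cell_b"] <- 9L
  tr <- rbind(tr, data.frame(frame = 1L, tri_id = 7:8,
                             cell_a = c(9L, 9L), cell_b = c(10L, 10L),
                             cell_c = c(1L, 2L)))
  lin <- data.frame(parent = 3L, child = c(9L, 10L), frame = 1L)
  tis2 <- epithelium(cl, tis$bonds, tr, lineage = lin)
  mt <- match_triangles(tis2, 0)
  expect_true(all(mt$created$fate == "division"))
  expect_gte(nrow(mt$created), 4)
  expect_true(all(mt$destroyed$fate == "division"))
})

test_that("an extrusion labels the vanished cell's triangles and wins
           priority", {
  tis <- quad_fixture(flip = FALSE)
  cl <- tis$cells
  tr <- tis$triangles
  keep <- !(cl$frame == 1 & cl$cell_id == 3)
  trk <- !(tr$frame == 1 & (tr$cell_a == 3 | tr$cell_b == 3 |
                              tr$cell_c == 3))
  tis3 <- epithelium(cl[keep, ], tis$bonds, tr[trk, ])
  mt <- match_triangles(tis3, 0)
  expect_true(all(mt$destroyed$fate == "extrusion"))
  expect_equal(nrow(mt$destroyed), 3)
})

test_that("event-free affine deformation gives total = log strain and no
           event terms", {
  base <- small_flat_tissue()
  k <- 0.07
  tl <- two_frame_tissue(base, function(p)
    cbind(p[, 1] * exp(k), p[, 2] * exp(-k)))
  d <- decompose_shear(tl, 0, projection = "tensor")
  expect_equal(d$total_xx, k, tolerance = 1e-8)
  expect_equal(d$total_xy, 0, tolerance = 1e-8)
  expect_equal(d$t1_xx, 0); expect_equal(d$cd_xx, 0)
  expect_equal(d$ex_xx, 0)
  expect_equal(d$dQ_xx, k, tolerance = 0.02)
  expect_lt(abs(d$corr_xx), 0.002)
})

test_that("rigid rotation leaves every co-rotational contribution at zero", {
  base <- small_flat_tissue()
  th <- 0.3
  tl <- two_frame_tissue(base, function(p)
    cbind(p[, 1] * cos(th) - p[, 2] * sin(th),
          p[, 1] * sin(th) + p[, 2] * cos(th)))
  d <- decompose_shear(tl, 0, projection = "tensor")
  vals <- as.numeric(d[, grep("_(xx|xy)$", names(d))])
  expect_lt(max(abs(vals)), 1e-10)
  expect_equal(d$psi, th, tolerance = 1e-10)
})

test_that("a scripted T1 yields a new-junction-oriented t1 term", {
  tis <- quad_fixture(flip = TRUE)
  d <- decompose_shear(tis, 0, projection = "tensor")
  # the new junction axis is x: t1 oriented along x (positive xx)
  expect_gt(d$t1_xx, 0.01)
  expect_lt(abs(d$t1_xy), 0.2 * d$t1_xx)
  # exact closure
  expect_equal(d$total_xx,
               d$dQ_xx + d$t1_xx + d$cd_xx + d$ex_xx + d$corr_xx,
               tolerance = 1e-12)
})

test_that("with frozen positions the T1 jump moves entirely between dQ and
           t1 with zero total", {
  tis <- quad_fixture(flip = TRUE, relax = FALSE)
  d <- decompose_shear(tis, 0, projection = "tensor")
  expect_lt(abs(d$total_xx) + abs(d$total_xy), 1e-12)
  expect_equal(d$t1_xx, -d$dQ_xx, tolerance = 1e-12)
  expect_equal(d$t1_xy, -d$dQ_xy, tolerance = 1e-12)
  expect_lt(abs(d$corr_xx), 1e-12)
})

test_that("closure holds exactly on a busy synthetic movie", {
  spec <- synthetic_spec(pouch_radius = 22, t1_rate = 1,
                         division_rate = 0.05, seed = 3)
  tl <- fixture("busy_movie", function()
    generate_timelapse(spec, duration = 1, dt = 0.05))
  ser <- shear_series(tl, projection = "tensor")
  for (comp in c("xx", "xy")) {
    res <- ser[[paste0("total_", comp)]] -
      (ser[[paste0("dQ_", comp)]] + ser[[paste0("t1_", comp)]] +
         ser[[paste0("cd_", comp)]] + ser[[paste0("ex_", comp)]] +
         ser[[paste0("corr_", comp)]])
    expect_lt(max(abs(res)), 1e-12)
  }
})

test_that("T1 triangle counts agree with the generator event log exactly", {
  spec <- synthetic_spec(pouch_radius = 22, t1_rate = 1,
                         division_rate = 0.05, seed = 3)
  tl <- fixture("busy_movie", function()
    generate_timelapse(spec, duration = 1, dt = 0.05))
  for (t in tissue_frames(tl)[1:8]) {
    mt <- match_triangles(tl, t)
    n_t1_tri <- sum(mt$destroyed$fate == "T1")
    n_log <- sum(tl$events$type == "T1" & tl$events$frame == t + 1)
    expect_equal(n_t1_tri, 2 * n_log)
  }
})

test_that("isotropic decomposition closes and matches the three oracles", {
  base <- small_flat_tissue()
  # static
  tls <- two_frame_tissue(base, identity)
  ds <- decompose_isotropic(tls, 0)
  expect_equal(as.numeric(ds[, 3:6]), rep(0, 4), tolerance = 1e-12)
  # uniform doubling of areas
  tld <- two_frame_tissue(base, function(p) p * sqrt(2))
  dd <- decompose_isotropic(tld, 0)
  expect_equal(dd$total, log(2), tolerance = 1e-10)
  expect_equal(dd$cell_area_change, log(2), tolerance = 1e-10)
  expect_equal(dd$division, 0, tolerance = 1e-10)
  # one extrusion, areas fixed
  cl <- base$cells; tr <- base$triangles; bo <- base$bonds
  vic <- cl$cell_id[cl$region == "blade"][15]
  cl2 <- cl[cl$cell_id != vic, ]; cl2$frame <- 1L
  tr2 <- tr[!(tr$cell_a == vic | tr$cell_b == vic | tr$cell_c == vic), ]
  tr2$frame <- 1L
  bo2 <- bo[!(bo$cell_a == vic | bo$cell_b == vic), ]; bo2$frame <- 1L
  tle <- epithelium(rbind(cl, cl2), rbind(bo, bo2), rbind(tr, tr2))
  de <- decompose_isotropic(tle, 0)
  blade <- cl$region != "excluded"
  a_lost <- cl$area[cl$cell_id == vic]
  expect_equal(de$extrusion, log(1 - a_lost / sum(cl$area[blade])),
               tolerance = 1e-10)
  expect_equal(de$total, de$cell_area_change + de$division + de$extrusion,
               tolerance = 1e-12)
})

test_that("cumulative radial curves: zeros propagate and constant rates
           accumulate linearly", {
  ser0 <- data.frame(t = 0:29, t_next = 1:30,
                     total_rr = 0, dQ_rr = 0, t1_rr = 0, cd_rr = 0,
                     ex_rr = 0, corr_rr = 0)
  cum0 <- cumulative_radial_shear(ser0, dt = 0.2, kernel = 11, skip = 2)
  expect_true(all(cum0$t1 == 0))
  rho1 <- 0.01
  ser1 <- ser0; ser1$t1_rr <- rho1
  cum1 <- cumulative_radial_shear(ser1, dt = 0.2, kernel = 11, skip = 2)
  # constant rate: cumulative curve is linear with slope rho1 per frame
  expect_equal(diff(cum1$t1), rep(rho1, nrow(cum1) - 1), tolerance = 1e-12)
  expect_error(cumulative_radial_shear(ser0[1:5, ], dt = 0.2, kernel = 11),
               "shorter")
})

test_that("a radially biased movie accumulates radial T1 and tangential dQ", {
  spec <- synthetic_spec(pouch_radius = 24, t1_rate = 1,
                         t1_radial_bias = 0.8, division_rate = 0, seed = 19)
  tl <- generate_timelapse(spec, duration = 2, dt = 0.1)
  ser <- shear_series(tl, projection = "radial")
  cum <- cumulative_radial_shear(ser, dt = 0.1, kernel = 11, skip = 0.5)
  n <- nrow(cum)
  # signs as in the cumulative radial shear decomposition: T1 contribution
  # radial (positive), elongation change tangential (negative)
  expect_gt(cum$t1[n], 0)
  expect_lt(cum$dQ[n], 0)
})
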