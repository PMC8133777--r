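# Shared fixtures, memoised so expensive synthetic objects are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_flat_tissue <- function() fixture("small_flat", function() {
  generate_tissue(synthetic_spec(
    pouch_radius = 20,
    elong_profile = function(r) rep(0, length(r)),
    area_profile = function(r) rep(4, length(r)),
    t1_rate = 0, division_rate = 0, seed = 41))
})

paper_like_tissue <- function() fixture("paper_like", function() {
  generate_tissue(synthetic_spec(pouch_radius = 50, seed = 42))
})

# two-frame epithelium built by transforming a static frame with `map`
two_frame_tissue <- function(base, map) {
  cl <- base$cells
  cl2 <- cl
  cl2$frame <- 1L
  xy <- map(cbind(cl$x, cl$y))
  cl2$x <- xy[, 1]; cl2$y <- xy[, 2]
  # areas transform with the Jacobian of an affine map; for test maps we
  # recompute from the mapped triangles to stay self-consistent
  tr <- base$triangles; tr2 <- tr; tr2$frame <- 1L
  bo <- base$bonds; bo2 <- bo; bo2$frame <- 1L
  p2 <- data.frame(id = cl2$cell_id, x = cl2$x, y = cl2$y)
  cl2$area <- epimech:::cell_areas_from_triangles(
    p2, as.matrix(tr[, c("cell_a", "cell_b", "cell_c")]))
  epithelium(rbind(cl, cl2), rbind(bo, bo2), rbind(tr, tr2))
}

# -- independent numerical elasticity oracle ---------------------------------
# Rim displacement of a traction-free circular hole (radius a) in a 2D sheet
# loaded at a far outer circle (radius R_out), computed by 1D finite-element
# minimization of the elastic energy per Fourier mode. Displacements are
# measured from the unstressed reference, matching the forward model's
# convention. Independent of all closed forms used in the package.
annulus_rim_fem <- function(K, Kbar, mode, load, a, R_out = 40 * a,
                            n_el = 800) {
  mu <- K; lam <- Kbar - K
  redge <- exp(seq(log(a), log(R_out), length.out = n_el + 1))
  nn <- n_el + 1
  if (mode == 0) {
    ndof <- nn
    iU <- function(i) i
  } else {
    ndof <- 2 * nn
    iU <- function(i) 2 * i - 1
    iV <- function(i) 2 * i
  }
  A <- matrix(0, ndof, ndof)
  gp <- c(-1, 1) / sqrt(3)
  Cm <- if (mode == 0) 2 * pi else pi
  for (e in seq_len(n_el)) {
    r1 <- redge[e]; r2 <- redge[e + 1]; h <- r2 - r1
    for (g in gp) {
      r <- (r1 + r2) / 2 + g * h / 2
      w <- h / 2
      N1 <- (r2 - r) / h; N2 <- (r - r1) / h
      dN1 <- -1 / h; dN2 <- 1 / h
      if (mode == 0) {
        dofs <- c(e, e + 1)
        cUp <- c(dN1, dN2)
        cg2 <- c(N1, N2) / r # (U)/r
      } else {
        dofs <- c(iU(e), iU(e + 1), iV(e), iV(e + 1))
        cUp <- c(dN1, dN2, 0, 0)
        cg2 <- c(N1 / r, N2 / r, mode * N1 / r, mode * N2 / r)
        cS <- c(-mode * N1 / r, -mode * N2 / r,
                dN1 - N1 / r, dN2 - N2 / r)
      }
      cg1 <- cUp + cg2
      Ael <- lam * outer(cg1, cg1) + 2 * mu * outer(cUp, cUp) +
        2 * mu * outer(cg2, cg2)
      if (mode != 0) Ael <- Ael + mu * outer(cS, cS)
      A[dofs, dofs] <- A[dofs, dofs] + Cm * w * r * Ael
    }
  }
  b <- numeric(ndof)
  if (mode == 0) {
    b[nn] <- 2 * pi * R_out * load
  } else {
    b[iU(nn)] <- pi * R_out * load
    b[iV(nn)] <- -pi * R_out * load
  }
  u <- solve(A, b)
  if (mode == 0) u[1] else c(U = u[iU(1)], V = u[iV(1)])
}
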