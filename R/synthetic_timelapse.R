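#' Generate a tracked synthetic timelapse
#'
#' Starting from [generate_tissue()], evolves the tissue over `duration`
#' hours in steps of `dt`. T1 rearrangements and divisions are drawn as
#' Poisson processes with per-cell rates `t1_rate` and `division_rate`.
#'
#' A T1 spans two intervals, as at typical imaging frame rates: in the
#' interval where the event fires, the junction between the doomed pair
#' shrinks (their opposite, soon-to-be-bonded centroids approach); in the
#' next, the triangulation edge flips and the quartet relaxes toward an
#' area-preserving, slightly confined rhombus on the new bond, with its
#' neighborhood yielding. "Bond" follows the junction convention: the new
#' bond axis is perpendicular to the line joining the newly bonded
#' centroids. Candidate flips are weighted by
#' `exp(b * cos 2(theta - theta_r))` where `theta` is the prospective
#' new-bond (junction) axis and `theta_r` the local radial axis; the
#' concentration `b` maps from `t1_radial_bias` in `[0, 1]` (0 = uniform,
#' 1 = deterministically the most radial candidate). Event quartets are
#' kept disjoint within a frame so per-interval triangle bookkeeping is
#' exact; events that find no disjoint candidate carry over to the next
#' frame, keeping total counts Poisson. A gentle per-frame
#' neighbor-centroid smoothing stands in for tissue elasticity. Divisions
#' pick a uniformly random interior cell and split its triangle fan along
#' a uniformly random axis. Every event is logged with its cells, frame
#' and axis, and lineage links are emitted, so downstream shear
#' bookkeeping can be checked against exact ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @param duration movie length, hr.
#' @param dt frame interval, hr; must satisfy
#'   `dt <= 1 / (10 * (t1_rate + division_rate))` so that per-cell
#'   per-frame event expectations stay small.
#' @param calibrate calibration passes for the initial frame (see
#'   [generate_tissue()]).
#' @return an [epithelium()] with frames `0 .. duration/dt`, a `lineage`
#'   table and an `events` log (`frame`, `type`, `cell_1..cell_4`, `axis`):
#'   for T1s, cells 1-2 lose their bond and cells 3-4 gain one along
#'   `axis`; for divisions, cell 1 is the parent and cells 2-3 the
#'   daughters separated along `axis`.
#' @export
generate_timelapse <- function(spec, duration, dt = 0.1, calibrate = 5L) {
  stopifnot(inherits(spec, "synthetic_spec"), duration > 0, dt > 0)
  rate <- spec$t1_rate + spec$division_rate
  if (rate > 0 && dt > 1 / (10 * rate))
    stop("dt too large for the event rates: need dt <= ",
         signif(1 / (10 * rate), 3), " hr", call. = FALSE)
  tis0 <- generate_tissue(spec, calibrate = calibrate)
  withr_seed(spec$seed + 1L, {
    sim_timelapse(tis0, spec, duration, dt)
  })
}

sim_timelapse <- function(tis0, spec, duration, dt) {
  fr0 <- get_frame(tis0, 0)
  n_frames <- floor(duration / dt + 1e-9) + 1L
  pos <- as.matrix(fr0$cells[, c("x", "y")])
  ids <- fr0$cells$cell_id
  rownames(pos) <- ids
  tris <- as.matrix(fr0$triangles[, c("cell_a", "cell_b", "cell_c")])
  region <- fr0$cells$region
  names(region) <- ids
  track <- stats::setNames(fr0$cells$track_id, ids)
  next_id <- max(ids) + 1L
  b <- bias_concentration(spec$t1_radial_bias)
  frames <- vector("list", n_frames)
  events <- list()
  lineage <- list()
  frames[[1]] <- snapshot(0L, pos, tris, region, track, spec$center)
  # a T1 spans two intervals, as at typical frame rates: the old bond
  # shrinks toward a fourfold configuration in the interval where the
  # event fires, and the topological flip plus relaxation of the quartet
  # happen in the next. Selections made "at frame 0" seed the queue so the
  # flip rate matches the nominal rate from the first interval on.
  backlog <- 0L # events that found no disjoint candidate yet
  n0 <- stats::rpois(1, nrow(pos) * spec$t1_rate * dt)
  pending <- select_t1s(pos, tris, spec, b, n0)
  backlog <- n0 - length(pending)
  for (f in seq_len(n_frames - 1L)) {
    blocked <- integer(0)
    done <- list()
    for (pd in pending) {
      res <- do_t1_flip(pos, tris, pd, blocked)
      if (is.null(res)) { backlog <- backlog + 1L; next }
      blocked <- c(blocked, res$old, res$new)
      pos <- res$pos; tris <- res$tris
      done[[length(done) + 1L]] <-
        data.frame(frame = f, type = "T1", cell_1 = res$old[1],
                   cell_2 = res$old[2], cell_3 = res$new[1],
                   cell_4 = res$new[2], axis = res$axis)
    }
    events <- c(events, done)
    n_live <- nrow(pos)
    n_div <- stats::rpois(1, n_live * spec$division_rate * dt)
    for (k in seq_len(n_div)) {
      res <- do_division(pos, tris, region, track, next_id,
                         blocked = blocked)
      if (is.null(res)) next
      blocked <- c(blocked, res$parent, res$d1, res$d2, res$fan)
      pos <- res$pos; tris <- res$tris; region <- res$region
      track <- res$track
      lineage[[length(lineage) + 1L]] <-
        data.frame(parent = res$parent, child = c(res$d1, res$d2),
                   frame = f)
      events[[length(events) + 1L]] <-
        data.frame(frame = f, type = "division", cell_1 = res$parent,
                   cell_2 = res$d1, cell_3 = res$d2, cell_4 = NA_integer_,
                   axis = res$axis)
      next_id <- next_id + 2L
    }
    # gentle global relaxation each frame with events: stands in for
    # tissue elasticity, letting event-induced distortions spread and
    # decay so cell elongation drifts slowly instead of accumulating per
    # event. A rate-free movie stays strictly static.
    if (length(done) || n_div > 0)
      pos <- global_smooth(pos, tris,
                           fixed = unname(region[rownames(pos)]) ==
                             "excluded")
    # select and pre-shrink the next interval's T1s (not in the last
    # frame: their flips could never be recorded)
    pending <- if (f < n_frames - 1L) {
      n_t1 <- stats::rpois(1, nrow(pos) * spec$t1_rate * dt) + backlog
      sel <- select_t1s(pos, tris, spec, b, n_t1, blocked)
      backlog <- n_t1 - length(sel)
      for (pd in sel) {
        shr <- shrink_quartet(pos, tris, pd)
        if (!is.null(shr)) pos <- shr
      }
      sel
    } else list()
    if (nrow(tris) < 4)
      stop("tissue lost connectivity during simulation", call. = FALSE)
    frames[[f + 1L]] <- snapshot(f, pos, tris, region, track, spec$center)
  }
  cells <- do.call(rbind, lapply(frames, `[[`, "cells"))
  triangles <- do.call(rbind, lapply(frames, `[[`, "triangles"))
  bonds <- do.call(rbind, lapply(frames, `[[`, "bonds"))
  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(frame = integer(), type = character(), cell_1 = integer(),
               cell_2 = integer(), cell_3 = integer(), cell_4 = integer(),
               axis = numeric())
  lin_df <- if (length(lineage)) do.call(rbind, lineage) else NULL
  epithelium(cells, bonds, triangles, lineage = lin_df, events = ev_df,
             meta = c(tis0$meta, list(duration = duration, dt = dt)))
}

# damped neighbor-centroid smoothing with triangle-validity back-off;
# `fixed` is a logical over rows of pos (ids order) for anchored cells
global_smooth <- function(pos, tris, fixed, iters = 2, w = 0.35) {
  ids <- as.integer(rownames(pos))
  names(fixed) <- NULL
  e <- tri_edges(tris)
  src <- match(c(e[, 1], e[, 2]), ids)
  dst <- match(c(e[, 2], e[, 1]), ids)
  deg <- tabulate(src, nbins = nrow(pos))
  mov <- which(!fixed & deg > 0)
  inc_all <- seq_len(nrow(tris))
  ref_sign <- sign(tri_signed_areas(pos, tris, inc_all, ids))
  for (it in seq_len(iters)) {
    sx <- unname(rowsum(pos[dst, 1], src, reorder = TRUE))[, 1]
    sy <- unname(rowsum(pos[dst, 2], src, reorder = TRUE))[, 1]
    ord <- sort(unique(src))
    mx <- pos[, 1]; my <- pos[, 2]
    mx[ord] <- sx / deg[ord]; my[ord] <- sy / deg[ord]
    cand <- pos
    cand[mov, 1] <- (1 - w) * pos[mov, 1] + w * mx[mov]
    cand[mov, 2] <- (1 - w) * pos[mov, 2] + w * my[mov]
    # revert only the cells whose incident triangles would invert
    for (rep in 1:3) {
      ar <- tri_signed_areas(cand, tris, inc_all, ids)
      bad <- which(sign(ar) != ref_sign | abs(ar) < 1e-9)
      if (!length(bad)) break
      bad_cells <- match(unique(as.vector(tris[bad, , drop = FALSE])), ids)
      cand[bad_cells, ] <- pos[bad_cells, ]
    }
    ar <- tri_signed_areas(cand, tris, inc_all, ids)
    if (all(sign(ar) == ref_sign) && all(abs(ar) > 1e-9)) pos <- cand
  }
  pos
}

# map bias in [0,1] to an angular concentration; 1 means argmax selection
bias_concentration <- function(bias) {
  if (bias >= 1) Inf else 2 * bias / (1 - bias)
}

snapshot <- function(frame, pos, tris, region, track, center) {
  ids <- as.integer(rownames(pos))
  p <- data.frame(id = ids, x = pos[, 1], y = pos[, 2])
  area <- cell_areas_from_triangles(p, tris)
  list(cells = data.frame(frame = frame, cell_id = ids,
                          track_id = unname(track[as.character(ids)]),
                          x = pos[, 1], y = pos[, 2], area = area,
                          region = unname(region[as.character(ids)]),
                          row.names = NULL),
       triangles = data.frame(frame = frame, tri_id = seq_len(nrow(tris)),
                              cell_a = tris[, 1], cell_b = tris[, 2],
                              cell_c = tris[, 3], row.names = NULL),
       bonds = {
         e <- tri_edges(tris)
         data.frame(frame = frame, cell_a = e[, 1], cell_b = e[, 2])
       })
}

# draw this interval's T1 quartets: interior edges chosen with radially
# biased weight on the prospective new-bond axis; chosen quartets are
# mutually disjoint and avoid blocked cells
select_t1s <- function(pos, tris, spec, b, n_t1, blocked = integer(0),
                       max_tries = 30L) {
  if (n_t1 == 0) return(list())
  ed <- interior_edges(tris)
  if (length(blocked)) {
    free <- !(ed[, 1] %in% blocked | ed[, 2] %in% blocked |
                ed[, 3] %in% blocked | ed[, 4] %in% blocked)
    ed <- ed[free, , drop = FALSE]
  }
  if (nrow(ed) == 0) return(list())
  kmax <- max(ed[, 1:4]) + 1
  key <- pmin(ed[, 1], ed[, 2]) * kmax + pmax(ed[, 1], ed[, 2])
  idx <- function(id) match(id, as.integer(rownames(pos)))
  cx <- pos[idx(ed[, 3]), 1]; cy <- pos[idx(ed[, 3]), 2]
  dx <- pos[idx(ed[, 4]), 1]; dy <- pos[idx(ed[, 4]), 2]
  # the new bond (junction) grows perpendicular to the line joining the
  # newly bonded pair of centroids
  newang <- atan2(dy - cy, dx - cx) + pi / 2
  mx <- (cx + dx) / 2 - spec$center[1]
  my <- (cy + dy) / 2 - spec$center[2]
  align <- cos(2 * (newang - atan2(my, mx)))
  w <- if (is.infinite(b)) as.numeric(align >= max(align) - 1e-12) else
    exp(b * align)
  picks <- list()
  for (ev in seq_len(n_t1)) {
    if (all(w <= 0)) break # no candidates left anywhere
    for (try in seq_len(max_tries)) {
      if (all(w <= 0)) break
      k <- sample.int(nrow(ed), 1, prob = w)
      a_id <- ed[k, 1]; b_id <- ed[k, 2]
      c_id <- ed[k, 3]; d_id <- ed[k, 4]
      if (any(key == min(c_id, d_id) * kmax + max(c_id, d_id))) {
        w[k] <- 0; next
      }
      if (!segments_cross(pos[idx(a_id), ], pos[idx(b_id), ],
                          pos[idx(c_id), ], pos[idx(d_id), ])) {
        w[k] <- 0; next
      }
      picks[[length(picks) + 1L]] <- c(a = a_id, b = b_id, c = c_id,
                                       d = d_id)
      # disjointness: retire every edge sharing a quartet cell
      quartet <- c(a_id, b_id, c_id, d_id)
      w[ed[, 1] %in% quartet | ed[, 2] %in% quartet |
          ed[, 3] %in% quartet | ed[, 4] %in% quartet] <- 0
      break
    }
  }
  picks
}

# stage one of a T1: as the doomed junction between a and b shrinks toward
# a fourfold vertex, the soon-to-be-bonded centroids c and d approach each
# other; the triangles on the a-b edge flatten along the a-b axis
shrink_quartet <- function(pos, tris, pd, keep = 0.7) {
  ids_all <- as.integer(rownames(pos))
  ic <- match(pd["c"], ids_all); id_ <- match(pd["d"], ids_all)
  if (is.na(ic) || is.na(id_)) return(NULL)
  inc <- which(tris[, 1] %in% pd | tris[, 2] %in% pd | tris[, 3] %in% pd)
  ref_sign <- sign(tri_signed_areas(pos, tris, inc, ids_all))
  mid <- (pos[ic, ] + pos[id_, ]) / 2
  base_c <- pos[ic, ]; base_d <- pos[id_, ]
  for (kp in c(keep, 0.7, 0.85, 1)) {
    pos[ic, ] <- mid + kp * (base_c - mid)
    pos[id_, ] <- mid + kp * (base_d - mid)
    ar <- tri_signed_areas(pos, tris, inc, ids_all)
    if (all(sign(ar) == ref_sign) && all(abs(ar) > 1e-9)) return(pos)
  }
  NULL
}

# stage two: flip the diagonal and relax the quartet (with its yielding
# neighborhood) toward the isotropic rhombus on the new bond
do_t1_flip <- function(pos, tris, pd, blocked = integer(0)) {
  if (any(pd %in% blocked)) return(NULL)
  ids_all <- as.integer(rownames(pos))
  ia <- match(pd["a"], ids_all); ib <- match(pd["b"], ids_all)
  ic <- match(pd["c"], ids_all); id_ <- match(pd["d"], ids_all)
  if (anyNA(c(ia, ib, ic, id_))) return(NULL)
  # the pair of triangles on the doomed bond must still be (a, b, c/d)
  on_ab <- which((tris[, 1] %in% pd[c("a", "b")]) +
                   (tris[, 2] %in% pd[c("a", "b")]) +
                   (tris[, 3] %in% pd[c("a", "b")]) == 2)
  third <- apply(tris[on_ab, , drop = FALSE], 1, function(tr)
    setdiff(tr, pd[c("a", "b")]))
  t_rows <- on_ab[third %in% pd[c("c", "d")]]
  if (length(t_rows) != 2) return(NULL)
  if (!segments_cross(pos[ia, ], pos[ib, ], pos[ic, ], pos[id_, ]))
    return(NULL)
  tris[t_rows[1], ] <- c(pd["c"], pd["d"], pd["a"])
  tris[t_rows[2], ] <- c(pd["c"], pd["d"], pd["b"])
  u <- pos[id_, ] - pos[ic, ]; u <- u / sqrt(sum(u^2))
  v <- pos[ib, ] - pos[ia, ]; v <- v / sqrt(sum(v^2))
  quartet <- c(ia, ib, ic, id_)
  ctr <- colMeans(pos[quartet, , drop = FALSE])
  inc <- which(tris[, 1] %in% pd | tris[, 2] %in% pd | tris[, 3] %in% pd)
  # local lattice scale from the surrounding (non-flipped) triangles: the
  # shrunken central pair would underestimate it
  ring <- setdiff(inc, t_rows)
  d_loc <- sqrt(4 * mean_incident_area(pos, tris, ring, ids_all) / sqrt(3))
  # confined, area-preserving relaxation target: in a free rhombus the old
  # pair a-b would separate to +-sqrt(3)/2 d_loc; the surrounding tissue
  # frustrates part of that extension (ext < sqrt(3)/2 ~ 0.87) and the new
  # pair c-d keeps the complementary separation so the quad area is
  # preserved. The residual c-d stretch is how rearrangements feed
  # elongation perpendicular to the new junction in a confined disc.
  ext <- 0.84
  target <- rbind(ctr - ext * d_loc * v,
                  ctr + ext * d_loc * v,
                  ctr - (sqrt(3) / 4 / ext) * d_loc * u,
                  ctr + (sqrt(3) / 4 / ext) * d_loc * u)
  ring1 <- setdiff(unique(as.vector(tris[inc, ])), pd)
  inc_r1 <- which(tris[, 1] %in% ring1 | tris[, 2] %in% ring1 |
                    tris[, 3] %in% ring1)
  fan_ids <- setdiff(unique(as.vector(tris[c(inc, inc_r1), ])), pd)
  fan_ids <- fan_ids[vapply(fan_ids, function(fid)
    sum(tris == fid) >= 5, logical(1))] # boundary cells stay anchored
  fan <- match(fan_ids, ids_all)
  inc2 <- which(tris[, 1] %in% c(pd, fan_ids) |
                  tris[, 2] %in% c(pd, fan_ids) |
                  tris[, 3] %in% c(pd, fan_ids))
  ref_sign <- sign(tri_signed_areas(pos, tris, inc2, ids_all))
  nb_of <- lapply(fan_ids, function(fid) {
    rows <- tris[tris[, 1] == fid | tris[, 2] == fid | tris[, 3] == fid, ,
                 drop = FALSE]
    match(setdiff(unique(as.vector(rows)), fid), ids_all)
  })
  for (sweep in 1:6) {
    prev <- pos
    cand <- pos
    cand[quartet, ] <- 0.5 * pos[quartet, ] + 0.5 * target
    for (j in seq_along(fan)) {
      cand[fan[j], ] <- 0.5 * pos[fan[j], ] +
        0.5 * colMeans(pos[nb_of[[j]], , drop = FALSE])
    }
    ok <- FALSE
    for (damp in c(1, 0.5, 0.25)) {
      pos2 <- (1 - damp) * prev + damp * cand
      ar <- tri_signed_areas(pos2, tris, inc2, ids_all)
      if (all(sign(ar) == ref_sign) && all(abs(ar) > 1e-9)) {
        pos <- pos2; ok <- TRUE; break
      }
    }
    if (!ok) break
  }
  # new-bond (junction) axis: perpendicular to the newly bonded centroids
  ang <- atan2(pos[id_, 2] - pos[ic, 2], pos[id_, 1] - pos[ic, 1]) + pi / 2
  list(pos = pos, tris = tris, old = unname(pd[c("a", "b")]),
       new = unname(pd[c("c", "d")]), axis = ang %% pi)
}

# edges shared by exactly two triangles, with the two opposite cells and
# the triangle row indices: columns (a, b, c, d, tri1, tri2)
interior_edges <- function(tris) {
  n <- nrow(tris)
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
  opp <- c(tris[, 3], tris[, 1], tris[, 2])
  trow <- rep(seq_len(n), 3)
  a <- pmin(e[, 1], e[, 2]); bb <- pmax(e[, 1], e[, 2])
  key <- a * (max(bb) + 1) + bb
  ord <- order(key)
  key <- key[ord]; a <- a[ord]; bb <- bb[ord]; opp <- opp[ord]
  trow <- trow[ord]
  same <- key[-1] == key[-length(key)]
  first <- which(c(same, FALSE) & !c(FALSE, same))
  cbind(a = a[first], b = bb[first], c = opp[first], d = opp[first + 1],
        t1 = trow[first], t2 = trow[first + 1])
}

segments_cross <- function(p1, p2, p3, p4) {
  side <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  side(p1, p2, p3) * side(p1, p2, p4) < 0 &&
    side(p3, p4, p1) * side(p3, p4, p2) < 0
}

# one division: split the closed triangle fan of an interior cell along a
# random axis; daughters displaced +/- along the axis.
do_division <- function(pos, tris, region, track, next_id, max_tries = 6L,
                        blocked = integer(0)) {
  ids <- as.integer(rownames(pos))
  for (try in seq_len(max_tries)) {
    ci <- sample.int(length(ids), 1)
    c_id <- ids[ci]
    if (c_id %in% blocked) next
    inc <- which(tris[, 1] == c_id | tris[, 2] == c_id | tris[, 3] == c_id)
    if (length(inc) < 4) next
    nb <- setdiff(unique(as.vector(tris[inc, ])), c_id)
    if (any(nb %in% blocked)) next
    # closed fan: every neighbor appears in exactly two incident triangles
    cnt <- table(as.vector(tris[inc, ]))
    if (any(cnt[as.character(nb)] != 2)) next
    phi <- stats::runif(1, 0, pi)
    nbi <- match(nb, ids)
    ang <- atan2(pos[nbi, 2] - pos[ci, 2], pos[nbi, 1] - pos[ci, 1])
    ord <- order(ang)
    nb <- nb[ord]; ang <- ang[ord]
    side1 <- cos(ang - phi) > 0
    if (!any(side1) || all(side1)) next
    # rotate the cyclic neighbor list so the d1-side arc is first
    m <- length(nb)
    start <- which(side1 & !c(side1[m], side1[-m]))[1]
    rot <- ((start - 1 + seq_len(m) - 1) %% m) + 1
    nb <- nb[rot]; side1 <- side1[rot]
    k <- sum(side1)
    if (any(side1[seq_len(k)] == FALSE)) next # arc not contiguous (rare)
    d1 <- next_id; d2 <- next_id + 1L
    # fan d1 over the side-1 arc, d2 over the side-2 arc, and close the two
    # transition quads through the new d1-d2 bond
    newtris <- list()
    for (i in seq_len(k - 1))
      newtris[[length(newtris) + 1L]] <- c(d1, nb[i], nb[i + 1])
    if (k + 1 <= m - 1)
      for (j in (k + 1):(m - 1))
        newtris[[length(newtris) + 1L]] <- c(d2, nb[j], nb[j + 1])
    newtris[[length(newtris) + 1L]] <- c(d1, nb[k], nb[k + 1])
    newtris[[length(newtris) + 1L]] <- c(d1, nb[k + 1], d2)
    newtris[[length(newtris) + 1L]] <- c(d2, nb[m], nb[1])
    newtris[[length(newtris) + 1L]] <- c(d2, nb[1], d1)
    newtris <- do.call(rbind, newtris)
    delta0 <- 0.35 * sqrt(mean_incident_area(pos, tris, inc, ids))
    good <- FALSE
    for (scale in c(1, 0.5, 0.25)) {
      delta <- delta0 * scale
      p1 <- pos[ci, ] + delta * c(cos(phi), sin(phi))
      p2 <- pos[ci, ] - delta * c(cos(phi), sin(phi))
      pos2 <- rbind(pos[-ci, , drop = FALSE], p1, p2)
      rownames(pos2)[nrow(pos2) - 1:0] <- c(d1, d2)
      ids2 <- as.integer(rownames(pos2))
      ar <- tri_signed_areas(pos2, newtris, seq_len(nrow(newtris)), ids2)
      if (all(ar > 1e-9)) { good <- TRUE; break }
    }
    if (!good) next
    pos <- pos2
    tris <- rbind(tris[-inc, , drop = FALSE], newtris)
    reg <- region[as.character(c_id)]
    region <- c(region[names(region) != as.character(c_id)],
                stats::setNames(rep(reg, 2), c(d1, d2)))
    tr <- track[as.character(c_id)]
    track <- c(track[names(track) != as.character(c_id)],
               stats::setNames(rep(unname(tr), 2), c(d1, d2)))
    return(list(pos = pos, tris = tris, region = region, track = track,
                parent = c_id, d1 = d1, d2 = d2, axis = phi, fan = nb))
  }
  NULL
}

tri_signed_areas <- function(pos, tris, inc, ids) {
  v <- function(col) match(tris[inc, col], ids)
  ax <- pos[v(1), 1]; ay <- pos[v(1), 2]
  bx <- pos[v(2), 1]; by <- pos[v(2), 2]
  cx <- pos[v(3), 1]; cy <- pos[v(3), 2]
  ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
}

mean_incident_area <- function(pos, tris, inc, ids) {
  v <- function(col) match(tris[inc, col], ids)
  ax <- pos[v(1), 1]; ay <- pos[v(1), 2]
  bx <- pos[v(2), 1]; by <- pos[v(2), 2]
  cx <- pos[v(3), 1]; cy <- pos[v(3), 2]
  mean(abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2)
}
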