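## Fingerprint search targets and scoring.
##
## A search target describes a rigid fragment (ribose sugar or phosphate
## group) by paired probe points in the fragment-local frame: "high" probes
## where density must be high if the fragment is present and "low" probes
## where it must be low. Two scores are used: s_mean (difference of the
## probe-set mean densities; sensitive, used for re-scoring) and s_minmax
## (min over high probes minus max over low probes; crude but prunable,
## because it can only worsen as probe pairs accumulate).

#' Construct a fingerprint target
#'
#' @param name fragment type, `"sugar"` or `"phosphate"`.
#' @param high n x 3 matrix of high-probe offsets (Angstrom, fragment-local
#'   frame; rownames label the source atoms). The first high probe must be
#'   the fragment's most conserved strong-density feature: it drives the
#'   immediate-elimination rule of the search.
#' @param low n x 3 matrix of low-probe offsets. High and low counts must
#'   be equal.
#' @param frame_fragment optional named coordinate matrix giving template
#'   atoms in the same local frame (used to convert hits into seeds).
#' @return object of class `fingerprint_target`.
#' @export
fingerprint_target <- function(name, high, low, frame_fragment = NULL) {
  high <- as.matrix(high); low <- as.matrix(low)
  if (nrow(high) != nrow(low))
    stop("the numbers of high and low probe points must be equal")
  if (max(sqrt(rowSums(high^2)), sqrt(rowSums(low^2))) > 6 + 1e-6)
    stop("probe offsets must lie within 6 Angstrom of the fragment centre")
  structure(list(name = name, high = high, low = low, n = nrow(high),
                 frame_fragment = frame_fragment),
            class = "fingerprint_target")
}

#' @export
print.fingerprint_target <- function(x, ...) {
  cat(sprintf("fingerprint_target '%s': %d probe pairs (first high probe: %s)\n",
              x$name, x$n, rownames(x$high)[1]))
  invisible(x)
}

#' Construct a placement (rotation + translation)
#'
#' @param rotation proper 3 x 3 rotation matrix (det = +1).
#' @param translation Cartesian translation (Angstrom).
#' @param score_minmax,score_mean optional attached scores.
#' @return object of class `placement`.
#' @export
placement <- function(rotation, translation, score_minmax = NA_real_,
                      score_mean = NA_real_) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be orthonormal with det = +1")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 score_minmax = score_minmax, score_mean = score_mean),
            class = "placement")
}

# probe positions of a placed target
.probe_positions <- function(target, placement) {
  R <- placement$rotation
  list(high = sweep(target$high %*% t(R), 2, -placement$translation),
       low = sweep(target$low %*% t(R), 2, -placement$translation))
}

#' Mean-difference fingerprint score
#'
#' `s_mean` = mean density at the placed high probes minus mean density at
#' the placed low probes.
#'
#' @param target a [fingerprint_target()].
#' @param grid a [density_grid()].
#' @param placement a [placement()].
#' @param interpolated use trilinear interpolation (`TRUE`, the sensitive
#'   re-scoring path) or nearest-node lookup (`FALSE`, the fast path).
#' @return numeric score.
#' @export
score_mean <- function(target, grid, placement, interpolated = TRUE) {
  p <- .probe_positions(target, placement)
  f <- if (interpolated) interp_density else density_at_node
  mean(f(grid, p$high)) - mean(f(grid, p$low))
}

#' Min/max fingerprint score
#'
#' `s_minmax` = minimum density over the placed high probes minus maximum
#' density over the placed low probes, using nearest-node densities. Always
#' `<= s_mean`; adding probe pairs can only lower it, which is what makes
#' early termination sound.
#'
#' @inheritParams score_mean
#' @return numeric score.
#' @export
score_minmax <- function(target, grid, placement) {
  p <- .probe_positions(target, placement)
  min(density_at_node(grid, p$high)) - max(density_at_node(grid, p$low))
}

#' Early-terminated min/max score
#'
#' Evaluates probe pairs in stored order, maintaining the running
#' min(high) - max(low). As soon as the partial score drops below
#' `threshold` evaluation stops and the placement is rejected; since the
#' partial score is an upper bound on the final score, rejection is exact.
#'
#' @inheritParams score_mean
#' @param threshold rejection threshold.
#' @return list with `rejected` (logical), `score` (equal to
#'   [score_minmax()] when accepted, `NA` otherwise) and `pairs_used`.
#' @export
score_minmax_pruned <- function(target, grid, placement, threshold) {
  p <- .probe_positions(target, placement)
  hv <- density_at_node(grid, p$high)
  lv <- density_at_node(grid, p$low)
  minh <- Inf; maxl <- -Inf
  for (i in seq_len(target$n)) {
    minh <- min(minh, hv[i])
    maxl <- max(maxl, lv[i])
    if (minh - maxl < threshold)
      return(list(rejected = TRUE, score = NA_real_, pairs_used = i))
  }
  list(rejected = FALSE, score = minh - maxl, pairs_used = target$n)
}

# ZYZ Euler rotation matrix
.euler_zyz <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  matrix(c(ca * cb * cg - sa * sg, sa * cb * cg + ca * sg, -sb * cg,
           -ca * cb * sg - sa * cg, -sa * cb * sg + ca * cg, sb * sg,
           ca * sb, sa * sb, cb), 3, 3)
}

#' Quasi-uniform rotation sampling
#'
#' ZYZ Euler grid with uniform beta rows; the number of alpha samples per
#' row is scaled by sin(beta) (alpha and gamma are degenerate at the
#' poles), which keeps neighbouring samples within `step_deg` of each
#' other in the rotation-angle metric. At the default 18 degree step this
#' yields 2680 orientations.
#'
#' @param step_deg angular step in degrees (0 < step <= 90 for search use;
#'   larger values give coarse covers).
#' @return list of 3 x 3 rotation matrices; attribute `quaternions` holds
#'   the corresponding unit quaternions (n x 4, scalar first).
#' @export
sample_rotations <- function(step_deg = 18) {
  if (step_deg <= 0) stop("step must be positive")
  step <- step_deg * pi / 180
  nb <- ceiling(pi / step)
  ng <- max(1L, ceiling(2 * pi / step))
  rots <- list()
  for (k in 0:nb) {
    beta <- k * pi / nb
    na <- if (k == 0 || k == nb) 1L else max(1L, ceiling(2 * pi * sin(beta) / step))
    for (ia in seq_len(na) - 1L)
      for (ig in seq_len(ng) - 1L)
        rots[[length(rots) + 1L]] <-
          .euler_zyz(2 * pi * ia / na, beta, 2 * pi * ig / ng)
  }
  attr(rots, "quaternions") <- t(vapply(rots, rotation_to_quat, numeric(4)))
  rots
}

#' Convert a rotation matrix to a unit quaternion
#'
#' @param R 3 x 3 rotation matrix.
#' @return length-4 unit quaternion (scalar component first).
#' @export
rotation_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  q / sqrt(sum(q^2))
}

#' Rotation-angle distance between two rotations
#'
#' @param R1,R2 3 x 3 rotation matrices.
#' @return angle of the relative rotation, in degrees.
#' @export
rotation_distance <- function(R1, R2) {
  q1 <- rotation_to_quat(R1); q2 <- rotation_to_quat(R2)
  2 * acos(pmin(1, abs(sum(q1 * q2)))) * 180 / pi
}

#' Sample rotations uniformly over SO(3)
#'
#' @param n number of rotations.
#' @return list of rotation matrices (uses the current RNG stream).
#' @export
random_rotations <- function(n) {
  q <- matrix(rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) quat_to_rotation(q[i, ]))
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q length-4 unit quaternion (scalar first).
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Derive probe points from ensemble min/max maps
#'
#' High probes are placed on the named fragment atoms (plus any extra
#' positions). Low probes follow a rising-contour procedure on the maximum
#' map: starting from the lowest value within `radius` of the fragment
#' centre, the contour is raised and a probe is placed whenever a new,
#' disconnected density region appears, subject to a pairwise separation of
#' at least `min_sep` from existing probes. Probe counts are equalized by
#' truncating the longer list (low probes with the lowest maximum-map
#' values are kept; high probes keep atom order).
#'
#' @param min_map,max_map ensemble minimum/maximum maps on a common grid.
#' @param fragment_atoms named coordinate matrix of high-probe atoms, in
#'   map coordinates, in the desired probe order (first row becomes the
#'   first high probe).
#' @param extra_high optional matrix of additional high-probe positions.
#' @param radius search radius around the fragment centre (Angstrom).
#' @param min_sep minimum separation between low probes (Angstrom).
#' @param center fragment centre in map coordinates; probe offsets are
#'   reported relative to it.
#' @param name target name passed to [fingerprint_target()].
#' @param frame_fragment optional template passed through.
#' @return a [fingerprint_target()].
#' @export
derive_probes <- function(min_map, max_map, fragment_atoms,
                          extra_high = NULL, radius = 6, min_sep = 1.5,
                          center = c(0, 0, 0), name = "sugar",
                          frame_fragment = NULL) {
  if (!identical(dim(min_map$values), dim(max_map$values)))
    stop("min_map and max_map must share geometry")
  sp <- max_map$spacing; org <- max_map$origin
  d <- dim(max_map$values)
  ilo <- ceiling((center - radius - org) / sp)
  ihi <- floor((center + radius - org) / sp)
  if (any(ihi < ilo)) stop("no low-probe candidates within radius")
  nodes <- as.matrix(expand.grid(i = ilo[1]:ihi[1], j = ilo[2]:ihi[2],
                                 k = ilo[3]:ihi[3]))
  pos <- cbind(org[1] + nodes[, 1] * sp[1],
               org[2] + nodes[, 2] * sp[2],
               org[3] + nodes[, 3] * sp[3])
  dist2 <- rowSums(sweep(pos, 2, center)^2)
  keep <- dist2 <= radius^2
  if (!any(keep)) stop("no low-probe candidates within radius")
  nodes <- nodes[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  dist2 <- dist2[keep]
  val <- density_at_node(max_map, pos)
  # box-local ids for constant-time neighbour lookup
  bdim <- ihi - ilo + 1L
  bid <- (nodes[, 1] - ilo[1]) + bdim[1] * ((nodes[, 2] - ilo[2]) +
           bdim[2] * (nodes[, 3] - ilo[3])) + 1L
  in_ball <- logical(prod(bdim)); in_ball[bid] <- TRUE
  visited <- logical(prod(bdim))
  noff <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  noff <- noff[rowSums(abs(noff)) > 0, ]
  ord <- order(val, dist2)
  low <- NULL; low_val <- NULL
  for (t in ord) {
    bi <- nodes[t, ] - ilo
    nb <- sweep(noff, 2, bi, `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < bdim[1] & nb[, 2] >= 0 &
      nb[, 2] < bdim[2] & nb[, 3] >= 0 & nb[, 3] < bdim[3]
    nid <- nb[ok, 1] + bdim[1] * (nb[ok, 2] + bdim[2] * nb[ok, 3]) + 1L
    nid <- nid[in_ball[nid]]
    birth <- !any(visited[nid])
    visited[bid[t]] <- TRUE
    if (birth) {
      p <- pos[t, ]
      if (is.null(low) || all(sqrt(rowSums(sweep(low, 2, p)^2)) >= min_sep)) {
        low <- rbind(low, p)
        low_val <- c(low_val, val[t])
      }
    }
  }
  high <- rbind(as.matrix(fragment_atoms),
                if (!is.null(extra_high)) as.matrix(extra_high))
  high_off <- sweep(high, 2, center)
  low_off <- sweep(low, 2, center)
  low_off <- low_off[order(low_val), , drop = FALSE]
  n <- min(nrow(high_off), nrow(low_off))
  fingerprint_target(name, head(high_off, n), head(low_off, n),
                     frame_fragment = frame_fragment)
}

#' Pruned local fingerprint search
#'
#' Scores every sampled orientation at every grid-node translation within
#' `radius` of `center` using the early-terminated `s_minmax` score with
#' per-rotation grid-rounded probe offsets. Translations whose first
#' high-probe density is below mean + 1 sigma of the map are eliminated
#' immediately, and a running best-list of size `n_best` raises the live
#' acceptance threshold (never below 0). Survivors are re-scored with the
#' interpolated `s_mean`; placements with `s_mean <= 0` are dropped and the
#' rest returned sorted by `s_mean` (ties: distance to `center`, then
#' rotation index).
#'
#' @param grid a [density_grid()].
#' @param target a [fingerprint_target()].
#' @param center Cartesian view centre (Angstrom).
#' @param radius translation search radius (Angstrom, default 6).
#' @param step_deg rotation search step in degrees (default 18).
#' @param n_best size of the retained best-list (default 50).
#' @param rotations optional pre-computed rotation list (from
#'   [sample_rotations()]), to avoid re-sampling across calls.
#' @param whole_cell search every grid node instead of a local sphere.
#' @return list of [placement()] objects with both scores attached, plus
#'   attributes `rot_index` usage on each element.
#' @export
search_local <- function(grid, target, center, radius = 6, step_deg = 18,
                         n_best = 50, rotations = NULL, whole_cell = FALSE) {
  if (!whole_cell && radius < max(grid$spacing))
    stop("radius smaller than one grid step: no candidate translations")
  if (is.null(rotations)) rotations <- sample_rotations(step_deg)
  rotm <- t(vapply(rotations, as.vector, numeric(9)))
  res <- cpp_search_local(grid$values, dim(grid$values),
                          grid$spacing, grid$origin, grid$mean, grid$sigma,
                          rotm, target$high, target$low,
                          as.numeric(center), radius,
                          as.integer(n_best), 0.0, whole_cell)
  if (length(res$score_minmax) == 0L) return(list())
  smean <- cpp_score_mean_batch(grid$values, dim(grid$values),
                                grid$spacing, grid$origin,
                                rotm[res$rot_index, , drop = FALSE],
                                res$translation, target$high, target$low,
                                interpolated = TRUE)
  keep <- smean > 0
  if (!any(keep)) return(list())
  dctr <- sqrt(rowSums(sweep(res$translation, 2, as.numeric(center))^2))
  ord <- order(-smean, dctr, res$rot_index)
  ord <- ord[keep[ord]]
  lapply(ord, function(q) {
    pl <- placement(rotations[[res$rot_index[q]]], res$translation[q, ],
                    score_minmax = res$score_minmax[q], score_mean = smean[q])
    pl$rot_index <- res$rot_index[q]
    pl
  })
}
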