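# Fingerprint scores, rotation sampling, probe derivation and the pruned
# local search.

# a small target and a map with hand-set densities at its probe nodes
.constructed_case <- function(high_vals, low_vals) {
  v <- array(0, dim = c(16, 16, 16))
  # spacing 1: node (i, j, k) is at (i-1, j-1, k-1)
  for (p in 1:3) {
    v[10 + p, 10, 10] <- high_vals[p]   # probe at (9 + p, 9, 9)
    v[10, 10 + p, 10] <- low_vals[p]
  }
  g <- density_grid(v, 1)
  tg <- fingerprint_target("sugar",
                           high = cbind(1:3, 0, 0), low = cbind(0, 1:3, 0))
  list(grid = g, target = tg, pl = placement(diag(3), c(9, 9, 9)))
}

test_that("score_mean and score_minmax follow their definitions", {
  cc <- .constructed_case(c(2, 2, 2), c(0, 0, 0))
  expect_equal(score_mean(cc$target, cc$grid, cc$pl), 2.0)
  cc2 <- .constructed_case(c(2, 3, 4), c(1, 0, -1))
  expect_equal(score_minmax(cc2$target, cc2$grid, cc2$pl), 2 - 1)
  # constant map: both scores vanish for any placement
  gc <- density_grid(array(1.7, dim = c(8, 8, 8)), 0.5)
  set.seed(11)
  for (R in random_rotations(5)) {
    pl <- placement(R, runif(3, 0, 4))
    expect_equal(score_mean(fx_targets()$sugar, gc, pl), 0)
    expect_equal(score_minmax(fx_targets()$sugar, gc, pl), 0)
  }
})

test_that("score_mean equals an independent per-probe lookup-and-average oracle", {
  g <- fx_helix()$grid
  tg <- fx_targets()$sugar
  set.seed(12)
  for (R in random_rotations(20)) {
    pl <- placement(R, runif(3, 10, 25))
    hp <- sweep(tg$high %*% t(R), 2, -pl$translation)
    lp <- sweep(tg$low %*% t(R), 2, -pl$translation)
    oracle <- sum(vapply(seq_len(tg$n), function(i)
      interp_density(g, hp[i, ]), numeric(1))) / tg$n -
      sum(vapply(seq_len(tg$n), function(i)
        interp_density(g, lp[i, ]), numeric(1))) / tg$n
    expect_equal(score_mean(tg, g, pl), oracle, tolerance = 1e-12)
  }
})

test_that("s_minmax never exceeds s_mean", {
  g <- fx_helix()$grid
  set.seed(13)
  for (tg in fx_targets()) {
    rots <- random_rotations(500)
    for (R in rots) {
      pl <- placement(R, runif(3, 0, g$cell))
      sm <- score_mean(tg, g, pl, interpolated = FALSE)
      sx <- score_minmax(tg, g, pl)
      expect_lte(sx, sm + 1e-12)
    }
  }
})

test_that("early-terminated scoring rejects exactly the sub-threshold placements", {
  g <- fx_helix()$grid
  tg <- fx_targets()$sugar
  # threshold -Inf never rejects and reproduces score_minmax
  set.seed(14)
  pls <- lapply(random_rotations(200), function(R)
    placement(R, runif(3, 0, g$cell)))
  for (pl in pls) {
    r <- score_minmax_pruned(tg, g, pl, -Inf)
    expect_false(r$rejected)
    expect_equal(r$score, score_minmax(tg, g, pl))
  }
  # first pair high 1, low 2 with threshold 0: rejected after one pair
  cc <- .constructed_case(c(1, 9, 9), c(2, -9, -9))
  r <- score_minmax_pruned(cc$target, cc$grid, cc$pl, 0)
  expect_true(r$rejected)
  expect_equal(r$pairs_used, 1L)
  # accepted set identical to brute force over many random placements
  set.seed(15)
  pls <- lapply(random_rotations(2000), function(R)
    placement(R, runif(3, 0, g$cell)))
  for (thr in c(0, 0.2)) {
    pruned <- vapply(pls, function(pl)
      !score_minmax_pruned(tg, g, pl, thr)$rejected, logical(1))
    full <- vapply(pls, function(pl)
      score_minmax(tg, g, pl) >= thr, logical(1))
    expect_identical(pruned, full)
    for (q in which(pruned))
      expect_equal(score_minmax_pruned(tg, g, pls[[q]], thr)$score,
                   score_minmax(tg, g, pls[[q]]))
  }
})

test_that("both scores are shift-invariant and scale linearly with the map", {
  g <- fx_helix()$grid
  gs <- density_grid(g$values + 2.5, g$spacing, g$origin)
  gk <- density_grid(g$values * 3, g$spacing, g$origin)
  tg <- fx_targets()$sugar
  set.seed(16)
  for (R in random_rotations(20)) {
    pl <- placement(R, runif(3, 5, 25))
    expect_equal(score_mean(tg, gs, pl), score_mean(tg, g, pl),
                 tolerance = 1e-9)
    expect_equal(score_minmax(tg, gs, pl), score_minmax(tg, g, pl),
                 tolerance = 1e-9)
    expect_equal(score_mean(tg, gk, pl), 3 * score_mean(tg, g, pl),
                 tolerance = 1e-9)
    expect_equal(score_minmax(tg, gk, pl), 3 * score_minmax(tg, g, pl),
                 tolerance = 1e-9)
  }
})

test_that("rotation sampling covers SO(3) at the requested step", {
  rots <- fx_rotations()
  expect_gte(length(rots), 2000)
  expect_lte(length(rots), 4200)
  q <- attr(rots, "quaternions")
  set.seed(17)
  m <- matrix(rnorm(4000), ncol = 4)
  m <- m / sqrt(rowSums(m^2))
  dmax <- 2 * acos(pmin(1, apply(abs(m %*% t(q)), 1, max))) * 180 / pi
  expect_lt(max(dmax), 18)
  # a very coarse cover still contains the identity and spans SO(3)
  coarse <- sample_rotations(180)
  expect_true(any(vapply(coarse, function(R) max(abs(R - diag(3))) < 1e-9,
                         logical(1))))
  qc <- attr(coarse, "quaternions")
  dmax <- 2 * acos(pmin(1, apply(abs(m %*% t(qc)), 1, max))) * 180 / pi
  expect_lte(max(dmax), 180)
  expect_error(sample_rotations(0), "positive")
})

test_that("probe derivation places one low probe per new density region", {
  # constant maximum map: a single low probe appears
  gc <- density_grid(array(1, dim = c(24, 24, 24)), 0.5)
  atoms <- rbind("C1'" = c(6.5, 6, 6), "C2'" = c(5.5, 6, 6), "C3'" = c(6, 7, 6))
  tg <- derive_probes(gc, gc, atoms, radius = 5, center = c(6, 6, 6))
  expect_equal(tg$n, 1L)
  expect_equal(rownames(tg$high), "C1'")
  # two well-separated minima: both receive probes, min_sep apart
  ii <- (0:23) * 0.5
  w <- array(1, dim = c(24, 24, 24))
  for (ctr in list(c(4, 6, 6), c(8, 6, 6))) {
    d2 <- outer(outer((ii - ctr[1])^2, (ii - ctr[2])^2, `+`), (ii - ctr[3])^2, `+`)
    w <- w - 0.4 * exp(-d2 / 0.8)
  }
  gw <- density_grid(w, 0.5)
  tg2 <- derive_probes(gw, gw, atoms[1:2, ], radius = 5, min_sep = 1.5,
                       center = c(6, 6, 6))
  expect_equal(tg2$n, 2L)
  lows <- sweep(tg2$low, 2, -c(6, 6, 6))   # back to map coordinates
  d_to_wells <- apply(lows, 1, function(p)
    min(sqrt(sum((p - c(4, 6, 6))^2)), sqrt(sum((p - c(8, 6, 6))^2))))
  expect_lt(max(d_to_wells), 0.8)
  expect_gte(sqrt(sum((lows[1, ] - lows[2, ])^2)), 1.5)
  expect_error(derive_probes(gc, gc, atoms, radius = 0.1,
                             center = c(6.25, 6.25, 6.25)), "candidates")
})

test_that("a derived sugar target separates conserved density from conserved holes", {
  tgs <- derive_default_targets(n_ensemble = 15, amplitude = 0.25, seed = 9)
  for (kind in c("sugar", "phosphate")) {
    tg <- tgs[[kind]]
    mm <- attr(tgs, paste0("maps_", kind))
    ctr <- rep(10, 3)
    hi <- interp_density(mm$min_map, sweep(tg$high, 2, -ctr))
    lo <- interp_density(mm$max_map, sweep(tg$low, 2, -ctr))
    expect_gt(min(hi), max(lo))
    expect_lte(max(sqrt(rowSums(tg$high^2)), sqrt(rowSums(tg$low^2))), 6 + 1e-6)
  }
  expect_equal(rownames(tgs$sugar$high)[1], "C1'")
  expect_equal(rownames(tgs$phosphate$high)[1], "P")
})

test_that("the local search recovers a known fragment placement", {
  s <- fx_single_nt()
  tg <- fx_targets()$sugar
  hits <- search_local(s$grid, tg, s$center, radius = 6,
                       rotations = fx_rotations())
  expect_gt(length(hits), 0)
  top <- hits[[1]]
  # translation lands within one grid diagonal of the true ring centroid
  expect_lte(sqrt(sum((top$translation - s$center)^2)),
             sqrt(3) * max(s$grid$spacing))
  # rotation within the search step of the true frame rotation
  truth <- superpose_rigid(tg$frame_fragment[ring_atoms, ],
                           s$frag[ring_atoms, ])
  expect_lte(rotation_distance(top$rotation, truth$rotation), 18)
  # scores are attached and ordered
  sm <- vapply(hits, function(h) h$score_mean, numeric(1))
  expect_true(all(diff(sm) <= 1e-12))
  expect_true(all(sm > 0))
})

test_that("an all-zero map yields no hits", {
  gz <- density_grid(array(0, dim = c(16, 16, 16)), 0.5)
  hits <- search_local(gz, fx_targets()$sugar, c(4, 4, 4), radius = 3,
                       rotations = sample_rotations(40))
  expect_length(hits, 0)
  expect_error(search_local(gz, fx_targets()$sugar, c(4, 4, 4), radius = 0.2),
               "radius")
})

test_that("pruned search equals the exhaustive oracle on a coarse case", {
  s <- fx_single_nt()
  tg <- fx_targets()$phosphate
  rots <- sample_rotations(30)
  hits <- search_local(s$grid, tg, s$center, radius = 4.5, rotations = rots,
                       n_best = 25)
  oracle <- oracle_search_local(s$grid, tg, s$center, 4.5, rots, n_best = 25)
  expect_equal(length(hits), length(oracle))
  for (q in seq_along(hits)) {
    expect_equal(hits[[q]]$rot_index, oracle[[q]]$rot_index)
    expect_equal(hits[[q]]$translation, oracle[[q]]$translation)
    expect_equal(hits[[q]]$score_minmax, oracle[[q]]$score_minmax)
    expect_equal(hits[[q]]$score_mean, oracle[[q]]$score_mean)
  }
})

test_that("targets validate probe-pair structure", {
  expect_error(fingerprint_target("sugar", cbind(1, 0, 0),
                                  rbind(c(0, 1, 0), c(0, 2, 0))),
               "equal")
  expect_error(fingerprint_target("sugar", cbind(7, 0, 0), cbind(0, 1, 0)),
               "6 Angstrom")
  expect_error(placement(matrix(rnorm(9), 3), c(0, 0, 0)), "orthonormal")
  # reflections are not rotations
  expect_error(placement(diag(c(-1, 1, 1)), c(0, 0, 0)), "orthonormal")
})
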