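# Conformer database construction, pruning, superposition, seeding and
# extension queries.

test_that("a synthetic helix builds a database with chain adjacency", {
  db <- build_database(make_helix(helix_spec(12)))
  expect_equal(db$size, 12L)
  expect_equal(sum(!is.na(db$next_idx)), 11L)
  # adjacency is consistent: the 3' neighbour's 5' neighbour is self
  for (i in which(!is.na(db$next_idx)))
    expect_equal(db$prev_idx[db$next_idx[i]], i)
  # a residue missing a ring atom is skipped with a warning
  frags <- make_helix(helix_spec(12))
  frags[[5]] <- frags[[5]][rownames(frags[[5]]) != "O4'", ]
  expect_warning(db2 <- build_database(frags), "sugar ring")
  expect_equal(db2$size, 11L)
  expect_error(build_database(list()), "no usable|unsupported")
})

test_that("conformer pruning removes exactly the outliers and is idempotent", {
  base <- nt_template()
  ens <- lapply(1:10, function(i) base)
  expect_length(prune_ensemble(ens, "O2'"), 10)
  # one fragment with O2' displaced by 3 A is removed, nothing else
  out <- ens
  out[[4]]["O2'", ] <- out[[4]]["O2'", ] + c(3, 0, 0)
  kept <- prune_ensemble(out, "O2'")
  expect_length(kept, 9)
  expect_true(all(vapply(kept, function(f) f["O2'", 1] == base["O2'", 1],
                         logical(1))))
  # idempotent on a noisy ensemble
  noisy <- perturb_ensemble(base, 30, amplitude = 0.6, seed = 21)
  once <- prune_ensemble(noisy, c("C5'", "C3'"), cutoff = 0.8)
  twice <- prune_ensemble(once, c("C5'", "C3'"), cutoff = 0.8)
  expect_identical(once, twice)
  expect_error(prune_ensemble(list(), "O2'"), "empty")
})

test_that("rigid superposition recovers known motions and refuses reflections", {
  set.seed(22)
  pts <- matrix(rnorm(30), ncol = 3)
  fit0 <- superpose_rigid(pts, pts)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  # known rotation + translation
  ax <- c(1, 2, 3) / sqrt(14)
  ang <- 30 * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  tv <- c(1.5, -2, 0.25)
  moved <- sweep(pts %*% t(R), 2, -tv)
  fit <- superpose_rigid(pts, moved)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, tv, tolerance = 1e-9)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  # superposition is an isometry
  out <- sweep(pts %*% t(fit$rotation), 2, -fit$translation)
  expect_equal(as.vector(dist(out)), as.vector(dist(pts)), tolerance = 1e-9)
  # mirrored point set: proper-rotation fit leaves residual
  mir <- pts %*% diag(c(-1, 1, 1))
  expect_gt(superpose_rigid(mir, pts)$rmsd, 0.1)
  expect_error(superpose_rigid(pts[1:2, ], pts[1:2, ]), "3 atoms")
  expect_warning(superpose_rigid(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
                 "degenerate")
})

test_that("sugar hits place the template as a nucleoside seed", {
  tg <- fx_targets()$sugar
  idhit <- placement(diag(3), c(0, 0, 0))
  expect_equal(seed_from_sugar(fx_db(), idhit, tg)[, ],
               tg$frame_fragment[, ], tolerance = 1e-12)
  set.seed(23)
  R <- random_rotations(1)[[1]]
  hit <- placement(R, c(4, -1, 2))
  seed <- seed_from_sugar(fx_db(), hit, tg)
  expect_equal(unname(seed[, ]),
               unname(sweep(tg$frame_fragment %*% t(R), 2, -c(4, -1, 2))),
               tolerance = 1e-9)
  # a hit from a real search lands the seed ring on the true ring
  s <- fx_single_nt()
  hits <- search_local(s$grid, tg, s$center, 6, rotations = fx_rotations())
  seed <- seed_from_sugar(fx_db(), hits[[1]], tg)
  expect_lt(frag_rmsd(seed, s$frag), 0.8)
})

test_that("phosphate hits select the best-scoring binucleotide", {
  db <- build_database(make_helix(helix_spec(6)))
  fix <- fx_helix()
  g <- fix$grid
  tg <- fx_targets()
  # true intervening phosphate group between fragments 6 and 7
  grp <- rbind(fix$fragments[[7]][c("P", "OP1", "OP2", "O5'"), ],
               "O3'" = fix$fragments[[6]]["O3'", ])
  hit <- superpose_rigid(tg$phosphate$frame_fragment, grp)
  pair <- seed_from_phosphate(db, hit, g, tg$phosphate, tg$sugar)
  expect_lt(max(sqrt(sum((pair[[1]]["C1'", ] - fix$fragments[[6]]["C1'", ])^2)),
                sqrt(sum((pair[[2]]["C1'", ] - fix$fragments[[7]]["C1'", ])^2))),
            1.5)
  # exhaustive oracle over adjacent pairs reproduces the winner
  best <- -Inf; best_pair <- NULL
  ref <- sweep(tg$phosphate$frame_fragment %*% t(hit$rotation), 2,
               -hit$translation)
  for (i in which(!is.na(db$next_idx))) {
    j <- db$next_idx[i]
    a <- db$nucleotides[[i]]; b <- db$nucleotides[[j]]
    gmov <- rbind(b[c("P", "OP1", "OP2", "O5'"), ], "O3'" = a["O3'", ])
    fit <- superpose_rigid(gmov, ref[rownames(gmov), ])
    ta <- sweep(a %*% t(fit$rotation), 2, -fit$translation)
    tb <- sweep(b %*% t(fit$rotation), 2, -fit$translation)
    rownames(ta) <- rownames(a); rownames(tb) <- rownames(b)
    sc <- score_fragment_sugar(g, tg$sugar, ta) +
      score_fragment_sugar(g, tg$sugar, tb)
    if (sc > best) { best <- sc; best_pair <- list(ta, tb) }
  }
  expect_equal(unname(pair[[1]][, ]), unname(best_pair[[1]][, ]),
               tolerance = 1e-9)
  expect_equal(attr(pair, "score"), best, tolerance = 1e-9)
  # constant map: every candidate ties at zero, lowest index wins
  gc <- density_grid(array(0.5, dim = c(24, 24, 24)), 1)
  pair0 <- seed_from_phosphate(db, hit, gc, tg$phosphate, tg$sugar)
  expect_match(attr(pair0[[1]], "source_id"), ":1$")
})

test_that("extension queries return plausible neighbours", {
  db3 <- build_database(make_helix(helix_spec(3)))
  term <- db3$nucleotides[[2]]
  expect_length(query_extensions(db3, term, "3"), 2)
  expect_length(query_extensions(db3, term, "5"), 2)
  # identity query: the entry's true neighbour appears with zero rmsd
  cands <- query_extensions(db3, db3$nucleotides[[1]], "3")
  own <- Filter(function(cn) cn$db_index == 1, cands)[[1]]
  expect_equal(own$rmsd, 0, tolerance = 1e-9)
  expect_equal(own$nucleotide[, ], db3$nucleotides[[2]][, ], tolerance = 1e-9)
  # curated database: every candidate's C1' lands 4-8 A from the terminal
  db <- fx_db()
  term <- fx_helix()$fragments[[6]]
  for (dir in c("3", "5")) {
    cands <- query_extensions(db, term, dir)
    d <- vapply(cands, function(cn)
      sqrt(sum((cn$nucleotide["C1'", ] - term["C1'", ])^2)), numeric(1))
    expect_true(all(d > 4 & d < 8))
  }
})

test_that("a database round-trips through PDB text", {
  db <- build_database(make_helix(helix_spec(5)))
  path <- tempfile(fileext = ".pdb")
  write_trace_pdb(list(chain_trace(db$nucleotides)), path)
  db2 <- build_database(path)
  expect_equal(db2$size, db$size)
  expect_equal(sum(!is.na(db2$next_idx)), sum(!is.na(db$next_idx)))
  for (i in seq_len(db$size))
    expect_equal(db2$nucleotides[[i]][rownames(db$nucleotides[[i]]), ],
                 db$nucleotides[[i]][, ], tolerance = 2e-3)
  unlink(path)
})
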