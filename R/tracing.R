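## Chain growing: calibrated stopping threshold, bidirectional extension,
## short-fragment filtering and trace merging.

#' Construct a chain trace
#'
#' @param nucleotides ordered 5' to 3' list of nucleotide fragments.
#' @param scores per-nucleotide sugar `s_mean` values.
#' @param seed_index position of the originating seed within the list.
#' @return object of class `chain_trace`.
#' @export
chain_trace <- function(nucleotides, scores = rep(NA_real_, length(nucleotides)),
                        seed_index = 1L) {
  stopifnot(length(nucleotides) >= 1L, length(scores) == length(nucleotides))
  structure(list(nucleotides = nucleotides, scores = scores,
                 seed_index = as.integer(seed_index)),
            class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf("chain_trace: %d nucleotides, total score %.3f\n",
              length(x$nucleotides), sum(x$scores, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.chain_trace <- function(x) length(x$nucleotides)

# C1' coordinate matrix of a trace
.trace_c1 <- function(trace) {
  t(vapply(trace$nucleotides, function(f) f["C1'", ], numeric(3)))
}

#' Calibrate the chain-growing acceptance threshold
#'
#' Scores `n_samples` uniformly random placements of the target (rotation
#' uniform over SO(3), translation uniform over the cell) with the
#' interpolated `s_mean`, and returns the empirical `1 - tail_prob`
#' quantile: the score that a random placement exceeds with probability
#' `tail_prob`.
#'
#' @param grid a [density_grid()].
#' @param target a [fingerprint_target()].
#' @param n_samples number of random placements (default 100000).
#' @param tail_prob exceedance probability (default 0.001, i.e. 0.1%).
#' @param seed RNG seed (reproducible).
#' @return object of class `score_threshold` with fields `value`,
#'   `n_samples`, `tail_prob`; the sampled scores are kept in attribute
#'   `scores`.
#' @export
calibrate_threshold <- function(grid, target, n_samples = 100000,
                                tail_prob = 0.001, seed = 1) {
  stopifnot(tail_prob > 0, tail_prob < 1, n_samples >= 1000)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  q <- matrix(rnorm(4 * n_samples), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  rotm <- .quat_to_rotmat_rows(q)
  trans <- cbind(runif(n_samples, 0, grid$cell[1]),
                 runif(n_samples, 0, grid$cell[2]),
                 runif(n_samples, 0, grid$cell[3]))
  trans <- sweep(trans, 2, grid$origin, `+`)
  scores <- cpp_score_mean_batch(grid$values, dim(grid$values),
                                 grid$spacing, grid$origin, rotm, trans,
                                 target$high, target$low, interpolated = TRUE)
  # k-th largest with k = ceiling(n * tail_prob): exceeded by < k samples
  k <- max(1L, ceiling(n_samples * tail_prob))
  value <- sort(scores, decreasing = TRUE)[k]
  if (grid$sigma == 0)
    warning("degenerate constant map: threshold is the constant difference 0")
  structure(list(value = value, n_samples = n_samples, tail_prob = tail_prob),
            class = "score_threshold", scores = scores)
}

# rows of N x 9 column-major rotation matrices from unit quaternions
.quat_to_rotmat_rows <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
}

#' @export
print.score_threshold <- function(x, ...) {
  cat(sprintf("score_threshold: %.4g (%d samples, tail %.3g)\n",
              x$value, x$n_samples, x$tail_prob))
  invisible(x)
}

#' Grow a seed into a chain
#'
#' Alternately attempts 3' and 5' extension. Candidates from
#' [query_extensions()] are scored with the interpolated `s_mean` of the
#' new sugar plus that of the intervening phosphate group; the best total
#' is accepted when its sugar score exceeds `threshold$value` and its C1'
#' is at least 3 Angstrom from every C1' already in the trace (the
#' anti-backtrack rule). An end closes when no candidate qualifies;
#' growth stops when both ends are closed.
#'
#' @param grid a [density_grid()].
#' @param db a [build_database()] result.
#' @param seed a [chain_trace()] of length >= 1 (or a single fragment).
#' @param threshold a [calibrate_threshold()] result (or a number).
#' @param sugar_target,phosphate_target the fingerprint targets used for
#'   scoring (defaults from [default_targets()]).
#' @param max_len safety bound on the chain length.
#' @return the grown [chain_trace()].
#' @export
grow_chain <- function(grid, db, seed, threshold,
                       sugar_target = NULL, phosphate_target = NULL,
                       max_len = 1000L) {
  if (is.matrix(seed)) seed <- chain_trace(list(seed))
  if (is.numeric(threshold)) threshold <- list(value = threshold)
  targets <- .resolve_targets(sugar_target, phosphate_target)
  nts <- seed$nucleotides
  scores <- seed$scores
  if (all(is.na(scores)))
    scores <- vapply(nts, function(f)
      score_fragment_sugar(grid, targets$sugar, f), numeric(1))
  seed_index <- seed$seed_index
  open3 <- TRUE; open5 <- TRUE
  turn3 <- TRUE
  while ((open3 || open5) && length(nts) < max_len) {
    dir3 <- if (open3 && (turn3 || !open5)) TRUE else FALSE
    turn3 <- !turn3
    terminal <- if (dir3) nts[[length(nts)]] else nts[[1]]
    cands <- query_extensions(db, terminal, if (dir3) "3" else "5")
    accepted <- FALSE
    if (length(cands)) {
      ssug <- vapply(cands, function(cn)
        score_fragment_sugar(grid, targets$sugar, cn$nucleotide), numeric(1))
      sphos <- vapply(cands, function(cn)
        score_fragment_phosphate(grid, targets$phosphate, cn$phosphate), numeric(1))
      total <- ssug + sphos
      c1 <- .trace_c1(chain_trace(nts))
      # stop rule: a sugar must beat the threshold; anti-backtrack: its C1'
      # must be >= 3 A from every C1' already in the trace
      viable <- which(ssug > threshold$value)
      viable <- viable[vapply(viable, function(q) {
        newc1 <- cands[[q]]$nucleotide["C1'", ]
        min(sqrt(rowSums(sweep(c1, 2, newc1)^2))) >= 3
      }, logical(1))]
      if (length(viable)) {
        q <- viable[which.max(total[viable])]
        nb <- cands[[q]]$nucleotide
        phos <- cands[[q]]$phosphate
        if (dir3) {
          nts[[length(nts) + 1L]] <- nb
          scores <- c(scores, ssug[q])
        } else {
          # the database conformation also fixes the terminal's phosphate
          nts[[1]][c("P", "OP1", "OP2", "O5'"), ] <-
            phos[c("P", "OP1", "OP2", "O5'"), ]
          nts <- c(list(nb), nts)
          scores <- c(ssug[q], scores)
          seed_index <- seed_index + 1L
        }
        accepted <- TRUE
      }
    }
    if (!accepted) {
      if (dir3) open3 <- FALSE else open5 <- FALSE
    }
  }
  chain_trace(nts, scores, seed_index)
}

#' Drop traces shorter than a minimum length
#'
#' Candidate fragments that fail to grow to at least `min_len` nucleotides
#' (default three) are rejected.
#'
#' @param traces list of [chain_trace()] objects.
#' @param min_len minimum retained length.
#' @return filtered list, order preserved.
#' @export
filter_short <- function(traces, min_len = 3L) {
  traces[vapply(traces, function(tr) length(tr$nucleotides) >= min_len,
                logical(1))]
}

# best same-direction alignment between two traces: returns the shift s
# such that B[j] matches A[j + s], with the length of the longest
# consecutive matched run, or NULL
.trace_alignment <- function(a_c1, b_c1, radius) {
  na <- nrow(a_c1); nb <- nrow(b_c1)
  best <- NULL
  for (s in (1 - nb):(na - 1)) {
    js <- seq_len(nb)
    is <- js + s
    ok <- is >= 1 & is <= na
    if (sum(ok) < 2) next
    d <- sqrt(rowSums((a_c1[is[ok], , drop = FALSE] -
                       b_c1[js[ok], , drop = FALSE])^2))
    m <- d < radius
    # longest consecutive run
    run <- 0; cur <- 0
    for (v in m) { cur <- if (v) cur + 1 else 0; run <- max(run, cur) }
    if (run >= 2 && (is.null(best) || run > best$run))
      best <- list(shift = s, run = run, matched = js[ok][m])
  }
  best
}

#' Merge overlapping chain traces
#'
#' Traces sharing at least two consecutive nucleotides (C1' within
#' `match_radius`, same 5' to 3' direction) are unioned. Merging is
#' score-greedy: traces are taken in order of decreasing total score, and
#' a lower-scoring trace can only extend the ends of the chain it overlaps
#' -- where it diverges inside the higher-scoring chain (a branch), the
#' higher-scoring continuation wins and the branch is dropped. The output
#' is pairwise non-overlapping and never contains more nucleotides than
#' the input.
#'
#' @param traces list of [chain_trace()] objects.
#' @param match_radius C1' matching radius in Angstrom (default 1.0).
#' @return merged list, sorted by total score (decreasing).
#' @export
merge_traces <- function(traces, match_radius = 1.0) {
  if (length(traces) <= 1L) return(traces)
  tot <- vapply(traces, function(tr) sum(tr$scores, na.rm = TRUE), numeric(1))
  traces <- traces[order(-tot)]
  out <- list()
  for (tr in traces) {
    merged <- FALSE
    for (q in seq_along(out)) {
      base <- out[[q]]
      al <- .trace_alignment(.trace_c1(base), .trace_c1(tr), match_radius)
      if (is.null(al)) next
      nb <- length(base$nucleotides); ntr <- length(tr$nucleotides)
      # 5' extension: B positions mapping before base position 1
      pre <- which(seq_len(ntr) + al$shift < 1)
      # only take the contiguous run leading into the matched region
      if (length(pre) && max(pre) + 1 %in% al$matched) {
        base$nucleotides <- c(tr$nucleotides[pre], base$nucleotides)
        base$scores <- c(tr$scores[pre], base$scores)
        base$seed_index <- base$seed_index + length(pre)
      }
      post <- which(seq_len(ntr) + al$shift > nb)
      if (length(post) && min(post) - 1 %in% al$matched) {
        base$nucleotides <- c(base$nucleotides, tr$nucleotides[post])
        base$scores <- c(base$scores, tr$scores[post])
      }
      out[[q]] <- base
      merged <- TRUE
      break
    }
    if (!merged) out[[length(out) + 1L]] <- tr
  }
  tot <- vapply(out, function(tr) sum(tr$scores, na.rm = TRUE), numeric(1))
  out[order(-tot)]
}

.resolve_targets <- function(sugar_target, phosphate_target) {
  if (is.null(sugar_target) || is.null(phosphate_target)) {
    dft <- default_targets()
    if (is.null(sugar_target)) sugar_target <- dft$sugar
    if (is.null(phosphate_target)) phosphate_target <- dft$phosphate
  }
  list(sugar = sugar_target, phosphate = phosphate_target)
}

#' Find and trace nucleotide chains around a view centre
#'
#' Runs the pruned fingerprint search for both targets, converts sugar
#' hits to nucleoside seeds and phosphate hits to binucleotide seeds,
#' grows every non-redundant seed in both directions against a threshold
#' calibrated on the same map, rejects traces shorter than `min_chain`
#' and merges the rest.
#'
#' @param grid a [density_grid()].
#' @param db a [build_database()] result.
#' @param center view centre (Angstrom); ignored when `whole_cell`.
#' @param radius search radius (Angstrom, default 6).
#' @param step_deg rotation search step (default 18).
#' @param n_best best-list size per target (default 50).
#' @param threshold_samples random placements for calibration (default
#'   100000).
#' @param tail_prob calibration exceedance probability (default 0.001).
#' @param min_chain minimum chain length kept (default 3).
#' @param seed RNG seed for the calibration stage.
#' @param sugar_target,phosphate_target fingerprint targets (defaults from
#'   [default_targets()]).
#' @param use_phosphate include phosphate-derived seeds (`TRUE`; disabling
#'   mirrors the ablation of dropping the phosphate target from seeding).
#' @param whole_cell search every grid node.
#' @return list of [chain_trace()] objects sorted by total score; the
#'   calibrated threshold is attached as attribute `threshold`.
#' @export
trace_all <- function(grid, db, center = NULL, radius = 6, step_deg = 18,
                      n_best = 50, threshold_samples = 100000,
                      tail_prob = 0.001, min_chain = 3L, seed = 1,
                      sugar_target = NULL, phosphate_target = NULL,
                      use_phosphate = TRUE, whole_cell = FALSE) {
  targets <- .resolve_targets(sugar_target, phosphate_target)
  if (is.null(center)) {
    center <- grid$origin + grid$cell / 2
    if (!whole_cell) stop("center is required unless whole_cell = TRUE")
  }
  rotations <- sample_rotations(step_deg)
  hits_s <- search_local(grid, targets$sugar, center, radius, step_deg,
                         n_best, rotations, whole_cell)
  hits_p <- if (use_phosphate)
    search_local(grid, targets$phosphate, center, radius, step_deg,
                 n_best, rotations, whole_cell)
  else list()
  if (length(hits_s) + length(hits_p) == 0L) return(list())
  thr <- calibrate_threshold(grid, targets$sugar, threshold_samples,
                             tail_prob, seed)
  seeds <- c(
    lapply(hits_s, function(h) {
      tr <- chain_trace(list(seed_from_sugar(db, h, targets$sugar)))
      attr(tr, "hit_score") <- h$score_mean
      tr
    }),
    lapply(hits_p, function(h) {
      pair <- seed_from_phosphate(db, h, grid, targets$phosphate, targets$sugar)
      tr <- chain_trace(pair)
      attr(tr, "hit_score") <- h$score_mean
      tr
    }))
  seeds <- seeds[order(-vapply(seeds, function(s) attr(s, "hit_score"), numeric(1)))]
  traces <- list()
  built_c1 <- NULL
  for (sd in seeds) {
    c1 <- .trace_c1(sd)
    if (!is.null(built_c1)) {
      dmin <- apply(c1, 1, function(p)
        min(sqrt(rowSums(sweep(built_c1, 2, p)^2))))
      if (all(dmin < 1.5)) next   # seed already covered by a built trace
    }
    tr <- grow_chain(grid, db, sd, thr, targets$sugar, targets$phosphate)
    traces[[length(traces) + 1L]] <- tr
    # only chains that pass the length filter suppress later seeds
    if (length(tr$nucleotides) >= min_chain)
      built_c1 <- rbind(built_c1, .trace_c1(tr))
  }
  traces <- filter_short(traces, min_chain)
  traces <- merge_traces(traces)
  attr(traces, "threshold") <- thr
  traces
}

#' Write chain traces as a PDB file
#'
#' Chains are labelled sequentially, residues numbered 5' to 3'. Bases are
#' not assigned: every residue is written as U with a REMARK noting this.
#'
#' @param traces list of [chain_trace()] objects.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_trace_pdb <- function(traces, path) {
  lines <- c("REMARK   3 UNASSIGNED BASE TYPES: ALL RESIDUES WRITTEN AS U")
  chains <- c(LETTERS, letters, 0:9)
  serial <- 0L
  for (ci in seq_along(traces)) {
    tr <- traces[[ci]]
    for (ri in seq_along(tr$nucleotides)) {
      f <- tr$nucleotides[[ri]]
      for (ai in seq_len(nrow(f))) {
        serial <- serial + 1L
        nm <- rownames(f)[ai]
        el <- substr(gsub("[^A-Za-z].*$", "", nm), 1, 1)
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, "U", chains[(ci - 1) %% length(chains) + 1], ri,
          f[ai, 1], f[ai, 2], f[ai, 3], 1.0, 20.0, el))
      }
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
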