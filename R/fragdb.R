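## Nucleotide conformer database: construction from a reference structure,
## ensemble pruning, rigid-body superposition, and conversion of search
## hits into nucleoside / binucleotide seeds.

.nt_resnames <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT", "T", "I")
.mainchain_atoms <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                      "C3'", "O3'", "C2'", "C1'")

#' Validate a nucleotide fragment
#'
#' A fragment is a named coordinate matrix holding the main-chain atoms of
#' one nucleotide. The five sugar-ring atoms must be present and the ring
#' bond lengths chemically plausible.
#'
#' @param fragment named coordinate matrix.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_fragment <- function(fragment) {
  if (!all(.ring_atoms %in% rownames(fragment)))
    stop("missing sugar-ring atoms: ",
         paste(setdiff(.ring_atoms, rownames(fragment)), collapse = ", "))
  ring <- fragment[.ring_atoms, ]
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))
  d <- sqrt(rowSums((ring[bonds[, 1], ] - ring[bonds[, 2], ])^2))
  if (any(d < 1.3 | d > 1.7))
    stop("sugar-ring bond length outside [1.3, 1.7] Angstrom")
  invisible(TRUE)
}

#' Build a nucleotide conformer database
#'
#' One entry per nucleotide with its main-chain atoms; chain adjacency is
#' recorded wherever consecutive residues are covalently plausible
#' (O3'-P distance below 2.0 Angstrom). Residues missing sugar-ring atoms
#' are skipped with a warning.
#'
#' @param reference a path to a PDB file, a `bio3d` pdb object, or a list
#'   of nucleotide fragments in chain order (adjacency inferred from
#'   O3'-P distances).
#' @return object of class `fragment_db` with fields `nucleotides`,
#'   `next_idx`, `prev_idx` and `size`.
#' @export
build_database <- function(reference) {
  frags <- if (is.character(reference)) {
    .fragments_from_pdb(bio3d::read.pdb(reference))
  } else if (inherits(reference, "pdb")) {
    .fragments_from_pdb(reference)
  } else if (is.list(reference)) {
    reference
  } else stop("unsupported reference type")
  keep <- vapply(frags, function(f) {
    ok <- tryCatch({ validate_fragment(f); TRUE }, error = function(e) FALSE)
    if (!ok) warning("skipping residue ", attr(f, "source_id"),
                     ": incomplete or distorted sugar ring", call. = FALSE)
    ok
  }, logical(1))
  frags <- frags[keep]
  n <- length(frags)
  if (n == 0L) stop("no usable nucleotides found in reference")
  next_idx <- rep(NA_integer_, n)
  prev_idx <- rep(NA_integer_, n)
  for (i in seq_len(n - 1L)) {
    a <- frags[[i]]; b <- frags[[i + 1L]]
    if ("O3'" %in% rownames(a) && "P" %in% rownames(b)) {
      if (sqrt(sum((a["O3'", ] - b["P", ])^2)) < 2.0) {
        next_idx[i] <- i + 1L
        prev_idx[i + 1L] <- i
      }
    }
  }
  structure(list(nucleotides = frags, next_idx = next_idx,
                 prev_idx = prev_idx, size = n),
            class = "fragment_db")
}

#' @export
print.fragment_db <- function(x, ...) {
  cat(sprintf("fragment_db: %d nucleotides, %d adjacent pairs\n",
              x$size, sum(!is.na(x$next_idx))))
  invisible(x)
}

# extract nucleotide fragments (named coordinate matrices) from a bio3d pdb
.fragments_from_pdb <- function(pdb) {
  at <- pdb$atom
  nt <- at[at$resid %in% .nt_resnames & at$type == "ATOM", ]
  if (nrow(nt) == 0L) stop("no nucleotide residues found")
  key <- paste(nt$chain, nt$resno, nt$insert)
  split_idx <- split(seq_len(nrow(nt)), factor(key, levels = unique(key)))
  lapply(split_idx, function(ix) {
    rows <- nt[ix, ]
    nm <- gsub("\\*", "'", rows$elety)    # old-style primes
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    rownames(xyz) <- nm
    colnames(xyz) <- c("x", "y", "z")
    xyz <- xyz[!duplicated(nm), , drop = FALSE]
    attr(xyz, "source_id") <- sprintf("%s:%s%s", rows$chain[1], rows$resno[1],
                                      trimws(rows$insert[1] %||% ""))
    xyz
  })
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Iteratively prune conformers far from the ensemble mean
#'
#' Computes the ensemble mean position of the probe atom(s) over fragments
#' already superposed on the conserved atoms of the search fragment, then
#' repeatedly removes the single worst fragment whose probe-atom deviation
#' exceeds `cutoff` and recomputes, until none exceeds. Used with O2' for
#' sugar ensembles and C5' + C3' for phosphate ensembles.
#'
#' @param fragments list of superposed fragments.
#' @param probe_atom character vector of probe atom name(s).
#' @param cutoff deviation cutoff in Angstrom (default 1.0).
#' @return the retained fragments (original order preserved).
#' @export
prune_ensemble <- function(fragments, probe_atom, cutoff = 1.0) {
  if (length(fragments) == 0L) stop("empty fragment list")
  repeat {
    dev <- rep(0, length(fragments))
    for (a in probe_atom) {
      xyz <- t(vapply(fragments, function(g) g[a, ], numeric(3)))
      dev <- pmax(dev, sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
    }
    worst <- which.max(dev)
    if (dev[worst] <= cutoff || length(fragments) == 1L) break
    fragments <- fragments[-worst]
  }
  fragments
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `moving` onto `fixed` (matched by row order; both must have >= 3 rows).
#' Reflections are refused: the rotation determinant is always +1, so a
#' mirrored point set fits with non-zero residual.
#'
#' @param moving,fixed n x 3 coordinate matrices.
#' @return a [placement()] with an `rmsd` field attached.
#' @export
superpose_rigid <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("atom counts differ")
  if (nrow(moving) < 3L) stop("need at least 3 atoms")
  mc <- colMeans(moving); fc <- colMeans(fixed)
  P <- sweep(moving, 2, mc); Q <- sweep(fixed, 2, fc)
  s <- svd(crossprod(P, Q))             # H = P^T Q
  dsign <- sign(det(s$v %*% t(s$u)))
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    warning("degenerate (collinear) point set in superposition")
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  t <- fc - as.vector(R %*% mc)
  moved <- sweep(moving %*% t(R), 2, -t)
  pl <- placement(R, t)
  pl$rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  pl
}

# apply a placement's rigid motion to a coordinate matrix
apply_placement <- function(placement, xyz) {
  out <- sweep(as.matrix(xyz) %*% t(placement$rotation), 2,
               -placement$translation)
  rownames(out) <- rownames(xyz)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Convert a sugar search hit into a nucleoside seed
#'
#' Places the target's template nucleotide by the hit's rotation and
#' translation. The terminal phosphate is in an arbitrary conformation at
#' this stage (the fitted part is a nucleoside); growth replaces it.
#'
#' @param db a [build_database()] result (part of the seeding interface;
#'   the sugar path places the template directly).
#' @param hit a [placement()] from [search_local()] with the sugar target.
#' @param sugar_target the sugar [fingerprint_target()] carrying the
#'   template in `frame_fragment`.
#' @return a nucleotide fragment.
#' @export
seed_from_sugar <- function(db, hit, sugar_target) {
  tmpl <- sugar_target$frame_fragment
  if (is.null(tmpl)) stop("sugar target carries no frame template")
  out <- apply_placement(hit, tmpl)
  attr(out, "source_id") <- "seed:sugar"
  out
}

#' Convert a phosphate search hit into a binucleotide seed
#'
#' Every adjacent nucleotide pair in the database is superposed, via its
#' intervening phosphate group (P, OP1, OP2, O5' of the 3' member plus O3'
#' of the 5' member), onto the hit-placed phosphate template. Both flanking
#' sugars of each candidate are scored against the map with the
#' interpolated `s_mean` sugar score; the best-scoring pair is returned
#' (ties: lowest database index).
#'
#' @param db a [build_database()] result with at least one adjacent pair.
#' @param hit a [placement()] from [search_local()] with the phosphate
#'   target.
#' @param grid the [density_grid()] being interpreted.
#' @param phosphate_target the phosphate [fingerprint_target()] (frame
#'   template of the five phosphate-group atoms).
#' @param sugar_target the sugar [fingerprint_target()] used for scoring.
#' @return list of two nucleotide fragments (5' then 3'), with the summed
#'   sugar score in attribute `score`.
#' @export
seed_from_phosphate <- function(db, hit, grid, phosphate_target, sugar_target) {
  pairs <- which(!is.na(db$next_idx))
  if (length(pairs) == 0L) stop("database has no adjacent pairs")
  anchor <- apply_placement(hit, phosphate_target$frame_fragment)
  best <- NULL; best_score <- -Inf
  for (i in pairs) {
    j <- db$next_idx[i]
    a <- db$nucleotides[[i]]; b <- db$nucleotides[[j]]
    if (!all(c("P", "OP1", "OP2", "O5'") %in% rownames(b))) next
    grp <- rbind(b[c("P", "OP1", "OP2", "O5'"), ], "O3'" = a["O3'", ])
    fit <- superpose_rigid(grp, anchor[rownames(grp), ])
    ta <- apply_placement(fit, a); tb <- apply_placement(fit, b)
    sc <- score_fragment_sugar(grid, sugar_target, ta) +
      score_fragment_sugar(grid, sugar_target, tb)
    if (sc > best_score) {
      best_score <- sc
      attr(ta, "source_id") <- sprintf("seed:phosphate:%d", i)
      attr(tb, "source_id") <- sprintf("seed:phosphate:%d", j)
      best <- list(ta, tb)
    }
  }
  if (is.null(best)) stop("no scorable adjacent pair in database")
  attr(best, "score") <- best_score
  best
}

#' Score a placed sugar ring with the sugar fingerprint
#'
#' Superposes the target's template ring onto the fragment's ring and
#' evaluates the interpolated `s_mean`.
#'
#' @param grid a [density_grid()].
#' @param sugar_target the sugar [fingerprint_target()].
#' @param fragment nucleotide fragment (or any matrix with the five ring
#'   atoms as rows).
#' @return numeric `s_mean`.
#' @export
score_fragment_sugar <- function(grid, sugar_target, fragment) {
  ring_ref <- sugar_target$frame_fragment[.ring_atoms, ]
  fit <- superpose_rigid(ring_ref, fragment[.ring_atoms, ])
  score_mean(sugar_target, grid, fit, interpolated = TRUE)
}

#' Score a placed phosphate group with the phosphate fingerprint
#'
#' @param grid a [density_grid()].
#' @param phosphate_target the phosphate [fingerprint_target()].
#' @param group coordinate matrix with rows P, OP1, OP2, O5', O3'.
#' @return numeric `s_mean`.
#' @export
score_fragment_phosphate <- function(grid, phosphate_target, group) {
  ref <- phosphate_target$frame_fragment[.phosphate_atoms, ]
  fit <- superpose_rigid(ref, group[.phosphate_atoms, ])
  score_mean(phosphate_target, grid, fit, interpolated = TRUE)
}

#' Candidate chain extensions from the database
#'
#' For every database nucleotide with a neighbour in the requested
#' direction, superposes its sugar ring onto the terminal sugar and emits
#' the transformed neighbour together with the intervening phosphate group.
#'
#' @param db a [build_database()] result.
#' @param terminal_sugar coordinate matrix with the five ring atoms of the
#'   chain terminus.
#' @param direction `"3"` to extend past the 3' end, `"5"` for the 5' end.
#' @return list of candidates, each a list with `nucleotide` (the
#'   transformed next/previous nucleotide), `phosphate` (the intervening
#'   P, OP1, OP2, O5', O3' group), `db_index` and `rmsd`.
#' @export
query_extensions <- function(db, terminal_sugar, direction = c("3", "5")) {
  direction <- match.arg(direction)
  if (db$size == 0L) stop("empty database")
  idx <- if (direction == "3") which(!is.na(db$next_idx)) else which(!is.na(db$prev_idx))
  out <- list()
  for (i in idx) {
    j <- if (direction == "3") db$next_idx[i] else db$prev_idx[i]
    a <- db$nucleotides[[i]]   # matches the terminal
    b <- db$nucleotides[[j]]   # the emitted neighbour
    pgrp_owner <- if (direction == "3") b else a
    pgrp_other <- if (direction == "3") a else b
    if (!all(c("P", "OP1", "OP2", "O5'") %in% rownames(pgrp_owner))) next
    if (!("O3'" %in% rownames(pgrp_other))) next
    fit <- superpose_rigid(a[.ring_atoms, ], terminal_sugar[.ring_atoms, ])
    nb <- apply_placement(fit, b)
    attr(nb, "source_id") <- attr(b, "source_id")
    phos <- rbind(apply_placement(fit, pgrp_owner[c("P", "OP1", "OP2", "O5'"), ]),
                  "O3'" = apply_placement(fit, pgrp_other["O3'", , drop = FALSE])["O3'", ])
    out[[length(out) + 1L]] <- list(nucleotide = nb, phosphate = phos,
                                    db_index = i, rmsd = fit$rmsd)
  }
  out
}
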