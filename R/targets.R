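## Default fingerprint targets: derivation from synthetic conformer
## ensembles, JSON serialization and the shipped fixture.

#' Derive the default sugar and phosphate targets from synthetic ensembles
#'
#' Builds an ensemble of perturbed trinucleotides, superposes each member
#' on the conserved atoms of the search fragment (the sugar ring, or the
#' phosphate group with its bridging O3'), prunes uncommon conformers
#' (O2' for sugars, C5'/C3' for phosphates, 1 Angstrom from the ensemble
#' mean), synthesizes a local density map per member, and derives probe
#' points from the pointwise minimum and maximum maps.
#'
#' @param n_ensemble ensemble size (default 50).
#' @param amplitude RMS perturbation amplitude in Angstrom.
#' @param seed RNG seed.
#' @param spacing local map grid step.
#' @param radius low-probe search radius around the fragment centre.
#' @param min_sep minimum low-probe separation.
#' @return list with elements `sugar` and `phosphate`
#'   ([fingerprint_target()] objects); ensemble min/max maps are attached
#'   as attributes `maps_sugar` and `maps_phosphate`.
#' @export
derive_default_targets <- function(n_ensemble = 50, amplitude = 0.25,
                                   seed = 42, spacing = 0.5, radius = 6,
                                   min_sep = 1.5) {
  frags <- make_helix(helix_spec(3))
  tri <- do.call(rbind, frags)           # 39 atoms, duplicated names
  members <- perturb_ensemble(tri, n_ensemble, amplitude, seed)
  names(members) <- sprintf("m%03d", seq_along(members))
  nat <- nrow(frags[[1]])
  rows_mid <- (nat + 1):(2 * nat)
  hw <- 10                                # local half-width, Angstrom
  c0 <- rep(hw, 3)

  build_target <- function(kind) {
    if (kind == "sugar") {
      ref_frame <- frags[[2]][.ring_atoms, ]
      prune_atoms <- "O2'"
      high_names <- c("C1'", "C2'", "C3'", "C4'", "O4'", "C5'", "O3'", "N9")
    } else {
      ref_frame <- rbind(frags[[2]][c("P", "OP1", "OP2", "O5'"), ],
                         "O3'" = frags[[1]]["O3'", ])
      prune_atoms <- c("C5'", "C3'")
      high_names <- c("P", "OP1", "OP2", "O5'", "O3'")
    }
    ctr <- colMeans(ref_frame)
    ref_local <- sweep(ref_frame, 2, ctr - c0)   # frame centre at c0
    # superpose every member onto the reference frame
    locals <- lapply(members, function(m) {
      mm <- m
      rownames(mm) <- rownames(tri)
      mov <- if (kind == "sugar") mm[rows_mid, ][.ring_atoms, ]
        else rbind(mm[rows_mid, ][c("P", "OP1", "OP2", "O5'"), ],
                   "O3'" = mm[1:nat, ]["O3'", ])
      fit <- superpose_rigid(mov, ref_local)
      apply_placement(fit, mm)
    })
    # fragment view used for conformer pruning
    frag_view <- lapply(locals, function(l) {
      mid <- l[rows_mid, ]; rownames(mid) <- rownames(frags[[2]])
      pre <- l[1:nat, ]; rownames(pre) <- rownames(frags[[1]])
      if (kind == "sugar") mid
      else rbind(mid[c("P", "OP1", "OP2", "O5'", "C5'"), ],
                 pre[c("O3'", "C3'"), ])
    })
    kept <- names(prune_ensemble(frag_view, prune_atoms, cutoff = 1.0))
    locals <- locals[kept]
    maps <- lapply(locals, function(l) {
      atoms <- atom_records(rownames(l), l, b_iso = 20)
      density_from_atoms(atoms, cell = rep(2 * hw, 3), spacing = spacing)
    })
    mm <- ensemble_minmax(maps)
    # high probes: ensemble-mean positions of the named atoms of the
    # middle nucleotide (O3' of the previous one for the phosphate target)
    mean_atom <- function(a, from_prev = FALSE) {
      rows <- if (from_prev) 1:nat else rows_mid
      colMeans(t(vapply(locals, function(l) {
        seg <- l[rows, ]; rownames(seg) <- rownames(frags[[1]])
        seg[a, ]
      }, numeric(3))))
    }
    high <- t(vapply(high_names, function(a)
      mean_atom(a, from_prev = (kind == "phosphate" && a == "O3'")),
      numeric(3)))
    frame_full <- {
      mid_local <- sweep(frags[[2]], 2, ctr - c0)
      sweep(mid_local, 2, c0)   # template relative to fragment centre
    }
    frame <- if (kind == "sugar") frame_full
      else sweep(ref_local, 2, c0)
    tg <- derive_probes(mm$min_map, mm$max_map, high, radius = radius,
                        min_sep = min_sep, center = c0, name = kind,
                        frame_fragment = frame)
    attr(tg, "maps") <- mm
    tg
  }

  sugar <- build_target("sugar")
  phosphate <- build_target("phosphate")
  out <- list(sugar = sugar, phosphate = phosphate)
  attr(out, "maps_sugar") <- attr(sugar, "maps")
  attr(out, "maps_phosphate") <- attr(phosphate, "maps")
  attr(sugar, "maps") <- NULL; attr(phosphate, "maps") <- NULL
  out
}

#' Serialize fingerprint targets to JSON
#'
#' @param targets list with `sugar` and `phosphate` targets.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_targets_json <- function(targets, path) {
  enc <- function(tg) list(
    name = tg$name,
    high_names = rownames(tg$high),
    high = unname(as.matrix(tg$high)),
    low = unname(as.matrix(tg$low)),
    frame_names = rownames(tg$frame_fragment),
    frame = unname(as.matrix(tg$frame_fragment)))
  jsonlite::write_json(lapply(targets, enc), path, digits = 8,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read fingerprint targets from JSON
#'
#' @param path JSON path written by [write_targets_json()].
#' @return list of [fingerprint_target()] objects.
#' @export
read_targets_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(tg) {
    high <- as.matrix(tg$high); rownames(high) <- tg$high_names
    low <- as.matrix(tg$low)
    frame <- as.matrix(tg$frame); rownames(frame) <- tg$frame_names
    colnames(frame) <- c("x", "y", "z")
    fingerprint_target(tg$name, high, low, frame_fragment = frame)
  })
}

#' The default fingerprint targets
#'
#' Loads (and caches) the sugar and phosphate targets shipped with the
#' package. These were derived from synthetic conformer ensembles with
#' [derive_default_targets()]; the file can be regenerated with
#' [write_targets_json()].
#'
#' @return list with `sugar` and `phosphate` [fingerprint_target()]s.
#' @export
default_targets <- function() {
  if (!is.null(.natrace_env$targets)) return(.natrace_env$targets)
  path <- system.file("extdata", "fingerprint_targets_synthetic.json",
                      package = "natrace")
  if (path == "") stop("shipped target fixture not found")
  .natrace_env$targets <- read_targets_json(path)
  .natrace_env$targets
}
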