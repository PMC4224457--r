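## Synthetic fixtures: an idealized ribonucleotide template compatible with
## A-form helical symmetry, helix generation, ensemble perturbation and
## FOM-driven phase-error degradation of maps.

# Idealized ribonucleotide main-chain template (Angstrom), derived from
# ideal monomer geometry and rigidly placed so that the A-form helix
# operator (32.7 deg twist about z, 2.81 A rise) gives an O3'-P link of
# 1.60 A to the next nucleotide, with C1' at 9.5 A and P at 9.4 A from the
# helix axis and no inter-nucleotide contact below 2.4 A. The base is
# represented by its N9 glycosidic anchor only.
.nt_template_xyz <- matrix(c(
   1.5848,  9.2654, 1.5248,   # P
   2.1706, 10.6175, 1.6506,   # OP1
   0.3960,  9.2937, 0.4403,   # OP2
   0.9989,  8.8000, 2.9502,   # O5'
   0.0013,  9.7520, 3.3189,   # C5'
  -0.5976,  9.3673, 4.6726,   # C4'
   0.4216,  9.3772, 5.6953,   # O4'
  -1.6265, 10.4241, 5.1297,   # C3'
  -2.9548,  9.9973, 4.8235,   # O3'
  -1.4236, 10.5094, 6.6593,   # C2'
  -2.6212, 10.1395, 7.3456,   # O2'
  -0.2934,  9.4955, 6.9434,   # C1'
   0.5935, 10.0001, 7.9935),  # N9
  ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                    "C3'", "O3'", "C2'", "O2'", "C1'", "N9"),
                  c("x", "y", "z")))

#' The idealized ribonucleotide template
#'
#' @return named 13 x 3 coordinate matrix (main-chain atoms plus O2' and
#'   the base anchor N9), positioned relative to a helix axis along z.
#' @export
nt_template <- function() .nt_template_xyz

# sugar-ring atom names; these must be present in every database fragment
.ring_atoms <- c("C1'", "C2'", "C3'", "C4'", "O4'")
# atoms defining the phosphate group frame
.phosphate_atoms <- c("P", "OP1", "OP2", "O5'", "O3'")

#' Helix specification
#'
#' @param n_nt nucleotide count (>= 1; >= 2 for a chain).
#' @param twist helical twist in degrees per step (A-form default 32.7).
#' @param rise rise in Angstrom per step (A-form default 2.81).
#' @param seed RNG seed used by downstream perturbations.
#' @param b_iso isotropic B (Angstrom^2) used when synthesizing maps.
#' @return list of class `helix_spec`.
#' @export
helix_spec <- function(n_nt = 12, twist = 32.7, rise = 2.81,
                       seed = 1, b_iso = 20) {
  stopifnot(n_nt >= 1, twist > 0, twist < 360, rise > 0)
  structure(list(n_nt = as.integer(n_nt), twist = twist, rise = rise,
                 seed = seed, b_iso = b_iso), class = "helix_spec")
}

# rotation about z by deg
.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Generate an idealized single-stranded A-form helix
#'
#' Nucleotide i is the template rotated by `(i-1) * twist` about the helix
#' axis (z) and translated by `(i-1) * rise` along it. At the A-form
#' defaults consecutive O3'-P distances are 1.60 A.
#'
#' @param spec a [helix_spec()].
#' @return list of nucleotide fragments (named coordinate matrices) in
#'   5' to 3' order, each carrying a `source_id` attribute.
#' @export
make_helix <- function(spec) {
  stopifnot(inherits(spec, "helix_spec"))
  tmpl <- nt_template()
  lapply(seq_len(spec$n_nt), function(i) {
    R <- .rot_z((i - 1) * spec$twist)
    xyz <- tmpl %*% t(R)
    xyz[, 3] <- xyz[, 3] + (i - 1) * spec$rise
    colnames(xyz) <- c("x", "y", "z")
    attr(xyz, "source_id") <- sprintf("helix:%d", i)
    xyz
  })
}

#' Perturb a nucleotide fragment into an ensemble
#'
#' Returns `n` copies with zero-mean Gaussian atomic displacements of RMS
#' magnitude `amplitude`; sugar-ring atoms are perturbed at half amplitude
#' (the ring is nearly rigid in real conformers).
#'
#' @param fragment named coordinate matrix.
#' @param n ensemble size.
#' @param amplitude RMS displacement magnitude in Angstrom (>= 0).
#' @param seed RNG seed (reproducible).
#' @return list of `n` perturbed fragments.
#' @export
perturb_ensemble <- function(fragment, n, amplitude, seed = 1) {
  stopifnot(amplitude >= 0, n >= 1)
  sd_xyz <- amplitude / sqrt(3)   # per-coordinate sd giving RMS |d| = amplitude
  half <- rownames(fragment) %in% .ring_atoms
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    d <- matrix(rnorm(length(fragment), sd = sd_xyz), nrow = nrow(fragment))
    d[half, ] <- d[half, ] / 2
    out <- fragment + d
    attr(out, "source_id") <- paste0(attr(fragment, "source_id"), ":perturbed", i)
    out
  })
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Solve the von Mises concentration kappa from the mean resultant
# E[cos(dphi)] = m (Best & Fisher approximation).
.vm_kappa <- function(m) {
  m <- pmin(m, 1 - 1e-6)   # m = 1 means kappa -> Inf; keep it finite
  k <- ifelse(m < 0.53, 2 * m + m^3 + 5 * m^5 / 6,
              ifelse(m < 0.85, -0.4 + 1.39 * m + 0.43 / (1 - m),
                     1 / (m^3 - 4 * m^2 + 3 * m)))
  pmax(k, 0)
}

# Vectorized von Mises sampler (Best & Fisher 1979 rejection scheme).
.rvonmises <- function(n, kappa) {
  out <- numeric(n)
  kappa <- rep_len(kappa, n)
  todo <- kappa > 1e-8
  out[!todo] <- runif(sum(!todo), -pi, pi)
  idx <- which(todo)
  k <- kappa[idx]
  tau <- 1 + sqrt(1 + 4 * k^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * k)
  r <- (1 + rho^2) / (2 * rho)
  res <- numeric(length(idx))
  pending <- seq_along(idx)
  while (length(pending)) {
    m <- length(pending)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r[pending] * z) / (r[pending] + z)
    c_ <- k[pending] * (r[pending] - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    ok[is.na(ok)] <- FALSE
    ang <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    res[pending[ok]] <- ang[ok]
    pending <- pending[!ok]
  }
  out[idx] <- res
  out
}

#' Degrade a map by FOM-consistent phase errors
#'
#' Fourier transforms the map, perturbs each coefficient's phase by an
#' angle drawn from a von Mises distribution whose concentration solves
#' `E[cos(dphi)] = fom`, and transforms back. Per-coefficient FOMs are
#' drawn as `mean_fom + N(0, 0.1)`, clipped to `[0, 1]`. Friedel mates
#' receive opposite phase shifts so the map stays real, and self-conjugate
#' (centric-like) coefficients are left unchanged. Amplitudes are preserved
#' exactly.
#'
#' @param grid a [density_grid()].
#' @param mean_fom target mean figure of merit in `[0, 1]` (1 = no error,
#'   0 = random phases).
#' @param seed RNG seed (reproducible).
#' @param fom_jitter standard deviation of the per-coefficient FOM spread.
#' @return degraded [density_grid()] on the same grid.
#' @export
degrade_map <- function(grid, mean_fom, seed = 1, fom_jitter = 0.1) {
  stopifnot(mean_fom >= 0, mean_fom <= 1)
  if (mean_fom >= 1) {           # perfect phases: nothing to perturb
    out <- grid
    attr(out, "phase_shift") <- array(0, dim = dim(grid$values))
    return(out)
  }
  d <- dim(grid$values)
  F <- fft(grid$values)
  # canonical half of reciprocal space: pair h with -h (mod n)
  idx <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  conj_i <- (d[1] - idx$i) %% d[1]
  conj_j <- (d[2] - idx$j) %% d[2]
  conj_k <- (d[3] - idx$k) %% d[3]
  lin <- 1 + idx$i + d[1] * (idx$j + d[2] * idx$k)
  lin_conj <- 1 + conj_i + d[1] * (conj_j + d[2] * conj_k)
  self <- lin == lin_conj
  canon <- !self & lin < lin_conj
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nc <- sum(canon)
  fom <- pmin(pmax(mean_fom + rnorm(nc, sd = fom_jitter), 0), 1)
  dphi <- .rvonmises(nc, .vm_kappa(fom))
  ph <- numeric(prod(d))
  ph[lin[canon]] <- dphi
  ph[lin_conj[canon]] <- -dphi
  Fv <- as.vector(F) * exp(1i * ph)
  out <- Re(fft(array(Fv, dim = d), inverse = TRUE)) / prod(d)
  g <- density_grid(out, grid$spacing, grid$origin)
  attr(g, "phase_shift") <- array(ph, dim = d)
  g
}

#' Build an atom table from nucleotide fragments
#'
#' @param fragments list of named coordinate matrices.
#' @param b_iso isotropic B applied to every atom.
#' @return an [atom_records()] data frame (element from atom-name prefix).
#' @export
fragments_to_atoms <- function(fragments, b_iso = 20) {
  xyz <- do.call(rbind, fragments)
  atom_records(rownames(xyz), xyz, b_iso = b_iso)
}

#' Synthesize a map fixture from a helix
#'
#' Generates an A-form helix, shifts it so every atom is at least `pad`
#' Angstrom from the cell edges, synthesizes the Gaussian-atom density and
#' optionally degrades it with phase errors.
#'
#' @param spec a [helix_spec()].
#' @param spacing grid step (Angstrom).
#' @param pad clearance between model and cell edge (Angstrom).
#' @param fom mean figure of merit; 1 leaves the map noise-free.
#' @return list with `grid` (the possibly degraded map), `clean_grid`,
#'   `fragments` (shifted coordinates) and `atoms`.
#' @export
make_fixture <- function(spec, spacing = 0.5, pad = 6, fom = 1.0) {
  frags <- make_helix(spec)
  atoms <- fragments_to_atoms(frags, b_iso = spec$b_iso)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  shift <- -lo
  cell <- hi - lo
  atoms$x <- atoms$x + shift[1]
  atoms$y <- atoms$y + shift[2]
  atoms$z <- atoms$z + shift[3]
  frags <- lapply(frags, function(f) {
    out <- sweep(f, 2, -shift)
    attr(out, "source_id") <- attr(f, "source_id")
    out
  })
  grid <- density_from_atoms(atoms, cell, spacing = spacing)
  clean <- grid
  if (fom < 1) grid <- degrade_map(grid, fom, seed = spec$seed)
  list(grid = grid, clean_grid = clean, fragments = frags, atoms = atoms)
}
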