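## Electron-density grids: construction, synthesis from atoms,
## interpolation and ensemble min/max maps.
##
## A density grid is a scalar field on a regular 3D grid over an orthogonal
## P1 cell. Node (i, j, k) (zero-based) sits at origin + (i, j, k) * spacing
## and indexing wraps periodically: the grid tiles the cell.

#' Construct a density grid
#'
#' @param values 3D numeric array of density values (arbitrary map units).
#' @param spacing grid step in Angstrom, scalar or length-3.
#' @param origin Cartesian position (Angstrom) of grid node (0, 0, 0).
#' @return An object of class `density_grid` with fields `values`, `cell`
#'   (box edge lengths, `dim * spacing`), `spacing`, `origin`, and the map
#'   statistics `mean` and `sigma` (population standard deviation over the
#'   whole grid, as used by the search pruning rule).
#' @export
density_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  storage.mode(values) <- "double"
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  structure(list(values = values,
                 cell = dim(values) * spacing,
                 spacing = spacing,
                 origin = as.numeric(origin),
                 mean = m, sigma = s),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d x %d nodes, spacing %.3g/%.3g/%.3g A\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  cell %.2f x %.2f x %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$cell[1], x$cell[2], x$cell[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  mean %.4g, sigma %.4g\n", x$mean, x$sigma))
  invisible(x)
}

# electron counts for the elements that occur in nucleic-acid main chains
.electrons <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

#' Atom records
#'
#' Plumbing helper: a data frame of atoms with PDB-style names, element,
#' Cartesian coordinates, isotropic B and occupancy.
#'
#' @param name atom names (PDB convention, e.g. `"C1'"`).
#' @param pos n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param element element symbols; guessed from the first letter of the
#'   atom name when missing.
#' @param b_iso isotropic displacement parameter(s) in Angstrom^2.
#' @param occupancy occupancies in `[0, 1]`.
#' @return data frame with columns name, element, x, y, z, b_iso, occupancy.
#' @export
atom_records <- function(name, pos, element = NULL, b_iso = 20, occupancy = 1) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  if (is.null(element)) element <- substr(gsub("[^A-Za-z].*$", "", name), 1, 1)
  b_iso <- rep_len(b_iso, length(name))
  occupancy <- rep_len(occupancy, length(name))
  if (any(b_iso <= 0)) stop("b_iso must be > 0")
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must be in [0, 1]")
  data.frame(name = name, element = element,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             b_iso = b_iso, occupancy = occupancy,
             stringsAsFactors = FALSE)
}

#' Synthesize a density map from an atomic model
#'
#' Each atom contributes a single isotropic Gaussian of integrated weight
#' `occupancy * Z` (Z = element electron count) and variance
#' `b_iso / (8 pi^2) + sigma_res^2`, where `sigma_res` is an effective
#' resolution blur. Contributions are truncated at 4.5 Angstrom and wrapped
#' periodically over the cell.
#'
#' @param atoms data frame from [atom_records()].
#' @param cell orthogonal box edge lengths (Angstrom), length 3.
#' @param spacing requested grid step (<= 1 Angstrom); the actual step is
#'   `cell / round(cell / spacing)` so the grid tiles the cell exactly.
#' @param sigma_res resolution blur in Angstrom (default 0.8, mimicking
#'   maps at roughly 2.5 Angstrom resolution).
#' @return A [density_grid()].
#' @export
density_from_atoms <- function(atoms, cell, spacing = 0.5, sigma_res = 0.8) {
  if (nrow(atoms) == 0L) stop("empty atom list")
  if (any(spacing > 1.0)) stop("spacing must be <= 1.0 Angstrom")
  cell <- rep_len(as.numeric(cell), 3L)
  n <- pmax(2L, as.integer(round(cell / rep_len(spacing, 3L))))
  sp <- cell / n
  vals <- array(0, dim = n)
  cutoff <- 4.5
  m <- floor(cutoff / sp)   # node half-extent of the truncated Gaussian
  offs <- lapply(1:3, function(a) (-m[a]):(m[a]))
  for (ai in seq_len(nrow(atoms))) {
    z <- unname(.electrons[atoms$element[ai]])
    if (is.na(z)) stop("unknown element: ", atoms$element[ai])
    var <- atoms$b_iso[ai] / (8 * pi^2) + sigma_res^2
    amp <- atoms$occupancy[ai] * z / (2 * pi * var)^1.5
    p <- c(atoms$x[ai], atoms$y[ai], atoms$z[ai])
    ctr <- round(p / sp)                  # nearest node (unwrapped)
    dx2 <- lapply(1:3, function(a) ((ctr[a] + offs[[a]]) * sp[a] - p[a])^2)
    r2 <- outer(outer(dx2[[1]], dx2[[2]], `+`), dx2[[3]], `+`)
    w <- amp * exp(-r2 / (2 * var))
    w[r2 > cutoff^2] <- 0
    ii <- (ctr[1] + offs[[1]]) %% n[1]
    jj <- (ctr[2] + offs[[2]]) %% n[2]
    kk <- (ctr[3] + offs[[3]]) %% n[3]
    idx <- as.vector(outer(outer(ii + 1L, jj * n[1], `+`), kk * n[1] * n[2], `+`))
    # wrapped indices may repeat when the cutoff box exceeds the cell
    acc <- rowsum(as.vector(w), idx)
    tgt <- as.integer(rownames(acc))
    vals[tgt] <- vals[tgt] + acc[, 1]
  }
  density_grid(vals, sp, origin = c(0, 0, 0))
}

#' Trilinear density interpolation (periodic)
#'
#' @param grid a [density_grid()].
#' @param pos a length-3 position or an n x 3 matrix of Cartesian positions.
#' @return interpolated density value(s); exact at grid nodes.
#' @export
interp_density <- function(grid, pos) {
  pos <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
  cpp_interp(grid$values, dim(grid$values), grid$spacing,
             grid$origin, pos)
}

#' Nearest-node density lookup (periodic)
#'
#' Fast-path density access used by the pruned search: the position is
#' rounded to the nearest grid vector and the stored node value is returned
#' without interpolation.
#'
#' @inheritParams interp_density
#' @return stored node value(s).
#' @export
density_at_node <- function(grid, pos) {
  pos <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
  cpp_nearest(grid$values, dim(grid$values), grid$spacing,
              grid$origin, pos)
}

#' Pointwise minimum and maximum over an ensemble of maps
#'
#' Used to derive fingerprint probe points: a high value in the minimum map
#' marks density conserved across every ensemble member, while a low value
#' in the maximum map marks a conserved hole.
#'
#' @param fragment_maps list of [density_grid()] objects on identical grids.
#' @return list with elements `min_map` and `max_map` (density grids).
#' @export
ensemble_minmax <- function(fragment_maps) {
  if (length(fragment_maps) < 1L) stop("need at least one map")
  g1 <- fragment_maps[[1]]
  for (g in fragment_maps[-1]) {
    if (!identical(dim(g$values), dim(g1$values)) ||
        max(abs(g$spacing - g1$spacing)) > 1e-9 ||
        max(abs(g$origin - g1$origin)) > 1e-9)
      stop("mismatched grid geometry in ensemble")
  }
  vmin <- vmax <- g1$values
  for (g in fragment_maps[-1]) {
    vmin <- pmin(vmin, g$values)
    vmax <- pmax(vmax, g$values)
  }
  list(min_map = density_grid(vmin, g1$spacing, g1$origin),
       max_map = density_grid(vmax, g1$spacing, g1$origin))
}
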