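## Model-vs-reference evaluation: C1' coverage within a cutoff and the
## phosphorus coordinate error.

# pull named-atom coordinates out of traces, fragment lists, bio3d pdb
# objects or plain matrices
.atom_coords <- function(model, name) {
  if (inherits(model, "chain_trace")) model <- model$nucleotides
  if (is.list(model) && length(model) && inherits(model[[1]], "chain_trace"))
    model <- unlist(lapply(model, function(tr) tr$nucleotides),
                    recursive = FALSE)
  if (inherits(model, "pdb")) {
    at <- model$atom
    nm <- gsub("\\*", "'", at$elety)
    sel <- nm == name
    return(as.matrix(at[sel, c("x", "y", "z")]))
  }
  if (is.matrix(model)) {
    return(model[rownames(model) == name, , drop = FALSE])
  }
  if (is.list(model)) {
    rows <- lapply(model, function(f) f[rownames(f) == name, , drop = FALSE])
    return(do.call(rbind, rows))
  }
  stop("unsupported model type")
}

.min_dists <- function(from, to) {
  # for each row of `from`, distance to the nearest row of `to`
  apply(from, 1, function(p) min(sqrt(rowSums(sweep(to, 2, p)^2))))
}

#' C1' coverage of a reference model
#'
#' A reference C1' atom counts as built when any C1' of the built model
#' lies within `cutoff` of it (counting is per reference atom; one built
#' atom may satisfy several). Also reports the mean matched-phosphorus
#' distance via [phosphorus_error()].
#'
#' @param built built model: a list of [chain_trace()]s, a trace, a list
#'   of fragments, a `bio3d` pdb object or a coordinate matrix.
#' @param reference reference model, same forms.
#' @param cutoff match cutoff in Angstrom (default 1.5).
#' @return object of class `coverage_report` with fields `n_built`,
#'   `n_total`, `fraction`, `p_error`.
#' @export
c1_coverage <- function(built, reference, cutoff = 1.5) {
  ref <- .atom_coords(reference, "C1'")
  if (nrow(ref) == 0L) stop("reference contains no C1' atoms")
  blt <- .atom_coords(built, "C1'")
  if (is.null(blt) || nrow(blt) == 0L) {
    rep <- list(n_built = 0L, n_total = nrow(ref), fraction = 0,
                p_error = NA_real_)
    return(structure(rep, class = "coverage_report"))
  }
  matched <- .min_dists(ref, blt) <= cutoff
  structure(list(n_built = sum(matched), n_total = nrow(ref),
                 fraction = mean(matched),
                 p_error = phosphorus_error(built, reference)),
            class = "coverage_report")
}

#' Phosphorus coordinate error
#'
#' Mean distance from each reference P atom to the nearest built P atom,
#' restricted to pairs within `cutoff` (default 3 Angstrom); reference
#' phosphorus atoms with no built P nearby are excluded. `NA` when nothing
#' matches.
#'
#' @inheritParams c1_coverage
#' @param cutoff matching radius in Angstrom.
#' @return mean matched distance in Angstrom, or `NA`.
#' @export
phosphorus_error <- function(built, reference, cutoff = 3) {
  ref <- .atom_coords(reference, "P")
  blt <- .atom_coords(built, "P")
  if (is.null(blt) || nrow(blt) == 0L || nrow(ref) == 0L) return(NA_real_)
  d <- .min_dists(ref, blt)
  d <- d[d <= cutoff]
  if (length(d) == 0L) return(NA_real_)
  mean(d)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage: %d / %d C1' built (%.1f%%), phosphorus error %s\n",
              x$n_built, x$n_total, 100 * x$fraction,
              if (is.na(x$p_error)) "n/a" else sprintf("%.2f A", x$p_error)))
  invisible(x)
}

#' Write coverage reports as a TSV table
#'
#' Columns: structure, built, total, fraction (%), phosphorus error (A).
#'
#' @param reports named list of `coverage_report` objects (names become
#'   the structure column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(reports, path) {
  df <- data.frame(
    structure = names(reports),
    built = vapply(reports, function(r) r$n_built, numeric(1)),
    total = vapply(reports, function(r) r$n_total, numeric(1)),
    fraction_pct = vapply(reports, function(r) 100 * r$fraction, numeric(1)),
    phosphorus_error_A = vapply(reports, function(r) r$p_error, numeric(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
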