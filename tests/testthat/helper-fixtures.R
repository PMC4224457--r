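# Shared, lazily built fixtures. Everything is generated in code; the
# memo environment persists across test files within one run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

ring_atoms <- c("C1'", "C2'", "C3'", "C4'", "O4'")

fx_targets <- function() fx_get("targets", default_targets)

fx_db <- function() fx_get("db", function() suppressWarnings(default_database()))

# one nucleotide in a 16 A cell (32^3 at 0.5 A): the oracle-equivalence map
fx_single_nt <- function() fx_get("single_nt", function() {
  tmpl <- nt_template()
  ctr <- colMeans(tmpl[ring_atoms, ])
  frag <- sweep(tmpl, 2, ctr - c(8, 8, 8))
  attr(frag, "source_id") <- "fixture:1"
  atoms <- atom_records(rownames(frag), frag, b_iso = 20)
  grid <- density_from_atoms(atoms, cell = c(16, 16, 16), spacing = 0.5)
  list(grid = grid, frag = frag, center = c(8, 8, 8))
})

fx_rotations <- function() fx_get("rotations", function() sample_rotations(18))

fx_helix <- function(fom = 1.0) {
  key <- sprintf("helix12_fom%g", fom)
  fx_get(key, function() make_fixture(helix_spec(12), fom = fom))
}

fx_view_center <- function(fix) colMeans(fix$fragments[[6]][ring_atoms, ])

fx_traces <- function(fom = 1.0, use_phosphate = TRUE) {
  key <- sprintf("traces_fom%g_p%d", fom, use_phosphate)
  fx_get(key, function() {
    fix <- fx_helix(fom)
    trace_all(fix$grid, fx_db(), center = fx_view_center(fix), seed = 1,
              use_phosphate = use_phosphate)
  })
}

fx_threshold <- function() fx_get("threshold", function() {
  calibrate_threshold(fx_helix()$grid, fx_targets()$sugar,
                      n_samples = 100000, tail_prob = 0.001, seed = 1)
})

# convenience: max absolute coordinate difference between two traces/lists
frag_rmsd <- function(a, b, atoms = ring_atoms) {
  sqrt(mean(rowSums((a[atoms, ] - b[atoms, ])^2)))
}
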