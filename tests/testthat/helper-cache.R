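# Shared, lazily computed fixtures. The ruler distances need eight
# accessible-volume calculations (~15 s), so they are computed once per test
# run and reused wherever the four construct distances are needed.

.fixture_cache <- new.env(parent = emptyenv())

cached_ruler_distances <- function() {
  if (is.null(.fixture_cache$ruler)) {
    .fixture_cache$ruler <- ruler_distances(c(0, 3, 5, 6))
  }
  .fixture_cache$ruler
}

# free-space structure: a single attachment atom and nothing else
point_structure <- function() {
  structure(list(
    atoms = data.frame(name = "SG", resno = 1L, resid = "CYS",
                       element = "S", vdw = 1.8, x = 0, y = 0, z = 0),
    n_pro = 0L, attachment_atoms = 1L), class = "quench_structure")
}

# structure with two bare attachment points a given distance apart
two_point_structure <- function(separation) {
  structure(list(
    atoms = data.frame(name = c("SG", "SG"), resno = c(1L, 2L),
                       resid = "CYS", element = "S", vdw = 1.8,
                       x = c(0, separation), y = 0, z = 0),
    n_pro = 0L, attachment_atoms = c(1L, 2L)), class = "quench_structure")
}
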