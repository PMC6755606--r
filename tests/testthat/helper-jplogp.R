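# Shared fixtures, computed once per test run.

.cache <- new.env(parent = emptyenv())

get_fixtures <- function() {
  if (is.null(.cache$fx))
    .cache$fx <- suppressWarnings(make_fixtures(seed = 1L))
  .cache$fx
}

get_fixture_fit <- function() {
  if (is.null(.cache$fit)) {
    fx <- get_fixtures()
    dm <- build_design_matrix(fx$holograms, codes = fx$vocabulary)
    .cache$fit <- suppressWarnings(
      fit_coefficients(dm$x, fx$targets, min_occurrence = 1L))
  }
  .cache$fit
}

type_smiles <- function(smi) type_molecule(suppressWarnings(perceive(smi)))

# Random toy hologram over a letter vocabulary (for algebra tests that
# need no chemistry).
random_hologram <- function(codes = letters[1:8], max_count = 5L) {
  k <- sample(seq_along(codes), sample(2:length(codes), 1L))
  h <- sample.int(max_count, length(k), replace = TRUE)
  names(h) <- codes[k]
  h[order(names(h))]
}

# Environment-class DD of the first atom matching an element in a SMILES.
dd_of <- function(smi, element, nth = 1L) {
  mol <- perceive(smi)
  idx <- which(mol$atoms$element == element)[nth]
  classify_atom(mol, idx)$dd
}
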