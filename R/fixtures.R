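## Deterministic fixture generation: a small labeled molecule set for
## end-to-end train/predict exercises with no external data, plus a
## synthetic-hologram simulator for parameter-recovery checks.

## Hard-coded structures spanning the classifier families: sp3 /
## aromatic / carbonyl carbons; amine, aniline, amide and heteroaromatic
## nitrogens; ether, hydroxyl, acid, ester and amide oxygens; F/Cl/Br/I;
## sulfur, phosphorus and charged atoms.
FIXTURE_SMILES <- c(
  methane = "C", ethane = "CC", propane = "CCC", butane = "CCCC",
  isobutane = "CC(C)C", pentane = "CCCCC", hexane = "CCCCCC",
  cyclohexane = "C1CCCCC1", methylcyclohexane = "CC1CCCCC1",
  ethylene = "C=C", propene = "CC=C", butadiene = "C=CC=C",
  acetylene = "C#C", propyne = "CC#C",
  ethanol = "CCO", propanol = "CCCO", isopropanol = "CC(C)O",
  butanol = "CCCCO", glycol = "OCCO", glycerol = "OCC(O)CO",
  dimethyl_ether = "COC", diethyl_ether = "CCOCC", thf = "C1CCOC1",
  benzene = "c1ccccc1", toluene = "Cc1ccccc1", ethylbenzene = "CCc1ccccc1",
  xylene = "Cc1ccccc1C", mesitylene = "Cc1cc(C)cc(C)c1",
  naphthalene = "c1ccc2ccccc2c1", styrene = "C=Cc1ccccc1",
  phenol = "Oc1ccccc1", p_cresol = "Cc1ccc(O)cc1", anisole = "COc1ccccc1",
  catechol = "Oc1ccccc1O",
  chlorobenzene = "Clc1ccccc1", bromobenzene = "Brc1ccccc1",
  chlorophenol_4 = "Oc1ccc(Cl)cc1", bromophenol_4 = "Oc1ccc(Br)cc1",
  chloroethane = "CCCl", bromoethane = "CCBr", iodoethane = "CCI",
  dichloromethane = "ClCCl", chloroform = "ClC(Cl)Cl",
  fluoroethane = "CCF", fluorobenzene = "Fc1ccccc1",
  benzotrifluoride = "FC(F)(F)c1ccccc1", tfe = "OCC(F)(F)F",
  acetone = "CC(C)=O", butanone = "CCC(C)=O", acetaldehyde = "CC=O",
  benzaldehyde = "O=Cc1ccccc1",
  acetic_acid = "CC(=O)O", propionic_acid = "CCC(=O)O",
  benzoic_acid = "OC(=O)c1ccccc1",
  methyl_acetate = "COC(C)=O", ethyl_acetate = "CCOC(C)=O",
  acetamide = "CC(N)=O", n_methylacetamide = "CNC(C)=O",
  acetanilide = "CC(=O)Nc1ccccc1",
  ethylamine = "CCN", propylamine = "CCCN", diethylamine = "CCNCC",
  triethylamine = "CCN(CC)CC", aniline = "Nc1ccccc1",
  n_methylaniline = "CNc1ccccc1", pyridine = "c1ccncc1",
  picoline = "Cc1ccccn1", pyrrole = "c1cc[nH]c1",
  acetonitrile = "CC#N", benzonitrile = "N#Cc1ccccc1",
  hydrazine = "NN", nitrobenzene = "O=[N+]([O-])c1ccccc1",
  dimethyl_sulfide = "CSC", ethanethiol = "CCS", thiophene = "c1ccsc1",
  dmso = "CS(C)=O", methanesulfonamide = "CS(N)(=O)=O",
  thioacetamide = "CC(N)=S",
  furan = "c1ccoc1", phosphoric_acid = "OP(O)(O)=O",
  trimethyl_phosphate = "COP(=O)(OC)OC",
  acetate_anion = "CC([O-])=O", phenolate = "[O-]c1ccccc1",
  tetramethylammonium = "C[N+](C)(C)C", anilinium = "[NH3+]c1ccccc1",
  allyl_alcohol = "C=CCO", crotonaldehyde = "CC=CC=O",
  cyclohexanone = "O=C1CCCCC1", cyclohexanol = "OC1CCCCC1"
)

#' Generate the deterministic fixture set
#'
#' Types a fixed panel of small organic molecules covering the
#' classifier families and attaches synthetic targets
#' `hologram %*% alpha_toy + N(0, noise_sd)`, where `alpha_toy` holds
#' seeded per-code coefficients on the scale of real atomic logP
#' contributions. The default noise level matches the magnitude of the
#' residual scatter a consensus-target fit leaves (about 0.35 log
#' units). Everything is reproducible from `seed`.
#'
#' @param seed integer seed for `alpha_toy` and the noise draws.
#' @param noise_sd Gaussian noise standard deviation, in log units.
#' @return object of class `jplogp_fixtures`: list with `ids`, `smiles`,
#'   `holograms`, `vocabulary`, `alpha` (the toy coefficients),
#'   `targets` and `noise_sd`.
#' @export
make_fixtures <- function(seed = 1L, noise_sd = 0.35) {
  mols <- suppressWarnings(
    perceive_smiles(unname(FIXTURE_SMILES), ids = names(FIXTURE_SMILES)))
  ok <- !vapply(mols, is.null, logical(1))
  holos <- lapply(mols[ok], type_molecule)
  vocab <- sort(unique(unlist(lapply(holos, names))))
  dm <- build_design_matrix(holos, codes = vocab)
  with_local_seed(seed, {
    alpha <- stats::setNames(stats::rnorm(length(vocab), 0, 0.4), vocab)
    targets <- drop(dm$x %*% alpha) + stats::rnorm(length(holos), 0, noise_sd)
  })
  structure(list(
    ids = names(FIXTURE_SMILES)[ok],
    smiles = unname(FIXTURE_SMILES)[ok],
    holograms = holos,
    vocabulary = vocab,
    alpha = alpha,
    targets = unname(targets),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "jplogp_fixtures")
}

#' @export
print.jplogp_fixtures <- function(x, ...) {
  cat("<jplogp_fixtures> ", length(x$ids), " molecules, ",
      length(x$vocabulary), " distinct atom codes (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Simulate synthetic count holograms
#'
#' Draws an `n`-by-`length(codes)` count matrix with Poisson-distributed
#' per-code counts (per-code rates drawn once from U(0.5, 3)), the input
#' for parameter-recovery checks at sizes real fixture sets cannot
#' reach.
#'
#' @param n number of synthetic compounds.
#' @param codes code vocabulary (character).
#' @param seed integer seed.
#' @return integer matrix with `codes` as column names.
#' @export
simulate_training_matrix <- function(n, codes, seed = 1L) {
  p <- length(codes)
  with_local_seed(seed, {
    lambda <- stats::runif(p, 0.5, 3)
    x <- matrix(stats::rpois(n * p, rep(lambda, each = n)), nrow = n,
                dimnames = list(NULL, codes))
  })
  x
}
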