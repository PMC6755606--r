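## Hierarchical atom typer.
##
## Every atom receives a six-digit code A BB C DD:
##   A  = formal charge + 1 (kept positive; charge -1 gives A = 0)
##   BB = atomic number (two digits, so Z <= 99)
##   C  = number of heavy (non-hydrogen) neighbors
##   DD = element-specific local-environment class (tables below)
##
## DD vocabularies. Carbon splits first on the maximum incident bond
## order (single < aromatic < double < triple); sp3 carbons form two
## classes (polar neighbor or not) while the higher-order groups are
## subdivided by how many polar atoms are attached through the multiple/
## aromatic bond versus through single bonds -- the carbon alpha to a
## pyridine nitrogen is a different type from the carbon of an aniline.
## Nitrogen has classes for direct polar-polar bonds, for delocalized
## lone pairs (aniline-/amide-like, thioamides included), then a
## bond-order split. Oxygen distinguishes O-N, O-S, the sp2 oxygens of
## amides/acids/esters/thioesters and plain carbonyls, the sp3 oxygens
## on carbonyl carbons (acid -OH vs ester -O-), aromatic O, hydroxyl,
## ether and oxide. Fluorine is keyed on the carrier carbon's bond-order
## group plus the number of additional electron-withdrawing substituents
## (halogens and polar atoms) on that carbon. Hydrogen depends only on
## the attached heavy atom (element family and bond-order group at
## topological distance 1). Every other element is aromatic vs
## 10 + polar-neighbor count.

is_polar_z <- function(z) z %in% POLAR_Z

#' Count polar neighbors of an atom
#'
#' A polar atom is S, O, N or P. Fluorine and the other halogens are not
#' polar under this definition.
#'
#' @param mol a [perceive()]d molecule.
#' @param i atom index.
#' @return integer count of directly bonded S/O/N/P neighbors.
#' @export
polar_neighbor_count <- function(mol, i) {
  nb <- mol$nbrs[[i]]$idx
  sum(is_polar_z(mol$atoms$z[nb]))
}

## Polar neighbors split by how they are attached: through the
## multiple/aromatic bond vs through a single bond.
polar_split <- function(mol, i, multi_orders) {
  nb <- mol$nbrs[[i]]$idx
  o <- mol$nbrs[[i]]$order
  pol <- is_polar_z(mol$atoms$z[nb])
  list(multi = sum(pol & o %in% multi_orders),
       single = sum(pol & o == 1))
}

## TRUE if atom i carries a double bond to oxygen or sulfur
## (carbonyl / thiocarbonyl and their analogues).
has_double_to_chalcogen <- function(mol, i) {
  nb <- mol$nbrs[[i]]$idx
  o <- mol$nbrs[[i]]$order
  any(o == 2 & mol$atoms$z[nb] %in% c(8L, 16L))
}

bond_order_group <- function(maxo) {
  if (maxo >= 3) "triple"
  else if (maxo >= 2) "double"
  else if (maxo > 1) "aromatic"
  else "sp3"
}

#' Environment classifiers
#'
#' Per-element classifiers mapping an atom's local environment to its
#' two-digit `DD` class. Each returns a list with `family`, `label` and
#' the numeric `dd`. [classify_atom()] dispatches on the element;
#' the per-element functions error on a wrong element.
#'
#' @param mol a [perceive()]d molecule.
#' @param i atom index.
#' @return list with `family` (character), `label` (character) and `dd`
#'   (integer in 0..99).
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
classify_carbon <- function(mol, i) {
  if (mol$atoms$z[i] != 6L) stop("classify_carbon: atom ", i, " is not carbon")
  grp <- bond_order_group(max_bond_order(mol, i))
  if (grp == "sp3") {
    pol <- polar_neighbor_count(mol, i)
    return(env_class("carbon",
                     if (pol > 0L) "sp3 polar neighbor" else "sp3 no polar",
                     if (pol > 0L) 2L else 1L))
  }
  multi_orders <- switch(grp, aromatic = 1.5, double = 2, triple = 3)
  ps <- polar_split(mol, i, multi_orders)
  base <- switch(grp, aromatic = 10L, double = 20L, triple = 30L)
  dd <- base + 3L * min(ps$multi, 2L) + min(ps$single, 2L)
  env_class("carbon",
            sprintf("%s, %d polar via %s bond, %d via single",
                    grp, ps$multi, grp, ps$single), dd)
}

#' @rdname classifiers
#' @export
classify_nitrogen <- function(mol, i) {
  if (mol$atoms$z[i] != 7L) stop("classify_nitrogen: atom ", i, " is not nitrogen")
  npol <- polar_neighbor_count(mol, i)
  if (npol > 0L)
    return(env_class("nitrogen",
                     sprintf("bound to %d polar atom(s)", npol),
                     1L + min(npol - 1L, 2L)))
  nb <- mol$nbrs[[i]]$idx
  o <- mol$nbrs[[i]]$order
  single_nb <- nb[o == 1]
  aniline_like <- any(mol$atoms$aromatic[single_nb])
  amide_like <- any(vapply(single_nb, function(j)
    mol$atoms$z[j] == 6L && has_double_to_chalcogen(mol, j), logical(1)))
  if (aniline_like || amide_like)
    return(env_class("nitrogen", "delocalized lone pair (aniline/amide-like)", 10L))
  grp <- bond_order_group(max_bond_order(mol, i))
  dd <- switch(grp, sp3 = 20L, aromatic = 21L, double = 22L, triple = 23L)
  env_class("nitrogen", grp, dd)
}

#' @rdname classifiers
#' @export
classify_oxygen <- function(mol, i) {
  if (mol$atoms$z[i] != 8L) stop("classify_oxygen: atom ", i, " is not oxygen")
  nb <- mol$nbrs[[i]]$idx
  o <- mol$nbrs[[i]]$order
  zn <- mol$atoms$z[nb]
  if (any(zn == 7L)) return(env_class("oxygen", "bound to nitrogen", 1L))
  if (any(zn == 16L)) return(env_class("oxygen", "bound to sulfur", 2L))

  dbl_c <- nb[o == 2 & zn == 6L]
  if (length(dbl_c) > 0L) {
    ## sp2 oxygen of a carbonyl: classify by the carbonyl carbon's
    ## single-bonded substituents.
    cc <- dbl_c[1L]
    cnb <- mol$nbrs[[cc]]$idx
    co <- mol$nbrs[[cc]]$order
    sub_z <- mol$atoms$z[cnb[co == 1 & cnb != i]]
    sub_idx <- cnb[co == 1 & cnb != i]
    if (any(sub_z == 7L)) return(env_class("oxygen", "sp2 amide", 3L))
    ox_sub <- sub_idx[sub_z == 8L]
    if (length(ox_sub) > 0L) {
      if (any(mol$atoms$nhyd[ox_sub] > 0L))
        return(env_class("oxygen", "sp2 carboxylic acid", 4L))
      return(env_class("oxygen", "sp2 ester", 5L))
    }
    if (any(sub_z == 16L)) return(env_class("oxygen", "sp2 thioester", 6L))
    return(env_class("oxygen", "sp2 ketone/aldehyde", 7L))
  }

  ## sp3 oxygen attached to a carbonyl / thiocarbonyl carbon
  acyl <- nb[o == 1 & zn == 6L]
  acyl <- acyl[vapply(acyl, function(j) has_double_to_chalcogen(mol, j), logical(1))]
  if (length(acyl) > 0L) {
    if (mol$atoms$nhyd[i] > 0L)
      return(env_class("oxygen", "acid hydroxyl", 8L))
    return(env_class("oxygen", "ester sp3", 9L))
  }

  if (mol$atoms$aromatic[i]) return(env_class("oxygen", "aromatic", 10L))
  if (mol$atoms$nhyd[i] > 0L) return(env_class("oxygen", "hydroxyl", 11L))
  if (mol$atoms$nheavy[i] >= 2L) return(env_class("oxygen", "ether", 12L))
  env_class("oxygen", "oxide/alkoxide", 13L)
}

#' @rdname classifiers
#' @export
classify_fluorine <- function(mol, i) {
  if (mol$atoms$z[i] != 9L) stop("classify_fluorine: atom ", i, " is not fluorine")
  nb <- mol$nbrs[[i]]$idx
  if (length(nb) == 0L) return(env_class("fluorine", "isolated", 0L))
  j <- nb[1L]
  if (mol$atoms$z[j] != 6L) return(env_class("fluorine", "on non-carbon", 1L))
  grp <- bond_order_group(max_bond_order(mol, j))
  base <- switch(grp, sp3 = 10L, aromatic = 20L, double = 30L, triple = 40L)
  cnb <- mol$nbrs[[j]]$idx
  cnb <- cnb[cnb != i]
  newg <- sum(mol$atoms$z[cnb] %in% c(HALOGEN_Z, POLAR_Z))
  env_class("fluorine",
            sprintf("on %s carbon with %d other withdrawing substituents", grp, newg),
            base + min(newg, 9L))
}

#' @rdname classifiers
#' @export
classify_hydrogen <- function(mol, i) {
  if (mol$atoms$z[i] != 1L) stop("classify_hydrogen: atom ", i, " is not hydrogen")
  nb <- mol$nbrs[[i]]$idx
  nb <- nb[mol$atoms$z[nb] != 1L]
  if (length(nb) == 0L) return(env_class("hydrogen", "no heavy carrier", 0L))
  j <- nb[1L]
  zj <- mol$atoms$z[j]
  if (zj == 6L) {
    grp <- bond_order_group(max_bond_order(mol, j))
    dd <- switch(grp, sp3 = 1L, aromatic = 2L, double = 3L, triple = 4L)
    return(env_class("hydrogen", paste("on", grp, "carbon"), dd))
  }
  dd <- switch(as.character(zj), "8" = 10L, "7" = 11L, "16" = 12L, 20L)
  env_class("hydrogen",
            paste("on", ELEMENT_SYMBOLS[zj]), dd)
}

#' @rdname classifiers
#' @export
classify_default <- function(mol, i) {
  if (mol$atoms$aromatic[i])
    return(env_class("default", "aromatic", 1L))
  env_class("default",
            sprintf("%d polar neighbors", polar_neighbor_count(mol, i)),
            10L + min(polar_neighbor_count(mol, i), 9L))
}

#' @rdname classifiers
#' @export
classify_atom <- function(mol, i) {
  switch(as.character(mol$atoms$z[i]),
         "6" = classify_carbon(mol, i),
         "7" = classify_nitrogen(mol, i),
         "8" = classify_oxygen(mol, i),
         "1" = classify_hydrogen(mol, i),
         "9" = classify_fluorine(mol, i),
         classify_default(mol, i))
}

env_class <- function(family, label, dd) {
  stopifnot(dd >= 0L, dd <= 99L)
  list(family = family, label = label, dd = as.integer(dd))
}

#' Assign the six-digit atom code
#'
#' Assembles `A*1e5 + BB*1e3 + C*1e2 + DD` for one atom: charge digit,
#' atomic number, heavy-atom degree and environment class.
#'
#' @inheritParams classifiers
#' @return integer code (interpret as a six-digit number; a leading zero
#'   means a formal charge of -1). Use [format_atom_code()] for the
#'   zero-padded text form.
#' @export
type_atom <- function(mol, i) {
  z <- mol$atoms$z[i]
  chg <- mol$atoms$charge[i]
  if (z > 99L) stop("atomic number ", z, " exceeds the two-digit element field")
  if (chg < -1L) stop("formal charge ", chg, " below -1 is out of range")
  if (chg > 8L) stop("formal charge ", chg, " above +8 is out of range")
  nh <- min(mol$atoms$nheavy[i], 9L)
  dd <- classify_atom(mol, i)$dd
  as.integer((chg + 1L) * 100000L + z * 1000L + nh * 100L + dd)
}

#' @rdname type_atom
#' @param code integer atom code.
#' @export
format_atom_code <- function(code) sprintf("%06d", as.integer(code))

#' Type a molecule into its atom-type hologram
#'
#' Types every atom (hydrogens included) and returns the count hologram:
#' a named integer vector, names are zero-padded six-digit codes, values
#' the number of atoms carrying each code. Counts always sum to the
#' total atom count.
#'
#' @param mol a [perceive()]d molecule, or a SMILES string.
#' @return named integer vector sorted by code.
#' @examples
#' \donttest{
#' type_molecule("c1ccccc1")  # two codes: aromatic C x6, aromatic H x6
#' }
#' @export
type_molecule <- function(mol) {
  if (is.character(mol)) mol <- perceive(mol)
  stopifnot(inherits(mol, "jpmol"))
  codes <- vapply(seq_len(nrow(mol$atoms)), function(i)
    type_atom(mol, i), integer(1))
  tab <- table(format_atom_code(codes))
  h <- as.integer(tab)
  names(h) <- names(tab)
  h[order(names(h))]
}
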