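## Molecular perception: SMILES/SDF -> annotated molecular graph.
##
## All input is normalized through OpenBabel (via ChemmineOB) into V2000
## SDF with explicit hydrogens, then parsed with ChemmineR. Ring and
## aromaticity perception comes from ChemmineR::rings(); formal charges
## are taken from the M CHG property lines of the normalized record
## (ChemmineR's SDF container does not retain them).

#' Parse and annotate a molecule
#'
#' Converts a SMILES string or a single V2000 SDF record into an
#' annotated molecular graph ready for atom typing: explicit hydrogens,
#' perceived aromaticity, formal charges, heavy-neighbor and hydrogen
#' counts per atom. Multi-fragment inputs (salts, mixtures) are reduced
#' to the largest covalent fragment with a warning; counter-ion driven
#' chemistry is outside the model's domain.
#'
#' @param structure a SMILES string, or SDF record text when
#'   `format = "sdf"`.
#' @param format `"smiles"` or `"sdf"`.
#' @param id optional identifier attached to the result.
#' @return an object of class `jpmol`: a list with `atoms`
#'   (data.frame: `element`, `z`, `charge`, `aromatic`, `nheavy`,
#'   `nhyd`), `bonds` (data.frame: `i`, `j`, `order`, `aromatic`) and
#'   `nbrs` (per-atom adjacency list).
#' @examples
#' \donttest{
#' mol <- perceive("c1ccccc1O", id = "phenol")
#' mol$atoms
#' }
#' @export
perceive <- function(structure, format = c("smiles", "sdf"), id = NULL) {
  format <- match.arg(format)
  stopifnot(is.character(structure), length(structure) == 1L)
  sdf_txt <- normalize_to_sdf(structure, from = if (format == "smiles") "SMI" else "SDF")
  recs <- split_sdf_records(sdf_txt)
  if (length(recs) == 0L)
    stop("could not parse structure", if (!is.null(id)) paste0(" '", id, "'"),
         ": ", substr(structure, 1L, 60L), call. = FALSE)
  build_jpmol(recs[[1L]], id = id)
}

#' @rdname perceive
#' @param structures character vector of SMILES strings.
#' @param ids optional identifiers, recycled to `length(structures)`.
#' @return `perceive_smiles()`: a list of `jpmol` objects; entries that
#'   fail to parse are `NULL` and reported via the `"failures"`
#'   attribute.
#' @export
perceive_smiles <- function(structures, ids = NULL) {
  stopifnot(is.character(structures))
  if (is.null(ids)) ids <- paste0("mol", seq_along(structures))
  out <- vector("list", length(structures))
  names(out) <- ids
  fail <- character(0)
  for (k in seq_along(structures)) {
    m <- tryCatch(perceive(structures[[k]], id = ids[[k]]),
                  error = function(e) e)
    if (inherits(m, "error")) {
      fail <- c(fail, ids[[k]])
      warning("skipping '", ids[[k]], "': ", conditionMessage(m), call. = FALSE)
    } else out[[k]] <- m
  }
  attr(out, "failures") <- fail
  out
}

## OpenBabel conversion with explicit-hydrogen expansion.
normalize_to_sdf <- function(text, from = "SMI") {
  opts <- data.frame(names = "h", args = "", stringsAsFactors = FALSE)
  out <- suppressWarnings(
    ChemmineOB::convertFormat(from, "SDF", source = text, options = opts))
  if (!is.character(out) || !nzchar(out)) out <- ""
  out
}

## Split concatenated SDF text into per-record character vectors of
## lines. A record must contain a counts line and "M  END".
split_sdf_records <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  idx <- cumsum(c(0L, head(grepl("^\\${4}", lines), -1L)))
  recs <- split(lines, idx)
  recs <- lapply(recs, function(x) x[!grepl("^\\${4}", x)])
  recs[vapply(recs, function(x) any(grepl("^M  END", x)), logical(1))]
}

## Assemble the annotated molecule from one normalized V2000 record.
build_jpmol <- function(rec_lines, id = NULL) {
  counts <- rec_lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || na < 1L) stop("malformed record: no atoms", call. = FALSE)
  if (identical(nb, 0L)) {
    ## ChemmineR's container refuses bond-less records (single atoms,
    ## bare ions); read the atom symbols from the fixed-width lines.
    element <- trimws(substr(rec_lines[4L + seq_len(na)], 32L, 34L))
    sdf <- NULL
    bb <- NULL
  } else {
    sdfset <- suppressWarnings(
      ChemmineR::read.SDFset(rec_lines, skipErrors = TRUE))
    sdf <- sdfset[[1L]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    element <- sub("_\\d+$", "", rownames(ab))
  }
  n <- length(element)
  z <- symbol_to_z(element)
  if (anyNA(z))
    stop("unsupported element (atomic number > 99 or unknown symbol): ",
         paste(unique(element[is.na(z)]), collapse = ", "), call. = FALSE)

  charge <- parse_mchg(rec_lines, n)

  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  }

  ## Largest covalent fragment (salt stripping).
  if (n > 1L) {
    g <- igraph::graph_from_data_frame(
      bonds[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      heavy_per <- tapply(element != "H", comp$membership, sum)
      keep_comp <- as.integer(names(which.max(heavy_per)))
      keep <- which(comp$membership == keep_comp)
      warning("multi-fragment input", if (!is.null(id)) paste0(" '", id, "'"),
              ": keeping largest covalent fragment (",
              sum(element[keep] != "H"), " heavy atoms)", call. = FALSE)
      remap <- integer(n); remap[keep] <- seq_along(keep)
      bonds <- bonds[bonds$i %in% keep & bonds$j %in% keep, , drop = FALSE]
      bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
      element <- element[keep]; z <- z[keep]; charge <- charge[keep]
      n <- length(keep)
      rec_lines <- NULL  # ring perception redone below on the fragment
      sdf <- subset_sdf(sdf, keep)
    }
  }

  if (any(z > 99L))
    stop("unsupported element with atomic number > 99", call. = FALSE)
  if (any(charge < -1L))
    stop("formal charge below -1 is outside the code's charge digit",
         call. = FALSE)

  aromatic_atoms <- rep(FALSE, n)
  aromatic_bonds <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L && !is.null(sdf)) {
    ar <- perceive_aromaticity(sdf, n, bonds)
    aromatic_atoms <- ar$atoms
    aromatic_bonds <- ar$bonds
  }
  bonds$aromatic <- aromatic_bonds

  nbrs <- vector("list", n)
  for (k in seq_len(n)) nbrs[[k]] <- list(idx = integer(0), order = numeric(0))
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      o <- if (bonds$aromatic[r]) 1.5 else as.numeric(bonds$order[r])
      nbrs[[i]]$idx <- c(nbrs[[i]]$idx, j); nbrs[[i]]$order <- c(nbrs[[i]]$order, o)
      nbrs[[j]]$idx <- c(nbrs[[j]]$idx, i); nbrs[[j]]$order <- c(nbrs[[j]]$order, o)
    }
  }

  nheavy <- vapply(seq_len(n), function(k)
    sum(element[nbrs[[k]]$idx] != "H"), integer(1))
  nhyd <- vapply(seq_len(n), function(k)
    sum(element[nbrs[[k]]$idx] == "H"), integer(1))

  structure(list(
    id = id,
    atoms = data.frame(element = element, z = z, charge = charge,
                       aromatic = aromatic_atoms, nheavy = nheavy,
                       nhyd = nhyd, stringsAsFactors = FALSE),
    bonds = bonds,
    nbrs = nbrs
  ), class = "jpmol")
}

## Formal charges from the "M  CHG" property lines.
parse_mchg <- function(rec_lines, n) {
  charge <- integer(n)
  if (is.null(rec_lines)) return(charge)
  for (line in grep("^M  CHG", rec_lines, value = TRUE)) {
    tok <- strsplit(trimws(sub("^M  CHG", "", line)), "\\s+")[[1L]]
    cnt <- as.integer(tok[1L])
    for (p in seq_len(cnt)) {
      idx <- as.integer(tok[2L * p])
      charge[idx] <- as.integer(tok[2L * p + 1L])
    }
  }
  charge
}

## Keep a subset of atoms in a ChemmineR SDF object (for ring perception
## on the stripped fragment).
subset_sdf <- function(sdf, keep) {
  sdfstr <- as(sdf, "SDFstr")
  # simplest robust route: rewrite via atom/bond blocks is fragile;
  # instead re-perceive from a fresh OpenBabel pass of the fragment SMILES
  # is unnecessary because ChemmineR supports [ indexing on SDF atom sets
  # only via sdfsubset helpers; we rebuild the SDF text manually.
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  bonds <- data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                      order = as.integer(bb[, 3L]))
  bonds <- bonds[bonds$i %in% keep & bonds$j %in% keep, , drop = FALSE]
  remap <- integer(nrow(ab)); remap[keep] <- seq_along(keep)
  el <- sub("_\\d+$", "", rownames(ab))[keep]
  na <- length(keep); nb <- nrow(bonds)
  hdr <- c("", " jplogp fragment", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atl <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                 0, 0, 0, el)
  bdl <- if (nb > 0L)
    sprintf("%3d%3d%3d  0  0  0  0", remap[bonds$i], remap[bonds$j], bonds$order)
  else character(0)
  txt <- c(hdr, atl, bdl, "M  END")
  ChemmineR::read.SDFset(txt, skipErrors = TRUE)[[1L]]
}

## Ring-based aromaticity flags for atoms and bonds, via ChemmineR ring
## perception on the (kekulized) OpenBabel output.
perceive_aromaticity <- function(sdf, n, bonds) {
  res <- list(atoms = rep(FALSE, n), bonds = rep(FALSE, nrow(bonds)))
  ri <- tryCatch(
    ChemmineR::rings(sdf, upper = 14, type = "all", arom = TRUE),
    error = function(e) NULL)
  if (is.null(ri) || length(ri$RINGS) == 0L) return(res)
  bond_key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  for (r in seq_along(ri$RINGS)) {
    if (!isTRUE(ri$AROMATIC[[r]])) next
    members <- as.integer(sub("^.*_", "", ri$RINGS[[r]]))
    res$atoms[members] <- TRUE
    ring_pairs <- cbind(members, c(members[-1L], members[1L]))
    keys <- paste(pmin(ring_pairs[, 1L], ring_pairs[, 2L]),
                  pmax(ring_pairs[, 1L], ring_pairs[, 2L]))
    res$bonds[bond_key %in% keys] <- TRUE
  }
  res
}

#' @export
print.jpmol <- function(x, ...) {
  cat("<jpmol", if (!is.null(x$id)) paste0(" '", x$id, "'"), "> ",
      nrow(x$atoms), " atoms (", sum(x$atoms$element != "H"),
      " heavy), ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

## Maximum effective incident bond order for an atom: aromatic bonds
## count 1.5, so the grouping single < aromatic < double < triple falls
## out of a numeric max.
max_bond_order <- function(mol, i) {
  o <- mol$nbrs[[i]]$order
  if (length(o) == 0L) 0 else max(o)
}
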