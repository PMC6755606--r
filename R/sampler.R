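## Targeted rarest-first diversity sampling.
##
## Builds a training subset that guarantees every sufficiently frequent
## atom-type is represented: iterate codes from rarest to most common
## and, for each, top up the selection with random compounds containing
## that code until `level` selected compounds carry it. Compounds picked
## for earlier (rarer) codes count toward later codes' quotas, so common
## types rarely force extra draws.

#' Atom-type occurrence table
#'
#' Total atom-level occurrence count of every code across a dataset of
#' holograms, sorted ascending (ties broken by code value).
#'
#' @param holograms list of holograms ([type_molecule()]).
#' @return named integer vector sorted by increasing count.
#' @export
count_occurrences <- function(holograms) {
  if (length(holograms) == 0L)
    return(structure(integer(0), names = character(0)))
  all <- unlist(unname(lapply(holograms, as_hologram)))
  tab <- tapply(all, names(all), sum)
  occ <- as.integer(tab)
  names(occ) <- names(tab)
  occ[order(occ, names(occ))]
}

#' Rarest-first targeted sampling
#'
#' Selects a subset such that every atom-type with at least
#' `min_occurrence` total occurrences appears in at least
#' `min(level, pool size)` selected compounds. Codes below the
#' occurrence cutoff are not targeted (they carry too little information
#' to train on), but compounds containing them are not excluded.
#'
#' @param holograms list of holograms, one per compound.
#' @param level per-code quota: number of selected compounds that must
#'   contain each targeted code.
#' @param min_occurrence codes with a smaller atom-level total are not
#'   targeted.
#' @param seed integer seed making the random draws reproducible.
#' @return sorted integer indices of the selected compounds. The
#'   `"manifest"` attribute records the parameters and the per-code
#'   coverage achieved.
#' @export
targeted_sample <- function(holograms, level, min_occurrence = 3L,
                            seed = NULL) {
  if (length(level) != 1L || level < 1L) stop("level must be a positive integer")
  n <- length(holograms)
  occ <- count_occurrences(holograms)
  targeted <- names(occ)[occ >= min_occurrence]
  membership <- lapply(holograms, names)
  code_pool <- split(
    rep(seq_len(n), lengths(membership)),
    unlist(membership))

  selected <- logical(n)
  with_local_seed(seed, {
    for (code in intersect(names(occ), targeted)) {
      pool <- code_pool[[code]]
      have <- sum(selected[pool])
      need <- min(level, length(pool)) - have
      if (need <= 0L) next
      remaining <- pool[!selected[pool]]
      draw <- if (length(remaining) <= need) remaining
              else sample(remaining, need)
      selected[draw] <- TRUE
    }
  })

  idx <- which(selected)
  coverage <- vapply(targeted, function(code)
    sum(idx %in% code_pool[[code]]), integer(1))
  attr(idx, "manifest") <- list(
    level = as.integer(level), min_occurrence = as.integer(min_occurrence),
    seed = seed, n_input = n, n_selected = length(idx),
    coverage = coverage)
  idx
}
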