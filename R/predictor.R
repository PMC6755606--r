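## Prediction: coefficient mode, library-corrected mode, the
## similarity/match-count grid search, and evaluation utilities.

#' Build a reference library
#'
#' A library pairs structures having experimental logP values with
#' precomputed holograms; [predict_library()] searches it by
#' count-Tanimoto similarity.
#'
#' @param structures character vector of SMILES, or a list of
#'   [perceive()]d molecules or holograms.
#' @param logp experimental logP values.
#' @param ids optional identifiers.
#' @return object of class `jplogp_library`.
#' @export
build_library <- function(structures, logp, ids = NULL) {
  stopifnot(length(structures) == length(logp))
  if (is.null(ids)) ids <- paste0("lib", seq_along(logp))
  holos <- structures_to_holograms(structures, ids)
  keep <- !vapply(holos, is.null, logical(1))
  if (!all(keep))
    warning(sum(!keep), " library record(s) failed typing and were dropped",
            call. = FALSE)
  structure(list(ids = ids[keep], logp = as.numeric(logp[keep]),
                 holograms = holos[keep],
                 typer_version = JPLOGP_TYPER_VERSION),
            class = "jplogp_library")
}

#' @export
print.jplogp_library <- function(x, ...) {
  cat("<jplogp_library> ", length(x$ids), " reference compounds\n", sep = "")
  invisible(x)
}

#' Coefficient-only prediction
#'
#' The coefficient-weighted hologram sum: `sum over codes of
#' alpha\[code\] * count\[code\]`. Codes without a trained coefficient
#' flag the prediction out-of-domain; the value is then computed over
#' the known codes only and the missing codes are reported.
#'
#' @param h a hologram ([type_molecule()]) or a SMILES string.
#' @param coeffs a `jplogp_model` or named coefficient vector.
#' @return object of class `jplogp_prediction`: list with `value`,
#'   `mode = "coeff"`, `in_domain`, `missing_codes`, `matches` (empty).
#' @export
predict_coeff <- function(h, coeffs) {
  if (is.character(h)) h <- type_molecule(h)
  h <- as_hologram(h)
  if (length(h) == 0L) stop("empty hologram")
  alpha <- as_coefficients(coeffs)
  known <- intersect(names(h), names(alpha))
  missing <- setdiff(names(h), names(alpha))
  value <- sum(alpha[known] * h[known])
  structure(list(value = value, mode = "coeff",
                 in_domain = length(missing) == 0L,
                 missing_codes = missing,
                 matches = empty_matches()),
            class = "jplogp_prediction")
}

empty_matches <- function() {
  data.frame(id = character(0), similarity = numeric(0),
             corrected = numeric(0), in_domain = logical(0),
             stringsAsFactors = FALSE)
}

#' Library correction from one known compound
#'
#' Adds the coefficient-weighted difference hologram (query minus
#' reference) to the reference compound's experimental logP. By
#' linearity this equals
#' `entry logP + predict_coeff(query) - predict_coeff(reference)`, so a
#' good experimental anchor removes the shared part of the least-squares
#' imprecision.
#'
#' @param unknown_h hologram of the query.
#' @param entry_h hologram of the reference compound.
#' @param entry_logp its experimental logP.
#' @param coeffs coefficients.
#' @return list with `value` and `in_domain` (`FALSE` when the
#'   difference hologram touches an untrained code).
#' @export
correct_from_known <- function(unknown_h, entry_h, entry_logp, coeffs) {
  alpha <- as_coefficients(coeffs)
  d <- hologram_difference(unknown_h, entry_h)
  known <- intersect(names(d), names(alpha))
  list(value = entry_logp + sum(alpha[known] * d[known]),
       in_domain = length(setdiff(names(d), names(alpha))) == 0L)
}

#' Library-corrected prediction
#'
#' Ranks the library by count-Tanimoto similarity to the query, keeps up
#' to `max_matches` entries at or above `min_similarity` (ties broken by
#' library id for reproducibility), corrects each reference's
#' experimental logP by its difference hologram, and averages. Matches
#' whose difference touches an untrained code are dropped from the mean
#' and noted. With no qualifying match the result falls back to
#' [predict_coeff()].
#'
#' @inheritParams predict_coeff
#' @param library a [build_library()] object.
#' @param min_similarity similarity threshold for a usable match.
#' @param max_matches maximum number of references averaged.
#' @param exclude_exact drop similarity-1 matches (useful when
#'   benchmarking against a library that contains the test compounds).
#' @return a `jplogp_prediction`; `mode` is `"library"` when at least
#'   one match was used, `"coeff"` otherwise.
#' @export
predict_library <- function(h, library, coeffs, min_similarity = 0.75,
                            max_matches = 5L, exclude_exact = FALSE) {
  if (is.character(h)) h <- type_molecule(h)
  h <- as_hologram(h)
  stopifnot(inherits(library, "jplogp_library"), length(library$ids) > 0L)
  sims <- vapply(library$holograms, function(k)
    hologram_similarity(h, k), numeric(1))
  ord <- order(-sims, library$ids)
  ok <- sims[ord] >= min_similarity
  if (exclude_exact) ok <- ok & sims[ord] < 1
  cand <- utils::head(ord[ok], max_matches)
  if (length(cand) == 0L) return(predict_coeff(h, coeffs))
  corr <- lapply(cand, function(k)
    correct_from_known(h, library$holograms[[k]], library$logp[[k]], coeffs))
  matches <- data.frame(
    id = library$ids[cand],
    similarity = sims[cand],
    corrected = vapply(corr, `[[`, numeric(1), "value"),
    in_domain = vapply(corr, `[[`, logical(1), "in_domain"),
    stringsAsFactors = FALSE)
  usable <- matches[matches$in_domain, , drop = FALSE]
  if (nrow(usable) == 0L) {
    res <- predict_coeff(h, coeffs)
    res$matches <- matches
    return(res)
  }
  structure(list(value = mean(usable$corrected), mode = "library",
                 in_domain = TRUE, missing_codes = character(0),
                 matches = matches),
            class = "jplogp_prediction")
}

#' @export
print.jplogp_prediction <- function(x, ...) {
  cat("<jplogp_prediction> ", formatC(x$value, digits = 2, format = "f"),
      " (", x$mode, " mode, ", nrow(x$matches), " matches",
      if (!x$in_domain) ", OUT OF DOMAIN", ")\n", sep = "")
  invisible(x)
}

#' Similarity/match-count grid search
#'
#' Recomputes the library-mode RMSE of an evaluation set for every
#' combination of minimum similarity threshold and maximum match count,
#' the tuning surface on which the defaults 0.75 / 5 were picked.
#'
#' @param library a [build_library()] object.
#' @param eval_holograms list of holograms (or SMILES vector) to predict.
#' @param eval_logp their measured logP values.
#' @param coeffs coefficients.
#' @param similarities thresholds to scan.
#' @param match_counts match caps to scan.
#' @param exclude_exact see [predict_library()].
#' @return numeric matrix of RMSE values, rows = match counts,
#'   columns = similarity thresholds.
#' @export
grid_search <- function(library, eval_holograms, eval_logp, coeffs,
                        similarities = c(0.5, 0.6, 0.7, 0.75, 0.8),
                        match_counts = 1:7, exclude_exact = FALSE) {
  if (is.character(eval_holograms)) {
    mols <- perceive_smiles(eval_holograms)
    eval_holograms <- lapply(mols, type_molecule)
  }
  stopifnot(length(eval_holograms) == length(eval_logp))
  out <- matrix(NA_real_, nrow = length(match_counts),
                ncol = length(similarities),
                dimnames = list(as.character(match_counts),
                                as.character(similarities)))
  for (si in seq_along(similarities)) {
    for (mi in seq_along(match_counts)) {
      preds <- vapply(eval_holograms, function(h)
        predict_library(h, library, coeffs,
                        min_similarity = similarities[si],
                        max_matches = match_counts[mi],
                        exclude_exact = exclude_exact)$value,
        numeric(1))
      out[mi, si] <- sqrt(mean((preds - eval_logp)^2))
    }
  }
  out
}

#' Evaluate predictions against observations
#'
#' RMSE plus the percentage of absolute errors falling in the five
#' half-open bins `[0,0.5) [0.5,1) [1,1.5) [1.5,2) [2,Inf)`.
#'
#' @param predictions,observations numeric vectors of equal length.
#' @return list with `rmse`, `bins` (named percentages) and `n`.
#' @export
evaluate_predictions <- function(predictions, observations) {
  if (length(predictions) != length(observations))
    stop("predictions and observations differ in length")
  if (length(predictions) == 0L) stop("nothing to evaluate")
  err <- abs(predictions - observations)
  breaks <- c(0, 0.5, 1, 1.5, 2, Inf)
  bins <- table(cut(err, breaks, right = FALSE,
                    labels = c("<0.5", "0.5-1", "1-1.5", "1.5-2", ">=2")))
  pct <- stats::setNames(100 * as.vector(bins) / length(err), names(bins))
  list(rmse = sqrt(mean((predictions - observations)^2)),
       bins = pct,
       n = length(err))
}
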