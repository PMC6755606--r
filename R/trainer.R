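## Training: consensus targets, design matrix over the atom-code
## vocabulary, QR least squares and fit statistics.

#' Consensus logP target
#'
#' Arithmetic mean of the per-method predicted logP values used as the
#' training target for one compound.
#'
#' @param predictions numeric vector, one value per prediction method.
#' @return the mean.
#' @export
consensus_mean <- function(predictions) {
  if (length(predictions) == 0L) stop("no predictions to average")
  if (!all(is.finite(predictions))) stop("non-finite prediction value")
  mean(predictions)
}

#' Assemble a training set
#'
#' Types each structure and pairs the holograms with the target logP
#' values. Structures that fail perception are dropped with a warning
#' and reported in the `dropped` field.
#'
#' @param structures character vector of SMILES, or a list of
#'   [perceive()]d molecules / precomputed holograms.
#' @param targets numeric target logP per structure.
#' @param ids optional identifiers.
#' @return object of class `jplogp_training_set`: list with
#'   `holograms`, `targets`, `ids`, `vocabulary`, `dropped`.
#' @export
training_set <- function(structures, targets, ids = NULL) {
  stopifnot(length(structures) == length(targets))
  if (is.null(ids)) ids <- paste0("mol", seq_along(targets))
  holos <- structures_to_holograms(structures, ids)
  keep <- !vapply(holos, is.null, logical(1))
  if (!all(keep))
    warning(sum(!keep), " record(s) failed typing and were dropped",
            call. = FALSE)
  holos <- holos[keep]
  structure(list(
    holograms = holos,
    targets = as.numeric(targets[keep]),
    ids = ids[keep],
    vocabulary = sort(unique(unlist(lapply(holos, names)))),
    dropped = ids[!keep]
  ), class = "jplogp_training_set")
}

structures_to_holograms <- function(structures, ids) {
  if (is.list(structures)) {
    lapply(structures, function(s) {
      if (inherits(s, "jpmol")) type_molecule(s) else as_hologram(s)
    })
  } else {
    mols <- perceive_smiles(structures, ids)
    lapply(mols, function(m) if (is.null(m)) NULL else type_molecule(m))
  }
}

#' Build the count design matrix
#'
#' Row i, column j is the count of atom-code j in compound i; there is
#' no intercept column -- the baseline is absorbed by the ubiquitous
#' carbon and hydrogen codes.
#'
#' @param ts a `jplogp_training_set`, or a list of holograms.
#' @param codes optional fixed, ordered code vocabulary (defaults to the
#'   union observed in `ts`).
#' @return list with `x` (n-by-p integer matrix with code dimnames) and
#'   `y` (target vector, `NULL` when `ts` is a bare hologram list).
#' @export
build_design_matrix <- function(ts, codes = NULL) {
  if (inherits(ts, "jplogp_training_set")) {
    holos <- ts$holograms; y <- ts$targets; ids <- ts$ids
    if (is.null(codes)) codes <- ts$vocabulary
  } else {
    holos <- lapply(ts, as_hologram); y <- NULL
    ids <- names(holos)
    if (is.null(codes)) codes <- sort(unique(unlist(lapply(holos, names))))
  }
  x <- matrix(0L, nrow = length(holos), ncol = length(codes),
              dimnames = list(ids, codes))
  for (r in seq_along(holos)) {
    h <- holos[[r]]
    hit <- intersect(names(h), codes)
    x[r, hit] <- h[hit]
  }
  list(x = x, y = y)
}

#' Fit per-atom-type coefficients by least squares
#'
#' Solves `x %*% alpha ~ y` through a QR decomposition after removing
#' codes whose total occurrence count across the training set is below
#' `min_occurrence` (rare types carry too little information and risk
#' spurious coefficients). Rank-deficient systems fall back to the
#' minimum-norm solution via SVD with a warning; different least-squares
#' solutions of a deficient system have essentially the same predictive
#' power, but the minimum-norm one is reproducible.
#'
#' @param x count design matrix (codes as column names).
#' @param y numeric targets.
#' @param min_occurrence drop codes with a smaller atom-level total.
#' @return object of class `jplogp_model`: list with `coefficients`
#'   (named numeric), `se` (standard errors, `NA` when rank deficient),
#'   `r2`, `rmse`, `n`, `p`, `rank`, `dropped_codes`, `typer_version`.
#' @export
fit_coefficients <- function(x, y, min_occurrence = 3L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  occ <- colSums(x)
  dropped <- colnames(x)[occ < min_occurrence]
  x <- x[, occ >= min_occurrence, drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (p == 0L) stop("no codes survive the occurrence filter")
  if (n < p)
    stop("fewer training rows (", n, ") than coefficients (", p, ")")
  qrx <- qr(x)
  if (qrx$rank < p) {
    warning("rank-deficient design (rank ", qrx$rank, " < ", p,
            "); returning the minimum-norm solution", call. = FALSE)
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-12
    alpha <- drop(sv$v[, pos, drop = FALSE] %*%
                    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
    se <- rep(NA_real_, p)
  } else {
    alpha <- qr.coef(qrx, y)
    resid <- y - drop(x %*% alpha)
    sigma2 <- sum(resid^2) / max(n - p, 1L)
    ## diag of (X'X)^-1 from the SVD factors (stable for ill-conditioned X)
    sv <- svd(x, nu = 0)
    se <- sqrt(rowSums((sv$v %*% diag(1 / sv$d, length(sv$d)))^2) * sigma2)
    names(se) <- colnames(x)
    se <- se[names(alpha)]
  }
  names(alpha) <- colnames(x)
  if (is.null(names(se))) names(se) <- colnames(x)
  met <- fit_metrics(alpha, x, y)
  structure(list(
    coefficients = alpha, se = se,
    r2 = met$r2, rmse = met$rmse,
    n = n, p = p, rank = qrx$rank,
    dropped_codes = dropped,
    min_occurrence = as.integer(min_occurrence),
    typer_version = JPLOGP_TYPER_VERSION
  ), class = "jplogp_model")
}

#' Fit statistics
#'
#' `R^2 = 1 - SS_res / SS_tot` (total sum of squares about the target
#' mean) and the root mean squared residual of the model's predictions.
#'
#' @param coeffs named coefficient vector or a `jplogp_model`.
#' @param x count design matrix.
#' @param y observed targets.
#' @return list with `r2` and `rmse`.
#' @export
fit_metrics <- function(coeffs, x, y) {
  alpha <- as_coefficients(coeffs)
  stopifnot(nrow(x) == length(y))
  common <- intersect(colnames(x), names(alpha))
  pred <- drop(x[, common, drop = FALSE] %*% alpha[common])
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance targets: R^2 undefined")
  ss_res <- sum((y - pred)^2)
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((y - pred)^2)))
}

as_coefficients <- function(coeffs) {
  if (inherits(coeffs, "jplogp_model")) return(coeffs$coefficients)
  if (is.numeric(coeffs) && !is.null(names(coeffs))) return(coeffs)
  stop("coefficients must be a jplogp_model or a named numeric vector")
}

#' @export
print.jplogp_model <- function(x, ...) {
  cat("<jplogp_model> ", x$p, " atom-type coefficients, fit on ", x$n,
      " compounds\n  R^2 = ", formatC(x$r2, digits = 4, format = "f"),
      ", training RMSE = ", formatC(x$rmse, digits = 4, format = "f"),
      "\n", sep = "")
  if (length(x$dropped_codes))
    cat("  ", length(x$dropped_codes),
        " code(s) below the occurrence filter were dropped\n", sep = "")
  invisible(x)
}
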