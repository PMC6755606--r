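## File I/O: structure files, coefficient bundles, libraries.

#' Read structures from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line, optionally followed by
#' whitespace and an identifier. SDF files are V2000. Per-record parse
#' failures are logged as warnings, not fatal.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @return list of [perceive()]d molecules (failed records are dropped);
#'   the `"failures"` attribute lists their ids.
#' @export
read_structures <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "'")
  if (format == "auto")
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE))
      "sdf" else "smiles"
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    tok <- strsplit(trimws(lines), "\\s+")
    smi <- vapply(tok, `[[`, character(1), 1L)
    ids <- vapply(seq_along(tok), function(k)
      if (length(tok[[k]]) > 1L) tok[[k]][2L] else paste0("mol", k),
      character(1))
    mols <- perceive_smiles(smi, ids)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    recs <- split_sdf_records(normalize_to_sdf(txt, from = "SDF"))
    mols <- vector("list", length(recs))
    fail <- character(0)
    for (k in seq_along(recs)) {
      id <- trimws(recs[[k]][1L])
      if (!nzchar(id)) id <- paste0("mol", k)
      m <- tryCatch(build_jpmol(recs[[k]], id = id), error = function(e) e)
      if (inherits(m, "error")) {
        fail <- c(fail, id)
        warning("skipping '", id, "': ", conditionMessage(m), call. = FALSE)
      } else mols[[k]] <- m
    }
    names(mols) <- vapply(seq_along(recs), function(k) {
      id <- trimws(recs[[k]][1L]); if (nzchar(id)) id else paste0("mol", k)
    }, character(1))
    attr(mols, "failures") <- fail
  }
  keep <- !vapply(mols, is.null, logical(1))
  out <- mols[keep]
  attr(out, "failures") <- attr(mols, "failures")
  out
}

#' Save / load a trained model bundle
#'
#' The interchange format is CSV with a `#`-prefixed metadata header
#' (typer version, training size, fit statistics) followed by
#' `code,coefficient` rows written at full precision, so a bundle
#' round-trips bit-exactly. Loading refuses a bundle whose typer version
#' differs from the running typer -- a silent vocabulary drift would
#' corrupt every prediction.
#'
#' @param model a `jplogp_model` ([fit_coefficients()]).
#' @param path output path.
#' @export
save_bundle <- function(model, path) {
  stopifnot(inherits(model, "jplogp_model"))
  hdr <- c(
    sprintf("# typer_version: %s", model$typer_version),
    sprintf("# n_train: %d", model$n),
    sprintf("# n_codes: %d", model$p),
    sprintf("# r2: %s", format(model$r2, digits = 17)),
    sprintf("# rmse: %s", format(model$rmse, digits = 17)),
    "code,coefficient")
  rows <- sprintf("%s,%s", names(model$coefficients),
                  vapply(model$coefficients, format, character(1), digits = 17))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname save_bundle
#' @return `load_bundle()`: a `jplogp_model` with the stored
#'   coefficients and metadata (standard errors are not serialized).
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(kv) == 3L) meta[[trimws(kv[2L])]] <- trimws(kv[3L])
  }
  ver <- meta[["typer_version"]]
  if (is.null(ver) || !identical(ver, JPLOGP_TYPER_VERSION))
    stop("coefficient bundle typer version '", ver %||% "<missing>",
         "' does not match the running typer '", JPLOGP_TYPER_VERSION, "'")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0L || body[1L] != "code,coefficient")
    stop("malformed coefficient bundle: missing 'code,coefficient' header")
  df <- utils::read.csv(text = body, colClasses = c("character", "numeric"))
  alpha <- stats::setNames(df$coefficient, df$code)
  structure(list(
    coefficients = alpha, se = rep(NA_real_, length(alpha)),
    r2 = as.numeric(meta[["r2"]] %||% NA),
    rmse = as.numeric(meta[["rmse"]] %||% NA),
    n = as.integer(meta[["n_train"]] %||% NA),
    p = length(alpha), rank = NA_integer_,
    dropped_codes = character(0),
    min_occurrence = NA_integer_,
    typer_version = ver
  ), class = "jplogp_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a reference library CSV
#'
#' Columns `id,smiles,logp`; holograms are computed on load under the
#' running typer.
#'
#' @param path CSV path.
#' @return a `jplogp_library`.
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "logp")
  if (!all(need %in% names(df)))
    stop("library CSV must have columns: ", paste(need, collapse = ", "))
  build_library(df$smiles, df$logp, ids = as.character(df$id))
}

#' @rdname read_library
#' @param library a `jplogp_library`.
#' @param smiles SMILES strings matching the library entries (the
#'   library object itself stores holograms, not structures).
#' @export
write_library <- function(library, smiles, path) {
  stopifnot(inherits(library, "jplogp_library"),
            length(smiles) == length(library$ids))
  utils::write.csv(
    data.frame(id = library$ids, smiles = smiles, logp = library$logp),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' JSON serialization of holograms
#'
#' @param holograms named list of holograms.
#' @param path output path.
#' @export
write_holograms_json <- function(holograms, path) {
  jsonlite::write_json(lapply(holograms, function(h) as.list(h)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_holograms_json
#' @export
read_holograms_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x) {
    h <- vapply(x, function(v) as.integer(v), integer(1))
    h[order(names(h))]
  })
}
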