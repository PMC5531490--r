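#' Read and write transient-absorption surfaces
#'
#' Two on-disk dialects are supported: a long-format CSV with columns
#' \code{wavelength_nm, time_s, delta_A}, and a wide-format TSV matrix whose
#' first column is \code{wavelength_nm} and whose remaining column names are
#' the delay times in seconds.
#'
#' @param surface a [TransientAbsorptionSurface-class].
#' @param path file path.
#' @return the written path (writers, invisibly) or a
#'   [TransientAbsorptionSurface-class] (readers).
#' @name surfaceIO
NULL

#' @rdname surfaceIO
#' @export
writeSurfaceCSV <- function(surface, path) {
  stopifnot(is(surface, "TransientAbsorptionSurface"))
  df <- data.frame(
    wavelength_nm = rep(surface@wavelengths, times = length(surface@times)),
    time_s = rep(surface@times, each = length(surface@wavelengths)),
    delta_A = as.vector(surface@deltaA))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname surfaceIO
#' @export
readSurfaceCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "time_s", "delta_A")
  if (!all(need %in% names(df)))
    stop("surface CSV must have columns ", paste(need, collapse = ", "))
  wl <- sort(unique(df$wavelength_nm)); tt <- sort(unique(df$time_s))
  m <- matrix(NA_real_, length(wl), length(tt))
  m[cbind(match(df$wavelength_nm, wl), match(df$time_s, tt))] <- df$delta_A
  if (anyNA(m)) stop("surface CSV does not cover a complete grid")
  new("TransientAbsorptionSurface", wavelengths = wl, times = tt, deltaA = m)
}

#' @rdname surfaceIO
#' @export
writeSurfaceTSV <- function(surface, path) {
  stopifnot(is(surface, "TransientAbsorptionSurface"))
  df <- data.frame(wavelength_nm = surface@wavelengths, surface@deltaA,
                   check.names = FALSE)
  names(df)[-1L] <- sprintf("%.12g", surface@times)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname surfaceIO
#' @export
readSurfaceTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  new("TransientAbsorptionSurface",
      wavelengths = df[[1L]],
      times = as.numeric(names(df)[-1L]),
      deltaA = unname(as.matrix(df[, -1L, drop = FALSE])))
}

#' Two-column trace CSV
#'
#' Plain (time, value) CSV used for photocurrent, pump and voltage traces;
#' epochs and recording metadata travel in a YAML sidecar (see
#' [writeParamsYAML()]).
#'
#' @param time,value the series.
#' @param path file path.
#' @param names column names.
#' @return written path (invisibly) or a data.frame with the two columns.
#' @export
writeTraceCSV <- function(time, value, path, names = c("time", "value")) {
  df <- data.frame(time, value)
  colnames(df) <- names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("trace CSV must have at least two columns")
  df[, 1:2]
}

#' Aligned FASTA input
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet} that additionally
#' checks the sequences are aligned (equal width) and uniquely named.
#'
#' @param path FASTA file of pre-aligned amino-acid sequences.
#' @return an \code{AAStringSet}.
#' @export
readAlignmentFasta <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  names(aln) <- sub("\\s.*$", "", names(aln))
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  if (anyDuplicated(names(aln))) stop("duplicate taxa names in ", path)
  aln
}

#' @rdname readAlignmentFasta
#' @param aln an \code{AAStringSet} or [SyntheticAlignment-class].
#' @export
writeAlignmentFasta <- function(aln, path) {
  if (is(aln, "SyntheticAlignment")) aln <- aln@alignment
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

#' PHYLIP square distance-matrix format
#'
#' @param d symmetric distance matrix with taxa dimnames.
#' @param path file path.
#' @return written path (invisibly) or the matrix (reader).
#' @export
writePhylipDist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  invisible(path)
}

#' @rdname writePhylipDist
#' @export
readPhylipDist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  parts <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  taxa <- vapply(parts, `[[`, character(1), 1L)
  d <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
  dimnames(d) <- list(taxa, taxa)
  d
}

#' Newick tree output
#'
#' @param tree a \code{phylo} (node labels, e.g. bootstrap supports, are
#'   written as internal-node labels).
#' @param path file path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' YAML parameter files
#'
#' Generator/run parameters are stored as YAML so that a simulation is fully
#' described by its sidecar.
#'
#' @param params named list.
#' @param path file path.
#' @export
writeParamsYAML <- function(params, path) {
  writeLines(yaml::as.yaml(params), path)
  invisible(path)
}

#' @rdname writeParamsYAML
#' @export
readParamsYAML <- function(path) yaml::read_yaml(path)

#' JSON fit report
#'
#' Serializes a [GlobalFitResult-class] (taus, RSS, BIC, parameter count) —
#' and optionally a [selectComponents()] BIC table — with fixed key order and
#' 12 significant digits, so reruns under the same seed are byte-identical.
#'
#' @param fit a [GlobalFitResult-class].
#' @param path file path.
#' @param bicTable optional data.frame from [selectComponents()].
#' @export
writeFitReport <- function(fit, path, bicTable = NULL) {
  stopifnot(is(fit, "GlobalFitResult"))
  rep <- list(
    n_components = length(fit@taus),
    tau_s = fit@taus,
    rss = fit@rss,
    bic = fit@bic,
    n_parameters = fit@nParameters,
    offset_fitted = fit@offsetFitted)
  if (!is.null(bicTable)) rep$bic_table <- bicTable
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' DAS matrix as TSV
#'
#' One row per wavelength, one column per component (named by tau), plus the
#' offset spectrum when fitted.
#'
#' @param fit a [GlobalFitResult-class].
#' @param path file path.
#' @export
writeDasTSV <- function(fit, path) {
  stopifnot(is(fit, "GlobalFitResult"))
  df <- data.frame(wavelength_nm = fit@wavelengths, fit@das,
                   check.names = FALSE)
  names(df)[-1L] <- sprintf("tau_%.6gs", fit@taus)
  if (fit@offsetFitted) df$offset <- fit@offsetSpectrum
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
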