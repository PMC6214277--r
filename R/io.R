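#' Read a PTE matrix from a labelled TSV file
#'
#' Expects a tab-separated square numeric table whose header row and first
#' column carry identical region labels. A nonzero diagonal is zeroed with
#' a warning; ragged rows and label mismatches are errors naming the
#' offending row.
#'
#' @param path file path.
#' @return a [pte_matrix_obj()].
#' @export
read_pte_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged table: row %d of '%s' has %d fields, expected %d",
                 bad, path, nf[bad], nf[1L]))
  }
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric entries in PTE table")
  if (nrow(M) != ncol(M)) {
    stop(sprintf("table is not square: %d rows x %d columns", nrow(M), ncol(M)))
  }
  if (!identical(rownames(M), colnames(M))) {
    bad <- which(rownames(M) != colnames(M))[1L]
    stop(sprintf("row/column label mismatch at position %d: '%s' vs '%s'",
                 bad, rownames(M)[bad], colnames(M)[bad]))
  }
  if (any(diag(M) != 0)) {
    warning("nonzero diagonal in PTE table; forcing diagonal to 0")
    diag(M) <- 0
  }
  pte_matrix_obj(M, rownames(M), meta = list(source = path))
}

#' Write a PTE matrix as labelled TSV
#'
#' @param pte a [pte_matrix_obj()] or square matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pte_tsv <- function(pte, path) {
  V <- pte_values(pte)
  df <- data.frame(region = rownames(V), V, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a directed network as an edge list (source TAB target)
#'
#' @param net a [directed_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  A <- net_adjacency(net)
  e <- which(A == 1L, arr.ind = TRUE)
  df <- data.frame(source = rownames(A)[e[, 1L]],
                   target = rownames(A)[e[, 2L]])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phase ensemble to a directory
#'
#' One TSV per subject-epoch unit (regions x samples) plus a
#' `meta.json` sidecar with labels and dimensions.
#'
#' @param ensemble a [phase_ensemble()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phase_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "phase_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(ensemble$data)
  for (s in seq_len(d[1L])) {
    for (e in seq_len(d[2L])) {
      X <- ensemble$data[s, e, , , drop = TRUE]
      if (d[3L] == 1L) X <- matrix(X, nrow = 1L)
      rownames(X) <- ensemble$region_labels
      utils::write.table(
        X, file.path(dir, sprintf("phases_s%03d_e%03d.tsv", s, e)),
        sep = "\t", quote = FALSE, col.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(n_subjects = d[1L], n_epochs = d[2L], n_regions = d[3L],
         n_samples = d[4L], region_labels = ensemble$region_labels),
    file.path(dir, "meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values parse as numbers when possible, `true`/`false` as logicals.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}
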