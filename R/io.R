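# Delimited-matrix input/output and sample alignment.
#
# Files are plain TSV/CSV: a header row of feature names, a first column
# of sample identifiers, numeric payload. Validation is strict and errors
# name the offending line, row or column, which is why parsing is done
# line-by-line rather than through a lenient reader.

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a labeled numeric matrix from delimited text
#'
#' @param path TSV (default) or CSV file; delimiter inferred from the
#'   extension, overridable with `delim`.
#' @param delim optional field delimiter.
#' @return numeric matrix with sample identifiers as rownames and feature
#'   names as colnames.
#' @export
scca_read_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- infer_delim(path, delim)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop(sprintf("%s: need a header and at least one row", path), call. = FALSE)
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- cells[[1L]]
  width <- length(header)
  widths <- lengths(cells[-1L])
  if (any(widths != width)) {
    bad <- which(widths != width)[1L] + 1L
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad, widths[bad - 1L], width), call. = FALSE)
  }
  if (width < 2L) stop(sprintf("%s: no feature columns", path), call. = FALSE)
  ids <- vapply(cells[-1L], `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate sample identifier(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  feat <- header[-1L]
  vals <- suppressWarnings(
    vapply(cells[-1L], function(row) as.numeric(row[-1L]), numeric(width - 1L)))
  vals <- matrix(vals, nrow = width - 1L)  # features x samples
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-numeric value at row '%s', column '%s'",
                 path, ids[bad[["col"]]], feat[bad[["row"]]]), call. = FALSE)
  }
  out <- t(vals)
  dimnames(out) <- list(ids, feat)
  out
}

#' Write a labeled numeric matrix as delimited text
#'
#' Values are written with 10 significant digits so that a
#' write/read round trip reproduces the matrix to float-formatting
#' precision.
#'
#' @param x numeric matrix with rownames (sample identifiers) and colnames.
#' @param path output file; delimiter inferred from the extension.
#' @param delim optional field delimiter.
#' @param id_name header label for the identifier column.
#' @return `path`, invisibly.
#' @export
scca_write_matrix <- function(x, path, delim = NULL, id_name = "sample_id") {
  delim <- infer_delim(path, delim)
  ids <- rownames(x) %||% sprintf("S%d", seq_len(nrow(x)))
  feat <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  body <- apply(x, 1L, function(row) {
    paste(formatC(row, digits = 10L, format = "g"), collapse = delim)
  })
  writeLines(c(paste(c(id_name, feat), collapse = delim),
               paste(ids, body, sep = delim)),
             path)
  invisible(path)
}

#' Align two labeled matrices by sample identifier
#'
#' Rows are reordered to the intersection of identifiers, preserving the
#' order of the first matrix; dropped samples are reported with a warning.
#'
#' @param m1,m2 numeric matrices with identifiers as rownames.
#' @return list with the aligned matrices `x1`, `x2` and `dropped_1`,
#'   `dropped_2` (identifiers not shared).
#' @export
scca_align <- function(m1, m2) {
  if (is.null(rownames(m1)) || is.null(rownames(m2))) {
    stop("both matrices must carry sample identifiers as rownames", call. = FALSE)
  }
  shared <- rownames(m1)[rownames(m1) %in% rownames(m2)]
  if (length(shared) == 0L) stop("no shared sample identifiers", call. = FALSE)
  if (length(shared) < 3L) stop("fewer than 3 shared samples", call. = FALSE)
  d1 <- setdiff(rownames(m1), shared)
  d2 <- setdiff(rownames(m2), shared)
  if (length(d1) || length(d2)) {
    warning(sprintf("dropped %d sample(s) from m1 and %d from m2 not shared",
                    length(d1), length(d2)), call. = FALSE)
  }
  list(x1 = m1[shared, , drop = FALSE],
       x2 = m2[shared, , drop = FALSE],
       dropped_1 = d1, dropped_2 = d2)
}

# ---- run output -----------------------------------------------------------

#' Write the outputs of a fit (and optional permutation test) to a directory
#'
#' Writes the canonical weights as two delimited tables, a tidy
#' per-component TSV, a JSON run summary (correlations, explained
#' variance, convergence, seed) and an echo of the effective
#' configuration. Nothing is written without the configuration echo
#' alongside it.
#'
#' @param fit an [scca_fit()].
#' @param dir output directory; must not exist unless `force`.
#' @param perm optional [scca_perm_test()] result.
#' @param config the effective configuration list to echo.
#' @param force overwrite an existing directory.
#' @return `dir`, invisibly.
#' @export
scca_write_run <- function(fit, dir, perm = NULL, config = list(), force = FALSE) {
  stopifnot(inherits(fit, "scca_fit"))
  if (dir.exists(dir) && !force &&
      length(list.files(dir, all.files = TRUE, no.. = TRUE))) {
    stop(sprintf("output directory %s exists and is not empty (use force)", dir),
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  w1 <- fit$alpha; w2 <- fit$beta
  scca_write_matrix(t(w1), file.path(dir, "weights_x1.tsv"), id_name = "component")
  scca_write_matrix(t(w2), file.path(dir, "weights_x2.tsv"), id_name = "component")

  comp_tab <- tibble::tibble(
    component = seq_len(fit$k),
    rho_insample = fit$rho,
    rho_oos = if (is.null(fit$rho_oos)) NA_real_ else fit$rho_oos,
    cpev = fit$ev_1$cpev,
    cpev_adj = fit$ev_1$cpev_adj,
    cpev_2 = fit$ev_2$cpev,
    cpev_adj_2 = fit$ev_2$cpev_adj,
    n_iter = fit$n_iter,
    converged = fit$converged)
  utils::write.table(comp_tab, file.path(dir, "components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    package = "softcca",
    version = as.character(utils::packageVersion("softcca")),
    n = fit$n, p = fit$p, q = fit$q, k = fit$k,
    sparsity = fit$sparsity,
    seed = fit$seed, tol = fit$tol, max_iter = fit$max_iter,
    init = fit$init, cpev_convention = fit$cpev_convention,
    rho_insample = fit$rho, rho_oos = fit$rho_oos,
    cpev_1 = fit$ev_1$cpev, cpev_adj_1 = fit$ev_1$cpev_adj,
    cpev_2 = fit$ev_2$cpev, cpev_adj_2 = fit$ev_2$cpev_adj,
    converged = fit$converged, n_iter = fit$n_iter)
  if (!is.null(perm)) {
    summary$permutation <- as.list(
      tibble::as_tibble(perm)[, setdiff(names(perm), "null_draws")])
    utils::write.table(
      tibble::as_tibble(perm)[, setdiff(names(perm), "null_draws")],
      file.path(dir, "permutation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
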