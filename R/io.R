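#' Read a tab-delimited expression matrix
#'
#' Expects the de-facto standard matrix dialect: a header row of sample ids,
#' then one row per gene with the gene id in the first column and numeric
#' log-scale expression values in the remaining columns. Duplicate gene ids
#' and non-numeric cells are rejected with the offending id / cell named in
#' the error.
#'
#' @param path Path to the tab-delimited file.
#' @return Numeric genes x samples matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) {
    stop(sprintf("'%s': expected a gene-id column plus at least one sample column",
                 path), call. = FALSE)
  }
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids) > 0L) {
    stop("duplicate sample ids in header", call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write an expression matrix as tab-delimited text
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Header of the gene-id column.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(expr, path, id_column = "gene_id") {
  check_expression_matrix(expr)
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then the member gene ids, all
#' tab-separated. File order is preserved; duplicate members within a line
#' are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; descriptions attached as
#'   attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning(sprintf("'%s' contains no gene sets", path), call. = FALSE)
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]), call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    u <- unique(members)
    if (length(u) < length(members)) {
      warning(sprintf("duplicate member(s) in set '%s' dropped", f[1]),
              call. = FALSE)
    }
    u
  })
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a DMI results table
#'
#' Tab-delimited, full precision (values survive a write-read round trip to
#' the printed precision of 15 significant digits).
#'
#' @param results A `dmi_result` data frame from [run_dmi()].
#' @param path File path.
#' @return `write_dmi_results` returns the path invisibly;
#'   `read_dmi_results` returns the data frame.
#' @export
write_dmi_results <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dmi_results
#' @export
read_dmi_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a stochastic run: the full
#' configuration, the seeds, digests of the input files, the gamma-table
#' provenance and the package version, as JSON.
#'
#' @param path Output path for the JSON manifest.
#' @param config A [dmi_config()] (or any list of settings).
#' @param inputs Named character vector of input file paths; MD5 digests are
#'   recorded for each existing file.
#' @param extra Optional named list of additional fields.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character(0),
                               extra = list()) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- c(list(
    package = "dmi",
    version = as.character(utils::packageVersion("dmi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass_deep(config),
    input_digests = digests,
    gamma_table = gamma_table()
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
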