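#' Read and write run reports, expression matrices and id lists
#'
#' Plain TSV formats used throughout the screen:
#' * run report: columns `protein_id`, `spectra`, `local_fdr_pct`; run
#'   metadata (`run_id`, `genotype`, `include_in_quant`) carried as
#'   attributes and written to/read from `# key: value` header comments;
#' * expression matrix: `gene_id` column then one column per sample;
#' * id list: one identifier per line, no header.
#'
#' FASTA is handled by Biostrings
#' ([Biostrings::readAAStringSet()] / [Biostrings::writeXStringSet()]).
#'
#' @param path File path.
#' @param report Run report data frame (see [simulate_runs()]).
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
write_run_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(run_id = attr(report, "run_id") %||% NA_character_,
            genotype = attr(report, "genotype") %||% NA_character_,
            include_in_quant = tolower(as.character(
              attr(report, "include_in_quant") %||% TRUE)))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_run_report <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: *", "", kv)
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric"))
  attr(df, "run_id") <- meta$run_id
  attr(df, "genotype") <- meta$genotype
  attr(df, "include_in_quant") <- identical(meta$include_in_quant, "true")
  df
}

#' @rdname screen_io
#' @param matrix Numeric matrix with gene rownames and sample colnames.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' @rdname screen_io
#' @param ids Character vector of identifiers.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_id_list <- function(path) {
  readLines(path)
}

#' @rdname screen_io
#' @param annotations Data frame with `gene_id`, `term_id`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, c("gene_id", "term_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_annotations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
}
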