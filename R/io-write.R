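# Table writers for pipeline outputs. Every kind has a fixed column order so
# downstream diffs are stable; floats are printed with 6 decimals, the
# precision used for reported discordance scores.

table_schemas <- list(
  candidates = c(
    loop_id = "c", chrom = "c", start1 = "i", end1 = "i",
    start2 = "i", end2 = "i", span = "i", pet_count = "i", fdr = "d",
    start_motif_start = "i", start_motif_end = "i", start_motif_strand = "c",
    start_motif_score = "d", end_motif_start = "i", end_motif_end = "i",
    end_motif_strand = "c", end_motif_score = "d", label = "c"
  ),
  scores = c(
    loop_id = "c", chrom = "c", start1 = "i", end1 = "i",
    start2 = "i", end2 = "i", score = "d"
  ),
  discordance = c(
    loop_id = "c", chrom = "c", startloop = "i", endloop = "i",
    s_control = "d", s_case = "d", d_score = "d", klass = "c",
    gene_name = "c", overlap_bp = "i"
  ),
  gene_ranking = c(
    gene_name = "c", klass = "c", total_d_score = "d", n_loops = "i"
  )
)

#' Write a pipeline table with a fixed, kind-specific layout
#'
#' @param x A data frame holding at least the columns of the chosen kind.
#' @param path Output path (tab-separated, header line).
#' @param kind One of `"candidates"`, `"scores"`, `"discordance"`,
#'   `"gene_ranking"`.
#' @return `path`, invisibly. Floating-point columns are written with six
#'   decimals; [read_genomic_table()] restores the typed tibble.
#' @export
write_genomic_table <- function(x, path, kind) {
  schema <- table_schemas[[match.arg(kind, names(table_schemas))]]
  missing <- setdiff(names(schema), names(x))
  if (length(missing) > 0) {
    abort(sprintf("Table of kind '%s' lacks column(s): %s.", kind,
                  paste(missing, collapse = ", ")))
  }
  out <- as_tibble(x)[, names(schema), drop = FALSE]
  for (col in names(schema)[schema == "d"]) {
    out[[col]] <- fmt_num(out[[col]])
  }
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) abort(sprintf("Cannot write %s: %s", path,
                                      conditionMessage(e)))
  )
  invisible(path)
}

#' Read back a table written by [write_genomic_table()]
#'
#' @param path Path to a table file.
#' @param kind The kind it was written as.
#' @return A typed tibble with the kind's column layout.
#' @export
read_genomic_table <- function(path, kind) {
  schema <- table_schemas[[match.arg(kind, names(table_schemas))]]
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = paste(schema, collapse = ""))
  missing <- setdiff(names(schema), names(x))
  if (length(missing) > 0) {
    abort(sprintf("File %s is not a '%s' table; lacks: %s.", path, kind,
                  paste(missing, collapse = ", ")))
  }
  x
}
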