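#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' Parses peak calls as produced by the ENCODE uniform ChIP-seq/DNase
#' pipelines. The `signalValue` column (column 7) is kept as the peak
#' `score`; the BED score column 5 is discarded. Data lines with inverted
#' coordinates (`end <= start`) are skipped with a warning naming the line
#' numbers; the number of skipped lines is available as
#' `attr(x, "n_skipped")`.
#'
#' @param path Path to a narrowPeak file (>= 10 tab-separated columns).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `strand` and `score` (the signalValue).
#' @export
read_narrowpeak <- function(path) {
  lines <- read_format_lines(path)
  if (length(lines$text) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), strand = character(), score = double())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  nf <- count_fields_tsv(lines$text)
  bad <- which(nf < 10)
  if (length(bad) > 0) {
    abort(sprintf(
      "narrowPeak requires >= 10 tab-separated columns; line %d of %s has %d.",
      lines$lineno[bad[1]], path, nf[bad[1]]))
  }
  raw <- parse_tsv_body(lines$text, n_max_col = 10)
  out <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = raw[[4]],
    strand = raw[[6]],
    score = as.numeric(raw[[7]])
  )
  inverted <- which(out$end <= out$start)
  if (length(inverted) > 0) {
    warn(sprintf(
      "Skipping %d narrowPeak line(s) with end <= start (line %s of %s).",
      length(inverted),
      paste(lines$lineno[inverted], collapse = ", "), path))
    out <- out[-inverted, , drop = FALSE]
  }
  attr(out, "n_skipped") <- length(inverted)
  out
}

#' Read loop calls from a bedpe file
#'
#' Reads paired-anchor loop calls such as the interaction files emitted by
#' ChIA-PET2 after conversion to bedpe. Anchors are normalised so that
#' `anchor1` is the one with the smaller midpoint; inter-chromosomal rows
#' are dropped and counted in `attr(x, "n_interchrom")`.
#'
#' @param path Path to the bedpe file.
#' @param pet_col,fdr_col 1-based column indices holding the PET count and
#'   the FDR. Defaults follow the ChIA-PET2 interaction layout
#'   (count in column 7, FDR in column 9). Set either to `NA` to fill the
#'   field with a permissive default (PET count 2, FDR 0).
#' @return A tibble with columns `loop_id`, `chrom`, `start1`, `end1`,
#'   `start2`, `end2`, `pet_count`, `fdr`.
#' @export
read_bedpe_loops <- function(path, pet_col = 7, fdr_col = 9) {
  lines <- read_format_lines(path)
  if (length(lines$text) == 0) {
    return(empty_loops_tbl())
  }
  nf <- count_fields_tsv(lines$text)
  bad <- which(nf < 6)
  if (length(bad) > 0) {
    abort(sprintf("bedpe requires >= 6 columns; line %d of %s has %d.",
                  lines$lineno[bad[1]], path, nf[bad[1]]))
  }
  need <- max(6, pet_col, fdr_col, na.rm = TRUE)
  short <- which(nf < need)
  if (length(short) > 0) {
    abort(sprintf(
      "bedpe line %d of %s has %d columns but pet/fdr columns %s were requested.",
      lines$lineno[short[1]], path, nf[short[1]],
      paste(c(pet_col, fdr_col), collapse = "/")))
  }
  raw <- parse_tsv_body(lines$text, n_max_col = need)
  chrom1 <- raw[[1]]
  chrom2 <- raw[[4]]
  out <- tibble(
    chrom = chrom1,
    start1 = as.integer(raw[[2]]),
    end1 = as.integer(raw[[3]]),
    start2 = as.integer(raw[[5]]),
    end2 = as.integer(raw[[6]]),
    pet_count = if (is.na(pet_col)) 2L else as.integer(raw[[pet_col]]),
    fdr = if (is.na(fdr_col)) 0 else as.numeric(raw[[fdr_col]])
  )
  inter <- which(chrom1 != chrom2)
  if (length(inter) > 0) {
    warn(sprintf("Dropping %d inter-chromosomal loop(s) in %s.",
                 length(inter), path))
    out <- out[-inter, , drop = FALSE]
  }
  # normalise anchor order by midpoint
  mid1 <- (out$start1 + out$end1) / 2
  mid2 <- (out$start2 + out$end2) / 2
  flip <- mid2 < mid1
  if (any(flip)) {
    tmp_s <- out$start1[flip]; tmp_e <- out$end1[flip]
    out$start1[flip] <- out$start2[flip]; out$end1[flip] <- out$end2[flip]
    out$start2[flip] <- tmp_s; out$end2[flip] <- tmp_e
  }
  out <- mutate(out, loop_id = sprintf("loop_%05d", row_number()))
  out <- relocate(out, "loop_id")
  attr(out, "n_interchrom") <- length(inter)
  out
}

empty_loops_tbl <- function() {
  out <- tibble(loop_id = character(), chrom = character(),
                start1 = integer(), end1 = integer(),
                start2 = integer(), end2 = integer(),
                pet_count = integer(), fdr = double())
  attr(out, "n_interchrom") <- 0L
  out
}

#' Read CTCF motif hits from a FIMO TSV file
#'
#' Consumes the tab-separated output of FIMO 5.x (header line with
#' `sequence_name`, `start`, `stop`, `strand`, `score`, `p-value`). FIMO
#' coordinates are 1-based inclusive and are converted to the package's
#' 0-based half-open convention (`start - 1`, `stop`). Hits without a
#' definite strand are rejected with a warning, since motif orientation is
#' what convergence is judged on.
#'
#' @param path Path to a FIMO `.tsv` output file.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `score` (FIMO log-odds) and `p_value`.
#' @export
read_fimo_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  needed <- c("sequence_name", "start", "stop", "strand", "score", "p-value")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("FIMO TSV %s lacks required column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = double(), p_value = double()))
  }
  out <- tibble(
    chrom = as.character(x$sequence_name),
    start = as.integer(x$start) - 1L,
    end = as.integer(x$stop),
    strand = as.character(x$strand),
    score = as.numeric(x$score),
    p_value = as.numeric(x[["p-value"]])
  )
  unstranded <- which(!out$strand %in% c("+", "-"))
  if (length(unstranded) > 0) {
    warn(sprintf("Rejecting %d FIMO hit(s) without a +/- strand in %s.",
                 length(unstranded), path))
    out <- out[-unstranded, , drop = FALSE]
  }
  out
}

#' Read gene records from a GTF annotation
#'
#' Imports the annotation through [rtracklayer::import()] and keeps only
#' rows with feature type `gene`, one record per `gene_id`. GTF 1-based
#' inclusive coordinates become 0-based half-open.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
             as.character(S4Vectors::mcols(gr)$type) == "gene"]
  ids <- S4Vectors::mcols(gr)$gene_id
  if (length(gr) > 0 && (is.null(ids) || anyNA(ids) || any(ids == ""))) {
    abort(sprintf("GTF %s contains gene line(s) without a gene_id.", path))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("GTF %s contains duplicated gene_id(s): %s.",
                  path, paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names_col <- S4Vectors::mcols(gr)$gene_name
  if (is.null(names_col)) names_col <- ids
  names_col <- ifelse(is.na(names_col) | names_col == "", ids, names_col)
  tibble(
    gene_id = as.character(ids %||% character(0)),
    gene_name = as.character(names_col %||% character(0)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# -- shared line-level plumbing ----------------------------------------------

read_format_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  text <- readr::read_lines(path, progress = FALSE)
  lineno <- seq_along(text)
  keep <- !grepl("^(#|track\\b|browser\\b)", text) & nzchar(text)
  list(text = text[keep], lineno = lineno[keep])
}

count_fields_tsv <- function(text) {
  lengths(strsplit(text, "\t", fixed = TRUE))
}

parse_tsv_body <- function(text, n_max_col) {
  fields <- strsplit(text, "\t", fixed = TRUE)
  lapply(seq_len(n_max_col), function(i) {
    vapply(fields, function(f) f[[i]], character(1))
  })
}
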