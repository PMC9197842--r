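#' Read a chrom.sizes file
#'
#' Tab-separated `name<TAB>length_bp`, no header.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = "cd", comment = "#")
}

#' Read a BED-like interval file
#'
#' First three columns `chrom`, `start`, `end` (0-based half-open);
#' optional fourth and fifth columns become `name` and `score`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  tibble::as_tibble(df)
}

#' Write intervals as BED
#'
#' @param df Tibble with `chrom`, `start`, `end` and optionally `name`
#'   and `score` columns (or columns named by `name_col` / `score_col`).
#' @param path Output path.
#' @param name_col,score_col Columns to place in BED fields 4 and 5.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name_col = "name", score_col = "score") {
  out <- df[, c("chrom", "start", "end")]
  if (name_col %in% names(df)) out$name <- df[[name_col]]
  if (score_col %in% names(df)) out$score <- df[[score_col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bin track as bedGraph
#'
#' @param track Tibble with `chrom`, `bin` and a value column.
#' @param binning The track's [genome_binning()].
#' @param path Output path.
#' @param value_col Name of the value column (default the third column).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, binning, path,
                           value_col = setdiff(names(track), c("chrom", "bin"))[1]) {
  iv <- bin_intervals(binning, track$chrom[1], track$bin)
  out <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                    value = track[[value_col]])
  out <- out[!is.na(out$value), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write PEI records as BEDPE
#'
#' Columns: promoter interval, enhancer interval, gene, intensity, FDR,
#' and class when present.
#'
#' @param peis PEI tibble (see [call_peis_simple()]).
#' @param binning The 5-kb [genome_binning()].
#' @param chrom Chromosome of the records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(peis, binning, chrom, path) {
  p <- bin_intervals(binning, chrom, peis$promoter_bin)
  e <- bin_intervals(binning, chrom, peis$enhancer_bin)
  out <- data.frame(chrom1 = p$chrom, start1 = p$start, end1 = p$end,
                    chrom2 = e$chrom, start2 = e$start, end2 = e$end,
                    gene = peis$gene, intensity = peis$intensity,
                    fdr = peis$fdr)
  if ("class" %in% names(peis)) out$class <- peis$class
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
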