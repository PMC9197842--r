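#' Define a genome binning
#'
#' A binning tiles each chromosome with fixed-width, 0-based half-open bins:
#' bin `i` covers `[i * bin_size, (i + 1) * bin_size)`. The last bin of a
#' chromosome may be short. All tracks, calls and domains in the package are
#' tied to a binning so that bin indices are convertible to base-pair
#' intervals without ambiguity.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `length`
#'   (chromosome length in bp), e.g. from [read_chrom_sizes()].
#' @param bin_size Bin width in bp (> 0). Typical resolutions are 5000,
#'   20000 and 100000.
#' @return An object of class `genome_binning`.
#' @examples
#' gb <- genome_binning(data.frame(chrom = "chr1", length = 1e6), 20000)
#' n_bins(gb, "chr1")
#' @export
genome_binning <- function(chrom_sizes, bin_size) {
  stopifnot(is.data.frame(chrom_sizes), all(c("chrom", "length") %in% names(chrom_sizes)))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("`bin_size` must be a single positive number")
  }
  cs <- tibble::tibble(
    chrom = as.character(chrom_sizes$chrom),
    length = as.numeric(chrom_sizes$length)
  )
  if (any(cs$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(cs$chrom)) stop("duplicated chromosome names")
  cs$n_bins <- as.integer(ceiling(cs$length / bin_size))
  structure(
    list(chrom_sizes = cs, bin_size = as.numeric(bin_size)),
    class = "genome_binning"
  )
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf(
    "<genome_binning> %d chromosome(s), bin size %g bp, %d bins total\n",
    nrow(x$chrom_sizes), x$bin_size, sum(x$chrom_sizes$n_bins)
  ))
  invisible(x)
}

#' Number of bins on a chromosome
#'
#' @param binning A [genome_binning()].
#' @param chrom Chromosome name.
#' @return Integer bin count.
#' @export
n_bins <- function(binning, chrom) {
  stopifnot(inherits(binning, "genome_binning"))
  i <- match(chrom, binning$chrom_sizes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  binning$chrom_sizes$n_bins[i]
}

#' Convert bin indices to genomic intervals
#'
#' @inheritParams n_bins
#' @param bins 0-based bin indices.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open bp) and
#'   `bin`. The final bin is truncated at the chromosome end.
#' @export
bin_intervals <- function(binning, chrom, bins) {
  stopifnot(inherits(binning, "genome_binning"))
  nb <- n_bins(binning, chrom)
  if (any(bins < 0 | bins >= nb)) stop("bin index out of range for ", chrom)
  len <- binning$chrom_sizes$length[match(chrom, binning$chrom_sizes$chrom)]
  bs <- binning$bin_size
  tibble::tibble(
    chrom = chrom,
    start = bins * bs,
    end = pmin((bins + 1) * bs, len),
    bin = as.integer(bins)
  )
}

#' Map bp positions to bin indices
#'
#' @inheritParams n_bins
#' @param pos 0-based bp positions. A position exactly on a bin edge belongs
#'   to the right-hand bin (half-open convention).
#' @return Integer vector of 0-based bin indices.
#' @export
pos_to_bin <- function(binning, chrom, pos) {
  stopifnot(inherits(binning, "genome_binning"))
  len <- binning$chrom_sizes$length[match(chrom, binning$chrom_sizes$chrom)]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  if (any(pos < 0 | pos >= len)) stop("position outside chromosome ", chrom)
  as.integer(floor(pos / binning$bin_size))
}
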