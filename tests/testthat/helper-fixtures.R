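# Shared fixtures: tiny binnings, planted-label generators, and the
# boundary-matching metric used by the TAD recovery tests.

tiny_binning <- function(n_bins, bin_size = 20000, chrom = "chrT") {
  b <- genome_binning(
    data.frame(chrom = chrom, length = n_bins * bin_size), bin_size)
  b
}

# Alternating +/-1 compartment blocks with geometric lengths.
block_labels <- function(n, mean_len = 6) {
  lab <- integer(0)
  cur <- 1L
  while (length(lab) < n) {
    len <- 1 + stats::rgeom(1, 1 / mean_len)
    lab <- c(lab, rep(cur, len))
    cur <- -cur
  }
  lab[seq_len(n)]
}

# Random TAD partition boundaries 0 = b0 < ... < bk = n.
random_tad_boundaries <- function(n, min_bins = 15, max_bins = 50) {
  bnd <- 0L
  while (utils::tail(bnd, 1) < n) {
    bnd <- c(bnd, min(utils::tail(bnd, 1) + sample(min_bins:max_bins, 1), n))
  }
  bnd
}

# Precision / recall / F1 of called vs true boundary positions at +/- tol.
boundary_f1 <- function(called, truth, tol = 1) {
  if (length(called) == 0 || length(truth) == 0) return(0)
  rec <- mean(vapply(truth, function(b) any(abs(called - b) <= tol), TRUE))
  prec <- mean(vapply(called, function(b) any(abs(truth - b) <= tol), TRUE))
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# A compartment call tibble from +/-1 labels.
labels_to_call <- function(labels, chrom = "chrT") {
  tibble::tibble(
    chrom = chrom, bin = seq_along(labels) - 1L,
    label = factor(ifelse(labels > 0, "A", "B"), levels = c("A", "B", "Un"))
  )
}
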