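#' Log-contact correlation matrix
#'
#' Computes the column-wise product-moment correlation of
#' `log2(value + pseudocount)` over unmasked bins of a balanced 100-kb map.
#' This is the matrix whose eigenvalue spectrum feeds the Von Neumann
#' entropy. Zero-variance columns (bins whose contact profile is constant)
#' are dropped with a warning.
#'
#' @param map A balanced [contact_map()] with at least 3 unmasked bins.
#' @param pseudocount Added inside the log to keep zero entries finite. The
#'   default `NULL` uses one raw-count-equivalent rescaled by the balancing
#'   biases (`b_i * b_j` per entry) when the map carries a bias vector, and
#'   the smallest positive matrix value otherwise.
#' @return A correlation matrix with attribute `bins` giving the 0-based bin
#'   indices of its rows.
#' @export
log_correlation <- function(map, pseudocount = NULL) {
  stopifnot(inherits(map, "contact_map"))
  if (map$state == "raw") stop("log_correlation() expects a balanced map")
  keep <- which(!map$mask)
  if (length(keep) < 3) stop("need at least 3 unmasked bins")
  A <- map$mat[keep, keep, drop = FALSE]
  if (is.null(pseudocount)) {
    if (!is.null(map$bias)) {
      b <- map$bias[keep]
      P <- outer(b, b)
    } else {
      P <- min(A[A > 0])
    }
  } else {
    P <- pseudocount
  }
  L <- log2(A + P)
  v <- apply(L, 2, stats::var)
  ok <- v > 0
  if (!all(ok)) {
    warning(sum(!ok), " zero-variance bin(s) dropped")
    L <- L[ok, ok, drop = FALSE]
    keep <- keep[ok]
  }
  C <- stats::cor(L)
  attr(C, "bins") <- keep - 1L
  C
}

#' Von Neumann entropy of a correlation matrix
#'
#' Eigen-decomposes `C`, clamps negative round-off eigenvalues to zero,
#' normalizes the spectrum to sum 1, and returns
#' `VNE = -sum(lambda_bar * ln(lambda_bar))` in nats (with `0 * ln 0 = 0`).
#' A rank-1 (perfectly ordered) matrix gives 0; the identity (maximal
#' disorder) gives `ln(n)`.
#'
#' @param C Symmetric correlation matrix, e.g. from [log_correlation()].
#' @return A list of class `vne_result` with `vne`, `spectrum` (raw
#'   eigenvalues), `normalized` and `n`.
#' @export
vne_from_correlation <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (sum(lam) <= 0) stop("degenerate correlation matrix: all-zero spectrum")
  lb <- lam / sum(lam)
  nz <- lb > 0
  vne <- -sum(lb[nz] * log(lb[nz]))
  structure(list(vne = vne, spectrum = lam, normalized = lb, n = nrow(C)),
            class = "vne_result")
}

#' @export
print.vne_result <- function(x, ...) {
  cat(sprintf("<vne_result> n=%d  VNE=%.4f nats (max ln n = %.4f)\n",
              x$n, x$vne, log(x$n)))
  invisible(x)
}

#' Von Neumann entropy per sample and chromosome
#'
#' Composes [log_correlation()] and [vne_from_correlation()] over a set of
#' balanced maps and reports a tidy table plus per-sample means. Higher
#' entropy corresponds to more disordered chromatin structure; in maturing
#' tissue the mean VNE is expected to fall as architecture solidifies.
#'
#' @param maps A named list of samples; each sample is a named list of
#'   balanced [contact_map()]s, one per chromosome.
#' @param pseudocount Passed to [log_correlation()].
#' @return A tibble with columns `sample`, `chromosome`, `n_bins`, `vne`,
#'   and `sample_mean` (the per-sample mean over chromosomes).
#' @export
vne_per_sample <- function(maps, pseudocount = NULL) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  rows <- purrr::imap(maps, function(chrom_maps, sample_id) {
    purrr::imap(chrom_maps, function(m, chrom_id) {
      res <- vne_from_correlation(log_correlation(m, pseudocount))
      tibble::tibble(sample = sample_id, chromosome = chrom_id,
                     n_bins = res$n, vne = res$vne)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(sample_mean = mean(.data$vne)) |>
    dplyr::ungroup()
}
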