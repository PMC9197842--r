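#' Contact map objects
#'
#' A `contact_map` holds one chromosome's symmetric binned contact matrix
#' together with its binning, a mask of invalid bins, and a normalization
#' state tag that only moves forward: `raw` -> `balanced` (KR or
#' KR+quantile) -> `oe`.
#'
#' @param mat Symmetric numeric matrix of non-negative contact values.
#' @param binning A [genome_binning()].
#' @param chrom Chromosome name.
#' @param state One of `"raw"`, `"balanced"`, `"oe"`.
#' @param mask Logical vector, `TRUE` for invalid (masked) bins. Masked bins
#'   have all-zero rows/columns.
#' @param bias Optional per-bin balancing bias vector (0 for masked bins).
#' @return A `contact_map` object.
#' @export
contact_map <- function(mat, binning, chrom, state = "raw", mask = NULL, bias = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  nb <- n_bins(binning, chrom)
  if (nrow(mat) != nb) stop("matrix dimension does not match binning (", nb, " bins)")
  if (any(mat < 0)) stop("contact values must be non-negative")
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) stop("matrix must be symmetric")
  state <- match.arg(state, c("raw", "balanced", "oe"))
  if (is.null(mask)) mask <- rowSums(mat) == 0
  stopifnot(length(mask) == nb)
  mat[mask, ] <- 0
  mat[, mask] <- 0
  structure(
    list(mat = mat, binning = binning, chrom = chrom, state = state,
         mask = mask, bias = bias),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %s: %d bins @ %g bp (%d masked), state=%s, total=%g\n",
    x$chrom, nrow(x$mat), x$binning$bin_size, sum(x$mask), x$state, sum(x$mat) / 2
  ))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$mat)

#' Load a contact map from sparse triplet text
#'
#' Reads tab-separated rows `bin_i<TAB>bin_j<TAB>value` (0-based bin indices,
#' `#` comment lines allowed), mirrors the entries to enforce symmetry, sums
#' duplicates, and masks bins with zero marginal. An empty file yields an
#' all-zero, fully masked map.
#'
#' @param path Path to the triplet file (one chromosome per file).
#' @inheritParams contact_map
#' @return A raw-state [contact_map()].
#' @export
load_contact_map <- function(path, binning, chrom) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("bin_i", "bin_j", "value"),
                          colClasses = c("integer", "integer", "numeric"))
  nb <- n_bins(binning, chrom)
  if (nrow(df) > 0) {
    bad <- which(df$value < 0)
    if (length(bad)) stop("negative contact value at row ", bad[1], " of ", path)
    oob <- which(df$bin_i < 0 | df$bin_i >= nb | df$bin_j < 0 | df$bin_j >= nb)
    if (length(oob)) stop("bin index out of range at row ", oob[1], " of ", path)
  }
  triplets_to_map(df, binning, chrom)
}

# Assemble a symmetric dense map from a (bin_i, bin_j, value) data frame.
# Duplicates (including an entry and its mirror) are summed.
triplets_to_map <- function(df, binning, chrom) {
  nb <- n_bins(binning, chrom)
  mat <- matrix(0, nb, nb)
  if (nrow(df) > 0) {
    i <- pmin(df$bin_i, df$bin_j) + 1L
    j <- pmax(df$bin_i, df$bin_j) + 1L
    key <- (i - 1) * nb + j
    agg <- rowsum(df$value, key)
    key_u <- as.numeric(rownames(agg))
    iu <- (key_u - 1) %/% nb + 1
    ju <- key_u - (iu - 1) * nb
    mat[cbind(iu, ju)] <- agg[, 1]
    low <- lower.tri(mat)
    mat[low] <- t(mat)[low]
  }
  contact_map(mat, binning, chrom, state = "raw")
}

#' Write a contact map as sparse triplet text
#'
#' Emits the upper triangle (including the diagonal) of non-zero entries so
#' that [load_contact_map()] round-trips the matrix exactly.
#'
#' @param map A [contact_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  idx <- which(upper.tri(map$mat, diag = TRUE) & map$mat != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   value = map$mat[idx])
  df <- df[order(df$bin_i, df$bin_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Balance a contact matrix to equal row sums
#'
#' Finds a per-bin bias vector `b` such that `diag(b) %*% A %*% diag(b)` has
#' all unmasked row sums equal to 1, by the symmetric diagonal-scaling fixed
#' point iteration. Bins that are masked (zero marginal, or below the
#' `mask_quantile` coverage quantile) are removed before balancing and get
#' bias 0.
#'
#' @param map A raw [contact_map()].
#' @param tolerance Convergence tolerance on the coefficient of variation of
#'   unmasked row sums (default `1e-6`).
#' @param max_iterations Iteration cap (default 1000).
#' @param mask_quantile Bins whose raw marginal falls at or below this
#'   quantile of the positive marginals are additionally masked (default 0:
#'   only empty bins are masked).
#' @param on_failure `"error"` (default) to fail on non-convergence, or
#'   `"warn"` to return the best iterate with a warning.
#' @return A balanced [contact_map()] whose `bias` field holds the bias
#'   vector.
#' @export
kr_balance <- function(map, tolerance = 1e-6, max_iterations = 1000,
                       mask_quantile = 0, on_failure = c("error", "warn")) {
  stopifnot(inherits(map, "contact_map"))
  if (map$state != "raw") stop("kr_balance() expects a raw map")
  on_failure <- match.arg(on_failure)
  mask <- map$mask
  marg <- rowSums(map$mat)
  if (mask_quantile > 0) {
    pos <- marg[marg > 0]
    mask <- mask | (marg <= stats::quantile(pos, mask_quantile))
  }
  keep <- which(!mask)
  if (length(keep) < 2) stop("need at least 2 unmasked bins to balance")
  A <- map$mat[keep, keep, drop = FALSE]
  b <- rep(1, length(keep))
  cv <- Inf
  for (it in seq_len(max_iterations)) {
    s <- b * as.vector(A %*% b)
    cv <- stats::sd(s) / mean(s)
    if (is.finite(cv) && cv < tolerance) break
    b <- b / sqrt(s)
  }
  b <- b / sqrt(mean(b * as.vector(A %*% b)))  # fix the scale: row sums = 1
  if (!is.finite(cv) || cv >= tolerance) {
    msg <- sprintf("balancing did not converge: row-sum CV %.3g after %d iterations",
                   cv, max_iterations)
    if (on_failure == "error") stop(msg) else warning(msg)
  }
  bias <- numeric(nrow(map$mat))
  bias[keep] <- b
  bal <- map$mat * outer(bias, bias)
  out <- contact_map(bal, map$binning, map$chrom, state = "balanced",
                     mask = mask, bias = bias)
  out
}

#' Distance-stratified quantile normalization across samples
#'
#' For each diagonal stratum (pairs at the same bin distance) the sorted
#' non-zero values of every sample are replaced by the rank-wise mean across
#' samples; within-sample ranks are preserved and zeros stay zero. With
#' `stratify_by_distance = FALSE` a single stratum covers the whole upper
#' triangle. A single sample is returned unchanged. When samples have
#' unequal non-zero counts in a stratum, the mean quantile function is
#' linearly interpolated.
#'
#' @param maps List of balanced [contact_map()]s sharing binning and
#'   chromosome.
#' @param stratify_by_distance Normalize each bin-distance separately
#'   (default `TRUE`).
#' @return List of normalized maps (state stays `balanced`).
#' @export
quantile_normalize <- function(maps, stratify_by_distance = TRUE) {
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, TRUE, "contact_map")))
  if (length(maps) == 1) return(maps)
  chrom <- maps[[1]]$chrom
  nb <- nrow(maps[[1]]$mat)
  for (m in maps) {
    if (m$chrom != chrom || nrow(m$mat) != nb) stop("maps must share chromosome and binning")
    if (m$state == "raw") stop("quantile_normalize() expects balanced maps")
  }
  mats <- lapply(maps, function(m) m$mat)
  strata <- if (stratify_by_distance) 0:(nb - 1) else list(0:(nb - 1))
  for (stratum in strata) {
    idx_list <- list()
    for (d in stratum) {
      i <- seq_len(nb - d)
      idx_list[[length(idx_list) + 1L]] <- cbind(i, i + d)
    }
    idx <- do.call(rbind, idx_list)
    vals <- lapply(mats, function(M) M[idx])
    nz <- lapply(vals, function(v) which(v > 0))
    lens <- lengths(nz)
    if (all(lens == 0)) next
    ref_n <- max(lens)
    sorted <- lapply(seq_along(vals), function(k) {
      v <- sort(vals[[k]][nz[[k]]])
      if (length(v) == 0) return(rep(NA_real_, ref_n))
      if (length(v) == ref_n) return(v)
      if (length(v) == 1) return(rep(v, ref_n))
      stats::approx(seq(0, 1, length.out = length(v)), v,
                    xout = seq(0, 1, length.out = ref_n))$y
    })
    ref <- rowMeans(do.call(cbind, sorted), na.rm = TRUE)
    for (k in seq_along(vals)) {
      if (lens[k] == 0) next
      v <- vals[[k]]
      target <- if (lens[k] == ref_n) ref else
        stats::approx(seq(0, 1, length.out = ref_n), ref,
                      xout = seq(0, 1, length.out = lens[k]))$y
      r <- rank(v[nz[[k]]], ties.method = "average")
      # average ranks interpolate between adjacent order statistics on ties
      v[nz[[k]]] <- if (lens[k] == 1) target[1] else
        stats::approx(seq_len(lens[k]), target, xout = r)$y
      vals[[k]] <- v
      M <- mats[[k]]
      M[idx] <- v
      M[idx[, c(2, 1), drop = FALSE]] <- v
      mats[[k]] <- M
    }
  }
  purrr::map2(maps, mats, function(m, M) {
    contact_map(M, m$binning, m$chrom, state = m$state, mask = m$mask, bias = m$bias)
  })
}

#' Expected contact value by bin distance
#'
#' `profile[d]` is the mean contact value over unmasked pairs at bin
#' distance `d` (d = 0 .. n-1). Distances with no unmasked pair are `NA`.
#'
#' @param map A balanced [contact_map()].
#' @return A tibble with columns `distance`, `expected`, `n_pairs`.
#' @export
expected_by_distance <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  nb <- nrow(map$mat)
  keep <- !map$mask
  out <- tibble::tibble(distance = 0:(nb - 1), expected = NA_real_, n_pairs = 0L)
  for (d in 0:(nb - 1)) {
    i <- seq_len(nb - d)
    ok <- keep[i] & keep[i + d]
    out$n_pairs[d + 1] <- sum(ok)
    if (any(ok)) out$expected[d + 1] <- mean(map$mat[cbind(i[ok], i[ok] + d)])
  }
  out
}

#' Observed-over-expected transform
#'
#' Divides each entry by the expected value at its bin distance. Entries at
#' distances whose expected value is absent or zero are masked (set to 0),
#' never infinite.
#'
#' @param map A balanced [contact_map()].
#' @param profile Expected profile from [expected_by_distance()], either of
#'   this map or of a pooled reference sharing the binning.
#' @return An O/E-state [contact_map()].
#' @export
observed_over_expected <- function(map, profile = expected_by_distance(map)) {
  stopifnot(inherits(map, "contact_map"))
  nb <- nrow(map$mat)
  exp_at <- rep(NA_real_, nb)
  exp_at[profile$distance + 1] <- profile$expected
  oe <- matrix(0, nb, nb)
  for (d in 0:(nb - 1)) {
    e <- exp_at[d + 1]
    i <- seq_len(nb - d)
    if (!is.na(e) && e > 0) {
      v <- map$mat[cbind(i, i + d)] / e
      oe[cbind(i, i + d)] <- v
      oe[cbind(i + d, i)] <- v
    }
  }
  contact_map(oe, map$binning, map$chrom, state = "oe", mask = map$mask,
              bias = map$bias)
}

#' Coarsen a contact map to a larger bin size
#'
#' Sums `factor` x `factor` blocks of the matrix, producing the map the same
#' data would give at `factor`-fold coarser resolution. Raw counts stay raw.
#'
#' @param map A raw [contact_map()].
#' @param factor Integer coarsening factor (e.g. 5 for 20 kb -> 100 kb).
#' @return A raw [contact_map()] on the coarser binning.
#' @export
coarsen_map <- function(map, factor) {
  stopifnot(inherits(map, "contact_map"), factor >= 1)
  if (factor == 1) return(map)
  nb <- nrow(map$mat)
  nb2 <- ceiling(nb / factor)
  grp <- rep(seq_len(nb2), each = factor)[seq_len(nb)]
  G <- matrix(0, nb, nb2)
  G[cbind(seq_len(nb), grp)] <- 1
  mat2 <- t(G) %*% map$mat %*% G
  mat2 <- (mat2 + t(mat2)) / 2
  b2 <- genome_binning(map$binning$chrom_sizes[, c("chrom", "length")],
                       map$binning$bin_size * factor)
  contact_map(mat2, b2, map$chrom, state = "raw")
}
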