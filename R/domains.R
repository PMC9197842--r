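#' Directionality index
#'
#' For each bin `i`, sums balanced contacts to the `window` bins immediately
#' upstream (`A`) and downstream (`B`), truncating one-sidedly at chromosome
#' ends, and scores the bias as a signed chi-square statistic:
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with `E = (A + B)/2`.
#' Positive DI marks downstream bias (domain starts), negative DI upstream
#' bias (domain ends); `DI = 0` when `A = B` or `E = 0`.
#'
#' @param map Balanced [contact_map()] at the TAD-calling resolution.
#' @param window Number of bins on each side (default 10, i.e. 200 kb at
#'   20 kb resolution).
#' @return A tibble with columns `chrom`, `bin`, `A`, `B`, `E`, `di`.
#' @export
directionality_index <- function(map, window = 10) {
  stopifnot(inherits(map, "contact_map"))
  if (map$state == "raw") stop("directionality_index() expects a balanced map")
  nb <- nrow(map$mat)
  M <- map$mat
  A <- B <- numeric(nb)
  for (i in seq_len(nb)) {
    up <- max(1, i - window):(i - 1)
    dn <- (i + 1):min(nb, i + window)
    A[i] <- if (i > 1) sum(M[i, up]) else 0
    B[i] <- if (i < nb) sum(M[i, dn]) else 0
  }
  E <- (A + B) / 2
  di <- ifelse(E > 0, sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E), 0)
  tibble::tibble(chrom = map$chrom, bin = 0:(nb - 1L), A = A, B = B,
                 E = E, di = di)
}

#' TAD calling from the directionality index by HMM
#'
#' Fits a 3-state Gaussian hidden Markov model (upstream-bias / none /
#' downstream-bias) to the DI track by expectation-maximization, decodes the
#' most-probable state path, and emits one domain per downstream-bias run
#' start through the end of the following upstream-bias run. Domains
#' shorter than `min_tad_bins` are discarded. If EM fails to converge, a
#' quantile-threshold state assignment is used with a warning.
#'
#' @param di DI track from [directionality_index()].
#' @param seed Seed for EM initialization jitter.
#' @param min_tad_bins Minimum domain size in bins (default 3).
#' The DI statistic is heavy-tailed (chi-square-like spikes at boundaries
#' over a near-zero interior); emissions are therefore modelled on the
#' signed square root `sign(DI) * sqrt(|DI|)` — a monotone, sign-preserving
#' transform that stabilizes the Gaussian EM without changing which bins
#' are upstream- or downstream-biased.
#'
#' @return A tibble of domains with columns `chrom`, `start_bin`, `end_bin`
#'   (half-open bins) and `source = "DI"`.
#' @export
di_hmm_domains <- function(di, seed = 1, min_tad_bins = 3) {
  x <- sign(di$di) * sqrt(abs(di$di))
  n <- length(x)
  if (all(x == 0)) {
    return(tibble::tibble(chrom = character(), start_bin = integer(),
                          end_bin = integer(), source = character()))
  }
  fit <- tryCatch(fit_gaussian_hmm(x, n_states = 3, seed = seed),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    warning("HMM EM did not converge; falling back to quantile thresholds")
    lo <- stats::quantile(x, 1 / 3); hi <- stats::quantile(x, 2 / 3)
    states <- ifelse(x <= lo, 1L, ifelse(x >= hi, 3L, 2L))
  } else {
    states <- fit$states
  }
  # state 3 = downstream bias (high DI, domain start); state 1 = upstream bias
  r <- rle(states)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  doms <- list()
  k <- 1L
  nruns <- length(r$values)
  while (k <= nruns) {
    if (r$values[k] == 3L) {
      # find next upstream-bias run
      j <- k + 1L
      while (j <= nruns && r$values[j] != 1L) j <- j + 1L
      if (j <= nruns) {
        doms[[length(doms) + 1L]] <- c(starts[k], ends[j])
        k <- j + 1L
        next
      }
    }
    k <- k + 1L
  }
  if (length(doms) == 0) {
    return(tibble::tibble(chrom = character(), start_bin = integer(),
                          end_bin = integer(), source = character()))
  }
  d <- do.call(rbind, doms)
  out <- tibble::tibble(chrom = di$chrom[1], start_bin = d[, 1] - 1L,
                        end_bin = d[, 2], source = "DI")
  out[out$end_bin - out$start_bin >= min_tad_bins, ]
}

#' Insulation score and boundary detection
#'
#' The raw insulation score of bin `i` is the mean contact in the square
#' window `[i-w .. i-1] x [i+1 .. i+w]` straddling the bin; the normalized
#' score is `log2(raw / chromosome mean of raw)`, so it averages 0 along
#' the chromosome. Boundaries are local minima of the normalized score —
#' the lowest point within `delta` bins on either side, which suppresses
#' shallow interior dips — whose prominence (mean of the flanking maxima
#' within `w` bins each side, minus the minimum) is at least
#' `min_strength`. Bins within `w` of the chromosome ends carry no value.
#'
#' @param map Balanced [contact_map()].
#' @param window_bp Square window size in bp (default 500000; 25 bins at
#'   20 kb).
#' @param min_strength Minimum boundary prominence (default 0.1).
#' @param delta Half-width in bins of the neighborhood over which a
#'   boundary must be minimal (default 4).
#' @return A tibble with columns `chrom`, `bin`, `raw`, `is` (normalized)
#'   and `boundary` (logical).
#' @export
insulation_score <- function(map, window_bp = 500000, min_strength = 0.1,
                             delta = 4) {
  stopifnot(inherits(map, "contact_map"))
  if (map$state == "raw") stop("insulation_score() expects a balanced map")
  nb <- nrow(map$mat)
  w <- max(1L, as.integer(round(window_bp / map$binning$bin_size)))
  M <- map$mat
  raw <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    if (i - w < 1 || i + w > nb) next
    raw[i] <- mean(M[(i - w):(i - 1), (i + 1):(i + w)])
  }
  mu <- mean(raw, na.rm = TRUE)
  # floor zero windows at half the smallest positive value so a fully
  # insulated junction scores a deep finite minimum rather than dropping out
  pos <- raw[!is.na(raw) & raw > 0]
  floor_val <- if (length(pos)) min(pos) / 2 else NA_real_
  isv <- ifelse(!is.na(raw) & mu > 0 & !is.na(floor_val),
                log2(pmax(raw, floor_val) / mu), NA_real_)
  boundary <- rep(FALSE, nb)
  v <- isv
  for (i in seq_len(nb)) {
    if (is.na(v[i])) next
    lo <- max(1, i - delta); hi <- min(nb, i + delta)
    nbr <- v[lo:hi][!is.na(v[lo:hi])]
    if (length(nbr) < 2 || v[i] > min(nbr)) next
    if (which.min(v[lo:hi]) + lo - 1L != i) next   # plateau: keep first
    lw <- v[max(1, i - w):(i - 1)]; rw <- v[(i + 1):min(nb, i + w)]
    lmax <- suppressWarnings(max(lw, na.rm = TRUE))
    rmax <- suppressWarnings(max(rw, na.rm = TRUE))
    if (is.finite(lmax) && is.finite(rmax) &&
        mean(c(lmax, rmax)) - v[i] >= min_strength) {
      boundary[i] <- TRUE
    }
  }
  tibble::tibble(chrom = map$chrom, bin = 0:(nb - 1L), raw = raw, is = isv,
                 boundary = boundary)
}

# Domains between consecutive IS boundaries (used by merge_di_is).
is_domains <- function(is_track, min_tad_bins = 3) {
  b <- is_track$bin[which(is_track$boundary)]
  if (length(b) < 2) {
    return(tibble::tibble(chrom = character(), start_bin = integer(),
                          end_bin = integer(), source = character()))
  }
  out <- tibble::tibble(chrom = is_track$chrom[1],
                        start_bin = b[-length(b)], end_bin = b[-1],
                        source = "IS")
  out[out$end_bin - out$start_bin >= min_tad_bins, ]
}

#' Merge DI-derived and IS-derived domains
#'
#' Splits each DI domain at any interior IS boundary, unions the result
#' with IS-derived domains, keeps the finer partition where the two
#' overlap, and re-merges fragments shorter than `min_tad_bins` with their
#' smaller neighbor inside the same parent interval. The output is a
#' non-overlapping domain set.
#'
#' @param tads_di DI domain tibble from [di_hmm_domains()].
#' @param is_track Insulation track from [insulation_score()].
#' @param min_tad_bins Minimum domain size in bins (default 3).
#' @return A tibble of merged domains (`source = "merged"`).
#' @export
merge_di_is <- function(tads_di, is_track, min_tad_bins = 3) {
  bnd <- is_track$bin[which(is_track$boundary)]
  isd <- is_domains(is_track, min_tad_bins)
  pieces <- list()
  covered <- rep(FALSE, nrow(is_track))
  split_interval <- function(s, e, cuts) {
    cuts <- sort(unique(cuts[cuts > s & cuts < e]))
    edges <- c(s, cuts, e)
    segs <- cbind(edges[-length(edges)], edges[-1])
    # re-merge sub-minimum fragments with their smaller neighbor
    repeat {
      lens <- segs[, 2] - segs[, 1]
      small <- which(lens < min_tad_bins)
      if (length(small) == 0 || nrow(segs) == 1) break
      i <- small[1]
      nb_left <- if (i > 1) segs[i - 1, 2] - segs[i - 1, 1] else Inf
      nb_right <- if (i < nrow(segs)) segs[i + 1, 2] - segs[i + 1, 1] else Inf
      if (nb_left <= nb_right) {
        segs[i - 1, 2] <- segs[i, 2]
      } else {
        segs[i + 1, 1] <- segs[i, 1]
      }
      segs <- segs[-i, , drop = FALSE]
    }
    segs
  }
  if (nrow(tads_di) > 0) {
    for (k in seq_len(nrow(tads_di))) {
      s <- tads_di$start_bin[k]; e <- tads_di$end_bin[k]
      segs <- split_interval(s, e, bnd)
      for (j in seq_len(nrow(segs))) {
        pieces[[length(pieces) + 1L]] <- segs[j, ]
      }
      covered[(s + 1):e] <- TRUE   # bins s..e-1, 1-based offset
    }
  }
  # IS domains not overlapping any DI domain are added as-is
  if (nrow(isd) > 0) {
    for (k in seq_len(nrow(isd))) {
      s <- isd$start_bin[k]; e <- isd$end_bin[k]
      if (!any(covered[(s + 1):e])) {
        pieces[[length(pieces) + 1L]] <- c(s, e)
        covered[(s + 1):e] <- TRUE
      }
    }
  }
  if (length(pieces) == 0) {
    return(tibble::tibble(chrom = character(), start_bin = integer(),
                          end_bin = integer(), source = character()))
  }
  d <- do.call(rbind, pieces)
  out <- tibble::tibble(chrom = is_track$chrom[1],
                        start_bin = as.integer(d[, 1]),
                        end_bin = as.integer(d[, 2]), source = "merged")
  out <- dplyr::arrange(out, .data$start_bin)
  out[out$end_bin - out$start_bin >= min_tad_bins, ]
}

#' Jaccard index of two boundary sets
#'
#' Boundaries (unique domain start/end bins) are matched greedily within
#' `tolerance_bins`; the Jaccard index is
#' `|matched| / (|b1| + |b2| - |matched|)`. Two empty sets give 1 by
#' convention.
#'
#' @param tads1,tads2 Domain tibbles sharing a binning.
#' @param tolerance_bins Matching slack in bins (default 1).
#' @return A single number in `[0, 1]`.
#' @export
boundary_jaccard <- function(tads1, tads2, tolerance_bins = 1) {
  b1 <- sort(unique(c(tads1$start_bin, tads1$end_bin)))
  b2 <- sort(unique(c(tads2$start_bin, tads2$end_bin)))
  if (length(b1) == 0 && length(b2) == 0) return(1)
  if (length(b1) == 0 || length(b2) == 0) return(0)
  used <- rep(FALSE, length(b2))
  matched <- 0L
  for (x in b1) {
    d <- abs(b2 - x)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tolerance_bins) {
      matched <- matched + 1L
      used[j] <- TRUE
    }
  }
  matched / (length(b1) + length(b2) - matched)
}

#' Consensus TADs across samples
#'
#' Clusters domains across samples when both boundaries agree within
#' `tolerance_bins`, and emits clusters present in at least
#' `min_fraction` of the samples with median boundaries.
#'
#' @param tad_sets Named list of per-sample domain tibbles.
#' @param tolerance_bins Boundary slack in bins (default 1).
#' @param min_fraction Minimum fraction of samples containing the domain
#'   (default 0.5).
#' @return A tibble of consensus domains with columns `chrom`,
#'   `start_bin`, `end_bin`, `n_samples`, `source = "consensus"`.
#' @export
consensus_tads <- function(tad_sets, tolerance_bins = 1, min_fraction = 0.5) {
  stopifnot(length(tad_sets) >= 2)
  all_tads <- purrr::imap(tad_sets, function(t, nm) {
    if (nrow(t) == 0) return(NULL)
    dplyr::mutate(t, .sample = nm)
  }) |> purrr::list_rbind()
  if (is.null(all_tads) || nrow(all_tads) == 0) {
    return(tibble::tibble(chrom = character(), start_bin = integer(),
                          end_bin = integer(), n_samples = integer(),
                          source = character()))
  }
  all_tads <- dplyr::arrange(all_tads, .data$start_bin, .data$end_bin)
  n <- nrow(all_tads)
  cluster <- integer(n)
  reps <- list()  # cluster representatives (start, end)
  for (i in seq_len(n)) {
    s <- all_tads$start_bin[i]; e <- all_tads$end_bin[i]
    hit <- 0L
    for (c in seq_along(reps)) {
      if (abs(reps[[c]][1] - s) <= tolerance_bins &&
          abs(reps[[c]][2] - e) <= tolerance_bins) {
        hit <- c
        break
      }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- c(s, e)
      hit <- length(reps)
    }
    cluster[i] <- hit
  }
  all_tads$.cluster <- cluster
  need <- length(tad_sets) * min_fraction
  out <- all_tads |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start_bin = as.integer(round(stats::median(.data$start_bin))),
      end_bin = as.integer(round(stats::median(.data$end_bin))),
      n_samples = dplyr::n_distinct(.data$.sample),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_samples >= need) |>
    dplyr::arrange(.data$start_bin) |>
    dplyr::mutate(source = "consensus") |>
    dplyr::select(-".cluster")
  out
}

#' Domain score (D-score)
#'
#' The fraction of a domain's cis contacts that stay inside the domain:
#' `D = (sum of contacts with both ends in the TAD) / (sum of contacts
#' with at least one end in the TAD)`, each symmetric pair counted once and
#' diagonal entries included. `D` lies in `[0, 1]`; 1 means a fully
#' isolated domain.
#'
#' @param map Balanced [contact_map()].
#' @param tad One domain: a list or one-row data frame with `start_bin`
#'   and `end_bin` (half-open bins).
#' @return A single number, or `NA` when the domain has no contacts.
#' @export
d_score <- function(map, tad) {
  stopifnot(inherits(map, "contact_map"))
  nb <- nrow(map$mat)
  s <- tad$start_bin[1]; e <- tad$end_bin[1]
  if (s < 0 || e > nb || e <= s) stop("TAD outside chromosome or empty")
  inside <- (s + 1):e
  M <- map$mat
  Sub <- M[inside, inside, drop = FALSE]
  intra <- sum(Sub[upper.tri(Sub, diag = TRUE)])
  outside <- setdiff(seq_len(nb), inside)
  inter <- if (length(outside)) sum(M[inside, outside, drop = FALSE]) else 0
  denom <- intra + inter
  if (denom == 0) return(NA_real_)
  intra / denom
}

#' D-scores for a set of domains
#'
#' @param map Balanced [contact_map()].
#' @param tads Domain tibble.
#' @return `tads` with a `d_score` column appended.
#' @export
d_score_table <- function(map, tads) {
  tads$d_score <- vapply(seq_len(nrow(tads)), function(k) {
    d_score(map, tads[k, ])
  }, 0)
  tads
}

#' Compartment status of a consensus TAD
#'
#' A cTAD is labelled A (or B) when at least `threshold` (default 80%) of
#' its compartment-labelled bins are A (or B); otherwise mixed. The mean
#' A-B index over unmasked bins is reported alongside.
#'
#' @param ctad One domain (list or one-row data frame with `start_bin`,
#'   `end_bin`).
#' @param index Fine-scale A-B index track (tibble with `bin`,
#'   `ab_index`).
#' @param calls Fine-scale compartment call (tibble with `bin`, `label`).
#' @param threshold Purity threshold, inclusive (default 0.8).
#' @return A list with `status` ("A", "B", "mixed", or `NA` when no bin is
#'   labelled) and `mean_index`.
#' @export
ctad_status <- function(ctad, index, calls, threshold = 0.8) {
  s <- ctad$start_bin[1]; e <- ctad$end_bin[1]
  sel <- calls$bin >= s & calls$bin < e
  lab <- as.character(calls$label[sel])
  lab <- lab[lab %in% c("A", "B")]
  mean_index <- mean(index$ab_index[index$bin >= s & index$bin < e], na.rm = TRUE)
  if (length(lab) == 0) {
    return(list(status = NA_character_, mean_index = mean_index))
  }
  fA <- mean(lab == "A")
  status <- if (fA >= threshold) "A" else if (1 - fA >= threshold) "B" else "mixed"
  list(status = status, mean_index = mean_index)
}
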