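#' First principal component of an O/E correlation matrix
#'
#' Computes the leading eigenvector of the correlation matrix of an O/E map
#' over unmasked bins — the classical coarse (100 kb) compartment signal.
#' The sign is arbitrary until oriented with [orient_and_call()].
#'
#' @param oe An O/E-state [contact_map()].
#' @return A tibble ("bin track") with columns `chrom`, `bin` (0-based) and
#'   `value` (`NA` for masked bins); unit-norm over unmasked bins.
#' @export
pc1_track <- function(oe) {
  stopifnot(inherits(oe, "contact_map"))
  if (oe$state != "oe") stop("pc1_track() expects an O/E map")
  keep <- which(!oe$mask)
  if (length(keep) < 3) stop("need at least 3 unmasked bins")
  A <- oe$mat[keep, keep, drop = FALSE]
  v <- apply(A, 2, stats::var)
  if (all(v == 0)) stop("constant O/E map: PC1 undefined")
  ok <- v > 0
  keep <- keep[ok]
  C <- stats::cor(A[ok, ok, drop = FALSE])
  ev <- eigen(C, symmetric = TRUE)
  pc1 <- ev$vectors[, 1]
  pc1 <- pc1 / sqrt(sum(pc1^2))
  out <- tibble::tibble(chrom = oe$chrom, bin = 0:(nrow(oe$mat) - 1L),
                        value = NA_real_)
  out$value[keep] <- pc1
  out
}

#' Orient PC1 and call coarse compartments
#'
#' Flips the PC1 track so that its Spearman correlation with a reference
#' track (GC content or gene density, both higher in active chromatin) is
#' positive, then labels bins: PC1 > 0 -> A, PC1 < 0 -> B, PC1 exactly 0 or
#' masked -> Un.
#'
#' @param pc1 Bin track from [pc1_track()].
#' @param reference Bin track (same binning) of GC content or gene density.
#' @param min_correlation If the absolute rank correlation with the
#'   reference is below this floor (default 0.1), orientation is flagged
#'   ambiguous with a warning.
#' @return A tibble ("compartment call") with columns `chrom`, `bin`,
#'   `label` (factor A/B/Un) and `pc1` (the oriented values), plus
#'   attributes `resolution` and `provenance`.
#' @export
orient_and_call <- function(pc1, reference, min_correlation = 0.1) {
  stopifnot(all(c("bin", "value") %in% names(pc1)),
            all(c("bin", "value") %in% names(reference)),
            nrow(pc1) == nrow(reference))
  ok <- !is.na(pc1$value) & !is.na(reference$value)
  rho <- suppressWarnings(
    stats::cor(pc1$value[ok], reference$value[ok], method = "spearman"))
  if (is.na(rho)) rho <- 0
  if (abs(rho) < min_correlation) {
    warning(sprintf("ambiguous PC1 orientation (|rho| = %.3f < %.2f)",
                    abs(rho), min_correlation))
  }
  v <- pc1$value * if (rho < 0) -1 else 1
  label <- dplyr::case_when(
    is.na(v) ~ "Un",
    v > 0 ~ "A",
    v < 0 ~ "B",
    TRUE ~ "Un"
  )
  out <- tibble::tibble(chrom = pc1$chrom, bin = pc1$bin,
                        label = factor(label, levels = c("A", "B", "Un")),
                        pc1 = v)
  attr(out, "provenance") <- "replicate"
  out
}

#' Fine-scale A-B index and 20-kb compartment call
#'
#' For each fine (20 kb) bin `i`, averages its O/E contacts with all fine
#' bins lying inside coarse (100 kb) A bins and inside coarse B bins, at
#' bin distance >= `min_sep`. The A-B index is the normalized contrast
#' `(I_A - I_B) / (I_A + I_B)` in `[-1, 1]`: positive means the segment
#' preferentially contacts the A compartment. The index sign gives the
#' fine-scale call; index exactly 0, or no eligible partner on either side,
#' gives Un.
#'
#' @param oe20 O/E [contact_map()] at the fine resolution.
#' @param call100 Coarse compartment call from [orient_and_call()], whose
#'   bin size must be an integer multiple of the fine bin size.
#' @param min_sep Minimum bin separation for contact averaging (default 2),
#'   excluding near-diagonal dominance.
#' @return A tibble with columns `chrom`, `bin`, `ab_index` and `label`
#'   (A/B/Un).
#' @export
ab_index <- function(oe20, call100, min_sep = 2) {
  stopifnot(inherits(oe20, "contact_map"))
  if (oe20$state != "oe") stop("ab_index() expects an O/E map")
  nb <- nrow(oe20$mat)
  bs_fine <- oe20$binning$bin_size
  # infer the coarse bin size from the call length
  nb_coarse <- nrow(call100)
  factor <- nb / nb_coarse
  if (abs(factor - round(factor)) > 1e-9 && nb_coarse * round(factor) < nb) {
    stop("fine bins do not nest in coarse bins")
  }
  factor <- round(nb / nb_coarse)
  coarse_of <- pmin((0:(nb - 1)) %/% factor + 1L, nb_coarse)
  fine_label <- as.character(call100$label)[coarse_of]
  inA <- which(fine_label == "A" & !oe20$mask)
  inB <- which(fine_label == "B" & !oe20$mask)
  idx <- rep(NA_real_, nb)
  M <- oe20$mat
  for (i in which(!oe20$mask)) {
    pa <- inA[abs(inA - i) >= min_sep]
    pb <- inB[abs(inB - i) >= min_sep]
    if (length(pa) == 0 && length(pb) == 0) next
    ia <- if (length(pa)) mean(M[i, pa]) else 0
    ib <- if (length(pb)) mean(M[i, pb]) else 0
    if (ia + ib > 0) idx[i] <- (ia - ib) / (ia + ib)
  }
  label <- dplyr::case_when(
    is.na(idx) ~ "Un",
    idx > 0 ~ "A",
    idx < 0 ~ "B",
    TRUE ~ "Un"
  )
  tibble::tibble(chrom = oe20$chrom, bin = 0:(nb - 1L), ab_index = idx,
                 label = factor(label, levels = c("A", "B", "Un")))
}

#' Replicate-consensus compartment call
#'
#' Assigns a bin's consensus label when strictly more than half of the
#' replicates agree — with 6 replicates, at least 4 ("more than three
#' biological replicates"); otherwise Un. A 3 A / 3 B tie is Un.
#'
#' @param calls List of compartment-call tibbles sharing the binning (each
#'   with columns `bin` and `label`).
#' @return A consensus call tibble with columns `chrom`, `bin`, `label`.
#' @export
consensus_call <- function(calls) {
  stopifnot(length(calls) >= 2)
  nb <- nrow(calls[[1]])
  for (k in calls) if (nrow(k) != nb || any(k$bin != calls[[1]]$bin)) {
    stop("mismatched binnings across replicates")
  }
  r <- length(calls)
  need <- floor(r / 2) + 1L
  lab <- vapply(seq_len(nb), function(i) {
    v <- vapply(calls, function(k) as.character(k$label[i]), "")
    nA <- sum(v == "A"); nB <- sum(v == "B")
    if (nA >= need) "A" else if (nB >= need) "B" else "Un"
  }, "")
  tibble::tibble(chrom = calls[[1]]$chrom, bin = calls[[1]]$bin,
                 label = factor(lab, levels = c("A", "B", "Un")))
}

#' Compartmentalization strength AA*BB/AB^2
#'
#' AA and BB are the mean O/E values over all unmasked pairs of bins with
#' the same compartment status; AB is the mean over cross-status pairs
#' (Un excluded everywhere). Strength contrasts within-class against
#' cross-class contact enrichment; it grows as the genome segregates.
#'
#' @param oe O/E [contact_map()].
#' @param call Compartment call at the matching resolution.
#' @return A list of class `strength_result` with `AA`, `BB`, `AB` and
#'   `strength` (`NA` when a class is empty).
#' @export
compartment_strength <- function(oe, call) {
  stopifnot(inherits(oe, "contact_map"), nrow(call) == nrow(oe$mat))
  lab <- as.character(call$label)
  lab[oe$mask] <- "Un"
  a <- which(lab == "A"); b <- which(lab == "B")
  M <- oe$mat
  pair_mean <- function(rows, cols, same) {
    if (length(rows) == 0 || length(cols) == 0) return(NA_real_)
    S <- M[rows, cols, drop = FALSE]
    if (same) mean(S[upper.tri(S, diag = TRUE)]) else mean(S)
  }
  AA <- pair_mean(a, a, TRUE)
  BB <- pair_mean(b, b, TRUE)
  AB <- pair_mean(a, b, FALSE)
  strength <- if (any(is.na(c(AA, BB, AB))) || AB == 0) NA_real_ else AA * BB / AB^2
  structure(list(AA = AA, BB = BB, AB = AB, strength = strength),
            class = "strength_result")
}

#' @export
print.strength_result <- function(x, ...) {
  cat(sprintf("<strength_result> AA=%.3f BB=%.3f AB=%.3f strength=%.3f\n",
              x$AA, x$BB, x$AB, x$strength))
  invisible(x)
}

#' Saddle matrix of an O/E map
#'
#' Sorts unmasked bins by their A-B index (lowest to highest), reorders the
#' O/E map accordingly, and aggregates it into an `n_quantiles` x
#' `n_quantiles` grid of sub-matrix means. Strong compartmentalization
#' shows as high same-class corners and a low cross-class anti-diagonal.
#'
#' @param oe O/E [contact_map()].
#' @param index A-B index track (tibble with `bin`, `ab_index` or `value`).
#' @param n_quantiles Grid size (default 50).
#' @return An `n_quantiles` x `n_quantiles` numeric matrix.
#' @export
saddle_matrix <- function(oe, index, n_quantiles = 50) {
  stopifnot(inherits(oe, "contact_map"))
  val <- if ("ab_index" %in% names(index)) index$ab_index else index$value
  keep <- which(!oe$mask & !is.na(val))
  if (length(keep) < n_quantiles) stop("need at least ", n_quantiles, " unmasked bins")
  ord <- keep[order(val[keep])]
  M <- oe$mat[ord, ord]
  grp <- as.integer(cut(seq_along(ord), breaks = n_quantiles, labels = FALSE))
  G <- matrix(0, length(ord), n_quantiles)
  G[cbind(seq_along(ord), grp)] <- 1
  sums <- t(G) %*% M %*% G
  counts <- t(G) %*% matrix(1, length(ord), length(ord)) %*% G
  sums / counts
}

#' Compartment switches between two stages
#'
#' Classifies each bin's transition between two consensus calls (A->B,
#' B->A, stable, or involving-Un), merges adjacent bins of the same class
#' into half-open bp regions, and reports total switched length. Regions
#' involving Un in either stage are kept as their own class and excluded
#' from A<->B totals.
#'
#' @param callX,callY Consensus compartment calls (same binning) for the
#'   earlier and later stage.
#' @param binning The [genome_binning()] of the calls.
#' @return A tibble of regions with columns `chrom`, `start`, `end`,
#'   `start_bin`, `end_bin` (half-open bins), `class` and `width`; total
#'   switched A<->B length in attribute `switched_bp`.
#' @export
detect_switches <- function(callX, callY, binning) {
  stopifnot(nrow(callX) == nrow(callY))
  lx <- as.character(callX$label); ly <- as.character(callY$label)
  cls <- dplyr::case_when(
    lx == "Un" | ly == "Un" ~ "involving-Un",
    lx == "A" & ly == "B" ~ "A->B",
    lx == "B" & ly == "A" ~ "B->A",
    TRUE ~ "stable"
  )
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  chrom <- callX$chrom[1]
  bs <- binning$bin_size
  len <- binning$chrom_sizes$length[match(chrom, binning$chrom_sizes$chrom)]
  out <- tibble::tibble(
    chrom = chrom,
    start_bin = callX$bin[starts],
    end_bin = callX$bin[ends] + 1L,
    class = r$values
  ) |>
    dplyr::mutate(start = .data$start_bin * bs,
                  end = pmin(.data$end_bin * bs, len),
                  width = .data$end - .data$start) |>
    dplyr::select("chrom", "start", "end", "start_bin", "end_bin",
                  "class", "width")
  attr(out, "switched_bp") <-
    sum(out$width[out$class %in% c("A->B", "B->A")])
  out
}
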