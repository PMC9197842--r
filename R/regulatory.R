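#' ChIP signal strength
#'
#' `log2(mark FPKM / input FPKM)`. When either term is 0 it is replaced by
#' `pseudocount`; both zero gives `NA`.
#'
#' @param mark_fpkm,input_fpkm Non-negative FPKM values (vectorized).
#' @param pseudocount Replacement for zeros (default 0.1 FPKM).
#' @return Numeric vector of log2 ratios.
#' @export
signal_strength <- function(mark_fpkm, input_fpkm, pseudocount = 0.1) {
  out <- rep(NA_real_, length(mark_fpkm))
  both_zero <- mark_fpkm == 0 & input_fpkm == 0
  m <- ifelse(mark_fpkm == 0, pseudocount, mark_fpkm)
  i <- ifelse(input_fpkm == 0, pseudocount, input_fpkm)
  out[!both_zero] <- log2(m / i)[!both_zero]
  out
}

# >= 1 bp overlap between a half-open interval [s, e) and a set of
# half-open peak intervals.
overlaps_any <- function(s, e, peak_start, peak_end) {
  any(peak_start < e & peak_end > s)
}

#' Classify promoters as active or inactive
#'
#' A gene's promoter bin is the single 5-kb bin containing its TSS (a TSS
#' exactly on a bin edge belongs to the right-hand bin). The promoter is
#' active when that bin overlaps an H3K4me3 peak by at least 1 bp; a peak
#' abutting the bin edge (half-open) does not count.
#'
#' @param tss Tibble with columns `gene`, `chrom`, `tss` (0-based bp).
#' @param h3k4me3 Peak tibble with columns `chrom`, `start`, `end`.
#' @param binning The promoter-resolution [genome_binning()] (5 kb).
#' @return `tss` with columns `promoter_bin` and `active` appended.
#' @export
classify_promoters <- function(tss, h3k4me3, binning) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(tss)))
  out <- tss
  out$promoter_bin <- NA_integer_
  out$active <- FALSE
  for (k in seq_len(nrow(out))) {
    ch <- out$chrom[k]
    b <- pos_to_bin(binning, ch, out$tss[k])
    out$promoter_bin[k] <- b
    iv <- bin_intervals(binning, ch, b)
    pk <- h3k4me3[h3k4me3$chrom == ch, , drop = FALSE]
    out$active[k] <- nrow(pk) > 0 &&
      overlaps_any(iv$start, iv$end, pk$start, pk$end)
  }
  tibble::as_tibble(out)
}

#' Rank-ordering of super-enhancers
#'
#' Merges H3K27ac peaks lying within `merge_gap` of each other (signals
#' summed), sorts the merged elements ascending by signal, min-max scales
#' rank and signal to `[0, 1]`, and places the cutoff at the element where
#' the scaled curve is farthest below the diagonal — the tangent point of
#' slope 1. Elements with signal strictly above the cutoff element's
#' signal are super-enhancers (SE), the rest regular enhancers (RE). A
#' flat or linear signal profile yields no SE.
#'
#' @param h3k27ac Peak tibble with columns `chrom`, `start`, `end`,
#'   `signal`.
#' @param merge_gap Maximum gap for merging neighboring elements
#'   (default 12500 bp).
#' @return A tibble of merged elements with columns `chrom`, `start`,
#'   `end`, `signal`, `rank` and `class` ("SE"/"RE").
#' @export
rose_classify <- function(h3k27ac, merge_gap = 12500) {
  stopifnot(all(c("chrom", "start", "end", "signal") %in% names(h3k27ac)))
  merged <- h3k27ac |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      .new = cumsum(c(1, (.data$start[-1] - cummax(.data$end[-dplyr::n()])) > merge_gap))
    ) |>
    dplyr::group_by(.data$chrom, .data$.new) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     signal = sum(.data$signal), .groups = "drop") |>
    dplyr::select(-".new")
  if (nrow(merged) < 3) stop("need at least 3 merged enhancer elements")
  merged <- dplyr::arrange(merged, .data$signal)
  n <- nrow(merged)
  merged$rank <- seq_len(n)
  rng <- range(merged$signal)
  if (diff(rng) == 0) {
    merged$class <- "RE"
    return(merged)
  }
  ss <- (merged$signal - rng[1]) / diff(rng)
  sr <- (merged$rank - 1) / (n - 1)
  gap <- ss - sr
  # among the minimizers pick the highest-signal one so a perfectly linear
  # ramp (gap identically 0) yields an empty SE set
  cut_idx <- max(which(gap == min(gap)))
  cutoff_signal <- merged$signal[cut_idx]
  merged$class <- ifelse(merged$signal > cutoff_signal, "SE", "RE")
  merged
}

#' Enhancer activity class
#'
#' An enhancer interval overlapping (>= 1 bp) a super-enhancer element is
#' SE; otherwise overlapping a regular-enhancer element is RE; an enhancer
#' with no H3K27ac overlap at all is a poised enhancer (PE). SE takes
#' priority over RE, matching the SE > RE > PE activity ranking.
#'
#' @param enh_start,enh_end Enhancer interval (0-based half-open bp).
#' @param elements Classified element tibble from [rose_classify()]
#'   (columns `chrom`, `start`, `end`, `class`), already subset to the
#'   enhancer's chromosome or carrying a `chrom` column.
#' @param chrom Enhancer chromosome.
#' @return `"SE"`, `"RE"` or `"PE"`.
#' @export
classify_enhancer <- function(enh_start, enh_end, elements, chrom = NULL) {
  if (!is.null(chrom) && "chrom" %in% names(elements)) {
    elements <- elements[elements$chrom == chrom, , drop = FALSE]
  }
  se <- elements[elements$class == "SE", , drop = FALSE]
  re <- elements[elements$class == "RE", , drop = FALSE]
  if (nrow(se) && overlaps_any(enh_start, enh_end, se$start, se$end)) return("SE")
  if (nrow(re) && overlaps_any(enh_start, enh_end, re$start, re$end)) return("RE")
  "PE"
}

#' Normalized interaction intensity
#'
#' `In = observed(p, e) - expected[|p - e|]` on a balanced 5-kb map: the
#' distance-corrected excess contact between a promoter bin and an
#' enhancer bin. Masked entries give `NA`.
#'
#' @param map5 Balanced [contact_map()] at 5 kb.
#' @param expected Profile from [expected_by_distance()].
#' @param promoter_bin,enhancer_bin 0-based bin indices, at least 4 bins
#'   (20 kb) apart.
#' @return A single number.
#' @export
interaction_intensity <- function(map5, expected, promoter_bin, enhancer_bin) {
  d <- abs(promoter_bin - enhancer_bin)
  if (d < 4) stop("promoter and enhancer must be at least 20 kb apart")
  if (map5$mask[promoter_bin + 1] || map5$mask[enhancer_bin + 1]) return(NA_real_)
  obs <- map5$mat[promoter_bin + 1, enhancer_bin + 1]
  e <- expected$expected[expected$distance == d]
  if (length(e) == 0 || is.na(e)) return(NA_real_)
  obs - e
}

#' Simple promoter-enhancer interaction caller
#'
#' A distance-decay surrogate caller (not a reimplementation of a
#' hierarchical-background method): for each promoter bin, a null count
#' distribution at each bin distance is estimated from all bins of the
#' chromosome at that distance (mean and variance of the raw counts; a
#' negative binomial when overdispersed, Poisson otherwise — a normal
#' upper tail would badly underestimate p on the sparse far diagonals),
#' each candidate contact gets an upper-tail p-value on its raw count,
#' Benjamini-Hochberg correction is applied across the promoter's
#' candidates, and records passing `fdr_threshold` at distance
#' `>= min_distance` are returned with their interaction intensity `In` —
#' observed minus expected on the balanced matrix, rescaled to count
#' units (total raw counts / total balanced mass) so that intensities are
#' comparable across depths and the `In > 1` RPS rule has its intended
#' count-scale meaning.
#'
#' @param map5 Balanced [contact_map()] at 5 kb, carrying the bias vector
#'   from [kr_balance()] (used to reconstruct raw counts).
#' @param promoters Tibble with columns `gene` and `promoter_bin` (e.g.
#'   from [classify_promoters()]).
#' @param fdr_threshold BH-adjusted p-value cutoff (default 0.01).
#' @param min_distance Minimum interaction distance in bp (default 20000).
#' @param max_distance Maximum candidate distance in bp (default 2e6).
#' @return A tibble of PEI records: `gene`, `promoter_bin`, `enhancer_bin`,
#'   `intensity`, `fdr`, `distance`.
#' @export
call_peis_simple <- function(map5, promoters, fdr_threshold = 0.01,
                             min_distance = 20000, max_distance = 2e6) {
  stopifnot(inherits(map5, "contact_map"))
  if (map5$state == "raw") stop("call_peis_simple() expects a balanced map")
  if (is.null(map5$bias)) stop("map must carry a bias vector (use kr_balance())")
  nb <- nrow(map5$mat)
  bs <- map5$binning$bin_size
  dmin <- as.integer(ceiling(min_distance / bs))
  dmax <- min(nb - 1L, as.integer(floor(max_distance / bs)))
  prof <- expected_by_distance(map5)
  keep <- !map5$mask
  b <- map5$bias
  raw <- map5$mat
  raw[keep, keep] <- raw[keep, keep] / outer(b[keep], b[keep])
  raw <- round(raw)
  count_scale <- sum(raw) / max(sum(map5$mat), .Machine$double.eps)
  # per-distance raw-count null: mean and variance over unmasked pairs
  mu_at <- var_at <- rep(NA_real_, nb)
  for (d in dmin:dmax) {
    i <- seq_len(nb - d)
    ok <- keep[i] & keep[i + d]
    if (sum(ok) >= 3) {
      v <- raw[cbind(i[ok], i[ok] + d)]
      # trim the extreme upper tail so genuine loops do not inflate the null
      v <- v[v <= stats::quantile(v, 0.995)]
      mu_at[d + 1] <- mean(v)
      var_at[d + 1] <- stats::var(v)
    }
  }
  count_p <- function(obs, mu, vr) {
    if (vr > mu * 1.05) {
      size <- mu^2 / (vr - mu)
      stats::pnbinom(obs - 1, size = size, mu = mu, lower.tail = FALSE)
    } else {
      stats::ppois(obs - 1, lambda = mu, lower.tail = FALSE)
    }
  }
  recs <- purrr::map(seq_len(nrow(promoters)), function(k) {
    p <- promoters$promoter_bin[k]
    if (is.na(p) || map5$mask[p + 1]) return(NULL)
    cand <- c((p - dmax):(p - dmin), (p + dmin):(p + dmax))
    cand <- cand[cand >= 0 & cand < nb]
    cand <- cand[!map5$mask[cand + 1]]
    if (length(cand) == 0) return(NULL)
    d <- abs(cand - p)
    mu <- mu_at[d + 1]
    vr <- var_at[d + 1]
    ok <- !is.na(mu) & !is.na(vr) & mu > 0
    if (!any(ok)) return(NULL)
    cand <- cand[ok]; d <- d[ok]; mu <- mu[ok]; vr <- vr[ok]
    obs_raw <- raw[p + 1, cand + 1]
    pval <- vapply(seq_along(cand), function(j) {
      count_p(obs_raw[j], mu[j], vr[j])
    }, 0)
    fdr <- stats::p.adjust(pval, method = "BH")
    sel <- fdr <= fdr_threshold
    if (!any(sel)) return(NULL)
    tibble::tibble(
      gene = promoters$gene[k],
      promoter_bin = p,
      enhancer_bin = cand[sel],
      intensity = (map5$mat[p + 1, cand[sel] + 1] -
                     prof$expected[d[sel] + 1]) * count_scale,
      fdr = fdr[sel],
      distance = d[sel] * bs
    )
  })
  out <- purrr::list_rbind(purrr::compact(recs))
  if (nrow(out) == 0) {
    return(tibble::tibble(gene = character(), promoter_bin = integer(),
                          enhancer_bin = integer(), intensity = numeric(),
                          fdr = numeric(), distance = numeric()))
  }
  out
}

#' Regulatory potential score of one gene
#'
#' `RPS = sum(log10(In))` over the gene's promoter-enhancer records with
#' `In > 1` (intensities at or below 1 would contribute non-positive or
#' undefined log terms and are excluded); a gene with no enhancer records
#' has RPS 0. With `clamp = TRUE`, intensities in `(0, 1]` are clamped to
#' 1 (contributing 0) instead of being dropped — the sum is identical, the
#' enhancer count is not.
#'
#' @param intensities Numeric vector of interaction intensities `In`.
#' @param clamp Use the clamp-to-1 alternative (default `FALSE`).
#' @return A list with `rps` and `n_enhancers` (records contributing).
#' @export
rps <- function(intensities, clamp = FALSE) {
  if (length(intensities) == 0) return(list(rps = 0, n_enhancers = 0L))
  if (clamp) {
    contrib <- pmax(intensities[intensities > 0], 1)
  } else {
    contrib <- intensities[intensities > 1]
  }
  if (length(contrib) == 0) return(list(rps = 0, n_enhancers = 0L))
  list(rps = sum(log10(contrib)), n_enhancers = length(contrib))
}

#' Per-gene, per-stage RPS table
#'
#' @param peis PEI record tibble (from [call_peis_simple()]) with columns
#'   `gene`, `intensity`, and optionally `stage`.
#' @param genes Optional character vector of all genes; genes with no
#'   records get RPS 0.
#' @param clamp Passed to [rps()].
#' @return A tibble with `gene`, (`stage`,) `rps`, `n_enhancers`.
#' @export
rps_table <- function(peis, genes = NULL, clamp = FALSE) {
  grp <- intersect(c("gene", "stage"), names(peis))
  out <- peis |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      rps = rps(.data$intensity, clamp = clamp)$rps,
      n_enhancers = rps(.data$intensity, clamp = clamp)$n_enhancers,
      .groups = "drop"
    )
  if (!is.null(genes)) {
    if ("stage" %in% grp) {
      full <- tidyr::expand_grid(gene = genes,
                                 stage = unique(peis$stage))
    } else {
      full <- tibble::tibble(gene = genes)
    }
    out <- full |>
      dplyr::left_join(out, by = grp) |>
      dplyr::mutate(rps = dplyr::coalesce(.data$rps, 0),
                    n_enhancers = dplyr::coalesce(.data$n_enhancers, 0L))
  }
  out
}

#' Differential RPS rule
#'
#' A gene's RPS change between two stages is differential when
#' `|log2FC| > 2` and `|delta| > 3` (both strict). The fold change
#' substitutes 0.1 for an RPS of exactly 0 in numerator and denominator
#' (so zero-RPS genes have a defined fold change); the delta uses the raw
#' values.
#'
#' @param rps_a,rps_b RPS at the earlier and later stage (vectorized).
#' @param fc_floor Substitution for zero RPS in the fold change
#'   (default 0.1).
#' @return A tibble with `log2fc`, `delta`, `is_differential`.
#' @export
differential_rps <- function(rps_a, rps_b, fc_floor = 0.1) {
  a <- ifelse(rps_a == 0, fc_floor, rps_a)
  b <- ifelse(rps_b == 0, fc_floor, rps_b)
  log2fc <- log2(b / a)
  delta <- rps_b - rps_a
  tibble::tibble(log2fc = log2fc, delta = delta,
                 is_differential = abs(log2fc) > 2 & abs(delta) > 3)
}
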