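#' Fiedler number of a contact network
#'
#' Treats the balanced contact matrix as a weighted graph (edge weights =
#' contact values, no self-loops), restricts it to its largest connected
#' component, and returns the second-smallest eigenvalue of the
#' unnormalized Laplacian `L = D - W` — the algebraic connectivity of the
#' chromosome's contact network.
#'
#' @param map Balanced [contact_map()], or a plain symmetric weight
#'   matrix.
#' @param normalized Use the symmetric normalized Laplacian instead
#'   (default `FALSE`).
#' @return A single non-negative number, or `NA` when fewer than 2 nodes
#'   remain.
#' @export
fiedler_number <- function(map, normalized = FALSE) {
  W <- if (inherits(map, "contact_map")) map$mat else map
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 2) return(NA_real_)
  Wk <- W[keep, keep, drop = FALSE]
  d <- rowSums(Wk)
  L <- diag(d) - Wk
  if (normalized) {
    s <- 1 / sqrt(pmax(d, .Machine$double.eps))
    L <- diag(s) %*% L %*% diag(s)
  }
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  sort(ev)[2]
}

#' Form-function phase distances
#'
#' Each chromosome contributes one point per stage: the Fiedler number of
#' its contact network (form) and the mean TPM of its genes (function).
#' Both axes are z-normalized across stages per chromosome using the
#' population (1/n) standard deviation — two stages on one axis sit at
#' z = +/-1 and are distance 2 apart — and the pairwise Euclidean distance
#' between stages is reported per chromosome plus a genome-level mean.
#'
#' @param points Tibble with columns `chrom`, `stage`, `fn` (Fiedler
#'   number) and `expr` (mean TPM).
#' @return A tibble with `chrom` (or `"genome"` for the mean over
#'   chromosomes), `stage_x`, `stage_y`, `distance`.
#' @export
phase_distance <- function(points) {
  stopifnot(all(c("chrom", "stage", "fn", "expr") %in% names(points)))
  stages <- unique(points$stage)
  if (length(stages) < 2) {
    return(tibble::tibble(chrom = character(), stage_x = character(),
                          stage_y = character(), distance = numeric()))
  }
  znorm <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  per_chrom <- points |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(fn_z = znorm(.data$fn), expr_z = znorm(.data$expr)) |>
    dplyr::ungroup()
  pairs <- utils::combn(as.character(stages), 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(k) {
    sx <- pairs[1, k]; sy <- pairs[2, k]
    per_chrom |>
      dplyr::filter(.data$stage %in% c(sx, sy)) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(
        distance = sqrt(diff(.data$fn_z[match(c(sx, sy), .data$stage)])^2 +
                          diff(.data$expr_z[match(c(sx, sy), .data$stage)])^2),
        .groups = "drop"
      ) |>
      dplyr::mutate(stage_x = sx, stage_y = sy)
  }) |> purrr::list_rbind()
  genome <- out |>
    dplyr::group_by(.data$stage_x, .data$stage_y) |>
    dplyr::summarise(distance = mean(.data$distance), .groups = "drop") |>
    dplyr::mutate(chrom = "genome")
  dplyr::bind_rows(
    dplyr::select(out, "chrom", "stage_x", "stage_y", "distance"),
    dplyr::select(genome, "chrom", "stage_x", "stage_y", "distance")
  )
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with an exact p-value by full enumeration of
#' the `choose(n+m, n)` group assignments whenever `n + m <= max_exact`
#' (ties handled by mid-ranks inside the enumeration), and a normal
#' approximation with tie correction and continuity correction beyond.
#' The two-sided exact p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y Numeric samples (no missing values).
#' @param max_exact Enumeration limit on `n + m` (default 12).
#' @return A list with `U` (Mann-Whitney statistic of `x`), `p` and
#'   `method`.
#' @export
wilcoxon_exact <- function(x, y, max_exact = 12) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])            # rank sum of x
  U <- W - n * (n + 1) / 2
  if (n + m <= max_exact) {
    idx <- utils::combn(n + m, n)
    Ws <- colSums(matrix(r[idx], nrow = n))
    p_le <- mean(Ws <= W + 1e-9)
    p_ge <- mean(Ws >= W - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    N <- n + m
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Expression comparison between labelled regions
#'
#' Assigns genes to labelled regions by TSS containment and compares the
#' expression distributions between two labels with [wilcoxon_exact()].
#'
#' @param expr Tibble with columns `gene` and `tpm`.
#' @param gene_coords Tibble with columns `gene`, `chrom`, `tss`.
#' @param regions Tibble with columns `chrom`, `start`, `end`, `class`
#'   (half-open bp intervals).
#' @param labels Length-2 character vector of classes to compare, e.g.
#'   `c("B->A", "A->B")`; the test is one- or two-sided per `alternative`.
#' @param alternative `"two.sided"` (default), `"greater"` (first label
#'   stochastically larger) or `"less"`. One-sided p-values use the
#'   normal approximation for large samples and halve the exact
#'   enumeration otherwise.
#' @return A list with per-label gene tables (`groups`), and `p` (`NA`
#'   when a group is empty).
#' @export
expression_by_region <- function(expr, gene_coords, regions,
                                 labels, alternative = "two.sided") {
  df <- dplyr::inner_join(expr, gene_coords, by = "gene")
  df$class <- NA_character_
  for (k in seq_len(nrow(regions))) {
    hit <- df$chrom == regions$chrom[k] &
      df$tss >= regions$start[k] & df$tss < regions$end[k]
    df$class[hit] <- regions$class[k]
  }
  g1 <- df$tpm[!is.na(df$class) & df$class == labels[1]]
  g2 <- df$tpm[!is.na(df$class) & df$class == labels[2]]
  if (length(g1) == 0 || length(g2) == 0) {
    return(list(groups = df, p = NA_real_))
  }
  if (alternative == "two.sided") {
    p <- wilcoxon_exact(g1, g2)$p
  } else {
    p <- stats::wilcox.test(g1, g2, alternative = alternative,
                            exact = FALSE)$p.value
  }
  list(groups = tibble::as_tibble(df), p = p)
}

#' Trait-SNP enrichment in genomic regions
#'
#' For each trait, the enrichment score is the relative SNP density
#' `(k / L_r) / (K / L_g)` where `k` of the trait's `K` SNPs fall in the
#' region set of total length `L_r` within a genome of length `L_g`.
#' Significance is a 2x2 chi-square test (trait SNPs in/out of the
#' regions vs all other SNPs in/out, no continuity correction), run only
#' for traits with more than `min_snps` SNPs.
#'
#' @param regions Tibble of merged, non-overlapping intervals (`chrom`,
#'   `start`, `end`).
#' @param snps Tibble with columns `chrom`, `pos`, `trait`.
#' @param genome_length Total genome length in bp.
#' @param min_snps Traits with at most this many SNPs get a score but no
#'   test (default 50; the rule is strict: K = 50 is not tested).
#' @return A tibble with `trait`, `k`, `K`, `region_length`, `score`,
#'   `chisq`, `p`.
#' @export
snp_enrichment <- function(regions, snps, genome_length, min_snps = 50) {
  L_r <- sum(regions$end - regions$start)
  if (L_r == 0) stop("regions have zero total length")
  in_region <- function(chrom, pos) {
    hit <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(regions))) {
      hit <- hit | (chrom == regions$chrom[k] &
                      pos >= regions$start[k] & pos < regions$end[k])
    }
    hit
  }
  snps$in_region <- in_region(snps$chrom, snps$pos)
  total_in <- sum(snps$in_region)
  total_n <- nrow(snps)
  snps |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(k = sum(.data$in_region), K = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(
      region_length = L_r,
      score = (.data$k / L_r) / (.data$K / genome_length),
      test = purrr::map2(.data$k, .data$K, function(k, K) {
        if (K <= min_snps) return(list(chisq = NA_real_, p = NA_real_))
        other_in <- total_in - k
        other_out <- (total_n - K) - other_in
        tab <- matrix(c(k, K - k, other_in, other_out), 2, 2)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
          return(list(chisq = NA_real_, p = NA_real_))
        }
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        list(chisq = unname(ct$statistic), p = ct$p.value)
      }),
      chisq = purrr::map_dbl(.data$test, "chisq"),
      p = purrr::map_dbl(.data$test, "p")
    ) |>
    dplyr::select(-"test")
}
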