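#' Simulation configuration
#'
#' Bundles every knob of the synthetic Hi-C generator: a desk-scale genome,
#' distance decay, planted compartments, TADs and loops per stage, noise
#' mixture weights, sequencing depth and replicate structure, and the
#' coefficients linking structure to expression. Defaults emulate a
#' multi-stage developmental series in which structure solidifies: the
#' noise weight `w` falls while compartment contrast `s` and intra-TAD
#' boost `beta` rise across stages.
#'
#' @param seed Master seed; all outputs are reproducible from
#'   `(config, seed)`.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp
#'   (default two 30-Mb chromosomes).
#' @param bin_size Working resolution in bp (default 20000; coarse calls
#'   use a 5-fold coarsening to 100 kb, loop work a 5-kb fine binning).
#' @param alpha Distance-decay exponent (default 1.0).
#' @param s Per-stage compartment contrast in `[0, 1)` (default rises
#'   0.25 -> 0.55 over 4 stages).
#' @param beta Per-stage intra-TAD contact boost, >= 1 (default rises
#'   1.6 -> 2.2).
#' @param w Per-stage uniform-noise mixture weight in `[0, 1]` (default
#'   falls 0.35 -> 0.05).
#' @param n_contacts Contacts sampled per replicate (default 2e6).
#' @param n_replicates Replicates per stage (default 6).
#' @param block_mean_bins Mean compartment block length in coarse (100 kb)
#'   bins (default 6).
#' @param tad_min_bins,tad_max_bins Planted TAD size range in working bins
#'   (default 15-50, i.e. 300 kb - 1 Mb).
#' @param n_switch_bins Coarse bins flipped between consecutive stages
#'   (default 10 per chromosome).
#' @param n_genes Genes per chromosome (default 150).
#' @param expr_a,expr_b,expr_c Expression link coefficients for
#'   A-compartment membership, D-score and planted RPS (defaults 1, 1,
#'   0.4 on the log-TPM scale).
#' @param expr_sd Log-TPM noise sd (default 0.5).
#' @param n_loops Planted promoter-enhancer loops per chromosome per stage
#'   (default 12).
#' @param loop_boost Multiplicative contact boost at loop anchors
#'   (default 40).
#' @param snp_per_trait SNPs per simulated trait (default 2000).
#' @param snp_enrichment_factor Density ratio of SNPs inside planted
#'   enhancer regions vs outside (default 2).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chrS1 = 30e6, chrS2 = 30e6),
                       bin_size = 20000,
                       alpha = 1.0,
                       s = c(0.25, 0.35, 0.45, 0.55),
                       beta = c(1.6, 1.8, 2.0, 2.2),
                       w = c(0.35, 0.25, 0.15, 0.05),
                       n_contacts = 2e6,
                       n_replicates = 6,
                       block_mean_bins = 6,
                       tad_min_bins = 15,
                       tad_max_bins = 50,
                       n_switch_bins = 10,
                       n_genes = 150,
                       expr_a = 1, expr_b = 1, expr_c = 0.4,
                       expr_sd = 0.5,
                       n_loops = 12,
                       loop_boost = 40,
                       snp_per_trait = 2000,
                       snp_enrichment_factor = 2) {
  stopifnot(all(s >= 0 & s < 1), all(beta >= 1), all(w >= 0 & w <= 1),
            length(s) == length(beta), length(beta) == length(w))
  structure(
    list(seed = seed, chrom_lengths = chrom_lengths, bin_size = bin_size,
         alpha = alpha, s = s, beta = beta, w = w, n_contacts = n_contacts,
         n_replicates = n_replicates, block_mean_bins = block_mean_bins,
         tad_min_bins = tad_min_bins, tad_max_bins = tad_max_bins,
         n_switch_bins = n_switch_bins, n_genes = n_genes,
         expr_a = expr_a, expr_b = expr_b, expr_c = expr_c,
         expr_sd = expr_sd, n_loops = n_loops, loop_boost = loop_boost,
         snp_per_trait = snp_per_trait,
         snp_enrichment_factor = snp_enrichment_factor,
         n_stages = length(s)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d chrom(s), %g bp bins, %d stages x %d replicates, N=%g\n",
    length(x$chrom_lengths), x$bin_size, x$n_stages, x$n_replicates,
    x$n_contacts))
  invisible(x)
}

# Planted structure for one chromosome: coarse compartment labels (+/-1),
# TAD boundaries, gene positions. Deterministic given the RNG state.
plant_chrom_truth <- function(cfg, nb, coarse_factor = 5) {
  nb_coarse <- ceiling(nb / coarse_factor)
  # alternating A/B blocks with geometric lengths at the coarse scale
  lab <- integer(0)
  cur <- sample(c(-1L, 1L), 1)
  while (length(lab) < nb_coarse) {
    len <- 1 + stats::rgeom(1, 1 / cfg$block_mean_bins)
    lab <- c(lab, rep(cur, len))
    cur <- -cur
  }
  lab_coarse <- lab[seq_len(nb_coarse)]
  lab_fine <- rep(lab_coarse, each = coarse_factor)[seq_len(nb)]
  # TAD partition at the working scale
  bnd <- 0L
  while (utils::tail(bnd, 1) < nb) {
    size <- sample(cfg$tad_min_bins:cfg$tad_max_bins, 1)
    bnd <- c(bnd, min(utils::tail(bnd, 1) + size, nb))
  }
  list(labels_coarse = lab_coarse, labels_fine = lab_fine,
       tad_boundaries = bnd)
}

#' Bin-pair contact probability model
#'
#' Builds the upper-triangle probability matrix
#' `P(i,j) ~ (1 + |i-j|)^(-alpha) * (1 + s * c_i * c_j) *
#' beta^[same TAD] * loop boosts`, mixed with a uniform matrix at weight
#' `w` and normalized to sum 1 over `i <= j`.
#'
#' @param nb Number of bins.
#' @param alpha Distance-decay exponent.
#' @param labels Per-bin compartment labels in `{-1, +1}` (0 to disable).
#' @param s Compartment contrast.
#' @param tad_boundaries Sorted boundary bins `0 = b0 < ... < bk = nb`
#'   (or `NULL`).
#' @param beta Intra-TAD boost.
#' @param loops Optional tibble with `bin1`, `bin2`, `boost`.
#' @param w Uniform-noise mixture weight.
#' @return A symmetric matrix of probabilities (upper triangle sums to 1).
#' @export
build_probability_model <- function(nb, alpha = 1, labels = NULL, s = 0,
                                    tad_boundaries = NULL, beta = 1,
                                    loops = NULL, w = 0) {
  stopifnot(s >= 0, s < 1, beta >= 1, w >= 0, w <= 1)
  D <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  P <- (1 + D)^(-alpha)
  if (!is.null(labels) && s > 0) {
    P <- P * (1 + s * outer(labels, labels))
  }
  if (!is.null(tad_boundaries) && beta > 1) {
    tad_id <- findInterval(0:(nb - 1), tad_boundaries,
                           rightmost.closed = FALSE)
    Same <- outer(tad_id, tad_id, "==")
    P <- ifelse(Same, P * beta, P)
  }
  if (!is.null(loops) && nrow(loops) > 0) {
    for (k in seq_len(nrow(loops))) {
      i <- loops$bin1[k] + 1L; j <- loops$bin2[k] + 1L
      P[i, j] <- P[i, j] * loops$boost[k]
      P[j, i] <- P[i, j]
    }
  }
  if (any(P < 0)) stop("negative probability factor in model")
  ut <- upper.tri(P, diag = TRUE)
  P_struct <- P / sum(P[ut])
  if (w > 0) {
    U <- matrix(1, nb, nb) / sum(ut)
    P_struct <- (1 - w) * P_struct + w * U
    P_struct <- (P_struct + t(P_struct)) / 2
    P_struct <- P_struct / sum(P_struct[ut])
  }
  P_struct
}

#' Sample a raw contact map from a probability model
#'
#' Draws `n` bin pairs multinomially from the upper triangle of `P` and
#' symmetrizes the counts. Deterministic for a fixed seed.
#'
#' @param P Probability matrix from [build_probability_model()].
#' @param n Number of contacts.
#' @param binning,chrom Passed to [contact_map()].
#' @param seed Seed for the draw.
#' @return A raw [contact_map()].
#' @export
sample_contact_map <- function(P, n, binning, chrom, seed = 1) {
  nb <- nrow(P)
  ut <- which(upper.tri(P, diag = TRUE))
  set.seed(seed)
  counts <- stats::rmultinom(1, size = n, prob = P[ut])[, 1]
  mat <- matrix(0, nb, nb)
  mat[ut] <- counts
  low <- lower.tri(mat)
  mat[low] <- t(mat)[low]
  contact_map(mat, binning, chrom, state = "raw")
}

#' Simulate a multi-stage, multi-replicate series with ground truth
#'
#' Applies the per-stage parameters of a [sim_config()] to every
#' chromosome: stage 1 plants compartments and TADs; each later stage
#' flips a configured subset of coarse compartment bins (creating switch
#' regions) and gains/loses loops (creating RPS trajectories); replicates
#' within a stage differ only by sampling seed. Ground truth (labels,
#' boundaries, switch lists, loop lists) is returned alongside the maps.
#'
#' @param cfg A [sim_config()].
#' @return A list with `maps` (`maps[[stage]][[chrom]][[replicate]]`, raw
#'   [contact_map()]s at the working resolution), `binning`, `truth` (per
#'   chromosome: per-stage labels, TAD boundaries, loops, switch bins)
#'   and `cfg`.
#' @export
simulate_stage_series <- function(cfg) {
  set.seed(cfg$seed)
  binning <- genome_binning(
    data.frame(chrom = names(cfg$chrom_lengths),
               length = as.numeric(cfg$chrom_lengths)),
    cfg$bin_size)
  coarse_factor <- as.integer(100000 / cfg$bin_size)
  truth <- list()
  maps <- rep(list(list()), cfg$n_stages)
  for (chrom in names(cfg$chrom_lengths)) {
    nb <- n_bins(binning, chrom)
    base <- plant_chrom_truth(cfg, nb, coarse_factor)
    labels_by_stage <- list(base$labels_coarse)
    switch_bins <- list()
    for (st in 2:cfg$n_stages) {
      prev <- labels_by_stage[[st - 1]]
      flip <- sample(seq_along(prev), min(cfg$n_switch_bins, length(prev)))
      cur <- prev
      cur[flip] <- -cur[flip]
      labels_by_stage[[st]] <- cur
      switch_bins[[st - 1]] <- sort(flip - 1L)
    }
    # loops: anchors at >= 20 kb separation at the working resolution
    loop_pool <- tibble::tibble(
      bin1 = sample(0:(nb - 30), cfg$n_loops * 2),
      offset = sample(2:25, cfg$n_loops * 2, replace = TRUE)
    ) |>
      dplyr::mutate(bin2 = .data$bin1 + pmax(.data$offset, 2),
                    boost = cfg$loop_boost) |>
      dplyr::filter(.data$bin2 < nb)
    loops_by_stage <- lapply(seq_len(cfg$n_stages), function(st) {
      # early stages carry the first half of the pool, late stages the rest
      n_half <- floor(nrow(loop_pool) / 2)
      if (st <= cfg$n_stages / 2) {
        loop_pool[seq_len(min(cfg$n_loops, n_half)), ]
      } else {
        loop_pool[(n_half + 1):min(n_half + cfg$n_loops, nrow(loop_pool)), ]
      }
    })
    truth[[chrom]] <- list(
      labels_coarse = labels_by_stage,
      labels_fine = lapply(labels_by_stage, function(l) {
        rep(l, each = coarse_factor)[seq_len(nb)]
      }),
      tad_boundaries = base$tad_boundaries,
      loops = loops_by_stage,
      switch_bins = switch_bins
    )
    for (st in seq_len(cfg$n_stages)) {
      lab_fine <- truth[[chrom]]$labels_fine[[st]]
      P <- build_probability_model(
        nb, alpha = cfg$alpha, labels = lab_fine, s = cfg$s[st],
        tad_boundaries = base$tad_boundaries, beta = cfg$beta[st],
        loops = loops_by_stage[[st]], w = cfg$w[st])
      reps <- lapply(seq_len(cfg$n_replicates), function(r) {
        sample_contact_map(
          P, cfg$n_contacts, binning, chrom,
          seed = (cfg$seed * 1000L + st * 100L + r) %% .Machine$integer.max)
      })
      maps[[st]][[chrom]] <- reps
    }
  }
  list(maps = maps, binning = binning, truth = truth, cfg = cfg)
}

#' Simulate an expression table linked to planted structure
#'
#' `log-TPM = mu + a * 1[A compartment] + b * dscore_link + c *
#' RPS_planted + noise`: the generative encoding of the associations the
#' pipeline is meant to detect (A-status, intra-TAD connectivity and
#' regulatory potential each raise expression).
#'
#' @param sim Output of [simulate_stage_series()].
#' @param stage Stage index.
#' @param seed Seed for gene placement and noise.
#' @param mu Baseline log-TPM (default 2).
#' @return A tibble with `gene`, `chrom`, `tss`, `bin`, `in_A`,
#'   `dscore_link`, `rps_planted`, `log_tpm`, `tpm`.
#' @export
simulate_expression <- function(sim, stage = 1, seed = sim$cfg$seed, mu = 2) {
  cfg <- sim$cfg
  set.seed(seed + 7L)
  rows <- purrr::map(names(cfg$chrom_lengths), function(chrom) {
    nb <- n_bins(sim$binning, chrom)
    bs <- sim$binning$bin_size
    tr <- sim$truth[[chrom]]
    bins <- sort(sample(0:(nb - 1), cfg$n_genes, replace = FALSE))
    in_A <- tr$labels_fine[[stage]][bins + 1] > 0
    # D-score link: genes inside the first half of each TAD get link 1
    tad_id <- findInterval(bins, tr$tad_boundaries)
    dlink <- stats::runif(cfg$n_genes)
    loops <- tr$loops[[stage]]
    rps_planted <- vapply(bins, function(b) {
      sum(loops$bin1 == b) * log10(cfg$loop_boost)
    }, 0)
    log_tpm <- mu + cfg$expr_a * in_A + cfg$expr_b * dlink +
      cfg$expr_c * rps_planted + stats::rnorm(cfg$n_genes, 0, cfg$expr_sd)
    tibble::tibble(
      gene = paste0(chrom, "_g", seq_len(cfg$n_genes)),
      chrom = chrom,
      tss = bins * bs + bs %/% 2,
      bin = bins,
      in_A = in_A,
      dscore_link = dlink,
      rps_planted = rps_planted,
      log_tpm = log_tpm,
      tpm = 2^log_tpm
    )
  })
  purrr::list_rbind(rows)
}

#' Simulate ChIP peaks and trait SNPs
#'
#' Emits H3K27ac peaks with heavy-tailed (log-normal) signals, a set of
#' designated super-enhancer clusters (runs of nearby high-signal peaks
#' within the ROSE merge gap), H3K4me3 peaks on active-gene promoter
#' bins, and trait SNPs drawn with a configured density enrichment inside
#' the enhancer regions.
#'
#' @param sim Output of [simulate_stage_series()].
#' @param genes Expression table from [simulate_expression()]; its top
#'   half by expression defines the active promoters.
#' @param seed Seed.
#' @param n_enhancers Regular-enhancer peaks per chromosome (default 60).
#' @param n_se_clusters Designated SE clusters per chromosome
#'   (default 4).
#' @param traits Character vector of trait names for the SNP table
#'   (default two traits, one enriched and one uniform).
#' @return A list with `h3k27ac`, `h3k4me3`, `se_truth` (designated SE
#'   cluster intervals), `snps`, and `enhancer_regions`.
#' @export
simulate_peaks_and_snps <- function(sim, genes, seed = sim$cfg$seed,
                                    n_enhancers = 60, n_se_clusters = 4,
                                    traits = c("enriched_trait", "uniform_trait")) {
  cfg <- sim$cfg
  set.seed(seed + 13L)
  peak_rows <- list()
  se_rows <- list()
  for (chrom in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[chrom]]
    # isolated regular peaks, well separated (> merge gap)
    starts <- sort(sample(seq(0, len - 2000, by = 30000), n_enhancers))
    peak_rows[[length(peak_rows) + 1L]] <- tibble::tibble(
      chrom = chrom, start = starts, end = starts + 1500,
      signal = stats::rlnorm(n_enhancers, meanlog = 1, sdlog = 0.4)
    )
    # SE clusters: 3 peaks within the merge gap, 20x the RE median signal
    anchors <- sort(sample(seq(1e6, len - 1e6, by = 2e6), n_se_clusters))
    for (a in anchors) {
      ps <- a + c(0, 6000, 12000)
      peak_rows[[length(peak_rows) + 1L]] <- tibble::tibble(
        chrom = chrom, start = ps, end = ps + 1500,
        signal = stats::rlnorm(3, meanlog = 1 + log(20), sdlog = 0.2)
      )
      se_rows[[length(se_rows) + 1L]] <- tibble::tibble(
        chrom = chrom, start = a, end = a + 13500
      )
    }
  }
  h3k27ac <- dplyr::arrange(purrr::list_rbind(peak_rows), .data$chrom,
                            .data$start)
  se_truth <- purrr::list_rbind(se_rows)
  # H3K4me3 on the promoter bins of the top-expressed half of genes
  active <- genes |>
    dplyr::arrange(dplyr::desc(.data$tpm)) |>
    dplyr::slice_head(n = floor(nrow(genes) / 2))
  bs <- sim$binning$bin_size
  h3k4me3 <- tibble::tibble(
    chrom = active$chrom,
    start = active$bin * bs + 100,
    end = active$bin * bs + 2100,
    signal = stats::rlnorm(nrow(active), 1.5, 0.3)
  )
  # enhancer regions for SNP planting: all H3K27ac peak footprints
  enh <- h3k27ac |> dplyr::select("chrom", "start", "end")
  L_enh <- sum(enh$end - enh$start)
  L_g <- sum(cfg$chrom_lengths)
  snp_rows <- purrr::map(traits, function(tr) {
    K <- cfg$snp_per_trait
    f <- if (tr == "enriched_trait") cfg$snp_enrichment_factor else 1
    # expected in-region share under a density ratio f
    p_in <- f * L_enh / (f * L_enh + (L_g - L_enh))
    n_in <- stats::rbinom(1, K, p_in)
    inside <- if (n_in > 0) {
      pick <- sample(nrow(enh), n_in, replace = TRUE)
      tibble::tibble(
        chrom = enh$chrom[pick],
        pos = floor(enh$start[pick] +
                      stats::runif(n_in) * (enh$end[pick] - enh$start[pick]))
      )
    } else NULL
    n_out <- K - n_in
    chroms <- sample(names(cfg$chrom_lengths), n_out, replace = TRUE)
    pos <- floor(stats::runif(n_out) * unname(cfg$chrom_lengths[chroms]))
    # re-draw the few that landed inside an enhancer so the two strata stay
    # disjoint and the planted density ratio is exact
    repeat {
      bad <- vapply(seq_len(n_out), function(j) {
        any(enh$chrom == chroms[j] & pos[j] >= enh$start & pos[j] < enh$end)
      }, TRUE)
      if (!any(bad)) break
      pos[bad] <- floor(stats::runif(sum(bad)) *
                          unname(cfg$chrom_lengths[chroms[bad]]))
    }
    outside <- tibble::tibble(chrom = chroms, pos = pos)
    dplyr::bind_rows(inside, outside) |> dplyr::mutate(trait = tr)
  })
  list(h3k27ac = h3k27ac, h3k4me3 = h3k4me3, se_truth = se_truth,
       snps = purrr::list_rbind(snp_rows), enhancer_regions = enh)
}

#' Write simulated inputs to plain-text files
#'
#' Emits the formats the pipeline readers accept — triplet contact text
#' per stage/chromosome/replicate, a chrom.sizes file, BED peak files, a
#' TSV expression table, a SNP table, and a `truth.json` with the planted
#' ground truth — under `dir`.
#'
#' @param sim Output of [simulate_stage_series()].
#' @param dir Output directory (created if missing).
#' @param stage Stage to write (default all).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, stage = seq_len(sim$cfg$n_stages)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- sim$binning$chrom_sizes
  readr::write_tsv(cs[, c("chrom", "length")],
                   file.path(dir, "chrom.sizes"), col_names = FALSE)
  for (st in stage) {
    for (chrom in names(sim$maps[[st]])) {
      for (r in seq_along(sim$maps[[st]][[chrom]])) {
        write_contact_map(
          sim$maps[[st]][[chrom]][[r]],
          file.path(dir, sprintf("stage%d_%s_rep%d.triplets.tsv", st, chrom, r)))
      }
    }
  }
  truth_plain <- lapply(sim$truth, function(t) {
    list(labels_coarse = t$labels_coarse,
         tad_boundaries = t$tad_boundaries,
         switch_bins = t$switch_bins,
         loops = lapply(t$loops, function(l) as.list(l)))
  })
  jsonlite::write_json(truth_plain, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
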