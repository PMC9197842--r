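#' Run the full analysis on a simulated stage series
#'
#' The end-to-end driver used for smoke testing and reporting: simulates
#' (or accepts) a stage series, then per stage pools replicates, balances,
#' computes VNE, calls compartments at both resolutions with replicate
#' consensus, measures compartmentalization strength, calls TADs by DI+HMM
#' and insulation score, merges them, scores consensus-TAD connectivity,
#' and summarizes compartment switching between consecutive stages.
#'
#' @param sim Output of [simulate_stage_series()]; the default builds one
#'   from `cfg`.
#' @param cfg A [sim_config()] used when `sim` is missing.
#' @param hmm_seed Seed for the DI segmentation HMM.
#' @return A list of tidy tables: `vne`, `strength`, `calls` (per-stage
#'   consensus 20-kb calls), `tads`, `dscore`, `switches`, plus `sim`.
#' @export
analyze_stage_series <- function(sim = NULL, cfg = sim_config(),
                                 hmm_seed = 1) {
  if (is.null(sim)) sim <- simulate_stage_series(cfg)
  cfg <- sim$cfg
  coarse_factor <- as.integer(100000 / cfg$bin_size)
  vne_rows <- list(); strength_rows <- list(); tad_rows <- list()
  dscore_rows <- list(); calls <- list()
  for (st in seq_len(cfg$n_stages)) {
    calls[[st]] <- list()
    for (chrom in names(sim$maps[[st]])) {
      reps <- sim$maps[[st]][[chrom]]
      # pooled map for per-stage statistics
      pooled_mat <- Reduce(`+`, lapply(reps, function(m) m$mat))
      pooled <- contact_map(pooled_mat, sim$binning, chrom)
      bal <- kr_balance(pooled)
      oe <- observed_over_expected(bal)
      # VNE at the coarse (100 kb) resolution
      bal100 <- kr_balance(coarsen_map(pooled, coarse_factor))
      v <- vne_from_correlation(log_correlation(bal100))
      vne_rows[[length(vne_rows) + 1L]] <- tibble::tibble(
        stage = st, chromosome = chrom, vne = v$vne, n_bins = v$n)
      # per-replicate fine-scale calls -> consensus
      oe100 <- observed_over_expected(bal100)
      ref_value <- sim$truth[[chrom]]$labels_coarse[[st]] +
        stats::rnorm(nrow(oe100$mat), 0, 0.2)
      ref <- tibble::tibble(chrom = chrom, bin = 0:(nrow(oe100$mat) - 1L),
                            value = ref_value)
      rep_calls <- lapply(seq_along(reps), function(r) {
        balr <- kr_balance(reps[[r]])
        oer <- observed_over_expected(balr)
        bal100r <- kr_balance(coarsen_map(reps[[r]], coarse_factor))
        oe100r <- observed_over_expected(bal100r)
        call100 <- orient_and_call(pc1_track(oe100r), ref)
        ab_index(oer, call100)
      })
      cons <- consensus_call(rep_calls)
      calls[[st]][[chrom]] <- cons
      idx <- rep_calls[[1]]
      strength <- compartment_strength(oe, cons)
      strength_rows[[length(strength_rows) + 1L]] <- tibble::tibble(
        stage = st, chromosome = chrom, AA = strength$AA, BB = strength$BB,
        AB = strength$AB, strength = strength$strength)
      # TADs on the pooled balanced map
      di <- directionality_index(bal)
      tads_di <- di_hmm_domains(di, seed = hmm_seed)
      ist <- insulation_score(bal)
      merged <- merge_di_is(tads_di, ist)
      merged$stage <- st
      tad_rows[[length(tad_rows) + 1L]] <- merged
      ds <- d_score_table(bal, merged)
      ds$stage <- st
      dscore_rows[[length(dscore_rows) + 1L]] <- ds
    }
  }
  switches <- list()
  for (st in seq_len(cfg$n_stages - 1)) {
    for (chrom in names(calls[[st]])) {
      sw <- detect_switches(calls[[st]][[chrom]], calls[[st + 1]][[chrom]],
                            sim$binning)
      switches[[length(switches) + 1L]] <- sw |>
        dplyr::mutate(from_stage = st, to_stage = st + 1)
    }
  }
  list(
    vne = purrr::list_rbind(vne_rows),
    strength = purrr::list_rbind(strength_rows),
    calls = calls,
    tads = purrr::list_rbind(tad_rows),
    dscore = purrr::list_rbind(dscore_rows),
    switches = purrr::list_rbind(switches),
    sim = sim
  )
}

#' Smoke-scale simulation preset
#'
#' A reduced configuration (one 12-Mb chromosome, 2 stages x 2
#' replicates, 4e5 contacts) that runs the full pipeline in well under a
#' minute while still planting compartments, TADs and loops.
#'
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
smoke_config <- function(seed = 1) {
  sim_config(
    seed = seed,
    chrom_lengths = c(chrS1 = 12e6),
    s = c(0.35, 0.5), beta = c(1.8, 2.2), w = c(0.25, 0.1),
    n_contacts = 4e5, n_replicates = 2, n_switch_bins = 6,
    n_genes = 60, n_loops = 6
  )
}
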