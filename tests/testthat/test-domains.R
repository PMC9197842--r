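test_that("directionality index follows the signed chi-square form", {
  n <- 10
  gb <- tiny_binning(n)
  # bin 0: no upstream (A = 0), downstream contact 20 -> DI = +20
  M <- matrix(0, n, n)
  M[1, 2] <- M[2, 1] <- 20
  m <- contact_map(M, gb, "chrT", state = "balanced", mask = rep(FALSE, n))
  di <- directionality_index(m)
  expect_equal(di$di[1], 20)
  expect_equal(di$A[1], 0)
  expect_equal(di$E[1], 10)

  # symmetric neighborhood (A = B) -> DI = 0 on untruncated interior bins
  M2 <- matrix(1, n, n)
  diag(M2) <- 2
  m2 <- contact_map(M2, gb, "chrT", state = "balanced", mask = rep(FALSE, n))
  di2 <- directionality_index(m2, window = 2)
  expect_true(all(abs(di2$di[3:8]) < 1e-12))

  # mirror-image matrix negates and reverses the track
  set.seed(1)
  M3 <- matrix(runif(n * n), n)
  M3 <- M3 + t(M3)
  m3 <- contact_map(M3, gb, "chrT", state = "balanced", mask = rep(FALSE, n))
  m3r <- contact_map(M3[n:1, n:1], gb, "chrT", state = "balanced",
                     mask = rep(FALSE, n))
  expect_equal(directionality_index(m3r)$di,
               -rev(directionality_index(m3)$di), tolerance = 1e-9)
})

test_that("HMM segmentation decodes a noiseless sawtooth exactly", {
  # +20 runs then -20 runs; boundaries at the -to-+ sign changes
  x <- rep(c(rep(20, 5), rep(-20, 5)), 6)
  di <- tibble::tibble(chrom = "chrT", bin = seq_along(x) - 1L, di = x)
  tads <- di_hmm_domains(di, seed = 1)
  expect_equal(tads$start_bin, seq(0, 50, by = 10))
  expect_equal(tads$end_bin, seq(10, 60, by = 10))

  # constant zero DI -> no domains
  di0 <- tibble::tibble(chrom = "chrT", bin = 0:59, di = rep(0, 60))
  expect_equal(nrow(di_hmm_domains(di0)), 0)
})

test_that("DI+HMM recovers planted boundaries on sampled maps", {
  nb <- 1000
  gb <- tiny_binning(nb)
  for (sd in 1:3) {
    set.seed(sd)
    bnd <- random_tad_boundaries(nb)
    P <- build_probability_model(nb, alpha = 1, tad_boundaries = bnd,
                                 beta = 2)
    bal <- kr_balance(sample_contact_map(P, 1e6, gb, "chrT", seed = sd + 50))
    tads <- di_hmm_domains(directionality_index(bal), seed = 1)
    called <- sort(unique(c(tads$start_bin, tads$end_bin)))
    expect_gte(boundary_f1(called, setdiff(bnd, c(0, nb))), 0.9)
  }
})

test_that("insulation score is flat on uniform maps and dips at junctions", {
  n <- 60
  gb <- tiny_binning(n)
  m <- contact_map(matrix(1, n, n), gb, "chrT", state = "balanced",
                   mask = rep(FALSE, n))
  ist <- insulation_score(m, window_bp = 2e5)  # w = 10 bins
  expect_true(all(abs(ist$is[!is.na(ist$is)]) < 1e-12))
  expect_false(any(ist$boundary))

  # two blocks with zero cross-block contact: single minimum at the junction
  M <- matrix(0, n, n)
  M[1:30, 1:30] <- 1
  M[31:60, 31:60] <- 1
  m2 <- contact_map(M, gb, "chrT", state = "balanced", mask = rep(FALSE, n))
  ist2 <- insulation_score(m2, window_bp = 2e5)
  b <- ist2$bin[ist2$boundary]
  expect_equal(length(b), 1)
  # the fully cross-block square sits on the last bin of the left block
  expect_true(b %in% c(29, 30))
})

test_that("IS boundaries recover planted domains on sampled maps", {
  nb <- 1000
  gb <- tiny_binning(nb)
  for (sd in 1:3) {
    set.seed(sd + 10)
    bnd <- random_tad_boundaries(nb)
    P <- build_probability_model(nb, alpha = 1, tad_boundaries = bnd,
                                 beta = 2)
    bal <- kr_balance(sample_contact_map(P, 1e6, gb, "chrT", seed = sd + 70))
    ist <- insulation_score(bal)
    expect_gte(boundary_f1(ist$bin[ist$boundary], setdiff(bnd, c(0, nb))),
               0.9)
  }
})

test_that("merging splits DI domains at IS boundaries and keeps the partition valid", {
  mk_is <- function(n, bnds) {
    tibble::tibble(chrom = "chrT", bin = 0:(n - 1), raw = NA, is = NA,
                   boundary = (0:(n - 1)) %in% bnds)
  }
  tads_di <- tibble::tibble(chrom = "chrT", start_bin = 0L, end_bin = 50L,
                            source = "DI")
  # no interior boundary -> unchanged
  merged0 <- merge_di_is(tads_di, mk_is(60, integer()))
  expect_equal(merged0$start_bin, 0L)
  expect_equal(merged0$end_bin, 50L)
  # boundary at bin 20 -> [0,20) and [20,50)
  merged <- merge_di_is(tads_di, mk_is(60, 20L))
  expect_equal(merged$start_bin, c(0L, 20L))
  expect_equal(merged$end_bin, c(20L, 50L))

  # random split positions never create sub-minimum domains and the result
  # is a refinement: every merged domain lies inside a DI domain or equals
  # an IS domain
  set.seed(5)
  for (rep in 1:20) {
    cuts <- sort(sample(1:49, sample(1:8, 1)))
    mg <- merge_di_is(tads_di, mk_is(60, cuts))
    expect_true(all(mg$end_bin - mg$start_bin >= 3))
    expect_true(all(mg$start_bin >= 0 & mg$end_bin <= 50))
    expect_true(all(mg$start_bin[-1] >= mg$end_bin[-nrow(mg)]))  # non-overlap
  }
})

test_that("boundary Jaccard counts greedy matches within tolerance", {
  mk <- function(b) tibble::tibble(chrom = "chrT", start_bin = b,
                                   end_bin = b + 5L, source = "x")
  t1 <- tibble::tibble(chrom = "chrT", start_bin = c(10L, 20L),
                       end_bin = c(20L, 30L), source = "x")
  expect_equal(boundary_jaccard(t1, t1), 1)
  t2 <- tibble::tibble(chrom = "chrT", start_bin = c(100L, 200L),
                       end_bin = c(150L, 260L), source = "x")
  expect_equal(boundary_jaccard(t1, t2, tolerance_bins = 0), 0)
  # sets {10,20,30} vs {10,20,40} at tolerance 0: 2 matched -> 2/4
  ta <- tibble::tibble(chrom = "chrT", start_bin = c(10L, 20L),
                       end_bin = c(20L, 30L), source = "x")
  tb <- tibble::tibble(chrom = "chrT", start_bin = c(10L, 20L),
                       end_bin = c(20L, 40L), source = "x")
  expect_equal(boundary_jaccard(ta, tb, tolerance_bins = 0), 0.5)
  # both empty -> 1 by convention
  e <- tibble::tibble(chrom = character(), start_bin = integer(),
                      end_bin = integer(), source = character())
  expect_equal(boundary_jaccard(e, e), 1)
})

test_that("consensus TADs honor the 50% rule and take median boundaries", {
  one <- tibble::tibble(chrom = "chrT", start_bin = 10L, end_bin = 40L,
                        source = "merged")
  sets <- list(a = one, b = one, c = one, d = one, e = one, f = one)
  ct <- consensus_tads(sets)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$start_bin, 10L)
  expect_equal(ct$end_bin, 40L)
  expect_equal(ct$n_samples, 6L)

  # present in 2 of 6 -> dropped
  none <- tibble::tibble(chrom = character(), start_bin = integer(),
                         end_bin = integer(), source = character())
  sets2 <- list(a = one, b = one, c = none, d = none, e = none, f = none)
  expect_equal(nrow(consensus_tads(sets2)), 0)

  # jittered boundaries cluster to the median
  jit <- function(d) tibble::tibble(chrom = "chrT", start_bin = 10L + d,
                                    end_bin = 40L + d, source = "merged")
  sets3 <- list(a = jit(-1L), b = jit(0L), c = jit(1L), d = jit(0L))
  ct3 <- consensus_tads(sets3)
  expect_equal(nrow(ct3), 1)
  expect_equal(ct3$start_bin, 10L)
  expect_equal(ct3$end_bin, 40L)
})

test_that("D-score equals exhaustive pair enumeration on random matrices", {
  d_score_oracle <- function(M, s, e) {
    # brute force over all (i <= j) pairs
    n <- nrow(M)
    intra <- 0; touching <- 0
    for (i in 1:n) for (j in i:n) {
      ini <- i > s && i <= e
      inj <- j > s && j <= e
      if (ini && inj) intra <- intra + M[i, j]
      if (ini || inj) touching <- touching + M[i, j]
    }
    if (touching == 0) NA_real_ else intra / touching
  }
  gb <- tiny_binning(12)
  for (sd in 1:100) {
    set.seed(sd)
    M <- matrix(rpois(144, 3), 12)
    M <- M + t(M)
    m <- contact_map(M, gb, "chrT", state = "balanced",
                     mask = rep(FALSE, 12))
    s <- sample(0:9, 1)
    e <- sample((s + 2):12, 1)
    expect_identical(d_score(m, list(start_bin = s, end_bin = e)),
                     d_score_oracle(m$mat, s, e))
  }
})

test_that("D-score extremes and toy arithmetic are exact", {
  gb <- tiny_binning(4)
  # intra {0,1}: (0,0)=2,(0,1)=2,(1,1)=2 -> 6; external to {2,3} -> 4
  M <- matrix(c(2, 2, 1, 1,
                2, 2, 1, 1,
                1, 1, 0, 0,
                1, 1, 0, 0), 4, byrow = TRUE)
  m <- contact_map(M, gb, "chrT", state = "balanced", mask = rep(FALSE, 4))
  expect_equal(d_score(m, list(start_bin = 0, end_bin = 2)), 0.6)

  # isolated TAD -> 1; only-external TAD -> 0
  M2 <- matrix(0, 4, 4)
  M2[1:2, 1:2] <- 3
  m2 <- contact_map(M2, gb, "chrT", state = "balanced", mask = rep(FALSE, 4))
  expect_equal(d_score(m2, list(start_bin = 0, end_bin = 2)), 1)
  M3 <- matrix(0, 4, 4)
  M3[1, 3] <- M3[3, 1] <- 5
  m3 <- contact_map(M3, gb, "chrT", state = "balanced", mask = rep(FALSE, 4))
  expect_equal(d_score(m3, list(start_bin = 0, end_bin = 2)), 0)
})

test_that("mean D-score rises with the planted intra-TAD boost", {
  nb <- 600
  gb <- tiny_binning(nb)
  set.seed(17)
  bnd <- random_tad_boundaries(nb)
  tads <- tibble::tibble(chrom = "chrT",
                         start_bin = bnd[-length(bnd)],
                         end_bin = bnd[-1], source = "truth")
  means <- vapply(c(1, 1.5, 2, 3), function(beta) {
    P <- build_probability_model(nb, alpha = 1, tad_boundaries = bnd,
                                 beta = beta)
    bal <- kr_balance(sample_contact_map(P, 5e5, gb, "chrT", seed = 23))
    mean(d_score_table(bal, tads)$d_score)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("intra-TAD contact totals never exceed the chromosome total", {
  set.seed(19)
  nb <- 100
  gb <- tiny_binning(nb)
  M <- matrix(rpois(nb * nb, 2), nb)
  M <- M + t(M)
  m <- contact_map(M, gb, "chrT", state = "balanced", mask = rep(FALSE, nb))
  bnd <- random_tad_boundaries(nb, 10, 30)
  total <- sum(M[upper.tri(M, diag = TRUE)])
  intra <- sum(vapply(seq_len(length(bnd) - 1), function(k) {
    idx <- (bnd[k] + 1):bnd[k + 1]
    S <- M[idx, idx, drop = FALSE]
    sum(S[upper.tri(S, diag = TRUE)])
  }, 0))
  expect_lte(intra, total)
})

test_that("cTAD compartment status applies the inclusive 80% rule", {
  idx <- tibble::tibble(chrom = "chrT", bin = 0:9,
                        ab_index = c(rep(0.5, 8), rep(-0.5, 2)))
  mk_calls <- function(labs) {
    tibble::tibble(chrom = "chrT", bin = 0:9,
                   label = factor(labs, levels = c("A", "B", "Un")))
  }
  ct <- list(start_bin = 0L, end_bin = 10L)
  expect_equal(ctad_status(ct, idx, mk_calls(rep("A", 10)))$status, "A")
  expect_equal(ctad_status(ct, idx, mk_calls(c(rep("A", 8), "B", "B")))$status,
               "A")   # exactly 80% counts
  expect_equal(ctad_status(ct, idx, mk_calls(c(rep("A", 7), rep("B", 3))))$status,
               "mixed")
  expect_true(is.na(ctad_status(ct, idx, mk_calls(rep("Un", 10)))$status))
  expect_equal(ctad_status(ct, idx, mk_calls(rep("A", 10)))$mean_index, 0.3)
})
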