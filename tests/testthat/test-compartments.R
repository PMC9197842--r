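oe_from_labels <- function(labels, s = 0.4, chrom = "chrT", bin_size = 1e5) {
  n <- length(labels)
  M <- 1 + s * outer(labels, labels)
  contact_map(M, tiny_binning(n, bin_size), chrom, state = "oe",
              mask = rep(FALSE, n))
}

test_that("PC1 separates a planted checkerboard and recovers labels", {
  set.seed(1)
  lab <- block_labels(300)
  oe <- oe_from_labels(lab)
  pc1 <- pc1_track(oe)
  # two-valued, constant within blocks, opposite signs across blocks
  expect_equal(length(unique(round(abs(pc1$value), 9))), 1)
  agree <- sign(pc1$value) == lab
  expect_true(mean(agree) >= 0.99 || mean(!agree) >= 0.99)

  # orientation via a reference that is higher in A
  ref <- tibble::tibble(chrom = "chrT", bin = pc1$bin,
                        value = lab + rnorm(300, 0, 0.1))
  call <- orient_and_call(pc1, ref)
  expect_gte(mean(as.character(call$label) == ifelse(lab > 0, "A", "B")), 0.99)

  # anti-correlated reference flips the track before labeling
  call_flip <- orient_and_call(
    dplyr::mutate(pc1, value = -value), ref)
  expect_equal(as.character(call_flip$label), as.character(call$label))
})

test_that("degenerate O/E inputs are rejected", {
  n <- 10
  m <- contact_map(matrix(1, n, n), tiny_binning(n, 1e5), "chrT",
                   state = "oe", mask = rep(FALSE, n))
  expect_error(pc1_track(m), "constant")
})

test_that("PC1 value exactly zero is labelled Un", {
  pc1 <- tibble::tibble(chrom = "chrT", bin = 0:3,
                        value = c(0.5, 0, -0.5, NA))
  ref <- tibble::tibble(chrom = "chrT", bin = 0:3, value = c(1, 0, -1, 0))
  call <- orient_and_call(pc1, ref)
  expect_equal(as.character(call$label), c("A", "Un", "B", "Un"))
})

test_that("A-B index hits its extremes and recovers planted fine labels", {
  # bin contacting only A partners -> +1 -> A; balanced contact -> Un
  lab100 <- c(1, 1, -1, -1)
  call100 <- labels_to_call(lab100)
  n <- 20
  M <- matrix(0, n, n)
  labf <- rep(lab100, each = 5)
  M[1, labf > 0] <- 2      # bin 0 touches only A bins
  M[labf > 0, 1] <- 2
  M[6, ] <- 1; M[, 6] <- 1 # bin 5 touches everything equally
  diag(M) <- 0
  oe <- contact_map(M, tiny_binning(n, 20000), "chrT", state = "oe",
                    mask = rep(FALSE, n))
  ab <- ab_index(oe, call100)
  expect_equal(ab$ab_index[1], 1)
  expect_equal(as.character(ab$label[1]), "A")
  expect_equal(ab$ab_index[6], 0)
  expect_equal(as.character(ab$label[6]), "Un")
  expect_true(all(abs(ab$ab_index) <= 1, na.rm = TRUE))

  # sampled recovery at the fine scale
  set.seed(4)
  nb <- 750
  gb <- tiny_binning(nb, 20000)
  labc <- block_labels(nb / 5)
  labf <- rep(labc, each = 5)
  P <- build_probability_model(nb, alpha = 1, labels = labf, s = 0.4)
  m <- sample_contact_map(P, 1e6, gb, "chrT", seed = 5)
  oe <- observed_over_expected(kr_balance(m))
  ab <- ab_index(oe, labels_to_call(labc))
  acc <- mean(as.character(ab$label) == ifelse(labf > 0, "A", "B"))
  expect_gte(acc, 0.95)
})

test_that("consensus requires strictly more than half of the replicates", {
  mk <- function(labs) labels_to_call(ifelse(labs == "A", 1, -1))
  calls6 <- lapply(c("A", "A", "A", "A", "A", "A"), function(l) mk(l))
  expect_equal(as.character(consensus_call(calls6)$label), "A")
  calls33 <- lapply(c("A", "A", "A", "B", "B", "B"), function(l) mk(l))
  expect_equal(as.character(consensus_call(calls33)$label), "Un")
  calls42 <- lapply(c("A", "A", "A", "A", "B", "B"), function(l) mk(l))
  expect_equal(as.character(consensus_call(calls42)$label), "A")
  expect_error(consensus_call(list(mk("A"), labels_to_call(c(1, 1)))),
               "mismatch")
})

test_that("compartmentalization strength is exact on planted O/E", {
  set.seed(2)
  lab <- block_labels(100)
  oe <- oe_from_labels(lab, s = 0.5)
  call <- labels_to_call(lab)
  st <- compartment_strength(oe, call)
  expect_equal(st$AA, 1.5)
  expect_equal(st$BB, 1.5)
  expect_equal(st$AB, 0.5)
  expect_equal(st$strength, 9)

  # invariant under A<->B relabeling with AA/BB swap
  flip <- labels_to_call(-lab)
  st2 <- compartment_strength(oe, flip)
  expect_equal(st2$strength, st$strength)
  expect_equal(st2$AA, st$BB)

  # one class empty -> absent
  st3 <- compartment_strength(oe, labels_to_call(rep(1, 100)))
  expect_true(is.na(st3$strength))
})

test_that("strength increases with planted checkerboard contrast", {
  set.seed(6)
  nb <- 500
  gb <- tiny_binning(nb, 20000)
  labc <- block_labels(nb / 5)
  labf <- rep(labc, each = 5)
  call <- labels_to_call(labf)
  strengths <- vapply(c(0.2, 0.4, 0.6), function(s) {
    P <- build_probability_model(nb, alpha = 1, labels = labf, s = s)
    m <- sample_contact_map(P, 5e5, gb, "chrT", seed = 11)
    compartment_strength(observed_over_expected(kr_balance(m)), call)$strength
  }, 0)
  expect_true(all(diff(strengths) > 0))
})

test_that("saddle matrix shows compartment corners and matches strength", {
  set.seed(8)
  nb <- 500
  gb <- tiny_binning(nb, 20000)
  labf <- rep(block_labels(nb / 5), each = 5)
  P <- build_probability_model(nb, alpha = 1, labels = labf, s = 0.5)
  m <- sample_contact_map(P, 2e6, gb, "chrT", seed = 21)
  oe <- observed_over_expected(kr_balance(m))
  idx <- tibble::tibble(chrom = "chrT", bin = 0:(nb - 1),
                        ab_index = labf + runif(nb, -0.1, 0.1))
  # perfectly sorted two-equal-block map: high same-class corners, low
  # anti-diagonal corners, center (straddling the class cut) in between
  lab2 <- c(rep(-1, 250), rep(1, 250))
  oe2 <- contact_map(1 + 0.5 * outer(lab2, lab2), gb, "chrT", state = "oe",
                     mask = rep(FALSE, nb))
  idx2 <- tibble::tibble(chrom = "chrT", bin = 0:(nb - 1), ab_index = lab2)
  sad2 <- saddle_matrix(oe2, idx2)
  expect_gt(mean(sad2[1:5, 1:5]), mean(sad2[23:28, 23:28]))
  expect_gt(mean(sad2[46:50, 46:50]), mean(sad2[23:28, 23:28]))
  expect_lt(mean(sad2[1:5, 46:50]), mean(sad2[23:28, 23:28]))

  sad <- saddle_matrix(oe, idx)
  expect_equal(dim(sad), c(50, 50))
  corner_bb <- mean(sad[1:5, 1:5])
  corner_aa <- mean(sad[46:50, 46:50])
  corner_ab <- mean(sad[1:5, 46:50])
  expect_gt(corner_aa, corner_ab)
  expect_gt(corner_bb, corner_ab)

  # corner means reproduce the class means within 15%
  st <- compartment_strength(oe, labels_to_call(labf))
  expect_equal(corner_aa, st$AA, tolerance = 0.15)
  expect_equal(corner_bb, st$BB, tolerance = 0.15)
  expect_equal(corner_ab, st$AB, tolerance = 0.15)

  # shuffled index -> approximately flat saddle
  ratios <- vapply(1:10, function(sd) {
    set.seed(sd)
    idx_sh <- dplyr::mutate(idx, ab_index = sample(ab_index))
    s2 <- saddle_matrix(oe, idx_sh)
    corners <- c(mean(s2[1:5, 1:5]), mean(s2[46:50, 46:50]),
                 mean(s2[1:5, 46:50]), mean(s2[46:50, 1:5]))
    max(corners) / min(corners)
  }, 0)
  expect_lt(stats::median(ratios), 1.2)
})

test_that("switch regions are merged, measured, and recover planted flips", {
  gb <- tiny_binning(20, 20000)
  labX <- rep(1, 20)
  labY <- labX
  labY[6:10] <- -1  # one 5-bin A->B run
  sw <- detect_switches(labels_to_call(labX), labels_to_call(labY), gb)
  ab_runs <- sw[sw$class == "A->B", ]
  expect_equal(nrow(ab_runs), 1)
  expect_equal(ab_runs$width, 100000)
  expect_equal(attr(sw, "switched_bp"), 100000)

  # identical calls -> zero switched length
  sw0 <- detect_switches(labels_to_call(labX), labels_to_call(labX), gb)
  expect_equal(attr(sw0, "switched_bp"), 0)

  # Un in either stage forms its own class, excluded from totals
  callU <- labels_to_call(labX)
  callU$label[1] <- "Un"
  swu <- detect_switches(callU, labels_to_call(labY), gb)
  expect_true("involving-Un" %in% swu$class)
  expect_equal(attr(swu, "switched_bp"), 100000)
})

test_that("planted stage flips are recovered with high Jaccard", {
  set.seed(31)
  cfg <- sim_config(seed = 31, chrom_lengths = c(chrT = 15e6),
                    n_contacts = 1e6, n_replicates = 4,
                    s = c(0.5, 0.5), beta = c(1, 1), w = c(0.05, 0.05),
                    n_switch_bins = 15)
  sim <- simulate_stage_series(cfg)
  res <- analyze_stage_series(sim = sim)
  truth_flips <- sim$truth$chrT$switch_bins[[1]]
  # fine bins inside flipped coarse bins
  truth_fine <- as.vector(outer(0:4, truth_flips * 5, "+"))
  called_fine <- unlist(lapply(which(
    res$switches$class %in% c("A->B", "B->A")), function(k) {
      res$switches$start_bin[k]:(res$switches$end_bin[k] - 1)
  }))
  jac <- length(intersect(called_fine, truth_fine)) /
    length(union(called_fine, truth_fine))
  expect_gte(jac, 0.95)
})
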