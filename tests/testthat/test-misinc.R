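test_that("misincorporation rate is the non-reference fraction", {
  expect_equal(misincorporation_rate(c(A = 930, C = 0, G = 0, T = 70), "A"),
               0.07)
  expect_equal(misincorporation_rate(c(A = 500, C = 0, G = 0, T = 0), "A"), 0)
  expect_equal(misincorporation_rate(c(A = 0, C = 0, G = 0, T = 10), "A"), 1)
  expect_error(misincorporation_rate(c(A = 0, C = 0, G = 0, T = 0), "A"),
               "zero depth")
  # vectorised over rows
  m <- rbind(c(A = 90, C = 0, G = 0, T = 10), c(A = 0, C = 50, G = 50, T = 0))
  expect_equal(misincorporation_rate(m, c("A", "C")), c(0.1, 0.5))
})

test_that("heterogeneity is the minority-mismatch fraction", {
  expect_equal(heterogeneity_fraction(c(A = 900, C = 4, G = 6, T = 90), "A"),
               0.10)
  expect_equal(heterogeneity_fraction(c(A = 0, C = 0, G = 100, T = 0), "A"),
               0)  # homogeneous, the A-to-I editing signature
  expect_equal(heterogeneity_fraction(c(A = 900, C = 1, G = 2, T = 97), "A"),
               0.03)
  expect_error(heterogeneity_fraction(c(A = 100, C = 0, G = 0, T = 0), "A"),
               "without mismatched reads")
})

test_that("per-replicate detection gates on depth and rate", {
  cfg <- filter_config()
  expect_true(replicate_detects(100, 0.05, cfg))
  expect_false(replicate_detects(10, 0.5, cfg))
  expect_false(replicate_detects(100, 0.005, cfg))
  expect_equal(replicate_detects(c(100, 10), c(0.05, 0.5), cfg),
               c(TRUE, FALSE))
})

# Build per-replicate single-column pileups by sampling the generative model
# at the column level: n covering reads per replicate, mismatch probability
# q split over the spectrum, error elsewhere.
column_pileups <- function(n_rep, depth, q, spectrum = c(T = 0.8, G = 0.1,
                                                         C = 0.1),
                           pos = 50L, e = 0.001) {
  lapply(seq_len(n_rep), function(i) {
    mm <- rbinom(1L, depth, q + e)
    alt <- if (mm > 0) {
      table(factor(sample(names(spectrum), mm, TRUE, prob = spectrum),
                   levels = c("A", "C", "G", "T")))
    } else c(A = 0L, C = 0L, G = 0L, T = 0L)
    data.frame(replicate_id = sprintf("rep%02d", i), seq_id = "chrT",
               pos = pos, ref = "A",
               A = depth - mm, C = as.integer(alt[["C"]]),
               G = as.integer(alt[["G"]]), T = as.integer(alt[["T"]]),
               depth = depth, stringsAsFactors = FALSE)
  })
}

test_that("a planted hard-stop signature is called high-confidence", {
  set.seed(31)
  ref <- c(chrT = strrep("A", 100L))
  # stoichiometry 0.2, read-through 0.2, misincorporation 0.9:
  # expected covering-read mismatch rate s*r*m / (s*r + 1 - s)
  q <- expected_mismatch_rate(0.2, 0.2, 0.9)
  expect_equal(round(q, 4), 0.0429)
  pls <- column_pileups(20L, 50L, q)
  sites <- call_candidate_sites(pls, NULL, ref, filter_config())
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 50L)
  expect_true(sites$high_confidence)
  expect_equal(sites$combined_depth, 1000L)
  expect_gt(sites$combined_rate, 0.01)
  # combined counts conserve the per-replicate sums
  expect_equal(sites$count_A + sites$count_C + sites$count_G + sites$count_T,
               sum(vapply(pls, function(p) p$depth, numeric(1))))

  # masking the position removes it regardless of signal
  mask <- data.frame(seq_id = "chrT", pos = 50L)
  expect_equal(nrow(call_candidate_sites(pls, mask, ref, filter_config())),
               0L)
})

test_that("heterozygous SNP decoys fail the heterogeneity gate", {
  set.seed(32)
  ref <- c(chrT = strrep("A", 100L))
  pls <- lapply(1:20, function(i) {
    alt <- rbinom(1L, 60L, 0.5)  # pure A->G allele sampling
    err <- rbinom(1L, 60L, 0.001)
    data.frame(replicate_id = sprintf("rep%02d", i), seq_id = "chrT",
               pos = 10L, ref = "A", A = 60L - alt - err,
               C = err, G = alt, T = 0L, depth = 60L,
               stringsAsFactors = FALSE)
  })
  sites <- call_candidate_sites(pls, NULL, ref, filter_config())
  expect_equal(nrow(sites), 1L)     # passes depth/rate/replication
  expect_false(sites$high_confidence)
  expect_lt(sites$heterogeneity, 0.05)
})

test_that("raising thresholds never adds sites (spot check)", {
  set.seed(33)
  ref <- c(chrT = strrep("A", 100L))
  pls <- c(column_pileups(10L, 60L, 0.05, pos = 20L),
           column_pileups(10L, 60L, 0.02, pos = 70L))
  # merge into 10 replicates with two columns each
  pls <- lapply(1:10, function(i) rbind(pls[[i]], pls[[10L + i]]))
  base_cfg <- filter_config(min_combined_depth = 100L, min_rate = 0.005,
                            min_replicate_fraction = 0.2,
                            min_heterogeneity = 0.01,
                            per_replicate_min_depth = 10L,
                            per_replicate_min_rate = 0.005)
  base <- call_candidate_sites(pls, NULL, ref, base_cfg)
  for (raised in list(
    filter_config(min_combined_depth = 650L, min_rate = 0.005,
                  min_replicate_fraction = 0.2, min_heterogeneity = 0.01,
                  per_replicate_min_depth = 10L,
                  per_replicate_min_rate = 0.005),
    filter_config(min_combined_depth = 100L, min_rate = 0.04,
                  min_replicate_fraction = 0.2, min_heterogeneity = 0.01,
                  per_replicate_min_depth = 10L,
                  per_replicate_min_rate = 0.005),
    filter_config(min_combined_depth = 100L, min_rate = 0.005,
                  min_replicate_fraction = 0.9, min_heterogeneity = 0.2,
                  per_replicate_min_depth = 40L,
                  per_replicate_min_rate = 0.03))) {
    sub <- call_candidate_sites(pls, NULL, ref, raised)
    expect_true(all(paste(sub$seq_id, sub$position) %in%
                      paste(base$seq_id, base$position)))
  }
})

test_that("read-through is the site depth over the 3' flank median", {
  pl <- data.frame(replicate_id = "rep01", seq_id = "chrT",
                   pos = 10:40, ref = "A", A = 100L, C = 0L, G = 0L, T = 0L,
                   depth = 100L, stringsAsFactors = FALSE)
  pl$depth[pl$pos == 10L] <- 15L
  est <- estimate_readthrough(pl, "chrT", 10L, flank_window = 20L)
  expect_equal(est$readthrough_rate, 0.15)
  expect_equal(est$flank_depth, 100)

  pl$depth[pl$pos == 10L] <- 100L
  est2 <- estimate_readthrough(pl, "chrT", 10L, flank_window = 20L)
  expect_equal(est2$readthrough_rate, 1)  # no hard stop

  expect_error(estimate_readthrough(pl, "chrT", 39L, flank_window = 20L),
               "no coverage")
})

test_that("read-through recovery from a full-stoichiometry simulation", {
  cfg <- sim_config(n_transcripts = 1L, transcript_length = c(400L, 400L),
                    n_replicates = 20L, molecules_per_replicate = 150L,
                    n_modified_sites = 1L, stoichiometry = 1,
                    readthrough = 0.25, n_snp_het = 0L, n_snp_hom = 0L,
                    n_editing = 0L, n_decoy_clean = 0L,
                    truth_placement = "five_prime", seed = 99L)
  sim <- simulate_dataset(cfg, "rnaseq")
  # no end clipping here: clipping would shadow the first 10 nt of coverage
  # downstream of the stop and bias the flank median
  pls <- lapply(sim$reads, build_pileup, reference = sim$reference,
                config = pileup_config(end_clip = 0L))
  comb <- do.call(rbind, pls)
  site <- sim$truth$sites
  est <- estimate_readthrough(comb, site$seq_id, site$pos,
                              flank_window = 20L)
  expect_lt(abs(est$readthrough_rate - 0.25), 0.05)
})
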