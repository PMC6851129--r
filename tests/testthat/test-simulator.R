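small_cfg <- function(seed = 5L, ...) {
  sim_config(n_transcripts = 2L, transcript_length = c(400L, 400L),
             n_replicates = 2L, molecules_per_replicate = 200L,
             n_modified_sites = 1L, n_snp_het = 1L, n_snp_hom = 0L,
             n_editing = 1L, n_decoy_clean = 5L, seed = seed, ...)
}

test_that("the same seed reproduces the dataset bit for bit", {
  a <- simulate_dataset(small_cfg(), "rnaseq")
  b <- simulate_dataset(small_cfg(), "rnaseq")
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
  d <- simulate_dataset(small_cfg(seed = 6L), "rnaseq")
  expect_false(identical(a$reads, d$reads))
})

test_that("reference generation obeys its contracts", {
  cfg <- sim_config(n_transcripts = 40L, transcript_length = c(400L, 500L),
                    a_start_fraction = 0.85, n_modified_sites = 0L,
                    n_snp_het = 0L, n_snp_hom = 0L, n_editing = 0L,
                    n_decoy_clean = 0L, seed = 3L)
  sim <- simulate_reference(cfg)
  expect_equal(length(sim$reference), 40L)
  expect_true(all(nchar(sim$reference) >= 400L))
  expect_identical(sim$annotations$start_nucleotide,
                   substr(sim$reference, 1L, 1L), ignore_attr = TRUE)
  # realised A-start fraction within a wide binomial band around 0.85
  frac <- mean(sim$annotations$start_nucleotide == "A")
  expect_gt(frac, 0.85 - 3 * sqrt(0.85 * 0.15 / 40))
  # with A-start forcing off it hovers near the base composition
  expect_error(sim_config(transcript_length = c(200L, 400L)))
  expect_error(sim_config(fragment_mean = 450L,
                          transcript_length = c(400L, 400L)))
})

test_that("planted sites sit on adenosines disjoint from decoys", {
  for (placement in c("interior", "five_prime")) {
    cfg <- sim_config(n_transcripts = 3L, transcript_length = c(400L, 400L),
                      n_modified_sites = 4L, n_snp_het = 1L, n_snp_hom = 1L,
                      n_editing = 2L, n_decoy_clean = 10L,
                      truth_placement = placement, seed = 8L)
    sim <- simulate_reference(cfg)
    tr <- sim$truth
    at <- function(df) mapply(function(s, p) substr(sim$reference[[s]],
                                                    p + 1L, p + 1L),
                              df$seq_id, df$pos)
    expect_true(all(at(tr$sites) == "A"))
    expect_true(all(at(tr$editing) == "A"))
    keys <- c(paste(tr$sites$seq_id, tr$sites$pos),
              paste(tr$snps$seq_id, tr$snps$pos),
              paste(tr$editing$seq_id, tr$editing$pos),
              paste(tr$clean_a$seq_id, tr$clean_a$pos))
    expect_false(any(duplicated(keys)))
  }
})

test_that("error-only data show only error-level mismatches", {
  cfg <- sim_config(n_transcripts = 1L, transcript_length = c(400L, 400L),
                    n_replicates = 4L, molecules_per_replicate = 400L,
                    n_modified_sites = 0L, n_snp_het = 0L, n_snp_hom = 0L,
                    n_editing = 0L, n_decoy_clean = 5L, seq_error = 0.001,
                    seed = 21L)
  sim <- simulate_dataset(cfg, "rnaseq")
  pls <- lapply(sim$reads, build_pileup, reference = sim$reference,
                config = pileup_config())
  comb <- do.call(rbind, pls)
  cm <- as.matrix(comb[, c("A", "C", "G", "T")])
  refc <- cm[cbind(seq_len(nrow(comb)), match(comb$ref, colnames(cm)))]
  mism <- sum(comb$depth) - sum(refc)
  total <- sum(comb$depth)
  # observed error rate within 3 binomial sigma of the configured rate
  expect_lt(abs(mism / total - 0.001), 3 * sqrt(0.001 / total) + 1e-4)
})

test_that("a full-stoichiometry pure hard stop leaves a coverage cliff", {
  cfg <- sim_config(n_transcripts = 1L, transcript_length = c(400L, 400L),
                    n_replicates = 2L, molecules_per_replicate = 300L,
                    n_modified_sites = 1L, stoichiometry = 1,
                    readthrough = 0, n_snp_het = 0L, n_snp_hom = 0L,
                    n_editing = 0L, n_decoy_clean = 0L, seq_error = 0,
                    truth_placement = "five_prime", seed = 13L)
  sim <- simulate_dataset(cfg, "rnaseq")
  site <- sim$truth$sites
  pls <- lapply(sim$reads, build_pileup, reference = sim$reference,
                config = pileup_config(end_clip = 0L))
  comb <- do.call(rbind, pls)
  on_site <- comb$seq_id == site$seq_id & comb$pos == site$pos
  after <- comb$seq_id == site$seq_id & comb$pos == site$pos + 1L
  expect_equal(sum(comb$depth[on_site]), 0L)   # no read traverses the stop
  expect_gt(sum(comb$depth[after]), 100L)      # truncations resume at +1
})

test_that("site mismatch rates converge to the closed-form expectation", {
  expect_equal(expected_mismatch_rate(1, 1, 1), 1)
  expect_equal(expected_mismatch_rate(0, 0.5, 0.9), 0)
  expect_equal(round(expected_mismatch_rate(0.2, 0.2, 0.9), 4), 0.0429)
  expect_error(expected_mismatch_rate(1, 0, 0.9), "degenerate")

  # independent Monte-Carlo oracle: per-molecule draws of the generative
  # process at one position
  set.seed(17)
  s <- 0.2; r <- 0.2; m <- 0.9
  n <- 2e5
  modified <- runif(n) < s
  readthrough <- !modified | runif(n) < r   # unmodified always traverse
  covering <- readthrough
  misinc <- modified & covering & runif(n) < m
  expect_lt(abs(sum(misinc) / sum(covering) -
                  expected_mismatch_rate(s, r, m)), 0.003)
})

test_that("SAM output round trips through the standard reader", {
  sim <- simulate_dataset(small_cfg(), "rnaseq")
  reads <- sim$reads[[1]]
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, sim$reference, sam)
  back <- read_alignments(sam, replicate_id = reads$replicate_id[1])
  ord <- function(df) {
    out <- df[order(df$read_id), c("read_id", "seq_id", "start", "strand",
                                   "bases", "umi", "replicate_id")]
    rownames(out) <- NULL
    out
  }
  expect_equal(ord(back), ord(reads))

  # a deletion-bearing read keeps its offsets through the round trip
  del <- toy_reads("tx001", 5L, "ACGT", umi = "AAAA",
                   replicate_id = "rep01", read_id = "del1",
                   offsets = list(c(5L, 6L, 8L, 9L)))
  del$bases <- paste0(substr(sim$reference[["tx001"]], 6L, 7L),
                      substr(sim$reference[["tx001"]], 9L, 10L))
  sam2 <- tempfile(fileext = ".sam")
  write_sam(del, sim$reference, sam2)
  back2 <- read_alignments(sam2, "rep01")
  expect_equal(back2$offsets[[1]], c(5L, 6L, 8L, 9L))
})

test_that("CLIP mode anchors terminations at the cap, RNA-seq at the TSS", {
  cfg <- sim_config(n_transcripts = 5L, transcript_length = c(400L, 400L),
                    n_replicates = 2L, molecules_per_replicate = 300L,
                    n_modified_sites = 0L, n_snp_het = 0L, n_snp_hom = 0L,
                    n_editing = 0L, n_decoy_clean = 0L, seed = 23L)
  rna <- simulate_dataset(cfg, "rnaseq")
  mic <- simulate_dataset(cfg, "miclip")
  rna_reads <- collapse_duplicates(do.call(rbind, rna$reads))
  mic_reads <- collapse_duplicates(do.call(rbind, mic$reads))
  tp <- termination_profiles(mic_reads, rna_reads, rna$annotations,
                             min_tss_coverage = 5L)
  agg <- tp$aggregate
  rna0 <- agg$mean_fraction[agg$assay == "rnaseq" & agg$offset == 0L]
  mic01 <- sum(agg$mean_fraction[agg$assay == "miclip" & agg$offset <= 1L])
  expect_gt(rna0, 0.9)
  expect_gt(mic01, 0.7)
})
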