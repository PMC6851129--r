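# Shared fixtures and independent oracles for the test suite.

# Construct a read table row by row without going through a SAM file.
toy_reads <- function(seq_id, start, bases, strand = "+", umi = NA,
                      replicate_id = "rep01", read_id = NULL,
                      offsets = NULL) {
  n <- max(length(seq_id), length(start), length(bases))
  if (is.null(read_id)) read_id <- sprintf("r%04d", seq_len(n))
  df <- data.frame(read_id = read_id,
                   seq_id = rep_len(seq_id, n),
                   start = as.integer(rep_len(start, n)),
                   strand = rep_len(strand, n),
                   bases = rep_len(bases, n),
                   umi = as.character(rep_len(umi, n)),
                   replicate_id = rep_len(replicate_id, n),
                   stringsAsFactors = FALSE)
  df$offsets <- if (is.null(offsets)) vector("list", n) else offsets
  df
}

write_toy_sam <- function(lines, seq_lines = "@SQ\tSN:chrT\tLN:1000") {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", seq_lines, lines), path)
  path
}

# Independent brute-force pileup: nested loops over reads and aligned bases,
# reimplementing collapse/clip/mismatch-cap semantics directly.
oracle_pileup <- function(reads, reference, end_clip = 0L, max_mm = 1L,
                          collapse = TRUE, strand_aware = TRUE) {
  seen <- character(0)
  tally <- list()
  for (i in seq_len(nrow(reads))) {
    key <- if (!is.na(reads$umi[i])) {
      paste(reads$seq_id[i], reads$start[i], reads$strand[i], reads$umi[i])
    } else {
      paste(reads$seq_id[i], reads$start[i], reads$strand[i],
            nchar(reads$bases[i]), reads$bases[i])
    }
    if (collapse) {
      if (key %in% seen) next
      seen <- c(seen, key)
    }
    chars <- strsplit(reads$bases[i], "")[[1]]
    off <- reads$offsets[[i]]
    if (is.null(off)) off <- reads$start[i] + seq_along(chars) - 1L
    if (strand_aware && reads$strand[i] == "-") {
      chars <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]
    }
    if (end_clip > 0L) {
      if (length(chars) <= 2L * end_clip) next
      keep <- (end_clip + 1L):(length(chars) - end_clip)
      chars <- chars[keep]; off <- off[keep]
    }
    refchars <- strsplit(reference[[reads$seq_id[i]]], "")[[1]][off + 1L]
    mm <- sum(chars != refchars & chars != "N" & refchars != "N")
    if (mm > max_mm) next
    for (k in seq_along(off)) {
      if (chars[k] == "N" || refchars[k] == "N") next
      id <- paste(reads$seq_id[i], off[k], sep = ":")
      if (is.null(tally[[id]])) {
        tally[[id]] <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      }
      tally[[id]][chars[k]] <- tally[[id]][chars[k]] + 1L
    }
  }
  if (length(tally) == 0L) {
    return(data.frame(seq_id = character(), pos = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer()))
  }
  parts <- strsplit(names(tally), ":")
  out <- data.frame(seq_id = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    A = vapply(tally, `[[`, 0L, "A"),
                    C = vapply(tally, `[[`, 0L, "C"),
                    G = vapply(tally, `[[`, 0L, "G"),
                    T = vapply(tally, `[[`, 0L, "T"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$seq_id, out$pos), , drop = FALSE]
}

# Independent two-sided Fisher p: enumerate all tables with the observed
# margins and sum the probabilities of those no more likely than observed.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  p_of <- function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }
  p_obs <- p_of(a)
  xs <- lo:hi
  ps <- vapply(xs, p_of, numeric(1))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Compact comparison form of a pileup data frame.
pileup_counts <- function(pl) {
  out <- pl[, c("seq_id", "pos", "A", "C", "G", "T")]
  out <- out[order(out$seq_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random gapless read set over a small reference, for property tests.
random_instance <- function(n_reads = 10L, ref_len = 50L, with_umi = TRUE) {
  ref <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
               collapse = "")
  starts <- sample.int(ref_len - 10L, n_reads, replace = TRUE) - 1L
  lens <- pmin(sample(5:15, n_reads, replace = TRUE), ref_len - starts)
  bases <- vapply(seq_len(n_reads), function(i) {
    s <- substr(ref, starts[i] + 1L, starts[i] + lens[i])
    # sprinkle mismatches and Ns
    if (runif(1) < 0.5) {
      at <- sample.int(nchar(s), 1L)
      substr(s, at, at) <- sample(c("A", "C", "G", "T", "N"), 1L)
    }
    s
  }, character(1))
  umi <- if (with_umi) {
    replicate(n_reads, paste(sample(c("A", "C", "G", "T"), 4L,
                                    replace = TRUE), collapse = ""))
  } else NA
  list(reference = c(chrR = ref),
       reads = toy_reads("chrR", starts, bases, umi = umi))
}
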