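# Misincorporation mapping: the depth / rate / replication / heterogeneity
# filter chain over multi-replicate pileups, with variant masking. Hard-stop
# modifications (m1A and relatives) leave reproducible, heterogeneous
# mismatch signatures that this chain separates from sequencing error,
# SNPs and A-to-I editing.

#' Filter configuration for candidate-site calling
#'
#' Defaults follow the published filter chain: at least 500 unique reads
#' combined across replicates, a 1% misincorporation rate, detection in at
#' least half of the replicates, and (for the high-confidence set) at least
#' 5% of misincorporations falling outside the modal mismatch class.
#'
#' @param min_combined_depth Minimum combined read depth across replicates.
#' @param min_rate Minimum combined misincorporation rate.
#' @param min_replicate_fraction Minimum fraction of replicates in which the
#'   site is independently detected.
#' @param min_heterogeneity Minimum minority-mismatch fraction for the
#'   high-confidence flag (rejects single-class signatures such as A-to-I
#'   editing and unmasked heterozygous alleles).
#' @param per_replicate_min_depth Depth gate for per-replicate detection.
#' @param per_replicate_min_rate Rate gate for per-replicate detection.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_combined_depth = 500L, min_rate = 0.01,
                          min_replicate_fraction = 0.5,
                          min_heterogeneity = 0.05,
                          per_replicate_min_depth = 20L,
                          per_replicate_min_rate = 0.01) {
  stopifnot(min_combined_depth >= 1L, per_replicate_min_depth >= 1L,
            min_rate >= 0, min_rate <= 1,
            min_replicate_fraction >= 0, min_replicate_fraction <= 1,
            min_heterogeneity >= 0, min_heterogeneity <= 1,
            per_replicate_min_rate >= 0, per_replicate_min_rate <= 1)
  structure(list(min_combined_depth = as.integer(min_combined_depth),
                 min_rate = min_rate,
                 min_replicate_fraction = min_replicate_fraction,
                 min_heterogeneity = min_heterogeneity,
                 per_replicate_min_depth = as.integer(per_replicate_min_depth),
                 per_replicate_min_rate = per_replicate_min_rate),
            class = "filter_config")
}

# Normalise counts input: named vector or matrix with A/C/G/T columns.
as_count_matrix <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    m <- as.matrix(counts[, BASES, drop = FALSE])
  } else {
    m <- matrix(counts[BASES], nrow = 1L,
                dimnames = list(NULL, BASES))
  }
  m[is.na(m)] <- 0
  storage.mode(m) <- "double"
  m
}

#' Misincorporation rate of a pileup column
#'
#' Fraction of reads at the position whose base differs from the reference.
#'
#' @param counts Named A/C/G/T count vector, or a matrix/data frame with
#'   those columns (vectorised over rows).
#' @param ref_base Reference base per row.
#' @return Numeric misincorporation rate(s) in `[0, 1]`.
#' @export
misincorporation_rate <- function(counts, ref_base) {
  m <- as_count_matrix(counts)
  depth <- rowSums(m)
  if (any(depth == 0))
    stop("misincorporation rate undefined at zero depth")
  refc <- m[cbind(seq_len(nrow(m)), match(ref_base, BASES))]
  unname((depth - refc) / depth)
}

#' Heterogeneity of a misincorporation profile
#'
#' One minus the fraction of mismatches carried by the modal mismatch base:
#' the minority-mismatch fraction. Hard-stop read-through produces mismatches
#' to all three alternative bases even when one dominates, whereas editing
#' and allelic variants produce a single class. Modal ties are broken in
#' fixed base order A < C < G < T; the value is identical under any
#' tie-break because only the modal count enters.
#'
#' @inheritParams misincorporation_rate
#' @return Minority-mismatch fraction(s) in `[0, 1]`.
#' @export
heterogeneity_fraction <- function(counts, ref_base) {
  m <- as_count_matrix(counts)
  m[cbind(seq_len(nrow(m)), match(ref_base, BASES))] <- 0
  total <- rowSums(m)
  if (any(total == 0))
    stop("heterogeneity undefined without mismatched reads")
  unname(1 - apply(m, 1L, max) / total)
}

#' Per-replicate detection gate
#'
#' A replicate detects a site when its own depth and misincorporation rate
#' clear the per-replicate gates. Vectorised.
#'
#' @param depth Per-replicate depth(s) at the position.
#' @param rate Per-replicate misincorporation rate(s).
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
replicate_detects <- function(depth, rate, config = filter_config()) {
  depth >= config$per_replicate_min_depth &
    rate >= config$per_replicate_min_rate
}

#' Call candidate modification sites from multi-replicate pileups
#'
#' Sums counts across replicates at every unmasked position and keeps
#' positions with combined depth, combined misincorporation rate and
#' cross-replicate detection above the configured gates. Each retained site
#' additionally carries a `high_confidence` flag requiring the heterogeneity
#' gate on the combined mismatch profile. Positions in the variant mask and
#' positions whose reference base is `N` are never called.
#'
#' @param pileups List of per-replicate pileup data frames
#'   (see [build_pileup()]).
#' @param mask Variant mask data frame (`seq_id`, `pos`) or `NULL`.
#' @param reference Named character vector of reference sequences.
#' @param config A [filter_config()].
#' @return Data frame of candidate sites sorted by (`seq_id`, `position`),
#'   with combined counts, depth, rate, replicate support, heterogeneity and
#'   the `high_confidence` flag. Attribute `n_replicates` records the number
#'   of replicates interrogated.
#' @export
call_candidate_sites <- function(pileups, mask, reference,
                                 config = filter_config()) {
  stopifnot(length(pileups) >= 1L, inherits(config, "filter_config"))
  n_rep <- length(pileups)
  all_cols <- do.call(rbind, pileups)
  empty <- empty_sites(n_rep)
  if (is.null(all_cols) || nrow(all_cols) == 0L) return(empty)

  key <- paste(all_cols$seq_id, all_cols$pos, sep = "\r")
  first <- !duplicated(key)
  cm <- rowsum(as.matrix(all_cols[, BASES]), key, reorder = FALSE)
  ukey <- key[first]
  stopifnot(identical(rownames(cm), ukey))
  seq_id <- all_cols$seq_id[first]
  pos <- all_cols$pos[first]
  ref <- all_cols$ref[first]

  depth <- rowSums(cm)
  refc <- cm[cbind(seq_len(nrow(cm)), match(ref, BASES))]
  refc[is.na(refc)] <- 0  # ref N: no matching column
  rate <- (depth - refc) / depth

  masked <- if (is.null(mask) || nrow(mask) == 0L) {
    rep(FALSE, length(ukey))
  } else {
    ukey %in% paste(mask$seq_id, mask$pos, sep = "\r")
  }
  keep <- !masked & ref %in% BASES &
    depth >= config$min_combined_depth & rate >= config$min_rate
  if (!any(keep)) return(empty)

  kkey <- ukey[keep]
  det <- integer(length(kkey))
  for (pl in pileups) {
    if (nrow(pl) == 0L) next
    pkey <- paste(pl$seq_id, pl$pos, sep = "\r")
    idx <- match(kkey, pkey)
    hit <- !is.na(idx)
    if (!any(hit)) next
    sub <- pl[idx[hit], , drop = FALSE]
    prate <- misincorporation_rate(sub[, BASES], sub$ref)
    det[hit] <- det[hit] +
      as.integer(replicate_detects(sub$depth, prate, config))
  }
  keep2 <- det / n_rep >= config$min_replicate_fraction
  if (!any(keep2)) return(empty)

  sel <- which(keep)[keep2]
  mism <- cm[sel, , drop = FALSE]
  mism[cbind(seq_len(nrow(mism)), match(ref[sel], BASES))] <- 0
  het <- 1 - apply(mism, 1L, max) / rowSums(mism)

  out <- data.frame(
    seq_id = seq_id[sel], position = pos[sel], ref_base = ref[sel],
    count_A = cm[sel, "A"], count_C = cm[sel, "C"],
    count_G = cm[sel, "G"], count_T = cm[sel, "T"],
    combined_depth = as.integer(depth[sel]),
    combined_rate = rate[sel],
    replicates_detected = det[keep2],
    n_replicates = n_rep,
    heterogeneity = het,
    high_confidence = het >= config$min_heterogeneity,
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$seq_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_replicates") <- n_rep
  out
}

empty_sites <- function(n_replicates) {
  out <- data.frame(seq_id = character(), position = integer(),
                    ref_base = character(),
                    count_A = integer(), count_C = integer(),
                    count_G = integer(), count_T = integer(),
                    combined_depth = integer(), combined_rate = numeric(),
                    replicates_detected = integer(), n_replicates = integer(),
                    heterogeneity = numeric(), high_confidence = logical(),
                    stringsAsFactors = FALSE)
  attr(out, "n_replicates") <- n_replicates
  out
}

#' Estimate the read-through rate at a hard-stop position
#'
#' Truncated cDNAs terminate 3' of a hard stop (their 5' ends sit one past
#' the modification), so coverage is depleted at the site and on its 5'
#' (cap-proximal) side while the 3' flank retains full coverage. The
#' read-through rate is therefore estimated as depth at the site divided by
#' the median depth over the `flank_window` positions immediately 3' of it,
#' clipped to `[0, 1]`. At a full-stoichiometry site this ratio estimates the
#' enzyme's read-through probability.
#'
#' @param pileup A pileup data frame (single replicate or combined; rows for
#'   one replicate set).
#' @param seq_id Sequence the position lies on.
#' @param position 0-based position of the putative hard stop.
#' @param flank_window Number of 3'-flank positions used. Default 20.
#' @param strand Transcript strand; the 3' flank is downstream on `"+"`,
#'   upstream on `"-"`.
#' @return List with `position`, `site_depth`, `flank_depth` (median) and
#'   `readthrough_rate`.
#' @export
estimate_readthrough <- function(pileup, seq_id, position, flank_window = 20L,
                                 strand = "+") {
  rows <- pileup[pileup$seq_id == seq_id, , drop = FALSE]
  site_depth <- sum(rows$depth[rows$pos == position])
  flank_pos <- if (strand == "+") {
    position + seq_len(flank_window)
  } else {
    position - seq_len(flank_window)
  }
  fd <- vapply(flank_pos, function(p) sum(rows$depth[rows$pos == p]),
               numeric(1))
  flank_depth <- stats::median(fd)
  if (!is.finite(flank_depth) || flank_depth <= 0)
    stop("no coverage in the 3' flank of ", seq_id, ":", position + 1L)
  list(position = position,
       site_depth = as.integer(site_depth),
       flank_depth = flank_depth,
       readthrough_rate = min(1, max(0, site_depth / flank_depth)))
}
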