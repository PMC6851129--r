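# Per-replicate pileups: duplicate collapsing, end clipping, a per-read
# mismatch ceiling mirroring the aligner setting, and per-position base
# counting. Columns with zero depth are never materialised.

#' Pileup configuration
#'
#' @param end_clip Aligned bases removed from each read end before counting
#'   (read ends are error-prone). Default 10.
#' @param max_mismatches_per_read Reads with more mismatches against the
#'   reference are discarded entirely, reproducing the alignment-time mismatch
#'   ceiling. Default 1.
#' @param collapse_duplicates Collapse PCR duplicates before counting.
#'   Default `TRUE`.
#' @param strand_aware Complement the contributed bases of minus-strand reads
#'   so counts are in transcript orientation (stranded protocols).
#'   Default `TRUE`.
#' @return A `pileup_config` list.
#' @export
pileup_config <- function(end_clip = 10L, max_mismatches_per_read = 1L,
                          collapse_duplicates = TRUE, strand_aware = TRUE) {
  stopifnot(end_clip >= 0L, max_mismatches_per_read >= 0L)
  structure(list(end_clip = as.integer(end_clip),
                 max_mismatches_per_read = as.integer(max_mismatches_per_read),
                 collapse_duplicates = isTRUE(collapse_duplicates),
                 strand_aware = isTRUE(strand_aware)),
            class = "pileup_config")
}

#' Collapse PCR duplicates
#'
#' When a read carries a UMI, one read is retained per
#' (seq_id, start, strand, UMI); molecules that merely share coordinates are
#' kept apart by their UMIs. Without a UMI, one read is retained per
#' (seq_id, start, strand, read length, base string). The first read in input
#' order wins.
#'
#' @param reads Read table.
#' @return Read table with duplicates removed.
#' @export
collapse_duplicates <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  key <- ifelse(is.na(reads$umi),
                paste(reads$seq_id, reads$start, reads$strand,
                      nchar(reads$bases), reads$bases, sep = "\r"),
                paste(reads$seq_id, reads$start, reads$strand, reads$umi,
                      sep = "\r"))
  out <- reads[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clip aligned bases from both read ends
#'
#' Removes the first and last `end_clip` *aligned* bases of every read. Reads
#' left with no aligned bases are dropped.
#'
#' @param reads Read table.
#' @param end_clip Number of aligned bases to remove from each end.
#' @return Clipped read table.
#' @export
clip_reads <- function(reads, end_clip) {
  end_clip <- as.integer(end_clip)
  if (end_clip == 0L || nrow(reads) == 0L) return(reads)
  n <- nchar(reads$bases)
  keep <- n > 2L * end_clip
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    rownames(out) <- NULL
    return(out)
  }
  n <- n[keep]
  has_off <- !vapply(out$offsets, is.null, logical(1))
  out$bases <- substr(out$bases, end_clip + 1L, n - end_clip)
  out$start <- ifelse(has_off, out$start, out$start + end_clip)
  if (any(has_off)) {
    idx <- which(has_off)
    out$offsets[idx] <- lapply(out$offsets[idx], function(o) {
      o[(end_clip + 1L):(length(o) - end_clip)]
    })
    out$start[idx] <- vapply(out$offsets[idx], `[`, integer(1), 1L)
  }
  rownames(out) <- NULL
  out
}

# Expand a read table into parallel vectors of absolute 0-based positions,
# base characters and originating read index. Fast path for gapless reads.
expand_read_bases <- function(reads) {
  n <- nchar(reads$bases)
  has_off <- vapply(reads$offsets, Negate(is.null), logical(1))
  pos <- vector("list", nrow(reads))
  pos[!has_off] <- lapply(which(!has_off), function(i) {
    reads$start[i] + seq_len(n[i]) - 1L
  })
  pos[has_off] <- reads$offsets[has_off]
  list(pos = unlist(pos, use.names = FALSE),
       base = unlist(strsplit(reads$bases, "", fixed = TRUE),
                     use.names = FALSE),
       read = rep.int(seq_len(nrow(reads)), n))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Build a per-replicate pileup
#'
#' Applies duplicate collapsing, end clipping and the per-read mismatch
#' ceiling, then tallies A/C/G/T at every covered reference position. `N`
#' read bases and positions whose reference base is `N` contribute nothing.
#' Deletions create no count at the deleted position.
#'
#' @param reads Read table for one replicate.
#' @param reference Named character vector of reference sequences.
#' @param config A [pileup_config()].
#' @return Data frame with one row per covered position: `replicate_id`,
#'   `seq_id`, `pos` (0-based), `ref`, `A`, `C`, `G`, `T`, `depth`.
#' @export
build_pileup <- function(reads, reference, config = pileup_config()) {
  stopifnot(inherits(config, "pileup_config"))
  rep_id <- if (nrow(reads)) reads$replicate_id[1] else NA_character_
  if (nrow(reads)) {
    missing_seq <- setdiff(unique(reads$seq_id), names(reference))
    if (length(missing_seq))
      stop("reads aligned to sequences absent from the reference: ",
           paste(missing_seq, collapse = ", "))
  }
  if (config$collapse_duplicates) reads <- collapse_duplicates(reads)
  reads <- clip_reads(reads, config$end_clip)
  if (nrow(reads) == 0L) return(empty_pileup(rep_id))

  if (config$strand_aware && any(reads$strand == "-")) {
    neg <- reads$strand == "-"
    reads$bases[neg] <- chartr("ACGTN", "TGCAN", reads$bases[neg])
  }

  seq_len_tab <- nchar(reference)
  seq_offset <- stats::setNames(cumsum(c(0L, seq_len_tab[-length(seq_len_tab)])),
                                names(reference))
  ref_chars <- unlist(strsplit(unname(reference), "", fixed = TRUE),
                      use.names = FALSE)

  ex <- expand_read_bases(reads)
  read_seq <- reads$seq_id[ex$read]
  over <- ex$pos >= seq_len_tab[read_seq] | ex$pos < 0L
  if (any(over)) {
    bad <- unique(reads$read_id[ex$read[over]])
    stop("read(s) extend past the reference end: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  gpos <- seq_offset[read_seq] + ex$pos
  refb <- ref_chars[gpos + 1L]

  mism <- ex$base != refb & ex$base != "N" & refb != "N"
  mm_per_read <- tabulate(ex$read[mism], nbins = nrow(reads))
  ok_read <- mm_per_read <= config$max_mismatches_per_read
  use <- ok_read[ex$read] & ex$base != "N" & refb != "N"
  if (!any(use)) return(empty_pileup(rep_id))

  gpos <- gpos[use]
  bidx <- match(ex$base[use], BASES)
  total_len <- sum(seq_len_tab)
  code <- gpos * 4L + bidx  # 1-based within 4 slots per position
  counts <- tabulate(code, nbins = total_len * 4L)
  cmat <- matrix(counts, ncol = 4L, byrow = TRUE)
  depth <- as.integer(rowSums(cmat))
  covered <- which(depth > 0L)
  seq_index <- findInterval(covered - 1L, cumsum(c(0L, seq_len_tab)))
  data.frame(
    replicate_id = rep_id,
    seq_id = names(reference)[seq_index],
    pos = as.integer(covered - 1L - seq_offset[seq_index]),
    ref = ref_chars[covered],
    A = cmat[covered, 1L], C = cmat[covered, 2L],
    G = cmat[covered, 3L], T = cmat[covered, 4L],
    depth = depth[covered],
    stringsAsFactors = FALSE, row.names = NULL)
}

empty_pileup <- function(replicate_id = NA_character_) {
  data.frame(replicate_id = character(), seq_id = character(),
             pos = integer(), ref = character(),
             A = integer(), C = integer(), G = integer(), T = integer(),
             depth = integer(), stringsAsFactors = FALSE)
}

#' Write a per-replicate pileup TSV
#' @param pileup Pileup data frame from [build_pileup()].
#' @param path Output path; positions written 1-based.
#' @export
write_pileup <- function(pileup, path) {
  out <- pileup
  out$pos <- out$pos + 1L
  names(out)[names(out) == "pos"] <- "position"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
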