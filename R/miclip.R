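# Truncation-signature analytics for antibody CLIP libraries: reverse
# transcription stops at the antibody-RNA adduct, so read 5' ends pinpoint
# binding sites. Profiles of terminations around transcription-start sites,
# stacked-read cluster calling, a simplified RNA-seq-normalised metagene,
# and start-nucleotide enrichment at TSSs.

# Reads overlapping a single position (span containment; deletion gaps in a
# read are ignored for coverage-at-a-point purposes).
reads_covering <- function(reads, seq_id, position) {
  sel <- reads$seq_id == seq_id
  sum(sel & reads$start <= position & read_span_end(reads) > position)
}

#' Termination profiles around transcription-start sites
#'
#' For every TSS covered by at least `min_tss_coverage` unique reads in both
#' the CLIP and the RNA-seq library, counts read 5' ends (reverse
#' transcription termination sites) at offsets 0..4 from the TSS in
#' transcript orientation. The aggregate gives each TSS equal weight: per-TSS
#' termination fractions are averaged across TSSs and reported with their
#' standard error.
#'
#' @param miclip_reads Deduplicated CLIP read table.
#' @param rnaseq_reads Deduplicated RNA-seq read table.
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param min_tss_coverage Minimum unique-read coverage at the TSS position
#'   in both libraries. Default 5.
#' @return List with `profiles` (long data frame: `transcript_id`, `assay`,
#'   `offset`, `count`, `tss_depth`) and `aggregate` (per assay and offset:
#'   mean per-TSS termination fraction and SEM over `n_tss` sites).
#' @export
termination_profiles <- function(miclip_reads, rnaseq_reads, annotations,
                                 min_tss_coverage = 5L) {
  assays <- list(miclip = miclip_reads, rnaseq = rnaseq_reads)
  five <- lapply(assays, read_five_prime)
  prof <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    cov <- vapply(assays, reads_covering, numeric(1),
                  seq_id = a$seq_id, position = a$tss)
    if (any(cov < min_tss_coverage)) next
    for (nm in names(assays)) {
      rd <- assays[[nm]]
      sel <- rd$seq_id == a$seq_id
      off <- if (a$strand == "+") five[[nm]][sel] - a$tss
             else a$tss - five[[nm]][sel]
      counts <- tabulate(off[off >= 0L & off <= 4L] + 1L, nbins = 5L)
      prof[[length(prof) + 1L]] <- data.frame(
        transcript_id = a$transcript_id, assay = nm, offset = 0:4,
        count = counts, tss_depth = cov[[nm]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(prof) == 0L) {
    warning("no TSS passed the coverage gate in both libraries")
    return(list(profiles = data.frame(transcript_id = character(),
                                      assay = character(), offset = integer(),
                                      count = integer(), tss_depth = integer()),
                aggregate = data.frame(assay = character(), offset = integer(),
                                       mean_fraction = numeric(),
                                       sem = numeric(), n_tss = integer())))
  }
  profiles <- do.call(rbind, prof)
  list(profiles = profiles,
       aggregate = aggregate_termination_fractions(profiles))
}

aggregate_termination_fractions <- function(profiles) {
  out <- list()
  for (nm in unique(profiles$assay)) {
    p <- profiles[profiles$assay == nm, , drop = FALSE]
    wide <- tapply(p$count, list(p$transcript_id, p$offset), sum)
    tot <- rowSums(wide)
    frac <- wide[tot > 0, , drop = FALSE] / tot[tot > 0]
    n <- nrow(frac)
    out[[nm]] <- data.frame(
      assay = nm, offset = 0:4,
      mean_fraction = if (n) colMeans(frac) else rep(NA_real_, 5L),
      sem = if (n > 1) apply(frac, 2L, stats::sd) / sqrt(n)
            else rep(NA_real_, 5L),
      n_tss = n, stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call stacked-read clusters
#'
#' Merges same-strand overlapping reads transitively into maximal intervals
#' and scores each interval by its maximum stacked depth (peak height of
#' overlapping unique reads). Clusters below `min_score` are dropped.
#'
#' @param reads Deduplicated read table.
#' @param min_score Minimum maximum-stack score to retain a cluster.
#'   Default 20.
#' @return Data frame sorted by (`seq_id`, `start`): `seq_id`, `start`,
#'   `end` (0-based half-open), `strand`, `score`.
#' @export
call_clusters <- function(reads, min_score = 20L) {
  if (nrow(reads) == 0L) return(empty_clusters())
  ends <- read_span_end(reads)
  groups <- split(seq_len(nrow(reads)),
                  paste(reads$seq_id, reads$strand, sep = "\r"))
  rows <- lapply(groups, function(idx) {
    ir <- IRanges::IRanges(start = reads$start[idx] + 1L, end = ends[idx])
    merged <- IRanges::reduce(ir)
    cov <- IRanges::coverage(ir)
    data.frame(seq_id = reads$seq_id[idx[1]],
               start = IRanges::start(merged) - 1L,
               end = IRanges::end(merged),
               strand = reads$strand[idx[1]],
               score = as.integer(IRanges::viewMaxs(
                 IRanges::Views(cov, merged))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_clusters <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), score = integer(), stringsAsFactors = FALSE)
}

#' Write clusters as BED6
#' @param clusters Cluster data frame from [call_clusters()].
#' @param path Output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  bed <- data.frame(clusters$seq_id, clusters$start, clusters$end,
                    paste0("cluster_", seq_len(nrow(clusters))),
                    clusters$score, clusters$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Map genomic/transcript positions to metagene bins (0..89). Returns NA for
# positions outside the annotated transcript body.
metagene_bin <- function(seq_id, position, annotations, bins_per_region = 30L) {
  idx <- match(seq_id, annotations$seq_id)
  a <- annotations[idx, , drop = FALSE]
  # transcript-relative coordinate, 5'->3'
  rel <- ifelse(a$strand == "+", position - a$tx_start,
                a$tx_end - 1L - position)
  len5 <- ifelse(a$strand == "+", a$cds_start - a$tx_start,
                 a$tx_end - a$cds_end)
  lenC <- a$cds_end - a$cds_start
  len3 <- ifelse(a$strand == "+", a$tx_end - a$cds_end,
                 a$cds_start - a$tx_start)
  bin <- rep(NA_real_, length(position))
  in5 <- !is.na(rel) & rel >= 0 & rel < len5
  inC <- !is.na(rel) & rel >= len5 & rel < len5 + lenC
  in3 <- !is.na(rel) & rel >= len5 + lenC & rel < len5 + lenC + len3
  bin[in5] <- floor(rel[in5] / len5[in5] * bins_per_region)
  bin[inC] <- bins_per_region +
    floor((rel[inC] - len5[inC]) / lenC[inC] * bins_per_region)
  bin[in3] <- 2L * bins_per_region +
    floor((rel[in3] - len5[in3] - lenC[in3]) / len3[in3] * bins_per_region)
  # transcripts lacking any of the three regions are skipped entirely
  bin[len5 <= 0 | lenC <= 0 | len3 <= 0] <- NA
  as.integer(bin)
}

#' Simplified metagene profile normalised to RNA-seq
#'
#' Each item (cluster or read) is reduced to its midpoint and mapped onto a
#' scaled transcript coordinate: 30 bins each for 5'UTR, CDS and 3'UTR.
#' Per-bin item density is divided by RNA-seq read-midpoint density in the
#' same bin; bins with zero RNA-seq density are reported as `NA` rather than
#' infinite. Transcripts lacking any of the three regions are skipped.
#'
#' @param items Cluster data frame (`seq_id`, `start`, `end`) or read table.
#' @param annotations Annotation data frame.
#' @param rnaseq_reads RNA-seq read table used for normalisation.
#' @param bins_per_region Bins per region. Default 30.
#' @return Data frame with `bin` (0-based), `region`, `item_density`,
#'   `rnaseq_density` and the normalised `value`.
#' @export
metagene <- function(items, annotations, rnaseq_reads, bins_per_region = 30L) {
  n_bins <- 3L * bins_per_region
  region <- rep(c("utr5", "cds", "utr3"), each = bins_per_region)
  mid <- function(df) {
    if ("bases" %in% names(df)) {
      as.integer(floor((df$start + read_span_end(df) - 1L) / 2))
    } else {
      as.integer(floor((df$start + df$end - 1L) / 2))
    }
  }
  item_bin <- if (nrow(items)) {
    metagene_bin(items$seq_id, mid(items), annotations, bins_per_region)
  } else integer(0)
  rna_bin <- metagene_bin(rnaseq_reads$seq_id, mid(rnaseq_reads),
                          annotations, bins_per_region)
  ic <- tabulate(item_bin + 1L, nbins = n_bins)
  rc <- tabulate(rna_bin + 1L, nbins = n_bins)
  item_density <- if (sum(ic)) ic / sum(ic) else rep(0, n_bins)
  rnaseq_density <- if (sum(rc)) rc / sum(rc) else rep(0, n_bins)
  value <- ifelse(rnaseq_density > 0, item_density / rnaseq_density,
                  ifelse(item_density > 0, NA_real_, 0))
  if (sum(ic) == 0L) value <- rep(0, n_bins)
  data.frame(bin = seq_len(n_bins) - 1L, region = region,
             item_count = ic, rnaseq_count = rc,
             item_density = item_density, rnaseq_density = rnaseq_density,
             value = value, stringsAsFactors = FALSE)
}

#' Start-nucleotide enrichment of TSSs overlapping clusters
#'
#' Cross-tabulates transcription-start sites by whether their start
#' nucleotide is adenosine and whether the TSS overlaps a cluster, and tests
#' association with a two-sided Fisher's exact test. The background is the
#' full TSS catalogue.
#'
#' @param clusters Cluster data frame from [call_clusters()].
#' @param annotations Annotation data frame carrying `start_nucleotide`.
#' @return List with the 2x2 `table` (A-start vs not, overlapping vs not),
#'   `fraction_overlap` (A-start fraction among overlapping TSSs),
#'   `fraction_background` (A-start fraction in the catalogue),
#'   `odds_ratio` (sample odds ratio) and `p_value`.
#' @export
tss_start_enrichment <- function(clusters, annotations) {
  overlaps <- vapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    any(clusters$seq_id == a$seq_id & clusters$strand == a$strand &
          clusters$start <= a$tss & clusters$end > a$tss)
  }, logical(1))
  is_a <- annotations$start_nucleotide == "A"
  tab <- matrix(c(sum(is_a & overlaps), sum(is_a & !overlaps),
                  sum(!is_a & overlaps), sum(!is_a & !overlaps)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(start = c("A", "notA"),
                                tss = c("overlap", "background")))
  fraction_overlap <- if (sum(tab[, "overlap"]) > 0)
    tab["A", "overlap"] / sum(tab[, "overlap"]) else 0
  fraction_background <- if (sum(tab) > 0) sum(tab["A", ]) / sum(tab) else 0
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warning("degenerate 2x2 margins; p-value set to 1")
    p <- 1
    or <- NA_real_
  } else {
    p <- fisher_exact_p(tab)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  list(table = tab, fraction_overlap = fraction_overlap,
       fraction_background = fraction_background,
       odds_ratio = or, p_value = p)
}

# Two-sided Fisher exact p for a 2x2 table.
fisher_exact_p <- function(tab) {
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}
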