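# Curation of externally published modification-site lists: defect filtering
# (missing gene identifiers, non-adenosine positions, isoform duplicates)
# and overlap accounting against annotated and experimentally inferred
# transcription-start sites.

#' Curate a putative modification-site list
#'
#' Filters are applied in a fixed order: (1) drop records whose gene
#' identifier is missing or absent from `valid_gene_ids`; (2) drop records
#' whose nucleotide is not adenosine; (3) among survivors, drop every record
#' after the first at each genomic coordinate (isoform duplicates). Tallies
#' reflect this order.
#'
#' @param records Site data frame with columns `site_id`, `gene_id`,
#'   `seq_id`, `genomic_position` (0-based), `nucleotide`, `transcript_id`.
#' @param valid_gene_ids Character vector of accepted gene identifiers.
#' @return A `curation_report` list: `n_input`, `n_missing_gene`,
#'   `n_non_adenosine`, `n_duplicate`, `n_removed`, `n_kept`, and the `kept`
#'   site data frame.
#' @export
curate <- function(records, valid_gene_ids) {
  n_input <- nrow(records)
  if (n_input == 0L) {
    return(structure(list(n_input = 0L, n_missing_gene = 0L,
                          n_non_adenosine = 0L, n_duplicate = 0L,
                          n_removed = 0L, n_kept = 0L,
                          kept = records),
                     class = "curation_report"))
  }
  bad_gene <- is.na(records$gene_id) | records$gene_id == "" |
    !(records$gene_id %in% valid_gene_ids)
  r1 <- records[!bad_gene, , drop = FALSE]
  not_a <- toupper(r1$nucleotide) != "A"
  r2 <- r1[!not_a, , drop = FALSE]
  dup <- duplicated(paste(r2$seq_id, r2$genomic_position, sep = "\r"))
  kept <- r2[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  n_removed <- sum(bad_gene) + sum(not_a) + sum(dup)
  structure(list(n_input = n_input,
                 n_missing_gene = sum(bad_gene),
                 n_non_adenosine = sum(not_a),
                 n_duplicate = sum(dup),
                 n_removed = as.integer(n_removed),
                 n_kept = nrow(kept),
                 kept = kept),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Site curation report\n",
      "  input records:      ", x$n_input, "\n",
      "  missing/bad gene:   ", x$n_missing_gene, "\n",
      "  non-adenosine:      ", x$n_non_adenosine, "\n",
      "  coordinate dups:    ", x$n_duplicate, "\n",
      "  removed:            ", x$n_removed, "\n",
      "  kept:               ", x$n_kept, "\n", sep = "")
  invisible(x)
}

# Membership of site coordinates in a TSS position set within a tolerance.
sites_near_set <- function(sites, tss_set, tolerance = 0L) {
  if (is.null(tss_set) || nrow(tss_set) == 0L || nrow(sites) == 0L)
    return(rep(FALSE, nrow(sites)))
  if (tolerance == 0L) {
    paste(sites$seq_id, sites$genomic_position, sep = "\r") %in%
      paste(tss_set$seq_id, tss_set$pos, sep = "\r")
  } else {
    by_seq <- split(tss_set$pos, tss_set$seq_id)
    vapply(seq_len(nrow(sites)), function(i) {
      p <- by_seq[[sites$seq_id[i]]]
      !is.null(p) && any(abs(p - sites$genomic_position[i]) <= tolerance)
    }, logical(1))
  }
}

#' Overlap curated sites with transcription-start-site catalogues
#'
#' Counts how many curated sites coincide (within `tolerance` nucleotides)
#' with annotated TSSs, with CAGE/m6Am-inferred TSSs, and with the union of
#' the two; the remainder are internal sites.
#'
#' @param kept Curated site data frame (see [curate()]).
#' @param annotated_tss Data frame (`seq_id`, `pos`) of annotated TSSs.
#' @param cage_m6am_tss Data frame (`seq_id`, `pos`) of experimentally
#'   inferred TSSs (CAGE-seq / m6Am extended caps).
#' @param tolerance Maximum distance (nt) counted as an overlap. Default 0
#'   (exact position).
#' @return A `tss_overlap_report` list: `n_sites`, `n_annotated_tss`,
#'   `n_cage_m6am`, `n_union`, `n_internal`.
#' @export
tss_overlap <- function(kept, annotated_tss, cage_m6am_tss, tolerance = 0L) {
  in_ann <- sites_near_set(kept, annotated_tss, tolerance)
  in_cage <- sites_near_set(kept, cage_m6am_tss, tolerance)
  structure(list(n_sites = nrow(kept),
                 n_annotated_tss = sum(in_ann),
                 n_cage_m6am = sum(in_cage),
                 n_union = sum(in_ann | in_cage),
                 n_internal = nrow(kept) - sum(in_ann | in_cage)),
            class = "tss_overlap_report")
}

#' @export
print.tss_overlap_report <- function(x, ...) {
  cat("TSS overlap report\n",
      "  sites:                 ", x$n_sites, "\n",
      "  at annotated TSS:      ", x$n_annotated_tss, "\n",
      "  at CAGE/m6Am TSS:      ", x$n_cage_m6am, "\n",
      "  at any TSS (union):    ", x$n_union, "\n",
      "  internal:              ", x$n_internal, "\n", sep = "")
  invisible(x)
}

#' Build the canonical synthetic curation fixture
#'
#' Deterministically constructs a 474-record site list with the defect
#' structure of a published external catalogue: 3 records with retired or
#' missing gene identifiers, 37 records at non-adenosine nucleotides, and 82
#' isoform duplicates of surviving coordinates, leaving 352 unique
#' adenosine sites. The defect categories are disjoint by construction, so
#' the tallies are robust to filter order. Companion TSS catalogues place 19
#' kept sites at annotated TSSs and 134 at CAGE/m6Am TSSs with an overlap of
#' 13, i.e. 140 sites at a transcription start by either evidence class.
#' All coordinates are synthetic.
#'
#' @return List with `records`, `valid_gene_ids`, `annotated_tss`,
#'   `cage_m6am_tss`.
#' @export
make_curation_fixture <- function() {
  n_kept <- 352L
  kept_pos <- 1000L + 10L * seq_len(n_kept)
  kept_gene <- sprintf("GENE%04d", seq_len(n_kept))
  kept <- data.frame(
    site_id = sprintf("site_%04d", seq_len(n_kept)),
    gene_id = kept_gene,
    seq_id = "chr1",
    genomic_position = kept_pos,
    nucleotide = "A",
    transcript_id = sprintf("GENE%04d-201", seq_len(n_kept)),
    stringsAsFactors = FALSE)

  bad_gene <- data.frame(
    site_id = sprintf("site_%04d", n_kept + 1:3),
    gene_id = c(NA, "RETIRED0001", "RETIRED0002"),
    seq_id = "chr1",
    genomic_position = 90000L + 10L * (1:3),
    nucleotide = "A",
    transcript_id = sprintf("RET%04d-201", 1:3),
    stringsAsFactors = FALSE)

  non_a <- data.frame(
    site_id = sprintf("site_%04d", n_kept + 3L + seq_len(37L)),
    gene_id = sprintf("GENE%04d", 400L + seq_len(37L)),
    seq_id = "chr1",
    genomic_position = 95000L + 10L * seq_len(37L),
    nucleotide = rep(c("C", "G", "T"), length.out = 37L),
    transcript_id = sprintf("GENE%04d-201", 400L + seq_len(37L)),
    stringsAsFactors = FALSE)

  dup_src <- seq_len(82L)  # duplicate the first 82 kept coordinates
  dups <- kept[dup_src, , drop = FALSE]
  dups$site_id <- sprintf("site_%04d", n_kept + 40L + seq_len(82L))
  dups$transcript_id <- sprintf("GENE%04d-202", dup_src)

  records <- rbind(kept, bad_gene, non_a, dups)
  # deterministic interleave so defect classes are not contiguous in input
  ord <- order((seq_len(nrow(records)) * 7L) %% nrow(records),
               seq_len(nrow(records)))
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  valid_gene_ids <- unique(c(kept_gene, non_a$gene_id))

  # TSS catalogues: annotated = kept sites 1..19; CAGE/m6Am = kept sites
  # 7..140; intersection 7..19 (13 sites); union 1..140 (140 sites).
  annotated_tss <- data.frame(seq_id = "chr1", pos = kept_pos[1:19],
                              stringsAsFactors = FALSE)
  cage_m6am_tss <- data.frame(seq_id = "chr1", pos = kept_pos[7:140],
                              stringsAsFactors = FALSE)
  # background TSS positions not at any site, as in a realistic catalogue
  annotated_tss <- rbind(annotated_tss,
                         data.frame(seq_id = "chr1",
                                    pos = 200000L + 50L * (1:30)))
  cage_m6am_tss <- rbind(cage_m6am_tss,
                         data.frame(seq_id = "chr1",
                                    pos = 300000L + 50L * (1:30)))

  list(records = records, valid_gene_ids = valid_gene_ids,
       annotated_tss = annotated_tss, cage_m6am_tss = cage_m6am_tss)
}

#' Read a site list TSV
#'
#' Tab-separated with header and the columns of [curate()]'s input;
#' `genomic_position` is 1-based on disk and converted to 0-based.
#' @param path TSV path.
#' @return Site data frame.
#' @export
read_site_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE,
                          colClasses = c(seq_id = "character"))
  df$genomic_position <- as.integer(df$genomic_position - 1L)
  df
}

#' Write a site list TSV (1-based positions on disk)
#' @param records Site data frame.
#' @param path Output path.
#' @export
write_site_list <- function(records, path) {
  out <- records
  out$genomic_position <- out$genomic_position + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
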