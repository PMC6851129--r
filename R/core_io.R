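# Readers/writers for the standard formats the pipeline touches, plus
# conversion into the internal coordinate convention: 0-based, half-open
# everywhere in memory; SAM/VCF are converted on read, TSV output is 1-based.

BASES <- c("A", "C", "G", "T")

#' Read a reference FASTA
#'
#' Loads all records of a FASTA file and returns the sequences uppercased.
#' Misincorporations are defined against these sequences, so lowercase
#' (soft-masked) characters are normalised on input. `N` is permitted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA string per record.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  dss <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dss) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(dss))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(dss))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA: ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in FASTA record(s): ",
                     paste(names(seqs)[bad], collapse = ", "))
  seqs
}

# Internal read table constructor. `offsets` holds absolute 0-based reference
# positions for each aligned base, but is left NULL for gapless reads (the
# overwhelmingly common case) so that pileup construction can stay vectorised.
new_reads <- function(read_id, seq_id, start, strand, bases, umi,
                      replicate_id, offsets = NULL) {
  n <- length(read_id)
  if (is.null(offsets)) offsets <- vector("list", n)
  df <- data.frame(read_id = as.character(read_id),
                   seq_id = as.character(seq_id),
                   start = as.integer(start),
                   strand = as.character(strand),
                   bases = as.character(bases),
                   umi = as.character(umi),
                   replicate_id = as.character(replicate_id),
                   stringsAsFactors = FALSE)
  df$offsets <- offsets
  df
}

empty_reads <- function() {
  new_reads(character(), character(), integer(), character(), character(),
            character(), character())
}

# 0-based position one past the last aligned base of each read.
read_span_end <- function(reads) {
  end <- reads$start + nchar(reads$bases)
  has_off <- !vapply(reads$offsets, is.null, logical(1))
  if (any(has_off)) {
    end[has_off] <- vapply(reads$offsets[has_off],
                           function(o) max(o) + 1L, integer(1))
  }
  as.integer(end)
}

# 5' end of each read in reference coordinates (strand-aware).
read_five_prime <- function(reads) {
  ends <- read_span_end(reads)
  ifelse(reads$strand == "-", ends - 1L, reads$start)
}

#' Read aligned reads from a SAM file
#'
#' Parses one replicate's alignments. Unmapped, secondary and supplementary
#' records are skipped. Per-base reference offsets are derived from the CIGAR
#' string (M/=/X consume read and reference, I/S consume read only, D/N
#' consume reference only, H/P consume neither). A UMI carried as a read-name
#' suffix (after `umi_delim`) is split off into its own field.
#'
#' @param path Path to a SAM file with a header.
#' @param replicate_id Label attached to every read from this file.
#' @param umi_delim Delimiter separating the UMI from the read name; set to
#'   `NA` to disable UMI extraction. Default `"_"`.
#' @return A read table (data frame) with columns `read_id`, `seq_id`,
#'   `start` (0-based), `strand`, `bases`, `umi`, `replicate_id`, `offsets`.
#' @export
read_alignments <- function(path, replicate_id, umi_delim = "_") {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  # htslib silently downgrades records whose RNAME is missing from the
  # header to unmapped; treat that as the input error it is
  txt <- readLines(path)
  is_hdr <- startsWith(txt, "@")
  sq <- sub(".*\tSN:([^\t]+).*", "\\1", grep("^@SQ\t", txt, value = TRUE))
  rnames <- unique(vapply(strsplit(txt[!is_hdr], "\t", fixed = TRUE),
                          function(f) f[3], character(1)))
  bad <- setdiff(rnames, c(sq, "*"))
  if (length(bad))
    stop("reference name(s) absent from SAM header: ",
         paste(bad, collapse = ", "))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "strand"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos) &
    bitwAnd(rec$flag, 0x4) == 0L &    # unmapped
    bitwAnd(rec$flag, 0x100) == 0L &  # secondary
    bitwAnd(rec$flag, 0x800) == 0L    # supplementary
  if (!any(keep)) return(empty_reads())
  qname <- rec$qname[keep]
  seq_id <- as.character(rec$rname[keep])
  pos0 <- rec$pos[keep] - 1L
  cigar <- rec$cigar[keep]
  seqs <- as.character(rec$seq[keep])
  strand <- as.character(rec$strand[keep])

  parsed <- lapply(seq_along(cigar), function(i) {
    expand_cigar(cigar[i], pos0[i], seqs[i])
  })
  bases <- vapply(parsed, `[[`, character(1), "bases")
  offsets <- lapply(parsed, function(p) if (p$gapless) NULL else p$offsets)
  starts <- vapply(parsed, `[[`, integer(1), "start")

  umi <- rep(NA_character_, length(qname))
  read_id <- qname
  if (!is.na(umi_delim)) {
    has <- grepl(umi_delim, qname, fixed = TRUE)
    pat <- paste0("^(.*)", umi_delim, "([^", umi_delim, "]*)$")
    read_id[has] <- sub(pat, "\\1", qname[has])
    umi[has] <- sub(pat, "\\2", qname[has])
  }
  new_reads(read_id, seq_id, starts, strand, bases, umi, replicate_id, offsets)
}

# Expand one CIGAR string into aligned bases and absolute reference offsets.
expand_cigar <- function(cigar, pos0, seq) {
  if (is.na(cigar) || cigar == "*") stop("alignment without CIGAR string")
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("invalid CIGAR: ", cigar)
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^\\d+", "", toks)
  ref <- pos0
  qry <- 0L
  off <- integer(0)
  qidx <- integer(0)
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      off <- c(off, ref + seq_len(len) - 1L)
      qidx <- c(qidx, qry + seq_len(len))
      ref <- ref + len; qry <- qry + len
    } else if (op %in% c("I", "S")) {
      qry <- qry + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    } # H, P consume neither
  }
  if (length(off) == 0L) stop("CIGAR aligns no bases: ", cigar)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]][qidx]
  gapless <- all(diff(off) == 1L)
  list(start = off[1], bases = paste(chars, collapse = ""),
       offsets = off, gapless = gapless)
}

#' Read a variant mask from VCF and/or BED files
#'
#' Builds the set of positions to exclude from misincorporation calling
#' (genomic variants, dbSNP-style SNP annotations). VCF positions are 1-based
#' and converted; multi-nucleotide REF alleles expand to every covered
#' position. BED intervals are 0-based half-open and expanded. The result is
#' the set union over all inputs.
#'
#' @param paths Character vector of VCF (`.vcf`) and/or BED file paths.
#' @return Data frame with columns `seq_id`, `pos` (0-based), one row per
#'   masked position, sorted and unique.
#' @export
read_variant_mask <- function(paths) {
  pieces <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("mask file not found: ", p)
    if (grepl("\\.vcf(\\.gz)?$", p, ignore.case = TRUE)) {
      v <- suppressWarnings(vcfR::read.vcfR(p, verbose = FALSE))
      fix <- vcfR::getFIX(v)
      if (is.null(fix) || nrow(fix) == 0L)
        return(data.frame(seq_id = character(), pos = integer()))
      pos1 <- as.integer(fix[, "POS"])
      reflen <- pmax(1L, nchar(ifelse(is.na(fix[, "REF"]), "N", fix[, "REF"])))
      data.frame(
        seq_id = rep(fix[, "CHROM"], reflen),
        pos = unlist(Map(function(p0, w) p0 + seq_len(w) - 1L,
                         pos1 - 1L, reflen)),
        stringsAsFactors = FALSE)
    } else {
      bed <- utils::read.table(p, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
      if (nrow(bed) == 0L)
        return(data.frame(seq_id = character(), pos = integer()))
      widths <- bed[[3]] - bed[[2]]
      data.frame(
        seq_id = rep(bed[[1]], widths),
        pos = unlist(Map(function(s, e) seq.int(s, e - 1L), bed[[2]], bed[[3]])),
        stringsAsFactors = FALSE)
    }
  })
  mask <- do.call(rbind, c(pieces,
                           list(data.frame(seq_id = character(),
                                           pos = integer()))))
  mask <- unique(mask)
  mask <- mask[order(mask$seq_id, mask$pos), , drop = FALSE]
  rownames(mask) <- NULL
  mask$pos <- as.integer(mask$pos)
  mask
}

#' Write candidate sites to TSV (and optionally BED6)
#'
#' Positions are written 1-based. The optional BED6 track scores each site as
#' `round(1000 * combined rate)`.
#'
#' @param sites Candidate-site data frame from [call_candidate_sites()].
#' @param path Output TSV path.
#' @param bed_path Optional BED6 output path.
#' @export
write_sites <- function(sites, path, bed_path = NULL) {
  out <- data.frame(
    seq_id = sites$seq_id,
    position = sites$position + 1L,
    ref_base = sites$ref_base,
    combined_depth = sites$combined_depth,
    combined_rate = sites$combined_rate,
    replicates_detected = sites$replicates_detected,
    n_replicates = sites$n_replicates,
    heterogeneity = sites$heterogeneity,
    count_A = sites$count_A, count_C = sites$count_C,
    count_G = sites$count_G, count_T = sites$count_T,
    high_confidence = sites$high_confidence,
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write sites to '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  if (!is.null(bed_path)) {
    bed <- data.frame(sites$seq_id, sites$position,
                      sites$position + 1L,
                      paste0("site_", seq_len(nrow(sites))),
                      round(1000 * sites$combined_rate), "+")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a candidate-site TSV written by [write_sites()]
#'
#' @param path TSV path.
#' @return Candidate-site data frame with 0-based `position`.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(seq_id = "character"))
  df$position <- as.integer(df$position - 1L)
  df
}

#' Write aligned reads as SAM
#'
#' Emits a minimal single-end SAM file (used by the simulator). The UMI, when
#' present, is appended to the read name after `umi_delim`, mirroring CLIP
#' pipelines that move the random barcode into the sequence header.
#'
#' @param reads Read table.
#' @param reference Named character vector of reference sequences (for the
#'   `@SQ` header lines).
#' @param path Output SAM path.
#' @param umi_delim Delimiter used to append the UMI to the read name.
#' @export
write_sam <- function(reads, reference, path, umi_delim = "_") {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(reference), "\tLN:", nchar(reference)))
  qname <- ifelse(is.na(reads$umi), reads$read_id,
                  paste(reads$read_id, reads$umi, sep = umi_delim))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  has_off <- !vapply(reads$offsets, is.null, logical(1))
  cigar <- paste0(nchar(reads$bases), "M")
  if (any(has_off)) {
    cigar[has_off] <- vapply(which(has_off), function(i) {
      offsets_to_cigar(reads$offsets[[i]])
    }, character(1))
  }
  lines <- paste(qname, flag, reads$seq_id, reads$start + 1L, 255L, cigar,
                 "*", 0L, 0L, reads$bases,
                 strrep("I", nchar(reads$bases)), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# Deletion-style CIGAR for reads whose aligned offsets are not contiguous.
offsets_to_cigar <- function(off) {
  gaps <- diff(off)
  cig <- character(0)
  run_len <- 1L
  for (k in seq_along(gaps)) {
    if (gaps[k] == 1L) {
      run_len <- run_len + 1L
    } else {
      cig <- c(cig, paste0(run_len, "M"), paste0(gaps[k] - 1L, "D"))
      run_len <- 1L
    }
  }
  paste0(paste(cig, collapse = ""), run_len, "M")
}

#' Read a transcript annotation table
#'
#' Tab-separated with header; columns `transcript_id`, `seq_id`, `strand`,
#' `tx_start`, `tx_end`, `cds_start`, `cds_end`, `tss`, `start_nucleotide`,
#' `tss_categories` (comma-separated subset of refseq, cage, m6am). All
#' coordinates 0-based, intervals half-open; `tss` equals `tx_start` on the
#' plus strand and `tx_end - 1` on the minus strand.
#'
#' @param path TSV path.
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(seq_id = "character"))
  validate_annotations(ann)
  ann
}

#' Write a transcript annotation table
#' @param annotations Annotation data frame.
#' @param path Output TSV path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_annotations <- function(ann) {
  stopifnot(all(c("transcript_id", "seq_id", "strand", "tx_start", "tx_end",
                  "cds_start", "cds_end", "tss", "start_nucleotide") %in%
                  names(ann)))
  with(ann, {
    if (any(!(tx_start <= cds_start & cds_start < cds_end & cds_end <= tx_end)))
      stop("annotation intervals violate tx_start <= cds_start < cds_end <= tx_end")
    tss_exp <- ifelse(strand == "+", tx_start, tx_end - 1L)
    if (any(tss != tss_exp))
      stop("tss must equal tx_start (+ strand) or tx_end - 1 (- strand)")
  })
  invisible(ann)
}
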