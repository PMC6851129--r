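# Seeded read simulator. Models the generative process behind hard-stop
# misincorporation data: transcripts are fragmented into ~250 nt pieces,
# cDNA synthesis proceeds 3'->5' and, on meeting a modified base on a
# modified molecule, either terminates (truncated cDNAs are retained — they
# are cloned in both protocols) or reads through with a misincorporation
# drawn from a base spectrum. Uniform sequencing error, per-fragment UMIs,
# PCR duplication, SNP and A->G editing decoys, and an antibody-crosslink
# mode for CLIP libraries are included so every analysis stage can be
# exercised against a known truth set.

#' Simulation configuration
#'
#' Defaults describe a stranded short-read library: 50 nt reads from ~250 nt
#' fragments, 20 replicates, modification stoichiometry 0.2, read-through
#' probability 0.25 with misincorporation probability 0.9 and an A->T
#' dominated spectrum (0.8/0.1/0.1), and uniform sequencing error 1e-3.
#'
#' @param n_transcripts Number of transcripts (each its own reference
#'   sequence).
#' @param transcript_length Integer range `c(min, max)`; minimum 300.
#' @param n_replicates Number of biological replicates. Default 20.
#' @param molecules_per_replicate RNA molecules sampled per replicate.
#' @param read_length Read length in nt. Default 50.
#' @param fragment_mean Mean fragment (insert) length. Default 250.
#' @param stoichiometry Fraction of molecules modified at a planted site;
#'   recycled over sites. Default 0.2.
#' @param readthrough Probability the reverse transcriptase traverses a
#'   modified position instead of terminating. Default 0.25.
#' @param misinc_given_readthrough Probability a read-through event leaves a
#'   misincorporation. Default 0.9.
#' @param spectrum Named weights over the three non-reference bases at an
#'   adenosine site. Default `c(T = 0.8, G = 0.1, C = 0.1)`.
#' @param seq_error Per-base uniform sequencing error rate. Default 0.001.
#' @param pcr_dup_rate Probability a fragment gains one PCR duplicate
#'   (shared UMI, fresh read id). Default 0.1.
#' @param n_modified_sites Planted modification sites (adenosines).
#' @param n_snp_het,n_snp_hom Heterozygous / homozygous SNP decoys.
#' @param n_editing Homogeneous A->G editing decoys.
#' @param editing_rate Per-molecule editing probability at a decoy.
#' @param n_decoy_clean Error-only adenosine positions recorded in the truth
#'   set for false-positive accounting.
#' @param a_start_fraction Fraction of transcripts forced to start with A
#'   (Initiator-style). Default 0.85.
#' @param crosslink_rate In CLIP mode, probability a molecule carries an
#'   antibody adduct at its cap. Default 0.9.
#' @param crosslink_offsets Mixture weights over termination offsets 0..4
#'   from the TSS for crosslinked molecules.
#' @param miclip_background In CLIP mode, retention probability of
#'   non-crosslinked fragments (wash-through background). Default 0.05.
#' @param dimroth_loss Optional stoichiometry loss modelling heat/base
#'   conversion of the modification during library preparation. Default 0.
#' @param truth_placement `"interior"` places truth sites anywhere in the
#'   transcript body (margin 60 nt from the ends); `"five_prime"` places
#'   modification and editing sites in the 5'-proximal window that
#'   truncation-anchored reads cover most deeply (offsets 14-36 from the
#'   TSS), matching the TSS-proximal question the method addresses. SNP
#'   decoys always go to the transcript body.
#' @param seed Integer seed fixing all outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 2L,
                       transcript_length = c(400L, 600L),
                       n_replicates = 20L,
                       molecules_per_replicate = 500L,
                       read_length = 50L,
                       fragment_mean = 250L,
                       stoichiometry = 0.2,
                       readthrough = 0.25,
                       misinc_given_readthrough = 0.9,
                       spectrum = c(T = 0.8, G = 0.1, C = 0.1),
                       seq_error = 0.001,
                       pcr_dup_rate = 0.1,
                       n_modified_sites = 2L,
                       n_snp_het = 1L,
                       n_snp_hom = 1L,
                       n_editing = 1L,
                       editing_rate = 0.2,
                       n_decoy_clean = 20L,
                       a_start_fraction = 0.85,
                       crosslink_rate = 0.9,
                       crosslink_offsets = c(0.45, 0.40, 0.07, 0.05, 0.03),
                       miclip_background = 0.05,
                       dimroth_loss = 0,
                       truth_placement = c("interior", "five_prime"),
                       seed = 1L) {
  truth_placement <- match.arg(truth_placement)
  stopifnot(length(transcript_length) == 2L,
            transcript_length[1] >= 300L,
            transcript_length[1] <= transcript_length[2],
            read_length > 0L, fragment_mean >= read_length,
            all(stoichiometry >= 0 & stoichiometry <= 1),
            readthrough >= 0, readthrough <= 1,
            misinc_given_readthrough >= 0, misinc_given_readthrough <= 1,
            abs(sum(spectrum) - 1) < 1e-8,
            seq_error >= 0, seq_error <= 1,
            pcr_dup_rate >= 0, pcr_dup_rate <= 1,
            editing_rate >= 0, editing_rate <= 1,
            a_start_fraction >= 0, a_start_fraction <= 1,
            crosslink_rate >= 0, crosslink_rate <= 1,
            length(crosslink_offsets) == 5L,
            dimroth_loss >= 0, dimroth_loss < 1)
  if (transcript_length[1] < fragment_mean)
    stop("transcript_length minimum must be at least fragment_mean")
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    n_replicates = as.integer(n_replicates),
    molecules_per_replicate = as.integer(molecules_per_replicate),
    read_length = as.integer(read_length),
    fragment_mean = as.integer(fragment_mean),
    stoichiometry = stoichiometry,
    readthrough = readthrough,
    misinc_given_readthrough = misinc_given_readthrough,
    spectrum = spectrum,
    seq_error = seq_error,
    pcr_dup_rate = pcr_dup_rate,
    n_modified_sites = as.integer(n_modified_sites),
    n_snp_het = as.integer(n_snp_het),
    n_snp_hom = as.integer(n_snp_hom),
    n_editing = as.integer(n_editing),
    editing_rate = editing_rate,
    n_decoy_clean = as.integer(n_decoy_clean),
    a_start_fraction = a_start_fraction,
    crosslink_rate = crosslink_rate,
    crosslink_offsets = crosslink_offsets / sum(crosslink_offsets),
    miclip_background = miclip_background,
    dimroth_loss = dimroth_loss,
    truth_placement = truth_placement,
    seed = as.integer(seed)), class = "sim_config")
}

#' Closed-form mismatch rate at a hard-stop site
#'
#' Among reads that cover a modified position (truncated cDNAs stop one base
#' 3' of it and therefore do not cover it), the expected mismatch fraction is
#' `s * r * m / (s * r + (1 - s))` for stoichiometry `s`, read-through
#' probability `r` and misincorporation-given-read-through `m`.
#'
#' @param s Stoichiometry in `[0, 1]`.
#' @param r Read-through probability in `[0, 1]`.
#' @param m Misincorporation probability given read-through in `[0, 1]`.
#' @return Expected mismatch fraction among covering reads.
#' @export
expected_mismatch_rate <- function(s, r, m) {
  stopifnot(all(s >= 0 & s <= 1), all(r >= 0 & r <= 1),
            all(m >= 0 & m <= 1))
  denom <- s * r + (1 - s)
  if (any(denom <= 0))
    stop("degenerate: no read ever covers the site (s = 1, r = 0)")
  s * r * m / denom
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a reference, annotations and truth set
#'
#' Generates random transcript sequences (one reference sequence per
#' transcript, plus strand, TSS at position 0), annotations with 5'UTR/CDS/
#' 3'UTR boundaries, and a truth set of planted modification sites,
#' SNP decoys, editing decoys, crosslink positions and clean error-only
#' adenosines. All truth categories occupy disjoint positions in the
#' transcript interior.
#'
#' @param config A [sim_config()].
#' @return List with `reference` (named character), `annotations`, `truth`
#'   (lists `sites`, `snps`, `editing`, `crosslinks`, `clean_a`) and the
#'   `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_tx <- config$n_transcripts
  lens <- if (config$transcript_length[1] == config$transcript_length[2]) {
    rep(config$transcript_length[1], n_tx)
  } else {
    sample(seq(config$transcript_length[1], config$transcript_length[2]),
           n_tx, replace = TRUE)
  }
  seq_ids <- sprintf("tx%03d", seq_len(n_tx))
  seqs <- vapply(lens, random_dna, character(1))
  a_start <- stats::runif(n_tx) < config$a_start_fraction
  substr(seqs[a_start], 1L, 1L) <- "A"
  names(seqs) <- seq_ids

  annotations <- data.frame(
    transcript_id = seq_ids, seq_id = seq_ids, strand = "+",
    tx_start = 0L, tx_end = lens,
    cds_start = as.integer(round(0.2 * lens)),
    cds_end = as.integer(round(0.7 * lens)),
    tss = 0L,
    start_nucleotide = substr(seqs, 1L, 1L),
    tss_categories = "refseq",
    stringsAsFactors = FALSE)

  # interior positions, clear of read ends and the TSS neighbourhood
  margin <- 60L
  used <- lapply(stats::setNames(vector("list", n_tx), seq_ids),
                 function(x) integer(0))
  draw_positions <- function(n_total, want_a, tx_pool = seq_len(n_tx)) {
    out <- data.frame(seq_id = character(), pos = integer())
    if (n_total == 0L) return(out)
    tx_of <- rep(tx_pool, length.out = n_total)
    for (k in seq_len(n_total)) {
      t <- tx_of[k]
      chars <- strsplit(seqs[[t]], "", fixed = TRUE)[[1]]
      cand <- seq.int(margin, lens[t] - margin - 1L)
      if (want_a) cand <- cand[chars[cand + 1L] == "A"]
      cand <- setdiff(cand, used[[seq_ids[t]]])
      if (length(cand) == 0L) stop("transcript too short to place truth sites")
      p <- cand[sample.int(length(cand), 1L)]
      used[[seq_ids[t]]] <<- c(used[[seq_ids[t]]], p)
      out <- rbind(out, data.frame(seq_id = seq_ids[t], pos = p,
                                   stringsAsFactors = FALSE))
    }
    out
  }
  # five_prime mode: evenly spaced slots in the deeply covered window just
  # past the clipped read start; planted bases are forced to adenosine
  place_window <- function(n_total, tx_pool, window = c(14L, 36L)) {
    out <- data.frame(seq_id = character(), pos = integer())
    if (n_total == 0L) return(out)
    tx_of <- sort(rep(tx_pool, length.out = n_total))
    for (t in unique(tx_of)) {
      k <- sum(tx_of == t)
      avail <- setdiff(seq.int(window[1], window[2]), used[[seq_ids[t]]])
      if (length(avail) < k) stop("5' window exhausted on ", seq_ids[t])
      slots <- avail[unique(as.integer(round(
        seq(1L, length(avail), length.out = k))))]
      if (length(slots) < k) slots <- avail[seq_len(k)]
      for (p in slots) {
        seqs[t] <<- `substr<-`(seqs[t], p + 1L, p + 1L, "A")
        used[[seq_ids[t]]] <<- c(used[[seq_ids[t]]], p)
      }
      out <- rbind(out, data.frame(seq_id = seq_ids[t], pos = slots,
                                   stringsAsFactors = FALSE))
    }
    out
  }

  five_prime <- config$truth_placement == "five_prime"
  site_pool <- if (five_prime && n_tx > 1L) seq_len(n_tx - 1L)
               else seq_len(n_tx)
  sp <- if (five_prime) place_window(config$n_modified_sites, site_pool)
        else draw_positions(config$n_modified_sites, want_a = TRUE)
  sites <- if (nrow(sp)) data.frame(
    sp, ref = "A",
    s = rep(config$stoichiometry, length.out = nrow(sp)),
    r = config$readthrough,
    m = config$misinc_given_readthrough,
    stringsAsFactors = FALSE) else
      data.frame(seq_id = character(), pos = integer(), ref = character(),
                 s = numeric(), r = numeric(), m = numeric())

  np <- draw_positions(config$n_snp_het + config$n_snp_hom, want_a = FALSE)
  snps <- if (nrow(np)) {
    refb <- mapply(function(sq, p) substr(seqs[[sq]], p + 1L, p + 1L),
                   np$seq_id, np$pos)
    alt <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L),
                  character(1))
    data.frame(np, ref = unname(refb), alt = unname(alt),
               genotype = rep(c("het", "hom"),
                              c(config$n_snp_het, config$n_snp_hom)),
               stringsAsFactors = FALSE)
  } else data.frame(seq_id = character(), pos = integer(), ref = character(),
                    alt = character(), genotype = character())

  ep <- if (five_prime) place_window(config$n_editing, n_tx)
        else draw_positions(config$n_editing, want_a = TRUE)
  editing <- if (nrow(ep)) data.frame(ep, rate = config$editing_rate,
                                      stringsAsFactors = FALSE) else
    data.frame(seq_id = character(), pos = integer(), rate = numeric())

  cp <- draw_positions(config$n_decoy_clean, want_a = TRUE)
  crosslinks <- data.frame(seq_id = seq_ids, pos = 0L,
                           stringsAsFactors = FALSE)

  list(reference = seqs, annotations = annotations,
       truth = list(sites = sites, snps = snps, editing = editing,
                    crosslinks = crosslinks, clean_a = cp),
       config = config)
}

#' SNP mask from a simulation truth set
#'
#' The positions a variant-aware pipeline would mask: all SNP decoys.
#' @param truth Truth list from [simulate_reference()].
#' @return Data frame (`seq_id`, `pos`).
#' @export
truth_snp_mask <- function(truth) {
  truth$snps[, c("seq_id", "pos"), drop = FALSE]
}

make_umis <- function(n, width = 8L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Fragment molecules into consecutive pieces. Returns piece-level vectors.
fragment_molecules <- function(mol_len, fragment_mean) {
  n_pieces <- pmax(1L, as.integer(round(mol_len / fragment_mean)))
  total <- sum(n_pieces)
  mol_of <- rep.int(seq_along(mol_len), n_pieces)
  piece_rank <- sequence(n_pieces)
  # interior cut points, sorted within molecule
  cuts_needed <- n_pieces - 1L
  cut_list <- vector("list", length(mol_len))
  has_cuts <- cuts_needed > 0L
  if (any(has_cuts)) {
    idx <- which(has_cuts)
    all_cuts <- lapply(idx, function(i) {
      sort(sample.int(mol_len[i] - 1L, cuts_needed[i]))
    })
    cut_list[idx] <- all_cuts
  }
  bounds <- lapply(seq_along(mol_len), function(i) {
    c(0L, cut_list[[i]], mol_len[i])
  })
  starts <- unlist(lapply(bounds, function(b) b[-length(b)]), use.names = FALSE)
  ends <- unlist(lapply(bounds, function(b) b[-1L]), use.names = FALSE)
  list(mol = mol_of, start = starts, end = ends, rank = piece_rank)
}

#' Simulate one replicate of reads
#'
#' Draws molecules, fragments them, and runs the reverse-transcription model
#' per fragment: termination versus read-through with misincorporation at
#' modified positions, antibody-crosslink terminations near the cap in CLIP
#' mode, SNP alleles and editing events per molecule, uniform sequencing
#' error, per-fragment UMIs, and PCR duplication. Consumes the current RNG
#' stream; use [simulate_dataset()] for a fully seeded run.
#'
#' @param sim Output of [simulate_reference()].
#' @param mode `"rnaseq"` or `"miclip"`.
#' @param replicate_id Replicate label.
#' @param n_molecules Molecules to draw (default from the configuration).
#' @return A read table (see [read_alignments()] for the schema).
#' @export
simulate_reads <- function(sim, mode = c("rnaseq", "miclip"), replicate_id,
                           n_molecules = NULL) {
  mode <- match.arg(mode)
  config <- sim$config
  if (is.null(n_molecules)) n_molecules <- config$molecules_per_replicate
  ref <- sim$reference
  lens <- nchar(ref)
  n_tx <- length(ref)
  truth <- sim$truth

  tx <- sample.int(n_tx, n_molecules, replace = TRUE)
  mol_len <- lens[tx]

  # molecule-level states
  eff_s <- truth$sites$s * (1 - config$dimroth_loss)
  site_tx <- match(truth$sites$seq_id, names(ref))
  mod_state <- matrix(FALSE, n_molecules, max(1L, nrow(truth$sites)))
  for (j in seq_len(nrow(truth$sites))) {
    on_tx <- tx == site_tx[j]
    mod_state[on_tx, j] <- stats::runif(sum(on_tx)) < eff_s[j]
  }
  snp_tx <- match(truth$snps$seq_id, names(ref))
  snp_state <- matrix(FALSE, n_molecules, max(1L, nrow(truth$snps)))
  for (j in seq_len(nrow(truth$snps))) {
    on_tx <- tx == snp_tx[j]
    p_alt <- if (truth$snps$genotype[j] == "hom") 1 else 0.5
    snp_state[on_tx, j] <- stats::runif(sum(on_tx)) < p_alt
  }
  ed_tx <- match(truth$editing$seq_id, names(ref))
  ed_state <- matrix(FALSE, n_molecules, max(1L, nrow(truth$editing)))
  for (j in seq_len(nrow(truth$editing))) {
    on_tx <- tx == ed_tx[j]
    ed_state[on_tx, j] <- stats::runif(sum(on_tx)) < truth$editing$rate[j]
  }
  crosslinked <- if (mode == "miclip") {
    stats::runif(n_molecules) < config$crosslink_rate
  } else rep(FALSE, n_molecules)

  fr <- fragment_molecules(mol_len, config$fragment_mean)
  np <- length(fr$mol)
  p_tx <- tx[fr$mol]
  read5 <- fr$start
  active <- rep(TRUE, np)
  edit_read <- integer(0); edit_pos <- integer(0); edit_base <- character(0)

  # hard-stop sites, 3'-most first: RT meets them in this order
  if (nrow(truth$sites)) {
    ord <- order(-truth$sites$pos)
    for (j in ord) {
      covers <- active & p_tx == site_tx[j] &
        fr$start <= truth$sites$pos[j] & fr$end > truth$sites$pos[j] &
        mod_state[cbind(fr$mol, j)]
      if (!any(covers)) next
      u <- stats::runif(sum(covers))
      idx <- which(covers)
      term <- u < (1 - truth$sites$r[j])
      read5[idx[term]] <- truth$sites$pos[j] + 1L
      active[idx[term]] <- FALSE
      thru <- idx[!term]
      if (length(thru)) {
        mi <- stats::runif(length(thru)) < truth$sites$m[j]
        hit <- thru[mi]
        if (length(hit)) {
          alt <- sample(names(config$spectrum), length(hit), replace = TRUE,
                        prob = config$spectrum)
          edit_read <- c(edit_read, hit)
          edit_pos <- c(edit_pos, rep(truth$sites$pos[j], length(hit)))
          edit_base <- c(edit_base, alt)
        }
      }
    }
  }

  keep <- rep(TRUE, np)
  if (mode == "miclip") {
    cap_piece <- fr$start == 0L & crosslinked[fr$mol]
    xl <- cap_piece & active
    if (any(xl)) {
      offs <- sample(0:4, sum(xl), replace = TRUE,
                     prob = config$crosslink_offsets)
      read5[xl] <- offs
      active[xl] <- FALSE
    }
    keep <- xl | (stats::runif(np) < config$miclip_background)
  }

  read_end <- pmin(read5 + config$read_length, fr$end)
  keep <- keep & (read_end - read5 >= 1L)
  if (!any(keep)) return(empty_reads())

  ridx <- which(keep)
  n_reads <- length(ridx)
  r_tx <- p_tx[ridx]
  r_start <- read5[ridx]
  r_end <- read_end[ridx]
  r_mol <- fr$mol[ridx]
  seqs <- substring(ref[r_tx], r_start + 1L, r_end)

  # collect per-read edits: planted misincorporations, SNP alleles, editing
  add_edits <- function(er, ep, eb) {
    m <- match(er, ridx)
    sel <- which(!is.na(m))
    m <- m[sel]; ep <- ep[sel]; eb <- eb[sel]
    ok <- ep >= r_start[m] & ep < r_end[m]
    list(read = m[ok], pos = ep[ok], base = eb[ok])
  }
  ed <- add_edits(edit_read, edit_pos, edit_base)
  for (j in seq_len(nrow(truth$snps))) {
    carrier <- which(r_tx == snp_tx[j] & snp_state[cbind(r_mol, j)] &
                       r_start <= truth$snps$pos[j] &
                       r_end > truth$snps$pos[j])
    if (length(carrier)) {
      ed$read <- c(ed$read, carrier)
      ed$pos <- c(ed$pos, rep(truth$snps$pos[j], length(carrier)))
      ed$base <- c(ed$base, rep(truth$snps$alt[j], length(carrier)))
    }
  }
  for (j in seq_len(nrow(truth$editing))) {
    carrier <- which(r_tx == ed_tx[j] & ed_state[cbind(r_mol, j)] &
                       r_start <= truth$editing$pos[j] &
                       r_end > truth$editing$pos[j])
    if (length(carrier)) {
      ed$read <- c(ed$read, carrier)
      ed$pos <- c(ed$pos, rep(truth$editing$pos[j], length(carrier)))
      ed$base <- c(ed$base, rep("G", length(carrier)))
    }
  }
  if (length(ed$read)) {
    for (k in seq_along(ed$read)) {
      i <- ed$read[k]
      at <- ed$pos[k] - r_start[i] + 1L
      substr(seqs[i], at, at) <- ed$base[k]
    }
  }

  # uniform sequencing error
  if (config$seq_error > 0) {
    blen <- nchar(seqs)
    total <- sum(blen)
    n_err <- stats::rbinom(1L, total, config$seq_error)
    if (n_err > 0L) {
      flat <- sample.int(total, n_err)
      cum <- cumsum(blen)
      ri <- findInterval(flat, c(0L, cum), left.open = TRUE)
      within <- flat - c(0L, cum)[ri]
      for (k in seq_len(n_err)) {
        i <- ri[k]; at <- within[k]
        cur <- substr(seqs[i], at, at)
        substr(seqs[i], at, at) <- sample(setdiff(BASES, cur), 1L)
      }
    }
  }

  umi <- make_umis(n_reads)
  read_id <- sprintf("%s.%06d", replicate_id, seq_len(n_reads))
  reads <- new_reads(read_id, names(ref)[r_tx], r_start, "+", seqs, umi,
                     replicate_id)

  if (config$pcr_dup_rate > 0) {
    dup <- stats::runif(n_reads) < config$pcr_dup_rate
    if (any(dup)) {
      copies <- reads[dup, , drop = FALSE]
      copies$read_id <- paste0(copies$read_id, "d")
      reads <- rbind(reads, copies)
      rownames(reads) <- NULL
    }
  }
  reads
}

#' Simulate a full multi-replicate dataset
#'
#' Seeds the RNG from the configuration, builds the reference/annotation/
#' truth set and then simulates every replicate in sequence, so the entire
#' output is a deterministic function of the seed.
#'
#' @param config A [sim_config()].
#' @param mode `"rnaseq"` or `"miclip"`.
#' @return The [simulate_reference()] list plus `reads` (list of per-
#'   replicate read tables, named by replicate) and `mode`.
#' @export
simulate_dataset <- function(config, mode = c("rnaseq", "miclip")) {
  mode <- match.arg(mode)
  sim <- simulate_reference(config)
  rep_ids <- sprintf("rep%02d", seq_len(config$n_replicates))
  sim$reads <- lapply(rep_ids, function(rid) simulate_reads(sim, mode, rid))
  names(sim$reads) <- rep_ids
  sim$mode <- mode
  sim
}
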