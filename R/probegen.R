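# Probe generation from per-ORF multiple sequence alignments of full-length
# intact L1 copies: column consensus under an identity threshold, stride-1
# candidate k-mers inside qualifying runs, a four-step refinement against the
# reference genome and its annotation, and assembly of the two per-ORF sets
# into one probe set on the ORF1-anchored offset axis.

#' Read an aligned FASTA file as an MSA block
#'
#' @param path Aligned FASTA (rows may contain `-`).
#' @param orf Which ORF the alignment covers (1 or 2).
#' @return A list of class `MsaBlock` with `rows` (named uppercase character
#'   vector of equal length) and `orf`.
#' @export
read_msa <- function(path, orf) {
  x <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(x))
  names(rows) <- sub("\\s.*$", "", names(x))
  msa_block(rows, orf)
}

#' Construct an MSA block
#'
#' @param rows Named character vector of aligned rows over A/C/G/T/- (at
#'   least two, equal length, unique ids).
#' @param orf Source ORF (1 or 2).
#' @return A list of class `MsaBlock`.
#' @export
msa_block <- function(rows, orf) {
  stopifnot(is.character(rows), length(rows) >= 2L)
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    format_error("MSA rows must carry unique ids")
  if (length(unique(nchar(rows))) != 1L)
    format_error("MSA rows must have equal length")
  if (any(grepl("[^ACGT-]", rows)))
    format_error("MSA rows must be over A/C/G/T/-")
  structure(list(rows = rows, orf = as.integer(orf)), class = "MsaBlock")
}

#' Column consensus of an MSA under an identity threshold
#'
#' For each alignment column the most frequent non-gap base is the consensus
#' base (ties to the alphabetically first base); the column qualifies iff
#' that base's count over *all* rows (gaps count in the denominator) reaches
#' the identity fraction.  All-gap columns are dropped from the consensus
#' coordinate space; failing columns stay in the consensus but are unmasked.
#'
#' @param msa An `MsaBlock`.
#' @param identity Required consensus-base fraction in (0, 1].
#' @return A list of class `ConsensusResult`: `consensus` (ungapped string),
#'   `mask` (logical per consensus position), `col_map` (alignment column ->
#'   consensus position, NA for all-gap columns).
#' @export
column_consensus <- function(msa, identity = 0.95) {
  stopifnot(inherits(msa, "MsaBlock"), identity > 0, identity <= 1)
  n <- length(msa$rows)
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  best <- max.col(counts, ties.method = "first")
  nbest <- counts[cbind(seq_len(nrow(counts)), best)]
  allgap <- nbest == 0
  cons <- DNA_BASES[best]
  qual <- nbest / n >= identity
  keep <- !allgap
  col_map <- rep(NA_integer_, ncol(mat))
  col_map[keep] <- seq_len(sum(keep))
  structure(list(consensus = paste(cons[keep], collapse = ""),
                 mask = qual[keep], col_map = col_map),
            class = "ConsensusResult")
}

#' Candidate k-mers from qualifying consensus runs
#'
#' Every window of k consecutive qualifying consensus positions becomes a
#' candidate (stride 1 within maximal qualifying runs); the offset is the
#' window start in ungapped consensus coordinates (0-based).
#'
#' @param cons A `ConsensusResult`.
#' @param k Window length in bp.
#' @return A `data.frame` with columns `sequence` and `orf_offset`.
#' @export
candidate_kmers <- function(cons, k) {
  stopifnot(inherits(cons, "ConsensusResult"), k >= 1L)
  mask <- cons$mask
  L <- length(mask)
  out_seq <- character()
  out_off <- integer()
  if (L >= k) {
    run_ok <- which(vapply(seq_len(L - k + 1L),
                           function(s) all(mask[s:(s + k - 1L)]), logical(1L)))
    if (length(run_ok) > 0L) {
      out_seq <- substring(cons$consensus, run_ok, run_ok + k - 1L)
      out_off <- run_ok - 1L
    }
  }
  data.frame(sequence = out_seq, orf_offset = out_off,
             stringsAsFactors = FALSE)
}

# genomic (0-based half-open) interval of one ORF of one annotated L1,
# derived from element-relative component coordinates and the element strand
orf_genomic_interval <- function(record, orf) {
  cs <- if (orf == 1L) record$orf1_start else record$orf2_start
  ce <- if (orf == 1L) record$orf1_end else record$orf2_end
  if (record$strand == "+") {
    lo <- record$l1_start + cs - 1L
    hi <- record$l1_start + ce - 1L
  } else {
    hi <- record$l1_end - cs + 1L
    lo <- record$l1_end - ce + 1L
  }
  c(lo - 1L, hi)  # 0-based half-open
}

# does the hit window fall inside the (slack-padded) interval?
hit_in_interval <- function(pos, len, interval, slack) {
  pos >= interval[1L] - slack & pos + len <= interval[2L] + slack
}

#' Refine candidate k-mers against the reference genome
#'
#' The four-step refinement: (1) map every candidate genome-wide (both
#' strands) at edit distance `e_map` and discard candidates with no hit
#' inside the source-ORF interval of at least one annotated L1; (2) discard
#' candidates lacking a hit inside the corresponding ORF interval of every
#' annotated L1; (3) sort survivors by total genome-wide hit count ascending
#' (fewer hits means fewer false positives; ties by smaller offset); (4)
#' greedily accept candidates whose offset interval overlaps no accepted
#' candidate.
#'
#' @param cands Candidate `data.frame` from [candidate_kmers()].
#' @param genome Reference genome (named character vector).
#' @param meta Metadata records `data.frame` (or [read_metadata()] list).
#' @param e_map Edit distance used for refinement mapping (default 2).
#' @param orf Source ORF of the candidates (1 or 2).
#' @return A `data.frame` of accepted probes (`sequence`, `orf_offset`,
#'   `genome_hit_count`) sorted by offset.
#' @export
refine_candidates <- function(cands, genome, meta, e_map = 2L, orf) {
  records <- if (is.data.frame(meta)) meta else meta$records
  stopifnot(nrow(records) >= 1L)
  if (!all(records$chrom %in% names(genome)))
    stop("metadata references chromosomes absent from the genome")
  if (nrow(cands) == 0L)
    stop("no candidate k-mers; lower the identity threshold or k")
  k <- nchar(cands$sequence[1L])
  intervals <- lapply(seq_len(nrow(records)), function(i)
    orf_genomic_interval(records[i, ], orf))
  n_univ <- integer(nrow(cands))
  hit_count <- integer(nrow(cands))
  in_source <- logical(nrow(cands))
  rc <- vapply(genome, revcomp, character(1L))
  for (ci in seq_len(nrow(cands))) {
    total <- 0L
    per_l1 <- rep(FALSE, nrow(records))
    for (chrom in names(genome)) {
      h <- match_both_strands(genome[[chrom]], rc[[chrom]],
                              cands$sequence[ci], e_map)
      total <- total + nrow(h)
      if (nrow(h) == 0L) next
      for (ri in seq_len(nrow(records))) {
        if (per_l1[ri] || records$chrom[ri] != chrom) next
        sel <- h$strand == records$strand[ri]
        if (any(hit_in_interval(h$pos[sel], h$matched_len[sel],
                                intervals[[ri]], e_map)))
          per_l1[ri] <- TRUE
      }
    }
    hit_count[ci] <- total
    in_source[ci] <- any(per_l1)
    n_univ[ci] <- sum(per_l1)
  }
  survivors <- which(in_source & n_univ == nrow(records))
  if (length(survivors) == 0L)
    stop("no universal probes for ORF", orf,
         ": no candidate maps inside every annotated L1; ",
         "try a lower identity threshold or a smaller k")
  sv <- cands[survivors, , drop = FALSE]
  sv$genome_hit_count <- hit_count[survivors]
  sv <- sv[order(sv$genome_hit_count, sv$orf_offset), , drop = FALSE]
  accepted <- integer()
  for (i in seq_len(nrow(sv))) {
    s <- sv$orf_offset[i]
    if (all(s + k <= sv$orf_offset[accepted] |
            s >= sv$orf_offset[accepted] + k))
      accepted <- c(accepted, i)
  }
  out <- sv[accepted, , drop = FALSE]
  out <- out[order(out$orf_offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine per-ORF probe sets on the ORF1-anchored offset axis
#'
#' ORF1 probe offsets pass through unchanged; ORF2 offsets are shifted by
#' the modal ORF1-start-to-ORF2-start distance.  The merged set is re-sorted
#' and re-validated (non-overlap across the union).
#'
#' @param orf1,orf2 Refined probe `data.frame`s from [refine_candidates()]
#'   (`orf2` may have zero rows).
#' @param model `ComponentLengthModel` from [length_modes()].
#' @param k Probe length.
#' @return A validated probe set `data.frame`.
#' @export
assemble_probeset <- function(orf1, orf2, model, k) {
  stopifnot(inherits(model, "ComponentLengthModel"))
  off1 <- orf1$orf_offset
  seq1 <- orf1$sequence
  off2 <- integer(0)
  seq2 <- character(0)
  if (!is.null(orf2) && nrow(orf2) > 0L) {
    off2 <- orf2$orf_offset + model$mode_orf1start_to_orf2start
    seq2 <- orf2$sequence
  }
  offset <- c(off1, off2)
  orf <- c(rep(1L, length(off1)), rep(2L, length(off2)))
  o <- order(offset)
  offset <- offset[o]
  if (length(offset) > 1L &&
      any(offset[-1L] < offset[-length(offset)] + k))
    stop("ORF1 and shifted ORF2 probes overlap; cannot assemble probe set")
  new_probeset(orf = orf[o], k = k, offset = offset,
               sequence = c(seq1, seq2)[o])
}

#' Generate a probe set from per-ORF alignments
#'
#' Full probe-generation pipeline: consensus extraction per ORF, stride-1
#' candidate k-mers, four-step refinement against the reference genome and
#' its metadata, and assembly onto the ORF1-anchored offset axis.
#'
#' @param orf1_msa,orf2_msa `MsaBlock`s of the aligned ORF1/ORF2 sequences.
#' @param genome Reference genome (named character vector).
#' @param meta Metadata from [read_metadata()] (list or records).
#' @param k Probe length.
#' @param identity Consensus identity threshold (default 0.95).
#' @param e_map Refinement mapping edit distance (default 2).
#' @return A validated probe set `data.frame`.
#' @export
generate_probes <- function(orf1_msa, orf2_msa, genome, meta, k,
                            identity = 0.95, e_map = 2L) {
  records <- if (is.data.frame(meta)) meta else meta$records
  model <- length_modes(records)
  p1 <- refine_candidates(candidate_kmers(column_consensus(orf1_msa,
                                                           identity), k),
                          genome, records, e_map, orf = 1L)
  p2 <- refine_candidates(candidate_kmers(column_consensus(orf2_msa,
                                                           identity), k),
                          genome, records, e_map, orf = 2L)
  assemble_probeset(p1, p2, model, k)
}
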