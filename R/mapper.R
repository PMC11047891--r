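# Built-in approximate probe mapper: every occurrence of each probe in a
# genome within a maximum edit distance, on both strands.  Replaces the
# external short-read mapper stage of the original pipeline; the contract is
# defined by equivalence with a brute-force semi-global edit-distance oracle.

#' Find approximate occurrences of a probe in one sequence
#'
#' Reports one hit per locus: for every genomic window whose best semi-global
#' edit distance to the probe is at most `e_max`, qualifying alignment end
#' positions within `e_max` of each other are collapsed to a single hit,
#' keeping the minimal edit distance (ties: leftmost start, then leftmost
#' end).  `N` in the genome matches no probe base.
#'
#' @param genome_seq Nucleotide string (A/C/G/T/N).
#' @param probe_seq Probe string of length k over A/C/G/T.
#' @param e_max Maximum edit distance (Levenshtein); must be smaller than k.
#' @return A `data.frame` with columns `pos` (0-based window start),
#'   `edit_distance` and `matched_len`.
#' @export
find_matches <- function(genome_seq, probe_seq, e_max) {
  stopifnot(is.character(genome_seq), length(genome_seq) == 1L,
            is.character(probe_seq), length(probe_seq) == 1L)
  e_max <- as.integer(e_max)
  if (e_max < 0L) stop("e_max must be >= 0")
  if (nchar(probe_seq) <= e_max)
    stop("probe length (", nchar(probe_seq),
         ") must exceed the edit distance (", e_max, ")")
  if (grepl("[^ACGT]", probe_seq)) stop("probe must be over A/C/G/T")
  if (nchar(genome_seq) < 1L)
    return(data.frame(pos = integer(), edit_distance = integer(),
                      matched_len = integer()))
  .cpp_find_matches(genome_seq, probe_seq, e_max)
}

# both-strand matching of one probe against one sequence; minus-strand hits
# are found by scanning the pre-computed reverse complement and mapping the
# positions back, so that detection is exactly mirror-symmetric under
# reverse complementation of the genome
match_both_strands <- function(seq, rc_seq, probe_seq, e_max) {
  L <- nchar(seq)
  fwd <- find_matches(seq, probe_seq, e_max)
  rev <- find_matches(rc_seq, probe_seq, e_max)
  if (nrow(fwd) > 0L) fwd$strand <- "+"
  if (nrow(rev) > 0L) {
    rev$pos <- L - (rev$pos + rev$matched_len)
    rev$strand <- "-"
  }
  rbind(fwd, rev)
}

#' Map a probe set against a genome on both strands
#'
#' Forward-strand hits come from [find_matches()] on each sequence; minus
#' strand hits are found by scanning the reverse complement of the sequence,
#' with positions reported on the forward coordinate system and strand `-`.
#'
#' @param genome Named character vector from [read_genome()].
#' @param probes Probe set `data.frame`.
#' @param e_max Maximum edit distance.
#' @return A hit table `data.frame` (columns `probe_id`, `chrom`, `pos`,
#'   `strand`, `edit_distance`, `matched_len`), grouped by (chrom, strand)
#'   and sorted by position.
#' @export
map_probeset <- function(genome, probes, e_max) {
  probes <- validate_probeset(probes)
  stopifnot(is.character(genome), length(genome) >= 1L,
            !is.null(names(genome)))
  out <- vector("list", length(genome) * nrow(probes))
  n <- 0L
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    rc_seq <- revcomp(seq)
    for (i in seq_len(nrow(probes))) {
      h <- match_both_strands(seq, rc_seq, probes$sequence[i], e_max)
      if (nrow(h) > 0L) {
        n <- n + 1L
        out[[n]] <- data.frame(
          probe_id = probes$probe_id[i], chrom = chrom, pos = h$pos,
          strand = h$strand, edit_distance = h$edit_distance,
          matched_len = h$matched_len, stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0L) return(empty_hit_table())
  normalize_hit_table(do.call(rbind, out[seq_len(n)]))
}
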