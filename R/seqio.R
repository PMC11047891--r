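# Readers and writers for the external formats the tool touches: FASTA
# (genomes and probes, the latter with a structured header dialect), SAM
# import of pre-computed probe mappings, GFF3 output, and the L1Base2-style
# CSV metadata schema, plus the component-length mode computation.
#
# Internal coordinates are 0-based half-open throughout the package;
# conversion to 1-based inclusive happens only at the GFF3/CSV/SAM boundary.

META_COLUMNS <- c("chrom", "l1_start", "l1_end", "strand",
                  "utr5_start", "utr5_end", "orf1_start", "orf1_end",
                  "orf2_start", "orf2_end", "utr3_start", "utr3_end")

#' Read an assembled genome from FASTA
#'
#' Sequence ids are the first whitespace-delimited token of each header and
#' must be unique.  Sequences are uppercased on read; only A, C, G, T and N
#' are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase nucleotide string per
#'   sequence, in file order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) format_error("genome FASTA not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) format_error("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) format_error("FASTA record with empty id in ", path)
  if (anyDuplicated(ids))
    format_error("duplicate sequence id in ", path, ": ",
                 ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(x))
  if (any(!nzchar(seqs)))
    format_error("empty sequence for record: ", ids[!nzchar(seqs)][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    format_error("characters outside A/C/G/T/N in record: ", ids[bad][1L])
  names(seqs) <- ids
  seqs
}

# ---- probe sets -----------------------------------------------------------

# A ProbeSet is a data.frame with columns probe_id, orf, k, offset, sequence,
# sorted by offset, with non-overlapping [offset, offset + k) intervals and a
# uniform k.  Offsets are 0-based distances from the first base of ORF1.

validate_probeset <- function(probes) {
  need <- c("probe_id", "orf", "k", "offset", "sequence")
  stopifnot(is.data.frame(probes), all(need %in% names(probes)))
  if (nrow(probes) == 0L) format_error("probe set is empty")
  if (anyDuplicated(probes$probe_id))
    format_error("duplicate probe ids in probe set")
  if (!all(probes$orf %in% c(1L, 2L)))
    format_error("probe orf values must be 1 or 2")
  if (length(unique(probes$k)) != 1L)
    format_error("probe set mixes k-mer sizes: ",
                 paste(unique(probes$k), collapse = ", "))
  if (!all(nchar(probes$sequence) == probes$k))
    format_error("probe sequence length differs from its k")
  if (any(grepl("[^ACGT]", probes$sequence)))
    format_error("probe sequences must be over A/C/G/T")
  if (any(probes$offset < 0L)) format_error("negative probe offset")
  if (is.unsorted(probes$offset, strictly = TRUE))
    format_error("probe offsets must be strictly ascending")
  if (nrow(probes) > 1L) {
    ends <- probes$offset + probes$k
    if (any(probes$offset[-1L] < ends[-nrow(probes)]))
      format_error("overlapping probe intervals in probe set")
  }
  probes
}

new_probeset <- function(orf, k, offset, sequence) {
  o <- order(offset)
  df <- data.frame(
    probe_id = sprintf("L1PD_probe_%d", seq_along(offset)),
    orf = as.integer(orf)[o], k = as.integer(k),
    offset = as.integer(offset)[o], sequence = as.character(sequence)[o],
    stringsAsFactors = FALSE)
  validate_probeset(df)
}

#' Read a probe set from FASTA
#'
#' Headers must follow the dialect
#' `>L1PD_probe_<n>|orf=<1|2>|k=<int>|offset=<int>` where `n` is the 1-based
#' rank of the probe by offset and the offset is the 0-based distance from
#' the first base of the ORF1 region to the first base of the probe.
#'
#' @param path Path to a probe FASTA file.
#' @return A probe set `data.frame` (columns `probe_id`, `orf`, `k`,
#'   `offset`, `sequence`) sorted by offset.
#' @export
read_probes <- function(path) {
  if (!file.exists(path)) format_error("probe FASTA not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) format_error("empty probe FASTA: ", path)
  hdr <- names(x)
  pat <- "^([^|]+)\\|orf=([12])\\|k=([0-9]+)\\|offset=([0-9]+)$"
  ok <- grepl(pat, hdr)
  if (any(!ok))
    format_error("probe header does not follow the ",
                 "'id|orf=..|k=..|offset=..' dialect: ", hdr[!ok][1L])
  df <- data.frame(
    probe_id = sub(pat, "\\1", hdr),
    orf = as.integer(sub(pat, "\\2", hdr)),
    k = as.integer(sub(pat, "\\3", hdr)),
    offset = as.integer(sub(pat, "\\4", hdr)),
    sequence = toupper(as.character(x)),
    stringsAsFactors = FALSE)
  df <- df[order(df$offset), , drop = FALSE]
  rownames(df) <- NULL
  validate_probeset(df)
}

#' Write a probe set to FASTA
#'
#' Emits the bit-exact header dialect read by [read_probes()].
#'
#' @param probes A probe set `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_probes <- function(probes, path) {
  probes <- validate_probeset(probes)
  seqs <- Biostrings::DNAStringSet(probes$sequence)
  names(seqs) <- sprintf("%s|orf=%d|k=%d|offset=%d",
                         probes$probe_id, probes$orf, probes$k, probes$offset)
  Biostrings::writeXStringSet(seqs, path, width = max(probes$k, 80L))
  invisible(path)
}

# ---- L1Base2-style metadata ----------------------------------------------

#' Read L1 annotation metadata (L1Base2-style CSV)
#'
#' One row per full-length intact L1.  `l1_start`/`l1_end` are 1-based
#' inclusive genomic coordinates; the component columns (5'UTR, ORF1, ORF2,
#' 3'UTR starts/ends) are 1-based inclusive coordinates relative to the
#' element's own 5' end.  Rows with any required field empty are skipped and
#' counted, mirroring the tolerant handling of incomplete database entries.
#'
#' @param path Path to a CSV file with columns `chrom, l1_start, l1_end,
#'   strand, utr5_start, utr5_end, orf1_start, orf1_end, orf2_start,
#'   orf2_end, utr3_start, utr3_end`.
#' @param quiet Suppress the skipped-row message.
#' @return A list with `records` (validated `data.frame`) and `skipped`
#'   (number of incomplete rows dropped).
#' @export
read_metadata <- function(path, quiet = FALSE) {
  if (!file.exists(path)) format_error("metadata CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(META_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    format_error("metadata CSV missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  df <- df[META_COLUMNS]
  incomplete <- apply(df, 1L, function(r) any(is.na(r) | !nzchar(trimws(r))))
  skipped <- sum(incomplete)
  df <- df[!incomplete, , drop = FALSE]
  if (nrow(df) == 0L)
    format_error("metadata CSV contains no complete rows: ", path)
  if (!quiet && skipped > 0L)
    message("read_metadata: skipped ", skipped, " incomplete row(s)")
  num <- setdiff(META_COLUMNS, c("chrom", "strand"))
  df[num] <- lapply(df[num], function(x) as.integer(x))
  if (anyNA(df[num])) format_error("non-numeric coordinate in metadata CSV")
  if (!all(df$strand %in% c("+", "-")))
    format_error("metadata strand must be '+' or '-'")
  if (any(df$l1_start > df$l1_end))
    format_error("metadata row with l1_start > l1_end")
  comp <- df[c("utr5_start", "utr5_end", "orf1_start", "orf1_end",
               "orf2_start", "orf2_end", "utr3_start", "utr3_end")]
  ordered_ok <- with(comp,
    utr5_start <= utr5_end & utr5_end < orf1_start &
    orf1_start <= orf1_end & orf1_end < orf2_start &
    orf2_start <= orf2_end & orf2_end < utr3_start &
    utr3_start <= utr3_end)
  if (!all(ordered_ok))
    format_error("metadata row with unordered or overlapping components")
  rownames(df) <- NULL
  list(records = df, skipped = skipped)
}

#' Component-length modes of annotated L1s
#'
#' For each element component the most common length (in bp) across the
#' annotation records, used to extrapolate call boundaries from an anchored
#' pattern.  Ties are broken by the smallest tied value, and the total
#' element mode is computed independently from the full-element lengths (it
#' is not forced to equal the sum of the component modes).
#'
#' @param records Metadata `data.frame` from [read_metadata()].
#' @return A list of class `ComponentLengthModel` with entries `mode_5utr`,
#'   `mode_orf1`, `mode_spacer`, `mode_orf2`, `mode_3utr`, `mode_total` and
#'   `mode_orf1start_to_orf2start`.
#' @export
length_modes <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  model <- list(
    mode_5utr  = mode_int(records$utr5_end - records$utr5_start + 1L),
    mode_orf1  = mode_int(records$orf1_end - records$orf1_start + 1L),
    mode_spacer = mode_int(records$orf2_start - records$orf1_end - 1L),
    mode_orf2  = mode_int(records$orf2_end - records$orf2_start + 1L),
    mode_3utr  = mode_int(records$utr3_end - records$utr3_start + 1L),
    mode_total = mode_int(records$l1_end - records$l1_start + 1L),
    mode_orf1start_to_orf2start =
      mode_int(records$orf2_start - records$orf1_start))
  class(model) <- "ComponentLengthModel"
  model
}

# ---- GFF3 output ----------------------------------------------------------

#' Write L1 calls to GFF3
#'
#' Nine tab-delimited columns: seqid, source `L1PD`, type
#' `mobile_genetic_element`, 1-based inclusive start/end, `.` score, strand,
#' `.` phase, and attribute `Name=LINE1`.  Records are sorted by
#' (seqid, start).
#'
#' @param calls A `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand` (may be empty).
#' @param path Output path.
#' @param header_comments Optional character vector of comment lines
#'   (written as `#...` after the version directive).
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(calls, path, header_comments = character()) {
  lines <- "##gff-version 3"
  if (length(header_comments) > 0L)
    lines <- c(lines, paste0("#", header_comments))
  if (nrow(calls) > 0L) {
    stopifnot(all(calls$start >= 1L), all(calls$start <= calls$end),
              all(calls$strand %in% c("+", "-")))
    calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tL1PD\tmobile_genetic_element\t%d\t%d\t.\t%s\t.\tName=LINE1",
      calls$chrom, calls$start, calls$end, calls$strand))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read L1 calls back from a GFF3 file
#'
#' Minimal reader for files produced by [write_gff3()] (and the simulator's
#' truth GFF3); comment lines are ignored.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `attributes`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      attributes = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) format_error("malformed GFF3 line in ", path)
  f <- do.call(rbind, f)
  data.frame(chrom = f[, 1L], start = as.integer(f[, 4L]),
             end = as.integer(f[, 5L]), strand = f[, 7L],
             attributes = f[, 9L], stringsAsFactors = FALSE)
}

# ---- SAM import -----------------------------------------------------------

#' Import probe hits from a SAM file
#'
#' Converts mapped SAM records into the internal hit table: `POS` becomes a
#' 0-based position, FLAG bit 0x10 sets strand `-`, and the `NM` tag is read
#' as the edit distance (a missing tag defaults to 0 with a warning).
#' Unmapped records (FLAG 0x4) are dropped; all other reported alignments —
#' including secondary ones — become hits.  Records whose query name is not
#' in the probe set are skipped with a warning.
#'
#' @param path Path to a SAM file (with header).
#' @param probes Probe set `data.frame` the query names must belong to.
#' @return A hit table `data.frame` (columns `probe_id`, `chrom`, `pos`,
#'   `strand`, `edit_distance`, `matched_len`), grouped by (chrom, strand)
#'   and sorted by position.
#' @export
read_sam_hits <- function(path, probes) {
  probes <- validate_probeset(probes)
  if (!file.exists(path)) format_error("SAM file not found: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"), tag = "NM")
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  mapped <- !bitwAnd(rec$flag, 4L)
  qname <- rec$qname[mapped]
  known <- qname %in% probes$probe_id
  if (any(!known))
    warning("skipping ", sum(!known),
            " SAM record(s) whose query is not in the probe set")
  keep <- which(mapped)[known]
  if (length(keep) == 0L)
    return(empty_hit_table())
  nm <- if (is.null(rec$tag$NM)) rep(NA_integer_, length(keep)) else
    rec$tag$NM[mapped][known]
  if (anyNA(nm)) {
    warning("missing NM tag on ", sum(is.na(nm)),
            " SAM record(s); edit distance set to 0")
    nm[is.na(nm)] <- 0L
  }
  hits <- data.frame(
    probe_id = rec$qname[keep],
    chrom = as.character(rec$rname[keep]),
    pos = rec$pos[keep] - 1L,
    strand = ifelse(bitwAnd(rec$flag[keep], 16L) > 0L, "-", "+"),
    edit_distance = as.integer(nm),
    matched_len = GenomicAlignments::cigarWidthAlongReferenceSpace(
      rec$cigar[keep]),
    stringsAsFactors = FALSE)
  normalize_hit_table(hits)
}

empty_hit_table <- function() {
  data.frame(probe_id = character(), chrom = character(), pos = integer(),
             strand = character(), edit_distance = integer(),
             matched_len = integer(), stringsAsFactors = FALSE)
}

# sort by (chrom, strand, pos, probe_id) and drop duplicate
# (probe_id, chrom, pos, strand) entries
normalize_hit_table <- function(hits) {
  hits <- hits[order(hits$chrom, hits$strand, hits$pos, hits$probe_id,
                     hits$edit_distance, hits$matched_len), , drop = FALSE]
  dup <- duplicated(hits[c("probe_id", "chrom", "pos", "strand")])
  hits <- hits[!dup, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
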