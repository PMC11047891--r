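# The pattern-matching core: chain probe hits that occur in probe order with
# inter-hit distances consistent with the probe offsets, suppress duplicate
# patterns over the same locus, and extrapolate call boundaries from the
# component-length modes.

#' Detection parameters
#'
#' The three user-tunable knobs of the detector.
#'
#' @param e Maximum edit distance between a probe and its genomic match.
#' @param t Distance threshold (bp): maximum allowed deviation between the
#'   observed inter-hit gap and the gap expected from the probe offsets.
#' @param m Minimum number of matched probes for a pattern to become a call.
#' @param gap_mode Whether the distance predicate applies between consecutive
#'   matched probes (`"consecutive"`, the default, which tolerates cumulative
#'   indel drift across a long element) or between each probe and the pattern
#'   anchor (`"anchor"`).
#' @return A list of class `DetectionParams`.
#' @export
detection_params <- function(e, t, m, gap_mode = c("consecutive", "anchor")) {
  gap_mode <- match.arg(gap_mode)
  e <- as.integer(e); t <- as.integer(t); m <- as.integer(m)
  stopifnot(e >= 0L, t >= 0L, m >= 2L)
  structure(list(e = e, t = t, m = m, gap_mode = gap_mode),
            class = "DetectionParams")
}

#' Shipped default detection parameters
#'
#' Per-species, per-k defaults (currently human only: e/t/m of 15/625/18 for
#' 50-mers, 30/625/17 for 75-mers and 30/600/9 for 100-mers, the combinations
#' that maximised F1 in the parameter sweeps).  Unrecognised species require
#' explicit parameters because suitable values vary considerably between
#' genomes.
#'
#' @param k Probe length (50, 75 or 100).
#' @param species Species name; only `"human"` ships defaults.
#' @return A `DetectionParams` object.
#' @export
default_params <- function(k, species = "human") {
  if (!identical(species, "human"))
    stop("no shipped defaults for species '", species,
         "'; supply e, t and m explicitly")
  tab <- list(`50` = c(15L, 625L, 18L),
              `75` = c(30L, 625L, 17L),
              `100` = c(30L, 600L, 9L))
  v <- tab[[as.character(k)]]
  if (is.null(v)) stop("no shipped defaults for k = ", k)
  detection_params(v[1L], v[2L], v[3L])
}

#' Distance predicate between two probe hits
#'
#' TRUE iff the observed genomic gap between the two hits deviates from the
#' gap expected from the probe offsets by at most `t` bp.
#'
#' @param pos_i,pos_j 0-based hit positions on the same (chrom, strand),
#'   `pos_i < pos_j`.
#' @param offset_i,offset_j Probe offsets, `offset_i < offset_j`.
#' @param t Distance threshold in bp.
#' @return Logical.
#' @export
distance_ok <- function(pos_i, pos_j, offset_i, offset_j, t) {
  stopifnot(offset_i < offset_j, pos_i < pos_j)
  abs((pos_j - pos_i) - (offset_j - offset_i)) <= t
}

#' Chain probe hits into candidate patterns
#'
#' Per (chrom, strand), finds ordered chains of hits with strictly
#' increasing probe indices whose spacing satisfies the distance predicate.
#' Each round accepts the best remaining chain (most probes, then smallest
#' summed gap deviation, then leftmost) and consumes its hits; rounds stop
#' when no chain of at least `m` hits remains.  Minus-strand hits are chained
#' in reverse-complement coordinate space so that probe order runs 5' to 3'
#' along the element.
#'
#' @param hits Hit table from [map_probeset()] or [read_sam_hits()].
#' @param probes Probe set `data.frame`.
#' @param params `DetectionParams`.
#' @return A list of patterns; each pattern is a list with `chrom`, `strand`,
#'   `hits` (the supporting hit rows in chain order), `n_probes`,
#'   `gap_error_sum` and `anchor_pos` (0-based position of the leftmost hit
#'   on the forward strand).
#' @export
chain_hits <- function(hits, probes, params) {
  probes <- validate_probeset(probes)
  stopifnot(inherits(params, "DetectionParams"))
  if (params$m > nrow(probes))
    stop("m (", params$m, ") exceeds the probe set size (", nrow(probes), ")")
  hits <- normalize_hit_table(hits)
  patterns <- list()
  if (nrow(hits) == 0L) return(patterns)
  groups <- split(seq_len(nrow(hits)),
                  list(hits$chrom, hits$strand), drop = TRUE)
  for (gname in sort(names(groups))) {
    g <- hits[groups[[gname]], , drop = FALSE]
    strand <- g$strand[1L]
    pidx <- match(g$probe_id, probes$probe_id) - 1L
    if (anyNA(pidx)) stop("hit with probe_id absent from the probe set")
    cpos <- if (strand == "+") g$pos else -(g$pos + g$matched_len)
    o <- order(cpos, pidx)
    g <- g[o, , drop = FALSE]
    pidx <- pidx[o]
    cpos <- cpos[o]
    found <- .cpp_chain(as.integer(cpos), as.integer(pidx),
                        as.integer(probes$offset), params$t, params$m,
                        identical(params$gap_mode, "anchor"))
    for (f in found) {
      rows <- g[f$idx, , drop = FALSE]
      patterns[[length(patterns) + 1L]] <- list(
        chrom = rows$chrom[1L], strand = strand, hits = rows,
        n_probes = nrow(rows), gap_error_sum = f$gap_error_sum,
        anchor_pos = min(rows$pos))
    }
  }
  patterns
}

#' Extrapolate an L1 call from a pattern
#'
#' The hit of the lowest-index (most 5') matched probe anchors the element;
#' the 5'UTR and total-length modes extrapolate the element boundaries, which
#' are clamped to the chromosome and reported 1-based inclusive.
#'
#' @param pattern One pattern from [chain_hits()].
#' @param probes Probe set `data.frame`.
#' @param model `ComponentLengthModel` from [length_modes()].
#' @param chrom_len Length of the pattern's chromosome in bp.
#' @return A one-row `data.frame`: `chrom`, `start`, `end`, `strand`,
#'   `n_probes`, `gap_error_sum`.
#' @export
call_from_pattern <- function(pattern, probes, model, chrom_len) {
  stopifnot(inherits(model, "ComponentLengthModel"))
  rows <- pattern$hits
  pidx <- match(rows$probe_id, probes$probe_id)
  a <- which.min(pidx)
  h <- rows$pos[a]
  off <- probes$offset[pidx[a]]
  if (pattern$strand == "+") {
    start0 <- h - off - model$mode_5utr
    end0 <- start0 + model$mode_total - 1L
  } else {
    end0 <- (h + rows$matched_len[a] - 1L) + off + model$mode_5utr
    start0 <- end0 - model$mode_total + 1L
  }
  start0 <- max(0L, min(start0, chrom_len - 1L))
  end0 <- max(0L, min(end0, chrom_len - 1L))
  data.frame(chrom = pattern$chrom, start = as.integer(start0 + 1L),
             end = as.integer(end0 + 1L), strand = pattern$strand,
             n_probes = pattern$n_probes,
             gap_error_sum = pattern$gap_error_sum,
             stringsAsFactors = FALSE)
}

#' Suppress duplicate patterns over the same locus
#'
#' Calls whose intervals overlap a retained call's interval by more than 50%
#' of the shorter interval are suppressed.  Retention priority: more
#' supporting probes, then smaller summed gap deviation, then leftmost.
#'
#' @param calls A `data.frame` of projected calls (`chrom`, `start`, `end`,
#'   `strand`, `n_probes`, `gap_error_sum`).
#' @return The retained subset, sorted by (chrom, start).
#' @export
dedupe_patterns <- function(calls) {
  if (nrow(calls) <= 1L) return(calls)
  o <- order(-calls$n_probes, calls$gap_error_sum, calls$start, calls$end)
  calls <- calls[o, , drop = FALSE]
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (calls$chrom[i] != calls$chrom[j]) next
      ov <- min(calls$end[i], calls$end[j]) -
        max(calls$start[i], calls$start[j]) + 1L
      if (ov <= 0L) next
      shorter <- min(calls$end[i] - calls$start[i],
                     calls$end[j] - calls$start[j]) + 1L
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect full-length L1 elements in a genome
#'
#' End-to-end orchestration: map the probes (or take imported SAM hits),
#' chain hits into patterns, suppress duplicates, and extrapolate call
#' boundaries from the component-length modes of the annotation metadata.
#'
#' @param genome Named character vector from [read_genome()].
#' @param probes Probe set `data.frame`.
#' @param meta Metadata: either the list returned by [read_metadata()] or
#'   its `records` `data.frame`.
#' @param params `DetectionParams`; see [default_params()].
#' @param hits Optional pre-computed hit table (e.g. from
#'   [read_sam_hits()]); when `NULL` the built-in mapper is used.
#' @return A `data.frame` of calls sorted by (chrom, start): `chrom`,
#'   `start`, `end` (1-based inclusive), `strand`, `n_probes`,
#'   `gap_error_sum`.
#' @export
detect_l1 <- function(genome, probes, meta, params, hits = NULL) {
  records <- if (is.data.frame(meta)) meta else meta$records
  model <- length_modes(records)
  if (is.null(hits)) hits <- map_probeset(genome, probes, params$e)
  patterns <- chain_hits(hits, probes, params)
  if (length(patterns) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_probes = integer(), gap_error_sum = numeric(),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, lapply(patterns, function(p)
    call_from_pattern(p, probes, model, nchar(genome[[p$chrom]]))))
  dedupe_patterns(calls)
}
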