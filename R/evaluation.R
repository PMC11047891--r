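# Precision/recall/F1 against truth annotations, and the parameter-grid
# sweep used to choose default detection parameters.

#' F1 score
#'
#' Harmonic mean of precision and recall; 0 when both are 0.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Match calls against truth annotations
#'
#' Greedy one-to-one matching in ascending call start order: a call matches
#' an unmatched truth element iff their overlap is at least `min_overlap`
#' times the truth element's length and (unless `ignore_strand`) the strands
#' agree.  When several truth elements qualify, the one with the largest
#' overlap (ties: smallest start) is taken.
#'
#' @param calls Call `data.frame` (`chrom`, `start`, `end`, `strand`).
#' @param truth Truth `data.frame` with columns `chrom`, `l1_start`,
#'   `l1_end`, `strand` (metadata records work directly).
#' @param min_overlap Required overlap as a fraction of the truth length
#'   (default 0.5).
#' @param ignore_strand Do not require strand agreement.
#' @return A list with integer `tp`, `fp`, `fn`.
#' @export
match_calls <- function(calls, truth, min_overlap = 0.5,
                        ignore_strand = FALSE) {
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  if (n_calls == 0L || n_truth == 0L)
    return(list(tp = 0L, fp = n_calls, fn = n_truth))
  o <- order(calls$chrom, calls$start, calls$end)
  calls <- calls[o, , drop = FALSE]
  matched <- rep(FALSE, n_truth)
  tlen <- truth$l1_end - truth$l1_start + 1L
  tp <- 0L
  for (i in seq_len(n_calls)) {
    ov <- pmin(calls$end[i], truth$l1_end) -
      pmax(calls$start[i], truth$l1_start) + 1L
    cand <- which(!matched & truth$chrom == calls$chrom[i] &
                    ov >= min_overlap * tlen &
                    (ignore_strand | truth$strand == calls$strand[i]))
    if (length(cand) == 0L) next
    best <- cand[order(-ov[cand], truth$l1_start[cand])][1L]
    matched[best] <- TRUE
    tp <- tp + 1L
  }
  list(tp = tp, fp = n_calls - tp, fn = n_truth - tp)
}

#' Evaluate calls against truth annotations
#'
#' @inheritParams match_calls
#' @return A list of class `EvalResult`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1` (zero-denominator cases yield 0).
#' @export
evaluate_calls <- function(calls, truth, min_overlap = 0.5,
                           ignore_strand = FALSE) {
  m <- match_calls(calls, truth, min_overlap, ignore_strand)
  precision <- if (m$tp + m$fp > 0L) m$tp / (m$tp + m$fp) else 0
  recall <- if (m$tp + m$fn > 0L) m$tp / (m$tp + m$fn) else 0
  structure(c(m, list(precision = precision, recall = recall,
                      f1 = f1_score(precision, recall))),
            class = "EvalResult")
}

#' Parameter-grid sweep
#'
#' Runs detection and evaluation for every (e, t, m) combination and reports
#' the best row by F1 (ties: higher precision, then lower e, t, m).
#'
#' @param genome Named character vector from [read_genome()].
#' @param probes Probe set `data.frame`.
#' @param meta Metadata from [read_metadata()] (list or records); also the
#'   truth set for evaluation.
#' @param e_values,t_values,m_values Integer vectors spanning the grid.
#' @param min_overlap,ignore_strand Passed to [evaluate_calls()].
#' @return A list with `table` (one row per combination: `k`, `e`, `t`, `m`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1`) and `best` (the argmax
#'   row).
#' @export
sweep_params <- function(genome, probes, meta, e_values, t_values, m_values,
                         min_overlap = 0.5, ignore_strand = FALSE) {
  records <- if (is.data.frame(meta)) meta else meta$records
  stopifnot(length(e_values) >= 1L, length(t_values) >= 1L,
            length(m_values) >= 1L)
  k <- probes$k[1L]
  rows <- list()
  for (e in sort(unique(as.integer(e_values)))) {
    hits <- map_probeset(genome, probes, e)
    for (t in sort(unique(as.integer(t_values)))) {
      for (m in sort(unique(as.integer(m_values)))) {
        calls <- detect_l1(genome, probes, records,
                           detection_params(e, t, m), hits = hits)
        ev <- evaluate_calls(calls, records, min_overlap, ignore_strand)
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, e = e, t = t, m = m, tp = ev$tp, fp = ev$fp, fn = ev$fn,
          precision = ev$precision, recall = ev$recall, f1 = ev$f1)
      }
    }
  }
  tab <- do.call(rbind, rows)
  o <- order(-tab$f1, -tab$precision, tab$e, tab$t, tab$m)
  list(table = tab, best = tab[o[1L], , drop = FALSE])
}

#' Write a sweep table as TSV
#'
#' Fractions are written 5-decimal fixed point.
#'
#' @param table Sweep table from [sweep_params()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sweep_tsv <- function(table, path) {
  out <- table
  for (col in c("precision", "recall", "f1"))
    out[[col]] <- sprintf("%.5f", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
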