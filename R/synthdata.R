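# Seeded simulator of L1Base2-like fixtures: one ancestral full-length
# element, diverged intact and 5'-truncated copies planted on both strands of
# a random host genome, the true per-ORF alignments, and truth metadata
# (CSV schema) plus truth GFF3.  Every mutation is recorded so tests can
# audit the planted divergence exactly.

#' Simulation configuration
#'
#' Defaults describe the fixture conditions used throughout the package's
#' validation: 30 intact copies of a human-like 6,011 bp element (component
#' lengths 900/1017/63/3825/206), 1% substitution rate, light indels
#' (rate 2e-4, geometric lengths with mean 2), and 5 heavily 5'-truncated
#' copies (fraction removed uniform in 0.6-0.9) that serve as negatives for
#' full-length detection.
#'
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param genome_length Host genome length in bp.
#' @param n_intact,n_truncated Number of intact / 5'-truncated copies.
#' @param len_5utr,len_orf1,len_spacer,len_orf2,len_3utr Ancestral component
#'   lengths in bp.
#' @param sub_rate Per-base substitution probability per copy.
#' @param indel_rate Per-base indel event probability per copy.
#' @param indel_mean_len Mean of the geometric indel length distribution.
#' @param truncation_range Fraction of the copy's 5' end removed for
#'   truncated copies, drawn uniformly from this range.
#' @param gc_content GC fraction of the background sequence.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, genome_length = 400000L,
                       n_intact = 30L, n_truncated = 5L,
                       len_5utr = 900L, len_orf1 = 1017L, len_spacer = 63L,
                       len_orf2 = 3825L, len_3utr = 206L,
                       sub_rate = 0.01, indel_rate = 2e-4,
                       indel_mean_len = 2, truncation_range = c(0.6, 0.9),
                       gc_content = 0.42) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_intact = as.integer(n_intact),
              n_truncated = as.integer(n_truncated),
              len_5utr = as.integer(len_5utr),
              len_orf1 = as.integer(len_orf1),
              len_spacer = as.integer(len_spacer),
              len_orf2 = as.integer(len_orf2),
              len_3utr = as.integer(len_3utr),
              sub_rate = sub_rate, indel_rate = indel_rate,
              indel_mean_len = indel_mean_len,
              truncation_range = truncation_range,
              gc_content = gc_content)
  stopifnot(cfg$sub_rate >= 0, cfg$sub_rate < 1,
            cfg$indel_rate >= 0, cfg$indel_rate < 1,
            cfg$indel_mean_len >= 1,
            length(cfg$truncation_range) == 2L,
            cfg$truncation_range[1L] > 0, cfg$truncation_range[2L] < 1,
            cfg$truncation_range[1L] <= cfg$truncation_range[2L],
            cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$n_intact >= 2L, cfg$n_truncated >= 0L,
            all(c(cfg$len_5utr, cfg$len_orf1, cfg$len_spacer,
                  cfg$len_orf2, cfg$len_3utr) > 0L))
  cfg$element_length <- cfg$len_5utr + cfg$len_orf1 + cfg$len_spacer +
    cfg$len_orf2 + cfg$len_3utr
  if (cfg$genome_length <=
      (cfg$n_intact + cfg$n_truncated) * cfg$element_length)
    stop("genome_length must exceed the total planted element length")
  class(cfg) <- "SimConfig"
  cfg
}

rand_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Mutate the ancestral element once: substitutions then indels, positions
# sampled without replacement.  A deletion is clipped so it never touches
# another sampled mutation position, which keeps the recorded history exactly
# recoverable from the resulting alignment.
mutate_copy <- function(anc, cfg) {
  L <- length(anc)
  nsub <- stats::rbinom(1L, L, cfg$sub_rate)
  nind <- stats::rbinom(1L, L, cfg$indel_rate)
  posm <- sample.int(L, nsub + nind)
  subpos <- posm[seq_len(nsub)]
  indpos <- posm[nsub + seq_len(nind)]
  emit <- anc
  ins <- character(L)
  ins[] <- ""
  hist <- list()
  for (p in subpos) {
    nb <- sample(setdiff(DNA_BASES, anc[p]), 1L)
    emit[p] <- nb
    hist[[length(hist) + 1L]] <- data.frame(
      type = "sub", pos = p, len = 1L, detail = nb,
      stringsAsFactors = FALSE)
  }
  if (nind > 0L) {
    types <- sample(c("ins", "del"), nind, replace = TRUE)
    lens <- stats::rgeom(nind, 1 / cfg$indel_mean_len) + 1L
    allpos <- sort(posm)
    for (q in seq_len(nind)) {
      p <- indpos[q]
      if (types[q] == "ins") {
        s <- paste(sample(DNA_BASES, lens[q], replace = TRUE),
                   collapse = "")
        ins[p] <- s
        hist[[length(hist) + 1L]] <- data.frame(
          type = "ins", pos = p, len = lens[q], detail = s,
          stringsAsFactors = FALSE)
      } else {
        nxt <- allpos[allpos > p]
        lim <- if (length(nxt) > 0L) nxt[1L] - p - 1L else L - p + 1L
        ld <- min(lens[q], lim, L - p + 1L)
        if (ld < 1L) next
        emit[p:(p + ld - 1L)] <- ""
        hist[[length(hist) + 1L]] <- data.frame(
          type = "del", pos = p, len = ld, detail = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  history <- if (length(hist) > 0L) do.call(rbind, hist) else
    data.frame(type = character(), pos = integer(), len = integer(),
               detail = character(), stringsAsFactors = FALSE)
  history <- history[order(history$pos, history$type), , drop = FALSE]
  rownames(history) <- NULL
  blocks <- paste0(emit, ins)
  list(seq = paste(blocks, collapse = ""), emit = emit, ins = ins,
       ends = cumsum(nchar(blocks)), history = history)
}

# 1-based copy coordinates of an ancestral component [cs, ce]; insertions
# after an ancestral position belong to the component containing it
component_in_copy <- function(copy, cs, ce) {
  start <- (if (cs == 1L) 0L else copy$ends[cs - 1L]) + 1L
  end <- copy$ends[ce]
  if (end < start)
    stop("simulated copy lost an entire component; ",
         "lower the mutation rates")
  c(start, end)
}

msa_rows <- function(copies, anc, positions) {
  widths <- rep(0L, length(positions))
  for (cp in copies)
    widths <- pmax(widths, nchar(cp$ins[positions]))
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  rows <- vapply(copies, function(cp) {
    em <- cp$emit[positions]
    em[!nzchar(em)] <- "-"
    paste(paste0(em, pad(cp$ins[positions], widths)), collapse = "")
  }, character(1L))
  anc_row <- paste(paste0(anc[positions], strrep("-", widths)),
                   collapse = "")
  list(rows = rows, anc = anc_row)
}

#' Simulate a host genome with planted L1 copies
#'
#' Deterministic for a fixed seed.  Copies are placed non-overlapping with
#' at least 10 bp of background between them, strand chosen 50/50; truncated
#' copies lose a 5' prefix covering (at least) the 5'UTR and part of ORF1
#' and appear in the genome and the truth table but not in the intact
#' metadata used as detection truth.
#'
#' @param cfg A `SimConfig` from [sim_config()].
#' @return A list of class `SimTruth`: `config`, `ancestor`, `genome`
#'   (named character vector), `meta` (intact-copy metadata in the CSV
#'   schema), `truth` (all planted copies with a `truncated` flag),
#'   `orf_seqs` (per-ORF sequences of the intact copies), `msa` (true
#'   per-ORF alignments of the intact copies), `copies` (planted sequences),
#'   `history` (per-copy mutation log) and `align` (per-copy alignment
#'   bookkeeping used by [mutation_audit()]).
#' @export
simulate_l1_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed, simulate_impl(cfg))
}

simulate_impl <- function(cfg) {
  anc <- strsplit(rand_dna(cfg$element_length, cfg$gc_content), "")[[1L]]
  n_total <- cfg$n_intact + cfg$n_truncated
  ids <- c(sprintf("L1_intact_%02d", seq_len(cfg$n_intact)),
           if (cfg$n_truncated > 0L)
             sprintf("L1_trunc_%02d", seq_len(cfg$n_truncated)))
  copies <- lapply(seq_len(n_total), function(i) mutate_copy(anc, cfg))
  names(copies) <- ids
  # component boundaries in ancestral coordinates (1-based inclusive)
  b <- cumsum(c(cfg$len_5utr, cfg$len_orf1, cfg$len_spacer, cfg$len_orf2,
                cfg$len_3utr))
  comp_anc <- list(utr5 = c(1L, b[1L]), orf1 = c(b[1L] + 1L, b[2L]),
                   orf2 = c(b[3L] + 1L, b[4L]), utr3 = c(b[4L] + 1L, b[5L]))
  comp_copy <- lapply(copies, function(cp)
    lapply(comp_anc, function(ab) component_in_copy(cp, ab[1L], ab[2L])))
  planted <- vapply(copies, `[[`, character(1L), "seq")
  truncated <- rep(c(FALSE, TRUE), c(cfg$n_intact, cfg$n_truncated))
  cut_bp <- integer(n_total)
  if (cfg$n_truncated > 0L) {
    fr <- stats::runif(cfg$n_truncated, cfg$truncation_range[1L],
                       cfg$truncation_range[2L])
    idx <- which(truncated)
    cut_bp[idx] <- as.integer(floor(fr * nchar(planted[idx])))
    planted[idx] <- substring(planted[idx], cut_bp[idx] + 1L)
  }
  strands <- sample(c("+", "-"), n_total, replace = TRUE)
  # placement: shuffled copy order, random background gaps >= 10 bp
  ord <- sample.int(n_total)
  li <- nchar(planted)[ord]
  free <- cfg$genome_length - sum(li)
  min_gap <- 10L
  if (free < min_gap * (n_total + 1L))
    stop("genome_length leaves no room for inter-copy gaps")
  r <- stats::runif(n_total + 1L)
  gaps <- min_gap + floor((free - min_gap * (n_total + 1L)) * r / sum(r))
  gaps[n_total + 1L] <- gaps[n_total + 1L] +
    (cfg$genome_length - sum(li) - sum(gaps))
  pieces <- character(2L * n_total + 1L)
  start_g <- integer(n_total)
  cur <- 0L
  for (q in seq_len(n_total)) {
    pieces[2L * q - 1L] <- rand_dna(gaps[q], cfg$gc_content)
    cur <- cur + gaps[q]
    start_g[q] <- cur + 1L
    i <- ord[q]
    pieces[2L * q] <- if (strands[i] == "+") planted[i] else
      revcomp(planted[i])
    cur <- cur + li[q]
  }
  pieces[2L * n_total + 1L] <- rand_dna(gaps[n_total + 1L], cfg$gc_content)
  genome <- c(chr1 = paste(pieces, collapse = ""))
  l1_start <- integer(n_total)
  l1_start[ord] <- start_g
  l1_end <- l1_start + nchar(planted) - 1L
  truth <- data.frame(copy_id = ids, chrom = "chr1", start = l1_start,
                      end = l1_end, strand = strands,
                      truncated = truncated, cut_bp = cut_bp,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  ii <- which(!truncated)
  meta <- data.frame(
    chrom = "chr1", l1_start = l1_start[ii], l1_end = l1_end[ii],
    strand = strands[ii],
    utr5_start = vapply(comp_copy[ii], function(x) x$utr5[1L], integer(1L)),
    utr5_end = vapply(comp_copy[ii], function(x) x$utr5[2L], integer(1L)),
    orf1_start = vapply(comp_copy[ii], function(x) x$orf1[1L], integer(1L)),
    orf1_end = vapply(comp_copy[ii], function(x) x$orf1[2L], integer(1L)),
    orf2_start = vapply(comp_copy[ii], function(x) x$orf2[1L], integer(1L)),
    orf2_end = vapply(comp_copy[ii], function(x) x$orf2[2L], integer(1L)),
    utr3_start = vapply(comp_copy[ii], function(x) x$utr3[1L], integer(1L)),
    utr3_end = vapply(comp_copy[ii], function(x) x$utr3[2L], integer(1L)),
    stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  orf_seqs <- lapply(c(orf1 = "orf1", orf2 = "orf2"), function(cn) {
    s <- vapply(ii, function(i)
      substring(copies[[i]]$seq, comp_copy[[i]][[cn]][1L],
                comp_copy[[i]][[cn]][2L]), character(1L))
    names(s) <- ids[ii]
    s
  })
  msa <- lapply(c(orf1 = "orf1", orf2 = "orf2"), function(cn) {
    ab <- comp_anc[[cn]]
    r <- msa_rows(copies[ii], anc, ab[1L]:ab[2L])
    names(r$rows) <- ids[ii]
    r$rows
  })
  structure(list(
    config = cfg, ancestor = paste(anc, collapse = ""), genome = genome,
    meta = meta, truth = truth, orf_seqs = orf_seqs, msa = msa,
    copies = planted,
    history = lapply(copies, `[[`, "history"),
    align = lapply(copies, function(cp) cp[c("emit", "ins")])),
    class = "SimTruth")
}

#' Audit the planted divergence of a simulation
#'
#' Recomputes per-copy substitution and indel counts from the stored
#' ancestor/copy alignment (column-wise, without consulting the event log),
#' so tests can check them against the recorded mutation history.
#'
#' @param truth A `SimTruth` from [simulate_l1_genome()].
#' @return A `data.frame` with one row per copy: `copy_id`, `n_sub`,
#'   `n_ins`, `n_del`, `ins_bases`, `del_bases`.
#' @export
mutation_audit <- function(truth) {
  stopifnot(inherits(truth, "SimTruth"))
  anc <- strsplit(truth$ancestor, "")[[1L]]
  rows <- lapply(names(truth$align), function(id) {
    al <- truth$align[[id]]
    present <- nzchar(al$emit)
    n_sub <- sum(present & al$emit != anc)
    d <- rle(!present)
    n_del <- sum(d$values)
    del_bases <- sum(d$lengths[d$values])
    has_ins <- nzchar(al$ins)
    data.frame(copy_id = id, n_sub = n_sub, n_ins = sum(has_ins),
               n_del = n_del, ins_bases = sum(nchar(al$ins)),
               del_bases = del_bases, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulation's fixture files
#'
#' Emits the formats the rest of the tool consumes: `genome.fa`, `meta.csv`
#' (intact copies, CSV schema), `truth.gff3` (all copies, truncated ones
#' flagged), per-ORF FASTA of the intact copies and their true alignments.
#'
#' @param truth A `SimTruth`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "SimTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(truth$genome)
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"), width = 80L)
  utils::write.csv(truth$meta, file.path(dir, "meta.csv"),
                   row.names = FALSE, quote = FALSE)
  lines <- c("##gff-version 3", sprintf(
    "%s\tL1PD_sim\tmobile_genetic_element\t%d\t%d\t.\t%s\t.\t%s",
    truth$truth$chrom, truth$truth$start, truth$truth$end,
    truth$truth$strand,
    sprintf("Name=LINE1;ID=%s;truncated=%s", truth$truth$copy_id,
            ifelse(truth$truth$truncated, "true", "false"))))
  writeLines(lines, file.path(dir, "truth.gff3"))
  for (cn in c("orf1", "orf2")) {
    s <- Biostrings::DNAStringSet(truth$orf_seqs[[cn]])
    Biostrings::writeXStringSet(s, file.path(dir, paste0(cn, ".fa")),
                                width = 80L)
    a <- Biostrings::BStringSet(truth$msa[[cn]])
    Biostrings::writeXStringSet(a, file.path(dir, paste0(cn, "_msa.fa")),
                                width = 80L)
  }
  invisible(dir)
}
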