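# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use different machinery from the implementation:
# utils::adist window sweeps for approximate matching, and exhaustive
# recursion for chain selection.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_subs <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[p]), 1)
  paste(ch, collapse = "")
}

# Brute-force semi-global matcher: per end position the best global edit
# distance over all windows, then the same transitive end-clustering and
# (min distance, leftmost start, leftmost end) collapsing rule.
oracle_find_matches <- function(text, pat, e) {
  n <- nchar(text)
  k <- nchar(pat)
  best_d <- rep(e + 1L, n)
  best_s <- rep(NA_integer_, n)
  for (s in 1:n) {
    for (L in max(1, k - e):(k + e)) {
      j <- s + L - 1
      if (j > n) next
      d <- utils::adist(pat, substr(text, s, j))[1, 1]
      if (d < best_d[j]) {
        best_d[j] <- d
        best_s[j] <- s - 1L
      }
    }
  }
  q <- which(best_d <= e)
  out <- list()
  while (length(q) > 0) {
    j <- q[1]
    ends <- j
    last <- j
    kk <- j + 1
    while (kk <= n && kk - last <= e) {
      if (best_d[kk] <= e) { ends <- c(ends, kk); last <- kk }
      kk <- kk + 1
    }
    dmin <- min(best_d[ends])
    cand <- ends[best_d[ends] == dmin]
    ss <- best_s[cand]
    pick <- which(ss == min(ss))
    pick <- pick[which.min(cand[pick])]
    out[[length(out) + 1]] <- data.frame(
      pos = as.integer(ss[pick]), edit_distance = as.integer(dmin),
      matched_len = as.integer(cand[pick] - ss[pick]))
    q <- q[q > last + e]
  }
  if (length(out) == 0)
    return(data.frame(pos = integer(), edit_distance = integer(),
                      matched_len = integer()))
  do.call(rbind, out)
}

# ---- chain enumeration oracle --------------------------------------------

chain_gap_cost <- function(pos, probe, offsets, i, j) {
  abs((pos[j] - pos[i]) - (offsets[probe[j] + 1] - offsets[probe[i] + 1]))
}

chain_err <- function(chain, pos, probe, offsets) {
  if (length(chain) < 2) return(0)
  sum(vapply(seq_len(length(chain) - 1), function(q)
    chain_gap_cost(pos, probe, offsets, chain[q], chain[q + 1]),
    numeric(1)))
}

# all valid chains (every prefix is itself valid) over alive hits
enumerate_chains <- function(pos, probe, offsets, t, alive) {
  ord <- order(pos, probe)
  res <- list()
  rec <- function(chain) {
    res[[length(res) + 1]] <<- chain
    last <- chain[length(chain)]
    for (j in ord) {
      if (!alive[j] || j %in% chain) next
      if (pos[j] <= pos[last] || probe[j] <= probe[last]) next
      if (chain_gap_cost(pos, probe, offsets, last, j) <= t)
        rec(c(chain, j))
    }
  }
  for (s in ord) if (alive[s]) rec(s)
  res
}

# TRUE if chain a is strictly preferred: longer, then smaller gap error,
# then lexicographically smaller (pos, then probe) sequence
chain_better <- function(a, b, pos, probe, offsets) {
  if (length(a) != length(b)) return(length(a) > length(b))
  ea <- chain_err(a, pos, probe, offsets)
  eb <- chain_err(b, pos, probe, offsets)
  if (ea != eb) return(ea < eb)
  for (q in seq_along(a)) {
    if (pos[a[q]] != pos[b[q]]) return(pos[a[q]] < pos[b[q]])
    if (probe[a[q]] != probe[b[q]]) return(probe[a[q]] < probe[b[q]])
  }
  FALSE
}

# accepted chains under round-based selection with consumption
oracle_chain_rounds <- function(pos, probe, offsets, t, m) {
  alive <- rep(TRUE, length(pos))
  accepted <- list()
  repeat {
    if (!any(alive)) break
    chains <- enumerate_chains(pos, probe, offsets, t, alive)
    best <- NULL
    for (ch in chains)
      if (is.null(best) || chain_better(ch, best, pos, probe, offsets))
        best <- ch
    if (is.null(best) || length(best) < m) break
    accepted[[length(accepted) + 1]] <- best
    alive[best] <- FALSE
  }
  accepted
}

# ---- fixture builders -----------------------------------------------------

# hit table on one chromosome's forward strand from (pos, probe index) pairs
hits_from_pairs <- function(pos, probe_idx, probes, matched_len = NULL) {
  if (is.null(matched_len)) matched_len <- rep(probes$k[1], length(pos))
  data.frame(probe_id = probes$probe_id[probe_idx + 1], chrom = "chr1",
             pos = as.integer(pos), strand = "+",
             edit_distance = 0L, matched_len = as.integer(matched_len),
             stringsAsFactors = FALSE)
}

toy_probes <- function(offsets, k = 50) {
  L1PD:::new_probeset(orf = rep(1L, length(offsets)), k = k,
                      offset = offsets,
                      sequence = vapply(seq_along(offsets),
                                        function(i) rand_seq(k),
                                        character(1)))
}

# single-row metadata data.frame in the CSV schema
meta_row <- function(chrom, l1_start, l1_end, strand,
                     utr5 = c(1, 150), orf1 = c(151, 450),
                     orf2 = c(471, 1070), utr3 = c(1071, 1120)) {
  data.frame(chrom = chrom, l1_start = l1_start, l1_end = l1_end,
             strand = strand,
             utr5_start = utr5[1], utr5_end = utr5[2],
             orf1_start = orf1[1], orf1_end = orf1[2],
             orf2_start = orf2[1], orf2_end = orf2[2],
             utr3_start = utr3[1], utr3_end = utr3[2],
             stringsAsFactors = FALSE)
}

# a controlled zero-divergence reference: identical element copies planted
# in a random genome, with handmade metadata
zero_div_fixture <- function(seed, n_copies = 3, k = 20) {
  set.seed(seed)
  element <- rand_seq(1120)
  gaps <- replicate(n_copies + 1, rand_seq(300))
  genome <- gaps[1]
  meta <- NULL
  for (i in seq_len(n_copies)) {
    start <- nchar(genome) + 1
    genome <- paste0(genome, element, gaps[i + 1])
    meta <- rbind(meta, meta_row("chr1", start, start + 1119, "+"))
  }
  list(genome = c(chr1 = genome), element = element, meta = meta, k = k)
}

# small simulated fixture shared by several tests
small_sim <- function(seed = 3, n_intact = 30, n_truncated = 3,
                      sub_rate = 0.01, indel_rate = 2e-4) {
  sim_config(seed = seed, genome_length = 250000, n_intact = n_intact,
             n_truncated = n_truncated, len_5utr = 300, len_orf1 = 500,
             len_spacer = 30, len_orf2 = 900, len_3utr = 80,
             sub_rate = sub_rate, indel_rate = indel_rate)
}

fixture_detection_params <- function(probes) {
  detection_params(e = 5, t = 50, m = max(2L, ceiling(0.6 * nrow(probes))))
}
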