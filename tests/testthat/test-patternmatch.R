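# Hit chaining, duplicate suppression and boundary extrapolation, checked
# against an exhaustive chain-enumeration oracle on small instances.

test_that("the distance predicate compares observed and expected gaps", {
  expect_true(distance_ok(10000, 10500, 0, 500, 0))
  expect_false(distance_ok(10000, 10560, 0, 500, 50))   # deviation 60
  expect_true(distance_ok(10000, 10560, 0, 500, 625))   # default human t
})

test_that("perfect constellations chain into one pattern, short ones never", {
  probes <- toy_probes(c(0L, 500L, 1100L, 1800L, 2600L), k = 50)
  params <- detection_params(e = 0, t = 0, m = 3)
  hits <- hits_from_pairs(1000 + probes$offset, 0:4, probes)
  pats <- chain_hits(hits, probes, params)
  expect_length(pats, 1)
  expect_equal(pats[[1]]$n_probes, 5)
  expect_equal(pats[[1]]$gap_error_sum, 0)
  expect_equal(pats[[1]]$anchor_pos, 1000)

  # m - 1 hits present: no pattern
  pats2 <- chain_hits(hits[1:2, ], probes, params)
  expect_length(pats2, 0)
})

test_that("chains skip missing probes and absorb indel drift within t", {
  probes <- toy_probes(c(0L, 500L, 1100L, 1800L, 2600L), k = 50)
  # probe 2 (offset 500) deleted; +40 insertion before probe 4
  pos <- 5000 + c(0, 1100, 1800 + 40, 2600 + 40)
  idx <- c(0L, 2L, 3L, 4L)
  hits <- hits_from_pairs(pos, idx, probes)
  params <- detection_params(e = 0, t = 50, m = 3)
  pats <- chain_hits(hits, probes, params)
  expect_length(pats, 1)
  expect_equal(pats[[1]]$n_probes, 4)
  expect_equal(pats[[1]]$gap_error_sum, 40)
  # matches the exhaustive enumeration oracle
  oracle <- oracle_chain_rounds(pos, idx, probes$offset, t = 50, m = 3)
  expect_length(oracle, 1)
  expect_identical(sort(hits$pos[oracle[[1]]]), sort(pats[[1]]$hits$pos))
})

test_that("accepted patterns equal the exhaustive oracle on random instances", {
  set.seed(911)
  probes <- toy_probes(seq(0L, 2200L, by = 200L), k = 50)
  for (i in 1:40) {
    nh <- sample(4:11, 1)
    idx <- sort(sample(0:11, nh, replace = TRUE))
    jitter <- sample(-80:80, nh, replace = TRUE)
    pos <- 3000 + probes$offset[idx + 1] + jitter
    o <- order(pos, idx)
    keep <- !duplicated(data.frame(pos[o], idx[o]))
    pos <- pos[o][keep]; idx <- idx[o][keep]
    t <- sample(c(20, 60, 120), 1)
    m <- sample(2:3, 1)
    got <- chain_hits(hits_from_pairs(pos, idx, probes), probes,
                      detection_params(0, t, m))
    want <- oracle_chain_rounds(pos, idx, probes$offset, t, m)
    expect_equal(length(got), length(want), label = paste("instance", i))
    for (q in seq_along(want)) {
      expect_identical(got[[q]]$hits$pos, as.integer(pos[want[[q]]]),
                       label = paste("instance", i, "pattern", q))
    }
  }
})

test_that("duplicate patterns over one locus are suppressed by priority", {
  base <- data.frame(chrom = "chr1", start = 1000L, end = 7000L,
                     strand = "+", stringsAsFactors = FALSE)
  a <- transform(base, n_probes = 9L, gap_error_sum = 5)
  b <- transform(base, n_probes = 7L, gap_error_sum = 0)
  out <- dedupe_patterns(rbind(a, b))
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_probes, 9L)             # more probes wins

  # disjoint intervals: both kept
  c2 <- transform(a, start = 20000L, end = 26000L)
  expect_equal(nrow(dedupe_patterns(rbind(a, c2))), 2L)

  # full tie: leftmost kept
  d1 <- transform(base, n_probes = 5L, gap_error_sum = 2)
  d2 <- transform(d1, start = 1400L, end = 7400L)
  out2 <- dedupe_patterns(rbind(d2, d1))
  expect_equal(out2$start, 1000L)

  # smaller gap error breaks the probe-count tie
  e1 <- transform(base, n_probes = 5L, gap_error_sum = 9)
  e2 <- transform(base, n_probes = 5L, gap_error_sum = 1)
  expect_equal(dedupe_patterns(rbind(e1, e2))$gap_error_sum, 1)
})

test_that("call boundaries extrapolate from the anchor via component modes", {
  model <- structure(list(mode_5utr = 900L, mode_orf1 = 1017L,
                          mode_spacer = 63L, mode_orf2 = 3825L,
                          mode_3utr = 206L, mode_total = 6000L,
                          mode_orf1start_to_orf2start = 1080L),
                     class = "ComponentLengthModel")
  probes <- toy_probes(c(120L, 500L), k = 50)
  mk_pattern <- function(pos, strand) {
    hits <- data.frame(probe_id = probes$probe_id, chrom = "chr1",
                       pos = pos, strand = strand, edit_distance = 0L,
                       matched_len = 50L, stringsAsFactors = FALSE)
    list(chrom = "chr1", strand = strand, hits = hits, n_probes = 2L,
         gap_error_sum = 0, anchor_pos = min(pos))
  }
  call <- call_from_pattern(mk_pattern(c(10000L, 10380L), "+"), probes,
                            model, 100000L)
  expect_equal(call$start, 8981L)
  expect_equal(call$end, 14980L)

  # clamping at the chromosome edge
  call2 <- call_from_pattern(mk_pattern(c(50L, 430L), "+"), probes,
                             model, 100000L)
  expect_equal(call2$start, 1L)

  # minus strand mirror formula
  call3 <- call_from_pattern(mk_pattern(c(10380L, 10000L), "-"), probes,
                             model, 100000L)
  expect_equal(call3$end, 10380L + 49L + 120L + 900L + 1L)
  expect_equal(call3$end - call3$start + 1L, 6000L)
})

test_that("pattern validity is monotone in t and m", {
  set.seed(912)
  probes <- toy_probes(seq(0L, 1500L, by = 300L), k = 50)
  valid_chain <- function(pos, idx, t, m) {
    length(pos) >= m &&
      all(vapply(seq_len(length(pos) - 1), function(q)
        distance_ok(pos[q], pos[q + 1], probes$offset[idx[q] + 1],
                    probes$offset[idx[q + 1] + 1], t), logical(1)))
  }
  for (i in 1:50) {
    nh <- sample(3:6, 1)
    idx <- sort(sample(0:5, nh))
    pos <- 2000 + probes$offset[idx + 1] +
      sample(-70:70, nh, replace = TRUE)
    if (is.unsorted(pos, strictly = TRUE)) next
    t <- sample(0:100, 1); m <- sample(2:nh, 1)
    if (valid_chain(pos, idx, t, m)) {
      expect_true(valid_chain(pos, idx, t + sample(0:100, 1), m))
      expect_true(valid_chain(pos, idx, t, sample(2:m, 1)))
    }
  }
})

test_that("chaining is invariant to the input order of hits", {
  set.seed(913)
  probes <- toy_probes(seq(0L, 1200L, by = 300L), k = 50)
  pos <- 4000 + probes$offset + sample(-20:20, 5)
  hits <- hits_from_pairs(pos, 0:4, probes)
  params <- detection_params(0, 60, 3)
  ref <- chain_hits(hits, probes, params)
  for (r in 1:5) {
    shuf <- hits[sample(nrow(hits)), ]
    expect_identical(chain_hits(shuf, probes, params), ref)
  }
})

test_that("detection is strand-symmetric on a simulated genome", {
  tr <- simulate_l1_genome(small_sim(seed = 21, n_intact = 12,
                                     n_truncated = 0))
  probes <- generate_probes(msa_block(tr$msa$orf1, 1),
                            msa_block(tr$msa$orf2, 2),
                            tr$genome, tr$meta, k = 50, identity = 0.9)
  params <- fixture_detection_params(probes)
  calls <- detect_l1(tr$genome, probes, tr$meta, params)
  L <- nchar(tr$genome[["chr1"]])
  rc_genome <- c(chr1 = revcomp(tr$genome[["chr1"]]))
  calls_rc <- detect_l1(rc_genome, probes, tr$meta, params)
  mirrored <- data.frame(chrom = calls_rc$chrom,
                         start = L - calls_rc$end + 1L,
                         end = L - calls_rc$start + 1L,
                         strand = ifelse(calls_rc$strand == "+", "-", "+"),
                         n_probes = calls_rc$n_probes,
                         gap_error_sum = calls_rc$gap_error_sum,
                         stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$chrom, mirrored$start), ]
  rownames(mirrored) <- NULL
  expect_identical(mirrored, calls)
})

test_that("negative controls produce no calls", {
  set.seed(914)
  tr <- simulate_l1_genome(small_sim(seed = 22, n_intact = 12,
                                     n_truncated = 0))
  probes <- generate_probes(msa_block(tr$msa$orf1, 1),
                            msa_block(tr$msa$orf2, 2),
                            tr$genome, tr$meta, k = 50, identity = 0.9)
  params <- fixture_detection_params(probes)
  # random genome with nothing planted
  empty <- c(chr1 = rand_seq(60000))
  expect_equal(nrow(detect_l1(empty, probes, tr$meta, params)), 0L)
  # a genome holding only one truncated copy (5'UTR and most of ORF1 gone):
  # fewer than m probes remain, so no call
  cp <- tr$copies[[1]]
  trunc <- substring(cp, floor(0.65 * nchar(cp)))
  g1 <- c(chr1 = paste0(rand_seq(3000), trunc, rand_seq(3000)))
  expect_equal(nrow(detect_l1(g1, probes, tr$meta, params)), 0L)
})

test_that("detection works from imported SAM hits", {
  probes <- toy_probes(c(0L, 500L, 1100L), k = 50)
  meta <- meta_row("chr1", 1, 1120, "+")
  genome <- c(chr1 = strrep("A", 30000))
  sam <- withr::local_tempfile(fileext = ".sam")
  rec <- function(qname, pos) paste(
    c(qname, 0, "chr1", pos, 60, "50M", "*", 0, 0, strrep("A", 50),
      "*", "NM:i:0"), collapse = "\t")
  writeLines(c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:chr1\tLN:30000",
               rec("L1PD_probe_1", 10001), rec("L1PD_probe_2", 10501),
               rec("L1PD_probe_3", 11101)), sam)
  hits <- read_sam_hits(sam, probes)
  calls <- detect_l1(genome, probes, meta, detection_params(0, 10, 3),
                     hits = hits)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_probes, 3L)
  expect_identical(calls$strand, "+")
})
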