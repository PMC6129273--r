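test_that("find_mems returns the exact maximal-match set", {
  expect_equal(find_mems("ACGTACGT", "ACGT", 4),
               data.frame(ref_start = c(0L, 4L), query_start = c(0L, 0L),
                          length = c(4L, 4L)))
  expect_equal(find_mems("AAAA", "AAAA", 4),
               data.frame(ref_start = 0L, query_start = 0L, length = 4L))
  expect_identical(nrow(find_mems("AAAA", "CCCC", 1)), 0L)
  # N terminates matches and never seeds
  expect_identical(nrow(find_mems("ANA", "ANA", 2)), 0L)
  expect_equal(find_mems("AANAA", "AA", 2)$ref_start, c(0L, 3L))
})

test_that("find_mems equals the brute-force diagonal oracle", {
  set.seed(42)
  for (i in 1:60) {
    x <- random_dna_str(sample(10:200, 1))
    y <- random_dna_str(sample(10:200, 1))
    for (lmin in c(3L, 5L, 8L))
      expect_equal(find_mems(x, y, lmin), mem_oracle(x, y, lmin))
  }
  # and with N-containing sequences
  for (i in 1:20) {
    x <- random_dna_str(sample(20:120, 1), c("A", "C", "G", "T", "N"))
    y <- random_dna_str(sample(20:120, 1), c("A", "C", "G", "T", "N"))
    expect_equal(find_mems(x, y, 3), mem_oracle(x, y, 3))
  }
})

test_that("find_mems output is independent of the worker count", {
  set.seed(17)
  x <- random_dna_str(20000)
  y <- plant_edits(x, 400L)
  a1 <- find_mems(x, y, 8, threads = 1)
  a3 <- find_mems(x, y, 8, threads = 3)
  expect_identical(a1, a3)
  expect_gt(nrow(a1), 0L)
})

test_that("merge_anchors builds co-linear chains with edit-distance gap cost", {
  set.seed(3)
  s1 <- random_dna_str(10); s2 <- random_dna_str(10)
  x <- paste0(s1, "AC", s2)
  y <- paste0(s1, "GT", s2)
  p <- cne_params(10, 100, 0.8)
  anchors <- data.frame(ref_start = c(0L, 12L), query_start = c(0L, 12L),
                        length = c(10L, 10L))
  chains <- merge_anchors(anchors, x, y, p)
  expect_length(chains, 1L)
  expect_identical(chains[[1]]$ref_span, c(0L, 22L))
  expect_identical(chains[[1]]$query_span, c(0L, 22L))
  expect_identical(chains[[1]]$gap_edit, dp_edit("AC", "GT"))
  expect_identical(nrow(chains[[1]]$anchors), 2L)
})

test_that("a single long anchor forms its own chain; overlaps never merge", {
  set.seed(4)
  x <- random_dna_str(60)
  p <- cne_params(10, 100, 0.8)
  one <- data.frame(ref_start = 5L, query_start = 9L, length = 20L)
  chains <- merge_anchors(one, x, x, p)
  expect_length(chains, 1L)
  expect_identical(chains[[1]]$gap_edit, 0L)

  # ref-overlapping anchors stay in separate chains
  two <- data.frame(ref_start = c(0L, 5L), query_start = c(0L, 20L),
                    length = c(10L, 10L))
  chains <- merge_anchors(two, x, x, p)
  expect_length(chains, 2L)
  expect_true(all(vapply(chains, function(ch) nrow(ch$anchors), 0L) == 1L))
})

test_that("chains below the coverage bound or beyond max_len are dropped", {
  set.seed(6)
  x <- random_dna_str(700)
  p <- cne_params(100, 500, 0.9)  # coverage >= 50
  small <- data.frame(ref_start = 0L, query_start = 0L, length = 20L)
  expect_length(merge_anchors(small, x, x, p), 0L)
  # an exact 600 bp self-match exceeds u = 500: no reportable chain
  a600 <- find_mems(x, x, min_anchor_length(p))
  expect_true(any(a600$length >= 600))
  expect_length(merge_anchors(a600, x, x, p), 0L)
})

test_that("extension reports the whole element when the pair is identical", {
  set.seed(8)
  s <- random_dna_str(200)
  p <- cne_params(200, 500, 0.9)
  anchors <- find_mems(s, s, min_anchor_length(p))
  chains <- merge_anchors(anchors, s, s, p)
  expect_length(chains, 1L)
  hit <- extend_chain(chains[[1]], s, s, p)
  expect_identical(hit$ref_start, 0L)
  expect_identical(hit$ref_end, 200L)
  expect_identical(hit$edit_distance, 0L)
  expect_equal(hit$identity, 1.0)
})

test_that("extension stops at the hull when both flanks are dissimilar", {
  set.seed(12)
  core <- random_dna_str(20)
  x <- paste0("AAAAA", core, "AAAAA")
  y <- paste0("CCCCC", core, "CCCCC")
  p <- cne_params(20, 50, 0.9, min_chain_coverage = 10)
  chains <- merge_anchors(find_mems(x, y, 10), x, y, p)
  hit <- extend_chain(chains[[1]], region("x", 0L, x), region("y", 0L, y), p)
  expect_identical(c(hit$ref_start, hit$ref_end), c(5L, 25L))
  expect_identical(c(hit$query_start, hit$query_end), c(5L, 25L))
  expect_equal(hit$identity, 1.0)
})

test_that("a planted diverged segment is recovered and fully covered", {
  set.seed(19)
  ref <- random_dna_str(2000)
  seg <- substr(ref, 501, 800)                       # 300 bp
  seg_mut <- plant_edits(seg, 6L, indel_fraction = 0) # 2% substitutions
  qry <- paste0(random_dna_str(600), seg_mut, random_dna_str(600))
  p <- cne_params(200, 500, 0.9)
  hits <- discover_cnes(ref, qry, p)
  expect_identical(nrow(hits), 1L)
  # hit covers >= 95% of the planted interval on both sides
  ov_ref <- min(hits$ref_end, 800) - max(hits$ref_start, 500)
  ov_qry <- min(hits$query_end, 900) - max(hits$query_start, 600)
  expect_gte(ov_ref / 300, 0.95)
  expect_gte(ov_qry / 300, 0.95)
  # the planted pair itself is 98% identical; the reported (possibly
  # extended) hit must still verify at the threshold
  expect_gte(identity_score(seg, seg_mut), 0.98)
  expect_gte(hits$identity, 0.9)
  got <- hit_substrings(hits[1, ], c(ref = ref), c(query = qry))
  expect_equal(identity_score(got$ref, got$query), hits$identity)
})

test_that("dedup keeps one representative per reciprocal-overlap group", {
  h <- function(rs, re, qs, qe, id)
    data.frame(ref_name = "r", ref_start = rs, ref_end = re,
               query_name = "q", query_start = qs, query_end = qe,
               ref_len = re - rs, query_len = qe - qs,
               edit_distance = 0L, identity = id, query_strand = "+",
               stringsAsFactors = FALSE)
  # identical duplicates collapse
  expect_identical(nrow(dedup_hits(rbind(h(0, 300, 0, 300, 0.95),
                                         h(0, 300, 0, 300, 0.95)))), 1L)
  # disjoint hits are both kept
  expect_identical(nrow(dedup_hits(rbind(h(0, 300, 0, 300, 0.95),
                                         h(1000, 1300, 0, 300, 0.95)))), 2L)
  # higher identity wins within a group
  d <- dedup_hits(rbind(h(0, 300, 0, 300, 0.96), h(10, 310, 10, 310, 0.93)))
  expect_identical(nrow(d), 1L)
  expect_equal(d$identity, 0.96)
  # overlap in ref only is not grouped
  d2 <- dedup_hits(rbind(h(0, 300, 0, 300, 0.96), h(10, 310, 5000, 5300, 0.93)))
  expect_identical(nrow(d2), 2L)
})

test_that("t = 1 reports only character-identical pairs", {
  set.seed(23)
  shared <- random_dna_str(300)
  x <- paste0(random_dna_str(800), shared, random_dna_str(800))
  y <- paste0(random_dna_str(500), shared, random_dna_str(500))
  p <- cne_params(200, 500, 1.0)
  hits <- discover_cnes(x, y, p)
  expect_gte(nrow(hits), 1L)
  for (i in seq_len(nrow(hits))) {
    got <- hit_substrings(hits[i, ], c(ref = x), c(query = y))
    expect_identical(got$ref, got$query)
  }
})

test_that("all-N or empty inputs yield no hits", {
  p <- cne_params(20, 100, 0.9)
  expect_identical(nrow(discover_cnes(strrep("N", 500), "ACGTACGT", p)), 0L)
  expect_identical(nrow(discover_cnes("", "ACGT", p)), 0L)
})

test_that("reverse-complement search maps query coordinates back", {
  set.seed(29)
  seg <- random_dna_str(250)
  x <- paste0(random_dna_str(300), seg, random_dna_str(300))
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(seg, "")[[1]]), collapse = ""))
  y <- paste0(random_dna_str(200), rc, random_dna_str(200))
  p <- cne_params(200, 500, 0.95)
  expect_identical(nrow(discover_cnes(x, y, p)), 0L)
  hits <- discover_cnes(x, y, p, revcomp = TRUE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$query_strand, "-")
  # reported minus-strand interval, reverse-complemented, matches the ref
  got <- substr(y, hits$query_start + 1, hits$query_end)
  got_rc <- chartr("ACGT", "TGCA",
                   paste(rev(strsplit(got, "")[[1]]), collapse = ""))
  ref_sub <- substr(x, hits$ref_start + 1, hits$ref_end)
  expect_gte(identity_score(ref_sub, got_rc), 0.95)
})

test_that("raising t keeps soundness; lowering the anchor length keeps recovery", {
  d <- generate_pair(synth_spec(ref_len = 150000, query_len = 80000,
                                n_cne = 12, n_decoys = 3, seed = 77))
  for (t in c(0.9, 0.95)) {
    p <- cne_params(200, 500, t)
    hits <- discover_cnes(d$ref, d$query, p)
    for (i in seq_len(nrow(hits))) {
      got <- hit_substrings(hits[i, ], d$ref, d$query)
      expect_gte(identity_score(got$ref, got$query), t)
      expect_true(hits$ref_len[i] >= 200 && hits$ref_len[i] <= 500)
      expect_true(hits$query_len[i] >= 200 && hits$query_len[i] <= 500)
    }
  }
  p_lo <- cne_params(200, 500, 0.9)                    # anchors >= 9
  p_hi <- cne_params(200, 500, 0.9, anchor_len = 14)   # anchors >= 14
  s_lo <- score_recovery(discover_cnes(d$ref, d$query, p_lo), d$truth)
  s_hi <- score_recovery(discover_cnes(d$ref, d$query, p_hi), d$truth)
  expect_gte(s_lo$sensitivity, s_hi$sensitivity)
  expect_gte(s_lo$sensitivity, 0.9)
})
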