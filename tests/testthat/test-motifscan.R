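test_that("profile training follows the pseudocount closed form", {
  # identical ungapped sequences, no pseudocount, uniform background:
  # every consensus column scores log2(1/0.25) = 2 bits
  aln <- rep("ACGTAC", 10)
  m <- train_profile(aln, pseudocount = 0)
  expect_equal(m$length, 6L)
  cons <- match(strsplit(aln[1], "")[[1]], c("A", "C", "G", "T"))
  expect_equal(unname(m$bits[cbind(cons, 1:6)]), rep(2, 6))
  expect_equal(m$max_score, 12)

  # a column with equal counts of all four bases scores 0 for any base
  aln2 <- c("A", "C", "G", "T")
  m2 <- train_profile(aln2, pseudocount = 0)
  expect_equal(unname(m2$bits[, 1]), rep(0, 4))

  # pseudocount keeps absent bases finite (and negative)
  m3 <- train_profile(rep("A", 5), pseudocount = 0.5)
  expect_true(all(is.finite(m3$bits)))
  expect_true(all(m3$bits[2:4, 1] < 0))

  expect_error(train_profile("ACGT"), "at least 2")
  expect_error(train_profile(c("ACGT", "AC")), "equal length")

  # majority-gap columns are dropped
  m4 <- train_profile(c("A-C", "A-C", "AGC"), pseudocount = 0.5)
  expect_equal(m4$length, 2L)
})

test_that("window scores equal brute-force summation", {
  set.seed(51)
  train <- sim_motif_training(box_consensus(), seed = 510)
  prof <- train_profile(train)
  g <- rand_seq(2000)
  s_fast <- draftweaver:::window_scores(
    draftweaver:::encode_seq(g), prof$bits)
  s_brute <- brute_window_scores(g, prof$bits)
  expect_equal(s_fast, s_brute)
  # reported hits carry exactly these scores
  hits <- scan_profile(c(g = g), prof, min_bits = -20)
  expect_true(all(abs(hits$bits[hits$strand == "+"] -
                      s_brute[hits$start[hits$strand == "+"] + 1L]) < 1e-9))
})

test_that("planted consensus is the top hit; unreachable threshold empties", {
  set.seed(52)
  train <- sim_motif_training(box_consensus(), seed = 520)
  prof <- train_profile(train)
  consensus <- paste(c("A", "C", "G", "T")[apply(prof$bits, 2, which.max)],
                     collapse = "")
  g <- rand_seq(3000)
  substr(g, 1001, 1000 + nchar(consensus)) <- consensus
  hits <- scan_profile(c(g = g), prof, min_bits = 3)
  best <- hits[which.max(hits$bits), ]
  expect_equal(best$start, 1000L)
  expect_equal(best$bits, prof$max_score)
  expect_equal(nrow(scan_profile(c(g = g), prof,
                                 min_bits = prof$max_score + 1)), 0L)
})

test_that("scanning the reverse complement flips strands and coordinates", {
  set.seed(53)
  train <- sim_motif_training(box_consensus(), seed = 530)
  prof <- train_profile(train)
  cfg <- sim_config(genome_len = 20000L, n_genes = 8L, n_motifs = 6L,
                    seed = 531L)
  g <- plant_features(simulate_genome(cfg), cfg, profile = prof)$genome
  fwd <- scan_profile(c(g = g), prof, min_bits = 3)
  rev <- scan_profile(c(g = rc(g)), prof, min_bits = 3)
  L <- nchar(g)
  expect_equal(nrow(fwd), nrow(rev))
  key_f <- paste(fwd$start, fwd$strand)
  key_r <- paste(L - rev$end, ifelse(rev$strand == "+", "-", "+"))
  expect_setequal(key_f, key_r)
  expect_equal(sort(fwd$bits), sort(rev$bits))
})

test_that("planted motifs are recovered with few background hits", {
  train <- sim_motif_training(box_consensus(), seed = 1)
  prof <- train_profile(train, background = c(A = 0.2, C = 0.3,
                                              G = 0.3, T = 0.2))
  cfg <- sim_config(genome_len = 100000L, gc = 0.6, n_genes = 30L,
                    n_motifs = 20L, seed = 77L)
  pf <- plant_features(simulate_genome(cfg), cfg, profile = prof)
  hits <- scan_profile(c(genome = pf$genome), prof, min_bits = 3.0)
  tr <- pf$motif_sites
  found <- mapply(function(s, st) any(hits$start == s & hits$strand == st),
                  tr$start, tr$strand)
  background <- sum(!mapply(function(s, st)
    any(tr$start == s & tr$strand == st), hits$start, hits$strand))
  expect_gte(sum(found), 18L)
  expect_lte(background, 2L)
  # planted sites pass the upstream-CDS filter by construction
  near <- filter_near_cds(hits, pf$genes, max_dist = 500)
  expect_equal(sum(near$start %in% tr$start), sum(found))
})

test_that("the upstream filter uses box-end to CDS-start distance", {
  genes <- data.frame(seq_id = "g", start = c(2000, 5000), end = c(2900, 5900),
                      strand = c("+", "+"), feature_id = c("cds1", "cds2"),
                      stringsAsFactors = FALSE)
  hits <- data.frame(seq_id = "g",
                     start = c(1896, 4472, 1500, 2500),
                     end = c(1923, 4499, 1527, 2527),
                     strand = c("+", "+", "+", "+"),
                     bits = 5, stringsAsFactors = FALSE)
  out <- filter_near_cds(hits, genes, max_dist = 500)
  # 2000 - 1923 = 77: retained with that distance
  expect_true(1896 %in% out$start)
  expect_equal(out$distance[out$start == 1896], 77L)
  expect_equal(out$nearest_cds[out$start == 1896], "cds1")
  # 5000 - 4499 = 501: one base too far
  expect_false(4472 %in% out$start)
  # exactly 500 is inclusive
  h500 <- data.frame(seq_id = "g", start = 1472, end = 1500, strand = "+",
                     bits = 5, stringsAsFactors = FALSE)
  expect_equal(filter_near_cds(h500, genes, 500)$distance, 500L)
  # a box downstream of the CDS start is removed (start 2500 inside cds1)
  expect_false(2500 %in% out$start)

  # opposite strand is removed; the minus-strand geometry mirrors plus
  gm <- data.frame(seq_id = "g", start = 2000, end = 2900, strand = "-",
                   feature_id = "m1", stringsAsFactors = FALSE)
  hm <- data.frame(seq_id = "g", start = c(2977, 2977), end = c(3004, 3004),
                   strand = c("-", "+"), bits = 5, stringsAsFactors = FALSE)
  outm <- filter_near_cds(hm, gm, 500)
  expect_equal(nrow(outm), 1L)
  expect_equal(outm$strand, "-")
  expect_equal(outm$distance, 78L)
})
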