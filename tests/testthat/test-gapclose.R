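test_that("contig ends come only from contigs strictly longer than 1 kb", {
  asm <- assembly(c(big = rand_seq(5000, seed = 1),
                    small = rand_seq(900, seed = 2),
                    edge = rand_seq(1000, seed = 3)))
  ends <- extract_ends(asm)
  expect_setequal(unique(ends$contig_id), "big")
  expect_equal(nrow(ends), 2L)
  left <- ends[ends$side == "left", ]
  right <- ends[ends$side == "right", ]
  expect_equal(c(left$start, left$end), c(0L, 300L))
  expect_equal(c(right$start, right$end), c(4700L, 5000L))
  expect_equal(right$seq, substr(asm$seqs[["big"]], 4701, 5000))
})

test_that("gap candidates require same reference, facing ends, close hits", {
  set.seed(21)
  ref <- rand_seq(12000)
  # two contigs flanking a 400 bp deletion of the reference
  asm <- assembly(c(A = substr(ref, 1, 3000), B = substr(ref, 3401, 6400)))
  idx <- build_seed_index(c(ref = ref))
  cand <- find_gap_candidates(extract_ends(asm), idx)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$implied_gap, 400L)
  expect_equal(cand$contig_a, "A")
  expect_equal(cand$side_a, "right")
  expect_equal(cand$side_b, "left")

  # a reverse-complemented partner is still recovered, with its stored side
  asm_rc <- assembly(c(A = substr(ref, 1, 3000),
                       B = rc(substr(ref, 3401, 6400))))
  cand_rc <- find_gap_candidates(extract_ends(asm_rc), idx)
  expect_equal(nrow(cand_rc), 1L)
  expect_equal(cand_rc$implied_gap, 400L)
  expect_equal(cand_rc$side_b, "right")

  # hits on different reference sequences never pair
  idx2 <- build_seed_index(c(r1 = substr(ref, 1, 3200),
                             r2 = substr(ref, 3201, 12000)))
  expect_equal(nrow(find_gap_candidates(extract_ends(asm), idx2)), 0L)

  # hits 5 kb apart never pair
  asm_far <- assembly(c(A = substr(ref, 1, 3000), B = substr(ref, 8001, 11000)))
  expect_equal(nrow(find_gap_candidates(extract_ends(asm_far), idx)), 0L)

  # the two ends of the same contig are never paired with each other
  solo <- assembly(c(A = substr(ref, 1, 3000)))
  expect_equal(nrow(find_gap_candidates(extract_ends(solo), idx)), 0L)
})

test_that("reference separation threshold is inclusive at 1000, not 1001", {
  set.seed(22)
  ref <- rand_seq(12000)
  at_1000 <- assembly(c(A = substr(ref, 1, 2000), B = substr(ref, 3001, 5000)))
  at_1001 <- assembly(c(A = substr(ref, 1, 2000), B = substr(ref, 3002, 5001)))
  idx <- build_seed_index(c(ref = ref))
  expect_equal(nrow(find_gap_candidates(extract_ends(at_1000), idx)), 1L)
  expect_equal(nrow(find_gap_candidates(extract_ends(at_1001), idx)), 0L)
})

test_that("overlap merges demand 15 bp of perfect overlap", {
  set.seed(23)
  g <- rand_seq(7000)
  asm <- assembly(c(A = substr(g, 1, 3520), B = substr(g, 3501, 7000)))
  adj <- data.frame(contig_a = "A", contig_b = "B",
                    orientation_a = "+", orientation_b = "+")
  prop <- merge_overlaps(asm, adj)
  expect_equal(nrow(prop), 1L)
  expect_equal(prop$overlap_len, 20L)
  res <- apply_joins(asm, prop)
  expect_length(res$scaffolds, 1L)
  merged <- scaffold_seq(res$scaffolds[[1]], asm)
  expect_equal(nchar(merged), 3520L + 3500L - 20L)
  expect_equal(merged, g)

  # 14 bp is one short of the rule
  asm14 <- assembly(c(A = substr(g, 1, 3514), B = substr(g, 3501, 7000)))
  expect_equal(nrow(merge_overlaps(asm14, adj)), 0L)

  # one mismatch inside a 20 bp junction breaks the 100% requirement
  bad <- asm$seqs
  substr(bad["A"], 3510, 3510) <- setdiff(c("A", "C", "G", "T"),
                                          substr(bad["A"], 3510, 3510))[1]
  expect_equal(nrow(merge_overlaps(assembly(bad), adj)), 0L)

  # unknown orientations are resolved by testing both
  asm_rc <- assembly(c(A = substr(g, 1, 3520), B = rc(substr(g, 3501, 7000))))
  prop_rc <- merge_overlaps(asm_rc, data.frame(contig_a = "A", contig_b = "B"))
  expect_equal(prop_rc$overlap_len, 20L)
  res_rc <- apply_joins(asm_rc, prop_rc)
  expect_equal(scaffold_seq(res_rc$scaffolds[[1]], asm_rc), g)
})

test_that("shared-gene pairing needs one gene, disjoint coverage", {
  set.seed(24)
  ref <- rand_seq(9000)
  genes <- data.frame(seq_id = "ref", start = 3001, end = 3600,
                      strand = "+", feature_id = "geneX",
                      stringsAsFactors = FALSE)
  idx <- build_seed_index(c(ref = ref))
  # A's right end covers gene bases 1-180; B's left end covers 241-540
  asm <- assembly(c(A = substr(ref, 1, 3180), B = substr(ref, 3241, 5300)))
  ends <- extract_ends(asm)
  prop <- pair_by_shared_gene(ends, genes, idx)
  expect_equal(nrow(prop), 1L)
  expect_equal(prop$kind, "shared_gene")
  expect_equal(prop$gap_n, 60L)

  # overlapping portions of the gene: no join
  asm_ovl <- assembly(c(A = substr(ref, 1, 3180), B = substr(ref, 3100, 5200)))
  expect_equal(nrow(pair_by_shared_gene(extract_ends(asm_ovl), genes, idx)), 0L)

  # hits to two different genes: no join
  genes2 <- data.frame(seq_id = "ref", start = c(2901, 3301),
                       end = c(3180, 3600), strand = "+",
                       feature_id = c("g1", "g2"), stringsAsFactors = FALSE)
  asm_far <- assembly(c(A = substr(ref, 1, 3180), B = substr(ref, 3301, 5400)))
  prop2 <- pair_by_shared_gene(extract_ends(asm_far), genes2, idx)
  expect_equal(nrow(prop2), 0L)
})

test_that("apply_joins chains proposals, ranks conflicts, breaks cycles", {
  asm <- assembly(c(A = rand_seq(1200, seed = 1), B = rand_seq(1200, seed = 2),
                    C = rand_seq(1200, seed = 3)))
  mk <- function(kind, a, sa, b, sb, gap = 10L, score = 1) {
    data.frame(kind = kind, contig_a = a, side_a = sa, contig_b = b,
               side_b = sb, gap_n = gap, overlap_len = NA_integer_,
               score = score, evidence = "", stringsAsFactors = FALSE)
  }
  # chain A-B and B-C through distinct ends of B -> one scaffold A,B,C
  chain <- rbind(mk("reference_adjacency", "A", "right", "B", "left"),
                 mk("reference_adjacency", "B", "right", "C", "left"))
  res <- apply_joins(asm, chain)
  expect_length(res$scaffolds, 1L)
  ids <- vapply(Filter(function(p) p$type == "contig",
                       res$scaffolds[[1]]$parts), `[[`, character(1),
                "contig_id")
  expect_true(identical(ids, c("A", "B", "C")) ||
              identical(ids, c("C", "B", "A")))

  # two proposals competing for the same end of A: higher rank wins
  comp <- rbind(mk("shared_gene", "A", "right", "B", "left", score = 1),
                mk("reference_adjacency", "A", "right", "C", "left", score = 9))
  res2 <- apply_joins(asm, comp)
  rep2 <- res2$report
  expect_true(rep2$accepted[rep2$kind == "shared_gene"])
  expect_false(rep2$accepted[rep2$kind == "reference_adjacency"])
  expect_match(rep2$reason[!rep2$accepted], "consumed")

  # A-B, B-C, C-A: the lowest-ranked edge of the cycle is rejected
  cyc <- rbind(mk("overlap_merge", "A", "right", "B", "left"),
               mk("shared_gene", "B", "right", "C", "left"),
               mk("reference_adjacency", "C", "right", "A", "left"))
  cyc$overlap_len[1] <- 20L; cyc$gap_n[1] <- NA_integer_
  res3 <- apply_joins(asm, cyc)
  rep3 <- res3$report
  expect_false(rep3$accepted[rep3$kind == "reference_adjacency"])
  expect_equal(sum(rep3$accepted), 2L)
  expect_match(rep3$reason[!rep3$accepted], "cycle")

  expect_error(apply_joins(asm, mk("shared_gene", "A", "right", "Z", "left")),
               "unknown contig")
})

test_that("joining conserves contig sequence", {
  set.seed(25)
  ref <- rand_seq(30000)
  cuts <- c(0, 6000, 12500, 19000, 24000, 29000)
  seqs <- setNames(lapply(1:5, function(i)
    substr(ref, cuts[i] + 1, cuts[i + 1] - (if (i < 5) sample(0:800, 1) else 0))),
    paste0("c", 1:5))
  asm <- assembly(vapply(seqs, identity, character(1)))
  idx <- build_seed_index(c(ref = ref))
  cand <- find_gap_candidates(extract_ends(asm), idx)
  res <- apply_joins(asm, candidates_to_proposals(cand))
  joined <- vapply(res$scaffolds, scaffold_seq, character(1), asm = asm)
  non_n <- function(x) sum(nchar(gsub("N", "", x)))
  expect_equal(non_n(joined), non_n(asm$seqs))
})

test_that("find_nruns reports maximal runs with 0-based starts", {
  r <- find_nruns(c(s = "ACGNNNNACG"))
  expect_equal(r$start, 3L)
  expect_equal(r$length, 4L)
  r2 <- find_nruns(c(s = "NNNACG"))
  expect_equal(r2$start, 0L)
  expect_equal(nrow(find_nruns(c(s = "ACGT"))), 0L)
  r3 <- find_nruns(c(s = "AnnNta"))  # case-insensitive
  expect_equal(r3$length, 3L)
})

test_that("N-run resizing follows the reference-span and cap rules", {
  set.seed(26)
  ref <- rand_seq(20000)
  th <- thresholds()
  # run of 12000 Ns whose flanks sit 480 bp apart on the reference
  sc <- paste0(substr(ref, 1, 5000), strrep("N", 12000),
               substr(ref, 5481, 11000))
  # run of 8000 Ns with unmappable flanks
  sc2 <- paste0(rand_seq(2000), strrep("N", 8000), rand_seq(2000))
  # run of 200 Ns: below the touch threshold
  sc3 <- paste0(substr(ref, 11001, 13000), strrep("N", 200),
                substr(ref, 13501, 15500))
  idx <- build_seed_index(c(ref = ref))
  res <- resize_nruns(c(a = sc, b = sc2, c = sc3), idx, th)
  rep <- res$report
  expect_equal(rep$new_n[rep$scaffold_id == "a"], 480L)
  expect_equal(rep$rule[rep$scaffold_id == "a"], "reference_span")
  expect_equal(rep$new_n[rep$scaffold_id == "b"], 300L)
  expect_equal(rep$rule[rep$scaffold_id == "b"], "capped")
  expect_equal(rep$new_n[rep$scaffold_id == "c"], 200L)
  expect_equal(rep$rule[rep$scaffold_id == "c"], "untouched")
  expect_equal(nchar(res$seqs[["a"]]), 5000L + 480L + 5520L)

  # a run of exactly 300 is untouched (strictly-greater rule)
  sc300 <- paste0(substr(ref, 1, 2000), strrep("N", 300),
                  substr(ref, 2001, 4000))
  res300 <- resize_nruns(c(x = sc300), idx, th)
  expect_equal(res300$report$rule, "untouched")
  expect_identical(res300$seqs[["x"]], sc300)

  # overlapping flank projections floor at 1 N with the overlap rule
  sc_ovl <- paste0(substr(ref, 1, 5000), strrep("N", 400),
                   substr(ref, 4801, 9000))
  res_ovl <- resize_nruns(c(y = sc_ovl), idx, th)
  expect_equal(res_ovl$report$new_n, 1L)
  expect_equal(res_ovl$report$rule, "reference_span_overlap")

  # a run flush against the scaffold start is warned about and unchanged
  flush <- paste0(strrep("N", 400), substr(ref, 15001, 18000))
  expect_warning(res_f <- resize_nruns(c(z = flush), idx, th), "flush")
  expect_equal(res_f$report$rule, "unchanged_no_flank")
  expect_identical(res_f$seqs[["z"]], flush)
})
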