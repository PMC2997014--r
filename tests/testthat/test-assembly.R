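test_that("read_fasta parses records, normalizes case and IUPAC codes", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), p)
  a <- read_fasta(p)
  expect_equal(length(a), 1L)
  expect_equal(unname(nchar(a$seqs)), 4L)

  writeLines(c(">c1", "acgt", ">c2", "NNNA"), p)
  a <- read_fasta(p)
  expect_equal(unname(a$seqs), c("ACGT", "NNNA"))

  writeLines(c(">c1 some description", "ACRT"), p)
  a <- read_fasta(p)
  expect_equal(names(a$seqs), "c1")
  expect_equal(unname(a$seqs), "ACNT")  # R is not ACGTN -> N
  expect_equal(a$n_mapped, 1)
})

test_that("read_fasta rejects duplicates, empty files and empty records", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), p)
  expect_error(read_fasta(p), "duplicate")
  writeLines(character(0), p)
  expect_error(read_fasta(p))
  writeLines(c(">c1", "", ">c2", "ACGT"), p)
  expect_error(read_fasta(p), "empty sequence")
})

test_that("AGP layout round-trips and renders gap runs as Ns", {
  asm <- assembly(c(c1 = rand_seq(500, seed = 1), c2 = rand_seq(400, seed = 2)))
  sc <- scaffold("s1", list(contig_part("c1", "+"), gap_part(100),
                            contig_part("c2", "-")))
  seqs <- write_layout(list(sc), asm)
  expect_equal(nchar(seqs[["s1"]]), 1000L)  # 500 + 100 + 400
  expect_equal(substr(seqs[["s1"]], 501, 600), strrep("N", 100))
  expect_equal(substr(seqs[["s1"]], 601, 1000), rc(asm$seqs[["c2"]]))

  # single-contig scaffold: one component line, no gap line
  agp1 <- tempfile(fileext = ".agp")
  write_layout(list(scaffold("solo", list(contig_part("c1", "+")))), asm,
               path_agp = agp1)
  body <- grep("^#", readLines(agp1), invert = TRUE, value = TRUE)
  expect_length(body, 1L)
  expect_equal(strsplit(body, "\t")[[1]][5], "W")

  # randomized 20-scaffold layout: write -> read -> write is byte-identical
  set.seed(42)
  contigs <- setNames(
    vapply(1:40, function(i) rand_seq(sample(200:1500, 1)), character(1)),
    sprintf("ctg%02d", 1:40))
  asm2 <- assembly(contigs)
  pool <- sample(names(contigs))
  scs <- list()
  taken <- 0L
  for (i in 1:20) {
    n <- sample(1:3, 1)
    ids <- pool[(taken + 1):(taken + n)]
    taken <- taken + n
    parts <- list()
    for (j in seq_along(ids)) {
      if (j > 1) parts <- c(parts, list(gap_part(sample(1:500, 1))))
      parts <- c(parts, list(contig_part(ids[j], sample(c("+", "-"), 1))))
    }
    scs[[i]] <- scaffold(sprintf("scf%02d", i), parts)
  }
  a1 <- tempfile(); a2 <- tempfile()
  write_layout(scs, asm2, path_agp = a1)
  write_layout(read_agp(a1), asm2, path_agp = a2)
  expect_identical(readLines(a1), readLines(a2))
})

test_that("scaffold constructor enforces part ordering and orientations", {
  expect_error(scaffold("s", list(gap_part(10), contig_part("c1"))),
               "start and end with a contig")
  expect_error(contig_part("c1", orientation = "x"), "orientation")
  expect_error(gap_part(0), "n_count")
})

test_that("read_gff keeps CDS rows, tolerates FASTA trailer, names bad lines", {
  p <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t101\t220\t.\t+\t0\tID=cds1",
               "chr1\tsrc\tgene\t90\t300\t.\t+\t.\tID=g1",
               "##FASTA", ">chr1", "ACGT"), p)
  g <- read_gff(p)
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 101L)
  expect_equal(g$end, 220L)
  expect_equal(g$strand, "+")

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t500\t400\t.\t+\t0\tID=bad"), p)
  expect_error(read_gff(p), "line 2")
})

test_that("length_stats matches a brute-force N50 and handles ties", {
  a <- assembly(setNames(
    vapply(c(400, 300, 200, 100), strrep, character(1), x = "A"),
    paste0("c", 1:4)))
  st <- length_stats(a)
  expect_equal(st$total_bases, 1000L)
  expect_equal(unname(st$n50_size), 300L)
  expect_equal(st$n50_number, 2L)

  one <- length_stats(assembly(c(x = strrep("A", 7))))
  expect_equal(unname(one$n50_size), 7L)
  expect_equal(one$n50_number, 1L)

  tie <- length_stats(assembly(c(x = strrep("A", 500),
                                 y = strrep("C", 500))))
  expect_equal(unname(tie$n50_size), 500L)
  expect_equal(tie$n50_number, 1L)  # first contig reaching half-total

  # property: agreement with the independent oracle on random multisets
  set.seed(7)
  for (i in 1:1000) {
    lens <- sample(1:5000, sample(1:50, 1), replace = TRUE)
    st <- length_stats(assembly(setNames(
      vapply(lens, strrep, character(1), x = "A"),
      paste0("c", seq_along(lens)))))
    o <- brute_n50(lens)
    expect_equal(unname(st$n50_size), o$size)
    expect_equal(st$n50_number, o$number)
  }
})

test_that("read trimming and ambiguity filtering follow the paired rules", {
  reads <- data.frame(
    id = c("r1", "r2", "r3"),
    seq = c(strrep("A", 36), paste0(strrep("A", 30), "N", strrep("A", 45)),
            strrep("C", 50)),
    qual = NA_character_, mate_id = NA_character_,
    stringsAsFactors = FALSE)
  out <- trim_and_filter_reads(reads)
  # 36-mer loses its last 4 bases; 76-mer has an internal N and is dropped
  expect_equal(nchar(out$seq[out$id == "r1"]), 32L)
  expect_false("r2" %in% out$id)
  expect_true("r3" %in% out$id)  # length not in the trim map: untouched

  # a trailing N inside the trimmed tail does not condemn the read
  reads2 <- data.frame(id = "r4", seq = paste0(strrep("A", 73), "NNN"),
                       qual = NA_character_, mate_id = NA_character_,
                       stringsAsFactors = FALSE)
  expect_equal(nrow(trim_and_filter_reads(reads2)), 1L)

  # paired mode: both reads drop when one mate has an ambiguous base
  pr <- data.frame(id = c("a/1", "a/2", "b/1", "b/2"),
                   seq = c(strrep("A", 36), strrep("C", 36),
                           strrep("G", 36), paste0("N", strrep("T", 35))),
                   qual = NA_character_,
                   mate_id = c("a/2", "a/1", "b/2", "b/1"),
                   stringsAsFactors = FALSE)
  out <- trim_and_filter_reads(pr, paired = TRUE)
  expect_setequal(out$id, c("a/1", "a/2"))

  orphan <- pr[-2, ]
  expect_error(trim_and_filter_reads(orphan, paired = TRUE), "orphan")

  # idempotence: a second pass changes nothing
  again <- trim_and_filter_reads(out, paired = TRUE)
  expect_equal(again$seq, out$seq)
})

test_that("fastq reading and pairing work end to end", {
  p <- tempfile(fileext = ".fq")
  writeLines(c("@r1 extra", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "GGGGCCCC", "+", "JJJJJJJJ"), p)
  r <- read_fastq(p)
  expect_equal(r$id, c("r1", "r2"))
  expect_equal(nchar(r$qual), c(8L, 8L))
  paired <- pair_reads(r[1, ], r[2, ])
  expect_equal(paired$mate_id, c("r2", "r1"))
})

test_that("theoretical coverage arithmetic is rounded and linear", {
  expect_equal(theoretical_coverage(0, 1, 32, 6.5e6), 0L)
  expect_error(theoretical_coverage(10, 1, 32, 0), "genome_size")
  # linearity: doubling reads doubles coverage within rounding
  set.seed(3)
  for (i in 1:50) {
    n <- sample.int(1e7, 1)
    c1 <- theoretical_coverage(n, 2, 70, 6.5e6)
    c2 <- theoretical_coverage(2 * n, 2, 70, 6.5e6)
    expect_lte(abs(c2 - 2 * c1), 1L)
  }
})
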