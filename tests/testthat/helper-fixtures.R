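# Shared fixture helpers: everything is generated in code, no stored data.

rand_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(s)))

# mutate a sequence by iid substitutions (no indels)
mutate_subs <- function(s, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- strsplit(s, "")[[1]]
  at <- which(runif(length(x)) < rate)
  x[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
  paste(x, collapse = "")
}

write_tmp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile(fileext = ".fa", tmpdir = dir)
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  path
}

# unordered contig-pair keys for comparing candidate/adjacency tables
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# independent brute-force N50: sort descending, scan cumulative sum
brute_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  cum <- cumsum(lens)
  i <- which(cum >= sum(lens) / 2)[1]
  list(size = lens[i], number = i)
}

# independent brute-force profile scores of every forward window
brute_window_scores <- function(seq, bits) {
  L <- ncol(bits)
  n <- nchar(seq)
  vapply(seq_len(n - L + 1L), function(i) {
    win <- strsplit(substr(seq, i, i + L - 1L), "")[[1]]
    idx <- match(win, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    sum(bits[cbind(idx, seq_len(L))])
  }, numeric(1))
}

# standard promoter-box-like consensus used by the motif fixtures
box_consensus <- function() "TGGAACCGTATCGGTTGCCTGACCACT"
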