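# Low-level sequence utilities shared by all modules.
# Internal coordinates are 0-based half-open throughout; conversion to the
# 1-based inclusive conventions of FASTA/GFF3/AGP happens only at I/O time.

BASES <- c("A", "C", "G", "T")

# structured run log: emitted via message() when options(draftweaver.verbose)
dw_log <- function(op, ...) {
  if (isTRUE(getOption("draftweaver.verbose", FALSE))) {
    kv <- list(...)
    msg <- paste(vapply(seq_along(kv), function(i)
      paste0(names(kv)[i], "=", format(kv[[i]])), character(1)), collapse = " ")
    message(sprintf("[draftweaver] %s %s", op, msg))
  }
  invisible(NULL)
}

# character sequence -> integer codes A=0 C=1 G=2 T=3, NA for anything else
encode_seq <- function(seq) {
  x <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(x))
  code[x == 65L] <- 0L  # A
  code[x == 67L] <- 1L  # C
  code[x == 71L] <- 2L  # G
  code[x == 84L] <- 3L  # T
  code
}

decode_seq <- function(code) {
  ch <- rep("N", length(code))
  ok <- !is.na(code)
  ch[ok] <- BASES[code[ok] + 1L]
  paste(ch, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# uppercase and map non-ACGTN IUPAC codes to N; returns seq with attribute
# "n_mapped" counting the replaced characters
normalize_seq <- function(seq) {
  s <- toupper(seq)
  x <- utf8ToInt(s)
  keep <- x %in% utf8ToInt("ACGTN")
  n_mapped <- sum(!keep)
  if (n_mapped > 0) {
    x[!keep] <- utf8ToInt("N")
    s <- intToUtf8(x)
  }
  attr(s, "n_mapped") <- n_mapped
  s
}

# numeric codes of all k-mers (forward strand); windows containing an
# ambiguous base are NA. Codes are exact doubles for k <= 26 (< 2^53).
kmer_codes <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  acc <- numeric(m)
  for (j in 0:(k - 1L)) acc <- acc * 4 + code[(1L + j):(m + j)]
  acc
}

# codes of the reverse complement of each forward window (same positions)
kmer_codes_rc <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  acc <- numeric(m)
  p <- 1
  for (j in 0:(k - 1L)) {
    acc <- acc + (3 - code[(1L + j):(m + j)]) * p
    p <- p * 4
  }
  acc
}

# maximal runs of N in a character sequence; 0-based starts, case-insensitive
n_runs <- function(seq) {
  isn <- is.na(encode_seq(toupper(seq)))
  if (!any(isn)) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  r <- rle(isn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}
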