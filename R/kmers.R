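# Unique k-mer machinery shared by the synteny and layout modules.
#
# Uniqueness is double-stranded: a k-mer and its reverse complement are the
# same entity, so a k-mer qualifies only if the total count of forward
# occurrences of itself and of its reverse complement across the whole
# sequence set equals one. Palindromic k-mers (self reverse complement)
# therefore never qualify. K-mers containing N are excluded.

# all windows of a sequence set: data.frame(seq (index), pos (0-based),
# code, rc_code, canon); NA-containing windows dropped
kmer_windows <- function(seqs, k) {
  rows <- lapply(seq_along(seqs), function(i) {
    code <- encode_seq(toupper(seqs[[i]]))
    fc <- kmer_codes(code, k)
    rc <- kmer_codes_rc(code, k)
    ok <- which(!is.na(fc))
    data.frame(seq = rep.int(i, length(ok)), pos = ok - 1L,
               code = fc[ok], rc_code = rc[ok])
  })
  w <- do.call(rbind, rows)
  w$canon <- pmin(w$code, w$rc_code)
  w
}

# mark windows whose canonical k-mer occurs exactly once in the set and is
# not palindromic
mark_unique <- function(w) {
  if (!nrow(w)) return(logical(0))
  tab <- sort(w$canon)
  runs <- rle(tab)
  singles <- runs$values[runs$lengths == 1L]
  (w$canon %in% singles) & (w$code != w$rc_code)
}

#' Unique k-mers of a genome
#'
#' A k-mer qualifies when its total occurrence count — forward occurrences
#' of itself plus forward occurrences of its reverse complement — equals
#' one. Palindromic and N-containing k-mers are excluded.
#'
#' @param genome a nucleotide string (single sequence).
#' @param k k-mer size (default 25).
#' @return data.frame with columns pos (0-based start) and code (numeric
#'   k-mer code); attribute `k`. Use [kmer_string()] to decode codes.
#' @export
unique_kmers <- function(genome, k = 25L) {
  k <- as.integer(k)
  if (nchar(genome) < k) {
    warning("sequence shorter than k; no k-mers")
    return(structure(data.frame(pos = integer(0), code = numeric(0)), k = k))
  }
  w <- kmer_windows(list(genome), k)
  u <- mark_unique(w)
  structure(data.frame(pos = w$pos[u], code = w$code[u]), k = k)
}

#' Decode a numeric k-mer code to its sequence
#'
#' @param code numeric code(s) as produced by [unique_kmers()].
#' @param k k-mer size.
#' @return Character vector of k-mer strings.
#' @export
kmer_string <- function(code, k) {
  vapply(code, function(x) {
    b <- integer(k)
    for (j in k:1) { b[j] <- x %% 4; x <- x %/% 4 }
    paste(BASES[b + 1L], collapse = "")
  }, character(1))
}
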