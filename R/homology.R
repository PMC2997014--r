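# Seeded local similarity search with Karlin-Altschul E-values.
#
# The engine behind gap finding, N-run resizing and shared-gene pairing:
# exact word seeding on both strands, ungapped X-drop extension, then a
# gapped Smith-Waterman restricted to a window around each surviving seed
# cluster. Statistics use the ungapped Karlin-Altschul form
# E = K * m * n * exp(-lambda * S) as an approximation for gapped scores.

#' Alignment scoring scheme and E-value statistics
#'
#' @param match match reward (> 0, default +1).
#' @param mismatch mismatch penalty (< 0, default -2).
#' @param gap_open gap opening cost, positive (a gap of length L costs
#'   `gap_open + L * gap_extend`; default 5).
#' @param gap_extend per-base gap extension cost, positive (default 2).
#' @param lambda Karlin-Altschul scale parameter per score unit (default 1.28).
#' @param K Karlin-Altschul search-space constant (default 0.46).
#' @return Object of class `dw_scoring`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = 5L,
                           gap_extend = 2L, lambda = 1.28, K = 0.46) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open < 0 || gap_extend <= 0) stop("gap costs must be positive")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "dw_scoring")
}

#' Karlin-Altschul expectation value
#'
#' `E = K * query_len * db_len * exp(-lambda * score)`: the expected number
#' of distinct alignments of at least this score arising by chance in a
#' search of this size.
#'
#' @param score alignment score in scheme units.
#' @param query_len query length in bases.
#' @param db_len total subject bases (one strand).
#' @param scoring a [scoring_scheme()].
#' @return Numeric E-value.
#' @export
evalue <- function(score, query_len, db_len, scoring = scoring_scheme()) {
  if (query_len <= 0 || db_len <= 0) stop("lengths must be positive")
  scoring$K * query_len * db_len * exp(-scoring$lambda * score)
}

#' Full Smith-Waterman local alignment (quadratic-time reference)
#'
#' Exact affine-gap local alignment by full dynamic programming. Intended as
#' the exhaustive reference for the seeded search on short sequences; inputs
#' are capped at 5 kb each.
#'
#' @param a,b nucleotide strings.
#' @param scoring a [scoring_scheme()].
#' @return List with `score`, 0-based half-open `q_start`/`q_end` (in `a`)
#'   and `s_start`/`s_end` (in `b`), and traceback column counts
#'   (`matches`, `mismatches`, `gaps`, `gap_opens`, `aln_len`).
#' @examples
#' smith_waterman("ACGTT", "ACGAT")$score  # 3: best local alignment "ACG"
#' @export
smith_waterman <- function(a, b, scoring = scoring_scheme()) {
  if (nchar(a) > 5000 || nchar(b) > 5000) {
    stop("smith_waterman is a quadratic reference; inputs capped at 5 kb")
  }
  ca <- encode_seq(toupper(a)); ca[is.na(ca)] <- -1L
  cb <- encode_seq(toupper(b)); cb[is.na(cb)] <- -1L
  sw_align_cpp(ca, cb, scoring$match, scoring$mismatch,
               scoring$gap_open, scoring$gap_extend)
}

#' Build an exact seed index over subject sequences
#'
#' Inverted index of every ACGT-only word of `word_size` bases on the
#' forward strand of each subject; minus-strand matches are found at query
#' time by looking up the reverse-complemented query, which is equivalent to
#' indexing both strands.
#'
#' @param subjects named character vector of sequences, or an [assembly()].
#' @param word_size seed word length (>= 4, default 11).
#' @return Object of class `dw_seed_index`.
#' @export
build_seed_index <- function(subjects, word_size = 11L) {
  if (inherits(subjects, "dw_assembly")) subjects <- subjects$seqs
  word_size <- as.integer(word_size)
  if (word_size < 4) stop("word_size must be >= 4")
  ids <- names(subjects)
  codes <- lapply(subjects, function(s) {
    x <- encode_seq(toupper(s)); x
  })
  word <- numeric(0); subj <- integer(0); pos <- integer(0)
  for (i in seq_along(codes)) {
    wc <- kmer_codes(codes[[i]], word_size)
    ok <- which(!is.na(wc))
    word <- c(word, wc[ok])
    subj <- c(subj, rep.int(i, length(ok)))
    pos <- c(pos, ok - 1L)
  }
  o <- order(word, subj, pos)
  structure(list(word_size = word_size, ids = ids,
                 lens = unname(nchar(subjects)),
                 codes = codes,
                 word = word[o], subj = subj[o], pos = pos[o],
                 db_len = sum(nchar(subjects))),
            class = "dw_seed_index")
}

#' @export
print.dw_seed_index <- function(x, ...) {
  cat(sprintf("seed index: %d subjects, %s bases, word size %d, %s words\n",
              length(x$ids), format(x$db_len, big.mark = ","), x$word_size,
              format(length(x$word), big.mark = ",")))
  invisible(x)
}

# positions of a word code in the index -> integer row range (possibly empty)
seed_lookup <- function(index, wq) {
  lo <- findInterval(wq - 0.5, index$word)
  hi <- findInterval(wq + 0.5, index$word)
  list(lo = lo, hi = hi)
}

# seeds of query codes against the index: data.frame(qpos, subj, spos), 0-based
query_seeds <- function(qcode, index) {
  w <- index$word_size
  wq <- kmer_codes(qcode, w)
  qp <- which(!is.na(wq))
  if (!length(qp)) {
    return(data.frame(qpos = integer(0), subj = integer(0), spos = integer(0)))
  }
  rng <- seed_lookup(index, wq[qp])
  cnt <- rng$hi - rng$lo
  keep <- cnt > 0
  if (!any(keep)) {
    return(data.frame(qpos = integer(0), subj = integer(0), spos = integer(0)))
  }
  rows <- sequence(cnt[keep], from = rng$lo[keep] + 1L)
  data.frame(qpos = rep.int(qp[keep] - 1L, cnt[keep]),
             subj = index$subj[rows], spos = index$pos[rows])
}

# cluster seeds of one subject/strand into diagonal bands; returns a list of
# integer index vectors into the seed frame
cluster_seeds <- function(seeds, qlen, band = 32L) {
  diag <- seeds$spos - seeds$qpos
  o <- order(diag, seeds$spos)
  d <- diag[o]
  grp <- cumsum(c(1L, diff(d) > band))
  out <- list()
  for (g in split(o, grp)) {
    g <- g[order(seeds$spos[g])]
    sub <- cumsum(c(1L, diff(seeds$spos[g]) > qlen + 100L))
    out <- c(out, split(g, sub))
  }
  out
}

#' Seeded gapped local alignment of a query against an indexed database
#'
#' Pipeline: exact word seeding (both strands), two-way ungapped X-drop
#' extension of each seed cluster, then an exact affine-gap Smith-Waterman
#' over a subject window spanning the cluster's diagonals. Overlapping hits
#' on the same subject and strand keep the best score. Hits above the
#' E-value ceiling are discarded; survivors are sorted by ascending E-value
#' then descending score. If qualifying hits fall in more than
#' `max_regions` distinct subject regions, the result carries attribute
#' `ambiguous = TRUE` (repeat guard for downstream join logic).
#'
#' @param query nucleotide string.
#' @param index a [build_seed_index()].
#' @param scoring a [scoring_scheme()].
#' @param max_evalue E-value ceiling (default 0.02).
#' @param query_id id used in the output table.
#' @param max_regions distinct-region ceiling of the repeat guard (default 5).
#' @param xdrop X-drop for the ungapped extension stage (default 20).
#' @param min_cluster_seeds minimum number of seeds a diagonal cluster needs
#'   to be extended (default 1, i.e. every seed is pursued; raise it when
#'   only high-identity alignments matter, to skip chance seed matches).
#' @return data.frame of hits (query_id, subject_id, q_start, q_end, s_start,
#'   s_end, strand, identity, mismatches, gap_opens, aln_len, score, evalue);
#'   coordinates 0-based half-open on the forward strand of each sequence.
#' @export
local_align <- function(query, index, scoring = scoring_scheme(),
                        max_evalue = 0.02, query_id = "query",
                        max_regions = 5L, xdrop = 20L,
                        min_cluster_seeds = 1L) {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      mismatches = integer(0), gap_opens = integer(0),
                      aln_len = integer(0), score = integer(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  qlen <- nchar(query)
  if (qlen < index$word_size) {
    warning("query shorter than word size; no hits")
    return(`attr<-`(empty, "ambiguous", FALSE))
  }
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") toupper(query) else revcomp(toupper(query))
    qcode <- encode_seq(q)
    seeds <- query_seeds(qcode, index)
    if (!nrow(seeds)) next
    for (si in unique(seeds$subj)) {
      ss <- seeds[seeds$subj == si, , drop = FALSE]
      scode <- index$codes[[si]]
      slen <- index$lens[si]
      for (cl in cluster_seeds(ss, qlen)) {
        if (length(cl) < min_cluster_seeds) next
        c1 <- ss[cl, , drop = FALSE]
        # ungapped X-drop survival check on the cluster's first seed
        first <- which.min(c1$spos)
        qa <- qcode; qa[is.na(qa)] <- -1L
        sa_full <- scode
        ext <- xdrop_extend_cpp(qa, {
          z <- sa_full; z[is.na(z)] <- -1L; z
        }, c1$qpos[first], c1$spos[first], index$word_size,
        scoring$match, scoring$mismatch, as.integer(xdrop))
        if (ext$score < index$word_size * scoring$match) next
        ws <- max(0L, min(c1$spos) - qlen - 50L)
        we <- min(slen, max(c1$spos) + index$word_size + qlen + 50L)
        sa <- scode[(ws + 1L):we]
        sa[is.na(sa)] <- -1L
        r <- sw_align_cpp(qa, sa, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
        if (r$score <= 0) next
        s_start <- ws + r$s_start; s_end <- ws + r$s_end
        if (strand == "+") {
          q_start <- r$q_start; q_end <- r$q_end
        } else {
          q_start <- qlen - r$q_end; q_end <- qlen - r$q_start
        }
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = query_id, subject_id = index$ids[si],
          q_start = q_start, q_end = q_end,
          s_start = s_start, s_end = s_end, strand = strand,
          identity = r$matches / r$aln_len,
          mismatches = r$mismatches, gap_opens = r$gap_opens,
          aln_len = r$aln_len, score = r$score,
          evalue = evalue(r$score, qlen, index$db_len, scoring),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(`attr<-`(empty, "ambiguous", FALSE))
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(hits)) return(`attr<-`(empty, "ambiguous", FALSE))
  # merge overlapping hits on the same subject and strand: keep best score
  hits <- hits[order(hits$subject_id, hits$strand, -hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    same <- prior[hits$subject_id[prior] == hits$subject_id[i] &
                  hits$strand[prior] == hits$strand[i]]
    if (length(same) &&
        any(hits$s_start[same] < hits$s_end[i] &
            hits$s_end[same] > hits$s_start[i])) {
      keep[i] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$score), , drop = FALSE]
  rownames(hits) <- NULL
  # repeat guard: count distinct subject regions among qualifying hits
  n_regions <- 0L
  for (si in unique(hits$subject_id)) {
    h <- hits[hits$subject_id == si, , drop = FALSE]
    o <- order(h$s_start)
    gaps <- h$s_start[o][-1] > cummax(h$s_end[o])[-nrow(h)]
    n_regions <- n_regions + 1L + sum(gaps)
  }
  attr(hits, "ambiguous") <- n_regions > max_regions
  hits
}

#' Export hits as a 12-column tab-separated table
#'
#' Columns follow the conventional tabular hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, q_start,
#' q_end, s_start, s_end, evalue, bit-like score), 1-based inclusive.
#'
#' @param hits data.frame from [local_align()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_hits <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", 100 * hits$identity), hits$aln_len,
                    hits$mismatches, hits$gap_opens,
                    hits$q_start + 1L, hits$q_end,
                    hits$s_start + 1L, hits$s_end,
                    format(hits$evalue, digits = 3), hits$score)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
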