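# Promoter-box profile training and genome scanning: an ungapped position
# log-odds model trained from aligned boxes, scanned on both strands with a
# bit-score floor, then filtered to hits lying within a fixed distance
# upstream of a CDS start on the same strand.

#' Train a position log-odds profile from aligned motif instances
#'
#' Column base probabilities are `(count + pseudocount) /
#' (n_nongap + 4 * pseudocount)`; scores are log2 odds against the supplied
#' background. Columns where gaps are the majority are dropped (logged), so
#' the model is an ungapped fixed-length profile.
#'
#' @param alignment character vector of >= 2 equal-length aligned sequences
#'   over A, C, G, T and "-".
#' @param pseudocount added to every base count per column (default 0.5).
#' @param background named base frequencies (A, C, G, T) summing to 1;
#'   typically the mononucleotide frequencies of the target genome.
#' @return Object of class `dw_profile`: list with `length`, `bits` (4 x L
#'   matrix of log-odds in bits, rows A/C/G/T), `background`, `pseudocount`,
#'   `max_score`.
#' @export
train_profile <- function(alignment, pseudocount = 0.5,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25)) {
  if (length(alignment) < 2) stop("need at least 2 aligned sequences")
  alignment <- toupper(alignment)
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("aligned sequences must all have equal length")
  background <- background[BASES]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-6) {
    stop("background must be named A/C/G/T frequencies summing to 1")
  }
  m <- do.call(rbind, strsplit(alignment, ""))
  counts <- apply(m, 2, function(col) {
    c(table(factor(col, levels = BASES)))
  })
  gaps <- colSums(m == "-")
  drop <- gaps > nrow(m) / 2
  if (any(drop)) dw_log("train_profile", majority_gap_columns_dropped = sum(drop))
  counts <- counts[, !drop, drop = FALSE]
  nongap <- colSums(counts)
  probs <- sweep(counts + pseudocount, 2, nongap + 4 * pseudocount, "/")
  bits <- log2(sweep(probs, 1, background, "/"))
  structure(list(length = ncol(bits), bits = bits,
                 background = background, pseudocount = pseudocount,
                 max_score = sum(apply(bits, 2, max))),
            class = "dw_profile")
}

#' @export
print.dw_profile <- function(x, ...) {
  cat(sprintf("position log-odds profile: %d columns, max score %.2f bits\n",
              x$length, x$max_score))
  invisible(x)
}

# vectorised per-position window scores of one strand's matrix over a code
# vector; windows containing ambiguous bases score NA
window_scores <- function(code, bits) {
  L <- ncol(bits)
  n <- length(code)
  if (n < L) return(numeric(0))
  m <- n - L + 1L
  s <- numeric(m)
  for (j in seq_len(L)) {
    b <- code[j:(m + j - 1L)]
    v <- rep(NA_real_, m)
    ok <- !is.na(b)
    v[ok] <- bits[b[ok] + 1L, j]
    s <- s + v
  }
  s
}

#' Scan sequences with a profile on both strands
#'
#' Every window on each strand is scored as the sum of per-column bits.
#' Windows at or above `min_bits` are reported with forward-strand
#' coordinates; overlapping same-strand hits whose starts lie within half a
#' model length collapse to the best-scoring one.
#'
#' @param seqs named character vector of sequences (or a single string).
#' @param model a [train_profile()] model.
#' @param min_bits bit-score floor (default 3.0).
#' @return data.frame with columns seq_id, start, end (0-based half-open),
#'   strand, bits.
#' @export
scan_profile <- function(seqs, model, min_bits = 3.0) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  L <- model$length
  rc_bits <- model$bits[4:1, L:1, drop = FALSE]  # scores of revcomp windows
  rows <- list()
  for (id in names(seqs)) {
    code <- encode_seq(toupper(seqs[[id]]))
    for (strand in c("+", "-")) {
      s <- window_scores(code, if (strand == "+") model$bits else rc_bits)
      hit <- which(!is.na(s) & s >= min_bits)
      if (!length(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = hit - 1L, end = hit - 1L + L,
        strand = strand, bits = s[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      bits = numeric(0)))
  }
  hits <- do.call(rbind, rows)
  # collapse same-strand clusters of overlapping windows
  out <- list()
  for (key in unique(paste(hits$seq_id, hits$strand))) {
    h <- hits[paste(hits$seq_id, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(1L, diff(h$start) > L / 2))
    for (g in split(seq_len(nrow(h)), grp)) {
      out[[length(out) + 1L]] <- h[g[which.max(h$bits[g])], , drop = FALSE]
    }
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$seq_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  dw_log("scan_profile", hits = nrow(hits))
  hits
}

#' Keep motif hits upstream of a CDS start
#'
#' A hit is retained when a CDS start lies downstream of the box end on the
#' same strand, at a distance of at most `max_dist` bp (inclusive; measured
#' from box end to CDS start, as promoter-distance tables conventionally
#' print it). The nearest such CDS and distance are recorded.
#'
#' @param hits data.frame from [scan_profile()].
#' @param genes data.frame of CDS features from [read_gff()] (1-based).
#' @param max_dist maximum distance in bp (default 500).
#' @return The retained hits with added columns nearest_cds and distance.
#' @export
filter_near_cds <- function(hits, genes, max_dist = 500L) {
  keep <- logical(nrow(hits))
  nearest <- character(nrow(hits))
  dist <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    g <- genes[genes$seq_id == hits$seq_id[i] &
               genes$strand == hits$strand[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- if (hits$strand[i] == "+") {
      g$start - hits$end[i]          # hits$end is the 1-based box end
    } else {
      (hits$start[i] + 1L) - g$end   # on "-", the CDS start is its end coord
    }
    ok <- which(d >= 0 & d <= max_dist)
    if (length(ok)) {
      j <- ok[which.min(d[ok])]
      keep[i] <- TRUE
      nearest[i] <- g$feature_id[j]
      dist[i] <- d[j]
    }
  }
  out <- hits[keep, , drop = FALSE]
  out$nearest_cds <- nearest[keep]
  out$distance <- dist[keep]
  rownames(out) <- NULL
  dw_log("filter_near_cds", n_in = nrow(hits), retained = nrow(out))
  out
}

#' Read an aligned FASTA of motif instances
#'
#' @param path aligned FASTA path.
#' @return Character vector of aligned sequences (names = record ids).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}
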