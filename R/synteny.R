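# Unique k-mer synteny dot plots and windowed GC / GC-skew tracks.

#' Synteny dot plot points from shared unique k-mers
#'
#' One point per k-mer that is unique (double-stranded) in genome A and
#' matches a unique k-mer of genome B on either strand; only perfect
#' matches count. Coordinates are forward-strand start positions in each
#' genome; strand is "-" when the match is to the reverse strand of B.
#'
#' @param genome_a,genome_b nucleotide strings.
#' @param k k-mer size (default 25).
#' @return data.frame of class `dw_dotplot` with columns x (position in A,
#'   0-based), y (position in B), strand.
#' @export
dotplot_points <- function(genome_a, genome_b, k = 25L) {
  ua <- unique_kmers(genome_a, k)
  ub <- unique_kmers(genome_b, k)
  canon_a <- pmin(ua$code, kmer_code_rc_of(ua$code, k))
  canon_b <- pmin(ub$code, kmer_code_rc_of(ub$code, k))
  m <- match(canon_a, canon_b)
  hit <- which(!is.na(m))
  strand <- ifelse(ua$code[hit] == ub$code[m[hit]], "+", "-")
  out <- data.frame(x = ua$pos[hit], y = ub$pos[m[hit]], strand = strand,
                    stringsAsFactors = FALSE)
  out <- out[order(out$x), , drop = FALSE]
  rownames(out) <- NULL
  dw_log("dotplot_points", unique_a = nrow(ua), unique_b = nrow(ub),
         points = nrow(out))
  structure(out, class = c("dw_dotplot", "data.frame"), k = k,
            len_a = nchar(genome_a), len_b = nchar(genome_b))
}

# reverse-complement code of a k-mer code (vectorised)
kmer_code_rc_of <- function(code, k) {
  out <- numeric(length(code))
  x <- code
  for (j in seq_len(k)) {
    out <- out * 4 + (3 - x %% 4)
    x <- x %/% 4
  }
  out
}

#' @export
plot.dw_dotplot <- function(x, ..., pch = ".", cex = 1.5,
                            col = c(`+` = "black", `-` = "red")) {
  plot(x$x, x$y, pch = pch, cex = cex, col = col[x$strand],
       xlab = "genome A position (bp)", ylab = "genome B position (bp)", ...)
  invisible(x)
}

#' Export dot plot points as TSV (1-based coordinates)
#'
#' @param points a [dotplot_points()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_dotplot <- function(points, path) {
  out <- data.frame(x = points$x + 1L, y = points$y + 1L,
                    strand = points$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Windowed GC fraction and GC skew tracks
#'
#' Sliding half-open windows (`window` wide, advancing by `step`; the final
#' partial window is included). N bases are excluded from numerator and
#' denominator. GC skew is (G - C) / (G + C), defined as 0 (and flagged)
#' when a window has no G or C.
#'
#' @param genome nucleotide string.
#' @param window window size in bp (default 10000).
#' @param step step size in bp (default 5000; must not exceed `window`).
#' @return data.frame with columns start, end (0-based half-open),
#'   gc_fraction, gc_skew, skew_undefined.
#' @export
gc_tracks <- function(genome, window = 10000L, step = 5000L) {
  window <- as.integer(window); step <- as.integer(step)
  if (!(window >= step && step >= 1)) stop("need window >= step >= 1")
  code <- encode_seq(toupper(genome))
  n <- length(code)
  cg <- c(0, cumsum(!is.na(code) & code == 2L))
  cc <- c(0, cumsum(!is.na(code) & code == 1L))
  cv <- c(0, cumsum(!is.na(code)))
  starts <- seq.int(0L, max(0L, n - 1L), by = step)
  ends <- pmin(starts + window, n)
  g <- cg[ends + 1L] - cg[starts + 1L]
  c_ <- cc[ends + 1L] - cc[starts + 1L]
  v <- cv[ends + 1L] - cv[starts + 1L]
  gc_fraction <- ifelse(v > 0, (g + c_) / v, NA_real_)
  denom <- g + c_
  gc_skew <- ifelse(denom > 0, (g - c_) / denom, 0)
  data.frame(start = starts, end = ends, gc_fraction = gc_fraction,
             gc_skew = gc_skew, skew_undefined = denom == 0)
}

#' Export GC tracks as BED-like 4-column files
#'
#' Writes `<prefix>.gc.bed` (GC fraction) and `<prefix>.skew.bed` (GC skew):
#' chrom, 0-based start, end, value.
#'
#' @param tracks data.frame from [gc_tracks()].
#' @param chrom sequence name for the first column.
#' @param prefix output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
export_gc_tracks <- function(tracks, chrom, prefix) {
  p1 <- paste0(prefix, ".gc.bed")
  p2 <- paste0(prefix, ".skew.bed")
  write.table(data.frame(chrom, tracks$start, tracks$end,
                         tracks$gc_fraction),
              p1, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(chrom, tracks$start, tracks$end, tracks$gc_skew),
              p2, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(p1, p2))
}
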