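# Reference-guided ordering/orientation of scaffolds via unique k-mer
# anchors, and congruency checking across independent assemblies.

#' Anchor scaffolds to a reference with unique k-mers
#'
#' An anchor is a k-mer that is unique (double-stranded) within the whole
#' scaffold set AND unique within the reference; only perfect matches count.
#' Each anchor gives an unambiguous coordinate correspondence.
#'
#' @param scaffolds named character vector of scaffold sequences, or an
#'   [assembly()].
#' @param reference named character vector of reference sequences, or an
#'   [assembly()].
#' @param k k-mer size (>= 15; default 25).
#' @return data.frame with columns scaffold_id, scaffold_pos, reference_id,
#'   reference_pos (0-based starts), strand; attribute `k`.
#' @export
anchor_scaffolds <- function(scaffolds, reference, k = 25L) {
  if (inherits(scaffolds, "dw_assembly")) scaffolds <- scaffolds$seqs
  if (inherits(reference, "dw_assembly")) reference <- reference$seqs
  k <- as.integer(k)
  if (k < 15) stop("k must be >= 15 for reliable uniqueness")
  ws <- kmer_windows(as.list(scaffolds), k)
  wr <- kmer_windows(as.list(reference), k)
  us <- ws[mark_unique(ws), , drop = FALSE]
  ur <- wr[mark_unique(wr), , drop = FALSE]
  m <- match(us$canon, ur$canon)
  hit <- which(!is.na(m))
  out <- data.frame(
    scaffold_id = names(scaffolds)[us$seq[hit]],
    scaffold_pos = us$pos[hit],
    reference_id = names(reference)[ur$seq[m[hit]]],
    reference_pos = ur$pos[m[hit]],
    strand = ifelse(us$code[hit] == ur$code[m[hit]], "+", "-"),
    stringsAsFactors = FALSE)
  out <- out[order(out$scaffold_id, out$scaffold_pos), , drop = FALSE]
  rownames(out) <- NULL
  dw_log("anchor_scaffolds", anchors = nrow(out))
  structure(out, k = k)
}

#' Order and orient scaffolds along a reference
#'
#' A scaffold is placed when it is strictly longer than `min_len_reorder`
#' and carries at least `min_anchors` anchors: its position is the median
#' reference coordinate of its anchors (on the reference sequence holding
#' the majority of them) and its orientation is the majority anchor strand
#' (a 50/50 tie leaves it unplaced). Placed scaffolds are sorted by
#' (reference, position), ties broken by descending length then id.
#'
#' @param anchors data.frame from [anchor_scaffolds()].
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @param th a [thresholds()].
#' @return List with `placements` (scaffold_id, reference_id, position,
#'   orientation, n_anchors, in order) and `unplaced` (scaffold_id, reason).
#' @export
reorder_scaffolds <- function(anchors, scaffold_lengths, th = thresholds()) {
  placed <- list(); unplaced <- list()
  for (id in names(scaffold_lengths)) {
    a <- anchors[anchors$scaffold_id == id, , drop = FALSE]
    if (scaffold_lengths[[id]] <= th$min_len_reorder) {
      unplaced[[id]] <- "below length cutoff"
      next
    }
    if (nrow(a) == 0) { unplaced[[id]] <- "no anchors"; next }
    ref_tab <- table(a$reference_id)
    ref <- names(ref_tab)[which.max(ref_tab)]
    a <- a[a$reference_id == ref, , drop = FALSE]
    if (nrow(a) < th$min_anchors) { unplaced[[id]] <- "too few anchors"; next }
    n_plus <- sum(a$strand == "+")
    if (n_plus * 2L == nrow(a)) { unplaced[[id]] <- "orientation tie"; next }
    placed[[id]] <- data.frame(
      scaffold_id = id, reference_id = ref,
      position = median(a$reference_pos),
      orientation = if (n_plus * 2L > nrow(a)) "+" else "-",
      n_anchors = nrow(a), stringsAsFactors = FALSE)
  }
  placements <- if (length(placed)) do.call(rbind, placed) else {
    data.frame(scaffold_id = character(0), reference_id = character(0),
               position = numeric(0), orientation = character(0),
               n_anchors = integer(0))
  }
  if (nrow(placements)) {
    o <- order(placements$reference_id, placements$position,
               -scaffold_lengths[placements$scaffold_id],
               placements$scaffold_id)
    placements <- placements[o, , drop = FALSE]
    rownames(placements) <- NULL
  }
  unplaced <- data.frame(scaffold_id = names(unplaced),
                         reason = unlist(unplaced, use.names = FALSE),
                         stringsAsFactors = FALSE)
  dw_log("reorder_scaffolds", placed = nrow(placements),
         unplaced = nrow(unplaced))
  list(placements = placements, unplaced = unplaced)
}

# fraction of a contig covered by qualifying local alignments to a SINGLE
# contig of another assembly (a chimera is not vouched for by stitching
# alignments to different contigs together); long queries are chunked so
# the aligner works on short windows. Returns the best per-subject fraction
# and that subject's id.
contig_support <- function(seq, index, scoring, min_ident,
                           chunk = 1000L) {
  L <- nchar(seq)
  starts <- seq.int(0L, L - 1L, by = chunk)
  covered <- list()  # subject id -> IRanges of covered query bases
  for (s in starts) {
    e <- min(L, s + chunk)
    if (e - s < index$word_size) next
    h <- local_align(substr(seq, s + 1L, e), index, scoring = scoring,
                     max_evalue = 1e-3, max_regions = 1e9,
                     min_cluster_seeds = 5L)
    h <- h[h$identity >= min_ident, , drop = FALSE]
    for (sid in unique(h$subject_id)) {
      hh <- h[h$subject_id == sid, , drop = FALSE]
      r <- IRanges::IRanges(start = s + hh$q_start + 1L, end = s + hh$q_end)
      covered[[sid]] <- if (is.null(covered[[sid]])) r
                        else c(covered[[sid]], r)
    }
  }
  if (!length(covered)) return(list(fraction = 0, subject = NA_character_))
  frac <- vapply(covered, function(r)
    sum(IRanges::width(IRanges::reduce(r))) / L, numeric(1))
  best <- which.max(frac)
  list(fraction = unname(frac[best]), subject = names(covered)[best])
}

#' Cross-assembly congruency report
#'
#' A contig is supported when at least `min_cov` of its length is covered by
#' local alignments at identity `min_ident` or better to a single contig of
#' another assembly (stitching alignments to different contigs together
#' would let a chimera vouch for itself). An assembly is marked for culling
#' when it
#' contains a contig of `large_cutoff` bp or more that no other assembly
#' supports — the signature of a large misassembly.
#'
#' @param assemblies named list of [assembly()] objects (>= 2).
#' @param large_cutoff size above which an unsupported contig condemns its
#'   assembly (default 10000).
#' @param min_cov minimum supported fraction (default 0.95).
#' @param min_ident minimum alignment identity (default 0.99).
#' @param scoring a [scoring_scheme()].
#' @return Object of class `dw_congruency`: list with `contigs` (assembly,
#'   contig_id, length, best_support_fraction, supporting_assembly,
#'   supported) and `verdicts` (assembly, verdict, offending contigs).
#' @export
congruency_report <- function(assemblies, large_cutoff = 10000L,
                              min_cov = 0.95, min_ident = 0.99,
                              scoring = scoring_scheme()) {
  if (length(assemblies) < 2) stop("need at least 2 assemblies")
  if (is.null(names(assemblies))) {
    names(assemblies) <- paste0("assembly", seq_along(assemblies))
  }
  idx <- lapply(assemblies, function(a) build_seed_index(a$seqs))
  rows <- list()
  for (ai in names(assemblies)) {
    for (cid in names(assemblies[[ai]]$seqs)) {
      s <- assemblies[[ai]]$seqs[[cid]]
      best <- 0; best_by <- NA_character_
      for (aj in setdiff(names(assemblies), ai)) {
        f <- contig_support(s, idx[[aj]], scoring, min_ident)
        if (f$fraction > best) {
          best <- f$fraction
          best_by <- paste0(aj, ":", f$subject)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        assembly = ai, contig_id = cid, length = nchar(s),
        best_support_fraction = best, supporting_assembly = best_by,
        supported = best >= min_cov, stringsAsFactors = FALSE)
    }
  }
  contigs <- do.call(rbind, rows)
  verdicts <- do.call(rbind, lapply(names(assemblies), function(ai) {
    c_ <- contigs[contigs$assembly == ai, , drop = FALSE]
    bad <- c_$contig_id[!c_$supported & c_$length >= large_cutoff]
    data.frame(assembly = ai,
               verdict = if (length(bad)) "cull" else "keep",
               offending = paste(bad, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(list(contigs = contigs, verdicts = verdicts),
            class = "dw_congruency")
}

#' @export
print.dw_congruency <- function(x, ...) {
  cat("assembly congruency report:\n")
  for (i in seq_len(nrow(x$verdicts))) {
    v <- x$verdicts[i, ]
    cat(sprintf("  %s: %s%s\n", v$assembly, v$verdict,
                if (nzchar(v$offending))
                  paste0(" (unsupported large contigs: ", v$offending, ")")
                else ""))
  }
  invisible(x)
}
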