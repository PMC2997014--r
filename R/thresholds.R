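#' Numeric thresholds governing the improvement pipeline
#'
#' Single source of truth for every numeric rule the toolkit applies. The
#' defaults are the published rules of the reference-assisted improvement
#' procedure: 300 bp contig-end queries taken from contigs strictly longer
#' than 1 kb, an E-value ceiling of 0.02 for qualifying homology, reference
#' separation of at most 1 kb between paired end alignments, exact overlaps of
#' at least 15 bp for contig merging, N-runs capped at 300 bases (only runs
#' strictly longer than 300 are touched), 25-mer synteny anchors, a 3.0-bit
#' floor for motif hits, and a 500 bp upstream window to the nearest CDS.
#'
#' @param end_len bases extracted from each contig end (default 300).
#' @param min_contig_for_ends only contigs strictly longer than this yield
#'   ends (default 1000).
#' @param max_evalue E-value ceiling for qualifying alignments (default 0.02).
#' @param max_ref_separation maximum inner-boundary separation, in bp, of two
#'   end alignments on the reference for a gap candidate (default 1000).
#' @param min_overlap minimum exact suffix-prefix overlap for a contig merge
#'   (default 15).
#' @param nrun_cap replacement size for unplaceable oversized N-runs
#'   (default 300).
#' @param nrun_min_to_touch only N-runs strictly longer than this are resized
#'   (default 300).
#' @param max_resize_separation ceiling, in bp, on the reference separation of
#'   the two flank alignments when resizing an N-run (default 50000).
#' @param k_synteny k-mer size for synteny anchors and dot plots (default 25).
#' @param min_bits bit-score floor for reported motif hits (default 3.0).
#' @param cds_window maximum distance, in bp, from a motif hit to a downstream
#'   CDS start (default 500).
#' @param min_len_reorder only scaffolds strictly longer than this are placed
#'   by the reorderer (default 1000).
#' @param min_anchors minimum number of unique k-mer anchors required to place
#'   a scaffold (default 3).
#' @param word_size seed word size of the local aligner (default 11).
#' @return An object of class `dw_thresholds` (a named list).
#' @examples
#' th <- thresholds()
#' th$max_evalue
#' @export
thresholds <- function(end_len = 300L,
                       min_contig_for_ends = 1000L,
                       max_evalue = 0.02,
                       max_ref_separation = 1000L,
                       min_overlap = 15L,
                       nrun_cap = 300L,
                       nrun_min_to_touch = 300L,
                       max_resize_separation = 50000L,
                       k_synteny = 25L,
                       min_bits = 3.0,
                       cds_window = 500L,
                       min_len_reorder = 1000L,
                       min_anchors = 3L,
                       word_size = 11L) {
  th <- list(end_len = as.integer(end_len),
             min_contig_for_ends = as.integer(min_contig_for_ends),
             max_evalue = as.numeric(max_evalue),
             max_ref_separation = as.integer(max_ref_separation),
             min_overlap = as.integer(min_overlap),
             nrun_cap = as.integer(nrun_cap),
             nrun_min_to_touch = as.integer(nrun_min_to_touch),
             max_resize_separation = as.integer(max_resize_separation),
             k_synteny = as.integer(k_synteny),
             min_bits = as.numeric(min_bits),
             cds_window = as.integer(cds_window),
             min_len_reorder = as.integer(min_len_reorder),
             min_anchors = as.integer(min_anchors),
             word_size = as.integer(word_size))
  bad <- names(th)[vapply(th, function(x) !is.finite(x) || x <= 0, logical(1))]
  if (length(bad)) stop("thresholds must be positive: ", paste(bad, collapse = ", "))
  structure(th, class = "dw_thresholds")
}

#' @export
print.dw_thresholds <- function(x, ...) {
  cat("draftweaver thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
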