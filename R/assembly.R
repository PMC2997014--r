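#' Construct an assembly from sequences
#'
#' An assembly is the core container of the toolkit: an ordered, uniquely
#' named collection of contig (or scaffold) sequences over the alphabet
#' ACGTN. Sequences are uppercased and any non-ACGTN IUPAC code is mapped to
#' N, so ambiguous bases never reach the alignment code.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param label free-text label for the assembly.
#' @return An object of class `dw_assembly`: a list with elements `seqs`
#'   (named character vector), `label`, and `n_mapped` (count of non-ACGTN
#'   characters replaced by N on ingest).
#' @export
assembly <- function(seqs, label = "assembly") {
  if (length(seqs) == 0) stop("assembly has no contigs")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all contigs must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for contig: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  norm <- lapply(seqs, normalize_seq)
  n_mapped <- sum(vapply(norm, attr, numeric(1), "n_mapped"))
  if (n_mapped > 0) dw_log("assembly", non_acgtn_mapped_to_N = n_mapped)
  out <- list(seqs = setNames(vapply(norm, as.character, character(1)), ids),
              label = label, n_mapped = n_mapped)
  structure(out, class = "dw_assembly")
}

#' @export
print.dw_assembly <- function(x, ...) {
  cat(sprintf("draftweaver assembly '%s': %d contigs, %s bases\n",
              x$label, length(x$seqs),
              format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' @export
length.dw_assembly <- function(x) length(x$seqs)

contig_lengths <- function(asm) setNames(nchar(asm$seqs), names(asm$seqs))

#' Read a multi-FASTA file into an assembly
#'
#' The id of each contig is the header token before the first whitespace.
#' Sequences are uppercased; non-ACGTN IUPAC codes become N (logged).
#'
#' @param path path to a FASTA file.
#' @param label assembly label (defaults to the file name).
#' @return A [assembly()] object, record order preserved.
#' @export
read_fasta <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- setNames(as.character(set), ids)
  assembly(seqs, label = label)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector, or a `dw_assembly`.
#' @param path output path.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "dw_assembly")) seqs <- seqs$seqs
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read CDS (or other) features from a GFF3 file
#'
#' Keeps rows whose type matches `types` and returns 1-based inclusive
#' coordinates, exactly as stored in GFF3. A trailing `##FASTA` section is
#' tolerated and ignored.
#'
#' @param path path to a GFF3 file.
#' @param types feature types to keep (default "CDS").
#' @return data.frame with columns seq_id, start, end, strand, feature_id.
#' @export
read_gff <- function(path, types = "CDS") {
  if (!file.exists(path)) stop("no such file: ", path)
  # pre-validate coordinates so the offending line can be named
  lines <- readLines(path)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1L)]
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
      if (!is.na(s) && !is.na(e) && s > e) {
        stop(sprintf("GFF line %d: start (%d) > end (%d)", i, s, e))
      }
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% types
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids[is.na(ids) | !nzchar(ids)] <-
    paste0("feature_", which(is.na(ids) | !nzchar(ids)))
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_id = ids,
    stringsAsFactors = FALSE)
  dw_log("read_gff", path = path, features = nrow(out))
  out
}

#' Write gene features to a GFF3 file
#'
#' @param genes data.frame as returned by [read_gff()].
#' @param path output path.
#' @param type feature type to write (default "CDS").
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path, type = "CDS", source = "draftweaver") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                       genes$seq_id, source, type,
                       as.integer(genes$start), as.integer(genes$end),
                       genes$strand, genes$feature_id), con)
  }
  invisible(path)
}

#' Assembly length statistics (N50 and friends)
#'
#' N50 size is the length of the contig at which the cumulative sum of
#' lengths, sorted descending, first reaches at least half the assembly
#' total; N50 number is how many contigs that takes (ties resolve to the
#' first contig reaching half-total).
#'
#' @param asm a [assembly()] object.
#' @param cutoffs length cutoffs for the "contigs greater than" counts.
#' @return An object of class `dw_stats`.
#' @examples
#' a <- assembly(c(c1 = strrep("A", 400), c2 = strrep("C", 300),
#'                 c3 = strrep("G", 200), c4 = strrep("T", 100)))
#' length_stats(a)  # N50 size 300 reached at the 2nd contig
#' @export
length_stats <- function(asm, cutoffs = c(100L, 1000L)) {
  stopifnot(inherits(asm, "dw_assembly"))
  len <- unname(sort(nchar(asm$seqs), decreasing = TRUE))
  total <- sum(len)
  cum <- cumsum(len)
  i50 <- which(cum >= total / 2)[1]
  out <- list(
    n_contigs = length(len),
    n_over = setNames(vapply(cutoffs, function(c) sum(len > c), integer(1)),
                      paste0(">", cutoffs)),
    total_bases = total,
    largest = len[1],
    n50_size = len[i50],
    n50_number = i50)
  structure(out, class = "dw_stats")
}

#' @export
print.dw_stats <- function(x, ...) {
  cat("assembly statistics:\n")
  cat(sprintf("  contigs:      %d\n", x$n_contigs))
  for (nm in names(x$n_over)) {
    cat(sprintf("  contigs %s: %d\n", nm, x$n_over[[nm]]))
  }
  cat(sprintf("  total bases:  %s\n", format(x$total_bases, big.mark = ",")))
  cat(sprintf("  largest:      %s\n", format(x$largest, big.mark = ",")))
  cat(sprintf("  N50 size:     %s\n", format(x$n50_size, big.mark = ",")))
  cat(sprintf("  N50 number:   %d\n", x$n50_number))
  invisible(x)
}

#' Read a FASTQ file
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return data.frame with columns id, seq, qual, mate_id (NA).
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(set)),
             seq = toupper(as.character(set)),
             qual = as.character(S4Vectors::mcols(set)$qualities),
             mate_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Pair two read sets positionally
#'
#' @param r1,r2 data.frames from [read_fastq()], same length, mates in order.
#' @return One combined data.frame with `mate_id` filled in.
#' @export
pair_reads <- function(r1, r2) {
  if (nrow(r1) != nrow(r2)) stop("mate files differ in read count")
  r1$mate_id <- r2$id
  r2$mate_id <- r1$id
  rbind(r1, r2)
}

#' Trim read tails and drop reads with ambiguous bases
#'
#' Reads are first trimmed: a read whose (pre-trim) length appears in
#' `trim_last` loses that many bases from its 3' end. The defaults remove the
#' last four bases of 36-mers and the last six of 76-mers. Ambiguity
#' filtering runs after trimming: any read still containing a non-ACGT
#' character is removed, and in paired mode its mate is removed with it.
#'
#' @param reads data.frame with columns id, seq, optional qual, optional
#'   mate_id.
#' @param trim_last named vector mapping read length to bases trimmed,
#'   e.g. `c("36" = 4, "76" = 6)`.
#' @param paired if TRUE, reads are mate pairs via `mate_id`, and a pair is
#'   dropped when either member has an ambiguous base.
#' @return The filtered data.frame; attributes `n_in`, `n_trimmed`,
#'   `n_dropped` summarise the run.
#' @export
trim_and_filter_reads <- function(reads, trim_last = c("36" = 4, "76" = 6),
                                  paired = FALSE) {
  n_in <- nrow(reads)
  len <- nchar(reads$seq)
  trim <- trim_last[as.character(len)]
  trim[is.na(trim)] <- 0
  newlen <- len - as.integer(trim)
  if (any(newlen < 1)) stop("trimming would remove an entire read")
  reads$seq <- substr(reads$seq, 1L, newlen)
  if (!is.null(reads$qual) && !all(is.na(reads$qual))) {
    reads$qual <- substr(reads$qual, 1L, newlen)
  }
  bad <- grepl("[^ACGT]", reads$seq)
  if (paired) {
    if (is.null(reads$mate_id) || anyNA(reads$mate_id)) {
      stop("paired mode requires mate_id for every read")
    }
    orphan <- !(reads$mate_id %in% reads$id)
    if (any(orphan)) {
      stop("orphan reads with missing mates: ",
           paste(head(reads$id[orphan], 10), collapse = ", "))
    }
    bad_ids <- reads$id[bad]
    bad <- bad | reads$mate_id %in% bad_ids
  }
  out <- reads[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_in") <- n_in
  attr(out, "n_trimmed") <- sum(trim > 0)
  attr(out, "n_dropped") <- sum(bad)
  dw_log("trim_and_filter_reads", n_in = n_in, n_out = nrow(out),
         dropped = sum(bad))
  out
}

#' Theoretical sequencing coverage
#'
#' Fold coverage implied by a read count: `read_count * ends_per_record *
#' read_len_after_trim / genome_size`, rounded to the nearest integer (as
#' coverage tables conventionally print whole folds).
#'
#' @param read_count number of records (pairs count once).
#' @param ends_per_record 1 for single-end, 2 for paired-end records.
#' @param read_len_after_trim read length after tail trimming, in nt.
#' @param genome_size assumed genome size in bp.
#' @return Integer fold coverage.
#' @examples
#' theoretical_coverage(16852820, 1, 32, 6.5e6)  # 83
#' theoretical_coverage(10854745, 2, 70, 6.5e6)  # 234
#' @export
theoretical_coverage <- function(read_count, ends_per_record,
                                 read_len_after_trim, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (read_count < 0 || ends_per_record <= 0 || read_len_after_trim <= 0) {
    stop("read_count must be >= 0; other arguments positive")
  }
  as.integer(round(read_count * ends_per_record * read_len_after_trim /
                     genome_size))
}
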