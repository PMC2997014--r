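# Scaffold layout model and AGP v2.1 I/O.
#
# A scaffold is an ordered list of parts: contig intervals with orientation,
# and gap records rendered as runs of N. Internally contig sub-intervals are
# 0-based half-open; AGP emission converts to the format's 1-based inclusive
# coordinates.

GAP_KINDS <- c(sequence_gap = "paired-ends",
               physical_gap_closed = "align_genus",
               unknown = "na")

#' Construct a contig part of a scaffold
#'
#' @param contig_id contig identifier.
#' @param orientation "+" or "-".
#' @param start,end 0-based half-open sub-interval of the contig; NA means
#'   the whole contig (resolved when a layout is written).
#' @return A list of class `dw_part`.
#' @export
contig_part <- function(contig_id, orientation = "+", start = NA_integer_,
                        end = NA_integer_) {
  if (!orientation %in% c("+", "-")) {
    stop("orientation must be '+' or '-', got: ", orientation)
  }
  structure(list(type = "contig", contig_id = contig_id,
                 orientation = orientation,
                 start = as.integer(start), end = as.integer(end)),
            class = "dw_part")
}

#' Construct a gap record
#'
#' @param n_count number of N characters (>= 1).
#' @param kind one of "sequence_gap", "physical_gap_closed", "unknown".
#' @param evidence free-text evidence note.
#' @return A list of class `dw_part`.
#' @export
gap_part <- function(n_count, kind = "unknown", evidence = "") {
  n_count <- as.integer(n_count)
  if (is.na(n_count) || n_count < 1) stop("gap n_count must be >= 1")
  kind <- match.arg(kind, names(GAP_KINDS))
  structure(list(type = "gap", n_count = n_count, kind = kind,
                 evidence = evidence), class = "dw_part")
}

#' Construct a scaffold
#'
#' @param id scaffold identifier.
#' @param parts list of [contig_part()] and [gap_part()] objects. Must start
#'   and end with a contig part, with no two consecutive gaps.
#' @return An object of class `dw_scaffold`.
#' @export
scaffold <- function(id, parts) {
  types <- vapply(parts, `[[`, character(1), "type")
  if (length(parts) == 0 || types[1] != "contig" ||
      types[length(types)] != "contig") {
    stop("scaffold must start and end with a contig part")
  }
  if (any(types[-1] == "gap" & types[-length(types)] == "gap")) {
    stop("scaffold has two consecutive gap records")
  }
  structure(list(id = id, parts = parts), class = "dw_scaffold")
}

#' @export
print.dw_scaffold <- function(x, ...) {
  desc <- vapply(x$parts, function(p) {
    if (p$type == "contig") paste0(p$contig_id, "(", p$orientation, ")")
    else paste0("gap:", p$n_count, "N")
  }, character(1))
  cat(sprintf("scaffold %s: %s\n", x$id, paste(desc, collapse = " - ")))
  invisible(x)
}

# resolve NA sub-intervals against the assembly; error on unknown contigs
resolve_parts <- function(sc, asm) {
  lens <- contig_lengths(asm)
  sc$parts <- lapply(sc$parts, function(p) {
    if (p$type != "contig") return(p)
    if (!p$contig_id %in% names(lens)) {
      stop("scaffold ", sc$id, " references unknown contig: ", p$contig_id)
    }
    if (is.na(p$start)) p$start <- 0L
    if (is.na(p$end)) p$end <- unname(lens[p$contig_id])
    if (p$start < 0 || p$end > lens[p$contig_id] || p$start >= p$end) {
      stop("invalid sub-interval for contig ", p$contig_id)
    }
    p
  })
  sc
}

#' Render the nucleotide sequence of a scaffold
#'
#' @param sc a [scaffold()].
#' @param asm the [assembly()] holding its contigs.
#' @return A single character string; gaps are runs of N.
#' @export
scaffold_seq <- function(sc, asm) {
  sc <- resolve_parts(sc, asm)
  pieces <- vapply(sc$parts, function(p) {
    if (p$type == "gap") return(strrep("N", p$n_count))
    s <- substr(asm$seqs[[p$contig_id]], p$start + 1L, p$end)
    if (p$orientation == "-") s <- revcomp(s)
    s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Write a scaffold layout as AGP v2.1 plus a scaffold FASTA
#'
#' Gap lines use gap_type "scaffold" with linkage "yes"; the gap kind is
#' carried in the linkage_evidence column (paired-ends = sequence gap,
#' align_genus = closed physical gap, na = unknown). Writing then reading
#' then writing again reproduces the AGP file byte for byte.
#'
#' @param scaffolds list of [scaffold()] objects.
#' @param asm the [assembly()] holding the component contigs.
#' @param path_agp output AGP path (NULL to skip).
#' @param path_fasta output FASTA path of rendered scaffolds (NULL to skip).
#' @return Invisibly, the named character vector of scaffold sequences.
#' @export
write_layout <- function(scaffolds, asm, path_agp = NULL, path_fasta = NULL) {
  lines <- character(0)
  seqs <- character(0)
  for (sc in scaffolds) {
    sc <- resolve_parts(sc, asm)
    pos <- 0L
    for (i in seq_along(sc$parts)) {
      p <- sc$parts[[i]]
      if (p$type == "contig") {
        w <- p$end - p$start
        lines <- c(lines, sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s",
                                  sc$id, pos + 1L, pos + w, i, p$contig_id,
                                  p$start + 1L, p$end, p$orientation))
        pos <- pos + w
      } else {
        lines <- c(lines, sprintf("%s\t%d\t%d\t%d\tN\t%d\tscaffold\tyes\t%s",
                                  sc$id, pos + 1L, pos + p$n_count, i,
                                  p$n_count, GAP_KINDS[[p$kind]]))
        pos <- pos + p$n_count
      }
    }
    seqs[sc$id] <- scaffold_seq(sc, asm)
  }
  if (!is.null(path_agp)) {
    writeLines(c("##agp-version\t2.1", lines), path_agp)
  }
  if (!is.null(path_fasta)) write_fasta(seqs, path_fasta)
  invisible(seqs)
}

#' Read an AGP v2.1 layout
#'
#' @param path AGP file path.
#' @return A list of [scaffold()] objects with explicit sub-intervals.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(f, `[[`, character(1), 1)
  kind_rev <- setNames(names(GAP_KINDS), GAP_KINDS)
  out <- lapply(split(seq_along(f), factor(ids, levels = unique(ids))),
                function(rows) {
    parts <- lapply(rows, function(i) {
      x <- f[[i]]
      if (x[5] %in% c("N", "U")) {
        gap_part(as.integer(x[6]),
                 kind = if (x[9] %in% names(kind_rev)) kind_rev[[x[9]]]
                        else "unknown")
      } else {
        contig_part(x[6], orientation = x[9],
                    start = as.integer(x[7]) - 1L, end = as.integer(x[8]))
      }
    })
    scaffold(f[[rows[1]]][1], parts)
  })
  unname(out)
}
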