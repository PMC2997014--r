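# Gap-closure logic: contig-end extraction, reference-mediated gap
# candidates, overlap and shared-gene joins, join application, and N-run
# resizing against homologous reference sequence.

#' Extract query ends from large contigs
#'
#' Takes `end_len` bases (default 300) from both ends of every contig
#' strictly longer than `min_contig_for_ends` (default 1 kb). Right ends are
#' stored in the contig's forward orientation.
#'
#' @param asm an [assembly()].
#' @param th a [thresholds()] object.
#' @return data.frame with columns contig_id, side ("left"/"right"), seq,
#'   start, end (0-based half-open interval on the contig).
#' @export
extract_ends <- function(asm, th = thresholds()) {
  stopifnot(inherits(asm, "dw_assembly"))
  lens <- contig_lengths(asm)
  qual <- names(lens)[lens > th$min_contig_for_ends]
  rows <- lapply(qual, function(id) {
    L <- lens[[id]]
    e <- min(th$end_len, L)
    data.frame(contig_id = id, side = c("left", "right"),
               seq = c(substr(asm$seqs[[id]], 1L, e),
                       substr(asm$seqs[[id]], L - e + 1L, L)),
               start = c(0L, L - e), end = c(e, L),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(contig_id = character(0), side = character(0),
               seq = character(0), start = integer(0), end = integer(0))
  }
  dw_log("extract_ends", contigs = length(lens), qualifying = length(qual))
  out
}

# which way an aligned end faces on the reference: the side of its hit on
# which the missing sequence (the gap) must lie
end_facing <- function(side, strand) {
  ifelse((side == "right") == (strand == "+"), "right", "left")
}

# unaligned end bases on the gap side (real sequence, not gap)
gap_overhang <- function(side, q_start, q_end, qlen) {
  ifelse(side == "right", qlen - q_end, q_start)
}

# geometry of a putative junction between two aligned ends on one reference:
# separation between the facing alignment boundaries (negative = overlap) and
# whether the facings are consistent with the two contigs bridging a gap
pair_geometry <- function(hA, hB) {
  sep <- max(hA$s_start, hB$s_start) - min(hA$s_end, hB$s_end)
  fA <- end_facing(hA$side, hA$strand)
  fB <- end_facing(hB$side, hB$strand)
  if (hA$s_start <= hB$s_start) {
    consistent <- (fA == "right" && fB == "left")
  } else {
    consistent <- (fA == "left" && fB == "right")
  }
  if (sep < 0 && fA == fB) consistent <- FALSE
  list(separation = sep, consistent = consistent,
       overhangs = gap_overhang(hA$side, hA$q_start, hA$q_end, hA$qlen) +
                   gap_overhang(hB$side, hB$q_start, hB$q_end, hB$qlen))
}

# best qualifying (lowest-E) hit of a sequence, or NULL; drops ambiguous
# (repeat-flagged) queries
best_hit <- function(seq, index, scoring, max_evalue, query_id = "q") {
  h <- local_align(seq, index, scoring = scoring, max_evalue = max_evalue,
                   query_id = query_id)
  if (isTRUE(attr(h, "ambiguous"))) return(structure(list(), ambiguous = TRUE))
  if (!nrow(h)) return(NULL)
  as.list(h[1, ])
}

# best hits for a frame of ends; adds hit columns, keeps only ends with a
# qualifying non-ambiguous hit (ambiguous ones logged)
ends_best_hits <- function(ends, index, scoring, max_evalue) {
  rows <- list()
  n_ambig <- 0L
  for (i in seq_len(nrow(ends))) {
    h <- best_hit(ends$seq[i], index, scoring, max_evalue,
                  query_id = paste0(ends$contig_id[i], ":", ends$side[i]))
    if (isTRUE(attr(h, "ambiguous"))) { n_ambig <- n_ambig + 1L; next }
    if (is.null(h)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = ends$contig_id[i], side = ends$side[i],
      qlen = nchar(ends$seq[i]),
      subject_id = h$subject_id, q_start = h$q_start, q_end = h$q_end,
      s_start = h$s_start, s_end = h$s_end, strand = h$strand,
      evalue = h$evalue, score = h$score, stringsAsFactors = FALSE)
  }
  if (n_ambig) dw_log("ends_best_hits", ambiguous_skipped = n_ambig)
  if (!length(rows)) {
    return(data.frame(contig_id = character(0), side = character(0),
                      qlen = integer(0), subject_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), evalue = numeric(0),
                      score = integer(0)))
  }
  do.call(rbind, rows)
}

#' Find reference-mediated gap candidates between contig ends
#'
#' For every unordered pair of ends from different contigs whose best
#' non-ambiguous qualifying hits (E-value at or below the ceiling) land on
#' the same reference sequence, with the two contigs facing each other and
#' their alignment inner boundaries separated by at most
#' `max_ref_separation` bp, emits one candidate. The implied gap subtracts
#' each end's unaligned gap-side overhang and is floored at zero with an
#' overlap flag. Candidates are sorted by the worse of the two E-values.
#'
#' @param ends data.frame from [extract_ends()].
#' @param ref_index reference [build_seed_index()].
#' @param th a [thresholds()].
#' @param scoring a [scoring_scheme()].
#' @return data.frame of candidates, one row per qualifying end pair, with
#'   contig/side pairs ordered left-to-right along the reference.
#' @export
find_gap_candidates <- function(ends, ref_index, th = thresholds(),
                                scoring = scoring_scheme()) {
  hits <- ends_best_hits(ends, ref_index, scoring, th$max_evalue)
  out <- list()
  if (nrow(hits) >= 2) {
    for (i in seq_len(nrow(hits) - 1L)) {
      for (j in (i + 1L):nrow(hits)) {
        if (hits$contig_id[i] == hits$contig_id[j]) next
        if (hits$subject_id[i] != hits$subject_id[j]) next
        a <- as.list(hits[i, ]); b <- as.list(hits[j, ])
        if (a$s_start > b$s_start) { tmp <- a; a <- b; b <- tmp }
        g <- pair_geometry(a, b)
        if (abs(g$separation) > th$max_ref_separation) next
        if (!g$consistent) next
        implied <- g$separation - g$overhangs
        out[[length(out) + 1L]] <- data.frame(
          contig_a = a$contig_id, side_a = a$side,
          contig_b = b$contig_id, side_b = b$side,
          reference_id = a$subject_id,
          a_start = a$s_start, a_end = a$s_end, strand_a = a$strand,
          b_start = b$s_start, b_end = b$s_end, strand_b = b$strand,
          separation = g$separation,
          implied_gap = max(0L, as.integer(implied)),
          overlap = implied < 0,
          evalue_a = a$evalue, evalue_b = b$evalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig_a = character(0), side_a = character(0),
                      contig_b = character(0), side_b = character(0),
                      reference_id = character(0), a_start = integer(0),
                      a_end = integer(0), strand_a = character(0),
                      b_start = integer(0), b_end = integer(0),
                      strand_b = character(0), separation = integer(0),
                      implied_gap = integer(0), overlap = logical(0),
                      evalue_a = numeric(0), evalue_b = numeric(0)))
  }
  cand <- do.call(rbind, out)
  cand <- cand[order(pmax(cand$evalue_a, cand$evalue_b)), , drop = FALSE]
  rownames(cand) <- NULL
  dw_log("find_gap_candidates", ends = nrow(ends), candidates = nrow(cand))
  cand
}

#' Convert gap candidates to join proposals
#'
#' @param candidates data.frame from [find_gap_candidates()].
#' @return Proposal data.frame for [apply_joins()], kind
#'   "reference_adjacency"; gap size is the implied gap floored at 1 N.
#' @export
candidates_to_proposals <- function(candidates) {
  if (!nrow(candidates)) return(empty_proposals())
  data.frame(kind = "reference_adjacency",
             contig_a = candidates$contig_a, side_a = candidates$side_a,
             contig_b = candidates$contig_b, side_b = candidates$side_b,
             gap_n = pmax(1L, candidates$implied_gap),
             overlap_len = NA_integer_,
             score = -log10(pmax(candidates$evalue_a, candidates$evalue_b) +
                            1e-300),
             evidence = paste0("ref:", candidates$reference_id),
             stringsAsFactors = FALSE)
}

empty_proposals <- function() {
  data.frame(kind = character(0), contig_a = character(0),
             side_a = character(0), contig_b = character(0),
             side_b = character(0), gap_n = integer(0),
             overlap_len = integer(0), score = numeric(0),
             evidence = character(0), stringsAsFactors = FALSE)
}

# maximal exact suffix(A)-prefix(B) overlap length in [min_len, cap], 0 if none
max_exact_overlap <- function(a, b, min_len, cap = 5000L) {
  la <- nchar(a); lb <- nchar(b)
  hi <- min(la, lb, cap)
  if (hi < min_len) return(0L)
  for (L in hi:min_len) {
    if (substr(a, la - L + 1L, la) == substr(b, 1L, L)) return(L)
  }
  0L
}

#' Propose exact-overlap merges between reference-adjacent contigs
#'
#' For contig pairs known to be adjacent from reference evidence, proposes a
#' merge when an exact suffix-prefix overlap of at least `min_overlap` bases
#' (default 15, 100% identity) exists, at the maximal such overlap. When a
#' pair's orientations are not supplied, all four orientation combinations
#' are tested.
#'
#' @param asm an [assembly()].
#' @param adjacency data.frame with columns contig_a, contig_b and optional
#'   orientation_a, orientation_b ("+"/"-"; NA = unknown).
#' @param th a [thresholds()].
#' @return Proposal data.frame (kind "overlap_merge") for [apply_joins()].
#' @export
merge_overlaps <- function(asm, adjacency, th = thresholds()) {
  out <- list()
  for (i in seq_len(nrow(adjacency))) {
    ca <- adjacency$contig_a[i]; cb <- adjacency$contig_b[i]
    oa <- if ("orientation_a" %in% names(adjacency))
      adjacency$orientation_a[i] else NA_character_
    ob <- if ("orientation_b" %in% names(adjacency))
      adjacency$orientation_b[i] else NA_character_
    combos <- expand.grid(oa = if (is.na(oa)) c("+", "-") else oa,
                          ob = if (is.na(ob)) c("+", "-") else ob,
                          stringsAsFactors = FALSE)
    best <- 0L; best_combo <- NULL
    for (k in seq_len(nrow(combos))) {
      sa <- asm$seqs[[ca]]; sb <- asm$seqs[[cb]]
      if (combos$oa[k] == "-") sa <- revcomp(sa)
      if (combos$ob[k] == "-") sb <- revcomp(sb)
      L <- max_exact_overlap(sa, sb, th$min_overlap)
      if (L > best) { best <- L; best_combo <- combos[k, ] }
    }
    if (best >= th$min_overlap) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "overlap_merge", contig_a = ca,
        side_a = if (best_combo$oa == "+") "right" else "left",
        contig_b = cb,
        side_b = if (best_combo$ob == "+") "left" else "right",
        gap_n = NA_integer_, overlap_len = best, score = as.numeric(best),
        evidence = sprintf("exact %d bp overlap", best),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_proposals())
  do.call(rbind, out)
}

#' Pair contig ends through a shared reference gene
#'
#' Proposes a join when the ends of two different contigs each carry a
#' qualifying hit overlapping the same reference gene, the covered portions
#' of the gene are disjoint, and the contigs face each other. The proposed
#' gap is the stretch of gene bases left unaccounted between the two hits
#' (at least 1 N).
#'
#' @param ends data.frame from [extract_ends()].
#' @param ref_genes data.frame of reference features from [read_gff()]
#'   (1-based inclusive coordinates).
#' @param ref_index reference [build_seed_index()].
#' @param th a [thresholds()].
#' @param scoring a [scoring_scheme()].
#' @return Proposal data.frame (kind "shared_gene") for [apply_joins()].
#' @export
pair_by_shared_gene <- function(ends, ref_genes, ref_index, th = thresholds(),
                                scoring = scoring_scheme()) {
  hits <- ends_best_hits(ends, ref_index, scoring, th$max_evalue)
  out <- list()
  if (nrow(hits) >= 2) {
    gs0 <- ref_genes$start - 1L  # 0-based half-open
    ge0 <- ref_genes$end
    for (i in seq_len(nrow(hits) - 1L)) {
      for (j in (i + 1L):nrow(hits)) {
        if (hits$contig_id[i] == hits$contig_id[j]) next
        if (hits$subject_id[i] != hits$subject_id[j]) next
        a <- as.list(hits[i, ]); b <- as.list(hits[j, ])
        if (a$s_start > b$s_start) { tmp <- a; a <- b; b <- tmp }
        g <- pair_geometry(a, b)
        if (!g$consistent) next
        on_seq <- which(ref_genes$seq_id == a$subject_id)
        for (gi in on_seq) {
          covA <- c(max(a$s_start, gs0[gi]), min(a$s_end, ge0[gi]))
          covB <- c(max(b$s_start, gs0[gi]), min(b$s_end, ge0[gi]))
          if (covA[1] >= covA[2] || covB[1] >= covB[2]) next  # must overlap gene
          if (max(covA[1], covB[1]) < min(covA[2], covB[2])) next  # disjoint?
          gap <- max(covA[1], covB[1]) - min(covA[2], covB[2])
          out[[length(out) + 1L]] <- data.frame(
            kind = "shared_gene", contig_a = a$contig_id, side_a = a$side,
            contig_b = b$contig_id, side_b = b$side,
            gap_n = max(1L, as.integer(gap)),
            overlap_len = NA_integer_,
            score = as.numeric(min(a$score, b$score)),
            evidence = paste0("gene:", ref_genes$feature_id[gi]),
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (!length(out)) return(empty_proposals())
  do.call(rbind, out)
}

#' Apply join proposals to an assembly, producing scaffolds
#'
#' Each contig end may be consumed at most once. Competing proposals are
#' resolved by evidence rank (overlap_merge > shared_gene >
#' reference_adjacency), then score, then lexicographic contig ids; a
#' proposal that would close a cycle is rejected (the cycle is broken at its
#' lowest-ranked edge). Accepted chains become scaffolds; unjoined contigs
#' become single-contig scaffolds. Overlap merges trim the duplicated bases
#' from the incoming contig; gap joins insert the proposed run of Ns.
#'
#' @param asm an [assembly()].
#' @param proposals data.frame of proposals (see [candidates_to_proposals()],
#'   [merge_overlaps()], [pair_by_shared_gene()]).
#' @return List with `scaffolds` (list of [scaffold()]) and `report`
#'   (proposals annotated with `accepted` and `reason`).
#' @export
apply_joins <- function(asm, proposals) {
  ids <- names(asm$seqs)
  unknown <- setdiff(unique(c(proposals$contig_a, proposals$contig_b)), ids)
  if (length(unknown)) {
    stop("proposals reference unknown contigs: ",
         paste(unknown, collapse = ", "))
  }
  rank <- c(overlap_merge = 3L, shared_gene = 2L, reference_adjacency = 1L)
  if (nrow(proposals)) {
    o <- order(-rank[proposals$kind], -proposals$score,
               pmin(proposals$contig_a, proposals$contig_b),
               pmax(proposals$contig_a, proposals$contig_b))
    proposals <- proposals[o, , drop = FALSE]
    rownames(proposals) <- NULL
  }
  # greedy acceptance with per-end exclusivity and cycle prevention
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  used <- character(0)
  accepted <- logical(nrow(proposals))
  reason <- character(nrow(proposals))
  for (i in seq_len(nrow(proposals))) {
    ea <- paste0(proposals$contig_a[i], ":", proposals$side_a[i])
    eb <- paste0(proposals$contig_b[i], ":", proposals$side_b[i])
    if (ea %in% used || eb %in% used) {
      reason[i] <- "end already consumed by a higher-ranked join"
    } else if (find(proposals$contig_a[i]) == find(proposals$contig_b[i])) {
      reason[i] <- "would close a cycle"
    } else {
      accepted[i] <- TRUE
      reason[i] <- "accepted"
      used <- c(used, ea, eb)
      parent[find(proposals$contig_a[i])] <- find(proposals$contig_b[i])
    }
  }
  report <- cbind(proposals, accepted = accepted, reason = reason)
  # build chains from accepted edges
  edges <- proposals[accepted, , drop = FALSE]
  link <- list()  # "contig:side" -> list(other, other_side, row)
  for (i in seq_len(nrow(edges))) {
    link[[paste0(edges$contig_a[i], ":", edges$side_a[i])]] <-
      list(other = edges$contig_b[i], side = edges$side_b[i], row = i)
    link[[paste0(edges$contig_b[i], ":", edges$side_b[i])]] <-
      list(other = edges$contig_a[i], side = edges$side_a[i], row = i)
  }
  other_side <- c(left = "right", right = "left")
  visited <- character(0)
  scaffolds <- list()
  lens <- contig_lengths(asm)
  # chains are acyclic by construction, so every chain has a contig with a
  # free side to start the walk from
  has_free_side <- vapply(ids, function(id)
    is.null(link[[paste0(id, ":left")]]) ||
    is.null(link[[paste0(id, ":right")]]), logical(1))
  for (start_id in ids[has_free_side]) {
    if (start_id %in% visited) next
    free_left <- is.null(link[[paste0(start_id, ":left")]])
    enter_side <- if (free_left) "left" else "right"
    cur <- start_id; side_in <- enter_side
    parts <- list()
    trim_next <- 0L
    repeat {
      visited <- c(visited, cur)
      ori <- if (side_in == "left") "+" else "-"
      st <- 0L; en <- unname(lens[cur])
      if (trim_next > 0L) {
        if (side_in == "left") st <- st + trim_next else en <- en - trim_next
      }
      parts[[length(parts) + 1L]] <- contig_part(cur, ori, st, en)
      exit_side <- other_side[[side_in]]
      e <- link[[paste0(cur, ":", exit_side)]]
      if (is.null(e)) break
      edge <- edges[e$row, ]
      trim_next <- 0L
      if (edge$kind == "overlap_merge") {
        trim_next <- edge$overlap_len
      } else {
        parts[[length(parts) + 1L]] <-
          gap_part(edge$gap_n, kind = "physical_gap_closed",
                   evidence = edge$evidence)
      }
      cur <- e$other; side_in <- e$side
    }
    scaffolds[[length(scaffolds) + 1L]] <- parts
  }
  scaffolds <- lapply(seq_along(scaffolds), function(i) {
    scaffold(sprintf("scaffold_%04d", i), scaffolds[[i]])
  })
  dw_log("apply_joins", proposals = nrow(proposals), accepted = sum(accepted),
         scaffolds = length(scaffolds))
  list(scaffolds = scaffolds, report = report)
}

#' Locate maximal N-runs in scaffold sequences
#'
#' @param seqs named character vector of scaffold sequences (or an
#'   [assembly()] of scaffolds).
#' @return data.frame with columns scaffold_id, start (0-based), length.
#' @export
find_nruns <- function(seqs) {
  if (inherits(seqs, "dw_assembly")) seqs <- seqs$seqs
  rows <- lapply(names(seqs), function(id) {
    r <- n_runs(seqs[[id]])
    if (!nrow(r)) return(NULL)
    cbind(data.frame(scaffold_id = id, stringsAsFactors = FALSE), r)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(scaffold_id = character(0), start = integer(0),
                      length = integer(0)))
  }
  do.call(rbind, rows)
}

#' Resize oversized N-runs against a reference
#'
#' Only runs strictly longer than `nrun_min_to_touch` (default 300) are
#' touched. For each, the `end_len` bases flanking the run on either side
#' are aligned to the reference; when both flanks have qualifying hits on
#' the same reference sequence, facing each other, separated by at most
#' `max_resize_separation` bp, the run is set to the reference-implied inner
#' distance (floored at 1 N, overlap flagged). Otherwise the run is set to
#' exactly `nrun_cap` Ns — the upper bound the paired-end library can
#' support. Runs flush against a scaffold boundary are left unchanged with a
#' warning.
#'
#' @param seqs named character vector of scaffold sequences.
#' @param ref_index reference [build_seed_index()].
#' @param th a [thresholds()].
#' @param scoring a [scoring_scheme()].
#' @return List with `seqs` (resized sequences) and `report` (data.frame:
#'   scaffold_id, start, old_n, new_n, rule).
#' @export
resize_nruns <- function(seqs, ref_index, th = thresholds(),
                         scoring = scoring_scheme()) {
  if (inherits(seqs, "dw_assembly")) seqs <- seqs$seqs
  report <- list()
  out <- seqs
  for (id in names(seqs)) {
    s <- seqs[[id]]
    runs <- n_runs(s)
    if (!nrow(runs)) next
    new_n <- integer(nrow(runs))
    rule <- character(nrow(runs))
    for (i in seq_len(nrow(runs))) {
      st <- runs$start[i]; L <- runs$length[i]
      if (L <= th$nrun_min_to_touch) {
        new_n[i] <- L; rule[i] <- "untouched"
        next
      }
      lf_start <- max(0L, st - th$end_len)
      lf <- substr(s, lf_start + 1L, st)
      rf_end <- min(nchar(s), st + L + th$end_len)
      rf <- substr(s, st + L + 1L, rf_end)
      if (!nzchar(lf) || !nzchar(rf)) {
        warning("N-run at ", id, ":", st, " flush against scaffold ",
                "boundary; left unchanged")
        new_n[i] <- L; rule[i] <- "unchanged_no_flank"
        next
      }
      hl <- best_hit(lf, ref_index, scoring, th$max_evalue)
      hr <- best_hit(rf, ref_index, scoring, th$max_evalue)
      resolved <- FALSE
      if (!isTRUE(attr(hl, "ambiguous")) && !isTRUE(attr(hr, "ambiguous")) &&
          !is.null(hl) && length(hl) && !is.null(hr) && length(hr) &&
          hl$subject_id == hr$subject_id) {
        a <- list(contig_id = "L", side = "right", qlen = nchar(lf),
                  s_start = hl$s_start, s_end = hl$s_end, strand = hl$strand,
                  q_start = hl$q_start, q_end = hl$q_end)
        b <- list(contig_id = "R", side = "left", qlen = nchar(rf),
                  s_start = hr$s_start, s_end = hr$s_end, strand = hr$strand,
                  q_start = hr$q_start, q_end = hr$q_end)
        if (a$s_start > b$s_start) { tmp <- a; a <- b; b <- tmp }
        g <- pair_geometry(a, b)
        if (g$consistent && abs(g$separation) <= th$max_resize_separation) {
          implied <- g$separation - g$overhangs
          new_n[i] <- max(1L, as.integer(implied))
          rule[i] <- if (implied < 1) "reference_span_overlap"
                     else "reference_span"
          resolved <- TRUE
        }
      }
      if (!resolved) {
        new_n[i] <- th$nrun_cap
        rule[i] <- "capped"
      }
    }
    # rebuild the sequence with the new run sizes
    pieces <- character(0)
    prev <- 0L
    for (i in seq_len(nrow(runs))) {
      pieces <- c(pieces, substr(s, prev + 1L, runs$start[i]),
                  strrep("N", new_n[i]))
      prev <- runs$start[i] + runs$length[i]
    }
    pieces <- c(pieces, substr(s, prev + 1L, nchar(s)))
    out[[id]] <- paste(pieces, collapse = "")
    report[[length(report) + 1L]] <- data.frame(
      scaffold_id = id, start = runs$start, old_n = runs$length,
      new_n = new_n, rule = rule, stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else {
    data.frame(scaffold_id = character(0), start = integer(0),
               old_n = integer(0), new_n = integer(0), rule = character(0))
  }
  dw_log("resize_nruns", runs = nrow(report),
         resized = sum(report$rule != "untouched"))
  list(seqs = out, report = report)
}
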