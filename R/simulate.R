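# Synthetic fixture generator: a truth-known genome, a diverged reference,
# a fragmented assembly with corrupted N-runs, planted genes and motifs.
# Every step is deterministic given the config seed; sub-steps use fixed
# small offsets from it so the pieces are independently reproducible.

# uniform integers in [lo, hi]; safe for degenerate lo == hi ranges where
# sample() would fall back to sampling 1:lo
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Configuration for the synthetic fixture generator
#'
#' The defaults describe the standard test substrate: a 500 kb genome at
#' 60.6% GC (a typical pseudomonad value) cut into 20 contigs separated by
#' physical gaps of 0-2000 bp, with every sequence gap corrupted to
#' 10,000 Ns — the shape of the assembly artifacts the resizing step
#' corrects — and 40% of contigs reverse-complemented before reordering.
#'
#' @param genome_len genome length in bp.
#' @param gc target GC fraction.
#' @param sub_rate per-base substitution probability of the reference.
#' @param indel_rate per-base indel probability of the reference.
#' @param indel_len_max maximum indel length in bp.
#' @param n_inversions number of non-overlapping inversions in the reference.
#' @param inversion_len length range of inversions, bp.
#' @param n_contigs number of contigs to cut the genome into.
#' @param gap_len range (min, max) of true physical gap sizes, bp.
#' @param overlap_bp range of duplicated-junction lengths used when a drawn
#'   gap is 0 (0 = no duplication).
#' @param min_contig_len smallest contig the fragmenter may emit.
#' @param rc_fraction fraction of contigs reverse-complemented when the
#'   assembly is scrambled.
#' @param nrun_corrupt_size wrong N-run size injected for every true gap
#'   ("exact" rule available via [corrupt_nruns()]).
#' @param n_genes,n_motifs planted feature counts.
#' @param seed mandatory RNG seed (integer).
#' @return Object of class `dw_simconfig`.
#' @export
sim_config <- function(genome_len = 500000L, gc = 0.606,
                       sub_rate = 0, indel_rate = 0, indel_len_max = 5L,
                       n_inversions = 0L, inversion_len = c(5000L, 15000L),
                       n_contigs = 20L, gap_len = c(0L, 2000L),
                       overlap_bp = c(0L, 0L), min_contig_len = 3000L,
                       rc_fraction = 0.4,
                       nrun_corrupt_size = 10000L,
                       n_genes = 0L, n_motifs = 0L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(gc >= 0, gc <= 1, sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  structure(list(genome_len = as.integer(genome_len), gc = gc,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_len_max = as.integer(indel_len_max),
                 n_inversions = as.integer(n_inversions),
                 inversion_len = as.integer(inversion_len),
                 n_contigs = as.integer(n_contigs),
                 gap_len = as.integer(gap_len),
                 overlap_bp = as.integer(overlap_bp),
                 min_contig_len = as.integer(min_contig_len),
                 rc_fraction = rc_fraction,
                 nrun_corrupt_size = as.integer(nrun_corrupt_size),
                 n_genes = as.integer(n_genes),
                 n_motifs = as.integer(n_motifs),
                 seed = as.integer(seed)),
            class = "dw_simconfig")
}

#' Simulate an i.i.d. genome sequence
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2. The background is repeat-free by construction,
#' matching the near-unique-placement assumption of the improvement
#' procedure; see [sim_config()] for the repeat caveats.
#'
#' @param config a [sim_config()].
#' @return A nucleotide string of length `genome_len`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  paste(sample(BASES, config$genome_len, replace = TRUE, prob = p),
        collapse = "")
}

#' Derive a diverged reference from a genome
#'
#' Applies substitutions, then indels (uniform lengths 1..`indel_len_max`),
#' then non-overlapping inversions. Returns the reference and an event map.
#'
#' @param genome nucleotide string.
#' @param config a [sim_config()].
#' @return List with `reference` (string), `events` (data.frame of indel
#'   events: genome_pos, type, len) and `inversions` (data.frame of
#'   intervals on the reference, 0-based half-open).
#' @export
diverge <- function(genome, config) {
  set.seed(config$seed + 1L)
  code <- encode_seq(genome)
  n <- length(code)
  # substitutions
  if (config$sub_rate > 0) {
    at <- which(runif(n) < config$sub_rate)
    code[at] <- (code[at] + sample(1:3, length(at), replace = TRUE)) %% 4L
  }
  # indels
  events <- data.frame(genome_pos = integer(0), type = character(0),
                       len = integer(0))
  if (config$indel_rate > 0) {
    at <- which(runif(n) < config$indel_rate)
    if (length(at)) {
      type <- sample(c("ins", "del"), length(at), replace = TRUE)
      len <- sample.int(config$indel_len_max, length(at), replace = TRUE)
      events <- data.frame(genome_pos = at - 1L, type = type, len = len)
      pieces <- character(0)
      prev <- 0L
      for (i in seq_along(at)) {
        seg <- decode_seq(code[(prev + 1L):at[i]])
        if (type[i] == "ins") {
          pieces <- c(pieces, seg,
                      paste(sample(BASES, len[i], replace = TRUE),
                            collapse = ""))
          prev <- at[i]
        } else {
          pieces <- c(pieces, seg)
          prev <- min(n, at[i] + len[i])
        }
      }
      if (prev < n) pieces <- c(pieces, decode_seq(code[(prev + 1L):n]))
      ref <- paste(pieces, collapse = "")
      code <- encode_seq(ref)
    }
  }
  # inversions
  inv <- data.frame(start = integer(0), end = integer(0))
  if (config$n_inversions > 0) {
    L <- length(code)
    taken <- integer(0)
    tries <- 0L
    while (nrow(inv) < config$n_inversions) {
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("could not place ", config$n_inversions,
             " non-overlapping inversions; reduce n_inversions")
      }
      w <- sample_range(config$inversion_len[1], config$inversion_len[2], 1L)
      s <- sample.int(L - w, 1L) - 1L
      if (any(s < inv$end & s + w > inv$start)) next
      inv <- rbind(inv, data.frame(start = s, end = s + w))
      code[(s + 1L):(s + w)] <- rev(3L - code[(s + 1L):(s + w)])
    }
  }
  list(reference = decode_seq(code), events = events, inversions = inv)
}

#' Fragment a genome into contigs with known physical gaps
#'
#' Deletes a gap of `gap_len` bases between consecutive contigs; when a
#' drawn gap is 0 and `overlap_bp` is positive, the two contigs instead
#' share a duplicated junction of that many bases (the signature the exact
#' overlap merger detects). Contigs are named c0001, c0002, ... in genome
#' order.
#'
#' @param genome nucleotide string.
#' @param config a [sim_config()].
#' @param plan optional explicit data.frame(contig_len, gap_len) overriding
#'   the automatic plan (last row's gap_len is ignored).
#' @return List with `assembly` (an [assembly()], contigs in genome order,
#'   forward orientation) and `truth`: data.frames `contigs` (contig_id,
#'   genome start/end, order) and `adjacencies` (contig_a, contig_b,
#'   gap, overlap_bp).
#' @export
fragment <- function(genome, config, plan = NULL) {
  set.seed(config$seed + 2L)
  glen <- nchar(genome)
  if (is.null(plan)) {
    n <- config$n_contigs
    gaps <- if (n > 1)
      sample_range(config$gap_len[1], config$gap_len[2], n - 1L)
    else integer(0)
    total_c <- glen - sum(gaps)
    if (total_c < n * config$min_contig_len) {
      stop("fragment plan exceeds genome length")
    }
    base <- total_c %/% n
    lens <- rep(base, n)
    lens[seq_len(total_c - base * n)] <- base + 1L
    # jitter lengths while preserving the total and the minimum
    jit <- round(runif(n, -0.2, 0.2) * base)
    jit <- jit - round(sum(jit) / n)
    jit[n] <- -(sum(jit) - jit[n])
    lens <- pmax(config$min_contig_len, lens + jit)
    lens[n] <- total_c - sum(lens[-n])
    if (lens[n] < config$min_contig_len) {
      stop("jittered plan leaves the last contig too short; ",
           "reduce n_contigs or gap sizes")
    }
    plan <- data.frame(contig_len = lens, gap_len = c(gaps, 0L))
  } else if (sum(plan$contig_len) + sum(plan$gap_len[-nrow(plan)]) > glen) {
    stop("fragment plan exceeds genome length")
  }
  n <- nrow(plan)
  ovl <- integer(n - 1L)
  if (n > 1 && config$overlap_bp[2] > 0) {
    ovl <- ifelse(plan$gap_len[-n] == 0L,
                  sample_range(config$overlap_bp[1], config$overlap_bp[2],
                               n - 1L), 0L)
  }
  ids <- sprintf("c%04d", seq_len(n))
  seqs <- character(n)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    s <- if (i > 1) pos - ovl[i - 1L] else pos
    e <- s + plan$contig_len[i]
    seqs[i] <- substr(genome, s + 1L, e)
    starts[i] <- s; ends[i] <- e
    pos <- e + if (i < n) plan$gap_len[i] else 0L
  }
  adj <- if (n > 1) {
    data.frame(contig_a = ids[-n], contig_b = ids[-1],
               gap = plan$gap_len[-n], overlap_bp = ovl,
               stringsAsFactors = FALSE)
  } else {
    data.frame(contig_a = character(0), contig_b = character(0),
               gap = integer(0), overlap_bp = integer(0))
  }
  list(assembly = assembly(setNames(seqs, ids), label = "simulated contigs"),
       truth = list(contigs = data.frame(contig_id = ids, start = starts,
                                         end = ends, order = seq_len(n),
                                         stringsAsFactors = FALSE),
                    adjacencies = adj))
}

#' Scramble an assembly for the reordering test
#'
#' Shuffles contig order and reverse-complements a random fraction,
#' recording the true orientation of every contig.
#'
#' @param asm an [assembly()] (contigs in true order, forward orientation).
#' @param config a [sim_config()] (`rc_fraction`, `seed`).
#' @return List with `assembly` (scrambled) and `orientation` (named "+"/"-"
#'   vector of true orientations as stored).
#' @export
scramble_assembly <- function(asm, config) {
  set.seed(config$seed + 3L)
  ids <- names(asm$seqs)
  ord <- sample(seq_along(ids))
  n_rc <- round(config$rc_fraction * length(ids))
  rc_ids <- sample(ids, n_rc)
  seqs <- asm$seqs[ord]
  for (id in rc_ids) seqs[[id]] <- revcomp(seqs[[id]])
  orientation <- setNames(ifelse(ids %in% rc_ids, "-", "+"), ids)
  list(assembly = assembly(seqs, label = paste0(asm$label, " (scrambled)")),
       orientation = orientation)
}

#' Build corrupted scaffolds from a fragmented genome
#'
#' Joins the contigs in true order and replaces every true gap with an
#' N-run of the wrong size (`nrun_corrupt_size`, default rule "fixed"), the
#' artifact shape the resizing step corrects. Rule "exact" emits the true
#' size (negative control). Gap-0 adjacencies emit no N-run.
#'
#' @param frag result of [fragment()].
#' @param config a [sim_config()].
#' @param rule "fixed" or "exact".
#' @return List with `seqs` (named character: one scaffold) and `truth`
#'   (data.frame: scaffold_id, start (0-based) and emitted/true run sizes).
#' @export
corrupt_nruns <- function(frag, config, rule = c("fixed", "exact")) {
  rule <- match.arg(rule)
  asm <- frag$assembly
  adj <- frag$truth$adjacencies
  ids <- frag$truth$contigs$contig_id
  pieces <- character(0)
  truth <- list()
  pos <- 0L
  for (i in seq_along(ids)) {
    s <- asm$seqs[[ids[i]]]
    pieces <- c(pieces, s)
    pos <- pos + nchar(s)
    if (i < length(ids)) {
      gap <- adj$gap[i]
      if (gap > 0L) {
        emit <- if (rule == "fixed") config$nrun_corrupt_size else gap
        pieces <- c(pieces, strrep("N", emit))
        truth[[length(truth) + 1L]] <- data.frame(
          scaffold_id = "scaffold_1", start = pos, emitted = emit,
          true_size = gap, stringsAsFactors = FALSE)
        pos <- pos + emit
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(scaffold_id = character(0), start = integer(0),
               emitted = integer(0), true_size = integer(0))
  }
  list(seqs = c(scaffold_1 = paste(pieces, collapse = "")), truth = truth)
}

#' Plant non-overlapping genes and upstream motif instances
#'
#' Gene intervals (uniform lengths 300-3000 bp, random strands) are placed
#' without overlap; motif instances sampled column-wise from `profile`'s
#' probabilities are written into the sequence 0-500 bp upstream of a
#' random subset of gene starts, on the gene's strand.
#'
#' @param genome nucleotide string.
#' @param config a [sim_config()] (`n_genes`, `n_motifs`, `seed`).
#' @param profile a [train_profile()] model to sample motif instances from
#'   (required when `n_motifs` > 0).
#' @param max_dist maximum planted upstream distance (default 500).
#' @return List with `genome` (modified string), `genes` (1-based
#'   data.frame as from [read_gff()]) and `motif_sites` (seq_id, start, end
#'   0-based half-open, strand, gene, distance).
#' @export
plant_features <- function(genome, config, profile = NULL, max_dist = 500L) {
  set.seed(config$seed + 4L)
  glen <- nchar(genome)
  genes <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      feature_id = character(0), stringsAsFactors = FALSE)
  placed <- data.frame(start = integer(0), end = integer(0))
  margin <- max_dist + 40L  # room upstream for a planted box
  tries <- 0L
  while (nrow(genes) < config$n_genes) {
    tries <- tries + 1L
    if (tries > config$n_genes * 200L) stop("cannot place genes; genome too small")
    w <- sample(300:3000, 1L)
    s <- sample.int(glen - w - 2L * margin, 1L) + margin  # 1-based start
    if (any(s - margin <= placed$end & s + w + margin >= placed$start)) next
    strand <- sample(c("+", "-"), 1L)
    id <- sprintf("gene%03d", nrow(genes) + 1L)
    genes <- rbind(genes, data.frame(seq_id = "genome", start = s,
                                     end = s + w - 1L, strand = strand,
                                     feature_id = id, stringsAsFactors = FALSE))
    placed <- rbind(placed, data.frame(start = s, end = s + w - 1L))
  }
  sites <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene = character(0), distance = integer(0))
  if (config$n_motifs > 0) {
    if (is.null(profile)) stop("profile required to plant motifs")
    if (config$n_motifs > nrow(genes)) stop("more motifs than genes")
    L <- profile$length
    probs <- 2^profile$bits * profile$background  # back to column probabilities
    probs <- sweep(probs, 2, colSums(probs), "/")
    pick <- sample(seq_len(nrow(genes)), config$n_motifs)
    for (gi in pick) {
      inst <- paste(vapply(seq_len(L), function(j)
        sample(BASES, 1L, prob = probs[, j]), character(1)), collapse = "")
      d <- sample(0:max_dist, 1L)
      g <- genes[gi, ]
      if (g$strand == "+") {
        box_end <- g$start - d        # 1-based box end: distance = start-end
        box_start <- box_end - L + 1L
        piece <- inst
      } else {
        box_start <- g$end + d        # 1-based box start on forward strand
        box_end <- box_start + L - 1L
        piece <- revcomp(inst)
      }
      substr(genome, box_start, box_end) <- piece
      sites <- rbind(sites, data.frame(
        seq_id = "genome", start = box_start - 1L, end = box_end,
        strand = g$strand, gene = g$feature_id, distance = d,
        stringsAsFactors = FALSE))
    }
  }
  list(genome = genome, genes = genes, motif_sites = sites)
}

#' Generate aligned training instances of a promoter box
#'
#' Emulates a confirmed-box training set: `n` ungapped instances of a
#' consensus box with independent per-position substitutions. The default
#' rate of 0.08 (about two substitutions per 27-mer) reproduces the
#' sharpness of real sigma-factor boxes, whose conserved cores leave
#' genome-wide chance-hit densities near one hit per hundred kb of scanned
#' windows at a 3-bit floor.
#'
#' @param consensus consensus box sequence.
#' @param n number of training instances (default 38).
#' @param rate per-position substitution probability (default 0.08).
#' @param seed RNG seed.
#' @return Character vector of aligned (equal-length, ungapped) instances.
#' @export
sim_motif_training <- function(consensus, n = 38L, rate = 0.08, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  vapply(seq_len(n), function(i) {
    x <- strsplit(toupper(consensus), "")[[1]]
    at <- which(runif(length(x)) < rate)
    x[at] <- sample(BASES, length(at), replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
}

#' Generate the full fixture bundle
#'
#' Orchestrates [simulate_genome()], [diverge()], [fragment()],
#' [scramble_assembly()] and [corrupt_nruns()] into one deterministic
#' bundle with its truth tables.
#'
#' @param config a [sim_config()].
#' @return List: `config`, `genome`, `reference`, `divergence` (event map),
#'   `assembly` (scrambled contigs), `truth` (contigs, adjacencies,
#'   orientation), `scaffolds` and `nruns` (corrupted scaffold + true run
#'   sizes).
#' @export
simulate_fixture <- function(config) {
  genome <- simulate_genome(config)
  div <- diverge(genome, config)
  frag <- fragment(genome, config)
  scr <- scramble_assembly(frag$assembly, config)
  cor <- corrupt_nruns(frag, config)
  # truth consistency: contig spans, gaps and duplicated junctions tile the
  # covered prefix of the genome
  tc <- frag$truth$contigs
  stopifnot(sum(tc$end - tc$start) + sum(frag$truth$adjacencies$gap) -
              sum(frag$truth$adjacencies$overlap_bp) == max(tc$end),
            max(tc$end) <= nchar(genome))
  list(config = config, genome = genome, reference = div$reference,
       divergence = div[c("events", "inversions")],
       assembly = scr$assembly,
       truth = c(frag$truth, list(orientation = scr$orientation)),
       scaffolds = cor$seqs, nruns = cor$truth)
}

#' Write a fixture bundle to disk
#'
#' Emits genome.fa, reference.fa, contigs.fa, scaffolds_corrupted.fa,
#' genes.gff (if present), truth.json and manifest.json.
#'
#' @param fix a [simulate_fixture()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(genome = fix$genome), file.path(dir, "genome.fa"))
  write_fasta(c(reference = fix$reference), file.path(dir, "reference.fa"))
  write_fasta(fix$assembly, file.path(dir, "contigs.fa"))
  write_fasta(fix$scaffolds, file.path(dir, "scaffolds_corrupted.fa"))
  if (!is.null(fix$genes)) write_gff(fix$genes, file.path(dir, "genes.gff"))
  jsonlite::write_json(
    list(contigs = fix$truth$contigs, adjacencies = fix$truth$adjacencies,
         orientation = as.list(fix$truth$orientation), nruns = fix$nruns),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(fix$config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
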