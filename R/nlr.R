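# Six-frame translation windows of one chromosome. Returns a tibble of
# amino-acid windows with enough bookkeeping to map protein-level hits back
# to genomic coordinates.
six_frame_windows <- function(seq, win_aa, step_aa) {
  n <- nchar(seq)
  frames <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      sub <- substr(s, f + 1L, n)
      sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
      if (nchar(sub) < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X", no.init.codon = TRUE))
      frames[[paste0(strand, f)]] <- list(strand = strand, frame = f, aa = aa)
    }
  }
  rows <- list()
  for (fr in frames) {
    la <- nchar(fr$aa)
    starts <- seq(1L, max(1L, la - win_aa + 1L), by = step_aa)
    if (length(starts) > 1L && starts[length(starts)] + win_aa - 1L < la) {
      starts <- c(starts, la - win_aa + 1L)
    }
    rows[[length(rows) + 1L]] <- tibble(
      strand = fr$strand, frame = fr$frame, aa_start = starts,
      window = substring(fr$aa, starts, pmin(starts + win_aa - 1L, la))
    )
  }
  bind_rows(rows)
}

# genomic coordinates (1-based inclusive) of aa positions [a1, a2] in a frame
aa_to_genomic <- function(strand, frame, a1, a2, chrom_len) {
  if (strand == "+") {
    start <- frame + 3L * (a1 - 1L) + 1L
    end <- frame + 3L * a2
  } else {
    end <- chrom_len - frame - 3L * (a1 - 1L)
    start <- chrom_len - frame - 3L * a2 + 1L
  }
  c(start, end)
}

#' Scan a genome for NB-ARC-like loci with protein seeds
#'
#' Translates the genome in six frames and scans each frame against each
#' protein seed by local alignment (BLOSUM62, gap open 11, gap extension 1),
#' via overlapping amino-acid windows. Hits with score at least `min_score`
#' and aligned length at least `min_len_aa` are mapped back to genomic
#' coordinates; hits overlapping on the genome merge into loci (union span,
#' maximum score).
#'
#' @param genome FASTA path or named character vector.
#' @param seeds Named character vector of seed protein sequences (or
#'   AAStringSet).
#' @param min_score Minimum local alignment score; calibrate with
#'   [calibrate_nbarc_min_score()].
#' @param min_len_aa Minimum aligned length in amino acids (default 80).
#' @param win_aa Scanning window length in aa; default twice the longest
#'   seed.
#' @return An `nlr_loci` tibble: `id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `score`.
#' @export
scan_nbarc_loci <- function(genome, seeds, min_score, min_len_aa = 80,
                            win_aa = NULL) {
  genome <- as_genome(genome)
  if (methods::is(seeds, "AAStringSet")) seeds <- as.character(seeds)
  if (!length(seeds)) {
    stop_napusweep("empty seed set", "configuration_error")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  max_seed <- max(nchar(seeds))
  win_aa <- win_aa %||% (2L * max_seed)
  step_aa <- win_aa - max_seed

  hits <- list()
  for (ch in names(genome)) {
    chrom_len <- nchar(genome[[ch]])
    wins <- six_frame_windows(genome[[ch]], win_aa, step_aa)
    pat <- Biostrings::AAStringSet(gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X",
                                        wins$window))
    for (sd in names(seeds)) {
      scores <- Biostrings::pairwiseAlignment(
        pat, Biostrings::AAString(seeds[[sd]]), type = "local",
        substitutionMatrix = blosum, gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE)
      keep <- which(scores >= min_score)
      for (i in keep) {
        aln <- Biostrings::pairwiseAlignment(
          pat[i], Biostrings::AAString(seeds[[sd]]), type = "local",
          substitutionMatrix = blosum, gapOpening = 11, gapExtension = 1)
        len_aa <- Biostrings::width(Biostrings::pattern(aln))
        if (len_aa < min_len_aa) next
        a1 <- wins$aa_start[i] + Biostrings::start(Biostrings::pattern(aln)) - 1L
        a2 <- wins$aa_start[i] + Biostrings::end(Biostrings::pattern(aln)) - 1L
        gc <- aa_to_genomic(wins$strand[i], wins$frame[i], a1, a2, chrom_len)
        hits[[length(hits) + 1L]] <- tibble(
          chrom = ch, start = gc[1], end = gc[2], strand = wins$strand[i],
          score = scores[i], seed = sd)
      }
    }
  }
  empty <- tibble(id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), score = numeric())
  class(empty) <- c("nlr_loci", class(empty))
  if (!length(hits)) return(empty)
  hits <- bind_rows(hits)
  # merge hits overlapping on genomic coordinates
  gr <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(hits$start, hits$end))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  hits$locus <- S4Vectors::subjectHits(ov)
  loci <- hits %>%
    group_by(.data$locus) %>%
    summarise(chrom = .data$chrom[1],
              start = min(.data$start), end = max(.data$end),
              strand = .data$strand[which.max(.data$score)],
              score = max(.data$score), .groups = "drop") %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(id = sprintf("nbarc%04d", row_number())) %>%
    select("id", "chrom", "start", "end", "strand", "score")
  class(loci) <- c("nlr_loci", class(loci))
  loci
}

#' Calibrate the NB-ARC scan score threshold on a shuffled-genome null
#'
#' Dinucleotide-shuffles the genome (preserving approximate dimer
#' composition), scores every scanning window against every seed, and
#' returns the 99.9th percentile of the pooled null scores times a safety
#' margin. Local-alignment null maxima fluctuate by a few points between
#' shuffles, so the margin (default 1.25) keeps fresh nulls below the
#' threshold while genuine domain hits score an order of magnitude higher.
#'
#' @inheritParams scan_nbarc_loci
#' @param n_shuffles Number of shuffled replicates pooled (default 3).
#' @param quantile Null quantile (default 0.999).
#' @param margin Multiplicative safety margin on the null quantile.
#' @param seed RNG seed for the shuffle.
#' @return Numeric score threshold.
#' @export
calibrate_nbarc_min_score <- function(genome, seeds, n_shuffles = 3,
                                      quantile = 0.999, margin = 1.25,
                                      win_aa = NULL, seed = 1L) {
  genome <- as_genome(genome)
  if (methods::is(seeds, "AAStringSet")) seeds <- as.character(seeds)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  max_seed <- max(nchar(seeds))
  win_aa <- win_aa %||% (2L * max_seed)
  step_aa <- win_aa - max_seed
  withr::with_seed(seed, {
    scores <- c()
    for (r in seq_len(n_shuffles)) {
      for (ch in names(genome)) {
        shuf <- dinucleotide_shuffle(genome[[ch]])
        wins <- six_frame_windows(shuf, win_aa, step_aa)
        pat <- Biostrings::AAStringSet(gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X",
                                            wins$window))
        for (sd in names(seeds)) {
          scores <- c(scores, Biostrings::pairwiseAlignment(
            pat, Biostrings::AAString(seeds[[sd]]), type = "local",
            substitutionMatrix = blosum, gapOpening = 11, gapExtension = 1,
            scoreOnly = TRUE))
        }
      }
    }
    floor(stats::quantile(scores, quantile, names = FALSE) * margin) + 1
  })
}

#' Dinucleotide shuffle of a sequence
#'
#' Resamples the sequence as a random permutation of its non-overlapping
#' dinucleotides, preserving approximate dimer composition.
#'
#' @param seq Sequence string.
#' @return Shuffled sequence of the same length.
#' @export
dinucleotide_shuffle <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n - 1L, by = 2L)
  dimers <- substring(seq, starts, starts + 1L)
  tail <- if (n %% 2L == 1L) substr(seq, n, n) else ""
  paste0(paste(sample(dimers), collapse = ""), tail)
}

#' Reconcile annotation NLR genes with scan loci
#'
#' Pairs an annotation gene with a scan locus when their intervals intersect
#' by at least `min_overlap` bp; genes with support are `both`, unsupported
#' scan loci are `scan_only`, unsupported annotation genes are
#' `annotation_only`, and the union is the sum of the three disjoint
#' categories.
#'
#' @param annotation_nlrs Tibble of annotation NLR genes (`id`, `chrom`,
#'   `start`, `end`, 1-based inclusive).
#' @param scan_loci Tibble of scan loci in the same layout.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Object of class `nlr_reconciliation`: list with `counts`
#'   (both/scan_only/annotation_only/union), `membership` tibble
#'   (id, source, category).
#' @export
reconcile_nlr_sets <- function(annotation_nlrs, scan_loci, min_overlap = 1) {
  ann <- as_tibble(annotation_nlrs)
  scn <- as_tibble(scan_loci)
  if (anyDuplicated(ann$id) || anyDuplicated(scn$id)) {
    stop_napusweep("duplicate ids in input sets", "input_error")
  }
  ov <- if (nrow(ann) && nrow(scn)) {
    GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start, ann$end)),
      GenomicRanges::GRanges(scn$chrom, IRanges::IRanges(scn$start, scn$end)),
      minoverlap = min_overlap)
  } else NULL
  ann_hit <- if (is.null(ov)) logical(nrow(ann)) else
    seq_len(nrow(ann)) %in% S4Vectors::queryHits(ov)
  scn_hit <- if (is.null(ov)) logical(nrow(scn)) else
    seq_len(nrow(scn)) %in% S4Vectors::subjectHits(ov)
  counts <- c(both = sum(ann_hit), scan_only = sum(!scn_hit),
              annotation_only = sum(!ann_hit))
  counts["union"] <- sum(counts)
  membership <- bind_rows(
    tibble(id = as.character(ann$id), source = "annotation",
           category = c("annotation_only", "both")[ann_hit + 1L]),
    tibble(id = as.character(scn$id), source = "seed_scan",
           category = c("scan_only", "both")[scn_hit + 1L])
  )
  structure(list(counts = counts, membership = membership),
            class = "nlr_reconciliation")
}

#' @export
print.nlr_reconciliation <- function(x, ...) {
  cat("<nlr_reconciliation>\n")
  print(x$counts)
  invisible(x)
}

#' @method glance nlr_reconciliation
#' @export
glance.nlr_reconciliation <- function(x, ...) {
  as_tibble(as.list(x$counts))
}

#' Call head-to-head (divergent) gene pairs
#'
#' An adjacent gene pair (A before B on the chromosome) qualifies when A is
#' on the '-' strand and B on '+' (both 5' ends face the shared intergenic
#' interval) and `B.start - A.end <= max_dist`. Candidates are paired
#' greedily by ascending distance so each gene joins at most one pair.
#' Overlapping genes are skipped with a warning.
#'
#' @param genes Tibble with `id`, `chrom`, `start`, `end`, `strand`.
#' @param max_dist Maximum intergenic distance in bp (default 10 000).
#' @return Tibble of pairs: `gene_minus`, `gene_plus`, `distance`.
#' @export
find_head_to_head_pairs <- function(genes, max_dist = 10000) {
  g <- as_tibble(genes) %>% arrange(.data$chrom, .data$start, .data$end)
  # drop genes overlapping their neighbour
  drop <- rep(FALSE, nrow(g))
  if (nrow(g) > 1L) {
    same <- g$chrom[-1] == g$chrom[-nrow(g)]
    ovl <- same & g$start[-1] <= g$end[-nrow(g)]
    if (any(ovl)) {
      drop[which(ovl)] <- TRUE
      drop[which(ovl) + 1L] <- TRUE
      warn(sprintf("skipping %d overlapping genes", sum(drop)))
    }
  }
  g <- g[!drop, , drop = FALSE]
  empty <- tibble(gene_minus = character(), gene_plus = character(),
                  distance = integer())
  if (nrow(g) < 2L) return(empty)
  i <- seq_len(nrow(g) - 1L)
  cand <- tibble(
    a = i, b = i + 1L,
    same_chrom = g$chrom[i] == g$chrom[i + 1L],
    dist = g$start[i + 1L] - g$end[i],
    ok_strand = g$strand[i] == "-" & g$strand[i + 1L] == "+"
  ) %>%
    filter(.data$same_chrom, .data$ok_strand, .data$dist > 0,
           .data$dist <= max_dist) %>%
    arrange(.data$dist, .data$a)
  used <- logical(nrow(g))
  out <- list()
  for (r in seq_len(nrow(cand))) {
    a <- cand$a[r]; b <- cand$b[r]
    if (used[a] || used[b]) next
    used[a] <- TRUE; used[b] <- TRUE
    out[[length(out) + 1L]] <- tibble(gene_minus = g$id[a],
                                      gene_plus = g$id[b],
                                      distance = cand$dist[r])
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Percentage of genes that are paired
#'
#' `100 * 2 * n_pairs / n_genes`, rounded half-up to one decimal (so 52
#' pairs among 597 genes gives 17.4).
#'
#' @param genes Tibble of genes, or a single gene count.
#' @param pairs Tibble of pairs from [find_head_to_head_pairs()], or a single
#'   pair count.
#' @return Percentage (one decimal).
#' @export
paired_fraction <- function(genes, pairs) {
  n_genes <- if (is.data.frame(genes)) nrow(genes) else as.numeric(genes)
  n_pairs <- if (is.data.frame(pairs)) nrow(pairs) else as.numeric(pairs)
  if (is.na(n_genes) || n_genes <= 0) {
    stop_napusweep("paired fraction undefined for an empty gene set",
                   "domain_error")
  }
  round_half_up(100 * 2 * n_pairs / n_genes, 1)
}
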