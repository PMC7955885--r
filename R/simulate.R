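#' Parameters for the population-resequencing simulator
#'
#' Defines the statistical structure the sweep scan assumes: groups share an
#' ancestral allele frequency drawn from a Beta model, group frequencies are
#' binomial resamples of it (creating weak background differentiation), and
#' selected windows get their minor-allele frequency shrunk in the selected
#' group and the other groups' frequency displaced towards the opposite
#' allele.
#'
#' @param n_groups Number of population groups (named "A", "B", ...).
#' @param samples_per_group Diploid samples per group.
#' @param n_windows Number of simulation windows on the single chromosome.
#' @param window_len Window length in bp.
#' @param snp_density Expected SNPs per bp; each window carries
#'   `round(snp_density * window_len)` SNPs.
#' @param beta_shape1,beta_shape2 Beta(alpha, beta) parameters of the shared
#'   ancestral alternate-allele frequency.
#' @param sweep_windows Data frame with columns `window` (1-based index) and
#'   `group` (selected group label), one row per planted sweep window;
#'   `NULL` for a null simulation.
#' @param sweep_diversity_factor Multiplier in `[0, 1)` applied as
#'   `(1 - factor)` shrinkage to the selected group's minor-allele frequency
#'   in sweep windows.
#' @param sweep_divergence_shift Displacement in `[0, 1]` of the non-selected
#'   groups' frequency towards the allele opposite the selected group's major
#'   allele.
#' @param resample_depth Binomial denominator of the group-frequency resample;
#'   smaller values give more background drift (and background FST).
#' @param seed RNG seed; identical parameters including seed give
#'   byte-identical output files.
#' @return A `pop_sim_params` list.
#' @export
pop_sim_params <- function(n_groups = 2, samples_per_group = 20,
                           n_windows = 50, window_len = 10000,
                           snp_density = 0.005,
                           beta_shape1 = 0.8, beta_shape2 = 0.8,
                           sweep_windows = NULL,
                           sweep_diversity_factor = 0.9,
                           sweep_divergence_shift = 0.6,
                           resample_depth = 200,
                           seed = 1L) {
  p <- list(
    n_groups = check_count(n_groups, "n_groups", 1L),
    samples_per_group = check_count(samples_per_group, "samples_per_group", 2L),
    n_windows = check_count(n_windows, "n_windows", 1L),
    window_len = check_count(window_len, "window_len", 10L),
    snp_density = check_fraction(snp_density, "snp_density", 0, 1),
    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
    sweep_windows = sweep_windows,
    sweep_diversity_factor = check_fraction(sweep_diversity_factor,
                                            "sweep_diversity_factor",
                                            0, 1, closed_hi = FALSE),
    sweep_divergence_shift = check_fraction(sweep_divergence_shift,
                                            "sweep_divergence_shift", 0, 1),
    resample_depth = check_count(resample_depth, "resample_depth", 2L),
    seed = check_count(seed, "seed", 0L)
  )
  if (!is.null(p$sweep_windows)) {
    sw <- as_tibble(p$sweep_windows)
    stopifnot(all(c("window", "group") %in% names(sw)))
    if (any(sw$window < 1 | sw$window > p$n_windows)) {
      stop_napusweep("sweep window index outside 1..n_windows", "parameter_error")
    }
    groups <- LETTERS[seq_len(p$n_groups)]
    if (!all(sw$group %in% groups)) {
      stop_napusweep("sweep group label not among simulated groups", "parameter_error")
    }
    p$sweep_windows <- sw
  }
  structure(p, class = "pop_sim_params")
}

#' Simulate resequencing genotypes with planted selective sweeps
#'
#' Generates a biallelic SNP VCF (diploid, GT-only), a sample-to-group map and
#' a truth BED of planted sweep windows. In sweep windows the selected group's
#' expected heterozygosity is reduced by `sweep_diversity_factor` and the
#' between-group frequency difference increased by `sweep_divergence_shift`;
#' elsewhere groups share Beta-model frequencies up to binomial resampling.
#'
#' @param params A [pop_sim_params()] object.
#' @param dir Output directory (created if missing); `NULL` to skip writing
#'   files and return the in-memory matrix only.
#' @return List with the in-memory [genotype matrix][load_genotypes]
#'   (`matrix`), the truth window tibble (`truth`, BED 0-based half-open), the
#'   group map tibble (`groups`) and, when `dir` is given, file paths
#'   `vcf_path`, `group_map_path`, `truth_bed_path`.
#' @export
simulate_populations <- function(params, dir = NULL) {
  stopifnot(inherits(params, "pop_sim_params"))
  withr::with_seed(params$seed, {
    groups <- LETTERS[seq_len(params$n_groups)]
    samples <- unlist(lapply(groups, function(g) {
      sprintf("%s%03d", g, seq_len(params$samples_per_group))
    }))
    group_of <- rep(groups, each = params$samples_per_group)
    n_hap_per_group <- 2L * params$samples_per_group
    snps_per_window <- as.integer(round(params$snp_density * params$window_len))

    win_list <- vector("list", params$n_windows)
    for (w in seq_len(params$n_windows)) {
      offsets <- sort(sample.int(params$window_len, snps_per_window))
      pos <- (w - 1L) * params$window_len + offsets
      p0 <- stats::rbeta(snps_per_window, params$beta_shape1, params$beta_shape2)
      freq <- vapply(groups, function(g) {
        stats::rbinom(snps_per_window, params$resample_depth, p0) /
          params$resample_depth
      }, numeric(snps_per_window))
      freq <- matrix(freq, nrow = snps_per_window,
                     dimnames = list(NULL, groups))

      sel <- NULL
      if (!is.null(params$sweep_windows)) {
        hit <- params$sweep_windows$window == w
        if (any(hit)) sel <- params$sweep_windows$group[which(hit)[1]]
      }
      if (!is.null(sel)) {
        ps <- freq[, sel]
        minor_is_alt <- ps <= 0.5
        shrink <- 1 - params$sweep_diversity_factor
        ps_new <- ifelse(minor_is_alt, ps * shrink, 1 - (1 - ps) * shrink)
        # opposite allele of the selected group's major allele
        target <- ifelse(minor_is_alt, 1, 0)
        for (g in setdiff(groups, sel)) {
          freq[, g] <- freq[, g] +
            params$sweep_divergence_shift * (target - freq[, g])
        }
        freq[, sel] <- ps_new
      }

      # Hardy-Weinberg diploids: two independent haploid draws per sample.
      gt <- matrix("", nrow = snps_per_window, ncol = length(samples))
      for (gi in seq_along(groups)) {
        hap1 <- matrix(stats::rbinom(snps_per_window * params$samples_per_group,
                                     1L, freq[, groups[gi]]),
                       nrow = snps_per_window)
        hap2 <- matrix(stats::rbinom(snps_per_window * params$samples_per_group,
                                     1L, freq[, groups[gi]]),
                       nrow = snps_per_window)
        cols <- (gi - 1L) * params$samples_per_group +
          seq_len(params$samples_per_group)
        gt[, cols] <- paste0(hap1, "/", hap2)
      }

      ref <- sample(DNA_BASES, snps_per_window, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                    character(1))
      win_list[[w]] <- list(
        sites = tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt),
        gt = gt
      )
    }

    sites <- bind_rows(lapply(win_list, `[[`, "sites"))
    gt <- do.call(rbind, lapply(win_list, `[[`, "gt"))
    colnames(gt) <- samples
    group_map <- tibble(sample = samples, group = group_of)

    truth <- if (is.null(params$sweep_windows)) {
      tibble(chrom = character(), start = integer(), end = integer(),
             group = character())
    } else {
      tibble(
        chrom = "chr1",
        start = (params$sweep_windows$window - 1L) * params$window_len,
        end = params$sweep_windows$window * params$window_len,
        group = params$sweep_windows$group
      )
    }

    out <- list(
      matrix = genotype_matrix_from_parts(sites, gt, group_map),
      truth = truth,
      groups = group_map
    )
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$vcf_path <- write_vcf(sites, gt, samples, file.path(dir, "sim.vcf"))
      out$group_map_path <- file.path(dir, "groups.tsv")
      readr::write_tsv(group_map, out$group_map_path, col_names = FALSE,
                       progress = FALSE)
      out$truth_bed_path <- file.path(dir, "sweep_truth.bed")
      if (nrow(truth)) {
        write_bed(truth, out$truth_bed_path)
      } else {
        file.create(out$truth_bed_path)
      }
    }
    out
  })
}

#' Parameters for the intact LTR retrotransposon simulator
#'
#' Each element is 5'LTR + internal + 3'LTR; the two terminal repeats start
#' identical at insertion and each accumulates independent substitutions with
#' per-site probability `rate * age`, so the expected pairwise divergence is
#' about `2 * rate * age`. Elements are placed on one chromosome inside or
#' outside a centromere interval with an age-group-specific probability,
#' emulating the centromeric clustering of recently amplified elements.
#'
#' @param n_elements Number of elements.
#' @param ltr_len Length of each terminal repeat (bp).
#' @param internal_len Length of the internal region (bp).
#' @param ages Insertion ages in years (recycled to `n_elements`).
#' @param rate Substitution rate per site per year (default 1.4e-8).
#' @param centromere_interval Numeric `(start, end)` of the centromere,
#'   0-based half-open.
#' @param centromere_placement_prob Probabilities that an element in age group
#'   <0.2 My, 0.2-1 My, >1 My respectively is placed inside the centromere.
#' @param chrom_len Chromosome length; default four times the centromere end.
#' @param seed RNG seed.
#' @return An `ltr_sim_params` list.
#' @export
ltr_sim_params <- function(n_elements = 300, ltr_len = 2000,
                           internal_len = 3000,
                           ages = c(1e4, 1e5, 1e6),
                           rate = 1.4e-8,
                           centromere_interval = c(4e6, 6e6),
                           centromere_placement_prob = c(0.45, 0.29, 0.26),
                           chrom_len = NULL,
                           seed = 1L) {
  if (any(ages < 0)) stop_napusweep("ages must be >= 0", "parameter_error")
  if (rate <= 0) stop_napusweep("rate must be > 0", "parameter_error")
  if (length(centromere_placement_prob) != 3L ||
      any(centromere_placement_prob < 0 | centromere_placement_prob > 1)) {
    stop_napusweep("centromere_placement_prob must be three probabilities",
                   "parameter_error")
  }
  stopifnot(length(centromere_interval) == 2L,
            centromere_interval[1] < centromere_interval[2])
  structure(list(
    n_elements = check_count(n_elements, "n_elements", 1L),
    ltr_len = check_count(ltr_len, "ltr_len", 10L),
    internal_len = check_count(internal_len, "internal_len", 0L),
    ages = rep_len(as.numeric(ages), n_elements),
    rate = as.numeric(rate),
    centromere_interval = as.numeric(centromere_interval),
    centromere_placement_prob = as.numeric(centromere_placement_prob),
    chrom_len = as.numeric(chrom_len %||% (4 * centromere_interval[2])),
    seed = check_count(seed, "seed", 0L)
  ), class = "ltr_sim_params")
}

#' Simulate intact LTR retrotransposons with known ages
#'
#' @param params An [ltr_sim_params()] object.
#' @param dir Output directory, or `NULL` for in-memory results only.
#' @return List with `elements` (tibble: id, age, age_group, ltr5, ltr3,
#'   chrom, start, end — placements BED 0-based half-open) and, when `dir` is
#'   given, `fasta_path`, `truth_path`, `bed_path`.
#' @export
simulate_ltr_elements <- function(params, dir = NULL) {
  stopifnot(inherits(params, "ltr_sim_params"))
  withr::with_seed(params$seed, {
    n <- params$n_elements
    elem_len <- 2L * params$ltr_len + params$internal_len
    grp <- age_group_of(params$ages)
    prob <- params$centromere_placement_prob[
      match(grp, c("<0.2My", "0.2-1My", ">1My"))]
    inside <- stats::runif(n) < prob

    cstart <- params$centromere_interval[1]
    cend <- params$centromere_interval[2]
    # placement by element midpoint
    mid <- numeric(n)
    mid[inside] <- floor(stats::runif(sum(inside), cstart, cend))
    out_len <- params$chrom_len - (cend - cstart)
    u <- floor(stats::runif(sum(!inside), 0, out_len))
    mid[!inside] <- ifelse(u < cstart, u, u + (cend - cstart))
    start <- pmax(0, pmin(round(mid - elem_len / 2), params$chrom_len - elem_len))
    end <- start + elem_len

    ltr5 <- character(n); ltr3 <- character(n); internal <- character(n)
    for (i in seq_len(n)) {
      anc <- rand_dna(params$ltr_len)
      p_mut <- min(params$rate * params$ages[i], 0.75)
      ltr5[i] <- mutate_bases(anc, p_mut)
      ltr3[i] <- mutate_bases(anc, p_mut)
      internal[i] <- rand_dna(params$internal_len)
    }
    elements <- tibble(
      id = sprintf("LTR%04d", seq_len(n)),
      age = params$ages, age_group = grp,
      ltr5 = ltr5, ltr3 = ltr3,
      chrom = "chr1", start = as.integer(start), end = as.integer(end)
    )
    out <- list(elements = elements)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      seqs <- paste0(ltr5, internal, ltr3)
      names(seqs) <- elements$id
      out$fasta_path <- write_fasta(seqs, file.path(dir, "ltr_elements.fasta"))
      out$truth_path <- file.path(dir, "ltr_truth.tsv")
      readr::write_tsv(elements[, c("id", "age", "age_group")], out$truth_path,
                       progress = FALSE)
      out$bed_path <- write_bed(elements[, c("chrom", "start", "end", "id")],
                                file.path(dir, "ltr_placements.bed"))
    }
    out
  })
}

#' Parameters for the tandem satellite array simulator
#'
#' @param monomer_len Monomer length in bp (>= 2).
#' @param n_copies Number of tandem copies.
#' @param substitution_rate Per-site substitution probability applied to each
#'   copy independently.
#' @param indel_rate Per-site probability of a single-base indel (half
#'   deletions, half insertions).
#' @param flank_len Length of random flanking sequence on each side.
#' @param seed RNG seed.
#' @return A `satellite_sim_params` list.
#' @export
satellite_sim_params <- function(monomer_len = 176, n_copies = 1000,
                                 substitution_rate = 0.02, indel_rate = 0,
                                 flank_len = 20000, seed = 1L) {
  structure(list(
    monomer_len = check_count(monomer_len, "monomer_len", 2L),
    n_copies = check_count(n_copies, "n_copies", 1L),
    substitution_rate = check_fraction(substitution_rate, "substitution_rate",
                                       0, 1, closed_hi = FALSE),
    indel_rate = check_fraction(indel_rate, "indel_rate", 0, 1,
                                closed_hi = FALSE),
    flank_len = check_count(flank_len, "flank_len", 0L),
    seed = check_count(seed, "seed", 0L)
  ), class = "satellite_sim_params")
}

#' Simulate a chromosome carrying one tandem satellite array
#'
#' Chromosome = random flank + `n_copies` mutated monomer copies + random
#' flank. The truth interval spans the array (0-based half-open).
#'
#' @param params A [satellite_sim_params()] object.
#' @param dir Output directory, or `NULL`.
#' @return List with `sequence` (chromosome string), `monomer` (truth
#'   monomer), `truth` (tibble chrom/start/end) and `fasta_path`,
#'   `truth_bed_path`, `monomer_path` when `dir` is given.
#' @export
simulate_tandem_array_genome <- function(params, dir = NULL) {
  stopifnot(inherits(params, "satellite_sim_params"))
  withr::with_seed(params$seed, {
    monomer <- rand_dna(params$monomer_len)
    copies <- character(params$n_copies)
    for (i in seq_len(params$n_copies)) {
      cp <- mutate_bases(monomer, params$substitution_rate)
      if (params$indel_rate > 0) cp <- apply_indels(cp, params$indel_rate)
      copies[i] <- cp
    }
    array_seq <- paste(copies, collapse = "")
    left <- rand_dna(params$flank_len)
    right <- rand_dna(params$flank_len)
    chrom_seq <- paste0(left, array_seq, right)
    truth <- tibble(chrom = "chr1",
                    start = params$flank_len,
                    end = params$flank_len + nchar(array_seq))
    out <- list(sequence = chrom_seq, monomer = monomer, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$fasta_path <- write_fasta(c(chr1 = chrom_seq),
                                    file.path(dir, "satellite_chrom.fasta"))
      out$truth_bed_path <- write_bed(truth, file.path(dir, "array_truth.bed"))
      out$monomer_path <- write_fasta(c(monomer = monomer),
                                      file.path(dir, "monomer.fasta"))
    }
    out
  })
}

# Single-base indels: each site deleted with prob rate/2; a random base
# inserted after each site with prob rate/2.
apply_indels <- function(seq, rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  keep <- stats::runif(length(bases)) >= rate / 2
  ins <- stats::runif(length(bases)) < rate / 2
  pieces <- ifelse(keep, bases, "")
  add <- which(ins)
  if (length(add)) {
    pieces[add] <- paste0(pieces[add],
                          sample(DNA_BASES, length(add), replace = TRUE))
  }
  paste(pieces, collapse = "")
}

#' Parameters for the gene-annotation simulator
#'
#' @param n_genes Total number of genes.
#' @param n_nlr Number of NLR genes (`2 * n_pairs <= n_nlr <= n_genes`).
#' @param n_pairs Number of planted head-to-head NLR pairs.
#' @param pair_intergenic_dist Intergenic distance inside each planted pair
#'   (bp, measured as downstream gene start minus upstream gene end).
#' @param chrom_len Chromosome length in bp.
#' @param gene_len Length of each simulated gene model.
#' @param min_gap Minimum gap between unpaired neighbouring genes; kept above
#'   any plausible pairing distance so only planted pairs qualify.
#' @param seed RNG seed.
#' @return An `annot_sim_params` list.
#' @export
annot_sim_params <- function(n_genes = 100, n_nlr = 30, n_pairs = 5,
                             pair_intergenic_dist = 2000, chrom_len = 4e6,
                             gene_len = 3000, min_gap = 15000, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", 1L)
  n_nlr <- check_count(n_nlr, "n_nlr", 0L)
  n_pairs <- check_count(n_pairs, "n_pairs", 0L)
  if (2L * n_pairs > n_nlr || n_nlr > n_genes) {
    stop_napusweep("need 2*n_pairs <= n_nlr <= n_genes", "parameter_error")
  }
  structure(list(
    n_genes = n_genes, n_nlr = n_nlr, n_pairs = n_pairs,
    pair_intergenic_dist = check_count(pair_intergenic_dist,
                                       "pair_intergenic_dist", 1L),
    chrom_len = check_count(chrom_len, "chrom_len", 1000L),
    gene_len = check_count(gene_len, "gene_len", 100L),
    min_gap = check_count(min_gap, "min_gap", 1L),
    seed = check_count(seed, "seed", 0L)
  ), class = "annot_sim_params")
}

#' Simulate a gene annotation with planted head-to-head NLR pairs
#'
#' Writes a GFF3 with gene/mRNA/CDS features (1-based inclusive), a truth
#' table of planted pairs and an NLR gene-id list. Planted pairs are
#' divergently oriented (upstream gene on '-', downstream on '+') with the
#' requested intergenic distance; all other neighbouring genes are separated
#' by at least `min_gap` so the pair detector's planted truth is exact.
#'
#' @param params An [annot_sim_params()] object.
#' @param dir Output directory, or `NULL`.
#' @return List with `genes` (tibble id/chrom/start/end/strand/is_nlr),
#'   `truth_pairs`, `nlr_ids` and file paths when `dir` is given.
#' @export
simulate_gene_annotation <- function(params, dir = NULL) {
  stopifnot(inherits(params, "annot_sim_params"))
  withr::with_seed(params$seed, {
    n_units <- params$n_genes - params$n_pairs  # a pair occupies one unit
    unit_len <- c(rep(2L * params$gene_len + params$pair_intergenic_dist,
                      params$n_pairs),
                  rep(params$gene_len, n_units - params$n_pairs))
    need <- sum(unit_len) + (n_units + 1L) * params$min_gap
    if (need > params$chrom_len) {
      stop_napusweep(sprintf(
        "cannot place %d genes on a %d bp chromosome without overlap",
        params$n_genes, params$chrom_len), "placement_error")
    }
    # shuffle unit order, then distribute leftover space as extra random gaps
    ord <- sample.int(n_units)
    unit_len <- unit_len[ord]
    is_pair_unit <- ord <= params$n_pairs
    slack <- params$chrom_len - sum(unit_len) - (n_units + 1L) * params$min_gap
    extra <- if (n_units + 1L > 1L && slack > 0) {
      as.vector(stats::rmultinom(1L, size = min(slack, 1e6),
                                 prob = rep(1, n_units + 1L)))
    } else rep(0L, n_units + 1L)
    extra <- round(extra / max(1, sum(extra)) * slack)
    gaps <- params$min_gap + extra

    genes <- list()
    cursor <- 0L
    gi <- 0L
    pair_rows <- list()
    for (u in seq_len(n_units)) {
      cursor <- cursor + gaps[u]
      if (is_pair_unit[u]) {
        gi <- gi + 1L; id_a <- sprintf("gene%04d", gi)
        gi <- gi + 1L; id_b <- sprintf("gene%04d", gi)
        a_start <- cursor + 1L
        a_end <- a_start + params$gene_len - 1L
        b_start <- a_end + params$pair_intergenic_dist
        b_end <- b_start + params$gene_len - 1L
        genes[[length(genes) + 1L]] <- tibble(
          id = c(id_a, id_b), start = c(a_start, b_start),
          end = c(a_end, b_end), strand = c("-", "+"), in_pair = TRUE)
        pair_rows[[length(pair_rows) + 1L]] <-
          tibble(gene_minus = id_a, gene_plus = id_b,
                 distance = b_start - a_end)
        cursor <- b_end
      } else {
        gi <- gi + 1L
        id <- sprintf("gene%04d", gi)
        s <- cursor + 1L
        e <- s + params$gene_len - 1L
        genes[[length(genes) + 1L]] <- tibble(
          id = id, start = s, end = e,
          strand = sample(c("+", "-"), 1L), in_pair = FALSE)
        cursor <- e
      }
    }
    genes <- bind_rows(genes) %>% mutate(chrom = "chr1", .before = 1L)
    truth_pairs <- if (length(pair_rows)) bind_rows(pair_rows) else
      tibble(gene_minus = character(), gene_plus = character(),
             distance = integer())

    # NLR assignment: paired genes are NLRs; remaining NLRs drawn from
    # unpaired genes.
    nlr_ids <- genes$id[genes$in_pair]
    pool <- genes$id[!genes$in_pair]
    n_more <- params$n_nlr - length(nlr_ids)
    if (n_more > 0) nlr_ids <- c(nlr_ids, sample(pool, n_more))
    genes$is_nlr <- genes$id %in% nlr_ids

    out <- list(genes = genes %>% select(-"in_pair"),
                truth_pairs = truth_pairs, nlr_ids = sort(nlr_ids))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      feats <- purrr::pmap_dfr(
        genes[, c("chrom", "id", "start", "end", "strand")],
        function(chrom, id, start, end, strand) {
          tibble(
            chrom = chrom, source = "napusweep",
            type = c("gene", "mRNA", "CDS"),
            start = start, end = end, score = ".", strand = strand,
            phase = c(".", ".", "0"),
            attributes = c(
              sprintf("ID=%s", id),
              sprintf("ID=%s.t1;Parent=%s", id, id),
              sprintf("ID=%s.cds;Parent=%s.t1", id, id)
            )
          )
        })
      out$gff3_path <- write_gff3(feats, file.path(dir, "annotation.gff3"))
      out$pairs_path <- file.path(dir, "pair_truth.tsv")
      readr::write_tsv(truth_pairs, out$pairs_path, progress = FALSE)
      out$nlr_ids_path <- file.path(dir, "nlr_ids.txt")
      writeLines(out$nlr_ids, out$nlr_ids_path)
    }
    out
  })
}

# Age-group partition used throughout: [0, 0.2 My), [0.2 My, 1 My], (1 My, Inf)
age_group_of <- function(age_years) {
  ifelse(age_years < 2e5, "<0.2My",
         ifelse(age_years <= 1e6, "0.2-1My", ">1My"))
}
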