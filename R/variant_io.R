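#' @importFrom generics tidy glance
NULL

# Internal constructor shared by load_genotypes() and the simulator.
# sites: tibble(chrom, pos, ref, alt); gt: character matrix "a/b" sites x
# samples; group_map: tibble(sample, group).
genotype_matrix_from_parts <- function(sites, gt, group_map,
                                       drop_log = tibble(reason = character(),
                                                         n = integer())) {
  samples <- colnames(gt)
  a1 <- suppressWarnings(
    matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt)))
  a2 <- suppressWarnings(
    matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt)))
  calls <- matrix(NA_integer_, nrow = nrow(gt), ncol = 2L * ncol(gt))
  calls[, seq(1L, ncol(calls), by = 2L)] <- a1
  calls[, seq(2L, ncol(calls), by = 2L)] <- a2
  colnames(calls) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  sites$missing <- rowMeans(is.na(calls))
  structure(list(
    sites = as_tibble(sites),
    calls = calls,
    samples = samples,
    groups = as_tibble(group_map),
    drop_log = drop_log
  ), class = "genotype_matrix")
}

#' Load biallelic VCF genotypes into matrix form
#'
#' Reads a VCF, keeps biallelic SNPs with per-site missing fraction at most
#' `max_missing` (the study's filter was a missing rate below 0.25), and
#' returns the sites-by-haplotypes allele matrix the sweep scan consumes.
#' Sites dropped by each filter are counted in the returned `drop_log`.
#'
#' @param vcf_path Path to a VCF file (GT genotypes).
#' @param group_map Sample-to-group map: TSV path or data frame with columns
#'   `sample`, `group`. Every VCF sample must appear in it.
#' @param max_missing Maximum tolerated per-site fraction of missing haploid
#'   calls (default 0.25).
#' @return An object of class `genotype_matrix`: list with `sites` (tibble
#'   chrom/pos/ref/alt/missing), `calls` (integer matrix, sites x haplotypes,
#'   0 = ref, 1 = alt, `NA` missing), `samples`, `groups`, `drop_log`.
#' @export
load_genotypes <- function(vcf_path, group_map, max_missing = 0.25) {
  group_map <- read_group_map(group_map)
  v <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop_napusweep(
      paste0("malformed VCF: ", conditionMessage(e)), "format_error"))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)
  missing_samples <- setdiff(samples, group_map$sample)
  if (length(missing_samples)) {
    stop_napusweep(paste0("samples absent from group map: ",
                          paste(missing_samples, collapse = ", ")),
                   "configuration_error")
  }
  group_map <- group_map[match(samples, group_map$sample), ]

  gt_raw <- gsub("|", "/", gt_raw, fixed = TRUE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) |
    nchar(fix$REF) != 1L | is.na(fix$ALT) | nchar(fix$ALT) != 1L
  gt_norm <- gt_raw
  gt_norm[is.na(gt_norm)] <- "./."
  sites <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT)
  n_alleles_called <- 2L * ncol(gt_norm)
  n_missing <- rowSums(matrix(
    (substr(gt_norm, 1L, 1L) == ".") , nrow = nrow(gt_norm))) +
    rowSums(matrix((substr(gt_norm, 3L, 3L) == ".") , nrow = nrow(gt_norm)))
  frac_missing <- n_missing / n_alleles_called
  too_missing <- !multi & frac_missing > max_missing

  keep <- !multi & !too_missing
  drop_log <- tibble(
    reason = c("multiallelic_or_indel", "missing_fraction"),
    n = c(sum(multi), sum(too_missing))
  )
  if (any(drop_log$n > 0)) {
    message(sprintf("load_genotypes: dropped %d multiallelic/indel and %d high-missing sites (kept %d)",
                    drop_log$n[1], drop_log$n[2], sum(keep)))
  }
  genotype_matrix_from_parts(sites[keep, , drop = FALSE],
                             gt_norm[keep, , drop = FALSE],
                             group_map, drop_log)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples (%d haplotypes), groups: %s\n",
              nrow(x$sites), length(x$samples), ncol(x$calls),
              paste(sort(unique(x$groups$group)), collapse = ", ")))
  invisible(x)
}

#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) x$sites

#' @method glance genotype_matrix
#' @export
glance.genotype_matrix <- function(x, ...) {
  tibble(n_sites = nrow(x$sites), n_samples = length(x$samples),
         n_groups = length(unique(x$groups$group)),
         n_dropped = sum(x$drop_log$n))
}

# haplotype column indices for a group
group_hap_cols <- function(gm, group) {
  smp <- gm$groups$sample[gm$groups$group == group]
  if (!length(smp)) {
    stop_napusweep(sprintf("group '%s' absent from sample groups", group),
                   "configuration_error")
  }
  idx <- match(smp, gm$samples)
  sort(c(2L * idx - 1L, 2L * idx))
}

#' Classify SNP effects against a gene annotation
#'
#' Emits one record per overlapping gene per SNP (so one SNP can have several
#' annotations) plus one intergenic record for SNPs touching no gene or
#' flank. Category is `exon` when the site lies in an exon/CDS of the gene,
#' `intron` inside the gene otherwise, `upstream`/`downstream` within `flank`
#' bp of the gene 5'/3' end (strand-aware), else `intergenic`. Sites inside a
#' CDS additionally get a codon-level subtype (missense, synonymous,
#' stop_gained, stop_lost) by translating the reference and alternate codon
#' with the standard genetic code.
#'
#' @param x A `genotype_matrix` or a tibble of sites with columns
#'   `chrom`, `pos`, `ref`, `alt` (1-based positions).
#' @param gff3 GFF3 path or tibble from [read_gff3()] with gene/mRNA/CDS
#'   features carrying strand and phase.
#' @param genome Reference sequence: FASTA path or named character vector.
#' @param flank Upstream/downstream window in bp (default 5000).
#' @return Tibble of effect records: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id` (`"."` for intergenic), `category`, `coding_subtype`
#'   (`"none"` outside CDS).
#' @export
classify_snp_effects <- function(x, gff3, genome, flank = 5000) {
  sites <- if (inherits(x, "genotype_matrix")) x$sites else as_tibble(x)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  ann <- read_gff3(gff3)
  genome <- as_genome(genome)
  genes <- ann %>% filter(.data$type == "gene")
  mrna <- ann %>% filter(.data$type == "mRNA")
  cds <- ann %>% filter(.data$type == "CDS")
  # map CDS -> gene through mRNA parents
  cds$gene_id <- mrna$parent[match(cds$parent, mrna$id)]
  cds$gene_id[is.na(cds$gene_id)] <- cds$parent[is.na(cds$gene_id)]
  exon <- ann %>% filter(.data$type %in% c("exon", "CDS"))
  exon$gene_id <- mrna$parent[match(exon$parent, mrna$id)]
  exon$gene_id[is.na(exon$gene_id)] <- exon$parent[is.na(exon$gene_id)]

  snp_gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos, sites$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  exon_gr <- GenomicRanges::GRanges(exon$chrom,
                                    IRanges::IRanges(exon$start, exon$end))

  records <- list()

  # genic records -------------------------------------------------------
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (length(hits)) {
    si <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    ex_hits <- GenomicRanges::findOverlaps(snp_gr, exon_gr)
    ex_key <- paste(S4Vectors::queryHits(ex_hits),
                    exon$gene_id[S4Vectors::subjectHits(ex_hits)])
    in_exon <- paste(si, genes$id[gi]) %in% ex_key
    genic <- tibble(
      chrom = sites$chrom[si], pos = sites$pos[si],
      ref = sites$ref[si], alt = sites$alt[si],
      gene_id = genes$id[gi],
      category = ifelse(in_exon, "exon", "intron"),
      coding_subtype = "none"
    )
    genic$coding_subtype <- coding_subtypes(genic, genes, cds, genome)
    records$genic <- genic
  }

  # flank records (strand-aware; exclude SNPs inside the same gene) -----
  up_start <- ifelse(genes$strand == "+", genes$start - flank, genes$end + 1L)
  up_end <- ifelse(genes$strand == "+", genes$start - 1L, genes$end + flank)
  dn_start <- ifelse(genes$strand == "+", genes$end + 1L, genes$start - flank)
  dn_end <- ifelse(genes$strand == "+", genes$end + flank, genes$start - 1L)
  for (side in c("upstream", "downstream")) {
    s <- if (side == "upstream") up_start else dn_start
    e <- if (side == "upstream") up_end else dn_end
    ok <- s <= e
    fg <- GenomicRanges::GRanges(genes$chrom[ok],
                                 IRanges::IRanges(pmax(1L, s[ok]), pmax(1L, e[ok])))
    fh <- GenomicRanges::findOverlaps(snp_gr, fg)
    if (length(fh)) {
      si <- S4Vectors::queryHits(fh)
      gi <- which(ok)[S4Vectors::subjectHits(fh)]
      records[[side]] <- tibble(
        chrom = sites$chrom[si], pos = sites$pos[si],
        ref = sites$ref[si], alt = sites$alt[si],
        gene_id = genes$id[gi], category = side, coding_subtype = "none"
      )
    }
  }

  out <- bind_rows(records)
  annotated <- if (nrow(out)) {
    paste(out$chrom, out$pos) } else character()
  rest <- !(paste(sites$chrom, sites$pos) %in% annotated)
  if (any(rest)) {
    out <- bind_rows(out, tibble(
      chrom = sites$chrom[rest], pos = sites$pos[rest],
      ref = sites$ref[rest], alt = sites$alt[rest],
      gene_id = ".", category = "intergenic", coding_subtype = "none"
    ))
  }
  out %>% arrange(.data$chrom, .data$pos, .data$gene_id)
}

# Codon-level classification for exonic records. Returns the subtype vector.
coding_subtypes <- function(genic, genes, cds, genome) {
  subtype <- genic$coding_subtype
  exonic <- which(genic$category == "exon")
  if (!length(exonic)) return(subtype)
  code <- Biostrings::GENETIC_CODE
  warned <- character()
  for (i in exonic) {
    gid <- genic$gene_id[i]
    gcds <- cds[cds$gene_id == gid, , drop = FALSE]
    if (!nrow(gcds)) next
    strand <- genes$strand[match(gid, genes$id)]
    pos <- genic$pos[i]
    hit <- gcds$start <= pos & gcds$end >= pos
    if (!any(hit)) next  # exon but not CDS (e.g. UTR exon)
    gcds <- gcds[order(gcds$start), , drop = FALSE]
    phase0 <- if (strand == "+") gcds$phase[1] else gcds$phase[nrow(gcds)]
    phase0 <- ifelse(is.na(phase0), 0L, as.integer(phase0))
    # coding sequence 5'->3'
    segs <- lapply(seq_len(nrow(gcds)), function(j) {
      substr(genome[[gcds$chrom[j]]], gcds$start[j], gcds$end[j])
    })
    if (strand == "+") {
      cds_seq <- paste(unlist(segs), collapse = "")
      offs <- cumsum(c(0L, gcds$end - gcds$start + 1L))
      k <- which(hit)[1]
      cidx <- offs[k] + (pos - gcds$start[k]) + 1L
      alt_b <- genic$alt[i]
    } else {
      cds_seq <- paste(rev(vapply(segs, revcomp, character(1))), collapse = "")
      lens <- gcds$end - gcds$start + 1L
      offs <- cumsum(c(0L, rev(lens)))
      k_rev <- nrow(gcds) - which(hit)[1] + 1L
      k <- which(hit)[1]
      cidx <- offs[k_rev] + (gcds$end[k] - pos) + 1L
      alt_b <- revcomp(genic$alt[i])
    }
    cds_seq <- substr(cds_seq, phase0 + 1L, nchar(cds_seq))
    cidx <- cidx - phase0
    if (cidx < 1L) next
    if (nchar(cds_seq) %% 3L != 0L) {
      if (!gid %in% warned) {
        warn(sprintf("CDS length of gene %s is not a multiple of 3 after phase adjustment; codon effects skipped", gid))
        warned <- c(warned, gid)
      }
      next
    }
    codon_i <- (cidx - 1L) %/% 3L
    within <- (cidx - 1L) %% 3L
    ref_codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_codon <- ref_codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_b
    ref_aa <- code[[ref_codon]]
    alt_aa <- code[[alt_codon]]
    subtype[i] <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*" && ref_aa != "*") "stop_gained"
      else if (ref_aa == "*" && alt_aa != "*") "stop_lost"
      else "missense"
  }
  subtype
}

#' Summarise SNP effect categories
#'
#' Counts effect records per category and expresses each as a percentage of
#' the total number of effects (not of SNPs: one SNP can carry several
#' annotations). Percentages are rounded half-up to two decimals, matching
#' the convention of the source tables.
#'
#' @param records Effect records from [classify_snp_effects()], or a
#'   pre-tabulated tibble with columns `category` and `n` (so published count
#'   tables can be summarised directly).
#' @param total_effects Optional known total number of effects to use as the
#'   percentage denominator; defaults to the number of records (or sum of
#'   counts). Supply it when summarising a published subset of categories
#'   whose overall effect total is known.
#' @return Tibble with `category`, `n`, `pct`; total effects in attribute
#'   `total_effects`.
#' @export
summarize_effects <- function(records, total_effects = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    out <- tibble(category = character(), n = integer(), pct = numeric())
    attr(out, "total_effects") <- 0L
    return(out)
  }
  counts <- if ("n" %in% names(records) && !"pos" %in% names(records)) {
    as_tibble(records[, c("category", "n")])
  } else {
    records %>% count(.data$category, name = "n")
  }
  total <- total_effects %||% sum(counts$n)
  out <- counts %>%
    mutate(pct = round_half_up(100 * .data$n / total, 2)) %>%
    arrange(desc(.data$n))
  attr(out, "total_effects") <- total
  out
}
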