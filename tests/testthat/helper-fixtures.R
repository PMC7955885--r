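# Shared fixtures: all built in code at test time.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

comp_base <- function(b) chartr("ACGT", "TGCA", b)

rc <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# Hand-rolled VCF writer, independent of the package's internal writer, so
# load_genotypes() is exercised against externally produced files.
toy_vcf <- function(path, sites, gt, samples) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  for (i in seq_len(nrow(sites))) {
    lines <- c(lines, paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i],
                              sites$alt[i], ".", "PASS", ".", "GT",
                              gt[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Build a genotype_matrix through the public VCF path.
gm_from_genotypes <- function(sites, gt, samples, groups,
                              max_missing = 0.25) {
  path <- tempfile(fileext = ".vcf")
  toy_vcf(path, sites, gt, samples)
  suppressMessages(load_genotypes(
    path, data.frame(sample = samples, group = groups),
    max_missing = max_missing))
}

# Brute-force nucleotide-diversity oracle: mean pairwise Hamming distance per
# bp over all haplotype pairs (complete data).
pi_window_oracle <- function(hap_matrix, window_len) {
  n <- ncol(hap_matrix)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(hap_matrix[, i] != hap_matrix[, j])
    }
  }
  total / choose(n, 2) / window_len
}

# Toy single-gene annotation (gene/mRNA/CDS spanning start..end) as a
# read_gff3()-layout tibble.
toy_gene_gff <- function(chrom, start, end, strand, id = "g1") {
  ids <- c(id, paste0(id, ".t1"), paste0(id, ".cds"))
  parents <- c(NA, id, paste0(id, ".t1"))
  tibble::tibble(
    chrom = chrom,
    type = c("gene", "mRNA", "CDS"),
    start = start, end = end, strand = strand,
    phase = c(NA, NA, 0L),
    id = ids,
    parent = parents
  )
}

# Recall of planted sweep windows: fraction of truth windows overlapped by a
# called region of the correct selected group.
sweep_window_recall <- function(truth, regions) {
  if (!nrow(truth)) return(NA_real_)
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    r <- regions[regions$selected_group == truth$group[i] &
                   regions$chrom == truth$chrom[i], , drop = FALSE]
    any(r$start < truth$end[i] & r$end > truth$start[i])
  }, logical(1))
  mean(hits)
}
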