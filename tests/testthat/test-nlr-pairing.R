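aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(aa_alphabet, n, TRUE), collapse = "")

protein_to_cds <- function(prot) {
  code <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(prot, "")[[1]],
               function(aa) names(code)[code == aa][1], character(1)),
        collapse = "")
}

test_that("a planted seed coding sequence is recovered on both strands", {
  set.seed(101)
  seed_prot <- random_protein(100)
  cds <- protein_to_cds(seed_prot)
  g <- random_dna(30000)
  genome <- c(chrX = paste0(substr(g, 1, 12000), cds,
                            substr(g, 12001, 30000)))
  ms <- calibrate_nbarc_min_score(genome, c(nbarc = seed_prot), seed = 5)
  loci <- scan_nbarc_loci(genome, c(nbarc = seed_prot), min_score = ms)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 12001L)
  expect_equal(loci$end, 12300L)
  expect_equal(loci$strand, "+")
  # same gene on the reverse strand
  genome_rc <- c(chrX = rc(genome[["chrX"]]))
  loci_rc <- scan_nbarc_loci(genome_rc, c(nbarc = seed_prot), min_score = ms)
  expect_equal(nrow(loci_rc), 1L)
  expect_equal(loci_rc$strand, "-")
  expect_equal(loci_rc$start, nchar(g) + 300 - 12300L + 1L)
  # empty seed set is a configuration error
  expect_error(scan_nbarc_loci(genome, character(), min_score = 50),
               class = "napusweep_configuration_error")
})

test_that("a dinucleotide-shuffled genome yields zero loci at the calibrated threshold", {
  set.seed(102)
  seed_prot <- random_protein(100)
  genome <- c(chrX = random_dna(30000))
  ms <- calibrate_nbarc_min_score(genome, c(nbarc = seed_prot), seed = 6)
  set.seed(103)
  shuffled <- c(chrX = dinucleotide_shuffle(genome[["chrX"]]))
  expect_equal(nrow(scan_nbarc_loci(shuffled, c(nbarc = seed_prot),
                                    min_score = ms)), 0L)
})

test_that("reconciliation categories partition the union", {
  ann <- tibble::tibble(id = c("g1", "g2", "g3"), chrom = "c",
                        start = c(1000L, 5000L, 9000L),
                        end = c(2000L, 6000L, 10000L))
  scn <- tibble::tibble(id = c("l1", "l4"), chrom = "c",
                        start = c(1500L, 20000L), end = c(2500L, 21000L))
  rec <- reconcile_nlr_sets(ann, scn)
  expect_equal(unname(rec$counts[c("both", "scan_only", "annotation_only")]),
               c(1L, 1L, 2L))
  expect_equal(unname(rec$counts["union"]), 4L)
  # categories partition the union regardless of input order
  rec2 <- reconcile_nlr_sets(ann[c(3, 1, 2), ], scn[c(2, 1), ])
  expect_equal(rec2$counts, rec$counts)
  # empty scan list: union equals the annotation count
  rec0 <- reconcile_nlr_sets(ann, scn[0, ])
  expect_equal(unname(rec0$counts["union"]), 3L)
  expect_error(reconcile_nlr_sets(dplyr::bind_rows(ann, ann[1, ]), scn),
               class = "napusweep_input_error")
})

test_that("head-to-head orientation and distance rules are enforced", {
  mk <- function(sa, sb, b_start = 6000L) {
    tibble::tibble(id = c("A", "B"), chrom = "c",
                   start = c(1000L, b_start), end = c(4000L, b_start + 3000L),
                   strand = c(sa, sb))
  }
  p1 <- find_head_to_head_pairs(mk("-", "+"))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$distance, 2000L)
  # tail-to-tail does not qualify
  expect_equal(nrow(find_head_to_head_pairs(mk("+", "-"))), 0L)
  # beyond max_dist does not qualify
  expect_equal(nrow(find_head_to_head_pairs(mk("-", "+", 19000L),
                                            max_dist = 10000)), 0L)
})

test_that("greedy pairing uses each gene at most once", {
  # chain minus, plus, ... with the middle gap smallest
  genes <- tibble::tibble(
    id = c("a", "b", "c", "d"), chrom = "c",
    start = c(1000L, 6000L, 12000L, 15000L),
    end = c(4000L, 9000L, 13000L, 18000L),
    strand = c("-", "+", "-", "+"))
  pairs <- find_head_to_head_pairs(genes)
  expect_equal(nrow(pairs), 2L)
  expect_true(!anyDuplicated(c(pairs$gene_minus, pairs$gene_plus)))
  # deterministic output
  expect_identical(pairs, find_head_to_head_pairs(genes))
})

test_that("planted pairs are recovered with perfect precision and recall", {
  sim <- simulate_gene_annotation(
    annot_sim_params(n_genes = 60, n_nlr = 20, n_pairs = 5,
                     pair_intergenic_dist = 2000, seed = 110))
  found <- find_head_to_head_pairs(sim$genes, max_dist = 10000)
  expect_setequal(paste(found$gene_minus, found$gene_plus),
                  paste(sim$truth_pairs$gene_minus,
                        sim$truth_pairs$gene_plus))
  # zero pairs planted: detector returns empty
  sim0 <- simulate_gene_annotation(
    annot_sim_params(n_genes = 30, n_nlr = 10, n_pairs = 0, seed = 111))
  expect_equal(nrow(find_head_to_head_pairs(sim0$genes)), 0L)
  # planted distance above max_dist: zero recall
  sim_far <- simulate_gene_annotation(
    annot_sim_params(n_genes = 30, n_nlr = 10, n_pairs = 3,
                     pair_intergenic_dist = 15000, seed = 112))
  expect_equal(nrow(find_head_to_head_pairs(sim_far$genes,
                                            max_dist = 10000)), 0L)
})

test_that("paired fractions follow the printed rounding convention", {
  expect_equal(paired_fraction(597, 52), 17.4)
  expect_equal(paired_fraction(100, 0), 0)
  expect_equal(paired_fraction(100, 50), 100)
  expect_error(paired_fraction(0, 0), class = "napusweep_domain_error")
})
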