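test_that("window pi matches the enumerated single-site value", {
  # one SNP, haploid counts 2 ref / 2 alt: 4 of the 6 haplotype pairs differ
  sites <- tibble::tibble(chrom = "chr1", pos = 5000L, ref = "A", alt = "T")
  gt <- matrix(c("0/0", "1/1", "0/1", "0/1"), nrow = 1)
  samples <- c("a1", "a2", "b1", "b2")
  gm <- gm_from_genotypes(sites, gt, samples, c("A", "A", "B", "B"))
  pa <- window_pi(gm, "A", window = 10000, step = 10000,
                  chrom_lens = c(chr1 = 10000))
  expect_equal(pa$pi, (4 / 6) / 10000, tolerance = 1e-12)
  # group B is 2 het diploids: also 2 ref / 2 alt haplotypes
  pb <- window_pi(gm, "B", window = 10000, step = 10000,
                  chrom_lens = c(chr1 = 10000))
  expect_equal(pb$pi, (4 / 6) / 10000, tolerance = 1e-12)
})

test_that("window pi equals the all-pairs Hamming oracle", {
  for (s in 1:5) {
    set.seed(400 + s)
    n_sites <- 30
    n_hap <- 8  # 4 diploids
    hap <- matrix(rbinom(n_sites * n_hap, 1, runif(n_sites)),
                  nrow = n_sites)
    gt <- matrix(paste0(hap[, c(1, 3, 5, 7)], "/", hap[, c(2, 4, 6, 8)]),
                 nrow = n_sites)
    sites <- tibble::tibble(chrom = "chr1",
                            pos = sort(sample(1:20000, n_sites)),
                            ref = "A", alt = "G")
    gm <- gm_from_genotypes(sites, gt, sprintf("s%d", 1:4), rep("A", 4))
    res <- window_pi(gm, "A", window = 20000, step = 20000,
                     chrom_lens = c(chr1 = 20000))
    expect_equal(res$pi, pi_window_oracle(hap, 20000), tolerance = 1e-12)
  }
})

test_that("monomorphic windows have zero diversity", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L), ref = "A",
                          alt = "G")
  gt <- matrix("0/0", nrow = 2, ncol = 4)
  gm <- gm_from_genotypes(sites, gt, sprintf("s%d", 1:4), rep("A", 4))
  res <- window_pi(gm, "A", window = 1000, step = 1000,
                   chrom_lens = c(chr1 = 1000))
  expect_equal(res$pi, 0)
})

test_that("single-site FST matches hand-computed variance components", {
  samples <- sprintf("s%02d", 1:20)
  groups <- rep(c("A", "B"), each = 10)
  sites <- tibble::tibble(chrom = "chr1", pos = 500L, ref = "A", alt = "T")
  # fixed difference: FST = 1
  gt_fix <- matrix(c(rep("1/1", 10), rep("0/0", 10)), nrow = 1)
  gm_fix <- gm_from_genotypes(sites, gt_fix, samples, groups)
  f_fix <- window_fst(gm_fix, "A", "B", window = 1000, step = 1000,
                      chrom_lens = c(chr1 = 1000))
  expect_equal(f_fix$fst, 1, tolerance = 1e-12)
  # both populations 5 hom-ref + 5 hom-alt, no heterozygotes:
  # a = -0.25/9, b = (10/9)*0.25, c = 0 => FST = -1/9
  gt_sym <- matrix(rep(c(rep("0/0", 5), rep("1/1", 5)), 2), nrow = 1)
  gm_sym <- gm_from_genotypes(sites, gt_sym, samples, groups)
  f_sym <- window_fst(gm_sym, "A", "B", window = 1000, step = 1000,
                      chrom_lens = c(chr1 = 1000))
  expect_equal(f_sym$fst, -1 / 9, tolerance = 1e-12)
  # unknown group label errors
  expect_error(window_fst(gm_sym, "A", "Z", window = 1000, step = 1000),
               class = "napusweep_configuration_error")
})

test_that("label permutation centres window FST near zero on null data", {
  sim <- simulate_populations(pop_sim_params(n_windows = 5,
                                             samples_per_group = 10,
                                             seed = 44))
  gm <- sim$matrix
  fsts <- replicate(200, {
    gm2 <- gm
    gm2$groups$group <- sample(gm2$groups$group)
    mean(window_fst(gm2, "A", "B", window = 50000, step = 50000,
                    chrom_lens = c(chr1 = 50000))$fst, na.rm = TRUE)
  })
  expect_lt(abs(mean(fsts)), 0.03)
})

test_that("empirical thresholds keep ties together and respect q", {
  up <- empirical_threshold(1:100, "upper", 0.05)
  expect_equal(up$threshold, 96)
  expect_setequal(up$retained, 96:100)
  lo <- empirical_threshold(1:100, "lower", 0.05)
  expect_setequal(lo$retained, 1:5)
  all_in <- empirical_threshold(1:100, "upper", 1)
  expect_equal(length(all_in$retained), 100L)
  # tie crossing the boundary shrinks the retained set
  vals <- c(1:95, rep(96, 5), rep(97, 3))
  tied <- empirical_threshold(vals, "upper", 0.05)  # k = ceil(5.15) = 6
  expect_equal(tied$threshold, 97)
  expect_equal(length(tied$retained), 3L)
  expect_error(empirical_threshold(rep(1, 30), "upper"),
               class = "napusweep_degenerate_error")
  expect_error(empirical_threshold(1:5, "upper"),
               class = "napusweep_parameter_error")
})

test_that("overlapping significant windows merge into one region", {
  # 60 sliding windows (step 10 kb, width 100 kb); windows 1 and 2 carry the
  # extreme FST and the lowest pi ratio, so they merge into (0, 110000)
  n <- 60
  fst <- c(0.9, 0.85, 0.5, seq(0.01, 0.3, length.out = n - 3))
  ratio <- c(0.01, 0.02, 0.95, 0.2, seq(0.9, 1.1, length.out = n - 4))
  # top-3 FST = windows 1,2,3 but window 3's ratio is mid-range; lowest-3
  # ratios = windows 1,2,4 but window 4's FST is background: only windows
  # 1 and 2 pass the joint filter
  stats <- tibble::tibble(
    chrom = "chr1",
    start = (0:(n - 1)) * 10000L,
    end = (0:(n - 1)) * 10000L + 100000L,
    partial = FALSE,
    pi_num = 1e-4, pi_den = 1e-4,
    pi_ratio = ratio,
    fst = fst,
    n_snps = 50L)
  attr(stats, "numerator") <- "A"
  attr(stats, "denominator") <- "B"
  class(stats) <- c("sweep_windows", class(stats))
  reg <- call_sweeps(stats, q_fst = 0.05, q_pi = 0.05)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 0L)
  expect_equal(reg$end, 110000L)
  expect_equal(reg$selected_group, "A")
  expect_equal(reg$n_windows, 2L)
})

test_that("no region is called when no window passes both filters", {
  n <- 40
  # FST and pi-ratio extremes deliberately on disjoint windows
  v <- seq(0.01, 0.3, length.out = n)
  fst <- numeric(n); fst[10:12] <- v[(n - 2):n]; fst[-(10:12)] <- v[1:(n - 3)]
  r <- seq(0.5, 1.5, length.out = n)
  ratio <- numeric(n)
  ratio[25:27] <- r[1:3]; ratio[35:37] <- r[(n - 2):n]
  ratio[-c(25:27, 35:37)] <- r[4:(n - 3)]
  stats <- tibble::tibble(
    chrom = "chr1", start = (0:(n - 1)) * 1000L,
    end = (0:(n - 1)) * 1000L + 1000L, partial = FALSE,
    pi_num = 1e-4, pi_den = 1e-4,
    pi_ratio = ratio,
    fst = fst,
    n_snps = 10L)
  attr(stats, "numerator") <- "A"
  attr(stats, "denominator") <- "B"
  class(stats) <- c("sweep_windows", class(stats))
  reg <- call_sweeps(stats)
  expect_equal(nrow(reg), 0L)
})

test_that("a planted sweep is recovered as one region with its annotations", {
  p <- pop_sim_params(n_windows = 50,
                      sweep_windows = data.frame(window = 40:45, group = "A"),
                      sweep_diversity_factor = 0.95,
                      sweep_divergence_shift = 0.8, seed = 55)
  sim <- simulate_populations(p)
  st <- sweep_scan(sim$matrix, "A", "B", window = 10000, step = 10000,
                   chrom_lens = c(chr1 = 500000))
  reg <- call_sweeps(st, q_fst = 0.12, q_pi = 0.12)  # 6/50 planted windows
  regA <- reg[reg$selected_group == "A", ]
  expect_equal(nrow(regA), 1L)
  expect_lte(regA$start, 390000)
  expect_gte(regA$end, 450000)

  # annotations: 3 NLR genes inside the planted region, 1 outside
  gff <- dplyr::bind_rows(
    toy_gene_gff("chr1", 395001L, 398000L, "+", "n1"),
    toy_gene_gff("chr1", 405001L, 408000L, "+", "n2"),
    toy_gene_gff("chr1", 415001L, 418000L, "-", "n3"),
    toy_gene_gff("chr1", 100001L, 103000L, "+", "n4"))
  ann <- overlap_annotations(regA, gff, nlr_ids = c("n1", "n2", "n3", "n4"))
  expect_setequal(ann$nlrs[[1]], c("n1", "n2", "n3"))
})

test_that("interval overlap uses the one-base half-open rule", {
  regions <- tibble::tibble(chrom = "chr1", start = 1000L, end = 5000L,
                            selected_group = "A", n_windows = 1L,
                            mean_fst = 0.5, mean_pi_ratio = 0.1)
  # gene 5000..8000 (1-based) starts at 0-based 4999: one-base overlap
  gff_in <- toy_gene_gff("chr1", 5000L, 8000L, "+", "gA")
  expect_equal(overlap_annotations(regions, gff_in)$n_genes, 1L)
  # gene 5001..8000 starts exactly at the half-open boundary: no overlap
  gff_out <- toy_gene_gff("chr1", 5001L, 8000L, "+", "gB")
  expect_equal(overlap_annotations(regions, gff_out)$n_genes, 0L)
  # chromosome mismatch errors with the offender listed
  gff_bad <- toy_gene_gff("chr2", 5000L, 8000L, "+", "gC")
  expect_error(overlap_annotations(regions, gff_bad),
               class = "napusweep_reconciliation_error")
})
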