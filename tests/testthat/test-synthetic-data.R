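test_that("population simulator is deterministic and conserves SNP counts", {
  p <- pop_sim_params(n_windows = 10, snp_density = 0.004, seed = 3)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  s1 <- simulate_populations(p, d1)
  s2 <- simulate_populations(p, d2)
  expect_identical(readBin(s1$vcf_path, "raw", file.size(s1$vcf_path)),
                   readBin(s2$vcf_path, "raw", file.size(s2$vcf_path)))
  # conservation: one rounded density * window_len block per window
  expect_equal(nrow(s1$matrix$sites), 10 * round(0.004 * 10000))
})

test_that("null sweep configuration is byte-identical to no sweep at all", {
  base <- pop_sim_params(n_windows = 10, seed = 5)
  nullsweep <- pop_sim_params(
    n_windows = 10, seed = 5,
    sweep_windows = data.frame(window = 4, group = "A"),
    sweep_diversity_factor = 0, sweep_divergence_shift = 0)
  a <- simulate_populations(base)
  b <- simulate_populations(nullsweep)
  expect_identical(a$matrix$calls, b$matrix$calls)
  expect_identical(a$matrix$sites$pos, b$matrix$sites$pos)
})

test_that("a strongly planted sweep window ranks highest in FST", {
  p <- pop_sim_params(n_windows = 50,
                      sweep_windows = data.frame(window = 17, group = "A"),
                      sweep_diversity_factor = 0.95,
                      sweep_divergence_shift = 0.8, seed = 9)
  sim <- simulate_populations(p)
  st <- sweep_scan(sim$matrix, "A", "B", window = 10000, step = 10000,
                   chrom_lens = c(chr1 = 500000))
  expect_equal(which.max(st$fst), 17L)
})

test_that("sweep parameters are validated", {
  expect_error(pop_sim_params(n_windows = 10,
                              sweep_windows = data.frame(window = 11,
                                                         group = "A")),
               class = "napusweep_parameter_error")
  expect_error(pop_sim_params(sweep_diversity_factor = 1),
               class = "napusweep_parameter_error")
  expect_error(ltr_sim_params(ages = -5),
               class = "napusweep_parameter_error")
  expect_error(annot_sim_params(n_genes = 10, n_nlr = 4, n_pairs = 3),
               class = "napusweep_parameter_error")
})

test_that("LTR generator: age zero gives identical terminal repeats", {
  sim <- simulate_ltr_elements(
    ltr_sim_params(n_elements = 5, ltr_len = 300, internal_len = 50,
                   ages = 0, seed = 2))
  expect_identical(sim$elements$ltr5, sim$elements$ltr3)
})

test_that("LTR divergence matches the closed-form expectation", {
  # expected differing sites = L * (1 - (1 - r*age)^2), binomial 99% interval
  age <- 1e6; rate <- 1.4e-8; L <- 2000; n <- 200
  sim <- simulate_ltr_elements(
    ltr_sim_params(n_elements = n, ltr_len = L, internal_len = 10,
                   ages = age, rate = rate, seed = 4))
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim$elements$ltr5, sim$elements$ltr3)
  p_site <- 1 - (1 - rate * age)^2
  ci <- qbinom(c(0.005, 0.995), size = n * L, prob = p_site)
  expect_gte(sum(diffs), ci[1])
  expect_lte(sum(diffs), ci[2])
})

test_that("LTR placement probabilities are honoured at the extremes", {
  sim <- simulate_ltr_elements(
    ltr_sim_params(n_elements = 60, ltr_len = 50, internal_len = 10,
                   ages = rep(c(1e4, 5e5, 2e6), 20),
                   centromere_interval = c(1e6, 2e6),
                   centromere_placement_prob = c(1, 0, 0), seed = 6))
  mid <- floor((sim$elements$start + sim$elements$end) / 2)
  young <- sim$elements$age_group == "<0.2My"
  expect_true(all(mid[young] >= 1e6 & mid[young] < 2e6))
  expect_true(all(mid[!young] < 1e6 | mid[!young] >= 2e6))
})

test_that("satellite generator: exact periodicity and array length arithmetic", {
  clean <- simulate_tandem_array_genome(
    satellite_sim_params(monomer_len = 20, n_copies = 50,
                         substitution_rate = 0, indel_rate = 0,
                         flank_len = 100, seed = 7))
  arr <- substr(clean$sequence, 101, 100 + 20 * 50)
  expect_identical(arr, paste(rep(clean$monomer, 50), collapse = ""))
  # with substitutions but no indels the array length is exactly n * L
  noisy <- simulate_tandem_array_genome(
    satellite_sim_params(monomer_len = 176, n_copies = 5000,
                         substitution_rate = 0.02, indel_rate = 0,
                         flank_len = 1000, seed = 8))
  expect_equal(noisy$truth$end - noisy$truth$start, 5000 * 176)
  again <- simulate_tandem_array_genome(
    satellite_sim_params(monomer_len = 176, n_copies = 5000,
                         substitution_rate = 0.02, indel_rate = 0,
                         flank_len = 1000, seed = 8))
  expect_identical(noisy$sequence, again$sequence)
})

test_that("annotation generator round-trips through the GFF3 reader", {
  dir <- tempfile()
  sim <- simulate_gene_annotation(
    annot_sim_params(n_genes = 20, n_nlr = 8, n_pairs = 2, seed = 10), dir)
  back <- read_gff3(sim$gff3_path)
  genes <- back[back$type == "gene", ]
  genes <- genes[order(genes$start), ]
  expect_equal(genes$start, sim$genes$start)
  expect_equal(genes$end, sim$genes$end)
  expect_equal(genes$strand, sim$genes$strand)
  expect_equal(genes$id, sim$genes$id)
})

test_that("annotation generator refuses impossible placements", {
  expect_error(
    simulate_gene_annotation(
      annot_sim_params(n_genes = 100, n_nlr = 10, n_pairs = 0,
                       chrom_len = 10000, seed = 1)),
    class = "napusweep_placement_error")
})
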