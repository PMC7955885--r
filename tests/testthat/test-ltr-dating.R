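test_that("divergence of identical and gapped sequences is zero", {
  set.seed(61)
  s <- random_dna(500)
  d0 <- ltr_divergence(s, s)
  expect_equal(d0$p_distance, 0)
  expect_equal(d0$K, 0)
  # 3 inserted bases: gap columns are excluded, p stays 0
  s_ins <- paste0(substr(s, 1, 250), "GGG", substr(s, 251, 500))
  d_ins <- ltr_divergence(s, s_ins)
  expect_equal(d_ins$p_distance, 0)
})

test_that("the Jukes-Cantor correction matches the closed form", {
  set.seed(62)
  s <- random_dna(500)
  pos <- sample(500, 10)
  s2 <- s
  for (i in pos) {
    substr(s2, i, i) <- setdiff(BASES, substr(s, i, i))[1]
  }
  d <- ltr_divergence(s, s2)
  expect_equal(d$p_distance, 0.02, tolerance = 1e-12)
  expect_equal(d$K, -0.75 * log(1 - 4 * 0.02 / 3), tolerance = 1e-12)
  # raw correction returns p itself
  expect_equal(ltr_divergence(s, s2, correction = "raw")$K, 0.02)
  # first-order identity: |K - p| <= p^2 for small p
  expect_lte(abs(d$K - d$p_distance), d$p_distance^2)
})

test_that("saturated divergence raises an error under JC69", {
  # maximally different homopolymers: p = 1
  expect_error(ltr_divergence(strrep("A", 200), strrep("C", 200)),
               class = "napusweep_saturation_error")
})

test_that("insertion ages follow T = K / (2r) with partitioned age groups", {
  expect_equal(insertion_age(0)$T_years, 0)
  expect_equal(insertion_age(0)$age_group, "<0.2My")
  # K = 2.8e-4 at the standard rate dates to exactly ten thousand years
  expect_equal(insertion_age(2.8e-4, 1.4e-8)$T_years, 10000)
  a <- insertion_age(0.020272, 1.4e-8)
  expect_equal(a$T_years, 0.020272 / (2 * 1.4e-8))
  expect_equal(a$age_group, "0.2-1My")
  # boundaries partition: 0.2 My belongs to the middle group, 1 My too
  expect_equal(insertion_age(2 * 1.4e-8 * 2e5)$age_group, "0.2-1My")
  expect_equal(insertion_age(2 * 1.4e-8 * 1e6)$age_group, "0.2-1My")
  expect_equal(insertion_age(2 * 1.4e-8 * 1e6 * 1.001)$age_group, ">1My")
  expect_error(insertion_age(-0.1), class = "napusweep_domain_error")
  # monotonicity in K at fixed rate
  ks <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(insertion_age(ks)$T_years) > 0))
})

test_that("age histograms conserve in-range counts", {
  el <- tibble::tibble(T_years = c(0, 5e3, 4.9e6))
  prof <- age_profile(el)
  expect_equal(sum(prof$count[prof$panel == "young"]), 2L)
  expect_equal(sum(prof$count[prof$panel == "old"]), 3L)
  empty <- age_profile(tibble::tibble(T_years = numeric()))
  expect_true(all(empty$count == 0L))
})

test_that("uniform simulated ages pass a chi-square uniformity check", {
  rejections <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    el <- tibble::tibble(T_years = runif(2000, 0, 5e5))
    young <- age_profile(el)
    counts <- young$count[young$panel == "young"]
    p <- suppressWarnings(chisq.test(counts)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  # 20 independent tests at alpha = 0.01: three or more rejections would be
  # overwhelming evidence of non-uniformity
  expect_lte(rejections, 2L)
})

test_that("centromeric fractions and the Fisher test behave on toy data", {
  el <- tibble::tibble(
    chrom = "chr1",
    start = c(seq(0, 9000, by = 1000), 50000L),
    end = c(seq(0, 9000, by = 1000), 50000L) + 100L,
    age_group = c(rep("<0.2My", 10), ">1My"))
  # centromere covers the first four midpoints
  bed <- tibble::tibble(chrom = "chr1", start = 0L, end = 3200L)
  enr <- centromere_enrichment(el, bed)
  young <- enr$fractions[enr$fractions$age_group == "<0.2My", ]
  expect_equal(young$fraction, 0.4)
  # empty centromere set: all fractions zero
  enr0 <- centromere_enrichment(el, bed[0, ])
  expect_true(all(enr0$fractions$fraction == 0))
})

test_that("planted centromeric placement probabilities are recovered", {
  probs <- c(0.45, 0.29, 0.26)
  sim <- simulate_ltr_elements(
    ltr_sim_params(n_elements = 6000, ltr_len = 30, internal_len = 10,
                   ages = rep(c(1e4, 5e5, 2e6), each = 2000),
                   centromere_interval = c(4e6, 6e6),
                   centromere_placement_prob = probs, seed = 77))
  enr <- centromere_enrichment(
    sim$elements, tibble::tibble(chrom = "chr1", start = 4e6, end = 6e6))
  expect_true(all(abs(enr$fractions$fraction - probs) <= 0.04))
  expect_lt(enr$fisher$p.value, 1e-6)
})

test_that("flank mapping distinguishes present, absent and repetitive sites", {
  set.seed(64)
  g <- random_dna(20000)
  el <- list(left_flank = substr(g, 1000, 2999),
             element_seq = substr(g, 3000, 7999),
             right_flank = substr(g, 8000, 9999))
  # the source genome itself contains the element
  expect_equal(flank_presence_test(el, c(chr1 = g)), "present")
  # element surgically deleted: flanks map adjacently
  deleted <- c(chr1 = paste0(substr(g, 1, 2999), substr(g, 8000, 20000)))
  expect_equal(flank_presence_test(el, deleted), "absent_specific")
  # flank inside a 50x repeated segment is unresolvable
  rep50 <- c(chr1 = paste(rep(substr(g, 1000, 2999), 50), collapse = ""))
  expect_equal(flank_presence_test(el, rep50), "unresolved")
})
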