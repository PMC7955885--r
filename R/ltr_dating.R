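#' Pairwise divergence of a 5'/3' LTR pair
#'
#' Globally aligns the two terminal repeats (match +1, mismatch -2, gap open
#' -4, gap extension -1), computes the p-distance over gap-free aligned
#' columns (columns containing N are excluded), and optionally applies the
#' Jukes-Cantor correction `K = -3/4 * log(1 - 4p/3)`.
#'
#' @param seq5,seq3 The 5' and 3' LTR sequences (A/C/G/T/N).
#' @param correction `"JC69"` (default) or `"raw"` (`K = p`).
#' @return List with `p_distance`, `K`, `aligned_sites` (gap-free, non-N
#'   columns) and `mismatches`.
#' @export
ltr_divergence <- function(seq5, seq3, correction = c("JC69", "raw")) {
  correction <- match.arg(correction)
  if (!nzchar(seq5) || !nzchar(seq3)) {
    stop_napusweep("LTR sequences must be non-empty", "parameter_error")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq5), Biostrings::DNAString(seq3),
    type = "global", substitutionMatrix = mat,
    gapOpening = 3, gapExtension = 1)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  n_cols <- sum(ok)
  if (n_cols == 0L) {
    stop_napusweep("no gap-free aligned columns", "alignment_error")
  }
  mism <- sum(a[ok] != b[ok])
  p <- mism / n_cols
  K <- if (correction == "raw") {
    p
  } else {
    if (p >= 0.75) {
      stop_napusweep(sprintf("p-distance %.3f saturates the JC69 correction", p),
                     "saturation_error")
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  list(p_distance = p, K = K, aligned_sites = n_cols, mismatches = mism)
}

#' LTR-RT insertion age from divergence
#'
#' `T = K / (2 r)` with substitution rate `r` per site per year (default
#' 1.4e-8). Ages are partitioned into the groups
#' `[0, 0.2 My)`, `[0.2 My, 1 My]`, `(1 My, Inf)`.
#'
#' @param K Corrected genetic distance (substitutions per site), `>= 0`.
#' @param rate Substitution rate per site per year, `> 0`.
#' @return List with `T_years` and `age_group`.
#' @export
insertion_age <- function(K, rate = 1.4e-8) {
  if (any(K < 0)) stop_napusweep("K must be >= 0", "domain_error")
  if (rate <= 0) stop_napusweep("rate must be > 0", "parameter_error")
  T_years <- K / (2 * rate)
  list(T_years = T_years, age_group = age_group_of(T_years))
}

#' Date a table of intact LTR elements
#'
#' @param elements Tibble with columns `id`, `ltr5`, `ltr3` and optionally
#'   `chrom`, `start`, `end` (as produced by [simulate_ltr_elements()], or
#'   read from an element table plus genome FASTA).
#' @param rate Substitution rate per site per year.
#' @param correction Distance correction passed to [ltr_divergence()].
#' @return `elements` with added `p_distance`, `K`, `T_years`, `age_group`;
#'   class `ltr_age_table`.
#' @export
date_ltr_elements <- function(elements, rate = 1.4e-8,
                              correction = c("JC69", "raw")) {
  correction <- match.arg(correction)
  div <- purrr::map2(elements$ltr5, elements$ltr3, ltr_divergence,
                     correction = correction)
  out <- elements %>%
    mutate(p_distance = purrr::map_dbl(div, "p_distance"),
           K = purrr::map_dbl(div, "K"))
  age <- insertion_age(out$K, rate)
  out$T_years <- age$T_years
  out$age_group <- age$age_group
  class(out) <- c("ltr_age_table", class(out))
  out
}

#' Insertion-age histograms
#'
#' Two fixed-range histograms of estimated insertion ages: a young panel
#' (default 10 000-year bins over 0-500 000 years) and an old panel (default
#' 100 000-year bins over 0-5 My). Elements outside a panel's range are
#' simply not counted in that panel.
#'
#' @param elements A dated element tibble with column `T_years`.
#' @param bin_width_young,range_young Bin width and range of the young panel.
#' @param bin_width_old,range_old Bin width and range of the old panel.
#' @return Tibble with `panel` ("young"/"old"), `bin_start`, `bin_end`,
#'   `count`.
#' @export
age_profile <- function(elements, bin_width_young = 1e4,
                        range_young = c(0, 5e5),
                        bin_width_old = 1e5, range_old = c(0, 5e6)) {
  one <- function(panel, width, range) {
    breaks <- seq(range[1], range[2], by = width)
    t <- elements$T_years
    t <- t[!is.na(t) & t >= range[1] & t <= range[2]]
    counts <- if (length(t)) {
      tabulate(pmin(floor((t - range[1]) / width) + 1L,
                    length(breaks) - 1L),
               nbins = length(breaks) - 1L)
    } else {
      rep(0L, length(breaks) - 1L)
    }
    tibble(panel = panel, bin_start = breaks[-length(breaks)],
           bin_end = breaks[-1], count = counts)
  }
  bind_rows(one("young", bin_width_young, range_young),
            one("old", bin_width_old, range_old))
}

#' Centromeric enrichment of LTR elements by age group
#'
#' An element is centromeric when its midpoint lies in any centromere
#' interval of its chromosome. Returns per-age-group centromeric fractions
#' and a 2x2 Fisher exact test of young (<0.2 My) versus older elements
#' against inside/outside the centromere.
#'
#' @param elements Tibble with `chrom`, `start`, `end` (BED, 0-based
#'   half-open) and `age_group`.
#' @param centromere_bed Centromere intervals: BED path or tibble (`chrom`,
#'   `start`, `end`).
#' @return Object of class `ltr_enrichment`: list with `fractions` (tibble
#'   age_group/n/n_centromeric/fraction), `fisher` (htest) and the 2x2
#'   `table`.
#' @export
centromere_enrichment <- function(elements, centromere_bed) {
  cen <- if (is.data.frame(centromere_bed)) as_tibble(centromere_bed) else
    read_bed(centromere_bed)
  known <- unique(cen$chrom)
  missing_chr <- setdiff(unique(elements$chrom), known)
  if (length(missing_chr) && nrow(cen)) {
    warn(paste0("element chromosomes absent from centromere BED (counted outside): ",
                paste(missing_chr, collapse = ", ")))
  }
  mid <- interval_mid(elements$start, elements$end)
  inside <- vapply(seq_len(nrow(elements)), function(i) {
    any(cen$chrom == elements$chrom[i] & cen$start <= mid[i] & mid[i] < cen$end)
  }, logical(1))
  fractions <- tibble(age_group = elements$age_group, inside = inside) %>%
    group_by(.data$age_group) %>%
    summarise(n = n(), n_centromeric = sum(.data$inside),
              fraction = mean(.data$inside), .groups = "drop") %>%
    arrange(factor(.data$age_group, levels = c("<0.2My", "0.2-1My", ">1My")))
  young <- elements$age_group == "<0.2My"
  tab <- table(factor(young, levels = c(TRUE, FALSE),
                      labels = c("young", "older")),
               factor(inside, levels = c(TRUE, FALSE),
                      labels = c("centromeric", "arm")))
  fisher <- if (all(dim(tab) == c(2L, 2L)) && sum(tab) > 0) {
    stats::fisher.test(tab)
  } else NULL
  structure(list(fractions = fractions, fisher = fisher, table = tab),
            class = "ltr_enrichment")
}

#' @export
print.ltr_enrichment <- function(x, ...) {
  cat("<ltr_enrichment> centromeric fraction by age group\n")
  print(x$fractions)
  if (!is.null(x$fisher)) {
    cat(sprintf("Fisher exact (young vs older): p = %.3g, OR = %.3g\n",
                x$fisher$p.value, unname(x$fisher$estimate)))
  }
  invisible(x)
}

#' @method tidy ltr_enrichment
#' @export
tidy.ltr_enrichment <- function(x, ...) x$fractions

#' @method glance ltr_enrichment
#' @export
glance.ltr_enrichment <- function(x, ...) {
  tibble(p_value = if (is.null(x$fisher)) NA_real_ else x$fisher$p.value,
         odds_ratio = if (is.null(x$fisher)) NA_real_ else
           unname(x$fisher$estimate),
         n = sum(x$fractions$n))
}

#' Flank-based presence/absence test of an element in another genome
#'
#' Simplified synteny check: locate the element's left and right flanks in a
#' second genome by exact seed matching plus alignment extension. If the
#' flanks map adjacently (gap below 10% of the element length) the site is
#' empty there (`absent_specific`); if they map separated by at least 90% of
#' the element length with element-like sequence between (identity at least
#' `min_identity`) the element is `present`; anything else (including a
#' repetitive flank mapping to more than 3 places) is `unresolved`.
#'
#' @param element One-row data frame or list with character fields
#'   `left_flank`, `element_seq`, `right_flank`.
#' @param other_genome FASTA path or named character vector.
#' @param flank_len Flank length used (both flanks must be at least this
#'   long; they are trimmed to it).
#' @param min_identity Minimum identity for the element-like middle sequence.
#' @param seed_len Exact seed length for flank anchoring.
#' @return One of `"present"`, `"absent_specific"`, `"unresolved"`.
#' @export
flank_presence_test <- function(element, other_genome, flank_len = 1000,
                                min_identity = 0.9, seed_len = 31) {
  genome <- as_genome(other_genome)
  lf <- element$left_flank
  rf <- element$right_flank
  if (nchar(lf) < flank_len || nchar(rf) < flank_len) {
    stop_napusweep("flanks shorter than flank_len", "parameter_error")
  }
  lf <- substr(lf, nchar(lf) - flank_len + 1L, nchar(lf))  # element-proximal
  rf <- substr(rf, 1L, flank_len)
  elem_len <- nchar(element$element_seq)

  # anchor a flank by its element-proximal seed
  locate <- function(flank, proximal_end) {
    seed <- if (proximal_end == "right") {
      substr(flank, nchar(flank) - seed_len + 1L, nchar(flank))
    } else {
      substr(flank, 1L, seed_len)
    }
    hits <- list()
    for (ch in names(genome)) {
      m <- Biostrings::matchPattern(seed, Biostrings::DNAString(genome[[ch]]))
      if (length(m)) {
        hits[[ch]] <- tibble(chrom = ch,
                             start = Biostrings::start(m),
                             end = Biostrings::end(m))
      }
    }
    if (!length(hits)) return(tibble())
    bind_rows(hits)
  }
  lh <- locate(lf, "right")   # left flank anchored at its 3' (proximal) end
  rh <- locate(rf, "left")
  if (nrow(lh) == 0L || nrow(rh) == 0L) return("unresolved")
  if (nrow(lh) > 3L || nrow(rh) > 3L) return("unresolved")

  best <- NULL
  for (i in seq_len(nrow(lh))) {
    for (j in seq_len(nrow(rh))) {
      if (lh$chrom[i] != rh$chrom[j]) next
      gap <- rh$start[j] - lh$end[i] - 1L
      if (gap < 0) next
      if (is.null(best) || gap < best$gap) {
        best <- list(chrom = lh$chrom[i], left_end = lh$end[i],
                     right_start = rh$start[j], gap = gap)
      }
    }
  }
  if (is.null(best)) return("unresolved")
  if (best$gap < 0.1 * elem_len) return("absent_specific")
  if (best$gap >= 0.9 * elem_len) {
    middle <- substr(genome[[best$chrom]], best$left_end + 1L,
                     best$right_start - 1L)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(element$element_seq),
      Biostrings::DNAString(middle),
      type = "local")
    if (Biostrings::pid(aln) / 100 >= min_identity &&
        Biostrings::nchar(aln) >= 0.5 * elem_len) {
      return("present")
    }
  }
  "unresolved"
}
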