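#' @importFrom data.table data.table := .N
NULL

# Sliding-window grid anchored at position 0 of a chromosome: starts at
# multiples of `step`, nominal width `window`, 0-based half-open. Trailing
# windows whose nominal end exceeds the chromosome are flagged partial.
window_grid <- function(chrom_len, window, step) {
  starts <- seq(0L, max(0L, chrom_len - 1L), by = step)
  starts <- starts[starts < chrom_len]
  tibble(start = as.integer(starts),
         end = as.integer(starts + window),
         partial = starts + window > chrom_len)
}

# Map 1-based site positions onto overlapping window indices of the grid.
# Returns data.table(site = site row index, win = window index, 1-based).
assign_windows <- function(pos, chrom_len, window, step) {
  p0 <- pos - 1L
  k_max <- p0 %/% step
  k_min <- pmax(0L, floor((p0 - window) / step) + 1L)
  n_rep <- k_max - k_min + 1L
  data.table(
    site = rep(seq_along(pos), n_rep),
    win = unlist(lapply(seq_along(pos), function(i) seq(k_min[i], k_max[i]))) + 1L
  )
}

# default chromosome lengths: highest position rounded up to the step grid
default_chrom_lens <- function(sites, step) {
  tapply(sites$pos, sites$chrom, function(p) {
    as.integer(ceiling(max(p) / step) * step)
  })
}

# Per-site nucleotide diversity for one group: pi_j = 2*c_ref*c_alt/(n*(n-1))
# over non-missing haploid calls; NA when fewer than 2 calls.
site_pi <- function(gm, group) {
  calls <- gm$calls[, group_hap_cols(gm, group), drop = FALSE]
  c_alt <- rowSums(calls == 1L, na.rm = TRUE)
  c_ref <- rowSums(calls == 0L, na.rm = TRUE)
  n <- c_alt + c_ref
  out <- ifelse(n >= 2L, 2 * c_ref * c_alt / (n * (n - 1)), NA_real_)
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Computes per-bp pi in sliding windows: per-site
#' `pi_j = c_ref * c_alt / choose(n_j, 2)` over non-missing haploid calls,
#' summed over sites in the window and divided by the nominal window length
#' (monomorphic and unobserved bases contribute zero). The study used 100 kb
#' windows sliding by 10 kb.
#'
#' @param gm A `genotype_matrix`.
#' @param group Group label.
#' @param window,step Window size and slide step in bp.
#' @param chrom_lens Named vector of chromosome lengths; inferred from the
#'   highest SNP position when `NULL`.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), `pi`,
#'   `n_snps`, `partial`.
#' @export
window_pi <- function(gm, group, window = 100000, step = 10000,
                      chrom_lens = NULL) {
  chrom_lens <- chrom_lens %||% default_chrom_lens(gm$sites, step)
  pi_site <- site_pi(gm, group)
  window_aggregate(gm$sites, list(pi_sum = pi_site), chrom_lens, window,
                   step) %>%
    mutate(pi = .data$pi_sum / window) %>%
    select("chrom", "start", "end", "pi", "n_snps", "partial")
}

# Weir & Cockerham (1984) two-population per-site variance components from
# diploid genotypes. Returns list(a, b, c) vectors; NA where either group has
# fewer than 2 genotyped individuals.
wc_site_components <- function(gm, groupA, groupB) {
  stats_for <- function(group) {
    cols <- group_hap_cols(gm, group)
    a1 <- gm$calls[, cols[seq(1L, length(cols), 2L)], drop = FALSE]
    a2 <- gm$calls[, cols[seq(2L, length(cols), 2L)], drop = FALSE]
    ok <- !is.na(a1) & !is.na(a2)
    n <- rowSums(ok)
    p <- ifelse(n > 0, rowSums((a1 + a2) * ok, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums((a1 != a2) & ok, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  s1 <- stats_for(groupA)
  s2 <- stats_for(groupB)
  valid <- s1$n >= 2L & s2$n >= 2L
  r <- 2
  nbar <- (s1$n + s2$n) / r
  nc <- (r * nbar - (s1$n^2 + s2$n^2) / (r * nbar)) / (r - 1)
  pbar <- (s1$n * s1$p + s2$n * s2$p) / (r * nbar)
  s2v <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (s1$n * s1$h + s2$n * s2$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - ((r - 1) / r) * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!valid] <- NA_real_; b[!valid] <- NA_real_; cc[!valid] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST between two groups
#'
#' Per-site among-population (a), among-individual (b) and within-individual
#' (c) variance components of the Weir & Cockerham (1984) diploid estimator
#' are summed over sites in each window; window FST is the ratio of sums
#' `sum(a) / sum(a + b + c)` (the "weighted" estimator of the tool the study
#' used). Windows with a zero denominator get `NA` FST and are excluded from
#' downstream quantiles. Negative values are retained, not clamped.
#'
#' @inheritParams window_pi
#' @param groupA,groupB Group labels; each needs at least two genotyped
#'   diploids at a site for the site to contribute.
#' @return Tibble with `chrom`, `start`, `end`, `fst`, `n_snps`, `partial`.
#' @export
window_fst <- function(gm, groupA, groupB, window = 100000, step = 10000,
                       chrom_lens = NULL) {
  chrom_lens <- chrom_lens %||% default_chrom_lens(gm$sites, step)
  comp <- wc_site_components(gm, groupA, groupB)
  window_aggregate(gm$sites,
                   list(a_sum = comp$a, abc_sum = comp$a + comp$b + comp$c),
                   chrom_lens, window, step) %>%
    mutate(fst = ifelse(!is.na(.data$abc_sum) & .data$abc_sum != 0,
                        .data$a_sum / .data$abc_sum, NA_real_)) %>%
    select("chrom", "start", "end", "fst", "n_snps", "partial")
}

# Shared windowing engine: sums the supplied per-site statistics (NA sites
# skipped per statistic) over the sliding-window grid of every chromosome.
window_aggregate <- function(sites, stat_list, chrom_lens, window, step) {
  out <- lapply(unique(sites$chrom), function(ch) {
    idx <- which(sites$chrom == ch)
    clen <- chrom_lens[[ch]]
    grid <- window_grid(clen, window, step)
    map <- assign_windows(sites$pos[idx], clen, window, step)
    map <- map[map$win <= nrow(grid), ]
    res <- grid
    res$n_snps <- 0L
    counts <- map[, .N, by = "win"]
    res$n_snps[counts$win] <- counts$N
    for (nm in names(stat_list)) {
      v <- stat_list[[nm]][idx]
      dt <- data.table(win = map$win, v = v[map$site])
      agg <- dt[!is.na(v), .(s = sum(v)), by = "win"]
      col <- rep(NA_real_, nrow(grid))
      col[agg$win] <- agg$s
      col[res$n_snps > 0 & is.na(col)] <- NA_real_  # all-NA windows stay NA
      col[res$n_snps == 0] <- 0
      res[[nm]] <- col
    }
    res$chrom <- ch
    res
  })
  bind_rows(out) %>% select("chrom", everything())
}

#' Joint pi / FST sweep-scan window table
#'
#' Convenience wrapper computing per-window pi for both groups, the pi ratio
#' (numerator group over denominator group) and Weir-Cockerham FST on one
#' grid.
#'
#' @inheritParams window_fst
#' @return A `sweep_windows` tibble with `pi_num`, `pi_den`, `pi_ratio`,
#'   `fst`, `n_snps`; the group labels are kept in attributes `numerator` and
#'   `denominator`. A zero-denominator ratio with positive numerator is
#'   `Inf`; both-zero windows get `NA` ratio.
#' @export
sweep_scan <- function(gm, groupA, groupB, window = 100000, step = 10000,
                       chrom_lens = NULL) {
  chrom_lens <- chrom_lens %||% default_chrom_lens(gm$sites, step)
  pa <- window_pi(gm, groupA, window, step, chrom_lens)
  pb <- window_pi(gm, groupB, window, step, chrom_lens)
  fs <- window_fst(gm, groupA, groupB, window, step, chrom_lens)
  out <- pa %>%
    rename(pi_num = "pi") %>%
    mutate(pi_den = pb$pi,
           pi_ratio = case_when(
             is.na(.data$pi_num) | is.na(pb$pi) ~ NA_real_,
             pb$pi > 0 ~ .data$pi_num / pb$pi,
             .data$pi_num > 0 ~ Inf,
             TRUE ~ NA_real_
           ),
           fst = fs$fst)
  attr(out, "numerator") <- groupA
  attr(out, "denominator") <- groupB
  class(out) <- c("sweep_windows", class(out))
  out
}

#' Empirical-quantile tail threshold
#'
#' Returns the threshold delimiting the extreme `q` tail of a vector of
#' window statistics: for the upper tail, the smallest value `v` such that
#' `#\{x >= v\} <= ceiling(q * N)`, keeping ties together (so a tie crossing
#' the nominal boundary shrinks the retained set rather than splitting the
#' tie). The study retained the highest 5% of FST and the lowest or highest
#' 5% of the pi ratio.
#'
#' @param values Numeric vector (`NA` dropped; `Inf` allowed and always in
#'   the upper tail). At least 20 non-missing values are required.
#' @param tail `"upper"` or `"lower"`.
#' @param q Tail fraction (default 0.05).
#' @return List with `threshold` and `retained` (indices into `values`).
#' @export
empirical_threshold <- function(values, tail = c("upper", "lower"), q = 0.05) {
  tail <- match.arg(tail)
  q <- check_fraction(q, "q", 0, 1)
  x <- values[!is.na(values)]
  if (length(x) < 20L) {
    stop_napusweep("need at least 20 non-missing values", "parameter_error")
  }
  if (length(unique(x)) == 1L) {
    stop_napusweep("degenerate distribution: all values identical",
                   "degenerate_error")
  }
  k <- ceiling(q * length(x))
  y <- if (tail == "upper") x else -x
  ux <- sort(unique(y), decreasing = TRUE)
  cnt_ge <- cumsum(as.integer(table(factor(y, levels = ux))))
  ok <- which(cnt_ge <= k)
  if (!length(ok)) {
    return(list(threshold = if (tail == "upper") Inf else -Inf,
                retained = integer()))
  }
  thr_y <- ux[max(ok)]
  threshold <- if (tail == "upper") thr_y else -thr_y
  retained <- if (tail == "upper") {
    which(!is.na(values) & values >= threshold)
  } else {
    which(!is.na(values) & values <= threshold)
  }
  list(threshold = threshold, retained = retained)
}

#' Call selective-sweep regions from a window scan
#'
#' A window is significant when its FST is in the upper `q_fst` tail and its
#' pi ratio is in the lower `q_pi` tail (selected group = the ratio's
#' numerator group: diversity lost there) or the upper `q_pi` tail (selected
#' group = denominator). Overlapping or abutting significant windows with the
#' same selected group on one chromosome merge into one region.
#'
#' @param stats A `sweep_windows` tibble from [sweep_scan()].
#' @param q_fst,q_pi Tail fractions (default 0.05 each).
#' @return A `sweep_regions` tibble: `chrom`, `start`, `end` (0-based
#'   half-open), `selected_group`, `n_windows`, `mean_fst`, `mean_pi_ratio`.
#' @export
call_sweeps <- function(stats, q_fst = 0.05, q_pi = 0.05) {
  num <- attr(stats, "numerator") %||% "numerator"
  den <- attr(stats, "denominator") %||% "denominator"
  usable <- !is.na(stats$pi_num) & !is.na(stats$pi_den)
  if (any(!usable)) {
    message(sprintf("call_sweeps: %d windows lacking pi in either group excluded",
                    sum(!usable)))
  }
  w <- stats[usable, , drop = FALSE]
  fst_thr <- empirical_threshold(w$fst, "upper", q_fst)$threshold
  lo <- empirical_threshold(w$pi_ratio, "lower", q_pi)$threshold
  hi <- empirical_threshold(w$pi_ratio, "upper", q_pi)$threshold
  fst_ok <- !is.na(w$fst) & w$fst >= fst_thr
  sel <- rep(NA_character_, nrow(w))
  sel[fst_ok & !is.na(w$pi_ratio) & w$pi_ratio <= lo] <- num
  sel[fst_ok & !is.na(w$pi_ratio) & w$pi_ratio >= hi] <- den
  sig <- w[!is.na(sel), , drop = FALSE]
  sig$selected_group <- sel[!is.na(sel)]
  regions <- merge_windows(sig)
  attr(regions, "fst_threshold") <- fst_thr
  attr(regions, "pi_ratio_thresholds") <- c(lower = lo, upper = hi)
  class(regions) <- c("sweep_regions", class(regions))
  regions
}

# Merge overlapping/abutting significant windows per chromosome and selected
# group.
merge_windows <- function(sig) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  selected_group = character(), n_windows = integer(),
                  mean_fst = numeric(), mean_pi_ratio = numeric())
  if (!nrow(sig)) return(empty)
  sig <- sig %>% arrange(.data$chrom, .data$selected_group, .data$start)
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    tibble(chrom = cur$chrom, start = cur$start, end = cur$end,
           selected_group = cur$group, n_windows = cur$n,
           mean_fst = mean(cur$fst), mean_pi_ratio = mean(cur$ratio))
  }
  for (i in seq_len(nrow(sig))) {
    row <- sig[i, ]
    if (!is.null(cur) && row$chrom == cur$chrom &&
        row$selected_group == cur$group && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$n <- cur$n + 1L
      cur$fst <- c(cur$fst, row$fst)
      cur$ratio <- c(cur$ratio, row$pi_ratio)
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = row$chrom, start = row$start, end = row$end,
                  group = row$selected_group, n = 1L, fst = row$fst,
                  ratio = row$pi_ratio)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  bind_rows(out) %>% arrange(.data$chrom, .data$start)
}

#' Overlap sweep regions with genes, NLR ids and QTL intervals
#'
#' A gene overlaps a region when their intervals intersect by at least one
#' base (regions are 0-based half-open, GFF3 genes 1-based inclusive). NLR
#' and QTL overlaps use the same rule.
#'
#' @param regions A `sweep_regions` tibble.
#' @param gff3 GFF3 path or tibble with gene features.
#' @param nlr_ids Character vector of NLR gene ids (subset of the
#'   annotation), or `NULL`.
#' @param qtl_bed QTL intervals: BED path or tibble (`chrom`, `start`, `end`,
#'   optional `name`), or `NULL`.
#' @return `regions` with list-columns `genes`, `nlrs`, `qtls` and counts
#'   `n_genes`, `n_nlr`, `n_qtl`.
#' @export
overlap_annotations <- function(regions, gff3, nlr_ids = NULL, qtl_bed = NULL) {
  genes <- gff3_genes(gff3)
  offenders <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(offenders) && nrow(regions)) {
    stop_napusweep(paste0("region chromosomes absent from annotation: ",
                          paste(offenders, collapse = ", ")),
                   "reconciliation_error")
  }
  overlap_ids <- function(rchrom, rstart, rend, feat, id_col) {
    hit <- feat$chrom == rchrom & (feat$start - 1L) < rend & feat$end > rstart
    feat[[id_col]][hit]
  }
  g <- purrr::pmap(list(regions$chrom, regions$start, regions$end),
                   overlap_ids, feat = genes, id_col = "id")
  regions$genes <- g
  regions$n_genes <- lengths(g)
  nl <- lapply(g, function(ids) intersect(ids, nlr_ids %||% character()))
  regions$nlrs <- nl
  regions$n_nlr <- lengths(nl)
  if (!is.null(qtl_bed)) {
    qtl <- if (is.data.frame(qtl_bed)) as_tibble(qtl_bed) else
      read_bed(qtl_bed, extra_cols = "name")
    if (!"name" %in% names(qtl)) qtl$name <- paste0("qtl", seq_len(nrow(qtl)))
    # QTL BED is already 0-based half-open; shift to the 1-based convention
    # the shared helper expects.
    qtl1 <- qtl %>% mutate(start = .data$start + 1L)
    ql <- purrr::pmap(list(regions$chrom, regions$start, regions$end),
                      overlap_ids, feat = qtl1, id_col = "name")
  } else {
    ql <- replicate(nrow(regions), character(), simplify = FALSE)
  }
  regions$qtls <- ql
  regions$n_qtl <- lengths(ql)
  regions
}
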