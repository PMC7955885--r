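#' Infer the satellite monomer length of a tandem array
#'
#' For every position whose k-mer recurs downstream within `max_period`, the
#' distance to its nearest recurrence is recorded; the fundamental period is
#' the modal distance, preferring the smallest period among modes within 5%
#' of the maximum count (which suppresses the harmonics a perfect array of
#' period L also produces at 2L, 3L, ...).
#'
#' @param sequence Chromosome or array sequence (character, or FASTA path /
#'   DNAStringSet with a single sequence).
#' @param k k-mer length (default 13).
#' @param max_period Largest period considered (default 2000 bp).
#' @return Inferred monomer length in bp.
#' @export
detect_monomer_length <- function(sequence, k = 13, max_period = 2000) {
  seq <- as_single_sequence(sequence)
  d <- kmer_recurrence_distances(seq, k, max_period)$dist
  d <- d[!is.na(d)]
  if (!length(d)) {
    stop_napusweep("no recurring k-mers within max_period", "no_repeat_error")
  }
  tab <- tabulate(d, nbins = max_period)
  m <- max(tab)
  candidates <- which(tab >= 0.95 * m)
  as.integer(min(candidates))
}

as_single_sequence <- function(sequence) {
  if (is.character(sequence) && length(sequence) == 1L &&
      !file.exists(sequence)) {
    return(sequence)
  }
  g <- as_genome(sequence)
  if (length(g) != 1L) {
    stop_napusweep("expected a single sequence", "parameter_error")
  }
  g[[1]]
}

# Distance from each k-mer start position to the nearest downstream
# recurrence of the same k-mer (NA if none within max_period). data.table
# keyed grouping keeps this linear-ish for megabase inputs.
kmer_recurrence_distances <- function(seq, k, max_period) {
  n <- nchar(seq)
  if (n < k + 1L) {
    stop_napusweep("sequence shorter than k", "parameter_error")
  }
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  dt <- data.table(kmer = kmers, pos = starts)
  data.table::setkey(dt, "kmer", "pos")
  dt[, dist := c(diff(pos), NA_integer_), by = "kmer"]
  dt[!is.na(dist) & dist > max_period, dist := NA_integer_]
  data.table::setkey(dt, "pos")
  dt
}

#' Find tandem satellite arrays on a chromosome
#'
#' Positions whose k-mer recurs at `monomer_len` +/- 10% are periodic;
#' maximal runs of periodic positions with internal gaps at most `max_gap`
#' and span at least `min_copies * monomer_len` become arrays. Each array's
#' periodic identity is the per-base match fraction between the array and
#' itself shifted by one monomer; arrays below `min_identity` are dropped.
#'
#' @param sequence Chromosome sequence (character / FASTA path).
#' @param monomer_len Monomer length (from [detect_monomer_length()] or
#'   known).
#' @param min_copies Minimum copies spanned by an array (default 10).
#' @param min_identity Minimum shifted-match identity (default 0.7).
#' @param max_gap Largest tolerated gap between periodic positions within one
#'   array (default 5000 bp).
#' @param k k-mer length.
#' @param chrom Chromosome name recorded in the output.
#' @return A `tandem_arrays` tibble: `chrom`, `start`, `end` (0-based
#'   half-open), `monomer_len`, `copy_number`, `identity`.
#' @export
find_tandem_arrays <- function(sequence, monomer_len, min_copies = 10,
                               min_identity = 0.7, max_gap = 5000, k = 13,
                               chrom = "chr1") {
  seq <- as_single_sequence(sequence)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  monomer_len = integer(), copy_number = numeric(),
                  identity = numeric())
  class(empty) <- c("tandem_arrays", class(empty))
  if (nchar(seq) < k + monomer_len) return(empty)
  dt <- kmer_recurrence_distances(seq, k, ceiling(1.1 * monomer_len))
  lo <- 0.9 * monomer_len
  hi <- 1.1 * monomer_len
  per <- dt$pos[!is.na(dt$dist) & dt$dist >= lo & dt$dist <= hi]
  if (!length(per)) return(empty)
  per <- sort(per)
  run_id <- cumsum(c(1L, diff(per) > max_gap))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- lapply(split(per, run_id), function(p) {
    start0 <- p[1] - 1L                      # 0-based
    end0 <- p[length(p)] + monomer_len - 1L  # extend by one monomer
    span <- end0 - start0
    if (span < min_copies * monomer_len) return(NULL)
    # shifted-match identity over the periodic-covered portion only, so a
    # non-repetitive spacer joined across max_gap does not dilute it
    cov <- IRanges::reduce(IRanges::IRanges(p, p + monomer_len))
    n_match <- 0L; n_cmp <- 0L
    for (j in seq_along(cov)) {
      i <- IRanges::start(cov)[j]:(IRanges::end(cov)[j] - monomer_len)
      n_match <- n_match + sum(bases[i] == bases[i + monomer_len])
      n_cmp <- n_cmp + length(i)
    }
    identity <- n_match / n_cmp
    if (identity < min_identity) return(NULL)
    tibble(chrom = chrom, start = as.integer(start0), end = as.integer(end0),
           monomer_len = as.integer(monomer_len),
           copy_number = span / monomer_len, identity = identity)
  })
  out <- bind_rows(out)
  if (!nrow(out)) return(empty)
  class(out) <- c("tandem_arrays", class(out))
  out
}

#' Call one centromere per chromosome from its tandem arrays
#'
#' Arrays within `cluster_gap` of each other merge into clusters; the cluster
#' with the greatest total array bp on each chromosome is called as that
#' chromosome's centromere (call interval = cluster span). The mean call
#' length over chromosomes is attached as attribute `mean_length`.
#'
#' @param arrays A `tandem_arrays` tibble (possibly several chromosomes).
#' @param cluster_gap Maximum gap joining arrays into one cluster (default
#'   100 kb).
#' @param chroms Optional chromosome universe; chromosomes without arrays are
#'   reported in attribute `chroms_without_arrays`.
#' @return A `centromere_calls` tibble: `chrom`, `start`, `end`,
#'   `n_arrays`, `array_bp`, `length`.
#' @export
call_centromeres <- function(arrays, cluster_gap = 1e5, chroms = NULL) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_arrays = integer(), array_bp = integer(),
                  length = integer())
  calls <- if (nrow(arrays)) {
    arrays %>%
      arrange(.data$chrom, .data$start) %>%
      group_by(.data$chrom) %>%
      group_modify(function(df, key) {
        cl <- cumsum(c(1L, pmax(df$start[-1] - cummax(df$end[-nrow(df)]), 0) >
                         cluster_gap))
        df %>%
          mutate(cluster = cl) %>%
          group_by(.data$cluster) %>%
          summarise(start = min(.data$start), end = max(.data$end),
                    n_arrays = n(),
                    array_bp = sum(.data$end - .data$start),
                    .groups = "drop") %>%
          slice_max(.data$array_bp, n = 1L, with_ties = FALSE) %>%
          select(-"cluster")
      }) %>%
      ungroup() %>%
      mutate(length = .data$end - .data$start)
  } else empty
  attr(calls, "mean_length") <- if (nrow(calls)) mean(calls$length) else NA_real_
  attr(calls, "chroms_without_arrays") <-
    setdiff(chroms %||% character(), calls$chrom)
  class(calls) <- c("centromere_calls", class(calls))
  calls
}

#' @method glance centromere_calls
#' @export
glance.centromere_calls <- function(x, ...) {
  tibble(n_calls = nrow(x), mean_length = attr(x, "mean_length"),
         n_chroms_without_arrays = length(attr(x, "chroms_without_arrays")))
}
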