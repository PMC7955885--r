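#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Round half away from zero, matching how the source tables print percentages
# (base round() is banker's rounding and would turn 17.45 into 17.4 or 17.5
# depending on binary representation).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#' @noRd
rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Apply independent per-site substitutions to a sequence. Each site mutates
# with probability `rate`; a mutated site becomes one of the three other bases
# uniformly.
mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
  }
  paste(bases, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Midpoint of a 0-based half-open interval.
interval_mid <- function(start, end) floor((start + end) / 2)

stop_napusweep <- function(msg, class) {
  rlang::abort(msg, class = paste0("napusweep_", class))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_napusweep(sprintf("`%s` must be a single integer >= %d", name, min),
                   "parameter_error")
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, closed_hi = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo &&
    (if (closed_hi) x <= hi else x < hi)
  if (!ok) {
    stop_napusweep(sprintf("`%s` must be in [%g, %g%s", name, lo, hi,
                           if (closed_hi) "]" else ")"),
                   "parameter_error")
  }
  as.numeric(x)
}
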