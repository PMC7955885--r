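#' Write sequences as wrapped FASTA
#'
#' Deterministic 60-column FASTA writer used by the synthetic generators, so
#' that identical simulation parameters give byte-identical files.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, n))
    writeLines(c(paste0(">", names(seqs)[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# Coerce a genome argument (FASTA path, named character vector, or
# DNAStringSet) into a named character vector of chromosome sequences.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(read_fasta(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(genome)
  }
  stop_napusweep("`genome` must be a FASTA path or named character vector",
                 "format_error")
}

#' Write a BED file (0-based half-open intervals)
#'
#' @param df Data frame with columns `chrom`, `start`, `end` and optionally
#'   further columns, written in order.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end)) {
    stop_napusweep("BED intervals must have start < end", "format_error")
  }
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file
#' @param path BED file.
#' @param extra_cols Names for columns beyond chrom/start/end.
#' @return Tibble with 0-based half-open intervals.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  nm <- c("chrom", "start", "end", extra_cols)
  names(df) <- c(nm, paste0("V", seq_len(max(0, ncol(df) - length(nm)))))[seq_len(ncol(df))]
  as_tibble(df)
}

#' Read a sample-to-group map
#'
#' Two-column TSV (sample, group), or a data frame with those columns.
#'
#' @param x Path or data frame.
#' @return Tibble with columns `sample`, `group`.
#' @export
read_group_map <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample", "group") %in% names(x)))
    return(as_tibble(x[, c("sample", "group")]))
  }
  df <- utils::read.table(x, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = c("sample", "group"))
  as_tibble(df)
}

# Minimal deterministic VCFv4.2 writer (GT-only FORMAT), diploid unphased.
# sites: tibble(chrom, pos, ref, alt); gt: character matrix sites x samples
# with entries like "0/1" or "./.".
write_vcf <- function(sites, gt, samples, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=napusweep",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(header, con, sep = "\n")
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
                ".", "GT", sep = "\t")
  body <- paste0(body, "\t", apply(gt, 1L, paste, collapse = "\t"))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

# Deterministic GFF3 writer. features: tibble(chrom, source, type, start, end,
# score, strand, phase, attributes) with 1-based inclusive coordinates.
write_gff3 <- function(features, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  body <- paste(features$chrom, features$source, features$type, features$start,
                features$end, features$score, features$strand, features$phase,
                features$attributes, sep = "\t")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read a GFF3 annotation into a tibble
#'
#' Thin wrapper over [rtracklayer::import()] returning the columns the
#' downstream operations use (1-based inclusive coordinates).
#'
#' @param x GFF3 path, or a data frame already in this layout (returned
#'   unchanged).
#' @return Tibble with columns `chrom`, `type`, `start`, `end`, `strand`,
#'   `phase`, `id`, `parent`.
#' @export
read_gff3 <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "type", "start", "end", "strand") %in% names(x)))
    return(as_tibble(x))
  }
  gr <- rtracklayer::import(x, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = if ("phase" %in% names(md)) as.integer(md$phase) else NA_integer_,
    id = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
    parent = parent
  )
}

# Extract gene-level records (id, chrom, start, end, strand) from a GFF3
# tibble or path.
gff3_genes <- function(gff3) {
  g <- read_gff3(gff3)
  g %>%
    filter(.data$type == "gene") %>%
    transmute(id = .data$id, chrom = .data$chrom, start = .data$start,
              end = .data$end, strand = .data$strand)
}
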