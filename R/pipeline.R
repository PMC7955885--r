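#' Declarative pipeline configuration
#'
#' One config drives every stage so runs are archivable: each CLI flag maps
#' to a config key. The config round-trips through YAML unchanged.
#'
#' @param out_dir Output directory of the run.
#' @param seed RNG seed for all simulation stages.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "snp_effects", "sweep_scan", "ltr_age", "centromere",
#'   "nlr", "anchor_summary")`.
#' @param sweep Named list of sweep-scan parameters (`window`, `step`,
#'   `q_fst`, `q_pi`, `groups` = c(numerator, denominator), and the
#'   [pop_sim_params()] fields under `sim`).
#' @param ltr Named list: [ltr_sim_params()] fields under `sim`, plus `rate`,
#'   `correction`.
#' @param satellite Named list: [satellite_sim_params()] fields under `sim`,
#'   plus `k`, `min_copies`.
#' @param annot Named list: [annot_sim_params()] fields under `sim`, plus
#'   `max_pair_dist`, `flank`.
#' @param anchoring Named list with `chrom_lengths` (named) and
#'   `assembly_total`.
#' @param inputs Optional named list of pre-existing input paths (`vcf`,
#'   `group_map`, `gff3`, `genome`); filled in by the simulate stage when it
#'   is enabled.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "snp_effects",
                                       "sweep_scan", "ltr_age", "centromere",
                                       "nlr", "anchor_summary"),
                            sweep = list(), ltr = list(), satellite = list(),
                            annot = list(), anchoring = list(),
                            inputs = list()) {
  all_stages <- c("simulate", "snp_effects", "sweep_scan", "ltr_age",
                  "centromere", "nlr", "anchor_summary")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  structure(list(
    out_dir = out_dir, seed = check_count(seed, "seed", 0L), stages = stages,
    sweep = utils::modifyList(list(window = 10000, step = 10000,
                                   q_fst = 0.05, q_pi = 0.05,
                                   groups = c("A", "B"), sim = list()),
                              sweep),
    ltr = utils::modifyList(list(rate = 1.4e-8, correction = "JC69",
                                 sim = list()), ltr),
    satellite = utils::modifyList(list(k = 13, min_copies = 10, sim = list()),
                                  satellite),
    annot = utils::modifyList(list(max_pair_dist = 10000, flank = 5000,
                                   sim = list()), annot),
    anchoring = anchoring,
    inputs = inputs
  ), class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#' @param path YAML file.
#' @return For `read_pipeline_config()`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  # YAML drops names from named atomic vectors; store lengths as a map
  if (!is.null(x$anchoring$chrom_lengths)) {
    x$anchoring$chrom_lengths <- as.list(x$anchoring$chrom_lengths)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

# TSV with a config-hash comment header, so every output names the run
# configuration it came from.
write_stage_tsv <- function(df, path, hash) {
  con <- file(path, open = "wb")
  writeLines(sprintf("# config_hash: %s", hash), con, sep = "\n")
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Run the full pipeline from a config
#'
#' Executes the enabled stages in dependency order (simulation first, then
#' the analyses that consume its outputs), writes every table under
#' `config$out_dir`, and returns a machine-readable run log of per-stage
#' input/output counts. Re-running with an identical config reproduces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the run log (list); also written as `run_log.yaml`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # hash the scientific configuration only, so identical runs written to
  # different directories stay byte-identical
  hash <- rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config_hash = hash, stages = list())
  stages <- config$stages
  inputs <- config$inputs

  need <- function(what, stage) {
    if (is.null(inputs[[what]])) {
      stop_napusweep(sprintf(
        "stage '%s' needs input '%s'; enable the simulate stage or provide it in config$inputs",
        stage, what), "dependency_error")
    }
    inputs[[what]]
  }

  if ("simulate" %in% stages) {
    sim_dir <- file.path(config$out_dir, "sim")
    pop <- do.call(pop_sim_params,
                   utils::modifyList(list(seed = config$seed),
                                     config$sweep$sim))
    pop_out <- simulate_populations(pop, file.path(sim_dir, "pop"))
    ltrp <- do.call(ltr_sim_params,
                    utils::modifyList(list(seed = config$seed),
                                      config$ltr$sim))
    ltr_out <- simulate_ltr_elements(ltrp, file.path(sim_dir, "ltr"))
    satp <- do.call(satellite_sim_params,
                    utils::modifyList(list(seed = config$seed),
                                      config$satellite$sim))
    sat_out <- simulate_tandem_array_genome(satp, file.path(sim_dir, "satellite"))
    annp <- do.call(annot_sim_params,
                    utils::modifyList(list(seed = config$seed),
                                      config$annot$sim))
    ann_out <- simulate_gene_annotation(annp, file.path(sim_dir, "annot"))
    inputs <- utils::modifyList(inputs, list(
      vcf = pop_out$vcf_path, group_map = pop_out$group_map_path,
      sweep_truth = pop_out$truth_bed_path,
      ltr_elements = ltr_out, satellite = sat_out, annot = ann_out,
      gff3 = ann_out$gff3_path))
    log$stages$simulate <- list(
      n_snps = nrow(pop_out$matrix$sites),
      n_ltr = nrow(ltr_out$elements),
      n_genes = nrow(ann_out$genes))
  }

  gm <- NULL
  if (any(c("snp_effects", "sweep_scan") %in% stages)) {
    gm <- load_genotypes(need("vcf", "sweep_scan"),
                         need("group_map", "sweep_scan"))
  }

  if ("sweep_scan" %in% stages) {
    gs <- config$sweep$groups
    stats <- sweep_scan(gm, gs[1], gs[2], window = config$sweep$window,
                        step = config$sweep$step)
    regions <- call_sweeps(stats, config$sweep$q_fst, config$sweep$q_pi)
    write_stage_tsv(as_tibble(stats), file.path(config$out_dir, "windows.tsv"),
                    hash)
    write_stage_tsv(as_tibble(regions)[, c("chrom", "start", "end",
                                           "selected_group", "n_windows",
                                           "mean_fst", "mean_pi_ratio")],
                    file.path(config$out_dir, "regions.tsv"), hash)
    if (nrow(regions)) {
      write_bed(as_tibble(regions)[, c("chrom", "start", "end",
                                       "selected_group")],
                file.path(config$out_dir, "regions.bed"))
    } else {
      file.create(file.path(config$out_dir, "regions.bed"))
    }
    log$stages$sweep_scan <- list(n_windows = nrow(stats),
                                  n_regions = nrow(regions))
  }

  if ("ltr_age" %in% stages) {
    ltr_in <- need("ltr_elements", "ltr_age")
    dated <- date_ltr_elements(ltr_in$elements, rate = config$ltr$rate,
                               correction = config$ltr$correction)
    write_stage_tsv(dated %>% select(-"ltr5", -"ltr3"),
                    file.path(config$out_dir, "ltr_ages.tsv"), hash)
    write_stage_tsv(age_profile(dated),
                    file.path(config$out_dir, "ltr_age_histogram.tsv"), hash)
    log$stages$ltr_age <- list(n_elements = nrow(dated))
  }

  if ("centromere" %in% stages) {
    sat <- need("satellite", "centromere")
    L <- detect_monomer_length(sat$sequence, k = config$satellite$k)
    arrays <- find_tandem_arrays(sat$sequence, L,
                                 min_copies = config$satellite$min_copies)
    calls <- call_centromeres(arrays)
    write_stage_tsv(as_tibble(arrays), file.path(config$out_dir, "arrays.tsv"),
                    hash)
    write_stage_tsv(as_tibble(calls), file.path(config$out_dir,
                                                "centromeres.tsv"), hash)
    log$stages$centromere <- list(monomer_len = L, n_arrays = nrow(arrays),
                                  n_calls = nrow(calls))
  }

  if ("nlr" %in% stages) {
    ann <- need("annot", "nlr")
    genes <- ann$genes
    pairs <- find_head_to_head_pairs(genes,
                                     max_dist = config$annot$max_pair_dist)
    nlr_genes <- genes %>% filter(.data$is_nlr)
    write_stage_tsv(pairs, file.path(config$out_dir, "nlr_pairs.tsv"), hash)
    log$stages$nlr <- list(n_nlr = nrow(nlr_genes), n_pairs = nrow(pairs),
                           paired_pct = paired_fraction(nlr_genes, pairs))
  }

  if ("snp_effects" %in% stages && !is.null(inputs$gff3) &&
      !is.null(inputs$genome)) {
    rec <- classify_snp_effects(gm, inputs$gff3, inputs$genome,
                                flank = config$annot$flank)
    write_stage_tsv(rec, file.path(config$out_dir, "snp_effects.tsv"), hash)
    write_stage_tsv(summarize_effects(rec),
                    file.path(config$out_dir, "snp_effect_summary.tsv"), hash)
    log$stages$snp_effects <- list(n_records = nrow(rec))
  }

  if ("anchor_summary" %in% stages && length(config$anchoring)) {
    anc <- summarize_anchoring(config$anchoring$chrom_lengths,
                               config$anchoring$assembly_total)
    write_stage_tsv(as_tibble(anc), file.path(config$out_dir, "anchoring.tsv"),
                    hash)
    log$stages$anchor_summary <- as.list(
      anc[anc$subgenome == "total", c("length", "pct")])
  }

  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  invisible(log)
}

#' Pseudochromosome anchoring summary
#'
#' Total and per-subgenome anchored lengths and percentages of the assembly:
#' `anchored% = 100 * sum(chromosome lengths) / assembly_total`, rounded
#' half-up to one decimal. Chromosome names are assigned to the A or C
#' subgenome by their first letter (after an optional `chr` prefix);
#' anything else counts as `scaffold`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp), or
#'   tibble with columns `chrom`, `length`.
#' @param assembly_total Total assembly length (bp).
#' @return An `anchoring_summary` tibble with rows per subgenome and a
#'   `total` row: `subgenome`, `n_chroms`, `length`, `pct`.
#' @export
summarize_anchoring <- function(chrom_lengths, assembly_total) {
  df <- if (is.data.frame(chrom_lengths)) {
    as_tibble(chrom_lengths[, c("chrom", "length")])
  } else {
    # accept a named vector or (e.g. from YAML configs) a named list
    v <- unlist(chrom_lengths)
    if (is.null(names(v))) {
      stop_napusweep("chrom_lengths must be named by chromosome", "input_error")
    }
    tibble(chrom = names(v), length = as.numeric(v))
  }
  if (any(df$length <= 0)) {
    stop_napusweep("chromosome lengths must be positive", "input_error")
  }
  if (sum(df$length) > assembly_total) {
    stop_napusweep("anchored length exceeds assembly total", "input_error")
  }
  sub <- toupper(substr(sub("^chr", "", df$chrom, ignore.case = TRUE), 1L, 1L))
  sub[!sub %in% c("A", "C")] <- "scaffold"
  per <- tibble(subgenome = sub, length = df$length) %>%
    group_by(.data$subgenome) %>%
    summarise(n_chroms = n(), length = sum(.data$length), .groups = "drop")
  out <- bind_rows(per,
                   tibble(subgenome = "total", n_chroms = nrow(df),
                          length = sum(df$length))) %>%
    mutate(pct = round_half_up(100 * .data$length / assembly_total, 1))
  class(out) <- c("anchoring_summary", class(out))
  attr(out, "assembly_total") <- assembly_total
  out
}

#' @method glance anchoring_summary
#' @export
glance.anchoring_summary <- function(x, ...) {
  tot <- x[x$subgenome == "total", ]
  tibble(anchored_bp = tot$length, anchored_pct = tot$pct,
         assembly_total = attr(x, "assembly_total"))
}
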