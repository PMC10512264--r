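#' @title Pipeline orchestration and cohort summaries
#' @name report
#' @description
#' One configuration drives all stages in dependency order (simulate ->
#' ancestry -> karyotype / k-mers / LOH -> summarize). All thresholds are
#' config keys defaulting to the analysis' standard values (0.85 assignment,
#' +/-30% calls, 2x masking, k = 17 / min_count 5, 20% per-parent LOH rule,
#' min_run 10). Every filter decision is recorded per sample so cohort
#' attrition is auditable; reruns with the same seed are byte-identical.
NULL

default_params <- function() {
  list(k = 17L, min_hits = 2L, min_margin = 2L,
       min_assigned = 0.85, minor_floor = 0.05,
       window_size = 10000L, threshold = 0.30, mask_fold = 2.0,
       kmer_min_count = 5L,
       loh = list(min_depth = 3L, purity = 0.9, min_run = 10L,
                  min_parent_frac = 0.20, bin_size = 10000L))
}

known_cross_keys <- c("name", "divergence", "n_samples", "contribution",
                      "aneuploidy_rate", "aneuploidy_weighting", "loh",
                      "mito_donor", "mito_divergence", "n_mito_clades",
                      "species_ids")

#' Validate a pipeline configuration
#'
#' Checks the key-value schema: top level (`cohort`, `params`, `stages`),
#' cohort settings, per-cross keys and parameter names. Unknown keys raise an
#' error naming the key.
#'
#' @param config a configuration list (see [run_pipeline()]).
#' @return the config, with defaults filled in.
#' @export
validate_config <- function(config) {
  chk <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stopf("unknown config key '%s' in %s", bad[1], where)
  }
  chk(config, c("cohort", "params", "stages"), "top level")
  if (is.null(config$cohort)) stopf("config$cohort is required")
  chk(config$cohort, c(names(default_cohort_settings()), "crosses",
                       "mito_divergence"), "cohort")
  if (is.null(config$cohort$crosses) || !length(config$cohort$crosses))
    stopf("config$cohort$crosses must list at least one cross")
  for (cr in config$cohort$crosses) chk(cr, known_cross_keys, "cross")
  params <- utils::modifyList(default_params(), config$params %||% list())
  chk(params, names(default_params()), "params")
  chk(params$loh, names(default_params()$loh), "params$loh")
  stages <- config$stages %||% c("ancestry", "karyotype", "kmers", "loh")
  bad <- setdiff(stages, c("ancestry", "karyotype", "kmers", "loh"))
  if (length(bad)) stopf("unknown stage '%s'", bad[1])
  list(cohort = config$cohort, params = params, stages = stages)
}

#' Read a pipeline configuration from YAML or JSON
#' @param path configuration file (`.yaml`/`.yml` requires the yaml package).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort, then runs the requested stages per sample: ancestry
#' (contribution profile, inclusion filter, mitochondrial majority),
#' karyotype (masked windowed depth, gain/loss calls, variance, slope),
#' k-mer profiling (distance matrix and cross statistics) and LOH (segments,
#' genome percentage, per-region cohort frequency per cross). Deterministic
#' given the seed; when `out_dir` is set, cohort artifacts, per-sample and
#' per-cross summary TSV/JSON are written.
#'
#' @param config configuration list with `cohort` (see [generate_cohort()]),
#'   optional `params` (thresholds; see [validate_config()]) and `stages`.
#' @param out_dir optional output directory.
#' @param seed integer master seed.
#' @return a `cohort_summary`: `samples` and `crosses` data.frames plus
#'   stage artifacts.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1L) {
  cfg <- validate_config(config)
  p <- cfg$params
  cohort <- generate_cohort(cfg$cohort, out_dir = out_dir, seed = seed)

  sample_rows <- list(); profiles <- list(); reports <- list()
  kprofiles <- list(); cross_of <- character(0)
  loh_by_cross <- list(); log_lines <- character(0)
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  for (cr in cohort$crosses) {
    idx <- mito_idx <- markers <- NULL
    if (length(intersect(c("ancestry", "karyotype", "loh"), cfg$stages))) {
      idx <- build_diagnostic_index(cr$parents, k = p$k)
      mito_idx <- build_mito_index(cr$parents, k = p$k)
    }
    if ("loh" %in% cfg$stages)
      markers <- derive_markers(cr$parents[[1]], cr$parents[[2]])
    lengths <- chrom_lengths_table(cr$parents)
    loh_segs <- list(); loh_contribs <- list()

    for (s in cr$samples) {
      sid <- s$truth$sample_id
      row <- list(sample_id = sid, cross = cr$name)
      profile <- NULL; tabs <- NULL
      if (!is.null(idx)) {
        tabs <- classify_reads(s$reads, idx, mito_idx,
                               min_hits = p$min_hits, min_margin = p$min_margin)
        profile <- contribution_profile(sid, tabs$nuclear, tabs$mito)
        filt <- inclusion_filter(profile, p$min_assigned, p$minor_floor)
        note("[%s] inclusion (>=%.0f%% assigned, two-parent): %s (%s)",
             sid, 100 * p$min_assigned, filt$include, filt$reason)
        fr <- profile$nuclear_fraction
        row <- c(row, list(
          contribution_sp1 = unname(fr[1]), contribution_sp2 = unname(fr[2]),
          assigned = profile$assigned, include = filt$include,
          reason = filt$reason, majority_nuclear = profile$majority_nuclear,
          majority_mito = profile$majority_mito,
          concordant = profile$concordant))
        profiles[[sid]] <- profile
      }
      if ("karyotype" %in% cfg$stages && !is.null(tabs)) {
        krep <- karyotype_report(tabs$nuclear, lengths,
                                window_size = p$window_size,
                                fold = p$mask_fold, threshold = p$threshold,
                                sample_id = sid)
        note("[%s] karyotype: %d gain, %d loss (+/-%.0f%% rule, %gx mask)",
             sid, krep$n_gain, krep$n_loss, 100 * p$threshold, p$mask_fold)
        row <- c(row, list(n_gain = krep$n_gain, n_loss = krep$n_loss,
                           variance = krep$variance, slope = krep$slope))
        reports[[sid]] <- krep
      }
      if ("kmers" %in% cfg$stages) {
        kprofiles[[sid]] <- kmer_profile(s$reads, k = p$k,
                                         min_count = p$kmer_min_count,
                                         sample_id = sid)
        cross_of <- c(cross_of, cr$name)
      }
      if ("loh" %in% cfg$stages && !is.null(tabs)) {
        gt <- genotype_markers(tabs$nuclear, markers, reads = s$reads,
                               min_depth = p$loh$min_depth,
                               purity = p$loh$purity)
        segs <- call_loh_segments(gt, min_run = p$loh$min_run)
        pct <- loh_fraction(segs, sum(nchar(cr$parents[[1]]$chromosomes)))
        row <- c(row, list(loh_pct = pct))
        loh_segs[[sid]] <- segs
        if (!is.null(profile)) loh_contribs[[sid]] <- profile$nuclear_fraction
        note("[%s] LOH: %d segment(s), %.2f%% of genome", sid, nrow(segs), pct)
      }
      sample_rows[[sid]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    if ("loh" %in% cfg$stages && length(loh_segs)) {
      freq <- tryCatch(
        region_frequency(loh_segs, nchar(cr$parents[[1]]$chromosomes),
                         contributions = loh_contribs,
                         bin_size = p$loh$bin_size,
                         min_parent_frac = p$loh$min_parent_frac),
        error = function(e) NULL)
      loh_by_cross[[cr$name]] <- list(segments = loh_segs, frequency = freq)
    }
  }

  samples <- do.call(rbind, sample_rows)
  rownames(samples) <- NULL
  kstats <- NULL; kmat <- NULL
  if ("kmers" %in% cfg$stages && length(kprofiles) >= 2) {
    kmat <- distance_matrix(kprofiles)
    pd <- vapply(cohort$crosses, function(cr)
      parental_divergence(cr$parents[[1]], cr$parents[[2]]), numeric(1))
    names(pd) <- names(cohort$crosses)
    kstats <- cross_statistics(kmat, cross_of, pd)
  }
  crosses_tbl <- summarize_cross(samples, kstats)

  out <- structure(list(samples = samples, crosses = crosses_tbl,
                        profiles = profiles, reports = reports,
                        kmer = list(matrix = kmat, stats = kstats),
                        loh = loh_by_cross, log = log_lines,
                        seed = as.integer(seed),
                        config_hash = config_hash(cfg)),
                   class = "cohort_summary")
  if (!is.null(out_dir)) {
    write_tsv(samples, file.path(out_dir, "sample_summary.tsv"))
    write_tsv(crosses_tbl, file.path(out_dir, "cross_summary.tsv"))
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    jsonlite::write_json(list(seed = out$seed, config_hash = out$config_hash,
                              n_samples = nrow(samples)),
                         file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE)
  }
  out
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d sample(s) in %d cross(es); seed %d\n",
              nrow(x$samples), length(unique(x$samples$cross)), x$seed))
  invisible(x)
}

#' Per-cross summary table
#'
#' Percentage of genomes with at least one gain, at least one loss, or both;
#' mean read-depth variance with its standard error (sd/sqrt(n), undefined
#' for single-sample crosses); mean/sd intra-cross shared k-mers when k-mer
#' statistics are available.
#'
#' @param samples per-sample summary data.frame (from [run_pipeline()]).
#' @param kstats optional output of [cross_statistics()].
#' @return per-cross data.frame.
#' @export
summarize_cross <- function(samples, kstats = NULL) {
  out <- do.call(rbind, lapply(unique(samples$cross), function(cr) {
    s <- samples[samples$cross == cr, , drop = FALSE]
    has_k <- !is.null(s$n_gain)
    data.frame(
      cross = cr, n_samples = nrow(s),
      pct_with_gain = if (has_k) 100 * mean(s$n_gain >= 1) else NA_real_,
      pct_with_loss = if (has_k) 100 * mean(s$n_loss >= 1) else NA_real_,
      pct_with_both = if (has_k) 100 * mean(s$n_gain >= 1 & s$n_loss >= 1)
                      else NA_real_,
      mean_variance = if (has_k) mean(s$variance, na.rm = TRUE) else NA_real_,
      se_variance = if (has_k && nrow(s) > 1)
        sd(s$variance, na.rm = TRUE) / sqrt(sum(!is.na(s$variance)))
        else NA_real_,
      stringsAsFactors = FALSE)
  }))
  if (!is.null(kstats)) {
    m <- match(out$cross, kstats$per_cross$cross)
    out$mean_shared_kmers <- kstats$per_cross$mean_shared[m]
    out$sd_shared_kmers <- kstats$per_cross$sd_shared[m]
  }
  out
}
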