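#' @title Read-depth karyotyping
#' @name karyotype
#' @description
#' Windowed read depth (nominal 10 kb windows), repeat-window masking
#' (windows above 2x the chromosome's mean window depth are excluded),
#' per-chromosome and genome-wide means, whole-chromosome gain/loss calls at
#' a relative +/-30% rule on total (sp1+sp2) chromosome depth, per-genome
#' variance and delta statistics, and chromosome-size regressions. Depth can
#' come from internal read assignments or external bedGraph tracks.
NULL

#' Chromosome length table for a parent pair
#' @param parents list of `parent_genome` objects.
#' @return `data.frame(species, chromosome, length)`.
#' @export
chrom_lengths_table <- function(parents) {
  do.call(rbind, lapply(parents, function(p)
    data.frame(species = p$species_id, chromosome = names(p$chromosomes),
               length = unname(nchar(p$chromosomes)),
               stringsAsFactors = FALSE)))
}

# per-base coverage vector of one chromosome from interval (start,end,weight)
coverage_vector <- function(L, start, end, weight = 1) {
  s <- pmax(start, 0L)
  e <- pmin(end, L)
  keep <- s < L & e > s
  s <- s[keep]; e <- e[keep]
  if (length(weight) > 1L) weight <- weight[keep]
  if (length(weight) == 1L && weight == 1) {
    delta <- tabulate(s + 1L, nbins = L) - tabulate(e + 1L, nbins = L)
  } else {
    if (length(weight) == 1L) weight <- rep(weight, length(s))
    delta <- numeric(L)
    add <- rowsum(c(weight, -weight), c(s + 1L, e + 1L))
    idx <- as.integer(rownames(add))
    ok <- idx <= L
    delta[idx[ok]] <- add[ok, 1L]
  }
  cumsum(delta)
}

#' Mean read depth in tiling windows
#'
#' Tiles every chromosome with non-overlapping windows of `window_size` bp
#' (the last window may be short; it is retained and width-weighted
#' downstream) and computes mean depth as aligned bases per window divided by
#' window width.
#'
#' @param x either an `assignment_table` (placements; reads are rectangles of
#'   `read_length` bp at their placed position, clipped to the chromosome) or
#'   a depth track `data.frame(species, chromosome, start, end, depth)` as
#'   read by [read_bedgraph()].
#' @param lengths `data.frame(species, chromosome, length)`; see
#'   [chrom_lengths_table()].
#' @param window_size window width in bp (default 10000; values below 1000
#'   are rejected as degenerate).
#' @param read_length read length for placement input; defaults to the
#'   table's `read_length` attribute.
#' @return a `window_table` data.frame: `species, chromosome, start, end,
#'   width, mean_depth, masked`.
#' @export
window_depth <- function(x, lengths, window_size = 10000L, read_length = NULL) {
  if (window_size < 1000L)
    stopf("window_size below 1000 bp gives degenerate statistics")
  is_track <- !inherits(x, "assignment_table") && !is.null(x$depth)
  if (!is_track) {
    read_length <- read_length %||% attr(x, "read_length")
    if (is.null(read_length)) stopf("read_length required for placement input")
  }
  out <- vector("list", nrow(lengths))
  for (i in seq_len(nrow(lengths))) {
    sp <- lengths$species[i]; ch <- lengths$chromosome[i]
    L <- lengths$length[i]
    if (is_track) {
      rows <- x[x$species == sp & x$chromosome == ch, , drop = FALSE]
      cov <- coverage_vector(L, rows$start, rows$end, rows$depth)
    } else {
      rows <- x[x$species == sp & x$chromosome == ch &
                !is.na(x$position), , drop = FALSE]
      cov <- coverage_vector(L, rows$position, rows$position + read_length)
    }
    starts <- seq.int(0L, L - 1L, by = window_size)
    ends <- pmin(starts + window_size, L)
    cs <- c(0, cumsum(cov))
    md <- (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts)
    out[[i]] <- data.frame(species = sp, chromosome = ch, start = starts,
                           end = ends, width = ends - starts,
                           mean_depth = md, masked = FALSE,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("window_table", "data.frame")
  res
}

#' Mask suspected repetitive windows
#'
#' A window is masked iff its mean depth strictly exceeds `fold` times its
#' chromosome's mean window depth (+1 on the log2 scale at the default
#' `fold = 2`). The chromosome mean is computed in one pass over all windows
#' including the candidate; an iterative variant re-computes the mean over
#' unmasked windows until a fixed point. A chromosome with mean zero cannot
#' mask anything. Masked windows are excluded from all downstream chromosome
#' statistics.
#'
#' @param windows a `window_table`.
#' @param fold masking fold-change threshold (default 2).
#' @param iterative recompute the chromosome mean after each exclusion round.
#' @return the `window_table` with `masked` set.
#' @export
mask_repetitive_windows <- function(windows, fold = 2, iterative = FALSE) {
  key <- paste(windows$species, windows$chromosome)
  windows$masked <- FALSE
  for (k in unique(key)) {
    idx <- which(key == k)
    repeat {
      live <- idx[!windows$masked[idx]]
      m <- mean(windows$mean_depth[live])
      if (m <= 0) break
      new_mask <- windows$mean_depth[idx] > fold * m & !windows$masked[idx]
      if (!any(new_mask)) break
      windows$masked[idx][new_mask] <- TRUE
      if (!iterative) break
    }
  }
  windows
}

#' Chromosome and genome-wide depth summary
#'
#' Per (species, chromosome), the mean depth is the width-weighted mean of
#' unmasked window means; the total chromosome depth sums the two homeologous
#' subgenome means (species 1 + species 2). The genome-wide mean is twice the
#' width-weighted mean over all unmasked windows of both subgenomes, i.e. the
#' expected total (homeolog-summed) depth of a euploid chromosome; see the
#' methods vignette. A chromosome with all windows of either subgenome masked
#' is flagged and excluded from calls.
#'
#' @param windows a masked `window_table`.
#' @return a `chromosome_depth_summary`: `per_species`, `per_chromosome`
#'   data.frames, `genome_mean`, and the window table.
#' @export
chromosome_summary <- function(windows) {
  un <- windows[!windows$masked, , drop = FALSE]
  key <- unique(windows[, c("species", "chromosome")])
  per_sp <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    w <- un[un$species == key$species[i] & un$chromosome == key$chromosome[i], ]
    all_len <- sum(windows$width[windows$species == key$species[i] &
                                 windows$chromosome == key$chromosome[i]])
    data.frame(species = key$species[i], chromosome = key$chromosome[i],
               length = all_len,
               mean_depth = if (nrow(w)) weighted.mean(w$mean_depth, w$width)
                            else NA_real_,
               all_masked = nrow(w) == 0L, stringsAsFactors = FALSE)
  }))
  chroms <- unique(per_sp$chromosome)
  per_chrom <- do.call(rbind, lapply(chroms, function(ch) {
    rows <- per_sp[per_sp$chromosome == ch, ]
    data.frame(chromosome = ch, length = mean(rows$length),
               total_depth = if (any(rows$all_masked)) NA_real_
                             else sum(rows$mean_depth),
               excluded = any(rows$all_masked), stringsAsFactors = FALSE)
  }))
  D_G <- 2 * weighted.mean(un$mean_depth, un$width)
  structure(list(per_species = per_sp, per_chromosome = per_chrom,
                 genome_mean = D_G, windows = windows),
            class = "chromosome_depth_summary")
}

#' @export
print.chromosome_depth_summary <- function(x, ...) {
  cat(sprintf("<chromosome_depth_summary> %d chromosome(s), genome-wide mean %.3f\n",
              nrow(x$per_chromosome), x$genome_mean))
  invisible(x)
}

#' Call whole-chromosome gains and losses
#'
#' GAIN iff total chromosome depth strictly exceeds `(1 + threshold)` times
#' the genome-wide mean; LOSS iff strictly below `(1 - threshold)` times;
#' EUPLOID otherwise (depth exactly at a boundary is not evidence of change).
#'
#' @param summary a `chromosome_depth_summary`.
#' @param threshold relative deviation for a call (default 0.30).
#' @return `data.frame(chromosome, ratio, call)`; excluded chromosomes get
#'   `NA` calls.
#' @export
call_aneuploidy <- function(summary, threshold = 0.30) {
  D_G <- summary$genome_mean
  if (!is.finite(D_G) || D_G <= 0) stopf("genome-wide mean depth must be > 0")
  pc <- summary$per_chromosome
  ratio <- pc$total_depth / D_G
  call <- ifelse(pc$total_depth > (1 + threshold) * D_G, "GAIN",
          ifelse(pc$total_depth < (1 - threshold) * D_G, "LOSS", "EUPLOID"))
  call[pc$excluded] <- NA_character_
  data.frame(chromosome = pc$chromosome, ratio = ratio, call = call,
             stringsAsFactors = FALSE)
}

ols_fit <- function(x, y) {
  if (length(x) < 2L || var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                p = NA_real_, flagged = TRUE))
  fit <- lm(y ~ x)
  r <- if (var(y) == 0) 0 else cor(x, y)
  p <- if (var(y) == 0 || length(x) < 3L) NA_real_
       else cor.test(x, y)$p.value
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r, p = p, flagged = var(y) == 0)
}

#' Per-genome instability metrics
#'
#' Counts gains and losses, computes the sample variance (n-1 denominator)
#' of total chromosome depths, the per-chromosome delta
#' `|D_c - D_G|`, and the per-genome OLS slope of delta on chromosome length.
#'
#' @param summary a `chromosome_depth_summary`.
#' @param calls output of [call_aneuploidy()].
#' @param sample_id optional sample label.
#' @return an `aneuploidy_report`.
#' @export
genome_metrics <- function(summary, calls, sample_id = NULL) {
  pc <- summary$per_chromosome[!summary$per_chromosome$excluded, , drop = FALSE]
  D_G <- summary$genome_mean
  delta <- data.frame(chromosome = pc$chromosome, length = pc$length,
                      delta = abs(pc$total_depth - D_G),
                      stringsAsFactors = FALSE)
  n_gain <- sum(calls$call == "GAIN", na.rm = TRUE)
  n_loss <- sum(calls$call == "LOSS", na.rm = TRUE)
  fit <- if (nrow(delta) >= 3L) ols_fit(delta$length, delta$delta)
         else list(slope = NA_real_, r = NA_real_)
  structure(list(sample_id = sample_id, calls = calls,
                 n_gain = n_gain, n_loss = n_loss,
                 both_gain_and_loss = n_gain > 0 && n_loss > 0,
                 variance = if (nrow(pc) >= 2L) var(pc$total_depth) else NA_real_,
                 delta = delta, genome_mean = D_G,
                 slope = fit$slope, r = fit$r,
                 per_species = summary$per_species),
            class = "aneuploidy_report")
}

#' @export
print.aneuploidy_report <- function(x, ...) {
  cat(sprintf("<aneuploidy_report> %s: %d gain(s), %d loss(es), variance %.4f, slope %.3g\n",
              x$sample_id %||% "(unnamed)", x$n_gain, x$n_loss,
              x$variance, x$slope))
  invisible(x)
}

#' Convenience wrapper: windows to aneuploidy report
#'
#' Runs [window_depth()], [mask_repetitive_windows()],
#' [chromosome_summary()], [call_aneuploidy()] and [genome_metrics()] with
#' the given thresholds.
#'
#' @inheritParams window_depth
#' @inheritParams mask_repetitive_windows
#' @inheritParams call_aneuploidy
#' @param sample_id optional sample label.
#' @param mask apply repeat-window masking (default TRUE).
#' @return an `aneuploidy_report`.
#' @export
karyotype_report <- function(x, lengths, window_size = 10000L,
                             read_length = NULL, fold = 2, threshold = 0.30,
                             mask = TRUE, sample_id = NULL) {
  w <- window_depth(x, lengths, window_size, read_length)
  if (mask) w <- mask_repetitive_windows(w, fold)
  s <- chromosome_summary(w)
  genome_metrics(s, call_aneuploidy(s, threshold), sample_id)
}

#' Chromosome-size regressions of depth instability
#'
#' Ordinary least squares of delta mean read depth on chromosome length,
#' per genome and pooled over all genomes (Pearson r and two-sided p for the
#' pooled fit), plus the fraction of per-genome slopes that are negative.
#'
#' @param reports list of `aneuploidy_report` objects.
#' @return list with `per_genome` data.frame, `pooled` fit and
#'   `fraction_negative`.
#' @export
size_regression <- function(reports) {
  per <- do.call(rbind, lapply(reports, function(r) {
    fit <- ols_fit(r$delta$length, r$delta$delta)
    data.frame(sample_id = r$sample_id %||% NA_character_,
               slope = fit$slope, r = fit$r, stringsAsFactors = FALSE)
  }))
  allx <- unlist(lapply(reports, function(r) r$delta$length))
  ally <- unlist(lapply(reports, function(r) r$delta$delta))
  pooled <- ols_fit(allx, ally)
  ok <- !is.na(per$slope)
  list(per_genome = per, pooled = pooled,
       fraction_negative = mean(per$slope[ok] < 0))
}

#' Cross-level delta heatmap with per-chromosome normalization
#'
#' Means of delta read depth per (cross, chromosome), normalized per
#' chromosome column with a two-sided piecewise-linear scale: 0 at the
#' minimum cross mean, 0.5 at the overall mean, 1 at the maximum.
#'
#' @param reports list of `aneuploidy_report` objects.
#' @param crosses character vector of cross labels, one per report.
#' @return list with `raw` and `normalized` cross-by-chromosome matrices.
#' @export
cross_heatmap <- function(reports, crosses) {
  stopifnot(length(reports) == length(crosses))
  if (length(unique(crosses)) < 2L) stopf("need at least two crosses")
  df <- do.call(rbind, Map(function(r, cr)
    cbind(r$delta, cross = cr, stringsAsFactors = FALSE), reports, crosses))
  chroms <- unique(df$chromosome); crs <- unique(df$cross)
  raw <- matrix(NA_real_, length(crs), length(chroms),
                dimnames = list(crs, chroms))
  for (cr in crs) for (ch in chroms) {
    v <- df$delta[df$cross == cr & df$chromosome == ch]
    if (length(v)) raw[cr, ch] <- mean(v)
  }
  norm <- raw
  for (ch in chroms) {
    v <- raw[, ch]
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    mid <- mean(v, na.rm = TRUE)
    norm[, ch] <- ifelse(v <= mid,
                         if (mid > lo) 0.5 * (v - lo) / (mid - lo) else 0.5,
                         0.5 + if (hi > mid) 0.5 * (v - mid) / (hi - mid) else 0)
  }
  list(raw = raw, normalized = norm)
}

#' Join contribution balance with instability metrics
#'
#' @param profile a `contribution_profile` of a two-parent sample.
#' @param report the sample's `aneuploidy_report`.
#' @return list with `balance` (sp1 fraction - sp2 fraction), `n_gain`,
#'   `n_loss`, `variance`.
#' @export
contribution_balance <- function(profile, report) {
  fr <- profile$nuclear_fraction
  list(balance = unname(fr[1] - fr[2]), n_gain = report$n_gain,
       n_loss = report$n_loss, variance = report$variance)
}
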