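#' @title Marker-based loss-of-heterozygosity analysis
#' @name loh
#' @description
#' Parental single-nucleotide markers are derived by direct comparison of the
#' collinear parent genomes (one marker per differing site). Markers are
#' genotyped from the read bases observed at each marker position (a pileup
#' surrogate), maximal same-parent homozygous runs are called as LOH
#' segments, and per-region cohort frequencies are mapped after the
#' at-least-20%-per-parent inclusion rule.
NULL

#' Derive single-nucleotide markers from a collinear parent pair
#'
#' @param p1,p2 `parent_genome` objects with equal chromosome structure
#'   (guaranteed by the simulator's substitution-only divergence model).
#' @return a `marker_table` data.frame: `chromosome, position, allele_p1,
#'   allele_p2` with positions strictly increasing per chromosome.
#' @export
derive_markers <- function(p1, p2) {
  if (!identical(names(p1$chromosomes), names(p2$chromosomes)))
    stopf("parents are not collinear (chromosome sets differ)")
  out <- lapply(names(p1$chromosomes), function(ch) {
    a <- strsplit(p1$chromosomes[[ch]], "", fixed = TRUE)[[1]]
    b <- strsplit(p2$chromosomes[[ch]], "", fixed = TRUE)[[1]]
    if (length(a) != length(b))
      stopf("chromosome %s lengths differ: collinearity violated", ch)
    d <- which(a != b)
    data.frame(chromosome = rep(ch, length(d)), position = d - 1L,
               allele_p1 = a[d], allele_p2 = b[d], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "parents") <- c(p1$species_id, p2$species_id)
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Per-marker allele depths from placed reads
#'
#' For every assigned read the base observed at each marker position it
#' covers is compared with the two parental alleles; other bases (sequencing
#' errors) are ignored. Placements come from the diagnostic-k-mer assignment
#' and are exact on the collinear coordinate system.
#'
#' @param reads the `read_set` the assignments were computed from.
#' @param assignments a nuclear `assignment_table` for those reads.
#' @param markers a `marker_table`.
#' @return data.frame `chromosome, position, depth_p1, depth_p2`.
#' @export
marker_allele_counts <- function(reads, assignments, markers) {
  ok <- !is.na(assignments$position)
  ass <- assignments[ok, , drop = FALSE]
  seqs <- reads$seq[match(ass$read_id, reads$id)]
  out <- lapply(unique(markers$chromosome), function(ch) {
    m <- markers[markers$chromosome == ch, , drop = FALSE]
    sel <- ass$chromosome == ch
    cnt <- cpp_count_alleles(seqs[sel], as.integer(ass$position[sel]),
                             as.integer(m$position), m$allele_p1, m$allele_p2)
    data.frame(chromosome = ch, position = m$position,
               depth_p1 = cnt$depth_p1, depth_p2 = cnt$depth_p2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genotype parental markers
#'
#' `HOM_P1` when the first parent's allele holds at least `purity` of the
#' allele-supporting depth, `HOM_P2` symmetrically, `HET` otherwise;
#' `NO_CALL` when total supporting depth is below `min_depth`.
#'
#' @param x either an allele-count table (`chromosome, position, depth_p1,
#'   depth_p2`) or an `assignment_table` (then `reads` is required).
#' @param markers a `marker_table`.
#' @param reads the `read_set`, when `x` is an assignment table.
#' @param min_depth minimum supporting depth for a call (default 3).
#' @param purity homozygosity threshold on the allele fraction (default 0.9).
#' @return a `marker_genotypes` data.frame with `call` added.
#' @export
genotype_markers <- function(x, markers, reads = NULL, min_depth = 3L,
                             purity = 0.9) {
  counts <- if (inherits(x, "assignment_table")) {
    if (is.null(reads)) stopf("reads are required with assignment input")
    marker_allele_counts(reads, x, markers)
  } else x
  tot <- counts$depth_p1 + counts$depth_p2
  f1 <- ifelse(tot > 0, counts$depth_p1 / tot, NA_real_)
  call <- ifelse(tot < min_depth, "NO_CALL",
          ifelse(f1 >= purity, "HOM_P1",
          ifelse(1 - f1 >= purity, "HOM_P2", "HET")))
  counts$call <- call
  attr(counts, "parents") <- attr(markers, "parents")
  class(counts) <- c("marker_genotypes", "data.frame")
  counts
}

#' Call LOH segments as homozygous marker runs
#'
#' Scans genotypes in position order per chromosome for maximal runs of at
#' least `min_run` same-parent homozygous calls uninterrupted by `HET` or
#' opposite-parent calls. `NO_CALL` markers are transparent (skipped):
#' missing data is not evidence of heterozygosity. Segment coordinates span
#' the first to last marker of the run (`end` = last marker position + 1).
#'
#' @param genotypes a `marker_genotypes` table.
#' @param min_run minimum number of consecutive informative same-parent
#'   homozygous markers (default 10).
#' @return data.frame `chromosome, start, end, retained_parent` (P1/P2),
#'   `species` (parent label when known), `n_markers`.
#' @export
call_loh_segments <- function(genotypes, min_run = 10L) {
  parents <- attr(genotypes, "parents")
  out <- list()
  for (ch in unique(genotypes$chromosome)) {
    g <- genotypes[genotypes$chromosome == ch, , drop = FALSE]
    g <- g[order(g$position), , drop = FALSE]
    g <- g[g$call != "NO_CALL", , drop = FALSE]
    if (!nrow(g)) next
    r <- rle(g$call)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i] %in% c("HOM_P1", "HOM_P2")) next
      if (r$lengths[i] < min_run) next
      who <- if (r$values[i] == "HOM_P1") "P1" else "P2"
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch,
        start = g$position[starts[i]],
        end = g$position[ends[i]] + 1L,
        retained_parent = who,
        species = if (!is.null(parents))
          parents[if (who == "P1") 1L else 2L] else NA_character_,
        n_markers = r$lengths[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), retained_parent = character(0),
                      species = character(0), n_markers = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Percentage of the genome in LOH
#'
#' @param segments segment table from [call_loh_segments()] (non-overlapping).
#' @param genome_length total genome length in bp.
#' @return percentage in `[0, 100]`.
#' @export
loh_fraction <- function(segments, genome_length) {
  if (nrow(segments)) {
    o <- order(segments$chromosome, segments$start)
    s <- segments[o, , drop = FALSE]
    for (ch in unique(s$chromosome)) {
      sub <- s[s$chromosome == ch, , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        stopf("overlapping LOH segments on %s", ch)
    }
  }
  100 * sum(segments$end - segments$start) / genome_length
}

#' Per-region cohort LOH frequency
#'
#' Tiles each chromosome with `bin_size` bins and reports, per bin and
#' retained-parent direction, the fraction of included samples in which at
#' least `min_cover` of the bin is covered by a matching LOH segment.
#' Samples are included only when each parent contributed at least
#' `min_parent_frac` of the nuclear genome.
#'
#' @param cohort_segments named list of per-sample segment tables.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param contributions optional named list (or data.frame with rownames) of
#'   per-sample two-parent nuclear fractions used for the inclusion rule.
#' @param bin_size bin width in bp (default 10000).
#' @param min_parent_frac minimum per-parent contribution (default 0.20).
#' @param min_cover minimum covered fraction of a bin (default 0.5).
#' @return data.frame `chromosome, start, end, freq_p1, freq_p2`; the number
#'   of included samples is in the `n_samples` attribute.
#' @export
region_frequency <- function(cohort_segments, chrom_lengths,
                             contributions = NULL, bin_size = 10000L,
                             min_parent_frac = 0.20, min_cover = 0.5) {
  ids <- names(cohort_segments) %||% as.character(seq_along(cohort_segments))
  keep <- rep(TRUE, length(ids))
  if (!is.null(contributions)) {
    keep <- vapply(ids, function(s) {
      fr <- contributions[[s]]
      !is.null(fr) && length(fr) >= 2 &&
        all(sort(fr, decreasing = TRUE)[1:2] >= min_parent_frac)
    }, logical(1))
  }
  if (!any(keep)) stopf("no samples pass the %.0f%% per-parent rule",
                        100 * min_parent_frac)
  segs <- cohort_segments[keep]
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    st <- seq.int(0L, chrom_lengths[[ch]] - 1L, by = bin_size)
    data.frame(chromosome = ch, start = st,
               end = pmin(st + bin_size, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  cover <- function(seg, dir) {
    hit <- numeric(nrow(bins))
    s <- seg[seg$retained_parent == dir, , drop = FALSE]
    for (i in seq_len(nrow(bins))) {
      sub <- s[s$chromosome == bins$chromosome[i], , drop = FALSE]
      if (!nrow(sub)) next
      ov <- pmin(sub$end, bins$end[i]) - pmax(sub$start, bins$start[i])
      hit[i] <- sum(pmax(ov, 0)) / (bins$end[i] - bins$start[i])
    }
    hit >= min_cover
  }
  f1 <- rowMeans(matrix(vapply(segs, cover, logical(nrow(bins)), dir = "P1"),
                        nrow = nrow(bins)))
  f2 <- rowMeans(matrix(vapply(segs, cover, logical(nrow(bins)), dir = "P2"),
                        nrow = nrow(bins)))
  bins$freq_p1 <- f1
  bins$freq_p2 <- f2
  attr(bins, "n_samples") <- length(segs)
  bins
}
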