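#' @title Species-contribution estimation from diagnostic k-mers
#' @name ancestry
#' @description
#' A diagnostic k-mer index over the candidate parent genomes stands in for
#' competitive read mapping: k-mers unique to one parent assign reads to a
#' subgenome, the hit-count/margin thresholds playing the role of a
#' mapping-quality filter. Contributions are read fractions; mitochondrial
#' inheritance is classified against a separate haplotype index with a
#' max-over-clades rule, and nuclear/mito concordance is tested with Welch's
#' t-test.
NULL

new_diag_index <- function(raw, k, unit_labels, chrom_labels, species_of_unit,
                           clade_of_unit) {
  structure(list(k = k, keys = raw$keys, unit = raw$species,
                 chrom = raw$chrom, pos = raw$pos,
                 unit_labels = unit_labels, chrom_labels = chrom_labels,
                 species_of_unit = species_of_unit,
                 clade_of_unit = clade_of_unit,
                 ambiguous_count = raw$ambiguous_count,
                 n_distinct = raw$n_distinct),
            class = "diagnostic_index")
}

#' @export
print.diagnostic_index <- function(x, ...) {
  cat(sprintf("<diagnostic_index> k=%d, %d unit(s), %s diagnostic k-mers, %s ambiguous\n",
              x$k, length(x$unit_labels),
              format(length(x$keys), big.mark = ","),
              format(x$ambiguous_count, big.mark = ",")))
  invisible(x)
}

#' Build a diagnostic k-mer index over parent genomes
#'
#' Indexes every canonical k-mer occurring in exactly one parent species with
#' one representative position (first occurrence); k-mers present in two or
#' more species are counted as ambiguous and excluded. k must be odd so a
#' k-mer never equals its own reverse complement.
#'
#' @param parents list of two or more `parent_genome` objects.
#' @param k k-mer size (odd, 11-25; default 17).
#' @return a `diagnostic_index`.
#' @export
build_diagnostic_index <- function(parents, k = 17L) {
  k <- check_k(k)
  stopifnot(length(parents) >= 2L)
  seqs <- character(0); unit <- integer(0); chrom <- integer(0)
  labels <- vapply(parents, `[[`, character(1), "species_id")
  chrom_labels <- lapply(parents, function(p) names(p$chromosomes))
  for (i in seq_along(parents)) {
    cs <- parents[[i]]$chromosomes
    if (any(nchar(cs) < k))
      stopf("parent %s has a chromosome shorter than k = %d", labels[i], k)
    seqs <- c(seqs, unname(cs))
    unit <- c(unit, rep(i, length(cs)))
    chrom <- c(chrom, seq_along(cs))
  }
  raw <- cpp_build_index(seqs, as.integer(unit), as.integer(chrom), k)
  new_diag_index(raw, k, labels, chrom_labels, labels,
                 rep(NA_character_, length(labels)))
}

#' Build a diagnostic index over mitochondrial haplotypes
#'
#' Each (species, clade) haplotype is an assignment unit of its own, so reads
#' can distinguish divergent donor clades within one species; k-mers shared
#' between clades (or species) are ambiguous.
#'
#' @inheritParams build_diagnostic_index
#' @export
build_mito_index <- function(parents, k = 17L) {
  k <- check_k(k)
  seqs <- character(0); sp <- character(0); cl <- character(0)
  for (p in parents) {
    if (any(nchar(p$mito) < k))
      stopf("mitochondrial haplotype shorter than k = %d", k)
    seqs <- c(seqs, unname(p$mito))
    sp <- c(sp, rep(p$species_id, length(p$mito)))
    cl <- c(cl, names(p$mito))
  }
  labels <- paste(sp, cl, sep = "::")
  raw <- cpp_build_index(seqs, seq_along(seqs), rep(1L, length(seqs)), k)
  new_diag_index(raw, k, labels, as.list(rep("mito", length(seqs))), sp, cl)
}

#' Fraction of one parent's distinct k-mers that are diagnostic
#'
#' For parents at divergence d, roughly `1 - (1 - d)^k` of a species'
#' distinct k-mers overlap a substituted site and are therefore diagnostic.
#'
#' @param index a `diagnostic_index`.
#' @param parent one of the parents the index was built from.
#' @return list with `n_distinct` and `fraction_diagnostic`.
#' @export
diagnostic_fraction <- function(index, parent) {
  i <- match(parent$species_id, index$unit_labels)
  if (is.na(i)) stopf("species '%s' not in index", parent$species_id)
  keys_i <- index$keys[index$unit == i]
  res <- cpp_distinct_in_keys(unname(parent$chromosomes), index$k, keys_i)
  list(n_distinct = res[1], fraction_diagnostic = res[2] / res[1])
}

#' Assign reads to parental subgenomes
#'
#' Counts diagnostic k-mer hits per assignment unit over all canonical
#' k-mers of each read. A read is assigned to the top unit when its hit count
#' reaches `min_hits` and exceeds the runner-up by at least `min_margin`
#' (the analogue of a mapping-quality filter); ties or insufficient hits
#' yield `AMBIGUOUS`, zero hits `UNASSIGNED`. The placement position is the
#' reference position of the first matching k-mer minus its offset in the
#' read. Reads shorter than k are `UNASSIGNED` (flagged, not fatal).
#'
#' @param reads a `read_set` or character vector of read sequences.
#' @param index a `diagnostic_index`.
#' @param min_hits minimum diagnostic hits for assignment (default 2).
#' @param min_margin minimum lead over the second-best unit (default 2).
#' @return an `assignment_table` data.frame with one row per read:
#'   `read_id, species, chromosome, position, n_hits, margin`.
#' @export
assign_reads <- function(reads, index, min_hits = 2L, min_margin = 2L) {
  if (inherits(reads, "read_set")) {
    seqs <- reads$seq; ids <- reads$id; rl <- reads$read_length
  } else {
    seqs <- reads; ids <- names(reads) %||% paste0("read", seq_along(reads))
    rl <- if (length(reads)) max(nchar(reads)) else 0L
  }
  if (!length(seqs)) stopf("empty read set")
  res <- cpp_assign_reads(seqs, index$keys, index$unit, index$chrom,
                          index$pos, index$k, length(index$unit_labels),
                          as.integer(min_hits), as.integer(min_margin))
  unit <- res$species
  lab <- ifelse(unit > 0, index$unit_labels[pmax(unit, 1L)],
                ifelse(unit == 0L, "UNASSIGNED", "AMBIGUOUS"))
  chrom <- rep(NA_character_, length(unit))
  ok <- which(unit > 0)
  if (length(ok))
    chrom[ok] <- mapply(function(u, c) index$chrom_labels[[u]][c],
                        unit[ok], res$chrom[ok])
  out <- data.frame(read_id = ids, species = lab, chromosome = chrom,
                    position = res$pos, n_hits = res$n_hits,
                    margin = res$margin, stringsAsFactors = FALSE)
  attr(out, "read_length") <- rl
  attr(out, "unit_labels") <- index$unit_labels
  attr(out, "species_of_unit") <- index$species_of_unit
  attr(out, "clade_of_unit") <- index$clade_of_unit
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Route reads between nuclear and mitochondrial indexes
#'
#' Each read is scored against both indexes; it is routed to the
#' mitochondrial table when its mitochondrial hit count is positive and at
#' least its nuclear hit count (mito wins ties, reflecting organelle copy
#' number), otherwise to the nuclear table.
#'
#' @param reads a `read_set`.
#' @param nuclear_index,mito_index diagnostic indexes from
#'   [build_diagnostic_index()] / [build_mito_index()].
#' @inheritParams assign_reads
#' @return list with `nuclear` and `mito` assignment tables.
#' @export
classify_reads <- function(reads, nuclear_index, mito_index,
                           min_hits = 2L, min_margin = 2L) {
  nuc <- assign_reads(reads, nuclear_index, min_hits, min_margin)
  mit <- assign_reads(reads, mito_index, min_hits, min_margin)
  route <- mit$n_hits > 0L & mit$n_hits >= nuc$n_hits
  keep_attrs <- function(x, template) {
    for (a in c("read_length", "unit_labels", "species_of_unit", "clade_of_unit"))
      attr(x, a) <- attr(template, a)
    class(x) <- c("assignment_table", "data.frame")
    x
  }
  list(nuclear = keep_attrs(nuc[!route, , drop = FALSE], nuc),
       mito = keep_attrs(mit[route, , drop = FALSE], mit))
}

#' Per-species read fractions from an assignment table
#'
#' Fractions are computed over all reads in the table; ambiguous and
#' unassigned fractions are reported separately and the three components
#' close to 1.
#'
#' @param table an `assignment_table`.
#' @return list with `fractions` (named, per unit), `assigned`, `ambiguous`,
#'   `unassigned`, `n_reads`.
#' @export
species_contributions <- function(table) {
  n <- nrow(table)
  if (!n) stopf("empty assignment table")
  labs <- attr(table, "unit_labels")
  fr <- vapply(labs, function(l) sum(table$species == l) / n, numeric(1))
  amb <- sum(table$species == "AMBIGUOUS") / n
  una <- sum(table$species == "UNASSIGNED") / n
  stopifnot(abs(sum(fr) + amb + una - 1) < 1e-9)
  list(fractions = fr, assigned = sum(fr), ambiguous = amb,
       unassigned = una, n_reads = n)
}

#' Summarize mitochondrial inheritance from a mito assignment table
#'
#' Fractions are reported per (species, clade) unit; a species' score is the
#' maximum over its clades (divergent-donor-clade rule) and the majority
#' species is the argmax of those scores. Zero assigned reads or a tie leave
#' the majority undefined and flag the sample.
#'
#' @param table a mito `assignment_table` (from [classify_reads()] or
#'   [assign_reads()] against a mito index).
#' @return list with `fractions`, `species_scores`, `majority_species`,
#'   `majority_clade`, `flagged`.
#' @export
mito_assign <- function(table) {
  if (!nrow(table))
    return(list(fractions = numeric(0), species_scores = numeric(0),
                majority_species = NA_character_,
                majority_clade = NA_character_, flagged = TRUE))
  sc <- species_contributions(table)
  sp_of <- attr(table, "species_of_unit")
  cl_of <- attr(table, "clade_of_unit")
  scores <- tapply(sc$fractions, sp_of, max)
  flagged <- sc$assigned == 0 ||
    (length(scores) > 1 && sum(scores == max(scores)) > 1)
  maj_sp <- if (flagged) NA_character_ else names(which.max(scores))
  maj_cl <- NA_character_
  if (!is.na(maj_sp)) {
    i <- which(sp_of == maj_sp)
    maj_cl <- cl_of[i[which.max(sc$fractions[i])]]
  }
  list(fractions = sc$fractions, species_scores = scores,
       majority_species = maj_sp, majority_clade = maj_cl, flagged = flagged)
}

#' Combine nuclear and mitochondrial assignments into a contribution profile
#'
#' @param sample_id sample label.
#' @param nuclear_table nuclear `assignment_table`.
#' @param mito_table optional mito `assignment_table`.
#' @return a `contribution_profile`: nuclear fractions, assigned fraction,
#'   mito fractions, majorities and the nuclear/mito concordance flag.
#' @export
contribution_profile <- function(sample_id, nuclear_table, mito_table = NULL) {
  nf <- species_contributions(nuclear_table)
  maj_nuc <- NA_character_
  if (nf$assigned > 0) {
    top <- which(nf$fractions == max(nf$fractions))
    if (length(top) == 1L) maj_nuc <- names(nf$fractions)[top]
  }
  mito <- if (!is.null(mito_table)) mito_assign(mito_table) else NULL
  conc <- if (is.null(mito) || is.na(maj_nuc) || is.na(mito$majority_species))
    NA else identical(maj_nuc, mito$majority_species)
  structure(list(sample_id = sample_id,
                 nuclear_fraction = nf$fractions,
                 assigned = nf$assigned, ambiguous = nf$ambiguous,
                 unassigned = nf$unassigned,
                 mito_fraction = if (is.null(mito)) NULL else mito$fractions,
                 majority_nuclear = maj_nuc,
                 majority_nuclear_pct = 100 * max(nf$fractions),
                 majority_mito = if (is.null(mito)) NA_character_ else mito$majority_species,
                 majority_mito_clade = if (is.null(mito)) NA_character_ else mito$majority_clade,
                 concordant = conc),
            class = "contribution_profile")
}

#' @export
print.contribution_profile <- function(x, ...) {
  cat(sprintf("<contribution_profile> %s: %s | assigned %.1f%% | mito %s | concordant: %s\n",
              x$sample_id,
              paste(sprintf("%s=%.3f", names(x$nuclear_fraction),
                            x$nuclear_fraction), collapse = " "),
              100 * x$assigned, x$majority_mito, x$concordant))
  invisible(x)
}

#' Cohort inclusion filter
#'
#' A sample is included when its confidently-assigned read fraction reaches
#' `min_assigned` (default 0.85, the >85% high-quality-mapping rule) and
#' exactly two species each hold at least `minor_floor` of the assigned reads
#' (the two-parent restriction; the 5% floor separates introgression noise
#' from parental signal).
#'
#' @param profile a `contribution_profile`.
#' @param min_assigned minimum assigned fraction (default 0.85).
#' @param minor_floor minimum share of assigned reads to count a species as
#'   a parent (default 0.05).
#' @return list with `include` (logical) and `reason` (`"ok"`,
#'   `"low assignment"`, `"not two-parent"`, or both).
#' @export
inclusion_filter <- function(profile, min_assigned = 0.85, minor_floor = 0.05) {
  reasons <- character(0)
  if (profile$assigned < min_assigned) reasons <- c(reasons, "low assignment")
  share <- if (profile$assigned > 0)
    profile$nuclear_fraction / profile$assigned else profile$nuclear_fraction
  if (sum(share >= minor_floor) != 2L) reasons <- c(reasons, "not two-parent")
  list(include = !length(reasons),
       reason = if (length(reasons)) paste(reasons, collapse = "; ") else "ok")
}

#' Welch's two-sample t-test (unequal variances)
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with `t`, `df` (Welch-Satterthwaite), `p_value`.
#' @export
welch_t <- function(x, y) {
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Nuclear/mitochondrial concordance test over a cohort
#'
#' Compares the majority-nuclear percentage between concordant and discordant
#' samples with Welch's t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom). When either group has fewer than two members the
#' comparison is reported as `NOT_TESTABLE` (a value, not an error).
#'
#' @param profiles list of `contribution_profile` objects.
#' @return list with `result` (`"TESTED"` or `"NOT_TESTABLE"`), `t`, `df`,
#'   `p_value`, `n_concordant`, `n_discordant`.
#' @export
concordance_test <- function(profiles) {
  conc <- vapply(profiles, function(p) p$concordant, logical(1))
  pct <- vapply(profiles, function(p) p$majority_nuclear_pct, numeric(1))
  keep <- !is.na(conc)
  x <- pct[keep & conc]; y <- pct[keep & !conc]
  if (length(x) < 2L || length(y) < 2L)
    return(list(result = "NOT_TESTABLE", t = NA_real_, df = NA_real_,
                p_value = NA_real_, n_concordant = length(x),
                n_discordant = length(y)))
  w <- welch_t(x, y)
  c(list(result = "TESTED"), w,
    list(n_concordant = length(x), n_discordant = length(y)))
}
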