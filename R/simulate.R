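#' @title Synthetic hybrid cohorts
#' @name simulate
#' @description
#' The simulator emits parent genomes, hybrid templates/read sets and truth
#' tables with the statistical structure the downstream analyses assume:
#' substitution-only parental divergence (collinear coordinates), per-subgenome
#' chromosome copy numbers, LOH tracts that replace one parent's sequence with
#' the other's, repeat inserts that inflate local depth, and homoplasmic
#' mitochondrial inheritance with optionally several donor clades per species.
NULL

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute each site independently with probability `divergence`, always to
# a different base
mutate_seq <- function(seq, divergence) {
  if (divergence == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(v)) < divergence)
  if (length(idx)) {
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 4, byrow = TRUE)
    v[idx] <- alt[cbind(match(v[idx], DNA_BASES),
                        sample.int(3L, length(idx), replace = TRUE))]
  }
  paste(v, collapse = "")
}

new_parent_genome <- function(species_id, chromosomes, mito) {
  stopifnot(!anyDuplicated(names(chromosomes)), all(nchar(chromosomes) > 0))
  if (length(mito) && max(nchar(mito)) >= min(nchar(chromosomes)))
    stopf("mitochondrial sequence must be shorter than any nuclear chromosome")
  structure(list(species_id = species_id, chromosomes = chromosomes,
                 mito = mito), class = "parent_genome")
}

#' @export
print.parent_genome <- function(x, ...) {
  cat(sprintf("<parent_genome> %s: %d chromosomes (%s bp), %d mito clade(s)\n",
              x$species_id, length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              length(x$mito)))
  invisible(x)
}

#' Generate a divergent pair of parent genomes
#'
#' Draws a random ancestor and derives the second parent by independent
#' per-site substitution, so the two genomes stay collinear (no indels) and
#' the realized genome-wide mismatch fraction converges to `divergence`.
#' Mitochondrial haplotypes are generated per clade, with an independently
#' configurable between-species mitochondrial divergence and a smaller
#' within-species divergence between clades of the same species.
#'
#' @param chrom_lengths integer vector of nuclear chromosome lengths (bp).
#' @param divergence probability that a site differs between the parents;
#'   must lie in `[0, 0.25]` (the substitution model saturates beyond that).
#' @param species_ids labels for the two parents.
#' @param mito_length mitochondrial genome length (bp); must be shorter than
#'   the shortest nuclear chromosome.
#' @param n_mito_clades number of mitochondrial donor clades per species
#'   (length 1 or 2; e.g. `c(1, 2)` gives the second species two divergent
#'   clades).
#' @param mito_divergence between-species mitochondrial divergence
#'   (default: same as nuclear).
#' @param clade_divergence divergence between clades within a species.
#' @param seed integer seed; output is deterministic given the arguments.
#' @return list of two `parent_genome` objects.
#' @export
generate_parent_pair <- function(chrom_lengths, divergence,
                                 species_ids = c("sp1", "sp2"),
                                 mito_length = 5000L,
                                 n_mito_clades = 1L,
                                 mito_divergence = divergence,
                                 clade_divergence = 0.02,
                                 seed = 1L) {
  if (divergence < 0 || divergence > 0.25)
    stopf("divergence must be in [0, 0.25], got %s", divergence)
  stopifnot(all(chrom_lengths > 0), mito_length > 0,
            length(species_ids) == 2L)
  if (length(n_mito_clades) == 1L) n_mito_clades <- rep(n_mito_clades, 2L)
  chrom_names <- names(chrom_lengths) %||% paste0("chr", seq_along(chrom_lengths))
  with_seed(seed, {
    anc <- vapply(chrom_lengths, random_dna, character(1))
    names(anc) <- chrom_names
    chrom2 <- vapply(anc, mutate_seq, character(1), divergence = divergence)
    mito_anc <- random_dna(mito_length)
    mito_sp <- list(mito_anc, mutate_seq(mito_anc, mito_divergence))
    mk_clades <- function(base, n) {
      cl <- c(base, vapply(seq_len(max(0L, n - 1L)), function(i)
        mutate_seq(base, clade_divergence), character(1)))
      names(cl) <- paste0("clade", seq_len(n))
      cl[seq_len(n)]
    }
    list(new_parent_genome(species_ids[1], anc, mk_clades(mito_sp[[1]], n_mito_clades[1])),
         new_parent_genome(species_ids[2], chrom2, mk_clades(mito_sp[[2]], n_mito_clades[2])))
  })
}

#' Realized per-site divergence between two collinear parents
#'
#' @param p1,p2 `parent_genome` objects with identical chromosome structure.
#' @return mismatch fraction over all nuclear sites.
#' @export
parental_divergence <- function(p1, p2) {
  stopifnot(identical(names(p1$chromosomes), names(p2$chromosomes)))
  mm <- 0; tot <- 0
  for (ch in names(p1$chromosomes)) {
    a <- charToRaw(p1$chromosomes[[ch]]); b <- charToRaw(p2$chromosomes[[ch]])
    if (length(a) != length(b)) stopf("chromosome %s lengths differ", ch)
    mm <- mm + sum(a != b); tot <- tot + length(a)
  }
  mm / tot
}

check_intervals <- function(x, lengths, what) {
  for (i in seq_len(nrow(x))) {
    ch <- x$chromosome[i]
    if (!ch %in% names(lengths)) stopf("%s names unknown chromosome '%s'", what, ch)
    if (x$start[i] < 0 || x$end[i] > lengths[[ch]] || x$end[i] <= x$start[i])
      stopf("%s interval out of bounds on %s: [%d, %d)", what, ch,
            x$start[i], x$end[i])
  }
  invisible(x)
}

#' Construct a hybrid genome and its ground-truth record
#'
#' Applies whole-chromosome aneuploidies (copy-number deltas per parental
#' subgenome), loss-of-heterozygosity tracts (the losing parent's template
#' sequence is replaced by the retained parent's homeologous sequence), and
#' repeat-insert annotations, and records the mitochondrial donor. All
#' coordinates are 0-based, half-open.
#'
#' @param parents list of two `parent_genome` objects (collinear).
#' @param contribution expected read fraction for the first parent, in (0,1).
#' @param aneuploidies `data.frame(species, chromosome, delta)` of copy-number
#'   changes relative to the 1+1 baseline, or `NULL`.
#' @param loh_tracts `data.frame(chromosome, start, end, retained_parent)`
#'   with `retained_parent` a species id; tracts must not overlap.
#' @param repeat_inserts `data.frame(species, chromosome, start, end,
#'   copy_count)` intervals whose read depth is inflated `copy_count`-fold.
#' @param mito_donor character `c(species)` or `c(species, clade)`; defaults
#'   to the first clade of the first parent.
#' @param sample_id label for the hybrid.
#' @param seed integer recorded in the truth table.
#' @return a `hybrid_truth` object (truth table plus per-subgenome templates).
#' @export
generate_hybrid <- function(parents, contribution = 0.5, aneuploidies = NULL,
                            loh_tracts = NULL, repeat_inserts = NULL,
                            mito_donor = NULL, sample_id = "hybrid",
                            seed = 1L) {
  stopifnot(length(parents) == 2L)
  if (contribution <= 0 || contribution >= 1)
    stopf("contribution must lie strictly inside (0, 1)")
  sp_ids <- vapply(parents, `[[`, character(1), "species_id")
  chrom_names <- names(parents[[1]]$chromosomes)
  stopifnot(identical(chrom_names, names(parents[[2]]$chromosomes)))
  lengths <- nchar(parents[[1]]$chromosomes)

  copy <- expand.grid(species = sp_ids, chromosome = chrom_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  copy$copies <- 1L
  if (!is.null(aneuploidies) && nrow(aneuploidies)) {
    for (i in seq_len(nrow(aneuploidies))) {
      j <- which(copy$species == aneuploidies$species[i] &
                 copy$chromosome == aneuploidies$chromosome[i])
      if (!length(j))
        stopf("aneuploidy names absent chromosome %s:%s",
              aneuploidies$species[i], aneuploidies$chromosome[i])
      copy$copies[j] <- copy$copies[j] + as.integer(aneuploidies$delta[i])
    }
    if (any(copy$copies < 0)) stopf("aneuploidies produce negative copy number")
  }

  templates <- lapply(parents, `[[`, "chromosomes")
  names(templates) <- sp_ids
  if (!is.null(loh_tracts) && nrow(loh_tracts)) {
    check_intervals(loh_tracts, lengths, "LOH tract")
    o <- order(loh_tracts$chromosome, loh_tracts$start)
    lt <- loh_tracts[o, , drop = FALSE]
    for (ch in unique(lt$chromosome)) {
      sub <- lt[lt$chromosome == ch, , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        stopf("LOH tracts overlap on %s", ch)
    }
    for (i in seq_len(nrow(lt))) {
      keep <- lt$retained_parent[i]
      if (!keep %in% sp_ids) stopf("unknown retained_parent '%s'", keep)
      lose <- setdiff(sp_ids, keep)
      donor <- substr(templates[[keep]][[lt$chromosome[i]]],
                      lt$start[i] + 1L, lt$end[i])
      s <- templates[[lose]][[lt$chromosome[i]]]
      substr(s, lt$start[i] + 1L, lt$end[i]) <- donor
      templates[[lose]][[lt$chromosome[i]]] <- s
    }
    loh_tracts <- lt
  }
  if (!is.null(repeat_inserts) && nrow(repeat_inserts))
    check_intervals(repeat_inserts, lengths, "repeat insert")

  if (is.null(mito_donor)) mito_donor <- c(sp_ids[1], names(parents[[1]]$mito)[1])
  if (length(mito_donor) == 1L) {
    p <- parents[[match(mito_donor, sp_ids)]]
    mito_donor <- c(mito_donor, names(p$mito)[1])
  }
  if (!mito_donor[1] %in% sp_ids) stopf("mito donor species '%s' unknown", mito_donor[1])

  contribs <- setNames(c(contribution, 1 - contribution), sp_ids)
  structure(list(sample_id = sample_id, copy_number = copy,
                 contribution = contribs, mito_donor = mito_donor,
                 loh_tracts = loh_tracts, repeat_inserts = repeat_inserts,
                 seed = as.integer(seed), templates = templates,
                 chrom_lengths = lengths),
            class = "hybrid_truth")
}

#' @export
print.hybrid_truth <- function(x, ...) {
  cat(sprintf("<hybrid_truth> %s: contributions %s; %d aneuploid chromosome(s); %d LOH tract(s); mito %s/%s\n",
              x$sample_id,
              paste(sprintf("%s=%.2f", names(x$contribution), x$contribution),
                    collapse = ", "),
              sum(x$copy_number$copies != 1L),
              if (is.null(x$loh_tracts)) 0L else nrow(x$loh_tracts),
              x$mito_donor[1], x$mito_donor[2]))
  invisible(x)
}

#' Simulate a single-end read set from a hybrid truth table
#'
#' Reads are drawn per template with Poisson counts and uniform start
#' positions, so the expected depth of each chromosome is proportional to its
#' copy number weighted by its parent's contribution (total yield is held at
#' `coverage` times the euploid template size). Repeat inserts contribute
#' `copy_count - 1` extra sampled copies of their interval; mitochondrial
#' reads are drawn only from the donor haplotype at `mito_ratio` times the
#' nuclear coverage. Sequencing errors are uniform substitutions. Read
#' identifiers encode the true origin as
#' `sample|species|chromosome|start|serial` (mitochondrial reads use
#' chromosome `mito`).
#'
#' @param truth a `hybrid_truth` from [generate_hybrid()].
#' @param parents the parent pair the truth was built from.
#' @param coverage target fold-coverage of the euploid nuclear template.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param mito_ratio mitochondrial to nuclear depth ratio (organelle
#'   over-representation; default 10).
#' @param seed integer seed.
#' @return a `read_set` (ids, sequences, read length, error rate).
#' @export
simulate_reads <- function(truth, parents, coverage = 20, read_length = 100L,
                           error_rate = 0.001, mito_ratio = 10, seed = 1L) {
  stopifnot(coverage > 0, inherits(truth, "hybrid_truth"))
  if (read_length > min(truth$chrom_lengths))
    stopf("read_length %d exceeds the shortest chromosome (%d bp)",
          read_length, min(truth$chrom_lengths))
  sp_ids <- names(truth$templates)
  cn <- truth$copy_number
  w <- truth$contribution[cn$species]
  L <- truth$chrom_lengths[cn$chromosome]
  Z <- sum(w * cn$copies * L)
  N <- coverage * sum(rep(truth$chrom_lengths, length(sp_ids))) / read_length
  lambda <- N * w * cn$copies * L / Z

  with_seed(seed, {
    ids <- list(); seqs <- list(); serial <- 0L
    draw <- function(seqstr, n_expected, sp, ch, offset = 0L) {
      n <- rpois(1L, n_expected)
      if (n == 0L) return(invisible(NULL))
      starts <- sample.int(nchar(seqstr) - read_length + 1L, n, replace = TRUE) - 1L
      rd <- cpp_extract_reads(seqstr, starts, as.integer(read_length), error_rate)
      i <- length(ids) + 1L
      ids[[i]] <<- sprintf("%s|%s|%s|%d|%d", truth$sample_id, sp, ch,
                           starts + offset, serial + seq_len(n))
      seqs[[i]] <<- rd
      serial <<- serial + n
      invisible(NULL)
    }
    for (i in seq_len(nrow(cn))) {
      if (lambda[i] <= 0 || cn$copies[i] == 0L) next
      draw(truth$templates[[cn$species[i]]][[cn$chromosome[i]]], lambda[i],
           cn$species[i], cn$chromosome[i])
    }
    ri <- truth$repeat_inserts
    if (!is.null(ri) && nrow(ri)) {
      for (i in seq_len(nrow(ri))) {
        if (ri$end[i] - ri$start[i] < read_length)
          stopf("repeat insert shorter than read_length")
        extra <- ri$copy_count[i] - 1L
        if (extra <= 0L) next
        seqstr <- substr(truth$templates[[ri$species[i]]][[ri$chromosome[i]]],
                         ri$start[i] + 1L, ri$end[i])
        lam <- N * truth$contribution[[ri$species[i]]] * extra *
          (ri$end[i] - ri$start[i]) / Z
        draw(seqstr, lam, ri$species[i], ri$chromosome[i], offset = ri$start[i])
      }
    }
    donor_sp <- truth$mito_donor[1]; donor_cl <- truth$mito_donor[2]
    mito_seq <- parents[[match(donor_sp, sp_ids)]]$mito[[donor_cl]]
    if (!is.null(mito_seq) && mito_ratio > 0) {
      lam_m <- mito_ratio * coverage * nchar(mito_seq) / read_length
      draw(mito_seq, lam_m, donor_sp, "mito")
    }
    structure(list(id = unlist(ids) %||% character(0),
                   seq = unlist(seqs) %||% character(0),
                   read_length = as.integer(read_length),
                   error_rate = error_rate, sample_id = truth$sample_id),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s: %d reads of %d bp (error rate %g)\n",
              x$sample_id, length(x$seq), x$read_length, x$error_rate))
  invisible(x)
}

#' Decode true read origins from simulated read identifiers
#'
#' @param x a `read_set` or a character vector of identifiers.
#' @return `data.frame(sample_id, species, chromosome, start)`.
#' @export
parse_read_ids <- function(x) {
  ids <- if (inherits(x, "read_set")) x$id else x
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(sample_id  = vapply(parts, `[[`, character(1), 1L),
             species    = vapply(parts, `[[`, character(1), 2L),
             chromosome = vapply(parts, `[[`, character(1), 3L),
             start      = as.integer(vapply(parts, `[[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' Default study conditions for simulated cohorts
#'
#' Eight nuclear chromosomes spanning 10-32 kb (162 kb per subgenome), a 5 kb
#' mitochondrion, 20x nuclear coverage with 100 bp single-end reads at 0.1%
#' error, and a 10:1 mitochondrial depth ratio. These are the defaults every
#' recovery analysis in the package runs under; see the methods vignette.
#'
#' @return named list of defaults consumed by [generate_cohort()].
#' @export
default_cohort_settings <- function() {
  list(chrom_lengths = c(chr1 = 32000L, chr2 = 28000L, chr3 = 24000L,
                         chr4 = 22000L, chr5 = 18000L, chr6 = 16000L,
                         chr7 = 12000L, chr8 = 10000L),
       mito_length = 5000L, coverage = 20, read_length = 100L,
       error_rate = 0.001, mito_ratio = 10, clade_divergence = 0.02)
}

sample_aneuploidies <- function(chrom_lengths, sp_ids, rate, weighting) {
  if (rate <= 0) return(NULL)
  w <- switch(weighting,
              uniform = rep(1, length(chrom_lengths)),
              inverse_length = 1 / chrom_lengths,
              stopf("unknown aneuploidy weighting '%s'", weighting))
  p <- pmin(rate * w / sum(w), 0.95)
  hit <- which(runif(length(p)) < p)
  if (!length(hit)) return(NULL)
  data.frame(species = sp_ids[sample.int(2L, length(hit), replace = TRUE)],
             chromosome = names(chrom_lengths)[hit],
             delta = sample(c(-1L, 1L), length(hit), replace = TRUE),
             stringsAsFactors = FALSE)
}

sample_loh_tracts <- function(chrom_lengths, sp_ids, n_tracts, tract_length) {
  if (n_tracts <= 0) return(NULL)
  out <- NULL
  for (i in seq_len(n_tracts)) {
    for (attempt in 1:50) {
      ch <- sample(names(chrom_lengths), 1L)
      if (chrom_lengths[[ch]] <= tract_length) next
      s <- sample.int(chrom_lengths[[ch]] - tract_length, 1L) - 1L
      cand <- data.frame(chromosome = ch, start = s, end = s + tract_length,
                         retained_parent = sample(sp_ids, 1L),
                         stringsAsFactors = FALSE)
      clash <- !is.null(out) && any(out$chromosome == ch &
                                    out$start < cand$end & cand$start < out$end)
      if (!clash) { out <- rbind(out, cand); break }
    }
  }
  out
}

#' Generate a full synthetic hybrid cohort
#'
#' Builds one parent pair per cross and simulates its samples (contributions,
#' aneuploidies, LOH tracts, mitochondrial donors drawn per the cross
#' configuration), deterministically for a given seed. When `out_dir` is
#' given, parent FASTA, read FASTQ, truth JSON, LOH/repeat BED and a cohort
#' manifest TSV are written there.
#'
#' @param config list with element `crosses` (a list; each cross a list with
#'   `name`, `divergence`, `n_samples` and optionally `contribution` (scalar
#'   or per-sample vector), `aneuploidy_rate` (expected aneuploid chromosomes
#'   per genome), `aneuploidy_weighting` (`"uniform"` or `"inverse_length"`),
#'   `loh` (`list(n_tracts, tract_length)`), `mito_donor` (`"random"` or a
#'   species id), `n_mito_clades`, `species_ids`) plus optional cohort-wide
#'   overrides of [default_cohort_settings()].
#' @param out_dir optional output directory.
#' @param seed integer master seed.
#' @return list with per-cross parents/samples and the cohort `manifest`.
#' @export
generate_cohort <- function(config, out_dir = NULL, seed = 1L) {
  if (is.null(config$crosses) || !length(config$crosses))
    stopf("config$crosses must list at least one cross")
  defs <- utils::modifyList(default_cohort_settings(),
                            config[setdiff(names(config), "crosses")])
  n_cross <- length(config$crosses)
  cross_seeds <- child_seeds(seed, n_cross)
  crosses <- list(); manifest <- NULL
  for (ci in seq_len(n_cross)) {
    cr <- config$crosses[[ci]]
    stopifnot(!is.null(cr$name), !is.null(cr$divergence), !is.null(cr$n_samples))
    sp_ids <- cr$species_ids %||% c("sp1", "sp2")
    seeds <- child_seeds(cross_seeds[ci], cr$n_samples + 1L)
    parents <- generate_parent_pair(
      defs$chrom_lengths, cr$divergence, species_ids = sp_ids,
      mito_length = defs$mito_length,
      n_mito_clades = cr$n_mito_clades %||% 1L,
      mito_divergence = cr$mito_divergence %||% cr$divergence,
      clade_divergence = defs$clade_divergence, seed = seeds[1L])
    contribs <- rep(cr$contribution %||% 0.5, length.out = cr$n_samples)
    samples <- vector("list", cr$n_samples)
    for (si in seq_len(cr$n_samples)) {
      s_seed <- seeds[si + 1L]
      sid <- sprintf("%s_s%02d", cr$name, si)
      truth <- with_seed(s_seed, {
        an <- sample_aneuploidies(defs$chrom_lengths, sp_ids,
                                  cr$aneuploidy_rate %||% 0,
                                  cr$aneuploidy_weighting %||% "uniform")
        loh <- if (!is.null(cr$loh))
          sample_loh_tracts(defs$chrom_lengths, sp_ids,
                            cr$loh$n_tracts, cr$loh$tract_length)
        donor <- cr$mito_donor %||% "random"
        if (identical(donor, "random")) donor <- sample(sp_ids, 1L)
        dp <- parents[[match(donor, sp_ids)]]
        clade <- sample(names(dp$mito), 1L)
        generate_hybrid(parents, contribution = contribs[si],
                        aneuploidies = an, loh_tracts = loh,
                        mito_donor = c(donor, clade), sample_id = sid,
                        seed = s_seed)
      })
      reads <- simulate_reads(truth, parents, coverage = defs$coverage,
                              read_length = defs$read_length,
                              error_rate = defs$error_rate,
                              mito_ratio = defs$mito_ratio, seed = s_seed)
      samples[[si]] <- list(truth = truth, reads = reads)
      manifest <- rbind(manifest, data.frame(
        sample_id = sid, cross = cr$name,
        contribution_sp1 = contribs[si],
        n_aneuploid = sum(truth$copy_number$copies != 1L),
        n_loh_tracts = if (is.null(truth$loh_tracts)) 0L else nrow(truth$loh_tracts),
        mito_donor = paste(truth$mito_donor, collapse = "/"),
        seed = s_seed, stringsAsFactors = FALSE))
    }
    crosses[[cr$name]] <- list(name = cr$name, parents = parents,
                               divergence = cr$divergence, samples = samples)
  }
  out <- list(crosses = crosses, manifest = manifest, seed = as.integer(seed))
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}
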