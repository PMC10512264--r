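test_that("parent pair generation preserves structure and calibrates divergence", {
  # zero divergence: base-identical genomes
  pp0 <- generate_parent_pair(c(chrA = 5000L, chrB = 3000L), 0, mito_length = 1000L, seed = 1)
  expect_identical(pp0[[1]]$chromosomes, pp0[[2]]$chromosomes)

  # requested chromosome structure is preserved exactly
  pp <- generate_parent_pair(c(50000L, 30000L), 0.10, seed = 2)
  for (p in pp) {
    expect_identical(unname(nchar(p$chromosomes)), c(50000L, 30000L))
    expect_identical(names(p$chromosomes), c("chr1", "chr2"))
    expect_true(all(strsplit(paste(p$chromosomes, collapse = ""), "")[[1]] %in%
                      c("A", "C", "G", "T")))
  }

  # realized mismatch count within the Binomial(L, d) 99.9% interval,
  # counted position-by-position with an independent comparison
  a <- strsplit(paste(pp[[1]]$chromosomes, collapse = ""), "")[[1]]
  b <- strsplit(paste(pp[[2]]$chromosomes, collapse = ""), "")[[1]]
  mm <- sum(a != b)
  half <- 3.29 * sqrt(80000 * 0.10 * 0.90)
  expect_gt(mm, 8000 - half)
  expect_lt(mm, 8000 + half)
  expect_equal(parental_divergence(pp[[1]], pp[[2]]), mm / 80000)

  expect_error(generate_parent_pair(c(5000L), 0.30, seed = 1), "divergence")
})

test_that("mitochondrial haplotypes respect clade structure", {
  pp <- generate_parent_pair(c(chrA = 20000L), 0.10, mito_length = 4000L,
                             n_mito_clades = c(1, 2), seed = 7)
  expect_length(pp[[1]]$mito, 1L)
  expect_length(pp[[2]]$mito, 2L)
  expect_named(pp[[2]]$mito, c("clade1", "clade2"))
  # clades of one species are close; species are far
  d_clade <- mean(charToRaw(pp[[2]]$mito[[1]]) != charToRaw(pp[[2]]$mito[[2]]))
  d_sp <- mean(charToRaw(pp[[1]]$mito[[1]]) != charToRaw(pp[[2]]$mito[[1]]))
  expect_lt(d_clade, 0.05)
  expect_gt(d_sp, 0.05)
})

test_that("hybrid construction tracks copy number, contributions and LOH", {
  pp <- generate_parent_pair(c(chr1 = 6000L, chr2 = 5000L, chr3 = 4000L),
                             0.10, mito_length = 2000L, seed = 3)
  hy <- generate_hybrid(pp, contribution = 0.5, sample_id = "h0")
  expect_true(all(hy$copy_number$copies == 1L))
  expect_equal(unname(hy$contribution), c(0.5, 0.5))
  expect_equal(sum(hy$contribution), 1, tolerance = 1e-12)

  hy2 <- generate_hybrid(pp, aneuploidies = data.frame(
    species = "sp2", chromosome = "chr3", delta = 1L))
  cn <- hy2$copy_number
  expect_equal(cn$copies[cn$species == "sp2" & cn$chromosome == "chr3"], 2L)
  expect_equal(sum(cn$copies), nrow(cn) + 1L)

  # LOH tract: losing parent's template becomes sequence-identical to the
  # retained parent over the tract, verified by substring comparison
  tr <- data.frame(chromosome = "chr2", start = 0L, end = 2000L,
                   retained_parent = "sp1")
  hy3 <- generate_hybrid(pp, loh_tracts = tr)
  expect_identical(substr(hy3$templates$sp2[["chr2"]], 1, 2000),
                   substr(pp[[1]]$chromosomes[["chr2"]], 1, 2000))
  expect_false(identical(substr(hy3$templates$sp2[["chr2"]], 2001, 5000),
                         substr(pp[[1]]$chromosomes[["chr2"]], 2001, 5000)))

  expect_error(generate_hybrid(pp, aneuploidies = data.frame(
    species = "sp1", chromosome = "chr9", delta = 1L)), "absent")
  expect_error(generate_hybrid(pp, loh_tracts = data.frame(
    chromosome = c("chr1", "chr1"), start = c(0L, 500L), end = c(1000L, 1500L),
    retained_parent = "sp1")), "overlap")
  expect_error(generate_hybrid(pp, contribution = 1), "contribution")
})

test_that("read simulation matches analytic coverage and copy-number expectations", {
  pp <- generate_parent_pair(c(chr1 = 30000L, chr2 = 20000L), 0.10,
                             mito_length = 2000L, seed = 4)
  hy <- generate_hybrid(pp, sample_id = "cov")
  # expected read count coverage * L_total / read_length, Poisson 99.9% bounds
  rs <- simulate_reads(hy, pp, coverage = 10, read_length = 100L,
                       error_rate = 0, mito_ratio = 0, seed = 5)
  expect_lt(abs(length(rs$seq) - 10000), 3.29 * sqrt(10000))

  # with error_rate = 0 every read is an exact substring of its template
  org <- parse_read_ids(rs)
  pick <- seq(1, length(rs$seq), by = 97)
  for (i in pick) {
    tmpl <- hy$templates[[org$species[i]]][[org$chromosome[i]]]
    expect_identical(substr(tmpl, org$start[i] + 1, org$start[i] + 100),
                     rs$seq[i])
  }

  expect_error(simulate_reads(hy, pp, coverage = 1, read_length = 30000L),
               "shortest chromosome")
})

test_that("simulated depth is proportional to contribution-weighted copy number", {
  # trisomy on a chromosome small relative to the genome, balanced hybrid:
  # total chr depth / genome-wide mean = 1.5 up to the genome-mean inflation
  # term 1/(1 + w*L_c / Z); checked within the 5% band around 1.5 and within
  # 3% of the exact expectation
  lens <- c(chr1 = 50000L, chr2 = 45000L, chr3 = 40000L, chr4 = 35000L,
            chr5 = 20000L, chr6 = 10000L)
  pp <- generate_parent_pair(lens, 0.10, seed = 11)
  hy <- generate_hybrid(pp, aneuploidies = data.frame(
    species = "sp2", chromosome = "chr6", delta = 1L), sample_id = "tri")
  rs <- simulate_reads(hy, pp, coverage = 50, error_rate = 0, mito_ratio = 0,
                       seed = 12)
  org <- parse_read_ids(rs)
  tab <- make_assignment_table(org$species, org$chromosome, org$start,
                               unit_labels = c("sp1", "sp2"))
  w <- window_depth(tab, chrom_lengths_table(pp))
  s <- chromosome_summary(w)
  ratio <- s$per_chromosome$total_depth[s$per_chromosome$chromosome == "chr6"] /
    s$genome_mean
  Z <- sum(lens) + 0.5 * lens[["chr6"]]
  expect_equal(ratio, 1.5 * sum(lens) / Z, tolerance = 0.03)
  expect_lt(abs(ratio - 1.5), 0.05 * 1.5)

  # euploid chromosomes sit at ratio 1 within 3% at 50x
  others <- s$per_chromosome$total_depth[s$per_chromosome$chromosome != "chr6"] /
    s$genome_mean
  expect_true(all(abs(others - sum(lens) / Z) < 0.03))
})

test_that("repeat inserts inflate local depth and mito reads come from the donor", {
  pp <- generate_parent_pair(c(chr1 = 30000L), 0.10, mito_length = 3000L,
                             n_mito_clades = c(1, 2), seed = 21)
  ri <- data.frame(species = "sp1", chromosome = "chr1", start = 5000L,
                   end = 7000L, copy_count = 20L)
  hy <- generate_hybrid(pp, repeat_inserts = ri,
                        mito_donor = c("sp2", "clade2"), sample_id = "rep")
  rs <- simulate_reads(hy, pp, coverage = 10, error_rate = 0, mito_ratio = 8,
                       seed = 22)
  org <- parse_read_ids(rs)
  in_rep <- org$species == "sp1" & org$start >= 5000 & org$start < 7000
  base <- org$species == "sp1" & org$start >= 10000 & org$start < 12000
  expect_gt(sum(in_rep) / sum(base), 10)  # ~20x locally

  mito <- org[org$chromosome == "mito", ]
  expect_true(all(mito$species == "sp2"))
  # mitochondrial depth ~ mito_ratio * coverage
  expect_equal(nrow(mito) * 100 / 3000, 80, tolerance = 0.15)
  # mito reads match the donor clade, not the other one
  expect_identical(substr(pp[[2]]$mito[["clade2"]], mito$start[1] + 1,
                          mito$start[1] + 100), rs$seq[org$chromosome == "mito"][1])
})

test_that("cohort generation is deterministic and honours the configuration", {
  cfg <- list(chrom_lengths = c(chrA = 12000L, chrB = 11000L),
              coverage = 3, mito_length = 2000L,
              crosses = list(
                list(name = "AxB", divergence = 0.10, n_samples = 3),
                list(name = "CxD", divergence = 0.15, n_samples = 3,
                     aneuploidy_rate = 0)))
  co <- generate_cohort(cfg, seed = 31)
  expect_equal(nrow(co$manifest), 6L)
  expect_equal(sort(unique(co$manifest$cross)), c("AxB", "CxD"))

  # degenerate aneuploidy parameter: all copy numbers 1
  for (s in co$crosses$CxD$samples)
    expect_true(all(s$truth$copy_number$copies == 1L))

  # same seed twice: byte-identical FASTQ output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = d1, seed = 31)
  generate_cohort(cfg, out_dir = d2, seed = 31)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_true(any(grepl("\\.fastq$", f1)))

  expect_error(generate_cohort(list(crosses = list()), seed = 1), "at least one")
})

test_that("sequence and truth files round-trip through standard formats", {
  pp <- generate_parent_pair(c(chrA = 3000L), 0.05, mito_length = 1000L,
                             seed = 41)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(pp[[1]]$chromosomes, f)
  expect_identical(read_fasta(f), pp[[1]]$chromosomes)

  hy <- generate_hybrid(pp, sample_id = "rt")
  rs <- simulate_reads(hy, pp, coverage = 2, seed = 42)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rs, fq)
  back <- read_fastq(fq, sample_id = "rt")
  expect_identical(back$seq, rs$seq)
  expect_identical(back$id, rs$id)

  tj <- withr::local_tempfile(fileext = ".json")
  write_truth_json(hy, tj)
  parsed <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(parsed$sample_id, "rt")
  expect_equal(parsed$contribution$sp1, 0.5)
})
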