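test_that("window depth equals aligned bases over window width", {
  # 10 reads of 100 bp wholly inside one 10-kb window -> mean depth 0.1
  tab <- make_assignment_table(rep("sp1", 10), chromosome = "chrA",
                               position = seq(1000L, 4600L, by = 400L))
  lens <- data.frame(species = c("sp1", "sp2"), chromosome = "chrA",
                     length = 10000L)
  w <- window_depth(tab, lens)
  expect_equal(w$mean_depth[w$species == "sp1"], 0.1)
  # no reads on the sp2 side: zero depth everywhere
  expect_equal(w$mean_depth[w$species == "sp2"], 0)
  expect_error(window_depth(tab, lens, window_size = 500L), "degenerate")
})

test_that("window means equal an independent per-base accumulation", {
  set.seed(31)
  L <- 50000L
  starts <- sample.int(L - 100L, 900L) - 1L
  tab <- make_assignment_table(rep("sp1", length(starts)), "chrA", starts)
  lens <- data.frame(species = "sp1", chromosome = "chrA", length = L)
  w <- window_depth(tab, lens)
  oracle <- brute_force_window_means(starts, 100L, L, 10000L)
  expect_equal(w$mean_depth, oracle, tolerance = 1e-9)

  # bedGraph track input reproduces the same windows
  track <- data.frame(species = "sp1", chromosome = "chrA",
                      start = starts, end = starts + 100L, depth = 1)
  w2 <- window_depth(track, lens)
  expect_equal(w2$mean_depth, oracle, tolerance = 1e-9)
})

test_that("repeat-window masking follows the one-pass 2x rule", {
  mk <- function(depths) {
    n <- length(depths)
    structure(data.frame(species = "sp1", chromosome = "chrA",
                         start = (0:(n - 1)) * 10000L, end = (1:n) * 10000L,
                         width = 10000L, mean_depth = depths, masked = FALSE,
                         stringsAsFactors = FALSE),
              class = c("window_table", "data.frame"))
  }
  # [10,10,10,50,10]: mean 18, threshold 36, only the 50 window masked;
  # recomputed unmasked mean is 10
  w <- mask_repetitive_windows(mk(c(10, 10, 10, 50, 10)))
  expect_identical(w$masked, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(mean(w$mean_depth[!w$masked]), 10)

  # uniform depths: nothing masked
  expect_false(any(mask_repetitive_windows(mk(rep(10, 4)))$masked))

  # exactly 2x the mean is NOT masked (strict inequality):
  # [10,10,10,30] has mean 15, so the 30 window sits exactly at threshold
  expect_false(any(mask_repetitive_windows(mk(c(10, 10, 10, 30)))$masked))

  # zero-mean chromosome: no masking possible
  expect_false(any(mask_repetitive_windows(mk(rep(0, 5)))$masked))

  # iterative variant re-excludes after removing the first outlier
  wi <- mask_repetitive_windows(mk(c(10, 10, 10, 200, 45, 10)), iterative = TRUE)
  wo <- mask_repetitive_windows(mk(c(10, 10, 10, 200, 45, 10)))
  expect_true(wi$masked[5] && !wo$masked[5])
})

test_that("chromosome summary sums homeolog depths and weights by width", {
  mk2 <- function(d1, d2, width = 10000L) {
    n <- length(d1)
    structure(rbind(
      data.frame(species = "sp1", chromosome = "chrA",
                 start = (0:(n - 1)) * width, end = (1:n) * width,
                 width = width, mean_depth = d1, masked = FALSE),
      data.frame(species = "sp2", chromosome = "chrA",
                 start = (0:(n - 1)) * width, end = (1:n) * width,
                 width = width, mean_depth = d2, masked = FALSE)),
      class = c("window_table", "data.frame"))
  }
  s <- chromosome_summary(mk2(rep(6, 4), rep(4, 4)))
  expect_equal(s$per_chromosome$total_depth, 10)
  # single-chromosome genome: genome-wide mean equals the chromosome total
  expect_equal(s$genome_mean, s$per_chromosome$total_depth)

  # all windows of one side masked: chromosome flagged and excluded
  w <- mk2(rep(6, 4), rep(4, 4))
  w$masked[w$species == "sp2"] <- TRUE
  s2 <- chromosome_summary(w)
  expect_true(s2$per_chromosome$excluded)
})

test_that("summary matches brute-force per-base totals on a 3-chromosome toy", {
  set.seed(41)
  lens <- c(chrA = 30000L, chrB = 20000L, chrC = 10000L)
  tabs <- list()
  for (sp in c("sp1", "sp2")) for (ch in names(lens)) {
    n <- rpois(1, lens[[ch]] / 50)
    tabs[[paste(sp, ch)]] <- data.frame(species = sp, chromosome = ch,
                                        position = sample.int(lens[[ch]] - 100L, n,
                                                              replace = TRUE) - 1L)
  }
  df <- do.call(rbind, tabs)
  tab <- make_assignment_table(df$species, df$chromosome, df$position)
  lt <- data.frame(species = rep(c("sp1", "sp2"), each = 3),
                   chromosome = rep(names(lens), 2),
                   length = rep(unname(lens), 2))
  s <- chromosome_summary(window_depth(tab, lt))
  # oracle: per-base accumulation of every (species, chromosome)
  exp_tot <- numeric(0); all_base <- 0; all_len <- 0
  for (ch in names(lens)) {
    tot <- 0
    for (sp in c("sp1", "sp2")) {
      st <- df$position[df$species == sp & df$chromosome == ch]
      depth <- numeric(lens[[ch]])
      for (p in st) {
        hi <- min(p + 100, lens[[ch]])
        depth[(p + 1):hi] <- depth[(p + 1):hi] + 1
      }
      tot <- tot + mean(depth)
      all_base <- all_base + sum(depth); all_len <- all_len + lens[[ch]]
    }
    exp_tot[ch] <- tot
  }
  expect_equal(setNames(s$per_chromosome$total_depth, s$per_chromosome$chromosome),
               exp_tot, tolerance = 1e-9)
  expect_equal(s$genome_mean, 2 * all_base / all_len, tolerance = 1e-9)
})

test_that("aneuploidy calls use strict 30% thresholds on total depth", {
  s <- make_summary(c(c1 = 10.0, c2 = 13.1, c3 = 6.9), genome_mean = 10)
  calls <- call_aneuploidy(s)
  expect_equal(calls$call, c("EUPLOID", "GAIN", "LOSS"))

  # boundary: exactly 13.0 with D_G = 10 stays EUPLOID (strict inequality)
  s2 <- make_summary(c(c1 = 13.0, c2 = 7.0), genome_mean = 10)
  expect_equal(call_aneuploidy(s2)$call, c("EUPLOID", "EUPLOID"))
  expect_error(call_aneuploidy(make_summary(c(c1 = 1), 0)), "must be > 0")
})

test_that("genome metrics reproduce hand-computed variance and delta", {
  s <- make_summary(c(c1 = 8, c2 = 10, c3 = 12), genome_mean = 10)
  rep <- genome_metrics(s, call_aneuploidy(s), sample_id = "toy")
  expect_equal(rep$variance, 4.0)       # sample variance, n-1 denominator
  expect_equal(rep$delta$delta, c(2, 0, 2))
  expect_equal(rep$n_gain + rep$n_loss, 0L)

  # degenerate: all equal
  s0 <- make_summary(c(c1 = 10, c2 = 10, c3 = 10), genome_mean = 10)
  rep0 <- genome_metrics(s0, call_aneuploidy(s0))
  expect_equal(rep0$variance, 0)
  expect_equal(rep0$delta$delta, c(0, 0, 0))

  # mixed gains and losses are flagged (the "both" category)
  s3 <- make_summary(c(c1 = 15, c2 = 6, c3 = 10, c4 = 10), genome_mean = 10)
  rep3 <- genome_metrics(s3, call_aneuploidy(s3))
  expect_equal(c(rep3$n_gain, rep3$n_loss), c(1L, 1L))
  expect_true(rep3$both_gain_and_loss)

  # fewer than 2 chromosomes: variance undefined
  s1 <- make_summary(c(c1 = 10), genome_mean = 10)
  expect_true(is.na(genome_metrics(s1, call_aneuploidy(s1))$variance))
})

test_that("size regressions match hand least-squares", {
  mk_rep <- function(lengths, deltas, id = "g") structure(
    list(sample_id = id,
         delta = data.frame(chromosome = paste0("c", seq_along(lengths)),
                            length = lengths, delta = deltas)),
    class = "aneuploidy_report")
  r <- size_regression(list(mk_rep(c(100, 200, 300), c(3, 2, 1))))
  expect_equal(r$pooled$slope, -0.01)
  expect_equal(r$pooled$r, -1)
  expect_equal(r$per_genome$slope, -0.01)
  expect_equal(r$fraction_negative, 1)

  # degenerate: all deltas zero -> slope 0, r reported as 0 and flagged
  r0 <- size_regression(list(mk_rep(c(100, 200, 300), c(0, 0, 0))))
  expect_equal(r0$pooled$slope, 0)
  expect_equal(r0$pooled$r, 0)
  expect_true(r0$pooled$flagged)
})

test_that("cross heatmap normalizes each chromosome column two-sidedly", {
  mk_rep <- function(deltas, id) structure(
    list(sample_id = id,
         delta = data.frame(chromosome = names(deltas),
                            length = rep(1e4, length(deltas)),
                            delta = unname(deltas))),
    class = "aneuploidy_report")
  # two crosses with means 2 and 6: endpoints 0 and 1
  h <- cross_heatmap(list(mk_rep(c(c1 = 2), "a"), mk_rep(c(c1 = 6), "b")),
                     c("X", "Y"))
  expect_equal(unname(h$normalized[, "c1"]), c(0, 1))

  # identical means: everything at the midpoint
  h2 <- cross_heatmap(list(mk_rep(c(c1 = 3), "a"), mk_rep(c(c1 = 3), "b")),
                      c("X", "Y"))
  expect_equal(unname(h2$normalized[, "c1"]), c(0.5, 0.5))

  # 3-cross toy vs hand-computed piecewise scaling:
  # values 1, 4, 9 -> mean 14/3; below: 0.5*(v-1)/(14/3-1); above: .5+.5*(v-14/3)/(9-14/3)
  h3 <- cross_heatmap(list(mk_rep(c(c1 = 1), "a"), mk_rep(c(c1 = 4), "b"),
                           mk_rep(c(c1 = 9), "c")), c("X", "Y", "Z"))
  m <- 14 / 3
  expect_equal(unname(h3$normalized[, "c1"]),
               c(0, 0.5 * (4 - 1) / (m - 1), 1))
  expect_error(cross_heatmap(list(mk_rep(c(c1 = 1), "a")), "X"), "two crosses")
})

test_that("scale invariance: calls and r unchanged, variance scales squared", {
  set.seed(51)
  depths <- c(c1 = 9.5, c2 = 14, c3 = 6.5, c4 = 10.2)
  s1 <- make_summary(depths, genome_mean = 10)
  s2 <- make_summary(depths * 3, genome_mean = 30)
  c1 <- call_aneuploidy(s1); c2 <- call_aneuploidy(s2)
  expect_identical(c1$call, c2$call)
  r1 <- genome_metrics(s1, c1); r2 <- genome_metrics(s2, c2)
  expect_equal(r2$variance, 9 * r1$variance)
  expect_equal(r1$r, r2$r)
})

test_that("masking protects calling against a planted repeat", {
  lens <- c(chr1 = 40000L, chr2 = 30000L, chr3 = 20000L)
  pp <- generate_parent_pair(lens, 0.10, seed = 61)
  ri <- data.frame(species = "sp1", chromosome = "chr1", start = 2000L,
                   end = 4000L, copy_count = 50L)
  hy <- generate_hybrid(pp, repeat_inserts = ri, sample_id = "rep")
  rs <- simulate_reads(hy, pp, coverage = 15, mito_ratio = 0, seed = 62)
  org <- parse_read_ids(rs)
  tab <- make_assignment_table(org$species, org$chromosome, org$start)
  lt <- chrom_lengths_table(pp)
  with_mask <- karyotype_report(tab, lt, mask = TRUE)
  without <- karyotype_report(tab, lt, mask = FALSE)
  expect_equal(with_mask$calls$call[with_mask$calls$chromosome == "chr1"],
               "EUPLOID")
  expect_equal(without$calls$call[without$calls$chromosome == "chr1"], "GAIN")
})

test_that("contribution balance joins ancestry and karyotype outputs", {
  prof <- structure(list(nuclear_fraction = c(sp1 = 0.7, sp2 = 0.3)),
                    class = "contribution_profile")
  rep <- structure(list(n_gain = 1L, n_loss = 0L, variance = 2.5),
                   class = "aneuploidy_report")
  b <- contribution_balance(prof, rep)
  expect_equal(b$balance, 0.4)
  prof0 <- structure(list(nuclear_fraction = c(sp1 = 0.5, sp2 = 0.5)),
                     class = "contribution_profile")
  expect_equal(contribution_balance(prof0, rep)$balance, 0)
})
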