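# Independent oracles and small constructors shared across tests. These are
# deliberately naive (string manipulation, per-base loops, closed forms) so
# they exercise none of the package's own code paths.

r_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# enumerate canonical k-mers of a sequence by brute force
r_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  rc <- vapply(kmers, r_revcomp, character(1), USE.NAMES = FALSE)
  ifelse(kmers <= rc, kmers, rc)
}

# encode a k-mer string into the package's numeric code (A=0 C=1 G=2 T=3)
encode_kmer <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1
  sum(v * 4^(rev(seq_along(v)) - 1))
}

canonical_code <- function(s) min(encode_kmer(s), encode_kmer(r_revcomp(s)))

# per-base depth accumulation oracle: mean depth per tiling window
brute_force_window_means <- function(starts, read_length, L, window_size) {
  depth <- numeric(L)
  for (s in starts) {
    lo <- max(s, 0) + 1
    hi <- min(s + read_length, L)
    if (hi >= lo) depth[lo:hi] <- depth[lo:hi] + 1
  }
  ws <- seq(0, L - 1, by = window_size)
  we <- pmin(ws + window_size, L)
  vapply(seq_along(ws), function(i) mean(depth[(ws[i] + 1):we[i]]), numeric(1))
}

# textbook Welch t statistic with Welch-Satterthwaite degrees of freedom
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# construct an assignment table without running the assigner
make_assignment_table <- function(species, chromosome = NA_character_,
                                  position = NA_integer_,
                                  unit_labels = c("sp1", "sp2"),
                                  read_length = 100L,
                                  species_of_unit = unit_labels,
                                  clade_of_unit = rep(NA_character_,
                                                      length(unit_labels))) {
  n <- length(species)
  out <- data.frame(read_id = paste0("r", seq_len(n)), species = species,
                    chromosome = rep_len(chromosome, n),
                    position = rep_len(position, n),
                    n_hits = 5L, margin = 5L, stringsAsFactors = FALSE)
  attr(out, "read_length") <- read_length
  attr(out, "unit_labels") <- unit_labels
  attr(out, "species_of_unit") <- species_of_unit
  attr(out, "clade_of_unit") <- clade_of_unit
  class(out) <- c("assignment_table", "data.frame")
  out
}

# construct a kmer_profile from explicit codes
make_profile <- function(kmers, k = 17L, id = "p") {
  structure(list(sample_id = id, k = as.integer(k), min_count = 1L,
                 kmers = sort(as.numeric(kmers)), total = length(kmers),
                 flagged = FALSE), class = "kmer_profile")
}

# construct a chromosome_depth_summary directly from totals
make_summary <- function(totals, genome_mean, lengths = NULL) {
  pc <- data.frame(chromosome = names(totals), length = lengths %||%
                     rep(1e5, length(totals)),
                   total_depth = unname(totals), excluded = FALSE,
                   stringsAsFactors = FALSE)
  structure(list(per_species = NULL, per_chromosome = pc,
                 genome_mean = genome_mean, windows = NULL),
            class = "chromosome_depth_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compact genomes used where the full default cohort would be overkill
small_lengths <- c(chrA = 30000L, chrB = 20000L, chrC = 10000L)
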