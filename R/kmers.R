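#' @title Alignment-free shared-k-mer analysis
#' @name kmer_net
#' @description
#' Exact canonical k-mer profiling (k = 17, occurrence threshold 5 by
#' default, with an n = 2 sensitivity variant), pairwise shared-k-mer counts,
#' an alignment-and-assembly-free distance matrix `D = -(1/k) ln(shared / min(total))` with
#' PHYLIP/NEXUS export for network software, and cross-level statistics
#' (intra/inter distributions, per-cross mean shared k-mers against parental
#' genetic distance).
NULL

#' Canonical k-mer profile of a read set or genome
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) exactly and keeps those observed at least `min_count` times
#' (inclusive threshold).
#'
#' @param x a `read_set`, a `parent_genome`, a `hybrid_truth` (its templates
#'   are profiled), or a character vector of sequences.
#' @param k k-mer size (odd, 11-25; default 17).
#' @param min_count occurrence threshold for inclusion (default 5; use 1 for
#'   assembled genomes, 2 for the sensitivity variant).
#' @param sample_id profile label.
#' @return a `kmer_profile` (sorted canonical k-mer codes and their count).
#' @export
kmer_profile <- function(x, k = 17L, min_count = 5L, sample_id = NULL) {
  k <- check_k(k)
  stopifnot(min_count >= 1L)
  seqs <- if (inherits(x, "read_set")) {
    sample_id <- sample_id %||% x$sample_id
    x$seq
  } else if (inherits(x, "parent_genome")) {
    sample_id <- sample_id %||% x$species_id
    unname(x$chromosomes)
  } else if (inherits(x, "hybrid_truth")) {
    sample_id <- sample_id %||% x$sample_id
    unname(unlist(x$templates))
  } else as.character(x)
  flagged <- !length(seqs) || all(nchar(seqs) < k)
  kmers <- if (flagged) numeric(0)
           else cpp_count_kmers(seqs, k, as.integer(min_count))
  structure(list(sample_id = sample_id %||% "sample", k = k,
                 min_count = as.integer(min_count), kmers = kmers,
                 total = length(kmers), flagged = flagged),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile> %s: %s canonical %d-mers (min_count %d)%s\n",
              x$sample_id, format(x$total, big.mark = ","), x$k,
              x$min_count, if (x$flagged) " [flagged: empty]" else ""))
  invisible(x)
}

#' Number of k-mers shared by two profiles
#'
#' @param a,b `kmer_profile` objects with the same k.
#' @return intersection size.
#' @export
shared_kmers <- function(a, b) {
  if (a$k != b$k) stopf("profiles use different k (%d vs %d)", a$k, b$k)
  cpp_intersect_size(a$kmers, b$kmers)
}

#' Pairwise shared-k-mer counts and alignment-free distances
#'
#' Builds the symmetric shared-count matrix `S` (diagonal = profile size)
#' and the distance matrix `D_ij = -(1/k) ln(S_ij / min(total_i, total_j))`.
#' Zero-overlap pairs get a documented cap (1.1 times the largest finite
#' distance) rather than infinity so matrices stay exportable; capped
#' entries are flagged. Empty profiles give NA rows and are flagged.
#'
#' @param profiles list of `kmer_profile` objects with common k.
#' @return a `shared_matrix`: `samples`, `shared`, `distance`, `capped`
#'   (logical matrix), `flagged_samples`.
#' @export
distance_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  ks <- vapply(profiles, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stopf("profiles mix k-mer sizes")
  k <- ks[1]
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  n <- length(profiles)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    S[i, i] <- profiles[[i]]$total
    for (j in seq_len(n)) if (j > i)
      S[i, j] <- S[j, i] <- shared_kmers(profiles[[i]], profiles[[j]])
  }
  tot <- vapply(profiles, `[[`, integer(1), "total")
  flagged <- tot == 0L
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  capped <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (flagged[i] || flagged[j]) { D[i, j] <- NA_real_; next }
    frac <- S[i, j] / min(tot[i], tot[j])
    D[i, j] <- if (frac > 0) -log(frac) / k else Inf
  }
  if (any(is.infinite(D))) {
    cap <- 1.1 * max(D[is.finite(D)], 0)
    capped[is.infinite(D)] <- TRUE
    D[is.infinite(D)] <- cap
  }
  structure(list(samples = ids, shared = S, distance = D, capped = capped,
                 flagged_samples = ids[flagged], k = k),
            class = "shared_matrix")
}

#' @export
print.shared_matrix <- function(x, ...) {
  cat(sprintf("<shared_matrix> %d samples, k=%d%s\n", length(x$samples), x$k,
              if (any(x$capped)) sprintf(" (%d capped pair(s))", sum(x$capped) / 2)
              else ""))
  invisible(x)
}

sanitize_labels <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

#' Export a distance matrix for network software
#'
#' Writes either a square PHYLIP distance matrix or a NEXUS file with TAXA
#' and DISTANCES blocks (the input to neighbor-net tools). Labels are
#' sanitized (spaces and special characters become underscores); capped
#' entries are noted in a warning comment (NEXUS) or via a message.
#'
#' @param matrix a `shared_matrix` or a square numeric distance matrix with
#'   dimnames.
#' @param path output file.
#' @param format `"phylip"` or `"nexus"`.
#' @return the path, invisibly.
#' @export
export_distances <- function(matrix, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  if (inherits(matrix, "shared_matrix")) {
    D <- matrix$distance
    has_cap <- any(matrix$capped)
  } else { D <- matrix; has_cap <- FALSE }
  if (any(is.na(D))) stopf("distance matrix has undefined entries")
  labs <- sanitize_labels(rownames(D))
  n <- nrow(D)
  if (format == "phylip") {
    if (has_cap) message("note: exported matrix contains capped distances")
    lines <- c(sprintf("%5d", n),
               vapply(seq_len(n), function(i)
                 paste(c(formatC(labs[i], width = -10),
                         sprintf("%.8f", D[i, ])), collapse = "  "),
                 character(1)))
  } else {
    lines <- c("#NEXUS",
               if (has_cap) "[ WARNING: zero-overlap pairs exported at a capped distance ]",
               "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", n),
               paste0("  TAXLABELS ", paste(labs, collapse = " "), ";"),
               "END;",
               "BEGIN DISTANCES;",
               sprintf("  DIMENSIONS NTAX=%d;", n),
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
               "  MATRIX",
               vapply(seq_len(n), function(i)
                 paste(c("   ", labs[i], sprintf("%.8f", D[i, ])),
                       collapse = " "), character(1)),
               "  ;",
               "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back an exported distance matrix
#'
#' @param path file written by [export_distances()].
#' @param format `"phylip"` or `"nexus"`.
#' @return square numeric matrix with dimnames.
#' @export
import_distances <- function(path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "phylip") {
    n <- as.integer(trimws(lines[1]))
    rows <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  } else {
    i0 <- grep("^\\s*MATRIX\\s*$", lines)
    if (!length(i0)) stopf("no DISTANCES MATRIX block in %s", path)
    i1 <- grep("^\\s*;\\s*$", lines)
    i1 <- min(i1[i1 > i0[1]])
    rows <- strsplit(trimws(lines[(i0[1] + 1):(i1 - 1)]), "[[:space:]]+")
    n <- length(rows)
  }
  labs <- vapply(rows, `[[`, character(1), 1L)
  D <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(D) <- list(labs, labs)
  D
}

#' Cross-level shared-k-mer statistics
#'
#' Splits all sample pairs into intra-network (within a cross) and
#' inter-network (across crosses) sets, summarizes intra-pair shared counts
#' per cross (mean, sd), and correlates the per-cross mean shared k-mers
#' with the parental genetic distance of each cross (Pearson). Crosses with
#' a single sample have no intra pairs and are excluded from the correlation.
#'
#' @param matrix a `shared_matrix`.
#' @param cross_labels character vector, one cross label per sample.
#' @param parent_distance named numeric: genetic distance between the two
#'   parents of each cross (e.g. [parental_divergence()] of the simulated
#'   parents).
#' @return list with `per_cross` data.frame, `intra`, `inter`, `total`
#'   shared-count vectors, and `correlation` (`r`, `p`, n).
#' @export
cross_statistics <- function(matrix, cross_labels, parent_distance = NULL) {
  n <- length(matrix$samples)
  stopifnot(length(cross_labels) == n)
  S <- matrix$shared
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  same <- cross_labels[pairs[, 1]] == cross_labels[pairs[, 2]]
  vals <- S[pairs]
  intra_cross <- cross_labels[pairs[, 1]][same]
  per_cross <- do.call(rbind, lapply(unique(cross_labels), function(cr) {
    v <- vals[same][intra_cross == cr]
    data.frame(cross = cr, n_samples = sum(cross_labels == cr),
               n_pairs = length(v),
               mean_shared = if (length(v)) mean(v) else NA_real_,
               sd_shared = if (length(v) > 1) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  correlation <- NULL
  if (!is.null(parent_distance)) {
    ok <- per_cross$n_pairs > 0 & per_cross$cross %in% names(parent_distance)
    x <- parent_distance[per_cross$cross[ok]]
    y <- per_cross$mean_shared[ok]
    correlation <- if (sum(ok) >= 3) {
      ct <- cor.test(x, y)
      list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    } else list(r = if (sum(ok) == 2) unname(cor(x, y)) else NA_real_,
                p = NA_real_, n = sum(ok))
  }
  list(per_cross = per_cross, intra = vals[same], inter = vals[!same],
       total = vals, correlation = correlation)
}
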