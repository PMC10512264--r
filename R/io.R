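# Standard-format IO. Sequence containers go through Biostrings; FASTQ is
# written directly (fixed 'I' qualities) so cohort output is byte-stable.

#' Write named sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a read set to FASTQ
#' @param reads a `read_set`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", reads$read_length)
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con,
             sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ file.
#' @param sample_id label for the read set.
#' @export
read_fastq <- function(path, sample_id = basename(path)) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(list(id = names(x), seq = unname(as.character(x)),
                 read_length = if (length(x)) max(Biostrings::width(x)) else 0L,
                 error_rate = NA_real_, sample_id = sample_id),
            class = "read_set")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based, half-open)
#' @param df data.frame with `chromosome`, `start`, `end` and optionally a
#'   name column (fourth BED column).
#' @param path output file.
#' @param name_col column to use as the BED name field.
#' @export
write_bed <- function(df, path, name_col = NULL) {
  bed <- df[, c("chromosome", "start", "end")]
  if (!is.null(name_col)) bed$name <- df[[name_col]]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph depth track
#'
#' @param path bedGraph file (`chrom start end depth`, 0-based half-open).
#' @param species species label to attach to the track.
#' @return `data.frame(species, chromosome, start, end, depth)`.
#' @export
read_bedgraph <- function(path, species) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chromosome", "start", "end", "depth"))
  data.frame(species = species, x, stringsAsFactors = FALSE)
}

truth_as_list <- function(truth) {
  list(sample_id = truth$sample_id,
       copy_number = truth$copy_number,
       contribution = as.list(truth$contribution),
       mito_donor = list(species = truth$mito_donor[1],
                         clade = truth$mito_donor[2]),
       loh_tracts = truth$loh_tracts,
       repeat_inserts = truth$repeat_inserts,
       seed = truth$seed)
}

#' Write a hybrid truth table as JSON
#' @param truth a `hybrid_truth`.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth_as_list(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

# write all cohort artifacts under out_dir
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$manifest, file.path(out_dir, "manifest.tsv"))
  for (cr in cohort$crosses) {
    cd <- file.path(out_dir, cr$name)
    dir.create(cd, showWarnings = FALSE)
    for (p in cr$parents) {
      write_fasta(p$chromosomes, file.path(cd, paste0(p$species_id, ".fa")))
      write_fasta(p$mito, file.path(cd, paste0(p$species_id, ".mito.fa")))
    }
    for (s in cr$samples) {
      sid <- s$truth$sample_id
      write_fastq(s$reads, file.path(cd, paste0(sid, ".fastq")))
      write_truth_json(s$truth, file.path(cd, paste0(sid, ".truth.json")))
      if (!is.null(s$truth$loh_tracts))
        write_bed(s$truth$loh_tracts, file.path(cd, paste0(sid, ".loh.bed")),
                  name_col = "retained_parent")
      if (!is.null(s$truth$repeat_inserts))
        write_bed(s$truth$repeat_inserts,
                  file.path(cd, paste0(sid, ".repeats.bed")),
                  name_col = "copy_count")
    }
  }
  invisible(out_dir)
}
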