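# Readers/writers for the pipeline's on-disk formats: FASTA and FASTQ via
# Biostrings, GFF3 via rtracklayer (1-based inclusive on disk, 0-based
# half-open in memory), TSV and JSON reports.

#' Convert 0-based half-open features to a GRanges for GFF3 export
#'
#' @param feats data.frame with `feature_id`, `contig_id`, `start`, `end`
#'   (0-based half-open), `strand` and any further metadata columns.
#' @param type GFF3 feature type.
#' @return A `GRanges` (1-based inclusive) carrying the metadata columns.
#' @export
features_to_granges <- function(feats, type = "open_reading_frame") {
  gr <- GenomicRanges::GRanges(
    seqnames = feats$contig_id,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand
  )
  meta <- feats[, setdiff(names(feats), c("contig_id", "start", "end",
                                          "strand")), drop = FALSE]
  S4Vectors::mcols(gr) <- cbind(S4Vectors::DataFrame(type = type), meta)
  names(gr) <- feats$feature_id %||% feats$orf_id
  gr
}

#' Write a fixture bundle to disk
#'
#' Writes `contigs.fa`, `truth.gff3`, `truth_table.tsv` and `params.json`
#' into `dir`.
#'
#' @param bundle An `ig_fixture`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("contigs.fa", "truth.gff3", "truth_table.tsv",
                            "params.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$contigs), paths[1])
  gr <- features_to_granges(bundle$orfs)
  rtracklayer::export(gr, paths[2], format = "gff3")
  utils::write.table(bundle$truth_table, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$params[setdiff(names(bundle$params),
                                             "gene_spec")],
                       paths[4], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Write simulated reads as FASTQ (constant Q30 placeholder qualities)
#'
#' @param reads data.frame with `read_id` and `seq`.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$seq), function(n) strrep("?", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into the package's plain read table
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id`, `seq`.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
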