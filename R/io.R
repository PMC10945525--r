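# Plain-text interchange: pairs tables, dense matrix TSV, bedGraph, BED,
# FASTA (via Biostrings).

#' Read a mapped read-pair table
#'
#' Accepts the native 5-column format (header: readID pos1 strand1 pos2
#' strand2, single chromosome) or a 4DN .pairs-style file (comment lines
#' starting with `#`; columns readID chrom1 pos1 chrom2 pos2 strand1
#' strand2), from which the single chromosome's pairs are taken.
#'
#' @param path File path.
#' @return data.frame with `readID`, `pos1`, `strand1`, `pos2`, `strand2`
#'   (positions 0-based bp).
#' @export
read_pairs <- function(path) {
  first <- readLines(path, n = 200L)
  body_start <- which(!startsWith(first, "#"))[1]
  header <- first[body_start]
  if (grepl("readID\tpos1", header)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    df[, c("readID", "pos1", "strand1", "pos2", "strand2")]
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    names(df)[1:7] <- c("readID", "chrom1", "pos1", "chrom2", "pos2",
                        "strand1", "strand2")
    if (length(unique(c(df$chrom1, df$chrom2))) > 1L)
      stop("multi-chromosome pairs are not supported")
    df[, c("readID", "pos1", "strand1", "pos2", "strand2")]
  }
}

#' Write a read-pair table
#' @param pairs data.frame with `readID`, `pos1`, `strand1`, `pos2`,
#'   `strand2`.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("readID", "pos1", "strand1", "pos2",
                               "strand2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a dense contact matrix as TSV
#'
#' The matrix is written bin-by-bin with a small `#key value` header
#' carrying bin size, chromosome length, circularity, state and masked
#' bins, so a map round-trips losslessly.
#'
#' @param cm A [contact_map()].
#' @param path Output path.
#' @export
write_matrix_tsv <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bin_size %d", cm$bin_size), con)
  writeLines(sprintf("#chrom_length %d", cm$chrom_length), con)
  writeLines(sprintf("#circular %s", cm$circular), con)
  writeLines(sprintf("#state %s", cm$state), con)
  writeLines(paste0("#masked_bins ",
                    paste(cm$masked_bins, collapse = ",")), con)
  utils::write.table(cm$matrix, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv`: the reconstructed `ContactMap`.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("#", key, " ?"), "",
                           hdr[startsWith(hdr, paste0("#", key))][1])
  m <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")],
                                   sep = "\t"))
  dimnames(m) <- NULL
  masked <- get("masked_bins")
  masked <- if (is.na(masked) || masked == "") integer(0)
  else as.integer(strsplit(masked, ",")[[1]])
  contact_map(m, as.integer(get("bin_size")),
              as.integer(get("chrom_length")),
              as.logical(get("circular")), masked_bins = masked,
              state = get("state"))
}

#' Write a per-interval signal as bedGraph
#'
#' @param df data.frame with 0-based half-open `start`, `end`, `value`.
#' @param path Output path.
#' @param chrom Chromosome name (default "chr").
#' @export
write_bedgraph <- function(df, path, chrom = "chr") {
  out <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    value = df$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write intervals as BED
#'
#' @param df data.frame with 0-based half-open `start`, `end`; optional
#'   `name` and `score` columns are carried into BED columns 4-5.
#' @param path Output path.
#' @param chrom Chromosome name (default "chr").
#' @export
write_bed <- function(df, path, chrom = "chr") {
  out <- data.frame(chrom = chrom, start = df$start, end = df$end)
  out$name <- if ("name" %in% names(df)) df$name
  else sprintf("feature_%d", seq_len(nrow(df)))
  if ("score" %in% names(df)) out$score <- df$score
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- Biostrings::DNAStringSet(unname(unlist(seqs)))
    names(seqs) <- nm
  }
  Biostrings::writeXStringSet(seqs, path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
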