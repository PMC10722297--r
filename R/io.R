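# File-format boundary. Everything internal is 0-based half-open; SAM
# (1-based) and the GRanges converters shift at this boundary only.

#' Read a bedGraph depth track
#'
#' @param path bedGraph file (chrom, start, end, depth; 0-based half-open).
#' @param layout [genome_layout()] supplying chromosome lengths.
#' @return Per-chromosome depth `RleList`.
#' @export
read_bedgraph_depth <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  gr <- rtracklayer::import(path, format = "bedGraph")
  bad <- !as.character(GenomicRanges::seqnames(gr)) %in% layout$chromosome
  if (any(bad))
    stop("bedGraph chromosome absent from layout: ",
         paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
               collapse = ", "))
  sl <- stats::setNames(layout$length, layout$chromosome)
  GenomeInfoDb::seqlevels(gr) <- layout$chromosome
  GenomeInfoDb::seqlengths(gr) <- sl
  GenomicRanges::coverage(gr, weight = "score")
}

#' Write a per-chromosome depth track as bedGraph
#'
#' @param depth depth `RleList`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph_depth <- function(depth, path) {
  gr <- methods::as(depth, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read/write windowed tracks and evidence tables as TSV
#'
#' Plain tab-separated serialisation of the per-window data frames used
#' throughout the pipeline (deterministic row order, no quoting).
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `write_track_tsv()` returns `path` invisibly; `read_track_tsv()`
#'   returns a data frame.
#' @export
write_track_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write intervals as BED
#'
#' @param x data frame with columns `chromosome`, `start`, `end` (0-based
#'   half-open) and optionally `name` and `score`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  bed <- data.frame(x$chromosome, format(x$start, scientific = FALSE,
                                         trim = TRUE),
                    format(x$end, scientific = FALSE, trim = TRUE),
                    name, score, strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (length(readLines(path, n = 1)) == 0L)
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chromosome = as.character(bed[[1]]),
                    start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4) out$name <- as.character(bed[[4]])
  out
}

#' Read and write FASTA as named character vectors
#'
#' Sequences move through the simulator and mapper as plain character
#' strings; Biostrings does the file handling.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Write paired reads as FASTQ
#'
#' @param reads1,reads2 character vectors of mate sequences.
#' @param path1,path2 output files for mate 1 and mate 2.
#' @param ids fragment identifiers (default `frag1 .. fragN`).
#' @export
write_fastq_pairs <- function(reads1, reads2, path1, path2, ids = NULL) {
  if (length(reads1) != length(reads2)) stop("mate vectors differ in length")
  if (is.null(ids)) ids <- paste0("frag", seq_along(reads1))
  wr <- function(reads, mate, path) {
    qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    writeLines(as.vector(rbind(paste0("@", ids, "/", mate),
                               reads, "+", qual)), path)
  }
  wr(reads1, 1, path1)
  wr(reads2, 2, path2)
  invisible(c(path1, path2))
}

#' @rdname write_fastq_pairs
#' @param path FASTQ file to read.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: record ", length(lines) %/% 4L + 1L,
         " is incomplete")
  }
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  stats::setNames(lines[seq(2, length(lines), by = 4)], ids)
}

# aligned reference span of a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    lens <- as.numeric(gsub("[A-Z=]", "",
                            regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]",
                                                    cg))[[1]]))
    typ <- gsub("[0-9]+", "",
                regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]])
    sum(lens[typ %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read alignment records from a SAM file
#'
#' Parses the handful of fields the pipeline uses (query name, flag,
#' reference, position, CIGAR) and converts the 1-based SAM position to the
#' internal 0-based half-open convention.  Unmapped records (flag 0x4 or
#' reference `*`) are dropped.
#'
#' @param path SAM file.
#' @return Data frame with columns `fragment_id`, `mate`, `flag`,
#'   `chromosome`, `start`, `end`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(fragment_id = character(), mate = integer(),
                      flag = integer(), chromosome = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short) > 0L)
    stop("malformed SAM record at line ", short[1])
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  df <- data.frame(fragment_id = get(1),
                   mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
                   flag = flag,
                   chromosome = get(3),
                   start = as.numeric(get(4)) - 1,
                   stringsAsFactors = FALSE)
  df$end <- df$start + cigar_ref_span(get(6))
  keep <- bitwAnd(flag, 4L) == 0L & df$chromosome != "*"
  df[keep, , drop = FALSE]
}
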