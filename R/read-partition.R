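#' SAM flag filter: properly paired primary alignments
#'
#' Keeps records that are mapped in a proper pair (`samtools view -f 3`) and
#' are neither secondary nor supplementary (`-F 2304`; 2304 = 256 + 2048).
#'
#' @param flag integer vector of SAM flags.
#' @return Logical vector, `TRUE` where `(flag & 3) == 3 && (flag & 2304) == 0`.
#' @examples
#' passes_filter(c(99, 355, 2147))  # TRUE FALSE FALSE
#' @export
passes_filter <- function(flag) {
  flag <- as.integer(flag)
  if (any(is.na(flag)) || any(flag < 0L)) stop("flags must be non-negative")
  bitwAnd(flag, 3L) == 3L & bitwAnd(flag, 2304L) == 0L
}

#' Exact-match mapping of error-free read pairs
#'
#' Minimal built-in mapper for synthetic, error-free reads: a read maps at
#' every position where the full read matches the reference exactly (k-mer
#' seed on the first `k` bases, then full-length verification), on either
#' strand.  Flags follow SAM semantics; a pair is proper when both mates map
#' to the same chromosome in converging orientation within `max_insert`.
#' Among equally valid pair placements (e.g. the two identical copies left
#' by a duplication-deletion exchange) the primary is drawn uniformly at
#' random through R's RNG -- as short-read aligners do -- so coverage is not
#' biased towards one copy; call `set.seed()` first for reproducibility.
#' Remaining matches are emitted as secondary (flag 0x100).  Real data
#' should enter via [read_sam()] from an external aligner instead.
#'
#' @param reads1,reads2 character vectors of mate-1 / mate-2 sequences.
#' @param genome named character vector of chromosome sequences.
#' @param k seed length (must not exceed the read length).
#' @param max_insert maximum outer distance of a proper pair (bp).
#' @param max_hits cap on recorded matches per read and orientation.
#' @return Data frame with columns `fragment_id` (integer index into the
#'   input pairs), `mate`, `flag`, `chromosome`, `start`, `end` (0-based
#'   half-open reference span).  Unmapped mates yield no row.
#' @export
exact_map <- function(reads1, reads2, genome, k = 31, max_insert = 2000,
                      max_hits = 16) {
  if (length(reads1) != length(reads2))
    stop("mate vectors differ in length")
  if (length(reads1) == 0L)
    return(data.frame(fragment_id = integer(), mate = integer(),
                      flag = integer(), chromosome = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  if (min(nchar(reads1), nchar(reads2)) < k)
    stop("k larger than read length")
  res <- cpp_exact_map_pairs(unname(genome), reads1, reads2,
                             as.integer(k), as.integer(max_insert),
                             as.integer(max_hits))
  data.frame(fragment_id = res$fragment, mate = res$mate, flag = res$flag,
             chromosome = names(genome)[res$chrom],
             start = as.numeric(res$start), end = as.numeric(res$end),
             stringsAsFactors = FALSE)
}

# fragments whose two mates both have filter-passing alignments to a genome
matched_fragments <- function(alignments) {
  ok <- passes_filter(alignments$flag)
  a <- alignments[ok, , drop = FALSE]
  intersect(unique(a$fragment_id[a$mate == 1L]),
            unique(a$fragment_id[a$mate == 2L]))
}

#' Partition read fragments into four origin classes
#'
#' A fragment "matches" a genome when both mates have filter-passing
#' ([passes_filter()]) alignments to it.  The 2x2 match table against the
#' two ancestral genomes gives an exhaustive, exclusive partition:
#' `UNIQUE_A`, `UNIQUE_F`, `BOTH`, `NEITHER`.
#'
#' @param alignments_a,alignments_f alignment data frames (from
#'   [exact_map()] or [read_sam()]) of the same fragments against ancestor A
#'   and ancestor F.
#' @param fragments vector of all fragment ids in the sequenced set; needed
#'   so fragments absent from both alignment sets are counted as `NEITHER`.
#'   Defaults to the union of ids seen in either alignment set.
#' @return Data frame `fragment_id`, `class` (factor with the four levels).
#' @export
classify_fragments <- function(alignments_a, alignments_f, fragments = NULL) {
  if (is.null(fragments))
    fragments <- union(unique(alignments_a$fragment_id),
                       unique(alignments_f$fragment_id))
  in_a <- fragments %in% matched_fragments(alignments_a)
  in_f <- fragments %in% matched_fragments(alignments_f)
  cls <- ifelse(in_a & in_f, "BOTH",
         ifelse(in_a, "UNIQUE_A",
         ifelse(in_f, "UNIQUE_F", "NEITHER")))
  data.frame(fragment_id = fragments,
             class = factor(cls, levels = c("UNIQUE_A", "UNIQUE_F",
                                            "BOTH", "NEITHER")),
             stringsAsFactors = FALSE)
}

# reference intervals of primary, filter-passing records
alignment_intervals <- function(alignments) {
  keep <- passes_filter(alignments$flag)
  alignments[keep, c("chromosome", "start", "end"), drop = FALSE]
}

#' Genomic HE evidence from re-mapped class-specific reads
#'
#' After the ancestor-unique read sets are re-mapped onto the hybrid, each
#' 100-kb window on a subgenome-a chromosome gets `cov_intra` = fraction of
#' bases covered by UNIQUE_A reads and `cov_inter` = fraction covered by
#' UNIQUE_F reads (mirror image on subgenome f).  A window is flagged when
#' the intraspecific coverage is strictly less than the interspecific one;
#' windows with no coverage from either class carry `no_data`.
#'
#' @param alignments_unique_a,alignments_unique_f re-mapped alignments (to
#'   the hybrid) of the UNIQUE_A and UNIQUE_F read sets.
#' @param hybrid_layout hybrid [genome_layout()] with subgenome labels.
#' @param window_size window width in bp (default 100000).
#' @param depth_threshold minimum depth for a covered base (default 1).
#' @return Data frame (class `genomic_evidence`): the window grid plus
#'   `cov_intra`, `cov_inter`, `flag_genomic`, `no_data`.
#' @export
genomic_evidence <- function(alignments_unique_a, alignments_unique_f,
                             hybrid_layout, window_size = 100000,
                             depth_threshold = 1) {
  stopifnot(inherits(hybrid_layout, "genome_layout"))
  if (any(hybrid_layout$subgenome == "none"))
    stop("hybrid layout has unlabelled subgenomes")
  grid <- make_windows(hybrid_layout, window_size)
  frac_a <- fraction_covered(
    depth_from_intervals(alignment_intervals(alignments_unique_a),
                         hybrid_layout), grid, depth_threshold)$fraction
  frac_f <- fraction_covered(
    depth_from_intervals(alignment_intervals(alignments_unique_f),
                         hybrid_layout), grid, depth_threshold)$fraction
  on_a <- grid$subgenome == "a"
  out <- grid
  out$cov_intra <- ifelse(on_a, frac_a, frac_f)
  out$cov_inter <- ifelse(on_a, frac_f, frac_a)
  out$no_data <- out$cov_intra == 0 & out$cov_inter == 0
  out$flag_genomic <- out$cov_intra < out$cov_inter
  class(out) <- c("genomic_evidence", class(grid))
  out
}
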