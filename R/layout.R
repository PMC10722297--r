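#' Genome layout: chromosome lengths with subgenome labels
#'
#' A `genome_layout` is the coordinate backbone of every windowed analysis:
#' an ordered table of chromosomes with their lengths (bp) and, for a hybrid
#' genome, the subgenome each chromosome belongs to (`"a"` for the
#' sweet-cherry-derived subgenome, `"f"` for the ground-cherry-derived one;
#' `"none"` for ancestral, non-hybrid genomes).
#'
#' @param chromosome character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (all > 0).
#' @param subgenome subgenome label per chromosome: `"a"`, `"f"` or `"none"`
#'   (default `"none"` for all).
#' @param genome_id identifier stored as an attribute.
#' @return A data frame of class `genome_layout` with columns `chromosome`,
#'   `length`, `subgenome`.
#' @examples
#' genome_layout(c("chr1_a", "chr1_f"), c(5e6, 5e6), c("a", "f"), "hybrid")
#' @export
genome_layout <- function(chromosome, length, subgenome = "none",
                          genome_id = "genome") {
  chromosome <- as.character(chromosome)
  length <- as.numeric(length)
  subgenome <- rep_len(as.character(subgenome), base::length(chromosome))
  if (base::length(chromosome) == 0L)
    stop("layout must contain at least one chromosome")
  if (anyDuplicated(chromosome))
    stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  if (!all(subgenome %in% c("a", "f", "none")))
    stop("subgenome labels must be 'a', 'f' or 'none'")
  out <- data.frame(chromosome = chromosome, length = length,
                    subgenome = subgenome, stringsAsFactors = FALSE)
  attr(out, "genome_id") <- genome_id
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a genome layout from FASTA or TSV
#'
#' `layout_from_fasta()` takes chromosome lengths from the sequences;
#' `layout_from_tsv()` expects columns `chromosome`, `length` and an optional
#' `subgenome` column.
#'
#' @param path path to the input file.
#' @param subgenome optional named vector mapping chromosome name to
#'   subgenome label (FASTA reader only).
#' @param genome_id identifier for the layout.
#' @return A [genome_layout()].
#' @export
layout_from_fasta <- function(path, subgenome = NULL, genome_id = "genome") {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  lab <- if (is.null(subgenome)) "none" else unname(subgenome[nm])
  genome_layout(nm, Biostrings::width(seqs), lab, genome_id)
}

#' @rdname layout_from_fasta
#' @export
layout_from_tsv <- function(path, genome_id = "genome") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chromosome", "length") %in% names(tab)))
    stop("layout TSV needs 'chromosome' and 'length' columns")
  lab <- if ("subgenome" %in% names(tab)) tab$subgenome else "none"
  genome_layout(tab$chromosome, tab$length, lab, genome_id)
}

#' Tile a genome layout with fixed-width windows
#'
#' Windows are 0-based half-open and tile each chromosome exactly: every
#' window has width `window_size` except possibly the last window of a
#' chromosome, which is truncated at the chromosome end (and kept).  The
#' window index is `floor(start / window_size)`.
#'
#' @param layout a [genome_layout()].
#' @param window_size window width in bp (e.g. 100000, 250000, 1000000).
#' @return A data frame of class `window_grid` with columns `chromosome`,
#'   `subgenome`, `index`, `start`, `end`; the layout and window size are
#'   carried as attributes.
#' @examples
#' lay <- genome_layout("chr1", 1050000, "a")
#' make_windows(lay, 250000)   # 5 windows, last one 50 kb
#' @export
make_windows <- function(layout, window_size) {
  stopifnot(inherits(layout, "genome_layout"))
  window_size <- as.numeric(window_size)
  if (length(window_size) != 1L || !is.finite(window_size) || window_size <= 0)
    stop("window_size must be a single positive number")
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chromosome = layout$chromosome[i],
               subgenome = layout$subgenome[i],
               index = as.integer(starts %/% window_size),
               start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "layout") <- layout
  attr(out, "window_size") <- window_size
  class(out) <- c("window_grid", "data.frame")
  out
}

grid_layout <- function(grid) attr(grid, "layout")
grid_window_size <- function(grid) attr(grid, "window_size")

#' Per-base depth from aligned intervals
#'
#' Piles up 0-based half-open intervals into a per-base depth track,
#' `depth(x)` = number of intervals containing `x`.
#'
#' @param intervals data frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open).
#' @param layout a [genome_layout()] giving chromosome lengths; intervals
#'   must fall within bounds.
#' @return A named [IRanges::RleList] with one integer run-length vector per
#'   chromosome of the layout.
#' @export
depth_from_intervals <- function(intervals, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(intervals) > 0) {
    len <- layout$length[match(intervals$chromosome, layout$chromosome)]
    if (anyNA(len))
      stop("interval on a chromosome absent from the layout")
    if (any(intervals$start < 0) || any(intervals$end > len) ||
        any(intervals$start >= intervals$end))
      stop("interval outside chromosome bounds")
  }
  rl <- lapply(seq_len(nrow(layout)), function(i) {
    chr <- layout$chromosome[i]
    sel <- intervals$chromosome == chr
    ir <- IRanges::IRanges(start = intervals$start[sel] + 1,
                           end = intervals$end[sel])
    IRanges::coverage(ir, width = layout$length[i])
  })
  names(rl) <- layout$chromosome
  methods::as(rl, "RleList")
}

#' Fraction of bases covered per window
#'
#' For every window of the grid, the fraction of bases whose depth is at
#' least `depth_threshold` (default 1, i.e. "percentage of covered bases at a
#' depth of 1").  Trailing partial windows are normalised by their true
#' width.
#'
#' @param depth a per-chromosome depth `RleList` as returned by
#'   [depth_from_intervals()] or [read_bedgraph_depth()].
#' @param grid a [make_windows()] grid on the same layout.
#' @param depth_threshold minimum depth for a base to count as covered.
#' @return The `grid` data frame with an added `fraction` column in [0, 1];
#'   class `coverage_track`.
#' @export
fraction_covered <- function(depth, grid, depth_threshold = 1) {
  stopifnot(inherits(grid, "window_grid"))
  if (depth_threshold < 1) stop("depth_threshold must be >= 1")
  lay <- grid_layout(grid)
  frac <- numeric(nrow(grid))
  for (chr in unique(grid$chromosome)) {
    if (!chr %in% names(depth))
      stop("no depth track for chromosome ", chr)
    d <- depth[[chr]]
    len <- lay$length[lay$chromosome == chr]
    if (length(d) != len)
      stop("depth track length mismatch for chromosome ", chr)
    sel <- which(grid$chromosome == chr)
    covered <- d >= depth_threshold
    S4Vectors::runValue(covered) <- as.integer(S4Vectors::runValue(covered))
    v <- IRanges::Views(covered,
                        start = grid$start[sel] + 1, end = grid$end[sel])
    frac[sel] <- IRanges::viewSums(v) / (grid$end[sel] - grid$start[sel])
  }
  out <- grid
  out$fraction <- frac
  class(out) <- c("coverage_track", class(grid))
  out
}

#' Pooled coverage across datasets of one species
#'
#' A base counts as covered if it is covered (depth >= `depth_threshold`) in
#' at least one of the datasets: the union of aligned bases, not an average
#' of fractions.
#'
#' @param depths list of per-chromosome depth `RleList`s, one per dataset.
#' @param grid window grid shared by all datasets.
#' @param depth_threshold per-dataset coverage threshold.
#' @return A `coverage_track` (see [fraction_covered()]).
#' @export
pooled_coverage <- function(depths, grid, depth_threshold = 1) {
  stopifnot(length(depths) >= 1L)
  pooled <- lapply(names(depths[[1]]), function(chr) {
    hit <- depths[[1]][[chr]] >= depth_threshold
    for (d in depths[-1]) {
      if (!chr %in% names(d) || length(d[[chr]]) != length(hit))
        stop("pooled datasets must share one grid/layout")
      hit <- hit | (d[[chr]] >= depth_threshold)
    }
    methods::as(hit, "Rle")
  })
  names(pooled) <- names(depths[[1]])
  fraction_covered(methods::as(pooled, "RleList"), grid, depth_threshold = 1)
}
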