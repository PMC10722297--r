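#' Harmonize the 100-kb genomic track onto the 250-kb grid
#'
#' The genomic evidence is computed on 100-kb windows while the RNA and
#' protein tracks live on 250-kb windows.  A 250-kb window inherits
#' `flag_genomic = TRUE` when at least one overlapping 100-kb window is
#' flagged (`policy = "any"`, default) or when every overlapping 100-kb
#' window is flagged (`policy = "all"`).  It is `no_data` only if all
#' overlapping 100-kb windows are.
#'
#' @param genomic a `genomic_evidence` data frame (100-kb windows).
#' @param grid target [make_windows()] grid (typically 250 kb) on the same
#'   layout.
#' @param policy `"any"` or `"all"`.
#' @return `grid` with added `flag_genomic` and `no_data_genomic` columns.
#' @export
harmonize_genomic <- function(genomic, grid, policy = c("any", "all")) {
  policy <- match.arg(policy)
  lay1 <- grid_layout(genomic)
  lay2 <- grid_layout(grid)
  if (!identical(lay1$chromosome, lay2$chromosome) ||
      !identical(lay1$length, lay2$length))
    stop("genomic track and target grid are on different layouts")
  gr_src <- GenomicRanges::GRanges(genomic$chromosome,
                                   IRanges::IRanges(genomic$start + 1,
                                                    genomic$end))
  gr_dst <- GenomicRanges::GRanges(grid$chromosome,
                                   IRanges::IRanges(grid$start + 1,
                                                    grid$end))
  ov <- GenomicRanges::findOverlaps(gr_dst, gr_src)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  out <- grid
  out$flag_genomic <- FALSE
  out$no_data_genomic <- TRUE
  agg_flag <- tapply(genomic$flag_genomic[sh], qh,
                     if (policy == "any") any else all)
  agg_nd <- tapply(genomic$no_data[sh], qh, all)
  idx <- as.integer(names(agg_flag))
  out$flag_genomic[idx] <- as.logical(agg_flag)
  out$no_data_genomic[idx] <- as.logical(agg_nd)
  out
}

#' Assemble the three evidence tracks into one per-window matrix
#'
#' @param genomic `genomic_evidence` (100-kb windows; harmonized internally).
#' @param rna `rna_evidence` (250-kb windows).
#' @param iaa `iaa_evidence` (same 250-kb grid as `rna`).
#' @param confirm optional `q70_confirmation` (1-Mb windows); each 250-kb
#'   window inherits the confirmation flag of the 1-Mb window containing its
#'   start.
#' @param policy harmonization policy, see [harmonize_genomic()].
#' @return Data frame (class `evidence_matrix`) on the 250-kb grid with the
#'   three boolean flags, per-track no-data markers and `confirm_q70`.
#' @export
evidence_matrix <- function(genomic, rna, iaa, confirm = NULL,
                            policy = c("any", "all")) {
  if (!identical(rna$chromosome, iaa$chromosome) ||
      !identical(rna$start, iaa$start))
    stop("RNA and protein tracks must share one window grid")
  target <- make_windows(grid_layout(rna), grid_window_size(rna))
  if (!identical(target$start, rna$start))
    stop("RNA track does not tile its own layout")
  out <- harmonize_genomic(genomic, target, policy)
  out$flag_rna <- rna$flag_rna
  out$no_data_rna <- rna$no_data
  out$flag_iaa <- iaa$flag_iaa
  out$no_data_iaa <- iaa$no_data
  if (is.null(confirm)) {
    out$confirm_q70 <- NA
  } else {
    cw <- grid_window_size(confirm)
    key <- paste(out$chromosome, out$start %/% cw)
    ckey <- paste(confirm$chromosome, confirm$index)
    out$confirm_q70 <- confirm$confirm_q70[match(key, ckey)]
  }
  class(out) <- c("evidence_matrix", "window_grid", "data.frame")
  out
}

#' Call homoeologous exchange regions
#'
#' A window qualifies when all three evidence flags hold
#' (`flag_genomic & flag_rna & flag_iaa`); maximal runs of adjacent
#' qualifying windows on one chromosome merge into one directed region
#' (the segment of the carrier subgenome replaced by homoeologous sequence
#' from the other subgenome).  The 70% quantile confirmation is annotated
#' per region, never used as a fourth criterion.
#'
#' @param evidence an [evidence_matrix()].
#' @return An object of class `he_calls`: a list with `regions` (one row
#'   per merged region: `chromosome`, `subgenome`, `start`, `end`,
#'   `n_windows`, `direction`, `n_confirmed`), `windows` (the evidence
#'   matrix with the added `qualifying` column), and `n_qualifying`.
#' @export
call_he <- function(evidence) {
  if (!inherits(evidence, "evidence_matrix") || nrow(evidence) == 0L)
    stop("empty or invalid evidence matrix")
  ev <- evidence
  ev$qualifying <- ev$flag_genomic & ev$flag_rna & ev$flag_iaa
  regions <- list()
  for (chr in unique(ev$chromosome)) {
    w <- ev[ev$chromosome == chr, , drop = FALSE]
    w <- w[order(w$index), , drop = FALSE]
    q <- which(w$qualifying)
    if (length(q) == 0L) next
    run_id <- cumsum(c(1L, diff(w$index[q]) != 1L))
    for (r in split(q, run_id)) {
      conf <- w$confirm_q70[r]
      regions[[length(regions) + 1L]] <- data.frame(
        chromosome = chr,
        subgenome = w$subgenome[r[1]],
        start = w$start[r[1]],
        end = w$end[r[length(r)]],
        n_windows = length(r),
        direction = "replaced_by_other_subgenome",
        n_confirmed = sum(conf %in% TRUE),
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chromosome = character(), subgenome = character(),
               start = numeric(), end = numeric(), n_windows = integer(),
               direction = character(), n_confirmed = integer(),
               stringsAsFactors = FALSE)
  lay <- grid_layout(evidence)
  regions <- regions[order(match(regions$chromosome, lay$chromosome),
                           regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, windows = ev,
                 n_qualifying = sum(ev$qualifying)),
            class = "he_calls")
}

#' @export
print.he_calls <- function(x, ...) {
  cat("Homoeologous exchange calls\n")
  cat(sprintf("  qualifying 250-kb windows: %d (a: %d, f: %d)\n",
              x$n_qualifying,
              sum(x$windows$qualifying & x$windows$subgenome == "a"),
              sum(x$windows$qualifying & x$windows$subgenome == "f")))
  cat(sprintf("  merged regions: %d (a: %d, f: %d)\n",
              nrow(x$regions), sum(x$regions$subgenome == "a"),
              sum(x$regions$subgenome == "f")))
  if (nrow(x$regions) > 0) {
    cat(sprintf("  total exchanged sequence: %.2f Mb\n",
                sum(x$regions$end - x$regions$start) / 1e6))
  }
  invisible(x)
}

#' @export
summary.he_calls <- function(object, ...) {
  r <- object$regions
  cat("Homoeologous exchange calls by region\n\n")
  if (nrow(r) == 0) { cat("  (no regions)\n"); return(invisible(object)) }
  r$length_kb <- (r$end - r$start) / 1e3
  r$confirmed <- ifelse(r$n_confirmed > 0, "yes", "no")
  print(r[, c("chromosome", "subgenome", "start", "end", "length_kb",
              "n_windows", "confirmed")], row.names = FALSE)
  invisible(object)
}

#' @export
plot.he_calls <- function(x, ...) {
  lay <- grid_layout(x$windows)
  n <- nrow(lay)
  graphics::plot(NULL, xlim = c(0, max(lay$length)), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "position (bp)", ylab = "",
                 main = "Homoeologous exchange regions", ...)
  graphics::axis(2, at = seq_len(n), labels = rev(lay$chromosome), las = 1)
  for (i in seq_len(n)) {
    y <- n - i + 1
    graphics::segments(0, y, lay$length[i], y, lwd = 3, col = "grey70")
    r <- x$regions[x$regions$chromosome == lay$chromosome[i], ,
                   drop = FALSE]
    if (nrow(r) > 0)
      graphics::segments(r$start, y, r$end, y, lwd = 6, col = "firebrick")
  }
  invisible(x)
}

#' Export evidence matrix and region calls as review-ready tracks
#'
#' Writes a BED6 of merged region calls (the name field packs subgenome,
#' window count, direction and confirmation so the BED round-trips), the
#' full per-window evidence matrix as TSV, and a chromosome table usable as
#' a circular-plot karyotype.
#'
#' @param calls an `he_calls` object.
#' @param prefix output path prefix; files `<prefix>_regions.bed`,
#'   `<prefix>_evidence.tsv` and `<prefix>_chromosomes.tsv` are written.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_tracks <- function(calls, prefix) {
  stopifnot(inherits(calls, "he_calls"))
  r <- calls$regions
  bed <- data.frame(
    chromosome = r$chromosome, start = r$start, end = r$end,
    name = sprintf("HE;subgenome=%s;n_windows=%d;direction=%s;n_confirmed=%d",
                   r$subgenome, r$n_windows, r$direction, r$n_confirmed),
    score = r$n_windows, stringsAsFactors = FALSE)
  paths <- c(regions = paste0(prefix, "_regions.bed"),
             evidence = paste0(prefix, "_evidence.tsv"),
             chromosomes = paste0(prefix, "_chromosomes.tsv"))
  write_bed(bed, paths["regions"])
  write_track_tsv(calls$windows, paths["evidence"])
  write_track_tsv(grid_layout(calls$windows), paths["chromosomes"])
  invisible(paths)
}

#' Re-import an exported region BED
#'
#' @param path BED written by [export_tracks()].
#' @return The regions data frame, identical to the exported one.
#' @export
read_he_bed <- function(path) {
  bed <- read_bed(path)
  if (nrow(bed) == 0L)
    return(data.frame(chromosome = character(), subgenome = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer(), direction = character(),
                      n_confirmed = integer(), stringsAsFactors = FALSE))
  field <- function(key) sub(sprintf(".*%s=([^;]*).*", key), "\\1", bed$name)
  data.frame(chromosome = bed$chromosome,
             subgenome = field("subgenome"),
             start = bed$start, end = bed$end,
             n_windows = as.integer(field("n_windows")),
             direction = field("direction"),
             n_confirmed = as.integer(field("n_confirmed")),
             stringsAsFactors = FALSE)
}

#' Score calls against planted truth intervals
#'
#' A truth interval counts as recovered when some called region overlaps it
#' reciprocally (overlap at least `min_reciprocal` of both lengths); a call
#' is a true positive under the same rule.
#'
#' @param regions called regions (`he_calls$regions` or compatible).
#' @param truth data frame of planted intervals (`chromosome`, `start`,
#'   `end`).
#' @param min_reciprocal reciprocal overlap fraction (default 0.5).
#' @return List with `recall`, `precision`, `n_truth`, `n_called`.
#' @export
compare_to_truth <- function(regions, truth, min_reciprocal = 0.5) {
  recip <- function(a, b) {
    ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
    same <- a$chromosome == b$chromosome
    same & ov >= min_reciprocal * (a$end - a$start) &
      ov >= min_reciprocal * (b$end - b$start)
  }
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    any(recip(truth[i, ], regions))
  }, logical(1))
  hit_call <- vapply(seq_len(nrow(regions)), function(i) {
    any(recip(regions[i, ], truth))
  }, logical(1))
  list(recall = if (nrow(truth)) mean(hit_truth) else NA_real_,
       precision = if (nrow(regions)) mean(hit_call) else NA_real_,
       n_truth = nrow(truth), n_called = nrow(regions))
}
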