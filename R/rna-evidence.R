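#' Transcriptomic HE evidence from species-wise RNA coverage
#'
#' All three RNA-seq datasets (the hybrid's own, and one per ancestral
#' species) are mapped onto the hybrid genome and reduced to per-window
#' fractions of covered bases on a shared 250-kb grid.  The hybrid-minus-
#' ancestor coverage differences then carry the signal: on a subgenome-a
#' window the intraspecific difference (hybrid minus sweet-cherry coverage)
#' is expected to sit near zero, below the interspecific difference (hybrid
#' minus ground-cherry coverage); the opposite ordering flags a potential
#' homoeologous exchange.  Mirror image on subgenome f.  Signed differences
#' are used, ties are not flagged, and windows where all three coverages are
#' zero carry `no_data`.
#'
#' @param cov_cerasus `coverage_track` of the hybrid RNA datasets (pool
#'   replicate datasets with [pooled_coverage()] first).
#' @param cov_avium,cov_fruticosa `coverage_track`s of the sweet cherry
#'   (ancestor A) and ground cherry (ancestor F) RNA datasets on the same
#'   grid.
#' @return Data frame (class `rna_evidence`): the window grid plus
#'   `cov_cerasus`, `cov_avium`, `cov_fruticosa`, `delta_intra`,
#'   `delta_inter`, `flag_rna`, `no_data`.
#' @export
rna_evidence <- function(cov_cerasus, cov_avium, cov_fruticosa) {
  same_grid <- function(x, y) {
    identical(x$chromosome, y$chromosome) &&
      identical(x$start, y$start) && identical(x$end, y$end)
  }
  if (!same_grid(cov_cerasus, cov_avium) ||
      !same_grid(cov_cerasus, cov_fruticosa))
    stop("the three coverage tracks must share one window grid")
  if (any(cov_cerasus$subgenome == "none"))
    stop("hybrid layout has unlabelled subgenomes")
  out <- cov_cerasus[, c("chromosome", "subgenome", "index", "start", "end")]
  out$cov_cerasus <- cov_cerasus$fraction
  out$cov_avium <- cov_avium$fraction
  out$cov_fruticosa <- cov_fruticosa$fraction
  delta_a <- out$cov_cerasus - out$cov_avium     # hybrid minus ancestor A
  delta_f <- out$cov_cerasus - out$cov_fruticosa # hybrid minus ancestor F
  on_a <- out$subgenome == "a"
  out$delta_intra <- ifelse(on_a, delta_a, delta_f)
  out$delta_inter <- ifelse(on_a, delta_f, delta_a)
  out$no_data <- out$cov_cerasus == 0 & out$cov_avium == 0 &
    out$cov_fruticosa == 0
  out$flag_rna <- out$delta_intra > out$delta_inter
  attr(out, "layout") <- attr(cov_cerasus, "layout")
  attr(out, "window_size") <- attr(cov_cerasus, "window_size")
  class(out) <- c("rna_evidence", "window_grid", "data.frame")
  out
}
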