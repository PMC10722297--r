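#' Run the full synthetic HE detection pipeline
#'
#' End-to-end run on the built-in generator: simulate ancestors, hybrid and
#' reads; map read pairs to both ancestors with the exact mapper; partition
#' fragments into the four origin classes; re-map the two ancestor-unique
#' read sets onto the hybrid for the genomic evidence (100-kb windows);
#' build the RNA (250-kb) and protein-identity (250-kb, 1-Mb confirmation)
#' tracks from the same simulated universe; intersect the three tracks and
#' call merged HE regions; score them against the planted truth; and date
#' and match the planted LTR elements.
#'
#' @param config a [sim_config()].
#' @param out_dir optional run directory; when given, evidence TSVs, the
#'   region BED, LTR tables and a JSON manifest (parameters + md5 checksums)
#'   are written there.
#' @param window_genomic,window_rna,window_confirm window sizes in bp
#'   (defaults 100000, 250000, 1000000).
#' @param policy harmonization policy for the genomic track
#'   ([harmonize_genomic()]).
#' @param tie_epsilon tie margin for protein assignment (percent points).
#' @param identity_tolerance LTR matching tolerance
#'   ([match_shared_ltrs()]).
#' @param mu LTR clock rate (substitutions per site per generation).
#' @param k seed length of the exact mapper.
#' @return A list of class `he_pipeline` with the truth, the class counts,
#'   the three evidence tracks, the evidence matrix, the `he_calls`, the
#'   truth-comparison `metrics`, the dated LTR tables with youngest shared
#'   ages per genome pair, and the written `paths` (or `NULL`).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         window_genomic = 100000, window_rna = 250000,
                         window_confirm = 1000000,
                         policy = c("any", "all"), tie_epsilon = 0,
                         identity_tolerance = 1e-4, mu = 7.7e-9, k = 31) {
  stopifnot(inherits(config, "sim_config"))
  policy <- match.arg(policy)

  anc <- simulate_ancestors(config)
  hyb <- simulate_hybrid(anc$A, anc$F, config)
  reads <- simulate_reads(hyb$hybrid, config)

  set.seed(config$seed + 6L)  # multi-mapping tie-breaks in the mapper
  aln_a <- exact_map(reads$reads1, reads$reads2, anc$A, k = k)
  aln_f <- exact_map(reads$reads1, reads$reads2, anc$F, k = k)
  classes <- classify_fragments(aln_a, aln_f,
                                fragments = reads$truth$fragment_id)
  class_counts <- table(classes$class)
  rm(aln_a, aln_f)

  sel_a <- classes$fragment_id[classes$class == "UNIQUE_A"]
  sel_f <- classes$fragment_id[classes$class == "UNIQUE_F"]
  remap_a <- exact_map(reads$reads1[sel_a], reads$reads2[sel_a],
                       hyb$hybrid, k = k)
  remap_f <- exact_map(reads$reads1[sel_f], reads$reads2[sel_f],
                       hyb$hybrid, k = k)
  rm(reads)
  genomic <- genomic_evidence(remap_a, remap_f, hyb$layout, window_genomic)
  rm(remap_a, remap_f)

  prot <- simulate_proteins(hyb$layout, hyb$truth, config)
  rna <- simulate_rna_tracks(prot$genes, config)
  grid_rna <- make_windows(hyb$layout, window_rna)
  cov_cer <- pooled_coverage(
    lapply(rna$cerasus, depth_from_intervals, layout = hyb$layout),
    grid_rna)
  cov_av <- fraction_covered(depth_from_intervals(rna$avium, hyb$layout),
                             grid_rna)
  cov_fr <- fraction_covered(depth_from_intervals(rna$fruticosa,
                                                  hyb$layout), grid_rna)
  rna_ev <- rna_evidence(cov_cer, cov_av, cov_fr)

  iaa_ev <- iaa_evidence(prot$records, hyb$layout, window_rna, tie_epsilon)
  confirm <- quantile70_confirm(prot$records, hyb$layout, window_confirm)

  evid <- evidence_matrix(genomic, rna_ev, iaa_ev, confirm, policy)
  calls <- call_he(evid)
  metrics <- compare_to_truth(calls$regions, hyb$truth)

  ltr <- simulate_ltrs(config)
  genome_pairs <- list(
    a_vs_avium = c("cerasus_a", "avium"),
    f_vs_fruticosa = c("cerasus_f", "fruticosa"),
    avium_vs_fruticosa = c("avium", "fruticosa"),
    a_vs_f = c("cerasus_a", "cerasus_f"),
    avium_vs_f = c("avium", "cerasus_f"),
    fruticosa_vs_a = c("fruticosa", "cerasus_a"))
  youngest <- vapply(genome_pairs, function(p) {
    if (!all(p %in% names(ltr$elements))) return(NA_real_)
    youngest_shared_ltr(ltr$elements[[p[1]]], ltr$elements[[p[2]]],
                        identity_tolerance = identity_tolerance)
  }, numeric(1))

  res <- structure(list(
    config = config, layout = hyb$layout, truth = hyb$truth,
    class_counts = class_counts, genomic = genomic, rna = rna_ev,
    iaa = iaa_ev, confirm = confirm, evidence = evid, calls = calls,
    metrics = metrics, ltr_elements = ltr$elements,
    ltr_youngest = youngest, paths = NULL), class = "he_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      export_tracks(calls, file.path(out_dir, "he")),
      genomic = write_track_tsv(genomic,
                                file.path(out_dir, "genomic_evidence.tsv")),
      rna = write_track_tsv(rna_ev, file.path(out_dir, "rna_evidence.tsv")),
      iaa = write_track_tsv(iaa_ev, file.path(out_dir, "iaa_evidence.tsv")),
      confirm = write_track_tsv(confirm,
                                file.path(out_dir, "q70_confirmation.tsv")),
      truth = write_bed(cbind(hyb$truth,
                              name = hyb$truth$donor_subgenome),
                        file.path(out_dir, "truth_he.bed")),
      ltr = write_track_tsv(do.call(rbind, ltr$elements),
                            file.path(out_dir, "ltr_dated.tsv")))
    manifest <- list(
      parameters = unclass(config)[setdiff(names(config),
                                           c("he_segments", "ltr_spec"))],
      windows = list(genomic = window_genomic, rna = window_rna,
                     confirm = window_confirm),
      policy = policy, mu = mu,
      metrics = metrics,
      checksums = as.list(tools::md5sum(unname(paths))))
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
    res$paths <- c(paths, manifest = mpath)
  }
  res
}

#' @export
print.he_pipeline <- function(x, ...) {
  cat("Synthetic allotetraploid HE pipeline run\n")
  cat(sprintf("  genome: %d chromosomes/subgenome x %.1f Mb, divergence %.3f, drift %.4f\n",
              x$config$n_chromosomes, x$config$chromosome_length / 1e6,
              x$config$ancestor_divergence, x$config$subgenome_drift))
  cc <- x$class_counts
  cat(sprintf("  fragments: UNIQUE_A %d | UNIQUE_F %d | BOTH %d | NEITHER %d\n",
              cc[["UNIQUE_A"]], cc[["UNIQUE_F"]], cc[["BOTH"]],
              cc[["NEITHER"]]))
  print(x$calls)
  cat(sprintf("  vs planted truth: recall %.3f, precision %.3f (n_truth %d)\n",
              x$metrics$recall, x$metrics$precision, x$metrics$n_truth))
  invisible(x)
}
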