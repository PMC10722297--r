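no_he <- function() {
  data.frame(subgenome = character(), chromosome = character(),
             start = numeric(), end = numeric())
}

test_that("config validation rejects impossible universes", {
  expect_error(sim_config(ancestor_divergence = 0.6), "rates")
  expect_error(sim_config(gene_spacing = 1000), "gene_spacing")
  expect_error(sim_config(
    he_segments = data.frame(subgenome = "a", chromosome = "chr1",
                             start = 100, end = 6e6)), "bounds")
  expect_error(sim_config(
    he_segments = data.frame(subgenome = c("a", "a"), chromosome = "chr1",
                             start = c(0, 50), end = c(100, 150))),
    "overlap")
})

test_that("ancestor divergence is planted at the configured rate", {
  cfg0 <- sim_config(seed = 3, n_chromosomes = 1, chromosome_length = 5e4,
                     ancestor_divergence = 0, he_segments = no_he())
  anc0 <- simulate_ancestors(cfg0)
  expect_identical(anc0$A, anc0$F)

  cfg <- sim_config(seed = 3, n_chromosomes = 1, chromosome_length = 1e6,
                    ancestor_divergence = 0.03, he_segments = no_he())
  anc <- simulate_ancestors(cfg)
  a <- charToRaw(anc$A[["chr1"]]); f <- charToRaw(anc$F[["chr1"]])
  mism <- mean(a != f)
  # two independent branches at rate 0.015; coincident or reverting hits
  # shrink the expectation slightly below 0.03
  p <- 2 * 0.015 * (1 - 0.015) + 2 * 0.015^2 * (3 / 4) * (2 / 3)
  expect_lt(abs(mism - p), 3 * sqrt(p * (1 - p) / 1e6))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chromosome_length = 4e4,
                    he_segments = data.frame(subgenome = "a",
                                             chromosome = "chr1",
                                             start = 10000, end = 20000),
                    coverage = 2)
  run <- function() {
    anc <- simulate_ancestors(cfg)
    hyb <- simulate_hybrid(anc$A, anc$F, cfg)
    reads <- simulate_reads(hyb$hybrid, cfg)
    prot <- simulate_proteins(hyb$layout, hyb$truth, cfg)
    rna <- simulate_rna_tracks(prot$genes, cfg)
    fa <- tempfile(fileext = ".fa")
    write_fasta(hyb$hybrid, fa)
    fq1 <- tempfile(); fq2 <- tempfile()
    write_fastq_pairs(reads$reads1, reads$reads2, fq1, fq2)
    list(md5 = unname(tools::md5sum(c(fa, fq1, fq2))),
         records = prot$records, rna = rna, truth = hyb$truth)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$md5, r2$md5)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$rna, r2$rna)
  expect_identical(r1$truth, r2$truth)
})

test_that("planted exchanges are literal copies of the homoeologous slice", {
  cfg <- sim_config(seed = 21, n_chromosomes = 1, chromosome_length = 1e5,
                    he_segments = data.frame(subgenome = "a",
                                             chromosome = "chr1",
                                             start = 40000, end = 60000),
                    coverage = 2)
  anc <- simulate_ancestors(cfg)
  hyb <- simulate_hybrid(anc$A, anc$F, cfg)
  expect_identical(substr(hyb$hybrid[["chr1_a"]], 40001, 60000),
                   substr(hyb$hybrid[["chr1_f"]], 40001, 60000))
  expect_equal(hyb$truth$chromosome, "chr1_a")
  expect_equal(hyb$truth$donor_subgenome, "f")

  # without exchanges and drift, the subgenomes equal the ancestors
  cfg0 <- sim_config(seed = 21, n_chromosomes = 1, chromosome_length = 5e4,
                     subgenome_drift = 0, he_segments = no_he())
  anc0 <- simulate_ancestors(cfg0)
  hyb0 <- simulate_hybrid(anc0$A, anc0$F, cfg0)
  expect_identical(unname(hyb0$hybrid[["chr1_a"]]), unname(anc0$A[["chr1"]]))
  expect_identical(unname(hyb0$hybrid[["chr1_f"]]), unname(anc0$F[["chr1"]]))
})

test_that("read simulation hits the coverage target with exact substrings", {
  cfg <- sim_config(seed = 33, n_chromosomes = 1, chromosome_length = 1e6,
                    he_segments = no_he(), coverage = 20)
  set.seed(33)
  genome <- c(chr1 = allohex:::random_dna(1e6))
  reads <- simulate_reads(genome, cfg)
  total <- sum(nchar(reads$reads1)) + sum(nchar(reads$reads2))
  expect_lt(abs(total - 2e7) / 2e7, 0.05)

  # every mate is an exact substring of its source fragment
  idx <- sample(length(reads$reads1), 50)
  for (i in idx) {
    tr <- reads$truth[i, ]
    frag <- substr(genome[[tr$chromosome]], tr$start + 1,
                   tr$start + tr$insert)
    expect_identical(reads$reads1[i], substr(frag, 1, 150))
    expect_identical(
      reads$reads2[i],
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(frag, tr$insert - 149, tr$insert)))))
  }

  short <- c(chr1 = allohex:::random_dna(300))
  expect_error(simulate_reads(short, cfg), "shorter than the insert")
})

test_that("simulated protein identities reflect gene origin", {
  cfg <- sim_config(seed = 55, n_chromosomes = 1, chromosome_length = 5e5,
                    he_segments = data.frame(subgenome = "a",
                                             chromosome = "chr1",
                                             start = 250000, end = 500000),
                    gene_spacing = 25000, coverage = 2)
  anc <- simulate_ancestors(cfg)
  hyb <- simulate_hybrid(anc$A, anc$F, cfg)
  prot <- simulate_proteins(hyb$layout, hyb$truth, cfg)
  rec <- prot$records
  on_a <- rec$chromosome == "chr1_a"
  in_he <- on_a & rec$anchor >= 250000
  expect_true(all(rec$iaa_a[on_a & !in_he] > rec$iaa_f[on_a & !in_he]))
  expect_true(all(rec$iaa_f[in_he] > rec$iaa_a[in_he]))
  f_side <- rec$chromosome == "chr1_f"
  expect_true(all(rec$iaa_f[f_side] > rec$iaa_a[f_side]))

  # degenerate universe: everything identical, all ties at 100
  cfg0 <- sim_config(seed = 56, n_chromosomes = 1, chromosome_length = 2e5,
                     ancestor_divergence = 0, subgenome_drift = 0,
                     he_segments = no_he(), coverage = 2)
  anc0 <- simulate_ancestors(cfg0)
  hyb0 <- simulate_hybrid(anc0$A, anc0$F, cfg0)
  rec0 <- simulate_proteins(hyb0$layout, hyb0$truth, cfg0)$records
  expect_true(all(rec0$iaa_a == 100 & rec0$iaa_f == 100))
})

test_that("RNA tracks cover genes by origin and leave gene deserts empty", {
  cfg <- sim_config(seed = 77, n_chromosomes = 1, chromosome_length = 5e5,
                    he_segments = data.frame(subgenome = "a",
                                             chromosome = "chr1",
                                             start = 250000, end = 500000),
                    gene_spacing = 25000, coverage = 2)
  anc <- simulate_ancestors(cfg)
  hyb <- simulate_hybrid(anc$A, anc$F, cfg)
  prot <- simulate_proteins(hyb$layout, hyb$truth, cfg)
  rna <- simulate_rna_tracks(prot$genes, cfg)
  # avium reads only cover A-origin loci: none on the exchanged block or
  # anywhere on the f subgenome
  expect_false(any(rna$avium$chromosome == "chr1_a" &
                     rna$avium$start >= 250000))
  expect_false(any(rna$avium$chromosome == "chr1_f"))
  # fruticosa covers the exchanged block on chr1_a and all of chr1_f
  expect_true(any(rna$fruticosa$chromosome == "chr1_a" &
                    rna$fruticosa$start >= 250000))
  # no dataset covers outside gene bodies
  lay <- hyb$layout
  g <- make_windows(lay, 250000)
  cov <- fraction_covered(depth_from_intervals(rna$avium, lay), g)
  genes_per_window <- 10 * cfg$gene_length / 250000
  expect_true(all(cov$fraction <= genes_per_window + 1e-9))
})

test_that("planted LTR tables date and match as specified", {
  cfg <- sim_config(seed = 88)
  dir <- tempfile()
  sim <- simulate_ltrs(cfg, dir = dir)
  expect_true(all(file.exists(sim$paths)))
  a <- parse_pass_list(sim$paths[["cerasus_a"]], "cerasus_a")
  expect_equal(nrow(a), sum(cfg$ltr_spec$genome_id == "cerasus_a"))
  # the youngest element shared with the sweet cherry genome dates to the
  # planted identity exactly
  av <- sim$elements[["avium"]]
  expect_equal(youngest_shared_ltr(a, av), 103896.1)
  # deterministic: identical files on a second write
  dir2 <- tempfile()
  sim2 <- simulate_ltrs(cfg, dir = dir2)
  expect_identical(unname(tools::md5sum(sim$paths)),
                   unname(tools::md5sum(sim2$paths)))

  bad <- cfg
  bad$ltr_spec$start[2] <- bad$ltr_spec$start[1]
  bad$ltr_spec$end[2] <- bad$ltr_spec$end[1] + 10
  expect_error(simulate_ltrs(bad), "overlapping")
})
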