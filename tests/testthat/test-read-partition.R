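test_that("the proper-pair/primary flag filter follows samtools -f 3 -F 2304", {
  expect_equal(passes_filter(c(99, 147, 83, 163)), rep(TRUE, 4))
  expect_false(passes_filter(355))    # 99 + secondary
  expect_false(passes_filter(2147))   # 99 + supplementary
  expect_false(passes_filter(1))      # paired but not proper
  expect_error(passes_filter(-1), "non-negative")
})

test_that("exact mapper recovers planted read positions", {
  set.seed(41)
  genome <- c(chrA = paste(sample(c("A", "C", "G", "T"), 100000,
                                  replace = TRUE), collapse = ""))
  r1 <- substr(genome, 1001, 1150)
  frag_end <- substr(genome, 1401, 1550)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag_end)))
  aln <- exact_map(r1, r2, genome)
  expect_equal(nrow(aln), 2)
  expect_equal(sort(aln$start), c(1000, 1400))
  expect_true(all(passes_filter(aln$flag)))
  expect_equal(aln$end - aln$start, c(150, 150))

  expect_error(exact_map("ACGT", "ACGT", genome), "read length")
})

test_that("a repeated locus yields a primary and a secondary alignment", {
  set.seed(43)
  unit <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  filler <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                  collapse = "")
  genome <- c(chr = paste0(unit, filler, unit))
  r1 <- substr(unit, 501, 650)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(unit, 901, 1050))))
  aln <- exact_map(r1, r2, genome)
  m1 <- aln[aln$mate == 1, ]
  expect_equal(nrow(m1), 2)                   # both copies reported
  expect_equal(sum(bitwAnd(m1$flag, 256L) == 0L), 1)  # exactly one primary
  expect_setequal(m1$start, c(500, 8500))
})

test_that("simulated fragments map back to their truth positions", {
  cfg <- sim_config(seed = 5, n_chromosomes = 2, chromosome_length = 50000,
                    he_segments = data.frame(subgenome = character(),
                                             chromosome = character(),
                                             start = numeric(),
                                             end = numeric()),
                    coverage = 3)
  set.seed(5)
  genome <- c(chr1 = allohex:::random_dna(50000),
              chr2 = allohex:::random_dna(50000))
  reads <- simulate_reads(genome, cfg)
  set.seed(99)
  aln <- exact_map(reads$reads1, reads$reads2, genome)
  prim1 <- aln[aln$mate == 1 & passes_filter(aln$flag), ]
  got <- prim1[order(prim1$fragment_id), ]
  tr <- reads$truth[match(got$fragment_id, reads$truth$fragment_id), ]
  expect_equal(got$chromosome, tr$chromosome)
  expect_equal(got$start, tr$start)
  expect_gt(nrow(got) / nrow(reads$truth), 0.99)  # random genomes are unique
})

test_that("fragment classification partitions exhaustively and exclusively", {
  set.seed(47)
  cfg <- sim_config(seed = 47, n_chromosomes = 1, chromosome_length = 1e5,
                    he_segments = data.frame(subgenome = "a",
                                             chromosome = "chr1",
                                             start = 50000, end = 75000),
                    coverage = 4)
  anc <- simulate_ancestors(cfg)
  hyb <- simulate_hybrid(anc$A, anc$F, cfg)
  reads <- simulate_reads(hyb$hybrid, cfg)
  aln_a <- exact_map(reads$reads1, reads$reads2, anc$A)
  aln_f <- exact_map(reads$reads1, reads$reads2, anc$F)
  cl <- classify_fragments(aln_a, aln_f, reads$truth$fragment_id)

  # partition closes over all sequenced fragments
  expect_equal(sum(table(cl$class)), nrow(reads$truth))
  expect_equal(anyDuplicated(cl$fragment_id), 0L)

  # fragments wholly inside the planted exchange carry F-derived sequence
  inside <- reads$truth$chromosome == "chr1_a" &
    reads$truth$start >= 50000 &
    reads$truth$start + reads$truth$insert <= 75000
  inside_classes <- cl$class[match(reads$truth$fragment_id[inside],
                                   cl$fragment_id)]
  expect_gt(mean(inside_classes %in% c("UNIQUE_F", "NEITHER")), 0.999)
  expect_gt(sum(inside_classes == "UNIQUE_F"), 0)

  # label symmetry: swapping the ancestors swaps the unique classes
  cl_sw <- classify_fragments(aln_f, aln_a, reads$truth$fragment_id)
  tab <- table(cl$class); tab_sw <- table(cl_sw$class)
  expect_equal(unname(tab[["UNIQUE_A"]]), unname(tab_sw[["UNIQUE_F"]]))
  expect_equal(unname(tab[["UNIQUE_F"]]), unname(tab_sw[["UNIQUE_A"]]))
  expect_equal(unname(tab[["BOTH"]]), unname(tab_sw[["BOTH"]]))
})

test_that("identical ancestors make every mapped fragment ambiguous", {
  cfg <- sim_config(seed = 13, n_chromosomes = 1, chromosome_length = 5e4,
                    ancestor_divergence = 0, subgenome_drift = 0,
                    he_segments = data.frame(subgenome = character(),
                                             chromosome = character(),
                                             start = numeric(),
                                             end = numeric()),
                    coverage = 2)
  anc <- simulate_ancestors(cfg)
  expect_identical(anc$A, anc$F)
  hyb <- simulate_hybrid(anc$A, anc$F, cfg)
  reads <- simulate_reads(hyb$hybrid, cfg)
  aln_a <- exact_map(reads$reads1, reads$reads2, anc$A)
  aln_f <- exact_map(reads$reads1, reads$reads2, anc$F)
  cl <- classify_fragments(aln_a, aln_f, reads$truth$fragment_id)
  expect_equal(sum(cl$class %in% c("UNIQUE_A", "UNIQUE_F")), 0)
  expect_gt(sum(cl$class == "BOTH"), 0)
})

test_that("genomic evidence flags windows where interspecific coverage wins", {
  lay <- tiny_layout()
  mk <- function(chrom, starts) {
    n <- length(starts)
    data.frame(fragment_id = seq_len(n), mate = 1L, flag = 99L,
               chromosome = chrom, start = starts, end = starts + 150,
               stringsAsFactors = FALSE)
  }
  # UNIQUE_A reads densely on c1_a[0,100k); UNIQUE_F reads on c1_a[100k,200k)
  aln_a <- mk("c1_a", seq(0, 99850, by = 75))
  aln_f <- mk("c1_a", seq(100000, 199850, by = 75))
  ev <- genomic_evidence(aln_a, aln_f, lay, window_size = 100000)
  w <- ev[ev$chromosome == "c1_a", ]
  expect_false(w$flag_genomic[1])  # intra-covered window
  expect_true(w$flag_genomic[2])   # inter-covered window
  expect_true(all(w$no_data[3:10]))
  expect_false(any(w$flag_genomic[3:10]))  # 0 < 0 is not a flag
  # the flag is exactly the strict coverage inequality
  expect_equal(ev$flag_genomic, ev$cov_intra < ev$cov_inter)

  expect_error(genomic_evidence(aln_a, aln_f,
                                genome_layout("c1", 1e6), 100000),
               "unlabelled")
})
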