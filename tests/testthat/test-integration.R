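# build a full evidence matrix directly from flag vectors on a tiny layout
build_evidence <- function(lay, flag_g100, flag_rna, flag_iaa,
                           policy = "any") {
  g100 <- make_windows(lay, 100000)
  g250 <- make_windows(lay, 250000)
  stopifnot(length(flag_g100) == nrow(g100),
            length(flag_rna) == nrow(g250))
  genomic <- g100
  genomic$cov_intra <- ifelse(flag_g100, 0.1, 0.9)
  genomic$cov_inter <- ifelse(flag_g100, 0.8, 0.1)
  genomic$no_data <- FALSE
  genomic$flag_genomic <- flag_g100
  class(genomic) <- c("genomic_evidence", class(g100))
  rna <- g250
  rna$flag_rna <- flag_rna
  rna$no_data <- FALSE
  class(rna) <- c("rna_evidence", class(g250))
  iaa <- g250
  iaa$flag_iaa <- flag_iaa
  iaa$no_data <- FALSE
  class(iaa) <- c("iaa_evidence", class(g250))
  evidence_matrix(genomic, rna, iaa, policy = policy)
}

test_that("harmonization follows the any/all policy and overlap structure", {
  lay <- genome_layout("c1_a", 1e6, "a")
  g100 <- make_windows(lay, 100000)
  g250 <- make_windows(lay, 250000)
  genomic <- g100
  genomic$flag_genomic <- rep(FALSE, 10)
  genomic$flag_genomic[2] <- TRUE       # [100k, 200k)
  genomic$no_data <- rep(FALSE, 10)
  class(genomic) <- c("genomic_evidence", class(g100))

  any_pol <- harmonize_genomic(genomic, g250, "any")
  expect_equal(any_pol$flag_genomic, c(TRUE, FALSE, FALSE, FALSE))
  all_pol <- harmonize_genomic(genomic, g250, "all")
  expect_equal(all_pol$flag_genomic, rep(FALSE, 4))

  set.seed(59)
  for (rep in 1:20) {
    genomic$flag_genomic <- runif(10) < 0.4
    got_any <- harmonize_genomic(genomic, g250, "any")$flag_genomic
    got_all <- harmonize_genomic(genomic, g250, "all")$flag_genomic
    # brute-force interval-overlap oracle
    for (w in seq_len(nrow(g250))) {
      ov <- genomic$start < g250$end[w] & genomic$end > g250$start[w]
      expect_equal(got_any[w], any(genomic$flag_genomic[ov]))
      expect_equal(got_all[w], all(genomic$flag_genomic[ov]))
    }
    # relaxing the policy from all to any never removes a flag
    expect_true(all(got_any >= got_all))
  }
})

test_that("adjacent qualifying windows merge into directed regions", {
  lay <- genome_layout(c("c1_a", "c1_f"), c(2e6, 2e6), c("a", "f"))
  n250 <- 16  # 8 windows per chromosome
  fr <- rep(FALSE, n250); fi <- rep(FALSE, n250)
  fg <- rep(FALSE, 40)

  # three adjacent qualifying windows on c1_a -> one 750-kb region
  fr[2:4] <- fi[2:4] <- TRUE
  fg[5:16] <- TRUE  # covers 100-kb windows under 250-kb windows 2..4
  ev <- build_evidence(lay, fg, fr, fi)
  calls <- call_he(ev)
  expect_equal(nrow(calls$regions), 1)
  expect_equal(calls$regions$start, 250000)
  expect_equal(calls$regions$end, 1000000)
  expect_equal(calls$regions$n_windows, 3)
  expect_equal(calls$regions$direction, "replaced_by_other_subgenome")
  expect_equal(calls$n_qualifying, 3)

  # non-adjacent qualifying windows stay separate regions
  fr2 <- rep(FALSE, n250); fi2 <- rep(FALSE, n250)
  fr2[c(3, 6)] <- fi2[c(3, 6)] <- TRUE
  ev2 <- build_evidence(lay, rep(TRUE, 40), fr2, fi2)
  calls2 <- call_he(ev2)
  expect_equal(nrow(calls2$regions), 2)
  expect_equal(calls2$regions$n_windows, c(1, 1))

  # every constituent window of every region satisfies all three flags
  w <- calls$windows
  for (r in seq_len(nrow(calls$regions))) {
    reg <- calls$regions[r, ]
    sel <- w$chromosome == reg$chromosome & w$start >= reg$start &
      w$end <= reg$end
    expect_true(all(w$flag_genomic[sel] & w$flag_rna[sel] &
                      w$flag_iaa[sel]))
  }

  expect_error(call_he(data.frame()), "empty or invalid")
})

test_that("calls are stable under window row reordering", {
  lay <- genome_layout(c("c1_a", "c1_f"), c(1e6, 1e6), c("a", "f"))
  fr <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  ev <- build_evidence(lay, rep(TRUE, 20), fr, fr)
  calls <- call_he(ev)
  shuffled <- ev[sample(nrow(ev)), ]
  attr(shuffled, "layout") <- attr(ev, "layout")
  attr(shuffled, "window_size") <- attr(ev, "window_size")
  class(shuffled) <- class(ev)
  calls2 <- call_he(shuffled)
  expect_equal(calls$regions, calls2$regions)
})

test_that("exported region BED round-trips exactly", {
  lay <- genome_layout(c("c1_a", "c1_f"), c(2e6, 2e6), c("a", "f"))
  fr <- rep(FALSE, 16); fr[c(3, 4, 11)] <- TRUE
  ev <- build_evidence(lay, rep(TRUE, 40), fr, fr)
  calls <- call_he(ev)
  dir <- tempfile(); dir.create(dir)
  paths <- export_tracks(calls, file.path(dir, "run"))
  back <- read_he_bed(paths[["regions"]])
  expect_equal(back, calls$regions)

  bed1 <- readLines(paths[["regions"]])
  # single region line is plain BED6 with 0-based half-open coordinates
  f <- strsplit(bed1[1], "\t")[[1]]
  expect_equal(f[1:3], c("c1_a", "500000", "1000000"))

  # empty call set round-trips to an empty frame
  fr0 <- rep(FALSE, 16)
  calls0 <- call_he(build_evidence(lay, rep(FALSE, 40), fr0, fr0))
  p0 <- export_tracks(calls0, file.path(dir, "empty"))
  expect_equal(nrow(read_he_bed(p0[["regions"]])), 0)
})

test_that("truth comparison scores reciprocal-overlap recovery", {
  truth <- data.frame(chromosome = c("c1_a", "c1_f"),
                      start = c(0, 500000), end = c(500000, 1500000))
  called <- data.frame(chromosome = c("c1_a", "c1_f", "c1_f"),
                       start = c(0, 500000, 1800000),
                       end = c(500000, 1500000, 1900000))
  m <- compare_to_truth(called, truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 2 / 3)

  # a sliver of overlap does not count as recovery
  off <- data.frame(chromosome = "c1_a", start = 400000, end = 2000000)
  m2 <- compare_to_truth(off, truth)
  expect_equal(m2$recall, 0)
})
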