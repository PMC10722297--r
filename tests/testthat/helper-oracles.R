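# Independent brute-force oracles and tiny fixture builders.

# per-base boolean counting oracle for windowed fraction-of-bases-covered
oracle_fraction_covered <- function(intervals, chrom_length, windows,
                                    depth_threshold = 1) {
  depth <- integer(chrom_length)
  for (i in seq_len(nrow(intervals))) {
    idx <- seq(intervals$start[i] + 1, intervals$end[i])
    depth[idx] <- depth[idx] + 1L
  }
  vapply(seq_len(nrow(windows)), function(w) {
    idx <- seq(windows$start[w] + 1, windows$end[w])
    mean(depth[idx] >= depth_threshold)
  }, numeric(1))
}

random_intervals <- function(n, chrom_length, chrom = "chr1",
                             max_len = 500) {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (chrom_length - len))
  data.frame(chromosome = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# exhaustive enumeration of every global alignment (paths in the edit
# lattice) for tiny sequences: returns max score and the identities
# achievable by optimal-score alignments under +1/0/-1 scoring
oracle_alignment <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  best <- list(score = -Inf, identities = numeric())
  recurse <- function(i, j, score, matches, cols) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score)
        best <<- list(score = score, identities = numeric())
      if (score == best$score)
        best$identities <<- union(best$identities, 100 * matches / cols)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      recurse(i + 1, j + 1, score + (a[i] == b[j]),
              matches + (a[i] == b[j]), cols + 1)
    if (i <= length(a)) recurse(i + 1, j, score - 1, matches, cols + 1)
    if (j <= length(b)) recurse(i, j + 1, score - 1, matches, cols + 1)
  }
  recurse(1L, 1L, 0L, 0L, 0L)
  best
}

# exhaustive maximum matchings over compatibility matrix `ok`
# (memoised top-down enumeration, independent of the package's LCS DP)
oracle_collinear_max <- function(ok) {
  n <- nrow(ok); m <- ncol(ok)
  if (n == 0 || m == 0) return(0L)
  memo <- array(NA_integer_, dim = c(n + 1, m + 1))
  f <- function(i, lastj) {
    if (i > n) return(0L)
    if (!is.na(memo[i, lastj + 1])) return(memo[i, lastj + 1])
    best <- f(i + 1L, lastj)                # leave element i unmatched
    js <- which(ok[i, ])
    for (j in js[js > lastj])
      best <- max(best, 1L + f(i + 1L, j))
    memo[i, lastj + 1] <<- best
    best
  }
  f(1L, 0L)
}

oracle_unordered_max <- function(ok) {
  n <- nrow(ok); m <- ncol(ok)
  if (n == 0 || m == 0) return(0L)
  f <- function(i, used) {
    if (i > n) return(0L)
    best <- f(i + 1L, used)
    for (j in which(ok[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      best <- max(best, 1L + f(i + 1L, used2))
    }
    best
  }
  f(1L, rep(FALSE, m))
}

# random LTR element tables over few families/identities so that matches
# and conflicts both occur
random_ltr_table <- function(n, genome_id) {
  fam <- sample(c("Copia-1", "Gypsy-2", "Pao-3"), n, replace = TRUE)
  ident <- sample(c(0.991, 0.9915, 0.995, 0.998), n, replace = TRUE)
  start <- sort(sample.int(1e6, n))
  ltr_elements(genome_id, "chr1", start, start + 300, fam, ident)
}

# tiny hybrid layout used across tests
tiny_layout <- function() {
  genome_layout(c("c1_a", "c1_f"), c(1e6, 1e6), c("a", "f"), "hybrid")
}

# coverage_track with prescribed per-window fractions
fake_track <- function(grid, fraction) {
  stopifnot(length(fraction) == nrow(grid))
  out <- grid
  out$fraction <- fraction
  class(out) <- c("coverage_track", class(grid))
  out
}
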