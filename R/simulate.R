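# Seeded generator of a segmental-allotetraploid test universe.  The model
# is substitution-only (no indels), which keeps exact-match read mapping and
# identity arithmetic closed-form; every stage derives its RNG stream from
# config$seed plus a fixed stage offset so outputs are reproducible
# regardless of call order.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  rawToChar(as.raw(utf8ToInt("ACGT")[sample.int(4L, n, replace = TRUE)]))
}

# substitute each base independently with probability `rate` (to one of the
# three other symbols, uniformly); works for DNA and protein alphabets
mutate_seq <- function(seq, rate, alphabet = DNA_BASES) {
  if (rate == 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  r <- charToRaw(seq)
  codes <- utf8ToInt(paste(alphabet, collapse = ""))
  cur <- match(as.integer(r[pos]), codes)
  shift <- sample.int(length(alphabet) - 1L, k, replace = TRUE)
  r[pos] <- as.raw(codes[((cur - 1L + shift) %% length(alphabet)) + 1L])
  rawToChar(r)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

default_he_segments <- function() {
  data.frame(
    subgenome = c("a", "a", "a", "f", "f", "f"),
    chromosome = c("chr1", "chr1", "chr2", "chr1", "chr2", "chr2"),
    start = c(1000000, 3500000, 2250000, 500000, 1000000, 3750000),
    end = c(2000000, 4000000, 4250000, 1250000, 2500000, 4750000),
    stringsAsFactors = FALSE)
}

default_ltr_spec <- function() {
  # shared elements are planted with identical left-right identity in both
  # carriers of a pair (one element, one insertion, two descendants) and in
  # the same positional order; identities of distinct elements differ by
  # more than the default matching tolerance
  shared <- rbind(
    data.frame(pair_1 = "cerasus_a", pair_2 = "avium",
               family = c("Copia-1", "Gypsy-3"),
               identity = c(0.9984, 0.9975)),
    data.frame(pair_1 = "cerasus_f", pair_2 = "fruticosa",
               family = c("Copia-2", "Gypsy-7"),
               identity = c(0.9985, 0.9962)),
    data.frame(pair_1 = "avium", pair_2 = "fruticosa",
               family = "Copia-5", identity = 0.9982),
    data.frame(pair_1 = "cerasus_a", pair_2 = "cerasus_f",
               family = "Gypsy-11", identity = 0.9970),
    data.frame(pair_1 = "avium", pair_2 = "cerasus_f",
               family = "Copia-9", identity = 0.9968),
    data.frame(pair_1 = "fruticosa", pair_2 = "cerasus_a",
               family = "Gypsy-4", identity = 0.9977))
  private <- data.frame(
    genome_id = c("cerasus_a", "cerasus_f", "avium", "fruticosa"),
    family = c("Copia-20", "Copia-21", "Gypsy-22", "Gypsy-23"),
    identity = c(0.9930, 0.9920, 0.9910, 0.9900),
    stringsAsFactors = FALSE)
  rows <- rbind(
    data.frame(genome_id = shared$pair_1, family = shared$family,
               identity = shared$identity, stringsAsFactors = FALSE),
    data.frame(genome_id = shared$pair_2, family = shared$family,
               identity = shared$identity, stringsAsFactors = FALSE),
    private)
  # positions: per genome, in row order along chromosome 1 of that genome
  rows <- rows[order(rows$genome_id), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(rows)), rows$genome_id, FUN = seq_along)
  rows$chromosome <- ifelse(rows$genome_id %in% c("cerasus_a", "cerasus_f"),
                            paste0("chr1_", sub("cerasus_", "",
                                                rows$genome_id)), "chr1")
  rows$start <- 10000 + (idx - 1L) * 20000
  rows$end <- rows$start + 5000
  rownames(rows) <- NULL
  rows
}

#' Configuration of the synthetic allotetraploid universe
#'
#' Defaults describe the shipped study conditions: two 5-Mb chromosomes per
#' subgenome, 3% substitution divergence between the ancestors, 0.2%
#' subgenome drift, six planted duplication-deletion HE segments of
#' 0.5-2 Mb snapped to 250-kb boundaries, error-free 150-bp read pairs with
#' a ~550-bp insert at 20x coverage, one gene every 50 kb, and an LTR table
#' with shared elements across all genome pairs.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_chromosomes chromosomes per subgenome.
#' @param chromosome_length chromosome length in bp.
#' @param ancestor_divergence substitution rate separating the two ancestors
#'   (applied as half on each branch from their common ancestor).
#' @param subgenome_drift substitution rate separating each hybrid subgenome
#'   from its ancestor.
#' @param he_segments data frame (`subgenome`, `chromosome`, `start`, `end`)
#'   of planted homoeologous-exchange segments (0-based half-open, ancestor
#'   chromosome names).
#' @param read_length,insert_mean,insert_sd,coverage read geometry: mate
#'   length (bp), Normal insert size (mean, sd; truncated at two read
#'   lengths) and fold coverage.
#' @param gene_spacing,gene_length gene anchors every `gene_spacing` bp
#'   (first at 10 kb), genes `gene_length` bp long (must be a multiple of
#'   3; protein length is `gene_length / 3`).
#' @param expression_prob probability that a gene is expressed at all;
#'   each RNA dataset then captures an expressed gene with probability
#'   `dataset_capture`.
#' @param dataset_capture per-dataset capture probability of an expressed
#'   gene.
#' @param ltr_spec data frame (`genome_id`, `chromosome`, `start`, `end`,
#'   `family`, `identity`) of planted LTR elements.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chromosome_length = 5e6,
                       ancestor_divergence = 0.03,
                       subgenome_drift = 0.002,
                       he_segments = default_he_segments(),
                       read_length = 150,
                       insert_mean = 550,
                       insert_sd = 50,
                       coverage = 20,
                       gene_spacing = 50000,
                       gene_length = 1500,
                       expression_prob = 0.85,
                       dataset_capture = 0.9,
                       ltr_spec = default_ltr_spec()) {
  if (ancestor_divergence < 0 || ancestor_divergence >= 0.5 ||
      subgenome_drift < 0 || subgenome_drift >= 0.5)
    stop("substitution rates must lie in [0, 0.5)")
  if (gene_spacing < 3000) stop("gene_spacing must be >= 3000 bp")
  if (gene_length %% 3 != 0) stop("gene_length must be a multiple of 3")
  if (nrow(he_segments) > 0) {
    if (any(he_segments$start < 0) ||
        any(he_segments$end > chromosome_length) ||
        any(he_segments$start >= he_segments$end))
      stop("HE segments outside chromosome bounds")
    by_chr <- split(he_segments, paste(he_segments$subgenome,
                                       he_segments$chromosome))
    for (g in by_chr) {
      g <- g[order(g$start), ]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
        stop("HE segments overlap within one chromosome")
    }
  }
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chromosome_length = chromosome_length,
                 ancestor_divergence = ancestor_divergence,
                 subgenome_drift = subgenome_drift,
                 he_segments = he_segments, read_length = read_length,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, gene_spacing = gene_spacing,
                 gene_length = gene_length,
                 expression_prob = expression_prob,
                 dataset_capture = dataset_capture,
                 ltr_spec = ltr_spec),
            class = "sim_config")
}

#' Simulate the two diverged ancestral genomes
#'
#' A common random ancestor accumulates independent substitutions at rate
#' `ancestor_divergence / 2` on each branch, so the observed A-F mismatch
#' fraction is close to `ancestor_divergence` (minus the small chance of
#' coincident hits).
#'
#' @param config a [sim_config()].
#' @return List with `A` and `F` (named character vectors of chromosome
#'   sequences `chr1..chrN`) and the two [genome_layout()]s.
#' @export
simulate_ancestors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  nms <- paste0("chr", seq_len(config$n_chromosomes))
  root <- stats::setNames(
    vapply(nms, function(i) random_dna(config$chromosome_length),
           character(1)), nms)
  half <- config$ancestor_divergence / 2
  a <- vapply(root, mutate_seq, character(1), rate = half)
  f <- vapply(root, mutate_seq, character(1), rate = half)
  list(A = a, F = f,
       layout_A = genome_layout(nms, nchar(a), "none", "avium"),
       layout_F = genome_layout(nms, nchar(f), "none", "fruticosa"))
}

#' Simulate the hybrid with planted homoeologous exchanges
#'
#' Each subgenome is its ancestor plus drift; every planted HE segment in
#' subgenome a is then overwritten with the corresponding slice of
#' (drifted) subgenome f -- a duplication-deletion event, unidirectional --
#' and symmetrically for segments planted in f.  Replacement sources are
#' the pre-exchange copies, so segments never chain.
#'
#' @param A,F named chromosome sequence vectors from [simulate_ancestors()].
#' @param config a [sim_config()].
#' @return List with `hybrid` (named sequences `chrN_a`, `chrN_f`),
#'   `layout` (hybrid [genome_layout()] with subgenome labels) and `truth`
#'   (BED-like data frame of planted segments in hybrid coordinates, with
#'   the donor subgenome).
#' @export
simulate_hybrid <- function(A, F, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  sub_a <- stats::setNames(
    vapply(A, mutate_seq, character(1), rate = config$subgenome_drift),
    paste0(names(A), "_a"))
  sub_f <- stats::setNames(
    vapply(F, mutate_seq, character(1), rate = config$subgenome_drift),
    paste0(names(F), "_f"))
  pre_a <- sub_a; pre_f <- sub_f
  he <- config$he_segments
  truth <- NULL
  for (i in seq_len(nrow(he))) {
    s <- he$start[i]; e <- he$end[i]
    if (he$subgenome[i] == "a") {
      chr <- paste0(he$chromosome[i], "_a")
      donor <- paste0(he$chromosome[i], "_f")
      substr(sub_a[chr], s + 1, e) <- substr(pre_f[donor], s + 1, e)
    } else {
      chr <- paste0(he$chromosome[i], "_f")
      donor <- paste0(he$chromosome[i], "_a")
      substr(sub_f[chr], s + 1, e) <- substr(pre_a[donor], s + 1, e)
    }
    truth <- rbind(truth, data.frame(
      chromosome = chr, start = s, end = e,
      donor_subgenome = if (he$subgenome[i] == "a") "f" else "a",
      stringsAsFactors = FALSE))
  }
  hybrid <- c(sub_a, sub_f)
  layout <- genome_layout(names(hybrid), nchar(hybrid),
                          rep(c("a", "f"), c(length(sub_a), length(sub_f))),
                          "cerasus")
  if (is.null(truth))
    truth <- data.frame(chromosome = character(), start = numeric(),
                        end = numeric(), donor_subgenome = character(),
                        stringsAsFactors = FALSE)
  list(hybrid = hybrid, layout = layout, truth = truth)
}

#' Simulate error-free paired-end reads
#'
#' Fragments are drawn uniformly (chromosomes weighted by length), inserts
#' are Normal(`insert_mean`, `insert_sd`) rounded and truncated at two read
#' lengths; mate 1 is the forward start of the fragment, mate 2 the
#' reverse complement of its end, so pairs converge with SAM semantics.
#'
#' @param genome named character vector of chromosome sequences.
#' @param config a [sim_config()]; `coverage`, `read_length`,
#'   `insert_mean`, `insert_sd` and `seed` are used.
#' @return List with `reads1`, `reads2` (character vectors) and `truth`
#'   (data frame `fragment_id`, `chromosome`, `start`, `insert`).
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$coverage <= 0) stop("coverage must be positive")
  set.seed(config$seed + 3L)
  rl <- config$read_length
  lens <- nchar(genome)
  if (any(lens < config$insert_mean))
    stop("chromosome shorter than the insert size")
  n <- round(config$coverage * sum(lens) / (2 * rl))
  chrom_idx <- sample.int(length(genome), n, replace = TRUE,
                          prob = lens / sum(lens))
  insert <- pmax(2L * rl,
                 as.integer(round(rnorm(n, config$insert_mean,
                                        config$insert_sd))))
  insert <- pmin(insert, lens[chrom_idx])
  start <- floor(runif(n) * (lens[chrom_idx] - insert + 1))
  seqs <- genome[chrom_idx]
  reads1 <- substring(seqs, start + 1, start + rl)
  reads2 <- revcomp(substring(seqs, start + insert - rl + 1, start + insert))
  list(reads1 = unname(reads1), reads2 = unname(reads2),
       truth = data.frame(fragment_id = seq_len(n),
                          chromosome = names(genome)[chrom_idx],
                          start = start, insert = insert,
                          stringsAsFactors = FALSE))
}

# gene anchors shared by the protein and RNA layers: first at 10 kb, then
# every gene_spacing, never crossing a 250-kb boundary at the defaults
gene_table <- function(hybrid_layout, truth, config) {
  rows <- lapply(seq_len(nrow(hybrid_layout)), function(i) {
    chr <- hybrid_layout$chromosome[i]
    anchors <- seq(10000, hybrid_layout$length[i] - config$gene_length,
                   by = config$gene_spacing)
    data.frame(gene_id = sprintf("%s_g%04d", chr, seq_along(anchors)),
               chromosome = chr, anchor = anchors,
               end = anchors + config$gene_length,
               subgenome = hybrid_layout$subgenome[i],
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  # sequence origin after the planted exchanges: a gene inside an HE
  # segment derives from the homoeologous ancestor
  genes$origin <- ifelse(genes$subgenome == "a", "A", "F")
  for (i in seq_len(nrow(truth))) {
    hit <- genes$chromosome == truth$chromosome[i] &
      genes$anchor >= truth$start[i] & genes$end <= truth$end[i]
    genes$origin[hit] <- ifelse(truth$donor_subgenome[i] == "a", "A", "F")
  }
  rownames(genes) <- NULL
  genes
}

#' Simulate anchored proteins and their identities to both ancestors
#'
#' One gene per anchor; the ancestral protein of each gene accumulates
#' substitutions on the A and F branches (rate `ancestor_divergence / 2`
#' each), and the hybrid protein derives from its local -- possibly
#' HE-swapped -- sequence origin plus drift.  Identities are computed with
#' [pairwise_identity()] against both ancestral proteins, so inside a
#' planted exchange on subgenome a the identity to F exceeds the identity
#' to A by construction.
#'
#' @param hybrid_layout,truth from [simulate_hybrid()].
#' @param config a [sim_config()].
#' @return List with `records` (protein records, see [protein_records()])
#'   and `genes` (the gene table with anchors, subgenome and origin used by
#'   the RNA layer).
#' @export
simulate_proteins <- function(hybrid_layout, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  genes <- gene_table(hybrid_layout, truth, config)
  plen <- config$gene_length / 3
  half <- config$ancestor_divergence / 2
  # orthologous genes (same ancestor chromosome + anchor) share one root
  ortho <- paste(sub("_[af]$", "", genes$chromosome), genes$anchor)
  roots <- new.env(parent = emptyenv())
  iaa_a <- iaa_f <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    key <- ortho[i]
    trio <- roots[[key]]
    if (is.null(trio)) {
      root <- paste(sample(AA_ALPHABET, plen, replace = TRUE),
                    collapse = "")
      trio <- list(A = mutate_seq(root, half, AA_ALPHABET),
                   F = mutate_seq(root, half, AA_ALPHABET))
      roots[[key]] <- trio
    }
    src <- if (genes$origin[i] == "A") trio$A else trio$F
    prot <- mutate_seq(src, config$subgenome_drift, AA_ALPHABET)
    iaa_a[i] <- pairwise_identity(prot, trio$A)
    iaa_f[i] <- pairwise_identity(prot, trio$F)
  }
  records <- protein_records(genes$gene_id, genes$chromosome, genes$anchor,
                             iaa_a, iaa_f)
  list(records = records, genes = genes)
}

#' Simulate species-wise RNA coverage interval sets
#'
#' Each gene is expressed with probability `expression_prob` (shared across
#' datasets).  The hybrid's own RNA is emulated as three replicate
#' datasets, each capturing an expressed gene with probability
#' `dataset_capture`; the two ancestor datasets capture expressed genes
#' whose local sequence origin matches that ancestor (HE-swapped genes are
#' therefore covered by the homoeologous ancestor's reads).
#'
#' @param genes gene table from [simulate_proteins()].
#' @param config a [sim_config()].
#' @return List of interval data frames (`chromosome`, `start`, `end`):
#'   `cerasus` (a list of three replicates), `avium`, `fruticosa`; plus the
#'   `expressed` gene table.
#' @export
simulate_rna_tracks <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 5L)
  expressed <- runif(nrow(genes)) < config$expression_prob
  iv <- function(sel) {
    data.frame(chromosome = genes$chromosome[sel],
               start = genes$anchor[sel], end = genes$end[sel],
               stringsAsFactors = FALSE)
  }
  cerasus <- lapply(1:3, function(r) {
    iv(expressed & runif(nrow(genes)) < config$dataset_capture)
  })
  list(cerasus = cerasus,
       avium = iv(expressed & genes$origin == "A"),
       fruticosa = iv(expressed & genes$origin == "F"),
       expressed = cbind(genes, expressed = expressed))
}

#' Simulate LTR element tables and pass-lists
#'
#' Elements are written exactly as specified in `config$ltr_spec` (family,
#' left-right identity, positional order); shared elements are entries of
#' the same family and identity planted in two genomes.  Deterministic: no
#' randomness is involved beyond the config itself.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, one `<genome_id>.pass.list`
#'   file per genome is written there.
#' @return List with `elements` (named list of [ltr_elements()] per genome),
#'   `truth` (the planted spec) and `paths` (written files or `NULL`).
#' @export
simulate_ltrs <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$ltr_spec
  elements <- lapply(split(spec, spec$genome_id), function(g) {
    g <- g[order(g$chromosome, g$start), , drop = FALSE]
    if (nrow(g) > 1) {
      same <- g$chromosome[-1] == g$chromosome[-nrow(g)]
      if (any(same & g$start[-1] < g$end[-nrow(g)]))
        stop("overlapping LTR elements in genome ", g$genome_id[1])
    }
    ltr_elements(g$genome_id, g$chromosome, g$start, g$end, g$family,
                 g$identity)
  })
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(names(elements), function(nm) {
      p <- file.path(dir, paste0(nm, ".pass.list"))
      write_pass_list(elements[[nm]], p)
      p
    }, character(1))
  }
  list(elements = elements, truth = spec, paths = paths)
}
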