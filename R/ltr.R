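#' LTR insertion age in generations from left-right LTR identity
#'
#' The two LTRs of a retrotransposon are identical at insertion and diverge
#' afterwards, so the insertion age follows the molecular clock
#' `T = K / (2 * mu)` with `K = 1 - identity` the left-right divergence and
#' `mu` the per-site, per-generation substitution rate.
#'
#' @param identity left-vs-right LTR identity as a fraction in [0, 1];
#'   vectorised.
#' @param mu substitution rate per site per generation; the default
#'   7.7e-9 is a Prunus-specific rate.
#' @return Insertion age in generations.
#' @examples
#' insertion_generations(0.9984)  # about 103896.1 generations
#' @export
insertion_generations <- function(identity, mu = 7.7e-9) {
  identity <- as.numeric(identity)
  if (any(is.na(identity)) || any(identity < 0) || any(identity > 1))
    stop("identity must lie in [0, 1]")
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("mu must be a single positive rate")
  (1 - identity) / (2 * mu)
}

#' Convert generations to calendar age (Mya)
#'
#' @param generations insertion age in generations (>= 0); vectorised.
#' @param years_per_generation assumed generation time in years; for
#'   long-lived trees a sweep (e.g. 10 to 60 years) is more honest than a
#'   point value.
#' @return Age in millions of years (Mya).
#' @examples
#' generations_to_mya(100000, 10)  # 1 Mya
#' @export
generations_to_mya <- function(generations, years_per_generation) {
  if (any(generations < 0) || any(years_per_generation <= 0))
    stop("generations must be >= 0 and years_per_generation > 0")
  outer_ok <- length(generations) == 1L || length(years_per_generation) == 1L
  if (!outer_ok && length(generations) != length(years_per_generation))
    stop("incompatible vector lengths")
  generations * years_per_generation / 1e6
}

#' Build a table of dated LTR elements
#'
#' @param genome_id,chromosome,start,end,family,identity element columns;
#'   `identity` is the left-right LTR identity as a fraction.
#' @param mu clock rate for the derived `t_generations` column.
#' @return Data frame of class `ltr_elements`, sorted by chromosome and
#'   start, with `t_generations = (1 - identity) / (2 * mu)`.
#' @export
ltr_elements <- function(genome_id, chromosome, start, end, family,
                         identity, mu = 7.7e-9) {
  df <- data.frame(genome_id = as.character(genome_id),
                   chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   family = as.character(family),
                   identity = as.numeric(identity),
                   stringsAsFactors = FALSE)
  df$t_generations <- insertion_generations(df$identity, mu)
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "mu") <- mu
  class(df) <- c("ltr_elements", "data.frame")
  df
}

#' Parse an EDTA-style pass-list of intact LTR retrotransposons
#'
#' Expects the tab-separated `.pass.list` layout whose first column is the
#' element location (`chrom:start..end`), with an `Identity` column (the
#' left-right LTR identity) and a `SuperFamily` classification column.
#' Malformed rows are skipped with a warning that reports their count.
#'
#' @param path pass-list TSV.
#' @param genome_id genome label attached to the parsed elements.
#' @param mu clock rate used to date the elements.
#' @return An [ltr_elements()] data frame (possibly empty).
#' @export
parse_pass_list <- function(path, genome_id = "genome", mu = 7.7e-9) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- ltr_elements(character(), character(), numeric(), numeric(),
                        character(), numeric(), mu)
  if (length(lines) == 0L) {
    warning("empty pass-list: ", path)
    return(empty)
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  id_col <- grep("^#?LTR_loc$|^#?loc", header, ignore.case = TRUE)[1]
  ident_col <- grep("^Identity$", header, ignore.case = TRUE)[1]
  fam_col <- grep("^SuperFamily$|^Family$", header, ignore.case = TRUE)[1]
  if (is.na(ident_col)) stop("pass-list has no Identity column")
  if (is.na(id_col)) id_col <- 1L
  if (length(lines) == 1L) return(empty)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  parsed <- lapply(rows, function(f) {
    if (length(f) < max(id_col, ident_col, fam_col, na.rm = TRUE))
      return(NULL)
    m <- regmatches(f[id_col],
                    regexec("^(.+):([0-9]+)\\.\\.([0-9]+)$", f[id_col]))[[1]]
    ident <- suppressWarnings(as.numeric(f[ident_col]))
    if (length(m) != 4L || is.na(ident) || ident < 0 || ident > 1)
      return(NULL)
    data.frame(chromosome = m[2],
               start = as.numeric(m[3]) - 1, end = as.numeric(m[4]),
               family = if (is.na(fam_col)) "unknown" else f[fam_col],
               identity = ident, stringsAsFactors = FALSE)
  })
  bad <- sum(vapply(parsed, is.null, logical(1)))
  if (bad > 0L)
    warning(bad, " malformed pass-list row(s) skipped in ", path)
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  if (length(parsed) == 0L) return(empty)
  tab <- do.call(rbind, parsed)
  ltr_elements(genome_id, tab$chromosome, tab$start, tab$end, tab$family,
               tab$identity, mu)
}

#' Write LTR elements in the pass-list layout
#'
#' @param elements an [ltr_elements()] data frame.
#' @param path output TSV.
#' @export
write_pass_list <- function(elements, path) {
  tab <- data.frame(
    "LTR_loc" = sprintf("%s:%d..%d", elements$chromosome,
                        as.integer(elements$start) + 1L,
                        as.integer(elements$end)),
    Category = "LTR", Motif = "TGCA", TSD = "NA",
    Identity = format(elements$identity, digits = 10),
    Strand = "+", SuperFamily = elements$family,
    stringsAsFactors = FALSE, check.names = FALSE)
  names(tab)[1] <- "#LTR_loc"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# maximum one-to-one matching without order constraint (Kuhn's algorithm)
max_bipartite_match <- function(ok) {
  n <- nrow(ok); m <- ncol(ok)
  match_j <- integer(m)  # j -> i, 0 = unmatched
  env <- environment()
  augment <- function(i) {
    for (j in which(ok[i, ])) {
      if (!env$seen[j]) {
        env$seen[j] <- TRUE
        if (env$match_j[j] == 0L || augment(env$match_j[j])) {
          env$match_j[j] <- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (i in seq_len(n)) {
    env$seen <- rep(FALSE, m)
    augment(i)
  }
  j <- which(match_j > 0L)
  pairs <- cbind(match_j[j], j)
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# order-preserving maximum matching of compatible elements (LCS-style DP)
collinear_match <- function(ok) {
  n <- nrow(ok); m <- ncol(ok)
  L <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1, j + 1] <- if (ok[i, j]) L[i, j] + 1L else
        max(L[i, j + 1], L[i + 1, j])
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (ok[i, j] && L[i + 1, j + 1] == L[i, j] + 1L) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1] >= L[i + 1, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  pairs
}

#' Match shared LTR elements across two (sub)genomes
#'
#' Candidate pairs must be of the same family and have left-right LTR
#' identities within `identity_tolerance` of each other ("same type with
#' the same insertion time").  With `enforce_order = TRUE` the reported set
#' is a maximum-cardinality collinear matching per chromosome pair
#' (order-preserving, LCS-style dynamic programming); each element is
#' matched at most once.
#'
#' @param elements_1,elements_2 [ltr_elements()] tables from two genomes.
#' @param identity_tolerance maximum identity difference of a pair
#'   (default 1e-4, about 6,500 generations at the default clock rate).
#' @param enforce_order require positional collinearity (default TRUE).
#' @param chromosome_pairs optional data frame (`chromosome_1`,
#'   `chromosome_2`) of homologous chromosome pairs to compare; defaults to
#'   all chromosome combinations present in the two tables.
#' @return Data frame with one row per matched pair: chromosome, position,
#'   family and identity of both elements plus `delta_t` (absolute
#'   insertion-age difference in generations, using each table's clock).
#' @export
match_shared_ltrs <- function(elements_1, elements_2,
                              identity_tolerance = 1e-4,
                              enforce_order = TRUE,
                              chromosome_pairs = NULL) {
  for (el in list(elements_1, elements_2)) {
    o <- order(el$chromosome, el$start)
    if (!identical(o, seq_len(nrow(el))))
      stop("elements must be sorted by (chromosome, start)")
  }
  if (is.null(chromosome_pairs))
    chromosome_pairs <- expand.grid(
      chromosome_1 = unique(elements_1$chromosome),
      chromosome_2 = unique(elements_2$chromosome),
      stringsAsFactors = FALSE)
  res <- list()
  for (p in seq_len(nrow(chromosome_pairs))) {
    e1 <- elements_1[elements_1$chromosome ==
                       chromosome_pairs$chromosome_1[p], , drop = FALSE]
    e2 <- elements_2[elements_2$chromosome ==
                       chromosome_pairs$chromosome_2[p], , drop = FALSE]
    if (nrow(e1) == 0L || nrow(e2) == 0L) next
    ok <- outer(e1$family, e2$family, "==") &
      abs(outer(e1$identity, e2$identity, "-")) <= identity_tolerance
    if (!any(ok)) next
    pairs <- if (enforce_order) collinear_match(ok) else
      max_bipartite_match(ok)
    if (nrow(pairs) == 0L) next
    i <- pairs[, 1]; j <- pairs[, 2]
    res[[length(res) + 1L]] <- data.frame(
      chromosome_1 = e1$chromosome[i], start_1 = e1$start[i],
      chromosome_2 = e2$chromosome[j], start_2 = e2$start[j],
      family = e1$family[i],
      identity_1 = e1$identity[i], identity_2 = e2$identity[j],
      t_generations_1 = e1$t_generations[i],
      t_generations_2 = e2$t_generations[j],
      delta_t = abs(e1$t_generations[i] - e2$t_generations[j]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chromosome_1 = character(), start_1 = numeric(),
               chromosome_2 = character(), start_2 = numeric(),
               family = character(), identity_1 = numeric(),
               identity_2 = numeric(), t_generations_1 = numeric(),
               t_generations_2 = numeric(), delta_t = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Youngest shared insertion between two element tables
#'
#' Convenience wrapper: matches shared elements and returns the smallest
#' mean insertion age among the matched pairs, in generations (rounded to
#' one decimal as in reporting; full precision via `round_digits = NULL`).
#'
#' @inheritParams match_shared_ltrs
#' @param round_digits decimals to round to (default 1), or `NULL`.
#' @return Single numeric, `NA` when nothing matches.
#' @export
youngest_shared_ltr <- function(elements_1, elements_2,
                                identity_tolerance = 1e-4,
                                enforce_order = TRUE,
                                chromosome_pairs = NULL,
                                round_digits = 1) {
  m <- match_shared_ltrs(elements_1, elements_2, identity_tolerance,
                         enforce_order, chromosome_pairs)
  if (nrow(m) == 0L) return(NA_real_)
  t <- min((m$t_generations_1 + m$t_generations_2) / 2)
  if (is.null(round_digits)) t else round(t, round_digits)
}
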