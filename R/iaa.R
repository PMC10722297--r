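AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Percent amino-acid identity from a global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and a linear
#' gap penalty of -1 per gap column; identity is 100 * matches / alignment
#' columns of an optimal-score alignment.  This is the built-in stand-in
#' identity calculator used for synthetic protein data; real data normally
#' arrive with precomputed identities (see [read_protein_tsv()]).
#'
#' @param seq1,seq2 non-empty protein sequences over the 20-letter alphabet.
#' @return Percent identity in [0, 100], with the alignment `score`,
#'   `matches` and `columns` attached as attributes.
#' @examples
#' pairwise_identity("MKVLA", "MKVLA")  # 100
#' @export
pairwise_identity <- function(seq1, seq2) {
  chk <- function(s, arg) {
    if (!is.character(s) || length(s) != 1L || nchar(s) == 0L)
      stop(arg, " must be a single non-empty sequence")
    if (!all(strsplit(toupper(s), "")[[1]] %in% AA_ALPHABET))
      stop(arg, " contains non-amino-acid symbols")
  }
  chk(seq1, "seq1"); chk(seq2, "seq2")
  r <- cpp_global_identity(toupper(seq1), toupper(seq2))
  structure(unname(r["identity"]), score = unname(r["score"]),
            matches = unname(r["matches"]), columns = unname(r["columns"]))
}

#' Assign each protein to the more similar ancestor
#'
#' @param iaa_a,iaa_f percent identity to ancestor A / ancestor F (`NA` for
#'   missing).  A record with only one identity present is assigned to that
#'   ancestor; a record with both missing is `unassigned`.
#' @param tie_epsilon identities within this margin (percent points) of each
#'   other count as a tie (default 0, exact equality).
#' @return Factor with levels `A_higher`, `F_higher`, `tie`, `unassigned`.
#' @export
assign_similarity <- function(iaa_a, iaa_f, tie_epsilon = 0) {
  if (tie_epsilon < 0) stop("tie_epsilon must be >= 0")
  n <- max(length(iaa_a), length(iaa_f))
  iaa_a <- rep_len(as.numeric(iaa_a), n)
  iaa_f <- rep_len(as.numeric(iaa_f), n)
  out <- rep("unassigned", n)
  both <- !is.na(iaa_a) & !is.na(iaa_f)
  out[both & (iaa_a - iaa_f > tie_epsilon)] <- "A_higher"
  out[both & (iaa_f - iaa_a > tie_epsilon)] <- "F_higher"
  out[both & abs(iaa_a - iaa_f) <= tie_epsilon] <- "tie"
  out[!is.na(iaa_a) & is.na(iaa_f)] <- "A_higher"
  out[is.na(iaa_a) & !is.na(iaa_f)] <- "F_higher"
  factor(out, levels = c("A_higher", "F_higher", "tie", "unassigned"))
}

#' Build or read anchored protein identity records
#'
#' A protein record carries the chromosome and coding-region start (0-based
#' `anchor`) of a hybrid protein and its percent identity to the best
#' homolog in each ancestral annotation.  When a protein appears several
#' times (several reference transcripts of one ancestor), the maximum
#' identity per ancestor is kept.
#'
#' @param protein_id,chromosome,anchor,iaa_a,iaa_f record columns.
#' @return Data frame with those five columns, one row per protein.
#' @export
protein_records <- function(protein_id, chromosome, anchor, iaa_a, iaa_f) {
  df <- data.frame(protein_id = as.character(protein_id),
                   chromosome = as.character(chromosome),
                   anchor = as.numeric(anchor),
                   iaa_a = as.numeric(iaa_a), iaa_f = as.numeric(iaa_f),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$protein_id)) {
    mx <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    sp <- split(df, df$protein_id)
    df <- do.call(rbind, lapply(sp, function(g) {
      g$iaa_a[1] <- mx(g$iaa_a); g$iaa_f[1] <- mx(g$iaa_f); g[1, ]
    }))
    df <- df[order(df$chromosome, df$anchor, df$protein_id), ]
    rownames(df) <- NULL
  }
  df
}

#' @rdname protein_records
#' @param path TSV with columns `protein_id`, `chromosome`, `anchor`,
#'   `iaa_a`, `iaa_f`.
#' @export
read_protein_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "chromosome", "anchor", "iaa_a", "iaa_f")
  if (!all(need %in% names(tab)))
    stop("protein TSV needs columns: ", paste(need, collapse = ", "))
  protein_records(tab$protein_id, tab$chromosome, tab$anchor,
                  tab$iaa_a, tab$iaa_f)
}

check_anchors <- function(records, layout) {
  len <- layout$length[match(records$chromosome, layout$chromosome)]
  if (anyNA(len)) stop("protein on a chromosome absent from the layout")
  if (any(records$anchor < 0) || any(records$anchor >= len))
    stop("protein anchor outside chromosome bounds")
}

#' Protein-identity HE evidence on 250-kb windows
#'
#' Within each window (a protein belongs to the window containing its coding
#' start) the assigned proteins are split into those more similar to
#' ancestor A, more similar to ancestor F, and ties; the three percentages
#' close to 100.  On a subgenome-a window the expectation is a majority of
#' A-similar proteins, so the window is flagged when the percentage similar
#' to the own ancestor is strictly smaller than the percentage similar to
#' the homoeologous one (mirror on subgenome f).
#'
#' @param records protein records (see [protein_records()]).
#' @param hybrid_layout hybrid [genome_layout()] with subgenome labels.
#' @param window_size window width in bp (default 250000).
#' @param tie_epsilon tie margin passed to [assign_similarity()].
#' @return Data frame (class `iaa_evidence`): the window grid plus
#'   `n_proteins`, `pct_a_higher`, `pct_f_higher`, `pct_tie`, `iaa_diff`
#'   (= `pct_f_higher - pct_a_higher`), `flag_iaa`, `no_data`.
#' @export
iaa_evidence <- function(records, hybrid_layout, window_size = 250000,
                         tie_epsilon = 0) {
  stopifnot(inherits(hybrid_layout, "genome_layout"))
  if (any(hybrid_layout$subgenome == "none"))
    stop("hybrid layout has unlabelled subgenomes")
  check_anchors(records, hybrid_layout)
  grid <- make_windows(hybrid_layout, window_size)
  cls <- assign_similarity(records$iaa_a, records$iaa_f, tie_epsilon)
  assigned <- cls != "unassigned"
  key <- paste(records$chromosome, records$anchor %/% window_size)
  gkey <- paste(grid$chromosome, grid$index)
  tab <- table(factor(key[assigned], levels = gkey),
               factor(as.character(cls[assigned]),
                      levels = c("A_higher", "F_higher", "tie")))
  n <- rowSums(tab)
  pct <- sweep(tab, 1, pmax(n, 1), "/") * 100
  out <- grid
  out$n_proteins <- as.integer(n)
  out$pct_a_higher <- pct[, "A_higher"]
  out$pct_f_higher <- pct[, "F_higher"]
  out$pct_tie <- pct[, "tie"]
  out$iaa_diff <- out$pct_f_higher - out$pct_a_higher
  out$no_data <- n == 0
  on_a <- out$subgenome == "a"
  pct_intra <- ifelse(on_a, out$pct_a_higher, out$pct_f_higher)
  pct_inter <- ifelse(on_a, out$pct_f_higher, out$pct_a_higher)
  out$flag_iaa <- !out$no_data & pct_intra < pct_inter
  class(out) <- c("iaa_evidence", class(grid))
  out
}

#' 70 percent quantile confirmation on 1-Mb windows
#'
#' Per 1-Mb window the 70% quantile (linear interpolation between order
#' statistics, R quantile type 7) of the identities to the homologous
#' ancestor and of the identities to the homoeologous ancestor are compared;
#' the window is confirmed when the homoeologous quantile is strictly
#' larger.  Windows without any protein carrying the needed identity are
#' `no_data`.
#'
#' @param records protein records.
#' @param hybrid_layout hybrid layout with subgenome labels.
#' @param window_size confirmation window width (default 1000000).
#' @return Data frame (class `q70_confirmation`): the window grid plus
#'   `q70_homologous`, `q70_homoeologous`, `confirm_q70`, `no_data`.
#' @export
quantile70_confirm <- function(records, hybrid_layout,
                               window_size = 1000000) {
  stopifnot(inherits(hybrid_layout, "genome_layout"))
  if (any(hybrid_layout$subgenome == "none"))
    stop("hybrid layout has unlabelled subgenomes")
  check_anchors(records, hybrid_layout)
  grid <- make_windows(hybrid_layout, window_size)
  sub <- hybrid_layout$subgenome[match(records$chromosome,
                                       hybrid_layout$chromosome)]
  homol <- ifelse(sub == "a", records$iaa_a, records$iaa_f)
  homoeo <- ifelse(sub == "a", records$iaa_f, records$iaa_a)
  key <- paste(records$chromosome, records$anchor %/% window_size)
  gkey <- paste(grid$chromosome, grid$index)
  q70 <- function(vals) {
    vapply(gkey, function(k) {
      x <- vals[key == k]
      x <- x[!is.na(x)]
      if (length(x) == 0L) NA_real_ else
        unname(quantile(x, 0.7, type = 7))
    }, numeric(1), USE.NAMES = FALSE)
  }
  out <- grid
  out$q70_homologous <- q70(homol)
  out$q70_homoeologous <- q70(homoeo)
  out$no_data <- is.na(out$q70_homologous) | is.na(out$q70_homoeologous)
  out$confirm_q70 <- !out$no_data &
    out$q70_homoeologous > out$q70_homologous
  class(out) <- c("q70_confirmation", class(grid))
  out
}

#' Per-chromosome summary of protein ancestor assignment
#'
#' Reproduces the layout of a per-chromosome transcript comparison table:
#' total transcripts, transcripts with a homolog in each donor annotation,
#' transcripts shared with both, and -- over the shared ones -- the
#' fractions with higher identity to F, tied, and higher to A.
#'
#' @param records protein records.
#' @param layout optional layout supplying the subgenome label per
#'   chromosome.
#' @param tie_epsilon tie margin (percent points).
#' @return Data frame with one row per chromosome: `chromosome`,
#'   `subgenome`, `n_transcripts`, `n_from_pf`, `n_from_pa`, `n_shared`,
#'   `frac_higher_pf`, `frac_tie`, `frac_higher_pa`.
#' @export
summarize_chromosomes <- function(records, layout = NULL, tie_epsilon = 0) {
  if (nrow(records) == 0L)
    return(data.frame(chromosome = character(), subgenome = character(),
                      n_transcripts = integer(), n_from_pf = integer(),
                      n_from_pa = integer(), n_shared = integer(),
                      frac_higher_pf = numeric(), frac_tie = numeric(),
                      frac_higher_pa = numeric(), stringsAsFactors = FALSE))
  chroms <- if (is.null(layout)) unique(records$chromosome) else
    layout$chromosome[layout$chromosome %in% records$chromosome]
  rows <- lapply(chroms, function(chr) {
    g <- records[records$chromosome == chr, , drop = FALSE]
    shared <- !is.na(g$iaa_a) & !is.na(g$iaa_f)
    cls <- assign_similarity(g$iaa_a[shared], g$iaa_f[shared], tie_epsilon)
    ns <- sum(shared)
    data.frame(chromosome = chr,
               subgenome = if (is.null(layout)) "none" else
                 layout$subgenome[layout$chromosome == chr],
               n_transcripts = nrow(g),
               n_from_pf = sum(!is.na(g$iaa_f)),
               n_from_pa = sum(!is.na(g$iaa_a)),
               n_shared = ns,
               frac_higher_pf = if (ns) mean(cls == "F_higher") else NA_real_,
               frac_tie = if (ns) mean(cls == "tie") else NA_real_,
               frac_higher_pa = if (ns) mean(cls == "A_higher") else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a per-chromosome summary to subgenome and genome level
#'
#' Count columns are column sums; the fraction columns are recomputed as
#' shared-count-weighted means, so each output row closes to 1 up to
#' rounding of the inputs.
#'
#' @param summary a per-chromosome summary data frame (see
#'   [summarize_chromosomes()] for the expected columns).
#' @param by column to group on before summing (default `"subgenome"`).
#' @return Data frame with one row per group plus a `"total"` row.
#' @export
aggregate_summary <- function(summary, by = "subgenome") {
  groups <- split(summary, summary[[by]])
  groups <- c(groups, list(total = summary))
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    w <- g$n_shared / sum(g$n_shared)
    data.frame(group = nm,
               n_transcripts = sum(g$n_transcripts),
               n_from_pf = sum(g$n_from_pf),
               n_from_pa = sum(g$n_from_pa),
               n_shared = sum(g$n_shared),
               frac_higher_pf = sum(w * g$frac_higher_pf),
               frac_tie = sum(w * g$frac_tie),
               frac_higher_pa = sum(w * g$frac_higher_pa),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
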