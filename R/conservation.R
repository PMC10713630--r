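## Alignment-based conservation statistics: per-column composition,
## consensus-logo matrices (probability or information-content bits),
## and pocket identity/similarity percentages between sequence pairs.
## "Similarity" is group-based: two residues are similar when they share
## a similarity group (identity is within-group by definition, so
## identity <= similarity always).

.aln_matrix <- function(alignment) {
  do.call(rbind, strsplit(unname(alignment$sequences), ""))
}

#' Per-column composition of an alignment
#'
#' @param alignment [Alignment].
#' @param positions columns to analyse (default all).
#' @param include_gaps include gaps in the frequency denominator
#'   (default FALSE: frequencies are over non-gap symbols).
#' @return object of class `ColumnStats`: `counts` (position x symbol),
#'   `frequencies` (rows sum to 1 where any non-gap symbol exists),
#'   `consensus` (modal residue, ties alphabetical; NA for all-gap
#'   columns, which are also flagged in `all_gap`), `gap_fraction`,
#'   `positions`, `gaps_included`.
#' @export
column_stats <- function(alignment, positions = seq_len(alignment$length),
                         include_gaps = FALSE) {
  if (any(positions < 1 | positions > alignment$length))
    stop("positions out of range 1..", alignment$length)
  m <- .aln_matrix(alignment)[, positions, drop = FALSE]
  syms <- c(.aa1, "X", if (include_gaps) "-")
  counts <- t(apply(m, 2, function(col) {
    tab <- table(factor(col[include_gaps | col != "-"], levels = syms))
    as.integer(tab)
  }))
  colnames(counts) <- syms
  rownames(counts) <- positions
  totals <- rowSums(counts)
  freqs <- counts / ifelse(totals == 0, 1, totals)
  gap_fraction <- apply(m, 2, function(col) mean(col == "-"))
  all_gap <- apply(m, 2, function(col) all(col == "-"))
  if (any(all_gap))
    warning("all-gap column(s) at position(s): ",
            paste(positions[all_gap], collapse = ", "))
  consensus <- vapply(seq_len(nrow(counts)), function(i) {
    if (all_gap[i]) return(NA_character_)
    cnt <- counts[i, setdiff(syms, "-"), drop = TRUE]
    best <- names(cnt)[cnt == max(cnt)]
    sort(best)[1]  # ties broken alphabetically
  }, character(1))
  structure(list(counts = counts, frequencies = freqs,
                 consensus = consensus, gap_fraction = gap_fraction,
                 all_gap = all_gap, positions = positions,
                 gaps_included = include_gaps),
            class = "ColumnStats")
}

#' @export
print.ColumnStats <- function(x, ...) {
  cat(sprintf("ColumnStats: %d columns, consensus %s%s\n",
              length(x$positions),
              paste(utils::head(x$consensus, 30), collapse = ""),
              if (length(x$positions) > 30) "..." else ""))
  invisible(x)
}

#' Pocket identity and similarity between two aligned sequences
#'
#' Over the given alignment columns, computes
#' `identity = 100 * matches / compared` and
#' `similarity = 100 * (matches + same-group pairs) / compared`, where
#' positions gapped in either sequence are excluded from the denominator
#' (reported in `n_excluded`).
#'
#' @param alignment [Alignment].
#' @param idA,idB sequence ids.
#' @param positions alignment columns of the pocket (default all).
#' @param groups similarity groups (default
#'   [default_similarity_groups()]).
#' @return object of class `PocketConservation`: `identity_pct`,
#'   `similarity_pct`, `n_compared`, `n_excluded`, `positions`, `pair`.
#' @export
pocket_identity <- function(alignment, idA, idB,
                            positions = seq_len(alignment$length),
                            groups = default_similarity_groups()) {
  for (id in c(idA, idB))
    if (!id %in% names(alignment$sequences))
      stop("sequence id not in alignment: ", id)
  if (any(positions < 1 | positions > alignment$length))
    stop("positions out of range 1..", alignment$length)
  a <- strsplit(alignment$sequences[[idA]], "")[[1]][positions]
  b <- strsplit(alignment$sequences[[idB]], "")[[1]][positions]
  gap <- a == "-" | b == "-"
  if (all(gap)) stop("all selected positions are gapped in the pair")
  a <- a[!gap]; b <- b[!gap]
  group_of <- unlist(lapply(names(groups), function(g)
    stats::setNames(rep(g, length(groups[[g]])), groups[[g]])))
  ident <- a == b
  ga <- group_of[a]; gb <- group_of[b]
  similar <- ident | (!is.na(ga) & !is.na(gb) & ga == gb)
  n <- length(a)
  structure(list(identity_pct = 100 * sum(ident) / n,
                 similarity_pct = 100 * sum(similar) / n,
                 n_compared = n, n_excluded = sum(gap),
                 positions = positions, pair = c(idA, idB),
                 groups = groups),
            class = "PocketConservation")
}

#' @export
print.PocketConservation <- function(x, ...) {
  cat(sprintf("PocketConservation %s vs %s: %.1f%% identity, %.1f%% similarity over %d positions (%d gapped excluded)\n",
              x$pair[1], x$pair[2], x$identity_pct, x$similarity_pct,
              x$n_compared, x$n_excluded))
  invisible(x)
}

#' Sequence-logo matrix
#'
#' Per-column residue weights for logo rendering: `"probability"` rows
#' are non-gap frequencies (sum to 1); `"bits"` rows are
#' `p * IC` with `IC = log2(20) - H(column)` (Shannon entropy over the
#' 20 residues), so an invariant column carries `log2(20) ~ 4.32` bits
#' on its single residue and a uniform column carries 0.
#'
#' @param alignment [Alignment].
#' @param positions columns (default all).
#' @param units `"probability"` or `"bits"`.
#' @return numeric matrix, positions x 20 residues.
#' @export
logo_matrix <- function(alignment, positions = seq_len(alignment$length),
                        units = c("probability", "bits")) {
  units <- match.arg(units)
  cs <- column_stats(alignment, positions, include_gaps = FALSE)
  p <- cs$frequencies[, .aa1, drop = FALSE]
  # renormalise over the 20 residues (drops X)
  tot <- rowSums(p)
  p <- p / ifelse(tot == 0, 1, tot)
  if (units == "probability") return(p)
  H <- apply(p, 1, function(row) {
    nz <- row[row > 0]
    -sum(nz * log2(nz))
  })
  ic <- pmax(log2(20) - H, 0)
  p * ic
}

#' Write a conservation or logo matrix as TSV
#'
#' @param m matrix from [logo_matrix()] (or any position x residue
#'   matrix).
#' @param path output file.
#' @param header_lines optional comment lines.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(m, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  df <- data.frame(position = rownames(m), round(m, 6),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
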