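# Instrument selection and grading: genome-wide significance filtering,
# greedy LD pruning against a user-supplied r^2 matrix, and per-SNP
# instrument-strength statistics.

#' Genome-wide significance filter
#'
#' Keeps associations with `pvalue < p_threshold` (strictly below, the
#' conventional genome-wide rule), preserving input order. Idempotent.
#'
#' @param assocs Associations data frame with `pvalue` present for all
#'   rows.
#' @param p_threshold Significance level; default `5e-8`.
#' @return The filtered associations data frame.
#' @export
gw_filter <- function(assocs, p_threshold = 5e-8) {
  if (nrow(assocs) > 0 && anyNA(assocs$pvalue)) {
    stop("gw_filter: pvalue missing for ",
         paste(assocs$rsid[is.na(assocs$pvalue)], collapse = ", "))
  }
  out <- assocs[assocs$pvalue < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD pruning
#'
#' Repeatedly keeps the remaining variant with the smallest p-value and
#' removes every other variant in linkage disequilibrium with it at
#' `r2 >= r2_threshold`. The result is a set with all pairwise
#' `r2 < r2_threshold`; given distinct p-values it does not depend on
#' input order. Ties in p-value are broken by lexicographic rsid order.
#'
#' @param assocs Associations data frame.
#' @param r2_matrix Symmetric numeric matrix of pairwise r² with rsid
#'   dimnames covering all variants in `assocs` (see
#'   [read_r2_matrix()]).
#' @param r2_threshold Pruning threshold; default 0.01, i.e. near-complete
#'   independence.
#' @return The pruned associations data frame, ordered by selection
#'   (ascending p-value).
#' @export
ld_prune <- function(assocs, r2_matrix, r2_threshold = 0.01) {
  ids <- assocs$rsid
  missing <- setdiff(ids, rownames(r2_matrix))
  if (length(missing) > 0 || !all(ids %in% colnames(r2_matrix))) {
    stop("ld_prune: r2 matrix does not cover ",
         paste(union(missing, setdiff(ids, colnames(r2_matrix))),
               collapse = ", "))
  }
  remaining <- ids[order(assocs$pvalue, ids)]
  kept <- character(0)
  while (length(remaining) > 0) {
    top <- remaining[1]
    kept <- c(kept, top)
    linked <- remaining[r2_matrix[top, remaining] >= r2_threshold]
    remaining <- setdiff(remaining, union(top, linked))
  }
  out <- assocs[match(kept, assocs$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pairwise r² matrix from a square TSV
#'
#' The file carries rsid column headers and rsid row labels in the first
#' column.
#'
#' @param path Path to the TSV.
#' @return A symmetric numeric matrix with rsid dimnames.
#' @export
read_r2_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Instrument-strength report
#'
#' Per-variant strength statistics. Two F formulations are reported
#' because published instrument tables rarely state which was used:
#' \itemize{
#'   \item `f_stat_wald = (beta/se)^2`, the squared Wald z — always
#'     available;
#'   \item `f_stat_r2 = r2 * (n - 2) / (1 - r2)` with per-SNP variance
#'     explained `r2 = 2 * eaf * (1 - eaf) * beta^2` (trait standardized)
#'     — only when EAF and sample size are present.
#' }
#' `F > 10` is the conventional bar for a strong instrument;
#' `pass_gw_significance` additionally records the `p < 5e-8` filter.
#'
#' @param assocs Associations data frame (one or more rows).
#' @param p_threshold Genome-wide significance level for the pass flag.
#' @return Data frame with columns `rsid`, `pass_gw_significance`,
#'   `f_stat_wald`, `r2_explained`, `f_stat_r2` (the last two `NA` when
#'   EAF or N is missing).
#' @export
f_statistic <- function(assocs, p_threshold = 5e-8) {
  if (any(assocs$se <= 0)) stop("f_statistic: se must be > 0")
  r2 <- 2 * assocs$eaf * (1 - assocs$eaf) * assocs$beta^2
  r2[is.na(assocs$eaf) | is.na(assocs$n)] <- NA_real_
  if (any(!is.na(r2) & r2 >= 1)) {
    stop("f_statistic: variance explained >= 1 for ",
         paste(assocs$rsid[!is.na(r2) & r2 >= 1], collapse = ", "),
         "; inputs are inconsistent with a standardized trait")
  }
  data.frame(
    rsid = assocs$rsid,
    pass_gw_significance = !is.na(assocs$pvalue) &
      assocs$pvalue < p_threshold,
    f_stat_wald = (assocs$beta / assocs$se)^2,
    r2_explained = r2,
    f_stat_r2 = r2 * (assocs$n - 2) / (1 - r2),
    stringsAsFactors = FALSE
  )
}
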