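# Reading, validating and harmonizing GWAS summary statistics.
#
# A summary-statistics table ("associations" below) has one row per variant
# with columns rsid, effect_allele, other_allele, beta, se, pvalue, eaf, n,
# trait, trait_type. beta is the per-allele effect of the effect allele:
# SD units for continuous traits, log odds for binary ones.

ASSOC_COLS <- c("rsid", "effect_allele", "other_allele", "beta", "se",
                "pvalue", "eaf", "n", "trait", "trait_type")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

# Validate one associations data frame; returns a character vector of
# per-row failure reasons ("" where the row is fine).
assoc_row_problems <- function(df) {
  reason <- character(nrow(df))
  bad <- !is.na(df$se) & df$se <= 0 | is.na(df$se)
  reason[bad] <- "se must be > 0"
  bad <- !(df$effect_allele %in% names(COMPLEMENT)) |
    !(df$other_allele %in% names(COMPLEMENT))
  reason[bad & reason == ""] <- "alleles must be single bases A/C/G/T"
  bad <- df$effect_allele == df$other_allele
  reason[bad & reason == ""] <- "effect and other allele identical"
  bad <- !is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1)
  reason[bad & reason == ""] <- "pvalue outside (0, 1]"
  bad <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  reason[bad & reason == ""] <- "eaf outside [0, 1]"
  reason
}

# Guess the field separator of a delimited text file from its header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-bearing delimited table (tab, comma or whitespace
#' separated — auto-detected unless `delim` is given), renames columns
#' through `column_map`, upper-cases alleles, and validates every row
#' against the association invariants (positive SE, distinct A/C/G/T
#' alleles, p in (0,1], EAF in [0,1]).
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector mapping canonical field names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, and optionally
#'   `pvalue`, `eaf`, `n`) to the file's column names. `NULL` means the
#'   file already uses canonical names.
#' @param trait Trait label attached to every row.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param strict If `TRUE` (default) any invalid row is a fatal error
#'   naming the offending rsid; if `FALSE` invalid rows are dropped with a
#'   warning listing the reasons.
#' @param delim Field separator; `NULL` auto-detects.
#' @return A validated associations data frame with the canonical columns,
#'   input row order preserved.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait = "trait",
                               trait_type = c("continuous", "binary"),
                               strict = TRUE, delim = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(raw))
    if (length(missing) > 0) {
      stop("read_summary_stats: mapped column(s) absent from ", path, ": ",
           paste(missing, collapse = ", "))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("read_summary_stats: required column(s) missing: ",
         paste(missing, collapse = ", "))
  }
  df <- data.frame(
    rsid = as.character(raw$rsid),
    effect_allele = toupper(as.character(raw$effect_allele)),
    other_allele = toupper(as.character(raw$other_allele)),
    beta = as.numeric(raw$beta),
    se = as.numeric(raw$se),
    pvalue = if ("pvalue" %in% names(raw)) as.numeric(raw$pvalue) else NA_real_,
    eaf = if ("eaf" %in% names(raw)) as.numeric(raw$eaf) else NA_real_,
    n = if ("n" %in% names(raw)) as.integer(raw$n) else NA_integer_,
    trait = trait,
    trait_type = trait_type,
    stringsAsFactors = FALSE
  )
  problems <- assoc_row_problems(df)
  if (any(problems != "")) {
    bad <- which(problems != "")
    msg <- paste0(df$rsid[bad], ": ", problems[bad], collapse = "; ")
    if (strict) stop("read_summary_stats: invalid row(s) — ", msg)
    warning("read_summary_stats: dropping invalid row(s) — ", msg)
    df <- df[-bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write summary statistics as TSV
#'
#' Inverse of [read_summary_stats()]: well-formed tables round-trip with
#' all fields preserved.
#'
#' @param assocs Associations data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(assocs, path) {
  utils::write.table(assocs[, ASSOC_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-orient an exposure to its decreasing direction
#'
#' Expresses every association per SD *decrease* of the exposure trait by
#' negating the betas — a sign flip of the trait itself, so allele labels
#' and frequencies are untouched and downstream harmonization is
#' unaffected. Used for transferrin, which falls as systemic iron status
#' rises, so that causal estimates for all four iron indicators point the
#' same way: the resulting MR estimate is exactly the negative of the
#' increasing-direction one. `direction = "increase"` is the identity;
#' applying `"decrease"` twice restores the input. (Note this is a trait
#' re-scaling, not an allele re-encoding: swapping effect/other alleles
#' together with the sign would describe the identical association and
#' leave every estimate unchanged.)
#'
#' @param assocs Associations data frame.
#' @param direction `"increase"` (identity) or `"decrease"`.
#' @return The re-oriented associations data frame.
#' @export
orient_exposure <- function(assocs, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (nrow(assocs) == 0L) stop("orient_exposure: empty association list")
  if (direction == "increase") return(assocs)
  out <- assocs
  out$beta <- -assocs$beta
  out
}

#' Harmonize exposure and outcome associations to a shared effect allele
#'
#' For every rsid present in both tables, aligns the outcome record to the
#' exposure's effect allele:
#' \itemize{
#'   \item alleles already match: copied through;
#'   \item alleles swapped: outcome beta negated, EAF reflected, flagged
#'     `flipped`;
#'   \item alleles on the opposite strand (complementary): complemented
#'     first, then the same match/swap logic;
#'   \item palindromic variants (A/T or C/G), whose strand cannot be
#'     resolved from alleles: handled per `palindromic_policy` — under
#'     `"drop_ambiguous"` (default) they are dropped when either EAF is
#'     missing or lies within `eaf_ambiguity_window` of 0.5, otherwise
#'     aligned by comparing which side of 0.5 the two frequencies fall on;
#'   \item anything else (allele sets that cannot be reconciled) is
#'     dropped with a message.
#' }
#' Both input files are assumed to report the forward strand; complement
#' resolution is attempted only when direct or swapped matching fails.
#'
#' @param exposure,outcome Associations data frames, each with unique
#'   rsids.
#' @param palindromic_policy `"drop_ambiguous"` (default), `"drop_all"` or
#'   `"keep"` (palindromic variants with usable EAFs are frequency-aligned
#'   under all three; `"keep"` retains even ambiguous ones, assuming
#'   same-strand reporting).
#' @param eaf_ambiguity_window Half-width of the EAF window around 0.5
#'   inside which a palindromic variant counts as ambiguous (default 0.08).
#' @return A harmonized instrument data frame with columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_exposure`, `eaf_outcome`,
#'   `flipped`, `palindromic`.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("drop_ambiguous", "drop_all",
                                             "keep"),
                      eaf_ambiguity_window = 0.08) {
  palindromic_policy <- match.arg(palindromic_policy)
  for (nm in c("exposure", "outcome")) {
    df <- get(nm)
    if (anyDuplicated(df$rsid)) {
      stop("harmonize: duplicated rsid in ", nm, " table: ",
           paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "))
    }
  }
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L) {
    warning("harmonize: no shared rsids between exposure and outcome")
  }
  exposure <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  outcome <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  rows <- lapply(seq_along(shared), function(i) {
    e1 <- exposure$effect_allele[i]; e2 <- exposure$other_allele[i]
    o1 <- outcome$effect_allele[i];  o2 <- outcome$other_allele[i]
    pal <- is_palindromic(e1, e2)
    flipped <- NA  # NA = drop this variant

    if (pal) {
      # For a palindromic variant the complement of a direct match looks
      # like a swap, so letters alone cannot orient it; use frequency.
      if (!setequal(c(o1, o2), c(e1, e2))) {
        message("harmonize: dropping ", shared[i],
                " (incompatible alleles ", o1, "/", o2, ")")
      } else if (palindromic_policy == "drop_all") {
        message("harmonize: dropping palindromic variant ", shared[i])
      } else {
        fe <- exposure$eaf[i]; fo <- outcome$eaf[i]
        ambiguous <- is.na(fe) || is.na(fo) ||
          abs(fe - 0.5) <= eaf_ambiguity_window ||
          abs(fo - 0.5) <= eaf_ambiguity_window
        if (ambiguous && palindromic_policy == "drop_ambiguous") {
          message("harmonize: dropping palindromic variant ", shared[i],
                  " (ambiguous allele frequency)")
        } else if (!is.na(fe) && !is.na(fo) && !ambiguous) {
          flipped <- (fe - 0.5) * (fo - 0.5) < 0
        } else {
          # keep policy with unusable EAFs: trust same-strand labels
          flipped <- o1 != e1
        }
      }
    } else if (o1 == e1 && o2 == e2) {
      flipped <- FALSE
    } else if (o1 == e2 && o2 == e1) {
      flipped <- TRUE
    } else if (COMPLEMENT[o1] == e1 && COMPLEMENT[o2] == e2) {
      flipped <- FALSE
    } else if (COMPLEMENT[o1] == e2 && COMPLEMENT[o2] == e1) {
      flipped <- TRUE
    } else {
      message("harmonize: dropping ", shared[i],
              " (unresolvable alleles ", e1, "/", e2,
              " vs ", o1, "/", o2, ")")
    }

    if (is.na(flipped)) return(NULL)
    data.frame(
      rsid = shared[i],
      effect_allele = e1,
      other_allele = e2,
      beta_exposure = exposure$beta[i],
      se_exposure = exposure$se[i],
      beta_outcome = if (flipped) -outcome$beta[i] else outcome$beta[i],
      se_outcome = outcome$se[i],
      eaf_exposure = exposure$eaf[i],
      eaf_outcome = if (flipped) 1 - outcome$eaf[i] else outcome$eaf[i],
      flipped = flipped,
      palindromic = pal,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(rsid = character(), effect_allele = character(),
                      other_allele = character(), beta_exposure = numeric(),
                      se_exposure = numeric(), beta_outcome = numeric(),
                      se_outcome = numeric(), eaf_exposure = numeric(),
                      eaf_outcome = numeric(), flipped = logical(),
                      palindromic = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a harmonized instrument table as TSV
#'
#' Fixed column order: rsid, effect_allele, other_allele, beta_exposure,
#' se_exposure, beta_outcome, se_outcome, eaf_exposure, eaf_outcome,
#' flipped, palindromic.
#'
#' @param h Harmonized table from [harmonize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  cols <- c("rsid", "effect_allele", "other_allele", "beta_exposure",
            "se_exposure", "beta_outcome", "se_outcome", "eaf_exposure",
            "eaf_outcome", "flipped", "palindromic")
  utils::write.table(h[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
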