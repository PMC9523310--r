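# Study runner: evaluates every exposure x outcome x method cell of an MR
# study grid and renders the results table. Sex strata and replication
# sources enter purely as additional outcome entries (different summary
# files); reverse MR is the same machinery with exposure and outcome roles
# swapped.

#' Study configuration
#'
#' Describes a full MR study grid. Each exposure or outcome entry is
#' either an associations data frame (see [read_summary_stats()]) or a
#' list with `path` and optionally `column_map` to be read from disk.
#' Outcome entries may additionally carry:
#' \itemize{
#'   \item `trait_type`: `"continuous"` or `"binary"` (default continuous);
#'   \item `stratum`: `"all"`, `"female"` or `"male"` (default `"all"`) —
#'     a label only; strata differ solely in which summary file they point
#'     at;
#'   \item `sd_scale`: phenotype SD used to standardize natural-unit
#'     betas (beta and SE divided by it);
#'   \item `case_fraction`: when a binary trait was analyzed with a linear
#'     model, its beta/SE are converted to the log-odds scale by dividing
#'     by `case_fraction * (1 - case_fraction)`.
#' }
#' Exposure entries may carry `direction = "decrease"` to express effects
#' per SD decrease (see [orient_exposure()]) — used for transferrin, which
#' falls as iron status rises.
#'
#' @param exposures Named list of exposure entries.
#' @param outcomes Named list of outcome entries.
#' @param instruments Named list: exposure name -> character vector of
#'   instrument rsids. Exposures absent from the list use all their rows.
#' @param methods Subset of `c("ivw_fixed", "weighted_median",
#'   "mr_egger")`.
#' @param alpha Nominal significance level for the `significant_nominal`
#'   flag (default 0.05; no multiplicity correction is applied).
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param seed Integer seed; results are deterministic given the config.
#' @return A validated `study_config` list.
#' @export
study_config <- function(exposures, outcomes, instruments = list(),
                         methods = c("ivw_fixed", "weighted_median",
                                     "mr_egger"),
                         alpha = 0.05, n_boot = 10000L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            !is.null(names(exposures)), !is.null(names(outcomes)))
  if (alpha <= 0 || alpha >= 1) stop("study_config: alpha must be in (0, 1)")
  structure(list(exposures = exposures, outcomes = outcomes,
                 instruments = instruments, methods = methods,
                 alpha = alpha, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "study_config")
}

# resolve a config entry to an associations data frame
resolve_assocs <- function(entry, name) {
  if (is.data.frame(entry)) return(entry)
  if (is.list(entry) && !is.null(entry$data)) return(entry$data)
  if (is.list(entry) && !is.null(entry$path)) {
    tt <- if (identical(entry$trait_type, "binary")) "binary" else "continuous"
    return(read_summary_stats(entry$path, column_map = entry$column_map,
                              trait = name, trait_type = tt))
  }
  stop("study_config entry '", name,
       "' must be a data frame or a list with $data or $path")
}

entry_field <- function(entry, field, default) {
  if (is.list(entry) && !is.data.frame(entry) && !is.null(entry[[field]])) {
    entry[[field]]
  } else {
    default
  }
}

result_row <- function(exposure, outcome, stratum, method, est, binary,
                       alpha, status = "ok") {
  or <- if (binary && !is.na(est$se)) to_odds_ratio(est) else
    list(or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_)
  data.frame(
    exposure = exposure, outcome = outcome, stratum = stratum,
    method = method, n_snps = est$n_snps, theta = est$theta, se = est$se,
    ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
    or = or$or, or_ci_low = or$or_ci_low, or_ci_high = or$or_ci_high,
    significant_nominal = !is.na(est$pvalue) && est$pvalue < alpha,
    status = status, stringsAsFactors = FALSE
  )
}

na_row <- function(exposure, outcome, stratum, method, n_snps, status) {
  data.frame(
    exposure = exposure, outcome = outcome, stratum = stratum,
    method = method, n_snps = as.integer(n_snps), theta = NA_real_,
    se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    pvalue = NA_real_, or = NA_real_, or_ci_low = NA_real_,
    or_ci_high = NA_real_, significant_nominal = NA, status = status,
    stringsAsFactors = FALSE
  )
}

#' Run a full MR study grid
#'
#' For every exposure x outcome pair: select the configured instruments,
#' harmonize the two summary tables, apply any outcome-scale transform,
#' compute per-SNP Wald ratios, and pool with each requested method.
#' MR-Egger contributes two rows per cell (slope and intercept, the
#' intercept being the directional-pleiotropy test). Instruments missing
#' from an outcome file are dropped with a note and the analysis proceeds
#' with the remaining subset (`n_snps` records how many were used);
#' methods needing at least 3 instruments yield a flagged `NA` row when
#' fewer survive. Results are deterministic given the config seed.
#'
#' @param cfg A [study_config()].
#' @return A results data frame, one row per exposure x outcome x method
#'   (two for MR-Egger), with a `manifest` attribute recording the seed,
#'   grid size and per-cell instrument counts.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  rows <- list()
  manifest <- list(seed = cfg$seed, methods = cfg$methods, cells = list())
  cell <- 0L
  for (ex_name in names(cfg$exposures)) {
    ex_entry <- cfg$exposures[[ex_name]]
    ex <- resolve_assocs(ex_entry, ex_name)
    wanted <- cfg$instruments[[ex_name]]
    if (!is.null(wanted)) {
      absent <- setdiff(wanted, ex$rsid)
      if (length(absent) > 0) {
        warning("run_study: instrument(s) absent from exposure '", ex_name,
                "': ", paste(absent, collapse = ", "))
      }
      ex <- ex[ex$rsid %in% wanted, , drop = FALSE]
    }
    direction <- entry_field(ex_entry, "direction", "increase")
    ex <- orient_exposure(ex, direction)

    for (out_name in names(cfg$outcomes)) {
      cell <- cell + 1L
      out_entry <- cfg$outcomes[[out_name]]
      out <- resolve_assocs(out_entry, out_name)
      stratum <- entry_field(out_entry, "stratum", "all")
      binary <- identical(entry_field(out_entry, "trait_type",
                                      out$trait_type[1]), "binary")
      missing_in_outcome <- setdiff(ex$rsid, out$rsid)

      h <- suppressWarnings(harmonize(ex, out))
      manifest$cells[[paste(ex_name, out_name, sep = " -> ")]] <-
        list(n_instruments = nrow(h), dropped = missing_in_outcome)

      if (nrow(h) == 0L) {
        for (m in cfg$methods) {
          rows[[length(rows) + 1L]] <-
            na_row(ex_name, out_name, stratum, m, 0L, "no_instruments")
        }
        next
      }

      sd_scale <- entry_field(out_entry, "sd_scale", NULL)
      if (!is.null(sd_scale)) {
        h$beta_outcome <- h$beta_outcome / sd_scale
        h$se_outcome <- h$se_outcome / sd_scale
      }
      cf <- entry_field(out_entry, "case_fraction", NULL)
      if (!is.null(cf) && binary) {
        h$beta_outcome <- h$beta_outcome / (cf * (1 - cf))
        h$se_outcome <- h$se_outcome / (cf * (1 - cf))
      }

      status <- if (length(missing_in_outcome) > 0) "partial_instruments"
                else "ok"
      per_snp <- wald_ratio(h)
      for (m in cfg$methods) {
        if (m == "ivw_fixed") {
          rows[[length(rows) + 1L]] <-
            result_row(ex_name, out_name, stratum, m, ivw_fixed(per_snp),
                       binary, cfg$alpha, status)
        } else if (m == "weighted_median") {
          if (nrow(h) < 3L) {
            rows[[length(rows) + 1L]] <-
              na_row(ex_name, out_name, stratum, m, nrow(h),
                     "too_few_instruments")
          } else {
            est <- weighted_median(h, n_boot = cfg$n_boot,
                                   seed = cfg$seed + cell)
            rows[[length(rows) + 1L]] <-
              result_row(ex_name, out_name, stratum, m, est, binary,
                         cfg$alpha, status)
          }
        } else if (m == "mr_egger") {
          if (nrow(h) < 3L) {
            rows[[length(rows) + 1L]] <-
              na_row(ex_name, out_name, stratum, "mr_egger_slope", nrow(h),
                     "too_few_instruments")
            rows[[length(rows) + 1L]] <-
              na_row(ex_name, out_name, stratum, "mr_egger_intercept",
                     nrow(h), "too_few_instruments")
          } else {
            eg <- mr_egger(h)
            rows[[length(rows) + 1L]] <-
              result_row(ex_name, out_name, stratum, "mr_egger_slope",
                         eg$slope, binary, cfg$alpha, status)
            rows[[length(rows) + 1L]] <-
              result_row(ex_name, out_name, stratum, "mr_egger_intercept",
                         eg$intercept, FALSE, cfg$alpha, status)
          }
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "manifest") <- manifest
  res
}

#' Run a reverse MR study
#'
#' Identical machinery to [run_study()] with the causal roles swapped: the
#' former outcome trait (e.g. a 12-variant NAFLD liability instrument set)
#' becomes the exposure and the former exposures (the four iron-status
#' indicators) become outcomes. A pure function of its config; shares no
#' state with the forward run.
#'
#' @param cfg A [study_config()] whose exposures are the reverse-direction
#'   instrument sets.
#' @return A results data frame as from [run_study()].
#' @export
run_reverse <- function(cfg) {
  run_study(cfg)
}

#' Render a results table
#'
#' Orders rows by outcome, exposure, then method and renders either a TSV
#' or a markdown table with forest-plot-ready columns (point estimate and
#' 95% CI on the odds-ratio scale for binary outcomes, beta scale
#' otherwise). Markdown and TSV carry the same numbers.
#'
#' @param rows Results data frame from [run_study()].
#' @param format `"tsv"` or `"markdown"`.
#' @param path Optional output path; when given the document is written
#'   there.
#' @return The document as a character vector of lines, invisibly when
#'   `path` is given.
#' @export
render_report <- function(rows, format = c("tsv", "markdown"),
                          path = NULL) {
  format <- match.arg(format)
  if (nrow(rows) == 0L) stop("render_report: no rows to render")
  ord <- order(rows$outcome, rows$exposure, rows$method)
  rows <- rows[ord, , drop = FALSE]
  num <- vapply(rows, is.numeric, logical(1))
  fmt <- rows
  fmt[num] <- lapply(rows[num], function(x) {
    ifelse(is.na(x), "", formatC(x, digits = 6, format = "g"))
  })
  fmt$significant_nominal <- ifelse(is.na(rows$significant_nominal), "",
                                    as.character(rows$significant_nominal))
  lines <- if (format == "tsv") {
    c(paste(names(fmt), collapse = "\t"),
      apply(fmt, 1, paste, collapse = "\t"))
  } else {
    c(paste0("| ", paste(names(fmt), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|"),
      apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                       " |")))
  }
  lines <- unname(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
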