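# Display names for the strategy variants, in Table column order.
.variants_all <- c("EN689:1995 prelim #1", "EN689:1995 prelim #3",
                   "EN689:2018 prelim #3", "EN689:2018 prelim #4",
                   "EN689:2018 prelim #5", "EN689:1995 stat 5% exc.",
                   "EN689:2018 stat UTL95,70")
.variant_bohs <- "BOHS-NVvA I.C."

#' Run all compliance strategies over a set of SEGs
#'
#' Applies, per SEG: the EN689:1995 preliminary test to the date-ordered
#' first 1 and 3 measurements; the EN689:2018 preliminary test to the
#' first 3, 4 and 5 measurements; both statistical tests to all
#' measurements; and the BOHS-NVvA test to the SEGs that have repeated
#' measurements of at least one worker. Decisions are tallied for the
#' full SEG set and, separately, for the repeats-only subgroup (the
#' BOHS-NVvA column only exists there, so its denominator is that
#' subgroup). SEGs with fewer than six measurements cannot take the
#' statistical tests and are skipped with a warning.
#'
#' @param segs List of `seg` objects (see [build_segs()] or
#'   [generate_study()]).
#' @param oel An [oel_spec()] or a positive number.
#' @param verbose If TRUE, prints a per-SEG decision trace (statistics
#'   and BOHS routing).
#' @return An object of class `comparison_table` with components
#'   `decisions` (long data frame: seg_id, variant, outcome, statistic,
#'   n_used), `tables` (list of per-subgroup tally data frames,
#'   `all_segs` and `repeats_only`), `n_segs`, `n_repeats`, `skipped`
#'   (ids of undersized SEGs) and `oel`.
#' @export
run_comparison <- function(segs, oel = oel_spec(), verbose = FALSE) {
  if (length(segs) == 0L) stop("no SEGs to analyse", call. = FALSE)
  limit <- oel_value(oel)
  usable <- vapply(segs, function(s) s$n_measurements >= 6L, TRUE)
  skipped <- vapply(segs[!usable], `[[`, "", "seg_id")
  if (length(skipped))
    warning(length(skipped), " SEG(s) with fewer than 6 measurements ",
            "skipped: ", paste(skipped, collapse = ", "), call. = FALSE)
  segs <- segs[usable]
  if (length(segs) == 0L)
    stop("no SEG has the 6 measurements the statistical tests require",
         call. = FALSE)

  rows <- lapply(segs, function(seg) seg_decisions(seg, limit, verbose))
  decisions <- do.call(rbind, rows)
  rownames(decisions) <- NULL

  repeats <- vapply(segs, `[[`, TRUE, "has_repeats")
  repeat_ids <- vapply(segs[repeats], `[[`, "", "seg_id")
  tables <- list(
    all_segs = tally_decisions(decisions, .variants_all),
    repeats_only = tally_decisions(
      decisions[decisions$seg_id %in% repeat_ids, , drop = FALSE],
      c(.variants_all, .variant_bohs))
  )
  structure(list(decisions = decisions, tables = tables,
                 n_segs = length(segs), n_repeats = sum(repeats),
                 skipped = as.character(skipped), oel = limit),
            class = "comparison_table")
}

# All applicable decisions for one SEG, as rows of the long decision table.
seg_decisions <- function(seg, limit, verbose = FALSE) {
  values <- seg$measurements$concentration
  fit <- fit_lognormal(values)
  out <- list()
  add <- function(variant, d) {
    out[[length(out) + 1L]] <<- data.frame(
      seg_id = seg$seg_id, variant = variant, outcome = d$outcome,
      statistic = d$statistic, n_used = d$n_used, stringsAsFactors = FALSE)
  }
  first <- function(n) select_preliminary_subset(seg, n)$concentration
  add(.variants_all[1], preliminary_1995(first(1L), limit))
  add(.variants_all[2], preliminary_1995(first(3L), limit))
  add(.variants_all[3], preliminary_2018(first(3L), limit))
  add(.variants_all[4], preliminary_2018(first(4L), limit))
  add(.variants_all[5], preliminary_2018(first(5L), limit))
  add(.variants_all[6], statistical_test_1995(fit, limit))
  add(.variants_all[7], statistical_test_2018(fit, limit))
  if (seg$has_repeats) {
    ic <- bohs_nvva_test(seg, limit)
    add(.variant_bohs, ic$decision)
    if (verbose)
      message(sprintf("%s: exc = %.4f, UTL = %.4f, rho_B = %.3f -> %s",
                      seg$seg_id, exceedance_probability(fit, limit),
                      utl_95_70(fit), ic$rho_B, ic$route))
  } else if (verbose) {
    message(sprintf("%s: exc = %.4f, UTL = %.4f (no repeats)",
                    seg$seg_id, exceedance_probability(fit, limit),
                    utl_95_70(fit)))
  }
  do.call(rbind, out)
}

# Tally a long decision table into one row per variant with counts and
# full-precision percentages.
tally_decisions <- function(decisions, variants) {
  rows <- lapply(variants, function(v) {
    sub <- decisions[decisions$variant == v, , drop = FALSE]
    n <- nrow(sub)
    counts <- vapply(.outcomes, function(o) sum(sub$outcome == o), 0L)
    pct <- if (n > 0) 100 * counts / n else rep(0, 3)
    data.frame(variant = v, n = n,
               compliance = counts[[1]], uncertain = counts[[2]],
               non_compliance = counts[[3]],
               compliance_pct = pct[[1]], uncertain_pct = pct[[2]],
               non_compliance_pct = pct[[3]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# "110 (52%)" display convention; percentages rounded to integer.
format_count_pct <- function(count, denom) {
  pct <- if (denom > 0) round(100 * count / denom) else 0
  sprintf("%d (%d%%)", as.integer(count), as.integer(pct))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("Compliance comparison: %d SEGs (%d with repeats), OEL = %g mg/m3\n",
              x$n_segs, x$n_repeats, x$oel))
  if (length(x$skipped))
    cat(sprintf("  (%d undersized SEG(s) skipped)\n", length(x$skipped)))
  for (name in names(x$tables)) {
    tab <- x$tables[[name]]
    if (nrow(tab) == 0L) next
    cat(sprintf("\n== %s ==\n", gsub("_", " ", name)))
    disp <- data.frame(
      variant = tab$variant,
      compliance = mapply(format_count_pct, tab$compliance, tab$n),
      uncertain = ifelse(grepl("prelim", tab$variant),
                         mapply(format_count_pct, tab$uncertain, tab$n), ""),
      non_compliance = mapply(format_count_pct, tab$non_compliance, tab$n),
      stringsAsFactors = FALSE)
    print(disp, row.names = FALSE, right = FALSE)
  }
  invisible(x)
}

#' Write a comparison report
#'
#' Serialises a [run_comparison()] result deterministically. The CSV
#' format carries one row per subgroup x variant with integer counts, the
#' `"count (percent%)"` display strings, and full-precision percentage
#' companion columns. The markdown format renders the two decision tables
#' with the display convention only. The uncertain column is left blank
#' for the statistical and individual tests, which always reach a binary
#' decision.
#'
#' @param table A `comparison_table`.
#' @param path Output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, format = c("csv", "markdown")) {
  stopifnot(inherits(table, "comparison_table"))
  format <- match.arg(format)
  if (format == "csv") {
    rows <- lapply(names(table$tables), function(name) {
      tab <- table$tables[[name]]
      data.frame(subgroup = name, tab,
        compliance_display = mapply(format_count_pct, tab$compliance, tab$n),
        uncertain_display = mapply(format_count_pct, tab$uncertain, tab$n),
        non_compliance_display = mapply(format_count_pct,
                                        tab$non_compliance, tab$n),
        stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else {
    lines <- c(sprintf("# Compliance comparison (OEL = %g mg/m3)", table$oel),
               "")
    for (name in names(table$tables)) {
      tab <- table$tables[[name]]
      prelim <- grepl("prelim", tab$variant)
      lines <- c(lines,
        sprintf("## %s (n = %d SEGs)", gsub("_", " ", name),
                max(tab$n)), "",
        "| Decision | " %+% paste(tab$variant, collapse = " | ") %+% " |",
        "|" %+% paste(rep("---", nrow(tab) + 1L), collapse = "|") %+% "|",
        "| Compliance | " %+%
          paste(mapply(format_count_pct, tab$compliance, tab$n),
                collapse = " | ") %+% " |",
        "| Uncertain compliance | " %+%
          paste(ifelse(prelim,
                       mapply(format_count_pct, tab$uncertain, tab$n), ""),
                collapse = " | ") %+% " |",
        "| Non-compliance | " %+%
          paste(mapply(format_count_pct, tab$non_compliance, tab$n),
                collapse = " | ") %+% " |",
        "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)
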