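#' Occupational exposure limit specification
#'
#' Bundles a substance label with its occupational exposure limit (OEL).
#' All compliance tests in the package compare full-shift concentrations,
#' in the same units as the OEL (mg/m3 throughout), against this limit.
#'
#' @param oel Positive number, the limit value in mg/m3.
#' @param substance Character label for the agent (default
#'   `"respirable dust"`, with the conventional limit of 1 mg/m3).
#' @return An object of class `oel_spec` with fields `substance` and `oel`.
#' @examples
#' oel_spec(1)
#' oel_spec(0.1, "respirable crystalline silica")
#' @export
oel_spec <- function(oel = 1, substance = "respirable dust") {
  if (!is.numeric(oel) || length(oel) != 1L || !is.finite(oel) || oel <= 0)
    stop("`oel` must be a single positive number", call. = FALSE)
  if (!is.character(substance) || length(substance) != 1L || !nzchar(substance))
    stop("`substance` must be a non-empty string", call. = FALSE)
  structure(list(substance = substance, oel = as.numeric(oel)),
            class = "oel_spec")
}

#' @export
print.oel_spec <- function(x, ...) {
  cat(sprintf("OEL: %g mg/m3 (%s)\n", x$oel, x$substance))
  invisible(x)
}

# Accept either an oel_spec or a bare positive number wherever an OEL is
# expected.
oel_value <- function(oel) {
  if (inherits(oel, "oel_spec")) return(oel$oel)
  if (is.numeric(oel) && length(oel) == 1L && is.finite(oel) && oel > 0)
    return(as.numeric(oel))
  stop("`oel` must be an `oel_spec` or a single positive number",
       call. = FALSE)
}

# Strategy identifiers used in ComplianceDecision objects.
.strategies <- c("EN689_1995_PRELIM", "EN689_2018_PRELIM",
                 "EN689_1995_STAT", "EN689_2018_STAT", "BOHS_NVVA")
.outcomes <- c("compliance", "uncertain", "non_compliance")

#' Compliance decision
#'
#' Constructor for the outcome of one compliance test on one SEG. The
#' `uncertain` outcome only occurs for the preliminary (screening) tests;
#' the statistical and individual tests always reach a binary decision.
#'
#' @param strategy One of `"EN689_1995_PRELIM"`, `"EN689_2018_PRELIM"`,
#'   `"EN689_1995_STAT"`, `"EN689_2018_STAT"`, `"BOHS_NVVA"`.
#' @param outcome One of `"compliance"`, `"uncertain"`, `"non_compliance"`.
#' @param statistic Optional supporting statistic (exceedance probability,
#'   UTL in mg/m3, or the individual overexposure fraction theta).
#' @param n_used Number of measurements the decision was based on.
#' @return An object of class `compliance_decision`.
#' @export
compliance_decision <- function(strategy, outcome, statistic = NA_real_,
                                n_used = NA_integer_) {
  strategy <- match.arg(strategy, .strategies)
  outcome <- match.arg(outcome, .outcomes)
  if (outcome == "uncertain" && !grepl("PRELIM$", strategy))
    stop("`uncertain` outcomes are only defined for preliminary tests",
         call. = FALSE)
  structure(list(strategy = strategy, outcome = outcome,
                 statistic = as.numeric(statistic),
                 n_used = as.integer(n_used)),
            class = "compliance_decision")
}

#' @export
print.compliance_decision <- function(x, ...) {
  stat <- if (is.na(x$statistic)) "" else sprintf(" (statistic = %.4g)",
                                                  x$statistic)
  cat(sprintf("[%s] %s%s, n = %d\n", x$strategy, x$outcome, stat, x$n_used))
  invisible(x)
}

#' Read full-shift exposure measurements from CSV
#'
#' Expects an RFC-4180 CSV with columns `seg_id`, `worker_id`,
#' `sample_date` (ISO-8601, YYYY-MM-DD) and `concentration` (mg/m3,
#' decimal point, strictly positive). Every invalid row is reported by
#' its row number; no imputation is attempted since the methods operate
#' on log concentrations.
#'
#' @param path Path to the CSV file.
#' @return A data frame of measurements with one row per sample, columns
#'   `seg_id` (character), `worker_id` (character), `sample_date` (`Date`)
#'   and `concentration` (numeric), in file order.
#' @seealso [build_segs()] to assemble SEGs, [write_measurements()] for the
#'   inverse operation.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("seg_id", "worker_id", "sample_date", "concentration")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) stop("no measurement rows in ", path, call. = FALSE)
  validate_measurements(data.frame(
    seg_id = raw$seg_id,
    worker_id = raw$worker_id,
    sample_date = raw$sample_date,
    concentration = suppressWarnings(as.numeric(raw$concentration)),
    stringsAsFactors = FALSE
  ))
}

# Validates and normalises a measurement data frame; errors name the
# offending rows (1-based, excluding the header).
validate_measurements <- function(df) {
  dates <- as.Date(as.character(df$sample_date), format = "%Y-%m-%d")
  problems <- character(0)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      sprintf("row %d: %s", idx, what)
    else
      character(0)
  }
  problems <- c(
    bad(is.na(df$seg_id) | !nzchar(df$seg_id), "empty seg_id"),
    bad(is.na(df$worker_id) | !nzchar(df$worker_id), "empty worker_id"),
    bad(is.na(dates), "unparseable sample_date (expected YYYY-MM-DD)"),
    bad(is.na(df$concentration), "non-numeric concentration"),
    bad(!is.na(df$concentration) & df$concentration <= 0,
        "concentration must be > 0")
  )
  if (length(problems))
    stop("invalid measurement rows:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  data.frame(seg_id = as.character(df$seg_id),
             worker_id = as.character(df$worker_id),
             sample_date = dates,
             concentration = as.numeric(df$concentration),
             stringsAsFactors = FALSE)
}

#' Write measurements to CSV
#'
#' Serialises a measurement data frame in the schema read by
#' [read_measurements()].
#'
#' @param measurements Data frame as returned by [read_measurements()] or
#'   [seg_measurements()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  out <- data.frame(seg_id = measurements$seg_id,
                    worker_id = measurements$worker_id,
                    sample_date = format(measurements$sample_date, "%Y-%m-%d"),
                    concentration = measurements$concentration,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble similar exposure groups (SEGs)
#'
#' Partitions measurements by `seg_id` into SEG objects. Within a SEG,
#' measurements are sorted by sampling date; same-day measurements keep
#' their input order, so the date-ordered preliminary subsets are stable
#' and reproducible. No minimum size is enforced here — the statistical
#' tests impose their own `n >= 6` requirement.
#'
#' @param measurements Data frame as returned by [read_measurements()].
#' @return A list of `seg` objects, in order of first appearance of each
#'   `seg_id`. Each `seg` carries `seg_id`, the sorted `measurements`
#'   data frame, `n_measurements`, `n_workers`, and `has_repeats` (TRUE
#'   iff at least one worker contributed two or more measurements).
#' @export
build_segs <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0L)
    stop("no measurements to group", call. = FALSE)
  ids <- unique(measurements$seg_id)
  lapply(ids, function(id) {
    rows <- measurements[measurements$seg_id == id, , drop = FALSE]
    new_seg(id, rows)
  })
}

# Internal seg constructor: sorts by date with stable input-order ties and
# derives the summary fields.
new_seg <- function(seg_id, rows) {
  ord <- order(rows$sample_date)  # order() is stable: ties keep input order
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  reps <- table(rows$worker_id)
  structure(list(seg_id = as.character(seg_id),
                 measurements = rows,
                 n_measurements = nrow(rows),
                 n_workers = length(reps),
                 has_repeats = any(reps >= 2L)),
            class = "seg")
}

#' @export
print.seg <- function(x, ...) {
  cat(sprintf("SEG %s: %d measurements, %d workers%s\n", x$seg_id,
              x$n_measurements, x$n_workers,
              if (x$has_repeats) " (with repeats)" else ""))
  invisible(x)
}

#' Extract the measurement table from SEGs
#'
#' Flattens one SEG or a list of SEGs back into a single measurement data
#' frame (the [read_measurements()] schema).
#'
#' @param segs A `seg` object or a list of them.
#' @return A data frame of measurements.
#' @export
seg_measurements <- function(segs) {
  if (inherits(segs, "seg")) segs <- list(segs)
  out <- do.call(rbind, lapply(segs, `[[`, "measurements"))
  rownames(out) <- NULL
  out
}

#' Date-ordered preliminary subset of a SEG
#'
#' Returns the `n` earliest measurements of a SEG, as used in the
#' preliminary (screening) phase where only the first few samples taken
#' are available. Sampling-date ties are broken by input order.
#'
#' @param seg A `seg` object.
#' @param n Subset size; one of 1, 3, 4, 5 (the sizes the preliminary
#'   tests accept).
#' @return A data frame of `n` measurements in ascending date order.
#' @export
select_preliminary_subset <- function(seg, n) {
  stopifnot(inherits(seg, "seg"))
  if (!n %in% c(1L, 3L, 4L, 5L))
    stop("`n` must be one of 1, 3, 4, 5", call. = FALSE)
  if (seg$n_measurements < n)
    stop(sprintf("SEG %s has only %d measurement(s); %d requested",
                 seg$seg_id, seg$n_measurements, n), call. = FALSE)
  seg$measurements[seq_len(n), , drop = FALSE]
}
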