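#' Declare a study variable
#'
#' A variable specification records how one column of a case-control dataset
#' is coded: categorical variables carry an ordered set of labelled integer
#' state codes plus the reference (control) level used in regression;
#' continuous variables carry the discretization rule applied before
#' Bayesian-network learning (ordered cut-points, one bin code per interval).
#'
#' Bins are half-open on the real line. By default a cut-point is
#' left-closed: values `>= cut` fall in the upper bin. A cut-point with
#' `closed = "right"` keeps values `<= cut` in the lower bin (used e.g. for a
#' heart-rate rule whose normal band is 60--100 inclusive).
#'
#' @param name variable name (unique within a codebook).
#' @param kind `"categorical"` or `"continuous"`.
#' @param states named integer vector of state codes (categorical only);
#'   names are the labels accepted by [encode_dataset()].
#' @param reference integer reference-level code (categorical only); must be
#'   one of `states`.
#' @param cutpoints strictly increasing numeric thresholds (continuous only).
#' @param bin_codes integer bin codes, one per interval, i.e.
#'   `length(cutpoints) + 1` values (continuous only).
#' @param closed character vector, one of `"left"`/`"right"` per cut-point;
#'   recycled if length 1. Default `"left"`.
#' @param units free-text measurement units.
#' @return An object of class `"variable_spec"`.
#' @export
variable_spec <- function(name, kind, states = NULL, reference = NULL,
                          cutpoints = NULL, bin_codes = NULL,
                          closed = "left", units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, c("categorical", "continuous"))
  if (kind == "categorical") {
    if (is.null(states) || is.null(names(states)) || any(!nzchar(names(states))))
      stop("categorical variable '", name, "' needs named integer states")
    labs <- names(states)
    states <- as.integer(states)
    names(states) <- labs
    if (anyDuplicated(states))
      stop("duplicate state codes for variable '", name, "'")
    if (anyDuplicated(names(states)))
      stop("duplicate state labels for variable '", name, "'")
    if (is.null(reference)) reference <- states[[1L]]
    reference <- as.integer(reference)
    if (!reference %in% states)
      stop("reference level ", reference, " of '", name,
           "' is not a declared state")
    cutpoints <- NULL; bin_codes <- NULL; closed <- NULL
  } else {
    if (is.null(cutpoints) || is.null(bin_codes))
      stop("continuous variable '", name, "' needs cutpoints and bin_codes")
    cutpoints <- as.numeric(cutpoints)
    if (length(cutpoints) < 1L || is.unsorted(cutpoints, strictly = TRUE))
      stop("cutpoints of '", name, "' must be strictly increasing")
    bin_codes <- as.integer(bin_codes)
    if (length(bin_codes) != length(cutpoints) + 1L)
      stop("'", name, "': need one bin code per interval (",
           length(cutpoints) + 1L, ")")
    if (anyDuplicated(bin_codes))
      stop("duplicate bin codes for variable '", name, "'")
    closed <- rep_len(match.arg(closed, c("left", "right"), several.ok = TRUE),
                      length(cutpoints))
    states <- NULL; reference <- NULL
  }
  structure(list(name = name, kind = kind, states = states,
                 reference = reference, cutpoints = cutpoints,
                 bin_codes = bin_codes, closed = closed, units = units),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  if (x$kind == "categorical") {
    cat(sprintf("<variable_spec> %s (categorical): %s; reference = %d\n",
                x$name,
                paste(sprintf("%s=%d", names(x$states), x$states),
                      collapse = ", "),
                x$reference))
  } else {
    cat(sprintf("<variable_spec> %s (continuous%s): cuts %s -> codes %s\n",
                x$name,
                if (nzchar(x$units)) paste0(", ", x$units) else "",
                paste(x$cutpoints, collapse = "/"),
                paste(x$bin_codes, collapse = "/")))
  }
  invisible(x)
}

#' Assemble a codebook
#'
#' A codebook is the ordered collection of [variable_spec()] objects for one
#' study, plus the outcome (case-group) names and a per-outcome exclusion
#' list. Exclusions remove variables that are part of an outcome's diagnostic
#' definition from its analysis (fasting blood glucose is excluded from the
#' diabetes analysis for this reason in the default codebook).
#'
#' @param variables list of [variable_spec()] objects.
#' @param outcomes character vector of case-group names.
#' @param exclusions named list: per outcome, variable names to drop.
#' @return An object of class `"codebook"`.
#' @export
codebook <- function(variables, outcomes = character(),
                     exclusions = list()) {
  stopifnot(is.list(variables), length(variables) > 0L)
  ok <- vapply(variables, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop("all elements of 'variables' must be variable_spec")
  nm <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate variable name: ", nm[duplicated(nm)][1L])
  names(variables) <- nm
  bad <- setdiff(unlist(exclusions, use.names = FALSE), nm)
  if (length(bad)) stop("exclusion of unknown variable: ", bad[1L])
  structure(list(variables = variables, outcomes = outcomes,
                 exclusions = exclusions),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  kinds <- vapply(x$variables, `[[`, character(1), "kind")
  cat(sprintf("<codebook> %d variables (%d categorical, %d continuous)\n",
              length(x$variables), sum(kinds == "categorical"),
              sum(kinds == "continuous")))
  if (length(x$outcomes))
    cat("  outcomes:", paste(x$outcomes, collapse = ", "), "\n")
  for (o in names(x$exclusions))
    cat(sprintf("  excluded for %s: %s\n", o,
                paste(x$exclusions[[o]], collapse = ", ")))
  invisible(x)
}

#' The default study codebook
#'
#' Reproduces the coding scheme of the source study: 17 categorical
#' variables with their labelled state codes and reference (control) levels,
#' and 10 continuous variables (age, BMI, blood pressure, heart rate, blood
#' glucose and lipids) with the discretization rules applied before network
#' learning. Fasting blood glucose (`fbg`) is excluded from the `T2DM`
#' analysis because it is part of the diagnostic definition of diabetes.
#'
#' Two clinically atypical lipid rules (the HDL-C abnormality threshold at
#' 2.3 mmol/L and the reversed LDL-C rule flagging values below 1.0 mmol/L)
#' are implemented as published; override them with a custom codebook if
#' analysing real data.
#'
#' @return A [codebook()] covering all 27 study variables plus the outcomes
#'   `T2DM`, `CAD` and `comorbidity`.
#' @export
default_codebook <- function() {
  cs <- function(...) {
    v <- c(...)
    stats::setNames(as.integer(v), names(v))
  }
  vars <- list(
    variable_spec("age", "continuous", cutpoints = c(45, 60),
                  bin_codes = 1:3, units = "years"),
    variable_spec("sex", "categorical", states = cs(male = 1, female = 2),
                  reference = 1),
    variable_spec("area", "categorical",
                  states = cs(rural = 1, suburban = 2, urban = 3),
                  reference = 1),
    variable_spec("education", "categorical",
                  states = cs(low = 1, middle = 2, high = 3), reference = 1),
    variable_spec("marriage", "categorical",
                  states = cs(married = 1, other = 2), reference = 1),
    variable_spec("occupation", "categorical",
                  states = cs(agriculture = 1, business = 2, government = 3,
                              student = 4, other = 5), reference = 1),
    variable_spec("fhx_dm", "categorical", states = cs(no = 0, yes = 1),
                  reference = 0),
    variable_spec("fhx_cad", "categorical", states = cs(no = 0, yes = 1),
                  reference = 0),
    variable_spec("smoke", "categorical",
                  states = cs(never = 1, occasionally = 2, often = 3,
                              quitting = 4), reference = 1),
    variable_spec("drink", "categorical",
                  states = cs(never = 1, occasionally = 2, often = 3,
                              quitting = 4), reference = 1),
    variable_spec("staple", "categorical",
                  states = cs(lt3 = 1, x3to6 = 2, ge6 = 3), reference = 1,
                  units = "liang/day"),
    variable_spec("meat", "categorical",
                  states = cs(lt7 = 1, x7to14 = 2, ge14 = 3), reference = 1,
                  units = "times/week"),
    variable_spec("vegetable", "categorical",
                  states = cs(lt7 = 1, x7to14 = 2, ge14 = 3), reference = 1,
                  units = "times/week"),
    variable_spec("fruit", "categorical",
                  states = cs(never = 1, lt7 = 2, x7to14 = 3, ge14 = 4),
                  reference = 1, units = "times/week"),
    variable_spec("sweet", "categorical",
                  states = cs(never = 1, lt3 = 2, x3to7 = 3, ge7 = 4),
                  reference = 1, units = "times/week"),
    variable_spec("exercise", "categorical", states = cs(no = 0, yes = 1),
                  reference = 0),
    variable_spec("sleep", "categorical",
                  states = cs(lt5 = 1, x5to7 = 2, x7to9 = 3, ge9 = 4),
                  reference = 1, units = "hours/day"),
    variable_spec("central_obesity", "categorical",
                  states = cs(no = 0, yes = 1), reference = 0),
    variable_spec("bmi", "continuous", cutpoints = c(18.5, 24, 28),
                  bin_codes = 1:4, units = "kg/m^2"),
    variable_spec("sbp", "continuous", cutpoints = 140, bin_codes = 0:1,
                  units = "mmHg"),
    variable_spec("dbp", "continuous", cutpoints = 90, bin_codes = 0:1,
                  units = "mmHg"),
    # normal band is 60--100 inclusive: upper cut right-closed
    variable_spec("heart_rate", "continuous", cutpoints = c(60, 100),
                  bin_codes = 1:3, closed = c("left", "right"),
                  units = "times/min"),
    variable_spec("fbg", "continuous", cutpoints = 7.0, bin_codes = 0:1,
                  units = "mmol/L"),
    variable_spec("tg", "continuous", cutpoints = 2.3, bin_codes = 0:1,
                  units = "mmol/L"),
    variable_spec("tc", "continuous", cutpoints = 6.2, bin_codes = 0:1,
                  units = "mmol/L"),
    variable_spec("hdl", "continuous", cutpoints = 2.3, bin_codes = 0:1,
                  units = "mmol/L"),
    # published rule is reversed: values below 1.0 are the "abnormal" code
    variable_spec("ldl", "continuous", cutpoints = 1.0, bin_codes = c(1L, 0L),
                  units = "mmol/L")
  )
  codebook(vars,
           outcomes = c("T2DM", "CAD", "comorbidity"),
           exclusions = list(T2DM = "fbg"))
}

#' Load a codebook from a configuration document
#'
#' Reads a YAML document (or an equivalent already-parsed list) declaring
#' variables, outcomes and exclusions, and validates it into a [codebook()].
#' Each entry of `variables` must give `kind` and either `states` (a
#' label-to-code mapping) plus optional `reference`, or `cutpoints` plus
#' `bin_codes` with optional `closed`.
#'
#' @param config path to a YAML file, or a list with elements `variables`,
#'   and optionally `outcomes` and `exclusions`.
#' @return A validated [codebook()].
#' @export
load_codebook <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$variables))
  vars <- lapply(names(config$variables), function(nm) {
    v <- config$variables[[nm]]
    if (identical(v$kind, "categorical")) {
      variable_spec(nm, "categorical", states = unlist(v$states),
                    reference = v$reference,
                    units = v$units %||% "")
    } else {
      variable_spec(nm, "continuous", cutpoints = v$cutpoints,
                    bin_codes = v$bin_codes,
                    closed = v$closed %||% "left",
                    units = v$units %||% "")
    }
  })
  codebook(vars,
           outcomes = config$outcomes %||% character(),
           exclusions = config$exclusions %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode a raw cohort table against a codebook
#'
#' Maps categorical labels to their integer state codes and passes
#' continuous columns through unchanged. Cells already holding a declared
#' integer code are accepted as-is. Row count and column order are
#' preserved; a `group` column is required and left untouched.
#'
#' @param raw data.frame with one row per subject, a `group` column, and
#'   columns named after codebook variables.
#' @param cb a [codebook()].
#' @return The encoded data.frame (class `"data.frame"`), all codebook
#'   columns integer or numeric, with no missing cells.
#' @export
encode_dataset <- function(raw, cb) {
  stopifnot(is.data.frame(raw), inherits(cb, "codebook"))
  if (!"group" %in% names(raw)) stop("missing 'group' column")
  unknown <- setdiff(setdiff(names(raw), "group"), names(cb$variables))
  if (length(unknown))
    stop("column not declared in codebook: ", unknown[1L])
  out <- raw
  for (nm in intersect(names(raw), names(cb$variables))) {
    spec <- cb$variables[[nm]]
    col <- raw[[nm]]
    if (spec$kind == "continuous") {
      col <- as.numeric(col)
      if (anyNA(col)) stop("non-numeric or missing value in continuous ",
                           "column '", nm, "'")
      out[[nm]] <- col
    } else {
      if (is.numeric(col)) {
        code <- as.integer(col)
      } else {
        code <- spec$states[match(as.character(col), names(spec$states))]
        # allow numeric codes given as strings
        chr_num <- suppressWarnings(as.integer(as.character(col)))
        code[is.na(code) & !is.na(chr_num)] <- chr_num[is.na(code) & !is.na(chr_num)]
      }
      bad <- which(is.na(code) | !code %in% spec$states)
      if (length(bad))
        stop(sprintf("unknown label '%s' in column '%s' (row %d)",
                     as.character(col[bad[1L]]), nm, bad[1L]))
      out[[nm]] <- as.integer(code)
    }
  }
  if (anyNA(out$group)) stop("missing group label")
  out
}

#' Discretize continuous cohort columns
#'
#' Replaces every continuous column by its bin code under the codebook's
#' discretization rule; categorical columns are untouched. The rule is total
#' on the reals: every finite value falls in exactly one bin.
#'
#' @param table encoded cohort data.frame (see [encode_dataset()]).
#' @param cb a [codebook()].
#' @return The data.frame with continuous columns replaced by integer codes.
#' @export
discretize <- function(table, cb) {
  stopifnot(is.data.frame(table), inherits(cb, "codebook"))
  for (nm in intersect(names(table), names(cb$variables))) {
    spec <- cb$variables[[nm]]
    if (spec$kind != "continuous") next
    x <- as.numeric(table[[nm]])
    if (any(!is.finite(x))) stop("non-finite value in column '", nm, "'")
    table[[nm]] <- discretize_values(x, spec)
  }
  table
}

discretize_values <- function(x, spec) {
  bin <- rep_len(1L, length(x))
  for (i in seq_along(spec$cutpoints)) {
    up <- if (spec$closed[i] == "left") x >= spec$cutpoints[i]
          else x > spec$cutpoints[i]
    bin[up] <- i + 1L
  }
  spec$bin_codes[bin]
}

#' Read / write a cohort CSV
#'
#' Comma-delimited, period decimal separator, UTF-8, mandatory header row of
#' variable names. `read_cohort_csv()` rejects ragged rows with the
#' offending line number; the write/read round trip is lossless.
#'
#' @param path file path.
#' @return `read_cohort_csv()`: a data.frame of character/numeric columns.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0L) stop("empty file (missing header): ", path)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row at line %d of %s (%d fields, header has %d)",
                 bad, path, nf[bad], nf[1L]))
  }
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  check.names = FALSE)
}

#' @rdname read_cohort_csv
#' @param table data.frame to write.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}
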