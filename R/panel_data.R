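#' Balanced panel time-series dataset
#'
#' The universal input container of the package: repeated measurements of a
#' set of variables on a set of subjects at a common grid of ordinal time
#' points, optionally split into experimental conditions (e.g. diet arms)
#' that are always analyzed separately. Construction validates balance —
#' every subject must have every variable at every time point within a
#' condition — and refuses missing or duplicated cells; no imputation is
#' ever performed. At least 2 subjects and 4 time points are required, the
#' minimum at which the downstream panel tests are defined.
#'
#' Time is ordinal: whatever the declared time column contains (clock times,
#' sample indices), it is mapped to `0..T-1` by sort order within condition,
#' and downstream lag-based tests treat consecutive points as one lag apart.
#' The original time labels are retained as metadata.
#'
#' @param data data.frame with columns `subject`, `time`, `variable`,
#'   `value`, and optionally `condition`.
#' @param units optional named character vector of measurement units per
#'   variable (free text, metadata only).
#' @param meta optional list of metadata (e.g. transformation log).
#' @return An object of class `panel_dataset` with fields `data` (long
#'   data.frame with ordinal integer `time`), `subjects`, `variables`,
#'   `conditions`, `n_subjects`, `n_times` (named per condition), `units`,
#'   `meta` (including `time_labels` per condition).
#' @export
panel_dataset <- function(data, units = NULL, meta = list()) {
  req <- c("subject", "time", "variable", "value")
  if (!is.data.frame(data)) stop_("`data` must be a data.frame")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop_("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!"condition" %in% names(data)) data$condition <- "all"
  data <- data[, c("subject", "condition", "time", "variable", "value")]
  data$subject <- as.character(data$subject)
  data$condition <- as.character(data$condition)
  data$variable <- as.character(data$variable)
  if (nrow(data) == 0L) stop_("empty dataset")
  if (!is.numeric(data$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(data$value))))
    stop_("non-numeric value(s) at row(s): %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(!is.finite(data$value))) {
    bad <- which(!is.finite(data$value))
    stop_("missing or non-finite value(s) at row(s): %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }

  key <- paste(data$subject, data$condition, data$time, data$variable, sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE]
    stop_("duplicate (subject, condition, time, variable) cell(s), e.g. subject %s, time %s, variable %s",
          d$subject[1], as.character(d$time[1]), d$variable[1])
  }

  conditions <- unique(data$condition)
  variables <- unique(data$variable)
  subjects <- unique(data$subject)
  if (anyDuplicated(variables)) stop_("variable names must be unique")
  if (length(subjects) < 2L) stop_("at least 2 subjects required (got %d)", length(subjects))

  time_labels <- list()
  n_times <- integer(0)
  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    dc <- data[data$condition == cond, , drop = FALSE]
    tl <- sort(unique(dc$time))
    if (length(tl) < 4L) {
      stop_("condition '%s': at least 4 time points required (got %d)", cond, length(tl))
    }
    # balance: every (subject, variable) must have exactly the full time grid
    tab <- table(dc$subject, dc$variable)
    if (any(tab != length(tl))) {
      idx <- which(tab != length(tl), arr.ind = TRUE)[1, ]
      subj <- rownames(tab)[idx[1]]; varb <- colnames(tab)[idx[2]]
      have <- dc$time[dc$subject == subj & dc$variable == varb]
      gap <- setdiff(as.character(tl), as.character(have))
      stop_("unbalanced panel in condition '%s': subject '%s', variable '%s' has %d of %d time points%s",
            cond, subj, varb, tab[idx[1], idx[2]], length(tl),
            if (length(gap)) paste0(" (missing time ", paste(gap, collapse = ", "), ")") else "")
    }
    missing_subj <- setdiff(subjects, unique(dc$subject))
    if (length(missing_subj)) {
      stop_("unbalanced panel: subject(s) %s absent from condition '%s'",
            paste(missing_subj, collapse = ", "), cond)
    }
    dc$time <- match(dc$time, tl) - 1L
    time_labels[[cond]] <- tl
    n_times[cond] <- length(tl)
    out[[ci]] <- dc
  }
  data <- do.call(rbind, out)
  ord <- order(match(data$condition, conditions), match(data$subject, subjects),
               data$time, match(data$variable, variables))
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  if (!is.null(units)) {
    units <- units[intersect(names(units), variables)]
  }
  meta$time_labels <- time_labels
  structure(list(
    data = data,
    subjects = subjects,
    variables = variables,
    conditions = conditions,
    n_subjects = length(subjects),
    n_times = n_times,
    units = units,
    meta = meta
  ), class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("<panel_dataset> %d subjects x %s time points x %d variables\n",
              x$n_subjects,
              paste(unique(x$n_times), collapse = "/"),
              length(x$variables)))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  variables: ", paste(x$variables, collapse = ", "), "\n")
  tr <- x$meta$transformations
  if (length(tr)) cat("  transformations:", paste(unlist(tr), collapse = "; "), "\n")
  invisible(x)
}

#' Extract one condition's measurements as a subjects x times x variables array
#'
#' @param panel a [panel_dataset()].
#' @param condition condition label; may be omitted when the panel has a
#'   single condition.
#' @return numeric array of dimension `N x T x V` with dimnames.
#' @export
panel_array <- function(panel, condition = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (is.null(condition)) {
    if (length(panel$conditions) != 1L) {
      stop_("panel has multiple conditions (%s); specify one",
            paste(panel$conditions, collapse = ", "))
    }
    condition <- panel$conditions
  }
  if (!condition %in% panel$conditions) stop_("unknown condition '%s'", condition)
  dc <- panel$data[panel$data$condition == condition, , drop = FALSE]
  N <- panel$n_subjects; T_ <- panel$n_times[[condition]]; V <- length(panel$variables)
  arr <- array(NA_real_, dim = c(N, T_, V),
               dimnames = list(panel$subjects, NULL, panel$variables))
  i <- match(dc$subject, panel$subjects)
  k <- match(dc$variable, panel$variables)
  arr[cbind(i, dc$time + 1L, k)] <- dc$value
  arr
}

#' Restrict a panel dataset to one condition
#'
#' @inheritParams panel_array
#' @return a [panel_dataset()] containing only the requested condition.
#' @export
filter_condition <- function(panel, condition) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (!condition %in% panel$conditions) stop_("unknown condition '%s'", condition)
  dc <- panel$data[panel$data$condition == condition, , drop = FALSE]
  dc$time <- panel$meta$time_labels[[condition]][dc$time + 1L]
  panel_dataset(dc, units = panel$units,
                meta = panel$meta[setdiff(names(panel$meta), "time_labels")])
}

infer_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a balanced panel dataset from a delimited text file
#'
#' Long layout expects one row per measurement with subject, time, variable
#' and value columns (plus an optional condition column); wide layout
#' expects one row per (subject, condition, time) with one column per
#' variable. The delimiter is inferred from the file extension (`.csv` is
#' comma, anything else tab). Column names can be remapped via `schema`.
#'
#' @param path file path.
#' @param layout `"long"` or `"wide"`.
#' @param schema named list mapping the canonical roles `subject`,
#'   `condition`, `time`, `variable`, `value` to the file's column names.
#'   Roles absent from the file (e.g. `condition`) may be omitted.
#' @param units optional named character vector of units per variable.
#' @return a validated [panel_dataset()].
#' @export
read_panel <- function(path, layout = c("long", "wide"), schema = list(),
                       units = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_delim(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  role <- function(r, default) schema[[r]] %||% default
  if (layout == "long") {
    cols <- c(subject = role("subject", "subject"),
              time = role("time", "time"),
              variable = role("variable", "variable"),
              value = role("value", "value"))
    missing_cols <- setdiff(unname(cols), names(df))
    if (length(missing_cols)) stop_("column(s) not in file: %s", paste(missing_cols, collapse = ", "))
    long <- data.frame(subject = df[[cols["subject"]]],
                       time = df[[cols["time"]]],
                       variable = df[[cols["variable"]]],
                       value = df[[cols["value"]]],
                       stringsAsFactors = FALSE)
    cond_col <- role("condition", "condition")
    if (cond_col %in% names(df)) long$condition <- df[[cond_col]]
    if (!is.numeric(long$value)) {
      parsed <- suppressWarnings(as.numeric(long$value))
      if (any(is.na(parsed) & !is.na(long$value))) {
        bad <- which(is.na(parsed) & !is.na(long$value))
        stop_("non-numeric value(s) in column '%s' at file row(s): %s",
              cols["value"], paste(utils::head(bad + 1L, 5L), collapse = ", "))
      }
      long$value <- parsed
    }
  } else {
    id_cols <- c(role("subject", "subject"), role("time", "time"))
    cond_col <- role("condition", "condition")
    has_cond <- cond_col %in% names(df)
    missing_cols <- setdiff(id_cols, names(df))
    if (length(missing_cols)) stop_("column(s) not in file: %s", paste(missing_cols, collapse = ", "))
    var_cols <- setdiff(names(df), c(id_cols, if (has_cond) cond_col))
    if (!length(var_cols)) stop_("wide file has no variable columns")
    long <- do.call(rbind, lapply(var_cols, function(v) {
      val <- df[[v]]
      if (!is.numeric(val)) {
        parsed <- suppressWarnings(as.numeric(val))
        if (any(is.na(parsed) & !is.na(val))) {
          bad <- which(is.na(parsed) & !is.na(val))
          stop_("non-numeric value(s) in column '%s' at file row(s): %s",
                v, paste(utils::head(bad + 1L, 5L), collapse = ", "))
        }
        val <- parsed
      }
      out <- data.frame(subject = df[[id_cols[1]]], time = df[[id_cols[2]]],
                        variable = v, value = val, stringsAsFactors = FALSE)
      if (has_cond) out$condition <- df[[cond_col]]
      out
    }))
  }
  panel_dataset(long, units = units)
}

#' Write a panel dataset to a delimited text file
#'
#' Inverse of [read_panel()]: the written file re-reads into a dataset equal
#' cell-for-cell to the original. Values are serialized at full double
#' precision; rounding is a report-layer concern only.
#'
#' @param panel a [panel_dataset()].
#' @param path output path (`.csv` for comma, else tab).
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, layout = c("long", "wide")) {
  stopifnot(inherits(panel, "panel_dataset"))
  layout <- match.arg(layout)
  if (length(panel$variables) == 0L) stop_("panel has no variables")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_("directory does not exist: %s", dir)
  sep <- infer_delim(path)
  df <- panel$data
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (layout == "long") {
    out <- data.frame(subject = df$subject, condition = df$condition,
                      time = df$time, variable = df$variable,
                      value = fmt(df$value), stringsAsFactors = FALSE)
  } else {
    out <- NULL
    for (cond in panel$conditions) {
      arr <- panel_array(panel, cond)
      N <- dim(arr)[1]; T_ <- dim(arr)[2]
      base <- data.frame(subject = rep(panel$subjects, each = T_),
                         condition = cond,
                         time = rep(seq_len(T_) - 1L, times = N),
                         stringsAsFactors = FALSE)
      for (v in panel$variables) {
        base[[v]] <- fmt(as.vector(t(arr[, , v])))
      }
      out <- rbind(out, base)
    }
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Albumin-corrected serum calcium
#'
#' Standard correction of total serum calcium for serum albumin:
#' `corrected = total + 0.02 * (40 - albumin)` with calcium in mmol/L and
#' albumin in g/L. At the reference albumin of 40 g/L the correction is the
#' identity; the adjustment is affine in total calcium.
#'
#' @param total_calcium total serum calcium, mmol/L.
#' @param albumin serum albumin, g/L (must be positive).
#' @return corrected serum calcium, mmol/L (vectorized).
#' @export
correct_calcium <- function(total_calcium, albumin) {
  assert_flag_finite(total_calcium, "total_calcium")
  assert_flag_finite(albumin, "albumin")
  if (any(albumin <= 0)) stop_("`albumin` must be positive")
  total_calcium + 0.02 * (40 - albumin)
}

#' Within-subject differencing of one panel variable
#'
#' Replaces the named variable's series by its within-subject differences of
#' the given order; all other variables are truncated (their first `order`
#' time points dropped) so the panel stays balanced. The transformation is
#' appended to the dataset's metadata log.
#'
#' @param panel a [panel_dataset()].
#' @param variable variable name to difference.
#' @param order positive integer difference order, `< T`.
#' @return a new [panel_dataset()] with `T` reduced by `order`.
#' @export
difference <- function(panel, variable, order = 1L) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (!variable %in% panel$variables) stop_("unknown variable '%s'", variable)
  order <- as.integer(order)
  if (order < 1L) stop_("`order` must be a positive integer")
  long <- NULL
  for (cond in panel$conditions) {
    T_ <- panel$n_times[[cond]]
    if (order >= T_) {
      stop_("difference order %d must be smaller than T = %d (condition '%s')",
            order, T_, cond)
    }
    arr <- panel_array(panel, cond)
    Tn <- T_ - order
    keep <- (order + 1L):T_
    out <- arr[, keep, , drop = FALSE]
    dv <- apply(arr[, , variable, drop = TRUE], 1L, function(s) diff(s, differences = order))
    out[, , variable] <- t(matrix(dv, nrow = Tn))
    N <- dim(out)[1]; V <- dim(out)[3]
    long <- rbind(long, data.frame(
      subject = rep(panel$subjects, times = Tn * V),
      condition = cond,
      time = rep(rep(seq_len(Tn) - 1L, each = N), times = V),
      variable = rep(panel$variables, each = N * Tn),
      value = as.vector(out),
      stringsAsFactors = FALSE))
  }
  meta <- panel$meta[setdiff(names(panel$meta), "time_labels")]
  meta$transformations <- c(meta$transformations,
                            sprintf("difference(%s, order=%d)", variable, order))
  panel_dataset(long, units = panel$units, meta = meta)
}
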