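#' Construct and validate a set of longitudinal follow-up records
#'
#' The canonical long-format container: one row per observation interval,
#' with columns `id`, `event` (death indicator for the interval), `t1`
#' (age at measurement), `t2` (age at next measurement, or at death /
#' censoring for the last row of a subject) followed by one column per
#' biomarker measured at `t1`.
#'
#' Validation enforces: `t2 > t1` on every row; within each subject rows
#' ordered by `t1` with each `t2` equal to the next row's `t1` (chained
#' follow-up); `event = 1` only on a subject's last row; no duplicate
#' `(id, t1)` pairs; the same biomarker set on every row.
#'
#' @param df data frame with columns `id, event, t1, t2` then covariates.
#' @param covariate_names optional character vector naming the covariate
#'   columns to keep (defaults to every column after `t2`).
#' @return a `longitudinal_records` data frame (attribute `covariates`
#'   holds the biomarker column names).
#' @export
longitudinal_records <- function(df, covariate_names = NULL) {
  need <- c("id", "event", "t1", "t2")
  if (!all(need %in% names(df)))
    stop("format error: required columns missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  covs <- covariate_names %||% setdiff(names(df), need)
  if (!length(covs)) stop("format error: at least one covariate column is required")
  if (!all(covs %in% names(df)))
    stop("format error: covariate column(s) not found: ",
         paste(setdiff(covs, names(df)), collapse = ", "))
  df <- df[, c(need, covs), drop = FALSE]
  for (col in c("event", "t1", "t2", covs)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(conv) & !is.na(v) & !(trimws(as.character(v)) %in% c("", "NA")))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value in column '%s' at row %d", col, bad[1]))
      df[[col]] <- conv
    }
  }
  if (nrow(df)) {
    if (anyNA(df$t1) || anyNA(df$t2))
      stop("parse error: missing age (t1/t2) values are not allowed")
    df <- df[order(df$id, df$t1), , drop = FALSE]
    rownames(df) <- NULL
    if (anyDuplicated(df[, c("id", "t1")]))
      stop("validation error: duplicate (id, t1) rows")
    if (any(df$t2 <= df$t1)) {
      bad <- sum(df$t2 <= df$t1)
      warning(sprintf("dropping %d row(s) violating t2 > t1", bad))
      df <- df[df$t2 > df$t1, , drop = FALSE]
      rownames(df) <- NULL
    }
    sp <- split(seq_len(nrow(df)), df$id)
    for (idx in sp) {
      n <- length(idx)
      if (n > 1L) {
        if (max(abs(df$t2[idx[-n]] - df$t1[idx[-1L]])) > 1e-8)
          stop(sprintf("validation error: subject %s has t2 not matching the next row's t1",
                       format(df$id[idx[1]])))
        if (any(df$event[idx[-n]] == 1))
          stop(sprintf("validation error: subject %s has event = 1 before its last record",
                       format(df$id[idx[1]])))
      }
    }
    if (!all(df$event %in% c(0, 1)))
      stop("validation error: event must be 0 or 1")
  }
  structure(df, covariates = covs, class = c("longitudinal_records", "data.frame"))
}

#' Number of biomarkers in a records object
#' @param records a `longitudinal_records` object.
#' @return integer dimension k.
#' @export
n_covariates <- function(records) length(attr(records, "covariates"))

#' Read a long-format follow-up table from CSV
#'
#' Expects a delimited text file with a header; the first four columns are
#' subject id, interval death indicator, age at measurement and age at the
#' next measurement (or censoring), and every remaining column is treated
#' as a covariate unless `covariate_names` selects a subset. Missing
#' biomarker values may be encoded as empty fields or `NA`.
#'
#' @param path path to a CSV file (or a connection).
#' @param covariate_names optional character vector of covariates to keep.
#' @return a [longitudinal_records()] object.
#' @export
load_long_table <- function(path, covariate_names = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), check.names = FALSE)
  if (ncol(df) < 5L)
    stop("format error: expected at least 5 columns (id, event, t1, t2, covariate...)")
  names(df)[1:4] <- c("id", "event", "t1", "t2")
  longitudinal_records(df, covariate_names = covariate_names)
}

#' Write a long-format follow-up table to CSV
#'
#' Inverse of [load_long_table()]: emits `id, event, t1, t2` followed by
#' the covariate columns, at full double precision so that a written table
#' reloads loss-free.
#'
#' @param records a [longitudinal_records()] object.
#' @param path output file path.
#' @export
write_long_table <- function(records, path) {
  stopifnot(inherits(records, "longitudinal_records"))
  df <- as.data.frame(records)
  for (col in setdiff(names(df), "id"))
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE, scientific = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("I/O error writing '", path, "': ", conditionMessage(e)))
  invisible(path)
}

# Linearly interpolate interior missing values of one subject's covariate
# trajectory; leading/trailing NAs are left missing (never extrapolated).
interp_interior <- function(t, y) {
  obs <- which(!is.na(y))
  if (length(obs) < 2L) return(y)
  gap <- which(is.na(y))
  gap <- gap[gap > min(obs) & gap < max(obs)]
  if (length(gap))
    y[gap] <- stats::approx(t[obs], y[obs], xout = t[gap])$y
  y
}

#' Build the paired datasets consumed by the SPM estimators
#'
#' Produces two per-interval tables from chained longitudinal records:
#'
#' * `arbitrary` — consecutive same-subject observations at their native
#'   measurement times (used by the continuous-time estimator);
#' * `fixed` — each subject's trajectory resampled by linear interpolation
#'   onto the grid `t1, t1 + interval, ...` anchored at the subject's own
#'   first measurement age (used by the discrete-time estimator). The
#'   terminal interval runs from the last grid point to the subject's
#'   recorded final age, carrying the event flag; biomarker values are
#'   never extrapolated beyond the last measurement, so `y2` of a terminal
#'   interval is undefined.
#'
#' With `impute = TRUE`, interior missing biomarker values are filled by
#' within-subject linear interpolation before pairing; leading/trailing
#' missing values are never imputed. Rows whose `y1` is missing are
#' dropped, as are non-terminal rows with missing `y2`. Subjects with all
#' biomarker values missing are dropped entirely (with a warning if that
#' empties the output).
#'
#' @param records a [longitudinal_records()] object.
#' @param interval positive grid width (years) for the fixed-interval table.
#' @param impute impute interior missing biomarker values?
#' @return list with elements `fixed` and `arbitrary`, each a
#'   `paired_observations` data frame with columns
#'   `id, case, t1, t2, <cov>, <cov>.next`.
#' @export
prepare_data <- function(records, interval = 1, impute = TRUE) {
  stopifnot(inherits(records, "longitudinal_records"))
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
    stop("argument error: 'interval' must be a positive scalar")
  covs <- attr(records, "covariates")
  k <- length(covs)
  df <- as.data.frame(records)

  # fast path: complete data already chained on an exact `interval` grid
  # (each subject's own anchor), as produced by the fixed-interval
  # simulator -- the fixed and arbitrary tables coincide row-for-row up to
  # the terminal interval, and no interpolation is needed
  if (!anyNA(df[, covs, drop = FALSE])) {
    last <- !duplicated(df$id, fromLast = TRUE)
    first <- !duplicated(df$id)
    on_grid <- all(abs(df$t2[!last] - df$t1[!last] - interval) < 1e-9)
    if (on_grid) {
      nxt <- c(df$t1[-1], NA)
      if (all(abs(df$t2[!last] - nxt[!last]) < 1e-9)) {
        out <- df[, c("id", "event", "t1", "t2"), drop = FALSE]
        names(out)[2] <- "case"
        out$case <- ifelse(last, df$event, 0)
        for (j in covs) out[[j]] <- df[[j]]
        for (j in covs) out[[paste0(j, ".next")]] <-
          ifelse(last, NA_real_, c(df[[j]][-1], NA))
        rownames(out) <- NULL
        out <- structure(out, covariates = covs,
                         class = c("paired_observations", "data.frame"))
        return(list(fixed = out, arbitrary = out))
      }
    }
  }

  sp <- split(df, df$id)

  all_missing <- vapply(sp, function(s) all(is.na(as.matrix(s[, covs, drop = FALSE]))),
                        logical(1))
  if (any(all_missing)) {
    sp <- sp[!all_missing]
    if (!length(sp))
      warning("all covariates missing for all subjects; output is empty")
  }

  arb_rows <- list(); fix_rows <- list()
  for (s in sp) {
    tms <- s$t1
    y <- as.matrix(s[, covs, drop = FALSE])
    if (impute && k) for (j in seq_len(k)) y[, j] <- interp_interior(tms, y[, j])
    n <- nrow(s)
    tau <- s$t2[n]; ev <- s$event[n]

    # arbitrary-interval pairs: native measurement times
    if (n > 1L) {
      y2 <- y[-1L, , drop = FALSE]
      arb_rows[[length(arb_rows) + 1L]] <- pair_frame(
        s$id[1], case = rep(0, n - 1L), t1 = tms[-n], t2 = s$t2[-n],
        y1 = y[-n, , drop = FALSE], y2 = y2, covs = covs)
    }
    arb_rows[[length(arb_rows) + 1L]] <- pair_frame(
      s$id[1], case = ev, t1 = tms[n], t2 = tau,
      y1 = y[n, , drop = FALSE], y2 = matrix(NA_real_, 1L, k), covs = covs)

    # fixed-interval pairs: per-subject grid anchored at the first age
    grid <- seq(tms[1], tms[n] + 1e-9, by = interval)
    gy <- matrix(NA_real_, length(grid), k)
    for (j in seq_len(k)) {
      obs <- which(!is.na(y[, j]))
      if (length(obs) >= 2L)
        gy[, j] <- stats::approx(tms[obs], y[obs, j], xout = grid, rule = 1)$y
      else if (length(obs) == 1L)
        gy[abs(grid - tms[obs]) < 1e-9, j] <- y[obs, j]
    }
    m <- length(grid)
    if (m > 1L) {
      fix_rows[[length(fix_rows) + 1L]] <- pair_frame(
        s$id[1], case = rep(0, m - 1L), t1 = grid[-m],
        t2 = grid[-m] + interval,
        y1 = gy[-m, , drop = FALSE], y2 = gy[-1L, , drop = FALSE], covs = covs)
    }
    # the terminal interval: last grid point to the recorded final age
    # (tau always exceeds grid[m] because t2 > t1 on the last record)
    fix_rows[[length(fix_rows) + 1L]] <- pair_frame(
      s$id[1], case = ev, t1 = grid[m], t2 = tau,
      y1 = gy[m, , drop = FALSE], y2 = matrix(NA_real_, 1L, k), covs = covs)
  }
  list(fixed = finalize_pairs(fix_rows, covs),
       arbitrary = finalize_pairs(arb_rows, covs))
}

pair_frame <- function(id, case, t1, t2, y1, y2, covs) {
  out <- data.frame(id = rep(id, length(t1)), case = case, t1 = t1, t2 = t2)
  for (j in seq_along(covs)) out[[covs[j]]] <- y1[, j]
  for (j in seq_along(covs)) out[[paste0(covs[j], ".next")]] <- y2[, j]
  out
}

finalize_pairs <- function(rows, covs) {
  if (!length(rows)) {
    out <- pair_frame(character(0), numeric(0), numeric(0), numeric(0),
                      matrix(numeric(0), 0, length(covs)),
                      matrix(numeric(0), 0, length(covs)), covs)
  } else {
    out <- do.call(rbind, rows)
  }
  # y1 must be observed; y2 must be observed unless the row is terminal (case
  # flag carries the event and y2 is by construction NA only on terminal rows)
  y1na <- rowSums(is.na(out[, covs, drop = FALSE])) > 0
  y2na <- rowSums(is.na(out[, paste0(covs, ".next"), drop = FALSE])) > 0
  keep <- !y1na & (!y2na | is_terminal_row(out))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, covariates = covs,
            class = c("paired_observations", "data.frame"))
}

# terminal rows are the last retained row of each subject (y2 undefined there
# is legitimate: it is the death/censoring interval)
is_terminal_row <- function(df) {
  if (!nrow(df)) return(logical(0))
  last <- !duplicated(df$id, fromLast = TRUE)
  last
}

#' Construct a paired-observations table directly
#'
#' Mostly useful in tests and when importing externally prepared tables
#' (columns `id, case, t1, t2, <cov>, <cov>.next`).
#'
#' @param df data frame in the paired layout.
#' @param covariate_names covariate base names; default: every column
#'   between `t2` and the first `*.next` column.
#' @return a `paired_observations` data frame.
#' @export
paired_observations <- function(df, covariate_names = NULL) {
  need <- c("id", "case", "t1", "t2")
  if (!all(need %in% names(df)))
    stop("format error: required columns missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  covs <- covariate_names %||% {
    rest <- setdiff(names(df), need)
    rest[!endsWith(rest, ".next")]
  }
  if (!length(covs) || !all(c(covs, paste0(covs, ".next")) %in% names(df)))
    stop("format error: paired table needs <cov> and <cov>.next columns")
  if (any(df$t2 <= df$t1)) stop("validation error: t2 > t1 violated")
  structure(df[, c(need, covs, paste0(covs, ".next"))],
            covariates = covs, class = c("paired_observations", "data.frame"))
}
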