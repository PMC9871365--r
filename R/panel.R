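#' Measure panel: subjects x conditions x trials x time
#'
#' The common container for one 1-Hz measure across a study: a 4-d numeric
#' array indexed by subject, condition (`treatment`, `control`), trial
#' (`T1`..`T5`) and grid time (one column per second of the protocol), plus a
#' logical validity mask of the same shape (`TRUE` = usable point).
#'
#' @param values 4-d numeric array `[subject, condition, trial, time]`.
#' @param mask logical array of the same shape; defaults to non-NA values.
#' @param measure measure name.
#' @param units unit label.
#' @return object of class `measure_panel`.
#' @export
measure_panel <- function(values, mask = NULL, measure = "", units = "") {
  stopifnot(length(dim(values)) == 4)
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(identical(dim(mask), dim(values)))
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, measure = measure,
                 units = units), class = "measure_panel")
}

#' @export
print.measure_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("measure_panel '%s' [%s]: %d subjects x %d conditions x %d trials x %d s, %.1f%% masked\n",
              x$measure, x$units, d[1], d[2], d[3], d[4],
              100 * mean(!x$mask)))
  invisible(x)
}

#' @export
dim.measure_panel <- function(x) dim(x$values)

#' Convert a panel to tidy long form
#'
#' @param panel a `measure_panel`.
#' @return data.frame with columns `subject, condition, trial, t, value,
#'   mask` (`t` in grid seconds, 0-based).
#' @export
panel_to_df <- function(panel) {
  d <- dim(panel$values)
  dn <- dimnames(panel$values)
  df <- expand.grid(subject = dn[[1]], condition = dn[[2]], trial = dn[[3]],
                    t = seq_len(d[4]) - 1L, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$value <- as.vector(panel$values)
  df$mask <- as.vector(panel$mask)
  df$measure <- panel$measure
  df
}

#' Build a panel from tidy long form
#'
#' @param df data.frame with columns `subject, condition, trial, t, value`
#'   and optionally `mask`.
#' @param measure,units labels (measure defaults to `df$measure[1]`).
#' @return a `measure_panel`.
#' @export
panel_from_df <- function(df, measure = NULL, units = "") {
  subjects <- unique(df$subject)
  conditions <- unique(df$condition)
  trials <- unique(df$trial)
  ts <- sort(unique(df$t))
  vals <- array(NA_real_, dim = c(length(subjects), length(conditions),
                                  length(trials), length(ts)),
                dimnames = list(subjects, conditions, trials, NULL))
  idx <- cbind(match(df$subject, subjects), match(df$condition, conditions),
               match(df$trial, trials), match(df$t, ts))
  vals[idx] <- df$value
  mask <- !is.na(vals)
  if (!is.null(df$mask)) {
    m2 <- array(TRUE, dim = dim(vals))
    m2[idx] <- df$mask
    mask <- mask & m2
  }
  measure_panel(vals, mask, measure %||% (df$measure[1] %||% ""), units)
}

#' Write / read tidy panel CSV
#' @param panel a `measure_panel`.
#' @param path file path.
#' @return `read_panel_csv` returns a `measure_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel_to_df(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  panel_from_df(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Extract the n x 2 x 5 cell table at one timepoint, dropping subjects with
# any masked cell (listwise deletion).
panel_cells_at <- function(panel, t_index) {
  y <- panel$values[, , , t_index, drop = FALSE]
  dim(y) <- dim(panel$values)[1:3]
  dimnames(y) <- dimnames(panel$values)[1:3]
  complete <- apply(!is.na(y), 1, all)
  list(y = y[complete, , , drop = FALSE], complete = complete)
}
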