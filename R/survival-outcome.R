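#' Right-censored survival outcomes
#'
#' Container for right-censored survival data: an observed time `t_i` per
#' subject together with the event indicator `d_i` (1 = event observed,
#' 0 = censored).  All downstream model fitting and evaluation in gsscox
#' consumes this class.
#'
#' @param time Positive observed times, one per subject.
#' @param status Event indicators, one per subject; 1 if the event was
#'   observed at `time`, 0 if the subject was censored.
#'
#' @return An object of class `"surv_outcome"`: a list with elements `time`
#'   and `status` (both numeric) and `n` (number of subjects).
#'
#' @examples
#' y <- surv_outcome(c(2.3, 1.1, 4.0), c(1, 0, 1))
#' y$n
#' @export
surv_outcome <- function(time, status) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != length(status))
    stop("'time' and 'status' must have the same length")
  if (length(time) == 0L) stop("empty survival outcome")
  if (anyNA(time) || anyNA(status)) stop("missing values in survival outcome")
  if (any(time <= 0)) stop("all survival times must be strictly positive")
  if (!all(status %in% c(0, 1))) stop("'status' must be 0 (censored) or 1 (event)")
  if (sum(status) == 0) stop("at least one event is required")
  structure(list(time = time, status = status, n = length(time)),
            class = "surv_outcome")
}

#' @export
print.surv_outcome <- function(x, ...) {
  cat(sprintf("Right-censored survival outcome: %d subjects, %d events (%.1f%% censored)\n",
              x$n, sum(x$status), 100 * mean(x$status == 0)))
  invisible(x)
}

as_surv_outcome <- function(y) {
  if (inherits(y, "surv_outcome")) return(y)
  if (inherits(y, "Surv")) return(surv_outcome(y[, "time"], y[, "status"]))
  if (is.data.frame(y) || is.matrix(y)) {
    cn <- colnames(y)
    if (!all(c("time", "status") %in% cn))
      stop("survival data must have 'time' and 'status' columns")
    return(surv_outcome(y[, "time"], y[, "status"]))
  }
  stop("cannot interpret 'y' as a survival outcome")
}

#' Read survival outcomes from a delimited file
#'
#' Reads a TSV/CSV file with a header containing columns `time` and `status`.
#' Row order must match the rows of the predictor matrix used alongside it.
#'
#' @param path Path to the file.  The delimiter is inferred from the
#'   extension (`.csv` uses a comma, anything else a tab).
#' @return A [surv_outcome] object.
#' @export
read_survival <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  if (!all(c("time", "status") %in% names(d)))
    stop("file must contain 'time' and 'status' columns: ", path)
  surv_outcome(d$time, d$status)
}

#' Read a predictor matrix from a delimited file
#'
#' Expects samples in rows and named predictors in columns, with a header
#' row.  A first column named `sample`, `id` or `""` is treated as row names.
#'
#' @param path Path to a TSV/CSV file.
#' @return A numeric matrix with column names.
#' @export
read_predictors <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  first <- names(d)[1L]
  if (first %in% c("", "sample", "id", "X")) {
    rn <- as.character(d[[1L]])
    d <- d[, -1L, drop = FALSE]
    x <- as.matrix(d)
    rownames(x) <- rn
  } else {
    x <- as.matrix(d)
  }
  storage.mode(x) <- "double"
  x
}
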