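#' Construct a longitudinal dataset for hidden Markov modelling
#'
#' Builds the long-format container used throughout the package: one row per
#' subject x time point, with a possibly-missing numeric response, a binary
#' missingness indicator derived from it, and fully observed covariates.
#' Rows are sorted by (series, time). Time points at which no measurement was
#' taken must be present as rows with a missing response, so that hidden-state
#' probabilities propagate across unobserved occasions.
#'
#' @param data a data.frame in long format.
#' @param id name of the subject/series identifier column.
#' @param time name of the integer time-index column (strictly increasing
#'   within each series).
#' @param response name of the numeric response column; `NA` marks a missing
#'   observation.
#' @param covariates character vector of covariate column names. Covariates
#'   must be complete (no missing cells).
#'
#' @return An object of class `hmm_data`: a list with elements
#'   `frame` (data.frame with columns `.id`, `.time`, `.y`, `.miss`, the
#'   covariates, and a `time` column mirroring `.time` so that time itself can
#'   be used as a covariate), `covariates`, `series` (row indices per series),
#'   and `n_series`.
#' @export
long_dataset <- function(data, id = "id", time = "time", response = "y",
                         covariates = character()) {
  stopifnot(is.data.frame(data))
  for (col in c(id, time, response)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in data", call. = FALSE)
    }
  }
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov) > 0 && !all(miss_cov %in% "time")) {
    stop("covariate column(s) not found: ",
         paste(setdiff(miss_cov, "time"), collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  if (is.character(y)) y[!nzchar(trimws(y))] <- NA
  y <- as.numeric(y)
  frame <- data.frame(
    .id = as.character(data[[id]]),
    .time = as.integer(data[[time]]),
    .y = y,
    .miss = as.integer(is.na(y)),
    stringsAsFactors = FALSE
  )
  frame$time <- as.numeric(frame$.time)
  for (cov in setdiff(covariates, "time")) {
    v <- data[[cov]]
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("covariate '", cov, "' is missing for series '",
           frame$.id[bad], "' at time ", frame$.time[bad],
           "; covariates must be complete", call. = FALSE)
    }
    frame[[cov]] <- as.numeric(v)
  }
  ord <- order(match(frame$.id, unique(frame$.id)), frame$.time)
  frame <- frame[ord, , drop = FALSE]
  rownames(frame) <- NULL
  series <- split(seq_len(nrow(frame)), factor(frame$.id, levels = unique(frame$.id)))
  for (idx in series) {
    tt <- frame$.time[idx]
    if (any(diff(tt) <= 0)) {
      stop("times are not strictly increasing within series '",
           frame$.id[idx[1]], "'", call. = FALSE)
    }
  }
  if (length(series) < 1) stop("dataset must contain at least one series", call. = FALSE)
  structure(
    list(frame = frame,
         covariates = union(covariates, character()),
         series = series,
         n_series = length(series)),
    class = "hmm_data"
  )
}

#' @export
print.hmm_data <- function(x, ...) {
  cat("Longitudinal HMM dataset:", x$n_series, "series,",
      nrow(x$frame), "rows,", sum(x$frame$.miss), "missing responses\n")
  if (length(x$covariates) > 0) {
    cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a long-format delimited table
#'
#' Reads a delimited text file (CSV by default) into an [long_dataset()].
#' Empty or `NA` cells in the response column become missing observations.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named list mapping roles to file columns; must contain
#'   `id`, `time`, and `response`.
#' @param covariates covariate column names (file headers).
#' @param sep field separator.
#' @return An `hmm_data` object.
#' @export
read_long_table <- function(path,
                            column_map = list(id = "id", time = "time", response = "y"),
                            covariates = character(), sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  for (role in c("id", "time", "response")) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("column map entry '", role, "' (", if (is.null(col)) "unset" else col,
           ") does not match a file column", call. = FALSE)
    }
  }
  long_dataset(raw, id = column_map$id, time = column_map$time,
               response = column_map$response, covariates = covariates)
}

#' Write a longitudinal dataset back to delimited text
#'
#' Inverse of [read_long_table()] up to column order and float formatting.
#'
#' @param dataset an `hmm_data` object.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "hmm_data"))
  out <- dataset$frame
  keep <- c(".id", ".time", ".y", ".miss", setdiff(dataset$covariates, "time"))
  out <- out[, keep, drop = FALSE]
  names(out) <- c("id", "time", "y", "miss", setdiff(dataset$covariates, "time"))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Rebuild the missingness indicator from the response
#'
#' Sets the missingness flag to 1 exactly where the response is absent.
#' Idempotent: applying it twice gives the same dataset.
#'
#' @param dataset an `hmm_data` object.
#' @return The dataset with `.miss` recomputed.
#' @export
build_missing_indicator <- function(dataset) {
  stopifnot(inherits(dataset, "hmm_data"))
  dataset$frame$.miss <- as.integer(is.na(dataset$frame$.y))
  dataset
}

#' Build a design matrix from named covariates
#'
#' Returns the row-wise design matrix for one of the model's regression
#' submodels: a leading intercept column of ones (unless disabled) followed by
#' the named covariate columns in declared order. The time index is always
#' available under the name `"time"`.
#'
#' @param dataset an `hmm_data` object.
#' @param design character vector of covariate names (possibly empty).
#' @param intercept include a leading column of ones (default `TRUE`).
#' @param rows optional integer vector of row indices to keep.
#' @return A numeric matrix with one row per dataset row.
#' @export
design_matrix <- function(dataset, design = character(), intercept = TRUE,
                          rows = NULL) {
  stopifnot(inherits(dataset, "hmm_data"))
  frame <- dataset$frame
  unknown <- setdiff(design, names(frame))
  if (length(unknown) > 0) {
    stop("unknown covariate(s) in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, nrow(frame))
  for (nm in design) cols[[nm]] <- frame[[nm]]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  X
}

# First row index of every series (the t = 1 occasions).
first_rows <- function(dataset) {
  vapply(dataset$series, function(idx) idx[1], integer(1))
}
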