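#' Construct a two-arm trial dataset
#'
#' Assembles per-participant arm labels, a continuous outcome (missing values
#' allowed) and optional covariate columns into the container consumed by every
#' estimator in the package.
#'
#' @param arm Integer/numeric vector of arm indicators, 0 = comparator,
#'   1 = treatment. No missing values allowed.
#' @param y Numeric outcome vector, `NA` for dropouts. Same length as `arm`.
#' @param covariates Optional data.frame (or named list) of covariate columns,
#'   continuous or categorical, values may be `NA`.
#' @param id Optional participant identifiers; defaults to row numbers.
#' @return A data.frame of class `"trial_data"` with columns `id`, `arm`, `y`
#'   and any covariates.
#' @examples
#' trial_data(arm = c(0, 0, 1, 1), y = c(1.2, NA, 0.5, 2.0))
#' @export
trial_data <- function(arm, y, covariates = NULL, id = NULL) {
  if (anyNA(arm)) stop("every participant must have a non-missing arm label")
  arm <- as.numeric(arm)
  if (!all(arm %in% c(0, 1))) {
    bad <- unique(arm[!arm %in% c(0, 1)])
    stop("arm labels must be 0 (comparator) or 1 (treatment); found: ",
         paste(bad, collapse = ", "))
  }
  if (length(y) != length(arm)) stop("`y` and `arm` must have equal length")
  y <- as.numeric(y)
  counts <- table(factor(arm, levels = c(0, 1)))
  if (any(counts < 2)) {
    stop("each arm needs at least 2 participants (n0 = ", counts[["0"]],
         ", n1 = ", counts[["1"]], ")")
  }
  if (is.null(id)) id <- seq_along(arm)
  out <- data.frame(id = id, arm = arm, y = y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(arm)) {
      stop("covariates must have one row per participant")
    }
    reserved <- intersect(names(covariates), c("id", "arm", "y"))
    if (length(reserved)) {
      stop("covariate names clash with reserved columns: ",
           paste(reserved, collapse = ", "))
    }
    out <- cbind(out, covariates)
  }
  class(out) <- c("trial_data", "data.frame")
  out
}

#' @export
print.trial_data <- function(x, ...) {
  n <- table(factor(x$arm, levels = c(0, 1)))
  miss <- tapply(is.na(x$y), factor(x$arm, levels = c(0, 1)), sum)
  cat("Two-arm trial dataset:", nrow(x), "participants\n")
  cat(sprintf("  comparator (0): n = %d, missing outcomes = %d\n",
              n[["0"]], miss[["0"]]))
  cat(sprintf("  treatment  (1): n = %d, missing outcomes = %d\n",
              n[["1"]], miss[["1"]]))
  covs <- covariate_columns(x)
  if (length(covs)) cat("  covariates:", paste(covs, collapse = ", "), "\n")
  ti <- attr(x, "trim_info")
  if (!is.null(ti)) {
    cat(sprintf("  trimmed: p_used = %.4g, direction = %s, retained = %d + %d\n",
                ti$p_used, ti$direction, ti$retained[1], ti$retained[2]))
  }
  invisible(x)
}

covariate_columns <- function(data) {
  setdiff(names(data), c("id", "arm", "y"))
}

as_trial_data <- function(df) {
  trial_data(arm = df$arm, y = df$y, id = df$id,
             covariates = df[setdiff(names(df), c("id", "arm", "y"))])
}

#' Read a trial dataset from CSV
#'
#' Expects columns `id`, `arm` (coded 0/1), `y` (empty cells = missing
#' outcome) and optionally further covariate columns (empty cells = missing).
#'
#' @param path Path to a CSV file.
#' @return A [trial_data] object.
#' @seealso [write_trial_csv()]
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("NA", ""))
  needed <- c("id", "arm", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(df$arm)) {
    stop("missing arm label in row(s): ",
         paste(utils::head(which(is.na(df$arm)), 5), collapse = ", "))
  }
  if (!all(df$arm %in% c(0, 1))) {
    bad <- which(!df$arm %in% c(0, 1))
    stop("non-binary arm code in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (arm must be 0 or 1)")
  }
  if (!is.numeric(df$y)) {
    suppressWarnings(yn <- as.numeric(as.character(df$y)))
    bad <- which(!is.na(df$y) & is.na(yn))
    if (length(bad)) {
      stop("non-numeric outcome in column 'y', row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    df$y <- yn
  }
  as_trial_data(df)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trial_csv()]; missing values become empty cells, so
#' read-write round-trips are stable.
#'
#' @param data A [trial_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}
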