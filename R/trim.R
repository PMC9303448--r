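#' Specify a trimming rule
#'
#' @param fraction Trimming fraction p in \[0, 1): the proportion of each arm's
#'   (missing-padded) outcome distribution removed from one tail. Ignored in
#'   adaptive mode.
#' @param direction Which tail is trimmed away: `"lower"` (worst-value dropout,
#'   the default) or `"higher"`.
#' @param mode `"fixed"` (p chosen a priori, must be at least the largest
#'   observed per-arm dropout proportion) or `"adaptive"` (p set to that
#'   largest observed dropout proportion).
#' @return An object of class `"trim_spec"`.
#' @examples
#' trim_spec(0.5)                      # customary 50% lower trimming
#' trim_spec(direction = "higher", mode = "adaptive")
#' @export
trim_spec <- function(fraction = 0.5, direction = c("lower", "higher"),
                      mode = c("fixed", "adaptive")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot(is.numeric(fraction), length(fraction) == 1L)
    if (fraction < 0 || fraction >= 1) {
      stop("trimming fraction must lie in [0, 1)")
    }
  }
  structure(list(fraction = fraction, direction = direction, mode = mode),
            class = "trim_spec")
}

#' @export
print.trim_spec <- function(x, ...) {
  cat(sprintf("trim_spec: %s, %s-value trimming%s\n", x$mode, x$direction,
              if (x$mode == "fixed") sprintf(", p = %.4g", x$fraction) else ""))
  invisible(x)
}

observed_dropout <- function(data) {
  vapply(c(0, 1), function(j) mean(is.na(data$y[data$arm == j])), numeric(1))
}

resolve_fraction <- function(data, spec, tol = 1e-12) {
  pd <- observed_dropout(data)
  p_min <- max(pd)
  if (spec$mode == "adaptive") return(p_min)
  if (spec$fraction < p_min - tol) {
    worst <- which.max(pd) - 1L
    stop(sprintf(paste0("fixed trimming fraction p = %.4g is below the observed ",
                        "dropout proportion %.4g in arm %d; p must be >= p_min = %.4g"),
                 spec$fraction, p_min, worst, p_min))
  }
  spec$fraction
}

#' Trim a trial dataset
#'
#' Within each arm independently, missing outcomes are assigned the extreme
#' rank on the trimmed side (lowest rank for lower-value trimming), outcomes
#' are ordered, and exactly `ceiling(n_j * (1 - p))` participants are retained.
#' The precise value imputed to dropouts is never materialized; only ranks are
#' used. Ties at the trim boundary are broken by input row order. If the
#' dropout count in an arm exceeds the trimmed count, some retained rows still
#' have missing outcomes (the strong MNAR assumption is mechanically violated
#' in-sample); downstream fits exclude them with a warning.
#'
#' @param data A [trial_data] object.
#' @param spec A [trim_spec].
#' @return The retained rows as a [trial_data], with attribute `"trim_info"`:
#'   a list with `p_used`, `direction`, `retained` (per-arm retained counts),
#'   `boundary` (per-arm trim threshold, the most extreme retained observed
#'   outcome on the trimmed side) and `n_missing_retained`.
#' @examples
#' d <- trial_data(arm = rep(0:1, each = 4), y = c(1, 2, 3, 4, 2, 3, 4, 5))
#' tm_trim(d, trim_spec(0.5))
#' @export
tm_trim <- function(data, spec) {
  stopifnot(inherits(data, "trial_data"), inherits(spec, "trim_spec"))
  p <- resolve_fraction(data, spec)
  keep_idx <- integer(0)
  retained <- integer(2)
  boundary <- numeric(2)
  n_missing_retained <- integer(2)
  for (j in c(0L, 1L)) {
    rows <- which(data$arm == j)
    yj <- data$y[rows]
    nj <- length(rows)
    # epsilon guard: p is often an exact dropout proportion k/n, and floating
    # point can push n*(1-p) fractionally above the integer n-k
    n_keep <- as.integer(ceiling(nj * (1 - p) - 1e-9))
    if (n_keep < 1L) {
      stop("arm ", j, " would be left empty after trimming (p = ", p, ")")
    }
    key <- if (spec$direction == "lower") {
      ifelse(is.na(yj), -Inf, yj)
    } else {
      ifelse(is.na(yj), Inf, yj)
    }
    ord <- order(key, seq_along(key)) # stable within ties and missing block
    kept <- if (spec$direction == "lower") {
      ord[(nj - n_keep + 1L):nj]
    } else {
      ord[seq_len(n_keep)]
    }
    obs_kept <- data$y[rows[kept]]
    obs_kept <- obs_kept[!is.na(obs_kept)]
    if (!length(obs_kept)) {
      stop("no observed outcomes retained in arm ", j, " after trimming")
    }
    retained[j + 1L] <- n_keep
    boundary[j + 1L] <- if (spec$direction == "lower") min(obs_kept) else max(obs_kept)
    n_missing_retained[j + 1L] <- n_keep - length(obs_kept)
    keep_idx <- c(keep_idx, rows[kept])
  }
  keep_idx <- sort(keep_idx)
  out <- data[keep_idx, , drop = FALSE]
  class(out) <- c("trial_data", "data.frame")
  attr(out, "trim_info") <- list(p_used = p,
                                 direction = spec$direction,
                                 retained = retained,
                                 boundary = boundary,
                                 n_missing_retained = n_missing_retained)
  out
}
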