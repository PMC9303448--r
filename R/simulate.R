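#' Design of a synthetic two-arm trial
#'
#' @param n_per_arm Participants per arm (a single count, or length 2 for
#'   comparator and treatment).
#' @param effect True treatment effect beta, in outcome units.
#' @param arm_sigmas Length-2 vector (sigma0, sigma1) of total outcome SDs.
#' @param outcome_family `"normal"` or `"lognormal"`. For log-normal outcomes
#'   the exponentiated scale is chosen so that each arm's outcome-scale SD
#'   equals `arm_sigmas`, with the effect added on the outcome scale.
#' @param covariate_effect Coefficient gamma on a standard-normal covariate
#'   `u` (0 = no covariate column). The residual SD is chosen so the total
#'   outcome SD equals `arm_sigmas`, so `gamma^2` must not exceed `sigma_j^2`.
#' @param mu0 Comparator-arm mean (default 0).
#' @return An object of class `"trial_design"`.
#' @examples
#' trial_design(n_per_arm = 500, effect = 0.5)
#' @export
trial_design <- function(n_per_arm = 500, effect = 0.5, arm_sigmas = c(1, 1),
                         outcome_family = c("normal", "lognormal"),
                         covariate_effect = 0, mu0 = 0) {
  outcome_family <- match.arg(outcome_family)
  if (length(n_per_arm) == 1L) n_per_arm <- rep(n_per_arm, 2)
  stopifnot(length(n_per_arm) == 2L, all(n_per_arm >= 2),
            length(arm_sigmas) == 2L, all(arm_sigmas > 0))
  if (covariate_effect^2 > min(arm_sigmas)^2 + 1e-12) {
    stop("infeasible residual variance: covariate_effect^2 = ",
         covariate_effect^2, " exceeds an arm variance")
  }
  structure(list(n_per_arm = as.integer(n_per_arm), effect = effect,
                 arm_sigmas = arm_sigmas, outcome_family = outcome_family,
                 covariate_effect = covariate_effect, mu0 = mu0),
            class = "trial_design")
}

# log-scale SD tau such that SD(exp(W)) = sigma for W ~ N(0, tau^2)
lognormal_tau <- function(sigma) {
  # (e^{tau^2} - 1) e^{tau^2} = sigma^2  =>  e^{tau^2} = (1 + sqrt(1 + 4 sigma^2)) / 2
  sqrt(log((1 + sqrt(1 + 4 * sigma^2)) / 2))
}

#' Generate a synthetic trial
#'
#' Draws outcomes y = mu_j + gamma * u + eps per arm, with `u` standard normal
#' (included as a covariate column when `covariate_effect != 0`) and residuals
#' scaled so the total outcome SD equals the design's `arm_sigmas`. For the
#' log-normal family the latent normal is exponentiated and centred so arm
#' means differ by the design effect on the outcome scale and the outcome SD
#' is preserved.
#'
#' @param design A [trial_design].
#' @param seed Optional integer seed; a fixed seed reproduces the dataset
#'   exactly.
#' @return A [trial_data] with complete outcomes (apply missingness with
#'   [apply_dropout()] / [apply_covariate_missingness()]).
#' @export
generate_trial <- function(design, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_per_arm
  arm <- rep(c(0, 1), times = n)
  mu <- design$mu0 + design$effect * arm
  gamma <- design$covariate_effect
  sig <- design$arm_sigmas[arm + 1]
  u <- stats::rnorm(sum(n))
  if (design$outcome_family == "normal") {
    eps <- stats::rnorm(sum(n), sd = sqrt(sig^2 - gamma^2))
    y <- mu + gamma * u + eps
  } else {
    # latent V = gamma*u + eps ~ N(0, sigma_j^2), rescaled to log-scale SD tau
    eps <- stats::rnorm(sum(n), sd = sqrt(sig^2 - gamma^2))
    v <- gamma * u + eps
    tau <- lognormal_tau(sig)
    w <- v * tau / sig
    y <- mu + exp(w) - exp(tau^2 / 2)
  }
  covs <- if (gamma != 0) data.frame(u = u) else NULL
  trial_data(arm = arm, y = y, covariates = covs)
}

#' Missingness mechanisms
#'
#' Constructors for the dropout mechanisms accepted by [apply_dropout()] and
#' [apply_covariate_missingness()]:
#'
#' * `mech_restricted(arm, pd, c, direction)`: exactly `round(pd * n_arm)`
#'   outcomes deleted, drawn uniformly without replacement from the rows whose
#'   pre-deletion outcome lies in the lowest (or highest) fraction `c` of the
#'   arm's empirical outcome distribution (homogeneous dropout).
#' * `mech_mcar(arm, pd)`: `mech_restricted` with `c = 1`.
#' * `mech_logit(intercept, slope_u, arm_offsets)`: each row missing
#'   independently with probability
#'   `plogis(intercept + slope_u * u + arm_offsets[arm + 1])` (both arms).
#' * `mech_threshold(arm, pd, tail)`: deletes exactly the most extreme
#'   `round(pd * n_arm)` values in the stated tail (the threshold selection
#'   model that attains the maximum-bias bounds).
#'
#' @param arm Arm the mechanism applies to (0 or 1).
#' @param pd Dropout proportion.
#' @param c Spread bound of the affected region.
#' @param direction,tail Which tail is affected.
#' @param intercept,slope_u Logit coefficients on 1 and the covariate `u`.
#' @param arm_offsets Length-2 additive logit offsets (comparator, treatment).
#' @return An object of class `"dropout_mechanism"`.
#' @name mechanisms
NULL

new_mechanism <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "dropout_mechanism")
}

#' @rdname mechanisms
#' @export
mech_restricted <- function(arm, pd, c = 1, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  sc <- dropout_scenario(pd, c, direction) # validates pd <= c etc.
  stopifnot(arm %in% c(0, 1))
  new_mechanism("restricted_homogeneous", arm = arm, pd = sc$pd, c = sc$c,
                direction = direction)
}

#' @rdname mechanisms
#' @export
mech_mcar <- function(arm, pd) mech_restricted(arm, pd, c = 1)

#' @rdname mechanisms
#' @export
mech_logit <- function(intercept, slope_u = 0, arm_offsets = c(0, 0)) {
  stopifnot(length(arm_offsets) == 2L)
  new_mechanism("logit_covariate", intercept = intercept, slope_u = slope_u,
                arm_offsets = arm_offsets)
}

#' @rdname mechanisms
#' @export
mech_threshold <- function(arm, pd, tail = c("higher", "lower")) {
  tail <- match.arg(tail)
  stopifnot(arm %in% c(0, 1), pd >= 0, pd < 1)
  new_mechanism("threshold_worst_case", arm = arm, pd = pd, tail = tail)
}

mechanism_missing <- function(data, mech, target = data$y) {
  miss <- rep(FALSE, nrow(data))
  if (mech$kind == "logit_covariate") {
    if (is.null(data$u)) stop("logit mechanism requires a covariate column 'u'")
    pr <- stats::plogis(mech$intercept + mech$slope_u * data$u +
                          mech$arm_offsets[data$arm + 1])
    miss <- stats::runif(nrow(data)) < pr
    return(miss)
  }
  rows <- which(data$arm == mech$arm)
  v <- target[rows]
  n <- length(rows)
  n_del <- round(mech$pd * n)
  if (n_del == 0) return(miss)
  if (mech$kind == "restricted_homogeneous") {
    m_region <- round(mech$c * n)
    if (n_del > m_region) {
      stop("requested ", n_del, " deletions exceed the affected region size ",
           m_region)
    }
    ord <- order(v)
    region <- if (mech$direction == "lower") ord[seq_len(m_region)] else
      ord[(n - m_region + 1L):n]
    del <- sample(region, n_del)
  } else { # threshold_worst_case
    ord <- order(v)
    del <- if (mech$tail == "lower") ord[seq_len(n_del)] else
      ord[(n - n_del + 1L):n]
  }
  miss[rows[del]] <- TRUE
  miss
}

#' Apply outcome missingness to a trial dataset
#'
#' Mechanisms are evaluated on the complete pre-deletion outcomes (region
#' membership uses the true empirical quantiles within arm); when several
#' mechanisms are given their missingness indicators are unioned.
#'
#' @param data A [trial_data] with fully observed outcomes.
#' @param mechanisms A `"dropout_mechanism"` or list of them (see
#'   [mechanisms]).
#' @param seed Optional integer seed.
#' @return The dataset with `y` set to `NA` for dropouts.
#' @export
apply_dropout <- function(data, mechanisms, seed = NULL) {
  stopifnot(inherits(data, "trial_data"))
  if (anyNA(data$y)) {
    stop("apply_dropout expects fully observed outcomes; compose mechanisms ",
         "in a single call instead of chaining")
  }
  if (inherits(mechanisms, "dropout_mechanism")) mechanisms <- list(mechanisms)
  if (!is.null(seed)) set.seed(seed)
  miss <- rep(FALSE, nrow(data))
  for (m in mechanisms) miss <- miss | mechanism_missing(data, m)
  data$y[miss] <- NA_real_
  data
}

#' Apply covariate missingness to a trial dataset
#'
#' As [apply_dropout()] but targeting a covariate column; region-based
#' mechanisms rank on the covariate's own values.
#'
#' @inheritParams apply_dropout
#' @param covariate Name of the covariate column (default `"u"`).
#' @return The dataset with the covariate set to `NA` where selected.
#' @export
apply_covariate_missingness <- function(data, mechanisms, covariate = "u",
                                        seed = NULL) {
  stopifnot(inherits(data, "trial_data"))
  check_covariates(data, covariate)
  if (inherits(mechanisms, "dropout_mechanism")) mechanisms <- list(mechanisms)
  if (!is.null(seed)) set.seed(seed)
  miss <- rep(FALSE, nrow(data))
  for (m in mechanisms) {
    miss <- miss | mechanism_missing(data, m, target = data[[covariate]])
  }
  data[[covariate]][miss] <- NA_real_
  data
}
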