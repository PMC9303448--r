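#' Describe a homogeneous dropout scenario for one arm
#'
#' Parameterizes dropout that is homogeneous within a quantile region of the
#' outcome distribution: a proportion `pd` of the arm drops out, with the
#' affected region the lowest (or highest) fraction `c` of the distribution;
#' within the region every value is equally likely to be missing (at rate
#' `pd / c`). `c = 1` is MCAR; `c = pd` is fully directional dropout.
#'
#' @param pd Dropout proportion in \[0, 1).
#' @param c Spread bound in (0, 1\]: quantile extent of the affected region.
#' @param direction `"lower"` or `"higher"`: which tail the dropout affects.
#' @return An object of class `"dropout_scenario"`.
#' @examples
#' dropout_scenario(0.2, 1)    # 20% MCAR dropout
#' dropout_scenario(0.2, 0.2)  # the lowest 20% of values drop out
#' @export
dropout_scenario <- function(pd, c = 1, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(pd), is.numeric(c), length(pd) == 1L, length(c) == 1L)
  if (pd < 0 || pd >= 1) stop("dropout proportion pd must lie in [0, 1)")
  if (c <= 0 || c > 1) stop("spread bound c must lie in (0, 1]")
  if (pd > c + 1e-12) {
    stop("dropout mass pd = ", pd, " cannot exceed the affected region mass c = ", c)
  }
  structure(list(pd = pd, c = c, direction = direction),
            class = "dropout_scenario")
}

#' @export
print.dropout_scenario <- function(x, ...) {
  cat(sprintf("dropout scenario: pd = %.4g homogeneous over the %s %.4g of the distribution\n",
              x$pd, if (x$direction == "lower") "lowest" else "highest", x$c))
  invisible(x)
}

#' Location-shift bias of the trimmed-means estimator
#'
#' Bias of the TM estimate for the population mean difference when the arms
#' are normal with unequal SDs and the strong MNAR assumption holds:
#' (sigma1 - sigma0) * phi(Phi^-1(p)) / (1 - p) for lower-value trimming,
#' reducing to (sigma1 - sigma0) * sqrt(2/pi) at p = 0.5. The sign flips for
#' higher-value trimming.
#'
#' @param sigma1,sigma0 Full-sample SDs of treatment and comparator arms.
#' @param p Trimming fraction in (0, 1).
#' @param direction Trimming direction.
#' @return The bias, in outcome units, on the beta-hat minus beta scale.
#' @examples
#' location_shift_bias(1, 1.5, 0.5)  # -0.399
#' @export
location_shift_bias <- function(sigma1, sigma0, p = 0.5,
                                direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(sigma1 > 0, sigma0 > 0)
  if (p <= 0 || p >= 1) stop("trimming fraction p must lie in (0, 1)")
  b <- (sigma1 - sigma0) * stats::dnorm(stats::qnorm(p)) / (1 - p)
  if (direction == "higher") -b else b
}

#' Shift quantile under homogeneous dropout
#'
#' When homogeneous dropout with proportion `pd` and spread bound `c` extends
#' beyond the trimmed fraction `p`, the retained fraction no longer starts at
#' the p-quantile but at a lower quantile b: the retained observed mass below
#' c satisfies h_{b,c} * (1 - pd/c) = c - p, giving
#' b = c - c * (c - p) / (c - pd). When `c <= p` the strong MNAR assumption is
#' satisfied and b = p (no shift).
#'
#' @param p Trimming fraction in (0, 1).
#' @param c Spread bound of the dropout region.
#' @param pd Dropout proportion; must not exceed `p` (otherwise trimming is
#'   infeasible).
#' @return The shift quantile b, with b <= p.
#' @examples
#' strong_mnar_shift(0.5, 1, 0.2)  # 0.375
#' @export
strong_mnar_shift <- function(p, c, pd) {
  if (p <= 0 || p >= 1) stop("trimming fraction p must lie in (0, 1)")
  stopifnot(pd >= 0, c > 0, c <= 1)
  if (pd > p + 1e-12) {
    stop("dropout proportion pd = ", pd, " exceeds the trimming fraction p = ",
         p, "; trimming is infeasible")
  }
  if (c <= p + 1e-12) return(p)
  c - c * (c - p) / (c - pd)
}

#' Strong-MNAR bias of the trimmed-means estimator under homogeneous dropout
#'
#' Magnitude of the per-arm TM bias when homogeneous dropout (proportion `pd`,
#' spread bound `c`) extends beyond the trimmed fraction `p`:
#' -\[(c - p)/(1 - p)\] * sigma * (Q_{p,c} - Q_{b,c}), with b the shift
#' quantile of [strong_mnar_shift()]. Zero when the dropout is confined to the
#' trimmed fraction (`c <= p`); maximal over homogeneous mechanisms at
#' `c = 1` (MCAR).
#'
#' @param sigma Full-sample SD of the affected arm.
#' @inheritParams strong_mnar_shift
#' @return The bias magnitude in outcome units (non-negative). The sign on the
#'   treatment-effect scale depends on which arm is affected and on the
#'   trimming direction; see [combine_biases()].
#' @examples
#' strong_mnar_bias(1, 0.5, 1, 0.2)     # 0.19
#' strong_mnar_bias(1, 0.5, 0.75, 0.2)  # 0.06
#' @export
strong_mnar_bias <- function(sigma, p, c, pd) {
  stopifnot(sigma > 0)
  if (c <= p + 1e-12) return(0)
  b <- strong_mnar_shift(p, c, pd)
  -((c - p) / (1 - p)) * sigma * (q_factor(p, c) - q_factor(b, c))
}

#' Complete-case bias under homogeneous dropout
#'
#' Bias of the complete-case treatment-effect estimate when the comparator arm
#' suffers homogeneous dropout with proportion `pd` over the lowest fraction
#' `c` of its (normal) outcome distribution: B_C = mu0 - mu_c0, with the
#' complete-case mean mu_c0 the mean of the thinned mixture
#' \[(c - pd) mu_{0,c} + (1 - c) mu_{c,1}\] / (1 - pd). Zero when `pd = 0` or
#' `c = 1` (MCAR); mirrored in sign for higher-value dropout.
#'
#' @param sigma Full-sample SD of the affected arm.
#' @param c Spread bound of the dropout region.
#' @param pd Dropout proportion; must not exceed `c`.
#' @param direction Tail affected by the dropout.
#' @return The bias in outcome units, on the beta_c minus beta scale for
#'   dropout in the comparator arm (negative for lower-value dropout).
#' @examples
#' cca_bias(1, 0.2, 0.2)  # -0.34996
#' cca_bias(1, 1, 0.2)    # 0 (MCAR)
#' @export
cca_bias <- function(sigma, c, pd, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(sigma > 0, pd >= 0, pd < 1, c > 0, c <= 1)
  if (pd > c + 1e-12) stop("pd = ", pd, " exceeds the region mass c = ", c)
  if (pd == 0 || c >= 1) return(0)
  m_upper <- -q_factor(c, 1) # mean of intact region, standard scale
  m_lower <- if (abs(c - pd) < 1e-12) 0 else -q_factor(0, c)
  mc <- ((c - pd) * m_lower + (1 - c) * m_upper) / (1 - pd)
  b <- -sigma * mc
  if (direction == "higher") -b else b
}

#' Maximum complete-case bias (Copas-Jackson bound)
#'
#' The largest possible complete-case bias for an arm with dropout proportion
#' `pd`, attained when the missing values are exactly the most extreme `pd`
#' fraction of the distribution (a threshold selection model):
#' sigma * phi(Phi^-1(pd)) / (1 - pd).
#'
#' @param sigma Full-sample SD of the arm.
#' @param pd Dropout proportion in \[0, 1).
#' @return The absolute bias bound, in outcome units.
#' @examples
#' cca_max_bias(13.2, 0.471)  # about 9.93
#' @export
cca_max_bias <- function(sigma, pd) {
  stopifnot(sigma > 0)
  if (pd < 0 || pd >= 1) stop("dropout proportion pd must lie in [0, 1)")
  sigma * phi_at(pd) / (1 - pd)
}

#' Maximum trimmed-means bias under adversarial opposite-tail dropout
#'
#' The worst case for lower-value trimming is dropout of the *highest* values.
#' With selection probability ps = 1 - pd, the comparator-arm strong-MNAR bias
#' bound is -sigma0/(1 - p) * \[phi(Phi^-1(ps)) - phi(Phi^-1(ps - (1 - p))) +
#' phi(Phi^-1(1 - p))\], and the total bound adds the location-shift term
#' (sigma1 - sigma0) * phi(Phi^-1(p)) / (1 - p). Signs flip for higher-value
#' trimming.
#'
#' @param sigma0,sigma1 Full-sample SDs of the comparator and treatment arms.
#' @param p Trimming fraction in (0, 1).
#' @param pd Dropout proportion in the comparator arm; requires
#'   `ps - (1 - p) >= 0`, i.e. `pd <= p`.
#' @param direction Trimming direction.
#' @return A list of class `"max_bias_bounds"`: `tm_sm_max` (strong-MNAR
#'   bound), `tm_total_max`, `cca_max` (the Copas-Jackson complete-case bound
#'   for the same arm), `selection_probability` and `threshold` (the selection
#'   threshold in SD units from the arm mean).
#' @examples
#' tm_max_bias(1, 1, p = 0.5, pd = 0.2)$tm_sm_max  # -0.662
#' @export
tm_max_bias <- function(sigma0, sigma1 = sigma0, p = 0.5, pd = 0,
                        direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(sigma0 > 0, sigma1 > 0, pd >= 0, pd < 1)
  if (p <= 0 || p >= 1) stop("trimming fraction p must lie in (0, 1)")
  ps <- 1 - pd
  if (ps - (1 - p) < -1e-12) {
    stop("infeasible quantile argument: ps - (1 - p) = ", ps - (1 - p),
         " < 0; the retained fraction (1 - p) cannot exceed the selection ",
         "probability 1 - pd")
  }
  sm <- -sigma0 / (1 - p) * (phi_at(ps) - phi_at(max(ps - (1 - p), 0)) + phi_at(1 - p))
  ls <- (sigma1 - sigma0) * phi_at(p) / (1 - p)
  s <- if (direction == "higher") -1 else 1
  structure(list(tm_sm_max = s * sm,
                 tm_total_max = s * (sm + ls),
                 cca_max = cca_max_bias(sigma0, pd),
                 selection_probability = ps,
                 threshold = s * sigma0 * stats::qnorm(ps)),
            class = "max_bias_bounds")
}

#' @export
print.max_bias_bounds <- function(x, ...) {
  cat("maximum-bias bounds (adversarial opposite-tail dropout):\n")
  cat(sprintf("  TM strong-MNAR bound: %.4f\n", x$tm_sm_max))
  cat(sprintf("  TM total bound:       %.4f\n", x$tm_total_max))
  cat(sprintf("  CCA bound (|B_Cmax|): %.4f\n", x$cca_max))
  cat(sprintf("  selection probability: %.4g, threshold offset: %.4f\n",
              x$selection_probability, x$threshold))
  invisible(x)
}

#' Infer a full-sample SD from an observed (thinned) SD
#'
#' Homogeneous dropout with proportion `pd` over the lowest (or highest)
#' fraction `c` of a normal distribution leaves an observed sample whose SD is
#' a known multiple of the full-sample SD: the thinned distribution is the
#' mixture of the intact region and the homogeneously thinned region with
#' masses (1 - c) and (c - pd), rescaled by 1/(1 - pd). This inverts that
#' relation. With `c = 1` (MCAR) the observed SD is returned unchanged.
#'
#' @param observed_sd SD of the observed (post-dropout) outcomes, > 0.
#' @param c Spread bound of the dropout region.
#' @param pd Dropout proportion; `pd <= c`.
#' @return The implied full-sample SD.
#' @examples
#' infer_full_sd(13.2, c = 1, pd = 0.523)  # 13.2
#' @export
infer_full_sd <- function(observed_sd, c, pd) {
  stopifnot(observed_sd > 0, pd >= 0, pd < 1, c > 0, c <= 1)
  if (pd > c + 1e-12) stop("pd = ", pd, " exceeds the region mass c = ", c)
  if (pd == 0 || c >= 1) return(observed_sd)
  w1 <- (c - pd) / (1 - pd)
  w2 <- (1 - c) / (1 - pd)
  if (w1 < 1e-12) {
    m <- -q_factor(c, 1)
    e2 <- truncated_e2_std(c, 1)
  } else {
    m1 <- -q_factor(0, c)
    m2 <- -q_factor(c, 1)
    m <- w1 * m1 + w2 * m2
    e2 <- w1 * truncated_e2_std(0, c) + w2 * truncated_e2_std(c, 1)
  }
  g <- sqrt(e2 - m^2) # thinned SD of a standard normal
  observed_sd / g
}

#' Assemble a bias decomposition from components
#'
#' Low-level constructor: combines a location-shift bias and signed per-arm
#' strong-MNAR biases into a total bias, a bias-adjusted estimate
#' (tm_estimate - total bias) and the ordered estimate bounds.
#'
#' @param tm_estimate The TM treatment-effect estimate.
#' @param b_ls Location-shift bias component.
#' @param b_sm_arm0,b_sm_arm1 Signed strong-MNAR components (on the beta-hat
#'   minus beta scale).
#' @return An object of class `"bias_decomposition"`.
#' @examples
#' bias_decomposition(-8.26, -7.17, -10.36, 0)$bias_adjusted_estimate  # 9.27
#' @export
bias_decomposition <- function(tm_estimate, b_ls, b_sm_arm0, b_sm_arm1) {
  b_total <- b_ls + b_sm_arm0 + b_sm_arm1
  adj <- tm_estimate - b_total
  structure(list(tm_estimate = tm_estimate,
                 b_ls = b_ls,
                 b_sm_arm0 = b_sm_arm0,
                 b_sm_arm1 = b_sm_arm1,
                 b_total = b_total,
                 bias_adjusted_estimate = adj,
                 estimate_bounds = sort(c(tm_estimate, adj))),
            class = "bias_decomposition")
}

#' @export
print.bias_decomposition <- function(x, ...) {
  cat("TM estimator bias decomposition:\n")
  cat(sprintf("  location-shift bias (B_LS):      %8.4f\n", x$b_ls))
  cat(sprintf("  strong-MNAR bias, comparator:    %8.4f\n", x$b_sm_arm0))
  cat(sprintf("  strong-MNAR bias, treatment:     %8.4f\n", x$b_sm_arm1))
  cat(sprintf("  total bias (B_t):                %8.4f\n", x$b_total))
  cat(sprintf("  TM estimate:                     %8.4f\n", x$tm_estimate))
  cat(sprintf("  bias-adjusted estimate:          %8.4f\n",
              x$bias_adjusted_estimate))
  cat(sprintf("  estimate bounds:                 [%.4f, %.4f]\n",
              x$estimate_bounds[1], x$estimate_bounds[2]))
  invisible(x)
}

#' Combine per-arm dropout scenarios into a signed bias decomposition
#'
#' Computes the location-shift bias from the arm SDs and the signed per-arm
#' strong-MNAR biases from each arm's homogeneous dropout scenario, under a
#' common trimming direction. With lower-value trimming, violation of the
#' strong MNAR assumption in the comparator arm biases the effect estimate
#' upward (and a treatment-arm violation downward); both signs flip for
#' higher-value trimming. The dropout direction of every scenario must match
#' the trimming direction (opposite-tail dropout is the territory of
#' [tm_max_bias()]).
#'
#' @param tm_estimate The TM treatment-effect estimate to adjust.
#' @param sigma0,sigma1 Full-sample SDs (see [infer_full_sd()] when only
#'   observed SDs are available).
#' @param scenario0,scenario1 [dropout_scenario()] for each arm, or `NULL` for
#'   no dropout in that arm.
#' @param p Trimming fraction.
#' @param direction Trimming direction.
#' @return A `"bias_decomposition"` (see [bias_decomposition()]).
#' @export
combine_biases <- function(tm_estimate, sigma0, sigma1,
                           scenario0 = NULL, scenario1 = NULL,
                           p = 0.5, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  for (sc in list(scenario0, scenario1)) {
    if (!is.null(sc)) {
      stopifnot(inherits(sc, "dropout_scenario"))
      if (sc$direction != direction) {
        stop("dropout scenario direction '", sc$direction,
             "' is inconsistent with the trimming direction '", direction, "'")
      }
    }
  }
  b_ls <- location_shift_bias(sigma1, sigma0, p, direction)
  s <- if (direction == "higher") -1 else 1
  mag0 <- if (is.null(scenario0)) 0 else
    strong_mnar_bias(sigma0, p, scenario0$c, scenario0$pd)
  mag1 <- if (is.null(scenario1)) 0 else
    strong_mnar_bias(sigma1, p, scenario1$c, scenario1$pd)
  bias_decomposition(tm_estimate, b_ls, s * mag0, -s * mag1)
}
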