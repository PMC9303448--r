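# shared fixtures and independent Monte-Carlo oracles

toy_trial <- function() {
  trial_data(arm = c(rep(0, 5), rep(1, 5)),
             y = c(1, 2, 3, 4, NA, 2, 3, 4, 5, 6))
}

# mean of a N(mu, sigma^2) between its u- and v-quantiles, by rejection sampling
mc_truncated_mean <- function(mu, sigma, u, v, n = 2e5) {
  z <- stats::rnorm(n)
  lo <- if (u <= 0) -Inf else stats::qnorm(u)
  hi <- if (v >= 1) Inf else stats::qnorm(v)
  kept <- z[z > lo & z < hi]
  c(mean = mu + sigma * mean(kept),
    se = sigma * stats::sd(kept) / sqrt(length(kept)))
}

# complete-case mean shift after homogeneous deletion of a fraction pd from
# the region below the c-quantile of a standard normal
mc_cca_bias <- function(c., pd, n = 1e6) {
  z <- sort(stats::rnorm(n))
  m_region <- round(c. * n)
  del <- sample.int(m_region, round(pd * n))
  kept <- z[-del]
  c(bias = -mean(kept), se = stats::sd(kept) / sqrt(length(kept)))
}

# trimmed-mean shift when the top pd fraction is deleted and the lowest p
# fraction of the padded sample is trimmed away (adversarial dropout)
mc_tm_worst_bias <- function(p, pd, n = 1e6) {
  z <- sort(stats::rnorm(n))
  obs <- z[seq_len(round((1 - pd) * n))] # delete the top pd fraction
  n_keep <- ceiling(n * (1 - p))         # retained count incl. missing padding
  kept <- obs[(length(obs) - n_keep + 1L):length(obs)]
  mean(kept) - mc_truncated_mean(0, 1, p, 1, n = 2e6)[["mean"]]
}
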