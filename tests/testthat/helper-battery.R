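# shared replicated-battery runner for the recovery and calibration suites:
# one scorer is trained once (the instrument is calibrated once and applied
# to every corpus, mirroring how a single SAS panel serves all communities)

battery_scorer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulate_sas(360, seed = 360, noise_sd = 2)
      cache <<- profile_scorer(d$profiles, d$sas, seed = 360)
    }
    cache
  }
})

run_battery <- function(config) {
  fit <- canx(simulate_corpus(config), scorer = battery_scorer())
  sm <- summary(fit)
  reg <- sm$regression
  list(h1a_p = sm$h1$familiarity$p,
       h1b_r = sm$h1$proximity$estimate, h1b_p = sm$h1$proximity$p,
       h2_b = sm$h2$estimate, h2_p = sm$h2$p,
       h3_rho = sm$h3$estimate, h3_p = sm$h3$p,
       reg_p = setNames(reg$p, reg$predictor),
       reg_beta = setNames(reg$beta, reg$predictor))
}
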