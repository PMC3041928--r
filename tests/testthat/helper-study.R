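# The reference simulation study: 48 areas x 7 sources at anchor 23, bias
# means on [-3, 3] and bias SDs on [0.5, 2] (the generator defaults), each
# replicate fitted with the independent-bias model.  Built once per session
# and shared by the calibration, residual, agreement and weight tests.
.study <- new.env(parent = emptyenv())

replicate_study <- function(n = 20) {
  key <- paste0("reps", n)
  if (!is.null(.study[[key]])) return(.study[[key]])
  reps <- lapply(seq_len(n), function(rep) {
    gen <- simulate_dataset(sim_config(seed = rep))
    fit <- fit_model1(gen$table, 23, mcmc = mcmc_config(seed = rep))
    s <- fit$summary
    pick <- function(prefix) s[startsWith(s$parameter, prefix), ]
    th <- pick("theta["); mu <- pick("mu["); tau <- pick("tau[")
    res <- posterior_residuals(fit)
    wt <- model_weights(fit)
    list(table = gen$table, truth = gen$truth,
         theta = th, mu = mu, tau = tau,
         ssr = res$ssr, ssr_df = res$df,
         w = wt$w, w_bar = wt$w_bar, dic = fit$dic)
  })
  .study[[key]] <- reps
  reps
}

# one fully retained fit (draws kept) on the first replicate's table
full_fit_rep1 <- function() {
  if (is.null(.study$full1)) {
    gen <- simulate_dataset(sim_config(seed = 1))
    .study$full1 <- list(
      gen = gen,
      fit = fit_model1(gen$table, 23, mcmc = mcmc_config(seed = 1)))
  }
  .study$full1
}
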