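# Shared simulation helpers and hand-rolled oracles for the test suite.

# Small-cohort generator configuration for fast tests.
quick_config <- function(seed = 1L, n = 4000L, n_snps = 40L, ...) {
  generator_config(n_participants = n, n_snps = n_snps, seed = seed, ...)
}

# generate -> exclusions -> polygenic-score merge, mirroring the pipeline
# prep stage, so analysis functions can be exercised directly.
make_test_cohort <- function(cfg) {
  sim <- generate_cohort(cfg)
  ex <- apply_exclusions(sim$cohort)
  g <- sim$genotypes[match(ex$cohort$participant_id,
                           rownames(sim$genotypes)), , drop = FALSE]
  prs <- compute_prs(g, sim$panel)
  cohort <- ex$cohort
  cohort$prs_raw <- prs$prs_raw
  cohort$prs_std <- prs$prs_std
  cohort$genetic_group <- prs$genetic_group
  list(cohort = cohort, audit = ex$audit, genotypes = g,
       panel = sim$panel, sim = sim)
}

# Breslow partial log-likelihood for one covariate, computed directly from
# the definition (one term per event, full risk-set sums).  Used as a
# grid-search oracle for the Newton-Raphson fit.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[rs])))
  }
  ll
}

breslow_grid_mle <- function(time, event, x, interval = c(-5, 5)) {
  stats::optimize(function(b) breslow_loglik(b, time, event, x),
                  interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Nelson-Aalen cumulative hazard (the Breslow baseline at beta = 0).
nelson_aalen <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  data.frame(time = tt,
             cumhaz = cumsum(vapply(tt, function(s)
               sum(event == 1 & time == s) / sum(time >= s), numeric(1))))
}
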