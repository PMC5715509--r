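# Shared fixtures, generated once per test run and cached.

tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(simulation_config(
        n_samples = 120L, n_cpgs = 2500L, n_snps = 600L, seed = 11L,
        n_mqtl_cpgs = 60L, n_factor_cpgs = 40L, n_panel_cpgs = 60L))
    cache
  }
})

# Per-tissue preprocessing of the tiny cohort: proportions, design,
# chip-adjusted matrices, variability calls.
tiny_prep <- local({
  cache <- list()
  function(tissue = "cord_tissue") {
    if (is.null(cache[[tissue]])) {
      sim <- tiny_cohort()
      b <- sim$beta[[tissue]]
      props <- estimate_cell_proportions(b, sim$panels[[tissue]])
      design <- build_design(sim$metadata, props$proportions, tissue = tissue)
      adj <- combat_adjust(beta_to_m(b), sim$metadata$chip, design)
      ba <- m_to_beta(adj)
      cache[[tissue]] <<- list(props = props, design = design, m_adj = adj,
                               beta_adj = ba, calls = variability_stats(ba))
    }
    cache[[tissue]]
  }
})

# Independent normal-equations OLS oracle: coefficient, SE and two-sided P
# for the last column of [design, x].
ne_oracle <- function(y, x, design) {
  X <- cbind(design, x)
  XtXi <- solve(crossprod(X))
  b <- XtXi %*% crossprod(X, y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtXi) * s2)
  k <- ncol(X)
  tt <- unname(b[k] / se[k])
  list(effect = unname(b[k]), se = unname(se[k]), t = tt,
       p = 2 * pt(-abs(tt), df))
}
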