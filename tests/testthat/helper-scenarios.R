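# Shared fixtures, all generated in code.

# A random uniform scenario with the inflation limb guaranteed open.
# Deflation pressure may put closure anywhere (interior, none, or all).
random_uniform_scenario <- function() {
  v_max <- runif(1, 10, 50)
  ratio <- runif(1, 0.1, 0.7)
  k <- runif(1, 0.1, 0.4)
  p_tm <- runif(1, 0, 2)
  height <- 35
  rho <- 0.25
  p_tlc <- runif(1, p_tm + rho * height + 1, 30)
  p_rv <- runif(1, p_tm - 1, p_tlc - 1)
  list(
    height = height, rho = rho,
    params = alveolar_params(v_max, v_max * ratio, k),
    pressures = lung_pressures(p_tlc, p_rv, rho),
    rule = closure_rule(p_tm)
  )
}

# Small hand-sized layered lung for brute-force checks.
toy_lung <- function(counts, params, height = 5) {
  n_layers <- length(counts)
  lung <- build_uniform_lung(height, sum(counts), params, n_layers = n_layers)
  lung$layers$n_alveoli <- counts
  lung
}

paper_treatments <- function(scenario, fraction = 0.5) {
  list(
    ult = treatment_spec(lobe_region(scenario, "upper", fraction), 22e6,
                         p_tlc_apex_post = 14, p_tm_post = 0.5, height_post = 33),
    llt = treatment_spec(lobe_region(scenario, "lower", fraction), 22e6,
                         p_tlc_apex_post = 14, p_tm_post = 0.5, height_post = 33)
  )
}
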