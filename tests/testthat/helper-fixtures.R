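# Shared builders for small in-code fixtures and oracles.

# a small planner-friendly instance: 14 schemes over 10 indications
small_cfg <- function(seed, n_schemes = 14L, n_indications = 10L,
                      scope_mix = c(TGI = 9L, TG = 3L, GI = 1L, I = 1L),
                      n_multiprovider = 3L, ...) {
  eqa_fixture_config(n_schemes = n_schemes, n_indications = n_indications,
                     scope_mix = scope_mix,
                     n_multiprovider = n_multiprovider, seed = seed, ...)
}

make_instance <- function(seed, horizon = 2024:2026, error_prob = NULL,
                          cfg = small_cfg(seed)) {
  inv <- generate_inventory(cfg)
  ctr <- generate_center(cfg, inv, seed = seed + 500L)
  hist <- generate_history(ctr, inv, (horizon[1] - 3):(horizon[1] - 1), cfg,
                           error_prob = error_prob %||% cfg$error_prob,
                           seed = seed + 900L)
  list(cfg = cfg, inv = inv, ctr = ctr, hist = hist, horizon = horizon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plan_fee <- function(plan, inv) {
  sum(vapply(as.character(plan$horizon), function(y) {
    ids <- plan$assignments[[y]]
    if (!length(ids)) 0L else sum(inv$fee_cents[match(ids, inv$scheme_id)])
  }, 1L))
}

# single-technique / single-indication micro inventory builder
micro_scheme <- function(id, indication, techniques, flags = c(1, 1, 1),
                         fee_eur = 1000, provider = "EMQN",
                         modality = "wet") {
  new_inventory(id, provider, indication, list(techniques),
                flags[1] == 1, flags[2] == 1, flags[3] == 1, modality,
                eur_to_cents(fee_eur))
}

micro_center <- function(techniques_df, indications_df, center_id = "C1") {
  new_center(center_id, techniques_df, indications_df)
}

# a center with one technique and one indication, parameterized for the
# exemption rules (plan year 2024: exemption needs validation before
# 2021-01-01, volume >= minn, no method change since 2021-01-01)
one_tech_center <- function(validation = "2015-01-01", volume = 400L,
                            change = NA, documented = TRUE,
                            technique = "sequencing",
                            indication = "cystic fibrosis") {
  tech <- data.frame(technique_id = technique,
                     validation_date = as.Date(validation),
                     method_class = "in_house",
                     annual_volume = as.integer(volume),
                     last_method_change = as.Date(change),
                     exemption_documented = documented,
                     stringsAsFactors = FALSE)
  ind <- data.frame(indication = indication, annual_requests = 50L,
                    stringsAsFactors = FALSE)
  ind$techniques_used <- list(technique)
  micro_center(tech, ind)
}

# independent numeric inversion of the Beta CDF by bisection (oracle for
# posterior quantiles; uses pbeta only, never qbeta)
beta_quantile_oracle <- function(p, shape1, shape2) {
  lo <- 0
  hi <- 1
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (stats::pbeta(mid, shape1, shape2) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
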