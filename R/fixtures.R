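# Seeded synthetic generator for scheme inventories, center profiles and
# participation histories.  The defaults emulate the statistical structure
# of the national inventory the planner was designed around: 90 schemes
# over 72 rare-disease indications, scope-category mix 65 TGI / 21 TG /
# 1 GI / 1 T / 1 G / 1 I, 15 indications offered by 2-3 providers, 8
# centers, a 1% per-participation error probability.
#
# Inventory, center and history generation use independent RNG streams
# derived from their own seeds (via withr::with_seed), so changing one
# configuration block never perturbs the others.

TECHNIQUE_VOCAB <- c("sequencing", "mlpa", "karyotyping", "fish",
                     "fragment_analysis", "qpcr", "array")

PROVIDER_VOCAB <- c("EMQN", "GenQA", "CAP", "Labquality", "RfB", "Instand")

#' Configuration for the synthetic fixture generator
#'
#' @param n_schemes total number of schemes (default 90).
#' @param n_indications number of distinct rare-disease indications
#'   (default 72); `n_schemes - n_indications` extra schemes are provider
#'   duplicates spread over `n_multiprovider` indications.
#' @param scope_mix named integer vector of scope-category counts summing
#'   to `n_schemes` (default `c(TGI=65, TG=21, GI=1, T=1, G=1, I=1)`).
#' @param n_multiprovider indications offered by 2-3 providers (default
#'   15); must satisfy
#'   `n_multiprovider <= n_schemes - n_indications <= 2 * n_multiprovider`.
#' @param fee_range_eur uniform fee range in whole euros (default
#'   500-2500).
#' @param n_centers number of centers (default 8).
#' @param volume_meanlog,volume_sdlog log-normal annual-volume parameters
#'   (default median 150 tests/year, sdlog 1).
#' @param error_prob per-participation probability of an error outcome
#'   (default 0.01, the guideline threshold; the ~1.4% rate reported by a
#'   large European provider is a plausible alternative).
#' @param capa_prob probability that an error has documented CAPA.
#' @param participation_rate probability a center participates in an
#'   eligible scheme in a given year.
#' @param indication_fraction fraction of eligible indications in a
#'   center's scope.
#' @param reference_year anchor for validation dates (default 2024).
#' @param horizon default planning years.
#' @param seed RNG seed for inventory generation.
#' @return a list of class `eqa_fixture_config`.
#' @export
eqa_fixture_config <- function(n_schemes = 90L, n_indications = 72L,
                               scope_mix = c(TGI = 65L, TG = 21L, GI = 1L,
                                             T = 1L, G = 1L, I = 1L),
                               n_multiprovider = 15L,
                               fee_range_eur = c(500L, 2500L),
                               n_centers = 8L,
                               volume_meanlog = log(150),
                               volume_sdlog = 1,
                               error_prob = 0.01,
                               capa_prob = 0.9,
                               participation_rate = 0.7,
                               indication_fraction = 0.5,
                               reference_year = 2024L,
                               horizon = 2024:2026,
                               seed = 1L) {
  cfg <- list(n_schemes = as.integer(n_schemes),
              n_indications = as.integer(n_indications),
              scope_mix = scope_mix, n_multiprovider = as.integer(n_multiprovider),
              fee_range_eur = fee_range_eur, n_centers = as.integer(n_centers),
              volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
              error_prob = error_prob, capa_prob = capa_prob,
              participation_rate = participation_rate,
              indication_fraction = indication_fraction,
              reference_year = as.integer(reference_year),
              horizon = as.integer(horizon), seed = as.integer(seed))
  if (sum(cfg$scope_mix) != cfg$n_schemes) {
    stop("scope_mix counts must sum to n_schemes", call. = FALSE)
  }
  if (!all(names(cfg$scope_mix) %in% SCOPE_CATEGORIES)) {
    stop("scope_mix names must be among ",
         paste(SCOPE_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  extras <- cfg$n_schemes - cfg$n_indications
  if (extras < 0) stop("n_schemes must be >= n_indications", call. = FALSE)
  if (cfg$n_multiprovider == 0 && extras > 0) {
    stop("extra schemes require n_multiprovider > 0", call. = FALSE)
  }
  if (cfg$n_multiprovider > 0 &&
      (extras < cfg$n_multiprovider || extras > 2L * cfg$n_multiprovider)) {
    stop("need n_multiprovider <= n_schemes - n_indications <= 2*n_multiprovider",
         call. = FALSE)
  }
  for (p in c("error_prob", "capa_prob", "participation_rate",
              "indication_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must be in [0, 1]", call. = FALSE)
    }
  }
  class(cfg) <- "eqa_fixture_config"
  cfg
}

#' Generate a synthetic scheme inventory
#'
#' Produces exactly `cfg$n_schemes` schemes over `cfg$n_indications`
#' indications with the configured scope-category tally; multiprovider
#' duplicates share the indication and techniques of their base scheme but
#' differ in provider and scheme id. Deterministic per seed. (The real
#' scheme catalog is proprietary to the EQA providers; everything here is
#' synthetic.)
#'
#' @param cfg an `eqa_fixture_config`.
#' @return an `eqa_inventory`.
#' @export
#' @examples
#' inv <- generate_inventory(eqa_fixture_config(seed = 1))
#' scope_summary(inv)
generate_inventory <- function(cfg) {
  stopifnot(inherits(cfg, "eqa_fixture_config"))
  withr::with_seed(cfg$seed, {
    ind_names <- sprintf("RD-%03d", seq_len(cfg$n_indications))
    ind_tech <- lapply(ind_names, function(i)
      sort(sample(TECHNIQUE_VOCAB, sample(1:3, 1))))
    names(ind_tech) <- ind_names
    base_provider <- sample(PROVIDER_VOCAB, cfg$n_indications, replace = TRUE)

    indication <- ind_names
    provider <- base_provider
    extras <- cfg$n_schemes - cfg$n_indications
    if (extras > 0) {
      multi <- sample(ind_names, cfg$n_multiprovider)
      n_triple <- extras - cfg$n_multiprovider
      triple <- if (n_triple > 0) sample(multi, n_triple) else character(0)
      for (ind in multi) {
        used <- provider[indication == ind]
        n_extra <- if (ind %in% triple) 2L else 1L
        extra_prov <- sample(setdiff(PROVIDER_VOCAB, used), n_extra)
        indication <- c(indication, rep(ind, n_extra))
        provider <- c(provider, extra_prov)
      }
    }
    n <- length(indication)
    stopifnot(n == cfg$n_schemes)
    category <- sample(rep(names(cfg$scope_mix), cfg$scope_mix))
    modality <- ifelse(category == "I", "virtual",
                       sample(c("wet", "virtual"), n, replace = TRUE,
                              prob = c(0.85, 0.15)))
    fee <- sample(seq(cfg$fee_range_eur[1], cfg$fee_range_eur[2]), n,
                  replace = TRUE) * 100L
    new_inventory(
      scheme_id = sprintf("EQA-%03d", seq_len(n)),
      provider = provider,
      indication = indication,
      techniques = ind_tech[indication],
      scope_technique = grepl("T", category),
      scope_genotyping = grepl("G", category),
      scope_interpretation = grepl("I", category),
      modality = modality,
      fee_cents = fee)
  })
}

#' Generate a synthetic center profile
#'
#' Draws the center's indications as a subset of the inventory's — only
#' indications with at least one scheme assessing genotyping or
#' interpretation are eligible, so the triennial
#' genotyping/interpretation requirement is always satisfiable — with
#' techniques taken from those indications' schemes, log-normal annual
#' volumes, validation dates spanning 0-10 years before the reference
#' date, and occasional recent method changes.
#'
#' @param cfg an `eqa_fixture_config`.
#' @param inventory an `eqa_inventory`.
#' @param seed RNG seed for this center (independent of the inventory
#'   stream).
#' @param center_id id for the profile.
#' @return an `eqa_center`.
#' @export
generate_center <- function(cfg, inventory, seed, center_id = "C1") {
  stopifnot(inherits(cfg, "eqa_fixture_config"), nrow(inventory) > 0)
  withr::with_seed(seed, {
    gi_ok <- inventory$scope_genotyping | inventory$scope_interpretation
    eligible <- sort(unique(inventory$indication[gi_ok]))
    if (!length(eligible)) {
      stop("inventory has no scheme assessing genotyping or interpretation",
           call. = FALSE)
    }
    n_ind <- max(1L, min(length(eligible),
                         as.integer(round(cfg$indication_fraction *
                                            length(eligible)))))
    chosen <- sort(sample(eligible, n_ind))
    ind_tech <- lapply(chosen, function(ind) {
      sort(unique(unlist(inventory$techniques[inventory$indication == ind])))
    })
    tech_ids <- sort(unique(unlist(ind_tech)))
    ref <- as.Date(sprintf("%d-01-01", cfg$reference_year))
    validation <- ref - round(runif(length(tech_ids), 0, 10 * 365.25))
    changed <- runif(length(tech_ids)) < 0.2
    change_date <- as.Date(ifelse(changed,
                                  validation + round(runif(length(tech_ids)) *
                                                       as.numeric(ref - validation)),
                                  NA), origin = "1970-01-01")
    techniques <- data.frame(
      technique_id = tech_ids,
      validation_date = validation,
      method_class = sample(c("in_house", "ce_kit"), length(tech_ids),
                            replace = TRUE),
      annual_volume = as.integer(round(rlnorm(length(tech_ids),
                                              cfg$volume_meanlog,
                                              cfg$volume_sdlog))),
      last_method_change = change_date,
      exemption_documented = runif(length(tech_ids)) < 0.9,
      stringsAsFactors = FALSE)
    indications <- data.frame(indication = chosen,
                              annual_requests = rpois(length(chosen), 20),
                              stringsAsFactors = FALSE)
    indications$techniques_used <- ind_tech
    new_center(center_id, techniques, indications)
  })
}

#' Generate a synthetic participation history
#'
#' For each year, the center participates in each scheme whose indication
#' is in its scope with probability `cfg$participation_rate`; each
#' participation is an error with probability `error_prob`, the error
#' category drawn uniformly from the four categories, and CAPA
#' documentation drawn with probability `cfg$capa_prob`.
#'
#' @param center an `eqa_center`.
#' @param inventory an `eqa_inventory`.
#' @param years integer vector of history years.
#' @param error_prob per-participation error probability (default from
#'   `cfg`).
#' @param cfg an `eqa_fixture_config`.
#' @param seed RNG seed for this history (independent stream).
#' @return an `eqa_history`.
#' @export
generate_history <- function(center, inventory, years, cfg,
                             error_prob = cfg$error_prob, seed) {
  stopifnot(inherits(center, "eqa_center"))
  withr::with_seed(seed, {
    scope <- normalize_indication(center$indications$indication)
    rows <- list()
    err_cats <- setdiff(OUTCOME_LEVELS, "satisfactory")
    for (y in as.integer(years)) {
      elig <- which(normalize_indication(inventory$indication) %in% scope &
                      scheme_offered(inventory, y))
      take <- elig[runif(length(elig)) < cfg$participation_rate]
      if (!length(take)) next
      is_err <- runif(length(take)) < error_prob
      outcome <- ifelse(is_err,
                        sample(err_cats, length(take), replace = TRUE),
                        "satisfactory")
      capa <- ifelse(is_err, runif(length(take)) < cfg$capa_prob, TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        center_id = center$center_id,
        scheme_id = inventory$scheme_id[take],
        year = y, outcome = outcome, capa_documented = capa,
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) return(new_history())
    new_history(df$center_id, df$scheme_id, df$year, df$outcome,
                df$capa_documented)
  })
}
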