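# Decisional algorithm for the minimal frequency of EQA participation:
# requirement derivation, poor-performance escalation, scheme/requirement
# matching, and cost-minimal multi-year plan selection.
#
# Rules implemented:
#   * every technique/platform must be assessed annually; a technique
#     validated for more than 3 years (strict, evaluated at January 1 of the
#     plan year) with an annual volume of at least `minn` tests and no method
#     change within 3 years qualifies for a triennial exemption, which must
#     be documented in the center's QMS;
#   * genotyping and interpretation of each clinical indication must be
#     assessed at least once in every rolling window of 3 consecutive
#     calendar years; interpretation-only virtual schemes count;
#   * a genotyping or critical interpretation error in year Y forces
#     participation in a scheme covering that indication in year Y+1;
#   * clerical/analytical errors change no frequency but must have CAPA
#     documentation.

REQUIREMENT_COLS <- c("subject", "aspect", "period", "reason",
                      "exemption_documented", "due_year")

new_requirements <- function(subject = character(), aspect = character(),
                             period = character(), reason = character(),
                             exemption_documented = logical(),
                             due_year = integer()) {
  r <- data.frame(subject = subject, aspect = aspect, period = period,
                  reason = reason, exemption_documented = exemption_documented,
                  due_year = as.integer(due_year), stringsAsFactors = FALSE)
  class(r) <- c("eqa_requirements", "data.frame")
  r
}

# triennial-exemption eligibility, evaluated at January 1 of plan_year
exemption_eligible <- function(tech, plan_year, minn) {
  cutoff <- as.Date(sprintf("%d-01-01", plan_year - 3L))
  tech$validation_date < cutoff &
    tech$annual_volume >= minn &
    (is.na(tech$last_method_change) | tech$last_method_change < cutoff)
}

#' Derive participation requirements for a plan year
#'
#' One technique-coverage requirement per technique the center runs —
#' annual by default, triennial when the triennial exemption applies
#' (validated more than 3 years before January 1 of `plan_year`, annual
#' volume at least `minn`, no method change within 3 years) — plus one
#' triennial genotyping/interpretation requirement per clinical indication
#' in the center's scope.
#'
#' @param center an `eqa_center`.
#' @param plan_year integer calendar year.
#' @param minn minimum annual test volume for the exemption, typically
#'   [min_volume_for_threshold()] at the 1% threshold (297).
#' @return an `eqa_requirements` data frame with columns `subject`,
#'   `aspect` (`technique_coverage` or `genotyping_interpretation`),
#'   `period` (`annual`/`triennial`), `reason` (`S1`, `S1-exemption`, `S2`,
#'   `S4-escalation`), `exemption_documented`, `due_year`.
#' @export
derive_requirements <- function(center, plan_year, minn) {
  stopifnot(inherits(center, "eqa_center"), minn > 0)
  plan_year <- as.integer(plan_year)
  tech <- center$techniques
  exempt <- exemption_eligible(tech, plan_year, minn)
  reqs_t <- new_requirements(
    subject = tech$technique_id,
    aspect = "technique_coverage",
    period = ifelse(exempt, "triennial", "annual"),
    reason = ifelse(exempt, "S1-exemption", "S1"),
    exemption_documented = ifelse(exempt, tech$exemption_documented, NA),
    due_year = rep(NA_integer_, nrow(tech)))
  ind <- center$indications
  reqs_i <- new_requirements(
    subject = normalize_indication(ind$indication),
    aspect = "genotyping_interpretation",
    period = rep("triennial", nrow(ind)),
    reason = rep("S2", nrow(ind)),
    exemption_documented = rep(NA, nrow(ind)),
    due_year = rep(NA_integer_, nrow(ind)))
  out <- rbind(reqs_t, reqs_i)
  class(out) <- c("eqa_requirements", "data.frame")
  out
}

#' Escalate requirements after poor EQA performance
#'
#' Every participation in year `plan_year - 1` scored as a genotyping or
#' critical interpretation error adds a one-shot requirement to
#' participate, in `plan_year`, in a scheme covering that scheme's
#' indication (genotyping/interpretation aspect). Clerical or analytical
#' errors without documented corrective/preventive actions are flagged in
#' the `"capa_flags"` attribute but change no frequency.
#'
#' @param reqs requirements from [derive_requirements()].
#' @param history an `eqa_history` (records predate `plan_year`).
#' @param plan_year integer year the requirements are for.
#' @param inventory the `eqa_inventory` the history refers to (needed to
#'   resolve each scheme's indication).
#' @return `reqs` with any `S4-escalation` rows appended and a
#'   `"capa_flags"` attribute (data frame `scheme_id`, `year`, `outcome`).
#' @export
apply_performance_rules <- function(reqs, history, plan_year, inventory) {
  plan_year <- as.integer(plan_year)
  if (is.null(history) || nrow(history) == 0) {
    attr(reqs, "capa_flags") <- data.frame(scheme_id = character(),
                                           year = integer(),
                                           outcome = character())
    return(reqs)
  }
  if (any(history$year >= plan_year)) {
    stop("history records must predate the plan year", call. = FALSE)
  }
  prev <- history[history$year == plan_year - 1L, , drop = FALSE]
  crit <- prev[prev$outcome %in% CRITICAL_OUTCOMES, , drop = FALSE]
  if (nrow(crit)) {
    idx <- match(crit$scheme_id, inventory$scheme_id)
    if (anyNA(idx)) {
      stop("history references unknown scheme(s): ",
           paste(unique(crit$scheme_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    esc_subjects <- unique(normalize_indication(inventory$indication[idx]))
    esc <- new_requirements(
      subject = esc_subjects,
      aspect = "genotyping_interpretation",
      period = rep("annual", length(esc_subjects)),
      reason = rep("S4-escalation", length(esc_subjects)),
      exemption_documented = rep(NA, length(esc_subjects)),
      due_year = rep(plan_year, length(esc_subjects)))
    reqs <- rbind(reqs, esc)
    class(reqs) <- c("eqa_requirements", "data.frame")
  }
  sloppy <- prev$outcome %in% c("clerical_error", "analytical_error") &
    !prev$capa_documented
  attr(reqs, "capa_flags") <- data.frame(scheme_id = prev$scheme_id[sloppy],
                                         year = prev$year[sloppy],
                                         outcome = prev$outcome[sloppy],
                                         stringsAsFactors = FALSE)
  reqs
}

#' Does a scheme satisfy a requirement?
#'
#' Technique coverage is satisfied by any scheme whose technique set
#' contains the subject — virtual (dry) schemes count. A
#' genotyping/interpretation requirement is satisfied by a scheme for the
#' same indication that assesses genotyping or interpretation (an
#' interpretation-only virtual scheme counts; a technique-only scheme does
#' not).
#'
#' @param scheme a single-row `eqa_inventory` subset.
#' @param req a single-row `eqa_requirements` subset.
#' @return logical.
#' @export
satisfies_requirement <- function(scheme, req) {
  if (req$aspect == "technique_coverage") {
    req$subject %in% scheme$techniques[[1]]
  } else {
    normalize_indication(scheme$indication) == req$subject &&
      (scheme$scope_genotyping || scheme$scope_interpretation)
  }
}

# logical matrix: schemes (rows) x requirements (cols)
requirement_coverage <- function(inventory, reqs) {
  m <- matrix(FALSE, nrow(inventory), nrow(reqs))
  for (j in seq_len(nrow(reqs))) {
    if (reqs$aspect[j] == "technique_coverage") {
      m[, j] <- vapply(inventory$techniques,
                       function(ts) reqs$subject[j] %in% ts, TRUE)
    } else {
      m[, j] <- normalize_indication(inventory$indication) ==
        reqs$subject[j] &
        (inventory$scope_genotyping | inventory$scope_interpretation)
    }
  }
  m
}

scheme_offered <- function(inventory, year) {
  vapply(inventory$offered_years,
         function(y) length(y) == 0 || year %in% y, TRUE)
}

# coverage key for the triennial clocks
req_key <- function(aspect, subject) paste(aspect, subject, sep = "|")

# keys a scheme's participation covers (for clock updates)
scheme_cov_keys <- function(scheme) {
  keys <- character(0)
  if (length(scheme$techniques[[1]])) {
    keys <- req_key("technique_coverage", scheme$techniques[[1]])
  }
  if (scheme$scope_genotyping || scheme$scope_interpretation) {
    keys <- c(keys, req_key("genotyping_interpretation",
                            normalize_indication(scheme$indication)))
  }
  keys
}

# TGI outranks TG outranks everything else when breaking fee ties
scope_breadth <- function(inventory) {
  cat <- classify_scope(inventory)
  ifelse(cat == "TGI", 2L, ifelse(cat == "TG", 1L, 0L))
}

# Deterministic candidate preference: lowest fee, then broadest scope, then
# lexicographic scheme_id; equivalence groups (same fee, breadth and
# coverage profile) are rotated round-robin anchored on the year index so
# turnover between interchangeable schemes is deterministic.
candidate_preference <- function(cands, cmat, year_index) {
  sig <- apply(cmat, 1, function(z) paste(as.integer(z), collapse = ""))
  ord <- order(cands$fee_cents, -scope_breadth(cands), cands$scheme_id)
  ord_grp <- paste(cands$fee_cents[ord], scope_breadth(cands)[ord],
                   sig[ord])
  for (g in unique(ord_grp)) {
    pos <- which(ord_grp == g)
    shift <- (year_index - 1L) %% length(pos)
    if (length(pos) > 1 && shift > 0) {
      ord[pos] <- ord[pos][c((shift + 1L):length(pos), seq_len(shift))]
    }
  }
  pref <- integer(nrow(cands))
  pref[ord] <- seq_len(nrow(cands))
  pref
}

# exact minimum-fee cover by subset enumeration (candidate count <= 14)
select_exhaustive <- function(cands, cmat, pref) {
  m <- nrow(cands)
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  cover <- combos %*% cmat  # count of selected schemes covering each req
  feasible <- rowSums(cover == 0) == 0
  if (!any(feasible)) stop("no feasible cover", call. = FALSE)
  fee <- as.numeric(combos %*% cands$fee_cents)
  fee[!feasible] <- Inf
  best_fee <- min(fee)
  tied <- which(fee == best_fee)
  if (length(tied) > 1) {
    size <- rowSums(combos[tied, , drop = FALSE])
    tied <- tied[size == min(size)]
  }
  if (length(tied) > 1) {
    # prefer the subset whose sorted preference ranks are lexicographically
    # smallest (rotation-adjusted)
    keys <- vapply(tied, function(i) {
      paste(sprintf("%03d", sort(pref[combos[i, ]])), collapse = "")
    }, "")
    tied <- tied[order(keys)][1]
  }
  which(combos[tied[1], ])
}

# greedy weighted set cover with redundancy pruning
select_greedy <- function(cands, cmat, pref) {
  uncovered <- rep(TRUE, ncol(cmat))
  chosen <- integer(0)
  avail <- setdiff(seq_len(nrow(cands)), chosen)
  while (any(uncovered)) {
    gain <- vapply(avail, function(i) sum(cmat[i, uncovered]), 1L)
    if (all(gain == 0)) stop("no feasible cover", call. = FALSE)
    ratio <- gain / pmax(cands$fee_cents[avail], 1L)
    best <- avail[order(-ratio, pref[avail])][1]
    chosen <- c(chosen, best)
    uncovered <- uncovered & !cmat[best, ]
    avail <- setdiff(avail, best)
  }
  # prune redundant picks, most expensive first
  for (i in chosen[order(-cands$fee_cents[chosen])]) {
    rest <- setdiff(chosen, i)
    if (length(rest) && all(colSums(cmat[rest, , drop = FALSE]) > 0)) {
      chosen <- rest
    }
  }
  sort(chosen)
}

#' Build a cost-minimal multi-year participation plan
#'
#' For each year of the horizon the planner derives the center's
#' requirements, applies the poor-performance escalation rules against the
#' history, determines which requirements are due (annual ones every year;
#' triennial ones three years after their last coverage, seeded from the
#' history; escalations in their due year) and selects a fee-minimal set of
#' offered schemes covering all of them. With at most 12 candidate schemes
#' the selection is an exact subset enumeration; above that a greedy
#' weighted set-cover heuristic with redundancy pruning is used. Selection
#' is deterministic: fee, then scope breadth, then scheme id, with
#' round-robin rotation among interchangeable schemes anchored on the year
#' index.
#'
#' @param center an `eqa_center`.
#' @param inventory an `eqa_inventory`.
#' @param history an `eqa_history` of participations before the horizon, or
#'   `NULL`.
#' @param horizon integer vector of consecutive calendar years.
#' @param minn minimum annual volume for the triennial exemption (see
#'   [min_volume_for_threshold()]).
#' @param optimizer `"auto"` (exhaustive when there are at most 12
#'   candidates, greedy otherwise), `"exhaustive"` or `"greedy"`.
#' @return an `eqa_plan`: list with `center_id`, `horizon`, `assignments`
#'   (per-year character vectors of scheme ids), `justifications` (per year
#'   and scheme, the requirement tags it discharges), `exemptions` (data
#'   frame of triennially exempt techniques and their documentation flag)
#'   and `minn`.
#' @export
build_plan <- function(center, inventory, history = NULL, horizon, minn,
                       optimizer = c("auto", "exhaustive", "greedy")) {
  optimizer <- match.arg(optimizer)
  stopifnot(inherits(center, "eqa_center"), is.data.frame(inventory))
  horizon <- as.integer(horizon)
  if (!length(horizon) || any(diff(horizon) != 1L)) {
    stop("horizon must be consecutive calendar years", call. = FALSE)
  }
  if (!is.null(history) && nrow(history) &&
      any(history$year >= horizon[1])) {
    stop("history records must predate the plan horizon", call. = FALSE)
  }

  # triennial clocks: last year each coverage key was participated in,
  # seeded from the history (any outcome counts as participation)
  last_cov <- new.env(parent = emptyenv())
  note_coverage <- function(scheme_row, year) {
    for (key in scheme_cov_keys(scheme_row)) {
      prev <- get0(key, last_cov, ifnotfound = -Inf)
      assign(key, max(prev, year), last_cov)
    }
  }
  if (!is.null(history) && nrow(history)) {
    idx <- match(history$scheme_id, inventory$scheme_id)
    if (anyNA(idx)) {
      stop("history references unknown scheme(s): ",
           paste(unique(history$scheme_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    for (r in seq_len(nrow(history))) {
      note_coverage(inventory[idx[r], , drop = FALSE], history$year[r])
    }
  }

  assignments <- list()
  justifications <- list()
  for (i in seq_along(horizon)) {
    y <- horizon[i]
    reqs <- derive_requirements(center, y, minn)
    reqs <- apply_performance_rules(reqs, history, y, inventory)
    due <- logical(nrow(reqs))
    for (j in seq_len(nrow(reqs))) {
      due[j] <- if (reqs$reason[j] == "S4-escalation") {
        reqs$due_year[j] == y
      } else if (reqs$period[j] == "annual") {
        TRUE
      } else {
        last <- get0(req_key(reqs$aspect[j], reqs$subject[j]), last_cov,
                     ifnotfound = -Inf)
        y >= last + 3
      }
    }
    due_reqs <- reqs[due, , drop = FALSE]
    if (nrow(due_reqs) == 0) {
      assignments[[as.character(y)]] <- character(0)
      justifications[[as.character(y)]] <- list()
      next
    }
    offered <- scheme_offered(inventory, y)
    cmat_all <- requirement_coverage(inventory, due_reqs)
    orphan <- colSums(cmat_all & offered) == 0
    if (any(orphan)) {
      stop("infeasible requirement(s) in year ", y, ": ",
           paste(unique(due_reqs$subject[orphan]), collapse = ", "),
           call. = FALSE)
    }
    cand_idx <- which(offered & rowSums(cmat_all) > 0)
    cands <- inventory[cand_idx, , drop = FALSE]
    cmat <- cmat_all[cand_idx, , drop = FALSE]
    pref <- candidate_preference(cands, cmat, i)
    use_exhaustive <- optimizer == "exhaustive" ||
      (optimizer == "auto" && nrow(cands) <= 12)
    if (use_exhaustive && nrow(cands) > 14) {
      stop("exhaustive optimizer limited to 14 candidate schemes (got ",
           nrow(cands), "); use optimizer = 'greedy'", call. = FALSE)
    }
    sel <- if (use_exhaustive) select_exhaustive(cands, cmat, pref) else
      select_greedy(cands, cmat, pref)
    sel <- sel[order(cands$scheme_id[sel])]
    assignments[[as.character(y)]] <- cands$scheme_id[sel]
    justifications[[as.character(y)]] <- lapply(sel, function(s) {
      sort(unique(due_reqs$reason[cmat[s, ]]))
    })
    names(justifications[[as.character(y)]]) <- cands$scheme_id[sel]
    for (s in sel) note_coverage(cands[s, , drop = FALSE], y)
  }

  first_reqs <- derive_requirements(center, horizon[1], minn)
  ex <- first_reqs[first_reqs$reason == "S1-exemption", , drop = FALSE]
  structure(list(center_id = center$center_id,
                 horizon = horizon,
                 assignments = assignments,
                 justifications = justifications,
                 exemptions = data.frame(
                   technique_id = ex$subject,
                   documented = as.logical(ex$exemption_documented),
                   stringsAsFactors = FALSE),
                 minn = as.integer(minn)),
            class = "eqa_plan")
}

#' @export
print.eqa_plan <- function(x, inventory = NULL, ...) {
  cat(sprintf("EQA participation plan for %s, %d-%d (minn = %d)\n",
              x$center_id, min(x$horizon), max(x$horizon), x$minn))
  for (y in as.character(x$horizon)) {
    ids <- x$assignments[[y]]
    cat(sprintf("  %s: %s\n", y,
                if (length(ids)) paste(ids, collapse = ", ") else "(none)"))
  }
  if (nrow(x$exemptions)) {
    cat("  triennial exemptions:",
        paste0(x$exemptions$technique_id,
               ifelse(x$exemptions$documented, "", " [UNDOCUMENTED]"),
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a plan to a data frame
#'
#' @param plan an `eqa_plan`.
#' @return data frame with columns `year`, `scheme_id`, `justification`
#'   (semicolon-joined requirement tags), one row per assignment.
#' @export
plan_to_df <- function(plan) {
  rows <- lapply(as.character(plan$horizon), function(y) {
    ids <- plan$assignments[[y]]
    if (!length(ids)) return(NULL)
    data.frame(year = as.integer(y), scheme_id = ids,
               justification = vapply(ids, function(s) {
                 paste(plan$justifications[[y]][[s]], collapse = ";")
               }, ""), row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(year = integer(), scheme_id = character(),
                      justification = character())
  }
  out
}

#' Write a plan to CSV
#' @param plan an `eqa_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  write.csv(plan_to_df(plan), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plan assignments from CSV
#'
#' Reads the `year, scheme_id, justification` format written by
#' [write_plan()]. The result carries assignments only (no exemption
#' metadata) and is sufficient for auditing and budgeting.
#'
#' @param path path to a `plan.csv`.
#' @param center_id center the plan belongs to.
#' @return an `eqa_plan`.
#' @export
read_plan <- function(path, center_id = NA_character_) {
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "scheme_id") %in% names(df)))
  years <- if (nrow(df)) seq(min(df$year), max(df$year)) else integer(0)
  assignments <- lapply(years, function(y)
    df$scheme_id[df$year == y])
  names(assignments) <- as.character(years)
  justifications <- lapply(years, function(y) {
    ids <- df$scheme_id[df$year == y]
    j <- lapply(seq_along(ids), function(i) {
      strsplit(df$justification[df$year == y][i] %||% "", ";")[[1]]
    })
    names(j) <- ids
    j
  })
  names(justifications) <- as.character(years)
  structure(list(center_id = center_id, horizon = as.integer(years),
                 assignments = assignments, justifications = justifications,
                 exemptions = data.frame(technique_id = character(),
                                         documented = logical()),
                 minn = NA_integer_),
            class = "eqa_plan")
}
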