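# Compliance auditing: independent re-derivation of the participation rules
# over an audit window, verdicts per requirement, CAPA and
# exemption-documentation findings, and change-management review triggers.
#
# The auditor deliberately shares no selection code with the planner: it
# re-derives the requirements and checks coverage of the recorded
# participations (history plus, optionally, a plan's assignments) against
# the annual and rolling-3-year rules.

FINDING_STATUSES <- c("met", "due_this_year", "overdue", "exempt_documented",
                      "capa_missing")

new_finding <- function(subject, aspect, window_start, window_end, status,
                        exemption_documented = NA, detail = "") {
  data.frame(subject = subject, aspect = aspect,
             window_start = as.integer(window_start),
             window_end = as.integer(window_end), status = status,
             exemption_documented = exemption_documented, detail = detail,
             stringsAsFactors = FALSE)
}

# participation events (year, scheme row index) from history and/or plan
participation_events <- function(inventory, history = NULL, plan = NULL) {
  years <- integer(0)
  ids <- character(0)
  if (!is.null(history) && nrow(history)) {
    years <- c(years, history$year)
    ids <- c(ids, history$scheme_id)
  }
  if (!is.null(plan)) {
    for (y in names(plan$assignments)) {
      a <- plan$assignments[[y]]
      years <- c(years, rep(as.integer(y), length(a)))
      ids <- c(ids, a)
    }
  }
  idx <- match(ids, inventory$scheme_id)
  if (anyNA(idx)) {
    stop("participation references unknown scheme(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  data.frame(year = years, scheme_id = ids, idx = idx,
             stringsAsFactors = FALSE)
}

aspect_period_at <- function(per_year, k, subject, aspect) {
  reqs <- per_year[[k]]
  p <- reqs$period[reqs$subject == subject & reqs$aspect == aspect]
  if (length(p)) p[1] else "annual"
}

# years in which `subject` of `aspect` was covered by a participation
coverage_years <- function(events, inventory, aspect, subject) {
  if (!nrow(events)) return(integer(0))
  hit <- vapply(seq_len(nrow(events)), function(r) {
    s <- inventory[events$idx[r], , drop = FALSE]
    if (aspect == "technique_coverage") {
      subject %in% s$techniques[[1]]
    } else {
      normalize_indication(s$indication) == subject &&
        (s$scope_genotyping || s$scope_interpretation)
    }
  }, TRUE)
  sort(unique(events$year[hit]))
}

#' Audit participation compliance over a window
#'
#' Independently re-derives the center's requirements for every year of the
#' window and verifies them against the recorded participations (the
#' history plus, if given, a plan's assignments). Produces one finding per
#' requirement subject — `met`, `due_this_year` (only the final, still-open
#' year of the window is uncovered), `overdue`, or `exempt_documented` for
#' a technique satisfied under a triennial exemption (with the
#' `exemption_documented` column `FALSE` when the rationale is missing from
#' the quality management system) — plus `capa_missing` findings for
#' clerical/analytical errors without documented corrective actions and
#' escalation checks for genotyping/critical interpretation errors. Annual
#' per-year participation counts are attached as attribute
#' `"participation_counts"`.
#'
#' @param center an `eqa_center`.
#' @param inventory an `eqa_inventory`.
#' @param history an `eqa_history` or `NULL`.
#' @param plan an `eqa_plan` whose assignments also count as
#'   participations, or `NULL` to audit the history alone.
#' @param window integer vector of consecutive years to audit.
#' @param minn minimum annual volume for the triennial exemption.
#' @return data frame of class `eqa_findings`.
#' @export
audit_compliance <- function(center, inventory, history = NULL, plan = NULL,
                             window, minn) {
  stopifnot(inherits(center, "eqa_center"))
  window <- as.integer(window)
  stopifnot(length(window) >= 1, all(diff(window) == 1L))
  w_end <- max(window)
  events <- participation_events(inventory, history, plan)
  findings <- list()

  # union of requirement subjects over the window (exemption status can
  # change between years, so periods are re-derived per year)
  per_year <- lapply(window, derive_requirements, center = center,
                     minn = minn)
  subjects <- unique(do.call(rbind, per_year)[, c("subject", "aspect")])

  for (r in seq_len(nrow(subjects))) {
    subject <- subjects$subject[r]
    aspect <- subjects$aspect[r]
    cov <- coverage_years(events, inventory, aspect, subject)
    known_start <- min(c(window[1], cov))
    flagged <- integer(0)
    exempt_any <- FALSE
    undoc <- FALSE
    for (k in seq_along(window)) {
      y <- window[k]
      reqs_y <- per_year[[k]]
      row <- reqs_y[reqs_y$subject == subject & reqs_y$aspect == aspect, ,
                    drop = FALSE]
      if (!nrow(row)) next
      if (row$reason[1] == "S1-exemption") {
        exempt_any <- TRUE
        if (!isTRUE(row$exemption_documented[1])) undoc <- TRUE
      }
      miss <- if (row$period[1] == "annual") {
        !(y %in% cov)
      } else {
        # rolling 3-year rule: uncovered in [y-2, y] once a full window of
        # obligation exists
        y >= known_start + 2L && !any(cov >= y - 2L & cov <= y)
      }
      if (miss) flagged <- c(flagged, y)
    }
    # "due this year": only the final, still-open year is flagged and the
    # obligation became due exactly then (annual: earlier years were
    # covered; triennial: the last coverage was exactly 3 years before).
    # A triennial requirement never covered in a full window is overdue.
    fresh_due <- length(flagged) && all(flagged == w_end) &&
      (aspect_period_at(per_year, length(window), subject, aspect) ==
         "annual" || (w_end - 3L) %in% cov)
    status <- if (!length(flagged)) {
      if (exempt_any) "exempt_documented" else "met"
    } else if (fresh_due) "due_this_year" else "overdue"
    detail <- if (length(flagged)) {
      paste0("uncovered in ", paste(flagged, collapse = ", "))
    } else ""
    findings[[length(findings) + 1]] <- new_finding(
      subject, aspect, window[1], w_end, status,
      exemption_documented = if (exempt_any) !undoc else NA,
      detail = detail)
    if (undoc) {
      findings[[length(findings) + 1]] <- new_finding(
        subject, aspect, window[1], w_end, "exempt_documented",
        exemption_documented = FALSE,
        detail = "triennial exemption claimed without documented rationale in the QMS")
    }
  }

  if (!is.null(history) && nrow(history)) {
    # escalations: a genotyping/critical interpretation error in year Y
    # must be answered by a covering participation in year Y+1
    crit <- history[history$outcome %in% CRITICAL_OUTCOMES &
                      (history$year + 1L) %in% window, , drop = FALSE]
    if (nrow(crit)) {
      idx <- match(crit$scheme_id, inventory$scheme_id)
      for (r in seq_len(nrow(crit))) {
        subject <- normalize_indication(inventory$indication[idx[r]])
        due <- crit$year[r] + 1L
        cov <- coverage_years(events, inventory,
                              "genotyping_interpretation", subject)
        status <- if (due %in% cov) "met" else
          if (due == w_end) "due_this_year" else "overdue"
        findings[[length(findings) + 1]] <- new_finding(
          subject, "genotyping_interpretation", due, due, status,
          detail = sprintf("escalation after %s in %d", crit$outcome[r],
                           crit$year[r]))
      }
    }
    # CAPA documentation for error outcomes inside the window
    sloppy <- history[history$outcome != "satisfactory" &
                        !history$capa_documented &
                        history$year %in% window, , drop = FALSE]
    for (r in seq_len(nrow(sloppy))) {
      findings[[length(findings) + 1]] <- new_finding(
        sloppy$scheme_id[r], "capa", sloppy$year[r], sloppy$year[r],
        "capa_missing",
        detail = sprintf("%s in %d without documented CAPA",
                         sloppy$outcome[r], sloppy$year[r]))
    }
  }

  out <- do.call(rbind, findings)
  if (is.null(out)) {
    out <- new_finding(character(), character(), integer(), integer(),
                       character())
  }
  class(out) <- c("eqa_findings", "data.frame")
  in_window <- events[events$year %in% window, , drop = FALSE]
  attr(out, "participation_counts") <-
    table(factor(in_window$year, levels = window))
  out
}

#' Any overdue findings?
#'
#' @param findings an `eqa_findings` frame.
#' @param include_due also count `due_this_year` findings (default `FALSE`).
#' @return logical.
#' @export
any_overdue <- function(findings, include_due = FALSE) {
  bad <- "overdue"
  if (include_due) bad <- c(bad, "due_this_year")
  any(findings$status %in% bad)
}

#' Review triggers after changes in activities or scheme availability
#'
#' Centers must keep their participation under review: a method or
#' platform change revokes the technique's triennial exemption (the
#' validation clock restarts); a change in annual volume beyond the
#' configured ratio triggers recomputation of exemption eligibility; a new
#' scheme on the market flags an optional re-optimization.
#'
#' @param events data frame with columns `type` (`method_change`,
#'   `volume_change`, `new_scheme`), `technique_id` (for the first two),
#'   `new_volume` (for `volume_change`), `scheme_id` (for `new_scheme`).
#' @param plan the current `eqa_plan`.
#' @param center the `eqa_center` the plan was built for.
#' @param minn minimum annual volume for the exemption.
#' @param volume_change_ratio year-over-year fractional change considered
#'   significant (default 0.5).
#' @return data frame with columns `flag`, `subject`, `detail`; zero rows
#'   when nothing needs review.
#' @export
review_triggers <- function(events, plan, center, minn,
                            volume_change_ratio = 0.5) {
  flags <- list()
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(flag = character(), subject = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  exempt_now <- plan$exemptions$technique_id
  for (r in seq_len(nrow(events))) {
    type <- events$type[r]
    if (type == "method_change") {
      tid <- events$technique_id[r]
      if (tid %in% exempt_now) {
        flags[[length(flags) + 1]] <- data.frame(
          flag = "exemption_revoked", subject = tid,
          detail = "method change resets the validation clock; technique returns to annual assessment",
          stringsAsFactors = FALSE)
      } else {
        flags[[length(flags) + 1]] <- data.frame(
          flag = "replan", subject = tid,
          detail = "method change; re-derive requirements",
          stringsAsFactors = FALSE)
      }
    } else if (type == "volume_change") {
      tid <- events$technique_id[r]
      old <- center$techniques$annual_volume[
        center$techniques$technique_id == tid]
      if (!length(old)) next
      new <- as.integer(events$new_volume[r])
      if (old > 0 && abs(new - old) / old >= volume_change_ratio) {
        upd <- center
        upd$techniques$annual_volume[
          upd$techniques$technique_id == tid] <- new
        reqs <- derive_requirements(upd, plan$horizon[1], minn)
        still_exempt <- reqs$reason[reqs$subject == tid &
                                      reqs$aspect == "technique_coverage"] ==
          "S1-exemption"
        if (tid %in% exempt_now && !still_exempt) {
          flags[[length(flags) + 1]] <- data.frame(
            flag = "exemption_revoked", subject = tid,
            detail = sprintf("volume %d -> %d no longer meets minn = %d",
                             old, new, plan$minn),
            stringsAsFactors = FALSE)
        } else {
          flags[[length(flags) + 1]] <- data.frame(
            flag = "recheck_exemption", subject = tid,
            detail = sprintf("significant volume change %d -> %d", old, new),
            stringsAsFactors = FALSE)
        }
      }
    } else if (type == "new_scheme") {
      flags[[length(flags) + 1]] <- data.frame(
        flag = "reoptimize_optional", subject = events$scheme_id[r],
        detail = "new scheme on the market; plan may be re-optimized",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, flags)
  out %||% data.frame(flag = character(), subject = character(),
                      detail = character(), stringsAsFactors = FALSE)
}
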