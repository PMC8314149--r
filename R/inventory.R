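# Data model and delimited-text I/O for EQA scheme inventories, center
# profiles and participation histories.
#
# File conventions (all UTF-8, comma-separated, mandatory header row,
# semicolon as the inner-list separator):
#   schemes.csv: scheme_id, provider, indication, techniques, scope_technique,
#     scope_genotyping, scope_interpretation, modality, fee_eur, offered_years
#   history.csv: center_id, scheme_id, year, outcome, capa_documented
#   center.yaml: center_id, techniques (list), indications (list)

SCHEME_COLS <- c("scheme_id", "provider", "indication", "techniques",
                 "scope_technique", "scope_genotyping", "scope_interpretation",
                 "modality", "fee_eur", "offered_years")

HISTORY_COLS <- c("center_id", "scheme_id", "year", "outcome",
                  "capa_documented")

OUTCOME_LEVELS <- c("satisfactory", "clerical_error", "analytical_error",
                    "genotyping_error", "critical_interpretation_error")

# outcomes that impact the diagnosis and force next-year participation
CRITICAL_OUTCOMES <- c("genotyping_error", "critical_interpretation_error")

# TI (technique + interpretation, no genotyping) is a valid flag triple even
# though typical inventories contain none; keeping it makes classification
# total on all seven triples
SCOPE_CATEGORIES <- c("TGI", "TG", "GI", "TI", "T", "G", "I")

#' Construct an EQA scheme inventory
#'
#' An inventory is a data frame with one row per scheme: identifier,
#' provider, clinical indication, the set of techniques covered, the three
#' scope flags (does the scheme assess the wet technique, the genotyping
#' call, the clinical interpretation), wet/virtual modality, the annual
#' participation fee in integer euro cents, and the calendar years the
#' scheme is offered (`integer(0)` meaning always offered).
#'
#' @param scheme_id character, unique per inventory.
#' @param provider character provider names.
#' @param indication character clinical indication (free text, compared
#'   case-insensitively after whitespace normalization).
#' @param techniques list of character vectors of technique ids.
#' @param scope_technique,scope_genotyping,scope_interpretation logical;
#'   at least one must be `TRUE` per scheme.
#' @param modality `"wet"` or `"virtual"`.
#' @param fee_cents non-negative integer euro cents.
#' @param offered_years list of integer vectors (empty = always offered).
#' @return a data frame of class `eqa_inventory`.
#' @export
new_inventory <- function(scheme_id, provider, indication, techniques,
                          scope_technique, scope_genotyping,
                          scope_interpretation, modality, fee_cents,
                          offered_years = NULL) {
  n <- length(scheme_id)
  offered_years <- offered_years %||% rep(list(integer(0)), n)
  inv <- data.frame(scheme_id = as.character(scheme_id),
                    provider = as.character(provider),
                    indication = as.character(indication),
                    scope_technique = as.logical(scope_technique),
                    scope_genotyping = as.logical(scope_genotyping),
                    scope_interpretation = as.logical(scope_interpretation),
                    modality = as.character(modality),
                    fee_cents = as.integer(fee_cents),
                    stringsAsFactors = FALSE)
  inv$techniques <- unname(lapply(techniques, as.character))
  inv$offered_years <- unname(lapply(offered_years, as.integer))
  inv <- inv[, c("scheme_id", "provider", "indication", "techniques",
                 "scope_technique", "scope_genotyping", "scope_interpretation",
                 "modality", "fee_cents", "offered_years")]
  class(inv) <- c("eqa_inventory", "data.frame")
  validate_inventory(inv)
}

#' Validate an EQA scheme inventory
#'
#' Checks scheme_id uniqueness, the at-least-one-scope-flag invariant,
#' non-negative fees and the wet/virtual modality vocabulary.
#'
#' @param inv an `eqa_inventory`.
#' @return `inv`, invisibly validated (returned for chaining).
#' @export
validate_inventory <- function(inv) {
  stopifnot(is.data.frame(inv))
  dup <- unique(inv$scheme_id[duplicated(inv$scheme_id)])
  if (length(dup)) {
    stop("duplicate scheme_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  no_scope <- !(inv$scope_technique | inv$scope_genotyping |
                  inv$scope_interpretation)
  if (any(no_scope)) {
    stop("scheme(s) with all scope flags false: ",
         paste(inv$scheme_id[no_scope], collapse = ", "), call. = FALSE)
  }
  if (any(is.na(inv$fee_cents) | inv$fee_cents < 0L)) {
    stop("annual_fee must be a non-negative amount", call. = FALSE)
  }
  bad_mod <- !inv$modality %in% c("wet", "virtual")
  if (any(bad_mod)) {
    stop("modality must be 'wet' or 'virtual' for scheme(s): ",
         paste(inv$scheme_id[bad_mod], collapse = ", "), call. = FALSE)
  }
  inv
}

parse_csv_field <- function(value, row, col, fn) {
  out <- tryCatch(fn(value), warning = function(w) NA, error = function(e) NA)
  if (length(out) == 1 && is.na(out)) {
    stop(sprintf("malformed value %s in row %d, column '%s'",
                 deparse(value), row, col), call. = FALSE)
  }
  out
}

parse_flag <- function(x) {
  if (!x %in% c("0", "1")) return(NA)
  x == "1"
}

split_list_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Read an EQA scheme inventory from CSV
#'
#' The file must carry the documented header (see [write_inventory()]);
#' technique sets and offered-year sets are semicolon-joined within their
#' cell, scope flags are 0/1, and `fee_eur` is in euros (converted to
#' integer cents internally). Malformed rows are reported with their row
#' number and column; duplicate scheme ids are rejected.
#'
#' @param path path to a CSV file.
#' @return an `eqa_inventory`.
#' @export
read_inventory <- function(path) {
  if (!file.exists(path)) stop("inventory file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing_cols <- setdiff(SCHEME_COLS, names(raw))
  if (length(missing_cols)) {
    stop("inventory is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  techniques <- vector("list", n)
  offered <- vector("list", n)
  flags <- matrix(NA, n, 3)
  fee <- integer(n)
  for (i in seq_len(n)) {
    techniques[[i]] <- split_list_field(raw$techniques[i])
    yrs <- split_list_field(raw$offered_years[i])
    offered[[i]] <- if (length(yrs)) {
      parse_csv_field(raw$offered_years[i], i, "offered_years",
                      function(x) as.integer(yrs))
    } else integer(0)
    flags[i, 1] <- parse_csv_field(raw$scope_technique[i], i,
                                   "scope_technique", parse_flag)
    flags[i, 2] <- parse_csv_field(raw$scope_genotyping[i], i,
                                   "scope_genotyping", parse_flag)
    flags[i, 3] <- parse_csv_field(raw$scope_interpretation[i], i,
                                   "scope_interpretation", parse_flag)
    fee[i] <- parse_csv_field(raw$fee_eur[i], i, "fee_eur",
                              function(x) eur_to_cents(as.numeric(x)))
  }
  new_inventory(scheme_id = raw$scheme_id, provider = raw$provider,
                indication = raw$indication, techniques = techniques,
                scope_technique = flags[, 1], scope_genotyping = flags[, 2],
                scope_interpretation = flags[, 3], modality = raw$modality,
                fee_cents = fee, offered_years = offered)
}

#' Write an EQA scheme inventory to CSV
#'
#' Writes the canonical format read by [read_inventory()]: header row,
#' semicolon-joined inner lists, 0/1 scope flags, fees in euros (no
#' trailing zero cents). `write_inventory(read_inventory(f), g)` is
#' byte-identical to `f` for canonically formatted files.
#'
#' @param inv an `eqa_inventory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inv, path) {
  validate_inventory(inv)
  txt_cols <- c(inv$provider, inv$indication)
  if (any(grepl("[,;]", txt_cols))) {
    stop("provider/indication fields must not contain ',' or ';'",
         call. = FALSE)
  }
  out <- data.frame(
    scheme_id = inv$scheme_id,
    provider = inv$provider,
    indication = inv$indication,
    techniques = vapply(inv$techniques, paste, "", collapse = ";"),
    scope_technique = as.integer(inv$scope_technique),
    scope_genotyping = as.integer(inv$scope_genotyping),
    scope_interpretation = as.integer(inv$scope_interpretation),
    modality = inv$modality,
    fee_eur = format_fee_csv(inv$fee_cents),
    offered_years = vapply(inv$offered_years, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify the scope of EQA schemes
#'
#' Maps the three scope flags to a category token: `TGI` (technique,
#' genotyping and interpretation), `TG`, `GI`, `T`, `G` or `I`. The mapping
#' is determined solely by the flags and is injective on flag triples with
#' at least one flag set.
#'
#' @param x an `eqa_inventory` (vectorized) or a single-row scheme.
#' @return character vector of category tokens.
#' @export
#' @examples
#' inv <- new_inventory("S1", "EMQN", "cystic fibrosis", list("sequencing"),
#'                      TRUE, TRUE, TRUE, "wet", 120000)
#' classify_scope(inv)
classify_scope <- function(x) {
  stopifnot(is.data.frame(x))
  token <- paste0(ifelse(x$scope_technique, "T", ""),
                  ifelse(x$scope_genotyping, "G", ""),
                  ifelse(x$scope_interpretation, "I", ""))
  if (any(!nzchar(token))) {
    stop("scheme with no scope flag set cannot be classified", call. = FALSE)
  }
  token
}

#' Summarize scope categories of an inventory
#'
#' @param inv a non-empty `eqa_inventory`.
#' @return data frame with `category`, `count` and `pct` (percentage of the
#'   inventory, rounded to the nearest integer), in canonical category order
#'   (TGI, TG, GI, T, G, I), categories with zero count omitted.
#' @export
scope_summary <- function(inv) {
  if (!is.data.frame(inv) || nrow(inv) == 0) {
    stop("scope_summary requires a non-empty inventory", call. = FALSE)
  }
  cat <- factor(classify_scope(inv), levels = SCOPE_CATEGORIES)
  counts <- table(cat)
  keep <- counts > 0
  data.frame(category = names(counts)[keep],
             count = as.integer(counts[keep]),
             pct = as.integer(round_half_up(100 * counts[keep] / nrow(inv))),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- center profiles --------------------------------------------------------

#' Construct a center profile
#'
#' A center profile describes one laboratory: the techniques it runs (with
#' validation date, method class, annual test volume, optional date of the
#' last method change and whether a triennial-exemption rationale is
#' documented in its quality management system) and the clinical
#' indications in its diagnostic scope (with the techniques each uses and
#' the annual number of requests).
#'
#' @param center_id character id.
#' @param techniques data frame with columns `technique_id`,
#'   `validation_date` (Date), `method_class` (`"in_house"` or `"ce_kit"`),
#'   `annual_volume` (non-negative integer), `last_method_change` (Date or
#'   `NA`) and optionally `exemption_documented` (logical, default `TRUE`).
#' @param indications data frame with columns `indication`,
#'   `techniques_used` (list of character vectors) and `annual_requests`.
#' @return a list of class `eqa_center`.
#' @export
new_center <- function(center_id, techniques, indications) {
  stopifnot(is.data.frame(techniques), is.data.frame(indications))
  techniques$validation_date <- as.Date(techniques$validation_date)
  techniques$annual_volume <- as.integer(techniques$annual_volume)
  if (is.null(techniques$last_method_change)) {
    techniques$last_method_change <- as.Date(NA)
  } else {
    techniques$last_method_change <- as.Date(techniques$last_method_change)
  }
  if (is.null(techniques$exemption_documented)) {
    techniques$exemption_documented <- TRUE
  }
  if (any(techniques$annual_volume < 0L)) {
    stop("annual_volume must be non-negative", call. = FALSE)
  }
  chg <- techniques$last_method_change
  bad <- !is.na(chg) & chg < techniques$validation_date
  if (any(bad)) {
    stop("last_method_change predates validation_date for: ",
         paste(techniques$technique_id[bad], collapse = ", "), call. = FALSE)
  }
  indications$techniques_used <- lapply(indications$techniques_used,
                                        as.character)
  if (any(lengths(indications$techniques_used) == 0)) {
    stop("every indication must reference at least one technique",
         call. = FALSE)
  }
  orphan <- setdiff(unlist(indications$techniques_used),
                    techniques$technique_id)
  if (length(orphan)) {
    stop("indication references unknown technique(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(center_id = as.character(center_id),
                 techniques = techniques, indications = indications),
            class = "eqa_center")
}

#' Read a center profile from YAML
#' @param path path to a `center.yaml` file.
#' @return an `eqa_center`.
#' @export
read_center <- function(path) {
  if (!file.exists(path)) stop("center file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  tech <- do.call(rbind, lapply(y$techniques, function(t) {
    data.frame(technique_id = t$technique_id,
               validation_date = as.Date(t$validation_date),
               method_class = t$method_class,
               annual_volume = as.integer(t$annual_volume),
               last_method_change = as.Date(t$last_method_change %||% NA),
               exemption_documented = isTRUE(t$exemption_documented %||% TRUE),
               stringsAsFactors = FALSE)
  }))
  ind <- data.frame(
    indication = vapply(y$indications, `[[`, "", "indication"),
    annual_requests = vapply(y$indications,
                             function(i) as.integer(i$annual_requests %||% 0L),
                             1L),
    stringsAsFactors = FALSE)
  ind$techniques_used <- lapply(y$indications, function(i)
    as.character(i$techniques_used))
  new_center(y$center_id, tech, ind)
}

#' Write a center profile to YAML
#' @param center an `eqa_center`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_center <- function(center, path) {
  tech <- lapply(seq_len(nrow(center$techniques)), function(i) {
    t <- center$techniques[i, ]
    list(technique_id = t$technique_id,
         validation_date = format(t$validation_date),
         method_class = t$method_class,
         annual_volume = t$annual_volume,
         last_method_change = if (is.na(t$last_method_change)) NULL else
           format(t$last_method_change),
         exemption_documented = t$exemption_documented)
  })
  ind <- lapply(seq_len(nrow(center$indications)), function(i) {
    x <- center$indications[i, ]
    list(indication = x$indication,
         techniques_used = as.list(x$techniques_used[[1]]),
         annual_requests = x$annual_requests)
  })
  yaml::write_yaml(list(center_id = center$center_id, techniques = tech,
                        indications = ind), path)
  invisible(path)
}

# ---- participation histories ------------------------------------------------

#' Construct a participation history
#'
#' One row per (center, scheme, year) EQA participation with its outcome
#' category and whether corrective/preventive actions (CAPA) were
#' documented.
#'
#' @param center_id,scheme_id character.
#' @param year integer calendar year (1990-2100).
#' @param outcome one of `satisfactory`, `clerical_error`,
#'   `analytical_error`, `genotyping_error`,
#'   `critical_interpretation_error`.
#' @param capa_documented logical.
#' @return data frame of class `eqa_history`.
#' @export
new_history <- function(center_id = character(), scheme_id = character(),
                        year = integer(), outcome = character(),
                        capa_documented = logical()) {
  h <- data.frame(center_id = as.character(center_id),
                  scheme_id = as.character(scheme_id),
                  year = as.integer(year),
                  outcome = as.character(outcome),
                  capa_documented = as.logical(capa_documented),
                  stringsAsFactors = FALSE)
  if (any(h$year < 1990L | h$year > 2100L)) {
    stop("participation year outside plausible range 1990-2100",
         call. = FALSE)
  }
  bad <- !h$outcome %in% OUTCOME_LEVELS
  if (any(bad)) {
    stop("unknown outcome(s): ", paste(unique(h$outcome[bad]), collapse = ", "),
         call. = FALSE)
  }
  class(h) <- c("eqa_history", "data.frame")
  h
}

#' Read a participation history from CSV
#' @param path path to a `history.csv` file.
#' @return an `eqa_history`.
#' @export
read_history <- function(path) {
  if (!file.exists(path)) stop("history file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  missing_cols <- setdiff(HISTORY_COLS, names(raw))
  if (length(missing_cols)) {
    stop("history is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  year <- integer(n)
  capa <- logical(n)
  for (i in seq_len(n)) {
    year[i] <- parse_csv_field(raw$year[i], i, "year",
                               function(x) as.integer(x))
    capa[i] <- parse_csv_field(raw$capa_documented[i], i, "capa_documented",
                               parse_flag)
  }
  new_history(raw$center_id, raw$scheme_id, year, raw$outcome, capa)
}

#' Write a participation history to CSV
#' @param history an `eqa_history`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  out <- history
  out$capa_documented <- as.integer(out$capa_documented)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
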