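#' Harmonization rules
#'
#' Participants encode the same clinical concept in different ways —
#' Karnofsky performance status dichotomized at 50, 60, 70 or 90, ECOG at
#' 1, or simply "good/bad" — and a moderated harmonization step maps each
#' raw encoding onto shared criteria such as `fitness` = fit/unfit before
#' any comparison. A rule maps one participant's (or everybody's, scope
#' `"*"`) source criterion levels onto levels of a harmonized target
#' criterion, totally and single-valuedly. Rules may also introduce a target
#' criterion a participant never used (the collectively defined "Zugzwang"
#' pattern): that participant's cells then replicate across its levels,
#' recording explicit non-dependence.
#'
#' @param participant Participant id this rule applies to, or `"*"` for all.
#' @param source Name of the raw criterion in the participant's table.
#' @param target Name of the harmonized criterion.
#' @param map Named character vector: source level -> target level, total
#'   over the source levels.
#' @param source_scale,cutoff Optional provenance for cut-off-derived rules
#'   (e.g. scale `"KPS"`, cutoff `70`).
#' @param note Free-text note (e.g. how an unscaled encoding was resolved).
#' @return `harmonization_rule()`: a `tc_harmonization_rule`.
#' @export
harmonization_rule <- function(participant, source, target, map,
                               source_scale = NULL, cutoff = NULL, note = "") {
  assert_string(participant, "participant scope")
  assert_string(source, "source criterion")
  assert_string(target, "target criterion")
  if (is.null(names(map)) || any(!nzchar(names(map))))
    tc_error("tc_schema_error", "rule map must be a named character vector")
  structure(
    list(participant = participant, source = source, target = target,
         map = vapply(map, trim_label, character(1L)),
         source_scale = source_scale, cutoff = cutoff, note = note),
    class = "tc_harmonization_rule"
  )
}

#' @rdname harmonization_rule
#' @param target_criteria [criteria_set()] (or list of [criterion()])
#'   defining the harmonized criteria the rules map into; fixes target level
#'   order.
#' @param rules List of `tc_harmonization_rule` objects.
#' @return `harmonization_rules()`: a `tc_harmonization_rules` rule set.
#' @export
harmonization_rules <- function(target_criteria, rules) {
  if (!inherits(target_criteria, "tc_criteria_set"))
    target_criteria <- criteria_set(target_criteria)
  ok <- vapply(rules, inherits, logical(1L), "tc_harmonization_rule")
  if (length(rules) && !all(ok))
    tc_error("tc_schema_error", "rules must be harmonization_rule objects")
  for (r in rules) {
    if (!r$target %in% cs_names(target_criteria))
      tc_error("tc_schema_error",
               sprintf("rule target '%s' not among target criteria", r$target))
    bad <- setdiff(unname(r$map), cs_levels(target_criteria, r$target))
    if (length(bad))
      tc_error("tc_schema_error",
               sprintf("rule for '%s' maps onto unknown target levels: %s",
                       r$source, paste(bad, collapse = ", ")))
  }
  structure(list(target_criteria = target_criteria, rules = rules),
            class = "tc_harmonization_rules")
}

# rules applicable to one participant; a participant-specific rule for a
# source criterion overrides a global one
rules_for <- function(ruleset, participant_id) {
  rr <- ruleset$rules
  specific <- Filter(function(r) r$participant == participant_id, rr)
  global <- Filter(function(r) r$participant == "*", rr)
  spec_src <- vapply(specific, `[[`, character(1L), "source")
  c(specific, Filter(function(r) !r$source %in% spec_src, global))
}

#' Harmonize a decision table
#'
#' Re-keys a participant's complete decision table onto the harmonized
#' criteria: touched criteria are relabelled through their rule maps,
#' untouched criteria pass through unchanged, and target criteria with no
#' source in this table are added by replication (explicit non-dependence).
#' When several source scenarios collapse onto one harmonized scenario,
#' their recommendation sets are unioned — never resolved to a preference
#' the participant did not state — and a non-singleton union is flagged
#' `equivalent-alternatives` with a merge note (retrievable via
#' `attr(result, "notes")`). Completeness over the harmonized Cartesian
#' product is preserved.
#'
#' @param table A complete `tc_decision_table`.
#' @param ruleset A `tc_harmonization_rules` object.
#' @return A complete `tc_decision_table` over the harmonized criteria set,
#'   with a `notes` attribute (data.frame: scenario, message).
#' @export
apply_rules <- function(table, ruleset) {
  nms <- cs_names(table$criteria)
  rr <- rules_for(ruleset, table$participant_id)
  rr <- Filter(function(r) r$source %in% nms, rr)

  for (r in rr) {
    unmapped <- setdiff(cs_levels(table$criteria, r$source), names(r$map))
    if (length(unmapped))
      tc_error("tc_partial_rules_error",
               sprintf("rule set is partial: levels of '%s' unmapped for participant '%s': %s",
                       r$source, table$participant_id, paste(unmapped, collapse = ", ")))
  }

  touched <- vapply(rr, `[[`, character(1L), "source")
  untouched <- setdiff(nms, touched)

  # harmonized universe: untouched criteria + every target criterion; when a
  # participant already uses a target criterion verbatim, the shared target
  # definition wins (fixing level order), provided the level sets agree
  tnames <- cs_names(ruleset$target_criteria)
  for (u in intersect(untouched, tnames)) {
    if (!setequal(cs_levels(table$criteria, u), cs_levels(ruleset$target_criteria, u)))
      tc_error("tc_partial_rules_error",
               sprintf("criterion '%s' of participant '%s' shares the name of a target criterion but not its levels; add a rule",
                       u, table$participant_id))
  }
  harmonized <- c(unname(table$criteria[setdiff(untouched, tnames)]),
                  unname(ruleset$target_criteria))
  hc <- criteria_set(harmonized)
  hnms <- cs_names(hc)

  df <- table$data
  n <- nrow(df)

  # per-row harmonized assignment of the mapped targets
  tvals <- list()
  ambiguous <- character(0L)
  for (cname in hnms) tvals[[cname]] <- rep(NA_character_, n)
  for (cname in untouched) tvals[[cname]] <- df[[cname]]
  for (r in rr) {
    mapped <- unname(r$map[df[[r$source]]])
    prev <- tvals[[r$target]]
    clash <- !is.na(prev) & prev != mapped
    if (any(clash))
      ambiguous <- c(ambiguous, row_keys(df[clash, , drop = FALSE], nms))
    tvals[[r$target]] <- ifelse(is.na(prev), mapped, prev)
  }
  if (length(ambiguous))
    tc_error("tc_merge_ambiguity_error",
             sprintf("source criteria map contradictorily onto one target at scenarios: %s",
                     paste(gsub(KEY_SEP, "/", unique(ambiguous), fixed = TRUE),
                           collapse = "; ")))

  new_crit <- hnms[vapply(hnms, function(c) all(is.na(tvals[[c]])), logical(1L))]

  # group source rows by the mapped part of the harmonized scenario
  mapped_crit <- setdiff(hnms, new_crit)
  gkeys <- do.call(paste, c(unname(tvals[mapped_crit]), list(sep = KEY_SEP)))

  merge_group <- function(rows) {
    ex <- df$excluded[rows]
    if (all(ex)) {
      list(recommendations = df$recommendations[rows][1L],
           multiplicity = df$multiplicity[rows][1L],
           excluded = TRUE, reason = paste(unique(df$reason[rows]), collapse = "; "),
           note = NA_character_)
    } else {
      rows <- rows[!ex]
      cells <- unique(paste_key(df$multiplicity[rows], df$recommendations[rows]))
      if (length(cells) == 1L) {
        list(recommendations = df$recommendations[rows][1L],
             multiplicity = df$multiplicity[rows][1L],
             excluded = FALSE, reason = "", note = NA_character_)
      } else {
        members <- sort(unique(unlist(strsplit(df$recommendations[rows], "|", fixed = TRUE))))
        list(recommendations = paste(members, collapse = "|"),
             multiplicity = if (length(members) > 1L) "equivalent-alternatives" else "single",
             excluded = FALSE, reason = "",
             note = sprintf("merged %d distinct source cells into {%s}",
                            length(cells), paste(members, collapse = ", ")))
      }
    }
  }

  groups <- split(seq_len(n), gkeys)
  merged <- lapply(groups, merge_group)

  # assemble harmonized rows: one per (merged group x new-criteria combo)
  base <- data.frame(.key = names(groups), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(base$.key, KEY_SEP, fixed = TRUE))
  for (i in seq_along(mapped_crit)) base[[mapped_crit[i]]] <- parts[, i]
  base$recommendations <- vapply(merged, `[[`, character(1L), "recommendations")
  base$multiplicity <- vapply(merged, `[[`, character(1L), "multiplicity")
  base$excluded <- vapply(merged, `[[`, logical(1L), "excluded")
  base$reason <- vapply(merged, `[[`, character(1L), "reason")
  base$.note <- vapply(merged, `[[`, character(1L), "note")

  if (length(new_crit)) {
    combos <- scenario_space(criteria_set(unname(hc[new_crit])))
    base <- merge(base, cbind(combos, .one = 1L), by = NULL)
    base$.one <- NULL
  }

  notes <- base[!is.na(base$.note), , drop = FALSE]
  notes_df <- data.frame(
    scenario = if (nrow(notes)) row_keys(notes, hnms) else character(0L),
    message = notes$.note %||% character(0L), stringsAsFactors = FALSE)
  base$.key <- NULL
  base$.note <- NULL

  out <- decision_table(table$participant_id, hc, base,
                        finalisation_date = table$finalisation_date, check = TRUE)
  attr(out, "notes") <- notes_df
  out
}

#' Criterion census of an ensemble
#'
#' For each criterion, the set of participants whose recommendations depend
#' on it (semantic dependence, as in [criteria_usage()]). The census drives
#' the inclusion threshold: the moderated process only keeps criteria
#' mentioned by at least `k` participants (conventionally three).
#'
#' @param ensemble List of complete `tc_decision_table`s over one shared
#'   criteria set.
#' @return A `tc_criterion_census`: named list, criterion name -> character
#'   vector of participant ids.
#' @export
criterion_census <- function(ensemble) {
  usage <- criteria_usage(ensemble)
  out <- lapply(colnames(usage), function(c) rownames(usage)[usage[, c]])
  names(out) <- colnames(usage)
  structure(out, class = "tc_criterion_census")
}

#' @export
print.tc_criterion_census <- function(x, ...) {
  for (n in names(x))
    cat(sprintf("  %s: %d participant(s)%s\n", n, length(x[[n]]),
                if (length(x[[n]])) paste0(" (", paste(x[[n]], collapse = ", "), ")") else ""))
  invisible(x)
}

# union-rule marginalization over the criteria in `drop`.
# keep_axes = TRUE keeps the full criteria set but makes the table
# independent of the dropped criteria (used by the synthetic generator);
# keep_axes = FALSE reduces the criteria set (inclusion filtering).
marginalize_table <- function(tab, drop, keep_axes = FALSE) {
  nms <- cs_names(tab$criteria)
  keep <- setdiff(nms, drop)
  if (length(keep) == 0L)
    tc_error("tc_semantic_error", "cannot marginalize away every criterion")
  df <- tab$data
  gkeys <- row_keys(df, keep)
  notes <- list()
  for (g in unique(gkeys)) {
    rows <- which(gkeys == g)
    ex <- df$excluded[rows]
    if (all(ex)) next
    act <- rows[!ex]
    cells <- unique(paste_key(df$multiplicity[act], df$recommendations[act]))
    if (length(cells) > 1L) {
      members <- sort(unique(unlist(strsplit(df$recommendations[act], "|", fixed = TRUE))))
      df$recommendations[rows] <- paste(members, collapse = "|")
      df$multiplicity[rows] <- if (length(members) > 1L) "equivalent-alternatives" else "single"
      df$excluded[rows] <- FALSE
      df$reason[rows] <- ""
      notes[[length(notes) + 1L]] <- data.frame(
        scenario = g, message = sprintf("union over dropped criteria {%s}: {%s}",
                                        paste(drop, collapse = ", "),
                                        paste(members, collapse = ", ")),
        stringsAsFactors = FALSE)
    } else {
      df$recommendations[rows] <- df$recommendations[act][1L]
      df$multiplicity[rows] <- df$multiplicity[act][1L]
      df$excluded[rows] <- FALSE
      df$reason[rows] <- ""
    }
  }
  notes_df <- if (length(notes)) do.call(rbind, notes) else
    data.frame(scenario = character(0L), message = character(0L), stringsAsFactors = FALSE)
  if (keep_axes) {
    out <- decision_table(tab$participant_id, tab$criteria, df,
                          finalisation_date = tab$finalisation_date, check = FALSE)
  } else {
    first <- !duplicated(gkeys)
    out <- decision_table(tab$participant_id, criteria_set(unname(tab$criteria[keep])),
                          df[first, c(keep, "recommendations", "multiplicity",
                                      "excluded", "reason"), drop = FALSE],
                          finalisation_date = tab$finalisation_date, check = TRUE)
  }
  attr(out, "notes") <- notes_df
  out
}

#' Filter criteria by participant count
#'
#' Removes from the analysis every criterion that fewer than `k`
#' participants depend on, by marginalizing each affected table (unioning
#' cells over the dropped criterion's levels — a non-singleton union becomes
#' `equivalent-alternatives` and is logged). Every exclusion is documented
#' in the returned log, as the method demands.
#'
#' @param ensemble List of complete `tc_decision_table`s over one shared
#'   criteria set.
#' @param census Optional precomputed [criterion_census()].
#' @param k Minimum number of participants (default 3, the conventional
#'   threshold).
#' @return List with `ensemble` (reduced tables), `exclusions` (data.frame:
#'   criterion, n_users, threshold) and `notes` (merge log).
#' @export
inclusion_filter <- function(ensemble, census = criterion_census(ensemble), k = 3L) {
  if (k < 1L) tc_error("tc_semantic_error", "k must be >= 1")
  n_users <- vapply(census, length, integer(1L))
  drop <- names(census)[n_users < k]
  exclusions <- data.frame(criterion = drop,
                           n_users = unname(n_users[drop]),
                           threshold = rep(as.integer(k), length(drop)),
                           stringsAsFactors = FALSE)
  if (length(drop) == 0L)
    return(list(ensemble = ensemble, exclusions = exclusions,
                notes = data.frame(participant = character(0L), scenario = character(0L),
                                   message = character(0L), stringsAsFactors = FALSE)))
  notes <- list()
  reduced <- lapply(ensemble, function(tab) {
    out <- marginalize_table(tab, drop, keep_axes = FALSE)
    nt <- attr(out, "notes")
    if (nrow(nt))
      notes[[length(notes) + 1L]] <<- cbind(participant = tab$participant_id, nt)
    out
  })
  notes_df <- if (length(notes)) do.call(rbind, notes) else
    data.frame(participant = character(0L), scenario = character(0L),
               message = character(0L), stringsAsFactors = FALSE)
  list(ensemble = reduced, exclusions = exclusions, notes = notes_df)
}
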