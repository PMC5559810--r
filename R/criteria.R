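#' Define a decision criterion
#'
#' A criterion is a named categorical decision axis with an ordered set of at
#' least two distinct levels, e.g. `fitness` with levels `fit` / `unfit`.
#' Level order is the entry order; it is used only for deterministic output
#' (scenario enumeration, serialization) and carries no ordinal semantics.
#'
#' Criteria whose levels were derived by dichotomizing a numeric clinical
#' scale (e.g. Karnofsky Performance Status at a cut-off of 70) can record
#' their provenance via `kind = "derived-from-cutoff"` and `source`.
#'
#' @param name Criterion name (identifier string, unique within a criteria set).
#' @param levels Character vector of >= 2 distinct level labels, in order.
#' @param description Optional free-text description.
#' @param kind `"categorical"` (default) or `"derived-from-cutoff"`.
#' @param source For `derived-from-cutoff` criteria, a list with elements
#'   `scale` (e.g. `"KPS"`) and `cutoff` (the threshold on that scale).
#' @return An object of class `tc_criterion`.
#' @examples
#' criterion("fitness", c("fit", "unfit"))
#' criterion("ps", c("fit", "unfit"), kind = "derived-from-cutoff",
#'           source = list(scale = "KPS", cutoff = 70))
#' @export
criterion <- function(name, levels, description = "",
                      kind = c("categorical", "derived-from-cutoff"),
                      source = NULL) {
  assert_string(name, "criterion name")
  kind <- match.arg(kind)
  levels <- trim_label(levels)
  if (length(levels) < 2L)
    tc_error("tc_semantic_error",
             sprintf("criterion '%s' needs >= 2 levels, got %d", name, length(levels)))
  if (anyDuplicated(levels))
    tc_error("tc_semantic_error",
             sprintf("criterion '%s' has duplicate levels: %s", name,
                     paste(levels[duplicated(levels)], collapse = ", ")))
  if (kind == "derived-from-cutoff") {
    if (is.null(source) || is.null(source$scale))
      tc_error("tc_semantic_error",
               sprintf("criterion '%s' is derived-from-cutoff but records no source scale", name))
  }
  structure(
    list(name = trim_label(name), levels = levels, description = description,
         kind = kind, source = source),
    class = "tc_criterion"
  )
}

#' Assemble a criteria set
#'
#' The criteria set is the governing universe for scenarios, tables and trees.
#' Criteria are stored sorted by name so that every downstream enumeration is
#' deterministic. Names must be unique.
#'
#' @param ... `tc_criterion` objects, or a single list of them.
#' @return An object of class `tc_criteria_set` (a named list of criteria).
#' @examples
#' cs <- criteria_set(criterion("age", c("<75", ">=75")),
#'                    criterion("fitness", c("fit", "unfit")))
#' names(cs)
#' @export
criteria_set <- function(...) {
  crits <- list(...)
  if (length(crits) == 1L && !inherits(crits[[1L]], "tc_criterion"))
    crits <- crits[[1L]]
  if (length(crits) == 0L)
    tc_error("tc_semantic_error", "criteria set must contain at least one criterion")
  ok <- vapply(crits, inherits, logical(1L), "tc_criterion")
  if (!all(ok))
    tc_error("tc_semantic_error", "all elements of a criteria set must be criteria")
  nms <- vapply(crits, function(c) c$name, character(1L))
  if (anyDuplicated(nms))
    tc_error("tc_semantic_error",
             sprintf("duplicate criterion names: %s",
                     paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  crits <- crits[order(nms)]
  names(crits) <- sort(nms)
  structure(crits, class = "tc_criteria_set")
}

cs_names <- function(cs) names(cs)

cs_levels <- function(cs, name) {
  if (!name %in% names(cs))
    tc_error("tc_semantic_error", sprintf("unknown criterion '%s'", name))
  cs[[name]]$levels
}

# TRUE iff two criteria sets describe the same universe (names + level sets,
# including level order, which fixes scenario order)
cs_equal <- function(a, b) {
  identical(cs_names(a), cs_names(b)) &&
    all(vapply(cs_names(a), function(n) identical(a[[n]]$levels, b[[n]]$levels),
               logical(1L)))
}

#' @export
print.tc_criteria_set <- function(x, ...) {
  cat(sprintf("Criteria set: %d criteria, %d scenarios\n",
              length(x), prod(vapply(x, function(c) length(c$levels), numeric(1L)))))
  for (c in x)
    cat(sprintf("  %s [%s]: %s\n", c$name, c$kind, paste(c$levels, collapse = ", ")))
  invisible(x)
}

#' Recommendation sets
#'
#' A leaf of a decision tree carries a nonempty set of recommendation labels
#' together with an explicit multiplicity flag:
#' \describe{
#'   \item{single}{exactly one recommendation (the default for one label);}
#'   \item{equivalent-alternatives}{several options without preference;}
#'   \item{ranked}{several options in stated preference order (the member
#'     order is the ranking).}
#' }
#' A set with several members but multiplicity `single` is constructible —
#' drafts contain exactly that defect — and is flagged as a *conflict* by
#' [validate_tree()], never silently reinterpreted.
#'
#' @param labels Character vector of recommendation labels (whitespace is
#'   normalized; comparison is case-sensitive).
#' @param multiplicity One of `"single"`, `"equivalent-alternatives"`,
#'   `"ranked"`. Defaults to `"single"` for one label; must be declared
#'   explicitly for several.
#' @return An object of class `tc_rec_set`.
#' @examples
#' rec_set("Gem")
#' rec_set(c("SUN", "PAZ"), "equivalent-alternatives")
#' @export
rec_set <- function(labels, multiplicity = NULL) {
  labels <- trim_label(labels)
  if (length(labels) == 0L || any(!nzchar(labels)))
    tc_error("tc_semantic_error", "recommendation labels must be nonempty")
  if (anyDuplicated(labels))
    tc_error("tc_semantic_error",
             sprintf("duplicate recommendation labels: %s",
                     paste(labels[duplicated(labels)], collapse = ", ")))
  if (is.null(multiplicity)) {
    if (length(labels) > 1L)
      tc_error("tc_semantic_error",
               "multiplicity must be declared explicitly for more than one recommendation")
    multiplicity <- "single"
  }
  if (!multiplicity %in% c("single", "equivalent-alternatives", "ranked"))
    tc_error("tc_semantic_error", sprintf("unknown multiplicity '%s'", multiplicity))
  if (multiplicity != "single" && length(labels) == 1L)
    multiplicity <- "single"
  structure(list(members = labels, multiplicity = multiplicity),
            class = "tc_rec_set")
}

# canonical encodings used for equality tests and table cells: members are
# pipe-joined, sorted unless the order carries a ranking
rec_members_string <- function(rs) {
  m <- rs$members
  if (rs$multiplicity != "ranked") m <- sort(m)
  paste(m, collapse = "|")
}

rec_key <- function(rs) paste_key(rs$multiplicity, rec_members_string(rs))

rec_from_string <- function(members_string, multiplicity) {
  rec_set(strsplit(members_string, "|", fixed = TRUE)[[1L]], multiplicity)
}

rec_equal <- function(a, b) identical(rec_key(a), rec_key(b))

#' @export
print.tc_rec_set <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$multiplicity, paste(x$members, collapse = " | ")))
  invisible(x)
}
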