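#' Six-center performance-status cut-off census and fit/unfit rules
#'
#' A worked harmonization example as collected in a real multi-center
#' glioblastoma project: six centers dichotomize patient fitness on
#' different scales — Karnofsky Performance Status (KPS) at cut-offs 50,
#' 60, 70 and 90, ECOG at 1, and one center with no specific scale
#' ("good"/"bad"). The returned rules map every encoding onto the shared
#' binary `fitness` criterion (fit/unfit). The good/bad encoding is mapped
#' 1:1 with a note: the resolution was a moderation decision, not stated on
#' any scale.
#'
#' @return List with `census` (data.frame: center, scale, cutoff,
#'   source_criterion, source_levels) and `rules`
#'   (a [harmonization_rules()] set).
#' @examples
#' ps <- performance_status_cutoffs()
#' ps$census
#' @export
performance_status_cutoffs <- function() {
  fitness <- criterion("fitness", c("fit", "unfit"),
                       description = "harmonized patient fitness",
                       kind = "derived-from-cutoff",
                       source = list(scale = "multiple", cutoff = NA))
  kps_rule <- function(center, cut) {
    map <- c("fit", "unfit")
    names(map) <- c(sprintf(">=%d", cut), sprintf("<%d", cut))
    harmonization_rule(center, "KPS", "fitness", map,
                       source_scale = "KPS", cutoff = cut)
  }
  rules <- list(
    kps_rule("A", 50L),
    kps_rule("B", 60L),
    kps_rule("C", 70L),
    kps_rule("D", 90L),
    harmonization_rule("E", "ECOG", "fitness", c("<=1" = "fit", ">1" = "unfit"),
                       source_scale = "ECOG", cutoff = 1L),
    harmonization_rule("F", "global_impression", "fitness",
                       c("good" = "fit", "bad" = "unfit"),
                       note = paste("no specific scale used by this center;",
                                    "good/bad mapped 1:1 to fit/unfit by moderation"))
  )
  census <- data.frame(
    center = c("A", "B", "C", "D", "E", "F"),
    scale = c("KPS", "KPS", "KPS", "KPS", "ECOG", "none"),
    cutoff = c(50L, 60L, 70L, 90L, 1L, NA_integer_),
    source_criterion = c("KPS", "KPS", "KPS", "KPS", "ECOG", "global_impression"),
    source_levels = c("<50|>=50", "<60|>=60", "<70|>=70", "<90|>=90",
                      "<=1|>1", "good|bad"),
    stringsAsFactors = FALSE
  )
  list(census = census, rules = harmonization_rules(criteria_set(fitness), rules))
}

#' The imperfect draft decision tree example
#'
#' Loads the packaged draft tree for first-line treatment of metastatic
#' pancreatic cancer — a synthetic transcription of the kind of first
#' submission the refinement loop exists for. It deliberately contains the
#' classic draft defects: a `fit` leaf offering two regimens without
#' declaring whether they are equivalent or ranked (a *conflict*), and an
#' unfit sub-tree in which best supportive care and gemcitabine compete for
#' the same elderly patients (an *overlap*) while younger unfit patients
#' receive no recommendation at all (a *gap*). [validate_tree()] flags all
#' of these; the tree is not expandable until they are resolved.
#'
#' @return A `tc_decision_tree` (built without structural checks).
#' @examples
#' rep <- validate_tree(draft_tree_example())
#' rep$is_valid
#' @export
draft_tree_example <- function() {
  path <- system.file("extdata", "draft_pancreatic_tree_synthetic.json",
                      package = "treeconsensus", mustWork = TRUE)
  parse_tree(path, check = FALSE)
}
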