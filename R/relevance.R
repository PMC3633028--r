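#' Relevance of a single condition within a rule
#'
#' Removing a condition from a rule `r` gives a weaker rule `r'` whose error
#' cannot be smaller; the error increase `E(r') - E(r)` measures how much the
#' condition contributes to keeping the rule clean, and is non-negative by
#' construction.
#'
#' @param rule A [rule()].
#' @param attribute Name of the attribute whose condition is scored (must be
#'   present in the premise).
#' @param dataset A [cohort_dataset()].
#' @return Non-negative relevance value `R(c) = E(r') - E(r)`.
#' @export
condition_relevance <- function(rule, attribute, dataset) {
  if (!attribute %in% names(rule$premise))
    stop("rule has no condition on attribute '", attribute, "'")
  reduced <- rule
  reduced$premise[[attribute]] <- NULL
  e_full <- rule_stats(confusion_counts(rule, dataset))$E
  e_red <- rule_stats(confusion_counts(reduced, dataset))$E
  e_red - e_full
}

#' Per-variable relevance of a classifier
#'
#' Aggregates condition relevances over all rules mentioning a variable:
#' `R_j = 1 - prod(1 - P(r_k) * R(c_kl))`, the product running over the rules
#' `r_k` holding a condition `c_kl` on attribute `x_j`. Both factors lie in
#' \[0, 1\], so `R_j` does too; a variable mentioned by no rule scores 0. A
#' rule whose precision is undefined (it covers nothing) contributes a
#' neutral factor.
#'
#' @param classifier A [rule_classifier()].
#' @param dataset A [cohort_dataset()] the relevances are computed on.
#' @param target_class Optional class label: restrict to the rules predicting
#'   that class (per-class relevance). Default `NULL` uses all rules.
#' @return Named numeric vector, one relevance in \[0, 1\] per schema
#'   attribute.
#' @export
#' @examples
#' sch <- cohort_schema(attr_nominal("A", c("a", "b")))
#' ds <- cohort_dataset(data.frame(A = c("a", "a", "b"), y = c("G", "G", "P")),
#'                      sch, outcome = "y")
#' clf <- rule_classifier(list(parse_rule("if A in {a} then y = G", sch)), sch)
#' variable_relevance(clf, ds)
variable_relevance <- function(classifier, dataset, target_class = NULL) {
  attrs <- schema_names(classifier$schema)
  out <- stats::setNames(numeric(length(attrs)), attrs)
  rules <- classifier$rules
  if (!is.null(target_class))
    rules <- Filter(function(r) r$consequence == target_class, rules)
  for (a in attrs) {
    prod_term <- 1
    for (r in rules) {
      if (!a %in% names(r$premise)) next
      st <- rule_stats(confusion_counts(r, dataset))
      if ("P" %in% st$undefined) next  # empty coverage: neutral factor
      rc <- condition_relevance(r, a, dataset)
      prod_term <- prod_term * (1 - st$P * rc)
    }
    out[a] <- 1 - prod_term
  }
  out
}
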