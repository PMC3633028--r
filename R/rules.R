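#' Construct a classification rule
#'
#' A rule is the logical AND of conditions on distinct attributes (the
#' premise) together with a consequence class label. The empty premise is the
#' always-true rule. The reserved label `"NC"` (not classified) marks derived
#' conflict rules.
#'
#' @param premise List of conditions built with the condition constructors
#'   (internally) or obtained from [parse_rule()]. Multiple conditions on one
#'   attribute are merged by intersection.
#' @param consequence Class label (or `"NC"`).
#' @param schema A [cohort_schema()] the conditions must conform to.
#' @param id Optional rule identifier.
#' @return An object of class `rule`.
#' @seealso [parse_rule()], [format_rule()], [confusion_counts()]
#' @export
rule <- function(premise, consequence, schema, id = NULL) {
  stopifnot(inherits(schema, "cohort_schema"))
  premise <- lapply(premise, check_condition, schema = schema)
  premise <- normalize_premise(premise, schema)
  structure(list(id = id, premise = premise, consequence = as.character(consequence),
                 counts = NULL, stats = NULL),
            class = "rule")
}

# Merge duplicate-attribute conditions by intersection and sort by attribute
# name. Stops if an intersection is empty (contradictory premise).
normalize_premise <- function(conds, schema) {
  if (!length(conds)) return(list())
  attrs <- vapply(conds, `[[`, character(1L), "attribute")
  out <- list()
  for (a in sort(unique(attrs))) {
    cur <- NULL
    for (cond in conds[attrs == a]) {
      cur <- cond_intersect(cur, cond, schema[[a]])
      if (!cond_satisfiable(cur, schema[[a]]))
        stop("contradictory conditions on attribute '", a, "'")
    }
    out[[a]] <- cur
  }
  out
}

#' Parse a rule from its textual form
#'
#' Grammar: `if <cond> [and <cond>]* then <attr> = <label>` where `<cond>` is
#' one of `attr > v`, `attr <= v`, `v < attr <= w`, `attr in {v1, v2, ...}`.
#' An empty premise (`if then ...`) yields the always-true rule.
#'
#' @param text One rule expression.
#' @param schema A [cohort_schema()] used to validate attributes and values.
#' @param id Optional rule identifier.
#' @return A [rule()]; `format_rule(parse_rule(t, s), ...)` round-trips
#'   semantically (same covered set on any dataset).
#' @export
#' @examples
#' sch <- cohort_schema(attr_ordered("x1", c(1, 100)),
#'                      attr_nominal("x2", c("red", "green", "blue")))
#' r <- parse_rule("if x1 > 40 and x2 in {red, blue} then y = 0", sch)
#' format_rule(r)
parse_rule <- function(text, schema, id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec("^\\s*if\\s*(.*?)\\s*then\\s+(\\S+)\\s*=\\s*(\\S+)\\s*$", text)
  g <- regmatches(text, m)[[1L]]
  if (!length(g))
    stop("parse error: expected 'if <premise> then <attr> = <label>' in: ", text)
  premise_txt <- g[2L]
  consequence <- g[4L]

  conds <- list()
  if (nzchar(premise_txt)) {
    parts <- strsplit(premise_txt, "\\s+and\\s+")[[1L]]
    offset <- 0L
    for (p in parts) {
      conds[[length(conds) + 1L]] <- parse_condition(p, text)
      offset <- offset + nchar(p)
    }
  }
  rule(conds, consequence, schema, id = id)
}

parse_condition <- function(p, full_text) {
  pos <- regexpr(p, full_text, fixed = TRUE)
  where <- if (pos > 0L) sprintf(" (at position %d)", as.integer(pos)) else ""
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("parse error: '", s, "' is not numeric in condition '",
                       p, "'", where)
    v
  }
  m <- regexec("^(\\S+)\\s+in\\s*\\{([^}]*)\\}$", p)
  g <- regmatches(p, m)[[1L]]
  if (length(g)) {
    vals <- trimws(strsplit(g[3L], ",")[[1L]])
    vals <- vals[nzchar(vals)]
    if (!length(vals)) stop("parse error: empty value set in '", p, "'", where)
    return(cond_member(g[2L], vals))
  }
  m <- regexec("^(\\S+)\\s*<\\s*(\\S+)\\s*<=\\s*(\\S+)$", p)
  g <- regmatches(p, m)[[1L]]
  if (length(g)) return(cond_interval(g[3L], num(g[2L]), num(g[4L])))
  m <- regexec("^(\\S+)\\s*>\\s*(\\S+)$", p)
  g <- regmatches(p, m)[[1L]]
  if (length(g)) return(cond_greater(g[2L], num(g[3L])))
  m <- regexec("^(\\S+)\\s*<=\\s*(\\S+)$", p)
  g <- regmatches(p, m)[[1L]]
  if (length(g)) return(cond_at_most(g[2L], num(g[3L])))
  stop("parse error: malformed condition '", p, "'", where)
}

#' Format a rule in the textual grammar
#'
#' @param x A [rule()].
#' @param outcome Name to print on the consequence side (default `"y"`).
#' @return A single string, e.g. `"if x1 > 40 then y = 0"`.
#' @export
format_rule <- function(x, outcome = "y") {
  stopifnot(inherits(x, "rule"))
  lhs <- if (length(x$premise))
    paste(vapply(x$premise, format_condition, character(1L)), collapse = " and ")
  else ""
  sprintf("if %s then %s = %s", lhs, outcome, x$consequence)
}

#' @export
print.rule <- function(x, ...) {
  cat(format_rule(x))
  if (!is.null(x$stats))
    cat(sprintf("   [C=%.3g E=%.3g P=%.3g]", x$stats$C, x$stats$E, x$stats$P))
  cat("\n")
  invisible(x)
}

#' Which instances satisfy a rule's premise
#'
#' @param rule A [rule()].
#' @param dataset A [cohort_dataset()].
#' @return Logical vector, one element per instance.
#' @export
rule_covered <- function(rule, dataset) {
  cov <- rep(TRUE, n_instances(dataset))
  for (cond in rule$premise)
    cov <- cov & cond_satisfied(cond, dataset$data[[cond$attribute]])
  cov
}

#' Confusion counts of a rule on a dataset
#'
#' TP and FP are the numbers of consequence-class and other-class instances
#' satisfying every condition of the premise; FN and TN are their complements,
#' so TP + FP + FN + TN equals the number of instances.
#'
#' @param rule A [rule()].
#' @param dataset A [cohort_dataset()] whose schema contains every attribute
#'   the rule mentions.
#' @return Named list with elements `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(rule, dataset) {
  cov <- rule_covered(rule, dataset)
  tgt <- dataset$outcome == rule$consequence
  list(TP = sum(cov & tgt), FP = sum(cov & !tgt),
       FN = sum(!cov & tgt), TN = sum(!cov & !tgt))
}

#' Covering, error and precision of a rule
#'
#' Covering C = TP/(TP+FN), error E = FP/(TN+FP), precision P = TP/(TP+FP).
#' A zero denominator yields 0 for that statistic, with its name recorded in
#' the `undefined` element so downstream consumers can tell a true zero from
#' an undefined one.
#'
#' @param counts Confusion counts as returned by [confusion_counts()].
#' @return List with numeric `C`, `E`, `P` and character vector `undefined`.
#' @export
#' @examples
#' rule_stats(list(TP = 3, FN = 1, FP = 0, TN = 4))  # C=0.75, E=0, P=1
rule_stats <- function(counts) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(counts)))
  if (any(unlist(counts[c("TP", "FP", "FN", "TN")]) < 0))
    stop("confusion counts must be non-negative")
  undef <- character(0L)
  div <- function(num, den, label) {
    if (den == 0) { undef <<- c(undef, label); 0 } else num / den
  }
  C <- div(counts$TP, counts$TP + counts$FN, "C")
  E <- div(counts$FP, counts$TN + counts$FP, "E")
  P <- div(counts$TP, counts$TP + counts$FP, "P")
  list(C = C, E = E, P = P, undefined = undef)
}

# Attach counts + stats computed on a dataset to a rule.
calibrate_rule <- function(rule, dataset) {
  rule$counts <- confusion_counts(rule, dataset)
  rule$stats <- rule_stats(rule$counts)
  rule
}

# Semantic equality of premises (after normalization) — used to resolve the
# degenerate rule-distance case where both covered sets are empty.
premise_identical <- function(r1, r2) {
  identical(lapply(r1$premise, unclass), lapply(r2$premise, unclass))
}
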