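#' Bundle rules into a classifier
#'
#' A classifier is an ordered list of rules sharing one schema. Prediction
#' follows the highest-covering policy: among the rules whose premise a
#' pattern satisfies, the one with maximal covering C decides; exact covering
#' ties are broken by higher precision, then by rule order.
#'
#' @param rules List of [rule()] objects.
#' @param schema The shared [cohort_schema()].
#' @param source Optional label of the training set the rules came from.
#' @param calibrate Optional [cohort_dataset()]; when given, per-rule
#'   confusion counts and C/E/P statistics are computed on it.
#' @return An object of class `rule_classifier`.
#' @export
rule_classifier <- function(rules, schema, source = NULL, calibrate = NULL) {
  stopifnot(inherits(schema, "cohort_schema"))
  rules <- unname(rules)
  ids <- vapply(seq_along(rules), function(i) {
    if (is.null(rules[[i]]$id)) sprintf("r%d", i) else rules[[i]]$id
  }, character(1L))
  if (anyDuplicated(ids)) stop("rule ids must be unique within a classifier")
  for (i in seq_along(rules)) rules[[i]]$id <- ids[i]
  clf <- structure(list(rules = rules, schema = schema, source = source,
                        contradictory_profiles = NULL),
                   class = "rule_classifier")
  if (!is.null(calibrate)) clf <- calibrate_classifier(clf, calibrate)
  clf
}

#' Recompute per-rule statistics of a classifier on a dataset
#'
#' @param classifier A [rule_classifier()].
#' @param dataset A [cohort_dataset()].
#' @return The classifier with per-rule counts and C/E/P attached.
#' @export
calibrate_classifier <- function(classifier, dataset) {
  classifier$rules <- lapply(classifier$rules, calibrate_rule, dataset = dataset)
  classifier
}

#' @export
print.rule_classifier <- function(x, ...) {
  cat(sprintf("rule classifier with %d rule(s)%s\n", length(x$rules),
              if (is.null(x$source)) "" else paste0(" [", x$source, "]")))
  for (r in x$rules) { cat(" ", r$id, ": ", sep = ""); print(r) }
  invisible(x)
}

#' Classify a single pattern
#'
#' @param classifier A calibrated [rule_classifier()] (per-rule covering
#'   values present; see [calibrate_classifier()]).
#' @param pattern Named list or one-row data.frame of attribute values.
#' @return The consequence of the satisfied rule with the highest covering, or
#'   `"NC"` if no rule is satisfied. Ties on covering are broken by higher
#'   precision, then by rule order.
#' @export
classify <- function(classifier, pattern) {
  stopifnot(inherits(classifier, "rule_classifier"))
  if (is.data.frame(pattern)) pattern <- as.list(pattern[1L, , drop = FALSE])
  if (!length(classifier$rules)) return("NC")
  best <- NULL
  for (r in classifier$rules) {
    sat <- all(vapply(r$premise, function(cond)
      cond_satisfied(cond, pattern[[cond$attribute]]), logical(1L)))
    if (!sat) next
    if (is.null(r$stats))
      stop("classifier is not calibrated; call calibrate_classifier() first")
    if (is.null(best) ||
        r$stats$C > best$stats$C ||
        (r$stats$C == best$stats$C && r$stats$P > best$stats$P))
      best <- r
  }
  if (is.null(best)) "NC" else best$consequence
}

#' Predict every instance of a dataset
#'
#' Vectorized application of the [classify()] policy.
#'
#' @param object A calibrated [rule_classifier()].
#' @param dataset A [cohort_dataset()].
#' @param ... Unused.
#' @return Character vector of predicted labels (`"NC"` where no rule fires).
#' @export
predict.rule_classifier <- function(object, dataset, ...) {
  n <- n_instances(dataset)
  if (!length(object$rules)) return(rep("NC", n))
  cov <- vapply(object$rules, rule_covered, logical(n), dataset = dataset)
  cov <- matrix(cov, nrow = n)
  C <- vapply(object$rules, function(r) {
    if (is.null(r$stats)) stop("classifier is not calibrated")
    r$stats$C
  }, numeric(1L))
  P <- vapply(object$rules, function(r) r$stats$P, numeric(1L))
  # order rules by (C desc, P desc, position asc); first satisfied rule wins
  ord <- order(-C, -P, seq_along(object$rules))
  cons <- vapply(object$rules, `[[`, character(1L), "consequence")[ord]
  cov <- cov[, ord, drop = FALSE]
  first <- apply(cov, 1L, function(z) { w <- which(z); if (length(w)) w[1L] else NA_integer_ })
  ifelse(is.na(first), "NC", cons[first])
}

#' Symbolic conflict analysis of a classifier
#'
#' Two rules conflict if some pattern of the full attribute domain satisfies
#' both premises while their consequences differ. Premises are intersected
#' attribute by attribute; a pair is reported iff the intersection is
#' satisfiable, and for each reported pair a derived rule with consequence
#' `"NC"` (not classified) is emitted whose premise is that intersection.
#'
#' @param classifier A [rule_classifier()].
#' @return List with `pairs` (data.frame of conflicting rule-id pairs and the
#'   witness premise) and `nc_rules` (list of derived NC [rule()]s).
#' @export
conflict_pairs <- function(classifier) {
  rules <- classifier$rules
  schema <- classifier$schema
  pairs <- list()
  nc_rules <- list()
  if (length(rules) >= 2L) {
    for (h in seq_len(length(rules) - 1L)) {
      for (k in (h + 1L):length(rules)) {
        rh <- rules[[h]]; rk <- rules[[k]]
        if (rh$consequence == rk$consequence) next
        inter <- premise_intersection(rh$premise, rk$premise, schema)
        if (is.null(inter)) next
        nc <- rule(inter, "NC", schema,
                   id = sprintf("NC_%s_%s", rh$id, rk$id))
        pairs[[length(pairs) + 1L]] <-
          data.frame(rule_h = rh$id, rule_k = rk$id,
                     witness = format_rule(nc), stringsAsFactors = FALSE)
        nc_rules[[length(nc_rules) + 1L]] <- nc
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(rule_h = character(0L), rule_k = character(0L),
                           witness = character(0L), stringsAsFactors = FALSE)
  list(pairs = pairs, nc_rules = nc_rules)
}

# Attribute-wise intersection of two premises over the full domain; an
# attribute missing from a premise is unconstrained. Returns the list of
# intersected conditions, or NULL if unsatisfiable.
premise_intersection <- function(p1, p2, schema) {
  out <- list()
  for (a in union(names(p1), names(p2))) {
    cur <- cond_intersect(p1[[a]], p2[[a]], schema[[a]])
    if (!cond_satisfiable(cur, schema[[a]])) return(NULL)
    if (!is.null(cur)) out[[a]] <- cur
  }
  out
}
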