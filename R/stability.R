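#' Configuration of repeated stratified cross-validation
#'
#' @param repetitions Number of independent cross-validations n (default 5).
#' @param folds Number of folds m per repetition (default 10); the total
#'   number of classifiers is N = n * m.
#' @param stratified Stratify folds by outcome class (default TRUE).
#' @param seed Integer seed making fold assignment reproducible.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(repetitions = 5L, folds = 10L, stratified = TRUE, seed = 1L) {
  stopifnot(folds >= 2L, repetitions >= 1L)
  structure(list(repetitions = as.integer(repetitions), folds = as.integer(folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_config")
}

# Run expr under a local RNG stream without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Train one classifier per held-out fold of repeated cross-validation
#'
#' Produces exactly `repetitions * folds` classifiers, each induced on the
#' instances outside one fold of one repetition. Fold assignment is stratified
#' by class and fully determined by the seed.
#'
#' @param dataset A [cohort_dataset()].
#' @param cv A [cv_config()].
#' @param induction An [induction_config()] passed to [induce_classifier()].
#' @return List of `rule_classifier` objects of length `repetitions * folds`,
#'   each carrying `repetition`, `fold` and `test_idx` attributes.
#' @export
run_cv <- function(dataset, cv = cv_config(), induction = induction_config()) {
  n <- n_instances(dataset)
  if (cv$stratified) {
    sizes <- table(dataset$outcome)
    if (any(sizes < cv$folds))
      stop("class '", names(sizes)[which.min(sizes)], "' has fewer instances (",
           min(sizes), ") than folds (", cv$folds, "); use fewer folds")
  }
  classifiers <- vector("list", cv$repetitions * cv$folds)
  with_seed(cv$seed, {
    for (rep_i in seq_len(cv$repetitions)) {
      fold_of <- integer(n)
      if (cv$stratified) {
        for (cl in unique(dataset$outcome)) {
          idx <- which(dataset$outcome == cl)
          idx <- idx[sample.int(length(idx))]
          fold_of[idx] <- rep_len(seq_len(cv$folds), length(idx))
        }
      } else {
        fold_of <- rep_len(seq_len(cv$folds), n)[sample.int(n)]
      }
      for (fold_i in seq_len(cv$folds)) {
        train <- subset_instances(dataset, fold_of != fold_i)
        clf <- induce_classifier(train, induction)
        clf$source <- sprintf("cv rep %d fold %d", rep_i, fold_i)
        attr(clf, "repetition") <- rep_i
        attr(clf, "fold") <- fold_i
        attr(clf, "test_idx") <- which(fold_of == fold_i)
        classifiers[[(rep_i - 1L) * cv$folds + fold_i]] <- clf
      }
    }
  })
  classifiers
}

#' Semantic distance between two rules
#'
#' One minus the Jaccard similarity of the two covered-instance sets,
#' evaluated on a common reference dataset. Rules with different consequences
#' are incomparable (`NA`). If both covered sets are empty the distance is 0
#' when the premises are symbolically identical and `NA` otherwise.
#'
#' @param r1,r2 [rule()] objects sharing a schema.
#' @param dataset Reference [cohort_dataset()].
#' @return A number in \[0, 1\], or `NA` for incomparable rules.
#' @export
rule_distance <- function(r1, r2, dataset) {
  if (r1$consequence != r2$consequence) return(NA_real_)
  c1 <- rule_covered(r1, dataset)
  c2 <- rule_covered(r2, dataset)
  u <- sum(c1 | c2)
  if (u == 0) return(if (premise_identical(r1, r2)) 0 else NA_real_)
  1 - sum(c1 & c2) / u
}

#' Stability of a rule across cross-validation classifiers
#'
#' A classifier contains an occurrence of the reference rule when it holds at
#' least one rule with the same consequence at [rule_distance()] below
#' `eps`. Stability is the fraction b/N of the N classifiers containing an
#' occurrence; the maximum, 1, means the rule reappears in every one.
#'
#' @param rule Reference [rule()].
#' @param classifiers List of classifiers from [run_cv()].
#' @param dataset Reference [cohort_dataset()] on which coverage is compared.
#' @param eps Occurrence tolerance in (0, 1) (default 0.05).
#' @return Stability value in \[0, 1\].
#' @export
rule_stability <- function(rule, classifiers, dataset, eps = 0.05) {
  stopifnot(length(classifiers) > 0, eps > 0, eps < 1)
  ref_cov <- rule_covered(rule, dataset)
  b <- sum(vapply(classifiers, function(clf) {
    any(vapply(clf$rules, function(r) {
      d <- rule_distance_cov(rule, ref_cov, r, rule_covered(r, dataset))
      !is.na(d) && d < eps
    }, logical(1L)))
  }, logical(1L)))
  b / length(classifiers)
}

# distance given precomputed coverages
rule_distance_cov <- function(r1, c1, r2, c2) {
  if (r1$consequence != r2$consequence) return(NA_real_)
  u <- sum(c1 | c2)
  if (u == 0) return(if (premise_identical(r1, r2)) 0 else NA_real_)
  1 - sum(c1 & c2) / u
}

#' Per-rule stability report for a classifier
#'
#' @param classifier The reference [rule_classifier()].
#' @param classifiers List of CV classifiers from [run_cv()].
#' @param dataset Reference [cohort_dataset()].
#' @param eps Occurrence tolerance (default 0.05).
#' @return A data.frame of class `stability_report`: rule id, formatted rule,
#'   consequence, occurrence count `b`, `N` and `stability`.
#' @export
stability_report <- function(classifier, classifiers, dataset, eps = 0.05) {
  rows <- lapply(classifier$rules, function(r) {
    s <- rule_stability(r, classifiers, dataset, eps)
    data.frame(rule = r$id, text = format_rule(r), consequence = r$consequence,
               b = as.integer(round(s * length(classifiers))),
               N = length(classifiers), stability = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stability_report", class(out))
  attr(out, "eps") <- eps
  out
}

#' Derive Core rules from cross-validation classifiers
#'
#' Same-consequence rules pooled from all classifiers are clustered by
#' single linkage under [rule_distance()] `< eps`; each cluster yields one
#' Core rule whose premise is the attribute-wise intersection of the
#' component premises (membership sets intersected, intervals intersected; an
#' attribute unconstrained in a component imposes nothing). Clusters whose
#' intersection is unsatisfiable are dropped. The Core rule's aggregated
#' stability is the fraction of classifiers contributing at least one
#' component.
#'
#' @param classifiers Non-empty list of classifiers from [run_cv()].
#' @param dataset Reference [cohort_dataset()].
#' @param eps Clustering tolerance (default 0.05).
#' @return A list of class `core_rule_set`: `rules` (calibrated Core
#'   [rule()]s, ids `C1`, `C2`, ...), `stability` (numeric vector aligned
#'   with `rules`), `summary` (data.frame), `n_classifiers`.
#' @export
build_core_rules <- function(classifiers, dataset, eps = 0.05) {
  stopifnot(length(classifiers) > 0)
  N <- length(classifiers)
  pool <- list(); origin <- integer(0L)
  for (i in seq_along(classifiers)) {
    for (r in classifiers[[i]]$rules) {
      pool[[length(pool) + 1L]] <- r
      origin <- c(origin, i)
    }
  }
  if (!length(pool))
    return(structure(list(rules = list(), stability = numeric(0L),
                          summary = data.frame(), n_classifiers = N),
                     class = "core_rule_set"))
  n <- n_instances(dataset)
  cov <- vapply(pool, rule_covered, logical(n), dataset = dataset)
  cov <- matrix(cov, nrow = n)
  cons <- vapply(pool, `[[`, character(1L), "consequence")

  # single-linkage = connected components of the (d < eps) graph, per class
  parent <- seq_along(pool)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sizes <- colSums(cov)
  for (cl in unique(cons)) {
    idx <- which(cons == cl)
    if (length(idx) < 2L) next
    M <- cov[, idx, drop = FALSE]
    inter <- crossprod(M)                 # pairwise intersection sizes
    uni <- outer(sizes[idx], sizes[idx], `+`) - inter
    for (a in seq_len(length(idx) - 1L)) {
      for (b in (a + 1L):length(idx)) {
        d <- if (uni[a, b] == 0) {
          if (premise_identical(pool[[idx[a]]], pool[[idx[b]]])) 0 else NA_real_
        } else 1 - inter[a, b] / uni[a, b]
        if (!is.na(d) && d < eps) {
          ra <- find(idx[a]); rb <- find(idx[b])
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
  }
  comp <- vapply(seq_along(pool), find, integer(1L))

  core <- list(); stab <- numeric(0L); members <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    prem <- pool[[idx[1L]]]$premise
    ok <- TRUE
    for (j in idx[-1L]) {
      prem <- tryCatch(premise_intersection(prem, pool[[j]]$premise, dataset$schema),
                       error = function(e) NULL)
      if (is.null(prem)) { ok <- FALSE; break }
    }
    if (!ok) next
    r <- rule(prem, cons[idx[1L]], dataset$schema)
    core[[length(core) + 1L]] <- calibrate_rule(r, dataset)
    stab <- c(stab, length(unique(origin[idx])) / N)
    members[[length(members) + 1L]] <- idx
  }
  ord <- order(-stab, vapply(core, format_rule, character(1L)))
  core <- core[ord]; stab <- stab[ord]; members <- members[ord]
  origins <- lapply(members, function(idx) sort(unique(origin[idx])))
  for (i in seq_along(core)) core[[i]]$id <- sprintf("C%d", i)

  summary <- data.frame(
    rule = vapply(core, `[[`, character(1L), "id"),
    text = vapply(core, format_rule, character(1L)),
    consequence = vapply(core, `[[`, character(1L), "consequence"),
    components = vapply(members, length, integer(1L)),
    stability = stab, stringsAsFactors = FALSE)
  structure(list(rules = core, stability = stab, summary = summary,
                 origins = origins, n_classifiers = N),
            class = "core_rule_set")
}

#' @export
print.core_rule_set <- function(x, ...) {
  cat(sprintf("core rule set: %d rule(s) from %d classifiers\n",
              length(x$rules), x$n_classifiers))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
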