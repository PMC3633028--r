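#' Configuration of the stabilization loop
#'
#' @param nu Stability slack: a rule is accepted when its stability is at
#'   least `1 - nu`. Default 0, i.e. every rule must reach the maximal
#'   stability of 1 before the loop stops.
#' @param s_cov Low-covering threshold for the first instability cause
#'   (default 0.1): unstable rules covering at most this fraction of their
#'   class are suspects.
#' @param s_diff Near-duplicate threshold for the second cause (default 1):
#'   two same-consequence rules whose covered sets differ by at most `s_diff`
#'   instances flag the instances in the difference.
#' @param max_iterations Safety cap on purge iterations (default 10).
#' @param eps Rule-occurrence tolerance passed to the stability machinery.
#' @param cv A [cv_config()].
#' @param induction An [induction_config()].
#' @return A list of class `stabilization_config`.
#' @export
stabilization_config <- function(nu = 0, s_cov = 0.1, s_diff = 1L,
                                 max_iterations = 10L, eps = 0.05,
                                 cv = cv_config(), induction = induction_config()) {
  stopifnot(nu >= 0, nu < 1, s_cov > 0, s_cov <= 1, s_diff >= 1)
  structure(list(nu = nu, s_cov = s_cov, s_diff = as.integer(s_diff),
                 max_iterations = as.integer(max_iterations), eps = eps,
                 cv = cv, induction = induction),
            class = "stabilization_config")
}

#' Diagnose the instances responsible for rule instability
#'
#' Three causes are screened, over the Core rules derived from the
#' cross-validation classifiers:
#' \enumerate{
#'   \item \emph{low_covering_unstable}: a rule with stability below `1 - nu`
#'     and covering at most `s_cov` exists only when all of its few instances
#'     fall in the training split; the instances it covers exclusively (no
#'     stable rule covers them) are flagged.
#'   \item \emph{near_duplicate_rule}: two same-consequence rules whose
#'     covered sets differ by between 1 and `s_diff` instances; the instances
#'     in the difference force the near-duplicate into existence and are
#'     flagged.
#'   \item \emph{ambiguous_profile}: instances sharing one full attribute
#'     profile but holding more than one outcome label; the class assigned to
#'     them depends only on the chance imbalance between training and test
#'     splits, so the whole group is flagged.
#' }
#'
#' @param dataset The current [cohort_dataset()].
#' @param core A [build_core_rules()] result computed on this dataset.
#' @param config A [stabilization_config()].
#' @return A data.frame of class `instability_diagnosis` with columns `id`,
#'   `cause` and `evidence` (rule ids or the shared profile); one row per
#'   (instance, cause), deduplicated within cause.
#' @export
diagnose_instability <- function(dataset, core, config = stabilization_config()) {
  n <- n_instances(dataset)
  flags <- list()
  add <- function(idx, cause, evidence) {
    if (!length(idx)) return()
    flags[[length(flags) + 1L]] <<- data.frame(
      id = dataset$ids[idx], cause = cause, evidence = evidence,
      stringsAsFactors = FALSE)
  }

  rules <- core$rules
  if (length(rules)) {
    cov <- vapply(rules, rule_covered, logical(n), dataset = dataset)
    cov <- matrix(cov, nrow = n)
    stab <- core$stability
    covering <- vapply(rules, function(r) r$stats$C, numeric(1L))
    stable <- stab >= 1 - config$nu

    # cause 1: low-covering unstable rules, instances they cover exclusively
    for (k in which(!stable & covering <= config$s_cov)) {
      other_stable <- stable & seq_along(rules) != k
      covered_by_stable <- if (any(other_stable))
        rowSums(cov[, other_stable, drop = FALSE]) > 0 else rep(FALSE, n)
      add(which(cov[, k] & !covered_by_stable), "low_covering_unstable",
          rules[[k]]$id)
    }

    # cause 2: near-duplicate rule pairs; the pair must have been generated
    # together in at least one CV classifier, otherwise the two rules are
    # mutually exclusive variants rather than a co-occurring duplicate
    cons <- vapply(rules, `[[`, character(1L), "consequence")
    for (k in seq_along(rules)) {
      for (h in seq_along(rules)) {
        if (k == h || cons[k] != cons[h]) next
        if (!is.null(core$origins) &&
            !length(intersect(core$origins[[k]], core$origins[[h]]))) next
        diff <- which(cov[, k] & !cov[, h])
        if (length(diff) >= 1L && length(diff) <= config$s_diff)
          add(diff, "near_duplicate_rule",
              sprintf("%s \\ %s", rules[[k]]$id, rules[[h]]$id))
      }
    }
  }

  # cause 3: duplicated profiles carrying more than one outcome label
  keys <- profile_keys(dataset)
  for (key in unique(keys[duplicated(keys)])) {
    idx <- which(keys == key)
    if (length(unique(dataset$outcome[idx])) > 1L)
      add(idx, "ambiguous_profile", gsub("\r", "|", key, fixed = TRUE))
  }

  out <- if (length(flags)) do.call(rbind, flags)
         else data.frame(id = character(0L), cause = character(0L),
                         evidence = character(0L), stringsAsFactors = FALSE)
  out <- unique(out[, c("id", "cause", "evidence")])
  rownames(out) <- NULL
  class(out) <- c("instability_diagnosis", class(out))
  out
}

#' Iteratively purge instability sources until every rule is fully stable
#'
#' One iteration: induce a classifier on the current dataset; assess every
#' rule's stability under `repetitions x folds` cross-validation; if each
#' rule reaches stability `>= 1 - nu` (and induction met its error contract
#' on every rule) the classifier is accepted; otherwise Core rules are built
#' from the cross-validation classifiers, [diagnose_instability()] flags the
#' responsible instances, those instances are removed, and a new iteration
#' starts on the purged dataset.
#'
#' @param dataset A [cohort_dataset()].
#' @param config A [stabilization_config()].
#' @return An object of class `stabilization_result`: `classifier` (final,
#'   calibrated on the purged dataset), `dataset` (purged), `removed`
#'   (data.frame id/cause/evidence/iteration), `iterations` (per-iteration
#'   log: n, stability report, core summary, flagged ids), `converged`.
#' @export
stabilize <- function(dataset, config = stabilization_config()) {
  current <- dataset
  removed <- data.frame(id = character(0L), cause = character(0L),
                        evidence = character(0L), iteration = integer(0L),
                        stringsAsFactors = FALSE)
  log <- list()

  for (iter in seq_len(config$max_iterations)) {
    clf <- induce_classifier(current, config$induction)
    cv_cfg <- config$cv
    cv_cfg$seed <- config$cv$seed + (iter - 1L) * 1009L
    cvs <- run_cv(current, cv_cfg, config$induction)
    rep <- stability_report(clf, cvs, current, config$eps)
    contradictory <- !is.null(clf$contradictory_profiles)
    stable <- all(rep$stability >= 1 - config$nu) && !contradictory

    entry <- list(iteration = iter, n = n_instances(current),
                  stability = rep, flagged = character(0L))
    if (stable) {
      log[[iter]] <- entry
      return(structure(list(classifier = clf, dataset = current,
                            removed = removed, iterations = log,
                            converged = TRUE),
                       class = "stabilization_result"))
    }

    core <- build_core_rules(cvs, current, config$eps)
    diag <- diagnose_instability(current, core, config)
    entry$core <- core$summary
    entry$flagged <- unique(diag$id)
    log[[iter]] <- entry

    if (!nrow(diag))
      stop(stabilize_error("instability persists but no instance was flagged",
                           log))
    removed <- rbind(removed,
                     cbind(diag, iteration = iter, stringsAsFactors = FALSE))
    current <- subset_instances(current, setdiff(current$ids, diag$id))
  }
  stop(stabilize_error(sprintf("no stable classifier within %d iterations",
                               config$max_iterations), log))
}

stabilize_error <- function(msg, log) {
  structure(class = c("stabilization_error", "error", "condition"),
            list(message = msg, call = sys.call(-1L), log = log))
}

#' @export
print.stabilization_result <- function(x, ...) {
  cat(sprintf("stabilization: %d iteration(s), %d instance(s) removed, %s\n",
              length(x$iterations), length(unique(x$removed$id)),
              if (x$converged) "converged" else "not converged"))
  print(x$classifier)
  invisible(x)
}

#' Purge a test set of the profiles removed during stabilization
#'
#' Removes every test instance whose full attribute profile equals the
#' profile of an instance removed from the training cohort, mirroring the
#' matched deletion applied to an independent validation set.
#'
#' @param test A [cohort_dataset()] (schema-compatible with the training
#'   cohort).
#' @param removed Either a `cohort_dataset` of removed instances or a
#'   data.frame holding their attribute columns.
#' @param schema The shared [cohort_schema()]; defaults to `test$schema`.
#' @return List with `dataset` (purged copy), `removed_ids` (test instance
#'   ids dropped) and `n_removed`.
#' @export
purge_matched <- function(test, removed, schema = test$schema) {
  stopifnot(inherits(test, "cohort_dataset"))
  rem_df <- if (inherits(removed, "cohort_dataset")) removed$data else removed
  key_of <- function(df) {
    cols <- lapply(schema, function(a) {
      v <- df[[a$name]]
      if (a$kind == "ordered") formatC(as.numeric(v), digits = 15, format = "g")
      else as.character(v)
    })
    do.call(paste, c(cols, sep = "\r"))
  }
  hit <- key_of(test$data) %in% key_of(rem_df)
  list(dataset = subset_instances(test, !hit),
       removed_ids = test$ids[hit],
       n_removed = sum(hit))
}
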