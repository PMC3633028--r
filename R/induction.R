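#' Configuration for rule induction
#'
#' Controls the bottom-up aggregative rule generalizer: every emitted rule
#' must keep its training error E(r) at or below `max_training_error`
#' (default 0, i.e. no false positive on the training set), condition counts
#' are minimized, and with `cover_all` every training instance ends up covered
#' by at least one rule.
#'
#' @param max_training_error Maximum admissible per-rule training error E(r),
#'   a fraction in \[0, 1\] (default 0).
#' @param minimize_conditions Drop conditions whose removal changes nothing
#'   (default TRUE).
#' @param cover_all Keep seeding rules until every training instance is
#'   covered (default TRUE; turning it off stops each class after its first
#'   rule).
#' @param attribute_order Character vector fixing the deterministic tie-break
#'   order over attributes (default: schema order).
#' @param discretizer A [discretizer_config()] applied to ordered attributes
#'   before induction.
#' @return A list of class `induction_config`.
#' @export
induction_config <- function(max_training_error = 0, minimize_conditions = TRUE,
                             cover_all = TRUE, attribute_order = NULL,
                             discretizer = discretizer_config()) {
  stopifnot(max_training_error >= 0, max_training_error <= 1)
  structure(list(max_training_error = max_training_error,
                 minimize_conditions = isTRUE(minimize_conditions),
                 cover_all = isTRUE(cover_all),
                 attribute_order = attribute_order,
                 discretizer = discretizer),
            class = "induction_config")
}

#' Configuration for ordered-attribute discretization
#'
#' @param min_class_distance Minimum class-proportion difference across a
#'   retained cutpoint, a fraction in (0, 1) (default 0.20).
#' @return A list of class `discretizer_config`.
#' @export
discretizer_config <- function(min_class_distance = 0.20) {
  stopifnot(min_class_distance > 0, min_class_distance < 1)
  structure(list(min_class_distance = min_class_distance),
            class = "discretizer_config")
}

#' Class-driven discretization of an ordered attribute
#'
#' Candidate cutpoints are placed at midpoints between consecutive distinct
#' sorted values whose class composition differs. Cutpoints are then merged
#' (weakest first) until the class-proportion difference between the segments
#' on either side of every retained cutpoint is at least `min_class_distance`.
#'
#' @param dataset A [cohort_dataset()].
#' @param attribute Name of an ordered attribute.
#' @param config A [discretizer_config()].
#' @return Sorted numeric vector of cutpoints (possibly empty: the attribute
#'   carries no class signal at the requested separation).
#' @export
discretize_attribute <- function(dataset, attribute, config = discretizer_config()) {
  a <- dataset$schema[[attribute]]
  if (is.null(a) || a$kind != "ordered")
    stop("'", attribute, "' is not an ordered attribute of the dataset")
  x <- dataset$data[[attribute]]
  y <- dataset$outcome
  classes <- sort(unique(y))
  vals <- sort(unique(x))
  if (length(vals) < 2L) return(numeric(0L))

  comp <- function(mask) {
    tab <- table(factor(y[mask], levels = classes))
    as.numeric(tab) / sum(tab)
  }
  # candidate cutpoints: boundaries where per-value class composition changes
  per_val <- lapply(vals, function(v) comp(x == v))
  keep <- vapply(seq_len(length(vals) - 1L), function(i)
    any(abs(per_val[[i]] - per_val[[i + 1L]]) > 0), logical(1L))
  cuts <- (vals[-length(vals)] + vals[-1L])[keep] / 2

  # merge adjacent segments until every retained cutpoint separates segments
  # whose class proportions differ by >= min_class_distance
  while (length(cuts)) {
    seg <- findInterval(x, cuts, left.open = TRUE) + 1L
    props <- lapply(seq_len(length(cuts) + 1L), function(s) comp(seg == s))
    gaps <- vapply(seq_along(cuts), function(i)
      max(abs(props[[i]] - props[[i + 1L]])), numeric(1L))
    if (min(gaps) >= config$min_class_distance) break
    cuts <- cuts[-which.min(gaps)]
  }
  cuts
}

#' Induce a rule classifier by bottom-up aggregative covering
#'
#' For each class, every distinct attribute profile held by a class instance
#' seeds a maximally specific premise (one condition per attribute pinned to
#' the seed's value, or to its discretization bin for ordered attributes).
#' Each premise is weakened one step at a time — dropping a condition, adding
#' one value to a membership set, or extending an interval to the adjacent
#' cutpoint — always taking the step with the largest gain in covered class
#' instances among those that keep the training error within
#' `max_training_error`, until no admissible step gains coverage. The
#' resulting pool of maximal candidate rules is deduplicated and a covering
#' subset is selected greedily (most newly covered class instances first,
#' ties by total covering, then fewer conditions, then rule text), so the
#' emitted rule set does not depend on instance order.
#'
#' A duplicated attribute profile split between classes cannot reach the
#' error bound; its instances are covered by flagged maximally specific rules
#' and the profile is reported in the classifier's `contradictory_profiles`
#' element (it is the third instability cause of [diagnose_instability()]).
#'
#' @param train A non-empty [cohort_dataset()].
#' @param config An [induction_config()].
#' @return A calibrated [rule_classifier()]; rules carry training counts and
#'   C/E/P, flagged rules carry `contradictory = TRUE`.
#' @export
induce_classifier <- function(train, config = induction_config()) {
  stopifnot(inherits(train, "cohort_dataset"))
  n <- n_instances(train)
  schema <- train$schema
  attr_names <- if (is.null(config$attribute_order)) schema_names(schema)
                else config$attribute_order
  if (!all(attr_names %in% schema_names(schema)))
    stop("attribute_order mentions unknown attributes")

  # per-attribute encodings
  enc <- lapply(attr_names, function(a) {
    s <- schema[[a]]
    if (s$kind == "nominal") {
      list(kind = "nominal", values = s$values,
           idx = match(train$data[[a]], s$values), nvals = length(s$values))
    } else {
      cuts <- discretize_attribute(train, a, config$discretizer)
      list(kind = "ordered", cuts = cuts, nbins = length(cuts) + 1L,
           bin = findInterval(train$data[[a]], cuts, left.open = TRUE) + 1L)
    }
  })
  names(enc) <- attr_names

  attr_mask <- function(a, spec) {
    e <- enc[[a]]
    if (e$kind == "nominal") e$idx %in% spec
    else e$bin >= spec[1L] & e$bin <= spec[2L]
  }
  premise_cov <- function(premise) {
    cov <- rep(TRUE, n)
    for (a in names(premise))
      if (!is.null(premise[[a]])) cov <- cov & attr_mask(a, premise[[a]])
    cov
  }
  to_conditions <- function(premise) {
    out <- list()
    for (a in names(premise)) {
      spec <- premise[[a]]
      if (is.null(spec)) next
      e <- enc[[a]]
      if (e$kind == "nominal") {
        if (length(spec) == e$nvals) next
        out[[a]] <- cond_member(a, e$values[sort(spec)])
      } else {
        lo <- spec[1L]; hi <- spec[2L]
        if (lo == 1L && hi == e$nbins) next
        out[[a]] <- if (lo == 1L) cond_at_most(a, e$cuts[hi])
                    else if (hi == e$nbins) cond_greater(a, e$cuts[lo - 1L])
                    else cond_interval(a, e$cuts[lo - 1L], e$cuts[hi])
      }
    }
    out
  }

  # greedy one-step weakening from a seed premise; prefers dropping a whole
  # condition, then attribute order, among equal TP gains. Gain climbing and
  # zero-gain condition drops are interleaved to a joint fixpoint: a drop that
  # gains nothing by itself can unlock further admissible gain steps.
  generalize <- function(premise, cov, tgt, fp_max) {
    repeat {
      # gain loop: apply the admissible step with the largest TP gain
      repeat {
        masks <- lapply(attr_names, function(a)
          if (is.null(premise[[a]])) NULL else attr_mask(a, premise[[a]]))
        names(masks) <- attr_names
        tp_cur <- sum(cov & tgt)
        best <- NULL
        for (ai in seq_along(attr_names)) {
          a <- attr_names[ai]
          if (is.null(premise[[a]])) next
          others <- masks[!vapply(masks, is.null, logical(1L))]
          others[[a]] <- NULL
          cov_except <- if (length(others)) Reduce(`&`, others) else rep(TRUE, n)
          consider <- function(new_spec, type, vpos) {
            m <- if (is.null(new_spec)) cov_except
                 else cov_except & attr_mask(a, new_spec)
            if (sum(m & !tgt) > fp_max) return()
            gain <- sum(m & tgt) - tp_cur
            if (gain <= 0) return()
            key <- c(-gain, type, ai, vpos)
            if (is.null(best) || keyless(key, best$key))
              best <<- list(key = key, attr = a, spec = new_spec)
          }
          consider(NULL, 0L, 0L)  # drop the whole condition
          e <- enc[[a]]
          if (e$kind == "nominal") {
            if (length(premise[[a]]) + 1L < e$nvals)
              for (v in setdiff(seq_len(e$nvals), premise[[a]]))
                consider(c(premise[[a]], v), 1L, v)
          } else {
            lo <- premise[[a]][1L]; hi <- premise[[a]][2L]
            if (lo > 1L && !(lo - 1L == 1L && hi == e$nbins))
              consider(c(lo - 1L, hi), 1L, 1L)
            if (hi < e$nbins && !(lo == 1L && hi + 1L == e$nbins))
              consider(c(lo, hi + 1L), 1L, 2L)
          }
        }
        if (is.null(best)) break
        premise[[best$attr]] <- best$spec
        cov <- premise_cov(premise)
      }
      if (!config$minimize_conditions) break
      # zero-gain drops (condition minimization)
      dropped <- FALSE
      tp_cur <- sum(cov & tgt)
      for (a in attr_names) {
        if (is.null(premise[[a]])) next
        trial <- premise; trial[[a]] <- NULL
        m <- premise_cov(trial)
        if (sum(m & !tgt) <= fp_max && sum(m & tgt) == tp_cur) {
          premise <- trial; cov <- m; dropped <- TRUE
          tp_cur <- sum(cov & tgt)
        }
      }
      if (!dropped) break
    }
    list(premise = premise, cov = cov)
  }

  rules <- list()
  contradictory <- integer(0L)  # row indices of contradictory profiles
  classes <- unique(train$outcome)
  keys <- profile_keys(train)

  for (cl in classes) {
    tgt <- train$outcome == cl
    n_non <- sum(!tgt)
    fp_max <- config$max_training_error * n_non + 1e-9

    # one seed per distinct class profile
    class_idx <- which(tgt)
    seeds <- class_idx[!duplicated(keys[class_idx])]
    pool <- list(); pool_keys <- character(0L)
    contr_rules <- list(); contr_cov <- rep(FALSE, n)

    for (seed in seeds) {
      premise <- lapply(attr_names, function(a) {
        e <- enc[[a]]
        if (e$kind == "nominal") e$idx[seed]
        else if (e$nbins > 1L) c(e$bin[seed], e$bin[seed]) else NULL
      })
      names(premise) <- attr_names
      cov <- premise_cov(premise)

      if (sum(cov & !tgt) > fp_max) {
        # identical profile carried by both classes: error bound unreachable
        r <- rule(to_conditions(premise), cl, schema)
        r <- calibrate_rule(r, train)
        r$contradictory <- TRUE
        contr_rules[[length(contr_rules) + 1L]] <- r
        contradictory <- c(contradictory, which(cov))
        contr_cov <- contr_cov | (cov & tgt)
        next
      }

      g <- generalize(premise, cov, tgt, fp_max)
      key <- format_rule(rule(to_conditions(g$premise), cl, schema))
      if (!key %in% pool_keys) {
        pool_keys <- c(pool_keys, key)
        pool[[length(pool) + 1L]] <-
          list(premise = g$premise, cov = g$cov, key = key,
               tp = sum(g$cov & tgt),
               ncond = sum(!vapply(g$premise, is.null, logical(1L))))
      }
    }

    # canonical covering selection over the candidate pool
    covered <- contr_cov
    while (length(pool) && any(tgt & !covered)) {
      gain <- vapply(pool, function(p) sum(p$cov & tgt & !covered), integer(1L))
      if (max(gain) == 0L) break
      tp <- vapply(pool, `[[`, integer(1L), "tp")
      nc <- vapply(pool, `[[`, integer(1L), "ncond")
      txt <- vapply(pool, `[[`, character(1L), "key")
      pick <- order(-gain, -tp, nc, txt)[1L]
      p <- pool[[pick]]
      rules[[length(rules) + 1L]] <-
        calibrate_rule(rule(to_conditions(p$premise), cl, schema), train)
      covered <- covered | (p$cov & tgt)
      pool <- pool[-pick]
      if (!config$cover_all) break
    }
    rules <- c(rules, contr_rules)
  }

  clf <- rule_classifier(rules, schema, source = "induced")
  if (length(contradictory)) {
    idx <- sort(unique(contradictory))
    prof <- train$data[idx, , drop = FALSE]
    prof$outcome <- train$outcome[idx]
    prof$id <- train$ids[idx]
    rownames(prof) <- NULL
    clf$contradictory_profiles <- prof
  }
  clf
}

# lexicographic "is key a strictly smaller than key b"
keyless <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}
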