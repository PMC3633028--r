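#' Specification of a synthetic categorical cohort
#'
#' Describes a cohort generator: attribute marginals, a planted rule set that
#' defines the outcome, an optional label-noise rate, ambiguous
#' duplicate-profile groups (one fixed profile carried by a group of
#' instances with an exact class split) and singleton injections (one unique
#' profile forced to carry a given class). Ambiguous and singleton profiles
#' are reserved: random draws never collide with them, so the planted ground
#' truth is exact.
#'
#' @param n Number of instances.
#' @param attributes Named list; each element is either a list
#'   `list(values = c(...), probs = c(...))` for a nominal attribute or
#'   `list(values = numeric, probs = c(...), ordered = TRUE)` for an ordered
#'   attribute sampled over a finite numeric value pool (schema bounds are
#'   taken from the pool range, widened by 5%). An element may instead carry
#'   `given = "<earlier attribute>"` and a `probs` MATRIX (one row per value
#'   of the conditioning attribute, rows summing to 1) to express a
#'   conditional marginal, e.g. an amplification rate that depends on tumor
#'   stage.
#' @param rules Character vector of planted rules in the [parse_rule()]
#'   grammar (consequence side `Outcome = <label>`); an instance takes the
#'   consequence of the first rule its profile satisfies.
#' @param background Class label for instances matching no planted rule.
#' @param noise Label-noise rate in \[0, 1\): each non-overwritten instance's
#'   label is flipped to another class with this probability (default 0).
#' @param ambiguous List of groups, each
#'   `list(profile = named list, size = k, split = named class counts)`.
#' @param singletons List of `list(profile = named list, class = label)`.
#' @return A list of class `cohort_spec` (includes the derived
#'   [cohort_schema()]).
#' @export
cohort_spec <- function(n, attributes, rules = character(0L),
                        background, noise = 0,
                        ambiguous = list(), singletons = list()) {
  stopifnot(n >= 1L, length(attributes) > 0, !is.null(names(attributes)),
            noise >= 0, noise < 1)
  schema <- cohort_schema(lapply(names(attributes), function(a) {
    sp <- attributes[[a]]
    if (!is.null(sp$given)) {
      giv <- attributes[[sp$given]]
      if (is.null(giv) || match(sp$given, names(attributes)) >= match(a, names(attributes)))
        stop("attribute '", a, "': 'given' must name an earlier attribute")
      if (!is.matrix(sp$probs) ||
          nrow(sp$probs) != length(giv$values) ||
          ncol(sp$probs) != length(sp$values))
        stop("attribute '", a, "': conditional probs must be a ",
             length(giv$values), " x ", length(sp$values), " matrix")
      if (any(abs(rowSums(sp$probs) - 1) > 1e-8))
        stop("attribute '", a, "': each conditional row must sum to 1")
    } else {
      if (length(sp$probs) != length(sp$values))
        stop("attribute '", a, "': probs and values differ in length")
      if (abs(sum(sp$probs) - 1) > 1e-8)
        stop("attribute '", a, "': marginal frequencies must sum to 1")
    }
    if (isTRUE(sp$ordered)) {
      rng <- range(as.numeric(sp$values))
      attr_ordered(a, rng + c(-1, 1) * 0.05 * diff(rng))
    } else attr_nominal(a, as.character(sp$values))
  }))
  structure(list(n = as.integer(n), attributes = attributes, schema = schema,
                 rules = rules, background = as.character(background),
                 noise = noise, ambiguous = ambiguous, singletons = singletons),
            class = "cohort_spec")
}

#' Generate a cohort from a specification
#'
#' Attribute vectors are drawn independently from the declared marginals
#' (redrawn if they collide with a reserved ambiguous/singleton profile);
#' outcomes come from the first matching planted rule, else the background
#' class, with optional label noise. The trailing instances are then
#' overwritten by the ambiguous groups (exact class split) and singletons.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same (spec, seed) pair always yields an
#'   identical cohort.
#' @return List with `dataset` (a [cohort_dataset()]) and `truth`, a
#'   data.frame with per-instance `id`, `provenance`
#'   (`clean`/`noisy`/`ambiguous`/`singleton`) and `planted_rule` (index of
#'   the first matching planted rule, NA otherwise).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  schema <- spec$schema
  anames <- names(spec$attributes)
  planted <- lapply(seq_along(spec$rules), function(i)
    parse_rule(spec$rules[i], schema, id = sprintf("planted%d", i)))

  profile_row <- function(profile) {
    missing <- setdiff(anames, names(profile))
    if (length(missing))
      stop("profile lacks attribute(s): ", paste(missing, collapse = ", "))
    row <- vapply(anames, function(a) {
      s <- schema[[a]]
      v <- profile[[a]]
      if (!check_value(s, v))
        stop("profile value '", v, "' outside domain of '", a, "'")
      as.character(v)
    }, character(1L))
    names(row) <- anames
    row
  }
  reserved <- c(lapply(spec$ambiguous, function(g) profile_row(g$profile)),
                lapply(spec$singletons, function(s) profile_row(s$profile)))
  n_overwrite <- sum(vapply(spec$ambiguous, function(g) as.integer(g$size),
                            integer(1L))) + length(spec$singletons)
  if (n_overwrite > spec$n)
    stop("ambiguous groups and singletons exceed the cohort size")

  with_seed(seed, {
    draw_row <- function() {
      row <- character(length(anames))
      names(row) <- anames
      for (a in anames) {
        sp <- spec$attributes[[a]]
        p <- if (is.null(sp$given)) sp$probs
             else sp$probs[match(row[[sp$given]],
                                 spec$attributes[[sp$given]]$values), ]
        row[[a]] <- as.character(sample(sp$values, 1L, prob = p))
      }
      row
    }
    is_reserved <- function(row)
      any(vapply(reserved, function(p) all(p == row), logical(1L)))
    rows <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      for (try in seq_len(1000L)) {
        row <- draw_row()
        if (!is_reserved(row)) break
        if (try == 1000L)
          stop("cannot draw a profile outside the reserved set; marginals ",
               "concentrate on reserved profiles")
      }
      rows[[i]] <- row
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- anames
    rownames(df) <- NULL

    # outcome: first matching planted rule, else background
    tmp <- df; tmp$.y <- spec$background
    base <- cohort_dataset(tmp, schema, outcome = ".y")
    rule_idx <- rep(NA_integer_, spec$n)
    outcome <- rep(spec$background, spec$n)
    for (i in rev(seq_along(planted))) {
      hit <- rule_covered(planted[[i]], base)
      outcome[hit] <- planted[[i]]$consequence
      rule_idx[hit] <- i
    }
    provenance <- rep("clean", spec$n)
    all_classes <- unique(c(vapply(planted, `[[`, character(1L), "consequence"),
                            spec$background))
    if (spec$noise > 0 && length(all_classes) > 1L) {
      flip <- stats::runif(spec$n) < spec$noise
      for (i in which(flip)) {
        outcome[i] <- sample(setdiff(all_classes, outcome[i]), 1L)
        provenance[i] <- "noisy"
      }
    }

    # overwrite trailing rows with ambiguous groups and singletons
    pos <- spec$n - n_overwrite
    for (g in spec$ambiguous) {
      row <- profile_row(g$profile)
      labels <- rep(names(g$split), times = as.integer(g$split))
      if (length(labels) != as.integer(g$size))
        stop("ambiguous group split does not add up to its size")
      for (j in seq_len(g$size)) {
        pos <- pos + 1L
        df[pos, ] <- as.list(row)
        outcome[pos] <- labels[j]
        provenance[pos] <- "ambiguous"
        rule_idx[pos] <- NA_integer_
      }
    }
    for (s in spec$singletons) {
      row <- profile_row(s$profile)
      pos <- pos + 1L
      df[pos, ] <- as.list(row)
      outcome[pos] <- as.character(s$class)
      provenance[pos] <- "singleton"
      rule_idx[pos] <- NA_integer_
    }

    df$Outcome <- outcome
    dataset <- cohort_dataset(df, schema, outcome = "Outcome")
    list(dataset = dataset,
         truth = data.frame(id = dataset$ids, provenance = provenance,
                            planted_rule = rule_idx, stringsAsFactors = FALSE))
  })
}

#' Default neuroblastoma-like cohort specification
#'
#' A four-risk-factor cohort shaped like a neuroblastoma training set: INSS
#' stage (1/2/3/4/4s at 23/13/13/38/13%), Age at diagnosis dichotomized at
#' one year (47% below), MYCN status (16% amplified) and a dichotomized
#' hypoxia signature (25% High). Age, MYCN and NBhypo are drawn conditionally
#' on stage so that the joint distribution is clinically coherent (4s is an
#' infant stage, stages 3-4 affect older children, amplification and high
#' hypoxia concentrate in advanced disease) and every rule-defining stratum
#' is well populated at the default cohort size; the marginals above are
#' preserved. Outcomes are planted by a four-rule final classifier (stage 4
#' older patients and high-hypoxia stage 2-4 older patients are poor
#' outcome; low-hypoxia MYCN-normal and non-stage-4 MYCN-normal patients are
#' good outcome). By default one ambiguous 24-instance group (low-hypoxia,
#' stage 4, MYCN normal, older than one year; 12 good / 12 poor) and one
#' unique poor-outcome singleton are planted as instability sources.
#'
#' @param n Cohort size (default 182).
#' @param ambiguous_size Size of the ambiguous group, split evenly
#'   (default 24; 0 disables it).
#' @param singletons Number of singleton injections, 0..2 (default 1).
#' @param noise Label-noise rate (default 0).
#' @return A [cohort_spec()].
#' @export
nb_cohort_spec <- function(n = 182L, ambiguous_size = 24L, singletons = 1L,
                           noise = 0) {
  stopifnot(ambiguous_size %% 2 == 0, singletons %in% 0:2)
  amb <- if (ambiguous_size > 0)
    list(list(profile = list(Age = ">=1", INSS = "4", MYCN = "normal",
                             NBhypo = "Low"),
              size = ambiguous_size,
              split = stats::setNames(rep(ambiguous_size / 2, 2L),
                                      c("Good", "Poor"))))
  else list()
  sing <- list(
    list(profile = list(Age = ">=1", INSS = "1", MYCN = "normal",
                        NBhypo = "Low"), class = "Poor"),
    list(profile = list(Age = ">=1", INSS = "4s", MYCN = "normal",
                        NBhypo = "Low"), class = "Poor"))[seq_len(singletons)]
  cohort_spec(
    n = n,
    attributes = list(
      INSS = list(values = c("1", "2", "3", "4", "4s"),
                  probs = c(0.23, 0.13, 0.13, 0.38, 0.13)),
      # stage 4s is an infant stage, stages 3-4 affect older children and
      # localized stage 1-2 disease skews young; rows solve to the 47%
      # marginal
      Age = list(values = c("<1", ">=1"), given = "INSS",
                 probs = rbind("1" = c(0.913, 0.087), "2" = c(1, 0),
                               "3" = c(0, 1), "4" = c(0, 1),
                               "4s" = c(1, 0))),
      # amplification concentrates in advanced (stage 4) disease; the rate
      # solves to the 16% marginal
      MYCN = list(values = c("normal", "amplified"), given = "INSS",
                  probs = rbind("1" = c(1, 0), "2" = c(1, 0),
                                "3" = c(1, 0), "4" = c(0.58, 0.42),
                                "4s" = c(1, 0))),
      # tumor hypoxia concentrates in invasive stages 3-4; rows solve to the
      # 25% marginal of the dichotomized signature
      NBhypo = list(values = c("Low", "High"), given = "INSS",
                    probs = rbind("1" = c(1, 0), "2" = c(1, 0),
                                  "3" = c(0.40, 0.60), "4" = c(0.55, 0.45),
                                  "4s" = c(1, 0)))),
    rules = c(
      "if INSS in {4} and Age in {>=1} then Outcome = Poor",
      "if NBhypo in {High} and INSS in {2, 3, 4} and Age in {>=1} then Outcome = Poor",
      "if NBhypo in {Low} and MYCN in {normal} then Outcome = Good",
      "if INSS in {1, 2, 3, 4s} and MYCN in {normal} then Outcome = Good"),
    background = "Good", noise = noise,
    ambiguous = amb, singletons = sing)
}

#' Specification of a synthetic two-group expression matrix
#'
#' @param samples Number of samples.
#' @param probes Number of probe sets (default 62, the size of a
#'   hypoxia-signature input).
#' @param group_sizes Length-2 integer vector of latent group sizes
#'   (must sum to `samples`).
#' @param shift Mean shift of group 2 on every probe (in noise SD units when
#'   `noise_sd = 1`).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @return A list of class `expression_spec`.
#' @export
expression_spec <- function(samples, probes = 62L, group_sizes = NULL,
                            shift = 3, noise_sd = 1) {
  if (is.null(group_sizes))
    group_sizes <- c(ceiling(samples * 0.75), floor(samples * 0.25))
  stopifnot(probes >= 2L, sum(group_sizes) == samples, all(group_sizes >= 1L))
  structure(list(samples = as.integer(samples), probes = as.integer(probes),
                 group_sizes = as.integer(group_sizes), shift = shift,
                 noise_sd = noise_sd),
            class = "expression_spec")
}

#' Generate a samples x probes expression matrix with two latent groups
#'
#' @param spec An [expression_spec()].
#' @param seed Integer seed.
#' @return List with `matrix` (samples x probes, dimnames `s1..`/`p1..`) and
#'   `groups` (integer vector of true group labels 1/2).
#' @export
generate_expression <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "expression_spec"))
  with_seed(seed, {
    groups <- rep(1:2, times = spec$group_sizes)
    mu <- ifelse(groups == 2L, spec$shift, 0)
    m <- matrix(stats::rnorm(spec$samples * spec$probes, sd = spec$noise_sd),
                nrow = spec$samples) + mu
    dimnames(m) <- list(paste0("s", seq_len(spec$samples)),
                        paste0("p", seq_len(spec$probes)))
    list(matrix = m, groups = groups)
  })
}

#' Dichotomize samples by Manhattan-distance k-means
#'
#' Lloyd-style k-means with Manhattan (L1) distance and component-wise median
#' centers, initialized deterministically with the first k rows (instance
#' order is preserved, so reruns are identical). Besides the labels at the
#' requested k, the sum of within-cluster distances is reported for every
#' candidate k in `k_range`; each candidate additionally warm-starts from the
#' previous solution (its centers plus the worst-fit row) and the lower-cost
#' fit is kept, which makes the curve monotone non-increasing in k.
#'
#' @param x Numeric matrix, samples in rows.
#' @param k Number of clusters for the returned labels (default 2).
#' @param iterations Maximum Lloyd iterations (default 500).
#' @param k_range Candidate k values for the within-cluster-distance curve
#'   (default `1:min(6, nrow(x))`).
#' @return List of class `kmeans_dichotomy`: `labels` (length-n integer),
#'   `centers`, `wcd` (sum of within-cluster Manhattan distances at `k`) and
#'   `curve` (data.frame k / wcd).
#' @export
kmeans_dichotomize <- function(x, k = 2L, iterations = 500L,
                               k_range = seq_len(min(6L, nrow(x)))) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of samples")
  if (any(k_range > n)) k_range <- k_range[k_range <= n]

  fit_from <- function(centers, kk) {
    labels <- integer(n)
    for (it in seq_len(iterations)) {
      d <- vapply(seq_len(kk), function(j)
        rowSums(abs(sweep(x, 2L, centers[j, ], `-`))), numeric(n))
      d <- matrix(d, nrow = n)
      new_labels <- max.col(-d, ties.method = "first")
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (j in seq_len(kk)) {
        idx <- which(labels == j)
        if (length(idx))
          centers[j, ] <- apply(x[idx, , drop = FALSE], 2L, stats::median)
      }
    }
    d <- vapply(seq_len(kk), function(j)
      rowSums(abs(sweep(x, 2L, centers[j, ], `-`))), numeric(n))
    d <- matrix(d, nrow = n)
    wcd <- sum(d[cbind(seq_len(n), labels)])
    list(labels = labels, centers = centers, wcd = wcd)
  }
  fit_k <- function(kk, prev = NULL) {
    f <- fit_from(x[seq_len(kk), , drop = FALSE], kk)
    if (!is.null(prev) && kk > 1L) {
      # warm start: previous centers plus the row worst served by them
      worst <- which.max(vapply(seq_len(n), function(i)
        min(rowSums(abs(sweep(prev$centers, 2L, x[i, ], `-`)))), numeric(1L)))
      f2 <- fit_from(rbind(prev$centers, x[worst, ]), kk)
      if (f2$wcd < f$wcd) f <- f2
    }
    f
  }

  curve <- data.frame(k = integer(0L), wcd = numeric(0L))
  prev <- NULL; chosen <- NULL
  for (kk in sort(unique(c(k_range, k)))) {
    f <- fit_k(kk, prev)
    if (kk %in% k_range)
      curve <- rbind(curve, data.frame(k = kk, wcd = f$wcd))
    if (kk == k) chosen <- f
    prev <- f
  }
  structure(list(labels = chosen$labels, centers = chosen$centers,
                 wcd = chosen$wcd, curve = curve),
            class = "kmeans_dichotomy")
}

#' @export
print.kmeans_dichotomy <- function(x, ...) {
  cat(sprintf("k-means dichotomy: k=%d, within-cluster distance %.4g\n",
              nrow(x$centers), x$wcd))
  invisible(x)
}
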