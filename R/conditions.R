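# Premise conditions. Ordered attributes use threshold forms with half-open
# intervals (lambda, mu]; nominal attributes use membership in a value set.

cond_greater  <- function(attribute, lambda)
  structure(list(attribute = attribute, form = "greater", lambda = as.numeric(lambda)),
            class = "rule_condition")
cond_at_most  <- function(attribute, mu)
  structure(list(attribute = attribute, form = "at_most", mu = as.numeric(mu)),
            class = "rule_condition")
cond_interval <- function(attribute, lambda, mu) {
  lambda <- as.numeric(lambda); mu <- as.numeric(mu)
  if (lambda >= mu) stop("interval condition requires lambda < mu")
  structure(list(attribute = attribute, form = "interval", lambda = lambda, mu = mu),
            class = "rule_condition")
}
cond_member   <- function(attribute, values) {
  values <- as.character(values)
  if (!length(values)) stop("membership condition needs a non-empty value set")
  structure(list(attribute = attribute, form = "member", values = unique(values)),
            class = "rule_condition")
}

# Interval view (lo, hi] of an ordered condition; NULL condition = whole axis.
cond_bounds <- function(cond) {
  if (is.null(cond)) return(c(-Inf, Inf))
  switch(cond$form,
    greater  = c(cond$lambda, Inf),
    at_most  = c(-Inf, cond$mu),
    interval = c(cond$lambda, cond$mu),
    stop("not an ordered condition"))
}

bounds_to_cond <- function(attribute, lo, hi) {
  if (lo >= hi) return(NA)                      # empty
  if (is.infinite(lo) && is.infinite(hi)) return(NULL)  # unconstrained
  if (is.infinite(lo)) return(cond_at_most(attribute, hi))
  if (is.infinite(hi)) return(cond_greater(attribute, lo))
  cond_interval(attribute, lo, hi)
}

# Vectorized satisfaction of a condition on a column of values.
cond_satisfied <- function(cond, values) {
  switch(cond$form,
    greater  = values > cond$lambda,
    at_most  = values <= cond$mu,
    interval = values > cond$lambda & values <= cond$mu,
    member   = values %in% cond$values,
    stop("unknown condition form"))
}

# Intersection of two conditions on the same attribute. Either may be NULL
# (no constraint). Returns NULL (unconstrained), a condition, or NA if the
# intersection is empty over the full axis / nominal domain.
cond_intersect <- function(a, b, attr_schema) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (attr_schema$kind == "nominal") {
    vals <- intersect(a$values, b$values)
    if (!length(vals)) return(NA)
    # keep domain order for canonical formatting
    return(cond_member(a$attribute, attr_schema$values[attr_schema$values %in% vals]))
  }
  ba <- cond_bounds(a); bb <- cond_bounds(b)
  bounds_to_cond(a$attribute, max(ba[1L], bb[1L]), min(ba[2L], bb[2L]))
}

# Is a (possibly NULL) condition satisfiable by some value of the attribute's
# declared domain?
cond_satisfiable <- function(cond, attr_schema) {
  if (is.null(cond)) return(TRUE)
  if (identical(cond, NA) || (length(cond) == 1L && is.na(cond[[1L]]))) return(FALSE)
  if (attr_schema$kind == "nominal")
    return(length(intersect(cond$values, attr_schema$values)) > 0L)
  b <- cond_bounds(cond)
  hi <- min(b[2L], attr_schema$bounds[2L])
  hi >= attr_schema$bounds[1L] && hi > b[1L]
}

format_condition <- function(cond) {
  switch(cond$form,
    greater  = sprintf("%s > %s", cond$attribute, format(cond$lambda)),
    at_most  = sprintf("%s <= %s", cond$attribute, format(cond$mu)),
    interval = sprintf("%s < %s <= %s", format(cond$lambda), cond$attribute,
                       format(cond$mu)),
    member   = sprintf("%s in {%s}", cond$attribute,
                       paste(cond$values, collapse = ", ")))
}

# Validate a condition against a schema; returns the condition or stops.
check_condition <- function(cond, schema) {
  if (!cond$attribute %in% schema_names(schema))
    stop("unknown attribute '", cond$attribute, "'")
  a <- schema[[cond$attribute]]
  if (cond$form == "member") {
    if (a$kind != "nominal")
      stop("membership condition on ordered attribute '", cond$attribute, "'")
    bad <- setdiff(cond$values, a$values)
    if (length(bad))
      stop("value '", bad[1L], "' is outside the domain of '", cond$attribute, "'")
  } else {
    if (a$kind != "ordered")
      stop("threshold condition on nominal attribute '", cond$attribute, "'")
  }
  cond
}
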