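# Shared fixtures and independent brute-force oracles.

# schema of the neuroblastoma-style risk factors (all categorical)
nb_schema <- function() {
  cohort_schema(attr_nominal("Age", c("<1", ">=1")),
                attr_nominal("INSS", c("1", "2", "3", "4", "4s")),
                attr_nominal("MYCN", c("normal", "amplified")),
                attr_nominal("NBhypo", c("Low", "High")))
}

# the four final-classifier rules as printed, in the rule grammar
table4_rules <- function() c(
  "4.1" = "if INSS in {4} and Age in {>=1} then Outcome = Poor",
  "4.2" = "if NBhypo in {High} and INSS in {2, 3, 4} and Age in {>=1} then Outcome = Poor",
  "4.3" = "if NBhypo in {Low} and MYCN in {normal} then Outcome = Good",
  "4.4" = "if INSS in {1, 2, 3, 4s} and MYCN in {normal} then Outcome = Good")

table4_classifier <- function() {
  sch <- nb_schema()
  txt <- table4_rules()
  rule_classifier(lapply(seq_along(txt), function(i)
    parse_rule(txt[i], sch, id = names(txt)[i])), sch)
}

# small mixed-schema fixture with one ordered attribute
toy_schema <- function() {
  cohort_schema(attr_ordered("x1", c(1, 100)),
                attr_nominal("x2", c("red", "green", "blue")))
}

toy_dataset <- function() {
  cohort_dataset(
    data.frame(x1 = c(10, 45, 60, 80, 20, 55, 95, 30),
               x2 = c("red", "blue", "red", "green", "blue",
                      "green", "red", "red"),
               y = c("0", "0", "1", "1", "0", "1", "1", "0")),
    toy_schema(), outcome = "y")
}

# random nominal dataset over a small grid
random_dataset <- function(n, n_attr = 3, n_vals = 3, n_classes = 2, seed = 1) {
  set.seed(seed)
  vals <- lapply(seq_len(n_attr), function(i) paste0("v", seq_len(n_vals)))
  sch <- cohort_schema(lapply(seq_len(n_attr), function(i)
    attr_nominal(paste0("a", i), vals[[i]])))
  df <- as.data.frame(lapply(vals, sample, size = n, replace = TRUE),
                      col.names = paste0("a", seq_len(n_attr)))
  df$y <- sample(paste0("c", seq_len(n_classes)), n, replace = TRUE)
  cohort_dataset(df, sch, outcome = "y")
}

# random rule over a nominal schema
random_rule <- function(schema, consequence, p_attr = 0.7) {
  conds <- list()
  for (a in schema) {
    if (stats::runif(1) > p_attr) next
    k <- sample(seq_len(length(a$values) - 1L), 1L)
    conds[[length(conds) + 1L]] <-
      parse_rule(sprintf("if %s in {%s} then y = %s", a$name,
                         paste(sample(a$values, k), collapse = ", "),
                         consequence), schema)$premise[[1L]]
  }
  rule(conds, consequence, schema)
}

# oracle: per-instance condition evaluation, no vectorization shortcuts
oracle_confusion <- function(rule, dataset) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(dataset$data))) {
    sat <- TRUE
    for (cond in rule$premise) {
      v <- dataset$data[[cond$attribute]][i]
      ok <- switch(cond$form,
                   greater = v > cond$lambda,
                   at_most = v <= cond$mu,
                   interval = v > cond$lambda && v <= cond$mu,
                   member = v %in% cond$values)
      if (!ok) { sat <- FALSE; break }
    }
    is_target <- dataset$outcome[i] == rule$consequence
    if (sat && is_target) tp <- tp + 1L
    else if (sat) fp <- fp + 1L
    else if (is_target) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# oracle: full-grid enumeration of conflicting pairs over a nominal schema
oracle_conflicts <- function(classifier) {
  sch <- classifier$schema
  grid <- expand.grid(lapply(sch, `[[`, "values"),
                      stringsAsFactors = FALSE)
  names(grid) <- schema_names(sch)
  sat <- function(r, row) all(vapply(r$premise, function(cond)
    row[[cond$attribute]] %in% cond$values, logical(1L)))
  found <- character(0L)
  rules <- classifier$rules
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, , drop = FALSE]
    hits <- which(vapply(rules, sat, logical(1L), row = row))
    if (length(hits) >= 2L) {
      for (a in hits) for (b in hits) {
        if (a < b && rules[[a]]$consequence != rules[[b]]$consequence)
          found <- c(found, paste(rules[[a]]$id, rules[[b]]$id))
      }
    }
  }
  sort(unique(found))
}

# oracle: one-sided Fisher p by enumerating all tables with the fixed margins
oracle_fisher_greater <- function(tp, fp, fn, tn) {
  m1 <- tp + fn  # target-class total
  m2 <- fp + tn
  k <- tp + fp   # premise-satisfying total
  lo <- max(0L, k - m2); hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x)
    choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k), numeric(1L))
  sum(probs[(lo:hi) >= tp])
}
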