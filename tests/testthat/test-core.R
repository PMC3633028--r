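test_that("parse_rule handles the documented grammar and round-trips", {
  sch <- toy_schema()
  r <- parse_rule("if x1 > 40 and x2 in {red, blue} then y = 0", sch)
  expect_equal(r$consequence, "0")
  expect_equal(names(r$premise), c("x1", "x2"))
  expect_equal(r$premise$x1$form, "greater")
  expect_equal(r$premise$x1$lambda, 40)
  expect_setequal(r$premise$x2$values, c("red", "blue"))

  # interval and at_most forms
  r2 <- parse_rule("if 10 < x1 <= 50 then y = 1", sch)
  expect_equal(r2$premise$x1$form, "interval")
  expect_equal(c(r2$premise$x1$lambda, r2$premise$x1$mu), c(10, 50))
  r3 <- parse_rule("if x1 <= 30 then y = 1", sch)
  expect_equal(r3$premise$x1$form, "at_most")

  # empty premise: the always-true rule
  r4 <- parse_rule("if then y = Good", sch)
  expect_length(r4$premise, 0L)
  expect_true(all(rule_covered(r4, toy_dataset())))

  # semantic round-trip through the formatter on every fixture rule
  ds <- toy_dataset()
  for (txt in c("if x1 > 40 and x2 in {red, blue} then y = 0",
                "if 10 < x1 <= 50 then y = 1",
                "if x2 in {green} then y = 0",
                "if then y = 1")) {
    orig <- parse_rule(txt, sch)
    back <- parse_rule(format_rule(orig), sch)
    expect_equal(rule_covered(back, ds), rule_covered(orig, ds), info = txt)
  }
})

test_that("parse_rule normalizes duplicate conditions by intersection", {
  sch <- toy_schema()
  r <- parse_rule("if x1 > 10 and x1 <= 50 and x2 in {red, blue} and x2 in {blue, green} then y = 0",
                  sch)
  expect_equal(r$premise$x1$form, "interval")
  expect_equal(c(r$premise$x1$lambda, r$premise$x1$mu), c(10, 50))
  expect_equal(r$premise$x2$values, "blue")
  # contradictory conditions are rejected
  expect_error(parse_rule("if x2 in {red} and x2 in {green} then y = 0", sch),
               "contradictory")
})

test_that("parse_rule reports schema and syntax errors", {
  sch <- toy_schema()
  expect_error(parse_rule("if x9 > 1 then y = 0", sch), "unknown attribute")
  expect_error(parse_rule("if x2 in {purple} then y = 0", sch),
               "outside the domain")
  expect_error(parse_rule("if x1 >> 40 then y = 0", sch), "parse error")
  expect_error(parse_rule("x1 > 40 then y = 0", sch), "parse error")
  expect_error(parse_rule("if x2 > 3 then y = 0", sch),
               "threshold condition on nominal")
})

test_that("parse_rule accepts the printed risk-factor rule shapes", {
  sch <- nb_schema()
  r <- parse_rule(
    "if NBhypo in {High} and INSS in {2, 3, 4} and Age in {>=1} then Outcome = Poor",
    sch)
  expect_equal(r$consequence, "Poor")
  expect_length(r$premise, 3L)
  expect_setequal(r$premise$INSS$values, c("2", "3", "4"))
})

test_that("confusion counts match a per-instance oracle and sum to n", {
  ds <- toy_dataset()
  sch <- toy_schema()
  # unsatisfiable premise covers nothing
  r0 <- parse_rule("if x1 > 99 and x2 in {blue} then y = 1", sch)
  expect_equal(confusion_counts(r0, ds),
               list(TP = 0L, FP = 0L, FN = 4L, TN = 4L))
  # always-true rule covers everything
  r1 <- parse_rule("if then y = 1", sch)
  expect_equal(confusion_counts(r1, ds),
               list(TP = 4L, FP = 4L, FN = 0L, TN = 0L))
  # randomized rules against the brute-force oracle
  for (s in 1:25) {
    set.seed(s)
    dsr <- random_dataset(50, seed = s)
    r <- random_rule(dsr$schema, sample(c("c1", "c2"), 1L))
    got <- confusion_counts(r, dsr)
    want <- oracle_confusion(r, dsr)
    expect_equal(got, want, info = paste("seed", s))
    expect_equal(with(got, TP + FP + FN + TN), 50L)
  }
})

test_that("rule statistics follow the printed formulas and flag zero denominators", {
  s <- rule_stats(list(TP = 3, FN = 1, FP = 0, TN = 4))
  expect_equal(s$C, 0.75)
  expect_equal(s$E, 0)
  expect_equal(s$P, 1)
  expect_length(s$undefined, 0L)

  s0 <- rule_stats(list(TP = 0, FN = 0, FP = 0, TN = 5))
  expect_equal(s0$C, 0)
  expect_equal(s0$E, 0)
  expect_setequal(s0$undefined, c("C", "P"))

  set.seed(42)
  for (i in 1:200) {
    ct <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("TP", "FP", "FN", "TN")))
    s <- rule_stats(ct)
    # direct recomputation from the three formulas
    if (ct$TP + ct$FN > 0) expect_equal(s$C, ct$TP / (ct$TP + ct$FN))
    if (ct$TN + ct$FP > 0) expect_equal(s$E, ct$FP / (ct$TN + ct$FP))
    if (ct$TP + ct$FP > 0) expect_equal(s$P, ct$TP / (ct$TP + ct$FP))
    expect_true(all(c(s$C, s$E, s$P) >= 0 & c(s$C, s$E, s$P) <= 1))
    expect_identical(s$P == 1 && !"P" %in% s$undefined,
                     ct$FP == 0 && ct$TP > 0)
  }
})

test_that("classify follows the highest-covering policy", {
  sch <- cohort_schema(attr_nominal("A", c("a", "b", "c", "d")))
  ds <- cohort_dataset(
    data.frame(A = c("a", "a", "a", "b", "c", "c", "c", "c", "d", "d"),
               y = c("Poor", "Poor", "Poor", "Good", "Good",
                     "Good", "Good", "Good", "Good", "Good")),
    sch, outcome = "y")
  rp <- parse_rule("if A in {a, b} then y = Poor", sch, id = "rp")  # C = 1
  rg <- parse_rule("if A in {b, c} then y = Good", sch, id = "rg")  # C = 5/7
  clf <- rule_classifier(list(rg, rp), sch, calibrate = ds)
  expect_equal(classify(clf, list(A = "a")), "Poor")   # single match
  expect_equal(classify(clf, list(A = "b")), "Poor")   # higher covering wins
  expect_equal(classify(clf, list(A = "c")), "Good")
  # no match and empty classifier give NC
  clf2 <- rule_classifier(list(rp), sch, calibrate = ds)
  expect_equal(classify(clf2, list(A = "c")), "NC")
  expect_equal(classify(rule_classifier(list(), sch), list(A = "a")), "NC")
  # vectorized predictions agree with classify, and never invent labels
  preds <- predict(clf, ds)
  expect_equal(preds, vapply(seq_len(10), function(i)
    classify(clf, as.list(ds$data[i, , drop = FALSE])), character(1L)))
  expect_true(all(preds %in% c("Good", "Poor", "NC")))
})

test_that("conflict_pairs recovers the printed conflicting pairs and NC rules", {
  clf <- table4_classifier()
  cp <- conflict_pairs(clf)
  expect_equal(nrow(cp$pairs), 2L)
  expect_setequal(paste(cp$pairs$rule_h, cp$pairs$rule_k),
                  c("4.1 4.3", "4.2 4.4"))
  nc <- vapply(cp$nc_rules, format_rule, character(1L))
  expect_setequal(nc, c(
    "if Age in {>=1} and INSS in {4} and MYCN in {normal} and NBhypo in {Low} then y = NC",
    "if Age in {>=1} and INSS in {2, 3} and MYCN in {normal} and NBhypo in {High} then y = NC"))
  expect_true(all(vapply(cp$nc_rules, `[[`, character(1L), "consequence") == "NC"))
})

test_that("conflict detection agrees with full-grid enumeration", {
  # disjoint member sets on one attribute: no conflict
  sch <- cohort_schema(attr_nominal("A", c("a", "b", "c")))
  clf <- rule_classifier(list(parse_rule("if A in {a} then y = 0", sch, "r1"),
                              parse_rule("if A in {b} then y = 1", sch, "r2")),
                         sch)
  expect_equal(nrow(conflict_pairs(clf)$pairs), 0L)
  # randomized rule sets over a 3-attribute nominal domain
  for (s in 1:20) {
    set.seed(s)
    sch <- random_dataset(5, seed = s)$schema
    rules <- lapply(1:4, function(i) {
      r <- random_rule(sch, sample(c("0", "1"), 1L), p_attr = 0.6)
      r$id <- paste0("r", i)
      r
    })
    clf <- rule_classifier(rules, sch)
    got <- conflict_pairs(clf)$pairs
    expect_setequal(paste(got$rule_h, got$rule_k), oracle_conflicts(clf))
  }
})

test_that("conflict analysis handles ordered attributes by interval overlap", {
  sch <- toy_schema()
  clf <- rule_classifier(list(
    parse_rule("if x1 > 40 then y = 0", sch, "hi"),
    parse_rule("if x1 <= 60 then y = 1", sch, "lo"),
    parse_rule("if x1 <= 30 then y = 1", sch, "lo2")), sch)
  cp <- conflict_pairs(clf)
  # (40, 60] overlaps; (40, ...] vs (..., 30] does not
  expect_equal(paste(cp$pairs$rule_h, cp$pairs$rule_k), "hi lo")
  expect_equal(format_rule(cp$nc_rules[[1]]), "if 40 < x1 <= 60 then y = NC")
})

test_that("cohort_dataset validates values, ids and the reserved NC label", {
  sch <- cohort_schema(attr_nominal("INSS", c("1", "2", "3", "4", "4s")))
  expect_error(cohort_dataset(data.frame(INSS = "5", y = "Good"), sch, "y"),
               "outside the domain")
  expect_error(cohort_dataset(data.frame(INSS = NA, y = "Good"), sch, "y"),
               "missing value")
  expect_error(cohort_dataset(data.frame(INSS = "1", y = "NC"), sch, "y"),
               "reserved")
  ds <- cohort_dataset(data.frame(INSS = c("1", "4s"), y = c("G", "P")),
                       sch, "y")
  expect_equal(ds$classes, c("G", "P"))
})
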