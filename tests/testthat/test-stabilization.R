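test_that("diagnose_instability flags a planted ambiguous duplicate-profile group", {
  # 24 copies of one profile split 12/12 between the classes, mirroring the
  # low-hypoxia stage-4 MYCN-normal older-patient group
  g <- generate_cohort(nb_cohort_spec(singletons = 0), seed = 61)
  amb_ids <- g$truth$id[g$truth$provenance == "ambiguous"]
  expect_length(amb_ids, 24L)
  cvs <- run_cv(g$dataset, cv_config(repetitions = 1, folds = 5, seed = 61))
  core <- build_core_rules(cvs, g$dataset)
  diag <- diagnose_instability(g$dataset, core)
  flagged_amb <- diag$id[diag$cause == "ambiguous_profile"]
  expect_setequal(flagged_amb, amb_ids)
})

test_that("an empty diagnosis comes back for a clean stable cohort", {
  g <- generate_cohort(nb_cohort_spec(ambiguous_size = 0, singletons = 0),
                       seed = 62)
  cvs <- run_cv(g$dataset, cv_config(seed = 62))
  core <- build_core_rules(cvs, g$dataset)
  diag <- diagnose_instability(g$dataset, core)
  expect_equal(nrow(diag), 0L)
})

test_that("near-duplicate rules flag exactly the instances in the set difference", {
  # hand-built core set: two same-consequence rules differing by one instance
  sch <- cohort_schema(attr_nominal("A", paste0("v", 1:6)))
  ds <- cohort_dataset(
    data.frame(A = paste0("v", c(1, 2, 3, 4, 5, 6, 6)),
               y = c(rep("X", 5), "Y", "Y")),
    sch, outcome = "y")
  big <- parse_rule("if A in {v1, v2, v3, v4} then y = X", sch, "big")
  bigger <- parse_rule("if A in {v1, v2, v3, v4, v5} then y = X", sch, "bigger")
  fake_core <- structure(
    list(rules = list(calibrate_rule(big, ds), calibrate_rule(bigger, ds)),
         stability = c(1, 0.5), origins = list(1:2, 1:2), n_classifiers = 2L),
    class = "core_rule_set")
  diag <- diagnose_instability(ds, fake_core)
  nd <- diag[diag$cause == "near_duplicate_rule", ]
  expect_equal(nd$id, ds$ids[ds$data$A == "v5"])
  # pairs that never co-occur in a classifier are not eligible
  fake_core$origins <- list(1L, 2L)
  expect_equal(nrow(diagnose_instability(ds, fake_core)), 0L)
})

test_that("low-covering unstable rules flag their exclusively covered instances", {
  sch <- cohort_schema(attr_nominal("A", paste0("v", 1:6)))
  ds <- cohort_dataset(
    data.frame(A = paste0("v", c(1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 3, 3)),
               y = c(rep("X", 10), "X", "Y")),
    sch, outcome = "y")
  stable_rule <- parse_rule("if A in {v1, v2} then y = X", sch, "s")
  lowcov <- parse_rule("if A in {v3} then y = X", sch, "l")  # C = 1/11
  fake_core <- structure(
    list(rules = list(calibrate_rule(stable_rule, ds),
                      calibrate_rule(lowcov, ds)),
         stability = c(1, 0.6), origins = list(1:2, 1L), n_classifiers = 2L),
    class = "core_rule_set")
  diag <- diagnose_instability(ds, fake_core)
  lc <- diag[diag$cause == "low_covering_unstable", ]
  # v3 instances are covered by the offending rule and by no stable rule
  expect_setequal(lc$id, ds$ids[ds$data$A == "v3"])
})

test_that("stabilize recovers exactly the planted noise and reaches full stability", {
  g <- generate_cohort(nb_cohort_spec(), seed = 71)
  planted <- g$truth$id[g$truth$provenance != "clean"]
  res <- stabilize(g$dataset, stabilization_config(cv = cv_config(seed = 71)))
  expect_true(res$converged)
  expect_setequal(unique(res$removed$id), planted)
  # final dataset = original minus the removed union; removed-instance sets
  # are disjoint across iterations (one id never removed twice)
  expect_equal(sort(res$dataset$ids),
               sort(setdiff(g$dataset$ids, res$removed$id)))
  iters_per_id <- tapply(res$removed$iteration, res$removed$id,
                         function(x) length(unique(x)))
  expect_true(all(iters_per_id == 1L))
  # every final rule at stability 1 (recorded in the last iteration log)
  final <- res$iterations[[length(res$iterations)]]$stability
  expect_true(all(final$stability == 1))
})

test_that("an already-stable cohort converges at iteration 1 with zero removals", {
  g <- generate_cohort(nb_cohort_spec(ambiguous_size = 0, singletons = 0),
                       seed = 72)
  res <- stabilize(g$dataset, stabilization_config(cv = cv_config(seed = 72)))
  expect_true(res$converged)
  expect_length(res$iterations, 1L)
  expect_equal(nrow(res$removed), 0L)
})

test_that("restabilizing the returned dataset is an identity (idempotence)", {
  g <- generate_cohort(nb_cohort_spec(), seed = 73)
  res <- stabilize(g$dataset, stabilization_config(cv = cv_config(seed = 73)))
  res2 <- stabilize(res$dataset, stabilization_config(cv = cv_config(seed = 173)))
  expect_length(res2$iterations, 1L)
  expect_equal(nrow(res2$removed), 0L)
  expect_setequal(vapply(res2$classifier$rules, format_rule, character(1L)),
                  vapply(res$classifier$rules, format_rule, character(1L)))
})

test_that("no remaining instance falls under a conflict witness premise", {
  g <- generate_cohort(nb_cohort_spec(), seed = 74)
  res <- stabilize(g$dataset, stabilization_config(cv = cv_config(seed = 74)))
  cp <- conflict_pairs(res$classifier)
  for (nc in cp$nc_rules)
    expect_false(any(rule_covered(nc, res$dataset)), info = format_rule(nc))
})

test_that("stabilize raises with its log when the iteration cap is exhausted", {
  g <- generate_cohort(nb_cohort_spec(), seed = 75)
  err <- tryCatch(
    stabilize(g$dataset, stabilization_config(max_iterations = 1L,
                                              cv = cv_config(seed = 75))),
    error = function(e) e)
  expect_s3_class(err, "stabilization_error")
  expect_match(conditionMessage(err), "within 1 iterations")
  expect_true(length(err$log) >= 1L)
})

test_that("purge_matched removes exactly the profile-matched test instances", {
  sch <- cohort_schema(attr_nominal("A", c("a", "b")),
                       attr_nominal("B", c("u", "v")))
  test <- cohort_dataset(
    data.frame(A = c("a", "a", "b", "b"), B = c("u", "v", "u", "v"),
               y = c("G", "G", "P", "P")),
    sch, outcome = "y")
  # no shared profile: unchanged
  none <- purge_matched(test, data.frame(A = character(0), B = character(0)))
  expect_equal(none$n_removed, 0L)
  expect_equal(none$dataset$ids, test$ids)
  # full match: emptied
  all_gone <- purge_matched(test, test$data)
  expect_equal(all_gone$n_removed, 4L)
  expect_equal(nrow(all_gone$dataset$data), 0L)
  # random removed sets vs a brute-force pairwise comparison
  for (s in 1:10) {
    set.seed(s)
    ds <- random_dataset(30, seed = s + 900)
    rem <- random_dataset(8, seed = s + 950)$data
    got <- purge_matched(ds, rem, schema = ds$schema)
    want <- vapply(seq_len(30), function(i)
      any(vapply(seq_len(8), function(j)
        all(ds$data[i, ] == rem[j, ]), logical(1L))), logical(1L))
    expect_setequal(got$removed_ids, ds$ids[want])
  }
})

test_that("profiles removed in training purge matched held-out instances", {
  g_train <- generate_cohort(nb_cohort_spec(), seed = 76)
  res <- stabilize(g_train$dataset, stabilization_config(cv = cv_config(seed = 76)))
  g_test <- generate_cohort(nb_cohort_spec(n = 51), seed = 77)
  removed_rows <- subset_instances(g_train$dataset, unique(res$removed$id))
  purged <- purge_matched(g_test$dataset, removed_rows)
  # the test cohort's own ambiguous-profile group shares the removed profile
  amb_test <- g_test$truth$id[g_test$truth$provenance == "ambiguous"]
  expect_true(all(amb_test %in% purged$removed_ids))
  # purged instances all match some removed profile
  expect_true(all(purged$removed_ids %in% g_test$dataset$ids))
  perf <- performance_metrics(calibrate_classifier(res$classifier, res$dataset),
                              purged$dataset, positive = "Good")
  expect_gte(perf$accuracy, 0.9)
})
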