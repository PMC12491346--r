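test_that("the 83-lesion fixture carries the reconstructed margins exactly", {
  d <- study_fixture("model1")
  expect_equal(nrow(d), 83L)
  expect_equal(sum(d$n_scans), 92L)
  rc <- d$rating_combined; rr <- d$rating_reference; cf <- d$confirmed
  expect_equal(sum(rc == "relapse"), 54L)
  expect_equal(sum(rc == "relapse" & cf == "relapse"), 54L)  # all confirmed
  expect_equal(sum(rc == "trc" & cf == "trc"), 21L)
  expect_equal(sum(rr == "relapse"), 68L)
  expect_equal(sum(rr == "relapse" & cf == "relapse"), 57L)
  expect_equal(sum(rr == "trc" & cf == "trc"), 10L)
  # single ground-truth column: confirmed totals agree across strategies
  expect_equal(sum(cf == "trc"), 21L)
  expect_equal(sum(cf == "relapse"), 62L)
})

test_that("the 22-lesion fixture gives effectiveness exactly 9/10", {
  d <- study_fixture("model2")
  expect_equal(nrow(d), 22L)
  expect_true(all(d$n_scans == 1L))
  expect_equal(sum(d$rating_combined == "relapse"), 10L)
  fit <- cea_model(d, model_id = "model2")
  expect_equal(fit$effectiveness$eff_by_strategy[["pet"]], 9/10)
})

test_that("brute-force search confirms the integer reconstruction is unique and matches the fixture", {
  hits <- reconstruct_model1_tables()
  expect_length(hits, 1L)
  expect_equal(hits[[1]],
               c(a = 54, x = 54, y = 21, c = 68, z = 57, w = 10))
})

test_that("generated cohorts honour degenerate and marginal specifications", {
  truth <- node_probs("model2", c(N1 = 1, N2 = 0.8, N3 = 0.5))
  d <- generate_cohort(cohort_spec(500, truth, seed = 5L))
  expect_true(all(d$rating_combined == "relapse"))

  dist <- list(values = c(1L, 2L), prob = c(0.8, 0.2))
  d2 <- generate_cohort(cohort_spec(1000,
    node_probs("model2", c(N1 = 0.5, N2 = 0.9, N3 = 0.75)),
    scans_per_lesion = dist, seed = 9L))
  expect_true(all(d2$n_scans %in% c(1L, 2L)))
  expect_gt(sum(d2$n_scans), 1000L)
})

test_that("an inconsistent model-1 joint specification errors with both implied prevalences", {
  # combined nodes imply a different confirmed-TRC prevalence than reference
  bad <- node_probs("model1", c(N1 = 0.5, N2 = 0.5, N3 = 1, N4 = 0.5,
                                N5 = 0.5, N6 = 0.5))
  expect_error(generate_cohort(cohort_spec(10, bad, seed = 1L)),
               "inconsistent joint specification")
})

test_that("parameter recovery holds across random generating probabilities", {
  set.seed(31)
  ok <- 0L
  reps <- 5L
  for (r in seq_len(reps)) {
    p <- runif(3, 0.1, 0.9)
    truth <- node_probs("model2", c(N1 = p[1], N2 = p[2], N3 = p[3]))
    n <- 100000L
    d <- generate_cohort(cohort_spec(n, truth, seed = 1000L + r))
    est <- estimate_nodes(d, "model2")
    n_cond <- c(N1 = n, N2 = sum(d$rating_combined == "relapse"),
                N3 = sum(d$rating_combined == "trc"))
    within <- all(vapply(names(truth$values), function(id) {
      se <- sqrt(truth$values[[id]] * (1 - truth$values[[id]]) / n_cond[[id]])
      abs(est$values[[id]] - truth$values[[id]]) < 3 * se
    }, logical(1)))
    ok <- ok + within
  }
  expect_gte(ok, reps - 1L)  # 3-SE misses are rare but possible
})

test_that("lesion CSV round-trips through write and read", {
  d <- study_fixture("model1")
  path <- tempfile(fileext = ".csv")
  write_lesion_csv(d, path)
  back <- read_lesion_csv(path)
  expect_equal(back$rating_combined, d$rating_combined)
  expect_equal(back$confirmed, d$confirmed)
  expect_equal(back$n_scans, d$n_scans)
  # absent reference ratings survive as NA
  path2 <- tempfile(fileext = ".csv")
  write_lesion_csv(study_fixture("model2"), path2)
  expect_true(all(is.na(read_lesion_csv(path2)$rating_reference)))
})
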