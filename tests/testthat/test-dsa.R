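base_fit <- function(model_id) {
  cfg <- read_model_config(example_config(model_id))
  cea_model(cfg$nodes, costs = cfg$costs)
}

test_that("varying N1 or N4 leaves the model-1 ICER exactly at base (perfect relapse confirmation)", {
  fit <- base_fit("model1")
  for (spec in list(list("N1", 0.50, 0.80), list("N4", 0.65, 0.80))) {
    row <- one_way(fit, spec[[1]], spec[[2]], spec[[3]])
    expect_identical(row$eff_low, fit$effectiveness$incremental)
    expect_identical(row$eff_high, fit$effectiveness$incremental)
    expect_identical(row$ratio_low, fit$ratio)
    expect_identical(row$ratio_high, fit$ratio)
    expect_equal(row$width, 0)
  }
})

test_that("a zero-width interval at the base value reproduces the base case", {
  fit <- base_fit("model2")
  base_val <- fit$nodes$values[["N2"]]
  row <- one_way(fit, "N2", base_val, base_val)
  expect_equal(row$eff_low, fit$effectiveness$eff_by_strategy[["pet"]])
  expect_equal(row$ratio_low, fit$ratio)
  expect_equal(row$ratio_high, fit$ratio)
})

test_that("model-2 N3 endpoints match direct substitution into the effectiveness formula", {
  fit <- base_fit("model2")
  row <- one_way(fit, "N3", 0.68, 0.83)
  expect_equal(row$eff_low, trc_identification_rate(10/22, 9/10, 0.68))
  expect_equal(row$eff_high, trc_identification_rate(10/22, 9/10, 0.83))
  expect_equal(round(100 * row$eff_low), 89)
  expect_equal(round(100 * row$eff_high), 91)
})

test_that("one-way endpoint evaluation shares the code path of the base evaluation", {
  fit <- base_fit("model1")
  row <- one_way(fit, "N5", 0.7632352941, 0.9132352941)
  v <- fit$nodes$values; v[["N5"]] <- 0.7632352941
  direct <- cea_model(node_probs("model1", v), costs = fit$costs)
  expect_equal(row$eff_low, direct$effectiveness$incremental)
  expect_equal(row$ratio_low, direct$ratio)
})

test_that("model-2 effectiveness is monotone in each node; CER moves oppositely", {
  fit <- base_fit("model2")
  grid <- seq(0.05, 0.95, by = 0.15)
  eff_at <- function(id, val) {
    v <- fit$nodes$values; v[[id]] <- val
    evaluate_model(node_probs("model2", v))$eff_by_strategy[["pet"]]
  }
  e_n1 <- vapply(grid, function(g) eff_at("N1", g), numeric(1))
  expect_true(all(diff(e_n1) < 0))          # decreasing in rated-relapse rate
  e_n2 <- vapply(grid, function(g) eff_at("N2", g), numeric(1))
  expect_true(all(diff(e_n2) > 0))
  e_n3 <- vapply(grid, function(g) eff_at("N3", g), numeric(1))
  expect_true(all(diff(e_n3) > 0))
  expect_true(all(diff(cer(1566.33, e_n3)) < 0))  # CER opposite
})

test_that("tornado tables order by descending ratio range with the widest bar as published", {
  fit1 <- base_fit("model1")
  cfg1 <- read_model_config(example_config("model1"))
  tab1 <- tornado_table(fit1, cfg1$dsa)
  expect_equal(tab1$node_id[1], "N2")
  expect_true(all(diff(tab1$width) <= 1e-9))
  # published ICER range across the whole table
  rng <- range(c(tab1$ratio_low, tab1$ratio_high))
  expect_equal(rng[1], 1962.97, tolerance = 0.025)
  expect_equal(rng[2], 5271.88, tolerance = 0.025)
  # N3 rows above 100% are flagged theoretical, never clamped
  n3 <- tab1[tab1$node_id == "N3", ]
  expect_true(n3$theoretical)
  expect_gt(n3$high, 1)

  fit2 <- base_fit("model2")
  cfg2 <- read_model_config(example_config("model2"))
  tab2 <- tornado_table(fit2, cfg2$dsa)
  # by CER range the N2 bar edges out N1 (261 vs 228 EUR); N1 has the widest
  # effectiveness range but ordering uses the ratio width
  expect_equal(tab2$node_id[1], "N2")
  expect_true(all(diff(tab2$width) <= 1e-9))
  rng2 <- range(c(tab2$ratio_low, tab2$ratio_high))
  expect_equal(rng2[1], 1609.84, tolerance = 0.01)
  expect_equal(rng2[2], 1885.60, tolerance = 0.01)
})

test_that("duplicate interval nodes and unknown nodes are errors; ties break by node id", {
  fit <- base_fit("model1")
  dup <- data.frame(node_id = c("N1", "N1"), low = c(0.5, 0.5),
                    high = c(0.8, 0.8))
  expect_error(tornado_table(fit, dup), "duplicate")
  expect_error(one_way(fit, "N9", 0.1, 0.2), "N9")
  # N1 and N4 both have zero width; N1 sorts first
  both <- data.frame(node_id = c("N4", "N1"), low = c(0.65, 0.50),
                     high = c(0.80, 0.80))
  tab <- tornado_table(fit, both)
  expect_equal(tab$node_id, c("N1", "N4"))
})

test_that("an endpoint with undefined effectiveness carries an explicit marker, not NaN", {
  fit <- base_fit("model2")
  # N1 at 1 with N2 = 1 would zero the confirmed-TRC mass; here N1 -> 1 and
  # N3 -> 0 via a crafted model: use a model whose other nodes make the
  # denominator vanish at the endpoint
  v <- c(N1 = 0.5, N2 = 1, N3 = 0.5)
  crafted <- cea_model(node_probs("model2", v),
                       costs = fit$costs)
  row <- one_way(crafted, "N3", 1e-15, 0.5)
  expect_true(row$undefined)
  expect_true(is.na(row$ratio_low))
  expect_false(is.nan(row$eff_low))
})
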