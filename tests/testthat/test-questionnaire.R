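test_that("pearson_r_with_p handles identities, reflection and degenerate input", {
  x <- c(1, 2, 3, 4, 5, 3, 2, 4)
  expect_equal(pearson_r_with_p(x, x)$r, 1)
  expect_equal(pearson_r_with_p(x, x)$p, 0)
  expect_equal(pearson_r_with_p(x, -x)$r, -1)
  expect_warning(res <- pearson_r_with_p(x, rep(2, 8)), "zero variance")
  expect_true(is.na(res$r))
  expect_error(pearson_r_with_p(1:2, 1:2), "at least 3")
  expect_error(pearson_r_with_p(c(1, 2, NA), 1:3), "finite")
})

test_that("p-values calibrate under independence (Monte-Carlo)", {
  set.seed(2024)
  hits <- vapply(1:1000, function(i) {
    pearson_r_with_p(rnorm(42), rnorm(42))$p < 0.05
  }, TRUE)
  expect_true(abs(mean(hits) - 0.05) <= 0.02)
})

test_that("sample r stays near a programmed correlation (Fisher-z band)", {
  rho <- 0.7
  z_band <- atanh(rho) + c(-1, 1) * 1.96 / sqrt(42 - 3)
  set.seed(77)
  inside <- vapply(1:200, function(i) {
    x <- rnorm(42)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(42)
    r <- pearson_r_with_p(x, y)$r
    atanh(r) >= z_band[1] && atanh(r) <= z_band[2]
  }, TRUE)
  expect_gte(mean(inside), 0.9)
})

test_that("correlation matrix is symmetric with unit diagonal and flags", {
  p <- make_profiles(11, 10, seed = 3)
  q <- synthesize_questionnaire(p, effect_spec(), seed = 5)
  cm <- correlation_matrix(q)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(diag(cm$r) == 1))
  expect_true(all(diag(cm$p) == 0))
  expect_true(all(abs(cm$r) <= 1, na.rm = TRUE))
  # reverse-coded copy correlates at exactly -1
  rev_rows <- as.data.frame(q)[q$item == "will_use_future", ]
  rev_rows$item <- "reverse"
  rev_rows$response <- 6 - rev_rows$response
  q2 <- likert_table(rbind(as.data.frame(q), rev_rows))
  cm2 <- correlation_matrix(q2)
  expect_equal(cm2$r["will_use_future", "reverse"], -1)
})

test_that("merge validation screens by positive correlation at alpha", {
  p <- make_profiles(11, 10, seed = 3)
  q <- synthesize_questionnaire(p, effect_spec(), seed = 5)
  cm <- correlation_matrix(q)
  spec_w <- default_composites()[[1]]
  v <- validate_merge(cm, spec_w, alpha = 0.001)
  expect_true(v$approved)
  expect_true(all(v$report$r > 0))
  # an independent-noise item breaks the merge, offending pairs listed
  set.seed(4)
  junk <- as.data.frame(q)[q$item == "will_use_future", ]
  junk$item <- "junk"
  junk$response <- sample(1:5, nrow(junk), replace = TRUE)
  q3 <- likert_table(rbind(as.data.frame(q), junk))
  cm3 <- correlation_matrix(q3)
  v3 <- validate_merge(cm3, composite_spec("w+", c(spec_w$items, "junk")))
  expect_false(v3$approved)
  expect_true(any(grepl("junk", paste(v3$report$item_a, v3$report$item_b))
                  & !v3$report$ok))
  # alpha = 0 rejects everything; approval is monotone in alpha
  expect_false(validate_merge(cm, spec_w, alpha = 0)$approved)
  alphas <- c(1e-6, 1e-4, 1e-2, 0.1)
  approvals <- vapply(alphas, function(a)
    validate_merge(cm, spec_w, alpha = a)$approved, TRUE)
  expect_true(all(diff(as.integer(approvals)) >= 0))
  expect_error(validate_merge(cm, composite_spec("x", "nope")), "nope")
})

test_that("composites are means on the 1-5 scale, order-invariant", {
  df <- expand.grid(subject_id = "s1", group = "g", condition = c("BB", "HM"),
                    item = c("a", "b"), stringsAsFactors = FALSE)
  df$response <- c(4, 4, 5, 3)   # BB: a=4 b=5; HM: a=4 b=3
  tab <- likert_table(df)
  comp <- build_composite(tab, composite_spec("c", c("a", "b")))
  expect_equal(comp$composite[comp$condition == "BB"], 4.5)
  expect_equal(comp$composite[comp$condition == "HM"], 3.5)
  # permuting the item list changes nothing
  comp2 <- build_composite(tab, composite_spec("c", c("b", "a")))
  expect_equal(comp$composite, comp2$composite)
  # all items identical -> composite equals the common item
  df$response <- c(2, 2, 2, 2)
  comp3 <- build_composite(likert_table(df), composite_spec("c", c("a", "b")))
  expect_true(all(comp3$composite == 2))
  # composite bounded by min and max item for every row
  p <- make_profiles(11, 10, seed = 9)
  q <- synthesize_questionnaire(p, effect_spec(), seed = 2)
  spec4 <- default_composites()[[2]]
  comp4 <- build_composite(q, spec4)
  wide <- reshape(as.data.frame(q)[q$item %in% spec4$items,
                                   c("subject_id", "condition", "item",
                                     "response")],
                  idvar = c("subject_id", "condition"), timevar = "item",
                  direction = "wide")
  key_a <- paste(comp4$subject_id, comp4$condition)
  key_b <- paste(wide$subject_id, wide$condition)
  mat <- as.matrix(wide[match(key_a, key_b), -(1:2)])
  expect_true(all(comp4$composite >= apply(mat, 1, min) - 1e-12))
  expect_true(all(comp4$composite <= apply(mat, 1, max) + 1e-12))
  expect_true(all(comp4$composite >= 1 & comp4$composite <= 5))
})

test_that("composite building respects validation unless forced", {
  df <- expand.grid(subject_id = paste0("s", 1:6), group = "g",
                    condition = c("BB", "HM"), item = c("a", "b"),
                    stringsAsFactors = FALSE)
  set.seed(10)
  df$response <- sample(1:5, nrow(df), replace = TRUE)
  tab <- likert_table(df)
  cm <- correlation_matrix(tab)
  v <- validate_merge(cm, composite_spec("c", c("a", "b")))
  expect_false(v$approved)
  expect_error(build_composite(tab, composite_spec("c", c("a", "b")),
                               validation = v), "force")
  expect_warning(build_composite(tab, composite_spec("c", c("a", "b")),
                                 validation = v, force = TRUE), "override")
  # missing responses exclude the row with a warning
  tab_m <- likert_table(df[-1, ])
  expect_warning(comp <- build_composite(tab_m,
                                         composite_spec("c", c("a", "b"))),
                 "excluded")
  expect_equal(nrow(comp), 11)
})

test_that("cronbach alpha is high for coherent constructs", {
  p <- make_profiles(11, 10, seed = 3)
  q <- synthesize_questionnaire(p, effect_spec(), seed = 5)
  a <- cronbach_alpha(q, default_composites()[[2]]$items)
  expect_gt(a, 0.6)
  expect_lte(a, 1)
})
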