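# logistic SV filters: feature assembly, training/recovery, strict 60%
# threshold, combined union rule, |t| importance, dominance analysis.

test_that("feature vectors follow the per-technology schema", {
  svs <- rbind(make_call("a", "DEL", pos1 = 1000L, pos2 = 3000L),
               make_call("b", "TRA", chrom1 = "chr1", pos1 = 100L,
                         chrom2 = "chr2", pos2 = 200L),
               make_call("u", "UNK", pos1 = 500L, pos2 = 900L))
  rq <- data.frame(sv_id = c("a", "b", "u"), jr_norm = c(1.2, 2, 0),
                   sp_norm = c(0.7, 1, 0))
  an <- data.frame(sv_id = c("a", "b", "u"), local_coverage_norm = c(1, 1, 1))
  fv <- build_features(svs, rq, an, technology = "SR")
  ## UNK excluded; SR vectors carry no gem_norm; TRA size encoded 0
  expect_equal(nrow(fv), 2)
  expect_false("gem_norm" %in% names(fv))
  expect_equal(fv$size[fv$sv_id == "b"], 0)
  expect_equal(fv$jr_norm[fv$sv_id == "a"] + fv$sp_norm[fv$sv_id == "a"], 1.9)
  ## LR needs the GEM table; missing features are named
  expect_error(build_features(svs, rq, an, technology = "LR"), "GEM")
  expect_error(build_features(svs, rq[1, ], an, technology = "SR"), "\\bb\\b")
})

test_that("training recovers known coefficients within 2 SE (n = 2000)", {
  beta <- c(b0 = -1.5, jr = 1.1, sp = 0.8, size = -0.4, cov = 0.3)
  fv <- gen_features(2000, beta, seed = 101)
  m <- train_model(fv, "SR", seed = 1)
  expect_false(m$ridge)
  est <- m$coefficients; se <- m$se
  expect_lt(abs(est[["(Intercept)"]] - beta[["b0"]]), 2 * se[["(Intercept)"]])
  expect_lt(abs(est[["jr_norm"]] - beta[["jr"]]), 2 * se[["jr_norm"]])
  expect_lt(abs(est[["sp_norm"]] - beta[["sp"]]), 2 * se[["sp_norm"]])
  expect_lt(abs(est[["size"]] - beta[["size"]]), 2 * se[["size"]])
  expect_lt(abs(est[["local_coverage_norm"]] - beta[["cov"]]),
            2 * se[["local_coverage_norm"]])
})

test_that("estimation bias shrinks as n grows", {
  beta <- c(b0 = -1, jr = 1.0, sp = 0.5, size = 0, cov = 0)
  err <- vapply(c(500, 2000, 8000), function(n) {
    m <- train_model(gen_features(n, beta, seed = 202), "SR", seed = 2)
    abs(m$coefficients[["jr_norm"]] - beta[["jr"]])
  }, numeric(1))
  expect_lt(err[3], err[1] + 0.05)   # monotone up to noise
  expect_lt(err[3], 0.2)
})

test_that("training is deterministic for a fixed seed", {
  fv <- gen_features(300, c(b0 = 0, jr = 1, sp = -1, size = 0.2, cov = 0),
                     seed = 7)
  m1 <- train_model(fv, "SR", seed = 11)
  m2 <- train_model(fv, "SR", seed = 11)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$test_metrics, m2$test_metrics)
  expect_error(train_model(fv[1:10, ], "SR"), ">= 20")
  one_class <- fv[fv$label == "POSITIVE", ][1:30, ]
  expect_error(train_model(one_class, "SR"), "classes")
})

test_that("the 60% decision threshold is strict", {
  mk_model <- function(p) {
    structure(list(
      technology = "SR",
      coefficients = setNames(c(qlogis(p), rep(0, 7)),
                              c("(Intercept)", "sv_typeDUP", "sv_typeINV",
                                "sv_typeTRA", "jr_norm", "sp_norm", "size",
                                "local_coverage_norm")),
      se = setNames(rep(1, 8), c("(Intercept)", "sv_typeDUP", "sv_typeINV",
                                 "sv_typeTRA", "jr_norm", "sp_norm", "size",
                                 "local_coverage_norm")),
      ridge = FALSE, threshold = 0.6,
      feature_names = c("(Intercept)", "sv_typeDUP", "sv_typeINV",
                        "sv_typeTRA", "jr_norm", "sp_norm", "size",
                        "local_coverage_norm")), class = "sv_logit_model")
  }
  fv <- data.frame(sv_id = "x", sv_type = factor("DEL",
                     levels = c("DEL", "DUP", "INV", "TRA")),
                   jr_norm = 0, sp_norm = 0, size = 0,
                   local_coverage_norm = 0)
  expect_equal(unname(predict(mk_model(0.59), fv)), "NEGATIVE")
  p60 <- predict(mk_model(0.60), fv, type = "prob")
  expect_lte(unname(p60), 0.6)            # exactly the threshold...
  expect_equal(unname(predict(mk_model(0.60), fv)), "NEGATIVE")  # ...not kept
  expect_equal(unname(predict(mk_model(0.61), fv)), "POSITIVE")
  ## schema mismatch is an error
  fv_lr <- cbind(fv, gem_norm = 1)
  expect_error(predict(mk_model(0.61), fv_lr), "schema")
})

test_that("combined model applies the union rule and keeps COMMON SVs", {
  expect_equal(combined_predict("COMMON", "NEGATIVE", "NEGATIVE"), "POSITIVE")
  expect_equal(combined_predict("ONLY_SR", "POSITIVE", NA), "POSITIVE")
  expect_equal(combined_predict("ONLY_LR", NA, "NEGATIVE"), "NEGATIVE")
  expect_equal(combined_predict("ONLY_LR", NA, "POSITIVE"), "POSITIVE")
  cat3 <- c("COMMON", "ONLY_SR", "ONLY_LR")
  out <- combined_predict(cat3, c(NA, "NEGATIVE", NA), c(NA, NA, "NEGATIVE"))
  ## positives always contain every COMMON SV
  expect_true(all(out[cat3 == "COMMON"] == "POSITIVE"))
})

test_that("feature importance is |t| rescaled to a 100 maximum", {
  m <- structure(list(
    coefficients = c("(Intercept)" = 0.5, f1 = 2, f2 = 1, f3 = 0),
    se = c("(Intercept)" = 1, f1 = 0.5, f2 = 0.5, f3 = 1)),
    class = "sv_logit_model")
  imp <- feature_importance(m)
  expect_equal(unname(imp[c("f1", "f2", "f3")]), c(100, 50, 0))
  ## single feature: importance 100
  m1 <- structure(list(coefficients = c("(Intercept)" = 0, f1 = -3),
                       se = c("(Intercept)" = 1, f1 = 1)),
                  class = "sv_logit_model")
  expect_equal(unname(feature_importance(m1)), 100)
  m_bad <- structure(list(coefficients = c("(Intercept)" = 0, f1 = 1),
                          se = c("(Intercept)" = 1, f1 = 0)),
                     class = "sv_logit_model")
  expect_error(feature_importance(m_bad), "singular")
})

test_that("monotonicity: raising jr support never lowers the probability", {
  fv <- gen_features(800, c(b0 = -1, jr = 1.2, sp = 0.5, size = 0.1,
                            cov = 0.1), seed = 55)
  m <- train_model(fv, "SR", seed = 3)
  expect_gt(m$coefficients[["jr_norm"]], 0)
  probe <- fv[1:20, ]
  p0 <- predict(m, probe, type = "prob")
  probe$jr_norm <- probe$jr_norm * 5 + 10
  p1 <- predict(m, probe, type = "prob")
  expect_true(all(p1 >= p0))
})

test_that("dominance weights sum to the full-model McFadden R2", {
  fv <- gen_features(600, c(b0 = -0.5, jr = 1, sp = -0.8, size = 0.3,
                            cov = 0.2), seed = 77)
  w <- dominance_analysis(fv)
  expect_equal(sum(w), attr(w, "full_r2"), tolerance = 1e-9)
  ## full-model R2 agrees with a direct glm oracle on the same transform
  df <- data.frame(y = as.integer(fv$label == "POSITIVE"),
                   sv_type = fv$sv_type,
                   jr_norm = log1p(fv$jr_norm), sp_norm = log1p(fv$sp_norm),
                   size = log1p(fv$size),
                   local_coverage_norm = log1p(fv$local_coverage_norm))
  r2_full <- oracle_mcfadden(df, "y", c("sv_type", "jr_norm", "sp_norm",
                                        "size", "local_coverage_norm"))
  expect_equal(attr(w, "full_r2"), r2_full, tolerance = 1e-6)
})

test_that("a single-feature model's dominance weight is its own R2", {
  fv <- gen_features(500, c(b0 = 0, jr = 1.5, sp = 0, size = 0, cov = 0),
                     seed = 88)
  fv1 <- fv[, c("sv_id", "jr_norm", "label")]
  fv1$sv_type <- factor("DEL", levels = c("DEL", "DUP", "INV", "TRA"))
  w <- dominance_analysis(fv1)
  expect_equal(length(w), 1L)
  df <- data.frame(y = as.integer(fv1$label == "POSITIVE"),
                   jr = log1p(fv1$jr_norm))
  expect_equal(as.numeric(w), oracle_mcfadden(df, "y", "jr"),
               tolerance = 1e-6)
})

test_that("two independent equal-effect features share dominance equally", {
  ## exchange-symmetric design: the data are invariant under swapping the
  ## two features, so their marginal fits — and hence the general-dominance
  ## weights — are exactly equal
  withr::with_seed(99, {
    n <- 2500
    z1 <- runif(n, 0, 3); z2 <- runif(n, 0, 3)
    y <- rbinom(n, 1, plogis(-1 + z1 + z2))
  })
  fv <- data.frame(sv_id = sprintf("s%04d", 1:(2 * n)),
                   sv_type = factor("DEL", levels = c("DEL", "DUP", "INV",
                                                      "TRA")),
                   jr_norm = expm1(c(z1, z2)), sp_norm = expm1(c(z2, z1)),
                   label = rep(ifelse(y == 1, "POSITIVE", "NEGATIVE"), 2))
  w <- dominance_analysis(fv)
  expect_lt(abs(w[["jr_norm"]] - w[["sp_norm"]]), 1e-8)
  expect_equal(sum(w), attr(w, "full_r2"), tolerance = 1e-9)
})

test_that("models serialize to JSON and back without behavioral change", {
  fv <- gen_features(400, c(b0 = 0, jr = 1, sp = 0.5, size = 0, cov = 0),
                     seed = 5)
  m <- train_model(fv, "SR", seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_identical(predict(m2, fv), predict(m, fv))
})
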