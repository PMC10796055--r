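# A cheap, strongly separable two-model problem reused across tests:
# independent sampling versus a near-frozen random walk.
make_toy_table <- function(n = 60, len = 120, seed = 1) {
  tab <- simulate_reference_table(c("iid", "MH"), line7, n, length = len,
                                  seed = seed)
  tab
}

frozen_mh_table <- function(n = 60, len = 120, seed = 1) {
  set.seed(seed)
  feats <- abc_features(line7)
  rows <- lapply(seq_len(2 * n), function(i) {
    m <- if (i <= n) "iid" else "MH"
    pp <- if (m == "MH") list(sigma = 0.5) else NULL
    repeat {
      sv <- summarize_sequence(generate_sequence(m, line7, len,
                                                 params = pp))[feats]
      if (!anyNA(sv)) return(sv)
    }
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab$model <- factor(rep(c("iid", "MH"), each = n), levels = c("iid", "MH"))
  structure(list(table = tab, features = feats, domain = line7,
                 n_per_model = n, length = len, seed = seed),
            class = "rg_reftable")
}

test_that("reference tables are complete, labelled and reproducible", {
  rt <- simulate_reference_table(c("iid", "schema", "MCREC"), line7, 30,
                                 length = 80, seed = 2)
  expect_equal(nrow(rt$table), 90)
  expect_false(anyNA(rt$table))
  expect_equal(as.vector(table(rt$table$model)), c(30, 30, 30))
  rt2 <- simulate_reference_table(c("iid", "schema", "MCREC"), line7, 30,
                                  length = 80, seed = 2)
  expect_identical(rt$table, rt2$table)
  # iid rows approach the analytic expectations on the line
  rti <- simulate_reference_table("iid", line7, 80, length = 355, seed = 3)
  expect_lt(abs(mean(rti$table$repetitions) - 1 / 7), 0.01)
  expect_lt(abs(mean(rti$table$central_turning_points) - 58 / 108), 0.02)
})

test_that("schema is excluded from 2-D reference tables with a warning", {
  expect_warning(
    rt <- simulate_reference_table(c("iid", "schema", "MH"), hex7, 20,
                                   length = 80, seed = 4),
    "schema")
  expect_false("schema" %in% levels(rt$table$model))
  expect_false("shape" %in% rt$features)
})

test_that("the classifier separates separable models and is deterministic", {
  train <- frozen_mh_table(n = 80, seed = 5)
  test <- frozen_mh_table(n = 100, seed = 6)
  cls <- train_classifier(train, seed = 1)
  pred <- classify(cls, test$table[, cls$features])
  expect_gte(mean(pred == test$table$model), 0.99)
  cls2 <- train_classifier(train, seed = 1)
  expect_identical(classify(cls2, test$table[, cls$features]), pred)
  expect_error(train_classifier(
    structure(list(table = droplevels(train$table[train$table$model == "iid", ]),
                   features = train$features), class = "rg_reftable")),
    "two models")
})

test_that("label permutation drives held-out accuracy to chance", {
  train <- frozen_mh_table(n = 150, seed = 7)
  test <- frozen_mh_table(n = 400, seed = 9)
  # a single permuted forest predicts near-constant labels per cluster, so
  # its accuracy is chance only in expectation; average over permutations
  acc <- mean(sapply(1:5, function(k) {
    set.seed(7 + k)
    tr <- train
    tr$table$model <- sample(tr$table$model)
    cls <- train_classifier(tr, seed = 1)
    mean(classify(cls, test$table[, cls$features]) == test$table$model)
  }))
  expect_lt(abs(acc - 0.5), 0.05)
})

test_that("recursive posteriors allocate mass by classification error", {
  train <- frozen_mh_table(n = 80, seed = 10)
  q <- summarize_sequence(
    generate_sequence("MH", line7, 120, params = list(sigma = 0.5),
                      seed = 11))
  po <- posterior_for_sequence(q, train, seed = 2)
  # two models: posterior is (1 - e, e) for the winner
  expect_equal(sum(po$posterior), 1, tolerance = 1e-9)
  expect_equal(unname(po$posterior[po$elimination_order[1]]),
               1 - po$stage_errors[1])
  expect_gt(po$posterior["MH"], 0.9) # deep inside the frozen-walk cluster
  expect_error(posterior_for_sequence(c(repetitions = NA), train), "incomplete")
})

test_that("posteriors are normalised for batches of random queries", {
  rt <- simulate_reference_table(c("iid", "MH", "HMC"), unif_heights, 40,
                                 length = 100, seed = 12)
  cache <- new.env(parent = emptyenv())
  set.seed(13)
  for (i in 1:100) {
    m <- sample(c("iid", "MH", "HMC"), 1)
    repeat {
      q <- summarize_sequence(generate_sequence(m, unif_heights, 100))
      if (!anyNA(q)) break
    }
    po <- posterior_for_sequence(q, rt, num_trees = 200, seed = 3,
                                 cache = cache)
    expect_equal(sum(po$posterior), 1, tolerance = 1e-9)
    expect_true(all(po$posterior >= 0))
  }
})

test_that("posterior combination multiplies and renormalises", {
  p1 <- c(A = 0.8, B = 0.2)
  cmb <- combine_posteriors(p1, p1)
  expect_equal(unname(cmb$posterior), c(0.64, 0.04) / 0.68)
  expect_equal(unname(combine_posteriors(c(A = .5, B = .5),
                                         c(A = .5, B = .5))$posterior),
               c(0.5, 0.5))
  # a uniform posterior is the identity element
  p3 <- c(A = 0.7, B = 0.3)
  expect_equal(combine_posteriors(p3, c(A = .5, B = .5))$posterior,
               p3 / sum(p3))
  expect_error(combine_posteriors(p1, c(A = .5, C = .5)), "model sets")
})

test_that("class and feature Bayes factors average matched posteriors", {
  u <- setNames(rep(1 / 8, 8), MODELS)
  expect_equal(class_bayes_factor(u, LOCAL_MODELS, c("iid", "schema")), 1)
  expect_equal(feature_bayes_factor(u, "multiple_chains"), 1)
  expect_equal(feature_bayes_factor(u, "gradient"), 1)
  expect_equal(feature_bayes_factor(u, "recycled"), 1)
  # singleton classes reduce to a plain posterior ratio
  p <- setNames(c(.4, .1, .05, .05, .1, .1, .1, .1), MODELS)
  expect_equal(class_bayes_factor(p, "iid", "schema"), 4)
  # six local models at p vs schema at q: ratio of means = p/q
  p2 <- setNames(c(.1, .06, rep(.14, 6)), MODELS)
  expect_equal(class_bayes_factor(p2, LOCAL_MODELS, "schema"), .14 / .06)
  # all mass on MCREC: infinite support for its two features
  p3 <- setNames(c(rep(0, 7), 1), MODELS)
  expect_identical(feature_bayes_factor(p3, "multiple_chains"), Inf)
  expect_identical(feature_bayes_factor(p3, "recycled"), Inf)
  # the gradient contrast ignores recycled-momentum models entirely
  p4 <- setNames(c(0, 0, .1, .2, .15, .3, .15, .1), MODELS)
  p5 <- p4; p5[c("REC", "MCREC")] <- 0; p5 <- p5 / sum(p5)
  expect_equal(feature_bayes_factor(p4, "gradient"),
               feature_bayes_factor(p5, "gradient"))
  expect_error(class_bayes_factor(u, "MH", "MH"), "disjoint")
})

test_that("model recovery separates a degenerate pair almost perfectly", {
  train <- frozen_mh_table(n = 80, seed = 14)
  test <- frozen_mh_table(n = 60, seed = 15)
  cls <- train_classifier(train, seed = 1)
  pred <- classify(cls, test$table[, cls$features])
  conf <- prop.table(table(test$table$model, pred), margin = 1)
  expect_equal(unname(rowSums(conf)), c(1, 1))
  expect_gte(conf["iid", "iid"], 0.95)
  expect_gte(conf["MH", "MH"], 0.95)
})

test_that("more training simulations never hurt median recovery accuracy", {
  tr500 <- simulate_reference_table(MODELS, unif_heights, 500, 400,
                                    seed = 301)
  tr2000 <- simulate_reference_table(MODELS, unif_heights, 2000, 400,
                                     seed = 302)
  te <- simulate_reference_table(MODELS, unif_heights, 150, 400, seed = 303)
  acc <- function(tr) {
    cls <- train_classifier(tr, seed = 1)
    pred <- classify(cls, te$table[, cls$features])
    tapply(pred == te$table$model, te$table$model, mean)
  }
  expect_gte(median(acc(tr2000)), median(acc(tr500)))
})

test_that("recycled-momentum cohorts earn higher recycled Bayes factors", {
  rt <- simulate_reference_table(MODELS, unif_heights, 250, length = 400,
                                 seed = 16)
  cache <- new.env(parent = emptyenv())
  set.seed(17)
  wins <- 0
  for (i in 1:20) {
    base <- draw_params_from_prior("MCREC", unif_heights)
    hi <- modifyList(base, list(alpha = 0.9))
    lo <- modifyList(base, list(alpha = 0))
    bf <- sapply(list(hi, lo), function(pp) {
      s <- generate_sequence("MCREC", unif_heights, 400, params = pp)
      po <- posterior_for_sequence(summarize_sequence(s), rt,
                                   num_trees = 300, seed = 4, cache = cache)
      feature_bayes_factor(po, "recycled")
    })
    if (isTRUE(bf[1] > bf[2])) wins <- wins + 1
  }
  expect_gte(wins, 11)
})
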