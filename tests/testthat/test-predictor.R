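test_that("coefficient prediction is the weighted hologram sum", {
  p <- predict_coeff(c(a = 2L), c(a = 0.5))
  expect_equal(p$value, 1)
  expect_equal(p$mode, "coeff")
  expect_true(p$in_domain)

  # untrained code: flagged, value over known codes only
  p2 <- predict_coeff(c(a = 2L, zz = 1L), c(a = 0.5))
  expect_false(p2$in_domain)
  expect_equal(p2$missing_codes, "zz")
  expect_equal(p2$value, 1)

  expect_error(predict_coeff(integer(0), c(a = 1)), "empty")
})

test_that("library correction equals the coefficient-prediction gap plus the anchor", {
  fit <- get_fixture_fit()
  fx <- get_fixtures()
  set.seed(21)
  for (k in 1:20) {
    pick <- sample(length(fx$holograms), 2)
    u <- fx$holograms[[pick[1]]]; v <- fx$holograms[[pick[2]]]
    anchor <- fx$targets[pick[2]]
    corr <- correct_from_known(u, v, anchor, fit)
    lin <- anchor + predict_coeff(u, fit)$value - predict_coeff(v, fit)$value
    expect_equal(corr$value, lin, tolerance = 1e-10)
  }
  # identical query: empty difference, anchor returned exactly
  h <- fx$holograms[[1]]
  expect_identical(correct_from_known(h, h, 1.23, fit)$value, 1.23)
})

test_that("library prediction: exact match, averaging, tie-breaking, fallback", {
  fit <- get_fixture_fit()
  fx <- get_fixtures()
  idx <- match(c("chlorophenol_4", "phenol", "p_cresol"), fx$ids)
  lib <- build_library(fx$holograms[idx], fx$targets[idx],
                       ids = c("clp", "phe", "cre"))

  # query present verbatim in the library ranks first at similarity 1
  # and returns its experimental value
  p_exact <- predict_library(fx$holograms[[idx[1]]], lib, fit,
                             min_similarity = 0.5, max_matches = 1L)
  expect_equal(p_exact$value, fx$targets[idx[1]])
  expect_equal(p_exact$mode, "library")
  expect_equal(p_exact$matches$similarity, 1)

  # raising the threshold above every similarity gives exactly coeff mode
  q <- fx$holograms[[match("hexane", fx$ids)]]
  p_fb <- predict_library(q, lib, fit, min_similarity = 0.999)
  expect_equal(p_fb$mode, "coeff")
  expect_equal(p_fb$value, predict_coeff(q, fit)$value)

  # value is the mean of corrected values over kept matches
  q2 <- type_smiles("Oc1ccc(Br)cc1")
  p2 <- predict_library(q2, lib, fit, min_similarity = 0.5, max_matches = 3L)
  corr <- vapply(idx, function(i)
    correct_from_known(q2, fx$holograms[[i]], fx$targets[i], fit)$value,
    numeric(1))
  sims <- vapply(idx, function(i)
    hologram_similarity(q2, fx$holograms[[i]]), numeric(1))
  expect_equal(p2$value, mean(corr[sims >= 0.5]))

  # library order must not matter; equal similarities break ties by id
  lib_rev <- build_library(fx$holograms[rev(idx)], fx$targets[rev(idx)],
                           ids = c("cre", "phe", "clp"))
  p3 <- predict_library(q2, lib_rev, fit, min_similarity = 0.5, max_matches = 3L)
  expect_equal(p3$value, p2$value)
  dup <- build_library(fx$holograms[c(idx[1], idx[1])], c(1, 9),
                       ids = c("b_id", "a_id"))
  p4 <- predict_library(q2, dup, fit, min_similarity = 0.5, max_matches = 1L)
  expect_equal(p4$matches$id, "a_id")
})

test_that("out-of-domain matches are dropped from the library mean", {
  alpha <- c(a = 0.5, b = -0.2)
  lib <- build_library(list(c(a = 2L, b = 1L), c(a = 2L, q = 1L)),
                       c(1.0, 5.0), ids = c("ok", "odd"))
  q <- c(a = 3L, b = 1L)
  p <- predict_library(q, lib, alpha, min_similarity = 0.1, max_matches = 2L)
  expect_equal(nrow(p$matches), 2)
  expect_false(all(p$matches$in_domain))
  expect_equal(p$value, 1.0 + 0.5)  # only the in-domain match contributes
})

test_that("grid search reproduces a brute-force per-compound recomputation", {
  fit <- get_fixture_fit()
  fx <- get_fixtures()
  lib_idx <- seq(1, length(fx$ids), by = 2)
  ev_idx <- seq(2, length(fx$ids), by = 4)
  lib <- build_library(fx$holograms[lib_idx], fx$targets[lib_idx],
                       ids = fx$ids[lib_idx])
  g <- grid_search(lib, fx$holograms[ev_idx], fx$targets[ev_idx], fit,
                   similarities = c(0.5, 0.75), match_counts = c(1L, 3L))
  expect_equal(dim(g), c(2L, 2L))
  for (s in c("0.5", "0.75")) for (m in c("1", "3")) {
    preds <- vapply(ev_idx, function(i)
      predict_library(fx$holograms[[i]], lib, fit,
                      min_similarity = as.numeric(s),
                      max_matches = as.integer(m))$value, numeric(1))
    expect_equal(g[m, s], sqrt(mean((preds - fx$targets[ev_idx])^2)),
                 label = paste("cell", m, s))
  }

  # evaluating library members against themselves is an exact lookup
  self <- grid_search(lib, fx$holograms[lib_idx], fx$targets[lib_idx], fit,
                      similarities = 0.5, match_counts = 1L)
  expect_equal(unname(self[1, 1]), 0)
})

test_that("averaging more matches does not hurt on mean-zero noisy anchors", {
  # one query, many equally similar anchors with symmetric noise: the
  # error of the averaged correction shrinks with the match count
  set.seed(33)
  base <- c(a = 5L, b = 5L)
  alpha <- c(a = 0.3, b = -0.1, c = 0.05)
  truth <- sum(alpha[names(base)] * base)
  n_anchor <- 40
  anchors <- replicate(n_anchor, {
    h <- base; h[["c"]] <- 1L; h
  }, simplify = FALSE)
  noisy <- vapply(anchors, function(h)
    sum(alpha[names(h)] * h), numeric(1)) + rnorm(n_anchor, 0, 0.5)
  lib <- build_library(anchors, noisy, ids = sprintf("a%02d", seq_len(n_anchor)))
  err <- vapply(c(1L, 5L, 40L), function(m)
    abs(predict_library(base, lib, alpha, min_similarity = 0.5,
                        max_matches = m)$value - truth), numeric(1))
  expect_lt(err[3], err[1])
})

test_that("exclude_exact skips similarity-1 matches", {
  alpha <- c(a = 1)
  lib <- build_library(list(c(a = 2L), c(a = 3L)), c(5, 7), ids = c("x", "y"))
  p <- predict_library(c(a = 2L), lib, alpha, min_similarity = 0.5,
                       exclude_exact = TRUE)
  expect_false("x" %in% p$matches$id)
})

test_that("evaluation reports RMSE and binned absolute-error percentages", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$rmse, 0)
  expect_equal(unname(ev$bins), c(100, 0, 0, 0, 0))

  ev2 <- evaluate_predictions(c(0.2, 0.7, 2.5), c(0, 0, 0))
  expect_equal(unname(ev2$bins), c(100 / 3, 100 / 3, 0, 0, 100 / 3))

  # the mean-predictor baseline reproduces the dataset standard deviation
  set.seed(8)
  y <- rnorm(500, 4.2, 1.1)
  ev3 <- evaluate_predictions(rep(mean(y), length(y)), y)
  expect_equal(ev3$rmse, sqrt(mean((y - mean(y))^2)), tolerance = 1e-12)

  expect_error(evaluate_predictions(1:3, 1:2), "length")
})
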