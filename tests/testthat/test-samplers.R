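test_that("leapfrog reproduces hand-computed steps and flat-target motion", {
  unit <- make_domain("gaussian", mean = 0, sd = 1)
  # one step from (x, p) = (1, 0) with eps = 0.1:
  # p <- 0 - 0.05*1 = -0.05; x <- 1 - 0.005 = 0.995; p <- -0.05 - 0.05*0.995
  lf <- leapfrog(unit, 1, 0, eps = 0.1, L = 1)
  expect_equal(lf$position, 0.995)
  expect_equal(lf$momentum, -0.09975)
  # flat target: straight-line motion with reflection at the boundary
  lf2 <- leapfrog(line7, 6.5, 1, eps = 1, L = 1)
  expect_equal(lf2$position, 6.5)
  expect_equal(lf2$momentum, -1)
  lf3 <- leapfrog(line7, 3, 1, eps = 0.5, L = 4) # x + eps*L*p, no reflection
  expect_equal(lf3$position, 5)
  expect_equal(lf3$momentum, 1)
})

test_that("leapfrog energy error scales as O(eps^2) at fixed trajectory length", {
  unit <- make_domain("gaussian", mean = 0, sd = 1)
  H <- function(x, p) 0.5 * x^2 + 0.5 * p^2
  cfg <- list(c(0.2, 5), c(0.1, 10), c(0.05, 20)) # eps * L = 1 throughout
  err <- sapply(cfg, function(cl) {
    lf <- leapfrog(unit, 1, 0.5, eps = cl[1], L = cl[2])
    abs(H(lf$position, lf$momentum) - H(1, 0.5))
  })
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5.5)
  expect_gt(err[2] / err[3], 3)
  expect_lt(err[2] / err[3], 5.5)
})

test_that("single-chain models are exact reductions of coupled ones", {
  p_mh <- list(sigma = 10)
  mh <- generate_sequence("MH", gauss_heights, 300, params = p_mh, seed = 11)
  mc3 <- generate_sequence("MC3", gauss_heights, 300,
                           params = c(p_mh, list(C = 1, Delta = 2, s = 0.7)),
                           seed = 11)
  expect_identical(mh$responses, mc3$responses)

  p_h <- list(eps = 4, psd = 1)
  hmc <- generate_sequence("HMC", gauss_heights, 300, params = p_h, seed = 12)
  rec <- generate_sequence("REC", gauss_heights, 300,
                           params = c(p_h, list(alpha = 0)), seed = 12)
  mchmc <- generate_sequence("MCHMC", gauss_heights, 300,
                             params = c(p_h, list(C = 1, Delta = 1, s = 0.4)),
                             seed = 12)
  mcrec <- generate_sequence("MCREC", gauss_heights, 300,
                             params = c(p_h, list(alpha = 0, C = 1,
                                                  Delta = 1, s = 0.4)),
                             seed = 12)
  expect_identical(hmc$responses, rec$responses)
  expect_identical(hmc$responses, mchmc$responses)
  expect_identical(hmc$responses, mcrec$responses)
})

test_that("fixed model, parameters and seed give identical sequences", {
  for (m in c("iid", "schema", "MH", "MCREC")) {
    pp <- if (m %in% c("iid")) NULL else {
      set.seed(77)
      draw_params_from_prior(m, unif_heights)
    }
    a <- generate_sequence(m, unif_heights, 120, params = pp, seed = 5)
    b <- generate_sequence(m, unif_heights, 120, params = pp, seed = 5)
    expect_identical(a$responses, b$responses)
  }
})

test_that("Metropolis-Hastings satisfies detailed balance on a 5-state target", {
  toy <- make_domain("scaled_beta", alpha = 2, beta = 2, lo = 0.5, hi = 5.5)
  s <- generate_sequence("MH", toy, 1e6, params = list(sigma = 1.5), seed = 30)
  x <- s$responses
  joint <- table(factor(x[-length(x)], 1:5), factor(x[-1], 1:5)) /
    (length(x) - 1)
  # reversibility: stationary flow i->j equals j->i
  expect_lt(max(abs(joint - t(joint))), 1e-2)
  # and the emitted marginal tracks the binned target mass
  pk <- diff(pbeta((0:5) / 5, 2, 2))
  expect_lt(max(abs(prop.table(table(factor(x, 1:5))) - pk)), 0.01)
})

test_that("chains are stationary: emitted states match the target CDF", {
  for (m in c("MH", "MC3", "HMC", "REC", "MCREC")) {
    pp <- localsampler:::midrange_params(m, gauss_heights)
    s <- generate_sequence(m, gauss_heights, 1e5, params = pp, seed = 20,
                           keep_states = TRUE)
    ks <- suppressWarnings(
      ks.test(s$states, pnorm, 176.4, 12)$statistic)
    expect_lt(unname(ks), 0.02)
  }
  pp <- localsampler:::midrange_params("MCHMC", unif_heights)
  s <- generate_sequence("MCHMC", unif_heights, 1e5, params = pp, seed = 21,
                         keep_states = TRUE)
  ks <- suppressWarnings(ks.test(s$states, function(q)
    pbeta((q - 122) / 97, 1.27, 1.43))$statistic)
  expect_lt(unname(ks), 0.02)
})

test_that("iid draws have the target moments and no serial dependence", {
  s <- generate_sequence("iid", gauss_heights, 1e5, seed = 8,
                         keep_states = TRUE)
  expect_lt(abs(mean(s$states) - 176.4), 3 * 12 / sqrt(1e5))
  r <- cor(s$states[-1], s$states[-1e5])
  expect_lt(abs(r), 0.01)
  u <- generate_sequence("iid", line7, 1e5, seed = 9)
  freq <- prop.table(table(factor(u$responses, 1:7)))
  expect_lt(max(abs(freq - 1 / 7)), 0.01)
})

test_that("momentum recycling straightens trajectories: turns fall with alpha", {
  tp <- sapply(c(0, 0.3, 0.6, 0.9), function(al) {
    mean(sapply(1:10, function(i) {
      s <- generate_sequence("REC", gauss_heights, 400,
                             params = list(eps = 2, psd = 1, alpha = al),
                             seed = 500 + i)
      stripped_tp(s)
    }))
  })
  expect_true(all(diff(tp) < 0))
})

test_that("tempered coupling escapes modes that trap a plain random walk", {
  bimodal <- make_domain("scaled_beta", alpha = 0.15, beta = 0.15,
                         lo = 0, hi = 10)
  both_modes <- function(model, pp, seed) {
    s <- generate_sequence(model, bimodal, 2000, params = pp, seed = seed,
                           keep_states = TRUE)
    min(mean(s$states < 2), mean(s$states > 8)) > 0.05
  }
  mh <- sum(sapply(1:10, function(i) both_modes("MH", list(sigma = 0.1), i)))
  mc3 <- sum(sapply(1:10, function(i)
    both_modes("MC3", list(sigma = 0.1, C = 5, Delta = 4, s = 0.9), i)))
  expect_gte(mc3, 6)
  expect_lte(mh, 4)
  expect_gt(mc3, mh)
})

test_that("schema rules: increments, boundary reflection, sawtooth at rho = 1", {
  ramp <- list(weights = c(1, 0, 0, 0, 0, 0), rho = 1) # always apply +1
  s <- generate_sequence("schema", line7, 60, params = ramp, seed = 3)
  x <- s$responses
  expect_true(all(abs(diff(x)) == 1))            # item 5 +1 -> 6; 7 +1 -> 6
  # persistent +1 with result reflection: after the ramp reaches the top the
  # deterministic trace alternates between the two topmost items, so every
  # turn happens against the boundary
  expect_true(all(x %in% 6:7))
  expect_true(all(diff(x) != 0))
  down <- list(weights = c(0, 1, 0, 0, 0, 0), rho = 1) # always apply -1
  x2 <- generate_sequence("schema", line7, 60, params = down, seed = 3)$responses
  expect_true(all(x2 %in% 1:2))
  expect_error(generate_sequence("schema", hex7, 60),
               "two-dimensional")
})

test_that("prior draws respect their ranges and always yield sequences", {
  set.seed(60)
  a <- replicate(2000, draw_params_from_prior("MCREC", unif_heights)$alpha)
  expect_lt(abs(mean(a) - 0.495), 0.03)
  expect_true(all(a >= 0 & a < 0.99))
  cc <- replicate(500, draw_params_from_prior("MC3", unif_heights)$C)
  expect_true(all(cc %in% 2:6))
  expect_gt(min(table(factor(cc, 2:6))), 0)
  for (m in MODELS) {
    dom <- if (m == "schema") line7 else hex7
    for (i in 1:25) {
      s <- generate_sequence(m, dom, 60)
      expect_length(s$responses, 60)
      expect_true(all(s$responses %in% 1:7))
    }
  }
  expect_error(generate_sequence("nope", line7, 10), "model_id")
})

test_that("a vanishing proposal scale freezes the rounded chain", {
  s <- generate_sequence("MH", unif_heights, 200,
                         params = list(sigma = 1e-4), seed = 44)
  expect_gt(repetitions(s), 0.95)
  st <- strip_repeats(s)
  d <- distances(st)
  expect_true(is.na(d) || d <= 1)
})
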