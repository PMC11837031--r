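test_that("quantile normalisation maps ranks onto Gaussian scores", {
  # (10, 20, 30): ranks 1..3 -> qnorm((r - 0.5)/3)
  expect_equal(quantile_normalise(c(10, 20, 30)),
               qnorm(c(1, 3, 5) / 6))
  expect_equal(round(quantile_normalise(c(10, 20, 30)), 3),
               c(-0.967, 0, 0.967))

  # rank invariance under strictly monotone transforms
  withr::with_seed(51, {
    x <- rnorm(40)
    expect_equal(quantile_normalise(exp(x)), quantile_normalise(x))
    expect_equal(quantile_normalise(3 * x - 10), quantile_normalise(x))
  })

  # symmetric rank pattern sums to zero; ties get average ranks
  expect_equal(sum(quantile_normalise(c(4, 8, 15, 16, 23))), 0)
  qn <- quantile_normalise(c(1, 2, 2, 3))
  expect_equal(qn[2], qn[3])
  expect_equal(qn[2], qnorm((2.5 - 0.5) / 4))

  # missingness preserved; degenerate input rejected
  qn <- quantile_normalise(c(5, NA, 7, 9))
  expect_true(is.na(qn[2]) && !anyNA(qn[-2]))
  expect_error(quantile_normalise(rep(1, 10)), "identical")
  expect_error(quantile_normalise(c(1, 2)), "at least 3")
})

test_that("linear association recovers closed-form least squares", {
  # identity fit
  withr::with_seed(52, x <- rnorm(30))
  fit <- suppressWarnings(fit_linear_assoc(x, x))
  expect_equal(fit$beta, 1)
  expect_lt(fit$p_raw, 1e-20)

  # orthogonal IDP at large n: slope near zero
  withr::with_seed(53, {
    y <- rnorm(5000); x <- rnorm(5000)
  })
  fit <- fit_linear_assoc(y, x)
  expect_lt(abs(fit$beta), 3 * fit$se)

  # 6-point hand dataset vs the normal-equations solution
  y6 <- c(1.2, 0.7, -0.3, 2.1, 1.4, -0.9)
  x6 <- c(0.5, 0.1, -1.0, 1.3, 0.8, -1.2)
  z6 <- c(1, 0, 1, 0, 1, 0)
  X <- cbind(1, x6, z6)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y6)
  fit <- fit_linear_assoc(y6, x6, data.frame(z = z6))
  expect_equal(fit$beta, unname(beta_hat[2, 1]))

  # rank deficiency is named, not silently dropped
  expect_error(fit_linear_assoc(rnorm(20), 1:20, data.frame(dup = 2 * (1:20))),
               "collinear.*dup|dup.*collinear")
})

test_that("ordinal association matches logistic regression on 2 levels", {
  withr::with_seed(54, {
    x <- rnorm(400)
    eta <- 0.8 * x
    y2 <- factor(ifelse(runif(400) < plogis(eta), "b", "a"),
                 levels = c("a", "b"), ordered = TRUE)
  })
  fit <- fit_ordinal_assoc(y2, x)
  glm_fit <- glm(I(y2 == "b") ~ x, family = binomial)
  expect_equal(fit$beta, unname(coef(glm_fit)["x"]), tolerance = 1e-4)

  # independent IDP at large n: log-odds near zero
  withr::with_seed(55, {
    x <- rnorm(5000)
    y <- cut(rlogis(5000), c(-Inf, -1, 1, Inf), labels = c("a", "b", "c"),
             ordered_result = TRUE)
  })
  fit <- fit_ordinal_assoc(y, x)
  expect_lt(abs(fit$beta), 3 * fit$se)

  # degenerate outcomes are rejected with a diagnostic
  one_level <- factor(rep("a", 50), levels = c("a", "b"),
                      ordered = TRUE)
  expect_error(fit_ordinal_assoc(one_level, rnorm(50)), "single")
  sep_y <- factor(rep(c("a", "b"), each = 25), levels = c("a", "b"),
                  ordered = TRUE)
  sep_x <- c(rnorm(25, -10), rnorm(25, 10))
  suppressWarnings(
    expect_error(fit_ordinal_assoc(sep_y, sep_x), "separation|failed"))
})

test_that("ordinal parameter recovery is unbiased at moderate n", {
  # 20 replicates here as a quick check; the full 200-replicate study runs
  # with the acceptance suite
  est <- withr::with_seed(56, {
    vapply(1:20, function(i) {
      x <- rnorm(2000)
      y <- cut(0.7 * x + rlogis(2000), c(-Inf, -1.1, 1.1, Inf),
               labels = c("a", "b", "c"), ordered_result = TRUE)
      fit_ordinal_assoc(y, x)$beta
    }, numeric(1))
  })
  expect_lt(abs(mean(est) - 0.7), 3 * sd(est) / sqrt(length(est)))
})

test_that("Simes p equals its enumeration oracle and sits between bounds", {
  expect_equal(simes_p(c(0.01, 0.03, 0.04)), 0.03)
  expect_equal(simes_p(rep(1, 5)), 1)
  expect_equal(simes_p(0.2), 0.2)
  expect_error(simes_p(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(simes_p(numeric()), "empty")

  withr::with_seed(57, {
    for (rep in 1:20) {
      p <- runif(sample(1:10, 1))^sample(1:3, 1)
      s <- simes_p(p)
      expect_equal(s, oracle_simes(p))
      expect_gte(s, min(p))
      expect_lte(s, min(1, length(p) * min(p)))
    }
  })
})

test_that("BH step-up matches the exhaustive threshold-search oracle", {
  out <- bh_reject(c(0.001, 0.02, 0.03, 0.9), 0.05)
  expect_equal(sum(out$reject), 3L)
  expect_equal(out$reject, out$p_adj <= 0.05)

  expect_equal(sum(bh_reject(0.2, 0.05)$reject), 0L)
  expect_equal(nrow(bh_reject(numeric(), 0.05)), 0L)

  withr::with_seed(58, {
    for (rep in 1:30) {
      p <- runif(sample(1:10, 1))^sample(1:3, 1)
      q <- runif(1, 0.01, 0.2)
      got <- bh_reject(p, q)
      expect_identical(got$reject, oracle_bh_reject(p, q))
      # independent cross-check of adjusted p-values
      expect_equal(got$p_adj, p.adjust(p, "BH"))
    }
  })

  # rejections are non-decreasing in the level
  withr::with_seed(59, p <- runif(15)^2)
  n_rej <- vapply(c(0.01, 0.05, 0.1, 0.3),
                  function(q) sum(bh_reject(p, q)$reject), integer(1))
  expect_true(all(diff(n_rej) >= 0))
})

test_that("hierarchical FDR follows the two-stage hand trace", {
  # Simes: A = 0.002, B = 0.95, C = 0.9; stage-1 BH at 0.05 selects A only;
  # stage-2 level 0.05/3 rejects exactly A's p = 0.001
  h <- hierarchical_fdr(list(A = c(0.001, 0.2), B = c(0.9, 0.95),
                             C = c(0.8, 0.9)), q = 0.05)
  expect_equal(h$family$simes_p, c(0.002, 0.95, 0.9))
  expect_identical(h$family$selected, c(TRUE, FALSE, FALSE))
  expect_equal(h$stage2_level, 0.05 / 3)
  rejected <- h$tests[h$tests$rejected, ]
  expect_equal(nrow(rejected), 1L)
  expect_equal(rejected$family, "A")
  expect_equal(rejected$p_raw, 0.001)

  # all-null families: nothing selected, nothing rejected
  h0 <- hierarchical_fdr(list(A = rep(1, 4), B = rep(1, 4)))
  expect_equal(h0$r_selected, 0L)
  expect_false(any(h0$tests$rejected))

  # a single family reduces to plain BH at q behind a Simes gate
  withr::with_seed(60, p <- runif(20)^3)
  h1 <- hierarchical_fdr(list(only = p), q = 0.05)
  if (h1$r_selected == 1) {
    expect_identical(h1$tests$rejected, oracle_bh_reject(p, 0.05))
    expect_equal(h1$stage2_level, 0.05)
  }
  # rejected tests only ever sit in selected families
  expect_true(all(h1$tests$family[h1$tests$rejected] %in%
                    h1$family$family[h1$family$selected]))
})

test_that("the hierarchical procedure controls FDR in a quick simulation", {
  sim <- simulate_hierarchical_fdr(n_rep = 300, seed = 61)
  fdr_hat <- mean(sim$fdp)
  mc_se <- sd(sim$fdp) / sqrt(nrow(sim))
  expect_lte(fdr_hat, 0.05 + 2 * mc_se)
  expect_gt(mean(sim$n_rejected), 0)
})
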