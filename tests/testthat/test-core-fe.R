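test_that("standardize centers and rescales every sample column", {
  em <- make_em(cbind(c(1, 2, 3), c(10, 50, 90)), time_h = c(1, 48))
  sm <- standardize(em)
  expect_equal(sm$values[, 1], c(-1.224744871391589, 0, 1.224744871391589),
               ignore_attr = TRUE)
  expect_equal(colSums(sm$values), c(0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(colSums(sm$values^2), c(3, 3), ignore_attr = TRUE)
  # idempotence: standardizing a standardized matrix changes nothing
  sm2 <- standardize(sm)
  expect_equal(sm2$values, sm$values, tolerance = 1e-12)
  # zero-variance column is an error naming the sample
  bad <- make_em(cbind(c(1, 2, 3), c(7, 7, 7)), time_h = c(1, 2))
  expect_error(standardize(bad), "zero-variance.*s02")
})

test_that("standardize satisfies the column constraints on a large random matrix", {
  set.seed(8)
  em <- make_em(matrix(rexp(500 * 7, rate = 0.01), 500), time_h = c(1, 2, 4, 8, 12, 24, 48))
  sm <- standardize(em)
  n <- nrow(sm$values)
  expect_true(all(abs(colSums(sm$values)) < 1e-8 * n))
  expect_true(all(abs(colSums(sm$values^2) - n) < 1e-6 * n))
})

test_that("decompose: rank-1 exactness, reconstruction, orthogonality, signs", {
  u <- c(3, 0, 4) / 5
  v <- c(1, 2, 2) / 3
  em <- make_em(5 * outer(u, v), time_h = c(1, 2, 3))
  d <- decompose(structure(list(values = em$values, condition = em$condition,
                                time_h = em$time_h),
                           class = c("StandardizedMatrix", "ExpressionMatrix")))
  expect_equal(d$singular_values[1], 5, tolerance = 1e-10)
  expect_true(all(d$singular_values[-1] < 1e-10))
  set.seed(21)
  sm <- standardize(make_em(matrix(rnorm(350), 50), time_h = c(1, 2, 4, 8, 12, 24, 48)))
  d <- decompose(sm)
  recon <- d$probe_scores %*% diag(d$singular_values) %*% t(d$sample_loadings)
  expect_lt(norm(recon - sm$values, "F") / norm(sm$values, "F"), 1e-10)
  expect_equal(crossprod(d$probe_scores), diag(7), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(crossprod(d$sample_loadings), diag(7), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(!diff(d$singular_values) > 0))
  # deterministic orientation: largest-magnitude probe score positive
  for (l in 1:7)
    expect_gt(d$probe_scores[which.max(abs(d$probe_scores[, l])), l], 0)
  expect_error(decompose(make_em(matrix(c(1, NA, 2, 3), 2), time_h = c(1, 2))),
               "non-finite")
})

test_that("permuting probe rows permutes probe scores and nothing else", {
  set.seed(33)
  sm <- standardize(make_em(matrix(rnorm(240), 40),
                            time_h = c(1, 2, 4, 8, 12, 24)))
  d <- decompose(sm)
  perm <- sample(40)
  smp <- structure(list(values = sm$values[perm, ], condition = sm$condition,
                        time_h = sm$time_h, n_probes = 40),
                   class = class(sm))
  dp <- decompose(smp)
  expect_equal(dp$singular_values, d$singular_values, tolerance = 1e-10)
  expect_equal(dp$sample_loadings, d$sample_loadings, tolerance = 1e-8)
  expect_equal(dp$probe_scores, d$probe_scores[perm, ], tolerance = 1e-8)
})

test_that("component-time association flags exactly the time-linear loadings", {
  times <- c(1, 2, 4, 8, 12, 24, 48)
  # hand-built decomposition: loadings column 2 proportional to time,
  # column 1 orthogonal to centered time
  tc <- times - mean(times)
  v1 <- rep(1, 7) / sqrt(7)             # constant: orthogonal to tc
  v2 <- tc / sqrt(sum(tc^2))
  d <- structure(list(singular_values = c(3, 2),
                      probe_scores = matrix(rnorm(20), 10),
                      sample_loadings = cbind(v1, v2),
                      condition = rep("treated", 7), time_h = times),
                 class = "DecompositionResult")
  assoc <- associate_components_with_time(d)
  expect_equal(assoc$component, c(1, 2))
  expect_equal(assoc$slope[1], 0, tolerance = 1e-12)
  expect_equal(assoc$p_value[1], 1, tolerance = 1e-9)
  expect_lt(assoc$p_value[2], 1e-10)
  expect_identical(assoc$selected, c(FALSE, TRUE))
  expect_true(all(assoc$adjusted_p >= assoc$p_value))
  # errors
  expect_error(associate_components_with_time(d, time_h = c(1, 2)), ">= 3")
  expect_error(associate_components_with_time(d, time_h = rep(2, 7)),
               "identical")
})

test_that("score_probes implements the standardized chi-squared score", {
  set.seed(2)
  u <- matrix(rnorm(300), 100)
  u[1, 1] <- 0
  d <- structure(list(singular_values = c(3, 2, 1), probe_scores = u,
                      sample_loadings = diag(3),
                      condition = rep("treated", 3), time_h = c(1, 2, 3)),
                 class = "DecompositionResult")
  rownames(d$probe_scores) <- sprintf("p%03d", 1:100)
  tab <- score_probes(d, selected = 1L, alpha_probe = 0.01)
  expect_equal(tab$statistic[1], 0)
  expect_equal(tab$p_value[1], 1)
  sigma <- sqrt(mean(u[, 1]^2))
  expect_equal(tab$statistic, (u[, 1] / sigma)^2)
  expect_equal(tab$p_value, pchisq(tab$statistic, 1, lower.tail = FALSE))
  expect_equal(tab$adjusted_p, bh_adjust(tab$p_value))
  expect_equal(attr(tab, "df"), 1L)
  expect_equal(unname(attr(tab, "sigma")), sigma)
  # multi-component: df = 2, statistic adds the standardized squares
  tab2 <- score_probes(d, selected = c(1L, 3L))
  s3 <- sqrt(mean(u[, 3]^2))
  expect_equal(tab2$statistic, (u[, 1] / sigma)^2 + (u[, 3] / s3)^2)
  expect_equal(tab2$p_value, pchisq(tab2$statistic, 2, lower.tail = FALSE))
  # sd mode differs from rms only through the scale estimate
  tabsd <- score_probes(d, selected = 1L, sigma_mode = "sd")
  expect_equal(tabsd$statistic, (u[, 1] / sd(u[, 1]))^2)
  expect_error(score_probes(d, integer()), "no time-associated component")
  expect_error(score_probes(d, 9L), "out of range")
})

test_that("run_pca_fe end to end: trend arm selects, null arm reports status", {
  em <- make_trend_em(seed = 4)
  planted <- attr(em, "planted")
  res <- run_pca_fe(em)
  expect_s3_class(res, "pca_fe_result")
  expect_identical(res$status, "ok")
  expect_true(length(res$selected_components) >= 1)
  sel <- res$scores$probe_id[res$scores$selected]
  expect_gte(mean(planted %in% sel), 0.9)   # recall at this fixed seed
  expect_gte(mean(sel %in% planted), 0.95)  # precision at this fixed seed
  expect_output(print(res), "probes selected")
  # pure-noise arm: no association, empty selection, no error
  set.seed(9)
  null_em <- make_em(matrix(rnorm(200 * 7), 200),
                     time_h = c(1, 2, 4, 8, 12, 24, 48))
  res0 <- run_pca_fe(null_em)
  if (res0$status == "no_time_associated_component") {
    expect_equal(nrow(res0$scores), 0)
    expect_length(res0$selected_components, 0)
  }
  # single_component restricts scoring to the strongest association
  res1 <- run_pca_fe(em, single_component = TRUE)
  expect_length(res1$selected_components, 1)
})
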