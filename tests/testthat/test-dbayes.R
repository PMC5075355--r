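fit2 <- dbayes(hcc_training_counts(), markers = c("ALB", "tumor_burden"))
pat2 <- c(ALB = 1L, tumor_burden = 3L)

test_that("single-division conditionals use the pattern-dependent denominator", {
  # counts: ALB division 1 = 15/60, tumor-burden division 3 = 12/13
  expect_equal(division_conditional(fit2, pat2, "ALB"), 15 / 27)
  expect_equal(division_conditional(fit2, pat2, "tumor_burden"), 12 / 27)
  expect_equal(division_conditional(fit2, pat2, "ALB", "nonrecurrence"),
               60 / 73)
  # shared denominator forces the d conditionals of a class to sum to 1
  for (cl in c("recurrence", "nonrecurrence")) {
    s <- division_conditional(fit2, pat2, "ALB", cl) +
      division_conditional(fit2, pat2, "tumor_burden", cl)
    expect_equal(s, 1)
  }
  # d = 1: any positive-count division has conditional 1
  fit1 <- dbayes(hcc_training_counts(), markers = "vp")
  expect_equal(division_conditional(fit1, c(vp = 1L), "vp"), 1)
  expect_equal(joint_conditional(fit1, c(vp = 1L)), 1)
})

test_that("joint conditionals and the worked posterior match hand arithmetic", {
  expect_equal(joint_conditional(fit2, pat2), (15 / 27) * (12 / 27))
  expect_equal(joint_conditional(fit2, pat2, "nonrecurrence"),
               (60 / 73) * (13 / 73))
  p <- posterior(fit2, pat2)
  expected <- (15 * 12 / 27^2) /
    ((15 * 12 / 27^2) + (60 * 13 / 73^2))
  expect_equal(unname(p$posterior["recurrence"]), expected,
               tolerance = 1e-12)
  expect_equal(round_half_up(unname(p$posterior["recurrence"]), 4), 0.6278)
  expect_equal(as.character(p$class), "recurrence")
  expect_false(p$tie)
})

test_that("posterior handles ties, degenerate priors and zero-count patterns", {
  mats <- list(m1 = cbind(recurrence = c(5L, 5L), nonrecurrence = c(5L, 5L)))
  rownames(mats$m1) <- c("d1", "d2")
  sym <- model_from_mats(mats, 10, 10)
  p <- posterior(sym, c(m1 = 1L))
  expect_equal(unname(p$posterior), c(0.5, 0.5))
  expect_true(p$tie)
  expect_equal(as.character(p$class), "recurrence")  # default tie-break
  sym2 <- model_from_mats(mats, 10, 10, tie_break = "nonrecurrence")
  expect_equal(as.character(posterior(sym2, c(m1 = 1L))$class),
               "nonrecurrence")
  # prior mass 1 on recurrence pins the posterior wherever P(x|w1) > 0
  pri <- model_from_mats(mats, 10, 10, prior = c(1, 0))
  expect_equal(unname(posterior(pri, c(m1 = 1L))$posterior), c(1, 0))
  # a zero-count division annihilates its class at smoothing 0 ...
  mats0 <- list(m1 = cbind(recurrence = c(0L, 10L),
                           nonrecurrence = c(4L, 6L)))
  rownames(mats0$m1) <- c("d1", "d2")
  z <- model_from_mats(mats0, 10, 10)
  expect_equal(unname(posterior(z, c(m1 = 1L))$posterior), c(0, 1))
  # ... and a pattern with zero counts in both classes is degenerate
  mats00 <- list(m1 = cbind(recurrence = c(0L, 10L),
                            nonrecurrence = c(0L, 10L)))
  rownames(mats00$m1) <- c("d1", "d2")
  z2 <- model_from_mats(mats00, 10, 10)
  p2 <- posterior(z2, c(m1 = 1L))
  expect_true(p2$degenerate)
  expect_true(all(is.nan(p2$posterior)))
  expect_equal(as.character(p2$class), "recurrence")
  # smoothing rescues the zero-count division
  zs <- model_from_mats(mats0, 10, 10, smoothing = 0.5)
  expect_gt(posterior(zs, c(m1 = 1L))$posterior[["recurrence"]], 0)
})

test_that("classifier agrees exactly with a direct evaluation of the rule", {
  set.seed(401)
  for (rep in 1:200) {
    n1 <- sample(1:25, 1); n2 <- sample(1:25, 1)
    mats <- random_count_table(n1 = n1, n2 = n2)
    fit <- model_from_mats(mats, n1, n2)
    pattern <- vapply(mats, function(m) sample(nrow(m), 1), integer(1))
    ours <- posterior(fit, pattern)
    ref <- oracle_posterior(mats, unname(pattern))
    if (all(is.nan(ref$posterior))) {
      expect_true(ours$degenerate)
    } else {
      expect_equal(unname(ours$posterior), ref$posterior,
                   tolerance = 1e-12)
      expect_equal(sum(ours$posterior), 1, tolerance = 1e-12)
      # shared-denominator identity per class
      for (cl in c("recurrence", "nonrecurrence")) {
        cc <- vapply(names(mats), function(mn)
          division_conditional(fit, pattern, mn, cl), numeric(1))
        if (!anyNA(cc) && !any(is.nan(cc)))
          expect_equal(sum(cc), 1, tolerance = 1e-12)
      }
    }
    # label swap symmetry
    swapped <- lapply(mats, function(m) {
      s <- m[, c(2, 1)]
      colnames(s) <- colnames(m)
      s
    })
    fs <- model_from_mats(swapped, n2, n1)
    ps <- posterior(fs, pattern)
    if (!ours$degenerate)
      expect_equal(unname(ps$posterior), unname(rev(ours$posterior)),
                   tolerance = 1e-12)
    # scaling all counts by a common positive integer preserves the decision
    k <- sample(2:5, 1)
    fk <- model_from_mats(lapply(mats, function(m) m * k), n1 * k, n2 * k)
    pk <- posterior(fk, pattern)
    if (!ours$degenerate)
      expect_equal(unname(pk$posterior), unname(ours$posterior),
                   tolerance = 1e-12)
  }
})

test_that("log-space evaluation matches direct products at high dimension", {
  set.seed(77)
  d <- 60
  mats <- random_count_table(n_markers = d, n1 = 20, n2 = 20)
  fit <- model_from_mats(mats, 20, 20)
  pattern <- vapply(mats, function(m) sample(nrow(m), 1), integer(1))
  ref <- oracle_posterior(mats, unname(pattern))
  ours <- posterior(fit, pattern)
  if (!all(is.nan(ref$posterior)))
    expect_equal(unname(ours$posterior), ref$posterior, tolerance = 1e-12)
  # direct product of 60 conditionals underflows toward 0 but the
  # posterior stays well-defined in log space
  expect_true(all(is.finite(ours$posterior)) || ours$degenerate)
})

test_that("fitting from data, counts and JSON give the same model", {
  sch <- hcc_marker_scheme()
  coh <- materialize_exact_counts(hcc_training_counts(), seed = 21)
  fd <- dbayes(coh, sch, markers = c("ALB", "vp", "ICG"))
  fc <- dbayes(count_divisions(coh, sch), markers = c("ALB", "vp", "ICG"))
  expect_identical(fd$counts$counts, fc$counts$counts)
  path <- withr::local_tempfile(fileext = ".json")
  dbayes_to_json(fd, path)
  fj <- dbayes_from_json(path)
  expect_identical(fj$counts$counts, fd$counts$counts)
  expect_identical(fj$n, fd$n)
  expect_identical(fj$prior, fd$prior)
  # predictions on raw records agree row-wise with posterior()
  test <- coh[sample(nrow(coh), 10), ]
  post <- predict(fd, test, type = "posterior")
  div <- discretize(test, sch, fd$markers)
  for (k in seq_len(nrow(test)))
    expect_equal(post[k, ], posterior(fd, div[k, ])$posterior)
  cls <- predict(fd, test)
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), c("recurrence", "nonrecurrence"))
})

test_that("model validation rejects inconsistent inputs", {
  expect_error(dbayes(hcc_training_counts(), markers = "bogus"),
               "not in count table")
  expect_error(dbayes(hcc_training_counts(), prior = c(0.7, 0.7)),
               "sum to 1")
  expect_error(dbayes(hcc_training_counts(), smoothing = -1))
  expect_error(posterior(fit2, c(ALB = 1L)), "lacks division index")
  expect_error(posterior(fit2, c(ALB = 1L, tumor_burden = 9L)),
               "invalid division index")
})
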