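test_that("tertile quotas use ceil tails with stable tie-breaking", {
  set.seed(2)
  lab214 <- stratify_by_tertiles(rnorm(214))
  expect_equal(unname(table(lab214)[c("high", "low")]), c(73L, 73L),
               ignore_attr = TRUE)
  expect_equal(attr(lab214, "counts"),
               c(high = 73, medium = 68, low = 73))

  lab9 <- stratify_by_tertiles(1:9, 1 / 3, 1 / 3)
  expect_equal(unname(table(lab9)), c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(as.character(lab9[1:3]), rep("low", 3))
  expect_equal(as.character(lab9[7:9]), rep("high", 3))

  expect_error(stratify_by_tertiles(1:10, 0.5, 0.5), "< 1")
  expect_error(stratify_by_tertiles(c(1, 2)), "at least 3")
})

test_that("total ties fill quotas deterministically in input order", {
  lab <- stratify_by_tertiles(rep(1, 10), 0.3, 0.3)
  # brute-force expectation: descending stable order is input order, so the
  # first ceil(0.3*10) = 3 become high, the last 3 low
  expect_equal(as.character(lab), c(rep("high", 3), rep("medium", 4),
                                    rep("low", 3)))
})

test_that("a separable problem is fit perfectly at small lambda", {
  set.seed(21)
  x <- rbind(matrix(rnorm(200, -3), 50, 4), matrix(rnorm(200, 3), 50, 4))
  y <- rep(c("no", "yes"), each = 50)
  m <- fit_lasso_discriminator(x, y, positive = "yes",
                               policy = lambda_policy("fixed", lambda = 1e-4))
  expect_equal(unname(predict(m, x, type = "class")), y)
})

test_that("the heavy-penalty limit is the intercept-only log-odds model", {
  set.seed(22)
  x <- matrix(rnorm(300), 100, 3)
  y <- c(rep("yes", 70), rep("no", 30))
  m <- fit_lasso_discriminator(x, y, positive = "yes",
                               policy = lambda_policy("fixed", lambda = 1e6))
  expect_equal(unname(m$weights), rep(0, 3))
  expect_equal(m$intercept, qlogis(0.7), tolerance = 1e-3)
})

test_that("single-class and non-finite inputs are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(
    fit_lasso_discriminator(x, rep("yes", 10), positive = "yes",
                            policy = lambda_policy("fixed", lambda = 0.1)),
    "2 classes")
  x[1, 1] <- NA
  expect_error(
    fit_lasso_discriminator(x, rep(c("yes", "no"), 5), positive = "yes",
                            policy = lambda_policy("fixed", lambda = 0.1)),
    "finite")
})

test_that("swapping class labels negates the model and flips probabilities", {
  set.seed(23)
  x <- matrix(rnorm(400), 100, 4)
  y <- ifelse(x[, 1] + rnorm(100, 0, 0.5) > 0, "a", "b")
  pol <- lambda_policy("fixed", lambda = 0.02)
  ma <- fit_lasso_discriminator(x, y, positive = "a", policy = pol)
  mb <- fit_lasso_discriminator(x, y, positive = "b", policy = pol)
  expect_equal(ma$weights, -mb$weights, tolerance = 1e-5)
  expect_equal(ma$intercept, -mb$intercept, tolerance = 1e-5)
  expect_equal(predict(ma, x), 1 - predict(mb, x), tolerance = 1e-5)
})

test_that("signs of planted generator weights are recovered at low noise", {
  d <- paper_descriptors()
  w <- default_true_weights(d)
  nz <- which(w != 0)
  tri <- sample_variant_library(214, seed = 31)
  scr <- simulate_thermostability(tri, generative_config(seed = 31), d)
  x <- encode_variants(as_triples(scr$records[c("pos1", "pos2", "pos3")]), d)
  act <- as.numeric(thermostability_activity(scr$records$activity_no_heat,
                                             scr$records$residual_activity))
  lab <- ifelse(stratify_by_tertiles(act) == "low", "non", "imp")
  m <- fit_lasso_discriminator(x, lab, positive = "imp",
                               policy = lambda_policy("cv", seed = 31))
  expect_equal(unname(sign(m$weights[nz])), unname(sign(w[nz])))
})

test_that("LOOCV is perfect on separable data and catches a planted mislabel", {
  set.seed(41)
  x <- cbind(c(rnorm(25, -4), rnorm(25, 4)), rnorm(50, 0, 0.1))
  y <- rep(c("no", "yes"), each = 25)
  pol <- lambda_policy("fixed", lambda = 1e-3)
  r <- loocv(x, y, positive = "yes", policy = pol)
  expect_equal(r$accuracy, 1)

  y_flip <- y
  y_flip[10] <- "yes"  # deep inside the "no" cluster
  r2 <- loocv(x, y_flip, positive = "yes", policy = pol)
  expect_equal(r2$accuracy, 49 / 50)
  expect_false(r2$per_sample$correct[10])
})

test_that("folds starved of a class fall back to majority with a flag", {
  set.seed(42)
  x <- matrix(rnorm(20), 10, 2)
  y <- c("yes", "yes", rep("no", 8))
  # suppress glmnet's small-class advisories on the 9-sample folds
  r <- suppressWarnings(loocv(x, y, positive = "yes",
                              policy = lambda_policy("fixed", lambda = 0.1)))
  # holding out either "yes" leaves a single-member class: majority fallback
  expect_true(all(r$per_sample$degenerate_fold[1:2]))
  expect_equal(r$per_sample$predicted[1:2], c("no", "no"))
  expect_false(any(r$per_sample$degenerate_fold[-(1:2)]))
})

test_that("candidate enumeration matches the combinatorial arithmetic", {
  space <- enumerate_triples()
  expect_equal(nrow(space), 8000L)
  expect_false(anyDuplicated(triple_strings(space)) > 0)
  obs <- sample_variant_library(214, seed = 1)
  expect_equal(nrow(enumerate_candidate_triples(obs)), 7786L)
  expect_equal(nrow(enumerate_candidate_triples(NULL)), 8000L)
  expect_equal(nrow(enumerate_candidate_triples(space)), 0L)
  expect_error(enumerate_candidate_triples(matrix(c("P", "X", "V"), 1)),
               "invalid residue")
})

test_that("enumeration agrees with brute-force nested loops on 4 letters", {
  ab <- c("A", "C", "D", "E")
  got <- enumerate_triples(ab)
  brute <- character(0)
  for (a in ab) for (b in ab) for (c in ab) {
    brute <- c(brute, paste0(a, b, c))
  }
  expect_identical(triple_strings(got), brute)
  obs <- got[c(1, 17, 40), ]
  expect_identical(triple_strings(enumerate_candidate_triples(obs, ab)),
                   setdiff(brute, brute[c(1, 17, 40)]))
})

test_that("constant classifiers keep all or no candidates at stage 1", {
  d <- paper_descriptors()
  cand <- enumerate_triples()[1:50, ]
  keep_all <- make_model(rep(0, 39), 1, positive = "improved",
                         negative = "non-improved")
  none <- make_model(rep(0, 39), -1, positive = "improved",
                     negative = "non-improved")
  s1 <- screen_stage1(keep_all, cand, d)
  expect_equal(nrow(s1$kept), 50L)
  expect_equal(s1$n_rejected, 0L)
  s2 <- screen_stage1(none, cand, d)
  expect_equal(nrow(s2$kept), 0L)
  expect_equal(s2$n_rejected, 50L)
})

test_that("raising a positively weighted feature never lowers the probability", {
  set.seed(51)
  for (i in 1:10) {
    p <- 6
    m <- make_model(rnorm(p), rnorm(1))
    x <- matrix(rnorm(p), 1, p)
    j <- sample(which(m$weights != 0), 1)
    x2 <- x
    x2[, j] <- x2[, j] + abs(rnorm(1))
    p1 <- predict(m, x)
    p2 <- predict(m, x2)
    if (m$weights[j] > 0) expect_gte(p2, p1) else expect_lte(p2, p1)
  }
})

test_that("stage-2 ranking orders by probability with lexicographic ties", {
  d <- paper_descriptors()
  # all-zero model: every candidate ties, so ranking must be enumeration order
  m0 <- make_model(rep(0, 39), 0.3, positive = "high", negative = "medium")
  cand <- enumerate_triples()[c(30, 2, 700, 14), ]
  rk <- rank_stage2(m0, cand, d)
  expect_equal(rk$triple,
               triple_strings(enumerate_triples()[c(2, 14, 30, 700), ]))
  expect_equal(rk$rank, 1:4)
  # distinct probabilities sort descending
  set.seed(52)
  m <- make_model(rnorm(39, sd = 0.2), 0)
  rk2 <- rank_stage2(m, enumerate_triples()[1:100, ], d)
  expect_true(all(diff(rk2$p_high) <= 0))
  expect_equal(rk2$rank, 1:100)
  # empty candidate list is a valid empty ranking
  expect_equal(nrow(rank_stage2(m, enumerate_triples()[0, ], d)), 0L)
})

test_that("ranking tracks the latent score on a low-noise synthetic screen", {
  d <- paper_descriptors()
  w <- default_true_weights(d)
  cfg <- generative_config(seed = 61, noise_sd = 0.1)
  tri <- sample_variant_library(214, seed = 61)
  scr <- simulate_thermostability(tri, cfg, d)
  x <- encode_variants(as_triples(scr$records[c("pos1", "pos2", "pos3")]), d)
  act <- as.numeric(thermostability_activity(scr$records$activity_no_heat,
                                             scr$records$residual_activity))
  lab <- stratify_by_tertiles(act)
  hm <- lab %in% c("high", "medium")
  m2 <- fit_lasso_discriminator(x[hm, ], as.character(lab[hm]), "high",
                                policy = lambda_policy("cv", seed = 61))
  cand <- enumerate_candidate_triples(tri)[1:500, ]
  rk <- rank_stage2(m2, cand, d)
  sc <- fit_scaler(encode_variants(enumerate_triples(), d))
  latent <- drop(apply_scaler(
    encode_variants(as_triples(rk[, c("pos1", "pos2", "pos3")]), d), sc) %*% w)
  rho <- cor(rk$rank, latent, method = "spearman")
  expect_lt(rho, -0.9)  # rank 1 is best, so correlation is strongly negative
})

test_that("candidate selection honours quotas, shortfalls and disjointness", {
  rk <- data.frame(rank = 1:40, pos1 = "A", pos2 = "A",
                   pos3 = rep(aa_alphabet()[1:20], 2),
                   triple = sprintf("t%02d", 1:40),
                   p_high = c(seq(0.95, 0.55, length.out = 25),
                              seq(0.45, 0.20, length.out = 15)))
  # 25 entries above 0.5, 15 below
  expect_equal(sum(rk$p_high > 0.5), 25L)
  expect_warning(sel <- select_top_candidates(rk, 20, 20), "only 15")
  expect_equal(nrow(sel$high), 20L)
  expect_equal(nrow(sel$medium), 15L)
  expect_length(intersect(sel$high$rank, sel$medium$rank), 0L)
  expect_equal(nrow(select_top_candidates(rk, 0, 5)$high), 0L)
  # disjointness over random rankings
  set.seed(71)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    r <- data.frame(rank = 1:n, p_high = sort(runif(n), decreasing = TRUE))
    nh <- sample(0:n, 1); nm <- sample(0:n, 1)
    sel <- suppressWarnings(select_top_candidates(r, nh, nm))
    expect_length(intersect(sel$high$rank, sel$medium$rank), 0L)
    expect_lte(nrow(sel$high), nh)
    expect_lte(nrow(sel$medium), nm)
  }
})

test_that("weight tables reshape position-major and round-trip", {
  d <- paper_descriptors()
  w <- rep(0, 39)
  names(w) <- names(default_true_weights(d))
  # headline cell: side-chain stability contribution at the first position
  w["pos1_SYNSCS0105"] <- -0.348
  m <- make_model(w, 0, positive = "high", negative = "medium")
  tab <- extract_weight_table(m, d$info$description)
  expect_equal(tab["Side-chain contribution to protein stability", "pos1"],
               -0.348)
  expect_equal(sum(tab != 0), 1L)
  expect_equal(as.numeric(tab), unname(w))
  m0 <- make_model(rep(0, 39), 0)
  expect_true(all(extract_weight_table(m0, d$info$description) == 0))
  expect_error(extract_weight_table(m, d$info$description[1:5]), "expected 15")
})
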