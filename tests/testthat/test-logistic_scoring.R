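make_dv <- function(n = 1, rmsddm = 0.2, e_inc = 3, f = 1,
                    n_removed = 0L, backbone_rmsd = 0.3, d_c = 3,
                    n_T = 3) {
  tibble::tibble(rmsddm = rmsddm, e_inc = e_inc,
                 n_exc = n_T * (1 - f), f = f, n_removed = n_removed,
                 backbone_rmsd = backbone_rmsd, d_c = d_c,
                 inv_dc = 1 / (d_c + 0.1),
                 interaction = f * e_inc / (d_c + 0.1), n_T = n_T)[
                   rep(1, n), ]
}

test_that("size bins follow the Heaviside-like switch", {
  expect_equal(size_bin(2), "2")
  expect_equal(size_bin(3), "3")
  expect_equal(size_bin(c(4, 5, 6, 7)), rep("4-7", 4))
  expect_equal(size_bin(15), "4-7")
  expect_error(size_bin(1), "n_T >= 2")
})

test_that("scores are sigmoid probabilities and respond to descriptors", {
  # zero linear predictor scores exactly 0.5
  m0 <- new_logistic_model(0, tibble::tibble(
    descriptor = character(0), bin = character(0), beta = numeric(0),
    transform = character(0)))
  expect_equal(score_hits(m0, make_dv()), 0.5)

  # monotone in the linear predictor: a negative rmsddm weight means
  # lower rmsddm never lowers the score
  m1 <- new_logistic_model(0, tibble::tibble(
    descriptor = "rmsddm", bin = "all", beta = -2,
    transform = "identity"))
  s <- score_hits(m1, make_dv(rmsddm = c(0, 0.5, 1.0, 1.5)))
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s < 1))

  # bundled final model: in the 4-7 bin the pocket-proximity pathway is
  # strictly positive (18.61 on (d_c+0.1)^-1 plus 3.18 on the interaction
  # term), so moving a match closer to a pocket center never lowers its
  # score
  final <- bundled_model("final")
  d_seq <- c(10, 5, 2, 1, 0.5)
  dv_seq <- make_dv(n = 5, rmsddm = 0.3, e_inc = 6, f = 1,
                    backbone_rmsd = 0.5, d_c = d_seq, n_T = 5)
  dv_seq$d_c <- d_seq
  dv_seq$inv_dc <- 1 / (d_seq + 0.1)
  dv_seq$interaction <- dv_seq$f * dv_seq$e_inc * dv_seq$inv_dc
  expect_true(all(diff(score_hits(final, dv_seq)) > 0))

  # the 4-7 bin pocket term only applies in its bin
  dv47 <- make_dv(n_T = 5)
  dv2 <- make_dv(n_T = 2)
  expect_error(score_hits(final, dplyr::select(dv47, -"rmsddm")),
               "rmsddm")
})

test_that("all bundled models expose the published structure", {
  for (which in c("initial", "minimal", "intermediate", "final")) {
    m <- bundled_model(which)
    expect_s3_class(m, "logistic_model")
    expect_equal(m$provenance, which)
    td <- tidy(m)
    expect_equal(td$descriptor[1], "(Intercept)")
  }
  final <- bundled_model("final")
  expect_equal(final$intercept, -4.8)
  expect_equal(final$terms$beta[final$terms$descriptor == "f"], -1.73)
  dc_term <- final$terms[final$terms$descriptor == "d_c", ]
  expect_equal(dc_term$bin, "4-7")
  expect_equal(dc_term$transform, "inv_dc")
  expect_equal(nrow(bundled_model("minimal")$terms), 2)
})

test_that("maximum-likelihood fitting recovers known coefficients", {
  set.seed(77)
  n <- 2000
  dv <- tibble::tibble(
    rmsddm = runif(n, 0, 1.5),
    f = runif(n, 0.3, 1),
    backbone_rmsd = runif(n, 0, 4),
    n_T = sample(c(2, 3, 5), n, replace = TRUE))
  dv$e_inc <- 2
  dv$n_removed <- 0L
  dv$d_c <- runif(n, 0.5, 20)
  dv$inv_dc <- 1 / (dv$d_c + 0.1)
  dv$interaction <- dv$f * dv$e_inc * dv$inv_dc
  beta_true <- c(`(Intercept)` = 1.0, rmsddm = -2.5, f = 2.0,
                 backbone_rmsd = -0.8)
  eta <- beta_true[1] + beta_true[2] * dv$rmsddm + beta_true[3] * dv$f +
    beta_true[4] * dv$backbone_rmsd
  dv$label <- runif(n) < plogis(eta)
  spec <- tibble::tibble(descriptor = c("rmsddm", "f", "backbone_rmsd"),
                         by_bin = FALSE, transform = "identity")
  m <- fit_logistic(dv, spec)
  ct <- m$coef_table
  expect_equal(nrow(ct), 4)
  z <- abs(ct$estimate - beta_true) / ct$std_error
  expect_true(all(z < 2))
  expect_true(is.finite(m$aic))

  # labels independent of descriptors: slopes within 2 SE of zero
  dv$label <- runif(n) < 0.5
  m0 <- fit_logistic(dv, spec)
  z0 <- abs(m0$coef_table$estimate[-1]) / m0$coef_table$std_error[-1]
  expect_true(all(z0 < 2.5))

  # single-class input errors
  dv$label <- TRUE
  expect_error(fit_logistic(dv, spec), "both positive and negative")
})

test_that("fitted models reproduce the training predictions through score_hits", {
  set.seed(3)
  n <- 400
  dv <- make_dv(n)
  dv$rmsddm <- runif(n, 0, 1.5)
  dv$f <- runif(n, 0.3, 1)
  dv$n_T <- sample(c(2, 3, 5), n, replace = TRUE)
  dv$label <- runif(n) < plogis(1 - 2 * dv$rmsddm)
  spec <- tibble::tibble(descriptor = c("rmsddm", "f"),
                         by_bin = c(TRUE, FALSE), transform = "identity")
  m <- fit_logistic(dv, spec)
  expect_equal(unname(score_hits(m, dv)),
               unname(fitted(m$fit)), tolerance = 1e-8)
})

test_that("labels require exact four-field EC agreement", {
  hits <- tibble::tibble(site_ec = c("3.2.1.17", "3.2.1.18", "3.2.1.-",
                                     NA))
  out <- label_hits(hits, "3.2.1.17")
  expect_equal(out$label, c(TRUE, FALSE, FALSE, FALSE))
  expect_false(any(label_hits(hits, "3.2.1.-")$label))
})

test_that("duplicate hits keep only the best-scoring family member", {
  hits <- tibble::tibble(
    target_id = "t1",
    site_id = c("1xyz-0cx", "1xyz-0A", "1xyz-0B", "2abc-0"),
    family_id = c("1xyz", "1xyz", "1xyz", "2abc"),
    label = c(TRUE, TRUE, TRUE, FALSE),
    score = c(0.7, 0.9, 0.8, 0.4))
  out <- dedupe_hits(hits)
  expect_equal(nrow(out), 2)
  expect_equal(out$site_id[out$family_id == "1xyz"], "1xyz-0A")
  # ties keep the lexicographically smallest site_id
  hits$score <- c(0.9, 0.9, 0.9, 0.4)
  expect_equal(dedupe_hits(hits)$site_id[1], "1xyz-0A")
  # same family, different labels: one survivor each
  hits$label <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(nrow(dedupe_hits(hits)), 3)
})

test_that("evaluation produces correct AUC, MCC, and size-bin breakdown", {
  # perfectly separated scores
  h1 <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1),
                       label = c(TRUE, TRUE, FALSE, FALSE), n_T = 3)
  ev1 <- evaluate_hits(h1)
  expect_equal(ev1$auc, 1.0)
  # ROC is monotone along the threshold sweep
  expect_true(all(diff(ev1$roc$tpr[order(-ev1$roc$threshold)]) >= -1e-12))
  expect_true(all(diff(ev1$roc$fpr[order(-ev1$roc$threshold)]) >= -1e-12))

  # random labels vs scores: AUC near 1/2
  set.seed(11)
  h2 <- tibble::tibble(score = runif(1000),
                       label = runif(1000) < 0.5,
                       n_T = sample(2:5, 1000, replace = TRUE))
  ev2 <- evaluate_hits(h2)
  expect_lt(abs(ev2$auc - 0.5), 0.05)
  expect_setequal(ev2$by_bin$bin, c("2", "3", "4-7"))

  # balanced confusion at a threshold gives MCC 0
  h3 <- tibble::tibble(score = c(0.9, 0.9, 0.1, 0.1),
                       label = c(TRUE, FALSE, TRUE, FALSE), n_T = 2)
  ev3 <- evaluate_hits(h3)
  row <- ev3$roc[ev3$roc$threshold == 0.9, ]
  expect_equal(row$mcc, 0)

  expect_error(evaluate_hits(tibble::tibble(score = 0.5, label = TRUE,
                                            n_T = 2)),
               "both positive and negative")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  score <- runif(300)
  label <- runif(300) < plogis(3 * score - 1.5)
  if (length(unique(label)) < 2) skip("degenerate draw")
  ours <- evaluate_hits(tibble::tibble(score = score, label = label,
                                       n_T = 3))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = as.integer(label),
                                        predictor = score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  score <- runif(200)
  label <- runif(200) < score
  h <- tibble::tibble(score = score, label = label, n_T = 4)
  h2 <- dplyr::mutate(h, score = plogis(5 * score - 2))
  expect_equal(evaluate_hits(h)$auc, evaluate_hits(h2)$auc,
               tolerance = 1e-12)
})

test_that("models serialize to flat text and back", {
  m <- bundled_model("final")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$terms, m$terms)
  expect_equal(m2$provenance, "final")
  dv <- make_dv(n = 5, rmsddm = seq(0, 1, length.out = 5))
  expect_equal(score_hits(m2, dv), score_hits(m, dv))
})
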