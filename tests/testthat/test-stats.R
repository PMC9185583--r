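# Helper: balanced two-condition frame with known cell structure.
balanced_frame <- function(n_users = 4, n_box = 4, effect = 0, sd = 0.3,
                           seed = 1) {
  set.seed(seed)
  grid <- expand.grid(user = seq_len(n_users), box = seq_len(n_box),
                      exo = c("noexo", "exo"), weight = c(7, 8))
  u <- rnorm(n_users, 0, 0.5)
  grid$y <- 10 + 0.2 * grid$box + u[grid$user] +
    effect * (grid$exo == "exo") + rnorm(nrow(grid), 0, sd)
  data.frame(y = grid$y, exo = factor(grid$exo, c("noexo", "exo")),
             box = factor(grid$box), weight = factor(grid$weight),
             user = factor(grid$user))
}

test_that("Holm adjustment matches the step-down algorithm by hand", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.5), 0.5)
  expect_equal(holm_adjust(c(0.2, 0.9)), c(0.4, 0.9))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  expect_error(holm_adjust(c(0.5, 1.2)), class = "exolift_input_error")
})

test_that("Holm is permutation-invariant, monotone, never below raw p", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    perm <- sample(seq_along(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("percent change follows the reduction convention", {
  expect_equal(percent_change(0.92, 1.00), -8)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(1.017, 1.000), 1.7)
  expect_true(is.na(percent_change(1, 0)))
  # scale invariance
  expect_equal(percent_change(3 * 0.92, 3 * 1.00), -8)
})

test_that("the random intercept demands at least two users", {
  fr <- balanced_frame()
  one <- fr[fr$user == "1", ]
  expect_error(fit_mixed(one), regexp = "random",
               class = "exolift_input_error")
  noex <- fr[fr$exo == "noexo", ]
  expect_error(fit_mixed(noex), class = "exolift_input_error")
})

test_that("marginal means on a balanced design equal raw cell-mean averages", {
  fr <- balanced_frame(effect = -1)
  fit <- fit_mixed(fr)
  mm <- marginal_means(fit, "exo")
  raw <- tapply(fr$y, fr$exo, mean)  # balanced: uniform cell averaging
  expect_equal(mm$emmean[mm$exo == "noexo"], unname(raw["noexo"]),
               tolerance = 1e-8)
  expect_equal(mm$emmean[mm$exo == "exo"], unname(raw["exo"]),
               tolerance = 1e-8)
  # no condition effect in the data: both means equal the grand mean
  fr0 <- fr
  fr0$y <- ave(fr0$y, fr0$user, fr0$box, fr0$weight)  # symmetrise conditions
  fit0 <- fit_mixed(fr0)
  mm0 <- marginal_means(fit0, "exo")
  expect_equal(mm0$emmean, rep(mean(fr0$y), 2), tolerance = 1e-8)
})

test_that("exo-by-box means separate only where the effect lives", {
  set.seed(11)
  grid <- expand.grid(user = 1:6, box = 1:16, exo = c("noexo", "exo"),
                      weight = 7)
  grid$y <- 5 + rnorm(6)[grid$user] +
    ifelse(grid$exo == "exo" & grid$box >= 13, -2, 0) +
    rnorm(nrow(grid), 0, 0.2)
  fr <- data.frame(y = grid$y, exo = factor(grid$exo, c("noexo", "exo")),
                   box = factor(grid$box), weight = factor(grid$weight),
                   user = factor(grid$user))
  fit <- fit_mixed(fr)
  mm <- marginal_means(fit, c("exo", "box"))
  wide <- reshape(mm[, c("exo", "box", "emmean")], idvar = "box",
                  timevar = "exo", direction = "wide")
  gap <- wide$emmean.exo - wide$emmean.noexo
  late <- as.integer(as.character(wide$box)) >= 13
  expect_true(all(gap[late] < -1.5))
  expect_true(all(abs(gap[!late]) < 0.5))
})

test_that("ICC reflects the variance decomposition and its limits", {
  fr <- balanced_frame(n_users = 8, sd = 0.5, seed = 3)
  fit <- fit_mixed(fr)
  expect_gt(icc(fit), 0.2)
  expect_lt(icc(fit), 0.8)

  # near-zero subject variance
  set.seed(4)
  fr$y <- rnorm(nrow(fr))
  expect_lt(icc(fit_mixed(fr)), 0.2)

  # noiseless per-user outcome: ICC at the upper boundary without errors
  # (the optimizer may warn about round-off at the zero-residual boundary)
  fr$y <- as.numeric(fr$user)
  fit1 <- suppressWarnings(fit_mixed(fr))
  expect_gt(icc(fit1), 0.99)
})

test_that("run_effects analyses every variable-by-muscle pair", {
  cfg <- synth_config(n_subjects = 3, weights_kg = 8, n_boxes = 4, seed = 13)
  feats <- list()
  for (s in 1:3) for (cond in c("noexo", "exo")) {
    g <- generate_emg(cfg, s, cond, 8)
    feats[[paste(s, cond)]] <- extract_features(g$recording,
                                                g$truth$intervals)
  }
  features <- do.call(rbind, feats)
  res <- run_effects(features)
  expect_equal(nrow(res$effects), 5 * 4)
  expect_true(all(is.finite(res$effects$percent)))
  expect_true(all(is.finite(res$effects$p_holm)))
  expect_true(all(res$effects$p_holm >= res$effects$p - 1e-12))
  expect_equal(nrow(res$curves), 5 * 4 * 2 * cfg$n_boxes)
  expect_true(all(res$effects$stars[res$effects$p_holm > 0.05] == ""))
  # Holm families: per-variable by default
  for (v in unique(res$effects$variable)) {
    sel <- res$effects$variable == v
    expect_equal(res$effects$p_holm[sel], holm_adjust(res$effects$p[sel]))
  }
})
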