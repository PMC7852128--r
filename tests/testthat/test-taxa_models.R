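test_that("intercept-only NB with a constant offset recovers the mean rate", {
  y <- c(5, 10, 15)
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_nb(y, X, offset = rep(log(100), 3))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[1]), log(0.1), tolerance = 1e-6)
})

test_that("degenerate NB inputs are flagged, not raised", {
  X <- cbind("(Intercept)" = rep(1, 4))
  f0 <- fit_nb(rep(0, 4), X)
  expect_false(f0$converged)
  expect_match(f0$reason, "all-zero")
  Xr <- cbind(1, c(1, 1, 0, 0), c(2, 2, 0, 0))  # collinear
  fr <- fit_nb(c(1, 2, 3, 4), Xr)
  expect_false(fr$converged)
  expect_match(fr$reason, "rank-deficient")
  expect_error(fit_nb(c(-1, 2), cbind(1, 1)), "negative")
})

test_that("fit_nb agrees with MASS::glm.nb on overdispersed data", {
  set.seed(71)
  n <- 120
  x <- rnorm(n)
  d <- sample(1000:5000, n, TRUE)
  mu <- exp(-4 + 0.5 * x + log(d))
  y <- rnbinom(n, size = 3, mu = mu)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_nb(y, X, offset = log(d))
  ref <- MASS::glm.nb(y ~ x + offset(log(d)))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(fit$dispersion, ref$theta, tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("fit_nb approaches the Poisson GLM when data are equidispersed", {
  set.seed(72)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  y <- rpois(n, exp(1 + 0.4 * x))
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_nb(y, X)
  ref <- glm(y ~ x, family = poisson())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-3)
})

test_that("symmetric beta-binomial data give the closed-form intercept", {
  n <- rep(1000, 8)
  y <- rep(200, 8)  # every proportion exactly 0.2
  X <- cbind("(Intercept)" = rep(1, 8))
  fit <- fit_bb(y, n, X)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.2), tolerance = 1e-4)
})

test_that("fit_bb approaches the binomial GLM as rho -> 0", {
  set.seed(73)
  n <- sample(500:2000, 100, TRUE)
  x <- rbinom(100, 1, 0.5)
  y <- rbinom(100, n, plogis(-2 + 0.5 * x))  # pure binomial data
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_bb(y, n, X)
  ref <- glm(cbind(y, n - y) ~ x, family = binomial())
  expect_lt(fit$dispersion, 0.01)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-2)
})

test_that("fit_bb matches glmmTMB's beta-binomial on overdispersed data", {
  skip_if_not_installed("glmmTMB")
  set.seed(74)
  n <- sample(1000:4000, 80, TRUE)
  x <- rnorm(80)
  mu <- plogis(-2 + 0.6 * x)
  rho <- 0.08
  p <- rbeta(80, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho)
  y <- rbinom(80, n, p)
  fit <- fit_bb(y, n, cbind("(Intercept)" = 1, x = x))
  ref <- glmmTMB::glmmTMB(cbind(y, n - y) ~ x, data = data.frame(y, n, x),
                          family = glmmTMB::betabinomial)
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("taxa_models partitions taxa, names coefficients by level, and
           reacts to the offset", {
  ms <- sim_ms(seed = 41, n_lib = 30, n_taxa = 10)
  mods <- suppressMessages(nb_mods(ms, "Genus", ~ Group))
  expect_s3_class(mods, "taxa_models")
  expect_equal(length(mods$fits) + length(mods$failed), 10)
  f1 <- mods$fits[[1]]
  expect_identical(names(f1$coefficients), c("(Intercept)", "GroupYes"))
  # unequal depths: dropping the offset must move the estimates
  mods_no <- suppressMessages(nb_mods(ms, "Genus", ~ Group, offset = FALSE))
  tx <- intersect(names(mods$fits), names(mods_no$fits))[1]
  expect_gt(abs(mods$fits[[tx]]$coefficients["(Intercept)"] -
                  mods_no$fits[[tx]]$coefficients["(Intercept)"]), 0.01)
  expect_error(suppressMessages(nb_mods(ms, "Genus", ~ NotAColumn)),
               "NotAColumn")
})

test_that("covariate LRT: df follows the coding, null term gives p near 1", {
  ms <- sim_ms(seed = 42, n_lib = 40, n_taxa = 6)
  mods <- suppressMessages(nb_mods(ms, "Genus", ~ Group + Smoking))
  lrt <- suppressMessages(covariate_lrt(mods, "Smoking"))
  expect_true(all(lrt$df == 2))  # 3-level factor
  lrt_g <- suppressMessages(covariate_lrt(mods, "Group"))
  expect_true(all(lrt_g$df == 1))
  expect_true(all(lrt$p >= 0 & lrt$p <= 1, na.rm = TRUE))
  expect_error(covariate_lrt(mods, "Age"), "not in the model")
})

test_that("profile intervals contain the MLE and approach Wald at large n", {
  set.seed(43)
  sim <- simulate_micro(n_lib = 150, n_taxa = 5, seed = 43,
                        effects = data.frame(taxon = 2, covariate = "Group",
                                             beta = 0.5))
  ms <- suppressMessages(build_micro_set(sim$otu_tabs, sim$clinical, "Lib"))
  mods <- suppressMessages(nb_mods(ms, "Genus", ~ Group))
  pci <- suppressMessages(profile_ci(mods))
  expect_true(all(pci$ci_low < pci$Estimate & pci$Estimate < pci$ci_high))
  wald <- taxa_summary(mods, ci = "wald")
  j <- dplyr::inner_join(pci, wald, by = c("Taxa", "Coefficient"),
                         suffix = c("_p", "_w"))
  width_p <- j$ci_high_p - j$ci_low_p
  width_w <- j$ci_high_w - j$ci_low_w
  expect_true(all(abs(width_p - width_w) / width_w < 0.05))
})

test_that("bh_adjust equals the brute-force step-up definition", {
  step_up <- function(p) {  # independent oracle
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.9)), c(0.015, 0.06, 0.9))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(44)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("estimate_table implements the interaction contrast algebra", {
  # hand-built model set: one taxon, known coefficients and covariance
  cf <- c("(Intercept)" = -1, "GroupYes" = 0.5, "GroupYes:Age" = 0.2)
  V <- matrix(0, 3, 3, dimnames = list(names(cf), names(cf)))
  diag(V) <- c(0.01, 0.04, 0.09)
  V["GroupYes", "GroupYes:Age"] <- V["GroupYes:Age", "GroupYes"] <- -0.02
  fit <- microtide:::new_taxa_fit("T1", coefs = cf, cov = V, loglik = 0,
                                  converged = TRUE, n_obs = 10,
                                  family = "negbin")
  models <- structure(list(fits = list(T1 = fit), failed = list()),
                      class = "taxa_models")
  est <- estimate_table(models, level = 0.95)
  row <- est[est$Coefficient == "GroupYes + GroupYes:Age", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$ratio, exp(0.7), tolerance = 1e-6)
  expect_equal(row$ratio, 2.014, tolerance = 1e-3)
  expect_equal(row$ci_low, exp(0.7 - qnorm(0.975) * 0.3), tolerance = 1e-6)
  expect_equal(row$ci_high, exp(0.7 + qnorm(0.975) * 0.3), tolerance = 1e-6)
  expect_equal(c(row$ci_low, row$ci_high), c(1.119, 3.625), tolerance = 1e-3)
  # plain rows are identity contrasts with symmetric log-scale CIs
  expect_true(all(abs(log(est$ci_high / est$ratio) -
                        log(est$ratio / est$ci_low)) < 1e-9))
  plain <- est[est$Coefficient == "GroupYes", ]
  expect_equal(plain$ratio, exp(0.5))
})

test_that("a zero coefficient yields ratio 1 with a CI straddling 1", {
  cf <- c("(Intercept)" = -1, "x" = 0)
  V <- diag(c(0.01, 0.04))
  dimnames(V) <- list(names(cf), names(cf))
  fit <- microtide:::new_taxa_fit("T1", coefs = cf, cov = V, loglik = 0,
                                  converged = TRUE, n_obs = 10,
                                  family = "negbin")
  models <- structure(list(fits = list(T1 = fit), failed = list()),
                      class = "taxa_models")
  est <- estimate_table(models)
  row <- est[est$Coefficient == "x", ]
  expect_equal(row$ratio, 1)
  expect_lt(row$ci_low, 1)
  expect_gt(row$ci_high, 1)
})

test_that("taxa_summary has the expected columns and FDR pooling", {
  ms <- sim_ms(seed = 45, n_lib = 30, n_taxa = 6)
  mods <- suppressMessages(nb_mods(ms, "Genus", ~ Group))
  s <- suppressMessages(taxa_summary(mods, ci = "wald"))
  expect_named(s, c("Taxa", "Coefficient", "Estimate", "ci_low", "ci_high",
                    "z", "p", "fdr_p", "lrt_term", "lrt_p"))
  # FDR recomputed by hand within one coefficient label
  sub <- s[s$Coefficient == "GroupYes", ]
  expect_equal(sub$fdr_p, bh_adjust(sub$p))
  expect_true(all(s$lrt_term[s$Coefficient == "GroupYes"] == "Group"))
})

test_that("rank tests reproduce the exact enumeration and KW hand values", {
  # {1,2,3} vs {4,5,6}: exact two-sided p = 0.1
  m <- matrix(0L, nrow = 2, ncol = 6,
              dimnames = list(c("A", "B"), paste0("L", 1:6)))
  m["A", ] <- c(10L, 20L, 30L, 40L, 50L, 60L)  # ra strictly increasing
  m["B", ] <- c(90L, 80L, 70L, 60L, 50L, 40L)
  clin <- tibble::tibble(Lib = paste0("L", 1:6),
                         Group = factor(rep(c("g1", "g2"), each = 3)))
  ms <- build_micro_set(otu_tbl("Genus", m), clin, lib_col = "Lib")
  out <- rank_taxa_test(ms, "Genus", "Group", on = "ra")
  expect_equal(out$p[out$Taxa == "A"], 0.1)
  expect_equal(unname(out$statistic[out$Taxa == "A"]), 0)  # W = rank sum - 6
  # Kruskal-Wallis on ranks 1..6 split (1,2,3),(4,5,6): H = 3.857
  clin3 <- tibble::tibble(Lib = paste0("L", 1:6),
                          Group = factor(c("a", "a", "a", "b", "b", "b")))
  ms3 <- build_micro_set(otu_tbl("Genus", m), clin3, lib_col = "Lib")
  # force the KW branch with 3 groups on a 9-library version
  m9 <- matrix(0L, 2, 9, dimnames = list(c("A", "B"), paste0("L", 1:9)))
  m9["A", ] <- as.integer(seq(10, 90, 10))
  m9["B", ] <- as.integer(100 - seq(10, 90, 10))
  clin9 <- tibble::tibble(Lib = paste0("L", 1:9),
                          Group = factor(rep(c("a", "b", "c"), each = 3)))
  ms9 <- build_micro_set(otu_tbl("Genus", m9), clin9, lib_col = "Lib")
  out9 <- rank_taxa_test(ms9, "Genus", "Group")
  ref <- kruskal.test(seq(10, 90, 10) ~ rep(c("a", "b", "c"), each = 3))
  expect_equal(unname(out9$statistic[out9$Taxa == "A"]),
               unname(ref$statistic))
  # two-group KW hand value on 6 ranks: 12/(6*7) * sum n(rbar - 3.5)^2
  expect_equal(unname(kruskal.test(1:6 ~ clin3$Group)$statistic), 3.857,
               tolerance = 1e-3)
})

test_that("presence chi-square: perfect split gives 20, degenerates flagged", {
  m <- matrix(0L, 2, 20, dimnames = list(c("A", "B"), sprintf("L%02d", 1:20)))
  m["A", 1:10] <- 5L       # present only in group g1
  m["B", ] <- 10L          # present everywhere -> degenerate
  clin <- tibble::tibble(Lib = sprintf("L%02d", 1:20),
                         Group = factor(rep(c("g1", "g2"), each = 10)))
  ms <- build_micro_set(otu_tbl("Genus", m), clin, lib_col = "Lib")
  out <- presence_chisq(ms, "Genus", "Group")
  expect_equal(unname(out$statistic[out$Taxa == "A"]), 20)
  expect_equal(unname(out$df[out$Taxa == "A"]), 1)
  expect_identical(out$flag[out$Taxa == "B"], "degenerate")
  expect_true(is.na(out$p[out$Taxa == "B"]))
})

test_that("failed_only restricts fallback tests to non-converged taxa", {
  set.seed(46)
  m <- random_counts(5, 16, lambda = 30)
  m[5, ] <- 0L  # guaranteed NB failure (all-zero taxon)
  ms <- make_ms(m)
  mods <- suppressMessages(nb_mods(ms, "Genus", ~ Group))
  expect_true(rownames(m)[5] %in% failed_taxa(mods))
  out <- rank_taxa_test(ms, "Genus", "Group", failed_only = mods)
  expect_setequal(out$Taxa, failed_taxa(mods))
})
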