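test_that("taxa_bars_data averages within groups and aggregates top taxa", {
  m <- cbind(L1 = c(60L, 40L), L2 = c(40L, 60L))
  rownames(m) <- c("A", "B")
  clin <- tibble::tibble(Lib = c("L1", "L2"), Group = factor(c("g", "g")))
  ms <- build_micro_set(otu_tbl("Genus", m), clin, lib_col = "Lib")
  bd <- taxa_bars_data(ms, "Genus", group = "Group")
  expect_equal(sort(bd$abundance), c(50, 50))
  # 3 taxa, top_taxa = 1 -> 2 categories, Other = sum of remaining means
  m3 <- cbind(L1 = c(50L, 30L, 20L), L2 = c(60L, 20L, 20L))
  rownames(m3) <- c("A", "B", "C")
  ms3 <- make_ms(m3)
  bd3 <- taxa_bars_data(ms3, "Genus", top_taxa = 1)
  expect_setequal(as.character(bd3$Taxa), c("A", "Other"))
  expect_equal(bd3$abundance[bd3$Taxa == "Other"], 25 + 20)
  expect_equal(levels(bd3$Taxa)[length(levels(bd3$Taxa))], "Other")
  expect_error(taxa_bars_data(ms3, "Genus", group = "Nope"), "Nope")
})

test_that("bar abundances always sum to 100 per bar", {
  set.seed(61)
  for (rep in 1:4) {
    ms <- sim_ms(seed = rep, n_lib = 12, n_taxa = 7)
    bd <- taxa_bars_data(ms, "Genus", group = "Group",
                         top_taxa = sample(2:5, 1))
    sums <- tapply(bd$abundance, bd$group, sum)
    expect_equal(as.vector(sums), rep(100, length(sums)), tolerance = 1e-6)
  }
})

test_that("nb_bars_data back-transforms intercept-only fits to a softmax", {
  ms <- sim_ms(seed = 62, n_lib = 10, n_taxa = 4)
  mods <- suppressMessages(nb_mods(ms, "Genus", ~ Group))
  # overwrite with hand-built intercept-only fits: beta0 = ln 1, ln 2, ln 3
  mk <- function(tx, b0) microtide:::new_taxa_fit(
    tx, coefs = c("(Intercept)" = b0), cov = matrix(0.01, 1, 1),
    loglik = 0, converged = TRUE, n_obs = 10, family = "negbin")
  mods$fits <- list(A = mk("A", log(1)), B = mk("B", log(2)),
                    C = mk("C", log(3)))
  mods$formula <- ~ 1
  mods$terms <- terms(~ 1)
  mods$xlevels <- list()
  bd <- nb_bars_data(mods, covariates = character(), top_taxa = 3)
  expect_equal(sort(bd$abundance), c(100 / 6, 100 / 3, 50), tolerance = 1e-9)
  # offset constant cancels in the normalization
  mods$offset <- TRUE
  mods$log_offset <- rep(log(5000), 10)
  bd2 <- nb_bars_data(mods, covariates = character(), top_taxa = 3)
  expect_equal(bd2$abundance, bd$abundance, tolerance = 1e-12)
})

test_that("two identical fits split estimated composition 50/50 everywhere", {
  ms <- sim_ms(seed = 63, n_lib = 12, n_taxa = 4)
  mods <- suppressMessages(nb_mods(ms, "Genus", ~ Age))
  f <- mods$fits[[1]]
  mods$fits <- list(A = f, B = f)
  bd <- nb_bars_data(mods, covariates = "Age", top_taxa = 2, grid_n = 5)
  expect_equal(bd$abundance, rep(50, nrow(bd)), tolerance = 1e-9)
})

test_that("interaction profiles match direct design-matrix evaluation", {
  sim <- simulate_micro(n_lib = 60, n_taxa = 5, seed = 64,
                        effects = data.frame(taxon = 1, covariate = "Group",
                                             beta = 0.6))
  ms <- suppressMessages(build_micro_set(sim$otu_tabs, sim$clinical, "Lib"))
  mods <- suppressMessages(nb_mods(ms, "Genus", ~ Group * Age))
  bd <- nb_bars_data(mods, covariates = c("Group", "Age"), top_taxa = 5,
                     grid_n = 3)
  # recompute one profile by hand for one taxon
  tx <- names(mods$fits)[1]
  cf <- mods$fits[[tx]]$coefficients
  age0 <- sort(unique(bd$Age))[2]
  eta <- cf["(Intercept)"] + cf["GroupYes"] + cf["Age"] * age0 +
    cf["GroupYes:Age"] * age0
  mu_all <- vapply(mods$fits, function(f) {
    v <- f$coefficients
    exp(v["(Intercept)"] + v["GroupYes"] + v["Age"] * age0 +
          v["GroupYes:Age"] * age0)
  }, numeric(1))
  expected_ra <- 100 * exp(eta) / sum(mu_all)
  got <- bd$abundance[bd$Taxa == tx & bd$Group == "Yes" & bd$Age == age0]
  expect_equal(got, unname(expected_ra), tolerance = 1e-9)
})

test_that("correlation rocky mountain data follow the rank formulas", {
  # monotone taxon -> Spearman +1
  m <- cbind(L1 = c(10L, 90L), L2 = c(20L, 80L), L3 = c(40L, 60L))
  rownames(m) <- c("Bacteria/PhyA/Up", "Bacteria/PhyB/Down")
  clin <- tibble::tibble(Lib = c("L1", "L2", "L3"), Age = c(30, 40, 50))
  ms <- build_micro_set(otu_tbl("Genus", m), clin, lib_col = "Lib")
  rd <- rocky_mtn_cor_data(ms, "Genus", "Age")
  expect_equal(rd$y[rd$label == "Up"], 1)
  expect_equal(rd$y[rd$label == "Down"], -1)
  expect_identical(rd$phylum, c("PhyA", "PhyB"))
  # hand value: x = 1,2,3 against ranks 3,1,2 -> rho = 1 - 6*6/(3*8) = -0.5
  expect_equal(cor(1:3, c(3, 1, 2), method = "spearman"), -0.5)
  expect_error(rocky_mtn_cor_data(ms, "Genus", "Lib"), "numeric")
})

test_that("label cutoff is a strict threshold on magnitude", {
  rd <- tibble::tibble(Taxa = "t", ratio = 2, fdr_p = 0.3,
                       Coefficient = "GroupYes")
  out <- rocky_mtn_model_data(rd, "GroupYes", label_cutoff = abs(log(0.29)))
  expect_false(out$labeled)  # |y| = -log(0.3) < cutoff
})

test_that("model rocky mountain y follows the signed log FDR rule", {
  est <- tibble::tibble(
    Taxa = c("Bacteria/P/A", "Bacteria/P/B", "Bacteria/P/C"),
    Coefficient = "GroupYes",
    ratio = c(2, 0.5, 1.2), ci_low = 1, ci_high = 3,
    z = 1, fdr_p = c(0.05, 0.05, 1))
  out <- rocky_mtn_model_data(est, "GroupYes")
  expect_equal(out$y[1], -log(0.05), tolerance = 1e-6)  # +2.996
  expect_equal(out$y[2], log(0.05), tolerance = 1e-6)   # -2.996
  expect_equal(out$y[3], 0)
  # antisymmetry under ratio inversion (beta sign flip) at fixed fdr_p
  est2 <- est
  est2$ratio <- 1 / est$ratio
  out2 <- rocky_mtn_model_data(est2, "GroupYes")
  expect_equal(out2$y, -out$y)
  lg10 <- rocky_mtn_model_data(est, "GroupYes", log_base = "10")
  expect_equal(lg10$y[1], -log10(0.05), tolerance = 1e-6)
  expect_error(rocky_mtn_model_data(est, "Nope"), "Nope")
})

test_that("heatmap entries match the rocky mountain correlations", {
  ms <- sim_ms(seed = 65, n_lib = 15, n_taxa = 6)
  hm <- cor_heatmap_data(ms, "Genus", "Age")
  rd <- rocky_mtn_cor_data(ms, "Genus", "Age")
  expect_equal(unname(hm[, "Age"]), rd$y)
  expect_true(all(abs(hm) <= 1))
  # sign flip of a covariate negates its column
  ms$AgeNeg <- -ms$Age
  hm2 <- cor_heatmap_data(ms, "Genus", c("Age", "AgeNeg"))
  expect_equal(unname(hm2[, "AgeNeg"]), -unname(hm2[, "Age"]))
  ms$Const <- 1
  expect_warning(hm3 <- cor_heatmap_data(ms, "Genus", c("Age", "Const")),
                 "constant")
  expect_identical(colnames(hm3), "Age")
})

test_that("forest data sort and top-k by |log ratio|", {
  set.seed(66)
  est <- tibble::tibble(
    Taxa = paste0("T", 1:10), Coefficient = "GroupYes",
    ratio = exp(rnorm(10)), ci_low = 0.1, ci_high = 10,
    z = 0, fdr_p = runif(10))
  fd <- forest_data(est, "GroupYes")
  expect_true(all(diff(fd$ratio) >= 0))
  top3 <- forest_data(est, "GroupYes", top = 3)
  expect_equal(nrow(top3), 3)
  expect_setequal(top3$Taxa,
                  est$Taxa[order(abs(log(est$ratio)), decreasing = TRUE)][1:3])
})

test_that("plot renderers return ggplot objects on pipeline outputs", {
  ms <- sim_ms(seed = 67, n_lib = 14, n_taxa = 6)
  expect_s3_class(plot_taxa_bars(taxa_bars_data(ms, "Genus", group = "Group")),
                  "ggplot")
  expect_s3_class(plot_rocky_mtn(rocky_mtn_cor_data(ms, "Genus", "Age")),
                  "ggplot")
  expect_s3_class(plot_cor_heatmap(cor_heatmap_data(ms, "Genus", "Age")),
                  "ggplot")
  ord <- pca_clr(ms, "Genus")
  g <- ms_lib_data(ms)$Group[match(rownames(ord$scores), ms_lib_data(ms)$Lib)]
  expect_s3_class(plot_ordination(ord, groups = g), "ggplot")
})
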