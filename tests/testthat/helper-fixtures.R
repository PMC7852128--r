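# Fixtures are always built in code, never stored.

# Tiny deterministic micro_set: one table, given count matrix (taxa x libs).
make_ms <- function(counts, clinical = NULL, name = "Genus") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("Bacteria/Phy%d/T%02d",
                                (seq_len(nrow(counts)) - 1L) %% 3 + 1,
                                seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("L%02d", seq_len(ncol(counts)))
  tab <- otu_tbl(name, counts)
  if (is.null(clinical)) {
    libs <- sort(colnames(counts))  # covariates are a function of the ID
    clinical <- tibble::tibble(
      Lib = libs,
      Group = factor(rep(c("No", "Yes"), length.out = length(libs)),
                     levels = c("No", "Yes")),
      Age = seq(50, 80, length.out = length(libs)))
  }
  suppressMessages(
    build_micro_set(setNames(list(tab), name), clinical, lib_col = "Lib"))
}

# Random count matrix with no all-zero library.
random_counts <- function(n_taxa, n_lib, lambda = 20) {
  m <- matrix(rpois(n_taxa * n_lib, lambda), n_taxa, n_lib,
              dimnames = list(sprintf("Bacteria/Phy%d/T%02d",
                                      (seq_len(n_taxa) - 1L) %% 3 + 1,
                                      seq_len(n_taxa)),
                              sprintf("L%02d", seq_len(n_lib))))
  zero <- colSums(m) == 0
  m[1, zero] <- 1L
  m
}

# micro_set from the simulator, the usual richer fixture.
sim_ms <- function(seed = 1, n_lib = 30, n_taxa = 8, ...) {
  sim <- simulate_micro(n_lib = n_lib, n_taxa = n_taxa, seed = seed, ...)
  suppressMessages(build_micro_set(sim$otu_tabs, sim$clinical, lib_col = "Lib"))
}

expect_micro_set_valid <- function(ms) {
  by_block <- split(seq_len(nrow(ms)), paste(ms$Table, ms$Lib))
  for (ix in by_block) {
    expect_equal(sum(ms$ra[ix]), 100, tolerance = 1e-9)
    expect_lt(abs(sum(ms$clr[ix])), 1e-9)
    expect_equal(ms$Total[ix], rep(sum(ms$cts[ix]), length(ix)))
  }
  expect_identical(ms$bin, as.integer(ms$cts > 0))
}
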