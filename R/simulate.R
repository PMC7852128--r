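# Dirichlet-multinomial fixture generator. The Dirichlet layer induces the
# between-library overdispersion that the negative binomial / beta-binomial
# taxon models assume, so simulated effects are recoverable by the pipeline.

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

sim_taxa_names <- function(n_taxa) {
  phyla <- c("Firmicutes", "Proteobacteria", "Bacteroidetes", "Actinobacteria")
  sprintf("Bacteria/%s/Genus%02d",
          phyla[(seq_len(n_taxa) - 1L) %% length(phyla) + 1L], seq_len(n_taxa))
}

#' Simulate an OTU table and clinical data with known ground truth
#'
#' Generates a cross-sectional 16S-style fixture shaped like a two-arm
#' case-control cohort: per library a binary group (balanced), a numeric age
#' drawn from N(71.7, 11.2^2) and a three-level smoking status; a base
#' composition drawn once from a log-normal profile (or supplied); and per
#' library counts drawn as multinomial(depth, pi) with
#' `pi ~ Dirichlet(concentration * p(x))`, where `log p(x)` shifts the base
#' composition by the requested per-taxon covariate effects before
#' renormalization. Depths are uniform integers in `depth_range`.
#'
#' The truth record stores, for every requested effect, the *induced*
#' log-fold change of the focal taxon's expected proportion (one covariate
#' unit from the reference profile, after renormalization) — the estimand
#' the count models target via a depth offset.
#'
#' @param n_lib Number of libraries (default 52, two balanced groups of 26).
#' @param n_taxa Number of taxa in the table (default 12).
#' @param table_name OTU table name (default `"Genus"`).
#' @param base_props Optional base composition (summing to 1).
#' @param concentration Dirichlet concentration; `Inf` gives pure
#'   multinomial sampling (default 50, mild overdispersion).
#' @param depth_range Integer range of library depths (default
#'   `c(10000, 60000)`).
#' @param effects Optional data frame with columns `taxon` (label or index),
#'   `covariate` (`"Group"` or `"Age"`), `beta` (log-scale shift per
#'   covariate unit; Age is standardized internally).
#' @param phylum_table Also emit a phylum-level table aggregated from the
#'   genus counts (default `FALSE`).
#' @param seed Integer seed; the whole fixture is reproducible.
#' @param dir Optional directory: write `otu_<table>.tsv`, `clinical.csv`
#'   and `truth.txt` there in the formats [read_otu_table()] and
#'   [read_clinical()] accept.
#' @return A list: `otu_tabs` (named list of [otu_tbl]), `clinical`
#'   (tibble with `Lib`, `Group`, `Age`, `Smoking`), `truth` (tibble of
#'   `taxon`, `covariate`, `beta`, `induced_beta`), and `files` when `dir`
#'   is given.
#' @export
simulate_micro <- function(n_lib = 52, n_taxa = 12, table_name = "Genus",
                           base_props = NULL, concentration = 50,
                           depth_range = c(10000, 60000), effects = NULL,
                           phylum_table = FALSE, seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_lib >= 2, n_taxa >= 2, depth_range[1] >= 1)
  taxa <- sim_taxa_names(n_taxa)
  if (is.null(base_props)) {
    base_props <- exp(rnorm(n_taxa, mean = 0, sd = 1.2))
    base_props <- base_props / sum(base_props)
  }
  stopifnot(length(base_props) == n_taxa,
            abs(sum(base_props) - 1) < 1e-8, all(base_props > 0))

  libs <- sprintf("L%03d", seq_len(n_lib))
  group <- factor(rep(c("No", "Yes"), length.out = n_lib),
                  levels = c("No", "Yes"))
  group <- group[sample.int(n_lib)]
  age <- rnorm(n_lib, 71.7, 11.2)
  smoking <- factor(sample(c("Never", "Former", "Current"), n_lib,
                           replace = TRUE, prob = c(0.31, 0.42, 0.27)),
                    levels = c("Never", "Former", "Current"))
  clinical <- tibble::tibble(Lib = libs, Group = group, Age = age,
                             Smoking = smoking)

  # per-library covariate design for the effects (Age standardized so beta
  # is a per-SD shift)
  xmat <- cbind(Group = as.numeric(group == "Yes"),
                Age = as.numeric(scale(age)))
  beta_mat <- matrix(0, nrow = n_taxa, ncol = ncol(xmat),
                     dimnames = list(taxa, colnames(xmat)))
  if (!is.null(effects)) {
    effects <- as.data.frame(effects)
    stopifnot(all(c("taxon", "covariate", "beta") %in% names(effects)))
    for (i in seq_len(nrow(effects))) {
      tx <- effects$taxon[i]
      if (is.numeric(tx)) tx <- taxa[tx]
      if (!tx %in% taxa) stop("effect references unknown taxon: ", tx)
      cv <- as.character(effects$covariate[i])
      if (!cv %in% colnames(xmat)) stop("unknown effect covariate: ", cv)
      beta_mat[tx, cv] <- beta_mat[tx, cv] + effects$beta[i]
    }
  }
  props_at <- function(x) {
    lp <- log(base_props) + drop(beta_mat %*% x)
    p <- exp(lp - max(lp))
    p / sum(p)
  }

  depth <- sample(seq.int(depth_range[1], depth_range[2]), n_lib,
                  replace = TRUE)
  counts <- matrix(0L, nrow = n_taxa, ncol = n_lib,
                   dimnames = list(taxa, libs))
  for (i in seq_len(n_lib)) {
    p <- props_at(xmat[i, ])
    pi_i <- if (is.infinite(concentration)) p else
      rdirichlet1(concentration * p)
    counts[, i] <- rmultinom(1L, size = depth[i], prob = pi_i)
  }
  tabs <- list(otu_tbl(table_name, counts))
  names(tabs) <- table_name
  if (phylum_table) {
    phy <- taxon_phylum(taxa)
    agg <- rowsum(counts, paste0("Bacteria/", phy))
    tabs$Phylum <- otu_tbl("Phylum", agg)
    tabs <- tabs[c("Phylum", table_name)]
  }

  truth <- NULL
  if (!is.null(effects) && nrow(effects)) {
    x0 <- setNames(rep(0, ncol(xmat)), colnames(xmat))
    truth <- dplyr::bind_rows(lapply(seq_len(nrow(effects)), function(i) {
      tx <- effects$taxon[i]
      if (is.numeric(tx)) tx <- taxa[tx]
      x1 <- x0
      x1[as.character(effects$covariate[i])] <- 1
      tibble::tibble(taxon = tx,
                     covariate = as.character(effects$covariate[i]),
                     beta = effects$beta[i],
                     induced_beta = log(props_at(x1)[tx] / props_at(x0)[tx]))
    }))
  }
  out <- list(otu_tabs = tabs, clinical = clinical, truth = truth)
  if (!is.null(dir)) out$files <- sim_write(out, dir)
  out
}

sim_write <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(sim$otu_tabs)) {
    f <- file.path(dir, paste0("otu_", nm, ".tsv"))
    write_otu_table(sim$otu_tabs[[nm]], f)
    files <- c(files, setNames(f, paste0("otu_", nm)))
  }
  clin_f <- file.path(dir, "clinical.csv")
  write.csv(as.data.frame(sim$clinical), clin_f, row.names = FALSE)
  files <- c(files, setNames(clin_f, "clinical"))
  if (!is.null(sim$truth)) {
    tr_f <- file.path(dir, "truth.txt")
    writeLines(sprintf("%s\t%s\t%.10g\t%.10g", sim$truth$taxon,
                       sim$truth$covariate, sim$truth$beta,
                       sim$truth$induced_beta), tr_f)
    files <- c(files, setNames(tr_f, "truth"))
  }
  files
}

#' Simulate a longitudinal cohort with repeated sequencing time points
#'
#' Shaped like a ventilated-preterm-infant airway study: `n_subject`
#' subjects sampled at `n_time` scheduled time points (days 7, 14, 21, ...),
#' with only `n_complete` subjects observed at every time point — the rest
#' lose a random suffix of visits, exercising complete-case handling in the
#' three-mode ordinations. Each subject's latent log-composition
#' random-walks across time with innovation standard deviation `drift`.
#'
#' @param n_subject Number of subjects (default 24).
#' @param n_time Number of time points (default 3).
#' @param n_complete Subjects with all time points (default 15).
#' @param drift Within-subject log-composition random-walk SD per step
#'   (default 0.4).
#' @param n_taxa,concentration,depth_range,seed,dir As [simulate_micro()].
#' @return A list: `otu_tabs`, `clinical` (with `Lib`, `Subject`, `Time`,
#'   `Group`), and `files` when `dir` is given.
#' @export
simulate_longitudinal <- function(n_subject = 24, n_time = 3, n_complete = 15,
                                  drift = 0.4, n_taxa = 12, concentration = 50,
                                  depth_range = c(10000, 60000), seed = NULL,
                                  dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_time >= 2, n_complete <= n_subject, n_complete >= 2)
  taxa <- sim_taxa_names(n_taxa)
  base_lp <- rnorm(n_taxa, 0, 1.2)
  times <- paste0("Day", 7 * seq_len(n_time))
  subjects <- sprintf("S%02d", seq_len(n_subject))
  incomplete <- if (n_subject > n_complete)
    sample(subjects, n_subject - n_complete) else character()
  rows <- list()
  cts <- list()
  for (s in subjects) {
    n_obs <- if (s %in% incomplete)
      sample.int(n_time - 1L, 1L) else n_time
    lp <- base_lp + rnorm(n_taxa, 0, 0.8)  # subject-level profile
    grp <- sample(c("No", "Yes"), 1L)
    for (t in seq_len(n_obs)) {
      if (t > 1L) lp <- lp + rnorm(n_taxa, 0, drift)
      p <- exp(lp - max(lp))
      p <- p / sum(p)
      pi_i <- if (is.infinite(concentration)) p else rdirichlet1(concentration * p)
      depth <- sample(seq.int(depth_range[1], depth_range[2]), 1L)
      lib <- paste0(s, "_", times[t])
      cts[[lib]] <- rmultinom(1L, depth, pi_i)[, 1L]
      rows[[lib]] <- tibble::tibble(Lib = lib, Subject = s, Time = times[t],
                                    Group = grp)
    }
  }
  counts <- do.call(cbind, cts)
  rownames(counts) <- taxa
  clinical <- dplyr::bind_rows(rows)
  clinical$Time <- factor(clinical$Time, levels = times)
  clinical$Group <- factor(clinical$Group, levels = c("No", "Yes"))
  clinical$Subject <- factor(clinical$Subject, levels = subjects)
  out <- list(otu_tabs = list(Genus = otu_tbl("Genus", counts)),
              clinical = clinical, truth = NULL)
  if (!is.null(dir)) out$files <- sim_write(out, dir)
  out
}
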