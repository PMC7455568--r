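#' Configure a synthetic pooled-sample study
#'
#' Builds the parameter set for [simulate_study()], which emulates the
#' pooled-cartilage design: eight libraries, one per genotype (WT/KO) x
#' condition (sham/DMM) x week (2/4) cell, with a planted subset of genes
#' whose DMM response is positive in WT but absent or reversed in KO.
#'
#' @param n_genes Number of genes (>= 8).
#' @param frac_attenuated Fraction of genes with a WT-specific DMM response
#'   (the planted "attenuated" class).
#' @param frac_shared_de Fraction responding equally in both genotypes.
#' @param effect_mean,effect_sd Mean and sd (log2 units) of the DMM effect
#'   magnitudes.
#' @param noise_sd Per-sample log2-scale noise sd.
#' @param baseline_log2_tpm_mean,baseline_log2_tpm_sd Baseline abundance
#'   distribution (log2 TPM) for expressed genes.
#' @param frac_unexpressed Fraction of genes kept below the TPM > 1 filter
#'   in every sample.
#' @param seed RNG seed.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              frac_attenuated = 0.05,
                              frac_shared_de = 0.10,
                              effect_mean = 2,
                              effect_sd = 0.5,
                              noise_sd = 0.25,
                              baseline_log2_tpm_mean = 5,
                              baseline_log2_tpm_sd = 2,
                              frac_unexpressed = 0.10,
                              seed = 7L) {
  cfg <- list(n_genes = as.integer(n_genes),
              frac_attenuated = frac_attenuated,
              frac_shared_de = frac_shared_de,
              effect_mean = effect_mean, effect_sd = effect_sd,
              noise_sd = noise_sd,
              baseline_log2_tpm_mean = baseline_log2_tpm_mean,
              baseline_log2_tpm_sd = baseline_log2_tpm_sd,
              frac_unexpressed = frac_unexpressed,
              seed = as.integer(seed))
  fr <- c(cfg$frac_attenuated, cfg$frac_shared_de, cfg$frac_unexpressed)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    val_error("class fractions must lie in [0,1] and sum to at most 1")
  if (cfg$n_genes < 8L) val_error("n_genes must be at least 8")
  if (cfg$effect_sd < 0 || cfg$noise_sd < 0 || cfg$baseline_log2_tpm_sd < 0)
    val_error("standard deviations must be non-negative")
  structure(cfg, class = "simulation_config")
}

#' Simulate a pooled two-genotype, two-week DMM study
#'
#' Generates eight samples (WT/KO x sham/DMM x weeks 2/4).  Per gene,
#' `log2 TPM = baseline + effect(genotype, condition, week) + N(0,
#' noise_sd)` and `TPM = 2^log2TPM`.  Gene classes:
#' \describe{
#'   \item{attenuated}{positive WT DMM effect `|N(effect_mean, effect_sd)|`
#'     and negative KO effect `-|N(effect_mean/2, effect_sd)|`, shared
#'     across weeks so the two-timepoint consistency requirement has
#'     discriminating power.}
#'   \item{shared_de}{one signed effect per week, identical in both
#'     genotypes (no genotype x condition interaction).}
#'   \item{null}{no condition effect.}
#'   \item{unexpressed}{baseline far below the filter floor; TPM is kept
#'     strictly below 1 in every sample.}
#' }
#' Expressed baselines are truncated below at log2 TPM = 0.5 so that the
#' expressed classes genuinely clear the TPM > 1 filter.
#'
#' @param config A [simulation_config()].
#' @return List with elements `matrix` (a `SummarizedExperiment`) and
#'   `truth` (data frame: `gene`, `class`, and per-week true WT/KO log2
#'   effects).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config"))
    arg_error("config must come from simulation_config()")
  withr::with_seed(config$seed, .simulate_study_impl(config))
}

.simulate_study_impl <- function(cfg) {
  n <- cfg$n_genes
  n_att <- round(cfg$frac_attenuated * n)
  n_sh <- round(cfg$frac_shared_de * n)
  n_un <- round(cfg$frac_unexpressed * n)
  n_null <- n - n_att - n_sh - n_un
  genes <- sprintf("Sim%05d", seq_len(n))
  class <- sample(rep(c("attenuated", "shared_de", "unexpressed", "null"),
                      times = c(n_att, n_sh, n_un, n_null)))

  baseline <- pmax(rnorm(n, cfg$baseline_log2_tpm_mean,
                         cfg$baseline_log2_tpm_sd), 0.5)
  baseline[class == "unexpressed"] <- rnorm(n_un, -4, 1)

  wt_eff <- matrix(0, n, 2L, dimnames = list(NULL, as.character(WEEKS)))
  ko_eff <- wt_eff
  att <- class == "attenuated"
  if (any(att)) {
    # week-shared planted effects
    w <- abs(rnorm(sum(att), cfg$effect_mean, cfg$effect_sd))
    k <- -abs(rnorm(sum(att), cfg$effect_mean / 2, cfg$effect_sd))
    wt_eff[att, ] <- w
    ko_eff[att, ] <- k
  }
  sh <- class == "shared_de"
  if (any(sh)) {
    for (j in 1:2) {
      e <- sample(c(-1, 1), sum(sh), replace = TRUE) *
        abs(rnorm(sum(sh), cfg$effect_mean, cfg$effect_sd))
      wt_eff[sh, j] <- e
      ko_eff[sh, j] <- e
    }
  }

  design <- expand.grid(condition = CONDITIONS, genotype = GENOTYPES,
                        week = WEEKS, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "condition", "week")]
  sample_ids <- paste0(design$genotype, "_", design$condition, "_wk",
                       design$week)
  tpm <- matrix(NA_real_, n, nrow(design),
                dimnames = list(genes, sample_ids))
  for (s in seq_len(nrow(design))) {
    eff <- if (design$condition[s] == "DMM") {
      if (design$genotype[s] == "WT") wt_eff[, as.character(design$week[s])]
      else ko_eff[, as.character(design$week[s])]
    } else 0
    lv <- baseline + eff + rnorm(n, 0, cfg$noise_sd)
    lv[class == "unexpressed"] <- pmin(lv[class == "unexpressed"], -0.1)
    tpm[, s] <- 2^lv
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(genotype = design$genotype,
                                   condition = design$condition,
                                   week = as.integer(design$week),
                                   row.names = sample_ids))
  truth <- data.frame(gene = genes, class = class,
                      wt_eff_wk2 = wt_eff[, "2"], ko_eff_wk2 = ko_eff[, "2"],
                      wt_eff_wk4 = wt_eff[, "4"], ko_eff_wk4 = ko_eff[, "4"],
                      stringsAsFactors = FALSE)
  list(matrix = se, truth = truth)
}

#' Build fixture gene-set and ortholog-map companions for a simulation
#'
#' Emits a collection with one set enriched for the planted attenuated
#' genes (80% attenuated members, the remainder random) plus `n_sets - 1`
#' random sets, and an identity-like ortholog map (human = uppercased
#' simulated symbol) covering every simulated gene.
#'
#' @param truth Truth table from [simulate_study()].
#' @param n_sets Number of gene sets.
#' @param set_size Genes per set.
#' @param seed RNG seed.
#' @return List with `collection` (named list, human namespace),
#'   `orthologs` (data frame `human`, `mouse`) and `enriched_set` (the name
#'   of the planted set).
#' @export
make_fixture_collections <- function(truth, n_sets = 5L, set_size = 50L,
                                     seed = 1L) {
  genes <- truth$gene
  if (set_size > length(genes))
    val_error("set_size exceeds the number of simulated genes")
  if (n_sets < 1L) val_error("n_sets must be at least 1")
  withr::with_seed(seed, {
    att <- truth$gene[truth$class == "attenuated"]
    other <- setdiff(genes, att)
    n_from_att <- min(round(0.8 * set_size), length(att))
    planted <- c(sample(att, n_from_att),
                 sample(other, set_size - n_from_att))
    collection <- list(PLANTED_ATTENUATED = toupper(planted))
    if (n_sets > 1L) {
      for (i in seq_len(n_sets - 1L))
        collection[[sprintf("RANDOM_%02d", i)]] <-
          toupper(sample(genes, set_size))
    }
    list(collection = collection,
         orthologs = data.frame(human = toupper(genes), mouse = genes,
                                stringsAsFactors = FALSE),
         enriched_set = "PLANTED_ATTENUATED")
  })
}
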