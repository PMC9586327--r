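# Spectral-count table simulator for the two-bait proximity-proteomics
# design (bait vs spatial-reference replicates), with negative-binomial
# count noise, per-protein abundance heterogeneity, a per-sample
# biotinylation-efficiency factor on exogenously biotinylated proteins, a
# per-sample recovery/loading factor shared by all proteins (tracked by the
# endogenously biotinylated carboxylase internal standards), and a planted
# enriched fraction.

#' Specification of a simulated proximity-proteomics experiment
#'
#' @param n_proteins Number of exogenously biotinylated proteins (the two
#'   internal controls are added on top).
#' @param n_bait,n_ctrl Replicates per group (mice per construct); the
#'   reference design is 4 bait vs 3 control.
#' @param frac_enriched Fraction of proteins truly enriched near the bait.
#' @param log2_fc Planted log2 fold change of enriched proteins in bait
#'   samples.
#' @param baseline_mean Median expected count of an exogenous protein;
#'   per-protein abundances vary lognormally (sdlog 0.5) around it.
#' @param dispersion Negative-binomial dispersion (`variance =
#'   mean + dispersion * mean^2`); `0` gives Poisson counts.
#' @param efficiency_range Interval for the per-sample biotinylation
#'   efficiency factor, applied to exogenous proteins only (the endogenous
#'   controls are biotinylated by cellular metabolism, not by the bait
#'   construct).
#' @param recovery_range Interval for the per-sample streptavidin
#'   recovery/loading factor, applied to every protein including the
#'   controls; this is the component of yield variation that
#'   internal-standard normalization can remove.
#' @param control_ids Identifiers of the two internal-control proteins
#'   (default the two carboxylases, `"Pcca"` and `"Pc"`).
#' @param control_baseline Expected count of each control protein before
#'   recovery scaling.
#' @param seed Integer seed.
#' @return An object of class `proteomics_sim_spec`.
#' @export
proteomics_sim_spec <- function(n_proteins = 2000,
                                n_bait = 4,
                                n_ctrl = 3,
                                frac_enriched = 0.05,
                                log2_fc = 2,
                                baseline_mean = 50,
                                dispersion = 0.05,
                                efficiency_range = c(1, 1),
                                recovery_range = c(1, 1),
                                control_ids = c("Pcca", "Pc"),
                                control_baseline = 500,
                                seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins", lower = 1)
  n_bait <- assert_count(n_bait, "n_bait", lower = 2)
  n_ctrl <- assert_count(n_ctrl, "n_ctrl", lower = 2)
  assert_fraction(frac_enriched, "frac_enriched")
  assert_number(log2_fc, "log2_fc")
  assert_number(baseline_mean, "baseline_mean", lower = 1e-9)
  assert_number(dispersion, "dispersion", lower = 0)
  assert_number(control_baseline, "control_baseline", lower = 1e-9)
  for (rng_name in c("efficiency_range", "recovery_range")) {
    rng <- get(rng_name)
    if (length(rng) != 2L || any(!is.finite(rng)) || any(rng <= 0) || rng[1] > rng[2]) {
      stop_spinescope(
        sprintf("`%s` must be an interval within (0, Inf).", rng_name),
        "parameter"
      )
    }
  }
  if (length(control_ids) != 2L || anyDuplicated(control_ids)) {
    stop_spinescope("`control_ids` must name exactly two distinct proteins.", "parameter")
  }
  structure(
    list(
      n_proteins = n_proteins, n_bait = n_bait, n_ctrl = n_ctrl,
      frac_enriched = frac_enriched, log2_fc = log2_fc,
      baseline_mean = baseline_mean, dispersion = dispersion,
      efficiency_range = as.numeric(efficiency_range),
      recovery_range = as.numeric(recovery_range),
      control_ids = as.character(control_ids),
      control_baseline = control_baseline,
      seed = as.integer(seed)
    ),
    class = "proteomics_sim_spec"
  )
}

draw_counts <- function(mu, dispersion) {
  if (dispersion <= 1e-12) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
}

#' Generate a spectral-count table with planted enrichment
#'
#' Counts for protein `p` in sample `s` are drawn from a negative binomial
#' with mean `recovery_s * efficiency_s * abundance_p` (exogenous proteins;
#' `abundance_p` is multiplied by `2^log2_fc` for enriched proteins in bait
#' samples) or `recovery_s * control_baseline` (internal controls, which do
#' not see the bait-specific efficiency factor). With a low yield the
#' controls therefore take a larger share of the sample's counts relative
#' to exogenous proteins. The controls are drawn Poisson rather than
#' negative-binomial: their biotinylation is constitutive, so across
#' animals they vary only through recovery and counting noise, which is
#' what makes them usable as internal standards.
#'
#' @param spec A [proteomics_sim_spec()].
#' @return A list of class `proteomics_phantom`: `table` (a
#'   [peptide_count_table]), `truth` (character vector of truly enriched
#'   protein ids) and `spec`.
#' @export
generate_proteomics_table <- function(spec) {
  stopifnot(inherits(spec, "proteomics_sim_spec"))
  n <- spec$n_proteins
  ids <- sprintf("prot%04d", seq_len(n))
  if (any(spec$control_ids %in% ids)) {
    stop_spinescope("`control_ids` collide with generated protein ids.", "parameter")
  }
  samples <- c(
    sprintf("bait_%d", seq_len(spec$n_bait)),
    sprintf("ctrl_%d", seq_len(spec$n_ctrl))
  )
  groups <- c(rep("bait", spec$n_bait), rep("control", spec$n_ctrl))

  withr::with_seed(spec$seed, {
    abundance <- spec$baseline_mean * rlnorm(n, 0, 0.5)
    n_enriched <- round(spec$frac_enriched * n)
    enriched <- if (n_enriched > 0) sample(ids, n_enriched) else character(0)
    efficiency <- runif(length(samples), spec$efficiency_range[1], spec$efficiency_range[2])
    recovery <- runif(length(samples), spec$recovery_range[1], spec$recovery_range[2])

    mu <- outer(abundance, recovery * efficiency)
    fc <- 2^spec$log2_fc
    mu[ids %in% enriched, groups == "bait"] <-
      mu[ids %in% enriched, groups == "bait"] * fc
    counts <- matrix(draw_counts(mu, spec$dispersion), nrow = n)
    # internal standards are constitutively biotinylated: no biological
    # overdispersion, only recovery scaling plus Poisson counting noise
    ctrl_mu <- outer(rep(spec$control_baseline, 2L), recovery)
    ctrl_counts <- matrix(rpois(length(ctrl_mu), ctrl_mu), nrow = 2L)
  })

  full <- rbind(counts, ctrl_counts)
  rownames(full) <- c(ids, spec$control_ids)
  colnames(full) <- samples

  structure(
    list(
      table = peptide_count_table(
        full,
        groups = tibble(sample = samples, group = groups),
        control_ids = spec$control_ids,
        experiment = sprintf("sim_seed%d", spec$seed)
      ),
      truth = enriched,
      spec = spec
    ),
    class = "proteomics_phantom"
  )
}
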