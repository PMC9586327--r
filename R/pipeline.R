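# Stage dispatcher: validates a run configuration, calls the simulation or
# analysis functions, writes their artifacts, and returns a run report
# with the headline numbers. Identical config + inputs + seed reproduce
# identical outputs.

KNOWN_STAGES <- c(
  "simulate_em", "simulate_proteomics", "simulate_scrna", "simulate_fluor",
  "ibioid", "ibioid_overlap", "coexpr", "spine_ef", "sa_census"
)

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_spinescope(sprintf("Config file not found: %s.", config), "io")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop_spinescope("`config` must be a list or a path to a JSON file.", "parameter")
  }
  config
}

validate_run_config <- function(cfg) {
  if (is.null(cfg[["stage"]]) || !(cfg[["stage"]] %in% KNOWN_STAGES)) {
    stop_spinescope(
      sprintf("Unknown stage '%s'; known stages: %s.",
              cfg[["stage"]] %||% "<missing>", paste(KNOWN_STAGES, collapse = ", ")),
      "config"
    )
  }
  if (is.null(cfg[["out_dir"]])) {
    stop_spinescope("`out_dir` is required.", "config")
  }
  if (!is.null(cfg[["alpha"]])) assert_number(cfg[["alpha"]], "alpha", lower = 1e-12, upper = 1)
  if (!is.null(cfg[["t"]])) assert_number(cfg[["t"]], "t", lower = 1e-12)
  if (!is.null(cfg[["k"]])) assert_count(cfg[["k"]], "k", lower = 1)
  if (!is.null(cfg[["seed"]])) assert_count(cfg[["seed"]], "seed")
  invisible(cfg)
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches to the package's simulation and analysis functions, writes
#' every artifact into `config$out_dir`, and returns a `run_report` with
#' the stage's headline outputs and collected warnings. The configuration
#' is validated before any computation; the seed is recorded in the
#' report.
#'
#' Stages and their main keys:
#' * `simulate_em`, `simulate_proteomics`, `simulate_scrna`,
#'   `simulate_fluor`: generator parameters (see the `*_spec()`
#'   constructors) plus `seed`.
#' * `ibioid`: `counts` (path from [write_count_table()]), `mode`
#'   (`"raw"`/`"endogenous_normalized"`), `alpha`.
#' * `ibioid_overlap`: `results_a`, `results_b` (result CSVs written by the
#'   `ibioid` stage).
#' * `coexpr`: `matrix_dir` (from [write_mtx_counts()]), `ref_gene`, `t`.
#' * `spine_ef`: `image` (path), `shaft_mask` (path), `threshold`, `k`.
#' * `sa_census`: `truth` (spine table CSV with `has_psd`, `has_er`,
#'   `has_sa`).
#'
#' @param config Named list or path to a JSON file.
#' @return An object of class `run_report`: `stage`, `config`, `outputs`
#'   (headline values), `artifacts` (paths written), `warnings`.
#' @export
run_stage <- function(config) {
  cfg <- validate_run_config(load_run_config(config))
  dir.create(cfg[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  outputs <- list()
  artifacts <- character(0)

  add_artifact <- function(path) artifacts <<- c(artifacts, path)
  seed <- as.integer(cfg[["seed"]] %||% 1L)

  withCallingHandlers(
    {
      if (cfg[["stage"]] == "simulate_proteomics") {
        spec_args <- cfg[intersect(names(cfg), names(formals(proteomics_sim_spec)))]
        spec_args$seed <- seed
        phantom <- generate_proteomics_table(do.call(proteomics_sim_spec, spec_args))
        p <- file.path(cfg[["out_dir"]], "counts.tsv")
        write_count_table(phantom$table, p)
        add_artifact(p)
        p2 <- file.path(cfg[["out_dir"]], "truth_enriched.txt")
        writeLines(phantom$truth, p2)
        add_artifact(p2)
        outputs <- list(
          n_proteins = nrow(phantom$table$counts),
          n_enriched_truth = length(phantom$truth)
        )
      } else if (cfg[["stage"]] == "simulate_scrna") {
        spec_args <- cfg[intersect(names(cfg), names(formals(scrna_sim_spec)))]
        spec_args$seed <- seed
        spec_args$target_r <- unlist(spec_args$target_r)
        m <- generate_scrna_matrix(do.call(scrna_sim_spec, spec_args))
        d <- file.path(cfg[["out_dir"]], "counts_mtx")
        write_mtx_counts(m, d)
        add_artifact(d)
        outputs <- list(n_genes = nrow(m), n_cells = ncol(m))
      } else if (cfg[["stage"]] == "simulate_em") {
        spec_args <- cfg[intersect(names(cfg), names(formals(volume_phantom_spec)))]
        spec_args$seed <- seed
        phantom <- generate_em_phantom(do.call(volume_phantom_spec, spec_args))
        pv <- file.path(cfg[["out_dir"]], "volume.txt")
        write_volume_text(phantom$volume, pv)
        add_artifact(pv)
        for (role in names(phantom$masks)) {
          pm <- file.path(cfg[["out_dir"]], sprintf("mask_%s.txt", role))
          write_volume_text(phantom$masks[[role]], pm)
          add_artifact(pm)
        }
        pt <- file.path(cfg[["out_dir"]], "spines.csv")
        readr::write_csv(phantom$spines, pt)
        add_artifact(pt)
        outputs <- list(
          n_spines = nrow(phantom$spines),
          frac_sa_realized = mean(phantom$spines$has_sa)
        )
      } else if (cfg[["stage"]] == "simulate_fluor") {
        spec_args <- cfg[intersect(names(cfg), names(formals(fluor_sim_spec)))]
        spec_args$seed <- seed
        phantom <- generate_fluor_image(do.call(fluor_sim_spec, spec_args))
        pi_ <- file.path(cfg[["out_dir"]], "image.txt")
        write_image_text(phantom$image, pi_)
        add_artifact(pi_)
        ps <- file.path(cfg[["out_dir"]], "shaft_mask.txt")
        write_image_text(phantom$shaft_mask + 0, ps)
        add_artifact(ps)
        pc <- file.path(cfg[["out_dir"]], "spots.csv")
        readr::write_csv(phantom$spots, pc)
        add_artifact(pc)
        outputs <- list(n_spots = nrow(phantom$spots))
      } else if (cfg[["stage"]] == "ibioid") {
        table <- if (!is.null(cfg[["table"]])) cfg[["table"]] else read_count_table(cfg[["counts"]])
        fit <- run_experiment(table, mode = cfg[["mode"]] %||% "raw", alpha = cfg[["alpha"]] %||% 0.1)
        p <- file.path(cfg[["out_dir"]], "enrichment_results.csv")
        writeLines(
          c(
            sprintf("# experiment: %s", fit$experiment),
            sprintf("# mode: %s", fit$mode),
            sprintf("# alpha: %g", fit$alpha),
            sprintf("# seed: %d", seed)
          ),
          p
        )
        readr::write_csv(fit$results, p, append = TRUE, col_names = TRUE)
        add_artifact(p)
        outputs <- list(
          n_proteins = nrow(fit$results),
          n_significant = length(fit$significant)
        )
      } else if (cfg[["stage"]] == "ibioid_overlap") {
        read_sig <- function(path) {
          df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
          df$protein_id[df$significant]
        }
        ov <- cross_experiment_overlap(read_sig(cfg[["results_a"]]), read_sig(cfg[["results_b"]]))
        p <- file.path(cfg[["out_dir"]], "overlap.csv")
        readr::write_csv(ov, p)
        add_artifact(p)
        outputs <- as.list(ov)
      } else if (cfg[["stage"]] == "coexpr") {
        m <- read_mtx_counts(cfg[["matrix_dir"]])
        res <- pearson_vs_reference(m, cfg[["ref_gene"]])
        r_min <- significance_threshold(ncol(m), t = cfg[["t"]] %||% 0.99)
        ranked <- rank_genes(res, ref_gene = cfg[["ref_gene"]], r_min = r_min)
        p <- file.path(cfg[["out_dir"]], "correlations.csv")
        readr::write_csv(ranked, p)
        add_artifact(p)
        outputs <- list(
          r_min = r_min,
          n_genes = nrow(res),
          top_gene = if (nrow(ranked) > 0) ranked$gene[1] else NA_character_,
          top_r = if (nrow(ranked) > 0) ranked$r[1] else NA_real_
        )
      } else if (cfg[["stage"]] == "spine_ef") {
        img <- read_image_text(cfg[["image"]])
        shaft <- read_image_text(cfg[["shaft_mask"]]) > 0
        rois <- sample_shaft_rois(shaft, n = cfg[["n_rois"]] %||% 5L)
        thr <- cfg[["threshold"]] %||% c(percentile = 99.5)
        rec <- spine_enrichment(
          img, thr, rois,
          k = cfg[["k"]] %||% 40L,
          mask = !shaft,
          image_id = cfg[["image_id"]] %||% basename(cfg[["image"]])
        )
        p <- file.path(cfg[["out_dir"]], "enrichment_factor.csv")
        readr::write_csv(rec, p)
        add_artifact(p)
        outputs <- as.list(rec)
      } else if (cfg[["stage"]] == "sa_census") {
        truth <- readr::read_csv(cfg[["truth"]], show_col_types = FALSE)
        census <- spine_census(truth)
        p <- file.path(cfg[["out_dir"]], "census.csv")
        readr::write_csv(census, p)
        add_artifact(p)
        outputs <- as.list(census)
      }
    },
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  structure(
    list(
      stage = cfg[["stage"]],
      config = cfg,
      seed = seed,
      outputs = outputs,
      artifacts = artifacts,
      warnings = warnings_seen
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report stage=%s seed=%d>\n", x$stage, x$seed))
  for (nm in names(x$outputs)) {
    val <- x$outputs[[nm]]
    cat(sprintf(
      "  %s: %s\n", nm,
      if (is.numeric(val)) format(val, digits = 6) else as.character(val)
    ))
  }
  if (length(x$warnings) > 0) {
    cat(sprintf("  warnings: %d\n", length(x$warnings)))
  }
  invisible(x)
}
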