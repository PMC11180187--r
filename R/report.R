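#' Recompute the embedded-fixture results and compare with expectations
#'
#' Runs marginal means, the AMMI decomposition, the GGE fit and the
#' qualitative biplot geometry on both embedded yield matrices and compares
#' each quantity against the expected values stored with the package, at the
#' stated tolerances (percentage shares carry a rounding tolerance because
#' the fixtures are printed to 2 decimal places; marginal means are checked
#' at half a unit of the last printed digit).
#'
#' @param out Optional path; when given, the report is written there as JSON.
#' @param tolerance_pct Tolerance (percentage points) for the axis-share
#'   checks; default 1.5.
#' @return Tibble with `check`, `value`, `expected`, `tol`, `pass` (logical;
#'   NA for qualitative checks reported as pass/fail only), invisibly a
#'   `pass_all` attribute over the quantitative checks.
#' @export
reproduce_paper <- function(out = NULL, tolerance_pct = 1.5) {
  stopifnot(tolerance_pct >= 0)
  rows <- list()
  add <- function(check, value, expected, tol) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, value = as.numeric(value),
      expected = as.numeric(expected), tol = tol,
      pass = abs(as.numeric(value) - as.numeric(expected)) <= tol)
  }
  for (regime in c("AWD", "CF")) {
    m <- yield_fixture(regime)
    mm <- margin_means(m)
    fit <- ammi_fit(m)
    gge <- gge_fit(m)
    exp_pc1 <- if (regime == "AWD") 59.8 else 66.6
    exp_cum <- if (regime == "AWD") 85.5 else 91.6
    exp_gge <- if (regime == "AWD") 54.94 else 56.31
    exp_grand <- if (regime == "AWD") 4.85 else 4.84
    exp_max <- if (regime == "AWD") 4.95 else 5.03
    exp_min <- if (regime == "AWD") 4.62 else 4.73
    add(paste0(regime, "_grand_mean"), mm$grand, exp_grand, 0.005)
    add(paste0(regime, "_gen_mean_max"), max(mm$genotype), exp_max, 0.005)
    add(paste0(regime, "_gen_mean_min"), min(mm$genotype), exp_min, 0.005)
    add(paste0(regime, "_ammi_pc1_pct"), fit$pct_gei[1], exp_pc1,
        tolerance_pct)
    add(paste0(regime, "_ammi_cum2_pct"), fit$cum_pct[2], exp_cum,
        tolerance_pct)
    add(paste0(regime, "_gge_pc1_pct"), gge$pct[1], exp_gge, tolerance_pct)
  }
  report <- do.call(rbind, rows)

  # qualitative geometry cross-checks (close calls can flip under the 2-dp
  # rounding of the fixtures, so these are reported, not gating)
  awd <- yield_fixture("AWD"); cf <- yield_fixture("CF")
  qual <- tibble::tibble(
    check = c("AWD_ideal_genotype_first_G3", "CF_ideal_genotype_first_G3",
              "AWD_hull_contains_G4", "AWD_ideal_env_nearest_E2",
              "CF_ideal_env_farthest_E7"),
    result = c(
      ideal_genotype_ranking(gge_fit(awd, "genotype"))$genotype[1] == "G3",
      ideal_genotype_ranking(gge_fit(cf, "genotype"))$genotype[1] == "G3",
      "G4" %in% which_won_where(gge_fit(awd, "symmetric"))$polygon,
      ideal_environment_ranking(
        gge_fit(awd, "environment"))$environment[1] == "E2",
      utils::tail(ideal_environment_ranking(
        gge_fit(cf, "environment"))$environment, 1) == "E7"))

  if (!is.null(out)) {
    jsonlite::write_json(
      list(quantitative = report, qualitative = qual,
           tolerance_pct = tolerance_pct),
      out, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(report, "qualitative") <- qual
  attr(report, "pass_all") <- all(report$pass)
  report
}

#' Run the full pipeline on one trial and write its artifact directory
#'
#' Simulates (or accepts) a replicate-level trial, then runs the AMMI, GGE,
#' stability and (for multi-trait input) MGIDI stages, writing one CSV per
#' stage. Outputs are deterministic given the seed; an existing directory is
#' not overwritten unless `force = TRUE`.
#'
#' @param out_dir Output directory.
#' @param trial Optional [trial_table()]; when NULL one is simulated from
#'   [synthetic_spec()] with the given seed.
#' @param trait Trait to analyse (default `"GY"`).
#' @param seed Seed for the simulated trial.
#' @param pressure MGIDI selection pressure.
#' @param force Overwrite an existing output directory.
#' @return Invisibly, the vector of files written.
#' @export
run_pipeline <- function(out_dir, trial = NULL, trait = "GY", seed = 1L,
                         pressure = 0.2, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory ", out_dir,
         " exists and is not empty; use force = TRUE to overwrite",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(trial)) {
    trial <- simulate_met(synthetic_spec(seed = seed))$trial
  }
  m <- to_means(trial, trait)
  fit <- ammi_fit(m, trial)
  st <- stability_table(m, trial)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(fit$anova, "anova.csv")
  wr(ammi1_coords(fit), "ammi1_coords.csv")
  if (length(fit$singulars) >= 2) {
    wr(ammi2_coords(fit), "ammi2_coords.csv")
    wr(asv(fit), "asv.csv")
  }
  gge <- gge_fit(m)
  wr(data.frame(label = c(rownames(gge$gen_scores), rownames(gge$env_scores)),
                type = rep(c("gen", "env"),
                           c(nrow(gge$gen_scores), nrow(gge$env_scores))),
                rbind(gge$gen_scores, gge$env_scores)),
     "gge_scores.csv")
  wr(st$values, "stability.csv")
  wr(st$ranks, "stability_ranks.csv")
  wr(as.data.frame(stability_correlations(st)), "stability_corr.csv")

  traits <- attr(trial, "traits")
  if (length(traits) >= 2) {
    gm <- sapply(traits, function(tr) margin_means(to_means(trial, tr))$genotype)
    mg <- mgidi(gm, pressure = pressure)
    wr(mg$result$index, "mgidi.csv")
    wr(data.frame(trait = rownames(mg$model$loadings), mg$model$loadings,
                  communality = mg$model$communality),
       "mgidi_factors.csv")
    wr(mg$contributions, "mgidi_contributions.csv")
  }
  jsonlite::write_json(
    list(seed = seed, trait = trait, pressure = pressure,
         n_files = length(files), package_version =
           as.character(utils::packageVersion("metstab"))),
    file.path(out_dir, "run.json"), auto_unbox = TRUE)
  invisible(files)
}
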