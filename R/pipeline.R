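#' Lifestyle mean curves of the normalized moment arm
#'
#' For every lifestyle category and grid pose, the arithmetic mean and
#' standard error (sd/sqrt(n), reported only for n >= 2) of the normalized
#' IMMA across species, with a `dataset_feasible` flag that is FALSE
#' whenever at least one specimen flags the pose as anatomically
#' infeasible. Means include species at poses infeasible for them
#' individually (the values remain geometrically defined); the mask is
#' carried for display.
#'
#' @param profiles named list of (normalized) `imma_profile` objects on a
#'   common grid.
#' @param lifestyles named character vector: lifestyle per species.
#' @return data frame: lifestyle, abduction_deg, extension_deg, mean_imma,
#'   se_imma, n_species, dataset_feasible.
#' @export
lifestyle_curves <- function(profiles, lifestyles) {
  if (!all(names(profiles) %in% names(lifestyles)))
    .stop_geom("every profiled species needs a lifestyle")
  ref <- profiles[[1L]]$poses[, c("abduction_deg", "extension_deg")]
  for (p in profiles)
    if (!identical(p$poses[, c("abduction_deg", "extension_deg")], ref))
      .stop_geom("profiles are not on a common pose grid")
  vals <- vapply(profiles, function(p) p$poses$imma_cm, numeric(nrow(ref)))
  feas <- vapply(profiles, function(p) p$poses$feasible, logical(nrow(ref)))
  ls <- lifestyles[names(profiles)]
  out <- do.call(rbind, lapply(sort(unique(ls)), function(l) {
    v <- vals[, ls == l, drop = FALSE]
    n <- ncol(v)
    data.frame(lifestyle = l, ref,
               mean_imma = rowMeans(v),
               se_imma = if (n >= 2) apply(v, 1, stats::sd) / sqrt(n)
                         else NA_real_,
               n_species = n,
               dataset_feasible = apply(feas, 1, all))
  }))
  rownames(out) <- NULL
  out
}

#' Extract trait tables at the focal joint poses
#'
#' For each requested extension angle at the focal abduction, builds a
#' table of natural-log moment arm (`y`) and natural-log femoral diameter
#' (`x`) per species, plus one table for the osteological in-lever. If a
#' focal pose is flagged infeasible for some species the value is still
#' emitted with a warning, and the flag is carried.
#'
#' @param profiles named list of raw (cm) `imma_profile` objects.
#' @param diameters named vector of femoral diameters per species; entries
#'   may be vectors of repeated measurements, which are averaged before the
#'   log.
#' @param angles focal extension angles, degrees.
#' @param abduction focal abduction, degrees.
#' @return named list of data frames (`imma_40` etc. plus `in_lever`), each
#'   with columns species, y, x, feasible.
#' @export
select_focal_traits <- function(profiles, diameters,
                                angles = c(40, 80, 120), abduction = 30) {
  sp <- names(profiles)
  if (!all(sp %in% names(diameters)))
    .stop_geom("every species needs a femoral diameter")
  x <- vapply(sp, function(s) log(mean(as.numeric(diameters[[s]]))), numeric(1))
  out <- list()
  for (a in angles) {
    rowsel <- function(p) which(p$poses$abduction_deg == abduction &
                                  p$poses$extension_deg == a)
    idx <- vapply(profiles, function(p) {
      i <- rowsel(p)
      if (length(i) != 1L)
        .stop_geom("pose %g deg at %g deg abduction absent from the grid", a,
                   abduction)
      i
    }, integer(1))
    imma <- mapply(function(p, i) p$poses$imma_cm[i], profiles, idx)
    feas <- mapply(function(p, i) p$poses$feasible[i], profiles, idx)
    if (any(!feas))
      warning(sprintf("focal pose %g deg infeasible for: %s", a,
                      paste(sp[!feas], collapse = ", ")))
    out[[sprintf("imma_%g", a)]] <-
      data.frame(species = sp, y = log(imma), x = x, feasible = feas,
                 row.names = NULL)
  }
  il <- vapply(profiles, function(p) p$in_lever_cm, numeric(1))
  out$in_lever <- data.frame(species = sp, y = log(il), x = x,
                             feasible = TRUE, row.names = NULL)
  out
}

#' Run the full analysis pipeline on a bundle directory
#'
#' End-to-end orchestration: read the bundle, profile moment arms over the
#' pose grid, normalize and average per lifestyle, fit the lifestyle Markov
#' model, draw stochastic character maps, collapse them to a consensus
#' regime painting, extract the focal-pose trait tables (three extension
#' angles at the focal abduction plus the in-lever), fit the candidate
#' macroevolutionary models on each trait and rank them by AICc. Writes
#' tidy CSV/JSON reports and a provenance record; a fixed seed makes the
#' output byte-identical across reruns.
#'
#' @param bundle_dir directory in the [write_dataset()] layout.
#' @param out_dir output directory.
#' @param seed integer seed for the stochastic-mapping stage.
#' @param n_maps number of stochastic character maps.
#' @param focal_extensions,focal_abduction focal poses, degrees.
#' @param models candidate model names (see [model_spec()]).
#' @param grid pose grid (default the 57-pose protocol grid).
#' @param hl_grid,vy_grid model-fit grids (default [default_grids()]).
#' @return (invisibly) a list with profiles, curves, mk fit, painting,
#'   traits, fits and rankings.
#' @export
run_pipeline <- function(bundle_dir, out_dir, seed = 1L, n_maps = 1000,
                         focal_extensions = c(40, 80, 120),
                         focal_abduction = 30,
                         models = c("BM1", "OU3", "OU2_terr", "OU2_over"),
                         grid = generate_pose_grid(),
                         hl_grid = NULL, vy_grid = NULL) {
  if (!dir.exists(bundle_dir)) .stop_geom("bundle directory not found: %s", bundle_dir)
  if (!all(focal_extensions %in% grid$extension_deg) ||
      !focal_abduction %in% grid$abduction_deg)
    .stop_geom("focal poses must be contained in the pose grid")
  bundle <- read_dataset(bundle_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: geometry
  profiles <- lapply(bundle$models, profile_imma, grid = grid)
  diam <- stats::setNames(bundle$tips$diameter_cm, bundle$tips$species)
  norm_profiles <- lapply(names(profiles), function(s)
    normalize_profile(profiles[[s]], diam[[s]]))
  names(norm_profiles) <- names(profiles)
  prof_df <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.csv(prof_df, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE, quote = FALSE)

  ## stage 2: exploratory lifestyle curves
  lifestyles <- stats::setNames(
    lifestyle_states()[max.col(bundle$tip_priors[names(profiles), ,
                                                 drop = FALSE],
                               ties.method = "first")],
    names(profiles))
  curves <- lifestyle_curves(norm_profiles, lifestyles)
  utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE, quote = FALSE)

  ## stage 3: lifestyle reconstruction
  set.seed(seed)
  mk <- fit_mk(bundle$tree, bundle$tip_priors)
  maps <- sample_simmap(bundle$tree, bundle$tip_priors, mk, n_maps = n_maps)
  painting <- consensus_painting(maps)
  paint_df <- data.frame(parent = painting$tree$edge[, 1L],
                         child = painting$tree$edge[, 2L],
                         regime = painting$branch_regime)
  utils::write.csv(paint_df, file.path(out_dir, "painting.csv"),
                   row.names = FALSE, quote = FALSE)

  ## stage 4: focal traits and model comparison
  traits <- select_focal_traits(profiles, diam, angles = focal_extensions,
                                abduction = focal_abduction)
  fits <- list(); rankings <- list()
  for (tn in names(traits)) {
    fits[[tn]] <- lapply(models, function(mn)
      fit_model(model_spec(mn), bundle$tree, painting, traits[[tn]],
                hl_grid = hl_grid, vy_grid = vy_grid))
    names(fits[[tn]]) <- models
    rankings[[tn]] <- cbind(trait = tn, rank_models(fits[[tn]]))
  }
  rank_df <- do.call(rbind, rankings)
  rownames(rank_df) <- NULL
  utils::write.csv(rank_df, file.path(out_dir, "ranking.csv"),
                   row.names = FALSE, quote = FALSE)
  fit_report <- lapply(fits, function(per_trait)
    lapply(per_trait, function(f) list(
      model = f$spec$name, n = f$n, k = f$spec$k, logLik = f$logLik,
      AICc = f$AICc, SIC = f$SIC,
      theta = as.list(f$theta), theta_se = as.list(f$theta_se),
      b = f$b, b_se = f$b_se,
      hl = f$ml_point[["hl"]], vy = f$ml_point[["vy"]],
      support = as.list(f$support))))
  jsonlite::write_json(fit_report, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  cfg_txt <- paste(utils::capture.output(utils::str(list(
    seed = seed, n_maps = n_maps, focal_extensions = focal_extensions,
    focal_abduction = focal_abduction, models = models))), collapse = "\n")
  prov <- list(package = "imma",
               version = as.character(utils::packageVersion("imma")),
               seed = seed, n_maps = n_maps,
               focal_extensions = focal_extensions,
               focal_abduction = focal_abduction,
               models = models, config_hash = .fnv1a(cfg_txt))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profiles = profiles, curves = curves, mk = mk,
                 painting = painting, traits = traits, fits = fits,
                 ranking = rank_df))
}
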