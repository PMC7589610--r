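#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis: paths, master seed,
#' component-selection settings, split fraction, trend tolerance and
#' accuracy metric. The master seed drives independent derived streams per
#' stage (simulation, splitting), so changing one stage's draws does not
#' shift another's.
#'
#' @param input path to a dataset CSV (not needed for `simulate`).
#' @param output_dir directory for artifacts; created if absent.
#' @param seed master RNG seed.
#' @param h_max maximum components considered during selection.
#' @param threshold Q-squared retention threshold, in (0, 1).
#' @param test_fraction held-out fraction, in (0, 0.5].
#' @param flat_tol relative excursion below which a trend is negligible.
#' @param metric accuracy metric name.
#' @param config path to a YAML generator config for `simulate` (optional).
#' @param delimiter dataset field delimiter.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = ".", seed = 1,
                       h_max = 4, threshold = q2_threshold(),
                       test_fraction = 0.2, flat_tol = 0.02,
                       metric = "mare", config = NULL, delimiter = ",") {
  stopifnot_scalar_in(threshold, "threshold", 0, 1, open_lo = TRUE, open_hi = TRUE)
  stopifnot_scalar_in(test_fraction, "test_fraction", 0, 0.5, open_lo = TRUE)
  structure(list(input = input, output_dir = output_dir,
                 seed = as.integer(seed), h_max = as.integer(h_max),
                 threshold = threshold, test_fraction = test_fraction,
                 flat_tol = flat_tol, metric = metric, config = config,
                 delimiter = delimiter),
            class = "run_config")
}

fingerprint <- function(cfg) {
  sprintf("# firefit seed=%d h_max=%d threshold=%.6g test_fraction=%.3g flat_tol=%.3g metric=%s",
          cfg$seed, cfg$h_max, cfg$threshold, cfg$test_fraction,
          cfg$flat_tol, cfg$metric)
}

write_artifact <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fingerprint(cfg), con)
  utils::write.table(format(df, digits = 12, trim = TRUE), con, sep = ",",
                     quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes one stage or the whole chain and writes every artifact under
#' `cfg$output_dir`. Stages:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort and write `dataset.csv`
#'     (plus the generator config used).}
#'   \item{fit}{fit a PLS model with `h_max` components capped at the data's
#'     limit and write `model.txt`.}
#'   \item{select}{leave-one-out component selection; writes `cv_table.csv`.}
#'   \item{sensitivity}{perturbation curves and trend table; one CSV per
#'     predictor plus `trends.csv`.}
#'   \item{evaluate}{split + leave-one-out evaluation; writes
#'     `evaluation.csv`.}
#'   \item{all}{read, summarize, split, select on the training rows, fit,
#'     sensitivity, evaluate — the full study protocol.}
#' }
#' Every artifact (except the round-trippable dataset CSV) starts with a
#' `#` comment carrying the configuration fingerprint, so outputs are
#' self-describing and byte-reproducible for a fixed seed.
#'
#' @param stage one of `"simulate"`, `"fit"`, `"select"`, `"sensitivity"`,
#'   `"evaluate"`, `"all"`.
#' @param cfg a [run_config()].
#' @return Invisibly, a named list of the paths written and the key fitted
#'   objects.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "fit", "select",
                                   "sensitivity", "evaluate"),
                         cfg = run_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(paths = character(0))
  path_of <- function(name) file.path(cfg$output_dir, name)

  if (stage == "simulate") {
    gen <- if (!is.null(cfg$config)) read_synthetic_config(cfg$config) else
      synthetic_config(seed = derive_seed(cfg$seed, "simulate"))
    ds <- generate_dataset(gen)
    write_dataset(ds, path_of("dataset.csv"), cfg$delimiter)
    yaml::write_yaml(list(n_subjects = gen$n, latent_rank = gen$latent_rank,
                          noise_sd_x = gen$noise_sd_x, noise_sd_y = gen$noise_sd_y,
                          seed = gen$seed),
                     path_of("generator_config.yaml"))
    out$dataset <- ds
    out$paths <- c(path_of("dataset.csv"), path_of("generator_config.yaml"))
    return(invisible(out))
  }

  if (is.null(cfg$input)) stop("cfg$input is required for this stage", call. = FALSE)
  ds <- read_dataset(cfg$input, cfg$delimiter)

  if (stage == "fit") {
    h <- min(cfg$h_max, nrow(ds$X) - 1L, ncol(ds$X))
    fit <- fit_plsr(ds, h = h)
    write_pls_model(fit, path_of("model.txt"))
    out$model <- fit
    out$paths <- path_of("model.txt")
    return(invisible(out))
  }

  if (stage == "select") {
    sel <- select_components(ds, h_max = cfg$h_max, threshold = cfg$threshold)
    write_artifact(sel$table, path_of("cv_table.csv"), cfg)
    message(sprintf("selected h=%d component(s)%s", sel$h,
                    if (sel$significant) "" else " (non-significant)"))
    out$selection <- sel
    out$paths <- path_of("cv_table.csv")
    return(invisible(out))
  }

  if (stage == "sensitivity") {
    summ <- compute_summary(ds)
    sel <- select_components(ds, h_max = cfg$h_max, threshold = cfg$threshold)
    fit <- fit_plsr(ds, h = sel$h)
    curves <- perturb_predict(fit, summ, quiet = TRUE)
    paths <- character(0)
    for (j in seq_along(curves)) {
      df <- data.frame(level = build_grid(summ)$levels[, j], curves[[j]],
                       check.names = FALSE)
      paths <- c(paths, write_artifact(df, path_of(sprintf("sensitivity_%s.csv",
                                                           names(curves)[j])), cfg))
    }
    trends <- classify_trends(curves, cfg$flat_tol)
    paths <- c(paths, write_artifact(
      data.frame(predictor = rownames(trends), trends, check.names = FALSE),
      path_of("trends.csv"), cfg))
    out$curves <- curves
    out$trends <- trends
    out$paths <- paths
    return(invisible(out))
  }

  if (stage == "evaluate") {
    sel <- select_components(ds, h_max = cfg$h_max, threshold = cfg$threshold)
    rep <- loo_report(ds, h = sel$h, test_fraction = cfg$test_fraction,
                      seed = cfg$seed, metric = cfg$metric)
    df <- data.frame(set = c(rep("train", length(rep$train_per_response)), "train",
                             rep("test", length(rep$test_per_response)), "test"),
                     response = c(names(rep$train_per_response), "overall",
                                  names(rep$test_per_response), "overall"),
                     accuracy = c(rep$train_per_response, rep$train_overall,
                                  rep$test_per_response, rep$test_overall))
    write_artifact(df, path_of("evaluation.csv"), cfg)
    out$report <- rep
    out$paths <- path_of("evaluation.csv")
    return(invisible(out))
  }

  # stage == "all": the full study protocol
  write_dataset(ds, path_of("dataset.csv"), cfg$delimiter)
  summ <- compute_summary(ds)
  write_artifact(as.data.frame(summ), path_of("summary.csv"), cfg)
  sp <- split_dataset(ds, cfg$test_fraction, cfg$seed)
  sel <- select_components(sp$train, h_max = cfg$h_max, threshold = cfg$threshold)
  write_artifact(sel$table, path_of("cv_table.csv"), cfg)
  fit <- fit_plsr(sp$train, h = sel$h)
  write_pls_model(fit, path_of("model.txt"))
  curves <- perturb_predict(fit, summ, quiet = TRUE)
  grid <- build_grid(summ)
  sens_paths <- character(0)
  for (j in seq_along(curves)) {
    df <- data.frame(level = grid$levels[, j], curves[[j]], check.names = FALSE)
    sens_paths <- c(sens_paths,
                    write_artifact(df, path_of(sprintf("sensitivity_%s.csv",
                                                       names(curves)[j])), cfg))
  }
  trends <- classify_trends(curves, cfg$flat_tol)
  write_artifact(data.frame(predictor = rownames(trends), trends,
                            check.names = FALSE),
                 path_of("trends.csv"), cfg)
  rep <- loo_report(ds, h = sel$h, test_fraction = cfg$test_fraction,
                    seed = cfg$seed, metric = cfg$metric)
  df <- data.frame(set = c(rep("train", length(rep$train_per_response)), "train",
                           rep("test", length(rep$test_per_response)), "test"),
                   response = c(names(rep$train_per_response), "overall",
                                names(rep$test_per_response), "overall"),
                   accuracy = c(rep$train_per_response, rep$train_overall,
                                rep$test_per_response, rep$test_overall))
  write_artifact(df, path_of("evaluation.csv"), cfg)
  out <- list(dataset = ds, summary = summ, split = sp, selection = sel,
              model = fit, curves = curves, trends = trends, report = rep,
              paths = c(path_of("dataset.csv"), path_of("summary.csv"),
                        path_of("cv_table.csv"), path_of("model.txt"),
                        sens_paths, path_of("trends.csv"),
                        path_of("evaluation.csv")))
  invisible(out)
}
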