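# End-to-end experiment runner: simulate -> sample -> learn -> classify ->
# evaluate, over a grid of sample-size ratios and repeated seeds, with
# reproducible outputs.

#' Read a flat key-value experiment configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Comma-separated
#' values become vectors. Keys mirror the arguments of
#' [experiment_config()].
#'
#' @param path config file path.
#' @return an `"experiment_config"` list.
#' @export
read_experiment_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), function(p) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    if (grepl(",", val, fixed = TRUE)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (!any(is.na(num))) val <- num
    if (identical(val, "TRUE") || identical(val, "FALSE"))
      val <- as.logical(val)
    stats::setNames(list(val), key)
  })
  do.call(experiment_config, do.call(c, kv))
}

#' Build an experiment configuration
#'
#' @param preset scene preset (`"phi"`, `"aviris"`, `"none"`).
#' @param rows,cols,bands,n_classes,snr_db,mix_fraction,scene_seed scene
#'   parameters (see [scene_spec()]); `bands`/`n_classes` default from the
#'   preset.
#' @param ratios training-set sizes as multiples of the band count.
#' @param per_class optional fixed per-class training count overriding
#'   `ratios` (a single-element "ratio" sweep is then run).
#' @param repeats number of repeated training draws per ratio.
#' @param seed base seed; every run's draw seed is derived from it.
#' @param contamination fraction of each class's training spectra replaced
#'   by other-class pixels before learning.
#' @param bag_size,refine,normalize,xi,max_iter,coef_threshold model
#'   settings (see [ncm_ddsr()]).
#' @param methods subset of `c("ncm_ddsr", "pca_mind", "svm")`.
#' @param out_dir output directory (`NULL`: nothing written).
#' @return an `"experiment_config"` list.
#' @export
experiment_config <- function(preset = "phi", rows = 42, cols = 42,
                              bands = NULL, n_classes = NULL, snr_db = 30,
                              mix_fraction = 0, scene_seed = 1,
                              ratios = 0.5, per_class = NULL, repeats = 1,
                              seed = 1, contamination = 0, bag_size = 1,
                              refine = FALSE, normalize = FALSE, xi = 1e-3,
                              max_iter = NULL, coef_threshold = 0.5,
                              methods = c("ncm_ddsr", "pca_mind"),
                              out_dir = NULL) {
  stopifnot(all(ratios > 0), repeats >= 1)
  methods <- match.arg(methods, c("ncm_ddsr", "pca_mind", "svm"),
                       several.ok = TRUE)
  structure(as.list(environment()), class = "experiment_config")
}

# one learn+classify+evaluate run for a given training draw
.run_once <- function(truth, config, ratio, draw_seed, method) {
  training <- sample_training(truth, ratio_to_bands = ratio,
                              seed = draw_seed,
                              per_class = config$per_class)
  if (config$contamination > 0)
    training <- contaminate_training(training, truth,
                                     config$contamination,
                                     seed = draw_seed + 1L)
  pred <- switch(method,
    ncm_ddsr = {
      fit <- ncm_ddsr(training, bag_size = config$bag_size,
                      refine = config$refine, normalize = config$normalize,
                      xi = config$xi, max_iter = config$max_iter,
                      coef_threshold = config$coef_threshold)
      predict(fit, truth$cube)
    },
    pca_mind = predict(fit_pca_mind(training), truth$cube),
    svm = svm_baseline(training, truth$cube)
  )
  ev <- evaluate_map(truth$labels, pred)
  list(pred = pred,
       metrics = list(overall_accuracy = ev$overall_accuracy,
                      kappa = ev$kappa, n = ev$n))
}

#' Run the full simulate/learn/classify/evaluate pipeline
#'
#' Renders the configured synthetic scene, then for every ratio x repeat x
#' method combination draws training pixels, learns the model, classifies
#' the cube and scores it against ground truth. Optionally writes per-run
#' classification maps, a metrics JSON, a sweep table (methods x ratios of
#' mean overall accuracy and kappa) and a reproducibility manifest under
#' `config$out_dir`. Fully deterministic given the configuration.
#'
#' @param config an [experiment_config()] (or a path to a config file).
#' @return invisibly, a list with `sweep` (data.frame: method, ratio,
#'   oa_mean, oa_sd, kappa_mean, kappa_sd), `runs` (nested per-run metrics),
#'   `truth` (the rendered scene).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  spec <- scene_spec(rows = config$rows, cols = config$cols,
                     bands = config$bands, n_classes = config$n_classes,
                     snr_db = config$snr_db,
                     mix_fraction = config$mix_fraction,
                     seed = config$scene_seed, preset = config$preset)
  truth <- render_scene(spec)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  ratios <- if (!is.null(config$per_class)) config$ratios[1] else config$ratios
  rows <- list(); runs <- list()
  for (ri in seq_along(ratios)) {
    for (method in config$methods) {
      oa <- numeric(config$repeats); ka <- numeric(config$repeats)
      for (r in seq_len(config$repeats)) {
        draw_seed <- config$seed + 1000L * ri + 10L * r
        res <- .run_once(truth, config, ratios[ri], draw_seed, method)
        oa[r] <- res$metrics$overall_accuracy
        ka[r] <- res$metrics$kappa
        runs[[sprintf("ratio_%g/%s/rep_%d", ratios[ri], method, r)]] <-
          res$metrics
        if (!is.null(out_dir))
          write_label_grid(res$pred,
                           file.path(out_dir,
                                     sprintf("map_%s_ratio%g_rep%d.txt",
                                             method, ratios[ri], r)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, ratio = ratios[ri],
        oa_mean = mean(oa), oa_sd = if (length(oa) > 1) stats::sd(oa) else 0,
        kappa_mean = mean(ka),
        kappa_sd = if (length(ka) > 1) stats::sd(ka) else 0)
    }
  }
  sweep_tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(sweep_tab, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(sweep = sweep_tab, runs = runs),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(config, out_dir)
  }
  invisible(list(sweep = sweep_tab, runs = runs, truth = truth))
}

# reproducibility manifest: config dump + hash + package version
write_manifest <- function(config, out_dir) {
  cfg <- config[!vapply(config, is.null, logical(1))]
  cfg <- cfg[order(names(cfg))]
  dump <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(format(cfg[[k]]), collapse = ", ")),
    character(1))
  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(dump, cfg_path)
  manifest <- c(
    sprintf("package_version = %s",
            as.character(utils::packageVersion("ddsr"))),
    sprintf("config_md5 = %s", unname(tools::md5sum(cfg_path))),
    sprintf("base_seed = %d", as.integer(config$seed))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(NULL)
}
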