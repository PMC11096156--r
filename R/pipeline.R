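#' Default pipeline configuration
#'
#' Every stage parameter with its default, as a nested list that
#' round-trips losslessly through YAML (see [write_run_config()]).
#' All randomness in a run flows from the single `seed`, expanded into
#' per-stage seeds.
#'
#' @param workdir directory that receives all stage outputs.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(workdir = "pearloct-run") {
  structure(list(
    seed = 1L,
    paths = list(workdir = workdir, images = "images", rois = "rois",
                 features = "features.csv", report = "report.json",
                 mask = "mask.json", manifest = "manifest.json"),
    simulate = list(n_per_class = 29L, image_height = 512L,
                    image_width = 512L, surface_apex_row = 140,
                    surface_curvature = 0.0012, nacre_thickness = 220,
                    background_noise_sigma = 4,
                    class_params = lapply(default_class_params(), unclass)),
    preprocess = list(degree = 2L, target_row = 20L, offset = 2L,
                      roi_size = 128L, canny_sigma = 2),
    train = list(model = "rfc", runs = 10L, iterations = 50L, folds = 5L,
                 train_fraction = 0.8, pca_k = NULL),
    select = list(enabled = FALSE, fraction = 0.2, model = "rfc")),
    class = "run_config")
}

#' Write / read a pipeline configuration
#'
#' @param cfg a `run_config` list.
#' @param path YAML file.
#' @return `write_run_config` invisibly returns `path`;
#'   `read_run_config` returns the `run_config` (defaults filled in for
#'   omitted keys).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- modifyList(unclass(default_run_config()), yaml::read_yaml(path))
  # a NULL pca_k means "no reduction"; YAML drops the key, restore it
  if (is.null(cfg$train$pca_k)) cfg$train["pca_k"] <- list(NULL)
  structure(cfg, class = "run_config")
}

config_synth <- function(cfg) {
  s <- cfg$simulate
  synth_config(image_height = s$image_height, image_width = s$image_width,
               surface_apex_row = s$surface_apex_row,
               surface_curvature = s$surface_curvature,
               nacre_thickness = s$nacre_thickness,
               background_noise_sigma = s$background_noise_sigma,
               class_params = lapply(s$class_params, function(p)
                 do.call(speckle_params, p)))
}

stage_path <- function(cfg, key) file.path(cfg$paths$workdir, cfg$paths[[key]])

require_stage_output <- function(path, stage) {
  if (!file.exists(path))
    stop("missing output of stage '", stage, "': ", path,
         "; run that stage first", call. = FALSE)
  invisible(path)
}

#' Run the end-to-end grading pipeline
#'
#' Executes the requested stages in order — `simulate` (synthetic B-scans +
#' manifest CSV), `preprocess` (ROI extraction, PNG + JSON sidecars),
#' `extract` (the 237-column feature CSV), `train` (repeated
#' split/tune/evaluate, report JSON) and optionally `select` (backward SFS
#' mask JSON) — and writes a run manifest with the config snapshot, package
#' version, per-stage output checksums, timestamps and seeds. Stages
#' consuming a missing upstream output abort with the missing stage named.
#'
#' @param cfg a `run_config` (or path to a YAML config).
#' @param stages subset of stages to execute, in pipeline order.
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, the manifest list (also written to
#'   `paths$manifest`).
#' @export
run_pipeline <- function(cfg = default_run_config(),
                         stages = c("simulate", "preprocess", "extract",
                                    "train"),
                         quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stages <- match.arg(stages, c("simulate", "preprocess", "extract",
                                "train", "select"), several.ok = TRUE)
  wd <- cfg$paths$workdir
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage_seeds <- setNames(sample.int(.Machine$integer.max, 5),
                          c("simulate", "preprocess", "extract", "train",
                            "select"))
  say <- function(...) if (!quiet) message("[pearloct] ", ...)
  manifest <- list(config = unclass(cfg),
                   version = as.character(packageVersion("pearloct")),
                   seeds = as.list(stage_seeds), stages = list())
  note <- function(stage, outputs) {
    files <- outputs[file.exists(outputs)]
    manifest$stages[[stage]] <<- list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = as.list(setNames(unname(tools::md5sum(files)), files)))
  }

  img_dir <- stage_path(cfg, "images")
  roi_dir <- stage_path(cfg, "rois")
  feat_csv <- stage_path(cfg, "features")

  if ("simulate" %in% stages) {
    say("simulate: ", 4 * cfg$simulate$n_per_class, " B-scans")
    scfg <- config_synth(cfg)
    ds <- generate_dataset(scfg, cfg$simulate$n_per_class,
                           seed = stage_seeds[["simulate"]])
    write_dataset(ds, scfg, img_dir)
    note("simulate", file.path(img_dir, "manifest.csv"))
  }

  if ("preprocess" %in% stages) {
    require_stage_output(file.path(img_dir, "manifest.csv"), "simulate")
    man <- read.csv(file.path(img_dir, "manifest.csv"))
    say("preprocess: ", nrow(man), " images")
    dir.create(roi_dir, showWarnings = FALSE)
    pp <- cfg$preprocess
    for (i in seq_len(nrow(man))) {
      img <- read_bscan(file.path(img_dir, man$filename[i]))
      loc <- locate_roi(img, degree = pp$degree, target_row = pp$target_row,
                        offset = pp$offset, size = pp$roi_size,
                        canny_sigma = pp$canny_sigma)
      base <- tools::file_path_sans_ext(man$filename[i])
      write_bscan_png(loc$roi$pixels, file.path(roi_dir, paste0(base, "_roi.png")))
      jsonlite::write_json(
        list(source = man$filename[i], label = man$label[i],
             threshold = loc$stats$threshold,
             poly_coeffs = loc$fit$poly_coeffs,
             residual_rms = loc$fit$residual_rms,
             origin_row = loc$roi$origin_row,
             origin_col = loc$roi$origin_col),
        file.path(roi_dir, paste0(base, "_roi.json")),
        auto_unbox = TRUE, digits = NA)
    }
    note("preprocess", list.files(roi_dir, full.names = TRUE))
  }

  if ("extract" %in% stages) {
    require_stage_output(roi_dir, "preprocess")
    sidecars <- list.files(roi_dir, pattern = "_roi\\.json$",
                           full.names = TRUE)
    if (!length(sidecars))
      stop("missing output of stage 'preprocess': no ROI sidecars in ",
           roi_dir, call. = FALSE)
    say("extract: ", length(sidecars), " ROIs -> 237 features each")
    rows <- lapply(sidecars, function(js) {
      meta <- jsonlite::read_json(js, simplifyVector = TRUE)
      roi <- read_bscan(sub("\\.json$", ".png", js))
      fv <- assemble_features(roi)
      cbind(as.data.frame(t(fv)), label = meta$label, source_id = meta$source)
    })
    write.csv(do.call(rbind, rows), feat_csv, row.names = FALSE)
    note("extract", feat_csv)
  }

  if ("train" %in% stages) {
    require_stage_output(feat_csv, "extract")
    tab <- read_feature_csv(feat_csv)
    tr <- cfg$train
    say("train: ", tr$model, ", ", tr$runs, " runs x ", tr$iterations,
        " search iterations")
    report <- repeated_experiment(
      tab, model_kind = tr$model, n_runs = tr$runs,
      train_fraction = tr$train_fraction,
      space = search_space(iterations = tr$iterations, folds = tr$folds),
      pca_k = tr$pca_k, seed = stage_seeds[["train"]])
    jsonlite::write_json(
      list(model = tr$model, pca_k = tr$pca_k, n_runs = tr$runs,
           per_run = report$per_run, aggregate = report$aggregate,
           confusions = lapply(report$confusions, unclass)),
      stage_path(cfg, "report"), auto_unbox = TRUE, digits = NA)
    note("train", stage_path(cfg, "report"))
  }

  if ("select" %in% stages) {
    require_stage_output(feat_csv, "extract")
    tab <- read_feature_csv(feat_csv)
    sl <- cfg$select
    say("select: backward SFS, fraction ", sl$fraction)
    mask <- sequential_select(tab, model_kind = sl$model,
                              fraction = sl$fraction,
                              seed = stage_seeds[["select"]])
    jsonlite::write_json(
      list(fraction = mask$fraction, selected = unname(mask$selected),
           feature_names = names(mask$selected),
           family_counts = as.list(mask$family_counts)),
      stage_path(cfg, "mask"), auto_unbox = TRUE, digits = NA)
    note("select", stage_path(cfg, "mask"))
  }

  jsonlite::write_json(manifest, stage_path(cfg, "manifest"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a feature CSV back into a feature table
#'
#' @param path CSV written by the extract stage (237 feature columns plus
#'   `label` and `source_id`).
#' @return A [feature_table()].
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- intersect(c("label", "source_id"), names(df))
  feature_table(as.matrix(df[setdiff(names(df), meta)]), df$label)
}
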