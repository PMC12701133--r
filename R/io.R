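# Readers and writers for the pipeline's interchange formats (clinical CSV,
# COCO-style annotation JSON, PNG images, JSON reports), the run
# configuration, and the command-line entry point.

#' Write a clinical cohort CSV
#'
#' @param cohort Data frame from [generate_clinical_cohort()] (or with the
#'   same columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clinical_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical cohort CSV
#'
#' Expects a header naming the 36 indicator columns plus `label` (and
#' optionally `patient_id`). Non-numeric indicator cells become `NA`
#' (explicitly coded missing, never silently zero).
#'
#' @param path CSV file.
#' @param indicator_names Expected indicator columns (default the canonical
#'   36).
#' @return Data frame with `patient_id`, indicators and integer `label`.
#' @export
read_clinical_csv <- function(path, indicator_names = clinical_indicator_names()) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  have <- setdiff(names(df), c("patient_id", "label"))
  missing <- setdiff(indicator_names, have)
  extra <- setdiff(have, indicator_names)
  if (length(missing) || length(extra)) {
    stop("clinical CSV schema mismatch; missing columns: ",
         if (length(missing)) paste(missing, collapse = ", ") else "none",
         "; unexpected columns: ",
         if (length(extra)) paste(extra, collapse = ", ") else "none")
  }
  if (!"label" %in% names(df)) stop("clinical CSV lacks a 'label' column")
  lab_raw <- df$label
  lab <- suppressWarnings(as.numeric(lab_raw))
  bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary label at row ", bad[1L], ": '", lab_raw[bad[1L]], "'")
  }
  ind <- df[, indicator_names, drop = FALSE]
  for (j in seq_along(ind)) {
    ind[[j]] <- suppressWarnings(as.numeric(ind[[j]]))
  }
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(df)) df$patient_id else
      sprintf("P%04d", seq_len(nrow(df))),
    ind, label = as.integer(lab), check.names = FALSE)
  out
}

#' Write COCO-style annotations
#'
#' Boxes are converted from the internal half-open corner convention to the
#' COCO `[x, y, w, h]` form.
#'
#' @param boxes Data frame with `image_id`, `class` and corner columns.
#' @param path Output JSON file.
#' @param image_size `c(height, width)` recorded for every listed image.
#' @param image_ids Image ids to list (default: those present in `boxes`).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(boxes, path, image_size,
                              image_ids = sort(unique(boxes$image_id))) {
  cats <- data.frame(id = c(1L, 2L), name = c("eye", "lip"))
  imgs <- lapply(image_ids, function(i) {
    list(id = i, height = image_size[1L], width = image_size[2L],
         file_name = sprintf("img_%04d.png", i))
  })
  anns <- lapply(seq_len(nrow(boxes)), function(k) {
    list(id = k, image_id = boxes$image_id[k],
         category_id = cats$id[match(boxes$class[k], cats$name)],
         bbox = c(boxes$x_min[k], boxes$y_min[k],
                  boxes$x_max[k] - boxes$x_min[k],
                  boxes$y_max[k] - boxes$y_min[k]))
  })
  jsonlite::write_json(list(images = imgs, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style annotations
#'
#' Boxes are converted to the internal 0-based half-open corner convention
#' and category ids resolved to names. Annotations referencing unknown
#' images are an error; degenerate boxes (non-positive width or height) are
#' dropped with a warning and counted in the `"n_dropped"` attribute.
#'
#' @param path JSON file with `images`, `annotations`, `categories`.
#' @return Named list mapping image id to a data frame of ground-truth
#'   boxes (possibly empty).
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  img_ids <- doc$images$id
  cats <- doc$categories
  out <- stats::setNames(
    lapply(img_ids, function(i) data.frame(
      image_id = integer(0), class = character(0), x_min = numeric(0),
      y_min = numeric(0), x_max = numeric(0), y_max = numeric(0))),
    as.character(img_ids))
  ann <- doc$annotations
  n_dropped <- 0L
  if (!is.null(ann) && length(ann) && nrow(as.data.frame(ann))) {
    ann <- as.data.frame(ann)
    bb <- do.call(rbind, ann$bbox)
    unknown <- setdiff(unique(ann$image_id), img_ids)
    if (length(unknown)) {
      stop("annotation references unknown image id(s): ",
           paste(unknown, collapse = ", "))
    }
    keep <- bb[, 3L] > 0 & bb[, 4L] > 0
    n_dropped <- sum(!keep)
    if (n_dropped) {
      warning(n_dropped, " degenerate box(es) with non-positive size dropped")
    }
    ann <- ann[keep, , drop = FALSE]; bb <- bb[keep, , drop = FALSE]
    df <- data.frame(image_id = ann$image_id,
                     class = cats$name[match(ann$category_id, cats$id)],
                     x_min = bb[, 1L], y_min = bb[, 2L],
                     x_max = bb[, 1L] + bb[, 3L], y_max = bb[, 2L] + bb[, 4L])
    for (i in as.character(unique(df$image_id))) {
      out[[i]] <- df[df$image_id == as.integer(i), , drop = FALSE]
    }
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write images as PNG files
#'
#' @param images List of labeled images (`$image` greyscale matrices in
#'   `[0, 1]`).
#' @param dir Output directory (created if needed).
#' @return Written file paths, invisibly.
#' @export
write_images <- function(images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(images, function(im) {
    p <- file.path(dir, sprintf("img_%04d.png", im$id))
    png::writePNG(im$image, p)
    p
  }, "")
  invisible(paths)
}

#' Read PNG images from a directory
#'
#' @param dir Directory of `img_*.png` files.
#' @return List of `list(image, id)` in file order.
#' @export
read_images <- function(dir) {
  files <- sort(list.files(dir, pattern = "^img_.*\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    id <- as.integer(gsub("\\D", "", basename(f)))
    list(image = img, id = id)
  })
}

#' Default run configuration
#'
#' Every tolerance and threshold used by the pipeline is a configuration
#' key; a YAML file can override any subset.
#'
#' @param seed Integer master seed.
#' @return Nested configuration list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    image_size = 96L,
    n_images = 60L,
    n_patients = 120L,
    gamma = 1.2,
    beta_scale = 1,
    contrast = 0.45,
    noise_sd = 0.02,
    occlusion_prob = 0,
    anchor_scales = list(c(10, 14, 19), c(28, 40), c(56, 80)),
    anchor_aspects = c(0.35, 0.7, 1.0),
    iou_thresholds = seq(0.5, 0.95, by = 0.05),
    iou_pos = 0.5, iou_neg = 0.4,
    score_thresh = 0.05, nms_iou = 0.5,
    detector_epochs = 12L, detector_lr = 5e-3,
    eted = list(hidden_size = 16L, n_timesteps = 6L, learning_rate = 3e-3,
                epochs = 40L, batch_size = 32L, patience = 10L),
    split = list(train_fraction = 0.8, stratified = TRUE),
    paths = list(images_dir = "images", annotations_file = "annotations.json",
                 clinical_csv = "cohort.csv", output_dir = "output")),
    class = "run_config")
}

validate_run_config <- function(cfg) {
  fr <- cfg$split$train_fraction
  if (!(fr > 0 && fr < 1)) stop("split$train_fraction must lie in (0, 1)")
  if (is.unsorted(cfg$iou_thresholds, strictly = TRUE)) {
    stop("iou_thresholds must be strictly increasing")
  }
  if (any(unlist(cfg[c("score_thresh", "nms_iou", "iou_pos", "iou_neg")]) < 0)) {
    stop("thresholds must be non-negative")
  }
  invisible(cfg)
}

#' Read a run configuration file
#'
#' @param path YAML file; keys override [default_run_config()].
#' @return Validated `"run_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_into <- function(base, upd) {
    for (k in names(upd)) {
      if (is.list(base[[k]]) && is.list(upd[[k]]) &&
          !is.null(names(base[[k]]))) {
        base[[k]] <- merge_into(base[[k]], upd[[k]])
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  cfg <- merge_into(cfg, user)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Write a JSON report
#'
#' @param x List of metric values.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

cli_usage <- function() {
  paste0(
    "usage: facesurv <command> --config <file.yaml> [--seed <int>]\n",
    "commands:\n",
    "  synth-images    generate annotated face-like images\n",
    "  synth-cohort    generate a synthetic clinical cohort CSV\n",
    "  train-detector  train the facial-feature detector\n",
    "  detect          run a trained detector over the images\n",
    "  train-eted      train the tabular survival classifier\n",
    "  evaluate        detection + classification metrics report\n",
    "  stats           group comparison and logistic regression tables\n",
    "  pipeline        full unimodal-vs-multimodal experiment\n")
}

cli_parse <- function(argv) {
  out <- list(command = NULL, config = NULL, seed = NULL)
  if (length(argv) < 1L) return(out)
  out$command <- argv[1L]
  i <- 2L
  while (i <= length(argv)) {
    if (argv[i] == "--config" && i < length(argv)) {
      out$config <- argv[i + 1L]; i <- i + 2L
    } else if (argv[i] == "--seed" && i < length(argv)) {
      out$seed <- as.integer(argv[i + 1L]); i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  out
}

run_config_to_specs <- function(cfg) {
  list(
    image_spec = synthetic_image_spec(
      n_images = cfg$n_images, image_size = cfg$image_size,
      contrast = cfg$contrast, noise_sd = cfg$noise_sd,
      occlusion_prob = cfg$occlusion_prob, seed = cfg$seed),
    cohort_spec = synthetic_cohort_spec(
      n_patients = cfg$n_patients, beta = cfg$beta_scale * default_beta(),
      gamma = cfg$gamma, seed = cfg$seed),
    detector_config = detector_config(
      image_size = cfg$image_size, anchor_scales = cfg$anchor_scales,
      anchor_aspects = cfg$anchor_aspects, iou_pos = cfg$iou_pos,
      iou_neg = cfg$iou_neg, score_thresh = cfg$score_thresh,
      nms_iou = cfg$nms_iou, epochs = cfg$detector_epochs,
      learning_rate = cfg$detector_lr, seed = cfg$seed),
    eted_config = eted_config(
      hidden_size = cfg$eted$hidden_size, n_timesteps = cfg$eted$n_timesteps,
      learning_rate = cfg$eted$learning_rate, epochs = cfg$eted$epochs,
      batch_size = cfg$eted$batch_size, patience = cfg$eted$patience,
      seed = cfg$seed))
}

#' Command-line entry point
#'
#' Dispatches the subcommands documented by the usage text; every
#' subcommand writes its outputs under the configured `output_dir` along
#' with a log echoing the seed and configuration, and reports are
#' deterministic for a fixed config and seed.
#'
#' @param argv Character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code (0 on success), invisibly.
#' @export
cli_main <- function(argv = character()) {
  opts <- cli_parse(argv)
  known <- c("synth-images", "synth-cohort", "train-detector", "detect",
             "train-eted", "evaluate", "stats", "pipeline")
  if (is.null(opts$command) || !opts$command %in% known) {
    message(cli_usage())
    return(invisible(2L))
  }
  if (is.null(opts$config)) {
    message("error: --config <file.yaml> is required")
    return(invisible(2L))
  }
  cfg <- tryCatch(read_config(opts$config), error = function(e) {
    message("error: ", conditionMessage(e))
    NULL
  })
  if (is.null(cfg)) return(invisible(1L))
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  out_dir <- cfg$paths$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  writeLines(c(paste("command:", opts$command), paste("seed:", cfg$seed),
               yaml::as.yaml(unclass(cfg))),
             file.path(out_dir, paste0(opts$command, "_config.log")))
  specs <- run_config_to_specs(cfg)
  code <- tryCatch({
    switch(opts$command,
      "synth-images" = {
        d <- generate_face_images(specs$image_spec)
        write_images(d$images, file.path(out_dir, cfg$paths$images_dir))
        write_annotations(d$annotations,
                          file.path(out_dir, cfg$paths$annotations_file),
                          c(cfg$image_size, cfg$image_size),
                          image_ids = seq_len(cfg$n_images))
      },
      "synth-cohort" = {
        co <- generate_clinical_cohort(specs$cohort_spec)
        write_clinical_csv(co, file.path(out_dir, cfg$paths$clinical_csv))
      },
      "train-detector" = {
        d <- generate_face_images(specs$image_spec)
        det <- train_detector(d$images, specs$detector_config)
        saveRDS(det, file.path(out_dir, "detector.rds"))
        write_report_json(list(final_loss = utils::tail(det$losses, 1L),
                               losses = det$losses),
                          file.path(out_dir, "detector_train_report.json"))
      },
      "detect" = {
        det <- readRDS(file.path(out_dir, "detector.rds"))
        d <- generate_face_images(specs$image_spec)
        dd <- do.call(rbind, lapply(d$images, function(im) {
          detect(im$image, det, image_id = im$id)
        }))
        utils::write.csv(dd, file.path(out_dir, "detections.csv"),
                         row.names = FALSE)
        # COCO-style results array alongside the CSV
        res <- lapply(seq_len(nrow(dd)), function(k) {
          list(image_id = dd$image_id[k],
               category_id = match(dd$class[k], c("eye", "lip")),
               bbox = c(dd$x_min[k], dd$y_min[k],
                        dd$x_max[k] - dd$x_min[k], dd$y_max[k] - dd$y_min[k]),
               score = dd$confidence[k])
        })
        jsonlite::write_json(res, file.path(out_dir, "detections.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      "train-eted" = {
        co <- generate_clinical_cohort(specs$cohort_spec)
        x <- as.matrix(co[, clinical_indicator_names()])
        fit <- train_eted(x, co$label, specs$eted_config)
        saveRDS(fit, file.path(out_dir, "eted.rds"))
        utils::write.csv(fit$history, file.path(out_dir, "eted_history.csv"),
                         row.names = FALSE)
        h <- fit$history[fit$best_epoch, ]
        write_report_json(list(best_epoch = fit$best_epoch,
                               val_accuracy = h$accuracy, val_auc = h$auc),
                          file.path(out_dir, "eted_train_report.json"))
      },
      "evaluate" = {
        rep <- run_pipeline(list(
          seed = cfg$seed,
          cohort_spec = specs$cohort_spec,
          image_spec_args = list(image_size = cfg$image_size,
                                 contrast = cfg$contrast,
                                 noise_sd = cfg$noise_sd),
          detector_config = specs$detector_config,
          eted_config = specs$eted_config,
          train_fraction = cfg$split$train_fraction))
        write_report_json(report_to_list(rep),
                          file.path(out_dir, "metrics_report.json"))
      },
      "stats" = {
        co <- generate_clinical_cohort(specs$cohort_spec)
        tab3 <- group_comparison_table(co)
        utils::write.csv(tab3, file.path(out_dir, "group_comparison.csv"),
                         row.names = FALSE)
        fit <- logistic_fit(as.matrix(co[, clinical_indicator_names()]),
                            co$label)
        utils::write.csv(fit$table, file.path(out_dir, "logistic_table.csv"),
                         row.names = FALSE)
      },
      "pipeline" = {
        rep <- run_pipeline(list(
          seed = cfg$seed,
          cohort_spec = specs$cohort_spec,
          image_spec_args = list(image_size = cfg$image_size,
                                 contrast = cfg$contrast,
                                 noise_sd = cfg$noise_sd),
          detector_config = specs$detector_config,
          eted_config = specs$eted_config,
          train_fraction = cfg$split$train_fraction))
        write_report_json(report_to_list(rep),
                          file.path(out_dir, "pipeline_report.json"))
      })
    0L
  }, error = function(e) {
    message("error in '", opts$command, "': ", conditionMessage(e))
    1L
  })
  invisible(code)
}

# Flatten a fusion report into plain JSON-ready values.
report_to_list <- function(rep) {
  cm <- function(m) list(accuracy = m$accuracy, precision = m$precision,
                         recall = m$recall, f1 = m$f1, auc = m$auc,
                         confusion = as.list(m$confusion))
  out <- list(seed = rep$seed, n_test = rep$n_test,
              unimodal = cm(rep$unimodal), multimodal = cm(rep$multimodal))
  if (!is.null(rep$detection)) {
    out$detection <- list(ap = rep$detection$ap, ar = rep$detection$ar,
                          map = rep$detection$map, ap50 = rep$detection$ap50,
                          precision = rep$detection$precision)
  }
  out
}
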