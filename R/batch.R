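#' Batch run configuration
#'
#' Collects every decision point of the pipeline into one object: which
#' colour carries the marker and which the query, how multi-slice stacks are
#' reduced, the analysed selection, the threshold, the particle filters,
#' manual ROI edits, group assignments for the statistics, and the seed.
#' These are the documented defaults applied when no persisted
#' configuration exists.
#'
#' @param marker_channel,query_channel Colour names (`"red"`, `"green"`,
#'   `"blue"`); must differ.
#' @param slice_policy `"max"` or `"single"` (see [split_channels()]).
#' @param slice 1-based slice index for `slice_policy = "single"`.
#' @param selection `NULL` (whole image), a vertex matrix / list of
#'   `[x, y]` pairs, a [selection_region()], or the path to an ImageJ
#'   `.roi` file.
#' @param threshold `NULL` for auto-thresholding or a [threshold_spec()]
#'   (a `list(min_level, max_level)` is accepted).
#' @param threshold_method Auto-threshold algorithm.
#' @param filter A [particle_filter()] (or a list of its arguments).
#' @param include_ids,exclude_ids ROI label edits applied to every image.
#' @param groups `NULL`, a named character vector mapping image file names
#'   to group names, or the path to a manifest CSV with `file` and `group`
#'   columns.
#' @param control_group Control group name for [fold_change()].
#' @param bg_stat Background statistic (`"mean"` or `"median"`).
#' @param out_dir Output directory for CSVs and the run log.
#' @param seed Integer seed recorded in the log (the pipeline itself is
#'   deterministic; the seed matters when the config drives synthetic
#'   generation).
#' @return An `fq_config` object.
#' @export
run_config <- function(marker_channel = "red", query_channel = "green",
                       slice_policy = "max", slice = NULL, selection = NULL,
                       threshold = NULL, threshold_method = "isodata",
                       filter = particle_filter(), include_ids = NULL,
                       exclude_ids = NULL, groups = NULL,
                       control_group = "control", bg_stat = "mean",
                       out_dir = "fluorquant_out", seed = NULL) {
  chans <- c("red", "green", "blue")
  if (!marker_channel %in% chans || !query_channel %in% chans) {
    stop("input error: channels must be one of red/green/blue")
  }
  if (marker_channel == query_channel) {
    stop("input error: marker and query channel must differ")
  }
  if (is.list(filter) && !inherits(filter, "particle_filter")) {
    filter <- do.call(particle_filter, filter)
  }
  if (!is.null(threshold) && !inherits(threshold, "threshold_spec")) {
    threshold <- do.call(threshold_spec, threshold)
  }
  structure(
    list(marker_channel = marker_channel, query_channel = query_channel,
         slice_policy = slice_policy, slice = slice,
         selection = selection, threshold = threshold,
         threshold_method = threshold_method, filter = filter,
         include_ids = include_ids, exclude_ids = exclude_ids,
         groups = groups, control_group = control_group, bg_stat = bg_stat,
         out_dir = out_dir, seed = seed),
    class = "fq_config"
  )
}

resolve_selection <- function(selection) {
  if (is.null(selection)) return(whole_image())
  if (inherits(selection, "selection_region")) return(selection)
  if (is.character(selection) && length(selection) == 1L) {
    return(read_imagej_roi(selection))
  }
  selection_region(selection)
}

resolve_groups <- function(groups, files) {
  if (is.null(groups)) return(NULL)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    man <- readr::read_csv(groups, show_col_types = FALSE)
    groups <- stats::setNames(as.character(man$group), man$file)
  }
  unname(groups[basename(files)])
}

#' Process a batch of images with one configuration
#'
#' Runs [quantify_image()] on every image with identical parameters, writes
#' one CSV per image plus a run-level `summary.csv`, computes group
#' statistics (`groups.csv`, `fold.csv`) when group assignments are given,
#' and writes a `run_log.txt` recording every effective parameter and the
#' software version — the log alone suffices to reproduce the run. A
#' failure on one image is recorded and the batch continues.
#'
#' @param config An [run_config()] object.
#' @param image_paths Character vector of TIFF paths (must be non-empty;
#'   all files must exist at run start).
#' @return A list of class `fq_batch`: `summary` (per-image tibble),
#'   `group_stats`, `fold` (tibbles or `NULL`), `failures` (named character
#'   vector of error messages), `files` (written paths) and `status`
#'   (0 = success, 1 = partial failures, 2 = nothing processed).
#' @export
run_batch <- function(config, image_paths) {
  stopifnot(inherits(config, "fq_config"))
  if (length(image_paths) == 0) {
    stop("input error: no images to process")
  }
  missing <- image_paths[!file.exists(image_paths)]
  if (length(missing)) {
    stop("input error: missing image file(s): ",
         paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  selection <- resolve_selection(config$selection)
  groups <- resolve_groups(config$groups, image_paths)
  written <- character(0)
  failures <- character(0)
  glances <- list()
  for (i in seq_along(image_paths)) {
    path <- image_paths[i]
    id <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      stack <- read_rgb_stack(path)
      ch <- split_channels(stack, slice_policy = config$slice_policy,
                           slice = config$slice)
      quantify_image(
        ch[[config$marker_channel]], ch[[config$query_channel]],
        selection = selection, threshold = config$threshold,
        filter = config$filter, include_ids = config$include_ids,
        exclude_ids = config$exclude_ids, image_id = id,
        bg_stat = config$bg_stat,
        threshold_method = config$threshold_method
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      next
    }
    written <- c(written, write_results_csv(res, config$out_dir))
    g <- glance(res)
    g$group <- if (is.null(groups)) NA_character_ else groups[i]
    glances[[id]] <- g
  }
  smry <- dplyr::bind_rows(glances)
  group_stats <- NULL
  fold <- NULL
  if (nrow(smry) > 0) {
    smry <- smry[, c("image", "group", "n_rois", "mean_corrected_mean",
                     "mean_bg")]
    spath <- file.path(config$out_dir, "summary.csv")
    readr::write_csv(smry, spath, na = "")
    written <- c(written, spath)
    if (!is.null(groups) && !anyNA(smry$group)) {
      group_stats <- group_summaries(smry)
      gpath <- file.path(config$out_dir, "groups.csv")
      readr::write_csv(group_stats, gpath)
      if (config$control_group %in% group_stats$group &&
          nrow(group_stats) > 1) {
        fold <- fold_change(smry, control = config$control_group)
        fpath <- file.path(config$out_dir, "fold.csv")
        readr::write_csv(
          dplyr::select(fold, fold = "fold", sd = "sd",
                        n_control = "n_control", n_experimental = "n"),
          fpath)
        written <- c(written, gpath, fpath)
      } else {
        written <- c(written, gpath)
      }
    }
  }
  status <- if (nrow(smry) == 0) 2L else if (length(failures)) 1L else 0L
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    paste0("fluorquant ", as.character(packageVersion("fluorquant")),
           " on R ", getRversion()),
    paste0("images: ", paste(image_paths, collapse = ", ")),
    paste0("config: ", config_json(config)),
    paste0("failures: ",
           if (length(failures))
             paste(names(failures), failures, sep = ": ", collapse = "; ")
           else "none"),
    paste0("status: ", status)
  ), log_path)
  structure(list(summary = smry, group_stats = group_stats, fold = fold,
                 failures = failures, files = written, status = status),
            class = "fq_batch")
}

#' @export
print.fq_batch <- function(x, ...) {
  cat(sprintf("<fq_batch> %d image(s), %d failure(s), status %d\n",
              nrow(x$summary), length(x$failures), x$status))
  invisible(x)
}

config_json <- function(config) {
  x <- unclass(config)
  if (inherits(x$selection, "selection_region")) {
    x$selection <- if (x$selection$type == "whole_image") NULL
    else unname(split(x$selection$vertices,
                      row(x$selection$vertices)))
  }
  if (inherits(x$threshold, "threshold_spec")) {
    x$threshold <- x$threshold[c("min_level", "max_level")]
  }
  x$filter <- unclass(x$filter)
  x$filter$max_area <- if (is.finite(x$filter$max_area))
    x$filter$max_area else "Inf"
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Persist and reload run parameters
#'
#' Mirrors the parameter-persistence behaviour of the original interactive
#' tool: the last-used configuration is kept in a well-known JSON file so a
#' later run without explicit settings starts from it. A corrupt file is
#' reported with a warning and the documented defaults are returned.
#'
#' @param config An [run_config()] object.
#' @param path Config file path (default `.fluorquant-config.json` in the
#'   working directory).
#' @return `persist_params()` returns `path` invisibly; `load_params()`
#'   returns an `fq_config`.
#' @export
persist_params <- function(config, path = ".fluorquant-config.json") {
  stopifnot(inherits(config, "fq_config"))
  writeLines(as.character(config_json(config)), path)
  invisible(path)
}

#' @rdname persist_params
#' @export
load_params <- function(path = ".fluorquant-config.json") {
  if (!file.exists(path)) return(run_config())
  x <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                   simplifyVector = TRUE),
                error = function(e) NULL)
  if (is.null(x) || !is.list(x)) {
    warning("corrupt config file '", path, "'; using defaults")
    return(run_config())
  }
  if (!is.null(x$filter)) {
    if (identical(x$filter$max_area, "Inf")) x$filter$max_area <- Inf
  }
  if (!is.null(x$selection) && is.list(x$selection)) {
    x$selection <- do.call(rbind, lapply(x$selection, as.numeric))
  }
  args <- x[names(x) %in% names(formals(run_config))]
  do.call(run_config, args)
}
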