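# Declarative plot configuration (YAML/JSON): the one-to-one automation
# surface over the library API.

CONFIG_KEYS <- list(
  top = c("seed", "output", "direction", "main", "title", "heatmaps"),
  output = c("path", "format", "width", "height", "dpi"),
  heatmap = c("name", "matrix", "format", "colors", "cluster_rows",
              "cluster_columns", "distance", "linkage", "row_order",
              "column_order", "row_km", "row_km_repeats", "column_km",
              "column_km_repeats", "row_split", "column_split", "row_title",
              "column_title", "show_row_dend", "show_column_dend",
              "show_row_names", "show_column_names", "width", "height",
              "raster", "annotations"),
  colors = c("breaks", "colors", "space", "levels", "na_color"),
  raster = c("strategy", "aggregator", "resize_filter", "trigger"),
  annotation = c("name", "kind", "file", "column", "values", "size")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("plot config: unknown key '%s' in %s (allowed: %s)",
                 extra[1L], where, paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
}

#' Read and validate a plot configuration
#'
#' The configuration declares a heatmap list: per-heatmap matrix source,
#' color specification, clustering/ordering/splitting, annotation blocks,
#' list direction and main heatmap, and the output file. Unknown keys are
#' rejected and every referenced file must exist at parse time.
#'
#' @param path YAML (or JSON) configuration file.
#' @return The validated configuration list (class `plot_config`).
#' @export
read_plot_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' does not exist", path), call. = FALSE)
  cfg <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  check_keys(cfg, CONFIG_KEYS$top, "the top level")
  if (is.null(cfg$heatmaps) || !length(cfg$heatmaps)) {
    stop("plot config: needs at least one entry under `heatmaps`", call. = FALSE)
  }
  if (is.null(cfg$output$path)) {
    stop("plot config: `output.path` is required", call. = FALSE)
  }
  check_keys(cfg$output, CONFIG_KEYS$output, "`output`")
  resolve_file <- function(f, what) {
    p <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(p)) {
      stop(sprintf("plot config: %s file '%s' does not exist", what, f), call. = FALSE)
    }
    p
  }
  for (i in seq_along(cfg$heatmaps)) {
    h <- cfg$heatmaps[[i]]
    check_keys(h, CONFIG_KEYS$heatmap, sprintf("heatmaps[%d]", i))
    if (is.null(h$matrix)) {
      stop(sprintf("plot config: heatmaps[%d] needs a `matrix` file", i), call. = FALSE)
    }
    cfg$heatmaps[[i]]$matrix <- resolve_file(h$matrix, "matrix")
    if (!is.null(h$colors)) check_keys(h$colors, CONFIG_KEYS$colors, "`colors`")
    if (!is.null(h$raster)) check_keys(h$raster, CONFIG_KEYS$raster, "`raster`")
    for (side in names(h$annotations %||% list())) {
      if (!side %in% c("top", "bottom", "left", "right")) {
        stop(sprintf("plot config: unknown annotation side '%s'", side), call. = FALSE)
      }
      for (j in seq_along(h$annotations[[side]])) {
        a <- h$annotations[[side]][[j]]
        check_keys(a, CONFIG_KEYS$annotation, sprintf("annotation %s[%d]", side, j))
        if (!is.null(a$file)) {
          cfg$heatmaps[[i]]$annotations[[side]][[j]]$file <-
            resolve_file(a$file, "annotation")
        }
      }
    }
  }
  structure(cfg, class = c("plot_config", "list"))
}

config_color_mapping <- function(spec, vm) {
  if (is.null(spec)) return(NULL)
  if (!is.null(spec$breaks)) {
    color_mapping(as.numeric(spec$breaks), unlist(spec$colors),
                  space = spec$space %||% "Lab",
                  na_color = spec$na_color %||% DEFAULT_NA_COLOR)
  } else {
    discrete_color_mapping(unlist(spec$colors), levels = unlist(spec$levels),
                           na_color = spec$na_color %||% DEFAULT_NA_COLOR)
  }
}

config_annotation_block <- function(specs, axis, n) {
  if (is.null(specs) || !length(specs)) return(NULL)
  tracks <- list()
  for (a in specs) {
    payload <- if (!is.null(a$values)) {
      unlist(a$values)
    } else {
      tab <- read_annotation_table(a$file)
      col <- a$column %||% names(tab)[1L]
      tab[[col]]
    }
    kind <- a$kind %||% "simple"
    tr <- switch(kind,
      simple = anno_simple(payload),
      points = anno_points(as.numeric(payload)),
      lines = anno_lines(as.numeric(payload)),
      barplot = anno_barplot(as.numeric(payload)),
      percent = anno_percent(as.numeric(payload)),
      text = anno_text(payload),
      stop(sprintf("plot config: annotation kind '%s' is not configurable; use the API",
                   kind), call. = FALSE))
    if (!is.null(a$size)) tr$size <- a$size
    tracks[[a$name %||% kind]] <- tr
  }
  do.call(annotation_block, c(tracks, list(axis = axis)))
}

#' Build and draw a heatmap list from a plot configuration
#'
#' @param config A `plot_config` or a path to one.
#' @return The output file path, invisibly.
#' @export
render_config <- function(config) {
  if (is.character(config)) config <- read_plot_config(config)
  seed <- config$seed %||% 1L
  hms <- lapply(config$heatmaps, function(h) {
    vm <- read_matrix(h$matrix, format = h$format)
    pol <- if (!is.null(h$raster)) {
      raster_policy(strategy = h$raster$strategy %||% "auto",
                    aggregator = h$raster$aggregator %||% "mean",
                    resize_filter = h$raster$resize_filter %||% "nearest",
                    trigger = h$raster$trigger %||% 1e6)
    } else NULL
    heat_map(
      vm, name = h$name %||% basename(h$matrix),
      colors = config_color_mapping(h$colors, vm),
      cluster_rows = h$cluster_rows %||% TRUE,
      cluster_columns = h$cluster_columns %||% TRUE,
      clustering_distance_rows = h$distance %||% "euclidean",
      clustering_distance_columns = h$distance %||% "euclidean",
      clustering_linkage_rows = h$linkage %||% "complete",
      clustering_linkage_columns = h$linkage %||% "complete",
      row_order = h$row_order, column_order = h$column_order,
      row_km = h$row_km, row_km_repeats = h$row_km_repeats %||% 10L,
      column_km = h$column_km, column_km_repeats = h$column_km_repeats %||% 10L,
      row_split = unlist(h$row_split), column_split = unlist(h$column_split),
      row_title = h$row_title, column_title = h$column_title,
      show_row_dend = h$show_row_dend %||% TRUE,
      show_column_dend = h$show_column_dend %||% TRUE,
      show_row_names = h$show_row_names %||% TRUE,
      show_column_names = h$show_column_names %||% TRUE,
      top_annotation = config_annotation_block(h$annotations$top, "column",
                                               ncol(vm$values)),
      bottom_annotation = config_annotation_block(h$annotations$bottom, "column",
                                                  ncol(vm$values)),
      left_annotation = config_annotation_block(h$annotations$left, "row",
                                                nrow(vm$values)),
      right_annotation = config_annotation_block(h$annotations$right, "row",
                                                 nrow(vm$values)),
      raster_policy = pol, width = h$width, height = h$height, seed = seed)
  })
  hl <- hm_list(hms, direction = config$direction %||% "horizontal",
                main = config$main, title = config$title)
  out <- config$output
  draw(hl, file = out$path, format = out$format,
       width = out$width %||% 7, height = out$height %||% 7,
       dpi = out$dpi %||% 100)
  hc_log(sprintf("render_config: wrote '%s' (seed %d)", out$path, seed))
  invisible(out$path)
}
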