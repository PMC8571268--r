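#' Read fibril traces from a file
#'
#' Two text dialects are supported. `"csv"`: header
#' `fibril_id,point_index,x_nm,y_nm,z_nm`; points are grouped by
#' `fibril_id` and sorted by `point_index`, coordinates already in nm.
#' `"point_text"`: whitespace-separated columns
#' `object contour x y z` with coordinates in pixels (the common
#' tomogram-model point-export layout); the fibril id becomes
#' `object.contour` and coordinates are multiplied by `pixel_size_nm`.
#' Consecutive duplicate points are merged with a warning; contours with
#' fewer than two distinct points are dropped with a warning.
#'
#' @param path File to read.
#' @param format `"csv"` or `"point_text"`.
#' @param pixel_size_nm Positive scale in nm/pixel; required for
#'   `"point_text"`.
#' @return List of [fibril_trace()] objects.
#' @export
read_traces <- function(path, format = c("csv", "point_text"),
                        pixel_size_nm = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("fibril_id", "point_index", "x_nm", "y_nm", "z_nm")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("trace CSV is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (col in c("point_index", "x_nm", "y_nm", "z_nm")) {
      if (!is.numeric(df[[col]])) {
        stop("non-numeric values in column '", col, "'", call. = FALSE)
      }
    }
    ids <- unique(df$fibril_id)
    scale <- 1
  } else {
    if (is.null(pixel_size_nm) || pixel_size_nm <= 0) {
      stop("`pixel_size_nm` (> 0) is required for point_text files",
           call. = FALSE)
    }
    raw <- utils::read.table(path, header = FALSE,
                             col.names = c("object", "contour",
                                           "x_nm", "y_nm", "z_nm"))
    df <- data.frame(fibril_id = paste(raw$object, raw$contour, sep = "."),
                     point_index = stats::ave(raw$object, raw$object,
                                              raw$contour,
                                              FUN = seq_along),
                     x_nm = raw$x_nm, y_nm = raw$y_nm, z_nm = raw$z_nm)
    ids <- unique(df$fibril_id)
    scale <- pixel_size_nm
  }
  traces <- list()
  for (id in ids) {
    sub <- df[df$fibril_id == id, ]
    if (is.unsorted(sub$point_index, strictly = TRUE)) {
      sub <- sub[order(sub$point_index), ]
    }
    pts <- as.matrix(sub[, c("x_nm", "y_nm", "z_nm")]) * scale
    tr <- tryCatch(
      fibril_trace(as.character(id), pts, provenance = "imported",
                   pixel_size_nm = if (format == "point_text")
                     pixel_size_nm else NULL),
      error = function(e) {
        warning("dropped trace '", id, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(tr)) traces[[length(traces) + 1L]] <- tr
  }
  traces
}

#' Write fibril traces to the canonical trace CSV
#'
#' @param traces List of [fibril_trace()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  rows <- lapply(traces, function(tr) {
    stopifnot(is_fibril_trace(tr))
    data.frame(fibril_id = tr$fibril_id,
               point_index = seq_len(nrow(tr$points)),
               x_nm = tr$points[, 1], y_nm = tr$points[, 2],
               z_nm = tr$points[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a per-fibril geometry table as TSV
#'
#' @param geometry Output of [measure_all()].
#' @param path Output file (tab-separated, UTF-8, Unix newlines).
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(is.data.frame(geometry))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(as.data.frame(geometry), con, sep = "\t",
                     row.names = FALSE, quote = FALSE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-fibril geometry TSV
#'
#' @param path File with columns `fibril_id`, `contour_length_um`,
#'   `end_to_end_um` and/or `r2_um2` (the squared column is recomputed if
#'   absent).
#' @return A data frame usable by [fit_persistence_length()].
#' @export
read_geometry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"r2_um2" %in% names(df)) {
    if (!"end_to_end_um" %in% names(df)) {
      stop("geometry table needs `r2_um2` or `end_to_end_um`",
           call. = FALSE)
    }
    df$r2_um2 <- df$end_to_end_um^2
  }
  if (!"contour_length_um" %in% names(df)) {
    stop("geometry table needs `contour_length_um`", call. = FALSE)
  }
  df
}

#' Read a normalized per-residue prediction TSV
#'
#' Expected columns: `protein_id`, `predictor`, `residue_index`, `value`
#' (tab-separated, header required).
#'
#' @param path File to read.
#' @return Data frame for [consensus_score()].
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "predictor", "residue_index", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("prediction TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read core annotations from YAML or JSON
#'
#' The file holds one annotation or a list of annotations, each with
#' fields `protein_id`, `seq_length`, `ordered_ranges` (list of
#' `[start, end]` pairs), `mutation_positions`, optional `sequence`.
#' Format is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path File to read.
#' @return List of [core_annotation()] objects.
#' @export
read_annotations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = FALSE)
         else stop("unsupported annotation format: .", ext, call. = FALSE)
  if (!is.null(raw$protein_id)) raw <- list(raw)
  lapply(raw, function(a) {
    core_annotation(a$protein_id, a$seq_length,
                    ordered_ranges = lapply(a$ordered_ranges, unlist),
                    mutation_positions = unlist(a$mutation_positions),
                    sequence = a$sequence)
  })
}

#' Write a reproducible JSON report
#'
#' Serializes a result list to JSON together with provenance fields: the
#' package version, the seed in use, and a hash of the configuration so a
#' changed configuration is detectable from the report alone.
#'
#' @param results Named list of results (numbers, vectors, nested lists).
#' @param path Output file.
#' @param seed The seed the computation used.
#' @param config Optional configuration list to hash and embed.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NA_integer_,
                         config = NULL) {
  payload <- list(
    tool = "alfibril",
    version = as.character(utils::packageVersion("alfibril")),
    seed = seed,
    config = config,
    config_hash = config_hash(config),
    results = results
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# stable short hash of a configuration list (polynomial checksum over the
# canonical JSON serialization; no extra dependencies)
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  txt <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
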