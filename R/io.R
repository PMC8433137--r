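#' Landmark file I/O
#'
#' Landmarks are exchanged as CSV with header `label,x,y,z,frame` (UTF-8,
#' comma separator, '.' decimal, mm) or an equivalent JSON document.
#' `write` followed by `read` reproduces labels exactly and coordinates to
#' full double precision.
#'
#' @param pts A [landmark_set].
#' @param path File path (`.csv` or `.json`; format chosen by extension).
#' @return `read_landmarks()` returns a [landmark_set];
#'   `write_landmarks()` returns `path` invisibly.
#' @export
write_landmarks <- function(pts, path) {
  stopifnot(inherits(pts, "landmark_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(frame = pts$frame, labels = pts$labels,
           coordinates = unname(pts$coords)),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- as.data.frame(pts)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(landmark_set(j$labels, rbind(j$coordinates), j$frame))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || tolower(gsub("\\s", "", lines[1])) != "label,x,y,z,frame") {
    nav_abort(sprintf("%s: line 1: expected header 'label,x,y,z,frame'", path),
              "parse_error")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 5L || anyNA(suppressWarnings(as.numeric(p[2:4])))) {
      nav_abort(sprintf("%s: line %d: malformed landmark row '%s'",
                        path, i + 1L, body[i]), "parse_error")
    }
  }
  labels <- vapply(parts, `[`, "", 1L)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  frames <- unique(vapply(parts, `[`, "", 5L))
  if (length(frames) != 1L) {
    nav_abort(sprintf("%s: all rows must share one frame (found: %s)",
                      path, paste(frames, collapse = ", ")), "parse_error")
  }
  landmark_set(labels, coords, frames)
}

#' Transform file I/O
#'
#' Transforms are stored as JSON objects with keys `matrix` (16 numbers,
#' row-major), `from_frame`, `to_frame` and `rigid`.
#'
#' @param t A `nav_transform`.
#' @param path File path.
#' @return `read_transform()` returns a `nav_transform`;
#'   `write_transform()` returns `path` invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "nav_transform"))
  jsonlite::write_json(
    list(matrix = as.numeric(t(t$matrix)), from_frame = t$from,
         to_frame = t$to, rigid = t$rigid),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("matrix", "from_frame", "to_frame", "rigid")) {
    if (is.null(j[[k]])) {
      nav_abort(sprintf("%s: transform JSON lacks key '%s'", path, k),
                "parse_error")
    }
  }
  if (length(j$matrix) != 16L) {
    nav_abort(sprintf("%s: transform matrix must hold 16 numbers", path),
              "parse_error")
  }
  new_transform(matrix(as.numeric(j$matrix), 4L, 4L, byrow = TRUE),
                j$from_frame, j$to_frame, rigid = isTRUE(j$rigid))
}

#' Acquisition-record CSV I/O
#'
#' Study records (one pointer acquisition per row, with full design
#' metadata) as CSV with columns `cadaver`, `technique`, `method`,
#' `observer`, `repetition`, `target`, `x`, `y`, `z`, `frame` and any extra
#' numeric columns present (e.g. `tre_mm`). A row with a missing or
#' non-numeric coordinate cell is rejected with its line number.
#'
#' @param records data.frame of acquisition records.
#' @param path File path.
#' @return `read_records()` returns a data.frame; `write_records()` returns
#'   `path` invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  need <- c("cadaver", "technique", "method", "observer", "repetition",
            "target", "x", "y", "z", "frame")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    nav_abort(sprintf("records lack required columns: %s",
                      paste(miss, collapse = ", ")), "input_error")
  }
  num <- vapply(records, is.numeric, TRUE)
  out <- records
  out[num] <- lapply(records[num], function(v)
    format(v, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cadaver", "technique", "method", "observer", "repetition",
            "target", "x", "y", "z", "frame")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    nav_abort(sprintf("%s: records CSV lacks column(s): %s", path,
                      paste(miss, collapse = ", ")), "parse_error")
  }
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      nav_abort(sprintf("%s: line %d: missing or non-numeric '%s' value",
                        path, bad[1] + 1L, col), "parse_error")
    }
    df[[col]] <- v
  }
  df
}

#' Study configuration files
#'
#' Reads a YAML (or JSON) study configuration holding the factorial design,
#' the noise model and the phantom seed, validating the schema before any
#' simulation runs; unknown keys are rejected so typos cannot silently fall
#' back to defaults.
#'
#' Recognized top-level keys: `seed`, `design` (fields of [study_design()]),
#' `noise` (fields of [noise_model()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `seed`, `design` (a `study_design`) and
#'   `noise` (a `noise_model`).
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), c("seed", "design", "noise"))
  if (length(unknown)) {
    nav_abort(sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")), "config_error")
  }
  d_args <- cfg$design %||% list()
  n_args <- cfg$noise %||% list()
  bad_d <- setdiff(names(d_args), names(formals(study_design)))
  bad_n <- setdiff(names(n_args), names(formals(noise_model)))
  if (length(bad_d) || length(bad_n)) {
    nav_abort(sprintf("unknown config key(s): %s",
                      paste(c(bad_d, bad_n), collapse = ", ")),
              "config_error")
  }
  if (!is.null(n_args$fle_sigma_mm)) {
    n_args$fle_sigma_mm <- unlist(n_args$fle_sigma_mm)
  }
  list(seed = cfg$seed %||% 1L,
       design = do.call(study_design, d_args),
       noise = do.call(noise_model, n_args))
}
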