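# File formats: PLUMED-dialect HILLS and COLVAR files, training-set and
# free energy tables, Grossfield-style WHAM metadata, and key = value
# configuration files. All numeric round-trips are lossless at %.9f.

.num_fmt <- "%.9f"

.write_fields_file <- function(path, fields, mat, comments = NULL) {
  con <- file(path, open = "wb") # binary mode: "\n" endings on every platform
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con, sep = "\n")
  if (!is.null(comments))
    writeLines(paste("#", comments), con, sep = "\n")
  if (nrow(mat) > 0) {
    rows <- do.call(paste, c(lapply(seq_len(ncol(mat)),
                                    function(j) sprintf(.num_fmt, mat[, j])),
                             list(sep = " ")))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

.read_fields_file <- function(path, expected_fields) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("malformed header in ", path, ": first line must be '#! FIELDS ...' (got: ",
         if (length(lines)) lines[1] else "<empty file>", ")")
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1])), "\\s+")[[1]]
  if (!identical(fields, expected_fields))
    stop("unexpected fields in ", path, ": got '", paste(fields, collapse = " "),
         "', expected '", paste(expected_fields, collapse = " "), "'")
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  body_idx <- body_idx[body_idx > 1L]
  mat <- matrix(numeric(0), 0, length(fields), dimnames = list(NULL, fields))
  if (length(body_idx) > 0) {
    parts <- strsplit(trimws(lines[body_idx]), "\\s+")
    nf <- lengths(parts)
    if (any(nf != length(fields)))
      stop("wrong column count in ", path, " at line ", body_idx[which(nf != length(fields))[1]])
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    bad <- !is.finite(vals)
    if (any(bad)) {
      row <- ceiling(which(bad)[1] / length(fields))
      stop("non-finite or non-numeric value in ", path, " at line ", body_idx[row])
    }
    mat <- matrix(vals, ncol = length(fields), byrow = TRUE,
                  dimnames = list(NULL, fields))
  }
  mat
}

#' Write / read a metadynamics HILLS file
#'
#' PLUMED v2 dialect: header `#! FIELDS time d1 sigma_d1 height biasf`, one
#' hill per row at `%.9f`. The reader tolerates comment lines and trailing
#' whitespace, and validates strictly increasing deposition times.
#'
#' @param log A [hills_log()].
#' @param path File path.
#' @param comments Optional character vector of comment lines written after
#'   the header.
#' @return `write_hills` returns the path; `read_hills` a [hills_log()].
#' @export
write_hills <- function(log, path, comments = NULL) {
  stopifnot(inherits(log, "hills_log"))
  h <- log$hills
  mat <- cbind(h$time, h$center, rep(log$width, nrow(h)), h$height,
               rep(log$bias_factor, nrow(h)))
  .write_fields_file(path, c("time", "d1", "sigma_d1", "height", "biasf"), mat,
                     comments)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  mat <- .read_fields_file(path, c("time", "d1", "sigma_d1", "height", "biasf"))
  if (nrow(mat) == 0)
    return(hills_log())
  if (any(diff(mat[, "time"]) <= 0))
    stop("non-monotone hill times in ", path, " at row ",
         which(diff(mat[, "time"]) <= 0)[1] + 1L)
  if (length(unique(mat[, "sigma_d1"])) != 1L || length(unique(mat[, "biasf"])) != 1L)
    stop("mixed hill widths or bias factors in ", path,
         ": this dialect assumes shared sigma_d1 and biasf")
  hills_log(mat[, "time"], mat[, "d1"], mat[, "height"],
            width = unname(mat[1, "sigma_d1"]),
            bias_factor = unname(mat[1, "biasf"]),
            omega0 = max(mat[, "height"]))
}

#' Write / read a COLVAR trajectory file
#'
#' Dialect: `#! FIELDS time d1 force bias`, one recorded frame per row.
#'
#' @param traj A `colvar_traj` data frame.
#' @param path File path.
#' @param comments Optional comment lines.
#' @return `write_colvar` returns the path; `read_colvar` a `colvar_traj`.
#' @export
write_colvar <- function(traj, path, comments = NULL) {
  mat <- cbind(traj$time, traj$s, traj$gen_force, traj$bias)
  .write_fields_file(path, c("time", "d1", "force", "bias"), mat, comments)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  mat <- .read_fields_file(path, c("time", "d1", "force", "bias"))
  out <- data.frame(time = mat[, "time"], s = mat[, "d1"],
                    gen_force = mat[, "force"], bias = mat[, "bias"])
  class(out) <- c("colvar_traj", "data.frame")
  out
}

#' Write / read a gradient training-set file
#'
#' Dialect: `#! FIELDS s dF_ds frame time`.
#'
#' @param train A [training_set()].
#' @param path File path.
#' @param comments Optional comment lines.
#' @return `write_training` returns the path; `read_training` a
#'   [training_set()].
#' @export
write_training <- function(train, path, comments = NULL) {
  stopifnot(inherits(train, "training_set"))
  mat <- cbind(train$s, train$y, train$frame, train$time)
  .write_fields_file(path, c("s", "dF_ds", "frame", "time"), mat, comments)
}

#' @rdname write_training
#' @export
read_training <- function(path) {
  mat <- .read_fields_file(path, c("s", "dF_ds", "frame", "time"))
  if (nrow(mat) == 0) stop("empty training set in ", path)
  training_set(mat[, "s"], mat[, "dF_ds"], frame_index = as.integer(mat[, "frame"]),
               time = mat[, "time"], source = list(file = path))
}

#' Write / read a tabulated free energy curve
#'
#' Two-column whitespace text with header `# s_nm F_kJ_mol`.
#'
#' @param fes A [fes_curve()].
#' @param path File path.
#' @param comments Optional comment lines.
#' @return `write_fes` returns the path; `read_fes` a [fes_curve()].
#' @export
write_fes <- function(fes, path, comments = NULL) {
  stopifnot(inherits(fes, "fes_curve"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# s_nm F_kJ_mol", con, sep = "\n")
  if (!is.null(comments)) writeLines(paste("#", comments), con, sep = "\n")
  writeLines(sprintf(paste(.num_fmt, .num_fmt), fes$s, fes$F), con, sep = "\n")
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "# s_nm F_kJ_mol"))
    stop("malformed header in ", path)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  parts <- strsplit(trimws(lines[body_idx]), "\\s+")
  if (any(lengths(parts) != 2L))
    stop("wrong column count in ", path, " at line ", body_idx[which(lengths(parts) != 2L)[1]])
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (any(!is.finite(vals)))
    stop("non-finite value in ", path, " at line ",
         body_idx[ceiling(which(!is.finite(vals))[1] / 2)])
  m <- matrix(vals, ncol = 2L, byrow = TRUE)
  fes_curve(m[, 1], m[, 2])
}

#' Write / read umbrella-window time series and WHAM metadata
#'
#' Per-window series files hold `time s` rows (comment header `# time s`);
#' the metadata file lists `path center spring_k` per line -- the layout
#' expected by Grossfield's WHAM implementation, so the same files can be
#' fed to that tool for cross-checking.
#'
#' @param window An [umbrella_window()].
#' @param path File path.
#' @return Writers return the path; `read_window_series` returns a
#'   two-column matrix, `read_wham_meta` a data frame with columns `path`,
#'   `center`, `spring_k`.
#' @export
write_window_series <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  tm <- window$time %||% seq_along(window$samples)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# time s", con, sep = "\n")
  writeLines(sprintf(paste(.num_fmt, .num_fmt), tm, window$samples), con, sep = "\n")
  invisible(path)
}

#' @rdname write_window_series
#' @export
read_window_series <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  parts <- strsplit(trimws(lines[body_idx]), "\\s+")
  if (any(lengths(parts) != 2L))
    stop("wrong column count in ", path, " at line ", body_idx[which(lengths(parts) != 2L)[1]])
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (any(!is.finite(vals)))
    stop("non-finite value in ", path, " at line ",
         body_idx[ceiling(which(!is.finite(vals))[1] / 2)])
  matrix(vals, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("time", "s")))
}

#' @rdname write_window_series
#' @param series_paths Character vector of per-window series file paths.
#' @param windows An [make_windows()] table matching `series_paths`.
#' @export
write_wham_meta <- function(series_paths, windows, path) {
  stopifnot(length(series_paths) == nrow(windows))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf(paste("%s", .num_fmt, .num_fmt),
                     series_paths, windows$center, windows$spring_k),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_window_series
#' @export
read_wham_meta <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  parts <- strsplit(trimws(lines[body_idx]), "\\s+")
  if (any(lengths(parts) != 3L))
    stop("wrong column count in ", path, " at line ", body_idx[which(lengths(parts) != 3L)[1]])
  out <- data.frame(path = vapply(parts, `[`, "", 1L),
                    center = as.numeric(vapply(parts, `[`, "", 2L)),
                    spring_k = as.numeric(vapply(parts, `[`, "", 3L)))
  if (any(!is.finite(out$center)) || any(!is.finite(out$spring_k)))
    stop("non-finite value in ", path)
  out
}

# --- configuration files: flat "key = value" text -------------------------

.flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]])) out <- c(out, .flatten_config(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

#' Write / read a pipeline configuration file
#'
#' Nested configuration lists are flattened to dotted keys and stored as
#' `key = value` lines (vectors comma-separated); reading rebuilds the
#' nested list. Numeric values round-trip exactly.
#'
#' @param config Nested named list of numeric/character/logical scalars or
#'   vectors.
#' @param path File path.
#' @return `write_config` returns the path; `read_config` the nested list.
#' @export
write_config <- function(config, path) {
  flat <- .flatten_config(config)
  fmt1 <- function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) ifelse(v, "TRUE", "FALSE")
    else sprintf("%.17g", v)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(flat), "=",
                   vapply(flat, function(v) paste(fmt1(v), collapse = ", "), "")),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    valstr <- trimws(paste(kv[-1], collapse = "="))
    items <- trimws(strsplit(valstr, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(items))
    val <- if (!any(is.na(num))) num
           else if (all(items %in% c("TRUE", "FALSE"))) items == "TRUE"
           else items
    keys <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- .assign_nested(out, keys, val)
  }
  out
}

.assign_nested <- function(lst, keys, val) {
  if (length(keys) == 1L) { lst[[keys]] <- val; return(lst) }
  head_key <- keys[1]
  if (is.null(lst[[head_key]])) lst[[head_key]] <- list()
  lst[[head_key]] <- .assign_nested(lst[[head_key]], keys[-1], val)
  lst
}

# Small deterministic content hash (FNV-1a, 32-bit) for provenance comments.
# Arithmetic is done in split 16-bit halves so every intermediate stays
# exactly representable in doubles.
.config_hash <- function(config) {
  txt <- paste(deparse(.flatten_config(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
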