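# Coordinate, trajectory, bias-log and configuration I/O.

#' Write a system in GRO format
#'
#' Fixed-width GRO (nm, 3 decimal places). Bead names are the type names;
#' each bead is its own residue.
#'
#' @param system a `cg_system`.
#' @param path output file.
#' @param title header line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(system, path, title = "cgnp system") {
  n <- n_beads(system)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%s t=%.3f", title, system$time), sprintf("%5d", n)), con)
  if (n > 0) {
    nm <- system$types$name[system$type]
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     (seq_len(n) - 1L) %% 100000L + 1L, nm, nm,
                     (seq_len(n) - 1L) %% 100000L + 1L,
                     system$pos[, 1], system$pos[, 2], system$pos[, 3])
    writeLines(lines, con)
  }
  writeLines(sprintf("%10.5f%10.5f%10.5f", system$box[1], system$box[2],
                     system$box[3]), con)
  invisible(path)
}

#' Read a GRO file
#'
#' @param path GRO file (nm coordinates).
#' @param types bead type table used to resolve bead names (default
#'   [default_bead_types()]).
#' @return a `cg_system` (positions, names, box; no topology).
#' @export
read_gro <- function(path, types = default_bead_types()) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0) stop("malformed GRO: bad atom count on line 2")
  if (length(lines) < 3 + n) stop("malformed GRO: truncated atom block")
  box_line <- lines[3 + n]
  box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3])) {
    stop("malformed GRO: bad box on line ", 3 + n)
  }
  if (n == 0) {
    return(cg_system(matrix(numeric(0), 0, 3), integer(0), types = types,
                     box = box[1:3]))
  }
  at <- lines[seq.int(3, 2 + n)]
  name <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stop("malformed GRO: bad coordinates on line ", 2 + bad[1])
  cg_system(cbind(x, y, z), name, types = types, box = box[1:3])
}

#' Write coordinates or a trajectory in XYZ format
#'
#' @param x a `cg_system` or `cg_trajectory`.
#' @param path output file (multi-frame for trajectories).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(pos, nm, t) {
    writeLines(c(sprintf("%d", nrow(pos)), sprintf("t= %.4f ps", t)), con)
    if (nrow(pos)) {
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", nm,
                         pos[, 1], pos[, 2], pos[, 3]), con)
    }
  }
  if (inherits(x, "cg_trajectory")) {
    nm <- x$final_system$types$name[x$final_system$type]
    for (f in seq_along(x$frames)) emit(x$frames[[f]], nm, x$times[f])
  } else {
    emit(x$pos, x$types$name[x$type], x$time)
  }
  invisible(path)
}

#' Read an XYZ file (single or multi-frame)
#'
#' @param path XYZ file.
#' @return list of `list(names, pos, comment)` frames.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: bad count on line ", i)
    at <- lines[seq.int(i + 2, i + 1 + n)]
    parts <- strsplit(trimws(at), "\\s+")
    nm <- vapply(parts, `[`, character(1), 1)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- list(names = nm, pos = pos,
                                         comment = lines[i + 1])
    i <- i + 2 + n
  }
  frames
}

#' Write a COLVAR-like bias log
#'
#' Whitespace table (full precision) with a `#! FIELDS` comment header
#' naming the columns, round-trippable with [read_bias_log()].
#'
#' @param cv_log data.frame (time, CV components, V).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bias_log <- function(cv_log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(cv_log), collapse = " ")), con)
  utils::write.table(format(cv_log, digits = 17, trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a COLVAR-like bias log
#'
#' @param path file written by [write_bias_log()] (or any whitespace table
#'   with a `#! FIELDS` header).
#' @param expect_fields optional character vector; a header mismatch is a
#'   schema error.
#' @return data.frame with the header's column names.
#' @export
read_bias_log <- function(path, expect_fields = NULL) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#! FIELDS")) stop("schema error: missing FIELDS header")
  fields <- strsplit(sub("^#! FIELDS\\s+", "", hdr), "\\s+")[[1]]
  if (!is.null(expect_fields) && !identical(fields, expect_fields)) {
    stop("schema error: header fields (", paste(fields, collapse = ", "),
         ") do not match expected (", paste(expect_fields, collapse = ", "), ")")
  }
  df <- utils::read.table(path, comment.char = "#", col.names = fields,
                          colClasses = "numeric")
  if (ncol(df) != length(fields)) stop("schema error: column count mismatch")
  df
}

#' Write a HILLS-like kernel table
#'
#' @param bias a `cg_bias`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hills <- function(bias, path) {
  k <- as.data.frame(bias$kernels)
  ndim <- length(bias$width)
  for (d in seq_len(ndim)) k[[paste0("sigma", d)]] <- bias$width[d]
  k <- k[, c("time", paste0("center", seq_len(ndim)),
             paste0("sigma", seq_len(ndim)), "height")]
  write_bias_log(k, path)
}

#' Read a HILLS-like kernel table
#'
#' @param path file written by [write_hills()].
#' @param cv_kind CV kind recorded in the returned bias.
#' @param bias_factor,temperature metadata for the returned bias.
#' @return a `cg_bias` (kernel list; no grid).
#' @export
read_hills <- function(path, cv_kind = "com_x", bias_factor = NULL,
                       temperature = 300) {
  df <- read_bias_log(path)
  centers <- grep("^center", names(df), value = TRUE)
  sigmas <- grep("^sigma", names(df), value = TRUE)
  ndim <- length(centers)
  k <- as.matrix(cbind(df[centers], height = df$height, time = df$time))
  colnames(k) <- c(centers, "height", "time")
  structure(list(cv_kind = cv_kind, kernels = k,
                 width = as.numeric(df[1, sigmas]),
                 bias_factor = bias_factor, temperature = temperature),
            class = "cg_bias")
}

# --- configuration -----------------------------------------------------------

.config_keys <- c("bead_types", "pair_table", "surface", "builder",
                  "integrator", "external_force", "restraint", "wall",
                  "metad", "observables", "seed", "output")

#' Load a run configuration
#'
#' YAML configuration with sections for bead types, pair parameters,
#' surface layout, builder settings, integrator, external force,
#' restraint, wall, metadynamics and observables. Unknown top-level keys
#' are rejected; a content hash is attached for provenance (every output
#' artifact can embed it).
#'
#' @param path YAML file.
#' @return a `run_config` list with attribute `hash`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config", hash = config_hash(cfg))
}

#' Write a run configuration
#'
#' @param cfg a `run_config` (or plain list with valid keys).
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Content hash of a configuration
#'
#' FNV-1a hash of the canonical JSON serialization; stable across
#' load/dump round trips.
#'
#' @param cfg list.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), arithmetic stays in doubles
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
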