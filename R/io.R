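# File formats: tab-delimited marker trajectories, a binary baseband signal
# container, YAML motion specifications and text serialization of training
# databases and PCA models. Numeric round-trips are exact: floats are written
# with 17 significant digits ("%.17g"), which reproduces IEEE doubles bit for
# bit on read.

.fmt <- function(x) sprintf("%.17g", x)

#' Write a marker trajectory as tab-delimited text
#'
#' Header lines `# rate_hz=<float>` and `# markers=<int>`, then one row per
#' frame with columns `x1 y1 z1 x2 y2 z2 ...`.
#'
#' @param traj A `marker_trajectory`.
#' @param file Output path.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "marker_trajectory"))
  d <- dim(traj$positions)
  wide <- matrix(0, d[2], 3L * d[1])
  for (k in seq_len(d[1])) {
    wide[, 3 * k - 2] <- traj$positions[k, , 1]
    wide[, 3 * k - 1] <- traj$positions[k, , 2]
    wide[, 3 * k] <- traj$positions[k, , 3]
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz=%s", .fmt(traj$rate)),
               sprintf("# markers=%d", d[1])), con)
  write.table(matrix(.fmt(wide), nrow(wide), ncol(wide)), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a tab-delimited marker trajectory
#'
#' @param file Path written by [write_trajectory()] (or matching its layout).
#' @param class_label Optional label to attach.
#' @return A `marker_trajectory`.
#' @export
read_trajectory <- function(file, class_label = NA_integer_) {
  hdr <- readLines(file, n = 2L)
  rate <- as.numeric(sub("^# rate_hz=", "", hdr[1]))
  n <- as.integer(sub("^# markers=", "", hdr[2]))
  wide <- as.matrix(read.table(file, sep = "\t", skip = 2L,
                               colClasses = "numeric"))
  stopifnot(ncol(wide) == 3L * n)
  pos <- array(0, c(n, nrow(wide), 3L))
  for (k in seq_len(n)) {
    pos[k, , 1] <- wide[, 3 * k - 2]
    pos[k, , 2] <- wide[, 3 * k - 1]
    pos[k, , 3] <- wide[, 3 * k]
  }
  marker_trajectory(pos, rate, class_label = class_label)
}

#' Write a complex baseband signal container
#'
#' A one-line text header (f0, rate, label and free metadata) followed by the
#' raw interleaved re/im doubles; round-trips are bit-exact.
#'
#' @param signal A `radar_signal`.
#' @param file Output path.
#' @param meta Optional named list of additional scalar metadata (e.g. seed,
#'   snr_db), stored in the header.
#' @export
write_radar_signal <- function(signal, file, meta = list()) {
  stopifnot(inherits(signal, "radar_signal"))
  hdr <- c(list(format = "radmotion-sig-1", n = length(signal$samples),
                f0 = .fmt(signal$config$f0), rate = .fmt(signal$rate),
                c0 = .fmt(signal$config$c0), label = signal$label),
           lapply(meta, as.character))
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(paste(names(hdr), unlist(hdr), sep = "=", collapse = "\t"), con)
  writeBin(as.numeric(rbind(Re(signal$samples), Im(signal$samples))), con,
           size = 8L, endian = "little")
  invisible(file)
}

#' Read a complex baseband signal container
#'
#' @param file Path written by [write_radar_signal()].
#' @return A `radar_signal`; extra header metadata is kept in
#'   `attr(, "meta")`.
#' @export
read_radar_signal <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr_line <- readLines(con, n = 1L)
  kv <- strsplit(strsplit(hdr_line, "\t")[[1]], "=", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  if (!identical(meta$format, "radmotion-sig-1"))
    stop("not a radmotion signal container", call. = FALSE)
  n <- as.integer(meta$n)
  raw <- readBin(con, "numeric", n = 2L * n, size = 8L, endian = "little")
  samples <- complex(real = raw[seq(1, 2 * n, 2)],
                     imaginary = raw[seq(2, 2 * n, 2)])
  cfg <- radar_config(f0 = as.numeric(meta$f0), rate = as.numeric(meta$rate),
                      c0 = as.numeric(meta$c0))
  out <- radar_signal(samples, cfg$rate, cfg,
                      label = suppressWarnings(as.integer(meta$label)))
  attr(out, "meta") <- meta[setdiff(names(meta),
                                    c("format", "n", "f0", "rate", "c0",
                                      "label"))]
  out
}

# numbers <-> strings for exact YAML round-trips
.num_to_chr <- function(x) {
  if (is.numeric(x)) .fmt(x)
  else if (is.list(x)) lapply(x, .num_to_chr)
  else x
}

#' Write a motion specification to a YAML file
#'
#' Numeric values are stored as full-precision strings so the round-trip via
#' [read_motion_spec()] is exact.
#'
#' @param spec A `motion_spec`.
#' @param file Output path.
#' @export
write_motion_spec <- function(spec, file) {
  stopifnot(inherits(spec, "motion_spec"))
  obj <- list(class_label = spec$class_label, class_name = spec$class_name,
              markers = lapply(spec$markers, function(mk) {
                list(static_position = .fmt(mk$static_position),
                     motion_axis = .fmt(mk$motion_axis),
                     components = lapply(mk$components, function(cp) {
                       list(kind = cp$kind, amplitude = .fmt(cp$amplitude),
                            angular_rate = .fmt(cp$angular_rate),
                            phase = .fmt(cp$phase))
                     }))
              }))
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' Read a motion specification from YAML
#'
#' @param file Path written by [write_motion_spec()].
#' @return A `motion_spec`.
#' @export
read_motion_spec <- function(file) {
  obj <- yaml::read_yaml(file)
  markers <- lapply(obj$markers, function(mk) {
    list(static_position = as.numeric(mk$static_position),
         motion_axis = as.numeric(mk$motion_axis),
         components = lapply(mk$components, function(cp) {
           motion_component(cp$kind, as.numeric(cp$amplitude),
                            as.numeric(cp$angular_rate), as.numeric(cp$phase))
         }))
  })
  motion_spec(markers, class_label = obj$class_label,
              class_name = obj$class_name %||% NA_character_)
}

.write_num_block <- function(con, name, x) {
  if (is.matrix(x)) {
    writeLines(sprintf(">%s matrix %d %d", name, nrow(x), ncol(x)), con)
    write.table(matrix(.fmt(x), nrow(x), ncol(x)), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(sprintf(">%s vector %d", name, length(x)), con)
    writeLines(paste(.fmt(x), collapse = "\t"), con)
  }
}

.read_blocks <- function(lines) {
  heads <- grep("^>", lines)
  blocks <- list()
  for (h in seq_along(heads)) {
    parts <- strsplit(sub("^>", "", lines[heads[h]]), " ")[[1]]
    name <- parts[1]
    end <- if (h < length(heads)) heads[h + 1] - 1L else length(lines)
    body <- lines[(heads[h] + 1L):end]
    vals <- lapply(strsplit(body, "\t"), as.numeric)
    if (parts[2] == "matrix") {
      blocks[[name]] <- do.call(rbind, vals)
    } else {
      blocks[[name]] <- vals[[1]]
    }
  }
  blocks
}

#' Serialize a training database to a single text archive
#'
#' Feature matrix, labels, extrema, per-class range matrices, segmentation
#' parameters, radar configuration and (if present) the PCA model are written
#' as labeled full-precision text blocks; [read_training_db()] reproduces
#' classification decisions exactly.
#'
#' @param db A `training_db`.
#' @param file Output path.
#' @export
write_training_db <- function(db, file) {
  stopifnot(inherits(db, "training_db"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("#radmotion-db-1", con)
  .write_num_block(con, "F", db$F)
  .write_num_block(con, "labels", as.numeric(db$labels))
  .write_num_block(con, "fmin", db$fmin)
  .write_num_block(con, "fmax", db$fmax)
  .write_num_block(con, "segmentation",
                   c(db$segmentation$T_end %||% NA_real_,
                     db$segmentation$T_samp, db$segmentation$dt_tr,
                     db$segmentation$seg_len))
  .write_num_block(con, "config", c(db$config$f0, db$config$rate,
                                    db$config$c0, db$config$radar_position))
  for (key in names(db$ranges)) {
    .write_num_block(con, paste0("ranges_", key), db$ranges[[key]])
    .write_num_block(con, paste0("offsets_", key),
                     as.numeric(db$offsets[[key]]))
  }
  if (!is.null(db$pca)) {
    .write_num_block(con, "pca_mean", db$pca$mean)
    .write_num_block(con, "pca_eigvecs", db$pca$eigvecs)
    .write_num_block(con, "pca_eigvals_all", db$pca$eigvals_all)
    .write_num_block(con, "pca_meta",
                     c(db$pca$d, as.numeric(db$pca$center)))
  }
  invisible(file)
}

#' Read a training database text archive
#'
#' @param file Path written by [write_training_db()].
#' @return A `training_db`.
#' @export
read_training_db <- function(file) {
  lines <- readLines(file)
  if (!identical(lines[1], "#radmotion-db-1"))
    stop("not a radmotion training-db archive", call. = FALSE)
  b <- .read_blocks(lines[-1])
  seg <- b$segmentation
  cfgv <- b$config
  config <- radar_config(f0 = cfgv[1], rate = cfgv[2], c0 = cfgv[3],
                         radar_position = cfgv[4:6])
  labels <- as.integer(b$labels)
  classes <- sort(unique(labels))
  keys <- as.character(classes)
  ranges <- lapply(keys, function(k) b[[paste0("ranges_", k)]])
  names(ranges) <- keys
  offsets <- lapply(keys, function(k) as.integer(b[[paste0("offsets_", k)]]))
  names(offsets) <- keys
  Ls <- as.integer(seg[4])
  banks0 <- lapply(keys, function(k) {
    basis_bank(ranges[[k]][, 1:Ls, drop = FALSE], config$lambda, config$rate,
               class_label = as.integer(k), t0 = 0)
  })
  names(banks0) <- keys
  db <- structure(list(
    F = b$F, Fnorm = normalize_features(b$F, b$fmin, b$fmax),
    labels = labels, classes = classes, fmin = b$fmin, fmax = b$fmax,
    ranges = ranges, banks0 = banks0, offsets = offsets,
    segmentation = list(T_end = if (is.na(seg[1])) NULL else seg[1],
                        T_samp = seg[2], dt_tr = seg[3], seg_len = Ls),
    config = config, pca = NULL, X = NULL),
    class = "training_db")
  if (!is.null(b$pca_meta)) {
    db$pca <- structure(list(mean = b$pca_mean,
                             eigvecs = b$pca_eigvecs,
                             eigvals = b$pca_eigvals_all[seq_len(b$pca_meta[1])],
                             eigvals_all = b$pca_eigvals_all,
                             d = as.integer(b$pca_meta[1]),
                             center = b$pca_meta[2] == 1),
                        class = "pca_model")
    db$X <- project(db$pca, db$Fnorm)
  }
  db
}

#' Serialize a PCA model to delimited text
#'
#' @param model A `pca_model`.
#' @param file Output path.
#' @export
write_pca_model <- function(model, file) {
  stopifnot(inherits(model, "pca_model"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("#radmotion-pca-1 d=%d center=%d", model$d,
                     as.integer(model$center)), con)
  .write_num_block(con, "mean", model$mean)
  .write_num_block(con, "eigvals_all", model$eigvals_all)
  .write_num_block(con, "eigvecs", model$eigvecs)
  invisible(file)
}

#' Read a PCA model from delimited text
#'
#' @param file Path written by [write_pca_model()].
#' @return A `pca_model`.
#' @export
read_pca_model <- function(file) {
  lines <- readLines(file)
  hdr <- lines[1]
  if (!grepl("^#radmotion-pca-1", hdr))
    stop("not a radmotion PCA model file", call. = FALSE)
  d <- as.integer(sub(".*d=(\\d+).*", "\\1", hdr))
  center <- sub(".*center=(\\d+).*", "\\1", hdr) == "1"
  b <- .read_blocks(lines[-1])
  eigvecs <- b$eigvecs
  if (!is.matrix(eigvecs)) eigvecs <- matrix(eigvecs, ncol = d)
  structure(list(mean = b$mean, eigvecs = eigvecs,
                 eigvals = b$eigvals_all[seq_len(d)],
                 eigvals_all = b$eigvals_all, d = d, center = center),
            class = "pca_model")
}
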