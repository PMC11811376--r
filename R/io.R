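# classed condition for schema/validation failures; the CLI maps these to
# exit code 2 (vs 1 for internal errors)
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("hasm_invalid", "error")))
}

#' Read and write landmark CSV files
#'
#' The shared tabular schema: columns \code{image_id},
#' \code{landmark_index} (1..22), \code{x_px}, \code{y_px}, and optionally
#' \code{pixel_spacing_mm} and \code{label}; one row per landmark, header
#' required, UTF-8. Coordinates are serialized with 17 significant digits so
#' a write-then-read roundtrip is bit-exact.
#'
#' @param path file path.
#' @return \code{read_landmarks_csv}: a named list of \code{landmarks}
#'   (names = image ids, in order of first appearance).
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_id", "landmark_index", "x_px", "y_px")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_invalid("landmark CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(stats::setNames(list(), character(0)))
  if (!is.numeric(df$x_px) || !is.numeric(df$y_px))
    stop_invalid("non-numeric coordinates in ", path)
  ids <- unique(df$image_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    rows <- df[df$image_id == id, ]
    if (anyDuplicated(rows$landmark_index))
      stop_invalid("image '", id, "': duplicate landmark_index ",
                   rows$landmark_index[duplicated(rows$landmark_index)][1L])
    miss <- setdiff(1:22, rows$landmark_index)
    if (length(miss))
      stop_invalid("image '", id, "': missing landmark_index ",
                   paste(miss, collapse = ", "))
    extra <- setdiff(rows$landmark_index, 1:22)
    if (length(extra))
      stop_invalid("image '", id, "': landmark_index out of range: ",
                   paste(extra, collapse = ", "))
    rows <- rows[order(rows$landmark_index), ]
    sp <- if ("pixel_spacing_mm" %in% names(rows) &&
              all(is.finite(rows$pixel_spacing_mm)))
      rows$pixel_spacing_mm[1L]
    lab <- if ("label" %in% names(rows) && !any(is.na(rows$label)) &&
               all(nzchar(rows$label)))
      rows$label[1L]
    out[[id]] <- landmarks(cbind(rows$x_px, rows$y_px),
                           pixel_spacing_mm = sp, label = lab)
  }
  out
}

#' @rdname read_landmarks_csv
#' @param sets a \code{landmarks} object or a (optionally named) list of
#'   them; names become image ids.
#' @export
write_landmarks_csv <- function(sets, path) {
  if (is_landmarks(sets)) sets <- list(sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- sprintf("image_%03d", seq_along(sets))
  have_sp <- any(vapply(sets, function(s)
    !is.null(attr(s, "pixel_spacing_mm")), TRUE))
  have_lab <- any(vapply(sets, function(s) !is.null(attr(s, "label")), TRUE))
  rows <- lapply(names(sets), function(id) {
    s <- sets[[id]]
    p <- unclass(s)
    df <- data.frame(image_id = id, landmark_index = 1:22,
                     x_px = sprintf("%.17g", p[, 1L]),
                     y_px = sprintf("%.17g", p[, 2L]),
                     stringsAsFactors = FALSE)
    if (have_sp) {
      sp <- attr(s, "pixel_spacing_mm")
      df$pixel_spacing_mm <- if (is.null(sp)) NA else sprintf("%.17g", sp)
    }
    if (have_lab) {
      lab <- attr(s, "label")
      df$label <- if (is.null(lab)) "" else lab
    }
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write heatmap stacks (multi-page TIFF + JSON sidecar)
#'
#' A stack is stored as a 22-page 16-bit unsigned TIFF (page k = landmark k;
#' stored values are the max-normalized response scaled to 0..65535) plus a
#' JSON sidecar holding the per-channel affine geometry:
#' \code{\{image_id, pixel_spacing_mm, channels: [\{landmark_index,
#' origin_offset, scale, sigma_hint\}]\}}. Responses come back in [0, 1];
#' the roundtrip quantization error is at most 1/65535 per pixel. Sidecar
#' channel entries may appear in any order; they are matched by
#' \code{landmark_index}.
#'
#' @param tiff_path,sidecar_path file paths.
#' @return \code{read_heatmap_stack}: a \code{heatmap_stack}.
#' @export
read_heatmap_stack <- function(tiff_path, sidecar_path) {
  if (!file.exists(tiff_path)) stop_invalid("no such file: ", tiff_path)
  if (!file.exists(sidecar_path)) stop_invalid("no such file: ", sidecar_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 22L)
    stop_invalid("expected a 22-page TIFF, found ", length(pages),
                 " page(s) in ", tiff_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
  chans <- side$channels
  if (is.null(chans) || length(chans) != 22L)
    stop_invalid("sidecar must describe exactly 22 channels")
  idx <- vapply(chans, function(ch) as.integer(ch$landmark_index), 1L)
  if (!setequal(idx, 1:22))
    stop_invalid("sidecar channel landmark_index must cover 1..22")
  channels <- vector("list", 22L)
  for (i in seq_len(22L)) {
    meta <- chans[[which(idx == i)]]
    sigma_hint <- if (!is.null(meta$sigma_hint)) as.numeric(meta$sigma_hint)
    channels[[i]] <- heatmap_channel(pages[[i]],
                                     origin_offset = as.numeric(unlist(meta$origin_offset)),
                                     scale = as.numeric(meta$scale),
                                     landmark_index = i,
                                     sigma_hint = sigma_hint)
  }
  heatmap_stack(channels,
                image_id = if (!is.null(side$image_id))
                  as.character(side$image_id) else "image",
                pixel_spacing_mm = if (!is.null(side$pixel_spacing_mm))
                  as.numeric(side$pixel_spacing_mm))
}

#' @rdname read_heatmap_stack
#' @param stack a \code{heatmap_stack}.
#' @export
write_heatmap_stack <- function(stack, tiff_path, sidecar_path) {
  stopifnot(inherits(stack, "heatmap_stack"))
  pages <- lapply(stack$channels, function(ch) {
    r <- ch$response
    mx <- max(r)
    if (mx > 0) r <- r / mx
    r
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  side <- list(
    image_id = stack$image_id,
    pixel_spacing_mm = stack$pixel_spacing_mm,
    channels = lapply(stack$channels, function(ch)
      list(landmark_index = ch$landmark_index,
           origin_offset = ch$origin_offset,
           scale = ch$scale,
           sigma_hint = ch$sigma_hint)))
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(tiff_path)
}

#' Read and write shape models as JSON
#'
#' Serializes the mean vector, eigenvector matrix (44 rows of K entries),
#' eigenvalues, and training metadata at full double precision.
#'
#' @param path file path.
#' @return \code{read_shape_model}: a \code{shape_model}.
#' @export
read_shape_model <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("mean", "eigenvectors", "eigenvalues"))
    if (is.null(obj[[f]])) stop_invalid("shape model JSON missing '", f, "'")
  P <- as.matrix(obj$eigenvectors)
  if (length(obj$mean) != 44L || nrow(P) != 44L)
    stop_invalid("shape model JSON has wrong dimensions")
  structure(list(mean = as.numeric(obj$mean),
                 eigenvectors = P,
                 eigenvalues = as.numeric(obj$eigenvalues),
                 n_train = obj$n_train,
                 gpa = obj$gpa,
                 augmentation = obj$augmentation),
            class = "shape_model")
}

#' @rdname read_shape_model
#' @param model a \code{shape_model}.
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  obj <- list(mean = model$mean,
              eigenvectors = model$eigenvectors,
              eigenvalues = model$eigenvalues,
              n_train = model$n_train,
              gpa = model$gpa,
              augmentation = model$augmentation,
              created_by = paste0("hasm ",
                                  as.character(utils::packageVersion("hasm"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Write an error report as JSON
#'
#' @param report an \code{error_report}.
#' @param path file path.
#' @export
write_error_report <- function(report, path) {
  stopifnot(inherits(report, "error_report"))
  obj <- unclass(report)
  obj$E <- unname(as.matrix(obj$E))
  obj$histogram <- as.list(obj$histogram)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", null = "null", pretty = TRUE)
  invisible(path)
}

# known run-config keys: the correction parameters (named exactly as in
# hasm_config) plus bookkeeping blocks
config_keys <- c("n_P", "mu", "max_iterations", "position_tol", "clamp_k",
                 "gamma", "normalize_heatmaps")
run_config_keys <- c(config_keys, "seed", "log_level", "paths",
                     "simulation", "augmentation")

#' Read and validate a YAML run configuration
#'
#' Recognized keys mirror [hasm_config()] field names exactly
#' (\code{n_P}, \code{mu}, \code{max_iterations}, \code{position_tol},
#' \code{clamp_k}, \code{gamma}, \code{normalize_heatmaps}) plus
#' \code{seed}, \code{log_level}, \code{paths}, \code{simulation},
#' \code{augmentation}. Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return list with \code{config} (a validated \code{hasm_config}) and the
#'   remaining blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown))
    stop_invalid("unknown configuration key(s): ",
                 paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), config_keys)]
  cfg <- tryCatch(do.call(hasm_config, args),
                  error = function(e) stop_invalid("invalid configuration: ",
                                                   conditionMessage(e)))
  list(config = cfg,
       seed = raw$seed, log_level = raw$log_level, paths = raw$paths,
       simulation = raw$simulation, augmentation = raw$augmentation)
}
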