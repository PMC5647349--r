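#' Read / write 16-bit grayscale frames
#'
#' Frames travel as 16-bit grayscale TIFF named `well{W}_day{D}.tif`; label
#' masks are written as 16-bit TIFF as well (the installed PNG writer is
#' 8-bit), binary maps as 8-bit PNG.
#'
#' @param path file path.
#' @return `read_frame` returns an integer matrix on the 16-bit scale.
#' @export
read_frame <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  out <- round(img * INTENSITY_MAX)
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_frame
#' @param frame integer/numeric matrix on the 16-bit scale.
#' @export
write_frame <- function(frame, path) {
  tiff::writeTIFF(pmin(pmax(frame, 0), INTENSITY_MAX) / INTENSITY_MAX, path,
                  bits.per.sample = 16)
  invisible(path)
}

#' @rdname read_frame
#' @param labels integer label matrix (values up to 65535).
#' @export
write_label_mask <- function(labels, path) {
  write_frame(labels, path)
}

#' @rdname read_frame
#' @export
read_label_mask <- function(path) {
  read_frame(path)
}

#' @rdname read_frame
#' @param bmap logical matrix.
#' @export
write_binary_map <- function(bmap, path) {
  png::writePNG((as.matrix(bmap) > 0) * 1, path)
  invisible(path)
}

#' @rdname read_frame
#' @export
read_binary_map <- function(path) {
  png::readPNG(path) > 0.5
}

frame_filename <- function(well, day) sprintf("well%d_day%d.tif", well, day)

#' Write / read a scene configuration as plain text
#'
#' `key = value` lines; vector values are comma-separated; texture and growth
#' blocks use dotted keys (e.g. `texture.colony.sd`).
#'
#' @param config a [scene_config()].
#' @param path file path.
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  flat <- c(
    image_size = paste(config$image_size, collapse = ","),
    n_colonies = config$n_colonies,
    day_range = paste(range(config$day_range), collapse = ","),
    reporter_snr = config$reporter_snr,
    maturity_fraction = config$maturity_fraction,
    seed = config$seed)
  for (side in names(config$texture))
    for (k in names(config$texture[[side]]))
      flat[paste("texture", side, k, sep = ".")] <- config$texture[[side]][[k]]
  for (k in names(config$growth))
    flat[paste("growth", k, sep = ".")] <- paste(config$growth[[k]], collapse = ",")
  writeLines(paste(names(flat), "=", flat), path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  num <- function(k) as.numeric(strsplit(vals[keys == k], ",")[[1]])
  tex <- list()
  for (side in c("background", "colony"))
    tex[[side]] <- list(mean = num(paste0("texture.", side, ".mean")),
                        sd = num(paste0("texture.", side, ".sd")),
                        corr_len = num(paste0("texture.", side, ".corr_len")))
  dr <- num("day_range")
  scene_config(image_size = num("image_size"),
               n_colonies = num("n_colonies"),
               day_range = dr[1]:dr[2],
               texture = tex,
               growth = list(
                 carrying_capacity = num("growth.carrying_capacity"),
                 rate = num("growth.rate"),
                 onset_day = num("growth.onset_day"),
                 initial_area = num("growth.initial_area")),
               reporter_snr = num("reporter_snr"),
               maturity_fraction = num("maturity_fraction"),
               seed = num("seed"))
}

#' Write a synthetic scene to disk in the pipeline's on-disk dialect
#'
#' Frames as `well{W}_day{D}.tif`, truth masks as 16-bit TIFF, the area table
#' and picking days as CSV, and the configuration as plain text.
#'
#' @param scene list from [generate_scene()].
#' @param dir output directory (created if needed).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (i in seq_len(nrow(scene$frames)))
    write_frame(scene$frames$frame[[i]],
                file.path(dir, frame_filename(scene$frames$well[i],
                                              scene$frames$day[i])))
  for (i in seq_len(nrow(scene$masks)))
    write_label_mask(scene$masks$mask[[i]],
                     file.path(dir, "truth",
                               sprintf("mask_day%d.tif", scene$masks$day[i])))
  utils::write.csv(scene$areas, file.path(dir, "truth", "areas.csv"),
                   row.names = FALSE)
  utils::write.csv(
    scene$colonies[, c("colony_id", "picking_day", "first_positive_day")],
    file.path(dir, "truth", "picking_days.csv"), row.names = FALSE)
  write_scene_config(scene$config, file.path(dir, "scene_config.txt"))
  invisible(dir)
}
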