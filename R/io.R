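# File-format plumbing: PNG images and masks, CSV truth tables, JSON sidecars.

#' Write an RGB image as PNG
#' @param image Array in [0, 1].
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' Write a binary mask as single-channel PNG (0/255)
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Read an RGB fundus image from PNG
#' @param path PNG path.
#' @return h x w x 3 array in [0, 1].
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read a binary mask from PNG
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (!is.matrix(m)) m <- m[, , 1]
  m > 0.5
}

#' Write a generated batch to disk
#'
#' Images as RGB PNG, disc and vessel masks as 0/255 PNG, scene truth as one
#' CSV row per image plus a JSON sidecar per image.
#'
#' @param batch A [generate_batch()] result.
#' @param dir Output directory (created if needed).
#' @return The truth table, invisibly.
#' @export
write_batch <- function(batch, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (el in batch) {
    id <- el$truth$id
    S <- nrow(el$image)
    write_image_png(el$image, file.path(dir, paste0(id, ".png")))
    write_mask_png(ellipse_mask(el$truth$disc, S, S),
                   file.path(dir, paste0(id, "_disc.png")))
    write_mask_png(el$truth$vessel_mask,
                   file.path(dir, paste0(id, "_vessels.png")))
    side <- el$truth[c("fovea", "background_rg", "laterality", "degradation")]
    side$disc <- unclass(el$truth$disc)
    side$zone_contrast <- as.list(el$truth$zone_contrast)
    jsonlite::write_json(side, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  truth <- batch_truth(batch)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}

#' Read a written batch back as measurement inputs
#'
#' @param dir Directory written by [write_batch()].
#' @return List per image: `id`, `image`, `disc` (refit from the disc mask),
#'   `fovea`, `vessel_mask`, `laterality`.
#' @export
read_batch_inputs <- function(dir) {
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  lapply(seq_len(nrow(truth)), function(i) {
    id <- truth$id[i]
    list(id = id,
         image = read_image_png(file.path(dir, paste0(id, ".png"))),
         disc = fit_ellipse(read_mask_png(file.path(dir, paste0(id, "_disc.png")))),
         fovea = c(truth$fovea_x[i], truth$fovea_y[i]),
         vessel_mask = read_mask_png(file.path(dir, paste0(id, "_vessels.png"))),
         laterality = truth$laterality[i])
  })
}
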