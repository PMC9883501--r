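# Stimulus construction ------------------------------------------------------
#
# All stimuli are square grayscale images held as numeric matrices with values
# in [0, 1]. Rectangles use a row-major, 0-based, half-open convention
# [r0, r1) x [c0, c1), so a 20x20 target centered in a 60x60 image is
# [20, 40) x [20, 40). Images are rendered background -> distractors ->
# target, and that ordering is part of the contract: re-rendering the regions
# reproduces the pixel matrix exactly.

new_rect <- function(r0, r1, c0, c1) {
  r <- c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
  if (any(r != floor(r))) stop_param("rectangle bounds must be integers")
  if (r1 <= r0 || c1 <= c0) stop_param("empty rectangle")
  storage.mode(r) <- "integer"
  r
}

rect_inside <- function(rect, height, width) {
  rect["r0"] >= 0 && rect["r1"] <= height && rect["c0"] >= 0 && rect["c1"] <= width
}

rects_overlap <- function(a, b) {
  a["r0"] < b["r1"] && b["r0"] < a["r1"] && a["c0"] < b["c1"] && b["c0"] < a["c1"]
}

rect_index <- function(rect) {
  list(rows = (rect["r0"] + 1L):rect["r1"], cols = (rect["c0"] + 1L):rect["c1"])
}

check_gray <- function(x, name) {
  for (v in x) check_number(v, name, 0, 1)
  invisible(x)
}

#' Construct a grayscale stimulus image
#'
#' Builds an image by painting a background, then distractor rectangles, then
#' the target rectangle. The target must lie fully inside the image and no
#' distractor may overlap it.
#'
#' @param image_size side length in pixels (square image).
#' @param background either a single gray value in \[0, 1\] (uniform
#'   background) or a length-2 vector `c(left, right)` for a vertically split
#'   background (left half / right half).
#' @param target_value gray value of the target square.
#' @param target_rect integer vector `c(r0, r1, c0, c1)`, 0-based half-open.
#' @param distractors list of `list(value =, rect = c(r0, r1, c0, c1))`.
#' @param label integer stimulus index.
#' @return An object of class `stimulus_image`: a list with `pixels`
#'   (`image_size` x `image_size` matrix), `target_region`, `background_spec`,
#'   `distractors` and `label`.
#' @export
stimulus_image <- function(image_size, background, target_value, target_rect,
                           distractors = list(), label = 1L) {
  check_number(image_size, "image_size", 1, Inf)
  check_gray(background, "background value")
  check_gray(target_value, "target_value")
  if (!length(background) %in% 1:2)
    stop_param("background must be one value or c(left, right)")
  tr <- new_rect(target_rect[1], target_rect[2], target_rect[3], target_rect[4])
  if (!rect_inside(tr, image_size, image_size))
    stop_param("target rectangle lies outside the image")
  distractors <- lapply(distractors, function(d) {
    check_gray(d$value, "distractor value")
    dr <- new_rect(d$rect[1], d$rect[2], d$rect[3], d$rect[4])
    if (!rect_inside(dr, image_size, image_size))
      stop_param("distractor rectangle lies outside the image")
    if (rects_overlap(dr, tr))
      stop_param("distractor rectangle overlaps the target")
    list(value = d$value, rect = dr)
  })

  px <- render_regions(image_size, background, target_value, tr, distractors)
  structure(list(pixels = px, target_region = tr,
                 background_spec = background, distractors = distractors,
                 label = as.integer(label)),
            class = "stimulus_image")
}

render_regions <- function(image_size, background, target_value, tr, distractors) {
  if (length(background) == 1L) {
    px <- matrix(background, image_size, image_size)
  } else {
    px <- matrix(background[2], image_size, image_size)
    split <- image_size %/% 2L
    px[, seq_len(split)] <- background[1]
  }
  for (d in distractors) {
    ix <- rect_index(d$rect)
    px[ix$rows, ix$cols] <- d$value
  }
  ix <- rect_index(tr)
  px[ix$rows, ix$cols] <- target_value
  px
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image %dx%d> label=%d target=[%d,%d)x[%d,%d) value=%g, %d distractor(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$label,
              x$target_region["r0"], x$target_region["r1"],
              x$target_region["c0"], x$target_region["c1"],
              target_value_of(x), length(x$distractors)))
  invisible(x)
}

#' @export
as.matrix.stimulus_image <- function(x, ...) x$pixels

#' Pixels of the target region
#' @param img a `stimulus_image`.
#' @return numeric matrix of the target-region pixel values.
#' @export
target_pixels <- function(img) {
  ix <- rect_index(img$target_region)
  img$pixels[ix$rows, ix$cols]
}

target_value_of <- function(img) img$pixels[img$target_region["r0"] + 1L,
                                            img$target_region["c0"] + 1L]

centered_rect <- function(image_size, target_size) {
  o <- (image_size - target_size) %/% 2L
  c(o, o + target_size, o, o + target_size)
}

half_centered_rect <- function(image_size, target_size, side) {
  split <- image_size %/% 2L
  ro <- (image_size - target_size) %/% 2L
  co <- (split - target_size) %/% 2L
  if (side == "right") co <- split + co
  c(ro, ro + target_size, co, co + target_size)
}

#' Simultaneous-brightness-contrast stimulus pair
#'
#' Two images with an identical centered gray target, one on a uniform dark
#' background and one on a uniform light background.
#'
#' @param target_value,dark_bg,light_bg gray values in \[0, 1\]
#'   (defaults 0.5 / 0.2 / 0.8).
#' @param image_size,target_size side lengths in pixels (defaults 60 / 20).
#' @return list of two `stimulus_image`s (labels 1 and 2).
#' @export
make_sbc_pair <- function(target_value = 0.5, dark_bg = 0.2, light_bg = 0.8,
                          image_size = 60, target_size = 20) {
  check_gray(c(target_value, dark_bg, light_bg), "gray value")
  if (target_size >= image_size)
    stop_param("target_size must be smaller than image_size")
  tr <- centered_rect(image_size, target_size)
  list(stimulus_image(image_size, dark_bg, target_value, tr, label = 1L),
       stimulus_image(image_size, light_bg, target_value, tr, label = 2L))
}

#' Combined-background stimulus pair
#'
#' Each image has a vertically split background (dark half / light half); the
#' target sits centered inside the dark half in the first image and inside the
#' light half in the second.
#'
#' @inheritParams make_sbc_pair
#' @param dark_side `"left"` or `"right"`: which half is dark.
#' @return list of two `stimulus_image`s.
#' @export
make_combined_background_pair <- function(target_value = 0.5, dark_bg = 0.2,
                                          light_bg = 0.8, image_size = 60,
                                          target_size = 20, dark_side = "left") {
  check_gray(c(target_value, dark_bg, light_bg), "gray value")
  if (target_size >= image_size %/% 2L)
    stop_param("target_size must fit inside one half of the image")
  dark_side <- match.arg(dark_side, c("left", "right"))
  bg <- if (dark_side == "left") c(dark_bg, light_bg) else c(light_bg, dark_bg)
  side_dark <- dark_side
  side_light <- if (dark_side == "left") "right" else "left"
  list(stimulus_image(image_size, bg, target_value,
                      half_centered_rect(image_size, target_size, side_dark),
                      label = 1L),
       stimulus_image(image_size, bg, target_value,
                      half_centered_rect(image_size, target_size, side_light),
                      label = 2L))
}

#' Distractor stimulus
#'
#' Places four square distractors around the target, each flush with the
#' image boundary ("along boundaries") and moved perpendicularly toward the
#' target by an offset — the top/bottom distractors take vertical moving
#' steps, the left/right ones horizontal steps. By default the distractors
#' are aligned with the target center on each side (`placement = "side"`);
#' `placement = "corner"` puts them in the image corners moving diagonally
#' inward instead.
#'
#' @inheritParams make_sbc_pair
#' @param bg_spec one gray value (uniform) or `c(dark, light)` halves.
#' @param distractor_value gray value of the distractors.
#' @param distractor_size distractor side length in pixels.
#' @param distractor_offsets inward offset from the boundary in pixels; a
#'   scalar (all four) or length 4 (top, bottom, left, right). 0 places
#'   distractors flush with the image boundary; one 5-px "moving step"
#'   corresponds to offset 5.
#' @param placement `"side"` (default) or `"corner"`.
#' @param target_rect optional explicit target rectangle; by default the
#'   target is centered in the image (on a split background it straddles the
#'   dark and light halves, sitting on both contexts symmetrically).
#' @param label stimulus index.
#' @return a `stimulus_image`.
#' @export
make_distractor_image <- function(target_value = 0.5, bg_spec = c(0.2, 0.8),
                                  distractor_value = 1, distractor_size = 10,
                                  distractor_offsets = 0, image_size = 60,
                                  target_size = 20, placement = c("side", "corner"),
                                  target_rect = NULL, label = 1L) {
  check_gray(c(target_value, bg_spec, distractor_value), "gray value")
  placement <- match.arg(placement)
  if (length(distractor_offsets) == 1L)
    distractor_offsets <- rep(distractor_offsets, 4L)
  stopifnot(length(distractor_offsets) == 4L)
  if (is.null(target_rect)) target_rect <- centered_rect(image_size, target_size)
  sz <- distractor_size
  clamp <- function(x) max(0L, min(as.integer(x), image_size - sz))
  if (placement == "side") {
    tr_mid_r <- clamp((target_rect[1] + target_rect[2] - sz) %/% 2)
    tr_mid_c <- clamp((target_rect[3] + target_rect[4] - sz) %/% 2)
    o <- distractor_offsets
    rects <- list(
      c(o[1], o[1] + sz, tr_mid_c, tr_mid_c + sz),                              # top
      c(image_size - o[2] - sz, image_size - o[2], tr_mid_c, tr_mid_c + sz),    # bottom
      c(tr_mid_r, tr_mid_r + sz, o[3], o[3] + sz),                              # left
      c(tr_mid_r, tr_mid_r + sz, image_size - o[4] - sz, image_size - o[4]))    # right
  } else {
    corner <- function(o, top, left) {
      r0 <- if (top) o else image_size - o - sz
      c0 <- if (left) o else image_size - o - sz
      c(r0, r0 + sz, c0, c0 + sz)
    }
    rects <- list(corner(distractor_offsets[1], TRUE, TRUE),
                  corner(distractor_offsets[2], TRUE, FALSE),
                  corner(distractor_offsets[3], FALSE, TRUE),
                  corner(distractor_offsets[4], FALSE, FALSE))
  }
  distractors <- lapply(rects, function(r) list(value = distractor_value, rect = r))
  stimulus_image(image_size, bg_spec, target_value, target_rect,
                 distractors, label = label)
}

#' Anchoring stimulus set
#'
#' One dark-background image plus one image per lighter background value, all
#' with the same centered target.
#'
#' @inheritParams make_sbc_pair
#' @param light_bg_values vector of lighter background gray values
#'   (default `c(0.8, 0.9, 1)`).
#' @return list of `stimulus_image`s (dark background first).
#' @export
make_anchoring_set <- function(light_bg_values = c(0.8, 0.9, 1),
                               target_value = 0.5, dark_bg = 0.2,
                               image_size = 60, target_size = 20) {
  check_gray(c(light_bg_values, target_value, dark_bg), "gray value")
  tr <- centered_rect(image_size, target_size)
  out <- list(stimulus_image(image_size, dark_bg, target_value, tr, label = 1L))
  for (i in seq_along(light_bg_values))
    out[[i + 1L]] <- stimulus_image(image_size, light_bg_values[i],
                                    target_value, tr, label = i + 1L)
  out
}

# Lossless raster export -----------------------------------------------------

#' Write a stimulus to an ASCII PGM file with a JSON metadata sidecar
#'
#' Pixels are quantized to 8 bits (`round(p * 255)`); geometry and gray values
#' go to `<path>.json`. Reading back reproduces the quantized pixels exactly.
#'
#' @param img a `stimulus_image`.
#' @param path output file path (conventionally `.pgm`).
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(img, path) {
  q <- round(img$pixels * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), "255"), con)
  # one image row per line, row-major
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  meta <- list(label = img$label, target_region = unname(img$target_region),
               background_spec = img$background_spec,
               target_value = target_value_of(img),
               distractors = lapply(img$distractors, function(d)
                 list(value = d$value, rect = unname(d$rect))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stimulus written by [write_stimulus()]
#' @param path the `.pgm` path.
#' @return a `stimulus_image` with 8-bit-quantized pixel values.
#' @export
read_stimulus <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P2") stop_param("not an ASCII PGM (P2) file")
  dims <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  maxval <- as.numeric(txt[3])
  vals <- as.numeric(unlist(strsplit(trimws(txt[-(1:3)]), "\\s+")))
  px <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE) / maxval
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- stimulus_image(dims[1], unlist(meta$background_spec),
                        meta$target_value, meta$target_region,
                        distractors = if (length(meta$distractors))
                          apply_meta_distractors(meta$distractors) else list(),
                        label = meta$label)
  img$pixels <- px  # quantized values override the re-rendered ideal ones
  img
}

apply_meta_distractors <- function(d) {
  if (is.data.frame(d))
    lapply(seq_len(nrow(d)), function(i) list(value = d$value[i], rect = d$rect[[i]]))
  else lapply(d, function(x) list(value = x$value, rect = unlist(x$rect)))
}
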