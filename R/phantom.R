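# Raster fundus phantoms and the demo blob detector.
#
# The phantom is deliberately simple — flat background, bright optic
# disc, dark foveal patch, random-walk vessels and hard-disc lesion
# blobs — a stand-in for real fundus photographs that lets the full
# detect-summarise-grade pipeline run end to end. Realism is a
# non-goal. Rasters are exchanged as plain-text PGM (P2), which keeps
# fixtures human-readable and diffable.

#' Read and write plain-text PGM (P2) images
#'
#' @param path file path.
#' @param img numeric matrix in \[0, 1\] (rows = y, columns = x).
#' @param maxval maximum grey value written (default 255).
#' @return `read_pgm()` returns a numeric matrix scaled to \[0, 1\].
#' @export
read_pgm <- function(path) {
  tokens <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tokens[1] != "P2") stop("only plain-text PGM (P2) is supported",
                              call. = FALSE)
  w <- as.integer(tokens[2])
  h <- as.integer(tokens[3])
  maxval <- as.double(tokens[4])
  vals <- as.double(tokens[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch", call. = FALSE)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img))
  vals <- round(pmin(pmax(img, 0), 1) * maxval)
  lines <- c("P2", paste(ncol(img), nrow(img)), as.character(maxval),
             apply(vals, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Compact geometry for a 400 x 400 phantom
#'
#' @return a [fundus_geometry()]: fovea at (200, 200), 60 px disc
#'   diameter, disc 2.5 DD temporal.
#' @export
phantom_geometry <- function() {
  fundus_geometry(disc_centre = c(350, 200), disc_diameter = 60,
                  fovea_centre = c(200, 200),
                  image_width = 400, image_height = 400)
}

is_bright_type <- function(type) type %in% c("EXUDATE", "CWS")

# Paint a filled disc onto the image (in place semantics via return).
paint_disc <- function(img, cx, cy, radius, value) {
  h <- nrow(img)
  w <- ncol(img)
  xr <- max(1, floor(cx + 1 - radius)):min(w, ceiling(cx + 1 + radius))
  yr <- max(1, floor(cy + 1 - radius)):min(h, ceiling(cy + 1 + radius))
  for (yy in yr) {
    dx2 <- radius^2 - (yy - 1 - cy)^2
    if (dx2 < 0) next
    xs <- xr[abs(xr - 1 - cx) <= sqrt(dx2)]
    img[yy, xs] <- value
  }
  img
}

#' Render an image record as a raster phantom
#'
#' @param record an [image_record()]; its geometry must fit the canvas.
#' @param seed integer seed controlling the vessel random walks.
#' @return numeric matrix in \[0, 1\] of size image_height x
#'   image_width.
#' @export
#' @seealso [demo_detect()]
render_phantom <- function(record, seed = 1L) {
  stopifnot(inherits(record, "image_record"))
  g <- record$geometry
  if (sqrt(sum((g$disc_centre - g$fovea_centre)^2)) < g$disc_diameter / 2) {
    stop("render error: disc and fovea landmarks overlap", call. = FALSE)
  }
  h <- as.integer(g$image_height)
  w <- as.integer(g$image_width)
  img <- matrix(0.45, h, w)
  img <- with_seed(seed, {
    # vessels: random walks leaving the disc in arcs
    for (v in 1:4) {
      pos <- g$disc_centre
      ang <- stats::runif(1, 0, 2 * pi)
      for (step in seq_len(250)) {
        ang <- ang + stats::rnorm(1, 0, 0.12)
        pos <- pos + 1.6 * c(cos(ang), sin(ang))
        if (pos[1] < 2 || pos[1] > w - 3 || pos[2] < 2 || pos[2] > h - 3)
          break
        img <- paint_disc(img, pos[1], pos[2], 1.4, 0.30)
      }
    }
    img
  })
  img <- paint_disc(img, g$disc_centre[1], g$disc_centre[2],
                    g$disc_diameter / 2, 0.90)
  img <- paint_disc(img, g$fovea_centre[1], g$fovea_centre[2],
                    0.4 * g$disc_diameter, 0.38)
  for (i in seq_len(nrow(record$lesions))) {
    les <- record$lesions[i, ]
    radius <- max(1.5, sqrt(les$area / pi))
    value <- if (is_bright_type(les$type)) 0.98 else 0.08
    img <- paint_disc(img, les$x, les$y, radius, value)
  }
  img
}

# 8-connected component labelling of a logical matrix.
label_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  current <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    current <- current + 1L
    stack <- start
    labels[start] <- current
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      y <- (p - 1L) %% h + 1L
      x <- (p - 1L) %/% h + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy
        xx <- x + dx
        if (yy < 1L || yy > h || xx < 1L || xx > w) next
        q <- (xx - 1L) * h + yy
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- current
          stack <- c(stack, q)
        }
      }
    }
  }
  labels
}

components_to_lesions <- function(labels, type_fun, id_offset = 0L) {
  n <- max(labels)
  if (n == 0L) {
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      area = numeric(), confidence = numeric()))
  }
  h <- nrow(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  y <- (idx - 1L) %% h  # 0-based pixel coordinates
  x <- (idx - 1L) %/% h
  data.frame(type = vapply(seq_len(n),
                           function(k) type_fun(sum(lab == k)), ""),
             x = as.double(tapply(x, lab, mean)),
             y = as.double(tapply(y, lab, mean)),
             area = as.double(table(lab)),
             confidence = 1, stringsAsFactors = FALSE)
}

#' Demo blob detector on a rendered phantom
#'
#' Recovers lesion candidates by intensity thresholding plus
#' 8-connected component analysis: bright components (outside the disc)
#' become exudates or cotton wool spots depending on size, dark
#' components (darker than the vessel shade) become microaneurysms or
#' haemorrhages. On noise-free phantoms with well-separated blobs the
#' planted blobs are recovered within 0.1 DD of their true centroids.
#'
#' @param img numeric matrix in \[0, 1\] (from [render_phantom()] or
#'   [read_pgm()]).
#' @param geometry the [fundus_geometry()] of the phantom (landmarks are
#'   taken as given, mirroring annotation-borne geometry).
#' @param image_id identifier for the returned record.
#' @param bright_threshold,dark_threshold intensity cut-offs.
#' @param min_area smallest component kept, in pixels.
#' @return an [image_record()] of the detected candidates.
#' @export
demo_detect <- function(img, geometry, image_id = "phantom",
                        bright_threshold = 0.75, dark_threshold = 0.2,
                        min_area = 3) {
  stopifnot(is.matrix(img))
  stopifnot_geometry(geometry)
  h <- nrow(img)
  w <- ncol(img)
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  in_disc <- (xg - geometry$disc_centre[1])^2 +
    (yg - geometry$disc_centre[2])^2 <= (0.62 * geometry$disc_diameter)^2
  bright <- img >= bright_threshold & !in_disc
  dark <- img <= dark_threshold
  to_frame <- function(labels, type_fun) {
    df <- components_to_lesions(labels, type_fun)
    df[df$area >= min_area, , drop = FALSE]
  }
  bright_df <- to_frame(label_components(bright),
                        function(a) if (a > 250) "CWS" else "EXUDATE")
  dark_df <- to_frame(label_components(dark),
                      function(a) if (a > 25) "HAEMORRHAGE" else "MA")
  df <- rbind(bright_df, dark_df)
  image_record(image_id, geometry,
               lesion_frame(type = df$type, x = df$x, y = df$y,
                            area = df$area, confidence = df$confidence),
               allow_outside = TRUE)
}

#' Convert a binary lesion mask to centroid + area lesions
#'
#' Reads a plain-text PGM mask (or takes a matrix), thresholds it, and
#' converts each 8-connected component into one lesion of the given
#' type.
#'
#' @param mask path to a P2 PGM file or a numeric matrix.
#' @param type lesion type assigned to every component.
#' @param threshold mask values strictly above this are foreground.
#' @return a lesion table ([lesion_frame()]).
#' @export
mask_to_lesions <- function(mask, type = "EXUDATE", threshold = 0.5) {
  if (is.character(mask)) mask <- read_pgm(mask)
  if (!type %in% lesion_types()) stop("unknown lesion type: ", type,
                                      call. = FALSE)
  labels <- label_components(mask > threshold)
  df <- components_to_lesions(labels, function(a) type)
  lesion_frame(type = df$type, x = df$x, y = df$y, area = df$area,
               confidence = df$confidence)
}
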