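# Reading and writing slice-wise segmentation data and result tables.
#
# Contour JSON schema (units fixed to millimetres):
#   {subject_id, muscle_label, units: "mm",
#    shank_landmarks: {z_distal, z_proximal},
#    slices: [{z, polygons: [{role: "outer"|"hole", xy: [[x, y], ...]}]}]}
#
# Contour CSV dialect: one vertex per row with columns
#   subject_id, muscle_label, z_mm, polygon_index, role, vertex_index,
#   x_mm, y_mm
# and stack-level metadata carried in leading comment lines
#   #shank_z_distal_mm=..., #shank_z_proximal_mm=...

#' Read a contour stack from JSON or CSV
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @return A validated [contour_stack()] with winding normalized and slices
#'   sorted ascending in z.
#' @export
read_contour_stack <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "json") read_contour_json(path) else read_contour_csv(path)
}

read_contour_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) {
    stop(sprintf("cannot parse '%s' as JSON: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  for (field in c("subject_id", "muscle_label", "slices")) {
    if (is.null(x[[field]])) {
      stop(sprintf("contour file '%s' is missing field '%s'", path, field),
           call. = FALSE)
    }
  }
  if (!is.null(x$units) && !identical(x$units, "mm")) {
    stop(sprintf("contour file '%s' declares units '%s'; only mm is supported",
                 path, x$units), call. = FALSE)
  }
  landmarks <- if (!is.null(x$shank_landmarks)) {
    c(x$shank_landmarks$z_distal, x$shank_landmarks$z_proximal)
  }
  contours <- list()
  for (sl in x$slices) {
    if (is.null(sl$z) || is.null(sl$polygons)) {
      stop(sprintf("malformed slice record in '%s' (needs z and polygons)", path),
           call. = FALSE)
    }
    for (pg in sl$polygons) {
      xy <- do.call(rbind, lapply(pg$xy, function(v) {
        if (length(v) != 2L || !is.numeric(unlist(v))) {
          stop(sprintf("malformed vertex in slice z = %g of '%s'", sl$z, path),
               call. = FALSE)
        }
        as.numeric(unlist(v))
      }))
      role <- if (is.null(pg$role)) "outer" else pg$role
      contours[[length(contours) + 1L]] <- contour(sl$z, xy, role = role)
    }
  }
  contour_stack(contours, subject_id = x$subject_id,
                muscle_label = x$muscle_label,
                shank_landmarks = landmarks)
}

read_contour_csv <- function(path) {
  header_lines <- grep("^#", readLines(path, n = 20L), value = TRUE)
  meta <- list()
  for (hl in header_lines) {
    kv <- strsplit(sub("^#", "", hl), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- as.numeric(kv[2L])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("subject_id", "muscle_label", "z_mm", "polygon_index", "role",
           "vertex_index", "x_mm", "y_mm")
  if (!all(req %in% names(df))) {
    stop(sprintf("contour CSV '%s' must have columns: %s", path,
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  landmarks <- if (!is.null(meta$shank_z_distal_mm) &&
                   !is.null(meta$shank_z_proximal_mm)) {
    c(meta$shank_z_distal_mm, meta$shank_z_proximal_mm)
  }
  keys <- unique(df[, c("z_mm", "polygon_index")])
  contours <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$z_mm == keys$z_mm[i] & df$polygon_index == keys$polygon_index[i]
    rows <- df[sel, ][order(df$vertex_index[sel]), ]
    contour(keys$z_mm[i], cbind(rows$x_mm, rows$y_mm), role = rows$role[1L])
  })
  contour_stack(contours, subject_id = df$subject_id[1L],
                muscle_label = df$muscle_label[1L],
                shank_landmarks = landmarks)
}

#' Write a contour stack to JSON or CSV
#'
#' Serialization is lossless: reading the file back reproduces all
#' coordinates and metadata exactly.
#'
#' @param stack A [contour_stack()].
#' @param path Output file path; the extension selects the format unless
#'   `format` is given.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_contour_stack <- function(stack, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(stack, "contour_stack"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  z_all <- vapply(stack$contours, function(ct) ct$z, numeric(1))
  if (format == "json") {
    slices <- lapply(stack$slice_positions, function(zi) {
      polys <- lapply(stack$contours[z_all == zi], function(ct) {
        list(role = ct$role,
             xy = lapply(seq_len(nrow(ct$vertices)),
                         function(i) ct$vertices[i, ]))
      })
      list(z = zi, polygons = polys)
    })
    out <- list(subject_id = stack$subject_id,
                muscle_label = stack$muscle_label, units = "mm")
    if (!is.null(stack$shank_landmarks)) {
      out$shank_landmarks <- list(
        z_distal = unname(stack$shank_landmarks["z_distal"]),
        z_proximal = unname(stack$shank_landmarks["z_proximal"]))
    }
    out$slices <- slices
    # digits = I(17): doubles survive the round trip bit-exactly
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  } else {
    rows <- do.call(rbind, lapply(seq_along(stack$contours), function(j) {
      ct <- stack$contours[[j]]
      nv <- nrow(ct$vertices)
      data.frame(subject_id = stack$subject_id,
                 muscle_label = stack$muscle_label,
                 z_mm = sprintf("%.17g", ct$z), polygon_index = j,
                 role = ct$role, vertex_index = seq_len(nv),
                 x_mm = sprintf("%.17g", ct$vertices[, 1L]),
                 y_mm = sprintf("%.17g", ct$vertices[, 2L]),
                 stringsAsFactors = FALSE)
    }))
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(stack$shank_landmarks)) {
      writeLines(sprintf("#shank_z_distal_mm=%.17g",
                         stack$shank_landmarks["z_distal"]), con)
      writeLines(sprintf("#shank_z_proximal_mm=%.17g",
                         stack$shank_landmarks["z_proximal"]), con)
    }
    utils::write.table(rows, con, row.names = FALSE, quote = FALSE,
                       sep = ",")  # %.17g fields: round-trip is bit-exact
  }
  invisible(path)
}

#' Extract per-slice contours from a 3-D label mask
#'
#' Traces the boundary of the voxels equal to `label` on every slice
#' (marching squares at the 0.5 iso-level of the binary slice image, in
#' physical coordinates), classifying nested boundaries as holes. For a
#' convex region of at least ~100 voxels the polygon area agrees with
#' voxel count x dx x dy to within 2%.
#'
#' @param mask 3-D integer/numeric array indexed (x, y, z).
#' @param spacing Numeric `c(dx, dy, dz)` voxel spacing in mm, all positive.
#'   In-plane anisotropy is applied as given.
#' @param label Label value to extract.
#' @param subject_id,muscle_label Metadata for the stack.
#' @param shank_landmarks Optional `c(z_distal, z_proximal)` mm.
#' @return A [contour_stack()] with one or more contours on every slice
#'   where the label occurs; slice z positions are voxel-centre positions
#'   `(k - 0.5) * dz`.
#' @export
mask_to_contours <- function(mask, spacing, label = 1L,
                             subject_id = "mask", muscle_label = "muscle",
                             shank_landmarks = NULL) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3-D array", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive values (dx, dy, dz)", call. = FALSE)
  }
  if (!any(mask == label)) {
    stop(sprintf("label %g not present in mask", label), call. = FALSE)
  }
  dx <- spacing[1L]; dy <- spacing[2L]; dz <- spacing[3L]
  nx <- dim(mask)[1L]; ny <- dim(mask)[2L]
  # pad in-plane with a zero ring so boundaries touching the array edge close
  xc <- (seq_len(nx + 2L) - 1.5) * dx
  yc <- (seq_len(ny + 2L) - 1.5) * dy
  contours <- list()
  for (k in seq_len(dim(mask)[3L])) {
    sl <- matrix(0, nx + 2L, ny + 2L)
    sl[2:(nx + 1L), 2:(ny + 1L)] <- (mask[, , k] == label) * 1
    if (!any(sl > 0)) next
    cl <- grDevices::contourLines(xc, yc, sl, levels = 0.5)
    if (!length(cl)) next
    zk <- (k - 0.5) * dz
    polys <- lapply(cl, function(cc) cbind(cc$x, cc$y))
    # nesting depth: a boundary inside an odd number of others is a hole
    depth <- vapply(seq_along(polys), function(i) {
      pt <- polys[[i]][1L, , drop = FALSE]
      sum(vapply(seq_along(polys), function(j) {
        j != i && points_in_polygon(pt, polys[[j]])
      }, logical(1)))
    }, integer(1))
    for (i in seq_along(polys)) {
      contours[[length(contours) + 1L]] <-
        contour(zk, polys[[i]],
                role = if (depth[i] %% 2L == 1L) "hole" else "outer",
                validate = FALSE)
    }
  }
  contour_stack(contours, subject_id = subject_id,
                muscle_label = muscle_label,
                shank_landmarks = shank_landmarks, validate = FALSE)
}

#' Read a multipage TIFF label mask
#'
#' @param path TIFF file with one page per slice.
#' @return 3-D array indexed (x, y, z); spacing must be supplied separately
#'   to [mask_to_contours()] (TIFF carries no reliable voxel size).
#' @export
read_mask_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to read TIFF masks", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(lapply(pages, function(p) t(as.matrix(p))))
  arr
}

#' Read a NIfTI label mask with voxel spacing
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return List with `mask` (3-D array) and `spacing` (dx, dy, dz in mm
#'   from the header).
#' @export
read_mask_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("package 'RNifti' is required to read NIfTI masks", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  list(mask = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Write a morphology table to CSV
#'
#' One row per (subject, muscle) with columns `subject_id`, `muscle_label`,
#' `L_muscle_cm`, `ACSA_max_cm2`, `acsa_max_position_pct_shank`,
#' `V_measured_cm3`, `shape_factor` (units cm, cm^2, cm^3).
#'
#' @param records Data frame of morphology rows ([measure_cohort()] output).
#' @param path Output CSV path.
#' @export
write_morphology_table <- function(records, path) {
  if (is.null(records) || !nrow(records)) {
    stop("`records` must contain at least one morphology row", call. = FALSE)
  }
  cols <- c("subject_id", "muscle_label", "L_muscle_cm", "ACSA_max_cm2",
            "acsa_max_position_pct_shank", "V_measured_cm3", "shape_factor")
  if (!all(cols %in% names(records))) {
    stop(sprintf("morphology records must have columns: %s",
                 paste(cols, collapse = ", ")), call. = FALSE)
  }
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a morphology table written by [write_morphology_table()]
#'
#' @param path CSV path.
#' @return Data frame of morphology rows.
#' @export
read_morphology_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
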