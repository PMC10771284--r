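#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1/2 file, applies any header scale slope/intercept, and
#' returns the voxel data together with the grid (shape + sform/qform affine,
#' RAS, mm). 4-D inputs are rejected: the pipeline works on one volume per
#' b-value and timepoint.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with elements `values` (numeric 3-D array) and `grid`
#'   (a [voxel_grid()]).
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI volume: ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), " dimensions", call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(values = array(as.numeric(img), dim = d),
       grid = voxel_grid(d, affine = aff))
}

#' Write a 3-D volume as NIfTI
#'
#' @param values numeric array (3-D).
#' @param grid the [voxel_grid()] describing it.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; default `"double"` so that a
#'   write-then-read round trip preserves values beyond float32 precision.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, grid, path, datatype = "double") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!all(dim(values) == grid$shape))
    stop("values shape does not match grid shape", call. = FALSE)
  img <- RNifti::asNifti(array(as.numeric(values), dim = grid$shape))
  RNifti::pixdim(img) <- grid_spacing(grid)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a tumor mask with its JSON sidecar
#'
#' Masks are stored as unsigned 8-bit NIfTI label volumes (nonzero = inside),
#' one file per tumor, with a sidecar `<stem>.json` carrying `label`,
#' `patient` and `timepoint`. Missing sidecars fall back to defaults.
#'
#' @param path path to the mask NIfTI.
#' @return an [roi_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(label = "primary", patient = NA_character_, timepoint = "preRT")
  if (file.exists(sidecar)) {
    got <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  roi_mask(v$values != 0, v$grid, label = meta$label,
           patient = meta$patient, timepoint = meta$timepoint)
}

#' Write a tumor mask and its JSON sidecar
#' @param roi an [roi_mask()].
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  write_volume(array(as.numeric(roi$mask), dim = roi$grid$shape),
               roi$grid, path, datatype = "uint8")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(label = roi$label, patient = roi$patient,
                            timepoint = roi$timepoint),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

.cohort_day_cols <- c("lp_day", "rp_day", "dp_day", "death_day", "last_fu_day")

#' Read and validate a cohort table
#'
#' The cohort CSV has one row per patient with columns `id`, `p16_group`
#' (`p16+OPSCC` or `LAHNSCC`), `arm` (`70Gy` or `80Gy`), `rt_start`, and the
#' event fields `lp`, `rp`, `dp`, `death` (each may be empty) plus `last_fu`.
#' Time fields are accepted either as ISO dates or as integer day offsets;
#' internally everything is converted to days since the start of
#' radiotherapy, the anchor for all time-to-event endpoints.
#'
#' @param path path to the CSV file.
#' @return a `data.frame` of class `cohort_table` with columns `id`,
#'   `p16_group`, `arm`, `lp_day`, `rp_day`, `dp_day`, `death_day`,
#'   `last_fu_day` (days since RT start; `NA` where absent).
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "p16_group", "arm", "rt_start", "lp", "rp", "dp",
            "death", "last_fu")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_grp <- setdiff(unique(raw$p16_group), c("p16+OPSCC", "LAHNSCC"))
  if (length(bad_grp))
    stop("unknown p16 group(s): ", paste(bad_grp, collapse = ", "),
         call. = FALSE)
  bad_arm <- setdiff(unique(raw$arm), c("70Gy", "80Gy"))
  if (length(bad_arm))
    stop("unknown arm(s): ", paste(bad_arm, collapse = ", "), call. = FALSE)

  is_int <- function(x) grepl("^-?[0-9]+$", trimws(as.character(x)))
  # per row: integer fields are day offsets relative to rt_start's own
  # offset; date fields are differenced against the rt_start date
  anchor_chr <- as.character(raw$rt_start)
  anchor_date <- rep(as.Date(NA), nrow(raw))
  rt0 <- rep(0, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (is_int(anchor_chr[i])) {
      rt0[i] <- as.numeric(anchor_chr[i])
    } else {
      d <- as.Date(anchor_chr[i])
      if (is.na(d)) stop("unparseable rt_start", call. = FALSE)
      anchor_date[i] <- d
    }
  }
  to_days <- function(x) {
    x <- as.character(x)
    out <- rep(NA_real_, length(x))
    for (i in seq_along(x)) {
      if (is.na(x[i]) || !nzchar(trimws(x[i]))) next
      if (is_int(x[i])) {
        out[i] <- as.numeric(x[i]) - rt0[i]
      } else {
        d <- as.Date(x[i])
        if (is.na(d))
          stop("unparseable date(s) in cohort table", call. = FALSE)
        if (is.na(anchor_date[i]))
          stop("date event with integer rt_start for id ", raw$id[i],
               call. = FALSE)
        out[i] <- as.numeric(d - anchor_date[i])
      }
    }
    out
  }

  out <- data.frame(id = as.character(raw$id),
                    p16_group = raw$p16_group,
                    arm = raw$arm,
                    stringsAsFactors = FALSE)
  for (nm in c("lp", "rp", "dp", "death", "last_fu"))
    out[[paste0(nm, "_day")]] <- to_days(raw[[nm]])

  ev <- as.matrix(out[.cohort_day_cols])
  if (any(ev < 0, na.rm = TRUE))
    stop("event or follow-up before RT start in cohort table", call. = FALSE)
  if (anyNA(out$last_fu_day))
    stop("last_fu is required for every patient", call. = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
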