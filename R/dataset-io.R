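# On-disk serialization of a synthetic cohort: NIfTI volumes for image data,
# TSV for tables, JSON for the manifest. All I/O goes through RNifti / readr /
# jsonlite.

#' Write a synthetic cohort to disk
#'
#' Materializes a cohort as a directory tree: one sub-directory per subject
#' holding the ROI mask, three resting sessions and the induced sessions as
#' 4D NIfTI volumes, events/ratings/associations as TSV, ground-truth
#' amplitudes and embed logs, plus a top-level `manifest.json` carrying the
#' full generating spec. Regenerating with the same spec (same seed) yields
#' byte-identical files.
#'
#' @param spec A [synthetic_spec()], or an already-simulated `preplay_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the cohort that was written.
#' @seealso [read_dataset()]
#' @export
make_dataset <- function(spec, dir) {
  cohort <- if (inherits(spec, "preplay_cohort")) spec else simulate_cohort(spec)
  spec <- cohort$spec
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(sprintf("cannot write dataset to '%s'.", dir))
  }
  manifest <- unclass(spec)
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  tr <- spec$tr_seconds
  for (sub in cohort$subjects) {
    sdir <- file.path(dir, sprintf("sub-%02d", sub$id))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    write_volume(array(as.numeric(sub$mask), dim(sub$mask)),
      file.path(sdir, "roi_mask.nii"), tr
    )
    for (sess in names(sub$rest)) {
      write_volume(
        series_to_volume(sub$rest[[sess]]$series),
        file.path(sdir, sprintf("rest_%s.nii", sess)), tr
      )
      readr::write_tsv(
        sub$rest[[sess]]$embed_log,
        file.path(sdir, sprintf("embed_%s.tsv", sess)),
        progress = FALSE
      )
    }
    for (k in seq_along(sub$induced$sessions)) {
      write_volume(
        matrix_to_volume(sub$induced$sessions[[k]], sub$mask),
        file.path(sdir, sprintf("induced_ses-%02d.nii", k)), tr
      )
    }
    readr::write_tsv(sub$induced$events, file.path(sdir, "events.tsv"),
      progress = FALSE
    )
    readr::write_tsv(sub$ratings, file.path(sdir, "ratings.tsv"),
      progress = FALSE
    )
    readr::write_tsv(sub$association, file.path(sdir, "associations.tsv"),
      progress = FALSE
    )
    readr::write_tsv(
      tibble::tibble(
        sentence_id = seq_along(sub$amplitudes),
        amplitude = sub$amplitudes
      ),
      file.path(sdir, "amplitudes.tsv"),
      progress = FALSE
    )
  }
  invisible(cohort)
}

#' Read a cohort written by [make_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `preplay_cohort` equivalent to the one that was written (up to
#'   single-precision NIfTI storage of voxel data).
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("'%s' does not contain a manifest.json.", dir))
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  spec <- do.call(synthetic_spec, m[setdiff(names(m), character(0))])
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  sdirs <- sdirs[grepl("sub-", basename(sdirs))]
  subjects <- lapply(seq_along(sdirs), function(i) {
    sdir <- sdirs[i]
    mask_arr <- as.array(RNifti::readNifti(file.path(sdir, "roi_mask.nii")))
    mask <- array(mask_arr != 0, dim(mask_arr))
    rest <- lapply(
      setNames(nm = c("day1", "day2pre", "day2post")),
      function(sess) {
        vol <- as.array(
          RNifti::readNifti(file.path(sdir, sprintf("rest_%s.nii", sess)))
        )
        list(
          series = volume_to_series(vol, mask, session = sess),
          embed_log = readr::read_tsv(
            file.path(sdir, sprintf("embed_%s.tsv", sess)),
            show_col_types = FALSE, progress = FALSE
          )
        )
      }
    )
    ind_files <- sort(list.files(sdir, "^induced_ses-", full.names = TRUE))
    sessions <- lapply(ind_files, function(f) {
      vol <- as.array(RNifti::readNifti(f))
      volume_to_series(vol, mask)$data
    })
    events <- readr::read_tsv(file.path(sdir, "events.tsv"),
      show_col_types = FALSE, progress = FALSE
    )
    list(
      id = i, mask = mask, representations = NULL,
      amplitudes = readr::read_tsv(file.path(sdir, "amplitudes.tsv"),
        show_col_types = FALSE, progress = FALSE
      )$amplitude,
      association = readr::read_tsv(file.path(sdir, "associations.tsv"),
        show_col_types = FALSE, progress = FALSE
      ),
      ratings = readr::read_tsv(file.path(sdir, "ratings.tsv"),
        show_col_types = FALSE, progress = FALSE
      ),
      rest = rest,
      induced = list(
        sessions = sessions, events = events,
        n_frames = if (length(sessions)) nrow(sessions[[1]]) else 0L,
        mask = mask
      )
    )
  })
  structure(list(spec = spec, subjects = subjects), class = "preplay_cohort")
}

# frames-x-voxels matrix -> 4D array (x, y, z, t) with zeros off-mask
matrix_to_volume <- function(data, mask) {
  d <- dim(mask)
  vol <- array(0, dim = c(d, nrow(data)))
  idx <- which(mask)
  n_vox <- prod(d)
  for (t in seq_len(nrow(data))) {
    vol[idx + (t - 1) * n_vox] <- data[t, ]
  }
  vol
}

series_to_volume <- function(series) {
  matrix_to_volume(series$data, series$mask)
}

#' Convert a 4D volume to a resting series
#'
#' @param vol 4D numeric array `(x, y, z, frames)`.
#' @param mask Logical 3D array on the same grid.
#' @param session Session label.
#' @return A [resting_series].
#' @export
volume_to_series <- function(vol, mask, session = "rest") {
  mask <- validate_mask(mask)
  d <- dim(vol)
  if (length(d) != 4L || !identical(d[1:3], dim(mask))) {
    abort("`vol` must be 4D on the same grid as `mask`.")
  }
  m <- matrix(vol, nrow = prod(d[1:3]), ncol = d[4])
  resting_series(t(m[which(mask), , drop = FALSE]), mask, session = session)
}

write_volume <- function(vol, path, tr) {
  img <- RNifti::asNifti(vol)
  if (length(dim(vol)) == 4L) {
    RNifti::pixdim(img) <- c(1, 1, 1, tr)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
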