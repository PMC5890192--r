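# Voxelwise (searchlight) version of the intensity analysis: a cube around
# each voxel plays the role of the ROI, and a max-statistic permutation test
# corrects the condition contrast for family-wise error.

#' Voxel indices of a cube neighborhood
#'
#' All in-bounds, in-mask voxels within Chebyshev distance `radius` of
#' `center` (a `(2 radius + 1)^3` cube, truncated at volume edges).
#'
#' @param center Integer vector of 3 voxel coordinates (1-based).
#' @param radius Cube radius in voxels (default 2, a 5x5x5 cube).
#' @param shape Grid dimensions.
#' @param mask Optional logical 3D array; the center must be in-mask.
#' @return Integer vector of linear (column-major) voxel indices.
#' @export
cube_indices <- function(center, radius = 2L, shape, mask = NULL) {
  stopifnot(length(center) == 3L, length(shape) == 3L, radius >= 0)
  if (any(center < 1 | center > shape)) {
    abort("`center` is outside the volume.")
  }
  if (!is.null(mask) && !mask[center[1], center[2], center[3]]) {
    abort("`center` is outside the mask.")
  }
  rng <- lapply(1:3, function(a) {
    seq(max(1L, center[a] - radius), min(shape[a], center[a] + radius))
  })
  coords <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  idx <- coords[, 1] + (coords[, 2] - 1L) * shape[1] +
    (coords[, 3] - 1L) * shape[1] * shape[2]
  if (!is.null(mask)) {
    idx <- idx[mask[idx]]
  }
  as.integer(idx)
}

#' Searchlight map of reactivation intensity
#'
#' At every in-mask voxel, the intensity statistic is computed exactly as in
#' the ROI pipeline but over the voxel's cube neighborhood: per-frame
#' correlation between the t-map pattern and the z-scored resting frames
#' within the cube, Fisher transform, mean of the top `n_top` values. Voxels
#' whose cube retains fewer than 3 usable voxels get `NA`.
#'
#' @param rest_vol 4D array `(x, y, z, frames)` of resting data.
#' @param tmap_vols List of 3D arrays, one t-map per sentence (same grid).
#' @param mask Logical 3D array of analyzable voxels.
#' @param n_top Top frames to average (default 13).
#' @param radius Cube radius (default 2).
#' @return A list of class `searchlight_map` per sentence: 3D `intensity`
#'   array (`NA` off-mask), plus `n_top`, `radius`, `mask`.
#' @export
searchlight_intensity <- function(rest_vol, tmap_vols, mask, n_top = 13L,
                                  radius = 2L) {
  mask <- validate_mask(mask)
  shape <- dim(mask)
  stopifnot(identical(dim(rest_vol)[1:3], shape))
  n_frames <- dim(rest_vol)[4]
  n_vox <- prod(shape)
  # z-score every voxel time course once; cube membership does not affect it
  flat <- matrix(rest_vol, nrow = n_vox, ncol = n_frames)
  mu <- rowMeans(flat)
  sdv <- sqrt(rowSums((flat - mu)^2) / n_frames)
  usable <- mask & array(sdv > 1e-12, shape)
  zflat <- (flat - mu) / ifelse(sdv > 0, sdv, 1)
  centers <- which(mask)
  maps <- lapply(tmap_vols, function(tv) {
    stopifnot(identical(dim(tv), shape))
    out <- array(NA_real_, shape)
    for (cen in centers) {
      coord <- arrayInd(cen, shape)
      idx <- cube_indices(coord[1, ], radius, shape)
      idx <- idx[usable[idx]]
      if (length(idx) < 3L) next
      r <- row_correlations(t(zflat[idx, , drop = FALSE]), tv[idx])
      out[cen] <- topn_mean(fisher_z(r), n_top)
    }
    structure(
      list(intensity = out, n_top = n_top, radius = radius, mask = mask),
      class = "searchlight_map"
    )
  })
  maps
}

#' Voxelwise condition contrast with max-statistic permutation FWE
#'
#' For each subject and voxel, the correlation between per-sentence
#' searchlight intensities and ratings is computed within each condition; the
#' voxel statistic is the across-subject mean of the Fisher-transformed
#' difference (w/prior minus w/o-prior). The null distribution is built by
#' permuting condition labels across sentences within each subject, and
#' family-wise error is controlled by the permutation distribution of the
#' maximum statistic over the mask.
#'
#' @param subject_maps List over subjects; each element is a voxels-by-
#'   sentences matrix of intensities (rows = in-mask voxels in `which(mask)`
#'   order), with sentence ids as column names or in `sentence_ids` order.
#' @param ratings Tibble with columns `subject`, `sentence_id`, `rating`.
#' @param conditions Tibble with columns `subject`, `sentence_id`,
#'   `condition` (`"w_prior"` / `"wo_prior"`).
#' @param mask Logical 3D array the maps were computed on.
#' @param n_permutations Number of label permutations (default 5000).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `contrast_map`: 3D `statistic` and `p_fwe` arrays,
#'   the permutation `max_null` distribution, `n_permutations`.
#' @export
condition_contrast_map <- function(subject_maps, ratings, conditions, mask,
                                   n_permutations = 5000L, seed = NULL) {
  mask <- validate_mask(mask)
  if (length(subject_maps) < 2L) {
    abort("need at least 2 subjects.")
  }
  if (n_permutations < 1L) {
    abort("`n_permutations` must be positive.")
  }
  subjects <- names(subject_maps) %||% as.character(seq_along(subject_maps))
  names(subject_maps) <- subjects
  # pre-extract each subject's ratings and labels in column order
  sub_info <- lapply(subjects, function(s) {
    m <- subject_maps[[s]]
    ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
    rt <- ratings[ratings$subject == as_subject(s, ratings$subject), ]
    cd <- conditions[conditions$subject == as_subject(s, conditions$subject), ]
    rating <- rt$rating[match(ids, as.character(rt$sentence_id))]
    label <- cd$condition[match(ids, as.character(cd$sentence_id))]
    if (anyNA(rating) || anyNA(label)) {
      abort(sprintf("missing ratings or condition labels for subject %s.", s))
    }
    list(m = m, rating = rating, label = label)
  })
  stat_for <- function(labels_list) {
    acc <- 0
    for (i in seq_along(sub_info)) {
      si <- sub_info[[i]]
      lab <- labels_list[[i]]
      rw <- row_correlations(si$m[, lab == "w_prior", drop = FALSE],
        si$rating[lab == "w_prior"]
      )
      ro <- row_correlations(si$m[, lab == "wo_prior", drop = FALSE],
        si$rating[lab == "wo_prior"]
      )
      acc <- acc + (fisher_z(rw) - fisher_z(ro))
    }
    acc / length(sub_info)
  }
  observed <- stat_for(lapply(sub_info, `[[`, "label"))
  max_null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm <- lapply(sub_info, function(si) sample(si$label))
      max(stat_for(perm), na.rm = TRUE)
    }, numeric(1))
  })
  p_fwe <- vapply(
    observed,
    function(s) {
      if (is.na(s)) NA_real_ else (1 + sum(max_null >= s)) / (1 + n_permutations)
    },
    numeric(1)
  )
  to_vol <- function(v) {
    out <- array(NA_real_, dim(mask))
    out[which(mask)] <- v
    out
  }
  structure(
    list(
      statistic = to_vol(observed),
      p_fwe = to_vol(p_fwe),
      max_null = max_null,
      n_permutations = n_permutations,
      mask = mask
    ),
    class = "contrast_map"
  )
}

# Coerce a subject key to the type used in a reference column, so string
# names of list elements can match integer subject ids.
as_subject <- function(s, ref) {
  if (is.numeric(ref)) as.numeric(s) else as.character(s)
}

#' @export
print.contrast_map <- function(x, ...) {
  n_sig <- sum(x$p_fwe <= 0.05, na.rm = TRUE)
  cat(sprintf(
    "<contrast_map> %d in-mask voxels, %d permutations, %d voxels with p_fwe <= 0.05\n",
    sum(x$mask), x$n_permutations, n_sig
  ))
  invisible(x)
}

#' Flatten searchlight maps into a voxels-by-sentences matrix
#'
#' Helper to assemble the input of [condition_contrast_map()] from
#' [searchlight_intensity()] output.
#'
#' @param maps List of `searchlight_map` objects (one per sentence).
#' @param sentence_ids Column names to assign.
#' @return Matrix with one row per in-mask voxel, one column per sentence.
#' @export
searchlight_matrix <- function(maps, sentence_ids = NULL) {
  mask <- maps[[1]]$mask
  m <- vapply(maps, function(sm) sm$intensity[which(mask)], numeric(sum(mask)))
  colnames(m) <- sentence_ids %||% as.character(seq_along(maps))
  m
}
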