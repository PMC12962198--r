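# ROI management: FreeSurfer-style integer label volumes with a lookup table,
# bilateral merging, composite regions, ventricular exclusion, common-ROI
# intersection across subjects, and ROI-level averaging of maps and spectra.

#' Integer anatomical label volume
#'
#' @param labels 3D integer array; 0 is background.
#' @param lut data.frame with columns `label_id`, `name`, `hemisphere`
#'   (`"left"`, `"right"` or `"none"`); every nonzero label in the volume
#'   must be present.
#' @param affine 4x4 voxel-to-world matrix.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, lut, affine = diag(4)) {
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, lut$label_id)
  if (length(missing)) {
    stop("labels missing from the lookup table: ", paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, lut = lut, affine = affine),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> grid %s, %d labels, %d foreground voxels\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$lut),
              sum(x$labels > 0)))
  invisible(x)
}

#' Read / write label volumes with TSV lookup tables
#'
#' The lookup table is a tab-separated file with columns `label_id`, `name`,
#' `hemisphere`, compatible with FreeSurfer color-table naming so that real
#' aseg/aparc outputs are drop-in replacements for phantom labels.
#'
#' @param labels_path NIfTI path for the integer labels.
#' @param lut_path TSV path for the lookup table.
#' @return `read_label_volume` returns a `label_volume`.
#' @export
read_label_volume <- function(labels_path, lut_path) {
  img <- RNifti::readNifti(labels_path)
  labels <- array(as.integer(round(img)), dim(img))
  lut <- utils::read.delim(lut_path, stringsAsFactors = FALSE)
  affine <- structure(RNifti::xform(img), dimnames = NULL)
  label_volume(labels, lut, affine)
}

#' @rdname read_label_volume
#' @param vol a `label_volume`.
#' @export
write_label_volume <- function(vol, labels_path, lut_path) {
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- abs(diag(vol$affine)[1:3])
  RNifti::writeNifti(img, labels_path)
  utils::write.table(vol$lut, lut_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(labels_path)
}

#' ROI set: named regions as sets of label ids
#'
#' @param definitions named list; each element an integer vector of label ids.
#' @param provenance character vector (recycled): `"atomic"`,
#'   `"bilateral-merged"` or `"composite"`.
#' @param n_voxels optional named integer vector of per-ROI voxel counts
#'   (filled by [roi_voxel_counts()]).
#' @return object of class `roi_set`.
#' @export
roi_set <- function(definitions, provenance = "atomic", n_voxels = NULL) {
  stopifnot(!is.null(names(definitions)), all(nzchar(names(definitions))))
  provenance <- rep_len(provenance, length(definitions))
  names(provenance) <- names(definitions)
  structure(list(definitions = definitions, provenance = provenance,
                 n_voxels = n_voxels),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs (%s)\n", length(x$definitions),
              paste(names(table(x$provenance)), table(x$provenance),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Atomic ROI set from a lookup table: one ROI per label
#' @param lut a label lookup table data.frame.
#' @return a `roi_set`.
#' @export
roiset_from_lut <- function(lut) {
  defs <- as.list(lut$label_id)
  names(defs) <- lut$name
  roi_set(defs, "atomic")
}

# strip the hemisphere marker from a FreeSurfer-style name
base_roi_name <- function(name) {
  out <- sub("^(Left|Right)-", "", name)
  out <- sub("^ctx-(lh|rh)-", "ctx-", out)
  sub("^wm-(lh|rh)-", "wm-", out)
}

#' Merge bilateral ROIs
#'
#' Left/right ROI pairs sharing a base name are merged into a single ROI whose
#' label set is the union of both hemispheres ("pooled voxels": the mean over
#' the merged ROI weights each hemisphere by its voxel count). Unpaired ROIs
#' pass through unchanged.
#'
#' @param roiset a `roi_set` of atomic ROIs.
#' @param lut the lookup table with hemisphere annotations.
#' @return a `roi_set` with merged definitions.
#' @export
merge_bilateral <- function(roiset, lut) {
  hemi <- lut$hemisphere[match(names(roiset$definitions), lut$name)]
  base <- base_roi_name(names(roiset$definitions))
  defs <- list(); prov <- character(0)
  for (b in unique(base)) {
    members <- which(base == b)
    if (length(members) == 1L) {
      defs[[names(roiset$definitions)[members]]] <- roiset$definitions[[members]]
      prov <- c(prov, roiset$provenance[members])
    } else {
      h <- hemi[members]
      if (anyNA(h) || any(h == "none")) {
        stop("hemisphere annotation missing for paired ROI name: ", b)
      }
      defs[[b]] <- sort(unique(unlist(roiset$definitions[members])))
      prov <- c(prov, "bilateral-merged")
    }
  }
  roi_set(defs, prov)
}

#' Default composite AD regions
#'
#' Medial temporal lobe (hippocampus, parahippocampal gyrus, entorhinal
#' cortex), lateral temporal lobe (middle/superior/inferior temporal gyri),
#' lateral parietal lobe (superior/inferior parietal lobules), and medial
#' parietal lobes (precuneus and posterior cingulate). Constituent names are
#' matched against the (bilateral-merged) ROI names actually present.
#' @return named list of character vectors of constituent ROI names.
#' @export
default_composites <- function() {
  list(
    "medial-temporal-lobe" = c("Hippocampus", "ctx-parahippocampal", "ctx-entorhinal"),
    "lateral-temporal-lobe" = c("ctx-middletemporal", "ctx-superiortemporal",
                                "ctx-inferiortemporal"),
    "lateral-parietal-lobe" = c("ctx-superiorparietal", "ctx-inferiorparietal"),
    "medial-parietal-lobe" = c("ctx-precuneus", "ctx-posteriorcingulate")
  )
}

#' Add composite ROIs to a set
#'
#' Each composite is the set union of its constituent ROIs' label ids
#' (overlapping labels counted once); constituents are retained. Composites
#' with constituents entirely absent from the set raise a config error
#' listing the gap; with `partial = TRUE` a composite is built from the
#' constituents that are present (skipped if none are).
#'
#' @param roiset a `roi_set`.
#' @param composite_config named list mapping composite name to constituent
#'   ROI names (default [default_composites()]); an empty list is a no-op.
#' @param partial build partial composites instead of erroring (default FALSE).
#' @return a `roi_set` including the composites.
#' @export
build_composites <- function(roiset, composite_config = default_composites(),
                             partial = FALSE) {
  if (!length(composite_config)) return(roiset)
  defs <- roiset$definitions
  prov <- roiset$provenance
  for (comp in names(composite_config)) {
    members <- composite_config[[comp]]
    present <- members[members %in% names(defs)]
    missing <- setdiff(members, present)
    if (length(missing) && !partial) {
      stop(sprintf("composite '%s' missing constituents: %s", comp,
                   paste(missing, collapse = ", ")))
    }
    if (!length(present)) next
    defs[[comp]] <- sort(unique(unlist(defs[present])))
    prov[comp] <- "composite"
  }
  roi_set(defs, prov)
}

#' Default exclusion list: ventricular system and CSF labels
#' @return character vector of ROI names.
#' @export
default_exclusions <- function() {
  c("Lateral-Ventricle", "Left-Lateral-Ventricle", "Right-Lateral-Ventricle",
    "Inf-Lat-Vent", "Left-Inf-Lat-Vent", "Right-Inf-Lat-Vent",
    "3rd-Ventricle", "4th-Ventricle", "5th-Ventricle", "CSF",
    "Left-choroid-plexus", "Right-choroid-plexus", "choroid-plexus")
}

#' Remove named ROIs from a set
#'
#' @param roiset a `roi_set`.
#' @param exclusion_names ROI names to drop (default the ventricular system);
#'   unknown names are ignored.
#' @return the reduced `roi_set`.
#' @export
exclude_rois <- function(roiset, exclusion_names = default_exclusions()) {
  keep <- !(names(roiset$definitions) %in% exclusion_names)
  roi_set(roiset$definitions[keep], roiset$provenance[keep])
}

#' Per-ROI voxel counts against a label volume
#' @param roiset a `roi_set`.
#' @param labels a `label_volume`.
#' @return the `roi_set` with `n_voxels` filled in.
#' @export
roi_voxel_counts <- function(roiset, labels) {
  tab <- table(factor(labels$labels[labels$labels > 0]))
  counts <- vapply(roiset$definitions, function(ids) {
    sum(tab[as.character(ids)], na.rm = TRUE)
  }, numeric(1))
  roiset$n_voxels <- counts
  roiset
}

#' Intersect ROI sets across subjects
#'
#' Only ROIs present by name in every subject's set, with at least
#' `min_voxels` voxels in every subject, are retained (partial-coverage
#' acquisitions leave different regions visible in different subjects).
#'
#' @param per_subject_roisets list of `roi_set` objects with `n_voxels` set
#'   (see [roi_voxel_counts()]).
#' @param min_voxels minimum per-subject voxel count (default 1).
#' @return the common `roi_set` (definitions from the first subject).
#' @export
common_rois <- function(per_subject_roisets, min_voxels = 1) {
  stopifnot(length(per_subject_roisets) >= 1)
  name_sets <- lapply(per_subject_roisets, function(rs) {
    nm <- names(rs$definitions)
    if (!is.null(rs$n_voxels)) nm <- nm[rs$n_voxels[nm] >= min_voxels]
    nm
  })
  common <- Reduce(intersect, name_sets)
  if (!length(common)) stop("no ROIs common to all subjects")
  first <- per_subject_roisets[[1]]
  roi_set(first$definitions[common], first$provenance[common])
}

#' ROI-averaged values of a map
#'
#' Arithmetic mean of the map over the valid voxels in each ROI's label set
#' (pooled across hemispheres/constituents). ROIs with zero valid voxels are
#' omitted with a warning.
#'
#' @param map an `asym_map` (or any list with `map` and `valid` 3D arrays).
#' @param roiset a `roi_set`.
#' @param labels a `label_volume` on the same grid.
#' @param subject_id,group,metric_name metadata stamped on each row.
#' @return data.frame with columns `subject_id`, `group`, `roi_name`,
#'   `metric_name`, `value`, `n_voxels`.
#' @export
roi_mean_map <- function(map, roiset, labels, subject_id = "subject",
                         group = NA_character_, metric_name = "metric") {
  if (!identical(dim(map$map), dim(labels$labels))) {
    stop("geometry mismatch between map and label volume")
  }
  rows <- lapply(names(roiset$definitions), function(nm) {
    sel <- labels$labels %in% roiset$definitions[[nm]] & map$valid
    n <- sum(sel)
    if (n == 0L) {
      warning(sprintf("ROI '%s' has no valid voxels; omitted", nm))
      return(NULL)
    }
    data.frame(subject_id = subject_id, group = group, roi_name = nm,
               metric_name = metric_name, value = mean(map$map[sel]),
               n_voxels = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' ROI-averaged B0-corrected Z-spectra
#'
#' Offset-wise mean of the per-voxel B0-corrected spectra over each ROI's
#' valid voxels, evaluated at the sampled offsets (each voxel's corrected
#' sample value is its dense interpolant read at `offset + shift`; samples
#' shifted outside the sampled span are dropped from the average). Averaging
#' N voxels boosts the effective SNR by about sqrt(N), which is what makes
#' ROI-level multi-pool fitting stable where voxel-wise fitting is not.
#'
#' @param zvol a `zvolume`.
#' @param roiset a `roi_set`.
#' @param labels a `label_volume` on the same grid.
#' @param b0 a `b0_map` from [compute_b0_map()].
#' @return named list of B0-corrected `zspectrum` objects (with the ROI's
#'   voxel count as attribute `n_voxels`); empty ROIs omitted with a warning.
#' @export
roi_mean_zspectrum <- function(zvol, roiset, labels, b0) {
  if (!identical(dim(zvol$valid), dim(labels$labels))) {
    stop("geometry mismatch between Z-volume and label volume")
  }
  step <- b0$grid_step
  dm <- dense_voxel_matrix(zvol, step)
  grid <- dm$grid
  n_grid <- length(grid)
  offs <- zvol$axis$offsets
  base_idx <- round((offs - grid[1]) / step) + 1
  shift_idx <- round(b0$shift[dm$idx] / step)
  out <- list()
  for (nm in names(roiset$definitions)) {
    cols <- which(labels$labels[dm$idx] %in% roiset$definitions[[nm]])
    if (!length(cols)) {
      warning(sprintf("ROI '%s' has no valid voxels; omitted", nm))
      next
    }
    acc <- matrix(NA_real_, length(cols), length(offs))
    for (ci in seq_along(cols)) {
      rows <- base_idx + shift_idx[cols[ci]]
      ok <- rows >= 1 & rows <= n_grid
      acc[ci, ok] <- dm$dense[rows[ok], cols[ci]]
    }
    zbar <- colMeans(acc, na.rm = TRUE)
    zbar[!is.finite(zbar)] <- NA_real_
    zs <- zspectrum(zbar, offs, zvol$axis$reference_offset,
                    b0_shift = mean(b0$shift[dm$idx][cols]))
    attr(zs, "n_voxels") <- length(cols)
    out[[nm]] <- zs
  }
  out
}

#' Write an ROI table as TSV
#' @param table data.frame of ROI rows.
#' @param path output TSV path.
#' @export
write_roi_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
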