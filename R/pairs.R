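#' Pair colocalized presynaptic and postsynaptic 3D objects
#'
#' One-to-one matching of segmented ribbon (CtBP2) objects to receptor
#' (GluA2) objects. Candidate pairs overlapping by at least one voxel are
#' matched greedily by descending voxel overlap; remaining objects are then
#' matched greedily by ascending centroid distance up to `radius_um`.
#' Unmatched objects are reported as orphans.
#'
#' @param ribbons,receptors `"segmentation"` results from [segment_objects()]
#'   on the two synaptic channels of the same field (same grid shape).
#' @param radius_um centroid-distance fallback radius in um (default 1.0).
#' @return list of class `"synaptic_pairs"`: `pairs` (data.frame:
#'   ribbon_label, receptor_label, ctbp2_volume_um3, glua2_volume_um3,
#'   overlap_vox, distance_um), `orphan_ribbons`, `orphan_receptors`
#'   (integer label vectors).
#' @export
pair_synapses <- function(ribbons, receptors, radius_um = 1.0) {
  abort_if(!inherits(ribbons, "segmentation") ||
             !inherits(receptors, "segmentation"),
           "`ribbons` and `receptors` must be segmentation results")
  abort_if(!identical(dim(ribbons$labels), dim(receptors$labels)),
           "segmentations are not on the same voxel grid")
  check_scalar_pos(radius_um, "radius_um")

  rib <- ribbons$objects
  rec <- receptors$objects
  empty <- data.frame(ribbon_label = integer(), receptor_label = integer(),
                      ctbp2_volume_um3 = numeric(),
                      glua2_volume_um3 = numeric(),
                      overlap_vox = integer(), distance_um = numeric())
  result <- function(pairs) {
    structure(list(
      pairs = pairs,
      orphan_ribbons = setdiff(rib$label, pairs$ribbon_label),
      orphan_receptors = setdiff(rec$label, pairs$receptor_label)),
      class = "synaptic_pairs")
  }
  if (nrow(rib) == 0 || nrow(rec) == 0) return(result(empty))

  # voxel overlaps between label pairs
  both <- which(ribbons$labels > 0 & receptors$labels > 0)
  cand <- if (length(both)) {
    ov <- table(ribbons$labels[both], receptors$labels[both])
    df <- as.data.frame(ov, stringsAsFactors = FALSE)
    names(df) <- c("ribbon_label", "receptor_label", "overlap_vox")
    df$ribbon_label <- as.integer(df$ribbon_label)
    df$receptor_label <- as.integer(df$receptor_label)
    df[df$overlap_vox > 0, , drop = FALSE]
  } else {
    data.frame(ribbon_label = integer(), receptor_label = integer(),
               overlap_vox = integer())
  }

  used_rib <- integer(0); used_rec <- integer(0)
  rows <- list()
  add_pair <- function(rl, gl, overlap, dist) {
    ri <- rib[rib$label == rl, ]; gi <- rec[rec$label == gl, ]
    data.frame(ribbon_label = rl, receptor_label = gl,
               ctbp2_volume_um3 = ri$volume_um3,
               glua2_volume_um3 = gi$volume_um3,
               overlap_vox = as.integer(overlap), distance_um = dist)
  }

  if (nrow(cand)) {
    cand <- cand[order(-cand$overlap_vox, cand$ribbon_label,
                       cand$receptor_label), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      rl <- cand$ribbon_label[i]; gl <- cand$receptor_label[i]
      if (rl %in% used_rib || gl %in% used_rec) next
      ri <- rib[rib$label == rl, ]; gi <- rec[rec$label == gl, ]
      dist <- sqrt((ri$cx_um - gi$cx_um)^2 + (ri$cy_um - gi$cy_um)^2 +
                     (ri$cz_um - gi$cz_um)^2)
      rows[[length(rows) + 1L]] <- add_pair(rl, gl, cand$overlap_vox[i], dist)
      used_rib <- c(used_rib, rl); used_rec <- c(used_rec, gl)
    }
  }

  # centroid-distance fallback for the remainder
  free_rib <- setdiff(rib$label, used_rib)
  free_rec <- setdiff(rec$label, used_rec)
  if (length(free_rib) && length(free_rec)) {
    ri <- rib[match(free_rib, rib$label), ]
    gi <- rec[match(free_rec, rec$label), ]
    dmat <- outer(seq_along(free_rib), seq_along(free_rec),
                  function(i, j) sqrt((ri$cx_um[i] - gi$cx_um[j])^2 +
                                        (ri$cy_um[i] - gi$cy_um[j])^2 +
                                        (ri$cz_um[i] - gi$cz_um[j])^2))
    ok <- which(dmat <= radius_um, arr.ind = TRUE)
    if (nrow(ok)) {
      ok <- ok[order(dmat[ok]), , drop = FALSE]
      taken_i <- logical(length(free_rib)); taken_j <- logical(length(free_rec))
      for (r in seq_len(nrow(ok))) {
        i <- ok[r, 1]; j <- ok[r, 2]
        if (taken_i[i] || taken_j[j]) next
        rows[[length(rows) + 1L]] <-
          add_pair(free_rib[i], free_rec[j], 0L, dmat[i, j])
        taken_i[i] <- TRUE; taken_j[j] <- TRUE
      }
    }
  }

  pairs <- if (length(rows)) do.call(rbind, rows) else empty
  result(pairs)
}

#' @export
print.synaptic_pairs <- function(x, ...) {
  cat(sprintf("Synaptic pairs: %d matched, %d orphan ribbons, %d orphan receptors\n",
              nrow(x$pairs), length(x$orphan_ribbons),
              length(x$orphan_receptors)))
  invisible(x)
}

#' Volumetric synapse analysis of a confocal stack
#'
#' Convenience pipeline for the volumetric branch: Richardson-Lucy
#' deconvolution per channel, 3D segmentation with the voxel-size gate (and
#' per-object half-max refinement), and pre/post object pairing.
#'
#' @param stack a `"confocal_stack"`.
#' @param psf PSF used for deconvolution.
#' @param n_iter Richardson-Lucy iterations (default 10).
#' @param cfg a [segmentation_config()]; its `voxel_dims` default is replaced
#'   by the stack's.
#' @param radius_um pairing fallback radius (default 1.0 um).
#' @return list: `ribbons`, `receptors` (segmentations), `pairs`
#'   (`"synaptic_pairs"`).
#' @export
measure_synapse_volumes <- function(stack, psf = make_psf(), n_iter = 10,
                                    cfg = NULL, radius_um = 1.0) {
  abort_if(!inherits(stack, "confocal_stack"),
           "`stack` must be a confocal_stack")
  if (is.null(cfg)) cfg <- segmentation_config(voxel_dims = stack$voxel_dims)
  seg <- lapply(c(ribbon = "ribbon", receptor = "receptor"), function(ch) {
    dec <- richardson_lucy(stack$channels[[ch]], psf, n_iter = n_iter)
    segment_objects(dec, cfg, channel = ch)
  })
  list(ribbons = seg$ribbon, receptors = seg$receptor,
       pairs = pair_synapses(seg$ribbon, seg$receptor, radius_um = radius_um))
}
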