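#' Motion-compensated adaptive reconstruction
#'
#' The full adaptive chain: McKinnon-Bates frames, deformable registration of
#' every frame to the reference phase (peak inhale by default), averaging of
#' the warped frames into the reference-phase image, and synthesis of the
#' remaining frames by warping the reference image with the inverted
#' displacement fields. The reference-phase image is the mean (not the bare
#' sum) of the warped frames, which preserves the attenuation scale. A failed
#' registration falls back to an identity field for that bin with a warning
#' (that frame then contributes blur rather than an error).
#'
#' @param d a [projection_set] with bin labels, every bin populated.
#' @param n_bins number of respiratory bins.
#' @param cfg a [reg_config]; `cfg$reference_bin` selects the reference phase.
#' @param grid reconstruction [grid_spec].
#' @return list with `adaptive` ([image4d]), `mkb` ([image4d]), `fdk`
#'   ([volume3d]), `fdk4d` ([image4d]), `dvfs` (list of [dvf], reference bin
#'   holds the zero field) and `failed_bins` (integer vector).
#' @export
adaptive_reconstruct <- function(d, n_bins, cfg = reg_config(), grid) {
  mk <- mkb_reconstruct(d, n_bins, grid)
  r <- cfg$reference_bin
  if (r < 1 || r > n_bins) stop("reference bin out of range")
  ref <- mk$mkb$frames[[r]]
  dvfs <- vector("list", n_bins)
  failed <- integer(0)
  for (j in seq_len(n_bins)) {
    if (j == r) {
      dvfs[[j]] <- zero_dvf(vol_grid(ref), source_bin = j, target_bin = r)
      next
    }
    Vj <- tryCatch(register_deformable(mk$mkb$frames[[j]], ref, cfg),
                   error = function(e) {
                     warning(sprintf("registration of bin %d failed (%s); using identity field",
                                     j, conditionMessage(e)))
                     NULL
                   })
    if (is.null(Vj)) {
      failed <- c(failed, j)
      Vj <- zero_dvf(vol_grid(ref))
    }
    Vj$source_bin <- j; Vj$target_bin <- r
    dvfs[[j]] <- Vj
  }
  warped <- lapply(seq_len(n_bins), function(j)
    if (j == r) ref else warp_volume(mk$mkb$frames[[j]], dvfs[[j]],
                                     interp = "cubic"))
  x_ref <- volume3d(Reduce(`+`, lapply(warped, `[[`, "data")) / n_bins,
                    grid$spacing, grid$origin)
  frames <- vector("list", n_bins)
  for (j in seq_len(n_bins)) {
    frames[[j]] <- if (j == r) x_ref else
      warp_volume(x_ref, invert_dvf(dvfs[[j]]), interp = "cubic")
  }
  list(adaptive = image4d(frames, seq_len(n_bins)), mkb = mk$mkb,
       fdk = mk$fdk, fdk4d = mk$fdk4d, dvfs = dvfs, failed_bins = failed)
}
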