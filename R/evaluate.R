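#' Compare a segmentation against synthetic ground truth
#'
#' Matches every true fiber to the predicted label with the largest pixel
#' overlap and reports detection recall (fraction of true fibers whose best
#' match reaches `iou_threshold`), the mean intersection-over-union of
#' detected fibers, and the mean absolute relative CSA error over detected
#' fibers.
#'
#' @param pred_labels predicted label map (pipeline output).
#' @param truth the `truth` element of [generate_section()], or any list
#'   with a `labels` raster.
#' @param pixel_size_um calibration used for the CSA comparison.
#' @param iou_threshold IoU above which a true fiber counts as detected
#'   (default 0.5).
#' @return List with `recall`, `mean_iou`, `csa_err_pct`, `n_truth`,
#'   `n_pred`, and a per-fiber data.frame `matches` (`truth_id`, `pred_id`,
#'   `iou`, `truth_csa_um2`, `pred_csa_um2`, `detected`).
#' @export
evaluate_segmentation <- function(pred_labels, truth, pixel_size_um = 0.647,
                                  iou_threshold = 0.5) {
  tl <- truth$labels
  stopifnot(identical(dim(tl), dim(pred_labels)))
  nt <- max(0L, max(tl))
  np <- max(0L, max(pred_labels))
  s2 <- pixel_size_um^2
  t_size <- tabulate(tl[tl > 0L], nt)
  p_size <- tabulate(pred_labels[pred_labels > 0L], np)
  best_pred <- rep(NA_integer_, nt)
  best_iou <- numeric(nt)
  if (nt > 0L && np > 0L) {
    both <- tl > 0L & pred_labels > 0L
    key <- (as.numeric(tl[both]) - 1) * np + as.numeric(pred_labels[both])
    ov <- tabulate(key, nt * np)
    nz <- which(ov > 0L)
    tid <- ((nz - 1L) %/% np) + 1L
    pid <- ((nz - 1L) %% np) + 1L
    inter <- ov[nz]
    iou <- inter / (t_size[tid] + p_size[pid] - inter)
    o <- order(tid, -iou)
    first <- !duplicated(tid[o])
    best_pred[tid[o][first]] <- pid[o][first]
    best_iou[tid[o][first]] <- iou[o][first]
  }
  detected <- best_iou >= iou_threshold
  matches <- data.frame(
    truth_id = seq_len(nt),
    pred_id = best_pred,
    iou = best_iou,
    truth_csa_um2 = t_size * s2,
    pred_csa_um2 = ifelse(is.na(best_pred), NA_real_, p_size[pmax(best_pred, 1L)] * s2),
    detected = detected
  )
  err <- abs(matches$pred_csa_um2 - matches$truth_csa_um2) / matches$truth_csa_um2
  list(
    recall = if (nt) mean(detected) else NA_real_,
    mean_iou = if (any(detected)) mean(best_iou[detected]) else NA_real_,
    csa_err_pct = if (any(detected)) 100 * mean(err[detected]) else NA_real_,
    n_truth = nt, n_pred = np,
    matches = matches
  )
}
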