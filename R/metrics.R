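#' Boundary pixels of a binary mask
#'
#' A mask pixel is a boundary point if any 4-neighbor lies outside the mask
#' (image borders count as outside).
#'
#' @param mask binary matrix.
#' @return Two-column matrix of (row, col) boundary coordinates.
#' @export
boundary_points <- function(mask) {
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}

#' Symmetric Hausdorff distance between two masks
#'
#' Classical sup-inf form on Euclidean distances between boundary pixels.
#' Both masks empty gives 0; exactly one empty gives `Inf`.
#'
#' @param mask_a,mask_b binary matrices of equal shape.
#' @return Nonnegative scalar (pixels).
#' @export
hausdorff_distance <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  S <- boundary_points(mask_a)
  T_ <- boundary_points(mask_b)
  if (nrow(S) == 0 && nrow(T_) == 0) return(0)
  if (nrow(S) == 0 || nrow(T_) == 0) return(Inf)
  D2 <- outer(S[, 1L], T_[, 1L], `-`)^2 + outer(S[, 2L], T_[, 2L], `-`)^2
  max(sqrt(max(apply(D2, 1L, min))), sqrt(max(apply(D2, 2L, min))))
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification and segmentation metrics
#'
#' Classification metrics come from the tile-label confusion counts
#' (metastatic = positive class): accuracy, precision, recall,
#' F1 = TP / (TP + (FP + FN)/2). Segmentation metrics aggregate pixel
#' confusion counts over tiles: Dice 2TP/(2TP+FP+FN) (plus the nonstandard
#' variant `dsc_as_printed` = 2TP/(TP+FP+TN+FN), reported for transparency
#' even though it can exceed 1), IoU TP/(TP+FP+FN), MAE of per-tile
#' positive-area fractions, and the mean symmetric Hausdorff distance over
#' tiles where both boundaries exist. `iou_positive` restricts the pixel
#' confusion to tiles with a nonempty ground-truth mask.
#'
#' @param pred_labels,true_labels binary tile labels.
#' @param pred_masks,gt_masks optional lists of binary masks (same length).
#' @return List of class `metrics_record`.
#' @export
compute_metrics <- function(pred_labels, true_labels,
                            pred_masks = NULL, gt_masks = NULL) {
  if (!length(pred_labels) || length(pred_labels) != length(true_labels)) {
    stop("label vectors must be nonempty and aligned")
  }
  tp <- sum(pred_labels == 1 & true_labels == 1)
  fp <- sum(pred_labels == 1 & true_labels == 0)
  tn <- sum(pred_labels == 0 & true_labels == 0)
  fn <- sum(pred_labels == 0 & true_labels == 1)
  out <- list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = safe_ratio(tp, tp + fp),
    recall = safe_ratio(tp, tp + fn),
    f1 = safe_ratio(tp, tp + (fp + fn) / 2)
  )
  if (!is.null(pred_masks)) {
    stopifnot(length(pred_masks) == length(gt_masks),
              length(pred_masks) == length(pred_labels))
    ptp <- pfp <- ptn <- pfn <- 0
    ptp_pos <- pfp_pos <- pfn_pos <- 0
    mae_terms <- hd_terms <- numeric(0)
    for (i in seq_along(pred_masks)) {
      pm <- pred_masks[[i]] > 0
      gm <- gt_masks[[i]] > 0
      a <- sum(pm & gm); b <- sum(pm & !gm); c <- sum(!pm & !gm); d <- sum(!pm & gm)
      ptp <- ptp + a; pfp <- pfp + b; ptn <- ptn + c; pfn <- pfn + d
      if (any(gm)) {
        ptp_pos <- ptp_pos + a; pfp_pos <- pfp_pos + b; pfn_pos <- pfn_pos + d
      }
      mae_terms <- c(mae_terms, abs(mean(pm) - mean(gm)))
      hd <- hausdorff_distance(pm, gm)
      if (is.finite(hd) && (any(pm) || any(gm))) hd_terms <- c(hd_terms, hd)
    }
    out$pixel_confusion <- c(TP = ptp, FP = pfp, TN = ptn, FN = pfn)
    out$dsc <- safe_ratio(2 * ptp, 2 * ptp + pfp + pfn)
    out$dsc_as_printed <- safe_ratio(2 * ptp, ptp + pfp + ptn + pfn)
    out$iou <- safe_ratio(ptp, ptp + pfp + pfn)
    out$iou_positive <- safe_ratio(ptp_pos, ptp_pos + pfp_pos + pfn_pos)
    out$mae <- mean(mae_terms)
    out$hd <- if (length(hd_terms)) mean(hd_terms) else NA_real_
  }
  structure(out, class = "metrics_record")
}
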