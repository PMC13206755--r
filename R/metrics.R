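# Evaluation metrics: Dice similarity coefficient, percentile-bootstrap
# confidence intervals, 95th-percentile Hausdorff distance and average
# surface distance on boundary point sets, and dataset-level reports.

as_binary_mask <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 2) stopf("expected a 2-D mask")
  x != 0 & !is.na(x)
}

#' Dice similarity coefficient
#'
#' `2TP / (2TP + FP + FN)` on pixels. Two empty regions score 1 (perfect
#' agreement on absence); exactly one empty region scores 0.
#'
#' @param pred,gt binary maps (logical or 0/1) of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(pred, gt) {
  pred <- as_binary_mask(pred); gt <- as_binary_mask(gt)
  if (!all(dim(pred) == dim(gt))) stopf("dsc: shape mismatch")
  tp <- sum(pred & gt)
  sp <- sum(pred); sg <- sum(gt)
  if (sp == 0 && sg == 0) return(1)
  if (sp == 0 || sg == 0) return(0)
  2 * tp / (sp + sg)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `reps` times, records each
#' resample mean and returns the percentile interval of the bootstrap
#' distribution (2.5th/97.5th percentiles at the default level).
#'
#' @param values numeric vector (e.g. per-image DSC).
#' @param reps number of bootstrap resamples (default 10,000).
#' @param level confidence level.
#' @param seed optional seed for a deterministic interval; the caller's RNG
#'   state is preserved.
#' @return named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, reps = 10000, level = 0.95, seed = NULL) {
  if (!length(values)) stopf("bootstrap_ci: empty value list")
  stopifnot(reps >= 1)
  n <- length(values)
  means <- with_seed(seed, {
    idx <- sample.int(n, n * reps, replace = TRUE)
    .rowMeans(matrix(values[idx], reps, n, byrow = TRUE), reps, n)
  })
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Boundary pixels of a binary region
#'
#' A region pixel is a boundary pixel if any 4-neighbor lies outside the
#' region or off the image.
#'
#' @param mask binary map.
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
boundary_points <- function(mask) {
  m <- as_binary_mask(mask)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  b <- m & !interior
  which(b, arr.ind = TRUE)
}

# nearest-rank percentile: ceil(p * n)-th order statistic
nearest_rank <- function(x, p) {
  n <- length(x)
  sort(x, partial = max(1, ceiling(p * n)))[max(1, ceiling(p * n))]
}

min_dists <- function(A, B) {
  # for each row of A, the minimum Euclidean distance to rows of B
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Directional 95th-percentile Hausdorff distance
#'
#' For each point of `A`, the minimum Euclidean distance to `B`; returns the
#' nearest-rank 95th percentile of those minima.
#'
#' @param A,B point sets: matrices with columns (row, col); both non-empty.
#' @param p percentile in (0, 1].
#' @return non-negative scalar.
#' @export
directional_h95 <- function(A, B, p = 0.95) {
  if (!nrow(A) || !nrow(B)) stopf("directional_h95: empty point set")
  nearest_rank(min_dists(A, B), p)
}

empty_sentinel <- function(mask) sqrt(nrow(mask)^2 + ncol(mask)^2)

surface_sets <- function(pred, gt, boundary = TRUE) {
  if (!all(dim(pred) == dim(gt))) stopf("shape mismatch")
  if (boundary) list(A = boundary_points(pred), B = boundary_points(gt))
  else list(A = which(as_binary_mask(pred), arr.ind = TRUE),
            B = which(as_binary_mask(gt), arr.ind = TRUE))
}

#' 95th-percentile Hausdorff distance between two regions
#'
#' The maximum of the two directional 95th-percentile distances between the
#' boundary point sets of prediction and ground truth. If exactly one region
#' is empty, the image diagonal is returned with attribute `empty = TRUE`;
#' two empty regions give 0.
#'
#' @param pred,gt binary maps of identical shape.
#' @param boundary use boundary point sets (default) or filled regions.
#' @return non-negative scalar (attribute `empty` flags the sentinel case).
#' @export
hd95 <- function(pred, gt, boundary = TRUE) {
  s <- surface_sets(pred, gt, boundary)
  ea <- nrow(s$A) == 0; eb <- nrow(s$B) == 0
  if (ea && eb) return(0)
  if (ea || eb) return(structure(empty_sentinel(pred), empty = TRUE))
  max(directional_h95(s$A, s$B), directional_h95(s$B, s$A))
}

#' Average surface distance
#'
#' Mean over prediction-boundary points of the minimum distance to the
#' ground-truth boundary (one-directional, prediction to truth, as printed;
#' `symmetric = TRUE` averages both directions). Empty-region policy as in
#' [hd95()].
#'
#' @param pred,gt binary maps of identical shape.
#' @param boundary use boundary point sets (default) or filled regions.
#' @param symmetric also average the truth-to-prediction direction.
#' @return non-negative scalar.
#' @export
asd <- function(pred, gt, boundary = TRUE, symmetric = FALSE) {
  s <- surface_sets(pred, gt, boundary)
  ea <- nrow(s$A) == 0; eb <- nrow(s$B) == 0
  if (ea && eb) return(0)
  if (ea || eb) return(structure(empty_sentinel(pred), empty = TRUE))
  fwd <- mean(min_dists(s$A, s$B))
  if (!symmetric) return(fwd)
  (fwd + mean(min_dists(s$B, s$A))) / 2
}

region_masks <- function(mask, K) {
  if (K == 3) list(OD = mask == 1 | mask == 2, OC = mask == 2)
  else list(OD = mask == 1)
}

#' Evaluate a dataset of predicted masks
#'
#' For the joint task (K = 3) the optic disc region is the union of the rim
#' and cup labels (the cup sits inside the disc anatomically) and the cup
#' region is label 2; for K = 2 the disc is label 1. Per-image DSC, HD95 and
#' ASD are aggregated per region with means and a percentile-bootstrap 95%
#' confidence interval on DSC.
#'
#' @param pred_masks,gt_masks lists of integer label masks (matched order).
#' @param K number of classes (2 or 3).
#' @param ci_reps,ci_seed bootstrap parameters for the DSC interval.
#' @return a `fundseg_report`: list with `per_image` (tibble: image, region,
#'   dsc, hd95, asd) and `summary` (tibble: region, n, dsc_mean, dsc_ci_low,
#'   dsc_ci_high, hd95_mean, asd_mean).
#' @export
evaluate_dataset <- function(pred_masks, gt_masks, K = 3,
                             ci_reps = 10000, ci_seed = 112316) {
  if (length(pred_masks) != length(gt_masks))
    stopf("evaluate_dataset: %d predictions vs %d ground truths",
          length(pred_masks), length(gt_masks))
  if (!length(pred_masks)) stopf("evaluate_dataset: empty mask lists")
  rows <- list()
  for (i in seq_along(pred_masks)) {
    pr <- region_masks(pred_masks[[i]], K)
    gr <- region_masks(gt_masks[[i]], K)
    for (rg in names(pr)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        image = i, region = rg,
        dsc = dsc(pr[[rg]], gr[[rg]]),
        hd95 = as.numeric(hd95(pr[[rg]], gr[[rg]])),
        asd = as.numeric(asd(pr[[rg]], gr[[rg]])))
    }
  }
  per_image <- do.call(rbind, rows)
  regs <- unique(per_image$region)
  summ <- lapply(regs, function(rg) {
    d <- per_image[per_image$region == rg, ]
    ci <- bootstrap_ci(d$dsc, reps = ci_reps, seed = ci_seed)
    tibble::tibble(region = rg, n = nrow(d), dsc_mean = mean(d$dsc),
                   dsc_ci_low = ci["low"], dsc_ci_high = ci["high"],
                   hd95_mean = mean(d$hd95), asd_mean = mean(d$asd))
  })
  structure(list(per_image = per_image, summary = do.call(rbind, summ)),
            class = "fundseg_report")
}

#' @method print fundseg_report
#' @export
print.fundseg_report <- function(x, ...) {
  cat("<fundseg_report>\n")
  print(x$summary)
  invisible(x)
}

#' Write a metric report to disk
#'
#' Per-image rows as CSV plus a JSON summary mirroring per-region DSC
#' (with CI), HD95 and ASD.
#'
#' @param report a `fundseg_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "per_image_metrics.csv")
  js <- file.path(dir, "summary.json")
  utils::write.csv(report$per_image, csv, row.names = FALSE)
  jsonlite::write_json(report$summary, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = csv, json = js))
}
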