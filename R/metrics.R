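# Evaluation: Dice-Sorensen coefficient, signed mean error, pixel- and
# instance-level precision/recall, average precision under the Dice-0.1
# matching rule, and the paired t comparison of per-image scores.

#' Dice-Sorensen coefficient
#'
#' `DSC(A, B) = 2 |A intersect B| / (|A| + |B|)`, from 0 (no overlap) to 1
#' (perfect overlap). Two empty masks agree that there is nothing, so the
#' value is defined as 1 and flagged (`attr(, "empty_pair")`) so aggregates
#' can exclude it.
#'
#' @param a,b binary masks of equal shape.
#' @return Dice value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  assert_same_shape(a, b)
  am <- a != 0; bm <- b != 0
  na <- sum(am); nb <- sum(bm)
  if (na + nb == 0L) return(structure(1, empty_pair = TRUE))
  2 * sum(am & bm) / (na + nb)
}

#' Signed mean error
#'
#' `ME = mean(pred - truth)` over all N pixels; positive means the
#' segmented area is overestimated, negative underestimated.
#'
#' @param truth,pred binary masks of equal shape.
#' @return ME in `[-1, 1]`.
#' @export
mean_error <- function(truth, pred) {
  assert_same_shape(truth, pred)
  mean((pred != 0) - (truth != 0))
}

#' Pixel-level precision and recall
#'
#' `Precision = TP / (TP + FP)`, `Recall = TP / (TP + FN)` over pixels. An
#' empty denominator yields 1 with a flag column (nothing predicted means
#' nothing falsely predicted; nothing to find means nothing missed).
#'
#' @param truth,pred binary masks of equal shape.
#' @return one-row tibble: `precision`, `recall`, `precision_defined`,
#'   `recall_defined`.
#' @export
pixel_precision_recall <- function(truth, pred) {
  assert_same_shape(truth, pred)
  tm <- truth != 0; pm <- pred != 0
  tp <- sum(tm & pm); fp <- sum(!tm & pm); fn <- sum(tm & !pm)
  tibble(precision = if (tp + fp > 0) tp / (tp + fp) else 1,
         recall = if (tp + fn > 0) tp / (tp + fn) else 1,
         precision_defined = tp + fp > 0,
         recall_defined = tp + fn > 0)
}

# pairwise Dice between all (pred, truth) instance label pairs
pairwise_dice <- function(preds, truths) {
  pid <- mask_labels(preds); tid <- mask_labels(truths)
  if (!length(pid) || !length(tid))
    return(tibble(pred = integer(), truth = integer(), dice = numeric()))
  both <- preds != 0L & truths != 0L
  inter <- as.data.frame(table(pred = preds[both], truth = truths[both]),
                         stringsAsFactors = FALSE)
  inter <- inter[inter$Freq > 0, ]
  pa <- tabulate(preds[preds != 0L], nbins = max(pid))
  ta <- tabulate(truths[truths != 0L], nbins = max(tid))
  tibble(pred = as.integer(inter$pred), truth = as.integer(inter$truth),
         dice = 2 * inter$Freq /
           (pa[as.integer(inter$pred)] + ta[as.integer(inter$truth)]))
}

#' Match predicted to ground-truth instances at a Dice threshold
#'
#' Candidate pairs are those with pairwise Dice strictly above
#' `dice_threshold`; among all one-to-one assignments restricted to the
#' candidates, the match maximizes the number of matched pairs and, among
#' those, the total Dice. Unmatched predictions are false positives,
#' unmatched truths false negatives. The low default threshold of 0.1
#' scores presence detection rather than pixel-perfect agreement.
#'
#' The optimum is computed exactly: the candidate bipartite graph is split
#' into connected components (in row imagery a prediction rarely overlaps
#' more than its own and the adjacent trees, so components are tiny) and
#' each component is solved by dynamic programming over truth subsets.
#'
#' @param preds,truths integer instance masks of equal shape.
#' @param dice_threshold Dice matching cutoff.
#' @return a `match_result` list: `pairs` tibble (`pred`, `truth`, `dice`),
#'   counts `TP`, `FP`, `FN`, `threshold`, and the unmatched id vectors.
#' @export
match_instances <- function(preds, truths, dice_threshold = 0.1) {
  assert_same_shape(preds, truths)
  pd <- pairwise_dice(preds, truths)
  cand <- pd[pd$dice > dice_threshold, ]
  pairs <- optimal_assignment(cand)
  pairs <- pairs[order(-pairs$dice, pairs$pred, pairs$truth), ]
  pid <- mask_labels(preds); tid <- mask_labels(truths)
  structure(list(pairs = as_tibble(pairs),
                 TP = nrow(pairs),
                 FP = length(setdiff(pid, pairs$pred)),
                 FN = length(setdiff(tid, pairs$truth)),
                 threshold = dice_threshold,
                 unmatched_pred = setdiff(pid, pairs$pred),
                 unmatched_truth = setdiff(tid, pairs$truth)),
            class = "match_result")
}

# exact maximum-cardinality, then maximum-total-dice one-to-one assignment
# over the candidate pairs; solved per connected component of the bipartite
# candidate graph by subset DP over that component's truths
optimal_assignment <- function(cand) {
  if (!nrow(cand)) return(cand)
  pv <- paste0("p", cand$pred); tv <- paste0("t", cand$truth)
  g <- igraph::graph_from_edgelist(cbind(pv, tv), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- list()
  for (cid in unique(comp)) {
    verts <- names(comp)[comp == cid]
    sub <- cand[pv %in% verts, ]
    tids <- sort(unique(sub$truth))
    pids <- sort(unique(sub$pred))
    nt <- length(tids)
    if (nt > 24L) abort("instance matching component too large")
    # dp over subsets of matched truths; value = (count, total dice)
    n_mask <- bitwShiftL(1L, nt)
    cnt <- rep(-1L, n_mask); tot <- rep(-Inf, n_mask)
    choice <- vector("list", n_mask)
    cnt[1] <- 0L; tot[1] <- 0; choice[[1]] <- integer(0)
    for (p in pids) {
      rows <- which(sub$pred == p)
      cnt2 <- cnt; tot2 <- tot; choice2 <- choice
      for (mask in which(cnt >= 0L) - 1L) {
        for (r in rows) {
          tbit <- bitwShiftL(1L, match(sub$truth[r], tids) - 1L)
          if (bitwAnd(mask, tbit) > 0L) next
          nm <- bitwOr(mask, tbit) + 1L
          nc <- cnt[mask + 1L] + 1L
          ntot <- tot[mask + 1L] + sub$dice[r]
          if (nc > cnt2[nm] || (nc == cnt2[nm] && ntot > tot2[nm])) {
            cnt2[nm] <- nc; tot2[nm] <- ntot
            choice2[[nm]] <- c(choice[[mask + 1L]], r)
          }
        }
      }
      cnt <- cnt2; tot <- tot2; choice <- choice2
    }
    best <- order(-cnt, -tot)[1]
    out[[length(out) + 1L]] <- sub[choice[[best]], ]
  }
  dplyr::bind_rows(out)
}

#' Average precision with Dice-threshold matching
#'
#' Detections are ranked by descending score (ties keep input order) and
#' swept: a detection is a true positive when it matches a still-unmatched
#' ground-truth instance with Dice strictly above the threshold (the
#' highest-Dice available truth is taken), otherwise a false positive. AP
#' is the area under the precision-recall curve with all-point
#' interpolation: precision is monotonized from the right and integrated
#' over the recall steps. Detectors without scores can pass uniform scores,
#' which collapses the curve to a single point.
#'
#' @param pred_masks list of binary masks, one per detection.
#' @param scores numeric scores, one per detection (default all 1).
#' @param truths integer instance mask of the ground-truth objects.
#' @param dice_threshold Dice matching cutoff.
#' @return AP in `[0, 1]`; 0 when there are truths but no matching
#'   detections; `NA` (flagged via `attr(, "undefined")`) when both sides
#'   are empty. The PR staircase is attached as `attr(, "pr")`.
#' @export
average_precision <- function(pred_masks, truths,
                              scores = rep(1, length(pred_masks)),
                              dice_threshold = 0.1) {
  stopifnot(length(pred_masks) == length(scores))
  tid <- mask_labels(truths)
  if (!length(pred_masks) && !length(tid))
    return(structure(NA_real_, undefined = TRUE))
  if (!length(tid)) return(0)
  if (!length(pred_masks)) return(0)

  ord <- order(-scores)  # stable: ties keep input order
  matched <- logical(max(tid))
  tp <- logical(length(ord))
  for (j in seq_along(ord)) {
    m <- pred_masks[[ord[j]]]
    best_d <- dice_threshold; best_t <- 0L
    for (t in tid[!matched[tid]]) {
      d <- dice(m, truths == t)
      if (d > best_d) { best_d <- d; best_t <- t }
    }
    if (best_t > 0L) { matched[best_t] <- TRUE; tp[j] <- TRUE }
  }
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(ctp)
  rec <- ctp / length(tid)
  # monotone envelope from the right, integrate over recall steps
  env <- rev(cummax(rev(prec)))
  ap <- sum((rec - c(0, head(rec, -1))) * env)
  structure(ap, pr = tibble(score = scores[ord], tp = tp,
                            precision = prec, recall = rec))
}

#' Paired Student t test on per-image scores
#'
#' For paired scores `x` and `y`, `d = x - y`, `t = mean(d) / (sd(d) /
#' sqrt(n))` with the sample (n - 1) standard deviation, and a two-sided p
#' from the t distribution with n - 1 degrees of freedom. Degenerate
#' cases: `sd(d) = 0` with zero mean gives `t = 0, p = 1`; with nonzero
#' mean the statistic is infinite (`p = 0`) and flagged.
#'
#' @param x,y equal-length numeric vectors (n >= 2), paired by image.
#' @return one-row tibble: `t`, `p_value`, `df`, `mean_diff`, `sd_diff`,
#'   `n`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 2) abort("need at least 2 pairs")
  d <- x - y
  md <- mean(d); sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) return(tibble(t = 0, p_value = 1, df = n - 1, mean_diff = 0,
                               sd_diff = 0, n = n, degenerate = TRUE))
    return(tibble(t = sign(md) * Inf, p_value = 0, df = n - 1, mean_diff = md,
                  sd_diff = 0, n = n, degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  tibble(t = t, p_value = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
         mean_diff = md, sd_diff = sdd, n = n, degenerate = FALSE)
}

#' Evaluate a run of predicted instance masks against ground truth
#'
#' Pairs predictions and truths by name, matches instances per image at the
#' Dice threshold, and aggregates the metrics per tree, per image, and over
#' the dataset (means with standard deviations). Per-image Dice is the mean
#' over matched trees with unmatched ground-truth trees contributing Dice
#' 0; the mean error is computed over the union foreground (any label vs
#' any label); instance-level precision/recall come from the match counts,
#' pixel-level precision/recall from the matched pairs. Per-image AP uses
#' uniform scores unless a `scores` list is supplied.
#'
#' @param pred_instances named list of integer instance masks.
#' @param truth_instances named list of integer instance masks; names pair
#'   images with `pred_instances`. Unpaired images are reported, not fatal.
#' @param dice_threshold Dice matching cutoff.
#' @param scores optional named list of per-instance score vectors (in
#'   label order) for AP ranking.
#' @return an `eval_report` list: `per_tree`, `per_image`, `summary`
#'   tibbles and `unpaired` names.
#' @export
evaluate_run <- function(pred_instances, truth_instances, dice_threshold = 0.1,
                         scores = NULL) {
  imgs <- intersect(names(pred_instances), names(truth_instances))
  unpaired <- c(setdiff(names(pred_instances), imgs),
                setdiff(names(truth_instances), imgs))
  if (length(unpaired)) warn(sprintf("unpaired images skipped: %s",
                                     paste(unpaired, collapse = ", ")))
  per_tree <- list(); per_image <- list()
  for (im in imgs) {
    pr <- pred_instances[[im]]; tr <- truth_instances[[im]]
    mr <- match_instances(pr, tr, dice_threshold)
    tid <- mask_labels(tr)
    rows <- purrr::map_dfr(tid, function(t) {
      hit <- mr$pairs[mr$pairs$truth == t, ]
      if (nrow(hit)) {
        pp <- pixel_precision_recall(tr == t, pr == hit$pred[1])
        tibble(image = im, tree = t, pred = hit$pred[1], dice = hit$dice[1],
               precision = pp$precision, recall = pp$recall)
      } else {
        tibble(image = im, tree = t, pred = NA_integer_, dice = 0,
               precision = NA_real_, recall = 0)
      }
    })
    per_tree[[im]] <- rows
    pid <- mask_labels(pr)
    sc <- if (!is.null(scores)) scores[[im]] else rep(1, length(pid))
    ap <- average_precision(lapply(pid, function(p) pr == p), tr,
                            scores = sc, dice_threshold = dice_threshold)
    per_image[[im]] <- tibble(
      image = im,
      n_truth = length(tid), n_pred = length(pid),
      tp = mr$TP, fp = mr$FP, fn = mr$FN,
      mean_dice = if (length(tid)) mean(rows$dice) else NA_real_,
      me = mean_error(tr, pr),
      ap = as.numeric(ap))
  }
  per_tree <- dplyr::bind_rows(per_tree)
  per_image <- dplyr::bind_rows(per_image)
  tp <- sum(per_image$tp); fp <- sum(per_image$fp); fn <- sum(per_image$fn)
  summary <- tibble(
    n_images = nrow(per_image), n_trees = sum(per_image$n_truth),
    mean_dice = mean(per_image$mean_dice, na.rm = TRUE),
    sd_dice = stats::sd(per_image$mean_dice, na.rm = TRUE),
    mean_me = mean(per_image$me), sd_me = stats::sd(per_image$me),
    mean_ap = mean(per_image$ap, na.rm = TRUE),
    instance_precision = if (tp + fp > 0) tp / (tp + fp) else 1,
    instance_recall = if (tp + fn > 0) tp / (tp + fn) else 1,
    pixel_precision = mean(per_tree$precision, na.rm = TRUE),
    pixel_recall = mean(per_tree$recall, na.rm = TRUE))
  structure(list(per_tree = per_tree, per_image = per_image,
                 summary = summary, unpaired = unpaired,
                 dice_threshold = dice_threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: %d images, %d trees, Dice threshold %.2f>\n",
    nrow(x$per_image), sum(x$per_image$n_truth), x$dice_threshold))
  cat("Per-image Dice averages matched trees; unmatched truths count as 0.\n")
  print(x$summary)
  invisible(x)
}

#' Write / read an evaluation report as CSV
#'
#' Two CSVs: `<stem>.csv` with per-tree rows (image_id, tree_id, dice,
#' precision, recall) and `<stem>_images.csv` with per-image rows (me, ap);
#' the dataset summary goes into `<stem>_summary.csv`.
#'
#' @param report an `eval_report`.
#' @param stem output path without extension.
#' @return the stem, invisibly.
#' @export
write_eval_report <- function(report, stem) {
  readr::write_csv(dplyr::rename(report$per_tree, image_id = "image",
                                 tree_id = "tree"),
                   paste0(stem, ".csv"))
  readr::write_csv(report$per_image, paste0(stem, "_images.csv"))
  readr::write_csv(report$summary, paste0(stem, "_summary.csv"))
  invisible(stem)
}

#' Compare two evaluation reports with the paired t test
#'
#' Pairs the per-image mean Dice of two reports by image id.
#'
#' @param a,b `eval_report` objects over the same images.
#' @param metric per-image column to compare (default `"mean_dice"`).
#' @return the [paired_t_test()] tibble.
#' @export
compare_reports <- function(a, b, metric = "mean_dice") {
  m <- dplyr::inner_join(a$per_image[, c("image", metric)],
                         b$per_image[, c("image", metric)],
                         by = "image", suffix = c("_a", "_b"))
  if (!nrow(m)) abort("no common images to compare")
  paired_t_test(m[[paste0(metric, "_a")]], m[[paste0(metric, "_b")]])
}
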