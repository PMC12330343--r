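# Group discriminability of per-event scores: probability-density histograms
# (0.2-unit bins) and empirical ROC curves discriminating MEC from SAL
# sessions, with the pairwise brute-force AUC oracle.

#' Probability-density histogram with fixed-width bins
#'
#' Histogram with bin edges aligned to multiples of \code{bin_width}
#' (default 0.2 z units), normalized so that the densities integrate to 1.
#'
#' @param scores finite numeric scores (at least one).
#' @param bin_width bin width.
#' @param score_kind optional label (\code{"mean_post_5s"} or
#'   \code{"delta_z"}).
#' @return list of class \code{"density_hist"} with \code{bin_edges},
#'   \code{counts}, \code{density}, \code{bin_width}, \code{score_kind}.
#' @export
density_hist <- function(scores, bin_width = 0.2, score_kind = NA_character_) {
  if (length(scores) == 0) stop("density_hist requires at least one score")
  if (!all(is.finite(scores))) stop("scores must all be finite")
  lo <- floor(min(scores) / bin_width) * bin_width
  hi <- floor(max(scores) / bin_width) * bin_width + bin_width
  edges <- seq(lo, hi, by = bin_width)
  # right-open bins [e_i, e_{i+1})
  bin <- findInterval(scores, edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 density = counts / (length(scores) * bin_width),
                 bin_width = bin_width, score_kind = score_kind),
            class = "density_hist")
}

#' Empirical ROC curve and AUC for MEC vs SAL discrimination
#'
#' Threshold sweep over the unique score values with the MEC day as the
#' positive class. Ties are handled by the rank/midpoint convention, so the
#' area equals the Mann-Whitney U statistic divided by
#' \code{n_pos * n_neg}; the reported AUC is the trapezoid of TPR over FPR,
#' which coincides with that value. The 95% CI uses the Hanley-McNeil
#' variance formula, truncated to [0, 1].
#'
#' @param scores numeric per-event scores.
#' @param labels class labels, one per score.
#' @param positive the positive-class label (default \code{"MEC"}).
#' @param score_kind optional label carried for group comparisons.
#' @param ci_method \code{"hanley"} (default) or \code{"bootstrap"}
#'   (percentile interval over \code{n_boot} stratified resamples).
#' @param n_boot,boot_seed bootstrap resamples and seed (used only when
#'   \code{ci_method = "bootstrap"}).
#' @return list of class \code{"roc_result"} with \code{fpr}, \code{tpr},
#'   \code{thresholds}, \code{auc}, \code{ci95}, \code{n_pos}, \code{n_neg},
#'   \code{positive_label}, \code{score_kind}.
#' @export
roc_curve <- function(scores, labels, positive = "MEC",
                      score_kind = NA_character_,
                      ci_method = c("hanley", "bootstrap"),
                      n_boot = 2000, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present (positive = ", positive, ")")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(th) sum(scores[pos] >= th), numeric(1))
  fp <- vapply(thr, function(th) sum(scores[!pos] >= th), numeric(1))
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  if (ci_method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
            (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
    se <- sqrt(max(v, 0))
    ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  } else {
    sp <- scores[pos]
    sn <- scores[!pos]
    set.seed(as.integer(boot_seed))
    boots <- vapply(seq_len(n_boot), function(b) {
      bs <- c(sample(sp, n_pos, replace = TRUE),
              sample(sn, n_neg, replace = TRUE))
      bl <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
      r <- rank(bs, ties.method = "average")
      (sum(r[bl]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auc = auc,
                 ci95 = ci, n_pos = n_pos, n_neg = n_neg,
                 positive_label = positive, score_kind = score_kind),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (95%% CI %.4f-%.4f), %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Brute-force AUC oracle (all positive-negative pairs)
#'
#' Mean over every positive-negative score pair of 1 if the positive score is
#' larger, 0.5 if tied, 0 otherwise. Exact by definition; intended for test
#' sets with \code{n_pos * n_neg <= 1e6}.
#'
#' @inheritParams roc_curve
#' @return the pairwise AUC.
#' @export
auc_bruteforce <- function(scores, labels, positive = "MEC") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  if (length(sp) == 0 || length(sn) == 0) stop("both classes must be present")
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Compare the discriminability of two exposure groups
#'
#' Reports the distance of each group's ROC from the line of equivalency
#' (|AUC - 0.5|) and their difference (nicotine minus tartrate); a larger
#' distance means SAL and MEC days are easier to tell apart in that group. No
#' hypothesis test is performed.
#'
#' @param roc_tartrate,roc_nicotine \code{roc_result}s computed on the same
#'   score kind.
#' @return list with \code{dev_tartrate}, \code{dev_nicotine},
#'   \code{difference}, and the two AUCs.
#' @export
compare_groups <- function(roc_tartrate, roc_nicotine) {
  if (!identical(roc_tartrate$score_kind, roc_nicotine$score_kind))
    stop("ROC results were computed on different score kinds")
  dev_t <- abs(roc_tartrate$auc - 0.5)
  dev_n <- abs(roc_nicotine$auc - 0.5)
  list(auc_tartrate = roc_tartrate$auc, auc_nicotine = roc_nicotine$auc,
       dev_tartrate = dev_t, dev_nicotine = dev_n,
       difference = dev_n - dev_t)
}

#' Subject-stratified ROC summary
#'
#' Computes one ROC per subject (each subject's own SAL vs MEC events) and
#' summarizes the per-subject AUCs; an alternative to pooling events across
#' subjects, which weights animals by their interaction counts. Subjects
#' missing either class are dropped with a count.
#'
#' @inheritParams roc_curve
#' @param subjects subject identifier per score.
#' @return list with \code{per_subject} (subject, auc, n_pos, n_neg),
#'   \code{mean_auc}, \code{sem_auc} (NA for a single subject), and
#'   \code{n_dropped}.
#' @export
roc_stratified <- function(scores, labels, subjects, positive = "MEC",
                           score_kind = NA_character_) {
  stopifnot(length(scores) == length(labels),
            length(scores) == length(subjects))
  rows <- list()
  dropped <- 0L
  for (s in unique(subjects)) {
    i <- subjects == s
    if (length(unique(labels[i])) < 2) {
      dropped <- dropped + 1L
      next
    }
    r <- roc_curve(scores[i], labels[i], positive = positive,
                   score_kind = score_kind)
    rows[[s]] <- data.frame(subject = s, auc = r$auc, n_pos = r$n_pos,
                            n_neg = r$n_neg)
  }
  if (length(rows) == 0) stop("no subject carries both classes")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(per_subject = per, mean_auc = mean(per$auc),
       sem_auc = if (nrow(per) > 1) sd(per$auc) / sqrt(nrow(per)) else
         NA_real_,
       n_dropped = dropped)
}
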