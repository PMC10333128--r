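# Condition comparisons: logistic-regression probes, cluster-fraction
# coefficients of variation, pairwise silhouette scores, and per-landmark
# mixed-effects fold-change models with Benjamini-Yekutieli correction.

#' Logistic-regression condition probe
#'
#' How much condition information a feature space carries: an L2-regularized
#' logistic regression is fitted on a class-stratified train/test split and
#' scored by balanced accuracy (mean of per-class recalls) on the held-out
#' part. 0.5 is chance for a binary problem regardless of class imbalance.
#'
#' @param features n x d numeric matrix
#' @param condition binary labels (factor/character/logical, exactly 2 levels)
#' @param seed integer seed for the split
#' @param test_fraction held-out fraction (default 0.25)
#' @param lambda ridge penalty for glmnet; default 1/n_train (recorded in the
#'   result)
#' @return a `ProbeResult` list: `balanced_accuracy`, `n_train`, `n_test`,
#'   `seed`, `lambda`
#' @export
condition_probe <- function(features, condition, seed = 0L,
                            test_fraction = 0.25, lambda = NULL) {
  features <- as.matrix(features)
  y <- factor(condition)
  if (nlevels(y) != 2) stop("condition must have exactly 2 classes present")
  set.seed(seed)
  test <- logical(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    test[sample(idx, round(test_fraction * length(idx)))] <- TRUE
  }
  x <- features
  if (ncol(x) == 1L) x <- cbind(x, 0)  # glmnet needs >= 2 columns
  n_train <- sum(!test)
  if (is.null(lambda)) lambda <- 1 / n_train
  if (all(apply(x[!test, , drop = FALSE], 2, function(v)
    max(v) - min(v)) == 0)) {
    # constant features: any constant prediction scores 0.5 balanced accuracy
    pred <- rep(levels(y)[1], sum(test))
  } else {
    fit <- glmnet::glmnet(x[!test, , drop = FALSE], y[!test],
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = FALSE)
    pred <- predict(fit, x[test, , drop = FALSE], type = "class")
  }
  structure(list(balanced_accuracy = balanced_accuracy(y[test], pred),
                 n_train = n_train, n_test = sum(test),
                 seed = seed, lambda = lambda),
            class = "ProbeResult")
}

#' Balanced accuracy (mean of per-class recalls)
#' @param truth true labels
#' @param pred predicted labels
#' @return real in \[0, 1\]
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- factor(truth)
  mean(vapply(levels(truth), function(lev)
    mean(pred[truth == lev] == lev), 1))
}

#' Condition probes over several split seeds
#'
#' @param features n x d matrix
#' @param condition binary labels
#' @param seeds vector of seeds
#' @param max_per_class optional per-class subsample cap (applied once, with
#'   the first seed) to bound the fit cost
#' @param ... passed to [condition_probe()]
#' @return data.frame with one row per seed (`seed`, `balanced_accuracy`)
#' @export
probe_over_seeds <- function(features, condition, seeds = 0:4,
                             max_per_class = 10000L, ...) {
  y <- factor(condition)
  if (!is.null(max_per_class)) {
    set.seed(derive_seed(seeds[1], 31L))
    keep <- unlist(lapply(levels(y), function(lev) {
      idx <- which(y == lev)
      if (length(idx) > max_per_class) sample(idx, max_per_class) else idx
    }))
    features <- features[keep, , drop = FALSE]
    y <- y[keep]
  }
  data.frame(seed = seeds, balanced_accuracy = vapply(seeds, function(s)
    condition_probe(features, y, seed = s, ...)$balanced_accuracy, 1))
}

#' Coefficient of variation of cluster fractions across conditions
#'
#' For each cluster: the fraction of each condition's pixels assigned to it;
#' the CV is the sample standard deviation over conditions divided by the
#' mean. Low CV means condition-consistent clusters. The summary is the
#' median over clusters.
#'
#' @param labels per-pixel cluster labels
#' @param conditions per-pixel condition levels (>= 2 levels)
#' @return list: `per_cluster` (data.frame cluster, cv), `median_cv`
#' @export
cluster_fraction_cv <- function(labels, conditions) {
  conditions <- factor(conditions)
  if (nlevels(conditions) < 2) stop("need at least 2 conditions")
  tab <- table(factor(labels), conditions)
  frac <- sweep(tab, 2, colSums(tab), "/")
  cv <- apply(frac, 1, function(f) {
    if (mean(f) == 0) return(NA_real_)
    sd(f) / mean(f)
  })
  list(per_cluster = data.frame(cluster = rownames(tab), cv = as.numeric(cv),
                                stringsAsFactors = FALSE),
       median_cv = median(cv, na.rm = TRUE))
}

l1_cross_dist <- function(A, B) {
  # |A| x |B| matrix of L1 distances
  out <- matrix(0, nrow(A), nrow(B))
  for (d in seq_len(ncol(A)))
    out <- out + abs(outer(A[, d], B[, d], "-"))
  out
}

#' Pairwise silhouette score between two groups (L1 distance)
#'
#' S(p,q) = mean over i in p of (d_q(i) - d_p(i)) / max(d_q(i), d_p(i)) with
#' d_g(i) the mean L1 distance of i to all members of group g. Note d_p(i)
#' includes the self term (distance 0), and the score is asymmetric; the
#' symmetrized mean (S(p,q) + S(q,p)) / 2 is also returned. This is not the
#' classical per-point silhouette.
#'
#' @param features_p n_p x d matrix of group-p feature vectors
#' @param features_q n_q x d matrix of group-q feature vectors
#' @return list: `s_pq`, `s_qp`, `symmetric`
#' @export
pairwise_silhouette <- function(features_p, features_q) {
  A <- as.matrix(features_p); B <- as.matrix(features_q)
  if (nrow(A) == 0 || nrow(B) == 0) stop("both groups must be non-empty")
  d_pp <- rowMeans(l1_cross_dist(A, A))
  d_pq <- rowMeans(l1_cross_dist(A, B))
  d_qq <- rowMeans(l1_cross_dist(B, B))
  d_qp <- rowMeans(l1_cross_dist(B, A))
  score <- function(d_other, d_own) {
    mx <- pmax(d_other, d_own)
    term <- ifelse(mx == 0, 0, (d_other - d_own) / mx)
    mean(term)
  }
  s_pq <- score(d_pq, d_pp)
  s_qp <- score(d_qp, d_qq)
  list(s_pq = s_pq, s_qp = s_qp, symmetric = (s_pq + s_qp) / 2)
}

#' Per-landmark fold-change mixed-effects model
#'
#' Fits log(Y) = mu + gamma * treated + well random intercept + condition-
#' specific residual variances (one model per channel/landmark pair). With
#' `normalize = TRUE` the response is log(Y) - log(Y_nucleus), so exp(gamma)
#' is the landmark-specific effect net of the whole-nucleus effect. The Wald
#' statistic uses conservative containment degrees of freedom
#' (number of wells - 2).
#'
#' @param df data.frame with columns `value` (> 0), `condition` (2 levels,
#'   reference first), `well`, and `nucleus_value` when `normalize = TRUE`
#' @param normalize whether to model the nucleus-normalized response
#' @param label optional (channel, csl) label used in error messages
#' @return a `FoldChangeResult` list: `estimate` (log scale), `se`,
#'   `wald_stat`, `df`, `p`, `fold_change`, `n_cells`, `normalized`
#' @export
fold_change_model <- function(df, normalize = FALSE, label = NULL) {
  df <- df[is.finite(df$value) & df$value > 0, , drop = FALSE]
  if (normalize)
    df <- df[is.finite(df$nucleus_value) & df$nucleus_value > 0, ,
             drop = FALSE]
  df$condition <- factor(df$condition)
  if (nlevels(df$condition) != 2) stop("condition must have 2 levels")
  wells_per <- tapply(df$well, df$condition, function(w) length(unique(w)))
  if (any(wells_per < 2)) stop("need at least 2 wells per condition")
  df$logy <- if (normalize) log(df$value) - log(df$nucleus_value) else
    log(df$value)
  fit <- try(nlme::lme(logy ~ condition, random = ~ 1 | well,
                       weights = nlme::varIdent(form = ~ 1 | condition),
                       data = df, method = "REML",
                       control = nlme::lmeControl(opt = "optim")),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop(sprintf("singular or failed mixed-model fit%s: %s",
                 if (is.null(label)) "" else paste0(" for ", label),
                 attr(fit, "condition")$message))
  co <- summary(fit)$tTable
  est <- co[2, "Value"]
  se <- co[2, "Std.Error"]
  dfree <- length(unique(df$well)) - 2
  wald <- est / se
  structure(list(estimate = est, se = se, wald_stat = wald, df = dfree,
                 p = 2 * pt(-abs(wald), dfree),
                 fold_change = exp(est), n_cells = nrow(df),
                 normalized = normalize),
            class = "FoldChangeResult")
}

#' Fold changes for all channel/landmark combinations of one comparison
#'
#' Loops [fold_change_model()] over channels and landmarks, and controls the
#' false discovery rate across the whole (channel, landmark) family with the
#' Benjamini-Yekutieli method. The whole-nucleus reference (`csl = "all"`) is
#' the pixel-count-weighted cell mean.
#'
#' @param ft a [feature_table()] result
#' @param meta [cell_metadata()] of the dataset (condition + well per cell)
#' @param channels channel names to test
#' @param condition_field metadata column holding the condition (default
#'   "perturbation")
#' @param normalize model the nucleus-normalized response (default TRUE)
#' @return data.frame: channel, csl, estimate, se, wald_stat, df, p, p_adj,
#'   fold_change, normalized
#' @export
fold_changes <- function(ft, meta, channels,
                         condition_field = "perturbation",
                         normalize = TRUE) {
  csls <- setdiff(unique(ft$csl), "all")
  rows <- list()
  for (ch in channels) {
    nuc <- nucleus_reference(ft, ch)
    for (cs in csls) {
      sub <- ft[ft$csl == cs & ft$n_pixels > 0, c("cell_id", ch)]
      names(sub)[2] <- "value"
      sub$nucleus_value <- nuc[sub$cell_id]
      sub$condition <- meta[[condition_field]][match(sub$cell_id,
                                                     meta$cell_id)]
      sub$well <- meta$well_id[match(sub$cell_id, meta$cell_id)]
      ok <- is.finite(sub$value) & sub$value > 0
      wells_per <- tapply(sub$well[ok], sub$condition[ok],
                          function(w) length(unique(w)))
      if (length(wells_per) < 2 || any(is.na(wells_per)) ||
          any(wells_per < 2)) next  # landmark too sparse for this contrast
      res <- fold_change_model(sub, normalize = normalize,
                               label = sprintf("(%s, %s)", ch, cs))
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, csl = cs, estimate = res$estimate, se = res$se,
        wald_stat = res$wald_stat, df = res$df, p = res$p,
        fold_change = res$fold_change, normalized = res$normalized,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_yekutieli(out$p)
  out
}

nucleus_reference <- function(ft, channel) {
  # pixel-count-weighted mean over landmarks = whole-cell mean intensity
  vals <- tapply(seq_len(nrow(ft)), ft$cell_id, function(idx) {
    w <- ft$n_pixels[idx]
    ok <- w > 0
    sum(ft[[channel]][idx][ok] * w[ok]) / sum(w[ok])
  })
  setNames(as.numeric(vals), names(vals))
}

#' Benjamini-Yekutieli adjusted p values
#'
#' Step-up adjustment with the harmonic-number inflation factor
#' c(m) = sum(1/l), valid under arbitrary dependence; family = all
#' (channel, landmark) combinations of one treatment comparison.
#'
#' @param pvals p values in \[0, 1\]
#' @return adjusted p values, clipped at 1
#' @export
benjamini_yekutieli <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BY")
}
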