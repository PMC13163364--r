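fold_seed <- function(seed, s) as.integer((as.numeric(seed) * 131 + s * 2654435) %% 2147483587)

#' Plan leave-one-out cross-validation folds
#'
#' One fold per subject: the subject is held out, the remaining subjects
#' form the reference set, and a seeded shuffle partitions the reference set
#' into 80% training and 20% validation (at least one validation subject).
#' Priors are always built from the full reference set; only the network
#' training uses the inner split.
#'
#' @param subject_ids vector of subject identifiers (typically `1:N`).
#' @param seed harness seed; fixed seed reproduces the plans exactly.
#' @return list of `fold_plan` objects with elements `held_out`,
#'   `reference`, `train`, `validation`, `seed`.
#' @export
plan_loocv <- function(subject_ids, seed = 1L) {
  n <- length(subject_ids)
  if (n < 3L) stop("LOOCV needs at least 3 subjects (the inner split needs one validation subject)")
  lapply(seq_len(n), function(s) {
    ref <- subject_ids[-s]
    fs <- fold_seed(seed, s)
    shuffled <- with_local_seed(fs, sample(ref))
    n_val <- max(1L, round(0.2 * length(ref)))
    structure(list(held_out = subject_ids[s], reference = ref,
                   train = sort(shuffled[-seq_len(n_val)]),
                   validation = sort(shuffled[seq_len(n_val)]),
                   seed = fs),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: hold out %s; %d train / %d validation\n",
              x$held_out, length(x$train), length(x$validation)))
  invisible(x)
}

cohort_pairs <- function(cohort) {
  list(volumes = lapply(cohort$subjects, `[[`, "volume"),
       masks = lapply(cohort$subjects, `[[`, "mask"))
}

#' Run one cross-validation fold
#'
#' Executes the per-fold stage sequence for one input configuration: ROI
#' standardisation, prior construction from the reference set only, GAN
#' training on the inner split, inference on the held-out subject (whose
#' mask is never read before evaluation), and scoring in the original volume
#' frame.
#'
#' @param cohort a `phantom_cohort` or any list with `subjects`, each having
#'   `volume` and `mask`.
#' @param plan a `fold_plan` (subject ids index into `cohort$subjects`).
#' @param config input configuration (`"raw"`, `"roi"`, `"roi_prob"`,
#'   `"full"`).
#' @param roi_size,net,train,... passed to [priorseg()]; the fold's derived
#'   seed replaces `train$seed` so folds are independently reproducible.
#' @param return_fit also return the fitted model (for audits).
#' @return one-row score `data.frame` (subject, config, dice, iou, hd95,
#'   assd, flagged); with `return_fit = TRUE`, a list `(scores, fit,
#'   prediction)`.
#' @export
run_fold <- function(cohort, plan, config = "full",
                     roi_size = c(16L, 64L, 64L), net = tiny_net(),
                     train = train_control(epochs = 30L), return_fit = FALSE,
                     ...) {
  pairs <- cohort_pairs(cohort)
  ref <- plan$reference
  train$seed <- plan$seed
  val_pos <- match(plan$validation, ref)
  fit <- priorseg(pairs$volumes[ref], pairs$masks[ref], config = config,
                  roi_size = roi_size, validation = val_pos, net = net,
                  train = train, ...)
  held_vol <- pairs$volumes[[plan$held_out]]
  pred <- predict(fit, held_vol)
  scores <- cbind(data.frame(subject = plan$held_out, config = config),
                  seg_scores(pred, pairs$masks[[plan$held_out]],
                             spacing(held_vol)))
  if (return_fit) list(scores = scores, fit = fit, prediction = pred)
  else scores
}

#' Leave-one-out cross-validation over a cohort
#'
#' @param cohort as in [run_fold()].
#' @param config input configuration.
#' @param folds indices of the folds to execute (default: all, i.e. full
#'   LOOCV; a subset gives a partial but unbiased estimate at reduced cost).
#' @param seed harness seed for the fold plans.
#' @param ... passed to [run_fold()].
#' @return score `data.frame`, one row per executed fold.
#' @export
run_loocv <- function(cohort, config = "full", folds = NULL, seed = 1L, ...) {
  n <- length(cohort$subjects)
  plans <- plan_loocv(seq_len(n), seed)
  if (is.null(folds)) folds <- seq_len(n)
  do.call(rbind, lapply(plans[folds], function(p)
    run_fold(cohort, p, config = config, ...)))
}

#' Aggregate per-subject scores
#'
#' Mean, standard deviation and a seeded nonparametric percentile-bootstrap
#' 95% confidence interval per metric, grouped by configuration.
#'
#' @param scores score `data.frame` from [run_loocv()] / [run_ablation()].
#' @param metrics which metric columns to aggregate.
#' @param boot number of bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return `data.frame` with one row per (configuration, metric).
#' @export
aggregate_scores <- function(scores, metrics = c("dice", "iou", "hd95", "assd"),
                             boot = 2000L, conf = 0.95, seed = 1L) {
  if (nrow(scores) < 2L) stop("aggregation needs at least two scored subjects")
  groups <- split(scores, scores$config)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(metrics, function(m) {
      x <- df[[m]]
      x <- x[is.finite(x)]
      ci <- with_local_seed(seed, {
        bs <- vapply(seq_len(boot), function(i)
          mean(sample(x, replace = TRUE)), numeric(1))
        quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      })
      data.frame(config = g, metric = m, n = length(x), mean = mean(x),
                 sd = sd(x), ci_lo = ci[1], ci_hi = ci[2])
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Exact Wilcoxon signed-rank test (two-sided)
#'
#' Paired test on per-subject differences. Zero differences are dropped;
#' ties in the absolute differences receive average ranks. For n <= 15 the
#' p-value is exact by enumeration of all 2^n sign assignments (this stays
#' correct under ties, where the classical exact distribution does not
#' apply); larger n uses the normal approximation with continuity
#' correction.
#'
#' @param x,y paired numeric vectors.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  obs <- abs(W - mu)
  if (n <= 15L) {
    m <- 2L^n
    cnt <- 0L
    for (k in 0:(m - 1L)) {
      w <- sum(r[bitwAnd(bitwShiftR(k, 0:(n - 1L)), 1L) == 1L])
      if (abs(w - mu) >= obs - 1e-9) cnt <- cnt + 1L
    }
    cnt / m
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    min(1, 2 * pnorm(-(obs - 0.5) / sigma))
  }
}

#' Paired significance between two input configurations
#'
#' Two-sided Wilcoxon signed-rank tests on the per-subject paired metric
#' differences between two configurations, Benjamini-Hochberg adjusted
#' across the metric family.
#'
#' @param scores score `data.frame` containing both configurations.
#' @param config_a,config_b configuration labels to compare.
#' @param metrics metric columns to test.
#' @return `data.frame` with columns `metric`, `p`, `p_adj`.
#' @export
paired_significance <- function(scores, config_a, config_b,
                                metrics = c("dice", "iou", "hd95", "assd")) {
  a <- scores[scores$config == config_a, ]
  b <- scores[scores$config == config_b, ]
  a <- a[order(a$subject), ]
  b <- b[order(b$subject), ]
  if (nrow(a) == 0L || nrow(b) == 0L || !identical(a$subject, b$subject))
    stop("configurations must cover identical subject sets")
  p <- vapply(metrics, function(m) wilcoxon_signed_rank(a[[m]], b[[m]]),
              numeric(1))
  data.frame(metric = metrics, p = p,
             p_adj = p.adjust(p, method = "BH"), row.names = NULL)
}

#' Input-configuration ablation over a cohort
#'
#' Runs (a subset of) the LOOCV folds for each input configuration and each
#' harness seed, mirroring the ablation protocol that compares raw input,
#' kidney-centred ROI, ROI plus appearance prior, and the full condition
#' volume.
#'
#' @param cohort as in [run_fold()].
#' @param configs configurations to evaluate.
#' @param seeds one run of the fold plans per seed.
#' @param folds fold indices per run (default: all).
#' @param ... passed to [run_fold()].
#' @return score `data.frame` with columns `seed`, `subject`, `config` and
#'   the four metrics.
#' @export
run_ablation <- function(cohort, configs = c("raw", "roi", "roi_prob", "full"),
                         seeds = 1L, folds = NULL, ...) {
  do.call(rbind, lapply(seeds, function(sd) {
    do.call(rbind, lapply(configs, function(cf) {
      sc <- run_loocv(cohort, config = cf, folds = folds, seed = sd, ...)
      cbind(data.frame(seed = sd), sc)
    }))
  }))
}
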