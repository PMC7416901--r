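#' Per-sample linear mixed-model significance scan
#'
#' For every sample of the epoch time axis a linear mixed model
#' `pupil ~ factor + (1 + factor | participant)` (or, with two factors,
#' `pupil ~ f1 * f2 + (1 + f1 + f2 | participant)`) is fitted and the
#' fixed-effect t statistics collected. Samples where `|t| > t_crit` are
#' grouped into maximal runs; runs shorter than `min_run_s` are discarded
#' (the cluster-duration rule that stands in for explicit p values or
#' multiplicity correction). Factors use deviation coding (-1/2, +1/2), so
#' each coefficient is the high-minus-low difference at that sample.
#'
#' Samples at which the mixed model fails to converge are refitted with a
#' random intercept only and flagged; runs made entirely of fallback
#' samples are marked in the output.
#'
#' @param epoch_set an `epoch_set` whose metadata contains `participant`
#'   and the factor columns; at least two participants and both factor
#'   levels are required.
#' @param factors character vector of one or two factor column names.
#' @param min_run_s minimum run duration in seconds.
#' @param t_crit significance criterion on `|t|`.
#' @return list with `runs` (data.frame: `term`, `start_s`, `end_s`,
#'   `n_samples`, `all_fallback`), `t` (terms x samples matrix),
#'   `fallback` (logical per sample) and `time`.
#' @export
lme_scan <- function(epoch_set, factors, min_run_s = 0.2, t_crit = 2) {
  stopifnot(inherits(epoch_set, "epoch_set"),
            length(factors) %in% 1:2,
            all(factors %in% names(epoch_set$meta)))
  meta <- epoch_set$meta
  if (length(unique(meta$participant)) < 2L)
    stop("lme_scan needs epochs from at least 2 participants")
  dat <- data.frame(participant = factor(meta$participant))
  for (f in factors) {
    lv <- sort(unique(as.character(meta[[f]])))
    if (length(lv) != 2L) stop("factor '", f, "' must have two levels")
    if (setequal(lv, c("low", "high"))) lv <- c("low", "high")
    x <- factor(meta[[f]], levels = lv)
    stats::contrasts(x) <- matrix(c(-0.5, 0.5), 2,
                                  dimnames = list(lv, lv[2]))
    dat[[f]] <- x
  }
  fixed <- paste(factors, collapse = " * ")
  ranef <- paste(c("1", factors), collapse = " + ")
  form <- stats::as.formula(
    sprintf("y ~ %s + (%s | participant)", fixed, ranef))
  form_fb <- stats::as.formula(sprintf("y ~ %s + (1 | participant)", fixed))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  ns <- ncol(epoch_set$data)
  fit0 <- NULL
  tmat <- NULL
  fallback <- logical(ns)
  for (j in seq_len(ns)) {
    dat$y <- epoch_set$data[, j]
    fit <- NULL
    if (!is.null(fit0))
      fit <- tryCatch(suppressMessages(lme4::refit(fit0, dat$y)),
                      error = function(e) NULL,
                      warning = function(w) NULL)
    if (is.null(fit))
      fit <- tryCatch(suppressMessages(
        lme4::lmer(form, dat, REML = TRUE, control = ctrl)),
        error = function(e) NULL)
    # a singular random-effects fit (variance at the boundary) is a valid
    # REML solution; only genuine non-convergence triggers the fallback
    if (!is.null(fit)) {
      msgs <- fit@optinfo$conv$lme4$messages
      if (length(msgs) && !all(grepl("singular", msgs, ignore.case = TRUE)))
        fit <- NULL
    }
    if (is.null(fit)) {
      fallback[j] <- TRUE
      fit <- suppressMessages(
        lme4::lmer(form_fb, dat, REML = TRUE, control = ctrl))
    } else if (is.null(fit0)) {
      fit0 <- fit
    }
    ct <- lme4::fixef(fit)
    tv <- stats::coef(summary(fit))[, "t value"]
    if (is.null(tmat)) {
      terms <- setdiff(names(ct), "(Intercept)")
      tmat <- matrix(NA_real_, length(terms), ns,
                     dimnames = list(terms, NULL))
    }
    tmat[, j] <- tv[rownames(tmat)]
  }
  dt <- 1 / epoch_set$rate_hz
  runs <- list()
  for (term in rownames(tmat)) {
    sig <- abs(tmat[term, ]) > t_crit
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (r$lengths[k] * dt < min_run_s - 1e-9) next
      idx <- starts[k]:ends[k]
      runs[[length(runs) + 1L]] <-
        data.frame(term = term,
                   start_s = epoch_set$time[starts[k]],
                   end_s = epoch_set$time[ends[k]] + dt,
                   n_samples = r$lengths[k],
                   all_fallback = all(fallback[idx]))
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs)
          else data.frame(term = character(), start_s = numeric(),
                          end_s = numeric(), n_samples = integer(),
                          all_fallback = logical())
  list(runs = runs, t = tmat, fallback = fallback, time = epoch_set$time)
}

#' Extract pupil features from epochs
#'
#' Within each named time window the signed maximum (dilation) and minimum
#' (constriction) of the baselined trace are extracted together with their
#' latencies (time of the earliest sample attaining the extremum, relative
#' to the lock event).
#'
#' @param epoch_set an `epoch_set`.
#' @param windows named list of `c(start_s, end_s)` windows on the epoch
#'   axis; a window with no sample inside the epoch span is an error
#'   naming the window.
#' @return data.frame: the epoch metadata followed by, per window `w`,
#'   columns `w_max_mm`, `w_max_lat_s`, `w_min_mm`, `w_min_lat_s`.
#' @export
extract_features <- function(epoch_set, windows) {
  stopifnot(inherits(epoch_set, "epoch_set"), is.list(windows),
            !is.null(names(windows)), all(nzchar(names(windows))))
  out <- epoch_set$meta
  for (w in names(windows)) {
    win <- windows[[w]]
    idx <- which(epoch_set$time >= win[1] & epoch_set$time <= win[2])
    if (!length(idx))
      stop(sprintf("window '%s' [%g, %g] lies outside the epoch span",
                   w, win[1], win[2]))
    seg <- epoch_set$data[, idx, drop = FALSE]
    imax <- apply(seg, 1L, which.max)
    imin <- apply(seg, 1L, which.min)
    out[[paste0(w, "_max_mm")]] <- seg[cbind(seq_len(nrow(seg)), imax)]
    out[[paste0(w, "_max_lat_s")]] <- epoch_set$time[idx][imax]
    out[[paste0(w, "_min_mm")]] <- seg[cbind(seq_len(nrow(seg)), imin)]
    out[[paste0(w, "_min_lat_s")]] <- epoch_set$time[idx][imin]
  }
  out
}

#' Trial classification by per-participant logistic regression
#'
#' For each participant a logistic regression of the class label on the
#' supplied features is evaluated two ways: (a) accuracy under stratified
#' k-fold cross-validation (folds drawn within class, under the recorded
#' seed), and (b) ROC/AUC. Two AUCs are reported: `auc_cv` from pooled
#' out-of-fold probabilities (unbiased; 0.5 is chance) and `auc_insample`
#' from the full-fit in-sample probabilities (optimistic for small trial
#' counts; kept for comparability with conventional reports). `auc_cv` is
#' the primary measure. A one-sample t-test of the per-participant
#' accuracies against 0.5 is reported alongside, since the AUC is only
#' meaningfully interpreted when accuracy is above chance.
#'
#' Participants with fewer than two trials in either class are excluded
#' with a warning.
#'
#' @param features data.frame with a `participant` column and the feature
#'   columns.
#' @param labels two-level factor (or coercible) of trial labels, one per
#'   row of `features`.
#' @param feature_cols character vector of feature column names; defaults
#'   to every numeric column except `participant`, `trial_id` and
#'   `baseline_mm`.
#' @param n_folds folds for cross-validation.
#' @param seed integer seed for fold assignment.
#' @return object of class `classification_result`: `per_participant`
#'   data.frame (`participant`, `n`, `accuracy`, `auc_cv`,
#'   `auc_insample`), means of each, `p_above_chance` (t-test of accuracy
#'   vs 0.5), `n_folds`, `seed`, `feature_cols`.
#' @export
classify_trials <- function(features, labels, feature_cols = NULL,
                            n_folds = 5, seed = 1) {
  stopifnot(is.data.frame(features), "participant" %in% names(features),
            nrow(features) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (is.null(feature_cols)) {
    num <- names(features)[vapply(features, is.numeric, logical(1))]
    feature_cols <- setdiff(num, c("participant", "trial_id",
                                   "baseline_mm"))
  }
  # fold assignment is seeded but must not disturb the caller's RNG stream
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  res <- list()
  for (p in unique(features$participant)) {
    rows <- which(features$participant == p)
    y <- labels[rows]
    if (min(table(y)) < 2L || nlevels(droplevels(y)) < 2L) {
      warning("participant ", p,
              " excluded: fewer than 2 trials in a class")
      next
    }
    X <- features[rows, feature_cols, drop = FALSE]
    df <- cbind(y = y, X)
    full <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial()))
    p_in <- stats::predict(full, type = "response")
    auc_in <- auc_probs(y, p_in)
    folds <- stratified_folds(y, n_folds)
    p_oof <- rep(NA_real_, length(y))
    correct <- logical(length(y))
    for (f in seq_len(n_folds)) {
      te <- which(folds == f)
      if (!length(te)) next
      tr <- which(folds != f)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = df[tr, , drop = FALSE],
                   family = stats::binomial()))
      pr <- suppressWarnings(
        stats::predict(fit, newdata = df[te, , drop = FALSE],
                       type = "response"))
      p_oof[te] <- pr
      correct[te] <- (pr > 0.5) == (y[te] == levels(y)[2])
    }
    res[[length(res) + 1L]] <-
      data.frame(participant = p, n = length(y),
                 accuracy = mean(correct),
                 auc_cv = auc_probs(y, p_oof),
                 auc_insample = auc_in)
  }
  if (!length(res)) stop("no participant with enough trials per class")
  per <- do.call(rbind, res)
  tt <- if (nrow(per) >= 2L && stats::sd(per$accuracy) > 0)
    stats::t.test(per$accuracy, mu = 0.5, alternative = "greater")$p.value
  else NA_real_
  structure(list(per_participant = per,
                 mean_accuracy = mean(per$accuracy),
                 mean_auc_cv = mean(per$auc_cv),
                 mean_auc_insample = mean(per$auc_insample),
                 p_above_chance = tt,
                 n_folds = n_folds, seed = seed,
                 feature_cols = feature_cols),
            class = "classification_result")
}

# AUC with a fixed direction (probability of the second level), so chance
# stays at 0.5 instead of being folded upward.
auc_probs <- function(y, p) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                 levels = levels(y), direction = "<",
                                 quiet = TRUE)))
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Trial classification (%d participants, %d-fold CV, seed %d)\n",
              nrow(x$per_participant), x$n_folds, x$seed))
  cat(sprintf("  mean accuracy %.3f (p vs chance %.3g), mean AUC %.3f (CV) / %.3f (in-sample)\n",
              x$mean_accuracy, x$p_above_chance, x$mean_auc_cv,
              x$mean_auc_insample))
  invisible(x)
}

#' Cowan's K visual working memory capacity estimate
#'
#' `K = N * (hit rate - false alarm rate)`, where `N` is the number of
#' items in the memory array. May be negative; reported as-is.
#'
#' @param n_items number of items in the memory array.
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @return K, same length as the inputs after recycling.
#' @export
cowans_k <- function(n_items, hit_rate, fa_rate) {
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1),
            all(fa_rate >= 0 & fa_rate <= 1))
  n_items * (hit_rate - fa_rate)
}

#' Inverse efficiency score
#'
#' Mean correct reaction time divided by the proportion of correct
#' responses; lower is better, guarding against speed-accuracy trade-offs.
#'
#' @param mean_rt mean RT (any time unit; the result carries the same
#'   unit).
#' @param prop_correct proportion correct, strictly positive.
#' @return IE = `mean_rt / prop_correct`.
#' @export
inverse_efficiency <- function(mean_rt, prop_correct) {
  if (any(prop_correct <= 0))
    stop("inverse efficiency undefined for prop_correct <= 0")
  mean_rt / prop_correct
}

#' Reaction-time trial filter
#'
#' Keeps trials with `lo <= rt_s <= hi`; the excluded fraction is attached
#' as attribute `excluded_frac`.
#'
#' @param trials data.frame with an `rt_s` column (seconds).
#' @param lo,hi inclusive bounds in seconds.
#' @return the kept rows.
#' @export
rt_filter <- function(trials, lo = 0.2, hi = 2.5) {
  stopifnot("rt_s" %in% names(trials))
  keep <- !is.na(trials$rt_s) & trials$rt_s >= lo & trials$rt_s <= hi
  out <- trials[keep, , drop = FALSE]
  attr(out, "excluded_frac") <- 1 - mean(keep)
  out
}
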