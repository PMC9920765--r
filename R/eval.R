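#' False acceptance and false rejection rates from confusion counts
#'
#' `FAR = FP / (FP + TN)`; `FRR = FN / (FN + TP)`.
#'
#' @param counts list or data.frame with fields `TP`, `FP`, `TN`, `FN`.
#' @return list with `FAR`, `FRR`.
#' @export
far_frr <- function(counts) {
  with(counts, {
    if (FP + TN <= 0 || FN + TP <= 0) stopf("empty FAR or FRR denominator")
    list(FAR = FP / (FP + TN), FRR = FN / (FN + TP))
  })
}

#' Equal error rate of genuine vs impostor score sets
#'
#' Sweeps the acceptance threshold over the pooled score support (accept
#' when score >= threshold), computes FAR/FRR per threshold, and returns the
#' rate at the FAR/FRR crossing by linear interpolation between the two
#' bracketing thresholds. Higher scores mean more genuine.
#'
#' @param genuine scores of genuine attempts.
#' @param impostor scores of impostor attempts.
#' @return list with `eer` and the operating `threshold` (`NA` with a
#'   warning when all scores are identical).
#' @export
eer <- function(genuine, impostor) {
  stopifnot(length(genuine) > 0, length(impostor) > 0)
  pooled <- sort(unique(c(genuine, impostor)))
  if (length(pooled) == 1) {
    warning("all scores identical: EER undefined")
    return(list(eer = NA_real_, threshold = NA_real_))
  }
  thr <- c(pooled, pooled[length(pooled)] + 1)
  far <- vapply(thr, function(t) mean(impostor >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(genuine < t), numeric(1))
  d <- far - frr # non-increasing in thr: starts >= 0, ends <= 0
  i <- which(d <= 0)[1]
  if (is.na(i)) i <- length(thr)
  if (d[i] == 0) return(list(eer = far[i], threshold = thr[i]))
  if (i == 1) {
    # FRR already exceeds FAR at the lowest threshold: no true crossing,
    # report the midpoint at that operating point
    return(list(eer = (far[1] + frr[1]) / 2, threshold = thr[1]))
  }
  j <- i - 1L
  denom <- (d[j] - d[i])
  alpha <- if (denom == 0) 0 else d[j] / denom
  list(eer = far[j] + alpha * (far[i] - far[j]),
       threshold = thr[j] + alpha * (thr[i] - thr[j]))
}

#' Cohort EER from a per-class score matrix
#'
#' One-vs-rest per subject: genuine scores are the subject's own column at
#' their trials, impostor scores the same column at everyone else's trials;
#' per-subject EERs are averaged.
#'
#' @param scores numeric matrix, trials x classes (columns named by class).
#' @param truth true class label per trial.
#' @return list with `eer` (cohort mean) and `per_subject` (named vector).
#' @export
cohort_eer <- function(scores, truth) {
  classes <- colnames(scores)
  per <- vapply(classes, function(cl) {
    own <- truth == cl
    if (!any(own) || all(own)) return(NA_real_)
    eer(scores[own, cl], scores[!own, cl])$eer
  }, numeric(1))
  list(eer = mean(per, na.rm = TRUE), per_subject = per)
}

# macro-averaged F1 over classes (classes absent from truth and prediction
# are excluded; an undefined per-class F1 counts as 0)
macro_f1 <- function(truth, pred, levels = sort(unique(c(truth, pred)))) {
  f1s <- vapply(levels, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp + fp + fn == 0) return(NA_real_)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Fit and score a conventional classifier on a feature subset
#'
#' Fits an RBF SVM (C = 1, one-vs-rest probability scores) or a
#' 100-tree random forest on the subset columns of the training matrix,
#' then emits hard predictions (accuracy / macro F1) and per-subject scores
#' (for EER) on the test matrix. Deterministic under `seed`.
#'
#' @param train normalized, SMOTE-balanced training `feature_matrix`.
#' @param test test `feature_matrix` (never SMOTE'd).
#' @param subset integer feature indices to use.
#' @param kind `"svm"` or `"rf"`.
#' @param seed RNG seed.
#' @param svm_cost SVM cost parameter C.
#' @param rf_trees number of random-forest trees.
#' @return list with `predictions`, `scores` (matrix trials x classes),
#'   `accuracy`, `macro_f1`.
#' @export
train_eval_classifier <- function(train, test, subset, kind = c("svm", "rf"),
                                  seed = 1L, svm_cost = 1, rf_trees = 100) {
  kind <- match.arg(kind)
  stopifnot(length(subset) >= 1)
  xtr <- feature_block(train)[, subset, drop = FALSE]
  ytr <- factor(train$subject)
  if (nlevels(droplevels(ytr)) < 2) stopf("single-class training data")
  xte <- feature_block(test)[, subset, drop = FALSE]
  yte <- factor(test$subject, levels = levels(ytr))

  local_seed(seed, {
    if (kind == "svm") {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = svm_cost,
                        probability = TRUE, scale = FALSE)
      pred <- stats::predict(fit, xte, probability = TRUE)
      scores <- attr(pred, "probabilities")
      scores <- scores[, levels(ytr), drop = FALSE]
    } else {
      fit <- randomForest::randomForest(xtr, ytr, ntree = rf_trees)
      pred <- stats::predict(fit, xte)
      scores <- stats::predict(fit, xte, type = "prob")
      scores <- scores[, levels(ytr), drop = FALSE]
    }
    list(predictions = pred, scores = scores,
         accuracy = mean(pred == yte),
         macro_f1 = macro_f1(as.character(yte), as.character(pred)))
  })
}

# k-fold CV accuracy of a DQN policy on a training matrix (model-selection
# objective for BOHB); folds assigned round-robin after a seeded shuffle
cv_dqn_accuracy <- function(train, hp, rl, reward = NULL, folds = 5,
                            seed = 1L) {
  n <- nrow(train)
  fold_id <- local_seed(derive_seed(seed, 31L), {
    sample(rep_len(seq_len(folds), n))
  })
  accs <- vapply(seq_len(folds), function(f) {
    tr <- train[fold_id != f, , drop = FALSE]
    va <- train[fold_id == f, , drop = FALSE]
    attr(tr, "feature_names") <- attr(train, "feature_names")
    attr(va, "feature_names") <- attr(train, "feature_names")
    class(tr) <- class(va) <- c("feature_matrix", "data.frame")
    pol <- dqn_train(tr, hp = hp, rl = rl, reward = reward,
                     seed = derive_seed(seed, 7L, f),
                     classes = sort(unique(train$subject)))
    derive_feature_subset(pol, va)$accuracy
  }, numeric(1))
  mean(accs)
}

#' Run the cumulative-day authentication protocol
#'
#' For each `k` in `days`: train on days `1..k` (z-score normalization and
#' SMOTE computed from those days only), select features with the chosen
#' selector, classify day-`test_day` beats, and report accuracy, macro F1,
#' per-subject-averaged EER and the mean number of features used. Repeated
#' `repetitions` times with derived seeds and averaged.
#'
#' Selectors: `"all"` (no selection), `"relieff"` / `"ig"` (top
#' `baseline_k` features by weight), `"rl"` (costly-feature DQN with the
#' given `hp`), `"orl"` (DQN whose architecture/optimizer are first tuned by
#' BOHB against cross-validated validation accuracy). Classifiers: `"svm"`,
#' `"rf"`, or `"dqn"` (the policy's own classification head; only with
#' `"rl"` / `"orl"`).
#'
#' @param fm labelled `feature_matrix` covering the training days and
#'   `test_day`.
#' @param selector,classifier see above.
#' @param days cumulative training-day maxima to evaluate (e.g. `1:5`).
#' @param test_day held-out day.
#' @param repetitions number of repeats to average.
#' @param seed base RNG seed.
#' @param lambda cost trade-off of the RL reward.
#' @param baseline_k subset size for ReliefF / IG (match it to the RL mean
#'   feature count for like-for-like comparisons).
#' @param smote_k SMOTE neighbour count.
#' @param hp default [hyperparam_config()] for the `"rl"` selector.
#' @param rl [qlearning_config()] used for policy training.
#' @param bohb [bohb_config()] for the `"orl"` selector.
#' @param base_episodes DQN episodes per unit of BOHB budget.
#' @param cv_folds folds of the BOHB validation objective.
#' @param subset_threshold selection-frequency threshold for the
#'   classifier-facing subset.
#' @return data.frame with one row per `k`: `train_days`, `accuracy`,
#'   `macro_f1`, `eer`, `mean_features`, `repetitions`; per-repetition
#'   details in attribute `details`.
#' @export
run_protocol <- function(fm, selector = c("rl", "orl", "relieff", "ig", "all"),
                         classifier = c("svm", "rf", "dqn"), days = 1:5,
                         test_day = 6, repetitions = 1, seed = 1L,
                         lambda = 0.01, baseline_k = 5, smote_k = 5,
                         hp = hyperparam_config(),
                         rl = qlearning_config(episodes = 400),
                         bohb = bohb_config(), base_episodes = 50,
                         cv_folds = 2, subset_threshold = 0.5) {
  selector <- match.arg(selector)
  classifier <- match.arg(classifier)
  stopifnot(inherits(fm, "feature_matrix"))
  if (!all(c(days, test_day) %in% unique(fm$day))) {
    stopf("feature matrix must cover days %s and test day %d",
          paste(days, collapse = ","), test_day)
  }
  if (classifier == "dqn" && !selector %in% c("rl", "orl")) {
    stopf("the DQN classification head requires selector 'rl' or 'orl'")
  }
  fn <- attr(fm, "feature_names")
  n <- length(fn)
  details <- list()
  rows <- lapply(days, function(k) {
    reps <- lapply(seq_len(repetitions), function(rep) {
      rs <- derive_seed(seed, k, rep)
      norm <- normalize_features(fm, train_days = seq_len(k))
      train <- norm[norm$day %in% seq_len(k), , drop = FALSE]
      test <- norm[norm$day == test_day, , drop = FALSE]
      for (obj in c("train", "test")) {
        v <- get(obj)
        attr(v, "feature_names") <- fn
        attr(v, "normalization") <- attr(norm, "normalization")
        class(v) <- c("feature_matrix", "data.frame")
        assign(obj, v)
      }
      train_s <- smote(train, k = smote_k, seed = derive_seed(rs, 2L))

      reward <- reward_config(n, lambda = lambda)
      policy <- NULL
      if (selector == "all") {
        subset <- seq_len(n)
        mean_count <- n
      } else if (selector %in% c("relieff", "ig")) {
        w <- if (selector == "relieff") {
          relieff_weights(train_s, k_neighbors = min(10, smote_k),
                          seed = derive_seed(rs, 3L))
        } else {
          info_gain(train_s)
        }
        subset <- select_top_k(w, baseline_k)
        mean_count <- baseline_k
      } else {
        hp_used <- hp
        if (selector == "orl") {
          obj <- function(hpc, budget) {
            rl_b <- rl
            rl_b$episodes <- max(50L, as.integer(round(budget * base_episodes)))
            1 - cv_dqn_accuracy(train_s, hpc, rl_b, reward,
                                folds = cv_folds, seed = derive_seed(rs, 4L))
          }
          hp_used <- run_bohb(obj, config = bohb,
                              seed = derive_seed(rs, 5L))$best
        }
        policy <- tryCatch(
          dqn_train(train_s, hp = hp_used, rl = rl, reward = reward,
                    seed = derive_seed(rs, 6L)),
          error = function(e) {
            # a tuned configuration can still diverge at full training
            # length; fall back to the default architecture
            warning("policy training failed (", conditionMessage(e),
                    "); retrying with the default configuration")
            NULL
          })
        sel <- if (is.null(policy)) NULL else {
          derive_feature_subset(policy, train_s, threshold = subset_threshold)
        }
        if (selector == "orl" && !identical(hp_used, hp)) {
          # model selection by validation accuracy: a configuration tuned at
          # reduced budgets can degenerate at full training length, so the
          # full-length tuned policy competes against the default one
          default_policy <- dqn_train(train_s, hp = hp, rl = rl,
                                      reward = reward,
                                      seed = derive_seed(rs, 6L))
          default_sel <- derive_feature_subset(default_policy, train_s,
                                               threshold = subset_threshold)
          message(sprintf(
            "orl model selection: tuned accuracy %.3f (%.1f features) vs default %.3f (%.1f features)",
            if (is.null(sel)) NA_real_ else sel$accuracy,
            if (is.null(sel)) NA_real_ else sel$mean_count,
            default_sel$accuracy, default_sel$mean_count))
          # a selector that acquires no features has failed its role; prefer
          # a non-degenerate policy, then higher greedy accuracy
          degen <- function(s) is.null(s) || s$mean_count == 0
          if (is.null(sel) ||
              (degen(sel) && !degen(default_sel)) ||
              (degen(sel) == degen(default_sel) &&
                 default_sel$accuracy > sel$accuracy)) {
            policy <- default_policy
            sel <- default_sel
          }
        }
        if (is.null(policy)) {
          stopf("policy training failed for every candidate configuration")
        }
        subset <- sel$subset
        if (length(subset) == 0) subset <- which.max(sel$frequency)
        mean_count <- sel$mean_count
      }

      if (classifier == "dqn") {
        xte <- feature_block(test)
        rolls <- lapply(seq_len(nrow(xte)), function(i) {
          dqn_rollout(policy, xte[i, ])
        })
        preds <- vapply(rolls, function(r) as.numeric(r$prediction), numeric(1))
        scores <- do.call(rbind, lapply(rolls, `[[`, "class_q"))
        colnames(scores) <- as.character(policy$space$classes)
        acc <- mean(preds == test$subject)
        f1 <- macro_f1(as.character(test$subject), as.character(preds))
        mean_count <- mean(lengths(lapply(rolls, `[[`, "features")))
      } else {
        res <- train_eval_classifier(train_s, test, subset, kind = classifier,
                                     seed = derive_seed(rs, 8L))
        acc <- res$accuracy
        f1 <- res$macro_f1
        scores <- res$scores
      }
      er <- cohort_eer(scores, as.character(test$subject))$eer
      list(accuracy = acc, macro_f1 = f1, eer = er,
           mean_features = mean_count, subset = subset,
           train_rows = nrow(train), test_rows = nrow(test))
    })
    details[[as.character(k)]] <<- reps
    data.frame(train_days = k,
               accuracy = mean(vapply(reps, `[[`, numeric(1), "accuracy")),
               macro_f1 = mean(vapply(reps, `[[`, numeric(1), "macro_f1")),
               eer = mean(vapply(reps, `[[`, numeric(1), "eer")),
               mean_features = mean(vapply(reps, `[[`, numeric(1),
                                           "mean_features")),
               repetitions = repetitions)
  })
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}
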