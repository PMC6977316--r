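#' Tanimoto similarity, 1-NN classification and model validation
#'
#' The benchmark protocol evaluates fingerprints with a 1-nearest-neighbour
#' classifier under Tanimoto similarity: ten repeats of a random
#' (class-stratified) 80/20 split, tenfold cross-validation on the training
#' portion, external validation on the held-out 20%, and the average of the
#' ten external results as the headline output. Y-randomization refits on
#' label-shuffled data and summarises the original model's separation from
#' the null as Z-scores; Z > 3 is taken as significant.
#'
#' @name benchmark
NULL

#' Tanimoto coefficient of two bit strings
#'
#' `|a AND b| / |a OR b|`; two all-zero vectors (possible when a query matches
#' no scaffold) return 0 by convention.
#'
#' @param a,b Fingerprints, 0/1 strings, or 0/1 vectors of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' tanimoto("1110", "0110") # 2/3
#' @export
tanimoto <- function(a, b) {
  a <- fp_bits(a); b <- fp_bits(b)
  if (length(a) != length(b)) {
    ncmfp_abort("Fingerprint lengths differ.", "ncmfp_length_error")
  }
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param a A 0/1 matrix (rows are fingerprints).
#' @param b Optional second matrix; defaults to `a`.
#' @return Matrix of similarities, `nrow(a)` x `nrow(b)`.
#' @export
tanimoto_matrix <- function(a, b = a) {
  if (ncol(a) != ncol(b)) {
    ncmfp_abort("Fingerprint lengths differ.", "ncmfp_length_error")
  }
  inter <- a %*% t(b)
  ra <- rowSums(a); rb <- rowSums(b)
  un <- outer(ra, rb, "+") - inter
  out <- ifelse(un == 0, 0, inter / un)
  out
}

#' 1-nearest-neighbour prediction
#'
#' Assigns each query the label of the single most similar training
#' fingerprint (Tanimoto). Ties are broken deterministically by stable input
#' order and logged.
#'
#' @param train_bits 0/1 matrix of training fingerprints.
#' @param train_labels Vector of training labels.
#' @param query_bits 0/1 matrix of query fingerprints.
#' @param sim Optional precomputed similarity matrix
#'   (`nrow(query)` x `nrow(train)`); when given, the bit matrices are unused.
#' @param quiet Suppress the tie log message.
#' @return Character vector of predicted labels.
#' @export
one_nn_predict <- function(train_bits, train_labels, query_bits, sim = NULL,
                           quiet = FALSE) {
  if (length(train_labels) == 0) {
    ncmfp_abort("Training set is empty.", "ncmfp_input_error")
  }
  if (is.null(sim)) {
    if (is.null(dim(train_bits))) train_bits <- matrix(train_bits, nrow = 1)
    if (is.null(dim(query_bits))) query_bits <- matrix(query_bits, nrow = 1)
    sim <- tanimoto_matrix(query_bits, train_bits)
  }
  n_ties <- 0L
  pred <- apply(sim, 1, function(s) {
    mx <- max(s)
    hits <- which(s == mx)
    if (length(hits) > 1 && length(unique(train_labels[hits])) > 1) {
      n_ties <<- n_ties + 1L
    }
    as.character(train_labels[hits[1]])
  })
  if (n_ties > 0 && !quiet) {
    rlang::inform(
      sprintf("1-NN: %d tie(s) broken by input order.", n_ties),
      class = "ncmfp_note"
    )
  }
  pred
}

## ---- confusion metrics -------------------------------------------------------

#' Confusion counts from truth and prediction
#'
#' @param truth,pred Label vectors.
#' @param positive The positive-class label.
#' @return A named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  list(
    TP = sum(truth == positive & pred == positive),
    FP = sum(truth != positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FN = sum(truth == positive & pred != positive)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall of the positive class), specificity,
#' precision, F1 (harmonic mean of precision and sensitivity) and the Matthews
#' correlation coefficient. Ratios with zero denominators are reported as 0
#' and flagged in the `degenerate` column.
#'
#' @param c A list or vector with elements `TP`, `FP`, `TN`, `FN`.
#' @return One-row tibble of metrics.
#' @examples
#' confusion_metrics(list(TP = 50, FP = 10, TN = 30, FN = 10))
#' @export
confusion_metrics <- function(c) {
  tp <- as.numeric(c[["TP"]]); fp <- as.numeric(c[["FP"]])
  tn <- as.numeric(c[["TN"]]); fn <- as.numeric(c[["FN"]])
  total <- tp + fp + tn + fn
  if (total <= 0) ncmfp_abort("Empty confusion table.", "ncmfp_input_error")
  safe <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- (tp + fn) == 0 || (tn + fp) == 0 || (tp + fp) == 0
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- safe(2 * prec * sens, prec + sens)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  tibble::tibble(
    accuracy = (tp + tn) / total,
    sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1, mcc = mcc,
    degenerate = degenerate
  )
}

#' Label activity from IC50
#'
#' A compound is active when its IC50 is strictly below 10 micromolar.
#'
#' @param ic50 Numeric vector of IC50 values (micromolar).
#' @param threshold Activity cut-off, default 10.
#' @return Factor with levels `active`, `inactive`.
#' @examples
#' label_activity(c(5, 10, 15)) # active, inactive, inactive
#' @export
label_activity <- function(ic50, threshold = 10) {
  if (any(is.na(ic50)) || any(ic50 < 0)) {
    ncmfp_abort("IC50 values must be present and non-negative.", "ncmfp_input_error")
  }
  factor(ifelse(ic50 < threshold, "active", "inactive"),
         levels = c("active", "inactive"))
}

## ---- split protocol ----------------------------------------------------------

#' Split-protocol settings
#'
#' @param train_fraction Fraction of the data used for training (default 0.8).
#' @param repeats Number of random splits (default 10).
#' @param cv_folds Cross-validation folds on the training portion (default 10).
#' @param seed Integer seed controlling all splits.
#' @param stratify Stratify splits by class (default `TRUE`; logged). Without
#'   stratification small datasets can produce single-class test sets.
#' @return A `split_protocol` list.
#' @export
split_protocol <- function(train_fraction = 0.8, repeats = 10L, cv_folds = 10L,
                           seed = 1L, stratify = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1, repeats >= 1)
  structure(
    list(
      train_fraction = train_fraction, repeats = as.integer(repeats),
      cv_folds = as.integer(cv_folds), seed = as.integer(seed),
      stratify = isTRUE(stratify)
    ),
    class = "split_protocol"
  )
}

# Rows are put in a canonical order (label, then bit string) before any
# seeded draw, so results do not depend on how the input happened to be
# sorted; rows with identical label and fingerprint are interchangeable.
canonical_row_order <- function(data) {
  data[order(as.character(data$label), data$bits), , drop = FALSE]
}

# stratified (or plain) index split; returns train indices
draw_train_idx <- function(labels, frac, stratify) {
  n <- length(labels)
  if (!stratify) return(sort(sample.int(n, round(frac * n))))
  idx <- unlist(lapply(split(seq_len(n), labels), function(ix) {
    k <- round(frac * length(ix))
    k <- max(1L, min(length(ix) - 1L, k))
    sample(ix, k)
  }), use.names = FALSE)
  sort(idx)
}

# fold assignment for CV, stratified
draw_folds <- function(labels, k, stratify) {
  n <- length(labels)
  fold <- integer(n)
  groups <- if (stratify) split(seq_len(n), labels) else list(seq_len(n))
  for (ix in groups) {
    fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# protocol engine over a precomputed similarity matrix (labels can be
# shuffled without recomputing similarities, which Y-randomization exploits)
run_protocol_sim <- function(sim, labels, protocol, positive) {
  n <- length(labels)
  reps <- list()
  for (r in seq_len(protocol$repeats)) {
    tr <- draw_train_idx(labels, protocol$train_fraction, protocol$stratify)
    te <- setdiff(seq_len(n), tr)
    # tenfold CV within the training portion
    fold <- draw_folds(labels[tr], protocol$cv_folds, protocol$stratify)
    cv_pred <- character(length(tr))
    for (f in seq_len(protocol$cv_folds)) {
      hold <- which(fold == f)
      if (length(hold) == 0) next
      fit <- tr[-hold]
      cv_pred[hold] <- one_nn_predict(
        NULL, labels[fit], NULL,
        sim = sim[tr[hold], fit, drop = FALSE], quiet = TRUE
      )
    }
    cv_m <- confusion_metrics(confusion_counts(labels[tr], cv_pred, positive))
    # external validation
    ext_pred <- one_nn_predict(
      NULL, labels[tr], NULL, sim = sim[te, tr, drop = FALSE], quiet = TRUE
    )
    ext_m <- confusion_metrics(confusion_counts(labels[te], ext_pred, positive))
    reps[[r]] <- dplyr::bind_rows(
      dplyr::mutate(cv_m, phase = "cv"),
      dplyr::mutate(ext_m, phase = "external")
    ) |> dplyr::mutate(repeat_ = r, n_train = length(tr), n_test = length(te))
  }
  per_repeat <- dplyr::bind_rows(reps)
  metrics <- c("accuracy", "sensitivity", "specificity", "precision", "f1", "mcc")
  average <- dplyr::summarise(
    dplyr::group_by(per_repeat, .data$phase),
    dplyr::across(dplyr::all_of(metrics), mean), .groups = "drop"
  )
  list(per_repeat = per_repeat, average = average)
}

#' Run the repeated split benchmark on labelled fingerprints
#'
#' For each of `repeats` seeded random splits: an 80/20 train/external split
#' (stratified by class), tenfold cross-validation within the training
#' portion, and 1-NN Tanimoto prediction of the external set. The average of
#' the external-validation metrics over the repeats is the headline result
#' (the CV metrics are reported for protocol fidelity; a 1-NN model has no
#' hyperparameters to tune).
#'
#' @param data A data frame with columns `label` and `bits` (0/1 strings from
#'   [ncmfp_fingerprints()]), or `label` plus a fingerprint matrix in
#'   `attr(data, "bits")`.
#' @param protocol A [split_protocol()].
#' @param positive Positive-class label (defaults to `"active"` when present,
#'   otherwise the first label).
#' @return An `ncmfp_task` with per-repeat and averaged metric sets; see
#'   [tidy.ncmfp_task()] and [glance.ncmfp_task()].
#' @export
run_split_protocol <- function(data, protocol = split_protocol(), positive = NULL) {
  data <- canonical_row_order(data)
  labels <- as.character(data$label)
  if (length(unique(labels)) < 2) {
    ncmfp_abort("Need at least two classes.", "ncmfp_input_error")
  }
  if (nrow(data) < 10) {
    ncmfp_abort("Need at least 10 records.", "ncmfp_input_error")
  }
  if (is.null(positive)) {
    positive <- if ("active" %in% labels) "active" else labels[1]
  }
  bits <- fp_matrix(data)
  sim <- tanimoto_matrix(bits)
  res <- withr::with_seed(
    protocol$seed,
    run_protocol_sim(sim, labels, protocol, positive)
  )
  structure(
    list(
      per_repeat = res$per_repeat, average = res$average,
      protocol = protocol, positive = positive, n = nrow(data)
    ),
    class = "ncmfp_task"
  )
}

#' @export
print.ncmfp_task <- function(x, ...) {
  cat(sprintf(
    "<ncmfp_task> %d records, %d repeats (positive class: %s)\n",
    x$n, x$protocol$repeats, x$positive
  ))
  print(x$average)
  invisible(x)
}

#' Per-repeat benchmark metrics
#' @param x An `ncmfp_task`.
#' @param ... Unused.
#' @method tidy ncmfp_task
#' @export
tidy.ncmfp_task <- function(x, ...) x$per_repeat

#' Averaged external-validation metrics (one row)
#' @param x An `ncmfp_task`.
#' @param ... Unused.
#' @method glance ncmfp_task
#' @export
glance.ncmfp_task <- function(x, ...) {
  out <- x$average[x$average$phase == "external", , drop = FALSE]
  out$phase <- NULL
  out$n <- x$n
  out$repeats <- x$protocol$repeats
  out
}

#' Plot per-repeat external metrics
#' @param object An `ncmfp_task`.
#' @param ... Unused.
#' @method autoplot ncmfp_task
#' @export
autoplot.ncmfp_task <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$per_repeat[object$per_repeat$phase == "external", ],
    cols = c("accuracy", "sensitivity", "specificity", "f1", "mcc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "external validation") +
    ggplot2::theme_minimal()
}

## ---- Y-randomization ----------------------------------------------------------

yrand_z <- function(ori, rand_mean, rand_sd) {
  if (is.na(rand_sd) || rand_sd == 0) return(NA_real_)
  (ori - rand_mean) / rand_sd
}

#' Y-randomization significance test
#'
#' Re-runs the split protocol on copies of the data whose labels have been
#' randomly shuffled, and compares the original model's accuracy and MCC with
#' the mean and standard deviation of the shuffled reruns as Z-scores. A model
#' whose Z-score exceeds 3 is considered unique and statistically significant
#' against chance.
#'
#' @inheritParams run_split_protocol
#' @param rounds Number of label-shuffling rounds (default 100).
#' @return An `ncmfp_yrand` object; `glance()` gives the one-row summary.
#' @export
y_randomization <- function(data, protocol = split_protocol(), rounds = 100L,
                            positive = NULL) {
  if (rounds < 2) ncmfp_abort("Need at least 2 rounds.", "ncmfp_input_error")
  data <- canonical_row_order(data)
  labels <- as.character(data$label)
  if (is.null(positive)) {
    positive <- if ("active" %in% labels) "active" else labels[1]
  }
  bits <- fp_matrix(data)
  sim <- tanimoto_matrix(bits)
  ext <- function(lab) {
    force(lab) # must be drawn before the seeded protocol rerun
    res <- withr::with_seed(
      protocol$seed,
      run_protocol_sim(sim, lab, protocol, positive)
    )
    res$average[res$average$phase == "external", c("accuracy", "mcc")]
  }
  ori <- ext(labels)
  rand <- withr::with_seed(protocol$seed + 1L, {
    dplyr::bind_rows(lapply(seq_len(rounds), function(r) ext(sample(labels))))
  })
  out <- list(
    acc_ori = ori$accuracy, mcc_ori = ori$mcc,
    acc_rand_mean = mean(rand$accuracy), mcc_rand_mean = mean(rand$mcc),
    acc_rand_sd = stats::sd(rand$accuracy), mcc_rand_sd = stats::sd(rand$mcc),
    rounds = rounds, per_round = rand
  )
  out$z_acc <- yrand_z(out$acc_ori, out$acc_rand_mean, out$acc_rand_sd)
  out$z_mcc <- yrand_z(out$mcc_ori, out$mcc_rand_mean, out$mcc_rand_sd)
  out$degenerate <- is.na(out$z_acc) || is.na(out$z_mcc)
  structure(out, class = "ncmfp_yrand")
}

#' @export
print.ncmfp_yrand <- function(x, ...) {
  cat(sprintf(
    "<ncmfp_yrand> %d rounds: Z_MCC = %.2f, Z_ACC = %.2f%s\n",
    x$rounds, x$z_mcc, x$z_acc,
    if (isTRUE(x$degenerate)) " (degenerate: zero spread)" else ""
  ))
  invisible(x)
}

#' Per-round shuffled metrics
#' @param x An `ncmfp_yrand`.
#' @param ... Unused.
#' @method tidy ncmfp_yrand
#' @export
tidy.ncmfp_yrand <- function(x, ...) x$per_round

#' One-row Y-randomization summary
#' @param x An `ncmfp_yrand`.
#' @param ... Unused.
#' @method glance ncmfp_yrand
#' @export
glance.ncmfp_yrand <- function(x, ...) {
  tibble::tibble(
    acc_ori = x$acc_ori, mcc_ori = x$mcc_ori,
    acc_rand_mean = x$acc_rand_mean, mcc_rand_mean = x$mcc_rand_mean,
    acc_rand_sd = x$acc_rand_sd, mcc_rand_sd = x$mcc_rand_sd,
    z_acc = x$z_acc, z_mcc = x$z_mcc,
    rounds = x$rounds,
    significant = !is.na(x$z_mcc) && x$z_mcc > 3
  )
}
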