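# Evaluation protocols: repeated random subsampling and repeated K-fold
# cross validation, plus the experiment driver that trains single-modal
# networks (and, for two or more modalities, the fused classifier) inside
# every split with standardization refit on the training portion only.

#' Evaluation protocol configuration
#'
#' Defaults follow the reference protocols: 1000 training and 1000 test
#' samples drawn without replacement, repeated 20 times; or 7-fold cross
#' validation (K equal to the number of classes) repeated 10 times.
#'
#' @param protocol `"random_subsample"` or `"kfold"`.
#' @param n_train,n_test sample counts for the subsampling protocol.
#' @param repetitions number of repetitions (default 20 for subsampling,
#'   10 for K-fold).
#' @param K number of folds.
#' @param seed master seed for split generation and per-fit seeds.
#' @param stratify stratify splits by class (keeps small synthetic runs from
#'   losing a class entirely; disable to match unstratified draws).
#' @return an object of class `gait_protocol`.
#' @export
protocol_config <- function(protocol = c("random_subsample", "kfold"),
                            n_train = 1000L, n_test = 1000L,
                            repetitions = NULL, K = 7L, seed = 1L,
                            stratify = TRUE) {
  protocol <- match.arg(protocol)
  repetitions <- repetitions %||% if (protocol == "kfold") 10L else 20L
  abort_if(K < 2, "K must be >= 2")
  abort_if(repetitions < 1, "repetitions must be >= 1")
  structure(list(protocol = protocol, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), repetitions = as.integer(repetitions),
                 K = as.integer(K), seed = as.integer(seed), stratify = stratify),
            class = "gait_protocol")
}

#' Partition indices into K folds
#'
#' Random partition of `1:n` into `K` disjoint folds whose sizes differ by
#' at most one; the union covers every index exactly once. For each fold the
#' training set is the complement.
#'
#' @param n total number of samples (>= K).
#' @param K number of folds.
#' @param seed integer seed.
#' @return list of K integer index vectors.
#' @export
#' @examples
#' lengths(split_kfold(13531, 7, seed = 1))   # all 1933
split_kfold <- function(n, K, seed = 1L) {
  abort_if(n < K, "cannot make %d folds from %d samples", K, n)
  sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  with_seed(seed, {
    idx <- sample.int(n)
    unname(lapply(split(idx, rep(seq_len(K), times = sizes)), unname))
  })
}

#' Repeated disjoint train/test draws
#'
#' Per repetition, draws `n_train + n_test` distinct indices without
#' replacement and splits them into disjoint training and test sets;
#' repetitions use independently derived seeds.
#'
#' @param n total number of samples.
#' @param n_train,n_test sizes of the two draws.
#' @param repetitions number of repetitions.
#' @param seed master seed.
#' @return list of `repetitions` lists with integer vectors `train`, `test`.
#' @export
split_random_subsample <- function(n, n_train, n_test, repetitions, seed = 1L) {
  abort_if(n_train + n_test > n,
           "n_train + n_test = %d exceeds the dataset size %d", n_train + n_test, n)
  seeds <- derive_seeds(seed, repetitions)
  lapply(seq_len(repetitions), function(r) {
    with_seed(seeds[r], {
      idx <- sample.int(n, n_train + n_test)
      list(train = idx[seq_len(n_train)], test = idx[n_train + seq_len(n_test)])
    })
  })
}

# Class-stratified variants used by run_experiment().
stratified_kfold <- function(labels, K, seed = 1L) {
  folds <- rep(list(integer(0)), K)
  seeds <- derive_seeds(seed, length(unique(labels)) + 1L)
  offset <- 0L
  for (ci in seq_along(sort(unique(labels)))) {
    cl <- sort(unique(labels))[ci]
    idx <- with_seed(seeds[ci], sample(which(labels == cl)))
    assign_to <- ((seq_along(idx) - 1L + offset) %% K) + 1L
    for (f in seq_len(K)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    offset <- (offset + length(idx)) %% K      # rotate so fold sizes balance
  }
  folds
}

stratified_subsample <- function(labels, n_train, n_test, repetitions, seed = 1L) {
  classes <- sort(unique(labels))
  n_class <- length(classes)
  alloc <- function(total, from_front) {
    base <- rep(total %/% n_class, n_class)
    extra <- total - sum(base)
    if (extra > 0) {
      who <- if (from_front) seq_len(extra) else n_class + 1L - seq_len(extra)
      base[who] <- base[who] + 1L
    }
    base
  }
  # train extras fill from the first class, test extras from the last, so a
  # perfectly balanced dataset can be split exhaustively
  a_tr <- alloc(n_train, TRUE); a_te <- alloc(n_test, FALSE)
  seeds <- derive_seeds(seed, repetitions)
  lapply(seq_len(repetitions), function(r) {
    with_seed(seeds[r], {
      tr <- integer(0); te <- integer(0)
      for (ci in seq_len(n_class)) {
        pool <- sample(which(labels == classes[ci]))
        abort_if(length(pool) < a_tr[ci] + a_te[ci],
                 "class %s has only %d samples; %d requested",
                 classes[ci], length(pool), a_tr[ci] + a_te[ci])
        tr <- c(tr, pool[seq_len(a_tr[ci])])
        te <- c(te, pool[a_tr[ci] + seq_len(a_te[ci])])
      }
      list(train = tr, test = te)
    })
  })
}

#' Classification accuracy
#'
#' Fraction of predictions matching the true labels.
#'
#' @param predicted,truth equal-length, non-empty label vectors (codes or
#'   names, compared element-wise).
#' @return accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(predicted, truth) {
  abort_if(length(predicted) != length(truth),
           "predicted (%d) and truth (%d) lengths differ",
           length(predicted), length(truth))
  abort_if(length(predicted) == 0, "cannot compute accuracy of empty vectors")
  mean(predicted == truth)
}

#' Run a full classification experiment
#'
#' For each repetition (and, under K-fold, each fold): split the samples,
#' refit standardization on the training portion, train one single-modal
#' DCNN per requested modality, fuse them if two or more modalities are
#' requested, predict the test portion and score it. Per-fit seeds are
#' derived deterministically from the protocol seed.
#'
#' @param samples a `gait_samples` dataset.
#' @param protocol a [protocol_config()].
#' @param modalities character vector of modality names to use.
#' @param config a [train_config()] applied to every fit (single-modal nets
#'   and the fused head alike).
#' @param model_args named list of extra arguments passed to
#'   [build_single_modal()] (e.g. `fc_sizes`, `dropout`).
#' @return an object of class `gait_experiment` with per-repetition
#'   accuracies, their mean and standard deviation, a pooled 7x7 confusion
#'   matrix (rows = true class, columns = predicted), and the seeds used.
#' @export
run_experiment <- function(samples, protocol = protocol_config(),
                           modalities = c("pressure", "accel", "gyro"),
                           config = train_config(), model_args = list()) {
  abort_if(!all(modalities %in% modality_names(samples)),
           "samples lack modalit(y/ies): %s",
           paste(setdiff(modalities, modality_names(samples)), collapse = ", "))
  n <- n_samples(samples)
  labels <- samples$label
  split_seeds <- derive_seeds(protocol$seed, protocol$repetitions + 1L)
  splits <- list()
  if (protocol$protocol == "random_subsample") {
    splits <- if (protocol$stratify)
      stratified_subsample(labels, protocol$n_train, protocol$n_test,
                           protocol$repetitions, seed = split_seeds[1])
    else split_random_subsample(n, protocol$n_train, protocol$n_test,
                                protocol$repetitions, seed = split_seeds[1])
  } else {
    for (r in seq_len(protocol$repetitions)) {
      folds <- if (protocol$stratify) stratified_kfold(labels, protocol$K, split_seeds[r])
               else split_kfold(n, protocol$K, split_seeds[r])
      for (f in seq_len(protocol$K)) {
        splits[[length(splits) + 1L]] <-
          list(train = unlist(folds[-f], use.names = FALSE), test = folds[[f]])
      }
    }
  }
  fit_seeds <- derive_seeds(split_seeds[protocol$repetitions + 1L],
                            length(splits) * (length(modalities) + 1L))
  accs <- numeric(length(splits))
  confusion <- matrix(0L, 7, 7, dimnames = list(true = gait_types(),
                                                predicted = gait_types()))
  details <- vector("list", length(splits))
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    std <- standardize_samples(subset_samples(samples, sp$train),
                               subset_samples(samples, sp$test))
    nets <- vector("list", length(modalities))
    for (mi in seq_along(modalities)) {
      seed_i <- fit_seeds[(si - 1L) * (length(modalities) + 1L) + mi]
      args <- c(list(modality = modalities[mi], k = samples$k, t = samples$t,
                     width = dim(samples[[modalities[mi]]])[3], seed = seed_i),
                model_args)
      net <- do.call(build_single_modal, args)
      cfg <- config; cfg$seed <- seed_i
      nets[[mi]] <- train_model(net, std$train, cfg)
    }
    model <- if (length(modalities) == 1) nets[[1]] else {
      seed_f <- fit_seeds[si * (length(modalities) + 1L)]
      fused <- build_multi_modal(nets,
                                 fc_sizes = model_args$fc_sizes %||% c(256L, 128L),
                                 dropout = model_args$dropout %||% 0.5,
                                 seed = seed_f)
      cfg <- config; cfg$seed <- seed_f
      train_model(fused, std$train, cfg)
    }
    pred <- predict(model, std$test)
    accs[si] <- evaluate_accuracy(pred$code, std$test$label)
    tab <- table(factor(std$test$label, levels = 0:6),
                 factor(pred$code, levels = 0:6))
    confusion <- confusion + as.matrix(tab)
    details[[si]] <- list(n_train = length(sp$train), n_test = length(sp$test),
                          accuracy = accs[si])
  }
  structure(list(accuracies = accs, mean_accuracy = mean(accs),
                 sd_accuracy = if (length(accs) > 1) stats::sd(accs) else 0,
                 confusion = confusion, modalities = modalities,
                 k = samples$k, protocol = protocol, details = details,
                 seeds = list(split = split_seeds, fit = fit_seeds)),
            class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat(sprintf("<gait_experiment> %s, k=%d, %s: accuracy %.4f +/- %.4f over %d fit(s)\n",
              paste(x$modalities, collapse = "+"), x$k, x$protocol$protocol,
              x$mean_accuracy, x$sd_accuracy, length(x$accuracies)))
  invisible(x)
}
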