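# Behavioral-state and sequence-type decoders with size-matched and
# time-randomized controls.

tree_control <- function() {
  rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0, xval = 0,
                       maxcompete = 0, maxsurrogate = 0)
}

accuracy_z <- function(acc, chance, alternative = "greater") {
  m <- mean(acc); s <- stats::sd(acc)
  z <- if (s > 0) (m - chance) / s else sign(m - chance) * Inf
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(mean = m, sd = s, z = z, p = p)
}

#' Decode behavioral state from sequence features
#'
#' Repeatedly splits the sequences into 75% training and 25% testing data,
#' fits an axis-aligned decision tree predicting the male partner's state
#' from the latency and duration of the interaction, and measures test
#' accuracy, yielding a distribution of accuracies compared to chance (50%)
#' with a one-sided z-test `z = (mean - chance) / sd`.
#'
#' Conditions: `"observed"` uses the sequences as given; `"size_matched"`
#' subsamples the majority class to the minority size in every iteration;
#' `"randomized"` rebuilds the sequences per iteration after uniformly
#' redrawing the trigger times (requires `events`, `interactions` and
#' `recording_length`), destroying the temporal linkage.
#'
#' @param sequences Sequence table.
#' @param features Feature column names.
#' @param label_col Class column (default `partner_state`).
#' @param split Training fraction.
#' @param n_iter Iterations.
#' @param condition "observed", "size_matched" or "randomized".
#' @param seed RNG seed.
#' @param events,interactions,recording_length Needed for the randomized
#'   condition; `kind` is the trigger kind passed to the extractor.
#' @param kind Trigger kind for rebuilding ("aggressive" by default).
#' @param fps Frames per second.
#' @return A `decoder_run`: list with `condition`, `accuracies` (percent),
#'   `mean`, `sd`, `chance`, `z`, `p`, `n_iterations`.
#' @export
decode_state <- function(sequences, features = c("latency_s", "duration_s"),
                         label_col = "partner_state", split = 0.75,
                         n_iter = 1000,
                         condition = c("observed", "size_matched", "randomized"),
                         seed = NULL, events = NULL, interactions = NULL,
                         recording_length = NULL, kind = "aggressive",
                         fps = 30) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  if (condition != "randomized") {
    if (nrow(sequences) < 20) stop("decode_state needs at least 20 sequences")
    check_two_class(sequences[[label_col]])
  } else if (is.null(events) || is.null(interactions) ||
             is.null(recording_length)) {
    stop("randomized condition needs events, interactions and recording_length")
  }
  trig_labels <- if (kind == "aggressive") c("chase", "flee") else kind
  acc <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    d <- sequences
    if (condition == "randomized") {
      ev <- randomize_event_times(events, recording_length)
      trg <- ev[ev$label %in% trig_labels, , drop = FALSE]
      d <- extract_triggered_sequences(trg, interactions, fps = fps, kind = kind)
      if (nrow(d) < 8 || length(unique(d[[label_col]])) < 2) {
        acc[it] <- NA; next
      }
    }
    if (condition == "size_matched") d <- size_match(d, label_col)
    acc[it] <- tree_split_accuracy(d, features, label_col, split)
  }
  acc <- acc[!is.na(acc)]
  stats <- accuracy_z(acc, 50)
  structure(list(condition = condition, features = features,
                 accuracies = acc, mean = stats$mean, sd = stats$sd,
                 chance = 50, z = stats$z, p = stats$p,
                 n_iterations = length(acc)),
            class = "decoder_run")
}

check_two_class <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("decoding needs at least two classes in the data")
}

size_match <- function(d, label_col) {
  tab <- table(d[[label_col]])
  n_min <- min(tab)
  idx <- unlist(lapply(names(tab), function(cl) {
    rows <- which(d[[label_col]] == cl)
    if (length(rows) > n_min) sample(rows, n_min) else rows
  }))
  d[idx, , drop = FALSE]
}

tree_split_accuracy <- function(d, features, label_col, split) {
  n <- nrow(d)
  tr_idx <- sample.int(n, max(2, floor(split * n)))
  train <- d[tr_idx, c(features, label_col)]
  test <- d[-tr_idx, c(features, label_col)]
  if (nrow(test) == 0 || length(unique(train[[label_col]])) < 2) return(NA)
  train[[label_col]] <- factor(train[[label_col]])
  fml <- stats::as.formula(paste(label_col, "~",
                                 paste(features, collapse = "+")))
  fit <- rpart::rpart(fml, data = train, method = "class",
                      control = tree_control())
  pred <- predict(fit, newdata = test, type = "class")
  100 * mean(as.character(pred) == test[[label_col]])
}

#' Multiclass margin-based decoding
#'
#' Repeated 75/25 split decoding with a linear-kernel support-vector
#' machine (one-vs-one ensemble), for multiclass targets such as the hour
#' of occurrence (chance 20%) or the three-step sequence type (chance 25%).
#' A size-matched variant subsamples every class to the smallest class.
#'
#' @param data data.frame of samples.
#' @param features Feature column names (factors are allowed and expanded
#'   by the SVM).
#' @param label_col Class column.
#' @param n_iter Iterations.
#' @param split Training fraction.
#' @param size_matched Subsample all classes to the smallest class size.
#' @param shuffle_labels Permute class labels each iteration (randomization
#'   control).
#' @param chance Chance accuracy in percent; defaults to `100 / #classes`.
#' @param seed RNG seed.
#' @return A `decoder_run` (see [decode_state()]).
#' @export
decode_multiclass <- function(data, features, label_col, n_iter = 1000,
                              split = 0.75, size_matched = FALSE,
                              shuffle_labels = FALSE, chance = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- factor(data[[label_col]])
  k <- nlevels(labels)
  if (k < 2) stop("decoding needs at least two classes")
  if (is.null(chance)) chance <- 100 / k
  if (size_matched && any(table(labels) < 4))
    stop("size-matched decoding needs at least 4 examples per class")
  data[[label_col]] <- labels
  acc <- numeric(n_iter)
  fml <- stats::as.formula(paste(label_col, "~",
                                 paste(features, collapse = "+")))
  for (it in seq_len(n_iter)) {
    d <- data
    if (shuffle_labels) d[[label_col]] <- sample(d[[label_col]])
    if (size_matched) d <- size_match(d, label_col)
    n <- nrow(d)
    tr_idx <- sample.int(n, max(k, floor(split * n)))
    train <- d[tr_idx, , drop = FALSE]
    test <- d[-tr_idx, , drop = FALSE]
    if (nrow(test) == 0 || nlevels(droplevels(train[[label_col]])) < 2) {
      acc[it] <- NA; next
    }
    train[[label_col]] <- droplevels(train[[label_col]])
    fit <- e1071::svm(fml, data = train, kernel = "linear", scale = TRUE)
    pred <- predict(fit, newdata = test)
    acc[it] <- 100 * mean(as.character(pred) == as.character(test[[label_col]]))
  }
  acc <- acc[!is.na(acc)]
  stats <- accuracy_z(acc, chance)
  structure(list(condition = if (shuffle_labels) "randomized"
                 else if (size_matched) "size_matched" else "observed",
                 features = features, accuracies = acc, mean = stats$mean,
                 sd = stats$sd, chance = chance, z = stats$z, p = stats$p,
                 n_iterations = length(acc)),
            class = "decoder_run")
}

#' @export
print.decoder_run <- function(x, ...) {
  cat(sprintf("decoder [%s]: mean accuracy %.1f%% (sd %.1f), chance %.0f%%, z = %.2f, p = %.3g (n = %d)\n",
              x$condition, x$mean, x$sd, x$chance, x$z, x$p, x$n_iterations))
  invisible(x)
}
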