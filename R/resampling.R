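#' Split-half cross-validated attribution
#'
#' The reliability check for the discriminant keys: each group is divided in
#' half at random (stratified), the discriminant is fitted on one half and the
#' held-out half is classified.
#'
#' @param data data.frame with a group column and the feature columns.
#' @param features feature column names.
#' @param group group column name (default `"group"`).
#' @param prior passed to [dfa()] (default `"equal"`).
#' @param seed integer seed controlling the random split.
#' @return list with `percent_correct`, `confusion` (held-out half), and
#'   `n_train`/`n_test`.
#' @export
split_half_cv <- function(data, features, group = "group", prior = "equal",
                          seed = NULL) {
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) != 2L) stop_volecall("split_half_cv needs two groups")
  if (any(table(g) < 4L))
    stop_volecall("each group needs at least 4 rows to split in half")
  with_seed(seed, {
    train_idx <- unlist(lapply(levels(g), function(l) {
      idx <- which(g == l)
      sample(idx, floor(length(idx) / 2))
    }))
    train <- data[train_idx, , drop = FALSE]
    test <- data[-train_idx, , drop = FALSE]
    fit <- dfa(train[features], train[[group]], prior = prior)
    res <- classify(fit, test, group = group)
    list(percent_correct = res$percent_correct, confusion = res$confusion,
         n_train = nrow(train), n_test = nrow(test))
  })
}

#' Randomization chance level for the attribution percentage
#'
#' The no-information baseline against which an observed attribution
#' percentage is judged: group labels are permuted (preserving the group
#' sizes), the discriminant is refitted and its resubstitution percent correct
#' recorded, `n_reps` times. Reported as mean +/- SE over replicates.
#'
#' @inheritParams split_half_cv
#' @param n_reps number of label permutations (default 100).
#' @return object of class `randomization_null`: list with `mean_percent`,
#'   `se_percent`, `n_reps`, `per_rep`.
#' @export
randomization_null <- function(data, features, group = "group",
                               prior = "equal", n_reps = 100, seed = NULL) {
  if (n_reps < 2) stop_volecall("n_reps must be at least 2")
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) != 2L) stop_volecall("randomization_null needs two groups")
  x <- data[features]
  with_seed(seed, {
    per_rep <- vapply(seq_len(n_reps), function(r) {
      perm <- sample(g)
      fit <- dfa(x, perm, prior = prior)
      d <- cbind(x, group = perm)
      classify(fit, d, group = "group")$percent_correct
    }, numeric(1))
    structure(list(mean_percent = mean(per_rep),
                   se_percent = stats::sd(per_rep) / sqrt(n_reps),
                   n_reps = n_reps, per_rep = per_rep),
              class = "randomization_null")
  })
}

#' @export
print.randomization_null <- function(x, ...) {
  cat(sprintf("Randomization chance level: %.2f +/- %.2f%% (n = %d)\n",
              x$mean_percent, x$se_percent, x$n_reps))
  invisible(x)
}
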