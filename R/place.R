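# Place recognition: can the 25-D codes alone tell apart the locations at
# which echoes were collected?

#' Train the place-recognition network
#'
#' Trains a softmax classifier ([place_net_spec()]) on encoded echoes
#' labeled by location, with a stratified train/test split, and reports
#' held-out accuracy and the confusion matrix.
#'
#' @param codes Numeric matrix of codes (one per row).
#' @param labels Location labels (factor or character), one per row.
#' @param spec An [mlp_spec()]; default [place_net_spec()] sized to the
#'   number of locations.
#' @param split Fraction of each class used for training (default 0.8).
#' @param seed RNG seed for the split.
#' @param in_sample Also report training-set accuracy (the "memorization"
#'   reading of the task).
#' @return A list with the trained `model`, held-out `accuracy`, the
#'   `confusion` matrix (true class in rows), the split indices and, if
#'   requested, `accuracy_in_sample`.
#' @export
train_place_net <- function(codes, labels, spec = NULL, split = 0.8,
                            seed = 1L, in_sample = FALSE) {
  codes <- as.matrix(codes)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two locations")
  if (nrow(codes) != length(labels)) stop("`codes` and `labels` sizes differ")
  if (is.null(spec))
    spec <- place_net_spec(n_classes = nlevels(labels), seed = seed)
  idx_train <- with_rng_seed(seed, {
    unlist(lapply(levels(labels), function(l) {
      ix <- which(labels == l)
      if (length(ix) < 2L)
        stop(sprintf("location %s has fewer than 2 echoes", l))
      sample(ix, max(1L, round(split * length(ix))))
    }))
  })
  idx_test <- setdiff(seq_along(labels), idx_train)
  if (any(!levels(labels) %in% labels[idx_train]))
    stop("a location is missing from the training split")
  model <- mlp_train(codes[idx_train, , drop = FALSE], labels[idx_train], spec)
  predict_class <- function(ix) {
    p <- mlp_predict(model, codes[ix, , drop = FALSE])
    factor(levels(labels)[max.col(p)], levels = levels(labels))
  }
  pred <- predict_class(idx_test)
  confusion <- table(true = labels[idx_test], predicted = pred)
  out <- list(model = model,
              accuracy = mean(pred == labels[idx_test]),
              confusion = confusion,
              idx_train = idx_train, idx_test = idx_test)
  if (in_sample)
    out$accuracy_in_sample <- mean(predict_class(idx_train) ==
                                     labels[idx_train])
  out
}

#' Per-class error attribution from a confusion matrix
#'
#' @param confusion Square nonnegative count matrix (true class in rows).
#' @param top Number of top confusion pairs to list.
#' @return A list with `rates` (row-normalized confusion), `class_error`
#'   (per-class error rate) and `top_confusions` (data frame of the most
#'   frequent misclassifications).
#' @export
confusion_report <- function(confusion, top = 10L) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || any(cm < 0) || any(cm != round(cm)))
    stop("`confusion` must be a square nonnegative integer matrix")
  n <- rowSums(cm)
  rates <- sweep(cm, 1L, pmax(n, 1L), "/")
  class_error <- 1 - diag(rates)
  off <- cm
  diag(off) <- 0L
  ix <- which(off > 0, arr.ind = TRUE)
  tc <- data.frame(true = rownames(cm)[ix[, 1]],
                   predicted = colnames(cm)[ix[, 2]],
                   count = off[ix],
                   rate = rates[cbind(ix[, 1], ix[, 2])])
  tc <- tc[order(-tc$count), , drop = FALSE]
  rownames(tc) <- NULL
  list(rates = rates, class_error = class_error,
       top_confusions = utils::head(tc, top))
}
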