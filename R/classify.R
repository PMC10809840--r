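#' Build per-subject observations for a classification scheme
#'
#' The three schemes mirror the clinical questions: (1) seizure vs
#' nonseizure period, (2) starting stage S1 vs nonseizure, (3) end stage
#' S3 vs starting stage S1. One observation per subject and class is
#' formed as the median of the feature over that subject's epochs in the
#' class, on a single contact (default C4-P4, the contact with the best
#' global discriminability) or per contact.
#'
#' @param table feature table (several subjects).
#' @param feature feature name.
#' @param scheme 1, 2 or 3.
#' @param fusion agreement level (default 3: consensus of all raters).
#' @param contact contact label, or `NULL` to pool all contacts (medians
#'   are then taken over all epochs of all contacts).
#' @return Data frame `subject`, `class` (factor, negative level first),
#'   `value`. Subjects missing a class are excluded with a message.
#' @export
make_observations <- function(table, feature = "sharpness", scheme = 1,
                              fusion = 3, contact = "C4-P4") {
  stopifnot(scheme %in% 1:3)
  df <- table[table$feature == feature & table$fusion == fusion &
                is.finite(table$value), ]
  if (!is.null(contact)) {
    df <- df[df$channel == contact, ]
    if (!nrow(df)) stop("contact ", contact, " not present in table")
  }
  sel <- switch(scheme,
    list(pos = df$period == "seizure", neg = df$period == "nonseizure",
         lev = c("nonseizure", "seizure")),
    list(pos = df$label == "S1", neg = df$period == "nonseizure",
         lev = c("nonseizure", "S1")),
    list(pos = df$label == "S3", neg = df$label == "S1",
         lev = c("S1", "S3")))
  med <- function(keep, cls) {
    sub <- df[keep, ]
    if (!nrow(sub)) return(NULL)
    ag <- stats::aggregate(value ~ subject, data = sub, FUN = stats::median)
    ag$class <- cls
    ag
  }
  obs <- rbind(med(sel$neg, sel$lev[1]), med(sel$pos, sel$lev[2]))
  if (is.null(obs) || length(unique(obs$class)) < 2)
    stop("scheme ", scheme, ": one of the classes is empty")
  keep <- names(which(base::table(obs$subject) == 2))
  dropped <- setdiff(unique(obs$subject), keep)
  if (length(dropped))
    message("excluded subject(s) missing a class: ",
            paste(dropped, collapse = ", "))
  obs <- obs[obs$subject %in% keep, ]
  if (length(unique(obs$class)) < 2)
    stop("scheme ", scheme, ": one of the classes is empty")
  data.frame(subject = obs$subject,
             class = factor(obs$class, levels = sel$lev),
             value = obs$value)
}

# ROC curve and AUC with a fixed orientation: higher score = positive
# (second) level, so relabelling the truth maps AUC to 1 - AUC
.roc_auc <- function(truth, score, levels) {
  roc <- pROC::roc(response = truth, predictor = score, levels = levels,
                   direction = "<", quiet = TRUE)
  list(curve = data.frame(fpr = rev(1 - roc$specificities),
                          tpr = rev(roc$sensitivities)),
       auc = as.numeric(pROC::auc(roc)))
}

# stratified index split: ~frac of each class for training
.stratified_split <- function(y, frac = 0.8) {
  tr <- unlist(lapply(levels(y), function(l) {
    idx <- which(y == l)
    n_tr <- max(1, min(length(idx) - 1, round(frac * length(idx))))
    sample(idx, n_tr)
  }))
  sort(tr)
}

# decision scores for the positive (second) class
.fit_score <- function(type, xtr, ytr, xte, pars) {
  pos <- levels(ytr)[2]
  tr <- data.frame(x = xtr, y = ytr)
  te <- data.frame(x = xte)
  switch(type,
    svm = {
      fit <- e1071::svm(y ~ x, data = tr, kernel = "radial",
                        cost = pars$cost, gamma = pars$gamma, scale = FALSE)
      dv <- attr(stats::predict(fit, te, decision.values = TRUE),
                 "decision.values")
      # e1071 orients the decision value to its first factor level
      s <- if (grepl(paste0("^", pos, "/"), colnames(dv)[1])) dv[, 1] else -dv[, 1]
      list(score = as.numeric(s), prob = stats::plogis(as.numeric(s)))
    },
    knn = {
      pr <- class::knn(matrix(xtr), matrix(xte), ytr, k = pars$k,
                       prob = TRUE)
      p_win <- attr(pr, "prob")
      p_pos <- ifelse(pr == pos, p_win, 1 - p_win)
      list(score = p_pos, prob = p_pos)
    },
    lr = {
      fit <- suppressWarnings(stats::glm(y ~ x, data = tr,
                                         family = stats::binomial()))
      p <- suppressWarnings(stats::predict(fit, te, type = "response"))
      list(score = as.numeric(p), prob = as.numeric(p))
    },
    nb = {
      fit <- e1071::naiveBayes(y ~ x, data = tr)
      p <- stats::predict(fit, te, type = "raw")[, pos]
      list(score = as.numeric(p), prob = as.numeric(p))
    })
}

.grids <- function(type, x) {
  switch(type,
    svm = {
      g0 <- 1 / max(stats::var(x), 1e-8)
      expand.grid(cost = c(0.1, 1, 10), gamma = g0 * c(0.1, 1, 10))
    },
    knn = expand.grid(k = c(3, 5, 7)),
    lr = expand.grid(dummy = 1),
    nb = expand.grid(dummy = 1))
}

# 5-fold CV accuracy for one hyperparameter setting
.cv_accuracy <- function(type, x, y, pars, folds = 5) {
  n <- length(y)
  fold <- rep(0L, n)
  for (l in levels(y)) {
    idx <- sample(which(y == l))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  correct <- 0
  for (f in seq_len(folds)) {
    te <- which(fold == f); tr <- which(fold != f)
    if (length(unique(y[tr])) < 2 || !length(te)) next
    sc <- try(.fit_score(type, x[tr], y[tr], x[te], pars), silent = TRUE)
    if (inherits(sc, "try-error")) next
    pred <- ifelse(sc$prob >= 0.5, levels(y)[2], levels(y)[1])
    correct <- correct + sum(pred == as.character(y[te]))
  }
  correct / n
}

#' Evaluate single-feature classifiers on per-subject observations
#'
#' Seeded stratified 80/20 train/test split; hyperparameters (SVM RBF
#' cost/gamma, kNN k) are chosen by 5-fold cross-validation on the
#' training 80%; accuracy, sensitivity, specificity, AUC, the ROC curve
#' and a quantile-binned calibration curve are computed on the held-out
#' 20%. The ROC/AUC is built from the positive-class decision score with
#' a fixed orientation (higher score = positive class), so swapping the
#' class labels maps AUC to 1 - AUC.
#'
#' @param obs observations from [make_observations()].
#' @param classifiers subset of `"svm"`, `"knn"`, `"lr"`, `"nb"`.
#' @param seed integer seed for split and fold assignment.
#' @param train_frac training fraction (default 0.8).
#' @param calibration_bins number of quantile bins.
#' @return `nw_classifier_report`: per-classifier list with `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `roc` (data frame `fpr`, `tpr`),
#'   `calibration` (data frame `predicted`, `observed`, `n`), and the
#'   selected hyperparameters; plus the `seed`.
#' @export
evaluate_classifiers <- function(obs, classifiers = c("svm", "knn", "lr", "nb"),
                                 seed = 1, train_frac = 0.8,
                                 calibration_bins = 5) {
  classifiers <- match.arg(classifiers, c("svm", "knn", "lr", "nb"),
                           several.ok = TRUE)
  y <- obs$class; x <- obs$value
  if (length(y) < 10) stop("need at least 10 observations")
  set.seed(seed)
  tr <- .stratified_split(y, train_frac)
  te <- setdiff(seq_along(y), tr)
  if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2)
    stop("both classes must appear in train and test sets")
  pos <- levels(y)[2]
  out <- lapply(stats::setNames(classifiers, classifiers), function(type) {
    grid <- .grids(type, x[tr])
    best <- grid[1, , drop = FALSE]
    if (nrow(grid) > 1) {
      acc <- vapply(seq_len(nrow(grid)), function(i)
        .cv_accuracy(type, x[tr], y[tr], grid[i, , drop = FALSE]),
        numeric(1))
      best <- grid[which.max(acc), , drop = FALSE]
    }
    sc <- .fit_score(type, x[tr], y[tr], x[te], best)
    truth <- y[te]
    pred <- factor(ifelse(sc$prob >= 0.5, levels(y)[2], levels(y)[1]),
                   levels = levels(y))
    roc <- .roc_auc(truth, sc$score, levels(y))
    rocdf <- roc$curve
    qs <- unique(stats::quantile(sc$prob,
                                 probs = seq(0, 1, length.out =
                                               calibration_bins + 1)))
    bin <- cut(sc$prob, breaks = qs, include.lowest = TRUE)
    cal <- data.frame(
      predicted = tapply(sc$prob, bin, mean),
      observed = tapply(truth == pos, bin, mean),
      n = as.integer(base::table(bin)))
    list(accuracy = mean(pred == truth),
         sensitivity = mean(pred[truth == pos] == pos),
         specificity = mean(pred[truth != pos] != pos),
         auc = roc$auc,
         roc = rocdf, calibration = cal, params = best)
  })
  structure(list(results = out, seed = seed,
                 n_train = length(tr), n_test = length(te),
                 classes = levels(y)),
            class = "nw_classifier_report")
}

#' @export
print.nw_classifier_report <- function(x, ...) {
  cat(sprintf("<nw_classifier_report> %s vs %s (train %d / test %d, seed %d)\n",
              x$classes[1], x$classes[2], x$n_train, x$n_test, x$seed))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-4s acc %.3f sens %.3f spec %.3f AUC %.3f\n",
                nm, r$accuracy, r$sensitivity, r$specificity, r$auc))
  }
  invisible(x)
}

#' Three-feature scatter clusters for a classification scheme
#'
#' For visual cluster inspection: per subject and class, the envelope,
#' sharpness and DoN values are taken from the two contacts with the
#' largest standardized between-class difference (summed over the three
#' features) and summed across the contact pair.
#'
#' @param table feature table (several subjects).
#' @param scheme 1, 2 or 3 (see [make_observations()]).
#' @param fusion agreement level.
#' @param features the three feature names.
#' @return List with `points` (data frame `subject`, `class`, one column
#'   per feature) and `contacts` (the selected pair).
#' @export
scatter_clusters <- function(table, scheme = 1, fusion = 3,
                             features = c("envelope", "sharpness", "don")) {
  contacts <- unique(table$channel)
  sep <- vapply(contacts, function(ct) {
    s <- 0
    for (f in features) {
      o <- try(suppressMessages(
        make_observations(table, f, scheme, fusion, ct)), silent = TRUE)
      if (inherits(o, "try-error")) next
      d <- abs(diff(tapply(o$value, o$class, mean)))
      s <- s + d / max(stats::sd(o$value), 1e-12)
    }
    s
  }, numeric(1))
  top2 <- contacts[order(sep, decreasing = TRUE)][1:min(2, length(contacts))]
  pts <- NULL
  for (f in features) {
    per_ct <- lapply(top2, function(ct)
      suppressMessages(make_observations(table, f, scheme, fusion, ct)))
    m <- Reduce(function(a, b)
      merge(a, b, by = c("subject", "class")), per_ct)
    val <- rowSums(as.matrix(m[, grep("^value", names(m)), drop = FALSE]))
    add <- data.frame(subject = m$subject, class = m$class, value = val)
    names(add)[3] <- f
    pts <- if (is.null(pts)) add else
      merge(pts, add, by = c("subject", "class"))
  }
  pts <- pts[stats::complete.cases(pts), ]
  list(points = pts, contacts = top2)
}
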