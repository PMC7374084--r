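# PCA-fed LDA with ANOVA component selection under leave-one-sample-out
# cross-validation. Per fold, PCA, the ANOVA selection and the LDA are all
# refit on the training spectra only; the held-out sample is projected
# through the fold's model and its pixel discriminant scores aggregated to
# one sample score. Note: the ANOVA runs on per-pixel scores labeled with
# their sample's pathology, so pixels of one sample are treated as
# independent replicates (pseudoreplication); this mirrors the target
# workflow and is deliberately reproduced, not corrected.

#' A per-sample spectra record
#'
#' @param sample_id sample identifier.
#' @param pathology `"normal"` or `"cancer"`.
#' @param tissue_class histology class the spectra come from (`"mucus"` or
#'   `"epithelium"`).
#' @param spectra n x bands matrix of extracted fingerprint spectra
#'   (n >= 1).
#' @param wavenumber the shared fingerprint axis.
#' @return object of class `sample_record`.
#' @export
sample_record <- function(sample_id, pathology, tissue_class, spectra,
                          wavenumber) {
  pathology <- match.arg(pathology, c("normal", "cancer"))
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 1L)
    stop("sample record needs at least one spectrum", call. = FALSE)
  if (ncol(spectra) != length(wavenumber))
    stop("spectra and wavenumber axis disagree", call. = FALSE)
  structure(list(sample_id = sample_id, pathology = pathology,
                 tissue_class = tissue_class, spectra = spectra,
                 wavenumber = check_axis(wavenumber)),
            class = "sample_record")
}

#' Principal component analysis of spectra
#'
#' Components of the column-centered data ordered by decreasing explained
#' variance, with a deterministic sign convention: the largest-magnitude
#' element of each loading is positive, so results are reproducible across
#' platforms and folds.
#'
#' @param X n x p matrix, one spectrum per row (n >= 2).
#' @param n_components number of components to keep; truncated to the
#'   data rank with a warning if it exceeds it.
#' @return object of class `pc_model`: `center`, `loadings` (p x r,
#'   orthonormal), `explained` (variance fractions, non-increasing),
#'   `scores` (n x r), `n`.
#' @export
pca_fit <- function(X, n_components = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PCA needs at least 2 spectra", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  r_max <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- r_max
  if (n_components > r_max) {
    warning(sprintf("n_components = %d exceeds the data rank; using %d",
                    n_components, r_max))
    n_components <- r_max
  }
  if (n - 1L >= p) {
    eg <- eigen(crossprod(Xc) / (n - 1L), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    V <- eg$vectors[, seq_len(n_components), drop = FALSE]
    lambda <- ev[seq_len(n_components)]
    total <- sum(ev)
  } else {
    sv <- svd(Xc, nu = 0L)
    ev <- sv$d^2 / (n - 1L)
    V <- sv$v[, seq_len(n_components), drop = FALSE]
    lambda <- ev[seq_len(n_components)]
    total <- sum(ev)
  }
  # deterministic sign convention
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(center = mu, loadings = V,
                 explained = if (total > 0) lambda / total else rep(0, length(lambda)),
                 scores = Xc %*% V, n = n),
            class = "pc_model")
}

#' Project new spectra onto a fitted PC model
#'
#' @param model a [pca_fit()] model.
#' @param X spectra matrix on the same axis.
#' @return score matrix.
#' @export
pca_project <- function(model, X) {
  sweep(as.matrix(X), 2L, model$center) %*% model$loadings
}

#' PCA of per-sample mean spectra
#'
#' One score vector per sample, for the PC-pair scatter views (PC1 vs
#' PC2, PC2 vs PC3, PC3 vs PC4) used to inspect group separation.
#'
#' @param records list of [sample_record()] objects (>= 3).
#' @param n_pcs number of components (default 4); reduced with a warning
#'   when it exceeds `length(records) - 1`.
#' @return a `pc_model` with extra fields `sample_id` and `pathology`.
#' @export
mean_spectrum_pca <- function(records, n_pcs = 4L) {
  if (length(records) < 3L)
    stop("mean-spectrum PCA needs at least 3 samples", call. = FALSE)
  M <- do.call(rbind, lapply(records, function(r) colMeans(r$spectra)))
  pm <- pca_fit(M, n_components = min(n_pcs, length(records) - 1L))
  if (n_pcs > length(records) - 1L)
    warning("n_pcs reduced to the number of samples minus one")
  pm$sample_id <- vapply(records, `[[`, "", "sample_id")
  pm$pathology <- vapply(records, `[[`, "", "pathology")
  pm
}

# vectorized one-way two-group ANOVA across score columns; returns F and p
anova_f_two_group <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("ANOVA selection needs exactly two groups present", call. = FALSE)
  n <- nrow(scores)
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1); n2 <- n - n1
  m1 <- colMeans(scores[g1, , drop = FALSE])
  m2 <- colMeans(scores[!g1, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  sst <- colSums(sweep(scores, 2L, gm)^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / 1) / (ssw / (n - 2L))
  p <- stats::pf(Fstat, 1, n - 2L, lower.tail = FALSE)
  list(F = Fstat, p = p, total_var = sst / (n - 1L))
}

#' ANOVA-based principal component selection
#'
#' One-way two-group ANOVA F test per PC score column; components with
#' p < `alpha` (99% significance by default) are kept in descending
#' explained-variance order, truncated at `cap` (default 25). Components
#' with zero total variance are excluded (their p is undefined). No
#' multiple-testing correction is applied: the selection operates at a
#' plain per-component significance level.
#'
#' @param scores n x m matrix of per-spectrum PC scores (columns ordered
#'   by explained variance).
#' @param labels pathology label per spectrum (two groups).
#' @param alpha significance level (default 0.01).
#' @param cap maximum number of selected components (default 25).
#' @return object of class `pc_selection`: `selected` (indices), `F`,
#'   `p`, `alpha`, `cap`, `fallback` (TRUE when nothing passed `alpha`
#'   and the single best component was kept instead).
#' @export
anova_select <- function(scores, labels, alpha = 0.01, cap = 25L) {
  scores <- as.matrix(scores)
  a <- anova_f_two_group(scores, labels)
  usable <- a$total_var > 1e-300
  p <- ifelse(usable, a$p, NA_real_)
  sel <- which(!is.na(p) & p < alpha)
  fallback <- FALSE
  if (!length(sel) && any(usable)) {
    sel <- which.min(p)
    fallback <- TRUE
  }
  if (length(sel) > cap) sel <- sel[seq_len(cap)]
  structure(list(selected = sel, F = a$F, p = p, alpha = alpha,
                 cap = as.integer(cap), fallback = fallback),
            class = "pc_selection")
}

#' Fisher two-class linear discriminant
#'
#' Closed-form Fisher rule: `w` proportional to the inverse pooled
#' within-class covariance times the class-mean difference, oriented so
#' the cancer mean projects above the normal mean; the equal-prior
#' decision threshold is the midpoint of the projected class means. When
#' the pooled covariance is near singular a ridge
#' `epsilon * trace/dim * I` is added.
#'
#' @param scores n x d matrix of selected PC scores.
#' @param labels pathology label per row; both classes with >= 2 rows.
#' @param positive positive class (default `"cancer"`).
#' @param ridge ridge epsilon (default 1e-6).
#' @return object of class `lda_model`: `w` (unit vector), `threshold`,
#'   `means`, `classes`, `positive`.
#' @export
lda_fit <- function(scores, labels, positive = "cancer", ridge = 1e-6) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("LDA needs exactly two classes", call. = FALSE)
  if (!positive %in% classes)
    stop("positive class not present in labels", call. = FALSE)
  negative <- setdiff(classes, positive)
  Xp <- scores[labels == positive, , drop = FALSE]
  Xn <- scores[labels == negative, , drop = FALSE]
  if (nrow(Xp) < 2L || nrow(Xn) < 2L)
    stop("LDA needs at least 2 spectra per class", call. = FALSE)
  mp <- colMeans(Xp); mn <- colMeans(Xn)
  Sw <- ((nrow(Xp) - 1L) * stats::cov(Xp) + (nrow(Xn) - 1L) * stats::cov(Xn)) /
    (nrow(Xp) + nrow(Xn) - 2L)
  d <- ncol(scores)
  w <- tryCatch({
    if (rcond(Sw) < 1e-10) stop("near singular")
    solve(Sw, mp - mn)
  }, error = function(e) {
    Swr <- Sw + ridge * (sum(diag(Sw)) / d) * diag(d)
    tryCatch(solve(Swr, mp - mn),
             error = function(e2)
               stop("pooled covariance singular even after ridge", call. = FALSE))
  })
  nw <- sqrt(sum(w^2))
  if (nw == 0) w <- rep(0, d) else w <- w / nw
  if (sum(w * (mp - mn)) < 0) w <- -w
  threshold <- (sum(w * mp) + sum(w * mn)) / 2
  structure(list(w = w, threshold = threshold,
                 means = rbind(positive = mp, negative = mn),
                 classes = c(positive = positive, negative = negative),
                 positive = positive),
            class = "lda_model")
}

#' Project scores onto the discriminant axis
#'
#' @param model an [lda_fit()] model.
#' @param scores matrix (or vector) in the selected-PC space.
#' @return numeric vector of discriminant scores.
#' @export
lda_project <- function(model, scores) {
  drop(as.matrix(scores) %*% model$w)
}

#' Aggregate pixel discriminant scores to one sample score
#'
#' @param scores pixel-level discriminant scores for one sample.
#' @param method `"mean"` (default), `"median"`, or `"vote"` (fraction of
#'   pixels above `threshold`, recentred so that positive values mean a
#'   positive-class majority).
#' @param threshold decision threshold (used by `"vote"`).
#' @return a single sample-level score.
#' @export
aggregate_sample_score <- function(scores, method = c("mean", "median", "vote"),
                                   threshold = 0) {
  method <- match.arg(method)
  if (!length(scores)) stop("no pixel scores to aggregate", call. = FALSE)
  switch(method,
         mean = mean(scores),
         median = stats::median(scores),
         vote = mean(scores > threshold) - 0.5 + threshold)
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds sweep the distinct scores (positive class = cancer by
#' default); the AUC is the trapezoid area, so tied scores contribute
#' one half, making the AUC equal the Mann-Whitney statistic
#' `U / (n1 * n0)`.
#'
#' @param scores sample-level scores.
#' @param labels true labels; both classes must be present.
#' @param positive positive class (default `"cancer"`).
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`,
#'   monotone non-decreasing in both coordinates) and `auc`.
#' @export
roc_and_auc <- function(scores, labels, positive = "cancer") {
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("ROC needs both classes present", call. = FALSE)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), 0)
  roc <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Confusion statistics
#'
#' Cancer-positive sensitivity and specificity, plus the per-class recall
#' pair (recall of cancer = sensitivity, recall of normal = specificity
#' under the cancer-positive convention); both framings are reported
#' because published summaries phrase results per class.
#'
#' @param predicted predicted labels.
#' @param truth true labels.
#' @param positive positive class (default `"cancer"`).
#' @return list with `counts` (TP, FP, TN, FN), `sensitivity`,
#'   `specificity`, `recall_by_class`.
#' @export
confusion_stats <- function(predicted, truth, positive = "cancer") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  classes <- unique(truth)
  negative <- setdiff(classes, positive)
  if (length(negative) != 1L)
    stop("confusion_stats expects two classes in truth", call. = FALSE)
  tp <- sum(predicted == positive & truth == positive)
  fn <- sum(predicted != positive & truth == positive)
  tn <- sum(predicted == negative & truth == negative)
  fp <- sum(predicted == positive & truth == negative)
  rec <- c(tp / (tp + fn), tn / (tn + fp))
  names(rec) <- c(positive, negative)
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity = rec[[positive]], specificity = rec[[negative]],
       recall_by_class = rec)
}

#' Leave-one-sample-out cross-validated classification
#'
#' Each fold holds out one whole sample; PCA, ANOVA selection and LDA are
#' refit on the remaining samples' spectra only; the held-out sample's
#' spectra are projected through the fold's PCA and LDA, pixel scores are
#' aggregated to a sample score, and the sample is labeled by the fold's
#' threshold. Confusion counts, ROC and AUC are computed over the
#' out-of-fold sample scores (reported relative to each fold's threshold
#' so scores are comparable across folds).
#'
#' @param records list of [sample_record()] objects, >= 2 per class.
#' @param n_pcs_max components extracted before selection (default 40).
#' @param alpha,cap ANOVA selection parameters (defaults 0.01 and 25).
#' @param aggregate pixel-to-sample aggregation method.
#' @param ridge LDA covariance ridge epsilon.
#' @param positive positive class for ROC/confusion.
#' @return object of class `loso_result`: `per_sample` (data.frame with
#'   `sample_id`, `pathology`, `score`, `predicted`), `confusion`,
#'   `sensitivity`, `specificity`, `recall_by_class`, `roc`, `auc`,
#'   `folds` (per-fold fitted models: PCA center/loadings, selection,
#'   LDA).
#' @export
loso_cv <- function(records, n_pcs_max = 40L, alpha = 0.01, cap = 25L,
                    aggregate = "mean", ridge = 1e-6, positive = "cancer") {
  n <- length(records)
  pathology <- vapply(records, `[[`, "", "pathology")
  if (any(table(pathology) < 2L) || length(unique(pathology)) != 2L)
    stop("LOSO needs at least 2 samples in each of two classes", call. = FALSE)
  counts <- vapply(records, function(r) nrow(r$spectra), 0L)
  X <- do.call(rbind, lapply(records, `[[`, "spectra"))
  sample_of_row <- rep(seq_len(n), counts)
  folds <- vector("list", n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    tr <- sample_of_row != i
    lab_tr <- pathology[sample_of_row[tr]]
    if (length(unique(lab_tr)) < 2L)
      stop("training fold ", i, " lost its last member of a class",
           call. = FALSE)
    pm <- suppressWarnings(pca_fit(X[tr, , drop = FALSE],
                                   n_components = min(n_pcs_max, sum(tr) - 1L)))
    sel <- anova_select(pm$scores, lab_tr, alpha = alpha, cap = cap)
    ld <- lda_fit(pm$scores[, sel$selected, drop = FALSE], lab_tr,
                  positive = positive, ridge = ridge)
    te_scores <- pca_project(pm, records[[i]]$spectra)[, sel$selected,
                                                       drop = FALSE]
    px <- lda_project(ld, te_scores)
    score[i] <- aggregate_sample_score(px, aggregate,
                                       threshold = ld$threshold) - ld$threshold
    folds[[i]] <- list(center = pm$center, loadings = pm$loadings,
                       explained = pm$explained, selection = sel, lda = ld)
  }
  predicted <- ifelse(score > 0, positive,
                      setdiff(unique(pathology), positive))
  cs <- confusion_stats(predicted, pathology, positive = positive)
  ra <- roc_and_auc(score, pathology, positive = positive)
  structure(list(per_sample = data.frame(
                   sample_id = vapply(records, `[[`, "", "sample_id"),
                   pathology = pathology, score = score,
                   predicted = predicted, row.names = NULL),
                 confusion = cs$counts, sensitivity = cs$sensitivity,
                 specificity = cs$specificity,
                 recall_by_class = cs$recall_by_class,
                 roc = ra$roc, auc = ra$auc, folds = folds,
                 positive = positive),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf(paste0("<loso_result> %d samples, AUC = %.3f, ",
                     "sensitivity = %.3f, specificity = %.3f\n"),
              nrow(x$per_sample), x$auc, x$sensitivity, x$specificity))
  invisible(x)
}

#' Permutation null distribution of the LOSO AUC
#'
#' Re-runs the full leave-one-sample-out analysis with pathology labels
#' permuted at the sample level.
#'
#' @param records list of [sample_record()] objects.
#' @param n_permutations number of permutations (default 20).
#' @param seed integer seed for the permutations.
#' @param ... passed to [loso_cv()].
#' @return numeric vector of null AUCs.
#' @export
permutation_null_auc <- function(records, n_permutations = 20L, seed = 1L, ...) {
  pathology <- vapply(records, `[[`, "", "pathology")
  perms <- withr::with_seed(seed, {
    replicate(n_permutations, sample(pathology), simplify = FALSE)
  })
  vapply(perms, function(pp) {
    rec <- records
    for (i in seq_along(rec)) rec[[i]]$pathology <- pp[i]
    loso_cv(rec, ...)$auc
  }, 0)
}
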