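#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference of the two empirical CDFs. The
#' p-value is exact (by enumeration over orderings) when both samples have
#' at most `exact_max` observations, and asymptotic (Kolmogorov
#' distribution) otherwise — matching common practice at radiomics cohort
#' sizes while keeping small-sample results checkable by brute force.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact_max exact-p sample-size cutoff (both samples must be at or
#'   below it).
#' @return A list `(D, p)`.
#' @export
#' @examples
#' ks_two_sample(c(0, 1), c(2, 3))$D   # 1: disjoint supports
ks_two_sample <- function(a, b, exact_max = 10L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- length(a) <= exact_max && length(b) <= exact_max
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Compare radiomic feature cohorts feature by feature
#'
#' Runs one two-sample Kolmogorov-Smirnov test per (family, feature) key
#' between a real and a synthetic cohort of feature vectors, and counts how
#' many features show no significant distribution difference (p >= alpha).
#' The report is sorted by descending p-value.
#'
#' @param real,synth lists of [extract_features()] tables (>= 2 each) with
#'   identical keys, or data frames with columns `family`, `feature`,
#'   `value` and one row per (case, feature).
#' @param alpha significance level; the convention is that p-values below
#'   0.05 are significant.
#' @return A `ks_report`: tibble with columns `family`, `feature`, `D`, `p`,
#'   sorted by descending `p`, with attributes `alpha`, `n_nonsignificant`,
#'   `n_total`.
#' @export
compare_cohorts <- function(real, synth, alpha = 0.05) {
  rm_ <- cohort_long(real); sm_ <- cohort_long(synth)
  if (length(unique(rm_$case)) < 2L || length(unique(sm_$case)) < 2L) {
    stop("each cohort needs at least two feature vectors", call. = FALSE)
  }
  keys_r <- unique(paste(rm_$family, rm_$feature, sep = "||"))
  keys_s <- unique(paste(sm_$family, sm_$feature, sep = "||"))
  if (!setequal(keys_r, keys_s)) {
    stop("cohorts have mismatched feature keys", call. = FALSE)
  }
  rn <- dplyr::group_nest(dplyr::group_by(rm_, .data$family, .data$feature))
  sn <- dplyr::group_nest(dplyr::group_by(sm_, .data$family, .data$feature))
  joined <- dplyr::inner_join(rn, sn, by = c("family", "feature"),
                              suffix = c("_real", "_synth"))
  tests <- purrr::map2(joined$data_real, joined$data_synth,
                       ~ ks_two_sample(.x$value, .y$value))
  out <- tibble::tibble(
    family = joined$family, feature = joined$feature,
    D = purrr::map_dbl(tests, "D"), p = purrr::map_dbl(tests, "p")
  )
  ks_report(out, alpha)
}

#' Build a KS report from a precomputed p-value table
#'
#' Applies the report's counting logic (sorting by descending p, counting
#' `p >= alpha` as non-significant) to an existing table of per-feature
#' Kolmogorov-Smirnov results — e.g. a published comparison table.
#'
#' @param tbl data frame with columns `family`, `feature`, `p` (and
#'   optionally `D`).
#' @param alpha significance level.
#' @return A `ks_report` tibble (see [compare_cohorts()]).
#' @export
ks_report <- function(tbl, alpha = 0.05) {
  stopifnot(all(c("family", "feature", "p") %in% names(tbl)))
  if (!"D" %in% names(tbl)) tbl$D <- NA_real_
  out <- dplyr::arrange(tibble::as_tibble(tbl[c("family", "feature", "D", "p")]),
                        dplyr::desc(.data$p))
  stopifnot(all(out$p >= 0 & out$p <= 1), all(is.na(out$D) | (out$D >= 0 & out$D <= 1)))
  attr(out, "alpha") <- alpha
  attr(out, "n_nonsignificant") <- sum(out$p >= alpha)
  attr(out, "n_total") <- nrow(out)
  class(out) <- c("ks_report", class(out))
  out
}

cohort_long <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("family", "feature", "value") %in% names(x)))
    if (!"case" %in% names(x)) stop("data-frame cohorts need a `case` column", call. = FALSE)
    return(tibble::as_tibble(x[c("case", "family", "feature", "value")]))
  }
  dplyr::bind_rows(purrr::imap(x, function(fv, i) {
    tibble::tibble(case = i, family = fv$family, feature = fv$feature,
                   value = fv$value)
  }))
}

#' @export
print.ks_report <- function(x, ...) {
  cat(sprintf("<ks_report: %d features, %d non-significant at alpha %.3g (%.1f%%)>\n",
              attr(x, "n_total"), attr(x, "n_nonsignificant"), attr(x, "alpha"),
              100 * attr(x, "n_nonsignificant") / attr(x, "n_total")))
  NextMethod()
}

#' @rdname tidy.ggn_gan
#' @exportS3Method generics::glance
glance.ks_report <- function(x, ...) {
  tibble::tibble(
    n_total = attr(x, "n_total"),
    n_nonsignificant = attr(x, "n_nonsignificant"),
    pct_nonsignificant = 100 * attr(x, "n_nonsignificant") / attr(x, "n_total"),
    alpha = attr(x, "alpha")
  )
}

#' Published reference table of per-feature KS p-values
#'
#' The packaged transcription of a published real-versus-synthetic GGN
#' radiomics comparison (93 features, six families, Kolmogorov-Smirnov
#' p-values), usable to exercise the [ks_report()] counting logic.
#'
#' @return A tibble with columns `family`, `feature`, `p_value`.
#' @export
table1_ks_pvalues <- function() {
  path <- system.file("extdata", "table1_ks_pvalues.csv", package = "ggnforge",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' ROC AUC by the midrank (Mann-Whitney) convention
#'
#' Equals the trapezoidal area under the ROC curve, i.e. the probability
#' that a random positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector; `TRUE` = positive.
#' @return Scalar in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validated real-versus-synthetic classification from radiomics
#'
#' Fits a logistic regression on standardised radiomic features to tell real
#' from synthetic cases, with stratified k-fold cross-validation: features
#' are standardised on each training fold (zero-variance features dropped
#' per fold), the model is fit on the training fold, and the held-out scores
#' are pooled over folds for the pooled AUC and the accuracy at threshold
#' 0.5.
#'
#' @param features list of [extract_features()] tables, or a numeric matrix
#'   (cases x features).
#' @param labels vector (`"real"`/`"synthetic"`, logical or factor);
#'   `"real"` / `TRUE` is the positive class.
#' @param k folds (default 4).
#' @param seed integer seed for the stratified fold assignment.
#' @return A `cv_result`: list with `fold_aucs`, `pooled_auc`,
#'   `pooled_accuracy`, `folds` (case -> fold), `scores` tibble.
#' @export
real_vs_fake_auc <- function(features, labels, k = 4L, seed = 1L) {
  X <- if (is.matrix(features)) features else cohort_matrix(features)
  y <- normalise_labels(labels)
  if (nrow(X) != length(y)) stop("features/labels length mismatch", call. = FALSE)
  folds <- stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  fold_aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2L) stop("single-class training fold", call. = FALSE)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    keep <- is.finite(sdv) & sdv > 0
    Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], `/`)
    df_tr <- data.frame(y = y[tr], Z[tr, , drop = FALSE])
    fit <- suppressWarnings(glm(y ~ ., data = df_tr, family = binomial()))
    pr <- suppressWarnings(
      predict(fit, newdata = data.frame(Z[te, , drop = FALSE]), type = "response"))
    scores[te] <- pr
    fold_aucs[f] <- roc_auc(pr, y[te])
  }
  structure(
    list(fold_aucs = fold_aucs,
         pooled_auc = roc_auc(scores, y),
         pooled_accuracy = mean((scores >= 0.5) == y),
         folds = folds,
         scores = tibble::tibble(case = seq_along(y), fold = folds,
                                 label = y, score = scores)),
    class = "cv_result"
  )
}

cohort_matrix <- function(features) {
  long <- cohort_long(features)
  wide <- tidyr::pivot_wider(long,
                             names_from = c("family", "feature"),
                             values_from = "value", names_sep = "::")
  as.matrix(wide[-1])
}

normalise_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  tolower(as.character(labels)) %in% c("real", "true", "1", "positive")
}

stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(seq_len(k), function(f) length(unique(y[folds == f])), integer(1)) < 2L)) {
    # re-stratify deterministically if a fold ended single-class
    return(stratified_folds(y, k, seed + 1L))
  }
  folds
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: pooled AUC %.3f, accuracy %.3f over %d folds>\n",
              x$pooled_auc, x$pooled_accuracy, length(x$fold_aucs)))
  invisible(x)
}

#' @rdname tidy.ggn_gan
#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$scores

#' @rdname tidy.ggn_gan
#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  tibble::tibble(pooled_auc = x$pooled_auc, pooled_accuracy = x$pooled_accuracy,
                 k = length(x$fold_aucs), mean_fold_auc = mean(x$fold_aucs))
}

# ---- visual Turing test -----------------------------------------------------

vtt_rating_levels <- c("confidently fake", "leaning fake",
                       "leaning real", "confidently real")

#' Summarise visual-Turing-test reader ratings
#'
#' Readers rate each case on a four-level scale (confidently fake, leaning
#' fake, leaning real, confidently real). Ratings are binarised as
#' called-real = \{leaning real, confidently real\} for the truth-by-call
#' confusion matrix, and used ordinally (0 = confidently fake ... 3 =
#' confidently real) as a score against the truth (real = positive) for the
#' reader ROC AUC. With a single truth class the AUC is not computable and
#' is reported as `NA` with `auc_computable = FALSE`.
#'
#' @param records data frame with columns `case_id`, `truth`
#'   (`"real"`/`"synthetic"`), `rating` (one of the four levels), and
#'   optionally `reader_id`.
#' @return A `vtt_summary`: list with `confusion` (2x2 counts), `proportions`
#'   (per-truth rating fractions, each truth class summing to 1), `auc`,
#'   `auc_computable`, `n`.
#' @export
vtt_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("case_id", "truth", "rating") %in% names(records)))
  rating <- tolower(as.character(records$rating))
  if (!all(rating %in% vtt_rating_levels)) {
    stop("unknown rating level(s): ",
         paste(setdiff(unique(rating), vtt_rating_levels), collapse = ", "),
         call. = FALSE)
  }
  truth <- tolower(as.character(records$truth))
  stopifnot(all(truth %in% c("real", "synthetic")))
  score <- match(rating, vtt_rating_levels) - 1L          # 0..3
  called_real <- score >= 2L
  confusion <- table(truth = factor(truth, c("real", "synthetic")),
                     call = factor(ifelse(called_real, "called real", "called fake"),
                                   c("called real", "called fake")))
  proportions <- tibble::as_tibble(
    prop.table(table(truth = factor(truth, c("real", "synthetic")),
                     rating = factor(rating, vtt_rating_levels)),
               margin = 1)
  )
  computable <- length(unique(truth)) == 2L
  auc <- if (computable) roc_auc(score, truth == "real") else NA_real_
  structure(
    list(confusion = confusion, proportions = proportions,
         auc = auc, auc_computable = computable, n = nrow(records)),
    class = "vtt_summary"
  )
}

#' @export
print.vtt_summary <- function(x, ...) {
  cat(sprintf("<vtt_summary: %d ratings, reader AUC %s>\n", x$n,
              if (x$auc_computable) sprintf("%.3f", x$auc) else "not computable"))
  print(x$confusion)
  invisible(x)
}

#' @rdname tidy.ggn_gan
#' @exportS3Method generics::tidy
tidy.vtt_summary <- function(x, ...) x$proportions

#' @rdname tidy.ggn_gan
#' @exportS3Method generics::glance
glance.vtt_summary <- function(x, ...) {
  syn_real <- x$confusion["synthetic", "called real"]
  syn_total <- sum(x$confusion["synthetic", ])
  tibble::tibble(
    n = x$n, auc = x$auc,
    synthetic_called_real = as.integer(syn_real),
    frac_synthetic_called_real = if (syn_total > 0) syn_real / syn_total else NA_real_
  )
}

#' Plot visual-Turing-test rating distributions
#'
#' @param object a `vtt_summary`.
#' @param ... unused.
#' @return A ggplot (stacked rating proportions per truth class).
#' @exportS3Method ggplot2::autoplot
autoplot.vtt_summary <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$truth, y = .data$n, fill = .data$rating)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "fraction of ratings", fill = NULL,
                  title = "Reader ratings by truth class") +
    ggplot2::theme_minimal()
}

#' Plot a KS report as a p-value profile
#'
#' @param object a `ks_report`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ks_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$p,
                                   colour = .data$family)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"), linetype = 2) +
    ggplot2::labs(x = "feature (sorted by descending p)", y = "KS p-value",
                  title = "Real vs synthetic feature distributions") +
    ggplot2::theme_minimal()
}
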