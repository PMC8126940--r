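# EPQ scoring, temperament classification, and instrument reliability.

#' Default EPQ item key
#'
#' The 48-item EPQ assigns exactly 12 items to each of the four subscales:
#' extroversion (E), neuroticism (N), psychoticism (P) and lying (L). Each
#' item is keyed so that either a "yes" (1) or a "no" (0) answer scores one
#' point on its subscale. The published instrument's item wording and keying
#' are proprietary and never reproduced here; this key is a documented
#' arbitrary stand-in with the correct structure (12 items per subscale,
#' alternating keyed directions), sufficient for every downstream stage,
#' which depends only on subscale scores.
#'
#' @return A data.frame with columns `item` (1--48), `subscale`
#'   (one of `"E"`, `"N"`, `"P"`, `"L"`) and `keyed_answer` (0 or 1, the
#'   answer that scores a point).
#' @export
epq_default_key <- function() {
  data.frame(
    item = 1:48,
    subscale = rep(c("E", "N", "P", "L"), each = 12L),
    keyed_answer = rep(c(1L, 0L), 24L)
  )
}

validate_epq_key <- function(key) {
  stopifnot(is.data.frame(key))
  need <- c("item", "subscale", "keyed_answer")
  if (!all(need %in% names(key)))
    stop("EPQ key must have columns: ", paste(need, collapse = ", "))
  if (nrow(key) != 48L)
    stop("EPQ key must have exactly 48 items, got ", nrow(key))
  bad <- !key$subscale %in% c("E", "N", "P", "L")
  if (any(bad))
    stop("unknown subscale tag for item(s) ",
         paste(key$item[bad], collapse = ", "))
  counts <- table(key$subscale)
  if (any(counts != 12L))
    stop("each subscale must have exactly 12 items; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  if (!all(key$keyed_answer %in% c(0L, 1L)))
    stop("keyed_answer must be 0 or 1")
  invisible(key)
}

#' Score a 48-item EPQ response sheet
#'
#' Each subscale score is the count of items whose dichotomous answer
#' matches the item's keyed direction; scores therefore lie in [0, 12].
#'
#' @param answers Vector of 48 dichotomous responses coded 0/1 (no/yes),
#'   ordered by item number of `key`.
#' @param key Item key as returned by [epq_default_key()]: one row per item
#'   with its subscale and keyed answer.
#' @return Named integer vector with elements `extroversion`, `neuroticism`,
#'   `psychoticism`, `lying`.
#' @export
score_epq <- function(answers, key = epq_default_key()) {
  validate_epq_key(key)
  if (length(answers) != 48L)
    stop("expected 48 answers, got ", length(answers))
  bad <- !(answers %in% c(0, 1)) | is.na(answers)
  if (any(bad))
    stop("non-dichotomous answer at item(s) ",
         paste(key$item[bad], collapse = ", "))
  hit <- as.integer(answers) == key$keyed_answer
  scores <- vapply(c(E = "E", N = "N", P = "P", L = "L"),
                   function(s) sum(hit[key$subscale == s]), integer(1))
  c(extroversion = scores[["E"]], neuroticism = scores[["N"]],
    psychoticism = scores[["P"]], lying = scores[["L"]])
}

#' Classify temperament from EPQ subscale scores
#'
#' The extroversion and neuroticism subscales define the four classical
#' temperament quadrants: extroverted--unstable is choleric,
#' extroverted--stable sanguine, introverted--unstable melancholic and
#' introverted--stable phlegmatic. "Extroverted" means an extroversion
#' score strictly above `e_cut`; "unstable" a neuroticism score strictly
#' above `n_cut`. The default cutoffs are the scale midpoint (6 on 0--12);
#' pass `e_cut = "median"` (and/or `n_cut = "median"`) to use the cohort
#' median instead.
#'
#' @param extroversion,neuroticism Integer scores in [0, 12] (vectorized).
#' @param e_cut,n_cut Thresholds in [0, 12], or the string `"median"`.
#' @return Factor with levels `choleric`, `sanguine`, `melancholic`,
#'   `phlegmatic`.
#' @export
classify_trait <- function(extroversion, neuroticism, e_cut = 6, n_cut = 6) {
  if (identical(e_cut, "median")) e_cut <- stats::median(extroversion)
  if (identical(n_cut, "median")) n_cut <- stats::median(neuroticism)
  stopifnot(e_cut >= 0, e_cut <= 12, n_cut >= 0, n_cut <= 12)
  if (any(extroversion < 0 | extroversion > 12 |
          neuroticism < 0 | neuroticism > 12, na.rm = FALSE))
    stop("subscale scores must lie in [0, 12]")
  ext <- extroversion > e_cut
  uns <- neuroticism > n_cut
  out <- ifelse(ext & uns, "choleric",
         ifelse(ext & !uns, "sanguine",
         ifelse(!ext & uns, "melancholic", "phlegmatic")))
  factor(out, levels = trait_levels())
}

#' @rdname classify_trait
#' @export
trait_levels <- function() c("choleric", "sanguine", "melancholic", "phlegmatic")

#' Cronbach's alpha internal-consistency reliability
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of total scores),
#' with the sample (n-1) variance throughout. Also reports the
#' leave-one-item-out alpha for each item, the usual "alpha if item
#' deleted" diagnostic.
#'
#' @param item_matrix Numeric matrix or data.frame, subjects in rows and
#'   items in columns; at least 2 subjects and 2 items.
#' @return List with `alpha`, `k` (number of items), `n` (subjects) and
#'   `alpha_drop` (named vector, alpha with each item removed).
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  if (!is.numeric(x)) stop("item matrix must be numeric")
  k <- ncol(x); n <- nrow(x)
  if (k < 2L || n < 2L) stop("need at least 2 items and 2 subjects")
  alpha_of <- function(m) {
    tot <- stats::var(rowSums(m))
    if (tot <= .Machine$double.eps)
      stop("total-score variance is zero: reliability undefined")
    kk <- ncol(m)
    kk / (kk - 1) * (1 - sum(apply(m, 2, stats::var)) / tot)
  }
  drop <- if (k > 2L) {
    vapply(seq_len(k), function(j) alpha_of(x[, -j, drop = FALSE]), numeric(1))
  } else rep(NA_real_, k)
  names(drop) <- colnames(x) %||% paste0("item_", seq_len(k))
  list(alpha = alpha_of(x), k = k, n = n, alpha_drop = drop)
}

#' Test--retest intraclass correlation coefficient
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC (often
#' written ICC(A,1)) from the standard two-way ANOVA mean squares: with
#' subjects as rows and the two administrations as columns,
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#' Agreement is flagged acceptable when ICC > 0.75.
#'
#' @param pairs Numeric matrix or data.frame with one row per subject and
#'   one column per administration (typically 2).
#' @return List with `icc`, `acceptable` (ICC > 0.75), `n`, `k` and the
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_test_retest <- function(pairs) {
  x <- as.matrix(pairs)
  if (!is.numeric(x)) stop("pairs must be numeric")
  if (any(is.na(x))) stop("both administrations must be present per subject")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 administrations")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps)
    stop("zero between-subject variance: reliability undefined")
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  list(icc = icc, acceptable = icc > 0.75, n = n, k = k,
       msr = msr, msc = msc, mse = mse)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
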