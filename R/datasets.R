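#' Activity labeling schemes
#'
#' A labeling scheme maps an IC50 (micromolar) to `high`, `weak` or
#' `excluded` via two comparator/threshold rules. The high and weak rules
#' must be disjoint over positive IC50 values; molecules matching neither
#' rule fall in the exclusion gap.
#'
#' @param high_op,high_thr comparator (`"<"` or `"<="`) and threshold (uM)
#'   for the highly active class.
#' @param weak_op,weak_thr comparator (`">"` or `">="`) and threshold (uM)
#'   for the weakly active class.
#' @param name scheme name.
#' @return object of class `label_scheme`.
#' @export
activity_scheme <- function(high_op, high_thr, weak_op, weak_thr,
                            name = "custom") {
  stopifnot(high_op %in% c("<", "<="), weak_op %in% c(">", ">="))
  # disjointness over positive reals
  overlap <- if (high_op == "<" && weak_op == ">") high_thr > weak_thr
    else if (high_op == "<=" && weak_op == ">=") high_thr >= weak_thr
    else high_thr > weak_thr ||
      (high_thr == weak_thr && high_op == "<=" && weak_op == ">=")
  if (isTRUE(overlap)) stop("high and weak rules overlap")
  structure(list(name = name, high_op = high_op, high_thr = high_thr,
                 weak_op = weak_op, weak_thr = weak_thr),
            class = "label_scheme")
}

#' Built-in labeling schemes
#'
#' Four schemes commonly used for COX-2 / mPGES-1 inhibitor datasets:
#' * `strict_gap`: high if IC50 < 0.1 uM, weak if IC50 > 10 uM (gapped).
#' * `potency_1um`: high if IC50 <= 1 uM, weak if IC50 > 1 uM (total).
#' * `gap_0.6_10`: high if IC50 < 0.6 uM, weak if IC50 > 10 uM (gapped).
#' * `cut_10um`: high if IC50 < 10 uM, weak if IC50 >= 10 uM (total).
#'
#' @return named list of `label_scheme` objects.
#' @export
builtin_schemes <- function() {
  list(
    strict_gap  = activity_scheme("<", 0.1, ">", 10, "strict_gap"),
    potency_1um = activity_scheme("<=", 1, ">", 1, "potency_1um"),
    gap_0.6_10  = activity_scheme("<", 0.6, ">", 10, "gap_0.6_10"),
    cut_10um    = activity_scheme("<", 10, ">=", 10, "cut_10um")
  )
}

#' Label IC50 values under a scheme
#'
#' @param ic50_um positive IC50 values in micromolar.
#' @param scheme a `label_scheme`.
#' @return factor with levels `high`, `weak`, `excluded`.
#' @export
label_activity <- function(ic50_um, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  if (any(!is.finite(ic50_um)) || any(ic50_um <= 0)) {
    stop("ic50_um must be positive and finite")
  }
  hi <- if (scheme$high_op == "<") ic50_um < scheme$high_thr
        else ic50_um <= scheme$high_thr
  wk <- if (scheme$weak_op == ">") ic50_um > scheme$weak_thr
        else ic50_um >= scheme$weak_thr
  factor(ifelse(hi, "high", ifelse(wk, "weak", "excluded")),
         levels = c("high", "weak", "excluded"))
}

#' IC50 / pIC50 conversions
#'
#' pIC50 is the negative base-10 logarithm of the IC50 expressed in mol/L;
#' with IC50 in micromolar, pIC50 = 6 - log10(IC50 uM). A 10 uM IC50
#' corresponds to pIC50 = 5.
#'
#' @param ic50_um positive IC50 values (micromolar).
#' @return numeric pIC50 values.
#' @export
pic50_from_ic50 <- function(ic50_um) {
  if (any(!is.na(ic50_um) & ic50_um <= 0)) stop("ic50_um must be positive")
  6 - log10(ic50_um)
}

#' @rdname pic50_from_ic50
#' @param pic50 pIC50 values.
#' @export
ic50_from_pic50 <- function(pic50) 10^(6 - pic50)

#' Build a labeled modeling dataset
#'
#' Attaches classification labels (under `scheme`) or a regression response
#' (pIC50) to molecule records with activity. For classification, molecules
#' in the scheme's exclusion gap are removed before any splitting; both
#' classes must be present.
#'
#' @param records `molecule_records` with `ic50_um` (or `pic50` for
#'   regression-only datasets).
#' @param target target identifier tag (e.g. `"COX-2"`).
#' @param task `"classification"` or `"regression"`.
#' @param scheme labeling scheme (classification only).
#' @return data.frame of class `activity_dataset` with a `label` (factor
#'   high/weak) or `pic50` response column.
#' @export
activity_dataset <- function(records, target = "target",
                             task = c("classification", "regression"),
                             scheme = NULL) {
  task <- match.arg(task)
  df <- as.data.frame(records)
  if (task == "classification") {
    stopifnot(inherits(scheme, "label_scheme"))
    lab <- label_activity(df$ic50_um, scheme)
    keep <- lab != "excluded"
    df <- df[keep, , drop = FALSE]
    df$label <- factor(as.character(lab[keep]), levels = c("high", "weak"))
    if (nlevels(droplevels(df$label)) < 2L) {
      stop("classification dataset must contain both classes")
    }
  } else {
    if (all(is.na(df$pic50))) stop("regression dataset needs pIC50 values")
    if (any(!is.finite(df$pic50))) stop("pIC50 values must be finite")
  }
  attr(df, "target") <- target
  attr(df, "task") <- task
  attr(df, "scheme") <- if (is.null(scheme)) NULL else scheme$name
  class(df) <- c("activity_dataset", "data.frame")
  df
}

round_half_up <- function(x) floor(x + 0.5)

# largest-remainder allocation of `total` across strata with weights `n_s`
largest_remainder <- function(n_s, total) {
  raw <- n_s * total / sum(n_s)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0L) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  base
}

#' Stratified train/test split
#'
#' The test-set size is `round-half-up(n * test_fraction)`; per-stratum test
#' counts are assigned by largest-remainder allocation so class proportions
#' deviate from exact proportionality by less than one molecule.
#' Classification stratifies on the label; regression stratifies on
#' `n_bins` response-quantile bins.
#'
#' @param ds an `activity_dataset` (or a factor/numeric response vector).
#' @param test_fraction fraction of molecules in the test set.
#' @param seed integer seed.
#' @param n_bins quantile bins for regression stratification (default 5).
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(ds, test_fraction, seed = 1L, n_bins = 5L) {
  y <- split_response(ds)
  n <- length(y)
  strata <- if (is.factor(y)) {
    if (any(table(y) < 2L)) stop("every class needs at least 2 members")
    y
  } else {
    if (n < 5L) stop("regression split needs n >= 5")
    qs <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
    cut(y, breaks = qs, include.lowest = TRUE)
  }
  n_test <- round_half_up(n * test_fraction)
  tab <- table(strata)
  alloc <- largest_remainder(as.numeric(tab), n_test)
  names(alloc) <- names(tab)
  set.seed(seed)
  test <- integer(0)
  for (s in names(tab)) {
    idx <- which(strata == s)
    k <- alloc[[s]]
    if (k > 0L) test <- c(test, sort(sample(idx, k)))
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

split_response <- function(ds) {
  if (is.data.frame(ds)) {
    if (!is.null(ds$label)) droplevels(ds$label) else ds$pic50
  } else ds
}

#' Repeated stratified splits
#'
#' Generates `n_repeats` stratified splits with seeds
#' `base_seed, base_seed + 1, ...`, the protocol used to average model
#' metrics over random partitions.
#'
#' @inheritParams stratified_split
#' @param n_repeats number of splits (default 10).
#' @param base_seed seed of the first split.
#' @return object of class `split_set`: list of `(train, test)` index pairs
#'   with the seeds and test fraction attached.
#' @export
repeated_splits <- function(ds, n_repeats = 10L, test_fraction = 0.2,
                            base_seed = 1L) {
  seeds <- base_seed + seq_len(n_repeats) - 1L
  splits <- lapply(seeds, function(s)
    stratified_split(ds, test_fraction, seed = s))
  structure(list(splits = splits, seeds = seeds,
                 test_fraction = test_fraction),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  sizes <- vapply(x$splits, function(s) length(s$test), 0L)
  cat("<split_set> ", length(x$splits), " repeats, test fraction ",
      x$test_fraction, ", |test| = ", paste(unique(sizes), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}
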