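#' Cascade screening configuration
#'
#' @param consensus_fraction fraction of classifiers that must call a
#'   molecule highly active for it to pass the first stage (default 1.0 =
#'   unanimity).
#' @param potency_cut_um predicted-IC50 retention cut in micromolar; a
#'   molecule passes when its implied IC50 is strictly below the cut
#'   (default 10).
#' @param hp_threshold SOM HP cut (default 0.8, inclusive).
#' @param hp_strict use a strict inequality for the HP cut.
#' @param aggregator_threshold MACCS Tanimoto threshold for the aggregator
#'   flag (default 1.0).
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(consensus_fraction = 1.0, potency_cut_um = 10,
                           hp_threshold = 0.8, hp_strict = FALSE,
                           aggregator_threshold = 1.0) {
  stopifnot(consensus_fraction > 0, consensus_fraction <= 1,
            potency_cut_um > 0, hp_threshold >= 0, hp_threshold <= 1)
  structure(list(consensus_fraction = consensus_fraction,
                 potency_cut_um = potency_cut_um,
                 hp_threshold = hp_threshold, hp_strict = hp_strict,
                 aggregator_threshold = aggregator_threshold),
            class = "cascade_config")
}

#' Select models by external-validation performance
#'
#' Deterministic selection of the models that go into the screening stages:
#' either the top k by metric or all models reaching a cutoff. Ties are
#' broken by model id.
#'
#' @param reports data.frame with columns `model_id` and `metric` (the
#'   external-validation MCC or RMSE per model).
#' @param criterion `"top_k"` or `"threshold"`.
#' @param k number of models kept under `"top_k"`.
#' @param cutoff metric cutoff under `"threshold"`.
#' @param higher_is_better `TRUE` for MCC-like metrics, `FALSE` for
#'   RMSE-like ones.
#' @return character vector of selected `model_id`s; empty selection is an
#'   error.
#' @export
select_models <- function(reports, criterion = c("top_k", "threshold"),
                          k = NULL, cutoff = NULL, higher_is_better = TRUE) {
  criterion <- match.arg(criterion)
  stopifnot(all(c("model_id", "metric") %in% names(reports)))
  m <- if (higher_is_better) reports$metric else -reports$metric
  ord <- order(-m, reports$model_id)
  sel <- if (criterion == "top_k") {
    stopifnot(!is.null(k), k >= 1L)
    reports$model_id[ord][seq_len(min(k, nrow(reports)))]
  } else {
    stopifnot(!is.null(cutoff))
    ok <- if (higher_is_better) reports$metric >= cutoff
          else reports$metric <= cutoff
    reports$model_id[ord][ok[ord]]
  }
  if (!length(sel)) stop("empty selection: no model meets the criterion")
  sel
}

# featurization ids required by a model (a stack needs all its bases')
model_feat_ids <- function(model) {
  if (inherits(model, "qsar_stack")) {
    unique(vapply(model$base_models, `[[`, "", "featurization_id"))
  } else {
    model$featurization_id
  }
}

fm_for_id <- function(records, id, cache) {
  if (!is.null(cache[[id]])) return(cache[[id]])
  fm <- if (id %in% c("maccs166", "path1024", "ecfp4_1024")) {
    fingerprints(records, id)
  } else {
    descriptors(records, id)
  }
  cache[[id]] <- fm
  fm
}

predict_any <- function(model, records, cache, type) {
  if (inherits(model, "qsar_stack")) {
    nd <- lapply(stats::setNames(nm = names(model$base_models)), function(nm)
      fm_for_id(records, model$base_models[[nm]]$featurization_id, cache))
    names(nd) <- names(model$base_models)
    predict(model, nd, type = type)
  } else {
    predict(model, fm_for_id(records, model$featurization_id, cache),
            type = type)
  }
}

#' Consensus classification of candidate molecules
#'
#' @param classifiers list of `qsar_model` / `qsar_stack` classifiers (each
#'   carrying its featurization id).
#' @param records candidate `molecule_records`.
#' @param consensus_fraction fraction of positive calls required.
#' @return data.frame: `id`, `n_positive`, `n_classifiers`, `keep`.
#' @export
consensus_classify <- function(classifiers, records,
                               consensus_fraction = 1.0) {
  cache <- new.env(parent = emptyenv())
  votes <- vapply(classifiers, function(m)
    predict_any(m, records, cache, type = "class") == "high",
    logical(nrow(records)))
  votes <- matrix(votes, nrow = nrow(records))
  n_pos <- rowSums(votes)
  data.frame(id = records$id, n_positive = n_pos,
             n_classifiers = length(classifiers),
             keep = n_pos / length(classifiers) >= consensus_fraction,
             stringsAsFactors = FALSE)
}

#' Averaged-regression potency prediction
#'
#' Predictions are averaged in pIC50 space (the regression response); the
#' implied IC50 is `10^(6 - mean pIC50)` micromolar, and molecules are kept
#' when it is strictly below the potency cut.
#'
#' @param regressors list of regression `qsar_model`s.
#' @param records candidate `molecule_records`.
#' @param potency_cut_um retention cut in micromolar (default 10).
#' @return data.frame: `id`, `mean_pic50`, `pred_ic50_um`, `keep`.
#' @export
average_potency <- function(regressors, records, potency_cut_um = 10) {
  cache <- new.env(parent = emptyenv())
  preds <- vapply(regressors, function(m)
    predict_any(m, records, cache, type = "class"),
    numeric(nrow(records)))
  preds <- matrix(preds, nrow = nrow(records))
  mean_pic50 <- rowMeans(preds)
  ic50 <- ic50_from_pic50(mean_pic50)
  data.frame(id = records$id, mean_pic50 = mean_pic50,
             pred_ic50_um = ic50, keep = ic50 < potency_cut_um,
             stringsAsFactors = FALSE)
}

#' Run the full screening cascade
#'
#' Stages, applied in order with short-circuiting (a molecule failing a
#' stage is not evaluated further):
#' 1. consensus classification over `classifiers`;
#' 2. averaged-regression potency, keep implied IC50 strictly below the cut;
#' 3. SOM HP rule (cell HP at least the threshold; unmapped cells fail);
#' 4. aggregator filter (flagged molecules fail).
#'
#' Every input molecule appears exactly once in the result with a full audit
#' trail; passed molecules are ranked by ascending predicted IC50.
#'
#' @param records screening library (`molecule_records`).
#' @param classifiers list of classification `qsar_model`/`qsar_stack`.
#' @param regressors list of regression `qsar_model`s.
#' @param som a `som_map` trained on the labeled dataset (or `NULL` to skip
#'   the stage).
#' @param som_featurization_id featurization feeding the SOM (default
#'   `"ecfp4_1024"`).
#' @param aggregators an `aggregator_set` (or `NULL` to skip the stage).
#' @param config a [cascade_config()].
#' @return data.frame of class `screening_result`.
#' @export
run_cascade <- function(records, classifiers, regressors, som = NULL,
                        som_featurization_id = "ecfp4_1024",
                        aggregators = NULL, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"),
            length(classifiers) >= 1L, length(regressors) >= 1L)
  n <- nrow(records)
  out <- data.frame(id = records$id,
                    n_positive = rep(NA_integer_, n),
                    n_classifiers = rep(length(classifiers), n),
                    mean_pic50 = rep(NA_real_, n),
                    pred_ic50_um = rep(NA_real_, n),
                    som_cell = rep(NA_integer_, n),
                    som_hp = rep(NA_real_, n),
                    aggregator_flag = rep(NA, n),
                    status = rep("passed", n),
                    stringsAsFactors = FALSE)
  if (!n) return(as_screening_result(out, config))
  cache <- new.env(parent = emptyenv())

  # stage 1: consensus classification
  votes <- vapply(classifiers, function(m)
    predict_any(m, records, cache, type = "class") == "high", logical(n))
  votes <- matrix(votes, nrow = n)
  out$n_positive <- rowSums(votes)
  alive <- out$n_positive / length(classifiers) >= config$consensus_fraction
  out$status[!alive] <- "failed@classification"

  # stage 2: averaged regression potency
  if (any(alive)) {
    sub <- records[alive, , drop = FALSE]
    sub_cache <- new.env(parent = emptyenv())
    preds <- vapply(regressors, function(m)
      predict_any(m, sub, sub_cache, type = "class"), numeric(nrow(sub)))
    preds <- matrix(preds, nrow = nrow(sub))
    mp <- rowMeans(preds)
    out$mean_pic50[alive] <- mp
    out$pred_ic50_um[alive] <- ic50_from_pic50(mp)
    fail2 <- alive & !(out$pred_ic50_um < config$potency_cut_um)
    out$status[fail2] <- "failed@potency"
    alive <- alive & !fail2
  }

  # stage 3: SOM HP rule
  if (!is.null(som) && any(alive)) {
    sub <- records[alive, , drop = FALSE]
    fm <- fm_for_id(sub, som_featurization_id, new.env(parent = emptyenv()))
    asg <- screen_by_hp(predict(som, fm), threshold = config$hp_threshold,
                        strict = config$hp_strict)
    out$som_cell[alive] <- asg$cell
    out$som_hp[alive] <- asg$hp
    fail3 <- rep(FALSE, n)
    fail3[alive] <- !asg$keep
    out$status[fail3] <- "failed@som"
    alive <- alive & !fail3
  }

  # stage 4: aggregator filter
  if (!is.null(aggregators) && any(alive)) {
    sub <- records[alive, , drop = FALSE]
    fl <- flag_aggregator(sub, aggregators,
                          threshold = config$aggregator_threshold)
    out$aggregator_flag[alive] <- fl$flag
    fail4 <- rep(FALSE, n)
    fail4[alive] <- fl$flag
    out$status[fail4] <- "failed@aggregator"
    alive <- alive & !fail4
  }

  # rank: passed molecules first by ascending predicted IC50, then the rest
  # in input order
  passed <- out$status == "passed"
  ord <- c(which(passed)[order(out$pred_ic50_um[passed])], which(!passed))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  as_screening_result(out, config)
}

as_screening_result <- function(df, config) {
  attr(df, "config") <- config
  class(df) <- c("screening_result", "data.frame")
  df
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", nrow(x), " molecules screened, ",
      sum(x$status == "passed"), " passed\n", sep = "")
  tab <- table(x$status)
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  df <- as.data.frame(x)
  top <- utils::head(df[df$status == "passed",
                        c("id", "pred_ic50_um", "som_hp")], 10L)
  if (nrow(top)) {
    cat("top candidates (predicted IC50, uM):\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.screening_result <- function(object, ...) {
  print(object)
  cfg <- attr(object, "config")
  cat("\nconfig: consensus >= ", cfg$consensus_fraction,
      ", IC50 < ", cfg$potency_cut_um, " uM, HP >= ", cfg$hp_threshold,
      ", aggregator TC >= ", cfg$aggregator_threshold, "\n", sep = "")
  invisible(object)
}
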