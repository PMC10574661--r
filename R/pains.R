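#' Load a reference list of known aggregators
#'
#' Aggregators (promiscuous colloid-forming compounds) cause false positives
#' in biochemical screens; candidates matching a curated aggregator list are
#' flagged at the end of the screening cascade. The list is an input
#' artifact: any SMILES CSV (column `smiles`, optional `id`) can be used. A
#' small synthetic fixture ships with the package
#' (`system.file("extdata", "aggregators_synthetic.csv", package =
#' "vscascade")`).
#'
#' @param x path to a SMILES CSV, or a `molecule_records` table.
#' @return object of class `aggregator_set`: standardized, deduplicated
#'   records with a cached MACCS fingerprint matrix.
#' @export
load_aggregators <- function(x) {
  records <- if (is.character(x)) read_library(x, "csv") else x
  if (!nrow(records)) stop("empty aggregator list")
  records <- deduplicate_records(records)
  fp <- fingerprints(records, "maccs166")
  message("loaded ", nrow(records), " aggregator(s)")
  structure(list(records = records, fp = unclass(fp)),
            class = "aggregator_set")
}

#' Flag candidates matching known aggregators
#'
#' A candidate is flagged when its canonical SMILES is identical to an
#' aggregator's, or when its MACCS Tanimoto similarity to any aggregator
#' reaches `threshold` (default 1.0, the strictest similarity reading;
#' lower thresholds give advisory near-matches). The best-matching
#' aggregator and its similarity are always reported.
#'
#' @param candidates `molecule_records` (standardized).
#' @param aggset an `aggregator_set`.
#' @param threshold MACCS Tanimoto flagging threshold in (0, 1].
#' @return data.frame: `id`, `flag`, `best_match_id`, `similarity`.
#' @export
flag_aggregator <- function(candidates, aggset, threshold = 1.0) {
  stopifnot(inherits(aggset, "aggregator_set"),
            threshold > 0, threshold <= 1)
  n <- nrow(candidates)
  if (!nrow(aggset$records)) {
    return(data.frame(id = candidates$id, flag = rep(FALSE, n),
                      best_match_id = NA_character_,
                      similarity = NA_real_, stringsAsFactors = FALSE))
  }
  fp <- unclass(fingerprints(candidates, "maccs166"))
  tc <- tanimoto_matrix(fp, aggset$fp)
  best <- max.col(tc, ties.method = "first")
  best_sim <- tc[cbind(seq_len(n), best)]
  exact <- candidates$smiles %in% aggset$records$smiles
  data.frame(id = candidates$id,
             flag = exact | best_sim >= threshold,
             best_match_id = aggset$records$id[best],
             similarity = best_sim,
             stringsAsFactors = FALSE)
}

#' @export
print.aggregator_set <- function(x, ...) {
  cat("<aggregator_set> ", nrow(x$records),
      " known aggregators (MACCS cached)\n", sep = "")
  invisible(x)
}
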