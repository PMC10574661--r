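#' Feature matrices
#'
#' A feature matrix is a numeric matrix (rows = molecules, identified by
#' rownames; columns = named features) carrying its `kind`
#' (`"fingerprint"` or `"descriptor"`) and an ordered provenance of the
#' transforms applied to it.
#'
#' @param values numeric matrix with unique column names.
#' @param kind `"fingerprint"` or `"descriptor"`.
#' @param provenance character vector of transform tags.
#' @return object of class `feature_matrix` (a matrix with attributes).
#' @export
feature_matrix <- function(values, kind = c("fingerprint", "descriptor"),
                           provenance = character(0)) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !anyDuplicated(colnames(values)), !anyNA(values))
  if (kind == "fingerprint" && !all(values %in% c(0, 1))) {
    stop("fingerprint feature matrices must be binary")
  }
  structure(values, kind = kind, provenance = provenance,
            class = c("feature_matrix", class(values)))
}

fm_kind <- function(fm) attr(fm, "kind")
fm_provenance <- function(fm) attr(fm, "provenance")

fm_update <- function(fm, values, tag) {
  feature_matrix(values, kind = fm_kind(fm),
                 provenance = c(fm_provenance(fm), tag))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x), " x ", ncol(x), " (", fm_kind(x), ")\n",
      sep = "")
  if (length(fm_provenance(x))) {
    cat("provenance:", paste(fm_provenance(x), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Molecular fingerprints
#'
#' Computes binary structural fingerprints for standardized molecules:
#' `maccs166` (166 dictionary keys), `path1024` (1024-bit linear-path
#' topological fingerprint), or `ecfp4_1024` (circular fingerprint of radius
#' 2, folded from 4096 to 1024 bits by OR over index modulo 1024). All three
#' are computed by OpenBabel and are deterministic per molecule.
#'
#' @param records `molecule_records` (or a character vector of canonical
#'   SMILES).
#' @param kind fingerprint kind.
#' @return a binary `feature_matrix` with 166 or 1024 columns.
#' @export
fingerprints <- function(records, kind = c("maccs166", "path1024",
                                           "ecfp4_1024")) {
  kind <- match.arg(kind)
  smiles <- if (is.data.frame(records)) records$smiles else records
  ids <- if (is.data.frame(records)) records$id else
    paste0("mol", seq_along(smiles))
  mat <- switch(kind,
    maccs166 = ob_fps(smiles, "MACCS")[, 1:166, drop = FALSE],
    path1024 = ob_fps(smiles, "FP2"),
    ecfp4_1024 = fold_bits(ob_fps(smiles, "ECFP4"), 1024L))
  colnames(mat) <- sprintf("%s_%04d", kind, seq_len(ncol(mat)))
  rownames(mat) <- ids
  feature_matrix(mat, "fingerprint", paste0("fingerprints(", kind, ")"))
}

fold_bits <- function(mat, width) {
  stopifnot(ncol(mat) %% width == 0L)
  out <- matrix(0L, nrow(mat), width)
  for (b in seq_len(ncol(mat) / width)) {
    blk <- mat[, (b - 1L) * width + seq_len(width), drop = FALSE]
    out <- pmax(out, blk)
  }
  out
}

# ---- descriptor providers ------------------------------------------------

descriptor_registry <- new.env(parent = emptyenv())

#' Register a descriptor provider
#'
#' Descriptor sets are pluggable: a provider is a function taking a
#' `molecule_records` table and returning a numeric matrix with named
#' columns. Two open 2D providers ship with the package (`physchem_2d`,
#' `fragment_counts`); a 3D or external set can be registered under a new id
#' without touching the modeling code.
#'
#' @param set_id provider identifier.
#' @param fun function(records) -> numeric matrix.
#' @export
register_descriptor_provider <- function(set_id, fun) {
  stopifnot(is.character(set_id), is.function(fun))
  assign(set_id, fun, envir = descriptor_registry)
  invisible(set_id)
}

#' Molecular descriptors
#'
#' Computes a fixed, documented descriptor block per `set_id`:
#' * `physchem_2d`: 21 global 2D physicochemical descriptors (molecular
#'   weight, logP by atom contribution, topological polar surface area,
#'   molar refractivity, H-bond donor/acceptor counts, atom/element/ring/
#'   rotatable-bond counts, aromatic fraction, ...).
#' * `fragment_counts`: counts of 32 functional groups and ring motifs
#'   matched as SMARTS patterns.
#'
#' Descriptor values that cannot be computed are imputed with the
#' training-set median via [autoscale_fit()]-compatible `impute` (here:
#' computed values are always finite, so no sentinel remains in practice).
#'
#' @param records `molecule_records`.
#' @param set_id descriptor set id (built-in or registered).
#' @return a `feature_matrix` of kind `"descriptor"`.
#' @export
descriptors <- function(records, set_id = c("physchem_2d", "fragment_counts")) {
  if (length(set_id) == 1L && exists(set_id, envir = descriptor_registry)) {
    fun <- get(set_id, envir = descriptor_registry)
  } else {
    set_id <- match.arg(set_id)
    fun <- switch(set_id, physchem_2d = physchem_2d_provider,
                  fragment_counts = fragment_counts_provider)
  }
  mat <- fun(records)
  rownames(mat) <- records$id
  # median-impute any failed (non-finite) descriptor values
  bad <- !is.finite(mat)
  if (any(bad)) {
    for (j in which(colSums(bad) > 0L)) {
      med <- stats::median(mat[is.finite(mat[, j]), j])
      mat[bad[, j], j] <- if (is.finite(med)) med else 0
    }
  }
  feature_matrix(mat, "descriptor", paste0("descriptors(", set_id, ")"))
}

physchem_2d_provider <- function(records) {
  sdf <- smiles_to_sdfset(records$smiles, records$id)
  p <- ChemmineR::propOB(sdf)
  elems <- lapply(records$smiles, smiles_elements)
  nheavy <- vapply(elems, length, 0L)
  cnt <- function(sym) vapply(elems, function(e) sum(e %in% sym), 0L)
  arom <- vapply(records$smiles, function(s) {
    toks <- smiles_elements_raw(s)
    sum(toks %in% c("b", "c", "n", "o", "p", "s"))
  }, 0L)
  nring <- vapply(seq_along(sdf), function(i) {
    bb <- ChemmineR::bondblock(sdf[[i]])
    ab <- ChemmineR::atomblock(sdf[[i]])
    nrow(bb) - nrow(ab) + 1L  # cyclomatic number of a connected fragment
  }, 0L)
  nrot <- ChemmineOB::smartsSearch_OB(
    obmol_refs(sdf), "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE)
  cbind(MW = p$MW, LogP = p$logP, TPSA = p$TPSA, MR = p$MR,
        HBA = p$HBA1, HBD = p$HBD,
        n_heavy = nheavy, n_C = cnt("C"), n_N = cnt("N"), n_O = cnt("O"),
        n_S = cnt("S"), n_halogen = cnt(c("F", "Cl", "Br", "I")),
        n_F = p$nF, n_rings = nring, n_aromatic_atoms = arom,
        frac_aromatic = ifelse(nheavy > 0, arom / nheavy, 0),
        n_rotatable = as.numeric(nrot),
        heteroatom_ratio = ifelse(nheavy > 0, 1 - cnt("C") / nheavy, 0),
        MW_per_heavy = ifelse(nheavy > 0, p$MW / nheavy, 0),
        HBondSites = p$HBA1 + p$HBD,
        n_atoms_total = nheavy + pmax(0, round((p$MW - amass(elems)) / 1.008)))
}

# all SMILES atom tokens including aromatic lower-case, for aromatic counts
smiles_elements_raw <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  be <- vapply(brackets, function(b) {
    m <- regmatches(b, regexec("^\\[[0-9]*([A-Z][a-z]?|[a-z]{1,2})", b))[[1]]
    if (length(m) == 2L) m[2] else ""
  }, "", USE.NAMES = FALSE)
  rest <- gsub("\\[[^]]*\\]", "", smiles)
  c(be, regmatches(rest, gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]", rest))[[1]])
}

amass <- function(elems) {
  w <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
         F = 18.998, Cl = 35.45, Br = 79.904, I = 126.9, B = 10.81)
  vapply(elems, function(e) {
    m <- w[e]
    sum(ifelse(is.na(m), 30, m))
  }, 0)
}

FRAGMENT_SMARTS <- c(
  carboxylic_acid = "C(=O)[OX2H1]",
  carboxylate     = "C(=O)[O-]",
  ester           = "C(=O)O[#6]",
  amide           = "C(=O)[NX3]",
  sulfonamide     = "S(=O)(=O)[NX3]",
  sulfone         = "[#6]S(=O)(=O)[#6]",
  sulfoxide       = "[#6][SX3](=O)[#6]",
  nitro           = "[N+](=O)[O-]",
  nitrile         = "C#N",
  aldehyde        = "[CX3H1]=O",
  ketone          = "[#6][CX3](=O)[#6]",
  hydroxyl        = "[OX2H]",
  phenol          = "c[OX2H]",
  ether           = "[#6][OX2][#6]",
  methoxy         = "[CH3][OX2]",
  primary_amine   = "[NX3H2][#6]",
  secondary_amine = "[NX3H1]([#6])[#6]",
  tertiary_amine  = "[NX3]([#6])([#6])[#6]",
  guanidine       = "NC(=N)N",
  urea            = "NC(=O)N",
  thiol           = "[SX2H]",
  thioether       = "[#6][SX2][#6]",
  trifluoromethyl = "C(F)(F)F",
  halogen_on_arene = "c[F,Cl,Br,I]",
  alkene          = "[CX3]=[CX3]",
  alkyne          = "C#C",
  benzene_ring    = "c1ccccc1",
  pyridine_ring   = "c1ccncc1",
  furan_ring      = "c1ccoc1",
  thiophene_ring  = "c1ccsc1",
  pyrrole_ring    = "c1cc[nH]c1",
  imidazole_ring  = "c1cnc[nH]1")

fragment_counts_provider <- function(records) {
  sdf <- smiles_to_sdfset(records$smiles, records$id)
  refs <- obmol_refs(sdf)
  cols <- lapply(FRAGMENT_SMARTS, function(pat)
    as.numeric(ChemmineOB::smartsSearch_OB(refs, pat, uniqueMatches = TRUE)))
  do.call(cbind, cols)
}

# OBMol references for a whole SDFset, reused across SMARTS queries so the
# set is parsed once rather than once per pattern.
obmol_refs <- function(sdf) ChemmineR::obmol(sdf)

# ---- filtering, ranking, scaling -----------------------------------------

#' Low-variance feature filter
#'
#' Removes the `floor(d * quartile)` lowest-variance columns; variance ties
#' are broken by column index (the lower index is dropped first). Intended
#' for binary fingerprints where near-constant bits carry no signal.
#'
#' @param fm a `feature_matrix` with at least two rows.
#' @param quartile fraction of columns to drop, in (0, 1); default 0.25.
#' @return the filtered `feature_matrix` (provenance appended).
#' @export
variance_filter <- function(fm, quartile = 0.25) {
  if (!is.numeric(quartile) || quartile <= 0 || quartile >= 1) {
    stop("quartile must be inside (0, 1)")
  }
  stopifnot(nrow(fm) >= 2L)
  v <- apply(fm, 2L, stats::var)
  ndrop <- floor(ncol(fm) * quartile)
  drop_idx <- order(v, seq_along(v))[seq_len(ndrop)]
  vals <- unclass(fm)[, setdiff(seq_len(ncol(fm)), drop_idx), drop = FALSE]
  fm_update(fm, vals, sprintf("variance_filter(q=%g)", quartile))
}

#' Pairwise-correlation feature filter
#'
#' For every feature pair whose absolute Pearson correlation exceeds
#' `r_cut`, the member with the lower absolute correlation to the response
#' is removed; pairs are processed greedily in order of descending absolute
#' correlation. Constant features are treated as having zero correlation
#' with the response (and unit correlation with identical columns), so
#' exact duplicates always lose one copy.
#'
#' @param fm a `feature_matrix`.
#' @param y numeric (or two-level) response, length `nrow(fm)`.
#' @param r_cut correlation threshold, default 0.95.
#' @return the filtered `feature_matrix`.
#' @export
pcc_filter <- function(fm, y, r_cut = 0.95) {
  stopifnot(nrow(fm) == length(y))
  if (is.factor(y)) y <- as.numeric(y)
  if (ncol(fm) < 2L) return(fm)
  cm <- suppressWarnings(stats::cor(unclass(fm)))
  cm[is.na(cm)] <- 0
  # identical columns are perfectly correlated even when constant
  dup <- duplicated(t(unclass(fm))) | duplicated(t(unclass(fm)), fromLast = TRUE)
  if (any(dup)) {
    di <- which(dup)
    for (a in di) for (b in di) {
      if (a < b && identical(unclass(fm)[, a], unclass(fm)[, b])) {
        cm[a, b] <- cm[b, a] <- 1
      }
    }
  }
  ry <- suppressWarnings(abs(stats::cor(unclass(fm), y)))
  ry[is.na(ry)] <- 0
  ut <- which(upper.tri(cm) & abs(cm) > r_cut, arr.ind = TRUE)
  keep <- rep(TRUE, ncol(fm))
  if (nrow(ut)) {
    ord <- order(-abs(cm[ut]))
    for (k in ord) {
      i <- ut[k, 1L]; j <- ut[k, 2L]
      if (keep[i] && keep[j]) {
        # drop the member less correlated with the response; ties drop the
        # higher column index
        drop <- if (ry[i] < ry[j]) i else j
        keep[drop] <- FALSE
      }
    }
  }
  vals <- unclass(fm)[, keep, drop = FALSE]
  fm_update(fm, vals, sprintf("pcc_filter(r_cut=%g)", r_cut))
}

#' Random-forest recursive feature elimination ranking
#'
#' Iteratively fits a random forest and removes the least important feature
#' (impurity importance; ties broken by dropping the higher column index)
#' until one feature remains. The returned ranking lists features from most
#' to least important: the survivor first, then features in reverse order of
#' elimination. Deterministic given `seed`.
#'
#' @param fm a `feature_matrix` of training data.
#' @param y response (factor for classification, numeric for regression).
#' @param seed integer seed.
#' @param num_trees forest size per elimination step (default 500).
#' @return character vector: feature names, most- to least-important.
#' @export
rfrfe_rank <- function(fm, y, seed = 1L, num_trees = 500L) {
  stopifnot(nrow(fm) == length(y))
  feats <- colnames(fm)
  if (length(feats) == 1L) return(feats)
  x <- as.data.frame(unclass(fm))
  names(x) <- make.names(feats)  # ranger needs syntactic names
  key <- stats::setNames(feats, names(x))
  eliminated <- character(0)
  remaining <- names(x)
  while (length(remaining) > 1L) {
    fit <- ranger::ranger(
      x = x[remaining], y = y, num.trees = num_trees,
      importance = "impurity", seed = seed, num.threads = 1L,
      verbose = FALSE)
    imp <- fit$variable.importance[remaining]
    worst <- remaining[order(imp, -seq_along(remaining))[1L]]
    eliminated <- c(worst, eliminated)
    remaining <- setdiff(remaining, worst)
  }
  unname(key[c(remaining, eliminated)])
}

#' Range scaling to [0.1, 0.9]
#'
#' `autoscale_fit` learns per-feature minima and maxima on a training
#' matrix; `autoscale_apply` maps the training minimum to 0.1 and maximum to
#' 0.9, linearly in between. Constant training features map to 0.5.
#' Out-of-range values in new data are NOT clipped (a test value above the
#' training maximum scales above 0.9).
#'
#' @param fm_train training `feature_matrix`.
#' @return `autoscale_fit`: an object of class `scaler_params` (per-feature
#'   min/max and the target interval).
#' @export
autoscale_fit <- function(fm_train) {
  list(
    features = colnames(fm_train),
    min = apply(fm_train, 2L, min),
    max = apply(fm_train, 2L, max),
    lo = 0.1, hi = 0.9
  ) -> p
  class(p) <- "scaler_params"
  p
}

#' @rdname autoscale_fit
#' @param fm a `feature_matrix` with the same features as the training data.
#' @param params a `scaler_params` object from `autoscale_fit`.
#' @export
autoscale_apply <- function(fm, params) {
  stopifnot(inherits(params, "scaler_params"))
  if (!identical(colnames(fm), params$features)) {
    stop("feature names do not match the fitted scaler")
  }
  rng <- params$max - params$min
  vals <- unclass(fm)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    out[, j] <- if (rng[j] == 0) {
      rep((params$lo + params$hi) / 2, nrow(vals))
    } else {
      params$lo + (vals[, j] - params$min[j]) / rng[j] *
        (params$hi - params$lo)
    }
  }
  fm2 <- fm_update(fm, out, "autoscale[0.1,0.9]")
  attr(fm2, "kind") <- "descriptor"
  fm2
}

# Subset a feature matrix to named features, preserving class/attributes.
fm_select <- function(fm, features) {
  miss <- setdiff(features, colnames(fm))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  vals <- unclass(fm)[, features, drop = FALSE]
  fm_update(fm, vals, sprintf("select(%d)", length(features)))
}
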