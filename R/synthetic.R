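# Scaffold templates (sprintf slots take substituent SMILES written as
# chain fragments that bond to the slot position) and substituent pool used
# by the default synthetic structure-activity generator. The pool mixes
# common medicinal-chemistry motifs; the pharmacophore substituents carrying
# activity effects (arylsulfonamide, trifluoromethyl, carboxamide) are
# detectable by MACCS/path/ECFP4 fingerprints and counted by the
# fragment_counts descriptor set.
SYN_SCAFFOLDS <- c(
  benzene      = "c1ccc(%s)cc1",
  pyridine     = "c1ccnc(%s)c1",
  naphthalene  = "c1ccc2ccc(%s)cc2c1",
  indole       = "c1ccc2[nH]cc(%s)c2c1",
  biphenyl     = "c1ccc(-c2ccc(%s)cc2)cc1",
  quinoline    = "c1ccc2ncc(%s)cc2c1",
  piperidinyl  = "C1CCN(CC1)c1ccc(%s)cc1",
  furylphenyl  = "c1ccc(-c2ccco2)c(%s)c1"
)

SYN_SUBSTITUENTS <- c(
  hydrogen        = "",
  methyl          = "C",
  methoxy         = "OC",
  hydroxyl        = "O",
  chloro          = "Cl",
  fluoro          = "F",
  nitro           = "[N+](=O)[O-]",
  amino           = "N",
  sulfonamide     = "S(N)(=O)=O",
  trifluoromethyl = "C(F)(F)F",
  carboxamide     = "C(N)=O",
  carboxyl        = "C(O)=O",
  acetyl          = "C(C)=O",
  cyano           = "C#N"
)

# pIC50 effects of planted substructures (SMARTS matched on the realized
# molecules, not on the construction recipe)
SYN_EFFECTS <- c(
  "S(=O)(=O)[NX3]" = 1.8,   # sulfonamide pharmacophore
  "C(F)(F)F"       = 1.7,   # trifluoromethyl
  "C(=O)[NX3]"     = 1.6,   # carboxamide
  "[N+](=O)[O-]"   = -1.5   # nitro, deactivating
)

# substituents carrying positive planted effects, and the scaffolds whose
# series are preferentially decorated with them (congeneric active series)
SYN_PHARMACOPHORES <- c("sulfonamide", "trifluoromethyl", "carboxamide")
SYN_ACTIVE_SERIES <- c("benzene", "indole", "quinoline", "piperidinyl")

#' Specification for the synthetic structure-activity generator
#'
#' Molecules are built by attaching one or two substituents from a pool onto
#' ring scaffolds; the activity model is linear in substructure indicators,
#' `pIC50 = beta0 + sum_k beta_k * 1[substructure k present] + eps`,
#' `eps ~ Normal(0, sigma^2)`, so IC50 noise is log-normal. The defaults
#' give a baseline pIC50 of 4.4 (weakly active under a 10 uM cut),
#' substructure effects of 1.5-1.8 pIC50 units for three pharmacophore-like
#' groups and -1.0 for a deactivating group, noise sigma 0.2, and roughly
#' balanced classes under the `cut_10um` labeling scheme.
#'
#' @param n_molecules library size (default 2000).
#' @param scaffolds named character vector of scaffold templates with one
#'   `%s` substitution slot.
#' @param substituents named character vector of substituent fragments
#'   (`""` = unsubstituted position).
#' @param effects named numeric vector: SMARTS pattern -> pIC50 effect.
#' @param beta0 baseline pIC50 (default 4.2).
#' @param sigma Gaussian pIC50 noise standard deviation (default 0.2).
#' @param scheme labeling scheme for class targets (default `cut_10um`).
#' @param max_substituents substituents per molecule drawn uniformly from
#'   1..max (default 2).
#' @param pharmacophores names (into `substituents`) of the groups carrying
#'   positive effects.
#' @param active_series names (into `scaffolds`) of the congeneric series
#'   preferentially decorated with pharmacophores.
#' @param p_pharma_active,p_pharma_other probability that a molecule's first
#'   substituent is a pharmacophore, on active-series vs other scaffolds
#'   (defaults 0.9 / 0.05). Real screening datasets are built from
#'   congeneric series in which potency-driving groups concentrate on a few
#'   chemotypes; these propensities reproduce that structure, which is what
#'   makes activity cluster on a self-organizing map.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 2000L,
                           scaffolds = SYN_SCAFFOLDS,
                           substituents = SYN_SUBSTITUENTS,
                           effects = SYN_EFFECTS,
                           beta0 = 4.2, sigma = 0.2,
                           scheme = builtin_schemes()$cut_10um,
                           max_substituents = 2L,
                           pharmacophores = SYN_PHARMACOPHORES,
                           active_series = SYN_ACTIVE_SERIES,
                           p_pharma_active = 0.9, p_pharma_other = 0.05,
                           seed = 1L) {
  stopifnot(n_molecules >= 1L, length(scaffolds) >= 1L,
            length(substituents) >= 1L, sigma >= 0,
            inherits(scheme, "label_scheme"),
            all(pharmacophores %in% names(substituents)),
            all(active_series %in% names(scaffolds)))
  structure(list(n_molecules = as.integer(n_molecules),
                 scaffolds = scaffolds, substituents = substituents,
                 effects = effects, beta0 = beta0, sigma = sigma,
                 scheme = scheme,
                 max_substituents = as.integer(max_substituents),
                 pharmacophores = pharmacophores,
                 active_series = active_series,
                 p_pharma_active = p_pharma_active,
                 p_pharma_other = p_pharma_other,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate an unlabeled synthetic library
#'
#' Samples scaffold + substituent combinations, assembles SMILES, and
#' standardizes the result. Chemically invalid combinations are resampled
#' (with a retry cap); all returned molecules are valid, canonical and
#' carry a `synthetic` source tag. Seeded and reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @param id_prefix id prefix (default `"syn"`).
#' @return `molecule_records` (without activity).
#' @export
generate_library <- function(spec, id_prefix = "syn") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_molecules
  plain <- setdiff(names(spec$substituents), spec$pharmacophores)
  build <- function(m) {
    sci <- sample.int(length(spec$scaffolds), m, replace = TRUE)
    sc <- spec$scaffolds[sci]
    on_active <- names(spec$scaffolds)[sci] %in% spec$active_series
    nsub <- sample.int(spec$max_substituents, m, replace = TRUE)
    # first substituent: pharmacophore with scaffold-dependent propensity
    p_ph <- ifelse(on_active, spec$p_pharma_active, spec$p_pharma_other)
    is_ph <- stats::runif(m) < p_ph & length(spec$pharmacophores) > 0
    first <- character(m)
    if (any(is_ph)) first[is_ph] <- spec$substituents[
      spec$pharmacophores[sample.int(length(spec$pharmacophores),
                                     sum(is_ph), replace = TRUE)]]
    if (any(!is_ph)) first[!is_ph] <- spec$substituents[
      plain[sample.int(length(plain), sum(!is_ph), replace = TRUE)]]
    # second substituent: drawn from the plain pool only
    second <- spec$substituents[
      plain[sample.int(length(plain), m, replace = TRUE)]]
    # a second substituent (when drawn) is prepended as a chain on the slot
    # position; empty fragments collapse gracefully
    frag <- ifelse(nsub >= 2L & nzchar(second) & nzchar(first),
                   paste0("C(", first, ")", second),
                   paste0(first, second))
    ifelse(nzchar(frag), sprintf(sc, frag),
           gsub("(%s)", "", sc, fixed = TRUE))
  }
  smiles <- character(0)
  tries <- 0L
  need <- n
  while (need > 0L && tries < 10L) {
    cand <- build(need)
    std <- standardize_smiles(cand)
    smiles <- c(smiles, std$smiles[std$ok])
    need <- n - length(smiles)
    tries <- tries + 1L
  }
  if (need > 0L) stop("could not assemble ", n, " valid molecules")
  molecule_records(smiles[seq_len(n)],
                   id = sprintf("%s%05d", id_prefix, seq_len(n)),
                   source = "synthetic")
}

# indicator matrix of the effect substructures on realized molecules
effect_indicators <- function(records, effects) {
  sdf <- smiles_to_sdfset(records$smiles, records$id)
  refs <- obmol_refs(sdf)
  ind <- vapply(names(effects), function(pat) {
    as.numeric(ChemmineOB::smartsSearch_OB(refs, pat,
                                           uniqueMatches = TRUE)) > 0
  }, logical(nrow(records)))
  matrix(ind, nrow = nrow(records),
         dimnames = list(records$id, names(effects)))
}

#' Assign synthetic activities
#'
#' Computes `pIC50 = beta0 + sum_k beta_k * 1[substructure k] + eps` with
#' `eps ~ Normal(0, sigma^2)` (seeded), derives `IC50 = 10^(6 - pIC50)` uM,
#' and attaches the noiseless ground truth (`true_pic50`) per molecule.
#'
#' @param records `molecule_records` from [generate_library()].
#' @param spec the generating [synthetic_spec()].
#' @param seed_offset shifts the noise seed so independent sets drawn from
#'   one spec get independent noise.
#' @return the records with `pic50`, `ic50_um` and `true_pic50` columns.
#' @export
assign_activity <- function(records, spec, seed_offset = 0L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ind <- effect_indicators(records, spec$effects)
  true_pic50 <- spec$beta0 + as.numeric(ind %*% spec$effects)
  set.seed(spec$seed + 10000L + seed_offset)
  eps <- stats::rnorm(nrow(records), 0, spec$sigma)
  records$pic50 <- true_pic50 + eps
  records$ic50_um <- ic50_from_pic50(records$pic50)
  records$true_pic50 <- true_pic50
  records
}

#' Generate a complete synthetic screening study
#'
#' Builds everything the pipeline needs with known ground truth: a labeled
#' training dataset, an external validation set, an unlabeled screening
#' library, and a truth table recording each screening molecule's noiseless
#' pIC50 and true activity class (planted actives are screening molecules
#' whose noiseless IC50 falls in the scheme's highly-active class).
#'
#' @param spec_train generator spec for the labeled data.
#' @param n_external external validation set size (default 400).
#' @param n_screen screening library size (default 1000).
#' @return list of class `synthetic_benchmark`: `train`
#'   (`molecule_records` with activity), `external`, `screen` (unlabeled),
#'   `truth` (data.frame id/true_pic50/true_label), `scheme`.
#' @export
generate_benchmark <- function(spec_train = synthetic_spec(),
                               n_external = 400L, n_screen = 1000L) {
  stopifnot(inherits(spec_train, "synthetic_spec"))
  train <- assign_activity(generate_library(spec_train, "trn"), spec_train)
  spec_ext <- spec_train
  spec_ext$n_molecules <- as.integer(n_external)
  spec_ext$seed <- spec_train$seed + 1L
  external <- assign_activity(generate_library(spec_ext, "ext"), spec_ext,
                              seed_offset = 1L)
  spec_scr <- spec_train
  spec_scr$n_molecules <- as.integer(n_screen)
  spec_scr$seed <- spec_train$seed + 2L
  screen <- generate_library(spec_scr, "scr")
  ind <- effect_indicators(screen, spec_scr$effects)
  true_pic50 <- spec_scr$beta0 + as.numeric(ind %*% spec_scr$effects)
  truth <- data.frame(
    id = screen$id, true_pic50 = true_pic50,
    true_label = as.character(
      label_activity(ic50_from_pic50(true_pic50), spec_train$scheme)),
    stringsAsFactors = FALSE)
  lab <- label_activity(train$ic50_um, spec_train$scheme)
  if (length(unique(lab[lab != "excluded"])) < 2L) {
    stop("class balance unattainable: the generated training set lacks a class")
  }
  structure(list(train = train, external = external, screen = screen,
                 truth = truth, scheme = spec_train$scheme,
                 spec = spec_train),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  lab <- label_activity(x$train$ic50_um, x$scheme)
  cat("<synthetic_benchmark> train ", nrow(x$train), " (",
      sum(lab == "high"), " high / ", sum(lab == "weak"), " weak), external ",
      nrow(x$external), ", screen ", nrow(x$screen), " (",
      sum(x$truth$true_label == "high"), " planted actives)\n", sep = "")
  invisible(x)
}
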