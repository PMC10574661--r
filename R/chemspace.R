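#' Tanimoto coefficient of two binary fingerprints
#'
#' `TC = |a AND b| / |a OR b|`; two all-zero fingerprints have TC 0 by
#' convention.
#'
#' @param fp_a,fp_b binary vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprint length mismatch")
  u <- sum(fp_a | fp_b)
  if (u == 0) return(0)
  sum(fp_a & fp_b) / u
}

# all-pairs Tanimoto via bit-matrix algebra
tanimoto_matrix <- function(A, B = A) {
  inter <- tcrossprod(A, B)
  ra <- rowSums(A); rb <- rowSums(B)
  uni <- outer(ra, rb, "+") - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  tc
}

#' Pairwise-similarity diversity profile of a library
#'
#' Computes the mean pairwise Tanimoto coefficient and the fraction of pairs
#' below a cut (default 0.6) over a fingerprint matrix. `mode = "exact"`
#' evaluates all n(n-1)/2 pairs; `mode = "sampled"` draws `max_pairs` pairs
#' uniformly without replacement (seeded), the desk-scale default for large
#' libraries.
#'
#' @param fm a fingerprint `feature_matrix` with n >= 2 rows.
#' @param cut dissimilarity cut for `frac_below` (default 0.6).
#' @param mode `"exact"` or `"sampled"`.
#' @param max_pairs pairs drawn in sampled mode (default 1e6).
#' @param seed sampling seed.
#' @return list of class `diversity_report`: `n_molecules`, `mean_tc`,
#'   `frac_below`, `mode`, `n_pairs_evaluated`, `seed`.
#' @export
diversity_stats <- function(fm, cut = 0.6, mode = c("sampled", "exact"),
                            max_pairs = 1e6, seed = 1L) {
  mode <- match.arg(mode)
  if (fm_kind(fm) != "fingerprint") stop("diversity_stats needs fingerprints")
  n <- nrow(fm)
  if (n < 2L) stop("need at least 2 molecules")
  npairs <- n * (n - 1) / 2
  A <- unclass(fm)
  if (mode == "exact" || max_pairs >= npairs) {
    tc <- tanimoto_matrix(A)
    vals <- tc[upper.tri(tc)]
    mode <- if (mode == "exact") "exact" else "sampled"
    n_eval <- npairs
  } else {
    set.seed(seed)
    ks <- sample(npairs, max_pairs)
    ij <- pair_index(ks, n)
    vals <- vapply(seq_len(nrow(ij)), function(r) {
      a <- A[ij[r, 1L], ]; b <- A[ij[r, 2L], ]
      u <- sum(a | b)
      if (u == 0) 0 else sum(a & b) / u
    }, 0)
    n_eval <- max_pairs
  }
  structure(list(n_molecules = n, mean_tc = mean(vals),
                 frac_below = mean(vals < cut), cut = cut, mode = mode,
                 n_pairs_evaluated = n_eval, seed = seed),
            class = "diversity_report")
}

# decode linear pair index k in 1..n(n-1)/2 to (i, j), i < j, row-major over
# the upper triangle
pair_index <- function(k, n) {
  k0 <- k - 1
  i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k0)) / 2)
  base <- i * n - i * (i + 1) / 2
  j <- k0 - base + i + 1
  cbind(as.integer(i + 1), as.integer(j + 1))
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    "<diversity_report> n=%d, mean TC=%.3f, %.2f%% of pairs below %.2f (%s, %g pairs)\n",
    x$n_molecules, x$mean_tc, 100 * x$frac_below, x$cut, x$mode,
    x$n_pairs_evaluated))
  invisible(x)
}

#' Murcko scaffolds
#'
#' Reduces each molecule to its ring systems plus the linkers connecting
#' them, with side chains removed; atoms attached to the scaffold by double
#' or triple bonds (e.g. exocyclic carbonyl oxygens) are retained. Acyclic
#' molecules have an empty scaffold (`""`).
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical scaffold SMILES (possibly `""`).
#' @export
murcko_scaffold <- function(smiles) {
  if (!length(smiles)) return(character(0))
  can <- ob_canonical(smiles)
  if (anyNA(can)) stop("unparsable SMILES passed to murcko_scaffold")
  sdf <- smiles_to_sdfset(can)
  out <- rep("", length(smiles))
  frag_strs <- character(0)
  for (i in seq_along(sdf)) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    keep <- murcko_atoms(nrow(ab), bb)
    if (!length(keep)) next
    sub <- ChemmineR::atomsubset(mol, keep)
    frag_strs <- c(frag_strs,
                   paste(ChemmineR::sdf2str(sub), collapse = "\n"))
  }
  if (length(frag_strs)) {
    res <- sdf_to_canonical(frag_strs)
    # molblock titles are the t<index> tokens assigned during SMILES->SDF
    pos <- as.integer(sub("^t", "", names(res)))
    out[pos] <- unname(res)
  }
  out
}

# scaffold atom indices: the 2-core of the molecular graph (rings + linkers
# between rings) plus atoms multiply bonded to it
murcko_atoms <- function(n_atoms, bondblock) {
  if (is.null(dim(bondblock)) || nrow(bondblock) == 0L) return(integer(0))
  edges <- cbind(bondblock[, 1L], bondblock[, 2L])
  order_ <- bondblock[, 3L]
  alive <- rep(TRUE, n_atoms)
  repeat {
    live <- alive[edges[, 1L]] & alive[edges[, 2L]]
    deg <- tabulate(c(edges[live, , drop = FALSE]), nbins = n_atoms)
    prune <- alive & deg <= 1L
    if (!any(prune)) break
    alive[prune] <- FALSE
  }
  core <- which(alive)
  if (!length(core)) return(integer(0))
  # re-attach atoms double/triple-bonded to the core
  multi <- order_ >= 2L
  add <- unique(c(
    edges[multi & (edges[, 1L] %in% core) & !(edges[, 2L] %in% core), 2L],
    edges[multi & (edges[, 2L] %in% core) & !(edges[, 1L] %in% core), 1L]))
  sort(c(core, add))
}

#' Scaffold clustering with a 2-D embedding
#'
#' Embeds the distinct Murcko scaffolds of a library (ECFP4 fingerprints) in
#' two dimensions and K-means-clusters the embedding. The default embedding
#' is t-SNE (package Rtsne) when available, else classical multidimensional
#' scaling of Tanimoto distances (`embed = "pcoa"`); clustering directly in
#' fingerprint space is available with `embed = "fingerprint"`.
#'
#' @param records `molecule_records`.
#' @param k number of clusters (default 11).
#' @param seed seed for the embedding and K-means.
#' @param embed `"tsne"`, `"pcoa"` or `"fingerprint"`.
#' @return data.frame (id, scaffold, x, y, cluster); molecules with empty
#'   scaffolds get `NA` cluster. Cluster labels are 0..k-1.
#' @export
cluster_scaffolds <- function(records, k = 11L, seed = 1L,
                              embed = c("tsne", "pcoa", "fingerprint")) {
  embed <- match.arg(embed)
  scaf <- murcko_scaffold(records$smiles)
  uniq <- unique(scaf[nzchar(scaf)])
  if (length(uniq) < k) stop("fewer distinct scaffolds (", length(uniq),
                             ") than clusters (", k, ")")
  fp <- unclass(fingerprints(uniq, "ecfp4_1024"))
  if (embed == "tsne" && !requireNamespace("Rtsne", quietly = TRUE)) {
    embed <- "pcoa"
  }
  set.seed(seed)
  xy <- switch(embed,
    tsne = {
      perp <- max(1, min(30, floor((length(uniq) - 1) / 3)))
      Rtsne::Rtsne(fp, perplexity = perp, check_duplicates = FALSE,
                   pca = length(uniq) > 50)$Y
    },
    pcoa = {
      d <- stats::as.dist(1 - tanimoto_matrix(fp))
      stats::cmdscale(d, k = 2)
    },
    fingerprint = NULL)
  feats <- if (embed == "fingerprint") fp else xy
  km <- if (k == 1L) list(cluster = rep(1L, length(uniq)))
        else stats::kmeans(feats, centers = k, nstart = 10L)
  if (is.null(xy)) {
    d <- stats::as.dist(1 - tanimoto_matrix(fp))
    xy <- stats::cmdscale(d, k = 2)
  }
  pos <- match(scaf, uniq)
  data.frame(id = records$id, scaffold = scaf,
             x = xy[pos, 1L], y = xy[pos, 2L],
             cluster = km$cluster[pos] - 1L,
             stringsAsFactors = FALSE)
}

#' Most frequent Murcko scaffolds
#'
#' @param records `molecule_records`.
#' @param n number of top scaffolds to report (default 20).
#' @return data.frame (scaffold, count, percent) sorted by descending count
#'   (ties lexicographic by scaffold); percents are relative to molecules
#'   with a non-empty scaffold. Empty for an all-acyclic library.
#' @export
top_scaffolds <- function(records, n = 20L) {
  scaf <- murcko_scaffold(records$smiles)
  scaf <- scaf[nzchar(scaf)]
  if (!length(scaf)) {
    return(data.frame(scaffold = character(0), count = integer(0),
                      percent = numeric(0)))
  }
  tab <- table(scaf)
  df <- data.frame(scaffold = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$scaffold), , drop = FALSE]
  df <- utils::head(df, n)
  df$percent <- 100 * df$count / length(scaf)
  rownames(df) <- NULL
  df
}
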