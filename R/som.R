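#' Train a self-organizing map with per-cell activity proportions
#'
#' Classic online Kohonen training on a rectangular grid: each input is
#' assigned to its best-matching unit (BMU, smallest Euclidean distance;
#' ties resolved to the lower row-major cell index) and the BMU's
#' neighborhood is pulled toward the input under a Gaussian kernel whose
#' learning rate and radius decay exponentially over epochs. After training,
#' every labeled training molecule is mapped once more and each cell records
#' `n_total` (molecules mapped there), `n_high` (highly active ones) and the
#' activity landscape statistic `HP = n_high / n_total` (`NA` for empty
#' cells): the proportion of a cell's molecules that are highly active.
#'
#' @param x `feature_matrix` (or numeric matrix) of the labeled training
#'   molecules; typically the same fingerprint kind used by the
#'   classification stage.
#' @param labels factor (high/weak) used for the per-cell counts; optional
#'   (an unlabeled map has empty counts).
#' @param width,height grid dimensions (default 10 x 11).
#' @param epochs training epochs (default 10).
#' @param alpha learning-rate start/end (default 0.5 -> 0.01).
#' @param radius neighborhood radius start/end; default
#'   `max(width, height)/2` -> 0.5.
#' @param seed integer seed (weight init and presentation order).
#' @return object of class `som_map`.
#' @export
som_fit <- function(x, labels = NULL, width = 10L, height = 11L,
                    epochs = 10L, alpha = c(0.5, 0.01), radius = NULL,
                    seed = 1L) {
  xm <- unclass(x)
  storage.mode(xm) <- "double"
  if (!nrow(xm)) stop("empty training input")
  if (anyNA(xm) || any(!is.finite(xm))) stop("non-finite training features")
  ncell <- as.integer(width) * as.integer(height)
  if (ncell < 2L) stop("the grid needs at least 2 cells")
  if (is.null(radius)) radius <- c(max(width, height) / 2, 0.5)
  set.seed(seed)
  # prototype init: sample training rows (with replacement when needed)
  init_idx <- sample.int(nrow(xm), ncell, replace = nrow(xm) < ncell)
  W <- xm[init_idx, , drop = FALSE]
  # grid coordinates, row-major: cell c -> (row, col)
  gr <- cbind(row = (seq_len(ncell) - 1L) %/% width,
              col = (seq_len(ncell) - 1L) %% width)
  grid_d2 <- as.matrix(stats::dist(gr))^2
  n <- nrow(xm)
  tmax <- epochs * n
  t <- 0L
  qe <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    qsum <- 0
    for (i in ord) {
      frac <- t / max(1L, tmax - 1L)
      a <- alpha[1L] * (alpha[2L] / alpha[1L])^frac
      r <- radius[1L] * (radius[2L] / radius[1L])^frac
      v <- xm[i, ]
      d2 <- rowSums(sweep(W, 2L, v)^2)
      bmu <- which.min(d2)  # lowest row-major index on ties
      qsum <- qsum + sqrt(d2[bmu])
      h <- a * exp(-grid_d2[, bmu] / (2 * r^2))
      act <- h > 1e-4
      W[act, ] <- W[act, , drop = FALSE] +
        h[act] * (matrix(v, sum(act), length(v), byrow = TRUE) -
                  W[act, , drop = FALSE])
      t <- t + 1L
    }
    qe[ep] <- qsum / n
  }
  obj <- structure(list(
    W = W, width = as.integer(width), height = as.integer(height),
    epochs = epochs, alpha = alpha, radius = radius, seed = seed,
    quantization_error = qe, features = colnames(xm),
    n_high = rep(0L, ncell), n_total = rep(0L, ncell),
    hp = rep(NA_real_, ncell)), class = "som_map")
  if (!is.null(labels)) {
    labels <- factor(as.character(labels), levels = c("high", "weak"))
    stopifnot(length(labels) == n)
    bmus <- som_bmu(obj, xm)
    obj$n_total <- tabulate(bmus, nbins = ncell)
    obj$n_high <- tabulate(bmus[labels == "high"], nbins = ncell)
    obj$hp <- ifelse(obj$n_total > 0, obj$n_high / obj$n_total, NA_real_)
  }
  obj
}

# best-matching unit (row-major cell index) for each row of xm
som_bmu <- function(object, xm) {
  W <- object$W
  # all-pairs squared distances via the expansion |x - w|^2
  cross <- xm %*% t(W)
  d2 <- outer(rowSums(xm^2), rep(1, nrow(W))) - 2 * cross +
    outer(rep(1, nrow(xm)), rowSums(W^2))
  max.col(-d2, ties.method = "first")
}

#' Map candidate molecules onto a trained SOM
#'
#' Each candidate is assigned to its best-matching unit and inherits that
#' cell's HP. Candidates landing in cells that no labeled training molecule
#' occupied get `hp = NA` (reported, never silently treated as 0).
#'
#' @param object a `som_map`.
#' @param newdata `feature_matrix` (or matrix) preprocessed identically to
#'   the training features.
#' @param ... unused.
#' @return data.frame: `cell` (row-major index), `row`, `col`, `hp`,
#'   `n_total` of the cell.
#' @export
predict.som_map <- function(object, newdata, ...) {
  xm <- unclass(newdata)
  storage.mode(xm) <- "double"
  if (ncol(xm) != ncol(object$W)) stop("feature dimension mismatch")
  if (!is.null(object$features) && !is.null(colnames(xm)) &&
      !identical(colnames(xm), object$features)) {
    stop("feature names do not match the trained map")
  }
  cell <- som_bmu(object, xm)
  data.frame(cell = cell,
             row = (cell - 1L) %/% object$width,
             col = (cell - 1L) %% object$width,
             hp = object$hp[cell],
             n_total = object$n_total[cell])
}

#' Screen SOM-mapped candidates by the HP rule
#'
#' Keeps candidates whose cell HP is defined and at least `threshold` (the
#' "over 80 percent" rule; set `strict = TRUE` for a strict inequality).
#' Unmapped candidates (empty cell, `hp = NA`) are dropped with reason
#' `"unmapped"`.
#'
#' @param assignments data.frame from [predict.som_map()].
#' @param threshold HP threshold (default 0.8).
#' @param strict use `>` instead of `>=`.
#' @return the assignments with logical `keep` and character `reason`
#'   columns added.
#' @export
screen_by_hp <- function(assignments, threshold = 0.8, strict = FALSE) {
  hp <- assignments$hp
  keep <- !is.na(hp) & (if (strict) hp > threshold else hp >= threshold)
  assignments$keep <- keep
  assignments$reason <- ifelse(is.na(hp), "unmapped",
                               ifelse(keep, "", "low_hp"))
  assignments
}

#' @export
print.som_map <- function(x, ...) {
  cat("<som_map> ", x$height, " x ", x$width, " grid, ",
      ncol(x$W), " features, ", x$epochs, " epochs\n", sep = "")
  occ <- sum(x$n_total > 0)
  if (occ > 0) {
    cat("occupied cells: ", occ, "/", length(x$n_total),
        "; mapped molecules: ", sum(x$n_total),
        "; cells with HP >= 0.8: ", sum(!is.na(x$hp) & x$hp >= 0.8),
        "\n", sep = "")
  }
  cat("final quantization error: ",
      signif(utils::tail(x$quantization_error, 1L), 4), "\n", sep = "")
  invisible(x)
}

#' Heat-map of the SOM activity landscape
#'
#' Draws the per-cell HP on the trained grid (warm = mostly highly active
#' inhibitors, cool = mostly weakly active; empty cells blank).
#'
#' @param x a `som_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.som_map <- function(x, ...) {
  m <- matrix(x$hp, nrow = x$width)  # column h = grid row h (row-major)
  graphics::image(x = seq_len(x$width), y = seq_len(x$height), z = m,
                  col = grDevices::hcl.colors(25, "Blue-Red 2"),
                  xlab = "column", ylab = "row",
                  main = "SOM activity landscape (HP)", ...)
  invisible(x)
}
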