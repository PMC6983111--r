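#' Unfold masked hypercubes into a pixels-by-bands matrix
#'
#' Stacks every foreground pixel spectrum of one or more samples into a
#' 2-D matrix: one row per pixel, one column per band. Rows are ordered
#' sample by sample, and within a sample in row-major spatial order
#' (row 1 left to right, then row 2, ...). The index maps each matrix row
#' back to `(sample, row, col)`, making the operation invertible via
#' [refold_scores()].
#'
#' @param cubes a list of entries, each `list(cube =, mask =, id =)`
#'   (`id` optional; defaults to `sample_<k>`). All cubes must share the
#'   same wavelength axis.
#' @return a list of class `unfolded_matrix`: `X` (pixels x bands),
#'   `index` (data.frame `sample`, `row`, `col`), `wavelengths`.
#' @export
unfold <- function(cubes) {
  stopifnot(is.list(cubes), length(cubes) >= 1L)
  wl <- cubes[[1]]$cube$wavelengths
  rows <- list(); idx <- list()
  for (k in seq_along(cubes)) {
    cb <- cubes[[k]]$cube; mk <- cubes[[k]]$mask
    id <- if (!is.null(cubes[[k]]$id)) cubes[[k]]$id else paste0("sample_", k)
    stopifnot(inherits(cb, "hyper_cube"), inherits(mk, "sample_mask"))
    if (!isTRUE(all.equal(cb$wavelengths, wl)))
      stop("wavelength axis of sample '", id,
           "' does not match the first sample")
    check_mask_cube(mk, cb)
    d <- dim(cb$values)
    w <- which(mk$mask, arr.ind = TRUE)
    ord <- order(w[, 1], w[, 2])           # row-major spatial order
    w <- w[ord, , drop = FALSE]
    flat <- matrix(cb$values, nrow = d[1] * d[2])
    rows[[k]] <- flat[(w[, 2] - 1L) * d[1] + w[, 1], , drop = FALSE]
    idx[[k]] <- data.frame(sample = id, row = w[, 1], col = w[, 2],
                           stringsAsFactors = FALSE)
  }
  index <- do.call(rbind, idx)
  if (anyDuplicated(index)) stop("duplicate (sample, row, col) in index")
  rownames(index) <- NULL
  structure(list(X = do.call(rbind, rows), index = index, wavelengths = wl),
            class = "unfolded_matrix")
}

#' Fit a principal component model to unfolded pixel spectra
#'
#' Decomposes the mean-centered matrix as scores times transposed
#' loadings plus residual. Centering only, no variance scaling (bands
#' share units, so correlation-mode PCA would distort the loadings that
#' drive waveband selection). The sign ambiguity of each component is
#' fixed by making its largest-magnitude loading element positive, so
#' score-image polarity is reproducible.
#'
#' @param unf an [unfold()] result, or a plain numeric matrix
#'   (pixels x bands).
#' @param n_components number of components to retain.
#' @return an object of class `pca_model`: `loadings` (bands x k, columns
#'   unit-norm and orthogonal), `scores` (pixels x k),
#'   `explained_variance_fraction` (length k, fractions of total
#'   variance), `mean_spectrum`, `wavelengths` (if available).
#' @export
fit_pca <- function(unf, n_components) {
  X <- if (inherits(unf, "unfolded_matrix")) unf$X else as.matrix(unf)
  wl <- if (inherits(unf, "unfolded_matrix")) unf$wavelengths else NULL
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(dim(X)))
    stop(sprintf("n_components must be in [1, %d]", min(dim(X))))

  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scor <- pc$x[, seq_len(k), drop = FALSE]
  evf <- pc$sdev^2 / sum(pc$sdev^2)

  # sign convention: largest-|loading| element of each column positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scor[, j] <- -scor[, j]
    }
  }
  if (!is.null(wl)) rownames(load) <- format(wl, trim = TRUE)

  structure(list(loadings = load, scores = scor,
                 explained_variance_fraction = evf[seq_len(k)],
                 all_variance_fractions = evf,
                 mean_spectrum = pc$center, wavelengths = wl),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d bands, %d pixels\n",
              ncol(x$loadings), nrow(x$loadings), nrow(x$scores)))
  cat("explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Refold a component's score vector into per-sample score images
#'
#' Inverts the unfolding: each sample's score values are placed back at
#' their pixel coordinates; background pixels hold `NA`.
#'
#' @param model a [fit_pca()] result fitted on the same unfolded matrix.
#' @param index the `index` data.frame from [unfold()].
#' @param shape spatial shape `c(rows, cols)` shared by all samples, or a
#'   named list of shapes keyed by sample id.
#' @param component which component's scores to refold.
#' @param samples sample ids to refold (default: all in the index).
#' @return a named list of score-image matrices.
#' @export
refold_scores <- function(model, index, shape, component = 2L,
                          samples = unique(index$sample)) {
  stopifnot(inherits(model, "pca_model"))
  component <- as.integer(component)
  if (component < 1L || component > ncol(model$scores))
    stop("component ", component, " not in fitted model")
  if (nrow(index) != nrow(model$scores))
    stop("index rows do not match score rows")
  out <- list()
  for (id in samples) {
    sel <- index$sample == id
    if (!any(sel)) stop("unknown sample id: '", id, "'")
    sh <- if (is.list(shape)) shape[[id]] else shape
    img <- matrix(NA_real_, sh[1], sh[2])
    img[cbind(index$row[sel], index$col[sel])] <- model$scores[sel, component]
    out[[id]] <- img
  }
  out
}

#' Rank components by how well they separate two sample groups
#'
#' For each fitted component, scores are averaged per sample and the
#' standardized difference between group means (absolute difference over
#' pooled standard deviation) is computed. A large value marks the
#' component that discriminates whitened from normal roots — the analyst's
#' aid for choosing the discriminating component, mirroring the visual
#' choice made from score images.
#'
#' @param model a [fit_pca()] result.
#' @param index the [unfold()] index matching the scores.
#' @param groups named character/factor: group label per sample id.
#' @return data.frame with `component`, `standardized_difference`,
#'   ordered best first.
#' @export
rank_components <- function(model, index, groups) {
  stopifnot(inherits(model, "pca_model"))
  ids <- unique(index$sample)
  g <- groups[ids]
  if (any(is.na(g))) stop("groups missing for some sample ids")
  lv <- unique(g)
  if (length(lv) != 2L) stop("exactly two groups required")
  k <- ncol(model$scores)
  sd_diff <- numeric(k)
  for (j in seq_len(k)) {
    per_sample <- tapply(model$scores[, j], index$sample, mean)[ids]
    a <- per_sample[g == lv[1]]; b <- per_sample[g == lv[2]]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
    sd_diff[j] <- if (sp > 0) abs(mean(a) - mean(b)) / sp else
      if (abs(mean(a) - mean(b)) > 0) Inf else 0
  }
  out <- data.frame(component = seq_len(k), standardized_difference = sd_diff)
  out[order(-out$standardized_difference), ]
}

#' Select characteristic wavebands from a component's loading vector
#'
#' Returns the wavelengths of the `n_bands` local extrema of the loading
#' with the largest absolute loading value. A local extremum is a band
#' whose `|loading|` strictly exceeds both neighbors (endpoints compare
#' against their single neighbor); a plateau of equal values counts once,
#' at its first band. Ties in `|loading|` break toward the lower
#' wavelength.
#'
#' @param model a [fit_pca()] result.
#' @param component component whose loading is scanned (default 2, the
#'   component that discriminates whitened tissue in this system).
#' @param n_bands how many wavebands to return (default 2).
#' @return numeric wavelengths (nm), ascending. If fewer extrema exist
#'   than requested, all found are returned with a warning.
#' @export
select_wavebands <- function(model, component = 2L, n_bands = 2L) {
  stopifnot(inherits(model, "pca_model"))
  component <- as.integer(component)
  if (component < 1L || component > ncol(model$loadings))
    stop("component ", component, " not in fitted model")
  if (is.null(model$wavelengths))
    stop("model has no wavelength axis; fit on an unfolded_matrix")
  v <- abs(model$loadings[, component])
  cand <- local_extrema(v)
  # rank by |loading| descending, ties toward lower wavelength
  cand <- cand[order(-v[cand], model$wavelengths[cand])]
  if (length(cand) < n_bands) {
    warning(sprintf("only %d local extrema found (requested %d)",
                    length(cand), n_bands))
    n_bands <- length(cand)
  }
  sort(model$wavelengths[cand[seq_len(n_bands)]])
}

# indices of strict local maxima of a non-negative vector; plateaus count
# once at their first index; endpoints compare to their single neighbor
local_extrema <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  keep <- logical(m)
  for (i in seq_len(m)) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == m || r$values[i] > r$values[i + 1L]
    keep[i] <- left_ok && right_ok
  }
  starts[keep]
}

#' One-way ANOVA between two sample groups at a single band
#'
#' Classical fixed-effects one-way analysis of variance computed from its
#' sums of squares: `F = MSB / MSW` with degrees of freedom `(k - 1,
#' N - k)` and the p-value from the upper tail of the F distribution.
#' The observation unit is the per-sample mean foreground spectrum — one
#' value per root, since pixels within a root are not independent.
#'
#' Degenerate cases: zero within-group variance with unequal group means
#' reports `F = Inf, p = 0`; identical constant groups report
#' `F = 0, p = 1`.
#'
#' @param group_a,group_b numeric matrices (samples x bands) of
#'   per-sample mean spectra, or numeric vectors when calling on a single
#'   band's values directly.
#' @param band band index (column) to test; ignored for vector input.
#' @return list with elements `F` and `p`.
#' @export
band_anova <- function(group_a, group_b, band = NULL) {
  a <- if (is.matrix(group_a)) group_a[, band] else as.numeric(group_a)
  b <- if (is.matrix(group_b)) group_b[, band] else as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples")
  oneway_f(list(a, b))
}

# k-group one-way ANOVA from scratch (sums of squares)
oneway_f <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  all_v <- unlist(groups)
  grand <- mean(all_v)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw <= 0) {
    if (ssb > 0) return(list(F = Inf, p = 0))
    return(list(F = 0, p = 1))
  }
  Fval <- (ssb / df1) / (ssw / df2)
  list(F = Fval, p = stats::pf(Fval, df1, df2, lower.tail = FALSE))
}

#' Per-band ANOVA ranking of wavebands
#'
#' Runs [band_anova()] at every band between the normal and abnormal
#' groups and tabulates F, p and (optionally) the PCA loadings, giving the
#' per-waveband discrimination table used to confirm the PCA-selected
#' bands.
#'
#' @param group_a,group_b matrices (samples x bands) of per-sample mean
#'   spectra.
#' @param wavelengths band centers (nm).
#' @param model optional [fit_pca()] result; its loadings are joined in.
#' @return data.frame with `wavelength`, `F`, `p`, and `loading_PC<k>`
#'   columns when a model is given.
#' @export
band_ranking <- function(group_a, group_b, wavelengths, model = NULL) {
  stopifnot(is.matrix(group_a), is.matrix(group_b),
            ncol(group_a) == ncol(group_b),
            ncol(group_a) == length(wavelengths))
  res <- lapply(seq_len(ncol(group_a)), function(b)
    band_anova(group_a, group_b, b))
  out <- data.frame(wavelength = wavelengths,
                    F = vapply(res, `[[`, numeric(1), "F"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  if (!is.null(model)) {
    stopifnot(nrow(model$loadings) == length(wavelengths))
    for (j in seq_len(ncol(model$loadings)))
      out[[paste0("loading_PC", j)]] <- model$loadings[, j]
  }
  out
}
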