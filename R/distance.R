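# Cohort band-power distance heatmaps and the per-band dissimilarity
# summary: every cell is a healthy-sensor x patient-sensor distance
# between group-mean band powers.

#' Per-phrase band-power distance matrix
#'
#' Cell (i, j) is the Euclidean distance between the mean band power of
#' healthy channel i and patient channel j for one phrase -- for scalar
#' powers this is the absolute difference.
#'
#' @param gm group-mean array from [group_mean_band_power()]
#'   (cohort x phrase x channel x band).
#' @param band band name.
#' @param phrase phrase id (matched against the phrase dimnames).
#' @return Non-negative channel x channel matrix (healthy rows, patient
#'   columns).
#' @export
distance_matrix <- function(gm, band, phrase) {
  h <- gm["healthy", as.character(phrase), , band]
  p <- gm["patient", as.character(phrase), , band]
  if (anyNA(h) || anyNA(p)) stop("missing cohort means for this cell")
  abs(outer(h, p, `-`))
}

#' Across-phrase band-power distance matrix
#'
#' Cell (i, j) is the Euclidean distance between the phrase-wise power
#' vectors (one coordinate per phrase) of healthy channel i and patient
#' channel j.
#'
#' @inheritParams distance_matrix
#' @return Non-negative channel x channel matrix.
#' @export
distance_matrix_across_phrases <- function(gm, band) {
  H <- gm["healthy", , , band, drop = FALSE]  # 1 x phrase x channel x 1
  P <- gm["patient", , , band, drop = FALSE]
  H <- matrix(H, dim(gm)[2], dim(gm)[3])  # phrase x channel
  P <- matrix(P, dim(gm)[2], dim(gm)[3])
  if (anyNA(H) || anyNA(P)) stop("missing phrase in group means")
  nch <- ncol(H)
  out <- matrix(0, nch, nch,
                dimnames = list(dimnames(gm)[[3]], dimnames(gm)[[3]]))
  # d(i, j) = || H[, i] - P[, j] || over the phrase coordinates
  for (j in seq_len(nch)) {
    out[, j] <- sqrt(colSums((H - P[, j])^2))
  }
  out
}

#' Joint min-max normalization of distance heatmaps
#'
#' Scales a set of distance matrices to `[0, 1]` using the global
#' minimum and maximum across the whole set, preserving cross-band
#' comparability.  Presentation-only: inferential summaries use
#' unnormalized distances.
#'
#' @param dms named list of distance matrices.
#' @return List of matrices on the shared `[0, 1]` scale.
#' @export
normalize_heatmap <- function(dms) {
  if (!length(dms)) stop("need at least one matrix")
  rng <- range(unlist(lapply(dms, range)))
  if (rng[1] == rng[2]) {
    warning("constant distance values; returning all-zero matrices")
    return(lapply(dms, function(m) m * 0))
  }
  lapply(dms, function(m) (m - rng[1]) / (rng[2] - rng[1]))
}

#' Per-band dissimilarity summary with ANOVA and Tukey post hoc
#'
#' Summarizes each band's healthy-vs-patient dissimilarity as the mean
#' of its per-phrase distance matrix (one sample per phrase), then
#' compares bands with a one-way ANOVA and Tukey HSD, and identifies the
#' band of maximal mean distance.
#'
#' @param gm group-mean array from [group_mean_band_power()].
#' @param bands band names to compare (default: all bands present).
#' @param alpha Tukey rejection level.
#' @return List: `samples` (band x phrase mean distances), `band_means`,
#'   `argmax_band`, `anova` (a `meg_test`), `tukey` (pairwise table),
#'   and `beta_vs_rest` (logical: does beta beat every other band with a
#'   significant Tukey flag, when beta is present).
#' @export
band_dissimilarity_summary <- function(gm, bands = NULL, alpha = 0.05) {
  if (is.null(bands)) bands <- dimnames(gm)[[4]]
  phrases <- dimnames(gm)[[2]]
  if (length(bands) < 2) stop("need at least 2 bands")
  samples <- sapply(bands, function(b) {
    vapply(phrases, function(ph) mean(distance_matrix(gm, b, ph)), 0)
  })  # phrase x band
  groups <- lapply(as.data.frame(samples), identity)
  names(groups) <- bands
  an <- one_way_anova(groups)
  tk <- tukey_hsd(groups, alpha = alpha)
  band_means <- colMeans(samples)
  argmax <- bands[which.max(band_means)]
  beta_vs_rest <- NA
  if ("beta" %in% bands) {
    inv <- grepl("(^beta-)|(-beta$)", tk$pair)
    beta_vs_rest <- all(tk$significant[inv]) &&
      which.max(band_means) == match("beta", bands)
  }
  list(samples = t(samples), band_means = band_means,
       argmax_band = argmax, anova = an, tukey = tk,
       beta_vs_rest = beta_vs_rest)
}
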