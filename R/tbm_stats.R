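## Voxel-wise statistics on Jacobian maps: Welch-type t maps and permutation
## inference with a pooled voxel null and Benjamini-Hochberg FDR.
##
## The pooling argument: with V voxels and P label permutations the null
## distribution holds V * P statistics, so the pooled-null resolution needed
## for FDR at level q (about V / q values) is reached with a modest number of
## label permutations rather than V / q of them.

#' Voxel-wise two-sample Welch t statistics
#'
#' `t = (meanA - meanB) / sqrt(sA^2/nA + sB^2/nB)` at each voxel (unequal
#' variances). Voxels with zero variance in both groups get t = 0 and are
#' flagged.
#'
#' @param a,b numeric matrices, one row per subject, one column per voxel
#'   (masked Jacobian values). At least 2 subjects per group.
#' @return list: `t` (numeric vector, one per voxel), `degenerate` (logical,
#'   zero-variance voxels).
#' @export
welch_t_map <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 subjects per group")
  stopifnot(ncol(a) == ncol(b))
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  degenerate <- se2 == 0
  t <- ifelse(degenerate, 0, (ma - mb) / sqrt(pmax(se2, .Machine$double.xmin)))
  list(t = t, degenerate = degenerate)
}

#' Required pooled-null size for FDR at level q
#'
#' `ceiling(n_voxels / q)`: the approximate number of null statistics needed
#' so that FDR-corrected p-values at level `q` are resolvable.
#'
#' @param n_voxels number of voxels tested (>= 1).
#' @param q FDR level in (0, 1].
#' @return integer.
#' @export
min_permutations <- function(n_voxels, q) {
  stopifnot(n_voxels >= 1, q > 0, q <= 1)
  as.integer(ceiling(n_voxels / q))
}

## all distinct assignments of na labels out of n subjects; columns =
## assignments, capped implicitly by the caller
group_splits <- function(n, na) {
  utils::combn(n, na)
}

#' Permutation inference with a pooled voxel null and FDR
#'
#' Recomputes the Welch t map under random relabellings of the subjects
#' (exchangeability unit = subject), pools the absolute null statistics from
#' all voxels into one null distribution, converts each observed |t| to
#' `p = (1 + #(null >= |t|)) / (1 + pool size)` (never exactly zero), and
#' applies Benjamini-Hochberg at level `q`. When the number of distinct
#' relabellings is at most `n_perm` the null is enumerated exhaustively (with
#' a warning). Optional stratified shuffling permutes labels within strata
#' (e.g. within sex).
#'
#' @param a,b subject x voxel matrices as in [welch_t_map()].
#' @param q FDR level.
#' @param n_perm requested number of permutations.
#' @param seed integer seed for the label shuffles.
#' @param strata optional factor of length `nrow(a) + nrow(b)` (group A rows
#'   first); permutations are performed within levels.
#' @return a `tbm_result`: list with `t` (signed observed t), `p` (pooled-null
#'   p-values), `q_value` (BH-adjusted), `mask` (q_value <= q), `pool_size`,
#'   `exhaustive`.
#' @export
permutation_fdr <- function(a, b, q = 0.05, n_perm = 100, seed = 1L,
                            strata = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(n_perm >= 1, q > 0, q < 1)
  na <- nrow(a); nb <- nrow(b); n <- na + nb
  all_data <- rbind(a, b)
  obs <- welch_t_map(a, b)

  exhaustive <- FALSE
  if (is.null(strata) && choose(n, na) <= n_perm) {
    splits <- group_splits(n, na)
    exhaustive <- TRUE
    warning("fewer distinct permutations than requested; ",
            "enumerating all ", ncol(splits), " relabellings")
    perm_idx <- lapply(seq_len(ncol(splits)), function(j) splits[, j])
  } else {
    set.seed(as.integer(seed))
    perm_idx <- lapply(seq_len(n_perm), function(i) {
      if (is.null(strata)) {
        sample.int(n, na)
      } else {
        ## shuffle the group labels within each stratum
        lab <- rep(c(TRUE, FALSE), c(na, nb))
        for (lv in unique(strata)) {
          w <- which(strata == lv)
          lab[w] <- sample(lab[w])
        }
        which(lab)
      }
    })
  }

  null_abs <- unlist(lapply(perm_idx, function(ia) {
    abs(welch_t_map(all_data[ia, , drop = FALSE],
                    all_data[-ia, , drop = FALSE])$t)
  }), use.names = FALSE)
  pool <- length(null_abs)
  srt <- sort(null_abs)
  ## #(null >= |t|) = pool - #(null < |t|)
  n_ge <- pool - findInterval(abs(obs$t), srt, left.open = TRUE)
  p <- (1 + n_ge) / (1 + pool)
  qv <- stats::p.adjust(p, method = "BH")
  structure(list(t = obs$t, p = p, q_value = qv, mask = qv <= q,
                 pool_size = pool, exhaustive = exhaustive,
                 degenerate = obs$degenerate),
            class = "tbm_result")
}

#' Genotype-contrast TBM on Jacobian maps
#'
#' Convenience wrapper: takes lists of Jacobian arrays per group and a brain
#' mask, flattens to subject x voxel matrices, runs [permutation_fdr()], and
#' returns maps reshaped into the mask geometry.
#'
#' @param jac_a,jac_b lists of Jacobian arrays (same shape).
#' @param mask logical array selecting the voxels to test.
#' @param smooth_sigma optional Gaussian smoothing (voxels) applied to each
#'   Jacobian map before testing; 0 disables.
#' @param log_jacobian analyse log(J) instead of J.
#' @param ... passed to [permutation_fdr()].
#' @return a `tbm_result` with additional arrays `t_map`, `q_map`,
#'   `mask_map` in the input geometry.
#' @export
tbm_contrast <- function(jac_a, jac_b, mask, smooth_sigma = 0,
                         log_jacobian = FALSE, ...) {
  prep <- function(j) {
    if (smooth_sigma > 0) j <- gaussian_smooth(j, smooth_sigma)
    if (log_jacobian) j <- log(pmax(j, .Machine$double.eps))
    j[mask]
  }
  a <- do.call(rbind, lapply(jac_a, prep))
  b <- do.call(rbind, lapply(jac_b, prep))
  res <- permutation_fdr(a, b, ...)
  shape_map <- function(v, fill = NA_real_) {
    m <- array(fill, dim(mask)); m[mask] <- v; m
  }
  res$t_map <- shape_map(res$t)
  res$q_map <- shape_map(res$q_value)
  res$mask_map <- shape_map(as.numeric(res$mask), fill = 0) > 0
  res
}

#' Dice overlap of two masks
#'
#' @param a,b logical arrays.
#' @return `2|A and B| / (|A| + |B|)`; NaN if both empty.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
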