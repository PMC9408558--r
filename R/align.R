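## Sequence-independent, TM-score-maximising structural alignment.
## Strategy (classic iterative scheme): several initial residue pairings
## (gapless threading at multiple offsets plus fragment superpositions),
## each refined by alternating Kabsch superposition and dynamic-programming
## re-alignment under the distance score 1/(1+(d_ij/d0)^2) with a gap-open
## penalty, until the paired set is stable. The best result by TM-score
## (normalised by reference length) is reported.

#' Alignment parameters
#'
#' @param gap_open_penalty DP gap-open penalty in score units (default -0.6;
#'   there is no gap-extension penalty).
#' @param d0_floor lower clamp of the TM-score scale d0 (default 0.5 A).
#' @param max_iterations superpose/re-align cycles per seed (default 30).
#' @param convergence_tol minimum TM-score improvement per refinement
#'   cycle; below it (or with an unchanged paired set) the seed has
#'   converged.
#' @param early_exit_tm stop scanning seeds once a seed reaches this
#'   TM-score (default 0.995); seeds are scanned in a fixed order so the
#'   result is deterministic.
#' @export
alignment_params <- function(gap_open_penalty = -0.6, d0_floor = 0.5,
                             max_iterations = 30L, convergence_tol = 1e-6,
                             early_exit_tm = 0.995) {
  stopifnot(max_iterations >= 1L, d0_floor > 0)
  list(gap_open_penalty = gap_open_penalty, d0_floor = d0_floor,
       max_iterations = as.integer(max_iterations),
       convergence_tol = convergence_tol, early_exit_tm = early_exit_tm)
}

#' Sequence-independent structural alignment of two C-alpha sets
#'
#' @param query,reference `abc_coordset`s (labels required for label-level
#'   output) or N x 3 matrices.
#' @param params see [alignment_params()].
#' @return `abc_superposition` with `rotation`, `translation` (mapping query
#'   onto reference), `paired` (index pairs), `paired_labels` (when labels
#'   are available), `rmsd` over the paired set, `tm_score` (normalised by
#'   reference length), `tm_score_query` (query-length normalisation) and
#'   `normalization_length`.
#' @export
structural_align <- function(query, reference, params = alignment_params()) {
  P <- .as_xyz(query); Q <- .as_xyz(reference)
  n <- nrow(P); m <- nrow(Q)
  if (n == 0L || m == 0L) stop("empty input coordinate set")
  if (min(n, m) < 20L)
    warning("fewer than 20 residues: alignment may not be meaningful")
  d0 <- tm_d0(m, params$d0_floor)
  seeds <- .alignment_seeds(P, Q, d0, params)
  best <- NULL
  for (seed in seeds) {
    res <- .refine_alignment(P, Q, seed, d0, params)
    if (is.null(best) || res$tm > best$tm ||
        (res$tm == best$tm && res$n_gaps < best$n_gaps)) best <- res
    if (best$tm >= params$early_exit_tm) break
  }
  pairs <- best$pairs
  fit <- .trimmed_kabsch(P, Q, pairs, d0)
  PT <- P %*% t(fit$rotation) + matrix(fit$translation, n, 3, byrow = TRUE)
  d <- sqrt(rowSums((PT[pairs[, 1], , drop = FALSE] -
                       Q[pairs[, 2], , drop = FALSE])^2))
  out <- fit
  out$paired <- pairs
  out$rmsd <- sqrt(mean(d^2))
  out$tm_score <- tm_score(d, m, params$d0_floor)
  out$tm_score_query <- tm_score(d, n, params$d0_floor)
  out$normalization_length <- m
  if (inherits(query, "abc_coordset") && inherits(reference, "abc_coordset"))
    out$paired_labels <- data.frame(
      query$labels[pairs[, 1], c("chain", "resno", "ins")],
      reference$labels[pairs[, 2], c("chain", "resno", "ins")] |>
        setNames(c("ref_chain", "ref_resno", "ref_ins")),
      row.names = NULL)
  out
}

## initial pairings: gapless threading offsets + fragment superposition DPs
.alignment_seeds <- function(P, Q, d0, params) {
  n <- nrow(P); m <- nrow(Q)
  lmin <- min(n, m)
  seeds <- list()
  ## gapless threading: pair i <-> i + o
  step <- max(1L, as.integer(round(lmin / 6)))
  offsets <- unique(c(0L, seq(-(n - max(3L, as.integer(lmin * 0.5))),
                              m - max(3L, as.integer(lmin * 0.5)),
                              by = step)))
  for (o in offsets) {
    i <- max(1L, 1L - o):min(n, m - o)
    if (length(i) < 3L) next
    seeds[[length(seeds) + 1L]] <- cbind(i, i + o)
  }
  ## fragment seeds: superpose short fragments, then DP once to get a seed
  f <- min(20L, max(3L, lmin %/% 2L))
  qstarts <- unique(pmax(1L, c(1L, (n - f) %/% 2L + 1L, n - f + 1L)))
  rstarts <- unique(pmax(1L, c(1L, (m - f) %/% 2L + 1L, m - f + 1L)))
  for (qs in qstarts) for (rs in rstarts) {
    if (qs + f - 1L > n || rs + f - 1L > m) next
    frag <- cbind(qs:(qs + f - 1L), rs:(rs + f - 1L))
    fit <- suppressWarnings(kabsch(P[frag[, 1], , drop = FALSE],
                                   Q[frag[, 2], , drop = FALSE]))
    PT <- P %*% t(fit$rotation) +
      matrix(fit$translation, n, 3, byrow = TRUE)
    p <- .dp_align_cpp(PT, Q, d0, params$gap_open_penalty)
    if (nrow(p) >= 3L) seeds[[length(seeds) + 1L]] <- p
  }
  seeds
}

.refine_alignment <- function(P, Q, pairs, d0, params) {
  m <- nrow(Q)
  best_tm <- -Inf; best_pairs <- pairs
  prev_tm <- -Inf
  for (it in seq_len(params$max_iterations)) {
    fit <- .trimmed_kabsch(P, Q, pairs, d0)
    PT <- P %*% t(fit$rotation) +
      matrix(fit$translation, nrow(P), 3, byrow = TRUE)
    new_pairs <- .dp_align_cpp(PT, Q, d0, params$gap_open_penalty)
    if (nrow(new_pairs) < 3L) break
    d <- sqrt(rowSums((PT[new_pairs[, 1], , drop = FALSE] -
                         Q[new_pairs[, 2], , drop = FALSE])^2))
    tm <- sum(1 / (1 + (d / d0)^2)) / m
    if (tm > best_tm) { best_tm <- tm; best_pairs <- new_pairs }
    if (nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)) break
    if (tm <= prev_tm + params$convergence_tol) break
    prev_tm <- tm
    pairs <- new_pairs
  }
  if (!is.finite(best_tm)) {
    ## seed never produced a usable DP pairing; score the seed itself
    fit <- suppressWarnings(
      kabsch(P[pairs[, 1], , drop = FALSE], Q[pairs[, 2], , drop = FALSE]))
    PT <- P %*% t(fit$rotation) +
      matrix(fit$translation, nrow(P), 3, byrow = TRUE)
    d <- sqrt(rowSums((PT[pairs[, 1], , drop = FALSE] -
                         Q[pairs[, 2], , drop = FALSE])^2))
    best_tm <- sum(1 / (1 + (d / d0)^2)) / m
    best_pairs <- pairs
  }
  list(tm = best_tm, pairs = best_pairs,
       n_gaps = (nrow(P) - nrow(best_pairs)) + (m - nrow(best_pairs)))
}

## superpose on the pairing, then re-fit on the well-matching core so a
## rigidly displaced domain cannot skew the transform away from the
## TM-optimal superposition. The trim threshold tightens from the 75th
## distance percentile down to ~1.5 d0, so even a large displaced block
## (e.g. a dissociated NBD) is shed progressively.
.trimmed_kabsch <- function(P, Q, pairs, d0) {
  keep <- pairs
  fit <- suppressWarnings(kabsch(P[keep[, 1], , drop = FALSE],
                                 Q[keep[, 2], , drop = FALSE]))
  floor_cut <- max(d0 * 1.5, 4.5)
  min_keep <- max(10L, as.integer(0.2 * nrow(pairs)))
  for (cycle in 1:6) {
    PT <- P[keep[, 1], , drop = FALSE] %*% t(fit$rotation) +
      matrix(fit$translation, nrow(keep), 3, byrow = TRUE)
    d <- sqrt(rowSums((PT - Q[keep[, 2], , drop = FALSE])^2))
    thr <- max(floor_cut, stats::quantile(d, 0.75, names = FALSE))
    inl <- d < thr
    if (all(inl) || sum(inl) < min_keep) break
    keep <- keep[inl, , drop = FALSE]
    fit <- suppressWarnings(kabsch(P[keep[, 1], , drop = FALSE],
                                   Q[keep[, 2], , drop = FALSE]))
  }
  fit
}
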