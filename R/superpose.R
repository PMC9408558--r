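## Rigid-body least-squares superposition and TM-score. These are the
## numerical core of family assignment and anchor transfer; everything is
## authored here (SVD via base R) so the aligner above it is self-contained.

.as_xyz <- function(x) {
  if (inherits(x, "abc_coordset")) return(x$xyz)
  m <- as.matrix(x)
  stopifnot(ncol(m) == 3L)
  m
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `R P + t` against `Q` over pre-paired points, via SVD of the
#' cross-covariance matrix with reflection correction.
#'
#' @param P,Q N x 3 matrices or `abc_coordset`s, paired by index, N >= 3.
#' @return list of class `abc_superposition`: `rotation`, `translation`,
#'   `rmsd`, `n`, `degenerate` (TRUE for near-collinear inputs),
#'   `tm_score` (NA; see [structural_align()]).
#' @export
kabsch <- function(P, Q) {
  P <- .as_xyz(P); Q <- .as_xyz(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must contain equally many points")
  if (nrow(P) < 3L) stop("at least 3 paired points are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - rot %*% cp)
  PT <- P %*% t(rot) + matrix(tr, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((PT - Q)^2)))
  ## collinear point sets leave the rotation about the axis undetermined
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  if (degenerate)
    warning("degenerate (near-collinear) point set: rotation not unique")
  out <- list(rotation = rot, translation = tr, rmsd = rmsd,
              n = nrow(P), degenerate = degenerate, tm_score = NA_real_,
              paired = cbind(query = seq_len(nrow(P)),
                             reference = seq_len(nrow(Q))))
  class(out) <- "abc_superposition"
  out
}

#' @export
print.abc_superposition <- function(x, ...) {
  cat("abc_superposition: ", x$n, " pairs, rmsd ",
      formatC(x$rmsd, digits = 3, format = "f"), " A",
      if (!is.na(x$tm_score))
        paste0(", TM-score ", formatC(x$tm_score, digits = 3, format = "f")),
      "\n", sep = "")
  invisible(x)
}

#' Length-dependent TM-score distance scale d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at `d0_floor` (short
#' chains would otherwise give a non-positive scale).
#'
#' @param l_target normalisation length.
#' @param d0_floor lower clamp in Angstrom (default 0.5).
#' @export
tm_d0 <- function(l_target, d0_floor = 0.5) {
  d0 <- if (l_target > 15) 1.24 * (l_target - 15)^(1 / 3) - 1.8 else d0_floor
  max(d0, d0_floor)
}

#' TM-score of a set of paired residue distances
#'
#' `TM = (1 / L_target) * sum_i 1 / (1 + (d_i / d0)^2)` with the standard
#' length-dependent scale `d0` of [tm_d0()]. Unpaired target residues
#' contribute zero, so the score is in (0, 1] and normalised by the chosen
#' target length.
#'
#' @param paired_distances distances of aligned residue pairs (Angstrom).
#' @param l_target normalisation length (>= 1; at least the pair count).
#' @param d0_floor lower clamp for d0.
#' @export
tm_score <- function(paired_distances, l_target, d0_floor = 0.5) {
  stopifnot(l_target >= 1, all(paired_distances >= 0))
  d0 <- tm_d0(l_target, d0_floor)
  sum(1 / (1 + (paired_distances / d0)^2)) / l_target
}

#' RMSD over a residue pairing, with optional outlier rejection
#'
#' Superposes query onto reference over the given pairing. With
#' `outlier_rejection`, pairs further than twice the current RMSD are
#' dropped and the remainder re-superposed, for at most five cycles or
#' until no pair is dropped.
#'
#' @param query,reference `abc_coordset`s (or N x 3 matrices).
#' @param pairing two-column integer matrix (query index, reference index);
#'   `NULL` pairs residues sharing a (chain, resno, ins) label.
#' @param outlier_rejection logical, default FALSE.
#' @return list: `rmsd`, `n_retained`, `n_total`, `rotation`, `translation`,
#'   `pairing` (retained pairs).
#' @export
matched_rmsd <- function(query, reference, pairing = NULL,
                         outlier_rejection = FALSE) {
  if (is.null(pairing)) pairing <- .shared_label_pairing(query, reference)
  pairing <- as.matrix(pairing)
  if (nrow(pairing) == 0L) stop("empty pairing")
  P <- .as_xyz(query); Q <- .as_xyz(reference)
  keep <- pairing
  fit <- kabsch(P[keep[, 1], , drop = FALSE], Q[keep[, 2], , drop = FALSE])
  if (outlier_rejection) {
    for (cycle in seq_len(5L)) {
      PT <- P[keep[, 1], , drop = FALSE] %*% t(fit$rotation) +
        matrix(fit$translation, nrow(keep), 3, byrow = TRUE)
      d <- sqrt(rowSums((PT - Q[keep[, 2], , drop = FALSE])^2))
      inl <- d <= 2 * fit$rmsd
      if (all(inl)) break
      if (sum(inl) < 3L)
        stop("outlier rejection removed (nearly) all pairs")
      keep <- keep[inl, , drop = FALSE]
      fit <- kabsch(P[keep[, 1], , drop = FALSE],
                    Q[keep[, 2], , drop = FALSE])
    }
  }
  list(rmsd = fit$rmsd, n_retained = nrow(keep), n_total = nrow(pairing),
       rotation = fit$rotation, translation = fit$translation,
       pairing = keep)
}

.label_key <- function(cs) {
  paste(cs$labels$chain, cs$labels$resno,
        ifelse(is.na(cs$labels$ins), "", cs$labels$ins))
}

.shared_label_pairing <- function(query, reference) {
  stopifnot(inherits(query, "abc_coordset"),
            inherits(reference, "abc_coordset"))
  i <- match(.label_key(reference), .label_key(query))
  cbind(query = i[!is.na(i)], reference = which(!is.na(i)))
}

## squared-distance matrix between two point sets (rows of A x rows of B)
.cdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
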