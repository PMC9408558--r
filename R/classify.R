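## Family assignment by TM-score against a reference library, anchor
## transfer by NBD structural alignment, and conformational-state calls by
## both the conftor distance rule and reference RMSD.

#' Build the synthetic reference structure library
#'
#' One entry per structural class, each holding an inward-facing
#' (bottom-open) and an outward-facing (bottom-closed) reference assembly
#' plus the annotated reference NBD used for anchor transfer. References are
#' generated deterministically in code (noise-free mock assemblies); the
#' library layout mirrors what a curated library of experimental references
#' would contain.
#'
#' @param classes class names (default all of [mock_class_names()]).
#' @return `abc_reference_library`: named list of entries with fields
#'   `structure` (canonical representative, the inward reference),
#'   `inward_ref`, `outward_ref` (each `abc_structure` with a cached `ca`
#'   coordset), and shared `nbd_reference` (`ca` + `anchors`).
#' @export
make_reference_library <- function(classes = mock_class_names()) {
  nbd <- mock_nbd_fold()
  entries <- lapply(classes, function(cl) {
    inw <- make_mock_transporter(mock_spec(cl, "open",
                                           planted_distances = c(40, 40)))
    out <- make_mock_transporter(mock_spec(cl, "closed",
                                           planted_distances = c(10, 10)))
    ## canonical representative: a widely open conformer, reflecting that
    ## inward-facing structures span a large range of opening levels
    rep_ <- make_mock_transporter(mock_spec(cl, "open",
                                            planted_distances = c(60, 60)))
    list(class_name = cl,
         structure = rep_$structure,
         inward_ref = inw$structure, outward_ref = out$structure,
         representative_ca = extract_ca(rep_$structure),
         inward_ca = extract_ca(inw$structure),
         outward_ca = extract_ca(out$structure),
         inward_truth = inw$truth, outward_truth = out$truth)
  })
  names(entries) <- classes
  lib <- list(entries = entries, nbd_reference = nbd)
  class(lib) <- "abc_reference_library"
  lib
}

#' @export
print.abc_reference_library <- function(x, ...) {
  cat("abc_reference_library:", length(x$entries), "classes (",
      paste(names(x$entries), collapse = ", "), ")\n")
  invisible(x)
}

#' Assign a structure to a structural family by TM-score
#'
#' The query is aligned against every reference of every class (the
#' canonical representative plus the inward and outward conformer
#' references); a class's score is the largest of these TM-scores
#' (reference-length normalised). The best-scoring class wins if its TM-score exceeds
#' `tm_threshold`, else the structure is `"unclassified"`. A Pfam-derived
#' class hint that disagrees with the structural assignment raises a flag
#' rather than overriding it.
#'
#' @param query `abc_structure` or `abc_coordset`.
#' @param library an `abc_reference_library`.
#' @param mode `"whole"` (default) aligns the full assembly; `"tmd_only"`
#'   aligns only the TM-domain residues given in `tmd_ranges`.
#' @param tm_threshold classification threshold (default 0.6).
#' @param hint optional Pfam class hint.
#' @param tmd_ranges data.frame (`chain`, `start`, `end`) for
#'   `mode = "tmd_only"`.
#' @param params alignment parameters.
#' @return list of class `abc_family_assignment`: `class_name`, `best_tm`,
#'   `runner_up_tm`, `mode`, `flags`, `by_class` (per-class per-conformer
#'   alignments, reusable for RMSD conformation calls).
#' @export
assign_family <- function(query, library, mode = c("whole", "tmd_only"),
                          tm_threshold = 0.6, hint = NULL,
                          tmd_ranges = NULL, params = alignment_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "abc_reference_library"))
  if (!length(library$entries)) stop("empty reference library")
  qca <- if (inherits(query, "abc_coordset")) query
  else if (mode == "tmd_only") {
    if (is.null(tmd_ranges)) stop("tmd_only mode requires tmd_ranges")
    .extract_ranges_ca(query, tmd_ranges)
  } else extract_ca(query)
  by_class <- lapply(library$entries, function(e) {
    ai <- structural_align(qca, e$inward_ca, params)
    ao <- structural_align(qca, e$outward_ca, params)
    ar <- structural_align(qca, e$representative_ca, params)
    list(inward = ai, outward = ao, representative = ar,
         tm = max(ai$tm_score, ao$tm_score, ar$tm_score))
  })
  tms <- vapply(by_class, `[[`, 0, "tm")
  o <- order(-tms)
  best <- tms[o[1]]
  runner <- if (length(tms) > 1L) tms[o[2]] else NA_real_
  class_name <- if (best > tm_threshold) names(tms)[o[1]] else "unclassified"
  flags <- character(0)
  if (!is.null(hint) && nzchar(hint) && class_name != "unclassified" &&
      hint != class_name)
    flags <- c(flags, "hint_disagreement")
  if (class_name == "unclassified" && !is.null(hint) && nzchar(hint))
    flags <- c(flags, "hint_without_structural_support")
  out <- list(class_name = class_name, best_tm = unname(best),
              runner_up_tm = unname(runner), mode = mode, flags = flags,
              by_class = by_class)
  class(out) <- "abc_family_assignment"
  out
}

#' @export
print.abc_family_assignment <- function(x, ...) {
  cat("family: ", x$class_name, " (TM ",
      formatC(x$best_tm, digits = 3, format = "f"), ", runner-up ",
      formatC(x$runner_up_tm, digits = 3, format = "f"), ", mode ",
      x$mode, ")\n", sep = "")
  invisible(x)
}

.extract_ranges_ca <- function(structure, ranges) {
  parts <- lapply(seq_len(nrow(ranges)), function(i)
    extract_ca(structure, chains = ranges$chain[i],
               resno_range = c(ranges$start[i], ranges$end[i])))
  labels <- do.call(rbind, lapply(parts, function(p) p$labels))
  xyz <- do.call(rbind, lapply(parts, function(p) p$xyz))
  coordset(labels, xyz, sum(vapply(parts, `[[`, 0L, "n_skipped")))
}

#' Locate conftor anchors on a query NBD by structural alignment
#'
#' Aligns the query NBD C-alpha set to the annotated reference NBD and
#' transfers the two anchor positions (Walker-A lysine, signature glycine)
#' through the alignment. If a reference anchor falls in an alignment gap,
#' the nearest paired reference position within two residues is used and
#' flagged; with no paired neighbour the anchor is reported as not found.
#' Alignments with TM-score below 0.45 carry a low-quality flag.
#'
#' @param nbd_ca `abc_coordset` of the query NBD (>= 80 residues advised).
#' @param nbd_reference reference NBD (list with `ca` and `anchors`),
#'   default the shipped synthetic reference.
#' @param params alignment parameters.
#' @return list of class `abc_anchors`: `anchors` (data.frame `role`,
#'   `chain`, `resno`, `ins`, `found`, `approximate`), `tm`, `flags`.
#' @export
locate_anchors <- function(nbd_ca, nbd_reference = mock_nbd_fold(),
                           params = alignment_params()) {
  stopifnot(inherits(nbd_ca, "abc_coordset"))
  if (nrow(nbd_ca$xyz) < 80L)
    warning("NBD extract has fewer than 80 residues")
  aln <- structural_align(nbd_ca, nbd_reference$ca, params)
  ref_resno <- nbd_reference$ca$labels$resno
  rows <- lapply(names(nbd_reference$anchors), function(role) {
    target <- nbd_reference$anchors[[role]]
    ref_pos <- match(target, ref_resno)
    hit <- which(aln$paired[, 2] == ref_pos)
    approximate <- FALSE
    if (!length(hit)) {
      near <- which(abs(ref_resno[aln$paired[, 2]] - target) <= 2L)
      if (length(near)) {
        hit <- near[which.min(abs(ref_resno[aln$paired[near, 2]] - target))]
        approximate <- TRUE
      }
    }
    if (!length(hit))
      return(data.frame(role = role, chain = NA_character_,
                        resno = NA_integer_, ins = NA_character_,
                        found = FALSE, approximate = FALSE,
                        stringsAsFactors = FALSE))
    qi <- aln$paired[hit[1], 1]
    data.frame(role = role, chain = nbd_ca$labels$chain[qi],
               resno = nbd_ca$labels$resno[qi],
               ins = nbd_ca$labels$ins[qi],
               found = TRUE, approximate = approximate,
               stringsAsFactors = FALSE)
  })
  anchors <- do.call(rbind, rows)
  flags <- character(0)
  if (any(anchors$approximate)) flags <- c(flags, "anchor_approximate")
  if (!all(anchors$found)) flags <- c(flags, "anchor_not_found")
  if (aln$tm_score < 0.45) flags <- c(flags, "low_anchor_alignment_quality")
  out <- list(anchors = anchors, tm = aln$tm_score, flags = flags)
  class(out) <- "abc_anchors"
  out
}

#' Measure the cross-NBD conftor distances of one assembly
#'
#' Computes the two Euclidean C-alpha distances: Walker-A anchor of NBD A
#' to signature anchor of NBD B (`distance_ab`) and Walker-A of B to
#' signature of A (`distance_ba`).
#'
#' @param structure an `abc_structure`.
#' @param anchors_a,anchors_b `abc_anchors` results (or their `anchors`
#'   data.frames) for the two NBDs.
#' @return list of class `abc_conftor`: `distance_ab`, `distance_ba`,
#'   `anchors` (4-row data.frame), `alignment_quality` (the two anchor
#'   TM-scores, NA when unavailable), `complete`.
#' @export
compute_conftor <- function(structure, anchors_a, anchors_b) {
  qa <- if (inherits(anchors_a, "abc_anchors")) anchors_a$anchors else anchors_a
  qb <- if (inherits(anchors_b, "abc_anchors")) anchors_b$anchors else anchors_b
  tm_a <- if (inherits(anchors_a, "abc_anchors")) anchors_a$tm else NA_real_
  tm_b <- if (inherits(anchors_b, "abc_anchors")) anchors_b$tm else NA_real_
  pos <- function(df, role) {
    r <- df[df$role == role, ]
    if (nrow(r) != 1L || !isTRUE(r$found) || is.na(r$resno)) return(NULL)
    .anchor_ca(structure, r$chain, r$resno, r$ins)
  }
  wa_a <- pos(qa, "walker_a_k"); sig_a <- pos(qa, "signature_g")
  wa_b <- pos(qb, "walker_a_k"); sig_b <- pos(qb, "signature_g")
  complete <- !is.null(wa_a) && !is.null(sig_a) &&
    !is.null(wa_b) && !is.null(sig_b)
  anchors <- rbind(cbind(qa, nbd = "A"), cbind(qb, nbd = "B"))
  out <- list(
    distance_ab = if (complete) sqrt(sum((wa_a - sig_b)^2)) else NA_real_,
    distance_ba = if (complete) sqrt(sum((wa_b - sig_a)^2)) else NA_real_,
    anchors = anchors,
    alignment_quality = c(nbd_a = tm_a, nbd_b = tm_b),
    complete = complete)
  class(out) <- "abc_conftor"
  out
}

.anchor_ca <- function(structure, chain, resno, ins) {
  at <- structure$atom
  sel <- !at$het & at$chain == chain & at$resno == resno & at$atom == "CA" &
    (is.na(ins) | is.na(at$ins) | at$ins == ins)
  if (!any(sel)) return(NULL)
  as.numeric(at[which(sel)[1], c("x", "y", "z")])
}

#' @export
print.abc_conftor <- function(x, ...) {
  if (x$complete)
    cat("conftor(WA/SIG): ",
        formatC(x$distance_ab, digits = 2, format = "f"), " / ",
        formatC(x$distance_ba, digits = 2, format = "f"), " A\n", sep = "")
  else cat("conftor(WA/SIG): incomplete (missing anchor CA)\n")
  invisible(x)
}

#' Conformational state from conftor distances
#'
#' Bottom-closed requires BOTH composite ATP sites to be formed, i.e. both
#' cross-NBD distances strictly below the cutoff; anything else is
#' bottom-open. Distances within 2 A of the cutoff raise a boundary flag
#' (such structures were historically confirmed by visual inspection).
#'
#' @param m an `abc_conftor` measurement.
#' @param cutoff distance cutoff in Angstrom (default 14).
#' @return list: `conformation` ("open", "closed" or "unassigned"),
#'   `boundary` flag.
#' @export
classify_conformation_conftor <- function(m, cutoff = 14) {
  if (!isTRUE(m$complete))
    return(list(conformation = "unassigned", boundary = FALSE))
  d <- c(m$distance_ab, m$distance_ba)
  list(conformation = if (all(d < cutoff)) "closed" else "open",
       boundary = any(abs(d - cutoff) <= 2))
}

#' Conformational state by RMSD to the two conformer references
#'
#' Labels the query with the nearer of the family's inward (open) and
#' outward (closed) references. Both RMSDs are returned so that a conftor
#' label can override this one; an equidistant query (within 0.01 A) is
#' left unassigned with a tie flag.
#'
#' @param query `abc_structure` or `abc_coordset`.
#' @param inward_ref,outward_ref references (`abc_structure`/coordset).
#' @param params alignment parameters.
#' @param alignments optional precomputed list (`inward`, `outward`) of
#'   `abc_superposition`s to reuse.
#' @return list: `conformation`, `rmsd_inward`, `rmsd_outward`, `flags`.
#' @export
classify_conformation_rmsd <- function(query, inward_ref, outward_ref,
                                       params = alignment_params(),
                                       alignments = NULL) {
  if (is.null(inward_ref) || is.null(outward_ref))
    return(list(conformation = "unassigned", rmsd_inward = NA_real_,
                rmsd_outward = NA_real_, flags = "missing_reference"))
  if (is.null(alignments)) {
    qca <- if (inherits(query, "abc_coordset")) query else extract_ca(query)
    ica <- if (inherits(inward_ref, "abc_coordset")) inward_ref
    else extract_ca(inward_ref)
    oca <- if (inherits(outward_ref, "abc_coordset")) outward_ref
    else extract_ca(outward_ref)
    alignments <- list(inward = structural_align(qca, ica, params),
                       outward = structural_align(qca, oca, params))
  }
  ri <- alignments$inward$rmsd; ro <- alignments$outward$rmsd
  if (abs(ri - ro) <= 0.01)
    return(list(conformation = "unassigned", rmsd_inward = ri,
                rmsd_outward = ro, flags = "rmsd_tie"))
  list(conformation = if (ri < ro) "open" else "closed",
       rmsd_inward = ri, rmsd_outward = ro, flags = character(0))
}

#' Pair the NBDs of an assembly
#'
#' Exactly two NBD ranges form the single pair. More than two are matched
#' greedily into disjoint pairs by minimal centroid distance (each such
#' pair is flagged `multi_unit`); an odd leftover is reported unpaired.
#'
#' @param structure an `abc_structure`.
#' @param nbd_ranges data.frame with columns `chain`, `start`, `end`.
#' @return list: `pairs` (list of index pairs into `nbd_ranges`),
#'   `leftover` (indices), `flags`.
#' @export
pair_nbds <- function(structure, nbd_ranges) {
  n <- nrow(nbd_ranges)
  if (n < 2L) stop("at least two NBD ranges are required")
  if (n == 2L)
    return(list(pairs = list(c(1L, 2L)), leftover = integer(0),
                flags = character(0)))
  cents <- t(vapply(seq_len(n), function(i) {
    ca <- extract_ca(structure, chains = nbd_ranges$chain[i],
                     resno_range = c(nbd_ranges$start[i], nbd_ranges$end[i]))
    colMeans(ca$xyz)
  }, numeric(3)))
  D <- .cdist(cents, cents)
  diag(D) <- Inf
  avail <- rep(TRUE, n)
  pairs <- list()
  while (sum(avail) >= 2L) {
    Dm <- D
    Dm[!avail, ] <- Inf; Dm[, !avail] <- Inf
    ij <- arrayInd(which.min(Dm), dim(Dm))
    pairs[[length(pairs) + 1L]] <- sort(c(ij[1], ij[2]))
    avail[ij] <- FALSE
  }
  list(pairs = pairs, leftover = which(avail),
       flags = c("multi_unit", if (any(avail)) "unpaired_nbd"))
}
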