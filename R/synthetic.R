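## Synthetic fixtures with planted ground truth. Mock transporters are
## CA-trace assemblies: two ideal-helix TM bundles (geometry per structural
## class) above two copies of a synthetic reference NBD fold whose Walker-A
## and signature anchor residues are placed at exactly the planted
## cross-NBD distances (solved in closed form, so planted geometry is exact
## to machine precision before noise). All generators are pure functions of
## their arguments and seed.

.rotation_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

.rotation_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

## rotation taking unit z to unit vector `axis` (Rodrigues)
.rotation_z_to <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  cth <- sum(z * axis)
  if (abs(cth + 1) < 1e-12) return(diag(c(1, -1, -1)))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Ideal alpha-helix C-alpha trace
#'
#' 1.5 A rise and 100 degree turn per residue on a 2.3 A radius, giving the
#' canonical ~3.8 A consecutive CA-CA spacing.
#'
#' @param n_residues number of residues (>= 4).
#' @param origin position of the helix base (axis point at residue 1's z).
#' @param axis helix axis direction (any non-zero 3-vector).
#' @param phase initial phase angle in radians.
#' @return `abc_coordset` with chain "H", resno 1..n.
#' @export
make_ideal_helix <- function(n_residues, origin = c(0, 0, 0),
                             axis = c(0, 0, 1), phase = 0) {
  stopifnot(n_residues >= 4L)
  k <- seq_len(n_residues) - 1L
  ang <- phase + k * (100 * pi / 180)
  local <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * k)
  R <- .rotation_z_to(axis)
  xyz <- local %*% t(R) + matrix(origin, n_residues, 3, byrow = TRUE)
  coordset(labels = data.frame(chain = "H", resno = seq_len(n_residues),
                               ins = NA_character_,
                               stringsAsFactors = FALSE),
           xyz = xyz)
}

## snake a set of helices (origin/axis/length rows) into one chain trace,
## inserting 3 interpolated connector points between consecutive helices
.helix_bundle <- function(spec_df, phase_step = 0.7) {
  pieces <- list()
  prev_end <- NULL
  for (i in seq_len(nrow(spec_df))) {
    h <- make_ideal_helix(spec_df$len[i],
                          origin = c(spec_df$x[i], spec_df$y[i], spec_df$z[i]),
                          axis = c(0, 0, spec_df$dir[i]),
                          phase = (i - 1) * phase_step)
    if (!is.null(prev_end)) {
      s <- h$xyz[1, ]
      conn <- t(sapply(1:3, function(k) prev_end + k / 4 * (s - prev_end)))
      pieces[[length(pieces) + 1L]] <- conn
    }
    pieces[[length(pieces) + 1L]] <- h$xyz
    prev_end <- h$xyz[nrow(h$xyz), ]
  }
  do.call(rbind, pieces)
}

#' Synthetic reference NBD fold with annotated conftor anchors
#'
#' A deterministic compact six-helix bundle (111 residues) standing in for
#' a real nucleotide-binding domain. Residue 54 carries the Walker-A lysine
#' anchor (motif position 7 of GXXXXGKT) and residue 73 the signature
#' glycine anchor (position 3 of LSGGQ); both sit at helix ends on the
#' dimerisation face, as in real NBDs.
#'
#' @return list: `ca` (`abc_coordset`, chain "N", resno 1..111), `anchors`
#'   (named list `walker_a_k`, `signature_g` of resno).
#' @export
mock_nbd_fold <- function() {
  grid <- data.frame(
    x = c(-9, 0, 9, 9, 0, -9),
    y = c(-4.5, -4.5, -4.5, 4.5, 4.5, 4.5),
    dir = c(1, -1, 1, -1, 1, -1),
    len = 16L)
  grid$z <- ifelse(grid$dir > 0, 0, 24)
  xyz <- .helix_bundle(grid)
  n <- nrow(xyz)  # 6*16 + 5*3 = 111
  list(ca = coordset(labels = data.frame(chain = "N", resno = seq_len(n),
                                         ins = NA_character_,
                                         stringsAsFactors = FALSE),
                     xyz = xyz),
       anchors = list(walker_a_k = 54L, signature_g = 73L))
}

## TM-bundle geometry per structural class (one half of the TMD)
.class_geometries <- list(
  "Pgp-like" = list(n_helix = 6L, len = 30L, layout = "ring", r = 11.5),
  "ABCG2-like" = list(n_helix = 6L, len = 18L, layout = "grid", r = 7.5),
  "MacB-like" = list(n_helix = 4L, len = 36L, layout = "ring", r = 6.5))

#' Names of the synthetic structural classes
#' @export
mock_class_names <- function() names(.class_geometries)

#' Synthetic TM-domain half-bundle for a structural class
#'
#' @param class_name one of [mock_class_names()].
#' @return N x 3 matrix of CA positions (local frame, z in [8, ...]).
#' @export
mock_tmd_fold <- function(class_name) {
  g <- .class_geometries[[class_name]]
  if (is.null(g)) stop("unknown structural class '", class_name, "'")
  k <- seq_len(g$n_helix) - 1L
  if (g$layout == "ring") {
    x <- g$r * cos(2 * pi * k / g$n_helix)
    y <- g$r * sin(2 * pi * k / g$n_helix)
  } else {
    x <- g$r * (k %% 3L - 1L)
    y <- g$r * 0.8 * (k %/% 3L - 0.5)
  }
  sp <- data.frame(x = x, y = y, dir = rep(c(1, -1), length.out = g$n_helix),
                   len = g$len)
  sp$z <- ifelse(sp$dir > 0, 8, 8 + 1.5 * (g$len - 1L))
  .helix_bundle(sp)
}

## deterministic point on the intersection of two spheres, preferring the
## plane z = z0; exact on both radii (closed form, no iteration)
.sphere_sphere_point <- function(p1, r1, p2, r2, z0) {
  dvec <- p2 - p1
  dd <- sqrt(sum(dvec^2))
  if (dd < 1e-9 || dd >= r1 + r2 || dd <= abs(r1 - r2))
    return(NULL)
  a <- (r1^2 - r2^2 + dd^2) / (2 * dd)
  h2 <- r1^2 - a^2
  if (h2 <= 0) return(NULL)
  nn <- dvec / dd
  cc <- p1 + a * nn
  rc <- sqrt(h2)
  ref <- if (abs(nn[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- c(nn[2] * ref[3] - nn[3] * ref[2],
          nn[3] * ref[1] - nn[1] * ref[3],
          nn[1] * ref[2] - nn[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nn[2] * e1[3] - nn[3] * e1[2],
          nn[3] * e1[1] - nn[1] * e1[3],
          nn[1] * e1[2] - nn[2] * e1[1])
  a1 <- rc * e1[3]; a2 <- rc * e2[3]
  rho <- sqrt(a1^2 + a2^2)
  if (rho < 1e-12) {
    th <- 0
  } else {
    phi <- atan2(a2, a1)
    s <- max(-1, min(1, (z0 - cc[3]) / rho))
    cands <- phi + c(acos(s), -acos(s))
    pts <- lapply(cands, function(t) cc + rc * (cos(t) * e1 + sin(t) * e2))
    th <- cands[[which.max(vapply(pts, function(p) p[1], 0))]]
  }
  cc + rc * (cos(th) * e1 + sin(th) * e2)
}

## place NBD copy B (rotated Rz(pi) then tilted about y by beta) so that
## the two cross-NBD anchor distances equal (d_ab, d_ba) exactly
.place_second_nbd <- function(wa_a, sig_a, wa_local, sig_local, d_ab, d_ba,
                              z0) {
  betas <- c(0, as.vector(rbind(1, -1) %o% seq(2, 178, by = 2))) * pi / 180
  for (beta in betas) {
    RB <- .rotation_y(beta) %*% .rotation_z(pi)
    p1 <- wa_a - as.numeric(RB %*% sig_local)   # |cB - p1| = d_ab
    p2 <- sig_a - as.numeric(RB %*% wa_local)   # |cB - p2| = d_ba
    cB <- .sphere_sphere_point(p1, d_ab, p2, d_ba, z0)
    if (!is.null(cB)) return(list(rotation = RB, center = cB, beta = beta))
  }
  stop("validation error: planted distances (", d_ab, ", ", d_ba,
       ") are not realisable by the mock NBD geometry")
}

#' Specification of one mock transporter
#'
#' @param planted_class structural class name (see [mock_class_names()]).
#' @param planted_state `"open"`, `"closed"` or `"boundary"`.
#' @param planted_distances the two cross-NBD Walker-A to signature
#'   distances (A), `c(ab, ba)`; must be consistent with the state under
#'   the both-below-14-A rule (boundary: one below, one at/above).
#' @param n_chains 1 (full transporter) or 2 (half-transporter dimer).
#' @param noise_sigma Gaussian coordinate noise s.d. (A).
#' @param seed integer seed fixing all randomness.
#' @param cutoff classification cutoff used for validation (default 14).
#' @export
mock_spec <- function(planted_class = "Pgp-like",
                      planted_state = c("open", "closed", "boundary"),
                      planted_distances = NULL, n_chains = 2L,
                      noise_sigma = 0, seed = 1L, cutoff = 14) {
  planted_state <- match.arg(planted_state)
  if (is.null(planted_distances))
    planted_distances <- switch(planted_state,
                                closed = c(10, 10), open = c(40, 40),
                                boundary = c(13, 15))
  stopifnot(length(planted_distances) == 2L, all(planted_distances > 0),
            n_chains %in% c(1L, 2L), noise_sigma >= 0)
  if (!planted_class %in% mock_class_names())
    stop("unknown structural class '", planted_class, "'")
  ok <- switch(planted_state,
               closed = all(planted_distances < cutoff),
               open = any(planted_distances >= cutoff),
               boundary = sum(planted_distances < cutoff) == 1L)
  if (!ok)
    stop("validation error: planted_distances inconsistent with state '",
         planted_state, "' under the ", cutoff, " A both-below rule")
  list(planted_class = planted_class, planted_state = planted_state,
       planted_distances = planted_distances, n_chains = as.integer(n_chains),
       noise_sigma = noise_sigma, seed = as.integer(seed), cutoff = cutoff)
}

#' Build a mock transporter assembly with planted ground truth
#'
#' @param spec a [mock_spec()].
#' @return list: `structure` (`abc_structure`), `truth` (class, state,
#'   distances, anchor labels, NBD/TMD residue ranges with label_seq spans).
#' @export
make_mock_transporter <- function(spec) {
  nbd <- mock_nbd_fold()
  nbd_xyz <- nbd$ca$xyz
  wa_i <- nbd$anchors$walker_a_k; sig_i <- nbd$anchors$signature_g
  ctr <- colMeans(nbd_xyz)
  nbd_local <- sweep(nbd_xyz, 2, ctr)
  wa_local <- nbd_local[wa_i, ]; sig_local <- nbd_local[sig_i, ]

  cA <- c(-14, 0, -28)
  nbd_a <- sweep(nbd_local, 2, cA, "+")
  wa_a <- nbd_a[wa_i, ]; sig_a <- nbd_a[sig_i, ]
  pose <- .place_second_nbd(wa_a, sig_a, wa_local, sig_local,
                            spec$planted_distances[1],
                            spec$planted_distances[2], z0 = cA[3])
  nbd_b <- nbd_local %*% t(pose$rotation) +
    matrix(pose$center, nrow(nbd_local), 3, byrow = TRUE)

  half <- mock_tmd_fold(spec$planted_class)
  half_ctr <- colMeans(half)
  h0 <- sweep(half, 2, c(half_ctr[1], half_ctr[2], 0))
  tmd1 <- sweep(h0, 2, c(-7, 0, 0), "+")
  tmd2 <- h0 %*% t(.rotation_z(pi)) +
    matrix(c(7, 0, 0), nrow(h0), 3, byrow = TRUE)

  t_len <- nrow(half); n_len <- nrow(nbd_local)
  seg <- function(chain, resno0, xyz, resname) {
    data.frame(chain = chain, resno = resno0 + seq_len(nrow(xyz)) - 1L,
               ins = NA_character_, resname = resname, atom = "CA",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE,
               stringsAsFactors = FALSE)
  }
  res_nbd <- rep("ALA", n_len)
  res_nbd[wa_i] <- "LYS"; res_nbd[sig_i] <- "GLY"
  if (spec$n_chains == 2L) {
    atoms <- rbind(seg("A", 1L, tmd1, "LEU"), seg("A", 201L, nbd_a, res_nbd),
                   seg("B", 1L, tmd2, "LEU"), seg("B", 201L, nbd_b, res_nbd))
    nbd_ranges <- data.frame(chain = c("A", "B"), start = 201L,
                             end = 200L + n_len,
                             label_from = t_len + 1L,
                             label_to = t_len + n_len,
                             stringsAsFactors = FALSE)
    tmd_ranges <- data.frame(chain = c("A", "B"), start = 1L, end = t_len,
                             label_from = 1L, label_to = t_len,
                             stringsAsFactors = FALSE)
    anchors <- data.frame(
      role = c("walker_a_k", "signature_g", "walker_a_k", "signature_g"),
      nbd = c("A", "A", "B", "B"),
      chain = c("A", "A", "B", "B"),
      resno = 200L + c(wa_i, sig_i, wa_i, sig_i),
      stringsAsFactors = FALSE)
  } else {
    atoms <- rbind(seg("A", 1L, tmd1, "LEU"), seg("A", 201L, nbd_a, res_nbd),
                   seg("A", 401L, tmd2, "LEU"), seg("A", 601L, nbd_b, res_nbd))
    nbd_ranges <- data.frame(chain = "A", start = c(201L, 601L),
                             end = c(200L, 600L) + n_len,
                             label_from = c(t_len + 1L, 2L * t_len + n_len + 1L),
                             label_to = c(t_len + n_len, 2L * (t_len + n_len)),
                             stringsAsFactors = FALSE)
    tmd_ranges <- data.frame(chain = "A", start = c(1L, 401L),
                             end = c(t_len, 400L + t_len),
                             label_from = c(1L, t_len + n_len + 1L),
                             label_to = c(t_len, 2L * t_len + n_len),
                             stringsAsFactors = FALSE)
    anchors <- data.frame(
      role = c("walker_a_k", "signature_g", "walker_a_k", "signature_g"),
      nbd = c("A1", "A1", "A2", "A2"),
      chain = "A",
      resno = c(200L + wa_i, 200L + sig_i, 600L + wa_i, 600L + sig_i),
      stringsAsFactors = FALSE)
  }
  if (spec$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    atoms$x <- atoms$x + rnorm(nrow(atoms), 0, spec$noise_sigma)
    atoms$y <- atoms$y + rnorm(nrow(atoms), 0, spec$noise_sigma)
    atoms$z <- atoms$z + rnorm(nrow(atoms), 0, spec$noise_sigma)
  }
  entry_id <- sprintf("mock_%s_s%d", gsub("[^A-Za-z0-9]", "",
                                          spec$planted_class), spec$seed)
  s <- abc_structure(atoms, entry_id = entry_id, source = "experimental")
  list(structure = s,
       truth = list(entry_id = entry_id, class = spec$planted_class,
                    state = spec$planted_state,
                    distances = c(ab = spec$planted_distances[1],
                                  ba = spec$planted_distances[2]),
                    anchors = anchors, nbd_ranges = nbd_ranges,
                    tmd_ranges = tmd_ranges, n_chains = spec$n_chains,
                    noise_sigma = spec$noise_sigma, seed = spec$seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Render a HMMER3 domtblout text from hit specifications
#'
#' Produces per-domain tabular text that [parse_domtblout()] inverts
#' exactly on all modeled fields.
#'
#' @param hits a data.frame in the layout returned by [parse_domtblout()]
#'   (see [mock_hit()] for building rows).
#' @return character vector of domtblout lines (with comment header).
#' @export
make_mock_domtblout <- function(hits) {
  num <- function(x) vapply(x, function(v) format(v, digits = 15), "")
  body <- sprintf(
    "%s %s %d %s %s %d %s %s %s %d %d %s %s %s %s %d %d %d %d %d %d %s %s",
    hits$target_name, hits$target_accession, hits$tlen,
    hits$profile_name, hits$profile_accession, hits$profile_length,
    num(hits$full_seq_evalue), num(hits$full_seq_score),
    num(hits$full_seq_bias),
    hits$dom_n, hits$dom_of,
    num(hits$domain_cevalue), num(hits$domain_ievalue),
    num(hits$domain_score), num(hits$domain_bias),
    hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
    hits$env_from, hits$env_to, num(hits$acc),
    ifelse(nzchar(hits$description), hits$description, "-"))
  c("#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
    body)
}

#' Build one domain-hit row with sensible defaults
#'
#' @param target_name sequence (chain) identifier, e.g. `"entry1_A"`.
#' @param profile_name,profile_accession Pfam profile identity.
#' @param profile_length HMM profile length.
#' @param ali_from,ali_to alignment span on the sequence (1-based).
#' @param hmm_from,hmm_to matched span on the profile; defaults to the full
#'   profile.
#' @param ievalue per-domain independent E-value.
#' @param tlen target sequence length.
#' @param dom_n,dom_of domain index bookkeeping.
#' @export
mock_hit <- function(target_name, profile_name, profile_accession,
                     profile_length, ali_from, ali_to,
                     hmm_from = 1L, hmm_to = profile_length,
                     ievalue = 1e-40, tlen = ali_to + 10L,
                     dom_n = 1L, dom_of = 1L) {
  data.frame(target_name = target_name, target_accession = "-",
             tlen = as.integer(tlen),
             profile_name = profile_name,
             profile_accession = profile_accession,
             profile_length = as.integer(profile_length),
             full_seq_evalue = ievalue, full_seq_score = 250.1,
             full_seq_bias = 0.1,
             dom_n = as.integer(dom_n), dom_of = as.integer(dom_of),
             domain_cevalue = ievalue, domain_ievalue = ievalue,
             domain_score = 200.2, domain_bias = 0.1,
             hmm_from = as.integer(hmm_from), hmm_to = as.integer(hmm_to),
             ali_from = as.integer(ali_from), ali_to = as.integer(ali_to),
             env_from = as.integer(max(1L, ali_from - 2L)),
             env_to = as.integer(ali_to + 2L),
             acc = 0.97, description = "synthetic",
             stringsAsFactors = FALSE)
}

## domain hits matching one mock transporter's ground truth, in sequence
## (label_seq) coordinates
.truth_hits <- function(truth, tmd_accession = NULL) {
  cls2acc <- c("Pgp-like" = "PF00664", "ABCG2-like" = "PF01061",
               "MacB-like" = "PF02687")
  cls2name <- c("Pgp-like" = "ABC_membrane", "ABCG2-like" = "ABC2_membrane",
                "MacB-like" = "FtsX")
  acc <- if (is.null(tmd_accession)) cls2acc[[truth$class]] else tmd_accession
  nm <- cls2name[[truth$class]]
  rows <- list()
  for (i in seq_len(nrow(truth$tmd_ranges))) {
    r <- truth$tmd_ranges[i, ]
    len <- r$label_to - r$label_from + 1L
    rows[[length(rows) + 1L]] <- mock_hit(
      paste0(truth$entry_id, "_", r$chain), nm, acc, profile_length = len,
      ali_from = r$label_from, ali_to = r$label_to, tlen = 400L)
  }
  for (i in seq_len(nrow(truth$nbd_ranges))) {
    r <- truth$nbd_ranges[i, ]
    len <- r$label_to - r$label_from + 1L
    rows[[length(rows) + 1L]] <- mock_hit(
      paste0(truth$entry_id, "_", r$chain), "ABC_tran", "PF00005",
      profile_length = len, ali_from = r$label_from, ali_to = r$label_to,
      tlen = 400L, dom_n = i, dom_of = nrow(truth$nbd_ranges))
  }
  do.call(rbind, rows)
}

#' Generate a seeded cohort of mock transporters
#'
#' States are assigned in the exact requested proportions (rounded); planted
#' distances are drawn per state, clear of the 14 +/- 2 A boundary band —
#' closed within 8-11.5 A, open with one distance in 20-80 A and the other
#' within 25 A of it (floored at 16.5 A; the rigid NBD geometry caps the
#' asymmetry), boundary with one distance in 12.4-13.6 and one in
#' 14.4-15.6 A. Classes cycle through [mock_class_names()].
#'
#' @param n cohort size.
#' @param p_open,p_closed,p_boundary state mix (must sum to 1).
#' @param noise_sigma coordinate noise (default 0.3 A).
#' @param seed master seed; the cohort is a pure function of it.
#' @param n_chains chains per assembly.
#' @return list of `list(structure, truth)`, plus attribute `domtblout`
#'   (rendered text for the whole cohort).
#' @export
make_cohort <- function(n, p_open = 0.5, p_closed = 0.5, p_boundary = 0,
                        noise_sigma = 0.3, seed = 1L, n_chains = 2L) {
  stopifnot(n >= 1L, abs(p_open + p_closed + p_boundary - 1) < 1e-9)
  n_open <- round(n * p_open)
  n_closed <- round(n * p_closed)
  n_boundary <- n - n_open - n_closed
  states <- rep(c("open", "closed", "boundary"),
                times = c(n_open, n_closed, n_boundary))
  classes <- rep(mock_class_names(), length.out = n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", n)
  hits <- list()
  for (i in seq_len(n)) {
    d <- switch(states[i],
                closed = runif(2, 8, 11.5),
                open = {
                  d1 <- runif(1, 20, 80)
                  c(d1, max(16.5, min(80, d1 + runif(1, -25, 25))))
                },
                boundary = sample(c(runif(1, 12.4, 13.6),
                                    runif(1, 14.4, 15.6))))
    sp <- mock_spec(planted_class = classes[i], planted_state = states[i],
                    planted_distances = d, n_chains = n_chains,
                    noise_sigma = noise_sigma,
                    seed = sample.int(.Machine$integer.max %/% 2L, 1L))
    mt <- make_mock_transporter(sp)
    mt$truth$entry_id <- sprintf("mock%03d", i)
    mt$structure$entry_id <- mt$truth$entry_id
    out[[i]] <- mt
    hits[[i]] <- .truth_hits(mt$truth)
  }
  attr(out, "domtblout") <- make_mock_domtblout(do.call(rbind, hits))
  out
}

#' Write a cohort to disk (structures as mmCIF + one domtblout)
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, list of written structure paths and the domtblout
#'   path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort, function(mt) {
    p <- file.path(dir, paste0(mt$truth$entry_id, ".cif"))
    write_mmcif(mt$structure, p)
    p
  }, "")
  dp <- file.path(dir, "hits.domtblout")
  writeLines(attr(cohort, "domtblout"), dp)
  invisible(list(structures = paths, domtblout = dp))
}
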