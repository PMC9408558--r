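# Family assignment, anchor transfer, conftor measurement, conformation
# rules, NBD pairing.

lib <- make_reference_library()

test_that("references assign to their own class with TM 1", {
  for (cl in mock_class_names()) {
    fam <- assign_family(lib$entries[[cl]]$structure, lib)
    expect_equal(fam$class_name, cl)
    expect_equal(fam$best_tm, 1, tolerance = 1e-6)
    expect_lt(fam$runner_up_tm, fam$best_tm)
  }
})

test_that("noise-perturbed references keep their class above threshold", {
  mt <- make_mock_transporter(mock_spec("Pgp-like", "open",
                                        planted_distances = c(40, 40),
                                        noise_sigma = 0.5, seed = 17))
  fam <- assign_family(mt$structure, lib)
  expect_equal(fam$class_name, "Pgp-like")
  expect_gt(fam$best_tm, 0.6)
})

test_that("an extended chain is unclassified and hints raise flags", {
  n <- length(lib$entries[["Pgp-like"]]$inward_ca)
  ext <- coordset(data.frame(chain = "A", resno = seq_len(n)),
                  cbind(3.8 * seq_len(n), 0, 0))
  fam <- assign_family(ext, lib, hint = "Pgp-like")
  expect_equal(fam$class_name, "unclassified")
  expect_true(all(vapply(fam$by_class, `[[`, 0, "tm") <= 0.6))
  expect_true("hint_without_structural_support" %in% fam$flags)
  # hint disagreeing with a confident structural call is flagged, not obeyed
  fam2 <- assign_family(lib$entries[["MacB-like"]]$structure, lib,
                        hint = "Pgp-like")
  expect_equal(fam2$class_name, "MacB-like")
  expect_true("hint_disagreement" %in% fam2$flags)
})

test_that("anchor transfer returns the annotated anchors on self-alignment", {
  nbd <- lib$nbd_reference
  found <- locate_anchors(nbd$ca, nbd)
  expect_equal(found$anchors$resno[found$anchors$role == "walker_a_k"],
               nbd$anchors$walker_a_k)
  expect_equal(found$anchors$resno[found$anchors$role == "signature_g"],
               nbd$anchors$signature_g)
  expect_equal(found$tm, 1, tolerance = 1e-6)
  expect_length(found$flags, 0)
})

test_that("anchor transfer follows renumbering", {
  nbd <- lib$nbd_reference
  shifted <- coordset(transform(nbd$ca$labels, resno = resno + 100L),
                      nbd$ca$xyz)
  found <- locate_anchors(shifted, nbd)
  expect_equal(sort(found$anchors$resno),
               sort(100L + c(nbd$anchors$walker_a_k,
                             nbd$anchors$signature_g)))
})

test_that("a deleted anchor residue falls back to a +/-2 neighbour", {
  nbd <- lib$nbd_reference
  wa <- nbd$anchors$walker_a_k
  drop <- which(nbd$ca$labels$resno %in% (wa - 1L):(wa + 1L))
  del <- coordset(nbd$ca$labels[-drop, ], nbd$ca$xyz[-drop, ])
  found <- locate_anchors(del, nbd)
  row <- found$anchors[found$anchors$role == "walker_a_k", ]
  expect_true(row$found)
  expect_true(row$approximate)
  expect_true("anchor_approximate" %in% found$flags)
  expect_lte(abs(row$resno - wa), 4L)  # a residue near the deleted anchor
})

test_that("planted conftor distances are recovered exactly", {
  for (dd in list(c(10, 10), c(12, 30))) {
    st <- if (all(dd < 14)) "closed" else "boundary"
    mt <- make_mock_transporter(mock_spec("Pgp-like", st,
                                          planted_distances = dd))
    tr <- mt$truth
    a <- tr$anchors[tr$anchors$nbd == unique(tr$anchors$nbd)[1], ]
    b <- tr$anchors[tr$anchors$nbd == unique(tr$anchors$nbd)[2], ]
    a$found <- TRUE; a$ins <- NA; b$found <- TRUE; b$ins <- NA
    m <- compute_conftor(mt$structure, a, b)
    expect_true(m$complete)
    expect_equal(m$distance_ab, dd[1], tolerance = 1e-6)
    expect_equal(m$distance_ba, dd[2], tolerance = 1e-6)
  }
})

test_that("a missing anchor CA yields an incomplete measurement", {
  mt <- make_mock_transporter(mock_spec("Pgp-like", "closed"))
  tr <- mt$truth
  a <- tr$anchors[tr$anchors$nbd == "A", ]
  b <- tr$anchors[tr$anchors$nbd == "B", ]
  a$found <- TRUE; a$ins <- NA; b$found <- TRUE; b$ins <- NA
  s <- mt$structure
  s$atom <- s$atom[!(s$atom$chain == a$chain[1] &
                       s$atom$resno == a$resno[1]), ]
  m <- compute_conftor(s, a, b)
  expect_false(m$complete)
  expect_true(is.na(m$distance_ab))
  expect_equal(classify_conformation_conftor(m)$conformation, "unassigned")
})

test_that("the conftor rule needs both distances below the cutoff", {
  mk <- function(ab, ba) list(distance_ab = ab, distance_ba = ba,
                              complete = TRUE)
  expect_equal(classify_conformation_conftor(mk(10, 11))$conformation,
               "closed")
  expect_equal(classify_conformation_conftor(mk(20, 22))$conformation,
               "open")
  # one formed ATP site is not enough
  r <- classify_conformation_conftor(mk(13, 15))
  expect_equal(r$conformation, "open")
  expect_true(r$boundary)
  # the cutoff itself is open (strict inequality), flagged as boundary
  r <- classify_conformation_conftor(mk(14, 10))
  expect_equal(r$conformation, "open")
  expect_true(r$boundary)
  expect_false(classify_conformation_conftor(mk(30, 40))$boundary)
})

test_that("the conftor rule is monotone in either distance", {
  mk <- function(ab, ba) list(distance_ab = ab, distance_ba = ba,
                              complete = TRUE)
  rank <- c(closed = 0, open = 1)
  for (ab in c(5, 10, 13, 15, 25)) for (ba in c(5, 13, 20)) {
    base <- rank[classify_conformation_conftor(mk(ab, ba))$conformation]
    for (bump in c(1, 5, 20)) {
      expect_gte(rank[classify_conformation_conftor(
        mk(ab + bump, ba))$conformation], base)
      expect_gte(rank[classify_conformation_conftor(
        mk(ab, ba + bump))$conformation], base)
    }
  }
})

test_that("RMSD conformation label picks the nearer reference", {
  e <- lib$entries[["Pgp-like"]]
  r <- classify_conformation_rmsd(e$inward_ref, e$inward_ref, e$outward_ref)
  expect_equal(r$conformation, "open")
  expect_equal(r$rmsd_inward, 0, tolerance = 1e-6)
  # noisy outward copy labels closed
  mt <- make_mock_transporter(mock_spec("Pgp-like", "closed",
                                        planted_distances = c(10, 10),
                                        noise_sigma = 0.3, seed = 8))
  r2 <- classify_conformation_rmsd(mt$structure, e$inward_ref,
                                   e$outward_ref)
  expect_equal(r2$conformation, "closed")
  expect_lt(r2$rmsd_outward, r2$rmsd_inward)
  # an exact tie stays unassigned
  r3 <- classify_conformation_rmsd(
    e$inward_ref, e$inward_ref, e$outward_ref,
    alignments = list(inward = list(rmsd = 1.000), outward = list(rmsd = 1.005)))
  expect_equal(r3$conformation, "unassigned")
  expect_true("rmsd_tie" %in% r3$flags)
  r4 <- classify_conformation_rmsd(e$inward_ref, NULL, NULL)
  expect_equal(r4$conformation, "unassigned")
})

test_that("NBD pairing handles 2, 3 and 4 domains", {
  mk_ranges <- function(centros) {
    nbd <- mock_nbd_fold()$ca$xyz
    nbd <- sweep(nbd, 2, colMeans(nbd))
    atoms <- do.call(rbind, lapply(seq_along(centros), function(i) {
      xyz <- sweep(nbd, 2, centros[[i]], "+")
      data.frame(chain = LETTERS[i], resno = seq_len(nrow(xyz)),
                 resname = "ALA", atom = "CA", x = xyz[, 1], y = xyz[, 2],
                 z = xyz[, 3], stringsAsFactors = FALSE)
    }))
    list(structure = abc_structure(atoms, "pairfix"),
         ranges = data.frame(chain = LETTERS[seq_along(centros)],
                             start = 1L, end = nrow(nbd),
                             stringsAsFactors = FALSE))
  }
  two <- mk_ranges(list(c(0, 0, 0), c(40, 0, 0)))
  p2 <- pair_nbds(two$structure, two$ranges)
  expect_equal(p2$pairs, list(c(1L, 2L)))
  expect_length(p2$flags, 0)
  # four NBDs in two planted couples
  four <- mk_ranges(list(c(0, 0, 0), c(30, 0, 0),
                         c(200, 0, 0), c(232, 0, 0)))
  p4 <- pair_nbds(four$structure, four$ranges)
  expect_setequal(lapply(p4$pairs, sort), list(c(1L, 2L), c(3L, 4L)))
  expect_true("multi_unit" %in% p4$flags)
  # three: best pair plus a flagged leftover
  three <- mk_ranges(list(c(0, 0, 0), c(30, 0, 0), c(500, 0, 0)))
  p3 <- pair_nbds(three$structure, three$ranges)
  expect_equal(p3$pairs[[1]], c(1L, 2L))
  expect_equal(p3$leftover, 3L)
  expect_true("unpaired_nbd" %in% p3$flags)
  expect_error(pair_nbds(two$structure, two$ranges[1, ]), "two NBD")
})
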