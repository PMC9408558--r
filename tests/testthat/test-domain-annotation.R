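# HMMER domtblout parsing, hit filtering, categorization, unit calls.

test_that("parse_domtblout reads data rows and skips comments", {
  h <- rbind(mock_hit("e1_A", "ABC_tran", "PF00005", 200, 10, 205),
             mock_hit("e1_A", "ABC_membrane", "PF00664", 270, 300, 560))
  txt <- make_mock_domtblout(h)
  hits <- parse_domtblout(txt)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$profile_accession, c("PF00005", "PF00664"))
  # comments only -> empty hit list
  expect_equal(nrow(parse_domtblout(c("# a comment", "", "# another"))), 0L)
})

test_that("a crafted row is parsed field by field", {
  h <- mock_hit("chainX", "ProfY", "PF99999", 260, ali_from = 7,
                ali_to = 251, hmm_from = 5, hmm_to = 250, ievalue = 1e-30)
  hits <- parse_domtblout(make_mock_domtblout(h))
  expect_equal(hits$domain_ievalue, 1e-30)
  expect_equal(hits$hmm_from, 5L)
  expect_equal(hits$hmm_to, 250L)
  expect_equal(hits$profile_length, 260L)
  expect_equal(hits$ali_from, 7L)
  expect_equal(hits$ali_to, 251L)
})

test_that("render -> parse is the identity on all modeled fields", {
  h <- rbind(mock_hit("e1_A", "ABC_tran", "PF00005", 200, 10, 205,
                      ievalue = 3.2e-57),
             mock_hit("e2_B", "FtsX", "PF02687", 120, 4, 119,
                      ievalue = 0.00042, hmm_from = 2, hmm_to = 117))
  back <- parse_domtblout(make_mock_domtblout(h))
  for (col in setdiff(names(h), "description"))
    expect_equal(back[[col]], h[[col]], info = col)
})

test_that("malformed rows fail with the offending line number", {
  txt <- make_mock_domtblout(mock_hit("e1_A", "ABC_tran", "PF00005",
                                      200, 10, 205))
  txt[4] <- "only three fields here"
  expect_error(parse_domtblout(txt), "line 4")
})

test_that("filter_hits applies the E-value and 90% coverage rules", {
  good <- mock_hit("e_A", "ABC_tran", "PF00005", 200, 1, 210,
                   hmm_from = 1, hmm_to = 195, ievalue = 1e-5)   # 97.5%
  bad_e <- mock_hit("e_A", "ABC_tran", "PF00005", 200, 1, 210,
                    ievalue = 0.01)                               # E too high
  bad_cov <- mock_hit("e_A", "ABC_tran", "PF00005", 200, 1, 180,
                      hmm_from = 1, hmm_to = 170, ievalue = 1e-40) # 85%
  hits <- parse_domtblout(make_mock_domtblout(rbind(good, bad_e, bad_cov)))
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$hmm_to, 195L)
  # exactly 90% coverage is retained (>= rule)
  edge <- parse_domtblout(make_mock_domtblout(
    mock_hit("e_A", "ABC_tran", "PF00005", 200, 1, 190,
             hmm_from = 1, hmm_to = 180, ievalue = 1e-10)))
  expect_equal(nrow(filter_hits(edge)), 1L)
})

test_that("filter_hits is idempotent and order-preserving", {
  set.seed(7)
  rows <- do.call(rbind, lapply(1:12, function(i)
    mock_hit(sprintf("e%d_A", i), "ABC_tran", "PF00005", 200, 1, 210,
             hmm_from = 1, hmm_to = sample(150:200, 1),
             ievalue = 10^runif(1, -50, 0))))
  hits <- parse_domtblout(make_mock_domtblout(rows))
  once <- filter_hits(hits)
  twice <- filter_hits(once)
  expect_identical(once, twice)
  expect_true(!is.unsorted(match(once$target_name, hits$target_name)))
})

test_that("categorize_hits annotates known profiles and reports unknowns", {
  h <- rbind(mock_hit("e_A", "ABC_membrane", "PF00664", 270, 1, 280),
             mock_hit("e_A", "ABC2_membrane", "PF01061", 240, 1, 250),
             mock_hit("e_A", "Mystery", "PF55555", 100, 1, 105))
  hits <- categorize_hits(parse_domtblout(make_mock_domtblout(h)))
  expect_equal(hits$category, c("TMD", "TMD", "other"))
  expect_equal(hits$class_hint[1:2], c("Pgp-like", "ABCG2-like"))
  expect_equal(attr(hits, "uncataloged"), "PF55555")
})

test_that("functional-unit verdicts follow the NBD/TMD counting rule", {
  cat_hits <- function(...) categorize_hits(parse_domtblout(
    make_mock_domtblout(rbind(...))))
  nbd <- function(chain, from = 1)
    mock_hit(paste0("e_", chain), "ABC_tran", "PF00005", 200, from,
             from + 209)
  tmd <- function(chain, from = 500)
    mock_hit(paste0("e_", chain), "ABC_membrane", "PF00664", 270, from,
             from + 279)
  # 1 NBD + 1 TMD: half a transporter
  u <- call_functional_unit("e", cat_hits(nbd("A"), tmd("A")))
  expect_equal(u$verdict, "not_functional")
  # homodimer of half transporters: 2 x (1 NBD + 1 TMD)
  u <- call_functional_unit("e", cat_hits(nbd("A"), tmd("A"),
                                          nbd("B"), tmd("B")))
  expect_equal(u$verdict, "functional")
  expect_equal(u$n_nbd, 2L)
  # 2 NBD and no TMD: candidate novel fold, flag for manual review
  u <- call_functional_unit("e", cat_hits(nbd("A"), nbd("A", from = 300)))
  expect_equal(u$verdict, "needs_review")
  # nothing at all
  u <- call_functional_unit("e", cat_hits(tmd("A"))[0, ])
  expect_equal(u$verdict, "not_functional")
})

test_that("unit verdicts are invariant under chain permutation", {
  rows <- rbind(
    mock_hit("e_B", "ABC_tran", "PF00005", 200, 300, 509),
    mock_hit("e_A", "ABC_membrane", "PF00664", 270, 1, 280),
    mock_hit("e_A", "ABC_tran", "PF00005", 200, 300, 509),
    mock_hit("e_B", "ABC_membrane", "PF00664", 270, 1, 280))
  hits <- categorize_hits(parse_domtblout(make_mock_domtblout(rows)))
  verdicts <- sapply(1:6, function(i) {
    perm <- hits[sample(nrow(hits)), ]
    call_functional_unit("e", perm)$verdict
  })
  expect_true(all(verdicts == "functional"))
})

test_that("overlapping same-category hits collapse to the best E-value", {
  rows <- rbind(
    mock_hit("e_A", "ABC_tran", "PF00005", 200, 10, 219, ievalue = 1e-50),
    mock_hit("e_A", "SMC_N", "PF02463", 210, 15, 224, ievalue = 1e-12),
    mock_hit("e_A", "ABC_tran", "PF00005", 200, 400, 609, ievalue = 1e-45))
  hits <- categorize_hits(parse_domtblout(make_mock_domtblout(rows)))
  collapsed <- collapse_overlapping_hits(hits)
  expect_equal(nrow(collapsed), 2L)
  expect_true(all(collapsed$domain_ievalue <= 1e-45))
  u <- call_functional_unit("e", hits)
  expect_equal(u$n_nbd, 2L)  # not 3: the overlap is one physical domain
})

test_that("map_hit_to_structure maps spans and reports gaps", {
  xyz <- fixture_xyz(30)
  s <- structure_from_xyz(xyz)
  hit <- mock_hit("fix_A", "ABC_tran", "PF00005", 20, 10, 20)
  mp <- map_hit_to_structure(hit, s, "A")
  expect_equal(nrow(mp$labels), 11L)
  expect_false(mp$low_coverage)
  # residues 12-14 unresolved (label_seq keeps the sequence positions)
  s2 <- structure_from_xyz(xyz[-(12:14), ], resno = (1:30)[-(12:14)],
                           label_seq = (1:30)[-(12:14)])
  mp2 <- map_hit_to_structure(hit, s2, "A")
  expect_equal(nrow(mp2$labels), 8L)
  expect_equal(mp2$gap_count, 3L)
  expect_error(map_hit_to_structure(hit, s, "Q"), "not present")
})
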