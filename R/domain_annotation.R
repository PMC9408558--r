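## HMMER3 per-domain tabular output ("domtblout") from `hmmsearch`: one row
## per domain, 22 whitespace-separated fields plus a free-text description.
## In hmmsearch the target is the sequence and the query is the profile HMM.

.domtblout_cols <- c(
  "target_name", "target_accession", "tlen",
  "profile_name", "profile_accession", "profile_length",
  "full_seq_evalue", "full_seq_score", "full_seq_bias",
  "dom_n", "dom_of", "domain_cevalue", "domain_ievalue",
  "domain_score", "domain_bias",
  "hmm_from", "hmm_to", "ali_from", "ali_to", "env_from", "env_to",
  "acc", "description")

#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' @param input path to a domtblout file, or a character vector of its lines.
#' @return data.frame of class `pfam_hits`, one row per domain hit.
#' @export
parse_domtblout <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) return(.empty_hits())
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    fields <- strsplit(trimws(lines[rows[k]]), "[ \t]+")[[1]]
    if (length(fields) < 22L)
      stop("format error in domtblout line ", rows[k], ": expected >= 22 ",
           "fields, found ", length(fields))
    desc <- if (length(fields) > 22L)
      paste(fields[23:length(fields)], collapse = " ") else ""
    out[[k]] <- data.frame(
      target_name = fields[1], target_accession = fields[2],
      tlen = as.integer(fields[3]),
      profile_name = fields[4], profile_accession = fields[5],
      profile_length = as.integer(fields[6]),
      full_seq_evalue = as.numeric(fields[7]),
      full_seq_score = as.numeric(fields[8]),
      full_seq_bias = as.numeric(fields[9]),
      dom_n = as.integer(fields[10]), dom_of = as.integer(fields[11]),
      domain_cevalue = as.numeric(fields[12]),
      domain_ievalue = as.numeric(fields[13]),
      domain_score = as.numeric(fields[14]),
      domain_bias = as.numeric(fields[15]),
      hmm_from = as.integer(fields[16]), hmm_to = as.integer(fields[17]),
      ali_from = as.integer(fields[18]), ali_to = as.integer(fields[19]),
      env_from = as.integer(fields[20]), env_to = as.integer(fields[21]),
      acc = as.numeric(fields[22]),
      description = desc, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  bad <- which(hits$hmm_from > hits$hmm_to | hits$hmm_to > hits$profile_length |
                 hits$ali_from > hits$ali_to |
                 hits$domain_ievalue < 0 | hits$full_seq_evalue < 0)
  if (length(bad))
    stop("format error in domtblout: inconsistent coordinates/E-values in ",
         "data row(s) ", paste(bad, collapse = ", "))
  class(hits) <- c("pfam_hits", "data.frame")
  hits
}

.empty_hits <- function() {
  hits <- as.data.frame(setNames(
    rep(list(character(0)), length(.domtblout_cols)), .domtblout_cols))
  class(hits) <- c("pfam_hits", "data.frame")
  hits
}

#' Filter domain hits on E-value and profile coverage
#'
#' A hit is retained iff its per-domain independent E-value is at most
#' `max_evalue` and the matched HMM span covers at least
#' `min_profile_coverage` of the profile length
#' (`(hmm_to - hmm_from + 1) >= min_profile_coverage * profile_length`).
#'
#' @param hits a `pfam_hits` data.frame.
#' @param max_evalue maximum i-Evalue; default 0.001.
#' @param min_profile_coverage minimum fraction of the HMM profile matched;
#'   default 0.90.
#' @export
filter_hits <- function(hits, max_evalue = 0.001, min_profile_coverage = 0.90) {
  if (nrow(hits) == 0L) return(hits)
  span <- hits$hmm_to - hits$hmm_from + 1L
  keep <- hits$domain_ievalue <= max_evalue &
    span >= min_profile_coverage * hits$profile_length
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read the shipped Pfam profile catalog
#'
#' The catalog maps Pfam accessions of ABC-related profiles to their domain
#' category (NBD, TMD or other), Pfam clan, and — for TMD profiles — the
#' structural class their members exhibit (Pgp-like, ABCG2-like, MacB-like,
#' ...). It ships as an editable TSV.
#'
#' @param path optional path to an alternative catalog TSV.
#' @return data.frame with columns `accession`, `name`, `category`, `clan`,
#'   `class_hint`.
#' @export
read_profile_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pfam_catalog.tsv", package = "abcconftor")
  cat_df <- utils::read.table(path, header = TRUE, sep = "\t",
                              quote = "", comment.char = "#",
                              stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "name", "category", "clan", "class_hint")
                %in% names(cat_df)))
  if (any(!cat_df$category %in% c("NBD", "TMD", "other")))
    stop("catalog category must be NBD, TMD or other")
  if (any(nzchar(cat_df$class_hint) & cat_df$category != "TMD"))
    stop("class_hint is only meaningful for TMD profiles")
  cat_df
}

#' Annotate hits with domain category and structural-class hint
#'
#' Accessions absent from the catalog are not dropped: their rows receive
#' category `"other"` and are listed in the `uncataloged` attribute.
#'
#' @param hits a `pfam_hits` data.frame.
#' @param catalog catalog data.frame from [read_profile_catalog()].
#' @return `hits` with `category` and `class_hint` columns; attribute
#'   `uncataloged` holds unmatched accessions.
#' @export
categorize_hits <- function(hits, catalog = read_profile_catalog()) {
  idx <- match(.strip_pfam_version(hits$profile_accession), catalog$accession)
  hits$category <- ifelse(is.na(idx), "other", catalog$category[idx])
  hits$class_hint <- ifelse(is.na(idx), "", catalog$class_hint[idx])
  attr(hits, "uncataloged") <-
    sort(unique(hits$profile_accession[is.na(idx)]))
  hits
}

.strip_pfam_version <- function(acc) sub("\\.[0-9]+$", "", acc)

#' Collapse overlapping same-category hits on one chain
#'
#' Two hits of the same category on the same target whose alignment spans
#' mutually overlap by more than 50 percent describe one physical domain;
#' only the lowest-i-Evalue hit of such a group is kept, so domains are not
#' double-counted in functional-unit calls.
#'
#' @param hits categorized `pfam_hits`.
#' @export
collapse_overlapping_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  drop <- rep(FALSE, nrow(hits))
  o <- order(hits$domain_ievalue, -hits$domain_score)
  for (a in seq_along(o)) {
    i <- o[a]
    if (drop[i]) next
    for (b in seq_along(o)) {
      j <- o[b]
      if (j == i || drop[j]) next
      if (hits$target_name[i] != hits$target_name[j] ||
          hits$category[i] != hits$category[j]) next
      ov <- min(hits$ali_to[i], hits$ali_to[j]) -
        max(hits$ali_from[i], hits$ali_from[j]) + 1L
      if (ov <= 0L) next
      len_i <- hits$ali_to[i] - hits$ali_from[i] + 1L
      len_j <- hits$ali_to[j] - hits$ali_from[j] + 1L
      if (ov > 0.5 * len_i && ov > 0.5 * len_j && b > a) drop[j] <- TRUE
    }
  }
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the functional ABC unit of one assembly
#'
#' Counts NBD- and TMD-category domain hits across all chains of one
#' biological unit (a homodimer of a half transporter contributes each
#' chain's hits) and issues the verdict: `functional` for at least two NBDs
#' and at least one TMD, `needs_review` for at least two NBDs without any
#' TMD (possible novel transmembrane fold), otherwise `not_functional`.
#'
#' @param entry_id assembly identifier.
#' @param hits filtered, categorized hits for all chains of the assembly.
#' @param collapse collapse overlapping same-category hits first
#'   (default TRUE).
#' @return list of class `unit_call`: `entry_id`, `n_nbd`, `n_tmd`,
#'   `verdict`, `contributing_hits`.
#' @export
call_functional_unit <- function(entry_id, hits, collapse = TRUE) {
  if (nrow(hits) && is.null(hits$category))
    stop("hits must be categorized first (see categorize_hits)")
  if (collapse && nrow(hits)) hits <- collapse_overlapping_hits(hits)
  n_nbd <- sum(hits$category == "NBD")
  n_tmd <- sum(hits$category == "TMD")
  verdict <- if (n_nbd >= 2L && n_tmd >= 1L) "functional"
  else if (n_nbd >= 2L) "needs_review"
  else "not_functional"
  out <- list(entry_id = entry_id, n_nbd = n_nbd, n_tmd = n_tmd,
              verdict = verdict, contributing_hits = hits)
  class(out) <- "unit_call"
  out
}

#' @export
print.unit_call <- function(x, ...) {
  cat("unit_call '", x$entry_id, "': ", x$n_nbd, " NBD + ", x$n_tmd,
      " TMD -> ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Map a sequence-coordinate domain hit onto structure residues
#'
#' Returns the structure residues whose per-chain polymer positions
#' (label_seq) fall inside the hit's alignment span; positions missing from
#' the structure (unresolved density) are reported as a gap count. When less
#' than half of the span is resolved, the result carries a low-coverage
#' flag.
#'
#' @param hit one row of a `pfam_hits` data.frame.
#' @param structure an `abc_structure`.
#' @param chain_id chain to map onto.
#' @return list: `labels` (data.frame of matched residues), `gap_count`,
#'   `low_coverage` flag, `resno_range`.
#' @export
map_hit_to_structure <- function(hit, structure, chain_id) {
  stopifnot(inherits(structure, "abc_structure"))
  if (!chain_id %in% chain_ids(structure))
    stop("chain '", chain_id, "' not present in structure '",
         structure$entry_id, "'")
  at <- structure$atom[!structure$atom$het &
                         structure$atom$chain == chain_id, , drop = FALSE]
  res <- at[!duplicated(paste(at$resno, at$ins)), , drop = FALSE]
  span <- hit$ali_from:hit$ali_to
  sel <- res[res$label_seq %in% span, , drop = FALSE]
  gap_count <- length(span) - nrow(sel)
  list(labels = data.frame(chain = sel$chain, resno = sel$resno,
                           ins = sel$ins, label_seq = sel$label_seq,
                           stringsAsFactors = FALSE),
       gap_count = gap_count,
       low_coverage = nrow(sel) < 0.5 * length(span),
       resno_range = if (nrow(sel)) range(sel$resno) else c(NA, NA))
}
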